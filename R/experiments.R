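#' Model grid of the simulation study
#'
#' The 15 (k, MAF) combinations with their low and high heritabilities used
#' to generate the strict epistatic models of the simulation study. Not
#' every listed heritability is attainable by a strict model under HWE
#' weighting (see [generate_penetrance_model()]); [run_table()] records such
#' cells as skipped.
#'
#' @return data.frame with columns `k`, `maf`, `h2_low`, `h2_high`.
#' @export
model_grid <- function() {
  data.frame(
    k   = rep(c(2L, 3L, 4L), each = 5L),
    maf = rep(c(0.05, 0.1, 0.2, 0.3, 0.4), 3L),
    h2_low  = c(0.05, 0.05, 0.05, 0.05, 0.05,
                0.005, 0.05, 0.05, 0.05, 0.05,
                0.001, 0.005, 0.05, 0.05, 0.05),
    h2_high = c(0.1, 0.2, 0.2, 0.2, 0.2,
                0.01, 0.1, 0.2, 0.2, 0.2,
                0.002, 0.01, 0.1, 0.2, 0.2))
}

#' Run one experiment cell
#'
#' For each replicate: generate a strict k-SNP model, sample a case-control
#' dataset, sort the SNPs by the expansion bound with `m = k - 1` and
#' (independently) by the 1-SNP score, locate the injected pattern
#' analytically from its sorted ranks, and record the fraction of the
#' \eqn{\binom{n}{k}} patterns checked under each sorting.
#'
#' @param k,maf,h2 model parameters of the cell.
#' @param n_snps SNPs per dataset.
#' @param replicates number of datasets (> 0).
#' @param seed master seed for the cell; per-replicate seeds derive from it.
#' @param n_cases,n_controls individuals per phenotype class.
#' @param alpha BDeu prior equivalent sample size.
#' @param prevalence_target,noise_maf_range passed to the simulator.
#' @return An object of class `experiment_cell`: the configuration, a
#'   `results` data.frame (replicate, fraction_bound, fraction_score) and a
#'   `summary` list with the two mean fractions.
#' @examples
#' \donttest{
#' cell <- run_cell(k = 2, maf = 0.05, h2 = 0.05, n_snps = 100,
#'                  replicates = 5, seed = 11)
#' cell$summary
#' }
#' @export
run_cell <- function(k, maf, h2, n_snps, replicates, seed,
                     n_cases = 1000L, n_controls = 1000L, alpha = 4,
                     prevalence_target = 0.25,
                     noise_maf_range = c(0.05, 0.5)) {
  stopifnot(replicates > 0)
  cfg <- score_config(alpha)
  seeds <- derive_seeds(seed, 2L * replicates)
  fb <- fs <- numeric(replicates)
  for (r in seq_len(replicates)) {
    model <- generate_penetrance_model(k, maf, h2, prevalence_target,
                                       seed = seeds[2L * r - 1L])
    sc <- sim_config(k, maf, h2, prevalence_target, n_snps = n_snps,
                     n_cases = n_cases, n_controls = n_controls,
                     noise_maf_range = noise_maf_range,
                     seed = seeds[2L * r])
    ds <- sample_dataset(model, sc)
    ord_b <- sort_snps(ds, "bound", m = k - 1L, cfg)
    ord_s <- sort_snps(ds, "score", cfg = cfg)
    fb[r] <- find_pattern_analytic(ord_b, ds$truth, k)$fraction
    fs[r] <- find_pattern_analytic(ord_s, ds$truth, k)$fraction
  }
  structure(list(config = list(k = k, maf = maf, h2 = h2, n_snps = n_snps,
                               replicates = replicates, seed = seed,
                               n_cases = n_cases, n_controls = n_controls,
                               alpha = alpha,
                               prevalence_target = prevalence_target,
                               noise_maf_range = noise_maf_range),
                 results = data.frame(replicate = seq_len(replicates),
                                      fraction_bound = fb,
                                      fraction_score = fs),
                 summary = list(mean_fraction_bound = mean(fb),
                                mean_fraction_score = mean(fs))),
            class = "experiment_cell")
}

#' @export
print.experiment_cell <- function(x, ...) {
  cat(sprintf(paste0("experiment_cell: k=%d maf=%g h2=%g, %d SNPs, ",
                     "%d replicates\n  mean fraction checked: bound %.4g, ",
                     "score %.4g\n"),
              x$config$k, x$config$maf, x$config$h2, x$config$n_snps,
              x$config$replicates, x$summary$mean_fraction_bound,
              x$summary$mean_fraction_score))
  invisible(x)
}

#' Run the simulation study over a model grid
#'
#' Expands `grid` (one row per (k, MAF) with low/high heritability) over the
#' requested dataset dimensions, runs [run_cell()] for every feasible cell
#' and returns one row per cell with the mean bound- and score-sorted
#' fractions. Infeasible cells (the target heritability is unattainable by
#' a strict model) are skipped and listed in the `"skipped"` attribute.
#'
#' @param grid data.frame as from [model_grid()].
#' @param n_snps dataset dimensions to cross with the grid.
#' @param replicates datasets per cell.
#' @param seed master seed; cell seeds derive from it deterministically.
#' @param ... further arguments passed to [run_cell()].
#' @param heritability which heritability columns to run.
#' @return data.frame with columns `k`, `maf`, `heritability` (low/high),
#'   `h2`, `n_snps`, `replicates`, `mean_fraction_bound`,
#'   `mean_fraction_score`; attribute `"skipped"` lists skipped cells, and
#'   `"cells"` holds the `experiment_cell` objects.
#' @export
run_table <- function(grid = model_grid(), n_snps = c(100L, 1000L),
                      replicates = 20L, seed = 1L, ...,
                      heritability = c("low", "high")) {
  heritability <- match.arg(heritability, several.ok = TRUE)
  cells <- expand.grid(row = seq_len(nrow(grid)), herit = heritability,
                       n_snps = n_snps, stringsAsFactors = FALSE)
  if (nrow(cells) == 0L || nrow(grid) == 0L) {
    out <- data.frame(k = integer(0), maf = numeric(0),
                      heritability = character(0), h2 = numeric(0),
                      n_snps = integer(0), replicates = integer(0),
                      mean_fraction_bound = numeric(0),
                      mean_fraction_score = numeric(0))
    attr(out, "skipped") <- character(0)
    return(out)
  }
  seeds <- derive_seeds(seed, nrow(cells))
  rows <- list()
  objs <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(cells))) {
    g <- grid[cells$row[i], ]
    h2 <- if (cells$herit[i] == "low") g$h2_low else g$h2_high
    label <- sprintf("k=%d maf=%g h2=%g n_snps=%d", g$k, g$maf, h2,
                     cells$n_snps[i])
    cell <- tryCatch(
      run_cell(k = g$k, maf = g$maf, h2 = h2, n_snps = cells$n_snps[i],
               replicates = replicates, seed = seeds[i], ...),
      error = function(e) {
        if (grepl("infeasible", conditionMessage(e))) NULL else stop(e)
      })
    if (is.null(cell)) {
      skipped <- c(skipped, label)
      next
    }
    objs[[label]] <- cell
    rows[[length(rows) + 1L]] <- data.frame(
      k = g$k, maf = g$maf, heritability = cells$herit[i], h2 = h2,
      n_snps = cells$n_snps[i], replicates = replicates,
      mean_fraction_bound = cell$summary$mean_fraction_bound,
      mean_fraction_score = cell$summary$mean_fraction_score)
  }
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  attr(out, "cells") <- objs
  out
}

#' Plot mean fractions of the search space checked
#'
#' One figure per pattern size k (mean bound-sorted fraction against MAF,
#' lines by heritability level and dataset dimension) plus one cross-k
#' figure restricted to high heritability and the largest dimension,
#' showing how performance improves with the number of interacting SNPs.
#' File names are derived from a hash of the result table, so reruns on the
#' same results overwrite their own files.
#'
#' @param results data.frame from [run_table()] (non-empty).
#' @param dir output directory.
#' @param device file extension understood by [ggplot2::ggsave()]
#'   (default `"png"`).
#' @return Character vector of files written, invisibly; the ggplot objects
#'   are attached as attribute `"plots"`.
#' @export
plot_summary <- function(results, dir = ".", device = "png") {
  if (is.null(results) || nrow(results) == 0L) stop("empty result table")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  key <- substr(paste(
    format(sum(results$mean_fraction_bound) * 1e7, digits = 12),
    nrow(results), sep = "x"), 1, 24)
  tag <- gsub("[^0-9a-zA-Z]", "", key)
  files <- character(0)
  plots <- list()
  for (kk in sort(unique(results$k))) {
    sub <- results[results$k == kk, ]
    sub$series <- paste0(sub$heritability, " h2, ", sub$n_snps, " SNPs")
    p <- ggplot2::ggplot(sub, ggplot2::aes(x = .data$maf,
                                           y = .data$mean_fraction_bound,
                                           colour = .data$series,
                                           group = .data$series)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "minor allele frequency",
                    y = "mean fraction of patterns checked (bound)",
                    colour = NULL,
                    title = sprintf("%d-SNP strict epistatic models", kk)) +
      ggplot2::theme_minimal()
    f <- file.path(dir, sprintf("fraction_k%d_%s.%s", kk, tag, device))
    ggplot2::ggsave(f, p, width = 6, height = 4)
    files <- c(files, f)
    plots[[sprintf("k%d", kk)]] <- p
  }
  hi <- results[results$heritability == "high" &
                  results$n_snps == max(results$n_snps), ]
  if (nrow(hi) > 0L) {
    hi$k_label <- factor(paste0(hi$k, "-SNP"))
    p <- ggplot2::ggplot(hi, ggplot2::aes(x = .data$maf,
                                          y = .data$mean_fraction_bound,
                                          colour = .data$k_label,
                                          group = .data$k_label)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "minor allele frequency",
                    y = "mean fraction of patterns checked (bound)",
                    colour = NULL,
                    title = sprintf("high heritability, %d SNPs",
                                    max(results$n_snps))) +
      ggplot2::theme_minimal()
    f <- file.path(dir, sprintf("fraction_across_k_%s.%s", tag, device))
    ggplot2::ggsave(f, p, width = 6, height = 4)
    files <- c(files, f)
    plots[["across_k"]] <- p
  }
  attr(files, "plots") <- plots
  invisible(files)
}
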