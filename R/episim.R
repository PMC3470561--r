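#' Hardy-Weinberg genotype probabilities
#'
#' Probability of carrying 0, 1 or 2 copies of the minor allele under
#' Hardy-Weinberg equilibrium at minor allele frequency `maf`.
#'
#' @param maf minor allele frequency in (0, 0.5].
#' @return Numeric vector of length 3, ordered by genotype code 0/1/2.
#' @export
hwe_genotype_probs <- function(maf) {
  stopifnot(maf > 0, maf <= 0.5)
  c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

# Enumeration of all 3^k joint genotypes: matrix G (3^k x k, codes 0/1/2,
# row id = 1 + sum_t G[,t] * 3^(t-1)) and HWE weights wg.
genotype_grid <- function(k, maf) {
  G <- as.matrix(expand.grid(rep(list(0:2), k), KEEP.OUT.ATTRS = FALSE))
  dimnames(G) <- NULL
  w <- hwe_genotype_probs(maf)
  wg <- apply(G, 1L, function(g) prod(w[g + 1L]))
  list(G = G, wg = wg, w = w)
}

# Orthogonal projection (in the HWE-weighted inner product) of a penetrance
# deviation table onto the pure k-way interaction subspace: the set of
# tables whose weighted mean over every coordinate is zero, hence whose
# marginal penetrance over every proper subset of loci equals the grand
# mean. Applies the per-coordinate centering operator (I - E_i) for each
# locus; the operators commute.
strict_projection <- function(f, k, w) {
  for (i in seq_len(k)) {
    step <- 3L^(i - 1L)
    gi <- ((seq_along(f) - 1L) %/% step) %% 3L
    base <- seq_along(f) - gi * step
    f <- f - (w[1] * f[base] + w[2] * f[base + step] + w[3] * f[base + 2L * step])
  }
  f
}

#' Generate a strict epistatic penetrance model
#'
#' Builds a k-SNP penetrance table f(g) over all 3^k joint genotypes such
#' that no proper subset of the loci shows a marginal effect: under
#' Hardy-Weinberg weights, the mean penetrance conditional on any proper
#' subset's genotypes equals the prevalence K for every assignment. The
#' achieved (broad-sense) heritability
#' \deqn{h^2 = \sum_g P(g) (f_g - K)^2 / (K (1 - K))}
#' matches the request exactly up to floating point.
#'
#' A random architecture is drawn as a near-binary random table, projected
#' onto the strict-interaction subspace by alternating projections between
#' the \[0, 1\] box and the subspace (both under the HWE-weighted metric),
#' and finally scaled around K to hit the target heritability; scaling down
#' stays inside the box, so strictness is never clipped away. Prevalence is
#' a soft target: strictness caps the achievable penetrance variance, so for
#' each architecture the generator scans a grid of prevalences and keeps the
#' feasible one closest to `prevalence_target`. Architectures that cannot
#' reach the target heritability at any prevalence are rejected and
#' resampled, up to `max_tries`; some MAF/heritability pairs are infeasible
#' outright (low MAF leaves too little weight on the cells where a strict
#' table may deviate), in which case the error names the pair.
#'
#' @param k number of interacting SNPs (2-4 in the study; any k >= 1 works).
#' @param maf shared minor allele frequency of the interacting SNPs.
#' @param h2 target heritability in \[0, 1).
#' @param prevalence_target preferred disease prevalence K (default 0.25).
#' @param seed optional integer seed (caller's RNG stream is preserved).
#' @param max_tries architectures to attempt before declaring infeasibility.
#' @return An object of class `penetrance_model`: list with `k`, `maf`,
#'   `table` (length 3^k, indexed as in `genotype_grid`), `prevalence`,
#'   `h2` (achieved), `h2_target` and `tries`.
#' @examples
#' m <- generate_penetrance_model(2, maf = 0.2, h2 = 0.05, seed = 1)
#' m
#' @export
generate_penetrance_model <- function(k, maf, h2, prevalence_target = 0.25,
                                      seed = NULL, max_tries = 500L) {
  stopifnot(k >= 1, h2 >= 0, h2 < 1,
            prevalence_target > 0, prevalence_target < 1)
  gg <- genotype_grid(k, maf)
  if (h2 == 0) {
    return(new_penetrance_model(k, maf, rep(prevalence_target, 3L^k),
                                prevalence_target, h2, 0L))
  }
  Kgrid <- unique(c(seq(0.02, 0.05, by = 0.01), seq(0.075, 0.5, by = 0.025),
                    prevalence_target))
  Kord <- Kgrid[order(abs(Kgrid - prevalence_target))]
  with_seed(seed, {
    for (t in seq_len(max_tries)) {
      r0 <- rbinom(3L^k, 1L, 0.5) + runif(3L^k, -0.02, 0.02)
      r0 <- r0 - mean(r0)
      for (K in Kord) {
        d <- strict_projection(r0, k, gg$w)
        for (it in 1:300) {
          f <- pmin(pmax(K + d, 0), 1)
          d2 <- strict_projection(f - K, k, gg$w)
          if (max(abs(d2 - d)) < 1e-10) { d <- d2; break }
          d <- d2
        }
        v0 <- sum(gg$wg * d^2)
        if (v0 < 1e-14) next
        need <- h2 * K * (1 - K)
        if (v0 < need) next
        f <- K + sqrt(need / v0) * d
        if (all(f >= -1e-12 & f <= 1 + 1e-12)) {
          f <- pmin(pmax(f, 0), 1)
          return(new_penetrance_model(k, maf, f, K, h2, t))
        }
      }
    }
  })
  stop(sprintf(paste0("infeasible model: no strict %d-SNP architecture ",
                      "reached h2 = %g at MAF = %g in %d tries ",
                      "(strictness caps the achievable heritability; ",
                      "try a lower h2)"),
               k, h2, maf, max_tries))
}

new_penetrance_model <- function(k, maf, table, prevalence, h2_target, tries) {
  m <- structure(list(k = as.integer(k), maf = maf, table = table,
                      prevalence = prevalence, h2 = NA_real_,
                      h2_target = h2_target, tries = tries),
                 class = "penetrance_model")
  gg <- genotype_grid(k, maf)
  K <- sum(gg$wg * table)
  m$prevalence <- K
  m$h2 <- if (K <= 0 || K >= 1) 0 else sum(gg$wg * (table - K)^2) / (K * (1 - K))
  validate_penetrance_model(m)
  m
}

#' Validate a strict penetrance model
#'
#' Recomputes prevalence, heritability and every proper-subset marginal
#' penetrance from the table and checks the strictness invariant (all
#' conditional mean penetrances within `tol` of K) and the heritability
#' recovery (within 1% relative of the target, unless the target is 0).
#'
#' @param model a `penetrance_model`.
#' @param tol absolute strictness tolerance (default 1e-6).
#' @return `model`, invisibly; errors on violation.
#' @export
validate_penetrance_model <- function(model, tol = 1e-6) {
  stopifnot(inherits(model, "penetrance_model"))
  f <- model$table
  k <- model$k
  if (length(f) != 3L^k) stop("penetrance table must have 3^k entries")
  if (any(f < 0 | f > 1)) stop("penetrance values must lie in [0, 1]")
  K <- model$prevalence
  if (K <= 0 || K >= 1) stop("prevalence must lie in (0, 1)")
  gg <- genotype_grid(k, model$maf)
  if (abs(sum(gg$wg * f) - K) > tol) stop("stored prevalence does not match table")
  # strictness: conditioning on any proper subset leaves mean penetrance K.
  # Checking all single-locus-removed marginals of the deviation iteratively
  # covers all subsets; do it directly per subset for independence from the
  # construction.
  if (k > 1) {
    for (ssize in seq_len(k - 1L)) {
      for (S in as.list(as.data.frame(combn(k, ssize)))) {
        # group cells by the subset's genotypes; weight by the complement
        gid <- rep(0L, 3L^k)
        for (t in seq_along(S)) gid <- gid + gg$G[, S[t]] * 3L^(t - 1L)
        wrest <- gg$wg
        for (t in seq_along(S)) wrest <- wrest / gg$w[gg$G[, S[t]] + 1L]
        cond <- vapply(split(seq_len(3L^k), gid),
                       function(idx) sum(wrest[idx] * f[idx]), numeric(1))
        if (max(abs(cond - K)) > tol)
          stop(sprintf("strictness violated for subset {%s}: max |marginal - K| = %.2e",
                       paste(S, collapse = ","), max(abs(cond - K))))
      }
    }
  }
  h2 <- sum(gg$wg * (f - K)^2) / (K * (1 - K))
  if (model$h2_target > 0 && abs(h2 - model$h2_target) > 0.01 * model$h2_target)
    stop(sprintf("achieved h2 (%.6g) not within 1%% of target (%.6g)",
                 h2, model$h2_target))
  invisible(model)
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat(sprintf(paste0("strict epistatic penetrance model: k = %d, MAF = %g,\n",
                     "  prevalence K = %g, heritability h2 = %.6g ",
                     "(target %.6g, %d architectures tried)\n"),
              x$k, x$maf, x$prevalence, x$h2, x$h2_target, x$tries))
  invisible(x)
}

#' Simulation configuration
#'
#' Parameters of one simulated case-control study: the interaction model
#' (k, maf, h2, prevalence target) and the dataset shape (number of SNPs,
#' cases and controls, noise-SNP MAF range, seed).
#'
#' @param k,maf,h2,prevalence_target model parameters; see
#'   [generate_penetrance_model()].
#' @param n_snps total SNPs in each dataset (>= k).
#' @param n_cases,n_controls individuals per phenotype class.
#' @param noise_maf_range range from which each noise SNP's MAF is drawn
#'   uniformly.
#' @param seed integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(k, maf, h2, prevalence_target = 0.25, n_snps,
                       n_cases = 1000L, n_controls = 1000L,
                       noise_maf_range = c(0.05, 0.5), seed = NULL) {
  stopifnot(maf > 0, maf <= 0.5, h2 >= 0, h2 < 1,
            n_cases >= 1, n_controls >= 1, n_snps >= k,
            length(noise_maf_range) == 2, noise_maf_range[1] <= noise_maf_range[2],
            noise_maf_range[1] > 0, noise_maf_range[2] <= 0.5)
  structure(list(k = as.integer(k), maf = maf, h2 = h2,
                 prevalence_target = prevalence_target,
                 n_snps = as.integer(n_snps), n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 noise_maf_range = noise_maf_range, seed = seed),
            class = "sim_config")
}

#' Sample a case-control dataset from a strict epistatic model
#'
#' Joint genotypes of the interacting SNPs are drawn from the exact
#' conditional distributions
#' \deqn{P(g \mid case) = f_g P(g) / K, \qquad
#'       P(g \mid control) = (1 - f_g) P(g) / (1 - K)}
#' with P(g) the HWE product over loci. Noise SNPs are independent of
#' phenotype, each under HWE at a MAF drawn uniformly from
#' `cfg$noise_maf_range`. The interacting SNPs are placed at seeded-random
#' columns, recorded in the dataset's `truth` field.
#'
#' @param model a [generate_penetrance_model()] result.
#' @param cfg a [sim_config()] with matching `k`.
#' @return A [genotype_dataset()] with `n_cases + n_controls` rows (cases
#'   first) and `cfg$n_snps` columns.
#' @export
sample_dataset <- function(model, cfg) {
  stopifnot(inherits(model, "penetrance_model"), inherits(cfg, "sim_config"),
            model$k == cfg$k)
  gg <- genotype_grid(model$k, model$maf)
  K <- model$prevalence
  pcase <- model$table * gg$wg / K
  pctrl <- (1 - model$table) * gg$wg / (1 - K)
  with_seed(cfg$seed, {
    gi <- c(sample.int(3L^model$k, cfg$n_cases, replace = TRUE, prob = pcase),
            sample.int(3L^model$k, cfg$n_controls, replace = TRUE, prob = pctrl))
    interacting <- gg$G[gi, , drop = FALSE]
    n <- cfg$n_cases + cfg$n_controls
    n_noise <- cfg$n_snps - cfg$k
    geno <- matrix(0L, n, cfg$n_snps)
    cols <- sort(sample.int(cfg$n_snps, cfg$k))
    geno[, cols] <- interacting
    if (n_noise > 0) {
      nmaf <- runif(n_noise, cfg$noise_maf_range[1], cfg$noise_maf_range[2])
      geno[, -cols] <- matrix(rbinom(n * n_noise, 2L, rep(nmaf, each = n)),
                              nrow = n)
    }
    genotype_dataset(geno,
                     phenotype = rep(c(1L, 0L), c(cfg$n_cases, cfg$n_controls)),
                     truth = cols)
  })
}

#' Conditional joint-genotype distributions of a model
#'
#' Closed-form P(g | case) and P(g | control) for the interacting SNPs,
#' in `genotype_grid` cell order. Used by goodness-of-fit checks on
#' [sample_dataset()] output.
#'
#' @param model a `penetrance_model`.
#' @return List with `G` (genotype rows), `case` and `control` probability
#'   vectors.
#' @export
conditional_genotype_probs <- function(model) {
  gg <- genotype_grid(model$k, model$maf)
  K <- model$prevalence
  list(G = gg$G,
       case = model$table * gg$wg / K,
       control = (1 - model$table) * gg$wg / (1 - K))
}

#' Generate a collection of simulated datasets on disk
#'
#' For each configuration in `grid`, generates `replicates` penetrance
#' models and datasets and writes them under `dir` along with a tab-separated
#' `manifest.tsv` mapping each file to its configuration, achieved
#' prevalence/heritability, alpha-independent truth columns and seed.
#' Infeasible grid cells are skipped and recorded in the manifest footer
#' file `skipped.tsv`.
#'
#' @param grid list of [sim_config()] objects (the `seed` fields are
#'   ignored; per-dataset seeds derive from `seed`).
#' @param replicates datasets per configuration (0 gives an empty, valid
#'   manifest).
#' @param seed master seed; dataset seeds are split from it deterministically.
#' @param dir output directory (created if needed).
#' @param format dataset file format, see [write_dataset()].
#' @return The manifest as a data.frame, invisibly; attribute `"skipped"`
#'   lists skipped cells.
#' @export
simulation_grid <- function(grid, replicates, seed, dir,
                            format = c("csv", "tsv", "plink_raw")) {
  format <- match.arg(format)
  stopifnot(replicates >= 0)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- if (length(grid) * replicates > 0)
    derive_seeds(seed, length(grid) * replicates) else integer(0)
  rows <- list()
  skipped <- character(0)
  idx <- 0L
  for (ci in seq_along(grid)) {
    cfg <- grid[[ci]]
    stopifnot(inherits(cfg, "sim_config"))
    for (r in seq_len(replicates)) {
      idx <- idx + 1L
      s <- seeds[idx]
      file <- sprintf("ds_cell%03d_rep%03d.%s", ci, r,
                      if (format == "plink_raw") "raw" else format)
      model <- tryCatch(
        generate_penetrance_model(cfg$k, cfg$maf, cfg$h2,
                                  cfg$prevalence_target, seed = s),
        error = function(e) NULL)
      if (is.null(model)) {
        skipped <- c(skipped, sprintf("cell %d (k=%d maf=%g h2=%g): infeasible",
                                      ci, cfg$k, cfg$maf, cfg$h2))
        break
      }
      cfg_r <- cfg
      cfg_r$seed <- s
      ds <- sample_dataset(model, cfg_r)
      write_dataset(ds, file.path(dir, file), format)
      rows[[length(rows) + 1L]] <- data.frame(
        file = file, cell = ci, replicate = r, k = cfg$k, maf = cfg$maf,
        h2 = cfg$h2, prevalence = model$prevalence, n_snps = cfg$n_snps,
        n_cases = cfg$n_cases, n_controls = cfg$n_controls, seed = s,
        truth = paste(ds$truth, collapse = ","))
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(file = character(0), cell = integer(0), replicate = integer(0),
               k = integer(0), maf = numeric(0), h2 = numeric(0),
               prevalence = numeric(0), n_snps = integer(0),
               n_cases = integer(0), n_controls = integer(0),
               seed = integer(0), truth = character(0))
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  if (length(skipped))
    writeLines(skipped, file.path(dir, "skipped.tsv"))
  attr(manifest, "skipped") <- skipped
  invisible(manifest)
}
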