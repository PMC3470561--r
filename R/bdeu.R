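#' Scoring configuration
#'
#' Bundles the BDeu prior equivalent sample size `alpha` with the arity of
#' the modelled variables: the disease node has 2 states, SNP nodes have 3
#' (minor-allele counts 0/1/2). The Dirichlet hyperparameters of the disease
#' node under a pattern with q joint parent instantiations are
#' `alpha / (2 * q)` per cell, i.e. a prior uniform distribution over each
#' variable with total prior weight `alpha`.
#'
#' @param alpha positive prior equivalent sample size (default 4).
#' @return An object of class `score_config`.
#' @export
score_config <- function(alpha = 4) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0)
  structure(list(alpha = alpha, child_states = 2L, snp_states = 3L),
            class = "score_config")
}

#' @export
print.score_config <- function(x, ...) {
  cat(sprintf("score_config: alpha = %g (disease 2 states, SNPs 3 states)\n",
              x$alpha))
  invisible(x)
}

#' Disease-by-genotype contingency counts for a SNP pattern
#'
#' For a pattern of L SNPs there are `q = 3^L` joint genotype
#' instantiations; instantiation j is the base-3 encoding of the pattern
#' SNPs' genotypes in pattern order (first SNP = most significant digit).
#' The result holds the q-by-2 count matrix `n`, with column 1 counting
#' cases (disease = 1) and column 2 controls.
#'
#' @param ds a [genotype_dataset()].
#' @param pattern integer vector of distinct SNP column indices; may be
#'   empty, giving the marginal case/control counts (q = 1).
#' @return An object of class `contingency_counts`: list with `pattern`,
#'   `q`, and the count matrix `n`.
#' @examples
#' ds <- make_toy_fixture(20, 4, seed = 7)
#' count_contingency(ds, c(1L, 3L))
#' @export
count_contingency <- function(ds, pattern) {
  stopifnot(inherits(ds, "genotype_dataset"))
  pattern <- as.integer(pattern)
  if (anyDuplicated(pattern)) stop("duplicate SNP index in pattern")
  if (length(pattern) && (min(pattern) < 1L || max(pattern) > ncol(ds$genotypes)))
    stop("SNP index out of range")
  L <- length(pattern)
  q <- 3L^L
  if (L == 0L) {
    j <- rep.int(1L, nrow(ds$genotypes))
  } else {
    j <- 1L
    for (t in seq_len(L)) j <- j + ds$genotypes[, pattern[t]] * 3L^(L - t)
  }
  n <- cbind(tabulate(j[ds$phenotype == 1L], nbins = q),
             tabulate(j[ds$phenotype == 0L], nbins = q))
  colnames(n) <- c("case", "control")
  structure(list(pattern = pattern, q = q, n = n), class = "contingency_counts")
}

#' @export
print.contingency_counts <- function(x, ...) {
  cat(sprintf("contingency_counts: pattern {%s}, q = %d, N = %d\n",
              paste(x$pattern, collapse = ", "), x$q, sum(x$n)))
  invisible(x)
}

#' Log BDeu local score of the disease node given a SNP pattern
#'
#' Natural log of the BDeu marginal likelihood of the disease node with the
#' pattern's SNPs as parents:
#' \deqn{\sum_j \left[\ln\Gamma(\alpha/q) - \ln\Gamma(\alpha/q + N_{j+})\right]
#'   + \sum_{j,k} \left[\ln\Gamma(\alpha/(2q) + N_{jk}) -
#'   \ln\Gamma(\alpha/(2q))\right]}
#' where \eqn{N_{jk}} is the number of individuals with joint genotype
#' instantiation j and disease value k, and \eqn{N_{j+}} its row sum. Only
#' the disease node's local score is used to compare patterns: under the
#' uniform prior the SNP nodes' own local scores are identical across
#' same-size patterns and cancel.
#'
#' @param counts a [count_contingency()] result.
#' @param cfg a [score_config()].
#' @return The log score (finite; 0 for an empty dataset).
#' @export
bdeu_local_log_score <- function(counts, cfg = score_config()) {
  stopifnot(inherits(counts, "contingency_counts"), inherits(cfg, "score_config"))
  bdeu_score_from_counts(counts$n, counts$q, cfg$alpha)
}

# core score on a q x 2 count matrix
bdeu_score_from_counts <- function(n, q, alpha) {
  aj <- alpha / q
  ajk <- alpha / (2 * q)
  nj <- n[, 1L] + n[, 2L]
  sum(lgamma(aj) - lgamma(aj + nj)) +
    sum(lgamma(ajk + n) - lgamma(ajk))
}

#' Upper bound on the BDeu score of any pattern expansion
#'
#' An upper limit on the log BDeu score of any SNP pattern obtained by adding
#' `m` SNPs (each with 3 states, so `s = 3^m` combined added states) to the
#' pattern underlying `counts`. Following the pure-cell maximization
#' (whichever joint value the added SNPs take, the score is maximal when all
#' data items sharing a parent instantiation share one disease value), each
#' nonzero cell \eqn{N_{jk}} is placed in its own pure sub-instantiation of
#' the refined parent space of size `q' = q * 3^m`:
#' \deqn{\sum_{j,k:\,N_{jk}>0} \left[\ln\Gamma(\alpha/q') -
#'   \ln\Gamma(\alpha/q' + N_{jk}) + \ln\Gamma(\alpha/(2q') + N_{jk}) -
#'   \ln\Gamma(\alpha/(2q'))\right]}
#' Concentrating each cell dominates splitting it (the per-cell term is
#' superadditive in the count), so the bound dominates every actual
#' expansion; the test suite re-verifies this by exhaustive enumeration.
#' The bound is loose by design: it is a search-ordering heuristic, not a
#' pruning certificate.
#'
#' @param counts a [count_contingency()] result.
#' @param m number of SNPs that could be added (>= 1).
#' @param cfg a [score_config()].
#' @return The log bound (0 for an empty dataset).
#' @export
bdeu_expansion_log_bound <- function(counts, m, cfg = score_config()) {
  stopifnot(inherits(counts, "contingency_counts"), inherits(cfg, "score_config"))
  if (!is.numeric(m) || length(m) != 1 || m < 1) stop("m must be >= 1")
  bdeu_bound_from_counts(counts$n, counts$q, m, cfg$alpha)
}

# core bound on a q x 2 count matrix
bdeu_bound_from_counts <- function(n, q, m, alpha) {
  qp <- q * 3^m
  a <- alpha / qp
  b <- alpha / (2 * qp)
  N <- n[n > 0]
  sum(lgamma(a) - lgamma(a + N) + lgamma(b + N) - lgamma(b))
}

#' Evaluate a SNP pattern: score plus expansion bounds
#'
#' Bundles [count_contingency()], [bdeu_local_log_score()] and
#' [bdeu_expansion_log_bound()] for one pattern.
#'
#' @param ds a [genotype_dataset()].
#' @param pattern integer vector of distinct SNP column indices (may be empty).
#' @param m_list integer vector of expansion sizes for which bounds are
#'   computed (default 1).
#' @param cfg a [score_config()].
#' @return An object of class `pattern_evaluation`: list with `pattern`,
#'   `log_score` and `log_bound` (named by m).
#' @examples
#' ds <- make_toy_fixture(30, 5, seed = 3)
#' evaluate_pattern(ds, c(2L, 4L), m_list = c(1, 2))
#' @export
evaluate_pattern <- function(ds, pattern, m_list = 1L, cfg = score_config()) {
  counts <- count_contingency(ds, pattern)
  lb <- vapply(m_list, function(m) bdeu_expansion_log_bound(counts, m, cfg),
               numeric(1))
  names(lb) <- as.character(m_list)
  structure(list(pattern = counts$pattern,
                 log_score = bdeu_local_log_score(counts, cfg),
                 log_bound = lb),
            class = "pattern_evaluation")
}

#' @export
print.pattern_evaluation <- function(x, ...) {
  cat(sprintf("pattern {%s}: log score %.4f\n",
              paste(x$pattern, collapse = ", "), x$log_score))
  for (m in names(x$log_bound))
    cat(sprintf("  bound on adding %s SNP(s): %.4f\n", m, x$log_bound[[m]]))
  invisible(x)
}

# Vectorized per-SNP 3 x 2 counts: returns list(case, control), each a
# 3 x n_snp matrix of genotype counts among cases resp. controls.
snp1_counts <- function(ds) {
  g <- ds$genotypes
  case <- ds$phenotype == 1L
  cs <- function(rows) {
    rbind(colSums(g[rows, , drop = FALSE] == 0L),
          colSums(g[rows, , drop = FALSE] == 1L),
          colSums(g[rows, , drop = FALSE] == 2L))
  }
  list(case = cs(case), control = cs(!case))
}

# Per-SNP 1-SNP log scores (vector over all SNPs).
snp1_scores <- function(ds, cfg = score_config()) {
  cc <- snp1_counts(ds)
  q <- 3
  aj <- cfg$alpha / q
  ajk <- cfg$alpha / (2 * q)
  nj <- cc$case + cc$control
  colSums(lgamma(aj) - lgamma(aj + nj)) +
    colSums(lgamma(ajk + cc$case) - lgamma(ajk)) +
    colSums(lgamma(ajk + cc$control) - lgamma(ajk))
}

# Per-SNP expansion bounds for adding m SNPs (vector over all SNPs).
snp1_bounds <- function(ds, m, cfg = score_config()) {
  cc <- snp1_counts(ds)
  qp <- 3 * 3^m
  a <- cfg$alpha / qp
  b <- cfg$alpha / (2 * qp)
  term <- function(N) {
    out <- lgamma(a) - lgamma(a + N) + lgamma(b + N) - lgamma(b)
    out[N == 0] <- 0
    out
  }
  colSums(term(cc$case)) + colSums(term(cc$control))
}
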