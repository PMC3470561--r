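# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (no lgamma-based score, no closed-form position,
# no weighted projection).

# Log BDeu local score computed factor by factor from the gamma-ratio
# product: Gamma(a)/Gamma(a+N) = 1/prod(a+i), Gamma(b+N)/Gamma(b) = prod(b+i).
oracle_bdeu_log_score <- function(n, q, alpha) {
  aj <- alpha / q
  ajk <- alpha / (2 * q)
  total <- 0
  for (j in seq_len(nrow(n))) {
    Nj <- sum(n[j, ])
    if (Nj > 0) total <- total - sum(log(aj + seq_len(Nj) - 1))
    for (k in 1:2) {
      N <- n[j, k]
      if (N > 0) total <- total + sum(log(ajk + seq_len(N) - 1))
    }
  }
  total
}

# All k-subsets of {1..n} in the search order, derived independently: a
# subset precedes another iff its reverse-sorted rank tuple is
# lexicographically smaller (largest rank first, then the next, ...).
oracle_pattern_order <- function(n, k) {
  cm <- utils::combn(n, k)
  key <- cm[rev(seq_len(k)), , drop = FALSE]
  ord <- do.call(order, lapply(seq_len(k), function(i) key[i, ]))
  lapply(ord, function(i) cm[, i])
}

# 1-based position of `ranks` in the search order by direct scan.
oracle_position <- function(ranks, n) {
  pats <- oracle_pattern_order(n, length(ranks))
  for (i in seq_along(pats)) if (all(pats[[i]] == sort(ranks))) return(i)
  stop("not found")
}

# Prevalence, heritability and all proper-subset conditional mean
# penetrances of a model, by direct enumeration over all 3^k genotypes.
oracle_model_moments <- function(model) {
  k <- model$k
  w <- c((1 - model$maf)^2, 2 * model$maf * (1 - model$maf), model$maf^2)
  G <- as.matrix(expand.grid(rep(list(0:2), k)))
  wg <- apply(G, 1, function(g) prod(w[g + 1]))
  K <- sum(wg * model$table)
  h2 <- sum(wg * (model$table - K)^2) / (K * (1 - K))
  worst <- 0
  if (k > 1) {
    for (ssize in 1:(k - 1)) {
      subsets <- utils::combn(k, ssize)
      for (ci in seq_len(ncol(subsets))) {
        S <- subsets[, ci]
        assign_grid <- as.matrix(expand.grid(rep(list(0:2), ssize)))
        for (ai in seq_len(nrow(assign_grid))) {
          sel <- rep(TRUE, nrow(G))
          for (t in seq_along(S)) sel <- sel & G[, S[t]] == assign_grid[ai, t]
          wrest <- wg[sel] / prod(w[assign_grid[ai, ] + 1])
          worst <- max(worst, abs(sum(wrest * model$table[sel]) - K))
        }
      }
    }
  }
  list(K = K, h2 = h2, worst_subset_marginal_dev = worst)
}

# Exhaustive expansion-bound dominance check on one dataset: for every
# base pattern of size `base_size` and every way of adding m SNPs, the
# bound must dominate the expanded pattern's score. Returns the worst
# (most violating) margin bound - score.
oracle_dominance_margin <- function(ds, base_size, m, cfg) {
  n <- ncol(ds$genotypes)
  worst <- Inf
  bases <- if (base_size == 0) list(integer(0)) else
    asplit(utils::combn(n, base_size), 2)
  for (b in bases) {
    b <- as.integer(b)
    bound <- bdeu_expansion_log_bound(count_contingency(ds, b), m, cfg)
    rest <- setdiff(seq_len(n), b)
    adds <- utils::combn(rest, m)
    for (ci in seq_len(ncol(adds))) {
      sc <- bdeu_local_log_score(count_contingency(ds, c(b, adds[, ci])), cfg)
      worst <- min(worst, bound - sc)
    }
  }
  worst
}
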