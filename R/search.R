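#' Sort SNPs by 1-SNP expansion bound or 1-SNP score
#'
#' Computes, for every SNP, either the log BDeu score of its 1-SNP pattern
#' or the expansion bound on any pattern obtained by adding `m` SNPs to it
#' (when searching k-SNP patterns, `m = k - 1`), and returns the SNPs in
#' descending key order. Ties are broken by ascending column index, so the
#' order is deterministic.
#'
#' @param ds a [genotype_dataset()].
#' @param criterion `"bound"` (default) or `"score"`.
#' @param m expansion size used when `criterion = "bound"`.
#' @param cfg a [score_config()].
#' @return An object of class `sorted_snp_order`: list with `order` (a
#'   permutation of column indices, best first), `criterion`, `m_used` and
#'   `key_values` (sort keys along `order`, non-increasing).
#' @export
sort_snps <- function(ds, criterion = c("bound", "score"), m = 1L,
                      cfg = score_config()) {
  criterion <- match.arg(criterion)
  keys <- if (criterion == "bound") {
    stopifnot(m >= 1)
    snp1_bounds(ds, m, cfg)
  } else {
    snp1_scores(ds, cfg)
  }
  ord <- order(-keys, seq_along(keys))
  structure(list(order = ord,
                 criterion = criterion,
                 m_used = if (criterion == "bound") as.integer(m) else NA_integer_,
                 key_values = keys[ord]),
            class = "sorted_snp_order")
}

#' @export
print.sorted_snp_order <- function(x, ...) {
  cat(sprintf("sorted_snp_order: %d SNPs by 1-SNP %s%s; best: %s\n",
              length(x$order), x$criterion,
              if (x$criterion == "bound") sprintf(" (m = %d)", x$m_used) else "",
              paste(head(x$order, 5), collapse = ", ")))
  invisible(x)
}

#' Position of a pattern in the sorted enumeration order
#'
#' The k-subsets of the ranked SNP list are enumerated so that every subset
#' of \{1..j\} precedes any subset containing a rank beyond j:
#' (1,2), (1,3), (2,3), (1,4), (2,4), (3,4), (1,5), ... The 1-based
#' position of the subset with ranks \eqn{r_1 < \dots < r_k} has the closed
#' form
#' \deqn{1 + \sum_{i=1}^{k} \binom{r_i - 1}{i}.}
#'
#' @param ranks strictly increasing 1-based positions of the target SNPs in
#'   the sorted order.
#' @return The 1-based position (a count of patterns checked, including the
#'   hit).
#' @examples
#' pattern_position(c(3, 4))  # found on the 6th pattern checked
#' @export
pattern_position <- function(ranks) {
  ranks <- as.numeric(ranks)
  if (length(ranks) < 1 || any(ranks < 1))
    stop("ranks must be 1-based positions")
  if (any(diff(ranks) <= 0)) stop("ranks must be strictly increasing")
  1 + sum(choose(ranks - 1, seq_along(ranks)))
}

# Successor of a k-subset (strictly increasing ranks) in the enumeration
# order; NULL when cur is the last subset of {1..n}.
next_pattern <- function(cur, n) {
  k <- length(cur)
  for (i in seq_len(k)) {
    nxt <- if (i < k) cur[i + 1L] else n + 1L
    if (cur[i] + 1L < nxt) {
      cur[i] <- cur[i] + 1L
      if (i > 1L) cur[seq_len(i - 1L)] <- seq_len(i - 1L)
      return(cur)
    }
  }
  NULL
}

# Full enumeration of k-subsets of {1..n} in search order (small n only;
# used by tests and find_pattern's total bookkeeping).
enumerate_patterns <- function(n, k) {
  stopifnot(k >= 1, n >= k)
  out <- vector("list", choose(n, k))
  cur <- seq_len(k)
  i <- 1L
  while (!is.null(cur)) {
    out[[i]] <- cur
    cur <- next_pattern(cur, n)
    i <- i + 1L
  }
  out
}

#' Locate a target pattern by sorted enumeration
#'
#' Enumerates k-SNP patterns over the sorted SNP list in the search order
#' (see [pattern_position()]) and checks each one until the target is
#' reached. With `stop_rule = "set_identity"` the search stops on the
#' target SNP set itself; with `"score_equality"` it stops on the first
#' pattern whose log BDeu score equals the target pattern's within 1e-9
#' (the score-matching rule; a collision with a non-target pattern is
#' possible in principle but not observed in practice).
#'
#' @param ds a [genotype_dataset()].
#' @param k pattern size.
#' @param order a [sort_snps()] result for `ds`.
#' @param target integer vector of k distinct SNP column indices (or
#'   character SNP ids).
#' @param stop_rule `"set_identity"` (default) or `"score_equality"`.
#' @param cfg a [score_config()] (used by `"score_equality"`).
#' @return An object of class `search_result`: list with `target`, `k`,
#'   `position` (patterns checked, including the hit), `total` =
#'   \eqn{\binom{n}{k}}, `fraction` = position/total, `mode = "enumerate"`
#'   and `stop_rule`.
#' @export
find_pattern <- function(ds, k, order, target,
                         stop_rule = c("set_identity", "score_equality"),
                         cfg = score_config()) {
  stop_rule <- match.arg(stop_rule)
  stopifnot(inherits(order, "sorted_snp_order"))
  target <- resolve_snps(ds, target)
  if (length(target) != k || anyDuplicated(target))
    stop("target must name k distinct SNPs")
  n <- ncol(ds$genotypes)
  if (any(!(target %in% seq_len(n)))) stop("target SNP absent from dataset")
  target_score <- if (stop_rule == "score_equality")
    bdeu_local_log_score(count_contingency(ds, target), cfg) else NULL
  target_set <- sort(target)
  cur <- seq_len(k)
  pos <- 0L
  repeat {
    if (is.null(cur)) stop("target pattern not reached")  # unreachable
    pos <- pos + 1L
    cols <- order$order[cur]
    hit <- if (stop_rule == "set_identity") {
      identical(sort(cols), target_set)
    } else {
      sc <- bdeu_local_log_score(count_contingency(ds, cols), cfg)
      abs(sc - target_score) <= 1e-9
    }
    if (hit) break
    cur <- next_pattern(cur, n)
  }
  structure(list(target = target_set, k = as.integer(k), position = pos,
                 total = choose(n, k), fraction = pos / choose(n, k),
                 mode = "enumerate", stop_rule = stop_rule),
            class = "search_result")
}

#' Locate a target pattern analytically from its sorted ranks
#'
#' Equivalent to [find_pattern()] with `stop_rule = "set_identity"`, but the
#' position is computed from the target SNPs' ranks in the sorted order via
#' the closed form in [pattern_position()], without scoring or enumerating
#' intermediate patterns. This is how large searches (1000 SNPs, k >= 3)
#' are evaluated.
#'
#' @param order a [sort_snps()] result.
#' @param target integer vector of k distinct SNP column indices.
#' @param k pattern size (defaults to `length(target)`).
#' @return A `search_result` with `mode = "analytic"`.
#' @export
find_pattern_analytic <- function(order, target, k = length(target)) {
  stopifnot(inherits(order, "sorted_snp_order"))
  target <- as.integer(target)
  if (length(target) != k || anyDuplicated(target))
    stop("target must name k distinct SNPs")
  ranks <- match(target, order$order)
  if (any(is.na(ranks))) stop("target SNP absent from sorted order")
  n <- length(order$order)
  pos <- pattern_position(sort(ranks))
  structure(list(target = sort(target), k = as.integer(k), position = pos,
                 total = choose(n, k), fraction = pos / choose(n, k),
                 mode = "analytic", stop_rule = "set_identity"),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf(paste0("search_result (%s): target {%s} found at position ",
                     "%s of %s (fraction %.3g)\n"),
              x$mode, paste(x$target, collapse = ", "),
              format(x$position, big.mark = ","),
              format(x$total, big.mark = ","), x$fraction))
  invisible(x)
}

# Accept SNP ids or column indices.
resolve_snps <- function(ds, snps) {
  if (is.character(snps)) {
    idx <- match(snps, ds$snp_ids)
    if (any(is.na(idx))) stop("unknown snp id: ", snps[is.na(idx)][1])
    idx
  } else {
    as.integer(snps)
  }
}
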