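#' Case-control genotype dataset
#'
#' Container for a genotype matrix (individuals in rows, SNPs in columns,
#' minor-allele counts coded 0/1/2) together with a binary phenotype
#' (1 = case, 0 = control). When the data were simulated, `truth` records the
#' column indices of the injected interacting SNPs.
#'
#' @param genotypes integer matrix with values in \{0, 1, 2\}; one row per
#'   individual, one column per SNP.
#' @param phenotype integer vector in \{0, 1\}, one entry per row of
#'   `genotypes`; 1 marks a case.
#' @param snp_ids character vector of unique SNP identifiers, one per column.
#'   Defaults to the column names of `genotypes`, or `snp1 ... snpP`.
#' @param truth optional integer vector of column indices of the injected
#'   interacting SNPs.
#'
#' @return An object of class `genotype_dataset`: a list with fields
#'   `genotypes`, `phenotype`, `snp_ids` and `truth`.
#' @examples
#' g <- matrix(c(0L, 2L, 1L, 1L), nrow = 2, byrow = TRUE)
#' ds <- genotype_dataset(g, phenotype = c(1L, 0L), snp_ids = c("snpA", "snpB"))
#' ds
#' @export
genotype_dataset <- function(genotypes, phenotype, snp_ids = NULL, truth = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(snp_ids)) {
    snp_ids <- colnames(genotypes)
    if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(genotypes)))
  }
  dimnames(genotypes) <- NULL
  ds <- structure(
    list(genotypes = genotypes,
         phenotype = as.integer(phenotype),
         snp_ids = as.character(snp_ids),
         truth = if (is.null(truth)) NULL else as.integer(truth)),
    class = "genotype_dataset")
  validate_genotype_dataset(ds)
  ds
}

#' Validate a genotype dataset
#'
#' Checks every invariant of the container: genotype codes in \{0,1,2\},
#' phenotype in \{0,1\}, matching dimensions, unique SNP ids and in-range
#' truth indices. Errors name the offending row/column.
#'
#' @param ds a [genotype_dataset()].
#' @return `ds`, invisibly, if valid; otherwise an error.
#' @export
validate_genotype_dataset <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  g <- ds$genotypes
  if (!is.matrix(g)) stop("genotypes must be a matrix")
  bad <- which(is.na(g) | g < 0L | g > 2L)
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(g)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(g)) + 1L
    stop(sprintf("invalid genotype value at row %d, column %d (%s): %s",
                 i, j, ds$snp_ids[j], deparse(g[i, j])))
  }
  if (length(ds$phenotype) != nrow(g))
    stop(sprintf("phenotype length (%d) does not match number of individuals (%d)",
                 length(ds$phenotype), nrow(g)))
  badp <- which(is.na(ds$phenotype) | !(ds$phenotype %in% c(0L, 1L)))
  if (length(badp))
    stop(sprintf("invalid phenotype value at row %d: %s",
                 badp[1], deparse(ds$phenotype[badp[1]])))
  if (length(ds$snp_ids) != ncol(g))
    stop(sprintf("snp_ids length (%d) does not match number of SNPs (%d)",
                 length(ds$snp_ids), ncol(g)))
  dup <- ds$snp_ids[duplicated(ds$snp_ids)]
  if (length(dup)) stop("duplicate snp_ids: ", paste(unique(dup), collapse = ", "))
  if (!is.null(ds$truth)) {
    if (anyDuplicated(ds$truth)) stop("truth indices must be distinct")
    if (any(ds$truth < 1L | ds$truth > ncol(g)))
      stop("truth indices out of range")
  }
  invisible(ds)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d individuals (%d cases / %d controls), %d SNPs\n",
              nrow(x$genotypes), sum(x$phenotype == 1L), sum(x$phenotype == 0L),
              ncol(x$genotypes)))
  if (!is.null(x$truth))
    cat("  injected interacting SNPs at columns:",
        paste(x$truth, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)

#' Small deterministic genotype fixture
#'
#' Draws genotypes uniformly from \{0, 1, 2\} and phenotypes uniformly from
#' \{0, 1\}, reproducibly for a fixed seed. Intended for unit tests and
#' oracle checks, not for simulating disease models (see [sample_dataset()]).
#'
#' @param n_ind number of individuals (>= 1).
#' @param n_snp number of SNPs (>= 1).
#' @param seed integer seed; the caller's RNG stream is left untouched.
#' @return A [genotype_dataset()].
#' @examples
#' make_toy_fixture(4, 2, seed = 1)
#' @export
make_toy_fixture <- function(n_ind, n_snp, seed) {
  stopifnot(n_ind >= 1, n_snp >= 1)
  with_seed(seed, {
    g <- matrix(sample(0:2, n_ind * n_snp, replace = TRUE), nrow = n_ind)
    ph <- sample(0:1, n_ind, replace = TRUE)
    genotype_dataset(g, ph)
  })
}
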