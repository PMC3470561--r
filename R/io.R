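#' Read a case-control genotype file
#'
#' Supported formats:
#' \describe{
#'   \item{`csv`, `tsv`}{header row of SNP ids plus a final `phenotype`
#'     column (0/1); genotype cells are minor-allele counts 0/1/2.}
#'   \item{`plink_raw`}{PLINK additive recoding (`--recode A`):
#'     `FID IID PAT MAT SEX PHENOTYPE` followed by one additive-coded column
#'     per SNP; `PHENOTYPE` 2 (case) / 1 (control) is remapped to 1 / 0.}
#' }
#' Missing genotypes are rejected, not imputed; an error names the first
#' offending row and column.
#'
#' @param path file to read.
#' @param format one of `"csv"`, `"tsv"`, `"plink_raw"`.
#' @return A [genotype_dataset()].
#' @seealso [write_dataset()]
#' @export
read_dataset <- function(path, format = c("csv", "tsv", "plink_raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (file.size(path) == 0L) stop("no records in ", path)
  if (format == "plink_raw") {
    tab <- data.table::fread(path, header = TRUE, sep = " ",
                             colClasses = list(character = 1:2),
                             data.table = FALSE, showProgress = FALSE)
    if (nrow(tab) == 0L) stop("no records in ", path)
    fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(fixed %in% names(tab)[1:6]))
      stop("not a PLINK .raw header: expected columns ", paste(fixed, collapse = " "))
    ph_raw <- tab$PHENOTYPE
    if (any(is.na(ph_raw)) || !all(ph_raw %in% c(1, 2)))
      stop("PLINK PHENOTYPE must be 1 (control) or 2 (case)")
    geno <- as.matrix(tab[, -(1:6), drop = FALSE])
    ids <- names(tab)[-(1:6)]
    phenotype <- as.integer(ph_raw == 2)
  } else {
    sep <- if (format == "csv") "," else "\t"
    header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
    dup <- header[duplicated(header)]
    if (length(dup))
      stop("duplicate snp_ids in header: ", paste(unique(dup), collapse = ", "))
    tab <- data.table::fread(path, header = TRUE, sep = sep,
                             data.table = FALSE, showProgress = FALSE)
    if (nrow(tab) == 0L) stop("no records in ", path)
    if (!"phenotype" %in% names(tab))
      stop("missing 'phenotype' column in ", path)
    phenotype <- tab$phenotype
    geno <- as.matrix(tab[, names(tab) != "phenotype", drop = FALSE])
    ids <- colnames(geno)
  }
  bad <- which(is.na(geno) | !(geno %in% c(0, 1, 2)))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(geno)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(geno)) + 1L
    stop(sprintf("malformed genotype at data row %d, column '%s': %s",
                 i, ids[j], deparse(unname(geno[i, j]))))
  }
  genotype_dataset(geno, phenotype, snp_ids = ids)
}

#' Write a case-control genotype file
#'
#' Inverse of [read_dataset()]: the written file reads back to an equal
#' dataset (the `truth` field is not serialized; [simulation_grid()] keeps
#' truth columns in its manifest instead).
#'
#' @param ds a valid [genotype_dataset()] with at least one SNP.
#' @param path output file.
#' @param format one of `"csv"`, `"tsv"`, `"plink_raw"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, format = c("csv", "tsv", "plink_raw")) {
  format <- match.arg(format)
  validate_genotype_dataset(ds)
  if (ncol(ds$genotypes) == 0L) stop("empty dataset: no SNPs to write")
  if (format == "plink_raw") {
    n <- nrow(ds$genotypes)
    tab <- data.frame(FID = paste0("F", seq_len(n)), IID = paste0("I", seq_len(n)),
                      PAT = 0L, MAT = 0L, SEX = 0L,
                      PHENOTYPE = ds$phenotype + 1L)
    geno <- as.data.frame(ds$genotypes)
    names(geno) <- ds$snp_ids
    data.table::fwrite(cbind(tab, geno), path, sep = " ", quote = FALSE,
                       showProgress = FALSE)
  } else {
    geno <- as.data.frame(ds$genotypes)
    names(geno) <- ds$snp_ids
    geno$phenotype <- ds$phenotype
    data.table::fwrite(geno, path, sep = if (format == "csv") "," else "\t",
                       quote = FALSE, showProgress = FALSE)
  }
  invisible(path)
}
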