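#' SNP dosage matrix container
#'
#' Wraps an individuals x markers additive-dosage matrix with values in
#' `{0, 1, 2}` (alternative-allele counts) or `NA` for missing calls.
#' Row names are individual ids, column names SNP ids; both must be unique.
#'
#' @param dosage numeric matrix with dimnames; entries 0/1/2 or NA.
#' @return object of class `genotype_matrix` with fields `dosage`,
#'   `snp_ids`, `individual_ids`.
#' @export
genotype_matrix <- function(dosage) {
  if (!is.matrix(dosage)) .err("dosage must be a matrix")
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("I", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("snp", seq_len(ncol(dosage)))
  if (anyDuplicated(rownames(dosage)) || anyDuplicated(colnames(dosage)))
    .err("individual and SNP ids must be unique")
  obs <- dosage[!is.na(dosage)]
  if (length(obs) && !all(obs %in% c(0, 1, 2)))
    .err("observed dosages must be 0, 1 or 2")
  structure(list(dosage = dosage, snp_ids = colnames(dosage),
                 individual_ids = rownames(dosage)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosage))
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage), 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Observed-call minor allele frequencies
#' @param geno a [genotype_matrix()].
#' @return per-SNP minor allele frequency computed from observed calls.
#' @export
observed_maf <- function(geno) {
  p <- colMeans(geno$dosage, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Filter SNPs on missingness and minor allele frequency
#'
#' Retains SNPs whose missing-call fraction is at most `max_missing` and
#' whose observed-call minor allele frequency is at least `min_maf`,
#' preserving marker order.
#'
#' @param geno a [genotype_matrix()].
#' @param max_missing maximum tolerated missing fraction (default 0.30).
#' @param min_maf minimum minor allele frequency (default 0.01).
#' @param quiet suppress the dropped-marker message.
#' @return filtered [genotype_matrix()].
#' @export
filter_snps <- function(geno, max_missing = 0.30, min_maf = 0.01,
                        quiet = FALSE) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (max_missing < 0 || max_missing >= 1)
    .err("max_missing must lie in [0, 1)")
  if (min_maf < 0 || min_maf > 0.5) .err("min_maf must lie in [0, 0.5]")
  miss <- colMeans(is.na(geno$dosage))
  maf <- observed_maf(geno)
  maf[is.na(maf)] <- 0          # all-missing columns
  keep <- miss <= max_missing & maf >= min_maf
  if (!any(keep))
    .err("all %d SNPs removed by filtering (max_missing = %g, min_maf = %g)",
         ncol(geno$dosage), max_missing, min_maf)
  if (!quiet)
    message(sprintf(
      "filter_snps: kept %d of %d SNPs (%d high-missingness, %d low-MAF)",
      sum(keep), length(keep), sum(miss > max_missing),
      sum(miss <= max_missing & maf < min_maf)))
  out <- genotype_matrix(geno$dosage[, keep, drop = FALSE])
  cm <- attr(geno, "complete")
  if (!is.null(cm)) attr(out, "complete") <- cm[, keep, drop = FALSE]
  out
}

#' Mean-frequency imputation of missing dosages
#'
#' Replaces each missing call with twice the observed allele frequency of
#' its SNP (the observed-call mean dosage); observed entries are untouched.
#'
#' @param geno a [genotype_matrix()].
#' @return a `genotype_matrix`-like object of class
#'   `c("imputed_genotype_matrix", "genotype_matrix")` with no missing
#'   entries (imputed values are fractional, so the 0/1/2 constraint is
#'   relaxed).
#' @export
impute_mean <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  M <- geno$dosage
  nobs <- colSums(!is.na(M))
  if (any(nobs == 0))
    .err("SNP(s) with zero observed calls cannot be imputed: %s",
         paste(head(colnames(M)[nobs == 0]), collapse = ", "))
  mu <- colMeans(M, na.rm = TRUE)
  idx <- which(is.na(M), arr.ind = TRUE)
  if (nrow(idx)) M[idx] <- mu[idx[, 2]]
  structure(list(dosage = M, snp_ids = colnames(M),
                 individual_ids = rownames(M)),
            class = c("imputed_genotype_matrix", "genotype_matrix"))
}

#' Write / read the package's tab-delimited genotype dialect
#'
#' Tab-delimited table, one row per individual, first column `id`, one
#' column per SNP (header = SNP ids), `NA` for missing calls.
#'
#' @param geno a [genotype_matrix()].
#' @param path output file.
#' @export
write_genotypes <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  df <- data.frame(id = rownames(geno$dosage), geno$dosage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @param dialect `"tsv"` for the internal dialect, `"raw"` for a PLINK
#'   `.raw` additive-dosage export (header row with
#'   `FID IID PAT MAT SEX PHENOTYPE` followed by per-SNP columns).
#' @return `read_genotypes` returns a [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("tsv", "raw")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .err("genotype file not found: %s", path)
  if (dialect == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                     na.strings = c("NA", "-9", ""),
                     stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    M <- as.matrix(df[, -1, drop = FALSE])
  } else {
    df <- read.table(path, header = TRUE, check.names = FALSE,
                     na.strings = c("NA", "-9", ""),
                     stringsAsFactors = FALSE)
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(meta %in% names(df)[seq_len(6)]))
      .err("not a PLINK .raw additive export: expected %s header columns",
           paste(meta, collapse = " "))
    ids <- as.character(df$IID)
    M <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  }
  storage.mode(M) <- "double"
  rownames(M) <- ids
  bad <- which(!is.na(M) & M != 0 & M != 1 & M != 2, arr.ind = TRUE)
  if (nrow(bad))
    .err("invalid dosage '%s' at row %s (individual %s), column %s",
         M[bad[1, 1], bad[1, 2]], bad[1, 1], ids[bad[1, 1]],
         colnames(M)[bad[1, 2]])
  genotype_matrix(M)
}

#' Phenotype / pedigree / ground-truth writers and readers
#'
#' The phenotype table is a CSV with one row per tree (design columns
#' `tree, mother, father, provenance, site, rep, set` then trait columns);
#' the pedigree is whitespace-delimited `id mother father` (0 = unknown);
#' simulation ground truth is stored as JSON.
#'
#' @param pheno phenotype data frame.
#' @param path output file.
#' @export
write_phenotypes <- function(pheno, path) {
  write.table(pheno, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) .err("phenotype file not found: %s", path)
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  need <- c("tree", "site", "rep", "set")
  if (!all(need %in% names(df)))
    .err("phenotype table must carry columns %s", paste(need, collapse = ", "))
  df
}

#' @rdname write_phenotypes
#' @param ped pedigree data frame with `id, mother, father`.
#' @export
write_pedigree <- function(ped, path) {
  write.table(ped[, c("id", "mother", "father")], path, quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) .err("pedigree file not found: %s", path)
  read.table(path, header = TRUE, stringsAsFactors = FALSE,
             colClasses = "character")
}

#' @rdname write_phenotypes
#' @param truth ground-truth list (as attached by [simulate_phenotypes()]).
#' @export
write_truth <- function(truth, path) {
  truth$bv <- NULL  # bulky; keep summary parameters only
  jsonlite::write_json(truth, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}
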