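#' Genomic relationship matrix from SNP dosages
#'
#' VanRaden-type GRM: with `M` the n x m dosage matrix and `p_i` the in-sample
#' allele frequencies, the rescaled genotypes are `W = M - P` (`P` broadcasts
#' `2 p_i`) and
#' \deqn{G = \frac{W W'}{2 \sum_i p_i (1 - p_i)}.}
#' To guarantee a positive-definite, invertible matrix the result is blended
#' with the identity, `G <- (1 - alpha) G + alpha I`.
#'
#' @param geno an imputed [genotype_matrix()] (no missing entries; run
#'   [impute_mean()] first).
#' @param blend_alpha identity blending fraction in `[0, 1)`; default 0.01.
#' @return object of class `grm`: `G` (n x n, dimnames = individual ids),
#'   `p` (allele frequencies), `denom` (`2 sum p(1-p)`), `blend_alpha`.
#' @export
compute_grm <- function(geno, blend_alpha = 0.01) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (blend_alpha < 0 || blend_alpha >= 1)
    .err("blend_alpha must lie in [0, 1)")
  M <- geno$dosage
  if (anyNA(M))
    .err("genotypes contain missing entries; run impute_mean() first")
  p <- colMeans(M) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) .err("all SNPs are monomorphic: GRM denominator is zero")
  W <- sweep(M, 2, 2 * p, "-")
  G <- tcrossprod(W) / denom
  if (blend_alpha > 0)
    G <- (1 - blend_alpha) * G + blend_alpha * diag(nrow(G))
  dimnames(G) <- list(rownames(M), rownames(M))
  structure(list(G = G, p = p, denom = denom, blend_alpha = blend_alpha,
                 individual_ids = rownames(M), snp_ids = colnames(M)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf(
    "grm: %d individuals, %d SNPs, mean diagonal %.3f, blend_alpha %.3g\n",
    nrow(x$G), length(x$p), mean(diag(x$G)), x$blend_alpha))
  invisible(x)
}

#' Centered, rescaled genotype matrix W = M - 2p
#'
#' The marker design matrix consistent with a fitted [compute_grm()] object
#' (same allele frequencies), as used for SNP-effect back-solving and for
#' marker-based regressions.
#'
#' @param geno imputed [genotype_matrix()].
#' @param grm optionally, the `grm` whose allele frequencies to reuse.
#' @return n x m centered dosage matrix.
#' @export
center_dosages <- function(geno, grm = NULL) {
  M <- geno$dosage
  if (anyNA(M)) .err("genotypes contain missing entries; impute first")
  p <- if (is.null(grm)) colMeans(M) / 2 else {
    if (!identical(colnames(M), grm$snp_ids))
      .err("genotype SNPs do not match the GRM's SNP panel")
    grm$p
  }
  sweep(M, 2, 2 * p, "-")
}

#' Write / read a GRM as a dense tab-delimited table with id header
#' @param grm a [compute_grm()] result.
#' @param path output file.
#' @export
write_grm <- function(grm, path) {
  df <- data.frame(id = rownames(grm$G), grm$G, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  G <- as.matrix(df[, -1, drop = FALSE])
  rownames(G) <- as.character(df[[1]])
  structure(list(G = G, p = NULL, denom = NULL, blend_alpha = NA_real_,
                 individual_ids = rownames(G), snp_ids = NULL),
            class = "grm")
}
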