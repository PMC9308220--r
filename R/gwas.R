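# GWAS by linear transformation of genomic breeding values: with
# G = WW'/denom, the SNP effects implied by a GBLUP fit are
#   g_hat = (1/denom) W' G^{-1} a_hat,
# their sampling variances
#   Var(g_hat) = (1/denom)^2 W' G^{-1} Var(a_hat) G^{-1} W,
#   Var(a_hat) = sigma2_a G - PEV,
# and each SNP gets the two-sided normal p-value
#   p = 2 (1 - Phi(|g_hat| / sd(g_hat))).

#' Back-solve SNP effects from genomic breeding values
#'
#' @param fit an `st_fit` or `mt_fit` (GBLUP, fitted with the same GRM).
#' @param grm the [compute_grm()] object used in the fit.
#' @param geno the imputed [genotype_matrix()] behind the GRM.
#' @param trait for `mt_fit`, the response to extract (default: all).
#' @return vector (or matrix, one column per response) of back-solved SNP
#'   effects, length = number of SNPs.
#' @export
backsolve_snp_effects <- function(fit, grm, geno, trait = NULL) {
  W <- center_dosages(geno, grm)
  ids <- fit$ids
  if (!all(ids %in% rownames(W)))
    .err("fit individuals missing from the genotype matrix")
  W <- W[ids, , drop = FALSE]
  A <- if (inherits(fit, "mt_fit")) {
    cols <- trait %||% fit$responses
    fit$ahat[, cols, drop = FALSE]
  } else matrix(fit$ahat, ncol = 1, dimnames = list(ids, fit$trait))
  eg <- fit$Geig
  GiA <- eg$vectors %*% (crossprod(eg$vectors, A) / eg$values)
  out <- crossprod(W, GiA) / grm$denom
  rownames(out) <- colnames(W)
  if (ncol(out) == 1) drop(out) else out
}

#' Sampling variances of back-solved SNP effects
#'
#' Uses the prediction-error structure of the fitted breeding values
#' (`Var(a_hat) = sigma2_a G - PEV`, with PEV taken from the mixed-model
#' equation inverse) to compute the per-SNP variance of the back-solved
#' effects. Nonpositive variances (no information) are flagged.
#'
#' @inheritParams backsolve_snp_effects
#' @param cache optional precomputed [gwas_cache()] shared across fits on
#'   the same individuals and SNP panel (saves the dominant matrix product
#'   when scanning many traits).
#' @return vector (or matrix) of variances, with attribute `"flagged"`
#'   giving the count of nonpositive entries floored to zero.
#' @export
snp_effect_variances <- function(fit, grm, geno, trait = NULL,
                                 cache = NULL) {
  if (is.null(cache)) cache <- gwas_cache(fit, grm, geno)
  W <- cache$W
  eg <- fit$Geig
  U <- eg$vectors; d <- eg$values
  s2 <- 1 / grm$denom^2
  Td <- cache$Td                       # so W'G^{-1} U = t(Td)
  diag_WGiW <- cache$diag_WGiW         # W'G^{-1}W diagonal
  one_trait <- function(sa2, pev_diag_fun) {
    v <- s2 * (sa2 * diag_WGiW - pev_diag_fun())
    flagged <- sum(v <= 1e-14 * max(abs(v), 1e-300))
    v[v < 0] <- 0
    attr(v, "flagged") <- flagged
    v
  }
  lowrank_diag <- function(w, H, Sinv, coef = 1) {
    # diag of coef * t(Td) (diag(w) + H Sinv H') Td
    A <- crossprod(H, Td)
    coef * (colSums(Td^2 * w) + colSums(A * (Sinv %*% A)))
  }
  if (inherits(fit, "st_fit")) {
    ps <- fit$pev_struct
    v <- one_trait(ps$sigma2_a, function()
      ps$sigma2_e * lowrank_diag(ps$w, ps$H, ps$Sinv))
    names(v) <- colnames(W)
    return(v)
  }
  stopifnot(inherits(fit, "mt_fit"))
  cols <- trait %||% fit$responses
  ps <- fit$pev_struct
  out <- sapply(cols, function(tt) {
    j <- match(tt, fit$responses)
    if (ps$type == "canonical") {
      pevd <- function() {
        tot <- 0
        for (k in seq_along(ps$per)) {
          g2 <- ps$Gi[k, j]^2
          if (g2 < 1e-14) next
          pk <- ps$per[[k]]
          tot <- tot + lowrank_diag(pk$w, pk$H, pk$Sinv, coef = g2)
        }
        tot
      }
    } else {
      pevd <- function() {
        n_ind <- ps$n_ind
        idx <- ps$p + (j - 1) * n_ind + seq_len(n_ind)
        Caa <- ps$Cinv[idx, idx]
        GiW <- U %*% Td
        colSums(GiW * (Caa %*% GiW))
      }
    }
    one_trait(fit$Sigma_a[j, j], pevd)
  })
  rownames(out) <- colnames(W)
  if (length(cols) == 1) drop(out) else out
}

#' Two-sided normal p-values for back-solved SNP effects
#'
#' @param effects back-solved effects (vector).
#' @param variances matching sampling variances (positive).
#' @param snp_ids optional SNP ids.
#' @param alpha significance level for the nominal and Bonferroni flags.
#' @return data frame of class `snp_association`: `snp_id, g_hat, sd_g_hat,
#'   z, p_value, neg_log10_p, passes_nominal, passes_bonferroni`, in input
#'   SNP order.
#' @export
snp_pvalues <- function(effects, variances, snp_ids = NULL, alpha = 0.05) {
  if (length(effects) != length(variances))
    .err("effects and variances differ in length")
  if (any(variances <= 0))
    .err("nonpositive SNP-effect variances: associations are undefined %s",
         "(no information in the breeding values)")
  sdv <- sqrt(variances)
  z <- effects / sdv
  p <- 2 * pnorm(abs(z), lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)
  thr <- bonferroni_threshold(alpha, length(effects))
  out <- data.frame(
    snp_id = snp_ids %||% names(effects) %||%
      paste0("snp", seq_along(effects)),
    g_hat = as.numeric(effects), sd_g_hat = as.numeric(sdv),
    z = as.numeric(z), p_value = p, neg_log10_p = -log10(p),
    passes_nominal = p < alpha,
    passes_bonferroni = p < thr$p_cutoff,
    stringsAsFactors = FALSE)
  class(out) <- c("snp_association", "data.frame")
  out
}

#' Bonferroni family-wise threshold
#'
#' Divides the significance level by the number of tested SNPs:
#' `p_cutoff = alpha / m`, reported also on the `-log10` scale.
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param m number of SNP tests (>= 1).
#' @return list with `p_cutoff` and `neg_log10`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (alpha <= 0 || alpha >= 1) .err("alpha must lie in (0, 1)")
  if (m < 1) .err("m must be >= 1")
  p <- alpha / m
  list(p_cutoff = p, neg_log10 = -log10(p))
}

#' Single- and multi-trait GWAS scan
#'
#' Convenience wrapper: back-solves effects and variances from a GBLUP fit
#' and returns association tables. For an `mt_fit` each response gets its
#' own table (per-trait p-values from the joint model).
#'
#' @inheritParams backsolve_snp_effects
#' @param alpha significance level.
#' @param cache optional shared [gwas_cache()].
#' @return a `snp_association` table, or a named list of them for `mt_fit`.
#' @export
gwas_scan <- function(fit, grm, geno, alpha = 0.05, cache = NULL) {
  if (inherits(fit, "st_fit")) {
    g <- backsolve_snp_effects(fit, grm, geno)
    v <- snp_effect_variances(fit, grm, geno, cache = cache)
    return(snp_pvalues(g, v, snp_ids = names(g), alpha = alpha))
  }
  g <- backsolve_snp_effects(fit, grm, geno)
  v <- snp_effect_variances(fit, grm, geno, cache = cache)
  out <- lapply(fit$responses, function(tt)
    snp_pvalues(g[, tt], v[, tt], snp_ids = rownames(g), alpha = alpha))
  names(out) <- fit$responses
  out
}

#' Precomputed quantities shared across GWAS scans
#'
#' Holds the centered dosages restricted to the fit's individuals, the
#' rotated product `U'W / d` and the diagonal of `W'G^{-1}W`, so scanning
#' many traits on one panel pays the dominant matrix cost once. Valid for
#' any fit sharing the same individuals and eigendecomposition.
#'
#' @inheritParams backsolve_snp_effects
#' @export
gwas_cache <- function(fit, grm, geno) {
  W <- center_dosages(geno, grm)[fit$ids, , drop = FALSE]
  eg <- fit$Geig
  Td <- crossprod(eg$vectors, W) / eg$values
  list(W = W, Td = Td, diag_WGiW = colSums(Td^2 * eg$values))
}

#' Compare single- and multi-trait association results
#'
#' Summarizes Bonferroni-significant SNP counts per trait and model, their
#' overlap, and cross-trait sharing of significant SNPs (pleiotropy
#' candidates): the returned `shared` matrix carries single-trait sharing
#' above the diagonal, multi-trait sharing below it, and per-trait
#' significant counts from both models alongside. QQ and Manhattan export
#' tables are included.
#'
#' @param st,mt named lists of `snp_association` tables (same SNP panel),
#'   one per trait, from the single- and multi-trait models.
#' @return list with `counts`, `shared`, `overlap`, `qq`, `manhattan`.
#' @export
association_summary <- function(st, mt) {
  traits <- names(st)
  if (!identical(traits, names(mt)))
    .err("single- and multi-trait results must cover the same traits")
  panel <- st[[1]]$snp_id
  for (x in c(st, mt)) if (!identical(x$snp_id, panel))
    .err("association tables are not on a common SNP panel")
  sig <- function(tab) tab$snp_id[tab$passes_bonferroni]
  st_sig <- lapply(st, sig); mt_sig <- lapply(mt, sig)
  counts <- data.frame(
    trait = traits,
    st_significant = vapply(st_sig, length, integer(1)),
    mt_significant = vapply(mt_sig, length, integer(1)),
    overlap = vapply(traits, function(tt)
      length(intersect(st_sig[[tt]], mt_sig[[tt]])), integer(1)),
    row.names = NULL)
  k <- length(traits)
  shared <- matrix(0L, k, k, dimnames = list(traits, traits))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j) shared[i, j] <- length(intersect(st_sig[[i]], st_sig[[j]]))
    if (i > j) shared[i, j] <- length(intersect(mt_sig[[i]], mt_sig[[j]]))
    if (i == j) shared[i, j] <- length(union(st_sig[[i]], mt_sig[[i]]))
  }
  qq <- do.call(rbind, lapply(traits, function(tt) {
    mk <- function(tab, model) {
      p <- sort(tab$p_value)
      data.frame(trait = tt, model = model,
                 expected = -log10((seq_along(p) - 0.5) / length(p)),
                 observed = -log10(p))
    }
    rbind(mk(st[[tt]], "ST"), mk(mt[[tt]], "MT"))
  }))
  manhattan <- do.call(rbind, lapply(traits, function(tt) {
    rbind(data.frame(trait = tt, model = "ST", snp_id = st[[tt]]$snp_id,
                     index = seq_along(panel),
                     neg_log10_p = st[[tt]]$neg_log10_p,
                     significant = st[[tt]]$passes_bonferroni),
          data.frame(trait = tt, model = "MT", snp_id = mt[[tt]]$snp_id,
                     index = seq_along(panel),
                     neg_log10_p = mt[[tt]]$neg_log10_p,
                     significant = mt[[tt]]$passes_bonferroni))
  }))
  list(counts = counts, shared = shared,
       overlap = sum(counts$overlap), qq = qq, manhattan = manhattan)
}
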