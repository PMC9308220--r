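#' Normal-score transform of ordinal ratings
#'
#' Maps each ordered category to the expected value of a standard normal
#' variable truncated to the category's cumulative-frequency interval: with
#' thresholds \eqn{t_c = \Phi^{-1}(F_c)} at the cumulative frequencies
#' \eqn{F_c}, category c receives
#' \eqn{(\phi(t_{c-1}) - \phi(t_c)) / (F_c - F_{c-1})}.
#' Scores are strictly increasing in the category index and have
#' (frequency-weighted) mean zero.
#'
#' @param ratings vector of ordinal ratings (integers or ordered factor);
#'   `NA`s are propagated.
#' @return numeric vector of normal scores, same length as `ratings`.
#' @export
normal_score_transform <- function(ratings) {
  x <- if (is.factor(ratings)) as.integer(ratings) else as.numeric(ratings)
  obs <- x[!is.na(x)]
  lev <- sort(unique(obs))
  if (length(lev) < 2)
    .err("normal-score transform needs at least two observed categories")
  freq <- tabulate(match(obs, lev))
  cum <- cumsum(freq) / length(obs)
  tt <- c(-Inf, qnorm(cum[-length(cum)]), Inf)
  lo <- tt[-length(tt)]; hi <- tt[-1]
  scores <- (dnorm(lo) - dnorm(hi)) / (pnorm(hi) - pnorm(lo))
  out <- scores[match(x, lev)]
  out
}

#' Dendrochronological growth decline index
#'
#' Ratio of the mean annual basal-area increment (BAI) during the 5-year
#' period of maximum growth to the mean BAI during the last 5 years:
#' `DECL = BAI_max / BAI_last`. Values near 1 indicate non-declining trees;
#' larger values indicate growth decline. Downstream analyses use
#' `log(DECL)`.
#'
#' @param bai_max mean 5-year BAI at peak growth (positive).
#' @param bai_last mean 5-year BAI over the final 5 years (positive).
#' @return the decline ratio, vectorized.
#' @export
decline_index <- function(bai_max, bai_last) {
  if (any(bai_max <= 0, na.rm = TRUE) || any(bai_last <= 0, na.rm = TRUE))
    .err("basal-area increments must be positive")
  bai_max / bai_last
}
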