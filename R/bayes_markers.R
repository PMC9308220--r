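#' Gibbs chain settings
#'
#' `"desk"` is the short default used for routine analysis and testing;
#' `"paper_st"` / `"paper_mt"` are the long single-chain settings typical of
#' published single- and multi-trait whole-genome regression analyses
#' (20,000 iterations / 2,000 burn-in / thin 100, and 200,000 / 1,000 /
#' 100 respectively).
#'
#' @param n_iter,burn_in,thin chain length, discarded prefix, thinning.
#' @param seed integer seed applied at the start of each sampler run.
#' @param preset optional shortcut overriding the numeric arguments.
#' @return list of class `chain_config`.
#' @export
chain_config <- function(n_iter = 3000L, burn_in = 500L, thin = 5L,
                         seed = 1L,
                         preset = c("custom", "desk", "paper_st",
                                    "paper_mt")) {
  preset <- match.arg(preset)
  if (preset == "desk") { n_iter <- 3000L; burn_in <- 500L; thin <- 5L }
  if (preset == "paper_st") { n_iter <- 20000L; burn_in <- 2000L; thin <- 100L }
  if (preset == "paper_mt") { n_iter <- 200000L; burn_in <- 1000L; thin <- 100L }
  if (burn_in >= n_iter) .err("burn_in must be smaller than n_iter")
  if (thin < 1) .err("thin must be >= 1")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "chain_config")
}

# shared prior setup: scaled-inverse-chi-square with df 5 and scale chosen
# so the prior mode splits the phenotypic variance half/half between the
# genetic and residual parts
.wgr_priors <- function(y, W) {
  vy <- var(y)
  msx <- sum(apply(W, 2, var))
  df <- 5
  list(df_e = df, S_e = 0.5 * vy * (df + 2) / df,
       df_g = df, S_g = 0.5 * vy / max(msx, 1e-8) * (df + 2) / df,
       msx = msx, vy = vy)
}

.fit_wgr <- function(y, W, chain, method, pi_prior = c(1, 99),
                     fix_varcomp = NULL) {
  stopifnot(inherits(chain, "chain_config"))
  if (length(y) != nrow(W)) .err("y and W have inconsistent dimensions")
  if (anyNA(y) || anyNA(W)) .err("missing values are not allowed here")
  pr <- .wgr_priors(y, W)
  S_g <- pr$S_g
  if (method == "bayesc")
    S_g <- pr$S_g / max(pi_prior[1] / sum(pi_prior), 10 / ncol(W))
  # lasso: gamma hyperprior on lambda^2 centred near the value matching a
  # half/half variance split of the double-exponential prior
  lam2_target <- max(2 * pr$msx, 1e-6)
  lambda_shape <- 1.2
  lambda_rate <- lambda_shape / lam2_target
  set.seed(chain$seed)
  fv <- as.list(fix_varcomp)
  res <- .gibbs_wgr(as.numeric(y), W, chain$n_iter, chain$burn_in,
                    chain$thin, method, pr$df_e, pr$S_e, pr$df_g, S_g,
                    pi_prior[1], pi_prior[2], lambda_shape, lambda_rate,
                    fv$sigma2_g %||% -1, fv$sigma2_e %||% -1)
  colnames(res$chains) <- c("sigma2_g", "sigma2_e", "pi", "lambda2")
  structure(list(
    method = method, mu = res$mu,
    g = setNames(as.numeric(res$g), colnames(W)),
    pip = if (method == "bayesc") setNames(as.numeric(res$pip),
                                           colnames(W)) else NULL,
    u = setNames(as.numeric(res$u), rownames(W)),
    varcomp = colMeans(res$chains), chains = res$chains,
    n_kept = res$n_kept, chain = chain), class = "wgr_fit")
}

#' Bayesian ridge regression on centered SNP dosages
#'
#' Gibbs sampler for `y = 1 mu + W g + e` with i.i.d. normal marker effects
#' and scaled-inverse-chi-square variance priors (df 5, prior mode at a
#' half/half phenotypic-variance split).
#'
#' @param y adjusted/standardized phenotype vector.
#' @param W column-centered dosage matrix (see [center_dosages()]).
#' @param chain a [chain_config()].
#' @param fix_varcomp optional named list/vector fixing `sigma2_g` and/or
#'   `sigma2_e` instead of sampling them (used for closed-form checks).
#' @return `wgr_fit`: posterior means of marker effects (`g`), genetic
#'   values (`u`), intercept, variance components, and kept-sample chains.
#' @export
fit_brr <- function(y, W, chain = chain_config(), fix_varcomp = NULL)
  .fit_wgr(y, W, chain, "brr", fix_varcomp = fix_varcomp)

#' BayesC spike-slab regression
#'
#' As [fit_brr()] but with a point-mass/normal mixture prior on marker
#' effects; the inclusion probability is sampled with a Beta prior (default
#' mean 0.01). Posterior inclusion probabilities per marker are returned in
#' `$pip`.
#'
#' @inheritParams fit_brr
#' @param pi_prior Beta prior parameters for the inclusion probability.
#' @export
fit_bayesc <- function(y, W, chain = chain_config(), pi_prior = c(1, 99))
  .fit_wgr(y, W, chain, "bayesc", pi_prior)

#' Bayesian lasso regression
#'
#' As [fit_brr()] but with a double-exponential marker prior implemented as
#' a normal/exponential scale mixture; `lambda^2` carries a gamma
#' hyperprior.
#'
#' @inheritParams fit_brr
#' @export
fit_blasso <- function(y, W, chain = chain_config())
  .fit_wgr(y, W, chain, "blasso")

#' @export
print.wgr_fit <- function(x, ...) {
  cat(sprintf("wgr_fit (%s): %d markers, %d kept samples\n", x$method,
              length(x$g), x$n_kept))
  print(round(x$varcomp, 4))
  invisible(x)
}

#' Predict genetic values for new individuals from a marker-model fit
#' @param object a `wgr_fit`.
#' @param W_new centered dosages of the new individuals (same SNP panel).
#' @param ... unused.
#' @return predicted genetic values (no intercept).
#' @export
predict.wgr_fit <- function(object, W_new, ...) {
  drop(W_new %*% object$g)
}
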