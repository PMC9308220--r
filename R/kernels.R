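#' Kernel specification for genomic prediction
#'
#' `"linear_G"` uses the genomic relationship matrix itself (kernel
#' regression with this kernel is the GBLUP model); `"gaussian"` builds
#' `K = exp(-h d^2)` from squared Euclidean distances between individuals'
#' marker profiles. By default `d^2` is divided by its off-diagonal mean so
#' the bandwidth `h` is dimensionless and comparable across marker panels.
#'
#' @param kind `"linear_G"` or `"gaussian"`.
#' @param h Gaussian bandwidth (> 0); ignored for the linear kernel.
#' @param normalize divide the squared distances by their off-diagonal mean.
#' @return list of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("linear_G", "gaussian"), h = 0.5,
                        normalize = TRUE) {
  kind <- match.arg(kind)
  if (kind == "gaussian" && h <= 0) .err("bandwidth h must be positive")
  structure(list(kind = kind, h = h, normalize = normalize),
            class = "kernel_spec")
}

#' Build a prediction kernel matrix
#'
#' @param x for `"linear_G"`, a [compute_grm()] object (or matrix); for
#'   `"gaussian"`, an imputed [genotype_matrix()] or a dosage matrix.
#' @param spec a [kernel_spec()].
#' @return symmetric PSD kernel matrix with individual ids as dimnames
#'   (Gaussian kernel has unit diagonal).
#' @export
build_kernel <- function(x, spec = kernel_spec()) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (spec$kind == "linear_G") {
    if (inherits(x, "grm")) return(x$G)
    if (is.matrix(x)) return(x)
    .err("linear_G kernel expects a grm or matrix")
  }
  M <- if (inherits(x, "genotype_matrix")) x$dosage else x
  if (anyNA(M)) .err("gaussian kernel needs complete dosages; impute first")
  ss <- rowSums(M^2)
  d2 <- outer(ss, ss, "+") - 2 * tcrossprod(M)
  d2[d2 < 0] <- 0
  if (spec$normalize) {
    md <- mean(d2[upper.tri(d2)])
    if (md <= 0) .err("degenerate marker matrix: all distances are zero")
    d2 <- d2 / md
  }
  K <- exp(-spec$h * d2)
  dimnames(K) <- list(rownames(M), rownames(M))
  K
}

#' Bayesian kernel regression (GBLUP / RKHS) by Gibbs sampling
#'
#' Fits `y = 1 mu + u + e`, `u ~ N(0, K sigma2_u)`, by a Gibbs sampler in
#' the eigenbasis of `K` (every step is O(n) after a one-time
#' eigendecomposition). Individuals with `NA` phenotype are excluded from
#' the likelihood and receive BLUP-extended posterior-mean genetic values
#' `K[new, obs] K[obs, obs]^{-1} u_obs` — with the linear G kernel this is
#' exactly the GBLUP prediction of unphenotyped trees.
#'
#' @param y phenotype vector (NA = unphenotyped individual to predict);
#'   names or order must match rows of `K`.
#' @param K kernel matrix (SPD; blended if necessary).
#' @param chain a [chain_config()].
#' @param Keig optional precomputed `eigen()` of `K[obs, obs]` (list with
#'   `values`, `vectors`, `obs` index vector) to reuse across traits.
#' @return `kernel_fit`: posterior-mean genetic values `u` for all rows of
#'   `K`, intercept, variance components, kept chains.
#' @export
fit_kernel_regression <- function(y, K, chain = chain_config(),
                                  Keig = NULL) {
  stopifnot(inherits(chain, "chain_config"))
  n_all <- nrow(K)
  if (length(y) != n_all) .err("y and K have inconsistent dimensions")
  obs <- which(!is.na(y))
  if (length(obs) < 10) .err("fewer than 10 phenotyped individuals")
  if (is.null(Keig) || !identical(Keig$obs, obs)) {
    eg <- eigen(K[obs, obs], symmetric = TRUE)
    Keig <- list(values = pmax(eg$values, 1e-8), vectors = eg$vectors,
                 obs = obs)
  }
  U <- Keig$vectors; lam <- Keig$values
  yo <- y[obs]; n <- length(yo)
  df0 <- 5; vy <- var(yo)
  S_u <- 0.5 * vy * (df0 + 2) / df0 / mean(lam)
  S_e <- 0.5 * vy * (df0 + 2) / df0
  set.seed(chain$seed)
  s2u <- 0.5 * vy / mean(lam); s2e <- 0.5 * vy
  mu <- mean(yo)
  cvec <- numeric(n)
  sU <- colSums(U)               # sum(u) = sum(sU * c), avoids O(n^2)/iter
  c_sum <- numeric(n); mu_sum <- 0
  chains <- NULL; kept <- 0
  n_kept <- length(seq(chain$burn_in, chain$n_iter - 1, by = chain$thin))
  chains <- matrix(NA_real_, n_kept, 2,
                   dimnames = list(NULL, c("sigma2_u", "sigma2_e")))
  zt <- numeric(n)
  for (it in seq_len(chain$n_iter)) {
    sum_u <- sum(sU * cvec)
    mu <- rnorm(1, (sum(yo) - sum_u) / n, sqrt(s2e / n))
    zt <- drop(crossprod(U, yo - mu))
    prec <- 1 / s2e + 1 / (s2u * lam)
    cvec <- rnorm(n, (zt / s2e) / prec, sqrt(1 / prec))
    s2u <- (sum(cvec^2 / lam) + df0 * S_u) / rchisq(1, df0 + n)
    sse <- sum((zt - cvec)^2)
    s2e <- (sse + df0 * S_e) / rchisq(1, df0 + n)
    if (!is.finite(s2e) || !is.finite(s2u))
      .err("divergent kernel-regression chain")
    if (it > chain$burn_in && (it - chain$burn_in - 1) %% chain$thin == 0) {
      kept <- kept + 1
      c_sum <- c_sum + cvec
      mu_sum <- mu_sum + mu
      chains[kept, ] <- c(s2u, s2e)
    }
  }
  cbar <- c_sum / kept
  u_obs <- drop(U %*% cbar)
  u_all <- rep(NA_real_, n_all)
  u_all[obs] <- u_obs
  if (length(obs) < n_all) {
    new <- setdiff(seq_len(n_all), obs)
    # BLUP extension: K[new, obs] %*% Kobs^{-1} u_obs
    u_all[new] <- drop(K[new, obs, drop = FALSE] %*%
                         (U %*% (cbar / lam)))
  }
  names(u_all) <- rownames(K)
  structure(list(u = u_all, mu = mu_sum / kept,
                 varcomp = colMeans(chains[seq_len(kept), , drop = FALSE]),
                 chains = chains[seq_len(kept), , drop = FALSE],
                 n_kept = kept, chain = chain, Keig = Keig),
            class = "kernel_fit")
}

#' Select the Gaussian-kernel bandwidth by cross-validated predictive ability
#'
#' Runs a k-fold cross-validation of the single-trait RKHS model for every
#' candidate bandwidth and returns the one maximizing the mean Pearson
#' correlation between predictions and held-out phenotypes; ties go to the
#' smallest bandwidth.
#'
#' @param y phenotype vector.
#' @param geno imputed [genotype_matrix()] (or dosage matrix).
#' @param grid candidate bandwidths (default includes the commonly selected
#'   0.5).
#' @param k,n_reps folds and replicates of the CV.
#' @param chain a [chain_config()].
#' @param seed fold-assignment seed.
#' @return list with `h` (selected), and `table` of mean predictive ability
#'   per candidate.
#' @export
select_bandwidth <- function(y, geno, grid = c(0.1, 0.25, 0.5, 1, 2.5),
                             k = 5, n_reps = 1, chain = chain_config(),
                             seed = 1L) {
  if (!length(grid)) .err("empty bandwidth grid")
  M <- if (inherits(geno, "genotype_matrix")) geno$dosage else geno
  obs <- which(!is.na(y))
  sched <- make_folds(obs, k = k, n_reps = n_reps, seed = seed)
  pa <- vapply(grid, function(h) {
    K <- build_kernel(M, kernel_spec("gaussian", h = h))
    r <- mapply(function(rep_i, fold_i) {
      val <- sched$id[sched$replicate == rep_i & sched$fold == fold_i]
      ytr <- y; ytr[val] <- NA
      fit <- fit_kernel_regression(ytr, K, chain)
      cor(fit$u[val], y[val])
    }, sched$replicate[!duplicated(sched[c("replicate", "fold")])],
       sched$fold[!duplicated(sched[c("replicate", "fold")])])
    mean(r, na.rm = TRUE)
  }, numeric(1))
  ord <- order(-pa, grid)
  list(h = grid[ord[1]],
       table = data.frame(h = grid, predictive_ability = pa))
}
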