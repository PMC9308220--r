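#' Multi-trait Bayesian kernel model with trait-assisted prediction
#'
#' Gibbs sampler for `Y = 1 mu' + Uv + E` where the rows of the genetic
#' values `Uv` follow a matrix-normal with row covariance `K` (a GRM or
#' Gaussian kernel) and unstructured trait covariance `Sigma_u`
#' (inverse-Wishart prior), and residual rows are i.i.d. `N(0, Sigma_e)`
#' (inverse-Wishart). Missing trait cells are sampled by data augmentation,
#' which is exactly trait-assisted prediction: a validation tree whose focal
#' trait is masked keeps its other phenotypes, and they inform its genetic
#' value through the sampled trait covariances.
#'
#' Each iteration simultaneously diagonalizes `(Sigma_u, Sigma_e)` so all
#' genetic values decouple and are sampled in vectorized form; the sampler
#' state lives in the eigenbasis of `K`, with only the missing cells
#' touched in the original basis, so per-iteration cost is O(n t + n_miss n)
#' after the one-time eigendecomposition.
#'
#' @param Y n x t phenotype matrix (NA = missing cell); rows match `K`.
#' @param K SPD kernel matrix.
#' @param chain a [chain_config()].
#' @param nu0,S0 inverse-Wishart prior degrees of freedom and scale for
#'   `Sigma_u` and `Sigma_e`; defaults `t + 2` and `0.5 diag(var(Y))`.
#' @param Keig optional precomputed eigen of `K` (list with `values`,
#'   `vectors`), reused across repeated fits on the same kernel.
#' @return `mt_gibbs_fit`: posterior-mean genetic values `u` (n x t),
#'   `mu`, posterior-mean `Sigma_u`, `Sigma_e`, kept chains of the variance
#'   components, and sampler metadata.
#' @export
fit_multitrait <- function(Y, K, chain = chain_config(), nu0 = NULL,
                           S0 = NULL, Keig = NULL) {
  stopifnot(inherits(chain, "chain_config"))
  Y <- as.matrix(Y)
  n <- nrow(Y); t <- ncol(Y)
  if (t < 2) .err("fit_multitrait needs at least two traits")
  if (nrow(K) != n) .err("Y and K have inconsistent dimensions")
  if (any(colSums(!is.na(Y)) == 0))
    .err("a trait with no records cannot be fitted")
  if (is.null(Keig)) {
    eg <- eigen(K, symmetric = TRUE)
    Keig <- list(values = pmax(eg$values, 1e-8), vectors = eg$vectors)
  }
  U <- Keig$vectors; lam <- pmax(Keig$values, 1e-8)
  nu0 <- nu0 %||% (t + 2)
  vars <- apply(Y, 2, var, na.rm = TRUE)
  S0 <- S0 %||% (0.5 * diag(vars, t))
  miss <- is.na(Y)
  pat_key <- apply(miss, 1, function(z) paste(as.integer(z), collapse = ""))
  pats <- split(seq_len(n), pat_key)
  pats <- pats[vapply(names(pats), function(k) grepl("1", k), logical(1))]
  pat_rows <- lapply(pats, identity)
  pat_miss <- lapply(names(pats), function(k)
    which(as.logical(as.integer(strsplit(k, "")[[1]]))))
  pat_U <- lapply(pat_rows, function(rows) U[rows, , drop = FALSE])
  set.seed(chain$seed)
  mu <- colMeans(Y, na.rm = TRUE)
  Yc <- Y
  for (j in seq_len(t)) Yc[miss[, j], j] <- mu[j]
  # state in the eigenbasis of K
  Yt <- crossprod(U, Yc)
  YtY <- crossprod(Yc)
  SY <- colSums(Yc)
  u1 <- drop(crossprod(U, rep(1, n)))
  csU <- colSums(U)
  Chat <- matrix(0, n, t)                     # rotated genetic values
  Sigma_u <- 0.5 * diag(vars, t) + 1e-6 * mean(vars) * diag(t)
  Sigma_e <- 0.5 * diag(vars, t) + 1e-6 * mean(vars) * diag(t)
  Chat_sum <- matrix(0, n, t); mu_sum <- numeric(t)
  Su_sum <- matrix(0, t, t); Se_sum <- matrix(0, t, t)
  n_kept <- length(seq(chain$burn_in, chain$n_iter - 1, by = chain$thin))
  chains <- matrix(NA_real_, n_kept, 2 * t,
                   dimnames = list(NULL, c(paste0("sigma2_u_", seq_len(t)),
                                           paste0("sigma2_e_", seq_len(t)))))
  kept <- 0
  for (it in seq_len(chain$n_iter)) {
    # 1. impute missing cells from the residual conditional, updating the
    #    rotated state incrementally
    for (pp in seq_along(pat_rows)) {
      rows <- pat_rows[[pp]]; mi <- pat_miss[[pp]]
      o <- setdiff(seq_len(t), mi)
      uv_rows <- pat_U[[pp]] %*% Chat
      if (length(o)) {
        R_o <- Yc[rows, o, drop = FALSE] -
          matrix(mu[o], length(rows), length(o), byrow = TRUE) -
          uv_rows[, o, drop = FALSE]
        So_inv <- solve(Sigma_e[o, o, drop = FALSE])
        cond_mean <- R_o %*% So_inv %*% t(Sigma_e[mi, o, drop = FALSE])
        cond_var <- Sigma_e[mi, mi, drop = FALSE] -
          Sigma_e[mi, o, drop = FALSE] %*% So_inv %*%
          t(Sigma_e[mi, o, drop = FALSE])
      } else {
        cond_mean <- matrix(0, length(rows), length(mi))
        cond_var <- Sigma_e[mi, mi, drop = FALSE]
      }
      L <- .chol_psd(cond_var)
      newv <- matrix(mu[mi], length(rows), length(mi), byrow = TRUE) +
        uv_rows[, mi, drop = FALSE] + cond_mean +
        matrix(rnorm(length(rows) * length(mi)), length(rows)) %*% t(L)
      oldv <- Yc[rows, mi, drop = FALSE]
      Yc[rows, mi] <- newv
      delta <- newv - oldv
      Yt[, mi] <- Yt[, mi] + crossprod(pat_U[[pp]], delta)
      SY[mi] <- SY[mi] + colSums(delta)
      # rank update of Yc'Yc restricted to affected entries
      A_old <- crossprod(Yc[rows, , drop = FALSE])   # after update
      B_rows <- Yc[rows, , drop = FALSE]
      B_rows[, mi] <- oldv
      A_prev <- crossprod(B_rows)
      YtY <- YtY + (A_old - A_prev)
    }
    # 2. intercepts
    mu <- (SY - drop(crossprod(Chat, csU))) / n +
      drop(.chol_psd(Sigma_e / n) %*% rnorm(t))
    # 3. genetic values via simultaneous diagonalization
    B <- t(chol(Sigma_e))
    Ei <- forwardsolve(B, t(forwardsolve(B, Sigma_u)))
    egE <- eigen((Ei + t(Ei)) / 2, symmetric = TRUE)
    th <- pmax(egE$values, 1e-12)
    Gam <- backsolve(t(B), egE$vectors)          # residual -> identity
    Gi <- solve(Gam)
    Zt <- Yt - u1 %o% mu                         # rotated residual data
    Zs <- Zt %*% Gam
    lam_th <- outer(lam, th)
    wpost <- lam_th / (lam_th + 1)
    Cs <- wpost * Zs + matrix(rnorm(n * t), n, t) * sqrt(wpost)
    Chat <- Cs %*% Gi
    # 4. trait covariances
    Su <- crossprod(Chat, Chat / lam)
    Sigma_u <- .riwish(nu0 + n, S0 + Su)
    ZtZ <- YtY - mu %o% SY - SY %o% mu + n * (mu %o% mu)
    Zu <- crossprod(Zt, Chat)
    EE <- ZtZ - Zu - t(Zu) + crossprod(Chat)
    EE <- (EE + t(EE)) / 2
    Sigma_e <- .riwish(nu0 + n, S0 + EE)
    if (it > chain$burn_in && (it - chain$burn_in - 1) %% chain$thin == 0) {
      kept <- kept + 1
      Chat_sum <- Chat_sum + Chat
      mu_sum <- mu_sum + mu
      Su_sum <- Su_sum + Sigma_u
      Se_sum <- Se_sum + Sigma_e
      chains[kept, ] <- c(diag(Sigma_u), diag(Sigma_e))
    }
  }
  u <- U %*% (Chat_sum / kept)
  dimnames(u) <- list(rownames(K), colnames(Y))
  structure(list(u = u, mu = mu_sum / kept, Sigma_u = Su_sum / kept,
                 Sigma_e = Se_sum / kept,
                 chains = chains[seq_len(kept), , drop = FALSE],
                 n_kept = kept, chain = chain, Keig = Keig),
            class = "mt_gibbs_fit")
}

# inverse-Wishart draw via rWishart on the inverted scale
.riwish <- function(df, S) {
  Sinv <- solve((S + t(S)) / 2)
  W <- rWishart(1, df, (Sinv + t(Sinv)) / 2)[, , 1]
  solve(W)
}

#' @export
print.mt_gibbs_fit <- function(x, ...) {
  cat(sprintf("mt_gibbs_fit: %d individuals x %d traits, %d kept samples\n",
              nrow(x$u), ncol(x$u), x$n_kept))
  cat("posterior-mean genetic covariance:\n")
  print(round(x$Sigma_u, 4))
  invisible(x)
}
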