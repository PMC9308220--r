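# Multi-trait GBLUP mixed model (traits, or one trait with sites treated as
# distinct responses):
#   y = X beta + Z_a a + e,  a ~ N(0, Sigma_a x G),  e ~ N(0, Sigma_e x I)
# ("x" = Kronecker). In site-split mode each tree carries one record at its
# own site and the cross-site residual covariances are structurally zero.
#
# Two exact EM-REML paths:
#  * canonical: complete records sharing one fixed-effect design. Each EM
#    iteration simultaneously diagonalizes (Sigma_a, Sigma_e); in the
#    transformed trait basis the model decouples into t univariate problems
#    that reuse the eigen-space machinery of the single-trait fitter.
#  * dense: per-record incidence on the full mixed-model equations; handles
#    missing trait cells and the site-split layout at desk scale.

#' Fit the multi-trait GBLUP model by EM-REML
#'
#' @param pheno phenotype data frame, normally design-adjusted and
#'   standardized (see [adjust_phenotypes()]).
#' @param grm a [compute_grm()] object.
#' @param responses trait columns to analyze jointly (across-trait mode).
#' @param trait single trait name for `site_split = TRUE` mode, where the
#'   trait's records at each site are treated as distinct correlated
#'   responses with zero cross-site residual covariance.
#' @param site_split treat sites as responses for one trait.
#' @param fixed genetic-group factor column, or `NULL` for intercept only.
#' @param method `"auto"` picks the canonical path for complete records and
#'   the dense path otherwise.
#' @param tol,max_iter EM convergence control (relative change, all
#'   components).
#' @param se compute approximate SEs from one AI evaluation (record-level,
#'   O(N^3) once); default only when the problem is small enough.
#' @param Geig optional precomputed eigen of the G sub-matrix.
#' @return object of class `mt_fit` with `Sigma_a`, `Sigma_e`, approximate
#'   SE information, breeding values `ahat` (individuals x responses) and
#'   prediction-error structure for GWAS back-solving.
#' @export
fit_mt_gblup <- function(pheno, grm, responses = NULL, trait = NULL,
                         site_split = FALSE, fixed = "provenance",
                         method = c("auto", "canonical", "dense"),
                         tol = 1e-6, max_iter = 500L, se = NULL,
                         Geig = NULL) {
  method <- match.arg(method)
  if (site_split) {
    if (is.null(trait)) .err("site_split mode needs a trait name")
    responses <- responses %||% unique(as.character(pheno$site))
    if (length(responses) < 2) .err("site_split needs >= 2 sites")
    keep <- !is.na(pheno[[trait]]) & pheno$site %in% responses
    dat <- pheno[keep, , drop = FALSE]
    ids <- unique(as.character(dat$tree))
    rec <- data.frame(ind = match(as.character(dat$tree), ids),
                      resp = match(as.character(dat$site), responses),
                      y = as.numeric(dat[[trait]]))
    recdat <- dat
    Ymat <- NULL
  } else {
    if (is.null(responses) || length(responses) < 2)
      .err("at least two response columns are required")
    ids <- as.character(pheno$tree)
    if (anyDuplicated(ids)) .err("one row per tree expected")
    Ymat <- as.matrix(pheno[, responses, drop = FALSE])
    obs <- !is.na(Ymat)
    keep_rows <- rowSums(obs) > 0
    pheno <- pheno[keep_rows, , drop = FALSE]
    Ymat <- Ymat[keep_rows, , drop = FALSE]
    obs <- obs[keep_rows, , drop = FALSE]
    ids <- ids[keep_rows]
    idx <- which(obs, arr.ind = TRUE)
    rec <- data.frame(ind = idx[, 1], resp = idx[, 2],
                      y = Ymat[obs])
    recdat <- pheno[rec$ind, , drop = FALSE]
  }
  t_resp <- length(responses)
  n_ind <- length(ids)
  missing_ids <- setdiff(ids, rownames(grm$G))
  if (length(missing_ids))
    .err("%d analyzed trees absent from the GRM", length(missing_ids))
  if (is.null(Geig) || !identical(Geig$ids, ids)) {
    eg <- eigen(grm$G[ids, ids], symmetric = TRUE)
    Geig <- list(values = pmax(eg$values, 1e-10), vectors = eg$vectors,
                 ids = ids)
  }
  complete <- !site_split && !anyNA(Ymat)
  if (method == "auto") method <- if (complete) "canonical" else "dense"
  if (method == "canonical" && !complete)
    .err("canonical path requires complete records for all responses")
  if (is.null(se)) se <- (nrow(rec) <= 2500)
  fit <- if (method == "canonical") {
    .mt_em_canonical(Ymat, pheno, Geig, responses, fixed, tol, max_iter)
  } else {
    .mt_em_dense(rec, recdat, Geig, responses, fixed, site_split, tol,
                 max_iter)
  }
  fit$responses <- responses
  fit$ids <- ids
  fit$site_split <- site_split
  fit$trait <- trait
  fit$method <- method
  rownames(fit$ahat) <- ids
  colnames(fit$ahat) <- responses
  if (se) fit <- .mt_ai_se(fit, rec, recdat, Geig, fixed, site_split)
  class(fit) <- "mt_fit"
  fit
}

# shared-X fixed design for a record set
.mt_fixed_design <- function(dat, fixed) {
  if (!is.null(fixed) && fixed %in% names(dat) &&
      length(unique(dat[[fixed]])) > 1) {
    X <- model.matrix(~factor(dat[[fixed]]))
  } else {
    X <- matrix(1, nrow(dat), 1)
  }
  colnames(X) <- paste0("b", seq_len(ncol(X)))
  X
}

# canonical-transformation EM (complete records, shared X)
.mt_em_canonical <- function(Ymat, pheno, Geig, responses, fixed, tol,
                             max_iter) {
  U <- Geig$vectors; d <- Geig$values
  n <- nrow(Ymat); t <- ncol(Ymat)
  X <- .mt_fixed_design(pheno, fixed)
  p <- ncol(X)
  Yt <- crossprod(U, Ymat)
  Xt <- crossprod(U, X)
  XtX <- crossprod(X)
  Sy <- var(Ymat)
  Sigma_a <- 0.4 * Sy + 1e-6 * mean(diag(Sy)) * diag(t)
  Sigma_e <- 0.6 * Sy + 1e-6 * mean(diag(Sy)) * diag(t)
  trace_ll <- numeric(0)
  psd_flag <- FALSE
  converged <- FALSE
  it <- 0L
  solve_once <- function(Sigma_a, Sigma_e) {
    B <- t(chol(Sigma_e))                       # Sigma_e = B B'
    Ei <- forwardsolve(B, t(forwardsolve(B, Sigma_a)))
    eg <- eigen((Ei + t(Ei)) / 2, symmetric = TRUE)
    th <- pmax(eg$values, 1e-10)
    Gam <- backsolve(t(B), eg$vectors)          # B^{-T} Q
    Ys <- Yt %*% Gam
    A_star <- matrix(0, n, t)
    Fh <- matrix(0, p, t)
    tr_vec <- numeric(t); vfit <- numeric(t); rq <- numeric(t)
    m2ll <- 0
    per <- vector("list", t)
    for (j in seq_len(t)) {
      lam <- 1 / th[j]
      w <- d / (d + lam)
      H <- w * Xt
      S <- XtX - crossprod(Xt, H)
      Sc <- chol(S)
      Sinv <- chol2inv(Sc)
      Fy <- drop(crossprod(Xt, Ys[, j]))
      rhs <- Fy - drop(crossprod(Xt, w * Ys[, j]))
      fh <- drop(Sinv %*% rhs)
      at <- w * (Ys[, j] - drop(Xt %*% fh))
      rq[j] <- sum(Ys[, j]^2) - sum(fh * Fy) - sum(at * Ys[, j])
      tr_vec[j] <- sum(w / d) + sum(Sinv * crossprod(H, H / d))
      XS <- Xt %*% Sinv
      vfit[j] <- sum(Xt * XS) - 2 * sum(XS * H) +
        sum(w) + sum((H %*% Sinv) * H)
      m2ll <- m2ll + n * log(th[j]) + sum(log(d)) +
        sum(log1p(lam / d)) + 2 * sum(log(diag(Sc))) + rq[j] +
        (n - p) * log(2 * pi)
      A_star[, j] <- at
      Fh[, j] <- fh
      per[[j]] <- list(w = w, H = H, Sinv = Sinv)
    }
    # REML loglik of the untransformed data
    m2ll <- m2ll + (n - p) * determinant(Sigma_e, logarithm = TRUE)$modulus[1]
    Eh <- Ys - Xt %*% Fh - A_star
    Sa_star <- (crossprod(A_star, A_star / d) + diag(tr_vec, t)) / n
    Se_star <- (crossprod(Eh) + diag(vfit, t)) / n
    Gi <- solve(Gam)
    list(Sigma_a_new = t(Gi) %*% Sa_star %*% Gi,
         Sigma_e_new = t(Gi) %*% Se_star %*% Gi,
         loglik = -m2ll / 2, A_star = A_star, Fh = Fh, Gam = Gam, Gi = Gi,
         per = per, theta = th)
  }
  st <- NULL
  for (it in seq_len(max_iter)) {
    st <- solve_once(Sigma_a, Sigma_e)
    trace_ll <- c(trace_ll, st$loglik)
    new_a <- (st$Sigma_a_new + t(st$Sigma_a_new)) / 2
    new_e <- (st$Sigma_e_new + t(st$Sigma_e_new)) / 2
    ra <- .clip_psd(new_a); re <- .clip_psd(new_e)
    psd_flag <- psd_flag || ra$repaired || re$repaired
    vscale <- mean(diag(Sy))
    rel <- max(abs(ra$S - Sigma_a), abs(re$S - Sigma_e)) / vscale
    Sigma_a <- ra$S; Sigma_e <- re$S
    if (rel < tol) { converged <- TRUE; break }
  }
  st <- solve_once(Sigma_a, Sigma_e)
  ahat <- U %*% (st$A_star %*% st$Gi)           # back to original traits
  dimnames(Sigma_a) <- dimnames(Sigma_e) <- list(responses, responses)
  list(Sigma_a = Sigma_a, Sigma_e = Sigma_e, ahat = ahat,
       varcomp = list(loglik = st$loglik, loglik_trace = trace_ll,
                      n_iter = it, converged = converged,
                      psd_repaired = psd_flag),
       pev_struct = list(type = "canonical", U = U, d = d,
                         per = st$per, Gi = st$Gi),
       X = X, beta = st$Fh %*% st$Gi, Geig = Geig)
}

# dense per-record MME EM (missing cells, site-split)
.mt_em_dense <- function(rec, recdat, Geig, responses, fixed, site_split,
                         tol, max_iter) {
  U <- Geig$vectors; d <- Geig$values
  Ginv <- U %*% (t(U) / d)
  n_ind <- length(Geig$ids); t <- length(responses)
  N <- nrow(rec)
  Xrec <- .mt_fixed_design(recdat, fixed)
  p1 <- ncol(Xrec)
  # direct-sum fixed design: block of p1 columns per response
  Fm <- matrix(0, N, p1 * t)
  for (j in seq_len(t)) {
    r <- rec$resp == j
    Fm[r, (j - 1) * p1 + seq_len(p1)] <- Xrec[r, , drop = FALSE]
  }
  keep_col <- colSums(abs(Fm)) > 0
  Fm <- Fm[, keep_col, drop = FALSE]
  p <- ncol(Fm)
  acol <- (rec$resp - 1L) * n_ind + rec$ind    # a-cell index per record
  by_ind <- split(seq_len(N), rec$ind)
  vy <- var(rec$y)
  Sigma_a <- diag(0.4 * vy, t); Sigma_e <- diag(0.6 * vy, t)
  trace_ll <- numeric(0); psd_flag <- FALSE; converged <- FALSE
  nt <- n_ind * t
  it <- 0L
  obs_pairs <- matrix(0L, t, t)
  for (r in by_ind) {
    o <- rec$resp[r]
    obs_pairs[o, o] <- obs_pairs[o, o] + 1L
  }
  solve_once <- function(Sigma_a, Sigma_e) {
    Sa_inv <- solve(Sigma_a)
    # record-level R^{-1}, assembled per individual
    Rw <- matrix(0, N, N)  # block-sparse; desk scale keeps this dense
    ldetR <- 0
    for (r in by_ind) {
      o <- rec$resp[r]
      Ri <- solve(Sigma_e[o, o, drop = FALSE])
      Rw[r, r] <- Ri
      ldetR <- ldetR + determinant(Sigma_e[o, o, drop = FALSE],
                                   logarithm = TRUE)$modulus[1]
    }
    RiF <- Rw %*% Fm; Riy <- drop(Rw %*% rec$y)
    C <- matrix(0, p + nt, p + nt)
    C[seq_len(p), seq_len(p)] <- crossprod(Fm, RiF)
    Cba <- matrix(0, nt, p)
    for (r in seq_len(N)) {
      Cba[acol[r], ] <- Cba[acol[r], ] + RiF[r, ]
    }
    C[p + seq_len(nt), seq_len(p)] <- Cba
    C[seq_len(p), p + seq_len(nt)] <- t(Cba)
    Zblock <- matrix(0, nt, nt)
    for (r in seq_len(N)) for (s2 in by_ind[[rec$ind[r]]]) {
      Zblock[acol[r], acol[s2]] <- Zblock[acol[r], acol[s2]] + Rw[r, s2]
    }
    C[p + seq_len(nt), p + seq_len(nt)] <- Zblock +
      kronecker(Sa_inv, Ginv)
    rhs <- c(drop(crossprod(Fm, Riy)), {
      za <- numeric(nt)
      for (r in seq_len(N)) za[acol[r]] <- za[acol[r]] + Riy[r]
      za
    })
    Cc <- chol(C)
    Cinv <- chol2inv(Cc)
    sol <- drop(Cinv %*% rhs)
    fhat <- sol[seq_len(p)]
    amat <- matrix(sol[p + seq_len(nt)], n_ind, t)
    yPy <- sum(rec$y * Riy) - sum(sol * rhs)
    m2ll <- ldetR + n_ind * determinant(Sigma_a, TRUE)$modulus[1] +
      t * sum(log(d)) + 2 * sum(log(diag(Cc))) + yPy +
      (N - p) * log(2 * pi)
    # EM updates
    Sa_new <- matrix(0, t, t)
    Caa <- Cinv[p + seq_len(nt), p + seq_len(nt)]
    for (j in seq_len(t)) for (k in j:t) {
      blk <- Caa[(j - 1) * n_ind + seq_len(n_ind),
                 (k - 1) * n_ind + seq_len(n_ind)]
      v <- (drop(crossprod(amat[, j], Ginv %*% amat[, k])) +
              sum(Ginv * t(blk))) / n_ind
      Sa_new[j, k] <- Sa_new[k, j] <- v
    }
    # residual update (pairwise-observed)
    ehat <- rec$y - drop(Fm %*% fhat) - amat[cbind(rec$ind, rec$resp)]
    Se_num <- matrix(0, t, t)
    for (i in seq_along(by_ind)) {
      r <- by_ind[[i]]
      o <- rec$resp[r]
      Ti <- matrix(0, length(r), p + nt)
      Ti[, seq_len(p)] <- Fm[r, , drop = FALSE]
      Ti[cbind(seq_along(r), p + acol[r])] <- 1
      Vf <- Ti %*% Cinv %*% t(Ti)
      Se_num[o, o] <- Se_num[o, o] + tcrossprod(ehat[r]) + Vf
    }
    Se_new <- Sigma_e
    for (j in seq_len(t)) for (k in j:t) {
      if (site_split && j != k) { Se_new[j, k] <- Se_new[k, j] <- 0; next }
      if (obs_pairs[j, k] > 0) {
        Se_new[j, k] <- Se_new[k, j] <- Se_num[j, k] / obs_pairs[j, k]
      }
    }
    list(Sigma_a_new = Sa_new, Sigma_e_new = Se_new, loglik = -m2ll / 2,
         fhat = fhat, amat = amat, Cinv = Cinv, p = p)
  }
  st <- NULL
  for (it in seq_len(max_iter)) {
    st <- solve_once(Sigma_a, Sigma_e)
    trace_ll <- c(trace_ll, st$loglik)
    ra <- .clip_psd(st$Sigma_a_new); re <- .clip_psd(st$Sigma_e_new)
    psd_flag <- psd_flag || ra$repaired || re$repaired
    if (site_split) {
      re$S[upper.tri(re$S)] <- 0; re$S[lower.tri(re$S)] <- 0
    }
    rel <- max(abs(ra$S - Sigma_a), abs(re$S - Sigma_e)) / vy
    Sigma_a <- ra$S; Sigma_e <- re$S
    if (rel < tol) { converged <- TRUE; break }
  }
  st <- solve_once(Sigma_a, Sigma_e)
  dimnames(Sigma_a) <- dimnames(Sigma_e) <- list(responses, responses)
  list(Sigma_a = Sigma_a, Sigma_e = Sigma_e, ahat = st$amat,
       varcomp = list(loglik = st$loglik, loglik_trace = trace_ll,
                      n_iter = it, converged = converged,
                      psd_repaired = psd_flag),
       pev_struct = list(type = "dense", Cinv = st$Cinv, p = st$p,
                         n_ind = n_ind, t = t),
       X = Xrec, beta = st$fhat, Geig = Geig)
}

# record-level AI information for approximate SEs of vech(Sigma_a) and the
# (free) residual components; delta-method SEs for h2 and r_a are derived
# from its inverse
.mt_ai_se <- function(fit, rec, recdat, Geig, fixed, site_split) {
  t <- length(fit$responses)
  ids <- Geig$ids
  U <- Geig$vectors; d <- Geig$values
  G <- U %*% (d * t(U))
  N <- nrow(rec)
  Xrec <- .mt_fixed_design(recdat, fixed)
  Fm <- matrix(0, N, ncol(Xrec) * t)
  for (j in seq_len(t)) {
    r <- rec$resp == j
    Fm[r, (j - 1) * ncol(Xrec) + seq_len(ncol(Xrec))] <-
      Xrec[r, , drop = FALSE]
  }
  Fm <- Fm[, colSums(abs(Fm)) > 0, drop = FALSE]
  Gobs <- G[rec$ind, rec$ind]
  same_ind <- outer(rec$ind, rec$ind, "==")
  V <- fit$Sigma_a[rec$resp, rec$resp] * Gobs +
    fit$Sigma_e[rec$resp, rec$resp] * same_ind
  Vi <- tryCatch(chol2inv(chol(V)), error = function(e) NULL)
  if (is.null(Vi)) return(fit)
  ViX <- Vi %*% Fm
  XtViX <- crossprod(Fm, ViX)
  XtViX_inv <- tryCatch(solve(XtViX), error = function(e) NULL)
  if (is.null(XtViX_inv)) return(fit)
  Pfun <- function(q) Vi %*% q - ViX %*% (XtViX_inv %*% crossprod(ViX, q))
  Py <- drop(Pfun(rec$y))
  pars <- list()
  for (j in seq_len(t)) for (k in j:t)
    pars[[sprintf("a_%d_%d", j, k)]] <- list(kind = "a", j = j, k = k)
  for (j in seq_len(t)) for (k in j:t) {
    if (site_split && j != k) next
    pars[[sprintf("e_%d_%d", j, k)]] <- list(kind = "e", j = j, k = k)
  }
  dV_y <- lapply(pars, function(pp) {
    Rj <- rec$resp == pp$j; Rk <- rec$resp == pp$k
    mask <- if (pp$j == pp$k) outer(Rj, Rj) else
      outer(Rj, Rk) | outer(Rk, Rj)
    Vd <- if (pp$kind == "a") Gobs * mask else same_ind * mask
    drop(Vd %*% Py)
  })
  k <- length(dV_y)
  AI <- matrix(0, k, k, dimnames = list(names(pars), names(pars)))
  PdV <- lapply(dV_y, Pfun)
  for (i in seq_len(k)) for (j in i:k)
    AI[i, j] <- AI[j, i] <- 0.5 * sum(dV_y[[i]] * PdV[[j]])
  cov <- tryCatch(solve(AI), error = function(e) NULL)
  if (is.null(cov)) return(fit)
  fit$ai_cov <- cov
  # delta-method h2 SEs per response
  h2_se <- rep(NA_real_, t)
  for (j in seq_len(t)) {
    na <- sprintf("a_%d_%d", j, j); ne <- sprintf("e_%d_%d", j, j)
    if (!all(c(na, ne) %in% rownames(cov))) next
    sa <- fit$Sigma_a[j, j]; se2 <- fit$Sigma_e[j, j]
    g <- c(se2, -sa) / (sa + se2)^2
    h2_se[j] <- sqrt(max(drop(t(g) %*% cov[c(na, ne), c(na, ne)] %*% g), 0))
  }
  fit$h2_se <- h2_se
  fit
}

#' @export
print.mt_fit <- function(x, ...) {
  cat(sprintf(
    "mt_fit (%s): %d responses, %d individuals, %s after %d EM iterations\n",
    x$method, length(x$responses), length(x$ids),
    if (x$varcomp$converged) "converged" else "NOT converged",
    x$varcomp$n_iter))
  cat("genetic covariance (Sigma_a):\n"); print(round(x$Sigma_a, 4))
  cat("residual covariance (Sigma_e):\n"); print(round(x$Sigma_e, 4))
  invisible(x)
}
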