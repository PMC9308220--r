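# Single-trait, single-site GBLUP mixed model:
#   y = X beta + Z_d d + Z_a a + e,  a ~ N(0, G sigma2_a),  e ~ N(0, I sigma2_e)
# with d the random design effects (replication, set-within-replication).
# Variance components by EM-REML, accelerated through a one-time
# eigendecomposition of G: with Z_a = I the additive MME block is
# I + lambda G^{-1} = U diag(1 + lambda/d) U', and the small fixed+design
# block is absorbed by a Woodbury identity, making every EM iteration O(n q).
# After convergence one average-information (AI) evaluation supplies the
# information matrix for approximate standard errors.

#' Fit the single-trait single-site GBLUP model by EM-REML
#'
#' @param pheno phenotype data frame (see [simulate_phenotypes()] layout).
#' @param grm a [compute_grm()] object covering all phenotyped trees.
#' @param trait name of the trait column.
#' @param site optional site label to subset on.
#' @param fixed name of the genetic-group (provenance) factor column, or
#'   `NULL` for an intercept-only fixed part (as in the GWAS models).
#' @param design character vector of random design factors; the default
#'   fits replication and set-within-replication. Use `NULL` for none.
#' @param fix_varcomp optional named vector
#'   (`sigma2_a`, `sigma2_e`, and optionally `sigma2_rep`, `sigma2_set`) at
#'   which the MME is solved once without REML iteration.
#' @param tol relative-change convergence tolerance (all components).
#' @param max_iter maximum EM iterations.
#' @param se compute approximate SEs via one AI evaluation (O(n^3) once).
#' @param Geig optional precomputed `eigen()` of the G sub-matrix for the
#'   analyzed trees (list with `values`, `vectors`, `ids`), reused across
#'   traits of one site.
#' @return object of class `st_fit`: variance components with approximate
#'   SEs, REML log-likelihood trace, fixed/design solutions, breeding values
#'   `ahat` with prediction-error variances, and heritability.
#' @export
fit_st_gblup <- function(pheno, grm, trait, site = NULL,
                         fixed = "provenance", design = c("rep", "set"),
                         fix_varcomp = NULL, tol = 1e-6, max_iter = 2000L,
                         se = TRUE, Geig = NULL) {
  dat <- pheno
  if (!is.null(site)) dat <- dat[dat$site == site, , drop = FALSE]
  if (!trait %in% names(dat)) .err("trait '%s' not in phenotype table", trait)
  dat <- dat[!is.na(dat[[trait]]), , drop = FALSE]
  n <- nrow(dat)
  if (n < 10) .err("fewer than 10 phenotyped trees for %s", trait)
  ids <- as.character(dat$tree)
  if (anyDuplicated(ids))
    .err("one record per tree required for the single-site model")
  missing_ids <- setdiff(ids, rownames(grm$G))
  if (length(missing_ids))
    .err("%d phenotyped trees absent from the GRM (e.g. %s)",
         length(missing_ids), missing_ids[1])
  y <- as.numeric(dat[[trait]])
  # fixed part
  if (!is.null(fixed) && fixed %in% names(dat) &&
      length(unique(dat[[fixed]])) > 1) {
    X <- model.matrix(~factor(dat[[fixed]]))
    colnames(X) <- c("(Intercept)",
                     paste0(fixed, levels(factor(dat[[fixed]]))[-1]))
  } else {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  # random design incidence
  Zlist <- list()
  if (!is.null(design) && length(design)) {
    if ("rep" %in% design && length(unique(dat$rep)) > 1) {
      f <- factor(dat$rep)
      Zlist$rep <- model.matrix(~0 + f)
    }
    if ("set" %in% design && "set" %in% names(dat)) {
      f <- factor(paste(dat$rep, dat$set, sep = ":"))
      if (nlevels(f) > 1) Zlist$set <- model.matrix(~0 + f)
    }
  }
  if (is.null(Geig) || !identical(Geig$ids, ids)) {
    Gsub <- grm$G[ids, ids]
    eg <- eigen(Gsub, symmetric = TRUE)
    Geig <- list(values = pmax(eg$values, 1e-10), vectors = eg$vectors,
                 ids = ids)
  }
  fit <- .st_em_reml(y, X, Zlist, Geig, fix_varcomp = fix_varcomp,
                     tol = tol, max_iter = max_iter, want_se = se)
  # expose the (possibly rank-truncated) eigen basis actually used, so that
  # downstream back-solving is consistent with the fitted pseudo-inverse
  fit$Geig <- list(values = fit$pev_struct$d, vectors = fit$pev_struct$U,
                   ids = ids)
  fit$trait <- trait; fit$site <- site; fit$ids <- ids
  names(fit$ahat) <- ids
  fit$model <- "st_gblup"
  class(fit) <- "st_fit"
  fit
}

# EM-REML core. Geig: eigen of the n x n G for the analyzed records.
# A singular G (e.g. unblended, where centering forces 1'W = 0) is handled
# by restricting the additive effect to the positive eigenspace of G
# (pseudo-inverse treatment); with a blended G the rank is full and this
# changes nothing.
.st_em_reml <- function(y, X, Zlist, Geig, fix_varcomp = NULL,
                        tol = 1e-6, max_iter = 2000L, want_se = TRUE) {
  n <- length(y); p <- ncol(X)
  keep <- Geig$values > max(Geig$values) * 1e-9
  U <- Geig$vectors[, keep, drop = FALSE]
  d <- Geig$values[keep]
  r <- length(d)
  Fm <- do.call(cbind, c(list(X), unname(Zlist)))
  q0 <- ncol(Fm)
  comp_cols <- list()
  off <- p
  for (k in names(Zlist)) {
    comp_cols[[k]] <- off + seq_len(ncol(Zlist[[k]]))
    off <- off + ncol(Zlist[[k]])
  }
  Ft <- crossprod(U, Fm); yt <- drop(crossprod(U, y))
  FtF <- crossprod(Fm); Fy <- drop(crossprod(Fm, y)); yy <- sum(y^2)
  vy <- var(y)
  floor_v <- 1e-8 * vy
  comps <- c("sigma2_a",
             if (length(Zlist)) paste0("sigma2_", names(Zlist)),
             "sigma2_e")
  if (!is.null(fix_varcomp)) {
    th <- rep(NA_real_, length(comps)); names(th) <- comps
    th["sigma2_a"] <- fix_varcomp[["sigma2_a"]]
    th["sigma2_e"] <- fix_varcomp[["sigma2_e"]]
    for (k in names(Zlist)) {
      nm <- paste0("sigma2_", k)
      th[nm] <- if (nm %in% names(fix_varcomp)) fix_varcomp[[nm]] else vy * 0.05
    }
    max_iter <- 0L
  } else {
    th <- setNames(c(0.3 * vy, rep(0.05 * vy, length(Zlist)), 0.5 * vy),
                   comps)
  }
  iterate <- function(th) {
    se2 <- th["sigma2_e"]; sa2 <- th["sigma2_a"]
    lam_a <- se2 / sa2
    w <- d / (d + lam_a)
    Df <- rep(0, q0)
    for (k in names(Zlist)) Df[comp_cols[[k]]] <- se2 / th[paste0("sigma2_", k)]
    H <- w * Ft
    S <- FtF + diag(Df, q0) - crossprod(Ft, H)
    Sc <- chol(S)
    Sinv <- chol2inv(Sc)
    rhs <- Fy - drop(crossprod(Ft, w * yt))
    fhat <- drop(Sinv %*% rhs)
    at <- w * (yt - drop(Ft %*% fhat))
    resid_q <- yy - sum(fhat * Fy) - sum(at * yt)
    resid_q <- max(resid_q, 1e-12 * yy)
    # REML log-likelihood at th (MME determinant identity)
    ldetC <- sum(log1p(lam_a / d)) + 2 * sum(log(diag(Sc)))
    m2ll <- n * log(se2) + r * log(sa2) + sum(log(d)) +
      sum(vapply(names(Zlist), function(k)
        ncol(Zlist[[k]]) * log(th[paste0("sigma2_", k)]), numeric(1))) +
      ldetC - (q0 + r) * log(se2) + resid_q / se2 + (n - p) * log(2 * pi)
    # EM updates
    tr_aa <- sum(w / d) + sum(Sinv * crossprod(H, H / d))
    new <- th
    new["sigma2_e"] <- resid_q / (n - p)
    new["sigma2_a"] <- (sum(at^2 / d) + se2 * tr_aa) / r
    for (k in names(Zlist)) {
      ck <- comp_cols[[k]]
      new[paste0("sigma2_", k)] <-
        (sum(fhat[ck]^2) + se2 * sum(diag(Sinv)[ck])) / length(ck)
    }
    new <- pmax(new, floor_v)
    list(th_new = new, loglik = -m2ll / 2, fhat = fhat, at = at, w = w,
         H = H, Sinv = Sinv)
  }
  trace_ll <- numeric(0)
  converged <- FALSE
  it <- 0L
  st <- iterate(th)
  if (max_iter > 0L) {
    for (it in seq_len(max_iter)) {
      st <- iterate(th)
      trace_ll <- c(trace_ll, st$loglik)
      rel <- abs(st$th_new - th) / vy
      th <- st$th_new
      if (max(rel) < tol) { converged <- TRUE; break }
    }
    # final solve at the converged components
    st <- iterate(th)
  } else {
    converged <- TRUE
    trace_ll <- st$loglik
  }
  ahat <- drop(U %*% st$at)
  # PEV: diag of sigma2_e * C^{aa}, C^{aa} = U (diag(w) + H Sinv H') U'
  UH <- U %*% st$H
  pev <- th["sigma2_e"] *
    (drop((U * U) %*% st$w) + rowSums((UH %*% st$Sinv) * UH))
  fhat <- st$fhat
  beta <- fhat[seq_len(p)]; names(beta) <- colnames(X)
  design_eff <- lapply(comp_cols, function(ck) {
    u <- fhat[ck]; names(u) <- colnames(Fm)[ck]; u
  })
  out <- list(
    varcomp = list(sigma2 = th, se = setNames(rep(NA_real_, length(th)),
                                              names(th)),
                   loglik = st$loglik, loglik_trace = trace_ll,
                   n_iter = it, converged = converged),
    beta = beta, design_effects = design_eff, ahat = ahat, pev = pev,
    pev_struct = list(U = U, w = st$w, H = st$H, Sinv = st$Sinv,
                      sigma2_e = unname(th["sigma2_e"]),
                      sigma2_a = unname(th["sigma2_a"]), d = d),
    X = X, Zlist = Zlist, y = y, Geig = Geig)
  out$h2 <- unname(th["sigma2_a"] / (th["sigma2_a"] + th["sigma2_e"]))
  if (want_se) out <- .st_ai_se(out)
  out
}

# one AI evaluation at the converged estimates -> approximate SEs for the
# variance components and (delta method) for h2
.st_ai_se <- function(fit) {
  th <- fit$varcomp$sigma2
  U <- fit$pev_struct$U; d <- fit$pev_struct$d
  n <- length(fit$y); X <- fit$X
  G <- U %*% (d * t(U))
  V <- th["sigma2_a"] * G + th["sigma2_e"] * diag(n)
  for (k in names(fit$Zlist))
    V <- V + th[paste0("sigma2_", k)] * tcrossprod(fit$Zlist[[k]])
  ok <- TRUE
  Vi <- tryCatch(chol2inv(chol(V)), error = function(e) { ok <<- FALSE; NULL })
  if (!ok) return(fit)
  ViX <- Vi %*% X
  XtViX_inv <- solve(crossprod(X, ViX))
  Pfun <- function(q) Vi %*% q - ViX %*% (XtViX_inv %*% crossprod(ViX, q))
  Py <- Pfun(fit$y)
  qs <- c(list(sigma2_a = G %*% Py),
          lapply(fit$Zlist, function(Z) Z %*% crossprod(Z, Py)),
          list(sigma2_e = Py))
  names(qs) <- names(th)
  k <- length(qs)
  AI <- matrix(0, k, k, dimnames = list(names(th), names(th)))
  Pq <- lapply(qs, Pfun)
  for (i in seq_len(k)) for (j in i:k) {
    AI[i, j] <- AI[j, i] <- 0.5 * sum(qs[[i]] * Pq[[j]])
  }
  cov <- tryCatch(solve(AI), error = function(e) NULL)
  if (!is.null(cov)) {
    fit$varcomp$se <- setNames(sqrt(pmax(diag(cov), 0)), names(th))
    fit$varcomp$ai_cov <- cov
    sa <- th["sigma2_a"]; se2 <- th["sigma2_e"]
    g <- c(se2, -sa) / (sa + se2)^2
    idx <- c("sigma2_a", "sigma2_e")
    fit$h2_se <- sqrt(max(drop(t(g) %*% cov[idx, idx] %*% g), 0))
  }
  fit
}

#' @export
print.st_fit <- function(x, ...) {
  cat(sprintf("st_fit: trait %s%s, n = %d, %s after %d EM iterations\n",
              x$trait, if (!is.null(x$site)) paste0(" at ", x$site) else "",
              length(x$y),
              if (x$varcomp$converged) "converged" else "NOT converged",
              x$varcomp$n_iter))
  print(round(rbind(estimate = x$varcomp$sigma2, se = x$varcomp$se), 4))
  cat(sprintf("h2 = %.3f (SE %.3f), REML loglik = %.3f\n", x$h2,
              if (is.null(x$h2_se)) NA_real_ else x$h2_se,
              x$varcomp$loglik))
  invisible(x)
}

#' Design-effect adjustment and standardization of phenotypes
#'
#' For every trait and site, subtracts the estimated replication and
#' set-within-replication BLUPs obtained from the single-site GBLUP fits,
#' then standardizes each trait-site column to zero mean and unit variance.
#' Ordinal traits should be normal-scored beforehand
#' (see [normal_score_transform()]).
#'
#' @param pheno phenotype data frame.
#' @param grm a [compute_grm()] covering all trees.
#' @param traits trait columns to adjust (default: all non-design columns).
#' @param st_fits optional pre-computed list of `st_fit`s named
#'   `"trait@site"`; fits are run where missing.
#' @param ... passed to [fit_st_gblup()].
#' @return the phenotype data frame with adjusted, standardized trait
#'   columns; the per-trait-site fits are attached as `attr(, "st_fits")`.
#' @export
adjust_phenotypes <- function(pheno, grm, traits = NULL, st_fits = list(),
                              ...) {
  design_cols <- c("tree", "mother", "father", "provenance", "site", "rep",
                   "set")
  if (is.null(traits)) traits <- setdiff(names(pheno), design_cols)
  if (!all(c("rep", "set") %in% names(pheno)))
    .err("phenotype table lacks design columns rep/set")
  out <- pheno
  sites <- unique(pheno$site)
  for (tr in traits) {
    for (s in sites) {
      key <- paste0(tr, "@", s)
      rows <- which(pheno$site == s & !is.na(pheno[[tr]]))
      if (!length(rows)) next
      yv <- pheno[[tr]][rows]
      if (sd(yv) < 1e-12)
        .err("trait %s at site %s is constant and cannot be standardized",
             tr, s)
      if (is.null(st_fits[[key]]))
        st_fits[[key]] <- fit_st_gblup(pheno, grm, tr, site = s, ...)
      fit <- st_fits[[key]]
      adj <- yv
      dat <- pheno[rows, ]
      de <- fit$design_effects
      if (!is.null(de$rep)) {
        lev <- sub("^f", "", names(de$rep))
        adj <- adj - de$rep[match(as.character(dat$rep), lev)]
      }
      if (!is.null(de$set)) {
        lev <- sub("^f", "", names(de$set))
        adj <- adj - de$set[match(paste(dat$rep, dat$set, sep = ":"), lev)]
      }
      out[[tr]][rows] <- (adj - mean(adj)) / sd(adj)
    }
  }
  attr(out, "st_fits") <- st_fits
  attr(out, "truth") <- attr(pheno, "truth")
  out
}

#' Narrow-sense heritability from fitted variance components
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_e)` per trait (or site), with a
#' delta-method SE from the AI information matrix when available.
#'
#' @param fit an `st_fit` or `mt_fit`.
#' @return data frame with columns `trait`, `h2`, `se`.
#' @export
estimate_h2 <- function(fit) {
  if (inherits(fit, "st_fit")) {
    if (fit$varcomp$sigma2[["sigma2_a"]] + fit$varcomp$sigma2[["sigma2_e"]] <= 0)
      .err("total variance is zero")
    return(data.frame(trait = fit$trait %||% "trait", h2 = fit$h2,
                      se = fit$h2_se %||% NA_real_))
  }
  if (inherits(fit, "mt_fit")) {
    sa <- diag(fit$Sigma_a); se2 <- diag(fit$Sigma_e)
    h2 <- sa / (sa + se2)
    ses <- fit$h2_se %||% rep(NA_real_, length(h2))
    return(data.frame(trait = fit$responses, h2 = h2, se = ses,
                      row.names = NULL))
  }
  .err("estimate_h2 expects an st_fit or mt_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genetic correlation between two responses of a multi-trait fit
#'
#' `r_a = sigma_a_ij / sqrt(sigma2_a_ii sigma2_a_jj)`, clipped for reporting
#' to `[-1, 1]`, with a delta-method SE when the AI covariance is available.
#'
#' @param fit an `mt_fit`.
#' @param i,j response names or indices.
#' @return list with `estimate` and `se`.
#' @export
estimate_genetic_correlation <- function(fit, i = 1, j = 2) {
  stopifnot(inherits(fit, "mt_fit"))
  if (is.character(i)) i <- match(i, fit$responses)
  if (is.character(j)) j <- match(j, fit$responses)
  Sa <- fit$Sigma_a
  if (Sa[i, i] <= 0 || Sa[j, j] <= 0)
    .err("zero genetic variance for one of the responses")
  r <- Sa[i, j] / sqrt(Sa[i, i] * Sa[j, j])
  se_r <- NA_real_
  cv <- fit$ai_cov
  if (!is.null(cv)) {
    nm <- c(sprintf("a_%d_%d", i, i), sprintf("a_%d_%d", min(i, j), max(i, j)),
            sprintf("a_%d_%d", j, j))
    if (all(nm %in% rownames(cv))) {
      g <- c(-r / (2 * Sa[i, i]), 1 / sqrt(Sa[i, i] * Sa[j, j]),
             -r / (2 * Sa[j, j]))
      se_r <- sqrt(max(drop(t(g) %*% cv[nm, nm] %*% g), 0))
    }
  }
  list(estimate = max(-1, min(1, r)), se = se_r)
}
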