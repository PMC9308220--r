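test_that("BLUPs at fixed components equal the direct dense MME solve", {
  ts <- tiny_setup()
  vc <- c(sigma2_a = 0.5, sigma2_e = 0.5, sigma2_rep = 0.05,
          sigma2_set = 0.05)
  fit <- fit_st_gblup(ts$fx$pheno, ts$grm, "T1", site = "S1",
                      fix_varcomp = vc, se = FALSE)
  ids <- fit$ids
  y <- fit$y; X <- fit$X
  Zr <- fit$Zlist$rep; Zs <- fit$Zlist$set
  G <- ts$grm$G[ids, ids]
  nb <- ncol(X) + ncol(Zr) + ncol(Zs)
  Wd <- cbind(X, Zr, Zs, diag(length(y)))
  D <- diag(c(rep(0, ncol(X)),
              rep(vc["sigma2_e"] / vc["sigma2_rep"], ncol(Zr)),
              rep(vc["sigma2_e"] / vc["sigma2_set"], ncol(Zs)),
              rep(0, length(y))))
  ai <- nb + seq_along(y)
  D[ai, ai] <- vc["sigma2_e"] / vc["sigma2_a"] * solve(G)
  C <- crossprod(Wd) + D
  sol <- solve(C, crossprod(Wd, y))
  expect_lt(max(abs(fit$ahat - sol[ai])), 1e-8)
  expect_lt(max(abs(fit$beta - sol[seq_len(ncol(X))])), 1e-8)
  pev <- vc["sigma2_e"] * diag(solve(C))[ai]
  expect_lt(max(abs(fit$pev - pev)), 1e-8)
  # PEV bounded by the prior variance
  expect_true(all(fit$pev > 0 & fit$pev <= vc["sigma2_a"] * diag(G) + 1e-8))
})

test_that("EM-REML recovers components, monotone loglik, null boundary", {
  ms <- mid_setup()
  fit <- fit_st_gblup(ms$pheno, ms$grm, "T1", site = "S1")
  expect_true(fit$varcomp$converged)
  expect_equal(fit$h2, 0.5, tolerance = 0.12)
  expect_gt(fit$varcomp$se["sigma2_a"], 0)
  ll <- fit$varcomp$loglik_trace
  expect_true(all(diff(ll) > -1e-6))
  # affine invariance of h2
  ph2 <- ms$pheno
  ph2$T1 <- 3 + 2.5 * ph2$T1
  fit2 <- fit_st_gblup(ms$pheno, ms$grm, "T1", site = "S1", se = FALSE)
  fit3 <- fit_st_gblup(ph2, ms$grm, "T1", site = "S1", se = FALSE)
  expect_equal(fit2$h2, fit3$h2, tolerance = 1e-4)
  # null fixture: additive variance shrinks to the boundary
  nf <- cached("null-fit", function() {
    fx <- make_fixture("null", 8)
    geno <- impute_mean(filter_snps(fx$geno, quiet = TRUE))
    grm <- compute_grm(geno)
    list(fit = fit_st_gblup(fx$pheno, grm, "T1", site = "S1", se = FALSE))
  })
  expect_lt(nf$fit$h2, 0.05)
})

test_that("adjustment removes design effects and standardizes", {
  ms <- mid_setup()
  adj <- adjust_phenotypes(ms$pheno, ms$grm, se = FALSE)
  for (tr in c("T1", "T2")) {
    expect_equal(mean(adj[[tr]]), 0, tolerance = 1e-10)
    expect_equal(sd(adj[[tr]]), 1, tolerance = 1e-10)
  }
  # adjusted data carry less replication signal than raw data
  raw_r2 <- summary(lm(T1 ~ factor(rep), ms$pheno))$r.squared
  adj_r2 <- summary(lm(T1 ~ factor(rep), adj))$r.squared
  expect_lt(adj_r2, raw_r2 + 1e-12)
  ph <- ms$pheno; ph$T1 <- 1
  expect_error(adjust_phenotypes(ph, ms$grm, traits = "T1"), "constant")
})

test_that("multi-trait EM: canonical and dense paths agree; r_a recovered", {
  ms <- mid_setup()
  adj <- adjust_phenotypes(ms$pheno, ms$grm, se = FALSE)
  fit <- cached("mid-mt", function()
    fit_mt_gblup(adj, ms$grm, responses = c("T1", "T2"), se = TRUE))
  expect_true(fit$varcomp$converged)
  ra <- estimate_genetic_correlation(fit, "T1", "T2")
  expect_equal(ra$estimate, 0.7, tolerance = 0.2)
  expect_true(is.finite(ra$se) && ra$se > 0)
  h2 <- estimate_h2(fit)
  expect_true(all(h2$h2 >= 0 & h2$h2 <= 1))
  ll <- fit$varcomp$loglik_trace
  expect_true(all(diff(ll) > -1e-6))
  # dense path on a subsample reproduces the canonical fit
  set.seed(2)
  sub <- adj[sort(sample(nrow(adj), 110)), ]
  f1 <- fit_mt_gblup(sub, ms$grm, responses = c("T1", "T2"),
                     method = "canonical", se = FALSE, tol = 1e-8)
  f2 <- fit_mt_gblup(sub, ms$grm, responses = c("T1", "T2"),
                     method = "dense", se = FALSE, tol = 1e-8)
  expect_lt(max(abs(f1$Sigma_a - f2$Sigma_a)), 5e-3)
  expect_lt(abs(f1$varcomp$loglik - f2$varcomp$loglik), 5e-3)
  expect_gt(cor(c(f1$ahat), c(f2$ahat)), 0.9999)
})

test_that("degenerate and unbalanced multi-trait cases behave", {
  ms <- mid_setup()
  adj <- adjust_phenotypes(ms$pheno, ms$grm, se = FALSE)
  # duplicating a trait drives the genetic correlation to the boundary
  dup <- adj
  dup$T1b <- dup$T1
  fd <- fit_mt_gblup(dup[seq_len(150), ], ms$grm,
                     responses = c("T1", "T1b"), se = FALSE,
                     max_iter = 200L)
  expect_gt(estimate_genetic_correlation(fd, 1, 2)$estimate, 0.98)
  # genetically independent traits: estimate near zero
  fi <- cached("mt-independent", function() {
    cfg <- sim_config(
      n_families = 30L, mothers_per_provenance = 10L, n_provenances = 3L,
      offspring_per_family_per_site = 14L, sites = "S1", n_snps = 1000L,
      n_traits = 2L, h2 = matrix(0.4, 2, 1), genetic_corr = diag(2),
      cross_site_corr = matrix(1, 1, 1), missing_rate = 0,
      n_reps = 4L, n_sets = 4L, n_qtl = 300L, seed = 77)
    sim <- simulate_genotypes(cfg)
    ph <- simulate_phenotypes(cfg, sim$geno, sim$pedigree)
    grm <- compute_grm(impute_mean(sim$geno))
    adj0 <- adjust_phenotypes(ph, grm, se = FALSE)
    bv <- attr(ph, "truth")$bv_at_site
    list(fit = fit_mt_gblup(adj0, grm, responses = c("T1", "T2"),
                            se = FALSE),
         realized = cor(bv[, 1], bv[, 2]))
  })
  # the estimate tracks the realized correlation of the true breeding
  # values (which differs from the nominal zero by LD/family sampling)
  est0 <- estimate_genetic_correlation(fi$fit, 1, 2)$estimate
  expect_lt(abs(est0 - fi$realized), 0.25)
  expect_lt(abs(fi$realized), 0.3)
  # scattered missing cells are handled by per-record incidence
  mis <- adj[seq_len(150), ]
  mis$T2[sample(150, 30)] <- NA
  fm <- fit_mt_gblup(mis, ms$grm, responses = c("T1", "T2"), se = FALSE)
  expect_true(all(is.finite(fm$Sigma_a)))
  expect_equal(fm$method, "dense")
  expect_equal(dim(fm$ahat), c(150L, 2L))
})

test_that("site-split mode estimates cross-site genetic correlation", {
  cs <- cached("site-split", function() {
    cfg <- sim_config(
      n_families = 25L, mothers_per_provenance = 13L, n_provenances = 2L,
      offspring_per_family_per_site = 5L, sites = c("A", "B"),
      n_snps = 1000L, n_traits = 2L,
      h2 = matrix(0.5, 2, 2), genetic_corr = diag(2),
      cross_site_corr = matrix(c(1, 0.8, 0.8, 1), 2),
      missing_rate = 0, n_reps = 3L, n_sets = 3L, n_qtl = 300L, seed = 21)
    sim <- simulate_genotypes(cfg)
    pheno <- simulate_phenotypes(cfg, sim$geno, sim$pedigree)
    geno <- impute_mean(filter_snps(sim$geno, quiet = TRUE))
    grm <- compute_grm(geno)
    adj <- adjust_phenotypes(pheno, grm, se = FALSE)
    fit_mt_gblup(adj, grm, trait = "T1", site_split = TRUE, se = FALSE,
                 max_iter = 200L)
  })
  expect_true(cs$site_split)
  # structural zero cross-site residual covariance
  expect_equal(cs$Sigma_e[1, 2], 0)
  ra <- estimate_genetic_correlation(cs, 1, 2)
  expect_equal(ra$estimate, 0.8, tolerance = 0.3)
})

test_that("parameter estimators follow their closed forms", {
  fake <- structure(list(Sigma_a = matrix(c(0.09, 0.06, 0.06, 0.16), 2),
                         Sigma_e = matrix(c(0.21, 0, 0, 0.24), 2),
                         responses = c("x", "y"), ai_cov = NULL),
                    class = "mt_fit")
  expect_equal(estimate_genetic_correlation(fake, 1, 2)$estimate, 0.5)
  fake$Sigma_a[1, 2] <- fake$Sigma_a[2, 1] <- 0
  expect_equal(estimate_genetic_correlation(fake, 1, 2)$estimate, 0)
  h2 <- estimate_h2(fake)
  expect_equal(h2$h2, c(0.3, 0.4))
  fake$Sigma_a[1, 1] <- 0
  expect_error(estimate_genetic_correlation(fake, 1, 2), "zero genetic")
})
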