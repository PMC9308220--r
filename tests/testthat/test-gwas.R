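test_that("back-solving is the stated linear transformation", {
  ts <- tiny_setup()
  fit <- fit_st_gblup(ts$fx$pheno, ts$grm, "T1", fixed = NULL,
                      design = NULL,
                      fix_varcomp = c(sigma2_a = 0.4, sigma2_e = 0.6),
                      se = FALSE)
  g <- backsolve_snp_effects(fit, ts$grm, ts$geno)
  W <- center_dosages(ts$geno, ts$grm)[fit$ids, ]
  G <- ts$grm$G[fit$ids, fit$ids]
  direct <- drop(crossprod(W, solve(G, fit$ahat))) / ts$grm$denom
  expect_lt(max(abs(g - direct)), 1e-8)
  # linearity: zero and doubled breeding values
  fit0 <- fit
  fit0$ahat <- fit$ahat * 0
  expect_true(all(backsolve_snp_effects(fit0, ts$grm, ts$geno) == 0))
  fit2 <- fit
  fit2$ahat <- fit$ahat * 2
  expect_equal(backsolve_snp_effects(fit2, ts$grm, ts$geno), 2 * g,
               tolerance = 1e-12)
})

test_that("effect variances match the dense MME-inverse oracle", {
  ts <- tiny_setup()
  vc <- c(sigma2_a = 0.4, sigma2_e = 0.6)
  fit <- fit_st_gblup(ts$fx$pheno, ts$grm, "T1", fixed = NULL,
                      design = NULL, fix_varcomp = vc, se = FALSE)
  v <- snp_effect_variances(fit, ts$grm, ts$geno)
  W <- center_dosages(ts$geno, ts$grm)[fit$ids, ]
  G <- ts$grm$G[fit$ids, fit$ids]
  n <- length(fit$ids)
  X <- matrix(1, n, 1)
  C <- rbind(cbind(crossprod(X), t(X)),
             cbind(X, diag(n) + vc["sigma2_e"] / vc["sigma2_a"] * solve(G)))
  Caa <- vc["sigma2_e"] * solve(C)[-1, -1]
  Va <- vc["sigma2_a"] * G - Caa
  GiW <- solve(G, W)
  oracle <- diag(crossprod(GiW, Va %*% GiW)) / ts$grm$denom^2
  expect_lt(max(abs(v - oracle)), 1e-8)
  expect_true(all(v > 0))
  # no-information boundary: PEV equal to the prior variance
  fit_no <- fit
  fit_no$pev_struct$w <- fit$pev_struct$d      # C^{aa} -> G in the basis
  fit_no$pev_struct$H[] <- 0
  fit_no$pev_struct$sigma2_e <- 1
  fit_no$pev_struct$sigma2_a <- 1
  fit_no$varcomp$sigma2["sigma2_a"] <- 1
  v0 <- snp_effect_variances(fit_no, ts$grm, ts$geno)
  expect_lt(max(abs(v0)), 1e-8)
  expect_gt(attr(v0, "flagged"), 0)
  expect_error(snp_pvalues(v0 * 0, v0), "nonpositive")
})

test_that("p-values follow the two-sided normal formula", {
  tab <- snp_pvalues(c(0, 1.959964, -1.959964), c(1, 1, 1))
  expect_equal(tab$p_value[1], 1)
  expect_equal(tab$p_value[2], 0.05, tolerance = 1e-6)
  expect_equal(tab$p_value[3], 0.05, tolerance = 1e-6)
  expect_equal(tab$p_value, 2 * (1 - pnorm(abs(tab$z))), tolerance = 1e-12)
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
})

test_that("Bonferroni thresholds reproduce the standard cutoffs", {
  thr <- bonferroni_threshold(0.05, 25099)
  expect_equal(signif(thr$p_cutoff, 3), 1.99e-06)
  expect_equal(round(thr$neg_log10, 1), 5.7)
  expect_equal(bonferroni_threshold(0.05, 1)$p_cutoff, 0.05)
  thr2 <- bonferroni_threshold(0.01, 100)
  expect_equal(thr2$p_cutoff, 1e-4)
  expect_equal(thr2$neg_log10, 4)
  expect_error(bonferroni_threshold(1.5, 10), "alpha")
})

test_that("association summary counts overlaps and pleiotropy sharing", {
  mk <- function(p) {
    tab <- snp_pvalues(qnorm(p / 2) * -1, rep(1, length(p)),
                       snp_ids = paste0("s", seq_along(p)))
    tab
  }
  p1 <- c(1e-9, 1e-8, 0.5, 0.9)
  p2 <- c(1e-9, 0.5, 1e-9, 0.9)
  st <- list(A = mk(p1), B = mk(p2))
  summ_same <- association_summary(st, st)
  expect_equal(summ_same$counts$overlap, summ_same$counts$st_significant)
  expect_equal(summ_same$shared["A", "B"], 1)   # s1 shared above diagonal
  expect_equal(summ_same$shared["B", "A"], 1)   # and below (same input)
  # empty significance: all-zero matrix
  null_tab <- mk(c(0.5, 0.6, 0.7, 0.8))
  s0 <- association_summary(list(A = null_tab, B = null_tab),
                            list(A = null_tab, B = null_tab))
  expect_true(all(s0$shared == 0))
  expect_true(all(s0$counts$st_significant == 0))
  # mismatched panels rejected
  other <- mk(p1); other$snp_id <- paste0("x", 1:4)
  expect_error(association_summary(list(A = mk(p1)), list(A = other)),
               "common SNP panel")
})
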