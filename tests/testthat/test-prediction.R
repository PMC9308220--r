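test_that("chain configuration validates and carries presets", {
  expect_error(chain_config(100, 200), "burn_in")
  expect_error(chain_config(100, 10, 0), "thin")
  expect_equal(chain_config(preset = "paper_st")$n_iter, 20000L)
  expect_equal(chain_config(preset = "paper_mt")$n_iter, 200000L)
})

test_that("marker samplers: ridge oracle, null response, determinism", {
  ts <- tiny_setup(5)
  W <- center_dosages(ts$geno, ts$grm)
  y <- ts$fx$pheno$T1
  s2g <- 0.4 / ts$grm$denom
  fit <- fit_brr(y, W, chain_config(12000, 2000, 2, seed = 7),
                 fix_varcomp = list(sigma2_g = s2g, sigma2_e = 0.6))
  X1 <- matrix(1, length(y), 1)
  lam <- 0.6 / s2g
  C <- rbind(cbind(crossprod(X1), t(X1) %*% W),
             cbind(crossprod(W, X1), crossprod(W) + lam * diag(ncol(W))))
  ridge <- solve(C, rbind(crossprod(X1, y), crossprod(W, y)))[-1]
  expect_lt(max(abs(fit$g - ridge)), 0.02)
  # seeded determinism for all three samplers
  for (f in list(fit_brr, fit_bayesc, fit_blasso)) {
    a <- f(y, W, chain_config(600, 100, 2, seed = 3))
    b <- f(y, W, chain_config(600, 100, 2, seed = 3))
    expect_identical(a$g, b$g)
  }
  # (near-)null response: effects collapse to zero
  y0 <- rnorm(length(y), 0, 1e-6)
  for (f in list(fit_brr, fit_blasso)) {
    f0 <- f(y0, W, chain_config(800, 200, 2, seed = 2))
    expect_lt(max(abs(f0$g)), 1e-5)
  }
  fc0 <- fit_bayesc(y0, W, chain_config(1500, 300, 2, seed = 2))
  # no signal: inclusion stays near the prior mean (0.01)
  expect_lt(mean(fc0$pip), 0.1)
})

test_that("BayesC finds large QTL and approaches BRR as pi -> 1", {
  oli <- cached("oligo", function() {
    set.seed(31)
    cfg <- sim_config(n_families = 20L, mothers_per_provenance = 10L,
                      n_provenances = 2L, offspring_per_family_per_site = 10L,
                      sites = "S1", n_snps = 300L, maf_range = c(0.2, 0.5),
                      n_traits = 2L, h2 = matrix(0.3, 2, 1),
                      genetic_corr = diag(2),
                      cross_site_corr = matrix(1, 1, 1), missing_rate = 0,
                      seed = 31)
    sim <- simulate_genotypes(cfg)
    geno <- impute_mean(sim$geno)
    grm <- compute_grm(geno)
    W <- center_dosages(geno, grm)
    qtl <- c(25, 150, 275)
    u <- W[, qtl] %*% c(1, -1, 1)
    y <- drop(u + rnorm(nrow(W), 0, sd(u) * 0.6))
    list(W = W, y = y, qtl = qtl)
  })
  hits <- vapply(1:5, function(s) {
    fc <- fit_bayesc(oli$y, oli$W, chain_config(1500, 300, 3, seed = s))
    sum(order(-fc$pip)[1:3] %in% oli$qtl)
  }, numeric(1))
  expect_gte(mean(hits == 3), 0.8)
  # pi prior mass near 1 reduces BayesC to ridge-like behaviour
  ch <- chain_config(2500, 500, 2, seed = 9)
  fb <- fit_brr(oli$y, oli$W, ch)
  fc1 <- fit_bayesc(oli$y, oli$W, ch, pi_prior = c(500, 1))
  expect_gt(cor(drop(oli$W %*% fb$g), drop(oli$W %*% fc1$g)), 0.99)
  # lasso shrinks small effects harder: heavier-tailed effect histogram
  fl <- fit_blasso(oli$y, oli$W, ch)
  kurt <- function(x) mean((x - mean(x))^4) / var(x)^2
  expect_gt(kurt(fl$g), kurt(fb$g))
})

test_that("kernels follow their closed forms and limits", {
  ts <- tiny_setup()
  expect_equal(build_kernel(ts$grm, kernel_spec("linear_G")), ts$grm$G)
  K <- build_kernel(ts$geno, kernel_spec("gaussian", h = 0.5))
  expect_true(all(diag(K) == 1))
  expect_lt(max(abs(K - t(K))), 1e-12)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  # hand value: normalized d2 = 2 at h = 0.5 gives exp(-1)
  M <- ts$geno$dosage
  ss <- rowSums(M^2)
  d2 <- outer(ss, ss, "+") - 2 * tcrossprod(M)
  d2 <- d2 / mean(d2[upper.tri(d2)])
  i <- which(abs(d2 - 2) == min(abs(d2 - 2)), arr.ind = TRUE)[1, ]
  expect_equal(K[i[1], i[2]], exp(-0.5 * d2[i[1], i[2]]), tolerance = 1e-12)
  # h -> 0 limit: all-ones kernel
  K0 <- build_kernel(ts$geno, kernel_spec("gaussian", h = 1e-12))
  expect_equal(max(abs(K0 - 1)), 0, tolerance = 1e-9)
  expect_error(kernel_spec("gaussian", h = -1), "positive")
})

test_that("kernel regression with the linear G kernel reproduces GBLUP", {
  ms <- mid_setup()
  adj <- adjust_phenotypes(ms$pheno, ms$grm, se = FALSE)
  sub <- seq_len(250)
  y <- adj$T1[sub]
  K <- ms$grm$G[adj$tree[sub], adj$tree[sub]]
  kf <- fit_kernel_regression(y, K, chain_config(2500, 500, 2, seed = 4))
  stf <- fit_st_gblup(adj[sub, ], ms$grm, "T1", fixed = NULL,
                      design = NULL, se = FALSE)
  expect_gt(cor(kf$u, stf$ahat), 0.99)
  # identity kernel: no covariance information, predictions collapse
  yna <- y; yna[1:50] <- NA
  ki <- fit_kernel_regression(yna, diag(length(y)),
                              chain_config(1000, 200, 2, seed = 4))
  expect_lt(var(ki$u[1:50]), 1e-4)
  # seeded determinism
  k1 <- fit_kernel_regression(y, K, chain_config(500, 100, 2, seed = 5))
  k2 <- fit_kernel_regression(y, K, chain_config(500, 100, 2, seed = 5))
  expect_identical(k1$u, k2$u)
})

test_that("bandwidth selection maximizes CV predictive ability", {
  ms <- mid_setup()
  y <- ms$pheno$T1
  expect_error(select_bandwidth(y, ms$geno, grid = numeric()), "empty")
  one <- select_bandwidth(y, ms$geno, grid = 0.5, k = 3,
                          chain = chain_config(400, 100, 2, seed = 1))
  expect_equal(one$h, 0.5)
  sel <- cached("bandwidth", function()
    select_bandwidth(y, ms$geno, grid = c(0.1, 0.5, 2.5), k = 3,
                     chain = chain_config(600, 150, 2, seed = 2)))
  expect_true(all(is.finite(sel$table$predictive_ability)))
  expect_true(sel$h %in% c(0.1, 0.5, 2.5))
})

test_that("multi-trait sampler: independence limit and determinism", {
  ms <- mid_setup()
  adj <- adjust_phenotypes(ms$pheno, ms$grm, se = FALSE)
  sub <- seq_len(250)
  ids <- adj$tree[sub]
  K <- ms$grm$G[ids, ids]
  set.seed(99)
  Y <- cbind(T1 = adj$T1[sub], X = rnorm(length(sub)))
  rownames(Y) <- ids
  mask <- 1:40
  Ym <- Y; Ym[mask, "T1"] <- NA
  ch <- chain_config(1500, 300, 3, seed = 6)
  mt <- fit_multitrait(Ym, K, ch)
  y1 <- Y[, "T1"]; y1[mask] <- NA
  st <- fit_kernel_regression(y1, K, ch)
  # an uncorrelated companion trait leaves predictions essentially ST
  expect_gt(cor(mt$u[, "T1"], st$u), 0.95)
  mt2 <- fit_multitrait(Ym, K, ch)
  expect_identical(mt$u, mt2$u)
  expect_error(fit_multitrait(Y[, 1, drop = FALSE], K), "two traits")
  Yall <- Y; Yall[, 2] <- NA
  expect_error(fit_multitrait(Yall, K, ch), "no records")
})
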