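test_that("config validation rejects bad inputs", {
  expect_error(sim_config(h2 = matrix(1, 13, 4)), "residual")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(missing_rate = 0.5), "missing_rate")
  bad <- diag(13); bad[1, 2] <- bad[2, 1] <- 2
  expect_error(sim_config(genetic_corr = bad), "positive semi-definite")
})

test_that("founder genotypes have binomial moments and offspring obey MAF box", {
  cfg <- sim_config(n_families = 10L, mothers_per_provenance = 40L,
                    n_provenances = 2L, offspring_per_family_per_site = 2L,
                    sites = "S1", n_snps = 1L, maf_range = c(0.5, 0.5),
                    n_traits = 2L, h2 = matrix(0.2, 2, 1),
                    genetic_corr = diag(2), cross_site_corr = matrix(1, 1, 1),
                    missing_rate = 0, seed = 2)
  sim <- simulate_genotypes(cfg)
  dose <- sim$founder_geno$dosage[, 1]
  # Binomial(2, 0.5): mean 1, variance 0.5 (160 founders)
  expect_equal(mean(dose), 1, tolerance = 0.15)
  expect_equal(var(dose), 0.5, tolerance = 0.25)

  cfg2 <- sim_config(n_families = 20L, mothers_per_provenance = 10L,
                     n_provenances = 2L, offspring_per_family_per_site = 10L,
                     sites = "S1", n_snps = 400L, maf_range = c(0.2, 0.5),
                     n_traits = 2L, h2 = matrix(0.2, 2, 1),
                     genetic_corr = diag(2), cross_site_corr = matrix(1, 1, 1),
                     missing_rate = 0, seed = 5)
  sim2 <- simulate_genotypes(cfg2)
  expect_false(anyNA(sim2$geno$dosage))
  maf <- observed_maf(sim2$geno)
  # realized MAF stays in the configured box up to sampling error
  expect_gt(mean(maf > 0.1), 0.95)
})

test_that("missingness is MCAR at the configured rate", {
  cfg <- sim_config(n_families = 10L, mothers_per_provenance = 5L,
                    n_provenances = 2L, offspring_per_family_per_site = 20L,
                    sites = "S1", n_snps = 500L, n_traits = 2L,
                    h2 = matrix(0.2, 2, 1), genetic_corr = diag(2),
                    cross_site_corr = matrix(1, 1, 1), missing_rate = 0.25,
                    seed = 4)
  sim <- simulate_genotypes(cfg)
  expect_equal(mean(is.na(sim$geno$dosage)), 0.25, tolerance = 0.01)
  expect_false(anyNA(attr(sim$geno, "complete")))
})

test_that("forced full-sib families show additive relationship near 0.5", {
  cfg <- sim_config(n_families = 8L, mothers_per_provenance = 8L,
                    n_provenances = 1L, offspring_per_family_per_site = 12L,
                    sites = "S1", n_snps = 3000L, maf_range = c(0.1, 0.5),
                    n_traits = 2L, h2 = matrix(0.2, 2, 1),
                    genetic_corr = diag(2), cross_site_corr = matrix(1, 1, 1),
                    missing_rate = 0, seed = 9)
  sim <- simulate_genotypes(cfg, one_father_per_family = TRUE)
  # genomic relationships referenced to the founder allele frequencies
  # (in-sample frequencies would deflate relatedness among relatives)
  p0 <- attr(sim$geno, "founder_freq")
  W <- sweep(sim$geno$dosage, 2, 2 * p0, "-")
  G <- tcrossprod(W) / (2 * sum(p0 * (1 - p0)))
  off <- sim$pedigree[sim$pedigree$generation == 1L, ]
  fams <- split(off$id, off$mother)
  within <- unlist(lapply(fams, function(ids) {
    g <- G[ids, ids]
    g[upper.tri(g)]
  }))
  # pedigree expectation for full sibs is 0.5
  expect_equal(mean(within), 0.5, tolerance = 0.07)
})

test_that("phenotype generator delivers its ground-truth parameters", {
  ms <- mid_setup()
  truth <- attr(ms$pheno, "truth")
  bv <- truth$bv_at_site
  # realized additive variance is scaled to the target heritabilities
  expect_equal(var(bv[, 1]), 0.5, tolerance = 1e-8)
  expect_equal(var(bv[, 2]), 0.3, tolerance = 1e-8)
  # realized genetic correlation close to the configured 0.7
  expect_equal(cor(bv[, 1], bv[, 2]), 0.7, tolerance = 0.12)
  # phenotypic variance ~ 1 + design fractions
  expect_lt(abs(var(ms$pheno$T1) - 1.1), 0.25)
})

test_that("zero heritability produces no parent-offspring resemblance", {
  fx <- make_fixture("null", 6)
  truth <- attr(fx$pheno, "truth")
  expect_true(all(truth$bv == 0))
  # families carry no signal: between-family variance share is ~ 1/family size
  fit <- summary(aov(T1 ~ mother, data = fx$pheno))[[1]]
  expect_gt(fit[["Pr(>F)"]][1], 0.001)
})

test_that("fixtures are seeded-deterministic and sized as documented", {
  a <- make_fixture("tiny", 1)
  b <- make_fixture("tiny", 1)
  expect_identical(a$geno$dosage, b$geno$dosage)
  expect_identical(a$pheno, b$pheno)
  expect_equal(dim(a$geno), c(30, 50))
  expect_error(make_fixture("nope", 1))
  pl <- cached("paper_like_dims", function() {
    fx <- make_fixture("paper_like", 7)
    list(dim = dim(fx$geno), traits = ncol(fx$pheno) - 7,
         sites = length(unique(fx$pheno$site)),
         fams = length(unique(fx$pheno$mother)),
         wgr = sort(unique(fx$pheno$WGR)))
  })
  expect_equal(pl$dim, c(1600, 5000))
  expect_equal(pl$traits, 13)
  expect_equal(pl$sites, 4)
  expect_equal(pl$fams, 40)
  expect_true(all(pl$wgr %in% 1:4))   # ordinal pest scores
})
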