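# shared, memoised simulation fixtures so expensive setup runs once per file
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

tiny_setup <- function(seed = 3) {
  cached(paste0("tiny-", seed), function() {
    fx <- make_fixture("tiny", seed)
    geno <- impute_mean(filter_snps(fx$geno, min_maf = 0.05, quiet = TRUE))
    list(fx = fx, geno = geno, grm = compute_grm(geno),
         grm0 = compute_grm(geno, blend_alpha = 0))
  })
}

# single-site two-trait fixture at moderate n for REML behaviour tests
mid_setup <- function(seed = 11) {
  cached(paste0("mid-", seed), function() {
    cfg <- sim_config(
      n_families = 40L, mothers_per_provenance = 10L, n_provenances = 4L,
      offspring_per_family_per_site = 15L, sites = "S1", n_snps = 1500L,
      n_traits = 2L, h2 = matrix(c(0.5, 0.3), 2, 1),
      genetic_corr = matrix(c(1, 0.7, 0.7, 1), 2),
      cross_site_corr = matrix(1, 1, 1), missing_rate = 0.05,
      n_reps = 5L, n_sets = 4L, n_qtl = 300L, seed = seed)
    sim <- simulate_genotypes(cfg)
    pheno <- simulate_phenotypes(cfg, sim$geno, sim$pedigree)
    geno <- impute_mean(filter_snps(sim$geno, quiet = TRUE))
    grm <- compute_grm(geno)
    list(cfg = cfg, pheno = pheno, geno = geno, grm = grm,
         pedigree = sim$pedigree)
  })
}
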