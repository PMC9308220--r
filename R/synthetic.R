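#' Simulation configuration for an open-pollinated multi-site progeny trial
#'
#' Builds and validates the parameter set for the ground-truth simulator. The
#' defaults emulate a series of four open-pollinated (OP) lodgepole pine
#' progeny trials: 40 OP families drawn from five provenances, about ten
#' offspring per family per site, a "set in reps" field design with five
#' replications, 13 correlated growth / wood quality / pest resistance /
#' drought tolerance / monoterpene traits with per-site narrow-sense
#' heritabilities spanning 0.0-0.8, mostly strong cross-site genetic
#' correlations (weak genotype-by-environment interaction), ordinal pest
#' scores, and biallelic SNP dosages with minor-allele frequencies down to
#' 0.01 and missing calls.
#'
#' @param n_families number of OP families (genotyped mothers) used.
#' @param mothers_per_provenance candidate mothers per provenance.
#' @param n_provenances number of provenances (genetic groups).
#' @param offspring_per_family_per_site trees per family at each site.
#' @param sites character vector of site labels.
#' @param n_snps number of simulated biallelic SNPs.
#' @param maf_range founder allele-frequency range, within (0, 0.5].
#' @param n_traits number of traits.
#' @param trait_names optional trait labels (length `n_traits`).
#' @param h2 per-trait, per-site narrow-sense heritability matrix
#'   (`n_traits` x `length(sites)`), entries in `[0, 1)`.
#' @param genetic_corr trait x trait additive genetic correlation matrix.
#' @param cross_site_corr site x site additive genetic correlation matrix
#'   (shared across traits).
#' @param rep_var,set_var variance of replication and set-within-replication
#'   effects as fractions of the within-design phenotypic variance.
#' @param prov_var variance of provenance (genetic-group) means.
#' @param missing_rate completely-at-random SNP missingness rate, in
#'   `[0, 0.3]`.
#' @param n_reps replications per site; `n_sets` sets nested in each.
#' @param n_sets sets per replication.
#' @param mode `"causal"` draws `n_qtl` causal SNPs with multivariate-normal
#'   effects; `"infinitesimal"` draws breeding values from the pedigree.
#' @param n_qtl number of causal SNPs in `"causal"` mode.
#' @param ordinal_traits trait names emitted as 4-category ordinal scores.
#' @param seed integer seed; every simulator call is reproducible from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_families = 40L,
                       mothers_per_provenance = 8L,
                       n_provenances = 5L,
                       offspring_per_family_per_site = 10L,
                       sites = c("JUDY", "VIRG", "SWAN", "TIME"),
                       n_snps = 5000L,
                       maf_range = c(0.01, 0.5),
                       n_traits = 13L,
                       trait_names = NULL,
                       h2 = NULL,
                       genetic_corr = NULL,
                       cross_site_corr = NULL,
                       rep_var = 0.05,
                       set_var = 0.05,
                       prov_var = 0.02,
                       missing_rate = 0.15,
                       n_reps = 5L,
                       n_sets = 7L,
                       mode = c("causal", "infinitesimal"),
                       n_qtl = 300L,
                       ordinal_traits = character(),
                       seed = 1L) {
  mode <- match.arg(mode)
  S <- length(sites)
  if (is.null(trait_names)) {
    trait_names <- if (n_traits == 13L) .default_trait_names else
      paste0("T", seq_len(n_traits))
  }
  if (length(trait_names) != n_traits)
    .err("trait_names must have length n_traits = %d", n_traits)
  if (is.null(h2)) {
    h2 <- if (n_traits == 13L && S == 4L) .default_h2() else
      matrix(0.4, n_traits, S)
  }
  h2 <- as.matrix(h2)
  if (!all(dim(h2) == c(n_traits, S)))
    .err("h2 must be a %d x %d matrix (traits x sites)", n_traits, S)
  if (any(h2 < 0) || any(h2 > 1)) .err("h2 entries must lie in [0, 1]")
  if (any(h2 > 0.999))
    .err("h2 = 1 implies a zero residual variance and is not supported")
  dimnames(h2) <- list(trait_names, sites)
  if (is.null(genetic_corr)) {
    genetic_corr <- if (n_traits == 13L) .default_genetic_corr() else
      diag(n_traits)
  }
  if (is.null(cross_site_corr)) {
    cross_site_corr <- if (S == 4L) .default_cross_site_corr() else diag(S)
  }
  genetic_corr <- .check_corr(as.matrix(genetic_corr), "genetic_corr")
  cross_site_corr <- .check_corr(as.matrix(cross_site_corr),
                                 "cross_site_corr")
  dimnames(genetic_corr) <- list(trait_names, trait_names)
  dimnames(cross_site_corr) <- list(sites, sites)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    .err("maf_range must be an increasing pair within (0, 0.5]")
  if (missing_rate < 0 || missing_rate > 0.3)
    .err("missing_rate must lie in [0, 0.3]")
  if (rep_var < 0 || set_var < 0 || prov_var < 0)
    .err("variance fractions must be non-negative")
  if (n_families > mothers_per_provenance * n_provenances)
    .err("n_families exceeds the available mothers (%d)",
         mothers_per_provenance * n_provenances)
  if (!all(ordinal_traits %in% trait_names))
    .err("ordinal_traits must be a subset of trait_names")
  structure(list(
    n_families = as.integer(n_families),
    mothers_per_provenance = as.integer(mothers_per_provenance),
    n_provenances = as.integer(n_provenances),
    offspring_per_family_per_site = as.integer(offspring_per_family_per_site),
    sites = sites, n_snps = as.integer(n_snps), maf_range = maf_range,
    n_traits = as.integer(n_traits), trait_names = trait_names, h2 = h2,
    genetic_corr = genetic_corr, cross_site_corr = cross_site_corr,
    rep_var = rep_var, set_var = set_var, prov_var = prov_var,
    missing_rate = missing_rate, n_reps = as.integer(n_reps),
    n_sets = as.integer(n_sets), mode = mode, n_qtl = as.integer(n_qtl),
    ordinal_traits = ordinal_traits, seed = as.integer(seed)),
    class = "sim_config")
}

.default_trait_names <- c("HT", "DBH", "WGR", "WD", "d13C", "MPB",
                          "a_pinene", "b_pinene", "myrcene", "limonene",
                          "b_phellandrene", "terpinolene",
                          "total_monoterpenes")

# per-site heritabilities spanning the realistic 0.0-0.8 range for growth,
# wood, pest, drought and monoterpene traits in interior lodgepole pine
.default_h2 <- function() {
  matrix(c(
    0.767, 0.503, 0.616, 0.432,   # HT
    0.495, 0.464, 0.186, 0.091,   # DBH
    0.465, 0.399, 0.648, 0.678,   # WGR
    0.617, 0.293, 0.203, 0.576,   # WD
    0.537, 0.423, 0.638, 0.434,   # d13C
    0.140, 0.651, 0.353, 0.013,   # MPB
    0.681, 0.355, 0.317, 0.503,   # a_pinene
    0.298, 0.491, 0.686, 0.547,   # b_pinene
    0.376, 0.281, 0.237, 0.374,   # myrcene
    0.523, 0.613, 0.495, 0.200,   # limonene
    0.437, 0.671, 0.795, 0.661,   # b_phellandrene
    0.233, 0.566, 0.373, 0.547,   # terpinolene
    0.266, 0.326, 0.256, 0.247),  # total_monoterpenes
    nrow = 13, byrow = TRUE)
}

# moderate positive within-block correlations (growth pair, monoterpene
# block), weak negative pest-vs-monoterpene structure, near-independent d13C
.default_genetic_corr <- function() {
  tn <- .default_trait_names
  R <- diag(13)
  dimnames(R) <- list(tn, tn)
  set_r <- function(a, b, r) {
    R[a, b] <<- r; R[b, a] <<- r
  }
  set_r("HT", "DBH", 0.70)
  mono <- tn[7:13]
  for (i in seq_along(mono)) for (j in seq_along(mono))
    if (i < j) set_r(mono[i], mono[j], 0.50)
  for (m in mono) {
    set_r("WGR", m, -0.20)
    set_r("MPB", m, -0.30)
  }
  set_r("MPB", "limonene", -0.55)
  set_r("HT", "MPB", 0.30); set_r("DBH", "MPB", 0.30)
  set_r("HT", "WGR", -0.20); set_r("DBH", "WGR", -0.15)
  set_r("HT", "myrcene", 0.35); set_r("DBH", "myrcene", 0.35)
  for (m in setdiff(tn, "d13C")) set_r("d13C", m, 0.08)
  set_r("WD", "HT", 0.10); set_r("WD", "DBH", 0.10)
  .check_corr(R, "default genetic_corr")
}

# strong cross-site genetic correlations (low GxE), weakest for the
# fire-disturbed site pairings
.default_cross_site_corr <- function() {
  s <- c("JUDY", "VIRG", "SWAN", "TIME")
  R <- matrix(0.70, 4, 4, dimnames = list(s, s))
  diag(R) <- 1
  R["JUDY", "VIRG"] <- R["VIRG", "JUDY"] <- 0.48
  R["JUDY", "TIME"] <- R["TIME", "JUDY"] <- 0.58
  .check_corr(R, "default cross_site_corr")
}

#' Simulate OP pedigree and Mendelian SNP genotypes
#'
#' Founder genotypes are drawn in Hardy-Weinberg proportions with per-SNP
#' allele frequencies uniform on `maf_range`. Each OP family has a known
#' mother; the pollen parent of every offspring is drawn uniformly from the
#' same-provenance founders (hidden relatedness through the pollen pool).
#' Offspring dosages follow Mendelian transmission; missing calls are applied
#' completely at random to the offspring matrix.
#'
#' @param cfg a [sim_config()].
#' @param one_father_per_family if `TRUE`, all offspring of a family share a
#'   single pollen parent (full-sib families; used for pedigree checks).
#' @return list with `geno` (a [genotype_matrix()] for the offspring, with the
#'   complete pre-missingness dosages in `attr(, "complete")` and founder
#'   allele frequencies in `attr(, "founder_freq")`), `pedigree` (data frame
#'   `id, mother, father, generation, provenance`), and `founder_geno`.
#' @export
simulate_genotypes <- function(cfg, one_father_per_family = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.sub_seed(cfg$seed, "genotypes"))
  m <- cfg$n_snps
  p0 <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  prov_names <- paste0("P", seq_len(cfg$n_provenances))
  # founders: mothers plus an equally sized pollen-donor pool per provenance
  n_per_prov <- 2L * cfg$mothers_per_provenance
  n_found <- n_per_prov * cfg$n_provenances
  founder_prov <- rep(prov_names, each = n_per_prov)
  founder_ids <- paste0("F", seq_len(n_found))
  Gf <- matrix(rbinom(n_found * m, 2L, rep(p0, each = n_found)),
               nrow = n_found, ncol = m)
  rownames(Gf) <- founder_ids
  snp_ids <- paste0("snp", seq_len(m))
  colnames(Gf) <- snp_ids
  # mothers: first mothers_per_provenance founders of each provenance,
  # drawn round-robin across provenances until n_families is reached
  mother_mat <- vapply(prov_names, function(p)
    head(founder_ids[founder_prov == p], cfg$mothers_per_provenance),
    character(cfg$mothers_per_provenance))
  mothers <- as.vector(t(mother_mat))[seq_len(cfg$n_families)]
  n_off_fam <- cfg$offspring_per_family_per_site * length(cfg$sites)
  n_off <- cfg$n_families * n_off_fam
  off_ids <- paste0("T", seq_len(n_off))
  off_mother <- rep(mothers, each = n_off_fam)
  off_prov <- founder_prov[match(off_mother, founder_ids)]
  # pollen parents: uniform over same-provenance founders, mother excluded
  off_father <- character(n_off)
  fam_father <- setNames(rep(NA_character_, cfg$n_families), mothers)
  for (prov in prov_names) {
    pool <- founder_ids[founder_prov == prov]
    idx <- which(off_prov == prov)
    if (!length(idx)) next
    if (one_father_per_family) {
      for (mo in unique(off_mother[idx])) {
        f <- sample(setdiff(pool, mo), 1L)
        fam_father[mo] <- f
        off_father[idx][off_mother[idx] == mo] <- f
      }
    } else {
      for (i in idx) {
        repeat {
          f <- pool[sample.int(length(pool), 1L)]
          if (f != off_mother[i]) break
        }
        off_father[i] <- f
      }
    }
  }
  # Mendelian transmission, one offspring at a time (vectorized over SNPs)
  Go <- matrix(0L, n_off, m, dimnames = list(off_ids, snp_ids))
  for (i in seq_len(n_off)) {
    pm <- Gf[off_mother[i], ] / 2
    pf <- Gf[off_father[i], ] / 2
    Go[i, ] <- rbinom(m, 1L, pm) + rbinom(m, 1L, pf)
  }
  complete <- Go
  if (cfg$missing_rate > 0) {
    drop <- matrix(runif(n_off * m) < cfg$missing_rate, n_off, m)
    Go[drop] <- NA_integer_
  }
  ped <- data.frame(
    id = c(founder_ids, off_ids),
    mother = c(rep("0", n_found), off_mother),
    father = c(rep("0", n_found), off_father),
    generation = c(rep(0L, n_found), rep(1L, n_off)),
    provenance = c(founder_prov, off_prov),
    stringsAsFactors = FALSE)
  geno <- genotype_matrix(Go)
  attr(geno, "complete") <- complete
  attr(geno, "founder_freq") <- p0
  list(geno = geno, pedigree = ped,
       founder_geno = genotype_matrix(Gf))
}

#' Simulate multi-site, multi-trait phenotypes with known ground truth
#'
#' Breeding values carry a (trait x site) additive covariance equal to the
#' Kronecker combination of the trait and cross-site genetic correlation
#' matrices, scaled so that each trait-site additive variance equals its
#' target heritability on a unit within-design phenotypic variance. In
#' `"causal"` mode effects load on `n_qtl` shared causal SNPs (pleiotropy via
#' correlated per-QTL effect vectors); in `"infinitesimal"` mode breeding
#' values descend through the pedigree by Mendelian sampling. Provenance
#' means, replication and set-within-replication effects and residuals are
#' added on top; the realized additive variance is rescaled to the target so
#' that stated heritabilities are exact in the simulated population.
#'
#' @param cfg a [sim_config()].
#' @param geno,ped output of [simulate_genotypes()] (`geno` and `pedigree`).
#' @return A phenotype data frame (one row per tree) with design columns
#'   `tree, mother, father, provenance, site, rep, set` and one column per
#'   trait; ordinal traits are integer scores 1-4. Ground-truth parameters
#'   (breeding values, variance components, causal SNPs, design effects) are
#'   stored in `attr(, "truth")`.
#' @export
simulate_phenotypes <- function(cfg, geno, ped) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.sub_seed(cfg$seed, "phenotypes"))
  t <- cfg$n_traits; S <- length(cfg$sites)
  off <- ped[ped$generation == 1L, ]
  n <- nrow(off)
  if (!all(off$id == rownames(geno$dosage)))
    .err("pedigree offspring and genotype rows are inconsistent")
  # (trait, site) covariance: Kronecker of correlations, scaled by sqrt(h2)
  Cts <- kronecker(cfg$genetic_corr, cfg$cross_site_corr)
  sds <- sqrt(as.vector(t(cfg$h2)))          # index = (trait-1)*S + site
  Sig <- Cts * tcrossprod(sds)
  Sig <- .clip_psd(Sig)$S
  q <- t * S
  if (cfg$mode == "causal") {
    W <- attr(geno, "complete")
    if (is.null(W)) W <- geno$dosage
    qtl <- sort(sample.int(ncol(W), min(cfg$n_qtl, ncol(W))))
    Wq <- scale(W[, qtl, drop = FALSE], center = TRUE, scale = FALSE)
    L <- .chol_psd(Sig)
    beta <- matrix(rnorm(length(qtl) * q), length(qtl), q) %*% t(L) /
      sqrt(length(qtl))
    bv <- Wq %*% beta                         # n x (t*S)
  } else {
    qtl <- integer()
    L <- .chol_psd(Sig)
    founders <- ped$id[ped$generation == 0L]
    bvf <- matrix(rnorm(length(founders) * q), length(founders), q) %*% t(L)
    rownames(bvf) <- founders
    Lm <- .chol_psd(Sig / 2)
    mend <- matrix(rnorm(n * q), n, q) %*% t(Lm)
    bv <- 0.5 * (bvf[off$mother, , drop = FALSE] +
                 bvf[off$father, , drop = FALSE]) + mend
  }
  # rescale realized additive SDs to the exact targets
  for (k in seq_len(q)) {
    sk <- sd(bv[, k])
    bv[, k] <- if (sds[k] == 0 || sk < 1e-12) 0 else bv[, k] * sds[k] / sk
  }
  rownames(bv) <- off$id
  # field layout: each family contributes offspring at every site
  site <- rep(rep(cfg$sites, each = cfg$offspring_per_family_per_site),
              times = cfg$n_families)
  rep_f <- integer(n); set_f <- integer(n)
  for (s in cfg$sites) {
    idx <- which(site == s)
    rep_f[idx] <- sample(rep_len(seq_len(cfg$n_reps), length(idx)))
    for (r in seq_len(cfg$n_reps)) {
      j <- idx[rep_f[idx] == r]
      set_f[j] <- sample(rep_len(seq_len(cfg$n_sets), length(j)))
    }
  }
  prov_means <- matrix(rnorm(cfg$n_provenances * t, 0, sqrt(cfg$prov_var)),
                       cfg$n_provenances, t,
                       dimnames = list(paste0("P", seq_len(cfg$n_provenances)),
                                       cfg$trait_names))
  rep_eff <- array(rnorm(S * cfg$n_reps * t, 0, sqrt(cfg$rep_var)),
                   dim = c(S, cfg$n_reps, t))
  set_eff <- array(rnorm(S * cfg$n_reps * cfg$n_sets * t, 0,
                         sqrt(cfg$set_var)),
                   dim = c(S, cfg$n_reps, cfg$n_sets, t))
  Y <- matrix(NA_real_, n, t, dimnames = list(off$id, cfg$trait_names))
  si <- match(site, cfg$sites)
  for (j in seq_len(t)) {
    a <- bv[cbind(seq_len(n), (j - 1L) * S + si)]
    e <- rnorm(n, 0, sqrt(pmax(1 - cfg$h2[j, si], 0)))
    Y[, j] <- prov_means[off$provenance, j] +
      rep_eff[cbind(si, rep_f, j)] +
      set_eff[cbind(si, rep_f, set_f, j)] + a + e
  }
  pheno <- data.frame(tree = off$id, mother = off$mother,
                      father = off$father, provenance = off$provenance,
                      site = site, rep = rep_f, set = set_f,
                      stringsAsFactors = FALSE)
  truth_scores <- list()
  for (tr in cfg$ordinal_traits) {
    cont <- Y[, tr]
    cuts <- quantile(cont, c(0.45, 0.75, 0.92))  # skewed pest-score classes
    truth_scores[[tr]] <- cont
    Y[, tr] <- as.integer(cut(cont, c(-Inf, cuts, Inf), labels = FALSE))
  }
  pheno <- cbind(pheno, as.data.frame(Y))
  attr(pheno, "truth") <- list(
    bv = bv, bv_at_site = vapply(seq_len(t), function(j)
      bv[cbind(seq_len(n), (j - 1L) * S + si)], numeric(n)),
    h2 = cfg$h2, genetic_corr = cfg$genetic_corr,
    cross_site_corr = cfg$cross_site_corr, qtl = qtl,
    prov_means = prov_means, latent_ordinal = truth_scores,
    trait_names = cfg$trait_names, sites = cfg$sites)
  pheno
}

# pivoted Cholesky-style factor for a PSD matrix (may be rank deficient)
.chol_psd <- function(S) {
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  ev$vectors %*% diag(sqrt(vals), length(vals))
}

#' Canned simulation fixtures
#'
#' Deterministic, seeded test beds: `"tiny"` (30 trees x 50 SNPs, one site,
#' two traits) for linear-algebra oracles; `"null"` (no genetic effects,
#' 2000 SNPs) for GWAS type-I-error calibration; `"pleiotropic"` (two traits
#' sharing causal SNPs, genetic correlation 0.8) for multi-trait power
#' checks; `"paper_like"` (4 sites, 40 OP families, ~1600 trees, 5000 SNPs,
#' 13 traits) for end-to-end runs.
#'
#' @param kind one of `"tiny"`, `"null"`, `"pleiotropic"`, `"paper_like"`.
#' @param seed integer seed.
#' @return list with `geno`, `pheno`, `pedigree`, and the `cfg` used.
#' @export
make_fixture <- function(kind = c("tiny", "null", "pleiotropic",
                                  "paper_like"), seed = 1L) {
  kind <- match.arg(kind)
  cfg <- switch(kind,
    tiny = sim_config(
      n_families = 6L, mothers_per_provenance = 4L, n_provenances = 2L,
      offspring_per_family_per_site = 5L, sites = "S1", n_snps = 50L,
      n_traits = 2L, h2 = matrix(c(0.5, 0.3), 2, 1),
      genetic_corr = matrix(c(1, 0.5, 0.5, 1), 2),
      cross_site_corr = matrix(1, 1, 1), missing_rate = 0,
      n_reps = 2L, n_sets = 2L, n_qtl = 20L, seed = seed),
    null = sim_config(
      n_families = 30L, mothers_per_provenance = 10L, n_provenances = 3L,
      offspring_per_family_per_site = 10L, sites = "S1", n_snps = 2000L,
      n_traits = 2L, h2 = matrix(0, 2, 1),
      genetic_corr = diag(2), cross_site_corr = matrix(1, 1, 1),
      missing_rate = 0, n_reps = 3L, n_sets = 3L, seed = seed),
    pleiotropic = sim_config(
      n_families = 30L, mothers_per_provenance = 10L, n_provenances = 3L,
      offspring_per_family_per_site = 10L, sites = "S1", n_snps = 1000L,
      n_traits = 2L, h2 = matrix(c(0.5, 0.4), 2, 1),
      genetic_corr = matrix(c(1, 0.8, 0.8, 1), 2),
      cross_site_corr = matrix(1, 1, 1), missing_rate = 0,
      n_reps = 3L, n_sets = 3L, n_qtl = 20L, seed = seed),
    paper_like = sim_config(ordinal_traits = c("WGR", "MPB"), seed = seed))
  sim <- simulate_genotypes(cfg)
  pheno <- simulate_phenotypes(cfg, sim$geno, sim$pedigree)
  list(geno = sim$geno, pheno = pheno, pedigree = sim$pedigree, cfg = cfg)
}
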