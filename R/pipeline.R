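#' Pipeline run configuration
#'
#' Builds (and validates) the configuration driving [run_pipeline()]:
#' either a simulation fixture or paths to genotype/phenotype/pedigree
#' files, SNP filter settings, GWAS and cross-validation settings, and the
#' master seed from which every stochastic stage derives its substream.
#' A YAML file with the same field names can be loaded via `yaml_path`;
#' explicit arguments override its values.
#'
#' @param out_dir output directory for all artifacts.
#' @param seed master seed.
#' @param fixture simulation fixture kind (see [make_fixture()]), or `NULL`
#'   when `geno_path`/`pheno_path` are given.
#' @param geno_path,pheno_path,pedigree_path optional input files
#'   (internal dialects; genotypes may be PLINK `.raw` via `geno_dialect`).
#' @param geno_dialect `"tsv"` or `"raw"`.
#' @param max_missing,min_maf,blend_alpha SNP filter and GRM settings.
#' @param ordinal_traits traits to normal-score before analysis (fixture
#'   default: its own ordinal traits).
#' @param gwas_traits traits scanned in the GWAS stage (default: all).
#' @param gwas_alpha significance level for Bonferroni control.
#' @param cv_traits traits carried into cross-validation (default: first
#'   two GWAS traits; the multi-trait engines need at least two).
#' @param cv_models prediction engines for the CV stage.
#' @param cv_folds,cv_reps CV design.
#' @param chain a [chain_config()] for the samplers.
#' @param cross_site_traits traits for the cross-site genetic-correlation
#'   stage (site-split REML); `NULL` disables the stage.
#' @param cross_site_n_per_site per-site subsample for that stage.
#' @param write_inputs also write the simulated genotype/phenotype/pedigree
#'   inputs and GRM as text artifacts.
#' @param yaml_path optional YAML file of defaults.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, fixture = "paper_like",
                       geno_path = NULL, pheno_path = NULL,
                       pedigree_path = NULL, geno_dialect = "tsv",
                       max_missing = 0.30, min_maf = 0.01,
                       blend_alpha = 0.01, ordinal_traits = NULL,
                       gwas_traits = NULL, gwas_alpha = 0.05,
                       cv_traits = NULL,
                       cv_models = c("GBLUP", "RKHS", "MT-GBLUP", "MT-RKHS"),
                       cv_folds = 5L, cv_reps = 2L,
                       chain = chain_config(1000L, 200L, 5L),
                       cross_site_traits = NULL,
                       cross_site_n_per_site = 50L,
                       write_inputs = FALSE, yaml_path = NULL) {
  cfg <- as.list(environment())
  cfg$yaml_path <- NULL
  if (!is.null(yaml_path)) {
    if (!file.exists(yaml_path)) .err("config file not found: %s", yaml_path)
    yml <- yaml::read_yaml(yaml_path)
    known <- intersect(names(yml), names(cfg))
    supplied <- names(match.call())[-1]
    for (nm in setdiff(known, supplied)) cfg[[nm]] <- yml[[nm]]
  }
  if (is.null(cfg$fixture) &&
      (is.null(cfg$geno_path) || is.null(cfg$pheno_path)))
    .err("either a fixture or genotype+phenotype paths must be given")
  for (p in c("geno_path", "pheno_path", "pedigree_path"))
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      .err("%s does not exist: %s", p, cfg[[p]])
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data simulation (or loading), SNP filtering +
#' imputation + GRM construction, ordinal-trait normal scoring, per-site
#' single-trait REML fits with design-effect adjustment and
#' standardization, the across-trait multi-trait REML fit (heritabilities,
#' genetic correlations, reference h2), optional cross-site site-split
#' fits, single- and multi-trait GWAS with Bonferroni control, replicated
#' cross-validation of the prediction engines, and the ANOVA/Tukey method
#' comparison. Every stage writes text artifacts under `out_dir` and is
#' recorded (with timing and output hashes) in `manifest.json`.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with the manifest and key in-memory results.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, started = format(Sys.time()),
                   r_version = as.character(getRversion()),
                   package_version =
                     as.character(utils::packageVersion("pinegp")),
                   stages = list())
  t_all <- proc.time()[3]
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(force(expr), error = function(e)
      .err("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[3] - t0, 2))
    res
  }
  art <- function(name) file.path(cfg$out_dir, name)
  results <- list()

  dat <- stage("inputs", {
    if (!is.null(cfg$fixture)) {
      fx <- make_fixture(cfg$fixture, seed = cfg$seed)
      if (is.null(cfg$ordinal_traits))
        cfg$ordinal_traits <- fx$cfg$ordinal_traits
      if (isTRUE(cfg$write_inputs)) {
        write_genotypes(fx$geno, art("genotypes.tsv"))
        write_phenotypes(fx$pheno, art("phenotypes.csv"))
        write_pedigree(fx$pedigree, art("pedigree.txt"))
        tr <- attr(fx$pheno, "truth")
        if (!is.null(tr)) write_truth(tr, art("truth.json"))
      }
      fx
    } else {
      list(geno = read_genotypes(cfg$geno_path, cfg$geno_dialect),
           pheno = read_phenotypes(cfg$pheno_path),
           pedigree = if (!is.null(cfg$pedigree_path))
             read_pedigree(cfg$pedigree_path) else NULL)
    }
  })
  pheno <- dat$pheno

  grm_parts <- stage("grm", {
    filt <- filter_snps(dat$geno, cfg$max_missing, cfg$min_maf,
                        quiet = TRUE)
    imp <- impute_mean(filt)
    g <- compute_grm(imp, blend_alpha = cfg$blend_alpha)
    if (isTRUE(cfg$write_inputs)) write_grm(g, art("grm.tsv"))
    list(geno = imp, grm = g)
  })
  geno <- grm_parts$geno; grm <- grm_parts$grm

  pheno <- stage("normal_scores", {
    for (tr in cfg$ordinal_traits %||% character()) {
      for (s in unique(pheno$site)) {
        r <- pheno$site == s
        pheno[[tr]][r] <- normal_score_transform(pheno[[tr]][r])
      }
    }
    pheno
  })

  design_cols <- c("tree", "mother", "father", "provenance", "site", "rep",
                   "set")
  traits <- setdiff(names(pheno), design_cols)

  adj <- stage("st_fits_adjust", {
    a <- adjust_phenotypes(pheno, grm, traits = traits, se = FALSE)
    fits <- attr(a, "st_fits")
    h2tab <- do.call(rbind, lapply(names(fits), function(key) {
      parts <- strsplit(key, "@", fixed = TRUE)[[1]]
      data.frame(trait = parts[1], site = parts[2],
                 h2 = fits[[key]]$h2,
                 sigma2_a = unname(fits[[key]]$varcomp$sigma2["sigma2_a"]),
                 sigma2_e = unname(fits[[key]]$varcomp$sigma2["sigma2_e"]),
                 converged = fits[[key]]$varcomp$converged)
    }))
    write.table(h2tab, art("heritability_by_site.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    results$h2_by_site <- h2tab
    write_phenotypes(a, art("phenotypes_adjusted.csv"))
    a
  })

  mt_fit <- stage("mt_fit", {
    fit <- fit_mt_gblup(adj, grm, responses = traits, fixed = "provenance",
                        se = FALSE)
    h2 <- estimate_h2(fit)
    write.table(h2, art("heritability_mt.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    rg <- stats::cov2cor(fit$Sigma_a)
    write.table(data.frame(trait = rownames(rg), round(rg, 4)),
                art("genetic_correlations.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    results$h2_ref <- setNames(h2$h2, h2$trait)
    fit
  })

  if (!is.null(cfg$cross_site_traits) && length(unique(pheno$site)) > 1) {
    stage("cross_site", {
      tab <- list()
      set.seed(.sub_seed(cfg$seed, "cross-site"))
      keep <- unlist(lapply(split(seq_len(nrow(adj)), adj$site),
                            function(ix) if (length(ix) >
                                             cfg$cross_site_n_per_site)
                              sample(ix, cfg$cross_site_n_per_site) else ix))
      sub <- adj[sort(keep), ]
      for (tr in cfg$cross_site_traits) {
        fit <- fit_mt_gblup(sub, grm, trait = tr, site_split = TRUE,
                            fixed = NULL, se = FALSE, max_iter = 150L)
        rg <- stats::cov2cor(fit$Sigma_a)
        sites <- fit$responses
        for (i in seq_along(sites)) for (j in seq_along(sites))
          if (i < j)
            tab[[length(tab) + 1]] <- data.frame(
              trait = tr, site_i = sites[i], site_j = sites[j],
              r_a = rg[i, j])
      }
      tab <- do.call(rbind, tab)
      write.table(tab, art("cross_site_correlations.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      results$cross_site <- tab
    })
  }

  gw <- stage("gwas", {
    gtr <- cfg$gwas_traits %||% traits
    st_fits <- list()
    Geig <- mt_fit$Geig
    for (tr in gtr)
      st_fits[[tr]] <- fit_st_gblup(adj, grm, tr, fixed = NULL,
                                    design = NULL, se = FALSE, Geig = Geig)
    cache <- gwas_cache(mt_fit, grm, geno)
    st_tabs <- lapply(st_fits, gwas_scan, grm = grm, geno = geno,
                      alpha = cfg$gwas_alpha, cache = cache)
    mt_tabs <- gwas_scan(mt_fit, grm, geno, alpha = cfg$gwas_alpha,
                         cache = cache)[gtr]
    summ <- association_summary(st_tabs, mt_tabs)
    for (tr in gtr) {
      write.table(st_tabs[[tr]], art(sprintf("gwas_st_%s.tsv", tr)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(mt_tabs[[tr]], art(sprintf("gwas_mt_%s.tsv", tr)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(summ$counts, art("gwas_counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(trait = rownames(summ$shared), summ$shared),
                art("gwas_shared_matrix.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(summ$qq, art("gwas_qq.csv"), sep = ",", quote = FALSE,
                row.names = FALSE)
    write.table(summ$manhattan, art("gwas_manhattan.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
    results$gwas_counts <- summ$counts
    summ
  })

  cvtab <- stage("cv", {
    ctr <- cfg$cv_traits %||% head(cfg$gwas_traits %||% traits, 2)
    cv <- run_cv(adj, geno, grm, traits = ctr, models = cfg$cv_models,
                 k = cfg$cv_folds, n_reps = cfg$cv_reps, seed = cfg$seed,
                 chain = cfg$chain, h2_ref = results$h2_ref[ctr])
    write.table(cv, art("cv_records.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    results$cv <- cv
    cv
  })

  stage("compare", {
    cmp <- compare_methods(cvtab, response = "accuracy",
                           alpha = cfg$gwas_alpha)
    lett <- data.frame(model = names(cmp$pooled$letters),
                       letters = unname(unlist(cmp$pooled$letters)))
    write.table(lett, art("method_letters.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(cmp$replicate_means, art("method_replicate_means.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    results$compare <- cmp
    cmp
  })

  manifest$elapsed_seconds <- round(proc.time()[3] - t_all, 2)
  arts <- list.files(cfg$out_dir, full.names = TRUE)
  arts <- arts[!grepl("manifest.json$", arts)]
  manifest$artifacts <- lapply(setNames(basename(arts), basename(arts)),
                               function(x) unname(tools::md5sum(
                                 file.path(cfg$out_dir, x))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(list(manifest = manifest), results))
}
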