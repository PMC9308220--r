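#' Replicated k-fold cross-validation schedule
#'
#' Per replicate, a random near-equal k-way partition of the ids,
#' optionally stratified (each stratum split into k parts so folds are
#' balanced across, e.g., sites).
#'
#' @param ids vector of individual ids (or indices).
#' @param k number of folds.
#' @param n_reps independent replicates of the whole partition.
#' @param seed partition seed.
#' @param strata optional stratification factor aligned with `ids`.
#' @return data frame with columns `replicate`, `fold`, `id`.
#' @export
make_folds <- function(ids, k = 10L, n_reps = 5L, seed = 1L,
                       strata = NULL) {
  n <- length(ids)
  if (k > n) .err("more folds (%d) than ids (%d)", k, n)
  if (!is.null(strata) && length(strata) != n)
    .err("strata must align with ids")
  set.seed(.sub_seed(seed, "folds"))
  out <- list()
  for (r in seq_len(n_reps)) {
    fold <- integer(n)
    if (is.null(strata)) {
      fold <- sample(rep_len(seq_len(k), n))
    } else {
      for (s in unique(strata)) {
        idx <- which(strata == s)
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    }
    out[[r]] <- data.frame(replicate = r, fold = fold, id = ids)
  }
  do.call(rbind, out)
}

#' Prediction accuracy from predictive ability
#'
#' Accuracy = predictive ability (Pearson correlation between predictions
#' and adjusted phenotypes) divided by the square root of the trait's
#' narrow-sense heritability (conventionally taken from the full-data
#' multi-trait GBLUP fit).
#'
#' @param pa predictive ability.
#' @param h2_ref reference heritability in (0, 1].
#' @export
accuracy_from_pa <- function(pa, h2_ref) {
  if (any(h2_ref <= 0) || any(h2_ref > 1))
    .err("h2_ref must lie in (0, 1]")
  pa / sqrt(h2_ref)
}

#' Prediction bias (dispersion) slope
#'
#' OLS regression coefficient of the observed adjusted phenotype on the
#' prediction; 1 = no bias, > 1 deflated, < 1 inflated predictions.
#'
#' @param observed_adjusted observed (adjusted) phenotypes.
#' @param predicted predictions.
#' @export
bias_slope <- function(observed_adjusted, predicted) {
  ok <- complete.cases(observed_adjusted, predicted)
  if (sum(ok) < 3) .err("at least 3 observation/prediction pairs needed")
  vpr <- var(predicted[ok])
  if (vpr <= 0) .err("zero variance of predictions: slope undefined")
  cov(observed_adjusted[ok], predicted[ok]) / vpr
}

.st_models <- c("GBLUP", "RKHS", "BRR", "BayesC", "BLasso")
.mt_models <- c("MT-GBLUP", "MT-RKHS")

#' Trait-assisted cross-validation of genomic prediction engines
#'
#' For every trait x model x fold x replicate: trains on the remaining
#' folds and predicts the validation trees, then records predictive ability
#' (Pearson r against the adjusted phenotype), accuracy (predictive ability
#' over `sqrt(h2_ref)`) and the bias slope. Multi-trait models mask only the
#' focal trait of the validation trees (trait-assisted prediction).
#'
#' @param pheno_adj adjusted/standardized phenotype table
#'   (see [adjust_phenotypes()]); ordinal traits already normal-scored.
#' @param geno imputed [genotype_matrix()].
#' @param grm the matching [compute_grm()].
#' @param traits traits to evaluate.
#' @param models subset of
#'   `c("GBLUP","RKHS","BRR","BayesC","BLasso","MT-GBLUP","MT-RKHS")`.
#' @param k,n_reps folds and replicates.
#' @param seed master seed (folds and chains derive substreams from it).
#' @param chain a [chain_config()] for all samplers.
#' @param h2_ref optional named per-trait reference heritabilities; by
#'   default estimated once from the full-data multi-trait GBLUP REML fit
#'   (single-trait fit if only one trait is evaluated).
#' @param rkhs_h Gaussian bandwidth for the RKHS kernels.
#' @param strata stratification column for fold balance (default site).
#' @return data frame of CV records: `trait, model, fold, replicate,
#'   predictive_ability, accuracy, bias, n_validation`; the reference
#'   heritabilities are attached as `attr(, "h2_ref")`.
#' @export
run_cv <- function(pheno_adj, geno, grm, traits, models = .st_models,
                   k = 10L, n_reps = 5L, seed = 1L,
                   chain = chain_config(), h2_ref = NULL, rkhs_h = 0.5,
                   strata = "site") {
  bad <- setdiff(models, c(.st_models, .mt_models))
  if (length(bad)) .err("unknown model(s): %s", paste(bad, collapse = ", "))
  ids <- as.character(pheno_adj$tree)
  n <- length(ids)
  W <- NULL
  if (any(models %in% c("BRR", "BayesC", "BLasso")))
    W <- center_dosages(geno, grm)[ids, , drop = FALSE]
  Kg <- grm$G[ids, ids]
  Krk <- NULL
  if (any(models %in% c("RKHS", "MT-RKHS")))
    Krk <- build_kernel(geno$dosage[ids, , drop = FALSE],
                        kernel_spec("gaussian", h = rkhs_h))
  mt_wanted <- any(models %in% .mt_models)
  if (is.null(h2_ref)) {
    if (length(traits) >= 2) {
      ref_fit <- fit_mt_gblup(pheno_adj, grm, responses = traits,
                              fixed = NULL, se = FALSE)
      h2_ref <- setNames(estimate_h2(ref_fit)$h2, traits)
    } else {
      ref_fit <- fit_st_gblup(pheno_adj, grm, traits, fixed = NULL,
                              design = NULL, se = FALSE)
      h2_ref <- setNames(ref_fit$h2, traits)
    }
  }
  h2_ref <- pmax(pmin(h2_ref, 1), 1e-4)
  strat <- if (!is.null(strata) && strata %in% names(pheno_adj))
    pheno_adj[[strata]] else NULL
  sched <- make_folds(seq_len(n), k = k, n_reps = n_reps, seed = seed,
                      strata = strat)
  Ymat <- as.matrix(pheno_adj[, traits, drop = FALSE])
  rownames(Ymat) <- ids
  # one-time eigendecompositions of the full kernels for the MT samplers
  mt_eig <- list()
  if (any(models == "MT-GBLUP")) {
    eg <- eigen(Kg, symmetric = TRUE)
    mt_eig[["MT-GBLUP"]] <- list(values = pmax(eg$values, 1e-8),
                                 vectors = eg$vectors)
  }
  if (any(models == "MT-RKHS")) {
    eg <- eigen(Krk, symmetric = TRUE)
    mt_eig[["MT-RKHS"]] <- list(values = pmax(eg$values, 1e-8),
                                vectors = eg$vectors)
  }
  recs <- list()
  for (r in seq_len(n_reps)) {
    for (f in seq_len(k)) {
      val <- sched$id[sched$replicate == r & sched$fold == f]
      sub_seed <- .sub_seed(seed, sprintf("cv-%d-%d", r, f))
      ch <- chain; ch$seed <- sub_seed
      # per-fold training-set eigen caches, shared across traits
      fold_keig <- list()
      for (mod in models) {
        if (mod %in% .mt_models) {
          Kmat <- if (mod == "MT-GBLUP") Kg else Krk
          for (tr in traits) {
            Ymask <- Ymat
            Ymask[val, tr] <- NA
            fit <- fit_multitrait(Ymask, Kmat, ch, Keig = mt_eig[[mod]])
            pred <- fit$u[val, tr]
            recs[[length(recs) + 1]] <-
              .cv_record(tr, mod, f, r, Ymat[val, tr], pred, h2_ref[tr])
          }
        } else {
          for (tr in traits) {
            y <- Ymat[, tr]
            ytr <- y; ytr[val] <- NA
            if (mod %in% c("GBLUP", "RKHS") &&
                is.null(fold_keig[[mod]])) {
              obs <- which(!is.na(ytr))
              Kt <- if (mod == "GBLUP") Kg else Krk
              eg <- eigen(Kt[obs, obs], symmetric = TRUE)
              fold_keig[[mod]] <- list(values = pmax(eg$values, 1e-8),
                                       vectors = eg$vectors, obs = obs)
            }
            pred <- switch(mod,
              GBLUP = fit_kernel_regression(ytr, Kg, ch,
                                            Keig = fold_keig$GBLUP)$u[val],
              RKHS = fit_kernel_regression(ytr, Krk, ch,
                                           Keig = fold_keig$RKHS)$u[val],
              {
                tr_rows <- which(!is.na(ytr))
                mf <- switch(mod,
                  BRR = fit_brr(ytr[tr_rows], W[tr_rows, , drop = FALSE], ch),
                  BayesC = fit_bayesc(ytr[tr_rows],
                                      W[tr_rows, , drop = FALSE], ch),
                  BLasso = fit_blasso(ytr[tr_rows],
                                      W[tr_rows, , drop = FALSE], ch))
                predict(mf, W[val, , drop = FALSE])
              })
            recs[[length(recs) + 1]] <-
              .cv_record(tr, mod, f, r, y[val], pred, h2_ref[tr])
          }
        }
      }
    }
  }
  out <- do.call(rbind, recs)
  attr(out, "h2_ref") <- h2_ref
  out
}

.cv_record <- function(trait, model, fold, rep, obs, pred, h2) {
  ok <- complete.cases(obs, pred)
  if (sum(ok) < 3)
    return(NULL)
  pa <- suppressWarnings(cor(pred[ok], obs[ok]))
  bias <- if (var(pred[ok]) > 0) bias_slope(obs[ok], pred[ok]) else NA_real_
  data.frame(trait = trait, model = model, fold = fold, replicate = rep,
             predictive_ability = pa,
             accuracy = accuracy_from_pa(pa, h2), bias = bias,
             n_validation = sum(ok), stringsAsFactors = FALSE)
}

#' ANOVA and Tukey comparison of prediction methods
#'
#' Per trait (and pooled across traits), fits a fixed-effects linear model
#' `value ~ method + replicate` on the replicate means of the chosen CV
#' statistic, then runs Tukey's HSD multiple comparisons at level `alpha`
#' and reports compact letter groups (methods sharing a letter are not
#' significantly different).
#'
#' @param cv CV record table from [run_cv()].
#' @param response `"accuracy"` or `"bias"` (or `"predictive_ability"`).
#' @param alpha significance level.
#' @return list with `per_trait` (named list) and `pooled`; each element
#'   carries `anova` (the aov summary table), `tukey` (pairwise table) and
#'   `letters` (compact letter display).
#' @export
compare_methods <- function(cv, response = "accuracy", alpha = 0.05) {
  if (length(unique(cv$model)) < 2) .err("at least two methods required")
  if (length(unique(cv$replicate)) < 2) .err("at least two replicates required")
  # replicate means per trait x method
  agg <- aggregate(cv[[response]],
                   by = list(trait = cv$trait, model = cv$model,
                             replicate = cv$replicate),
                   FUN = mean, na.rm = TRUE)
  names(agg)[4] <- "value"
  one <- function(df) {
    df$method <- factor(df$model)
    df$block <- factor(df$replicate)
    fit <- aov(value ~ method + block, data = df)
    tk <- TukeyHSD(fit, which = "method", conf.level = 1 - alpha)$method
    glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(method = "Tukey"))
    letters <- multcomp::cld(glht_fit, level = alpha)$mcletters$Letters
    list(anova = summary(fit)[[1]], tukey = tk, letters = letters)
  }
  per_trait <- lapply(split(agg, agg$trait), one)
  pooled_df <- aggregate(agg$value,
                         by = list(model = agg$model,
                                   replicate = agg$replicate),
                         FUN = mean, na.rm = TRUE)
  names(pooled_df)[3] <- "value"
  pooled_df$trait <- "pooled"
  pooled <- one(pooled_df)
  list(per_trait = per_trait, pooled = pooled, replicate_means = agg)
}
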