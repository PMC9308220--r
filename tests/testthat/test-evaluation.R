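test_that("fold schedules partition ids with near-equal sizes", {
  s <- make_folds(1:100, k = 10, n_reps = 2, seed = 3)
  for (r in 1:2) {
    sub <- s[s$replicate == r, ]
    expect_setequal(sub$id, 1:100)
    expect_true(all(table(sub$fold) == 10))
  }
  s2 <- make_folds(1:101, k = 10, n_reps = 1, seed = 3)
  expect_equal(sort(as.integer(table(s2$fold))), c(rep(10, 9), 11))
  expect_identical(make_folds(1:50, 5, 2, seed = 9),
                   make_folds(1:50, 5, 2, seed = 9))
  expect_error(make_folds(1:5, k = 10), "folds")
  # stratified folds balance the strata
  strata <- rep(c("a", "b"), each = 50)
  s3 <- make_folds(1:100, k = 5, n_reps = 1, seed = 1, strata = strata)
  tab <- table(s3$fold, strata[s3$id])
  expect_true(all(tab == 10))
})

test_that("accuracy and bias follow their definitions", {
  expect_equal(accuracy_from_pa(0.5, 0.25), 1)
  expect_equal(accuracy_from_pa(0, 0.7), 0)
  expect_error(accuracy_from_pa(0.5, 0), "h2_ref")
  # relative gain arithmetic used in method comparisons
  gain <- 100 * (accuracy_from_pa(0.703, 1) - accuracy_from_pa(0.644, 1)) /
    accuracy_from_pa(0.644, 1)
  expect_equal(round(gain, 1), 9.2)
  # bias slope: identity, inverse scaling, brute-force cov/var oracle
  set.seed(4)
  obs <- rnorm(50)
  expect_equal(bias_slope(obs, obs), 1)
  expect_equal(bias_slope(obs, 0.5 * obs), 2)
  pred <- 0.8 * obs + rnorm(50, 0, 0.3)
  expect_equal(bias_slope(obs, pred), cov(obs, pred) / var(pred),
               tolerance = 1e-12)
  expect_equal(bias_slope(obs, pred),
               unname(coef(lm(obs ~ pred))[2]), tolerance = 1e-12)
  expect_error(bias_slope(obs, rep(1, 50)), "zero variance")
  expect_error(bias_slope(obs[1:2], pred[1:2]), "3 observation")
})

test_that("cross-validation records the expected statistics", {
  ms <- mid_setup()
  adj <- adjust_phenotypes(ms$pheno, ms$grm, se = FALSE)
  cv <- cached("cv-small", function()
    run_cv(adj, ms$geno, ms$grm, traits = c("T1", "T2"),
           models = c("GBLUP", "MT-GBLUP"), k = 3, n_reps = 2, seed = 5,
           chain = chain_config(600, 150, 3)))
  expect_setequal(unique(cv$model), c("GBLUP", "MT-GBLUP"))
  expect_equal(nrow(cv), 2 * 2 * 3 * 2)
  expect_true(all(cv$n_validation > 50))
  h2r <- attr(cv, "h2_ref")
  expect_equal(cv$accuracy, cv$predictive_ability / sqrt(h2r[cv$trait]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # folds partition: each tree validated once per replicate
  expect_true(all(is.finite(cv$predictive_ability)))
  expect_error(run_cv(adj, ms$geno, ms$grm, traits = "T1",
                      models = "Magic"), "unknown model")
})

test_that("method comparison matches a direct ANOVA/Tukey computation", {
  # engineered table: method C shifted far above A and B
  set.seed(8)
  tab <- expand.grid(trait = "t", model = c("A", "B", "C"),
                     fold = 1:4, replicate = 1:5,
                     stringsAsFactors = FALSE)
  tab$accuracy <- rnorm(nrow(tab), 0.5, 0.01) +
    ifelse(tab$model == "C", 0.3, 0)
  tab$bias <- 1
  cmp <- compare_methods(tab, response = "accuracy")
  lt <- cmp$pooled$letters
  expect_equal(lt[["A"]], lt[["B"]])
  expect_false(lt[["C"]] == lt[["A"]])
  # oracle: recompute the two-way ANOVA F by explicit sums of squares
  agg <- aggregate(accuracy ~ model + replicate, tab, mean)
  gm <- mean(agg$accuracy)
  ssm <- sum(tapply(agg$accuracy, agg$model,
                    function(x) length(x) * (mean(x) - gm)^2))
  ssb <- sum(tapply(agg$accuracy, agg$replicate,
                    function(x) length(x) * (mean(x) - gm)^2))
  sst <- sum((agg$accuracy - gm)^2)
  sse <- sst - ssm - ssb
  dfm <- 2; dfb <- 4; dfe <- nrow(agg) - 1 - dfm - dfb
  Fm <- (ssm / dfm) / (sse / dfe)
  expect_equal(cmp$pooled$anova["method", "F value"], Fm,
               tolerance = 1e-8)
  # Tukey q-based p-value for the A-B contrast
  tk <- cmp$pooled$tukey
  se2 <- sse / dfe
  qstat <- abs(diff(tapply(agg$accuracy, agg$model, mean)[c("A", "B")])) /
    sqrt(se2 / 5)
  p_ab <- ptukey(qstat, nmeans = 3, df = dfe, lower.tail = FALSE)
  expect_equal(tk["B-A", "p adj"], p_ab, tolerance = 1e-8,
               ignore_attr = TRUE)
  # degenerate guards
  expect_error(compare_methods(tab[tab$model == "A", ]), "two methods")
  expect_error(compare_methods(tab[tab$replicate == 1, ]),
               "two replicates")
  # identical methods share a single letter
  tab2 <- tab
  tab2$accuracy <- rep(rnorm(20, 0.5, 0.01),
                       times = tabulate(as.integer(interaction(
                         tab2$replicate, tab2$fold))))[seq_len(nrow(tab2))]
  tab2$accuracy <- 0.5 + as.numeric(tab2$replicate) / 100 +
    rnorm(nrow(tab2), 0, 1e-3)
  cmp2 <- compare_methods(tab2, response = "accuracy")
  expect_equal(length(unique(unlist(cmp2$pooled$letters))), 1)
})
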