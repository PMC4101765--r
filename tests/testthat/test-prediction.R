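test_that("stratified folds partition subjects with balanced classes", {
  y <- rep(c(1L, 0L), each = 20)
  folds <- stratified_kfold(y, k = 10, seed = 3)
  for (f in folds) {
    expect_equal(sum(y[f$test] == 1L), 2)
    expect_equal(sum(y[f$test] == 0L), 2)
    expect_setequal(c(f$train, f$test), seq_along(y))
  }
  expect_setequal(unlist(lapply(folds, `[[`, "test")), seq_along(y))
  expect_identical(folds, stratified_kfold(y, k = 10, seed = 3))
  # uneven sizes: per-fold class counts within 1 of proportionality
  y2 <- rep(c(1L, 0L), c(37, 53))
  folds2 <- stratified_kfold(y2, k = 10, seed = 3)
  n_case <- vapply(folds2, function(f) sum(y2[f$test] == 1L), integer(1))
  expect_true(all(abs(n_case - 3.7) < 1))
  expect_error(stratified_kfold(rep(c(1L, 0L), c(5, 50)), k = 10), "fewer")
})

test_that("auc_mann_whitney equals brute-force pair enumeration", {
  expect_equal(auc_mann_whitney(c(0.9, 0.7, 0.8, 0.6), c(1L, 1L, 0L, 0L)), 0.75)
  expect_equal(auc_mann_whitney(rep(0.3, 10), rep(c(1L, 0L), 5)), 0.5)
  expect_equal(auc_mann_whitney(c(5, 6, 1, 2), c(1L, 1L, 0L, 0L)), 1.0)
  expect_error(auc_mann_whitney(1:3, c(1L, 1L, 1L)), "single class")
  set.seed(2468)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    lab <- c(1L, 0L, sample(c(0L, 1L), n - 2, replace = TRUE))
    sc <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # heavy ties
    expect_equal(auc_mann_whitney(sc, lab), auc_brute(sc, lab),
                 tolerance = 1e-12)
  }
  # invariance under strictly increasing transforms
  sc <- runif(50); lab <- rep(c(1L, 0L), 25)
  expect_equal(auc_mann_whitney(sc, lab), auc_mann_whitney(qlogis(sc), lab))
})

test_that("hanley_mcneil_ci reproduces the standard error formula", {
  ci <- hanley_mcneil_ci(0.5, 1000, 1000)
  expect_equal(mean(ci), 0.5, tolerance = 1e-12)
  wide <- diff(hanley_mcneil_ci(0.6, 100, 100))
  narrow <- diff(hanley_mcneil_ci(0.6, 1000, 1000))
  expect_lt(narrow, wide)
  # independent re-derivation of the same formula
  a <- 0.6; n1 <- 85; n0 <- 100
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
               (n1 * n0))
  expect_equal(hanley_mcneil_ci(a, n1, n0),
               a + c(-1, 1) * qnorm(0.975) * se, tolerance = 1e-10)
  dg <- hanley_mcneil_ci(1, 50, 50)
  expect_true(isTRUE(attr(dg, "degenerate")) && dg[2] == 1)
})

test_that("confusion metrics count the 2x2 table at the threshold", {
  expect_equal(confusion_metrics(rep(0, 10), rep(c(1L, 0L), 5)),
               c(sensitivity = 0, specificity = 1, accuracy = 0.5))
  expect_equal(confusion_metrics(c(1, 1, 0, 0), c(1L, 1L, 0L, 0L)),
               c(sensitivity = 1, specificity = 1, accuracy = 1))
  expect_equal(confusion_metrics(c(0.9, 0.4, 0.6, 0.1), c(1L, 1L, 0L, 0L)),
               c(sensitivity = 0.5, specificity = 0.5, accuracy = 0.5))
  noc <- confusion_metrics(c(0.2, 0.8), c(0L, 0L))
  expect_true(is.na(noc["sensitivity"]) && noc["specificity"] == 0.5)
})

test_that("the classifier registry resolves names and accepts plug-ins", {
  expect_true(all(c("logistic", "naive_bayes_genotype", "knn", "bayes_optimal")
                  %in% classifier_names()))
  expect_error(get_classifier("bart"), "available.*logistic")
  register_classifier("always_half",
                      fit = function(x, y, h) list(),
                      predict = function(m, x) rep(0.5, nrow(x)))
  spec <- classifier_spec("always_half")
  ds <- simulate_cohort(cohort_config(n_case = 60, n_control = 60, seed = 2))
  r <- evaluate_cv(ds, spec, k = 5, seed = 1)
  expect_equal(r$auc_mean, 0.5)
  expect_error(classifier_spec("no_such"), "unknown classifier")
})

test_that("native classifiers behave at their degenerate limits", {
  # naive Bayes with identical class frequencies: probability = case fraction
  x <- matrix(rep(c(0L, 1L, 2L), 4), ncol = 1, dimnames = list(NULL, "rs"))
  y <- rep(c(1L, 0L), each = 6)          # same genotype counts per class
  nb <- get_classifier("naive_bayes_genotype")
  m <- nb$fit(x, y, list())
  expect_equal(unname(nb$predict(m, x)), rep(0.5, 12))
  # knn with k = n: probability = training case fraction
  kn <- get_classifier("knn")
  y2 <- rep(c(1L, 0L), c(8, 4))
  m2 <- kn$fit(x, y2, list(k = 12L))
  expect_equal(unname(kn$predict(m2, x[1:3, , drop = FALSE])), rep(8 / 12, 3))
  # bayes_optimal refuses to run without the true generating panel
  expect_error(get_classifier("bayes_optimal")$fit(x, y, list()), "panel")
})

test_that("logistic recovers the per-allele log odds ratio at scale", {
  lo <- locus_model("x", 0.35, 1.53)
  ds <- simulate_cohort(cohort_config(panel = panel_model(lo),
                                      n_case = 20000, n_control = 20000,
                                      seed = 55))
  cl <- get_classifier("logistic")
  m <- cl$fit(dosage_matrix(ds), ds$status, list())
  fit <- glm(ds$status ~ dosage_matrix(ds), family = binomial())
  se <- sqrt(diag(vcov(fit)))[2]
  expect_lt(abs(m$beta[2] - log(1.53)), 3 * se)
})

test_that("evaluate_cv is deterministic and honest about weak signal", {
  ds <- simulate_cohort(cohort_config(seed = 21))
  r1 <- evaluate_cv(ds, classifier_spec("logistic"), seed = 6)
  r2 <- evaluate_cv(ds, classifier_spec("logistic"), seed = 6)
  expect_identical(r1, r2)
  expect_equal(nrow(r1$per_fold), 10)
  expect_equal(r1$auc_mean, mean(r1$per_fold$auc))
  expect_true(r1$auc_ci_range[1] <= r1$auc_mean &&
                r1$auc_mean <= r1$auc_ci_range[2])
  # null panel: no classifier can find signal
  null_panel <- panel_model(list(locus_model("a", 0.35, 1, 1),
                                 locus_model("b", 0.45, 1, 1)))
  ds0 <- simulate_cohort(cohort_config(panel = null_panel, seed = 22))
  r0 <- evaluate_cv(ds0, classifier_spec("logistic"), seed = 6)
  expect_lt(abs(r0$auc_mean - 0.5), 0.05)
})

test_that("missing dosages are mode-imputed from the training fold only", {
  ds <- simulate_cohort(cohort_config(n_case = 400, n_control = 400,
                                      missing_rate = 0.08, seed = 33))
  r <- evaluate_cv(ds, classifier_spec("logistic"), k = 5, seed = 2)
  expect_true(is.finite(r$auc_mean))
  expect_equal(r$n_excluded_folds, 0)
})

test_that("no native classifier beats the Bayes-optimal ceiling", {
  panel <- study_panel()
  ds <- simulate_cohort(cohort_config(panel = panel, n_case = 4000,
                                      n_control = 4000, seed = 71))
  tr <- 1:4000 + rep(c(0, 4000), each = 2000)  # half of each group
  te <- setdiff(1:8000, tr)
  x <- dosage_matrix(ds); y <- ds$status
  opt <- get_classifier("bayes_optimal")
  mo <- opt$fit(x[tr, ], y[tr], list(panel = panel))
  auc_opt <- auc_mann_whitney(opt$predict(mo, x[te, ]), y[te])
  for (nm in c("logistic", "naive_bayes_genotype", "knn")) {
    cl <- get_classifier(nm)
    m <- cl$fit(x[tr, ], y[tr], list())
    auc <- auc_mann_whitney(cl$predict(m, x[te, ]), y[te])
    expect_lt(auc, auc_opt + 0.01)
  }
})

test_that("performance_table assembles one row per spec and guards inputs", {
  ds <- simulate_cohort(cohort_config(n_case = 200, n_control = 200, seed = 14))
  specs <- list(classifier_spec("logistic"),
                classifier_spec("logistic", feature_set = "genotypes+gender"),
                classifier_spec("naive_bayes_genotype"))
  tab <- performance_table(ds, specs, k = 5, seed = 9)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$classifier, c("logistic", "logistic", "naive_bayes_genotype"))
  expect_equal(tab$feature_set[2], "genotypes+gender")
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  expect_error(performance_table(ds, list()), "length")
})

test_that("feature-set expansion never changes the Bayes-optimal AUC", {
  panel <- study_panel()
  ds <- simulate_cohort(cohort_config(panel = panel, n_case = 400,
                                      n_control = 400, seed = 91))
  h <- list(panel = panel)
  r1 <- evaluate_cv(ds, classifier_spec("bayes_optimal", hyperparameters = h),
                    k = 5, seed = 13)
  r2 <- evaluate_cv(ds, classifier_spec("bayes_optimal",
                                        feature_set = "genotypes+gender+age",
                                        hyperparameters = h),
                    k = 5, seed = 13)
  expect_equal(r1$auc_mean, r2$auc_mean, tolerance = 1e-12)
})
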