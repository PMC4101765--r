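#' Stratified k-fold partition
#'
#' Splits subjects into `k` folds stratified by case status: within each
#' class, subjects are shuffled and dealt round-robin, so per-fold class
#' counts differ from proportionality by at most one subject. Deterministic
#' given `seed`.
#'
#' @param labels Integer 0/1 status vector.
#' @param k Number of folds (default 10).
#' @param seed Integer RNG seed.
#' @return List of `k` elements, each with `train` and `test` index vectors;
#'   the test sets partition `seq_along(labels)`.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  stopifnot(all(labels %in% c(0L, 1L)), k >= 2L)
  for (cl in c(0L, 1L))
    if (sum(labels == cl) < k)
      stop("class ", cl, " has fewer than k = ", k, " members; ",
           "infeasible stratified split", call. = FALSE)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  fold <- integer(length(labels))
  for (cl in c(0L, 1L)) {
    idx <- which(labels == cl)
    fold[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
  }
  lapply(seq_len(k), function(f)
    list(train = which(fold != f), test = which(fold == f)))
}

#' Tie-aware Mann-Whitney AUC
#'
#' The fraction of case-control pairs in which the case scores higher, ties
#' counted one half -- equivalently the normalised Mann-Whitney U statistic,
#' computed from midranks. Invariant under any strictly increasing transform
#' of the scores.
#'
#' @param scores Numeric risk scores.
#' @param labels Integer 0/1 status vector (1 = case).
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), !anyNA(scores),
            all(labels %in% c(0L, 1L)))
  n1 <- as.numeric(sum(labels == 1L)); n0 <- as.numeric(sum(labels == 0L))
  if (n1 == 0 || n0 == 0)
    stop("AUC is undefined with a single class", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Hanley-McNeil confidence interval for an AUC
#'
#' Normal-approximation interval using the Hanley-McNeil standard error
#' \eqn{SE^2 = [A(1-A) + (n_1-1)(Q_1 - A^2) + (n_0-1)(Q_2 - A^2)]/(n_1 n_0)}
#' with \eqn{Q_1 = A/(2-A)} and \eqn{Q_2 = 2A^2/(1+A)}, clipped to \[0, 1\].
#' A degenerate AUC of exactly 0 or 1 yields a clipped one-sided interval,
#' flagged via the `degenerate` attribute.
#'
#' @param auc Point estimate in \[0, 1\].
#' @param n_case,n_control Group sizes (each >= 2).
#' @param level Confidence level (default 0.95).
#' @return Numeric `(lower, upper)`.
#' @export
hanley_mcneil_ci <- function(auc, n_case, n_control, level = 0.95) {
  stopifnot(auc >= 0, auc <= 1, n_case >= 2, n_control >= 2,
            level > 0, level < 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_case - 1) * (q1 - auc^2) +
                (n_control - 1) * (q2 - auc^2)) / (n_case * n_control))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * z * se))
  if (auc %in% c(0, 1)) attr(ci, "degenerate") <- TRUE
  ci
}

#' Threshold confusion metrics
#'
#' Sensitivity, specificity and accuracy of predicted case probabilities at a
#' decision threshold (predict case when `prob >= threshold`).
#'
#' @param probabilities Predicted case probabilities in \[0, 1\].
#' @param labels Integer 0/1 status vector.
#' @param threshold Decision threshold (default 0.5).
#' @return Named numeric: `sensitivity`, `specificity`, `accuracy`; a metric
#'   whose group is absent is `NA`.
#' @export
confusion_metrics <- function(probabilities, labels, threshold = 0.5) {
  stopifnot(length(probabilities) == length(labels),
            all(probabilities >= 0 & probabilities <= 1, na.rm = TRUE),
            all(labels %in% c(0L, 1L)))
  pred <- probabilities >= threshold
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  sens <- if (n1) sum(pred & labels == 1L) / n1 else NA_real_
  spec <- if (n0) sum(!pred & labels == 0L) / n0 else NA_real_
  c(sensitivity = sens, specificity = spec,
    accuracy = sum(pred == (labels == 1L)) / length(labels))
}

#' Classifier specification
#'
#' @param name Registry name of the classifier (see [classifier_names()]).
#' @param feature_set One of `"genotypes"`, `"genotypes+gender"`,
#'   `"genotypes+gender+age"` -- the three feature configurations the
#'   evaluation compares.
#' @param hyperparameters Named list of classifier-specific settings.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(name, feature_set = "genotypes",
                            hyperparameters = list()) {
  feature_set <- match.arg(feature_set,
                           c("genotypes", "genotypes+gender",
                             "genotypes+gender+age"))
  get_classifier(name)  # fail fast on unknown names
  structure(list(name = name, feature_set = feature_set,
                 hyperparameters = hyperparameters),
            class = "classifier_spec")
}

# design matrix for a feature set: dosage columns (+ gender as 0/1, + age)
feature_matrix <- function(dataset, feature_set) {
  x <- dosage_matrix(dataset)
  if (feature_set %in% c("genotypes+gender", "genotypes+gender+age"))
    x <- cbind(x, gender_f = as.numeric(dataset$gender == "F"))
  if (feature_set == "genotypes+gender+age")
    x <- cbind(x, age = as.numeric(dataset$age))
  x
}

# mode imputation of missing dosages, fitted on the training fold only
fit_imputer <- function(train_x, n_geno) {
  vapply(seq_len(n_geno), function(j) {
    tab <- tabulate(train_x[, j] + 1L, nbins = 3L)
    which.max(tab) - 1L
  }, integer(1))
}

apply_imputer <- function(x, modes) {
  for (j in seq_along(modes)) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- modes[j]
  }
  x
}

#' Cross-validated evaluation of one classifier
#'
#' Stratified k-fold cross-validation: per fold the classifier is fitted on
#' the training subjects only (including mode imputation of missing dosages
#' learned on the training fold), predicted case probabilities are computed
#' for the held-out subjects, and the tie-aware AUC with its Hanley-McNeil
#' 95% interval plus threshold-0.5 confusion metrics are recorded. Fold
#' metrics are aggregated as arithmetic means; the reported AUC CI range runs
#' from the smallest fold lower bound to the largest fold upper bound. A fold
#' whose test set lacks a class is flagged and excluded from the means.
#'
#' @param dataset A [genotype_dataset()].
#' @param spec A [classifier_spec()].
#' @param k Number of folds (default 10).
#' @param seed Integer RNG seed (folds and any classifier randomness).
#' @param threshold Decision threshold for the confusion metrics.
#' @return Object of class `cv_result`: `classifier`, `feature_set`,
#'   `auc_mean`, `sensitivity_mean`, `specificity_mean`, `accuracy_mean`,
#'   `auc_ci_range`, `per_fold` (data.frame), `n_excluded_folds`.
#' @export
evaluate_cv <- function(dataset, spec, k = 10L, seed = 1L, threshold = 0.5) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(spec, "classifier_spec"))
  folds <- stratified_kfold(dataset$status, k = k, seed = seed)
  clf <- get_classifier(spec$name)
  x <- feature_matrix(dataset, spec$feature_set)
  n_geno <- length(snp_names(dataset))
  y <- dataset$status
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds[[f]]$train; te <- folds[[f]]$test
    modes <- fit_imputer(x[tr, , drop = FALSE], n_geno)
    xtr <- apply_imputer(x[tr, , drop = FALSE], modes)
    xte <- apply_imputer(x[te, , drop = FALSE], modes)
    if (length(unique(y[te])) < 2L) {
      rows[[f]] <- data.frame(fold = f, auc = NA_real_, auc_lo = NA_real_,
                              auc_hi = NA_real_, sensitivity = NA_real_,
                              specificity = NA_real_, accuracy = NA_real_,
                              excluded = TRUE)
      next
    }
    old <- set_local_seed(seed + 7919L * f)
    model <- clf$fit(xtr, y[tr], spec$hyperparameters)
    prob <- clf$predict(model, xte)
    restore_seed(old)
    auc <- auc_mann_whitney(prob, y[te])
    ci <- hanley_mcneil_ci(min(max(auc, 1e-12), 1 - 1e-12),
                           sum(y[te] == 1L), sum(y[te] == 0L))
    cm <- confusion_metrics(prob, y[te], threshold)
    rows[[f]] <- data.frame(fold = f, auc = auc, auc_lo = ci[1], auc_hi = ci[2],
                            sensitivity = cm["sensitivity"],
                            specificity = cm["specificity"],
                            accuracy = cm["accuracy"], excluded = FALSE)
  }
  per_fold <- do.call(rbind, rows)
  rownames(per_fold) <- NULL
  ok <- !per_fold$excluded
  if (!any(ok)) stop("all folds were excluded (single-class test sets)",
                     call. = FALSE)
  structure(list(classifier = spec$name, feature_set = spec$feature_set,
                 auc_mean = mean(per_fold$auc[ok]),
                 sensitivity_mean = mean(per_fold$sensitivity[ok]),
                 specificity_mean = mean(per_fold$specificity[ok]),
                 accuracy_mean = mean(per_fold$accuracy[ok]),
                 auc_ci_range = c(min(per_fold$auc_lo[ok]),
                                  max(per_fold$auc_hi[ok])),
                 per_fold = per_fold,
                 n_excluded_folds = sum(!ok)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s [%s]  AUC=%.4f  sens=%.4f  spec=%.4f  acc=%.4f  CI range [%.4f, %.4f]\n",
              x$classifier, x$feature_set, x$auc_mean, x$sensitivity_mean,
              x$specificity_mean, x$accuracy_mean,
              x$auc_ci_range[1], x$auc_ci_range[2]))
  invisible(x)
}

#' Cross-validated performance table for a set of classifiers
#'
#' Runs [evaluate_cv()] for every specification and assembles a report table
#' (one row per classifier and feature set) with mean AUC, sensitivity,
#' specificity, accuracy and the per-fold AUC confidence-interval range.
#'
#' @param dataset A [genotype_dataset()].
#' @param specs List of [classifier_spec()] objects (at least one).
#' @param k Folds (default 10).
#' @param seed Integer RNG seed (same folds for every classifier).
#' @return Data.frame of class `performance_table` with columns `classifier`,
#'   `feature_set`, `auc`, `sensitivity`, `specificity`, `accuracy`,
#'   `auc_ci_low`, `auc_ci_high`; the `cv_results` attribute keeps the full
#'   [evaluate_cv()] objects.
#' @export
performance_table <- function(dataset, specs, k = 10L, seed = 1L) {
  if (inherits(specs, "classifier_spec")) specs <- list(specs)
  stopifnot(is.list(specs), length(specs) >= 1L)
  res <- lapply(specs, function(sp) evaluate_cv(dataset, sp, k = k, seed = seed))
  out <- do.call(rbind, lapply(res, function(r)
    data.frame(classifier = r$classifier, feature_set = r$feature_set,
               auc = r$auc_mean, sensitivity = r$sensitivity_mean,
               specificity = r$specificity_mean, accuracy = r$accuracy_mean,
               auc_ci_low = r$auc_ci_range[1], auc_ci_high = r$auc_ci_range[2])))
  attr(out, "cv_results") <- res
  class(out) <- c("performance_table", "data.frame")
  out
}
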