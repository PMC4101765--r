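# Classifier registry
#
# Classifiers plug in as a pair of pure functions:
#   fit(x, y, hyperparameters) -> model      (x: numeric feature matrix whose
#       genotype columns hold dosages 0/1/2; optional columns "gender_f" and
#       "age"; y: integer 0/1 status)
#   predict(model, x) -> case probabilities in [0, 1]
# Models must be pure functions of their training fold -- no test leakage.
# External methods (random forest, SVM, BART, boosting,
# recursive partitioning, fuzzy rule systems) attach through the same
# interface via register_classifier(); their internals are out of scope here.

the_registry <- new.env(parent = emptyenv())

#' Register a classifier
#'
#' @param name Registry name.
#' @param fit Function `(x, y, hyperparameters) -> model`.
#' @param predict Function `(model, x) -> probabilities`.
#' @export
register_classifier <- function(name, fit, predict) {
  stopifnot(is.character(name), length(name) == 1L,
            is.function(fit), is.function(predict))
  assign(name, list(fit = fit, predict = predict), envir = the_registry)
  invisible(name)
}

#' Names of the registered classifiers
#' @export
classifier_names <- function() sort(ls(the_registry))

#' Look up a registered classifier
#'
#' @param name Registry name.
#' @return List with `fit` and `predict` functions.
#' @export
get_classifier <- function(name) {
  if (!exists(name, envir = the_registry, inherits = FALSE))
    stop("unknown classifier '", name, "'; available: ",
         paste(classifier_names(), collapse = ", "), call. = FALSE)
  get(name, envir = the_registry, inherits = FALSE)
}

geno_cols <- function(x) {
  cn <- colnames(x)
  if (is.null(cn)) seq_len(ncol(x)) else which(!cn %in% c("gender_f", "age"))
}

# -- logistic regression (additive dosage coding, IRLS via stats::glm.fit) ----

fit_logistic <- function(x, y, hyper = list()) {
  maxit <- hyper$maxit %||% 100L
  eps <- hyper$epsilon %||% 1e-8
  fit <- suppressWarnings(stats::glm.fit(
    cbind(`(Intercept)` = 1, x), y, family = stats::binomial(),
    control = stats::glm.control(epsilon = eps, maxit = maxit)))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  list(beta = beta)
}

predict_logistic <- function(model, x) {
  as.vector(stats::plogis(cbind(1, x) %*% model$beta))
}

# -- naive Bayes over genotype categories (+ gender category, Gaussian age) --

fit_naive_bayes <- function(x, y, hyper = list()) {
  alpha <- hyper$smoothing %||% 1
  gi <- geno_cols(x)
  lev <- function(col) if (identical(colnames(x)[col], "gender_f")) 0:1 else 0:2
  cond <- lapply(c(gi, which(colnames(x) == "gender_f")), function(j) {
    lv <- lev(j)
    tab <- vapply(c(0L, 1L), function(cl) {
      cnt <- vapply(lv, function(v) sum(x[y == cl, j] == v), numeric(1))
      (cnt + alpha) / (sum(cnt) + alpha * length(lv))
    }, numeric(length(lv)))
    list(col = j, levels = lv, prob = tab)  # prob: levels x class(0,1)
  })
  agec <- which(colnames(x) == "age")
  age_par <- if (length(agec)) {
    lapply(c(0L, 1L), function(cl) {
      v <- x[y == cl, agec]
      c(mean = mean(v), sd = max(stats::sd(v), 1e-6))
    })
  } else NULL
  list(prior = mean(y == 1L), cond = cond, age_col = agec, age_par = age_par)
}

predict_naive_bayes <- function(model, x) {
  n <- nrow(x)
  ll1 <- rep(log(model$prior), n)
  ll0 <- rep(log(1 - model$prior), n)
  for (cd in model$cond) {
    idx <- match(x[, cd$col], cd$levels)
    ll0 <- ll0 + log(cd$prob[idx, 1])
    ll1 <- ll1 + log(cd$prob[idx, 2])
  }
  if (length(model$age_col)) {
    v <- x[, model$age_col]
    ll0 <- ll0 + stats::dnorm(v, model$age_par[[1]]["mean"],
                              model$age_par[[1]]["sd"], log = TRUE)
    ll1 <- ll1 + stats::dnorm(v, model$age_par[[2]]["mean"],
                              model$age_par[[2]]["sd"], log = TRUE)
  }
  stats::plogis(ll1 - ll0)
}

# -- k-nearest neighbours (city-block distance on dosage vectors) ------------

fit_knn <- function(x, y, hyper = list()) {
  k <- hyper$k %||% 21L
  xs <- x
  agec <- which(colnames(x) == "age")
  age_scale <- NULL
  if (length(agec)) {                 # bring age onto the dosage scale
    age_scale <- max(stats::sd(x[, agec]), 1e-6)
    xs[, agec] <- x[, agec] / age_scale
  }
  list(x = xs, y = y, k = min(k, nrow(x)), age_col = agec,
       age_scale = age_scale)
}

predict_knn <- function(model, x) {
  if (length(model$age_col)) x[, model$age_col] <- x[, model$age_col] / model$age_scale
  apply(x, 1L, function(row) {
    d <- colSums(abs(t(model$x) - row))
    # include every neighbour tied with the k-th distance: dosage vectors tie
    # massively (3^L distinct profiles) and an index tie-break would leak the
    # case-first row order of simulated cohorts
    kth <- sort(d, partial = model$k)[model$k]
    mean(model$y[d <= kth] == 1L)
  })
}

# -- Bayes-optimal likelihood-ratio classifier (synthetic data only) ---------

fit_bayes_optimal <- function(x, y, hyper = list()) {
  panel <- hyper$panel
  if (is.null(panel) || !inherits(panel, "panel_model"))
    stop("bayes_optimal requires the true generating panel in ",
         "hyperparameters$panel (synthetic data only)", call. = FALSE)
  list(panel = panel, prior = mean(y == 1L))
}

predict_bayes_optimal <- function(model, x) {
  g <- x[, geno_cols(x), drop = FALSE][, seq_along(model$panel$loci),
                                       drop = FALSE]
  s <- llr_score(g, model$panel)
  stats::plogis(s + stats::qlogis(model$prior))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

register_native_classifiers <- function() {
  register_classifier("logistic", fit_logistic, predict_logistic)
  register_classifier("naive_bayes_genotype", fit_naive_bayes,
                      predict_naive_bayes)
  register_classifier("knn", fit_knn, predict_knn)
  register_classifier("bayes_optimal", fit_bayes_optimal,
                      predict_bayes_optimal)
}

.onLoad <- function(libname, pkgname) {
  register_native_classifiers()
}
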