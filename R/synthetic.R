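#' Study-emulating four-SNP susceptibility panel
#'
#' The default panel mirrors the Han-Chinese case-control study the generator
#' emulates: four thyroid-cancer risk SNPs with per-allele odds ratios 1.53,
#' 1.53, 1.31 and 1.41 under multiplicative genotype effects (`r1 = OR`,
#' `r2 = OR^2`). The study publishes no allele frequencies, so the risk-allele
#' frequencies 0.35, 0.39, 0.45 and 0.35 are stated assumptions of this
#' package (common-variant range typical of GWAS hits in East-Asian
#' populations); they are echoed in every output header.
#'
#' @param prevalence Population disease risk `K`; default 0, the rare-disease
#'   limit appropriate for thyroid cancer.
#' @return A [panel_model()] with four loci.
#' @export
study_panel <- function(prevalence = 0) {
  ors <- c(rs965513 = 1.53, rs944289 = 1.53, rs966423 = 1.31, rs2439302 = 1.41)
  frq <- c(rs965513 = 0.35, rs944289 = 0.39, rs966423 = 0.45, rs2439302 = 0.35)
  loci <- lapply(names(ors), function(s) locus_model(s, frq[[s]], ors[[s]]))
  panel_model(loci, prevalence = prevalence)
}

#' Simulation configuration for a case-control cohort
#'
#' Bundles the generative panel with sample sizes, covariate distributions and
#' missingness. Defaults emulate the study: 845 cases and 1005 controls; a
#' strongly female case series (papillary thyroid carcinoma is about 3:1
#' female) against a more balanced population-based control series, and a
#' mildly younger case age distribution -- so gender/age matching is
#' non-trivial -- while covariates stay independent of genotype and carry no
#' information about status beyond group membership.
#'
#' @param panel A [panel_model()]; default [study_panel()].
#' @param n_case,n_control Group sizes (defaults 845 / 1005).
#' @param case_female,control_female Probability a subject is female
#'   (defaults 0.75 / 0.70: the control pool is female-enriched relative to
#'   the population, as a pool recruited to support gender matching of a
#'   female-predominant disease must be, yet still leaner in females than the
#'   case series -- so matching is non-trivial but feasible).
#' @param case_age_mean,case_age_sd Case age distribution in years
#'   (defaults 45 / 12, truncated to the enrollment window \[20, 72\]).
#' @param control_age_mean,control_age_sd Control age distribution
#'   (defaults 45 / 14: same centre, wider spread, so every case age bin has
#'   control support; truncated to \[20, 72\]).
#' @param monomorphic_snps Names of extra SNPs emitted as all-zero dosage
#'   columns (a locus undetected in the population); default none.
#' @param missing_rate Per-dosage missingness probability in \[0, 1).
#' @param seed Integer RNG seed.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(panel = study_panel(),
                          n_case = 845L, n_control = 1005L,
                          case_female = 0.75, control_female = 0.70,
                          case_age_mean = 45, case_age_sd = 12,
                          control_age_mean = 45, control_age_sd = 14,
                          monomorphic_snps = character(),
                          missing_rate = 0, seed = 1L) {
  stopifnot(inherits(panel, "panel_model"),
            n_case >= 1L, n_control >= 1L,
            case_female >= 0, case_female <= 1,
            control_female >= 0, control_female <= 1,
            case_age_sd > 0, control_age_sd > 0,
            missing_rate >= 0, missing_rate < 1)
  structure(list(panel = panel, n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 case_female = case_female, control_female = control_female,
                 case_age_mean = case_age_mean, case_age_sd = case_age_sd,
                 control_age_mean = control_age_mean,
                 control_age_sd = control_age_sd,
                 monomorphic_snps = monomorphic_snps,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a case-control genotype cohort
#'
#' Case dosages are drawn per locus from [case_genotype_frequencies()] and
#' control dosages from [control_genotype_frequencies()] at the panel's
#' prevalence; loci are independent (linkage equilibrium). Gender and age are
#' drawn from the per-group distributions, independent of genotype.
#' Deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A [genotype_dataset()] with `config$n_case` case rows followed by
#'   `config$n_control` control rows.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- set_local_seed(config$seed)
  on.exit(restore_seed(old), add = TRUE)
  n1 <- config$n_case; n0 <- config$n_control
  panel <- config$panel
  fr <- panel_frequencies(panel)
  draw <- function(freqs, n) sample(0:2, n, replace = TRUE, prob = freqs)
  g1 <- vapply(seq_along(panel$loci), function(l) draw(fr$case[, l], n1),
               integer(n1))
  g0 <- vapply(seq_along(panel$loci), function(l) draw(fr$control[, l], n0),
               integer(n0))
  g <- rbind(matrix(g1, nrow = n1), matrix(g0, nrow = n0))
  colnames(g) <- names(panel$loci)
  trunc_age <- function(a) pmin(72, pmax(20, round(a)))  # enrollment window
  age1 <- trunc_age(stats::rnorm(n1, config$case_age_mean, config$case_age_sd))
  age0 <- trunc_age(stats::rnorm(n0, config$control_age_mean, config$control_age_sd))
  sex1 <- ifelse(stats::runif(n1) < config$case_female, "F", "M")
  sex0 <- ifelse(stats::runif(n0) < config$control_female, "F", "M")
  df <- data.frame(subject_id = sprintf("S%05d", seq_len(n1 + n0)),
                   status = rep(c(1L, 0L), c(n1, n0)),
                   gender = c(sex1, sex0),
                   age = c(age1, age0))
  df <- cbind(df, as.data.frame(g))
  for (s in config$monomorphic_snps) df[[s]] <- 0L
  out <- genotype_dataset(df)
  if (config$missing_rate > 0)
    out <- inject_missingness(out, config$missing_rate,
                              seed = config$seed + 1000003L)
  out
}

#' Inject genotype missingness
#'
#' Each dosage is independently replaced by `NA` with probability `rate`
#' (emulating genotyping failures). Deterministic given `seed`.
#'
#' @param dataset A [genotype_dataset()].
#' @param rate Missingness probability in \[0, 1).
#' @param seed Integer RNG seed.
#' @return The dataset with `NA`s injected.
#' @export
inject_missingness <- function(dataset, rate, seed = 1L) {
  stopifnot(inherits(dataset, "genotype_dataset"), rate >= 0, rate < 1)
  if (rate == 0) return(dataset)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  for (s in snp_names(dataset)) {
    hit <- stats::runif(nrow(dataset)) < rate
    dataset[[s]][hit] <- NA_integer_
  }
  dataset
}

#' Gender- and age-matched control resampling
#'
#' Builds `n_replicates` matched cohorts: within each replicate, every case is
#' paired 1:1 with a control drawn uniformly from the same gender and age bin
#' (bins of `age_bin_years` years, left-closed from age 0), so each
#' replicate's matched control multiset has exactly the cases' gender and
#' age-bin distribution by construction. Fresh draws are taken in every
#' replicate -- the "resampling" that lets many replicates explore the
#' control pool.
#'
#' By default draws are with replacement within a replicate (a control may
#' serve several cases of its stratum); this only requires each case stratum
#' to contain at least one control, which is attainable at realistic
#' case:control ratios. With `replace = FALSE` controls are drawn without
#' replacement, which additionally requires every stratum's controls to be at
#' least as numerous as its cases -- rarely satisfiable when controls
#' outnumber cases by only ~20%.
#'
#' In strict mode (default) an unmatchable stratum is an error naming the
#' stratum; in permissive mode its age caliper is widened by one bin on each
#' side (sacrificing exact age-bin identity for that stratum) and the
#' widening is recorded in the result's `widened` field.
#'
#' @param dataset A [genotype_dataset()].
#' @param n_replicates Number of matched cohorts (default 1000).
#' @param age_bin_years Age bin width in years (default 5).
#' @param seed Integer RNG seed.
#' @param strict Error on an unmatchable stratum (default `TRUE`).
#' @param replace Draw controls with replacement within a replicate
#'   (default `TRUE`).
#' @return Object of class `matched_replicates`: a list with `replicates`
#'   (each a list of `case_idx` and `control_idx` row indices into `dataset`),
#'   `age_bin_years`, `seed` and `widened` (character vector of widened
#'   strata, empty in strict mode).
#' @export
matched_resample <- function(dataset, n_replicates = 1000L, age_bin_years = 5,
                             seed = 1L, strict = TRUE, replace = TRUE) {
  stopifnot(inherits(dataset, "genotype_dataset"), n_replicates >= 1L,
            age_bin_years > 0)
  case_idx <- which(dataset$status == 1L)
  ctrl_idx <- which(dataset$status == 0L)
  if (!length(case_idx) || !length(ctrl_idx))
    stop("matching needs both cases and controls", call. = FALSE)
  bin <- floor(dataset$age / age_bin_years)
  stratum <- paste0(dataset$gender, ":", bin * age_bin_years, "-",
                    (bin + 1) * age_bin_years)
  widened <- character()
  case_strata <- split(case_idx, stratum[case_idx])
  ctrl_strata <- split(ctrl_idx, stratum[ctrl_idx])
  pools <- lapply(names(case_strata), function(st) {
    pool <- ctrl_strata[[st]]
    need <- if (replace) 1L else length(case_strata[[st]])
    if (is.null(pool) || length(pool) < need) {
      if (strict)
        stop("matching failure in stratum ", st, ": ",
             length(case_strata[[st]]), " case(s) but ", length(pool),
             " control(s) (need >= ", need, "); widen the age bin or use ",
             "strict = FALSE", call. = FALSE)
      # permissive: widen the caliper by one bin on each side
      g <- sub(":.*$", "", st)
      b <- as.numeric(sub("-.*$", "", sub("^.*:", "", st))) / age_bin_years
      wide <- ctrl_idx[dataset$gender[ctrl_idx] == g &
                         abs(bin[ctrl_idx] - b) <= 1]
      if (length(wide) < need)
        stop("matching failure in stratum ", st,
             " even after widening the age caliper by one bin", call. = FALSE)
      widened <<- c(widened, st)
      pool <- wide
    }
    pool
  })
  names(pools) <- names(case_strata)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  replicates <- lapply(seq_len(n_replicates), function(rep_i) {
    ctl <- unlist(lapply(names(case_strata), function(st) {
      pool <- pools[[st]]
      need <- length(case_strata[[st]])
      pool[sample.int(length(pool), need, replace = replace)]
    }), use.names = FALSE)
    list(case_idx = unlist(case_strata, use.names = FALSE), control_idx = ctl)
  })
  structure(list(replicates = replicates, age_bin_years = age_bin_years,
                 seed = as.integer(seed), widened = unique(widened)),
            class = "matched_replicates")
}

#' @export
print.matched_replicates <- function(x, ...) {
  cat(sprintf("<matched_replicates> %d replicates, %d matched pairs each, %g-year age bins\n",
              length(x$replicates), length(x$replicates[[1]]$case_idx),
              x$age_bin_years))
  if (length(x$widened))
    cat("  widened strata:", paste(x$widened, collapse = ", "), "\n")
  invisible(x)
}
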