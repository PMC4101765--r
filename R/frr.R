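#' Familial relative risk attributable to one locus
#'
#' The relative risk of disease to the offspring of an affected individual,
#' attributable to a single codominant biallelic locus in Hardy-Weinberg
#' equilibrium:
#' \deqn{\lambda^* = \frac{p\,(p r_2 + q r_1)^2 + q\,(p r_1 + q)^2}{(p^2 r_2 + 2 p q r_1 + q^2)^2}}
#' with \eqn{q = 1 - p}. Equals 1 for a null locus and is invariant under
#' relabelling the risk allele with baseline rescaling,
#' \eqn{\lambda^*(p, r_1, r_2) = \lambda^*(1-p, r_1/r_2, 1/r_2)}.
#' An independent Monte-Carlo check of this closed form is [mc_family_frr()].
#'
#' @param locus A [locus_model()].
#' @return Scalar \eqn{\lambda^*} (dimensionless, >= 1 when r2 >= r1 >= 1).
#' @examples
#' familial_relative_risk(locus_model("x", 0.5, 1.32, 1.7424))  # ~1.0190
#' @export
familial_relative_risk <- function(locus) {
  stopifnot(inherits(locus, "locus_model"))
  p <- locus$p; q <- 1 - p; r1 <- locus$r1; r2 <- locus$r2
  m <- p^2 * r2 + 2 * p * q * r1 + q^2
  (p * (p * r2 + q * r1)^2 + q * (p * r1 + q)^2) / m^2
}

#' Proportion of overall familial risk explained by a locus
#'
#' Under multiplicative joint effects across loci, the share of the overall
#' familial relative risk \eqn{\lambda_o} explained by a locus with familial
#' relative risk \eqn{\lambda^*} is \eqn{\log(\lambda^*)/\log(\lambda_o)}.
#' Additive over independent loci: the proportions of two loci sum to the
#' proportion of the product of their \eqn{\lambda^*} values.
#'
#' @param frr \eqn{\lambda^*} value(s), typically >= 1.
#' @param lambda_o Overall familial relative risk of the disease; the default
#'   8.48 is the literature estimate for thyroid cancer.
#' @return Fraction(s) in \[0, 1\] (negative if `frr < 1`, with a warning).
#' @export
proportion_of_familial_risk <- function(frr, lambda_o = 8.48) {
  stopifnot(is.numeric(frr), is.numeric(lambda_o), lambda_o > 1)
  if (any(frr < 1, na.rm = TRUE))
    warning("frr < 1 yields a negative proportion of familial risk")
  log(frr) / log(lambda_o)
}

#' Per-SNP genotype counts of a case-control dataset
#'
#' @param dataset A [genotype_dataset()].
#' @param snp SNP column name.
#' @return Object of class `genotype_counts`: integer triples `case_counts`
#'   and `control_counts` over dosages 0, 1, 2 (missing dosages excluded).
#' @export
genotype_counts <- function(dataset, snp) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (!snp %in% snp_names(dataset))
    stop("unknown SNP column: ", snp, call. = FALSE)
  d <- dataset[[snp]]
  cnt <- function(v) vapply(0:2, function(g) sum(v == g, na.rm = TRUE), integer(1))
  structure(list(snp = snp,
                 case_counts = cnt(d[dataset$status == 1L]),
                 control_counts = cnt(d[dataset$status == 0L])),
            class = "genotype_counts")
}

#' Build a genotype-counts object from two dosage triples
#'
#' @param snp SNP identifier.
#' @param case_counts,control_counts Non-negative counts over dosages 0, 1, 2.
#' @return Object of class `genotype_counts`.
#' @export
as_genotype_counts <- function(snp, case_counts, control_counts) {
  stopifnot(length(case_counts) == 3L, length(control_counts) == 3L,
            all(case_counts >= 0), all(control_counts >= 0))
  structure(list(snp = snp,
                 case_counts = as.numeric(case_counts),
                 control_counts = as.numeric(control_counts)),
            class = "genotype_counts")
}

is_monomorphic <- function(counts) {
  tot <- counts$case_counts + counts$control_counts
  sum(tot > 0) <= 1L
}

#' Genotype relative risks from case-control counts
#'
#' Odds ratios of dosage-1 and dosage-2 genotypes against the dosage-0
#' (common homozygote) baseline, with Woolf (log-scale normal) confidence
#' intervals. A Haldane-Anscombe continuity correction (+0.5 on all four
#' cells) is applied to a 2x2 table only when it contains a zero cell.
#'
#' @param counts A `genotype_counts` object (see [genotype_counts()]).
#' @param level Confidence level, default 0.95.
#' @return List with `r1`, `r2`, `r1_ci`, `r2_ci`, and `na` (TRUE for a
#'   monomorphic SNP, in which case all estimates are `NA` -- reported as
#'   not-applicable, never as numbers).
#' @export
estimate_genotype_relative_risks <- function(counts, level = 0.95) {
  stopifnot(inherits(counts, "genotype_counts"))
  if (is_monomorphic(counts))
    return(list(r1 = NA_real_, r2 = NA_real_,
                r1_ci = c(NA_real_, NA_real_), r2_ci = c(NA_real_, NA_real_),
                na = TRUE))
  z <- stats::qnorm(1 - (1 - level) / 2)
  or_one <- function(a, b, c, d) {      # a,c cases; b,d controls; (dosage g, dosage 0)
    if (min(a, b, c, d) == 0) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
    or <- (a * d) / (b * c)
    se <- sqrt(1/a + 1/b + 1/c + 1/d)
    list(or = or, ci = exp(log(or) + c(-1, 1) * z * se))
  }
  ca <- counts$case_counts; co <- counts$control_counts
  e1 <- or_one(ca[2], co[2], ca[1], co[1])
  e2 <- or_one(ca[3], co[3], ca[1], co[1])
  list(r1 = e1$or, r2 = e2$or, r1_ci = e1$ci, r2_ci = e2$ci, na = FALSE)
}

#' Risk-allele frequency from control genotype counts
#'
#' Controls are used as the population proxy (cases are risk-enriched):
#' `p = (het + 2 * hom) / (2 * n_controls)`.
#'
#' @inheritParams estimate_genotype_relative_risks
#' @return Scalar `p` in \[0, 1\]; `NA` for a monomorphic SNP (with 0 or 1 as
#'   the degenerate edge reported when only controls are monomorphic).
#' @export
estimate_risk_allele_frequency <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  co <- counts$control_counts
  n <- sum(co)
  if (n == 0) stop("control group is empty", call. = FALSE)
  (co[2] + 2 * co[3]) / (2 * n)
}

# point estimates (p, r1, r2, lambda*, proportion) from a counts object;
# returns NULL when the counts are monomorphic or degenerate for the formula
frr_point_estimates <- function(counts, lambda_o) {
  if (is_monomorphic(counts)) return(NULL)
  p <- estimate_risk_allele_frequency(counts)
  if (p <= 0 || p >= 1) return(NULL)
  rr <- estimate_genotype_relative_risks(counts)
  lo <- locus_model(counts$snp, p, rr$r1, rr$r2)
  frr <- familial_relative_risk(lo)
  list(p = p, r1 = rr$r1, r2 = rr$r2, frr = frr,
       proportion = log(frr) / log(lambda_o))
}

#' Bootstrap confidence interval for the familial relative risk of one SNP
#'
#' Nonparametric bootstrap resampling subjects with replacement within the
#' case and the control group. Because \eqn{p, r_1, r_2, \lambda^*} depend on
#' the data only through the per-group genotype counts, resampling subjects is
#' equivalent to drawing each group's counts from a multinomial with the
#' observed proportions, which is how replicates are generated. Percentile
#' 2.5/97.5 intervals; deterministic given `seed`. Monomorphic or degenerate
#' replicates are dropped and counted; more than 10% dropped triggers an
#' instability warning.
#'
#' @param dataset A [genotype_dataset()].
#' @param snp SNP column name.
#' @param B Number of bootstrap replicates, >= 100 (default 1000).
#' @param seed Integer RNG seed.
#' @param lambda_o Overall familial relative risk (default 8.48).
#' @return Object of class `frr_result`: fields `snp`, `frr`, `frr_ci`,
#'   `proportion`, `proportion_ci`, `lambda_o`, `na`, `n_dropped`.
#' @export
frr_bootstrap_ci <- function(dataset, snp, B = 1000L, seed = 1L,
                             lambda_o = 8.48) {
  stopifnot(B >= 100L)
  counts <- genotype_counts(dataset, snp)
  frr_bootstrap_ci_counts(counts, B = B, seed = seed, lambda_o = lambda_o)
}

frr_bootstrap_ci_counts <- function(counts, B = 1000L, seed = 1L,
                                    lambda_o = 8.48) {
  pt <- frr_point_estimates(counts, lambda_o)
  if (is.null(pt))
    return(structure(list(snp = counts$snp, frr = NA_real_,
                          frr_ci = c(NA_real_, NA_real_),
                          proportion = NA_real_,
                          proportion_ci = c(NA_real_, NA_real_),
                          lambda_o = lambda_o, na = TRUE, n_dropped = 0L),
                     class = "frr_result"))
  n_case <- sum(counts$case_counts); n_ctrl <- sum(counts$control_counts)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  bc <- stats::rmultinom(B, n_case, counts$case_counts / n_case)
  bt <- stats::rmultinom(B, n_ctrl, counts$control_counts / n_ctrl)
  frrs <- vapply(seq_len(B), function(b) {
    est <- frr_point_estimates(as_genotype_counts(counts$snp, bc[, b], bt[, b]),
                               lambda_o)
    if (is.null(est)) NA_real_ else est$frr
  }, numeric(1))
  dropped <- sum(is.na(frrs))
  if (dropped > 0.1 * B)
    warning("bootstrap instability for ", counts$snp, ": ", dropped, " of ",
            B, " replicates were monomorphic/degenerate and dropped")
  ci <- stats::quantile(frrs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(snp = counts$snp, frr = pt$frr, frr_ci = ci,
                 proportion = pt$proportion,
                 proportion_ci = log(ci) / log(lambda_o),
                 lambda_o = lambda_o, na = FALSE, n_dropped = dropped),
            class = "frr_result")
}

#' @export
print.frr_result <- function(x, ...) {
  if (x$na) {
    cat(sprintf("<frr_result> %s  N.A. (monomorphic)\n", x$snp))
  } else {
    cat(sprintf("<frr_result> %s  lambda*=%.4f (%.4f-%.4f)  proportion=%.3f%% (%.3f-%.3f)\n",
                x$snp, x$frr, x$frr_ci[1], x$frr_ci[2],
                100 * x$proportion, 100 * x$proportion_ci[1],
                100 * x$proportion_ci[2]))
  }
  invisible(x)
}

#' Familial-relative-risk table for all SNPs of a dataset
#'
#' One row per SNP: risk-allele frequency (from controls), genotype relative
#' risks, \eqn{\lambda^*} with bootstrap CI, and the proportion of overall
#' familial risk, plus the summed proportion across non-monomorphic SNPs.
#' Monomorphic SNPs appear as not-applicable rows and are excluded from the
#' sum.
#'
#' @inheritParams frr_bootstrap_ci
#' @param lambda_o Overall familial relative risk (default 8.48).
#' @param B Bootstrap replicates per SNP (default 1000); `B = 0` skips CIs.
#' @return Object of class `frr_table`: a data.frame with columns `snp`, `p`,
#'   `r1`, `r2`, `frr`, `frr_lo`, `frr_hi`, `proportion_pct`,
#'   `proportion_lo_pct`, `proportion_hi_pct`, `p_value` (placeholder, `NA`),
#'   `na_flag`; attribute `total_proportion_pct` carries the sum.
#' @export
frr_table <- function(dataset, lambda_o = 8.48, B = 1000L, seed = 1L) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  snps <- snp_names(dataset)
  if (length(snps) == 0L) stop("dataset has no SNP columns", call. = FALSE)
  if (!any(dataset$status == 1L) || !any(dataset$status == 0L))
    stop("dataset must contain both cases and controls", call. = FALSE)
  rows <- lapply(seq_along(snps), function(i) {
    counts <- genotype_counts(dataset, snps[i])
    pt <- frr_point_estimates(counts, lambda_o)
    if (is.null(pt)) {
      data.frame(snp = snps[i], p = NA_real_, r1 = NA_real_, r2 = NA_real_,
                 frr = NA_real_, frr_lo = NA_real_, frr_hi = NA_real_,
                 proportion_pct = NA_real_, proportion_lo_pct = NA_real_,
                 proportion_hi_pct = NA_real_, p_value = NA_real_,
                 na_flag = TRUE)
    } else {
      ci <- c(NA_real_, NA_real_); pci <- c(NA_real_, NA_real_)
      if (B > 0) {
        br <- frr_bootstrap_ci_counts(counts, B = B, seed = seed + i,
                                      lambda_o = lambda_o)
        ci <- br$frr_ci; pci <- br$proportion_ci
      }
      data.frame(snp = snps[i], p = pt$p, r1 = pt$r1, r2 = pt$r2,
                 frr = pt$frr, frr_lo = ci[1], frr_hi = ci[2],
                 proportion_pct = 100 * pt$proportion,
                 proportion_lo_pct = 100 * pci[1],
                 proportion_hi_pct = 100 * pci[2],
                 p_value = NA_real_, na_flag = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "total_proportion_pct") <- sum(out$proportion_pct, na.rm = TRUE)
  attr(out, "lambda_o") <- lambda_o
  class(out) <- c("frr_table", "data.frame")
  out
}

#' Monte-Carlo parent-offspring oracle for the familial relative risk
#'
#' Independent simulation check of the closed-form [familial_relative_risk()].
#' Parent pairs are drawn from Hardy-Weinberg equilibrium, one offspring
#' genotype is produced by Mendelian transmission, and
#' \eqn{\lambda^* = E[r_{offspring} \mid parent\ affected] / E[r]} is estimated
#' by weighting parents by their genotype relative risk and normalising by an
#' independent population draw. Standard errors come from batch means.
#'
#' @param locus A [locus_model()].
#' @param n_families Number of simulated families (>= 10000).
#' @param seed Integer RNG seed.
#' @param n_batches Batches for the standard error (default 50).
#' @return List with `frr` (the estimate) and `se` (Monte-Carlo standard
#'   error).
#' @export
mc_family_frr <- function(locus, n_families = 1e5, seed = 1L, n_batches = 50L) {
  stopifnot(inherits(locus, "locus_model"), n_families >= 1e4)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  n <- as.integer(n_families)
  f <- genotype_frequencies(locus)
  r <- c(1, locus$r1, locus$r2)
  draw_hwe <- function(k) sample(0:2, k, replace = TRUE, prob = f)
  g_par <- draw_hwe(n)                    # the affected-candidate parent
  g_mate <- draw_hwe(n)                   # the other parent
  # Mendelian transmission: each parent passes the risk allele w.p. dosage/2
  g_off <- stats::rbinom(n, 1L, g_par / 2) + stats::rbinom(n, 1L, g_mate / 2)
  g_pop <- draw_hwe(n)                    # independent population sample
  w <- r[g_par + 1L]                      # parent-affection weight
  ro <- r[g_off + 1L]
  rp <- r[g_pop + 1L]
  batch <- rep(seq_len(n_batches), length.out = n)
  est_batch <- vapply(seq_len(n_batches), function(b) {
    i <- batch == b
    (sum(w[i] * ro[i]) / sum(w[i])) / mean(rp[i])
  }, numeric(1))
  list(frr = (sum(w * ro) / sum(w)) / mean(rp),
       se = stats::sd(est_batch) / sqrt(n_batches))
}
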