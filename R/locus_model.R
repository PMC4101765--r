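#' Single-locus multiplicative relative-risk model
#'
#' A biallelic susceptibility locus is described by the frequency `p` of its
#' risk allele (genotypes assumed in Hardy-Weinberg equilibrium, so the
#' dosage-0/1/2 genotypes have population frequencies \eqn{q^2, 2pq, p^2} with
#' \eqn{q = 1 - p}) and by the genotype relative risks `r1` (heterozygote vs.
#' common homozygote) and `r2` (risk homozygote vs. common homozygote). The
#' multiplicative special case is `r2 = r1^2`.
#'
#' @param name SNP identifier (scalar character).
#' @param p Risk-allele frequency, strictly inside (0, 1).
#' @param r1 Heterozygote relative risk, > 0.
#' @param r2 Risk-homozygote relative risk, > 0. Defaults to `r1^2`
#'   (multiplicative per-allele effects).
#' @return An object of class `locus_model`.
#' @examples
#' locus_model("rs965513", p = 0.35, r1 = 1.53)
#' @export
locus_model <- function(name, p, r1, r2 = r1^2) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
    stop("risk-allele frequency 'p' must be a single number strictly in (0, 1), got ",
         format(p), call. = FALSE)
  if (!is.numeric(r1) || length(r1) != 1L || !is.finite(r1) || r1 <= 0)
    stop("'r1' must be a single positive number", call. = FALSE)
  if (!is.numeric(r2) || length(r2) != 1L || !is.finite(r2) || r2 <= 0)
    stop("'r2' must be a single positive number", call. = FALSE)
  structure(list(name = name, p = p, r1 = r1, r2 = r2), class = "locus_model")
}

#' @export
print.locus_model <- function(x, ...) {
  cat(sprintf("<locus_model> %s  p=%.4g  r1=%.4g  r2=%.4g\n",
              x$name, x$p, x$r1, x$r2))
  invisible(x)
}

#' Multi-locus panel model
#'
#' A panel bundles independent loci (linkage equilibrium by construction) with
#' a population disease prevalence `K`. `K = 0` is the rare-disease limit in
#' which controls are distributed as the general population. Admissibility
#' requires every genotype penetrance \eqn{r_g K / m \le 1}, where `m` is the
#' locus mean relative risk.
#'
#' @param loci A list of [locus_model()] objects (or a single one).
#' @param prevalence Population disease risk `K` in \[0, 1).
#' @return An object of class `panel_model`.
#' @examples
#' panel_model(list(locus_model("a", 0.3, 1.5), locus_model("b", 0.4, 1.3)))
#' @export
panel_model <- function(loci, prevalence = 0) {
  if (inherits(loci, "locus_model")) loci <- list(loci)
  stopifnot(is.list(loci), length(loci) >= 1L)
  ok <- vapply(loci, inherits, logical(1), what = "locus_model")
  if (!all(ok)) stop("all elements of 'loci' must be locus_model objects", call. = FALSE)
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      prevalence < 0 || prevalence >= 1)
    stop("'prevalence' must be a single number in [0, 1)", call. = FALSE)
  nm <- vapply(loci, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicated locus names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "),
                              call. = FALSE)
  names(loci) <- nm
  obj <- structure(list(loci = loci, prevalence = prevalence),
                   class = "panel_model")
  # admissibility: penetrance of the riskiest genotype cannot exceed 1
  for (lo in loci) {
    m <- mean_relative_risk(lo)
    if (max(1, lo$r1, lo$r2) * prevalence / m > 1)
      stop("inadmissible panel: penetrance r_g*K/m > 1 at locus ", lo$name,
           call. = FALSE)
  }
  obj
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf("<panel_model> %d loci, prevalence K=%.4g\n",
              length(x$loci), x$prevalence))
  for (lo in x$loci) print(lo)
  invisible(x)
}

#' Hardy-Weinberg genotype frequencies of a locus
#'
#' @param locus A [locus_model()].
#' @return Numeric triple `(q^2, 2pq, p^2)` over risk-allele dosages 0, 1, 2.
#' @export
genotype_frequencies <- function(locus) {
  stopifnot(inherits(locus, "locus_model"))
  p <- locus$p; q <- 1 - p
  c(q^2, 2 * p * q, p^2)
}

#' Mean relative risk of a locus
#'
#' The population mean genotype relative risk
#' \eqn{m = q^2 + 2pq\,r_1 + p^2 r_2}; equals 1 for a null locus.
#'
#' @inheritParams genotype_frequencies
#' @return Scalar `m`.
#' @export
mean_relative_risk <- function(locus) {
  f <- genotype_frequencies(locus)
  sum(f * c(1, locus$r1, locus$r2))
}

#' Genotype distribution among cases
#'
#' Bayes' rule under the relative-risk model: \eqn{f_{case}(g) = f(g) r_g / m}
#' with \eqn{r_0 = 1}. Independent of prevalence.
#'
#' @inheritParams genotype_frequencies
#' @return Numeric triple over dosages 0, 1, 2; sums to 1.
#' @export
case_genotype_frequencies <- function(locus) {
  f <- genotype_frequencies(locus)
  r <- c(1, locus$r1, locus$r2)
  f * r / sum(f * r)
}

#' Genotype distribution among unaffected controls
#'
#' Exact control distribution at prevalence `K`:
#' \eqn{f_{ctrl}(g) = f(g)\,(1 - r_g K/m) / (1 - K)}. Reduces to the population
#' (Hardy-Weinberg) distribution exactly at `K = 0`, the rare-disease limit.
#'
#' @inheritParams genotype_frequencies
#' @param prevalence Population disease risk `K` in \[0, 1).
#' @return Numeric triple over dosages 0, 1, 2; sums to 1.
#' @export
control_genotype_frequencies <- function(locus, prevalence = 0) {
  f <- genotype_frequencies(locus)
  r <- c(1, locus$r1, locus$r2)
  m <- sum(f * r)
  pen <- r * prevalence / m               # genotype penetrances
  if (any(pen > 1))
    stop("inadmissible model: genotype penetrance r_g*K/m exceeds 1", call. = FALSE)
  f * (1 - pen) / (1 - prevalence)
}

# per-locus case/control frequency matrices for a panel (3 x L each)
panel_frequencies <- function(panel) {
  stopifnot(inherits(panel, "panel_model"))
  fc <- vapply(panel$loci, case_genotype_frequencies, numeric(3))
  ft <- vapply(panel$loci, control_genotype_frequencies, numeric(3),
               prevalence = panel$prevalence)
  list(case = matrix(fc, nrow = 3), control = matrix(ft, nrow = 3))
}

#' Log-likelihood-ratio risk score
#'
#' The Bayes-optimal score for discriminating cases from controls under the
#' generative panel model: \eqn{\sum_l \log(f_{case}(g_l)/f_{ctrl}(g_l))},
#' additive over loci and identically 0 for an all-null panel.
#'
#' @param genotypes Integer dosages in \{0, 1, 2\}: a vector of length L
#'   (one subject) or an n-by-L matrix (n subjects). No missing values.
#' @param panel A [panel_model()].
#' @return Numeric score(s), one per subject.
#' @export
llr_score <- function(genotypes, panel) {
  stopifnot(inherits(panel, "panel_model"))
  L <- length(panel$loci)
  g <- if (is.matrix(genotypes)) genotypes else matrix(genotypes, nrow = 1L)
  if (ncol(g) != L)
    stop("genotype vector length (", ncol(g), ") does not match panel size (",
         L, ")", call. = FALSE)
  if (anyNA(g))
    stop("missing dosages are not scoreable; impute or drop subjects first",
         call. = FALSE)
  if (!all(g %in% 0:2))
    stop("dosages must be 0, 1 or 2", call. = FALSE)
  fr <- panel_frequencies(panel)
  lw <- log(fr$case) - log(fr$control)    # 3 x L log weight table
  s <- numeric(nrow(g))
  for (l in seq_len(L)) s <- s + lw[g[, l] + 1L, l]
  s
}

#' Exact AUC ceiling of a SNP panel
#'
#' Enumerates all \eqn{3^L} genotype profiles, scores each with the
#' Bayes-optimal [llr_score()], and computes the exact area under the ROC
#' curve of that ranking:
#' \eqn{\sum_{i,j} f_{case}(i) f_{ctrl}(j) [s_i > s_j] + \tfrac12 \sum f_{case} f_{ctrl} [s_i = s_j]}.
#' This is the best AUC any classifier using only these genotypes can attain;
#' it is 0.5 for a null panel and never below 0.5. Ties (frequent, since an
#' L-SNP panel has only \eqn{3^L} distinct profiles) receive half credit,
#' consistent with the Mann-Whitney estimator.
#'
#' @param panel A [panel_model()] with at most `max_loci` loci.
#' @param max_loci Enumeration guard; default 15 (about 1.4e7 profiles).
#' @return Exact AUC in \[0.5, 1\].
#' @examples
#' lo <- locus_model("x", p = 0.5, r1 = 2, r2 = 4)
#' analytic_panel_auc(panel_model(lo))  # 0.625
#' @export
analytic_panel_auc <- function(panel, max_loci = 15L) {
  stopifnot(inherits(panel, "panel_model"))
  L <- length(panel$loci)
  if (L > max_loci)
    stop("refusing to enumerate 3^", L, " genotype profiles (guard: ",
         max_loci, " loci)", call. = FALSE)
  fr <- panel_frequencies(panel)
  lw <- log(fr$case) - log(fr$control)
  # joint probabilities and scores over all 3^L profiles, built locus by locus
  pc <- 1; pt <- 1; sc <- 0
  for (l in seq_len(L)) {
    pc <- as.vector(outer(fr$case[, l], pc))
    pt <- as.vector(outer(fr$control[, l], pt))
    sc <- as.vector(outer(lw[, l], sc, `+`))
  }
  o <- order(sc)
  sc <- sc[o]; pc <- pc[o]; pt <- pt[o]
  # group scores equal up to numerical tolerance (sums of logs in permuted order)
  grp <- cumsum(c(TRUE, diff(sc) > 1e-9))
  pcg <- rowsum(pc, grp)[, 1L]
  ptg <- rowsum(pt, grp)[, 1L]
  cum_below <- c(0, cumsum(ptg))[seq_along(ptg)]
  sum(pcg * (cum_below + 0.5 * ptg))
}
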