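---
title: "Models and methods behind snpfrr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind snpfrr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpfrr)
```

# The question the package answers

Genome-wide association studies keep delivering SNPs whose association with a
disease is statistically unimpeachable yet whose effect sizes are modest
(per-allele odds ratios around 1.3-1.5). `snpfrr` quantifies what such loci
are actually worth clinically, from two complementary angles:

1. **Familial aggregation**: how much of the disease's familial clustering
   does a locus explain? This is the familial relative risk
   $\lambda^*$ and its share $\log\lambda^*/\log\lambda_o$ of the overall
   familial relative risk $\lambda_o$.
2. **Individual prediction**: how well can genotypes at these loci separate
   future cases from controls? This is the cross-validated AUC of a panel of
   classifiers, and — more fundamentally — the *exact ceiling* on the AUC
   that any classifier could reach given the panel's generative law.

The worked defaults emulate a Han-Chinese papillary thyroid carcinoma
case-control study: 845 cases, 1005 controls, four risk SNPs with per-allele
odds ratios 1.53, 1.53, 1.31, 1.41, and an overall familial relative risk of
$\lambda_o = 8.48$ for thyroid cancer.

# The single-locus model

A biallelic locus has risk-allele frequency $p$ ($q = 1-p$) with genotypes in
Hardy-Weinberg equilibrium, so dosages $g \in \{0,1,2\}$ occur with
frequencies $(q^2, 2pq, p^2)$. Genotype relative risks are $r_1$
(heterozygote) and $r_2$ (risk homozygote) against the common-homozygote
baseline; the multiplicative special case $r_2 = r_1^2$ is the default. The
population mean relative risk is $m = q^2 + 2pq\,r_1 + p^2 r_2$.

Bayes' rule gives the genotype distribution in cases,
$f_{case}(g) = f(g)\,r_g/m$, and in unaffected controls at prevalence $K$,
$f_{ctrl}(g) = f(g)(1 - r_g K/m)/(1-K)$. At $K = 0$ — the rare-disease limit
used by default, appropriate for thyroid cancer — controls are distributed as
the population. A panel is inadmissible if any genotype penetrance
$r_g K / m$ exceeds 1.

## Familial relative risk

The risk to the offspring of an affected individual, relative to the
population risk, that is attributable to one codominant locus is

$$\lambda^* \;=\; \frac{p\,(p r_2 + q r_1)^2 + q\,(p r_1 + q)^2}
                       {(p^2 r_2 + 2pq\,r_1 + q^2)^2}.$$

Two properties are worth internalising. First, $\lambda^*$ is invariant
under relabelling which allele is "risk" (with the baseline rescaled):
$\lambda^*(p, r_1, r_2) = \lambda^*(1-p,\, r_1/r_2,\, 1/r_2)$. Second,
$\lambda^* \ge 1$ for *any* $(r_1, r_2) \ne (1,1)$ — any genotype-risk
variation induces positive familial aggregation. The boundary matters for
inference: under a null generative model the sampling distribution of
$\hat\lambda^*$ sits entirely at or above 1, so a percentile bootstrap
interval hugs 1 from above rather than covering it — the correct behaviour
for a boundary parameter, and what the test suite asserts.

Because the closed form is easy to mistranscribe, the package carries an
independent oracle, `mc_family_frr()`: parent pairs drawn from HWE, one
offspring by Mendelian transmission, parents importance-weighted by their
genotype relative risk, and the population mean risk estimated from an
independent draw. Its batch-mean standard errors let the test suite demand
agreement within 3 Monte-Carlo SE across a grid of $(p, r_1, r_2)$.

Under multiplicative joint effects across independent loci, the familial
relative risks multiply, so shares on the log scale add:
`proportion_of_familial_risk()` is exactly additive, and `frr_table()` sums
the per-SNP proportions into a total.

## Estimation from case-control counts

$r_1$ and $r_2$ are estimated as the dosage-1-vs-0 and dosage-2-vs-0 odds
ratios with Woolf (log-normal) intervals; a Haldane-Anscombe +0.5 correction
is applied to a 2x2 table only when it has a zero cell. The risk-allele
frequency is counted from controls only, which are the population proxy
(cases are risk-enriched). A SNP with a single observed dosage class is
*monomorphic* and is reported as a not-applicable row, never as numbers —
mirroring how a locus undetected in a population must appear in the report —
and it is excluded from the summed proportion.

Confidence intervals are subject-level nonparametric bootstrap, B = 1000,
percentile method, seeded. Every statistic involved depends on the data only
through the per-group genotype counts, so resampling subjects is
distributionally identical to drawing each group's counts from a multinomial
with the observed proportions; the implementation uses the multinomial form,
which makes the 100-repetition coverage experiment in the acceptance suite
cheap. Published per-SNP intervals for this design are often far tighter than
a subject-level bootstrap can produce and their construction is typically
unstated; the package makes no attempt to imitate them, and its report keeps
a placeholder (`NA`) p-value column rather than invent a test it cannot
attribute.

# The AUC ceiling

The Bayes-optimal score for the generative model is the log-likelihood ratio
$s(g) = \sum_l \log f_{case}(g_l)/f_{ctrl}(g_l)$, additive over loci. With
$L$ loci there are only $3^L$ genotype profiles, so the AUC of the optimal
ranking can be *enumerated exactly*:

$$\mathrm{AUC} = \sum_{i,j} f_{case}(i)\, f_{ctrl}(j)\,\big[ s_i > s_j \big]
  \;+\; \tfrac12 \sum_{i} f_{case}(i)\, f_{ctrl}(i'),\; s_i = s_{i'}.$$

Ties get half credit, consistent with the Mann-Whitney estimator; they are
unavoidable (a 4-SNP panel has 81 profiles) and ignoring them would bias the
ceiling. Profile scores that differ by less than $10^{-9}$ are treated as
tied, because the same profile sum assembled in a different locus order can
differ in the last floating-point bits. Enumeration is guarded at 15 loci
($3^{15} \approx 1.4\times10^7$ profiles).

No classifier that sees only these genotypes can beat this number. For the
default study-emulating panel the ceiling is about 0.64 — the observed
cross-validated AUC range of 0.54-0.60 is not a shortcoming of any
particular learner, but close to all the panel has to give.

# The synthetic world

`simulate_cohort()` draws case dosages from $f_{case}$, control dosages from
$f_{ctrl}$, loci independent (linkage equilibrium), and covariates
independent of genotype. The defaults state the emulated study: 845 cases /
1005 controls and the four-SNP panel above. The risk-allele frequencies
(0.35, 0.39, 0.45, 0.35) are this package's assumptions — the study
publishes none — chosen once in the common-variant range typical of GWAS
hits; they are echoed in every output header and not revisited.

Covariates are designed to reproduce the study's structure: gender and age
carry *no* information about status beyond group membership, so adding them
to a classifier cannot genuinely help. Cases are 75% female (papillary
thyroid carcinoma is roughly 3:1 female) with ages $N(45, 12^2)$; controls
are 70% female with ages $N(45, 14^2)$; both are truncated to an enrollment
window of 20-72 years and rounded to whole years. The control pool is
female-enriched and age-broadened relative to a general population — as a
pool recruited to support matching of a female-predominant disease must be —
yet still leaner in females than the case series, so matching is non-trivial.

What the generator does *not* emulate: linkage disequilibrium between loci,
population stratification, relatedness, Hardy-Weinberg violations,
genotyping-error confusion structure, or covariates that truly predict
status. A green test therefore establishes correctness of the machinery on
the stated world, not robustness to those real-data complications.

## Matched resampling

`matched_resample()` builds 1000 gender/age-matched cohorts: each case draws
one control uniformly from its (gender x 5-year age bin) stratum, fresh
draws in every replicate. Draws are **with replacement** within a replicate
by default. The without-replacement variant (`replace = FALSE`) demands that
every stratum's controls outnumber its cases; with only ~19% more controls
than cases overall, binomial stratum noise defeats that for essentially any
realistic covariate design — whereas with-replacement draws need only one
control per case stratum, which is the natural reading of "resampling" and
is what the generator's stated world satisfies for every seed tried. Either
way each replicate's matched control multiset has exactly the cases' gender
and age-bin distribution by construction. Strict mode refuses an
unmatchable stratum by name; permissive mode widens that stratum's age
caliper by one bin (sacrificing exact bin identity there) and records the
widening.

# Cross-validated prediction

`evaluate_cv()` runs stratified 10-fold cross-validation: folds are
stratified by case status (per-fold class counts within one subject of
proportionality), missing dosages are mode-imputed *from the training fold
only*, models never see test subjects, and each fold yields a tie-aware
Mann-Whitney AUC with a Hanley-McNeil 95% interval plus
sensitivity/specificity/accuracy at threshold 0.5. Fold metrics are averaged
arithmetically; the reported interval range runs from the smallest fold
lower bound to the largest fold upper bound, which describes fold-level
uncertainty, not a pooled interval.

Numerical choices, all fixed and documented rather than tuned: threshold 0.5
(the neutral convention; with cases the minority at 845/1850 it reproduces
the characteristic sensitivity < specificity pattern), knn with k = 21 and
city-block distance on dosage vectors — every neighbour tied at the k-th
distance is included, because dosage vectors tie massively over $3^L$
profiles and an index-order tie-break would leak the row order of simulated
cohorts — naive Bayes with additive smoothing 1 (categorical genotypes and
gender, Gaussian age), and logistic regression by iteratively reweighted
least squares (maximum 100 iterations, tolerance $10^{-8}$). The
`bayes_optimal` entry wraps the log-likelihood-ratio score and requires the
true generating panel, so it is usable on synthetic data only; it turns the
analytic ceiling into an empirical benchmark no other entry should beat.
Tree ensembles, SVMs and the rest attach through `register_classifier()`;
their internals are deliberately out of scope.

# Design decisions that were genuinely open

* **CI method for $\lambda^*$** — unstated in the emulated study; seeded
  percentile bootstrap chosen for reproducibility, divergence from published
  interval widths accepted and documented rather than imitated.
* **Prevalence** — controls default to the rare-disease limit $K=0$; the
  exact-$K$ control distribution is retained for sensitivity analysis.
* **Matching replacement policy** — with replacement (see above), the single
  deliberate deviation from the stricter variant, forced by arithmetic at
  the stated sample sizes.
* **Hyperparameters** — fixed defaults, no tuning loop: any "optimally
  selected" search would be impossible to reproduce and would leak test
  information unless nested, and nesting is not warranted at AUC
  differences this small.
* **Degenerate inputs** — monomorphic SNPs flow end-to-end as N.A. rows;
  single-class folds are flagged and excluded from means; degenerate AUCs of
  0 or 1 yield clipped, flagged Hanley-McNeil intervals.

# Limitations

The familial relative risk formula assumes a codominant autosomal locus,
HWE, and no shared environment; $\lambda_o$ enters only through the log
ratio, so its own (considerable) estimation uncertainty is not propagated.
The AUC ceiling is exact only for the stated generative law — linkage
disequilibrium or interactions would change it in either direction. All
empirical claims in this vignette are computed by the package's test suite
or acceptance script; none are transcribed from elsewhere.
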