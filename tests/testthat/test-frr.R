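test_that("familial_relative_risk matches hand-computed closed form", {
  expect_equal(familial_relative_risk(locus_model("x", 0.3, 1, 1)), 1.0)
  expect_equal(familial_relative_risk(locus_model("x", 0.8, 1, 1)), 1.0)
  # hand arithmetic: numerator 1.8450867, m^2 = 1.3456^2 = 1.8106394
  expect_equal(familial_relative_risk(locus_model("x", 0.5, 1.32, 1.7424)),
               1.019025, tolerance = 1e-5)
})

test_that("lambda* is invariant under allele relabeling with baseline rescaling", {
  for (p in c(0.1, 0.3, 0.5, 0.7, 0.9))
    for (r1 in c(1.3, 2))
      for (r2 in c(r1, r1^2, 2 * r1)) {
        a <- familial_relative_risk(locus_model("x", p, r1, r2))
        b <- familial_relative_risk(locus_model("x", 1 - p, r1 / r2, 1 / r2))
        expect_equal(a, b, tolerance = 1e-12)
      }
})

test_that("proportion_of_familial_risk has the log-ratio properties", {
  expect_equal(proportion_of_familial_risk(1), 0)
  expect_equal(proportion_of_familial_risk(8.48, 8.48), 1)
  # additivity over independent loci under multiplicative joint effects
  la <- 1.04; lb <- 1.11
  expect_equal(proportion_of_familial_risk(la * lb),
               proportion_of_familial_risk(la) + proportion_of_familial_risk(lb),
               tolerance = 1e-12)
  # strictly increasing in lambda*
  frr <- seq(1.0, 3, by = 0.1)
  expect_true(all(diff(proportion_of_familial_risk(frr)) > 0))
  expect_warning(proportion_of_familial_risk(0.98), "negative")
})

test_that("genotype relative risks are the dosage odds ratios with Woolf CIs", {
  cnt <- as_genotype_counts("s", c(50, 40, 10), c(60, 35, 5))
  est <- estimate_genotype_relative_risks(cnt)
  expect_equal(est$r1, (40 * 60) / (50 * 35), tolerance = 1e-12)
  expect_equal(est$r2, (10 * 60) / (50 * 5), tolerance = 1e-12)
  expect_false(est$na)
  # Woolf interval straddles the point estimate on the log scale
  expect_true(est$r1_ci[1] < est$r1 && est$r1 < est$r1_ci[2])
  se2 <- sqrt(1/10 + 1/5 + 1/50 + 1/60)
  expect_equal(est$r2_ci, 2.4 * exp(c(-1, 1) * qnorm(0.975) * se2),
               tolerance = 1e-10)
  # identical distributions: no association
  same <- estimate_genotype_relative_risks(
    as_genotype_counts("s", c(30, 20, 10), c(30, 20, 10)))
  expect_equal(c(same$r1, same$r2), c(1, 1))
  # zero cell triggers the Haldane-Anscombe correction, stays finite
  zc <- estimate_genotype_relative_risks(
    as_genotype_counts("s", c(50, 40, 3), c(60, 35, 0)))
  expect_true(is.finite(zc$r2) && zc$r2 > 0)
  # monomorphic SNP reported as not-applicable, never as numbers
  mono <- estimate_genotype_relative_risks(
    as_genotype_counts("s", c(10, 0, 0), c(10, 0, 0)))
  expect_true(mono$na)
  expect_true(is.na(mono$r1) && is.na(mono$r2))
})

test_that("risk-allele frequency is counted from controls", {
  expect_equal(estimate_risk_allele_frequency(
    as_genotype_counts("s", c(1, 1, 1), c(60, 35, 5))), 45 / 200)
  expect_equal(estimate_risk_allele_frequency(
    as_genotype_counts("s", c(1, 1, 1), c(25, 50, 25))), 0.5)
  expect_equal(estimate_risk_allele_frequency(
    as_genotype_counts("s", c(0, 0, 5), c(0, 0, 50))), 1.0)
})

test_that("mc_family_frr is a deterministic unbiased oracle for lambda*", {
  lo <- locus_model("x", 0.5, 1.32, 1.7424)
  a <- mc_family_frr(lo, n_families = 5e4, seed = 11)
  b <- mc_family_frr(lo, n_families = 5e4, seed = 11)
  expect_identical(a, b)
  # a null locus is exact (all weights 1), so the MC error is identically 0
  null <- mc_family_frr(locus_model("x", 0.4, 1, 1), n_families = 5e4, seed = 3)
  expect_lte(abs(null$frr - 1), 3 * null$se + 1e-12)
  big <- mc_family_frr(lo, n_families = 1e6, seed = 5)
  expect_lt(abs(big$frr - familial_relative_risk(lo)), 3 * big$se)
})

test_that("bootstrap FRR intervals are seeded, cover the null, flag monomorphs", {
  df <- data.frame(subject_id = sprintf("s%03d", 1:800),
                   status = rep(c(1L, 0L), each = 400),
                   gender = rep(c("F", "M"), 400),
                   age = rep(40:49, 80))
  set.seed(42)
  df$rs_null <- sample(0:2, 800, replace = TRUE, prob = c(0.36, 0.48, 0.16))
  df$rs_mono <- 0L
  ds <- genotype_dataset(df)
  r1 <- frr_bootstrap_ci(ds, "rs_null", B = 300, seed = 9)
  r2 <- frr_bootstrap_ci(ds, "rs_null", B = 300, seed = 9)
  expect_identical(r1, r2)
  # lambda* >= 1 for any genotype-risk variation, so under a null generative
  # model the estimate sits at the boundary: the interval hugs 1 from above
  expect_lt(r1$frr - 1, 0.005)
  expect_lt(r1$frr_ci[1] - 1, 1e-3)
  expect_true(r1$frr_ci[1] <= r1$frr && r1$frr <= r1$frr_ci[2])
  mono <- frr_bootstrap_ci(ds, "rs_mono", B = 300, seed = 9)
  expect_true(mono$na)
})

test_that("frr_table mirrors the per-SNP report shape and sums proportions", {
  lo <- locus_model("rs_sig", 0.35, 1.8)
  cc <- cohort_config(panel = panel_model(lo), n_case = 2000, n_control = 2000,
                      monomorphic_snps = "rs_gone", seed = 77)
  ds <- simulate_cohort(cc)
  tab <- frr_table(ds, B = 200, seed = 5)
  expect_s3_class(tab, "frr_table")
  expect_equal(tab$snp, c("rs_sig", "rs_gone"))
  expect_true(tab$na_flag[2])
  expect_true(all(is.na(tab[2, c("frr", "proportion_pct")])))
  # monomorphic row excluded from the total
  expect_equal(attr(tab, "total_proportion_pct"), tab$proportion_pct[1])
  expect_true(tab$frr_lo[1] <= tab$frr[1] && tab$frr[1] <= tab$frr_hi[1])
  # refuse single-class data
  only_ctrl <- genotype_dataset(as.data.frame(ds)[ds$status == 0L, ])
  expect_error(frr_table(only_ctrl, B = 0), "cases and controls")
})

test_that("closed-form lambda* matches the Monte-Carlo family oracle on a grid", {
  # reduced grid here; the full spec grid runs in the acceptance suite
  for (p in c(0.1, 0.5, 0.9))
    for (r1 in c(1.3, 2)) {
      lo <- locus_model("x", p, r1, r1^2)
      mc <- mc_family_frr(lo, n_families = 1e5, seed = round(1e4 * p) + r1 * 10)
      expect_lt(abs(mc$frr - familial_relative_risk(lo)), 3 * mc$se)
    }
})
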