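# Independent brute-force AUC: enumerate every case-control pair, half credit
# for ties. Quadratic; only for small inputs.
auc_brute <- function(scores, labels) {
  cs <- scores[labels == 1L]
  ct <- scores[labels == 0L]
  mean(outer(cs, ct, ">") + 0.5 * outer(cs, ct, "=="))
}

# tiny deterministic dataset builder for io/structure tests
tiny_dataset <- function() {
  genotype_dataset(data.frame(
    subject_id = c("a", "b", "c", "d"),
    status = c(1L, 1L, 0L, 0L),
    gender = c("F", "M", "F", "M"),
    age = c(40, 55, 41, 56),
    rs1 = c(2L, 1L, 0L, 1L),
    rs2 = c(0L, NA, 1L, 2L)))
}

# single-locus cohort straight from the generative frequencies (no covariates),
# used where only genotype counts matter
simulate_counts <- function(locus, n_case, n_control, seed) {
  set.seed(seed)
  fc <- case_genotype_frequencies(locus)
  ft <- control_genotype_frequencies(locus)
  as_counts <- function(n, f) as.vector(stats::rmultinom(1, n, f))
  list(case = as_counts(n_case, fc), control = as_counts(n_control, ft))
}
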