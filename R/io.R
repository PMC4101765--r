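#' Read a genotype dataset from TSV
#'
#' Canonical interchange format: a tab-separated table with header columns
#' `subject_id`, `status` (1 = case, 0 = control), `gender` (M/F), `age`, then
#' one column per SNP with dosages 0/1/2 or `NA`. Lines starting with `#`
#' (provenance headers written by this package) are ignored. Validation
#' errors name the offending line.
#'
#' @param path File path.
#' @return A [genotype_dataset()].
#' @export
read_genotype_tsv <- function(path) {
  if (!file.exists(path)) stop("cannot read ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = "NA", check.names = FALSE)
  required <- c("subject_id", "status", "gender", "age")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(path, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  # line-numbered dosage validation before the constructor's generic checks
  n_header <- 1L + sum(startsWith(readLines(path, n = 200L), "#"))
  for (s in setdiff(names(df), required)) {
    v <- df[[s]]
    bad <- which(!(is.na(v) | v %in% 0:2))
    if (length(bad))
      stop(path, " line ", bad[1] + n_header, ": SNP ", s, " has dosage '",
           v[bad[1]], "' (must be 0, 1, 2 or NA)", call. = FALSE)
  }
  ds <- genotype_dataset(df)
  miss <- vapply(snp_names(ds), function(s) mean(is.na(ds[[s]])), numeric(1))
  message(sprintf("read %d subjects (%d cases / %d controls), %d SNPs; ",
                  nrow(ds), sum(ds$status == 1L), sum(ds$status == 0L),
                  length(miss)),
          "per-SNP missing rates: ",
          paste(sprintf("%s=%.3f", names(miss), miss), collapse = ", "))
  ds
}

#' Write a genotype dataset to TSV
#'
#' Writes the canonical TSV (see [read_genotype_tsv()]) with `#`-prefixed
#' provenance header lines carrying the seed and config hash when supplied.
#'
#' @param dataset A [genotype_dataset()].
#' @param path Output file path.
#' @param seed,config Optional provenance stamped into the header.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(dataset, path, seed = NULL, config = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  if (!is.null(config))
    writeLines(sprintf("# config_hash: %s", config_hash(config)), con)
  utils::write.table(as.data.frame(dataset), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a SNP panel specification
#'
#' Delimited table with columns `name`, `p`, `r1` and optionally `r2`
#' (defaulting to `r1^2`); an optional `# prevalence: K` header line sets the
#' panel prevalence (default 0, the rare-disease limit).
#'
#' @param path File path (tab- or whitespace-separated).
#' @return A [panel_model()].
#' @export
read_panel_tsv <- function(path) {
  if (!file.exists(path)) stop("cannot read ", path, call. = FALSE)
  lines <- readLines(path)
  prev <- 0
  hdr <- grep("^#\\s*prevalence\\s*:", lines, value = TRUE)
  if (length(hdr)) prev <- as.numeric(sub("^#\\s*prevalence\\s*:\\s*", "", hdr[1]))
  df <- utils::read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("name", "p", "r1") %in% names(df)))
    stop(path, ": panel file needs columns name, p, r1 (r2 optional)",
         call. = FALSE)
  if (is.null(df$r2)) df$r2 <- df$r1^2
  loci <- lapply(seq_len(nrow(df)), function(i)
    locus_model(df$name[i], df$p[i], df$r1[i], df$r2[i]))
  panel_model(loci, prevalence = prev)
}

#' Write a SNP panel specification
#'
#' @param panel A [panel_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel_tsv <- function(panel, path) {
  stopifnot(inherits(panel, "panel_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# prevalence: %g", panel$prevalence), con)
  df <- do.call(rbind, lapply(panel$loci, function(lo)
    data.frame(name = lo$name, p = lo$p, r1 = lo$r1, r2 = lo$r2)))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Extracts risk-allele dosages from the GT field of a standard VCF (via the
#' VariantAnnotation package) and merges them with a phenotype table by
#' subject ID. Dosage is the count of risk alleles; the risk allele defaults
#' to ALT and can be flipped to REF per SNP. Half-missing genotypes (e.g.
#' `./1`) become `NA`.
#'
#' @param path VCF file path (plain or bgzipped).
#' @param phenotype Data.frame with columns `subject_id`, `status`, `gender`,
#'   `age` covering exactly the VCF samples.
#' @param snps SNP IDs to extract (default: all VCF records).
#' @param risk_allele Named character vector mapping SNP ID to `"ALT"`
#'   (default) or `"REF"`.
#' @return A [genotype_dataset()].
#' @export
read_vcf <- function(path, phenotype, snps = NULL, risk_allele = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf requires the VariantAnnotation package", call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path)
  gt_all <- VariantAnnotation::geno(vcf)$GT
  ids <- rownames(gt_all)
  if (is.null(snps)) snps <- ids
  absent <- setdiff(snps, ids)
  if (length(absent))
    stop("SNP(s) absent from VCF: ", paste(absent, collapse = ", "),
         call. = FALSE)
  gt <- gt_all[snps, , drop = FALSE]
  samples <- colnames(gt)
  mism <- c(setdiff(samples, phenotype$subject_id),
            setdiff(phenotype$subject_id, samples))
  if (length(mism))
    stop("subject mismatch between VCF and phenotype table: ",
         paste(unique(mism), collapse = ", "), call. = FALSE)
  dos <- vapply(snps, function(s) {
    alt_is_risk <- is.null(risk_allele) ||
      is.na(risk_allele[s]) || identical(unname(risk_allele[s]), "ALT")
    vapply(gt[s, ], function(g) {
      al <- strsplit(g, "[/|]")[[1]]
      if (any(al == ".") || !length(al)) return(NA_integer_)
      alt_count <- sum(al != "0")
      if (alt_is_risk) alt_count else length(al) - alt_count
    }, integer(1))
  }, integer(ncol(gt)))
  dos <- matrix(dos, nrow = ncol(gt), dimnames = list(samples, snps))
  ph <- phenotype[match(samples, phenotype$subject_id), , drop = FALSE]
  genotype_dataset(cbind(ph, as.data.frame(dos)))
}

#' Write a familial-relative-risk table
#'
#' @param tab An [frr_table()] result.
#' @param path Output TSV path.
#' @param seed,config Optional provenance stamped into the header.
#' @return `path`, invisibly.
#' @export
write_frr_tsv <- function(tab, path, seed = NULL, config = NULL) {
  stopifnot(inherits(tab, "frr_table"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  if (!is.null(config))
    writeLines(sprintf("# config_hash: %s", config_hash(config)), con)
  writeLines(sprintf("# lambda_o: %g", attr(tab, "lambda_o")), con)
  writeLines(sprintf("# total_proportion_pct: %.6f",
                     attr(tab, "total_proportion_pct")), con)
  utils::write.table(as.data.frame(tab), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write matched-resampling replicate index sets
#'
#' Long format: columns `replicate`, `role` (case/control), `subject_id`.
#'
#' @param matches A [matched_resample()] result.
#' @param dataset The dataset the indices refer to.
#' @param path Output TSV path.
#' @param seed,config Optional provenance stamped into the header.
#' @return `path`, invisibly.
#' @export
write_matches_tsv <- function(matches, dataset, path, seed = NULL,
                              config = NULL) {
  stopifnot(inherits(matches, "matched_replicates"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  if (!is.null(config))
    writeLines(sprintf("# config_hash: %s", config_hash(config)), con)
  rows <- do.call(rbind, lapply(seq_along(matches$replicates), function(i) {
    r <- matches$replicates[[i]]
    data.frame(replicate = i,
               role = rep(c("case", "control"),
                          c(length(r$case_idx), length(r$control_idx))),
               subject_id = dataset$subject_id[c(r$case_idx, r$control_idx)])
  }))
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cross-validated performance table
#'
#' @param tab A [performance_table()] result.
#' @param path Output TSV path.
#' @param seed,config Optional provenance stamped into the header.
#' @return `path`, invisibly.
#' @export
write_performance_tsv <- function(tab, path, seed = NULL, config = NULL) {
  stopifnot(inherits(tab, "performance_table"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  if (!is.null(config))
    writeLines(sprintf("# config_hash: %s", config_hash(config)), con)
  utils::write.table(as.data.frame(tab), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
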