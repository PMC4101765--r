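#' Case-control genotype dataset
#'
#' Validates and tags a data.frame as a genotype dataset: one row per subject
#' with columns `subject_id` (unique), `status` (1 = case, 0 = control),
#' `gender` ("M"/"F"), `age` (non-negative), followed by one dosage column per
#' SNP with values 0/1/2 or `NA` for a failed genotype. SNP column order is
#' fixed and shared across subjects.
#'
#' @param df A data.frame with the columns above.
#' @return The same data.frame with class `genotype_dataset`.
#' @export
genotype_dataset <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("subject_id", "status", "gender", "age")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id values: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "),
         call. = FALSE)
  if (anyNA(df$status) || !all(df$status %in% c(0L, 1L)))
    stop("status must be 1 (case) or 0 (control), non-missing", call. = FALSE)
  if (anyNA(df$gender) || !all(df$gender %in% c("M", "F")))
    stop("gender must be 'M' or 'F', non-missing", call. = FALSE)
  if (anyNA(df$age) || any(df$age < 0))
    stop("age must be non-negative and non-missing", call. = FALSE)
  snps <- setdiff(names(df), required)
  for (s in snps) {
    v <- df[[s]]
    bad <- which(!(is.na(v) | v %in% 0:2))
    if (length(bad))
      stop("SNP ", s, ": dosage must be 0, 1, 2 or NA (first offending row: ",
           bad[1], ")", call. = FALSE)
    df[[s]] <- as.integer(v)
  }
  df$status <- as.integer(df$status)
  class(df) <- c("genotype_dataset", "data.frame")
  df
}

#' SNP column names of a genotype dataset
#'
#' @param dataset A [genotype_dataset()].
#' @return Character vector of SNP columns, in dataset order.
#' @export
snp_names <- function(dataset) {
  stopifnot(is.data.frame(dataset))
  setdiff(names(dataset), c("subject_id", "status", "gender", "age"))
}

#' Dosage matrix of a genotype dataset
#'
#' @param dataset A [genotype_dataset()].
#' @return Integer matrix, subjects by SNPs (NA preserved).
#' @export
dosage_matrix <- function(dataset) {
  snps <- snp_names(dataset)
  as.matrix(as.data.frame(dataset)[, snps, drop = FALSE])
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("<genotype_dataset> %d subjects (%d cases / %d controls), %d SNPs\n",
              nrow(x), sum(x$status == 1L), sum(x$status == 0L),
              length(snp_names(x))))
  NextMethod()
}
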