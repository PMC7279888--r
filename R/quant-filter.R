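# Pre-processing of LFQ matrices: log2 transform, consistency filter,
# per-batch median normalization. No imputation is performed anywhere.

#' Log2-transform raw LFQ intensities
#'
#' Positive intensities become `log2(value)`; zeros (a common missing-value
#' encoding in raw search-engine exports) become missing. Negative
#' intensities are an error.
#'
#' @param pm a [protein_matrix()] with `scale = "raw"`.
#' @return The matrix on log2 scale (`scale = "log2"`).
#' @export
log2_transform <- function(pm) {
  stopifnot(inherits(pm, "protein_matrix"))
  if (pm$scale != "raw") stop("matrix is already log2 transformed")
  e <- pm$exprs
  if (any(e < 0, na.rm = TRUE)) stop("negative intensity encountered")
  e[!is.na(e) & e == 0] <- NA_real_
  e <- log2(e)
  protein_matrix(e, gene = pm$annot$gene, scale = "log2")
}

#' Consistency filter for one contrast
#'
#' Retains exactly the proteins quantified in every sample of the given
#' (model, age) contrast, i.e. in all transgenic and all wild-type samples
#' of that age group. Only such consistently quantified proteins enter
#' statistical testing; nothing is imputed.
#'
#' @param pm a log2 [protein_matrix()].
#' @param sheet a [sample_sheet()].
#' @param model model label.
#' @param age age in months.
#' @param per_genotype if `TRUE`, require completeness separately within
#'   each genotype instead of across all contrast samples (equivalent here,
#'   exposed for alternative designs with unequal group sizes).
#' @return The `protein_matrix` restricted to consistently quantified rows;
#'   all sample columns are kept untouched.
#' @export
filter_consistent <- function(pm, sheet, model, age, per_genotype = FALSE) {
  stopifnot(inherits(pm, "protein_matrix"))
  grp <- contrast_samples(sheet, model, age)
  if (length(grp$tg) < 2 || length(grp$wt) < 2) {
    stop(sprintf("contrast %s/%sm needs >=2 samples per genotype", model, age))
  }
  ids <- c(grp$tg, grp$wt)
  missing_cols <- setdiff(ids, colnames(pm$exprs))
  if (length(missing_cols)) {
    stop("sample(s) absent from matrix: ", paste(missing_cols, collapse = ", "))
  }
  keep <- rowSums(is.na(pm$exprs[, ids, drop = FALSE])) == 0
  pm[keep, ]
}

#' Batch-wise median normalization
#'
#' Within each batch (by default every model x age group, because LC-MS/MS
#' data for different age groups is typically acquired in separate batches),
#' every sample column is shifted so that its median over the proteins
#' mutually observed in all batch samples equals the batch's
#' median-of-medians. Missing cells stay missing; the operation is
#' idempotent and never equalizes levels across batches.
#'
#' @param pm a log2 [protein_matrix()].
#' @param sheet a [sample_sheet()].
#' @param batch_key character vector of sheet columns defining batches
#'   (default `c("model", "age_months")`).
#' @return The normalized `protein_matrix`.
#' @export
normalize_by_batch <- function(pm, sheet, batch_key = c("model", "age_months")) {
  stopifnot(inherits(pm, "protein_matrix"))
  if (pm$scale != "log2") stop("normalize_by_batch expects a log2 matrix")
  e <- pm$exprs
  sheet <- sheet[sheet$sample_id %in% colnames(e), , drop = FALSE]
  batch <- interaction(sheet[, batch_key, drop = FALSE], drop = TRUE)
  for (b in levels(batch)) {
    ids <- sheet$sample_id[batch == b]
    sub <- e[, ids, drop = FALSE]
    if (any(colSums(!is.na(sub)) == 0)) {
      stop(sprintf("batch '%s' has a fully-missing sample column", b))
    }
    shared <- rowSums(is.na(sub)) == 0
    if (!any(shared)) {
      stop(sprintf("batch '%s' has no mutually-observed proteins", b))
    }
    med <- apply(sub[shared, , drop = FALSE], 2, stats::median)
    target <- stats::median(med)
    e[, ids] <- sweep(sub, 2, med - target, "-")
  }
  protein_matrix(e, gene = pm$annot$gene, scale = "log2")
}
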