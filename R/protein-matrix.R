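#' Protein quantification matrix
#'
#' Container for a proteins x samples table of label-free quantification
#' (LFQ) intensities. Rows are keyed by protein-group accession and carry a
#' gene symbol; columns are keyed by sample id and must match a sample
#' sheet. Values are either log2 intensities or raw intensities (tracked by
#' the `scale` field); missing quantifications are `NA`.
#'
#' @param exprs numeric matrix, proteins in rows (rownames = accessions),
#'   samples in columns (colnames = sample ids).
#' @param gene character vector of gene symbols, one per row. Multi-gene
#'   protein groups may be given as `"Sym1;Sym2"`; the first entry is kept
#'   and uppercased.
#' @param scale `"log2"` (default) or `"raw"`.
#' @return An object of class `protein_matrix`: a list with elements
#'   `exprs` (the matrix), `annot` (data.frame with `accession`, `gene`)
#'   and `scale`.
#' @export
protein_matrix <- function(exprs, gene = NULL, scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  exprs <- as.matrix(exprs)
  if (is.null(rownames(exprs))) {
    stop("exprs must have rownames (protein-group accessions)")
  }
  if (anyDuplicated(rownames(exprs))) {
    dup <- unique(rownames(exprs)[duplicated(rownames(exprs))])
    stop("duplicate accession(s): ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (is.null(colnames(exprs))) {
    stop("exprs must have colnames (sample ids)")
  }
  storage.mode(exprs) <- "double"
  if (any(is.infinite(exprs), na.rm = TRUE)) {
    stop("intensities must be finite where present")
  }
  if (is.null(gene)) gene <- rownames(exprs)
  gene <- normalize_gene_symbol(gene)
  structure(
    list(
      exprs = exprs,
      annot = data.frame(
        accession = rownames(exprs), gene = gene,
        row.names = NULL, stringsAsFactors = FALSE
      ),
      scale = scale
    ),
    class = "protein_matrix"
  )
}

# first semicolon-separated entry, uppercased
normalize_gene_symbol <- function(gene) {
  toupper(sub(";.*$", "", as.character(gene)))
}

#' @export
dim.protein_matrix <- function(x) dim(x$exprs)

#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf(
    "protein_matrix: %d proteins x %d samples [%s scale], %.1f%% missing\n",
    nrow(x$exprs), ncol(x$exprs), x$scale,
    100 * mean(is.na(x$exprs))
  ))
  invisible(x)
}

#' Subset a protein matrix
#'
#' @param x a [protein_matrix()].
#' @param i row index (integer, logical or accession character).
#' @param j column index (integer, logical or sample-id character).
#' @param ... ignored.
#' @return A `protein_matrix` restricted to the selected rows/columns.
#' @export
`[.protein_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$exprs))
  if (missing(j)) j <- seq_len(ncol(x$exprs))
  e <- x$exprs[i, j, drop = FALSE]
  g <- x$annot$gene[match(rownames(e), x$annot$accession)]
  protein_matrix(e, gene = g, scale = x$scale)
}

#' Validate a sample sheet
#'
#' A sample sheet describes one sample per row with columns `sample_id`,
#' `model`, `genotype` (`"TG"` or `"WT"`), `age_months` and `replicate`.
#' It defines which matrix columns enter each (model, age) contrast and the
#' normalization batches.
#'
#' @param df data.frame with the required columns.
#' @return The validated data.frame (invisibly classed `sample_sheet`).
#' @export
sample_sheet <- function(df) {
  req <- c("sample_id", "model", "genotype", "age_months", "replicate")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("sample ids must be unique")
  if (!all(df$genotype %in% c("TG", "WT"))) {
    stop("genotype must be 'TG' or 'WT'")
  }
  df$age_months <- as.numeric(df$age_months)
  df$sample_id <- as.character(df$sample_id)
  df$model <- as.character(df$model)
  class(df) <- unique(c("sample_sheet", class(df)))
  df
}

# sample ids of the two genotype groups of one (model, age) contrast
contrast_samples <- function(sheet, model, age) {
  sel <- sheet$model == model & sheet$age_months == age
  if (!any(sel)) {
    stop(sprintf("empty contrast: no samples for model '%s' at %s months", model, age))
  }
  list(
    tg = sheet$sample_id[sel & sheet$genotype == "TG"],
    wt = sheet$sample_id[sel & sheet$genotype == "WT"]
  )
}

#' Read a protein quantification table
#'
#' Reads a tab-separated proteins x samples table as exported by common
#' search engines. The `dialect` controls which columns hold intensities,
#' the value scale, missing-value encodings and decoy/contaminant handling:
#'
#' * `"generic"`: columns `accession`, `gene`, then one column per sample;
#'   values already log2 transformed; empty cells and `NaN` are missing.
#'   This is the format written by [write_protein_matrix()].
#' * `"raw"`: like `"generic"` but raw (linear) intensities; `0` additionally
#'   encodes a missing quantification.
#' * `"maxquant"`: MaxQuant proteinGroups export. Intensity columns are those
#'   starting with `intensity_prefix` (default `"LFQ intensity "`), raw
#'   scale with `0` missing; rows flagged `+` in `Reverse` or
#'   `Potential contaminant` are skipped and reported.
#'
#' @param path path to a TSV file.
#' @param dialect one of `"generic"`, `"raw"`, `"maxquant"`.
#' @param intensity_prefix prefix identifying intensity columns (maxquant
#'   dialect; default `"LFQ intensity "`).
#' @return A [protein_matrix()] (raw dialects keep `scale = "raw"`; apply
#'   [log2_transform()] before analysis). Skipped decoy/contaminant rows are
#'   attached as a data.frame in `attr(, "skipped")`.
#' @export
read_protein_matrix <- function(path, dialect = c("generic", "raw", "maxquant"),
                                intensity_prefix = "LFQ intensity ") {
  dialect <- match.arg(dialect)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA", "NaN"))
  skipped <- data.frame(row = integer(), accession = character(),
                        reason = character(), stringsAsFactors = FALSE)
  if (dialect == "maxquant") {
    acc_col <- intersect(c("Protein IDs", "Majority protein IDs", "accession"), names(df))[1]
    gene_col <- intersect(c("Gene names", "gene"), names(df))[1]
    if (is.na(acc_col)) stop("maxquant dialect: no 'Protein IDs' column found")
    int_cols <- grep(paste0("^", intensity_prefix), names(df), value = TRUE)
    if (!length(int_cols)) {
      stop("no intensity columns matched prefix '", intensity_prefix, "'")
    }
    flag <- function(col) {
      if (col %in% names(df)) !is.na(df[[col]]) & df[[col]] == "+" else rep(FALSE, nrow(df))
    }
    drop <- flag("Reverse") | flag("Potential contaminant") | flag("Contaminant")
    if (any(drop)) {
      reason <- ifelse(flag("Reverse")[drop], "reverse/decoy", "contaminant")
      skipped <- data.frame(row = which(drop), accession = df[[acc_col]][drop],
                            reason = reason, stringsAsFactors = FALSE)
      df <- df[!drop, , drop = FALSE]
    }
    e <- as.matrix(df[, int_cols, drop = FALSE])
    storage.mode(e) <- "double"
    colnames(e) <- sub(paste0("^", intensity_prefix), "", int_cols)
    rownames(e) <- df[[acc_col]]
    e[e == 0] <- NA_real_
    gene <- if (!is.na(gene_col)) df[[gene_col]] else rownames(e)
    out <- protein_matrix(e, gene = gene, scale = "raw")
  } else {
    if (!all(c("accession", "gene") %in% names(df))) {
      stop("generic dialect expects 'accession' and 'gene' as first columns")
    }
    int_cols <- setdiff(names(df), c("accession", "gene"))
    if (!length(int_cols)) stop("no intensity columns found")
    e <- as.matrix(df[, int_cols, drop = FALSE])
    storage.mode(e) <- "double"
    rownames(e) <- df$accession
    if (dialect == "raw") e[e == 0] <- NA_real_
    out <- protein_matrix(e, gene = df$gene,
                          scale = if (dialect == "raw") "raw" else "log2")
  }
  attr(out, "skipped") <- skipped
  out
}

#' Write a protein matrix as TSV
#'
#' Writes the `generic` dialect understood by [read_protein_matrix()]:
#' columns `accession`, `gene`, then one column per sample id; missing
#' values as empty cells.
#'
#' @param pm a [protein_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_matrix <- function(pm, path) {
  df <- data.frame(accession = pm$annot$accession, gene = pm$annot$gene,
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(pm$exprs, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write a sample sheet
#'
#' @param path TSV path with columns `sample_id`, `model`, `genotype`,
#'   `age_months`, `replicate`.
#' @return [read_sample_sheet()] returns a validated [sample_sheet()];
#'   [write_sample_sheet()] returns `path` invisibly.
#' @export
read_sample_sheet <- function(path) {
  sample_sheet(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_sample_sheet
#' @param sheet a [sample_sheet()].
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
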