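# Proteome-transcriptome concordance and term enrichment against a custom
# background. Gene matching is by uppercased symbol (first entry of
# multi-gene protein groups); unmatched genes are counted, never guessed.

#' Classify proteome vs transcriptome regulation overlap
#'
#' For every gene quantified in both data sets, assigns one concordance
#' class: `unidirectional` (regulated in both, same sign), `inverse`
#' (regulated in both, opposite sign), `protein_only`, `transcript_only`,
#' or `neither`. Genes present in only one table are excluded from the
#' class universe and counted separately.
#'
#' @param protein_table data.frame with columns `gene`, `regulated`
#'   (logical) and `direction` (`up`/`down`/`none`), e.g. derived from the
#'   12-month cross-model intersection.
#' @param transcript_table data.frame with the same columns for the
#'   comparison transcriptome.
#' @return list of class `overlap_classes`: `classes` (per-gene data.frame)
#'   and `summary` (named counts, including `quantified_both`,
#'   `protein_unmatched`, `transcript_unmatched`; duplicate genes dropped
#'   with a warning and counted in `dropped_duplicates`).
#' @export
overlap_classes <- function(protein_table, transcript_table) {
  prep <- function(df, what) {
    df$gene <- toupper(as.character(df$gene))
    dup <- duplicated(df$gene)
    if (any(dup)) {
      warning(sum(dup), " duplicate ", what, " gene(s) dropped after uppercasing")
    }
    df[!dup, , drop = FALSE]
  }
  pt <- prep(protein_table, "protein")
  tt <- prep(transcript_table, "transcript")
  shared <- intersect(pt$gene, tt$gene)
  pi <- match(shared, pt$gene); ti <- match(shared, tt$gene)
  p_reg <- pt$regulated[pi]; t_reg <- tt$regulated[ti]
  p_dir <- pt$direction[pi]; t_dir <- tt$direction[ti]
  cls <- ifelse(p_reg & t_reg & p_dir == t_dir, "unidirectional",
         ifelse(p_reg & t_reg, "inverse",
         ifelse(p_reg, "protein_only",
         ifelse(t_reg, "transcript_only", "neither"))))
  classes <- data.frame(gene = shared, class = cls,
                        protein_direction = p_dir, transcript_direction = t_dir,
                        stringsAsFactors = FALSE)
  summary <- c(
    quantified_both = length(shared),
    unidirectional = sum(cls == "unidirectional"),
    inverse = sum(cls == "inverse"),
    protein_only = sum(cls == "protein_only"),
    transcript_only = sum(cls == "transcript_only"),
    neither = sum(cls == "neither"),
    protein_unmatched = sum(!pt$gene %in% shared),
    transcript_unmatched = sum(!tt$gene %in% shared),
    dropped_duplicates = (nrow(protein_table) - nrow(pt)) +
      (nrow(transcript_table) - nrow(tt))
  )
  structure(list(classes = classes, summary = summary),
            class = "overlap_classes")
}

#' Percent change between two counts
#'
#' `100 * (new - old) / old`, rounded half away from zero to the requested
#' number of decimals - the convention used when reporting e.g. the gain in
#' peptide or protein identifications between acquisition methods.
#'
#' @param old reference count (> 0).
#' @param new new count.
#' @param decimals decimal places of the result (default 1).
#' @return The rounded percentage.
#' @examples
#' percent_change(53912, 74281)      # 37.8
#' percent_change(4412, 5699, 0)     # 29
#' @export
percent_change <- function(old, new, decimals = 1) {
  if (old <= 0) stop("old count must be > 0")
  round_half_up(100 * (new - old) / old, decimals)
}

#' Gene set collection
#'
#' Named gene sets plus the background universe against which enrichment is
#' evaluated. The background should be the set of consistently quantified
#' proteins of the experiment (a custom background), not a whole-genome
#' default.
#'
#' @param sets named list of character vectors (gene symbols).
#' @param background character vector of gene symbols.
#' @param descriptions optional named character vector of set descriptions.
#' @return list of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, background, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) stop("sets must be named")
  sets <- lapply(sets, function(s) unique(toupper(s)))
  if (any(lengths(sets) == 0)) stop("every gene set must be non-empty")
  background <- unique(toupper(background))
  outside <- lapply(sets, function(s) setdiff(s, background))
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets, background = background,
                 descriptions = descriptions,
                 outside_background = outside),
            class = "gene_set_collection")
}

#' Read gene sets in GMT format
#'
#' Tab-separated, one set per line: set name, description, then member gene
#' symbols.
#'
#' @param path GMT file path.
#' @param background background gene symbols for the returned collection.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, background) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  nm <- vapply(parts, `[[`, "", 1)
  desc <- stats::setNames(vapply(parts, `[[`, "", 2), nm)
  sets <- stats::setNames(lapply(parts, function(p) p[-(1:2)]), nm)
  gene_set_collection(sets, background, desc)
}

#' Write gene sets in GMT format
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric term enrichment against a custom background
#'
#' For each term, tests over-representation of the query genes with the
#' one-sided (upper tail) hypergeometric test: with background size `N`,
#' term size in background `m`, query size `n` and overlap `k`,
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, m, n)`. Fold enrichment is
#' `(k/n) / (m/N)`. Query genes outside the background are dropped with a
#' warning.
#'
#' @param query character vector of gene symbols.
#' @param collection a [gene_set_collection()].
#' @param adjust if `TRUE`, append Benjamini-Hochberg adjusted p-values
#'   (off by default; downstream cluster scoring uses raw p-values).
#' @return data.frame sorted by p-value: `term`, `description`, `k`, `m`,
#'   `n`, `N`, `fold_enrichment`, `p_value` (and `p_adjust` if requested),
#'   with the query genes of each term in a `genes` column.
#' @export
term_enrichment <- function(query, collection, adjust = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(toupper(query))
  if (!length(query)) stop("empty query")
  outside <- setdiff(query, collection$background)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the background dropped")
    query <- setdiff(query, outside)
  }
  if (!length(query)) stop("empty query after dropping genes outside background")
  N <- length(collection$background)
  n <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    term_bg <- intersect(collection$sets[[nm]], collection$background)
    m <- length(term_bg)
    hits <- intersect(query, term_bg)
    k <- length(hits)
    p <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    data.frame(term = nm, description = collection$descriptions[[nm]],
               k = k, m = m, n = n, N = N,
               fold_enrichment = if (m > 0) (k / n) / (m / N) else NA_real_,
               p_value = p,
               genes = paste(sort(hits), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, -out$fold_enrichment), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster enrichment score
#'
#' Minus log10 of the geometric mean of the member-term p-values,
#' equivalently the mean of the `-log10 p` values. A cluster of terms all
#' at p = 0.05 scores `-log10(0.05) = 1.301`, the conventional threshold
#' for calling a cluster enriched.
#'
#' @param term_p_values p-values of the terms grouped into one cluster
#'   (all in (0, 1]).
#' @return The enrichment score.
#' @export
cluster_score <- function(term_p_values) {
  if (!length(term_p_values)) stop("need at least one p-value")
  if (any(term_p_values <= 0) || any(term_p_values > 1)) {
    stop("p-values must be in (0, 1]")
  }
  mean(-log10(term_p_values))
}

#' Read / write a transcript regulation table
#'
#' TSV with columns `gene`, `log2_fc`, `regulated`, `direction`.
#'
#' @param path file path.
#' @return data.frame; the writer returns `path` invisibly.
#' @export
read_transcript_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene", "log2_fc", "regulated", "direction")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("transcript table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$regulated <- as.logical(df$regulated)
  df
}

#' @rdname read_transcript_table
#' @param table transcript table data.frame.
#' @export
write_transcript_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
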