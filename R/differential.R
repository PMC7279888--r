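# Per-contrast differential abundance: log2 fold change, pooled two-sample
# t-test, SAM-style s0-moderated statistic and permutation-based FDR.
#
# The regulation call used throughout follows the thresholds of the LFQ
# workflow this package implements: |log2 FC| > 0.5, p < 0.05 and
# significance after permutation FDR control (target 5%, s0 = 0.1).

#' FDR configuration
#'
#' Parameters of the permutation-based FDR estimation.
#'
#' @param target_fdr target false discovery rate in (0,1); default 0.05.
#' @param s0 non-negative moderation constant added to the pooled standard
#'   error in the denominator of the test statistic; default 0.1. It damps
#'   the significance of proteins whose variance is accidentally tiny.
#' @param n_permutations maximum number of label shuffles; default 250.
#'   When the number of distinct informative label assignments is smaller
#'   (20 - 2 = 18 for a 3 vs 3 contrast), all of them are enumerated
#'   exactly instead.
#' @param balanced if `TRUE` (default) only label assignments in which each
#'   pseudo-group mixes both genotypes are used as the null, excluding the
#'   observed assignment and its mirror. Including the identity assignment
#'   would bound the estimated FDR below by 2/(number of assignments) and
#'   make small targets unreachable.
#' @param seed integer seed for permutation sampling (only used when
#'   sampling is needed; exact enumeration is deterministic).
#' @return A list of class `fdr_config`.
#' @export
fdr_config <- function(target_fdr = 0.05, s0 = 0.1, n_permutations = 250,
                       balanced = TRUE, seed = NULL) {
  if (!(target_fdr > 0 && target_fdr < 1)) stop_config("target_fdr", "must be in (0,1)")
  if (s0 < 0) stop_config("s0", "must be >= 0")
  if (n_permutations < 1) stop_config("n_permutations", "must be >= 1")
  structure(list(target_fdr = target_fdr, s0 = s0,
                 n_permutations = n_permutations, balanced = balanced,
                 seed = seed),
            class = "fdr_config")
}

#' Log2 fold change between transgenic and wild-type samples
#'
#' @param tg_values,wt_values observed log2 intensities (>= 2 each).
#' @return `mean(tg_values) - mean(wt_values)`.
#' @export
log2_fold_change <- function(tg_values, wt_values) {
  check_groups(tg_values, wt_values)
  mean(tg_values) - mean(wt_values)
}

check_groups <- function(tg, wt) {
  if (length(tg) < 2 || length(wt) < 2 || anyNA(tg) || anyNA(wt)) {
    stop("need >= 2 observed values per group (apply the consistency filter first)")
  }
}

# pooled-variance standard error of the mean difference
pooled_se <- function(tg, wt) {
  n1 <- length(tg); n2 <- length(wt)
  sp2 <- ((n1 - 1) * stats::var(tg) + (n2 - 1) * stats::var(wt)) / (n1 + n2 - 2)
  sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Two-sided Student's t-test (pooled variance)
#'
#' Two-sample t-test with pooled variance, the test applied per protein to
#' each transgenic vs wild-type age-group contrast. Degenerate inputs use
#' documented conventions: zero pooled variance with equal means gives
#' p = 1 (t = 0); zero pooled variance with unequal means gives p = 0.
#'
#' @inheritParams log2_fold_change
#' @param welch if `TRUE` use the Welch unequal-variance form instead.
#' @return Two-sided p-value.
#' @export
student_t_test <- function(tg_values, wt_values, welch = FALSE) {
  check_groups(tg_values, wt_values)
  diff <- mean(tg_values) - mean(wt_values)
  if (welch) {
    n1 <- length(tg_values); n2 <- length(wt_values)
    v1 <- stats::var(tg_values) / n1; v2 <- stats::var(wt_values) / n2
    se <- sqrt(v1 + v2)
    df <- if (se > 0) (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1)) else 1
  } else {
    se <- pooled_se(tg_values, wt_values)
    df <- length(tg_values) + length(wt_values) - 2
  }
  if (se == 0) return(if (diff == 0) 1 else 0)
  2 * stats::pt(-abs(diff / se), df = df)
}

#' s0-moderated test statistic
#'
#' The SAM-style statistic `d = (mean_tg - mean_wt) / (se_pooled + s0)`. With
#' `s0 = 0` it reduces exactly to the Student t statistic; with `s0 > 0` it
#' stays finite for zero-variance proteins.
#'
#' @inheritParams log2_fold_change
#' @param s0 non-negative moderation constant (default 0.1).
#' @return The moderated statistic `d`.
#' @export
s0_statistic <- function(tg_values, wt_values, s0 = 0.1) {
  check_groups(tg_values, wt_values)
  if (s0 < 0) stop_config("s0", "must be >= 0")
  (mean(tg_values) - mean(wt_values)) / (pooled_se(tg_values, wt_values) + s0)
}

# vectorized d statistics for a complete matrix slice
matrix_d_stats <- function(e, idx1, idx2, s0) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(e[, idx1, drop = FALSE])
  m2 <- rowMeans(e[, idx2, drop = FALSE])
  ss1 <- rowSums((e[, idx1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((e[, idx2, drop = FALSE] - m2)^2)
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  list(diff = m1 - m2, se = se, d = (m1 - m2) / (se + s0))
}

# all size-n1 subsets of seq_len(n1+n2) as pseudo-group-1; optionally only
# those mixing both true groups (drops identity and mirror)
null_assignments <- function(n1, n2, balanced = TRUE) {
  splits <- utils::combn(n1 + n2, n1)
  if (balanced) {
    in1 <- colSums(splits <= n1)        # members drawn from true group 1
    splits <- splits[, in1 > 0 & in1 < n1, drop = FALSE]
  }
  splits
}

# number of values >= each cutoff; vals need not be sorted
count_ge <- function(vals, cutoffs) {
  sv <- sort(vals)
  length(sv) - findInterval(cutoffs, sv, left.open = TRUE)
}

#' Permutation-based FDR control for one contrast
#'
#' Computes the observed moderated statistic `|d|` for every protein, builds
#' a null distribution by recomputing `|d|` under genotype-label shuffles,
#' and estimates, for every candidate cutoff `c`,
#' `FDR(c) = mean_permutations #\{null |d| >= c\} / max(1, #\{observed |d| >= c\})`.
#' The raw estimate is monotonized (running minimum towards lenient
#' cutoffs, as in Benjamini-Hochberg step-up) and the smallest cutoff with
#' estimated FDR at or below the target is selected; proteins with
#' `|d| >=` cutoff are flagged. When the number of distinct informative
#' label assignments does not exceed `n_permutations`, all of them are
#' enumerated, making the result fully deterministic; otherwise assignments
#' are sampled with replacement under the configured seed.
#'
#' @param pm a [protein_matrix()] (or plain matrix) with no missing values
#'   in the contrast columns, i.e. after [filter_consistent()].
#' @param tg,wt sample ids (or column indices) of the transgenic and
#'   wild-type groups; at least 2 each.
#' @param config an [fdr_config()].
#' @return A list of class `permutation_fdr`: `d_stat` (named vector),
#'   `significant` (named logical), `cutoff`, `est_fdr` (estimate at the
#'   chosen cutoff), `n_null_sets`, `exact` (whether enumeration was
#'   exhaustive) and `table` (per-cutoff estimates).
#' @export
permutation_fdr <- function(pm, tg, wt, config = fdr_config()) {
  e <- if (inherits(pm, "protein_matrix")) pm$exprs else as.matrix(pm)
  if (is.character(tg)) tg <- match(tg, colnames(e))
  if (is.character(wt)) wt <- match(wt, colnames(e))
  if (anyNA(tg) || anyNA(wt)) stop("tg/wt sample ids not found in matrix")
  if (length(tg) < 2 || length(wt) < 2) stop("need >= 2 samples per group")
  sl <- e[, c(tg, wt), drop = FALSE]
  if (anyNA(sl)) stop("missing values in contrast slice; apply filter_consistent() first")
  n1 <- length(tg); n2 <- length(wt)
  idx1 <- seq_len(n1); idx2 <- n1 + seq_len(n2)

  obs <- matrix_d_stats(sl, idx1, idx2, config$s0)
  d_obs <- obs$d
  usable <- rep(TRUE, length(d_obs))
  if (config$s0 == 0 && any(obs$se == 0)) {
    warning(sum(obs$se == 0), " zero-variance protein(s) excluded (s0 = 0)")
    usable <- obs$se > 0
    d_obs[!usable] <- NA_real_
  }

  splits <- null_assignments(n1, n2, balanced = config$balanced)
  exact <- ncol(splits) <= config$n_permutations
  if (!exact) {
    pick <- with_seed(config$seed, sample.int(ncol(splits), config$n_permutations,
                                              replace = TRUE))
    splits <- splits[, pick, drop = FALSE]
  }
  n_sets <- ncol(splits)

  null_abs <- vector("list", n_sets)
  all_idx <- seq_len(n1 + n2)
  for (k in seq_len(n_sets)) {
    g1 <- splits[, k]
    nd <- matrix_d_stats(sl, g1, setdiff(all_idx, g1), config$s0)$d
    null_abs[[k]] <- abs(nd[usable])
  }
  null_pool <- unlist(null_abs, use.names = FALSE)

  a_obs <- abs(d_obs[usable])
  cutoffs <- sort(unique(a_obs))
  n_obs_ge <- count_ge(a_obs, cutoffs)
  e_null_ge <- count_ge(null_pool, cutoffs) / n_sets
  fdr_raw <- e_null_ge / pmax(1, n_obs_ge)
  fdr <- cummin(fdr_raw)                 # non-increasing in the cutoff

  ok <- which(fdr <= config$target_fdr)
  cutoff <- if (length(ok)) cutoffs[min(ok)] else Inf
  significant <- !is.na(d_obs) & abs(d_obs) >= cutoff
  names(significant) <- names(d_obs) <- rownames(sl)

  structure(list(
    d_stat = d_obs,
    significant = significant,
    cutoff = cutoff,
    est_fdr = if (is.finite(cutoff)) fdr[min(ok)] else NA_real_,
    n_null_sets = n_sets,
    exact = exact,
    table = data.frame(cutoff = cutoffs, n_obs = n_obs_ge,
                       e_null = e_null_ge, fdr_raw = fdr_raw, fdr = fdr)
  ), class = "permutation_fdr")
}

#' Three-condition regulation call
#'
#' A protein is called `up` when its log2 fold change exceeds
#' `fc_threshold`, its t-test p-value is below `p_threshold` and it is
#' significant after FDR filtering; `down` symmetrically; otherwise `none`.
#'
#' @param log2_fc,p_value,fdr_significant per-protein statistics.
#' @param fc_threshold log2 fold-change threshold (default 0.5).
#' @param p_threshold p-value threshold (default 0.05).
#' @return Character vector in `c("up", "down", "none")`.
#' @export
call_regulation <- function(log2_fc, p_value, fdr_significant,
                            fc_threshold = 0.5, p_threshold = 0.05) {
  sig <- p_value < p_threshold & fdr_significant
  ifelse(sig & log2_fc > fc_threshold, "up",
         ifelse(sig & log2_fc < -fc_threshold, "down", "none"))
}

#' Run the full differential analysis of one contrast
#'
#' Applies the consistency filter, computes per-protein log2 fold changes,
#' pooled t-test p-values, moderated `d` statistics and permutation-FDR
#' flags, and calls regulation.
#'
#' @inheritParams filter_consistent
#' @param config an [fdr_config()].
#' @param fc_threshold,p_threshold regulation thresholds
#'   (defaults 0.5 and 0.05).
#' @return A data.frame of class `contrast_result` with one row per tested
#'   protein: `accession`, `gene`, `model`, `age_months`, `log2_fc`,
#'   `p_value`, `d_stat`, `fdr_significant`, `direction`, `n_tg`, `n_wt`.
#'   The chosen `|d|` cutoff and estimated FDR are attached as attributes.
#' @export
run_contrast <- function(pm, sheet, model, age, config = fdr_config(),
                         fc_threshold = 0.5, p_threshold = 0.05) {
  fpm <- filter_consistent(pm, sheet, model, age)
  grp <- contrast_samples(sheet, model, age)
  e <- fpm$exprs[, c(grp$tg, grp$wt), drop = FALSE]
  n1 <- length(grp$tg); n2 <- length(grp$wt)
  st <- matrix_d_stats(e, seq_len(n1), n1 + seq_len(n2), config$s0)
  tval <- ifelse(st$se > 0, st$diff / st$se, ifelse(st$diff == 0, 0, Inf))
  p <- 2 * stats::pt(-abs(tval), df = n1 + n2 - 2)
  perm <- permutation_fdr(fpm, grp$tg, grp$wt, config)
  out <- data.frame(
    accession = fpm$annot$accession,
    gene = fpm$annot$gene,
    model = model,
    age_months = age,
    log2_fc = st$diff,
    p_value = p,
    d_stat = perm$d_stat,
    fdr_significant = unname(perm$significant),
    n_tg = n1,
    n_wt = n2,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  out$direction <- call_regulation(out$log2_fc, out$p_value, out$fdr_significant,
                                   fc_threshold, p_threshold)
  attr(out, "cutoff") <- perm$cutoff
  attr(out, "est_fdr") <- perm$est_fdr
  class(out) <- c("contrast_result", class(out))
  out
}

#' Volcano-plot export table
#'
#' One row per tested protein with the quantities of a volcano plot:
#' log2 fold change, minus log10 p-value and the regulated flag.
#'
#' @param contrast a `contrast_result` from [run_contrast()].
#' @return data.frame with columns `accession`, `gene`, `log2_fc`,
#'   `minus_log10_p`, `d_stat`, `fdr_significant`, `regulated`, `direction`.
#' @export
volcano_table <- function(contrast) {
  data.frame(
    accession = contrast$accession,
    gene = contrast$gene,
    log2_fc = contrast$log2_fc,
    minus_log10_p = -log10(contrast$p_value),
    d_stat = contrast$d_stat,
    fdr_significant = contrast$fdr_significant,
    regulated = contrast$direction != "none",
    direction = contrast$direction,
    stringsAsFactors = FALSE
  )
}

#' Read / write a contrast result as CSV
#'
#' @param contrast a `contrast_result` data.frame.
#' @param path output path.
#' @return `path` invisibly; [read_contrast_csv()] returns the data.frame.
#' @export
write_contrast_csv <- function(contrast, path) {
  utils::write.csv(as.data.frame(contrast), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contrast_csv
#' @export
read_contrast_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("contrast_result", class(df))
  df
}
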