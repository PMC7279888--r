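# Shared fixtures and independent brute-force oracles. Oracles are written
# as plain loops, deliberately not reusing package internals.

# small complete log2 matrix with a matching sheet for one contrast
toy_contrast <- function(n_proteins = 12, n_rep = 3, seed = 1, effect = NULL) {
  set.seed(seed)
  ids <- c(sprintf("TG_r%d", 1:n_rep), sprintf("WT_r%d", 1:n_rep))
  e <- matrix(rnorm(n_proteins * 2 * n_rep, 25, 1), n_proteins,
              dimnames = list(sprintf("P%03d", 1:n_proteins), ids))
  if (!is.null(effect)) e[seq_along(effect), 1:n_rep] <- e[seq_along(effect), 1:n_rep] + effect
  sheet <- sample_sheet(data.frame(
    sample_id = ids, model = "M1",
    genotype = rep(c("TG", "WT"), each = n_rep),
    age_months = 3, replicate = rep(1:n_rep, 2)
  ))
  list(pm = protein_matrix(e), sheet = sheet, e = e)
}

# brute-force permutation FDR: plain loops over all label splits in which
# each pseudo-group mixes both true groups
oracle_permutation_fdr <- function(e, tg_idx, wt_idx, s0, target) {
  d_of <- function(g1, g2) {
    out <- numeric(nrow(e))
    for (i in seq_len(nrow(e))) {
      x <- e[i, g1]; y <- e[i, g2]
      sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
        (length(x) + length(y) - 2)
      se <- sqrt(sp2 * (1 / length(x) + 1 / length(y)))
      out[i] <- (mean(x) - mean(y)) / (se + s0)
    }
    out
  }
  all_cols <- c(tg_idx, wt_idx)
  splits <- combn(all_cols, length(tg_idx))
  mixed <- apply(splits, 2, function(g1) any(g1 %in% tg_idx) && any(g1 %in% wt_idx))
  splits <- splits[, mixed, drop = FALSE]
  d_obs <- d_of(tg_idx, wt_idx)
  null_abs <- c()
  for (k in seq_len(ncol(splits))) {
    g1 <- splits[, k]
    null_abs <- c(null_abs, abs(d_of(g1, setdiff(all_cols, g1))))
  }
  cutoffs <- sort(unique(abs(d_obs)))
  fdr <- numeric(length(cutoffs))
  for (j in seq_along(cutoffs)) {
    n_obs <- sum(abs(d_obs) >= cutoffs[j])
    e_null <- sum(null_abs >= cutoffs[j]) / ncol(splits)
    fdr[j] <- e_null / max(1, n_obs)
  }
  fdr <- cummin(fdr)
  ok <- which(fdr <= target)
  cutoff <- if (length(ok)) cutoffs[min(ok)] else Inf
  list(d = d_obs, cutoff = cutoff, flags = abs(d_obs) >= cutoff)
}

# independent per-gene overlap classifier
oracle_overlap_class <- function(p_reg, p_dir, t_reg, t_dir) {
  if (p_reg && t_reg) {
    if (p_dir == t_dir) "unidirectional" else "inverse"
  } else if (p_reg) {
    "protein_only"
  } else if (t_reg) {
    "transcript_only"
  } else {
    "neither"
  }
}

ref_sim_config <- function(seed, n_proteins = 2000) {
  simulation_config(n_proteins = n_proteins, effect_size_range = c(1, 3),
                    seed = seed)
}
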