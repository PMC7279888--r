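# Synthetic study generator. Emulates the design of a two-model amyloidosis
# time course: for each model, transgenic and wild-type groups of
# n_replicates animals at each age, log-normal protein intensities, planted
# regulation whose onset age defines the temporal stage (the first age is a
# pre-deposition baseline and never carries an effect), a model-specific
# onset lag, left-censored (intensity-dependent, MNAR) missingness, and
# per-batch/per-sample offsets so that the per-age-group normalization is
# exercised. Ground truth is returned for recovery scoring.

#' Simulation configuration
#'
#' @param n_proteins number of protein groups.
#' @param n_replicates animals per genotype group (default 3).
#' @param ages ordered ages in months (default `c(1, 3, 6, 12)`); the first
#'   age is the pre-deposition baseline, the remaining three are the
#'   early/middle/advanced onset ages.
#' @param models model labels; the first is the reference (earlier-onset)
#'   model (default `c("APPPS1", "APPKI")`).
#' @param frac_regulated fraction of proteins with planted regulation.
#' @param stage_mix proportions of regulated proteins per onset stage
#'   (early, middle, advanced); must sum to 1. Default `c(0.15, 0.25,
#'   0.60)`, the shape observed for staged amyloid-response proteins.
#' @param effect_size_range interval of absolute planted log2 fold changes
#'   (default `c(0.5, 3)`).
#' @param onset_lag per-model onset delay in number of ages: model `i`
#'   lags the reference by `(i-1) * onset_lag` positions in the age list,
#'   capped at the final age (default 1).
#' @param baseline_log2_mean,baseline_log2_sd log2-intensity distribution
#'   of protein baselines (defaults 25 and 2, typical of LFQ intensities).
#' @param noise_sd within-group log2 standard deviation (default 0.3).
#' @param missing_rate_at_floor missingness probability approached by the
#'   lowest-intensity proteins (default 0.3). Missingness is logistic
#'   left-censoring on the true log2 value: midpoint two baseline SDs below
#'   the baseline mean, scale half a baseline SD.
#' @param batch_offset_sd SD of the additive per-(model x age) batch offset
#'   (default 0.3).
#' @param sample_offset_sd SD of the additive per-sample offset that
#'   normalization must remove (default 0.15).
#' @param transcript_mix proportions of regulated proteins whose transcript
#'   behaves concordantly, inversely, or not at all (protein_only); must
#'   sum to 1.
#' @param transcript_only_rate fraction of null proteins regulated only on
#'   the transcript level (default 0.2; transcript-only regulation is the
#'   largest discordance class in proteome/transcriptome comparisons).
#' @param seed integer seed; equal configs and seeds give bit-identical
#'   output.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_proteins = 2000,
                              n_replicates = 3,
                              ages = c(1, 3, 6, 12),
                              models = c("APPPS1", "APPKI"),
                              frac_regulated = 0.1,
                              stage_mix = c(early = 0.15, middle = 0.25, advanced = 0.60),
                              effect_size_range = c(0.5, 3),
                              onset_lag = 1,
                              baseline_log2_mean = 25,
                              baseline_log2_sd = 2,
                              noise_sd = 0.3,
                              missing_rate_at_floor = 0.3,
                              batch_offset_sd = 0.3,
                              sample_offset_sd = 0.15,
                              transcript_mix = c(concordant = 0.6, inverse = 0.15,
                                                 protein_only = 0.25),
                              transcript_only_rate = 0.2,
                              seed = 1L) {
  if (n_proteins < 1) stop_config("n_proteins", "must be >= 1")
  if (n_replicates < 2) stop_config("n_replicates", "must be >= 2")
  if (any(diff(ages) <= 0)) stop_config("ages", "must be strictly increasing")
  if (length(models) < 1) stop_config("models", "need at least one model label")
  if (frac_regulated < 0 || frac_regulated > 1) {
    stop_config("frac_regulated", "must be in [0, 1]")
  }
  if (abs(sum(stage_mix) - 1) > 1e-9) stop_config("stage_mix", "must sum to 1")
  if (length(stage_mix) != 3) stop_config("stage_mix", "needs early/middle/advanced proportions")
  if (effect_size_range[1] < 0 || diff(effect_size_range) < 0) {
    stop_config("effect_size_range", "lower bound must be >= 0 and <= upper bound")
  }
  if (frac_regulated > 0 && length(ages) != 4) {
    stop_config("ages", "planted staging needs 4 ages (baseline + 3 onset ages)")
  }
  if (missing_rate_at_floor < 0 || missing_rate_at_floor > 1) {
    stop_config("missing_rate_at_floor", "must be in [0, 1]")
  }
  if (noise_sd < 0) stop_config("noise_sd", "must be >= 0")
  if (abs(sum(transcript_mix) - 1) > 1e-9) stop_config("transcript_mix", "must sum to 1")
  structure(as.list(environment()), class = "simulation_config")
}

stage_names <- c("early", "middle", "advanced")

# onset age of a stage for model number `k` (1 = reference), capped at the
# final age
onset_age_for <- function(stage, ages, k, onset_lag) {
  idx <- match(stage, stage_names) + 1L          # early -> ages[2], ...
  idx <- pmin(idx + (k - 1L) * onset_lag, length(ages))
  ages[idx]
}

#' Generate a synthetic two-model study
#'
#' Draws protein baselines, plants stage-specific regulation (zero effect at
#' the pre-deposition age by construction; the lagged model's onset never
#' precedes the reference model's), adds batch/sample offsets and noise,
#' and left-censors low intensities. Output is bit-identical for equal
#' seeds.
#'
#' @param config a [simulation_config()].
#' @return list with elements `matrices` (named list of log2
#'   [protein_matrix()] per model), `sheet` (a [sample_sheet()] covering all
#'   models) and `truth` (ground-truth data.frame of class `ground_truth`:
#'   `accession`, `gene`, `direction`, `effect_size`, `stage`,
#'   `transcript_class`, `baseline_log2` and one `onset_<model>` column per
#'   model, `NA` for null proteins).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n <- config$n_proteins
    acc <- sprintf("P%05d", seq_len(n))
    gene <- sprintf("GENE%d", seq_len(n))
    baseline <- stats::rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)

    n_reg <- round(n * config$frac_regulated)
    reg_idx <- if (n_reg > 0) sort(sample.int(n, n_reg)) else integer()
    direction <- rep("null", n)
    direction[reg_idx] <- sample(c("up", "down"), n_reg, replace = TRUE)
    effect <- rep(0, n)
    effect[reg_idx] <- stats::runif(n_reg, config$effect_size_range[1],
                                    config$effect_size_range[2])
    stage <- rep("none", n)
    stage[reg_idx] <- sample(stage_names, n_reg, replace = TRUE,
                             prob = config$stage_mix)

    truth <- data.frame(accession = acc, gene = gene, direction = direction,
                        effect_size = effect, stage = stage,
                        baseline_log2 = baseline, stringsAsFactors = FALSE)
    for (k in seq_along(config$models)) {
      onset <- rep(NA_real_, n)
      onset[reg_idx] <- onset_age_for(stage[reg_idx], config$ages, k,
                                      config$onset_lag)
      truth[[paste0("onset_", config$models[k])]] <- onset
    }
    truth$transcript_class <- "null"
    if (n_reg > 0) {
      truth$transcript_class[reg_idx] <- sample(names(config$transcript_mix),
                                                n_reg, replace = TRUE,
                                                prob = config$transcript_mix)
    }
    nulls <- setdiff(seq_len(n), reg_idx)
    t_only <- nulls[stats::runif(length(nulls)) < config$transcript_only_rate]
    truth$transcript_class[t_only] <- "transcript_only"
    class(truth) <- c("ground_truth", class(truth))
    attr(truth, "models") <- config$models

    sgn <- ifelse(direction == "up", 1, ifelse(direction == "down", -1, 0))
    mu0 <- config$baseline_log2_mean - 2 * config$baseline_log2_sd
    msc <- config$baseline_log2_sd / 2

    sheets <- list(); mats <- list()
    for (k in seq_along(config$models)) {
      model <- config$models[k]
      onset <- truth[[paste0("onset_", model)]]
      cols <- expand.grid(replicate = seq_len(config$n_replicates),
                          genotype = c("TG", "WT"), age_months = config$ages,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      cols$model <- model
      cols$sample_id <- sprintf("%s_%s_%gm_r%d", model, cols$genotype,
                                cols$age_months, cols$replicate)
      e <- matrix(NA_real_, n, nrow(cols), dimnames = list(acc, cols$sample_id))
      batch_off <- stats::rnorm(length(config$ages), 0, config$batch_offset_sd)
      names(batch_off) <- as.character(config$ages)
      sample_off <- stats::rnorm(nrow(cols), 0, config$sample_offset_sd)
      for (j in seq_len(nrow(cols))) {
        eff <- sgn * effect *
          (cols$genotype[j] == "TG") *
          (!is.na(onset) & cols$age_months[j] >= onset)
        v <- baseline + batch_off[as.character(cols$age_months[j])] +
          sample_off[j] + eff + stats::rnorm(n, 0, config$noise_sd)
        p_miss <- config$missing_rate_at_floor *
          stats::plogis(-(v - mu0) / msc)
        v[stats::runif(n) < p_miss] <- NA_real_
        e[, j] <- v
      }
      mats[[model]] <- protein_matrix(e, gene = gene, scale = "log2")
      sheets[[model]] <- cols[, c("sample_id", "model", "genotype",
                                  "age_months", "replicate")]
    }
    list(matrices = mats,
         sheet = sample_sheet(do.call(rbind, c(sheets, make.row.names = FALSE))),
         truth = truth)
  })
}

#' Generate a transcript table matched to a ground truth
#'
#' Transcript regulation is derived from the planted `transcript_class`:
#' `concordant` genes carry a same-sign regulated log2 fold change,
#' `inverse` genes an opposite-sign one, `transcript_only` genes are
#' regulated without protein regulation, and `protein_only`/`null` genes are
#' unregulated with small noise fold changes.
#'
#' @param truth a `ground_truth` from [generate_study()].
#' @param seed integer seed.
#' @return data.frame with columns `gene`, `log2_fc`, `regulated`,
#'   `direction`.
#' @export
generate_transcript_table <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  with_seed(seed, {
    n <- nrow(truth)
    cls <- truth$transcript_class
    sgn <- ifelse(truth$direction == "up", 1, ifelse(truth$direction == "down", -1, 0))
    mag <- pmax(0.6, truth$effect_size * stats::runif(n, 0.6, 1.4))
    lfc <- stats::rnorm(n, 0, 0.2)                       # protein_only / null
    lfc[cls == "concordant"] <- (sgn * mag)[cls == "concordant"]
    lfc[cls == "inverse"] <- (-sgn * mag)[cls == "inverse"]
    t_only <- cls == "transcript_only"
    lfc[t_only] <- sample(c(-1, 1), sum(t_only), replace = TRUE) *
      stats::runif(sum(t_only), 0.6, 2.5)
    regulated <- cls %in% c("concordant", "inverse", "transcript_only")
    data.frame(gene = truth$gene, log2_fc = lfc, regulated = regulated,
               direction = ifelse(regulated, ifelse(lfc > 0, "up", "down"), "none"),
               transcript_class = cls, stringsAsFactors = FALSE)
  })
}

#' Generate synthetic LCO emission spectra
#'
#' Each plaque spectrum is the sum of two Gaussian peaks on the wavelength
#' grid (blue-shifted ~502 nm, red-shifted ~588 nm) whose heights are
#' solved so that the max-normalized 502/588 intensity ratio equals a
#' per-plaque target drawn from `N(ratio_mean, ratio_sd)`.
#'
#' @param n_plaques number of plaques.
#' @param ratio_mean mean of the target blue/red peak ratio (> 0).
#' @param ratio_sd SD of the target ratio (0 gives identical ratios).
#' @param wavelengths acquisition grid in nm; must cover both peaks
#'   (default `seq(470, 695, by = 5)`).
#' @param seed integer seed.
#' @param animal_id,group labels attached to the plaques (scalar or
#'   per-plaque vector).
#' @param blue_nm,red_nm peak positions (defaults 502 and 588).
#' @param peak_sd Gaussian peak width in nm (default 30).
#' @return Long-format spectra data.frame (`plaque_id`, `animal_id`,
#'   `group`, `wavelength_nm`, `intensity`).
#' @export
generate_spectra <- function(n_plaques, ratio_mean, ratio_sd = 0,
                             wavelengths = seq(470, 695, by = 5),
                             seed = 1L, animal_id = "animal1", group = "group1",
                             blue_nm = 502, red_nm = 588, peak_sd = 30) {
  if (ratio_mean <= 0) stop_config("ratio_mean", "must be > 0")
  if (min(wavelengths) > blue_nm || max(wavelengths) < red_nm) {
    stop(sprintf("wavelength grid must cover both peaks (%g and %g nm)",
                 blue_nm, red_nm))
  }
  animal_id <- rep_len(animal_id, n_plaques)
  group <- rep_len(group, n_plaques)
  cross <- exp(-(red_nm - blue_nm)^2 / (2 * peak_sd^2))   # peak leakage
  with_seed(seed, {
    r <- stats::rnorm(n_plaques, ratio_mean, ratio_sd)
    r <- pmin(pmax(r, cross + 1e-3), 1 / cross - 1e-3)    # keep heights > 0
    g_blue <- exp(-(wavelengths - blue_nm)^2 / (2 * peak_sd^2))
    g_red <- exp(-(wavelengths - red_nm)^2 / (2 * peak_sd^2))
    rows <- lapply(seq_len(n_plaques), function(i) {
      a <- (r[i] - cross) / (1 - cross^2)
      b <- (1 - cross * r[i]) / (1 - cross^2)
      data.frame(plaque_id = sprintf("%s_plaque%03d", animal_id[i], i),
                 animal_id = animal_id[i], group = group[i],
                 wavelength_nm = wavelengths,
                 intensity = a * g_blue + b * g_red,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Write / read ground truth as JSON
#'
#' @param truth a `ground_truth` data.frame.
#' @param path file path.
#' @return `path` invisibly; the reader returns the `ground_truth`.
#' @export
write_ground_truth <- function(truth, path) {
  payload <- list(models = attr(truth, "models"), table = as.data.frame(truth))
  jsonlite::write_json(payload, path, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth <- payload$table
  class(truth) <- c("ground_truth", class(truth))
  attr(truth, "models") <- payload$models
  truth
}
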