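# End-to-end orchestration: simulate or ingest -> normalize -> differential
# per contrast -> staging -> cross-model MARP table -> concordance ->
# optional recovery scoring, with deterministic seeds and CSV/TSV/JSON
# artifacts.

#' Pipeline run configuration
#'
#' @param sim a [simulation_config()] to generate the study, or `NULL` when
#'   reading data from files.
#' @param matrix_paths named list (by model) of TSV matrix paths (generic
#'   dialect) when `sim` is `NULL`.
#' @param sheet_path sample sheet TSV path when `sim` is `NULL`.
#' @param transcript_table optional transcript table (data.frame or TSV
#'   path) for the concordance step; when `sim` is given it defaults to a
#'   matched synthetic transcript table.
#' @param contrasts data.frame with columns `model`, `age_months` selecting
#'   the contrasts to run; default: every model x age cell in the sheet.
#' @param fdr an [fdr_config()].
#' @param reference_model model defining stages (default: first model).
#' @param staging_ages ages used for staging (default `c(3, 6, 12)`); all
#'   other ages are analyzed for QC only.
#' @param require_same_direction cross-model support rule (default `TRUE`).
#' @param fc_threshold,p_threshold regulation thresholds (0.5, 0.05).
#' @param out_dir output directory for artifacts, or `NULL` to skip writing.
#' @param seed integer master seed (drives the simulation and the
#'   transcript table).
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = NULL, matrix_paths = NULL, sheet_path = NULL,
                       transcript_table = NULL, contrasts = NULL,
                       fdr = fdr_config(), reference_model = NULL,
                       staging_ages = c(3, 6, 12),
                       require_same_direction = TRUE,
                       fc_threshold = 0.5, p_threshold = 0.05,
                       out_dir = NULL, seed = 1L) {
  if (is.null(sim) && (is.null(matrix_paths) || is.null(sheet_path))) {
    stop_config("sim", "provide either a simulation_config or matrix_paths + sheet_path")
  }
  structure(as.list(environment()), class = "run_config")
}

# accessions evaluable under the full staging rule: tested at every staging
# age in the reference model and at >= 1 staging age in the second model
stageable_proteins <- function(profiles, reference_model, second_model,
                               staging_ages = c(3, 6, 12)) {
  ref <- profiles[profiles$model == reference_model &
                    profiles$age_months %in% staging_ages, ]
  ok_ref <- tapply(ref$direction != "untested", ref$accession, all)
  sec <- profiles[profiles$model == second_model &
                    profiles$age_months %in% staging_ages, ]
  ok_sec <- tapply(sec$direction != "untested", sec$accession, any)
  acc <- names(ok_ref)[ok_ref]
  if (length(ok_sec)) acc <- acc[acc %in% names(ok_sec)[ok_sec]]
  acc
}

# gene-level regulation table at one age: regulated iff same-direction
# regulation in both models
protein_regulation_table <- function(profiles, age, models) {
  per_model <- lapply(models, function(m) {
    sub <- profiles[profiles$model == m & profiles$age_months == age, ]
    sub[match(unique(profiles$accession), sub$accession), "direction"]
  })
  acc <- unique(profiles$accession)
  gene <- profiles$gene[match(acc, profiles$accession)]
  d1 <- per_model[[1]]; d1[is.na(d1)] <- "untested"
  d2 <- if (length(per_model) > 1) per_model[[2]] else d1
  d2[is.na(d2)] <- "untested"
  both_reg <- d1 %in% c("up", "down") & d1 == d2
  data.frame(gene = gene,
             regulated = both_reg,
             direction = ifelse(both_reg, d1, "none"),
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) the study, normalizes each model's matrix per age
#' group, runs the differential analysis of every contrast, stages the
#' reference-model time courses, intersects across models into the MARP
#' table, classifies proteome-transcriptome concordance at the final
#' staging age, and - when ground truth is available - scores stage
#' recovery. Deterministic given the seed; all artifacts are written to
#' `out_dir` when set.
#'
#' @param config a [run_config()].
#' @return list of class `run_report`: `contrast_counts` (per-contrast
#'   tested/up/down counts), `marps`, `marp_counts`, `stages`, `profiles`,
#'   `overlap` (concordance summary or `NULL`), `recovery` (or `NULL`),
#'   `stageable`, `manifest` (paths written).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  manifest <- character()
  truth <- NULL
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- config$seed
    study <- generate_study(sim)
    mats <- study$matrices
    sheet <- study$sheet
    truth <- study$truth
    transcript <- config$transcript_table
    if (is.null(transcript)) {
      transcript <- generate_transcript_table(truth, seed = config$seed + 1L)
    }
  } else {
    mats <- lapply(config$matrix_paths, read_protein_matrix)
    sheet <- read_sample_sheet(config$sheet_path)
    transcript <- config$transcript_table
    if (is.character(transcript)) transcript <- read_transcript_table(transcript)
  }
  models <- unique(sheet$model)
  reference_model <- if (is.null(config$reference_model)) models[1] else config$reference_model
  second_model <- setdiff(models, reference_model)[1]

  # per-age-group normalization within each model
  mats <- lapply(mats, function(pm) normalize_by_batch(pm, sheet))

  grid <- if (is.null(config$contrasts)) {
    unique(as.data.frame(sheet)[, c("model", "age_months")])
  } else {
    config$contrasts
  }
  grid <- grid[order(match(grid$model, models), grid$age_months), , drop = FALSE]

  contrasts <- list()
  counts <- list()
  for (i in seq_len(nrow(grid))) {
    m <- grid$model[i]; a <- grid$age_months[i]
    cc <- run_contrast(mats[[m]], sheet, m, a, config = config$fdr,
                       fc_threshold = config$fc_threshold,
                       p_threshold = config$p_threshold)
    key <- sprintf("%s_%gm", m, a)
    contrasts[[key]] <- cc
    counts[[key]] <- data.frame(model = m, age_months = a,
                                n_tested = nrow(cc),
                                n_up = sum(cc$direction == "up"),
                                n_down = sum(cc$direction == "down"),
                                stringsAsFactors = FALSE)
  }
  contrast_counts <- do.call(rbind, c(counts, make.row.names = FALSE))

  profiles <- temporal_profiles(contrasts)
  stages <- assign_stage(profiles, reference_model,
                         staging_ages = config$staging_ages)
  marps <- if (!is.na(second_model)) {
    cross_model_filter(stages, profiles, second_model,
                       staging_ages = config$staging_ages,
                       require_same_direction = config$require_same_direction)
  } else {
    cross_model_filter(stages, profiles, reference_model,
                       staging_ages = config$staging_ages,
                       require_same_direction = config$require_same_direction)
  }

  overlap <- NULL
  if (!is.null(transcript)) {
    prot_reg <- protein_regulation_table(
      profiles, max(config$staging_ages),
      c(reference_model, if (!is.na(second_model)) second_model)
    )
    overlap <- overlap_classes(prot_reg, transcript)
  }

  stageable <- if (!is.na(second_model)) {
    stageable_proteins(profiles, reference_model, second_model,
                       config$staging_ages)
  } else {
    stageable_proteins(profiles, reference_model, reference_model,
                       config$staging_ages)
  }

  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- evaluate_recovery(
      marps[, c("accession", "stage", "direction")], truth,
      restrict_to = stageable
    )
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(config$out_dir, ...)
    for (m in names(mats)) {
      f <- p(sprintf("matrix_%s_normalized.tsv", m))
      write_protein_matrix(mats[[m]], f); manifest <- c(manifest, f)
    }
    f <- p("sample_sheet.tsv"); write_sample_sheet(sheet, f)
    manifest <- c(manifest, f)
    for (key in names(contrasts)) {
      f <- p(sprintf("contrast_%s.csv", key))
      write_contrast_csv(contrasts[[key]], f); manifest <- c(manifest, f)
    }
    f <- p("marp_table.csv"); write_marp_csv(marps, f)
    manifest <- c(manifest, f)
    f <- p("contrast_counts.csv")
    utils::write.csv(contrast_counts, f, row.names = FALSE)
    manifest <- c(manifest, f)
    if (!is.null(truth)) {
      f <- p("ground_truth.json"); write_ground_truth(truth, f)
      manifest <- c(manifest, f)
    }
    if (!is.null(overlap)) {
      f <- p("overlap_classes.csv")
      utils::write.csv(overlap$classes, f, row.names = FALSE)
      manifest <- c(manifest, f)
      f <- p("overlap_summary.csv")
      utils::write.csv(data.frame(class = names(overlap$summary),
                                  count = as.integer(overlap$summary)),
                       f, row.names = FALSE)
      manifest <- c(manifest, f)
    }
  }

  structure(list(
    contrast_counts = contrast_counts,
    contrasts = contrasts,
    profiles = profiles,
    stages = stages,
    marps = marps,
    marp_counts = marp_counts(marps),
    overlap = overlap,
    recovery = recovery,
    stageable = stageable,
    reference_model = reference_model,
    second_model = second_model,
    manifest = manifest
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run report\n")
  cat("  contrasts:\n")
  print(x$contrast_counts, row.names = FALSE)
  cat("  MARPs: ",
      paste(sprintf("%d %s", x$marp_counts, names(x$marp_counts)),
            collapse = ", "), "\n", sep = "")
  if (!is.null(x$recovery)) print(x$recovery)
  invisible(x)
}
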