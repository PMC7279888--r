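# Temporal staging of regulated proteins. A protein's response profile over
# the sampled ages is classified by the age at which regulation first
# appears AND persists through the final age:
#   early    - regulated (same direction) at 3, 6 and 12 months
#   middle   - regulated at 6 and 12 months but not at 3
#   advanced - regulated at 12 months only
# Any other pattern is "none". Proteins staged in the reference model are
# then intersected with the second model (same-direction regulation at any
# staging age) to give the model-independent MARP table. The 1-month
# (pre-deposition) contrast is computed for QC but never used for staging.

#' Build temporal regulation profiles
#'
#' Combines per-contrast results into one long table giving, for every
#' protein, model and age, the regulation direction and log2 fold change.
#' Proteins that did not pass the consistency filter for a contrast (and
#' thus were never tested there) are recorded as `"untested"`, which is
#' distinct from a tested `"none"`.
#'
#' @param contrasts list of `contrast_result` data.frames from
#'   [run_contrast()], covering the desired model x age grid.
#' @param universe optional character vector of accessions to profile;
#'   default: union of all tested accessions.
#' @return A data.frame of class `temporal_profiles` with columns
#'   `accession`, `gene`, `model`, `age_months`, `direction`
#'   (`up`/`down`/`none`/`untested`) and `log2_fc` (`NA` when untested).
#' @export
temporal_profiles <- function(contrasts, universe = NULL) {
  stopifnot(length(contrasts) > 0)
  long <- do.call(rbind, lapply(contrasts, function(cc) {
    as.data.frame(cc)[, c("accession", "gene", "model", "age_months",
                          "direction", "log2_fc")]
  }))
  if (is.null(universe)) universe <- unique(long$accession)
  gene_map <- long$gene[match(universe, long$accession)]
  gene_map[is.na(gene_map)] <- universe[is.na(gene_map)]
  grid <- unique(long[, c("model", "age_months")])
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sub <- long[long$model == grid$model[i] & long$age_months == grid$age_months[i], ]
    j <- match(universe, sub$accession)
    data.frame(
      accession = universe,
      gene = gene_map,
      model = grid$model[i],
      age_months = grid$age_months[i],
      direction = ifelse(is.na(j), "untested", sub$direction[j]),
      log2_fc = ifelse(is.na(j), NA_real_, sub$log2_fc[j]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  class(out) <- c("temporal_profiles", class(out))
  out
}

# stage from the three staging-age directions of one protein
stage_from_directions <- function(d3, d6, d12) {
  if (any(c(d3, d6, d12) == "untested")) {
    return(list(stage = "none", direction = "none", stageable = FALSE, flip = FALSE))
  }
  reg <- c(d3, d6, d12) != "none"
  res <- function(stage, dirs) {
    u <- unique(dirs)
    if (length(u) == 1) {
      list(stage = stage, direction = u, stageable = TRUE, flip = FALSE)
    } else {  # qualifying ages disagree in sign
      list(stage = "none", direction = "none", stageable = TRUE, flip = TRUE)
    }
  }
  if (all(reg)) return(res("early", c(d3, d6, d12)))
  if (!reg[1] && reg[2] && reg[3]) return(res("middle", c(d6, d12)))
  if (!reg[1] && !reg[2] && reg[3]) return(res("advanced", d12))
  list(stage = "none", direction = "none", stageable = TRUE, flip = FALSE)
}

#' Assign temporal stages in the reference model
#'
#' Classifies every profiled protein into `early`, `middle`, `advanced` or
#' `none` from its regulation directions at the staging ages in the
#' reference model. Regulation must persist from onset through the final
#' age; a protein untested at any staging age is not stageable; qualifying
#' ages with conflicting directions yield `none` with a direction-flip
#' annotation.
#'
#' @param profiles a [temporal_profiles()] table.
#' @param reference_model model whose time course defines the stage.
#' @param staging_ages ages (months) defining onset classes; default
#'   `c(3, 6, 12)` (the pre-deposition age never contributes).
#' @return data.frame of class `stage_table`: `accession`, `gene`, `stage`,
#'   `direction`, `stageable`, `direction_flip`.
#' @export
assign_stage <- function(profiles, reference_model, staging_ages = c(3, 6, 12)) {
  stopifnot(length(staging_ages) == 3)
  ref <- profiles[profiles$model == reference_model &
                    profiles$age_months %in% staging_ages, , drop = FALSE]
  if (!nrow(ref)) stop("no profiles for reference model '", reference_model, "'")
  acc <- unique(ref$accession)
  dir_at <- function(age) {
    sub <- ref[ref$age_months == age, ]
    out <- sub$direction[match(acc, sub$accession)]
    out[is.na(out)] <- "untested"
    out
  }
  d3 <- dir_at(staging_ages[1]); d6 <- dir_at(staging_ages[2]); d12 <- dir_at(staging_ages[3])
  rows <- lapply(seq_along(acc), function(i) stage_from_directions(d3[i], d6[i], d12[i]))
  out <- data.frame(
    accession = acc,
    gene = ref$gene[match(acc, ref$accession)],
    stage = vapply(rows, `[[`, "", "stage"),
    direction = vapply(rows, `[[`, "", "direction"),
    stageable = vapply(rows, `[[`, TRUE, "stageable"),
    direction_flip = vapply(rows, `[[`, TRUE, "flip"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("stage_table", class(out))
  out
}

#' Cross-model intersection into the MARP table
#'
#' Retains reference-model staged proteins that are also regulated in the
#' second model at one or more staging ages - later onset in the second
#' model is explicitly allowed. By default the second-model regulation must
#' have the same direction as the reference stage.
#'
#' @param stages a `stage_table` from [assign_stage()] (reference model).
#' @param profiles the [temporal_profiles()] covering the second model.
#' @param second_model label of the confirming model.
#' @param staging_ages ages eligible as second-model support
#'   (default `c(3, 6, 12)`).
#' @param require_same_direction if `FALSE`, any regulation in the second
#'   model counts as support regardless of sign (relaxed rule; never yields
#'   fewer MARPs than the strict rule).
#' @return data.frame of class `marp_table`: `accession`, `gene`, `stage`,
#'   `direction`, `supported_in_second_model`, `supporting_ages`
#'   (comma-separated) and per-model per-age `log2_fc_<model>_<age>m`
#'   columns (`NA` where untested).
#' @export
cross_model_filter <- function(stages, profiles, second_model,
                               staging_ages = c(3, 6, 12),
                               require_same_direction = TRUE) {
  staged <- stages[stages$stage != "none", , drop = FALSE]
  sec <- profiles[profiles$model == second_model &
                    profiles$age_months %in% staging_ages, , drop = FALSE]
  support <- lapply(seq_len(nrow(staged)), function(i) {
    sub <- sec[sec$accession == staged$accession[i], ]
    hit <- if (require_same_direction) {
      sub$direction == staged$direction[i]
    } else {
      sub$direction %in% c("up", "down")
    }
    sort(sub$age_months[hit])
  })
  keep <- lengths(support) > 0
  out <- staged[keep, c("accession", "gene", "stage", "direction"), drop = FALSE]
  out$supported_in_second_model <- rep(TRUE, nrow(out))
  out$supporting_ages <- vapply(support[keep], paste, "", collapse = ",")
  # attach per-model per-age fold changes
  grid <- unique(profiles[, c("model", "age_months")])
  grid <- grid[order(grid$model, grid$age_months), ]
  for (i in seq_len(nrow(grid))) {
    sub <- profiles[profiles$model == grid$model[i] &
                      profiles$age_months == grid$age_months[i], ]
    col <- sprintf("log2_fc_%s_%gm", grid$model[i], grid$age_months[i])
    out[[col]] <- sub$log2_fc[match(out$accession, sub$accession)]
  }
  rownames(out) <- NULL
  class(out) <- c("marp_table", class(out))
  out
}

#' Stage counts of a MARP table
#'
#' @param marps a `marp_table`.
#' @return Named integer vector with counts for early, middle and advanced.
#' @export
marp_counts <- function(marps) {
  vapply(c("early", "middle", "advanced"),
         function(s) sum(marps$stage == s), integer(1))
}

#' Top regulated proteins per stage for heatmap export
#'
#' Selects, per stage, the `k` strongest up- and `k` strongest
#' down-regulated MARPs ranked by the absolute log2 fold change at the
#' stage-onset age in the reference model. Untested cells in the exported
#' fold-change columns remain `NA` (rendered as crosses/blanks by heatmap
#' tools).
#'
#' @param marps a `marp_table` from [cross_model_filter()].
#' @param reference_model model whose onset-age fold change ranks proteins.
#' @param k number of proteins per direction per stage (default 74). If
#'   fewer are available, all are returned and a note is attached as
#'   `attr(, "note")`.
#' @param staging_ages onset ages of the three stages (default `c(3, 6, 12)`).
#' @return data.frame: `stage`, `direction`, `rank`, then all `marp_table`
#'   columns.
#' @export
top_regulated_heatmap_table <- function(marps, reference_model, k = 74,
                                        staging_ages = c(3, 6, 12)) {
  onset_of <- c(early = staging_ages[1], middle = staging_ages[2],
                advanced = staging_ages[3])
  notes <- character()
  blocks <- list()
  for (st in names(onset_of)) {
    col <- sprintf("log2_fc_%s_%gm", reference_model, onset_of[[st]])
    if (!col %in% names(marps)) stop("missing fold-change column ", col)
    for (dir in c("up", "down")) {
      sub <- marps[marps$stage == st & marps$direction == dir, , drop = FALSE]
      if (!nrow(sub)) next
      sub <- sub[order(-abs(sub[[col]])), , drop = FALSE]
      if (nrow(sub) < k) {
        notes <- c(notes, sprintf("%s/%s: only %d of %d requested", st, dir,
                                  nrow(sub), k))
      }
      sub <- utils::head(sub, k)
      sub <- cbind(data.frame(stage_rank = seq_len(nrow(sub))), sub)
      blocks[[paste(st, dir)]] <- sub
    }
  }
  out <- if (length(blocks)) do.call(rbind, blocks) else
    cbind(data.frame(stage_rank = integer()), marps[0, ])
  rownames(out) <- NULL
  names(out)[names(out) == "stage_rank"] <- "rank"
  if (length(notes)) attr(out, "note") <- notes
  out
}

#' Write a MARP table as CSV
#'
#' @param marps a `marp_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marp_csv <- function(marps, path) {
  utils::write.csv(as.data.frame(marps), path, row.names = FALSE, na = "")
  invisible(path)
}
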