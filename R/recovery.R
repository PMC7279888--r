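# Recovery scoring: compare staged calls against the simulator's planted
# ground truth.

#' Score staged calls against planted ground truth
#'
#' Builds the stage confusion matrix (true stage x called stage, including
#' `none`), per-stage sensitivity, direction accuracy among correctly
#' staged proteins, and the empirical false discovery proportion (called
#' proteins that are true nulls over all called proteins; 0 when nothing is
#' called).
#'
#' @param calls data.frame with columns `accession`, `stage`, `direction` -
#'   a `marp_table` or `stage_table`. Proteins absent from `calls` count as
#'   `none`; accessions not present in `truth` are an error.
#' @param truth a `ground_truth` from [generate_study()].
#' @param restrict_to optional accession vector (e.g. the proteins
#'   consistently quantified at every staging age); when given, per-stage
#'   sensitivities are additionally reported restricted to that universe as
#'   `sensitivity_restricted`.
#' @return list of class `recovery_report`: `confusion`, `sensitivity`,
#'   `direction_accuracy`, `fdp`, `n_called`, `adjacent_misassignment_rate`
#'   (share of wrongly staged planted proteins landing in the neighbouring
#'   stage) and, if requested, `sensitivity_restricted`.
#' @export
evaluate_recovery <- function(calls, truth, restrict_to = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  unknown <- setdiff(calls$accession, truth$accession)
  if (length(unknown)) {
    stop("call accession(s) absent from truth: ",
         paste(utils::head(unknown, 10), collapse = ", "))
  }
  if (anyDuplicated(calls$accession)) stop("duplicate accessions in calls")
  lv <- c(stage_names, "none")
  called_stage <- rep("none", nrow(truth))
  called_dir <- rep("none", nrow(truth))
  j <- match(calls$accession, truth$accession)
  called_stage[j] <- calls$stage
  called_dir[j] <- calls$direction
  true_stage <- ifelse(truth$stage %in% stage_names, truth$stage, "none")

  confusion <- table(true = factor(true_stage, lv),
                     called = factor(called_stage, lv))

  sens <- function(universe) {
    vapply(stage_names, function(s) {
      in_s <- universe & true_stage == s
      if (!any(in_s)) return(NA_real_)
      mean(called_stage[in_s] == s)
    }, numeric(1))
  }
  all_univ <- rep(TRUE, nrow(truth))
  sensitivity <- sens(all_univ)

  tp <- true_stage != "none" & called_stage == true_stage
  direction_accuracy <- if (any(tp)) {
    mean(called_dir[tp] == truth$direction[tp])
  } else {
    NA_real_
  }

  called <- called_stage != "none"
  fdp <- if (any(called)) {
    sum(called & truth$direction == "null") / sum(called)
  } else {
    0
  }

  mis <- true_stage %in% stage_names & called_stage %in% stage_names &
    called_stage != true_stage
  adjacent <- abs(match(called_stage, stage_names) - match(true_stage, stage_names)) == 1
  adjacent_rate <- if (any(mis)) mean(adjacent[mis]) else NA_real_

  out <- list(confusion = confusion, sensitivity = sensitivity,
              direction_accuracy = direction_accuracy, fdp = fdp,
              n_called = sum(called),
              adjacent_misassignment_rate = adjacent_rate)
  if (!is.null(restrict_to)) {
    out$sensitivity_restricted <- sens(truth$accession %in% restrict_to)
    out$n_restricted <- vapply(stage_names, function(s)
      sum(truth$accession %in% restrict_to & true_stage == s), integer(1))
  }
  structure(out, class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("recovery report\n")
  cat("  sensitivity:",
      paste(sprintf("%s %.3f", names(x$sensitivity), x$sensitivity), collapse = ", "),
      "\n")
  if (!is.null(x$sensitivity_restricted)) {
    cat("  sensitivity (stageable universe):",
        paste(sprintf("%s %.3f", names(x$sensitivity_restricted),
                      x$sensitivity_restricted), collapse = ", "), "\n")
  }
  cat(sprintf("  direction accuracy %.3f | FDP %.4f | called %d\n",
              x$direction_accuracy, x$fdp, x$n_called))
  invisible(x)
}
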