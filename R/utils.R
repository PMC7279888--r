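# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Round half away from zero
#'
#' Decimal rounding in which ties go away from zero (`0.5 -> 1`), as opposed
#' to the IEC 60559 round-half-even used by [base::round()]. Used wherever a
#' printed percentage must match conventional manual rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @examples
#' round_half_up(0.5)    # 1
#' round_half_up(2.345, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

# sum over rows ignoring NA, but returning NA when all values are NA
row_mean_narm <- function(m) {
  n <- rowSums(!is.na(m))
  out <- rowSums(m, na.rm = TRUE) / n
  out[n == 0] <- NA_real_
  out
}
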