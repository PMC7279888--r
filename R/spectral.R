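# LCO emission-spectrum processing. Spectra are double stained with qFTAA
# (blue-shifted peak, ~502 nm, dense-core amyloid fibrils) and hFTAA
# (red-shifted peak, ~588 nm, fibrillar plus pre-fibrillar aggregates);
# the 502/588 intensity ratio of the max-normalized per-plaque spectrum
# distinguishes plaque-core conformations.
#
# Spectra travel as long-format data.frames with columns plaque_id,
# animal_id, group, wavelength_nm, intensity.

validate_spectra <- function(spectra) {
  req <- c("plaque_id", "animal_id", "group", "wavelength_nm", "intensity")
  miss <- setdiff(req, names(spectra))
  if (length(miss)) stop("spectra table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(spectra$intensity < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  invisible(spectra)
}

#' Normalize each plaque spectrum to its maximum
#'
#' Divides every intensity by the within-plaque maximum so each spectrum
#' peaks at exactly 1. Idempotent; an all-zero spectrum is an error.
#'
#' @param spectra long-format spectra data.frame (`plaque_id`, `animal_id`,
#'   `group`, `wavelength_nm`, `intensity`).
#' @return The data.frame with normalized `intensity`.
#' @export
normalize_spectrum <- function(spectra) {
  validate_spectra(spectra)
  mx <- stats::ave(spectra$intensity, spectra$plaque_id,
                   FUN = function(v) max(v, na.rm = TRUE))
  if (any(mx <= 0)) {
    bad <- unique(spectra$plaque_id[mx <= 0])
    stop("all-zero spectrum for plaque(s): ", paste(bad, collapse = ", "))
  }
  spectra$intensity <- spectra$intensity / mx
  spectra
}

# intensity at one wavelength by linear interpolation on the grid
interp_intensity <- function(wl, int, at) {
  ord <- order(wl)
  wl <- wl[ord]; int <- int[ord]
  if (at < min(wl) || at > max(wl)) {
    stop(sprintf("wavelength %g nm outside acquired grid [%g, %g]",
                 at, min(wl), max(wl)))
  }
  stats::approx(wl, int, xout = at, method = "linear", ties = "ordered")$y
}

#' Blue/red peak intensity ratio of one or more spectra
#'
#' Reads the normalized intensity at the blue-shifted (502 nm) and
#' red-shifted (588 nm) emission peaks by linear interpolation between the
#' two nearest grid points and returns their ratio per plaque. Because the
#' within-plaque normalization cancels in the ratio's scale, the ratio is
#' invariant under global rescaling of the raw spectrum.
#'
#' @param spectra long-format spectra data.frame (normalized with
#'   [normalize_spectrum()]; raw spectra are normalized on the fly).
#' @param blue_nm,red_nm peak read-out wavelengths (defaults 502 and 588).
#' @return data.frame with one row per plaque: `plaque_id`, `animal_id`,
#'   `group`, `blue`, `red`, `ratio`.
#' @export
peak_ratio <- function(spectra, blue_nm = 502, red_nm = 588) {
  spectra <- normalize_spectrum(spectra)
  ids <- unique(spectra$plaque_id)
  rows <- lapply(ids, function(id) {
    sub <- spectra[spectra$plaque_id == id, ]
    b <- interp_intensity(sub$wavelength_nm, sub$intensity, blue_nm)
    r <- interp_intensity(sub$wavelength_nm, sub$intensity, red_nm)
    if (r == 0) stop("red-peak intensity is 0 for plaque ", id)
    data.frame(plaque_id = id, animal_id = sub$animal_id[1],
               group = sub$group[1], blue = b, red = r, ratio = b / r,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate peak ratios per animal and per group
#'
#' Randomly subsamples each animal to `plaques_per_animal` plaques when it
#' contributes more (seed-deterministic), averages the ratio per animal,
#' and summarizes each group by the mean and SD of its animal means. When
#' exactly two groups each contribute at least two animals, the groups are
#' compared with the two-sided pooled Student t-test on animal means.
#'
#' @param ratios per-plaque ratio table from [peak_ratio()].
#' @param plaques_per_animal plaques retained per animal (default 20).
#' @param seed integer seed for the subsampling.
#' @return list of class `ratio_summary`: `animals` (per-animal mean ratio
#'   and plaque count), `groups` (per-group mean, sd, n animals) and
#'   `p_value` (`NA`, with a `flag`, when a group has a single animal or
#'   the design is not two groups).
#' @export
aggregate_ratios <- function(ratios, plaques_per_animal = 20, seed = NULL) {
  stopifnot(all(c("animal_id", "group", "ratio") %in% names(ratios)))
  ratios <- ratios[order(ratios$animal_id, ratios$plaque_id), , drop = FALSE]
  animals <- unique(ratios[, c("animal_id", "group")])
  animals <- animals[order(animals$animal_id), , drop = FALSE]
  sub <- with_seed(seed, {
    do.call(rbind, lapply(animals$animal_id, function(a) {
      rr <- ratios[ratios$animal_id == a, , drop = FALSE]
      if (nrow(rr) > plaques_per_animal) {
        rr <- rr[sample.int(nrow(rr), plaques_per_animal), , drop = FALSE]
      }
      rr
    }))
  })
  animals$n_plaques <- vapply(animals$animal_id, function(a)
    sum(sub$animal_id == a), integer(1))
  animals$mean_ratio <- vapply(animals$animal_id, function(a)
    mean(sub$ratio[sub$animal_id == a]), numeric(1))
  groups <- do.call(rbind, lapply(unique(animals$group), function(g) {
    v <- animals$mean_ratio[animals$group == g]
    data.frame(group = g, n_animals = length(v), mean_ratio = mean(v),
               sd_ratio = if (length(v) > 1) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  p <- NA_real_; flag <- NULL
  if (nrow(groups) == 2) {
    g1 <- animals$mean_ratio[animals$group == groups$group[1]]
    g2 <- animals$mean_ratio[animals$group == groups$group[2]]
    if (length(g1) >= 2 && length(g2) >= 2) {
      p <- student_t_test(g1, g2)
    } else {
      flag <- "a group has a single animal; no p-value computed"
    }
  } else {
    flag <- "group comparison requires exactly two groups"
  }
  structure(list(animals = animals, groups = groups, p_value = p, flag = flag),
            class = "ratio_summary")
}

#' Read / write long-format spectra tables
#'
#' TSV with columns `plaque_id`, `animal_id`, `group`, `wavelength_nm`,
#' `intensity`.
#'
#' @param path file path.
#' @return data.frame; the writer returns `path` invisibly.
#' @export
read_spectra <- function(path) {
  validate_spectra(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_spectra
#' @param spectra spectra data.frame.
#' @export
write_spectra <- function(spectra, path) {
  validate_spectra(spectra)
  utils::write.table(spectra, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
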