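## Nest census arithmetic: elliptical comb areas, totals, and brood
## fractions.

#' Elliptical comb area
#'
#' Combs are approximately oval, so area is estimated from the longest axis
#' and the longest axis at right angles to it as an ellipse:
#' `pi * (length/2) * (width/2)`.
#'
#' @param length_cm longest comb dimension, cm.
#' @param width_cm widest dimension perpendicular to it, cm (must not exceed
#'   `length_cm`).
#' @return area in cm^2 (full precision; round for display).
#' @examples
#' round(comb_area(38.0, 27.5))  # 821
#' @export
comb_area <- function(length_cm, width_cm) {
  if (any(length_cm <= 0) || any(width_cm <= 0)) {
    stop("comb dimensions must be positive")
  }
  if (any(width_cm > length_cm)) {
    stop("width must not exceed length (length is the maximum dimension)")
  }
  pi * (length_cm / 2) * (width_cm / 2)
}

#' Construct a nest census from per-comb records
#'
#' @param combs data frame with columns `comb` (1 = oldest, top),
#'   `length_cm`, `width_cm`, `cells`, `large_cells`, `pupae`,
#'   `large_pupae`. Count invariants (`large_cells <= cells`,
#'   `large_pupae <= pupae <= cells`) are enforced.
#' @param nest nest id label.
#' @return object of class `nest_census` (the validated data frame with an
#'   added `area_cm2` column, plus the nest id as attribute).
#' @export
nest_census <- function(combs, nest = "nest") {
  need <- c("comb", "length_cm", "width_cm", "cells", "large_cells",
            "pupae", "large_pupae")
  if (!all(need %in% names(combs))) {
    stop("comb table needs columns ", paste(need, collapse = ", "))
  }
  if (nrow(combs) < 1) stop("need at least one comb")
  with(combs, {
    if (any(large_cells > cells)) stop("large_cells exceeds cells")
    if (any(large_pupae > pupae)) stop("large_pupae exceeds pupae")
    if (any(pupae > cells)) stop("pupae exceeds cells")
  })
  combs$area_cm2 <- comb_area(combs$length_cm, combs$width_cm)
  structure(combs, class = c("nest_census", "data.frame"), nest = nest)
}

#' Read a comb census table from CSV
#'
#' @param path CSV file with the columns of [nest_census()].
#' @param nest nest id label (default: file name without extension).
#' @return a `nest_census`.
#' @export
read_comb_table <- function(path, nest = NULL) {
  if (is.null(nest)) nest <- sub("\\.[^.]*$", "", basename(path))
  nest_census(utils::read.csv(path), nest = nest)
}

#' Summarise a nest census
#'
#' Totals and brood fractions: total comb area (sum of per-comb elliptical
#' areas computed from raw dimensions), total cells and pupae, the sealed
#' fraction (pupae / cells) and the large-sealed fraction (large pupae /
#' pupae). Fractions are kept at full precision; the print method displays
#' integer percentages and integer cm^2.
#'
#' @param census a [nest_census()].
#' @return object of class `census_summary`: list with `nest`, `per_comb`
#'   (data frame with comb areas), `total_area_cm2`, `total_cells`,
#'   `total_large_cells`, `total_pupae`, `total_large_pupae`,
#'   `sealed_fraction`, `large_sealed_fraction` (the latter two `NA` with a
#'   `degenerate` flag when a denominator is zero).
#' @examples
#' census_summary(vespa_soror_combs("N1"))
#' @export
census_summary <- function(census) {
  stopifnot(inherits(census, "nest_census"))
  cells <- sum(census$cells)
  pupae <- sum(census$pupae)
  structure(list(
    nest = attr(census, "nest"),
    per_comb = as.data.frame(census),
    total_area_cm2 = sum(census$area_cm2),
    total_cells = cells,
    total_large_cells = sum(census$large_cells),
    total_pupae = pupae,
    total_large_pupae = sum(census$large_pupae),
    sealed_fraction = if (cells > 0) pupae / cells else NA_real_,
    large_sealed_fraction = if (pupae > 0) sum(census$large_pupae) / pupae
                            else NA_real_,
    degenerate = cells == 0 || pupae == 0
  ), class = "census_summary")
}

#' @export
print.census_summary <- function(x, ...) {
  cat("Nest", x$nest, "census\n")
  pc <- x$per_comb
  cat(sprintf("  combs: %d, total area %.0f cm^2\n", nrow(pc),
              round_half_up(x$total_area_cm2)))
  cat(sprintf("  cells: %d (%d large), pupae: %d (%d large)\n",
              x$total_cells, x$total_large_cells, x$total_pupae,
              x$total_large_pupae))
  if (!is.na(x$sealed_fraction)) {
    cat(sprintf("  sealed cells: %.0f%%\n",
                round_half_up(100 * x$sealed_fraction)))
  }
  if (!is.na(x$large_sealed_fraction)) {
    cat(sprintf("  large among sealed: %.0f%%\n",
                round_half_up(100 * x$large_sealed_fraction)))
  }
  if (x$degenerate) cat("  (zero denominator; fraction(s) undefined)\n")
  invisible(x)
}

#' Descriptive summary of a petiole measurement table
#'
#' Petioles are the pillars attaching adjacent combs. This computes
#' descriptive means only (per-dimension mean and sd); comparative
#' statistics on petiole data are outside the scope of the census module.
#'
#' @param petioles data frame of numeric petiole measurements (e.g. top and
#'   bottom diameters in mm), one row per petiole.
#' @return data frame with `measure`, `n`, `mean`, `sd`.
#' @export
petiole_summary <- function(petioles) {
  stopifnot(is.data.frame(petioles), nrow(petioles) >= 1)
  num <- vapply(petioles, is.numeric, TRUE)
  cols <- names(petioles)[num]
  data.frame(
    measure = cols,
    n = vapply(cols, function(c) sum(!is.na(petioles[[c]])), 1L),
    mean = vapply(cols, function(c) mean(petioles[[c]], na.rm = TRUE), 1.0),
    sd = vapply(cols, function(c) stats::sd(petioles[[c]], na.rm = TRUE), 1.0),
    row.names = NULL
  )
}
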