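#' Spheroid doubling time
#'
#' Exponential-growth doubling time from two measurements of a growing
#' quantity (spheroid volume or cell number):
#' `DT = t * ln(2) / ln(v2 / v1)`, where `t` is the time elapsed between the
#' two measurements. A shrinking quantity (`v2 < v1`) gives a negative DT,
#' returned as-is with a warning, since callers may legitimately handle
#' regression phases.
#'
#' @param v1,v2 Positive quantities at the start and end of the interval.
#' @param t Elapsed time in days, positive.
#' @return Doubling time in days.
#' @examples
#' doubling_time(1, 2, 4)   # 4 days: doubled once in 4 days
#' doubling_time(1, 8, 3)   # 1 day: three doublings in 3 days
#' @export
doubling_time <- function(v1, v2, t) {
  if (any(!is.finite(c(v1, v2, t))) || v1 <= 0 || v2 <= 0 || t <= 0) {
    stop("'v1', 'v2' and 't' must be positive and finite", call. = FALSE)
  }
  if (v2 == v1) {
    stop("doubling time is undefined when v2 equals v1", call. = FALSE)
  }
  dt <- t * log(2) / log(v2 / v1)
  if (v2 < v1) {
    warning("quantity decreased over the interval; doubling time is negative",
            call. = FALSE)
  }
  dt
}

#' Sphere volume from diameter
#'
#' `V = (pi/6) d^3`, the volume of a sphere of diameter `d` — used to convert
#' microscopy diameters of spheroids to volumes.
#'
#' @param diameter Diameter in µm, positive (vectorized).
#' @return Volume in µm³.
#' @examples
#' sphere_volume(2)
#' @export
sphere_volume <- function(diameter) {
  if (any(!is.finite(diameter)) || any(diameter <= 0)) {
    stop("'diameter' must be positive", call. = FALSE)
  }
  (pi / 6) * diameter^3
}

#' Growth record series
#'
#' Validates a data.frame of spheroid growth records: a `time_days` column
#' plus exactly the measured quantity columns among `volume_um3`,
#' `diameter_um` and `cell_count`.
#'
#' @param df A data.frame with `time_days` and at least one quantity column.
#' @return The validated data.frame, sorted by time, with class
#'   `growth_series` prepended.
#' @export
growth_series <- function(df) {
  stopifnot(is.data.frame(df), "time_days" %in% names(df))
  qcols <- intersect(c("volume_um3", "diameter_um", "cell_count"), names(df))
  if (!length(qcols)) {
    stop("need at least one of volume_um3, diameter_um, cell_count",
         call. = FALSE)
  }
  if (any(df$time_days < 0)) stop("'time_days' must be >= 0", call. = FALSE)
  for (q in qcols) {
    v <- df[[q]]
    if (any(!is.na(v) & v <= 0)) {
      stop(sprintf("'%s' values must be positive", q), call. = FALSE)
    }
  }
  df <- df[order(df$time_days), , drop = FALSE]
  class(df) <- c("growth_series", class(df))
  df
}

#' Fold change relative to the first record
#'
#' Ratio of the chosen quantity to its value at the first (earliest) record;
#' the first entry is exactly 1, and the result is invariant to rescaling the
#' whole series.
#'
#' @param series A [growth_series()] (or plain data.frame accepted by it).
#' @param quantity One of `"volume_um3"`, `"diameter_um"`, `"cell_count"`.
#' @return Numeric vector of fold changes, one per record.
#' @examples
#' s <- growth_series(data.frame(time_days = c(0, 4, 8),
#'                               cell_count = c(1e6, 1.5e6, 2.74e6)))
#' fold_change(s, "cell_count")
#' @export
fold_change <- function(series,
                        quantity = c("volume_um3", "diameter_um",
                                     "cell_count")) {
  if (!inherits(series, "growth_series")) series <- growth_series(series)
  quantity <- match.arg(quantity)
  if (!quantity %in% names(series)) {
    stop(sprintf("series has no '%s' column", quantity), call. = FALSE)
  }
  v <- series[[quantity]]
  if (any(is.na(v))) stop("chosen quantity has missing values", call. = FALSE)
  v / v[1]
}

#' Microplate seeding arithmetic
#'
#' Capacity of a spheroid-forming microplate: wells with spheroid-forming
#' microcavities and a per-microcavity seeding density. Defaults describe a
#' 24-well plate with 12 spheroid-forming wells of 750 microcavities each,
#' seeded at 1500 cells per microcavity.
#'
#' @param forming_wells Spheroid-forming wells per plate.
#' @param microcavities_per_well Microcavities per well.
#' @param cells_per_microcavity Cells seeded per microcavity.
#' @return List with `spheroids_per_plate` and `cells_per_well`.
#' @examples
#' plate_capacity()
#' @export
plate_capacity <- function(forming_wells = 12,
                           microcavities_per_well = 750,
                           cells_per_microcavity = 1500) {
  stopifnot(forming_wells >= 1, microcavities_per_well >= 1,
            cells_per_microcavity >= 1)
  list(spheroids_per_plate = forming_wells * microcavities_per_well,
       cells_per_well = cells_per_microcavity * microcavities_per_well)
}
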