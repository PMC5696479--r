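#' Frequency-to-dB transformation table
#'
#' A named table of (frequency, dB value) pairs with a declared interpolation
#' policy, used for the ear-canal-to-free-field sound pressure transformation
#' T_d, for audiometric dB HL to dB SPL conversions, and for acceptance
#' corridor bounds.
#'
#' @param frequency_hz Strictly increasing frequencies in Hz (>= 2 entries).
#' @param value_db Finite dB values, one per frequency.
#' @param name Short name of the table.
#' @param interpolation `"linear_hz"` (default) interpolates linearly on the
#'   Hz axis; `"linear_log_hz"` linearly on log-frequency.
#' @return A data frame of class `transform_table` with columns
#'   `frequency_hz`, `value_db`.
#' @export
transform_table <- function(frequency_hz, value_db, name = "table",
                            interpolation = c("linear_hz", "linear_log_hz")) {
  interpolation <- match.arg(interpolation)
  frequency_hz <- as.numeric(frequency_hz)
  value_db <- as.numeric(value_db)
  if (length(frequency_hz) < 2L)
    stop("a transform table needs at least 2 entries", call. = FALSE)
  if (length(value_db) != length(frequency_hz))
    stop("`frequency_hz` and `value_db` lengths differ", call. = FALSE)
  if (is.unsorted(frequency_hz, strictly = TRUE))
    stop("`frequency_hz` must be strictly increasing", call. = FALSE)
  if (any(!is.finite(value_db)))
    stop("`value_db` must be finite", call. = FALSE)
  structure(data.frame(frequency_hz = frequency_hz, value_db = value_db),
            name = name, interpolation = interpolation,
            class = c("transform_table", "data.frame"))
}

#' Look up a transformation value
#'
#' Evaluates a [transform_table()] at frequencies `f`.  Values are exact at
#' table knots and interpolated between bracketing knots according to the
#' table's interpolation policy.  Frequencies outside the table span are an
#' error -- there is no silent extrapolation.  With `knot_only = TRUE` the
#' frequency must match a knot exactly (audiometric conversion tables).
#'
#' @param table A [transform_table()].
#' @param f Frequencies in Hz.
#' @param knot_only Require exact knot matches.
#' @return Numeric dB values.
#' @export
tt_lookup <- function(table, f, knot_only = FALSE) {
  stopifnot(inherits(table, "transform_table"))
  f <- as.numeric(f)
  if (knot_only) {
    idx <- match(f, table$frequency_hz)
    if (anyNA(idx)) {
      miss <- unique(f[is.na(idx)])
      stop(sprintf("frequency not in table '%s': %s", attr(table, "name"),
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    return(table$value_db[idx])
  }
  lo <- min(table$frequency_hz); hi <- max(table$frequency_hz)
  if (any(f < lo | f > hi))
    stop(sprintf(
      "frequency outside the span of table '%s' (%g-%g Hz); no extrapolation",
      attr(table, "name"), lo, hi), call. = FALSE)
  x <- table$frequency_hz
  xo <- f
  if (identical(attr(table, "interpolation"), "linear_log_hz")) {
    x <- log(x); xo <- log(f)
  }
  stats::approx(x, table$value_db, xout = xo, method = "linear",
                ties = "ordered")$y
}

#' @export
print.transform_table <- function(x, ...) {
  cat(sprintf("<transform_table> '%s' (%s), %d knots, %g-%g Hz\n",
              attr(x, "name"), attr(x, "interpolation"), nrow(x),
              min(x$frequency_hz), max(x$frequency_hz)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Placeholder ear-canal-to-free-field transformation table
#'
#' PLACEHOLDER VALUES.  The published frequency-specific transformation
#' between eardrum and free-field sound pressure is not shipped with this
#' package; this table contains smooth, physiologically plausible values
#' (canal/concha resonance gain peaking near 2.5 kHz) for demonstration and
#' simulation only.  Replace it with your laboratory's table via
#' [transform_table()] or [read_transform_table()] for real analyses.
#'
#' @return A [transform_table()] named `"td_placeholder"`.
#' @export
td_placeholder <- function() {
  transform_table(
    frequency_hz = c(100, 200, 400, 630, 1000, 1500, 2000, 2500, 3000,
                     4000, 5000, 6300, 8000, 10000),
    value_db = c(0.5, 1, 1.5, 2.5, 3.5, 5.5, 9, 14.5, 16, 13, 9.5, 6,
                 2.5, -1),
    name = "td_placeholder")
}

#' Flat (identity) transformation table
#'
#' A constant table, mostly useful for tests: with `value_db = 0` the
#' ear-canal and free-field levels coincide.
#'
#' @param value_db Constant value in dB.
#' @param band Two-element span in Hz.
#' @return A [transform_table()].
#' @export
td_flat <- function(value_db = 0, band = c(50, 12000)) {
  transform_table(band, rep(value_db, 2), name = "td_flat")
}
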