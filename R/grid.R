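#' Uniform FFT frequency grid
#'
#' Represents the analysis grid of an FFT-based acquisition chain: `n_bins`
#' uniformly spaced lines starting at `f_start`, with spacing `bin_spacing`.
#' The default mirrors a 12.5 Hz-resolution acquisition spanning 0-10 kHz
#' inclusive, so that both band edges -- including the 10 kHz stimulation
#' tone -- fall exactly on a grid line, plus three guard lines above the
#' band so the adjacent-bin noise estimate is defined at 10 kHz (804 lines
#' in total).
#'
#' @param bin_spacing Line spacing in Hz (> 0).
#' @param n_bins Number of FFT lines.
#' @param f_start Frequency of the first line in Hz (default 0).
#' @return An object of class `frequency_grid` with elements `bin_spacing`,
#'   `n_bins`, `f_start` and `frequencies`.
#' @examples
#' g <- frequency_grid()
#' range(g$frequencies)  # 0 to 10000 Hz
#' @export
frequency_grid <- function(bin_spacing = 12.5, n_bins = 804L, f_start = 0) {
  stop_if_not_scalar_number(bin_spacing, "bin_spacing")
  if (bin_spacing <= 0) stop("`bin_spacing` must be > 0", call. = FALSE)
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("`n_bins` must be >= 1", call. = FALSE)
  structure(
    list(bin_spacing = bin_spacing,
         n_bins = n_bins,
         f_start = f_start,
         frequencies = f_start + (seq_len(n_bins) - 1) * bin_spacing),
    class = "frequency_grid")
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf("<frequency_grid> %d bins, %.4g Hz spacing, %.4g-%.4g Hz\n",
              x$n_bins, x$bin_spacing, x$frequencies[1],
              x$frequencies[x$n_bins]))
  invisible(x)
}

#' Locate the grid bin of a stimulation frequency
#'
#' Snaps `f` to the nearest FFT line.  A frequency is considered on-grid when
#' it lies within half a bin spacing of a line; anything farther away is an
#' error, because a pure tone generated by the same clock as the acquisition
#' always falls exactly on a line.
#'
#' @param grid A [frequency_grid()].
#' @param f Frequency in Hz.
#' @return Integer bin index (1-based).
#' @export
bin_index <- function(grid, f) {
  stopifnot(inherits(grid, "frequency_grid"))
  stop_if_not_scalar_number(f, "f")
  idx <- round((f - grid$f_start) / grid$bin_spacing) + 1
  if (idx < 1 || idx > grid$n_bins)
    stop(sprintf("frequency %g Hz is outside the grid", f), call. = FALSE)
  if (abs(f - grid$frequencies[idx]) > grid$bin_spacing / 2 + 1e-9)
    stop(sprintf("frequency %g Hz is off-grid by more than half a bin", f),
         call. = FALSE)
  as.integer(idx)
}

#' Complex amplitude spectrum on a frequency grid
#'
#' Container for an (averaged) complex spectrum as produced by a multichannel
#' FFT acquisition: one complex amplitude per grid line, a physical unit, and
#' the number of coherent averages that produced it.
#'
#' @param values Complex vector, one value per grid bin.
#' @param grid A [frequency_grid()].
#' @param unit Unit string, one of `"Pa"`, `"m/s"`, `"m"`, `"V"`.
#' @param n_averages Number of coherent averages behind `values` (optional).
#' @return An object of class `complex_spectrum`.
#' @export
complex_spectrum <- function(values, grid, unit, n_averages = NA_integer_) {
  stopifnot(inherits(grid, "frequency_grid"))
  if (length(values) != grid$n_bins)
    stop("`values` must have one element per grid bin", call. = FALSE)
  unit <- match.arg(unit, c("Pa", "m/s", "m", "V"))
  structure(
    list(grid = grid, values = as.complex(values), unit = unit,
         n_averages = as.integer(n_averages)),
    class = "complex_spectrum")
}

#' @export
print.complex_spectrum <- function(x, ...) {
  cat(sprintf("<complex_spectrum> %d bins [%s], %s averages\n",
              x$grid$n_bins, x$unit,
              ifelse(is.na(x$n_averages), "?", x$n_averages)))
  invisible(x)
}

#' Pure-tone stimulus sequence
#'
#' An ordered set of stimulation frequencies, each of which must lie on the
#' acquisition grid.  The default is the package's 23-tone sequence: a
#' roughly 3-steps-per-octave geometric series from 100 Hz to 10 kHz snapped
#' to the 12.5 Hz grid, augmented with the audiometric frequencies 3 and
#' 6 kHz so that all standard audiometric comparison frequencies except
#' 1.5 kHz are stimulated directly.
#'
#' @param frequencies Numeric vector of tone frequencies in Hz.
#' @param grid A [frequency_grid()] the tones must lie on.
#' @return An object of class `stimulus_sequence` (numeric vector of Hz).
#' @examples
#' length(stimulus_sequence())  # 23 tones
#' @export
stimulus_sequence <- function(frequencies = default_tone_frequencies(),
                              grid = frequency_grid()) {
  frequencies <- sort(as.numeric(frequencies))
  if (anyDuplicated(frequencies))
    stop("duplicate stimulus frequencies", call. = FALSE)
  ## validates each tone is on-grid
  invisible(vapply(frequencies, function(f) bin_index(grid, f), integer(1)))
  structure(frequencies, class = "stimulus_sequence")
}

#' @rdname stimulus_sequence
#' @export
default_tone_frequencies <- function() {
  c(100, 125, 162.5, 200, 250, 312.5, 400, 500, 625, 787.5, 1000,
    1262.5, 1587.5, 2000, 2525, 3000, 3175, 4000, 5037.5, 6000, 6350,
    8000, 10000)
}

#' Audiometric comparison frequencies
#'
#' The standard audiometric frequencies at which temporal-bone and clinical
#' actuator outputs are compared (0.25-6 kHz).
#'
#' @return Numeric vector of Hz.
#' @export
audiometric_frequencies <- function() {
  c(250, 500, 1000, 1500, 2000, 3000, 4000, 6000)
}
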