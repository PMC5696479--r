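#' Adjacent-bin signal-to-noise ratio of a stimulation tone
#'
#' Estimates the SNR of a pure tone from a complex spectrum, using the mean
#' of the three FFT lines below and three above the stimulation bin as the
#' noise level estimate.  By default the six neighbour *amplitudes* are
#' averaged; `noise_average = "power"` switches to an RMS (power) average of
#' the neighbours.
#'
#' SNR is capped at +/-200 dB so that noiseless synthetic spectra stay
#' finite: a zero noise estimate returns +200 dB, a zero signal with nonzero
#' noise returns -200 dB.
#'
#' @param spectrum A [complex_spectrum()].
#' @param stim_bin 1-based bin index of the stimulation tone; must have at
#'   least three bins on each side.
#' @param noise_average `"amplitude"` (default) or `"power"`.
#' @return SNR in dB.
#' @examples
#' g <- frequency_grid(1, 11)
#' v <- rep(0.1 + 0i, 11); v[6] <- 1
#' snr_estimate(complex_spectrum(v, g, "Pa"), 6)  # 20 dB
#' @export
snr_estimate <- function(spectrum, stim_bin,
                         noise_average = c("amplitude", "power")) {
  stopifnot(inherits(spectrum, "complex_spectrum"))
  noise_average <- match.arg(noise_average)
  n <- spectrum$grid$n_bins
  stim_bin <- as.integer(stim_bin)
  if (stim_bin - 3L < 1L || stim_bin + 3L > n)
    stop("stimulation bin too close to the grid edge for noise estimation",
         call. = FALSE)
  sig <- Mod(spectrum$values[stim_bin])
  nb <- Mod(spectrum$values[stim_bin + c(-3L, -2L, -1L, 1L, 2L, 3L)])
  noise <- if (noise_average == "amplitude") mean(nb) else sqrt(mean(nb^2))
  if (noise == 0) return(200)
  if (sig == 0) return(-200)
  max(-200, min(200, amp_db(sig / noise)))
}

#' Coherent averaging until a target SNR is reached
#'
#' Averages complex spectrum frames coherently (complex mean) until the SNR
#' at the stimulation bin reaches `snr_target`, with at least `n_min` and at
#' most `n_max` averages -- the acquisition protocol used for intracochlear
#' pressure and vibrometry responses (target 12 dB, 30 to 1000 averages).
#' If the target is never reached, all available frames up to `n_max` are
#' used and the (sub-target) SNR is reported; exclusion of such responses is
#' the caller's decision.
#'
#' @param frames A list of complex vectors, or a matrix with one frame per
#'   row, all on `grid`.
#' @param stim_bin 1-based stimulation bin index.
#' @param grid The [frequency_grid()] of the frames.
#' @param unit Unit string of the frames.
#' @param snr_target Target SNR in dB (default 12).
#' @param n_min,n_max Minimum / maximum number of averages (defaults 30 and
#'   1000).
#' @param noise_average Passed to [snr_estimate()].
#' @return A list with `spectrum` (the averaged [complex_spectrum()] carrying
#'   `n_averages`), `n_used` and `snr_db`.
#' @export
average_until_snr <- function(frames, stim_bin, grid, unit,
                              snr_target = 12, n_min = 30L, n_max = 1000L,
                              noise_average = c("amplitude", "power")) {
  noise_average <- match.arg(noise_average)
  if (is.list(frames)) frames <- do.call(rbind, frames)
  if (!is.matrix(frames) || ncol(frames) != grid$n_bins)
    stop("`frames` must be a list/matrix of spectra on `grid`", call. = FALSE)
  n_avail <- nrow(frames)
  if (n_avail < n_min)
    stop(sprintf("need at least n_min = %d frames, got %d", n_min, n_avail),
         call. = FALSE)
  n_cap <- min(n_max, n_avail)
  stim_bin <- as.integer(stim_bin)
  if (stim_bin - 3L < 1L || stim_bin + 3L > grid$n_bins)
    stop("stimulation bin too close to the grid edge", call. = FALSE)

  ## cumulative sums over the 7 bins that the SNR estimate needs
  cols <- stim_bin + (-3L:3L)
  csum <- apply(frames[, cols, drop = FALSE], 2, cumsum)
  if (n_avail == 1L) csum <- matrix(csum, nrow = 1L)
  snr_at <- function(n) {
    m <- csum[n, ] / n
    sig <- Mod(m[4L])
    nb <- Mod(m[-4L])
    noise <- if (noise_average == "amplitude") mean(nb) else sqrt(mean(nb^2))
    if (noise == 0) return(200)
    if (sig == 0) return(-200)
    max(-200, min(200, amp_db(sig / noise)))
  }

  n_used <- n_cap
  for (n in n_min:n_cap) {
    if (snr_at(n) >= snr_target) { n_used <- n; break }
  }
  mean_values <- colMeans(frames[seq_len(n_used), , drop = FALSE])
  out <- complex_spectrum(mean_values, grid, unit, n_averages = n_used)
  list(spectrum = out, n_used = n_used, snr_db = snr_at(n_used))
}

#' Extract a single stimulation tone from a spectrum
#'
#' Picks the complex amplitude of the grid bin nearest to `f` (within half a
#' bin spacing) and records the adjacent-bin SNR of that bin.
#'
#' @param spectrum A [complex_spectrum()].
#' @param f Tone frequency in Hz.
#' @inheritParams snr_estimate
#' @return A list with `frequency` (the snapped bin frequency), `response`
#'   (complex), `snr_db`, `n_averages` and `unit`.
#' @export
extract_tone <- function(spectrum, f,
                         noise_average = c("amplitude", "power")) {
  stopifnot(inherits(spectrum, "complex_spectrum"))
  noise_average <- match.arg(noise_average)
  bin <- bin_index(spectrum$grid, f)
  list(frequency = spectrum$grid$frequencies[bin],
       response = spectrum$values[bin],
       snr_db = snr_estimate(spectrum, bin, noise_average),
       n_averages = spectrum$n_averages,
       unit = spectrum$unit)
}

#' Renormalize two sequentially measured runs to a common input
#'
#' When two response channels are acquired in separate stimulations (for
#' example intracochlear pressures first, then stapes vibration), the input
#' signal differs minutely between the runs.  This function rescales both
#' runs' responses (complex division) so that each tone shares a common
#' input reference -- the complex geometric mean of the two recorded inputs.
#' The physically meaningful response/input ratios are unchanged to machine
#' precision.
#'
#' Input discrepancies beyond `tol_db` / `tol_deg` are reported with a
#' warning but processing continues, since the ratio is invariant anyway.
#'
#' @param run_a,run_b Data frames with columns `frequency`, `response`
#'   (complex) and `input_ref` (complex), covering the same frequencies in
#'   the same order; extra columns are preserved.
#' @param tol_db,tol_deg Tolerated per-tone input discrepancy in magnitude
#'   (dB, default 1) and phase (degrees, default 5).
#' @return A list with elements `run_a` and `run_b`, both carrying the common
#'   `input_ref`.
#' @export
renormalize_to_common_input <- function(run_a, run_b, tol_db = 1,
                                        tol_deg = 5) {
  if (!isTRUE(all.equal(run_a$frequency, run_b$frequency)))
    stop("runs must cover the same frequencies", call. = FALSE)
  a <- as.complex(run_a$input_ref)
  b <- as.complex(run_b$input_ref)
  if (any(Mod(a) == 0) || any(Mod(b) == 0))
    stop("zero input reference", call. = FALSE)
  dmag <- abs(amp_db(Mod(b) / Mod(a)))
  dph <- abs(Arg(b / a)) * 180 / pi
  bad <- dmag > tol_db | dph > tol_deg
  if (any(bad))
    warning(sprintf(
      "input discrepancy beyond tolerance at %d tone(s) (max %.2f dB, %.2f deg); proceeding",
      sum(bad), max(dmag), max(dph)), call. = FALSE)
  ## complex geometric mean: sqrt of magnitudes, halfway phase
  g <- sqrt(Mod(a) * Mod(b)) * exp(1i * (Arg(a) + Arg(b / a) / 2))
  run_a$response <- run_a$response * g / a
  run_a$input_ref <- g
  run_b$response <- run_b$response * g / b
  run_b$input_ref <- g
  list(run_a = run_a, run_b = run_b)
}

#' Cosine correction of single-point vibrometry data
#'
#' Corrects a velocity (or displacement) measured with a laser beam at angle
#' `angle_deg` to the surface normal: the measured projection is divided by
#' `cos(angle)`.  Angles of 90 degrees or more carry no information about
#' the normal component and are rejected.
#'
#' @param v Complex velocity (vectorized).
#' @param angle_deg Beam angle to the surface normal, in `[0, 90)` degrees.
#' @return Corrected complex velocity.
#' @examples
#' Mod(cosine_correct(1 + 0i, 60))  # 2
#' @export
cosine_correct <- function(v, angle_deg) {
  stop_if_not_scalar_number(angle_deg, "angle_deg")
  if (angle_deg < 0 || angle_deg >= 90)
    stop("`angle_deg` must be in [0, 90)", call. = FALSE)
  v / cospi(angle_deg / 180)
}

#' Convert complex velocity to displacement
#'
#' For a stationary tone at frequency `f`, displacement is velocity divided
#' by `i * 2 * pi * f`: the magnitude scales by `1/(2 pi f)` and the phase
#' shifts by -90 degrees.
#'
#' @param v Complex velocity in m/s (vectorized).
#' @param f Frequency in Hz (> 0; recycled against `v`).
#' @return Complex displacement in m.
#' @export
velocity_to_displacement <- function(v, f) {
  if (any(!is.finite(f)) || any(f <= 0))
    stop("`f` must be positive and finite", call. = FALSE)
  v / (1i * 2 * pi * f)
}
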