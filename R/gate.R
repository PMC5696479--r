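#' Middle-ear transfer function of the acoustic run
#'
#' The per-tone magnitude of the cosine-corrected stapes response per unit
#' ear-canal pressure, as displacement (default) or velocity per Pa.  This
#' is the quantity gated against an acceptance corridor before a temporal
#' bone enters the analysis.  Tones whose stapes-response SNR falls below
#' `snr_threshold` are flagged invalid and ignored by the gate.
#'
#' @param record A [tb_record()].
#' @param quantity `"displacement"` (m/Pa) or `"velocity"` (m/s/Pa).
#' @param snr_threshold Minimum SNR in dB for a tone to count (default 12).
#' @return A data frame with columns `frequency_hz`, `magnitude`,
#'   `level_db` (dB re 1 of the chosen unit) and `valid`.
#' @export
metf <- function(record, quantity = c("displacement", "velocity"),
                 snr_threshold = 12) {
  stopifnot(inherits(record, "tb_record"))
  quantity <- match.arg(quantity)
  ac <- record$acoustic
  v <- cosine_correct(ac$v_stapes, record$angle_deg)
  resp <- if (quantity == "displacement")
    velocity_to_displacement(v, ac$frequency) else v
  mag <- Mod(resp / ac$p_t)
  valid <- !is.na(ac$snr_stapes) & ac$snr_stapes >= snr_threshold &
    !is.na(mag) & mag > 0
  data.frame(frequency_hz = ac$frequency, magnitude = mag,
             level_db = ifelse(valid, amp_db(mag), NA_real_),
             valid = valid)
}

#' Acceptance corridor for the middle-ear transfer function
#'
#' Lower and upper bounds, in dB re 1 of the gated quantity, that a bone's
#' middle-ear transfer function must stay within over the check band
#' (default 0.25-4 kHz) to be accepted for analysis.  Bounds are supplied as
#' [transform_table()]s and interpolated at the stimulation tones.
#'
#' @param lower,upper [transform_table()]s of bound levels in dB.
#' @param check_band Two-element band in Hz over which the gate applies.
#' @return An object of class `acceptance_corridor`.
#' @export
acceptance_corridor <- function(lower, upper, check_band = c(250, 4000)) {
  stopifnot(inherits(lower, "transform_table"),
            inherits(upper, "transform_table"))
  span <- function(t) range(t$frequency_hz)
  if (span(lower)[1] > check_band[1] || span(lower)[2] < check_band[2] ||
      span(upper)[1] > check_band[1] || span(upper)[2] < check_band[2])
    stop("corridor tables must cover the check band", call. = FALSE)
  probe <- sort(unique(c(check_band,
                         lower$frequency_hz[lower$frequency_hz >= check_band[1] &
                                              lower$frequency_hz <= check_band[2]],
                         upper$frequency_hz[upper$frequency_hz >= check_band[1] &
                                              upper$frequency_hz <= check_band[2]])))
  if (any(tt_lookup(lower, probe) > tt_lookup(upper, probe)))
    stop("lower bound exceeds upper bound inside the check band",
         call. = FALSE)
  structure(list(lower = lower, upper = upper, check_band = check_band),
            class = "acceptance_corridor")
}

#' Gate a middle-ear transfer function against a corridor
#'
#' A bone passes when every SNR-valid tone inside the check band lies within
#' the corridor, bounds inclusive.  Tones outside the band never influence
#' the verdict.  Per-tone verdicts are retained for reporting.
#'
#' @param metf_series A data frame from [metf()].
#' @param corridor An [acceptance_corridor()].
#' @return An object of class `gate_report`: list with `pass` (logical),
#'   `verdicts` (data frame with per-tone `within`, `lower_db`, `upper_db`)
#'   and `violating_frequencies`.
#' @export
check_acceptance <- function(metf_series, corridor) {
  stopifnot(inherits(corridor, "acceptance_corridor"))
  band <- corridor$check_band
  in_band <- metf_series$frequency_hz >= band[1] &
    metf_series$frequency_hz <= band[2]
  use <- in_band & metf_series$valid
  if (!any(use))
    stop("no SNR-valid tones inside the check band; gate not applicable",
         call. = FALSE)
  f <- metf_series$frequency_hz[use]
  lo <- tt_lookup(corridor$lower, f)
  up <- tt_lookup(corridor$upper, f)
  lev <- metf_series$level_db[use]
  within <- lev >= lo & lev <= up
  verdicts <- data.frame(frequency_hz = f, level_db = lev,
                         lower_db = lo, upper_db = up, within = within)
  structure(list(pass = all(within), verdicts = verdicts,
                 violating_frequencies = f[!within]),
            class = "gate_report")
}

#' @export
print.gate_report <- function(x, ...) {
  cat(sprintf("<gate_report> %s (%d/%d tones within corridor)\n",
              if (x$pass) "PASS" else "FAIL", sum(x$verdicts$within),
              nrow(x$verdicts)))
  if (!x$pass)
    cat("  violating:", paste(x$violating_frequencies, collapse = ", "),
        "Hz\n")
  invisible(x)
}

#' Gate a cohort of temporal bones
#'
#' Applies [metf()] and [check_acceptance()] to each record and tabulates
#' the verdicts.
#'
#' @param records List of [tb_record()]s.
#' @inheritParams metf
#' @param corridor An [acceptance_corridor()].
#' @return A data frame with columns `bone_id`, `pass`,
#'   `violating_frequencies` (comma-separated).
#' @export
gate_cohort <- function(records, corridor,
                        quantity = c("displacement", "velocity"),
                        snr_threshold = 12) {
  quantity <- match.arg(quantity)
  rows <- lapply(records, function(r) {
    rep_ <- check_acceptance(metf(r, quantity, snr_threshold), corridor)
    data.frame(bone_id = r$bone_id, pass = rep_$pass,
               violating_frequencies =
                 paste(rep_$violating_frequencies, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
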