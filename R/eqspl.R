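#' Intracochlear pressure difference
#'
#' The complex (vector) difference between the sound pressures in scala
#' vestibuli and scala tympani, taken in the frequency domain.  The
#' difference is treated as the effective input to the cochlea: common-mode
#' pressure cancels.
#'
#' @param p_sv,p_st Complex pressures (Pa) measured simultaneously at the
#'   same frequency with phase-calibrated sensors.  Vectorized.
#' @return Complex pressure difference in Pa.
#' @examples
#' Mod(icpd(1 + 0i, 0.5i))  # sqrt(1.25)
#' @export
icpd <- function(p_sv, p_st) {
  as.complex(p_sv) - as.complex(p_st)
}

#' Equivalent ear-canal SPL from stapes displacement
#'
#' Computes the maximum achievable equivalent sound pressure level at the
#' tympanic membrane produced by an actuator driven at `e_max` volts rms,
#' from paired acoustic and actuator measurements of stapes displacement:
#'
#'   L = 20 log10( |d_A/E * p_T/d_U| * E_max / 2e-5 Pa )
#'
#' where `d_U` is the stapes displacement per the acoustic run at ear-canal
#' pressure `p_T`, and `d_A` the displacement driven by voltage `E`.  The
#' magnitude of the full complex ratio product is taken in the final step
#' (per-factor magnitudes give the identical level).  Displacements must
#' already be cosine-corrected and converted from velocity.
#'
#' @param d_u Complex unimplanted (acoustic-run) stapes displacement, m.
#' @param p_t Complex ear-canal pressure at the tympanic membrane, Pa.
#' @param d_a Complex actuator-driven stapes displacement, m.
#' @param e Complex actuator drive voltage, V rms.
#' @param e_max Hypothetical drive voltage the level is normalized to
#'   (default 1 V rms).
#' @return Equivalent dB SPL at the tympanic membrane.  Vectorized.
#' @export
eqspl_from_stapes <- function(d_u, p_t, d_a, e, e_max = 1) {
  if (any(Mod(as.complex(d_u)) == 0) || any(Mod(as.complex(p_t)) == 0) ||
      any(Mod(as.complex(e)) == 0))
    stop("zero denominator quantity (d_U, p_T or E)", call. = FALSE)
  amp_db(Mod(as.complex(d_a) / as.complex(e) *
               as.complex(p_t) / as.complex(d_u)) * e_max / PA_REF)
}

#' Equivalent ear-canal SPL from intracochlear pressure difference
#'
#' Same normalization as [eqspl_from_stapes()], with the intracochlear
#' pressure difference in place of stapes displacement.  The equivalent
#' ear-canal sound pressure transfer function is
#' `H_ET = (dP_A / E) * (p_T / dP_U)` and the level is
#' `L = 20 log10(|H_ET| * E_max / 2e-5 Pa)`.
#'
#' @param dp_u Complex acoustic-run pressure difference, Pa.
#' @param p_t Complex ear-canal pressure during the acoustic run, Pa.
#' @param dp_a Complex actuator-run pressure difference, Pa.
#' @inheritParams eqspl_from_stapes
#' @return Equivalent dB SPL at the tympanic membrane.  Vectorized.
#' @export
eqspl_from_icpd <- function(dp_u, p_t, dp_a, e, e_max = 1) {
  if (any(Mod(as.complex(dp_u)) == 0) || any(Mod(as.complex(p_t)) == 0) ||
      any(Mod(as.complex(e)) == 0))
    stop("zero denominator quantity (dP_U, p_T or E)", call. = FALSE)
  h_et <- as.complex(dp_a) / as.complex(e) * as.complex(p_t) /
    as.complex(dp_u)
  amp_db(Mod(h_et) * e_max / PA_REF)
}

#' Convert equivalent SPL at the eardrum to free field
#'
#' Subtracts the frequency-specific ear-canal-to-free-field transformation
#' value `T_d(f)`: `L_FF = L_TM - T_d(f)`.  `T_d` is exact at table knots
#' and interpolated between the adjacent table frequencies below and above.
#'
#' @param l_tm Equivalent dB SPL at the tympanic membrane (vectorized).
#' @param f Frequencies in Hz, recycled against `l_tm`.
#' @param td_table A [transform_table()] of `T_d` values.
#' @return Equivalent dB SPL in the free field.
#' @export
to_free_field <- function(l_tm, f, td_table) {
  l_tm - tt_lookup(td_table, f)
}

#' Temporal-bone measurement record
#'
#' Bundles the paired acoustic and actuator stimulation runs of one cadaver
#' temporal bone at one actuator position.  Each run holds, per stimulation
#' tone, the complex input reference (ear-canal pressure `p_t` in Pa for the
#' acoustic run, drive voltage `e` in V rms for the actuator run), the
#' measured complex stapes velocity and scala vestibuli / scala tympani
#' pressures, and the per-channel SNR of each response.  Runs are expected
#' to be already renormalized to a common input
#' (see [renormalize_to_common_input()]).
#'
#' @param bone_id Bone identifier.
#' @param position_label Actuator coupling position, `"4 mN"` (initial
#'   contact force) or `"4 mN + 60 um"` (advanced by 60 micrometres).
#' @param contact_force_mn Static contact force in mN (>= 0).
#' @param angle_deg Laser beam angle to the stapes footplate normal,
#'   degrees; applied to both runs by the analysis.
#' @param acoustic Data frame with columns `frequency`, `p_t`, `v_stapes`,
#'   `p_sv`, `p_st` (complex), `snr_stapes`, `snr_sv`, `snr_st`,
#'   `n_averages`.
#' @param actuator Same layout with drive voltage column `e` instead of
#'   `p_t`.
#' @return An object of class `tb_record`.
#' @export
tb_record <- function(bone_id, position_label, contact_force_mn, angle_deg,
                      acoustic, actuator) {
  position_label <- match.arg(position_label, c("4 mN", "4 mN + 60 um"))
  stop_if_not_scalar_number(contact_force_mn, "contact_force_mn")
  if (contact_force_mn < 0) stop("`contact_force_mn` must be >= 0",
                                 call. = FALSE)
  need_ac <- c("frequency", "p_t", "v_stapes", "p_sv", "p_st",
               "snr_stapes", "snr_sv", "snr_st")
  need_act <- c("frequency", "e", "v_stapes", "p_sv", "p_st",
                "snr_stapes", "snr_sv", "snr_st")
  if (!all(need_ac %in% names(acoustic)))
    stop("acoustic run missing columns: ",
         paste(setdiff(need_ac, names(acoustic)), collapse = ", "),
         call. = FALSE)
  if (!all(need_act %in% names(actuator)))
    stop("actuator run missing columns: ",
         paste(setdiff(need_act, names(actuator)), collapse = ", "),
         call. = FALSE)
  if (!isTRUE(all.equal(acoustic$frequency, actuator$frequency)))
    stop("acoustic and actuator runs must share the stimulus sequence",
         call. = FALSE)
  if (nrow(acoustic) == 0) stop("empty measurement runs", call. = FALSE)
  structure(
    list(bone_id = as.character(bone_id), position_label = position_label,
         contact_force_mn = contact_force_mn, angle_deg = angle_deg,
         acoustic = acoustic, actuator = actuator),
    class = "tb_record")
}

#' @export
print.tb_record <- function(x, ...) {
  cat(sprintf("<tb_record> %s @ '%s' (%.1f mN, beam %.1f deg), %d tones %g-%g Hz\n",
              x$bone_id, x$position_label, x$contact_force_mn, x$angle_deg,
              nrow(x$acoustic), min(x$acoustic$frequency),
              max(x$acoustic$frequency)))
  invisible(x)
}

#' Equivalent free-field output series of a temporal bone
#'
#' The central estimator: computes, per stimulation tone, the equivalent
#' free-field sound pressure level the actuator produces at `e_max` volts
#' rms, using either stapes motion or the intracochlear pressure difference
#' as the cochlear-input reference.
#'
#' The stapes path cosine-corrects the measured velocities, converts them to
#' displacement, and applies the displacement-ratio level formula; the ICPD
#' path forms the scala vestibuli minus scala tympani vector difference in
#' both runs and applies the pressure-ratio level formula.  The eardrum-
#' referenced level is finally converted to free field with `td_table`.
#' Tones whose relevant response SNR falls below `snr_threshold`
#' (inclusive bound: SNR equal to the threshold is kept) are masked with
#' reason `"snr"`; tones with missing data are masked with reason
#' `"missing"`.  Masked tones carry `NA` levels, never zeros.
#'
#' @param record A [tb_record()].
#' @param reference `"stapes"` or `"icpd"`.
#' @param td_table A [transform_table()] of ear-canal-to-free-field values.
#' @param snr_threshold Minimum acceptable SNR in dB (default 12).
#' @param e_max Drive voltage the output is normalized to (default 1 V rms).
#' @return An `eqspl_series`: a data frame with columns `frequency_hz`,
#'   `level_db` (eq. dB SPL_FF), `excluded`, `reason`, carrying the bone id,
#'   position, reference and `e_max` as attributes.
#' @examples
#' rec <- generate_tb(seed = 1)
#' s <- tb_output_series(rec, "icpd", td_placeholder())
#' head(as.data.frame(s))
#' @export
tb_output_series <- function(record, reference = c("stapes", "icpd"),
                             td_table, snr_threshold = 12, e_max = 1) {
  stopifnot(inherits(record, "tb_record"))
  reference <- match.arg(reference)
  ac <- record$acoustic
  act <- record$actuator
  n <- nrow(ac)
  if (n == 0) stop("empty measurement runs", call. = FALSE)

  if (reference == "stapes") {
    snr_ok <- ac$snr_stapes >= snr_threshold & act$snr_stapes >= snr_threshold
    vals <- cbind(ac$p_t, ac$v_stapes, act$e, act$v_stapes)
  } else {
    snr_ok <- ac$snr_sv >= snr_threshold & ac$snr_st >= snr_threshold &
      act$snr_sv >= snr_threshold & act$snr_st >= snr_threshold
    vals <- cbind(ac$p_t, ac$p_sv, ac$p_st, act$e, act$p_sv, act$p_st)
  }
  missing_mask <- apply(vals, 1, function(r) any(is.na(r)))
  snr_ok[is.na(snr_ok)] <- FALSE

  level <- rep(NA_real_, n)
  keep <- !missing_mask & snr_ok
  if (any(keep)) {
    f <- ac$frequency[keep]
    if (reference == "stapes") {
      d_u <- velocity_to_displacement(
        cosine_correct(ac$v_stapes[keep], record$angle_deg), f)
      d_a <- velocity_to_displacement(
        cosine_correct(act$v_stapes[keep], record$angle_deg), f)
      l_tm <- eqspl_from_stapes(d_u, ac$p_t[keep], d_a, act$e[keep], e_max)
    } else {
      dp_u <- icpd(ac$p_sv[keep], ac$p_st[keep])
      dp_a <- icpd(act$p_sv[keep], act$p_st[keep])
      l_tm <- eqspl_from_icpd(dp_u, ac$p_t[keep], dp_a, act$e[keep], e_max)
    }
    level[keep] <- to_free_field(l_tm, f, td_table)
  }

  reason <- rep("", n)
  reason[!snr_ok] <- "snr"
  reason[missing_mask] <- "missing"  # missing data trumps the SNR flag
  eqspl_series(frequency_hz = ac$frequency, level_db = level,
               excluded = !keep, reason = reason,
               reference = reference, e_max = e_max,
               bone_id = record$bone_id,
               position_label = record$position_label)
}

#' Construct an equivalent-SPL series
#'
#' Low-level constructor for the per-frequency output-level container used
#' throughout the package (temporal-bone and clinical paths alike).
#'
#' @param frequency_hz Frequencies in Hz.
#' @param level_db Equivalent dB SPL_FF levels (`NA` where excluded).
#' @param excluded Logical exclusion mask.
#' @param reason Character reason per tone (`""`, `"snr"`, `"missing"`).
#' @param reference `"stapes"`, `"icpd"` or `"clinical"`.
#' @param e_max Normalization voltage, V rms.
#' @param bone_id,position_label Provenance labels (either may be `NA`).
#' @return An object of classes `eqspl_series` and `data.frame`.
#' @export
eqspl_series <- function(frequency_hz, level_db, excluded = rep(FALSE, length(frequency_hz)),
                         reason = rep("", length(frequency_hz)),
                         reference = c("stapes", "icpd", "clinical"),
                         e_max = 1, bone_id = NA_character_,
                         position_label = NA_character_) {
  reference <- match.arg(reference)
  if (any(!excluded & !is.finite(level_db)))
    stop("non-finite level at a non-excluded tone", call. = FALSE)
  structure(
    data.frame(frequency_hz = frequency_hz, level_db = level_db,
               excluded = excluded, reason = reason,
               stringsAsFactors = FALSE),
    reference = reference, e_max = e_max, bone_id = bone_id,
    position_label = position_label,
    class = c("eqspl_series", "data.frame"))
}

#' @export
print.eqspl_series <- function(x, ...) {
  cat(sprintf("<eqspl_series> reference=%s, E_max=%g V rms, id=%s, position=%s\n",
              attr(x, "reference"), attr(x, "e_max"), attr(x, "bone_id"),
              attr(x, "position_label")))
  cat(sprintf("  %d tones, %d excluded (%s)\n", nrow(x), sum(x$excluded),
              if (any(x$excluded))
                paste(unique(x$reason[x$excluded]), collapse = ", ")
              else "-"))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
plot.eqspl_series <- function(x, ..., ylab = "eq. dB SPL_FF",
                              xlab = "Frequency (Hz)") {
  ok <- !x$excluded
  graphics::plot(x$frequency_hz[ok], x$level_db[ok], log = "x", type = "b",
                 xlab = xlab, ylab = ylab,
                 main = sprintf("%s (%s)", attr(x, "bone_id"),
                                attr(x, "reference")), ...)
  if (any(x$excluded))
    graphics::rug(x$frequency_hz[x$excluded], col = "red")
  invisible(x)
}
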