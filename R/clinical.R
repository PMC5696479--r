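#' Clinical threshold record of one implant recipient
#'
#' Per-patient paired thresholds at the audiometric frequencies: the
#' bone-conduction threshold `bc_db_hl` (dB HL), the direct threshold
#' through the implant's own drive `direct_db_met` (dB MET), and optionally
#' the air-conduction threshold and preoperative air-bone gap used by the
#' bone-conduction fallback rule.  Any threshold may be `NA` (not measured).
#'
#' @param patient_id Patient identifier.
#' @param thresholds Data frame with columns `frequency_hz`, `bc_db_hl`,
#'   `direct_db_met` and optionally `ac_db_hl`, `preop_abg_db`.
#' @return An object of class `clinical_record`.
#' @export
clinical_record <- function(patient_id, thresholds) {
  need <- c("frequency_hz", "bc_db_hl", "direct_db_met")
  if (!all(need %in% names(thresholds)))
    stop("thresholds missing columns: ",
         paste(setdiff(need, names(thresholds)), collapse = ", "),
         call. = FALSE)
  if (is.null(thresholds$ac_db_hl))
    thresholds$ac_db_hl <- NA_real_
  if (is.null(thresholds$preop_abg_db))
    thresholds$preop_abg_db <- NA_real_
  usable_b <- !is.na(thresholds$bc_db_hl) |
    (!is.na(thresholds$ac_db_hl) & !is.na(thresholds$preop_abg_db) &
       thresholds$preop_abg_db <= 10)
  if (!any(usable_b & !is.na(thresholds$direct_db_met)))
    stop("record needs at least one frequency with both a usable BC and a direct threshold",
         call. = FALSE)
  structure(list(patient_id = as.character(patient_id),
                 thresholds = thresholds),
            class = "clinical_record")
}

#' @export
print.clinical_record <- function(x, ...) {
  cat(sprintf("<clinical_record> %s, %d frequencies\n", x$patient_id,
              nrow(x$thresholds)))
  print.data.frame(x$thresholds, ...)
  invisible(x)
}

#' Audiometric conversion tables
#'
#' The two additive per-frequency conversions of the clinical chain:
#' `hl_to_spl_ff` converts a bone-conduction threshold from dB HL to the
#' free-field dB SPL of an equally loud tone, and `met_to_dbv` converts a
#' direct threshold from the fitting software's dB MET scale to dB re 1 V
#' electrical input.  Both are knot-only lookups: every audiometric
#' frequency used must be present.  The shipped defaults are PLACEHOLDER
#' values for simulation; replace them with your calibrated tables for real
#' data.
#'
#' @param hl_to_spl_ff,met_to_dbv [transform_table()]s of additive offsets.
#' @return An object of class `conversion_tables`.
#' @export
conversion_tables <- function(hl_to_spl_ff = hl_to_spl_ff_placeholder(),
                              met_to_dbv = met_to_dbv_placeholder()) {
  stopifnot(inherits(hl_to_spl_ff, "transform_table"),
            inherits(met_to_dbv, "transform_table"))
  structure(list(hl_to_spl_ff = hl_to_spl_ff, met_to_dbv = met_to_dbv),
            class = "conversion_tables")
}

#' @rdname conversion_tables
#' @export
hl_to_spl_ff_placeholder <- function() {
  ## plausible free-field reference-threshold offsets; placeholders only
  transform_table(audiometric_frequencies(),
                  c(11, 4, 2, 2.5, -1.5, -6, -5.5, 4.5),
                  name = "hl_to_spl_ff_placeholder")
}

#' @rdname conversion_tables
#' @export
met_to_dbv_placeholder <- function() {
  ## flat placeholder offset from the fitting software's dB MET scale to dB V
  transform_table(audiometric_frequencies(), rep(-110, 8),
                  name = "met_to_dbv_placeholder")
}

#' Convert a bone-conduction threshold to free-field SPL
#'
#' `b' = b + offset(f)` with the frequency-specific additive offset from the
#' dB HL to dB SPL_FF conversion table.
#'
#' @param b Threshold(s) in dB HL.
#' @param f Audiometric frequency in Hz (must be a table knot).
#' @param tables A [conversion_tables()].
#' @return Threshold in dB SPL_FF.
#' @export
bc_to_spl_ff <- function(b, f, tables) {
  stopifnot(inherits(tables, "conversion_tables"))
  b + tt_lookup(tables$hl_to_spl_ff, f, knot_only = TRUE)
}

#' Convert a direct threshold to dB V
#'
#' `a' = a + offset_met(f)` with the frequency-specific additive offset from
#' the dB MET to dB V conversion table.
#'
#' @param a Threshold(s) in dB MET.
#' @inheritParams bc_to_spl_ff
#' @return Threshold in dB re 1 V rms.
#' @export
met_to_dbv <- function(a, f, tables) {
  stopifnot(inherits(tables, "conversion_tables"))
  a + tt_lookup(tables$met_to_dbv, f, knot_only = TRUE)
}

#' Actuator output from paired clinical thresholds
#'
#' Under the assumption that loudness at the bone-conduction threshold and
#' at the direct threshold is the same, the actuator output at 1 V rms input
#' is the difference `L_E = b' - a'` between the converted thresholds.
#'
#' @param b_prime Bone-conduction threshold in dB SPL_FF.
#' @param a_prime Direct threshold in dB V.
#' @return Equivalent free-field output level in eq. dB SPL_FF at 1 V rms.
#' @export
clinical_output <- function(b_prime, a_prime) {
  b_prime - a_prime
}

#' Bone-conduction fallback from the air-conduction threshold
#'
#' When the bone-conduction threshold at `f` was not measurable, the
#' air-conduction threshold stands in for it provided the preoperative
#' air-bone gap gives no indication of a conductive component
#' (ABG <= 10 dB, inclusive).  When the BC threshold is present it is
#' returned unchanged and the fallback is not consulted.
#'
#' @param record A [clinical_record()].
#' @param f Audiometric frequency in Hz.
#' @return A list with `b` (dB HL, or `NA` if unavailable) and `fallback`
#'   (logical, whether the AC threshold was substituted).
#' @export
bc_fallback <- function(record, f) {
  stopifnot(inherits(record, "clinical_record"))
  th <- record$thresholds
  i <- match(f, th$frequency_hz)
  if (is.na(i)) return(list(b = NA_real_, fallback = FALSE))
  if (!is.na(th$bc_db_hl[i]))
    return(list(b = th$bc_db_hl[i], fallback = FALSE))
  if (!is.na(th$ac_db_hl[i]) && !is.na(th$preop_abg_db[i]) &&
      th$preop_abg_db[i] <= 10)
    return(list(b = th$ac_db_hl[i], fallback = TRUE))
  list(b = NA_real_, fallback = FALSE)
}

#' Per-patient equivalent output series from clinical thresholds
#'
#' Applies the threshold conversions and the output formula at every
#' audiometric frequency of the record, with the bone-conduction fallback
#' rule.  Frequencies where either converted threshold is unavailable are
#' masked with reason `"missing"` (producing the varying per-frequency N of
#' a clinical cohort); fallback use is recorded in the returned series'
#' `fallback` attribute.
#'
#' @param record A [clinical_record()].
#' @param tables A [conversion_tables()].
#' @return An [eqspl_series()] with `reference = "clinical"` and the patient
#'   id in the `bone_id` slot.
#' @export
clinical_output_series <- function(record, tables) {
  stopifnot(inherits(record, "clinical_record"))
  th <- record$thresholds
  n <- nrow(th)
  level <- rep(NA_real_, n)
  fallback <- logical(n)
  for (i in seq_len(n)) {
    f <- th$frequency_hz[i]
    bb <- bc_fallback(record, f)
    fallback[i] <- bb$fallback
    a <- th$direct_db_met[i]
    if (is.na(bb$b) || is.na(a)) next
    level[i] <- clinical_output(bc_to_spl_ff(bb$b, f, tables),
                                met_to_dbv(a, f, tables))
  }
  excluded <- is.na(level)
  out <- eqspl_series(frequency_hz = th$frequency_hz, level_db = level,
                      excluded = excluded,
                      reason = ifelse(excluded, "missing", ""),
                      reference = "clinical",
                      bone_id = record$patient_id)
  attr(out, "fallback") <- fallback
  out
}
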