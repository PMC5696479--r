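#' Synthetic ear model
#'
#' A minimal linear model of a cadaveric ear used to synthesize measurement
#' records with known ground truth.  `h_me` is the middle-ear transfer
#' function (complex stapes displacement per Pa of ear-canal pressure),
#' `z_c` the cochlear map (complex intracochlear pressure difference per
#' metre of piston-like stapes displacement).  The stapes is piston-like by
#' default; `rocking_fraction > 0` adds a non-piston contamination term to
#' the *measured* stapes velocity of the actuator run only (rocking motion
#' picked up by a single-point laser beam but producing no net perilymph
#' volume displacement), with magnitude growing as `(f / f_rock)^2` above
#' the corner frequency `f_rock`.
#'
#' @param h_me Function of frequency (Hz) returning complex m/Pa.
#' @param z_c Function of frequency (Hz) returning complex Pa/m.
#' @param rocking_fraction Dimensionless contamination amplitude (>= 0) at
#'   the corner frequency.
#' @param f_rock Corner frequency of the contamination in Hz.
#' @param common_mode Common-mode fraction of the scala pressures: both
#'   scalae receive `common_mode * dP` (rotated) on top of `+/- dP/2`, so
#'   the vector difference is exercised nontrivially.
#' @param noise_floor Per-bin RMS noise amplitude, as a fraction of the
#'   channel's median tone amplitude (0 = noiseless).
#' @return An object of class `ear_model`.
#' @export
ear_model <- function(h_me = function(f) 3e-8 / (1 + 1i * f / 1500),
                      z_c = function(f) 3e8 * (1 + 1i * f / 2000),
                      rocking_fraction = 0, f_rock = 2000,
                      common_mode = 0.5, noise_floor = 0.02) {
  stopifnot(is.function(h_me), is.function(z_c))
  if (rocking_fraction < 0) stop("`rocking_fraction` must be >= 0",
                                 call. = FALSE)
  if (noise_floor < 0) stop("`noise_floor` must be >= 0", call. = FALSE)
  structure(list(h_me = h_me, z_c = z_c,
                 rocking_fraction = rocking_fraction, f_rock = f_rock,
                 common_mode = common_mode, noise_floor = noise_floor),
            class = "ear_model")
}

#' Synthetic actuator model
#'
#' Ground-truth actuator output for the synthetic generators: the
#' equivalent free-field SPL the actuator produces at 1 V rms, per
#' frequency, plus the drive level used in simulated runs (about -8 dB re
#' 1 V rms).  The default truth is a smooth curve peaking near 113 eq. dB
#' SPL_FF around 1.25 kHz, in the range reported for incus-driven
#' transducers.
#'
#' @param true_output_ff Either a single level (flat truth) or a function
#'   of frequency returning eq. dB SPL_FF at 1 V rms.
#' @param drive_db_re_1v Simulated drive level in dB re 1 V rms.
#' @return An object of class `actuator_model`.
#' @export
actuator_model <- function(true_output_ff = function(f)
                             103 + 10 * exp(-0.5 * (log2(f / 1250) / 1.2)^2),
                           drive_db_re_1v = -8) {
  if (is.numeric(true_output_ff)) {
    lvl <- true_output_ff
    if (length(lvl) != 1L || !is.finite(lvl))
      stop("numeric `true_output_ff` must be a single finite level",
           call. = FALSE)
    true_output_ff <- function(f) rep(lvl, length(f))
  }
  stopifnot(is.function(true_output_ff))
  structure(list(true_output_ff = true_output_ff,
                 drive_db_re_1v = drive_db_re_1v),
            class = "actuator_model")
}

#' Ground-truth output of an actuator model
#'
#' @param act An [actuator_model()].
#' @param f Frequencies in Hz.
#' @return Numeric eq. dB SPL_FF at 1 V rms.
#' @export
true_output <- function(act, f) {
  stopifnot(inherits(act, "actuator_model"))
  out <- act$true_output_ff(f)
  if (length(out) != length(f) || any(!is.finite(out)))
    stop("`true_output_ff` must return one finite level per frequency",
         call. = FALSE)
  out
}

## complex per-bin measurement noise, circularly symmetric, RMS `rms`
cnoise <- function(n, rms) {
  if (rms <= 0) return(complex(real = numeric(n), imaginary = numeric(n)))
  complex(real = stats::rnorm(n, 0, rms / sqrt(2)),
          imaginary = stats::rnorm(n, 0, rms / sqrt(2)))
}

## measure tone signals one stimulation at a time (tones are presented
## sequentially, so each tone gets its own averaged spectrum): place the
## signal on the grid, add per-bin noise, and read it back through the
## adjacent-bin SNR estimator; returns response and snr vectors
measure_channel <- function(signals, bins, grid, unit, noise_floor,
                            n_averages) {
  rms <- noise_floor * stats::median(Mod(signals))
  resp <- complex(length(bins))
  snr <- numeric(length(bins))
  zero <- complex(real = numeric(grid$n_bins),
                  imaginary = numeric(grid$n_bins))
  for (k in seq_along(bins)) {
    values <- zero + cnoise(grid$n_bins, rms)
    values[bins[k]] <- values[bins[k]] + signals[k]
    spec <- complex_spectrum(values, grid, unit, n_averages = n_averages)
    resp[k] <- spec$values[bins[k]]
    snr[k] <- snr_estimate(spec, bins[k])
  }
  list(response = resp, snr_db = snr)
}

#' Generate one synthetic temporal-bone record
#'
#' Synthesizes the paired acoustic and actuator runs of one temporal bone
#' by inverting the analysis chain, so that running [tb_output_series()] on
#' the noiseless, piston-only record returns exactly the actuator model's
#' configured true output for both references.  The simulation reproduces
#' the acquisition conditions: acoustic stimulation at `p_t_level_db`
#' dB SPL at the tympanic membrane, actuator drive near -8 dB re 1 V rms,
#' sequential sub-measurements whose inputs differ by up to 0.07 dB and
#' 0.54 degrees and are then renormalized to a common input, single-point
#' vibrometry at `angle_deg` (cosine-corrected by the analysis), additive
#' measurement noise on the response channels, and per-tone adjacent-bin
#' SNR bookkeeping.
#'
#' @param ear An [ear_model()].
#' @param act An [actuator_model()].
#' @param sequence A [stimulus_sequence()].
#' @param grid A [frequency_grid()].
#' @param td_table [transform_table()] used to invert the free-field
#'   conversion (use the same table for analysis to recover the truth).
#' @param position_label,contact_force_mn Coupling position metadata.
#' @param angle_deg Laser beam angle (degrees; default 37.5, the middle of
#'   the 30-45 degree range typical of footplate access).
#' @param p_t_level_db Acoustic stimulation level, dB SPL at the TM.
#' @param n_averages Number of averages recorded per tone (default 30).
#' @param input_jitter Simulate the small input differences between
#'   sequential sub-measurements (renormalized away downstream).
#' @param seed Integer seed or `NULL`.
#' @param bone_id Identifier stored in the record.
#' @return A [tb_record()] carrying the per-tone ground truth as attribute
#'   `"truth"`.
#' @examples
#' rec <- generate_tb(ear_model(noise_floor = 0),
#'                    actuator_model(100), seed = 1)
#' s <- tb_output_series(rec, "stapes", td_placeholder())
#' all.equal(s$level_db, rep(100, 23))
#' @export
generate_tb <- function(ear = ear_model(), act = actuator_model(),
                        sequence = stimulus_sequence(),
                        grid = frequency_grid(),
                        td_table = td_placeholder(),
                        position_label = "4 mN", contact_force_mn = 4,
                        angle_deg = 37.5, p_t_level_db = 100,
                        n_averages = 30L, input_jitter = TRUE,
                        seed = NULL, bone_id = "TB01") {
  stopifnot(inherits(ear, "ear_model"), inherits(act, "actuator_model"))
  with_seed(seed, {
    f <- as.numeric(sequence)
    bins <- vapply(f, function(ff) bin_index(grid, ff), integer(1))
    cosf <- cospi(angle_deg / 180)

    p_t <- complex(real = PA_REF * db_amp(p_t_level_db), imaginary = 0)
    p_t <- rep(p_t, length(f))
    e <- rep(complex(real = db_amp(act$drive_db_re_1v), imaginary = 0),
             length(f))
    l_true <- true_output(act, f)
    td <- tt_lookup(td_table, f)
    ## eardrum-referenced transfer magnitude (Pa per V) the actuator must show
    target_t <- PA_REF * db_amp(l_true + td)

    jit <- function() {
      if (!input_jitter) return(rep(1 + 0i, length(f)))
      db_amp(stats::runif(length(f), -0.07, 0.07)) *
        exp(1i * stats::runif(length(f), -0.54, 0.54) * pi / 180)
    }

    d_u <- ear$h_me(f) * p_t
    dp_u <- ear$z_c(f) * d_u
    v_u <- 1i * 2 * pi * f * d_u
    d_a <- d_u / p_t * target_t * e
    dp_a <- dp_u / p_t * target_t * e
    rock <- ifelse(f > ear$f_rock,
                   ear$rocking_fraction * (f / ear$f_rock)^2, 0)
    v_a <- 1i * 2 * pi * f * d_a * (1 + rock)

    split_scalae <- function(dp) {
      cm <- ear$common_mode * dp * exp(0.5i)
      list(sv = cm + dp / 2, st = cm - dp / 2)
    }

    build_run <- function(input, v_true, dp, is_acoustic) {
      ## two sequential sub-measurements with slightly different inputs
      j_p <- jit(); j_v <- jit()
      in_p <- input * j_p              # pressure sub-run input
      in_v <- input * j_v              # vibrometry sub-run input
      sc <- split_scalae(dp / input * in_p)
      v_meas <- v_true / input * in_v * cosf
      ch_sv <- measure_channel(sc$sv, bins, grid, "Pa", ear$noise_floor,
                               n_averages)
      ch_st <- measure_channel(sc$st, bins, grid, "Pa", ear$noise_floor,
                               n_averages)
      ch_v <- measure_channel(v_meas, bins, grid, "m/s", ear$noise_floor,
                              n_averages)
      ren <- renormalize_to_common_input(
        data.frame(frequency = f, response = ch_sv$response,
                   input_ref = in_p),
        data.frame(frequency = f, response = ch_v$response,
                   input_ref = in_v))
      g <- ren$run_a$input_ref
      out <- data.frame(frequency = f,
                        v_stapes = ren$run_b$response,
                        p_sv = ren$run_a$response,
                        p_st = ch_st$response * g / in_p,
                        snr_stapes = ch_v$snr_db,
                        snr_sv = ch_sv$snr_db,
                        snr_st = ch_st$snr_db,
                        n_averages = as.integer(n_averages))
      if (is_acoustic) out$p_t <- g else out$e <- g
      out
    }

    acoustic <- build_run(p_t, v_u, dp_u, TRUE)
    actuator <- build_run(e, v_a, dp_a, FALSE)
    rec <- tb_record(bone_id, position_label, contact_force_mn, angle_deg,
                     acoustic, actuator)
    attr(rec, "truth") <- data.frame(frequency_hz = f,
                                     level_db = l_true)
    rec
  })
}

#' Build a synthetic acceptance corridor around an ear model
#'
#' A corridor of `+/- margin_db` around the model's middle-ear transfer
#' function (displacement per Pa, in dB), with knots at the stimulus tones.
#' Synthetic stand-in for a published corridor; clearly not calibrated
#' bounds.
#'
#' @param ear An [ear_model()].
#' @param margin_db Half-width of the corridor in dB (default 10).
#' @param sequence Tone frequencies used as knots.
#' @param check_band Band over which the gate applies, Hz.
#' @return An [acceptance_corridor()].
#' @export
synthetic_corridor <- function(ear = ear_model(), margin_db = 10,
                               sequence = stimulus_sequence(),
                               check_band = c(250, 4000)) {
  f <- as.numeric(sequence)
  tmpl <- amp_db(Mod(ear$h_me(f)))
  acceptance_corridor(
    transform_table(f, tmpl - margin_db, name = "synthetic_lower"),
    transform_table(f, tmpl + margin_db, name = "synthetic_upper"),
    check_band = check_band)
}

#' Generate a synthetic temporal-bone cohort
#'
#' Draws `n_bones` bones around a template ear model with log-normal (in
#' dB) inter-individual spread of the middle-ear transfer function, and
#' constructs exactly `n_pass_gate` of them inside the acceptance corridor
#' (the rest are pushed outside it).  Because the equivalent-SPL estimate
#' is a ratio, anatomical spread of the transfer function does not move the
#' recovered output levels: cohort medians stay at the actuator model's
#' configured truth up to measurement noise.
#'
#' @param n_bones Number of bones (default 14).
#' @param n_pass_gate Number of bones built inside the corridor (default
#'   10).
#' @param inter_bone_sd_db Inter-individual spread of the transfer function
#'   in dB (default 5).
#' @param corridor An [acceptance_corridor()]; default a
#'   [synthetic_corridor()] of `+/-10` dB around the template.
#' @param ear Template [ear_model()].
#' @param act An [actuator_model()].
#' @param sequence,grid,td_table,position_label,angle_deg,... Passed to
#'   [generate_tb()].
#' @param seed Integer seed; all bones flow from this single seed.
#' @return List of [tb_record()]s; the corridor used is attached as
#'   attribute `"corridor"` and the pass design as `"expected_pass"`.
#' @export
generate_tb_cohort <- function(n_bones = 14L, n_pass_gate = 10L,
                               inter_bone_sd_db = 5,
                               corridor = NULL, ear = ear_model(),
                               act = actuator_model(),
                               sequence = stimulus_sequence(),
                               grid = frequency_grid(),
                               td_table = td_placeholder(),
                               position_label = "4 mN", angle_deg = 37.5,
                               seed = NULL, ...) {
  if (n_pass_gate > n_bones)
    stop("`n_pass_gate` cannot exceed `n_bones`", call. = FALSE)
  if (is.null(corridor))
    corridor <- synthetic_corridor(ear, sequence = sequence)
  f_seq <- as.numeric(sequence)
  band <- corridor$check_band
  f_band <- f_seq[f_seq >= band[1] & f_seq <= band[2]]
  tmpl_db <- amp_db(Mod(ear$h_me(f_band)))
  rel_lo <- tt_lookup(corridor$lower, f_band) - tmpl_db
  rel_up <- tt_lookup(corridor$upper, f_band) - tmpl_db
  clamp_margin <- 1  # keep pass bones clear of the bounds despite noise
  if (any(rel_lo > 0) || any(rel_up < 0))
    stop("template ear lies outside the corridor", call. = FALSE)
  if (any(rel_lo + clamp_margin > rel_up - clamp_margin))
    stop("corridor too narrow for the template ear", call. = FALSE)

  ctrl_f <- exp(seq(log(100), log(10000), length.out = 6))
  with_seed(seed, {
    records <- vector("list", n_bones)
    for (b in seq_len(n_bones)) {
      o_ctrl <- stats::rnorm(length(ctrl_f), 0, inter_bone_sd_db)
      o_fun <- stats::approxfun(log(ctrl_f), o_ctrl, rule = 2)
      o_band <- o_fun(log(f_band))
      if (b <= n_pass_gate) {
        adj <- pmin(pmax(o_band, rel_lo + clamp_margin),
                    rel_up - clamp_margin) - o_band
      } else {
        j <- which.max(o_band - rel_up)
        adj_shift <- rel_up[j] - o_band[j] + 4  # 4 dB clear violation
        adj <- rep(adj_shift, length(f_band))
      }
      ## smooth per-frequency correction applied on top of the raw curve
      adj_fun <- stats::approxfun(log(f_band), adj, rule = 2)
      h_template <- ear$h_me
      offset_fun <- function(f) o_fun(log(f)) + adj_fun(log(f))
      ear_b <- ear_model(
        h_me = local({
          off <- offset_fun; h0 <- h_template
          function(f) h0(f) * db_amp(off(f))
        }),
        z_c = ear$z_c, rocking_fraction = ear$rocking_fraction,
        f_rock = ear$f_rock, common_mode = ear$common_mode,
        noise_floor = ear$noise_floor)
      records[[b]] <- generate_tb(
        ear_b, act, sequence, grid, td_table,
        position_label = position_label, angle_deg = angle_deg,
        seed = NULL, bone_id = sprintf("TB%02d", b), ...)
    }
    attr(records, "corridor") <- corridor
    attr(records, "expected_pass") <- sprintf("TB%02d",
                                              seq_len(n_pass_gate))
    records
  })
}

#' Generate a synthetic clinical cohort
#'
#' Draws per-patient bone-conduction thresholds, inverts the clinical
#' output formula and the conversion tables to produce consistent
#' (BC, direct) threshold pairs for the actuator model's configured truth,
#' quantizes both thresholds to the audiometric step (default 5 dB), and
#' applies a per-frequency missingness pattern (default mirroring a cohort
#' in which e.g. only 5 of 24 recipients contribute 0.25 kHz data).  With
#' `threshold_step_db = 0` and no missingness, [clinical_output_series()]
#' recovers the truth exactly for every patient; with a 5 dB step the
#' per-patient error is bounded by one step and unbiased over the cohort.
#'
#' @param n_patients Number of recipients (default 24).
#' @param act An [actuator_model()].
#' @param tables A [conversion_tables()].
#' @param threshold_step_db Audiometric quantization step in dB (default 5;
#'   0 disables quantization).
#' @param missing_pattern Named integer vector: number of patients with
#'   data per audiometric frequency.  Default scales the pattern
#'   `c(250 Hz: 5, 500: 20, 1000: 23, 1500: 24, 2000: 24, 3000: 16,
#'   4000: 22, 6000: 20)` of a 24-patient cohort.
#' @param bc_mean_db_hl,bc_sd_db Population mean / SD of the underlying
#'   bone-conduction thresholds in dB HL (defaults 50 and 10, a typical
#'   implant-candidate population).
#' @param n_fallback Number of patient-frequency slots converted into
#'   BC-fallback cases (BC threshold removed, AC threshold provided with an
#'   air-bone gap <= 10 dB), exercising the fallback rule (default 1).
#' @param seed Integer seed.
#' @return List of [clinical_record()]s with the truth attached as
#'   attribute `"truth"`.
#' @export
generate_clinical_cohort <- function(n_patients = 24L,
                                     act = actuator_model(),
                                     tables = conversion_tables(),
                                     threshold_step_db = 5,
                                     missing_pattern = NULL,
                                     bc_mean_db_hl = 50, bc_sd_db = 10,
                                     n_fallback = 1L, seed = NULL) {
  freqs <- audiometric_frequencies()
  off_hl <- tt_lookup(tables$hl_to_spl_ff, freqs, knot_only = TRUE)
  off_met <- tt_lookup(tables$met_to_dbv, freqs, knot_only = TRUE)
  l_true <- true_output(act, freqs)
  if (is.null(missing_pattern)) {
    base <- c(`250` = 5, `500` = 20, `1000` = 23, `1500` = 24,
              `2000` = 24, `3000` = 16, `4000` = 22, `6000` = 20)
    missing_pattern <- round(base * n_patients / 24)
    missing_pattern <- pmin(pmax(missing_pattern, 1), n_patients)
  }
  if (!all(as.character(freqs) %in% names(missing_pattern)))
    stop("`missing_pattern` must name every audiometric frequency",
         call. = FALSE)

  with_seed(seed, {
    have <- sapply(as.character(freqs), function(fc) {
      idx <- logical(n_patients)
      idx[sample.int(n_patients, missing_pattern[[fc]])] <- TRUE
      idx
    })  # n_patients x n_freqs
    recs <- vector("list", n_patients)
    for (p in seq_len(n_patients)) {
      b_cont <- stats::rnorm(length(freqs), bc_mean_db_hl, bc_sd_db)
      qb <- quantize(b_cont, threshold_step_db)
      a_cont <- (b_cont + off_hl) - l_true - off_met
      qa <- quantize(a_cont, threshold_step_db)
      th <- data.frame(frequency_hz = freqs,
                       bc_db_hl = ifelse(have[p, ], qb, NA_real_),
                       direct_db_met = ifelse(have[p, ], qa, NA_real_),
                       ac_db_hl = NA_real_, preop_abg_db = NA_real_)
      recs[[p]] <- clinical_record(sprintf("P%02d", p), th)
    }
    ## convert a few measured slots into BC-fallback cases
    slots <- which(have, arr.ind = TRUE)
    if (n_fallback > 0 && nrow(slots) > 0) {
      take <- slots[sample.int(nrow(slots), min(n_fallback, nrow(slots))),
                    , drop = FALSE]
      for (k in seq_len(nrow(take))) {
        p <- take[k, 1]; j <- take[k, 2]
        th <- recs[[p]]$thresholds
        th$ac_db_hl[j] <- th$bc_db_hl[j]    # ABG of 0: AC equals BC
        th$preop_abg_db[j] <- 0
        th$bc_db_hl[j] <- NA_real_
        recs[[p]] <- clinical_record(recs[[p]]$patient_id, th)
      }
    }
    attr(recs, "truth") <- data.frame(frequency_hz = freqs,
                                      level_db = l_true)
    recs
  })
}
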