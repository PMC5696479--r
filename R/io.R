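#' Write and read temporal-bone measurement records
#'
#' Measurement tables are exchanged as plain CSV with one row per
#' (stimulus type, channel, frequency): columns `bone_id`,
#' `position_label`, `stimulus_type` (`acoustic`/`actuator`), `channel`
#' (`stapes`/`p_sv`/`p_st`), `frequency_hz`, `response_re`, `response_im`,
#' `response_unit`, `input_re`, `input_im`, `input_unit`, `snr_db`,
#' `n_averages`, `angle_deg`, `contact_force_mn`.
#'
#' @param record A [tb_record()].
#' @param path CSV file path.
#' @return `write_tb_record()` returns `path` invisibly; `read_tb_record()`
#'   returns a [tb_record()].
#' @export
write_tb_record <- function(record, path) {
  stopifnot(inherits(record, "tb_record"))
  one_run <- function(run, stim, input_col, input_unit) {
    rows <- lapply(c(stapes = "v_stapes", p_sv = "p_sv", p_st = "p_st"),
                   function(col) {
      snr_col <- c(v_stapes = "snr_stapes", p_sv = "snr_sv",
                   p_st = "snr_st")[[col]]
      data.frame(
        bone_id = record$bone_id,
        position_label = record$position_label,
        stimulus_type = stim,
        channel = names(which(c(stapes = "v_stapes", p_sv = "p_sv",
                                p_st = "p_st") == col)),
        frequency_hz = run$frequency,
        response_re = Re(run[[col]]),
        response_im = Im(run[[col]]),
        response_unit = if (col == "v_stapes") "m/s" else "Pa",
        input_re = Re(run[[input_col]]),
        input_im = Im(run[[input_col]]),
        input_unit = input_unit,
        snr_db = run[[snr_col]],
        n_averages = run$n_averages,
        angle_deg = record$angle_deg,
        contact_force_mn = record$contact_force_mn,
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  out <- rbind(one_run(record$acoustic, "acoustic", "p_t", "Pa"),
               one_run(record$actuator, "actuator", "e", "V"))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tb_record
#' @export
read_tb_record <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bone_id", "position_label", "stimulus_type", "channel",
            "frequency_hz", "response_re", "response_im", "input_re",
            "input_im", "snr_db", "n_averages", "angle_deg",
            "contact_force_mn")
  if (!all(need %in% names(d)))
    stop("measurement CSV missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  one_run <- function(stim) {
    s <- d[d$stimulus_type == stim, ]
    wide <- NULL
    for (ch in c("stapes", "p_sv", "p_st")) {
      c_ <- s[s$channel == ch, ]
      c_ <- c_[order(c_$frequency_hz), ]
      col <- c(stapes = "v_stapes", p_sv = "p_sv", p_st = "p_st")[[ch]]
      snr_col <- c(stapes = "snr_stapes", p_sv = "snr_sv",
                   p_st = "snr_st")[[ch]]
      if (is.null(wide)) {
        wide <- data.frame(frequency = c_$frequency_hz)
        wide$input <- complex(real = c_$input_re, imaginary = c_$input_im)
        wide$n_averages <- c_$n_averages
      }
      wide[[col]] <- complex(real = c_$response_re,
                             imaginary = c_$response_im)
      wide[[snr_col]] <- c_$snr_db
    }
    wide
  }
  ac <- one_run("acoustic"); ac$p_t <- ac$input; ac$input <- NULL
  act <- one_run("actuator"); act$e <- act$input; act$input <- NULL
  tb_record(d$bone_id[1], d$position_label[1], d$contact_force_mn[1],
            d$angle_deg[1], ac, act)
}

#' Write and read equivalent-SPL series
#'
#' Series CSV layout: `bone_id`, `position_label`, `reference`,
#' `frequency_hz`, `level_eq_db_spl_ff`, `excluded`, `reason`.
#'
#' @param series An [eqspl_series()].
#' @param path CSV file path.
#' @return `write_eqspl_series()` returns `path` invisibly;
#'   `read_eqspl_series()` returns an [eqspl_series()].
#' @export
write_eqspl_series <- function(series, path) {
  stopifnot(inherits(series, "eqspl_series"))
  out <- data.frame(bone_id = attr(series, "bone_id"),
                    position_label = attr(series, "position_label"),
                    reference = attr(series, "reference"),
                    frequency_hz = series$frequency_hz,
                    level_eq_db_spl_ff = series$level_db,
                    excluded = series$excluded,
                    reason = series$reason,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eqspl_series
#' @export
read_eqspl_series <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$reason[is.na(d$reason)] <- ""
  eqspl_series(frequency_hz = d$frequency_hz,
               level_db = d$level_eq_db_spl_ff,
               excluded = d$excluded, reason = d$reason,
               reference = d$reference[1],
               bone_id = d$bone_id[1],
               position_label = d$position_label[1])
}

#' Write and read transformation tables
#'
#' Two-column CSV (`frequency_hz`, `value_db`) with a JSON sidecar
#' (`<path>.json`) recording the table name and interpolation policy.
#'
#' @param table A [transform_table()].
#' @param path CSV file path.
#' @return `write_transform_table()` returns `path` invisibly;
#'   `read_transform_table()` returns a [transform_table()].
#' @export
write_transform_table <- function(table, path) {
  stopifnot(inherits(table, "transform_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  jsonlite::write_json(list(name = attr(table, "name"),
                            interpolation = attr(table, "interpolation")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform_table
#' @export
read_transform_table <- function(path) {
  d <- utils::read.csv(path)
  meta <- list(name = basename(path), interpolation = "linear_hz")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar)
  transform_table(d$frequency_hz, d$value_db, name = meta$name,
                  interpolation = meta$interpolation)
}

#' Write and read clinical threshold records
#'
#' Clinical CSV layout: `patient_id`, `frequency_hz`, `bc_db_hl`,
#' `ac_db_hl`, `preop_abg_db`, `direct_db_met`; one file may hold a whole
#' cohort.
#'
#' @param records List of [clinical_record()]s.
#' @param path CSV file path.
#' @return `write_clinical_records()` returns `path` invisibly;
#'   `read_clinical_records()` returns a list of [clinical_record()]s.
#' @export
write_clinical_records <- function(records, path) {
  rows <- lapply(records, function(r) {
    th <- r$thresholds
    data.frame(patient_id = r$patient_id, frequency_hz = th$frequency_hz,
               bc_db_hl = th$bc_db_hl, ac_db_hl = th$ac_db_hl,
               preop_abg_db = th$preop_abg_db,
               direct_db_met = th$direct_db_met, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clinical_records
#' @export
read_clinical_records <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(d, d$patient_id), function(s) {
    s <- s[order(s$frequency_hz), ]
    clinical_record(s$patient_id[1],
                    data.frame(frequency_hz = s$frequency_hz,
                               bc_db_hl = s$bc_db_hl,
                               direct_db_met = s$direct_db_met,
                               ac_db_hl = s$ac_db_hl,
                               preop_abg_db = s$preop_abg_db))
  })
}
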