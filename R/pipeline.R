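#' Simulate a complete synthetic study
#'
#' Orchestration entry point: generates a temporal-bone cohort (with a
#' known number of bones inside the acceptance corridor) and a clinical
#' cohort from the same actuator truth, optionally writing all inputs to
#' `out_dir` in the package's CSV dialects.  Rerunning with the same seed
#' reproduces the files bit for bit.
#'
#' @param out_dir Directory for the CSV files, or `NULL` to skip writing.
#' @param seed Integer seed driving all randomness.
#' @param n_bones,n_pass_gate,n_patients Cohort sizes (defaults 14 bones,
#'   10 inside the corridor, 24 recipients).
#' @param ear,act,tables,td_table Model and table configuration.
#' @param ... Passed to [generate_tb_cohort()].
#' @return A list with `records`, `clinical`, `corridor`, `td_table`,
#'   `tables`, `truth` and `seed`.
#' @export
amei_simulate <- function(out_dir = NULL, seed = 1L, n_bones = 14L,
                          n_pass_gate = 10L, n_patients = 24L,
                          ear = ear_model(), act = actuator_model(),
                          tables = conversion_tables(),
                          td_table = td_placeholder(), ...) {
  records <- generate_tb_cohort(n_bones = n_bones,
                                n_pass_gate = n_pass_gate, ear = ear,
                                act = act, td_table = td_table,
                                seed = seed, ...)
  clinical <- generate_clinical_cohort(n_patients = n_patients, act = act,
                                       tables = tables, seed = seed + 1L)
  out <- list(records = records, clinical = clinical,
              corridor = attr(records, "corridor"), td_table = td_table,
              tables = tables, truth = attr(records[[1]], "truth"),
              seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (r in records)
      write_tb_record(r, file.path(out_dir,
                                   sprintf("tb_%s.csv", r$bone_id)))
    write_clinical_records(clinical, file.path(out_dir, "clinical.csv"))
    write_transform_table(td_table, file.path(out_dir, "td_table.csv"))
    write_transform_table(out$corridor$lower,
                          file.path(out_dir, "corridor_lower.csv"))
    write_transform_table(out$corridor$upper,
                          file.path(out_dir, "corridor_upper.csv"))
    writeLines(jsonlite::toJSON(list(seed = seed, n_bones = n_bones,
                                     n_pass_gate = n_pass_gate,
                                     n_patients = n_patients),
                                auto_unbox = TRUE),
               file.path(out_dir, "provenance.json"))
  }
  out
}

#' Gate and analyze a cohort of temporal-bone records
#'
#' Applies the acceptance gate, then computes per-bone equivalent
#' free-field output series for the requested reference(s) on the bones
#' that pass, plus cohort summaries.  Optionally writes the gate report,
#' series and summaries as CSV.
#'
#' @param records List of [tb_record()]s.
#' @param corridor An [acceptance_corridor()].
#' @param td_table [transform_table()] of ear-canal-to-free-field values.
#' @param references Character vector among `"stapes"`, `"icpd"`.
#' @param snr_threshold Minimum SNR in dB (default 12).
#' @param e_max Normalization voltage (default 1 V rms).
#' @param out_dir Directory for CSV output, or `NULL`.
#' @return A list with `gate` (data frame), `series` (list per reference of
#'   lists of [eqspl_series()]) and `summaries` (data frame).
#' @export
amei_analyze <- function(records, corridor, td_table,
                         references = c("stapes", "icpd"),
                         snr_threshold = 12, e_max = 1, out_dir = NULL) {
  references <- match.arg(references, c("stapes", "icpd"),
                          several.ok = TRUE)
  gate <- gate_cohort(records, corridor, snr_threshold = snr_threshold)
  passed <- records[gate$pass]
  series <- lapply(references, function(ref)
    lapply(passed, tb_output_series, reference = ref,
           td_table = td_table, snr_threshold = snr_threshold,
           e_max = e_max))
  names(series) <- references
  summaries <- do.call(rbind, lapply(references, function(ref)
    summarize_cohort(series[[ref]], group = ref)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(gate, file.path(out_dir, "gate_report.csv"),
                     row.names = FALSE)
    for (ref in references)
      for (s in series[[ref]])
        write_eqspl_series(s, file.path(
          out_dir, sprintf("series_%s_%s.csv", ref, attr(s, "bone_id"))))
    utils::write.csv(summaries, file.path(out_dir, "summaries.csv"),
                     row.names = FALSE)
  }
  list(gate = gate, series = series, summaries = summaries)
}

#' Compare references and cohorts
#'
#' Runs the study's statistical comparisons: a paired per-frequency
#' Wilcoxon signed-rank test between the stapes- and ICPD-referenced
#' outputs of the same bones, and unpaired Mann-Whitney tests of each
#' temporal-bone reference against the clinical outputs at the audiometric
#' frequencies (temporal-bone levels at 1.5 kHz are interpolated between
#' the bracketing tones first).
#'
#' @param series Named list as returned in `amei_analyze()$series`,
#'   containing `stapes` and/or `icpd` series lists.
#' @param clinical_series List of clinical [eqspl_series()] (from
#'   [clinical_output_series()]).
#' @param out_dir Directory for the CSV report, or `NULL`.
#' @param alpha Significance threshold (default 0.05, two-sided, per
#'   frequency, uncorrected).
#' @return A data frame of class `comparison_report` with columns
#'   `comparison`, `frequency_hz`, `test`, `n`, `p_value`, `significant`.
#' @export
amei_compare <- function(series, clinical_series, out_dir = NULL,
                         alpha = 0.05) {
  rows <- list()
  if (all(c("stapes", "icpd") %in% names(series))) {
    a <- cohort_values(series$stapes)
    b <- cohort_values(series$icpd)
    pc <- paired_compare(a, b, alpha = alpha)
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = "stapes_vs_icpd", frequency_hz = pc$frequency_hz,
      test = "wilcoxon_signed_rank", n = pc$n, p_value = pc$p_value,
      significant = pc$significant, stringsAsFactors = FALSE)
  }
  if (length(clinical_series)) {
    clin <- cohort_values(clinical_series,
                          frequencies = audiometric_frequencies())
    for (ref in names(series)) {
      tb_aud <- t(vapply(series[[ref]], audiometric_levels,
                         numeric(length(audiometric_frequencies()))))
      colnames(tb_aud) <- as.character(audiometric_frequencies())
      uc <- unpaired_compare(tb_aud, clin, alpha = alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = sprintf("%s_vs_clinical", ref),
        frequency_hz = uc$frequency_hz, test = "mann_whitney",
        n = uc$n_a + uc$n_b, p_value = uc$p_value,
        significant = uc$significant, stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  class(report) <- c("comparison_report", "data.frame")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
  }
  report
}
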