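tabs <- conversion_tables(
  hl_to_spl_ff = transform_table(audiometric_frequencies(),
                                 c(11, 4, 2, 2.5, -1.5, -6, -5.5, 4.5),
                                 name = "hl"),
  met_to_dbv = transform_table(audiometric_frequencies(), rep(-100, 8),
                               name = "met"))

test_that("threshold conversions are additive per-frequency offsets", {
  null_tabs <- conversion_tables(
    transform_table(audiometric_frequencies(), rep(0, 8), name = "hl0"),
    transform_table(audiometric_frequencies(), rep(0, 8), name = "met0"))
  expect_equal(bc_to_spl_ff(40, 1000, null_tabs), 40)
  expect_equal(bc_to_spl_ff(40, 250, tabs), 51)
  expect_equal(met_to_dbv(20, 500, tabs), -80)
  expect_equal(met_to_dbv(20, 500, null_tabs), 20)
  expect_error(bc_to_spl_ff(40, 750, tabs), "not in table")
})

test_that("clinical output is the converted-threshold difference", {
  expect_equal(clinical_output(45, -60), 105)
  expect_equal(clinical_output(77, 77), 0)
  # adding c to b shifts L_E by +c; adding c to a shifts by -c
  b <- 50; a <- 30; f <- 2000
  l0 <- clinical_output(bc_to_spl_ff(b, f, tabs), met_to_dbv(a, f, tabs))
  expect_equal(clinical_output(bc_to_spl_ff(b + 7, f, tabs),
                               met_to_dbv(a, f, tabs)), l0 + 7)
  expect_equal(clinical_output(bc_to_spl_ff(b, f, tabs),
                               met_to_dbv(a + 7, f, tabs)), l0 - 7)
})

test_that("the BC fallback substitutes AC only when the air-bone gap allows", {
  rec <- clinical_record("P1", data.frame(
    frequency_hz = c(500, 1000, 2000),
    bc_db_hl = c(NA, NA, 35),
    direct_db_met = c(25, 25, 25),
    ac_db_hl = c(70, 60, 40),
    preop_abg_db = c(8, 15, 2)))
  expect_equal(bc_fallback(rec, 500), list(b = 70, fallback = TRUE))
  expect_equal(bc_fallback(rec, 1000), list(b = NA_real_, fallback = FALSE))
  # BC present: returned unchanged, fallback not consulted
  expect_equal(bc_fallback(rec, 2000), list(b = 35, fallback = FALSE))
  # boundary: ABG of exactly 10 dB still allows the fallback
  rec10 <- clinical_record("P2", data.frame(
    frequency_hz = c(500, 1000), bc_db_hl = c(NA, 30),
    direct_db_met = c(25, 25), ac_db_hl = c(55, NA),
    preop_abg_db = c(10, NA)))
  expect_equal(bc_fallback(rec10, 500)$b, 55)
})

test_that("per-patient series mask unavailable frequencies with reason codes", {
  rec <- clinical_record("P1", data.frame(
    frequency_hz = c(500, 1000, 2000),
    bc_db_hl = c(40, NA, 35),
    direct_db_met = c(25, 25, NA)))
  s <- clinical_output_series(rec, tabs)
  expect_equal(attr(s, "reference"), "clinical")
  expect_equal(s$excluded, c(FALSE, TRUE, TRUE))
  expect_equal(s$reason[2:3], c("missing", "missing"))
  expect_equal(s$level_db[1],
               clinical_output(bc_to_spl_ff(40, 500, tabs),
                               met_to_dbv(25, 500, tabs)))
  # the masked frequencies drop out of a cohort summary (varying N)
  sm <- summarize_cohort(list(s), "clinical")
  expect_equal(sm$frequency_hz, 500)
  expect_equal(sm$n, 1)
})

test_that("synthetic clinical cohort inverts the output formula", {
  act <- actuator_model(110)
  # no quantization, no missingness: exact recovery for every patient
  cl <- generate_clinical_cohort(
    n_patients = 6, act = act, tables = tabs, threshold_step_db = 0,
    missing_pattern = stats::setNames(rep(6L, 8),
                                      audiometric_frequencies()),
    n_fallback = 2, seed = 91)
  for (r in cl) {
    s <- clinical_output_series(r, tabs)
    expect_false(any(s$excluded))
    expect_equal(s$level_db, rep(110, 8), tolerance = 1e-12)
  }

  # 5 dB steps: per-patient error bounded by one step, none masked
  cl5 <- generate_clinical_cohort(
    n_patients = 6, act = act, tables = tabs, threshold_step_db = 5,
    missing_pattern = stats::setNames(rep(6L, 8),
                                      audiometric_frequencies()),
    seed = 92)
  err <- unlist(lapply(cl5, function(r)
    clinical_output_series(r, tabs)$level_db - 110))
  expect_lte(max(abs(err)), 5)

  # default missingness reproduces the per-frequency N pattern
  cl24 <- generate_clinical_cohort(n_patients = 24, act = act,
                                   tables = tabs, seed = 93)
  ser <- lapply(cl24, clinical_output_series, tables = tabs)
  sm <- summarize_cohort(ser, "clinical")
  expect_equal(sm$n[sm$frequency_hz == 250], 5)
  expect_equal(sm$n[sm$frequency_hz == 1500], 24)
})
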