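noiseless <- function(...) ear_model(noise_floor = 0, ...)

test_that("generated records are bit-identical under the same seed", {
  r1 <- generate_tb(seed = 123)
  r2 <- generate_tb(seed = 123)
  expect_identical(r1, r2)
  r3 <- generate_tb(seed = 124)
  expect_false(identical(r1$acoustic$v_stapes, r3$acoustic$v_stapes))

  c1 <- generate_clinical_cohort(n_patients = 5, seed = 9)
  c2 <- generate_clinical_cohort(n_patients = 5, seed = 9)
  expect_identical(c1, c2)
})

test_that("the noiseless piston-only chain returns the configured truth", {
  # the central oracle of the repository: generate -> analyze is identity
  rec <- generate_tb(noiseless(), actuator_model(100), seed = 1)
  for (ref in c("stapes", "icpd")) {
    s <- tb_output_series(rec, ref, td_placeholder())
    expect_false(any(s$excluded))
    expect_lt(max(abs(s$level_db - 100)), 1e-6)
  }
  # also with a frequency-dependent truth and the other coupling position
  act <- actuator_model()
  rec2 <- generate_tb(noiseless(), act, position_label = "4 mN + 60 um",
                      contact_force_mn = 40, seed = 2)
  tr <- attr(rec2, "truth")
  s2 <- tb_output_series(rec2, "icpd", td_placeholder())
  expect_lt(max(abs(s2$level_db - tr$level_db)), 1e-6)
})

test_that("rocking contamination inflates only the stapes path above the corner", {
  ear <- noiseless(rocking_fraction = 0.15, f_rock = 2000)
  rec <- generate_tb(ear, actuator_model(100), seed = 3)
  s_st <- tb_output_series(rec, "stapes", td_placeholder())
  s_ic <- tb_output_series(rec, "icpd", td_placeholder())
  below <- s_st$frequency_hz <= 2000
  expect_equal(s_st$level_db[below], s_ic$level_db[below],
               tolerance = 1e-9)
  expect_true(all(s_st$level_db[!below] > s_ic$level_db[!below]))
  # the ICPD path still recovers the truth
  expect_lt(max(abs(s_ic$level_db - 100)), 1e-6)

  # strict isolation: the pressure channels are untouched by rocking
  rec0 <- generate_tb(noiseless(), actuator_model(100), seed = 3)
  expect_identical(rec$actuator$p_sv, rec0$actuator$p_sv)
  expect_identical(rec$actuator$p_st, rec0$actuator$p_st)
  expect_identical(rec$acoustic, rec0$acoustic)
})

test_that("the noise floor drives SNR realistically and monotonically", {
  med_snr <- function(nf) {
    rec <- generate_tb(ear_model(noise_floor = nf), actuator_model(100),
                       seed = 44)
    median(c(rec$acoustic$snr_stapes, rec$acoustic$snr_sv,
             rec$acoustic$snr_st))
  }
  snrs <- vapply(c(0.002, 0.02, 0.2), med_snr, numeric(1))
  expect_true(all(diff(snrs) < 0))
  # default noise floor sits in the 20-60 dB band typical of 30 averages
  expect_gt(snrs[2], 20); expect_lt(snrs[2], 60)
})

test_that("cohort generation honours the gate design and recovers the truth", {
  coh <- generate_tb_cohort(n_bones = 14, n_pass_gate = 10, seed = 10)
  g <- gate_cohort(coh, attr(coh, "corridor"))
  expect_equal(sum(g$pass), 10)

  # zero inter-bone spread and no noise: records identical up to labels
  coh0 <- generate_tb_cohort(n_bones = 3, n_pass_gate = 3,
                             inter_bone_sd_db = 0,
                             ear = noiseless(), input_jitter = FALSE,
                             seed = 11)
  expect_equal(coh0[[1]]$acoustic, coh0[[2]]$acoustic)
  expect_equal(coh0[[2]]$actuator, coh0[[3]]$actuator)

  # cohort medians of recovered output sit at the template truth
  act <- actuator_model(105)
  coh2 <- generate_tb_cohort(n_bones = 8, n_pass_gate = 8, act = act,
                             seed = 12)
  ser <- lapply(coh2, tb_output_series, reference = "icpd",
                td_table = td_placeholder())
  sm <- summarize_cohort(ser, "icpd")
  expect_lt(max(abs(sm$median - 105)), 1)
})

test_that("temporal-bone and clinical cohorts from one truth agree at cohort scale", {
  act <- actuator_model()
  coh <- generate_tb_cohort(n_bones = 10, n_pass_gate = 10, act = act,
                            seed = 42)
  tb_ser <- lapply(coh, tb_output_series, reference = "icpd",
                   td_table = td_placeholder())
  cl <- generate_clinical_cohort(n_patients = 24, act = act, seed = 43)
  cl_ser <- lapply(cl, clinical_output_series,
                   tables = conversion_tables())

  tb_aud <- t(vapply(tb_ser, audiometric_levels, numeric(8)))
  colnames(tb_aud) <- as.character(audiometric_frequencies())
  sm_tb <- summarize_cohort(tb_aud, "tb")
  sm_cl <- summarize_cohort(cl_ser, "clinical")
  merged <- merge(sm_tb, sm_cl, by = "frequency_hz")
  expect_equal(nrow(merged), 8)
  gap <- abs(merged$median.x - merged$median.y)
  # at well-sampled frequencies the two cohort medians track within 3 dB;
  # sparse frequencies (e.g. 0.25 kHz, N = 5 quantized patients) carry too
  # much median sampling error for that band and get a looser bound
  expect_lt(max(gap[merged$n.y >= 10]), 3)
  expect_lt(max(gap), 5)
})
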