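test_that("frequency grid construction and tone snapping follow the bin rule", {
  g <- frequency_grid()
  expect_equal(g$bin_spacing, 12.5)
  expect_true(all(diff(g$frequencies) == 12.5))
  expect_true(10000 %in% g$frequencies)
  expect_equal(bin_index(g, 1000), 81L)   # 1000 / 12.5 lines above DC
  expect_equal(bin_index(g, 1006), 81L)   # snaps to 1000 (6 Hz < 6.25)
  expect_equal(bin_index(g, 1007), 82L)   # nearest line is now 1012.5
  expect_error(bin_index(g, 10100), "outside")
  expect_error(frequency_grid(bin_spacing = 0), "bin_spacing")

  seq_ <- stimulus_sequence()
  expect_length(seq_, 23)
  expect_true(all(as.numeric(seq_) %% 12.5 == 0))
  # roughly three tones per octave over 100 Hz - 10 kHz
  expect_equal(length(seq_) / log2(10000 / 100), 3.5, tolerance = 0.2)
})

test_that("adjacent-bin SNR estimate matches direct arithmetic and caps", {
  g <- frequency_grid(1, 21)
  mk <- function(sig, nb) {
    v <- rep(0 + 0i, 21)
    v[11] <- sig
    v[11 + c(-3:-1, 1:3)] <- nb
    complex_spectrum(v, g, "Pa")
  }
  expect_equal(snr_estimate(mk(1, 0.1), 11), 20)
  expect_equal(snr_estimate(mk(1, 0.2), 11), 20 * log10(5))
  expect_equal(snr_estimate(mk(1, 0), 11), 200)     # zero-noise cap
  expect_equal(snr_estimate(mk(0, 0.1), 11), -200)  # zero-signal floor
  expect_error(snr_estimate(mk(1, 0.1), 2), "edge")

  # power averaging differs from amplitude averaging for unequal neighbours
  v <- rep(0 + 0i, 21); v[11] <- 1
  v[11 + c(-3:-1, 1:3)] <- c(0.1, 0.1, 0.1, 0.3, 0.3, 0.3)
  s <- complex_spectrum(v, g, "Pa")
  expect_equal(snr_estimate(s, 11), 20 * log10(1 / 0.2))
  expect_equal(snr_estimate(s, 11, noise_average = "power"),
               20 * log10(1 / sqrt(mean(c(0.1, 0.1, 0.1, 0.3, 0.3, 0.3)^2))))

  # invariant under global scaling of the spectrum
  set.seed(11)
  v <- complex(real = rnorm(21), imaginary = rnorm(21))
  s1 <- complex_spectrum(v, g, "Pa")
  s2 <- complex_spectrum(v * (3 - 2i), g, "Pa")
  expect_equal(snr_estimate(s1, 11), snr_estimate(s2, 11))
})

test_that("coherent averaging stops at the SNR target within [n_min, n_max]", {
  g <- frequency_grid(1, 21)
  sig <- rep(0 + 0i, 21); sig[11] <- 1

  # identical noiseless frames: mean equals any single frame exactly
  frames <- matrix(rep(sig, 40), nrow = 40, byrow = TRUE)
  out <- average_until_snr(frames, 11, g, "Pa", n_min = 30, n_max = 40)
  expect_identical(out$spectrum$values, sig)
  expect_equal(out$n_used, 30)
  expect_equal(out$snr_db, 200)

  # strong signal with small noise reaches the target at n_min
  set.seed(21)
  noisy <- t(vapply(1:60, function(i)
    sig + complex(real = rnorm(21, 0, 0.02), imaginary = rnorm(21, 0, 0.02)),
    complex(21)))
  out <- average_until_snr(noisy, 11, g, "Pa", n_min = 30, n_max = 60)
  expect_equal(out$n_used, 30)
  expect_gt(out$snr_db, 20)

  # pure noise never reaches the target: all frames consumed, SNR < 12
  noise_only <- t(vapply(1:80, function(i)
    complex(real = rnorm(21, 0, 1), imaginary = rnorm(21, 0, 1)),
    complex(21)))
  out <- average_until_snr(noise_only, 11, g, "Pa", n_min = 30, n_max = 80)
  expect_equal(out$n_used, 80)
  expect_lt(out$snr_db, 12)

  expect_error(average_until_snr(noisy[1:10, ], 11, g, "Pa", n_min = 30),
               "n_min")
})

test_that("tone extraction picks the nearest bin and carries its SNR", {
  g <- frequency_grid()
  v <- rep(0 + 0i, g$n_bins)
  v[81] <- 2 + 1i
  v[81 + c(-3:-1, 1:3)] <- 0.01
  s <- complex_spectrum(v, g, "Pa", n_averages = 30)
  tone <- extract_tone(s, 1006)
  expect_equal(tone$frequency, 1000)
  expect_equal(tone$response, 2 + 1i)
  expect_equal(tone$snr_db, 20 * log10(Mod(2 + 1i) / 0.01))
  expect_equal(tone$n_averages, 30)
  # beyond half a bin from 1000 Hz the nearest line is 1012.5
  expect_equal(extract_tone(s, 1007)$frequency, 1012.5)
  expect_error(extract_tone(s, 10100), "outside")
})

test_that("renormalization preserves response/input ratios exactly", {
  f <- c(500, 1000)
  a <- data.frame(frequency = f, response = c(1 + 1i, 2 - 1i),
                  input_ref = c(2 + 0i, 2 + 0i))
  # identical inputs: identity
  out <- renormalize_to_common_input(a, a)
  expect_equal(out$run_a, a)
  expect_equal(out$run_b, a)

  # input 0.07 dB higher in run b: each run adjusted by half (0.035 dB)
  b <- a
  b$input_ref <- a$input_ref * 10^(0.07 / 20)
  out <- renormalize_to_common_input(a, b)
  expect_equal(20 * log10(Mod(out$run_a$response) / Mod(a$response)),
               rep(0.035, 2))
  expect_equal(20 * log10(Mod(out$run_b$response) / Mod(b$response)),
               rep(-0.035, 2))

  # input ratio exactly 2: responses move by sqrt(2) toward the mean
  b2 <- a; b2$input_ref <- 2 * a$input_ref
  expect_warning(renormalize_to_common_input(a, b2), "tolerance")
  out <- suppressWarnings(renormalize_to_common_input(a, b2))
  expect_equal(Mod(out$run_a$response) / Mod(a$response), rep(sqrt(2), 2))
  expect_equal(Mod(out$run_b$response) / Mod(b2$response),
               rep(1 / sqrt(2), 2))

  # property: ratios invariant to 1e-12 relative error under random jitter
  set.seed(31)
  for (i in 1:20) {
    ra <- data.frame(
      frequency = f,
      response = complex(real = rnorm(2), imaginary = rnorm(2)),
      input_ref = complex(real = rnorm(2, 2), imaginary = rnorm(2, 0, 0.2)))
    rb <- ra
    jit <- 10^(runif(2, -0.1, 0.1) / 20) * exp(1i * runif(2, -0.05, 0.05))
    rb$input_ref <- ra$input_ref * jit
    rb$response <- ra$response * jit * (0.8 + 0.1i)  # different channel
    out <- renormalize_to_common_input(ra, rb)
    expect_equal(out$run_a$response / out$run_a$input_ref,
                 ra$response / ra$input_ref, tolerance = 1e-12)
    expect_equal(out$run_b$response / out$run_b$input_ref,
                 rb$response / rb$input_ref, tolerance = 1e-12)
  }
})

test_that("cosine correction rescales by 1/cos(angle) and rejects >= 90 deg", {
  expect_equal(cosine_correct(1 + 2i, 0), 1 + 2i)
  expect_equal(Mod(cosine_correct(1 + 0i, 60)), 2)
  expect_equal(Mod(cosine_correct(1i, 45)), sqrt(2))
  expect_error(cosine_correct(1 + 0i, 90), "90")
  expect_error(cosine_correct(1 + 0i, -1), "90")
})

test_that("velocity-displacement conversion is 1/(i 2 pi f) with its inverse", {
  d <- velocity_to_displacement(2 * pi * 1e-6 + 0i, 1000)
  expect_equal(Mod(d), 1e-9)
  expect_equal(Arg(velocity_to_displacement(1 + 0i, 500)), -pi / 2)
  # doubling f halves |d|
  expect_equal(Mod(velocity_to_displacement(1 + 0i, 2000)),
               Mod(velocity_to_displacement(1 + 0i, 1000)) / 2)
  # roundtrip identity
  set.seed(41)
  v <- complex(real = rnorm(10), imaginary = rnorm(10))
  f <- runif(10, 100, 10000)
  expect_equal(velocity_to_displacement(v, f) * (1i * 2 * pi * f), v)
  expect_error(velocity_to_displacement(1 + 0i, 0), "positive")
})
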