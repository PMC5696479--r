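mk_series <- function(levels, freqs = c(1262.5, 1587.5), id = "TB",
                      excluded = rep(FALSE, length(levels))) {
  eqspl_series(freqs, ifelse(excluded, NA_real_, levels),
               excluded = excluded,
               reason = ifelse(excluded, "snr", ""), reference = "icpd",
               bone_id = id)
}

test_that("cohort summaries use interpolated percentiles and skip masked values", {
  m <- matrix(c(100, 110, 120), ncol = 1, dimnames = list(NULL, "1000"))
  sm <- summarize_cohort(m)
  expect_equal(sm$median, 110)
  expect_equal(sm$p25, 105)
  expect_equal(sm$p75, 115)
  expect_equal(sm$n, 3)

  # degenerate single-value cohort
  sm1 <- summarize_cohort(matrix(107, 1, 1, dimnames = list(NULL, "500")))
  expect_equal(unlist(sm1[c("median", "p25", "p75")]),
               c(median = 107, p25 = 107, p75 = 107))

  # masked values change nothing; all-masked frequencies are omitted
  s_list <- list(mk_series(c(100, 104)), mk_series(c(110, NA),
                                                   excluded = c(FALSE, TRUE)),
                 mk_series(c(120, NA), excluded = c(FALSE, TRUE)))
  sm2 <- summarize_cohort(s_list)
  expect_equal(sm2$n, c(3, 1))
  expect_equal(sm2$median[1], 110)
  s_all_masked <- lapply(s_list, function(s) {
    s$excluded <- c(FALSE, TRUE); s$level_db[2] <- NA; s
  })
  expect_equal(nrow(summarize_cohort(s_all_masked)), 1)

  # invariant to the order of bones
  expect_equal(summarize_cohort(rev(s_list))$median,
               summarize_cohort(s_list)$median)
})

test_that("the 1.5 kHz level interpolates linearly between the bracket tones", {
  expect_equal(interpolate_at_1500(mk_series(c(100, 113))), 109.5)
  expect_equal(interpolate_at_1500(mk_series(c(105, 105))), 105)
  # always between the bracket levels
  set.seed(5)
  for (i in 1:20) {
    l <- runif(2, 80, 130)
    v <- interpolate_at_1500(mk_series(l))
    expect_gte(v, min(l)); expect_lte(v, max(l))
  }
  # masked bracket masks the result
  expect_true(is.na(interpolate_at_1500(
    mk_series(c(100, NA), excluded = c(FALSE, TRUE)))))
})

test_that("normality screening flags non-normal samples and degenerate input", {
  scr <- normality_screen(matrix(rep(100, 8), ncol = 1,
                                 dimnames = list(NULL, "1000")))
  expect_true(is.na(scr$p_value))
  expect_true(is.na(normality_screen(
    matrix(c(1, 2), ncol = 1, dimnames = list(NULL, "1000")))$p_value))

  # strongly bimodal sample (two clusters 30 dB apart) rejects mostly
  set.seed(61)
  rej <- mean(replicate(50, {
    v <- c(rnorm(5, 100, 1), rnorm(5, 130, 1))
    normality_screen(matrix(v, ncol = 1,
                            dimnames = list(NULL, "1")))$p_value < 0.05
  }))
  expect_gt(rej, 0.8)

  # under a normal null, p-values are roughly uniform: rejection near alpha
  set.seed(62)
  rej0 <- mean(replicate(400, {
    v <- rnorm(10)
    normality_screen(matrix(v, ncol = 1,
                            dimnames = list(NULL, "1")))$p_value < 0.05
  }))
  expect_gt(rej0, 0.02); expect_lt(rej0, 0.09)
})

test_that("paired comparison matches the exact signed-rank distribution", {
  f <- as.character(c(1000))
  mat <- function(v) matrix(v, ncol = 1, dimnames = list(NULL, f))

  # identical series: no nonzero differences, p = 1
  a <- mat(c(100, 105, 110, 115, 120))
  expect_equal(paired_compare(a, a)$p_value, 1)

  # uniformly positive (tie-free) differences over 10 bones: the test
  # statistic is at its maximum and the exact two-sided p is 2 / 2^10
  set.seed(71)
  base <- rnorm(10, 110, 5)
  shift <- runif(10, 5, 15)
  pc <- paired_compare(mat(base + shift), mat(base))
  expect_equal(pc$p_value, 2 / 2^10)
  expect_equal(pc$p_value, signed_rank_exact_p(shift))
  # agreement with the enumeration oracle on arbitrary tie-free data
  for (i in 1:5) {
    d <- rnorm(8)
    expect_equal(paired_compare(mat(d), mat(rep(0, 8)))$p_value,
                 signed_rank_exact_p(d))
  }

  # invariant to adding a common constant to both series
  b <- mat(base + rnorm(10, 0, 3))
  expect_equal(paired_compare(mat(base), b)$p_value,
               paired_compare(mat(base) + 50, b + 50)$p_value)
  # too few pairs: not applicable
  expect_true(is.na(paired_compare(mat(1:3), mat(c(2, 4, 7)))$p_value))
})

test_that("unpaired comparison matches the exact Mann-Whitney distribution", {
  f <- "2000"
  mat <- function(v) matrix(v, ncol = 1, dimnames = list(NULL, f))
  # identical groups carry no evidence
  expect_gt(unpaired_compare(mat(c(1, 2, 3, 4)), mat(c(1, 2, 3, 4)))$p_value,
            0.99)
  # fully separated 4 vs 4: exact p = 2/70
  uc <- unpaired_compare(mat(c(1, 2, 3, 4)), mat(c(10, 11, 12, 13)))
  expect_equal(uc$p_value, 2 / 70)
  expect_equal(uc$p_value,
               mann_whitney_exact_p(c(1, 2, 3, 4), c(10, 11, 12, 13)))
  set.seed(81)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(5, 0.5)
    expect_equal(unpaired_compare(mat(c(x, NA, NA, NA, NA)),
                                  mat(c(y, NA, NA, NA, NA, NA)))$p_value,
                 mann_whitney_exact_p(x, y))
  }
  # insufficient group size: not applicable
  expect_true(is.na(unpaired_compare(mat(c(1, 2, NA)),
                                     mat(c(3, 4, 5)))$p_value))
})
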