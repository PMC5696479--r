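#' Align a list of output series into a value matrix
#'
#' Stacks the unmasked levels of several [eqspl_series()] into a matrix with
#' one row per series (bone or patient) and one column per frequency;
#' masked or absent tones become `NA`.
#'
#' @param series_list List of [eqspl_series()].
#' @param frequencies Column frequencies; defaults to the union of all
#'   series' frequencies.
#' @return Numeric matrix with frequency column names and series-id row
#'   names.
#' @export
cohort_values <- function(series_list, frequencies = NULL) {
  if (is.null(frequencies))
    frequencies <- sort(unique(unlist(
      lapply(series_list, function(s) s$frequency_hz))))
  m <- t(vapply(series_list, function(s) {
    v <- rep(NA_real_, length(frequencies))
    i <- match(s$frequency_hz, frequencies)
    lv <- ifelse(s$excluded, NA_real_, s$level_db)
    v[i[!is.na(i)]] <- lv[!is.na(i)]
    v
  }, numeric(length(frequencies))))
  colnames(m) <- as.character(frequencies)
  rownames(m) <- vapply(series_list, function(s)
    as.character(attr(s, "bone_id")), character(1))
  m
}

#' Cohort summary: median and quartiles per frequency
#'
#' Median and 25/75 percentiles of the unmasked values at each frequency,
#' using linear interpolation between order statistics
#' (`stats::quantile(type = 7)`).  Frequencies where every value is masked
#' are omitted from the summary.
#'
#' @param x List of [eqspl_series()] or a matrix from [cohort_values()].
#' @param group Label for the summarized group.
#' @return A data frame of class `cohort_summary` with columns `group`,
#'   `frequency_hz`, `n`, `median`, `p25`, `p75`.
#' @examples
#' summarize_cohort(matrix(c(100, 110, 120), ncol = 1,
#'                         dimnames = list(NULL, "1000")))
#' @export
summarize_cohort <- function(x, group = "cohort") {
  if (!is.matrix(x)) x <- cohort_values(x)
  rows <- lapply(colnames(x), function(fc) {
    v <- x[, fc]
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NULL)
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = group, frequency_hz = as.numeric(fc),
               n = length(v), median = q[2], p25 = q[1], p75 = q[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Interpolate a temporal-bone series at 1.5 kHz
#'
#' The stimulus sequence has no tone at the audiometric frequency 1.5 kHz;
#' the output there is estimated by linear interpolation (on the Hz axis)
#' between the measured levels at 1262.5 and 1587.5 Hz.  If either
#' bracketing tone is masked the result is `NA`.
#'
#' @param series An [eqspl_series()].
#' @param brackets The two bracketing tone frequencies in Hz.
#' @param at Target frequency in Hz (default 1500).
#' @return Interpolated level in eq. dB SPL_FF, or `NA`.
#' @export
interpolate_at_1500 <- function(series, brackets = c(1262.5, 1587.5),
                                at = 1500) {
  i <- match(brackets, series$frequency_hz)
  if (anyNA(i)) return(NA_real_)
  if (any(series$excluded[i])) return(NA_real_)
  l <- series$level_db[i]
  l[1] + (l[2] - l[1]) * (at - brackets[1]) / (brackets[2] - brackets[1])
}

#' Levels of a temporal-bone series at the audiometric frequencies
#'
#' Extracts the levels at 0.25, 0.5, 1, 2, 3, 4 and 6 kHz directly and
#' fills 1.5 kHz by [interpolate_at_1500()], for comparison against
#' clinical data.
#'
#' @param series An [eqspl_series()].
#' @return Named numeric vector over [audiometric_frequencies()].
#' @export
audiometric_levels <- function(series) {
  freqs <- audiometric_frequencies()
  out <- vapply(freqs, function(f) {
    if (f == 1500) return(interpolate_at_1500(series))
    i <- match(f, series$frequency_hz)
    if (is.na(i) || series$excluded[i]) NA_real_ else series$level_db[i]
  }, numeric(1))
  names(out) <- as.character(freqs)
  out
}

#' Shapiro-Wilk normality screen
#'
#' Per-frequency Shapiro-Wilk p-values of the unmasked cohort values, with
#' the 0.05 flag used for reporting.  Samples with fewer than 3 values or
#' no variability are marked not applicable (`NA`).
#'
#' @param x Matrix from [cohort_values()] (or list of series).
#' @param alpha Flagging threshold (default 0.05).
#' @return Data frame with `frequency_hz`, `n`, `p_value`, `non_normal`.
#' @export
normality_screen <- function(x, alpha = 0.05) {
  if (!is.matrix(x)) x <- cohort_values(x)
  rows <- lapply(colnames(x), function(fc) {
    v <- x[, fc]; v <- v[!is.na(v)]
    p <- if (length(v) < 3 || stats::sd(v) == 0) NA_real_
         else stats::shapiro.test(v)$p.value
    data.frame(frequency_hz = as.numeric(fc), n = length(v), p_value = p,
               non_normal = !is.na(p) & p < alpha)
  })
  do.call(rbind, rows)
}

## exact-capable wilcoxon p with documented zero handling; returns NA when
## the test is not applicable
wilcoxon_paired_p <- function(d, zero_handling = c("drop", "keep")) {
  zero_handling <- match.arg(zero_handling)
  if (zero_handling == "drop") d <- d[d != 0]
  if (length(d) == 0) return(1)   # no nonzero differences: no evidence
  suppressWarnings(stats::wilcox.test(d, exact = TRUE)$p.value)
}

#' Paired per-frequency comparison (Wilcoxon signed-rank)
#'
#' Two-sided Wilcoxon signed-rank test of the per-bone differences between
#' two output series at each frequency.  Only bones unmasked in both groups
#' at a frequency contribute; fewer than `n_min` pairs marks the frequency
#' not applicable.  Zero differences are discarded before ranking
#' (Wilcoxon's original rule, switchable); a frequency with no nonzero
#' differences reports p = 1.  Exact p-values are used when there are no
#' ties (falling back to the normal approximation otherwise).
#'
#' @param a,b Matrices from [cohort_values()], same shape and row order
#'   (same bones).
#' @param n_min Minimum number of complete pairs (default 5).
#' @param zero_handling `"drop"` (default) or `"keep"`.
#' @param alpha Significance threshold for the reporting flag.
#' @return Data frame with `frequency_hz`, `n`, `p_value`, `significant`.
#' @export
paired_compare <- function(a, b, n_min = 5, zero_handling = "drop",
                           alpha = 0.05) {
  if (!identical(dim(a), dim(b)))
    stop("`a` and `b` must have identical shape", call. = FALSE)
  rows <- lapply(seq_len(ncol(a)), function(j) {
    ok <- !is.na(a[, j]) & !is.na(b[, j])
    d <- a[ok, j] - b[ok, j]
    p <- if (sum(ok) < n_min) NA_real_
         else wilcoxon_paired_p(d, zero_handling)
    data.frame(frequency_hz = as.numeric(colnames(a)[j]), n = sum(ok),
               p_value = p, significant = !is.na(p) & p < alpha)
  })
  do.call(rbind, rows)
}

#' Unpaired per-frequency comparison (Mann-Whitney rank sum)
#'
#' Two-sided Mann-Whitney U test between two independent cohorts (for
#' example temporal-bone outputs, interpolated to the audiometric
#' frequencies, against clinical outputs).  Exact p-values when there are
#' no ties.
#'
#' @param a,b Matrices from [cohort_values()] with matching columns (the
#'   rows are unrelated).
#' @param n_min Minimum group size per frequency (default 3).
#' @param alpha Significance threshold for the reporting flag.
#' @return Data frame with `frequency_hz`, `n_a`, `n_b`, `p_value`,
#'   `significant`.
#' @export
unpaired_compare <- function(a, b, n_min = 3, alpha = 0.05) {
  if (!identical(colnames(a), colnames(b)))
    stop("`a` and `b` must share the same frequency columns", call. = FALSE)
  rows <- lapply(seq_len(ncol(a)), function(j) {
    x <- a[, j]; x <- x[!is.na(x)]
    y <- b[, j]; y <- y[!is.na(y)]
    p <- if (length(x) < n_min || length(y) < n_min) NA_real_
         else suppressWarnings(
           stats::wilcox.test(x, y, exact = TRUE)$p.value)
    data.frame(frequency_hz = as.numeric(colnames(a)[j]),
               n_a = length(x), n_b = length(y), p_value = p,
               significant = !is.na(p) & p < alpha)
  })
  do.call(rbind, rows)
}
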