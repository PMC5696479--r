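# Brute-force oracles and small fixture builders shared across the suite.

# Exact two-sided signed-rank p-value by enumerating all 2^n sign
# assignments of the ranked absolute differences (no ties, no zeros).
signed_rank_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- drop(signs %*% r)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Exact two-sided Mann-Whitney p-value by enumerating all group-A rank
# assignments (no ties).
mann_whitney_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  # with no ties the ranks are 1..n1+n2, so a combination's rank sum is
  # just the sum of the chosen rank positions
  combos <- utils::combn(n1 + n2, n1)
  w_all <- apply(combos, 2, sum)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# A minimal consistent tone set: a linear piston-only ear at one frequency
# where stapes displacement and pressure-difference references must agree.
consistent_tone <- function(f = 1000, h_me = 3e-8 + 0i, z_c = 3e8 + 0i,
                            p_t = 2 + 0i, e = 0.4 + 0i,
                            transfer_pa_per_v = 25) {
  d_u <- h_me * p_t
  dp_u <- z_c * d_u
  d_a <- d_u / p_t * transfer_pa_per_v * e
  dp_a <- dp_u / p_t * transfer_pa_per_v * e
  list(f = f, p_t = p_t, e = e, d_u = d_u, d_a = d_a, dp_u = dp_u,
       dp_a = dp_a)
}

# Hand-built two-tone temporal-bone record with explicit SNR values.
# Velocities are chosen so the analysis recovers `level_db` exactly when
# td is flat 0 dB and the beam angle is 0.
toy_record <- function(level_db = c(100, 100), snr = c(200, 200),
                       freqs = c(1000, 2000), e = 0.5 + 0i) {
  p_t <- rep(2 + 0i, length(freqs))
  h <- 3e-8
  d_u <- h * p_t
  dp_u <- (3e8 + 0i) * d_u
  transfer <- PA_REF * 10^(level_db / 20)       # Pa per V at the eardrum
  d_a <- d_u / p_t * transfer * e
  dp_a <- dp_u / p_t * transfer * e
  w <- 1i * 2 * pi * freqs
  run <- function(v, sv, st, input, input_name) {
    out <- data.frame(frequency = freqs, v_stapes = v, p_sv = sv,
                      p_st = st, snr_stapes = snr, snr_sv = snr,
                      snr_st = snr, n_averages = 30L)
    out[[input_name]] <- input
    out
  }
  tb_record("TBX", "4 mN", 4, 0,
            run(w * d_u, dp_u / 2, -dp_u / 2, p_t, "p_t"),
            run(w * d_a, dp_a / 2, -dp_a / 2, rep(e, length(freqs)), "e"))
}
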