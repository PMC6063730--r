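# Independent brute-force oracles used to freeze expected values.

# literal enumeration of all 2^n sign assignments of the mid-rank vector
brute_signed_rank <- function(d, sided = "two", direction = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  p_le <- mean(w_all <= w_obs + 1e-9)
  if (sided == "two") min(1, 2 * min(p_ge, p_le))
  else if (direction == "greater") p_ge else p_le
}

# literal enumeration of all choose(n1+n2, n1) group assignments
brute_rank_sum <- function(x, y, sided = "two", direction = "greater") {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(N, n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  p_ge <- mean(w_all >= w_obs - 1e-9)
  p_le <- mean(w_all <= w_obs + 1e-9)
  if (sided == "two") min(1, 2 * min(p_ge, p_le))
  else if (direction == "greater") p_ge else p_le
}

# direct DFT of one window: band power as sum of squared magnitudes over
# the bins with frequency in [1, 5] Hz (complex-exponential sums, no fft)
oracle_window_band_power <- function(w, fs, window_s = 2, band = c(1, 5)) {
  N <- length(w)
  kbins <- seq(ceiling(band[1] * window_s), floor(band[2] * window_s))
  sum(vapply(kbins, function(k) {
    e <- exp(-2i * pi * k * (0:(N - 1)) / N)
    Mod(sum(w * e))^2
  }, numeric(1)))
}

# direct DFT amplitude spectrum of one 1 s segment (2|X|/N, DC excluded)
oracle_segment_amplitude <- function(seg, kmax) {
  N <- length(seg)
  vapply(seq_len(kmax), function(k) {
    e <- exp(-2i * pi * k * (0:(N - 1)) / N)
    2 * Mod(sum(seg * e)) / N
  }, numeric(1))
}

# fraction of classifier-assigned (Active+Quiet) time agreeing with the
# planted behavioral states
state_agreement <- function(ses, gt) {
  num <- interval_total_duration(
    interval_intersect(ses$states$Active, gt$planted_active)) +
    interval_total_duration(
      interval_intersect(ses$states$Quiet, gt$planted_quiet))
  den <- interval_total_duration(ses$states$Active) +
    interval_total_duration(ses$states$Quiet)
  num / den
}

# random small interval set on [0, span) built from a random logical vector
random_interval_set <- function(span = 10, label = "x") {
  flag <- runif(span * 4) < 0.4
  intervals_from_logical(flag, 0, 0.25, label)
}
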