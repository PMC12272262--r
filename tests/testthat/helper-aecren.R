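# Shared helpers: small-scale simulation defaults and independent oracles.

# reduced-scale simulation settings used across unit tests (study-scale
# conditions are exercised in test-acceptance.R)
test_config <- function(...) {
  args <- utils::modifyList(list(fs = 250, duration_s = 120), list(...))
  do.call(simulation_config, args)
}

# Monte-Carlo tolerance for an envelope correlation estimate: narrow-band
# envelopes decorrelate over ~1/bandwidth seconds, giving roughly
# duration * bandwidth effective samples.
corr_tol <- function(duration_s, bandwidth_hz, rho = 0, k_sigma = 3) {
  n_eff <- duration_s * bandwidth_hz
  k_sigma * (1 - rho^2) / sqrt(n_eff)
}

# fraction of variance of x inside [lo, hi] Hz, by periodogram integration
band_variance_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  sum(p[f >= lo & f <= hi]) / sum(p[-1L])
}

# brute-force Viterbi: enumerate every state path of a short sequence
brute_viterbi <- function(x, means, sds, trans, init) {
  n <- length(x)
  K <- length(means)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  best <- -Inf
  best_path <- NULL
  for (i in seq_len(nrow(paths))) {
    s <- as.integer(paths[i, ])
    lp <- log(init[s[1L]]) + dnorm(x[1L], means[s[1L]], sds[s[1L]], log = TRUE)
    for (t in seq_len(n - 1L))
      lp <- lp + log(trans[s[t], s[t + 1L]]) +
        dnorm(x[t + 1L], means[s[t + 1L]], sds[s[t + 1L]], log = TRUE)
    if (lp > best) { best <- lp; best_path <- s }
  }
  best_path
}

# two-level square-wave envelope with gaussian jitter (ground truth known)
two_level_envelope <- function(n, fs, low = 1, high = 3, dwell_s = 1,
                               jitter = 0.25, seed = 1) {
  set.seed(seed)
  n_seg <- ceiling(n / (dwell_s * fs))
  states <- rep(rep(c(1L, 2L), length.out = n_seg), each = dwell_s * fs)[1:n]
  mu <- c(low, high)[states]
  list(envelope = pmax(mu + rnorm(n, 0, jitter), 0.01), states = states)
}
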