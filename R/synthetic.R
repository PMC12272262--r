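# Synthetic narrow-band signal pairs with controlled envelope coupling and
# SNR. Signals are built directly in the analytic (positive-frequency) domain:
# a band-limited gaussian process is drawn as independent complex spectral
# coefficients over the band, so its real part is the band-filtered white
# noise and its modulus the exact Hilbert envelope.

#' Simulation configuration for coupled synthetic pairs
#'
#' Describes one cell of the coupling/SNR simulation experiments: a pair of
#' narrow-band gaussian "connectivity processes" with envelope coupling
#' `aec0`, plus additive band-matched background noise with coupling
#' `aec_noise`, at signal-to-noise ratios `snr_x`, `snr_y`.
#'
#' @param band_low_hz,band_high_hz band edges (Hz).
#' @param fs sampling rate (Hz).
#' @param duration_s length of each realization (seconds).
#' @param aec0 envelope-power coupling of the connectivity processes, in
#'   `[0, 1)`.
#' @param aec_noise coupling of the noise processes, in `[0, 1)`.
#' @param snr_x,snr_y signal-to-noise ratios (> 0; `Inf` for noise-free).
#' @param n_repetitions repetitions per cell.
#' @param seed master seed for the cell.
#' @param mix variable in which the k-mixing rule operates: `"power"`
#'   (squared envelope, default — the variable AEC itself correlates) or
#'   `"envelope"`.
#' @param gain `"exact"` solves the mixing gain so the realized clean-pair
#'   correlation equals `aec0`; `"formula"` uses the closed-form plug-in
#'   gain (see [envelope_mixing_gain()]).
#' @param snr_convention `"process"`: SNR is the std ratio of the rescaled
#'   connectivity process to the noise process (default); `"measured"`: SNR
#'   is the std ratio of the summed measurement to the noise process
#'   (requires SNR > 1).
#' @param couple_after_rescale apply the envelope coupling to the
#'   SNR-rescaled processes (default) rather than before rescaling.
#' @return a `simulation_config` object.
#' @export
simulation_config <- function(band_low_hz = 8, band_high_hz = 12, fs = 1000,
                              duration_s = 300, aec0 = 0.5, aec_noise = 0,
                              snr_x = 2, snr_y = 2, n_repetitions = 31,
                              seed = 1L,
                              mix = c("power", "envelope"),
                              gain = c("exact", "formula"),
                              snr_convention = c("process", "measured"),
                              couple_after_rescale = TRUE) {
  check_band(band_low_hz, band_high_hz, fs)
  stopifnot_scalar(duration_s, "duration_s", positive = TRUE)
  if (aec0 < 0 || aec0 >= 1) stop("aec0 must be in [0, 1)", call. = FALSE)
  if (aec_noise < 0 || aec_noise >= 1)
    stop("aec_noise must be in [0, 1)", call. = FALSE)
  for (s in c(snr_x, snr_y))
    if (!(is.numeric(s) && length(s) == 1L && !is.na(s) && s > 0))
      stop("snr_x and snr_y must be positive", call. = FALSE)
  if (n_repetitions < 1L) stop("n_repetitions must be >= 1", call. = FALSE)
  structure(list(
    band_low_hz = band_low_hz, band_high_hz = band_high_hz, fs = fs,
    duration_s = duration_s, aec0 = aec0, aec_noise = aec_noise,
    snr_x = snr_x, snr_y = snr_y, n_repetitions = as.integer(n_repetitions),
    seed = as.integer(seed), mix = match.arg(mix), gain = match.arg(gain),
    snr_convention = match.arg(snr_convention),
    couple_after_rescale = isTRUE(couple_after_rescale)),
    class = "simulation_config")
}

# analytic band-limited gaussian noise, unit variance of the real part
band_limited_analytic <- function(n, fs, lo, hi, seed = NULL) {
  check_band(lo, hi, fs)
  if (n < 8L) stop("duration too short", call. = FALSE)
  f <- (seq_len(n) - 1) * fs / n
  keep <- which(f >= lo & f <= hi & f <= fs / 2)
  if (length(keep) < 2L)
    stop("band too narrow for the requested duration", call. = FALSE)
  with_seed(seed, {
    Z <- complex(length.out = n)
    Z[keep] <- complex(real = rnorm(length(keep)),
                       imaginary = rnorm(length(keep)))
    z <- fft(Z, inverse = TRUE) / sqrt(n)
    z / sd(Re(z))
  })
}

#' Band-filtered gaussian white noise
#'
#' @param band_low_hz,band_high_hz band edges (Hz), inside the Nyquist range.
#' @param fs sampling rate (Hz).
#' @param duration_s duration (seconds); must give at least 8 samples.
#' @param seed RNG seed (deterministic output for a given seed).
#' @return zero-mean, unit-variance real vector of `fs * duration_s` samples
#'   whose spectral energy lies in the requested band.
#' @export
gen_band_limited_gaussian <- function(band_low_hz, band_high_hz, fs,
                                      duration_s, seed = NULL) {
  stopifnot_scalar(duration_s, "duration_s", positive = TRUE)
  n <- round(fs * duration_s)
  Re(band_limited_analytic(n, fs, band_low_hz, band_high_hz, seed))
}

#' Envelope mixing gain of the k-mixing rule
#'
#' Closed-form gain `k = aec0 / sqrt(1 - aec0^2) * sigma_ay0 / sigma_ax0`
#' such that, for independent processes, `corr(A_y0 + k * A_x0, A_x0) =
#' aec0` (identity: with `c = aec0 / sqrt(1 - aec0^2)`, the correlation is
#' `c / sqrt(1 + c^2) = aec0`). The same formula applies in whichever
#' amplitude variable (envelope or squared envelope) the sigmas are taken.
#'
#' @param aec0 target coupling in `[0, 1)`.
#' @param sigma_ay0,sigma_ax0 standard deviations of the two amplitude
#'   series (> 0).
#' @return non-negative scalar gain.
#' @export
envelope_mixing_gain <- function(aec0, sigma_ay0, sigma_ax0) {
  if (!is.finite(aec0) || aec0 < 0 || aec0 >= 1)
    stop("aec0 must be in [0, 1): the mixing gain diverges at aec0 = 1",
         call. = FALSE)
  stopifnot_scalar(sigma_ax0, "sigma_ax0", positive = TRUE)
  stopifnot_scalar(sigma_ay0, "sigma_ay0", positive = TRUE)
  aec0 / sqrt(1 - aec0^2) * sigma_ay0 / sigma_ax0
}

# gain solving corr(b + k a, a) = r exactly in the sample moments of a, b
solve_mixing_gain <- function(a, b, r) {
  va <- var(a); vb <- var(b); cab <- cov(a, b)
  A <- (1 - r^2) * va^2
  B <- 2 * cab * va * (1 - r^2)
  C <- cab^2 - r^2 * va * vb
  disc <- B^2 - 4 * A * C
  if (!is.finite(disc) || disc < 0) disc <- 0
  (-B + sqrt(disc)) / (2 * A)
}

# core coupling operator on analytic signals; returns the coupled analytic y.
# The mixed envelope is low-passed below the band edge and projected back
# onto an analytic signal so the Hilbert envelope of the reconstructed real
# signal reproduces the constructed one. Envelope substitution necessarily
# spreads some spectral energy outside the original band (the new envelope
# no longer matches the phase factor's frequency excursions); when
# band_high_hz is given the result is additionally band-limited back to
# [band_low_hz, band_high_hz], which costs coupling strength. With gain =
# "exact" the gain target is iterated until the realized clean-pair
# correlation equals aec0 after all post-processing.
couple_analytic <- function(zx0, zy0, aec0, fs, band_low_hz,
                            band_high_hz = NULL, mix = "power",
                            gain = "exact", n_calib = 8L, calib_tol = 5e-4) {
  if (aec0 == 0) return(zy0)
  ax <- Mod(zx0); ay <- Mod(zy0)
  vax <- if (mix == "power") ax^2 else ax
  vay <- if (mix == "power") ay^2 else ay
  phasor <- zy0 / ay
  cutoff <- max(band_low_hz - 0.5, band_low_hz * 0.75)
  n <- length(zy0)
  bg <- if (is.null(band_high_hz)) NULL else
    band_gain(fft_freqs(n, fs), band_low_hz, band_high_hz, 0.25)
  build <- function(k) {
    a_new <- if (mix == "power") sqrt(pmax(vay + k * vax, 0)) else vay + k * vax
    a_lp <- lowpass_filter(a_new, fs, cutoff)
    z <- project_analytic(a_lp * phasor)
    if (!is.null(bg)) z <- fft(fft(z) * bg, inverse = TRUE) / n
    z
  }
  if (gain == "formula") {
    k <- envelope_mixing_gain(aec0, sd(vay), sd(vax))
    z <- build(k)
  } else {
    target <- aec0
    for (it in seq_len(max(1L, n_calib))) {
      k <- solve_mixing_gain(vax, vay, target)
      z <- build(k)
      va_out <- if (mix == "power") Mod(z)^2 else Mod(z)
      achieved <- suppressWarnings(cor(vax, va_out))
      if (!is.finite(achieved) || abs(achieved - aec0) < calib_tol) break
      target <- target + (aec0 - achieved)
    }
  }
  attr(z, "gain") <- k
  z
}

#' Couple the envelope of one narrow-band signal to another
#'
#' Replaces the amplitude of `y0` with `A_y0 + k * A_x0` (variable chosen by
#' `mix`: squared envelopes by default), keeping the instantaneous phase of
#' `y0`, so that the clean-pair amplitude correlation equals `aec0`. The
#' mixed envelope is low-passed below the band's lower edge and projected
#' back onto an analytic signal before reconstruction, so the Hilbert
#' envelope of the returned real signal reproduces the constructed one.
#'
#' @param x0,y0 real narrow-band signals of equal length, statistically
#'   independent.
#' @param aec0 target coupling in `[0, 1)`; `0` returns `y0` unchanged.
#' @param fs sampling rate (Hz).
#' @param band_low_hz lower band edge (Hz), used for the envelope smoother.
#' @param band_high_hz upper band edge (Hz); when given, the coupled signal
#'   is band-limited back to `[band_low_hz, band_high_hz]`.
#' @param mix `"power"` or `"envelope"` mixing variable.
#' @param gain `"exact"` (solve for the realized correlation) or
#'   `"formula"` (closed-form plug-in gain).
#' @return real vector: the coupled version of `y0`. Attribute `"gain"`
#'   carries the mixing gain used.
#' @export
couple_envelopes <- function(x0, y0, aec0, fs, band_low_hz,
                             band_high_hz = NULL,
                             mix = c("power", "envelope"),
                             gain = c("exact", "formula")) {
  if (length(x0) != length(y0)) stop("length mismatch", call. = FALSE)
  if (aec0 < 0 || aec0 >= 1) stop("aec0 must be in [0, 1)", call. = FALSE)
  if (sd(x0) <= 0 || sd(y0) <= 0)
    stop("inputs must have positive variance", call. = FALSE)
  if (abs(cor(x0, y0)) > 0.2)
    warning("x0 and y0 look correlated; the coupling identity assumes ",
            "independent inputs")
  if (aec0 == 0) return(y0)
  z <- couple_analytic(analytic_signal(x0), analytic_signal(y0), aec0, fs,
                       band_low_hz, band_high_hz, match.arg(mix),
                       match.arg(gain))
  out <- Re(z)
  attr(out, "gain") <- attr(z, "gain")
  out
}

#' Assemble one synthetic measurement pair
#'
#' Draws independent band-limited gaussian connectivity and noise processes,
#' rescales the connectivity processes to the requested SNRs (noise processes
#' have unit std), applies the envelope coupling (`aec0` between the
#' connectivity processes, `aec_noise` between the noise processes), and sums
#' them into the measured pair `x`, `y`. The generating processes are
#' retained so ground-truth noise statistics can be computed.
#'
#' @param config a [simulation_config()].
#' @return object of class `simulated_pair` with elements `x`, `y`, `x0`,
#'   `y0`, `eps_x`, `eps_y` (real series), `analytic` (the corresponding
#'   analytic signals, named `zx`, `zy`, `zx0`, `zy0`, `zex`, `zey`), and
#'   `config`.
#' @export
assemble_pair <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- round(config$fs * config$duration_s)
  lo <- config$band_low_hz; hi <- config$band_high_hz; fs <- config$fs
  seeds <- vapply(c("x0", "y0", "ex", "ey"), function(k)
    derive_seed(config$seed, k), integer(1))
  scale_for <- function(snr) {
    if (is.infinite(snr)) return(1)
    if (config$snr_convention == "measured") {
      if (snr <= 1) stop("measured-convention SNR must exceed 1", call. = FALSE)
      sqrt(snr^2 - 1)
    } else snr
  }
  zx0 <- band_limited_analytic(n, fs, lo, hi, seeds[["x0"]]) * scale_for(config$snr_x)
  zy0 <- band_limited_analytic(n, fs, lo, hi, seeds[["y0"]]) * scale_for(config$snr_y)
  # the coupled process is not re-band-limited: the measured pair is the
  # plain sum of coupled and noise processes, as in the simulation protocol
  if (!config$couple_after_rescale && config$aec0 > 0) {
    sc <- sd(Re(zy0))
    zy0 <- couple_analytic(zx0 / sd(Re(zx0)), zy0 / sc, config$aec0, fs, lo,
                           NULL, config$mix, config$gain)
    zy0 <- zy0 * sc
  } else if (config$aec0 > 0) {
    zy0 <- couple_analytic(zx0, zy0, config$aec0, fs, lo, NULL,
                           config$mix, config$gain)
  }
  noise_free_x <- is.infinite(config$snr_x)
  noise_free_y <- is.infinite(config$snr_y)
  zex <- if (noise_free_x) complex(length.out = n) else
    band_limited_analytic(n, fs, lo, hi, seeds[["ex"]])
  zey <- if (noise_free_y) complex(length.out = n) else
    band_limited_analytic(n, fs, lo, hi, seeds[["ey"]])
  if (config$aec_noise > 0 && !noise_free_x && !noise_free_y)
    zey <- couple_analytic(zex, zey, config$aec_noise, fs, lo, NULL,
                           config$mix, config$gain)
  zx <- zx0 + zex
  zy <- zy0 + zey
  structure(list(
    x = Re(zx), y = Re(zy), x0 = Re(zx0), y0 = Re(zy0),
    eps_x = Re(zex), eps_y = Re(zey),
    analytic = list(zx = zx, zy = zy, zx0 = zx0, zy0 = zy0,
                    zex = zex, zey = zey),
    config = config), class = "simulated_pair")
}

#' @export
print.simulated_pair <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<simulated_pair> %g-%g Hz, %g s @ %g Hz | aec0=%g aec_noise=%g snr=(%g, %g)\n",
    cfg$band_low_hz, cfg$band_high_hz, cfg$duration_s, cfg$fs,
    cfg$aec0, cfg$aec_noise, cfg$snr_x, cfg$snr_y))
  invisible(x)
}
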