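# Frequency-domain signal primitives: zero-phase band filters, the analytic
# signal, and Hilbert envelopes. All filtering is done by direct spectral
# masking with raised-cosine transition edges, which is exactly zero-phase and
# well behaved for the 1 Hz-wide bands used throughout (narrow IIR designs are
# numerically fragile at relative bandwidths of ~1e-3).

# two-sided frequency axis of an n-point DFT (Hz, folded at Nyquist)
fft_freqs <- function(n, fs) {
  f <- (seq_len(n) - 1) * fs / n
  pmin(f, fs - f)
}

# raised-cosine band gain: 1 inside [lo, hi], cosine roll-off over `transition`
band_gain <- function(f, lo, hi, transition) {
  g <- numeric(length(f))
  g[f >= lo & f <= hi] <- 1
  if (transition > 0) {
    left <- f >= lo - transition & f < lo
    g[left] <- 0.5 * (1 + cos(pi * (lo - f[left]) / transition))
    right <- f > hi & f <= hi + transition
    g[right] <- 0.5 * (1 + cos(pi * (f[right] - hi) / transition))
  }
  g
}

#' Zero-phase band-pass filter
#'
#' Filters a real signal by multiplying its spectrum with a raised-cosine
#' band gain. The operation is exactly zero-phase; edge transients are the
#' caller's concern (see [edge_trim_samples()]).
#'
#' @param x real numeric vector.
#' @param fs sampling rate (Hz).
#' @param lo,hi band edges (Hz), `0 < lo < hi < fs/2`.
#' @param transition width of the cosine roll-off on each side (Hz).
#' @return filtered real vector of the same length.
#' @export
bandpass_filter <- function(x, fs, lo, hi, transition = 0.25) {
  check_band(lo, hi, fs)
  n <- length(x)
  if (n < 2L) stop("signal too short to filter", call. = FALSE)
  g <- band_gain(fft_freqs(n, fs), lo, hi, transition)
  Re(fft(fft(x) * g, inverse = TRUE)) / n
}

# zero-phase low-pass by spectral masking (shared by the envelope smoother)
lowpass_filter <- function(x, fs, cutoff, transition = 0.25) {
  n <- length(x)
  f <- fft_freqs(n, fs)
  g <- numeric(n)
  g[f <= cutoff] <- 1
  if (transition > 0) {
    edge <- f > cutoff & f <= cutoff + transition
    g[edge] <- 0.5 * (1 + cos(pi * (f[edge] - cutoff) / transition))
  }
  Re(fft(fft(x) * g, inverse = TRUE)) / n
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' @param x real numeric vector.
#' @return complex vector `z` with `Re(z) == x` and `Im(z)` the Hilbert
#'   transform of `x`; `Mod(z)` is the Hilbert envelope.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2L == 0L) {
    h[n / 2L + 1L] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[2:((n + 1L) / 2L)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

# project a complex series onto the space of analytic signals
# (zero out negative-frequency content)
project_analytic <- function(z) {
  n <- length(z)
  Z <- fft(z)
  half <- if (n %% 2L == 0L) n / 2L + 1L else (n + 1L) / 2L
  if (half + 1L <= n) Z[(half + 1L):n] <- 0
  fft(Z, inverse = TRUE) / n
}

#' Number of samples to drop at each edge after narrow-band filtering
#'
#' The filter transient scales with the inverse bandwidth; `ceiling(3 /
#' bandwidth)` seconds are trimmed at each end.
#'
#' @param bandwidth_hz filter bandwidth (Hz).
#' @param fs sampling rate (Hz).
#' @return integer number of samples.
#' @export
edge_trim_samples <- function(bandwidth_hz, fs) {
  as.integer(ceiling(3 / bandwidth_hz) * fs)
}

#' Narrow-band filterbank decomposition
#'
#' Decomposes every channel of a recording into narrow bands centred at
#' `centers_hz` with full bandwidth `bandwidth_hz` (the spectral connectivity
#' convention used throughout: a 1 Hz band centred at 10 Hz covers
#' 9.5-10.5 Hz).
#'
#' @param rec a [multichannel_recording()].
#' @param centers_hz numeric vector of band centres (Hz).
#' @param bandwidth_hz full bandwidth of each band (Hz).
#' @param trim_edges drop the filter transient at both ends
#'   ([edge_trim_samples()] per edge)?
#' @return list of [band_analytic] objects, one per centre.
#' @export
filterbank <- function(rec, centers_hz, bandwidth_hz = 1, trim_edges = TRUE) {
  stopifnot(inherits(rec, "multichannel_recording"))
  fs <- rec$fs
  bad <- centers_hz[centers_hz - bandwidth_hz / 2 <= 0 |
                    centers_hz + bandwidth_hz / 2 >= fs / 2]
  if (length(bad))
    stop("band centres outside (0, Nyquist): ", paste(bad, collapse = ", "),
         call. = FALSE)
  n <- nrow(rec$data)
  trim <- if (trim_edges) edge_trim_samples(bandwidth_hz, fs) else 0L
  if (n - 2L * trim < 2L)
    stop("recording too short for the filter transient of a ",
         bandwidth_hz, " Hz band", call. = FALSE)
  lapply(centers_hz, function(fc) {
    lo <- fc - bandwidth_hz / 2
    hi <- fc + bandwidth_hz / 2
    g <- band_gain(fft_freqs(n, fs), lo, hi, min(bandwidth_hz / 4, 0.25))
    z <- mvfft(mvfft(rec$data) * g, inverse = TRUE) / n
    # band-limited input => filtered spectrum has no negative-frequency
    # overlap, so the analytic signal is obtained by the same Hilbert mask
    h <- numeric(n)
    h[1L] <- 1
    if (n %% 2L == 0L) { h[n / 2L + 1L] <- 1; h[2:(n / 2L)] <- 2 }
    else h[2:((n + 1L) / 2L)] <- 2
    za <- mvfft(mvfft(Re(z)) * h, inverse = TRUE) / n
    if (trim > 0L) za <- za[(trim + 1L):(n - trim), , drop = FALSE]
    band_analytic(center_hz = fc, bandwidth_hz = bandwidth_hz, fs = fs,
                  analytic = za, channel_labels = rec$channel_labels)
  })
}

#' Per-band analytic container
#'
#' @param center_hz,bandwidth_hz band centre and full bandwidth (Hz).
#' @param fs sampling rate (Hz).
#' @param analytic complex matrix (samples x channels).
#' @param channel_labels character vector.
#' @return object of class `band_analytic` with an `envelope` accessor field.
#' @export
band_analytic <- function(center_hz, bandwidth_hz, fs, analytic,
                          channel_labels = colnames(analytic)) {
  if (is.null(dim(analytic))) analytic <- matrix(analytic, ncol = 1L)
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(ncol(analytic)))
  structure(
    list(center_hz = center_hz, bandwidth_hz = bandwidth_hz, fs = fs,
         analytic = analytic, envelope = Mod(analytic),
         channel_labels = channel_labels),
    class = "band_analytic")
}

#' Analytic signal and Hilbert envelope of a band-filtered recording
#'
#' @param x real numeric vector or samples-x-channels matrix (already
#'   narrow-band).
#' @param fs sampling rate (Hz).
#' @param center_hz,bandwidth_hz metadata carried into the result.
#' @return a [band_analytic] object.
#' @export
analytic_and_envelope <- function(x, fs, center_hz = NA_real_,
                                  bandwidth_hz = NA_real_) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  za <- apply(x, 2L, analytic_signal)
  band_analytic(center_hz, bandwidth_hz, fs, za, colnames(x))
}

#' @export
print.band_analytic <- function(x, ...) {
  cat(sprintf("<band_analytic> %g Hz (bw %g Hz), %d samples x %d channels\n",
              x$center_hz, x$bandwidth_hz, nrow(x$analytic),
              ncol(x$analytic)))
  invisible(x)
}

#' Zero-lag orthogonalization of one signal with respect to another
#'
#' Removes the zero-lag component of `y` along `x` by subtracting the
#' least-squares regression of `Re(y)` on `Re(x)` (the standard leakage
#' correction for instantaneous mixing). Applied to analytic signals the
#' residual stays analytic because the regression coefficient is real.
#'
#' @param x_analytic,y_analytic complex analytic vectors of equal length.
#' @param tol relative tolerance below which the orthogonalized signal is
#'   declared degenerate (total leakage).
#' @return complex analytic vector `y - beta * x`; attribute `"degenerate"`
#'   is `TRUE` when the residual variance is below `tol^2` times the input
#'   variance (e.g. `y == x`), in which case downstream AEC is undefined.
#' @export
orthogonalize_pair <- function(x_analytic, y_analytic, tol = 1e-6) {
  if (length(x_analytic) != length(y_analytic))
    stop("length mismatch", call. = FALSE)
  xr <- Re(x_analytic)
  vx <- var(xr)
  if (vx <= 0 || !is.finite(vx) || vx < .Machine$double.eps)
    stop("x is (numerically) zero: cannot orthogonalize against it",
         call. = FALSE)
  beta <- cov(xr, Re(y_analytic)) / vx
  out <- y_analytic - beta * x_analytic
  vy <- var(Re(y_analytic))
  degen <- var(Re(out)) < tol^2 * max(vy, vx)
  attr(out, "degenerate") <- degen
  out
}
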