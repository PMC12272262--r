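# Amplitude envelope correlation (AEC): Pearson correlation between the
# squared Hilbert envelopes of two narrow-band signals (the squared-envelope
# convention matches the renormalization's correction terms; plain-envelope
# correlation is available as a variant).

#' Amplitude envelope correlation between two envelopes
#'
#' @param envelope_x,envelope_y non-negative real vectors of equal length.
#' @param squared correlate squared envelopes (default) or plain envelopes.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
aec <- function(envelope_x, envelope_y, squared = TRUE) {
  if (length(envelope_x) != length(envelope_y))
    stop("envelopes must have equal length", call. = FALSE)
  if (squared) {
    envelope_x <- envelope_x^2
    envelope_y <- envelope_y^2
  }
  # relative-variation guard: a stochastic narrow-band envelope has a
  # coefficient of variation of order 0.5; an (almost) constant envelope
  # such as a pure tone's carries no amplitude information and would yield
  # numerical-noise correlations
  cv_x <- sd(envelope_x) / max(mean(envelope_x), .Machine$double.xmin)
  cv_y <- sd(envelope_y) / max(mean(envelope_y), .Machine$double.xmin)
  if (!is.finite(cv_x) || !is.finite(cv_y) || cv_x < 1e-6 || cv_y < 1e-6)
    stop("degenerate envelope (near-zero relative variance, e.g. a pure ",
         "tone): AEC undefined", call. = FALSE)
  cor(envelope_x, envelope_y)
}

#' Symmetrized, leakage-corrected AEC for an analytic signal pair
#'
#' Orthogonalizes each signal with respect to the other at zero lag and
#' averages the two directed AEC estimates
#' `AEC(A_x, A_{y perp x})` and `AEC(A_y, A_{x perp y})`.
#'
#' @param x_analytic,y_analytic complex analytic vectors of equal length.
#' @param squared squared-envelope (default) or plain-envelope correlation.
#' @param orthogonalize apply the zero-lag leakage correction (default); when
#'   `FALSE` the plain AEC of the two envelopes is returned.
#' @return symmetrized AEC; `NA` with a warning when orthogonalization
#'   degenerates (e.g. `y == x`: pure leakage leaves nothing to correlate).
#' @export
aec_symmetrized <- function(x_analytic, y_analytic, squared = TRUE,
                            orthogonalize = TRUE) {
  if (!orthogonalize)
    return(aec(Mod(x_analytic), Mod(y_analytic), squared = squared))
  y_perp <- orthogonalize_pair(x_analytic, y_analytic)
  x_perp <- orthogonalize_pair(y_analytic, x_analytic)
  if (isTRUE(attr(y_perp, "degenerate")) ||
      isTRUE(attr(x_perp, "degenerate"))) {
    warning("orthogonalization degenerate (total zero-lag leakage): ",
            "AEC undefined for this pair")
    return(NA_real_)
  }
  (aec(Mod(x_analytic), Mod(y_perp), squared = squared) +
   aec(Mod(y_analytic), Mod(x_perp), squared = squared)) / 2
}

#' Spectrally resolved AEC for one channel pair
#'
#' @param rec a [multichannel_recording()].
#' @param pair character vector of two channel labels (or two indices).
#' @param centers_hz band centres (Hz).
#' @param bandwidth_hz full bandwidth (Hz).
#' @param squared,orthogonalize passed to [aec_symmetrized()].
#' @return data frame of class `connectivity_spectrum` with columns
#'   `pair_a`, `pair_b`, `center_hz`, `variant`, `aec`. Bands whose AEC is
#'   undefined (degenerate envelope or total leakage) carry `NA`, never a
#'   silent zero.
#' @export
connectivity_spectrum <- function(rec, pair, centers_hz, bandwidth_hz = 1,
                                  squared = TRUE, orthogonalize = TRUE) {
  stopifnot(inherits(rec, "multichannel_recording"))
  idx <- match_pair(rec, pair)
  bands <- filterbank(rec, centers_hz, bandwidth_hz)
  vals <- vapply(bands, function(b) {
    tryCatch(
      aec_symmetrized(b$analytic[, idx[1L]], b$analytic[, idx[2L]],
                      squared = squared, orthogonalize = orthogonalize),
      error = function(e) NA_real_, warning = function(w) NA_real_)
  }, numeric(1))
  structure(data.frame(
    pair_a = rec$channel_labels[idx[1L]], pair_b = rec$channel_labels[idx[2L]],
    center_hz = centers_hz, variant = "raw", aec = vals,
    stringsAsFactors = FALSE),
    class = c("connectivity_spectrum", "data.frame"))
}

match_pair <- function(rec, pair) {
  if (is.numeric(pair)) {
    idx <- as.integer(pair)
  } else {
    idx <- match(pair, rec$channel_labels)
  }
  if (length(idx) != 2L || anyNA(idx) || any(idx < 1L) ||
      any(idx > ncol(rec$data)))
    stop("unknown channel label(s): ",
         paste(pair[is.na(match(pair, rec$channel_labels))], collapse = ", "),
         call. = FALSE)
  if (idx[1L] == idx[2L]) stop("pair must name two distinct channels",
                               call. = FALSE)
  idx
}

#' Spectrally resolved AEC for every channel pair
#'
#' @inheritParams connectivity_spectrum
#' @return data frame with one row per unordered pair and band (diagonal
#'   excluded); values are invariant to channel ordering.
#' @export
connectome_spectra <- function(rec, centers_hz, bandwidth_hz = 1,
                               squared = TRUE, orthogonalize = TRUE) {
  stopifnot(inherits(rec, "multichannel_recording"))
  nc <- ncol(rec$data)
  if (nc < 2L) stop("need at least 2 channels", call. = FALSE)
  bands <- filterbank(rec, centers_hz, bandwidth_hz)
  out <- list()
  for (i in seq_len(nc - 1L)) for (j in (i + 1L):nc) {
    vals <- vapply(bands, function(b) {
      tryCatch(
        aec_symmetrized(b$analytic[, i], b$analytic[, j],
                        squared = squared, orthogonalize = orthogonalize),
        error = function(e) NA_real_, warning = function(w) NA_real_)
    }, numeric(1))
    out[[length(out) + 1L]] <- data.frame(
      pair_a = rec$channel_labels[i], pair_b = rec$channel_labels[j],
      center_hz = centers_hz, variant = "raw", aec = vals,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Root-mean-square norm of a connectivity spectrum
#'
#' Summary used to quantify how flat/small a spectrum is; non-negative and
#' zero iff the spectrum is identically zero.
#'
#' @param aec_values numeric vector (NAs dropped).
#' @return scalar RMS.
#' @export
spectrum_norm <- function(aec_values) {
  v <- aec_values[!is.na(aec_values)]
  if (!length(v)) return(NA_real_)
  sqrt(mean(v^2))
}
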