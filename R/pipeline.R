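# End-to-end pipeline (filterbank -> AEC -> burst segmentation -> noise
# statistics -> renormalization) and programmatic fixture scenarios.

#' Generate a named fixture scenario
#'
#' Deterministic synthetic datasets exercising the pipeline:
#' \describe{
#'   \item{`fig1_cell`}{a coupled pair (aec0 = 0.5, SNR 2/2, 8-12 Hz) plus
#'     the matching noise-only recording.}
#'   \item{`burst_gated`}{two channels whose coupling exists only inside
#'     coincident high-amplitude bursts riding on independent alpha-band
#'     backgrounds; non-bursting AEC should be flat near zero.}
#'   \item{`uncoupled`}{three mutually independent narrow-band channels.}
#' }
#'
#' @param scenario scenario name.
#' @param master_seed integer seed; identical inputs give identical files.
#' @param dir optional output directory; when given, the recording(s) are
#'   written as delimited text and the manifest as JSON.
#' @param fs,duration_s sampling rate and duration of the fixture.
#' @return list with `recording`, optional `noise_recording`, and `manifest`
#'   (ground-truth description: couplings, band, seeds, burst mask when
#'   applicable).
#' @export
fixture_generator <- function(scenario, master_seed = 1L, dir = NULL,
                              fs = 250, duration_s = 120) {
  scenarios <- c("fig1_cell", "burst_gated", "uncoupled")
  if (!scenario %in% scenarios)
    stop("unknown scenario '", scenario, "'; available: ",
         paste(scenarios, collapse = ", "), call. = FALSE)
  n <- round(fs * duration_s)
  out <- switch(scenario,
    fig1_cell = {
      cfg <- simulation_config(band_low_hz = 8, band_high_hz = 12, fs = fs,
                               duration_s = duration_s, aec0 = 0.5,
                               snr_x = 2, snr_y = 2,
                               seed = derive_seed(master_seed, "fig1_cell"))
      p <- assemble_pair(cfg)
      list(
        recording = multichannel_recording(cbind(x = p$x, y = p$y), fs),
        noise_recording = multichannel_recording(
          cbind(x = p$eps_x, y = p$eps_y), fs),
        manifest = list(scenario = scenario, fs = fs,
                        duration_s = duration_s, band_hz = c(8, 12),
                        aec0 = 0.5, snr = c(2, 2), seed = master_seed))
    },
    burst_gated = {
      s <- function(k) derive_seed(master_seed, paste0("bg", k))
      bgx <- gen_band_limited_gaussian(8, 12, fs, duration_s, s(1))
      bgy <- gen_band_limited_gaussian(8, 12, fs, duration_s, s(2))
      bx <- gen_band_limited_gaussian(8, 12, fs, duration_s, s(3))
      by0 <- gen_band_limited_gaussian(8, 12, fs, duration_s, s(4))
      by <- couple_envelopes(bx, by0, 0.6, fs, 8, 12)
      # coincident bursts: two-state Markov mask, mean dwell ~1 s
      mask <- with_seed(s(5), {
        p_switch <- 1 / fs       # ~1 s expected dwell per state
        st <- logical(n)
        st[1] <- FALSE
        flips <- runif(n) < p_switch
        for (t in 2:n) st[t] <- if (flips[t]) !st[t - 1] else st[t - 1]
        st
      })
      # crisp gate with short cosine ramps (~0.1 s) to limit spectral splatter
      ramp <- 0.5 * (1 - cos(pi * seq_len(round(0.1 * fs)) /
                               (round(0.1 * fs) + 1)))
      kern <- c(ramp, rev(ramp))
      kern <- kern / sum(kern)
      gate <- stats::filter(as.numeric(mask), kern, sides = 2L)
      gate[is.na(gate)] <- 0
      gate <- pmin(pmax(as.numeric(gate), 0), 1)
      x <- bgx + 3 * gate * bx
      y <- bgy + 3 * gate * by
      list(
        recording = multichannel_recording(cbind(x = x, y = y), fs),
        manifest = list(scenario = scenario, fs = fs,
                        duration_s = duration_s, band_hz = c(8, 12),
                        aec0_burst = 0.6, burst_amplitude = 3,
                        burst_fraction = mean(mask), seed = master_seed))
    },
    uncoupled = {
      d <- vapply(1:3, function(k)
        gen_band_limited_gaussian(8, 12, fs, duration_s,
                                  derive_seed(master_seed, paste0("u", k))),
        numeric(n))
      colnames(d) <- c("a", "b", "c")
      list(recording = multichannel_recording(d, fs),
           manifest = list(scenario = scenario, fs = fs,
                           duration_s = duration_s, band_hz = c(8, 12),
                           aec0 = 0, seed = master_seed))
    })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_recording(out$recording, file.path(dir, paste0(scenario, ".csv")))
    if (!is.null(out$noise_recording))
      write_recording(out$noise_recording,
                      file.path(dir, paste0(scenario, "_noise.csv")))
    if (requireNamespace("jsonlite", quietly = TRUE))
      jsonlite::write_json(out$manifest,
                           file.path(dir, paste0(scenario, "_manifest.json")),
                           auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Full connectivity pipeline with power-bias correction
#'
#' Runs, for every requested pair and band: spectral decomposition, zero-lag
#' orthogonalization, symmetrized raw AEC; per-node burst segmentation and
#' the non-bursting AEC; renormalized AEC with noise statistics from
#' coincident non-bursting periods; and, when a separate noise recording is
#' given, renormalized AEC with measurement-noise statistics.
#'
#' @param rec a [multichannel_recording()].
#' @param centers_hz,bandwidth_hz filterbank parameters.
#' @param pairs 2-column matrix/data.frame of channel labels, or `NULL` for
#'   all pairs.
#' @param noise_rec optional noise recording (same layout).
#' @param segment run the burst HMM and produce `non_bursting` /
#'   `renorm_nonburst` variants (default `TRUE`).
#' @param orthogonalize apply the zero-lag leakage correction.
#' @param master_seed seed for HMM restarts.
#' @param min_noise_seconds minimum duration of coincident non-bursting data
#'   per pair and band.
#' @return tidy data frame: `pair_a`, `pair_b`, `center_hz`, `variant`
#'   (`raw`, `non_bursting`, `renorm_nonburst`, `renorm_noise`), `aec`,
#'   `conditioned`, `n_samples`. Bands whose estimate is undefined carry
#'   `NA` and `conditioned = FALSE`, never silent zeros.
#' @export
end_to_end_pipeline <- function(rec, centers_hz, bandwidth_hz = 1,
                                pairs = NULL, noise_rec = NULL,
                                segment = TRUE, orthogonalize = TRUE,
                                master_seed = 1L, min_noise_seconds = 10) {
  stopifnot(inherits(rec, "multichannel_recording"))
  labels <- rec$channel_labels
  if (is.null(pairs)) {
    pairs <- t(combn(labels, 2L))
  } else {
    pairs <- as.matrix(pairs)
  }
  bands <- filterbank(rec, centers_hz, bandwidth_hz)
  noise_bands <- if (!is.null(noise_rec)) {
    if (!identical(noise_rec$channel_labels, labels) ||
        !isTRUE(all.equal(noise_rec$fs, rec$fs)))
      stop("noise recording layout does not match", call. = FALSE)
    filterbank(noise_rec, centers_hz, bandwidth_hz)
  } else NULL
  min_noise_samples <- max(2L, round(min_noise_seconds * rec$fs))
  rows <- list()
  emit <- function(a, b, fc, variant, value, conditioned, n) {
    rows[[length(rows) + 1L]] <<- data.frame(
      pair_a = a, pair_b = b, center_hz = fc, variant = variant,
      aec = value, conditioned = conditioned, n_samples = n,
      stringsAsFactors = FALSE)
  }
  for (bi in seq_along(bands)) {
    b <- bands[[bi]]
    fc <- b$center_hz
    # per-channel burst segmentation, cached per band
    segs <- if (segment) lapply(seq_along(labels), function(ci) {
      tryCatch(
        viterbi(b$envelope[, ci],
                fit_two_state_hmm(b$envelope[, ci],
                                  seed = derive_seed(master_seed,
                                                     sprintf("hmm_%d_%d", bi, ci)))),
        error = function(e) NULL)
    }) else NULL
    for (pi in seq_len(nrow(pairs))) {
      ij <- match(pairs[pi, ], labels)
      a_lab <- pairs[pi, 1L]; b_lab <- pairs[pi, 2L]
      zx <- b$analytic[, ij[1L]]; zy <- b$analytic[, ij[2L]]
      directed <- tryCatch({
        if (orthogonalize) {
          yp <- orthogonalize_pair(zx, zy)
          xp <- orthogonalize_pair(zy, zx)
          if (isTRUE(attr(yp, "degenerate")) || isTRUE(attr(xp, "degenerate")))
            stop("degenerate orthogonalization")
          list(list(zx, yp), list(zy, xp))
        } else list(list(zx, zy), list(zy, zx))
      }, error = function(e) NULL)
      if (is.null(directed)) {
        for (v in c("raw", if (segment) c("non_bursting", "renorm_nonburst"),
                    if (!is.null(noise_bands)) "renorm_noise"))
          emit(a_lab, b_lab, fc, v, NA_real_, FALSE, NA_integer_)
        next
      }
      raw_dir <- vapply(directed, function(d)
        tryCatch(aec(Mod(d[[1L]]), Mod(d[[2L]])), error = function(e) NA_real_),
        numeric(1))
      emit(a_lab, b_lab, fc, "raw", mean(raw_dir), !anyNA(raw_dir),
           length(zx))
      if (segment) {
        seg_ok <- !is.null(segs[[ij[1L]]]) && !is.null(segs[[ij[2L]]])
        nb <- if (seg_ok) tryCatch(
          coincident_nonburst_mask(segs[[ij[1L]]], segs[[ij[2L]]],
                                   min_samples = min_noise_samples),
          error = function(e) NULL) else NULL
        if (is.null(nb)) {
          emit(a_lab, b_lab, fc, "non_bursting", NA_real_, FALSE, NA_integer_)
          emit(a_lab, b_lab, fc, "renorm_nonburst", NA_real_, FALSE,
               NA_integer_)
        } else {
          nb_dir <- vapply(directed, function(d)
            tryCatch(aec(Mod(d[[1L]][nb]), Mod(d[[2L]][nb])),
                     error = function(e) NA_real_), numeric(1))
          emit(a_lab, b_lab, fc, "non_bursting", mean(nb_dir), !anyNA(nb_dir),
               sum(nb))
          ren_dir <- vapply(seq_along(directed), function(k) {
            d <- directed[[k]]
            if (is.na(raw_dir[k])) return(NA_real_)
            st <- nonburst_noise_statistics(d[[1L]], d[[2L]], nb)
            aec_renormalized(raw_dir[k], st)$value
          }, numeric(1))
          emit(a_lab, b_lab, fc, "renorm_nonburst", mean(ren_dir),
               !anyNA(ren_dir), sum(nb))
        }
      }
      if (!is.null(noise_bands)) {
        nzb <- noise_bands[[bi]]
        znx <- nzb$analytic[, ij[1L]]; zny <- nzb$analytic[, ij[2L]]
        ren_dir <- vapply(seq_along(directed), function(k) {
          d <- directed[[k]]
          if (is.na(raw_dir[k])) return(NA_real_)
          nz <- if (k == 1L) list(znx, if (orthogonalize)
            orthogonalize_pair(znx, zny) else zny)
          else list(zny, if (orthogonalize)
            orthogonalize_pair(zny, znx) else znx)
          st <- renorm_stats_from_analytic(d[[1L]], d[[2L]], nz[[1L]], nz[[2L]])
          aec_renormalized(raw_dir[k], st)$value
        }, numeric(1))
        emit(a_lab, b_lab, fc, "renorm_noise", mean(ren_dir), !anyNA(ren_dir),
             nrow(nzb$analytic))
      }
    }
  }
  do.call(rbind, rows)
}

#' @importFrom utils combn
NULL
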