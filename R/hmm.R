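# Cerebral background-noise model: per node and band, a two-state gaussian
# HMM on the Hilbert envelope separates transient high-amplitude bursts from
# sustained low-amplitude (non-bursting) activity. Statistics of the
# background-noise processes are then estimated from coincident non-bursting
# periods of the two signals.

#' Fit a two-state gaussian HMM to an envelope
#'
#' Standard Baum-Welch EM on the 1-D amplitude series, best of `n_init`
#' restarts by log-likelihood, deterministic given `seed`.
#'
#' @param envelope non-negative real vector (length >= `min_samples`).
#' @param seed RNG seed for the restarts.
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param max_iter maximum EM iterations per restart.
#' @param n_init number of restarts.
#' @param min_samples minimum accepted envelope length.
#' @return object of class `two_state_hmm` with elements `means`, `stds`,
#'   `transition` (2 x 2, row-stochastic), `initial`, `loglik_trace`
#'   (non-decreasing), `converged`.
#' @export
fit_two_state_hmm <- function(envelope, seed = 1L, tol = 1e-6,
                              max_iter = 100L, n_init = 5L,
                              min_samples = 50L) {
  x <- as.numeric(envelope)
  if (length(x) < min_samples)
    stop("envelope too short (< ", min_samples, " samples)", call. = FALSE)
  sx <- sd(x)
  if (!is.finite(sx) || sx <= 0)
    stop(degenerate_fit_error("constant envelope: no amplitude states"))
  best <- NULL
  for (i in seq_len(n_init)) {
    fit <- with_seed(derive_seed(seed, paste0("hmm_init", i)), {
      q <- quantile(x, c(0.25, 0.75))
      means <- as.numeric(q) + rnorm(2L, 0, 0.1 * sx)
      em_two_state(x, means, c(sx, sx) / 2, tol, max_iter)
    })
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (abs(diff(best$means)) < 0.05 * sx)
    stop(degenerate_fit_error(
      "state collapse: emission means closer than 0.05 sd(envelope); ",
      "the envelope shows a single amplitude regime"))
  structure(list(
    means = best$means, stds = best$stds, transition = best$transition,
    initial = best$initial, loglik_trace = best$trace,
    converged = best$converged), class = "two_state_hmm")
}

degenerate_fit_error <- function(...) {
  structure(class = c("aecren_degenerate_fit", "error", "condition"),
            list(message = paste0(...), call = NULL))
}

em_two_state <- function(x, means, stds, tol, max_iter) {
  n <- length(x)
  trans <- matrix(c(0.95, 0.05, 0.05, 0.95), 2L)
  init <- c(0.5, 0.5)
  floor_sd <- 1e-4 * sd(x)
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    e <- hmm_forward_backward(x, means, stds, trans, init)
    trace <- c(trace, e$loglik)
    g <- e$gamma
    w <- colSums(g)
    means <- as.numeric(crossprod(g, x)) / w
    stds <- pmax(sqrt(colSums(g * (outer(x, means, "-"))^2) / w), floor_sd)
    trans <- e$xi / rowSums(e$xi)
    init <- g[1L, ]
    if (is.finite(prev) && e$loglik - prev < tol) { converged <- TRUE; break }
    prev <- e$loglik
  }
  list(means = means, stds = stds, transition = trans, initial = init,
       loglik = trace[length(trace)], trace = trace, converged = converged)
}

#' @export
print.two_state_hmm <- function(x, ...) {
  cat(sprintf("<two_state_hmm> means = (%.3g, %.3g), stds = (%.3g, %.3g)\n",
              x$means[1], x$means[2], x$stds[1], x$stds[2]))
  cat(sprintf("  stay probabilities: %.3f / %.3f | loglik %.2f (%d iters)\n",
              x$transition[1, 1], x$transition[2, 2],
              x$loglik_trace[length(x$loglik_trace)], length(x$loglik_trace)))
  invisible(x)
}

#' Viterbi state decoding of an envelope
#'
#' Maximum-probability state path under a fitted HMM; the non-bursting state
#' is the one with the lowest emission mean. Ties in the path recursion are
#' broken toward the lower state index.
#'
#' @param envelope real vector.
#' @param hmm a fitted [fit_two_state_hmm()] model (or a list with `means`,
#'   `stds`, `transition`, `initial`).
#' @return object of class `state_segmentation`: `labels` (1-based state
#'   indices), `nonbursting_state`, `mask_nonburst` (logical).
#' @export
viterbi <- function(envelope, hmm) {
  path <- hmm_viterbi(as.numeric(envelope), hmm$means, hmm$stds,
                      hmm$transition, hmm$initial)
  nb <- which.min(hmm$means)
  structure(list(labels = path, nonbursting_state = nb,
                 mask_nonburst = path == nb),
            class = "state_segmentation")
}

#' Coincident non-bursting mask of two segmentations
#'
#' @param seg_x,seg_y [state_segmentation][viterbi()] objects (or logical
#'   masks) of equal length.
#' @param min_samples minimum number of retained samples (default 2; pass
#'   `10 * fs` to enforce the 10-second minimum used for noise statistics).
#' @return logical mask (AND of the two non-bursting masks) with attribute
#'   `"n_retained"`.
#' @export
coincident_nonburst_mask <- function(seg_x, seg_y, min_samples = 2L) {
  mx <- if (inherits(seg_x, "state_segmentation")) seg_x$mask_nonburst else as.logical(seg_x)
  my <- if (inherits(seg_y, "state_segmentation")) seg_y$mask_nonburst else as.logical(seg_y)
  if (length(mx) != length(my)) stop("mask length mismatch", call. = FALSE)
  m <- mx & my
  if (sum(m) < min_samples)
    stop(structure(class = c("aecren_insufficient_noise_data", "error",
                             "condition"),
                   list(message = sprintf(
                     "only %d coincident non-bursting samples (< %d): too few for noise statistics",
                     sum(m), as.integer(min_samples)), call = NULL)))
  attr(m, "n_retained") <- sum(m)
  m
}

#' Noise statistics from coincident non-bursting periods
#'
#' Treats the measured signals during coincident non-bursting periods as
#' observations of the background-noise processes and computes every moment
#' the renormalization needs: noise envelope moments and covariances over
#' the masked samples, signal moments over all samples.
#'
#' @param x_analytic,y_analytic complex analytic vectors (same band).
#' @param mask logical vector from [coincident_nonburst_mask()].
#' @return a [renorm_stats()] bundle with `n_samples_used = sum(mask)`.
#' @export
nonburst_noise_statistics <- function(x_analytic, y_analytic, mask) {
  if (length(mask) != length(x_analytic))
    stop("mask length mismatch", call. = FALSE)
  ax2 <- Mod(x_analytic)^2; ay2 <- Mod(y_analytic)^2
  xm <- x_analytic[mask]; ym <- y_analytic[mask]
  renorm_stats(
    mean_sq_env_x = mean(ax2), std_sq_env_x = sd(ax2),
    mean_sq_env_y = mean(ay2), std_sq_env_y = sd(ay2),
    cov_xy = cov(Re(x_analytic), Re(y_analytic)),
    cov_x_hy = cov(Re(x_analytic), Im(y_analytic)),
    noise_mean_sq_env_x = mean(Mod(xm)^2),
    noise_std_sq_env_x = sd(Mod(xm)^2),
    noise_mean_sq_env_y = mean(Mod(ym)^2),
    noise_std_sq_env_y = sd(Mod(ym)^2),
    noise_cov_sq_env = cov(Mod(xm)^2, Mod(ym)^2),
    noise_cov = cov(Re(xm), Re(ym)),
    noise_cov_h = cov(Re(xm), Im(ym)),
    n_samples_used = sum(mask))
}

#' Noise statistics from a separate noise recording
#'
#' The measurement-noise analogue of the background-noise model: all noise
#' moments are taken from a separate recording of the same channel layout
#' (e.g. an empty-room measurement), processed with the same filterbank.
#'
#' @param noise_rec a [multichannel_recording()].
#' @param centers_hz,bandwidth_hz filterbank parameters.
#' @param match_rec optional subject recording; layout (labels and sampling
#'   rate) must agree.
#' @return list with one element per band: `center_hz`, per-channel
#'   `mean_sq_env`, `std_sq_env`, `sigma`, and channel x channel matrices
#'   `cov_sq_env`, `cov`, `cov_h` (the `cov(eps_i, H eps_j)` analogue), plus
#'   `n_samples`.
#' @export
measurement_noise_statistics <- function(noise_rec, centers_hz,
                                         bandwidth_hz = 1,
                                         match_rec = NULL) {
  stopifnot(inherits(noise_rec, "multichannel_recording"))
  if (!is.null(match_rec)) {
    if (!identical(match_rec$channel_labels, noise_rec$channel_labels) ||
        !isTRUE(all.equal(match_rec$fs, noise_rec$fs)))
      stop("noise recording layout (channels/fs) does not match the subject recording",
           call. = FALSE)
  }
  bands <- filterbank(noise_rec, centers_hz, bandwidth_hz)
  lapply(bands, function(b) {
    a2 <- Mod(b$analytic)^2
    list(center_hz = b$center_hz,
         mean_sq_env = colMeans(a2),
         std_sq_env = apply(a2, 2L, sd),
         sigma = apply(Re(b$analytic), 2L, sd),
         cov_sq_env = cov(a2),
         cov = cov(Re(b$analytic)),
         cov_h = cov(Re(b$analytic), Im(b$analytic)),
         n_samples = nrow(a2))
  })
}
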