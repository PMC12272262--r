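# Power-bias correction by renormalization: the corrected amplitude
# correlation is
#
#   AEC_ren = [ AEC - cov(Ae_x^2, Ae_y^2) / (sd(A_x^2) sd(A_y^2))
#                   - (L(x, y) + L(x, Hy)) / (sd(A_x^2) sd(A_y^2)) ]
#             / [ sqrt(1 - SNR_x,ampl^-2) * sqrt(1 - SNR_y,ampl^-2) ]
#
# where Ae are background-noise envelopes, L(x, y) = 8 [cov(x,y) cov(ex,ey)
# - cov(ex,ey)^2] corrects residual linear (zero-lag) synchronization, H is
# the Hilbert transform, and SNR_ampl is the amplitude-specific
# signal-to-noise ratio below. The denominator factor equals the ratio of
# clean to measured squared-envelope standard deviations whenever the noise
# is independent of the signal with uniformly distributed phases, which is
# what makes the correction exact in population.

#' Plain signal-to-noise ratio
#'
#' @param sigma_x std of the measured signal.
#' @param sigma_eps std of the background-noise process.
#' @return `sigma_x / sigma_eps`; `Inf` when `sigma_eps == 0` (noise-free).
#' @export
snr_plain <- function(sigma_x, sigma_eps) {
  stopifnot_scalar(sigma_x, "sigma_x", positive = TRUE)
  if (sigma_eps < 0) stop("sigma_eps must be >= 0", call. = FALSE)
  if (sigma_eps == 0) return(Inf)
  sigma_x / sigma_eps
}

#' Amplitude-specific signal-to-noise ratio
#'
#' `SNR_ampl = sd(A_x^2) / sqrt(sd(Ae_x^2)^2 + 2 <A_x^2><Ae_x^2> -
#' 2 <Ae_x^2>^2)`. The radicand equals `var(A_x^2) - var(A_x0^2)` for
#' independent signal and noise, so `sqrt(1 - SNR_ampl^-2)` is the
#' clean-to-measured ratio of squared-envelope standard deviations (for a
#' gaussian signal this reduces to `1 - sigma_eps^2 / sigma_x^2`, using the
#' exponential squared-envelope moments `<A^2> = 2 sigma^2`, `var(A^2) = 4
#' sigma^4`).
#'
#' @param std_sq_env std of the measured squared envelope `A_x^2`.
#' @param mean_sq_env mean of the measured squared envelope.
#' @param noise_std_sq_env,noise_mean_sq_env the same moments for the
#'   background-noise envelope.
#' @return scalar > 1 in the well-conditioned regime; `Inf` when the noise
#'   moments vanish.
#' @export
snr_ampl <- function(std_sq_env, mean_sq_env, noise_std_sq_env,
                     noise_mean_sq_env) {
  stopifnot_scalar(std_sq_env, "std_sq_env", positive = TRUE)
  if (noise_std_sq_env == 0 && noise_mean_sq_env == 0) return(Inf)
  rad <- noise_std_sq_env^2 + 2 * mean_sq_env * noise_mean_sq_env -
    2 * noise_mean_sq_env^2
  if (rad <= 0)
    stop(ill_conditioned_error(
      "amplitude SNR radicand <= 0: noise dominates the amplitude moments"))
  std_sq_env / sqrt(rad)
}

ill_conditioned_error <- function(msg) {
  structure(class = c("aecren_ill_conditioned", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Linear-synchronization correction term
#'
#' `L(x, y) = 8 [cov(x, y) cov(eps_x, eps_y) - cov(eps_x, eps_y)^2]`.
#'
#' @param cov_xy zero-lag covariance of the measured signals.
#' @param cov_eps zero-lag covariance of the noise processes.
#' @return scalar.
#' @export
lin_sync <- function(cov_xy, cov_eps) {
  stopifnot_scalar(cov_xy, "cov_xy")
  stopifnot_scalar(cov_eps, "cov_eps")
  8 * (cov_xy * cov_eps - cov_eps^2)
}

#' Bundle of moments required by the renormalization
#'
#' All temporal averages are plain sample moments. `x`/`y` moments refer to
#' the measured signals; `noise_*` to the background-noise model
#' (ground-truth simulated noise, a separate noise recording, or coincident
#' non-bursting periods).
#'
#' @param mean_sq_env_x,std_sq_env_x,mean_sq_env_y,std_sq_env_y moments of
#'   the measured squared envelopes.
#' @param cov_xy,cov_x_hy covariances `cov(x, y)` and `cov(x, H y)`.
#' @param noise_mean_sq_env_x,noise_std_sq_env_x,noise_mean_sq_env_y,noise_std_sq_env_y
#'   squared-envelope moments of the noise processes.
#' @param noise_cov_sq_env `cov(Ae_x^2, Ae_y^2)`.
#' @param noise_cov,noise_cov_h `cov(eps_x, eps_y)` and `cov(eps_x, H eps_y)`.
#' @param n_samples_used number of samples behind the noise moments.
#' @return object of class `renorm_stats`.
#' @export
renorm_stats <- function(mean_sq_env_x, std_sq_env_x,
                         mean_sq_env_y, std_sq_env_y,
                         cov_xy, cov_x_hy,
                         noise_mean_sq_env_x, noise_std_sq_env_x,
                         noise_mean_sq_env_y, noise_std_sq_env_y,
                         noise_cov_sq_env, noise_cov, noise_cov_h,
                         n_samples_used = NA_integer_) {
  if (noise_mean_sq_env_x < 0 || noise_mean_sq_env_y < 0 ||
      noise_std_sq_env_x < 0 || noise_std_sq_env_y < 0)
    stop("noise envelope moments must be non-negative", call. = FALSE)
  cs <- noise_std_sq_env_x * noise_std_sq_env_y
  if (cs > 0 && abs(noise_cov_sq_env) > cs * (1 + 1e-8))
    stop("noise_cov_sq_env violates the Cauchy-Schwarz bound", call. = FALSE)
  structure(list(
    mean_sq_env_x = mean_sq_env_x, std_sq_env_x = std_sq_env_x,
    mean_sq_env_y = mean_sq_env_y, std_sq_env_y = std_sq_env_y,
    cov_xy = cov_xy, cov_x_hy = cov_x_hy,
    noise_mean_sq_env_x = noise_mean_sq_env_x,
    noise_std_sq_env_x = noise_std_sq_env_x,
    noise_mean_sq_env_y = noise_mean_sq_env_y,
    noise_std_sq_env_y = noise_std_sq_env_y,
    noise_cov_sq_env = noise_cov_sq_env, noise_cov = noise_cov,
    noise_cov_h = noise_cov_h, n_samples_used = n_samples_used),
    class = "renorm_stats")
}

# moments from analytic signal + analytic noise-process pairs
renorm_stats_from_analytic <- function(zx, zy, zex, zey) {
  ax2 <- Mod(zx)^2; ay2 <- Mod(zy)^2
  aex2 <- Mod(zex)^2; aey2 <- Mod(zey)^2
  renorm_stats(
    mean_sq_env_x = mean(ax2), std_sq_env_x = sd(ax2),
    mean_sq_env_y = mean(ay2), std_sq_env_y = sd(ay2),
    cov_xy = cov(Re(zx), Re(zy)), cov_x_hy = cov(Re(zx), Im(zy)),
    noise_mean_sq_env_x = mean(aex2), noise_std_sq_env_x = sd(aex2),
    noise_mean_sq_env_y = mean(aey2), noise_std_sq_env_y = sd(aey2),
    noise_cov_sq_env = cov(aex2, aey2),
    noise_cov = cov(Re(zex), Re(zey)),
    noise_cov_h = cov(Re(zex), Im(zey)),
    n_samples_used = length(zex))
}

#' Renormalized (power-bias-corrected) amplitude envelope correlation
#'
#' @param aec raw AEC estimate (Pearson correlation of the measured squared
#'   envelopes) for the directed pair.
#' @param stats a [renorm_stats()] bundle.
#' @param tol ill-conditioning tolerance: both amplitude SNRs must exceed
#'   `1 + tol`.
#' @return list with `value` (the corrected AEC, `NA` when ill-conditioned),
#'   `conditioned` (logical), `snr_ampl_x`, `snr_ampl_y`, and `denominator`.
#' @export
aec_renormalized <- function(aec, stats, tol = 1e-6) {
  stopifnot(inherits(stats, "renorm_stats"))
  out <- list(value = NA_real_, conditioned = FALSE,
              snr_ampl_x = NA_real_, snr_ampl_y = NA_real_,
              denominator = NA_real_)
  sx <- try(snr_ampl(stats$std_sq_env_x, stats$mean_sq_env_x,
                     stats$noise_std_sq_env_x, stats$noise_mean_sq_env_x),
            silent = TRUE)
  sy <- try(snr_ampl(stats$std_sq_env_y, stats$mean_sq_env_y,
                     stats$noise_std_sq_env_y, stats$noise_mean_sq_env_y),
            silent = TRUE)
  if (inherits(sx, "try-error") || inherits(sy, "try-error"))
    return(out)
  out$snr_ampl_x <- sx
  out$snr_ampl_y <- sy
  if (sx <= 1 + tol || sy <= 1 + tol) return(out)
  fx <- if (is.infinite(sx)) 1 else sqrt(1 - sx^-2)
  fy <- if (is.infinite(sy)) 1 else sqrt(1 - sy^-2)
  den <- fx * fy
  ss <- stats$std_sq_env_x * stats$std_sq_env_y
  L <- lin_sync(stats$cov_xy, stats$noise_cov) +
    lin_sync(stats$cov_x_hy, stats$noise_cov_h)
  num <- aec - stats$noise_cov_sq_env / ss - L / ss
  out$value <- num / den
  out$denominator <- den
  out$conditioned <- TRUE
  out
}

#' Power bias measure (PBM)
#'
#' Global percentage deviation between a connectivity spectrum and a
#' reference spectrum. Default aggregation is the root-mean-square of the
#' difference divided by the root-mean-square of the reference, times 100;
#' `method = "mean"` averages per-bin relative differences instead.
#'
#' @param spectrum,reference equal-length numeric vectors (a single value
#'   each for one-band experiments).
#' @param method `"rms"` (default) or `"mean"`.
#' @return non-negative percentage.
#' @export
pbm <- function(spectrum, reference, method = c("rms", "mean")) {
  method <- match.arg(method)
  if (length(spectrum) != length(reference))
    stop("spectrum and reference must have equal length", call. = FALSE)
  if (sqrt(mean(reference^2)) == 0)
    stop("reference spectrum is identically zero", call. = FALSE)
  if (method == "rms") {
    100 * sqrt(mean((spectrum - reference)^2)) / sqrt(mean(reference^2))
  } else {
    nz <- reference != 0
    if (!any(nz)) stop("reference spectrum is identically zero", call. = FALSE)
    100 * mean(abs(spectrum[nz] - reference[nz]) / abs(reference[nz]))
  }
}

#' Model nonlinearity of the power-bias slope
#'
#' The slope of estimated AEC against true coupling as a function of one
#' signal's SNR follows `sqrt(1 - 2 / snr^2)`, defined for `snr > sqrt(2)`.
#'
#' @param snr signal-to-noise ratio, `> sqrt(2)`.
#' @return value in `(0, 1)`.
#' @export
slope_model <- function(snr) {
  if (any(snr <= sqrt(2)))
    stop("slope model undefined for snr <= sqrt(2)", call. = FALSE)
  sqrt(1 - 2 / snr^2)
}

#' Linear-regression correction baseline
#'
#' Regresses an AEC spectrum on the corresponding power spectrum (or several
#' power covariates) across frequencies and returns intercept-plus-residual
#' spectra. Provided only as a comparison arm: the power bias is nonlinear
#' in SNR, so this correction is expected to underperform the
#' renormalization.
#'
#' @param aec_spectrum numeric vector over frequencies.
#' @param power_spectrum numeric vector or matrix (frequencies x covariates)
#'   on the same frequency axis.
#' @return corrected spectrum (intercept + residuals).
#' @export
regression_correction_baseline <- function(aec_spectrum, power_spectrum) {
  p <- as.matrix(power_spectrum)
  if (length(aec_spectrum) != nrow(p))
    stop("mismatched frequency axes", call. = FALSE)
  if (length(aec_spectrum) < 3L)
    stop("need at least 3 frequencies to fit the regression", call. = FALSE)
  if (any(apply(p, 2L, var) == 0))
    stop("constant power spectrum: regression is rank-deficient",
         call. = FALSE)
  fit <- lm(aec_spectrum ~ p)
  unname(coef(fit)[1L] + residuals(fit))
}
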