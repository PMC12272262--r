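# Spectral-similarity statistics: one-sided Pearson correlation tests
# between spectra, with the number of spectral degrees of freedom estimated
# from the cross-frequency covariance of individual spectra and family-wise
# error control by Bonferroni correction.

#' Effective spectral degrees of freedom
#'
#' Eigenvalue participation ratio `(sum lambda)^2 / sum lambda^2` of the
#' cross-frequency correlation matrix of individual (per-subject or
#' per-repetition) spectra — equivalently `F^2 / ||R||_F^2` for `F`
#' frequency bins: `F` for independent bins, 1 for perfectly redundant
#' ones. When estimated from a finite sample of spectra, the squared
#' Frobenius norm is debiased using its Wishart expectation (the raw sample
#' value overstates cross-frequency redundancy and would make the
#' correlation test strongly conservative).
#'
#' @param individual_spectra matrix (observations x frequency bins), or a
#'   frequency x frequency covariance/correlation matrix (used as is, no
#'   debiasing).
#' @return scalar in `[1, n_bins]`.
#' @export
effective_spectral_df <- function(individual_spectra) {
  m <- as.matrix(individual_spectra)
  nu <- Inf
  if (nrow(m) == ncol(m) && isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    cc <- m
  } else {
    if (nrow(m) < 2L || ncol(m) < 2L)
      stop("need >= 2 individual spectra over >= 2 frequency bins",
           call. = FALSE)
    v <- apply(m, 2L, var)
    if (all(v == 0)) stop("rank-0 cross-frequency covariance", call. = FALSE)
    cc <- cov(m)
    nu <- nrow(m) - 1
  }
  d <- diag(cc)
  if (all(d == 0)) stop("rank-0 cross-frequency covariance", call. = FALSE)
  keep <- d > 0
  cc <- cov2cor(cc[keep, keep, drop = FALSE])
  F <- ncol(cc)
  s2 <- sum(cc^2)                       # ||R||_F^2 = sum lambda^2
  if (is.finite(nu) && nu > 1)          # E||R_hat||^2 ~ (1+1/nu)||R||^2 + F^2/nu
    s2 <- max((s2 - F^2 / nu) / (1 + 1 / nu), F)
  min(max(F^2 / s2, 1), F)
}

#' One-sided Fisher-z Pearson correlation test for spectra
#'
#' Under the null, the Fisher-transformed correlation `z = atanh(r)` of two
#' spectra is gaussian with mean 0 and variance `1 / (n_eff - 3)`, where
#' `n_eff` is the effective number of independent frequency bins.
#'
#' @param r observed Pearson correlation, `|r| < 1`.
#' @param n_eff effective spectral degrees of freedom (> 3), from
#'   [effective_spectral_df()].
#' @param m_comparisons Bonferroni count for the significance decision.
#' @param alpha family-wise error level.
#' @return object of class `spectral_test_result`: `r`, `n_eff`, `z`, `p`
#'   (one-sided, upper tail), `m_comparisons`, `significant`.
#' @export
fisher_one_sided_test <- function(r, n_eff, m_comparisons = 1L,
                                  alpha = 0.05) {
  if (!is.finite(r) || abs(r) >= 1)
    stop("|r| must be < 1", call. = FALSE)
  if (!is.finite(n_eff) || n_eff <= 3)
    stop("n_eff must exceed 3", call. = FALSE)
  z <- atanh(r)
  p <- pnorm(z * sqrt(n_eff - 3), lower.tail = FALSE)
  structure(list(r = r, n_eff = n_eff, z = z, p = p,
                 m_comparisons = as.integer(m_comparisons),
                 significant = p < alpha / m_comparisons),
            class = "spectral_test_result")
}

#' @export
print.spectral_test_result <- function(x, ...) {
  cat(sprintf("<spectral_test_result> r = %.4f, n_eff = %.1f, z = %.4f, p = %.3g%s\n",
              x$r, x$n_eff, x$z, x$p,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Bonferroni family-wise error control
#'
#' Significance threshold `alpha / m` with `m = rho` for node-level tests
#' and `m = rho (rho - 1) / 2` for connection-level tests, `rho` being the
#' number of independent nodes (supplied by the caller).
#'
#' @param p_values numeric vector of p-values.
#' @param n_independent_units `rho` (>= 1).
#' @param level `"node"` or `"connection"`.
#' @param alpha family-wise error level.
#' @return list with `m`, `threshold`, and logical `significant`.
#' @export
familywise_correct <- function(p_values, n_independent_units,
                               level = c("node", "connection"),
                               alpha = 0.05) {
  level <- match.arg(level)
  rho <- n_independent_units
  if (!is.numeric(rho) || rho < 1) stop("need n_independent_units >= 1",
                                        call. = FALSE)
  m <- if (level == "node") rho else rho * (rho - 1) / 2
  m <- max(m, 1)
  list(m = m, threshold = alpha / m, significant = p_values < alpha / m)
}
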