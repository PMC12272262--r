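#' @keywords internal
"_PACKAGE"

#' @useDynLib aecren, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cov cov2cor fft lm coef residuals sd var rnorm
#'   pnorm qnorm quantile dnorm mvfft runif
#' @importFrom utils read.table write.table
NULL

# run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic sub-seed from a master seed and an operation key (< 2^31)
derive_seed <- function(master_seed, key) {
  h <- sum(utf8ToInt(as.character(key)) * (31L^(seq_along(utf8ToInt(as.character(key))) %% 7L)))
  (as.integer(master_seed) %% 1000000L) * 2029L + as.integer(h %% 100000L)
}

stopifnot_scalar <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single non-missing number", name), call. = FALSE)
  if (finite && !is.finite(x))
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

check_band <- function(band_low_hz, band_high_hz, fs) {
  if (!(band_low_hz > 0 && band_high_hz > band_low_hz && band_high_hz < fs / 2))
    stop(sprintf(
      "invalid band [%g, %g] Hz: need 0 < low < high < Nyquist (%g Hz)",
      band_low_hz, band_high_hz, fs / 2), call. = FALSE)
  invisible(TRUE)
}
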