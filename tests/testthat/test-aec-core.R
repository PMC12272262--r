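test_that("aec handles self-correlation, independence, and degenerate envelopes", {
  fs <- 250; dur <- 120
  e1 <- Mod(analytic_signal(gen_band_limited_gaussian(8, 12, fs, dur, seed = 1)))
  e2 <- Mod(analytic_signal(gen_band_limited_gaussian(8, 12, fs, dur, seed = 2)))
  expect_equal(aec(e1, e1), 1)
  expect_lt(abs(aec(e1, e2)), corr_tol(dur, 4))
  expect_error(aec(rep(1, 100), e1[1:100]), "degenerate")
  expect_error(aec(e1, e2[-1]), "length")
  # coupled pair without noise recovers the simulated coupling
  p <- assemble_pair(test_config(aec0 = 0.5, snr_x = Inf, snr_y = Inf, seed = 3))
  expect_lt(abs(aec(Mod(p$analytic$zx), Mod(p$analytic$zy)) - 0.5), 5e-3)
})

test_that("symmetrized AEC is invariant to argument order and flags total leakage", {
  p <- assemble_pair(test_config(aec0 = 0.5, snr_x = 3, snr_y = 3, seed = 4))
  zx <- p$analytic$zx; zy <- p$analytic$zy
  expect_identical(aec_symmetrized(zx, zy), aec_symmetrized(zy, zx))
  expect_warning(out <- aec_symmetrized(zx, zx), "degenerate")
  expect_true(is.na(out))
})

test_that("connectivity spectra peak where the coupling lives and flag degenerate bands", {
  p <- assemble_pair(test_config(aec0 = 0.6, snr_x = 4, snr_y = 4, seed = 5))
  rec <- multichannel_recording(cbind(x = p$x, y = p$y), 250)
  sp <- connectivity_spectrum(rec, c("x", "y"), centers_hz = c(10, 20, 30),
                              bandwidth_hz = 4)
  expect_s3_class(sp, "connectivity_spectrum")
  expect_identical(nrow(sp), 3L)
  expect_gt(sp$aec[1], 0.3)
  # out-of-band channels carry no signal at all -> degenerate, marked NA
  expect_true(all(is.na(sp$aec[2:3])))
  expect_error(connectivity_spectrum(rec, c("x", "nope"), 10), "nope")
  # single requested band gives a length-1 spectrum
  expect_identical(nrow(connectivity_spectrum(rec, c("x", "y"), 10, 4)), 1L)
})

test_that("connectome spectra are pair-complete, order-invariant and scale-invariant", {
  set.seed(6)
  fs <- 250
  d <- cbind(a = gen_band_limited_gaussian(8, 12, fs, 60, seed = 61) + 0.05 * rnorm(fs * 60),
             b = gen_band_limited_gaussian(8, 12, fs, 60, seed = 62) + 0.05 * rnorm(fs * 60),
             c = gen_band_limited_gaussian(8, 12, fs, 60, seed = 63) + 0.05 * rnorm(fs * 60))
  rec <- multichannel_recording(d, fs)
  cs <- connectome_spectra(rec, centers_hz = 10, bandwidth_hz = 4)
  expect_identical(nrow(cs), 3L)              # 3 channels -> 3 pairs
  expect_true(all(abs(cs$aec) < corr_tol(60, 4)))  # independent channels
  # permuting channels leaves values unchanged under relabelling
  rec2 <- multichannel_recording(d[, c(3, 1, 2)], fs)
  cs2 <- connectome_spectra(rec2, centers_hz = 10, bandwidth_hz = 4)
  key <- function(x) paste(pmin(x$pair_a, x$pair_b), pmax(x$pair_a, x$pair_b))
  expect_equal(cs2$aec[order(key(cs2))], cs$aec[order(key(cs))],
               tolerance = 1e-12)
  # positive rescaling of one channel changes nothing
  d3 <- d; d3[, 2] <- 7 * d3[, 2]
  cs3 <- connectome_spectra(multichannel_recording(d3, fs), 10, 4)
  expect_equal(cs3$aec, cs$aec, tolerance = 1e-10)
  expect_error(connectome_spectra(multichannel_recording(d[, 1], fs), 10, 4),
               "2 channels")
})

test_that("spectrum RMS norm is zero only for an identically zero spectrum", {
  expect_equal(spectrum_norm(c(0, 0, 0)), 0)
  expect_gt(spectrum_norm(c(0, 0.1, NA)), 0)
  expect_true(is.na(spectrum_norm(c(NA_real_, NA_real_))))
})
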