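test_that("band-limited gaussian generator concentrates variance in band and is reproducible", {
  x <- gen_band_limited_gaussian(8, 12, 250, 60, seed = 11)
  expect_length(x, 250 * 60)
  expect_lt(abs(mean(x)), 0.02)
  expect_gt(band_variance_fraction(x, 250, 7, 13), 0.9)
  expect_identical(x, gen_band_limited_gaussian(8, 12, 250, 60, seed = 11))
  expect_false(identical(x, gen_band_limited_gaussian(8, 12, 250, 60, seed = 12)))
  expect_error(gen_band_limited_gaussian(8, 12, 250, 0, seed = 1), "duration")
  expect_error(gen_band_limited_gaussian(100, 130, 250, 10, seed = 1), "band")
})

test_that("mixing gain follows the closed form and rejects boundary couplings", {
  expect_identical(envelope_mixing_gain(0, 1, 1), 0)
  expect_equal(envelope_mixing_gain(0.6, 1, 1), 0.75)   # 0.6 / 0.8
  expect_equal(envelope_mixing_gain(0.6, 2, 1), 1.5)
  expect_error(envelope_mixing_gain(1, 1, 1), "aec0")
  expect_error(envelope_mixing_gain(0.5, 1, 0), "sigma_ax0")
})

test_that("coupling fixes the envelope correlation at aec0", {
  fs <- 250; dur <- 200
  x0 <- gen_band_limited_gaussian(8, 12, fs, dur, seed = 21)
  y0 <- gen_band_limited_gaussian(8, 12, fs, dur, seed = 22)
  # closed-form gain, envelope mixing: identity corr(A_y0 + k A_x0, A_x0) = aec0
  yc <- couple_envelopes(x0, y0, 0.5, fs, 8, mix = "envelope", gain = "formula")
  r_env <- cor(Mod(analytic_signal(x0)), Mod(analytic_signal(yc)))
  expect_lt(abs(r_env - 0.5), corr_tol(dur, 4, rho = 0.5))
  # solved gain, power mixing: realized squared-envelope correlation is pinned
  yp <- couple_envelopes(x0, y0, 0.5, fs, 8, 12)
  r_pow <- cor(Mod(analytic_signal(x0))^2, Mod(analytic_signal(yp))^2)
  expect_lt(abs(r_pow - 0.5), 5e-3)
  # trivial and degenerate cases
  expect_identical(couple_envelopes(x0, y0, 0, fs, 8, 12), y0)
  expect_error(couple_envelopes(x0, y0[-1], 0.5, fs, 8, 12), "length")
  expect_warning(couple_envelopes(x0, x0, 0.5, fs, 8, 12), "independent")
})

test_that("assemble_pair respects the SNR convention, the noise-free limit and determinism", {
  cfg <- test_config(aec0 = 0.4, snr_x = 2, snr_y = 3, seed = 31)
  p <- assemble_pair(cfg)
  expect_equal(p$x, p$x0 + p$eps_x)
  expect_equal(p$y, p$y0 + p$eps_y)
  expect_equal(sd(p$x0) / sd(p$eps_x), 2, tolerance = 1e-6)
  expect_equal(sd(p$eps_y), 1, tolerance = 1e-6)
  p2 <- assemble_pair(cfg)
  expect_identical(p$x, p2$x)
  expect_identical(p$y, p2$y)
  # noise-free limit: measurement equals the connectivity process
  pn <- assemble_pair(test_config(aec0 = 0.4, snr_x = Inf, snr_y = Inf, seed = 31))
  expect_identical(pn$x, pn$x0)
  expect_identical(pn$eps_x, rep(0, length(pn$x)))
  # measured-SNR convention: sd(x)/sd(eps) is the dial
  pm <- assemble_pair(test_config(aec0 = 0, snr_x = 2, snr_y = 2, seed = 31,
                                  snr_convention = "measured"))
  expect_equal(sd(pm$x) / sd(pm$eps_x), 2, tolerance = 0.02)
})

test_that("noise coupling is off by default and controlled by aec_noise", {
  p0 <- assemble_pair(test_config(aec0 = 0.5, snr_x = 2, snr_y = 2, seed = 41))
  r0 <- cor(Mod(p0$analytic$zex)^2, Mod(p0$analytic$zey)^2)
  expect_lt(abs(r0), corr_tol(120, 4))
  pc <- assemble_pair(test_config(aec0 = 0.5, aec_noise = 0.3,
                                  snr_x = 2, snr_y = 2, seed = 41))
  rc <- cor(Mod(pc$analytic$zex)^2, Mod(pc$analytic$zey)^2)
  expect_lt(abs(rc - 0.3), 5e-3)   # solved gain pins the realized coupling
})

test_that("power-bias experiment: slope near 1 at high SNR, monotone in SNR", {
  cfg <- test_config(duration_s = 60)
  grid <- data.frame(snr_x = c(1.4, 2.5, 30), snr_y = c(1.4, 2.5, 30))
  res <- run_bias_experiment(grid, aec0_levels = c(0, 0.3, 0.6), config = cfg,
                             n_repetitions = 4, master_seed = 5)
  s <- unique(res$summary[, c("snr_x", "slope")])
  slopes <- s$slope[order(s$snr_x)]
  expect_true(all(diff(slopes) > 0))         # non-decreasing in SNR
  expect_gt(slopes[3], 0.9)                  # noise-free limit: slope ~ 1
  expect_lt(slopes[1], 0.55)                 # strong bias at SNR 1.4
  expect_error(run_bias_experiment(data.frame()), "empty")
})

test_that("estimated bias slope matches the gaussian-moment attenuation factor", {
  # with y nearly noise-free and weak coupling, the slope reduces to the
  # x-side factor snr^2 / (1 + snr^2) from the exponential A^2 moments
  cfg <- test_config(duration_s = 120)
  grid <- data.frame(snr_x = c(2, 5), snr_y = c(1000, 1000))
  res <- run_bias_experiment(grid, aec0_levels = c(0, 0.15, 0.3), config = cfg,
                             n_repetitions = 6, master_seed = 6)
  s <- unique(res$summary[, c("snr_x", "slope")])
  for (i in seq_len(nrow(s))) {
    f <- s$snr_x[i]^2 / (1 + s$snr_x[i]^2)
    expect_lt(abs(s$slope[i] - f), 0.08)
  }
  # the model curve sqrt(1 - 2/snr^2) approximates this factor at high SNR
  expect_lt(abs(slope_model(5) - 25 / 26), 0.005)
})
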