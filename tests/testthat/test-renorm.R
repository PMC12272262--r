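test_that("plain and amplitude SNR follow their formulas and limits", {
  expect_equal(snr_plain(1, 1), 1)
  expect_equal(snr_plain(3, 1), 3)
  expect_identical(snr_plain(2, 0), Inf)
  expect_identical(snr_ampl(1, 2, 0, 0), Inf)
  # gaussian example: total variance 2, noise variance 1 -> A^2 moments
  # <A^2> = 2 s^2, sd(A^2) = 2 s^2 give snr_ampl^2 = s_x^4/(2 s_x^2 s_n^2 - s_n^4)
  s <- snr_ampl(std_sq_env = 4, mean_sq_env = 4,
                noise_std_sq_env = 2, noise_mean_sq_env = 2)
  expect_equal(sqrt(1 - s^-2), 1 - 1 / 2, tolerance = 1e-12)
  # noise dominating the amplitude moments is ill-conditioned
  expect_error(snr_ampl(1, 0.1, 10, 10), class = "aecren_ill_conditioned")
})

test_that("gaussian closed form: sqrt(1 - snr_ampl^-2) equals 1 - var ratio on simulation", {
  fs <- 250; dur <- 240
  for (snr in c(1.4, 3)) {
    p <- assemble_pair(simulation_config(fs = fs, duration_s = dur, aec0 = 0,
                                         snr_x = snr, snr_y = snr, seed = 7))
    ax2 <- Mod(p$analytic$zx)^2
    ae2 <- Mod(p$analytic$zex)^2
    s <- snr_ampl(sd(ax2), mean(ax2), sd(ae2), mean(ae2))
    expect_lt(abs(sqrt(1 - s^-2) - (1 - var(p$eps_x) / var(p$x))), 0.03)
  }
})

test_that("linear-synchronization term evaluates exactly", {
  expect_equal(lin_sync(0.2, 0.1), 0.08)
  expect_equal(lin_sync(5, 0), 0)
  expect_equal(lin_sync(0.3, 0.3), 0)
})

test_that("renormalization is the identity in the noise-free limit", {
  st <- renorm_stats(mean_sq_env_x = 2, std_sq_env_x = 2,
                     mean_sq_env_y = 2, std_sq_env_y = 2,
                     cov_xy = 0.1, cov_x_hy = 0.05,
                     noise_mean_sq_env_x = 0, noise_std_sq_env_x = 0,
                     noise_mean_sq_env_y = 0, noise_std_sq_env_y = 0,
                     noise_cov_sq_env = 0, noise_cov = 0, noise_cov_h = 0)
  out <- aec_renormalized(0.42, st)
  expect_true(out$conditioned)
  expect_identical(out$value, 0.42)
  expect_identical(out$denominator, 1)
})

test_that("ill-conditioned cells are flagged, not silently returned", {
  st <- renorm_stats(mean_sq_env_x = 2, std_sq_env_x = 2,
                     mean_sq_env_y = 2, std_sq_env_y = 2,
                     cov_xy = 0, cov_x_hy = 0,
                     noise_mean_sq_env_x = 2, noise_std_sq_env_x = 2,
                     noise_mean_sq_env_y = 0, noise_std_sq_env_y = 0,
                     noise_cov_sq_env = 0, noise_cov = 0, noise_cov_h = 0)
  out <- aec_renormalized(0.1, st)    # noise as strong as the signal on x
  expect_false(out$conditioned)
  expect_true(is.na(out$value))
  expect_error(
    renorm_stats(2, 2, 2, 2, 0, 0, 1, 1, 1, 1,
                 noise_cov_sq_env = 5, noise_cov = 0, noise_cov_h = 0),
    "Cauchy")
})

test_that("renormalization with ground-truth noise statistics recovers the coupling", {
  cfg <- simulation_config(fs = 250, duration_s = 240)
  res <- run_correction_experiment(data.frame(snr_x = 2, snr_y = 2),
                                   aec0_levels = 0.5, config = cfg,
                                   n_repetitions = 10, master_seed = 9)
  expect_identical(sum(res$summary$n_flagged), 0L)
  expect_lt(res$summary$error_pct, 5)       # MC-limited at this reduced scale
  expect_lt(res$summary$correction_error_pct, 5)
  # the uncorrected estimate is far more biased than the corrected one
  expect_gt(abs(res$summary$mean_aec - 0.5), 5 * abs(res$summary$mean_aec_ren - 0.5))
})

test_that("renormalization stays valid with correlated noise", {
  cfg <- simulation_config(fs = 250, duration_s = 240, aec_noise = 0.35)
  res <- run_correction_experiment(data.frame(snr_x = 2, snr_y = 2),
                                   aec0_levels = 0.5, config = cfg,
                                   n_repetitions = 8, master_seed = 10)
  expect_identical(sum(res$summary$n_flagged), 0L)
  expect_lt(res$summary$error_pct, 5)
})

test_that("PBM aggregates relative deviation and guards the reference", {
  expect_equal(pbm(c(0.5, 0.3), c(0.5, 0.3)), 0)
  expect_equal(pbm(0.25, 0.5), 50)
  expect_equal(pbm(0.5 * c(0.4, 0.2, 0.6), c(0.4, 0.2, 0.6)), 50)
  expect_equal(pbm(c(0.2, 0.4), c(0.4, 0.8), method = "mean"), 50)
  expect_error(pbm(c(0, 0), c(0, 0)), "zero")
  expect_error(pbm(1, c(1, 2)), "length")
})

test_that("slope model follows sqrt(1 - 2/snr^2) on its domain", {
  expect_equal(slope_model(2), sqrt(0.5))
  expect_equal(slope_model(1e8), 1, tolerance = 1e-12)
  expect_error(slope_model(sqrt(2)), "undefined")
  expect_error(slope_model(1), "undefined")
})

test_that("regression baseline is exact for affine bias but fails nonlinear bias", {
  snr <- c(1.5, 1.8, 2.2, 3, 4, 6, 9, 15)
  power <- 1 + snr^2                       # measured band power
  truth <- rep(0.5, length(snr))
  # affine relation: residual-plus-intercept is flat
  affine <- 0.1 + 0.02 * power
  flat <- regression_correction_baseline(affine, power)
  expect_lt(diff(range(flat)), 1e-10)
  # nonlinear SNR attenuation leaves structured residuals: the regression
  # cannot recover the flat true spectrum
  biased <- truth * (snr^2 / (1 + snr^2))^2
  corrected <- regression_correction_baseline(biased, power)
  expect_gt(sqrt(mean((corrected - truth)^2)), 0.05)
  expect_error(regression_correction_baseline(biased, rep(2, length(snr))),
               "rank")
  expect_error(regression_correction_baseline(0.5, 1), "frequencies")
})
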