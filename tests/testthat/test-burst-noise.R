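test_that("EM recovers a two-level envelope and is deterministic", {
  tl <- two_level_envelope(20000, 250, low = 1, high = 3, seed = 12)
  h <- fit_two_state_hmm(tl$envelope, seed = 1)
  m <- sort(h$means)
  expect_lt(abs(m[1] - 1) / 1, 0.1)
  expect_lt(abs(m[2] - 3) / 3, 0.1)
  expect_true(all(diff(h$loglik_trace) > -1e-6))   # EM monotonicity
  expect_true(all(abs(rowSums(h$transition) - 1) < 1e-10))
  h2 <- fit_two_state_hmm(tl$envelope, seed = 1)
  expect_identical(h$means, h2$means)
  expect_identical(h$loglik_trace, h2$loglik_trace)
  expect_error(fit_two_state_hmm(rep(2, 1000)),
               class = "aecren_degenerate_fit")
  expect_error(fit_two_state_hmm(rnorm(10)), "short")
})

test_that("Viterbi equals exhaustive search on short sequences", {
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    x <- rnorm(n, mean = sample(c(1, 3), n, replace = TRUE), sd = 0.8)
    means <- sort(runif(2, 0, 4))
    sds <- runif(2, 0.3, 1.5)
    a <- runif(1, 0.6, 0.95); b <- runif(1, 0.6, 0.95)
    trans <- matrix(c(a, 1 - a, 1 - b, b), 2, byrow = TRUE)
    init <- c(0.5, 0.5)
    hmm <- list(means = means, stds = sds, transition = trans, initial = init)
    seg <- viterbi(x, hmm)
    expect_identical(seg$labels, brute_viterbi(x, means, sds, trans, init))
  }
})

test_that("Viterbi reduces to nearest-mean labelling for separated emissions", {
  hmm <- list(means = c(1, 10), stds = c(0.5, 0.5),
              transition = matrix(0.5, 2, 2), initial = c(0.5, 0.5))
  x <- c(1.2, 9.7, 0.8, 10.3, 1.1)
  seg <- viterbi(x, hmm)
  expect_identical(seg$labels, c(1L, 2L, 1L, 2L, 1L))
  expect_identical(seg$nonbursting_state, 1L)
  expect_identical(seg$mask_nonburst, seg$labels == 1L)
})

test_that("coincident non-bursting mask is the AND of masks with a floor", {
  m1 <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  expect_identical(as.logical(coincident_nonburst_mask(m1, m1)), m1)
  expect_error(coincident_nonburst_mask(c(TRUE, FALSE), c(FALSE, TRUE)),
               class = "aecren_insufficient_noise_data")
  set.seed(15)
  a <- runif(20000) < 0.6
  b <- runif(20000) < 0.5
  expect_lt(abs(mean(coincident_nonburst_mask(a, b)) - 0.3), 0.02)
})

test_that("full-mask noise statistics equal whole-signal statistics", {
  p <- assemble_pair(test_config(aec0 = 0.3, snr_x = 2, snr_y = 2, seed = 16))
  zx <- p$analytic$zx; zy <- p$analytic$zy
  st <- nonburst_noise_statistics(zx, zy, rep(TRUE, length(zx)))
  expect_equal(st$noise_mean_sq_env_x, mean(Mod(zx)^2))
  expect_equal(st$noise_std_sq_env_x, sd(Mod(zx)^2))
  expect_equal(st$noise_cov, cov(Re(zx), Re(zy)))
  expect_identical(st$n_samples_used, length(zx))
})

test_that("burst-gated coupling: raw AEC is peaked, non-bursting AEC is flat", {
  fx <- fixture_generator("burst_gated", master_seed = 17, fs = 250,
                          duration_s = 240)
  res <- end_to_end_pipeline(fx$recording, centers_hz = c(10, 20),
                             bandwidth_hz = 4, master_seed = 18,
                             min_noise_seconds = 5)
  raw10 <- res$aec[res$variant == "raw" & res$center_hz == 10]
  nb10 <- res$aec[res$variant == "non_bursting" & res$center_hz == 10]
  expect_gt(raw10, 0.25)              # coupling visible on the whole signal
  expect_lt(abs(nb10), raw10 / 2)     # much weaker outside coincident bursts
  expect_lt(abs(nb10), 0.2)
  # non-bursting power spectrum keeps the spectral shape of the whole signal
  b <- filterbank(fx$recording, centers_hz = c(8, 10, 12, 16, 20),
                  bandwidth_hz = 2)
  seg <- lapply(1:2, function(ci)
    viterbi(b[[2]]$envelope[, ci],
            fit_two_state_hmm(b[[2]]$envelope[, ci], seed = 19)))
  mask <- coincident_nonburst_mask(seg[[1]], seg[[2]])
  pw_whole <- vapply(b, function(bb) mean(bb$envelope[, 1]^2), numeric(1))
  pw_nb <- vapply(b, function(bb) mean(bb$envelope[mask, 1]^2), numeric(1))
  expect_gt(cor(pw_whole, pw_nb), 0.9)
})

test_that("measurement-noise statistics: independent channels give near-zero covariances", {
  fx <- fixture_generator("uncoupled", master_seed = 20, fs = 250,
                          duration_s = 120)
  ns <- measurement_noise_statistics(fx$recording, centers_hz = 10,
                                     bandwidth_hz = 4)
  off <- ns[[1]]$cov_sq_env[upper.tri(ns[[1]]$cov_sq_env)]
  scale <- sqrt(ns[[1]]$std_sq_env[1] * ns[[1]]$std_sq_env[2])
  expect_lt(max(abs(off)) / scale^1, corr_tol(120, 4))
  other <- multichannel_recording(fx$recording$data[, 1:2], 250)
  expect_error(measurement_noise_statistics(fx$recording, 10, 4,
                                            match_rec = other), "layout")
})
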