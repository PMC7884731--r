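# Pupil impulse response, preprocessing, and deconvolution: analytic IRF
# properties, blink interpolation, decimation/normalization, and exact
# forward-then-inverse recovery.

test_that("Erlang-gamma IRF peaks at t_max with unit amplitude", {
  t <- seq(0, 5, by = 0.001)
  h <- erlang_irf(t)
  expect_equal(h[1], 0)
  expect_equal(t[which.max(h)], 1.30, tolerance = 1e-9)
  expect_equal(max(h), 1)
  # unimodal: increasing before the peak, decreasing after
  expect_true(all(diff(h[t < 1.30]) > 0))
  expect_true(all(diff(h[t >= 1.30]) < 0))
  expect_gt(erlang_irf(1.30), erlang_irf(0.65))
  expect_gt(erlang_irf(1.30), erlang_irf(2.60))
  # causal: zero for negative times
  expect_equal(erlang_irf(c(-1, -0.1)), c(0, 0))
  # custom parameters move the peak
  expect_equal(t[which.max(erlang_irf(t, irf_params(n = 8, t_max = 0.9)))],
               0.9, tolerance = 1e-3)
  expect_error(irf_params(n = -1), "positive")
})

test_that("blink interpolation reconstructs linear segments exactly", {
  x <- seq(0, 10, length.out = 501)    # 50 Hz, linear trace
  blink <- rep(FALSE, 501)
  blink[200:220] <- TRUE
  s <- pupil_series(x, 50, blink)
  si <- interpolate_blinks(s, pad = 200)
  expect_equal(si$diameter, x, tolerance = 1e-12)
  # no blinks: identity
  s2 <- pupil_series(x, 50)
  expect_identical(interpolate_blinks(s2)$diameter, x)
  # blink over a curved bump: chord error bounded by max |h''| * width^2 / 8
  tt <- (0:2000) / 500
  bump <- erlang_irf(tt - 1)
  blink3 <- rep(FALSE, length(tt))
  blink3[abs(tt - 2.3) < 0.05] <- TRUE
  s3 <- pupil_series(bump, 500, blink3)
  si3 <- interpolate_blinks(s3, pad = 200)
  gap <- which(abs(tt - 2.3) < 0.05 + 0.2 + 1e-9)
  width <- (length(gap) - 1) / 500
  d2 <- abs(diff(bump, differences = 2)) * 500^2
  bound <- max(d2[(min(gap) - 1):(max(gap) + 1)]) * width^2 / 8
  err <- max(abs(si3$diameter - bump))
  expect_lte(err, bound)
  expect_gt(bound, 0)
  # blink at the trace edge extends the nearest valid sample
  blink4 <- rep(FALSE, 501)
  blink4[1:5] <- TRUE
  s4 <- pupil_series(x, 50, blink4)
  expect_true(all(is.finite(interpolate_blinks(s4)$diameter)))
})

test_that("preprocessing decimates by block means and z-scores", {
  x <- stats::rnorm(5000)             # 10 s at 500 Hz
  s <- preprocess_pupil(pupil_series(x, 500), 20)
  expect_length(s$diameter, 200)
  expect_equal(s$rate, 20)
  expect_lt(abs(mean(s$diameter)), 1e-9)
  expect_lt(abs(stats::sd(s$diameter) - 1), 1e-9)
  # block means without normalization
  raw <- preprocess_pupil(pupil_series(x, 500), 20, normalize = FALSE)
  expect_equal(raw$diameter[1], mean(x[1:25]))
  expect_error(preprocess_pupil(pupil_series(rep(2, 500), 500), 20),
               "zero-variance")
  expect_error(preprocess_pupil(pupil_series(x, 500), 30), "divide")
})

test_that("deconvolution inverts a noise-free forward simulation", {
  # single event type: trace is the shifted IRF times its amplitude
  amp <- 1.7
  n <- 5000
  pulse <- numeric(n)
  pulse[501] <- amp                    # event at 1.0 s
  kern <- erlang_irf((0:(n - 1)) / 500)
  trace <- stats::convolve(pulse, rev(kern), type = "open")[1:n]
  expect_equal(max(trace), amp, tolerance = 1e-6)
  s <- preprocess_pupil(pupil_series(trace, 500), 20, normalize = FALSE)
  fit <- deconvolve_pupil(s, data.frame(time = 1.0, type = "cue"))
  expect_equal(fit$coefficients$estimate, amp, tolerance = 1e-6)
  # two overlapping event types, 0.5 s apart: superposition is unmixed
  pulse2 <- numeric(n)
  pulse2[501] <- 1.0
  pulse2[751] <- 0.4
  trace2 <- stats::convolve(pulse2, rev(kern), type = "open")[1:n]
  s2 <- preprocess_pupil(pupil_series(trace2, 500), 20, normalize = FALSE)
  fit2 <- deconvolve_pupil(s2, data.frame(time = c(1.0, 1.5),
                                          type = c("cue", "target")))
  est <- stats::setNames(fit2$coefficients$estimate, fit2$coefficients$group)
  expect_equal(unname(est["cue"]), 1.0, tolerance = 1e-6)
  expect_equal(unname(est["target"]), 0.4, tolerance = 1e-6)
  # linearity: the summed trace yields the summed coefficients
  s12 <- preprocess_pupil(pupil_series(trace + trace2, 500), 20,
                          normalize = FALSE)
  fit12 <- deconvolve_pupil(s12, data.frame(time = c(1.0, 1.5),
                                            type = c("cue", "target")))
  e12 <- stats::setNames(fit12$coefficients$estimate, fit12$coefficients$group)
  expect_equal(unname(e12["cue"]), 1.0 + amp, tolerance = 1e-6)
  # scale equivariance
  sK <- preprocess_pupil(pupil_series(3 * trace, 500), 20, normalize = FALSE)
  fitK <- deconvolve_pupil(sK, data.frame(time = 1.0, type = "cue"))
  expect_equal(fitK$coefficients$estimate, 3 * amp, tolerance = 1e-6)
})

test_that("collinear event regressors raise a singular-design error", {
  n <- 5000
  trace <- stats::rnorm(n / 25)
  s <- pupil_series(trace, 20)
  ev <- data.frame(time = c(1, 1), type = c("a", "b"))  # identical regressors
  expect_error(deconvolve_pupil(s, ev), "collinear")
})

test_that("session-level simulation recovers planted cue condition effects", {
  cfg <- design_config(2, n_subjects = 1, blocks = 1, trials_per_block = 40,
                       seed = 13)
  des <- generate_design(cfg)
  sub <- draw_subjects(1, generator_config(subject = list(pupil_cue_sd = 0)),
                       seed = 13)
  g <- generator_config(pupil = list(noise_sd = 0.1, cue_reward = 0),
                        subject = list(pupil_cue_sd = 0))
  beh <- simulate_behavior(des, sub, cfg, gcfg = g, seed = 13)
  hit <- 0
  for (r in 1:20) {
    ps <- simulate_pupil(beh$records, sub[1, ], g, seed = derive_seed(13, r))
    s20 <- preprocess_pupil(interpolate_blinks(ps$series), 20,
                            normalize = FALSE)
    fit <- deconvolve_pupil(s20, ps$events)
    est <- stats::setNames(fit$coefficients$estimate, fit$coefficients$group)
    lo <- mean(est[grep("_E0$", names(est))])
    hi <- mean(est[grep("_E1$", names(est))])
    if (hi < lo) hit <- hit + 1
  }
  # planted efficacy effect (high < low) recovered in sign in >= 19/20 runs
  expect_gte(hit, 19)
})
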