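# ERP quantification: baseline correction, artifact rejection thresholds,
# windowed ROI means, peak-to-peak FRN scoring, split-half reliability, and
# exact recovery of planted amplitudes from noise-free epochs.

test_that("baseline correction subtracts the pre-anchor mean", {
  es <- flat_epochs(2, value = 5)
  bc <- baseline_correct(es)
  expect_equal(max(abs(bc$epochs$data)), 0)
  expect_equal(unname(bc$baselines[1, ]), rep(5, 6))
  # step from 0 to 4 at the anchor: baseline 0, post-anchor amplitude 4
  es2 <- flat_epochs(1, 0)
  es2$data[1, , es2$times_ms >= 0] <- 4
  bc2 <- baseline_correct(es2)
  expect_equal(unname(bc2$baselines[1, ]), rep(0, 6))
  expect_equal(unname(mean_amplitude(bc2$epochs, c(0, 100), "FCz")), 4)
  # zero-mean baseline leaves the epoch unchanged
  es3 <- flat_epochs(1, 0)
  nbl <- sum(es3$times_ms < 0)
  es3$data[1, 1, seq_len(nbl)] <- rep(c(-1, 1), length.out = nbl)
  if (abs(mean(es3$data[1, 1, seq_len(nbl)])) < 1e-12) {
    bc3 <- baseline_correct(es3)
    expect_equal(bc3$epochs$data[1, 2, ], es3$data[1, 2, ])
  }
  # missing pre-anchor samples are an error
  es4 <- flat_epochs(1, 0)
  es4$times_ms <- es4$times_ms + 300
  expect_error(baseline_correct(es4), "baseline")
})

test_that("artifact rejection applies the amplitude and gradient thresholds", {
  es <- flat_epochs(4, 0)
  # smooth ramps (steps < 50 uV) probing the amplitude boundary alone
  es$data[2, 3, 100:106] <- c(40, 80, 120, 151, 120, 80, 40)  # peak 151: out
  es$data[3, 3, 100:106] <- c(40, 80, 120, 149, 120, 80, 40)  # peak 149: kept
  es$data[4, 5, 200:210] <- cumsum(rep(60, 11)) / 10  # 6 uV steps, then...
  es$data[4, 5, 211] <- es$data[4, 5, 210] + 60       # one 60 uV jump: out
  expect_equal(unname(reject_artifacts(es)), c(FALSE, TRUE, FALSE, TRUE))
  # a 40 uV jump is retained
  es5 <- flat_epochs(1, 0)
  es5$data[1, 1, 50] <- 40
  expect_false(reject_artifacts(es5))
  # mask invariant to channel and trial ordering
  perm <- sample(dim(es$data)[1])
  es_p <- es
  es_p$data <- es$data[perm, rev(seq_len(6)), , drop = FALSE]
  es_p$channels <- rev(es$channels)
  es_p$subject <- es$subject[perm]
  es_p$trial <- es$trial[perm]
  expect_equal(unname(reject_artifacts(es_p)), unname(reject_artifacts(es)[perm]))
})

test_that("mean amplitude averages the closed window over the ROI", {
  es <- flat_epochs(1, 3)
  expect_equal(unname(mean_amplitude(es, c(0, 100), c("Pz", "P3", "P4"))), 3)
  # degenerate single-channel ROI equals that channel's window mean
  es$data[1, 2, ] <- 7
  expect_equal(unname(mean_amplitude(es, c(0, 100), "FCz")), 7)
  expect_error(mean_amplitude(es, c(0, 100), "Oz"), "unknown ROI")
  expect_error(mean_amplitude(es, c(700, 900), "FCz"), "window")
})

test_that("FRN peak-to-peak scores constructed waveforms", {
  # flat epoch scores zero
  expect_equal(unname(frn_peak_to_peak(flat_epochs(1, 0))), 0)
  # peak +6 at 230 ms, trough -4 at 300 ms: peak-to-peak 10
  es <- flat_epochs(1, 0)
  i230 <- which.min(abs(es$times_ms - 230))
  i300 <- which.min(abs(es$times_ms - 300))
  ch <- which(es$channels == "FCz")
  es$data[1, ch, i230] <- 6
  es$data[1, ch, i300] <- -4
  expect_equal(unname(frn_peak_to_peak(es)), 10)
  # trough exactly at the window edge: the preceding search is [150, 250)
  es2 <- flat_epochs(1, 0)
  i250 <- which(abs(es2$times_ms - 250) < 1e-9)
  es2$data[1, ch, i250] <- -5
  i140 <- which.min(abs(es2$times_ms - 140))   # outside the 100 ms pre-window
  es2$data[1, ch, i140] <- 9
  i200 <- which.min(abs(es2$times_ms - 200))   # inside
  es2$data[1, ch, i200] <- 2
  expect_equal(unname(frn_peak_to_peak(es2)), 7)
})

test_that("noise-free planted epochs reproduce the amplitude ledger exactly", {
  cfg <- tiny_config()
  des <- generate_design(cfg)
  sub <- draw_subjects(cfg$n_subjects, seed = 8)
  beh <- simulate_behavior(des, sub, cfg, seed = 8)
  g0 <- quiet_erp()
  amp <- simulate_erp_amplitudes(beh$records, sub, g0, seed = 8)
  eps <- simulate_eeg_epochs(beh$records, amp$amplitudes, g0, seed = 8)
  q <- quantify_epochs(eps)
  expect_equal(q$p3b, amp$amplitudes$p3b, tolerance = 1e-9)
  expect_equal(q$cnv, amp$amplitudes$cnv, tolerance = 1e-9)
  expect_equal(q$ern_crn, amp$amplitudes$ern_crn, tolerance = 1e-9)
  expect_equal(q$frn, amp$amplitudes$frn, tolerance = 1e-9)
  expect_equal(q$p3b_baseline, amp$amplitudes$p3b_baseline, tolerance = 1e-9)
  expect_equal(q$cnv_baseline, amp$amplitudes$cnv_baseline, tolerance = 1e-9)
  expect_false(any(q$rejected))
  # quantification is condition-agnostic: amplitudes are untouched by labels
  q2 <- quantify_epochs(eps)
  expect_identical(q$p3b, q2$p3b)
})

test_that("artifact injection count is exact and flagged by rejection", {
  cfg <- tiny_config()
  des <- generate_design(cfg)
  sub <- draw_subjects(cfg$n_subjects, seed = 8)
  beh <- simulate_behavior(des, sub, cfg, seed = 8)
  g <- generator_config(erp = list(artifact_fraction = 0.1))
  amp <- simulate_erp_amplitudes(beh$records, sub, g, seed = 8)
  eps <- simulate_eeg_epochs(beh$records, amp$amplitudes, g, seed = 8,
                             anchors = "cue")
  expect_length(eps$artifact_trials, round(0.1 * nrow(beh$records)))
  rej <- reject_artifacts(baseline_correct(eps$cue)$epochs)
  expect_true(all(rej[eps$artifact_trials]))
})

test_that("split-half reliability behaves at its limits", {
  # identical odd/even means: r = 1
  v <- rep(1:6, each = 10)
  tr <- rep(1:10, 6)
  subj <- rep(1:6, each = 10)
  expect_equal(split_half_reliability(v, tr, subj), 1)
  # independent pure noise: |r| small at many subjects
  set.seed(3)
  n_sub <- 44
  v2 <- stats::rnorm(n_sub * 40)
  tr2 <- rep(1:40, n_sub)
  s2 <- rep(seq_len(n_sub), each = 40)
  expect_lt(abs(split_half_reliability(v2, tr2, s2)), 0.3)
  expect_error(split_half_reliability(1:3, 1:3, c(1, 1, 1)), ">= 2 subjects")
})

test_that("low-noise planted P3b is highly reliable across halves", {
  cfg <- design_config(2, n_subjects = 44, blocks = 2, trials_per_block = 30,
                       seed = 21)
  des <- generate_design(cfg)
  sub <- draw_subjects(cfg$n_subjects, seed = 21)
  beh <- simulate_behavior(des, sub, cfg, seed = 21)
  amp <- simulate_erp_amplitudes(beh$records, sub, seed = 21)
  a <- amp$amplitudes
  r <- split_half_reliability(a$p3b, a$trial, a$subject)
  expect_gt(r, 0.8)
})

test_that("within-subject z-scoring standardizes each subject", {
  a <- tiny_sim$erp
  z <- zscore_within(a$p3b, a$subject)
  for (s in unique(a$subject)) {
    expect_lt(abs(mean(z[a$subject == s])), 1e-9)
    expect_lt(abs(stats::sd(z[a$subject == s]) - 1), 1e-9)
  }
})

test_that("epoch containers round-trip through the binary format", {
  es <- flat_epochs(3, 0)
  es$data[] <- stats::rnorm(length(es$data))
  dir <- withr::local_tempdir()
  write_epochs(es, dir)
  es2 <- read_epochs(dir)
  expect_equal(es2$data, es$data)
  expect_equal(es2$times_ms, es$times_ms)
  expect_equal(es2$channels, es$channels)
})
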