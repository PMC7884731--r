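# The synthetic study generator: design balance, the yoked reward schedule,
# trial-record invariants, and reproducibility from seeds.

test_that("designs have the configured geometry and balanced cells", {
  d2 <- generate_design(design_config(2, n_subjects = 2, seed = 7))
  expect_equal(nrow(d2), 2 * 8 * 75)
  expect_equal(as.vector(table(d2$subject)), rep(600L, 2))
  # four cue conditions, balanced within one trial per block
  for (b in 1:8) {
    blk <- d2[d2$subject == 1 & d2$block == b, ]
    counts <- table(blk$reward, blk$efficacy)
    expect_true(all(abs(counts - 75 / 4) <= 1))
  }
  d3 <- generate_design(design_config(3, n_subjects = 2, seed = 7))
  expect_equal(as.vector(table(d3$subject)), rep(300L, 2))
  expect_equal(nrow(unique(d3[, c("reward", "efficacy")])), 16L)
  # chronological, contiguous trial indices
  expect_equal(d3$trial[d3$subject == 1], 1:300)
})

test_that("designs are deterministic under the seed", {
  cfg <- design_config(1, n_subjects = 3, seed = 11)
  expect_identical(generate_design(cfg), generate_design(cfg))
  cfg2 <- design_config(1, n_subjects = 3, seed = 12)
  expect_false(identical(generate_design(cfg), generate_design(cfg2)))
})

test_that("yoked probability is the windowed mean with a 0.5 cold start", {
  h <- c(1, 0, 1, 1, 1, 0, 1, 1, 0, 1)      # 7 successes in the last 10
  expect_equal(yoked_reward_probability(h), 0.7)
  expect_equal(yoked_reward_probability(numeric(0)), 0.5)
  # 13 outcomes, window 10: only the final 10 count
  h13 <- c(1, 1, 1, h)
  expect_equal(yoked_reward_probability(h13, 10), mean(h13[4:13]))
  # short history uses what exists
  expect_equal(yoked_reward_probability(c(1, 0)), 0.5)
  expect_error(yoked_reward_probability(h, -1), "window")
  expect_error(yoked_reward_probability(c(1, 2)), "0/1")
})

test_that("trial records satisfy the outcome invariants", {
  r <- tiny_sim$records
  expect_equal(r$criterion_met,
               as.integer(r$accuracy == 1 & !is.na(r$rt) & r$rt < 750))
  hi <- r$performance_determined == 1
  expect_equal(r$rewarded[hi], r$criterion_met[hi])
  expect_equal(r$outcome_amount, r$rewarded * r$reward)
  # full efficacy forces performance-determined outcomes on every trial
  expect_true(all(r$performance_determined[r$efficacy == 1] == 1))
  expect_true(all(r$performance_determined[r$efficacy == 0] == 0))
})

test_that("behavior simulation is reproducible and noise-degenerate", {
  cfg <- tiny_config()
  des <- generate_design(cfg)
  sub <- draw_subjects(cfg$n_subjects, seed = 1)
  b1 <- simulate_behavior(des, sub, cfg, seed = 3)
  b2 <- simulate_behavior(des, sub, cfg, seed = 3)
  expect_identical(b1$records, b2$records)
  # zero noise, zero lapses: identical deterministic RTs within a condition
  g0 <- generator_config(behavior = list(rt_noise_sdlog = 1e-12,
                                         lapse_rate = 0, rt_trend = 0,
                                         rt_coupling_p3b = 0,
                                         rt_coupling_cnv = 0))
  sub0 <- draw_subjects(cfg$n_subjects,
                        generator_config(subject = list(
                          rt_intercept_sd = 0, rt_reward_sd = 0,
                          rt_efficacy_sd = 0, rt_interaction_sd = 0)),
                        seed = 1)
  b0 <- simulate_behavior(des, sub0, cfg, gcfg = g0, seed = 3)
  r0 <- b0$records[b0$records$congruency == "neutral" &
                     b0$records$reward == 1 & b0$records$efficacy == 1, ]
  expect_lt(max(r0$rt) - min(r0$rt), 1e-6)
})

test_that("yoking equates reward rates across efficacy under stationarity", {
  cfg <- design_config(1, n_subjects = 1, blocks = 20, trials_per_block = 500,
                       seed = 5)
  des <- generate_design(cfg)
  sub <- draw_subjects(1, seed = 5)
  g <- generator_config(behavior = list(rt_trend = 0, acc_trend = 0))
  b <- simulate_behavior(des, sub, cfg, gcfg = g, seed = 5)
  r <- b$records
  rate_hi <- mean(r$rewarded[r$efficacy == 1])
  rate_lo <- mean(r$rewarded[r$efficacy == 0])
  expect_lt(abs(rate_hi - rate_lo), 0.02)
})

test_that("low-efficacy outcomes track a constant yoked rate", {
  # criterion outcomes held at a constant 0.7 rate: the yoked draws must
  # land within 3 binomial SDs of 0.7
  set.seed(99)
  n <- 10000
  hist <- rep(c(1, 1, 1, 1, 1, 1, 1, 0, 0, 0), 2)  # rate exactly 0.7
  p <- yoked_reward_probability(hist, 10)
  expect_equal(p, 0.7)
  draws <- stats::rbinom(n, 1, p)
  expect_lt(abs(mean(draws) - 0.7), 3 * sqrt(0.7 * 0.3 / n))
})

test_that("planted behavioral truth matches the condition-mean contrasts", {
  # 2 x 2 design: the planted RT reward effect is the average u*-driven
  # condition difference times the RT gain
  cfg <- tiny_config()
  cells <- evcontrol:::condition_table(cfg)
  g <- generator_config()
  m <- -g$behavior$rt_gain * cells$u_star
  bR <- mean(m[cells$xR == 0.5]) - mean(m[cells$xR == -0.5])
  truth <- tiny_sim$truth
  expect_equal(unname(truth$value[truth$model == "rt" & truth$term == "reward_c"]),
               unname(bR), tolerance = 1e-12)
})
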