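# The EVC allocation model: payoff/cost decomposition, logistic performance
# function, and the monotonicity of the optimal control surface in reward
# and efficacy.

test_that("success probability follows the logistic closed form", {
  p <- evc_params(performance_intercept = -1, performance_slope = 4,
                  congruency_penalty = 1)
  # linear predictor -1 + 4*0.5 - 1*2 = -1
  expect_equal(success_probability(0.5, "incongruent", p), 0.2689414,
               tolerance = 1e-6)
  # symmetric point: predictor 0 for congruent at u = 0.25
  expect_equal(success_probability(0.25, "congruent", p), 0.5)
  # monotone in control, decreasing in incongruence
  expect_true(success_probability(1, "neutral", p) >
                success_probability(0, "neutral", p))
  expect_true(all(diff(success_probability(seq(0, 1, 0.05), "neutral", p)) > 0))
  expect_true(success_probability(0.5, "congruent", p) >
                success_probability(0.5, "neutral", p))
  expect_error(success_probability(1.2, "neutral", p), "\\[0, 1\\]")
})

test_that("payoff degenerates correctly and reflects efficacy", {
  p0 <- evc_params(intrinsic_accuracy_value = 0)
  u <- seq(0, 1, 0.1)
  # zero efficacy, zero intrinsic value: flat payoff R * r0
  flat <- evc_payoff(u, incentive_condition(1, 0), params = p0)
  expect_equal(flat, rep(p0$noncontingent_reward_rate, length(u)))
  # zero reward, zero intrinsic value: identically zero
  expect_equal(evc_payoff(u, incentive_condition(0, 1), params = p0),
               rep(0, length(u)))
  # payoff spread between high and low control shrinks under low efficacy
  p <- evc_params()
  spread <- function(e) {
    po <- evc_payoff(c(0.2, 0.9), incentive_condition(1, e), params = p)
    po[2] - po[1]
  }
  expect_true(spread(0.25) < spread(1))
})

test_that("evc curve satisfies the payoff-minus-cost identity and argmax rules", {
  ec <- evc_curve(incentive_condition(1, 1), grid_size = 101)
  expect_equal(ec$evc, ec$payoff - ec$cost, tolerance = 1e-12)
  expect_true(ec$u_star %in% ec$u)
  # no cost, full efficacy, positive reward: all-in control
  free <- evc_curve(incentive_condition(1, 1),
                    params = evc_params(cost_coefficient = 0))
  expect_equal(free$u_star, 1)
  # zero efficacy and zero intrinsic value: no control worth the cost
  idle <- evc_curve(incentive_condition(1, 0),
                    params = evc_params(intrinsic_accuracy_value = 0))
  expect_equal(idle$u_star, 0)
  # ties break toward the smallest u (flat EVC at zero cost, zero reward)
  tie <- evc_curve(incentive_condition(0, 1),
                   params = evc_params(cost_coefficient = 0,
                                       intrinsic_accuracy_value = 0))
  expect_equal(tie$u_star, 0)
  expect_error(evc_curve(incentive_condition(1, 1), grid_size = 1), "grid_size")
})

test_that("grid argmax matches a fine-grid brute-force oracle", {
  p <- evc_params()
  for (cond in list(incentive_condition(0.1, 1), incentive_condition(1, 1),
                    incentive_condition(0.8, 0.5),
                    incentive_condition(0.4, 0.25))) {
    coarse <- evc_curve(cond, params = p, grid_size = 101)$u_star
    fine <- evc_curve(cond, params = p, grid_size = 10001)$u_star
    expect_lt(abs(coarse - fine), 1 / 100 + 1e-12)
  }
})

test_that("optimal control increases with reward and efficacy", {
  p <- evc_params()
  # higher reward at full efficacy commands more control
  expect_gt(evc_curve(incentive_condition(1, 1), params = p)$u_star,
            evc_curve(incentive_condition(0.1, 1), params = p)$u_star)
  s <- optimal_control_surface(seq(0.05, 1, length.out = 20),
                               seq(0.05, 1, length.out = 20), p)
  expect_true(all(apply(s, 2, function(x) all(diff(x) >= 0))))
  expect_true(all(apply(s, 1, function(x) all(diff(x) >= 0))))
  # reward-by-efficacy interaction of the shipped defaults
  s2 <- optimal_control_surface(c(0.1, 1), c(0, 1), p)
  expect_gte(s2[2, 2] - s2[1, 2], s2[2, 1] - s2[1, 1])
  # doubling rewards never lowers any optimum
  lv <- c(0.1, 0.2, 0.4, 0.8)
  expect_true(all(optimal_control_surface(2 * lv, c(0.25, 0.5, 0.75, 1), p) >=
                    optimal_control_surface(lv, c(0.25, 0.5, 0.75, 1), p)))
  # degenerate 1x1 input stays consistent with evc_curve
  expect_equal(unname(optimal_control_surface(0.4, 0.75, p)[1, 1]),
               evc_curve(incentive_condition(0.4, 0.75), params = p)$u_star)
})

test_that("parameter validation rejects out-of-domain inputs", {
  expect_error(incentive_condition(-1, 0.5), "reward_magnitude")
  expect_error(incentive_condition(1, 1.5), "efficacy")
  expect_error(evc_params(performance_slope = 0), "performance_slope")
  expect_error(evc_params(noncontingent_reward_rate = 2), "\\[0, 1\\]")
})
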