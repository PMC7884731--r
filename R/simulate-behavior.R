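# Behavioral simulation: control allocation via the EVC model, accurate-RT
# and accuracy generation with subject-level random variation, and the yoked
# reward schedule resolving non-performance-determined outcomes.

#' Draw subject-level random effects
#'
#' Independent zero-mean normal deviations per subject: RT intercept and
#' incentive slopes, accuracy intercept, per-component ERP offsets, and a
#' pupil cue-response offset, with SDs from the generator config.
#'
#' @param n_subjects Number of subjects.
#' @param gcfg A [generator_config()].
#' @param seed Integer seed.
#' @return A tibble with one row per subject.
#' @export
draw_subjects <- function(n_subjects, gcfg = generator_config(), seed = 1L) {
  stopifnot(inherits(gcfg, "generator_config"))
  set.seed(derive_seed(seed, 77L))
  s <- gcfg$subject
  tibble::tibble(
    subject = seq_len(n_subjects),
    rt_intercept = stats::rnorm(n_subjects, 0, s$rt_intercept_sd),
    rt_reward = stats::rnorm(n_subjects, 0, s$rt_reward_sd),
    rt_efficacy = stats::rnorm(n_subjects, 0, s$rt_efficacy_sd),
    rt_interaction = stats::rnorm(n_subjects, 0, s$rt_interaction_sd),
    acc_intercept = stats::rnorm(n_subjects, 0, s$acc_intercept_sd),
    p3b = stats::rnorm(n_subjects, 0, s$p3b_sd),
    cnv = stats::rnorm(n_subjects, 0, s$cnv_sd),
    ern = stats::rnorm(n_subjects, 0, s$ern_sd),
    frn = stats::rnorm(n_subjects, 0, s$frn_sd),
    pupil_cue = stats::rnorm(n_subjects, 0, s$pupil_cue_sd))
}

# Least-squares projection of condition-cell means onto the incentive
# regressor basis (intercept, xR, xE, xR*xE) with equal cell weights. For
# 2 x 2 designs this is exact (saturated); for parametric designs it is the
# linear-model estimand under a balanced design.
project_incentive_truth <- function(cells, means) {
  X <- cbind(1, cells$xR, cells$xE, cells$xR * cells$xE)
  b <- solve(crossprod(X), crossprod(X, means))
  c(intercept = b[1], reward_c = b[2], efficacy_c = b[3],
    `reward_c:efficacy_c` = b[4])
}

# u* for every reward x efficacy cell of a design config, with coded
# regressors attached. Allocation uses a neutral target because the cue
# carries no congruency information.
condition_table <- function(config, evc = evc_params(), grid_size = 101L) {
  cells <- expand.grid(reward = config$reward_levels,
                       efficacy = config$efficacy_levels,
                       KEEP.OUT.ATTRS = FALSE)
  cells$u_star <- vapply(seq_len(nrow(cells)), function(i) {
    evc_curve(incentive_condition(cells$reward[i], cells$efficacy[i]),
              "neutral", evc, grid_size)$u_star
  }, numeric(1))
  cells$xR <- incentive_coding(cells$reward, config$reward_levels)
  cells$xE <- incentive_coding(cells$efficacy, config$efficacy_levels)
  cells
}

#' Simulate trial-level behavior with yoked reward outcomes
#'
#' For each trial, control intensity is the EVC-maximizing `u_star` of the
#' cued condition; RT is built from the subject's intercept, control-driven
#' speeding, congruency slowing, a practice trend, incentive random slopes
#' and mean-centered lognormal noise, and is missing beyond the recording
#' window; accuracy is Bernoulli with log-odds linear in allocated control,
#' congruency and trial. Whether the outcome is performance-determined is
#' Bernoulli(efficacy); non-determined outcomes are drawn at the rolling
#' yoked rate of recent performance-determined outcomes
#' ([yoked_reward_probability()]).
#'
#' @param specs Chronological trial specs from [generate_design()].
#' @param subjects Subject effects from [draw_subjects()].
#' @param config The [design_config()] used to generate `specs`.
#' @param evc [evc_params()] governing control allocation.
#' @param gcfg [generator_config()] with planted effects and noise.
#' @param coupling Optional per-trial numeric vector added to RT (used to
#'   couple cue-ERP residual variation into behavior); must be aligned with
#'   `specs` rows.
#' @param seed Integer seed.
#' @param yoking_window Rolling window for the yoked rate (default 10).
#' @return A list with `records` (tibble: the columns of `specs` plus `u_star`, `rt`,
#'   `accuracy`, `criterion_met`, `performance_determined`, `rewarded`,
#'   `outcome_amount`) and `truth` (tibble of planted fixed effects for the
#'   behavioral models: model, term, value).
#' @export
simulate_behavior <- function(specs, subjects, config, evc = evc_params(),
                              gcfg = generator_config(), coupling = NULL,
                              seed = 1L, yoking_window = 10L) {
  stopifnot(inherits(config, "design_config"), inherits(gcfg, "generator_config"))
  if (is.unsorted(specs$trial[specs$subject == specs$subject[1]]))
    stop("trial specs must be chronological within subject")
  if (!is.null(coupling) && length(coupling) != nrow(specs))
    stop("coupling must align with specs rows")
  b <- gcfg$behavior
  cells <- condition_table(config, evc)
  d <- dplyr::left_join(specs, cells, by = c("reward", "efficacy"))
  d <- d[order(d$subject, d$trial), ]
  k <- congruency_step(d$congruency)
  d$trial_c <- stats::ave(d$trial, d$subject, FUN = function(t) trial_regressor(t))

  sub <- subjects[match(d$subject, subjects$subject), ]
  det_rt <- b$rt_intercept + sub$rt_intercept - b$rt_gain * d$u_star +
    sub$rt_reward * d$xR + sub$rt_efficacy * d$xE +
    sub$rt_interaction * d$xR * d$xE +
    b$rt_cong_step * k + b$rt_trend * d$trial_c +
    (coupling %||% 0)
  logit_acc <- b$acc_intercept + sub$acc_intercept + b$acc_slope * d$u_star +
    b$acc_cong_step * k + b$acc_trend * d$trial_c

  set.seed(derive_seed(seed, 101L))
  n <- nrow(d)
  noise <- stats::rlnorm(n, b$rt_noise_meanlog, b$rt_noise_sdlog) -
    exp(b$rt_noise_meanlog + b$rt_noise_sdlog^2 / 2)
  rt <- det_rt + noise
  lapse <- stats::runif(n) < b$lapse_rate
  rt[lapse | rt > config$recording_window] <- NA_real_
  accuracy <- as.integer(stats::runif(n) < stats::plogis(logit_acc))
  accuracy[is.na(rt)] <- 0L
  criterion_met <- as.integer(accuracy == 1L & !is.na(rt) &
                                rt < config$response_deadline)
  performance_determined <- as.integer(stats::runif(n) < d$efficacy)

  # Yoked outcome pass (chronological within subject).
  rewarded <- integer(n)
  rand_draw <- stats::runif(n)
  for (s in unique(d$subject)) {
    idx <- which(d$subject == s)
    hist <- numeric(0)
    for (i in idx) {
      if (performance_determined[i] == 1L) {
        rewarded[i] <- criterion_met[i]
        hist <- c(hist, rewarded[i])
      } else {
        p <- yoked_reward_probability(hist, yoking_window)
        rewarded[i] <- as.integer(rand_draw[i] < p)
      }
    }
  }
  d$rt <- rt
  d$accuracy <- accuracy
  d$criterion_met <- criterion_met
  d$performance_determined <- performance_determined
  d$rewarded <- rewarded
  d$outcome_amount <- rewarded * d$reward

  rt_truth <- project_incentive_truth(cells, -b$rt_gain * cells$u_star)
  acc_truth <- project_incentive_truth(cells, b$acc_slope * cells$u_star)
  truth <- tibble::tibble(
    model = rep(c("rt", "accuracy"), each = 6L),
    term = rep(c("reward_c", "efficacy_c", "rew_eff",
                 "cong_nc", "cong_in", "trial_c"), times = 2L),
    value = c(rt_truth[c("reward_c", "efficacy_c", "reward_c:efficacy_c")],
              b$rt_cong_step, b$rt_cong_step, b$rt_trend,
              acc_truth[c("reward_c", "efficacy_c", "reward_c:efficacy_c")],
              b$acc_cong_step, b$acc_cong_step, b$acc_trend))
  records <- d[, c("subject", "trial", "block", "reward", "efficacy",
                   "congruency", "u_star", "rt", "accuracy", "criterion_met",
                   "performance_determined", "rewarded", "outcome_amount")]
  list(records = tibble::as_tibble(records), truth = truth)
}
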