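# Declared generator parameters: every planted effect and noise magnitude of
# the synthetic experiment lives here, so that ground truth is explicit and
# recovery tests have a single authoritative source.

#' Generator configuration (planted effects and noise levels)
#'
#' Returns the declared parameter set of the synthetic experiment. The
#' defaults are fixtures chosen to produce incentive effects of realistic
#' magnitude and direction (reward and efficacy speed correct responses and
#' enlarge cue-locked ERP components; only the CNV carries the
#' reward-by-efficacy interaction; errors deepen the ERN; reward omission
#' deepens the FRN; higher efficacy shrinks the cue-evoked pupil response).
#' Any entry can be overridden by passing a partial nested list.
#'
#' Units: RT effects in ms, accuracy effects in log-odds, ERP effects in
#' microvolts, pupil effects in trace units. Trend coefficients are per 100
#' trials of the within-subject centered trial number.
#'
#' @param behavior,erp,pupil,subject Optional named lists overriding
#'   individual defaults within each block.
#' @return A nested list of class `generator_config`.
#' @export
generator_config <- function(behavior = list(), erp = list(), pupil = list(),
                             subject = list()) {
  def <- list(
    behavior = list(
      rt_intercept = 650,      # ms, grand mean at u* = 0, congruent target
      rt_gain = 30,            # ms of speeding per unit allocated control
      rt_cong_step = 30,       # ms slowing per congruency step
      rt_trend = -3,           # ms per 100 trials (practice speeding)
      rt_noise_meanlog = 5,    # lognormal residual (mean-centered before use)
      rt_noise_sdlog = 0.35,
      lapse_rate = 0.002,      # response missing (> recording window)
      rt_coupling_p3b = -7,    # ms per SD of cue-ERP residual (see vignette)
      rt_coupling_cnv = 15,
      acc_intercept = 1.3,     # log-odds correct at u* = 0, congruent
      acc_slope = 0.8,         # log-odds per unit allocated control
      acc_cong_step = -0.3,    # log-odds per congruency step
      acc_trend = 0.05),       # log-odds per 100 trials
    erp = list(
      p3b = list(intercept = 4, reward = 0.5, efficacy = 0.6, interaction = 0,
                 trend = -0.3, baseline_leak = 0, noise_sd = 2.5,
                 baseline_sd = 1.5),
      cnv = list(intercept = -2, reward = -0.4, efficacy = -0.45,
                 interaction = -0.5, trend = 0, p3b_leak = 0.16,
                 baseline_leak = -0.05, noise_sd = 2, baseline_sd = 1.5),
      ern = list(intercept = -2, accuracy = 4, cong_step = -0.5, reward = 0,
                 efficacy = 0, interaction = 0, noise_sd = 2),
      frn = list(intercept = 6, outcome = -2, reward = 0, efficacy = 0,
                 interaction = 0, noise_sd = 1.5),
      artifact_fraction = 0.05,  # waveform epochs injected with >150 uV spikes
      background_noise_sd = 8),  # 1/f-ish background in waveform epochs, uV
    pupil = list(
      fixation = 0.3, target = 0.8, response = 0.5, feedback = 0.6,
      cue_intercept = 0.85, cue_reward = 0.05, cue_efficacy = -0.3,
      cue_interaction = 0,
      noise_sd = 0.1,          # white noise on the continuous trace
      drift_sd = 0.05,         # slow within-session drift amplitude
      blink_rate = 0.05,       # blinks per second
      blink_duration = 0.12,   # s
      coef_noise_sd = 0.05),   # coefficient-layer measurement noise
    subject = list(
      rt_intercept_sd = 30, rt_reward_sd = 5, rt_efficacy_sd = 5,
      rt_interaction_sd = 5, acc_intercept_sd = 0.3,
      p3b_sd = 1, cnv_sd = 0.8, ern_sd = 0.8, frn_sd = 0.8,
      pupil_cue_sd = 0.1))
  out <- def
  out$behavior <- utils::modifyList(def$behavior, behavior)
  out$erp <- utils::modifyList(def$erp, erp)
  out$pupil <- utils::modifyList(def$pupil, pupil)
  out$subject <- utils::modifyList(def$subject, subject)
  structure(out, class = "generator_config")
}

# Incentive regressor coding shared by the generator (ground truth) and the
# analysis-table builder: +/-0.5 effect coding for two-level factors,
# level-set standardization for parametric designs. Balanced designs make
# this identical to within-subject mean-centering in expectation.
incentive_coding <- function(value, levels) {
  levels <- sort(unique(levels))
  if (length(levels) == 1L) return(rep(0, length(value)))
  if (length(levels) == 2L)
    return(ifelse(value == levels[2L], 0.5, -0.5))
  (value - mean(levels)) / stats::sd(levels)
}

# Sliding-difference (repeated) congruency contrasts: coefficients estimate
# (neutral - congruent) and (incongruent - neutral).
congruency_contrasts <- function(congruency) {
  k <- congruency_step(congruency)
  list(cong_nc = ifelse(k == 0, -2 / 3, 1 / 3),
       cong_in = ifelse(k == 2, 2 / 3, -1 / 3))
}

# Centered trial-number regressor in per-100-trial units.
trial_regressor <- function(trial) (trial - mean(trial)) / 100
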