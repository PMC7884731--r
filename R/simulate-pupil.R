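# Forward simulation of continuous pupil recordings: every task event
# (fixation, cue, target, response, feedback) contributes an Erlang-gamma
# impulse response scaled by its planted amplitude; slow drift, white noise,
# and blink gaps are added on top. A lighter coefficient layer generates the
# per-subject deconvolution outputs directly for large recovery runs.

PUPIL_RATE <- 500

# Event schedule for one subject's session, following the cued-Stroop trial
# timeline (fixation ~0.75 s, cue 1.5 s, target, response after RT, feedback
# 0.8 s post-response, then inter-trial interval).
pupil_event_schedule <- function(records, seed = 1L) {
  set.seed(derive_seed(seed, 404L))
  n <- nrow(records)
  ev <- vector("list", n)
  t <- 0.5
  for (i in seq_len(n)) {
    fix <- t
    cue <- fix + stats::runif(1, 0.5, 1.0)
    target <- cue + 1.75
    rt_s <- if (is.na(records$rt[i])) NA_real_ else records$rt[i] / 1000
    response <- if (is.na(rt_s)) NA_real_ else target + rt_s
    feedback <- if (is.na(response)) target + 1.8 else response + 0.8
    ev[[i]] <- tibble::tibble(
      trial = records$trial[i],
      type = c("fixation", "cue", "target", "response", "feedback"),
      time = c(fix, cue, target, response, feedback))
    t <- feedback + 0.75 + stats::runif(1, 0.5, 1.0)
  }
  out <- dplyr::bind_rows(ev)
  out[!is.na(out$time), ]
}

#' Simulate a continuous pupil recording for one subject
#'
#' Builds the session event schedule from the subject's trial records,
#' assigns each event its planted amplitude (cue amplitudes are linear in
#' the coded reward and efficacy regressors; other event types have fixed
#' amplitudes), and forward-convolves the resulting pulse train with the
#' unit-peak Erlang-gamma impulse response at 500 Hz. Slow sinusoidal drift,
#' white noise, and blink gaps (masked spans at a configured rate and
#' duration) are superimposed.
#'
#' @param records One subject's trial records (chronological).
#' @param subject_row The subject's row from [draw_subjects()] (supplies the
#'   cue-response offset); may be NULL for none.
#' @param gcfg A [generator_config()].
#' @param params An [irf_params()] object.
#' @param seed Integer seed.
#' @return A list with `series` (a [pupil_series()] with blink mask),
#'   `events` (tibble: trial, type, time, group, amplitude; cue events are
#'   grouped by incentive condition), and `truth` (planted fixed effects of
#'   the cue-amplitude model).
#' @export
simulate_pupil <- function(records, subject_row = NULL,
                           gcfg = generator_config(), params = irf_params(),
                           seed = 1L) {
  stopifnot(length(unique(records$subject)) == 1L)
  p <- gcfg$pupil
  ev <- pupil_event_schedule(records, seed)
  xR <- incentive_coding(records$reward, unique(records$reward))
  xE <- incentive_coding(records$efficacy, unique(records$efficacy))
  cue_amp <- p$cue_intercept + (subject_row$pupil_cue %||% 0) +
    p$cue_reward * xR + p$cue_efficacy * xE + p$cue_interaction * xR * xE
  i <- match(ev$trial, records$trial)
  ev$amplitude <- dplyr::case_when(
    ev$type == "fixation" ~ p$fixation,
    ev$type == "cue" ~ cue_amp[i],
    ev$type == "target" ~ p$target,
    ev$type == "response" ~ p$response,
    TRUE ~ p$feedback)
  ev$group <- ev$type
  cue_rows <- ev$type == "cue"
  ev$group[cue_rows] <- paste0("cue_R", records$reward[i[cue_rows]],
                               "_E", records$efficacy[i[cue_rows]])

  dur <- max(ev$time) + 6 * params$t_max
  n <- as.integer(ceiling(dur * PUPIL_RATE))
  pulse <- numeric(n)
  idx <- as.integer(round(ev$time * PUPIL_RATE)) + 1L
  for (j in seq_along(idx)) pulse[idx[j]] <- pulse[idx[j]] + ev$amplitude[j]
  kern_len <- as.integer(round(PUPIL_RATE * 6 * params$t_max))
  kern <- erlang_irf((seq_len(kern_len) - 1) / PUPIL_RATE, params)
  trace <- convolve_causal(pulse, kern)

  set.seed(derive_seed(seed, 405L))
  tt <- (seq_len(n) - 1) / PUPIL_RATE
  drift <- p$drift_sd * sin(2 * pi * tt / dur * stats::runif(1, 1, 3) +
                              stats::runif(1, 0, 2 * pi))
  trace <- trace + drift + stats::rnorm(n, 0, p$noise_sd)

  blink <- rep(FALSE, n)
  n_blink <- stats::rpois(1, p$blink_rate * dur)
  if (n_blink > 0) {
    onsets <- sort(stats::runif(n_blink, 1, dur - 1))
    len <- as.integer(round(p$blink_duration * PUPIL_RATE))
    for (o in onsets) {
      j0 <- as.integer(round(o * PUPIL_RATE)) + 1L
      j1 <- min(n, j0 + len - 1L)
      if (j1 > n) stop("blink extends beyond trace")
      blink[j0:j1] <- TRUE
      trace[j0:j1] <- 0  # lost samples
    }
  }
  truth <- tibble::tibble(
    model = "pupil_cue",
    term = c("reward_c", "efficacy_c", "rew_eff"),
    value = c(p$cue_reward, p$cue_efficacy, p$cue_interaction))
  list(series = pupil_series(trace, PUPIL_RATE, blink), events = ev,
       truth = truth)
}

#' Simulate per-subject, per-condition pupil cue coefficients directly
#'
#' Coefficient-layer counterpart of the full trace pipeline: for each
#' subject and reward-by-efficacy cell, the deconvolved cue-response
#' magnitude is drawn as the planted condition amplitude plus measurement
#' noise. Used for large statistical-recovery runs, where the trace-level
#' forward-then-inverse path (validated separately) would only add runtime.
#'
#' @param config A [design_config()].
#' @param subjects Subject effects from [draw_subjects()].
#' @param gcfg A [generator_config()].
#' @param seed Integer seed.
#' @return A list with `coefficients` (tibble: subject, reward, efficacy,
#'   coefficient) and `truth`.
#' @export
simulate_pupil_coefficients <- function(config, subjects,
                                        gcfg = generator_config(), seed = 1L) {
  p <- gcfg$pupil
  cells <- expand.grid(reward = config$reward_levels,
                       efficacy = config$efficacy_levels,
                       KEEP.OUT.ATTRS = FALSE)
  xR <- incentive_coding(cells$reward, config$reward_levels)
  xE <- incentive_coding(cells$efficacy, config$efficacy_levels)
  d <- tidyr::expand_grid(subject = subjects$subject, cell = seq_len(nrow(cells)))
  set.seed(derive_seed(seed, 406L))
  d$reward <- cells$reward[d$cell]
  d$efficacy <- cells$efficacy[d$cell]
  d$coefficient <- p$cue_intercept +
    subjects$pupil_cue[match(d$subject, subjects$subject)] +
    p$cue_reward * xR[d$cell] + p$cue_efficacy * xE[d$cell] +
    p$cue_interaction * xR[d$cell] * xE[d$cell] +
    stats::rnorm(nrow(d), 0, p$coef_noise_sd)
  truth <- tibble::tibble(
    model = "pupil_cue",
    term = c("reward_c", "efficacy_c", "rew_eff"),
    value = c(p$cue_reward, p$cue_efficacy, p$cue_interaction))
  list(coefficients = tibble::as_tibble(d[, c("subject", "reward", "efficacy",
                                              "coefficient")]),
       truth = truth)
}
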