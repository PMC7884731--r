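# Expected value of control (EVC): payoff minus effort cost over a grid of
# candidate control intensities, and the intensity that maximizes the
# difference. Reward and efficacy enter the payoff; effort enters the cost.

#' Incentive condition (reward magnitude and efficacy)
#'
#' A trial's incentive state: the monetary reward at stake and the efficacy,
#' i.e. the probability that the trial's outcome is determined by performance
#' rather than by a random draw.
#'
#' @param reward_magnitude Reward at stake in dollars (>= 0).
#' @param efficacy Probability in \[0, 1\] that performance determines the
#'   outcome. 1 means fully performance-contingent, 0 means the outcome is
#'   decided by a (yoked) coin flip.
#' @return An object of class `incentive_condition`.
#' @export
#' @examples
#' incentive_condition(1.00, 1)    # high reward, high efficacy
#' incentive_condition(0.10, 0.25) # low reward, low efficacy
incentive_condition <- function(reward_magnitude, efficacy) {
  stopifnot(is.numeric(reward_magnitude), is.numeric(efficacy),
            length(reward_magnitude) == 1L, length(efficacy) == 1L)
  if (!is.finite(reward_magnitude) || reward_magnitude < 0)
    stop("reward_magnitude must be finite and >= 0")
  if (!is.finite(efficacy) || efficacy < 0 || efficacy > 1)
    stop("efficacy must lie in [0, 1]")
  structure(list(reward_magnitude = reward_magnitude, efficacy = efficacy),
            class = "incentive_condition")
}

#' EVC model parameters
#'
#' Parameters of the control-allocation model. Success probability is
#' logistic in control intensity `u` with a per-step congruency penalty;
#' effort cost is quadratic in `u`; the payoff mixes performance-contingent
#' and noncontingent reward according to efficacy, plus a small intrinsic
#' value of being correct (nonzero so that some control is worth investing
#' even at zero efficacy).
#'
#' @param cost_coefficient Curvature of the effort cost c * u^2 (>= 0),
#'   currency-equivalent units.
#' @param performance_intercept Log-odds of criterion success at u = 0 for a
#'   congruent target.
#' @param performance_slope Log-odds gain per unit control (> 0).
#' @param congruency_penalty Log-odds lost per congruency step
#'   (congruent -> neutral -> incongruent), >= 0.
#' @param intrinsic_accuracy_value Currency-equivalent value of an accurate
#'   response independent of payout (>= 0).
#' @param noncontingent_reward_rate Probability of reward on trials whose
#'   outcome is not performance-determined, in \[0, 1\]. Free-standing model
#'   parameter; the synthetic experiment instead yokes this rate empirically.
#' @return An object of class `evc_params`.
#' @export
evc_params <- function(cost_coefficient = 0.5,
                       performance_intercept = -1,
                       performance_slope = 4,
                       congruency_penalty = 1,
                       intrinsic_accuracy_value = 0.05,
                       noncontingent_reward_rate = 0.7) {
  p <- list(cost_coefficient = cost_coefficient,
            performance_intercept = performance_intercept,
            performance_slope = performance_slope,
            congruency_penalty = congruency_penalty,
            intrinsic_accuracy_value = intrinsic_accuracy_value,
            noncontingent_reward_rate = noncontingent_reward_rate)
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                  logical(1))))
    stop("all evc_params fields must be finite scalars")
  if (cost_coefficient < 0) stop("cost_coefficient must be >= 0")
  if (performance_slope <= 0) stop("performance_slope must be > 0")
  if (congruency_penalty < 0) stop("congruency_penalty must be >= 0")
  if (intrinsic_accuracy_value < 0) stop("intrinsic_accuracy_value must be >= 0")
  if (noncontingent_reward_rate < 0 || noncontingent_reward_rate > 1)
    stop("noncontingent_reward_rate must lie in [0, 1]")
  structure(p, class = "evc_params")
}

congruency_step <- function(congruency) {
  lev <- c(congruent = 0, neutral = 1, incongruent = 2)
  congruency <- as.character(congruency)
  if (!all(congruency %in% names(lev)))
    stop("congruency must be one of 'congruent', 'neutral', 'incongruent'")
  unname(lev[congruency])
}

#' Probability of criterion success as a function of control intensity
#'
#' Logistic in control: plogis(intercept + slope * u - penalty * k), where k
#' counts congruency steps (0 congruent, 1 neutral, 2 incongruent). Strictly
#' increasing in `u`, decreasing in incongruence.
#'
#' @param u Control intensity in \[0, 1\] (vectorized).
#' @param congruency One of `"congruent"`, `"neutral"`, `"incongruent"`
#'   (scalar or vector recycled against `u`).
#' @param params An [evc_params()] object.
#' @return Success probabilities.
#' @export
#' @examples
#' success_probability(0.5, "incongruent",
#'   evc_params(performance_intercept = -1, performance_slope = 4,
#'              congruency_penalty = 1))
success_probability <- function(u, congruency = "neutral", params = evc_params()) {
  stopifnot(inherits(params, "evc_params"), is.numeric(u))
  if (any(!is.finite(u)) || any(u < 0 | u > 1))
    stop("control intensity u must lie in [0, 1]")
  k <- congruency_step(congruency)
  stats::plogis(params$performance_intercept + params$performance_slope * u -
                  params$congruency_penalty * k)
}

#' Expected payoff of a control intensity
#'
#' The payoff weighs the performance-contingent reward path by efficacy and
#' the noncontingent path by its complement:
#' R * (E * P(u) + (1 - E) * r0) + v_acc * P(u), with P(u) the success
#' probability. At zero efficacy and zero intrinsic accuracy value the payoff
#' is flat in `u`, so no control is worth its cost.
#'
#' @param u Control intensity in \[0, 1\] (vectorized).
#' @param cond An [incentive_condition()].
#' @param congruency Congruency level used for P(u).
#' @param params An [evc_params()] object.
#' @return Expected payoff (currency-equivalent), same length as `u`.
#' @export
evc_payoff <- function(u, cond, congruency = "neutral", params = evc_params()) {
  stopifnot(inherits(cond, "incentive_condition"))
  p <- success_probability(u, congruency, params)
  cond$reward_magnitude *
    (cond$efficacy * p + (1 - cond$efficacy) * params$noncontingent_reward_rate) +
    params$intrinsic_accuracy_value * p
}

#' EVC curve over a control-intensity grid
#'
#' Evaluates payoff, quadratic effort cost, and their difference (the EVC) on
#' an evenly spaced grid over \[0, 1\], and records the maximizing intensity
#' `u_star` (ties broken toward the smallest u, since effort is costly).
#'
#' @param cond An [incentive_condition()].
#' @param congruency Congruency level (default `"neutral"`, the cue gives no
#'   congruency information so allocation cannot condition on it).
#' @param params An [evc_params()] object.
#' @param grid_size Number of grid points (>= 2; default 101).
#' @return An object of class `evc_curve`: list with `u`, `payoff`, `cost`,
#'   `evc` (numeric vectors) and `u_star`.
#' @export
#' @examples
#' ec <- evc_curve(incentive_condition(1, 1))
#' ec$u_star
evc_curve <- function(cond, congruency = "neutral", params = evc_params(),
                      grid_size = 101L) {
  if (!is.numeric(grid_size) || length(grid_size) != 1L || grid_size < 2)
    stop("grid_size must be >= 2")
  u <- seq(0, 1, length.out = as.integer(grid_size))
  payoff <- evc_payoff(u, cond, congruency, params)
  cost <- params$cost_coefficient * u^2
  evc <- payoff - cost
  structure(list(u = u, payoff = payoff, cost = cost, evc = evc,
                 u_star = u[which.max(evc)],
                 cond = cond, congruency = congruency),
            class = "evc_curve")
}

#' @export
print.evc_curve <- function(x, ...) {
  cat(sprintf(
    "EVC curve: R = $%.2f, E = %.2f, %s target; %d grid points, u* = %.3f\n",
    x$cond$reward_magnitude, x$cond$efficacy, x$congruency, length(x$u),
    x$u_star))
  invisible(x)
}

#' Export an EVC curve as a data frame
#'
#' @param x An `evc_curve`.
#' @param row.names,optional,... Passed through for S3 compatibility.
#' @return A data frame with columns `u`, `payoff`, `cost`, `evc`.
#' @export
as.data.frame.evc_curve <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(u = x$u, payoff = x$payoff, cost = x$cost, evc = x$evc)
}

#' Optimal-control surface over reward and efficacy levels
#'
#' Computes `u_star` for every combination of the supplied reward and
#' efficacy levels. Under the default parameterization the surface is
#' nondecreasing along both axes: more reward and more efficacy both justify
#' more control.
#'
#' @param reward_levels Nonempty numeric vector of reward magnitudes.
#' @param efficacy_levels Nonempty numeric vector of efficacy levels.
#' @param params An [evc_params()] object.
#' @param congruency Congruency level for the underlying curves.
#' @param grid_size Grid resolution per curve.
#' @return Matrix of u_star values, rewards in rows, efficacies in columns.
#' @export
optimal_control_surface <- function(reward_levels, efficacy_levels,
                                    params = evc_params(),
                                    congruency = "neutral", grid_size = 101L) {
  if (length(reward_levels) == 0L || length(efficacy_levels) == 0L)
    stop("reward_levels and efficacy_levels must be nonempty")
  out <- matrix(NA_real_, length(reward_levels), length(efficacy_levels),
                dimnames = list(paste0("R", reward_levels),
                                paste0("E", efficacy_levels)))
  for (i in seq_along(reward_levels)) {
    for (j in seq_along(efficacy_levels)) {
      out[i, j] <- evc_curve(
        incentive_condition(reward_levels[i], efficacy_levels[j]),
        congruency, params, grid_size)$u_star
    }
  }
  out
}
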