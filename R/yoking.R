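# The yoked reward schedule: on trials whose outcome is not determined by
# performance, reward is drawn with the rolling reward rate observed on
# recent performance-determined trials, equating expected reward across
# efficacy levels.

#' Rolling yoked reward probability
#'
#' Mean of the last `window` outcomes (0/1 reward indicators) observed on
#' performance-determined (high-efficacy) trials. With fewer than `window`
#' outcomes available, all available history is used; with no history at all
#' the probability defaults to 0.5 (an unbiased cold-start).
#'
#' @param high_eff_outcomes Chronological 0/1 vector of reward outcomes on
#'   performance-determined trials so far.
#' @param window Rolling window size (default 10).
#' @return A probability.
#' @export
#' @examples
#' yoked_reward_probability(c(0, 1, 1, 0, 1, 1, 1, 0, 1, 1, 1, 0, 1))  # last 10
yoked_reward_probability <- function(high_eff_outcomes, window = 10L) {
  if (!is.numeric(window) || length(window) != 1L || window < 0)
    stop("window must be a nonnegative count")
  if (length(high_eff_outcomes) == 0L) return(0.5)
  if (!all(high_eff_outcomes %in% c(0, 1)))
    stop("high_eff_outcomes must be 0/1 indicators")
  n <- length(high_eff_outcomes)
  k <- min(n, as.integer(window))
  if (k == 0L) return(0.5)
  mean(high_eff_outcomes[(n - k + 1L):n])
}
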