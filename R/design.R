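# Trial-design generation for the three study layouts: dichotomous reward x
# efficacy cues (Studies 1-2) and the parametric 4 x 4 version (Study 3),
# with congruent/neutral/incongruent Stroop targets balanced within block.

study_defaults <- function(study) {
  switch(as.character(study),
    "1" = list(n_subjects = 21L, blocks = 4L, trials_per_block = 75L,
               reward_levels = c(0.10, 1.00), efficacy_levels = c(0, 1)),
    "2" = list(n_subjects = 44L, blocks = 8L, trials_per_block = 75L,
               reward_levels = c(0.10, 1.00), efficacy_levels = c(0, 1)),
    "3" = list(n_subjects = 35L, blocks = 4L, trials_per_block = 75L,
               reward_levels = c(0.10, 0.20, 0.40, 0.80),
               efficacy_levels = c(0.25, 0.50, 0.75, 1.00)),
    stop("study must be 1, 2, or 3"))
}

#' Design configuration for a synthetic incentive-Stroop study
#'
#' Captures the layout of one study: cue conditions (reward and efficacy
#' levels), block structure, congruency mix, and response timing. Defaults
#' follow the three study layouts: Study 1, 4 blocks of 75 trials with
#' $0.10/$1.00 rewards and 0/100% efficacy; Study 2, 8 blocks of 75; Study 3,
#' 300 trials crossing rewards $0.10/$0.20/$0.40/$0.80 with efficacies
#' 25/50/75/100%. The response deadline is 750 ms; responses are recorded up
#' to 1000 ms.
#'
#' @param study Study layout, 1, 2 or 3.
#' @param n_subjects Number of simulated participants.
#' @param blocks Blocks per subject.
#' @param trials_per_block Trials per block.
#' @param reward_levels Reward magnitudes (dollars).
#' @param efficacy_levels Efficacy levels (probabilities).
#' @param congruency_proportions Length-3 vector (congruent, neutral,
#'   incongruent) summing to 1.
#' @param response_deadline Criterion deadline in ms (default 750).
#' @param recording_window Response recording window in ms (default 1000);
#'   later responses are treated as missing.
#' @param seed Integer seed controlling design randomization.
#' @return An object of class `design_config`.
#' @export
design_config <- function(study = 2, n_subjects = NULL, blocks = NULL,
                          trials_per_block = NULL, reward_levels = NULL,
                          efficacy_levels = NULL,
                          congruency_proportions = c(1, 1, 1) / 3,
                          response_deadline = 750, recording_window = 1000,
                          seed = 1L) {
  d <- study_defaults(study)
  cfg <- list(study = as.integer(study),
              n_subjects = as.integer(n_subjects %||% d$n_subjects),
              blocks = as.integer(blocks %||% d$blocks),
              trials_per_block = as.integer(trials_per_block %||% d$trials_per_block),
              reward_levels = reward_levels %||% d$reward_levels,
              efficacy_levels = efficacy_levels %||% d$efficacy_levels,
              congruency_proportions = congruency_proportions,
              response_deadline = response_deadline,
              recording_window = recording_window,
              seed = as.integer(seed))
  if (length(cfg$reward_levels) == 0L || length(cfg$efficacy_levels) == 0L)
    stop("reward_levels and efficacy_levels must be nonempty")
  if (length(cfg$congruency_proportions) != 3L ||
      abs(sum(cfg$congruency_proportions) - 1) > 1e-9)
    stop("congruency_proportions must be a 3-vector summing to 1")
  if (cfg$n_subjects < 1L || cfg$blocks < 1L || cfg$trials_per_block < 1L)
    stop("n_subjects, blocks and trials_per_block must be positive")
  structure(cfg, class = "design_config")
}

# Balanced assignment of `n` trials to `levels`, each level within one trial
# of n / length(levels); remainder cells chosen at random without replacement.
balanced_fill <- function(levels, n) {
  k <- length(levels)
  base <- rep(seq_len(k), floor(n / k))
  rem <- n - length(base)
  if (rem > 0) base <- c(base, sample.int(k, rem))
  levels[sample(base)]
}

#' Generate the chronological trial design for every subject
#'
#' Produces one row per trial with the cued incentive condition and target
#' congruency. Reward-by-efficacy cells are balanced within each block (up to
#' rounding); congruency follows the configured proportions within block.
#' Deterministic given `config$seed`.
#'
#' @param config A [design_config()].
#' @return A tibble with columns `subject`, `trial` (1-based, chronological
#'   within subject), `block`, `reward`, `efficacy`, `congruency`.
#' @export
generate_design <- function(config) {
  stopifnot(inherits(config, "design_config"))
  cells <- expand.grid(reward = config$reward_levels,
                       efficacy = config$efficacy_levels,
                       KEEP.OUT.ATTRS = FALSE)
  cong_levels <- c("congruent", "neutral", "incongruent")
  out <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    set.seed(derive_seed(config$seed, 1000L + s))
    blocks <- vector("list", config$blocks)
    for (b in seq_len(config$blocks)) {
      n <- config$trials_per_block
      cell_idx <- balanced_fill(seq_len(nrow(cells)), n)
      # congruency proportions within block, remainder randomized
      n_cong <- floor(config$congruency_proportions * n)
      rem <- n - sum(n_cong)
      extra <- if (rem > 0) sample.int(3L, rem, prob = config$congruency_proportions) else integer(0)
      cong <- sample(c(rep(seq_len(3L), n_cong), extra))
      blocks[[b]] <- tibble::tibble(
        subject = s, block = b,
        reward = cells$reward[cell_idx],
        efficacy = cells$efficacy[cell_idx],
        congruency = cong_levels[cong])
    }
    d <- dplyr::bind_rows(blocks)
    d$trial <- seq_len(nrow(d))
    out[[s]] <- d[, c("subject", "trial", "block", "reward", "efficacy",
                      "congruency")]
  }
  dplyr::bind_rows(out)
}
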