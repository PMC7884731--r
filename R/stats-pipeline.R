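# Hierarchical regression stage: single-trial analysis table construction
# (within-subject centering, sliding-difference congruency contrasts,
# within-subject z-scored ERP amplitudes), mixed-effects fitting with
# singularity-driven random-slope pruning, and the model families for
# behavior, cue ERPs, ERP-to-behavior coupling, outcome ERPs, and pupil
# coefficients.

#' Build the single-trial analysis table
#'
#' Merges trial records with (optionally) single-trial ERP amplitudes, and
#' constructs the model regressors: effect-coded reward and efficacy
#' (+/-0.5 for two-level designs, standardized levels for parametric ones)
#' and their product `rew_eff`; sliding-difference congruency contrasts
#' `cong_nc` (neutral - congruent) and `cong_in` (incongruent - neutral);
#' within-subject centered trial number (`trial_c`, per 100 trials);
#' centered response accuracy (`acc_c`) and reward receipt (`rewarded_c`);
#' and, when ERP data are present, within-subject centered baselines
#' (`p3b_base_c`, `cnv_base_c`), centered P3b (`p3b_c`) and within-subject
#' z-scored amplitudes (`p3b_z`, `cnv_z`). Trials with rejected epochs keep
#' their behavioral columns but carry NA ERP regressors.
#'
#' @param records Trial records from [simulate_behavior()].
#' @param erp Optional amplitude table (subject, trial, p3b, cnv, ern_crn,
#'   frn, p3b_baseline, cnv_baseline, rejected).
#' @return A tibble, one row per trial.
#' @export
build_analysis_table <- function(records, erp = NULL) {
  if (anyDuplicated(records[, c("subject", "trial")]))
    stop("duplicate subject/trial keys in records")
  d <- records
  d$reward_c <- incentive_coding(d$reward, unique(d$reward))
  d$efficacy_c <- incentive_coding(d$efficacy, unique(d$efficacy))
  d$rew_eff <- d$reward_c * d$efficacy_c
  cc <- congruency_contrasts(d$congruency)
  d$cong_nc <- cc$cong_nc
  d$cong_in <- cc$cong_in
  d$trial_c <- stats::ave(d$trial, d$subject, FUN = function(t) trial_regressor(t))
  d$acc_c <- d$accuracy - 0.5
  d$rewarded_c <- d$rewarded - 0.5
  if (!is.null(erp)) {
    if (anyDuplicated(erp[, c("subject", "trial")]))
      stop("duplicate subject/trial keys in erp table")
    e <- erp
    e$p3b[e$rejected] <- e$cnv[e$rejected] <- NA_real_
    d <- dplyr::left_join(d, e, by = c("subject", "trial"))
    d$p3b_base_c <- center_within(d$p3b_baseline, d$subject)
    d$cnv_base_c <- center_within(d$cnv_baseline, d$subject)
    d$p3b_c <- center_within(d$p3b, d$subject)
    d$p3b_z <- zscore_within(d$p3b, d$subject)
    d$cnv_z <- zscore_within(d$cnv, d$subject)
    d$acc_rew <- d$acc_c * d$reward_c
    d$acc_eff <- d$acc_c * d$efficacy_c
    d$out_rew <- d$rewarded_c * d$reward_c
    d$out_eff <- d$rewarded_c * d$efficacy_c
  }
  tibble::as_tibble(d)
}

re_variances <- function(fit, group = "subject") {
  vc <- as.data.frame(lme4::VarCorr(fit))
  vc <- vc[grepl(paste0("^", group), vc$grp) & is.na(vc$var2), ]
  stats::setNames(vc$vcov, vc$var1)
}

build_formula <- function(response, fixed, random_slopes, group) {
  re <- if (length(random_slopes) == 0L) sprintf("(1 | %s)", group)
  else sprintf("(1 + %s || %s)", paste(random_slopes, collapse = " + "), group)
  stats::as.formula(paste(response, "~", paste(c(fixed, re), collapse = " + ")))
}

#' Fit a mixed-effects model with singularity-driven random-slope pruning
#'
#' Fits the declared random structure (independent random intercept and
#' slopes per subject). If the random-effects covariance is singular --
#' smallest singular value below `tol` relative to the largest (for the
#' diagonal structure used here, the variances are the singular values) --
#' the slope with the smallest variance share is removed and the model
#' refit, down to a random intercept if necessary. Fixed-effect p-values use
#' the large-sample normal approximation.
#'
#' @param response Response column name.
#' @param fixed Character vector of fixed-effect column names.
#' @param data Analysis table (rows with NA in used columns are dropped).
#' @param family `"gaussian"` (fit by ML) or `"binomial"` (logit link).
#' @param random_slopes Character vector of declared random-slope columns.
#' @param group Grouping column (default `"subject"`).
#' @param tol Relative singular-value tolerance (default 1e-6).
#' @return An object of class `evc_fit`: `terms` (tibble with estimate, se,
#'   statistic, p, ci_lo, ci_hi), `random` (named variances), `singular`,
#'   `pruning_path`, `logLik`, `nobs`, `family`, `formula`, and the lme4
#'   `fit`.
#' @export
fit_mixed <- function(response, fixed, data, family = "gaussian",
                      random_slopes = character(0), group = "subject",
                      tol = 1e-6) {
  family <- match.arg(family, c("gaussian", "binomial"))
  used <- unique(c(response, fixed, group))
  data <- data[stats::complete.cases(data[, used]), used]
  if (nrow(data) == 0L) stop("no complete observations for model ", response)
  if (length(unique(data[[group]])) < 2L)
    stop("two-level model needs >= 2 groups (", group, ")")
  if (family == "binomial") {
    y <- data[[response]]
    if (length(unique(y)) < 2L)
      stop("complete separation: binomial response '", response,
           "' is constant")
  }
  slopes <- random_slopes
  path <- character(0)
  repeat {
    fml <- build_formula(response, fixed, slopes, group)
    fit <- withCallingHandlers(
      if (family == "gaussian")
        lme4::lmer(fml, data = data, REML = FALSE,
                   control = lme4::lmerControl(calc.derivs = FALSE))
      else
        lme4::glmer(fml, data = data, family = stats::binomial(),
                    control = lme4::glmerControl(calc.derivs = FALSE)),
      message = function(m) invokeRestart("muffleMessage"),
      warning = function(w) invokeRestart("muffleWarning"))
    v <- re_variances(fit, group)
    rel <- if (max(v) == 0) 0 else min(v) / max(v)
    if (rel >= tol || length(slopes) == 0L) break
    sv <- v[setdiff(names(v), "(Intercept)")]
    drop <- names(sv)[which.min(sv)]
    path <- c(path, drop)
    slopes <- setdiff(slopes, drop)
  }
  b <- lme4::fixef(fit)
  se <- sqrt(Matrix::diag(stats::vcov(fit)))
  z <- b / se
  ci <- stats::qnorm(0.975) * se
  structure(list(
    terms = tibble::tibble(term = names(b), estimate = unname(b),
                           se = unname(se), statistic = unname(z),
                           p = 2 * stats::pnorm(-abs(unname(z))),
                           ci_lo = unname(b - ci), ci_hi = unname(b + ci)),
    random = re_variances(fit, group),
    singular = lme4::isSingular(fit, tol = tol),
    pruning_path = path,
    logLik = as.numeric(stats::logLik(fit)),
    nobs = nrow(data),
    family = family,
    formula = deparse1(build_formula(response, fixed, slopes, group)),
    fit = fit), class = "evc_fit")
}

#' @export
print.evc_fit <- function(x, ...) {
  cat(sprintf("<evc_fit> %s, n = %d, logLik = %.1f%s\n", x$formula, x$nobs,
              x$logLik,
              if (length(x$pruning_path)) paste0(" (pruned: ",
                paste(x$pruning_path, collapse = ", "), ")") else ""))
  print(as.data.frame(x$terms), digits = 3)
  invisible(x)
}

BEHAVIOR_FIXED <- c("reward_c", "efficacy_c", "rew_eff", "cong_nc", "cong_in",
                    "trial_c")

#' Behavioral models: accurate RT and accuracy
#'
#' Accurate RTs (correct responses within the recording window) are modeled
#' with a linear mixed model; accuracy with a binomial-logit mixed model.
#' Fixed effects: reward, efficacy, their interaction, the two congruency
#' contrasts, and trial number. The RT model declares incentive random
#' slopes; the accuracy model a random intercept.
#'
#' @param table Analysis table from [build_analysis_table()].
#' @return A list of two `evc_fit` objects: `rt` and `accuracy`.
#' @export
behavior_models <- function(table) {
  rt_dat <- table[table$accuracy == 1 & !is.na(table$rt), ]
  list(
    rt = fit_mixed("rt", BEHAVIOR_FIXED, rt_dat,
                   random_slopes = c("reward_c", "efficacy_c", "rew_eff")),
    accuracy = fit_mixed("accuracy", BEHAVIOR_FIXED, table,
                         family = "binomial"))
}

#' Cue-locked ERP models (P3b and CNV)
#'
#' P3b: reward, efficacy, their interaction, trial, and the centered P3b
#' baseline. CNV: the same plus the centered P3b amplitude (to absorb
#' component overlap) and the centered CNV baseline. Rejected epochs are
#' excluded via their NA amplitudes.
#'
#' @param table Analysis table with ERP columns.
#' @return A list of two `evc_fit` objects: `p3b` and `cnv`.
#' @export
erp_models <- function(table) {
  list(
    p3b = fit_mixed("p3b", c("reward_c", "efficacy_c", "rew_eff", "trial_c",
                             "p3b_base_c"), table),
    cnv = fit_mixed("cnv", c("reward_c", "efficacy_c", "rew_eff", "trial_c",
                             "p3b_c", "cnv_base_c"), table))
}

ERP_BEHAVIOR_FIXED <- c("efficacy_c", "reward_c", "p3b_z", "cnv_z", "cong_in",
                        "cong_nc", "cnv_base_c", "trial_c", "rew_eff")

#' Sign-aligned equal-slope comparison of the two cue ERPs
#'
#' Likelihood-ratio test between the full model (separate P3b and CNV
#' slopes) and a model constraining the two slopes to equal magnitude with
#' opposite sign (the CNV is negative-going, so its behavioral slope is
#' sign-flipped before equating). Both models are fit by maximum likelihood;
#' the statistic is chi-square with 1 df.
#'
#' @param table Analysis table with ERP columns.
#' @param response `"rt"` (accurate RTs) or `"accuracy"`.
#' @return List with `chisq`, `df`, `p`, and the two `evc_fit` objects.
#' @export
compare_erp_slopes <- function(table, response = "rt") {
  response <- match.arg(response, c("rt", "accuracy"))
  dat <- if (response == "rt")
    table[table$accuracy == 1 & !is.na(table$rt), ] else table
  family <- if (response == "rt") "gaussian" else "binomial"
  dat$erp_diff <- dat$cnv_z - dat$p3b_z
  full <- fit_mixed(response, ERP_BEHAVIOR_FIXED, dat, family = family)
  constrained <- fit_mixed(
    response, c(setdiff(ERP_BEHAVIOR_FIXED, c("p3b_z", "cnv_z")), "erp_diff"),
    dat, family = family)
  chisq <- max(0, 2 * (full$logLik - constrained$logLik))
  list(chisq = chisq, df = 1L,
       p = stats::pchisq(chisq, 1L, lower.tail = FALSE),
       full = full, constrained = constrained)
}

#' ERP-to-behavior models (accuracy and accurate RT with ERP predictors)
#'
#' Extends the behavioral models with within-subject z-scored P3b and CNV
#' amplitudes and the centered CNV-epoch baseline as predictors, and runs
#' the sign-aligned equal-slope comparison for the RT model.
#'
#' @param table Analysis table with ERP columns.
#' @return List with `accuracy`, `rt` (`evc_fit`) and `slope_comparison`
#'   (from [compare_erp_slopes()], RT response).
#' @export
erp_to_behavior_models <- function(table) {
  rt_dat <- table[table$accuracy == 1 & !is.na(table$rt), ]
  list(
    accuracy = fit_mixed("accuracy", ERP_BEHAVIOR_FIXED, table,
                         family = "binomial"),
    rt = fit_mixed("rt", ERP_BEHAVIOR_FIXED, rt_dat),
    slope_comparison = compare_erp_slopes(table, "rt"))
}

#' Outcome-monitoring models (ERN/CRN and FRN)
#'
#' ERN/CRN: response accuracy, congruency contrasts, incentives, their
#' interactions with accuracy, and trial. FRN: reward receipt, incentives,
#' their interactions with receipt, and trial.
#'
#' @param table Analysis table with ERP columns.
#' @return A list of two `evc_fit` objects: `ern` and `frn`.
#' @export
outcome_models <- function(table) {
  list(
    ern = fit_mixed("ern_crn", c("acc_c", "cong_nc", "cong_in", "reward_c",
                                 "efficacy_c", "rew_eff", "acc_rew", "acc_eff",
                                 "trial_c"), table),
    frn = fit_mixed("frn", c("rewarded_c", "reward_c", "efficacy_c", "rew_eff",
                             "out_rew", "out_eff", "trial_c"), table))
}

#' Pupil cue-coefficient model
#'
#' Mixed model of the deconvolved cue-response magnitudes on reward,
#' efficacy, and their interaction, with a subject random intercept.
#'
#' @param coefficients Tibble with columns `subject`, `reward`, `efficacy`,
#'   `coefficient` (one row per subject and condition).
#' @return An `evc_fit`.
#' @export
pupil_models <- function(coefficients) {
  d <- coefficients
  if (length(unique(d$subject)) < 2L)
    stop("two-level model needs >= 2 subjects")
  d$reward_c <- incentive_coding(d$reward, unique(d$reward))
  d$efficacy_c <- incentive_coding(d$efficacy, unique(d$efficacy))
  d$rew_eff <- d$reward_c * d$efficacy_c
  fit_mixed("coefficient", c("reward_c", "efficacy_c", "rew_eff"), d)
}
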