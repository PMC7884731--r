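# Single-trial ERP quantification: baseline correction over [-200, 0) ms,
# threshold/gradient artifact rejection, windowed ROI mean amplitudes
# (P3b, CNV, ERN/CRN), peak-to-peak FRN scoring, and split-half reliability.

#' Baseline-correct an epoch set
#'
#' Subtracts, per trial and channel, the mean amplitude over the pre-anchor
#' interval \[-200, 0) ms. The subtracted means are returned so they can
#' serve as nuisance covariates in the statistical models.
#'
#' @param es An `epoch_set` whose window includes \[-200, 0) ms.
#' @return A list with `epochs` (corrected `epoch_set`) and `baselines`
#'   (trial x channel matrix of subtracted means, channels in columns).
#' @export
baseline_correct <- function(es) {
  stopifnot(inherits(es, "epoch_set"))
  bl_idx <- which(es$times_ms >= -200 - 1e-9 & es$times_ms < 0 - 1e-9)
  if (length(bl_idx) == 0L ||
      min(es$times_ms) > -200 + 1000 / es$sampling_rate + 1e-6)
    stop("epoch window does not cover the [-200, 0) ms baseline interval")
  # trial x channel means over the baseline samples
  bl <- apply(es$data[, , bl_idx, drop = FALSE], c(1, 2), mean)
  es$data <- es$data - array(rep(bl, dim(es$data)[3]), dim(es$data))
  colnames(bl) <- es$channels
  list(epochs = es, baselines = bl)
}

#' Artifact rejection by amplitude and gradient thresholds
#'
#' Flags an epoch when any channel sample exceeds `amp_limit` in absolute
#' value, or any absolute difference between successive samples exceeds
#' `gradient_limit`. Invariant to trial and channel ordering.
#'
#' @param es A baseline-corrected `epoch_set`.
#' @param amp_limit Absolute amplitude limit in microvolts (default 150).
#' @param gradient_limit Successive-sample difference limit in microvolts
#'   (default 50).
#' @return Logical vector, `TRUE` for rejected epochs.
#' @export
reject_artifacts <- function(es, amp_limit = 150, gradient_limit = 50) {
  stopifnot(inherits(es, "epoch_set"))
  nt <- dim(es$data)[3]
  amp_bad <- apply(abs(es$data), 1, max) > amp_limit
  grad <- abs(es$data[, , -1, drop = FALSE] - es$data[, , -nt, drop = FALSE])
  grad_bad <- apply(grad, 1, max) > gradient_limit
  amp_bad | grad_bad
}

#' Windowed ROI mean amplitude per trial
#'
#' Mean over the closed time window (sample-inclusive at both ends) and the
#' listed ROI channels.
#'
#' @param es An `epoch_set`.
#' @param window Length-2 ms range within the epoch.
#' @param channels ROI channel names (must exist in `es`).
#' @return Numeric vector, one amplitude per trial.
#' @export
mean_amplitude <- function(es, window, channels) {
  stopifnot(inherits(es, "epoch_set"))
  if (!all(channels %in% es$channels))
    stop("unknown ROI channel(s): ",
         paste(setdiff(channels, es$channels), collapse = ", "))
  idx <- window_samples(es$times_ms, window)
  if (length(idx) == 0L || window[1] < min(es$times_ms) - 1e-9 ||
      window[2] > max(es$times_ms) + 1e-9)
    stop("window not contained in epoch")
  ch <- match(channels, es$channels)
  apply(es$data[, ch, idx, drop = FALSE], 1, mean)
}

#' Peak-to-peak FRN amplitude
#'
#' Locates the negative peak (minimum) between 250 and 350 ms post-feedback
#' at the given channel, then the positive peak (maximum) within the 100 ms
#' strictly preceding that minimum's latency, and returns their difference
#' (positive peak minus negative peak). A flat epoch scores 0.
#'
#' @param es A feedback-locked `epoch_set` covering at least \[150, 350\] ms.
#' @param channel Channel name (default `"FCz"`).
#' @param trough_window Search window for the negative peak, ms.
#' @return Numeric vector of peak-to-peak amplitudes per trial.
#' @export
frn_peak_to_peak <- function(es, channel = "FCz", trough_window = c(250, 350)) {
  stopifnot(inherits(es, "epoch_set"))
  if (!channel %in% es$channels) stop("unknown channel: ", channel)
  if (min(es$times_ms) > 150 || max(es$times_ms) < trough_window[2])
    stop("epoch must cover [150, 350] ms post-feedback")
  ch <- match(channel, es$channels)
  tw <- window_samples(es$times_ms, trough_window)
  vapply(seq_len(dim(es$data)[1]), function(i) {
    x <- es$data[i, ch, ]
    ti <- tw[which.min(x[tw])]
    t_trough <- es$times_ms[ti]
    pre <- which(es$times_ms >= t_trough - 100 - 1e-9 &
                   es$times_ms < t_trough - 1e-9)
    if (length(pre) == 0L) return(0)
    max(x[pre]) - x[ti]
  }, numeric(1))
}

#' Split-half reliability of a per-trial measure
#'
#' Per subject, averages the measure over odd- and even-numbered trials and
#' returns the Pearson correlation of the two subject-level vectors.
#' Subjects with fewer than one valid trial per half are excluded with a
#' warning.
#'
#' @param values Per-trial measure (NAs dropped).
#' @param trial Trial numbers (parity defines the halves).
#' @param subject Subject ids.
#' @return Pearson correlation between odd- and even-half subject means.
#' @export
split_half_reliability <- function(values, trial, subject) {
  stopifnot(length(values) == length(trial), length(trial) == length(subject))
  d <- data.frame(values, trial, subject)[!is.na(values), ]
  odd <- tapply(d$values[d$trial %% 2 == 1], d$subject[d$trial %% 2 == 1], mean)
  even <- tapply(d$values[d$trial %% 2 == 0], d$subject[d$trial %% 2 == 0], mean)
  subj <- intersect(names(odd), names(even))
  if (length(subj) < length(unique(d$subject)))
    warning("excluding subject(s) without trials in both halves")
  if (length(subj) < 2L) stop("need >= 2 subjects with both halves")
  stats::cor(odd[subj], even[subj])
}

#' Quantify a set of simulated epoch sets into a single-trial amplitude table
#'
#' Applies baseline correction and artifact rejection to the cue-locked
#' epochs, extracts windowed mean amplitudes (P3b 250-550 ms over Pz/P3/P4;
#' CNV 1000-1500 ms over Fz/FCz/Cz; ERN/CRN 0-100 ms at FCz, response-locked)
#' and the feedback-locked peak-to-peak FRN at FCz. ROI-mean baselines of the
#' P3b and CNV ROIs are returned as covariates. Rejected cue epochs carry no
#' cue-locked amplitudes.
#'
#' @param epoch_sets Named list with elements `cue`, `response`, `feedback`
#'   as produced by [simulate_eeg_epochs()].
#' @return Tibble with columns `subject`, `trial`, `p3b`, `cnv`, `ern_crn`,
#'   `frn`, `p3b_baseline`, `cnv_baseline`, `rejected`.
#' @export
quantify_epochs <- function(epoch_sets) {
  cue <- epoch_sets$cue
  stopifnot(inherits(cue, "epoch_set"))
  bc <- baseline_correct(cue)
  rej <- reject_artifacts(bc$epochs)
  p3b <- mean_amplitude(bc$epochs, P3B_WINDOW, P3B_ROI)
  cnv <- mean_amplitude(bc$epochs, CNV_WINDOW, CNV_ROI)
  p3b_bl <- rowMeans(bc$baselines[, P3B_ROI, drop = FALSE])
  cnv_bl <- rowMeans(bc$baselines[, CNV_ROI, drop = FALSE])
  p3b[rej] <- cnv[rej] <- p3b_bl[rej] <- cnv_bl[rej] <- NA_real_
  out <- tibble::tibble(subject = cue$subject, trial = cue$trial,
                        p3b = p3b, cnv = cnv,
                        ern_crn = NA_real_, frn = NA_real_,
                        p3b_baseline = p3b_bl, cnv_baseline = cnv_bl,
                        rejected = rej)
  if (!is.null(epoch_sets$response)) {
    rbc <- baseline_correct(epoch_sets$response)
    rrej <- reject_artifacts(rbc$epochs)
    ern <- mean_amplitude(rbc$epochs, ERN_WINDOW, ERN_ROI)
    ern[rrej] <- NA_real_
    i <- match(paste(epoch_sets$response$subject, epoch_sets$response$trial),
               paste(out$subject, out$trial))
    out$ern_crn[i] <- ern
  }
  if (!is.null(epoch_sets$feedback)) {
    fbc <- baseline_correct(epoch_sets$feedback)
    frej <- reject_artifacts(fbc$epochs)
    frn <- frn_peak_to_peak(fbc$epochs)
    frn[frej] <- NA_real_
    i <- match(paste(epoch_sets$feedback$subject, epoch_sets$feedback$trial),
               paste(out$subject, out$trial))
    out$frn[i] <- frn
  }
  out
}
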