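# Single-trial ERP generation in two layers. The amplitude layer draws the
# planted single-trial component amplitudes (the quantities the downstream
# models analyze); the waveform layer renders those amplitudes into 512 Hz
# multichannel epochs whose quantification reproduces the planted values
# exactly in the noise-free case.

EEG_CHANNELS <- c("Fz", "FCz", "Cz", "Pz", "P3", "P4")
EEG_RATE <- 512
P3B_WINDOW <- c(250, 550)
P3B_ROI <- c("Pz", "P3", "P4")
CNV_WINDOW <- c(1000, 1500)
CNV_ROI <- c("Fz", "FCz", "Cz")
ERN_WINDOW <- c(0, 100)
ERN_ROI <- "FCz"
FRN_CHANNEL <- "FCz"

# Cue-locked component draw. Depends on the trial design (condition, trial
# number) and subject offsets only -- not on behavior -- so cue-stage neural
# variability can feed forward into RT.
cue_amplitude_components <- function(specs, subjects, gcfg = generator_config(),
                                     seed = 1L) {
  e <- gcfg$erp
  n <- nrow(specs)
  xR <- incentive_coding(specs$reward, unique(specs$reward))
  xE <- incentive_coding(specs$efficacy, unique(specs$efficacy))
  xRE <- xR * xE
  trial_c <- stats::ave(specs$trial, specs$subject,
                        FUN = function(t) trial_regressor(t))
  sub <- subjects[match(specs$subject, subjects$subject), ]
  set.seed(derive_seed(seed, 202L))
  p3b_base <- stats::rnorm(n, 0, e$p3b$baseline_sd)
  cnv_base <- stats::rnorm(n, 0, e$cnv$baseline_sd)
  p3b_resid <- stats::rnorm(n, 0, e$p3b$noise_sd)
  cnv_noise <- stats::rnorm(n, 0, e$cnv$noise_sd)
  p3b <- e$p3b$intercept + sub$p3b + e$p3b$reward * xR + e$p3b$efficacy * xE +
    e$p3b$interaction * xRE + e$p3b$trend * trial_c +
    e$p3b$baseline_leak * p3b_base + p3b_resid
  cnv <- e$cnv$intercept + sub$cnv + e$cnv$reward * xR + e$cnv$efficacy * xE +
    e$cnv$interaction * xRE + e$cnv$trend * trial_c + e$cnv$p3b_leak * p3b +
    e$cnv$baseline_leak * cnv_base + cnv_noise
  tibble::tibble(subject = specs$subject, trial = specs$trial,
                 p3b = p3b, cnv = cnv,
                 p3b_baseline = p3b_base, cnv_baseline = cnv_base,
                 p3b_resid = p3b_resid,
                 cnv_resid = e$cnv$p3b_leak * p3b_resid + cnv_noise)
}

#' Simulate single-trial ERP amplitudes with planted incentive effects
#'
#' Cue-locked P3b and CNV amplitudes are linear in the coded incentive
#' regressors: the P3b carries reward and efficacy main effects (no
#' interaction), the CNV additionally carries the reward-by-efficacy
#' interaction and a leak term proportional to the same trial's P3b
#' (component overlap). Response-locked ERN/CRN depends on response accuracy
#' and congruency; feedback-locked FRN depends on reward receipt. Baseline
#' values are drawn per trial and leak into the measured amplitudes with
#' configured coefficients. Every planted coefficient is returned in the
#' ground-truth table.
#'
#' @param records Trial records from [simulate_behavior()].
#' @param subjects Subject effects from [draw_subjects()].
#' @param gcfg A [generator_config()].
#' @param seed Integer seed.
#' @param cue Optional predrawn cue components (internal); when supplied,
#'   the cue-locked draw is reused rather than redrawn, which lets the same
#'   residuals feed both the epochs and the RT coupling.
#' @return A list with `amplitudes` (tibble: subject, trial, p3b, cnv,
#'   ern_crn, frn, p3b_baseline, cnv_baseline, rejected), `truth` (planted
#'   fixed effects keyed by model/term), and `resid` (tibble of the
#'   incentive-orthogonal residual components of P3b and CNV, usable for
#'   coupling cue-stage neural variability into RT).
#' @export
simulate_erp_amplitudes <- function(records, subjects, gcfg = generator_config(),
                                    seed = 1L, cue = NULL) {
  e <- gcfg$erp
  n <- nrow(records)
  xR <- incentive_coding(records$reward, unique(records$reward))
  xE <- incentive_coding(records$efficacy, unique(records$efficacy))
  xRE <- xR * xE
  k <- congruency_step(records$congruency)
  sub <- subjects[match(records$subject, subjects$subject), ]

  cue <- cue %||% cue_amplitude_components(records, subjects, gcfg, seed)
  stopifnot(nrow(cue) == n)
  p3b <- cue$p3b
  cnv <- cue$cnv
  p3b_base <- cue$p3b_baseline
  cnv_base <- cue$cnv_baseline

  set.seed(derive_seed(seed, 203L))
  acc_c <- records$accuracy - 0.5
  ern <- e$ern$intercept + sub$ern + e$ern$accuracy * acc_c +
    e$ern$cong_step * k + e$ern$reward * xR + e$ern$efficacy * xE +
    e$ern$interaction * xRE + stats::rnorm(n, 0, e$ern$noise_sd)
  ern[is.na(records$rt)] <- NA_real_  # no response, no response-locked epoch

  out_c <- records$rewarded - 0.5
  frn <- e$frn$intercept + sub$frn + e$frn$outcome * out_c +
    e$frn$reward * xR + e$frn$efficacy * xE + e$frn$interaction * xRE +
    stats::rnorm(n, 0, e$frn$noise_sd)

  truth <- tibble::tibble(
    model = c(rep("p3b", 5L), rep("cnv", 6L), rep("ern", 9L), rep("frn", 7L)),
    term = c(
      "reward_c", "efficacy_c", "rew_eff", "trial_c", "p3b_base_c",
      "reward_c", "efficacy_c", "rew_eff", "trial_c", "p3b_c", "cnv_base_c",
      "acc_c", "cong_nc", "cong_in", "reward_c", "efficacy_c", "rew_eff",
      "acc_rew", "acc_eff", "trial_c",
      "rewarded_c", "reward_c", "efficacy_c", "rew_eff", "out_rew", "out_eff",
      "trial_c"),
    value = c(
      e$p3b$reward, e$p3b$efficacy, e$p3b$interaction, e$p3b$trend,
      e$p3b$baseline_leak,
      e$cnv$reward, e$cnv$efficacy, e$cnv$interaction, e$cnv$trend,
      e$cnv$p3b_leak, e$cnv$baseline_leak,
      e$ern$accuracy, e$ern$cong_step, e$ern$cong_step, e$ern$reward,
      e$ern$efficacy, e$ern$interaction, 0, 0, 0,
      e$frn$outcome, e$frn$reward, e$frn$efficacy, e$frn$interaction, 0, 0, 0))

  list(
    amplitudes = tibble::tibble(
      subject = records$subject, trial = records$trial,
      p3b = p3b, cnv = cnv, ern_crn = ern, frn = frn,
      p3b_baseline = p3b_base, cnv_baseline = cnv_base, rejected = FALSE),
    truth = truth,
    resid = tibble::tibble(subject = records$subject, trial = records$trial,
                           p3b_resid = cue$p3b_resid,
                           cnv_resid = cue$cnv_resid))
}

# Sample indices (1-based) of an epoch time axis falling inside a closed
# window in ms. Shared by the waveform generator and the quantifier so that
# planted and recovered windowed means agree sample-for-sample.
window_samples <- function(times_ms, window) {
  which(times_ms >= window[1] - 1e-9 & times_ms <= window[2] + 1e-9)
}

epoch_times_ms <- function(window_ms, rate = EEG_RATE) {
  n0 <- ceiling(window_ms[1] / 1000 * rate)
  n1 <- floor(window_ms[2] / 1000 * rate)
  (n0:n1) / rate * 1000
}

# Raised-cosine bump supported on [t0, t1] ms, peak 1 at the midpoint.
raised_cosine <- function(times_ms, t0, t1) {
  w <- numeric(length(times_ms))
  i <- times_ms >= t0 & times_ms <= t1
  w[i] <- 0.5 * (1 - cos(2 * pi * (times_ms[i] - t0) / (t1 - t0)))
  w
}

# Channel topographies, normalized so the quantification ROI has mean
# weight 1 (planted amplitude == quantified ROI-window mean).
component_topography <- function(component) {
  w <- switch(component,
    p3b = c(Fz = 0.2, FCz = 0.3, Cz = 0.5, Pz = 1.0, P3 = 0.9, P4 = 0.9),
    cnv = c(Fz = 0.9, FCz = 1.0, Cz = 1.1, Pz = 0.4, P3 = 0.3, P4 = 0.3),
    ern = c(Fz = 0.8, FCz = 1.0, Cz = 0.9, Pz = 0.3, P3 = 0.2, P4 = 0.2),
    frn = c(Fz = 0.8, FCz = 1.0, Cz = 0.9, Pz = 0.3, P3 = 0.2, P4 = 0.2),
    stop("unknown component"))
  roi <- switch(component, p3b = P3B_ROI, cnv = CNV_ROI, ern = ERN_ROI,
                frn = FRN_CHANNEL)
  w / mean(w[roi])
}

# Temporal template normalized so its mean over the quantification window
# equals 1 (P3b/CNV/ERN) or so the peak-to-peak read-out equals 1 (FRN).
component_template <- function(component, times_ms) {
  tv <- switch(component,
    p3b = raised_cosine(times_ms, P3B_WINDOW[1], P3B_WINDOW[2]),
    cnv = pmax(0, (times_ms - CNV_WINDOW[1]) / diff(CNV_WINDOW)) *
      (times_ms <= CNV_WINDOW[2]),
    ern = raised_cosine(times_ms, ERN_WINDOW[1], ERN_WINDOW[2]),
    frn = {
      # positive bump peaking ~221 ms, trough ~301 ms (disjoint supports so
      # the peak-to-peak read-out is exactly the planted amplitude)
      pos_c <- round(0.221 * EEG_RATE) / EEG_RATE * 1000
      neg_c <- round(0.301 * EEG_RATE) / EEG_RATE * 1000
      0.5 * raised_cosine(times_ms, pos_c - 40, pos_c + 40) -
        0.5 * raised_cosine(times_ms, neg_c - 30, neg_c + 30)
    },
    stop("unknown component"))
  if (component != "frn") {
    win <- switch(component, p3b = P3B_WINDOW, cnv = CNV_WINDOW, ern = ERN_WINDOW)
    tv <- tv / mean(tv[window_samples(times_ms, win)])
  }
  tv
}

#' Construct an epoch set
#'
#' Container for a stack of fixed-length event-locked EEG epochs: a trial x
#' channel x time array with its time axis (ms relative to the anchor
#' event), channel names, and per-epoch subject/trial ids.
#'
#' @param data Numeric array, trial x channel x time.
#' @param times_ms Time axis in ms (length matching `dim(data)[3]`).
#' @param channels Unique channel names (length matching `dim(data)[2]`).
#' @param anchor Anchor event label (e.g. `"cue"`).
#' @param subject,trial Per-epoch ids (length matching `dim(data)[1]`).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, times_ms, channels, anchor, subject, trial) {
  stopifnot(length(dim(data)) == 3L, dim(data)[2] == length(channels),
            dim(data)[3] == length(times_ms), !anyDuplicated(channels))
  structure(list(data = data, times_ms = times_ms, sampling_rate = EEG_RATE,
                 channels = channels, anchor = anchor,
                 subject = subject, trial = trial),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %s-locked: %d epochs x %d channels x %d samples (%g Hz, %g..%g ms)\n",
              x$anchor, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$sampling_rate, min(x$times_ms), max(x$times_ms)))
  invisible(x)
}

# AR(1) background noise shaped like low-frequency-dominated EEG.
background_noise <- function(n_trial, n_chan, n_time, sd, phi = 0.97) {
  if (sd <= 0) return(array(0, c(n_trial, n_chan, n_time)))
  e <- array(stats::rnorm(n_trial * n_chan * n_time, 0, sd * sqrt(1 - phi^2)),
             c(n_trial, n_chan, n_time))
  for (t in 2:n_time) e[, , t] <- phi * e[, , t - 1] + e[, , t]
  e
}

#' Render planted ERP amplitudes into multichannel 512 Hz epochs
#'
#' Builds cue- (-200..1500 ms), stimulus-, response-, and feedback-locked
#' (-200..800 ms) epochs. Each component is a fixed temporal template times a
#' fixed topography, scaled by the trial's planted amplitude; per-trial
#' baseline values are added as constant offsets (parietal offsets carry the
#' P3b baseline, frontocentral offsets the CNV baseline). With background
#' noise disabled, quantification of these epochs returns the planted
#' amplitudes exactly. A configured fraction of cue epochs receives a
#' deterministic >150 microvolt artifact spike.
#'
#' @param records Trial records from [simulate_behavior()].
#' @param amplitudes Amplitude table from [simulate_erp_amplitudes()].
#' @param gcfg A [generator_config()]; `erp$background_noise_sd` and
#'   `erp$artifact_fraction` control noise and artifact injection.
#' @param anchors Which epoch sets to generate.
#' @param seed Integer seed.
#' @return A named list of `epoch_set` objects plus `artifact_trials`
#'   (indices into `records` rows injected with artifacts).
#' @export
simulate_eeg_epochs <- function(records, amplitudes, gcfg = generator_config(),
                                anchors = c("cue", "stimulus", "response",
                                            "feedback"),
                                seed = 1L) {
  stopifnot(nrow(records) == nrow(amplitudes))
  n <- nrow(records)
  set.seed(derive_seed(seed, 303L))
  n_art <- round(gcfg$erp$artifact_fraction * n)
  artifact_trials <- if (n_art > 0) sort(sample.int(n, n_art)) else integer(0)
  out <- list()

  add_component <- function(arr, times, component, amp) {
    tv <- component_template(component, times)
    wv <- component_topography(component)[EEG_CHANNELS]
    pat <- as.numeric(wv %o% tv)
    amp[is.na(amp)] <- 0
    arr + array(amp %o% pat, dim(arr))
  }
  add_offset <- function(arr, channels_on, offset) {
    m <- as.numeric(EEG_CHANNELS %in% channels_on)
    arr + array(offset %o% as.numeric(m %o% rep(1, dim(arr)[3])), dim(arr))
  }

  for (anchor in anchors) {
    win <- if (anchor == "cue") c(-200, 1500) else c(-200, 800)
    times <- epoch_times_ms(win)
    keep <- if (anchor == "response") which(!is.na(records$rt)) else seq_len(n)
    arr <- background_noise(length(keep), length(EEG_CHANNELS), length(times),
                            gcfg$erp$background_noise_sd)
    if (anchor == "cue") {
      arr <- add_component(arr, times, "p3b", amplitudes$p3b[keep])
      arr <- add_component(arr, times, "cnv", amplitudes$cnv[keep])
      arr <- add_offset(arr, P3B_ROI, amplitudes$p3b_baseline[keep])
      arr <- add_offset(arr, CNV_ROI, amplitudes$cnv_baseline[keep])
      if (length(artifact_trials) > 0) {
        spike_at <- which.min(abs(times - 700))
        arr[match(artifact_trials, keep), which(EEG_CHANNELS == "Cz"),
            spike_at] <- 200
      }
    } else if (anchor == "response") {
      arr <- add_component(arr, times, "ern", amplitudes$ern_crn[keep])
    } else if (anchor == "feedback") {
      arr <- add_component(arr, times, "frn", amplitudes$frn[keep])
    }
    out[[anchor]] <- epoch_set(arr, times, EEG_CHANNELS, anchor,
                                   records$subject[keep], records$trial[keep])
  }
  out$artifact_trials <- artifact_trials
  out
}

#' Write an epoch set as a flat binary array with a JSON sidecar
#'
#' @param es An `epoch_set`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_epochs <- function(es, dir) {
  stopifnot(inherits(es, "epoch_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "epochs.f64"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(es$data, c(3, 2, 1))), con, size = 8,
           endian = "little")
  jsonlite::write_json(
    list(anchor = es$anchor, sampling_rate = es$sampling_rate,
         channels = es$channels, times_ms = es$times_ms,
         dim = dim(es$data), subject = es$subject, trial = es$trial,
         layout = "time-fastest, then channel, then trial; float64 little-endian"),
    file.path(dir, "epochs.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an epoch set written by [write_epochs()]
#'
#' @param dir Directory containing `epochs.f64` and `epochs.json`.
#' @return An `epoch_set`.
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "epochs.json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  x <- readBin(file.path(dir, "epochs.f64"), "double", n = n, size = 8,
               endian = "little")
  data <- aperm(array(x, rev(meta$dim)), c(3, 2, 1))
  epoch_set(data, meta$times_ms, meta$channels, meta$anchor,
                meta$subject, meta$trial)
}
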