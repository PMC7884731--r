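# Pupil preprocessing and event-related deconvolution. The pupillary
# response to each task event is modeled as a causal Erlang-gamma impulse
# response; per-event-type magnitudes are estimated by ordinary least
# squares against regressors built by superposing impulse responses at the
# event times.

#' Erlang-gamma impulse-response parameters
#'
#' Shape `n` and response-maximum latency `t_max` of the pupillary impulse
#' response h(t) = t^n exp(-n t / t_max). Defaults n = 10.1 and
#' t_max = 1.30 s follow established empirical estimates.
#'
#' @param n Shape parameter (> 0).
#' @param t_max Latency of the response maximum in seconds (> 0).
#' @return An object of class `irf_params`.
#' @export
irf_params <- function(n = 10.1, t_max = 1.30) {
  if (!is.numeric(n) || n <= 0 || !is.numeric(t_max) || t_max <= 0)
    stop("irf_params: n and t_max must be positive")
  structure(list(n = n, t_max = t_max), class = "irf_params")
}

#' Erlang-gamma pupil impulse response (unit peak)
#'
#' h(t) = t^n exp(-n t / t_max), rescaled to peak amplitude 1 so that event
#' coefficients are expressed in trace units (the unnormalized form has
#' magnitude t_max^n, numerically hostile at n ~ 10). The response is causal:
#' h(t) = 0 for t <= 0. Its maximum is attained exactly at t = t_max
#' (d/dt log h = n/t - n/t_max vanishes there).
#'
#' @param t Time since event onset in seconds (vectorized; negative times
#'   return 0).
#' @param params An [irf_params()] object.
#' @return Response values with peak 1 at `t = t_max`.
#' @export
#' @examples
#' erlang_irf(c(0, 0.65, 1.30, 2.60))
erlang_irf <- function(t, params = irf_params()) {
  stopifnot(inherits(params, "irf_params"))
  h <- numeric(length(t))
  pos <- which(t > 0)
  r <- t[pos] / params$t_max
  h[pos] <- exp(params$n * (log(r) + 1 - r))
  h
}

#' Pupil time series
#'
#' Lightweight container for a uniformly sampled pupil-diameter recording.
#'
#' @param diameter Numeric samples (arbitrary or z units).
#' @param rate Sampling rate in Hz.
#' @param blink Optional logical blink mask (same length as `diameter`).
#' @param start_time Time of the first sample in seconds.
#' @return An object of class `pupil_series`.
#' @export
pupil_series <- function(diameter, rate, blink = NULL, start_time = 0) {
  stopifnot(is.numeric(diameter), rate > 0)
  blink <- blink %||% rep(FALSE, length(diameter))
  stopifnot(length(blink) == length(diameter))
  structure(list(diameter = as.numeric(diameter), rate = rate,
                 blink = as.logical(blink), start_time = start_time),
            class = "pupil_series")
}

#' @export
print.pupil_series <- function(x, ...) {
  cat(sprintf("<pupil_series> %d samples at %g Hz (%.1f s), %d blink samples\n",
              length(x$diameter), x$rate, length(x$diameter) / x$rate,
              sum(x$blink)))
  invisible(x)
}

series_times <- function(series)
  series$start_time + (seq_along(series$diameter) - 1L) / series$rate

#' Linearly interpolate blink gaps
#'
#' Replaces samples from `pad` ms before each blink onset to `pad` ms after
#' its offset by linear interpolation between the nearest valid boundary
#' samples. Blinks abutting the trace edge are extended from the nearest
#' valid sample.
#'
#' @param series A [pupil_series()] with a blink mask.
#' @param pad Padding around each blink in ms (default 200).
#' @return The interpolated `pupil_series` (blink mask cleared).
#' @export
interpolate_blinks <- function(series, pad = 200) {
  stopifnot(inherits(series, "pupil_series"))
  if (!any(series$blink)) return(series)
  n <- length(series$diameter)
  pad_n <- round(pad / 1000 * series$rate)
  bad <- series$blink
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    lo <- max(1L, starts[i] - pad_n)
    hi <- min(n, ends[i] + pad_n)
    bad[lo:hi] <- TRUE
  }
  good <- which(!bad)
  if (length(good) < 2L) stop("not enough valid samples to interpolate blinks")
  x <- series$diameter
  x[bad] <- stats::approx(good, x[good], xout = which(bad), rule = 2)$y
  pupil_series(x, series$rate, NULL, series$start_time)
}

#' Downsample and normalize a pupil series
#'
#' Decimates to `out_rate` by non-overlapping block means (anti-aliasing by
#' averaging), then optionally z-scores the whole series (subtract the mean
#' of all samples, divide by their SD) as a within-subject normalization.
#'
#' @param series A blink-interpolated [pupil_series()].
#' @param out_rate Output rate in Hz (default 20); must divide the input rate.
#' @param normalize Z-score the output (default TRUE). Raw units are kept
#'   when recovering amplitudes in the input scale.
#' @return A [pupil_series()] at `out_rate`.
#' @export
preprocess_pupil <- function(series, out_rate = 20, normalize = TRUE) {
  stopifnot(inherits(series, "pupil_series"))
  fac <- series$rate / out_rate
  if (abs(fac - round(fac)) > 1e-9)
    stop("out_rate must divide the input sampling rate")
  fac <- as.integer(round(fac))
  n_out <- floor(length(series$diameter) / fac)
  x <- series$diameter[seq_len(n_out * fac)]
  y <- colMeans(matrix(x, nrow = fac))
  if (normalize) {
    s <- stats::sd(y)
    if (!is.finite(s) || s == 0)
      stop("cannot z-score a zero-variance pupil trace")
    y <- (y - mean(y)) / s
  }
  pupil_series(y, out_rate, NULL, series$start_time)
}

# Event-type regressors on the analysis grid: a pulse train at `sim_rate` is
# convolved with the unit-peak IRF and block-mean decimated exactly like the
# data, so a noise-free forward simulation inverts to machine precision.
build_event_regressors <- function(n_out, out_rate, events, groups, params,
                                   sim_rate = 500, start_time = 0) {
  fac <- as.integer(round(sim_rate / out_rate))
  n_sim <- n_out * fac
  kern_len <- min(n_sim, as.integer(round(sim_rate * 6 * params$t_max)))
  kern <- erlang_irf((seq_len(kern_len) - 1) / sim_rate, params)
  gl <- unique(groups)
  X <- matrix(0, n_out, length(gl), dimnames = list(NULL, gl))
  for (g in gl) {
    pulse <- numeric(n_sim)
    for (te in events[groups == g]) {
      i <- as.integer(round((te - start_time) * sim_rate)) + 1L
      if (i < 1L || i > n_sim) stop("event time outside trace span")
      pulse[i] <- pulse[i] + 1
    }
    reg <- convolve_causal(pulse, kern)
    X[, g] <- colMeans(matrix(reg, nrow = fac))
  }
  X
}

#' Estimate per-event pupil-response magnitudes by deconvolution
#'
#' Builds one regressor per event group (the superposition of unit-peak
#' Erlang-gamma responses at that group's event times, rendered at `sim_rate`
#' and decimated to the series rate), adds an intercept, and solves ordinary
#' least squares. Temporally overlapping responses are thereby unmixed.
#'
#' @param series A preprocessed [pupil_series()] (typically 20 Hz).
#' @param events Data frame with columns `time` (s) and `type`; an optional
#'   `group` column overrides the regressor grouping (e.g. type-by-condition
#'   cue regressors).
#' @param params An [irf_params()] object.
#' @param sim_rate Internal rendering rate for the regressors (Hz; default
#'   500, must be a multiple of the series rate).
#' @return An object of class `pupil_fit`: tibble `coefficients` (group,
#'   estimate), `intercept`, `sigma2` (residual variance), `kappa` (design
#'   condition number), `nobs`.
#' @export
deconvolve_pupil <- function(series, events, params = irf_params(),
                             sim_rate = 500) {
  stopifnot(inherits(series, "pupil_series"), is.data.frame(events))
  groups <- as.character(events$group %||% events$type)
  n_out <- length(series$diameter)
  X <- build_event_regressors(n_out, series$rate, events$time, groups, params,
                              sim_rate, series$start_time)
  Xi <- cbind(`(intercept)` = 1, X)
  qr_x <- qr(Xi)
  if (qr_x$rank < ncol(Xi)) {
    dropped <- colnames(Xi)[qr_x$pivot[(qr_x$rank + 1):ncol(Xi)]]
    stop("singular deconvolution design; collinear regressor(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qr_x, series$diameter)
  resid <- series$diameter - Xi %*% beta
  structure(list(
    coefficients = tibble::tibble(group = colnames(X),
                                  estimate = unname(beta[-1])),
    intercept = unname(beta[1]),
    sigma2 = sum(resid^2) / (n_out - ncol(Xi)),
    kappa = kappa(qr_x$qr, exact = FALSE),
    nobs = n_out), class = "pupil_fit")
}

#' @export
print.pupil_fit <- function(x, ...) {
  cat(sprintf("<pupil_fit> %d samples, residual SD %.4g, condition number %.3g\n",
              x$nobs, sqrt(x$sigma2), x$kappa))
  print(x$coefficients)
  invisible(x)
}
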