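# Internal helpers shared across modules.

#' @importFrom rlang .data
#' @keywords internal
"_PACKAGE"

#' Derive a reproducible child seed from a master seed
#'
#' Replicates, subjects, and pipeline stages each draw from their own seed
#' stream so that any unit of work can be regenerated in isolation. The
#' mapping is a fixed affine-mod scheme on 32-bit-safe integers.
#'
#' @param master Master seed (integer).
#' @param stream Stream index (integer >= 0), e.g. replicate or subject index.
#' @return An integer seed in [0, 2^31 - 1).
#' @export
derive_seed <- function(master, stream = 0L) {
  master <- as.numeric(master) %% 2147483647
  stream <- as.numeric(stream)
  as.integer((master * 48271 + stream * 16807 + 11) %% 2147483647)
}

#' Z-score a vector within groups
#'
#' Standardizes `x` to mean 0, SD 1 separately within each level of `group`
#' (typically a subject id). Used for ERP amplitudes and pupil coefficients
#' entering hierarchical models.
#'
#' @param x Numeric vector.
#' @param group Grouping vector of the same length.
#' @return Numeric vector of within-group z-scores.
#' @export
zscore_within <- function(x, group) {
  stopifnot(length(x) == length(group))
  out <- rep(NA_real_, length(x))
  for (g in unique(group)) {
    i <- which(group == g & !is.na(x))
    if (length(i) < 2L) next
    s <- stats::sd(x[i])
    if (s == 0) stop("zscore_within(): zero variance within a group")
    out[i] <- (x[i] - mean(x[i])) / s
  }
  out
}

#' Mean-center a vector within groups
#'
#' @param x Numeric vector.
#' @param group Grouping vector of the same length.
#' @return Centered numeric vector (per-group mean 0).
#' @export
center_within <- function(x, group) {
  stopifnot(length(x) == length(group))
  out <- x
  for (g in unique(group)) {
    i <- which(group == g & !is.na(x))
    out[i] <- x[i] - mean(x[i])
  }
  out
}

# Causal linear convolution via FFT, zero-padded to a highly composite
# length (raw signal lengths often factor badly and make the DFT quadratic).
convolve_causal <- function(x, kern) {
  n <- length(x)
  m <- stats::nextn(n + length(kern) - 1L, c(2L, 3L, 5L))
  xf <- stats::fft(c(x, numeric(m - n)))
  kf <- stats::fft(c(kern, numeric(m - length(kern))))
  Re(stats::fft(xf * kf, inverse = TRUE))[seq_len(n)] / m
}

# Stable hash of an R object (used for config manifests).
config_hash <- function(x) rlang::hash(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
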