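#' Observation streams for the two-chain classifier
#'
#' A segment (or stage) of a recording is reduced to two aligned feature
#' streams sharing one windowing grid: a **gesture stream** of per-window
#' per-channel sEMG MAVs (4-dim) and a **trajectory stream** of per-window
#' per-axis ACC/AV means, optionally augmented with their first differences
#' (6- or 12-dim). The feature sets are deliberately minimal — the fusion
#' model is agnostic to richer per-stream front ends.
#'
#' @name features
NULL

#' Feature configuration
#'
#' @param window_len window length in samples (default 50, shared convention
#'   with the segmenter).
#' @param step window step in samples (default 25).
#' @param include_derivative append first differences of the window means to
#'   the trajectory stream (12-dim instead of 6-dim)?
#' @return an `sf_feature_config`.
#' @export
feature_config <- function(window_len = 50L, step = 25L,
                           include_derivative = TRUE) {
  if (window_len < 3L) stop_domain("window_len must be >= 3")
  check_step_ratio(window_len, step)
  structure(list(window_len = as.integer(window_len), step = as.integer(step),
                 include_derivative = isTRUE(include_derivative)),
            class = "sf_feature_config")
}

.check_span <- function(rec, span, K) {
  n <- ncol(rec$semg)
  if (span[1] < 0 || span[2] > n || span[2] <= span[1]) {
    stop_domain("span [", span[1], ", ", span[2], ") outside recording of ", n,
                " samples")
  }
  if (span[2] - span[1] < K) {
    stop_domain("span shorter than one window (", span[2] - span[1], " < ", K, ")")
  }
}

#' Gesture observation stream (sEMG)
#'
#' Per window, the MAV of each of the 4 sEMG channels over the window.
#'
#' @param rec an `sf_recording`.
#' @param span 0-based half-open sample interval.
#' @param cfg an [feature_config()].
#' @return numeric matrix, windows x 4.
#' @export
gesture_stream <- function(rec, span, cfg = feature_config()) {
  .check_span(rec, span, cfg$window_len)
  x <- rec$semg[, (span[1] + 1L):span[2], drop = FALSE]
  t(sliding_mav(x, cfg$window_len, cfg$step)$values)
}

# per-window plain means (signed), channels x windows -> windows x channels
.window_means <- function(x, K, T_step) {
  n <- ncol(x)
  n_win <- (n - K) %/% T_step + 1L
  starts <- (seq_len(n_win) - 1L) * T_step
  out <- matrix(0, n_win, nrow(x))
  for (ch in seq_len(nrow(x))) {
    cs <- c(0, cumsum(x[ch, ]))
    out[, ch] <- (cs[starts + K + 1L] - cs[starts + 1L]) / K
  }
  out
}

#' Trajectory observation stream (ACC + AV)
#'
#' Per window, the concatenated per-axis means of the 3 ACC and 3 AV
#' channels; with `include_derivative`, the first differences between
#' consecutive window means are appended (zeros for the first window),
#' giving a 12-dim stream.
#'
#' @inheritParams gesture_stream
#' @return numeric matrix, windows x 6 (or x 12).
#' @export
trajectory_stream <- function(rec, span, cfg = feature_config()) {
  .check_span(rec, span, cfg$window_len)
  idx <- (span[1] + 1L):span[2]
  x <- rbind(rec$acc[, idx, drop = FALSE], rec$av[, idx, drop = FALSE])
  m <- .window_means(x, cfg$window_len, cfg$step)
  if (!cfg$include_derivative) return(m)
  d <- rbind(0, diff(m))
  cbind(m, d)
}

#' Build the aligned observation pair for a span
#'
#' Both streams use the identical windowing, so their lengths always agree.
#'
#' @inheritParams gesture_stream
#' @return an `sf_obs_pair`: list with matrices `o1` (gesture stream) and
#'   `o2` (trajectory stream), equal row counts.
#' @export
build_observation_pair <- function(rec, span, cfg = feature_config()) {
  o1 <- gesture_stream(rec, span, cfg)
  o2 <- trajectory_stream(rec, span, cfg)
  stopifnot(nrow(o1) == nrow(o2))
  structure(list(o1 = o1, o2 = o2), class = "sf_obs_pair")
}
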