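#' Activity segmentation by dual-signal amplitude state
#'
#' Word boundaries are detected from the joint amplitude state of the sEMG
#' and ACC streams. Each stream is reduced to per-window mean-absolute-value
#' (MAV) envelopes on a sliding window (length `K`, step `T`); a window is
#' *active* when any channel's MAV strictly exceeds the stream's threshold.
#' A word is a maximal run of windows active in **either** stream — so the
#' brief muscle relaxation inside a dynamic word, during which the wrist
#' keeps moving, never splits the word in two. Inside a word, maximal
#' sEMG-active runs delimit the gesture stages.
#'
#' @name segmentation
NULL

#' Segmenter configuration
#'
#' @param window_len MAV window length `K` in samples. The default 50 (50 ms
#'   at 1000 Hz) follows the published operating point.
#' @param step window step `T` in samples (default 25). Steps outside
#'   `[K/3, K/2]` work but emit a warning; that band gives the best
#'   accuracy/cost trade-off.
#' @param t_semg sEMG activity threshold (envelope units); `NULL` until
#'   calibrated, see [calibrate_thresholds()].
#' @param t_acc ACC activity threshold.
#' @param min_segment minimum segment length in windows; shorter runs are
#'   treated as spurious and dropped.
#' @param max_gap longest run of jointly-quiet windows closable inside a
#'   segment (in windows).
#' @param min_stage_gap shortest run of sEMG-quiet windows that can split
#'   two stages (in windows); shorter dips are closed.
#' @return an `sf_segmenter_config`.
#' @export
segmenter_config <- function(window_len = 50L, step = 25L, t_semg = NULL,
                             t_acc = NULL, min_segment = 8L, max_gap = 3L,
                             min_stage_gap = 2L) {
  if (window_len < 3L) stop_domain("window_len must be >= 3")
  check_step_ratio(window_len, step)
  if (!is.null(t_semg) && t_semg <= 0) stop_domain("t_semg must be > 0")
  if (!is.null(t_acc) && t_acc <= 0) stop_domain("t_acc must be > 0")
  structure(list(window_len = as.integer(window_len), step = as.integer(step),
                 t_semg = t_semg, t_acc = t_acc,
                 min_segment = as.integer(min_segment),
                 max_gap = as.integer(max_gap),
                 min_stage_gap = as.integer(min_stage_gap)),
            class = "sf_segmenter_config")
}

check_step_ratio <- function(K, T_step) {
  if (T_step < K / 3 || T_step > K / 2) {
    warning(sprintf("step %d outside the recommended band [K/3, K/2] = [%g, %g]",
                    T_step, K / 3, K / 2), call. = FALSE)
  }
  invisible(TRUE)
}

#' Mean absolute value of a sample series
#'
#' `mav(x) = sum(|x_i|) / N` — the amplitude envelope statistic both streams
#' are thresholded on.
#'
#' @param x non-empty numeric vector.
#' @return non-negative scalar.
#' @export
mav <- function(x) {
  if (length(x) == 0L) stop_domain("mav of an empty series is undefined")
  mean(abs(x))
}

#' Sliding-window MAV envelope of a multichannel series
#'
#' Window `w` (0-based) covers samples `[w*T, w*T + K)`; a trailing partial
#' window is discarded, so `n_windows = floor((n_samples - K)/T) + 1`.
#'
#' @param x numeric matrix, channels x samples (a vector is treated as one
#'   channel).
#' @param K window length in samples.
#' @param T_step window step in samples.
#' @return an `sf_envelope`: list with `values` (channels x windows MAV
#'   matrix), `starts` (0-based window start samples), `K`, `T_step`.
#' @export
sliding_mav <- function(x, K = 50L, T_step = 25L) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  K <- as.integer(K); T_step <- as.integer(T_step)
  n <- ncol(x)
  if (n < K) stop_domain("series shorter than one window (", n, " < ", K, ")")
  check_step_ratio(K, T_step)
  n_win <- (n - K) %/% T_step + 1L
  starts <- (seq_len(n_win) - 1L) * T_step
  # cumulative sum of |x| gives every window MAV in O(n) per channel
  vals <- matrix(0, nrow(x), n_win)
  for (ch in seq_len(nrow(x))) {
    cs <- c(0, cumsum(abs(x[ch, ])))
    vals[ch, ] <- (cs[starts + K + 1L] - cs[starts + 1L]) / K
  }
  structure(list(values = vals, starts = starts, K = as.integer(K),
                 T_step = as.integer(T_step)),
            class = "sf_envelope")
}

#' Calibrate activity thresholds from a rest recording
#'
#' Per modality, pools window MAVs of all channels over a rest-only
#' recording and sets the threshold at `mean + k_sigma * sd`, the standard
#' amplitude-onset rule. ACC thresholds use the 3 acceleration axes; angular
#' velocity is not used for segmentation.
#'
#' @param rest an `sf_recording` containing no activity.
#' @param k_sigma threshold height in rest-MAV standard deviations. The
#'   default 4 keeps the per-window false-positive rate low enough
#'   (~3e-5 per channel) that stray rest windows cannot be welded onto a
#'   word by gap closing; at `k = 3` roughly one word in ten grows a
#'   boundary by a spurious adjacent window. `k_sigma = 0` degenerates to
#'   the rest mean and warns.
#' @param K,T_step windowing as in [sliding_mav()].
#' @return list `(t_semg, t_acc)`. A hard floor of `1e-8` keeps thresholds
#'   strictly positive even for an identically-zero rest signal.
#' @export
calibrate_thresholds <- function(rest, k_sigma = 4, K = 50L, T_step = 25L) {
  if (k_sigma < 0) stop_domain("k_sigma must be >= 0")
  if (k_sigma == 0) warning("k_sigma = 0: threshold equals the rest mean",
                            call. = FALSE)
  if (ncol(rest$semg) < K) stop_domain("rest recording shorter than one window")
  floor_eps <- 1e-8
  one <- function(mat) {
    v <- as.vector(sliding_mav(mat, K, T_step)$values)
    max(mean(v) + k_sigma * stats::sd(v), floor_eps)
  }
  list(t_semg = one(rest$semg), t_acc = one(rest$acc))
}

#' Binary activity mask of an envelope
#'
#' A window is active when **any** channel's MAV strictly exceeds
#' `threshold`; equality counts as rest.
#'
#' @param env an `sf_envelope`.
#' @param threshold positive activity threshold.
#' @return logical vector, one element per window.
#' @export
amplitude_mask <- function(env, threshold) {
  if (threshold <= 0) stop_domain("threshold must be > 0")
  apply(env$values > threshold, 2L, any)
}

#' Detect word-level activity segments from the two masks
#'
#' The combined mask is the element-wise OR of the sEMG and ACC masks;
#' internal quiet runs of at most `max_gap` windows are closed, maximal
#' active runs become segments, and runs shorter than `min_segment` are
#' dropped.
#'
#' @param semg_mask,acc_mask logical activity masks of equal length.
#' @param cfg an [segmenter_config()].
#' @return list of `sf_segment` objects, each with 0-based half-open window
#'   interval `start`/`end` (and empty `stage_bounds` until
#'   [split_stages()]).
#' @export
detect_segments <- function(semg_mask, acc_mask, cfg = segmenter_config()) {
  if (length(semg_mask) != length(acc_mask)) {
    stop_domain("mask lengths differ (", length(semg_mask), " vs ",
                length(acc_mask), ")")
  }
  combined <- close_gaps(semg_mask | acc_mask, cfg$max_gap)
  r <- runs_true(combined)
  keep <- (r[, "end"] - r[, "start"]) >= cfg$min_segment
  lapply(which(keep), function(i) {
    structure(list(start = unname(r[i, "start"]), end = unname(r[i, "end"]),
                   stage_bounds = list()),
              class = "sf_segment")
  })
}

#' Split a segment into gesture stages
#'
#' Stages are maximal sEMG-active runs inside the segment after closing
#' sEMG-quiet runs shorter than `min_stage_gap`. A quiet run of at least
#' `min_stage_gap` windows during which the ACC stream stays active (at
#' least half of its windows) marks a stage boundary and is excluded from
#' both stages; a quiet run without motion cover is closed into the stage.
#' A segment in which the sEMG is never active yields one stage spanning
#' the whole segment.
#'
#' @param seg an `sf_segment` from [detect_segments()].
#' @param semg_mask,acc_mask the masks the segment was detected on.
#' @param cfg an [segmenter_config()].
#' @return the segment with `stage_bounds` filled (list of 0-based
#'   half-open window intervals).
#' @export
split_stages <- function(seg, semg_mask, acc_mask, cfg = segmenter_config()) {
  idx <- (seg$start + 1L):seg$end
  s <- semg_mask[idx]
  if (!any(s)) {
    seg$stage_bounds <- list(c(seg$start, seg$end))
    return(seg)
  }
  s <- close_gaps(s, cfg$min_stage_gap - 1L)
  # close remaining quiet runs that lack motion cover (not stage switches)
  r <- rle(s)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  n_runs <- length(r$values)
  if (n_runs >= 3L) {
    for (i in seq(2L, n_runs - 1L)) {
      if (!r$values[i]) {
        acc_frac <- mean(acc_mask[idx][(starts[i] + 1L):ends[i]])
        if (acc_frac < 0.5) r$values[i] <- TRUE
      }
    }
  }
  s <- inverse.rle(r)
  runs <- runs_true(s)
  seg$stage_bounds <- lapply(seq_len(nrow(runs)), function(i) {
    unname(c(seg$start + runs[i, "start"], seg$start + runs[i, "end"]))
  })
  seg
}

#' Segment a recording end to end
#'
#' Convenience wrapper: envelopes, masks, [detect_segments()] and
#' [split_stages()] in one call.
#'
#' @param rec an `sf_recording`.
#' @param cfg an [segmenter_config()] with calibrated `t_semg`, `t_acc`.
#' @return list of `sf_segment` with stage bounds.
#' @export
segment_recording <- function(rec, cfg) {
  if (is.null(cfg$t_semg) || is.null(cfg$t_acc)) {
    stop_domain("segmenter thresholds not calibrated; see calibrate_thresholds()")
  }
  env_semg <- sliding_mav(rec$semg, cfg$window_len, cfg$step)
  env_acc <- sliding_mav(rec$acc, cfg$window_len, cfg$step)
  m1 <- amplitude_mask(env_semg, cfg$t_semg)
  m2 <- amplitude_mask(env_acc, cfg$t_acc)
  segs <- detect_segments(m1, m2, cfg)
  lapply(segs, split_stages, semg_mask = m1, acc_mask = m2, cfg = cfg)
}

#' Convert a window interval to its sample span
#'
#' Window `w` covers samples `[w*T, w*T + K)`, so the half-open window
#' interval `[a, b)` spans samples `[a*T, (b-1)*T + K)`.
#'
#' @param win length-2 vector or `start`/`end` pair (0-based windows).
#' @param cfg an [segmenter_config()] (or anything with `window_len`, `step`).
#' @return length-2 integer sample interval, 0-based half-open.
#' @export
window_to_samples <- function(win, cfg) {
  c(win[[1]] * cfg$step, (win[[2]] - 1L) * cfg$step + cfg$window_len)
}
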