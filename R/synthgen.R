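#' Synthetic multimodal recording generation
#'
#' Seeded generators emulating the acquisition setup behind the recognition
#' pipeline: four forearm sEMG channels plus a triaxial accelerometer (ACC)
#' and gyroscope (AV) at the wrist, all sampled at 1000 Hz. A word is an
#' activity burst of roughly 2 s embedded in rest padding; dynamic (DGV)
#' words contain a brief mid-word sEMG relaxation between gesture stages
#' while the wrist keeps moving. sEMG is modeled as amplitude-modulated
#' white Gaussian noise (the recognition math consumes only amplitude
#' envelopes); trajectories are smooth per-class sinusoid banks.
#'
#' @name synthgen
NULL

#' Synthesis configuration
#'
#' @param fs sampling rate, Hz.
#' @param word_duration total activity duration of one word, seconds.
#' @param rest_pad rest padding before and after the word, seconds.
#' @param relaxation_gap duration of the inter-stage sEMG relaxation in
#'   dynamic words, seconds. Must stay below `word_duration / 4`.
#' @param ramp_len envelope ramp at activity on/offsets, seconds; avoids
#'   unrealistic step edges.
#' @param baseline_sd standard deviation of rest sEMG noise (arbitrary
#'   units, the scale every gesture level is relative to).
#' @param traj_noise_sd additive noise on ACC/AV channels.
#' @param subject_gain_sd log-scale SD of the per-subject per-channel gain
#'   jitter emulating inter-subject variation.
#' @return an `sf_synth_config` list.
#' @export
synth_config <- function(fs = 1000, word_duration = 2.0, rest_pad = 0.5,
                         relaxation_gap = 0.15, ramp_len = 0.03,
                         baseline_sd = 0.05, traj_noise_sd = 0.05,
                         subject_gain_sd = 0.1) {
  stopifnot(fs > 0, word_duration > 0, rest_pad > 0, relaxation_gap > 0,
            ramp_len >= 0, baseline_sd > 0, traj_noise_sd > 0)
  if (relaxation_gap >= word_duration / 4) {
    stop_domain("relaxation_gap must be < word_duration / 4")
  }
  structure(list(fs = fs, word_duration = word_duration, rest_pad = rest_pad,
                 relaxation_gap = relaxation_gap, ramp_len = ramp_len,
                 baseline_sd = baseline_sd, traj_noise_sd = traj_noise_sd,
                 subject_gain_sd = subject_gain_sd),
            class = "sf_synth_config")
}

#' Construct a Recording container
#'
#' @param semg 4 x n matrix of sEMG samples.
#' @param acc 3 x n matrix of acceleration samples.
#' @param av 3 x n matrix of angular-velocity samples.
#' @param fs sampling rate, Hz.
#' @return an `sf_recording`.
#' @export
recording <- function(semg, acc, av, fs) {
  stopifnot(is.matrix(semg), is.matrix(acc), is.matrix(av))
  if (nrow(semg) != 4L || nrow(acc) != 3L || nrow(av) != 3L) {
    stop_domain("expected 4 sEMG, 3 ACC and 3 AV channels")
  }
  n <- ncol(semg)
  if (ncol(acc) != n || ncol(av) != n) {
    stop_domain("all channel blocks must share n_samples")
  }
  if (fs <= 0) stop_domain("fs must be > 0")
  dimnames(semg) <- dimnames(acc) <- dimnames(av) <- NULL
  structure(list(semg = semg, acc = acc, av = av, fs = fs,
                 channel_names = c(paste0("semg", 1:4),
                                   paste0("acc", c("x", "y", "z")),
                                   paste0("av", c("x", "y", "z")))),
            class = "sf_recording")
}

#' @export
print.sf_recording <- function(x, ...) {
  cat(sprintf("<sf_recording> %d samples @ %g Hz (%.2f s), 4 sEMG + 3 ACC + 3 AV\n",
              ncol(x$semg), x$fs, ncol(x$semg) / x$fs))
  invisible(x)
}

#' Per-gesture sEMG amplitude profiles
#'
#' Draws one amplitude level per (gesture, sEMG channel), standing in for the
#' muscle-group activation pattern that distinguishes gestures. Levels are
#' uniform on `[0.5, 3]` (units of the rest-noise SD scale) and the draw is
#' retried until every pair of gesture level vectors is at least `separation`
#' apart in Euclidean distance.
#'
#' @param n_gestures number of gesture classes (>= 1).
#' @param seed RNG seed; identical arguments give identical output.
#' @param separation minimum pairwise distance between gesture level vectors.
#' @param baseline_sd rest-noise SD recorded alongside the levels.
#' @return an `sf_gesture_profiles` list with a `n_gestures x 4` `levels`
#'   matrix and `baseline_sd`.
#' @export
make_gesture_profiles <- function(n_gestures, seed, separation = 1.0,
                                  baseline_sd = 0.05) {
  if (n_gestures < 1) stop_domain("n_gestures must be >= 1")
  levels <- with_seed(seed, {
    for (try in 1:500) {
      lv <- matrix(stats::runif(n_gestures * 4L, 0.5, 3.0), n_gestures, 4L)
      if (n_gestures == 1L) break
      d <- as.matrix(stats::dist(lv))
      if (min(d[upper.tri(d)]) >= separation) break
      if (try == 500) {
        stop_domain("could not reach separation ", separation,
                    " for ", n_gestures, " gestures after 500 tries")
      }
    }
    lv
  })
  structure(list(levels = levels, baseline_sd = baseline_sd),
            class = "sf_gesture_profiles")
}

#' Per-trajectory ACC/AV waveform templates
#'
#' Class 0 (rest) is the identically-zero template; classes `1..M-1` are
#' distinct smooth waveforms built from per-channel sinusoids with seeded
#' amplitudes, frequencies and phases. Templates are sampled on `n_t` points
#' and time-rescaled to a stage's span at synthesis time.
#'
#' @param n_movement_states number of movement states including rest.
#' @param n_t template length in samples (>= 10).
#' @param seed RNG seed.
#' @param noise_sd additive noise level recorded alongside.
#' @return an `sf_trajectory_templates` list with a
#'   `n_movement_states x 6 x n_t` array `templates` (channels ACCx..z,
#'   AVx..z) and `noise_sd`.
#' @export
make_trajectory_templates <- function(n_movement_states, n_t = 2000, seed,
                                      noise_sd = 0.05) {
  if (n_movement_states < 1) stop_domain("n_movement_states must be >= 1")
  if (n_t < 10) stop_domain("n_t must be >= 10")
  tmpl <- with_seed(seed, {
    a <- array(0, dim = c(n_movement_states, 6L, n_t))
    u <- seq(0, 1, length.out = n_t)
    if (n_movement_states > 1L) {
      for (m in 2:n_movement_states) {
        for (ch in 1:6) {
          amp <- stats::runif(1, 0.6, 1.4)
          # cycles over the ~2 s stage; >= 1.6 keeps every window of the
          # three-axis group above the rest threshold
          f <- stats::runif(1, 1.6, 5.0)
          ph <- stats::runif(1, 0, 2 * pi)
          a[m, ch, ] <- amp * sin(2 * pi * f * u + ph)
        }
      }
    }
    a
  })
  structure(list(templates = tmpl, noise_sd = noise_sd),
            class = "sf_trajectory_templates")
}

# trapezoid envelope over sample grid: 0 outside [on, off), ramping over
# `ramp` samples inside the interval edges
.trapezoid <- function(n, on, off, ramp) {
  env <- numeric(n)
  if (off <= on) return(env)
  idx <- on:(off - 1L)
  e <- rep(1, length(idx))
  if (ramp > 0) {
    k <- seq_along(idx) - 1L
    e <- pmin(1, pmin((k + 1) / ramp, (length(idx) - k) / ramp))
  }
  env[idx + 1L] <- e
  env
}

# linear time-rescaling of one template channel to `len` samples
.rescale_template <- function(v, len) {
  if (len == 1L) return(v[1L])
  stats::approx(x = seq(0, 1, length.out = length(v)), y = v,
                xout = seq(0, 1, length.out = len))$y
}

#' Synthesize one word recording with ground truth
#'
#' Layout: `rest_pad | stage 1 | gap | stage 2 | ... | rest_pad`, the stages
#' sharing `word_duration` minus the inter-stage relaxation gaps. Within a
#' stage, each sEMG channel is zero-mean Gaussian noise with SD equal to the
#' stage gesture's channel level (rest-noise SD elsewhere), ramped over
#' `ramp_len` at edges. ACC/AV carry the stage's trajectory template,
#' time-rescaled to the stage span, plus noise; during a relaxation gap the
#' sEMG drops to baseline while ACC/AV continue the neighbouring non-rest
#' stage's trajectory, which is what keeps a dynamic word segmentable as one
#' word.
#'
#' @param entry a [lexicon_entry()].
#' @param profiles an `sf_gesture_profiles`.
#' @param templates an `sf_trajectory_templates`.
#' @param cfg an [synth_config()].
#' @param seed RNG seed; same `(entry, seed)` reproduces bit-identical output.
#' @return list with elements `recording` (an `sf_recording`) and `truth`
#'   (word_id, category, `segment` and `stage_intervals` as 0-based half-open
#'   sample intervals, `stage_states` matrix).
#' @export
synthesize_word <- function(entry, profiles, templates, cfg, seed) {
  fs <- cfg$fs
  n_stages <- nrow(entry$stages)
  if (any(entry$stages[, "gesture"] > nrow(profiles$levels)) ||
      any(entry$stages[, "movement"] > dim(templates$templates)[1] - 1L)) {
    stop_domain("entry states outside profile/template ranges")
  }
  gap <- as.integer(round(cfg$relaxation_gap * fs))
  word <- as.integer(round(cfg$word_duration * fs))
  pad <- as.integer(round(cfg$rest_pad * fs))
  ramp <- as.integer(round(cfg$ramp_len * fs))
  stage_len <- (word - (n_stages - 1L) * gap) %/% n_stages
  if (stage_len <= 4L * ramp) {
    stop_domain("word_duration cannot hold ", n_stages, " stages")
  }
  starts <- pad + (seq_len(n_stages) - 1L) * (stage_len + gap)
  ends <- starts + stage_len
  n <- 2L * pad + n_stages * stage_len + (n_stages - 1L) * gap

  out <- with_seed(seed, {
    semg <- matrix(stats::rnorm(4L * n, sd = cfg$baseline_sd), 4L, n)
    for (k in seq_len(n_stages)) {
      env <- .trapezoid(n, starts[k], ends[k], ramp)
      lv <- profiles$levels[entry$stages[k, "gesture"], ]
      active <- env > 0
      for (ch in 1:4) {
        sd_t <- cfg$baseline_sd + env[active] * (lv[ch] - cfg$baseline_sd)
        semg[ch, active] <- stats::rnorm(sum(active), sd = sd_t)
      }
    }
    # trajectory spans: each stage's interval, with relaxation gaps covered
    # by the adjacent non-rest stage so wrist motion bridges the sEMG dip
    tr_start <- starts; tr_end <- ends
    if (n_stages > 1L) {
      for (k in seq_len(n_stages - 1L)) {
        if (entry$stages[k + 1L, "movement"] > 0L) {
          tr_start[k + 1L] <- ends[k]          # next stage starts early
        } else if (entry$stages[k, "movement"] > 0L) {
          tr_end[k] <- starts[k + 1L]          # previous stage runs long
        }
      }
    }
    motion <- matrix(stats::rnorm(6L * n, sd = cfg$traj_noise_sd), 6L, n)
    for (k in seq_len(n_stages)) {
      m <- entry$stages[k, "movement"]
      if (m > 0L) {
        len <- tr_end[k] - tr_start[k]
        env <- .trapezoid(n, tr_start[k], tr_end[k], ramp)
        idx <- (tr_start[k] + 1L):tr_end[k]
        for (ch in 1:6) {
          wave <- .rescale_template(templates$templates[m + 1L, ch, ], len)
          motion[ch, idx] <- motion[ch, idx] + wave * env[idx]
        }
      }
    }
    list(semg = semg, motion = motion)
  })

  rec <- recording(out$semg, out$motion[1:3, , drop = FALSE],
                   out$motion[4:6, , drop = FALSE], fs)
  truth <- list(word_id = entry$word_id, category = entry$category,
                segment = c(pad, ends[n_stages]),
                stage_intervals = lapply(seq_len(n_stages),
                                         function(k) c(starts[k], ends[k])),
                stage_states = entry$stages)
  list(recording = rec, truth = truth)
}

#' Synthesize a rest-only recording
#'
#' Used to calibrate activity thresholds: all channels carry only their rest
#' noise.
#'
#' @param duration length in seconds.
#' @param cfg an [synth_config()].
#' @param seed RNG seed.
#' @return an `sf_recording`.
#' @export
synthesize_rest <- function(duration, cfg, seed) {
  n <- round(duration * cfg$fs)
  with_seed(seed, {
    recording(matrix(stats::rnorm(4L * n, sd = cfg$baseline_sd), 4L, n),
              matrix(stats::rnorm(3L * n, sd = cfg$traj_noise_sd), 3L, n),
              matrix(stats::rnorm(3L * n, sd = cfg$traj_noise_sd), 3L, n),
              cfg$fs)
  })
}

# per-subject multiplicative channel gains, lognormal(0, subject_gain_sd),
# seeded by subject index
.subject_gains <- function(subject, cfg, seed) {
  with_seed(derive_seed(seed, 7001, subject), {
    exp(stats::rnorm(10L, 0, cfg$subject_gain_sd))
  })
}

.apply_gains <- function(rec, gains) {
  recording(rec$semg * gains[1:4], rec$acc * gains[5:7],
            rec$av * gains[8:10], rec$fs)
}

#' Synthesize a full multi-subject dataset
#'
#' One recording per (subject, word). Subjects are indexed `0..n_subjects-1`
#' and carry seeded per-channel multiplicative gain jitter emulating
#' inter-subject variation. The train/test split is deterministic:
#' even subject indices train, odd test — with 8 subjects and the 120-word
#' lexicon this reproduces the 960-recording, 480/480 design.
#'
#' @param lex an `sf_lexicon`.
#' @param n_subjects number of subjects (>= 1).
#' @param cfg an [synth_config()].
#' @param seed RNG seed driving profiles, templates and every recording.
#' @param out_dir if non-`NULL`, recordings, ground-truth sidecars and the
#'   manifest are written there (see [write_recording()]); otherwise
#'   recordings are kept in memory.
#' @return list with `manifest` (data.frame: subject, word_id, category,
#'   path, split), `recordings` (named list, `NULL` when written to disk),
#'   `truths`, `profiles`, `templates`.
#' @export
synthesize_dataset <- function(lex, n_subjects, cfg = synth_config(), seed,
                               out_dir = NULL) {
  if (n_subjects < 1) stop_domain("n_subjects must be >= 1")
  profiles <- make_gesture_profiles(lex$n_gestures, derive_seed(seed, 1))
  templates <- make_trajectory_templates(lex$n_movement_states,
                                         seed = derive_seed(seed, 2))
  n_words <- length(lex$entries)
  rows <- vector("list", n_subjects * n_words)
  recs <- if (is.null(out_dir)) vector("list", n_subjects * n_words) else NULL
  truths <- vector("list", n_subjects * n_words)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  i <- 0L
  for (subj in 0:(n_subjects - 1L)) {
    gains <- .subject_gains(subj, cfg, seed)
    for (e in lex$entries) {
      i <- i + 1L
      sw <- synthesize_word(e, profiles, templates, cfg,
                            derive_seed(seed, 3, subj * 100000 + e$word_id))
      rec <- .apply_gains(sw$recording, gains)
      key <- sprintf("s%02d_w%03d", subj, e$word_id)
      split <- if (subj %% 2L == 0L) "train" else "test"
      path <- NA_character_
      if (is.null(out_dir)) {
        recs[[key]] <- rec
      } else {
        path <- file.path(out_dir, paste0(key, ".csv"))
        write_recording(rec, path)
        write_ground_truth(sw$truth, paste0(path, ".truth.json"))
      }
      truths[[key]] <- sw$truth
      rows[[i]] <- data.frame(subject = subj, word_id = e$word_id,
                              category = e$category, path = path,
                              split = split, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(manifest = manifest, recordings = recs, truths = truths,
       profiles = profiles, templates = templates)
}

#' Write a ground-truth sidecar JSON
#'
#' @param truth a ground-truth list as produced by [synthesize_word()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  obj <- list(word_id = truth$word_id, category = truth$category,
              segment = truth$segment,
              stage_intervals = truth$stage_intervals,
              stage_states = lapply(seq_len(nrow(truth$stage_states)),
                                    function(i) unname(truth$stage_states[i, ])))
  writeLines(jsonlite::toJSON(obj, auto_unbox = FALSE, pretty = TRUE), path)
  invisible(path)
}

#' Read a ground-truth sidecar JSON
#'
#' @param path sidecar path.
#' @return ground-truth list (see [synthesize_word()]).
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  list(word_id = raw$word_id[[1]], category = raw$category[[1]],
       segment = unlist(raw$segment),
       stage_intervals = lapply(raw$stage_intervals, unlist),
       stage_states = {
         m <- do.call(rbind, lapply(raw$stage_states, unlist))
         colnames(m) <- c("gesture", "movement"); m
       })
}
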