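#' End-to-end experiment orchestration
#'
#' Glue for the full simulate -> segment -> featurize -> train -> classify ->
#' report loop, with on-disk artifacts: recording CSVs with a `# fs=` header,
#' a manifest CSV, a JSON model file and a per-category accuracy report
#' shaped like the published results table.
#'
#' @name pipeline
NULL

.REC_COLS <- c("t", paste0("semg", 1:4), "accx", "accy", "accz",
               "avx", "avy", "avz")

#' Write a recording to delimited text
#'
#' Format: one comment header line `# fs=<Hz>`, then CSV columns
#' `t, semg1..semg4, accx, accy, accz, avx, avy, avz` (time in seconds).
#'
#' @param rec an `sf_recording`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  n <- ncol(rec$semg)
  dt <- data.table::data.table(
    t = (seq_len(n) - 1L) / rec$fs,
    semg1 = rec$semg[1, ], semg2 = rec$semg[2, ],
    semg3 = rec$semg[3, ], semg4 = rec$semg[4, ],
    accx = rec$acc[1, ], accy = rec$acc[2, ], accz = rec$acc[3, ],
    avx = rec$av[1, ], avy = rec$av[2, ], avz = rec$av[3, ])
  writeLines(sprintf("# fs=%.10g", rec$fs), path)
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a recording from delimited text
#'
#' @param path file written by [write_recording()] (or matching its dialect).
#' @return an `sf_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop_domain("recording file not found: ", path)
  hdr <- readLines(path, n = 1L)
  fsm <- regmatches(hdr, regexec("^#\\s*fs=([0-9.eE+-]+)", hdr))[[1]]
  if (length(fsm) < 2L) stop_domain("missing '# fs=' header in ", path)
  fs <- as.numeric(fsm[2])
  dt <- data.table::fread(path, skip = 1L, header = TRUE)
  missing <- setdiff(.REC_COLS, names(dt))
  if (length(missing)) {
    stop_domain("recording ", path, " missing column(s): ",
                paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(dt), .REC_COLS)
  if (length(extra)) {
    stop_domain("recording ", path, " has unexpected column(s): ",
                paste(extra, collapse = ", "))
  }
  if (is.unsorted(dt$t, strictly = TRUE)) {
    stop_domain("recording ", path, ": time column not strictly increasing")
  }
  recording(t(as.matrix(dt[, c("semg1", "semg2", "semg3", "semg4")])),
            t(as.matrix(dt[, c("accx", "accy", "accz")])),
            t(as.matrix(dt[, c("avx", "avy", "avz")])), fs)
}

#' Experiment configuration
#'
#' @param lexicon_path lexicon JSON (default: the packaged 120-word fixture).
#' @param data_dir directory for simulated recordings + manifest.
#' @param out_dir directory for model and report artifacts.
#' @param n_subjects number of simulated subjects (default 8, reproducing
#'   the 960-recording design).
#' @param synth an [synth_config()].
#' @param segmenter an [segmenter_config()] (thresholds may be `NULL`; they
#'   are calibrated at run time from a seeded rest recording).
#' @param features an [feature_config()].
#' @param k_sigma threshold height for [calibrate_thresholds()].
#' @param max_iter,tol EM training parameters. The pipeline default is a
#'   single Baum-Welch refinement pass after the supervised warm start:
#'   further unsupervised passes keep increasing the likelihood but slowly
#'   drift the composite states away from the lexicon labeling the
#'   classifier looks states up by (see the methods vignette).
#' @param var_reg emission-variance regularization used for training
#'   (default `1e-3`); guards the classifier against overconfident
#'   per-state variances in the presence of inter-subject gain variation.
#' @param seed mandatory base seed for every random step.
#' @return an `sf_experiment_config`.
#' @export
experiment_config <- function(lexicon_path = system.file("extdata", "lexicon120.json",
                                                         package = "signfuse"),
                              data_dir, out_dir = data_dir,
                              n_subjects = 8L,
                              synth = synth_config(),
                              segmenter = segmenter_config(),
                              features = feature_config(),
                              k_sigma = 4,
                              max_iter = 1L, tol = 1e-4, var_reg = 1e-3,
                              seed) {
  if (missing(seed)) stop_domain("seed is mandatory")
  structure(list(lexicon_path = lexicon_path, data_dir = data_dir,
                 out_dir = out_dir, n_subjects = as.integer(n_subjects),
                 synth = synth, segmenter = segmenter, features = features,
                 k_sigma = k_sigma, max_iter = as.integer(max_iter),
                 tol = tol, var_reg = var_reg, seed = as.integer(seed)),
            class = "sf_experiment_config")
}

# Calibrated segmenter config, deterministic given cfg$seed. One rest
# recording per subject (with that subject's channel gains); the working
# threshold is the max of the per-subject mean + k*sd values, i.e. the
# lowest threshold that classifies every subject's rest as rest — the
# all-volunteers-jointly calibration.
.calibrated_segmenter <- function(cfg) {
  seg <- cfg$segmenter
  if (is.null(seg$t_semg) || is.null(seg$t_acc)) {
    th <- lapply(0:(cfg$n_subjects - 1L), function(subj) {
      rest <- synthesize_rest(10, cfg$synth, derive_seed(cfg$seed, 999, subj))
      rest <- .apply_gains(rest, .subject_gains(subj, cfg$synth, cfg$seed))
      calibrate_thresholds(rest, cfg$k_sigma, seg$window_len, seg$step)
    })
    seg$t_semg <- seg$t_semg %||% max(vapply(th, `[[`, numeric(1), "t_semg"))
    seg$t_acc <- seg$t_acc %||% max(vapply(th, `[[`, numeric(1), "t_acc"))
  }
  seg
}

#' Simulate a dataset to disk
#'
#' @param cfg an [experiment_config()].
#' @param force overwrite an existing non-empty `data_dir`?
#' @return the manifest `data.frame`, invisibly.
#' @export
run_simulation <- function(cfg, force = FALSE) {
  lex <- load_lexicon(cfg$lexicon_path)
  if (dir.exists(cfg$data_dir) &&
      length(list.files(cfg$data_dir)) > 0L && !force) {
    stop_domain("data_dir ", cfg$data_dir,
                " exists and is non-empty; use force = TRUE to overwrite")
  }
  ds <- synthesize_dataset(lex, cfg$n_subjects, cfg$synth, cfg$seed,
                           out_dir = cfg$data_dir)
  invisible(ds$manifest)
}

# segment one recording into per-stage observation pairs;
# returns NULL when no usable segment is found
.stage_obs_of <- function(rec, seg_cfg, feat_cfg) {
  segs <- segment_recording(rec, seg_cfg)
  if (length(segs) == 0L) return(NULL)
  if (length(segs) > 1L) {
    lens <- vapply(segs, function(s) s$end - s$start, numeric(1))
    segs <- segs[which.max(lens)]
  }
  seg <- segs[[1]]
  lapply(seg$stage_bounds, function(b) {
    build_observation_pair(rec, window_to_samples(b, seg_cfg), feat_cfg)
  })
}

#' Train the coupled HMM on the manifest's train split
#'
#' Each training recording is segmented; its per-stage observation pairs are
#' labeled with the lexicon entry's stage states (recordings with no
#' detected segment, or whose detected stage count disagrees with the
#' lexicon, are logged and skipped — more than 10% skips abort the run).
#' The model is warm-started supervised ([supervised_chmm()]) and refined
#' with [em_fit()]. Deterministic for a fixed config and seed.
#'
#' @param cfg an [experiment_config()] whose `data_dir` holds a simulated
#'   (or equivalent) dataset with `manifest.csv`.
#' @param verbose print per-stage progress lines?
#' @return list with `model`, `report` (the EM trace report plus skip
#'   counts), and `model_path` (JSON written under `out_dir`).
#' @export
run_training <- function(cfg, verbose = FALSE) {
  lex <- load_lexicon(cfg$lexicon_path)
  man <- utils::read.csv(file.path(cfg$data_dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  man <- man[man$split == "train", , drop = FALSE]
  if (nrow(man) == 0L) stop_domain("manifest has no train split")
  seg_cfg <- .calibrated_segmenter(cfg)
  by_id <- stats::setNames(lex$entries,
                           vapply(lex$entries, function(e) e$word_id, integer(1)))
  obs_list <- list(); labels <- list(); skipped <- 0L
  for (i in seq_len(nrow(man))) {
    entry <- by_id[[as.character(man$word_id[i])]]
    rec <- read_recording(man$path[i])
    so <- .stage_obs_of(rec, seg_cfg, cfg$features)
    if (is.null(so) || length(so) != nrow(entry$stages)) {
      skipped <- skipped + 1L
      if (verbose) message("skip ", man$path[i], " (segmentation mismatch)")
      next
    }
    for (k in seq_along(so)) {
      obs_list[[length(obs_list) + 1L]] <- so[[k]]
      labels[[length(labels) + 1L]] <- c(entry$stages[k, "gesture"],
                                         entry$stages[k, "movement"] + 1L)
    }
  }
  if (skipped > 0.1 * nrow(man)) {
    stop_domain(skipped, " of ", nrow(man), " training recordings skipped (>10%)")
  }
  init <- supervised_chmm(obs_list, labels, lex$n_gestures,
                          lex$n_movement_states, var_reg = cfg$var_reg)
  fit <- em_fit(init, obs_list, max_iter = cfg$max_iter, tol = cfg$tol,
                var_reg = cfg$var_reg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  model_path <- file.path(cfg$out_dir, "model.json")
  write_chmm(fit$model, model_path)
  fit$report$n_train <- nrow(man)
  fit$report$n_skipped <- skipped
  list(model = fit$model, report = fit$report, model_path = model_path)
}

#' Evaluate a trained model on the manifest's test split
#'
#' Every test recording is segmented and classified ([classify_word()]),
#' candidates restricted to the recording's vocabulary category (taken from
#' manifest metadata, not inferred from the signal) and to entries with the
#' detected stage count. Recordings with no detected segment, or no
#' candidate with the detected stage count, count as errors.
#'
#' @param cfg an [experiment_config()].
#' @param model a fitted `sf_chmm` or a path to a model JSON.
#' @return an `sf_evaluation`: per-category rows ([accuracy_report()]),
#'   micro-average, confusion matrix (true x predicted word_id, with an
#'   `unclassified` column) and the per-recording `records` data.frame.
#' @export
run_evaluation <- function(cfg, model) {
  if (is.character(model)) model <- read_chmm(model)
  lex <- load_lexicon(cfg$lexicon_path)
  man <- utils::read.csv(file.path(cfg$data_dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  man <- man[man$split == "test", , drop = FALSE]
  if (nrow(man) == 0L) stop_domain("manifest has no test split")
  seg_cfg <- .calibrated_segmenter(cfg)
  ids <- vapply(lex$entries, function(e) e$word_id, integer(1))
  conf <- matrix(0L, length(ids), length(ids) + 1L,
                 dimnames = list(true = ids, pred = c(ids, "unclassified")))
  pred <- integer(nrow(man))
  for (i in seq_len(nrow(man))) {
    rec <- read_recording(man$path[i])
    so <- .stage_obs_of(rec, seg_cfg, cfg$features)
    p <- NA_integer_
    if (!is.null(so)) {
      p <- tryCatch(
        classify_word(model, so, lex, category = man$category[i])$word_id,
        error = function(e) NA_integer_)
    }
    pred[i] <- p
    row <- match(man$word_id[i], ids)
    col <- if (is.na(p)) length(ids) + 1L else match(p, ids)
    conf[row, col] <- conf[row, col] + 1L
  }
  records <- data.frame(man[, c("subject", "word_id", "category")],
                        predicted = pred,
                        correct = !is.na(pred) & pred == man$word_id)
  cats <- c("SHGV", "DHGV", "DGV")
  totals <- vapply(cats, function(ct) sum(man$category == ct), integer(1))
  correct <- vapply(cats, function(ct) {
    sum(records$correct[records$category == ct])
  }, integer(1))
  n_words <- category_counts(lex)[cats]
  rep <- accuracy_report(correct, totals, n_words = n_words)
  structure(c(rep, list(confusion = conf, records = records)),
            class = "sf_evaluation")
}

#' Per-category accuracy rows and the micro-average
#'
#' Accuracies are reported as percentages truncated (not rounded) to two
#' decimal places, the convention the published integer counts were printed
#' under (e.g. 80/92 -> 86.95, 434/480 -> 90.41); the truncation is done in
#' integer arithmetic so the printed figure is exact. The overall accuracy
#' is the micro-average `sum(correct) / sum(total)`, not the mean of the
#' category accuracies.
#'
#' @param correct named integer vector of per-category correct counts.
#' @param totals named integer vector of per-category test-sample counts.
#' @param n_words optional per-category word counts, carried into the rows.
#' @return list with `rows` (`data.frame`: category, n_words, n_test,
#'   n_correct, accuracy, accuracy_pct) and `overall` (same fields for the
#'   micro-average row).
#' @export
accuracy_report <- function(correct, totals, n_words = NULL) {
  cat_names <- names(totals) %||% names(correct) %||%
    as.character(seq_along(totals))
  correct <- as.integer(correct); totals <- as.integer(totals)
  if (length(correct) != length(totals)) stop_domain("length mismatch")
  if (any(correct > totals)) stop_domain("correct exceeds total")
  if (any(totals < 0) || any(correct < 0)) stop_domain("negative count")
  trunc_pct <- function(num, den) {
    ifelse(den == 0L, NA_real_, (num * 10000L) %/% den / 100)
  }
  rows <- data.frame(
    category = cat_names,
    n_words = if (is.null(n_words)) NA_integer_ else as.integer(n_words),
    n_test = totals, n_correct = correct,
    accuracy = ifelse(totals == 0L, NA_real_, correct / totals),
    accuracy_pct = trunc_pct(correct, totals),
    stringsAsFactors = FALSE)
  overall <- data.frame(
    category = "total", n_words = sum(rows$n_words),
    n_test = sum(totals), n_correct = sum(correct),
    accuracy = sum(correct) / sum(totals),
    accuracy_pct = trunc_pct(sum(correct), sum(totals)),
    stringsAsFactors = FALSE)
  list(rows = rows, overall = overall)
}

#' @export
print.sf_evaluation <- function(x, ...) {
  tab <- rbind(x$rows, x$overall)
  cat("Vocabulary-type accuracy\n")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report to CSV and JSON
#'
#' @param ev an `sf_evaluation`.
#' @param out_dir output directory; writes `report.csv` (category rows plus
#'   total) and `report.json` (rows plus full confusion matrix).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(ev, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- rbind(ev$rows, ev$overall)
  utils::write.csv(tab[, c("category", "n_words", "n_test", "n_correct",
                           "accuracy_pct")],
                   file.path(out_dir, "report.csv"), row.names = FALSE)
  obj <- list(rows = ev$rows, overall = ev$overall,
              confusion = list(true_word_id = rownames(ev$confusion),
                               predicted = colnames(ev$confusion),
                               counts = apply(ev$confusion, 1L, identity,
                                              simplify = FALSE)))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, dataframe = "rows"),
             file.path(out_dir, "report.json"))
  invisible(out_dir)
}

#' Run the full pipeline: simulate, train, evaluate
#'
#' @param cfg an [experiment_config()].
#' @param force passed to [run_simulation()].
#' @return list with `train` (see [run_training()]) and `evaluation`
#'   (see [run_evaluation()]); report files are written under `out_dir`.
#' @export
run_pipeline <- function(cfg, force = FALSE) {
  run_simulation(cfg, force = force)
  tr <- run_training(cfg)
  ev <- run_evaluation(cfg, tr$model)
  write_report(ev, cfg$out_dir)
  list(train = tr, evaluation = ev)
}
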