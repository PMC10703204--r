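test_that("mav computes the absolute mean and rejects empty input", {
  expect_identical(mav(c(0, 0, 0, 0)), 0)
  expect_identical(mav(rep(-3.5, 17)), 3.5)
  expect_equal(mav(c(1, -2, 3)), 2)
  expect_error(mav(numeric(0)), "empty")
  # scaling linearity
  set.seed(1)
  for (k in 1:20) {
    x <- rnorm(50); a <- runif(1, -5, 5)
    expect_equal(mav(a * x), abs(a) * mav(x))
  }
})

test_that("sliding_mav windows follow the K/T convention", {
  env <- sliding_mav(matrix(1, 1, 100), K = 50, T_step = 25)
  expect_identical(ncol(env$values), 3L)
  expect_identical(env$starts, c(0L, 25L, 50L))
  expect_true(all(env$values == 1))
  expect_error(sliding_mav(matrix(1, 1, 30), K = 50, T_step = 25), "shorter")
  expect_warning(sliding_mav(matrix(1, 1, 200), K = 50, T_step = 10),
                 "recommended band")
})

test_that("sliding_mav equals the naive per-window oracle", {
  naive <- function(x, K, T_step) {
    n_win <- (length(x) - K) %/% T_step + 1
    vapply(seq_len(n_win), function(w) {
      mean(abs(x[((w - 1) * T_step + 1):((w - 1) * T_step + K)]))
    }, numeric(1))
  }
  set.seed(2024)
  for (k in 1:200) {
    n <- sample(60:400, 1)
    K <- sample(10:40, 1)
    T_step <- max(3L, K %/% 3 + sample(0:(K %/% 6), 1))
    x <- rnorm(n, sd = runif(1, 0.1, 10))
    # draws intentionally cover steps outside the recommended band
    env <- suppressWarnings(sliding_mav(matrix(x, 1), K, T_step))
    expect_equal(as.vector(env$values), naive(x, K, T_step), tolerance = 1e-12)
  }
})

test_that("calibrate_thresholds follows the mean + k*sd rule", {
  cfg <- synth_config()
  rest <- synthesize_rest(5, cfg, seed = 77)
  th <- calibrate_thresholds(rest, k_sigma = 3)
  v <- as.vector(sliding_mav(rest$semg, 50, 25)$values)
  expect_gte(th$t_semg, mean(v) + 2.5 * sd(v))
  expect_lte(th$t_semg, mean(v) + 3.5 * sd(v))
  expect_gt(th$t_semg, mean(v))
  # degenerate zero signal hits the documented floor
  zero <- recording(matrix(0, 4, 200), matrix(0, 3, 200), matrix(0, 3, 200), 1000)
  thz <- calibrate_thresholds(zero)
  expect_identical(thz$t_semg, 1e-8)
  expect_warning(calibrate_thresholds(rest, k_sigma = 0), "rest mean")
  short <- recording(matrix(0, 4, 10), matrix(0, 3, 10), matrix(0, 3, 10), 1000)
  expect_error(calibrate_thresholds(short), "shorter")
})

test_that("amplitude_mask uses a strict any-channel rule", {
  env <- structure(list(values = matrix(c(0.1, 0.1, 0.1,
                                          0.1, 0.9, 0.1), 2, 3, byrow = TRUE),
                        starts = c(0L, 25L, 50L), K = 50L, T_step = 25L),
                   class = "sf_envelope")
  expect_identical(amplitude_mask(env, 0.5), c(FALSE, TRUE, FALSE))
  expect_identical(amplitude_mask(env, 1.0), c(FALSE, FALSE, FALSE))
  # equality counts as rest
  expect_identical(amplitude_mask(env, 0.9), c(FALSE, FALSE, FALSE))
  expect_error(amplitude_mask(env, 0), "> 0")
})

mask_of <- function(idx, n) seq_len(n) %in% (idx + 1)

test_that("detect_segments ORs the masks and closes short gaps", {
  cfg <- segmenter_config(t_semg = 1, t_acc = 1)
  n <- 30
  expect_identical(detect_segments(rep(FALSE, n), rep(FALSE, n), cfg), list())
  # sEMG [3,10) + ACC [3,12) -> one segment [3,12)
  s1 <- detect_segments(mask_of(3:9, n), mask_of(3:11, n), cfg)
  expect_length(s1, 1)
  expect_identical(c(s1[[1]]$start, s1[[1]]$end), c(3L, 12L))
  # sEMG dips inside ACC activity never split the word
  semg <- mask_of(c(1:9, 14:24), n)
  acc <- mask_of(1:24, n)
  s2 <- detect_segments(semg, acc, cfg)
  expect_length(s2, 1)
  expect_identical(c(s2[[1]]$start, s2[[1]]$end), c(1L, 25L))
  # short runs are dropped
  expect_length(detect_segments(mask_of(4:6, n), rep(FALSE, n), cfg), 0)
  expect_error(detect_segments(rep(TRUE, 5), rep(TRUE, 6), cfg), "length")
})

test_that("split_stages separates sEMG runs only under motion cover", {
  cfg <- segmenter_config(t_semg = 1, t_acc = 1)
  n <- 30
  semg <- mask_of(c(1:9, 14:24), n)
  acc <- mask_of(1:24, n)
  seg <- detect_segments(semg, acc, cfg)[[1]]
  seg <- split_stages(seg, semg, acc, cfg)
  expect_identical(seg$stage_bounds, list(c(1L, 10L), c(14L, 25L)))
  # same dip without ACC cover: one merged stage
  seg2 <- detect_segments(semg, acc, cfg)[[1]]
  seg2 <- split_stages(seg2, semg, rep(FALSE, n), cfg)
  expect_identical(seg2$stage_bounds, list(c(1L, 25L)))
  # sEMG active throughout -> one stage equal to the segment
  semg3 <- mask_of(2:20, n)
  seg3 <- detect_segments(semg3, rep(FALSE, n), cfg)[[1]]
  seg3 <- split_stages(seg3, semg3, rep(FALSE, n), cfg)
  expect_identical(seg3$stage_bounds, list(c(2L, 21L)))
  # ACC-only segment -> one stage spanning the segment
  acc4 <- mask_of(0:14, n)
  seg4 <- detect_segments(rep(FALSE, n), acc4, cfg)[[1]]
  seg4 <- split_stages(seg4, rep(FALSE, n), acc4, cfg)
  expect_identical(seg4$stage_bounds, list(c(0L, 15L)))
})

test_that("segments are invariant to rest padding (up to index shift)", {
  cfg <- segmenter_config(t_semg = 1, t_acc = 1)
  semg <- mask_of(c(5:12, 15:20), 40)
  acc <- mask_of(5:20, 40)
  base <- detect_segments(semg, acc, cfg)
  pad <- 13L
  shifted <- detect_segments(c(rep(FALSE, pad), semg), c(rep(FALSE, pad), acc), cfg)
  expect_length(shifted, length(base))
  for (i in seq_along(base)) {
    expect_identical(shifted[[i]]$start, base[[i]]$start + pad)
    expect_identical(shifted[[i]]$end, base[[i]]$end + pad)
  }
})

test_that("raising the threshold never lengthens a segment", {
  cfg <- fixture_seg_cfg
  lex <- small_lexicon()
  sw <- synthesize_word(lex$entries[[1]], fixture_profiles, fixture_templates,
                        fixture_cfg, seed = 31)
  env_s <- sliding_mav(sw$recording$semg, cfg$window_len, cfg$step)
  env_a <- sliding_mav(sw$recording$acc, cfg$window_len, cfg$step)
  lengths <- vapply(c(1, 1.5, 2.5, 4), function(f) {
    segs <- detect_segments(amplitude_mask(env_s, f * cfg$t_semg),
                            amplitude_mask(env_a, f * cfg$t_acc), cfg)
    if (length(segs)) sum(vapply(segs, function(s) s$end - s$start, numeric(1)))
    else 0
  }, numeric(1))
  expect_true(all(diff(lengths) <= 0))
})

test_that("DGV synthetic words split into their two stages", {
  lex <- default_lexicon()
  dgv <- Filter(function(e) e$category == "DGV", lex$entries)
  for (i in seq(1, 23, by = 3)) {
    sw <- synthesize_word(dgv[[i]], fixture_profiles, fixture_templates,
                          fixture_cfg, seed = 500 + i)
    segs <- segment_recording(sw$recording, fixture_seg_cfg)
    expect_length(segs, 1)
    expect_length(segs[[1]]$stage_bounds, 2)
    for (k in 1:2) {
      true_w <- sw$truth$stage_intervals[[k]] / fixture_seg_cfg$step
      expect_lte(abs(segs[[1]]$stage_bounds[[k]][1] - true_w[1]), 1)
      expect_lte(abs(segs[[1]]$stage_bounds[[k]][2] - true_w[2]), 1)
    }
  }
})
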