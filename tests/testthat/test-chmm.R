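test_that("validate_model reports violations instead of throwing", {
  m <- uniform_chmm()
  expect_identical(validate_model(m), character(0))
  m_bad <- m
  m_bad$trans[[1]][2, ] <- c(0.4, 0.5)             # sums to 0.9
  v <- validate_model(m_bad)
  expect_match(v, "chain 1, composite row 2", all = FALSE)
  m_bad2 <- m
  m_bad2$emissions[[2]]$var[1, 1] <- -1
  expect_match(validate_model(m_bad2), "variance", all = FALSE)
  m_bad3 <- m
  m_bad3$initial[[1]] <- c(0.7, 0.7)
  expect_match(validate_model(m_bad3), "initial sums", all = FALSE)
})

test_that("composite transition matrix factorizes and is row-stochastic", {
  # single-state model
  m1 <- coupled_hmm(list(1, 1), list(matrix(1, 1, 1), matrix(1, 1, 1)),
                    list(list(mean = matrix(0, 1, 1), var = matrix(1, 1, 1)),
                         list(mean = matrix(0, 1, 1), var = matrix(1, 1, 1))))
  expect_identical(composite_transition_matrix(m1), matrix(1, 1, 1))
  # chains depending only on their own previous state -> Kronecker product
  A <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, 2, byrow = TRUE)   # chain 1
  B <- matrix(c(0.6, 0.4, 0.2, 0.8), 2, 2, byrow = TRUE)   # chain 2
  A1 <- rbind(A[1, ], A[1, ], A[2, ], A[2, ])  # rows (i1,i2) chain-2-fastest
  B2 <- rbind(B[1, ], B[2, ], B[1, ], B[2, ])
  m <- uniform_chmm()
  m$trans <- list(A1, B2)
  expect_equal(composite_transition_matrix(m), kronecker(A, B))
  # random models: rows sum to 1 within 1e-12
  for (k in 1:10) {
    mr <- random_chmm(3, 2, seed = k)
    expect_lt(max(abs(rowSums(composite_transition_matrix(mr)) - 1)), 1e-12)
  }
})

test_that("log_forward matches closed forms and the enumeration oracle", {
  m <- random_chmm(2, 2, d1 = 2, d2 = 3, seed = 11)
  # T = 1 closed form
  o <- sample_sequence(m, 1, seed = 2)$obs
  direct <- 0
  for (i1 in 1:2) for (i2 in 1:2) {
    b1 <- prod(dnorm(o$o1[1, ], m$emissions[[1]]$mean[i1, ],
                     sqrt(m$emissions[[1]]$var[i1, ])))
    b2 <- prod(dnorm(o$o2[1, ], m$emissions[[2]]$mean[i2, ],
                     sqrt(m$emissions[[2]]$var[i2, ])))
    direct <- direct + m$initial[[1]][i1] * m$initial[[2]][i2] * b1 * b2
  }
  expect_equal(log_forward(m, o)$loglik, log(direct), tolerance = 1e-12)
  # equal emissions across all states: P(O) = prod_t b(o_t)
  m_const <- m
  for (c_i in 1:2) {
    for (j in 1:2) {
      m_const$emissions[[c_i]]$mean[j, ] <- m$emissions[[c_i]]$mean[1, ]
      m_const$emissions[[c_i]]$var[j, ] <- m$emissions[[c_i]]$var[1, ]
    }
  }
  o3 <- sample_sequence(m_const, 4, seed = 3)$obs
  per_t <- vapply(1:4, function(t) {
    sum(dnorm(o3$o1[t, ], m_const$emissions[[1]]$mean[1, ],
              sqrt(m_const$emissions[[1]]$var[1, ]), log = TRUE)) +
      sum(dnorm(o3$o2[t, ], m_const$emissions[[2]]$mean[1, ],
                sqrt(m_const$emissions[[2]]$var[1, ]), log = TRUE))
  }, numeric(1))
  expect_equal(log_forward(m_const, o3)$loglik, sum(per_t), tolerance = 1e-9)
  expect_error(brute_force_loglik(m, obs_pair(matrix(0, 20, 2), matrix(0, 20, 3))),
               "too large")
})

test_that("sample_sequence is seeded and follows the transition law", {
  m <- uniform_chmm()
  s1 <- sample_sequence(m, 10, seed = 4)
  expect_identical(s1, sample_sequence(m, 10, seed = 4))
  # deterministic degenerate model follows its single path
  m_det <- m
  m_det$initial <- list(c(1, 0), c(0, 1))
  m_det$trans[[1]][] <- rep(c(0, 1), each = 4)     # always -> state 2
  m_det$trans[[2]][] <- rep(c(1, 0), each = 4)     # always -> state 1
  sd1 <- sample_sequence(m_det, 5, seed = 9)
  expect_identical(sd1$states[1, ], c(1L, 2L))
  expect_true(all(sd1$states[-1, 1] == 2L))
  expect_true(all(sd1$states[-1, 2] == 1L))
  # long-run transition frequencies within 3 standard errors
  m2 <- random_chmm(2, 2, seed = 21)
  sq <- sample_sequence(m2, 10000, seed = 22)
  comp <- (sq$states[, 1] - 1L) * 2L + sq$states[, 2]
  for (i in 1:4) {
    from <- which(comp[-10000] == i)
    if (length(from) < 100) next
    for (j1 in 1:2) {
      p_hat <- mean(sq$states[from + 1L, 1] == j1)
      p <- m2$trans[[1]][i, j1]
      se <- sqrt(p * (1 - p) / length(from))
      expect_lte(abs(p_hat - p), 3 * se + 1e-12)
    }
  }
})

test_that("single-state EM recovers pooled moments exactly", {
  m1 <- coupled_hmm(list(1, 1), list(matrix(1, 1, 1), matrix(1, 1, 1)),
                    list(list(mean = matrix(5, 1, 2), var = matrix(4, 1, 2)),
                         list(mean = matrix(0, 1, 1), var = matrix(1, 1, 1))))
  set.seed(12)
  dat <- lapply(1:5, function(i) {
    obs_pair(matrix(rnorm(20, 3), 10, 2), matrix(rnorm(10, -1), 10, 1))
  })
  fit <- em_fit(m1, dat, max_iter = 2, tol = 0)
  all1 <- do.call(rbind, lapply(dat, function(o) o$o1))
  all2 <- do.call(rbind, lapply(dat, function(o) o$o2))
  expect_equal(as.vector(fit$model$emissions[[1]]$mean), colMeans(all1),
               tolerance = 1e-12)
  expect_equal(as.vector(fit$model$emissions[[2]]$mean), colMeans(all2),
               tolerance = 1e-12)
})

test_that("EM started at the generating model barely moves", {
  m <- random_chmm(2, 2, seed = 31)
  dat <- lapply(1:100, function(i) sample_sequence(m, 15, seed = 3000 + i)$obs)
  fit <- em_fit(m, dat, max_iter = 2, tol = 0)
  tr <- fit$report$loglik_trace
  rel <- abs(diff(tr)) / abs(tr[1])
  expect_lt(rel, 10 * 1e-3)
})

test_that("EM keeps rows stochastic and the likelihood non-decreasing", {
  m_true <- random_chmm(2, 3, d1 = 2, d2 = 2, seed = 41)
  dat <- lapply(1:40, function(i) sample_sequence(m_true, 12, seed = 4000 + i)$obs)
  init <- random_chmm(2, 3, d1 = 2, d2 = 2, seed = 99)
  fit <- em_fit(init, dat, max_iter = 30, tol = 1e-10)
  tr <- fit$report$loglik_trace
  expect_true(all(diff(tr) >= -1e-8))
  expect_identical(validate_model(fit$model), character(0))
})

test_that("state_scores ranks dwell states correctly", {
  m <- uniform_chmm()
  # identical parameters for all states -> identical scores
  for (c_i in 1:2) {
    m$emissions[[c_i]]$mean[] <- 0
    m$emissions[[c_i]]$var[] <- 1
  }
  o <- obs_pair(matrix(rnorm(10), 5, 2), matrix(rnorm(10), 5, 2))
  sc <- state_scores(m, o)
  expect_lt(diff(range(sc)), 1e-12)
  # separated emissions: dwell data is assigned to its own state
  m_sep <- random_chmm(3, 3, d1 = 2, d2 = 2, seed = 55)
  for (c_i in 1:2) {
    m_sep$emissions[[c_i]]$mean <- matrix(c(0, 0, 6, 6, 12, 12), 3, 2, byrow = TRUE)
    m_sep$emissions[[c_i]]$var[] <- 1
  }
  hits <- 0
  for (r in 1:100) {
    i1 <- (r %% 3) + 1; i2 <- ((r %/% 3) %% 3) + 1
    set.seed(6000 + r)
    o1 <- matrix(rnorm(2 * 200, m_sep$emissions[[1]]$mean[i1, ]), 200, 2,
                 byrow = TRUE)
    o2 <- matrix(rnorm(2 * 200, m_sep$emissions[[2]]$mean[i2, ]), 200, 2,
                 byrow = TRUE)
    sc <- state_scores(m_sep, obs_pair(o1, o2))
    hits <- hits + (which.max(sc) == composite_index(m_sep, i1, i2))
  }
  expect_gte(hits, 99)
  # T = 1 with uniform initials/self-transitions: ranking = emission density
  o1f <- obs_pair(matrix(c(0.2, 0.1), 1, 2), matrix(c(5.9, 6.2), 1, 2))
  scf <- state_scores(m_sep, o1f)
  dens <- vapply(1:9, function(s) {
    i1 <- (s - 1) %/% 3 + 1; i2 <- (s - 1) %% 3 + 1
    sum(dnorm(o1f$o1[1, ], m_sep$emissions[[1]]$mean[i1, ], 1, log = TRUE)) +
      sum(dnorm(o1f$o2[1, ], m_sep$emissions[[2]]$mean[i2, ], 1, log = TRUE))
  }, numeric(1))
  expect_identical(order(scf), order(dens))
})

test_that("classify_word scores stages against the lexicon", {
  lex <- small_lexicon()
  m <- random_chmm(9, 9, d1 = 4, d2 = 12, seed = 71)
  o <- obs_pair(matrix(rnorm(40), 10, 4), matrix(rnorm(120), 10, 12))
  # single-candidate lexicon always wins
  solo <- lexicon(list(lexicon_entry(9, "only", "SHGV", rbind(c(2L, 2L)))), 9, 9)
  expect_identical(classify_word(m, list(o), solo)$word_id, 9L)
  # ties break to the smallest word_id
  tied <- lexicon(list(lexicon_entry(3, "b", "DHGV", rbind(c(4L, 4L))),
                       lexicon_entry(8, "a", "SHGV", rbind(c(4L, 4L)))), 9, 9)
  expect_identical(classify_word(m, list(o), tied)$word_id, 3L)
  # stage-count filtering and the no-candidate error
  expect_error(classify_word(m, list(o, o, o), lex), "no lexicon candidate")
  expect_error(classify_word(m, list(o), lex, category = "DGV"),
               "no lexicon candidate")
  # category restriction honors metadata
  got <- classify_word(m, list(o, o), lex, category = "DGV")
  expect_true(got$word_id %in% c(4L, 5L))
})

test_that("a synthetic two-stage word is recognized end to end", {
  lex <- small_lexicon()
  sw <- synthesize_word(lex$entries[[4]], fixture_profiles, fixture_templates,
                        fixture_cfg, seed = 81)
  segs <- segment_recording(sw$recording, fixture_seg_cfg)
  expect_length(segs[[1]]$stage_bounds, 2)
  # train a supervised model on a few draws of each word
  obs <- list(); labels <- list()
  for (e in lex$entries) for (r in 1:4) {
    swr <- synthesize_word(e, fixture_profiles, fixture_templates,
                           fixture_cfg, seed = 9000 + 10 * e$word_id + r)
    sgr <- segment_recording(swr$recording, fixture_seg_cfg)[[1]]
    for (k in seq_along(sgr$stage_bounds)) {
      sp <- window_to_samples(sgr$stage_bounds[[k]], fixture_seg_cfg)
      obs[[length(obs) + 1L]] <- build_observation_pair(swr$recording, sp)
      labels[[length(labels) + 1L]] <- c(e$stages[k, 1], e$stages[k, 2] + 1L)
    }
  }
  model <- supervised_chmm(obs, labels, 9, 9, var_reg = 1e-3)
  so <- lapply(segs[[1]]$stage_bounds, function(b) {
    build_observation_pair(sw$recording, window_to_samples(b, fixture_seg_cfg))
  })
  expect_identical(classify_word(model, so, lex)$word_id, 4L)
})

test_that("model JSON round trips exactly", {
  m <- random_chmm(3, 2, d1 = 2, d2 = 4, seed = 91)
  f <- withr::local_tempfile(fileext = ".json")
  write_chmm(m, f)
  m2 <- read_chmm(f)
  expect_identical(m2$initial, m$initial)
  expect_identical(m2$trans[[1]], unname(m$trans[[1]]))
  expect_identical(m2$trans[[2]], unname(m$trans[[2]]))
  expect_identical(m2$emissions[[1]]$mean, unname(m$emissions[[1]]$mean))
  expect_identical(m2$emissions[[2]]$var, unname(m$emissions[[2]]$var))
})
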