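# Shared fixtures, built in code. Everything is seeded so the suite is
# deterministic.

fixture_cfg <- synth_config()
fixture_profiles <- make_gesture_profiles(9, seed = 7)
fixture_templates <- make_trajectory_templates(9, seed = 3)

# segmenter calibrated once on a clean rest recording
fixture_seg_cfg <- local({
  rest <- synthesize_rest(10, fixture_cfg, seed = 11)
  th <- calibrate_thresholds(rest)
  segmenter_config(t_semg = th$t_semg, t_acc = th$t_acc)
})

# small lexicon: 3 one-stage words + 2 two-stage DGV words, hand-built
small_lexicon <- function() {
  lexicon(list(
    lexicon_entry(1, "alpha", "SHGV", rbind(c(1L, 2L))),
    lexicon_entry(2, "beta", "SHGV", rbind(c(3L, 0L))),
    lexicon_entry(3, "gamma", "DHGV", rbind(c(5L, 4L))),
    lexicon_entry(4, "delta", "DGV", rbind(c(2L, 1L), c(6L, 3L))),
    lexicon_entry(5, "epsilon", "DGV", rbind(c(7L, 0L), c(4L, 8L)))
  ), n_gestures = 9, n_movement_states = 9)
}

# a tiny deterministic uniform model for structural tests
uniform_chmm <- function(N1 = 2L, N2 = 2L, d1 = 2L, d2 = 2L) {
  S <- N1 * N2
  coupled_hmm(
    initial = list(rep(1 / N1, N1), rep(1 / N2, N2)),
    trans = list(matrix(1 / N1, S, N1), matrix(1 / N2, S, N2)),
    emissions = list(
      list(mean = matrix(seq_len(N1 * d1), N1, d1), var = matrix(1, N1, d1)),
      list(mean = matrix(seq_len(N2 * d2), N2, d2), var = matrix(1, N2, d2))
    )
  )
}

obs_pair <- function(o1, o2) {
  structure(list(o1 = o1, o2 = o2), class = "sf_obs_pair")
}

# align an estimated model's chain states to a reference by matching
# emission means; returns the permuted model
permute_chmm <- function(m, p1, p2) {
  N1 <- m$N1; N2 <- m$N2
  comp_perm <- integer(N1 * N2)
  for (i1 in seq_len(N1)) for (i2 in seq_len(N2)) {
    comp_perm[(i1 - 1L) * N2 + i2] <- (p1[i1] - 1L) * N2 + p2[i2]
  }
  # state j of the permuted model is state p[j] of the original
  m2 <- m
  m2$initial[[1]] <- m$initial[[1]][p1]
  m2$initial[[2]] <- m$initial[[2]][p2]
  m2$emissions[[1]]$mean <- m$emissions[[1]]$mean[p1, , drop = FALSE]
  m2$emissions[[1]]$var <- m$emissions[[1]]$var[p1, , drop = FALSE]
  m2$emissions[[2]]$mean <- m$emissions[[2]]$mean[p2, , drop = FALSE]
  m2$emissions[[2]]$var <- m$emissions[[2]]$var[p2, , drop = FALSE]
  m2$trans[[1]] <- m$trans[[1]][comp_perm, p1, drop = FALSE]
  m2$trans[[2]] <- m$trans[[2]][comp_perm, p2, drop = FALSE]
  m2
}

# best per-chain permutation of `est` matching `ref` by emission means
align_chmm <- function(est, ref) {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best_perm <- function(chain) {
    em_e <- est$emissions[[chain]]$mean; em_r <- ref$emissions[[chain]]$mean
    cand <- perms(seq_len(nrow(em_e)))
    costs <- vapply(cand, function(p) sum((em_e[p, , drop = FALSE] - em_r)^2),
                    numeric(1))
    cand[[which.min(costs)]]
  }
  permute_chmm(est, best_perm(1), best_perm(2))
}
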