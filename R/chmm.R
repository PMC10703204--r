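#' Two-chain coupled hidden Markov model
#'
#' The fusion classifier is a coupled HMM with two chains — a gesture chain
#' (states `1..N1`) and a movement-trajectory chain (states `1..N2`, state 1
#' being rest). The model state at time `t` is the composite pair
#' `q_t = (q_t^1, q_t^2)`; each chain's next state depends on the *composite*
#' previous state, and the two chains' transition probabilities multiply:
#' `a[(i1,i2),(j1,j2)] = a1[(i1,i2), j1] * a2[(i1,i2), j2]`. Initial
#' probabilities and emission densities factorize per chain the same way,
#' emissions being diagonal Gaussians on each chain's observation stream.
#' Composite states are enumerated chain-2-fastest:
#' `index(i1, i2) = (i1 - 1) * N2 + i2`.
#'
#' @name chmm
NULL

.VAR_FLOOR <- 1e-6

#' Construct a coupled HMM
#'
#' @param initial list of two probability vectors (`N1`, `N2` long).
#' @param trans list of two coupled transition matrices: `trans[[c]]` has
#'   `N1*N2` rows (composite previous state, chain-2-fastest) and `Nc`
#'   columns (chain `c` next state); every row sums to 1.
#' @param emissions list of two per-chain emission sets, each a list with
#'   `mean` and `var` matrices (`Nc` x stream dimension).
#' @return an `sf_chmm`. Errors when [validate_model()] reports violations.
#' @export
coupled_hmm <- function(initial, trans, emissions) {
  m <- structure(list(N1 = length(initial[[1]]), N2 = length(initial[[2]]),
                      initial = initial, trans = trans, emissions = emissions),
                 class = "sf_chmm")
  bad <- validate_model(m)
  if (length(bad)) {
    stop_domain("invalid coupled HMM:\n", paste0("  - ", bad, collapse = "\n"))
  }
  m
}

#' Validate a coupled HMM
#'
#' @param m an `sf_chmm` candidate.
#' @return character vector of violations (empty when the model is valid);
#'   violations name the chain and composite row concerned.
#' @export
validate_model <- function(m) {
  bad <- character(0)
  tol <- 1e-9
  S <- m$N1 * m$N2
  for (c_i in 1:2) {
    pi_c <- m$initial[[c_i]]
    if (any(pi_c < 0)) bad <- c(bad, paste0("chain ", c_i, ": negative initial probability"))
    if (abs(sum(pi_c) - 1) > tol) {
      bad <- c(bad, sprintf("chain %d: initial sums to %.12f, not 1", c_i, sum(pi_c)))
    }
    A <- m$trans[[c_i]]
    Nc <- if (c_i == 1) m$N1 else m$N2
    if (!is.matrix(A) || nrow(A) != S || ncol(A) != Nc) {
      bad <- c(bad, paste0("chain ", c_i, ": transition tensor must be ", S, " x ", Nc))
      next
    }
    if (any(A < 0)) bad <- c(bad, paste0("chain ", c_i, ": negative transition probability"))
    rs <- rowSums(A)
    off <- which(abs(rs - 1) > tol)
    for (i in off) {
      bad <- c(bad, sprintf("chain %d, composite row %d: row sums to %.12f, not 1",
                            c_i, i, rs[i]))
    }
    em <- m$emissions[[c_i]]
    if (nrow(em$mean) != Nc || !all(dim(em$mean) == dim(em$var))) {
      bad <- c(bad, paste0("chain ", c_i, ": emission dimensions inconsistent"))
    } else if (any(em$var < .VAR_FLOOR)) {
      bad <- c(bad, paste0("chain ", c_i, ": emission variance below the ",
                           .VAR_FLOOR, " floor"))
    }
  }
  bad
}

#' Composite index of a (gesture, movement-chain-state) pair
#'
#' Chain-2-fastest enumeration. Note that chain-2 state indices are 1-based
#' with state 1 = rest; a lexicon movement index `m` maps to chain-2 state
#' `m + 1`.
#'
#' @param m an `sf_chmm` (only `N2` is used).
#' @param i1 chain-1 (gesture) state, 1-based.
#' @param i2 chain-2 state, 1-based.
#' @return integer composite index in `1..N1*N2`.
#' @export
composite_index <- function(m, i1, i2) {
  (as.integer(i1) - 1L) * m$N2 + as.integer(i2)
}

#' Full composite transition matrix
#'
#' Expands the two coupled tensors into the `(N1*N2) x (N1*N2)` transition
#' matrix of the composite chain; every row sums to 1 because each chain's
#' row does.
#'
#' @param m a valid `sf_chmm`.
#' @return row-stochastic matrix in composite (chain-2-fastest) order.
#' @export
composite_transition_matrix <- function(m) {
  bad <- validate_model(m)
  if (length(bad)) stop_domain("invalid model: ", bad[1])
  S <- m$N1 * m$N2
  P <- matrix(0, S, S)
  for (j1 in seq_len(m$N1)) {
    cols <- (j1 - 1L) * m$N2 + seq_len(m$N2)
    P[, cols] <- m$trans[[1]][, j1] * m$trans[[2]]
  }
  P
}

# composite initial vector, chain-2-fastest: pi[(i1,i2)] = pi1[i1]*pi2[i2]
.composite_initial <- function(m) {
  as.vector(t(outer(m$initial[[1]], m$initial[[2]])))
}

# log diagonal-Gaussian densities of one stream under one chain's states:
# obs T x d, returns T x Nc
.log_dens_chain <- function(em, obs) {
  T_obs <- nrow(obs); Nc <- nrow(em$mean)
  out <- matrix(0, T_obs, Nc)
  for (j in seq_len(Nc)) {
    mu <- em$mean[j, ]; v <- em$var[j, ]
    z <- sweep(obs, 2L, mu)
    out[, j] <- -0.5 * (sum(log(2 * pi * v)) +
                          as.vector(z^2 %*% (1 / v)))
  }
  out
}

# composite log emission matrix, T x (N1*N2)
.log_emission <- function(m, obs) {
  lb1 <- .log_dens_chain(m$emissions[[1]], obs$o1)
  lb2 <- .log_dens_chain(m$emissions[[2]], obs$o2)
  T_obs <- nrow(lb1)
  out <- matrix(0, T_obs, m$N1 * m$N2)
  for (i1 in seq_len(m$N1)) {
    cols <- (i1 - 1L) * m$N2 + seq_len(m$N2)
    out[, cols] <- lb1[, i1] + lb2
  }
  list(comp = out, lb1 = lb1, lb2 = lb2)
}

.check_obs <- function(m, obs) {
  if (!inherits(obs, "sf_obs_pair")) stop_domain("obs must be an sf_obs_pair")
  if (nrow(obs$o1) < 1L) stop_domain("empty observation sequence")
  if (ncol(obs$o1) != ncol(m$emissions[[1]]$mean) ||
      ncol(obs$o2) != ncol(m$emissions[[2]]$mean)) {
    stop_domain("observation dimensions do not match emission dimensions")
  }
}

#' Log-domain forward recursion on the composite lattice
#'
#' Exact forward algorithm over the `N1*N2` composite states, computed in
#' the log domain with per-step max shifting.
#'
#' @param m a valid `sf_chmm`.
#' @param obs an `sf_obs_pair`.
#' @return list with `loglik` (`log P(O | lambda)`) and `alpha`
#'   (`T x N1*N2` log forward lattice).
#' @export
log_forward <- function(m, obs) {
  .check_obs(m, obs)
  P <- composite_transition_matrix(m)
  lB <- .log_emission(m, obs)$comp
  T_obs <- nrow(lB); S <- ncol(lB)
  alpha <- matrix(-Inf, T_obs, S)
  alpha[1, ] <- log(.composite_initial(m)) + lB[1, ]
  if (T_obs > 1L) {
    for (t in 2:T_obs) {
      mx <- max(alpha[t - 1L, ])
      if (!is.finite(mx)) break
      a <- exp(alpha[t - 1L, ] - mx)
      alpha[t, ] <- log(as.vector(crossprod(P, a))) + mx + lB[t, ]
    }
  }
  list(loglik = logsumexp(alpha[T_obs, ]), alpha = alpha)
}

# log-domain backward recursion; returns T x S log beta
.log_backward <- function(P, lB) {
  T_obs <- nrow(lB); S <- ncol(lB)
  beta <- matrix(0, T_obs, S)
  if (T_obs > 1L) {
    for (t in (T_obs - 1L):1L) {
      v <- beta[t + 1L, ] + lB[t + 1L, ]
      mx <- max(v)
      if (!is.finite(mx)) { beta[t, ] <- -Inf; next }
      beta[t, ] <- log(as.vector(P %*% exp(v - mx))) + mx
    }
  }
  beta
}

#' Brute-force log-likelihood by path enumeration
#'
#' Independent oracle for [log_forward()]: sums the probability of every
#' composite state path explicitly. Refuses state spaces with more than
#' `1e6` paths.
#'
#' @inheritParams log_forward
#' @return log probability of the observation pair.
#' @export
brute_force_loglik <- function(m, obs) {
  .check_obs(m, obs)
  S <- m$N1 * m$N2
  T_obs <- nrow(obs$o1)
  if (S^T_obs > 1e6) stop_domain("path space too large: ", S, "^", T_obs)
  lP <- log(composite_transition_matrix(m))
  lpi <- log(.composite_initial(m))
  lB <- .log_emission(m, obs)$comp
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), T_obs)))
  lp <- lpi[paths[, 1]] + lB[cbind(1L, paths[, 1])]
  if (T_obs > 1L) {
    for (t in 2:T_obs) {
      lp <- lp + lP[cbind(paths[, t - 1L], paths[, t])] + lB[cbind(t, paths[, t])]
    }
  }
  logsumexp(lp)
}

#' Sample a composite state path and observation pair from the model
#'
#' @param m a valid `sf_chmm`.
#' @param T_obs sequence length (>= 1).
#' @param seed RNG seed; identical seeds reproduce the draw.
#' @return list with `states` (`T x 2` matrix of chain states) and `obs`
#'   (an `sf_obs_pair`).
#' @export
sample_sequence <- function(m, T_obs, seed) {
  if (T_obs < 1L) stop_domain("T_obs must be >= 1")
  bad <- validate_model(m)
  if (length(bad)) stop_domain("invalid model: ", bad[1])
  with_seed(seed, {
    d1 <- ncol(m$emissions[[1]]$mean); d2 <- ncol(m$emissions[[2]]$mean)
    st <- matrix(0L, T_obs, 2L)
    o1 <- matrix(0, T_obs, d1); o2 <- matrix(0, T_obs, d2)
    draw <- function(p) sample.int(length(p), 1L, prob = p)
    st[1, 1] <- draw(m$initial[[1]]); st[1, 2] <- draw(m$initial[[2]])
    for (t in seq_len(T_obs)) {
      if (t > 1L) {
        row <- composite_index(m, st[t - 1L, 1], st[t - 1L, 2])
        st[t, 1] <- draw(m$trans[[1]][row, ])
        st[t, 2] <- draw(m$trans[[2]][row, ])
      }
      o1[t, ] <- stats::rnorm(d1, m$emissions[[1]]$mean[st[t, 1], ],
                              sqrt(m$emissions[[1]]$var[st[t, 1], ]))
      o2[t, ] <- stats::rnorm(d2, m$emissions[[2]]$mean[st[t, 2], ],
                              sqrt(m$emissions[[2]]$var[st[t, 2], ]))
    }
    list(states = st, obs = structure(list(o1 = o1, o2 = o2),
                                      class = "sf_obs_pair"))
  })
}

#' Baum-Welch (EM) training on the composite lattice
#'
#' E-step: exact forward-backward posteriors over composite states for each
#' sequence. M-step: per-chain initial vectors from the chain marginals of
#' the first-frame posterior; coupled transition tensors from expected
#' composite transition counts summed over the other chain's next state and
#' normalized per composite row; Gaussian emission means/variances from the
#' per-chain marginal posteriors. The total log-likelihood is non-decreasing
#' across iterations (up to `1e-8` numerical slack). Composite rows or
#' states with zero expected visits keep their previous values; emission
#' variances are floored at `1e-6` (with a warning on collapse).
#'
#' @param init a valid `sf_chmm` used as the starting point.
#' @param dataset non-empty list of `sf_obs_pair`.
#' @param max_iter iteration cap (default 100).
#' @param tol relative log-likelihood change for convergence (default 1e-6).
#' @param var_reg additive emission-variance regularization (MAP-style, as
#'   in hmmlearn's covariance prior), added to every re-estimated variance.
#'   The default 0 is plain maximum likelihood, for which the likelihood is
#'   guaranteed non-decreasing; positive values trade that guarantee for
#'   robustness against overconfident emissions (unmodeled inter-subject
#'   variation).
#' @return list with `model` (the fitted `sf_chmm`) and `report`
#'   (`loglik_trace`, `iterations`, `converged`, `final_change`).
#' @export
em_fit <- function(init, dataset, max_iter = 100L, tol = 1e-6, var_reg = 0) {
  if (length(dataset) == 0L) stop_domain("dataset must be non-empty")
  bad <- validate_model(init)
  if (length(bad)) stop_domain("invalid init model: ", bad[1])
  m <- init
  N1 <- m$N1; N2 <- m$N2; S <- N1 * N2
  d1 <- ncol(m$emissions[[1]]$mean); d2 <- ncol(m$emissions[[2]]$mean)
  # composite -> chain indicator matrices (S x Nc)
  I1 <- matrix(0, S, N1); I2 <- matrix(0, S, N2)
  for (i1 in seq_len(N1)) for (i2 in seq_len(N2)) {
    s <- (i1 - 1L) * N2 + i2
    I1[s, i1] <- 1; I2[s, i2] <- 1
  }
  trace <- numeric(0)
  converged <- FALSE
  change <- NA_real_
  warned_floor <- FALSE

  for (iter in seq_len(max_iter)) {
    P <- composite_transition_matrix(m)
    lP <- log(P)
    total_ll <- 0
    g_first <- numeric(S)
    C <- matrix(0, S, S)                   # expected transition counts
    W1 <- numeric(N1); M1s <- matrix(0, N1, d1); Q1s <- matrix(0, N1, d1)
    W2 <- numeric(N2); M2s <- matrix(0, N2, d2); Q2s <- matrix(0, N2, d2)

    for (obs in dataset) {
      lE <- .log_emission(m, obs)
      lB <- lE$comp
      T_obs <- nrow(lB)
      fw <- log_forward(m, obs)
      ll <- fw$loglik
      if (!is.finite(ll)) stop_domain("non-finite likelihood during EM")
      total_ll <- total_ll + ll
      beta <- .log_backward(P, lB)
      gamma <- exp(fw$alpha + beta - ll)   # T x S composite posteriors
      g_first <- g_first + gamma[1, ]
      if (T_obs > 1L) {
        for (t in seq_len(T_obs - 1L)) {
          lu <- fw$alpha[t, ]
          lv <- lB[t + 1L, ] + beta[t + 1L, ]
          C <- C + exp(outer(lu, lv, "+") - ll) * P
        }
      }
      g1 <- gamma %*% I1                   # T x N1 chain marginals
      g2 <- gamma %*% I2
      W1 <- W1 + colSums(g1); W2 <- W2 + colSums(g2)
      M1s <- M1s + crossprod(g1, obs$o1); Q1s <- Q1s + crossprod(g1, obs$o1^2)
      M2s <- M2s + crossprod(g2, obs$o2); Q2s <- Q2s + crossprod(g2, obs$o2^2)
    }
    trace <- c(trace, total_ll)
    if (iter > 1L) {
      change <- abs(trace[iter] - trace[iter - 1L]) /
        (abs(trace[iter - 1L]) + .Machine$double.eps)
      if (change < tol) { converged <- TRUE; break }
    }
    # ---- M-step ----
    p1 <- as.vector(crossprod(I1, g_first)); p2 <- as.vector(crossprod(I2, g_first))
    if (sum(p1) > 0) m$initial[[1]] <- p1 / sum(p1)
    if (sum(p2) > 0) m$initial[[2]] <- p2 / sum(p2)
    C1 <- C %*% I1; C2 <- C %*% I2         # S x Nc expected per-chain counts
    for (s in seq_len(S)) {
      if (sum(C1[s, ]) > 1e-300) m$trans[[1]][s, ] <- C1[s, ] / sum(C1[s, ])
      if (sum(C2[s, ]) > 1e-300) m$trans[[2]][s, ] <- C2[s, ] / sum(C2[s, ])
    }
    upd_em <- function(em, W, Ms, Qs) {
      for (j in seq_along(W)) {
        if (W[j] > 1e-300) {
          mu <- Ms[j, ] / W[j]
          v <- Qs[j, ] / W[j] - mu^2
          if (any(v < .VAR_FLOOR) && !warned_floor) {
            warning("emission variance collapsed; floored at ", .VAR_FLOOR,
                    call. = FALSE)
            warned_floor <<- TRUE
          }
          em$mean[j, ] <- mu
          em$var[j, ] <- pmax(v, .VAR_FLOOR) + var_reg
        }
      }
      em
    }
    m$emissions[[1]] <- upd_em(m$emissions[[1]], W1, M1s, Q1s)
    m$emissions[[2]] <- upd_em(m$emissions[[2]], W2, M2s, Q2s)
  }
  list(model = m,
       report = list(loglik_trace = trace, iterations = length(trace),
                     converged = converged, final_change = change))
}

#' Length-normalized dwell score of every composite state
#'
#' For composite state `s`, the score is the log-likelihood of the path that
#' enters `s` and stays there for the whole sequence, normalized by the
#' sequence length:
#' `score(s) = (log pi_s + (T-1) log a_{s,s} + sum_t log b_s(o_t)) / T`,
#' with `pi_s` and `a_{s,s}` the per-chain products. This is the per-state
#' output value a stage is classified on; a zero-probability self-transition
#' gives `-Inf`.
#'
#' @inheritParams log_forward
#' @return numeric vector of length `N1*N2` in composite order.
#' @export
state_scores <- function(m, obs) {
  .check_obs(m, obs)
  lE <- .log_emission(m, obs)
  T_obs <- nrow(lE$comp)
  lpi <- log(.composite_initial(m))
  self1 <- numeric(m$N1 * m$N2); self2 <- numeric(m$N1 * m$N2)
  for (i1 in seq_len(m$N1)) for (i2 in seq_len(m$N2)) {
    s <- (i1 - 1L) * m$N2 + i2
    self1[s] <- m$trans[[1]][s, i1]
    self2[s] <- m$trans[[2]][s, i2]
  }
  (lpi + (T_obs - 1) * (log(self1) + log(self2)) + colSums(lE$comp)) / T_obs
}

#' Classify a word from its per-stage observation pairs
#'
#' Every lexicon entry with the same number of stages as `stage_obs` (and,
#' when `category` is given, that category) is scored by summing, over
#' stages, the [state_scores()] value of the entry's stage state on that
#' stage's observations. The arg-max entry wins; exact ties go to the
#' smallest `word_id`.
#'
#' @param m a valid `sf_chmm` whose chain-2 states are
#'   `movement index + 1` (rest = state 1).
#' @param stage_obs list of `sf_obs_pair`, one per detected stage.
#' @param lex an `sf_lexicon`.
#' @param category optional category restriction (`"SHGV"`, `"DHGV"`,
#'   `"DGV"`), e.g. when the category is known from metadata.
#' @return list with `word_id`, `label`, and `ranking` — a `data.frame`
#'   (`word_id`, `label`, `score`) of all candidates, best first.
#' @export
classify_word <- function(m, stage_obs, lex, category = NULL) {
  if (length(stage_obs) < 1L) stop_domain("need at least one stage")
  n_stages <- length(stage_obs)
  cand <- Filter(function(e) {
    nrow(e$stages) == n_stages &&
      (is.null(category) || e$category == category)
  }, lex$entries)
  if (length(cand) == 0L) {
    stop_domain("no lexicon candidate with ", n_stages, " stage(s)",
                if (!is.null(category)) paste0(" in category ", category) else "")
  }
  score_mats <- lapply(stage_obs, function(o) state_scores(m, o))
  scores <- vapply(cand, function(e) {
    sum(vapply(seq_len(n_stages), function(k) {
      s <- composite_index(m, e$stages[k, "gesture"], e$stages[k, "movement"] + 1L)
      score_mats[[k]][s]
    }, numeric(1)))
  }, numeric(1))
  ids <- vapply(cand, function(e) e$word_id, integer(1))
  labels <- vapply(cand, function(e) e$label, character(1))
  ord <- order(-scores, ids)
  best <- ord[1]
  list(word_id = ids[best], label = labels[best],
       ranking = data.frame(word_id = ids[ord], label = labels[ord],
                            score = scores[ord], stringsAsFactors = FALSE))
}

#' Supervised warm start from labeled stage observations
#'
#' Builds an initial coupled HMM from dwell-labeled observation pairs (each
#' sequence labeled with the single composite state it was produced in):
#' emissions are per-chain-state moments of the labeled frames (states never
#' observed fall back to the pooled moments), initial vectors are
#' Laplace-smoothed label frequencies, and transition rows are
#' self-transition-dominated (`self_prob` on staying in the own chain
#' state, the remainder uniform).
#'
#' @param obs_list list of `sf_obs_pair`.
#' @param labels list (or matrix rows) of `(gesture, movement-chain-state)`
#'   1-based chain-state pairs, one per sequence.
#' @param N1,N2 chain sizes.
#' @param self_prob dwell probability of each chain (default 0.9).
#' @param smooth Laplace smoothing count for initial vectors (default 1).
#' @param var_reg additive emission-variance regularization, as in
#'   [em_fit()] (default 0).
#' @return a valid `sf_chmm`.
#' @export
supervised_chmm <- function(obs_list, labels, N1, N2, self_prob = 0.9,
                            smooth = 1, var_reg = 0) {
  if (length(obs_list) != length(labels)) stop_domain("one label per sequence required")
  lab <- do.call(rbind, lapply(labels, function(x) as.integer(x[1:2])))
  d1 <- ncol(obs_list[[1]]$o1); d2 <- ncol(obs_list[[1]]$o2)
  moments <- function(Nc, d, col, get) {
    all_x <- do.call(rbind, lapply(obs_list, get))
    gmu <- colMeans(all_x); gv <- pmax(apply(all_x, 2, stats::var), .VAR_FLOOR)
    mean_m <- matrix(rep(gmu, each = Nc), Nc, d)
    var_m <- matrix(rep(gv, each = Nc), Nc, d)
    for (j in seq_len(Nc)) {
      sel <- which(lab[, col] == j)
      if (length(sel)) {
        x <- do.call(rbind, lapply(obs_list[sel], get))
        mean_m[j, ] <- colMeans(x)
        if (nrow(x) > 1L) var_m[j, ] <- pmax(apply(x, 2, stats::var), .VAR_FLOOR)
      }
    }
    list(mean = mean_m, var = var_m + var_reg)
  }
  em1 <- moments(N1, d1, 1L, function(o) o$o1)
  em2 <- moments(N2, d2, 2L, function(o) o$o2)
  pi1 <- tabulate(lab[, 1], N1) + smooth; pi1 <- pi1 / sum(pi1)
  pi2 <- tabulate(lab[, 2], N2) + smooth; pi2 <- pi2 / sum(pi2)
  S <- N1 * N2
  row_c <- function(Nc, own) {
    if (Nc == 1L) return(rep(1, 1))
    r <- rep((1 - self_prob) / (Nc - 1L), Nc); r[own] <- self_prob; r
  }
  A1 <- matrix(0, S, N1); A2 <- matrix(0, S, N2)
  for (i1 in seq_len(N1)) for (i2 in seq_len(N2)) {
    s <- (i1 - 1L) * N2 + i2
    A1[s, ] <- row_c(N1, i1)
    A2[s, ] <- row_c(N2, i2)
  }
  coupled_hmm(list(pi1, pi2), list(A1, A2), list(em1, em2))
}

#' Random valid coupled HMM (testing / simulation helper)
#'
#' @param N1,N2 chain sizes.
#' @param d1,d2 stream dimensions.
#' @param seed RNG seed.
#' @return a valid `sf_chmm` with Dirichlet-like random probabilities and
#'   unit-scale random Gaussian emissions.
#' @export
random_chmm <- function(N1, N2, d1 = 2L, d2 = 2L, seed) {
  with_seed(seed, {
    S <- N1 * N2
    rdir <- function(n) { g <- stats::rgamma(n, 1); g / sum(g) }
    A1 <- t(vapply(seq_len(S), function(i) rdir(N1), numeric(N1)))
    A2 <- t(vapply(seq_len(S), function(i) rdir(N2), numeric(N2)))
    if (N1 == 1L) A1 <- matrix(1, S, 1L)
    if (N2 == 1L) A2 <- matrix(1, S, 1L)
    em <- function(Nc, d) list(mean = matrix(stats::rnorm(Nc * d, 0, 2), Nc, d),
                               var = matrix(stats::runif(Nc * d, 0.5, 1.5), Nc, d))
    coupled_hmm(list(rdir(N1), rdir(N2)), list(A1, A2),
                list(em(N1, d1), em(N2, d2)))
  })
}

#' Write a coupled HMM to JSON
#'
#' Numbers are serialized at full double precision (17 significant digits),
#' so a write/read round trip reproduces the model exactly.
#'
#' @param m an `sf_chmm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chmm <- function(m, path) {
  obj <- list(N1 = m$N1, N2 = m$N2,
              initial = m$initial,
              coupled_transitions = lapply(m$trans, function(A) {
                lapply(seq_len(nrow(A)), function(i) unname(A[i, ]))
              }),
              emissions = lapply(m$emissions, function(em) {
                list(mean = lapply(seq_len(nrow(em$mean)),
                                   function(i) unname(em$mean[i, ])),
                     var = lapply(seq_len(nrow(em$var)),
                                  function(i) unname(em$var[i, ])))
              }))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17)), path)
  invisible(path)
}

#' Read a coupled HMM from JSON
#'
#' @param path model file written by [write_chmm()].
#' @return a valid `sf_chmm`.
#' @export
read_chmm <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  A <- lapply(raw$coupled_transitions, function(rows) {
    do.call(rbind, lapply(rows, unlist))
  })
  em <- lapply(raw$emissions, function(e) {
    list(mean = do.call(rbind, lapply(e$mean, unlist)),
         var = do.call(rbind, lapply(e$var, unlist)))
  })
  coupled_hmm(lapply(raw$initial, unlist), A, em)
}

#' @export
print.sf_chmm <- function(x, ...) {
  cat(sprintf("<sf_chmm> chains %d x %d (%d composite states), streams %d-d / %d-d\n",
              x$N1, x$N2, x$N1 * x$N2,
              ncol(x$emissions[[1]]$mean), ncol(x$emissions[[2]]$mean)))
  invisible(x)
}
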