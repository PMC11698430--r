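# Independent oracles used by the unit and acceptance tests. These
# deliberately avoid the package's computational paths: brute-force
# enumeration, direct simulation of the null processes, and naive
# re-implementations of the formulas.

# --- Polya urn -------------------------------------------------------------

# exact distribution of the focal edge's weight by enumerating the urn
# process (reinforcement a, k categories, s sequential unit draws);
# feasible only for tiny s
polya_urn_enumerate <- function(s, k, a) {
  # state: count on the focal edge after t draws; transition probability
  # follows the urn composition (focal mass 1/a + c, rest (k-1)/a + (t - c))
  probs <- c(1, numeric(s))  # P(count = 0..s) after 0 draws
  for (t in seq_len(s)) {
    new <- numeric(s + 1L)
    for (c in 0:(t - 1L)) {
      pc <- probs[c + 1L]
      if (pc == 0) next
      p_focal <- (1 / a + c) / (k / a + (t - 1L))
      new[c + 2L] <- new[c + 2L] + pc * p_focal
      new[c + 1L] <- new[c + 1L] + pc * (1 - p_focal)
    }
    probs <- new
  }
  probs  # P(W = 0..s)
}

# Monte-Carlo urn: vectorized over replicates, sequential over the s draws
polya_urn_mc <- function(s, k, a, n_draws) {
  count <- numeric(n_draws)
  for (t in seq_len(s)) {
    p_focal <- (1 / a + count) / (k / a + (t - 1))
    count <- count + (runif(n_draws) < p_focal)
  }
  count
}

# --- ECM ensemble ----------------------------------------------------------

# draw networks from the fitted ensemble: pair (i, j) connected with
# probability p_ij, weight 1 + geometric(1 - y_i y_j) when connected
ecm_sample_stats <- function(params, edge_from, edge_to, edge_w, n_draws) {
  x <- params$x; y <- params$y
  nodes <- params$nodes
  n <- length(nodes)
  ij <- utils::combn(n, 2)
  i <- ij[1, ]; j <- ij[2, ]
  yy <- y[i] * y[j]
  p <- x[i] * x[j] * yy / (1 - yy + x[i] * x[j] * yy)
  npair <- length(p)
  # incidence matrix: node v x pair column, for fast per-draw strengths
  M <- matrix(0, n, npair)
  M[cbind(i, seq_len(npair))] <- 1
  M[cbind(j, seq_len(npair))] <- 1
  kacc <- sacc <- matrix(0, n_draws, n)
  eidx <- match(paste(edge_from, edge_to), paste(nodes[i], nodes[j]))
  eidx2 <- match(paste(edge_to, edge_from), paste(nodes[i], nodes[j]))
  eidx[is.na(eidx)] <- eidx2[is.na(eidx)]
  tail_hits <- numeric(length(eidx))
  for (d in seq_len(n_draws)) {
    exists <- runif(npair) < p
    w <- ifelse(exists, 1 + rgeom(npair, prob = 1 - yy), 0)
    kacc[d, ] <- as.numeric(M %*% exists)
    sacc[d, ] <- as.numeric(M %*% w)
    tail_hits <- tail_hits + (w[eidx] >= edge_w)
  }
  list(k_mean = colMeans(kacc), k_se = apply(kacc, 2, sd) / sqrt(n_draws),
       s_mean = colMeans(sacc), s_se = apply(sacc, 2, sd) / sqrt(n_draws),
       tail_freq = tail_hits / n_draws,
       tail_se = sqrt(pmax(tail_hits / n_draws * (1 - tail_hits / n_draws),
                           1e-12) / n_draws))
}

# --- GloSS shuffling -------------------------------------------------------

# fixed-topology weight randomization: weights drawn i.i.d. from the
# empirical weight distribution (the stated null); each edge's conditional
# p-value is estimated as the fraction of draws, among those whose endpoint
# strengths fall in a bin around the observed strengths, with drawn weight
# >= observed
gloss_shuffle_mc <- function(net, n_draws, tol_abs = 1) {
  et <- edge_table(net)
  s_obs <- node_strengths(net)
  w <- et$weight
  m <- nrow(et)
  n <- length(s_obs)
  hits <- trials <- numeric(m)
  fi <- match(et$from, names(s_obs))
  ti <- match(et$to, names(s_obs))
  M <- matrix(0, n, m)
  M[cbind(fi, seq_len(m))] <- 1
  M[cbind(ti, seq_len(m))] <- 1
  for (d in seq_len(n_draws)) {
    ws <- sample(w, m, replace = TRUE)
    s_dr <- as.numeric(M %*% ws)
    cond <- abs(s_dr[fi] - s_obs[fi]) <= tol_abs &
            abs(s_dr[ti] - s_obs[ti]) <= tol_abs
    trials <- trials + cond
    hits <- hits + (cond & ws >= w)
  }
  list(p_hat = ifelse(trials > 0, hits / trials, NA_real_), trials = trials)
}

# --- corrections and metrics ----------------------------------------------

# step-up BH: largest i with p_(i) <= i * alpha / m rejects hypotheses 1..i
bh_stepup_reject <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= seq_len(m) * alpha / m)
  rej <- logical(m)
  if (length(below)) rej[ord[seq_len(max(below))]] <- TRUE
  rej
}

ks_bruteforce <- function(a, b) {
  d <- 0
  for (x in c(a, b)) {
    d <- max(d, abs(mean(a <= x) - mean(b <= x)))
  }
  d
}

# small deterministic heterogeneous test network (no package generator)
toy_random_network <- function(n, p_edge, wmax, seed) {
  set.seed(seed)
  pairs <- utils::combn(paste0("v", seq_len(n)), 2)
  keep <- runif(ncol(pairs)) < p_edge
  if (!any(keep)) keep[1] <- TRUE
  suppressWarnings(weighted_network(data.frame(
    from = pairs[1, keep], to = pairs[2, keep],
    weight = sample(seq_len(wmax), sum(keep), replace = TRUE))))
}
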