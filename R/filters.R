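# Per-edge significance under the seven null models.
#
# Conventions shared by all filters:
#   * every edge of the network gets exactly one p-value in [0, 1];
#   * for the per-endpoint filters (df, pf, lans) the edge p-value is the
#     minimum of the two one-sided endpoint p-values, which are also stored;
#   * a degree-1 endpoint has a degenerate null (its single edge carries the
#     whole strength), contributing p = 1 for df/pf; lans counts strictly
#     greater incident weights and so gives 0 there.

new_edge_pvalues <- function(net, method, p, side_from = NULL, side_to = NULL,
                             params = list()) {
  et <- edge_table(net)
  stopifnot(length(p) == nrow(et), all(p >= 0 & p <= 1 + 1e-12))
  et$p <- pmin(p, 1)
  if (!is.null(side_from)) {
    et$p_side_from <- pmin(side_from, 1)
    et$p_side_to <- pmin(side_to, 1)
  }
  structure(et,
            class = c("edge_pvalues", class(et)),
            method = method, m = nrow(et), params = params)
}

#' @export
print.edge_pvalues <- function(x, ...) {
  cat(sprintf("<edge_pvalues> method '%s', %d edges\n",
              attr(x, "method"), attr(x, "m")))
  NextMethod()
}

# endpoint degree/strength aligned with edge_table() rows
endpoint_stats <- function(net) {
  et <- edge_table(net)
  k <- node_degrees(net)
  s <- node_strengths(net)
  list(et = et,
       k_from = unname(k[et$from]), k_to = unname(k[et$to]),
       s_from = unname(s[et$from]), s_to = unname(s[et$to]))
}

require_integer_weights <- function(net, method) {
  rep_ <- validate_for_method(net, method)
  if (!rep_$ok) {
    stop(paste(rep_$messages, collapse = "; "),
         " (see validate_for_method())", call. = FALSE)
  }
  invisible(TRUE)
}

#' Compute edge p-values under a chosen null model
#'
#' Dispatches to one of the seven filters. See the individual functions for
#' the null models: [disparity_pvalues()], [polya_pvalues()],
#' [mlf_pvalues()], [nc_pvalues()], [ecm_pvalues()], [gloss_pvalues()],
#' [lans_pvalues()].
#'
#' @param net A `weighted_network`.
#' @param method One of [filter_methods()].
#' @param pf_a Polya urn reinforcement parameter (method `"pf"`).
#' @param gloss_mode `"conditional"` or `"marginal"` (method `"gloss"`).
#' @param ecm_tol,ecm_max_iter Solver controls for method `"ecm"`.
#' @param ecm_params Optionally a pre-fitted [ecm_fit()] result.
#' @return An `edge_pvalues` tibble: `from`, `to`, `weight`, `p` and, for the
#'   per-endpoint methods, `p_side_from`, `p_side_to`.
#' @export
edge_pvalues <- function(net, method, pf_a = 1,
                         gloss_mode = c("conditional", "marginal"),
                         ecm_tol = 1e-6, ecm_max_iter = 5000,
                         ecm_params = NULL) {
  method <- match.arg(method, filter_methods())
  switch(method,
    df = disparity_pvalues(net),
    pf = polya_pvalues(net, a = pf_a),
    mlf = mlf_pvalues(net),
    nc = nc_pvalues(net),
    ecm = {
      if (is.null(ecm_params)) {
        ecm_params <- ecm_fit(net, tol = ecm_tol, max_iter = ecm_max_iter)
      }
      ecm_pvalues(net, ecm_params)
    },
    gloss = gloss_pvalues(net, mode = match.arg(gloss_mode)),
    lans = lans_pvalues(net)
  )
}

#' Disparity filter p-values
#'
#' Null model: a node of degree \eqn{k} splits its strength uniformly at
#' random among its edges, so each normalized weight \eqn{w/s} behaves as the
#' minimum-free marginal of a uniform partition. The one-sided p-value from
#' endpoint \eqn{i} with \eqn{k_i > 1} is
#' \deqn{p_i(e) = (1 - w_e/s_i)^{k_i - 1},}
#' a degree-1 endpoint contributes 1, and the edge p-value is the minimum of
#' the two endpoint values.
#'
#' @param net A `weighted_network` (any positive weights).
#' @return An `edge_pvalues` tibble.
#' @export
disparity_pvalues <- function(net) {
  es <- endpoint_stats(net)
  w <- es$et$weight
  side <- function(k, s) ifelse(k > 1L, pmax(0, 1 - w / s)^(k - 1L), 1)
  pf_ <- side(es$k_from, es$s_from)
  pt_ <- side(es$k_to, es$s_to)
  new_edge_pvalues(net, "df", pmin(pf_, pt_), pf_, pt_)
}

# log-space beta-binomial survival P(W >= w), W ~ BetaBinomial(n, alpha, beta)
betabinom_survival <- function(w, n, alpha, beta) {
  if (w <= 0) return(1)
  if (w > n) return(0)
  x <- w:n
  lp <- lchoose(n, x) + lbeta(x + alpha, n - x + beta) - lbeta(alpha, beta)
  mx <- max(lp)
  min(1, exp(mx + log(sum(exp(lp - mx)))))
}

#' Polya urn filter p-values
#'
#' Null model: a node of degree \eqn{k} and strength \eqn{s} allocates its
#' \eqn{s} weight units among its edges by a Polya urn with reinforcement
#' parameter \eqn{a}; the weight on one edge is then beta-binomial,
#' \eqn{W \sim \mathrm{BetaBin}(n = s, \alpha = 1/a, \beta = (k-1)/a)}.
#' The one-sided p-value from an endpoint with \eqn{k > 1} is the survival
#' \eqn{P(W \ge w_e)} (computed in log space); a degree-1 endpoint
#' contributes 1; the edge p-value is the minimum over endpoints. With
#' \eqn{a = 1} and large \eqn{s} the null converges to the disparity filter's.
#'
#' @param net A `weighted_network` with integer weights.
#' @param a Reinforcement parameter, \eqn{a > 0}. Larger values make past
#'   allocations more attractive (heavier-tailed null).
#' @return An `edge_pvalues` tibble.
#' @export
polya_pvalues <- function(net, a = 1) {
  stopifnot(a > 0)
  require_integer_weights(net, "pf")
  es <- endpoint_stats(net)
  w <- round(es$et$weight)
  side <- function(k, s) {
    vapply(seq_along(w), function(i) {
      if (k[i] <= 1L) return(1)
      betabinom_survival(w[i], round(s[i]), 1 / a, (k[i] - 1) / a)
    }, numeric(1))
  }
  pf_ <- side(es$k_from, es$s_from)
  pt_ <- side(es$k_to, es$s_to)
  new_edge_pvalues(net, "pf", pmin(pf_, pt_), pf_, pt_,
                   params = list(a = a))
}

# shared binomial-survival machinery for mlf/nc
binomial_edge_pvalues <- function(net, method, n_trials, q_fun) {
  require_integer_weights(net, method)
  es <- endpoint_stats(net)
  w <- round(es$et$weight)
  q <- q_fun(es$s_from, es$s_to)
  if (any(q > 1)) {
    warning("null connection probability q > 1 clipped for ",
            sum(q > 1), " edge(s)", call. = FALSE)
    q <- pmin(q, 1)
  }
  p <- pbinom(w - 1, n_trials, q, lower.tail = FALSE)
  new_edge_pvalues(net, method, p)
}

#' Marginal likelihood filter p-values
#'
#' Null model: the network's \eqn{T} weight units are placed independently,
#' each landing on the node pair \eqn{(i, j)} with probability
#' \eqn{q_{ij} = s_i s_j / (2 T^2)}, preserving the total weight exactly and
#' the strength sequence on average. The (symmetric) edge p-value is the
#' binomial survival \eqn{P(X \ge w_e)}, \eqn{X \sim \mathrm{Bin}(T, q_{ij})},
#' evaluated through the regularized incomplete beta function.
#'
#' @param net A `weighted_network` with integer weights.
#' @return An `edge_pvalues` tibble.
#' @export
mlf_pvalues <- function(net) {
  T_ <- round(total_weight(net))
  binomial_edge_pvalues(net, "mlf", T_, function(si, sj) si * sj / (2 * T_^2))
}

#' Noise corrected filter p-values
#'
#' Binomial approximation of the noise-corrected null: with
#' \eqn{N_t = \sum_i s_i = 2T} trials and pair probability
#' \eqn{q_{ij} = s_i s_j / N_t^2}, the edge p-value is
#' \eqn{P(X \ge w_e)}, \eqn{X \sim \mathrm{Bin}(N_t, q_{ij})}. The null mean
#' \eqn{s_i s_j / N_t} coincides with the marginal likelihood filter's; the
#' variance differs, which is what separates the two methods in practice.
#'
#' @param net A `weighted_network` with integer weights.
#' @return An `edge_pvalues` tibble.
#' @export
nc_pvalues <- function(net) {
  Nt <- round(2 * total_weight(net))
  binomial_edge_pvalues(net, "nc", Nt, function(si, sj) si * sj / Nt^2)
}

#' Global statistical significance (GloSS) p-values
#'
#' Null model: edge weights are randomly drawn from the network's empirical
#' weight distribution \eqn{\hat P(w)} over the fixed observed topology.
#'
#' In `"marginal"` mode the p-value is the plain survival
#' \eqn{\Pr_{W \sim \hat P}(W \ge w_e)}. In `"conditional"` mode (default)
#' the null law of an edge's weight is conditioned on its endpoints' observed
#' strengths and degrees,
#' \deqn{p(w \mid s_i, s_j, k_i, k_j) \propto \hat P(w)\,
#'   Q^{(k_i-1)}(s_i - w)\, Q^{(k_j-1)}(s_j - w),}
#' where \eqn{Q^{(m)}} is the m-fold convolution of \eqn{\hat P}
#' (\eqn{Q^{(0)}} a point mass at 0), and the p-value is the tail mass at or
#' above \eqn{w_e} after normalization. Conditional mode requires integer
#' weights (the convolutions live on the integer grid).
#'
#' @param net A `weighted_network`.
#' @param mode `"conditional"` or `"marginal"`.
#' @return An `edge_pvalues` tibble.
#' @export
gloss_pvalues <- function(net, mode = c("conditional", "marginal")) {
  mode <- match.arg(mode)
  es <- endpoint_stats(net)
  w_all <- es$et$weight
  if (mode == "marginal") {
    p <- vapply(w_all, function(w) mean(w_all >= w), numeric(1))
    return(new_edge_pvalues(net, "gloss", p, params = list(mode = mode)))
  }
  require_integer_weights(net, "gloss")
  w <- round(w_all)
  wmax <- max(w)
  # empirical pmf on 1..wmax
  f <- tabulate(w, nbins = wmax) / length(w)
  s_from <- round(es$s_from); s_to <- round(es$s_to)
  kmax <- max(es$k_from, es$k_to)
  # Q[[m + 1]] = m-fold convolution of f, support 0..(m * wmax);
  # f0 puts f on the 0-based grid so each convolution extends it by wmax
  f0 <- c(0, f)
  Q <- vector("list", kmax)
  Q[[1L]] <- 1
  if (kmax > 1L) {
    for (m in 2:kmax) {
      Q[[m]] <- pmax(stats::convolve(Q[[m - 1L]], rev(f0), type = "open"), 0)
    }
  }
  # value of Q^{(m)} at integer t (support 0..m*wmax), zero outside
  qm_at <- function(m, t) {
    v <- numeric(length(t))
    ok <- t >= 0 & t <= m * wmax
    v[ok] <- Q[[m + 1L]][t[ok] + 1L]
    v
  }
  support <- seq_len(wmax)
  fpos <- f
  empty <- 0L
  p <- vapply(seq_along(w), function(e) {
    g <- fpos *
      qm_at(es$k_from[e] - 1L, s_from[e] - support) *
      qm_at(es$k_to[e] - 1L, s_to[e] - support)
    tot <- sum(g)
    if (tot <= 0) {
      empty <<- empty + 1L
      return(1)
    }
    sum(g[support >= w[e]]) / tot
  }, numeric(1))
  if (empty > 0L) {
    warning("empty conditional support for ", empty,
            " edge(s); p = 1 assigned", call. = FALSE)
  }
  new_edge_pvalues(net, "gloss", pmin(pmax(p, 0), 1),
                   params = list(mode = mode))
}

#' Locally adaptive network sparsification (LANS) p-values
#'
#' Each endpoint scores its edge against the empirical distribution of its own
#' incident weights: the one-sided p-value from endpoint \eqn{i} is the
#' fraction of \eqn{i}'s incident edges strictly heavier than the edge,
#' \eqn{p_i(e) = |\{e' \ni i : w_{e'} > w_e\}| / k_i}. The edge p-value is the
#' minimum over the two endpoints. Every node's strongest edge gets a one-sided
#' p of 0, so LANS retains at least one edge per node at any \eqn{\alpha > 0}.
#'
#' @param net A `weighted_network` (any positive weights).
#' @return An `edge_pvalues` tibble.
#' @export
lans_pvalues <- function(net) {
  es <- endpoint_stats(net)
  et <- es$et
  # incident weight lists per node
  inc <- split(c(et$weight, et$weight), c(et$from, et$to))
  side <- function(nodes) {
    vapply(seq_len(nrow(et)), function(e) {
      ws <- inc[[nodes[e]]]
      sum(ws > et$weight[e]) / length(ws)
    }, numeric(1))
  }
  pf_ <- side(et$from)
  pt_ <- side(et$to)
  new_edge_pvalues(net, "lans", pmin(pf_, pt_), pf_, pt_)
}
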