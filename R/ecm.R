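# Enhanced configuration model: maximum-entropy ensemble of weighted networks
# constrained to reproduce both the degree and the strength sequence of the
# observed network (in expectation). Each node carries two Lagrange
# multipliers, x_i (degree) and y_i (strength); under the ensemble a pair
# (i, j) is connected with probability
#     p_ij = x_i x_j y_i y_j / (1 - y_i y_j + x_i x_j y_i y_j)
# and, conditional on being connected, its weight is geometric with
# success probability 1 - y_i y_j, so <w_ij> = p_ij / (1 - y_i y_j).

ecm_expectations <- function(x, y) {
  XY <- outer(x, x) * outer(y, y)
  YY <- outer(y, y)
  D <- 1 - YY + XY
  P <- XY / D
  diag(P) <- 0
  W <- P / (1 - YY)
  diag(W) <- 0
  list(P = P, W = W, YY = YY, D = D)
}

# log-likelihood of the ensemble given the observed (k, s); concave in the
# natural parameters (log x, log y), whose gradient is exactly the residual
# of the degree/strength constraints
ecm_loglik <- function(u, b, k, s) {
  x <- exp(u); y <- exp(b)
  YY <- outer(y, y)
  D <- 1 - YY + outer(x, x) * YY
  pen <- log(D / (1 - YY))
  diag(pen) <- 0
  sum(k * u) + sum(s * b) - sum(pen) / 2
}

ecm_grad <- function(u, b, k, s) {
  ex <- ecm_expectations(exp(u), exp(b))
  c(k - rowSums(ex$P), s - rowSums(ex$W))
}

# analytic Jacobian of the constraint residuals wrt (log x, log y)
ecm_jacobian <- function(x, y) {
  n <- length(x)
  YY <- outer(y, y)
  TT <- outer(x, x)
  D <- 1 - YY + TT * YY
  Pt <- YY * (1 - YY) / D^2          # d p_ij / d (x_i x_j)
  Pz <- TT / D^2                     # d p_ij / d (y_i y_j)
  Wt <- YY / D^2                     # d w_ij / d (x_i x_j)
  Wz <- TT * ((1 - YY) + YY * D) / (D^2 * (1 - YY)^2)
  diag(Pt) <- diag(Pz) <- diag(Wt) <- diag(Wz) <- 0
  # d F_i / d log(theta_l): off-diagonal entries go through the pair product
  # (x_i x_l or y_i y_l); the diagonal collects the node's own derivative,
  # which carries the same product, so both reduce to M * outer(theta, theta)
  A <- Pt * outer(x, x);  diag(A) <- rowSums(Pt * outer(x, x))
  Bm <- Pz * outer(y, y); diag(Bm) <- rowSums(Pz * outer(y, y))
  Cm <- Wt * outer(x, x); diag(Cm) <- rowSums(Wt * outer(x, x))
  Em <- Wz * outer(y, y); diag(Em) <- rowSums(Wz * outer(y, y))
  rbind(cbind(A, Bm), cbind(Cm, Em))
}

#' Fit the enhanced configuration model
#'
#' Solves the 2n-equation system \eqn{\sum_{j \ne i} p_{ij} = k_i} and
#' \eqn{\sum_{j \ne i} p_{ij}/(1 - y_i y_j) = s_i} for the per-node
#' multipliers \eqn{x_i > 0} and \eqn{y_i \in (0, 1)}. The system is the
#' stationarity condition of the ensemble's log-likelihood, which is concave
#' in \eqn{(\log x, \log y)}: the solver runs L-BFGS-B on that likelihood
#' from the deterministic start
#' (\eqn{x_i = k_i/\sqrt{\sum k}}, \eqn{y_i = s_i/(1 + \sum s)}) and then
#' polishes with damped Newton steps on the constraint residuals, so fits
#' are reproducible without random restarts.
#'
#' @param net A `weighted_network` with integer weights.
#' @param tol Convergence tolerance on both residual maxima
#'   \eqn{\max_i |\langle k_i \rangle - k_i|} and
#'   \eqn{\max_i |\langle s_i \rangle - s_i|}.
#' @param max_iter Iteration budget (shared by the two phases).
#' @return An `ecm_parameters` list: `x`, `y` (named by node), `residual_k`,
#'   `residual_s`, `iterations`, and the node names the fit belongs to.
#' @export
ecm_fit <- function(net, tol = 1e-6, max_iter = 5000) {
  require_integer_weights(net, "ecm")
  k <- as.numeric(node_degrees(net))
  s <- as.numeric(node_strengths(net))
  n <- length(k)
  if (n < 3L) stop("ECM fit needs at least 3 nodes", call. = FALSE)
  nodes <- names(node_degrees(net))
  u <- log(k / sqrt(sum(k)))
  b <- log(s / (1 + sum(s)))
  # phase 1: concave likelihood maximization in the log-parameters
  opt <- stats::optim(
    par = c(u, b),
    fn = function(th) -ecm_loglik(th[1:n], th[(n + 1):(2 * n)], k, s),
    gr = function(th) -ecm_grad(th[1:n], th[(n + 1):(2 * n)], k, s),
    method = "L-BFGS-B",
    lower = c(rep(-Inf, n), rep(-log(1e12), n)),
    upper = c(rep(log(1e12), n), rep(-1e-12, n)),
    control = list(maxit = min(max_iter, 500L), factr = 10)
  )
  u <- opt$par[1:n]; b <- opt$par[(n + 1):(2 * n)]
  iterations <- opt$counts[["function"]]
  # phase 2: Levenberg-Marquardt polish of the constraint residuals, with
  # the analytic Jacobian in the log-parameters
  if (max(abs(ecm_grad(u, b, k, s))) > tol) {
    lm <- minpack.lm::nls.lm(
      par = c(u, b),
      fn = function(th) -ecm_grad(th[1:n], th[(n + 1):(2 * n)], k, s),
      jac = function(th) ecm_jacobian(exp(th[1:n]), exp(th[(n + 1):(2 * n)])),
      upper = c(rep(log(1e12), n), rep(-1e-12, n)),
      lower = c(rep(-log(1e12), n), rep(-log(1e12), n)),
      control = minpack.lm::nls.lm.control(
        maxiter = min(max_iter, 1000L), ftol = 0, ptol = 1e-15, gtol = 0)
    )
    u <- lm$par[1:n]; b <- lm$par[(n + 1):(2 * n)]
    iterations <- iterations + lm$niter
  }
  x <- exp(u); y <- exp(b)
  g <- ecm_grad(u, b, k, s)
  residual_k <- max(abs(g[1:n]))
  residual_s <- max(abs(g[(n + 1):(2 * n)]))
  # a multiplier pinned at the box bound means the solution lies on the
  # boundary of the parameter space: some constraint (typically p_ij -> 1
  # for a node adjacent to all others) is only attainable in the limit
  at_bound <- x >= 1e12 * (1 - 1e-6) | y >= 1 - 1e-9
  if (any(at_bound)) {
    stop("ECM constraints saturated: no interior solution; offending node(s): ",
         paste(head(nodes[at_bound], 5L), collapse = ", "), call. = FALSE)
  }
  if (max(residual_k, residual_s) > tol) {
    sat <- nodes[k == n - 1L]
    extra <- if (length(sat)) {
      paste0("; node(s) adjacent to all others (saturated connection ",
             "probability): ", paste(head(sat, 5L), collapse = ", "))
    } else ""
    stop(sprintf(
      paste0("ECM fit did not converge ",
             "(residual_k = %.3g, residual_s = %.3g, tol = %.3g)%s"),
      residual_k, residual_s, tol, extra), call. = FALSE)
  }
  structure(list(x = setNames(x, nodes), y = setNames(y, nodes),
                 residual_k = residual_k, residual_s = residual_s,
                 iterations = iterations, tol = tol, nodes = nodes),
            class = "ecm_parameters")
}

#' @export
print.ecm_parameters <- function(x, ...) {
  cat(sprintf(
    "<ecm_parameters> %d nodes, %d iterations, residuals k %.2e / s %.2e\n",
    length(x$x), x$iterations, x$residual_k, x$residual_s))
  invisible(x)
}

#' Enhanced configuration model p-values
#'
#' With fitted multipliers, the null weight of an edge has the
#' zero-inflated-geometric law of the maximum-entropy ensemble, whose tail is
#' closed form:
#' \deqn{P(W_{ij} \ge w) = \frac{x_i x_j (y_i y_j)^w}
#'   {1 - y_i y_j + x_i x_j y_i y_j}.}
#' At \eqn{w = 1} this is the ensemble connection probability \eqn{p_{ij}}.
#' The edge p-value is this survival evaluated at the observed weight
#' (symmetric in the endpoints).
#'
#' @param net A `weighted_network` with integer weights.
#' @param params An [ecm_fit()] result fitted on `net`.
#' @return An `edge_pvalues` tibble.
#' @export
ecm_pvalues <- function(net, params) {
  stopifnot(inherits(params, "ecm_parameters"))
  et <- edge_table(net)
  if (!setequal(params$nodes, unique(c(et$from, et$to)))) {
    stop("ECM parameters were fitted on a different network", call. = FALSE)
  }
  xi <- params$x[et$from]; xj <- params$x[et$to]
  yi <- params$y[et$from]; yj <- params$y[et$to]
  w <- round(et$weight)
  yy <- yi * yj
  p <- exp(log(xi) + log(xj) + w * log(yy)) / (1 - yy + xi * xj * yy)
  new_edge_pvalues(net, "ecm", pmin(pmax(unname(p), 0), 1),
                   params = list(tol = params$tol,
                                 iterations = params$iterations))
}
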