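# Scalar measures used by the evaluation studies: rank correlation, overlap,
# per-edge properties, graph-level properties, and the two-sample KS distance.

#' Tie-aware Spearman rank correlation
#'
#' Pearson correlation of mean ranks (reducing to the classical
#' rank-difference formula when there are no ties). Constant input has no
#' rank ordering, so the correlation is undefined and returned as `NA` with
#' a warning.
#'
#' @param x,y Numeric vectors of equal length (at least 2).
#' @return A correlation in \[-1, 1\], or `NA`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L || sd(x) == 0 || sd(y) == 0) {
    warning("constant input: Spearman correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  unname(cor(x, y, method = "spearman"))
}

#' Asymmetric overlap coefficient
#'
#' The per-viewpoint overlap \eqn{|X \cap Y| / |X|}: the fraction of `x`'s
#' elements also found in `y`. Asymmetric by design, which is what makes the
#' backbone-overlap heatmap readable as "X's edges are contained in Y's".
#'
#' @param x,y Sets given as vectors (duplicates ignored).
#' @return A value in \[0, 1\], or `NA` with a warning when `x` is empty
#'   (as happens for backbones emptied by correction).
#' @export
overlap_from <- function(x, y) {
  x <- unique(x); y <- unique(y)
  if (length(x) == 0L) {
    warning("empty reference set: overlap undefined", call. = FALSE)
    return(NA_real_)
  }
  length(intersect(x, y)) / length(x)
}

#' Per-edge properties on the original network
#'
#' `edge_degree()` is the product of the endpoint degrees
#' \eqn{k(i,j) = k_i k_j} (large values flag hub-hub edges).
#' `edge_betweenness_values()` is the sum over unordered node pairs of the
#' fraction of shortest paths through the edge; by default shortest paths are
#' hop counts (`distance = "hops"`), with `distance = "inverse_weight"`
#' treating \eqn{1/w} as edge length.
#'
#' @param net A `weighted_network`.
#' @param distance `"hops"` or `"inverse_weight"`.
#' @return A numeric vector aligned with [edge_table()] rows.
#' @export
edge_degree <- function(net) {
  es <- endpoint_stats(net)
  es$k_from * es$k_to
}

#' @rdname edge_degree
#' @export
edge_betweenness_values <- function(net, distance = c("hops", "inverse_weight")) {
  distance <- match.arg(distance)
  wts <- if (distance == "hops") NA else 1 / igraph::E(net)$weight
  b <- igraph::edge_betweenness(net, directed = FALSE, weights = wts)
  # align igraph's edge order with the canonical edge_table() order
  el <- igraph::as_data_frame(net, what = "edges")
  ord <- order(pmin(el$from, el$to), pmax(el$from, el$to), method = "radix")
  b[ord]
}

#' Graph-level backbone properties
#'
#' `weight_entropy()` is the Shannon entropy (bits) of the edge-weight shares
#' \eqn{q_e = w_e / \sum w}. `reachability()` is the fraction of ordered node
#' pairs joined by a path, over the graph's own node set. `transitivity_ratio()`
#' is \eqn{3\Delta/\tau} (0 when there are no connected triples), and
#' `component_count()` the number of connected components.
#'
#' @param net A `weighted_network`, a `backbone`, or `NULL` (empty backbone),
#'   in which case `NA` is returned.
#' @return A scalar.
#' @export
weight_entropy <- function(net) {
  if (is.null(net)) return(NA_real_)
  if (inherits(net, "backbone")) net <- net$graph
  if (is.null(net) || igraph::ecount(net) == 0L) return(NA_real_)
  q <- igraph::E(net)$weight / total_weight(net)
  -sum(q * log2(q))
}

#' @rdname weight_entropy
#' @export
reachability <- function(net) {
  if (is.null(net)) return(NA_real_)
  if (inherits(net, "backbone")) net <- net$graph
  if (is.null(net)) return(NA_real_)
  n <- igraph::vcount(net)
  if (n < 2L) return(NA_real_)
  comp <- igraph::components(net)
  sizes <- comp$csize
  sum(sizes * (sizes - 1)) / (n * (n - 1))
}

#' @rdname weight_entropy
#' @export
transitivity_ratio <- function(net) {
  if (is.null(net)) return(NA_real_)
  if (inherits(net, "backbone")) net <- net$graph
  if (is.null(net)) return(NA_real_)
  tr <- igraph::transitivity(net, type = "global")
  if (is.nan(tr)) 0 else tr
}

#' @rdname weight_entropy
#' @export
component_count <- function(net) {
  if (is.null(net)) return(NA_real_)
  if (inherits(net, "backbone")) net <- net$graph
  if (is.null(net)) return(NA_real_)
  igraph::components(net)$no
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The greatest vertical distance \eqn{D = \max_x |F(x) - G(x)|} between the
#' two samples' empirical CDFs, evaluated over the pooled support (exact under
#' ties).
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return \eqn{D \in [0, 1]}, or `NA` with a warning for an empty sample.
#' @export
ks_statistic <- function(sample_a, sample_b) {
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  if (length(sample_a) == 0L || length(sample_b) == 0L) {
    warning("empty sample: KS statistic undefined", call. = FALSE)
    return(NA_real_)
  }
  grid <- sort(unique(c(sample_a, sample_b)))
  Fa <- vapply(grid, function(v) mean(sample_a <= v), numeric(1))
  Gb <- vapply(grid, function(v) mean(sample_b <= v), numeric(1))
  max(abs(Fa - Gb))
}
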