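# Multiple-testing correction and backbone extraction. Every edge of a
# network is one hypothesis test, so m = |E| per (network, method).

#' Adjust edge p-values for multiple testing
#'
#' `"bonferroni"` returns \eqn{\min(1, m p)} per edge; `"fdr_bh"` the
#' Benjamini-Hochberg step-up adjusted p-value
#' \eqn{\min(1, \min_{j \ge i} m p_{(j)} / j)}; `"none"` returns the input.
#' Adjusted p-values (rather than reject flags) are returned so that
#' downstream similarity analyses can correlate corrected p-values.
#'
#' @param pvals An `edge_pvalues` tibble.
#' @param correction `"none"`, `"bonferroni"` or `"fdr_bh"`.
#' @return An `edge_pvalues` tibble with `p` replaced by the adjusted values
#'   (endpoint one-sided columns, if present, are left raw).
#' @export
adjust_pvalues <- function(pvals, correction = c("none", "bonferroni", "fdr_bh")) {
  correction <- match.arg(correction)
  stopifnot(inherits(pvals, "edge_pvalues"))
  if (correction == "none") return(pvals)
  meth <- switch(correction, bonferroni = "bonferroni", fdr_bh = "BH")
  out <- pvals
  out$p <- p.adjust(pvals$p, method = meth, n = attr(pvals, "m"))
  attr(out, "correction") <- correction
  out
}

#' Extract a backbone at a significance level
#'
#' Applies the chosen multiple-testing correction to the edge p-values and
#' retains the edges whose (corrected) p-value is at most `alpha` ("removing
#' edges with p above the significance level"; boundary ties are kept). The
#' backbone's node set is the set of endpoints of retained edges, so nodes
#' that lose all their edges are dropped.
#'
#' @param net The `weighted_network` the p-values were computed on.
#' @param pvals An `edge_pvalues` tibble from one of the filters.
#' @param alpha Significance level in (0, 1).
#' @param correction `"none"`, `"bonferroni"` or `"fdr_bh"`.
#' @return A `backbone` object: list with `graph` (the retained subgraph as a
#'   `weighted_network`, or `NULL` when no edge survives), `edges` (tibble of
#'   retained edges with raw and adjusted p), `method`, `alpha`, `correction`,
#'   `n_edges_total`.
#' @export
extract_backbone <- function(net, pvals, alpha = 0.05,
                             correction = c("none", "bonferroni", "fdr_bh")) {
  correction <- match.arg(correction)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single value in (0, 1)", call. = FALSE)
  }
  stopifnot(inherits(pvals, "edge_pvalues"))
  adj <- adjust_pvalues(pvals, correction)
  keep <- adj$p <= alpha
  edges <- tibble(from = adj$from, to = adj$to, weight = adj$weight,
                  p_raw = pvals$p, p_adj = adj$p)[keep, ]
  graph <- if (any(keep)) {
    weighted_network(data.frame(from = edges$from, to = edges$to,
                                weight = edges$weight))
  } else NULL
  structure(list(graph = graph, edges = edges,
                 method = attr(pvals, "method"), alpha = alpha,
                 correction = correction,
                 n_edges_total = attr(pvals, "m")),
            class = "backbone")
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf(
    "<backbone> method '%s', alpha %g, correction '%s': %d / %d edges kept\n",
    x$method, x$alpha, x$correction, nrow(x$edges), x$n_edges_total))
  invisible(x)
}

#' Backbone edge keys and emptiness
#'
#' `backbone_edge_set()` returns the retained edges as canonical
#' `"from\rto"` keys (from < to); `is_proper_backbone()` is `TRUE` when the
#' extraction kept some but not all edges — the accounting used by the
#' extraction-rate table.
#'
#' @param bb A `backbone`.
#' @return Character vector of edge keys, or a logical scalar.
#' @export
backbone_edge_set <- function(bb) {
  stopifnot(inherits(bb, "backbone"))
  if (nrow(bb$edges) == 0L) return(character())
  paste(bb$edges$from, bb$edges$to, sep = "\r")
}

#' @rdname backbone_edge_set
#' @export
is_proper_backbone <- function(bb) {
  stopifnot(inherits(bb, "backbone"))
  nrow(bb$edges) > 0L && nrow(bb$edges) < bb$n_edges_total
}
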