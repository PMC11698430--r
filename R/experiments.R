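# The comparative-evaluation procedures: p-value similarity, backbone
# overlap, local edge-property correlation, global backbone properties, and
# KS distribution ranking, plus the extraction-rate accounting. Each consumes
# a named list of networks and emits tidy tables; a failing (network, method)
# cell is recorded and excluded, never silently dropped.

as_net_list <- function(nets) {
  if (inherits(nets, "weighted_network")) nets <- list(nets)
  if (is.null(names(nets)) || any(!nzchar(names(nets)))) {
    names(nets) <- sprintf("net%02d", seq_along(nets))
  }
  nets
}

#' Compute edge p-values for every (network, method) cell
#'
#' Runs each requested filter on each network, capturing failures (for
#' example ECM non-convergence on degenerate networks) instead of aborting.
#'
#' @param nets A named list of `weighted_network` objects.
#' @param methods Character vector of [filter_methods()].
#' @param ... Passed to [edge_pvalues()] (e.g. `pf_a`, `gloss_mode`).
#' @return A list with `pvals` (nested list `[[network]][[method]]`) and
#'   `failures` (tibble `network`, `method`, `error`).
#' @export
compute_all_pvalues <- function(nets, methods = filter_methods(), ...) {
  nets <- as_net_list(nets)
  methods <- match.arg(methods, filter_methods(), several.ok = TRUE)
  fail <- list()
  pv <- lapply(names(nets), function(nm) {
    out <- list()
    for (m in methods) {
      res <- tryCatch(edge_pvalues(nets[[nm]], m, ...), error = identity)
      if (inherits(res, "error")) {
        fail[[length(fail) + 1L]] <<- tibble(network = nm, method = m,
                                             error = conditionMessage(res))
      } else {
        out[[m]] <- res
      }
    }
    out
  })
  names(pv) <- names(nets)
  failures <- if (length(fail)) do.call(rbind, fail) else
    tibble(network = character(), method = character(), error = character())
  list(pvals = pv, failures = failures)
}

aggregate_pairs <- function(per_network, methods, value_col) {
  # mean and population-SD matrices over networks, per ordered method pair
  mu <- sigma <- matrix(NA_real_, length(methods), length(methods),
                        dimnames = list(methods, methods))
  for (a in methods) for (b in methods) {
    v <- per_network[[value_col]][per_network$method_x == a &
                                  per_network$method_y == b]
    v <- v[!is.na(v)]
    if (length(v)) {
      mu[a, b] <- mean(v)
      sigma[a, b] <- sqrt(mean((v - mean(v))^2))
    }
  }
  list(mu = mu, sigma = sigma)
}

#' P-value similarity study
#'
#' Per network, the Spearman rank correlation between two methods' edge
#' p-value vectors over the network's full edge set (every method scores
#' every edge, so the vectors align without imputation); optionally the
#' p-values are Benjamini-Hochberg corrected first. Results are aggregated
#' into mean and population-standard-deviation matrices across networks.
#'
#' @param nets Named list of `weighted_network` objects.
#' @param methods Methods to compare (>= 2).
#' @param correction `"none"` or `"fdr_bh"` applied before correlating.
#' @param pvals Optional precomputed [compute_all_pvalues()] result.
#' @param ... Passed to [compute_all_pvalues()] when `pvals` is `NULL`.
#' @return List with `mu`, `sigma` (method x method matrices), `per_network`
#'   (tibble) and `failures`.
#' @export
similarity_study <- function(nets, methods = filter_methods(),
                             correction = c("none", "fdr_bh"),
                             pvals = NULL, ...) {
  nets <- as_net_list(nets)
  correction <- match.arg(correction)
  stopifnot(length(methods) >= 2L)
  if (is.null(pvals)) pvals <- compute_all_pvalues(nets, methods, ...)
  rows <- list()
  for (nm in names(nets)) {
    avail <- intersect(methods, names(pvals$pvals[[nm]]))
    vecs <- lapply(pvals$pvals[[nm]], function(pv) {
      adjust_pvalues(pv, correction)$p
    })
    for (a in avail) for (b in avail) {
      r <- if (a == b) 1 else
        suppressWarnings(spearman(vecs[[a]], vecs[[b]]))
      rows[[length(rows) + 1L]] <- tibble(network = nm, method_x = a,
                                          method_y = b, spearman = r)
    }
  }
  per_network <- do.call(rbind, rows)
  c(aggregate_pairs(per_network, methods, "spearman"),
    list(per_network = per_network, failures = pvals$failures))
}

#' Backbone overlap study
#'
#' Per network, extracts each method's backbone at level `alpha` (with the
#' chosen correction) and computes the asymmetric overlap
#' \eqn{|E_X \cap E_Y| / |E_X|} for every ordered method pair; aggregates
#' mean and population SD across networks. Empty backbones yield missing
#' cells, consistent with the extraction-rate accounting.
#'
#' @inheritParams similarity_study
#' @param alpha Significance level.
#' @param correction `"none"`, `"bonferroni"` or `"fdr_bh"`.
#' @return List with `mu`, `sigma`, `per_network`, `failures`.
#' @export
overlap_study <- function(nets, methods = filter_methods(), alpha = 0.05,
                          correction = c("none", "bonferroni", "fdr_bh"),
                          pvals = NULL, ...) {
  nets <- as_net_list(nets)
  correction <- match.arg(correction)
  if (is.null(pvals)) pvals <- compute_all_pvalues(nets, methods, ...)
  rows <- list()
  for (nm in names(nets)) {
    avail <- intersect(methods, names(pvals$pvals[[nm]]))
    sets <- lapply(avail, function(m) {
      backbone_edge_set(extract_backbone(nets[[nm]], pvals$pvals[[nm]][[m]],
                                         alpha, correction))
    })
    names(sets) <- avail
    for (a in avail) for (b in avail) {
      ov <- suppressWarnings(overlap_from(sets[[a]], sets[[b]]))
      rows[[length(rows) + 1L]] <- tibble(network = nm, method_x = a,
                                          method_y = b, overlap = ov)
    }
  }
  per_network <- do.call(rbind, rows)
  c(aggregate_pairs(per_network, methods, "overlap"),
    list(per_network = per_network, failures = pvals$failures))
}

#' Local edge-property correlation study
#'
#' Per (network, method, property), the Spearman correlation between the
#' method's edge p-values and the property (weight, edge degree, edge
#' betweenness) evaluated on the original network. Constant vectors give a
#' missing correlation.
#'
#' @inheritParams similarity_study
#' @param properties Subset of `"weight"`, `"edge_degree"`,
#'   `"edge_betweenness"`.
#' @return List with `records` (tibble `network`, `method`, `property`,
#'   `spearman`) and `failures`.
#' @export
local_property_study <- function(nets, methods = filter_methods(),
                                 correction = c("none", "fdr_bh"),
                                 properties = c("weight", "edge_degree",
                                                "edge_betweenness"),
                                 pvals = NULL, ...) {
  nets <- as_net_list(nets)
  correction <- match.arg(correction)
  properties <- match.arg(properties, several.ok = TRUE)
  if (is.null(pvals)) pvals <- compute_all_pvalues(nets, methods, ...)
  rows <- list()
  for (nm in names(nets)) {
    net <- nets[[nm]]
    props <- list()
    if ("weight" %in% properties) props$weight <- edge_table(net)$weight
    if ("edge_degree" %in% properties) props$edge_degree <- edge_degree(net)
    if ("edge_betweenness" %in% properties) {
      props$edge_betweenness <- edge_betweenness_values(net)
    }
    for (m in intersect(methods, names(pvals$pvals[[nm]]))) {
      p <- adjust_pvalues(pvals$pvals[[nm]][[m]], correction)$p
      for (pr in names(props)) {
        r <- suppressWarnings(spearman(p, props[[pr]]))
        rows[[length(rows) + 1L]] <- tibble(network = nm, method = m,
                                            property = pr, spearman = r)
      }
    }
  }
  list(records = do.call(rbind, rows), failures = pvals$failures)
}

backbone_global_properties <- function(net, bb) {
  n0 <- igraph::vcount(net); e0 <- igraph::ecount(net)
  w0 <- total_weight(net)
  g <- bb$graph
  nb <- if (is.null(g)) 0L else igraph::vcount(g)
  eb <- nrow(bb$edges)
  wb <- if (eb == 0L) 0 else sum(bb$edges$weight)
  ratio <- function(v, v0) if (is.na(v) || is.na(v0) || v0 == 0) NA_real_ else v / v0
  tibble(
    property = c("edge_fraction", "node_fraction", "weight_fraction",
                 "weight_entropy", "reachability", "components",
                 "transitivity"),
    value = c(eb, nb, wb, weight_entropy(g), reachability(g),
              component_count(g), transitivity_ratio(g)),
    original = c(e0, n0, w0, weight_entropy(net), reachability(net),
                 component_count(net), transitivity_ratio(net)),
    normalized = c(eb / e0, nb / n0, wb / w0,
                   ratio(weight_entropy(g), weight_entropy(net)),
                   ratio(reachability(g), reachability(net)),
                   ratio(component_count(g), component_count(net)),
                   ratio(transitivity_ratio(g), transitivity_ratio(net)))
  )
}

#' Global backbone-property study
#'
#' Per (network, method, correction): extracts the backbone at `alpha` and
#' computes each global property and its value normalized by the original
#' network's (edge/node/weight fractions, weight entropy, reachability,
#' component count, transitivity). Also returns the pooled
#' counter-cumulative distribution of the normalized values across networks
#' (fraction of networks with a value at or above x).
#'
#' @inheritParams overlap_study
#' @param corrections Character vector of corrections to run.
#' @return List with `records`, `ccdf` tibbles and `failures`.
#' @export
global_property_study <- function(nets, methods = filter_methods(),
                                  alpha = 0.05,
                                  corrections = c("none", "fdr_bh"),
                                  pvals = NULL, ...) {
  nets <- as_net_list(nets)
  corrections <- match.arg(corrections, c("none", "bonferroni", "fdr_bh"),
                           several.ok = TRUE)
  if (is.null(pvals)) pvals <- compute_all_pvalues(nets, methods, ...)
  rows <- list()
  for (nm in names(nets)) {
    for (m in intersect(methods, names(pvals$pvals[[nm]]))) {
      for (corr in corrections) {
        bb <- extract_backbone(nets[[nm]], pvals$pvals[[nm]][[m]], alpha, corr)
        props <- backbone_global_properties(nets[[nm]], bb)
        props$network <- nm; props$method <- m; props$correction <- corr
        rows[[length(rows) + 1L]] <- props
      }
    }
  }
  records <- do.call(rbind, rows)[, c("network", "method", "correction",
                                      "property", "value", "original",
                                      "normalized")]
  ccdf_rows <- list()
  for (m in unique(records$method)) for (corr in corrections) {
    for (pr in unique(records$property)) {
      v <- records$normalized[records$method == m &
                              records$correction == corr &
                              records$property == pr]
      v <- v[!is.na(v)]
      if (!length(v)) next
      xs <- sort(unique(v))
      ccdf_rows[[length(ccdf_rows) + 1L]] <- tibble(
        method = m, correction = corr, property = pr, value = xs,
        tail_fraction = vapply(xs, function(x) mean(v >= x), numeric(1)))
    }
  }
  list(records = records, ccdf = do.call(rbind, ccdf_rows),
       failures = pvals$failures)
}

#' Distribution-closeness ranking study
#'
#' Per eligible network (at least `min_edges` edges): the two-sample KS
#' statistic between the backbone's and the original network's weight
#' multisets and degree multisets, with methods ranked ascending by D
#' (rank 1 = closest to the original; average ranks on ties). Methods whose
#' backbone is empty are unranked for that network.
#'
#' @inheritParams overlap_study
#' @param min_edges Minimum edge count for a network to enter the study.
#' @return List with `records` (tibble `network`, `distribution`, `method`,
#'   `ks`, `rank`) and `failures`.
#' @export
distribution_rank_study <- function(nets, methods = filter_methods(),
                                    alpha = 0.05,
                                    correction = c("none", "bonferroni",
                                                   "fdr_bh"),
                                    min_edges = 1000, pvals = NULL, ...) {
  nets <- as_net_list(nets)
  correction <- match.arg(correction)
  nets <- nets[vapply(nets, igraph::ecount, numeric(1)) >= min_edges]
  if (length(nets) == 0L) {
    stop("no network has at least ", min_edges, " edges", call. = FALSE)
  }
  if (is.null(pvals)) pvals <- compute_all_pvalues(nets, methods, ...)
  rows <- list()
  for (nm in names(nets)) {
    net <- nets[[nm]]
    w0 <- edge_table(net)$weight
    d0 <- as.numeric(node_degrees(net))
    for (m in intersect(methods, names(pvals$pvals[[nm]]))) {
      bb <- extract_backbone(net, pvals$pvals[[nm]][[m]], alpha, correction)
      if (nrow(bb$edges) == 0L) next
      wb <- bb$edges$weight
      db <- as.numeric(node_degrees(bb$graph))
      rows[[length(rows) + 1L]] <- tibble(
        network = nm, distribution = c("weight", "degree"), method = m,
        ks = c(ks_statistic(wb, w0), ks_statistic(db, d0)))
    }
  }
  records <- do.call(rbind, rows)
  if (is.null(records)) {
    return(list(records = tibble(network = character(),
                                 distribution = character(),
                                 method = character(), ks = numeric(),
                                 rank = numeric()),
                failures = pvals$failures))
  }
  records$rank <- NA_real_
  for (nm in unique(records$network)) for (d in c("weight", "degree")) {
    sel <- records$network == nm & records$distribution == d
    records$rank[sel] <- rank(records$ks[sel], ties.method = "average")
  }
  list(records = records, failures = pvals$failures)
}

#' Extraction-rate accounting
#'
#' A method "extracts a backbone" on a network iff it ran successfully and
#' retained strictly more than zero and strictly fewer than all edges. The
#' table gives, per (method, correction), the percentage of networks where
#' that happened — mirroring the observation that some filters keep or drop
#' everything on many networks.
#'
#' @inheritParams global_property_study
#' @return List with `records` (tibble `method`, `correction`,
#'   `n_networks`, `n_extracted`, `rate_percent`) and `failures`.
#' @export
extraction_rate_table <- function(nets, methods = filter_methods(),
                                  alpha = 0.05,
                                  corrections = c("none", "fdr_bh"),
                                  pvals = NULL, ...) {
  nets <- as_net_list(nets)
  corrections <- match.arg(corrections, c("none", "bonferroni", "fdr_bh"),
                           several.ok = TRUE)
  if (is.null(pvals)) pvals <- compute_all_pvalues(nets, methods, ...)
  rows <- list()
  for (m in methods) for (corr in corrections) {
    ok <- 0L
    for (nm in names(nets)) {
      pv <- pvals$pvals[[nm]][[m]]
      if (is.null(pv)) next  # method failed on this network
      bb <- extract_backbone(nets[[nm]], pv, alpha, corr)
      if (is_proper_backbone(bb)) ok <- ok + 1L
    }
    rows[[length(rows) + 1L]] <- tibble(
      method = m, correction = corr, n_networks = length(nets),
      n_extracted = ok, rate_percent = 100 * ok / length(nets))
  }
  list(records = do.call(rbind, rows), failures = pvals$failures)
}
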