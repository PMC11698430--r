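# Seeded generators for the synthetic study corpus: heterogeneous weighted
# networks with heavy-tailed degrees, broad positive integer weights, a single
# connected component, and (optionally) a planted set of anomalously strong
# edges providing ground truth that real networks lack.

#' Named deterministic fixture networks
#'
#' Small hand-specified graphs anchoring the filters' closed-form examples:
#' `triangle_unit` (3 nodes, unit weights), `path3_unit`, `star5_geometric`
#' (hub with leaf weights 1, 2, 4, 8, 16), `two_cliques` (two 4-cliques joined
#' by a single bridge), and `conditional_gloss_30` (a 30-node seeded graph
#' with integer weights 1-20, used to exercise the strength-conditioned
#' GloSS null).
#'
#' @param name Fixture name.
#' @return A `weighted_network`.
#' @export
fixture <- function(name = c("triangle_unit", "path3_unit", "star5_geometric",
                             "two_cliques", "conditional_gloss_30")) {
  name <- match.arg(name)
  ed <- switch(name,
    triangle_unit = data.frame(from = c("a", "b", "a"),
                               to = c("b", "c", "c"), weight = 1),
    path3_unit = data.frame(from = c("a", "b"), to = c("b", "c"), weight = 1),
    star5_geometric = data.frame(from = "hub",
                                 to = paste0("leaf", 1:5),
                                 weight = c(1, 2, 4, 8, 16)),
    two_cliques = {
      cl <- function(v) {
        cmb <- utils::combn(v, 2)
        data.frame(from = cmb[1, ], to = cmb[2, ], weight = 1)
      }
      rbind(cl(paste0("a", 1:4)), cl(paste0("b", 1:4)),
            data.frame(from = "a1", to = "b1", weight = 1))
    },
    conditional_gloss_30 = {
      withr_seed <- function(code) {
        old <- if (exists(".Random.seed", globalenv())) {
          get(".Random.seed", globalenv())
        } else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(303L)
        code
      }
      withr_seed({
        n <- 30L
        # Erdos-Renyi-style topology, then integer weights 1..20
        pairs <- utils::combn(sprintf("v%02d", 1:n), 2)
        keep <- runif(ncol(pairs)) < 0.18
        data.frame(from = pairs[1, keep], to = pairs[2, keep],
                   weight = sample(1:20, sum(keep), replace = TRUE))
      })
    }
  )
  suppressWarnings(weighted_network(ed))
}

# discrete truncated power-law degree sample on {1, ..., cutoff}
sample_powerlaw_degrees <- function(n, gamma, cutoff) {
  support <- seq_len(max(2L, cutoff))
  probs <- support^(-gamma)
  sample(support, n, replace = TRUE, prob = probs / sum(probs))
}

sample_integer_weights <- function(m, weight_model) {
  switch(weight_model,
    lognormal_int = pmax(1L, as.integer(round(rlnorm(m, meanlog = 1, sdlog = 1)))),
    zipf_int = {
      # power-law ranks: inverse-CDF sample on 1..1e4 with exponent 2
      support <- seq_len(10000L)
      probs <- support^(-2)
      sample(support, m, replace = TRUE, prob = probs / sum(probs))
    },
    poisson_shifted = 1L + rpois(m, lambda = 3),
    stop("unknown weight model: ", weight_model, call. = FALSE)
  )
}

#' Generate a heterogeneous synthetic weighted network
#'
#' Draws a truncated power-law degree sequence (exponent `degree_exponent`,
#' cutoff \eqn{\sqrt{n \cdot \text{mean\_degree}}}), rescaled to the requested
#' mean degree, realizes it as a simple configuration-model-style graph,
#' keeps the largest connected component, and assigns i.i.d. integer weights
#' \eqn{\ge 1} from the chosen model. Fully determined by `seed`.
#'
#' @param n Number of nodes before largest-component extraction (>= 10).
#' @param mean_degree Target mean degree.
#' @param degree_exponent Power-law exponent \eqn{\gamma} of the degree
#'   distribution.
#' @param weight_model `"lognormal_int"` (round of log-normal(1, 1), clipped
#'   to >= 1), `"zipf_int"` (power-law ranks) or `"poisson_shifted"`
#'   (1 + Poisson(3)).
#' @param seed Integer RNG seed.
#' @return A `weighted_network` with integer weights and a single component.
#' @export
gen_heterogeneous <- function(n, mean_degree = 6, degree_exponent = 2.5,
                              weight_model = c("lognormal_int", "zipf_int",
                                               "poisson_shifted"),
                              seed = 0L) {
  stopifnot(n >= 10L, mean_degree > 1)
  weight_model <- match.arg(weight_model)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  cutoff <- max(3L, floor(sqrt(n * mean_degree)))
  g <- NULL
  for (attempt in seq_len(100L)) {
    deg <- sample_powerlaw_degrees(n, degree_exponent, cutoff)
    # rescale toward the requested mean degree, keeping degrees in range
    fac <- mean_degree / mean(deg)
    deg <- pmin(pmax(1L, as.integer(round(deg * fac))), min(cutoff, n - 1L))
    if (sum(deg) %% 2L == 1L) deg[which.max(deg)] <- deg[which.max(deg)] - 1L
    if (!igraph::is_graphical(deg)) next
    cand <- try(igraph::sample_degseq(deg, method = "fast.heur.simple"),
                silent = TRUE)
    if (inherits(cand, "try-error")) next
    comp <- igraph::components(cand)
    giant <- igraph::induced_subgraph(cand, comp$membership == which.max(comp$csize))
    if (igraph::vcount(giant) >= max(10L, 0.5 * n)) {
      g <- giant
      break
    }
  }
  if (is.null(g)) {
    stop("could not realize a degree sequence after 100 attempts", call. = FALSE)
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  nodes <- sprintf("n%04d", seq_len(igraph::vcount(g)))
  w <- sample_integer_weights(nrow(el), weight_model)
  weighted_network(data.frame(from = nodes[el[, 1]], to = nodes[el[, 2]],
                              weight = as.numeric(w)))
}

#' Generate a network with planted anomalously strong edges
#'
#' Builds a baseline network with [gen_heterogeneous()], then multiplies the
#' weight of a seeded random fraction `rho` of edges by the boost factor
#' `boost` (multiplicative, so the planted signal is scale-free across weight
#' models). The labels are returned as ground truth for recovery testing.
#'
#' @inheritParams gen_heterogeneous
#' @param rho Fraction of edges planted, in (0, 0.5).
#' @param boost Weight multiplier for planted edges, >= 2.
#' @return A `planted_network` list: `net` (`weighted_network`), `planted`
#'   (logical vector aligned with [edge_table()] rows), `params`.
#' @export
gen_planted <- function(n, mean_degree = 6, weight_model = "lognormal_int",
                        rho = 0.05, boost = 10, seed = 0L,
                        degree_exponent = 2.5) {
  stopifnot(rho > 0, rho < 0.5, boost >= 2)
  base <- gen_heterogeneous(n, mean_degree, degree_exponent, weight_model,
                            seed = seed)
  et <- edge_table(base)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed) + 1000003L)
  m <- nrow(et)
  planted_idx <- sample.int(m, size = max(1L, round(rho * m)))
  planted <- rep(FALSE, m)
  planted[planted_idx] <- TRUE
  et$weight[planted] <- et$weight[planted] * boost
  structure(list(net = weighted_network(et),
                 planted = planted,
                 params = list(n = n, mean_degree = mean_degree,
                               weight_model = weight_model, rho = rho,
                               boost = boost, seed = seed)),
            class = "planted_network")
}

#' Precision and recall of a backbone against planted edges
#'
#' @param planted A `planted_network`.
#' @param backbone A `backbone` extracted from `planted$net`.
#' @return A list with `precision` (\eqn{|retained \cap planted|/|retained|})
#'   and `recall` (\eqn{|retained \cap planted|/|planted|}); `NA` when the
#'   corresponding denominator is empty.
#' @export
recovery_metrics <- function(planted, backbone) {
  stopifnot(inherits(planted, "planted_network"), inherits(backbone, "backbone"))
  keys <- edge_keys(planted$net)
  if (backbone$n_edges_total != length(keys)) {
    stop("backbone was not extracted from this planted network", call. = FALSE)
  }
  planted_keys <- keys[planted$planted]
  retained <- backbone_edge_set(backbone)
  if (length(setdiff(retained, keys)) > 0L) {
    stop("backbone edges are not a subset of the planted network", call. = FALSE)
  }
  hit <- length(intersect(retained, planted_keys))
  list(
    precision = if (length(retained) == 0L) NA_real_ else hit / length(retained),
    recall = if (length(planted_keys) == 0L) NA_real_ else hit / length(planted_keys)
  )
}
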