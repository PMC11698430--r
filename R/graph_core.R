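#' @import igraph
#' @importFrom tibble tibble as_tibble
#' @importFrom stats cor integrate p.adjust pbinom rbeta rbinom rgeom rlnorm
#'   rpois runif sd setNames complete.cases
#' @importFrom utils head read.table write.table
#' @importFrom tools file_path_sans_ext
NULL

#' The seven implemented filter methods
#'
#' Method identifiers accepted throughout the package: `"df"` (disparity),
#' `"pf"` (Polya urn), `"mlf"` (marginal likelihood), `"nc"` (noise corrected),
#' `"ecm"` (enhanced configuration model), `"gloss"` (global statistical
#' significance) and `"lans"` (locally adaptive network sparsification).
#'
#' @return Character vector of method identifiers.
#' @export
filter_methods <- function() {
  c("df", "pf", "mlf", "nc", "ecm", "gloss", "lans")
}

# methods whose null model requires integer weights
.integer_weight_methods <- c("pf", "mlf", "nc", "ecm", "gloss")

#' Construct a weighted network
#'
#' Builds the package's canonical network object: an undirected simple
#' [igraph::igraph] with a positive `weight` edge attribute and a
#' deterministic (lexicographic) edge ordering. Duplicate edges are merged by
#' summing their weights (with a warning), self-loops are dropped (with a
#' warning) and non-positive weights are an error. Isolated nodes are not
#' represented: the node set is exactly the set of edge endpoints.
#'
#' @param edges A data frame with columns `from`, `to`, `weight` (extra
#'   columns are ignored). Node identifiers are treated as opaque strings.
#' @return A `weighted_network` object (also an `igraph`).
#' @examples
#' net <- weighted_network(data.frame(
#'   from = c("a", "b", "a"), to = c("b", "c", "c"), weight = 1
#' ))
#' total_weight(net) # 3
#' @export
weighted_network <- function(edges) {
  edges <- as.data.frame(edges)
  need <- c("from", "to", "weight")
  if (!all(need %in% names(edges))) {
    stop("`edges` must have columns from, to, weight", call. = FALSE)
  }
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  w <- as.numeric(edges$weight)
  if (anyNA(from) || anyNA(to) || anyNA(w)) {
    stop("missing values in edge list", call. = FALSE)
  }
  loop <- from == to
  if (any(loop)) {
    warning(sum(loop), " self-loop(s) dropped", call. = FALSE)
    from <- from[!loop]; to <- to[!loop]; w <- w[!loop]
  }
  if (length(from) == 0L) stop("network has no edges", call. = FALSE)
  if (any(w <= 0)) stop("edge weights must be > 0", call. = FALSE)
  # canonical unordered pair: lexicographically smaller endpoint first
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate edge(s) merged by summing weights",
            call. = FALSE)
    w <- as.numeric(tapply(w, key, sum)[unique(key)])
    a <- a[!duplicated(key)]
    b <- b[!duplicated(key)]
    key <- unique(key)
  }
  ord <- order(a, b, method = "radix")
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[ord], to = b[ord], weight = w[ord],
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = sort(unique(c(a, b)))
  )
  class(g) <- c("weighted_network", class(g))
  g
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf(
    "<weighted_network> %d nodes, %d edges, total weight %g (%s weights)\n",
    igraph::vcount(x), igraph::ecount(x), total_weight(x),
    if (has_integer_weights(x)) "integer" else "real"
  ))
  invisible(x)
}

#' Edge table of a network or backbone
#'
#' @param net A `weighted_network` or `backbone`.
#' @return A tibble with columns `from`, `to`, `weight`, one row per edge,
#'   `from < to` lexicographically, rows in canonical order.
#' @export
edge_table <- function(net) {
  if (inherits(net, "backbone")) net <- net$graph
  el <- igraph::as_data_frame(net, what = "edges")
  a <- pmin(el$from, el$to)
  b <- pmax(el$from, el$to)
  ord <- order(a, b, method = "radix")
  tibble(from = a[ord], to = b[ord], weight = el$weight[ord])
}

# canonical per-edge keys, aligned with edge_table() rows
edge_keys <- function(net) {
  et <- edge_table(net)
  paste(et$from, et$to, sep = "\r")
}

#' Node degrees, strengths and total weight
#'
#' Degree \eqn{k_i} counts incident edges; strength \eqn{s_i} sums incident
#' weights; total weight \eqn{T} sums each edge weight once, so
#' \eqn{\sum_i s_i = 2T}.
#'
#' @param net A `weighted_network`.
#' @return Named numeric vector (degrees, strengths) or a scalar (total weight).
#' @export
node_degrees <- function(net) igraph::degree(net)

#' @rdname node_degrees
#' @export
node_strengths <- function(net) igraph::strength(net, weights = igraph::E(net)$weight)

#' @rdname node_degrees
#' @export
total_weight <- function(net) sum(igraph::E(net)$weight)

#' @rdname node_degrees
#' @export
has_integer_weights <- function(net) {
  w <- igraph::E(net)$weight
  all(abs(w - round(w)) < 1e-9)
}

#' Read a weighted network from disk
#'
#' Edge lists are tab-separated `source<TAB>target<TAB>weight` rows; lines
#' starting with `#` are ignored. GraphML files must be undirected and carry a
#' `weight` edge attribute. Duplicate rows are merged (weights summed) and
#' self-loops dropped, each with a warning; non-positive weights are an error.
#'
#' @param path Path to the file.
#' @param format `"edgelist"` or `"graphml"`.
#' @return A `weighted_network`.
#' @export
read_network <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "edgelist") {
    lines <- readLines(path, warn = FALSE)
    keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
    lines <- lines[keep]
    lineno <- which(keep)
    if (length(lines) == 0L) stop("no edges in ", path, call. = FALSE)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- vapply(parts, length, 1L) != 3L
    if (any(bad)) {
      stop("malformed edge list row at line ", lineno[which(bad)[1L]],
           " of ", path, call. = FALSE)
    }
    m <- do.call(rbind, parts)
    w <- suppressWarnings(as.numeric(m[, 3L]))
    if (anyNA(w)) {
      stop("non-numeric weight at line ", lineno[which(is.na(w))[1L]],
           " of ", path, call. = FALSE)
    }
    weighted_network(data.frame(from = m[, 1L], to = m[, 2L], weight = w,
                                stringsAsFactors = FALSE))
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    if (igraph::is_directed(g)) {
      stop("directed GraphML input rejected: the null models are undirected",
           call. = FALSE)
    }
    if (!"weight" %in% igraph::edge_attr_names(g)) {
      stop("GraphML file lacks a 'weight' edge attribute", call. = FALSE)
    }
    el <- igraph::as_data_frame(g, what = "edges")
    weighted_network(data.frame(from = el$from, to = el$to, weight = el$weight,
                                stringsAsFactors = FALSE))
  }
}

#' Write a weighted network to disk
#'
#' Round-trips through [read_network()]: node set, edge set and weights are
#' reproduced exactly (12 significant digits for real weights).
#'
#' @inheritParams read_network
#' @param net A `weighted_network`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (igraph::ecount(net) == 0L) stop("refusing to write an empty network",
                                      call. = FALSE)
  if (format == "edgelist") {
    et <- edge_table(net)
    wtxt <- formatC(et$weight, digits = 12, format = "g")
    writeLines(paste(et$from, et$to, wtxt, sep = "\t"), path)
  } else {
    g <- net
    class(g) <- "igraph"
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Check that a network is usable by a filter method
#'
#' The model-based filters `pf`, `mlf`, `nc`, `ecm` and (conditional-mode)
#' `gloss` require integer weights; `df` and `lans` accept any positive
#' weights. The report never errors: it flags problems and suggests a remedy.
#'
#' @param net A `weighted_network`.
#' @param method One of [filter_methods()].
#' @return A list with `method`, `ok` (logical) and `messages` (character).
#' @export
validate_for_method <- function(net, method) {
  method <- match.arg(method, filter_methods())
  msgs <- character()
  if (method %in% .integer_weight_methods && !has_integer_weights(net)) {
    msgs <- c(msgs, paste0(
      "method '", method, "' requires integer weights; ",
      "scale the weights to a common unit and round before filtering"
    ))
  }
  list(method = method, ok = length(msgs) == 0L, messages = msgs)
}
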