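# Vertex weighting: w(v) = k_max * d over the inclusive depth-1
# neighbourhood N(v) u {v}. k_max is the maximum whole-graph degree over
# that neighbourhood; d is the density of the subgraph it induces.

# Internal index-based representation used by weighting and clustering.
# Vertices are renumbered 1..n in byte-lexicographic name order, so index
# order IS the tie-breaking order; adjacency vectors are sorted ascending.
mine_rep <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::is_directed(graph)) {
    stop("graph must be undirected", call. = FALSE)
  }
  nm <- igraph::V(graph)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(graph)))
  o <- order_c(nm)
  names_sorted <- nm[o]
  rank <- integer(length(nm))
  rank[o] <- seq_along(nm)
  el <- igraph::as_edgelist(graph, names = FALSE)
  a <- rank[el[, 1L]]
  b <- rank[el[, 2L]]
  keep <- a != b
  a <- a[keep]
  b <- b[keep]
  n <- length(nm)
  adj <- vector("list", n)
  m <- 0L
  if (length(a)) {
    # collapse duplicates on canonical (min,max) keys
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    dup <- duplicated((lo - 1) * as.double(n) + hi)
    lo <- lo[!dup]
    hi <- hi[!dup]
    m <- length(lo)
    sp <- split(c(hi, lo), c(lo, hi))
    idx <- as.integer(names(sp))
    for (k in seq_along(sp)) adj[[idx[[k]]]] <- sort.int(sp[[k]])
  }
  for (i in which(lengths(adj) == 0L)) adj[[i]] <- integer(0)
  deg <- lengths(adj)
  # CSR form for the compiled per-seed pipeline
  offsets <- c(0L, cumsum(deg))
  list(names = names_sorted, adj = adj, deg = deg, n = n, m = m,
       offsets = offsets, nbr = unlist(adj, use.names = FALSE) %||% integer(0))
}

# Edges of the subgraph induced by vertex index set `idx` (sorted or not).
induced_edge_count <- function(rep, idx) {
  inset <- logical(rep$n)
  inset[idx] <- TRUE
  tot <- 0L
  for (v in idx) tot <- tot + sum(inset[rep$adj[[v]]])
  tot %/% 2L
}

#' Density of a vertex's inclusive neighbourhood
#'
#' The density of the subgraph induced by a vertex together with its direct
#' neighbours: `d = 2 e / (n (n - 1))` where `n` counts the vertex and its
#' neighbours and `e` counts graph edges with both endpoints in that set.
#' Returns 0 for an isolated vertex (`n <= 1`), so isolated vertices carry
#' zero weight.
#'
#' @param graph an undirected [igraph::graph] with character vertex names.
#' @param v a vertex name present in `graph`.
#' @return density in `[0, 1]`.
#' @examples
#' g <- igraph::make_full_graph(3)
#' igraph::V(g)$name <- c("a", "b", "c")
#' neighborhood_density(g, "a")  # 1
#' @export
neighborhood_density <- function(graph, v) {
  rep <- mine_rep(graph)
  i <- match(v, rep$names)
  if (is.na(i)) stop(sprintf("vertex '%s' not in graph", v), call. = FALSE)
  nbhd_density_idx(rep, i)
}

nbhd_density_idx <- function(rep, i) {
  idx <- c(i, rep$adj[[i]])
  n <- length(idx)
  if (n <= 1L) return(0)
  2 * induced_edge_count(rep, idx) / (n * (n - 1))
}

#' Compute MINE vertex weights for every node
#'
#' For each vertex `v`, the weight is `k_max * d`: `k_max` is the maximum
#' whole-graph degree of any vertex in the inclusive neighbourhood
#' `N(v) u {v}`, and `d` is [neighborhood_density()] of that set. This
#' scheme up-weights densely grouped vertices attached to hubs, which seeds
#' cluster growth inside modules rather than at module boundaries. Weights
#' are computed once per graph and are not updated during clustering.
#'
#' @param graph an undirected [igraph::graph] with character vertex names.
#' @return a `data.frame` with columns `node`, `degree`, `k_max`, `density`,
#'   `weight`, one row per vertex in byte-lexicographic name order.
#' @examples
#' g <- igraph::make_star(4, mode = "undirected", center = 1)
#' igraph::V(g)$name <- c("hub", "l1", "l2", "l3")
#' compute_vertex_weights(g)  # leaves outweigh the hub
#' @export
compute_vertex_weights <- function(graph) {
  rep <- mine_rep(graph)
  vertex_weights_rep(rep)
}

vertex_weights_rep <- function(rep) {
  n <- rep$n
  k_max <- integer(n)
  dens <- numeric(n)
  for (i in seq_len(n)) {
    idx <- c(i, rep$adj[[i]])
    k_max[[i]] <- if (length(idx)) max(rep$deg[idx]) else 0L
    nn <- length(idx)
    dens[[i]] <- if (nn <= 1L) 0 else
      2 * induced_edge_count(rep, idx) / (nn * (nn - 1))
  }
  data.frame(node = rep$names, degree = rep$deg, k_max = k_max,
             density = dens, weight = k_max * dens,
             stringsAsFactors = FALSE)
}

#' Write the vertex weight table as TSV
#'
#' @param weights result of [compute_vertex_weights()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vertex_weights <- function(weights, path) {
  utils::write.table(weights, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
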