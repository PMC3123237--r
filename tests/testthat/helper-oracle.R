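# Brute-force oracles, written against a plain character edge matrix so they
# share no code with the package internals.

# 2-column character edge matrix (one row per undirected edge) + node vector.
as_plain <- function(graph) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  if (!is.matrix(el)) el <- matrix(el, ncol = 2)
  list(nodes = igraph::V(graph)$name, edges = el)
}

plain_degree <- function(pl, v) {
  sum(pl$edges[, 1] == v) + sum(pl$edges[, 2] == v)
}

plain_neighbors <- function(pl, v) {
  sort(unique(c(pl$edges[pl$edges[, 1] == v, 2],
                pl$edges[pl$edges[, 2] == v, 1])), method = "radix")
}

# Edges of the subgraph induced by `set`, counted by scanning every edge.
plain_induced_edges <- function(pl, set) {
  sum(pl$edges[, 1] %in% set & pl$edges[, 2] %in% set)
}

# Oracle for neighborhood density and the vertex weight of one node.
oracle_vertex_weight <- function(graph, v) {
  pl <- as_plain(graph)
  nbhd <- c(v, plain_neighbors(pl, v))
  n <- length(nbhd)
  d <- if (n <= 1) 0 else 2 * plain_induced_edges(pl, nbhd) / (n * (n - 1))
  k_max <- max(vapply(nbhd, function(u) plain_degree(pl, u), numeric(1)))
  list(density = d, k_max = k_max, weight = k_max * d)
}

# Oracle for E_in / E_out and the derived statistics of a member set.
oracle_cluster_stats <- function(graph, members) {
  pl <- as_plain(graph)
  inn <- pl$edges[, 1] %in% members & pl$edges[, 2] %in% members
  out <- xor(pl$edges[, 1] %in% members, pl$edges[, 2] %in% members)
  e_in <- sum(inn)
  e_out <- sum(out)
  k <- length(members)
  dens <- if (k <= 1) 0 else 2 * e_in / (k * (k - 1))
  mod <- if (e_in == 0) 0 else if (e_out == 0) Inf else e_in / e_out
  list(e_in = e_in, e_out = e_out, density = dens, modularity = mod,
       score = dens * k)
}

# Hypergeometric upper tail by explicit summation of choose() terms.
oracle_hyper <- function(population, complex, cluster, overlap) {
  ks <- overlap:min(complex, cluster)
  sum(choose(complex, ks) * choose(population - complex, cluster - ks)) /
    choose(population, cluster)
}

# Characteristic path length by exhaustive breadth-first search per node.
oracle_cpl <- function(graph) {
  pl <- as_plain(graph)
  total <- 0
  count <- 0
  for (i in seq_along(pl$nodes)) {
    src <- pl$nodes[i]
    dist <- stats::setNames(rep(Inf, length(pl$nodes)), pl$nodes)
    dist[src] <- 0
    frontier <- src
    while (length(frontier)) {
      nxt <- character(0)
      for (v in frontier) {
        for (u in plain_neighbors(pl, v)) {
          if (is.infinite(dist[u])) {
            dist[u] <- dist[v] + 1
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
    }
    reach <- dist[-i][is.finite(dist[-i])]
    total <- total + sum(reach)
    count <- count + length(reach)
  }
  if (count == 0) NaN else total / count
}
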