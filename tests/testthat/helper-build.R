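# Small graph builders used across the suite.

# Build an undirected igraph from a flat character vector of edge endpoints
# (a1,b1, a2,b2, ...) plus optional isolated vertices.
graph_chr <- function(edges = character(0), isolated = character(0)) {
  stopifnot(length(edges) %% 2 == 0)
  from <- edges[seq_along(edges) %% 2 == 1]
  to <- edges[seq_along(edges) %% 2 == 0]
  nodes <- sort(unique(c(from, to, isolated)), method = "radix")
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(match(from, nodes), match(to, nodes)))
  }
  igraph::simplify(g)
}

clique_chr <- function(names) {
  pairs <- utils::combn(names, 2)
  as.vector(rbind(pairs[1, ], pairs[2, ]))
}

# Erdos-Renyi graph with zero-padded vertex names (byte order == numeric
# order) so lexicographic tie-breaking is predictable.
rand_gnp <- function(n, p) {
  g <- igraph::sample_gnp(n, p, directed = FALSE)
  igraph::set_vertex_attr(g, "name", value = sprintf("v%02d", seq_len(n)))
}

# Two K4 cliques joined by a single bridge edge a1-b1.
two_k4 <- function() {
  graph_chr(c(clique_chr(paste0("a", 1:4)), clique_chr(paste0("b", 1:4)),
              "a1", "b1"))
}
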