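# Seeded benchmark generators with known ground-truth modules. The two
# kinds span the topological regimes that matter for seed-expansion
# clustering: sparse, strongly modular networks (ring of cliques; yeast-like)
# and denser, more interconnected ones (planted partition with rising
# between-block probability; worm-like). Randomness uses R's default
# Mersenne-Twister generator under a local seed, so a spec is a pure
# function of its arguments.

#' Ring of cliques with optional noise edges
#'
#' `n_cliques` disjoint complete cliques of `clique_size` vertices; the
#' first vertex of each clique is bridged to the second vertex of the next,
#' ring-closing, so every clique has exactly two boundary edges (local
#' modularity `E_in / 2` in the noise-free graph) on two distinct vertices. `n_noise_edges` extra
#' distinct edges are then drawn uniformly among the absent vertex pairs.
#'
#' @param n_cliques number of cliques (>= 2).
#' @param clique_size vertices per clique (>= 3).
#' @param n_noise_edges extra uniform random edges (default 0).
#' @param seed RNG seed (required when `n_noise_edges > 0`).
#' @return a list with `graph` (an [igraph::graph]) and `truth` (an
#'   [annotation_set()] whose sets are the planted cliques).
#' @examples
#' b <- ring_of_cliques(5, 6, n_noise_edges = 0, seed = 1)
#' igraph::ecount(b$graph)  # 5 * 15 + 5 = 80
#' @export
ring_of_cliques <- function(n_cliques, clique_size, n_noise_edges = 0L,
                            seed = 1L) {
  if (!is_count(n_cliques, 2L)) stop("n_cliques must be an integer >= 2", call. = FALSE)
  if (!is_count(clique_size, 3L)) stop("clique_size must be an integer >= 3", call. = FALSE)
  if (!is_count(n_noise_edges, 0L)) stop("n_noise_edges must be a non-negative integer", call. = FALSE)
  wc <- nchar(as.character(n_cliques))
  wk <- nchar(as.character(clique_size))
  node <- function(i, j) sprintf("c%0*d_%0*d", wc, i, wk, j)
  nodes <- as.vector(vapply(seq_len(n_cliques), function(i) {
    vapply(seq_len(clique_size), function(j) node(i, j), character(1))
  }, character(clique_size)))
  from <- character(0)
  to <- character(0)
  for (i in seq_len(n_cliques)) {
    pairs <- utils::combn(seq_len(clique_size), 2)
    from <- c(from, node(i, pairs[1, ]))
    to <- c(to, node(i, pairs[2, ]))
  }
  # bridge clique i's first vertex to clique i+1's second vertex so the two
  # bridges of a clique land on distinct vertices and consecutive bridges
  # never collapse (also for n_cliques = 2)
  for (i in seq_len(n_cliques)) {
    from <- c(from, node(i, 1L))
    to <- c(to, node(if (i == n_cliques) 1L else i + 1L, 2L))
  }
  n <- length(nodes)
  max_extra <- n * (n - 1) / 2 - length(from)
  if (n_noise_edges > max_extra) {
    stop(sprintf("cannot place %d noise edges; only %d vertex pairs are free",
                 n_noise_edges, as.integer(max_extra)), call. = FALSE)
  }
  if (n_noise_edges > 0L) {
    key <- function(a, b) (pmin(a, b) - 1) * as.double(n) + pmax(a, b)
    taken <- key(match(from, nodes), match(to, nodes))
    extra <- with_seed(seed, {
      got <- integer(0)
      while (length(got) < 2L * n_noise_edges) {
        a <- sample.int(n, 1L)
        b <- sample.int(n, 1L)
        if (a == b) next
        k <- key(a, b)
        if (k %in% taken || k %in% key_pairs(got, n)) next
        got <- c(got, a, b)
      }
      got
    })
    ii <- extra[seq(1L, length(extra), by = 2L)]
    jj <- extra[seq(2L, length(extra), by = 2L)]
    from <- c(from, nodes[ii])
    to <- c(to, nodes[jj])
  }
  graph <- graph_from_parts(nodes, from, to)
  sets <- lapply(seq_len(n_cliques), function(i) node(i, seq_len(clique_size)))
  names(sets) <- sprintf("clique_%0*d", wc, seq_len(n_cliques))
  list(graph = graph,
       truth = annotation_set(sets, name = "ring_of_cliques"))
}

key_pairs <- function(flat, n) {
  if (!length(flat)) return(double(0))
  a <- flat[seq(1L, length(flat), by = 2L)]
  b <- flat[seq(2L, length(flat), by = 2L)]
  (pmin(a, b) - 1) * as.double(n) + pmax(a, b)
}

#' Planted-partition benchmark graph
#'
#' `n_blocks` blocks of `block_size` vertices; each within-block vertex pair
#' carries an edge with probability `p_in` and each between-block pair with
#' probability `p_out` (`p_out <= p_in`), all draws from the seeded RNG in a
#' fixed pair order. Raising `p_out` toward `p_in` produces the denser,
#' shorter-path regime of highly interconnected interactomes.
#'
#' @param n_blocks number of planted blocks (>= 1).
#' @param block_size vertices per block (>= 1).
#' @param p_in within-block edge probability.
#' @param p_out between-block edge probability (`<= p_in`).
#' @param seed RNG seed.
#' @return a list with `graph` and `truth` as in [ring_of_cliques()].
#' @export
planted_partition <- function(n_blocks, block_size, p_in, p_out, seed = 1L) {
  if (!is_count(n_blocks, 1L)) stop("n_blocks must be an integer >= 1", call. = FALSE)
  if (!is_count(block_size, 1L)) stop("block_size must be an integer >= 1", call. = FALSE)
  if (!is_prob(p_in) || !is_prob(p_out) || p_out > p_in) {
    stop("need 0 <= p_out <= p_in <= 1", call. = FALSE)
  }
  n <- n_blocks * block_size
  wb <- nchar(as.character(n_blocks))
  wk <- nchar(as.character(block_size))
  block <- base::rep(seq_len(n_blocks), each = block_size)
  nodes <- sprintf("b%0*d_%0*d", wb, block, wk,
                   base::rep(seq_len(block_size), times = n_blocks))
  from <- character(0)
  to <- character(0)
  if (n >= 2L) {
    i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
    j <- sequence((n - 1L):1L, from = 2:n)
    prob <- ifelse(block[i] == block[j], p_in, p_out)
    keep <- with_seed(seed, stats::runif(length(i)) < prob)
    from <- nodes[i[keep]]
    to <- nodes[j[keep]]
  }
  graph <- graph_from_parts(nodes, from, to)
  sets <- split(nodes, block)
  names(sets) <- sprintf("block_%0*d", wb, seq_len(n_blocks))
  list(graph = graph,
       truth = annotation_set(sets, name = "planted_partition"))
}
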