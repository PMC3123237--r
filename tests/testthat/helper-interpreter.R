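# A naive, step-by-step interpreter of the clustering procedure, written
# directly over the plain edge matrix with no shared code or data structures
# with the package: modularity is recomputed from scratch by scanning the
# edge list at every step, the queue is a pair of growing character vectors,
# and all set work uses character vectors. Used as the independent oracle
# for run_mine.

naive_modularity <- function(pl, members) {
  e_in <- sum(pl$edges[, 1] %in% members & pl$edges[, 2] %in% members)
  e_out <- sum(xor(pl$edges[, 1] %in% members, pl$edges[, 2] %in% members))
  if (e_in == 0) 0 else if (e_out == 0) Inf else e_in / e_out
}

naive_keep_ok <- function(new, old, msp) {
  if (is.infinite(old)) {
    if (is.infinite(new)) return(msp > 0)
    return(FALSE)
  }
  new > old - old * msp
}

naive_improve_ok <- function(new, old, msp) {
  if (is.infinite(old)) return(FALSE)
  new > old + old * msp
}

naive_weights <- function(pl) {
  w <- numeric(length(pl$nodes))
  names(w) <- pl$nodes
  for (v in pl$nodes) {
    nbhd <- c(v, plain_neighbors(pl, v))
    n <- length(nbhd)
    d <- if (n <= 1) 0 else 2 * plain_induced_edges(pl, nbhd) / (n * (n - 1))
    w[v] <- max(vapply(nbhd, function(u) plain_degree(pl, u), numeric(1))) * d
  }
  w
}

naive_grow <- function(pl, w, seed, vwp, msp) {
  members <- seed
  visited <- seed
  q_node <- plain_neighbors(pl, seed)
  q_src <- rep(seed, length(q_node))
  while (length(q_node)) {
    nd <- q_node[1]
    src <- q_src[1]
    q_node <- q_node[-1]
    q_src <- q_src[-1]
    if (nd %in% visited) next
    visited <- c(visited, nd)
    old <- naive_modularity(pl, members)
    new <- naive_modularity(pl, c(members, nd))
    # pseudocode branching: the weight test selects which modularity rule
    # applies (no-decrease within tolerance vs strict improvement)
    ok <- if (w[nd] >= w[src] * (1 - vwp)) {
      naive_keep_ok(new, old, msp)
    } else {
      naive_improve_ok(new, old, msp)
    }
    if (ok) {
      members <- c(members, nd)
      fresh <- setdiff(plain_neighbors(pl, nd), c(members, visited))
      q_node <- c(q_node, fresh)
      q_src <- c(q_src, rep(nd, length(fresh)))
    }
  }
  members
}

naive_cull <- function(pl, members, msp) {
  repeat {
    old <- naive_modularity(pl, members)
    removed <- FALSE
    for (v in sort(members, method = "radix")) {
      if (naive_improve_ok(naive_modularity(pl, setdiff(members, v)), old, msp)) {
        members <- setdiff(members, v)
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  members
}

naive_trim <- function(pl, members) {
  indeg <- vapply(members, function(v) {
    sum((pl$edges[, 1] == v & pl$edges[, 2] %in% members) |
          (pl$edges[, 2] == v & pl$edges[, 1] %in% members))
  }, numeric(1))
  members[indeg >= 2]
}

naive_mine <- function(graph, vwp, msp, mp = 0.5, trim = TRUE, min_size = 3) {
  pl <- as_plain(graph)
  w <- naive_weights(pl)
  seed_order <- pl$nodes[order(-w, pl$nodes, method = "radix")]
  clusters <- list()
  for (seed in seed_order) {
    mem <- naive_grow(pl, w, seed, vwp, msp)
    mem <- naive_cull(pl, mem, msp)
    if (trim) mem <- naive_trim(pl, mem)
    merged <- FALSE
    if (length(mem)) {
      for (i in seq_along(clusters)) {
        ex <- clusters[[i]]
        if (!length(ex)) next
        ov <- length(intersect(mem, ex)) / min(length(mem), length(ex))
        if (ov >= mp) {
          clusters[[i]] <- sort(union(ex, mem), method = "radix")
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) clusters[[length(clusters) + 1]] <- sort(mem, method = "radix")
  }
  clusters <- clusters[lengths(clusters) >= min_size]
  if (!length(clusters)) return(list())
  score <- vapply(clusters, function(m) oracle_cluster_stats(graph, m)$score,
                  numeric(1))
  size <- lengths(clusters)
  first <- vapply(clusters, function(m) if (length(m)) m[1] else "", character(1))
  clusters[order(-score, -size, first, method = "radix")]
}
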