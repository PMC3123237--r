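# The MINE core: seed-expansion growth under the vertex-weight (vwp) and
# local-modularity (msp) admission rules, iterative culling, optional trim,
# overlap merging, size filtering and scoring.

#' Clustering parameters
#'
#' @param vwp vertex weight percentage in `[0, 1]`: a candidate popped from
#'   the expansion queue passes the weight test when its weight is at least
#'   `(1 - vwp)` times the weight of the member that enqueued it. `vwp = 1`
#'   disables the weight test; `vwp = 0` requires candidates at least as
#'   heavy as their source.
#' @param msp modularity score percentage in `[0, 1]`: the relative
#'   tolerance on the cluster's local modularity `E_in / E_out` used in the
#'   admission, rejection and culling rules.
#' @param mp merge percentage in `(0, 1]`: two clusters merge when their
#'   overlap, measured against the smaller cluster, is at least `mp`.
#' @param trim when `TRUE`, vertices with fewer than 2 connections inside
#'   the finished cluster are removed (single simultaneous pass).
#' @param min_size clusters smaller than this after the full pipeline are
#'   discarded (the default 3 drops size-1/2 clusters).
#'
#' The defaults `vwp = 0.9`, `msp = 0.3`, `trim = TRUE` are the settings
#' that balance modularity and geometric accuracy on a dense metazoan
#' protein-interaction network; sparser, more modular networks tolerate a
#' wide range around them.
#'
#' @return an object of class `mine_params`.
#' @export
mine_params <- function(vwp = 0.9, msp = 0.3, mp = 0.5, trim = TRUE,
                        min_size = 3L) {
  if (!is_prob(vwp)) stop("vwp must be a single value in [0, 1]", call. = FALSE)
  if (!is_prob(msp)) stop("msp must be a single value in [0, 1]", call. = FALSE)
  if (!is_prob(mp) || mp == 0) stop("mp must be a single value in (0, 1]", call. = FALSE)
  if (!is_count(min_size, min = 1L)) stop("min_size must be an integer >= 1", call. = FALSE)
  if (!is.logical(trim) || length(trim) != 1L || is.na(trim)) {
    stop("trim must be TRUE or FALSE", call. = FALSE)
  }
  structure(list(vwp = vwp, msp = msp, mp = mp, trim = trim,
                 min_size = as.integer(min_size)),
            class = "mine_params")
}

#' @export
print.mine_params <- function(x, ...) {
  cat(sprintf("mine_params: vwp=%g msp=%g mp=%g trim=%s min_size=%d\n",
              x$vwp, x$msp, x$mp, x$trim, x$min_size))
  invisible(x)
}

# Local modularity value with the degenerate conventions:
# E_in = 0 -> 0; E_out = 0 with E_in > 0 -> +Inf.
mod_value <- function(e_in, e_out) {
  if (e_in == 0) 0 else if (e_out == 0) Inf else e_in / e_out
}

# Does `new` exceed `old + sign * old * msp`?  sign = -1 is the
# "does not decrease beyond tolerance" test (admission criterion A),
# sign = +1 the strict-improvement test (criterion B and culling).
# Conventions for the +Inf sentinel: a finite `new` against an infinite
# `old` is a decrease (fails both); +Inf against +Inf is "no change", which
# passes the no-decrease test only when the tolerance is positive and never
# counts as an improvement.
mod_improves <- function(new, old, sign, msp) {
  if (is.infinite(old)) {
    if (is.infinite(new)) return(sign < 0 && msp > 0)
    return(FALSE)
  }
  new > old + sign * old * msp
}

# ---------------------------------------------------------------------------
# Index-level pipeline stage: the growth/cull/trim hot path is compiled
# (src/mine_core.cpp); this wrapper hands over the CSR arrays. Returns the
# sorted integer member set for one seed.
pipeline_idx <- function(rep, w, seed, params, cull = TRUE) {
  .mine_grow_core(rep$offsets, rep$nbr, w, seed,
                  params$vwp, params$msp, cull, params$trim)
}

# E_in / E_out for an index member set.
counts_idx <- function(rep, mem) {
  inset <- logical(rep$n)
  inset[mem] <- TRUE
  e_in <- 0L
  e_out <- 0L
  for (v in mem) {
    k <- sum(inset[rep$adj[[v]]])
    e_in <- e_in + k
    e_out <- e_out + (rep$deg[[v]] - k)
  }
  list(e_in = e_in %/% 2L, e_out = e_out)
}

cluster_from_idx <- function(rep, mem, seed = NA_character_) {
  mem <- sort.int(mem)
  cnt <- counts_idx(rep, mem)
  size <- length(mem)
  density <- if (size <= 1L) 0 else 2 * cnt$e_in / (size * (size - 1))
  structure(list(
    members = rep$names[mem],
    seed = seed,
    size = size,
    e_in = cnt$e_in,
    e_out = cnt$e_out,
    density = density,
    local_modularity = mod_value(cnt$e_in, cnt$e_out),
    score = density * size
  ), class = "mine_cluster")
}

#' @export
print.mine_cluster <- function(x, ...) {
  cat(sprintf(
    "mine_cluster: %d members, E_in=%d E_out=%d, density=%.4g, modularity=%s, score=%.4g\n",
    x$size, x$e_in, x$e_out, x$density,
    if (is.infinite(x$local_modularity)) "inf" else
      sprintf("%.4g", x$local_modularity),
    x$score))
  cat("  members:", paste(x$members, collapse = ", "), "\n")
  invisible(x)
}

members_of <- function(x) {
  if (inherits(x, "mine_cluster")) x$members else as.character(x)
}

# Canonical presentation order: score desc, size desc, then smallest member.
sort_clusters <- function(clusters) {
  if (!length(clusters)) return(clusters)
  score <- vapply(clusters, function(cl) cl$score, numeric(1))
  size <- vapply(clusters, function(cl) cl$size, numeric(1))
  first <- vapply(clusters, function(cl) {
    if (cl$size) cl$members[[1L]] else ""
  }, character(1))
  clusters[order(-score, -size, first, method = "radix")]
}

# ---------------------------------------------------------------------------
# Exported, graph-level operations.

#' Local modularity of a vertex set
#'
#' `E_in / E_out`, where `E_in` counts edges with both endpoints in
#' `members` and `E_out` counts edges with exactly one endpoint in
#' `members`. Degenerate conventions: 0 when `E_in = 0`; `+Inf` when
#' `E_out = 0` with `E_in > 0` (a whole connected component).
#'
#' @param graph an undirected [igraph::graph] with character vertex names.
#' @param members character vector of vertex names (a subset of the graph).
#' @return a single number, possibly `Inf`.
#' @export
local_modularity <- function(graph, members) {
  rep <- mine_rep(graph)
  mem <- match(unique(members), rep$names)
  if (anyNA(mem)) {
    stop(sprintf("members not in graph: %s",
                 paste(setdiff(unique(members), rep$names), collapse = ", ")),
         call. = FALSE)
  }
  cnt <- counts_idx(rep, mem)
  mod_value(cnt$e_in, cnt$e_out)
}

#' Score a cluster
#'
#' The cluster score is `density * size`, with density
#' `2 E_in / (size (size - 1))` and 0 for clusters of size 0 or 1.
#'
#' @inheritParams local_modularity
#' @param cluster a `mine_cluster` or character vector of member names.
#' @return a single non-negative number.
#' @export
score_cluster <- function(graph, cluster) {
  rep <- mine_rep(graph)
  mem <- match(unique(members_of(cluster)), rep$names)
  if (anyNA(mem)) stop("cluster members not in graph", call. = FALSE)
  cluster_from_idx(rep, mem)$score
}

#' Grow a cluster from a seed vertex
#'
#' Breadth-first seed expansion: the seed is the initial member and its
#' neighbours enter a FIFO queue. A candidate `n` popped from the queue
#' (enqueued by member `v_s`) is admitted when either (A) its weight is at
#' least `weight(v_s) * (1 - vwp)` and adding it does not drop the cluster's
#' local modularity below `mod * (1 - msp)`, or (B) adding it raises the
#' modularity above `mod * (1 + msp)`. Admitted members enqueue their
#' unvisited non-member neighbours; each vertex is examined at most once per
#' seed. After the queue empties the cluster is iteratively culled (members
#' whose removal improves modularity beyond the tolerance are removed, one
#' at a time, until no removal fires) and, if `params$trim`, trimmed.
#'
#' @inheritParams local_modularity
#' @param seed vertex name to nucleate from.
#' @param params a [mine_params()] object.
#' @param weights optional result of [compute_vertex_weights()] for `graph`
#'   (computed on the fly when omitted).
#' @return a `mine_cluster`.
#' @export
grow_cluster <- function(graph, seed, params = mine_params(), weights = NULL) {
  stopifnot(inherits(params, "mine_params"))
  rep <- mine_rep(graph)
  s <- match(seed, rep$names)
  if (is.na(s)) stop(sprintf("seed '%s' not in graph", seed), call. = FALSE)
  w <- weights_vector(rep, weights)
  cluster_from_idx(rep, pipeline_idx(rep, w, s, params), seed = seed)
}

weights_vector <- function(rep, weights) {
  if (is.null(weights)) return(vertex_weights_rep(rep)$weight)
  stopifnot(is.data.frame(weights), all(c("node", "weight") %in% names(weights)))
  i <- match(rep$names, weights$node)
  if (anyNA(i)) stop("weights table does not cover all graph vertices", call. = FALSE)
  weights$weight[i]
}

#' Trim a cluster (haircut)
#'
#' Single simultaneous pass: every member with fewer than 2 connections
#' inside the cluster-induced subgraph (judged against the pre-pass
#' membership) is removed. A path of three vertices therefore loses both
#' ends at once.
#'
#' @inheritParams score_cluster
#' @return a `mine_cluster` with recomputed statistics.
#' @export
trim_cluster <- function(graph, cluster) {
  rep <- mine_rep(graph)
  mem <- match(unique(members_of(cluster)), rep$names)
  if (anyNA(mem)) stop("cluster members not in graph", call. = FALSE)
  kept <- .mine_trim_core(rep$offsets, rep$nbr, mem)
  seed <- if (inherits(cluster, "mine_cluster")) cluster$seed else NA_character_
  cluster_from_idx(rep, kept, seed = seed)
}

#' Merge a candidate cluster into a list, by overlap
#'
#' Overlap between two clusters is `|A intersect B| / min(|A|, |B|)`. The
#' candidate merges (set union, statistics recomputed, no re-growth) into
#' the first existing cluster, in creation order, whose overlap is at least
#' `mp`; otherwise it is appended. Empty clusters never merge.
#'
#' @inheritParams local_modularity
#' @param existing list of `mine_cluster` objects (creation order).
#' @param candidate a `mine_cluster` or character vector of members.
#' @param mp merge threshold in `(0, 1]`.
#' @return the updated list of `mine_cluster` objects.
#' @export
maybe_merge <- function(graph, existing, candidate, mp = 0.5) {
  rep <- mine_rep(graph)
  ex_idx <- lapply(existing, function(cl) match(members_of(cl), rep$names))
  cand <- match(unique(members_of(candidate)), rep$names)
  if (anyNA(cand) || any(vapply(ex_idx, anyNA, logical(1)))) {
    stop("cluster members not in graph", call. = FALSE)
  }
  seeds <- vapply(existing, function(cl) {
    if (inherits(cl, "mine_cluster")) cl$seed else NA_character_
  }, character(1))
  cand_seed <- if (inherits(candidate, "mine_cluster")) candidate$seed else NA_character_
  res <- merge_or_append(rep, ex_idx, cand, mp)
  out <- vector("list", length(res$sets))
  for (i in seq_along(res$sets)) {
    seed <- if (i <= length(seeds)) seeds[[i]] else cand_seed
    out[[i]] <- cluster_from_idx(rep, res$sets[[i]], seed = seed)
  }
  out
}

merge_or_append <- function(rep, ex_idx, cand, mp) {
  nc <- length(cand)
  if (nc) {
    for (i in seq_along(ex_idx)) {
      ne <- length(ex_idx[[i]])
      if (!ne) next
      ov <- sum(match(cand, ex_idx[[i]], nomatch = 0L) > 0L) / min(nc, ne)
      if (ov >= mp) {
        ex_idx[[i]] <- sort.int(unique(c(ex_idx[[i]], cand)))
        return(list(sets = ex_idx, merged = i))
      }
    }
  }
  ex_idx[[length(ex_idx) + 1L]] <- sort.int(cand)
  list(sets = ex_idx, merged = NA_integer_)
}

#' Run the full MINE clustering pipeline
#'
#' Vertex weights are computed once; every vertex is inspected as a seed in
#' descending weight order (ties broken byte-lexicographically by name).
#' Each grown cluster passes through culling, optional trimming, and
#' merge-or-append against the clusters produced so far; finally clusters
#' smaller than `params$min_size` are discarded and the survivors sorted by
#' score (descending; ties by size then smallest member). Clustering is
#' non-exclusive: a vertex may appear in several output clusters. The whole
#' pipeline is deterministic given the graph and parameters.
#'
#' @inheritParams local_modularity
#' @param params a [mine_params()] object.
#' @return an object of class `mine_result`: a list with elements
#'   `clusters` (list of `mine_cluster`), `params`, `n_nodes`, `n_edges`.
#' @examples
#' bench <- ring_of_cliques(3, 4, n_noise_edges = 0, seed = 1)
#' res <- run_mine(bench$graph, mine_params(vwp = 1, msp = 0, trim = FALSE))
#' length(res$clusters)  # the 3 planted cliques
#' @export
run_mine <- function(graph, params = mine_params()) {
  stopifnot(inherits(params, "mine_params"))
  rep <- mine_rep(graph)
  out <- structure(list(clusters = list(), params = params,
                        n_nodes = rep$n, n_edges = rep$m),
                   class = "mine_result")
  if (!rep$n) return(out)
  w <- vertex_weights_rep(rep)$weight
  seed_order <- order(-w, seq_len(rep$n))
  sets <- list()
  seeds <- integer(0)
  for (s in seed_order) {
    mem <- pipeline_idx(rep, w, s, params)
    res <- merge_or_append(rep, sets, mem, params$mp)
    sets <- res$sets
    if (is.na(res$merged)) seeds <- c(seeds, s)
  }
  keep <- lengths(sets) >= params$min_size
  sets <- sets[keep]
  seeds <- seeds[keep]
  clusters <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    clusters[[i]] <- cluster_from_idx(rep, sets[[i]],
                                      seed = rep$names[[seeds[[i]]]])
  }
  out$clusters <- sort_clusters(clusters)
  out
}

#' @export
print.mine_result <- function(x, ...) {
  cat(sprintf("mine_result: %d clusters from %d nodes / %d edges\n",
              length(x$clusters), x$n_nodes, x$n_edges))
  print(x$params)
  if (length(x$clusters)) {
    df <- as.data.frame(x)
    df$members <- NULL
    print(utils::head(df, 10L))
    if (nrow(df) > 10L) cat(sprintf("... and %d more\n", nrow(df) - 10L))
  }
  invisible(x)
}

#' @export
as.data.frame.mine_result <- function(x, ...) {
  cl <- x$clusters
  data.frame(
    rank = seq_along(cl),
    seed = vapply(cl, function(c) c$seed, character(1)),
    size = vapply(cl, function(c) c$size, integer(1)),
    e_in = vapply(cl, function(c) as.integer(c$e_in), integer(1)),
    e_out = vapply(cl, function(c) as.integer(c$e_out), integer(1)),
    density = vapply(cl, function(c) c$density, numeric(1)),
    local_modularity = vapply(cl, function(c) c$local_modularity, numeric(1)),
    score = vapply(cl, function(c) c$score, numeric(1)),
    members = vapply(cl, function(c) paste(c$members, collapse = ";"),
                     character(1)),
    stringsAsFactors = FALSE
  )
}
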