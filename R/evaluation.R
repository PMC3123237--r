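# Validation statistics: hypergeometric cluster-to-complex matching,
# recall / precision / geometric accuracy, composite (global) modularity,
# and basic network statistics.

#' Upper-tail hypergeometric overlap p-value
#'
#' Probability of observing at least `overlap` shared members between a
#' cluster of `cluster_size` vertices drawn from a network of `population`
#' vertices, of which `complex_size` belong to the annotated complex:
#' `P(X >= overlap)` for `X` hypergeometric.
#'
#' @param population number of vertices in the network (the universe).
#' @param complex_size members of the complex present in the network.
#' @param cluster_size size of the predicted cluster.
#' @param overlap observed intersection size.
#' @return a p-value in `[0, 1]`.
#' @examples
#' hypergeom_overlap_pvalue(10, 4, 3, 3)  # 4/120
#' @export
hypergeom_overlap_pvalue <- function(population, complex_size, cluster_size,
                                     overlap) {
  if (!is_count(population, 0L) || !is_count(complex_size, 0L) ||
      !is_count(cluster_size, 0L) || !is_count(overlap, 0L)) {
    stop("all arguments must be single non-negative integers", call. = FALSE)
  }
  if (complex_size > population || cluster_size > population ||
      overlap > min(complex_size, cluster_size)) {
    stop("violated bounds: need overlap <= min(complex_size, cluster_size) <= population",
         call. = FALSE)
  }
  stats::phyper(overlap - 1, complex_size, population - complex_size,
                cluster_size, lower.tail = FALSE)
}

#' Geometric accuracy
#'
#' The geometric mean `sqrt(R * P)` of recall and precision: a single score
#' for how strictly a clustering recovers an annotated complex without
#' drawing in extraneous vertices.
#'
#' @param recall,precision values in `[0, 1]` (vectorised).
#' @return `sqrt(recall * precision)`, in `[0, 1]`.
#' @export
geometric_accuracy <- function(recall, precision) {
  if (any(!is.finite(recall) | recall < 0 | recall > 1) ||
      any(!is.finite(precision) | precision < 0 | precision > 1)) {
    stop("recall and precision must lie in [0, 1]", call. = FALSE)
  }
  sqrt(recall * precision)
}

#' Match annotated complexes to predicted clusters
#'
#' For each annotated complex, membership is first restricted to vertices
#' present in the network (complexes with no member in the network are
#' excluded). The cluster with the smallest hypergeometric overlap p-value
#' is selected (ties: larger overlap, then smaller cluster, then lower
#' cluster index); the match is recorded only when `p <= alpha`. Against
#' the matched cluster, `TP` is the intersection size, `FN` the complex
#' members outside the cluster, and `FP` the cluster members outside the
#' complex, giving `recall = TP/(TP+FN)` and `precision = TP/(TP+FP)`.
#'
#' @param clusters a [run_mine()] result, or a list of `mine_cluster`
#'   objects / character member vectors.
#' @param annotations an [annotation_set()].
#' @param graph the network the clusters were predicted on; its vertex count
#'   is the hypergeometric population.
#' @param alpha significance threshold (default 0.05).
#' @return a `data.frame` with one row per complex retained after
#'   restriction: `complex_id`, `complex_size` (restricted), `best_cluster`
#'   (index into `clusters`, `NA` when no significant match), `overlap`,
#'   `p_value`, `recall`, `precision`, `geometric_accuracy` (the last three
#'   `NA` when unmatched). The names of excluded complexes are attached as
#'   attribute `"excluded"`.
#' @export
match_complexes <- function(clusters, annotations, graph, alpha = 0.05) {
  stopifnot(inherits(annotations, "annotation_set"))
  if (!is_prob(alpha) || alpha == 0) {
    stop("alpha must be a single value in (0, 1]", call. = FALSE)
  }
  if (!length(annotations$sets)) stop("annotations are empty", call. = FALSE)
  if (inherits(clusters, "mine_result")) clusters <- clusters$clusters
  member_sets <- lapply(clusters, members_of)
  nodes <- igraph::V(graph)$name
  population <- length(nodes)
  ids <- names(annotations$sets)
  rows <- vector("list", length(ids))
  excluded <- character(0)
  for (ci in seq_along(ids)) {
    complex <- intersect(annotations$sets[[ci]], nodes)
    ks <- length(complex)
    if (!ks) {
      excluded <- c(excluded, ids[[ci]])
      next
    }
    best <- NA_integer_
    best_p <- Inf
    best_ov <- -1L
    best_sz <- .Machine$integer.max
    for (k in seq_along(member_sets)) {
      mem <- member_sets[[k]]
      sz <- length(mem)
      if (!sz) next
      ov <- sum(match(complex, mem, nomatch = 0L) > 0L)
      p <- hypergeom_overlap_pvalue(population, ks, sz, ov)
      if (p < best_p ||
          (p == best_p && (ov > best_ov ||
                           (ov == best_ov && sz < best_sz)))) {
        best <- k
        best_p <- p
        best_ov <- ov
        best_sz <- sz
      }
    }
    significant <- !is.na(best) && best_p <= alpha
    if (significant) {
      tp <- best_ov
      recall <- tp / ks
      precision <- tp / best_sz
      rows[[ci]] <- data.frame(
        complex_id = ids[[ci]], complex_size = ks,
        best_cluster = best, overlap = tp, p_value = best_p,
        recall = recall, precision = precision,
        geometric_accuracy = sqrt(recall * precision),
        stringsAsFactors = FALSE)
    } else {
      rows[[ci]] <- data.frame(
        complex_id = ids[[ci]], complex_size = ks,
        best_cluster = NA_integer_, overlap = NA_integer_,
        p_value = if (is.finite(best_p)) best_p else NA_real_,
        recall = NA_real_, precision = NA_real_,
        geometric_accuracy = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    stop("no annotated complex has any member in the network", call. = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Composite (global) modularity of a clustering
#'
#' The Newman-Girvan community-modularity form aggregated over clusters:
#' `Q = sum_c [ E_cIn/E_total - ((2 E_cIn + E_cOut) / (2 E_total))^2 ]`,
#' where `E_cIn` and `E_cOut` are each cluster's internal and boundary edge
#' counts and `E_total` the number of edges in the network. Only clusters
#' fully contained in the largest connected component are counted. A single
#' cluster spanning a whole connected network scores exactly 0.
#'
#' @inheritParams match_complexes
#' @return a single number (0 for an empty cluster list).
#' @export
global_modularity <- function(graph, clusters) {
  if (inherits(clusters, "mine_result")) clusters <- clusters$clusters
  if (!length(clusters)) return(0)
  e_total <- igraph::ecount(graph)
  if (e_total < 1L) stop("graph has no edges (E_total must be >= 1)", call. = FALSE)
  comp <- igraph::components(graph)
  main <- which.max(comp$csize)
  in_main <- igraph::V(graph)$name[comp$membership == main]
  rep <- mine_rep(graph)
  q <- 0
  for (cl in clusters) {
    mem <- members_of(cl)
    if (!length(mem) || !all(mem %in% in_main)) next
    cnt <- counts_idx(rep, match(mem, rep$names))
    q <- q + cnt$e_in / e_total -
      ((2 * cnt$e_in + cnt$e_out) / (2 * e_total))^2
  }
  q
}

#' Basic network statistics
#'
#' Density `2|E| / (|V|(|V|-1))` and characteristic path length (mean
#' shortest-path length over all connected unordered vertex pairs;
#' disconnected pairs are excluded, so multi-component interactomes still
#' report a finite number). With fewer than 2 vertices the density is 0 and
#' the path length `NaN`; a graph with no connected pairs also reports
#' `NaN`.
#'
#' @inheritParams local_modularity
#' @return a list with elements `n_nodes`, `n_edges`, `density`,
#'   `characteristic_path_length`.
#' @export
network_stats <- function(graph) {
  n <- igraph::vcount(graph)
  m <- igraph::ecount(graph)
  density <- if (n < 2L) 0 else 2 * m / (n * (n - 1))
  cpl <- if (n < 2L || m < 1L) NaN else
    suppressWarnings(igraph::mean_distance(graph, directed = FALSE,
                                           unconnected = TRUE))
  if (is.na(cpl)) cpl <- NaN
  list(n_nodes = n, n_edges = m, density = density,
       characteristic_path_length = cpl)
}

#' Aggregate an evaluation into summary statistics
#'
#' Means of recall, precision and geometric accuracy over the annotated
#' complexes, plus the composite modularity and cluster-size/density
#' summaries. By default complexes without a significant match contribute
#' to none of the means; with `include_unmatched = TRUE` they count as
#' zeros (a sensitivity mode).
#'
#' @param matches result of [match_complexes()].
#' @param clusters the clusters that were evaluated ([run_mine()] result or
#'   list).
#' @param graph the network.
#' @param include_unmatched count unmatched complexes as zero recall /
#'   precision / accuracy.
#' @return an object of class `evaluation_summary`: a list with
#'   `mean_recall`, `mean_precision`, `mean_geometric_accuracy`,
#'   `global_modularity`, `n_clusters`, `n_complexes`, `n_matched`,
#'   `mean_cluster_size`, `mean_cluster_density`.
#' @export
evaluation_summary <- function(matches, clusters, graph,
                               include_unmatched = FALSE) {
  if (inherits(clusters, "mine_result")) clusters <- clusters$clusters
  r <- matches$recall
  p <- matches$precision
  ga <- matches$geometric_accuracy
  if (include_unmatched) {
    r[is.na(r)] <- 0
    p[is.na(p)] <- 0
    ga[is.na(ga)] <- 0
  }
  sizes <- vapply(clusters, function(cl) length(members_of(cl)), numeric(1))
  dens <- vapply(clusters, function(cl) {
    if (inherits(cl, "mine_cluster")) cl$density else
      2 * local_modularity_counts(graph, members_of(cl))$e_in /
        max(1, length(members_of(cl)) * (length(members_of(cl)) - 1))
  }, numeric(1))
  structure(list(
    mean_recall = mean(r, na.rm = TRUE),
    mean_precision = mean(p, na.rm = TRUE),
    mean_geometric_accuracy = mean(ga, na.rm = TRUE),
    global_modularity = if (length(clusters)) global_modularity(graph, clusters) else 0,
    n_clusters = length(clusters),
    n_complexes = nrow(matches),
    n_matched = sum(!is.na(matches$best_cluster)),
    mean_cluster_size = if (length(sizes)) mean(sizes) else NaN,
    mean_cluster_density = if (length(dens)) mean(dens) else NaN
  ), class = "evaluation_summary")
}

local_modularity_counts <- function(graph, members) {
  rep <- mine_rep(graph)
  counts_idx(rep, match(unique(members), rep$names))
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "evaluation_summary: %d clusters vs %d complexes (%d matched)\n",
    "  mean recall            %.4f\n",
    "  mean precision         %.4f\n",
    "  mean geometric accuracy %.4f\n",
    "  global modularity      %.4f\n",
    "  mean cluster size      %.2f   mean cluster density %.4f\n"),
    x$n_clusters, x$n_complexes, x$n_matched,
    x$mean_recall, x$mean_precision, x$mean_geometric_accuracy,
    x$global_modularity, x$mean_cluster_size, x$mean_cluster_density))
  invisible(x)
}
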