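#' Read an interaction network from SIF or TSV edge-list files
#'
#' Builds a simple, undirected, unweighted graph of string identifiers from
#' one or more interaction files. Self-loops are dropped, duplicate edges
#' (within or across files) collapse to one, and node identifiers are taken
#' verbatim (case-sensitive). Multiple files are unioned into one graph.
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`sif`}{Cytoscape simple interaction format. Each line is
#'     `nodeA <interactionType> nodeB [nodeB2 ...]`, delimited by tabs when
#'     the line contains a tab and by runs of whitespace otherwise. A line
#'     with a single token declares an isolated node. Interaction types are
#'     discarded (the graph is unweighted and untyped).}
#'   \item{`tsv`}{Two-column tab-separated edge list `nodeA<TAB>nodeB`.
#'     A line with a single token declares an isolated node, so that graphs
#'     written by [write_network()] round-trip exactly.}
#' }
#'
#' @param path character vector of file paths; their union is returned.
#' @param format `"sif"` or `"tsv"`.
#' @return an undirected simple [igraph::graph] with character vertex names,
#'   vertices ordered byte-lexicographically.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("A\tB", "B\tC"), tf)
#' g <- read_network(tf, format = "tsv")
#' igraph::vcount(g)
#' @export
read_network <- function(path, format = c("sif", "tsv")) {
  format <- match.arg(format)
  nodes <- character(0)
  from <- character(0)
  to <- character(0)
  for (p in path) {
    if (!file.exists(p)) {
      stop(sprintf("network file not found: %s", p), call. = FALSE)
    }
    parsed <- switch(format,
      sif = parse_sif(p),
      tsv = parse_edge_tsv(p)
    )
    nodes <- c(nodes, parsed$nodes)
    from <- c(from, parsed$from)
    to <- c(to, parsed$to)
  }
  graph_from_parts(nodes, from, to)
}

parse_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nodes <- character(0)
  from <- list()
  to <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    # Cytoscape rule: tab-delimited if the line contains a tab, otherwise
    # any run of whitespace delimits.
    tok <- if (grepl("\t", line, fixed = TRUE)) {
      strsplit(line, "\t", fixed = TRUE)[[1]]
    } else {
      strsplit(trimws(line), "[[:space:]]+")[[1]]
    }
    tok <- tok[nzchar(tok)]
    if (length(tok) == 1L) {
      nodes <- c(nodes, tok)
    } else if (length(tok) == 2L) {
      stop_parse(path, i, "SIF line has 2 fields; expected 1 (isolated node) or >= 3 (source, type, targets...)")
    } else {
      from[[length(from) + 1L]] <- rep(tok[[1L]], length(tok) - 2L)
      to[[length(to) + 1L]] <- tok[-(1:2)]
    }
  }
  list(nodes = nodes, from = unlist(from) %||% character(0),
       to = unlist(to) %||% character(0))
}

parse_edge_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nodes <- character(0)
  from <- character(0)
  to <- character(0)
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(line)) next
    if (startsWith(line, "#")) next
    tok <- strsplit(line, "\t", fixed = TRUE)[[1]]
    tok <- tok[nzchar(tok)]
    if (length(tok) == 1L) {
      nodes <- c(nodes, tok)
    } else if (length(tok) == 2L) {
      from <- c(from, tok[[1L]])
      to <- c(to, tok[[2L]])
    } else {
      stop_parse(path, i, sprintf("edge-list line has %d fields; expected 1 or 2", length(tok)))
    }
  }
  list(nodes = nodes, from = from, to = to)
}

# Assemble the canonical graph: vertices sorted byte-lexicographically,
# loops removed, parallel edges collapsed.
graph_from_parts <- function(nodes, from, to) {
  all_nodes <- sort_c(unique(c(nodes, from, to)))
  keep <- from != to
  from <- from[keep]
  to <- to[keep]
  g <- igraph::make_empty_graph(n = length(all_nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = all_nodes)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(match(from, all_nodes), match(to, all_nodes)))
  }
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a network as a two-column tab-separated edge list
#'
#' Edges are written one per line with endpoints in byte-lexicographic order
#' within and across lines; isolated vertices are written as single-token
#' lines so [read_network()] (format `"tsv"`) round-trips the graph exactly.
#'
#' @param graph an undirected [igraph::graph] with character vertex names.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(graph, path) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  lines <- character(0)
  if (nrow(el)) {
    a <- pmin(el[, 1L], el[, 2L])
    b <- pmax(el[, 1L], el[, 2L])
    o <- order_c(a, b)
    lines <- paste(a[o], b[o], sep = "\t")
  }
  iso <- igraph::V(graph)$name[igraph::degree(graph) == 0L]
  lines <- c(lines, sort_c(iso))
  writeLines(lines, path)
  invisible(path)
}

#' Construct an annotation set (named gene sets)
#'
#' An annotation set is the validation gold standard: a collection of named
#' gene sets (protein complexes, GO term memberships, or planted ground-truth
#' modules). Duplicate members within a set collapse; set identifiers must be
#' unique.
#'
#' @param sets named list of character vectors (set id -> members).
#' @param name label for the collection (e.g. the source file).
#' @param description optional character vector of per-set descriptions,
#'   parallel to `sets`.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(sets, name = "", description = NULL) {
  stopifnot(is.list(sets))
  ids <- names(sets)
  if (length(sets) && (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))) {
    stop("set identifiers must be unique, non-empty names", call. = FALSE)
  }
  sets <- lapply(sets, function(m) sort_c(unique(as.character(m))))
  if (!is.null(description)) {
    stopifnot(length(description) == length(sets))
    names(description) <- ids
  }
  structure(list(name = name, sets = sets, description = description),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat(sprintf("annotation_set '%s': %d sets", x$name, length(x$sets)))
  if (length(sizes)) {
    cat(sprintf(", sizes %d-%d (median %g)", min(sizes), max(sizes),
                stats::median(sizes)))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.annotation_set <- function(x) length(x$sets)

#' Read gene sets in GMT format
#'
#' GMT (Broad gene-set format) lines are
#' `setID<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line collapse to one member; sets whose deduplicated size falls outside
#' `[min_size, max_size]` are excluded. The defaults (3 and 100) keep
#' annotation categories that are neither too specific nor too general.
#'
#' @param path GMT file path.
#' @param min_size,max_size inclusive bounds on retained set size.
#' @return an [annotation_set()].
#' @export
read_gmt <- function(path, min_size = 3L, max_size = 100L) {
  if (!file.exists(path)) stop(sprintf("GMT file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(line) || startsWith(line, "#")) next
    tok <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(tok) < 3L) {
      stop_parse(path, i, sprintf("GMT line has %d fields; expected at least 3", length(tok)))
    }
    id <- tok[[1L]]
    if (id %in% names(sets)) {
      stop_parse(path, i, sprintf("duplicate set identifier '%s'", id))
    }
    members <- unique(tok[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) < min_size || length(members) > max_size) next
    sets[[id]] <- members
    desc[[id]] <- tok[[2L]]
  }
  annotation_set(sets, name = basename(path),
                 description = if (length(sets)) unname(desc[names(sets)]))
}

#' Read gene sets from a two-column (set id, gene) table
#'
#' A convenience reader for MIPS-style dumps: each line is
#' `setID<TAB>gene`. Genes are grouped by set id; the same size filter as
#' [read_gmt()] applies after deduplication.
#'
#' @inheritParams read_gmt
#' @return an [annotation_set()].
#' @export
read_set_pairs <- function(path, min_size = 3L, max_size = 100L) {
  if (!file.exists(path)) stop(sprintf("set file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  ids <- character(0)
  genes <- character(0)
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(line) || startsWith(line, "#")) next
    tok <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(tok) != 2L) {
      stop_parse(path, i, sprintf("pair line has %d fields; expected 2", length(tok)))
    }
    ids <- c(ids, tok[[1L]])
    genes <- c(genes, tok[[2L]])
  }
  sets <- lapply(split(genes, ids), unique)
  sizes <- lengths(sets)
  sets <- sets[sizes >= min_size & sizes <= max_size]
  annotation_set(sets[sort_c(names(sets))], name = basename(path))
}

#' Write an annotation set in GMT format
#'
#' @param annotations an [annotation_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_set"))
  ids <- names(annotations$sets)
  desc <- annotations$description %||% rep("na", length(ids))
  desc[!nzchar(desc)] <- "na"
  lines <- vapply(seq_along(ids), function(i) {
    paste(c(ids[[i]], desc[[i]], annotations$sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a cluster report
#'
#' Tab-separated, one row per cluster, ranked by descending score (ties:
#' larger size first, then byte-lexicographically smallest member). Columns:
#' rank, score, size, local modularity (the string `"inf"` when the cluster
#' has no outgoing edges), density, and the semicolon-joined, sorted member
#' list. Comment lines (`#`) record the parameters that produced the
#' clustering, so every report carries its own provenance.
#'
#' @param clusters a [run_mine()] result or a list of `mine_cluster` objects.
#' @param path output file path.
#' @param comments optional extra comment lines (without the leading `#`).
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path, comments = character(0)) {
  params <- NULL
  if (inherits(clusters, "mine_result")) {
    params <- clusters$params
    clusters <- clusters$clusters
  }
  header <- c(
    sprintf("# mineclust %s cluster report",
            as.character(utils::packageVersion("mineclust"))),
    if (!is.null(params)) {
      sprintf("# parameters: vwp=%g msp=%g mp=%g trim=%s min_size=%d",
              params$vwp, params$msp, params$mp,
              tolower(as.character(params$trim)), params$min_size)
    },
    if (length(comments)) paste0("# ", comments)
  )
  rows <- "rank\tscore\tsize\tlocal_modularity\tdensity\tmembers"
  if (length(clusters)) {
    clusters <- sort_clusters(clusters)
    rows <- c(rows, vapply(seq_along(clusters), function(i) {
      cl <- clusters[[i]]
      mod <- if (is.infinite(cl$local_modularity)) "inf" else
        format(cl$local_modularity, digits = 10)
      paste(i, format(cl$score, digits = 10), cl$size, mod,
            format(cl$density, digits = 10),
            paste(cl$members, collapse = ";"), sep = "\t")
    }, character(1)))
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read member lists from a cluster report
#'
#' Reads the format written by [write_clusters()] (comment lines ignored) and
#' returns just the member sets, so evaluation can run on clusters produced
#' by any tool writing that format.
#'
#' @param path cluster report path.
#' @return list of character vectors of members, in file order.
#' @export
read_clusters <- function(path) {
  if (!file.exists(path)) stop(sprintf("cluster file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(list())
  if (startsWith(lines[[1]], "rank\t")) lines <- lines[-1L]
  lapply(lines, function(line) {
    tok <- strsplit(line, "\t", fixed = TRUE)[[1]]
    sort_c(unique(strsplit(tok[[length(tok)]], ";", fixed = TRUE)[[1]]))
  })
}
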