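test_that("local modularity counts boundary and internal edges", {
  g <- two_k4()
  expect_equal(local_modularity(g, paste0("a", 1:4)), 6 / 1)
  # whole connected graph: E_out = 0 -> +Inf sentinel
  expect_equal(local_modularity(g, c(paste0("a", 1:4), paste0("b", 1:4))), Inf)
  # singleton: E_in = 0 -> 0
  expect_equal(local_modularity(g, "a2"), 0)
  expect_error(local_modularity(g, "zz"), "not in graph")

  # two triangles joined by one bridge, members = one triangle -> 3
  g2 <- graph_chr(c(clique_chr(c("p", "q", "r")), clique_chr(c("x", "y", "z")),
                    "p", "x"))
  expect_equal(local_modularity(g2, c("p", "q", "r")), 3)
})

test_that("cluster score is density times size", {
  k4 <- graph_chr(clique_chr(paste0("a", 1:4)))
  expect_equal(score_cluster(k4, paste0("a", 1:4)), 4)
  path <- graph_chr(c("a", "b", "b", "c"))
  expect_equal(score_cluster(path, c("a", "b", "c")), 2)
  expect_equal(score_cluster(path, "a"), 0)
})

test_that("growth stops at the bridge between two dense cliques", {
  g <- two_k4()
  cl <- grow_cluster(g, "a2", mine_params(vwp = 1, msp = 0, trim = FALSE))
  expect_equal(cl$members, paste0("a", 1:4))
  expect_equal(cl$e_in, 6)
  expect_equal(cl$e_out, 1)
  expect_equal(cl$local_modularity, 6)
  expect_equal(cl$score, 4)
})

test_that("an isolated triangle grows to the whole component with inf modularity", {
  g <- graph_chr(clique_chr(c("a", "b", "c")), isolated = "w")
  cl <- grow_cluster(g, "a", mine_params(vwp = 1, msp = 0, trim = FALSE))
  expect_equal(cl$members, c("a", "b", "c"))
  expect_equal(cl$local_modularity, Inf)
})

test_that("a complete clique is fully admitted even with vwp = 0", {
  g <- graph_chr(clique_chr(paste0("k", 1:4)))
  cl <- grow_cluster(g, "k1", mine_params(vwp = 0, msp = 0, trim = FALSE))
  expect_equal(cl$members, paste0("k", 1:4))
})

test_that("trim removes weakly attached members in one simultaneous pass", {
  g <- graph_chr(c(clique_chr(c("a", "b", "c")), "a", "d"))
  expect_equal(trim_cluster(g, c("a", "b", "c", "d"))$members, c("a", "b", "c"))

  # path cluster loses both ends at once (not sequentially)
  p <- graph_chr(c("a", "b", "b", "c"))
  expect_equal(trim_cluster(p, c("a", "b", "c"))$members, "b")

  k4 <- graph_chr(clique_chr(paste0("a", 1:4)))
  expect_equal(trim_cluster(k4, paste0("a", 1:4))$size, 4)
})

test_that("merging unions into the first sufficiently overlapping cluster", {
  g <- rand_gnp(8, 0.5)
  nodes <- igraph::V(g)$name
  ex <- list(nodes[1:4])
  # identical candidate merges, list length unchanged
  out <- maybe_merge(g, ex, nodes[1:4], mp = 0.5)
  expect_length(out, 1)
  expect_equal(out[[1]]$members, sort(nodes[1:4]))
  # disjoint candidate appends
  out <- maybe_merge(g, ex, nodes[5:8], mp = 0.5)
  expect_length(out, 2)
  # overlap 2/4 = 0.5 >= mp -> union
  out <- maybe_merge(g, ex, nodes[3:6], mp = 0.5)
  expect_length(out, 1)
  expect_equal(out[[1]]$members, sort(nodes[1:6]))
  # same overlap below threshold -> append
  out <- maybe_merge(g, ex, nodes[3:6], mp = 0.51)
  expect_length(out, 2)
})

test_that("run_mine recovers a ring of cliques exactly", {
  b <- ring_of_cliques(5, 6, n_noise_edges = 0, seed = 1)
  res <- run_mine(b$graph, mine_params(vwp = 1, msp = 0, trim = FALSE))
  expect_length(res$clusters, 5)
  for (cl in res$clusters) {
    expect_equal(cl$size, 6)
    expect_equal(cl$density, 1)
    expect_equal(cl$e_in, 15)
    expect_equal(cl$e_out, 2)
    expect_equal(cl$local_modularity, 7.5)
  }
  got <- lapply(res$clusters, function(cl) cl$members)
  expect_setequal(got, unname(b$truth$sets))
})

test_that("degenerate inputs: edgeless graphs and size filtering", {
  g0 <- graph_chr(isolated = paste0("n", 1:6))
  expect_length(run_mine(g0, mine_params())$clusters, 0)

  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_length(run_mine(empty, mine_params())$clusters, 0)

  # K3 plus isolated nodes: one cluster, isolated nodes remain unclustered
  g <- graph_chr(clique_chr(c("x", "y", "z")), isolated = paste0("i", 1:10))
  res <- run_mine(g, mine_params())
  expect_length(res$clusters, 1)
  expect_equal(res$clusters[[1]]$members, c("x", "y", "z"))

  # a single edge is always filtered (size 2 < min_size 3)
  g2 <- graph_chr(c("a", "b"))
  expect_length(run_mine(g2, mine_params(trim = FALSE))$clusters, 0)

  # min_size is respected
  res <- run_mine(g, mine_params(min_size = 4))
  expect_length(res$clusters, 0)
})

test_that("identical runs are byte-identical", {
  set.seed(33)
  g <- rand_gnp(40, 0.15)
  p <- mine_params(vwp = 0.7, msp = 0.2)
  t1 <- withr::local_tempfile()
  t2 <- withr::local_tempfile()
  write_clusters(run_mine(g, p), t1)
  write_clusters(run_mine(g, p), t2)
  expect_identical(readLines(t1), readLines(t2))
})

test_that("clustering is non-exclusive: distinct output clusters can share nodes", {
  # with mp = 1 only (near-)duplicates merge, so genuinely distinct clusters
  # that share boundary nodes survive side by side
  shared_pairs <- 0L
  pairs_checked <- 0L
  for (i in 1:10) {
    g <- planted_partition(5, 7, 0.8, 0.03, seed = i)$graph
    res <- run_mine(g, mine_params(vwp = 0.5, msp = 0.1, mp = 1.0,
                                   trim = FALSE, min_size = 2))
    cl <- lapply(res$clusters, function(c) c$members)
    if (length(cl) < 2) next
    for (a in seq_along(cl)) {
      for (b in seq_along(cl)) {
        if (a >= b) next
        pairs_checked <- pairs_checked + 1L
        common <- length(intersect(cl[[a]], cl[[b]]))
        if (common > 0 && common < min(length(cl[[a]]), length(cl[[b]]))) {
          shared_pairs <- shared_pairs + 1L
        }
      }
    }
  }
  expect_gt(pairs_checked, 0L)
  expect_gt(shared_pairs, 0L)
})

test_that("raising mp toward 1 never decreases the number of clusters", {
  set.seed(55)
  for (i in 1:8) {
    g <- rand_gnp(20, 0.3)
    counts <- vapply(c(0.3, 0.5, 0.8, 1.0), function(mp) {
      length(run_mine(g, mine_params(vwp = 0.8, msp = 0.2, mp = mp))$clusters)
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("cluster statistics agree with the brute-force oracle", {
  set.seed(66)
  for (i in 1:10) {
    g <- rand_gnp(12, 0.35)
    res <- run_mine(g, mine_params(vwp = 0.9, msp = 0.3, min_size = 1))
    for (cl in res$clusters) {
      o <- oracle_cluster_stats(g, cl$members)
      expect_equal(cl$e_in, o$e_in)
      expect_equal(cl$e_out, o$e_out)
      expect_equal(cl$density, o$density)
      expect_equal(cl$local_modularity, o$modularity)
      expect_equal(cl$score, o$score)
    }
  }
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(mine_params(vwp = 1.5), "vwp")
  expect_error(mine_params(msp = -0.1), "msp")
  expect_error(mine_params(mp = 0), "mp")
  expect_error(mine_params(min_size = 0), "min_size")
  g <- two_k4()
  expect_error(grow_cluster(g, "nope", mine_params()), "not in graph")
})
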