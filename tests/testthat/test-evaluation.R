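test_that("hypergeometric p-values match closed forms and the enumeration oracle", {
  expect_equal(hypergeom_overlap_pvalue(10, 4, 3, 0), 1)
  expect_equal(hypergeom_overlap_pvalue(10, 4, 3, 3), 4 / 120, tolerance = 1e-12)
  expect_equal(hypergeom_overlap_pvalue(5, 5, 5, 5), 1)

  set.seed(9)
  for (i in 1:200) {
    population <- sample(2:12, 1)
    complex <- sample(1:population, 1)
    cluster <- sample(1:population, 1)
    overlap <- sample(0:min(complex, cluster), 1)
    expect_equal(
      hypergeom_overlap_pvalue(population, complex, cluster, overlap),
      oracle_hyper(population, complex, cluster, overlap),
      tolerance = 1e-12
    )
  }

  expect_error(hypergeom_overlap_pvalue(10, 4, 3, 4), "bounds")
  expect_error(hypergeom_overlap_pvalue(10, 11, 3, 1), "bounds")
})

test_that("p-value is non-increasing in overlap", {
  for (population in c(8, 12)) {
    for (complex in c(3, 5)) {
      for (cluster in c(2, 6)) {
        ps <- vapply(0:min(complex, cluster), function(k) {
          hypergeom_overlap_pvalue(population, complex, cluster, k)
        }, numeric(1))
        expect_true(all(diff(ps) <= 1e-12))
      }
    }
  }
})

test_that("geometric accuracy is the geometric mean, symmetric and bounded", {
  expect_equal(geometric_accuracy(1, 1), 1)
  expect_equal(geometric_accuracy(0, 0.7), 0)
  expect_equal(geometric_accuracy(0.5, 0.5), 0.5)
  set.seed(10)
  r <- runif(50)
  p <- runif(50)
  expect_equal(geometric_accuracy(r, p), geometric_accuracy(p, r))
  expect_true(all(geometric_accuracy(r, p) <= pmax(r, p) + 1e-12))
  expect_error(geometric_accuracy(1.2, 0.5), "\\[0, 1\\]")
})

test_that("complex matching restricts to network members and applies alpha", {
  # network misses complex member D; cluster {A,B,X}: TP=2, FN=1, FP=1
  g <- graph_chr(c("A", "B", "B", "C", "C", "X", "X", "A"), isolated = "Y")
  an <- annotation_set(list(cpx = c("A", "B", "C", "D"),
                            ghost = c("g1", "g2", "g3")))
  m <- match_complexes(list(c("A", "B", "X")), an, g, alpha = 1)
  expect_equal(nrow(m), 1)  # ghost has no member in the network
  expect_equal(attr(m, "excluded"), "ghost")
  expect_equal(m$complex_size, 3)
  expect_equal(m$overlap, 2)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$geometric_accuracy, 2 / 3)

  # with a strict alpha the same overlap is not significant
  m2 <- match_complexes(list(c("A", "B", "X")), an, g, alpha = 0.05)
  expect_true(is.na(m2$best_cluster))
  expect_true(is.na(m2$recall))
})

test_that("a cluster identical to a complex gives recall = precision = 1", {
  b <- ring_of_cliques(3, 5, n_noise_edges = 0, seed = 2)
  cl <- unname(b$truth$sets)
  m <- match_complexes(cl, b$truth, b$graph, alpha = 0.05)
  expect_equal(m$recall, rep(1, 3))
  expect_equal(m$precision, rep(1, 3))
  expect_equal(m$best_cluster, seq_len(3))
})

test_that("a complex sharing no member with any cluster stays unmatched", {
  g <- graph_chr(c(clique_chr(c("a", "b", "c")), clique_chr(c("x", "y", "z"))))
  an <- annotation_set(list(far = c("x", "y", "z")))
  m <- match_complexes(list(c("a", "b", "c")), an, g, alpha = 0.05)
  expect_true(is.na(m$best_cluster))
  s <- evaluation_summary(m, list(c("a", "b", "c")), g)
  expect_true(is.nan(s$mean_recall))
  s0 <- evaluation_summary(m, list(c("a", "b", "c")), g, include_unmatched = TRUE)
  expect_equal(s0$mean_recall, 0)
})

test_that("tie-breaking prefers larger overlap then smaller cluster", {
  g <- graph_chr(clique_chr(sprintf("n%d", 1:6)))
  an <- annotation_set(list(S = c("n1", "n2", "n3")))
  # both clusters contain the complex; the smaller one wins on equal p only
  # if p ties; build an exact tie: same size, same overlap -> lower index
  m <- match_complexes(list(c("n1", "n2", "n4"), c("n1", "n2", "n5")),
                       an, g, alpha = 1)
  expect_equal(m$best_cluster, 1)
  # larger overlap has smaller p-value and wins regardless of order
  m2 <- match_complexes(list(c("n1", "n4", "n5"), c("n1", "n2", "n6")),
                        an, g, alpha = 1)
  expect_equal(m2$best_cluster, 2)
})

test_that("global modularity matches hand computations", {
  g <- two_k4()
  expect_equal(global_modularity(g, list(paste0("a", 1:4), paste0("b", 1:4))),
               2 * (6 / 13 - (13 / 26)^2), tolerance = 1e-12)
  # entire connected graph as one cluster -> exactly 0
  expect_equal(global_modularity(g, list(igraph::V(g)$name)), 0)
  expect_equal(global_modularity(g, list()), 0)
})

test_that("global modularity only counts clusters inside the main component", {
  # main component: two bridged K4s; satellite triangle is a separate component
  g <- graph_chr(c(clique_chr(paste0("a", 1:4)), clique_chr(paste0("b", 1:4)),
                   "a1", "b1", clique_chr(c("s1", "s2", "s3"))))
  q_main <- global_modularity(g, list(paste0("a", 1:4), paste0("b", 1:4)))
  q_with_sat <- global_modularity(g, list(paste0("a", 1:4), paste0("b", 1:4),
                                          c("s1", "s2", "s3")))
  expect_equal(q_with_sat, q_main)
})

test_that("network statistics: density and characteristic path length", {
  k4 <- graph_chr(clique_chr(paste0("a", 1:4)))
  st <- network_stats(k4)
  expect_equal(st$density, 1)
  expect_equal(st$characteristic_path_length, 1)

  path <- graph_chr(c("a", "b", "b", "c"))
  st <- network_stats(path)
  expect_equal(st$density, 2 / 3)
  expect_equal(st$characteristic_path_length, 4 / 3)

  # disconnected pairs are excluded
  two_edges <- graph_chr(c("a", "b", "c", "d"))
  st <- network_stats(two_edges)
  expect_equal(st$density, 2 / 6)
  expect_equal(st$characteristic_path_length, 1)

  st <- network_stats(graph_chr(isolated = "solo"))
  expect_equal(st$density, 0)
  expect_true(is.nan(st$characteristic_path_length))

  # random graphs agree with the exhaustive BFS oracle
  set.seed(12)
  for (i in 1:5) {
    g <- rand_gnp(sample(4:10, 1), runif(1, 0.2, 0.6))
    if (igraph::ecount(g) == 0) next
    expect_equal(network_stats(g)$characteristic_path_length, oracle_cpl(g))
  }
})
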