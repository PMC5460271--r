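wmat <- function(n, edges) {
  w <- matrix(NA_real_, n, n)
  for (e in edges) w[e[1], e[2]] <- w[e[2], e[1]] <- e[3]
  w
}

test_that("closed-form fixtures: path, cycle, star, complete graphs", {
  # 3-node path a-b-c, unit weights
  p3 <- shortest_paths_all(wmat(3, list(c(1, 2, 1), c(2, 3, 1))))
  expect_equal(p3$d[1, 3], 2)
  expect_equal(p3$sigma[1, 3], 1)
  cl <- closeness_centrality(p3)
  expect_equal(unname(cl), c(2 / 3, 1, 2 / 3))
  expect_equal(cpl(p3), 4 / 3)

  # two nodes joined by weight w: closeness 1/w on both
  p2 <- shortest_paths_all(wmat(2, list(c(1, 2, 0.4))))
  expect_equal(unname(closeness_centrality(p2)), c(2.5, 2.5))

  # 4-cycle, unit weights: two equal shortest paths between opposite corners
  p4 <- shortest_paths_all(wmat(4, list(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1),
                                        c(4, 1, 1))))
  expect_equal(p4$d[1, 3], 2)
  expect_equal(p4$sigma[1, 3], 2)

  # 5-node star: centre betweenness C(4,2) = 6, leaves 0
  star <- wmat(5, lapply(2:5, function(i) c(1, i, 1)))
  bs <- betweenness_centrality(shortest_paths_all(star))
  expect_equal(unname(bs), c(6, 0, 0, 0, 0))

  # complete graphs: all betweenness 0, CPL 1, K4 DPL identically 0
  k4 <- wmat(4, list(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1), c(2, 3, 1),
                     c(2, 4, 1), c(3, 4, 1)))
  pk <- shortest_paths_all(k4)
  expect_equal(unname(betweenness_centrality(pk)), rep(0, 4))
  expect_equal(cpl(pk), 1)
  expect_equal(dpl(k4)$dpl, rep(0, 4))

  # removing an end node of the 3-path: CPL 4/3 -> 1
  expect_equal(dpl(wmat(3, list(c(1, 2, 1), c(2, 3, 1))))$dpl[1], -1 / 3)
})

test_that("all metrics agree with exhaustive path enumeration on random
           graphs", {
  set.seed(100)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    w <- random_graph(n)
    bf <- bf_all_paths(w)
    p <- shortest_paths_all(w)
    expect_equal(p$d, bf$d, tolerance = 1e-12)
    expect_equal(p$sigma, bf$sigma)
    expect_equal(unname(closeness_centrality(p)), bf_closeness(bf),
                 tolerance = 1e-12)
    expect_equal(unname(betweenness_centrality(p)), bf_betweenness(bf))
    expect_equal(cpl(p), bf_cpl(bf), tolerance = 1e-12)
    expect_equal(dpl(w)$dpl, bf_dpl(w), tolerance = 1e-12)
    # cross-algorithm check against an independent library implementation
    g <- igraph::graph_from_adjacency_matrix(
      ifelse(is.na(w), 0, w), mode = "undirected", weighted = TRUE)
    expect_equal(p$d, unname(igraph::distances(g)), tolerance = 1e-12)
  }
})

test_that("negative weights are rejected", {
  expect_error(shortest_paths_all(wmat(2, list(c(1, 2, -0.1)))), "negative")
})

test_that("closeness scales inversely with uniform weight scaling", {
  set.seed(7)
  w <- random_graph(7)
  c1 <- closeness_centrality(shortest_paths_all(w))
  c3 <- closeness_centrality(shortest_paths_all(3 * w))
  expect_equal(c3, c1 / 3, tolerance = 1e-12)
  # betweenness and DPL *rankings* are invariant to the scale (log base)
  p1 <- betweenness_centrality(shortest_paths_all(w))
  p3 <- betweenness_centrality(shortest_paths_all(3 * w))
  expect_equal(order(p1), order(p3))
  expect_equal(order(dpl(w)$dpl), order(dpl(3 * w)$dpl))
})

test_that("disconnected graphs: closeness per component, unreachable pairs
           dropped from CPL, disconnection flagged in DPL", {
  w <- wmat(5, list(c(1, 2, 1), c(2, 3, 1), c(4, 5, 2)))
  p <- shortest_paths_all(w)
  expect_false(p$reachable[1, 4])
  expect_equal(p$sigma[1, 4], 0)
  cl <- closeness_centrality(p)
  expect_equal(unname(cl)[4], 1 / 2)       # (2-1)/2 within its component
  expect_equal(cpl(p), mean(c(1, 1, 2, 2)))
  d <- dpl(w)
  expect_true(d$disconnects[2])            # removing the middle splits 1|3
  expect_false(d$disconnects[1])
})

test_that("z-score flags behave at the boundaries", {
  expect_warning(z0 <- zscore_flags(c(a = 1, b = 1, c = 1)), "zero standard")
  expect_equal(z0$z, rep(0, 3))
  expect_false(any(z0$flagged))
  z <- zscore_flags(c(0, 0, 0, 10), cutoff = 1.5)
  expect_equal(z$flagged, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(mean(z$z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z$z^2)), 1, tolerance = 1e-12)  # population sd
  expect_error(zscore_flags(1), "at least 2")
})

test_that("closeness tiers split 20/40/40 with ties sharing the better
           tier", {
  v <- setNames(10:1, letters[1:10])
  t10 <- closeness_tiers(v)
  expect_equal(sum(t10 == "high"), 2L)
  expect_equal(sum(t10 == "intermediate"), 4L)
  expect_equal(unname(t10[c("a", "b", "c")]),
               c("high", "high", "intermediate"))
  set.seed(9)
  t100 <- closeness_tiers(runif(100))
  expect_equal(as.integer(table(factor(t100, c("high", "intermediate",
                                               "low")))), c(20L, 40L, 40L))
  expect_warning(tied <- closeness_tiers(rep(1, 6)), "equal")
  expect_true(all(tied == "high"))
  expect_error(closeness_tiers(1:4), "at least 5")
})

test_that("a planted hub is flagged at z > 1.5", {
  # every shortest path between the 6 satellites runs through the hub
  edges <- lapply(2:7, function(i) c(1, i, 1))
  w <- wmat(7, edges)
  b <- betweenness_centrality(shortest_paths_all(w))
  z <- zscore_flags(b, cutoff = 1.5)
  expect_equal(which(z$flagged), 1L)
})
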