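test_that("graph distances follow hops, shortcuts and the surrogate rule", {
  abc <- path_network(c("a", "b", "c"))
  d <- graph_distances(abc)
  expect_equal(d["a", "c"], 2)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))

  d2 <- graph_distances(abc, data.frame(a = "a", b = "c", weight = 1))
  expect_equal(d2["a", "c"], 1)

  # disconnected pair: 1.5 x finite diameter
  split <- network(c("a", "b", "c", "d"), rbind(c("a", "b"), c("c", "d")))
  d3 <- graph_distances(split)
  expect_equal(d3["a", "c"], 1.5)
})

test_that("distances equal a Floyd-Warshall oracle on random 12-node graphs", {
  for (seed in 1:3) {
    fx <- generate_annotated_graph(12, edges = 0.15, n_groups = 0,
                                   overlap_fraction = 0, seed = seed)
    extra <- data.frame(a = fx$network$nodes[1], b = fx$network$nodes[12],
                        weight = 0.5)
    expect_equal(graph_distances(fx$network), fw_distances(fx$network))
    expect_equal(graph_distances(fx$network, extra),
                 fw_distances(fx$network, extra))
  }
})

test_that("spanning graphs are minimum trees with deterministic ties", {
  net <- path_network(letters[1:10])
  d <- graph_distances(net)

  single <- spanning_graph(net, group("g", "c"), d)
  expect_equal(nrow(single$links), 0)

  pair <- spanning_graph(net, group("g", c("b", "e")), d)
  expect_equal(nrow(pair$links), 1)
  expect_equal(pair$links$weight, 3)

  # tie-break: equally distant options resolve lexicographically, twice alike
  tie <- network(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  sg1 <- spanning_graph(tie, group("g", c("a", "b", "c")),
                        graph_distances(tie))
  sg2 <- spanning_graph(tie, group("g", c("c", "b", "a")),
                        graph_distances(tie))
  expect_identical(sg1$links, sg2$links)
})

test_that("tree weight matches exhaustive enumeration on 5-member sets", {
  for (seed in c(4, 8, 15)) {
    fx <- generate_annotated_graph(10, edges = 0.2, n_groups = 0,
                                   overlap_fraction = 0, seed = seed)
    d <- graph_distances(fx$network)
    members <- fx$network$nodes[c(1, 3, 5, 7, 9)]
    sg <- spanning_graph(fx$network, group("g", members), d)
    expect_equal(nrow(sg$links), 4)
    expect_equal(sum(sg$links$weight), brute_mst_weight(members, d))
    # links form a connected acyclic graph on the members
    g <- igraph::graph_from_data_frame(sg$links[, c("a", "b")],
                                       directed = FALSE,
                                       vertices = sg$vertices)
    expect_true(igraph::is_connected(g))
  }
})

test_that("stress matches closed forms and a naive double loop", {
  d <- matrix(c(0, 1, 1, 0), 2)
  w <- stress_weights(d)
  at_target <- rbind(c(0, 0), c(1, 0))
  expect_equal(stress(at_target, d, w), 0)
  coincident <- rbind(c(0, 0), c(0, 0))
  expect_equal(stress(coincident, d, w), 1)

  set.seed(99)
  fx <- generate_annotated_graph(6, edges = 0.3, n_groups = 0,
                                 overlap_fraction = 0, seed = 6)
  d6 <- graph_distances(fx$network)
  w6 <- stress_weights(d6)
  pos <- matrix(rnorm(12), 6, 2)
  expect_equal(stress(pos, d6, w6), naive_stress(pos, d6, w6))
})

test_that("layout places a single node at the origin", {
  lay <- compute_layout(network("solo"), seed = 1)
  expect_equal(unname(lay$positions["solo", ]), c(0, 0))
})

test_that("two connected nodes settle within 1% of the target distance", {
  net <- network(c("a", "b"), rbind(c("a", "b")))
  params <- layout_params()
  lay <- compute_layout(net, seed = 2, params = params)
  gap <- sqrt(sum((lay$positions["a", ] - lay$positions["b", ])^2))
  expect_lt(abs(gap - params$edge_length) / params$edge_length, 0.01)
})

test_that("stress never increases across majorization iterations", {
  for (seed in 1:4) {
    fx <- generate_annotated_graph(18, edges = 0.1, n_groups = 3,
                                   overlap_fraction = 0.2, seed = seed)
    sys <- generate_groups(fx$network, fx$table, "Community",
                           use_all_nodes = TRUE)
    sys <- select_groups(sys, names(sys$groups)[1])
    lay <- compute_layout(fx$network, sys, seed = seed)
    trace <- attr(lay, "stress_trace")
    expect_true(all(diff(trace) <= 1e-9))
  }
})

test_that("identical seed and inputs give bit-identical positions", {
  fx <- generate_annotated_graph(16, edges = 0.1, n_groups = 3,
                                 overlap_fraction = 0.2, seed = 5)
  sys <- generate_groups(fx$network, fx$table, "Community",
                         use_all_nodes = TRUE)
  a <- compute_layout(fx$network, sys, seed = 13)
  b <- compute_layout(fx$network, sys, seed = 13)
  expect_identical(a$positions, b$positions)
  c <- compute_layout(fx$network, sys, seed = 14)
  expect_false(identical(a$positions, c$positions))
})

test_that("selecting a set pulls its members closer together", {
  wins <- 0L
  for (seed in 1:5) {
    fx <- generate_annotated_graph(20, edges = 0.08, n_groups = 4,
                                   overlap_fraction = 0.2, seed = seed)
    sys <- generate_groups(fx$network, fx$table, "Community",
                           use_all_nodes = TRUE)
    gid <- names(sys$groups)[which.max(vapply(sys$groups, function(g)
      length(g$members), 0L))]
    members <- sys$groups[[gid]]$members
    mean_dist <- function(lay) {
      p <- lay$positions[members, , drop = FALSE]
      mean(dist(p))
    }
    off <- compute_layout(fx$network, sys, seed = seed)
    on <- compute_layout(fx$network, select_groups(sys, gid), seed = seed)
    if (mean_dist(on) <= mean_dist(off)) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("coincident equal rectangles separate exactly along x", {
  pos <- matrix(0, 2, 2, dimnames = list(c("a", "b"), NULL))
  he <- matrix(rep(c(10, 5), each = 2), 2, 2,
               dimnames = list(c("a", "b"), NULL))
  out <- remove_overlaps(layout_result(pos, he), padding = 2)
  expect_equal(unname(out$positions["b", 1] - out$positions["a", 1]), 22,
               tolerance = 1e-6)
  expect_equal(unname(out$positions[, 2]), c(0, 0))
})

test_that("non-overlapping layouts are a fixed point of overlap removal", {
  pos <- rbind(a = c(0, 0), b = c(100, 0), c = c(0, 100))
  he <- matrix(9, 3, 2, dimnames = list(c("a", "b", "c"), NULL))
  lay <- layout_result(pos, he)
  expect_identical(remove_overlaps(lay)$positions, pos)
})

test_that("a crowded layout becomes overlap-free (exhaustive pair check)", {
  set.seed(20)
  ids <- sprintf("n%02d", 1:20)
  pos <- matrix(runif(40, 0, 60), 20, 2, dimnames = list(ids, NULL))
  he <- glyph_half_extents(setNames(ids, ids))
  out <- remove_overlaps(layout_result(pos, he), padding = 2)
  expect_true(out$converged)
  expect_equal(oracle_overlap_pairs(out, padding = 2), 0L)
  expect_equal(count_overlaps(out, padding = 2), 0L)
})
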