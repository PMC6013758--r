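point_layout <- function(coords, glyph = 1e-3) {
  ids <- rownames(coords)
  he <- matrix(glyph, nrow(coords), 2, dimnames = list(ids, NULL))
  layout_result(coords, he, seed = 1)
}

bare_spanning <- function(vertices, links = NULL) {
  if (is.null(links))
    links <- data.frame(a = character(0), b = character(0),
                        weight = numeric(0))
  structure(list(group_id = "g", vertices = vertices, links = links),
            class = "cg_spanning")
}

test_that("a single member yields a disc of radius r + circumradius", {
  lay <- point_layout(matrix(c(3, -2), 1, 2, dimnames = list("a", NULL)))
  cs <- contour_shape(bare_spanning("a"), lay, radius = 14)
  r <- 14 + sqrt(2) * 1e-3
  expect_length(cs$boundary, 1)
  expect_lt(abs(contour_area(cs) - pi * r^2) / (pi * r^2), 0.01)
  # >= 16 segments per full circle
  expect_gte(nrow(cs$boundary[[1]]), 17)
  expect_true(point_in_polygon(c(3, -2), cs$boundary))
})

test_that("two members produce a capsule of area 2rL + pi r^2", {
  L <- 100; r <- 14
  coords <- matrix(c(0, L, 0, 0), 2, 2, dimnames = list(c("a", "b"), NULL))
  lay <- point_layout(coords)
  sg <- bare_spanning(c("a", "b"), data.frame(a = "a", b = "b", weight = 1))
  cs <- contour_shape(sg, lay, radius = r)
  expected <- 2 * r * L + pi * r^2
  expect_lt(abs(contour_area(cs) - expected) / expected, 0.01)
  expect_length(cs$boundary, 1)
})

test_that("contours are closed, simple and contain every member center", {
  lf <- laid_out_fixture(seed = 21, n = 18, select = 2)
  spanning <- attr(lf$layout, "spanning")
  for (gid in lf$system$selection) {
    cs <- contour_shape(spanning[[gid]], lf$layout, radius = 14)
    for (ring in cs$boundary) {
      expect_identical(ring[1, ], ring[nrow(ring), ])
      expect_gte(nrow(ring), 4)
    }
    members <- lf$system$groups[[gid]]$members
    for (m in members) {
      center <- lf$layout$positions[m, ]
      expect_true(point_in_polygon(center, cs$boundary))
      expect_true(oracle_inside(center, cs$boundary))   # independent oracle
    }
    # package ray caster agrees with mgcv on a probe grid
    rng <- apply(do.call(rbind, cs$boundary), 2, range)
    probes <- cbind(seq(rng[1, 1] - 10, rng[2, 1] + 10, length.out = 7),
                    seq(rng[1, 2] - 10, rng[2, 2] + 10, length.out = 7))
    for (i in seq_len(nrow(probes)))
      expect_identical(point_in_polygon(probes[i, ], cs$boundary),
                       oracle_inside(probes[i, ], cs$boundary))
  }
})

test_that("far non-members lie outside the contour", {
  lf <- laid_out_fixture(seed = 33, n = 20, select = 1)
  gid <- lf$system$selection[1]
  sg <- attr(lf$layout, "spanning")[[gid]]
  radius <- 14
  cs <- contour_shape(sg, lf$layout, radius = radius)
  members <- lf$system$groups[[gid]]$members
  P <- lf$layout$positions
  circum <- sqrt(rowSums(lf$layout$half_extents^2))
  for (n in setdiff(rownames(P), members)) {
    # distance from the node center to every member disc and link band
    dmin <- min(vapply(members, function(m)
      sqrt(sum((P[n, ] - P[m, ])^2)) - circum[m], 0))
    if (nrow(sg$links)) {
      seg <- vapply(seq_len(nrow(sg$links)), function(k) {
        a <- P[sg$links$a[k], ]; b <- P[sg$links$b[k], ]
        v <- b - a; t <- sum((P[n, ] - a) * v) / sum(v^2)
        t <- min(1, max(0, t))
        sqrt(sum((P[n, ] - (a + t * v))^2))
      }, 0)
      dmin <- min(dmin, seg)
    }
    if (dmin > radius + circum[n])
      expect_false(point_in_polygon(P[n, ], cs$boundary))
  }
})

test_that("scenes stack large sets below small ones with stable colors", {
  fx <- generate_annotated_graph(34, edges = 78, n_groups = 6,
                                 overlap_fraction = 0.2, seed = 1)
  sys <- generate_groups(fx$network, fx$table, "Community",
                         use_all_nodes = TRUE)
  sys <- select_groups(sys, LETTERS[1:6])
  lay <- compute_layout(fx$network, sys, seed = 2)
  scene <- build_scene(fx$network, sys, lay,
                       cg_settings(label_column = "label"),
                       table = fx$table)
  expect_length(scene$contours, 6)
  expect_length(scene$glyphs, 34)
  sizes <- vapply(names(scene$contours), function(g)
    length(sys$groups[[g]]$members), 0L)
  expect_true(all(diff(sizes) <= 0))    # painted biggest-first
  # color by selection order, reproducibly
  scene2 <- build_scene(fx$network, sys, lay,
                        cg_settings(label_column = "label"),
                        table = fx$table)
  for (gid in names(scene$contours))
    expect_identical(scene$contours[[gid]]$fill, scene2$contours[[gid]]$fill)
  expect_identical(scene$contours[[LETTERS[1]]]$fill, contour_color(1))
})

test_that("two selected groups of sizes 5 and 3 paint the larger one first", {
  net <- path_network(letters[1:8])
  sys <- set_system(list(group("big", letters[1:5]),
                         group("small", letters[6:8])),
                    selection = c("small", "big"))
  lay <- compute_layout(net, sys, seed = 4)
  scene <- build_scene(net, sys, lay)
  expect_identical(names(scene$contours), c("big", "small"))
  # but colors still follow selection order
  expect_identical(scene$contours$small$fill, contour_color(1))
  expect_identical(scene$contours$big$fill, contour_color(2))
})

test_that("empty selections render contour-free scenes", {
  lf <- laid_out_fixture(seed = 3, select = 0)
  scene <- build_scene(lf$fixture$network, lf$system, lf$layout)
  expect_length(scene$contours, 0)
  expect_length(scene$group_labels, 0)
})

test_that("a missing label column falls back to node ids with a warning", {
  lf <- laid_out_fixture(seed = 3, select = 0)
  expect_warning(
    scene <- build_scene(lf$fixture$network, lf$system, lf$layout,
                         cg_settings(label_column = "Nope"),
                         table = lf$fixture$table),
    "label column")
  expect_identical(scene$glyphs[[1]]$label, lf$fixture$network$nodes[1])
})
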