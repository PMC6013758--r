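#' @title Distance-preserving layout with set attraction
#' @name layout
#' @description
#' The layout pipeline: all-pairs graph-theoretic target distances, optional
#' virtual links from each selected group's spanning graph (scaled by an
#' attraction factor, pulling members together), stress majorization from a
#' seeded random start, and finally glyph overlap removal.
NULL

#' Layout parameters
#'
#' @param alpha spanning-link attraction factor in (0,1]: a spanning link of
#'   graph distance d is injected with weight `alpha * d`, shortening paths
#'   between group members.  Default 0.7.
#' @param edge_length layout units per hop; sets the drawing scale relative
#'   to glyph sizes.  Default 100.
#' @param weight_exponent exponent q of the stress weights w = d^q.
#'   Default -2 (emphasises local distances).
#' @param max_iter majorization iteration cap.  Default 300.
#' @param tol relative stress-change convergence threshold.  Default 1e-6.
#' @param padding minimum gap between node glyph rectangles, layout units.
#'   Default 2.
#' @param max_sweeps overlap-removal sweep cap.  Default 200.
#' @export
layout_params <- function(alpha = 0.7, edge_length = 100,
                          weight_exponent = -2, max_iter = 300L,
                          tol = 1e-6, padding = 2, max_sweeps = 200L) {
  stopifnot(alpha > 0, alpha <= 1, edge_length > 0, max_iter >= 1, tol > 0)
  list(alpha = alpha, edge_length = edge_length,
       weight_exponent = weight_exponent, max_iter = as.integer(max_iter),
       tol = tol, padding = padding, max_sweeps = as.integer(max_sweeps))
}

#' All-pairs graph-theoretic target distances
#'
#' Shortest paths over the network's unit-weight edges plus any weighted
#' extra links (e.g. spanning-graph links).  Node pairs in different
#' components receive a surrogate distance of 1.5 x the finite diameter,
#' keeping components nearby but separate.
#'
#' @param net a [network()].
#' @param extra_links data.frame with columns `a`, `b`, `weight`, or `NULL`.
#' @return symmetric numeric matrix of distances in hop units, dimnames =
#'   node ids, zero diagonal, all entries finite.
#' @export
graph_distances <- function(net, extra_links = NULL) {
  ids <- net$nodes
  n <- length(ids)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  weights <- numeric(0)
  if (nrow(net$edges)) {
    ei <- rbind(match(net$edges[, 1], ids), match(net$edges[, 2], ids))
    g <- igraph::add_edges(g, as.vector(ei))
    weights <- rep(1, nrow(net$edges))
  }
  if (!is.null(extra_links) && NROW(extra_links)) {
    ei <- rbind(match(as.character(extra_links$a), ids),
                match(as.character(extra_links$b), ids))
    g <- igraph::add_edges(g, as.vector(ei))
    weights <- c(weights, as.numeric(extra_links$weight))
  }
  d <- if (length(weights)) igraph::distances(g, weights = weights)
       else igraph::distances(g)
  finite <- d[is.finite(d) & d > 0]
  surrogate <- if (length(finite)) 1.5 * max(finite) else 1
  d[!is.finite(d)] <- surrogate
  dimnames(d) <- list(ids, ids)
  d
}

#' Stress weights for a distance matrix
#'
#' w(u,v) = d(u,v)^q with zero diagonal.
#'
#' @param d distance matrix from [graph_distances()].
#' @param exponent q, default -2.
#' @export
stress_weights <- function(d, exponent = -2) {
  w <- d
  w[d > 0] <- d[d > 0]^exponent
  diag(w) <- 0
  w
}

#' Minimum spanning tree over a group's members
#'
#' Kruskal's algorithm on the complete graph over the members, weighted by
#' the base graph distances.  Ties are broken lexicographically on the
#' (sorted) endpoint pair, so the tree is fully deterministic.
#'
#' @param net a [network()] (members must belong to it).
#' @param grp a [group()].
#' @param base_distances matrix from [graph_distances()] on `net` alone.
#' @return object of class `cg_spanning` with `group_id`, `vertices`, and
#'   `links` (data.frame `a`, `b`, `weight`); a tree, so
#'   `nrow(links) == length(vertices) - 1`.
#' @export
spanning_graph <- function(net, grp, base_distances) {
  members <- sort(grp$members)
  m <- length(members)
  if (m == 1) {
    links <- data.frame(a = character(0), b = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  } else {
    pairs <- utils::combn(members, 2)
    wts <- base_distances[cbind(pairs[1, ], pairs[2, ])]
    ord <- order(wts, pairs[1, ], pairs[2, ])
    # union-find
    parent <- seq_len(m); names(parent) <- members
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    keep <- logical(length(ord)); taken <- 0L
    for (k in ord) {
      ra <- find(match(pairs[1, k], members))
      rb <- find(match(pairs[2, k], members))
      if (ra != rb) {
        parent[ra] <- rb
        keep[k] <- TRUE
        taken <- taken + 1L
        if (taken == m - 1L) break
      }
    }
    links <- data.frame(a = pairs[1, keep], b = pairs[2, keep],
                        weight = wts[keep], stringsAsFactors = FALSE)
  }
  structure(list(group_id = grp$id, vertices = members, links = links),
            class = "cg_spanning")
}

#' Stress of a placement against target distances
#'
#' Sum over unordered pairs of w(u,v) * (||p_u - p_v|| - d(u,v))^2.
#'
#' @param positions numeric n x 2 matrix, rows ordered as `d`.
#' @param d target distance matrix.
#' @param w weight matrix; default `stress_weights(d)`.
#' @export
stress <- function(positions, d, w = stress_weights(d)) {
  delta <- as.matrix(stats::dist(positions))
  sum(w[upper.tri(w)] * (delta[upper.tri(delta)] - d[upper.tri(d)])^2)
}

majorize <- function(positions, d, w, max_iter, tol) {
  n <- nrow(positions)
  trace <- stress(positions, d, w)
  wsum <- rowSums(w)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # Gauss-Seidel localized majorization: each node moves to the minimum of
    # its majorizing function given the others, so stress never increases.
    for (u in seq_len(n)) {
      if (wsum[u] == 0) next
      diff <- sweep(positions, 2, positions[u, ])
      dist_u <- sqrt(rowSums(diff^2))
      safe <- dist_u > 1e-12
      unit <- matrix(0, n, 2)
      unit[safe, ] <- -diff[safe, , drop = FALSE] / dist_u[safe]
      tgt <- positions + d[u, ] * unit       # others' preferred spot for u
      tgt[u, ] <- 0
      positions[u, ] <- colSums(w[u, ] * tgt) / wsum[u]
    }
    s <- stress(positions, d, w)
    trace <- c(trace, s)
    prev <- trace[length(trace) - 1]
    if (prev == 0 || abs(prev - s) / max(prev, .Machine$double.eps) < tol) {
      converged <- TRUE
      break
    }
  }
  list(positions = positions, trace = trace, converged = converged)
}

#' Glyph half-extents from label text
#'
#' Monospace approximation: width 7 units per character plus 10, height 18.
#'
#' @param labels character vector (named by node id if available).
#' @return n x 2 matrix of (half-width, half-height).
#' @export
glyph_half_extents <- function(labels) {
  he <- cbind((7 * nchar(labels) + 10) / 2, rep(9, length(labels)))
  rownames(he) <- names(labels)
  he
}

#' Compute the full layout for a network and its selected groups
#'
#' Pipeline: (1) base all-pairs distances; (2) a spanning graph per selected
#' group, its links injected as virtual links with weight `alpha * distance`;
#' (3) distances recomputed over the augmented graph and scaled to layout
#' units; (4) stress majorization from a seeded uniform-random start in a
#' `sqrt(n)`-side square; (5) glyph overlap removal.  Fully reproducible for
#' a fixed seed.
#'
#' @param net a [network()] with at least one node.
#' @param system a [set_system()] whose selection drives the attraction (may
#'   be `NULL` or empty).
#' @param seed integer RNG seed.
#' @param params a [layout_params()] list.
#' @param labels named character vector of node labels (sizes the glyphs);
#'   defaults to the node ids.
#' @return a [layout_result()]; attributes `stress_trace` (per-iteration
#'   stress values) and `spanning` (list of the spanning graphs used).
#' @export
compute_layout <- function(net, system = NULL, seed = 1L,
                           params = layout_params(), labels = NULL) {
  ids <- net$nodes
  n <- length(ids)
  if (n == 0) stop("cannot lay out an empty network")
  if (is.null(labels)) labels <- stats::setNames(ids, ids)
  labels <- labels[ids]
  labels[is.na(labels) | !nzchar(labels)] <- ids[is.na(labels) | !nzchar(labels)]
  names(labels) <- ids
  he <- glyph_half_extents(labels)

  base_d <- graph_distances(net)
  spanning <- list()
  extra <- NULL
  if (!is.null(system) && length(system$selection)) {
    links <- list()
    for (gid in system$selection) {
      sg <- spanning_graph(net, system$groups[[gid]], base_d)
      spanning[[gid]] <- sg
      if (nrow(sg$links))
        links[[gid]] <- data.frame(a = sg$links$a, b = sg$links$b,
                                   weight = params$alpha * sg$links$weight)
    }
    if (length(links)) extra <- do.call(rbind, links)
  }
  d <- graph_distances(net, extra) * params$edge_length
  w <- stress_weights(d, params$weight_exponent)

  if (n == 1) {
    pos <- matrix(0, 1, 2, dimnames = list(ids, NULL))
    lay <- layout_result(pos, he, seed = seed)
    attr(lay, "stress_trace") <- 0
    attr(lay, "spanning") <- spanning
    return(lay)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  pos <- matrix(stats::runif(2 * n), n, 2) * sqrt(n)
  rownames(pos) <- ids

  fit <- majorize(pos, d, w, params$max_iter, params$tol)
  pos <- fit$positions
  pos <- sweep(pos, 2, colMeans(pos))    # center on the origin
  rownames(pos) <- ids

  lay <- layout_result(pos, he, seed = seed, converged = fit$converged)
  lay <- remove_overlaps(lay, padding = params$padding,
                         max_sweeps = params$max_sweeps)
  attr(lay, "stress_trace") <- fit$trace
  attr(lay, "spanning") <- spanning
  lay
}

#' Displace node glyphs until no two label rectangles overlap
#'
#' Iterative pairwise separation: overlapping rectangle pairs are pushed
#' apart along the axis through their centers, each node moving half the
#' required distance; coincident centers separate along x.  Sweeps over all
#' pairs in input order until overlap-free or the sweep cap is reached
#' (then a warning is raised and the best-so-far layout is returned with its
#' `converged` flag unset).
#'
#' @param layout a [layout_result()].
#' @param padding minimum gap required between rectangles, layout units.
#' @param max_sweeps sweep cap.
#' @export
remove_overlaps <- function(layout, padding = 2, max_sweeps = 200L) {
  pos <- layout$positions
  he <- layout$half_extents
  n <- nrow(pos)
  eps <- 1e-9
  done <- n < 2
  sweeps <- 0L
  while (!done && sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    done <- TRUE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        X <- he[i, 1] + he[j, 1] + padding
        Y <- he[i, 2] + he[j, 2] + padding
        dx <- pos[j, 1] - pos[i, 1]
        dy <- pos[j, 2] - pos[i, 2]
        if (abs(dx) >= X || abs(dy) >= Y) next
        done <- FALSE
        len <- sqrt(dx * dx + dy * dy)
        if (len < 1e-12) { ux <- 1; uy <- 0 } else { ux <- dx / len; uy <- dy / len }
        tx <- if (abs(ux) > 1e-12) (X - abs(dx)) / abs(ux) else Inf
        ty <- if (abs(uy) > 1e-12) (Y - abs(dy)) / abs(uy) else Inf
        t <- min(tx, ty) + eps
        pos[i, 1] <- pos[i, 1] - ux * t / 2
        pos[i, 2] <- pos[i, 2] - uy * t / 2
        pos[j, 1] <- pos[j, 1] + ux * t / 2
        pos[j, 2] <- pos[j, 2] + uy * t / 2
      }
    }
  }
  if (!done)
    warning("overlap removal did not converge within ", max_sweeps, " sweeps")
  layout_result(pos, he, seed = layout$seed, converged = done)
}

#' Count overlapping glyph pairs in a layout
#'
#' Exhaustive rectangle-pair check, mainly for diagnostics and testing.
#'
#' @inheritParams remove_overlaps
#' @export
count_overlaps <- function(layout, padding = 2) {
  pos <- layout$positions; he <- layout$half_extents
  n <- nrow(pos); cnt <- 0L
  if (n < 2) return(0L)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (abs(pos[j, 1] - pos[i, 1]) < he[i, 1] + he[j, 1] + padding &&
          abs(pos[j, 2] - pos[i, 2]) < he[i, 2] + he[j, 2] + padding)
        cnt <- cnt + 1L
    }
  }
  cnt
}
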