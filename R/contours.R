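#' @title Rounded set contours and scene assembly
#' @name contours
#' @description
#' Each selected group's contour is the outline of the union of discs around
#' its member glyphs and rounded-end bands of half-width `radius` along its
#' spanning-graph links.  The outline is extracted as the zero level set of
#' the exact signed distance field of that union, sampled on a regular grid,
#' which yields smooth rounded corners and handles merging shapes without a
#' polygon-clipping dependency.
NULL

# Fixed qualitative palette, 12 distinct hues; assigned by selection order.
CONTOUR_PALETTE <- c(
  "#e41a1c", "#377eb8", "#4daf4a", "#984ea3", "#ff7f00", "#a65628",
  "#f781bf", "#1b9e77", "#66a61e", "#e6ab02", "#7570b3", "#666666")

#' Fill/outline color for the k-th selected group
#' @param k 1-based position in the selection order.
#' @export
contour_color <- function(k) {
  CONTOUR_PALETTE[(k - 1L) %% length(CONTOUR_PALETTE) + 1L]
}

dist_point <- function(gx, gy, p) sqrt((gx - p[1])^2 + (gy - p[2])^2)

dist_segment <- function(gx, gy, a, b) {
  vx <- b[1] - a[1]; vy <- b[2] - a[2]
  len2 <- vx * vx + vy * vy
  if (len2 < 1e-18) return(dist_point(gx, gy, a))
  t <- pmin(1, pmax(0, ((gx - a[1]) * vx + (gy - a[2]) * vy) / len2))
  sqrt((gx - (a[1] + t * vx))^2 + (gy - (a[2] + t * vy))^2)
}

#' Even-odd (ray casting) point-in-polygon test
#'
#' Works across multiple rings: a point inside an odd number of rings is
#' inside the region (so holes are respected).
#'
#' @param pt numeric length-2 point.
#' @param rings list of closed two-column coordinate matrices.
#' @export
point_in_polygon <- function(pt, rings) {
  inside <- FALSE
  for (ring in rings) {
    x <- ring[, 1]; y <- ring[, 2]
    n <- length(x)
    j <- n
    for (i in seq_len(n)) {
      if ((y[i] > pt[2]) != (y[j] > pt[2])) {
        xi <- x[j] + (pt[2] - y[j]) / (y[i] - y[j]) * (x[i] - x[j])
        if (pt[1] < xi) inside <- !inside
      }
      j <- i
    }
  }
  inside
}

shoelace <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

#' Area enclosed by a contour shape (holes subtracted)
#' @param shape a contour shape from [contour_shape()].
#' @export
contour_area <- function(shape) {
  rings <- shape$boundary
  total <- 0
  for (i in seq_along(rings)) {
    depth <- sum(vapply(seq_along(rings), function(j) {
      j != i && point_in_polygon(rings[[i]][1, ], rings[j])
    }, logical(1)))
    sgn <- if (depth %% 2 == 0) 1 else -1
    total <- total + sgn * abs(shoelace(rings[[i]]))
  }
  total
}

#' Rounded contour region for one spanning graph
#'
#' The region is the union of (a) a disc of radius `radius + glyph
#' circumradius` at every member position and (b) a band of half-width
#' `radius` with rounded ends along every spanning link.  Its outline is the
#' zero level set of the union's exact signed distance field, extracted with
#' [grDevices::contourLines()] on a grid fine enough to give well over 16
#' segments per full circle.
#'
#' @param spanning a [spanning_graph()].
#' @param layout a [layout_result()] covering every spanning vertex.
#' @param radius contour radius in layout units (> 0), default 14.
#' @param fill,outline colors; `opacity` contour fill opacity.
#' @param grid_step sampling step; default `radius / 10`.
#' @return object of class `cg_contour`: `group_id`, `boundary` (list of
#'   closed two-column matrices), `fill`, `opacity`, `outline`.
#' @export
contour_shape <- function(spanning, layout, radius = 14,
                          fill = CONTOUR_PALETTE[1], outline = fill,
                          opacity = 0.25, grid_step = radius / 10) {
  stopifnot(radius > 0)
  verts <- spanning$vertices
  missing <- setdiff(verts, rownames(layout$positions))
  if (length(missing))
    stop("no position for spanning vertices: ", paste(missing, collapse = ", "))
  P <- layout$positions[verts, , drop = FALSE]
  he <- layout$half_extents[verts, , drop = FALSE]
  circum <- sqrt(rowSums(he^2))
  disc_r <- radius + circum

  pad <- max(disc_r, radius) + 2 * grid_step
  xr <- range(P[, 1]) + c(-pad, pad)
  yr <- range(P[, 2]) + c(-pad, pad)
  gx <- seq(xr[1], xr[2], by = grid_step)
  gy <- seq(yr[1], yr[2], by = grid_step)
  gxm <- rep(gx, times = length(gy))
  gym <- rep(gy, each = length(gx))

  f <- rep(-Inf, length(gxm))
  for (i in seq_along(verts))
    f <- pmax(f, disc_r[i] - dist_point(gxm, gym, P[i, ]))
  if (nrow(spanning$links)) {
    for (k in seq_len(nrow(spanning$links))) {
      a <- P[spanning$links$a[k], ]
      b <- P[spanning$links$b[k], ]
      f <- pmax(f, radius - dist_segment(gxm, gym, a, b))
    }
  }
  z <- matrix(f, nrow = length(gx), ncol = length(gy))
  cl <- grDevices::contourLines(gx, gy, z, levels = 0)
  if (!length(cl)) stop("degenerate contour geometry for group '",
                        spanning$group_id, "'")
  boundary <- lapply(cl, function(l) {
    m <- cbind(l$x, l$y)
    if (!isTRUE(all.equal(m[1, ], m[nrow(m), ]))) m <- rbind(m, m[1, ])
    m
  })
  structure(list(group_id = spanning$group_id, boundary = boundary,
                 fill = fill, opacity = opacity, outline = outline),
            class = "cg_contour")
}

#' Assemble the drawing list for a rendered scene
#'
#' Drawing order: contours sorted largest member count first (so small sets
#' paint above large ones), then edges, then node glyphs with labels, then
#' group labels (with score badges when `show_score` is on).  Each selected
#' group's color comes from the fixed palette, indexed by selection order.
#' Node labels come from the settings' label column, falling back to node
#' ids with a warning when the column is missing.
#'
#' @param net a [network()].
#' @param system a [set_system()]; its selection is rendered.
#' @param layout a [layout_result()] covering every node (typically from
#'   [compute_layout()] run with the same selection, so its cached spanning
#'   graphs are reused).
#' @param settings a [cg_settings()].
#' @param table optional [node_table()] providing label/URL columns.
#' @param radius contour radius, layout units.
#' @return object of class `cg_scene`.
#' @export
build_scene <- function(net, system = NULL, layout, settings = cg_settings(),
                        table = NULL, radius = 14) {
  ids <- net$nodes
  missing <- setdiff(ids, rownames(layout$positions))
  if (length(missing))
    stop("layout lacks positions for: ", paste(missing, collapse = ", "))

  col_values <- function(column) {
    if (is.null(table) || is.null(column) ||
        !column %in% names(table$columns)) return(NULL)
    v <- table$columns[[column]]$values
    stats::setNames(as.character(unlist(lapply(v, `[`, 1))), table$keys)[ids]
  }
  labels <- col_values(settings$label_column)
  if (is.null(labels)) {
    if (!is.null(settings$label_column))
      warning("label column '", settings$label_column,
              "' not found; using node ids")
    labels <- stats::setNames(ids, ids)
  }
  labels[is.na(labels) | !nzchar(labels)] <-
    ids[is.na(labels) | !nzchar(labels)]
  urls <- col_values(settings$url_column)

  selection <- if (is.null(system)) character(0) else system$selection
  spanning_cache <- attr(layout, "spanning")
  base_d <- NULL
  contours <- list()
  for (k in seq_along(selection)) {
    gid <- selection[k]
    sg <- spanning_cache[[gid]]
    if (is.null(sg)) {
      if (is.null(base_d)) base_d <- graph_distances(net)
      sg <- spanning_graph(net, system$groups[[gid]], base_d)
    }
    col <- contour_color(k)
    contours[[gid]] <- contour_shape(sg, layout, radius = radius,
                                     fill = col, outline = col)
  }
  if (length(contours)) {
    sizes <- vapply(selection, function(g)
      length(system$groups[[g]]$members), 0L)
    contours <- contours[selection[order(-sizes)]]   # big sets painted first
  }

  pos <- layout$positions
  edges <- if (nrow(net$edges)) {
    cbind(pos[net$edges[, 1], 1], pos[net$edges[, 1], 2],
          pos[net$edges[, 2], 1], pos[net$edges[, 2], 2])
  } else matrix(numeric(0), ncol = 4)

  glyphs <- lapply(ids, function(id) {
    list(id = id, x = pos[id, 1], y = pos[id, 2],
         hw = layout$half_extents[id, 1], hh = layout$half_extents[id, 2],
         label = unname(labels[id]),
         url = if (!is.null(urls) && !is.na(urls[id])) unname(urls[id]) else NULL)
  })

  centroid <- colMeans(pos)
  group_labels <- list()
  for (k in seq_along(selection)) {
    gid <- selection[k]
    rings <- contours[[gid]]$boundary
    allpts <- do.call(rbind, rings)
    far <- which.max((allpts[, 1] - centroid[1])^2 +
                     (allpts[, 2] - centroid[2])^2)
    grp <- system$groups[[gid]]
    score_text <- if (settings$show_score && !is.na(grp$score))
      format_score(grp$score) else NULL
    group_labels[[gid]] <- list(
      label = grp$label, score_text = score_text,
      x = allpts[far, 1], y = allpts[far, 2], color = contour_color(k))
  }

  xs <- c(pos[, 1] - layout$half_extents[, 1],
          pos[, 1] + layout$half_extents[, 1])
  ys <- c(pos[, 2] - layout$half_extents[, 2],
          pos[, 2] + layout$half_extents[, 2])
  for (cs in contours) for (r in cs$boundary) {
    xs <- c(xs, r[, 1]); ys <- c(ys, r[, 2])
  }
  extents <- c(min(xs), max(xs), min(ys), max(ys))

  structure(list(contours = contours, edges = edges, glyphs = glyphs,
                 group_labels = group_labels, extents = extents,
                 settings = settings),
            class = "cg_scene")
}
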