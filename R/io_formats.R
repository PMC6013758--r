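#' @title Readers and writers for the supported file dialects
#' @name io_formats
#' @description
#' Tab-separated edge lists with configurable 1-based id columns, GML and SIF
#' networks, typed annotation tables driven by a compact `s,f,sl` type
#' specifier (where `sl` cells hold pipe-separated token lists), and the SVG
#' scene writer.  All paths are local files; fetching remote resources is the
#' caller's concern.
NULL

#' Parse a comma-separated column type specifier
#'
#' Tokens: `s` (string), `f` (float), `sl` (string-list, pipe-separated).
#'
#' @param spec e.g. `"s,s,f,f,f,s,s,s,sl,sl,sl,sl"`.
#' @return character vector of canonical type names, one per token.
#' @export
parse_type_spec <- function(spec) {
  if (!is.character(spec) || length(spec) != 1 || !nzchar(spec))
    stop("type spec must be a non-empty string")
  tokens <- trimws(strsplit(spec, ",", fixed = TRUE)[[1]])
  bad <- which(!tokens %in% names(COLUMN_TYPES))
  if (length(bad))
    stop(sprintf("unknown type token '%s' at position %d", tokens[bad[1]],
                 bad[1]))
  unname(COLUMN_TYPES[tokens])
}

#' Split a pipe-separated list cell into tokens
#'
#' Empty and whitespace-only tokens are dropped; an empty cell yields an
#' empty character vector.
#'
#' @param cell a single string such as `"GO:0008013|GO:0008083"`.
#' @export
split_list_cell <- function(cell) {
  if (is.na(cell) || !nzchar(cell)) return(character(0))
  tokens <- trimws(strsplit(cell, "|", fixed = TRUE)[[1]])
  tokens[nzchar(tokens)]
}

read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(trimws(lines))]
}

#' Read a tab-separated edge list
#'
#' Source and target id columns are selected by 1-based index, mirroring the
#' `indexColumnSourceInteraction` / `indexColumnTargetInteraction` command
#' arguments.  Duplicate and reversed edges collapse to one stored edge;
#' self-loops are dropped with a warning.
#'
#' @param path tab-separated text file.
#' @param source_column,target_column 1-based column indices of the ids.
#' @param name network name (defaults to the file name).
#' @return a [network()].
#' @export
read_edge_list <- function(path, source_column = 1L, target_column = 2L,
                           name = basename(path)) {
  lines <- read_tsv_lines(path)
  if (!length(lines)) return(network(character(0), name = name))
  need <- max(source_column, target_column)
  src <- character(length(lines)); dst <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < need)
      stop(sprintf("line %d: %d column(s), need at least %d", i, length(f),
                   need))
    src[i] <- f[source_column]; dst[i] <- f[target_column]
  }
  loops <- src == dst
  if (any(loops)) {
    warning(sum(loops), " self-loop row(s) dropped")
    src <- src[!loops]; dst <- dst[!loops]
  }
  network(unique(c(src, dst)), cbind(src, dst), name = name,
          directed_warning = FALSE)
}

#' Read a SIF network (node TAB relation TAB node ...)
#'
#' Each row lists a source, a relation type (ignored) and one or more
#' targets.  Rows with a single column declare isolated nodes.
#'
#' @inheritParams read_edge_list
#' @export
read_sif <- function(path, name = basename(path)) {
  lines <- read_tsv_lines(path)
  src <- character(0); dst <- character(0); singles <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) == 1) { singles <- c(singles, f); next }
    if (length(f) == 2)
      stop(sprintf("line %d: SIF rows need 1 or >=3 columns", i))
    for (t in f[-(1:2)]) { src <- c(src, f[1]); dst <- c(dst, t) }
  }
  keep <- src != dst
  network(unique(c(src, dst, singles)),
          cbind(src[keep], dst[keep]), name = name, directed_warning = FALSE)
}

#' Read a GML network
#'
#' Parsing is delegated to igraph.  Node ids become the GML `label` when
#' present, else the stringified GML `id`.  Duplicate edges collapse.
#'
#' @inheritParams read_edge_list
#' @export
read_gml <- function(path, name = basename(path)) {
  g <- igraph::read_graph(path, format = "gml")
  attrs <- igraph::vertex_attr_names(g)
  ids <- if ("label" %in% attrs) {
    as.character(igraph::V(g)$label)
  } else if ("id" %in% attrs) {
    as.character(igraph::V(g)$id)
  } else {
    as.character(seq_len(igraph::vcount(g)))
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  keep <- el[, 1] != el[, 2]
  network(ids, cbind(ids[el[keep, 1]], ids[el[keep, 2]]), name = name,
          directed_warning = FALSE)
}

#' Read a network, dispatching on file extension
#'
#' `.gml` is parsed as GML, `.sif` as SIF, anything else as a tab-separated
#' edge list.
#'
#' @inheritParams read_edge_list
#' @export
read_network <- function(path, source_column = 1L, target_column = 2L,
                         name = basename(path)) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         gml = read_gml(path, name = name),
         sif = read_sif(path, name = name),
         read_edge_list(path, source_column, target_column, name = name))
}

#' Read a typed annotation table
#'
#' Tab-separated, one column type per entry of `type_spec` (see
#' [parse_type_spec()]).  `sl` cells are split on `|`; float cells that fail
#' to parse become missing with a warning.
#'
#' @param path tab-separated text file.
#' @param type_spec character vector of canonical types, or a single spec
#'   string such as `"s,sl"`.
#' @param key_column 1-based index of the key column.
#' @param first_row_names first row holds column names?
#' @param start_row 1-based first data row (after the header, if any).
#' @return a [node_table()].
#' @export
read_node_table <- function(path, type_spec, key_column = 1L,
                            first_row_names = TRUE, start_row = 1L) {
  if (is.character(type_spec) && length(type_spec) == 1 &&
      !type_spec[1] %in% COLUMN_TYPES)
    type_spec <- parse_type_spec(type_spec)
  lines <- read_tsv_lines(path)
  ncol <- length(type_spec)
  cells <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    # trailing empty fields are dropped by strsplit; pad them back
    if (length(f) < ncol &&
        nchar(gsub("[^\t]", "", lines[[i]])) == ncol - 1)
      f <- c(f, rep("", ncol - length(f)))
    if (length(f) != ncol)
      stop(sprintf("line %d: %d column(s), type spec declares %d", i,
                   length(f), ncol))
    f
  })
  if (first_row_names && length(cells)) {
    col_names <- cells[[1]]
    cells <- cells[-1]
  } else {
    col_names <- paste0("V", seq_len(ncol))
  }
  if (start_row > 1 && length(cells) >= start_row - 1)
    cells <- cells[-seq_len(start_row - 1)]
  n <- length(cells)
  raw <- matrix("", nrow = n, ncol = ncol)
  for (i in seq_len(n)) raw[i, ] <- cells[[i]]
  columns <- list()
  for (j in seq_len(ncol)) {
    if (j == key_column) next
    v <- raw[, j]
    columns[[col_names[j]]] <- switch(
      type_spec[j],
      "string" = list(type = "string", values = v),
      "float" = {
        num <- suppressWarnings(as.numeric(v))
        bad <- which(is.na(num) & nzchar(trimws(v)))
        if (length(bad))
          warning(sprintf("column '%s': %d non-numeric float cell(s) set to missing",
                          col_names[j], length(bad)))
        list(type = "float", values = num)
      },
      "string-list" = list(type = "string-list",
                           values = lapply(v, split_list_cell)))
  }
  node_table(if (n) raw[, key_column] else character(0), columns,
             key_column = col_names[key_column])
}

#' Report table keys with no matching node
#'
#' @param table a [node_table()].
#' @param net a [network()].
#' @return character vector of unmatched keys.
#' @export
unmatched_keys <- function(table, net) setdiff(table$keys, net$nodes)

#' Write a network's edge list back to a tab-separated file
#'
#' Inverse of [read_edge_list()] with id columns 1 and 2.
#'
#' @param net a [network()].
#' @param path output file.
#' @export
write_edge_list <- function(net, path) {
  writeLines(paste(net$edges[, 1], net$edges[, 2], sep = "\t"), path)
  invisible(path)
}

fmt_num <- function(x) {
  # fixed 3-decimal formatting keeps repeated exports byte-identical
  sprintf("%.3f", x)
}

#' Write a rendered scene to an SVG 1.1 file
#'
#' Painter's order: contours (already sorted largest-membership first by
#' [build_scene()]), then edges, then node glyphs and labels, then group
#' labels with optional score badges.  The viewBox wraps the drawing extents
#' with a 5% margin; SVG's native y-down orientation is used directly.
#'
#' @param scene a scene description from [build_scene()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_svg <- function(scene, path) {
  ext <- scene$extents
  w <- ext[2] - ext[1]; h <- ext[4] - ext[3]
  mx <- 0.05 * max(w, 1); my <- 0.05 * max(h, 1)
  vb <- c(ext[1] - mx, ext[3] - my, w + 2 * mx, h + 2 * my)
  doc <- xml2::xml_new_root(
    "svg", xmlns = "http://www.w3.org/2000/svg", version = "1.1",
    viewBox = paste(fmt_num(vb), collapse = " "),
    width = fmt_num(vb[3]), height = fmt_num(vb[4]))

  for (cs in scene$contours) {
    d <- vapply(cs$boundary, function(poly) {
      pts <- paste(fmt_num(poly[, 1]), fmt_num(poly[, 2]), sep = ",")
      paste0("M ", paste(pts, collapse = " L "), " Z")
    }, "")
    xml2::xml_add_child(doc, "path",
                        d = paste(d, collapse = " "),
                        fill = cs$fill, `fill-opacity` = fmt_num(cs$opacity),
                        stroke = cs$outline, `stroke-width` = "1.5",
                        `fill-rule` = "evenodd",
                        class = "contour", `data-group` = cs$group_id)
  }
  for (i in seq_len(nrow(scene$edges))) {
    e <- scene$edges[i, ]
    xml2::xml_add_child(doc, "line",
                        x1 = fmt_num(e[1]), y1 = fmt_num(e[2]),
                        x2 = fmt_num(e[3]), y2 = fmt_num(e[4]),
                        stroke = "#888888", `stroke-width` = "1")
  }
  for (g in scene$glyphs) {
    glyph <- xml2::xml_add_child(doc, "g", class = "node",
                                 `data-id` = g$id)
    if (!is.null(g$url))
      xml2::xml_set_attr(glyph, "data-url", g$url)
    xml2::xml_add_child(glyph, "rect",
                        x = fmt_num(g$x - g$hw), y = fmt_num(g$y - g$hh),
                        width = fmt_num(2 * g$hw), height = fmt_num(2 * g$hh),
                        rx = "4", fill = "#ffffff", stroke = "#333333",
                        `stroke-width` = "1")
    lab <- xml2::xml_add_child(glyph, "text",
                               x = fmt_num(g$x), y = fmt_num(g$y + 4),
                               `text-anchor` = "middle",
                               `font-family` = "monospace",
                               `font-size` = "12")
    xml2::xml_set_text(lab, g$label)
  }
  for (gl in scene$group_labels) {
    txt <- if (!is.null(gl$score_text)) paste0(gl$label, " ", gl$score_text)
           else gl$label
    lab <- xml2::xml_add_child(doc, "text",
                               x = fmt_num(gl$x), y = fmt_num(gl$y),
                               `text-anchor` = "middle",
                               `font-family` = "sans-serif",
                               `font-size` = "13", `font-weight` = "bold",
                               fill = gl$color, class = "group-label")
    xml2::xml_set_text(lab, txt)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
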