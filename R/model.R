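#' @title Domain types for set-annotated networks
#' @name model
#' @description
#' In-memory types shared by every stage of the pipeline: an undirected
#' [network()] of identified nodes, a typed [node_table()] keyed to node ids,
#' overlapping node [group()]s collected in a [set_system()], display
#' [cg_settings()], and the layout/geometry results produced downstream.
NULL

#' Construct an undirected network
#'
#' Nodes are opaque, case-sensitive string identifiers.  Edges are unordered
#' id pairs; self-loops are rejected and duplicate edges (in either endpoint
#' order) are collapsed to a single stored edge.
#'
#' @param nodes character vector of unique node ids.
#' @param edges two-column character matrix (or data.frame) of endpoint ids;
#'   may have zero rows.
#' @param name network name.
#' @param directed_warning warn if duplicate/reversed edges were collapsed
#'   (directed input is symmetrized).
#' @return An object of class `cg_network` with elements `nodes`, `edges`
#'   (two-column character matrix, endpoints ordered so `edges[,1] <= edges[,2]`
#'   never holds by id semantics but canonically by string order) and `name`.
#' @export
network <- function(nodes, edges = NULL, name = "network",
                    directed_warning = TRUE) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) {
    stop("duplicate node ids: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  }
  if (is.null(edges) || NROW(edges) == 0) {
    em <- matrix(character(0), ncol = 2)
  } else {
    em <- as.matrix(edges)
    storage.mode(em) <- "character"
    if (ncol(em) != 2) stop("edges must have two columns")
    if (any(em[, 1] == em[, 2])) {
      bad <- em[em[, 1] == em[, 2], 1]
      stop("self-loop edge(s): ", paste(unique(bad), collapse = ", "))
    }
    missing <- setdiff(c(em), nodes)
    if (length(missing)) {
      stop("edge endpoint(s) not in node set: ",
           paste(missing, collapse = ", "))
    }
    # canonical endpoint order, then dedupe
    swap <- em[, 1] > em[, 2]
    em[swap, ] <- em[swap, c(2, 1)]
    key <- paste(em[, 1], em[, 2], sep = "\r")
    dup <- duplicated(key)
    if (any(dup) && directed_warning) {
      warning(sum(dup), " duplicate/reversed edge(s) collapsed (network is undirected)")
    }
    em <- em[!dup, , drop = FALSE]
  }
  structure(list(nodes = nodes, edges = em, name = name),
            class = "cg_network")
}

#' Report invariant violations of a network object
#'
#' A reporting operation: returns a character vector of human-readable
#' violation descriptions, empty when all invariants hold (unique node ids,
#' no self-loops, no dangling endpoints, no duplicate edges).
#'
#' @param net a list shaped like a `cg_network` (possibly hand-built).
#' @return character vector of violations; `character(0)` if well-formed.
#' @export
validate_network <- function(net) {
  out <- character(0)
  nodes <- as.character(net$nodes)
  dups <- unique(nodes[duplicated(nodes)])
  for (d in dups) out <- c(out, sprintf("duplicate node id '%s'", d))
  em <- net$edges
  if (NROW(em)) {
    em <- as.matrix(em)
    for (i in seq_len(nrow(em))) {
      a <- em[i, 1]; b <- em[i, 2]
      if (a == b) out <- c(out, sprintf("self-loop edge on '%s'", a))
      if (!(a %in% nodes))
        out <- c(out, sprintf("edge (%s,%s): endpoint '%s' not a node", a, b, a))
      if (!(b %in% nodes))
        out <- c(out, sprintf("edge (%s,%s): endpoint '%s' not a node", a, b, b))
    }
    key <- paste(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]), sep = "\r")
    for (k in unique(key[duplicated(key)])) {
      p <- strsplit(k, "\r", fixed = TRUE)[[1]]
      out <- c(out, sprintf("duplicate edge (%s,%s)", p[1], p[2]))
    }
  }
  out
}

#' @export
print.cg_network <- function(x, ...) {
  cat(sprintf("<network '%s': %d nodes, %d edges>\n",
              x$name, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# Column type codes and their dialect tokens (s / f / sl).
COLUMN_TYPES <- c(s = "string", f = "float", sl = "string-list")

#' Construct a typed node annotation table
#'
#' @param keys character vector of row keys (matched against node ids).
#' @param columns named list; each element is `list(type=, values=)` where
#'   `type` is one of `"string"`, `"float"`, `"string-list"` and `values` is a
#'   vector (or list of character vectors for string-list) of `length(keys)`.
#' @param key_column name of the key column.
#' @return object of class `cg_node_table`.
#' @export
node_table <- function(keys, columns = list(), key_column = "key") {
  keys <- as.character(keys)
  for (nm in names(columns)) {
    col <- columns[[nm]]
    if (!col$type %in% COLUMN_TYPES)
      stop("unknown column type '", col$type, "' for column '", nm, "'")
    if (length(col$values) != length(keys))
      stop("column '", nm, "' has ", length(col$values),
           " values for ", length(keys), " keys")
    if (col$type == "string-list" && !is.list(col$values))
      stop("string-list column '", nm, "' must hold a list of token vectors")
    if (col$type == "float") {
      v <- col$values
      if (any(!is.na(v) & !is.finite(v)))
        stop("float column '", nm, "' holds non-finite values")
    }
  }
  structure(list(keys = keys, columns = columns, key_column = key_column),
            class = "cg_node_table")
}

#' @export
print.cg_node_table <- function(x, ...) {
  types <- vapply(x$columns, function(c) c$type, "")
  cat(sprintf("<node table: %d rows, %d columns (%s)>\n", length(x$keys),
              length(x$columns),
              paste(names(x$columns), types, sep = ":", collapse = ", ")))
  invisible(x)
}

#' Construct a node group (one named, possibly overlapping set)
#'
#' @param id group identifier, unique within a set system.
#' @param members character vector of member node ids (non-empty).
#' @param source_column annotation column the group was generated from.
#' @param label display label (defaults to the id).
#' @param url optional URL.
#' @param score optional numeric enrichment score (unitless).
#' @param network optional `cg_network`; when given, membership closure
#'   (`members` a subset of the network's nodes) is asserted.
#' @export
group <- function(id, members, source_column = NA_character_,
                  label = NULL, url = NULL, score = NULL, network = NULL) {
  members <- unique(as.character(members))
  if (!length(members)) stop("group '", id, "' has no members")
  if (!is.null(network)) {
    stray <- setdiff(members, network$nodes)
    if (length(stray))
      stop("group '", id, "' members outside network: ",
           paste(stray, collapse = ", "))
  }
  structure(list(id = as.character(id), members = members,
                 source_column = source_column,
                 label = if (is.null(label)) as.character(id) else label,
                 url = url,
                 score = if (is.null(score)) NA_real_ else as.numeric(score)),
            class = "cg_group")
}

#' Construct a set system (ordered groups plus the current selection)
#'
#' Selection order is significant: it drives palette assignment and contour
#' stacking downstream.
#'
#' @param groups list of [group()] objects with unique ids.
#' @param selection character vector of selected group ids (subset of ids).
#' @export
set_system <- function(groups = list(), selection = character(0)) {
  ids <- vapply(groups, function(g) g$id, "")
  if (anyDuplicated(ids))
    stop("duplicate group ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  selection <- as.character(selection)
  unknown <- setdiff(selection, ids)
  if (length(unknown))
    stop("selection references unknown group id(s): ",
         paste(unknown, collapse = ", "))
  names(groups) <- ids
  structure(list(groups = groups, selection = selection),
            class = "cg_set_system")
}

#' @export
print.cg_set_system <- function(x, ...) {
  cat(sprintf("<set system: %d groups, %d selected>\n",
              length(x$groups), length(x$selection)))
  invisible(x)
}

#' Visualization settings
#'
#' @param label_column node-table column holding node labels.
#' @param url_column node-table column holding node URLs.
#' @param score_column group-annotation column holding enrichment scores.
#' @param show_score draw group scores next to contour labels?
#' @param selected_group_columns columns whose groups are shown (display
#'   filter).
#' @export
cg_settings <- function(label_column = NULL, url_column = NULL,
                        score_column = NULL, show_score = FALSE,
                        selected_group_columns = NULL) {
  structure(list(label_column = label_column, url_column = url_column,
                 score_column = score_column,
                 show_score = isTRUE(show_score) ||
                   identical(tolower(as.character(show_score)), "true"),
                 selected_group_columns = selected_group_columns),
            class = "cg_settings")
}

#' Construct a layout result
#'
#' @param positions numeric matrix (n x 2) of node centers, rownames = ids.
#' @param half_extents numeric matrix (n x 2) of glyph half-width /
#'   half-height per node, rownames = ids; strictly positive.
#' @param seed integer seed the layout was computed with.
#' @param converged logical flags for the stress and overlap stages.
#' @export
layout_result <- function(positions, half_extents, seed = NA_integer_,
                          converged = TRUE) {
  stopifnot(is.matrix(positions), ncol(positions) == 2,
            is.matrix(half_extents), ncol(half_extents) == 2,
            identical(rownames(positions), rownames(half_extents)))
  if (!all(is.finite(positions))) stop("non-finite layout coordinates")
  if (!all(half_extents > 0)) stop("glyph half-extents must be positive")
  structure(list(positions = positions, half_extents = half_extents,
                 seed = seed, converged = converged),
            class = "cg_layout")
}

#' @export
print.cg_layout <- function(x, ...) {
  cat(sprintf("<layout: %d nodes, seed %s>\n", nrow(x$positions),
              format(x$seed)))
  invisible(x)
}
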