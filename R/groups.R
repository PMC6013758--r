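#' @title Generating, annotating and selecting node groups
#' @name groups
#' @description
#' Groups are born from string-list annotation columns: every distinct token
#' appearing in a named column, restricted to the current scope (all nodes or
#' only the selected ones), becomes one group whose members are the scoped
#' nodes carrying that token.
NULL

#' Generate groups from string-list columns of the node table
#'
#' One group per distinct token in the named columns, scoped either to every
#' network node or to an explicit selection.  Group ids are the raw tokens;
#' when the same token occurs in two different columns the later occurrence
#' is qualified as `"column:token"` so ids stay unique.  Groups whose scoped
#' membership is empty are dropped.  Order: column order, then first
#' appearance within the column.
#'
#' @param net a [network()].
#' @param table a [node_table()].
#' @param group_columns character vector of string-list column names.
#' @param use_all_nodes scope to all network nodes (`TRUE`) or to
#'   `selected_nodes` (`FALSE`).
#' @param selected_nodes node ids forming the scope when
#'   `use_all_nodes = FALSE`.
#' @return a [set_system()] with empty selection.
#' @export
generate_groups <- function(net, table, group_columns,
                            use_all_nodes = FALSE,
                            selected_nodes = character(0)) {
  missing_cols <- setdiff(group_columns, names(table$columns))
  if (length(missing_cols))
    stop("column(s) not in node table: ", paste(missing_cols, collapse = ", "))
  for (cn in group_columns) {
    if (table$columns[[cn]]$type != "string-list")
      stop("column '", cn, "' is not a string-list column")
  }
  scope <- if (use_all_nodes) net$nodes else intersect(selected_nodes, net$nodes)
  if (!length(scope)) stop("empty node scope for group generation")

  row_of <- match(table$keys, net$nodes)   # table rows keyed to nodes
  groups <- list(); seen <- character(0)
  for (cn in group_columns) {
    vals <- table$columns[[cn]]$values
    members_of <- list(); order_of <- character(0)
    for (i in seq_along(table$keys)) {
      nid <- table$keys[i]
      if (is.na(row_of[i]) || !(nid %in% scope)) next
      for (tok in vals[[i]]) {
        if (is.null(members_of[[tok]])) {
          members_of[[tok]] <- character(0)
          order_of <- c(order_of, tok)
        }
        members_of[[tok]] <- c(members_of[[tok]], nid)
      }
    }
    for (tok in order_of) {
      id <- if (tok %in% seen) paste0(cn, ":", tok) else tok
      seen <- c(seen, id)
      groups[[length(groups) + 1L]] <-
        group(id, members_of[[tok]], source_column = cn, network = net)
    }
  }
  set_system(groups)
}

#' Annotate groups from a group table
#'
#' Fills label / URL / score fields of groups whose id matches a table key.
#' Unmatched table keys produce a warning; groups without a matching row keep
#' their defaults (label = id).
#'
#' @param system a [set_system()].
#' @param group_table a [node_table()] keyed by group id.
#' @param label_column,url_column,score_column column names in `group_table`;
#'   `NULL` columns are skipped.
#' @export
annotate_groups <- function(system, group_table, label_column = NULL,
                            url_column = NULL, score_column = NULL) {
  ids <- names(system$groups)
  hit <- group_table$keys %in% ids
  if (!all(hit) || !any(hit))
    warning(sum(!hit), " annotation key(s) match no group")
  col_val <- function(cn, i) {
    if (is.null(cn) || !cn %in% names(group_table$columns)) return(NULL)
    v <- group_table$columns[[cn]]$values
    if (is.list(v)) v[[i]] else v[[i]]
  }
  for (i in which(hit)) {
    id <- group_table$keys[i]
    g <- system$groups[[id]]
    lab <- col_val(label_column, i)
    if (!is.null(lab) && !is.na(lab) && nzchar(lab)) g$label <- lab
    u <- col_val(url_column, i)
    if (!is.null(u) && !is.na(u) && nzchar(u)) g$url <- u
    s <- col_val(score_column, i)
    if (!is.null(s) && !is.na(s)) g$score <- as.numeric(s)
    system$groups[[id]] <- g
  }
  system
}

#' Replace the current group selection
#'
#' Order is preserved: it determines contour colors and stacking.
#'
#' @param system a [set_system()].
#' @param ids character vector of group ids (possibly empty).
#' @export
select_groups <- function(system, ids) {
  ids <- as.character(ids)
  unknown <- setdiff(ids, names(system$groups))
  if (length(unknown))
    stop("unknown group id(s): ", paste(unknown, collapse = ", "))
  system$selection <- ids
  system
}

#' Remove all generated groups (and the selection with them)
#'
#' @param system a [set_system()].
#' @export
remove_groups <- function(system) set_system()

#' Format a group score for display: 2 significant digits
#' @param score numeric scalar (may be `NA`).
#' @export
format_score <- function(score) {
  if (is.null(score) || is.na(score)) return("")
  format(signif(score, 2), scientific = FALSE)
}
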