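#' @title Scriptable command interface
#' @name commands
#' @description
#' A session holds the current network, node table, group table, set system,
#' settings and layout cache.  Commands in the `network`, `table` and
#' `examine` namespaces mirror the automation vocabulary of set-annotated
#' network tools: import a network and its typed annotations, select nodes,
#' generate/select/remove groups, update settings, and export an SVG.
#' Commands are atomic: a failing command leaves the session untouched.
NULL

#' Create a fresh session
#'
#' @param seed integer seed for layout randomness.
#' @param params a [layout_params()] list.
#' @param radius contour radius in layout units.
#' @export
new_session <- function(seed = 1L, params = layout_params(), radius = 14) {
  structure(list(network = NULL, table = NULL, group_table = NULL,
                 system = set_system(), settings = cg_settings(),
                 selected_nodes = character(0), seed = as.integer(seed),
                 params = params, radius = radius,
                 layout_cache = NULL),
            class = "cg_session")
}

#' @export
print.cg_session <- function(x, ...) {
  cat("<session:",
      if (is.null(x$network)) "no network" else
        sprintf("%d nodes/%d edges", length(x$network$nodes),
                nrow(x$network$edges)),
      sprintf("| %d groups, %d selected | seed %d>\n",
              length(x$system$groups), length(x$system$selection), x$seed))
  invisible(x)
}

arg_of <- function(args, ...) {
  for (nm in c(...)) if (!is.null(args[[nm]])) return(args[[nm]])
  NULL
}

split_arg_list <- function(x) {
  if (is.null(x)) return(character(0))
  trimws(strsplit(paste(x, collapse = ","), ",", fixed = TRUE)[[1]])
}

as_flag <- function(x, default = FALSE) {
  if (is.null(x)) return(default)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Select nodes by specifier
#'
#' `"all"` selects every node; `"Column:value"` selects nodes whose cell in
#' the named node-table column equals the value (string columns) or contains
#' it (string-list columns).  A value matching no node yields an empty
#' selection; an unknown column is an error.
#'
#' @param session a [new_session()].
#' @param spec node list specifier.
#' @export
select_nodes <- function(session, spec) {
  if (is.null(session$network)) stop("no network imported")
  if (identical(spec, "all")) {
    session$selected_nodes <- session$network$nodes
    return(session)
  }
  m <- regmatches(spec, regexec("^([^:]+):(.*)$", spec))[[1]]
  if (length(m) != 3) stop("node list must be 'all' or 'Column:value'")
  column <- m[2]; value <- m[3]
  tab <- session$table
  if (is.null(tab) || !column %in% names(tab$columns))
    stop("unknown node-table column '", column, "'")
  col <- tab$columns[[column]]
  hit <- switch(col$type,
    "string" = vapply(col$values, identical, logical(1), y = value),
    "string-list" = vapply(col$values, function(v) value %in% v, logical(1)),
    "float" = vapply(col$values, function(v)
      isTRUE(!is.na(v) && v == suppressWarnings(as.numeric(value))),
      logical(1)))
  session$selected_nodes <- intersect(tab$keys[hit], session$network$nodes)
  session
}

# Route an imported table: group annotation if its keys match existing group
# ids at least as well as node ids, else node annotation.
route_table <- function(session, tab) {
  node_hits <- if (is.null(session$network)) 0L
               else sum(tab$keys %in% session$network$nodes)
  group_hits <- sum(tab$keys %in% names(session$system$groups))
  if (group_hits > 0 && group_hits >= node_hits) {
    session$group_table <- tab
  } else {
    if (!is.null(session$network)) {
      um <- unmatched_keys(tab, session$network)
      if (length(um))
        warning(length(um), " table key(s) match no node: ",
                paste(utils::head(um, 5), collapse = ", "))
    }
    session$table <- tab
    session$layout_cache <- NULL
  }
  session
}

# Infer a type spec when none is given: float where every non-empty cell is
# numeric, else string.
infer_type_spec <- function(path) {
  lines <- read_tsv_lines(path)
  if (length(lines) < 2) return(NULL)
  cells <- strsplit(lines[-1], "\t", fixed = TRUE)
  ncol <- length(strsplit(lines[[1]], "\t", fixed = TRUE)[[1]])
  vapply(seq_len(ncol), function(j) {
    v <- vapply(cells, function(f) if (length(f) >= j) f[[j]] else "", "")
    v <- v[nzchar(trimws(v))]
    if (length(v) && !anyNA(suppressWarnings(as.numeric(v)))) "float"
    else "string"
  }, "")
}

annotated_system <- function(session) {
  system <- session$system
  gt <- session$group_table
  if (is.null(gt) || !length(system$groups)) return(system)
  nm <- names(gt$columns)
  pick <- function(wanted) {
    hit <- nm[tolower(nm) %in% tolower(wanted)]
    if (length(hit)) hit[1] else NULL
  }
  suppressWarnings(annotate_groups(
    system, gt,
    label_column = pick(c("label", "name", "symbol")),
    url_column = if (!is.null(session$settings$url_column) &&
                     session$settings$url_column %in% nm)
                   session$settings$url_column else pick("url"),
    score_column = if (!is.null(session$settings$score_column) &&
                       session$settings$score_column %in% nm)
                     session$settings$score_column else NULL))
}

session_layout <- function(session) {
  if (is.null(session$network)) stop("no network imported")
  labels <- NULL
  lc <- session$settings$label_column
  if (!is.null(lc) && !is.null(session$table) &&
      lc %in% names(session$table$columns)) {
    v <- session$table$columns[[lc]]$values
    labels <- stats::setNames(as.character(unlist(lapply(v, `[`, 1))),
                              session$table$keys)
  }
  key <- list(session$network, session$system$selection,
              lapply(session$system$groups[session$system$selection],
                     function(g) g$members),
              session$seed, session$params, labels)
  if (!is.null(session$layout_cache) &&
      identical(session$layout_cache$key, key))
    return(session)
  lay <- compute_layout(session$network, session$system,
                        seed = session$seed, params = session$params,
                        labels = labels)
  session$layout_cache <- list(key = key, layout = lay)
  session
}

export_svg <- function(session, path) {
  session <- session_layout(session)
  system <- annotated_system(session)
  scene <- build_scene(session$network, system,
                       session$layout_cache$layout, session$settings,
                       table = session$table, radius = session$radius)
  write_svg(scene, path)
  session
}

cmd_table <- list(
  "network/import" = function(session, args) {
    path <- arg_of(args, "path", "url")
    if (is.null(path)) stop("missing 'path' argument")
    src <- as.integer(arg_of(args, "indexColumnSourceInteraction") %||% 1L)
    dst <- as.integer(arg_of(args, "indexColumnTargetInteraction") %||% 2L)
    session$network <- read_network(path, src, dst)
    session$selected_nodes <- character(0)
    session$system <- set_system()
    session$layout_cache <- NULL
    list(session = session,
         message = sprintf("imported %d nodes, %d edges",
                           length(session$network$nodes),
                           nrow(session$network$edges)))
  },
  "network/select" = function(session, args) {
    spec <- arg_of(args, "nodeList")
    if (is.null(spec)) stop("missing 'nodeList' argument")
    session <- select_nodes(session, spec)
    list(session = session,
         message = sprintf("%d node(s) selected",
                           length(session$selected_nodes)))
  },
  "table/import" = function(session, args) {
    path <- arg_of(args, "path", "url")
    if (is.null(path)) stop("missing 'path' argument")
    spec <- arg_of(args, "dataTypeList")
    type_spec <- if (is.null(spec)) infer_type_spec(path)
                 else parse_type_spec(spec)
    if (is.null(type_spec)) stop("cannot infer column types for ", path)
    tab <- read_node_table(
      path, type_spec,
      key_column = as.integer(arg_of(args, "keyColumnIndex") %||% 1L),
      first_row_names = as_flag(arg_of(args, "firstRowAsColumnNames"), TRUE),
      start_row = as.integer(arg_of(args, "startLoadRow") %||% 1L))
    session <- route_table(session, tab)
    list(session = session,
         message = sprintf("imported %d row(s)", length(tab$keys)))
  },
  "examine/generate groups" = function(session, args) {
    if (is.null(session$network)) stop("no network imported")
    if (is.null(session$table)) stop("no node table imported")
    cols <- split_arg_list(arg_of(args, "selectedGroupColumns"))
    if (!length(cols)) stop("missing 'selectedGroupColumns' argument")
    use_all <- as_flag(arg_of(args, "useAllNodes"), FALSE)
    session$system <- generate_groups(session$network, session$table, cols,
                                      use_all_nodes = use_all,
                                      selected_nodes = session$selected_nodes)
    session$layout_cache <- NULL
    list(session = session,
         message = sprintf("%d group(s) generated",
                           length(session$system$groups)))
  },
  "examine/select groups" = function(session, args) {
    ids <- split_arg_list(arg_of(args, "selectedGroups", "selectedGroup"))
    session$system <- select_groups(session$system, ids)
    session$layout_cache <- NULL
    list(session = session,
         message = sprintf("%d group(s) selected", length(ids)))
  },
  "examine/remove groups" = function(session, args) {
    session$system <- remove_groups(session$system)
    session$layout_cache <- NULL
    list(session = session, message = "groups removed")
  },
  "examine/update settings" = function(session, args) {
    s <- session$settings
    upd <- function(key, cur) {
      v <- arg_of(args, key)
      if (is.null(v)) cur else v
    }
    s$label_column <- upd("labelColumn", s$label_column)
    s$url_column <- upd("urlColumn", s$url_column)
    s$score_column <- upd("scoreColumn", s$score_column)
    if (!is.null(arg_of(args, "showScore")))
      s$show_score <- as_flag(arg_of(args, "showScore"))
    sgc <- arg_of(args, "selectedGroupColumns")
    if (!is.null(sgc)) {
      cols <- split_arg_list(sgc)
      produced <- unique(vapply(session$system$groups,
                                function(g) g$source_column, ""))
      idle <- setdiff(cols, produced)
      if (length(idle) && length(session$system$groups))
        warning("settings column(s) generated no groups: ",
                paste(idle, collapse = ", "))
      s$selected_group_columns <- cols
    }
    session$settings <- s
    session$layout_cache <- NULL
    list(session = session, message = "settings updated")
  },
  "examine/export" = function(session, args) {
    path <- arg_of(args, "path")
    if (is.null(path)) stop("missing 'path' argument")
    session <- export_svg(session, path)
    list(session = session, message = paste("wrote", path))
  },
  "examine/interact" = function(session, args) {
    # interactive windows are a non-goal; emit the scene to a debug SVG
    path <- arg_of(args, "path") %||%
      file.path(tempdir(), "contourgraph-interact.svg")
    session <- export_svg(session, path)
    list(session = session,
         message = paste("interactive mode unavailable; scene written to",
                         path))
  }
)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Execute one command against a session
#'
#' Dispatches on `namespace` + `command`.  List-valued arguments are
#' comma-split and trimmed; `selectedGroup` and `selectedGroups` are both
#' accepted.  On error the returned session is identical to the input
#' (commands are atomic) and the status carries `ok = FALSE` with the error
#' message.
#'
#' @param session a [new_session()].
#' @param namespace one of `"network"`, `"table"`, `"examine"`.
#' @param command command name within the namespace.
#' @param args named list (or named character vector) of arguments.
#' @return list with elements `session` and `status`
#'   (`list(ok, namespace, command, message)`).
#' @export
run_command <- function(session, namespace, command, args = list()) {
  args <- as.list(args)
  key <- paste0(namespace, "/", command)
  # importer commands may carry a source-suffixed name (import url/file)
  key <- sub("^network/import( url| file)?$", "network/import", key)
  key <- sub("^table/import( url| file)?$", "table/import", key)
  status <- list(ok = FALSE, namespace = namespace, command = command,
                 message = "")
  if (!namespace %in% c("network", "table", "examine")) {
    status$message <- paste0("unknown namespace '", namespace, "'")
    return(list(session = session, status = status))
  }
  handler <- cmd_table[[key]]
  if (is.null(handler)) {
    status$message <- paste0("unknown command '", namespace, " ", command, "'")
    return(list(session = session, status = status))
  }
  out <- tryCatch(handler(session, args), error = function(e) e)
  if (inherits(out, "error")) {
    status$message <- conditionMessage(out)
    return(list(session = session, status = status))
  }
  status$ok <- TRUE
  status$message <- out$message
  list(session = out$session, status = status)
}

parse_script_line <- function(line) {
  tokens <- scan(text = line, what = "", quiet = TRUE)
  is_arg <- grepl("=", tokens, fixed = TRUE)
  first_arg <- which(is_arg)[1]
  if (is.na(first_arg)) first_arg <- length(tokens) + 1L
  if (first_arg < 3L) stop("malformed command line: ", line)
  args <- list()
  for (tok in tokens[is_arg]) {
    eq <- regexpr("=", tok, fixed = TRUE)
    args[[substr(tok, 1, eq - 1)]] <- substring(tok, eq + 1)
  }
  list(namespace = tokens[1],
       command = paste(tokens[2:(first_arg - 1)], collapse = " "),
       args = args)
}

#' Run a command script against a session
#'
#' Two dialects: one command per line (`namespace command key=value ...`,
#' `#` comments, double quotes protect spaces) or a JSON array of objects
#' with `namespace`, `command` and `args` fields.  Execution stops at the
#' first failing command unless `keep_going` is set.
#'
#' @param session a [new_session()].
#' @param path script file.
#' @param keep_going continue past failing commands?
#' @return list with the final `session` and `statuses`, one per attempted
#'   command.
#' @export
run_script <- function(session, path, keep_going = FALSE) {
  if (!file.exists(path)) stop("cannot read script: ", path)
  first <- trimws(paste(readLines(path, warn = FALSE), collapse = " "))
  cmds <- if (grepl("^\\[", first) || tolower(tools::file_ext(path)) == "json") {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    lapply(lines, parse_script_line)
  }
  script_dir <- dirname(normalizePath(path))
  statuses <- list()
  for (cmd in cmds) {
    args <- as.list(cmd$args %||% list())
    # input paths resolve against the script's directory when not found as-is
    for (k in intersect(c("path", "url"), names(args))) {
      cand <- file.path(script_dir, args[[k]])
      if (!file.exists(args[[k]]) && file.exists(cand)) args[[k]] <- cand
    }
    res <- run_command(session, cmd$namespace, cmd$command, args)
    statuses[[length(statuses) + 1L]] <- res$status
    session <- res$session
    if (!res$status$ok && !keep_going) break
  }
  list(session = session, statuses = statuses)
}
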