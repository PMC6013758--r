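#' @title Synthetic annotated-graph fixtures
#' @name fixtures
#' @description
#' Generates small sparse connected graphs carrying overlapping node-set
#' annotations in the same table dialects the readers consume, so every
#' pipeline stage is testable without external data.  Groups are planted as
#' connected node patches; a configurable fraction of nodes belongs to two
#' or more groups; a connected "Module" patch emulates an upstream
#' subnetwork-extraction result.
NULL

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic set-annotated graph
#'
#' The graph is a uniform random spanning tree plus extra edges, so it is
#' always connected.  Groups are planted by round-robin breadth-first
#' claiming from random seed nodes (each patch connected by construction);
#' overlap is created by adding boundary nodes to an adjacent second group,
#' which preserves per-group connectivity.
#'
#' @param n_nodes number of nodes (>= 1).
#' @param edges extra-edge probability in (0,1), or a total edge count
#'   >= `n_nodes - 1`.
#' @param n_groups number of planted groups (>= 0).
#' @param overlap_fraction target fraction of nodes belonging to >= 2 groups.
#' @param seed integer seed; the fixture is fully reproducible.
#' @param sl_columns names of the string-list columns the group tokens are
#'   spread over.
#' @param group_tokens group identifiers; default `LETTERS[1:n_groups]`.
#' @param token_columns which `sl_columns` entry each token belongs to;
#'   default round-robin.
#' @param module_size size of the planted connected `Module = "small"` patch
#'   (default `min(17, n_nodes)`).
#' @param style `"minimal"` (label + Score + Module + the sl columns) or
#'   `"rich"` (a 12-column `s,s,f,f,f,s,s,s,sl,sl,sl,sl` table mirroring a
#'   typical enriched-module annotation export).
#' @return list with `network`, `table`, `memberships` (token -> member
#'   ids), `group_info` (data.frame id/Label/URL/Score), `module_nodes`,
#'   `type_spec` (the table's specifier string) and `seed`.
#' @export
generate_annotated_graph <- function(n_nodes, edges = 0.06, n_groups = 4,
                                     overlap_fraction = 0.2, seed = 1L,
                                     sl_columns = "Community",
                                     group_tokens = NULL,
                                     token_columns = NULL,
                                     module_size = NULL,
                                     style = c("minimal", "rich")) {
  style <- match.arg(style)
  stopifnot(n_nodes >= 1, n_groups >= 0)
  if (n_groups > n_nodes) stop("more groups than nodes")
  if (overlap_fraction > 0 && n_groups < 2)
    stop("infeasible overlap request: need at least 2 groups")
  if (is.null(group_tokens)) {
    group_tokens <- if (n_groups <= 26) LETTERS[seq_len(n_groups)]
                    else sprintf("S%02d", seq_len(n_groups))
  }
  stopifnot(length(group_tokens) == n_groups)
  if (is.null(token_columns))
    token_columns <- sl_columns[(seq_len(n_groups) - 1) %% length(sl_columns) + 1]

  with_seed(seed, {
    ids <- sprintf("n%02d", seq_len(n_nodes))
    # random spanning tree + extras
    ep <- matrix(integer(0), ncol = 2)
    if (n_nodes > 1) {
      parents <- vapply(2:n_nodes, function(i) sample.int(i - 1L, 1L), 1L)
      tree <- cbind(parents, 2:n_nodes)
      all_pairs <- t(utils::combn(n_nodes, 2))
      tkey <- paste(pmin(tree[, 1], tree[, 2]), pmax(tree[, 1], tree[, 2]))
      akey <- paste(all_pairs[, 1], all_pairs[, 2])
      spare <- all_pairs[!(akey %in% tkey), , drop = FALSE]
      extra <- if (edges < 1) {
        spare[stats::runif(nrow(spare)) < edges, , drop = FALSE]
      } else {
        m_extra <- as.integer(edges) - (n_nodes - 1L)
        if (m_extra < 0) stop("edge count below n_nodes - 1")
        if (m_extra > nrow(spare)) stop("edge count exceeds the complete graph")
        spare[sample.int(nrow(spare), m_extra), , drop = FALSE]
      }
      ep <- rbind(tree, extra)
    }
    adj <- lapply(seq_len(n_nodes), function(i)
      sort(unique(c(ep[ep[, 1] == i, 2], ep[ep[, 2] == i, 1]))))
    net <- network(ids, cbind(ids[ep[, 1]], ids[ep[, 2]]),
                   name = sprintf("synthetic-%d", seed))

    # plant groups: round-robin BFS claiming from random seeds
    memberships <- stats::setNames(vector("list", n_groups), group_tokens)
    if (n_groups > 0) {
      owner <- integer(n_nodes)
      starts <- sample.int(n_nodes, n_groups)
      owner[starts] <- seq_len(n_groups)
      frontier <- as.list(starts)
      while (any(owner == 0L)) {
        progressed <- FALSE
        for (g in seq_len(n_groups)) {
          fr <- frontier[[g]]
          nxt <- integer(0); claimed <- integer(0)
          for (v in fr) {
            free <- adj[[v]][owner[adj[[v]]] == 0L]
            if (length(free)) {
              pick <- free[sample.int(length(free), 1L)]
              owner[pick] <- g
              claimed <- c(claimed, pick)
              progressed <- TRUE
            }
            if (any(owner[adj[[v]]] == 0L)) nxt <- c(nxt, v)
          }
          frontier[[g]] <- unique(c(nxt, claimed))
        }
        if (!progressed) break   # unreachable on a connected graph
      }
      member_sets <- lapply(seq_len(n_groups), function(g) which(owner == g))
      # create overlap: boundary nodes join one adjacent second group
      want <- round(overlap_fraction * n_nodes)
      if (want > 0) {
        boundary <- which(vapply(seq_len(n_nodes), function(v)
          any(owner[adj[[v]]] != owner[v]), logical(1)))
        if (length(boundary) < want)
          stop("infeasible overlap request: only ", length(boundary),
               " boundary node(s) for ", want)
        chosen <- sample(boundary, want)
        for (v in chosen) {
          others <- setdiff(unique(owner[adj[[v]]]), owner[v])
          g2 <- others[sample.int(length(others), 1L)]
          member_sets[[g2]] <- c(member_sets[[g2]], v)
        }
      }
      memberships <- stats::setNames(
        lapply(member_sets, function(m) ids[sort(unique(m))]), group_tokens)
    }

    # planted connected module patch
    if (is.null(module_size)) module_size <- min(17L, n_nodes)
    mod <- sample.int(n_nodes, 1L)
    while (length(mod) < module_size) {
      nb <- setdiff(unique(unlist(adj[mod])), mod)
      if (!length(nb)) break
      mod <- c(mod, nb[sample.int(length(nb), 1L)])
    }
    module_nodes <- ids[sort(mod)]

    sl_values <- lapply(sl_columns, function(cn) {
      toks <- group_tokens[token_columns == cn]
      lapply(ids, function(id)
        toks[vapply(toks, function(tk) id %in% memberships[[tk]],
                    logical(1))])
    })
    names(sl_values) <- sl_columns
    score <- round(stats::runif(n_nodes, -3, 3), 3)
    module_col <- ifelse(ids %in% module_nodes, "small", "")

    if (style == "minimal") {
      columns <- c(
        list(label = list(type = "string", values = paste0("v", seq_len(n_nodes))),
             Score = list(type = "float", values = score),
             Module = list(type = "string", values = module_col)),
        lapply(sl_values, function(v) list(type = "string-list", values = v)))
      type_spec <- paste(c("s", "s", "f", "s",
                           rep("sl", length(sl_columns))), collapse = ",")
    } else {
      if (!identical(sl_columns, c("Process", "Function", "Component", "Pathway")))
        stop("rich style requires sl_columns Process,Function,Component,Pathway")
      columns <- list(
        Name = list(type = "string", values = paste0(ids, "-protein")),
        Score = list(type = "float", values = score),
        LogFC = list(type = "float", values = round(stats::rnorm(n_nodes), 3)),
        PValue = list(type = "float",
                      values = signif(stats::runif(n_nodes, 1e-5, 0.05), 3)),
        Module = list(type = "string", values = module_col),
        URL = list(type = "string",
                   values = paste0("https://example.org/node/", ids)),
        Symbol = list(type = "string",
                      values = paste0("Gene", toupper(ids))),
        Process = NULL, Function = NULL, Component = NULL, Pathway = NULL)
      for (cn in sl_columns)
        columns[[cn]] <- list(type = "string-list", values = sl_values[[cn]])
      type_spec <- "s,s,f,f,f,s,s,s,sl,sl,sl,sl"
    }
    table <- node_table(ids, columns, key_column = "id")

    group_info <- data.frame(
      id = group_tokens,
      Label = if (n_groups) paste("set", tolower(group_tokens)) else character(0),
      URL = if (n_groups) paste0("https://example.org/set/", group_tokens)
            else character(0),
      Score = if (n_groups) signif(stats::runif(n_groups, 0.5, 9.5), 3)
              else numeric(0),
      stringsAsFactors = FALSE)

    list(network = net, table = table, memberships = memberships,
         group_info = group_info, module_nodes = module_nodes,
         type_spec = type_spec, seed = seed)
  })
}

format_cell <- function(col, i) {
  v <- col$values
  switch(col$type,
         "string" = v[[i]],
         "float" = if (is.na(v[[i]])) "" else format(v[[i]], scientific = FALSE),
         "string-list" = paste(v[[i]], collapse = "|"))
}

#' Write a node table in the tab-separated dialect
#'
#' Key column first, then the requested columns; `sl` cells joined with `|`.
#'
#' @param table a [node_table()].
#' @param path output file.
#' @param columns column subset (default all, in table order).
#' @return the matching type specifier string, invisibly.
#' @export
write_node_table <- function(table, path, columns = names(table$columns)) {
  header <- c(table$key_column, columns)
  lines <- vapply(seq_along(table$keys), function(i) {
    paste(c(table$keys[i],
            vapply(columns, function(cn) format_cell(table$columns[[cn]], i),
                   "")), collapse = "\t")
  }, "")
  writeLines(c(paste(header, collapse = "\t"), lines), path)
  spec <- c("s", vapply(columns, function(cn)
    names(COLUMN_TYPES)[COLUMN_TYPES == table$columns[[cn]]$type], ""))
  invisible(paste(spec, collapse = ","))
}

#' Write a network as GML
#'
#' Minimal GML: integer ids, the node identifier stored as `label`.
#'
#' @param net a [network()].
#' @param path output file.
#' @export
write_gml <- function(net, path) {
  idx <- stats::setNames(seq_along(net$nodes) - 1L, net$nodes)
  lines <- c("graph [", "  directed 0",
             vapply(net$nodes, function(id)
               sprintf("  node [\n    id %d\n    label \"%s\"\n  ]",
                       idx[[id]], id), ""),
             if (nrow(net$edges)) vapply(seq_len(nrow(net$edges)), function(i)
               sprintf("  edge [\n    source %d\n    target %d\n  ]",
                       idx[[net$edges[i, 1]]], idx[[net$edges[i, 2]]]), ""),
             "]")
  writeLines(lines, path)
  invisible(path)
}

#' Write a fixture's files in all supported dialects
#'
#' Emits `edges.txt` (tab-separated edge list), `network.gml`, `nodes.txt`
#' (typed node table) and `sets.txt` (group annotation table: id, Label,
#' URL, Score).  Reading the files back reproduces the in-memory fixture.
#'
#' @param fixture result of [generate_annotated_graph()].
#' @param dir output directory (created if needed).
#' @return named list of the written paths plus the node-table `type_spec`.
#' @export
write_fixture_files <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  edges_path <- file.path(dir, "edges.txt")
  write_edge_list(fixture$network, edges_path)
  gml_path <- file.path(dir, "network.gml")
  write_gml(fixture$network, gml_path)
  nodes_path <- file.path(dir, "nodes.txt")
  spec <- write_node_table(fixture$table, nodes_path)
  sets_path <- file.path(dir, "sets.txt")
  gi <- fixture$group_info
  writeLines(c("id\tLabel\tURL\tScore",
               if (nrow(gi)) paste(gi$id, gi$Label, gi$URL,
                                   format(gi$Score, scientific = FALSE),
                                   sep = "\t")),
             sets_path)
  list(edges = edges_path, gml = gml_path, nodes = nodes_path,
       sets = sets_path, type_spec = spec)
}
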