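# Shared builders for tests.

path_network <- function(ids) {
  n <- length(ids)
  edges <- if (n > 1) cbind(ids[-n], ids[-1]) else NULL
  network(ids, edges, name = "path")
}

extdata <- function(...) {
  system.file("extdata", ..., package = "contourgraph", mustWork = TRUE)
}

# Replay a bundled workflow script in a scratch directory; returns the final
# session, statuses and the rendered SVG path.
replay_workflow <- function(which, seed = 5L, out = NULL) {
  script <- extdata(which, "workflow.txt")
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  withr::local_dir(dir, .local_envir = parent.frame())
  res <- suppressWarnings(run_script(new_session(seed = seed), script))
  svg <- file.path(dir, c(usecase_module = "fig1a.svg",
                          karate_like = "fig1b.svg")[[which]])
  c(res, list(svg = svg))
}

# A laid-out fixture with groups, reused across contour/layout tests.
laid_out_fixture <- function(seed = 7, n = 20, select = 3) {
  fx <- generate_annotated_graph(n, edges = 0.08, n_groups = 4,
                                 overlap_fraction = 0.25, seed = seed)
  sys <- generate_groups(fx$network, fx$table, "Community",
                         use_all_nodes = TRUE)
  if (select > 0)
    sys <- select_groups(sys, names(sys$groups)[seq_len(select)])
  lay <- compute_layout(fx$network, sys, seed = seed)
  list(fixture = fx, system = sys, layout = lay)
}
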