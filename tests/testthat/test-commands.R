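karate_session <- function(seed = 5L) {
  s <- new_session(seed = seed)
  s <- run_command(s, "network", "import",
                   list(path = extdata("karate_like",
                                       "edges_karate.gml")))$session
  s <- run_command(s, "table", "import",
                   list(path = extdata("karate_like",
                                       "nodes_karate_induced.txt"),
                        dataTypeList = "s,sl"))$session
  s <- run_command(s, "network", "select", list(nodeList = "all"))$session
  run_command(s, "examine", "generate groups",
              list(selectedGroupColumns = "Community"))$session
}

test_that("group selection accepts both argument spellings", {
  s <- karate_session()
  r1 <- run_command(s, "examine", "select groups",
                    list(selectedGroups = "A,B,C,D,E,F"))
  expect_true(r1$status$ok)
  expect_length(r1$session$system$selection, 6)
  r2 <- run_command(s, "examine", "select groups",
                    list(selectedGroup = "A, B"))
  expect_true(r2$status$ok)
  expect_identical(r2$session$system$selection, c("A", "B"))
})

test_that("unknown commands fail with a naming error and no state change", {
  s <- karate_session()
  r <- run_command(s, "examine", "frobnicate", list())
  expect_false(r$status$ok)
  expect_match(r$status$message, "frobnicate")
  expect_identical(r$session, s)
  r2 <- run_command(s, "cosmos", "select", list())
  expect_false(r2$status$ok)
  expect_match(r2$status$message, "namespace")
  expect_identical(r2$session, s)
})

test_that("failing commands are atomic", {
  s <- karate_session()
  s <- run_command(s, "examine", "select groups",
                   list(selectedGroups = "A,B"))$session
  # unknown group id mid-way must not clobber the existing selection
  r <- run_command(s, "examine", "select groups",
                   list(selectedGroups = "C,Zebra"))
  expect_false(r$status$ok)
  expect_match(r$status$message, "Zebra")
  expect_identical(r$session, s)
  # missing file on import leaves the session intact too
  r2 <- run_command(s, "network", "import", list(path = "no/such/file.txt"))
  expect_false(r2$status$ok)
  expect_identical(r2$session, s)
})

test_that("node selection handles all, column matches and misses", {
  s <- karate_session()
  expect_length(select_nodes(s, "all")$selected_nodes, 34)
  hit <- select_nodes(s, "Community:A")
  vals <- s$table$columns$Community$values
  expect_setequal(hit$selected_nodes,
                  s$table$keys[vapply(vals, function(v) "A" %in% v,
                                      logical(1))])
  expect_length(select_nodes(s, "Community:absent")$selected_nodes, 0)
  expect_error(select_nodes(s, "Nope:x"), "unknown node-table column")
})

test_that("module-style string match selects exactly the flagged nodes", {
  f <- extdata("usecase_module")
  s <- new_session()
  s <- run_command(s, "network", "import",
                   list(path = file.path(f, "edges.txt")))$session
  s <- run_command(s, "table", "import",
                   list(path = file.path(f, "nodes_induced.txt"),
                        dataTypeList = "s,s,f,f,f,s,s,s,sl,sl,sl,sl"))$session
  s <- select_nodes(s, "Module:small")
  mods <- s$table$keys[vapply(s$table$columns$Module$values,
                              identical, logical(1), y = "small")]
  expect_setequal(s$selected_nodes, mods)
  expect_length(s$selected_nodes, 17)
})

test_that("scripts halt at the first failure unless told otherwise", {
  lines <- c("network import path=definitely_missing.gml",
             "network select nodeList=all")
  script <- withr::local_tempfile(lines = lines)
  res <- run_script(new_session(), script)
  expect_length(res$statuses, 1)
  expect_false(res$statuses[[1]]$ok)
  res2 <- run_script(new_session(), script, keep_going = TRUE)
  expect_length(res2$statuses, 2)
})

test_that("an empty script leaves the session unchanged", {
  script <- withr::local_tempfile(lines = c("# nothing to do"))
  s <- new_session(seed = 3)
  res <- run_script(s, script)
  expect_identical(res$session, s)
  expect_length(res$statuses, 0)
})

test_that("JSON scripts are an accepted dialect", {
  cmds <- list(
    list(namespace = "network", command = "import",
         args = list(path = extdata("karate_like", "edges_karate.gml"))),
    list(namespace = "network", command = "select",
         args = list(nodeList = "all")))
  script <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cmds, script, auto_unbox = TRUE)
  res <- run_script(new_session(), script)
  expect_true(all(vapply(res$statuses, `[[`, logical(1), "ok")))
  expect_length(res$session$selected_nodes, 34)
})

test_that("replaying a workflow twice yields byte-identical SVG", {
  r1 <- replay_workflow("karate_like", seed = 5)
  bytes1 <- readBin(r1$svg, "raw", file.size(r1$svg))
  r2 <- replay_workflow("karate_like", seed = 5)
  bytes2 <- readBin(r2$svg, "raw", file.size(r2$svg))
  expect_identical(bytes1, bytes2)
})

test_that("layout cache is reused until a mutation invalidates it", {
  s <- karate_session()
  s <- run_command(s, "examine", "select groups",
                   list(selectedGroups = "A,B"))$session
  out <- withr::local_tempfile(fileext = ".svg")
  s <- run_command(s, "examine", "export", list(path = out))$session
  cache1 <- s$layout_cache
  expect_false(is.null(cache1))
  s <- run_command(s, "examine", "export", list(path = out))$session
  expect_identical(s$layout_cache, cache1)         # unchanged inputs: reused
  s <- run_command(s, "examine", "select groups",
                   list(selectedGroups = "C"))$session
  expect_null(s$layout_cache)                      # mutation invalidates
})
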