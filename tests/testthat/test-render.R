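# A light structural check of DOT syntax: brace balance plus a statement
# grammar for the subset the renderer emits.
expect_valid_dot <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  expect_equal(lines[1], "digraph meta_rem {")
  expect_equal(lines[length(lines)], "}")
  body <- lines[-c(1, length(lines))]
  stmt <- paste0(
    "^  (",
    "rankdir=LR;|",
    "node \\[[^]]*\\];|",
    "\"[^\"]*\" \\[[^]]*\\];|",                       # node statement
    "\"[^\"]*\" -> \"[^\"]*\"( \\[[^]]*\\])?;|",      # edge statement
    "\\{ rank=same;( \"[^\"]*\";)+ \\}",              # rank group
    ")$")
  bad <- body[!grepl(stmt, body)]
  expect_identical(bad, character(0))
  expect_equal(sum(unlist(gregexpr("\\{", txt)) > 0) ,
               sum(unlist(gregexpr("\\}", txt)) > 0))
}

test_that("DOT output carries a spine, rank groups and all statements", {
  nodes <- toy_nodes(c("A", "B"), date = c("2020-01", "2020-05"),
                     stage = c("activity", "output"),
                     group = c("knowledge_evidence", "research_capacity"))
  edges <- toy_edges("A", "B")
  map <- build_meta_map(nodes, edges, cascade_exclude(nodes, edges))
  txt <- to_dot(map)
  expect_valid_dot(txt)
  lines <- strsplit(txt, "\n")[[1]]
  # one spine node and one rank group per occupied bin
  expect_equal(sum(grepl("style=invis, label=", lines)), 2)
  expect_equal(sum(grepl("rank=same", lines)), 2)
  # one invisible spine edge, one visible edge
  expect_equal(sum(grepl("-> .*style=invis", lines)), 1)
  expect_equal(sum(grepl('"A" -> "B"', lines, fixed = TRUE)), 1)
  # shapes and colours applied
  expect_true(any(grepl("shape=ellipse", lines)))
  expect_true(any(grepl("shape=diamond", lines)))
})

test_that("an empty map renders a valid DOT header with no node statements", {
  nodes <- toy_nodes("A")          # undated -> excluded
  edges <- toy_edges("A", "A")[0, ]
  ex <- cascade_exclude(nodes, edges)
  map <- suppressWarnings(build_meta_map(nodes, edges, ex))
  txt <- to_dot(map)
  expect_valid_dot(txt)
  expect_false(grepl("rank=same", txt))
})

test_that("two nodes share a rank group iff they share a bin", {
  fx <- random_fixture(12)
  fit <- run_pipeline(fx)
  txt <- to_dot(fit$map)
  lines <- strsplit(txt, "\n")[[1]]
  ranks <- grep("rank=same", lines, value = TRUE)
  expect_equal(length(ranks), length(unique(fit$map$node_bin)))
  # membership per rank group matches the bin assignment
  ids_in <- lapply(ranks, function(l) {
    ids <- regmatches(l, gregexpr('"[^"]*"', l))[[1]]
    ids <- gsub('"', "", ids)
    setdiff(ids, ids[startsWith(ids, "bin_")])
  })
  got <- lapply(ids_in, sort)
  want <- lapply(split(names(fit$map$node_bin), unname(fit$map$node_bin)),
                 sort)
  expect_identical(unname(got), unname(want[order(as.integer(names(want)))]))
})

test_that("parallel edges collapse with a multiplicity label in DOT only", {
  nodes <- toy_nodes(c("A", "B"), date = c("2020-01", "2020-02"))
  edges <- rbind(toy_edges("A", "B", "r1"), toy_edges("A", "B", "r2"))
  map <- build_meta_map(nodes, edges, cascade_exclude(nodes, edges))
  expect_equal(nrow(map$edges), 2)  # analytics keep both
  txt <- to_dot(map)
  expect_equal(sum(grepl('"A" -> "B"', strsplit(txt, "\n")[[1]],
                         fixed = TRUE)), 1)
  expect_true(grepl('label="x2"', txt))
})

test_that("rendering is byte-identical across repeated runs", {
  fx <- random_fixture(21)
  fit <- run_pipeline(fx)
  expect_identical(to_dot(fit$map), to_dot(fit$map))
  expect_identical(as.character(to_json(fit$map)),
                   as.character(to_json(fit$map)))
  # and across a rebuild of the same fixture
  fit2 <- run_pipeline(random_fixture(21))
  expect_identical(to_dot(fit$map), to_dot(fit2$map))
})

test_that("JSON round-trips losslessly to an equal meta-map", {
  fx <- random_fixture(33)
  fit <- run_pipeline(fx)
  back <- meta_map_from_json(to_json(fit$map))
  expect_true(meta_map_equal(fit$map, back))
  # empty map round-trips too
  nodes <- toy_nodes("A")
  ex <- cascade_exclude(nodes, toy_edges("A", "A")[0, ])
  empty <- suppressWarnings(build_meta_map(nodes, toy_edges("A", "A")[0, ],
                                           ex))
  back2 <- meta_map_from_json(to_json(empty))
  expect_equal(nrow(back2$nodes), 0)
  expect_equal(nrow(back2$edges), 0)
  expect_equal(nrow(back2$bins), 0)
})

test_that("style overrides from YAML merge over the defaults", {
  tmp <- withr::local_tempdir()
  yml <- file.path(tmp, "style.yaml")
  writeLines(c("shape_by_stage:", "  activity: oval",
               "color_by_group:", "  research_capacity: red"), yml)
  st <- read_style_config(yml)
  expect_equal(unname(st$shape_by_stage[["activity"]]), "oval")
  expect_equal(unname(st$color_by_group[["research_capacity"]]), "red")
  expect_equal(unname(st$shape_by_stage[["output"]]), "diamond")
})
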