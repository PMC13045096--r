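test_that("the same seed reproduces a byte-identical fixture", {
  p <- rem_fixture_params(n_workshops = 3, n_records = 50, n_duplicates = 6,
                          n_conceptual = 4, n_undatable = 5, n_cascade = 4,
                          seed = 1234)
  a <- generate_rem_fixture(p)
  b <- generate_rem_fixture(p)
  expect_identical(a$dataset$nodes, b$dataset$nodes)
  expect_identical(a$dataset$edges, b$dataset$edges)
  expect_identical(unclass(a$aliases), unclass(b$aliases))
  expect_identical(a$truth, b$truth)
  tmp <- withr::local_tempdir()
  write_fixture(a, file.path(tmp, "a"))
  write_fixture(b, file.path(tmp, "b"))
  for (f in list.files(file.path(tmp, "a"))) {
    expect_identical(readLines(file.path(tmp, "a", f)),
                     readLines(file.path(tmp, "b", f)))
  }
})

test_that("a clean fixture has no exclusions at all", {
  fx <- generate_rem_fixture(rem_fixture_params(
    n_workshops = 2, n_records = 20, n_duplicates = 0, n_conceptual = 0,
    n_undatable = 0, n_cascade = 0, seed = 8))
  fit <- run_pipeline(fx)
  expect_equal(fit$accounting$cascade_excluded, 0)
  expect_equal(fit$accounting$undatable, 0)
  expect_equal(fit$accounting$conceptual, 0)
  expect_equal(fit$accounting$dated_included, fit$accounting$event)
})

test_that("the pipeline recovers the planted ground truth exactly", {
  skip_if_not_installed("igraph")
  for (seed in c(2, 14, 31, 57, 88)) {
    fx <- random_fixture(seed)
    fit <- run_pipeline(fx)
    lo <- label_of(fit)
    expect_identical(sort(unname(lo[fit$exclusion$included])),
                     fx$truth$included)
    expect_identical(sort(unname(lo[fit$exclusion$undatable])),
                     fx$truth$undatable)
    expect_identical(sort(unname(lo[fit$exclusion$conceptual])),
                     fx$truth$conceptual)
    expect_identical(sort(unname(lo[fit$exclusion$cascade_excluded])),
                     fx$truth$cascade_excluded)
    # the independent oracle agrees with the planted exclusion
    expect_identical(oracle_cascade_included(fit$nodes, fit$edges),
                     fit$exclusion$included)
    # generated ripples never violate temporal order
    expect_equal(nrow(fit$violations), 0)
  }
})

test_that("infeasible parameter combinations are rejected up front", {
  expect_error(rem_fixture_params(n_records = 10, n_duplicates = 10),
               "feasibility")
  expect_error(rem_fixture_params(n_records = 20, n_duplicates = 0,
                                  n_conceptual = 15, n_undatable = 10),
               "feasibility")
  expect_error(rem_fixture_params(n_records = 20, n_duplicates = 0,
                                  n_conceptual = 0, n_undatable = 0,
                                  n_cascade = 5),
               "feasibility")
  expect_error(rem_fixture_params(n_workshops = 1, n_records = 20,
                                  n_duplicates = 2, n_conceptual = 0,
                                  n_undatable = 0, n_cascade = 0),
               "feasibility")
})

test_that("the replica profile reproduces every planted count", {
  fx <- actearly_replica()
  fit <- run_pipeline(fx)
  a <- fit$accounting
  expect_equal(a$raw_total, 440)
  expect_equal(a$duplicates, 74)
  expect_equal(a$unique, 366)
  expect_equal(a$conceptual, 54)
  expect_equal(a$event, 312)
  expect_equal(a$dated_included, 173)
  expect_equal(a$undatable, 63)
  expect_equal(a$cascade_excluded, 76)
  expect_equal(nrow(fit$map$nodes), 173)
  # five workshops, dates spanning the programme window
  expect_equal(length(fx$dataset$workshop_ids), 5)
  expect_equal(min(fit$map$nodes$date), "2019-01")
  expect_equal(max(fit$map$nodes$date), "2023-10")
  # alias code path exercised: the abbreviation resolves to the full title
  expect_equal(
    unname(canonicalize_label("HWF pilot", fx$aliases)),
    "Healthier Wealthier Families project pilot")
  # the theme research groups are planted among the most influential nodes
  inf <- influence(fit$map, top_k = 10)
  expect_true("Evaluation theme research group" %in% inf$label)
  expect_true("Food and Healthy Weight theme research group" %in% inf$label)
})

test_that("replica node files carry 440 records by independent row count", {
  fx <- actearly_replica()
  tmp <- withr::local_tempdir()
  write_fixture(fx, tmp)
  per_ws <- vapply(fx$dataset$workshop_ids, function(ws) {
    length(readLines(file.path(tmp, paste0("nodes_", ws, ".csv")))) - 1L
  }, integer(1))
  expect_equal(sum(per_ws), 440L)
  parts <- lapply(fx$dataset$workshop_ids, function(ws) {
    read_workshop(file.path(tmp, paste0("nodes_", ws, ".csv")),
                  file.path(tmp, paste0("edges_", ws, ".csv")))
  })
  expect_equal(nrow(merge_datasets(parts)$nodes), 440)
})
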