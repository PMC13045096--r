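test_that("read_workshop parses a minimal chain and enforces its contract", {
  tmp <- withr::local_tempdir()
  nf <- write_csv_tmp(data.frame(workshop_id = "W1",
                                 local_id = c("a", "b", "c"),
                                 label = c("Node A", "Node B", "Node C")),
                      tmp, "nodes.csv")
  ef <- write_csv_tmp(data.frame(workshop_id = "W1", ripple_id = "r1",
                                 from_local = c("a", "b"),
                                 to_local = c("b", "c")),
                      tmp, "edges.csv")
  ds <- read_workshop(nf, ef)
  expect_s3_class(ds, "rem_dataset")
  expect_equal(nrow(ds$nodes), 3)
  expect_equal(nrow(ds$edges), 2)
  expect_equal(length(unique(ds$edges$ripple_id)), 1)
  expect_equal(ds$nodes$site, rep("unknown", 3))

  # unknown endpoint is a reference error naming the offender
  ef2 <- write_csv_tmp(data.frame(workshop_id = "W1", ripple_id = "r1",
                                  from_local = "a", to_local = "Z"),
                       tmp, "edges2.csv")
  expect_error(read_workshop(nf, ef2), "reference error.*'Z'")

  # missing column is a format error naming the column
  nf2 <- write_csv_tmp(data.frame(workshop_id = "W1", local_id = "a"),
                       tmp, "nodes2.csv")
  expect_error(read_workshop(nf2, ef), "format error.*label")

  # duplicate (workshop, local) pair
  nf3 <- write_csv_tmp(data.frame(workshop_id = "W1",
                                  local_id = c("a", "a"),
                                  label = c("X", "Y")),
                       tmp, "nodes3.csv")
  expect_error(read_workshop(nf3, ef2), "uniqueness error")
})

test_that("self-edges and cross-workshop ripples are rejected, stray marks warn", {
  nodes <- data.frame(workshop_id = c("W1", "W1", "W1", "W1"),
                      local_id = c("a", "b", "c", "d"),
                      label = c("A", "B", "C", "D"))
  expect_error(
    toy_raw(nodes, data.frame(workshop_id = "W1", ripple_id = "r1",
                              from_local = "a", to_local = "a")),
    "self-edge")
  # a ripple with two disconnected components warns but is kept
  expect_warning(
    ds <- toy_raw(nodes, data.frame(workshop_id = "W1", ripple_id = "r1",
                                    from_local = c("a", "c"),
                                    to_local = c("b", "d"))),
    "not weakly connected")
  expect_equal(nrow(ds$edges), 2)
})

test_that("merge_datasets is an order-invariant disjoint union", {
  mk <- function(ws, labs) {
    toy_raw(data.frame(workshop_id = ws, local_id = paste0("n", seq_along(labs)),
                       label = labs))
  }
  a <- mk("W1", c("A", "B"))
  b <- mk("W2", c("C", "D"))
  m <- merge_datasets(list(a, b))
  expect_equal(nrow(m$nodes), 4)
  expect_equal(length(m$workshop_ids), 2)
  # reversed order yields the same record set
  m2 <- merge_datasets(list(b, a))
  key <- function(d) {
    sort(do.call(paste, c(d$nodes, sep = "\r")))
  }
  expect_identical(key(m), key(m2))
  # identity with respect to the other part's absence
  expect_identical(key(merge_datasets(list(a))), key(a))
  # colliding workshop ids conflict
  expect_error(merge_datasets(list(a, mk("W1", "E"))), "conflict error")
})

test_that("datasets round-trip through the two-table format", {
  fx <- random_fixture(42)
  tmp <- withr::local_tempdir()
  write_dataset(fx$dataset, file.path(tmp, "n.csv"), file.path(tmp, "e.csv"))
  back <- read_dataset(file.path(tmp, "n.csv"), file.path(tmp, "e.csv"))
  expect_identical(back$nodes, fx$dataset$nodes)
  expect_identical(back$edges, fx$dataset$edges)
  expect_identical(back$workshop_ids, fx$dataset$workshop_ids)
})

test_that("alias maps expand in one step and reject chains", {
  tmp <- withr::local_tempdir()
  af <- write_csv_tmp(
    data.frame(variant = "HWF",
               canonical = "Healthier Wealthier Families project pilot"),
    tmp, "alias.csv")
  am <- read_alias_map(af)
  expect_equal(unname(canonicalize_label("hwf", am)),
               "Healthier Wealthier Families project pilot")
  # chains are rejected: B -> C while A -> B
  expect_error(as_alias_map(c("A", "B"), c("B", "C")), "chain")
  # empty file gives an empty map
  ef <- write_csv_tmp(data.frame(variant = character(0),
                                 canonical = character(0)), tmp, "e.csv")
  expect_length(read_alias_map(ef), 0)
})

test_that("date tables parse ISO dates, flag year-only, reject bad rows", {
  dt <- as_date_table(c("A", "B"), c("2020-03", "2021"),
                      c("participant", "document"))
  expect_equal(dt$precision, c("month", "year"))
  expect_equal(dt$date, c("2020-03", "2021-01"))  # year binned to January
  expect_error(as_date_table("A", "2023-13", "participant"),
               "row 1.*month out of range")
  expect_error(as_date_table("A", "soon", "participant"), "format error")
  expect_error(as_date_table("A", "2020-01", "guess"), "source")
  expect_error(as_date_table("A", "2030-01", "participant",
                             window = c("2019-01", "2023-10")),
               "window")
})
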