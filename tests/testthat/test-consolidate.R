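test_that("canonicalize_label normalises, aliases once, and is idempotent", {
  am <- as_alias_map("hwf pilot",
                     "Healthier Wealthier Families project pilot")
  out <- canonicalize_label("  HWF  pilot ", am)
  expect_equal(out, "Healthier Wealthier Families project pilot")
  # no alias entry: normalisation only, original casing kept
  expect_equal(canonicalize_label("  Some   Node "), "Some Node")
  # idempotence over a batch of messy labels
  raw <- c(" a  b ", "HWF PILOT", "x", "Mixed   Case Label")
  once <- canonicalize_label(raw, am)
  expect_identical(canonicalize_label(once, am), once)
})

test_that("find_duplicates clusters by normalised label and counts duplicates", {
  ds <- toy_raw(data.frame(workshop_id = "W1",
                           local_id = paste0("n", 1:5),
                           label = c("a", "a ", "b", "B", "c")))
  # forbid within-dataset duplicate ids only; duplicate labels are the point
  cl <- find_duplicates(ds)
  expect_equal(attr(cl, "n_clusters"), 3)
  expect_equal(attr(cl, "n_duplicates"), 2)
  # brute-force oracle: pairwise normalised equality
  key <- tolower(trimws(ds$nodes$label))
  expect_equal(attr(cl, "n_clusters"), length(unique(key)))
  # clusters partition the records
  expect_equal(nrow(cl), nrow(ds$nodes))
  expect_equal(sum(table(cl$cluster_id)), nrow(ds$nodes))
  # all-distinct labels give singletons and zero duplicates
  ds2 <- toy_raw(data.frame(workshop_id = "W1", local_id = c("x", "y"),
                            label = c("P", "Q")))
  cl2 <- find_duplicates(ds2)
  expect_equal(attr(cl2, "n_duplicates"), 0)
  # idempotence: clustering already-consolidated labels yields singletons
  ds3 <- toy_raw(data.frame(workshop_id = "W1",
                            local_id = paste0("m", seq_len(3)),
                            label = unique(cl$canonical_label)))
  expect_equal(attr(find_duplicates(ds3), "n_duplicates"), 0)
})

test_that("fuzzy policy only writes a review file and needs a path", {
  ds <- toy_raw(data.frame(workshop_id = "W1", local_id = c("a", "b"),
                           label = c("Healthy Places project",
                                     "Healthy Places projects")))
  expect_error(find_duplicates(ds, policy = "fuzzy"),
               "configuration error")
  tmp <- withr::local_tempdir()
  rf <- file.path(tmp, "review.csv")
  cl <- find_duplicates(ds, policy = "fuzzy", review_file = rf)
  expect_equal(attr(cl, "n_clusters"), 2)  # never auto-merged
  rev <- utils::read.csv(rf)
  expect_equal(nrow(rev), 1)
  expect_true(rev$similarity >= 0.9)
})

test_that("merge_clusters unions provenance and sites, applies dates", {
  nodes <- data.frame(workshop_id = c("W1", "W1", "W3"),
                      local_id = c("a", "b", "a"),
                      label = c("Shared node", "Only here", "shared NODE"),
                      site = c("bradford", "bradford", "lbth"))
  ds <- toy_raw(nodes)
  cl <- find_duplicates(ds)
  coding <- as_coding_table(c("Shared node", "Only here"),
                            c("event", "event"),
                            c("activity", "output"),
                            c("knowledge_evidence", "research_capacity"))
  dates <- as_date_table("Shared node", "2020-05", "member_check")
  cn <- merge_clusters(ds, cl, coding, dates)
  expect_equal(nrow(cn), 2)
  shared <- cn[cn$label == "Shared node", ]
  expect_equal(shared$sites, "bradford;lbth")
  expect_equal(shared$provenance, "W1:a;W3:a")
  expect_equal(shared$n_records, 2L)
  expect_equal(shared$date, "2020-05")
  expect_equal(shared$date_source, "member_check")
  only <- cn[cn$label == "Only here", ]
  expect_equal(only$n_records, 1L)
  expect_true(is.na(only$ym))
  expect_equal(only$date_source, "none")
  # a date for a conceptual-flagged label is a contradiction
  coding2 <- as_coding_table(c("Shared node", "Only here"),
                             c("conceptual", "event"))
  expect_error(merge_clusters(ds, cl, coding2, dates),
               "contradiction error.*Shared node")
  # missing kind flag is an error
  coding3 <- as_coding_table("Shared node", "event")
  expect_error(merge_clusters(ds, cl, coding3, dates), "kind flag missing")
})

test_that("consolidation is invariant to workshop order", {
  fx <- random_fixture(7)
  parts <- lapply(fx$dataset$workshop_ids, function(ws) {
    rem_dataset(fx$dataset$nodes[fx$dataset$nodes$workshop_id == ws, ],
                fx$dataset$edges[fx$dataset$edges$workshop_id == ws, ])
  })
  fit1 <- run_pipeline(fx)
  ds2 <- merge_datasets(rev(parts))
  fit2 <- suppressWarnings(meta_rem(ds2, fx$coding, fx$aliases, fx$dates))
  expect_identical(fit1$nodes$canonical_id, fit2$nodes$canonical_id)
  expect_identical(fit1$nodes$provenance, fit2$nodes$provenance)
  expect_identical(fit1$nodes$sites, fit2$nodes$sites)
})

test_that("dedup partition identity holds on random fixtures", {
  for (seed in c(11, 23, 35)) {
    fx <- random_fixture(seed)
    cl <- find_duplicates(fx$dataset, fx$aliases)
    expect_equal(attr(cl, "n_records"),
                 attr(cl, "n_clusters") + attr(cl, "n_duplicates"))
    expect_equal(attr(cl, "n_records"), nrow(fx$dataset$nodes))
    # cluster sizes sum to the record count
    expect_equal(sum(table(cl$cluster_id)), nrow(fx$dataset$nodes))
    # matches the generator's planted partition
    truth_sizes <- sort(as.integer(table(tolower(fx$truth$clusters$label))))
    got_sizes <- sort(as.integer(table(cl$cluster_id)))
    expect_identical(got_sizes, truth_sizes)
  }
})
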