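# Shared toy constructors and independent oracles.

toy_raw <- function(nodes, edges = NULL, site = "unknown") {
  # nodes: data.frame(workshop_id, local_id, label); edges likewise
  if (is.null(edges)) {
    edges <- data.frame(workshop_id = character(0), ripple_id = character(0),
                        from_local = character(0), to_local = character(0),
                        stringsAsFactors = FALSE)
  }
  rem_dataset(nodes, edges, default_site = site)
}

toy_nodes <- function(ids, kind = "event", date = NA_character_,
                      stage = NA_character_, group = NA_character_,
                      sites = "unknown") {
  n <- length(ids)
  parsed <- ym_parse(rep_len(date, n))
  data.frame(canonical_id = ids, label = ids,
             kind = rep_len(kind, n), date = parsed$date, ym = parsed$ym,
             date_precision = parsed$precision,
             date_source = ifelse(is.na(parsed$ym), "none", "participant"),
             stage = rep_len(stage, n), group = rep_len(group, n),
             sites = rep_len(sites, n), workshops = "W1",
             provenance = paste0("W1:", ids), n_records = 1L,
             stringsAsFactors = FALSE)
}

toy_edges <- function(from, to, ripple_id = "r1", workshop_id = "W1") {
  data.frame(from = from, to = to,
             ripple_id = rep_len(ripple_id, length(from)),
             workshop_id = rep_len(workshop_id, length(from)),
             stringsAsFactors = FALSE)
}

# Independent reachability oracle for the exclusion policy, built on igraph.
oracle_cascade_included <- function(nodes, edges) {
  removed <- nodes$canonical_id[nodes$kind == "conceptual" |
                                  (nodes$kind == "event" & is.na(nodes$ym))]
  inc <- character(0)
  for (rid in unique(edges$ripple_id)) {
    e <- edges[edges$ripple_id == rid, , drop = FALSE]
    mem <- unique(c(e$from, e$to))
    origins <- setdiff(mem, e$to)
    dated <- setdiff(mem, removed)
    seeds <- intersect(origins, dated)
    ge <- e[e$from %in% dated & e$to %in% dated, , drop = FALSE]
    g <- igraph::graph_from_data_frame(ge[, c("from", "to")],
                                       directed = TRUE,
                                       vertices = data.frame(name = dated))
    reach <- unique(unlist(lapply(seeds, function(s0) {
      names(igraph::subcomponent(g, s0, mode = "out"))
    })))
    live <- ge[ge$from %in% reach & ge$to %in% reach, , drop = FALSE]
    inc <- c(inc, intersect(reach, unique(c(live$from, live$to))))
  }
  sort(unique(inc))
}

# Random small ripple instance (DAG, possibly several ripples) with random
# unplaceable flags, for oracle-equivalence trials.
random_instance <- function(n, n_ripples = NULL) {
  ids <- sprintf("v%02d", seq_len(n))
  if (is.null(n_ripples)) n_ripples <- sample(1:3, 1)
  grp <- sort(sample(seq_len(n_ripples), n, replace = TRUE))
  kind <- sample(c("event", "conceptual"), n, replace = TRUE,
                 prob = c(0.85, 0.15))
  date <- ifelse(kind == "event" & stats::runif(n) > 0.25,
                 sprintf("20%02d-%02d", sample(19:23, n, replace = TRUE),
                         sample(1:12, n, replace = TRUE)),
                 NA_character_)
  nodes <- toy_nodes(ids)
  nodes$kind <- kind
  parsed <- ym_parse(date)
  nodes$ym <- parsed$ym
  nodes$date <- parsed$date
  nodes$date_precision <- parsed$precision
  from <- character(0); to <- character(0); rid <- character(0)
  for (g in unique(grp)) {
    at <- which(grp == g)
    if (length(at) < 2) next
    for (i in seq_along(at)[-1]) {
      from <- c(from, ids[at[sample.int(i - 1, 1)]])
      to <- c(to, ids[at[i]])
      rid <- c(rid, paste0("r", g))
    }
    # extra forward edges keep it a DAG but not a tree
    extra <- which(stats::runif(length(at)) < 0.2)
    for (i in setdiff(extra, 1)) {
      j <- sample.int(i - 1, 1)
      from <- c(from, ids[at[j]]); to <- c(to, ids[at[i]])
      rid <- c(rid, paste0("r", g))
    }
  }
  e <- unique(toy_edges(from, to, ripple_id = rid))
  list(nodes = nodes, edges = e)
}

# Random generator parameters that respect the generator's feasibility
# rules; regenerates on an infeasible draw.
random_fixture <- function(seed) {
  for (try in 0:10) {
    s <- seed + try * 100003L
    set.seed(s)
    n_w <- sample(2:5, 1)
    n_unique <- sample(18:40, 1)
    n_conc <- sample(0:4, 1)
    n_und <- sample(0:5, 1)
    n_dated <- n_unique - n_conc - n_und
    n_casc <- if ((n_und + n_conc) >= 1 && n_dated >= 10) sample(0:4, 1)
      else 0L
    n_dup <- sample(0:6, 1)
    fx <- tryCatch(
      generate_rem_fixture(rem_fixture_params(
        n_workshops = n_w, n_records = n_unique + n_dup,
        n_duplicates = n_dup, n_conceptual = n_conc, n_undatable = n_und,
        n_cascade = n_casc, seed = s)),
      error = function(e) NULL)
    if (!is.null(fx)) return(fx)
  }
  stop("random_fixture: no feasible draw near seed ", seed)
}

run_pipeline <- function(fx, ...) {
  suppressWarnings(meta_rem(fx$dataset, fx$coding, fx$aliases, fx$dates,
                            ...))
}

label_of <- function(fit) {
  stats::setNames(fit$nodes$label, fit$nodes$canonical_id)
}

meta_map_equal <- function(a, b) {
  df_eq <- function(x, y) {
    isTRUE(all.equal(as.data.frame(x), as.data.frame(y),
                     check.attributes = FALSE))
  }
  df_eq(a$nodes, b$nodes) && df_eq(a$edges, b$edges) &&
    df_eq(a$bins, b$bins) &&
    identical(a$bin_width, b$bin_width) &&
    identical(names(a$node_bin), names(b$node_bin)) &&
    identical(as.integer(unname(a$node_bin)),
              as.integer(unname(b$node_bin)))
}

write_csv_tmp <- function(df, dir, name) {
  p <- file.path(dir, name)
  utils::write.csv(df, p, row.names = FALSE)
  p
}
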