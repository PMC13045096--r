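# Seeded synthetic-workshop generator with planted ground truth.
#
# The generator builds the meta-REM inputs backwards from the quantities the
# pipeline is supposed to recover. Clean ripples are random trees over dated
# labels whose dates never decrease along an edge. The cascade is planted by
# direct construction: dedicated subtrees of the form
#   origin -> survivor            (keeps the origin pair included)
#   origin -> breaker -> chain    (breaker unplaceable; the dated chain
#                                  behind it is lost)
# sized so the lost chains total exactly the cascade target. Undatable and
# conceptual labels not used as breakers are attached as leaves, which break
# nothing. Duplicate records are extra appearances of dated labels in other
# workshops' ripples, attached so dates still run forwards.

#' Parameters for the synthetic-workshop generator
#'
#' The defaults are the study conditions of the packaged case study: five
#' workshops, 440 raw node records of which 74 are duplicates, 54 conceptual
#' labels, 63 undatable event labels, a cascade loss of 76, dates spanning
#' January 2019 to October 2023.
#'
#' @param n_workshops number of workshops.
#' @param n_records total raw node records across all workshops.
#' @param n_duplicates records beyond the first appearance of their label.
#' @param n_conceptual unique conceptual (undatable-by-nature) labels.
#' @param n_undatable unique event labels with no verified date.
#' @param n_cascade dated event labels the default exclusion policy must
#'   remove.
#' @param ripple_size two-element range for clean-ripple node counts.
#' @param branching_prob probability a new ripple node attaches to a random
#'   earlier node instead of the previous one (tree branching).
#' @param date_window `c("YYYY-MM", "YYYY-MM")` programme window.
#' @param stage_weights,group_weights sampling weights for logic-model
#'   codes.
#' @param stage_counts,group_counts optional exact code counts over the
#'   included labels (named integer vectors summing to the included count);
#'   used by the replica profile to plant printed marginals.
#' @param n_alias number of alias-map abbreviation variants to plant.
#' @param profile `NULL` or `"actearly-replica"` (themed labels, planted
#'   multiplicities and exact code marginals).
#' @param seed integer RNG seed; identical parameters and seed reproduce
#'   byte-identical fixtures.
#' @return A validated list of class `rem_fixture_params`.
#' @export
rem_fixture_params <- function(n_workshops = 5L, n_records = 440L,
                               n_duplicates = 74L, n_conceptual = 54L,
                               n_undatable = 63L, n_cascade = 76L,
                               ripple_size = c(4L, 10L),
                               branching_prob = 0.3,
                               date_window = c("2019-01", "2023-10"),
                               stage_weights = c(input = 0.08,
                                                 activity = 0.38,
                                                 output = 0.32,
                                                 outcome = 0.14,
                                                 impact = 0.08),
                               group_weights = c(
                                 knowledge_evidence = 0.55,
                                 research_capacity = 0.18,
                                 coproduction_citizen_science = 0.12,
                                 data_infrastructure = 0.08,
                                 wider_system_context = 0.07),
                               stage_counts = NULL, group_counts = NULL,
                               n_alias = 2L, profile = NULL, seed = 2019L) {
  p <- list(n_workshops = as.integer(n_workshops),
            n_records = as.integer(n_records),
            n_duplicates = as.integer(n_duplicates),
            n_conceptual = as.integer(n_conceptual),
            n_undatable = as.integer(n_undatable),
            n_cascade = as.integer(n_cascade),
            ripple_size = as.integer(ripple_size),
            branching_prob = branching_prob,
            date_window = date_window,
            stage_weights = stage_weights, group_weights = group_weights,
            stage_counts = stage_counts, group_counts = group_counts,
            n_alias = as.integer(n_alias),
            profile = profile, seed = as.integer(seed))
  p$n_unique <- p$n_records - p$n_duplicates
  p$n_event <- p$n_unique - p$n_conceptual
  p$n_dated <- p$n_event - p$n_undatable
  p$n_included <- p$n_dated - p$n_cascade
  with(p, {
    if (n_workshops < 1L) stop("feasibility error: need >= 1 workshop",
                               call. = FALSE)
    if (n_duplicates < 0L || n_duplicates >= n_records) {
      stop("feasibility error: duplicates must be < total records",
           call. = FALSE)
    }
    if (n_event < 0L || n_dated < 0L || n_included < 0L) {
      stop("feasibility error: conceptual + undatable + cascade exceed the ",
           "unique label count", call. = FALSE)
    }
    if (n_cascade > 0L && (n_undatable + n_conceptual) < 1L) {
      stop("feasibility error: a cascade needs at least one unplaceable ",
           "breaker label", call. = FALSE)
    }
    if (n_cascade > 0L && n_included < 2L) {
      stop("feasibility error: cascade planting needs >= 2 included labels",
           call. = FALSE)
    }
    if (n_duplicates > 0L && n_workshops < 2L) {
      stop("feasibility error: duplicates need >= 2 workshops",
           call. = FALSE)
    }
  })
  w <- ym_parse(p$date_window)
  if (nrow(w) != 2L || any(is.na(w$ym)) || w$ym[1] > w$ym[2]) {
    stop("feasibility error: invalid date window", call. = FALSE)
  }
  structure(p, class = "rem_fixture_params")
}

rem_event_vocab <- function(n) {
  themes <- c("Healthy Places", "Healthy Learning", "Food and Healthy Weight",
              "Play and Physical Activity", "Healthy Livelihoods",
              "Evaluation")
  things <- c("project", "pilot study", "workshop series", "data linkage",
              "community event", "training programme", "partnership",
              "funding award", "publication", "policy briefing")
  grid <- expand.grid(theme = themes, thing = things,
                      stringsAsFactors = FALSE)
  k <- nrow(grid)
  idx <- seq_len(n)
  sprintf("%s %s %03d", grid$theme[(idx - 1L) %% k + 1L],
          grid$thing[(idx - 1L) %% k + 1L], (idx - 1L) %/% k + 1L)
}

rem_conceptual_vocab <- function(n) {
  base <- c("Relationship building", "Trust between partners",
            "Shared learning culture", "Raised programme visibility",
            "Momentum for coproduction", "Research-minded practice",
            "Cross-sector goodwill", "Community confidence")
  idx <- seq_len(n)
  sprintf("%s %02d", base[(idx - 1L) %% length(base) + 1L],
          (idx - 1L) %/% length(base) + 1L)
}

replica_named_labels <- function() {
  data.frame(
    label = c("Universal Basic Income and mental health project",
              "Healthier Wealthier Families project pilot",
              "Families in Tower Hamlets project",
              "Evaluation theme research group",
              "Food and Healthy Weight theme research group",
              "Bradford Health Determinants Research Collaboration",
              "Tower Hamlets Health Determinants Research Collaboration",
              "Nothing about us Without Us coproduction strategy",
              "Community engagement researcher posts"),
    group = c("knowledge_evidence", "knowledge_evidence",
              "knowledge_evidence", "research_capacity", "research_capacity",
              "research_capacity", "research_capacity",
              "coproduction_citizen_science", "coproduction_citizen_science"),
    extras = c(2L, 2L, 2L, 4L, 3L, 2L, 2L, 2L, 2L),
    stringsAsFactors = FALSE)
}

pick <- function(x, n = 1L) x[sample.int(length(x), n)]

#' Generate a synthetic multi-workshop REM fixture
#'
#' Deterministic given the seed. The returned ground truth records exactly
#' what the default pipeline policies should recover: the duplicate
#' partition, the kind/date/code of every label, and the included /
#' undatable / conceptual / cascade-excluded sets.
#'
#' @param params a [rem_fixture_params()] object.
#' @return A list of class `rem_fixture` with elements `dataset`
#'   ([rem_dataset()]), `aliases`, `dates`, `coding`, `truth` and `params`.
#' @export
generate_rem_fixture <- function(params = rem_fixture_params()) {
  stopifnot(inherits(params, "rem_fixture_params"))
  set.seed(params$seed)
  p <- params
  w <- ym_parse(p$date_window)
  w0 <- w$ym[1]; w1 <- w$ym[2]
  replica <- identical(p$profile, "actearly-replica")

  conceptual_labels <- rem_conceptual_vocab(p$n_conceptual)
  ev <- rem_event_vocab(p$n_event)
  included_labels <- if (p$n_included) ev[seq_len(p$n_included)] else
    character(0)
  cascade_labels <- if (p$n_cascade)
    ev[p$n_included + seq_len(p$n_cascade)] else character(0)
  undatable_labels <- if (p$n_undatable)
    ev[p$n_included + p$n_cascade + seq_len(p$n_undatable)] else character(0)
  named <- if (replica) replica_named_labels() else NULL
  protected <- integer(0)
  if (replica) {
    stopifnot(p$n_included >= nrow(named))
    included_labels[seq_len(nrow(named))] <- named$label
    protected <- seq_len(nrow(named))
  }

  # Dates of included labels: sorted, so label index order is date order.
  ym_of <- integer(0)
  if (p$n_included >= 2L) {
    ym_incl <- sort(c(w0, w1, sample(w0:w1, p$n_included - 2L,
                                     replace = TRUE)))
  } else if (p$n_included == 1L) {
    ym_incl <- sample(w0:w1, 1L)
  } else ym_incl <- integer(0)
  ym_of <- stats::setNames(ym_incl, included_labels)

  # ---- sacrifice structures carrying the cascade ------------------------
  s <- 0L; chunk_sizes <- integer(0)
  if (p$n_cascade > 0L) {
    reserve <- if (p$n_duplicates > 0L) 2L else 0L
    s_max <- min(p$n_undatable + p$n_conceptual,
                 (p$n_included - reserve) %/% 2L, p$n_cascade)
    s <- min(max(1L, ceiling(p$n_cascade / 2)), s_max)
    if (s < 1L) {
      stop("feasibility error: cascade target unreachable with so few ",
           "included or unplaceable labels", call. = FALSE)
    }
    chunk_sizes <- rep(p$n_cascade %/% s, s)
    extra <- p$n_cascade %% s
    if (extra) chunk_sizes[seq_len(extra)] <- chunk_sizes[seq_len(extra)] + 1L
  }
  breaker_pool <- c(undatable_labels, conceptual_labels)
  breakers <- if (s) breaker_pool[seq_len(s)] else character(0)
  leaf_labels <- setdiff(c(undatable_labels, conceptual_labels), breakers)

  cand <- setdiff(seq_len(p$n_included), protected)
  if (length(cand) < 2L * s) {
    stop("feasibility error: not enough unprotected included labels for ",
         "cascade planting", call. = FALSE)
  }
  sac_idx <- if (s) sort(pick(cand, 2L * s)) else integer(0)
  clean_idx <- setdiff(seq_len(p$n_included), sac_idx)

  ripples <- list()   # each: list(members = labels in order, edges = df)

  edge_df <- function(from, to) {
    data.frame(from = from, to = to, stringsAsFactors = FALSE)
  }

  xi <- 0L
  for (k in seq_len(s)) {
    la <- included_labels[sac_idx[2L * k - 1L]]
    lb <- included_labels[sac_idx[2L * k]]
    u <- breakers[k]
    xs <- cascade_labels[xi + seq_len(chunk_sizes[k])]
    xi <- xi + chunk_sizes[k]
    ym_of[xs] <- pmin(w1, ym_of[[la]] + seq_along(xs))
    chain_from <- c(u, xs[-length(xs)])
    edges <- edge_df(c(la, la, chain_from), c(lb, u, xs))
    ripples[[length(ripples) + 1L]] <- list(members = c(la, lb, u, xs),
                                            edges = edges)
  }

  pl <- length(clean_idx)
  n_clean <- 0L
  clean_ripple_ids <- integer(0)
  if (pl >= 2L) {
    n_clean <- max(1L, min(pl %/% 2L, round(pl / mean(p$ripple_size))))
    for (j in seq_len(n_clean)) {
      members <- included_labels[clean_idx[seq.int(j, pl, by = n_clean)]]
      from <- character(0); to <- character(0)
      for (i in seq_along(members)[-1]) {
        parent <- if (i > 2L && stats::runif(1) < p$branching_prob) {
          pick(seq_len(i - 1L))
        } else i - 1L
        from <- c(from, members[parent]); to <- c(to, members[i])
      }
      ripples[[length(ripples) + 1L]] <- list(members = members,
                                              edges = edge_df(from, to))
      clean_ripple_ids <- c(clean_ripple_ids, length(ripples))
    }
  } else if (pl == 1L) {
    # a lone leftover label joins the last sacrifice pair's surviving edge
    if (s) {
      lab <- included_labels[clean_idx]
      ym_of[lab] <- max(ym_of[[lab]],
                        ym_of[[ripples[[s]]$members[2]]])
      ripples[[s]]$edges <- rbind(ripples[[s]]$edges,
                                  edge_df(ripples[[s]]$members[2], lab))
      ripples[[s]]$members <- c(ripples[[s]]$members, lab)
    } else if (p$n_included == 1L) {
      stop("feasibility error: a single included label cannot form a ripple",
           call. = FALSE)
    }
  }

  # locate home ripple of each included label
  home_of <- character(0)
  for (ri in seq_along(ripples)) {
    for (m in ripples[[ri]]$members) home_of[m] <- as.character(ri)
  }

  # undatable/conceptual leaves: attach to a dated anchor's home ripple
  anchors <- included_labels
  if (!length(anchors) && length(leaf_labels)) {
    # degenerate fixture with no datable core: chain the leaves up in pairs
    if (length(leaf_labels) < 2L) {
      stop("feasibility error: a single unplaceable label cannot form a ",
           "ripple", call. = FALSE)
    }
    for (i in seq(1L, length(leaf_labels) - 1L, by = 2L)) {
      a <- leaf_labels[i]
      b <- leaf_labels[min(i + 1L, length(leaf_labels))]
      ripples[[length(ripples) + 1L]] <- list(members = c(a, b),
                                              edges = edge_df(a, b))
    }
    if (length(leaf_labels) %% 2L == 1L) {
      # odd leftover joins the last pair as a second child
      last <- length(ripples)
      a <- ripples[[last]]$members[1]
      b <- leaf_labels[length(leaf_labels)]
      ripples[[last]]$edges <- rbind(ripples[[last]]$edges, edge_df(a, b))
      ripples[[last]]$members <- c(ripples[[last]]$members, b)
    }
    leaf_labels <- character(0)
  }
  for (leaf in leaf_labels) {
    a <- pick(anchors)
    ri <- as.integer(home_of[[a]])
    ripples[[ri]]$edges <- rbind(ripples[[ri]]$edges, edge_df(a, leaf))
    ripples[[ri]]$members <- c(ripples[[ri]]$members, leaf)
  }

  # refresh: every unique label's home ripple (leaves included)
  home_of <- character(0)
  for (ri in seq_along(ripples)) {
    for (m in ripples[[ri]]$members) home_of[m] <- as.character(ri)
  }

  # ---- workshops --------------------------------------------------------
  n_r <- length(ripples)
  wids <- sprintf("W%d", seq_len(p$n_workshops))
  sites <- if (p$n_workshops == 5L) {
    c("bradford", "bradford", "lbth", "both", "both")
  } else rep_len(c("bradford", "lbth", "both"), p$n_workshops)
  names(sites) <- wids
  ripple_ws <- character(n_r)
  ripple_ws[sample.int(n_r)] <- wids[(seq_len(n_r) - 1L) %% p$n_workshops +
                                       1L]

  # ---- duplicate appearances -------------------------------------------
  # planted multiplicities for the replica's named labels, then a shuffled
  # fill of (label, workshop) pairs over the clean pool. Extra appearances
  # may join any ripple whose origin is dated (clean or sacrifice): an
  # attachment below an excluded chain node is itself dropped by the
  # exclusion policy, so the planted sets stay exact, while the label still
  # gains a ripple membership through its surviving home ripple.
  eligible_ripples <- c(seq_len(s), clean_ripple_ids)
  home_ws_of <- function(lab) ripple_ws[as.integer(home_of[[lab]])]
  appearances <- list()  # per extra appearance: label, ws, ripple index
  used_pair <- character(0)
  origin_of <- vapply(ripples, function(r) r$members[1], character(1))

  attach_dup <- function(lab, ws) {
    cand_r <- eligible_ripples[ripple_ws[eligible_ripples] == ws]
    cand_r <- cand_r[vapply(cand_r, function(ri) {
      !(lab %in% ripples[[ri]]$members)
    }, logical(1))]
    if (!length(cand_r)) return(FALSE)
    ri <- pick(cand_r)
    mem <- ripples[[ri]]$members
    dated <- mem[mem %in% names(ym_of)]
    par_cand <- dated[ym_of[dated] <= ym_of[[lab]]]
    if (length(par_cand)) {
      parent <- par_cand[which.max(ym_of[par_cand])]
      ripples[[ri]]$edges <<- rbind(ripples[[ri]]$edges,
                                    edge_df(parent, lab))
    } else {
      ripples[[ri]]$edges <<- rbind(ripples[[ri]]$edges,
                                    edge_df(lab, origin_of[[ri]]))
      origin_of[[ri]] <<- lab
    }
    ripples[[ri]]$members <<- c(ripples[[ri]]$members, lab)
    appearances[[length(appearances) + 1L]] <<- list(label = lab, ws = ws)
    used_pair <<- c(used_pair, paste(lab, ws, sep = "\r"))
    TRUE
  }

  n_placed <- 0L
  if (p$n_duplicates > 0L) {
    dup_pool <- included_labels[clean_idx]
    ws_elig <- unique(ripple_ws[eligible_ripples])
    if (replica) {
      for (i in seq_len(nrow(named))) {
        lab <- named$label[i]
        elig <- setdiff(ws_elig, home_ws_of(lab))
        elig <- pick(elig, min(named$extras[i], length(elig)))
        for (ws in elig) {
          if (n_placed >= p$n_duplicates) break
          if (attach_dup(lab, ws)) n_placed <- n_placed + 1L
        }
      }
      dup_pool <- setdiff(dup_pool, named$label)
    }
    pairs <- expand.grid(label = dup_pool, ws = ws_elig,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$ws != vapply(pairs$label, home_ws_of,
                                      character(1)), , drop = FALSE]
    pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
    for (i in seq_len(nrow(pairs))) {
      if (n_placed >= p$n_duplicates) break
      key <- paste(pairs$label[i], pairs$ws[i], sep = "\r")
      if (key %in% used_pair) next
      if (attach_dup(pairs$label[i], pairs$ws[i])) n_placed <- n_placed + 1L
    }
    if (n_placed < p$n_duplicates) {
      stop("feasibility error: could not place ", p$n_duplicates,
           " duplicate records (placed ", n_placed, "); too few clean ",
           "ripples or workshops", call. = FALSE)
    }
  }

  # ---- alias variants ---------------------------------------------------
  variant_of <- character(0)
  if (replica) {
    variant_of <- c(
      "hwf pilot" = "Healthier Wealthier Families project pilot",
      "UBI project" = "Universal Basic Income and mental health project",
      "HDRC Bradford" = "Bradford Health Determinants Research Collaboration")
    variant_of <- stats::setNames(unname(variant_of), names(variant_of))
  } else if (p$n_alias > 0L && length(appearances)) {
    dup_labs <- unique(vapply(appearances, `[[`, character(1), "label"))
    take <- utils::head(dup_labs, p$n_alias)
    for (lab in take) {
      v <- unname(abbreviate(lab, minlength = 8L, strict = TRUE))
      if (!norm_key(v) %in% norm_key(c(conceptual_labels, ev))) {
        variant_of[v] <- lab
      }
    }
  }
  alias_map <- if (length(variant_of)) {
    as_alias_map(names(variant_of), unname(variant_of))
  } else structure(character(0), class = "rem_aliases")
  variant_used <- stats::setNames(rep(FALSE, length(variant_of)),
                                  unname(variant_of))

  # ---- emit node and edge records --------------------------------------
  node_rows <- list(); edge_rows <- list()
  for (ws in wids) {
    rids <- which(ripple_ws == ws)
    if (!length(rids)) next  # more workshops than ripples: leave it empty
    labs <- unique(unlist(lapply(ripples[rids], `[[`, "members"),
                          use.names = FALSE))
    local <- stats::setNames(sprintf("n%03d", seq_along(labs)), labs)
    raw <- labs
    for (i in seq_along(labs)) {
      lab <- labs[i]
      is_home <- identical(home_ws_of(lab), ws)
      if (!is_home && length(variant_of) && lab %in% variant_of &&
          !variant_used[[lab]]) {
        raw[i] <- names(variant_of)[match(lab, variant_of)]
        variant_used[[lab]] <- TRUE
      } else if (!is_home && stats::runif(1) < 0.3) {
        raw[i] <- paste0(" ", sub(" ", "  ", lab), " ")  # whitespace noise
      }
    }
    node_rows[[ws]] <- data.frame(workshop_id = ws, local_id = unname(local),
                                  label = raw, site = unname(sites[ws]),
                                  stringsAsFactors = FALSE)
    for (ri in rids) {
      e <- ripples[[ri]]$edges
      if (!nrow(e)) next
      edge_rows[[length(edge_rows) + 1L]] <- data.frame(
        workshop_id = ws, ripple_id = sprintf("R%03d", ri),
        from_local = unname(local[e$from]), to_local = unname(local[e$to]),
        stringsAsFactors = FALSE)
    }
  }
  nodes_df <- do.call(rbind, node_rows)
  edges_df <- if (length(edge_rows)) do.call(rbind, edge_rows) else
    data.frame(workshop_id = character(0), ripple_id = character(0),
               from_local = character(0), to_local = character(0),
               stringsAsFactors = FALSE)
  rownames(nodes_df) <- rownames(edges_df) <- NULL
  dataset <- rem_dataset(nodes_df, edges_df)
  stopifnot(nrow(dataset$nodes) == p$n_records)

  # ---- date table -------------------------------------------------------
  dated_labels <- c(included_labels, cascade_labels)
  dates <- if (length(dated_labels)) {
    as_date_table(dated_labels, ym_format(ym_of[dated_labels]),
                  sample(c("participant", "member_check", "document"),
                         length(dated_labels), replace = TRUE,
                         prob = c(0.5, 0.25, 0.25)))
  } else as_date_table(character(0), character(0), character(0))

  # ---- logic-model coding ----------------------------------------------
  stage_of <- group_of <- stats::setNames(
    rep(NA_character_, p$n_unique),
    c(conceptual_labels, included_labels, cascade_labels, undatable_labels))
  draw <- function(n, weights) {
    if (n == 0L) return(character(0))
    sample(names(weights), n, replace = TRUE, prob = weights)
  }
  if (p$n_included) {
    if (!is.null(p$stage_counts)) {
      stopifnot(sum(p$stage_counts) == p$n_included)
      # stages progress along the timeline: inputs earliest, impacts last
      ordered <- c("input", "activity", "output", "outcome", "impact")
      stage_of[included_labels] <-
        rep(ordered, p$stage_counts[ordered])
    } else {
      stage_of[included_labels] <- draw(p$n_included, p$stage_weights)
    }
    if (!is.null(p$group_counts)) {
      stopifnot(sum(p$group_counts) == p$n_included)
      counts <- p$group_counts
      rest <- included_labels
      if (replica) {
        group_of[named$label] <- named$group
        for (g in unique(named$group)) {
          counts[g] <- counts[g] - sum(named$group == g)
        }
        stopifnot(all(counts >= 0L))
        rest <- setdiff(included_labels, named$label)
      }
      if (length(rest)) group_of[rest] <- sample(rep(names(counts), counts))
    } else {
      group_of[included_labels] <- draw(p$n_included, p$group_weights)
    }
  }
  other_ev <- c(cascade_labels, undatable_labels)
  stage_of[other_ev] <- draw(length(other_ev), p$stage_weights)
  group_of[other_ev] <- draw(length(other_ev), p$group_weights)
  all_labels <- c(conceptual_labels, included_labels, cascade_labels,
                  undatable_labels)
  coding <- as_coding_table(
    all_labels,
    c(rep("conceptual", p$n_conceptual), rep("event", length(all_labels) -
                                               p$n_conceptual)),
    unname(stage_of[all_labels]), unname(group_of[all_labels]))

  truth <- list(
    clusters = {
      cl <- find_raw_truth_clusters(dataset, alias_map)
      cl
    },
    kind = stats::setNames(coding$kind, coding$label),
    date = stats::setNames(ym_format(ym_of[dated_labels]), dated_labels),
    stage = stage_of, group = group_of,
    included = sort(included_labels),
    undatable = sort(undatable_labels),
    conceptual = sort(conceptual_labels),
    cascade_excluded = sort(cascade_labels),
    n_records = p$n_records, n_duplicates = p$n_duplicates,
    n_unique = p$n_unique)

  structure(list(dataset = dataset, aliases = alias_map, dates = dates,
                 coding = coding, truth = truth, params = p),
            class = "rem_fixture")
}

# True record partition by construction: canonicalise raw labels the same
# way the generator wrote them (whitespace squish + alias expansion).
find_raw_truth_clusters <- function(dataset, aliases) {
  lab <- canonicalize_label(dataset$nodes$label, aliases)
  data.frame(workshop_id = dataset$nodes$workshop_id,
             local_id = dataset$nodes$local_id, label = lab,
             stringsAsFactors = FALSE)
}

#' @export
print.rem_fixture <- function(x, ...) {
  p <- x$params
  cat("Synthetic REM fixture (seed ", p$seed,
      if (!is.null(p$profile)) paste0(", profile ", p$profile), "):\n",
      sep = "")
  cat("  ", p$n_records, " records over ", p$n_workshops, " workshops; ",
      p$n_duplicates, " duplicates, ", p$n_conceptual, " conceptual, ",
      p$n_undatable, " undatable, cascade target ", p$n_cascade, "\n",
      sep = "")
  invisible(x)
}

#' The packaged replica of the case-study counts
#'
#' A fixed-seed profile of [generate_rem_fixture()]: five workshops, 440 raw
#' records, 74 duplicates, 54 conceptual labels, 63 undatable event labels,
#' 76 dated labels lost to cascade exclusion and 173 included, with
#' logic-model codes planted so the included nodes tally to 71 activities,
#' 63 outputs, 114 knowledge-and-evidence and 31 research-capacity nodes,
#' and themed labels whose ripple multiplicities put the two theme research
#' groups at the top of the influence ranking.
#'
#' @return A `rem_fixture`.
#' @export
actearly_replica <- function() {
  generate_rem_fixture(rem_fixture_params(
    profile = "actearly-replica",
    stage_counts = c(input = 12L, activity = 71L, output = 63L,
                     outcome = 18L, impact = 9L),
    group_counts = c(knowledge_evidence = 114L, research_capacity = 31L,
                     coproduction_citizen_science = 12L,
                     data_infrastructure = 9L, wider_system_context = 7L),
    seed = 2019L))
}

#' Write a fixture to a directory of plain-text tables
#'
#' Writes per-workshop node/edge CSVs (`nodes_W1.csv`, ...), combined
#' `nodes.csv`/`edges.csv`, `aliases.csv`, `dates.csv`, `coding.csv` and a
#' `truth.json` ground-truth document (all synthetic).
#'
#' @param fixture a `rem_fixture`.
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "rem_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- fixture$dataset
  utils::write.csv(ds$nodes, file.path(dir, "nodes.csv"), row.names = FALSE)
  utils::write.csv(ds$edges, file.path(dir, "edges.csv"), row.names = FALSE)
  for (ws in ds$workshop_ids) {
    utils::write.csv(ds$nodes[ds$nodes$workshop_id == ws, ],
                     file.path(dir, paste0("nodes_", ws, ".csv")),
                     row.names = FALSE)
    utils::write.csv(ds$edges[ds$edges$workshop_id == ws, ],
                     file.path(dir, paste0("edges_", ws, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(data.frame(variant = names(fixture$aliases),
                              canonical = unname(unclass(fixture$aliases)),
                              stringsAsFactors = FALSE),
                   file.path(dir, "aliases.csv"), row.names = FALSE)
  utils::write.csv(data.frame(canonical_label = fixture$dates$label,
                              date = fixture$dates$date,
                              source = fixture$dates$source,
                              stringsAsFactors = FALSE),
                   file.path(dir, "dates.csv"), row.names = FALSE)
  utils::write.csv(data.frame(canonical_label = fixture$coding$label,
                              kind = fixture$coding$kind,
                              stage = fixture$coding$stage,
                              group = fixture$coding$group,
                              stringsAsFactors = FALSE),
                   file.path(dir, "coding.csv"), row.names = FALSE)
  jsonlite::write_json(fixture$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, null = "null", na = "null")
  invisible(dir)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir the directory.
#' @return A list with `dataset`, `aliases`, `dates`, `coding`.
#' @export
read_fixture <- function(dir) {
  list(dataset = read_dataset(file.path(dir, "nodes.csv"),
                              file.path(dir, "edges.csv")),
       aliases = read_alias_map(file.path(dir, "aliases.csv")),
       dates = read_date_table(file.path(dir, "dates.csv")),
       coding = read_coding_table(file.path(dir, "coding.csv")))
}
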