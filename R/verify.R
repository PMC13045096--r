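# Temporal verification and exclusion. Ripples are read as forward ripples:
# arrows indicating the passage of time only go forwards, so within a ripple
# the source of an edge may never post-date its target. Nodes that cannot be
# placed on the timeline (conceptual phenomena, or events whose date could
# not be verified) are excluded; a dated node is also lost when its only
# connection to a ripple's origin runs through an unplaceable node.

#' Check temporal ordering of ripple edges
#'
#' Returns exactly the edges whose source date exceeds the target date at
#' the requested granularity; equal (truncated) dates are not violations.
#' Edges with an undated endpoint are skipped. Year-precision dates compare
#' at year granularity regardless of the `granularity` argument, so a
#' year-only verification is never flagged against a month within that year.
#'
#' @param nodes a [merge_clusters()] result.
#' @param edges a [canonical_edges()] result.
#' @param granularity comparison granularity: `"month"` (default),
#'   `"quarter"` or `"year"`.
#' @return A data.frame of violations: `from`, `to`, `ripple_id`,
#'   `from_date`, `to_date`.
#' @export
check_temporal_order <- function(nodes, edges,
                                 granularity = c("month", "quarter", "year")) {
  granularity <- match.arg(granularity)
  ym <- stats::setNames(nodes$ym, nodes$canonical_id)
  prec <- stats::setNames(nodes$date_precision, nodes$canonical_id)
  f <- ym[edges$from]
  t <- ym[edges$to]
  keep <- !is.na(f) & !is.na(t)
  gran <- rep(granularity, nrow(edges))
  yr_only <- !is.na(prec[edges$from]) & prec[edges$from] == "year" |
             !is.na(prec[edges$to]) & prec[edges$to] == "year"
  gran[yr_only] <- "year"
  fl <- function(v, g) {
    out <- v
    for (w in c("month", "quarter", "year")) {
      at <- which(g == w)
      out[at] <- ym_floor(v[at], w)
    }
    out
  }
  viol <- keep & fl(f, gran) > fl(t, gran)
  out <- data.frame(from = edges$from[viol], to = edges$to[viol],
                    ripple_id = edges$ripple_id[viol],
                    from_date = ym_format(f[viol]),
                    to_date = ym_format(t[viol]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Kahn topological check; returns TRUE when the edge set is acyclic.
edges_acyclic <- function(from, to) {
  verts <- unique(c(from, to))
  indeg <- table(factor(to, levels = verts))
  adj <- split(to, factor(from, levels = verts))
  queue <- verts[indeg == 0]
  seen <- 0L
  indeg <- as.integer(indeg)
  names(indeg) <- verts
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    seen <- seen + 1L
    for (w in adj[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  seen == length(verts)
}

#' Exclude unplaceable nodes and the ripple segments they disconnect
#'
#' Partitions the canonical nodes into four disjoint sets whose union is all
#' nodes: `conceptual` (cannot sit on a timeline by nature), `undatable`
#' (event nodes with no verified date), `included` and `cascade_excluded`
#' (dated event nodes lost because their ripple linkage passes through an
#' unplaceable node).
#'
#' Under the default `"reachability"` policy each ripple is treated
#' separately: unplaceable nodes and their incident edges are removed, and a
#' dated node survives in that ripple iff a directed path from one of the
#' ripple's origin nodes (no incoming edge within the ripple's full edge
#' set, and itself dated) reaches it using only dated nodes, and it retains
#' at least one surviving edge there. A node is included overall iff it
#' survives in at least one ripple. Under `"strict_ripple"` any unplaceable
#' member discards the whole ripple.
#'
#' @param nodes a [merge_clusters()] result (or any data.frame with columns
#'   `canonical_id`, `kind`, `ym`).
#' @param edges a [canonical_edges()] result.
#' @param policy `"reachability"` (default) or `"strict_ripple"`.
#' @return An object of class `rem_exclusion`: a list with sorted character
#'   vectors `included`, `undatable`, `conceptual`, `cascade_excluded`, and
#'   `per_ripple`, a list of surviving node ids per ripple.
#' @export
cascade_exclude <- function(nodes, edges,
                            policy = c("reachability", "strict_ripple")) {
  policy <- match.arg(policy)
  ids <- nodes$canonical_id
  conceptual <- ids[nodes$kind == "conceptual"]
  undatable <- ids[nodes$kind == "event" & is.na(nodes$ym)]
  removed <- c(conceptual, undatable)
  per_ripple <- list()
  for (rid in unique(edges$ripple_id)) {
    e <- edges[edges$ripple_id == rid, , drop = FALSE]
    if (!edges_acyclic(e$from, e$to)) {
      stop("structural error: ripple ", sQuote(rid),
           " contains a cycle; ripples are drawn as forward ripples",
           call. = FALSE)
    }
    members <- unique(c(e$from, e$to))
    bad <- intersect(members, removed)
    if (policy == "strict_ripple") {
      per_ripple[[rid]] <- if (length(bad)) character(0) else members
      next
    }
    dated <- setdiff(members, bad)
    keep <- e$from %in% dated & e$to %in% dated
    origins <- setdiff(members, e$to)          # no incoming edge in ripple
    frontier <- intersect(origins, dated)
    reached <- frontier
    while (length(frontier)) {
      nxt <- unique(e$to[keep & e$from %in% frontier])
      frontier <- setdiff(nxt, reached)
      reached <- c(reached, frontier)
    }
    live <- keep & e$from %in% reached & e$to %in% reached
    per_ripple[[rid]] <- intersect(reached,
                                   unique(c(e$from[live], e$to[live])))
  }
  included <- sort(unique(unlist(per_ripple, use.names = FALSE)))
  dated_all <- ids[nodes$kind == "event" & !is.na(nodes$ym)]
  structure(list(included = included,
                 undatable = sort(undatable),
                 conceptual = sort(conceptual),
                 cascade_excluded = sort(setdiff(dated_all, included)),
                 per_ripple = per_ripple,
                 policy = policy),
            class = "rem_exclusion")
}

#' @export
print.rem_exclusion <- function(x, ...) {
  cat("REM exclusion (policy = ", x$policy, "):\n",
      "  included:          ", length(x$included), "\n",
      "  undatable:         ", length(x$undatable), "\n",
      "  conceptual:        ", length(x$conceptual), "\n",
      "  cascade excluded:  ", length(x$cascade_excluded), "\n", sep = "")
  invisible(x)
}

#' Tabulate an exclusion result for reporting
#'
#' @param exclusion a [cascade_exclude()] result.
#' @param edges the canonical edge list (used to list the ripples each node
#'   belongs to).
#' @return A data.frame with columns `canonical_id`, `category`, `reason`,
#'   `ripple_ids`.
#' @export
exclusion_report <- function(exclusion, edges) {
  cat_of <- c(stats::setNames(rep("included", length(exclusion$included)),
                              exclusion$included),
              stats::setNames(rep("undatable", length(exclusion$undatable)),
                              exclusion$undatable),
              stats::setNames(rep("conceptual", length(exclusion$conceptual)),
                              exclusion$conceptual),
              stats::setNames(rep("cascade_excluded",
                                  length(exclusion$cascade_excluded)),
                              exclusion$cascade_excluded))
  reason <- c(included = "dated and reachable within at least one ripple",
              undatable = "event node with no verified date",
              conceptual = "conceptual node; cannot be placed on a timeline",
              cascade_excluded =
                "linked within a ripple only through an unplaceable node")
  ids <- sort(names(cat_of))
  rips <- vapply(ids, function(id) {
    paste(sort(unique(edges$ripple_id[edges$from == id | edges$to == id])),
          collapse = ";")
  }, character(1))
  data.frame(canonical_id = ids, category = unname(cat_of[ids]),
             reason = unname(reason[cat_of[ids]]), ripple_ids = unname(rips),
             stringsAsFactors = FALSE)
}
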