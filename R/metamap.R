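# The meta-map: all surviving ripples merged into one time-binned directed
# graph, plus the accounting report that tracks every node from raw
# extraction to inclusion.

#' Build the meta-map from surviving ripples
#'
#' Restricts nodes and edges to the included set, so duplicate-derived nodes
#' appear once and join up the ripples of all their provenance workshops,
#' and assigns every node to a time bin. Bins are contiguous,
#' non-overlapping, and cover the span from the earliest to the latest
#' included date.
#'
#' @param nodes a [merge_clusters()] result.
#' @param edges a [canonical_edges()] result.
#' @param exclusion a [cascade_exclude()] result.
#' @param bin_width `"quarter"` (default), `"month"` or `"year"`.
#' @return An object of class `meta_rem_map`: a list with `nodes`, `edges`,
#'   `bins` (data.frame `label`, `start`, `end`), `node_bin` (named integer,
#'   1-based bin index per node) and `bin_width`.
#' @export
build_meta_map <- function(nodes, edges, exclusion,
                           bin_width = c("quarter", "month", "year")) {
  bin_width <- match.arg(bin_width)
  stopifnot(inherits(exclusion, "rem_exclusion"))
  inc <- nodes[nodes$canonical_id %in% exclusion$included, , drop = FALSE]
  inc <- inc[order(inc$canonical_id), ]
  rownames(inc) <- NULL
  keep <- edges$from %in% inc$canonical_id & edges$to %in% inc$canonical_id
  e <- edges[keep, , drop = FALSE]
  rownames(e) <- NULL
  if (!nrow(inc)) {
    warning("empty meta-map: no nodes could be included", call. = FALSE)
    bins <- data.frame(label = character(0), start = character(0),
                       end = character(0), stringsAsFactors = FALSE)
    return(structure(list(nodes = inc, edges = e, bins = bins,
                          node_bin = stats::setNames(integer(0), character(0)),
                          bin_width = bin_width),
                     class = "meta_rem_map"))
  }
  step <- switch(bin_width, month = 1L, quarter = 3L, year = 12L)
  lo <- ym_floor(min(inc$ym), bin_width)
  hi <- ym_floor(max(inc$ym), bin_width)
  starts <- seq.int(lo, hi, by = step)
  bins <- data.frame(label = bin_label(starts, bin_width),
                     start = ym_format(starts),
                     end = ym_format(starts + step - 1L),
                     stringsAsFactors = FALSE)
  node_bin <- (ym_floor(inc$ym, bin_width) - lo) %/% step + 1L
  names(node_bin) <- inc$canonical_id
  structure(list(nodes = inc, edges = e, bins = bins, node_bin = node_bin,
                 bin_width = bin_width),
            class = "meta_rem_map")
}

#' @export
print.meta_rem_map <- function(x, ...) {
  cat("Meta-REM map: ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges, ", length(unique(x$edges$ripple_id)), " ripples, ",
      nrow(x$bins), " ", x$bin_width, " bins\n", sep = "")
  invisible(x)
}

#' Nodes whose ripples were expanded across workshops
#'
#' A ripple drawn in one workshop is expanded when one of its nodes also
#' carries edges from a ripple drawn in another workshop; the shared node
#' links the two chains of consequences into a longer pathway. Returns the
#' nodes whose incident meta-map edges span at least two distinct workshops.
#'
#' @param map a [build_meta_map()] result.
#' @return A data.frame sorted by `canonical_id`: columns `canonical_id`,
#'   `ripple_ids`, `workshop_ids` (';'-joined).
#' @export
expanded_ripples <- function(map) {
  stopifnot(inherits(map, "meta_rem_map"))
  e <- map$edges
  out <- lapply(map$nodes$canonical_id, function(id) {
    at <- e$from == id | e$to == id
    ws <- unique(e$workshop_id[at])
    if (length(ws) < 2L) return(NULL)
    data.frame(canonical_id = id,
               ripple_ids = paste(sort(unique(e$ripple_id[at])),
                                  collapse = ";"),
               workshop_ids = paste(sort(ws), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(canonical_id = character(0), ripple_ids = character(0),
                      workshop_ids = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' The node accounting report
#'
#' Counts every node from raw extraction to meta-map inclusion and enforces
#' the three identities that tie the pipeline together:
#' `raw_total = duplicates + unique`, `unique = conceptual + event`, and
#' `event = dated_included + undatable + cascade_excluded`. A violation
#' signals a pipeline bug and is an error, never silently reported.
#'
#' @param dataset the raw [rem_dataset()].
#' @param clusters the [find_duplicates()] result.
#' @param nodes the [merge_clusters()] result.
#' @param exclusion the [cascade_exclude()] result.
#' @return A one-row data.frame of class `rem_accounting` with columns
#'   `raw_total`, `duplicates`, `unique`, `conceptual`, `event`,
#'   `dated_included`, `undatable`, `cascade_excluded`.
#' @export
accounting <- function(dataset, clusters, nodes, exclusion) {
  out <- data.frame(
    raw_total = nrow(dataset$nodes),
    duplicates = attr(clusters, "n_duplicates"),
    unique = attr(clusters, "n_clusters"),
    conceptual = sum(nodes$kind == "conceptual"),
    event = sum(nodes$kind == "event"),
    dated_included = length(exclusion$included),
    undatable = length(exclusion$undatable),
    cascade_excluded = length(exclusion$cascade_excluded))
  ok <- out$raw_total == out$duplicates + out$unique &&
    out$unique == out$conceptual + out$event &&
    out$event == out$dated_included + out$undatable + out$cascade_excluded
  if (!ok) {
    stop("internal consistency error: accounting identities violated (",
         paste(names(out), unlist(out), sep = "=", collapse = ", "), ")",
         call. = FALSE)
  }
  class(out) <- c("rem_accounting", "data.frame")
  out
}

#' @export
print.rem_accounting <- function(x, ...) {
  cat("REM node accounting\n")
  cat(sprintf("  raw records            %5d\n", x$raw_total))
  cat(sprintf("  - duplicates           %5d\n", x$duplicates))
  cat(sprintf("  = unique nodes         %5d\n", x$unique))
  cat(sprintf("    conceptual           %5d\n", x$conceptual))
  cat(sprintf("    event                %5d\n", x$event))
  cat(sprintf("      dated, included    %5d\n", x$dated_included))
  cat(sprintf("      undatable          %5d\n", x$undatable))
  cat(sprintf("      cascade excluded   %5d\n", x$cascade_excluded))
  invisible(x)
}

#' Serialize a meta-map to three tables
#'
#' Writes the meta-map in the same two-table template the ingest side reads,
#' plus a bins table. [build_meta_map()] on the re-read tables reproduces
#' the map.
#'
#' @param map a `meta_rem_map`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_meta_map <- function(map, dir) {
  stopifnot(inherits(map, "meta_rem_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- map$nodes
  nodes$bin <- unname(map$node_bin[nodes$canonical_id])
  paths <- file.path(dir, c("meta_nodes.csv", "meta_edges.csv",
                            "meta_bins.csv"))
  utils::write.csv(nodes, paths[1], row.names = FALSE)
  utils::write.csv(map$edges, paths[2], row.names = FALSE)
  utils::write.csv(map$bins, paths[3], row.names = FALSE)
  invisible(paths)
}
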