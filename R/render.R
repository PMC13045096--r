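# Rendering: Graphviz DOT with date-aligned ranks, and a JSON document for
# interactive viewers. The DOT output never runs a layout engine; it is a
# plain-text digraph whose rank constraints make nodes line up with the
# dates of the events. An invisible timeline spine (one node per occupied
# bin, chained left to right) anchors one same-rank group per bin.

#' Styling for rendered meta-maps
#'
#' Shapes encode the logic-model stage and colours the activity group. The
#' defaults give every stage and group a mapping; partial overrides are
#' merged over them.
#'
#' @param shape_by_stage,color_by_group named character vectors overriding
#'   individual defaults.
#' @param highlight optional character vector of canonical ids or ripple ids
#'   to emphasise (thicker border / bold edge).
#' @return An object of class `rem_style`.
#' @export
rem_style <- function(shape_by_stage = NULL, color_by_group = NULL,
                      highlight = NULL) {
  shapes <- c(input = "box", activity = "ellipse", output = "diamond",
              outcome = "hexagon", impact = "doubleoctagon",
              uncoded = "ellipse")
  colors <- c(research_capacity = "#66c2a5",
              knowledge_evidence = "#8da0cb",
              coproduction_citizen_science = "#fc8d62",
              data_infrastructure = "#e78ac3",
              wider_system_context = "#a6d854",
              uncoded = "#cccccc")
  if (length(shape_by_stage)) shapes[names(shape_by_stage)] <- shape_by_stage
  if (length(color_by_group)) colors[names(color_by_group)] <- color_by_group
  structure(list(shape_by_stage = shapes, color_by_group = colors,
                 highlight = highlight),
            class = "rem_style")
}

#' Read style overrides from a YAML file
#'
#' Flat keys `shape_by_stage`, `color_by_group` and `highlight` mirroring
#' the [rem_style()] arguments.
#'
#' @param file YAML path.
#' @return An object of class `rem_style`.
#' @export
read_style_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  rem_style(shape_by_stage = unlist(cfg$shape_by_stage),
            color_by_group = unlist(cfg$color_by_group),
            highlight = cfg$highlight)
}

dot_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

#' Emit the meta-map as Graphviz DOT
#'
#' The document reads left to right along the timeline: one invisible spine
#' node per occupied bin, chained by invisible edges in chronological order,
#' with a same-rank group per occupied bin holding its spine node and all
#' nodes dated within the bin. Parallel edges (the same node pair in
#' different ripples) are collapsed to a single drawn edge with a
#' multiplicity label; analytics always work on the uncollapsed edge set.
#' Output is byte-identical across runs on identical input.
#'
#' @param map a [build_meta_map()] result.
#' @param style a [rem_style()].
#' @return A single string of DOT source.
#' @export
to_dot <- function(map, style = rem_style()) {
  stopifnot(inherits(map, "meta_rem_map"), inherits(style, "rem_style"))
  lines <- c("digraph meta_rem {",
             "  rankdir=LR;",
             "  node [fontname=\"Helvetica\", style=filled];")
  occupied <- sort(unique(unname(map$node_bin)))
  spine <- paste0("bin_", map$bins$label[occupied])
  if (length(spine)) {
    lines <- c(lines, paste0("  ", dot_quote(spine),
                             " [shape=point, style=invis, label=",
                             dot_quote(map$bins$label[occupied]), "];"))
    if (length(spine) > 1) {
      lines <- c(lines,
                 paste0("  ", dot_quote(spine[-length(spine)]), " -> ",
                        dot_quote(spine[-1]), " [style=invis];"))
    }
  }
  hl <- style$highlight
  for (i in seq_along(occupied)) {
    b <- occupied[i]
    ids <- sort(names(map$node_bin)[map$node_bin == b])
    lines <- c(lines, paste0("  { rank=same; ", dot_quote(spine[i]), "; ",
                             paste(dot_quote(ids), collapse = "; "), "; }"))
  }
  nodes <- map$nodes[order(map$nodes$canonical_id), , drop = FALSE]
  for (i in seq_len(nrow(nodes))) {
    stage <- nodes$stage[i]
    if (is.na(stage)) stage <- "uncoded"
    group <- nodes$group[i]
    if (is.na(group)) group <- "uncoded"
    extra <- if (!is.null(hl) && nodes$canonical_id[i] %in% hl) {
      ", penwidth=3"
    } else ""
    lines <- c(lines, paste0(
      "  ", dot_quote(nodes$canonical_id[i]),
      " [label=", dot_quote(paste0(nodes$label[i], "\\n", nodes$date[i])),
      ", shape=", style$shape_by_stage[[stage]],
      ", fillcolor=", dot_quote(style$color_by_group[[group]]),
      extra, "];"))
  }
  if (nrow(map$edges)) {
    e <- map$edges
    pair <- paste(e$from, e$to, sep = "\r")
    agg <- lapply(split(seq_len(nrow(e)), pair), function(idx) {
      data.frame(from = e$from[idx[1]], to = e$to[idx[1]],
                 n = length(unique(e$ripple_id[idx])),
                 hl = !is.null(hl) && any(e$ripple_id[idx] %in% hl),
                 stringsAsFactors = FALSE)
    })
    agg <- do.call(rbind, agg)
    agg <- agg[order(agg$from, agg$to), ]
    lab <- ifelse(agg$n > 1L, paste0("label=\"x", agg$n, "\""), "")
    pen <- ifelse(agg$hl, "penwidth=3", "")
    both <- ifelse(nzchar(lab) & nzchar(pen),
                   paste0(lab, ", ", pen), paste0(lab, pen))
    attrs <- ifelse(nzchar(both), paste0(" [", both, "]"), "")
    lines <- c(lines, paste0("  ", dot_quote(agg$from), " -> ",
                             dot_quote(agg$to), attrs, ";"))
  }
  paste0(paste(c(lines, "}"), collapse = "\n"), "\n")
}

#' Export the meta-map as JSON
#'
#' A flat document with `nodes` (id, label, date, stage, group, sites,
#' ripples, bin), `edges` (from, to, ripple_id, workshop_id) and `bins`.
#' [meta_map_from_json()] restores an equal `meta_rem_map`.
#'
#' @param map a [build_meta_map()] result.
#' @param style optional [rem_style()] embedded for viewers.
#' @return A JSON string.
#' @export
to_json <- function(map, style = NULL) {
  stopifnot(inherits(map, "meta_rem_map"))
  e <- map$edges
  ripples_of <- function(id) {
    sort(unique(e$ripple_id[e$from == id | e$to == id]))
  }
  n <- map$nodes
  nodes <- lapply(seq_len(nrow(n)), function(i) {
    list(id = n$canonical_id[i], label = n$label[i], date = n$date[i],
         date_precision = n$date_precision[i],
         date_source = n$date_source[i],
         stage = n$stage[i], group = n$group[i],
         sites = strsplit(n$sites[i], ";", fixed = TRUE)[[1]],
         workshops = strsplit(n$workshops[i], ";", fixed = TRUE)[[1]],
         provenance = strsplit(n$provenance[i], ";", fixed = TRUE)[[1]],
         n_records = n$n_records[i],
         ripples = ripples_of(n$canonical_id[i]),
         bin = unname(map$node_bin[n$canonical_id[i]]))
  })
  doc <- list(bin_width = map$bin_width,
              bins = map$bins,
              nodes = nodes,
              edges = e)
  if (!is.null(style)) doc$style <- unclass(style)
  jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, na = "null",
                   digits = NA)
}

#' Rebuild a meta-map from its JSON export
#'
#' @param txt JSON string or path produced by [to_json()].
#' @return A `meta_rem_map` equal to the exported one.
#' @export
meta_map_from_json <- function(txt) {
  doc <- jsonlite::fromJSON(txt, simplifyDataFrame = TRUE,
                            simplifyVector = TRUE)
  ns <- doc$nodes
  rejoin <- function(v) {
    vapply(v, function(x) paste(x, collapse = ";"), character(1))
  }
  scal <- function(v) {
    v <- as.character(v)
    v[!is.na(v) & v == "NA"] <- NA_character_
    v
  }
  if (is.null(ns) || !length(ns)) {
    nodes <- data.frame(canonical_id = character(0), label = character(0),
                        kind = character(0), date = character(0),
                        ym = integer(0), date_precision = character(0),
                        date_source = character(0), stage = character(0),
                        group = character(0), sites = character(0),
                        workshops = character(0), provenance = character(0),
                        n_records = integer(0), stringsAsFactors = FALSE)
    node_bin <- stats::setNames(integer(0), character(0))
  } else {
    parsed <- ym_parse(ns$date)
    nodes <- data.frame(canonical_id = ns$id, label = ns$label,
                        kind = "event", date = ns$date, ym = parsed$ym,
                        date_precision = scal(ns$date_precision),
                        date_source = scal(ns$date_source),
                        stage = scal(ns$stage), group = scal(ns$group),
                        sites = rejoin(ns$sites),
                        workshops = rejoin(ns$workshops),
                        provenance = rejoin(ns$provenance),
                        n_records = as.integer(ns$n_records),
                        stringsAsFactors = FALSE)
    node_bin <- stats::setNames(as.integer(ns$bin), ns$id)
  }
  nodes <- nodes[order(nodes$canonical_id), ]
  rownames(nodes) <- NULL
  class(nodes) <- c("rem_nodes", "data.frame")
  ed <- doc$edges
  if (is.null(ed) || !length(ed) || !nrow(as.data.frame(ed))) {
    edges <- data.frame(from = character(0), to = character(0),
                        ripple_id = character(0), workshop_id = character(0),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(ed, stringsAsFactors = FALSE)
  }
  class(edges) <- c("rem_edges", "data.frame")
  bins <- as.data.frame(doc$bins, stringsAsFactors = FALSE)
  if (!nrow(bins)) {
    bins <- data.frame(label = character(0), start = character(0),
                       end = character(0), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, bins = bins,
                 node_bin = node_bin[nodes$canonical_id],
                 bin_width = doc$bin_width),
            class = "meta_rem_map")
}
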