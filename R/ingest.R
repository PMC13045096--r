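# Reading and validating per-workshop REM exports. A workshop export is the
# two-sheet workbook of the coding template flattened to two CSV tables:
# a node sheet (one row per activity recorded on the map) and a ripple-edge
# sheet (one row per arrow, grouped into ripples).

REM_SITES <- c("bradford", "lbth", "both", "unknown")

req_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("format error in ", what, ": missing column(s) ",
         paste(sQuote(missing), collapse = ", "), call. = FALSE)
  }
}

read_table_chr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = TRUE)
  df
}

#' Construct a validated REM dataset
#'
#' The raw dataset is the union of node records and ripple edges extracted
#' from one or more workshop outputs. All structural invariants are enforced
#' here: unique `(workshop_id, local_id)` pairs, non-empty labels, edge
#' endpoints that resolve within their workshop, no self-edges, and ripples
#' that do not span workshops. Ripples whose edges do not form a weakly
#' connected subgraph trigger a warning (hand-drawn maps contain stray
#' marks), not an error.
#'
#' @param nodes data.frame with columns `workshop_id`, `local_id`, `label`
#'   and optionally `site` (one of `"bradford"`, `"lbth"`, `"both"`,
#'   `"unknown"`).
#' @param edges data.frame with columns `workshop_id`, `ripple_id`,
#'   `from_local`, `to_local`.
#' @param default_site site used where the `site` column is absent or blank.
#' @return An object of class `rem_dataset`: a list with elements `nodes`,
#'   `edges` and `workshop_ids`.
#' @export
rem_dataset <- function(nodes, edges = NULL, default_site = "unknown") {
  if (is.null(edges)) {
    edges <- data.frame(workshop_id = character(0), ripple_id = character(0),
                        from_local = character(0), to_local = character(0),
                        stringsAsFactors = FALSE)
  }
  req_cols(nodes, c("workshop_id", "local_id", "label"), "node table")
  req_cols(edges, c("workshop_id", "ripple_id", "from_local", "to_local"),
           "edge table")
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  for (cl in c("workshop_id", "local_id", "label")) {
    nodes[[cl]] <- as.character(nodes[[cl]])
  }
  if (!"site" %in% names(nodes)) nodes$site <- default_site
  nodes$site <- tolower(trimws(as.character(nodes$site)))
  nodes$site[is.na(nodes$site) | !nzchar(nodes$site)] <- default_site
  bad_site <- setdiff(unique(nodes$site), REM_SITES)
  if (length(bad_site)) {
    stop("format error: unknown site value(s) ",
         paste(sQuote(bad_site), collapse = ", "), call. = FALSE)
  }
  nodes$label <- as.character(nodes$label)
  if (any(is.na(nodes$label) | !nzchar(trimws(nodes$label)))) {
    stop("format error: empty node label(s) at row(s) ",
         paste(which(is.na(nodes$label) | !nzchar(trimws(nodes$label))),
               collapse = ", "), call. = FALSE)
  }
  key <- paste(nodes$workshop_id, nodes$local_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("uniqueness error: duplicate (workshop_id, local_id) pair(s): ",
         paste(gsub("\r", ":", dup), collapse = ", "), call. = FALSE)
  }
  for (cl in c("workshop_id", "ripple_id", "from_local", "to_local")) {
    edges[[cl]] <- as.character(edges[[cl]])
  }
  if (nrow(edges)) {
    self <- edges$from_local == edges$to_local
    if (any(self)) {
      stop("reference error: self-edge(s) at edge row(s) ",
           paste(which(self), collapse = ", "), call. = FALSE)
    }
    fk <- paste(edges$workshop_id, edges$from_local, sep = "\r")
    tk <- paste(edges$workshop_id, edges$to_local, sep = "\r")
    bad <- !(fk %in% key) | !(tk %in% key)
    if (any(bad)) {
      ids <- unique(c(edges$from_local[!(fk %in% key)],
                      edges$to_local[!(tk %in% key)]))
      stop("reference error: edge row(s) ",
           paste(which(bad), collapse = ", "),
           " reference unknown local_id(s): ",
           paste(sQuote(ids), collapse = ", "), call. = FALSE)
    }
    rw <- unique(edges[, c("ripple_id", "workshop_id")])
    if (anyDuplicated(rw$ripple_id)) {
      stop("reference error: ripple_id(s) spanning multiple workshops: ",
           paste(unique(rw$ripple_id[duplicated(rw$ripple_id)]),
                 collapse = ", "), call. = FALSE)
    }
    check_ripple_connectivity(edges)
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes[, c("workshop_id", "local_id", "label", "site")],
                 edges = edges[, c("workshop_id", "ripple_id",
                                   "from_local", "to_local")],
                 workshop_ids = unique(nodes$workshop_id)),
            class = "rem_dataset")
}

# Warn for ripples whose edge set is not weakly connected.
check_ripple_connectivity <- function(edges) {
  for (rid in unique(edges$ripple_id)) {
    e <- edges[edges$ripple_id == rid, , drop = FALSE]
    verts <- unique(c(e$from_local, e$to_local))
    comp <- seq_along(verts)
    names(comp) <- verts
    find <- function(v) {
      while (comp[[v]] != match(v, verts)) v <- verts[comp[[v]]]
      v
    }
    for (i in seq_len(nrow(e))) {
      a <- find(e$from_local[i]); b <- find(e$to_local[i])
      if (a != b) comp[[a]] <- match(b, verts)
    }
    roots <- unique(vapply(verts, find, character(1)))
    if (length(roots) > 1L) {
      warning("ripple ", sQuote(rid), " is not weakly connected (",
              length(roots), " components)", call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Read one workshop's REM export
#'
#' Reads the node and edge tables of a single workshop and returns a
#' validated [rem_dataset()] restricted to that workshop.
#'
#' @param nodes_file,edges_file paths to CSV tables (UTF-8, header row).
#' @param workshop_id the workshop to keep; defaults to the single workshop
#'   present in the node table (an error if there are several).
#' @param default_site site recorded when the node table has no `site`
#'   column; workshops held in one locality typically declare it here.
#' @return A `rem_dataset` containing one workshop.
#' @export
read_workshop <- function(nodes_file, edges_file, workshop_id = NULL,
                          default_site = "unknown") {
  nodes <- read_table_chr(nodes_file)
  edges <- read_table_chr(edges_file)
  req_cols(nodes, c("workshop_id", "local_id", "label"), nodes_file)
  req_cols(edges, c("workshop_id", "ripple_id", "from_local", "to_local"),
           edges_file)
  if (is.null(workshop_id)) {
    ws <- unique(nodes$workshop_id)
    if (length(ws) != 1L) {
      stop("format error: ", nodes_file, " contains ", length(ws),
           " workshops; pass workshop_id", call. = FALSE)
    }
    workshop_id <- ws
  }
  nodes <- nodes[nodes$workshop_id == workshop_id, , drop = FALSE]
  edges <- edges[edges$workshop_id == workshop_id, , drop = FALSE]
  if (!nrow(nodes)) {
    stop("format error: no node records for workshop ", sQuote(workshop_id),
         call. = FALSE)
  }
  rem_dataset(nodes, edges, default_site = default_site)
}

#' Read a combined multi-workshop dataset from two tables
#'
#' @inheritParams read_workshop
#' @return A `rem_dataset` possibly spanning several workshops.
#' @export
read_dataset <- function(nodes_file, edges_file, default_site = "unknown") {
  rem_dataset(read_table_chr(nodes_file), read_table_chr(edges_file),
              default_site = default_site)
}

#' Write a dataset back to the two-table format
#'
#' Inverse of [read_dataset()]: `read_dataset()` on the written files yields
#' an equal dataset.
#'
#' @param dataset a `rem_dataset`.
#' @param nodes_file,edges_file output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(dataset, nodes_file, edges_file) {
  stopifnot(inherits(dataset, "rem_dataset"))
  utils::write.csv(dataset$nodes, nodes_file, row.names = FALSE)
  utils::write.csv(dataset$edges, edges_file, row.names = FALSE)
  invisible(c(nodes_file, edges_file))
}

#' Merge disjoint per-workshop datasets
#'
#' Takes the union of record sets; workshop ids must be pairwise disjoint.
#' The order of the parts does not affect the resulting record sets.
#'
#' @param parts a list of `rem_dataset` objects (or several passed via
#'   `...`).
#' @param ... alternative to `parts`.
#' @return A combined `rem_dataset`.
#' @export
merge_datasets <- function(parts = list(), ...) {
  if (!is.list(parts) || inherits(parts, "rem_dataset")) parts <- list(parts)
  parts <- c(parts, list(...))
  parts <- parts[vapply(parts, function(p) !is.null(p), logical(1))]
  if (!length(parts)) stop("merge_datasets: no datasets given", call. = FALSE)
  stopifnot(all(vapply(parts, inherits, logical(1), "rem_dataset")))
  ws <- unlist(lapply(parts, `[[`, "workshop_ids"))
  if (anyDuplicated(ws)) {
    stop("conflict error: workshop_id(s) present in more than one part: ",
         paste(unique(ws[duplicated(ws)]), collapse = ", "), call. = FALSE)
  }
  nodes <- do.call(rbind, lapply(parts, `[[`, "nodes"))
  edges <- do.call(rbind, lapply(parts, `[[`, "edges"))
  rem_dataset(nodes, edges)
}

#' @export
print.rem_dataset <- function(x, ...) {
  cat("REM dataset: ", nrow(x$nodes), " node records, ",
      nrow(x$edges), " edges, ",
      length(unique(x$edges$ripple_id)), " ripples, ",
      length(x$workshop_ids), " workshop(s)\n", sep = "")
  invisible(x)
}

#' Read an alias map for label expansion
#'
#' Alias entries expand abbreviated or shorthand node labels to their full
#' canonical form (abbreviations spelled out in full). The map must be flat:
#' no canonical label may itself map onward to another canonical label.
#'
#' @param file CSV with columns `variant`, `canonical`.
#' @return A named character vector of class `rem_aliases`; names are
#'   normalised variant keys, values are canonical display labels.
#' @export
read_alias_map <- function(file) {
  df <- read_table_chr(file)
  if (!nrow(df)) {
    return(structure(character(0), class = "rem_aliases"))
  }
  req_cols(df, c("variant", "canonical"), file)
  as_alias_map(df$variant, df$canonical)
}

#' Build an alias map from vectors
#' @param variant,canonical character vectors of equal length.
#' @return An object of class `rem_aliases`.
#' @export
as_alias_map <- function(variant, canonical) {
  keys <- norm_key(variant)
  vals <- squish_ws(canonical)
  if (anyDuplicated(keys)) {
    stop("alias error: duplicate variant(s): ",
         paste(unique(variant[duplicated(keys)]), collapse = ", "),
         call. = FALSE)
  }
  # chain check: a canonical label must not be a variant of something else
  tgt_keys <- norm_key(vals)
  hit <- match(tgt_keys, keys)
  chained <- !is.na(hit) & vals[hit] != vals
  if (any(chained)) {
    stop("alias chain error: canonical label(s) map onward: ",
         paste(sQuote(unique(vals[chained])), collapse = ", "),
         call. = FALSE)
  }
  structure(stats::setNames(vals, keys), class = "rem_aliases")
}

#' Read the date-verification table
#'
#' One row per canonical label whose date could be verified, with the source
#' of the verification. Dates are `"YYYY-MM"` or year-only `"YYYY"`;
#' year-only entries are flagged as reduced precision and compare at year
#' precision in temporal checks.
#'
#' @param file CSV with columns `canonical_label`, `date`, `source`
#'   (`participant`, `member_check` or `document`).
#' @param window optional two-element character vector giving the programme
#'   window (`c("YYYY-MM", "YYYY-MM")`); dates outside it are an error.
#' @return A data.frame of class `rem_dates` with columns `label`, `key`,
#'   `ym`, `precision`, `date`, `source`.
#' @export
read_date_table <- function(file, window = NULL) {
  df <- read_table_chr(file)
  if (!nrow(df)) {
    out <- data.frame(label = character(0), key = character(0),
                      ym = integer(0), precision = character(0),
                      date = character(0), source = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("rem_dates", "data.frame")
    return(out)
  }
  req_cols(df, c("canonical_label", "date", "source"), file)
  as_date_table(df$canonical_label, df$date, df$source, window = window)
}

#' Build a date table from vectors
#' @inheritParams read_date_table
#' @param label,date,source equal-length character vectors.
#' @return An object of class `rem_dates`.
#' @export
as_date_table <- function(label, date, source, window = NULL) {
  n <- length(label)
  if (n == 0L) {
    out <- data.frame(label = character(0), key = character(0),
                      ym = integer(0), precision = character(0),
                      date = character(0), source = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("rem_dates", "data.frame")
    return(out)
  }
  parsed <- vector("list", n)
  for (i in seq_len(n)) {
    parsed[[i]] <- tryCatch(ym_parse(date[i]), error = function(e) {
      stop("date format error at row ", i, ": ", conditionMessage(e),
           call. = FALSE)
    })
  }
  parsed <- do.call(rbind, parsed)
  if (any(is.na(parsed$ym))) {
    stop("date format error at row ", which(is.na(parsed$ym))[1],
         ": empty date", call. = FALSE)
  }
  source <- tolower(trimws(as.character(source)))
  bad <- !source %in% c("participant", "member_check", "document")
  if (any(bad)) {
    stop("date format error at row ", which(bad)[1],
         ": source must be participant, member_check or document",
         call. = FALSE)
  }
  if (!is.null(window)) {
    w <- ym_parse(window)
    out_of <- parsed$ym < w$ym[1] | parsed$ym > w$ym[2]
    if (any(out_of)) {
      stop("date error at row ", which(out_of)[1],
           ": date outside programme window ", window[1], "..", window[2],
           call. = FALSE)
    }
  }
  lab <- squish_ws(label)
  key <- norm_key(lab)
  if (anyDuplicated(key)) {
    stop("date error: duplicate entries for label(s): ",
         paste(unique(lab[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(label = lab, key = key, ym = parsed$ym,
                    precision = parsed$precision, date = parsed$date,
                    source = source, stringsAsFactors = FALSE)
  class(out) <- c("rem_dates", "data.frame")
  out
}

#' Read the logic-model coding table
#'
#' One row per canonical label, carrying the judgement-based codes that the
#' pipeline never infers: whether the node is a datable `event` or a
#' `conceptual` phenomenon, its logic-model stage and its activity group.
#' Each label is coded once regardless of how many workshop outputs it
#' appears in.
#'
#' @param file CSV with columns `canonical_label`, `kind` and optionally
#'   `stage` (`input`, `activity`, `output`, `outcome`, `impact`) and
#'   `group` (`research_capacity`, `knowledge_evidence`,
#'   `coproduction_citizen_science`, `data_infrastructure`,
#'   `wider_system_context`). Blank codes are treated as uncoded.
#' @return A data.frame of class `rem_coding` with columns `label`, `key`,
#'   `kind`, `stage`, `group`.
#' @export
read_coding_table <- function(file) {
  df <- read_table_chr(file)
  req_cols(df, c("canonical_label", "kind"), file)
  as_coding_table(df$canonical_label, df$kind,
                  if ("stage" %in% names(df)) df$stage else NA,
                  if ("group" %in% names(df)) df$group else NA)
}

REM_STAGES <- c("input", "activity", "output", "outcome", "impact")
REM_GROUPS <- c("research_capacity", "knowledge_evidence",
                "coproduction_citizen_science", "data_infrastructure",
                "wider_system_context")

#' Build a coding table from vectors
#' @param label,kind,stage,group vectors; `stage` and `group` may be `NA`.
#' @return An object of class `rem_coding`.
#' @export
as_coding_table <- function(label, kind, stage = NA, group = NA) {
  lab <- squish_ws(label)
  key <- norm_key(lab)
  n <- length(lab)
  norm_enum <- function(x, allowed, what) {
    x <- tolower(trimws(as.character(x)))
    x[!is.na(x) & !nzchar(x)] <- NA_character_
    x <- rep_len(x, n)
    bad <- !is.na(x) & !x %in% allowed
    if (any(bad)) {
      stop("coding error: invalid ", what, " value(s): ",
           paste(sQuote(unique(x[bad])), collapse = ", "), call. = FALSE)
    }
    x
  }
  kind <- norm_enum(kind, c("event", "conceptual"), "kind")
  if (any(is.na(kind))) {
    stop("coding error: kind missing for label(s): ",
         paste(sQuote(lab[is.na(kind)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(key)) {
    stop("coding error: duplicate entries for label(s): ",
         paste(unique(lab[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(label = lab, key = key, kind = kind,
                    stage = norm_enum(stage, REM_STAGES, "stage"),
                    group = norm_enum(group, REM_GROUPS, "group"),
                    stringsAsFactors = FALSE)
  class(out) <- c("rem_coding", "data.frame")
  out
}
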