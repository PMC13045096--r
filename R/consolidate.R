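# Label canonicalisation and cross-workshop duplicate consolidation.
#
# Two raw records denote the same node when their labels agree after
# whitespace normalisation, case folding and alias expansion. Matching is
# deliberately conservative: fuzzy similarity only ever produces a review
# file of candidate pairs for a human decision, never an automatic merge,
# because ambiguous labels were resolved by member checking -- a human step.

squish_ws <- function(x) gsub("[[:space:]]+", " ", trimws(as.character(x)))

# Case-insensitive comparison key of a (display-form) label.
norm_key <- function(x) tolower(squish_ws(x))

#' Canonicalize a raw node label
#'
#' Trims and collapses whitespace, then applies the alias map at most once
#' (matching is case-insensitive). The display form keeps the casing of the
#' alias target where an alias applies, else the original casing. The
#' function is total and idempotent.
#'
#' @param raw_label character vector of raw labels.
#' @param aliases an [as_alias_map()] object, or `NULL` for
#'   normalisation-only behaviour.
#' @return Character vector of canonical display labels.
#' @examples
#' am <- as_alias_map("HWF pilot", "Healthier Wealthier Families project pilot")
#' canonicalize_label("  hwf   pilot ", am)
#' @export
canonicalize_label <- function(raw_label, aliases = NULL) {
  disp <- squish_ws(raw_label)
  if (length(aliases)) {
    hit <- match(tolower(disp), names(aliases))
    disp[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  }
  disp
}

#' Identify duplicate nodes across workshop outputs
#'
#' Clusters every raw node record by canonical label. The clusters partition
#' the records; the duplicate count is `raw records - clusters`. With
#' `policy = "fuzzy"` an additional review table of near-miss label pairs
#' (normalised Levenshtein similarity at or above `fuzzy_threshold`) is
#' written to `review_file`; fuzzy candidates are never merged
#' automatically.
#'
#' @param dataset a validated [rem_dataset()].
#' @param aliases optional alias map.
#' @param policy `"exact"` (default: exact match after normalisation and
#'   aliasing) or `"fuzzy"` (exact clustering plus a candidate-pair review
#'   file).
#' @param review_file path for the fuzzy candidate table; required when
#'   `policy = "fuzzy"`.
#' @param fuzzy_threshold minimum similarity for a candidate pair.
#' @return A data.frame of class `rem_clusters`, one row per raw record,
#'   with columns `workshop_id`, `local_id`, `raw_label`, `canonical_label`,
#'   `cluster_id`, `match_basis`; rows sorted by canonical label, workshop
#'   and local id. Attributes `n_records`, `n_clusters`, `n_duplicates`.
#' @export
find_duplicates <- function(dataset, aliases = NULL,
                            policy = c("exact", "fuzzy"),
                            review_file = NULL, fuzzy_threshold = 0.9) {
  policy <- match.arg(policy)
  stopifnot(inherits(dataset, "rem_dataset"))
  if (policy == "fuzzy" && is.null(review_file)) {
    stop("configuration error: fuzzy policy requires a review_file path",
         call. = FALSE)
  }
  nodes <- dataset$nodes
  disp <- squish_ws(nodes$label)
  basis <- rep("exact_normalized", nrow(nodes))
  if (length(aliases)) {
    hit <- match(tolower(disp), names(aliases))
    basis[!is.na(hit)] <- "alias"
    disp[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  }
  key <- tolower(disp)
  # Display label per cluster: the alias target if any member matched an
  # alias, else the longest member form (ties: lexicographically first).
  canon <- vapply(split(seq_along(key), key), function(idx) {
    al <- idx[basis[idx] == "alias"]
    if (length(al)) return(disp[al[1]])
    forms <- unique(disp[idx])
    forms <- forms[order(-nchar(forms), forms)]
    forms[1]
  }, character(1))
  canonical_label <- unname(canon[match(key, names(canon))])
  out <- data.frame(workshop_id = nodes$workshop_id,
                    local_id = nodes$local_id,
                    raw_label = nodes$label,
                    canonical_label = canonical_label,
                    match_basis = basis,
                    stringsAsFactors = FALSE)
  out <- out[order(out$canonical_label, out$workshop_id, out$local_id), ]
  out$cluster_id <- cumsum(!duplicated(tolower(out$canonical_label)))
  rownames(out) <- NULL
  if (policy == "fuzzy") {
    write_fuzzy_review(unique(out$canonical_label), review_file,
                       fuzzy_threshold)
  }
  structure(out,
            n_records = nrow(out),
            n_clusters = max(0L, out$cluster_id[length(out$cluster_id)]),
            n_duplicates = nrow(out) -
              (if (nrow(out)) out$cluster_id[nrow(out)] else 0L),
            class = c("rem_clusters", "data.frame"))
}

write_fuzzy_review <- function(labels, review_file, threshold) {
  pairs <- data.frame(label_a = character(0), label_b = character(0),
                      similarity = numeric(0), stringsAsFactors = FALSE)
  if (length(labels) > 1) {
    lk <- tolower(labels)
    d <- utils::adist(lk)
    mx <- outer(nchar(lk), nchar(lk), pmax)
    sim <- 1 - d / mx
    idx <- which(upper.tri(sim) & sim >= threshold, arr.ind = TRUE)
    if (nrow(idx)) {
      pairs <- data.frame(label_a = labels[idx[, 1]],
                          label_b = labels[idx[, 2]],
                          similarity = round(sim[idx], 4),
                          stringsAsFactors = FALSE)
      pairs <- pairs[order(-pairs$similarity, pairs$label_a, pairs$label_b), ]
    }
  }
  utils::write.csv(pairs, review_file, row.names = FALSE)
  invisible(pairs)
}

#' @export
print.rem_clusters <- function(x, ...) {
  cat("REM duplicate clusters: ", attr(x, "n_records"), " records in ",
      attr(x, "n_clusters"), " clusters (", attr(x, "n_duplicates"),
      " duplicates)\n", sep = "")
  invisible(x)
}

# Stable identifier from a canonical label.
slugify <- function(x) {
  s <- tolower(x)
  s <- gsub("[^a-z0-9]+", "-", s)
  s <- gsub("^-+|-+$", "", s)
  s[!nzchar(s)] <- "node"
  s
}

#' Merge duplicate clusters into canonical nodes
#'
#' Produces one canonical node per cluster: provenance is the set of member
#' records, sites are the union of member sites, and the verified date (with
#' its source) is attached from the date table for event nodes. A date-table
#' entry for a conceptual-flagged label is a contradiction and an error.
#'
#' @param dataset the [rem_dataset()] the clusters were computed from.
#' @param clusters the [find_duplicates()] result.
#' @param coding an [as_coding_table()] covering every canonical label.
#' @param dates optional [as_date_table()].
#' @return A data.frame of class `rem_nodes`, one row per canonical node:
#'   `canonical_id`, `label`, `kind`, `date`, `ym`, `date_precision`,
#'   `date_source`, `stage`, `group`, `sites` (';'-joined), `workshops`,
#'   `provenance` (';'-joined `workshop:local`), `n_records`.
#' @export
merge_clusters <- function(dataset, clusters, coding, dates = NULL) {
  stopifnot(inherits(dataset, "rem_dataset"),
            inherits(clusters, "rem_clusters"),
            inherits(coding, "rem_coding"))
  site <- dataset$nodes$site[match(
    paste(clusters$workshop_id, clusters$local_id, sep = "\r"),
    paste(dataset$nodes$workshop_id, dataset$nodes$local_id, sep = "\r"))]
  cl <- split(seq_len(nrow(clusters)), clusters$cluster_id)
  labels <- vapply(cl, function(idx) clusters$canonical_label[idx[1]],
                   character(1))
  keys <- norm_key(labels)
  cx <- match(keys, coding$key)
  if (anyNA(cx)) {
    stop("coding error: kind flag missing for label(s): ",
         paste(sQuote(labels[is.na(cx)]), collapse = ", "), call. = FALSE)
  }
  kind <- coding$kind[cx]
  stage <- coding$stage[cx]
  group <- coding$group[cx]
  ym <- rep(NA_integer_, length(labels))
  dprec <- rep(NA_character_, length(labels))
  dsrc <- rep("none", length(labels))
  if (!is.null(dates) && nrow(dates)) {
    dx <- match(keys, dates$key)
    contradiction <- !is.na(dx) & kind == "conceptual"
    if (any(contradiction)) {
      stop("contradiction error: date-table entry for conceptual node(s): ",
           paste(sQuote(labels[contradiction]), collapse = ", "),
           call. = FALSE)
    }
    ok <- !is.na(dx)
    ym[ok] <- dates$ym[dx[ok]]
    dprec[ok] <- dates$precision[dx[ok]]
    dsrc[ok] <- dates$source[dx[ok]]
  }
  joined <- function(v) paste(sort(unique(v)), collapse = ";")
  sites <- vapply(cl, function(idx) joined(site[idx]), character(1))
  workshops <- vapply(cl, function(idx) joined(clusters$workshop_id[idx]),
                      character(1))
  provenance <- vapply(cl, function(idx) {
    paste(sort(paste(clusters$workshop_id[idx], clusters$local_id[idx],
                     sep = ":")), collapse = ";")
  }, character(1))
  ids <- slugify(labels)
  if (anyDuplicated(ids)) {
    # deterministic disambiguation of rare slug collisions
    for (d in unique(ids[duplicated(ids)])) {
      at <- which(ids == d)
      ids[at] <- paste0(d, "-", seq_along(at))
    }
  }
  out <- data.frame(canonical_id = ids, label = labels, kind = kind,
                    date = ym_format(ym), ym = ym, date_precision = dprec,
                    date_source = dsrc, stage = stage, group = group,
                    sites = sites, workshops = workshops,
                    provenance = provenance,
                    n_records = vapply(cl, length, integer(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$label), ]
  rownames(out) <- NULL
  class(out) <- c("rem_nodes", "data.frame")
  out
}

#' Map raw ripple edges onto canonical node ids
#'
#' @param dataset the raw dataset.
#' @param clusters the [find_duplicates()] result.
#' @return A data.frame of class `rem_edges` with columns `from`, `to`
#'   (canonical ids), `ripple_id`, `workshop_id`. Edges whose endpoints
#'   merged into the same canonical node are dropped with a warning.
#' @export
canonical_edges <- function(dataset, clusters) {
  stopifnot(inherits(dataset, "rem_dataset"),
            inherits(clusters, "rem_clusters"))
  merge_key <- paste(clusters$workshop_id, clusters$local_id, sep = "\r")
  labs <- clusters$canonical_label
  ids <- slugify(labs)
  # reproduce merge_clusters' collision handling
  first <- !duplicated(clusters$cluster_id)
  uids <- ids[first]
  if (anyDuplicated(uids)) {
    ulabs <- labs[first]
    fixed <- uids
    for (d in unique(uids[duplicated(uids)])) {
      at <- which(uids == d)
      fixed[at] <- paste0(d, "-", seq_along(at))
    }
    ids <- fixed[match(clusters$cluster_id, clusters$cluster_id[first])]
  }
  e <- dataset$edges
  fx <- match(paste(e$workshop_id, e$from_local, sep = "\r"), merge_key)
  tx <- match(paste(e$workshop_id, e$to_local, sep = "\r"), merge_key)
  out <- data.frame(from = ids[fx], to = ids[tx],
                    ripple_id = e$ripple_id, workshop_id = e$workshop_id,
                    stringsAsFactors = FALSE)
  loop <- out$from == out$to
  if (any(loop)) {
    warning(sum(loop), " edge(s) collapsed to self-loops by consolidation; ",
            "dropped", call. = FALSE)
    out <- out[!loop, , drop = FALSE]
  }
  out <- unique(out)
  out <- out[order(out$ripple_id, out$from, out$to), ]
  rownames(out) <- NULL
  class(out) <- c("rem_edges", "data.frame")
  out
}
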