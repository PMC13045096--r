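# Analytics over the meta-map: ripple-membership influence, logic-model
# tallies and cross-site ripples. Ripple membership means edge membership --
# a node is involved in a ripple when it is an endpoint of at least one edge
# carrying that ripple id, never by mere co-location in a time bin.

#' Rank nodes by the number of ripples they are involved in
#'
#' The number of distinct ripples a node participates in is the method's
#' measure of influence: a node shared by many ripples is an activity many
#' chains of consequences flow through.
#'
#' @param map a [build_meta_map()] result.
#' @param top_k number of rows to keep.
#' @return A data.frame with columns `canonical_id`, `label`,
#'   `ripple_count`, sorted by descending count with ties broken by
#'   `canonical_id`.
#' @export
influence <- function(map, top_k = 10L) {
  stopifnot(inherits(map, "meta_rem_map"))
  if (!is.numeric(top_k) || length(top_k) != 1L || top_k < 1) {
    stop("argument error: top_k must be a positive count", call. = FALSE)
  }
  e <- map$edges
  both <- data.frame(id = c(e$from, e$to),
                     ripple_id = c(e$ripple_id, e$ripple_id),
                     stringsAsFactors = FALSE)
  both <- unique(both)
  cnt <- table(factor(both$id, levels = map$nodes$canonical_id))
  out <- data.frame(canonical_id = map$nodes$canonical_id,
                    label = map$nodes$label,
                    ripple_count = as.integer(cnt),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$ripple_count, out$canonical_id), ]
  out <- utils::head(out, as.integer(top_k))
  rownames(out) <- NULL
  out
}

#' Logic-model tallies over the meta-map
#'
#' Counts nodes by logic-model stage, by activity group, and by (year,
#' stage). Nodes without a code fall into an explicit `uncoded` bucket, so
#' every marginal sums to the meta-map node count.
#'
#' @param map a [build_meta_map()] result.
#' @return An object of class `rem_tallies`: a list with named integer
#'   vectors `stage` and `group`, and data.frame `year_stage` (`year`,
#'   `stage`, `n`).
#' @export
tallies <- function(map) {
  stopifnot(inherits(map, "meta_rem_map"))
  n <- map$nodes
  stage <- n$stage
  stage[is.na(stage)] <- "uncoded"
  group <- n$group
  group[is.na(group)] <- "uncoded"
  stage_tab <- table(factor(stage, levels = c(REM_STAGES, "uncoded")))
  group_tab <- table(factor(group, levels = c(REM_GROUPS, "uncoded")))
  year <- n$ym %/% 12L
  ys <- as.data.frame(table(year = factor(year, levels = sort(unique(year))),
                            stage = factor(stage,
                                           levels = c(REM_STAGES, "uncoded"))),
                      stringsAsFactors = FALSE)
  names(ys)[3] <- "n"
  ys$year <- as.integer(as.character(ys$year))
  ys <- ys[order(ys$year, match(ys$stage, c(REM_STAGES, "uncoded"))), ]
  rownames(ys) <- NULL
  structure(list(stage = stats::setNames(as.integer(stage_tab),
                                         names(stage_tab)),
                 group = stats::setNames(as.integer(group_tab),
                                         names(group_tab)),
                 year_stage = ys,
                 n_nodes = nrow(n)),
            class = "rem_tallies")
}

#' @export
print.rem_tallies <- function(x, ...) {
  cat("Logic-model tallies over", x$n_nodes, "meta-map nodes\n")
  cat("  by stage:\n")
  for (s in names(x$stage)) {
    if (x$stage[[s]] > 0) cat(sprintf("    %-28s %4d\n", s, x$stage[[s]]))
  }
  cat("  by group:\n")
  for (g in names(x$group)) {
    if (x$group[[g]] > 0) cat(sprintf("    %-28s %4d\n", g, x$group[[g]]))
  }
  invisible(x)
}

#' Ripples that span more than one study site
#'
#' A ripple is cross-site when the sites of its member nodes cover at least
#' two concrete localities; a node attributed to `both` covers both on its
#' own.
#'
#' @param map a [build_meta_map()] result.
#' @return Sorted character vector of ripple ids.
#' @export
cross_site <- function(map) {
  stopifnot(inherits(map, "meta_rem_map"))
  sites <- strsplit(map$nodes$sites, ";", fixed = TRUE)
  names(sites) <- map$nodes$canonical_id
  covered <- function(ids) {
    s <- unique(unlist(sites[ids], use.names = FALSE))
    if ("both" %in% s) s <- unique(c(s, "bradford", "lbth"))
    setdiff(s, c("both", "unknown"))
  }
  e <- map$edges
  rids <- sort(unique(e$ripple_id))
  hit <- vapply(rids, function(rid) {
    at <- e$ripple_id == rid
    length(covered(unique(c(e$from[at], e$to[at])))) >= 2L
  }, logical(1))
  rids[hit]
}
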