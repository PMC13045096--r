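# The whole meta-REM pipeline behind one call, returning a classed object
# that carries every intermediate stage alongside the final map.

#' Build a meta-REM from raw workshop data
#'
#' Runs the full pipeline: canonicalise labels and consolidate duplicates,
#' apply verified dates and logic-model codes, check temporal ordering,
#' exclude unplaceable nodes and their cascade, merge the surviving ripples
#' into a time-binned meta-map, and compute the accounting report.
#'
#' @param dataset a [rem_dataset()] (typically [merge_datasets()] over
#'   per-workshop reads).
#' @param coding an [as_coding_table()] covering every canonical label.
#' @param aliases optional [as_alias_map()].
#' @param dates optional [as_date_table()].
#' @param dedup duplicate-identification policy, see [find_duplicates()].
#' @param policy exclusion policy, see [cascade_exclude()].
#' @param bin_width time-bin width for the map, see [build_meta_map()].
#' @param granularity temporal-order comparison granularity.
#' @param strict if `TRUE`, temporal-order violations are an error instead
#'   of a warning (verification is normally iterative triangulation, so the
#'   default only warns).
#' @param review_file candidate-pair output path for `dedup = "fuzzy"`.
#' @return An object of class `meta_rem`: a list with `dataset`, `clusters`,
#'   `nodes`, `edges`, `violations`, `exclusion`, `map`, `accounting` and
#'   the policies used.
#' @examples
#' fx <- generate_rem_fixture(rem_fixture_params(
#'   n_workshops = 3, n_records = 40, n_duplicates = 5, n_conceptual = 4,
#'   n_undatable = 5, n_cascade = 4, seed = 7))
#' fit <- meta_rem(fx$dataset, fx$coding, fx$aliases, fx$dates)
#' fit
#' @export
meta_rem <- function(dataset, coding, aliases = NULL, dates = NULL,
                     dedup = c("exact", "fuzzy"),
                     policy = c("reachability", "strict_ripple"),
                     bin_width = c("quarter", "month", "year"),
                     granularity = c("month", "quarter", "year"),
                     strict = FALSE, review_file = NULL) {
  dedup <- match.arg(dedup)
  policy <- match.arg(policy)
  bin_width <- match.arg(bin_width)
  granularity <- match.arg(granularity)
  clusters <- find_duplicates(dataset, aliases, policy = dedup,
                              review_file = review_file)
  nodes <- merge_clusters(dataset, clusters, coding, dates)
  edges <- canonical_edges(dataset, clusters)
  violations <- check_temporal_order(nodes, edges, granularity)
  if (nrow(violations)) {
    msg <- paste0(nrow(violations), " temporal-order violation(s), e.g. ",
                  violations$from[1], " (", violations$from_date[1],
                  ") -> ", violations$to[1], " (", violations$to_date[1],
                  ")")
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  exclusion <- cascade_exclude(nodes, edges, policy)
  map <- build_meta_map(nodes, edges, exclusion, bin_width)
  acct <- accounting(dataset, clusters, nodes, exclusion)
  structure(list(dataset = dataset, clusters = clusters, nodes = nodes,
                 edges = edges, violations = violations,
                 exclusion = exclusion, map = map, accounting = acct,
                 dedup = dedup, policy = policy, bin_width = bin_width,
                 granularity = granularity),
            class = "meta_rem")
}

#' @export
print.meta_rem <- function(x, ...) {
  cat("Meta-REM (", length(x$dataset$workshop_ids), " workshops, policy = ",
      x$policy, ", bins = ", x$bin_width, ")\n", sep = "")
  print(x$accounting)
  if (nrow(x$violations)) {
    cat("  !", nrow(x$violations), "temporal-order violation(s)\n")
  }
  invisible(x)
}

#' @param object,x a `meta_rem` object.
#' @param top_k rows of the influence ranking to show.
#' @param ... unused.
#' @rdname meta_rem
#' @export
summary.meta_rem <- function(object, top_k = 10L, ...) {
  structure(list(accounting = object$accounting,
                 influence = influence(object$map, top_k),
                 tallies = tallies(object$map),
                 expanded = expanded_ripples(object$map),
                 cross_site = cross_site(object$map),
                 n_violations = nrow(object$violations)),
            class = "summary.meta_rem")
}

#' @export
print.summary.meta_rem <- function(x, ...) {
  print(x$accounting)
  cat("\nMost influential nodes (distinct ripples):\n")
  for (i in seq_len(nrow(x$influence))) {
    cat(sprintf("  %2d. %-55s %3d\n", i,
                substr(x$influence$label[i], 1, 55),
                x$influence$ripple_count[i]))
  }
  cat("\n")
  print(x$tallies)
  cat("\nRipples expanded across workshops: ", nrow(x$expanded),
      " nodes; cross-site ripples: ", length(x$cross_site), "\n", sep = "")
  if (x$n_violations) {
    cat("Temporal-order violations:", x$n_violations, "\n")
  }
  invisible(x)
}

#' @rdname meta_rem
#' @export
plot.meta_rem <- function(x, ...) {
  map <- x$map
  if (!nrow(map$nodes)) {
    warning("empty meta-map; nothing to plot", call. = FALSE)
    return(invisible(x))
  }
  stage <- map$nodes$stage
  stage[is.na(stage)] <- "uncoded"
  lv <- c(REM_STAGES, "uncoded")
  tab <- table(factor(stage, levels = lv),
               factor(unname(map$node_bin), levels = seq_len(nrow(map$bins))))
  colnames(tab) <- map$bins$label
  keep <- rowSums(tab) > 0
  cols <- c("#8dd3c7", "#80b1d3", "#fdb462", "#b3de69", "#fb8072",
            "#d9d9d9")[keep]
  graphics::barplot(tab[keep, , drop = FALSE], col = cols, border = NA,
                    las = 2, cex.names = 0.7,
                    ylab = "nodes per bin",
                    main = "Meta-REM activity over the timeline",
                    legend.text = rownames(tab)[keep],
                    args.legend = list(x = "topleft", bty = "n",
                                       cex = 0.8), ...)
  invisible(x)
}

#' Write the bundled report of a meta-REM
#'
#' Writes the accounting report, influence ranking, logic-model tallies,
#' cross-site ripple list, expanded-ripple list, exclusion report and the
#' serialized meta-map into one directory.
#'
#' @param fit a [meta_rem()] object.
#' @param dir output directory.
#' @param top_k influence rows to keep.
#' @return Invisibly, the directory.
#' @export
write_report <- function(fit, dir, top_k = 10L) {
  stopifnot(inherits(fit, "meta_rem"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(fit$accounting, file.path(dir, "accounting.csv"),
                   row.names = FALSE)
  utils::write.csv(influence(fit$map, top_k),
                   file.path(dir, "influence.csv"), row.names = FALSE)
  tl <- tallies(fit$map)
  utils::write.csv(data.frame(stage = names(tl$stage), n = tl$stage),
                   file.path(dir, "tally_stage.csv"), row.names = FALSE)
  utils::write.csv(data.frame(group = names(tl$group), n = tl$group),
                   file.path(dir, "tally_group.csv"), row.names = FALSE)
  utils::write.csv(tl$year_stage, file.path(dir, "tally_year_stage.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(ripple_id = cross_site(fit$map)),
                   file.path(dir, "cross_site.csv"), row.names = FALSE)
  utils::write.csv(expanded_ripples(fit$map),
                   file.path(dir, "expanded_ripples.csv"), row.names = FALSE)
  utils::write.csv(exclusion_report(fit$exclusion, fit$edges),
                   file.path(dir, "exclusion.csv"), row.names = FALSE)
  utils::write.csv(fit$violations, file.path(dir, "violations.csv"),
                   row.names = FALSE)
  write_meta_map(fit$map, dir)
  invisible(dir)
}
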