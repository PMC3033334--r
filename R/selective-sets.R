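# Venn construction of condition-"selective" gene sets: a gene is
# selective for a condition when it is concordance-selected and >= 2-fold
# up-regulated against every comparator (for G9: versus G22, the same
# cell type at puberty, and versus S9, the other cell type at the same
# stage). The intersection construction makes the four selective sets
# pairwise disjoint whenever each pairwise comparison is antisymmetric.

#' Up-regulated gene list from a concordance table
#'
#' @param records Output of [concordance_select()] for an ordered
#'   (experimental, reference) comparison.
#' @return Character vector of selected, up-regulated feature IDs.
#' @export
pairwise_up_list <- function(records) {
  records$feature_id[records$selected & records$direction == "Up"]
}

#' Build one condition's selective gene set
#'
#' Intersects the condition's pairwise up-regulation lists over all its
#' comparators, and enumerates the counts of every Venn region of those
#' lists (all `2^m - 1` non-empty membership patterns for `m` comparator
#' lists; region enumeration is capped at `m = 6`, beyond which only the
#' full intersection and the pairwise region of each list are reported).
#'
#' @param condition Condition label.
#' @param up_lists Named list: comparator label -> up-regulated gene IDs
#'   (from [pairwise_up_list()] for condition-vs-comparator).
#' @return List of class `selective_set_result`: `condition`,
#'   `comparators`, `pairwise_up`, `selective`, `venn_counts`
#'   (data.frame `region`, `count`).
#' @export
build_selective <- function(condition, up_lists) {
  if (length(up_lists) < 1 || is.null(names(up_lists))) {
    stop("up_lists must be a non-empty named list of comparator gene sets")
  }
  up_lists <- lapply(up_lists, function(s) unique(as.character(s)))
  selective <- Reduce(intersect, up_lists)
  m <- length(up_lists)
  if (m <= 6) {
    all_ids <- unique(unlist(up_lists, use.names = FALSE))
    membership <- vapply(up_lists, function(s) all_ids %in% s, logical(length(all_ids)))
    if (length(all_ids) == 1) membership <- matrix(membership, nrow = 1)
    patterns <- expand.grid(rep(list(c(FALSE, TRUE)), m))[-1, , drop = FALSE]
    names(patterns) <- names(up_lists)
    counts <- apply(patterns, 1, function(pat) {
      if (length(all_ids) == 0) return(0L)
      sum(apply(membership, 1, function(row) all(row == pat)))
    })
    region <- apply(patterns, 1, function(pat)
      paste(names(up_lists)[as.logical(pat)], collapse = "&"))
    venn_counts <- data.frame(region = region, count = as.integer(counts),
                              stringsAsFactors = FALSE)
  } else {
    venn_counts <- data.frame(
      region = c(names(up_lists), "all"),
      count = c(vapply(up_lists, length, integer(1)), length(selective)),
      stringsAsFactors = FALSE)
  }
  structure(list(condition = condition, comparators = names(up_lists),
                 pairwise_up = up_lists, selective = sort(selective),
                 venn_counts = venn_counts),
            class = "selective_set_result")
}

#' @export
print.selective_set_result <- function(x, ...) {
  cat(sprintf("%s-selective: %d gene(s) (intersection over %s)\n",
              x$condition, length(x$selective),
              paste(x$comparators, collapse = ", ")))
  invisible(x)
}

#' Check pairwise disjointness of selective sets
#'
#' The construction guarantees that a gene cannot be selective for two
#' conditions; this reports any violation (an empty report is a pass).
#'
#' @param results List of `selective_set_result` objects.
#' @return data.frame: `set_a`, `set_b`, `gene_id`, one row per shared
#'   gene; zero rows when all sets are pairwise disjoint.
#' @export
check_disjoint <- function(results) {
  stopifnot(length(results) >= 2)
  rows <- list()
  for (i in seq_along(results)) {
    for (j in seq_along(results)) {
      if (j <= i) next
      shared <- intersect(results[[i]]$selective, results[[j]]$selective)
      if (length(shared) > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          set_a = results[[i]]$condition, set_b = results[[j]]$condition,
          gene_id = shared, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    data.frame(set_a = character(0), set_b = character(0),
               gene_id = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
}
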