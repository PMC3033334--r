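# Hypergeometric enrichment/depletion of gene clusters against
# annotation categories and external gene lists. The expected overlap is
# m*n/N (category size x cluster size / annotated universe); a category
# is flagged enriched when the upper-tail P < 0.001 and the observed
# overlap exceeds 3, depleted when the lower-tail P < 0.001.

#' Enrichment configuration
#'
#' @param p_cutoff One-sided P-value cutoff (default 0.001).
#' @param min_observed Minimum observed overlap for an enriched flag
#'   (default 4, i.e. "observed > 3").
#' @param universe_mode `"annotated_only"` (genes appearing in at least
#'   one category) or `"full_array"` (every matrix feature).
#' @return Object of class `enrich_config`.
#' @export
enrich_config <- function(p_cutoff = 0.001, min_observed = 4L,
                          universe_mode = c("annotated_only", "full_array")) {
  universe_mode <- match.arg(universe_mode)
  stopifnot(p_cutoff > 0, p_cutoff < 1, min_observed >= 0)
  structure(list(p_cutoff = p_cutoff, min_observed = as.integer(min_observed),
                 universe_mode = universe_mode),
            class = "enrich_config")
}

#' Exact hypergeometric tail probability
#'
#' Tail probability of the number of category members drawn in a cluster
#' of size `n` sampled without replacement from a universe of `N` genes
#' of which `m` belong to the category. Tails are inclusive:
#' upper = P(X >= k), lower = P(X <= k).
#'
#' @param N Universe size.
#' @param m Category size within the universe.
#' @param n Cluster (draw) size within the universe.
#' @param k Observed overlap.
#' @param tail `"upper"` or `"lower"`.
#' @return The tail probability.
#' @export
hypergeom_tail <- function(N, m, n, k, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (any(c(N, m, n, k) < 0) || m > N || n > N || k > min(m, n)) {
    stop("invalid hypergeometric parameters (need 0 <= m,n <= N, 0 <= k <= min(m,n))")
  }
  if (tail == "upper") {
    stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
  } else {
    stats::phyper(k, m, N - m, n, lower.tail = TRUE)
  }
}

enrich_one <- function(cluster, category, universe, cfg) {
  N <- length(universe)
  m <- length(intersect(category, universe))
  n <- length(intersect(cluster, universe))
  k <- length(intersect(intersect(cluster, universe), category))
  expected <- m * n / N
  p_enr <- hypergeom_tail(N, m, n, k, "upper")
  p_dep <- hypergeom_tail(N, m, n, k, "lower")
  flag <- if (p_enr < cfg$p_cutoff && k >= cfg$min_observed) "enriched"
          else if (p_dep < cfg$p_cutoff) "depleted" else "none"
  data.frame(N = N, m = m, n = n, k = k, expected = expected,
             p_enrich = p_enr, p_deplete = p_dep, flag = flag,
             stringsAsFactors = FALSE)
}

#' Category enrichment and depletion of a gene cluster
#'
#' One row per category, each with the observed overlap `k`, the random
#' expectation `m*n/N`, and one-sided hypergeometric tail P-values.
#' Genes outside the universe are dropped (with a message giving counts).
#' A Benjamini-Hochberg column over the enrichment P-values is emitted
#' as a diagnostic; flagging uses only the raw one-sided cutoff plus the
#' minimum-observed filter.
#'
#' @param cluster Character vector of gene IDs.
#' @param categories A [gene_set_collection()].
#' @param universe Character vector of gene IDs; when `NULL`, the
#'   `universe_mode` of `cfg` decides between the union of category
#'   members (`annotated_only`) and the collection's own universe.
#' @param cfg An [enrich_config()].
#' @param cluster_name Label for the output rows.
#' @return data.frame: `cluster_name`, `category_name`, `N`, `m`, `n`,
#'   `k`, `expected`, `p_enrich`, `p_deplete`, `p_enrich_bh`, `flag`.
#' @export
enrich <- function(cluster, categories, universe = NULL, cfg = enrich_config(),
                   cluster_name = "cluster") {
  stopifnot(inherits(categories, "gene_set_collection"))
  if (is.null(universe)) {
    universe <- if (cfg$universe_mode == "annotated_only" ||
                    is.null(categories$universe)) {
      unique(unlist(categories$sets, use.names = FALSE))
    } else {
      categories$universe
    }
  }
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe")
  cluster <- unique(as.character(cluster))
  n_out <- sum(!cluster %in% universe)
  if (n_out > 0) {
    message(n_out, " cluster gene(s) outside the universe dropped")
  }
  rows <- lapply(names(categories$sets), function(nm) {
    r <- enrich_one(cluster, categories$sets[[nm]], universe, cfg)
    cbind(data.frame(cluster_name = cluster_name, category_name = nm,
                     stringsAsFactors = FALSE), r)
  })
  out <- do.call(rbind, rows)
  out$p_enrich_bh <- stats::p.adjust(out$p_enrich, method = "BH")
  out[c("cluster_name", "category_name", "N", "m", "n", "k", "expected",
        "p_enrich", "p_deplete", "p_enrich_bh", "flag")]
}

#' Overlap of gene clusters with external gene lists
#'
#' The "64 observed versus 17 expected" style comparison: every cluster
#' is intersected with every external list under the same hypergeometric
#' model as [enrich()]. External IDs can first be translated through a
#' many-to-many ortholog map; a gene counts once however many partners
#' map to it, and untranslatable IDs are counted and reported in the
#' `n_unmapped` column.
#'
#' @param clusters A [gene_set_collection()] of gene clusters.
#' @param external_lists A [gene_set_collection()] of external lists.
#' @param universe Character vector of gene IDs.
#' @param ortholog_map Optional data.frame from [read_pair_table()] with
#'   columns (external ID, universe ID); `NULL` for none.
#' @param cfg An [enrich_config()].
#' @return data.frame, one row per (cluster, list), same statistics as
#'   [enrich()] plus `n_unmapped`.
#' @export
list_overlap <- function(clusters, external_lists, universe,
                         ortholog_map = NULL, cfg = enrich_config()) {
  stopifnot(inherits(clusters, "gene_set_collection"),
            inherits(external_lists, "gene_set_collection"))
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe")
  rows <- list()
  for (ln in names(external_lists$sets)) {
    ids <- external_lists$sets[[ln]]
    n_unmapped <- 0L
    if (!is.null(ortholog_map)) {
      translated <- unique(ortholog_map[[2]][ortholog_map[[1]] %in% ids])
      n_unmapped <- sum(!ids %in% ortholog_map[[1]])
      ids <- translated
    }
    for (cn in names(clusters$sets)) {
      r <- enrich_one(clusters$sets[[cn]], ids, universe, cfg)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(cluster_name = cn, category_name = ln,
                   stringsAsFactors = FALSE),
        r, data.frame(n_unmapped = n_unmapped))
    }
  }
  out <- do.call(rbind, rows)
  out$p_enrich_bh <- stats::p.adjust(out$p_enrich, method = "BH")
  out[c("cluster_name", "category_name", "N", "m", "n", "k", "expected",
        "p_enrich", "p_deplete", "p_enrich_bh", "flag", "n_unmapped")]
}
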