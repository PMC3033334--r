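# Ligand-receptor complementarity between two condition-selective sets:
# a hit is a curated ligand-receptor pair whose ligand sits in one
# population's selective set and whose receptor sits in the other's
# (e.g. vegfc in the spermatogonial set with its receptor kdr in the
# Sertoli set). An accompanying hypergeometric statistic asks whether
# that many pairs complete by chance; the statistic is an extension of
# the construction, not part of it.

#' Detect complementary ligand-receptor expression between two gene sets
#'
#' The pair table's first column is read as ligand, the second as
#' receptor. Hits are reported in both orientations: `A->B` (ligand in
#' `set_a`, receptor in `set_b`) and `B->A`. Pairs whose two members fall
#' in the same set are not hits. For each orientation, the upper-tail
#' hypergeometric probability of the observed number of completed pairs
#' is computed over the candidate pairs whose ligand (resp. receptor)
#' side is already in place, treating the placement of the other
#' endpoint as a random draw of the receiving set from the universe.
#'
#' @param set_a Character vector of gene IDs (first population).
#' @param set_b Character vector of gene IDs (second population).
#' @param pairs data.frame from [read_pair_table()], columns
#'   (ligand, receptor).
#' @param label_a,label_b Condition labels for the two sets.
#' @param universe Optional character vector of all assayable gene IDs;
#'   required for the significance statistic, which is skipped (NA) when
#'   absent.
#' @return List with `hits` (data.frame: `ligand_id`, `receptor_id`,
#'   `ligand_set`, `receptor_set`, `orientation`) and `stats`
#'   (data.frame per orientation: `orientation`, `n_candidates`,
#'   `n_hits`, `p_value`).
#' @export
find_crosstalk <- function(set_a, set_b, pairs, label_a = "A", label_b = "B",
                           universe = NULL) {
  if (nrow(pairs) == 0) stop("empty pair table")
  if (identical(label_a, label_b)) stop("the two sets must have distinct labels")
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  ligand <- pairs[[1]]
  receptor <- pairs[[2]]

  orient <- function(lig_set, rec_set, lig_label, rec_label, tag) {
    cand <- ligand %in% lig_set
    hit <- cand & receptor %in% rec_set
    hits <- data.frame(ligand_id = ligand[hit], receptor_id = receptor[hit],
                       ligand_set = rep(lig_label, sum(hit)),
                       receptor_set = rep(rec_label, sum(hit)),
                       orientation = rep(tag, sum(hit)), stringsAsFactors = FALSE)
    p <- NA_real_
    if (!is.null(universe) && sum(cand) > 0) {
      uni <- unique(as.character(universe))
      recs <- unique(receptor[cand])
      recs <- intersect(recs, uni)
      k <- length(intersect(recs, rec_set))
      p <- hypergeom_tail(length(uni), length(intersect(rec_set, uni)),
                          length(recs), k, "upper")
    }
    list(hits = hits,
         stats = data.frame(orientation = tag, n_candidates = sum(cand),
                            n_hits = sum(hit), p_value = p,
                            stringsAsFactors = FALSE))
  }

  ab <- orient(set_a, set_b, label_a, label_b, paste0(label_a, "->", label_b))
  ba <- orient(set_b, set_a, label_b, label_a, paste0(label_b, "->", label_a))
  list(hits = rbind(ab$hits, ba$hits), stats = rbind(ab$stats, ba$stats))
}

#' Bundled demonstration ligand-receptor pair table
#'
#' Five curated stem-cell/niche couples (vegfc-kdr, edn1-ednrb,
#' bdnf-ntrk1, cxcl12-cxcr4, kitl-kit) shipped as a small TSV for
#' demonstrations and tests.
#'
#' @return data.frame with columns `ligand`, `receptor`.
#' @export
demo_lr_pairs <- function() {
  read_pair_table(system.file("extdata", "lr_pairs_demo.tsv", package = "stageset"),
                  col_names = c("ligand", "receptor"))
}
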