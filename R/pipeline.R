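# End-to-end orchestration: simulate (or read) -> signal summary ->
# detection calls -> pairwise concordance DE for every
# (condition, comparator) -> selective sets -> clustering -> category
# enrichment -> ligand-receptor crosstalk, with deterministic outputs
# and a run manifest.

#' Default comparator scheme for the four-population design
#'
#' Each condition is compared against the same cell type at the other
#' stage and the other cell type at the same stage (G9 vs G22 and
#' G9 vs S9, etc.). For condition sets without that structure, every
#' other condition is a comparator.
#'
#' @param conditions Condition labels.
#' @return Named list: condition -> character vector of comparators.
#' @export
default_comparator_scheme <- function(conditions) {
  canonical <- c("G9", "S9", "G22", "S22")
  if (setequal(conditions, canonical)) {
    list(G9 = c("G22", "S9"), S9 = c("S22", "G9"),
         G22 = c("G9", "S22"), S22 = c("S9", "G22"))[conditions]
  } else {
    stats::setNames(lapply(conditions, function(cc) setdiff(conditions, cc)),
                    conditions)
  }
}

#' Pipeline configuration
#'
#' @param synthetic A [synthetic_spec()] for simulation mode, or `NULL`
#'   to read data from files.
#' @param matrix_path,sample_sheet_path Input files (ignored in
#'   simulation mode).
#' @param categories_path Optional GMT file of annotation categories
#'   (simulation mode uses the generated categories).
#' @param de A [de_config()].
#' @param enrich An [enrich_config()].
#' @param comparators Named list condition -> comparators; `NULL` for
#'   [default_comparator_scheme()].
#' @param crosstalk_between Length-2 character vector: the two selective
#'   sets screened for ligand-receptor complementarity.
#' @param lr_pairs_path TSV of ligand-receptor pairs; `NULL` for the
#'   bundled demonstration table.
#' @param background Detection background intensity; `NULL` takes the
#'   synthetic spec's `background_level` (required for file input).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_spec(),
                            matrix_path = NULL, sample_sheet_path = NULL,
                            categories_path = NULL,
                            de = de_config(), enrich = enrich_config(),
                            comparators = NULL,
                            crosstalk_between = c("G9", "S9"),
                            lr_pairs_path = NULL,
                            background = NULL) {
  if (is.null(synthetic)) {
    stopifnot(!is.null(matrix_path), !is.null(sample_sheet_path),
              !is.null(background))
  }
  structure(list(synthetic = synthetic, matrix_path = matrix_path,
                 sample_sheet_path = sample_sheet_path,
                 categories_path = categories_path, de = de, enrich = enrich,
                 comparators = comparators,
                 crosstalk_between = crosstalk_between,
                 lr_pairs_path = lr_pairs_path, background = background),
            class = "pipeline_config")
}

validate_pipeline_config <- function(config, conditions) {
  comparators <- config$comparators
  if (is.null(comparators)) comparators <- default_comparator_scheme(conditions)
  bad <- setdiff(c(names(comparators), unlist(comparators)), conditions)
  if (length(bad) > 0) {
    stop("comparator scheme references undeclared condition(s): ",
         paste(bad, collapse = ", "))
  }
  if (length(config$crosstalk_between) == 2 &&
      !all(config$crosstalk_between %in% conditions)) {
    stop("crosstalk_between references undeclared condition(s)")
  }
  comparators
}

#' Run the full analysis pipeline
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for result tables; `NULL` to skip
#'   writing.
#' @return List of class `pipeline_result`: `signals`, `detections`,
#'   `records` (one concordance table per "EXP_vs_REF"), `selective`
#'   (one `selective_set_result` per condition), `disjoint_report`,
#'   `sample_tree`, `gene_tree`, `enrichment`, `crosstalk`, `truth`
#'   (simulation mode), `recovery` (simulation mode), `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  categories <- NULL
  if (!is.null(config$synthetic)) {
    sim <- generate_expression(config$synthetic)
    mat <- sim$matrix
    truth <- sim$truth
    categories <- sim$categories
    background <- if (is.null(config$background)) config$synthetic$background_level
                  else config$background
  } else {
    mat <- read_expression_matrix(config$matrix_path, config$sample_sheet_path)
    background <- config$background
  }
  if (!is.null(config$categories_path)) {
    categories <- read_gene_sets(config$categories_path, format = "gmt")
  }
  conditions <- unique(mat$samples$condition)
  comparators <- validate_pipeline_config(config, conditions)

  signals <- summarize_signal(mat, method = config$de$signal_summary)
  detections <- detection_call(mat, background, config$de)

  records <- list()
  for (cc in names(comparators)) {
    for (ref in comparators[[cc]]) {
      key <- paste0(cc, "_vs_", ref)
      if (!key %in% names(records)) {
        calls <- pairwise_change_calls(mat, cc, ref, config$de)
        records[[key]] <- concordance_select(calls, signals, config$de)
      }
    }
  }

  selective <- lapply(names(comparators), function(cc) {
    up <- lapply(comparators[[cc]], function(ref)
      pairwise_up_list(records[[paste0(cc, "_vs_", ref)]]))
    names(up) <- comparators[[cc]]
    build_selective(cc, up)
  })
  names(selective) <- names(comparators)
  disjoint_report <- if (length(selective) >= 2) check_disjoint(selective)
                     else NULL

  sample_tree <- cluster_profiles(signals, axis = "samples")
  de_genes <- sort(unique(unlist(lapply(records, function(r)
    r$feature_id[r$selected]), use.names = FALSE)))
  gene_tree <- NULL
  if (length(de_genes) >= 2) {
    sub <- signals$values[match(de_genes, signals$feature_ids), , drop = FALSE]
    rownames(sub) <- de_genes
    gene_tree <- cluster_profiles(sub, axis = "genes")
  }

  enrichment <- NULL
  if (!is.null(categories) && length(categories$sets) > 0) {
    enrichment <- do.call(rbind, lapply(names(selective), function(cc)
      enrich(selective[[cc]]$selective, categories, cfg = config$enrich,
             cluster_name = paste0(cc, "_sel"))))
  }

  crosstalk <- NULL
  if (length(config$crosstalk_between) == 2) {
    a <- config$crosstalk_between[1]
    b <- config$crosstalk_between[2]
    pairs <- if (is.null(config$lr_pairs_path)) demo_lr_pairs()
             else read_pair_table(config$lr_pairs_path,
                                  col_names = c("ligand", "receptor"))
    crosstalk <- find_crosstalk(selective[[a]]$selective,
                                selective[[b]]$selective,
                                pairs, label_a = a, label_b = b,
                                universe = unique(mat$feature_ids))
  }

  recovery <- NULL
  if (!is.null(truth)) {
    called <- gene_set_collection(lapply(selective, `[[`, "selective"))
    recovery <- truth_confusion(truth, called)
  }

  result <- structure(list(signals = signals, detections = detections,
                           records = records, selective = selective,
                           disjoint_report = disjoint_report,
                           sample_tree = sample_tree, gene_tree = gene_tree,
                           enrichment = enrichment, crosstalk = crosstalk,
                           truth = truth, recovery = recovery,
                           categories = categories, config = config,
                           manifest = NULL),
                      class = "pipeline_result")

  if (!is.null(out_dir)) {
    tables <- list(detections = detections)
    for (key in names(records)) tables[[paste0("de_", key)]] <- records[[key]]
    for (cc in names(selective)) {
      tables[[paste0("selective_", cc)]] <-
        data.frame(feature_id = selective[[cc]]$selective,
                   stringsAsFactors = FALSE)
      tables[[paste0("venn_", cc)]] <- selective[[cc]]$venn_counts
    }
    if (!is.null(disjoint_report)) tables$disjoint_report <- disjoint_report
    if (!is.null(enrichment)) tables$enrichment <- enrichment
    if (!is.null(crosstalk)) {
      tables$crosstalk_hits <- crosstalk$hits
      tables$crosstalk_stats <- crosstalk$stats
    }
    if (!is.null(recovery)) tables$recovery <- recovery
    if (!is.null(truth)) tables$truth <- truth
    manifest <- write_results(tables, out_dir)
    tree_newick(sample_tree, file.path(out_dir, "sample_tree.nwk"))
    if (!is.null(gene_tree)) {
      tree_newick(gene_tree, file.path(out_dir, "gene_tree.nwk"))
    }
    result$manifest <- manifest
  }
  result
}

#' Summary report of a pipeline run
#'
#' @param result A `pipeline_result`.
#' @param top_n Number of top enriched categories to list per set.
#' @return List: `selective_sizes` (named integer vector),
#'   `top_enriched` (data.frame), `crosstalk_hits` (integer),
#'   `recovery` (data.frame, only when ground truth is present).
#' @export
pipeline_report <- function(result, top_n = 3) {
  stopifnot(inherits(result, "pipeline_result"))
  sizes <- vapply(result$selective, function(s) length(s$selective), integer(1))
  top <- NULL
  if (!is.null(result$enrichment)) {
    enr <- result$enrichment[result$enrichment$flag == "enriched", ]
    if (nrow(enr) > 0) {
      enr <- enr[order(enr$cluster_name, enr$p_enrich), ]
      top <- do.call(rbind, lapply(split(enr, enr$cluster_name), utils::head, top_n))
      rownames(top) <- NULL
    }
  }
  out <- list(selective_sizes = sizes, top_enriched = top,
              crosstalk_hits = if (is.null(result$crosstalk)) NA_integer_
                               else nrow(result$crosstalk$hits))
  if (!is.null(result$recovery)) out$recovery <- result$recovery
  out
}
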