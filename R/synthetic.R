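# Planted-structure generator. Emulates a 4-condition x 3-replicate
# probe-level microarray experiment (germ and Sertoli cells at 9 and
# 22 dpp): log-normal intensities, per-gene condition-selective blocks,
# a shared mitotic block co-elevated in both 9-dpp populations, absent
# genes sitting at array background, and annotation categories spiked
# with genes from a chosen block.

#' Default planted blocks
#'
#' One selective block per condition plus a shared block elevated in both
#' 9-dpp populations (the common mitotic program).
#' @param conditions Condition labels.
#' @param block_size Genes per condition-selective block.
#' @param shared_size Genes in the shared block.
#' @param effect_log2 Planted log2 effect size.
#' @return List of block descriptors.
#' @export
default_planted_blocks <- function(conditions = c("G9", "S9", "G22", "S22"),
                                   block_size = 50, shared_size = 60,
                                   effect_log2 = 2.0) {
  blocks <- lapply(conditions, function(cc) {
    list(name = paste0(cc, "_block"), conditions = cc,
         n_genes = block_size, effect_log2 = effect_log2)
  })
  if (all(c("G9", "S9") %in% conditions)) {
    blocks <- c(blocks, list(list(name = "mitotic_shared",
                                  conditions = c("G9", "S9"),
                                  n_genes = shared_size,
                                  effect_log2 = effect_log2)))
  }
  blocks
}

#' Default annotation categories
#'
#' One category spiked from each condition-selective block (a fraction of
#' its members drawn from the block) plus null categories sampled
#' uniformly from the gene universe.
#' @param conditions Condition labels.
#' @param size Category size.
#' @param fraction Fraction of a spiked category drawn from its block.
#' @param n_null Number of null categories.
#' @return List of category descriptors.
#' @export
default_categories <- function(conditions = c("G9", "S9", "G22", "S22"),
                               size = 40, fraction = 0.5, n_null = 20) {
  spiked <- lapply(conditions, function(cc) {
    list(name = paste0("GO_", cc, "_program"), size = size,
         block = paste0(cc, "_block"), fraction = fraction)
  })
  nulls <- lapply(seq_len(n_null), function(i) {
    list(name = sprintf("GO_null_%02d", i), size = size,
         block = NA_character_, fraction = 0)
  })
  c(spiked, nulls)
}

#' Default ligand/receptor symbol planting
#'
#' Renames a few genes of the G9 and S9 selective blocks to the symbols of
#' well-known stem-cell/niche ligand-receptor couples, so the bundled
#' demonstration pair table finds planted cross-population hits (ligands
#' vegfc, edn1, bdnf and the receptor cxcr4 in the spermatogonial set;
#' receptors kdr, ednrb, ntrk1 and the ligand cxcl12 in the Sertoli set).
#' @return Named list: condition -> character vector of symbols.
#' @export
default_symbol_assignments <- function() {
  list(G9 = c("vegfc", "edn1", "bdnf", "cxcr4"),
       S9 = c("kdr", "ednrb", "ntrk1", "cxcl12"))
}

#' Parameterize the synthetic experiment
#'
#' All randomness is governed by the single integer `seed`. Draw order is
#' fixed: block membership, absent genes, per-gene baseline effects,
#' per-probe affinities, per-cell noise, category membership.
#'
#' @param n_genes Number of genes on the simulated array.
#' @param probes_per_gene Probes per probe set (default 11).
#' @param conditions Ordered condition labels.
#' @param replicates_per_condition Biological replicates per condition.
#' @param baseline_log2_mean Mean log2 intensity of expressed genes.
#' @param gene_sd_log2 SD of the per-gene baseline offset (log2).
#' @param noise_sd_log2 SD of the per-measurement noise (log2).
#' @param probe_sd_log2 SD of the fixed per-probe affinity offsets (log2).
#' @param planted_blocks List of blocks, each
#'   `list(name, conditions, n_genes, effect_log2)` with `effect_log2 >= 1`.
#' @param absent_fraction Fraction of genes emitted at background in every
#'   sample.
#' @param background_level Array background intensity (linear scale).
#' @param categories List of `list(name, size, block, fraction)`; `block`
#'   `NA` for null categories.
#' @param symbol_assignments Named list condition -> symbols to rename the
#'   leading genes of that condition's selective block; `NULL` for none.
#' @param seed Integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 1000,
                           probes_per_gene = 11,
                           conditions = c("G9", "S9", "G22", "S22"),
                           replicates_per_condition = 3,
                           baseline_log2_mean = 8,
                           gene_sd_log2 = 1.0,
                           noise_sd_log2 = 0.35,
                           probe_sd_log2 = 0.5,
                           planted_blocks = default_planted_blocks(conditions),
                           absent_fraction = 0.1,
                           background_level = 32,
                           categories = default_categories(conditions),
                           symbol_assignments = default_symbol_assignments(),
                           seed = 1L) {
  stopifnot(n_genes >= 1, probes_per_gene >= 1, replicates_per_condition >= 1,
            noise_sd_log2 >= 0, probe_sd_log2 >= 0, gene_sd_log2 >= 0,
            absent_fraction >= 0, absent_fraction <= 1, background_level >= 0,
            length(conditions) >= 1, !anyDuplicated(conditions))
  for (b in planted_blocks) {
    stopifnot(all(c("name", "conditions", "n_genes", "effect_log2") %in% names(b)))
    if (b$effect_log2 < 1) stop("block '", b$name, "': effect_log2 must be >= 1")
    if (!all(b$conditions %in% conditions)) {
      stop("block '", b$name, "' targets unknown condition(s)")
    }
  }
  n_block_genes <- sum(vapply(planted_blocks, `[[`, numeric(1), "n_genes"))
  n_absent <- round(absent_fraction * n_genes)
  if (n_block_genes + n_absent > n_genes) {
    stop("infeasible spec: planted blocks (", n_block_genes, ") plus absent genes (",
         n_absent, ") exceed n_genes (", n_genes, ")")
  }
  block_names <- vapply(planted_blocks, `[[`, character(1), "name")
  if (anyDuplicated(block_names)) stop("duplicated block names")
  for (cat in categories) {
    stopifnot(all(c("name", "size", "block", "fraction") %in% names(cat)))
    if (!is.na(cat$block)) {
      if (!cat$block %in% block_names) {
        stop("category '", cat$name, "' references unknown block '", cat$block, "'")
      }
      blk <- planted_blocks[[match(cat$block, block_names)]]
      if (round(cat$fraction * cat$size) > blk$n_genes) {
        stop("category '", cat$name, "' wants more block genes than the block holds")
      }
    }
    if (cat$size > n_genes) stop("category '", cat$name, "' larger than the universe")
  }
  structure(list(n_genes = as.integer(n_genes),
                 probes_per_gene = as.integer(probes_per_gene),
                 conditions = conditions,
                 replicates_per_condition = as.integer(replicates_per_condition),
                 baseline_log2_mean = baseline_log2_mean,
                 gene_sd_log2 = gene_sd_log2,
                 noise_sd_log2 = noise_sd_log2,
                 probe_sd_log2 = probe_sd_log2,
                 planted_blocks = planted_blocks,
                 absent_fraction = absent_fraction,
                 background_level = background_level,
                 categories = categories,
                 symbol_assignments = symbol_assignments,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic probe-level experiment
#'
#' Per-probe intensities are
#' `2 ^ (baseline + gene effect + block effects for the sample's condition
#' + probe affinity + noise)`; absent genes use
#' `log2(background_level)` in place of baseline, gene and block effects.
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `matrix` (probe-level [expr_matrix()]),
#'   `truth` (per-gene data.frame: `gene_id`, `blocks`,
#'   `selective_condition`, `absent`), and `categories`
#'   (a [gene_set_collection()] whose attribute `"enriched_block"` records
#'   each spiked category's source block).
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  gene_ids <- sprintf("gene%05d", seq_len(n))

  # 1) block membership (disjoint, drawn without replacement in list order)
  available <- seq_len(n)
  block_genes <- list()
  for (b in spec$planted_blocks) {
    idx <- sort(sample(available, b$n_genes))
    block_genes[[b$name]] <- idx
    available <- setdiff(available, idx)
  }
  # 2) absent genes, never overlapping a planted block
  n_absent <- round(spec$absent_fraction * n)
  absent_idx <- sort(sample(available, n_absent))

  # plant recognisable symbols into single-condition blocks
  if (!is.null(spec$symbol_assignments)) {
    for (cc in names(spec$symbol_assignments)) {
      bname <- paste0(cc, "_block")
      if (!bname %in% names(block_genes)) next
      syms <- spec$symbol_assignments[[cc]]
      idx <- block_genes[[bname]][seq_along(syms)]
      gene_ids[idx] <- syms
    }
  }

  # 3) per-gene baseline offsets; 4) per-probe affinities
  gene_effect <- stats::rnorm(n, 0, spec$gene_sd_log2)
  p <- spec$probes_per_gene
  affinity <- stats::rnorm(n * p, 0, spec$probe_sd_log2)

  samples <- data.frame(
    sample_id = as.vector(t(outer(spec$conditions,
                                  seq_len(spec$replicates_per_condition),
                                  function(cc, r) paste0(cc, "_r", r)))),
    condition = rep(spec$conditions, each = spec$replicates_per_condition),
    replicate = rep(seq_len(spec$replicates_per_condition),
                    times = length(spec$conditions)),
    stringsAsFactors = FALSE)
  n_samp <- nrow(samples)

  absent <- logical(n)
  absent[absent_idx] <- TRUE
  base <- ifelse(absent, log2(max(spec$background_level, .Machine$double.eps)),
                 spec$baseline_log2_mean + gene_effect)

  # per-gene, per-condition block effect
  cond_effect <- matrix(0, n, length(spec$conditions),
                        dimnames = list(NULL, spec$conditions))
  for (b in spec$planted_blocks) {
    cond_effect[block_genes[[b$name]], b$conditions] <-
      cond_effect[block_genes[[b$name]], b$conditions] + b$effect_log2
  }

  # 5) noise, drawn row-major over (gene-probe rows) x samples
  mu <- matrix(rep(base, each = p) + affinity, n * p, n_samp)
  cond_of_sample <- samples$condition
  blk <- cond_effect[rep(seq_len(n), each = p), cond_of_sample, drop = FALSE]
  blk[rep(absent, each = p), ] <- 0
  noise <- matrix(stats::rnorm(n * p * n_samp, 0, spec$noise_sd_log2), n * p, n_samp)
  values <- 2^(mu + blk + noise)
  values[values < 0] <- 0
  colnames(values) <- samples$sample_id

  feature_ids <- rep(gene_ids, each = p)
  probe_index <- rep(seq_len(p), times = n)
  mat <- expr_matrix(values, feature_ids, samples, probe_index = probe_index,
                     min_probes = min(3, p))

  single_cond <- vapply(spec$planted_blocks, function(b)
    if (length(b$conditions) == 1) b$conditions else NA_character_, character(1))
  names(single_cond) <- names(block_genes)
  blocks_of <- rep("", n)
  selective <- rep(NA_character_, n)
  for (bn in names(block_genes)) {
    idx <- block_genes[[bn]]
    blocks_of[idx] <- ifelse(nzchar(blocks_of[idx]),
                             paste(blocks_of[idx], bn, sep = ";"), bn)
    if (!is.na(single_cond[[bn]])) selective[idx] <- single_cond[[bn]]
  }
  truth <- data.frame(gene_id = gene_ids, blocks = blocks_of,
                      selective_condition = selective, absent = absent,
                      stringsAsFactors = FALSE)
  attr(truth, "conditions") <- spec$conditions

  # 6) categories
  sets <- list()
  enriched_block <- character(0)
  for (cat in spec$categories) {
    if (!is.na(cat$block)) {
      k_block <- round(cat$fraction * cat$size)
      from_block <- sample(block_genes[[cat$block]], k_block)
      pool <- setdiff(seq_len(n), block_genes[[cat$block]])
      rest <- sample(pool, cat$size - k_block)
      members <- gene_ids[c(from_block, rest)]
    } else {
      members <- gene_ids[sample(seq_len(n), cat$size)]
    }
    sets[[cat$name]] <- sort(members)
    enriched_block[cat$name] <- cat$block
  }
  categories <- gene_set_collection(sets, universe = gene_ids)
  attr(categories, "enriched_block") <- enriched_block

  list(matrix = mat, truth = truth, categories = categories)
}

#' Compare called gene sets with the generator's ground truth
#'
#' For each called set (named by condition), sensitivity is the fraction
#' of planted condition-selective genes recovered and the false-discovery
#' proportion (FDP) is the fraction of called genes that were not planted
#' for that condition. An empty called set has sensitivity 0 and FDP 0 by
#' convention.
#'
#' @param truth Ground-truth data.frame from [generate_expression()].
#' @param called A [gene_set_collection()] whose set names are condition
#'   labels known to the truth table.
#' @return data.frame: `set_name`, `n_planted`, `n_called`, `n_recovered`,
#'   `sensitivity`, `fdp`.
#' @export
truth_confusion <- function(truth, called) {
  stopifnot(inherits(called, "gene_set_collection"))
  conditions <- attr(truth, "conditions")
  if (is.null(conditions)) conditions <- unique(stats::na.omit(truth$selective_condition))
  unknown <- setdiff(names(called$sets), conditions)
  if (length(unknown) > 0) {
    stop("called set name(s) do not match any condition: ",
         paste(unknown, collapse = ", "))
  }
  rows <- lapply(names(called$sets), function(nm) {
    planted <- truth$gene_id[!is.na(truth$selective_condition) &
                               truth$selective_condition == nm]
    called_ids <- called$sets[[nm]]
    n_rec <- length(intersect(planted, called_ids))
    data.frame(set_name = nm,
               n_planted = length(planted),
               n_called = length(called_ids),
               n_recovered = n_rec,
               sensitivity = if (length(planted) == 0) NA_real_
                             else n_rec / length(planted),
               fdp = if (length(called_ids) == 0) 0
                     else (length(called_ids) - n_rec) / length(called_ids),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
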