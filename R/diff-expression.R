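# Two detection layers: per-sample Present/Absent calls from probe
# intensities versus array background, and the replicate-pairwise
# concordance differential-expression caller (every experimental
# replicate against every reference replicate, 3 x 3 = 9 comparisons,
# a 77% consistency-of-change cutoff, then a two-fold change filter
# on condition mean signals).

#' Differential-expression configuration
#'
#' Houses the procedural constants of the caller: detection and change
#' alpha 0.05, concordance cutoff 0.77 (at least 7 of 9 pairwise
#' comparisons agreeing), and a two-fold change threshold.
#'
#' @param detection_alpha One-sided alpha for Present calls.
#' @param change_alpha Two-sided alpha for per-pair change calls.
#' @param concordance_cutoff Minimum fraction of agreeing pairwise calls.
#' @param fc_threshold Fold-change threshold (> 1).
#' @param signal_summary `"median"` or `"trimmed_mean"` (10% trimmed).
#' @param min_present Minimum Present calls required (reported, default 0).
#' @param pair_test `"signed_rank"` (matched probes) or `"rank_sum"`
#'   (unmatched Wilcoxon rank-sum on raw probe intensities).
#' @return An object of class `de_config`.
#' @export
de_config <- function(detection_alpha = 0.05, change_alpha = 0.05,
                      concordance_cutoff = 0.77, fc_threshold = 2.0,
                      signal_summary = c("median", "trimmed_mean"),
                      min_present = 0L,
                      pair_test = c("signed_rank", "rank_sum")) {
  signal_summary <- match.arg(signal_summary)
  pair_test <- match.arg(pair_test)
  stopifnot(detection_alpha > 0, detection_alpha < 1,
            change_alpha > 0, change_alpha < 1,
            concordance_cutoff > 0, concordance_cutoff <= 1,
            fc_threshold > 1, min_present >= 0)
  structure(list(detection_alpha = detection_alpha, change_alpha = change_alpha,
                 concordance_cutoff = concordance_cutoff,
                 fc_threshold = fc_threshold, signal_summary = signal_summary,
                 min_present = as.integer(min_present), pair_test = pair_test),
            class = "de_config")
}

#' Smallest concordant count satisfying the cutoff
#'
#' Ceiling semantics: the smallest integer `c` with `c / n_pairs >= cutoff`
#' (7 for the default 0.77 cutoff with 9 pairwise comparisons).
#'
#' @param n_pairs Number of pairwise comparisons.
#' @param cutoff Concordance cutoff in (0, 1].
#' @return Integer count.
#' @export
required_concordant_count <- function(n_pairs, cutoff) {
  stopifnot(n_pairs >= 1, cutoff > 0, cutoff <= 1)
  as.integer(ceiling(cutoff * n_pairs - 1e-9))
}

#' Summarize probe-level intensities to one signal per gene and sample
#'
#' A simple documented summarizer (median by default, or a 10%-trimmed
#' mean) standing where a platform-specific probe-set signal computation
#' would sit. Gene-level input passes through unchanged.
#'
#' @param matrix An [expr_matrix()].
#' @param method `"median"` or `"trimmed_mean"`.
#' @return A gene-level `expr_matrix` (one row per feature, input feature
#'   order preserved by first occurrence).
#' @export
summarize_signal <- function(matrix, method = c("median", "trimmed_mean")) {
  method <- match.arg(method)
  if (!is_probe_level(matrix)) return(matrix)
  f <- factor(matrix$feature_ids, levels = unique(matrix$feature_ids))
  if (any(tabulate(f) == 0)) stop("feature with zero probes")
  fun <- if (method == "median") function(v) stats::median(v)
         else function(v) mean(v, trim = 0.1)
  out <- apply(matrix$values, 2, function(col) tapply(col, f, fun))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(levels(f), names(out)))
  expr_matrix(out, feature_ids = levels(f), samples = matrix$samples)
}

#' Present/Absent detection calls
#'
#' Per (gene, sample), a one-sided Wilcoxon signed-rank test of the
#' probe log2 intensities against the array background; Present when
#' p < `detection_alpha`. Genes with fewer than 3 probes are called
#' Absent with p = 1 (conservative) and a warning.
#'
#' @param matrix Probe-level [expr_matrix()].
#' @param background Background intensity (linear scale, >= 0).
#' @param cfg A [de_config()].
#' @return data.frame: `feature_id`, `sample_id`, `status`
#'   (`"Present"`/`"Absent"`), `detection_p`.
#' @export
detection_call <- function(matrix, background, cfg = de_config()) {
  stopifnot(is_probe_level(matrix), background >= 0)
  f <- factor(matrix$feature_ids, levels = unique(matrix$feature_ids))
  idx_by_gene <- split(seq_len(nrow(matrix$values)), f)
  log_bg <- log2(max(background, .Machine$double.xmin))
  genes <- levels(f)
  n_samp <- ncol(matrix$values)
  res <- vector("list", length(genes))
  warned <- FALSE
  for (gi in seq_along(genes)) {
    rows <- idx_by_gene[[gi]]
    p <- numeric(n_samp)
    if (length(rows) < 3) {
      if (!warned) {
        warning("gene(s) with fewer than 3 probes called Absent with p = 1")
        warned <- TRUE
      }
      p[] <- 1
    } else {
      lx <- log2(pmax(matrix$values[rows, , drop = FALSE], .Machine$double.xmin))
      for (j in seq_len(n_samp)) {
        p[j] <- signed_rank_test(lx[, j] - log_bg, alternative = "greater")$p_value
      }
    }
    res[[gi]] <- data.frame(feature_id = genes[gi],
                            sample_id = colnames(matrix$values),
                            status = ifelse(p < cfg$detection_alpha, "Present", "Absent"),
                            detection_p = p, stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Replicate-pairwise change calls between two conditions
#'
#' Every experimental replicate is compared with every reference
#' replicate (3 x 3 = 9 pairwise comparisons for triplicates). For each
#' pair and gene, a two-sided rank test on the matched per-probe log2
#' ratios against zero (signed-rank; or an unmatched rank-sum on raw
#' probe intensities when `cfg$pair_test == "rank_sum"`). Direction is
#' the sign of the median log-ratio when p < `change_alpha`, else
#' `NoChange`.
#'
#' @param matrix Probe-level [expr_matrix()].
#' @param cond_exp Experimental condition label.
#' @param cond_ref Reference condition label.
#' @param cfg A [de_config()].
#' @return data.frame: `feature_id`, `sample_exp`, `sample_ref`,
#'   `direction` (`"Increase"`/`"Decrease"`/`"NoChange"`), `change_p`.
#' @export
pairwise_change_calls <- function(matrix, cond_exp, cond_ref, cfg = de_config()) {
  stopifnot(is_probe_level(matrix))
  samples <- matrix$samples
  for (cc in c(cond_exp, cond_ref)) {
    if (!cc %in% samples$condition) stop("unknown condition label: ", cc)
  }
  exp_ids <- samples$sample_id[samples$condition == cond_exp]
  ref_ids <- samples$sample_id[samples$condition == cond_ref]
  f <- factor(matrix$feature_ids, levels = unique(matrix$feature_ids))
  idx_by_gene <- split(seq_len(nrow(matrix$values)), f)
  genes <- levels(f)
  vals <- pmax(matrix$values, .Machine$double.xmin)
  out <- vector("list", length(exp_ids) * length(ref_ids))
  k <- 0
  for (se in exp_ids) {
    for (sr in ref_ids) {
      k <- k + 1
      p <- numeric(length(genes))
      med <- numeric(length(genes))
      for (gi in seq_along(genes)) {
        rows <- idx_by_gene[[gi]]
        if (cfg$pair_test == "signed_rank") {
          lr <- log2(vals[rows, se]) - log2(vals[rows, sr])
          tst <- signed_rank_test(lr, alternative = "two.sided")
          p[gi] <- tst$p_value
          med[gi] <- stats::median(lr)
        } else {
          xe <- vals[rows, se]; xr <- vals[rows, sr]
          p[gi] <- stats::wilcox.test(xe, xr, exact = FALSE, correct = TRUE)$p.value
          med[gi] <- stats::median(log2(xe)) - stats::median(log2(xr))
        }
      }
      dir <- rep("NoChange", length(genes))
      sig <- p < cfg$change_alpha & med != 0
      dir[sig & med > 0] <- "Increase"
      dir[sig & med < 0] <- "Decrease"
      out[[k]] <- data.frame(feature_id = genes, sample_exp = se, sample_ref = sr,
                             direction = dir, change_p = p,
                             stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, out)
  attr(calls, "cond_exp") <- cond_exp
  attr(calls, "cond_ref") <- cond_ref
  calls
}

#' Concordance-based gene selection
#'
#' Aggregates the pairwise change calls per gene: the concordance is the
#' fraction of comparisons agreeing in the majority direction; a gene is
#' selected when at least `required_concordant_count()` comparisons agree
#' and its condition-mean fold change passes the two-fold filter in the
#' same direction. Fisher's combination of the pairwise p-values is
#' reported as a ranking aid but plays no role in selection.
#'
#' @param calls Output of [pairwise_change_calls()].
#' @param signals Gene-level [expr_matrix()] (see [summarize_signal()]).
#' @param cfg A [de_config()].
#' @return data.frame: `feature_id`, `n_pairs`, `n_increase`,
#'   `n_decrease`, `n_nochange`, `concordance`, `combined_p`,
#'   `fold_change`, `direction` (`"Up"`/`"Down"`/`"None"`), `selected`.
#' @export
concordance_select <- function(calls, signals, cfg = de_config()) {
  cond_exp <- attr(calls, "cond_exp")
  cond_ref <- attr(calls, "cond_ref")
  if (is.null(cond_exp) || is.null(cond_ref)) {
    stop("calls must carry cond_exp/cond_ref attributes from pairwise_change_calls()")
  }
  f <- factor(calls$feature_id, levels = unique(calls$feature_id))
  n_pairs <- tabulate(f)
  if (any(n_pairs == 0) || nrow(calls) == 0) stop("no pairwise calls")
  if (length(unique(n_pairs)) != 1) stop("incomplete calls: unequal pair counts per gene")
  n_inc <- tapply(calls$direction == "Increase", f, sum)
  n_dec <- tapply(calls$direction == "Decrease", f, sum)
  chisq <- tapply(calls$change_p, f, function(p) -2 * sum(log(pmax(p, 1e-300))))
  np <- n_pairs[1]
  combined_p <- stats::pchisq(chisq, df = 2 * np, lower.tail = FALSE)

  sam <- signals$samples
  mean_exp <- rowMeans(signals$values[, sam$sample_id[sam$condition == cond_exp],
                                      drop = FALSE])
  mean_ref <- rowMeans(signals$values[, sam$sample_id[sam$condition == cond_ref],
                                      drop = FALSE])
  names(mean_exp) <- names(mean_ref) <- signals$feature_ids
  genes <- levels(f)
  # floor the denominator at 1 intensity unit to avoid low-signal blow-ups
  fc <- pmax(mean_exp[genes], .Machine$double.xmin) / pmax(mean_ref[genes], 1.0)

  req <- required_concordant_count(np, cfg$concordance_cutoff)
  up <- n_inc >= req & fc >= cfg$fc_threshold
  down <- n_dec >= req & fc <= 1 / cfg$fc_threshold
  direction <- ifelse(up & !down, "Up", ifelse(down & !up, "Down",
                ifelse(up & down, ifelse(n_inc >= n_dec, "Up", "Down"), "None")))
  rec <- data.frame(feature_id = genes,
                    n_pairs = np,
                    n_increase = as.integer(n_inc),
                    n_decrease = as.integer(n_dec),
                    n_nochange = as.integer(np - n_inc - n_dec),
                    concordance = pmax(n_inc, n_dec) / np,
                    combined_p = as.numeric(combined_p),
                    fold_change = as.numeric(fc),
                    direction = direction,
                    selected = direction != "None",
                    stringsAsFactors = FALSE)
  attr(rec, "cond_exp") <- cond_exp
  attr(rec, "cond_ref") <- cond_ref
  rownames(rec) <- NULL
  rec
}

#' Marker panel report
#'
#' For a list of marker genes, reports the fold-change call between the
#' two conditions of a concordance table (`Up` / `Down` / `Unchanged`)
#' and the number of Present calls among each condition's replicates.
#' Markers absent from the matrix are listed separately, not an error.
#'
#' @param records Output of [concordance_select()].
#' @param detections Output of [detection_call()].
#' @param markers A [gene_set_collection()]; all sets are pooled.
#' @param samples Optional sample sheet mapping `sample_id` to
#'   `condition`; when `NULL`, conditions are parsed from the
#'   `<condition>_r<replicate>` sample naming convention.
#' @return List with `report` (data.frame: `feature_id`, `call`,
#'   one `present_<condition>` column per condition) and
#'   `not_represented` (character vector).
#' @export
marker_panel <- function(records, detections, markers, samples = NULL) {
  stopifnot(inherits(markers, "gene_set_collection"))
  ids <- unique(unlist(markers$sets, use.names = FALSE))
  known <- ids[ids %in% records$feature_id]
  not_represented <- setdiff(ids, known)
  rec <- records[match(known, records$feature_id), ]
  call <- ifelse(rec$selected & rec$direction == "Up", "Up",
                 ifelse(rec$selected & rec$direction == "Down", "Down", "Unchanged"))
  report <- data.frame(feature_id = known, call = call, stringsAsFactors = FALSE)
  det <- detections[detections$feature_id %in% known, ]
  if (nrow(det) > 0) {
    det$condition <- if (!is.null(samples)) {
      samples$condition[match(det$sample_id, samples$sample_id)]
    } else {
      sub("_r[0-9]+$", "", det$sample_id)
    }
    for (cc in unique(det$condition)) {
      cnt <- tapply(det$status[det$condition == cc] == "Present",
                    det$feature_id[det$condition == cc], sum)
      report[[paste0("present_", cc)]] <- as.integer(cnt[report$feature_id])
    }
  }
  list(report = report, not_represented = not_represented)
}
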