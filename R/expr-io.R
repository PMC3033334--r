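#' Read a sample sheet
#'
#' A sample sheet is a tab-separated file with columns `sample_id`,
#' `condition` and `replicate` describing one hybridization per row,
#' e.g. the four populations G9/S9/G22/S22 with three biological
#' replicates each.
#'
#' @param path Path to a TSV file with a header row.
#' @return A data.frame with columns `sample_id`, `condition`, `replicate`.
#' @export
read_sample_sheet <- function(path) {
  stopifnot(file.exists(path))
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("sample_id", "condition", "replicate")
  missing <- setdiff(required, names(sheet))
  if (length(missing) > 0) {
    stop("sample sheet is missing column(s): ", paste(missing, collapse = ", "))
  }
  validate_sample_sheet(sheet[required])
}

validate_sample_sheet <- function(sheet) {
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$condition <- as.character(sheet$condition)
  sheet$replicate <- as.integer(sheet$replicate)
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicated sample_id in sample sheet: ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]), collapse = ", "))
  }
  if (any(is.na(sheet$replicate)) || any(sheet$replicate < 1)) {
    stop("replicate must be a positive integer")
  }
  key <- paste(sheet$condition, sheet$replicate)
  if (anyDuplicated(key)) {
    stop("duplicated (condition, replicate) pair in sample sheet")
  }
  sheet
}

#' Construct an expression matrix object
#'
#' The central container of the pipeline: a probe-level (or gene-level)
#' intensity matrix together with its sample sheet. Rows are probes when
#' `probe_index` is given (several rows per feature, like the 11
#' probes of a microarray probe set) and genes otherwise.
#'
#' @param values Numeric matrix of non-negative intensities; columns are
#'   samples and must be named by `sample_id`.
#' @param feature_ids Character vector, one per row; repeated across the
#'   probes of one feature when probe-level.
#' @param samples Sample sheet data.frame (`sample_id`, `condition`,
#'   `replicate`).
#' @param probe_index Optional integer vector, one per row; `NULL` for
#'   gene-level matrices.
#' @param min_probes Minimum number of probes required per feature when
#'   probe-level (default 3).
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, feature_ids, samples, probe_index = NULL,
                        min_probes = 3) {
  samples <- validate_sample_sheet(samples)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != length(feature_ids)) {
    stop("feature_ids length does not match number of rows")
  }
  missing <- setdiff(samples$sample_id, colnames(values))
  if (length(missing) > 0) {
    stop("sample(s) in sheet but not in matrix: ", paste(missing, collapse = ", "))
  }
  values <- values[, samples$sample_id, drop = FALSE]
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid intensity at row %d, sample '%s' (must be finite and >= 0)",
                 bad[1, 1], colnames(values)[bad[1, 2]]))
  }
  if (!is.null(probe_index)) {
    probe_index <- as.integer(probe_index)
    if (length(probe_index) != nrow(values)) {
      stop("probe_index length does not match number of rows")
    }
    n_probes <- table(feature_ids)
    short <- names(n_probes)[n_probes < min_probes]
    if (length(short) > 0) {
      stop("probe-level feature(s) with fewer than ", min_probes, " probes: ",
           paste(utils::head(short, 5), collapse = ", "))
    }
  } else if (anyDuplicated(feature_ids)) {
    stop("duplicated feature_ids in a gene-level matrix")
  }
  structure(list(values = values,
                 feature_ids = as.character(feature_ids),
                 probe_index = probe_index,
                 samples = samples),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  level <- if (is.null(x$probe_index)) "gene-level" else "probe-level"
  cat(sprintf("expr_matrix (%s): %d rows (%d features) x %d samples, %d condition(s)\n",
              level, nrow(x$values), length(unique(x$feature_ids)),
              ncol(x$values), length(unique(x$samples$condition))))
  invisible(x)
}

#' Is this matrix probe-level?
#' @param x An `expr_matrix`.
#' @return Logical.
#' @export
is_probe_level <- function(x) !is.null(x$probe_index)

#' Read an expression matrix with its sample sheet
#'
#' Expects a tab-separated file whose first column is the feature ID, whose
#' optional second column `probe_index` marks probe-level data, and whose
#' remaining columns are intensities named by sample. Lines starting with
#' `#` are comments. Row order is preserved.
#'
#' @param path Path to the matrix TSV.
#' @param sample_sheet_path Path to the sample sheet TSV.
#' @param min_probes Passed to [expr_matrix()].
#' @return An `expr_matrix`.
#' @export
read_expression_matrix <- function(path, sample_sheet_path, min_probes = 3) {
  stopifnot(file.exists(path))
  samples <- read_sample_sheet(sample_sheet_path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                           check.names = FALSE)
  if (ncol(tab) < 2) stop("expression matrix needs at least one sample column")
  probe_index <- NULL
  value_start <- 2
  if (ncol(tab) >= 2 && names(tab)[2] == "probe_index") {
    probe_index <- tab[[2]]
    value_start <- 3
  }
  values <- as.matrix(tab[, value_start:ncol(tab), drop = FALSE])
  rownames(values) <- NULL
  missing <- setdiff(samples$sample_id, colnames(values))
  if (length(missing) > 0) {
    stop("matrix header is missing sample(s) from sheet: ",
         paste(missing, collapse = ", "))
  }
  expr_matrix(values, feature_ids = as.character(tab[[1]]), samples = samples,
              probe_index = probe_index, min_probes = min_probes)
}

#' Write an expression matrix and its sample sheet
#'
#' Inverse of [read_expression_matrix()]: values survive a round trip at
#' full precision and in identical order.
#'
#' @param x An `expr_matrix`.
#' @param path Output path for the matrix TSV.
#' @param sample_sheet_path Output path for the sample sheet TSV.
#' @return Invisibly, `c(path, sample_sheet_path)`.
#' @export
write_expression_matrix <- function(x, path, sample_sheet_path) {
  tab <- data.frame(feature_id = x$feature_ids, stringsAsFactors = FALSE)
  if (!is.null(x$probe_index)) tab$probe_index <- x$probe_index
  vals <- as.data.frame(x$values, check.names = FALSE)
  # format full precision, no scientific rounding surprises
  for (j in seq_along(vals)) vals[[j]] <- sprintf("%.17g", vals[[j]])
  out <- cbind(tab, vals)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples, sample_sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, sample_sheet_path))
}

#' Construct a named collection of gene sets
#'
#' @param sets Named list of character vectors (set name -> member IDs).
#' @param universe Optional character vector; when given, every member must
#'   belong to it.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (length(sets) > 0 &&
      (is.null(names(sets)) || any(names(sets) == "") || anyDuplicated(names(sets)))) {
    stop("sets must have unique non-empty names")
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (!is.null(universe)) {
    universe <- unique(as.character(universe))
    for (nm in names(sets)) {
      outside <- setdiff(sets[[nm]], universe)
      if (length(outside) > 0) {
        stop("set '", nm, "' has member(s) outside the universe: ",
             paste(utils::head(outside, 5), collapse = ", "))
      }
    }
  }
  structure(list(sets = sets, universe = universe), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d set(s)%s\n", length(x$sets),
              if (is.null(x$universe)) "" else
                sprintf(", universe of %d IDs", length(x$universe))))
  invisible(x)
}

#' Read gene sets from a list file or a GMT file
#'
#' A "list" file holds one ID per line and yields a single set named after
#' the file. A GMT file holds one set per line: name, description, then the
#' member IDs, tab-separated. Duplicate members within a set are collapsed
#' with a warning.
#'
#' @param path Path to the file.
#' @param format `"list"` or `"gmt"`.
#' @param name Set name for `"list"` format (default: file base name).
#' @return A `gene_set_collection`.
#' @export
read_gene_sets <- function(path, format = c("list", "gmt"), name = NULL) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty gene-set file: ", path)
  if (format == "list") {
    ids <- trimws(lines)
    if (anyDuplicated(ids)) {
      warning(sum(duplicated(ids)), " duplicated ID(s) collapsed in ", path)
    }
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
    sets <- stats::setNames(list(unique(ids)), name)
  } else {
    sets <- list()
    for (i in seq_along(lines)) {
      fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(fields) < 3) {
        stop("malformed GMT line ", i, " (need category, description, >=1 member)")
      }
      members <- fields[-(1:2)]
      members <- members[nzchar(members)]
      if (anyDuplicated(members)) {
        warning("duplicated member(s) collapsed in GMT set '", fields[1], "'")
      }
      sets[[fields[1]]] <- unique(members)
    }
  }
  gene_set_collection(sets)
}

#' Write gene sets as a GMT file
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @param descriptions Optional named character vector of descriptions.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  lines <- vapply(names(collection$sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, desc, collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column pair table (ligand-receptor or ortholog map)
#'
#' @param path TSV with two columns; a header line is detected and skipped
#'   when its fields are non-numeric labels `id_a`/`id_b` (any header is
#'   accepted). Duplicate rows are rejected.
#' @param col_names Names to give the two columns.
#' @return A data.frame with the two requested columns.
#' @export
read_pair_table <- function(path, col_names = c("id_a", "id_b")) {
  stopifnot(file.exists(path), length(col_names) == 2)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                           header = TRUE)
  if (ncol(tab) < 2) stop("pair table needs two columns")
  tab <- tab[, 1:2]
  names(tab) <- col_names
  for (j in 1:2) {
    v <- trimws(as.character(tab[[j]]))
    v[is.na(tab[[j]])] <- ""
    tab[[j]] <- v
  }
  if (any(!nzchar(tab[[1]])) || any(!nzchar(tab[[2]]))) {
    stop("pair table has empty identifier(s)")
  }
  if (anyDuplicated(tab)) stop("duplicate row(s) in pair table")
  tab
}

#' Write result tables deterministically
#'
#' Every table is written as TSV with a fixed column order and rows sorted
#' by their leading identifier column(s), so two runs over the same results
#' produce byte-identical files. A manifest data.frame listing each file
#' and its row count is returned and also written as `manifest.tsv`.
#'
#' @param tables Named list of data.frames.
#' @param out_dir Output directory (created if needed).
#' @return The manifest data.frame (columns `file`, `rows`), invisibly.
#' @export
write_results <- function(tables, out_dir) {
  if (is.null(names(tables)) || any(names(tables) == "")) {
    stop("tables must be a named list")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2) != 0) stop("out_dir not writable: ", out_dir)
  manifest <- data.frame(file = character(0), rows = integer(0),
                         stringsAsFactors = FALSE)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]], stringsAsFactors = FALSE)
    sort_cols <- intersect(c("feature_id", "gene_id", "set_name", "cluster_name",
                             "category_name", "condition", "sample_id",
                             "ligand_id", "receptor_id"), names(tab))
    if (nrow(tab) > 1 && length(sort_cols) > 0) {
      tab <- tab[do.call(order, tab[sort_cols]), , drop = FALSE]
    }
    file <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- rbind(manifest, data.frame(file = basename(file), rows = nrow(tab),
                                           stringsAsFactors = FALSE))
  }
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
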