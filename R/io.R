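# Readers and writers for the tabular formats the pipeline consumes and emits.
#
# Formats (all plain text):
#   * sample sheet: CSV with header sample_id,group,lot,replicate,include
#   * raw intensities: one TSV per sample with columns probe_id, fg_median,
#     bg_median (optional gene_symbol); spots sharing a probe_id are replicate
#     spots of one unique probe
#   * expression matrix: TSV, probes as rows, samples as columns
#   * reports: JSON

SHEET_COLUMNS <- c("sample_id", "group", "lot", "replicate", "include")
RAW_COLUMNS <- c("probe_id", "fg_median", "bg_median")

#' Read and validate a sample sheet
#'
#' The sample sheet declares one row per hybridized array: its sample id,
#' treatment group, product lot, replicate index and an `include` QC flag.
#' Rows with `include = FALSE` (e.g. arrays excluded for poor quality) are
#' retained but never reach any statistical computation.
#'
#' @param path Path to a CSV file with header
#'   `sample_id,group,lot,replicate,include`.
#' @return A `data.frame` of class `"sample_sheet"` with validated columns;
#'   `include` is logical.
#' @examples
#' sheet <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
#'                     group = c("media", "media", "reference", "reference"),
#'                     lot = "l1", replicate = 1:4, include = TRUE)
#' tf <- tempfile(fileext = ".csv")
#' write.csv(sheet, tf, row.names = FALSE)
#' read_sample_sheet(tf)
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  sheet <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("sample sheet is empty or malformed: ", conditionMessage(e))
  )
  validate_sample_sheet(sheet)
}

validate_sample_sheet <- function(sheet) {
  missing <- setdiff(SHEET_COLUMNS, names(sheet))
  if (length(missing)) {
    stop("sample sheet is missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(sheet) == 0) stop("sample sheet has no rows")
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$group <- as.character(sheet$group)
  sheet$lot <- as.character(sheet$lot)
  if (anyDuplicated(sheet$sample_id)) {
    dup <- unique(sheet$sample_id[duplicated(sheet$sample_id)])
    stop("duplicate sample_id in sample sheet: ", paste(dup, collapse = ", "))
  }
  sheet$include <- parse_logical(sheet$include, "include")
  sheet$replicate <- as.integer(sheet$replicate)
  if (any(is.na(sheet$replicate)) || any(sheet$replicate < 1L)) {
    stop("replicate must be a positive integer")
  }
  inc_groups <- unique(sheet$group[sheet$include])
  orphan <- setdiff(unique(sheet$group), inc_groups)
  if (length(orphan)) {
    stop("group(s) with no included sample: ", paste(orphan, collapse = ", "))
  }
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

parse_logical <- function(x, what) {
  if (is.logical(x)) {
    out <- x
  } else {
    out <- rep(NA, length(x))
    xs <- toupper(trimws(as.character(x)))
    out[xs %in% c("TRUE", "T", "1", "YES")] <- TRUE
    out[xs %in% c("FALSE", "F", "0", "NO")] <- FALSE
  }
  if (any(is.na(out))) stop("column '", what, "' must be TRUE/FALSE")
  as.logical(out)
}

#' Samples retained for analysis
#'
#' @param sheet A sample sheet (see [read_sample_sheet()]).
#' @return The rows of `sheet` with `include = TRUE`.
#' @export
included_samples <- function(sheet) {
  sheet[sheet$include, , drop = FALSE]
}

#' Assemble per-sample raw intensity files into a raw intensity set
#'
#' Each included sample contributes one tab-delimited file with columns
#' `probe_id`, `fg_median`, `bg_median` (and optionally `gene_symbol`):
#' the median foreground and background fluorescence extracted for every
#' array spot. Spots sharing a `probe_id` are replicate spots of the same
#' unique probe. All files must list the identical spots in the same order.
#'
#' For GenePix-style exports, `fg_median`/`bg_median` correspond to the
#' "F532 Median" / "B532 Median" columns.
#'
#' @param paths Character vector of file paths, named by `sample_id`
#'   (unnamed paths are matched to included samples in sheet order).
#' @param sheet A sample sheet; only `include = TRUE` rows are read.
#' @return An object of class `"raw_intensity_set"`: a list with `fg` and
#'   `bg` spot-by-sample matrices (columns in sample-sheet order), a
#'   `spots` data.frame (`spot_id`, `unique_probe_id`, `gene_symbol`) and
#'   the included `targets` rows.
#' @export
read_raw_intensities <- function(paths, sheet) {
  sheet <- validate_sample_sheet(sheet)
  inc <- included_samples(sheet)
  if (is.null(names(paths))) {
    if (length(paths) != nrow(inc)) {
      stop("need one raw file per included sample (", nrow(inc), "), got ", length(paths))
    }
    names(paths) <- inc$sample_id
  }
  missing <- setdiff(inc$sample_id, names(paths))
  if (length(missing)) {
    stop("no raw file supplied for included sample(s): ", paste(missing, collapse = ", "))
  }
  tabs <- lapply(inc$sample_id, function(sid) read_one_raw(paths[[sid]], sid))
  names(tabs) <- inc$sample_id

  ref <- tabs[[1L]]$probe_id
  bad <- vapply(tabs, function(t) !identical(t$probe_id, ref), logical(1))
  if (any(bad)) {
    stop("probe lists differ across samples (relative to ",
         inc$sample_id[1L], "): ", paste(inc$sample_id[bad], collapse = ", "))
  }
  fg <- vapply(tabs, function(t) t$fg_median, numeric(length(ref)))
  bg <- vapply(tabs, function(t) t$bg_median, numeric(length(ref)))
  dim(fg) <- dim(bg) <- c(length(ref), nrow(inc))
  colnames(fg) <- colnames(bg) <- inc$sample_id
  spot_id <- make.unique(ref, sep = "_spot")
  rownames(fg) <- rownames(bg) <- spot_id
  gene_symbol <- tabs[[1L]]$gene_symbol %||% rep(NA_character_, length(ref))
  spots <- data.frame(spot_id = spot_id, unique_probe_id = ref,
                      gene_symbol = gene_symbol, stringsAsFactors = FALSE)
  new_raw_intensity_set(fg, bg, spots, inc)
}

read_one_raw <- function(path, sid) {
  if (!file.exists(path)) stop("raw intensity file not found for ", sid, ": ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(RAW_COLUMNS, names(tab))
  if (length(missing)) {
    stop("raw file for ", sid, " is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!all(is.finite(tab$fg_median)) || !all(is.finite(tab$bg_median))) {
    stop("raw file for ", sid, " contains non-finite intensities")
  }
  if (any(tab$fg_median < 0) || any(tab$bg_median < 0)) {
    stop("raw file for ", sid, " contains negative intensities")
  }
  tab$probe_id <- as.character(tab$probe_id)
  tab
}

new_raw_intensity_set <- function(fg, bg, spots, targets) {
  stopifnot(identical(dim(fg), dim(bg)))
  if (any(fg < 0) || any(bg < 0)) stop("raw intensities must be nonnegative")
  structure(list(fg = fg, bg = bg, spots = spots, targets = targets),
            class = "raw_intensity_set")
}

#' @export
print.raw_intensity_set <- function(x, ...) {
  cat("raw_intensity_set:", nrow(x$fg), "spots x", ncol(x$fg), "samples;",
      length(unique(x$spots$unique_probe_id)), "unique probes\n")
  invisible(x)
}

#' Write a raw intensity set as per-sample TSV files
#'
#' Inverse of [read_raw_intensities()]; used by the synthetic-data generator
#' to emit datasets in the same dialect real exports are read from.
#'
#' @param raw A `raw_intensity_set`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths (one per sample).
#' @export
write_raw_intensities <- function(raw, dir) {
  stopifnot(inherits(raw, "raw_intensity_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sids <- colnames(raw$fg)
  paths <- file.path(dir, paste0(sids, ".tsv"))
  names(paths) <- sids
  has_symbol <- !all(is.na(raw$spots$gene_symbol))
  for (j in seq_along(sids)) {
    tab <- data.frame(probe_id = raw$spots$unique_probe_id,
                      fg_median = raw$fg[, j],
                      bg_median = raw$bg[, j])
    if (has_symbol) tab$gene_symbol <- raw$spots$gene_symbol
    utils::write.table(tab, paths[j], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  paths
}

#' Construct an expression matrix object
#'
#' Container for analysis-ready log2 expression: one row per unique probe,
#' one column per included sample, plus probe annotation and a provenance
#' record of the preprocessing steps applied (in order).
#'
#' @param E Numeric matrix, probes x samples, with unique probe ids as
#'   rownames and sample ids as colnames.
#' @param genes Optional data.frame with `unique_probe_id` and `gene_symbol`.
#' @param targets Optional sample sheet rows for the columns of `E`.
#' @param provenance List describing the steps that produced `E`.
#' @return An object of class `"expression_matrix"`.
#' @export
expression_matrix <- function(E, genes = NULL, targets = NULL, provenance = list()) {
  stopifnot(is.matrix(E), is.numeric(E))
  if (is.null(rownames(E))) stop("E must carry unique probe ids as rownames")
  if (anyDuplicated(rownames(E))) stop("expression matrix rows must be one per unique probe")
  if (!all(is.finite(E))) stop("expression values must all be finite")
  if (is.null(genes)) {
    genes <- data.frame(unique_probe_id = rownames(E),
                        gene_symbol = NA_character_, stringsAsFactors = FALSE)
  }
  structure(list(E = E, genes = genes, targets = targets, provenance = provenance),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$E)

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$E), "probes x", ncol(x$E), "samples\n")
  if (length(x$provenance)) {
    steps <- vapply(x$provenance, function(s) s$step %||% "?", character(1))
    cat("provenance:", paste(steps, collapse = " -> "), "\n")
  }
  invisible(x)
}

# Accept either an expression_matrix or a bare numeric matrix.
as_expr_matrix <- function(x) {
  if (inherits(x, "expression_matrix")) return(x$E)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("expected an expression_matrix or a numeric matrix")
}

#' Write an expression matrix to TSV
#'
#' Probes as rows, samples as columns; first column `unique_probe_id`.
#' The written values round-trip through [read_expression_matrix()] to at
#' least six decimal places.
#'
#' @param m An `expression_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  stopifnot(inherits(m, "expression_matrix"))
  if (!all(is.finite(m$E))) stop("refusing to write non-finite expression values")
  tab <- data.frame(unique_probe_id = rownames(m$E), m$E,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix written by [write_expression_matrix()]
#'
#' @param path TSV path; header must name the samples, first column
#'   `unique_probe_id`.
#' @param sheet Optional sample sheet; if given, the file's samples must
#'   exactly match the included samples (in order).
#' @return An `expression_matrix`.
#' @export
read_expression_matrix <- function(path, sheet = NULL) {
  if (!file.exists(path)) stop("expression matrix file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1L] != "unique_probe_id") {
    stop("expression matrix file must start with a unique_probe_id column")
  }
  E <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(E) <- as.character(tab$unique_probe_id)
  targets <- NULL
  if (!is.null(sheet)) {
    inc <- included_samples(validate_sample_sheet(sheet))
    if (!identical(colnames(E), inc$sample_id)) {
      stop("expression matrix samples do not match the sample sheet's included samples")
    }
    targets <- inc
  }
  expression_matrix(E, targets = targets,
                    provenance = list(list(step = "read_expression_matrix", path = path)))
}

#' Write an analysis result as a JSON report
#'
#' Serializes any result produced by the pipeline (probe test tables,
#' permutation-count results, mvt results, comparison grids, full pipeline
#' bundles) into a machine-readable JSON document carrying the statistics,
#' thresholds, seeds and counts needed to regenerate its summary tables.
#'
#' @param results A result object (or plain list).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @seealso [read_report()]
#' @export
write_report <- function(results, path) {
  jsonlite::write_json(as_report(results), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a report written by [write_report()]
#' @param path JSON path.
#' @return A list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Convert a result object to a serializable report list
#' @param x A result object.
#' @param ... Unused.
#' @return A plain list safe to serialize as JSON.
#' @export
as_report <- function(x, ...) UseMethod("as_report")

#' @export
as_report.default <- function(x, ...) {
  if (is.list(x)) return(lapply(unclass(x), as_report))
  x
}

#' @export
as_report.data.frame <- function(x, ...) x

#' @export
as_report.probe_test_table <- function(x, ...) {
  a <- attributes(x)
  list(kind = "probe_tests",
       group_a = a$group_a, group_b = a$group_b,
       alpha = a$alpha, n_probes = nrow(x), pi0 = a$pi0,
       counts = list(uncorrected = sum(x$sig_uncorrected),
                     fdr = sum(x$sig_fdr),
                     bonferroni = sum(x$sig_bonferroni)))
}

#' @export
as_report.perm_count_result <- function(x, ...) {
  c(list(kind = "permutation_count_test"), unclass(x))
}

#' @export
as_report.mvt_result <- function(x, ...) {
  c(list(kind = "mvt"), unclass(x))
}

#' @export
as_report.comparison_grid <- function(x, ...) {
  list(kind = "comparison_grid", groups = x$groups,
       count_matrix = x$count_matrix, mvt_p_matrix = x$mvt_p_matrix,
       q_threshold = x$q_threshold, fc_threshold = x$fc_threshold,
       n_probes = x$n_probes, seed = x$seed)
}

#' @export
as_report.hclust <- function(x, ...) {
  list(kind = "ward_tree", merge = x$merge, height = x$height, labels = x$labels)
}
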