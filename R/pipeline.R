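# Orchestration of the full equivalence analysis: responsive-probe
# selection, the pairwise comparison grid, the marker-gene panel, the
# three-pronged equivalence verdict and the end-to-end pipeline runner.

#' Select treatment-responsive probes
#'
#' Tests `treated` against `reference` (typically the media control) and
#' keeps probes with `q < q_thresh` and `|log2_fold| >= log2(fc_thresh)`
#' (the fold-change filter is two-sided). The resulting set defines a
#' sensitized feature space for the multivariate comparisons.
#'
#' @param expr An `expression_matrix`.
#' @param sheet Sample sheet (optional when stored in `expr`).
#' @param treated,reference Group labels.
#' @param q_thresh Q-value threshold (default 0.05).
#' @param fc_thresh Linear fold-change threshold (default 1.3).
#' @return A list of class `"responsive_set"`: `probe_ids`, the thresholds
#'   and the source comparison.
#' @export
select_responsive_probes <- function(expr, sheet = NULL, treated, reference,
                                     q_thresh = 0.05, fc_thresh = 1.3) {
  tt <- probe_tests(expr, sheet, treated, reference)
  keep <- tt$q_value < q_thresh & abs(tt$log2_fold) >= log2(fc_thresh)
  structure(list(probe_ids = tt$unique_probe_id[keep],
                 q_threshold = q_thresh,
                 fc_threshold = fc_thresh,
                 source_comparison = c(treated, reference)),
            class = "responsive_set")
}

#' @export
print.responsive_set <- function(x, ...) {
  cat(sprintf("responsive_set: %d probes (q < %g, FC >= %g; %s vs %s)\n",
              length(x$probe_ids), x$q_threshold, x$fc_threshold,
              x$source_comparison[1L], x$source_comparison[2L]))
  invisible(x)
}

#' Pairwise comparison grid over treatment groups
#'
#' For every unordered pair of groups: (i) the number of probes (within
#' `probe_set`, if given) passing `q < q_thresh` and `|log2_fold| >=
#' log2(fc_thresh)` in that pair's own test (q-values computed within the
#' restricted set, so the FDR denominator is the set size), and (ii) the
#' mvt permutation p-value on the Pearson dissimilarity restricted to the
#' same probes.
#'
#' @inheritParams select_responsive_probes
#' @param groups Character vector of >= 2 group labels.
#' @param probe_set Optional `responsive_set` (or character vector of probe
#'   ids) restricting all comparisons.
#' @param n_perm_mvt Permutations per mvt test (default `1e5`).
#' @param seed RNG seed; each pair gets a deterministic child seed.
#' @return A list of class `"comparison_grid"` with symmetric
#'   `count_matrix` and `mvt_p_matrix` (NA diagonals).
#' @export
comparison_grid <- function(expr, sheet = NULL, groups, probe_set = NULL,
                            q_thresh = 0.05, fc_thresh = 1.3,
                            n_perm_mvt = 1e5, seed = NULL) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  probe_ids <- if (inherits(probe_set, "responsive_set")) probe_set$probe_ids else probe_set
  X <- as_expr_matrix(expr)
  sub_expr <- if (is.null(probe_ids)) expr else {
    miss <- setdiff(probe_ids, rownames(X))
    if (length(miss)) stop("probe_set names absent probes, e.g. ", miss[1L])
    if (inherits(expr, "expression_matrix")) {
      expression_matrix(X[probe_ids, , drop = FALSE],
                        genes = expr$genes[match(probe_ids, expr$genes$unique_probe_id), ],
                        targets = expr$targets, provenance = expr$provenance)
    } else X[probe_ids, , drop = FALSE]
  }
  d <- pearson_dissimilarity(sub_expr)
  gi <- resolve_groups(sub_expr, sheet, groups)
  ng <- length(groups)
  counts <- matrix(NA_real_, ng, ng, dimnames = list(groups, groups))
  mvt_p <- counts
  pair_id <- 0L
  for (i in seq_len(ng - 1L)) {
    for (j in (i + 1L):ng) {
      pair_id <- pair_id + 1L
      tt <- probe_tests(sub_expr, sheet, groups[i], groups[j], alpha = q_thresh)
      counts[i, j] <- counts[j, i] <-
        sum(tt$q_value < q_thresh & abs(tt$log2_fold) >= log2(fc_thresh))
      mt <- mvt_permutation_test(d, gi$idx[[groups[i]]], gi$idx[[groups[j]]],
                                 n_perm = n_perm_mvt,
                                 seed = child_seed(seed, pair_id))
      mvt_p[i, j] <- mvt_p[j, i] <- mt$p_value
    }
  }
  structure(list(groups = groups, count_matrix = counts, mvt_p_matrix = mvt_p,
                 q_threshold = q_thresh, fc_threshold = fc_thresh,
                 n_probes = nrow(as_expr_matrix(sub_expr)),
                 n_perm_mvt = n_perm_mvt, seed = seed),
            class = "comparison_grid")
}

#' @export
print.comparison_grid <- function(x, ...) {
  cat("comparison_grid over", x$n_probes, "probes\nsignificant-probe counts:\n")
  print(x$count_matrix)
  cat("mvt permutation p-values:\n")
  print(x$mvt_p_matrix)
  invisible(x)
}

#' Marker-gene panel comparison
#'
#' For each requested gene symbol: the log2 mean-expression difference of
#' each product versus the reference group, and a pooled Student t-test of
#' product B versus product A with its log2 fold difference
#' (`mean(B) - mean(A)`). Genes mapping to several probes are reported at
#' the probe with the largest `|log2_fold|` versus reference for product A,
#' with the remaining probe ids listed; unmatched symbols are reported, not
#' fatal.
#'
#' @param expr An `expression_matrix` with gene annotation.
#' @param sheet Sample sheet (optional when stored in `expr`).
#' @param genes Character vector of gene symbols.
#' @param productA,productB Product group labels (e.g. reference product
#'   and test product).
#' @param reference Baseline group label (e.g. media).
#' @return A data.frame of class `"marker_panel"` with one row per matched
#'   gene; attribute `unmatched` lists symbols with no probe.
#' @export
marker_panel <- function(expr, sheet = NULL, genes, productA, productB, reference) {
  if (!inherits(expr, "expression_matrix") || all(is.na(expr$genes$gene_symbol))) {
    stop("marker_panel needs an expression_matrix with gene_symbol annotation")
  }
  gi <- resolve_groups(expr, sheet, c(productA, productB, reference))
  X <- gi$X
  mA <- rowMeans(X[, gi$idx[[productA]], drop = FALSE])
  mB <- rowMeans(X[, gi$idx[[productB]], drop = FALSE])
  mR <- rowMeans(X[, gi$idx[[reference]], drop = FALSE])
  lfc_A <- mA - mR
  lfc_B <- mB - mR
  symbol_of <- expr$genes$gene_symbol[match(rownames(X), expr$genes$unique_probe_id)]

  rows <- list()
  unmatched <- character(0)
  for (g in genes) {
    hits <- which(!is.na(symbol_of) & toupper(symbol_of) == toupper(g))
    if (!length(hits)) {
      unmatched <- c(unmatched, g)
      next
    }
    best <- hits[which.max(abs(lfc_A[hits]))]
    tt <- student_t_test(X[best, gi$idx[[productB]]], X[best, gi$idx[[productA]]],
                         variant = "pooled")
    rows[[g]] <- data.frame(
      gene_symbol = g,
      probe_id = rownames(X)[best],
      n_probes = length(hits),
      other_probes = paste(setdiff(rownames(X)[hits], rownames(X)[best]), collapse = ";"),
      log2_fold_a_vs_ref = unname(lfc_A[best]),
      log2_fold_b_vs_ref = unname(lfc_B[best]),
      between_product_p = tt$p_value,
      between_product_log2_fold = unname(mB[best] - mA[best]),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE))) else
    data.frame(gene_symbol = character(0), probe_id = character(0),
               n_probes = integer(0), other_probes = character(0),
               log2_fold_a_vs_ref = numeric(0), log2_fold_b_vs_ref = numeric(0),
               between_product_p = numeric(0), between_product_log2_fold = numeric(0))
  structure(out, class = c("marker_panel", "data.frame"),
            unmatched = unmatched,
            products = c(A = productA, B = productB, reference = reference))
}

#' Three-pronged equivalence verdict between two products
#'
#' Two products are reported "not distinguishable" when all three prongs
#' hold at level `alpha`: (1) the excess of nominally significant probes is
#' nonsignificant by the permutation-count test, (2) zero probes pass FDR
#' control (`q < alpha`), and (3) the mvt permutation p-value exceeds
#' `alpha`. Each prong attacks a different failure mode: per-probe shifts,
#' distributed weak shifts and coexpression-level shifts.
#'
#' @param expr An `expression_matrix`.
#' @param sheet Sample sheet (optional when stored in `expr`).
#' @param gA,gB Product group labels.
#' @param probe_set Optional `responsive_set` restricting the mvt prong's
#'   dissimilarity (the count prongs always use all supplied probes).
#' @param alpha Significance level (default 0.05).
#' @param n_perm_count Permutations for the count test (default 2000).
#' @param n_perm_mvt Permutations for the mvt test (default `1e5`).
#' @param seed RNG seed.
#' @return A list of class `"equivalence_verdict"` with the three prong
#'   results, logical `prongs`, and `equivalent`.
#' @export
equivalence_verdict <- function(expr, sheet = NULL, gA, gB, probe_set = NULL,
                                alpha = 0.05, n_perm_count = 2000,
                                n_perm_mvt = 1e5, seed = NULL) {
  pct <- permutation_count_test(expr, sheet, gA, gB, alpha = alpha,
                                n_perm = n_perm_count, seed = child_seed(seed, 1L))
  tt <- probe_tests(expr, sheet, gA, gB, alpha = alpha)
  fdr_count <- sum(tt$sig_fdr)
  probe_ids <- if (inherits(probe_set, "responsive_set")) probe_set$probe_ids else probe_set
  d <- pearson_dissimilarity(expr, probe_subset = probe_ids)
  gi <- resolve_groups(expr, sheet, c(gA, gB))
  mt <- mvt_permutation_test(d, gi$idx[[gA]], gi$idx[[gB]],
                             n_perm = n_perm_mvt, seed = child_seed(seed, 2L))
  prongs <- c(count_test = pct$p_value > alpha,
              zero_fdr = fdr_count == 0L,
              mvt = mt$p_value > alpha)
  structure(list(group_a = gA, group_b = gB, alpha = alpha,
                 count_test = pct, fdr_count = fdr_count, mvt_test = mt,
                 prongs = prongs, equivalent = all(prongs), seed = seed),
            class = "equivalence_verdict")
}

#' @export
print.equivalence_verdict <- function(x, ...) {
  cat(sprintf("%s vs %s: %s\n", x$group_a, x$group_b,
              if (x$equivalent) "not distinguishable" else "distinguishable"))
  cat(sprintf("  count test P = %.4g | FDR-significant probes = %d | mvt P = %.4g\n",
              x$count_test$p_value, x$fdr_count, x$mvt_test$p_value))
  invisible(x)
}

#' Run the full equivalence analysis
#'
#' Executes preprocessing, the univariate test battery for each product
#' against the control, responsive-probe selection, the pairwise comparison
#' grid (counts + mvt), the multivariate views (MDS, PCA, Ward tree), the
#' optional marker panel and the equivalence verdicts of every product
#' against the reference product. Fully deterministic given `config$seed`.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{data}{either `list(raw = , sheet = )` or a
#'       [synthetic_config()] to generate data from.}
#'     \item{roles}{named list/vector mapping `reference` (reference
#'       product), `control` (media group) and optionally `others`
#'       (further product groups) to group labels. Defaults fit the
#'       synthetic generator's group names.}
#'     \item{offset, alpha, q_thresh, fc_thresh}{thresholds (defaults 8,
#'       0.05, 0.05, 1.3).}
#'     \item{n_perm_count, n_perm_mvt}{permutation counts (defaults 2000,
#'       `1e5`).}
#'     \item{markers}{optional character vector of gene symbols.}
#'     \item{seed}{run seed.}
#'     \item{out_dir}{optional output directory for `report.json` and TSV
#'       tables.}
#'   }
#' @return A list of class `"equivalence_report"` with all stage results.
#' @export
run_pipeline <- function(config) {
  seed <- config$seed %||% 1L
  offset <- config$offset %||% 8
  alpha <- config$alpha %||% 0.05
  q_thresh <- config$q_thresh %||% 0.05
  fc_thresh <- config$fc_thresh %||% 1.3
  n_perm_count <- config$n_perm_count %||% 2000
  n_perm_mvt <- config$n_perm_mvt %||% 1e5

  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  if (!is.null(config$data$raw)) {
    raw <- config$data$raw
    sheet <- validate_sample_sheet(config$data$sheet)
    truth <- NULL
  } else if (inherits(config$data, "synthetic_config") || is.null(config$data)) {
    gen <- stage("simulate", generate_dataset(config$data %||% synthetic_config(seed = seed)))
    raw <- gen$raw; sheet <- gen$sheet; truth <- gen$truth
  } else stop("config$data must supply raw+sheet or a synthetic_config")

  roles <- config$roles %||% list(reference = "reference", control = "media",
                                  others = intersect(c("test", "nonequivalent"),
                                                     unique(sheet$group)))
  ref <- roles$reference; ctrl <- roles$control
  others <- setdiff(roles$others %||% character(0), c(ref, ctrl))
  all_groups <- c(ctrl, ref, others)

  expr <- stage("preprocess", preprocess(raw, sheet, offset = offset))

  battery <- list()
  pair_id <- 10L
  for (g in c(ctrl, others)) {
    key <- paste0(ref, "_vs_", g)
    pair_id <- pair_id + 1L
    battery[[key]] <- stage(paste0("probe_tests:", key), {
      tt <- probe_tests(expr, NULL, ref, g, alpha = alpha)
      pct <- permutation_count_test(expr, NULL, ref, g, alpha = alpha,
                                    n_perm = n_perm_count,
                                    seed = child_seed(seed, pair_id))
      list(tests = tt, count_test = pct)
    })
  }

  responsive <- stage("select_responsive_probes",
                      select_responsive_probes(expr, NULL, ref, ctrl,
                                               q_thresh = q_thresh, fc_thresh = fc_thresh))
  grid <- NULL
  if (length(responsive$probe_ids) >= 2L) {
    grid <- stage("comparison_grid",
                  comparison_grid(expr, NULL, all_groups, probe_set = responsive,
                                  q_thresh = q_thresh, fc_thresh = fc_thresh,
                                  n_perm_mvt = n_perm_mvt, seed = child_seed(seed, 20L)))
  }

  views <- stage("multivariate_views", {
    d_all <- pearson_dissimilarity(expr)
    list(mds = classical_mds(d_all, k = 2),
         pca = pca_scores(expr),
         tree = ward_clustering(d_all))
  })

  markers <- NULL
  if (!is.null(config$markers) && length(others)) {
    markers <- stage("marker_panel",
                     marker_panel(expr, NULL, config$markers,
                                  productA = ref, productB = others[1L],
                                  reference = ctrl))
  }

  verdicts <- list()
  for (k in seq_along(others)) {
    g <- others[k]
    verdicts[[paste0(ref, "_vs_", g)]] <-
      stage(paste0("equivalence_verdict:", g),
            equivalence_verdict(expr, NULL, ref, g, probe_set = responsive,
                                alpha = alpha, n_perm_count = n_perm_count,
                                n_perm_mvt = n_perm_mvt,
                                seed = child_seed(seed, 30L + k)))
  }

  report <- structure(list(
    groups = all_groups, roles = roles, seed = seed,
    thresholds = list(offset = offset, alpha = alpha,
                      q_thresh = q_thresh, fc_thresh = fc_thresh,
                      n_perm_count = n_perm_count, n_perm_mvt = n_perm_mvt),
    expression = expr, battery = battery, responsive = responsive,
    grid = grid, views = views, markers = markers, verdicts = verdicts,
    truth = truth), class = "equivalence_report")

  if (!is.null(config$out_dir)) write_report_bundle(report, config$out_dir)
  report
}

#' @export
print.equivalence_report <- function(x, ...) {
  cat("equivalence_report: groups", paste(x$groups, collapse = ", "),
      "|", nrow(x$expression$E), "probes\n")
  cat("responsive set:", length(x$responsive$probe_ids), "probes\n")
  for (v in x$verdicts) print(v)
  invisible(x)
}

#' @export
as_report.equivalence_report <- function(x, ...) {
  list(kind = "equivalence_report",
       groups = x$groups, seed = x$seed, thresholds = x$thresholds,
       n_probes = nrow(x$expression$E),
       battery = lapply(x$battery, function(b)
         list(tests = as_report(b$tests), count_test = as_report(b$count_test))),
       responsive_set_size = length(x$responsive$probe_ids),
       grid = if (!is.null(x$grid)) as_report(x$grid),
       markers = if (!is.null(x$markers)) as.data.frame(x$markers),
       verdicts = lapply(x$verdicts, function(v)
         list(group_a = v$group_a, group_b = v$group_b,
              count_p = v$count_test$p_value, fdr_count = v$fdr_count,
              mvt_p = v$mvt_test$p_value,
              equivalent = unname(v$equivalent))))
}

# Write report.json plus flat TSV tables for downstream consumption.
write_report_bundle <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_report(report, file.path(dir, "report.json"))
  write_expression_matrix(report$expression, file.path(dir, "expression.tsv"))
  t1 <- do.call(rbind, lapply(names(report$battery), function(k) {
    b <- report$battery[[k]]
    data.frame(comparison = k,
               uncorrected = sum(b$tests$sig_uncorrected),
               fdr = sum(b$tests$sig_fdr),
               bonferroni = sum(b$tests$sig_bonferroni),
               perm_count_p = b$count_test$p_value)
  }))
  utils::write.table(t1, file.path(dir, "table1.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(report$grid)) {
    utils::write.table(report$grid$count_matrix, file.path(dir, "table2.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(report$grid$mvt_p_matrix, file.path(dir, "table3.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  if (!is.null(report$markers)) {
    utils::write.table(as.data.frame(report$markers), file.path(dir, "markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(data.frame(sample_id = rownames(report$views$mds),
                                report$views$mds),
                     file.path(dir, "mds.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample_id = rownames(report$views$pca$scores),
                                report$views$pca$scores[, 1:2, drop = FALSE]),
                     file.path(dir, "pca.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}
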