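# Per-probe two-group testing and false-positive control: uncorrected
# Student t-tests, Bonferroni familywise control, Storey q-value FDR with
# the smoother pi0 estimate, and a permutation test on the count of
# nominally significant probes (which, unlike the per-probe corrections,
# is valid under gene-gene coexpression).

#' Two-sample Student t-test
#'
#' Thin wrapper around [stats::t.test()] returning the two-sided statistic
#' and p-value; `variant = "pooled"` uses the pooled-variance test with
#' `n_a + n_b - 2` degrees of freedom, `"welch"` the Satterthwaite
#' approximation. Zero-variance input is handled explicitly: equal means
#' give `t = 0, p = 1`; unequal means give `p = 0` with a warning.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return A list with `statistic`, `p_value` and `df`.
#' @export
student_t_test <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs at least 2 values")
  stopifnot_finite(c(a, b), "input")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(statistic = 0, p_value = 1,
                  df = if (variant == "pooled") length(a) + length(b) - 2 else NA_real_))
    }
    warning("zero variance with unequal means; reporting p = 0")
    return(list(statistic = sign(mean(a) - mean(b)) * Inf, p_value = 0,
                df = if (variant == "pooled") length(a) + length(b) - 2 else NA_real_))
  }
  ht <- stats::t.test(a, b, var.equal = (variant == "pooled"))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

# Vectorized pooled-variance t-tests over the rows of X between column sets
# idx_a and idx_b. Returns t, p, df and the difference of means (a - b).
row_t_tests <- function(X, idx_a, idx_b) {
  na <- length(idx_a); nb <- length(idx_b)
  A <- X[, idx_a, drop = FALSE]; B <- X[, idx_b, drop = FALSE]
  ma <- rowMeans(A); mb <- rowMeans(B)
  ssa <- rowSums(A * A) - na * ma^2
  ssb <- rowSums(B * B) - nb * mb^2
  df <- na + nb - 2
  sp2 <- (ssa + ssb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  diff <- ma - mb
  t <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf * sign(diff)))
  p <- ifelse(is.finite(t), 2 * stats::pt(-abs(t), df), ifelse(t == 0, 1, 0))
  p[t == 0] <- 1
  list(t = t, p = p, df = df, diff = diff)
}

#' Per-probe differential expression table between two groups
#'
#' Runs a pooled-variance Student t-test on every probe between groups
#' `gA` and `gB`, attaches Storey q-values and flags significance under
#' three regimes computed independently of one another: uncorrected
#' (`p < alpha`), FDR (`q < alpha`) and Bonferroni (`p < alpha / n_probes`).
#' `log2_fold` is `mean(gA) - mean(gB)` per probe.
#'
#' @param expr An `expression_matrix` (or bare matrix plus `sheet`).
#' @param sheet Sample sheet; defaults to the targets stored in `expr`.
#' @param gA,gB Group labels to compare.
#' @param alpha Significance level (default 0.05).
#' @return A data.frame of class `"probe_test_table"` with columns
#'   `unique_probe_id`, `t_stat`, `p_value`, `q_value`, `log2_fold`,
#'   `sig_uncorrected`, `sig_fdr`, `sig_bonferroni`; attributes carry the
#'   groups, `alpha` and the estimated `pi0`.
#' @export
probe_tests <- function(expr, sheet = NULL, gA, gB, alpha = 0.05) {
  gi <- resolve_groups(expr, sheet, c(gA, gB))
  X <- gi$X
  res <- row_t_tests(X, gi$idx[[gA]], gi$idx[[gB]])
  qv <- qvalues(res$p)
  m <- nrow(X)
  out <- data.frame(unique_probe_id = rownames(X),
                    t_stat = res$t,
                    p_value = res$p,
                    q_value = qv$qvalues,
                    log2_fold = res$diff,
                    sig_uncorrected = res$p < alpha,
                    sig_fdr = qv$qvalues < alpha,
                    sig_bonferroni = res$p < alpha / m,
                    stringsAsFactors = FALSE)
  structure(out, class = c("probe_test_table", "data.frame"),
            group_a = gA, group_b = gB, alpha = alpha, pi0 = qv$pi0)
}

# Resolve expression + sheet + group labels into the expression matrix and
# per-group column indices (>= 2 included samples each).
resolve_groups <- function(expr, sheet, groups) {
  X <- as_expr_matrix(expr)
  targets <- if (!is.null(sheet)) {
    included_samples(validate_sample_sheet(sheet))
  } else if (inherits(expr, "expression_matrix") && !is.null(expr$targets)) {
    expr$targets
  } else stop("a sample sheet is required")
  if (!identical(colnames(X), targets$sample_id)) {
    keep <- match(targets$sample_id, colnames(X))
    if (any(is.na(keep))) stop("sample sheet names samples absent from the expression matrix")
    X <- X[, keep, drop = FALSE]
  }
  idx <- lapply(groups, function(g) {
    i <- which(targets$group == g)
    if (length(i) == 0L) stop("unknown group: ", g)
    if (length(i) < 2L) stop("group '", g, "' has fewer than 2 included samples")
    i
  })
  names(idx) <- groups
  list(X = X, targets = targets, idx = idx)
}

#' Storey q-values with the smoother pi0 estimate
#'
#' Estimates the proportion of true null hypotheses as
#' `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))` over the grid
#' `lambda = 0, 0.05, ..., 0.90`, fits a cubic smoothing spline through the
#' `(lambda, pi0(lambda))` points and takes the smoothed value at the
#' largest lambda, clamped to `(0, 1]`. Q-values are the step-up transform
#' `q_(i) = min_{j >= i} pi0 * m * p_(j) / j` on the sorted p-values; with
#' `pi0 = 1` they reduce to Benjamini-Hochberg adjusted p-values.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param pi0 Optional fixed pi0 overriding the smoother estimate.
#' @param lambda Grid for the pi0 estimate.
#' @param smooth_df Degrees of freedom of the smoothing spline.
#' @return A list with `qvalues` (same order as `p`) and `pi0`.
#' @export
qvalues <- function(p, pi0 = NULL, lambda = seq(0, 0.9, by = 0.05), smooth_df = 3) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (is.null(pi0)) {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lambda, pi0_l, df = smooth_df)
    pi0 <- stats::predict(fit, x = max(lambda))$y
    # clamp to (0, 1]; the lower floor 1/m corresponds to "at least one
    # true null", the least committal admissible estimate when nearly all
    # hypotheses are false and the smoother undershoots zero
    pi0 <- min(max(pi0, 1 / m), 1)
  } else {
    if (pi0 <= 0 || pi0 > 1) stop("pi0 must lie in (0, 1]")
  }
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  list(qvalues = q, pi0 = pi0)
}

#' Permutation test on the count of nominally significant probes
#'
#' The observed statistic is the number of probes with uncorrected t-test
#' `p < alpha` between the two groups. Samples are pooled and randomly
#' reassigned to two groups of the original sizes; the count is recomputed
#' for each permutation and the upper-tail p-value is
#' `(1 + #\{count_perm >= count_obs\}) / (n_perm + 1)`. Because whole
#' samples are permuted, gene-gene coexpression is preserved under the
#' null. With `exact = TRUE` all distinct reassignments are enumerated and
#' the p-value is the exact proportion with `count >= count_obs` (the
#' identity split included).
#'
#' @param expr An `expression_matrix` (or matrix).
#' @param sheet Sample sheet (optional when stored in `expr`).
#' @param gA,gB Group labels.
#' @param alpha Per-probe significance threshold (default 0.05).
#' @param n_perm Number of random permutations (default 2000).
#' @param seed RNG seed for the permutations.
#' @param exact Enumerate all reassignments instead of sampling.
#' @return A list of class `"perm_count_result"`: `observed_count`,
#'   `alpha`, `n_perm`, `perm_count_quantiles`, `p_value`, `seed`, `exact`.
#' @export
permutation_count_test <- function(expr, sheet = NULL, gA, gB, alpha = 0.05,
                                   n_perm = 2000, seed = NULL, exact = FALSE) {
  if (!exact && n_perm < 1) stop("n_perm must be >= 1")
  gi <- resolve_groups(expr, sheet, c(gA, gB))
  idx <- c(gi$idx[[gA]], gi$idx[[gB]])
  na <- length(gi$idx[[gA]])
  X <- gi$X[, idx, drop = FALSE]
  n <- ncol(X)
  observed <- sum(row_t_tests(X, seq_len(na), (na + 1):n)$p < alpha)

  count_for <- function(a_cols) {
    sum(row_t_tests(X, a_cols, setdiff(seq_len(n), a_cols))$p < alpha)
  }
  if (exact) {
    combos <- utils::combn(n, na)
    counts <- apply(combos, 2L, count_for)
    p_value <- mean(counts >= observed)
    n_perm <- ncol(combos)
  } else {
    counts <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) count_for(sample.int(n, na)), numeric(1))
    })
    p_value <- (1 + sum(counts >= observed)) / (n_perm + 1)
  }
  structure(list(observed_count = observed, alpha = alpha, n_perm = n_perm,
                 perm_count_quantiles = stats::quantile(counts, c(0, .25, .5, .75, .95, 1)),
                 p_value = p_value, seed = seed, exact = exact),
            class = "perm_count_result")
}

#' @export
print.perm_count_result <- function(x, ...) {
  cat(sprintf("permutation count test: %d probes at p < %g; P = %.4g (%s%d permutations)\n",
              x$observed_count, x$alpha, x$p_value,
              if (x$exact) "exact, " else "", x$n_perm))
  invisible(x)
}

#' Linear fold change from a log2 fold difference
#'
#' @param log2_fold Finite numeric vector of log2 fold differences.
#' @return A data.frame with `log2_fold`, the linear `fold = 2^|log2_fold|`
#'   and the `direction` (`"up"`, `"down"` or `"none"`). A fold-change
#'   threshold `FC >= f` is equivalent to `|log2_fold| >= log2(f)`.
#' @export
fold_change <- function(log2_fold) {
  stopifnot_finite(log2_fold, "log2_fold")
  data.frame(log2_fold = log2_fold,
             fold = 2^abs(log2_fold),
             direction = ifelse(log2_fold > 0, "up",
                                ifelse(log2_fold < 0, "down", "none")),
             stringsAsFactors = FALSE)
}
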