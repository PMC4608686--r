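# Sample-level (multivariate) analysis: Pearson dissimilarity between
# samples, the mvt group-dissimilarity statistic with its permutation null,
# classical MDS, standardized PCA and Ward hierarchical clustering.

new_dissimilarity_matrix <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d))) {
    dimnames(d) <- list(paste0("S", seq_len(nrow(d))), paste0("S", seq_len(nrow(d))))
  }
  if (max(abs(d - t(d))) > 1e-12) stop("dissimilarity matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("dissimilarity matrix must have zero diagonal")
  if (min(d) < -1e-12 || max(d) > 2 + 1e-12) stop("dissimilarities must lie in [0, 2]")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  structure(d, class = c("dissimilarity_matrix", "matrix"))
}

#' Pearson dissimilarity between samples
#'
#' `d_ij = 1 - r_ij`, where `r_ij` is the Pearson correlation of samples
#' `i` and `j` across the (optionally subset) probes. Values lie in
#' `[0, 2]`: 0 for identical profiles, 2 for perfectly anticorrelated ones.
#'
#' @param expr An `expression_matrix` or numeric matrix (probes x samples).
#' @param probe_subset Optional character vector of unique probe ids (or
#'   integer row indices) restricting the profile, e.g. a responsive set.
#' @return A `dissimilarity_matrix` over the samples.
#' @export
pearson_dissimilarity <- function(expr, probe_subset = NULL) {
  X <- as_expr_matrix(expr)
  if (!is.null(probe_subset)) {
    if (is.character(probe_subset)) {
      miss <- setdiff(probe_subset, rownames(X))
      if (length(miss)) stop("probe_subset names absent probes, e.g. ", miss[1L])
      X <- X[probe_subset, , drop = FALSE]
    } else {
      X <- X[probe_subset, , drop = FALSE]
    }
  }
  if (nrow(X) < 2L) stop("need at least 2 probes to correlate samples")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance sample profile: ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  d <- 1 - stats::cor(X)
  d <- pmin(pmax(d, 0), 2)
  diag(d) <- 0
  new_dissimilarity_matrix(d)
}

#' Multivariate group-dissimilarity statistic (mvt)
#'
#' `mvt = d(G, H) / (s(G) + s(H))`, where `d(G, H)` is the mean
#' dissimilarity over all `|G||H|` between-group sample pairs and `s(G)`
#' the mean over the `|G|(|G|-1)/2` within-group pairs. Like the univariate
#' t statistic it is a ratio of between-group difference to within-group
#' spread; it is invariant to relabeling within groups and to positive
#' rescaling of the dissimilarities.
#'
#' @param d A `dissimilarity_matrix` (or symmetric numeric matrix).
#' @param G,H Disjoint sample sets (ids or column indices), each of
#'   size >= 2.
#' @return A list of class `"mvt_result"` with `statistic`, `d_between`,
#'   `s_G` and `s_H`.
#' @export
mvt <- function(d, G, H) {
  pr <- resolve_mvt_groups(d, G, H)
  stat_parts <- mvt_parts(pr$d, pr$g, pr$h)
  denom <- stat_parts$s_G + stat_parts$s_H
  statistic <- if (denom > 0) {
    stat_parts$d_between / denom
  } else if (stat_parts$d_between > 0) {
    warning("zero within-group spread; mvt is infinite")
    Inf
  } else {
    stop("all dissimilarities zero between and within groups; mvt undefined")
  }
  structure(c(list(statistic = statistic), stat_parts), class = "mvt_result")
}

resolve_mvt_groups <- function(d, G, H) {
  if (!inherits(d, "dissimilarity_matrix")) d <- new_dissimilarity_matrix(as.matrix(d))
  ids <- rownames(d)
  to_idx <- function(s, what) {
    i <- if (is.character(s)) match(s, ids) else as.integer(s)
    if (any(is.na(i)) || any(i < 1L) || any(i > nrow(d))) stop("unknown sample in ", what)
    i
  }
  g <- to_idx(G, "G"); h <- to_idx(H, "H")
  if (length(g) < 2L || length(h) < 2L) stop("each group needs at least 2 samples")
  if (length(intersect(g, h))) stop("G and H must be disjoint")
  list(d = unclass(d), g = g, h = h)
}

mvt_parts <- function(d, g, h) {
  ng <- length(g); nh <- length(h)
  s_G <- sum(d[g, g]) / (ng * (ng - 1))
  s_H <- sum(d[h, h]) / (nh * (nh - 1))
  d_between <- sum(d[g, h]) / (ng * nh)
  list(d_between = d_between, s_G = s_G, s_H = s_H)
}

#' @export
print.mvt_result <- function(x, ...) {
  cat(sprintf("mvt = %.4g (d_between = %.4g, s_G = %.4g, s_H = %.4g)",
              x$statistic, x$d_between, x$s_G, x$s_H))
  if (!is.null(x$p_value)) {
    cat(sprintf("; P = %.4g (%s%d permutations)", x$p_value,
                if (isTRUE(x$exact)) "exact, " else "", x$n_perm))
  }
  cat("\n")
  invisible(x)
}

#' Permutation test for the mvt statistic
#'
#' The pooled `|G| + |H|` samples are reassigned uniformly at random into
#' groups of the original sizes and the mvt statistic recomputed; the
#' p-value estimates `Pr(MVT > mvt_obs)` under this null as
#' `(1 + #\{MVT_perm > mvt_obs\}) / (n_perm + 1)` (strict inequality, with
#' add-one smoothing so the p-value is never zero). With `exact = TRUE`
#' all `choose(|G|+|H|, |G|)` reassignments are enumerated and the p-value
#' is the exact proportion with `MVT >= mvt_obs` (the identity
#' reassignment included).
#'
#' @inheritParams mvt
#' @param n_perm Number of random permutations (default `1e5`).
#' @param seed RNG seed.
#' @param exact Enumerate all reassignments.
#' @return An `"mvt_result"` with additional `p_value`, `n_perm`, `seed`,
#'   `exact`.
#' @export
mvt_permutation_test <- function(d, G, H, n_perm = 1e5, seed = NULL, exact = FALSE) {
  pr <- resolve_mvt_groups(d, G, H)
  obs <- mvt(d, G, H)
  idx <- c(pr$g, pr$h)
  ng <- length(pr$g); nh <- length(pr$h)
  dd <- pr$d[idx, idx, drop = FALSE]
  n <- ng + nh
  total <- sum(dd)

  stats_for_assignments <- function(Z) {
    # Z: n x P 0/1 matrix, column sums ng. diag(Z' D Z) gives the doubled
    # within-G pair sum for every assignment in one product.
    DZ <- dd %*% Z
    w_G <- colSums(Z * DZ)
    Zc <- 1 - Z
    w_H <- colSums(Zc * (dd %*% Zc))
    s_G <- w_G / (ng * (ng - 1))
    s_H <- w_H / (nh * (nh - 1))
    d_b <- (total - w_G - w_H) / (2 * ng * nh)
    d_b / (s_G + s_H)
  }

  if (exact) {
    combos <- utils::combn(n, ng)
    Z <- matrix(0, n, ncol(combos))
    Z[cbind(as.vector(combos), rep(seq_len(ncol(combos)), each = ng))] <- 1
    stats <- stats_for_assignments(Z)
    p_value <- mean(stats >= obs$statistic - 1e-12)
    n_perm <- ncol(combos)
    exceed <- sum(stats > obs$statistic + 1e-12)
  } else {
    exceed <- with_seed(seed, {
      chunk <- 5000L
      done <- 0L; cnt <- 0L
      while (done < n_perm) {
        k <- min(chunk, n_perm - done)
        Z <- matrix(0, n, k)
        picks <- vapply(seq_len(k), function(i) sample.int(n, ng), integer(ng))
        Z[cbind(as.vector(picks), rep(seq_len(k), each = ng))] <- 1
        cnt <- cnt + sum(stats_for_assignments(Z) > obs$statistic)
        done <- done + k
      }
      cnt
    })
    p_value <- (1 + exceed) / (n_perm + 1)
  }
  structure(c(unclass(obs),
              list(p_value = p_value, n_perm = n_perm, n_exceed = exceed,
                   seed = seed, exact = exact)),
            class = "mvt_result")
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers `-d^2 / 2` and embeds the samples on the top `k`
#' eigenvectors scaled by the square roots of their (nonnegative)
#' eigenvalues, via [stats::cmdscale()]. When `d` is Euclidean-embeddable
#' in `k` dimensions the embedding reproduces the input distances exactly.
#'
#' @param d A `dissimilarity_matrix` (or symmetric matrix).
#' @param k Embedding dimension, `k < n_samples`.
#' @return Numeric matrix of sample coordinates (n x k), rownames = sample
#'   ids.
#' @export
classical_mds <- function(d, k = 2) {
  if (!inherits(d, "dissimilarity_matrix")) d <- new_dissimilarity_matrix(as.matrix(d))
  n <- nrow(d)
  if (k >= n) stop("k must be smaller than the number of samples")
  pts <- stats::cmdscale(stats::as.dist(unclass(d)), k = k)
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 1L, dimnames = list(rownames(d), NULL))
  pts
}

#' Principal component scores of probe-standardized expression
#'
#' Each probe is mean-centered and scaled by its standard deviation across
#' all samples (sample sd, `n - 1`); principal components are then computed
#' over samples. Zero-variance probes are dropped with a warning before
#' scaling. Component signs are fixed by making each component's
#' largest-magnitude probe loading positive.
#'
#' @param expr An `expression_matrix` or matrix (probes x samples).
#' @param standardize Scale probes to unit variance (default `TRUE`;
#'   centering is always applied).
#' @return A list with `scores` (samples x components),
#'   `variance_fractions` and the probe `loadings`.
#' @export
pca_scores <- function(expr, standardize = TRUE) {
  X <- as_expr_matrix(expr)
  if (ncol(X) < 2L) stop("PCA needs at least 2 samples")
  sds <- apply(X, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance probe(s) dropped before scaling")
    X <- X[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (nrow(X) < 1L) stop("no varying probes left")
  Xs <- X - rowMeans(X)
  if (standardize) Xs <- Xs / sds
  pr <- stats::prcomp(t(Xs), center = FALSE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pr$rotation)), function(j) {
    v <- pr$rotation[, j]
    sign(v[which.max(abs(v))]) < 0
  }, logical(1))
  pr$rotation[, flip] <- -pr$rotation[, flip]
  pr$x[, flip] <- -pr$x[, flip]
  list(scores = pr$x,
       variance_fractions = pr$sdev^2 / sum(pr$sdev^2),
       loadings = pr$rotation)
}

#' Ward hierarchical clustering of samples
#'
#' Agglomerative clustering of the unsquared dissimilarities under Ward's
#' minimum-variance update (the historical `"ward.D"` convention of
#' [stats::hclust()]).
#'
#' @param d A `dissimilarity_matrix` (or symmetric matrix), n >= 2.
#' @return An [stats::hclust] merge tree.
#' @export
ward_clustering <- function(d) {
  if (!inherits(d, "dissimilarity_matrix")) d <- new_dissimilarity_matrix(as.matrix(d))
  if (nrow(d) < 2L) stop("clustering needs at least 2 samples")
  stats::hclust(stats::as.dist(unclass(d)), method = "ward.D")
}
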