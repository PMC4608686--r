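# Raw-intensity preprocessing: normexp background correction (per-array MLE
# fit), offset, log2, quantile normalization, replicate-probe averaging.
#
# The normexp convolution model takes the observed net spot intensity as
# X = B + S with background B ~ Normal(mu_b, sigma_b) and true signal
# S ~ Exponential(mean alpha); background correction replaces x by the
# conditional expectation E[S | X = x], which is always positive, so low
# intensities survive the subsequent log2 transform.

#' Fit the normexp convolution model to one array
#'
#' Maximum-likelihood fit of `X = B + S`, `B ~ N(mu_b, sigma_b)`,
#' `S ~ Exp(mean alpha)`, to the net intensities `fg - bg`, with
#' method-of-moments initialization: `mu_b` starts at the mean of values
#' below the median, `sigma_b` at the spread of that lower tail and `alpha`
#' at the mean excess above `mu_b`. Optimization is over
#' `(mu_b, log sigma_b, log alpha)` by Nelder-Mead.
#'
#' @param fg,bg Foreground and background median intensities (same length,
#'   at least 100 spots).
#' @return A list of class `"normexp_params"` with `mu_b`, `sigma_b`,
#'   `alpha` and the log-likelihood at the optimum.
#' @export
fit_normexp <- function(fg, bg) {
  if (length(fg) != length(bg)) stop("fg and bg must have the same length")
  if (length(fg) < 100L) stop("normexp fitting needs at least 100 spots")
  x <- fg - bg
  stopifnot_finite(x, "net intensity")

  init <- normexp_moments_init(x)
  if (stats::var(x) == 0) {
    warning("degenerate constant net intensities; returning moments estimate")
    return(new_normexp_params(init$mu_b, init$sigma_b, init$alpha, loglik = NA_real_))
  }
  # The convolution moments bound the parameters: var(X) = sigma^2 + alpha^2
  # and E[X] = mu_b + alpha, so the MLE is sought inside that box; this also
  # keeps the optimizer away from the numerically degenerate large-sigma /
  # tiny-alpha ridge where the log-density suffers catastrophic cancellation.
  sx <- stats::sd(x)
  lo <- c(mean(x) - 1.1 * sx, log(1e-6 * sx), log(1e-6 * sx))
  hi <- c(mean(x), log(1.1 * sx), log(1.1 * sx))
  par0 <- pmin(pmax(c(init$mu_b, log(init$sigma_b), log(init$alpha)), lo), hi)
  negll <- function(par) {
    ll <- sum(normexp_logdensity(x, par[1L], exp(par[2L]), exp(par[3L])))
    if (!is.finite(ll)) return(1e300)
    -ll
  }
  fit <- stats::optim(par0, negll, method = "L-BFGS-B", lower = lo, upper = hi,
                      control = list(maxit = 500, factr = 1e4))
  new_normexp_params(fit$par[1L], exp(fit$par[2L]), exp(fit$par[3L]),
                     loglik = -fit$value)
}

normexp_moments_init <- function(x) {
  med <- stats::median(x)
  lower <- x[x <= med]
  mu_b <- mean(lower)
  sigma_b <- sqrt(mean((lower - mu_b)^2))
  alpha <- mean(x) - mu_b
  list(mu_b = mu_b,
       sigma_b = max(sigma_b, 1e-6),
       alpha = max(alpha, 1e-6))
}

new_normexp_params <- function(mu_b, sigma_b, alpha, loglik = NA_real_) {
  if (!is.finite(mu_b) || !is.finite(sigma_b) || !is.finite(alpha)) {
    stop("normexp parameters must be finite")
  }
  structure(list(mu_b = mu_b,
                 sigma_b = max(sigma_b, .Machine$double.eps),
                 alpha = max(alpha, .Machine$double.eps),
                 loglik = loglik),
            class = "normexp_params")
}

#' @export
print.normexp_params <- function(x, ...) {
  cat(sprintf("normexp_params: mu_b = %.4g, sigma_b = %.4g, alpha = %.4g\n",
              x$mu_b, x$sigma_b, x$alpha))
  invisible(x)
}

# Log-density of the normal + exponential convolution, stable in log space:
# f(x) = (1/a) exp((mu - x)/a + s^2/(2 a^2)) * Phi((x - mu - s^2/a)/s)
normexp_logdensity <- function(x, mu, sigma, alpha) {
  -log(alpha) + (mu - x) / alpha + sigma^2 / (2 * alpha^2) +
    stats::pnorm((x - mu - sigma^2 / alpha) / sigma, log.p = TRUE)
}

#' Normexp background correction
#'
#' Replaces each net intensity `x` by the conditional expected signal
#' `E[S | X = x] = mu_sf + sigma_b * phi(z) / Phi(z)` with
#' `mu_sf = x - mu_b - sigma_b^2 / alpha` and `z = mu_sf / sigma_b`
#' (`phi`, `Phi` the standard normal density and cdf), plus an offset that
#' stabilizes the variance of low intensities under log2. The inverse Mills
#' ratio is evaluated in log space so that arbitrarily negative `x` are
#' handled without underflow; the output is strictly positive and
#' nondecreasing in `x`.
#'
#' @param x Net intensities (`fg - bg`), any finite values.
#' @param params A `normexp_params` fit.
#' @param offset Constant added after correction (default 8).
#' @return Corrected intensities, strictly positive.
#' @export
normexp_correct <- function(x, params, offset = 8) {
  stopifnot(inherits(params, "normexp_params"))
  stopifnot_finite(x, "net intensity")
  mu_sf <- x - params$mu_b - params$sigma_b^2 / params$alpha
  z <- mu_sf / params$sigma_b
  # inverse Mills ratio phi(z)/Phi(z) in log space; for z << 0 the sum
  # mu_sf + sigma * mills cancels catastrophically, so switch to the
  # asymptotic tail expansion E[S|X] = (sigma/u)(1 - 2/u^2 + 10/u^4 - 74/u^6),
  # u = -z, there
  mills <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
  signal <- mu_sf + params$sigma_b * mills
  far <- z < -20
  if (any(far)) {
    u <- -z[far]
    signal[far] <- (params$sigma_b / u) * (1 - 2 / u^2 + 10 / u^4 - 74 / u^6)
  }
  pmax(signal + offset, .Machine$double.xmin)
}

#' Quantile normalization across arrays
#'
#' Forces every column (array) to share one empirical distribution: the
#' sorted values of each column are replaced by the across-column mean of
#' sorted values. Ties within a column receive the mean of the reference
#' values over their rank span, so the result is deterministic and
#' independent of input order. The operation is idempotent.
#'
#' @param m Numeric matrix, probes/spots x samples, all finite.
#' @return Matrix of the same shape with identical column distributions.
#' @export
quantile_normalize <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (!all(is.finite(m))) stop("quantile normalization requires finite values")
  if (ncol(m) == 1L) return(m)
  sorted <- apply(m, 2L, sort)
  ref <- rowMeans(sorted)
  out <- m
  for (j in seq_len(ncol(m))) out[, j] <- qn_map_column(m[, j], ref)
  out
}

# Map one column onto the reference distribution, tie groups -> rank-span mean.
qn_map_column <- function(x, ref) {
  o <- order(x)
  xs <- x[o]
  vals <- ref
  ties <- rle(xs)
  if (any(ties$lengths > 1L)) {
    stop_idx <- cumsum(ties$lengths)
    start_idx <- stop_idx - ties$lengths + 1L
    for (k in which(ties$lengths > 1L)) {
      span <- start_idx[k]:stop_idx[k]
      vals[span] <- mean(ref[span])
    }
  }
  out <- numeric(length(x))
  out[o] <- vals
  out
}

#' Average replicate spots into unique probes
#'
#' @param m Numeric matrix, spots x samples (typically log2 scale).
#' @param spot_map Character vector mapping each row of `m` to its unique
#'   probe id; every spot must be mapped.
#' @return Matrix with one row per unique probe (first-appearance order),
#'   each the arithmetic mean of its spots' values.
#' @export
average_replicate_probes <- function(m, spot_map) {
  stopifnot(is.matrix(m))
  if (length(spot_map) != nrow(m)) stop("spot_map must have one entry per row of m")
  if (any(is.na(spot_map) | !nzchar(spot_map))) stop("every spot must map to a unique probe")
  f <- factor(spot_map, levels = unique(spot_map))
  sums <- rowsum(m, f, reorder = FALSE)
  counts <- as.vector(table(f)[levels(f)])
  out <- sums / counts
  rownames(out) <- levels(f)
  out
}

#' Full preprocessing pipeline: raw intensities to log2 expression
#'
#' Per array: fit the normexp model to net intensities `fg - bg`, correct
#' with [normexp_correct()] plus `offset`, take log2; then quantile-
#' normalize across arrays and average replicate spots per unique probe.
#' The provenance of the returned matrix records every step and each
#' array's fitted normexp parameters.
#'
#' @param raw A `raw_intensity_set`.
#' @param sheet Optional sample sheet; defaults to the targets stored in
#'   `raw`. Only included samples are processed (and `raw` must contain
#'   exactly those).
#' @param offset Offset added after background correction (default 8).
#' @return An `expression_matrix` (unique probes x included samples).
#' @export
preprocess <- function(raw, sheet = NULL, offset = 8) {
  stopifnot(inherits(raw, "raw_intensity_set"))
  inc <- if (is.null(sheet)) raw$targets else included_samples(validate_sample_sheet(sheet))
  if (!identical(colnames(raw$fg), inc$sample_id)) {
    stop("raw intensity samples do not match the sample sheet's included samples")
  }
  n <- ncol(raw$fg)
  corrected <- raw$fg
  params <- vector("list", n)
  names(params) <- inc$sample_id
  for (j in seq_len(n)) {
    x <- raw$fg[, j] - raw$bg[, j]
    params[[j]] <- fit_normexp(raw$fg[, j], raw$bg[, j])
    corrected[, j] <- normexp_correct(x, params[[j]], offset = offset)
  }
  logged <- log2(corrected)
  normalized <- quantile_normalize(logged)
  averaged <- average_replicate_probes(normalized, raw$spots$unique_probe_id)
  genes <- unique(raw$spots[, c("unique_probe_id", "gene_symbol")])
  genes <- genes[match(rownames(averaged), genes$unique_probe_id), , drop = FALSE]
  rownames(genes) <- NULL
  expression_matrix(
    averaged, genes = genes, targets = inc,
    provenance = list(
      list(step = "normexp_correct", offset = offset,
           params = lapply(params, function(p) p[c("mu_b", "sigma_b", "alpha")])),
      list(step = "log2"),
      list(step = "quantile_normalize"),
      list(step = "average_replicate_probes",
           n_spots = nrow(raw$fg), n_unique_probes = nrow(averaged))))
}
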