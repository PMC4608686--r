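test_that("normexp MLE is unbiased at the recovery condition and matches limma", {
  # estimator bias over replicate datasets: mean estimate within 5% of truth
  est <- vapply(1:15, function(s) {
    set.seed(100 + s)
    fg <- rnorm(10000, 50, 10) + rexp(10000, 1 / 200)
    p <- fit_normexp(fg, rep(0, 10000))
    c(p$mu_b, p$sigma_b, p$alpha)
  }, numeric(3))
  avg <- rowMeans(est)
  expect_lt(abs(avg[1] - 50) / 50, 0.05)
  expect_lt(abs(avg[2] - 10) / 10, 0.05)
  expect_lt(abs(avg[3] - 200) / 200, 0.05)

  # implementation check: identical optimum to limma's normexp MLE on one draw
  skip_if_not_installed("limma")
  set.seed(101)
  fg <- rnorm(10000, 50, 10) + rexp(10000, 1 / 200)
  ours <- fit_normexp(fg, rep(0, 10000))
  lf <- limma::normexp.fit(as.matrix(fg), method = "mle")$par
  expect_equal(ours$mu_b, lf[1], tolerance = 1e-3)
  expect_equal(ours$sigma_b, exp(lf[2]), tolerance = 1e-3)
  expect_equal(ours$alpha, exp(lf[3]), tolerance = 1e-3)
})

test_that("normexp fit handles degenerate inputs as specified", {
  # pure normal input: the signal mean collapses to its lower clamp
  set.seed(1)
  fg <- rnorm(5000, 100, 5)
  p <- fit_normexp(fg, rep(0, 5000))
  expect_lt(p$alpha, 0.05 * sd(fg))
  expect_equal(p$mu_b, 100, tolerance = 0.05)

  expect_warning(pc <- fit_normexp(rep(7, 200), rep(0, 200)), "degenerate")
  expect_equal(pc$mu_b, 7)
  expect_lte(pc$sigma_b, 1e-6)

  expect_error(fit_normexp(1:50, rep(0, 50)), "100")
  expect_error(fit_normexp(c(rep(1, 199), NA), rep(0, 200)), "non-finite")
})

test_that("normexp correction matches numerical integration of E[S|X=x]", {
  # quadrature oracle over the conditional density of S given X = x
  quad <- function(x, mu, sigma, alpha) {
    # conditional density of S given X = x is proportional to
    # exp(-s/alpha) * phi((x - mu - s)/sigma) on s > 0; integrate over a
    # window around its mass with the integrand rescaled in log space
    lo <- max(0, x - mu - 15 * sigma)
    hi <- max(0, x - mu) + 15 * sigma
    logg <- function(s) -s / alpha + dnorm(x - s, mu, sigma, log = TRUE)
    ref <- logg(min(max(x - mu, lo), hi))
    g <- function(s) exp(logg(s) - ref)
    f <- function(s) s * g(s)
    num <- integrate(f, lo, hi, rel.tol = 1e-12, abs.tol = 0)$value
    den <- integrate(g, lo, hi, rel.tol = 1e-12, abs.tol = 0)$value
    num / den
  }
  grid <- expand.grid(x = c(-40, 0, 30, 100, 400),
                      mu = c(0, 50), sigma = c(5, 10), alpha = c(50, 100, 500))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    params <- structure(list(mu_b = g$mu, sigma_b = g$sigma, alpha = g$alpha),
                        class = "normexp_params")
    expect_equal(normexp_correct(g$x, params, offset = 0),
                 quad(g$x, g$mu, g$sigma, g$alpha), tolerance = 1e-6)
  }
})

test_that("normexp correction obeys its limits and is positive and monotone", {
  # sigma -> 0 limit: corrected ~ x - mu_b - sigma^2/alpha + offset
  p_small <- structure(list(mu_b = 50, sigma_b = 1e-4, alpha = 100),
                       class = "normexp_params")
  expect_equal(normexp_correct(150, p_small, offset = 8),
               150 - 50 - 1e-8 + 8, tolerance = 1e-6)

  p <- structure(list(mu_b = 50, sigma_b = 10, alpha = 100),
                 class = "normexp_params")
  # very negative input: corrected approaches the offset from above
  vneg <- normexp_correct(c(-1e3, -1e5, -1e7), p, offset = 8)
  expect_true(all(vneg > 8))
  expect_lt(vneg[3] - 8, 1e-3)
  expect_true(all(normexp_correct(seq(-500, 500, by = 50), p, offset = 0) > 0))

  # property: positive and nondecreasing for random parameter draws
  set.seed(99)
  for (rep in 1:20) {
    pr <- structure(list(mu_b = runif(1, -50, 200), sigma_b = runif(1, 0.5, 50),
                         alpha = runif(1, 1, 1000)), class = "normexp_params")
    x <- sort(runif(50, -2000, 2000))
    y <- normexp_correct(x, pr, offset = 0)
    expect_true(all(y > 0))
    expect_true(all(diff(y) >= -1e-9))
  }
})

test_that("normexp correction agrees with limma's conditional-mean signal", {
  skip_if_not_installed("limma")
  p <- structure(list(mu_b = 40, sigma_b = 12, alpha = 150),
                 class = "normexp_params")
  x <- c(-100, -10, 0, 25, 80, 300, 5000)
  ours <- normexp_correct(x, p, offset = 0)
  theirs <- limma::normexp.signal(c(40, log(12), log(150)), x)
  expect_equal(ours, theirs, tolerance = 1e-8)
})

test_that("quantile normalization implements the rank-mean rule", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  got <- quantile_normalize(m)
  expect_equal(unname(got[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(got[, 2]), c(2.5, 3.5, 4.5))

  # order within a column is preserved regardless of input arrangement
  m2 <- cbind(a = c(3, 1, 2), b = c(4, 5, 6))
  got2 <- quantile_normalize(m2)
  expect_equal(unname(got2[, 1]), c(4.5, 2.5, 3.5))

  # ties receive the mean of the reference values over their rank span
  mt <- cbind(a = c(1, 1, 3), b = c(4, 5, 6))
  ref <- c((1 + 4) / 2, (1 + 5) / 2, (3 + 6) / 2)
  gt <- quantile_normalize(mt)
  expect_equal(unname(gt[, 1]), c(mean(ref[1:2]), mean(ref[1:2]), ref[3]))
})

test_that("quantile normalization is idempotent and equalizes distributions", {
  set.seed(4)
  m <- matrix(rnorm(200, sd = 2), 50, 4)
  qn <- quantile_normalize(m)
  sorted <- apply(qn, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  expect_equal(quantile_normalize(qn), qn, tolerance = 1e-12)

  # single column and identical columns are fixed points
  expect_identical(quantile_normalize(m[, 1, drop = FALSE]), m[, 1, drop = FALSE])
  same <- m[, c(1, 1, 1)]
  expect_equal(quantile_normalize(same), same, tolerance = 1e-12)

  # permutation-equivariant in columns
  perm <- c(3, 1, 4, 2)
  expect_equal(quantile_normalize(m[, perm]), qn[, perm], tolerance = 1e-12)

  expect_error(quantile_normalize(cbind(c(1, NA), c(2, 3))), "finite")
})

test_that("quantile normalization matches limma on tie-free input", {
  skip_if_not_installed("limma")
  set.seed(5)
  m <- matrix(rnorm(300), 60, 5)
  expect_equal(unname(quantile_normalize(m)),
               unname(limma::normalizeQuantiles(m)), tolerance = 1e-10)
})

test_that("replicate spots average into unique probes", {
  m <- matrix(c(4, 6, 10, 2, 8, 12), 3, 2)
  rownames(m) <- c("s1", "s2", "s3")
  got <- average_replicate_probes(m, c("P1", "P1", "P2"))
  expect_equal(unname(got["P1", ]), c(5, 5))
  expect_equal(unname(got["P2", ]), c(10, 12))

  # spots_per_probe = 1 is an identity re-indexing
  one <- average_replicate_probes(m, c("A", "B", "C"))
  expect_equal(unname(one), unname(m))
  expect_equal(rownames(one), c("A", "B", "C"))

  expect_error(average_replicate_probes(m, c("P1", NA, "P2")), "unique probe")
  # row count equals the number of unique probes at scale
  big <- matrix(rnorm(3000 * 2), 3000, 2)
  map <- rep(sprintf("P%04d", 1:1000), each = 3)
  expect_equal(nrow(average_replicate_probes(big, map)), 1000)
})

test_that("preprocess composes its stages with recorded provenance", {
  gen <- generate_dataset(synthetic_config(
    n_unique_probes = 300, spots_per_probe = 2,
    group_sizes = c(media = 3, reference = 3), n_responsive = 30, seed = 21))
  expr <- preprocess(gen$raw, gen$sheet)
  expect_true(all(is.finite(expr$E)))
  expect_equal(nrow(expr$E), 300)
  expect_equal(colnames(expr$E), gen$sheet$sample_id)
  steps <- vapply(expr$provenance, `[[`, "", "step")
  expect_equal(steps, c("normexp_correct", "log2", "quantile_normalize",
                        "average_replicate_probes"))
  expect_length(expr$provenance[[1]]$params, 6)
})

test_that("two identical arrays preprocess to identical columns", {
  gen <- generate_dataset(synthetic_config(
    n_unique_probes = 200, group_sizes = c(media = 2, reference = 2),
    n_responsive = 0, effect_log2 = 0, seed = 31))
  raw <- gen$raw
  raw$fg[, 2] <- raw$fg[, 1]
  raw$bg[, 2] <- raw$bg[, 1]
  expr <- preprocess(raw, gen$sheet)
  expect_equal(expr$E[, 1], expr$E[, 2], tolerance = 1e-10)
})

test_that("rescaling all arrays shifts bright probes by log2(c)", {
  gen <- generate_dataset(synthetic_config(
    n_unique_probes = 400, group_sizes = c(media = 3, reference = 3),
    n_responsive = 0, effect_log2 = 0, seed = 41))
  expr1 <- preprocess(gen$raw, gen$sheet)
  scaled <- gen$raw
  scaled$fg <- scaled$fg * 4
  scaled$bg <- scaled$bg * 4
  expr2 <- preprocess(scaled, gen$sheet)
  bright <- rowMeans(expr1$E) > quantile(rowMeans(expr1$E), 0.75)
  shift <- expr2$E[bright, ] - expr1$E[bright, ]
  expect_equal(median(shift), 2, tolerance = 0.05)
})
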