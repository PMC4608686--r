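test_that("Pearson dissimilarity matches the direct correlation formula", {
  X <- matrix(c(1, 2, 3, 4,
                2, 4, 6, 8,
                4, 3, 2, 1), 4, 3)
  colnames(X) <- c("s1", "s2", "s3")
  rownames(X) <- paste0("P", 1:4)
  d <- pearson_dissimilarity(X)
  expect_equal(unname(d["s1", "s2"]), 0)          # identical up to scale
  expect_equal(unname(d["s1", "s3"]), 2)          # perfectly anticorrelated
  expect_equal(unname(diag(d)), rep(0, 3))
  # hand oracle on a random 4-probe profile
  set.seed(12)
  Y <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("P", 1:4), paste0("t", 1:3)))
  dy <- pearson_dissimilarity(Y)
  expect_equal(unname(dy[1, 2]), 1 - cor(Y[, 1], Y[, 2]), tolerance = 1e-12)
  expect_equal(unname(dy[2, 3]), 1 - cor(Y[, 2], Y[, 3]), tolerance = 1e-12)
})

test_that("dissimilarity subsetting and degenerate profiles are handled", {
  run <- shared_small_run()
  ids <- rownames(run$expr$E)[1:50]
  d_sub <- pearson_dissimilarity(run$expr, probe_subset = ids)
  d_man <- pearson_dissimilarity(run$expr$E[ids, ])
  expect_equal(unname(unclass(d_sub)), unname(unclass(d_man)))
  expect_error(pearson_dissimilarity(run$expr, probe_subset = c(ids, "NOPE")),
               "NOPE")
  flat <- matrix(c(1, 1, 1, 2, 3, 4), 3, 2,
                 dimnames = list(NULL, c("flat", "ok")))
  expect_error(pearson_dissimilarity(flat), "flat")
})

test_that("mvt evaluates its formula on the block fixture", {
  d <- generate_dissimilarity_fixture(2, 2, within = 0.1, between = 0.4)
  r <- mvt(d, c("G1", "G2"), c("H1", "H2"))
  expect_equal(r$d_between, 0.4)
  expect_equal(r$s_G, 0.1)
  expect_equal(r$s_H, 0.1)
  expect_equal(r$statistic, 2)

  # within == between forces mvt = 1/2
  flat <- generate_dissimilarity_fixture(3, 4, within = 0.3, between = 0.3)
  expect_equal(mvt(flat, 1:3, 4:7)$statistic, 0.5)

  # symmetry and relabeling invariance
  expect_equal(mvt(d, c("H1", "H2"), c("G1", "G2"))$statistic, 2)
  expect_equal(mvt(d, c("G2", "G1"), c("H2", "H1"))$statistic, 2)
})

test_that("mvt enforces its contract and scales out the dissimilarity units", {
  d <- generate_dissimilarity_fixture(3, 3, within = 0.2, between = 0.5)
  expect_error(mvt(d, 1:3, 3:6), "disjoint")
  expect_error(mvt(d, 1, 2:6), "at least 2")
  expect_error(mvt(d, 1:3, c(4, 5, 99)), "unknown sample")

  r1 <- mvt(d, 1:3, 4:6)$statistic
  r2 <- mvt(new_d <- structure(unclass(d) * 3.7, class = class(d)), 1:3, 4:6)$statistic
  expect_equal(r1, r2, tolerance = 1e-12)

  zero <- generate_dissimilarity_fixture(2, 2, within = 0, between = 0.4)
  expect_warning(rz <- mvt(zero, 1:2, 3:4), "infinite")
  expect_identical(rz$statistic, Inf)
  allzero <- generate_dissimilarity_fixture(2, 2, within = 0, between = 0)
  expect_error(suppressWarnings(mvt(allzero, 1:2, 3:4)), "undefined")
})

test_that("mvt on random data agrees with a brute-force oracle", {
  set.seed(23)
  X <- matrix(rnorm(30 * 9), 30, 9,
              dimnames = list(NULL, paste0("s", 1:9)))
  d <- pearson_dissimilarity(X)
  got <- mvt(d, 1:4, 5:9)
  expect_equal(got$statistic, oracle_mvt(unclass(d), 1:4, 5:9), tolerance = 1e-12)
})

test_that("mvt permutation p is exact under enumeration and seeded otherwise", {
  set.seed(14)
  X <- matrix(rnorm(40 * 8), 40, 8, dimnames = list(NULL, paste0("s", 1:8)))
  X[, 1:4] <- X[, 1:4] + rnorm(40, sd = 0.6)  # correlated shift for group 1
  d <- pearson_dissimilarity(X)
  ex <- mvt_permutation_test(d, 1:4, 5:8, exact = TRUE)
  expect_equal(ex$n_perm, 70)

  combos <- combn(8, 4)
  stats <- apply(combos, 2, function(g) {
    oracle_mvt(unclass(d), g, setdiff(1:8, g))
  })
  obs <- oracle_mvt(unclass(d), 1:4, 5:8)
  expect_equal(ex$statistic, obs, tolerance = 1e-12)
  expect_equal(ex$p_value, mean(stats >= obs - 1e-12))

  mc1 <- mvt_permutation_test(d, 1:4, 5:8, n_perm = 400, seed = 5)
  mc2 <- mvt_permutation_test(d, 1:4, 5:8, n_perm = 400, seed = 5)
  expect_identical(mc1$p_value, mc2$p_value)
  expect_gte(mc1$p_value, 1 / 401)
  expect_lte(mc1$p_value, 1)
})

test_that("classical MDS reproduces Euclidean-embeddable distances", {
  # 3 collinear points, distances 1, 1, 2 -> exact 1-D recovery
  d3 <- matrix(c(0, 1, 2,
                 1, 0, 1,
                 2, 1, 0), 3, 3)
  pts <- classical_mds(d3, k = 1)
  expect_lt(max(abs(as.matrix(dist(pts)) - d3)), 1e-9)

  # all-equal dissimilarities: an equilateral triangle
  deq <- generate_dissimilarity_fixture(1, 2, within = 1, between = 1)
  pts2 <- classical_mds(deq, k = 2)
  expect_lt(max(abs(as.matrix(dist(pts2)) - unclass(deq))), 1e-9)

  expect_error(classical_mds(d3, k = 3), "smaller")
})

test_that("standardized PCA matches the eigen decomposition", {
  # single varying probe: PC1 scores proportional to its standardized values
  X <- rbind(P1 = c(1, 3, 5, 7), P2 = c(2, 2, 2, 2))
  colnames(X) <- paste0("s", 1:4)
  expect_warning(res <- pca_scores(X), "zero-variance")
  std <- as.numeric(scale(c(1, 3, 5, 7)))
  expect_equal(abs(unname(res$scores[, 1])), abs(std), tolerance = 1e-10)
  expect_error(suppressWarnings(pca_scores(rbind(P2 = c(2, 2, 2, 2)))), "varying")

  X2 <- rbind(P1 = c(1, 3, 5, 7), P2 = c(7, 3, 1, 5), P3 = c(2, 6, 4, 8))
  colnames(X2) <- paste0("s", 1:4)
  res2 <- pca_scores(X2)
  Xs <- t(scale(t(X2)))
  ev <- eigen(cov(t(Xs)))
  expect_equal(unname(res2$variance_fractions[1:2]),
               (ev$values / sum(ev$values))[1:2], tolerance = 1e-10)
  # scores match projection onto eigenvectors up to the fixed sign convention
  for (j in 1:2) {
    expect_equal(abs(unname(res2$scores[, j])),
                 abs(unname(t(Xs) %*% ev$vectors[, j]))[, 1], tolerance = 1e-8)
    v <- res2$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("group separation shows up in PC1 when treatment dominates the variance", {
  # treatment-dominated dataset (no latent factors): PC1 is the
  # treatment direction, so Welch tests on PC1 separate media from the
  # products but not the products from one another
  gen <- generate_dataset(synthetic_config(
    n_unique_probes = 400, group_sizes = c(media = 5, reference = 6, test = 6),
    n_responsive = 80, n_factors = 0, seed = 51))
  expr <- preprocess(gen$raw, gen$sheet)
  res <- pca_scores(expr)
  g <- gen$sheet$group
  ht <- t.test(res$scores[g == "media", 1], res$scores[g == "reference", 1])
  expect_lt(ht$p.value, 0.001)
  ht2 <- t.test(res$scores[g == "test", 1], res$scores[g == "reference", 1])
  expect_gt(ht2$p.value, 0.05)
})

test_that("Ward clustering separates well-separated blobs and merges nearest first", {
  d3 <- matrix(c(0, 0.1, 0.9,
                 0.1, 0, 0.8,
                 0.9, 0.8, 0), 3, 3,
               dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  tree <- ward_clustering(d3)
  expect_equal(sort(tree$merge[1, ]), c(-2, -1))  # d(1,2) smallest

  blob <- generate_dissimilarity_fixture(4, 5, within = 0.05, between = 1.5)
  tr <- ward_clustering(blob)
  k2 <- cutree(tr, k = 2)
  expect_equal(length(unique(k2[1:4])), 1)
  expect_equal(length(unique(k2[5:9])), 1)
  expect_false(k2[1] == k2[5])
})
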