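test_that("zscore_features standardizes rows with n-1 SD and zeroes constants", {
  m <- matrix(c(0, 2), 1, 2, dimnames = list("f", c("a", "b")))
  expect_equal(unname(zscore_features(m)[1, ]), c(-1, 1) / sqrt(2),
               tolerance = 1e-12)
  const <- matrix(5, 1, 3, dimnames = list("f", letters[1:3]))
  expect_equal(unname(zscore_features(const)[1, ]), c(0, 0, 0))
  r <- rand_expr(10, 20, seed = 301)
  z <- zscore_features(r)
  expect_true(all(abs(rowMeans(z)) < 1e-10))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-10))
  expect_error(zscore_features(r[, 1, drop = FALSE]), "at least 2 samples")
})

test_that("duplicate samples always reach consensus 1 when co-sampled", {
  set.seed(302)
  m <- matrix(rnorm(20 * 30), 20, 30,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:30)))
  m[, 2] <- m[, 1]  # exact duplicate pair
  cc <- consensus_cluster(m, k = 3, iterations = 30, seed = 303)
  expect_equal(cc$consensus_matrix[1, 2], 1)
})

test_that("consensus clustering is deterministic given the seed", {
  spec <- cohort_spec(n_samples = 60, separation = 3, seed = 304)
  z <- zscore_features(generate_abundance_cohort(spec)$abundance)
  a <- consensus_cluster(z, k = 4, iterations = 25, seed = 305)
  b <- consensus_cluster(z, k = 4, iterations = 25, seed = 305)
  expect_identical(a, b)
  expect_true(all(a$consensus_matrix >= 0 & a$consensus_matrix <= 1))
  expect_true(isSymmetric(a$consensus_matrix))
  expect_equal(unname(diag(a$consensus_matrix)), rep(1, 60))
})

test_that("planted well-separated blobs are recovered exactly", {
  spec <- cohort_spec(n_samples = 200, separation = 6, seed = 306)
  ab <- generate_abundance_cohort(spec)
  z <- zscore_features(ab$abundance)
  cc <- consensus_cluster(z, k = 4, iterations = 50, seed = 307)
  expect_equal(adjusted_rand_index(cc$labels, ab$labels), 1.0)
})

test_that("full-sample consensus on separated duplicate-free data is 0/1 block-diagonal", {
  spec <- cohort_spec(n_samples = 48, separation = 8, seed = 308)
  ab <- generate_abundance_cohort(spec)
  z <- zscore_features(ab$abundance)
  cc <- consensus_cluster(z, k = 4, iterations = 10, subsample_fraction = 1,
                          seed = 309)
  expect_true(all(cc$consensus_matrix %in% c(0, 1)))
  same <- outer(ab$labels, ab$labels, "==")
  expect_equal(unname(cc$consensus_matrix), unname(same) * 1)
})

test_that("consensus_cluster validates its arguments", {
  z <- zscore_features(rand_expr(5, 10, seed = 310))
  expect_error(consensus_cluster(z, k = 1), ">= 2")
  expect_error(consensus_cluster(z, k = 10), "more samples than clusters")
  expect_error(consensus_cluster(z, k = 4, subsample_fraction = 0.3),
               "subsample too small")
  zc <- z; zc[, 1] <- 0
  expect_error(consensus_cluster(zc, k = 2), "zero variance")
})

test_that("silhouettes match the brute-force oracle and hit the duplicate limit", {
  # two tight duplicate pairs, far apart: all silhouettes exactly 1
  base <- matrix(rnorm(12), 12, 1)
  m <- cbind(base, base, -base, -base)
  rownames(m) <- paste0("f", 1:12); colnames(m) <- paste0("s", 1:4)
  s <- silhouette_scores(m, c("A", "A", "B", "B"))
  expect_equal(unname(s), rep(1, 4), tolerance = 1e-12)

  # 6-point example against the plain-loop oracle
  z <- zscore_features(rand_expr(8, 6, seed = 311))
  labels <- c("x", "x", "y", "y", "z", "z")
  d <- 1 - cor(z)
  expect_equal(unname(silhouette_scores(z, labels)),
               oracle_silhouette(d, labels), tolerance = 1e-12)

  # singleton cluster gets 0
  s2 <- silhouette_scores(z, c("x", "x", "x", "y", "y", "solo"))
  expect_equal(unname(s2[6]), 0)
  expect_error(silhouette_scores(z, rep("x", 6)), "at least 2")
})

test_that("random labels on structureless data give near-zero mean silhouette", {
  vals <- vapply(1:50, function(i) {
    z <- zscore_features(rand_expr(20, 24, seed = 400 + i))
    set.seed(500 + i)
    mean(silhouette_scores(z, sample(rep(c("a", "b", "c"), 8))))
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.1)
})

test_that("centroids equal per-subtype feature means", {
  z <- zscore_features(rand_expr(64, 100, seed = 312))
  set.seed(313)
  labels <- factor(sample(paste0("C", 1:4), 100, replace = TRUE))
  cent <- compute_centroids(z, labels)
  for (g in levels(labels)) for (f in sample(rownames(z), 10))
    expect_equal(cent[f, g], mean(z[f, labels == g]))
  # one sample per subtype: centroid is that sample
  z4 <- z[, 1:4]
  c4 <- compute_centroids(z4, paste0("C", 1:4))
  expect_equal(unname(c4), unname(z4))
  # all samples in one subtype: single centroid = overall feature mean
  c1 <- compute_centroids(z, rep("C1", 100))
  expect_equal(unname(c1[, 1]), unname(rowMeans(z)))
  expect_error(compute_centroids(z, factor(rep("C1", 100), levels = c("C1", "C2"))),
               "empty subtype")
})

test_that("label recovery improves monotonically with separation", {
  aris <- vapply(c(0, 2, 4, 6), function(sep) {
    mean(vapply(1:8, function(i) {
      spec <- cohort_spec(n_samples = 80, separation = sep, seed = 600 + i)
      ab <- generate_abundance_cohort(spec)
      z <- zscore_features(ab$abundance)
      cc <- consensus_cluster(z, k = 4, iterations = 20, seed = 700 + i)
      adjusted_rand_index(cc$labels, ab$labels)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(aris) > -0.05))  # non-decreasing up to sampling noise
  expect_lt(aris[1], 0.2)
  expect_gt(aris[4], 0.95)
})
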