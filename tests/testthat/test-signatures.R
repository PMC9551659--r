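test_that("mean signature scores are plain gene averages", {
  expr <- matrix(5, 7, 2, dimnames = list(tls_genes(), c("s1", "s2")))
  expect_equal(unname(tls_score(expr)), c(5, 5), ignore_attr = TRUE)

  toy <- matrix(c(1, 2, 6), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(unname(mean_signature_score(toy, c("a", "b", "c"))), 3,
               ignore_attr = TRUE)
  # linearity and gene-order invariance
  expect_equal(unname(mean_signature_score(2 * toy, c("a", "b", "c"))), 6,
               ignore_attr = TRUE)
  expect_equal(mean_signature_score(toy, c("c", "a", "b")),
               mean_signature_score(toy, c("a", "b", "c")), ignore_attr = TRUE)

  expr2 <- rand_expr(20, 5, seed = 901)
  genes <- rownames(expr2)[c(2, 9, 15, 17)]
  expect_equal(unname(mean_signature_score(expr2, genes)),
               unname(colMeans(expr2[genes, ])), ignore_attr = TRUE)
})

test_that("missing signature genes warn above half coverage, error below", {
  expr <- rand_expr(10, 3, seed = 902)
  genes6 <- c(rownames(expr)[1:4], "MISS1", "MISS2")   # 4/6 present
  expect_warning(v <- mean_signature_score(expr, genes6), "missing")
  expect_equal(attr(v, "genes_missing"), c("MISS1", "MISS2"))
  genes5 <- c(rownames(expr)[1:2], paste0("MISS", 1:3))  # 2/5 present
  expect_error(suppressWarnings(mean_signature_score(expr, genes5)), "signature genes present")
  expect_error(mean_signature_score(expr, c("NO1", "NO2")), "no .*genes found")
})

test_that("two-group centroid derivation recovers planted DEGs", {
  set.seed(903)
  n_genes <- 500; n_planted <- 50
  genes <- paste0("g", seq_len(n_genes))
  a <- matrix(rnorm(n_genes * 10), n_genes, 10, dimnames = list(genes, paste0("a", 1:10)))
  b <- matrix(rnorm(n_genes * 10), n_genes, 10, dimnames = list(genes, paste0("b", 1:10)))
  a[seq_len(n_planted), ] <- a[seq_len(n_planted), ] + 4
  cent <- derive_two_group_centroids(a, b, fdr_threshold = 0.05, min_abs_lfc = 1)
  planted <- genes[seq_len(n_planted)]
  expect_gte(sum(cent$genes %in% planted), 45)
  false_hits <- sum(!cent$genes %in% planted)
  expect_lte(false_hits / max(1, length(cent$genes)), 0.05)
  # planted genes are up in A: centroid_a above centroid_b there
  expect_true(all(cent$centroid_a[intersect(cent$genes, planted)] >
                    cent$centroid_b[intersect(cent$genes, planted)]))
})

test_that("two-group derivation is symmetric and rejects identical groups", {
  set.seed(904)
  genes <- paste0("g", 1:100)
  a <- matrix(rnorm(1000), 100, 10, dimnames = list(genes, paste0("a", 1:10)))
  b <- matrix(rnorm(1000), 100, 10, dimnames = list(genes, paste0("b", 1:10)))
  a[1:10, ] <- a[1:10, ] + 5
  ab <- derive_two_group_centroids(a, b)
  ba <- derive_two_group_centroids(b, a)
  expect_equal(ab$genes, ba$genes)
  expect_equal(ab$centroid_a, ba$centroid_b)
  expect_equal(ab$centroid_b, ba$centroid_a)
  expect_error(derive_two_group_centroids(a, a), "empty DEG panel")
  expect_error(derive_two_group_centroids(a[, 1:2], b), "3 samples")
})

test_that("tfr_score equals the two-Pearson-term oracle and is antisymmetric", {
  set.seed(905)
  genes <- paste0("g", 1:40)
  cent <- structure(list(genes = genes,
                         centroid_a = setNames(rnorm(40), genes),
                         centroid_b = setNames(rnorm(40), genes),
                         group_names = c("Tfr", "Treg")),
                    class = "two_group_centroids")
  expr <- matrix(rnorm(40 * 8), 40, 8, dimnames = list(genes, paste0("s", 1:8)))
  sc <- tfr_score(expr, cent)
  z <- zscore_features(expr)
  for (j in 1:8)
    expect_equal(unname(sc[j]),
                 oracle_pearson(z[, j], cent$centroid_a) -
                   oracle_pearson(z[, j], cent$centroid_b),
                 tolerance = 1e-12)
  swapped <- cent
  swapped$centroid_a <- cent$centroid_b
  swapped$centroid_b <- cent$centroid_a
  expect_equal(unname(tfr_score(expr, swapped)), unname(-sc), tolerance = 1e-12)
  expect_equal(unname(tfr_score(expr, swapped, kernel = "euclidean")),
               unname(-tfr_score(expr, cent, kernel = "euclidean")),
               tolerance = 1e-12)
})

test_that("a sample matching an orthogonal Tfr centroid scores 1", {
  # build orthogonal, zero-mean unit-structure centroids
  ca <- setNames(rep(c(1, -1), 10), paste0("g", 1:20))
  cb <- setNames(rep(c(1, 1, -1, -1), 5), paste0("g", 1:20))
  stopifnot(abs(sum(ca * cb)) < 1e-12, abs(oracle_pearson(ca, cb)) < 1e-12)
  cent <- structure(list(genes = names(ca), centroid_a = ca, centroid_b = cb,
                         group_names = c("Tfr", "Treg")),
                    class = "two_group_centroids")
  # cohort whose first sample z-vector reproduces ca: use +/- pairs per gene
  expr <- cbind(s1 = ca, s2 = -ca)
  sc <- tfr_score(expr, cent)
  expect_equal(unname(sc["s1"]), 1, tolerance = 1e-12)
  # equidistant sample: equal correlation to both centroids scores 0
  expr2 <- cbind(s1 = ca + cb, s2 = -(ca + cb))
  expect_equal(unname(tfr_score(expr2, cent)["s1"]), 0, tolerance = 1e-12)
})

test_that("on synthetic cohorts the Tfr-high subtype has the top mean TFRscore", {
  spec <- cohort_spec(n_samples = 400, separation = 3, seed = 906)
  ex <- generate_expression_cohort(spec, synthetic_signatures())
  sigs <- synthetic_signatures()
  genes <- c(sigs$`Tfr-up`, sigs$`Treg-up`)
  cent <- structure(list(genes = genes,
                         centroid_a = setNames(c(rep(1, 15), rep(-1, 15)), genes),
                         centroid_b = setNames(c(rep(-1, 15), rep(1, 15)), genes),
                         group_names = c("Tfr", "Treg")),
                    class = "two_group_centroids")
  sc <- tfr_score(ex$expression, cent)
  by_st <- tapply(sc, ex$labels, mean)
  expect_equal(names(which.max(by_st)), "C3")
})

test_that("dichotomize_score cuts at the interpolated quantile, ties to low", {
  lab <- dichotomize_score(setNames(1:9, paste0("s", 1:9)), q = 0.6666)
  expect_equal(sum(lab == "high"), 3L)
  expect_equal(names(lab)[lab == "high"], c("s7", "s8", "s9"))
  lab2 <- dichotomize_score(c(1, 2, 3, 4), q = 0.5)
  expect_equal(as.character(lab2), c("low", "low", "high", "high"))
  # a value exactly at the cut goes low
  lab3 <- dichotomize_score(c(1, 2, 3), q = 0.5)
  expect_equal(as.character(lab3), c("low", "low", "high"))
  expect_equal(attr(lab3, "cutoff"), 2)
  expect_error(dichotomize_score(rep(2, 5)), "constant")
  expect_error(dichotomize_score(c(1, 2)), "at least 3")
})
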