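test_that("generators are pure functions of spec and seed", {
  spec <- cohort_spec(n_samples = 40, seed = 9)
  a1 <- generate_abundance_cohort(spec)
  a2 <- generate_abundance_cohort(spec)
  expect_identical(a1, a2)
  e1 <- generate_expression_cohort(spec, synthetic_signatures())
  e2 <- generate_expression_cohort(spec, synthetic_signatures())
  expect_identical(e1, e2)
  c1 <- generate_clinical(a1$labels, spec)
  expect_identical(c1, generate_clinical(a1$labels, spec))
  # a different seed changes values but not shape or composition
  a3 <- generate_abundance_cohort(cohort_spec(n_samples = 40, seed = 10))
  expect_identical(dim(a3$abundance), dim(a1$abundance))
  expect_identical(table(a3$labels), table(a1$labels))
  expect_false(identical(a3$abundance, a1$abundance))
})

test_that("cohort_spec rejects inconsistent parameters", {
  expect_error(cohort_spec(subtype_proportions = c(0.5, 0.2, 0.2, 0.05)),
               "sum to 1")
  expect_error(cohort_spec(response_rates = c(0.2, 1.2, 0.1, 0.1)), "\\[0, 1\\]")
  expect_error(cohort_spec(hazard_ratios = c(1, -1, 1, 1)), "positive")
  expect_error(generate_abundance_cohort(cohort_spec(n_samples = 4)), ">= 8")
})

test_that("abundance subtype structure drives classification accuracy", {
  # strong separation: nearest-centroid recovery is essentially perfect
  spec <- cohort_spec(n_samples = 200, separation = 6, seed = 21)
  ab <- generate_abundance_cohort(spec)
  z <- zscore_features(ab$abundance)
  cent <- compute_centroids(z, ab$labels)
  cls <- classify_cohort(ab$abundance, cent)
  acc <- mean(cls$assignments$label == as.character(ab$labels))
  expect_gte(acc, 0.99)

  # zero separation: held-out accuracy is at chance for balanced proportions
  # (evaluation must be out-of-sample, since each training sample contributes
  # to its own centroid)
  spec_tr <- cohort_spec(n_samples = 2000, separation = 0,
                         subtype_proportions = rep(0.25, 4), seed = 22)
  tr <- generate_abundance_cohort(spec_tr)
  cent0 <- compute_centroids(zscore_features(tr$abundance), tr$labels)
  spec_te <- cohort_spec(n_samples = 2000, separation = 0,
                         subtype_proportions = rep(0.25, 4), seed = 23)
  te <- generate_abundance_cohort(spec_te)
  cls0 <- classify_cohort(te$abundance, cent0,
                          classifier_config(min_correlation = -0.99, min_gap = 0))
  acc0 <- mean(cls0$assignments$label == as.character(te$labels))
  ci <- qbinom(c(0.0025, 0.9975), 2000, 0.25) / 2000
  expect_gte(acc0, ci[1]); expect_lte(acc0, ci[2])
})

test_that("expression cohorts elevate signature blocks in designated subtypes", {
  spec <- cohort_spec(n_samples = 160, separation = 3, seed = 31)
  ex <- generate_expression_cohort(spec, synthetic_signatures())
  tls <- tls_score(ex$expression)
  by_st <- tapply(tls, ex$labels, mean)
  expect_equal(names(which.max(by_st)), "C3")
  expect_gt(by_st[["C3"]], max(by_st[c("C1", "C2", "C4")]))
  ft <- ftbrs_score(ex$expression, synthetic_signatures()$FTBRS)
  expect_equal(names(which.max(tapply(ft, ex$labels, mean))), "C2")
  expect_error(generate_expression_cohort(spec, list(TLS = "CCL19")),
               "missing required")
})

test_that("null expression cohorts keep Kruskal-Wallis near nominal size", {
  # all shifts zero: TLSscore has no subtype signal, type-I at alpha = 0.05
  rejections <- vapply(1:300, function(i) {
    spec <- cohort_spec(n_samples = 60, separation = 0, seed = 1000 + i)
    ex <- generate_expression_cohort(spec, synthetic_signatures())
    tls <- tls_score(ex$expression)
    kruskal_wallis(split(tls, ex$labels))$p.value < 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_gt(rate, 0.02); expect_lt(rate, 0.09)
})

test_that("clinical generator honours response and hazard structure", {
  spec <- cohort_spec(n_samples = 40, response_rates = c(1, 1, 1, 1), seed = 5)
  ab <- generate_abundance_cohort(spec)
  clin <- generate_clinical(ab$labels, spec)
  expect_true(all(clin$response == 1))
  expect_true(all(clin$time >= 0))
  expect_error(generate_clinical(c("C1", "C9"), spec), "unknown subtype")

  # censor_rate is approximately realized
  specc <- cohort_spec(n_samples = 4000, censor_rate = 0.3, seed = 6,
                       hazard_ratios = c(1, 1, 1, 1))
  abc <- generate_abundance_cohort(specc)
  clc <- generate_clinical(abc$labels, specc)
  expect_lt(abs(mean(clc$event == 0) - 0.3), 0.03)
})

test_that("null hazards give uniform log-rank p-values", {
  spec <- cohort_spec(n_samples = 100, hazard_ratios = c(1, 1, 1, 1),
                      censor_rate = 0.2)
  ps <- vapply(1:200, function(i) {
    sp <- spec; sp$seed <- 2000L + i
    ab <- generate_abundance_cohort(sp)
    clin <- generate_clinical(ab$labels, sp)
    logrank_test(clin$time, clin$event, clin$subtype)$p.value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("paired transitions realize the requested margins exactly", {
  tr <- generate_paired_transitions(default_transition_counts(),
                                    cohort_spec(seed = 77))
  expect_equal(nrow(tr$pairs), 20L)
  expect_equal(unname(table(factor(tr$pairs$pre_label, levels = paste0("C", 1:4)))),
               c(9L, 3L, 3L, 5L), ignore_attr = TRUE)
  expect_equal(unname(table(factor(tr$pairs$post_label, levels = paste0("C", 1:4)))),
               c(4L, 9L, 4L, 3L), ignore_attr = TRUE)
  realized <- table(tr$pairs$pre_label, tr$pairs$post_label)
  expect_equal(unclass(realized), unclass(default_transition_counts()),
               ignore_attr = TRUE)

  # identity matrix: every pair keeps its label
  id <- diag(c(5L, 5L, 5L, 5L))
  dimnames(id) <- dimnames(default_transition_counts())
  tid <- generate_paired_transitions(id, cohort_spec(seed = 78))
  expect_true(all(tid$pairs$pre_label == tid$pairs$post_label))

  # determinism
  expect_identical(tr, generate_paired_transitions(default_transition_counts(),
                                                   cohort_spec(seed = 77)))
  neg <- default_transition_counts(); neg[1, 1] <- -1L
  expect_error(generate_paired_transitions(neg, cohort_spec()), "nonnegative")
})
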