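#' Z-score a matrix per feature across samples
#'
#' Each row is centred to mean 0 and scaled to sample SD 1 (n - 1
#' denominator). Constant rows map to all zeros rather than NaN, so
#' uninformative features drop out of correlation-based distances.
#'
#' @param m Numeric features x samples matrix with >= 2 samples.
#' @return Matrix of the same shape.
#' @export
zscore_features <- function(m) {
  if (ncol(m) < 2L) stop("z-scoring needs at least 2 samples", call. = FALSE)
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

# 1 - Pearson correlation between samples (columns); errors on zero-variance
# columns, for which the correlation is undefined.
.pearson_dist <- function(m) {
  sds <- apply(m, 2L, sd)
  if (any(sds == 0))
    stop("samples with zero variance across features (correlation undefined): ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  d <- 1 - cor(m)
  d[d < 0] <- 0  # clamp tiny negative rounding
  d
}

#' Consensus clustering by resampled k-medoids (Monti procedure)
#'
#' Repeatedly subsamples the cohort without replacement, partitions each
#' subsample with PAM (k-medoids) under the distance
#' `d(i, j) = 1 - Pearson(sample_i, sample_j)` computed over features, and
#' records how often each pair of samples lands in the same cluster among
#' the runs in which both were drawn:
#' `consensus(i, j) = co-clustered / co-sampled`. Pairs never co-sampled get
#' consensus 0 with a warning; the diagonal is forced to 1. Final subtype
#' labels come from an average-linkage hierarchical cut of
#' `1 - consensus` into `k` groups, labelled `C1..Ck` in cluster-index
#' order.
#'
#' @param z Numeric features x samples matrix, typically from
#'   [zscore_features()].
#' @param k Number of subtypes (>= 2, < number of samples).
#' @param iterations Number of resampling runs (default 100).
#' @param subsample_fraction Fraction of samples drawn per run, in (0, 1]
#'   (default 0.8).
#' @param seed Integer seed; the result is a pure function of
#'   (inputs, seed).
#' @return An object of class `consensus_result`: list with `k`,
#'   `consensus_matrix` (n x n, symmetric, values in `[0, 1]`), `labels`
#'   (factor `C1..Ck` named by sample), `silhouette` (per-sample, from
#'   [silhouette_scores()]), and `resample_params`.
#' @export
consensus_cluster <- function(z, k, iterations = 100L, subsample_fraction = 0.8,
                              seed = 1L) {
  n <- ncol(z)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (n <= k) stop("need more samples than clusters", call. = FALSE)
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stop("subsample_fraction must lie in (0, 1]", call. = FALSE)
  m_sub <- floor(subsample_fraction * n)
  if (m_sub <= k)
    stop("subsample too small for k clusters; raise subsample_fraction",
         call. = FALSE)
  d_full <- .pearson_dist(z)
  co_cluster <- matrix(0, n, n)
  co_sample <- matrix(0, n, n)
  set.seed(seed)
  for (it in seq_len(iterations)) {
    idx <- sort(sample.int(n, m_sub))
    cl <- cluster::pam(stats::as.dist(d_full[idx, idx]), k = k,
                       cluster.only = TRUE, pamonce = 5)
    same <- outer(cl, cl, "==")
    co_sample[idx, idx] <- co_sample[idx, idx] + 1
    co_cluster[idx, idx] <- co_cluster[idx, idx] + same
  }
  never <- co_sample == 0
  diag(never) <- FALSE
  if (any(never))
    warning(sum(never) / 2, " sample pairs were never co-sampled; their consensus is set to 0")
  consensus <- ifelse(co_sample > 0, co_cluster / co_sample, 0)
  diag(consensus) <- 1
  dimnames(consensus) <- list(colnames(z), colnames(z))
  hc <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
  cut <- stats::cutree(hc, k = k)
  labels <- factor(paste0("C", cut), levels = paste0("C", seq_len(k)))
  names(labels) <- colnames(z)
  if (nlevels(droplevels(labels)) < k)
    warning("fewer than k non-empty clusters in the consensus cut")
  sil <- silhouette_scores(z, labels)
  structure(list(k = k, consensus_matrix = consensus, labels = labels,
                 silhouette = sil,
                 resample_params = list(iterations = iterations,
                                        subsample_fraction = subsample_fraction,
                                        seed = seed)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus clustering: k = %d, %d samples, %d iterations (%.0f%% subsample)\n",
              x$k, ncol(x$consensus_matrix), x$resample_params$iterations,
              100 * x$resample_params$subsample_fraction))
  print(table(x$labels))
  cat(sprintf("mean silhouette: %.3f\n", mean(x$silhouette)))
  invisible(x)
}

#' Per-sample silhouette widths under the 1 - Pearson distance
#'
#' Standard silhouette `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a` the
#' mean distance to the sample's own cluster and `b` the smallest mean
#' distance to another cluster; samples in singleton clusters get `s = 0`.
#'
#' @param z Features x samples matrix.
#' @param labels Cluster label per sample (factor or character).
#' @return Numeric vector of silhouettes in `[-1, 1]`, named by sample.
#' @export
silhouette_scores <- function(z, labels) {
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 non-empty clusters", call. = FALSE)
  d <- .pearson_dist(z)
  n <- ncol(z)
  s <- numeric(n)
  sizes <- table(labels)
  for (i in seq_len(n)) {
    own <- labels[i]
    if (sizes[[own]] == 1L) { s[i] <- 0; next }
    a <- sum(d[i, labels == own]) / (sizes[[own]] - 1L)
    b <- min(vapply(setdiff(levels(labels), as.character(own)), function(g)
      mean(d[i, labels == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  names(s) <- colnames(z)
  s
}

#' Mean-silhouette sweep over candidate numbers of clusters
#'
#' Runs [consensus_cluster()] for each `k` and reports the mean silhouette,
#' as a diagnostic for choosing the number of subtypes. No automatic choice
#' is made.
#'
#' @param z Features x samples matrix.
#' @param ks Candidate cluster counts (default 2:6).
#' @inheritParams consensus_cluster
#' @return `data.frame` with columns `k` and `mean_silhouette`.
#' @export
silhouette_sweep <- function(z, ks = 2:6, iterations = 100L,
                             subsample_fraction = 0.8, seed = 1L) {
  res <- vapply(ks, function(k) {
    cc <- consensus_cluster(z, k, iterations, subsample_fraction, seed)
    mean(cc$silhouette)
  }, numeric(1))
  data.frame(k = ks, mean_silhouette = res)
}

#' Subtype centroids as per-feature mean z-values
#'
#' `centroid(feature, subtype)` is the mean of that feature's (z-scored)
#' values over the subtype's samples -- the profile later used for
#' nearest-centroid classification.
#'
#' @param z Features x samples matrix (z-scored).
#' @param labels Subtype per sample.
#' @return Features x subtypes numeric matrix.
#' @export
compute_centroids <- function(z, labels) {
  if (!is.factor(labels)) labels <- factor(labels)
  empty <- levels(labels)[table(labels) == 0L]
  if (length(empty))
    stop("empty subtype(s): ", paste(empty, collapse = ", "), call. = FALSE)
  stopifnot(ncol(z) == length(labels))
  cent <- sapply(levels(labels), function(g)
    rowMeans(z[, labels == g, drop = FALSE]))
  if (is.null(dim(cent)))
    cent <- matrix(cent, nrow = 1L,
                   dimnames = list(rownames(z), levels(labels)))
  cent
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same samples;
#' 1 for identical partitions (up to label names), about 0 for independent
#' ones.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
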