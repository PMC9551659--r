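#' Marker genes of the tertiary-lymphoid-structure score
#'
#' The canonical 7-gene TLS panel: CCL19, CCL21, CXCL13, CCR7, CXCR5, SELL
#' and LAMP3. `tls_score()` averages these genes.
#' @export
tls_genes <- function() c("CCL19", "CCL21", "CXCL13", "CCR7", "CXCR5", "SELL", "LAMP3")

#' Mean-expression signature score
#'
#' The unweighted per-sample mean of the signature genes present in the
#' expression matrix. Signature genes absent from the matrix are recorded
#' and a warning is raised; fewer than `min_fraction` of the signature
#' present is an error.
#'
#' @param expr Genes x samples numeric matrix.
#' @param genes Character vector of signature genes.
#' @param name Score name (stored as an attribute).
#' @param min_fraction Minimum fraction of the signature that must be
#'   present (default 0.5).
#' @return Named numeric vector (one score per sample) with attributes
#'   `score_name`, `genes_used` and `genes_missing`.
#' @export
mean_signature_score <- function(expr, genes, name = "signature",
                                 min_fraction = 0.5) {
  genes <- unique(genes)
  present <- intersect(genes, rownames(expr))
  if (length(present) == 0L)
    stop(sprintf("no '%s' signature genes found in the expression matrix", name),
         call. = FALSE)
  if (length(present) / length(genes) < min_fraction)
    stop(sprintf("only %d/%d '%s' signature genes present (need >= %.0f%%)",
                 length(present), length(genes), name, 100 * min_fraction),
         call. = FALSE)
  if (length(present) < length(genes))
    warning(sprintf("%d '%s' signature genes missing from the matrix; scoring over %d genes",
                    length(genes) - length(present), name, length(present)))
  v <- colMeans(expr[present, , drop = FALSE])
  attr(v, "score_name") <- name
  attr(v, "genes_used") <- present
  attr(v, "genes_missing") <- setdiff(genes, present)
  v
}

#' Tertiary lymphoid structure score (7-gene mean)
#'
#' @inheritParams mean_signature_score
#' @return Named numeric score vector.
#' @export
tls_score <- function(expr) mean_signature_score(expr, tls_genes(), "TLSscore")

#' Fibroblast TGF-beta response score (19-gene mean)
#'
#' Mean expression of a pan-fibroblast TGF-beta-induced signature. The
#' published panel is not bundled; supply it via `genes`.
#'
#' @inheritParams mean_signature_score
#' @param genes The 19-gene pan-fibroblast TGF-beta response signature.
#' @return Named numeric score vector.
#' @export
ftbrs_score <- function(expr, genes) mean_signature_score(expr, genes, "FTBRS")

#' Derive two-group discriminant centroids from labelled reference profiles
#'
#' Finds the genes differing between two reference expression groups
#' (two-sided rank-sum test, BH-adjusted p below `fdr_threshold`, absolute
#' mean log2 difference at least `min_abs_lfc`), then computes each group's
#' per-gene mean on the z-scale, with z-scores taken across the pooled
#' samples. The resulting panel and centroid pair parameterize
#' [tfr_score()].
#'
#' @param expr_a,expr_b Genes x samples matrices over the same gene
#'   universe (log2 scale), >= 3 samples each.
#' @param fdr_threshold BH-adjusted p cutoff (default 0.05).
#' @param min_abs_lfc Minimum |mean log2 difference| (default 1).
#' @param group_names Length-2 character vector naming the groups
#'   (default `c("Tfr", "Treg")`).
#' @return Object of class `two_group_centroids`: list with `genes`,
#'   `centroid_a`, `centroid_b`, `group_names`.
#' @export
derive_two_group_centroids <- function(expr_a, expr_b, fdr_threshold = 0.05,
                                       min_abs_lfc = 1,
                                       group_names = c("Tfr", "Treg")) {
  if (ncol(expr_a) < 3L || ncol(expr_b) < 3L)
    stop("need at least 3 samples per group", call. = FALSE)
  if (!identical(rownames(expr_a), rownames(expr_b)))
    stop("the two groups must share an identical gene universe", call. = FALSE)
  p <- vapply(seq_len(nrow(expr_a)), function(i)
    suppressWarnings(stats::wilcox.test(expr_a[i, ], expr_b[i, ])$p.value),
    numeric(1))
  lfc <- rowMeans(expr_a) - rowMeans(expr_b)
  padj <- stats::p.adjust(p, method = "BH")
  deg <- padj < fdr_threshold & abs(lfc) >= min_abs_lfc
  if (!any(deg))
    stop("empty DEG panel; relax fdr_threshold or min_abs_lfc", call. = FALSE)
  panel <- rownames(expr_a)[deg]
  pooled <- cbind(expr_a[panel, , drop = FALSE], expr_b[panel, , drop = FALSE])
  z <- zscore_features(pooled)
  na <- ncol(expr_a)
  structure(list(genes = panel,
                 centroid_a = rowMeans(z[, seq_len(na), drop = FALSE]),
                 centroid_b = rowMeans(z[, -seq_len(na), drop = FALSE]),
                 group_names = group_names),
            class = "two_group_centroids")
}

#' Centroid-based follicular-regulatory-T-cell score
#'
#' Expression is z-scored per gene across the cohort over the centroid
#' panel; each sample's score contrasts its similarity to the first-group
#' centroid (Tfr) with its similarity to the second (Treg). Two kernels are
#' offered: `"correlation"` (default) gives
#' `Pearson(sample, centroid_Tfr) - Pearson(sample, centroid_Treg)`;
#' `"euclidean"` gives the (panel-size-normalized) distance to the Treg
#' centroid minus the distance to the Tfr centroid. Both are antisymmetric
#' under swapping the two centroids, and higher means more Tfr-like.
#'
#' @param expr Genes x samples matrix (log2 scale).
#' @param centroids A [derive_two_group_centroids()] result.
#' @param kernel `"correlation"` or `"euclidean"`.
#' @param min_overlap Minimum fraction of panel genes present (default 0.8).
#' @return Named numeric score vector with attribute `score_name = "TFRscore"`.
#' @export
tfr_score <- function(expr, centroids, kernel = c("correlation", "euclidean"),
                      min_overlap = 0.8) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(centroids, "two_group_centroids"))
  panel <- centroids$genes
  present <- intersect(panel, rownames(expr))
  if (length(present) / length(panel) < min_overlap)
    stop(sprintf("only %d/%d panel genes present (need >= %.0f%%)",
                 length(present), length(panel), 100 * min_overlap),
         call. = FALSE)
  z <- zscore_features(expr[present, , drop = FALSE])
  ca <- centroids$centroid_a[present]
  cb <- centroids$centroid_b[present]
  score <- vapply(seq_len(ncol(z)), function(j) {
    x <- z[, j]
    if (sd(x) == 0)
      stop(sprintf("zero-variance sample '%s' over the panel", colnames(z)[j]),
           call. = FALSE)
    if (kernel == "correlation")
      cor(x, ca) - cor(x, cb)
    else
      (sqrt(mean((x - cb)^2)) - sqrt(mean((x - ca)^2)))
  }, numeric(1))
  names(score) <- colnames(expr)
  attr(score, "score_name") <- "TFRscore"
  attr(score, "kernel") <- kernel
  score
}

#' Dichotomize a score at an empirical quantile
#'
#' Samples strictly above the `q` quantile (linear interpolation, R type 7)
#' are labelled `"high"`, the rest `"low"`; values exactly at the cut go to
#' `"low"`. The conventional cut for survival stratification of the
#' TFRscore is the 66.66% quantile.
#'
#' @param score Numeric vector (>= 3 values, not all equal).
#' @param q Quantile in (0, 1) (default 0.6666).
#' @return Factor with levels `low`, `high`, named like `score`; the cut
#'   value is attached as attribute `cutoff`.
#' @export
dichotomize_score <- function(score, q = 0.6666) {
  if (length(score) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)", call. = FALSE)
  if (length(unique(score)) == 1L)
    stop("constant scores cannot be dichotomized", call. = FALSE)
  cut <- unname(quantile(score, probs = q, type = 7))
  out <- factor(ifelse(score > cut, "high", "low"), levels = c("low", "high"))
  names(out) <- names(score)
  attr(out, "cutoff") <- cut
  out
}
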