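#' Single-sample gene-set enrichment scores (rank-based running sum)
#'
#' For each sample, genes are ranked by expression (average ranks for ties)
#' and walked in decreasing order: in-set positions increment the running
#' sum proportionally to `rank^alpha` (normalized so in-set increments sum
#' to 1), out-of-set positions decrement it uniformly. The enrichment score
#' is the signed area of the walk -- the area above zero minus the area
#' below zero, i.e. the sum of the running values -- so a set concentrated
#' at the top of the ranking scores positive and its complement (at
#' `alpha = 0`) scores the exact negative. With `normalize = TRUE`, all
#' scores are divided by the range (max - min) across the whole matrix.
#'
#' Scores depend on expression only through within-sample ranks, so they are
#' invariant to gene order and to any strictly increasing transform of a
#' sample's values.
#'
#' @param expr Numeric genes x samples matrix.
#' @param sets Named list of gene identifier vectors.
#' @param alpha Rank-weight exponent, >= 0 (default 0.25).
#' @param normalize Divide scores by the matrix-wide score range
#'   (default FALSE).
#' @return Numeric sets x samples matrix with attributes `alpha` and
#'   `normalized`.
#' @export
ssgsea_scores <- function(expr, sets, alpha = 0.25, normalize = FALSE) {
  if (nrow(expr) < 2L) stop("need at least 2 genes", call. = FALSE)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (length(sets) == 0L) stop("empty gene-set collection", call. = FALSE)
  genes <- rownames(expr)
  idx_sets <- lapply(sets, function(g) which(genes %in% g))
  empty <- names(sets)[vapply(idx_sets, length, integer(1)) == 0L]
  if (length(empty))
    stop("gene sets with empty intersection with the expression matrix: ",
         paste(empty, collapse = ", "), call. = FALSE)
  full <- names(sets)[vapply(idx_sets, length, integer(1)) == nrow(expr)]
  if (length(full))
    stop("gene sets covering every gene (empty complement): ",
         paste(full, collapse = ", "), call. = FALSE)
  n <- nrow(expr)
  out <- matrix(NA_real_, length(sets), ncol(expr),
                dimnames = list(names(sets), colnames(expr)))
  for (s in seq_len(ncol(expr))) {
    x <- expr[, s]
    if (length(unique(x)) == 1L)
      stop(sprintf("constant expression in sample '%s': ranks undefined",
                   colnames(expr)[s]), call. = FALSE)
    r <- rank(x, ties.method = "average")        # high expression = high rank
    ord <- order(x, decreasing = TRUE)           # walk from top-ranked down
    w <- r^alpha
    for (k in seq_along(idx_sets)) {
      inset <- logical(n)
      inset[idx_sets[[k]]] <- TRUE
      inset_ord <- inset[ord]
      step <- ifelse(inset_ord, w[ord] / sum(w[idx_sets[[k]]]),
                     -1 / (n - length(idx_sets[[k]])))
      out[k, s] <- sum(cumsum(step))
    }
  }
  if (normalize) {
    rng <- max(out) - min(out)
    if (rng > 0) out <- out / rng
  }
  attr(out, "alpha") <- alpha
  attr(out, "normalized") <- normalize
  out
}

#' Cell-type abundance from per-population gene signatures
#'
#' Generic signature-based abundance: one [ssgsea_scores()] row per
#' cell-population signature, in the order of the input collection. Intended
#' as a stand-in for precomputed deconvolution output (e.g. xCell or
#' ConsensusTME scores) when only expression and signatures are available.
#'
#' @inheritParams ssgsea_scores
#' @param cell_signatures Named list: one gene vector per cell population.
#' @return Cell types x samples abundance matrix.
#' @export
abundance_from_signatures <- function(expr, cell_signatures, alpha = 0.25,
                                      normalize = FALSE) {
  ssgsea_scores(expr, cell_signatures, alpha = alpha, normalize = normalize)
}

#' Subtype-specific marker pathways by one-vs-rest ranking
#'
#' For each subtype, a pathway is subtype-specific when its enrichment
#' scores differ from every other subtype (two-sided rank-sum test, p-values
#' BH-adjusted across pathways within each pairwise contrast, all adjusted
#' p < `p_threshold`) and its mean enrichment is highest in that subtype.
#' The top `top_n` such pathways by within-subtype mean enrichment are
#' returned per subtype.
#'
#' @param scores Sets x samples enrichment matrix.
#' @param labels Subtype per sample (factor or character), aligned with the
#'   columns of `scores`.
#' @param top_n Number of pathways to report per subtype (default 10).
#' @param p_threshold Adjusted-p cutoff (default 0.05).
#' @return A `data.frame` with columns `subtype`, `pathway`, `mean_score`
#'   and `max_adj_p` (the largest adjusted p over that pathway's pairwise
#'   contrasts), ordered by subtype then decreasing mean score.
#' @export
subtype_marker_pathways <- function(scores, labels, top_n = 10L,
                                    p_threshold = 0.05) {
  labels <- factor(labels)
  stopifnot(ncol(scores) == length(labels))
  lev <- levels(labels)
  if (length(lev) < 2L) stop("need at least 2 subtypes", call. = FALSE)
  small <- lev[table(labels) < 2L]
  if (length(small))
    stop("subtypes with fewer than 2 samples: ", paste(small, collapse = ", "),
         call. = FALSE)
  if (top_n == 0L)
    return(data.frame(subtype = character(0), pathway = character(0),
                      mean_score = numeric(0), max_adj_p = numeric(0)))
  grp_mean <- sapply(lev, function(g) rowMeans(scores[, labels == g, drop = FALSE]))
  if (is.null(dim(grp_mean))) grp_mean <- matrix(grp_mean, nrow = 1,
                                                 dimnames = list(rownames(scores), lev))
  # adjusted p per (pathway, contrast), BH within each contrast
  contrasts <- utils::combn(lev, 2L, simplify = FALSE)
  adj <- list()
  for (ct in contrasts) {
    p <- apply(scores, 1L, function(v)
      suppressWarnings(stats::wilcox.test(v[labels == ct[1L]],
                                          v[labels == ct[2L]])$p.value))
    adj[[paste(ct, collapse = "|")]] <- stats::p.adjust(p, method = "BH")
  }
  out <- lapply(lev, function(g) {
    rel <- vapply(contrasts, function(ct) g %in% ct, logical(1))
    pm <- do.call(cbind, adj[rel])
    max_p <- apply(pm, 1L, max)
    specific <- max_p < p_threshold & max.col(grp_mean)[seq_len(nrow(scores))] == match(g, lev)
    hits <- which(specific)
    hits <- hits[order(grp_mean[hits, g], decreasing = TRUE)]
    hits <- utils::head(hits, top_n)
    data.frame(subtype = rep(g, length(hits)),
               pathway = rownames(scores)[hits],
               mean_score = grp_mean[hits, g],
               max_adj_p = max_p[hits],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}
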