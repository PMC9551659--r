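#' Classifier configuration with unclassifiable-sample QC thresholds
#'
#' A sample is left UNCLASSIFIED when its maximum centroid correlation is
#' below `min_correlation` (default 0.15) or when the margin between the
#' best and second-best correlation is below `min_gap` (default 0.06). Both
#' rules are strict "less than" comparisons, so boundary values are
#' assigned.
#'
#' @param min_correlation Minimum acceptable top correlation, in (-1, 1).
#' @param min_gap Minimum top-vs-runner-up margin, >= 0.
#' @param min_feature_overlap_fraction Minimum fraction of centroid features
#'   that must be present in the cohort, in (0, 1] (default 0.8).
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(min_correlation = 0.15, min_gap = 0.06,
                              min_feature_overlap_fraction = 0.8) {
  if (min_correlation <= -1 || min_correlation >= 1)
    stop("min_correlation must lie in (-1, 1)", call. = FALSE)
  if (min_gap < 0) stop("min_gap must be >= 0", call. = FALSE)
  if (min_feature_overlap_fraction <= 0 || min_feature_overlap_fraction > 1)
    stop("min_feature_overlap_fraction must lie in (0, 1]", call. = FALSE)
  structure(list(min_correlation = min_correlation, min_gap = min_gap,
                 min_feature_overlap_fraction = min_feature_overlap_fraction),
            class = "classifier_config")
}

#' Pearson correlations of one sample profile with each subtype centroid
#'
#' Correlations are computed over the features shared by the sample and the
#' centroid table; an error is raised if the overlap covers less than
#' `min_overlap` of the centroid features or if the sample has zero variance
#' over the overlap.
#'
#' @param sample_z Named numeric vector of per-feature z-values.
#' @param centroids Features x subtypes matrix.
#' @param min_overlap Minimum overlap fraction (default 0.8).
#' @return Named numeric vector, one correlation per subtype.
#' @export
correlate_to_centroids <- function(sample_z, centroids, min_overlap = 0.8) {
  common <- intersect(rownames(centroids), names(sample_z))
  frac <- length(common) / nrow(centroids)
  if (frac < min_overlap) {
    missing <- setdiff(rownames(centroids), names(sample_z))
    stop(sprintf("feature overlap %.0f%% below required %.0f%%; missing: %s%s",
                 100 * frac, 100 * min_overlap,
                 paste(head(missing, 10L), collapse = ", "),
                 if (length(missing) > 10L) ", ..." else ""), call. = FALSE)
  }
  if (frac < 1)
    warning(sprintf("%d centroid features absent from the sample were dropped",
                    nrow(centroids) - length(common)))
  x <- sample_z[common]
  if (sd(x) == 0)
    stop("zero-variance sample over the centroid features", call. = FALSE)
  drop(cor(x, centroids[common, , drop = FALSE]))[colnames(centroids)]
}

#' Assign a subtype from centroid correlations with QC rules
#'
#' The label is the argmax subtype when the maximum correlation is at least
#' `min_correlation` and the gap to the second maximum is at least
#' `min_gap`; otherwise `UNCLASSIFIED` with reason `low_max_corr` or
#' `low_gap`. An exact tie for the maximum gives gap 0, hence
#' `UNCLASSIFIED`.
#'
#' @param correlations Named numeric vector (>= 2 subtypes).
#' @param config A [classifier_config()].
#' @return List with `label`, `reason` (one of `assigned`, `low_max_corr`,
#'   `low_gap`) and `correlations`.
#' @export
assign_subtype <- function(correlations, config = classifier_config()) {
  if (length(correlations) < 2L)
    stop("need correlations to at least 2 subtypes", call. = FALSE)
  ord <- order(correlations, decreasing = TRUE)
  top <- correlations[ord[1L]]
  gap <- top - correlations[ord[2L]]
  if (top < config$min_correlation) {
    label <- "UNCLASSIFIED"; reason <- "low_max_corr"
  } else if (gap < config$min_gap) {
    label <- "UNCLASSIFIED"; reason <- "low_gap"
  } else {
    label <- names(correlations)[ord[1L]]; reason <- "assigned"
  }
  list(label = label, reason = reason, correlations = correlations)
}

#' Classify a cohort against subtype centroids
#'
#' Z-scores the cohort per feature (within the cohort being classified),
#' correlates each sample with every centroid over the shared features, and
#' applies the QC assignment rules.
#'
#' @param abundance Cell types x samples matrix (raw scale; z-scored
#'   internally).
#' @param centroids Features x subtypes matrix (mean z-values).
#' @param config A [classifier_config()].
#' @return Object of class `subtype_classification`: a list with
#'   `assignments` (data.frame: `sample_id`, `label`, `reason` and one
#'   correlation column per subtype) and `summary` (per-label counts and
#'   the unclassified fraction).
#' @export
classify_cohort <- function(abundance, centroids, config = classifier_config()) {
  z <- zscore_features(abundance)
  common <- intersect(rownames(centroids), rownames(z))
  frac <- length(common) / nrow(centroids)
  if (frac < config$min_feature_overlap_fraction)
    stop(sprintf("cohort covers only %.0f%% of centroid features (need %.0f%%); missing: %s",
                 100 * frac, 100 * config$min_feature_overlap_fraction,
                 paste(head(setdiff(rownames(centroids), rownames(z)), 10L),
                       collapse = ", ")), call. = FALSE)
  if (frac < 1)
    warning(sprintf("%d centroid features absent from the cohort were dropped",
                    nrow(centroids) - length(common)))
  cz <- z[common, , drop = FALSE]
  cent <- centroids[common, , drop = FALSE]
  res <- lapply(seq_len(ncol(cz)), function(j) {
    r <- correlate_to_centroids(setNames(cz[, j], rownames(cz)), cent,
                                min_overlap = config$min_feature_overlap_fraction)
    assign_subtype(r, config)
  })
  corr_mat <- t(vapply(res, `[[`, numeric(ncol(centroids)), "correlations"))
  colnames(corr_mat) <- paste0("cor_", colnames(centroids))
  assignments <- data.frame(
    sample_id = colnames(abundance),
    label = vapply(res, `[[`, character(1), "label"),
    reason = vapply(res, `[[`, character(1), "reason"),
    corr_mat, stringsAsFactors = FALSE, row.names = NULL)
  counts <- table(factor(assignments$label,
                         levels = c(colnames(centroids), "UNCLASSIFIED")))
  summary <- list(counts = counts,
                  fractions = counts / sum(counts),
                  unclassified_fraction = unname(counts[["UNCLASSIFIED"]] / sum(counts)))
  structure(list(assignments = assignments, summary = summary,
                 config = config), class = "subtype_classification")
}

#' @export
print.subtype_classification <- function(x, ...) {
  cat("Nearest-centroid subtype classification\n")
  print(x$summary$counts)
  cat(sprintf("unclassified fraction: %.2f%%\n",
              100 * x$summary$unclassified_fraction))
  invisible(x)
}
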