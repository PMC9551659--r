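#' @importFrom stats IQR quantile sd cor setNames complete.cases
#' @importFrom utils read.delim write.table head
NULL

# Delimiter by extension: .csv -> comma, everything else tab.
.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.validate_matrix <- function(m, what) {
  if (nrow(m) == 0L || ncol(m) == 0L)
    stop(sprintf("%s: empty matrix", what), call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop(sprintf("%s: duplicate row identifiers: %s", what,
                 paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop(sprintf("%s: duplicate sample identifiers: %s", what,
                 paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", ")),
         call. = FALSE)
  if (!all(is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("%s: non-finite value at row '%s', column '%s'", what,
                 rownames(m)[bad[1L]], colnames(m)[bad[2L]]), call. = FALSE)
  }
  invisible(m)
}

#' Read a gene-by-sample expression matrix
#'
#' Reads a delimited text file (tab for `.tsv`/`.txt`, comma for `.csv`)
#' whose first column holds gene identifiers and whose header row holds
#' sample identifiers. Duplicate gene rows are collapsed by keeping, for each
#' gene, the row with the maximum interquartile range across samples (ties
#' broken by first occurrence) -- the standard convention for multi-probe
#' genes on expression arrays.
#'
#' @param path Path to a TSV/CSV file.
#' @param scale Either `"log2"` or `"linear"`. Linear-scale matrices must be
#'   nonnegative.
#' @return A numeric matrix (genes x samples) with attribute `scale`.
#' @export
read_expression <- function(path, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  df <- read.delim(path, sep = .delim_for(path), header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop(sprintf("malformed expression file '%s': need a gene-id column plus at least one sample column", path),
         call. = FALSE)
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn)) {
        i <- which(is.na(vn))[1L]
        stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                     v[i], ids[i], names(vals)[j]), call. = FALSE)
      }
      vals[[j]] <- vn
    } else if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop(sprintf("missing value at row '%s', column '%s'",
                   ids[i], names(vals)[j]), call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m <- collapse_duplicate_genes(m)
  .validate_matrix(m, "expression matrix")
  if (scale == "linear" && any(m < 0))
    stop("linear-scale expression must be nonnegative", call. = FALSE)
  attr(m, "scale") <- scale
  m
}

#' Collapse duplicated gene rows by maximum interquartile range
#'
#' For each duplicated gene identifier, keeps the row with the largest IQR
#' across samples; ties keep the first occurrence.
#'
#' @param m Numeric matrix with gene identifiers as row names.
#' @return Matrix with unique row names, original relative order preserved.
#' @export
collapse_duplicate_genes <- function(m) {
  if (!anyDuplicated(rownames(m))) return(m)
  iqr <- apply(m, 1L, IQR)
  # visit rows by decreasing IQR (ties by original index), keep first per id,
  # then restore original row order
  ord <- order(-iqr, seq_len(nrow(m)))
  sel <- sort(ord[!duplicated(rownames(m)[ord])])
  m[sel, , drop = FALSE]
}

#' Write an expression or abundance matrix to TSV
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path; first column is named by `id_col`.
#' @param id_col Name for the identifier column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cell-type-by-sample abundance matrix
#'
#' Same on-disk layout as [read_expression()] but rows are cell populations
#' (e.g. the 64 xCell populations) rather than genes. Values must be finite.
#'
#' @param path Path to a TSV/CSV file.
#' @return Numeric matrix (cell types x samples).
#' @export
read_abundance <- function(path) {
  m <- read_expression(path, scale = "log2")  # reuse parser; no sign constraint
  attr(m, "scale") <- NULL
  .validate_matrix(m, "abundance matrix")
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then gene identifiers. Gene order is preserved;
#' duplicate genes within a set are removed.
#'
#' @param path Path to a `.gmt` file.
#' @return A named list of character vectors with attribute `description`
#'   (named character vector of per-set descriptions).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT parse error at line %d: expected at least 3 tab-separated fields, got %d",
                   i, length(f)), call. = FALSE)
    nm <- f[1L]
    if (nm %in% names(sets))
      stop(sprintf("GMT parse error at line %d: duplicate set name '%s'", i, nm),
           call. = FALSE)
    genes <- unique(f[-c(1L, 2L)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L)
      stop(sprintf("GMT parse error at line %d: set '%s' has no genes", i, nm),
           call. = FALSE)
    sets[[nm]] <- genes
    desc[nm] <- f[2L]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets Named list of character vectors (as returned by [read_gmt()]).
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else ""
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Filter gene sets by size after intersection with a gene universe
#'
#' Each set is intersected with `universe`; sets whose post-intersection size
#' falls outside `[min_size, max_size]` are dropped. The conventional filter
#' for MSigDB-style collections keeps sets of 10 to 500 genes.
#'
#' @param sets Named list of character vectors.
#' @param universe Character vector of gene identifiers present in the data.
#' @param min_size,max_size Inclusive size bounds (defaults 10 and 500).
#' @return Filtered collection; the surviving sets keep their full gene lists.
#' @export
filter_gene_sets <- function(sets, universe, min_size = 10L, max_size = 500L) {
  stopifnot(min_size >= 1L, max_size >= min_size)
  sz <- vapply(sets, function(g) sum(g %in% universe), integer(1))
  keep <- sz >= min_size & sz <= max_size
  out <- sets[keep]
  desc <- attr(sets, "description")
  if (!is.null(desc)) attr(out, "description") <- desc[names(out)]
  out
}

#' Convert raw RNA-seq counts to FPKM
#'
#' Genes with fewer than `min_count` counts in at least `min_fraction` of
#' samples are removed first, then
#' \deqn{FPKM_{gs} = counts_{gs} \times 10^9 / (length_g \times libsize_s)}
#' where `libsize_s` is the post-filter column sum.
#'
#' @param counts Nonnegative integer matrix (genes x samples).
#' @param lengths Named numeric vector of exonic lengths in base pairs.
#' @param min_count,min_fraction Expression filter: a gene is kept if it has
#'   at least `min_count` counts in at least `min_fraction` of samples
#'   (defaults 10 and 0.5).
#' @return FPKM matrix (linear scale) for the surviving genes.
#' @export
fpkm_from_counts <- function(counts, lengths, min_count = 10, min_fraction = 0.5) {
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  missing_len <- setdiff(rownames(counts), names(lengths))
  if (length(missing_len))
    stop("missing gene lengths for: ", paste(head(missing_len, 10L), collapse = ", "),
         if (length(missing_len) > 10L) ", ..." else "", call. = FALSE)
  len <- lengths[rownames(counts)]
  if (any(len <= 0)) stop("gene lengths must be positive", call. = FALSE)
  keep <- rowMeans(counts >= min_count) >= min_fraction
  counts <- counts[keep, , drop = FALSE]
  len <- len[keep]
  if (nrow(counts) == 0L)
    stop("no genes survive the expression filter", call. = FALSE)
  libsize <- colSums(counts)
  if (any(libsize == 0))
    stop("all-zero library: ", paste(colnames(counts)[libsize == 0], collapse = ", "),
         call. = FALSE)
  fpkm <- sweep(counts / len, 2L, libsize, "/") * 1e9
  attr(fpkm, "scale") <- "linear"
  fpkm
}

#' Convert a linear-scale expression matrix to log2
#'
#' Applies `log2(x + 1)`.
#'
#' @param m Nonnegative numeric matrix.
#' @return log2-scale matrix.
#' @export
to_log2 <- function(m) {
  if (any(m < 0)) stop("linear-scale input must be nonnegative", call. = FALSE)
  out <- log2(m + 1)
  attr(out, "scale") <- "log2"
  out
}

#' Read a clinical table
#'
#' A delimited file with a `sample_id` column and any of `response`
#' (0/1 or two-level factor), `time` (nonnegative, e.g. months) and `event`
#' (0/1); remaining columns are treated as covariates.
#'
#' @param path Path to a TSV/CSV file.
#' @return A `data.frame` with one row per sample.
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, sep = .delim_for(path), header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("clinical table must have a 'sample_id' column", call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in clinical table", call. = FALSE)
  validate_clinical(df)
  df
}

validate_clinical <- function(df) {
  if ("event" %in% names(df)) {
    if (!"time" %in% names(df))
      stop("clinical table has 'event' but no 'time' column", call. = FALSE)
    if (!all(df$event %in% c(0, 1)))
      stop("'event' must be 0/1", call. = FALSE)
  }
  if ("time" %in% names(df) && any(df$time < 0, na.rm = TRUE))
    stop("'time' must be nonnegative", call. = FALSE)
  invisible(df)
}

#' Read a centroid table
#'
#' Features-by-subtype matrix of mean z-values, one row per feature and one
#' column per subtype, in the same on-disk layout as [read_expression()].
#'
#' @param path Path to a TSV/CSV file.
#' @return Numeric matrix (features x subtypes).
#' @export
read_centroids <- function(path) {
  m <- read_abundance(path)
  if (ncol(m) < 2L) stop("centroid table needs at least 2 subtypes", call. = FALSE)
  m
}
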