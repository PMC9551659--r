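#' Build a contingency table from response counts
#'
#' Convenience constructor: `responders` and `totals` per group give a
#' groups x 2 table with columns `responder`, `non_responder`.
#'
#' @param responders,totals Integer vectors of equal length.
#' @param group_names Optional row labels (default `C1..`).
#' @return Integer matrix.
#' @export
response_table <- function(responders, totals, group_names = NULL) {
  stopifnot(length(responders) == length(totals), all(responders <= totals),
            all(responders >= 0))
  if (is.null(group_names)) group_names <- paste0("C", seq_along(totals))
  m <- cbind(responder = responders, non_responder = totals - responders)
  rownames(m) <- group_names
  storage.mode(m) <- "integer"
  m
}

.check_table <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("contingency table must hold nonnegative integers", call. = FALSE)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("contingency table needs at least 2 rows and 2 columns", call. = FALSE)
  if (sum(tab) == 0) stop("empty contingency table", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has a zero row or column margin", call. = FALSE)
  storage.mode(tab) <- "double"
  tab
}

#' Pearson chi-square test of independence
#'
#' The classical `sum((O - E)^2 / E)` statistic with margins-based expected
#' counts, `df = (r - 1)(c - 1)` and an upper-tail chi-square p-value. No
#' continuity correction is applied, also for 2x2 tables, keeping all table
#' shapes on the same statistic.
#'
#' @param tab r x c matrix of nonnegative integer counts with positive
#'   margins.
#' @return An `htest`-like list with `statistic`, `df`, `p.value`, `method`.
#' @export
chisq_test <- function(tab) {
  tab <- .check_table(tab)
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(statistic = unname(res$statistic), df = unname(res$parameter),
                 p.value = res$p.value, method = "Pearson chi-square (no continuity correction)",
                 expected = res$expected, table = tab),
            class = "tme_test")
}

#' @export
print.tme_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.null(x$statistic) && !is.na(x$statistic))
    cat(sprintf("statistic = %.4g%s, ", x$statistic,
                if (!is.null(x$df)) sprintf(", df = %g", x$df) else ""))
  cat(sprintf("p = %.4g\n", x$p.value))
  if (!is.null(x$mc_se)) cat(sprintf("(Monte Carlo SE = %.2g)\n", x$mc_se))
  invisible(x)
}

# log multivariate hypergeometric probability of a margin-fixed table
.log_table_prob <- function(tab, lfac_row, lfac_col, lfac_n) {
  lfac_row + lfac_col - lfac_n - sum(lgamma(tab + 1))
}

# Enumerate all r x c tables with the given margins, calling fn(tab) on each.
# Returns TRUE, or FALSE if more than `cap` tables were visited.
.enumerate_tables <- function(row_sums, col_sums, cap, fn) {
  r <- length(row_sums); cc <- length(col_sums)
  count <- 0L
  tab <- matrix(0, r, cc)
  rec <- function(i, rem_col) {
    if (count > cap) return(FALSE)
    if (i == r) {
      if (any(rem_col < 0)) return(TRUE)
      tab[r, ] <<- rem_col
      count <<- count + 1L
      if (count > cap) return(FALSE)
      fn(tab)
      return(TRUE)
    }
    fill_row <- function(j, rem_row, rc) {
      if (count > cap) return(FALSE)
      if (j == cc) {
        if (rem_row > rc[cc]) return(TRUE)
        tab[i, cc] <<- rem_row
        rc[cc] <- rc[cc] - rem_row
        return(rec(i + 1L, rc))
      }
      for (v in 0:min(rem_row, rc[j])) {
        tab[i, j] <<- v
        rc2 <- rc; rc2[j] <- rc2[j] - v
        if (!fill_row(j + 1L, rem_row - v, rc2)) return(FALSE)
      }
      TRUE
    }
    fill_row(1L, row_sums[i], rem_col)
  }
  rec(1L, col_sums)
}

#' Exact Freeman-Halton test for r x c contingency tables
#'
#' The probability-ordering generalization of Fisher's exact test: under
#' fixed margins, the two-sided p-value is the total multivariate
#' hypergeometric probability of every table at most as probable as the
#' observed one (a relative tolerance of `1e-7` guards floating-point ties).
#' All margin-consistent tables are enumerated when their number does not
#' exceed `max_enumeration`; otherwise a Monte Carlo estimate over
#' margin-fixed random tables (Patefield's algorithm) is returned together
#' with its standard error.
#'
#' @param tab r x c matrix of nonnegative integer counts.
#' @param max_enumeration Enumeration cap before the Monte Carlo fallback
#'   engages (default 2e5).
#' @param mc_iterations Monte Carlo sample size (default 1e5).
#' @param seed Seed for the Monte Carlo fallback.
#' @return A `tme_test` list with `p.value`, `method`, and for the Monte
#'   Carlo path `mc_se`; for the enumeration path `n_tables` and
#'   `total_prob` (the probability mass over all enumerated tables, which
#'   must be 1 up to rounding).
#' @export
fisher_exact_rxc <- function(tab, max_enumeration = 2e5, mc_iterations = 1e5,
                             seed = 1L) {
  tab <- .check_table(tab)
  row_sums <- rowSums(tab); col_sums <- colSums(tab); n <- sum(tab)
  lfac_row <- sum(lgamma(row_sums + 1))
  lfac_col <- sum(lgamma(col_sums + 1))
  lfac_n <- lgamma(n + 1)
  lp_obs <- .log_table_prob(tab, lfac_row, lfac_col, lfac_n)
  cutoff <- lp_obs + log1p(1e-7)
  p_sum <- 0; total <- 0; n_tables <- 0L
  done <- .enumerate_tables(row_sums, col_sums, max_enumeration, function(t2) {
    lp <- .log_table_prob(t2, lfac_row, lfac_col, lfac_n)
    pr <- exp(lp)
    total <<- total + pr
    n_tables <<- n_tables + 1L
    if (lp <= cutoff) p_sum <<- p_sum + pr
  })
  if (done) {
    return(structure(list(statistic = NA_real_, df = NULL,
                          p.value = min(1, p_sum),
                          method = "Freeman-Halton exact test (full enumeration)",
                          n_tables = n_tables, total_prob = total, table = tab),
                     class = "tme_test"))
  }
  set.seed(seed)
  draws <- stats::r2dtable(mc_iterations, row_sums, col_sums)
  hits <- vapply(draws, function(t2)
    .log_table_prob(t2, lfac_row, lfac_col, lfac_n) <= cutoff, logical(1))
  # add-one estimator keeps p > 0
  p_hat <- (sum(hits) + 1) / (mc_iterations + 1)
  se <- sqrt(p_hat * (1 - p_hat) / mc_iterations)
  structure(list(statistic = NA_real_, df = NULL, p.value = p_hat,
                 method = "Freeman-Halton exact test (Monte Carlo)",
                 mc_se = se, table = tab),
            class = "tme_test")
}

#' Kruskal-Wallis rank-sum test with optional post-hoc comparisons
#'
#' H statistic with tie correction and the chi-square approximation on
#' `groups - 1` degrees of freedom; optionally followed by all pairwise
#' two-sided rank-sum tests with BH adjustment.
#'
#' @param groups List of numeric vectors (>= 2 non-empty groups).
#' @param posthoc Run pairwise rank-sum comparisons (default FALSE).
#' @return A `tme_test` list; with `posthoc = TRUE` also `pairwise`, a
#'   data.frame of BH-adjusted pairwise p-values.
#' @export
kruskal_wallis <- function(groups, posthoc = FALSE) {
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) == 0L)) stop("empty group", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) < 2L)
    stop("all values tied; ranks carry no information", call. = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  res <- stats::kruskal.test(x, g)
  out <- structure(list(statistic = unname(res$statistic),
                        df = unname(res$parameter), p.value = res$p.value,
                        method = "Kruskal-Wallis rank-sum test"),
                   class = "tme_test")
  if (posthoc) {
    nm <- names(groups)
    if (is.null(nm)) nm <- paste0("g", seq_along(groups))
    pw <- stats::pairwise.wilcox.test(x, factor(rep(nm, lengths(groups)), levels = nm),
                                      p.adjust.method = "BH", exact = FALSE)
    idx <- which(!is.na(pw$p.value), arr.ind = TRUE)
    out$pairwise <- data.frame(group1 = rownames(pw$p.value)[idx[, 1L]],
                               group2 = colnames(pw$p.value)[idx[, 2L]],
                               p_adj = pw$p.value[idx],
                               stringsAsFactors = FALSE)
  }
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the input and applies the BH step-up procedure (monotone,
#' capped at 1).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method Adjustment procedure: `"BH"` (default), `"holm"` or
#'   `"bonferroni"`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p, method = c("BH", "holm", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = method)
}
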