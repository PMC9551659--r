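#' Kaplan-Meier product-limit survival curve
#'
#' The product-limit estimator over the distinct event times, with the
#' standard convention that subjects censored at an event time are still at
#' risk for that event (censoring happens after events at equal times).
#' With no censoring the estimator equals one minus the empirical CDF.
#'
#' @param time Nonnegative follow-up times.
#' @param event 0/1 event indicators (1 = event).
#' @return Object of class `km_curve`: data.frame with `time` (distinct
#'   event times, sorted), `n_risk`, `n_event`, `survival` (non-increasing,
#'   starting from S(0) = 1).
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) == length(event))
  if (any(time < 0)) stop("negative follow-up time", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  ev_times <- sort(unique(time[event == 1]))
  if (length(ev_times) == 0L) {
    out <- data.frame(time = numeric(0), n_risk = numeric(0),
                      n_event = numeric(0), survival = numeric(0))
    class(out) <- c("km_curve", "data.frame")
    return(out)
  }
  n_risk <- vapply(ev_times, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ev_times, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = ev_times, n_risk = n_risk, n_event = n_event,
                    survival = surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' K-group log-rank test
#'
#' The standard (unweighted) log-rank chi-square: at each distinct event
#' time the observed events per group are compared with their
#' hypergeometric expectation given the risk sets; the quadratic form of
#' the summed observed-minus-expected vector against the summed covariance
#' (dropping the last group) is referred to a chi-square on `groups - 1`
#' degrees of freedom.
#'
#' @param time Nonnegative follow-up times.
#' @param event 0/1 event indicators.
#' @param group Group label per subject (>= 2 non-empty groups).
#' @return A `tme_test` list with `statistic`, `df`, `p.value`, and
#'   `observed` / `expected` per group.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (any(time < 0)) stop("negative follow-up time", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  group <- factor(group)
  group <- droplevels(group)
  g <- nlevels(group)
  if (g < 2L) stop("need at least 2 groups", call. = FALSE)
  if (sum(event) == 0) stop("no events observed", call. = FALSE)
  lev <- levels(group)
  ev_times <- sort(unique(time[event == 1]))
  O <- setNames(numeric(g), lev)
  E <- setNames(numeric(g), lev)
  V <- matrix(0, g - 1L, g - 1L)
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(event == 1 & time == t)
    n_g <- vapply(lev, function(l) sum(at_risk & group == l), numeric(1))
    d_g <- vapply(lev, function(l) sum(event == 1 & time == t & group == l),
                  numeric(1))
    e_g <- d * n_g / n
    O <- O + d_g
    E <- E + e_g
    if (n > 1) {
      p <- n_g / n
      fac <- d * (n - d) / (n - 1)
      v <- fac * (diag(p[-g], g - 1L) - outer(p[-g], p[-g]))
      V <- V + v
    }
  }
  u <- (O - E)[-g]
  Vi <- tryCatch(solve(V), error = function(e) MASS_ginv(V))
  stat <- drop(t(u) %*% Vi %*% u)
  structure(list(statistic = stat, df = g - 1L,
                 p.value = stats::pchisq(stat, g - 1L, lower.tail = FALSE),
                 method = "log-rank test", observed = O, expected = E),
            class = "tme_test")
}

# Moore-Penrose pseudoinverse via SVD for (near-)singular covariance.
MASS_ginv <- function(m, tol = sqrt(.Machine$double.eps)) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1L]
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Cox proportional-hazards regression (delegated)
#'
#' Thin wrapper over [survival::coxph()], returning the fitted model plus a
#' tidy table of hazard ratios with 95% confidence intervals.
#'
#' @param clinical Data frame with `time`, `event` and the model covariates.
#' @param formula Right-hand side of the model, e.g. `~ subtype + age`.
#' @return List with `fit` (the `coxph` object) and `hazard_ratios`
#'   (data.frame: `term`, `hr`, `lower95`, `upper95`, `p`).
#' @export
cox_model <- function(clinical, formula = ~ subtype) {
  validate_clinical(clinical)
  f <- stats::as.formula(paste("survival::Surv(time, event)",
                               paste(deparse(formula), collapse = ""), sep = " "))
  fit <- survival::coxph(f, data = clinical)
  s <- summary(fit)
  hr <- data.frame(term = rownames(s$coefficients),
                   hr = s$coefficients[, "exp(coef)"],
                   lower95 = s$conf.int[, "lower .95"],
                   upper95 = s$conf.int[, "upper .95"],
                   p = s$coefficients[, "Pr(>|z|)"],
                   stringsAsFactors = FALSE, row.names = NULL)
  list(fit = fit, hazard_ratios = hr)
}

#' Per-subtype response rates and the matching association test
#'
#' Builds the subtype x response contingency table from classified samples
#' (UNCLASSIFIED samples are excluded), computes per-subtype response
#' rates, and tests association with the chi-square test -- switching to
#' the exact Freeman-Halton test whenever any expected cell count is below
#' 5, the conventional validity rule.
#'
#' @param assignments Either a [classify_cohort()] result or a data.frame
#'   with `sample_id` and `label`.
#' @param clinical Data frame with `sample_id` and binary `response`.
#' @return List with `table` (subtypes x response), `rates` (per-subtype
#'   response rate), `test` (a `tme_test`), `n_excluded` (unclassified or
#'   unmatched samples).
#' @export
response_rate_summary <- function(assignments, clinical) {
  if (inherits(assignments, "subtype_classification"))
    assignments <- assignments$assignments
  stopifnot(all(c("sample_id", "label") %in% names(assignments)),
            all(c("sample_id", "response") %in% names(clinical)))
  df <- merge(assignments[, c("sample_id", "label")],
              clinical[, c("sample_id", "response")], by = "sample_id")
  if (any(is.na(df$response))) df <- df[!is.na(df$response), ]
  n_excl <- sum(df$label == "UNCLASSIFIED") +
    (nrow(assignments) - nrow(df))
  df <- df[df$label != "UNCLASSIFIED", ]
  if (nrow(df) == 0L) stop("no classified samples with response data", call. = FALSE)
  if (!all(df$response %in% c(0, 1)))
    stop("response must be binary 0/1", call. = FALSE)
  labs <- sort(unique(df$label))
  tab <- t(vapply(labs, function(l)
    c(responder = sum(df$response[df$label == l] == 1),
      non_responder = sum(df$response[df$label == l] == 0)), numeric(2)))
  rates <- tab[, "responder"] / rowSums(tab)
  tab <- .check_table(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  test <- if (any(expected < 5)) fisher_exact_rxc(tab) else chisq_test(tab)
  list(table = tab, rates = rates, test = test, n_excluded = n_excl)
}

#' Per-group Kaplan-Meier curves and log-rank comparison
#'
#' @param clinical Data frame with `time`, `event` and a grouping column.
#' @param group_col Name of the grouping column (default `"subtype"`);
#'   samples labelled `UNCLASSIFIED` are excluded.
#' @return List with `curves` (named list of [km_curve()] per group) and
#'   `logrank` (the k-group [logrank_test()]).
#' @export
survival_by_group <- function(clinical, group_col = "subtype") {
  validate_clinical(clinical)
  stopifnot(all(c("time", "event", group_col) %in% names(clinical)))
  df <- clinical[clinical[[group_col]] != "UNCLASSIFIED", ]
  g <- factor(df[[group_col]])
  curves <- lapply(levels(g), function(l)
    km_curve(df$time[g == l], df$event[g == l]))
  names(curves) <- levels(g)
  list(curves = curves, logrank = logrank_test(df$time, df$event, g))
}
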