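#' Specification of a synthetic cohort
#'
#' Bundles the parameters of the generative model used throughout the test
#' pipeline: four latent immune subtypes with distinct mean abundance
#' profiles over a panel of cell types, subtype-dependent objective-response
#' probabilities and recurrence hazards. Defaults mirror the study setting
#' this generator emulates: 4 subtypes over 64 cell populations, per-subtype
#' response rates 21/88, 7/64, 20/60 and 9/39, and a markedly elevated
#' recurrence hazard for the stromal-high subtype (C2 vs C1 hazard ratio
#' 3.239).
#'
#' @param n_samples Cohort size (>= 8).
#' @param subtype_proportions Four nonnegative numbers summing to 1.
#' @param separation Distance between subtype mean profiles, in within-
#'   subtype SD units, applied on each subtype's own block of cell types.
#' @param n_cell_types Number of cell populations (default 64).
#' @param response_rates Per-subtype probability of objective response.
#' @param hazard_ratios Per-subtype hazard ratio relative to C1 (first = 1).
#' @param baseline_hazard Event hazard of C1, per month.
#' @param censor_rate Target fraction of censored subjects in `[0, 1)`.
#' @param seed Integer seed; every generator is a pure function of
#'   (spec, seed).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 200L,
                        subtype_proportions = c(0.35, 0.25, 0.24, 0.16),
                        separation = 4,
                        n_cell_types = 64L,
                        response_rates = c(21/88, 7/64, 20/60, 9/39),
                        hazard_ratios = c(1, 3.239, 0.921, 1.660),
                        baseline_hazard = 0.02,
                        censor_rate = 0.2,
                        seed = 1L) {
  stopifnot(length(subtype_proportions) == 4L,
            length(response_rates) == 4L,
            length(hazard_ratios) == 4L)
  if (any(subtype_proportions < 0) ||
      abs(sum(subtype_proportions) - 1) > 1e-9)
    stop("subtype_proportions must be nonnegative and sum to 1", call. = FALSE)
  if (any(response_rates < 0 | response_rates > 1))
    stop("response_rates must lie in [0, 1]", call. = FALSE)
  if (any(hazard_ratios <= 0) || baseline_hazard <= 0)
    stop("hazards must be positive", call. = FALSE)
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must lie in [0, 1)", call. = FALSE)
  if (separation < 0) stop("separation must be nonnegative", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 subtype_proportions = subtype_proportions,
                 separation = separation,
                 n_cell_types = as.integer(n_cell_types),
                 response_rates = response_rates,
                 hazard_ratios = hazard_ratios,
                 baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

SUBTYPES <- c("C1", "C2", "C3", "C4")

# Deterministic subtype counts by largest remainder, then a seeded shuffle.
.subtype_labels <- function(n, props) {
  base <- floor(props * n)
  rem <- props * n - base
  short <- n - sum(base)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1L
  }
  if (any(props > 0 & base == 0L))
    stop("a subtype with positive proportion has 0 expected members; increase n_samples",
         call. = FALSE)
  factor(sample(rep(SUBTYPES, times = base)), levels = SUBTYPES)
}

# Mean profile of each subtype: its own contiguous block of cell types is
# elevated by `separation` (unit within-subtype SD), the rest sits at 0.
.subtype_means <- function(n_cell_types, separation) {
  blocks <- split(seq_len(n_cell_types),
                  cut(seq_len(n_cell_types), 4L, labels = FALSE))
  mu <- matrix(0, n_cell_types, 4L, dimnames = list(
    sprintf("celltype_%02d", seq_len(n_cell_types)), SUBTYPES))
  for (k in 1:4) mu[blocks[[k]], k] <- separation
  mu
}

#' Generate a synthetic cell-type abundance cohort
#'
#' Each sample is drawn from its subtype's multivariate Gaussian profile:
#' subtype mean vectors differ by `spec$separation` SD units on a
#' subtype-specific block of cell types; within-subtype noise is independent
#' unit-variance Gaussian. Abundances are generated directly on the z-like
#' scale on which every downstream consumer operates.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `abundance` (cell types x samples matrix) and
#'   `labels` (factor of true subtypes, named by sample).
#' @export
generate_abundance_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_samples < 8L) stop("need n_samples >= 8", call. = FALSE)
  set.seed(spec$seed)
  labels <- .subtype_labels(spec$n_samples, spec$subtype_proportions)
  mu <- .subtype_means(spec$n_cell_types, spec$separation)
  noise <- matrix(rnorm(spec$n_cell_types * spec$n_samples),
                  spec$n_cell_types, spec$n_samples)
  m <- mu[, as.integer(labels), drop = FALSE] + noise
  ids <- sprintf("S%04d", seq_len(spec$n_samples))
  dimnames(m) <- list(rownames(mu), ids)
  names(labels) <- ids
  list(abundance = m, labels = labels)
}

#' Default signature-to-subtype elevation map for expression cohorts
#'
#' TLS and Tfr-up genes are elevated in the immune-high subtype C3; FTBRS and
#' Treg-up genes in the stromal-high subtype C2, matching the biology the
#' cohorts emulate (C3 immune/TLS-high, C2 fibroblast/TGF-beta-high).
#' @export
default_signature_subtypes <- function() {
  c(TLS = "C3", FTBRS = "C2", "Tfr-up" = "C3", "Treg-up" = "C2")
}

#' Generate a synthetic expression cohort with signature-gene blocks
#'
#' Filler genes are Gaussian noise around a common baseline; the genes of
#' each named signature are shifted up by `spec$separation` in the subtype
#' designated "high" for that signature.
#'
#' @param spec A [cohort_spec()].
#' @param signatures Named list of gene vectors; must contain sets named
#'   `TLS`, `FTBRS`, `Tfr-up` and `Treg-up`.
#' @param high_subtype Named character vector mapping signature names to the
#'   subtype in which their genes are elevated
#'   (default [default_signature_subtypes()]).
#' @param n_filler Number of noise genes appended (default 200).
#' @param baseline Mean log2 expression of unshifted genes (default 3).
#' @return A list with `expression` (genes x samples, log2 scale) and
#'   `labels`.
#' @export
generate_expression_cohort <- function(spec, signatures,
                                       high_subtype = default_signature_subtypes(),
                                       n_filler = 200L, baseline = 3) {
  stopifnot(inherits(spec, "cohort_spec"))
  required <- c("TLS", "FTBRS", "Tfr-up", "Treg-up")
  missing <- setdiff(required, names(signatures))
  if (length(missing))
    stop("signatures missing required sets: ", paste(missing, collapse = ", "),
         call. = FALSE)
  set.seed(spec$seed + 1L)
  labels <- .subtype_labels(spec$n_samples, spec$subtype_proportions)
  sig_genes <- unique(unlist(signatures[required], use.names = FALSE))
  genes <- c(sig_genes, sprintf("FILLER_%04d", seq_len(n_filler)))
  n <- spec$n_samples
  m <- matrix(rnorm(length(genes) * n, mean = baseline), length(genes), n,
              dimnames = list(genes, sprintf("S%04d", seq_len(n))))
  for (sig in required) {
    st <- high_subtype[[sig]]
    cols <- which(labels == st)
    rows <- match(signatures[[sig]], genes)
    m[rows, cols] <- m[rows, cols] + spec$separation
  }
  names(labels) <- colnames(m)
  attr(m, "scale") <- "log2"
  list(expression = m, labels = labels)
}

#' Generate synthetic clinical endpoints for labelled samples
#'
#' Response is Bernoulli with the subtype's response rate; survival times are
#' exponential with hazard `baseline_hazard * hazard_ratio[subtype]`;
#' censoring is administrative-uniform on `(0, tau)` with `tau` solved so the
#' expected censored fraction matches `spec$censor_rate`.
#'
#' @param labels Factor or character vector of subtypes in `C1..C4`, named by
#'   sample id.
#' @param spec A [cohort_spec()].
#' @return A `data.frame` with columns `sample_id`, `subtype`, `response`,
#'   `time` (months) and `event`.
#' @export
generate_clinical <- function(labels, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  labels <- as.character(labels)
  if (!all(labels %in% SUBTYPES))
    stop("unknown subtype label: ",
         paste(unique(setdiff(labels, SUBTYPES)), collapse = ", "), call. = FALSE)
  set.seed(spec$seed + 2L)
  idx <- match(labels, SUBTYPES)
  n <- length(labels)
  response <- rbinom(n, 1L, spec$response_rates[idx])
  lambda <- spec$baseline_hazard * spec$hazard_ratios[idx]
  t_event <- rexp(n, rate = lambda)
  if (spec$censor_rate > 0) {
    lam_bar <- mean(lambda)
    # with C ~ U(0, tau) and T ~ Exp(lam):
    # P(censored) = P(C < T) = (1 - exp(-lam*tau)) / (lam*tau), decreasing in tau
    g <- function(tau) (1 - exp(-lam_bar * tau)) / (lam_bar * tau) - spec$censor_rate
    tau <- uniroot(g, c(1e-8, 1e8), tol = 1e-10)$root
    t_cens <- runif(n, 0, tau)
    event <- as.integer(t_event <= t_cens)
    time <- pmin(t_event, t_cens)
  } else {
    event <- rep(1L, n)
    time <- t_event
  }
  ids <- names(labels)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(n))
  data.frame(sample_id = ids, subtype = labels,
             response = response, time = time, event = event,
             stringsAsFactors = FALSE)
}

#' Pre/post treatment subtype transition counts
#'
#' The default 4x4 matrix of matched pre-to-post subtype transitions used by
#' [generate_paired_transitions()] (20 pairs; pre totals 9, 3, 3, 5; post
#' totals 4, 9, 4, 3).
#' @return Integer matrix with rownames = pre subtype, colnames = post.
#' @export
default_transition_counts <- function() {
  m <- matrix(c(3L, 2L, 3L, 1L,
                1L, 2L, 0L, 0L,
                0L, 3L, 0L, 0L,
                0L, 2L, 1L, 2L),
              4L, 4L, byrow = TRUE,
              dimnames = list(pre = SUBTYPES, post = SUBTYPES))
  m
}

#' Generate paired pre/post abundance cohorts realizing exact transitions
#'
#' For each cell (i, j) of `counts`, generates `counts[i, j]` sample pairs
#' whose pre-treatment profile is drawn from subtype i and post-treatment
#' profile from subtype j, so the realized transition table equals `counts`
#' exactly (not just in expectation).
#'
#' @param counts 4x4 nonnegative integer matrix of pre -> post transitions.
#' @param spec A [cohort_spec()] supplying `separation`, `n_cell_types` and
#'   `seed`.
#' @return A list with `pre` and `post` abundance matrices, a `pairs`
#'   data.frame (pair id, pre/post sample ids and true labels).
#' @export
generate_paired_transitions <- function(counts = default_transition_counts(),
                                        spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("transition counts must be nonnegative integers", call. = FALSE)
  if (nrow(counts) != 4L || ncol(counts) != 4L)
    stop("transition counts must be 4x4", call. = FALSE)
  n <- sum(counts)
  if (n == 0L) stop("empty transition matrix", call. = FALSE)
  pre_lab <- rep(rep(SUBTYPES, times = rowSums(counts)))
  post_lab <- unlist(lapply(1:4, function(i) rep(SUBTYPES, times = counts[i, ])),
                     use.names = FALSE)
  set.seed(spec$seed + 3L)
  mu <- .subtype_means(spec$n_cell_types, spec$separation)
  draw <- function(lab, tag) {
    m <- mu[, match(lab, SUBTYPES), drop = FALSE] +
      matrix(rnorm(spec$n_cell_types * n), spec$n_cell_types, n)
    colnames(m) <- sprintf("P%03d_%s", seq_len(n), tag)
    m
  }
  pre <- draw(pre_lab, "pre")
  post <- draw(post_lab, "post")
  pairs <- data.frame(pair_id = sprintf("P%03d", seq_len(n)),
                      pre_id = colnames(pre), post_id = colnames(post),
                      pre_label = pre_lab, post_label = post_lab,
                      stringsAsFactors = FALSE)
  list(pre = pre, post = post, pairs = pairs)
}

#' Synthetic gene signatures for the scoring pipeline
#'
#' A small GMT-style collection with a 7-gene TLS set (the canonical marker
#' panel CCL19, CCL21, CXCL13, CCR7, CXCR5, SELL, LAMP3), a 19-gene
#' synthetic pan-fibroblast TGF-beta response set, and 15-gene synthetic
#' Tfr-up / Treg-up panels. Only the TLS list corresponds to published
#' marker genes; the others are synthetic placeholders for testing.
#' @return Named list of character vectors.
#' @export
synthetic_signatures <- function() {
  sets <- list(
    TLS = c("CCL19", "CCL21", "CXCL13", "CCR7", "CXCR5", "SELL", "LAMP3"),
    FTBRS = sprintf("FTBRSG_%02d", 1:19),
    `Tfr-up` = sprintf("TFRG_%02d", 1:15),
    `Treg-up` = sprintf("TREGG_%02d", 1:15))
  attr(sets, "description") <- c(
    TLS = "tertiary lymphoid structure markers",
    FTBRS = "synthetic pan-fibroblast TGF-beta response genes",
    `Tfr-up` = "synthetic follicular-regulatory-T-cell genes",
    `Treg-up` = "synthetic regulatory-T-cell genes")
  sets
}
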