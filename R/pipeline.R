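#' Validate a pipeline configuration
#'
#' Reads a YAML/JSON file (or accepts a list) describing an end-to-end run
#' and validates it structurally and semantically, reporting all problems at
#' once. Recognized sections: `seed` (integer), `output_dir`, `stages`
#' (subset of simulate, cluster, classify, score, stats, survival),
#' `cohort` (arguments of [cohort_spec()]) and `classifier` (arguments of
#' [classifier_config()]) and `cluster` (`k`, `iterations`,
#' `subsample_fraction`).
#'
#' @param config Path to a YAML/JSON file, or a list.
#' @return A validated config list of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a file path", call. = FALSE)
  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)

  all_stages <- c("simulate", "cluster", "classify", "score", "stats", "survival")
  config$stages <- config$stages %||% all_stages
  bad <- setdiff(config$stages, all_stages)
  if (length(bad)) note(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  config$seed <- config$seed %||% 1L
  if (!is.numeric(config$seed) || config$seed != round(config$seed))
    note("seed must be an integer")
  config$output_dir <- config$output_dir %||% "tmesubtype_out"

  spec <- tryCatch(do.call(cohort_spec, c(config$cohort %||% list(),
                                          list(seed = as.integer(config$seed)))),
                   error = function(e) { note(paste0("cohort: ", conditionMessage(e))); NULL })
  cls <- tryCatch(do.call(classifier_config, config$classifier %||% list()),
                  error = function(e) { note(paste0("classifier: ", conditionMessage(e))); NULL })
  cl <- config$cluster %||% list()
  cl$k <- cl$k %||% 4L
  cl$iterations <- cl$iterations %||% 100L
  cl$subsample_fraction <- cl$subsample_fraction %||% 0.8
  if (cl$k < 2) note("cluster: k must be >= 2")
  if (cl$subsample_fraction <= 0 || cl$subsample_fraction > 1)
    note("cluster: subsample_fraction must lie in (0, 1]")

  if (length(errors))
    stop("invalid pipeline config:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  structure(list(seed = as.integer(config$seed), output_dir = config$output_dir,
                 stages = config$stages, cohort = spec, classifier = cls,
                 cluster = cl),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-stage seed derived from the run seed and the stage name,
# kept inside 32-bit integer range.
.stage_seed <- function(seed, stage) {
  (as.integer(seed) + sum(utf8ToInt(stage)) * 131L) %% .Machine$integer.max
}

#' Run the end-to-end synthetic-cohort analysis pipeline
#'
#' Executes the requested stages in dependency order on a synthetic cohort:
#' `simulate` (abundance, expression and clinical tables), `cluster`
#' (z-scoring, consensus clustering, centroids), `classify` (nearest-
#' centroid re-prediction with QC), `score` (TLSscore, FTBRS, TFRscore),
#' `stats` (per-subtype response rates and association test) and `survival`
#' (Kaplan-Meier curves and log-rank test). All tabular outputs are written
#' as TSV under `config$output_dir` together with a JSON manifest of
#' parameters and output MD5 hashes; the run is a pure function of the
#' config.
#'
#' @param config A [validate_config()] result, a config list, or a path to
#'   a YAML/JSON config.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  files <- character(0)
  emit <- function(name, writer) {
    path <- file.path(config$output_dir, name)
    writer(path)
    files <<- c(files, path)
  }
  stages <- config$stages

  if ("simulate" %in% stages) {
    spec <- config$cohort
    spec$seed <- .stage_seed(config$seed, "simulate")
    ab <- generate_abundance_cohort(spec)
    ex <- generate_expression_cohort(spec, synthetic_signatures())
    clin <- generate_clinical(ab$labels, spec)
    out$simulate <- list(abundance = ab, expression = ex, clinical = clin)
    emit("abundance.tsv", function(p) write_matrix_tsv(ab$abundance, p, "cell_type"))
    emit("expression.tsv", function(p) write_matrix_tsv(ex$expression, p, "gene_id"))
    emit("clinical.tsv", function(p)
      write.table(clin, p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit("true_labels.tsv", function(p)
      write.table(data.frame(sample_id = names(ab$labels),
                             true_label = as.character(ab$labels)),
                  p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  if ("cluster" %in% stages) {
    if (is.null(out$simulate)) stop("stage 'cluster' needs stage 'simulate'", call. = FALSE)
    z <- zscore_features(out$simulate$abundance$abundance)
    cc <- consensus_cluster(z, k = config$cluster$k,
                            iterations = config$cluster$iterations,
                            subsample_fraction = config$cluster$subsample_fraction,
                            seed = .stage_seed(config$seed, "cluster"))
    cent <- compute_centroids(z, cc$labels)
    out$cluster <- list(z = z, consensus = cc, centroids = cent)
    emit("consensus_labels.tsv", function(p)
      write.table(data.frame(sample_id = names(cc$labels),
                             label = as.character(cc$labels),
                             silhouette = cc$silhouette),
                  p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit("consensus_matrix.tsv", function(p)
      write_matrix_tsv(cc$consensus_matrix, p, "sample_id"))
    emit("centroids.tsv", function(p) write_matrix_tsv(cent, p, "cell_type"))
  }

  if ("classify" %in% stages) {
    if (is.null(out$cluster)) stop("stage 'classify' needs stage 'cluster'", call. = FALSE)
    cls <- classify_cohort(out$simulate$abundance$abundance,
                           out$cluster$centroids, config$classifier)
    out$classify <- cls
    emit("assignments.tsv", function(p)
      write.table(cls$assignments, p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit("classification_summary.json", function(p)
      jsonlite::write_json(list(counts = as.list(cls$summary$counts),
                                unclassified_fraction = cls$summary$unclassified_fraction),
                           p, auto_unbox = TRUE, digits = NA))
  }

  if ("score" %in% stages) {
    if (is.null(out$simulate)) stop("stage 'score' needs stage 'simulate'", call. = FALSE)
    expr <- out$simulate$expression$expression
    sigs <- synthetic_signatures()
    scores <- data.frame(
      sample_id = colnames(expr),
      TLSscore = tls_score(expr),
      FTBRS = ftbrs_score(expr, sigs$FTBRS),
      row.names = NULL)
    out$score <- scores
    emit("scores.tsv", function(p)
      write.table(scores, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  if ("stats" %in% stages) {
    if (is.null(out$classify)) stop("stage 'stats' needs stage 'classify'", call. = FALSE)
    rr <- response_rate_summary(out$classify, out$simulate$clinical)
    out$stats <- rr
    emit("response_test.json", function(p)
      jsonlite::write_json(list(method = rr$test$method,
                                statistic = rr$test$statistic,
                                df = rr$test$df, p_value = rr$test$p.value,
                                rates = as.list(rr$rates)),
                           p, auto_unbox = TRUE, digits = NA))
  }

  if ("survival" %in% stages) {
    if (is.null(out$classify)) stop("stage 'survival' needs stage 'classify'", call. = FALSE)
    clin <- merge(out$simulate$clinical,
                  out$classify$assignments[, c("sample_id", "label")],
                  by = "sample_id")
    clin$subtype <- NULL
    names(clin)[names(clin) == "label"] <- "subtype"
    sv <- survival_by_group(clin)
    out$survival <- sv
    emit("km_curves.tsv", function(p) {
      df <- do.call(rbind, lapply(names(sv$curves), function(g) {
        cv <- sv$curves[[g]]
        if (nrow(cv) == 0L) return(NULL)
        cbind(group = g, as.data.frame(cv))
      }))
      write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    })
    emit("logrank.json", function(p)
      jsonlite::write_json(list(statistic = sv$logrank$statistic,
                                df = sv$logrank$df,
                                p_value = sv$logrank$p.value),
                           p, auto_unbox = TRUE, digits = NA))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("tmesubtype")),
    seed = config$seed,
    stages = stages,
    parameters = list(cohort = unclass(config$cohort),
                      classifier = unclass(config$classifier),
                      cluster = config$cluster),
    outputs = as.list(tools::md5sum(files)))
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}
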