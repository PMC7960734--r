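# End-to-end orchestration: simulate (or load) -> coherence features ->
# PRS + ancestry -> assemble -> stratified evaluation, from one config.

pipeline_schema <- function() {
  list(
    seed = "integer",
    output_dir = "character",
    simulate = c("n_per_group", "n_rois", "fs", "duration", "n_snps",
                 "n_blocks", "block_r2", "n_ref", "coherence_effects",
                 "causal_snps", "covariate_effects"),
    inputs = c("signals_dir", "phenotypes", "dosages", "snps", "summary_stats",
               "reference_dosages", "reference_snps"),
    spectral = c("segment_length", "overlap", "window"),
    clumping = c("r2_threshold", "window_kb", "thresholds"),
    cv = c("mode", "outer_folds", "repeats"),
    matching = c("caliper"),
    strata = NULL # list of stratum blocks, validated separately
  )
}

#' Validate a pipeline configuration
#'
#' Checks a configuration list (or YAML file) against the published schema
#' before any computation: unknown keys are rejected with field-level
#' messages, required blocks checked, defaults filled in and recorded so a
#' run is self-describing.
#'
#' @param config Named list, or path to a YAML file.
#' @return The validated, default-completed config (invisibly usable by
#'   [run_pipeline()]).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  assert_that(is.list(config), "config must be a list or a YAML path")
  schema <- pipeline_schema()
  unknown <- setdiff(names(config), names(schema))
  assert_that(length(unknown) == 0,
              paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  for (blk in c("simulate", "inputs", "spectral", "clumping", "cv", "matching")) {
    if (!is.null(config[[blk]])) {
      bad <- setdiff(names(config[[blk]]), schema[[blk]])
      assert_that(length(bad) == 0,
                  sprintf("unknown key(s) in %s: %s", blk, paste(bad, collapse = ", ")))
    }
  }
  assert_that(!is.null(config$seed), "config$seed is required")
  assert_that(xor(is.null(config$simulate), is.null(config$inputs)),
              "exactly one of 'simulate' or 'inputs' must be present")
  assert_that(!is.null(config$strata) && length(config$strata) > 0,
              "config$strata must list at least one stratum")
  for (i in seq_along(config$strata)) {
    st <- config$strata[[i]]
    bad <- setdiff(names(st), c("sex", "ancestry", "ancestry_mode", "features"))
    assert_that(length(bad) == 0,
                sprintf("unknown key(s) in strata[[%d]]: %s", i, paste(bad, collapse = ", ")))
    assert_that(all(c("sex", "ancestry", "features") %in% names(st)),
                sprintf("strata[[%d]] needs sex, ancestry and features", i))
  }
  defaults <- list(
    spectral = list(segment_length = 2, overlap = 0.5, window = "hann"),
    clumping = list(r2_threshold = 0.25, window_kb = 500, thresholds = prs_thresholds()),
    cv = list(mode = "paper_faithful", outer_folds = 10, repeats = 10),
    matching = list(caliper = 2))
  for (blk in names(defaults)) {
    config[[blk]] <- utils::modifyList(defaults[[blk]], config[[blk]] %||% list())
  }
  for (i in seq_along(config$strata)) {
    config$strata[[i]]$ancestry_mode <- config$strata[[i]]$ancestry_mode %||% "self_report"
  }
  config
}

#' Run the full remission-prediction pipeline from one configuration
#'
#' Executes, per the config: cohort simulation (or loading of on-disk
#' inputs), coherence feature extraction, clumping-and-thresholding PRS,
#' genotype-PCA ancestry assignment, feature-table assembly, and — for every
#' configured stratum — stratification, complete-case filtering, age
#' matching and repeated cross-validated evaluation. All results are
#' returned, and written as JSON/CSV when `output_dir` is set. A failure in
#' one stratum is isolated: other strata still complete, and the failure is
#' recorded as a warning in the report.
#'
#' The run is deterministic given the config (including its seed): two runs
#' produce byte-identical result JSONs.
#'
#' @param config Config list or YAML path; see [validate_config()].
#' @return Object of class `run_report`: `results` (named list of
#'   [repeated_cv_evaluate()] results per stratum), `tables` (rendered
#'   results table), `outputs` (tibble of written files with MD5 content
#'   hashes), `warnings`, `config`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  seed <- as.integer(config$seed)
  warnings_log <- character()
  log_warn <- function(msg) warnings_log <<- c(warnings_log, msg)

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    truth <- cohort_truth(
      n_per_group = sim$n_per_group %||% 50,
      coherence_effects = if (!is.null(sim$coherence_effects))
        dplyr::bind_rows(lapply(sim$coherence_effects, tibble::as_tibble)) else NULL,
      causal_snps = if (!is.null(sim$causal_snps))
        dplyr::bind_rows(lapply(sim$causal_snps, tibble::as_tibble)) else NULL,
      covariate_effects = sim$covariate_effects,
      seed = seed)
    cohort <- generate_cohort(truth,
                              n_rois = sim$n_rois %||% 68,
                              fs = sim$fs %||% 256,
                              duration = sim$duration %||% 240,
                              n_snps = sim$n_snps %||% 200,
                              n_blocks = sim$n_blocks %||% 20,
                              block_r2 = sim$block_r2 %||% 0.5,
                              n_ref = sim$n_ref %||% 200)
    signals <- cohort$signals
    phenotypes <- cohort$subjects
    genotypes <- cohort$genotypes
    summary_stats <- cohort$summary_stats
    reference <- cohort$reference
  } else {
    inp <- config$inputs
    signals <- read_signals_csv(inp$signals_dir)
    phenotypes <- read_phenotypes_csv(inp$phenotypes)
    genotypes <- read_dosage_tsv(inp$dosages, inp$snps)
    summary_stats <- read_summary_stats(inp$summary_stats)
    reference <- read_dosage_tsv(inp$reference_dosages, inp$reference_snps)
  }

  sp <- config$spectral
  eeg <- coherence_features(signals, segment_length = sp$segment_length,
                            overlap = sp$overlap, window = sp$window)
  cl <- config$clumping
  prs <- compute_prs(genotypes, list(pheno = summary_stats), reference,
                     r2_threshold = cl$r2_threshold, window_kb = cl$window_kb,
                     thresholds = cl$thresholds)
  pcs <- ancestry_pca(genotypes)
  gen_anc <- assign_ancestry(pcs, phenotypes[, c("subject_id", "ancestry")],
                             seed = seed)
  table <- build_feature_table(list(eeg, prs), phenotypes)

  results <- list()
  for (st in config$strata) {
    label <- paste(st$ancestry, st$sex, st$ancestry_mode %||% "self_report", sep = "_")
    res <- tryCatch({
      stratum <- stratify(table, st$sex, st$ancestry, st$features,
                          ancestry_mode = st$ancestry_mode,
                          genetic_ancestry = gen_anc)
      stratum <- complete_cases(stratum)
      stratum <- age_match(stratum, caliper = config$matching$caliper)
      repeated_cv_evaluate(stratum, mode = config$cv$mode,
                           outer_folds = config$cv$outer_folds,
                           repeats = config$cv$repeats,
                           seed = substream_seed(seed, paste0("stratum_", label)))
    }, error = function(e) {
      log_warn(sprintf("stratum %s failed: %s", label, conditionMessage(e)))
      NULL
    })
    results[label] <- list(res) # keep NULL entries for failed strata
  }
  ok <- !vapply(results, is.null, logical(1))
  rendered <- if (any(ok)) render_results_table(results[ok]) else tibble::tibble()

  outputs <- tibble::tibble(path = character(), md5 = character())
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(results)[ok]) {
      p <- file.path(config$output_dir, paste0("result_", nm, ".json"))
      write_model_result_json(results[[nm]], p)
      outputs <- dplyr::bind_rows(outputs, tibble::tibble(path = p, md5 = unname(tools::md5sum(p))))
    }
    if (nrow(rendered)) {
      p <- file.path(config$output_dir, "results_table.csv")
      write.csv(rendered, p, row.names = FALSE)
      outputs <- dplyr::bind_rows(outputs, tibble::tibble(path = p, md5 = unname(tools::md5sum(p))))
    }
  }
  structure(list(results = results, tables = rendered, outputs = outputs,
                 warnings = warnings_log, config = config,
                 timestamp = format(Sys.time(), tz = "UTC")),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  ok <- sum(!vapply(x$results, is.null, logical(1)))
  cat(sprintf("<run_report> %d/%d strata completed, %d warning(s)\n",
              ok, length(x$results), length(x$warnings)))
  if (nrow(x$tables)) print(x$tables)
  invisible(x)
}

#' Render a results table in reporting style
#'
#' One row per model with specificity, sensitivity and accuracy as
#' percentages and the AUC on its 0-1 scale, each formatted
#' `"mean ± SD"`. Undefined metrics render as an em dash, never 0.
#' Column order is fixed regardless of input order.
#'
#' @param results Named list of `remit_cv_result` objects.
#' @return Tibble: `model`, `specificity`, `sensitivity`, `accuracy`,
#'   `auc`.
#' @export
render_results_table <- function(results) {
  assert_that(length(results) > 0, "results must be non-empty")
  if (inherits(results, "remit_cv_result")) results <- list(model = results)
  fmt <- function(s, metric, scale, digits_m, digits_s) {
    row <- s[s$metric == metric, ]
    if (!nrow(row) || !is.finite(row$mean)) return("—")
    sprintf(paste0("%.", digits_m, "f ± %.", digits_s, "f"),
            row$mean * scale, row$sd * scale)
  }
  purrr::imap_dfr(results, function(r, nm) {
    s <- r$summary
    tibble::tibble(model = nm,
                   specificity = fmt(s, "specificity", 100, 2, 1),
                   sensitivity = fmt(s, "sensitivity", 100, 2, 1),
                   accuracy = fmt(s, "accuracy", 100, 2, 1),
                   auc = fmt(s, "auc", 1, 2, 2))
  })
}

#' Render a selected-feature report
#'
#' Breaks a model's selected features into modality sections in reporting
#' style: EEG features as (ROI pair, band, connectivity direction, weight
#' rank), PRS features as (phenotype, threshold, rank), demographics and
#' medications as (name, rank). The connectivity direction says whether the
#' remitted group carries the higher or lower coherence, read from the sign
#' of the SVM weight on the standardized feature. Ranks are exactly
#' [rank_features()] output. Sections with no selected features are
#' omitted.
#'
#' @param result A `remit_cv_result`.
#' @return Tibble: `modality`, `feature`, `detail`, `direction`, `rank`.
#' @export
render_feature_report <- function(result) {
  assert_that(inherits(result, "remit_cv_result"), "result must be a remit_cv_result")
  sel <- result$selected[result$selected$weight != 0, , drop = FALSE]
  assert_that(nrow(sel) > 0, "result has no selected features")
  parts <- purrr::pmap_dfr(sel, function(feature, weight, rank, ...) {
    if (startsWith(feature, "eeg_")) {
      core <- sub("^eeg_", "", feature)
      band <- sub("^.*@", "", core)
      pair <- sub("@.*$", "", core)
      tibble::tibble(modality = "EEG", feature = pair, detail = band,
                     direction = if (weight > 0) "higher in remitted" else "lower in remitted",
                     rank = rank)
    } else if (startsWith(feature, "prs_")) {
      core <- sub("^prs_", "", feature)
      tibble::tibble(modality = "PRS", feature = sub("@.*$", "", core),
                     detail = paste0("p < ", sub("^.*@", "", core)),
                     direction = if (weight > 0) "higher in remitted" else "lower in remitted",
                     rank = rank)
    } else {
      tibble::tibble(modality = if (startsWith(feature, "med_")) "medication" else "demographic",
                     feature = sub("^(dem|med)_", "", feature), detail = "",
                     direction = if (weight > 0) "higher in remitted" else "lower in remitted",
                     rank = rank)
    }
  })
  dplyr::arrange(parts, .data$modality, .data$rank)
}

# Serialize a remit_cv_result deterministically (no timestamps; fixed digit
# handling) so identical runs give byte-identical files.
write_model_result_json <- function(result, path) {
  payload <- list(mode = result$mode, n = result$n, seed = result$seed,
                  outer_folds = result$outer_folds, repeats = result$repeats,
                  summary = result$summary, metrics = result$metrics,
                  selected = result$selected)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
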