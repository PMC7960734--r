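# Feature tables are plain tibbles with reserved metadata columns; every
# other column is a feature whose modality is encoded in its name prefix:
#   eeg_  coherence features      prs_  polygenic scores
#   dem_  demographic indicators  med_  medication indicators

meta_cols <- function() {
  c("subject_id", "label", "sex", "ancestry", "ancestry_genetic", "age")
}

#' Feature columns and their modality tags
#'
#' @param table A feature table (tibble).
#' @return Named character vector: feature column name -> modality
#'   (`"EEG"`, `"PRS"`, `"demographic"`, `"medication"`).
#' @export
feature_modalities <- function(table) {
  feats <- setdiff(names(table), meta_cols())
  tag <- dplyr::case_when(
    startsWith(feats, "eeg_") ~ "EEG",
    startsWith(feats, "prs_") ~ "PRS",
    startsWith(feats, "dem_") ~ "demographic",
    startsWith(feats, "med_") ~ "medication",
    TRUE ~ NA_character_)
  assert_that(!anyNA(tag),
              paste("unrecognized feature column prefix:",
                    paste(head(feats[is.na(tag)], 5), collapse = ", ")))
  setNames(tag, feats)
}

#' Merge modality blocks and phenotypes into one labeled feature table
#'
#' Outer-joins any number of per-modality feature blocks on `subject_id`,
#' attaches outcome labels and stratification metadata from the phenotype
#' records, and encodes demographics as binary indicators (`dem_married`,
#' `dem_employed`) alongside the eight `med_*` flags. A subject absent from
#' a block simply has missing values there (handled later by
#' [complete_cases()]).
#'
#' @param blocks List of tibbles, each with `subject_id` plus prefixed
#'   feature columns (e.g. [coherence_features()], [compute_prs()] output).
#' @param phenotypes Tibble of subject records as produced by
#'   [simulate_demographics()] (`subject_id`, `label`, `sex`, `ancestry`,
#'   `age`, `married`, `employed`, `med_*`).
#' @return A feature table tibble.
#' @export
build_feature_table <- function(blocks, phenotypes) {
  phenotypes <- tibble::as_tibble(phenotypes)
  need <- c("subject_id", "label", "sex", "ancestry", "age", "married", "employed")
  assert_that(all(need %in% names(phenotypes)),
              paste("phenotypes needs columns:", paste(need, collapse = ", ")))
  assert_that(!anyDuplicated(phenotypes$subject_id), "duplicate subject ids in phenotypes")
  base <- dplyr::rename(phenotypes, dem_married = "married", dem_employed = "employed")
  if (is.data.frame(blocks)) blocks <- list(blocks)
  feat_names <- unlist(lapply(blocks, function(b) setdiff(names(b), "subject_id")))
  dup <- feat_names[duplicated(feat_names)]
  assert_that(length(dup) == 0,
              paste("duplicate feature names across blocks:",
                    paste(unique(head(dup, 5)), collapse = ", ")))
  out <- purrr::reduce(blocks, function(acc, b) {
    dplyr::full_join(acc, tibble::as_tibble(b), by = "subject_id")
  }, .init = base)
  feature_modalities(out) # validates prefixes
  out
}

# Resolve a feature-set selector to concrete columns. Entries may be
# modality tags (EEG/PRS/demographic/medication, case-insensitive), aliases
# (marital, employment), exact column names, or column names sans prefix.
resolve_features <- function(table, selector) {
  assert_that(length(selector) > 0, "feature selector must be non-empty")
  mods <- feature_modalities(table)
  alias <- c(marital = "dem_married", marital_status = "dem_married",
             employment = "dem_employed", employment_status = "dem_employed")
  picked <- character()
  for (s in selector) {
    sl <- tolower(s)
    if (sl %in% tolower(unique(mods))) {
      picked <- c(picked, names(mods)[tolower(mods) == sl])
    } else if (sl %in% names(alias)) {
      picked <- c(picked, alias[[sl]])
    } else if (s %in% names(mods)) {
      picked <- c(picked, s)
    } else if (any(sub("^(eeg|prs|dem|med)_", "", names(mods)) == s)) {
      picked <- c(picked, names(mods)[sub("^(eeg|prs|dem|med)_", "", names(mods)) == s])
    } else {
      stop(sprintf("selector entry '%s' matches no modality or feature", s), call. = FALSE)
    }
  }
  unique(picked)
}

#' Restrict a feature table to one sex/ancestry stratum and feature set
#'
#' Filters subjects to the requested sex and ancestry — using self-reported
#' ancestry or a genetic assignment (from [assign_ancestry()]) — and keeps
#' only the selected feature columns plus metadata.
#'
#' @param table Feature table from [build_feature_table()].
#' @param sex `"male"` or `"female"`.
#' @param ancestry `"EA"` or `"AA"`.
#' @param features Feature-set selector: modality tags (`"EEG"`, `"PRS"`,
#'   `"demographic"`, `"medication"`), aliases (`"marital"`,
#'   `"employment"`), or column names.
#' @param ancestry_mode `"self_report"` (default) or `"genetic"`.
#' @param genetic_ancestry Tibble `subject_id`, `ancestry_genetic`; required
#'   when `ancestry_mode = "genetic"`.
#' @return The stratum feature table.
#' @export
stratify <- function(table, sex, ancestry, features,
                     ancestry_mode = c("self_report", "genetic"),
                     genetic_ancestry = NULL) {
  ancestry_mode <- match.arg(ancestry_mode)
  if (ancestry_mode == "genetic") {
    assert_that(!is.null(genetic_ancestry),
                "genetic ancestry_mode requires a genetic_ancestry assignment")
    table <- dplyr::left_join(
      dplyr::select(table, -dplyr::any_of("ancestry_genetic")),
      dplyr::select(tibble::as_tibble(genetic_ancestry), "subject_id", "ancestry_genetic"),
      by = "subject_id")
    anc_col <- "ancestry_genetic"
  } else {
    anc_col <- "ancestry"
  }
  keep <- table$sex == sex & table[[anc_col]] == ancestry
  if (!any(keep)) {
    counts <- dplyr::count(table, .data$sex, !!rlang::sym(anc_col))
    stop(paste0("empty stratum ", sex, "/", ancestry, " (", ancestry_mode,
                "); available strata:\n",
                paste(utils::capture.output(print(as.data.frame(counts))), collapse = "\n")),
         call. = FALSE)
  }
  cols <- resolve_features(table, features)
  dplyr::select(table[keep, , drop = FALSE],
                dplyr::any_of(meta_cols()), dplyr::all_of(cols))
}

#' Greedy 1:1 age matching of the two outcome groups
#'
#' Pairs continued with remitted subjects by nearest age at the baseline
#' visit, without replacement: candidate pairs are ordered by absolute age
#' difference (ties by the two subject ids), accepted greedily, and pairs
#' beyond the caliper are never formed. The result keeps only matched
#' subjects, so group sizes come out equal.
#'
#' @param table Feature table with `label` and `age`.
#' @param caliper Maximum tolerated age difference within a pair, in years
#'   (default 2).
#' @return The matched feature table, with a `pairs` attribute (tibble
#'   `subject_continued`, `subject_remitted`, `delta_age`).
#' @export
age_match <- function(table, caliper = 2) {
  a <- which(table$label == "continued")
  b <- which(table$label == "remitted")
  assert_that(length(a) > 0 && length(b) > 0, "both outcome groups must be non-empty")
  grid <- expand.grid(i = a, j = b)
  grid$delta <- abs(table$age[grid$i] - table$age[grid$j])
  grid <- grid[grid$delta <= caliper, , drop = FALSE]
  if (nrow(grid) == 0) {
    stop(sprintf("no age pairs within the %.3g-year caliper", caliper), call. = FALSE)
  }
  grid <- grid[order(grid$delta, table$subject_id[grid$i], table$subject_id[grid$j]), ]
  used_i <- logical(nrow(table)); used_j <- logical(nrow(table))
  keep <- logical(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    i <- grid$i[r]; j <- grid$j[r]
    if (!used_i[i] && !used_j[j]) {
      keep[r] <- TRUE
      used_i[i] <- TRUE
      used_j[j] <- TRUE
    }
  }
  grid <- grid[keep, , drop = FALSE]
  pairs <- tibble::tibble(subject_continued = table$subject_id[grid$i],
                          subject_remitted = table$subject_id[grid$j],
                          delta_age = grid$delta)
  out <- table[sort(c(grid$i, grid$j)), , drop = FALSE]
  attr(out, "pairs") <- pairs
  out
}

#' Drop subjects with any missing feature value
#'
#' Listwise deletion over the feature columns currently in the table (the
#' selected feature set), mirroring analyses whose subject subsets are
#' dictated by per-modality missingness. Removal counts per modality are
#' reported as a message.
#'
#' @param table Feature table.
#' @return Table without rows containing missing feature values.
#' @export
complete_cases <- function(table) {
  mods <- feature_modalities(table)
  feats <- names(mods)
  if (!length(feats)) return(table)
  miss <- is.na(as.matrix(table[, feats, drop = FALSE]))
  drop <- rowSums(miss) > 0
  if (any(drop)) {
    per_mod <- vapply(unique(mods), function(m) {
      sum(rowSums(miss[, mods == m, drop = FALSE]) > 0)
    }, integer(1))
    message(sprintf("dropping %d subject(s) with missing features [%s]",
                    sum(drop),
                    paste(sprintf("%s: %d", names(per_mod), per_mod), collapse = ", ")))
  }
  out <- table[!drop, , drop = FALSE]
  assert_that(nrow(out) > 0, "all subjects removed by complete-case filtering")
  out
}

#' Z-normalize feature columns
#'
#' Without supplied statistics, fits per-feature mean and standard deviation
#' on the table and transforms it; with `statistics` supplied (a previous
#' result's `norm_stats` attribute or a tibble `feature`, `mean`, `sd`), it
#' only transforms — the form needed for leakage-free cross-validation,
#' where scaling must be learned on training rows alone. Constant features
#' are set to 0 with a warning.
#'
#' @param table Feature table with >= 2 rows.
#' @param statistics Optional tibble (`feature`, `mean`, `sd`).
#' @return The normalized table; the statistics used are attached as
#'   attribute `norm_stats` (retrieve with `norm_stats()`).
#' @export
znormalize <- function(table, statistics = NULL) {
  feats <- names(feature_modalities(table))
  if (is.null(statistics)) {
    assert_that(nrow(table) >= 2, "z-normalization needs >= 2 rows")
    mu <- vapply(table[feats], mean, numeric(1))
    sg <- vapply(table[feats], sd, numeric(1))
    if (any(sg == 0)) {
      warning(sprintf("%d constant feature(s) set to 0", sum(sg == 0)))
    }
    statistics <- tibble::tibble(feature = feats, mean = mu, sd = sg)
  } else {
    statistics <- tibble::as_tibble(statistics)
    assert_that(all(feats %in% statistics$feature),
                "statistics must cover every feature column")
    statistics <- statistics[match(feats, statistics$feature), ]
  }
  for (k in seq_along(feats)) {
    v <- table[[feats[k]]]
    table[[feats[k]]] <- if (statistics$sd[k] == 0) rep(0, length(v)) else
      (v - statistics$mean[k]) / statistics$sd[k]
  }
  attr(table, "norm_stats") <- statistics
  table
}

#' @rdname znormalize
#' @export
norm_stats <- function(table) attr(table, "norm_stats")
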