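# Plain-text I/O for every pipeline artifact. ROI signals are stored as one
# CSV per subject (samples x ROIs) plus a JSON sidecar holding the sampling
# rate and ROI order; genotypes as a dosage TSV plus a SNP metadata TSV;
# summary statistics as the conventional `snp chr pos a1 a2 beta p` TSV.

#' Write / read ROI signals as per-subject CSV files
#'
#' @param set A [roi_ts_set()].
#' @param dir Output directory (created if needed). One `<subject>.csv` per
#'   subject (columns = ROIs) and a `signals_meta.json` with `fs`,
#'   `roi_names` and subject order.
#' @return `dir` (write) or a [roi_ts_set()] (read), invisibly for write.
#' @export
write_signals_csv <- function(set, dir) {
  assert_that(inherits(set, "roi_ts_set"), "set must be a roi_ts_set")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(set$signals)) {
    m <- t(set$signals[[id]])
    colnames(m) <- set$roi_names
    write.csv(m, file.path(dir, paste0(id, ".csv")), row.names = FALSE)
  }
  jsonlite::write_json(list(fs = set$fs, roi_names = set$roi_names,
                            subjects = names(set$signals)),
                       file.path(dir, "signals_meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_signals_csv
#' @export
read_signals_csv <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "signals_meta.json"),
                              simplifyVector = TRUE)
  sigs <- lapply(meta$subjects, function(id) {
    m <- as.matrix(read.csv(file.path(dir, paste0(id, ".csv")), check.names = FALSE))
    t(m)
  })
  names(sigs) <- meta$subjects
  roi_ts_set(sigs, meta$fs, meta$roi_names)
}

#' Write / read the phenotype CSV
#'
#' @param phenotypes Subject-record tibble ([simulate_demographics()]).
#' @param path CSV path.
#' @return `path`, or the tibble on read.
#' @export
write_phenotypes_csv <- function(phenotypes, path) {
  write.csv(phenotypes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_csv
#' @export
read_phenotypes_csv <- function(path) {
  tibble::as_tibble(read.csv(path, check.names = FALSE))
}

#' Write / read GWAS summary statistics TSV
#'
#' Tab-separated with header `snp chr pos a1 a2 beta p`; positions 1-based.
#'
#' @param stats Summary-statistics tibble.
#' @param path TSV path.
#' @export
write_summary_stats <- function(stats, path) {
  utils::write.table(stats[, c("snp", "chr", "pos", "a1", "a2", "beta", "p")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  st <- tibble::as_tibble(read.delim(path, colClasses = c(chr = "character")))
  assert_that(all(c("snp", "chr", "pos", "a1", "a2", "beta", "p") %in% names(st)),
              "summary stats must have header: snp chr pos a1 a2 beta p")
  assert_that(all(st$p > 0 & st$p <= 1), "p values must lie in (0, 1]")
  st
}

#' Write / read genotype dosages as TSV
#'
#' The dosage TSV has subjects as rows (`subject_id` first column) and SNP
#' ids as remaining columns; SNP metadata (`snp chr pos a1 a2`) travels in a
#' companion TSV.
#'
#' @param genotypes A [genotype_matrix()].
#' @param dosage_path,snps_path Output paths.
#' @export
write_dosage_tsv <- function(genotypes, dosage_path, snps_path) {
  df <- data.frame(subject_id = rownames(genotypes$dosage),
                   genotypes$dosage, check.names = FALSE)
  utils::write.table(df, dosage_path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(genotypes$snps, snps_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(dosage_path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(dosage_path, snps_path) {
  df <- read.delim(dosage_path, check.names = FALSE)
  snps <- tibble::as_tibble(read.delim(snps_path, colClasses = c(chr = "character")))
  dos <- as.matrix(df[, -1, drop = FALSE])
  rownames(dos) <- df$subject_id
  genotype_matrix(dos, snps)
}

#' Read genotype dosages from a VCF
#'
#' Extracts GT genotypes with vcfR and converts them to dosages of the ALT
#' allele (a1 = ALT, a2 = REF). Missing genotypes become NA.
#'
#' @param path VCF path (uncompressed or gzipped).
#' @return A [genotype_matrix()].
#' @export
read_vcf_dosages <- function(path) {
  assert_that(requireNamespace("vcfR", quietly = TRUE),
              "reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    sum(as.numeric(strsplit(g, "[/|]")[[1]]))
  })
  fix <- vcfR::getFIX(v)
  snps <- tibble::tibble(snp = fix[, "ID"], chr = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         a1 = fix[, "ALT"], a2 = fix[, "REF"])
  genotype_matrix(t(dos), snps)
}

#' Write genotype dosages as a minimal VCF
#'
#' Emits a VCFv4.2 file with GT fields reconstructed from rounded dosages
#' (0 -> 0/0, 1 -> 0/1, 2 -> 1/1; NA -> ./.), a1 as ALT. Suitable for
#' interchange with standard genetics tooling; fractional dosages are
#' rounded.
#'
#' @param genotypes A [genotype_matrix()].
#' @param path Output path.
#' @export
write_vcf_dosages <- function(genotypes, path) {
  snps <- genotypes$snps
  dos <- round(t(genotypes$dosage)) # SNPs x subjects
  gt <- matrix(c("0/0", "0/1", "1/1")[dos + 1], nrow(dos), ncol(dos))
  gt[is.na(dos)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(genotypes$dosage)), collapse = "\t"))
  body <- vapply(seq_len(nrow(snps)), function(i) {
    paste(c(snps$chr[i], snps$pos[i], snps$snp[i], snps$a2[i], snps$a1[i],
            ".", "PASS", ".", "GT", gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write / read the ground-truth JSON of a synthetic cohort
#'
#' @param truth A [cohort_truth()].
#' @param path JSON path.
#' @export
write_truth_json <- function(truth, path) {
  assert_that(inherits(truth, "cohort_truth"), "truth must be a cohort_truth")
  payload <- unclass(truth)
  # named vectors serialize as JSON objects (name -> scalar), not arrays
  if (!is.null(payload$covariate_effects)) {
    payload$covariate_effects <- as.list(payload$covariate_effects)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cohort_truth(n_per_group = x$n_per_group,
               coherence_effects = if (!is.null(x$coherence_effects) &&
                                         length(x$coherence_effects))
                 tibble::as_tibble(x$coherence_effects) else NULL,
               causal_snps = if (!is.null(x$causal_snps) && length(x$causal_snps))
                 tibble::as_tibble(x$causal_snps) else NULL,
               covariate_effects = if (length(x$covariate_effects))
                 unlist(x$covariate_effects) else NULL,
               baseline_log_odds = x$baseline_log_odds %||% 0,
               seed = x$seed)
}

#' Write a feature table to CSV (round-trip safe)
#'
#' @param table Feature table.
#' @param path CSV path.
#' @export
write_feature_table_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table_csv
#' @export
read_feature_table_csv <- function(path) {
  tibble::as_tibble(read.csv(path, check.names = FALSE))
}
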