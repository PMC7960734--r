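# Feature-table assembly, stratification, age matching, missingness and
# Z-normalization.

make_pheno <- function(n = 8, seed = 50) {
  subs <- make_subjects(n / 2, seed = seed)
  simulate_demographics(subs, NULL, seed = seed)
}

test_that("blocks outer-join on subject id with missingness crosswise", {
  ph <- make_pheno(8)
  ids <- ph$subject_id
  b1 <- tibble::tibble(subject_id = ids[1:4], eeg_a = 1:4)
  b2 <- tibble::tibble(subject_id = ids[5:8], prs_b = 5:8)
  tb <- build_feature_table(list(b1, b2), ph)
  expect_true(all(is.na(tb$eeg_a[match(ids[5:8], tb$subject_id)])))
  expect_true(all(is.na(tb$prs_b[match(ids[1:4], tb$subject_id)])))
  expect_equal(nrow(tb), 8)
  # duplicate feature names rejected with the collision listed
  b3 <- tibble::tibble(subject_id = ids, eeg_a = 0)
  expect_error(build_feature_table(list(b1, b3), ph), "eeg_a")
})

test_that("column arithmetic matches the block widths", {
  ph <- make_pheno(6)
  b1 <- tibble::tibble(subject_id = ph$subject_id,
                       !!!setNames(as.list(1:5), paste0("eeg_f", 1:5)))
  b2 <- tibble::tibble(subject_id = ph$subject_id,
                       !!!setNames(as.list(1:3), paste0("prs_g", 1:3)))
  tb <- build_feature_table(list(b1, b2), ph)
  # 5 EEG + 3 PRS + 2 demographic + 8 medication feature columns
  expect_length(feature_modalities(tb), 5 + 3 + 2 + 8)
  mods <- table(feature_modalities(tb))
  expect_equal(as.integer(mods[c("EEG", "PRS", "demographic", "medication")]),
               c(5L, 3L, 2L, 8L))
})

test_that("feature tables round-trip through CSV", {
  ph <- make_pheno(6)
  tb <- build_feature_table(list(tibble::tibble(subject_id = ph$subject_id,
                                                eeg_x = rnorm(6))), ph)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table_csv(tb, path)
  tb2 <- read_feature_table_csv(path)
  expect_equal(as.data.frame(tb), as.data.frame(tb2), tolerance = 1e-12)
})

test_that("stratification filters rows and selects feature sets", {
  ph <- make_pheno(40, seed = 51)
  tb <- build_feature_table(list(tibble::tibble(subject_id = ph$subject_id,
                                                eeg_x = rnorm(40),
                                                prs_y = rnorm(40))), ph)
  st <- stratify(tb, "male", "EA", features = c("PRS"))
  expect_true(all(st$sex == "male" & st$ancestry == "EA"))
  expect_identical(names(feature_modalities(st)), "prs_y")
  st2 <- stratify(tb, "male", "EA", features = c("EEG", "marital"))
  expect_setequal(names(feature_modalities(st2)), c("eeg_x", "dem_married"))
  expect_error(stratify(tb, "male", "EA", features = "nonexistent"),
               "matches no modality")
})

test_that("self-report and genetic stratification differ exactly on disagreements", {
  ph <- make_pheno(30, seed = 52)
  tb <- build_feature_table(list(tibble::tibble(subject_id = ph$subject_id,
                                                prs_y = rnorm(30))), ph)
  gen <- tibble::tibble(subject_id = ph$subject_id,
                        ancestry_genetic = ph$ancestry)
  flip <- c(3, 7, 11)
  gen$ancestry_genetic[flip] <- ifelse(gen$ancestry_genetic[flip] == "EA", "AA", "EA")
  for (sx in c("male", "female")) for (an in c("EA", "AA")) {
    rows_self <- tryCatch(stratify(tb, sx, an, "PRS")$subject_id, error = function(e) character())
    rows_gen <- tryCatch(stratify(tb, sx, an, "PRS", ancestry_mode = "genetic",
                                  genetic_ancestry = gen)$subject_id,
                         error = function(e) character())
    sym_diff <- union(setdiff(rows_self, rows_gen), setdiff(rows_gen, rows_self))
    disagree <- ph$subject_id[flip][ph$sex[flip] == sx]
    expect_setequal(sym_diff, intersect(sym_diff, disagree))
  }
  expect_error(stratify(tb, "male", "EA", "PRS", ancestry_mode = "genetic"),
               "requires")
})

test_that("strata partition the cohort", {
  ph <- make_pheno(40, seed = 53)
  tb <- build_feature_table(list(tibble::tibble(subject_id = ph$subject_id,
                                                prs_y = rnorm(40))), ph)
  got <- unlist(lapply(c("male", "female"), function(sx) {
    unlist(lapply(c("EA", "AA"), function(an) {
      tryCatch(stratify(tb, sx, an, "PRS")$subject_id,
               error = function(e) character())
    }))
  }))
  expect_setequal(got, tb$subject_id)
  expect_false(anyDuplicated(got) > 0)
})

test_that("age matching reproduces the worked greedy example", {
  tb <- tibble::tibble(subject_id = paste0("s", 1:5),
                       label = c("continued", "continued", "continued",
                                 "remitted", "remitted"),
                       sex = "male", ancestry = "EA",
                       age = c(20, 30, 40, 21, 39),
                       prs_x = rnorm(5))
  m <- age_match(tb, caliper = 2)
  pairs <- attr(m, "pairs")
  expect_equal(nrow(pairs), 2)
  expect_setequal(paste(pairs$subject_continued, pairs$subject_remitted),
                  c("s1 s4", "s3 s5"))
  expect_false("s2" %in% m$subject_id)
  expect_identical(unname(table(m$label)), table(c(1, 1, 2, 2)) |> unname())
  # identical age lists pair perfectly at zero distance
  tb2 <- tb
  tb2$age <- c(25, 30, 35, 25, 30)
  m2 <- age_match(tb2, caliper = 2)
  expect_true(all(attr(m2, "pairs")$delta_age == 0))
  # group-mean balance bounded by the caliper
  expect_lte(abs(mean(m$age[m$label == "continued"]) -
                   mean(m$age[m$label == "remitted"])), 2)
  tb3 <- tb
  tb3$age[4:5] <- c(90, 95)
  expect_error(age_match(tb3, caliper = 2), "caliper")
})

test_that("matched cohorts balance age to within the caliper (simulated)", {
  ph <- make_pheno(300, seed = 54)
  tb <- build_feature_table(list(tibble::tibble(subject_id = ph$subject_id,
                                                prs_y = rnorm(300))), ph)
  m <- age_match(tb, caliper = 2)
  tt <- t.test(age ~ label, data = m)
  expect_lt(abs(unname(tt$statistic)), 2)
})

test_that("complete-case filtering is selector-aware", {
  ph <- make_pheno(6, seed = 55)
  eeg <- tibble::tibble(subject_id = ph$subject_id, eeg_x = rnorm(6))
  prs <- tibble::tibble(subject_id = ph$subject_id, prs_y = rnorm(6))
  eeg$eeg_x[2] <- NA
  tb <- build_feature_table(list(eeg, prs), ph)
  expect_message(cc <- complete_cases(tb), "EEG: 1")
  expect_false(ph$subject_id[2] %in% cc$subject_id)
  # under a PRS-only selector the same subject is retained
  prs_only <- stratify(tb, ph$sex[2], ph$ancestry[2], "PRS")
  expect_true(ph$subject_id[2] %in% complete_cases(prs_only)$subject_id)
  # no missingness -> identity
  tb_full <- build_feature_table(list(prs), ph)
  expect_identical(complete_cases(tb_full), tb_full)
})

test_that("z-normalization fits, transforms, and respects external statistics", {
  tb <- tibble::tibble(subject_id = paste0("s", 1:3), label = "continued",
                       sex = "male", ancestry = "EA", age = 30,
                       eeg_x = c(2, 4, 6))
  z <- znormalize(tb)
  expect_equal(z$eeg_x, c(-1, 0, 1))
  stats0 <- tibble::tibble(feature = "eeg_x", mean = 0, sd = 1)
  z_id <- znormalize(tb, stats0)
  expect_equal(z_id$eeg_x, tb$eeg_x)
  # fit on train, apply to test: test column mean generally nonzero
  tr <- tibble::tibble(subject_id = paste0("t", 1:4), label = "continued",
                       sex = "male", ancestry = "EA", age = 30,
                       eeg_x = c(0, 1, 2, 3))
  zt <- znormalize(tr)
  te <- znormalize(tb, norm_stats(zt))
  expect_gt(abs(mean(te$eeg_x)), 1e-6)
  cst <- tb
  cst$eeg_x <- 5
  expect_warning(zc <- znormalize(cst), "constant")
  expect_true(all(zc$eeg_x == 0))
})
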