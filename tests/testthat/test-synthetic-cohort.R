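# Synthetic multimodal cohort generator: determinism, planted effects,
# demographics odds ratios, LD-block behaviour.

small_cohort <- function(seed, n_per_group = 5, ...) {
  generate_cohort(cohort_truth(n_per_group = n_per_group, seed = seed, ...),
                  n_rois = 4, duration = 8, n_snps = 24, n_blocks = 6,
                  block_r2 = 0.4, n_ref = 60)
}

test_that("identical truth and seed give byte-identical cohorts", {
  a <- small_cohort(7)
  b <- small_cohort(7)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c2 <- small_cohort(8)
  expect_false(identical(a$subjects$label, c2$subjects$label) &&
                 identical(a$signals$signals[[1]], c2$signals$signals[[1]]))
})

test_that("null configuration yields exchangeable groups", {
  co <- generate_cohort(cohort_truth(n_per_group = 40, seed = 3),
                        n_rois = 3, duration = 8, n_snps = 12, n_blocks = 4,
                        block_r2 = 0.3, n_ref = 40)
  is_rem <- co$subjects$label == "remitted"
  # group means of an arbitrary signal summary and of dosage differ only by
  # sampling noise (3 standard errors)
  rms <- vapply(co$signals$signals, function(m) sqrt(mean(m^2)), numeric(1))
  d <- mean(rms[is_rem]) - mean(rms[!is_rem])
  se <- sd(rms) * sqrt(2 / 40)
  expect_lt(abs(d), 3 * se)
  dose_mean <- rowMeans(co$genotypes$dosage)
  dd <- mean(dose_mean[is_rem]) - mean(dose_mean[!is_rem])
  expect_lt(abs(dd), 3 * sd(dose_mean) * sqrt(2 / 40))
})

test_that("a planted coherence effect reproduces its magnitude downstream", {
  eff <- tibble::tibble(roi_i = 1L, roi_j = 2L, band = "theta",
                        msc_continued = 0.2, msc_remitted = 0.6)
  subs <- make_subjects(50, seed = 4)
  set <- simulate_roi_signals(subs, eff, n_rois = 2, fs = 256, duration = 240,
                              seed = 5)
  est <- vapply(set$signals,
                function(x) estimate_band_coherence(x, 256)$theta[1, 2],
                numeric(1))
  is_rem <- subs$label == "remitted"
  gap <- mean(est[is_rem]) - mean(est[!is_rem])
  expect_equal(gap, 0.4, tolerance = 0.05)
})

test_that("increasing the coherence gap never decreases group separation", {
  subs <- make_subjects(25, seed = 6)
  sep <- vapply(c(0.2, 0.4, 0.6), function(target_gap) {
    eff <- tibble::tibble(roi_i = 1L, roi_j = 2L, band = "alpha",
                          msc_continued = 0.1,
                          msc_remitted = 0.1 + target_gap)
    set <- simulate_roi_signals(subs, eff, n_rois = 2, fs = 256,
                                duration = 60, seed = 7)
    est <- vapply(set$signals,
                  function(x) estimate_band_coherence(x, 256)$alpha[1, 2],
                  numeric(1))
    mean(est[subs$label == "remitted"]) - mean(est[subs$label == "continued"])
  }, numeric(1))
  expect_true(all(diff(sep) > 0))
})

test_that("invalid coherence targets are rejected naming the pair", {
  expect_error(
    cohort_truth(5, coherence_effects = tibble::tibble(
      roi_i = 1L, roi_j = 3L, band = "theta",
      msc_continued = 1.2, msc_remitted = 0.5)),
    "\\(1,3\\)@theta")
  subs <- make_subjects(2)
  expect_error(
    simulate_roi_signals(subs, tibble::tibble(
      roi_i = 2L, roi_j = 2L, band = "theta",
      msc_continued = 0.5, msc_remitted = 0.5), n_rois = 4, duration = 4),
    "roi_i != roi_j")
})

test_that("single strong LD block collapses to one clumped SNP", {
  subs <- make_subjects(30, seed = 8)
  g <- simulate_genetics(subs, NULL, n_snps = 5, n_blocks = 1, block_r2 = 0.9,
                         seed = 9, n_ref = 400)
  r2s <- cor(g$reference$dosage)^2
  expect_true(all(r2s[upper.tri(r2s)] >= 0.25))
  kept <- clump(g$summary_stats, g$reference)
  expect_length(kept, 1)
})

test_that("independent SNPs survive clumping in full", {
  subs <- make_subjects(30, seed = 10)
  g <- simulate_genetics(subs, NULL, n_snps = 8, n_blocks = 8, block_r2 = 0,
                         seed = 11, n_ref = 300)
  kept <- clump(g$summary_stats, g$reference)
  expect_setequal(kept, g$summary_stats$snp)
})

test_that("within-block dosage r2 is calibrated to its target", {
  subs <- make_subjects(250, seed = 12)
  g <- simulate_genetics(subs, NULL, n_snps = 6, n_blocks = 2, block_r2 = 0.5,
                         seed = 13, n_ref = 500)
  dos <- g$reference$dosage
  blocks <- list(1:3, 4:6)
  r2 <- unlist(lapply(blocks, function(ix) {
    m <- cor(dos[, ix])^2
    m[upper.tri(m)]
  }))
  expect_true(all(r2 > 0.38 & r2 < 0.62))
})

test_that("a causal SNP shifts the PRS between outcome groups", {
  subs <- make_subjects(500, seed = 14)
  causal <- tibble::tibble(snp = "rs_causal", log_odds = 0.5)
  g <- simulate_genetics(subs, causal, n_snps = 30, n_blocks = 6,
                         block_r2 = 0.3, seed = 15, n_ref = 200)
  kept <- clump(g$summary_stats, g$reference)
  expect_true("rs_causal" %in% kept)
  prs <- prs_scores(g$genotypes, g$summary_stats, kept, thresholds = 1e-4)
  sc <- prs[[2]]
  is_rem <- subs$label == "remitted"
  expect_gt(mean(sc[is_rem]), mean(sc[!is_rem]))
  expect_lt(t.test(sc[is_rem], sc[!is_rem])$p.value, 1e-3)
})

test_that("block_r2 = 1 with distinct within-block frequencies is rejected", {
  subs <- make_subjects(5)
  expect_error(
    simulate_genetics(subs, NULL, n_snps = 4, n_blocks = 2, block_r2 = 1,
                      allele_freqs = c(0.2, 0.4, 0.3, 0.3), seed = 1),
    "unattainable")
})

test_that("covariate odds ratios are realized empirically", {
  subs <- make_subjects(1000, seed = 16)
  demo <- simulate_demographics(subs, c(married = log(3)), seed = 17,
                                base_rates = list(married = 0.3))
  tab <- table(demo$label, demo$married)
  or <- (tab["remitted", "1"] / tab["remitted", "0"]) /
    (tab["continued", "1"] / tab["continued", "0"])
  expect_gt(or, 2.2)
  expect_lt(or, 4.1)
  # null covariate: rates equal within binomial error
  d0 <- simulate_demographics(subs, NULL, seed = 18)
  p <- tapply(d0$employed, d0$label, mean)
  expect_lt(abs(p[1] - p[2]), 3 * sqrt(2 * 0.6 * 0.4 / 1000))
})

test_that("age distributions are shared between groups", {
  subs <- make_subjects(688, seed = 19)
  demo <- simulate_demographics(subs, NULL, seed = 20)
  mu <- tapply(demo$age, demo$label, mean)
  expect_lt(abs(mu[1] - mu[2]), 1)
  expect_true(all(demo$age >= 18))
  expect_equal(mean(demo$age), 30.7, tolerance = 0.1 * 30.7)
})

test_that("cohort components share one subject universe", {
  co <- small_cohort(21, n_per_group = 4)
  ids <- co$subjects$subject_id
  expect_false(anyDuplicated(ids) > 0)
  expect_identical(names(co$signals$signals), ids)
  expect_identical(rownames(co$genotypes$dosage), ids)
  expect_identical(sort(table(co$subjects$label)), sort(table(c(
    rep("continued", 4), rep("remitted", 4)))))
  expect_true(all(co$truth$seed == 21))
})
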