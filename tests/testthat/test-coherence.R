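# Welch magnitude-squared coherence estimator and feature extraction.

test_that("identical channels give MSC exactly 1 in every band", {
  withr::with_seed(11, {
    x <- rnorm(256 * 20)
    m <- rbind(x, x)
    bc <- estimate_band_coherence(m, 256, default_bands())
    for (b in names(bc)) {
      expect_identical(dim(bc[[b]]), c(2L, 2L))
      expect_equal(bc[[b]][1, 2], 1, tolerance = 0)
      expect_equal(unname(diag(bc[[b]])), c(1, 1))
    }
  })
})

test_that("independent channels sit near the 1/K bias floor", {
  # 240 s at 256 Hz with 2 s Hann segments, 50% overlap: 239 segments, so
  # the independence bias should be well under 0.05
  msc <- withr::with_seed(21, {
    replicate(20, {
      m <- matrix(rnorm(2 * 256 * 240), 2)
      mean(unlist(lapply(estimate_band_coherence(m, 256), function(z) z[1, 2])))
    })
  })
  expect_lt(mean(msc), 0.05)
  expect_gt(mean(msc), 0) # strictly positive bias, never negative
})

test_that("estimator matches an independent Welch implementation (frozen oracle)", {
  # same construction evaluated with scipy.signal.coherence (hann, 512-sample
  # segments, 50% overlap, constant detrend); band means frozen at 6 decimals
  withr::with_seed(9, {
    n <- 256 * 60
    s <- rnorm(n)
    x <- 0.8 * s + 0.6 * rnorm(n)
    y <- 0.8 * s + 0.6 * rnorm(n)
    bc <- estimate_band_coherence(rbind(x, y), 256, default_bands())
    est <- vapply(bc, function(z) z[1, 2], numeric(1))
    expect_equal(unname(est),
                 c(0.377413, 0.457166, 0.432679, 0.424939),
                 tolerance = 1e-5)
  })
})

test_that("shared-component construction hits its closed-form band MSC", {
  subs <- make_subjects(25, seed = 2)
  eff <- tibble::tibble(roi_i = 1L, roi_j = 2L, band = "theta",
                        msc_continued = 0.25, msc_remitted = 0.25)
  set <- simulate_roi_signals(subs, eff, n_rois = 2, fs = 256, duration = 120,
                              seed = 3)
  est <- vapply(set$signals,
                function(x) estimate_band_coherence(x, 256)$theta[1, 2],
                numeric(1))
  expect_gt(mean(est), 0.20)
  expect_lt(mean(est), 0.30)
})

test_that("MSC is scale invariant, symmetric and in [0, 1]", {
  withr::with_seed(31, {
    m <- matrix(rnorm(3 * 256 * 10), 3)
    bc1 <- estimate_band_coherence(m, 256)
    m2 <- m * c(5, 0.01, 1000) # per-channel positive rescaling
    bc2 <- estimate_band_coherence(m2, 256)
    for (b in names(bc1)) {
      expect_equal(bc1[[b]], bc2[[b]], tolerance = 1e-12)
      expect_identical(bc1[[b]], t(bc1[[b]]))
      expect_true(all(bc1[[b]] >= 0 & bc1[[b]] <= 1))
    }
  })
})

test_that("independence bias decreases as segment count grows", {
  # K segments with 2 s segments and 50% overlap needs 512 + (K-1)*256 samples
  bias_at_k <- function(K) {
    n <- 512 + (K - 1) * 256
    mean(replicate(12, {
      m <- matrix(rnorm(2 * n), 2)
      mean(unlist(lapply(estimate_band_coherence(m, 256), function(z) z[1, 2])))
    }))
  }
  withr::with_seed(41, {
    b <- vapply(c(8, 32, 128), bias_at_k, numeric(1))
    expect_true(all(diff(b) < 0))
  })
})

test_that("estimate converges to the construction's closed form with duration", {
  # broadband shared component: theoretical MSC = alpha^4 in every bin, with
  # no band-edge effects, so the estimate must approach it as duration grows
  target <- 0.36
  alpha <- target^(1 / 4)
  err_at <- function(dur) {
    mean(replicate(8, {
      n <- 256 * dur
      s <- rnorm(n)
      x <- alpha * s + sqrt(1 - alpha^2) * rnorm(n)
      y <- alpha * s + sqrt(1 - alpha^2) * rnorm(n)
      bc <- estimate_band_coherence(rbind(x, y), 256)
      abs(mean(vapply(bc, function(z) z[1, 2], numeric(1))) - target)
    }))
  }
  withr::with_seed(51, {
    expect_lt(err_at(480), err_at(60))
  })
})

test_that("degenerate inputs are rejected with informative errors", {
  m <- matrix(rnorm(2 * 1024), 2, dimnames = list(c("precuneus", "insula"), NULL))
  m[2, ] <- 7 # constant channel
  expect_error(estimate_band_coherence(m, 256), "insula")
  m2 <- matrix(rnorm(2 * 1024), 2)
  m2[1, 5] <- NaN
  expect_error(estimate_band_coherence(m2, 256), "NaN")
  expect_error(estimate_band_coherence(matrix(rnorm(2 * 100), 2), 256),
               "too short")
})

test_that("feature naming, count and ordering follow the construction", {
  # 3 ROIs x 2 bands -> 6 features in band-major, pair-lexicographic order
  b2 <- default_bands()[1:2, ]
  nm <- remitpredict:::coherence_feature_names(c("A", "B", "C"), b2)
  expect_identical(nm, c("A-B@theta", "A-C@theta", "B-C@theta",
                         "A-B@alpha", "A-C@alpha", "B-C@alpha"))
  # 68 ROIs x 4 bands -> 4 * C(68,2) = 9112 features
  expect_length(remitpredict:::coherence_feature_names(dk_roi_names(),
                                                       default_bands()), 9112)
})

test_that("cohort feature extraction is subject-order invariant", {
  subs <- make_subjects(3, seed = 5)
  set <- simulate_roi_signals(subs, NULL, n_rois = 3, fs = 128, duration = 10,
                              seed = 6)
  f1 <- coherence_features(set)
  set_rev <- roi_ts_set(rev(set$signals), set$fs, set$roi_names)
  f2 <- coherence_features(set_rev)
  merged <- dplyr::inner_join(f1, f2, by = "subject_id",
                              suffix = c("_a", "_b"))
  feats <- setdiff(names(f1), "subject_id")
  for (fn in feats[c(1, 5, 9)]) {
    expect_equal(merged[[paste0(fn, "_a")]], merged[[paste0(fn, "_b")]])
  }
  # values live in [0,1] and matrices contribute C(3,2) features per band
  expect_identical(ncol(f1), 1L + 4L * 3L)
  expect_true(all(as.matrix(f1[, -1]) >= 0 & as.matrix(f1[, -1]) <= 1))
})

test_that("band definitions reject overlap and bad edges", {
  expect_error(band_definitions("a", 0, 4), "0 < low")
  expect_error(band_definitions(c("a", "b"), c(4, 6), c(8, 10)), "overlap")
  expect_silent(band_definitions(c("a", "b"), c(4, 8), c(8, 12)))
})
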