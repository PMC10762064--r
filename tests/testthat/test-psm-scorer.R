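test_that("peak matching uses a ppm window around the closest peak", {
  theo <- data.frame(mz = 500.000, intensity = 1, series = "y")
  sp_near <- base_peak_normalize(spectrum("a", 500.005, 10, 600, 2L))
  expect_equal(match_peaks(theo, sp_near, 20)$matched, 1)   # 0.005 < 0.01
  sp_far <- base_peak_normalize(spectrum("b", 500.020, 10, 600, 2L))
  expect_equal(match_peaks(theo, sp_far, 20)$matched, 0)    # 0.020 > 0.01
  # the closest of several in-window peaks is assigned
  sp_two <- base_peak_normalize(
    spectrum("c", c(500.004, 500.008), c(5, 10), 600, 2L))
  expect_equal(match_peaks(theo, sp_two, 20)$matched, 0.5)  # 500.004 peak
})

test_that("enlarging the tolerance never unmatches a peak", {
  set.seed(37)
  for (i in 1:20) {
    theo <- data.frame(mz = runif(15, 100, 1900), intensity = runif(15),
                       series = "y")
    sp <- base_peak_normalize(
      spectrum("m", runif(40, 100, 1900), runif(40), 900, 2L))
    m10 <- match_peaks(theo, sp, 10)$matched
    m40 <- match_peaks(theo, sp, 40)$matched
    expect_true(all(m40[m10 > 0] > 0))
  }
})

test_that("the spectral angle has its closed-form values", {
  expect_equal(spectral_angle(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(spectral_angle(c(1, 0), c(0, 1)), 0)
  expect_equal(spectral_angle(c(1, 1), c(1, 0)),
               1 - 2 * acos(1 / sqrt(2)) / pi)   # = 0.5
  expect_equal(spectral_angle(c(1, 1), c(1, 0)),
               spectral_angle(c(1, 0), c(1, 1)))
  z <- spectral_angle(c(0, 0), c(1, 0))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))
})

test_that("the feature registry has 114 unique names", {
  reg <- feature_registry()
  expect_length(reg, 114)
  expect_false(any(duplicated(reg)))
  # family bookkeeping: 26 + 8 per ion group, 12 change counts
  expect_length(grep("_all$", reg), 34)
  expect_length(grep("^changes_", reg), 12)
})

test_that("features of a perfect match are perfect", {
  p <- "PEPTIDEK"
  sp <- noiseless_spectrum(p, 2L)
  model <- init_reclassifier(reclass_config(max_mz = 2000L))
  f <- extract_features(sp, p, model)
  expect_length(f, 114)
  expect_identical(names(f), feature_registry())
  expect_equal(unname(f["spectral_angle_all"]), 1, tolerance = 1e-9)
  expect_equal(unname(f["n_theo1_exp0_all"]), 0)
  expect_equal(unname(f["absdiff_max_y"]), 0, tolerance = 1e-12)
})

test_that("change-count features use a strict threshold", {
  p <- "PEPTIDEK"
  sp <- noiseless_spectrum(p, 2L)
  model <- init_reclassifier(reclass_config(max_mz = 2000L))
  model$params$head$W[] <- 0
  model$params$head$b[] <- 0       # p = 0.5 everywhere
  f <- extract_features(sp, p, model)
  expect_equal(unname(f["changes_y_t50"]), 0)   # 0.5 > 0.5 is FALSE
  expect_gt(unname(f["changes_y_t45"]), 0)
})

test_that("features are invariant to peak order and intensity scale", {
  p <- "PEPTIDEK"
  sp <- noiseless_spectrum(p, 2L)
  set.seed(41)
  o <- sample(length(sp$mz))
  sp_perm <- spectrum(sp$spectrum_id, sp$mz[o], sp$intensity[o] * 37.5,
                      sp$precursor_mz, sp$precursor_charge)
  model <- init_reclassifier(reclass_config(max_mz = 2000L))
  expect_equal(extract_features(sp, p, model),
               extract_features(sp_perm, p, model))
  expect_error(extract_features(sp, "GAGAK", model), "eligible")
})

test_that("the scorer rejects degenerate targets and recovers the
           regression baseline on constant features", {
  X <- matrix(1, 60, 114)
  expect_error(train_scorer(X, rep(2, 60)), "single-valued")
  set.seed(43)
  d <- sample(0:5, 60, replace = TRUE)
  sc <- train_scorer(X, d, num.trees = 20L)
  pred <- predict(sc, X)
  targ <- log2(d + 1)
  # trees see only bootstrap means, so the forest predicts near-constant
  expect_equal(pred, rep(mean(targ), 60), tolerance = 0.05)
  rmse <- sqrt(mean((pred - targ)^2))
  expect_equal(rmse, sqrt(mean((targ - mean(targ))^2)), tolerance = 0.02)
})

test_that("PSM ranking is ascending, stable and sentinels ineligible
           candidates", {
  p <- "PEPTIDEK"
  sp <- noiseless_spectrum(p, 2L)
  swapped <- peptide_string(seqmend:::.corrupt_swap(parse_peptide(p)))
  model <- init_reclassifier(reclass_config(max_mz = 2000L))
  set.seed(47)
  Xtr <- matrix(runif(80 * 114), 80)
  sc <- train_scorer(Xtr, sample(0:4, 80, replace = TRUE), num.trees = 10L)
  psms <- data.frame(
    spectrum_id = sp$spectrum_id,
    peptide = c(p, swapped, strrep("A", 31)),
    tool = c("a", "b", "c"))
  out <- score_psms(psms, list(sp), sc, model)
  expect_identical(out$rank, 1:3)
  expect_true(all(diff(out$score) >= 0))
  expect_identical(out$peptide[3], strrep("A", 31))  # sentinel ranks last
  expect_identical(out$score[3], Inf)
})
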