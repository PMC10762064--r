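test_that("the noiseless limit reproduces every theoretical ion", {
  cfg <- sim_config(num_peptides = 5L, dropout = 0, contamination_rate = 0,
                    jitter_ppm = 0, seed = 51)
  sim <- simulate_dataset(cfg)
  for (i in seq_along(sim$spectra)) {
    s <- sim$spectra[[i]]
    ions <- surrogate_predict(sim$truth$peptide[i], sim$truth$charge[i])
    expect_equal(length(s$mz), nrow(ions))
    expect_equal(sort(s$mz), sort(ions$mz), tolerance = 1e-9)
    # and, after the shared 0.02 intensity floor, the spectral angle
    # against the true peptide's prediction is 1
    ions$intensity[ions$intensity < 0.02] <- 0
    f <- spectral_angle(
      match_peaks(ions, base_peak_normalize(s), 20)$matched,
      ions$intensity)
    expect_equal(as.numeric(f), 1, tolerance = 1e-6)
  }
})

test_that("fixed seeds give byte-identical simulated files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- sim_config(num_peptides = 15L, seed = 53)
  simulate_dataset(cfg, dir = d1)
  simulate_dataset(cfg, dir = d2)
  for (f in c("spectra.mgf", "truth.tsv", "candidates.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("simulated peptides are tryptic and length-bounded", {
  sim <- simulate_dataset(sim_config(num_peptides = 40L, seed = 57))
  lens <- nchar(gsub("M\\(ox\\)", "m", sim$truth$peptide))
  expect_true(all(lens >= 7 & lens <= 30))
  last <- vapply(sim$truth$peptide, function(p) {
    t <- parse_peptide(p)
    t[length(t)]
  }, "")
  expect_true(all(last %in% c("K", "R")))
  expect_false(any(duplicated(sim$truth$peptide)))
  expect_error(simulate_dataset(sim_config(length_range = c(10, 7))),
               "length range")
})

test_that("corruption preserves mass within tolerance and records true
           distances", {
  sim <- simulate_dataset(sim_config(num_peptides = 60L, seed = 59))
  cand <- sim$candidates
  truth_of <- setNames(sim$truth$peptide, sim$truth$spectrum_id)
  for (i in which(cand$tool == "sim_corrupt")) {
    truth_p <- truth_of[[cand$spectrum_id[i]]]
    expect_identical(cand$true_distance[i],
                     levenshtein(cand$peptide[i], truth_p))
    expect_gt(cand$true_distance[i], 0)
    rel <- abs(peptide_mass(cand$peptide[i]) - peptide_mass(truth_p)) /
      peptide_mass(truth_p) * 1e6
    expect_lte(rel, 20 + 1e-9)
  }
  expect_true(all(cand$true_distance[cand$tool == "sim_true"] == 0))
})

test_that("an adjacent swap of distinct residues has edit distance 2", {
  set.seed(61)
  for (i in 1:20) {
    p <- random_peptide(10)
    sw <- seqmend:::.corrupt_swap(p)
    expect_identical(levenshtein(p, sw), 2L)
    expect_equal(peptide_mass(sw), peptide_mass(p))
  }
})

test_that("dropout monotonically removes matchable peaks", {
  counts <- vapply(c(0, 0.3, 0.7), function(dr) {
    sim <- simulate_dataset(sim_config(num_peptides = 25L, dropout = dr,
                                       contamination_rate = 0,
                                       jitter_ppm = 0, seed = 63))
    sum(vapply(sim$spectra, function(s) length(s$mz), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(counts) < 0))
})

test_that("splits group by peptide and respect the fractions", {
  sim <- simulate_dataset(sim_config(num_peptides = 50L, seed = 67))
  set.seed(1)
  sp <- split_dataset(sim$truth)
  expect_setequal(unlist(sp), sim$truth$spectrum_id)
  # duplicate-peptide spectra always travel together
  truth_dup <- data.frame(spectrum_id = sprintf("s%02d", 1:9),
                          peptide = rep(c("AAPEPK", "LLPEPK", "GGPEPK"),
                                        each = 3))
  set.seed(2)
  spd <- split_dataset(truth_dup, c(0.4, 0.3, 0.3))
  for (part in spd) {
    peps <- truth_dup$peptide[truth_dup$spectrum_id %in% part]
    expect_true(all(table(peps) %in% c(0, 3)))
  }
  expect_identical(sort(split_dataset(sim$truth, c(1, 0, 0))$train),
                   sort(sim$truth$spectrum_id))
  # 80/10/10 on 1000 unique peptides lands within one of the targets
  big <- data.frame(spectrum_id = sprintf("b%04d", 1:1000),
                    peptide = sprintf("PEP%04dK", 1:1000))
  set.seed(3)
  spb <- split_dataset(big)
  expect_lte(abs(length(spb$train) - 800), 1)
  expect_lte(abs(length(spb$validation) - 100), 1)
  expect_lte(abs(length(spb$test) - 100), 1)
  expect_error(split_dataset(big, c(0.5, 0.5, 0.1)), "sum to 1")
})
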