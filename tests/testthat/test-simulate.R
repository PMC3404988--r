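test_that("generators are deterministic given a seed", {
  r1 <- simulate_reference_set(n_clades = 3, seq_length = 500, seed = 91)
  r2 <- simulate_reference_set(n_clades = 3, seq_length = 500, seed = 91)
  expect_identical(r1, r2)
  r3 <- simulate_reference_set(n_clades = 3, seq_length = 500, seed = 92)
  expect_false(identical(r1$seq, r3$seq))

  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_reference_fasta(r1, f1)
  write_reference_fasta(r2, f2)
  expect_identical(readLines(f1), readLines(f2))

  c1 <- simulate_clone_library(r1, c(A = 0.5, B = 0.5), 20, seed = 93)
  c2 <- simulate_clone_library(r1, c(A = 0.5, B = 0.5), 20, seed = 93)
  expect_identical(c1, c2)
  expect_error(simulate_clone_library(r1, c(A = 1), 5),
               class = "trflpr_input_error") # seed is mandatory
})

test_that("reference geometry encodes the requested T-RF lengths", {
  refs <- simulate_reference_set(n_clades = 1, seq_length = 500, seed = 94)
  preds <- predict_trf_refs(refs)
  expect_equal(length(unique(preds$trf_bp)), 1)
  expect_true(all(preds$cut))

  refs2 <- simulate_reference_set(n_clades = 4, seq_length = 700,
                                  trf_targets = c(306L, 331L, 150L, 260L),
                                  seed = 95)
  preds2 <- predict_trf_refs(refs2)
  got <- preds2 |> dplyr::distinct(clade, trf_bp)
  expect_equal(setNames(got$trf_bp, got$clade),
               c(A = 306L, B = 331L, C = 150L, D = 260L))
  # within-clade divergence never moves the first cut site
  expect_equal(nrow(got), 4)

  expect_error(simulate_reference_set(n_clades = 2, seq_length = 300,
                                      trf_targets = c(500L, 600L), seed = 1),
               class = "trflpr_config_error")
})

test_that("clone libraries follow the mixture multinomially", {
  refs <- simulate_reference_set(n_clades = 2, seq_length = 500, seed = 96)
  pure <- simulate_clone_library(refs, c(A = 1), 10, pcr_error_rate = 0,
                                 seed = 97)
  expect_true(all(pure$seq %in% refs$seq[refs$clade == "A"]))

  mixed <- simulate_clone_library(refs, c(A = 0.7, B = 0.3), 200,
                                  pcr_error_rate = 0, seed = 98)
  nA <- sum(mixed$clade_true == "A")
  expect_gte(nA, qbinom(0.025, 200, 0.7))
  expect_lte(nA, qbinom(0.975, 200, 0.7))
  expect_error(simulate_clone_library(refs, c(A = 1), 0, seed = 1),
               class = "trflpr_input_error")
})

test_that("the chimera screen recovers the injected chimera fraction", {
  refs <- simulate_reference_set(n_clades = 4, seq_length = 600,
                                 between_divergence = 0.03, seed = 99)
  clones <- simulate_clone_library(refs, c(A = 0.25, B = 0.25, C = 0.25, D = 0.25),
                                   400, pcr_error_rate = 0.001,
                                   chimera_rate = 0.05, seed = 100)
  scr <- chimera_screen(clones, refs)
  frac <- mean(scr$flagged)
  sigma <- sqrt(0.05 * 0.95 / 400)
  expect_lte(abs(frac - 0.05), 2 * sigma + mean(clones$is_chimera) - 0.05 + 0.01)
  # flags line up with the truth labels almost perfectly
  expect_gte(mean(scr$flagged == clones$is_chimera), 0.97)
})

test_that("dedup plus nearest-reference assignment recovers true clade labels", {
  refs <- simulate_reference_set(n_clades = 4, seq_length = 600,
                                 within_divergence = 0.002, seed = 101)
  clones <- simulate_clone_library(refs, c(A = 0.4, B = 0.3, C = 0.2, D = 0.1),
                                   100, pcr_error_rate = 0.001, seed = 102)
  reps <- dedup_clones(clones[, c("id", "seq")])
  # score every clone through its representative's nearest reference clade
  assign_clade <- function(s) {
    d <- vapply(seq_len(nrow(refs)), function(i) p_distance(s, refs$seq[i]),
                numeric(1))
    refs$clade[which.min(d)]
  }
  rep_clade <- vapply(reps$seq, assign_clade, character(1))
  lookup <- setNames(rep(rep_clade, lengths(reps$member_ids)),
                     unlist(reps$member_ids))
  acc <- mean(lookup[clones$id] == clones$clade_true)
  expect_gte(acc, 0.95)
})

test_that("zero-noise electropherograms hit the predicted lengths exactly", {
  refs <- simulate_reference_set(n_clades = 3, seq_length = 600, seed = 103)
  pk <- simulate_electropherogram(refs, c(A = 1), height_cv = 0,
                                  size_jitter = 0, seed = 104)
  expect_equal(nrow(pk), 1)
  truth <- attr(pk, "truth")
  expect_equal(pk$size_bp, truth$trf_bp)
})

test_that("injected out-of-window noise peaks are removed by QC", {
  refs <- simulate_reference_set(n_clades = 2, seq_length = 600, seed = 105)
  pk <- simulate_electropherogram(refs, c(A = 0.6, B = 0.4), noise_peaks = 4,
                                  seed = 106)
  expect_equal(nrow(pk), 6)
  kept <- qc_chromatograms(pk)
  expect_equal(nrow(kept), 2)
  expect_true(all(kept$size_bp >= 100 & kept$size_bp <= 1200))
})

test_that("isotope simulation plus group estimation is unbiased", {
  means <- vapply(1:500, function(r) {
    iso <- simulate_aa_isotopes(1.5, n = 5, noise_sd = 0.3, seed = 5000 + r)
    group_tp(iso)$tp_mean
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lte(abs(mean(means) - 1.5), 3 * se)
})
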