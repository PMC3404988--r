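peak_row <- function(sample_id, size, height, qv = 90, month = "2005-06") {
  tibble::tibble(sample_id = sample_id, month = month, size_bp = size,
                 height = height, qv = qv)
}

cats_toy <- tibble::tibble(
  category = c("Prsp/Habo", "Rhle", "Casp"),
  clades = list(c("A", "D"), "B", "F"),
  trf_lengths = list(306L, 331L, c(191L, 291L)),
  n_clades = c(2L, 1L, 1L)
)

test_that("QC drops out-of-window peaks and whole low-quality chromatograms", {
  peaks <- dplyr::bind_rows(
    peak_row("s1", c(95, 306.2, 1250), c(10, 100, 20), qv = 80),
    peak_row("s2", c(306.2, 331.1), c(50, 60), qv = 75),   # qv == 75 rejected
    peak_row("s3", numeric(0), numeric(0), qv = 90)
  )
  kept <- qc_chromatograms(peaks)
  expect_setequal(unique(kept$sample_id), "s1")
  expect_equal(kept$size_bp, 306.2)
  rej <- attr(kept, "rejected")
  expect_equal(rej$sample_id, "s2")
  # boundary sizes are retained (inclusive window)
  edge <- qc_chromatograms(peak_row("e", c(100, 1200), c(5, 5), qv = 90))
  expect_equal(nrow(edge), 2)
})

test_that("peaks match the nearest category within tolerance", {
  asg <- assign_peaks(peak_row("s1", c(306.4, 500.0), c(10, 10)), cats_toy)
  expect_equal(asg$category, c("Prsp/Habo", NA))
  expect_false(any(asg$ambiguous))
  # both subtypes of a two-T-RF clade land in the same category
  asg2 <- assign_peaks(peak_row("s1", c(191.2, 290.9), c(5, 5)), cats_toy)
  expect_equal(asg2$category, c("Casp", "Casp"))
  expect_error(assign_peaks(peak_row("s1", 306, 1), cats_toy[0, ]),
               class = "trflpr_input_error")
})

test_that("equidistant peaks are flagged ambiguous and left unassigned", {
  cats2 <- tibble::tibble(category = c("L", "R"), clades = list("L", "R"),
                          trf_lengths = list(100L, 102L), n_clades = c(1L, 1L))
  asg <- assign_peaks(peak_row("s1", 101, 10), cats2, tolerance = 1.5)
  expect_true(asg$ambiguous)
  expect_true(is.na(asg$category))
})

test_that("assignment ignores peak order and never grows when tolerance shrinks", {
  set.seed(61)
  peaks <- peak_row("s1", runif(30, 100, 400), runif(30, 10, 100))
  a1 <- assign_peaks(peaks, cats_toy, tolerance = 1.5)
  a2 <- assign_peaks(peaks[sample(30), ], cats_toy, tolerance = 1.5) |>
    dplyr::arrange(size_bp)
  expect_equal(dplyr::arrange(a1, size_bp)$category, a2$category)
  for (tol in c(1.0, 0.5, 0.1)) {
    expect_lte(sum(!is.na(assign_peaks(peaks, cats_toy, tolerance = tol)$category)),
               sum(!is.na(a1$category)))
  }
})

test_that("relative abundance follows the peak-height formula", {
  one <- relative_abundance(
    assign_peaks(peak_row("s1", 306.0, 42), cats_toy))
  expect_equal(one$ra_pct, 100)

  two <- relative_abundance(
    assign_peaks(peak_row("s1", c(306, 331), c(30, 70)), cats_toy))
  expect_equal(two$ra_pct[two$category == "Prsp/Habo"], 30)
  expect_equal(two$ra_pct[two$category == "Rhle"], 70)

  three <- relative_abundance(
    assign_peaks(peak_row("s1", c(306, 331, 191), c(50, 30, 20)), cats_toy))
  expect_equal(sum(three$ra_pct), 100)
  expect_equal(sort(three$ra_pct), c(20, 30, 50))

  expect_error(relative_abundance(
    assign_peaks(peak_row("s1", 306, 0), cats_toy)),
    class = "trflpr_undefined_profile")
})

test_that("unassigned height stays in the denominator and closes the profile to 100", {
  asg <- assign_peaks(peak_row("s1", c(306, 500), c(60, 40)), cats_toy)
  prof <- relative_abundance(asg)
  expect_equal(prof$ra_pct[prof$category == "Prsp/Habo"], 60)
  expect_equal(prof$ra_pct[prof$category == "(unassigned)"], 40)
  expect_equal(sum(prof$ra_pct), 100, tolerance = 1e-9)
  # alternative reading: drop unassigned from the total
  prof2 <- relative_abundance(asg, drop_unassigned_from_total = TRUE)
  expect_equal(prof2$ra_pct, 100)
})

test_that("profiles always sum to 100 under random peak sets", {
  set.seed(62)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    peaks <- peak_row("s", runif(n, 100, 400), runif(n, 1, 100))
    prof <- relative_abundance(assign_peaks(peaks, cats_toy))
    expect_equal(sum(prof$ra_pct), 100, tolerance = 1e-9)
    expect_true(all(prof$ra_pct >= 0 & prof$ra_pct <= 100))
  }
})

test_that("monthly summaries report five numbers, counts and low-n flags", {
  profiles <- tibble::tibble(
    sample_id = c("a", "b", "c", "d", "e"),
    month = c("2005-06", "2005-06", "2005-06", "2005-08", "2005-08"),
    category = "X",
    ra_pct = c(10, 20, 30, 50, 70)
  )
  agg <- aggregate_by_month(profiles)
  jun <- agg[agg$month == "2005-06", ]
  expect_equal(jun$median, 20)
  expect_equal(jun$min, 10)
  expect_equal(jun$max, 30)
  expect_false(jun$low_n)
  aug <- agg[agg$month == "2005-08", ]
  expect_true(aug$low_n)
  expect_match(attr(agg, "quartile_convention"), "linear interpolation")
  empty <- aggregate_by_month(profiles[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("samples without a detected category enter monthly summaries as zeros", {
  profiles <- tibble::tibble(
    sample_id = c("a", "a", "b"),
    month = "2005-06",
    category = c("X", "Y", "X"),
    ra_pct = c(60, 40, 100)
  )
  agg <- aggregate_by_month(profiles)
  y <- agg[agg$category == "Y", ]
  expect_equal(y$min, 0)  # sample b had no Y peak
  expect_equal(y$n, 2)
})

test_that("inconsistent per-sample quality values are a schema error", {
  bad <- dplyr::bind_rows(peak_row("s1", 306, 10, qv = 80),
                          peak_row("s1", 331, 10, qv = 90))
  expect_error(qc_chromatograms(bad), class = "trflpr_schema_error")
})
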