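# Electropherogram peak QC, peak-to-category assignment, relative-abundance
# profiles and monthly aggregation.
#
# Peak tables are plain tibbles with one row per peak and columns
# sample_id, month, size_bp, height, qv (qv repeated within a sample).

validate_peak_table <- function(peaks) {
  need <- c("sample_id", "month", "size_bp", "height", "qv")
  missing <- setdiff(need, names(peaks))
  if (length(missing) > 0) {
    abort(sprintf("peak table is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "trflpr_schema_error")
  }
  if (any(peaks$size_bp <= 0, na.rm = TRUE)) abort("size_bp must be positive")
  if (any(peaks$height < 0, na.rm = TRUE)) abort("height must be non-negative")
  bad <- peaks |>
    group_by(.data$sample_id) |>
    summarise(n_qv = dplyr::n_distinct(.data$qv), .groups = "drop") |>
    filter(.data$n_qv > 1)
  if (nrow(bad) > 0) {
    abort(sprintf("inconsistent qv within sample(s): %s",
                  paste(bad$sample_id, collapse = ", ")),
          class = "trflpr_schema_error")
  }
  invisible(peaks)
}

#' Quality-control electropherogram peak tables
#'
#' Whole chromatograms are rejected unless their quality value exceeds
#' `qv_min` (strictly, QV > 75 by default), and surviving peaks outside the
#' `[size_min, size_max]` bp window are discarded as noise (primer artefacts
#' below 100 bp, beyond-standard fragments above 1200 bp).
#'
#' @param peaks Peak table (`sample_id`, `month`, `size_bp`, `height`, `qv`).
#' @param qv_min Chromatogram quality threshold (retain iff `qv > qv_min`).
#' @param size_min,size_max Retained fragment-size window in bp (inclusive).
#' @return The filtered peak table; rejected sample ids (with their qv) are
#'   attached as attribute `"rejected"`.
#' @export
qc_chromatograms <- function(peaks, qv_min = 75, size_min = 100,
                             size_max = 1200) {
  validate_peak_table(peaks)
  samples <- peaks |> distinct(.data$sample_id, .data$qv)
  rejected <- samples |> filter(.data$qv <= qv_min)
  kept <- peaks |>
    filter(.data$qv > qv_min,
           .data$size_bp >= size_min, .data$size_bp <= size_max) |>
    as_tibble()
  attr(kept, "rejected") <- as_tibble(rejected)
  kept
}

#' Assign peaks to predicted T-RF categories
#'
#' Each peak is matched to the category with the nearest predicted T-RF
#' length, provided it lies within `tolerance` bp. A category carrying
#' several lengths (e.g. a clade with two restriction subtypes) matches on
#' any of them. Peaks exactly equidistant from two categories are flagged
#' ambiguous and left unassigned; peaks with no prediction in range are
#' unassigned.
#'
#' @param peaks QC'd peak table.
#' @param categories Category table from [trf_categories()].
#' @param tolerance Maximum |observed - predicted| in bp (default 1.5).
#' @return The peak table with added columns `category` (`NA` when
#'   unassigned) and `ambiguous`.
#' @export
assign_peaks <- function(peaks, categories, tolerance = 1.5) {
  if (!is.data.frame(categories) || nrow(categories) == 0) {
    abort("categories must be a non-empty prediction table",
          class = "trflpr_input_error")
  }
  lengths_tbl <- categories |>
    select(all_of(c("category", "trf_lengths"))) |>
    tidyr::unnest("trf_lengths") |>
    rename(pred_bp = "trf_lengths")

  assign_one <- function(size) {
    dd <- abs(lengths_tbl$pred_bp - size)
    in_tol <- which(dd <= tolerance)
    if (length(in_tol) == 0) return(list(cat = NA_character_, amb = FALSE))
    best <- min(dd[in_tol])
    cats <- unique(lengths_tbl$category[in_tol][dd[in_tol] <= best + 1e-9])
    if (length(cats) > 1) return(list(cat = NA_character_, amb = TRUE))
    list(cat = cats, amb = FALSE)
  }
  res <- purrr::map(peaks$size_bp, assign_one)
  peaks |>
    mutate(category = purrr::map_chr(res, "cat"),
           ambiguous = purrr::map_lgl(res, "amb")) |>
    as_tibble()
}

#' Relative-abundance profiles from assigned peaks
#'
#' Per sample, RA(%) = height of a category's peaks / total height of all
#' retained peaks x 100. Unassigned peaks stay in the denominator and are
#' reported as the pseudo-category `"(unassigned)"` so each sample's rows sum
#' to 100.
#'
#' @param assigned Peak table with a `category` column from [assign_peaks()].
#' @param drop_unassigned_from_total If `TRUE`, unassigned peaks are removed
#'   from the denominator instead (alternative reading of the RA formula).
#' @return A long tibble `sample_id`, `month`, `category`, `ra_pct`.
#' @export
relative_abundance <- function(assigned, drop_unassigned_from_total = FALSE) {
  stopifnot(all(c("sample_id", "month", "height", "category") %in% names(assigned)))
  if (drop_unassigned_from_total) {
    assigned <- assigned |> filter(!is.na(.data$category))
  }
  totals <- assigned |>
    group_by(.data$sample_id) |>
    summarise(h_total = sum(.data$height), .groups = "drop")
  if (any(totals$h_total <= 0)) {
    abort(sprintf("profile undefined: zero total peak height in sample(s) %s",
                  paste(totals$sample_id[totals$h_total <= 0], collapse = ", ")),
          class = "trflpr_undefined_profile")
  }
  assigned |>
    mutate(category = dplyr::coalesce(.data$category, "(unassigned)")) |>
    group_by(.data$sample_id, .data$month, .data$category) |>
    summarise(h = sum(.data$height), .groups = "drop") |>
    left_join(totals, by = "sample_id") |>
    mutate(ra_pct = 100 * .data$h / .data$h_total) |>
    select(all_of(c("sample_id", "month", "category", "ra_pct"))) |>
    arrange(.data$sample_id, .data$category)
}

#' Widen a long profile table into a sample x category matrix
#'
#' @param profiles Long profile tibble from [relative_abundance()].
#' @return A wide tibble, one row per sample, categories as columns
#'   (absent categories filled with 0).
#' @export
profile_matrix <- function(profiles) {
  profiles |>
    tidyr::pivot_wider(names_from = "category", values_from = "ra_pct",
                       values_fill = 0) |>
    arrange(.data$sample_id)
}

#' Monthly five-number summaries of relative abundance
#'
#' Summarises profiles per collection month and category with the Tukey
#' boxplot statistics (min, Q1, median, Q3, max). Samples in which a
#' category was not detected count as 0%. Months with fewer than three
#' samples are flagged low-n. Quartiles use linear interpolation between
#' order statistics (type 7); the convention is recorded in the
#' `"quartile_convention"` attribute.
#'
#' @param profiles Long profile tibble.
#' @param min_n Months with fewer samples than this are flagged (default 3).
#' @return A tibble `month`, `category`, `n`, `min`, `q1`, `median`, `q3`,
#'   `max`, `low_n`.
#' @export
aggregate_by_month <- function(profiles, min_n = 3) {
  if (nrow(profiles) == 0) {
    out <- tibble(month = character(0), category = character(0),
                  n = integer(0), min = numeric(0), q1 = numeric(0),
                  median = numeric(0), q3 = numeric(0), max = numeric(0),
                  low_n = logical(0))
    attr(out, "quartile_convention") <- "linear interpolation (stats::quantile type 7)"
    return(out)
  }
  filled <- profiles |>
    tidyr::complete(tidyr::nesting(!!rlang::sym("sample_id"), !!rlang::sym("month")),
                    !!rlang::sym("category"), fill = list(ra_pct = 0))
  out <- filled |>
    group_by(.data$month, .data$category) |>
    summarise(
      n = dplyr::n_distinct(.data$sample_id),
      min = min(.data$ra_pct),
      q1 = quantile(.data$ra_pct, 0.25, type = 7, names = FALSE),
      median = quantile(.data$ra_pct, 0.5, type = 7, names = FALSE),
      q3 = quantile(.data$ra_pct, 0.75, type = 7, names = FALSE),
      max = max(.data$ra_pct),
      .groups = "drop"
    ) |>
    mutate(low_n = .data$n < min_n) |>
    arrange(.data$month, .data$category)
  attr(out, "quartile_convention") <- "linear interpolation (stats::quantile type 7)"
  out
}
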