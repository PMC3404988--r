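# File-in/file-out orchestration of the four analysis stages plus data
# generation. Each run_* function wraps the in-memory API, writes TSV/CSV
# outputs and a JSON metadata sidecar recording every threshold and seed so
# runs are auditable and, with fixed inputs and seed, byte-identical.

write_run_metadata <- function(out_dir, stage, params) {
  meta <- c(list(stage = stage, package_version = as.character(utils::packageVersion("trflpr"))),
            params)
  jsonlite::write_json(meta, file.path(out_dir, paste0(stage, "_metadata.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Design stage: T-RF predictions and enzyme ranking from references
#'
#' @param ref_fasta Path to the reference FASTA (clades tagged `clade=X`).
#' @param out_dir Output directory (created if needed).
#' @param enzymes List of `trf_enzyme` objects to screen (default: TaiI only).
#' @param tolerance Size tolerance in bp for category merging.
#' @param primers Primer pair.
#' @return Invisibly, a list with `predictions`, `categories`, `ranking`.
#' @export
run_design <- function(ref_fasta, out_dir, enzymes = list(tai1()),
                       tolerance = 1.5, primers = trbcl_primers()) {
  refs <- read_reference_fasta(ref_fasta)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ranking <- screen_enzymes(refs, enzymes, tolerance = tolerance,
                            fwd = primers$fwd, rev = primers$rev)
  best <- enzymes[[which(vapply(enzymes, `[[`, character(1), "name") == ranking$enzyme[1])]]
  preds <- predict_trf_refs(refs, fwd = primers$fwd, rev = primers$rev,
                            enzyme = best)
  cats <- trf_categories(preds, tolerance = tolerance)
  readr::write_tsv(preds, file.path(out_dir, "trf_predictions.tsv"))
  write_trf_report(cats, file.path(out_dir, "trf_categories.tsv"))
  readr::write_tsv(ranking, file.path(out_dir, "enzyme_ranking.tsv"))
  write_run_metadata(out_dir, "design",
                     list(ref_fasta = ref_fasta, tolerance = tolerance,
                          enzymes = vapply(enzymes, `[[`, character(1), "name"),
                          best_enzyme = best$name))
  invisible(list(predictions = preds, categories = cats, ranking = ranking))
}

#' Profile stage: QC, peak assignment and relative abundance
#'
#' @param peak_file Path to the peak table (CSV/TSV).
#' @param categories Category table from [trf_categories()] (or the
#'   `categories` element of [run_design()]).
#' @param out_dir Output directory.
#' @param qv_min,size_min,size_max QC thresholds.
#' @param tolerance Peak-to-category match tolerance in bp.
#' @return Invisibly, a list with `profiles` (long), `matrix` (wide) and
#'   `monthly` summaries.
#' @export
run_profile <- function(peak_file, categories, out_dir, qv_min = 75,
                        size_min = 100, size_max = 1200, tolerance = 1.5) {
  peaks <- read_peak_table(peak_file)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  kept <- qc_chromatograms(peaks, qv_min = qv_min, size_min = size_min,
                           size_max = size_max)
  rejected <- attr(kept, "rejected")
  if (nrow(kept) == 0) {
    warn(sprintf("no chromatograms passed QC (%d rejected)", nrow(rejected)))
    profiles <- tibble(sample_id = character(0), month = character(0),
                       category = character(0), ra_pct = numeric(0))
  } else {
    assigned <- assign_peaks(kept, categories, tolerance = tolerance)
    profiles <- relative_abundance(assigned)
  }
  monthly <- aggregate_by_month(profiles)
  readr::write_tsv(profiles, file.path(out_dir, "profiles_long.tsv"))
  readr::write_tsv(profile_matrix(profiles), file.path(out_dir, "profiles_matrix.tsv"))
  readr::write_tsv(monthly, file.path(out_dir, "monthly_summary.tsv"))
  write_run_metadata(out_dir, "profile",
                     list(peak_file = peak_file, qv_min = qv_min,
                          size_min = size_min, size_max = size_max,
                          tolerance = tolerance,
                          n_samples_rejected = nrow(rejected),
                          quartile_convention = attr(monthly, "quartile_convention")))
  invisible(list(profiles = profiles, matrix = profile_matrix(profiles),
                 monthly = monthly))
}

#' Test stage: month-to-month shift in one category
#'
#' @param profile_file Path to the long profile TSV written by
#'   [run_profile()].
#' @param category,month_a,month_b What to compare.
#' @param out_dir Output directory.
#' @param n_perm,seed Permutation settings (seed required for the
#'   Monte-Carlo path).
#' @return Invisibly, the `trf_bm_test`.
#' @export
run_month_test <- function(profile_file, category, month_a, month_b, out_dir,
                           n_perm = 10000, seed = NULL) {
  profiles <- readr::read_tsv(profile_file, show_col_types = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- compare_months(profiles, category, month_a, month_b,
                        n_perm = n_perm, seed = seed)
  readr::write_tsv(tidy(res), file.path(out_dir, "month_test.tsv"))
  write_run_metadata(out_dir, "test",
                     list(profile_file = profile_file, category = category,
                          months = c(month_a, month_b), n_perm = n_perm,
                          seed = seed, exhaustive = res$exhaustive,
                          low_power = res$low_power))
  invisible(res)
}

#' Trophic-position stage
#'
#' @param isotope_file Path to the isotope table.
#' @param out_dir Output directory.
#' @param beta,tef Calibration constants.
#' @param sd_type Dispersion convention, `"sample"` or `"population"`.
#' @return Invisibly, a list with `per_specimen` and `groups` tibbles.
#' @export
run_tp <- function(isotope_file, out_dir, beta = 3.4, tef = 7.6,
                   sd_type = "sample") {
  records <- read_isotope_table(isotope_file)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  per <- tp_estimate(records, beta = beta, tef = tef)
  grp <- group_tp(records, sd_type = sd_type, beta = beta, tef = tef)
  readr::write_tsv(per, file.path(out_dir, "tp_per_specimen.tsv"))
  readr::write_tsv(grp, file.path(out_dir, "tp_groups.tsv"))
  write_run_metadata(out_dir, "tp",
                     list(isotope_file = isotope_file, beta = beta, tef = tef,
                          sd_type = sd_type))
  invisible(list(per_specimen = per, groups = grp))
}

#' Simulation stage: emit a full synthetic input bundle
#'
#' Writes a reference FASTA, a one-sample-per-draw peak table over the given
#' months, and an isotope table, plus the truth sidecars, so the design,
#' profile, test and tp stages can be run end to end without real data.
#'
#' @param out_dir Output directory.
#' @param n_clades,seq_length,collisions Reference-set geometry.
#' @param months Character vector of collection months to simulate.
#' @param n_per_month Samples per month.
#' @param tp_true,n_isotope Trophic-position truth and specimen count.
#' @param seed Integer seed (required).
#' @return Invisibly, a list of output paths.
#' @export
run_simulate <- function(out_dir, n_clades = 8, seq_length = 800,
                         collisions = list(c(1, 4), c(5, 7)),
                         months = c("2005-06", "2005-08"), n_per_month = 8,
                         tp_true = 1.9, n_isotope = 3, seed = NULL) {
  seed <- check_seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  collisions <- Filter(function(pr) all(pr <= n_clades), collisions)
  refs <- simulate_reference_set(n_clades = n_clades, seq_length = seq_length,
                                 collisions = collisions, seed = seed)
  fasta <- file.path(out_dir, "references.fasta")
  write_reference_fasta(refs, fasta)

  clades <- unique(refs$clade)
  peak_rows <- list()
  truth_rows <- list()
  k <- 0L
  for (mi in seq_along(months)) {
    for (si in seq_len(n_per_month)) {
      k <- k + 1L
      sub_seed <- (seed + 7901L * k) %% .Machine$integer.max
      mix <- withr::with_seed(sub_seed, {
        raw <- stats::rexp(length(clades))
        setNames(raw / sum(raw), clades)
      })
      pk <- simulate_electropherogram(
        refs, mix, sample_id = sprintf("sim_%s_%02d", months[mi], si),
        month = months[mi], seed = sub_seed + 1L
      )
      peak_rows[[k]] <- pk
      truth_rows[[k]] <- attr(pk, "truth") |>
        mutate(sample_id = unique(pk$sample_id))
    }
  }
  peaks <- bind_rows(peak_rows)
  peak_file <- file.path(out_dir, "peaks.csv")
  write_peak_table(peaks, peak_file)
  jsonlite::write_json(bind_rows(truth_rows),
                       file.path(out_dir, "peaks_truth.json"),
                       dataframe = "rows", digits = NA)

  iso <- simulate_aa_isotopes(tp_true, n_isotope, seed = seed + 3L)
  iso_file <- file.path(out_dir, "isotopes.csv")
  readr::write_csv(iso, iso_file)
  jsonlite::write_json(list(tp_true = tp_true),
                       file.path(out_dir, "isotopes_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_run_metadata(out_dir, "simulate",
                     list(seed = seed, n_clades = n_clades,
                          months = months, n_per_month = n_per_month,
                          tp_true = tp_true))
  invisible(list(ref_fasta = fasta, peak_file = peak_file,
                 isotope_file = iso_file))
}
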