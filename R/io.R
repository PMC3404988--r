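# Readers and writers for the plain-text dialects the pipeline consumes:
# multi-FASTA references/clones (clade carried as "clade=X" in the
# description), delimited peak tables, isotope tables, and TSV reports.

#' Read reference or clone sequences from FASTA
#'
#' The description line may carry the clade as a `clade=X` token, e.g.
#' `>A_ref01 clade=A`.
#'
#' @param path Path to a multi-FASTA file.
#' @return A tibble `id`, `clade` (`NA` when untagged), `seq`.
#' @export
read_reference_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path), class = "trflpr_io_error")
  }
  ss <- Biostrings::readDNAStringSet(path)
  full <- names(ss)
  id <- sub("\\s.*$", "", full)
  clade <- ifelse(grepl("clade=", full),
                  sub(".*clade=([^ ]+).*", "\\1", full), NA_character_)
  tibble(id = id, clade = clade,
         seq = vapply(as.character(ss), normalize_iupac, character(1),
                      USE.NAMES = FALSE))
}

#' Write a sequence table to FASTA
#'
#' @param seqs Tibble with `id`, `seq` and optionally `clade` (written as a
#'   `clade=X` description token).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(seqs, path) {
  hdr <- seqs$id
  if ("clade" %in% names(seqs)) {
    hdr <- ifelse(is.na(seqs$clade), hdr,
                  paste0(hdr, " clade=", seqs$clade))
  }
  ss <- Biostrings::DNAStringSet(seqs$seq)
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path, width = 70)
  invisible(path)
}

#' Read an electropherogram peak table
#'
#' Expects a delimited file (comma or tab, sniffed from the header) with
#' columns `sample_id`, `month`, `size_bp`, `height`, `qv` - one row per
#' peak, the chromatogram quality value repeated on each of its peaks.
#' Per-sample qv consistency is validated.
#'
#' @param path Path to a CSV/TSV peak table.
#' @return A peak tibble.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("peak table not found: %s", path), class = "trflpr_io_error")
  }
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  peaks <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                             col_types = readr::cols(
                               sample_id = readr::col_character(),
                               month = readr::col_character(),
                               .default = readr::col_double()
                             ))
  validate_peak_table(peaks)
  as_tibble(peaks)
}

#' Write a peak table as CSV
#'
#' @param peaks Peak tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  readr::write_csv(peaks, path)
  invisible(path)
}

#' Read an amino-acid isotope table
#'
#' Expects columns `specimen_id`, `group`, `d15n_glu`, `d15n_phe`
#' (comma- or tab-delimited).
#'
#' @param path Path to the table.
#' @return An isotope tibble.
#' @export
read_isotope_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("isotope table not found: %s", path), class = "trflpr_io_error")
  }
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  need <- c("specimen_id", "group", "d15n_glu", "d15n_phe")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("isotope table is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "trflpr_schema_error")
  }
  as_tibble(tbl)
}

#' Write the T-RF category report as TSV
#'
#' One row per category: clade labels, comma-joined predicted lengths and
#' the merged category label.
#'
#' @param categories Category table from [trf_categories()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trf_report <- function(categories, path) {
  flat <- categories |>
    mutate(clades = purrr::map_chr(.data$clades, paste, collapse = ","),
           trf_lengths = purrr::map_chr(.data$trf_lengths, paste, collapse = ",")) |>
    select(all_of(c("category", "clades", "trf_lengths", "n_clades")))
  readr::write_tsv(flat, path)
  invisible(path)
}
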