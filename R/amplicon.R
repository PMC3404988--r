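# In silico PCR and terminal restriction fragment prediction.

#' Extract the in silico PCR amplicon from a template
#'
#' Finds the forward primer on the given strand and the reverse primer as its
#' reverse complement downstream, and returns the spanned amplicon including
#' both primer footprints. Where several sites exist, the 5'-most forward and
#' the 3'-most compatible reverse site are used (the maximal product, which
#' dominates in PCR). The amplicon is oriented so that the labelled primer's
#' 5' end is at position 1; if the labelled primer is the reverse one, the
#' amplicon is reverse complemented before being returned.
#'
#' @param template Template DNA string (or a one-row data frame with a `seq`
#'   column).
#' @param fwd,rev `trf_primer` objects; exactly one must be labelled.
#' @return The amplicon as a single DNA string.
#' @export
#' @examples
#' f <- primer("F", "ACGTACGTAC", labeled = TRUE)
#' r <- primer("R", "TTTTGGGGCC", labeled = FALSE)
#' tmpl <- paste0("ACGTACGTAC", strrep("A", 30), revcomp_iupac("TTTTGGGGCC"))
#' nchar(extract_amplicon(tmpl, f, r))
extract_amplicon <- function(template, fwd, rev) {
  if (is.data.frame(template)) {
    stopifnot(nrow(template) == 1L, "seq" %in% names(template))
    template <- template$seq
  }
  template <- normalize_iupac(template, "template")
  validate_primer_pair(list(fwd = fwd, rev = rev))

  fwd_starts <- match_iupac(fwd$seq, template)
  if (length(fwd_starts) == 0) {
    abort("no amplicon: forward primer does not match the template",
          class = "trflpr_no_amplicon")
  }
  rev_starts <- match_iupac(revcomp_iupac(rev$seq), template)
  if (length(rev_starts) == 0) {
    abort("no amplicon: reverse primer (as reverse complement) does not match the template",
          class = "trflpr_no_amplicon")
  }
  start <- min(fwd_starts)
  # reverse footprint must lie entirely downstream of the forward footprint
  ok <- rev_starts[rev_starts >= start + nchar(fwd$seq)]
  if (length(ok) == 0) {
    abort("no amplicon: reverse site is not downstream of the forward site",
          class = "trflpr_no_amplicon")
  }
  end <- max(ok) + nchar(rev$seq) - 1L
  amp <- substr(template, start, end)
  if (rev$labeled) amp <- revcomp_iupac(amp)
  amp
}

#' Predict the terminal restriction fragment length of an amplicon
#'
#' Scans the labelled strand for the 5'-most (possibly degenerate) match of
#' the enzyme's recognition site; the T-RF length is the number of bases from
#' the labelled 5' terminus through the cut, i.e. `match start - 1 +
#' cut_offset`. An amplicon without a recognition site is reported uncut at
#' its full length.
#'
#' @param amplicon DNA string with the labelled 5' terminus at position 1.
#' @param enzyme A `trf_enzyme`.
#' @return A list with `trf_bp` (integer length), `cut` (logical) and
#'   `amplicon_bp`.
#' @export
#' @examples
#' predict_trf(paste0(strrep("A", 20), "ACGT", strrep("C", 40)), tai1())
predict_trf <- function(amplicon, enzyme) {
  stopifnot(inherits(enzyme, "trf_enzyme"))
  amplicon <- normalize_iupac(amplicon, "amplicon")
  hits <- match_iupac(enzyme$recognition, amplicon)
  if (length(hits) == 0) {
    return(list(trf_bp = nchar(amplicon), cut = FALSE,
                amplicon_bp = nchar(amplicon)))
  }
  list(trf_bp = min(hits) - 1L + enzyme$cut_offset, cut = TRUE,
       amplicon_bp = nchar(amplicon))
}

#' Predict T-RFs for a table of reference sequences
#'
#' Runs [extract_amplicon()] and [predict_trf()] over every reference and
#' returns a tidy table. References where a primer fails to find a site are
#' reported with `NA` lengths rather than an error.
#'
#' @param refs Data frame with columns `id`, `seq` and optionally `clade`.
#' @param fwd,rev `trf_primer` objects (default: the shipped trbcL pair).
#' @param enzyme A `trf_enzyme` (default TaiI).
#' @return A tibble with columns `id`, `clade`, `amplicon_bp`, `trf_bp`,
#'   `cut`.
#' @export
predict_trf_refs <- function(refs, fwd = trbcl_primers()$fwd,
                             rev = trbcl_primers()$rev, enzyme = tai1()) {
  stopifnot(is.data.frame(refs), all(c("id", "seq") %in% names(refs)))
  clade <- if ("clade" %in% names(refs)) refs$clade else NA_character_
  rows <- purrr::pmap(
    list(refs$id, refs$seq, clade),
    function(id, seq, cl) {
      amp <- tryCatch(extract_amplicon(seq, fwd, rev), trflpr_no_amplicon = function(e) NULL)
      if (is.null(amp)) {
        return(tibble(id = id, clade = cl, amplicon_bp = NA_integer_,
                      trf_bp = NA_integer_, cut = NA))
      }
      p <- predict_trf(amp, enzyme)
      tibble(id = id, clade = cl, amplicon_bp = p$amplicon_bp,
             trf_bp = as.integer(p$trf_bp), cut = p$cut)
    }
  )
  bind_rows(rows)
}
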