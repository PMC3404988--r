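# IUPAC nucleotide alphabet and degenerate matching.
#
# All matching runs through Biostrings with fixed = FALSE, so an ambiguity
# code on either side matches whenever the two nucleotide sets intersect.

IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  M = "AC", R = "AG", W = "AT", S = "CG", Y = "CT", K = "GT",
  V = "ACG", H = "ACT", D = "AGT", B = "CGT", N = "ACGT"
)

#' Validate and normalise an IUPAC nucleotide string
#'
#' Uppercases, converts U to T, and checks every symbol is one of the 15
#' IUPAC nucleotide codes (`ACGTMRWSYKVHDBN`).
#'
#' @param x A single DNA string.
#' @param what Label used in error messages.
#' @return The normalised string.
#' @export
#' @examples
#' normalize_iupac("acgu")
normalize_iupac <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    abort(sprintf("%s must be a single non-empty string", what))
  }
  x <- chartr("u", "T", toupper(x))
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- setdiff(unique(strsplit(x, "")[[1]]), names(IUPAC_CODES))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s contains non-IUPAC symbol(s): %s", what,
      paste(sQuote(bad), collapse = ", ")
    ))
  }
  x
}

#' Find all degenerate matches of an IUPAC pattern in a sequence
#'
#' Returns every start position at which each pattern symbol's nucleotide set
#' intersects the corresponding sequence symbol's set, i.e. degenerate codes
#' act as wildcards on both sides. A literal (non-degenerate) pattern reduces
#' to plain substring search.
#'
#' @param pattern IUPAC pattern string (e.g. a degenerate primer).
#' @param seq Subject DNA string, IUPAC alphabet.
#' @return Sorted integer vector of 1-based match start positions.
#' @export
#' @examples
#' match_iupac("ACKT", "ACGTACTT") # K = G or T
match_iupac <- function(pattern, seq) {
  pattern <- normalize_iupac(pattern, "pattern")
  seq <- normalize_iupac(seq, "seq")
  if (nchar(pattern) > nchar(seq)) return(integer(0))
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(pattern), Biostrings::DNAString(seq),
    fixed = FALSE
  )
  sort(BiocGenerics::start(hits))
}

#' Reverse complement of an IUPAC DNA string
#'
#' @param seq DNA string over the IUPAC alphabet.
#' @return The reverse complement, ambiguity codes mapped to their complements.
#' @export
#' @examples
#' revcomp_iupac("ACGTK")
revcomp_iupac <- function(seq) {
  seq <- normalize_iupac(seq, "seq")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
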