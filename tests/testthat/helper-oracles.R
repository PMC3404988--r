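# Independent brute-force oracles, kept free of the package's matching code
# paths on purpose.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"), S = c("C", "G"),
  Y = c("C", "T"), K = c("G", "T"), V = c("A", "C", "G"),
  H = c("A", "C", "T"), D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

# slide the pattern over the sequence; a window matches when every position's
# nucleotide sets intersect
brute_match_iupac <- function(pattern, seq) {
  p <- strsplit(toupper(pattern), "")[[1]]
  s <- strsplit(toupper(seq), "")[[1]]
  k <- length(p); n <- length(s)
  if (k > n) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n - k + 1)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (length(intersect(IUPAC_SETS[[p[j]]], IUPAC_SETS[[s[i + j - 1]]])) == 0) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# minimum recognition start + cut offset, by enumeration
brute_trf <- function(amplicon, recognition, cut_offset) {
  hits <- brute_match_iupac(recognition, amplicon)
  if (length(hits) == 0) return(list(trf = nchar(amplicon), cut = FALSE))
  list(trf = min(hits) - 1L + cut_offset, cut = TRUE)
}

# relative effect by direct pair counting
brute_p_hat <- function(x, y) {
  lt <- sum(outer(x, y, `<`))
  eq <- sum(outer(x, y, `==`))
  (lt + 0.5 * eq) / (length(x) * length(y))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# a template that carries the shipped primer pair around a given insert
make_template <- function(insert, fwd = trbcl_primers()$fwd,
                          rev = trbcl_primers()$rev) {
  fwd_lit <- trflpr:::expand_iupac_literal(fwd$seq, avoid = "ACGT")
  rev_lit <- trflpr:::expand_iupac_literal(rev$seq)
  paste0(fwd_lit, insert, revcomp_iupac(rev_lit))
}
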