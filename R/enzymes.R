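# Restriction-enzyme and primer definitions, plus the shipped defaults used
# throughout the rbcL T-RFLP workflow.

#' Define a restriction enzyme
#'
#' The cut offset is measured on the labelled (5'-fluoresceinated) strand, in
#' bases from the 5' start of the recognition site. An offset equal to the
#' recognition length means cleavage immediately 3' of the site.
#'
#' @param name Enzyme name.
#' @param recognition IUPAC recognition string, length >= 4.
#' @param cut_offset Integer in `[0, nchar(recognition)]`.
#' @return An object of class `trf_enzyme`.
#' @export
#' @examples
#' restriction_enzyme("TaiI", "ACGT", 4)
restriction_enzyme <- function(name, recognition, cut_offset) {
  recognition <- normalize_iupac(recognition, "recognition")
  if (nchar(recognition) < 4) {
    abort("recognition site must be at least 4 bases long")
  }
  cut_offset <- as.integer(cut_offset)
  if (length(cut_offset) != 1L || is.na(cut_offset) ||
      cut_offset < 0L || cut_offset > nchar(recognition)) {
    abort("cut_offset must lie between 0 and nchar(recognition); cleavage outside the recognition site is not supported")
  }
  structure(
    list(name = as.character(name), recognition = recognition,
         cut_offset = cut_offset),
    class = "trf_enzyme"
  )
}

#' @export
print.trf_enzyme <- function(x, ...) {
  cat(sprintf("<enzyme %s: %s, cut at +%d on the labelled strand>\n",
              x$name, x$recognition, x$cut_offset))
  invisible(x)
}

#' The shipped TaiI enzyme
#'
#' TaiI recognises ACGT and is modelled as cleaving immediately 3' of the
#' site on the labelled strand (cut offset 4). The offset is configurable via
#' [restriction_enzyme()] should a different cleavage convention be needed.
#'
#' @return A `trf_enzyme`.
#' @export
tai1 <- function() restriction_enzyme("TaiI", "ACGT", 4L)

#' Define a PCR primer
#'
#' @param name Primer name.
#' @param seq IUPAC sequence, length >= 10, written 5'->3'.
#' @param labeled Whether the 5' end carries the fluorescent label. Exactly
#'   one primer of a pair must be labelled.
#' @return An object of class `trf_primer`.
#' @export
primer <- function(name, seq, labeled = FALSE) {
  seq <- normalize_iupac(seq, "primer seq")
  if (nchar(seq) < 10) abort("primer sequences must be at least 10 bases")
  structure(
    list(name = as.character(name), seq = seq, labeled = isTRUE(labeled)),
    class = "trf_primer"
  )
}

#' @export
print.trf_primer <- function(x, ...) {
  cat(sprintf("<primer %s%s: %s>\n", x$name,
              if (x$labeled) " [labelled]" else "", x$seq))
  invisible(x)
}

#' The shipped rbcL T-RFLP primer pair
#'
#' Nested consensus primers amplifying the rbcL fragment that carries the
#' clade-discriminating TaiI site: trbcL-F (fluoresceinated) and trbcL-R.
#'
#' @return A list with elements `fwd` and `rev` (class `trf_primer_pair`).
#' @export
trbcl_primers <- function() {
  pair <- list(
    fwd = primer("trbcL-F", "CTKGCDGYDYTTMGDATGACAC", labeled = TRUE),
    rev = primer("trbcL-R", "MRGCWARWGAACGTCCTTCATT", labeled = FALSE)
  )
  validate_primer_pair(pair)
  structure(pair, class = "trf_primer_pair")
}

validate_primer_pair <- function(pair) {
  if (!all(c("fwd", "rev") %in% names(pair))) {
    abort("a primer pair needs elements 'fwd' and 'rev'")
  }
  n_lab <- sum(vapply(pair[c("fwd", "rev")], function(p) isTRUE(p$labeled),
                      logical(1)))
  if (n_lab != 1L) abort("exactly one primer of a pair must be labelled")
  invisible(pair)
}

#' Read an enzyme catalogue from a YAML config file
#'
#' The file holds a list of entries with keys `name`, `recognition` and
#' `cut_offset`.
#'
#' @param path Path to a YAML file.
#' @return A list of `trf_enzyme` objects, named by enzyme.
#' @export
read_enzyme_catalogue <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("enzyme catalogue not found: %s", path), class = "trflpr_config_error")
  }
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0) abort("enzyme catalogue is empty", class = "trflpr_config_error")
  enz <- lapply(raw, function(e) {
    if (!all(c("name", "recognition", "cut_offset") %in% names(e))) {
      abort("each catalogue entry needs name, recognition and cut_offset",
            class = "trflpr_config_error")
    }
    restriction_enzyme(e$name, e$recognition, e$cut_offset)
  })
  setNames(enz, vapply(enz, `[[`, character(1), "name"))
}

#' Read a primer pair from a YAML config file
#'
#' The file holds entries with keys `name`, `seq` and `labeled`; exactly two
#' entries, one labelled.
#'
#' @param path Path to a YAML file.
#' @return A `trf_primer_pair`.
#' @export
read_primer_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("primer config not found: %s", path), class = "trflpr_config_error")
  }
  raw <- yaml::read_yaml(path)
  if (length(raw) != 2) abort("primer config must define exactly two primers",
                              class = "trflpr_config_error")
  ps <- lapply(raw, function(p) primer(p$name, p$seq, isTRUE(p$labeled)))
  pair <- list(fwd = ps[[1]], rev = ps[[2]])
  validate_primer_pair(pair)
  structure(pair, class = "trf_primer_pair")
}
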