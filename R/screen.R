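# Clade-level T-RF category construction and restriction-enzyme screening.

#' Merge clades into T-RF categories
#'
#' Clades whose predicted T-RF length sets come within `2 * tolerance` bp of
#' one another (minimum pairwise gap, single linkage) cannot be told apart on
#' a sizing trace and are merged into one category; a clade with several
#' T-RFs keeps them all within its category. Uncut references are excluded
#' unless `include_uncut` (full amplicon length used as a pseudo-T-RF).
#'
#' @param predictions Per-reference predictions from [predict_trf_refs()]
#'   (columns `clade`, `trf_bp`, `cut`).
#' @param tolerance Size-match tolerance in bp (default 1.5); two clades
#'   separated by more than `2 * tolerance` are resolvable.
#' @param include_uncut Keep uncut full-length amplicons as pseudo-T-RFs.
#' @return A tibble with one row per category: `category` (clade labels
#'   joined with "/"), `clades` (list of clade labels), `trf_lengths` (list
#'   of integer bp), `n_clades`.
#' @export
trf_categories <- function(predictions, tolerance = 1.5, include_uncut = FALSE) {
  stopifnot(is.data.frame(predictions),
            all(c("clade", "trf_bp", "cut") %in% names(predictions)))
  keep <- predictions[!is.na(predictions$trf_bp), , drop = FALSE]
  if (!include_uncut) keep <- keep[keep$cut %in% TRUE, , drop = FALSE]
  if (nrow(keep) == 0) {
    return(tibble(category = character(0), clades = list(),
                  trf_lengths = list(), n_clades = integer(0)))
  }
  sets <- keep |>
    group_by(clade = .data$clade) |>
    summarise(lengths = list(sort(unique(.data$trf_bp))), .groups = "drop") |>
    arrange(.data$clade)

  n <- nrow(sets)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        gap <- min(abs(outer(sets$lengths[[i]], sets$lengths[[j]], `-`)))
        if (gap <= 2 * tolerance) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  out <- lapply(unique(comp), function(cc) {
    idx <- which(comp == cc)
    tibble(
      category = paste(sets$clade[idx], collapse = "/"),
      clades = list(sets$clade[idx]),
      trf_lengths = list(sort(unique(unlist(sets$lengths[idx])))),
      n_clades = length(idx)
    )
  })
  bind_rows(out) |> arrange(.data$category)
}

#' Screen restriction enzymes for clade discrimination
#'
#' For each candidate enzyme, predicts the T-RF of every reference, merges
#' clades that are closer than `2 * tolerance` bp (see [trf_categories()])
#' and counts the resulting distinguishable categories. Enzymes are ranked
#' by category count (descending), ties broken alphabetically by name.
#' Enzymes that never cut are kept in the ranking and flagged.
#'
#' @param refs Reference table (`id`, `clade`, `seq`).
#' @param enzymes List of `trf_enzyme` objects.
#' @param tolerance Size tolerance in bp.
#' @param fwd,rev Primer pair.
#' @return A tibble `enzyme`, `n_categories`, `n_clades`, `n_uncut_refs`,
#'   `all_uncut`, sorted best-first.
#' @export
screen_enzymes <- function(refs, enzymes, tolerance = 1.5,
                           fwd = trbcl_primers()$fwd,
                           rev = trbcl_primers()$rev) {
  stopifnot(length(enzymes) > 0)
  if (inherits(enzymes, "trf_enzyme")) enzymes <- list(enzymes)
  rows <- purrr::map(enzymes, function(enz) {
    preds <- predict_trf_refs(refs, fwd = fwd, rev = rev, enzyme = enz)
    cats <- trf_categories(preds, tolerance = tolerance)
    tibble(
      enzyme = enz$name,
      n_categories = nrow(cats),
      n_clades = dplyr::n_distinct(preds$clade[!is.na(preds$trf_bp)]),
      n_uncut_refs = sum(preds$cut %in% FALSE),
      all_uncut = all(preds$cut %in% FALSE)
    )
  })
  bind_rows(rows) |>
    arrange(desc(.data$n_categories), .data$enzyme)
}
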