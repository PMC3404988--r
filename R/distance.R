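# p-distance, clone deduplication and the half-sequence chimera screen.
# All three assume pre-aligned, equal-length sequences (the synthetic
# generators emit indel-free alignments; real data should be aligned first).

seq_matrix <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    abort("sequences must be pre-aligned to equal length")
  }
  do.call(rbind, strsplit(toupper(seqs), ""))
}

#' Proportion of differing sites between two aligned sequences
#'
#' Only columns where both symbols are unambiguous nucleotides (A, C, G or T)
#' are compared; gaps and ambiguity codes are skipped.
#'
#' @param a,b Aligned DNA strings of equal length.
#' @return The proportion of compared columns that differ, in `[0, 1]`.
#' @export
#' @examples
#' p_distance("ACGTACGT", "ACGTACTT")
p_distance <- function(a, b) {
  if (!is.character(a) || !is.character(b) || length(a) != 1 || length(b) != 1) {
    abort("a and b must be single strings")
  }
  if (nchar(a) != nchar(b)) abort("a and b must have equal (aligned) length")
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  if (!any(ok)) abort("p-distance undefined: no comparable (unambiguous) columns")
  mean(av[ok] != bv[ok])
}

# pairwise p-distance matrix over a character matrix of aligned sequences,
# restricted to columns `cols` (default all)
p_distance_matrix <- function(mat, cols = seq_len(ncol(mat))) {
  sub <- mat[, cols, drop = FALSE]
  unamb <- sub == "A" | sub == "C" | sub == "G" | sub == "T"
  n <- nrow(sub)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      if (i == j) next
      ok <- unamb[i, ] & unamb[j, ]
      if (!any(ok)) {
        d[i, j] <- d[j, i] <- NA_real_
      } else {
        d[i, j] <- d[j, i] <- mean(sub[i, ok] != sub[j, ok])
      }
    }
  }
  d
}

#' Collapse near-identical clones into representatives
#'
#' Clone sequences closer than `threshold` (strict) in p-distance are treated
#' as PCR copies of the same template: sequences are grouped by
#' single-linkage at `p < threshold` and each group is reported once. The
#' representative is the group's most frequent sequence; frequency ties are
#' broken by the lexicographically smallest clone id.
#'
#' @param clones Data frame with columns `id` and `seq` (aligned, equal
#'   length).
#' @param threshold Distance below which two clones are merged (default
#'   0.001; two clones at exactly the threshold stay separate).
#' @return A tibble `id`, `seq`, `n_members`, `member_ids` (list column),
#'   one row per representative.
#' @export
dedup_clones <- function(clones, threshold = 0.001) {
  stopifnot(is.data.frame(clones), all(c("id", "seq") %in% names(clones)))
  if (nrow(clones) == 0) {
    return(tibble(id = character(0), seq = character(0),
                  n_members = integer(0), member_ids = list()))
  }
  mat <- seq_matrix(clones$seq)
  d <- p_distance_matrix(mat)
  n <- nrow(clones)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (!is.na(d[i, j]) && d[i, j] < threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  reps <- lapply(unique(comp), function(cc) {
    idx <- which(comp == cc)
    seqs <- clones$seq[idx]
    freq <- table(seqs)
    top_seq <- names(freq)[freq == max(freq)]
    cand <- idx[seqs %in% top_seq]
    rep_i <- cand[order(clones$id[cand])][1]
    tibble(
      id = clones$id[rep_i], seq = clones$seq[rep_i],
      n_members = length(idx),
      member_ids = list(sort(clones$id[idx]))
    )
  })
  bind_rows(reps) |> arrange(.data$id)
}

#' Half-sequence chimera screen against clade references
#'
#' A deterministic screen for PCR chimeras: the alignment is split at its
#' midpoint, each half is assigned to the nearest reference clade by
#' p-distance, and the query is flagged as chimeric when the two halves
#' assign to different clades that are themselves separated by at least
#' `min_divergence` over each corresponding half. Queries shorter than twice
#' `min_half` columns are reported unscreenable.
#'
#' @param queries Data frame with columns `id` and `seq`, aligned to `refs`.
#' @param refs Reference table (`id`, `clade`, `seq`), same alignment.
#' @param min_divergence Minimum between-clade divergence for a discordant
#'   assignment to count as chimeric (default 0.005).
#' @param min_half Minimum usable half-length in columns (default 100).
#' @return A tibble `id`, `clade_5p`, `clade_3p`, `flagged`, `screenable`.
#' @export
chimera_screen <- function(queries, refs, min_divergence = 0.005,
                           min_half = 100) {
  stopifnot(is.data.frame(queries), all(c("id", "seq") %in% names(queries)),
            is.data.frame(refs), all(c("id", "clade", "seq") %in% names(refs)))
  all_len <- unique(nchar(c(queries$seq, refs$seq)))
  if (length(all_len) != 1) abort("queries and references must share one aligned length")
  L <- all_len
  if (L < 2 * min_half) {
    return(tibble(id = queries$id, clade_5p = NA_character_,
                  clade_3p = NA_character_, flagged = NA, screenable = FALSE))
  }
  mid <- L %/% 2
  halves <- list(seq_len(mid), (mid + 1):L)
  ref_mat <- seq_matrix(refs$seq)

  nearest_clade <- function(qv, cols) {
    sub <- ref_mat[, cols, drop = FALSE]
    q <- qv[cols]
    dists <- vapply(seq_len(nrow(sub)), function(i) {
      ok <- q %in% c("A", "C", "G", "T") & sub[i, ] %in% c("A", "C", "G", "T")
      if (!any(ok)) return(NA_real_)
      mean(q[ok] != sub[i, ok])
    }, numeric(1))
    agg <- tapply(dists, refs$clade, min, na.rm = TRUE)
    names(agg)[which.min(agg)]
  }

  clade_gap <- function(cl_a, cl_b, cols) {
    ia <- which(refs$clade == cl_a); ib <- which(refs$clade == cl_b)
    d <- p_distance_matrix(ref_mat, cols)
    min(d[ia, ib], na.rm = TRUE)
  }

  rows <- purrr::map2(queries$id, queries$seq, function(id, seq) {
    qv <- strsplit(toupper(seq), "")[[1]]
    c5 <- nearest_clade(qv, halves[[1]])
    c3 <- nearest_clade(qv, halves[[2]])
    flagged <- FALSE
    if (!identical(c5, c3)) {
      gap5 <- clade_gap(c5, c3, halves[[1]])
      gap3 <- clade_gap(c5, c3, halves[[2]])
      flagged <- isTRUE(gap5 >= min_divergence && gap3 >= min_divergence)
    }
    tibble(id = id, clade_5p = c5, clade_3p = c3, flagged = flagged,
           screenable = TRUE)
  })
  bind_rows(rows)
}
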