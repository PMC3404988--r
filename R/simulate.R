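# Seeded generators emulating the study's inputs: clade-structured rbcL-like
# reference sets with engineered restriction-site geometry, clone libraries
# with PCR point error and chimeras, electropherogram peak tables, and
# amino-acid delta-15N datasets obtained by inverting the TP formula.
#
# Sequence evolution is independent uniform substitution without indels, so
# every generated set is a ready-made alignment (all downstream distance
# operations assume equal-length input).

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) sample(BASES, n, replace = TRUE)

mutate_positions <- function(chars, positions, rate) {
  if (length(positions) == 0 || rate <= 0) return(chars)
  hit <- positions[runif(length(positions)) < rate]
  for (p in hit) {
    chars[p] <- sample(setdiff(BASES, chars[p]), 1)
  }
  chars
}

# literal expansion of a degenerate IUPAC string that avoids containing any
# match of `avoid` (a recognition site); degenerate positions are switched
# greedily until clean
expand_iupac_literal <- function(seq, avoid = NULL) {
  syms <- strsplit(normalize_iupac(seq), "")[[1]]
  sets <- strsplit(unname(IUPAC_CODES[syms]), "")
  lit <- vapply(sets, `[[`, character(1), 1)
  if (is.null(avoid)) return(paste(lit, collapse = ""))
  for (iter in 1:50) {
    hits <- match_iupac(avoid, paste(lit, collapse = ""))
    if (length(hits) == 0) return(paste(lit, collapse = ""))
    s <- hits[1]
    span <- s:(s + nchar(avoid) - 1)
    fixed <- FALSE
    for (p in span) {
      alt <- setdiff(sets[[p]], lit[p])
      if (length(alt) > 0) { lit[p] <- alt[1]; fixed <- TRUE; break }
    }
    if (!fixed) {
      abort("cannot expand primer without a recognition site: no degenerate position available",
            class = "trflpr_config_error")
    }
  }
  abort("primer expansion did not converge", class = "trflpr_config_error")
}

# remove recognition matches starting in [from, to] of `chars`, never
# touching `protected` positions
scrub_recognition <- function(chars, recognition, from, to, protected) {
  rec_len <- nchar(recognition)
  rec_sets <- strsplit(unname(IUPAC_CODES[strsplit(recognition, "")[[1]]]), "")
  for (iter in 1:200) {
    hits <- match_iupac(recognition, paste(chars, collapse = ""))
    hits <- hits[hits >= from & hits <= to]
    if (length(hits) == 0) return(chars)
    s <- hits[1]
    span <- s:(s + rec_len - 1)
    cand <- setdiff(span, protected)
    fixed <- FALSE
    for (p in rev(cand)) {
      off <- p - s + 1
      alt <- setdiff(BASES, c(rec_sets[[off]], chars[p]))
      if (length(alt) > 0) { chars[p] <- alt[1]; fixed <- TRUE; break }
    }
    if (!fixed) {
      abort("infeasible geometry: cannot remove a stray recognition site without touching a protected region",
            class = "trflpr_config_error")
    }
  }
  abort("recognition-site scrub did not converge", class = "trflpr_config_error")
}

check_seed <- function(seed) {
  if (is.null(seed) || is.na(seed)) {
    abort("a seed is required for every stochastic generator call",
          class = "trflpr_input_error")
  }
  as.integer(seed)
}

#' Simulate a clade-structured reference set with engineered T-RF geometry
#'
#' Builds `n_clades` clades of equal-length reference sequences that all
#' carry the forward and reverse primer sites and exactly one engineered
#' recognition site whose position sets the clade's predicted T-RF length.
#' Within a clade, references differ only downstream of the cut site (so the
#' predicted T-RF is identical within a clade); between clades, both the
#' site window and the downstream region diverge. Stray recognition matches
#' upstream of the engineered site are scrubbed so the engineered site is
#' always the 5'-most. Length collisions between clades (indistinguishable
#' categories, as happens with real taxa) are requested via `collisions` or
#' by passing explicit equal `trf_targets`.
#'
#' @param n_clades Number of clades (labelled A, B, ...).
#' @param n_refs_per_clade References per clade.
#' @param seq_length Total template length (>= 300).
#' @param trf_targets Integer vector of target T-RF lengths per clade;
#'   default `130 + 10 * (0:(n_clades-1))` (>= 5 bp apart).
#' @param collisions List of integer pairs; each pair's second clade gets
#'   the first clade's T-RF target (emulating merged categories).
#' @param between_divergence Substitution rate clade spine vs ancestral core.
#' @param within_divergence Substitution rate of each reference vs its clade
#'   spine (downstream of the cut site only).
#' @param primers A `trf_primer_pair` embedded in every reference.
#' @param enzyme The `trf_enzyme` whose site is engineered.
#' @param seed Integer seed (required; same seed, same FASTA byte for byte).
#' @return A tibble `id`, `clade`, `seq` with attribute `"trf_targets"`
#'   (named integer vector of the engineered T-RF lengths).
#' @export
simulate_reference_set <- function(n_clades = 8, n_refs_per_clade = 3,
                                   seq_length = 800, trf_targets = NULL,
                                   collisions = list(),
                                   between_divergence = 0.02,
                                   within_divergence = 0.002,
                                   primers = trbcl_primers(),
                                   enzyme = tai1(), seed = NULL) {
  seed <- check_seed(seed)
  stopifnot(n_clades >= 1, seq_length >= 300, n_refs_per_clade >= 1)
  if (is.null(trf_targets)) {
    trf_targets <- 130L + 10L * (seq_len(n_clades) - 1L)
  }
  stopifnot(length(trf_targets) == n_clades, all(trf_targets >= 1))
  for (pr in collisions) {
    if (length(pr) != 2 || any(pr < 1) || any(pr > n_clades)) {
      abort("each collision must be a pair of clade indices within n_clades",
            class = "trflpr_config_error")
    }
    trf_targets[pr[2]] <- trf_targets[pr[1]]
  }
  clades <- LETTERS[seq_len(n_clades)]
  names(trf_targets) <- clades

  rec <- enzyme$recognition
  rec_len <- nchar(rec)
  rec_lit <- strsplit(expand_iupac_literal(rec), "")[[1]]
  fwd_lit <- strsplit(expand_iupac_literal(primers$fwd$seq, avoid = rec), "")[[1]]
  rev_lit <- expand_iupac_literal(primers$rev$seq)
  rc_rev_lit <- strsplit(revcomp_iupac(rev_lit), "")[[1]]
  fwd_len <- length(fwd_lit); rev_len <- nchar(rev_lit)

  prefix_len <- 25L; suffix_len <- 25L
  amp_len <- seq_length - prefix_len - suffix_len
  # engineered site starts at amplicon offset T - cut_offset + 1
  site_amp_start <- trf_targets - enzyme$cut_offset + 1L
  if (any(site_amp_start <= fwd_len)) {
    abort("infeasible geometry: a T-RF target falls inside the forward primer footprint",
          class = "trflpr_config_error")
  }
  w_len <- max(site_amp_start) + rec_len + 4L - fwd_len
  d_len <- amp_len - fwd_len - w_len - rev_len
  if (d_len < 50) {
    abort("infeasible geometry: seq_length too short for the requested T-RF targets",
          class = "trflpr_config_error")
  }

  withr::with_seed(seed, {
    prefix <- random_dna(prefix_len)
    suffix <- random_dna(suffix_len)
    w_core <- random_dna(w_len)
    d_core <- random_dna(d_len)

    amp_start <- prefix_len + 1L
    w_start <- amp_start + fwd_len
    d_start <- w_start + w_len
    rev_start <- d_start + d_len
    fwd_span <- amp_start:(amp_start + fwd_len - 1L)
    rev_span <- rev_start:(rev_start + rev_len - 1L)

    rows <- list()
    for (ci in seq_len(n_clades)) {
      w_c <- mutate_positions(w_core, seq_len(w_len), between_divergence)
      d_c <- mutate_positions(d_core, seq_len(d_len), between_divergence)
      site_template_start <- prefix_len + site_amp_start[ci]
      w_off <- site_template_start - w_start + 1L
      w_c[w_off:(w_off + rec_len - 1L)] <- rec_lit
      spine <- c(prefix, fwd_lit, w_c, d_c, rc_rev_lit, suffix)
      site_span <- site_template_start:(site_template_start + rec_len - 1L)
      spine <- scrub_recognition(
        spine, rec,
        from = amp_start, to = site_template_start - 1L,
        protected = c(fwd_span, site_span, rev_span)
      )
      cut_end <- site_template_start + rec_len - 1L
      free <- setdiff(d_start:(d_start + d_len - 1L), seq_len(cut_end))
      for (ri in seq_len(n_refs_per_clade)) {
        chars <- mutate_positions(spine, free, within_divergence)
        rows[[length(rows) + 1L]] <- tibble(
          id = sprintf("%s_ref%02d", clades[ci], ri),
          clade = clades[ci],
          seq = paste(chars, collapse = "")
        )
      }
    }
    out <- bind_rows(rows)
    attr(out, "trf_targets") <- trf_targets
    out
  })
}

#' Simulate a clone library from a kleptoplast mixture
#'
#' Draws clones multinomially from the mixture weights, copies a random
#' reference of the drawn clade, applies PCR point errors (independent
#' uniform substitutions at `pcr_error_rate` per base), and turns a
#' `chimera_rate` fraction into two-parent chimeras spliced at a breakpoint
#' drawn uniformly from the middle third of the alignment. Truth labels are
#' retained for scoring.
#'
#' @param refs Reference tibble from [simulate_reference_set()].
#' @param mixture Named numeric vector of clade weights (>= 0, normalised to
#'   sum to 1; names must be clades of `refs`).
#' @param n_clones Number of clones (> 0).
#' @param pcr_error_rate Per-base substitution probability per clone.
#' @param chimera_rate Fraction of clones replaced by chimeras.
#' @param seed Integer seed (required).
#' @return A tibble `id`, `seq`, `clade_true` (`NA` for chimeras),
#'   `is_chimera`, `parent_5p`, `parent_3p`.
#' @export
simulate_clone_library <- function(refs, mixture, n_clones,
                                   pcr_error_rate = 0.001,
                                   chimera_rate = 0, seed = NULL) {
  seed <- check_seed(seed)
  if (n_clones <= 0) abort("n_clones must be positive", class = "trflpr_input_error")
  if (is.null(names(mixture)) || any(!names(mixture) %in% refs$clade)) {
    abort("mixture must be named by clades present in refs",
          class = "trflpr_input_error")
  }
  if (any(mixture < 0) || sum(mixture) <= 0) {
    abort("mixture weights must be non-negative and not all zero",
          class = "trflpr_input_error")
  }
  w <- mixture / sum(mixture)
  L <- unique(nchar(refs$seq))
  stopifnot(length(L) == 1)

  withr::with_seed(seed, {
    clades <- sample(names(w), n_clones, replace = TRUE, prob = w)
    chim <- runif(n_clones) < chimera_rate
    rows <- vector("list", n_clones)
    pick_ref <- function(cl) {
      cand <- which(refs$clade == cl)
      refs$seq[cand[sample.int(length(cand), 1)]]
    }
    for (i in seq_len(n_clones)) {
      if (chim[i] && length(unique(names(w)[w > 0])) >= 2) {
        pool <- names(w)[w > 0]
        p5 <- sample(pool, 1, prob = w[pool])
        p3 <- sample(setdiff(pool, p5), 1)
        b <- sample(seq.int(floor(L / 3), floor(2 * L / 3)), 1)
        seqc <- paste0(substr(pick_ref(p5), 1, b),
                       substr(pick_ref(p3), b + 1, L))
        truth <- list(clade = NA_character_, is_chim = TRUE, p5 = p5, p3 = p3)
      } else {
        seqc <- pick_ref(clades[i])
        truth <- list(clade = clades[i], is_chim = FALSE,
                      p5 = clades[i], p3 = clades[i])
      }
      chars <- strsplit(seqc, "")[[1]]
      chars <- mutate_positions(chars, seq_len(L), pcr_error_rate)
      rows[[i]] <- tibble(
        id = sprintf("clone%04d", i), seq = paste(chars, collapse = ""),
        clade_true = truth$clade, is_chimera = truth$is_chim,
        parent_5p = truth$p5, parent_3p = truth$p3
      )
    }
    bind_rows(rows)
  })
}

#' Simulate an electropherogram peak table with known truth
#'
#' Emits one peak per mixture clade at its predicted T-RF length plus
#' Gaussian size-calling jitter, with height proportional to the mixture
#' weight under multiplicative lognormal noise (positive by construction).
#' Optional spurious peaks outside the 100-1200 bp window exercise the QC
#' filter.
#'
#' @param refs Reference tibble (first reference of each clade sets its
#'   predicted T-RF).
#' @param mixture Named clade weights as in [simulate_clone_library()].
#' @param enzyme,primers Digestion/amplification definitions.
#' @param height_cv Coefficient of variation of the multiplicative height
#'   noise (default 0.1).
#' @param size_jitter Standard deviation of the size-calling error in bp
#'   (default 0.3).
#' @param base_height Expected total-height scale in fluorescence units.
#' @param qv Chromatogram quality value to record.
#' @param sample_id,month Identifiers written into the peak table.
#' @param noise_peaks Number of spurious out-of-window peaks to inject.
#' @param seed Integer seed (required).
#' @return A peak tibble (`sample_id`, `month`, `size_bp`, `height`, `qv`)
#'   with attribute `"truth"`: tibble `clade`, `trf_bp`, `weight`.
#' @export
simulate_electropherogram <- function(refs, mixture, enzyme = tai1(),
                                      primers = trbcl_primers(),
                                      height_cv = 0.1, size_jitter = 0.3,
                                      base_height = 1000, qv = 90,
                                      sample_id = "sim1", month = "2005-06",
                                      noise_peaks = 0, seed = NULL) {
  seed <- check_seed(seed)
  w <- mixture[mixture > 0]
  w <- w / sum(w)
  first_refs <- refs |>
    filter(.data$clade %in% names(w)) |>
    group_by(.data$clade) |>
    dplyr::slice(1) |>
    ungroup()
  preds <- predict_trf_refs(first_refs, fwd = primers$fwd, rev = primers$rev,
                            enzyme = enzyme)
  if (any(is.na(preds$trf_bp)) || any(!preds$cut)) {
    abort("every mixture clade needs a valid, cut amplicon",
          class = "trflpr_input_error")
  }
  sdlog <- sqrt(log(1 + height_cv^2))
  withr::with_seed(seed, {
    peaks <- tibble(
      sample_id = sample_id, month = month,
      size_bp = preds$trf_bp + rnorm(nrow(preds), 0, size_jitter),
      height = unname(w[preds$clade]) * base_height *
        exp(rnorm(nrow(preds), -sdlog^2 / 2, sdlog)),
      qv = qv
    )
    if (noise_peaks > 0) {
      lo <- runif(noise_peaks) < 0.5
      noise <- tibble(
        sample_id = sample_id, month = month,
        size_bp = ifelse(lo, runif(noise_peaks, 40, 99),
                         runif(noise_peaks, 1201, 1300)),
        height = runif(noise_peaks, 10, 60),
        qv = qv
      )
      peaks <- bind_rows(peaks, noise)
    }
    truth <- tibble(clade = preds$clade, trf_bp = preds$trf_bp,
                    weight = unname(w[preds$clade]))
    attr(peaks, "truth") <- truth
    peaks
  })
}

#' Simulate amino-acid delta-15N records from a known trophic position
#'
#' Inverts the trophic-position formula: per specimen,
#' `d15N_Phe = base + e1` and
#' `d15N_Glu = d15N_Phe + beta + tef * (tp_true - 1) + e2`, with independent
#' Gaussian errors of standard deviation `noise_sd`.
#'
#' @param tp_true Generating trophic position.
#' @param n Number of specimens (>= 1).
#' @param d15n_phe_base Baseline phenylalanine delta-15N in permil
#'   (default 7.3, a typical shallow-water primary-consumer value).
#' @param noise_sd Per-measurement noise in permil (>= 0).
#' @param beta,tef Calibration constants of the TP formula.
#' @param group Group label written into the records.
#' @param seed Integer seed (required).
#' @return An isotope tibble `specimen_id`, `group`, `d15n_glu`, `d15n_phe`.
#' @export
simulate_aa_isotopes <- function(tp_true, n, d15n_phe_base = 7.3,
                                 noise_sd = 0.5, beta = 3.4, tef = 7.6,
                                 group = "sim", seed = NULL) {
  seed <- check_seed(seed)
  stopifnot(n >= 1, noise_sd >= 0)
  withr::with_seed(seed, {
    phe <- d15n_phe_base + rnorm(n, 0, noise_sd)
    glu <- phe + beta + tef * (tp_true - 1) + rnorm(n, 0, noise_sd)
    tibble(
      specimen_id = sprintf("%s%03d", group, seq_len(n)),
      group = group, d15n_glu = glu, d15n_phe = phe
    )
  })
}
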