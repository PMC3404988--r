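# Trophic position from compound-specific amino-acid delta-15N.
#
# Glutamic acid enriches in 15N by the trophic enrichment factor (TEF,
# 7.6 permil per trophic level in the standard marine calibration) at each
# trophic transfer while phenylalanine barely fractionates, so the Glu-Phe
# offset beyond the producer-level baseline (beta = 3.4 permil) counts
# trophic steps:
#   TP = (d15N_Glu - d15N_Phe - beta) / TEF + 1.

# display rounding: half away from zero, one decimal, as printed in isotope
# tables (plain round() would take 1.95 to 1.9)
round_display <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Trophic position from glutamic-acid and phenylalanine delta-15N
#'
#' @param d15n_glu,d15n_phe delta-15N values in permil vs air; vectorised.
#' @param beta Producer-level Glu-Phe offset in permil (default 3.4).
#' @param tef Trophic enrichment factor in permil per level (default 7.6,
#'   must be positive).
#' @return Numeric trophic position(s) at full precision; see
#'   [tp_estimate()] for a table that adds the one-decimal display value.
#' @export
#' @examples
#' trophic_position(17.4, 7.3) # ~1.88, displays as 1.9
trophic_position <- function(d15n_glu, d15n_phe, beta = 3.4, tef = 7.6) {
  if (!is.numeric(tef) || length(tef) != 1 || !is.finite(tef) || tef <= 0) {
    abort("tef must be a single positive number", class = "trflpr_input_error")
  }
  if (anyNA(d15n_glu) || anyNA(d15n_phe) ||
      any(!is.finite(d15n_glu)) || any(!is.finite(d15n_phe))) {
    abort("delta-15N inputs must be finite", class = "trflpr_input_error")
  }
  (d15n_glu - d15n_phe - beta) / tef + 1
}

#' Per-specimen trophic positions from an isotope table
#'
#' @param records Data frame with columns `specimen_id`, `d15n_glu`,
#'   `d15n_phe` and optionally `group`.
#' @inheritParams trophic_position
#' @return A tibble with the input columns plus `tp` (full precision) and
#'   `tp_display` (rounded to one decimal, half away from zero).
#' @export
tp_estimate <- function(records, beta = 3.4, tef = 7.6) {
  need <- c("specimen_id", "d15n_glu", "d15n_phe")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0) {
    abort(sprintf("isotope table is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "trflpr_schema_error")
  }
  records |>
    as_tibble() |>
    mutate(tp = trophic_position(.data$d15n_glu, .data$d15n_phe,
                                 beta = beta, tef = tef),
           tp_display = round_display(.data$tp))
}

#' Group-level trophic position with dispersion
#'
#' Computes the trophic position per specimen, then averages within groups
#' and reports the 1-sigma dispersion across specimens (absent for n = 1).
#' Also reports `tp_from_mean_deltas`, the trophic position of the
#' group-averaged delta values; the two differ slightly because the TP
#' formula is applied before vs after averaging (isotope tables are
#' conventionally printed from per-specimen averaging).
#'
#' @param records Isotope table with a `group` column (a single implicit
#'   group is assumed when absent).
#' @param sd_type `"sample"` (divisor n-1, default) or `"population"`
#'   (divisor n) for the dispersion.
#' @inheritParams trophic_position
#' @return A tibble `group`, `n`, `tp_mean`, `tp_sd`, `tp_display`,
#'   `tp_from_mean_deltas`.
#' @export
#' @examples
#' recs <- tibble::tibble(specimen_id = 1:3, group = "fresh",
#'                        d15n_glu = c(17.0, 17.4, 17.8),
#'                        d15n_phe = c(7.0, 7.3, 7.6))
#' group_tp(recs)
group_tp <- function(records, sd_type = c("sample", "population"),
                     beta = 3.4, tef = 7.6) {
  sd_type <- match.arg(sd_type)
  if (nrow(records) == 0) {
    abort("isotope table is empty", class = "trflpr_input_error")
  }
  if (!"group" %in% names(records)) records$group <- "all"
  per <- tp_estimate(records, beta = beta, tef = tef)
  sd_fun <- function(v) {
    if (length(v) < 2) return(NA_real_)
    s <- sd(v)
    if (sd_type == "population") s * sqrt((length(v) - 1) / length(v)) else s
  }
  per |>
    group_by(.data$group) |>
    summarise(
      n = n(),
      tp_mean = mean(.data$tp),
      tp_sd = sd_fun(.data$tp),
      tp_from_mean_deltas = trophic_position(mean(.data$d15n_glu),
                                             mean(.data$d15n_phe),
                                             beta = beta, tef = tef),
      .groups = "drop"
    ) |>
    mutate(tp_display = round_display(.data$tp_mean)) |>
    select(all_of(c("group", "n", "tp_mean", "tp_sd", "tp_display",
                    "tp_from_mean_deltas")))
}
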