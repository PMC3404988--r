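# Brunner-Munzel rank statistic and its permutation test.
#
# The Brunner-Munzel test addresses the two-sample nonparametric
# Behrens-Fisher problem: it tests H0: P(X < Y) + 0.5 P(X = Y) = 1/2 using
# pooled midranks, without assuming equal variances or shapes. The
# permutation variant replaces the t-approximation by a null distribution
# obtained from group-label reassignment, which is preferable at the small
# per-month sample sizes typical of field collections.

#' Brunner-Munzel statistic and stochastic-superiority estimate
#'
#' Computes the relative-effect estimate
#' `p_hat = P(X < Y) + 0.5 P(X = Y)` from pooled midranks, and the
#' studentized Brunner-Munzel statistic. When the pooled rank variance is
#' zero the statistic is 0 if all values are tied, and +/-Inf for perfect
#' group separation; groups of size one contribute zero variance.
#'
#' @param x,y Numeric samples, both non-empty.
#' @return An object of class `trf_bm`: list with `statistic`, `p_hat`,
#'   `n_x`, `n_y`.
#' @export
#' @examples
#' brunner_munzel(c(1, 3), c(2, 4)) # p_hat = 0.75
brunner_munzel <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    abort("both samples must be non-empty", class = "trflpr_input_error")
  }
  if (!is.numeric(x) || !is.numeric(y) || anyNA(x) || anyNA(y)) {
    abort("samples must be numeric without missing values",
          class = "trflpr_input_error")
  }
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  rx_in <- rank(x); ry_in <- rank(y)
  Rx <- r[seq_len(nx)]; Ry <- r[nx + seq_len(ny)]
  m1 <- mean(Rx); m2 <- mean(Ry)
  p_hat <- (m2 - (ny + 1) / 2) / nx
  v1 <- if (nx > 1) sum((Rx - rx_in - m1 + (nx + 1) / 2)^2) / (nx - 1) else 0
  v2 <- if (ny > 1) sum((Ry - ry_in - m2 + (ny + 1) / 2)^2) / (ny - 1) else 0
  denom <- sqrt(nx * v1 + ny * v2)
  num <- nx * ny * (m2 - m1) / (nx + ny)
  statistic <- if (denom == 0) {
    if (num == 0) 0 else sign(num) * Inf
  } else {
    num / denom
  }
  structure(
    list(statistic = statistic, p_hat = p_hat, n_x = nx, n_y = ny),
    class = "trf_bm"
  )
}

#' @export
print.trf_bm <- function(x, ...) {
  cat(sprintf("Brunner-Munzel: W = %.4g, p_hat = P(X<Y)+0.5P(X=Y) = %.4g (n = %d vs %d)\n",
              x$statistic, x$p_hat, x$n_x, x$n_y))
  invisible(x)
}

# threshold for |W*| >= |W_obs| comparisons, robust to rounding and to
# infinite observed statistics
abs_threshold <- function(w_obs) {
  aw <- abs(w_obs)
  if (!is.finite(aw)) return(Inf)
  aw - 1e-9 * max(1, aw)
}

#' Permuted Brunner-Munzel two-sample test
#'
#' Derives the null distribution of the Brunner-Munzel statistic by
#' reassigning the pooled values to groups of the observed sizes. When the
#' number of distinct assignments `choose(n_x + n_y, n_x)` does not exceed
#' `exhaustive_limit` all assignments are enumerated and the two-sided
#' p-value is the exact proportion with `|W*| >= |W_obs|`; otherwise
#' `n_perm` seeded Monte-Carlo reassignments are drawn and
#' `p = (1 + #{|W*| >= |W_obs|}) / (1 + n_perm)`, which can never be zero.
#' Degenerate permutations with zero rank variance contribute `|W*| = 0`
#' (or Inf under perfect separation, mirroring the observed convention).
#'
#' @param x,y Numeric samples with `length(x) + length(y) >= 4`.
#' @param n_perm Monte-Carlo permutation count (default 10000).
#' @param seed Optional integer seed for the Monte-Carlo draw.
#' @param exhaustive_limit Enumerate exhaustively when the number of distinct
#'   assignments is at most this (default 20000).
#' @return An object of class `trf_bm_test`: `statistic`, `p_hat`,
#'   `p_value`, `n_perm` (draws or assignments used), `exhaustive`, `n_x`,
#'   `n_y`.
#' @export
#' @examples
#' permuted_bm_test(c(1, 2, 3), c(4, 5, 6))$p_value # exact 2/20
permuted_bm_test <- function(x, y, n_perm = 10000, seed = NULL,
                             exhaustive_limit = 20000) {
  if (length(x) + length(y) < 4) {
    abort("the permutation null needs at least 4 observations in total; collect more samples or use the observed relative effect descriptively",
          class = "trflpr_input_error")
  }
  obs <- brunner_munzel(x, y)
  pooled <- c(x, y)
  N <- length(pooled); nx <- length(x)
  n_assign <- choose(N, nx)
  thr <- abs_threshold(obs$statistic)
  if (n_assign <= exhaustive_limit) {
    xidx <- combn(N, nx)
    stats <- cpp_bm_assignments(pooled, xidx)
    p <- mean(abs(stats) >= thr)
    res <- list(statistic = obs$statistic, p_hat = obs$p_hat, p_value = p,
                n_perm = as.integer(n_assign), exhaustive = TRUE,
                n_x = obs$n_x, n_y = obs$n_y)
  } else {
    draw <- function() cpp_bm_perm(pooled, nx, as.integer(n_perm))
    stats <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    p <- (1 + sum(abs(stats) >= thr)) / (1 + n_perm)
    res <- list(statistic = obs$statistic, p_hat = obs$p_hat, p_value = p,
                n_perm = as.integer(n_perm), exhaustive = FALSE,
                n_x = obs$n_x, n_y = obs$n_y)
  }
  structure(res, class = "trf_bm_test")
}

#' @export
print.trf_bm_test <- function(x, ...) {
  cat(sprintf(
    "Permuted Brunner-Munzel test\n  W = %.4g, p_hat = %.4g\n  two-sided p = %.4g (%s, %d %s)\n  n = %d vs %d\n",
    x$statistic, x$p_hat, x$p_value,
    if (x$exhaustive) "exhaustive" else "Monte-Carlo",
    x$n_perm, if (x$exhaustive) "assignments" else "draws",
    x$n_x, x$n_y))
  invisible(x)
}

#' @rdname permuted_bm_test
#' @param x A `trf_bm_test`.
#' @param ... Unused.
#' @export
tidy.trf_bm_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_hat = x$p_hat, p_value = x$p_value,
         n_perm = x$n_perm, exhaustive = x$exhaustive,
         n_x = x$n_x, n_y = x$n_y)
}

#' @rdname permuted_bm_test
#' @export
glance.trf_bm_test <- function(x, ...) tidy(x)

#' Compare a category's relative abundance between two months
#'
#' Extracts the per-sample RA of one T-RF category in two collection months
#' and runs the permuted Brunner-Munzel test. Samples in which the category
#' was not detected enter as 0%; if the category is absent from every sample
#' of a month a warning is issued. Months with fewer than three samples are
#' flagged low-power.
#'
#' @param profiles Long profile tibble from [relative_abundance()].
#' @param category Category label to compare.
#' @param month_a,month_b Collection months (values of the `month` column).
#' @inheritParams permuted_bm_test
#' @return A `trf_bm_test` with extra fields `category`, `months`,
#'   `n_per_month`, `low_power`.
#' @export
compare_months <- function(profiles, category, month_a, month_b,
                           n_perm = 10000, seed = NULL,
                           exhaustive_limit = 20000) {
  stopifnot(all(c("sample_id", "month", "category", "ra_pct") %in% names(profiles)))
  month_ra <- function(m) {
    sub <- profiles |> filter(.data$month == m)
    if (nrow(sub) == 0) {
      abort(sprintf("no profiles for month %s", m), class = "trflpr_input_error")
    }
    samples <- unique(sub$sample_id)
    hit <- sub |> filter(.data$category == !!category)
    if (nrow(hit) == 0) {
      warn(sprintf("category %s absent from all samples of month %s; treated as zeros",
                   category, m))
    }
    ra <- setNames(rep(0, length(samples)), samples)
    ra[hit$sample_id] <- hit$ra_pct
    unname(ra)
  }
  xa <- month_ra(month_a)
  xb <- month_ra(month_b)
  res <- permuted_bm_test(xa, xb, n_perm = n_perm, seed = seed,
                          exhaustive_limit = exhaustive_limit)
  res$category <- category
  res$months <- c(month_a, month_b)
  res$n_per_month <- c(length(xa), length(xb))
  res$low_power <- any(res$n_per_month < 3)
  res
}
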