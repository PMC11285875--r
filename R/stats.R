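# Nonparametric inference used throughout the incubation analysis,
# implemented from the rank definitions so every step (mid-ranks, tie
# correction, pooled variance) is explicit and testable.

# mid-ranks and the tie sum T = sum(t^3 - t) over tied groups
rank_info <- function(values) {
  r <- rank(values, ties.method = "average")
  t <- table(values)
  list(ranks = r, tie_sum = sum(t^3 - t), n = length(values))
}

check_groups <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop_domain("values and groups must have equal length")
  }
  if (any(!is.finite(values))) stop_domain("values must be finite")
  counts <- table(groups)
  if (length(counts) < 2) stop_domain("at least 2 groups are required")
  if (any(counts < 2)) {
    stop_domain(sprintf("every group needs n >= 2 (smallest has %d)",
                        min(counts)))
  }
  invisible(counts)
}

#' Kruskal-Wallis rank test with tie correction
#'
#' Tie-corrected Kruskal-Wallis H across k groups:
#' H = \[12 / (N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2\] / C with the tie
#' correction C = 1 - sum(t^3 - t) / (N^3 - N) over tied value groups; the
#' p value uses the chi-square approximation with k - 1 degrees of
#' freedom (adequate at the design's 8 replicates per group).
#'
#' @param data A data frame.
#' @param value,group Columns (tidy-eval) holding the measurements and
#'   group labels. Groups are typically treatment x timepoint cells.
#' @return A one-row tibble: `statistic` (H), `df`, `p_value`,
#'   `n_groups`, `n_total`, `tie_correction`.
#' @examples
#' vials <- sim_vials(sim_config(), seed = 1)
#' vials |> dplyr::mutate(cell = paste(treatment, timepoint_h)) |>
#'   kw_test(act_ca45_skel_kbq, cell)
#' @export
kw_test <- function(data, value, group) {
  values <- dplyr::pull(data, {{ value }})
  groups <- dplyr::pull(data, {{ group }})
  check_groups(values, groups)
  ri <- rank_info(values)
  N <- ri$n
  means <- tapply(ri$ranks, groups, mean)
  sizes <- tapply(ri$ranks, groups, length)
  h_raw <- 12 / (N * (N + 1)) * sum(sizes * (means - (N + 1) / 2)^2)
  C <- 1 - ri$tie_sum / (N^3 - N)
  if (C == 0) stop_domain("all values are tied; H is undefined")
  h <- h_raw / C
  k <- length(means)
  tibble(statistic = h, df = k - 1,
         p_value = pchisq(h, k - 1, lower.tail = FALSE),
         n_groups = k, n_total = N, tie_correction = C)
}

#' Dunn post-hoc comparisons with Sidak correction
#'
#' Pairwise Dunn z statistics on mean ranks from the pooled ranking,
#' z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j)),
#' with T = sum(t^3 - t) the tie sum. Raw two-sided normal p values are
#' Sidak-adjusted over all m = k(k-1)/2 comparisons:
#' p_adj = 1 - (1 - p)^m.
#'
#' @inheritParams kw_test
#' @return A tibble with one row per pair: `group1`, `group2`, `z`,
#'   `p_value`, `p_adj`, `m`.
#' @examples
#' vials <- sim_vials(sim_config(), seed = 1)
#' vials |> dplyr::mutate(cell = paste(treatment, timepoint_h)) |>
#'   dunn_sidak(act_ca45_skel_kbq, cell) |> head()
#' @export
dunn_sidak <- function(data, value, group) {
  values <- dplyr::pull(data, {{ value }})
  groups <- dplyr::pull(data, {{ group }})
  check_groups(values, groups)
  ri <- rank_info(values)
  N <- ri$n
  means <- tapply(ri$ranks, groups, mean)
  sizes <- tapply(ri$ranks, groups, length)
  lev <- names(means)
  k <- length(lev)
  m <- k * (k - 1) / 2
  pooled_var <- N * (N + 1) / 12 - ri$tie_sum / (12 * (N - 1))
  pairs <- utils::combn(seq_len(k), 2)
  tibble(
    group1 = lev[pairs[1, ]],
    group2 = lev[pairs[2, ]],
    z = as.numeric((means[pairs[1, ]] - means[pairs[2, ]]) /
      sqrt(pooled_var * (1 / sizes[pairs[1, ]] + 1 / sizes[pairs[2, ]]))),
  ) |>
    mutate(p_value = 2 * pnorm(-abs(.data$z)),
           p_adj = 1 - (1 - .data$p_value)^m,
           m = m)
}

#' Pearson correlation with t-based p value
#'
#' Sample Pearson correlation r between two columns, with the two-sided p
#' value from t = r sqrt((n-2)/(1-r^2)) on n - 2 degrees of freedom.
#'
#' @param data A data frame.
#' @param x,y Columns (tidy-eval); need n >= 3 and nonzero variance.
#' @return A one-row tibble: `r`, `statistic` (t), `df`, `p_value`, `n`.
#' @examples
#' pearson_cor(data.frame(a = 1:10, b = (1:10)^2), a, b)
#' @export
pearson_cor <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  n <- length(xv)
  if (n < 3) stop_domain("pearson_cor() needs n >= 3")
  if (var(xv) == 0 || var(yv) == 0) {
    stop_domain("zero variance in x or y")
  }
  r <- sum((xv - mean(xv)) * (yv - mean(yv))) /
    sqrt(sum((xv - mean(xv))^2) * sum((yv - mean(yv))^2))
  if (abs(r) >= 1) {
    tstat <- Inf * sign(r)
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), n - 2)
  }
  tibble(r = r, statistic = tstat, df = n - 2, p_value = p, n = n)
}
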