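## broom-style tidiers for the package's result objects.

#' Tidy a gene-set enrichment result
#'
#' @param x A `gsea_result` from [gsea()].
#' @param ... Unused.
#' @return A plain tibble, one row per scored set, with a `direction` column.
#' @export
tidy.gsea_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "gsea_result")
  mutate(out, direction = ifelse(.data$es >= 0, "up", "down"))
}

#' One-row summary of a gene-set enrichment run
#'
#' @param x A `gsea_result`.
#' @param q_cutoff Significance threshold used for the `n_significant` count.
#' @param ... Unused.
#' @return A one-row tibble: sets scored, significant count, permutations,
#'   universe size.
#' @export
glance.gsea_result <- function(x, q_cutoff = 0.1, ...) {
  tibble(
    n_sets = nrow(x),
    n_significant = sum(x$q_value <= q_cutoff),
    n_perm = attr(x, "n_perm"),
    universe_size = attr(x, "universe_size")
  )
}

#' Tidy a hub report
#'
#' @param x A `hub_report` from [identify_common_hubs()].
#' @param ... Unused.
#' @return A plain tibble of ranked candidates.
#' @export
tidy.hub_report <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "hub_report")
  out
}

#' One-row summary of a hub report
#'
#' @param x A `hub_report`.
#' @param ... Unused.
#' @return A one-row tibble: candidate count, top hub and its degree and
#'   empirical p (NA if the null has not been run).
#' @export
glance.hub_report <- function(x, ...) {
  tibble(
    n_candidates = nrow(x),
    top_hub = if (nrow(x)) x$id[x$rank == 1][1] else NA_character_,
    top_degree = if (nrow(x)) x$combined_degree[x$rank == 1][1] else NA_integer_,
    empirical_p = if (nrow(x)) x$empirical_p[x$rank == 1][1] else NA_real_
  )
}

#' Tidy a random-seed null result
#'
#' @param x A `hub_null` from [random_seed_null()].
#' @param ... Unused.
#' @return A tibble with one row per null iteration (`iteration`,
#'   `null_stat`) plus the observed value and statistic name as columns.
#' @export
tidy.hub_null <- function(x, ...) {
  tibble(
    iteration = seq_along(x$null_stats),
    null_stat = x$null_stats,
    observed = x$observed,
    statistic = x$statistic
  )
}

#' One-row summary of a random-seed null
#'
#' @param x A `hub_null`.
#' @param ... Unused.
#' @return A one-row tibble: empirical p, observed value, null mean/max,
#'   iteration and seed counts.
#' @export
glance.hub_null <- function(x, ...) {
  tibble(
    empirical_p = x$empirical_p,
    observed = x$observed,
    null_mean = mean(x$null_stats),
    null_max = max(x$null_stats),
    n_iterations = x$n_iterations,
    n_random_seeds = x$n_random_seeds
  )
}
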