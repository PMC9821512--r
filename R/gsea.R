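## Cutoff-free gene-set enrichment on a ranked fold-change list.
##
## The statistic is the weighted Kolmogorov-Smirnov running sum: walking down
## the ranked list, members ("hits") increment the sum by |score|^exponent
## normalised over hits, non-members decrement by 1/(N - N_hits); the
## enrichment score is the extremum by absolute value. Significance comes from
## a gene-label permutation null (random member sets of equal size), the only
## null available when no sample-level data survive to this stage.

#' Weighted running-sum enrichment score
#'
#' @param ranked Ranked list tibble (`gene_id`, `score`), sorted descending
#'   (see [compute_ranked_list()]).
#' @param members Character vector of member gene IDs.
#' @param weight_exponent Weight on |score| for hit increments. 0 gives the
#'   classical unweighted KS statistic; 1 (default) the weighted statistic.
#' @return A list with `es` (scalar in [-1, 1]) and `running_sum` (numeric
#'   vector along the ranked list, ending at 0 up to floating error).
#' @export
enrichment_score <- function(ranked, members, weight_exponent = 1) {
  hit <- ranked$gene_id %in% members
  n <- nrow(ranked)
  n_hit <- sum(hit)
  if (n_hit == 0) {
    abort("No members of the set are present in the ranked list.",
          class = "hubseeker_undefined_score")
  }
  if (n_hit == n) {
    abort("Set equals the ranked universe; enrichment is undefined.",
          class = "hubseeker_undefined_score")
  }
  rs <- running_sum_impl(ranked$score, hit, weight_exponent)
  es <- rs[which.max(abs(rs))]
  list(es = es, running_sum = rs)
}

running_sum_impl <- function(scores, hit, weight_exponent) {
  w <- abs(scores)^weight_exponent
  inc <- ifelse(hit, w, 0)
  tot <- sum(inc)
  if (tot == 0) inc[hit] <- 1 / sum(hit) else inc <- inc / tot
  dec <- ifelse(hit, 0, 1 / (length(hit) - sum(hit)))
  cumsum(inc - dec)
}

#' Permutation p-value and normalised enrichment score for one set
#'
#' The null distribution is the enrichment score of `n_perm` random member
#' sets of equal size drawn from the ranked universe (gene-label
#' permutation). `p = (1 + #\{|es_null| >= |es_obs|\}) / (1 + n_perm)`;
#' `nes = es_obs / mean(|es_null|)` over null scores sharing the observed
#' sign. A degenerate all-zero null is flagged and reported with p = 1.
#'
#' @inheritParams enrichment_score
#' @param n_perm Number of permutations (>= 100).
#' @param rng_seed Integer seed; identical seeds give identical results.
#' @return A list with `es`, `nes`, `p_value`, `n_hits` and `degenerate`.
#' @export
permutation_p <- function(ranked, members, n_perm = 1000L, rng_seed = 1L,
                          weight_exponent = 1) {
  n_perm <- assert_scalar_int(n_perm, "n_perm", min = 100)
  rng_seed <- assert_scalar_int(rng_seed, "rng_seed")
  obs <- enrichment_score(ranked, members, weight_exponent)
  n <- nrow(ranked)
  n_hit <- sum(ranked$gene_id %in% members)
  null_es <- withr::with_seed(rng_seed, {
    vapply(seq_len(n_perm), function(i) {
      hit <- logical(n)
      hit[sample.int(n, n_hit)] <- TRUE
      rs <- running_sum_impl(ranked$score, hit, weight_exponent)
      rs[which.max(abs(rs))]
    }, numeric(1))
  })
  if (all(null_es == 0)) {
    return(list(es = obs$es, nes = NA_real_, p_value = 1, n_hits = n_hit,
                degenerate = TRUE))
  }
  p <- (1 + sum(abs(null_es) >= abs(obs$es))) / (1 + n_perm)
  same_sign <- null_es[sign(null_es) == sign(obs$es)]
  nes <- if (length(same_sign)) obs$es / mean(abs(same_sign)) else NA_real_
  list(es = obs$es, nes = nes, p_value = p, n_hits = n_hit, degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Thin validated wrapper around `p.adjust(method = "BH")`.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Vector of q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    abort("p-values must lie in (0, 1].", class = "hubseeker_validation_error")
  }
  p.adjust(p_values, method = "BH")
}

#' Gene-set enrichment over a collection
#'
#' Clips every set to the ranked universe, drops sets outside
#' `[min_set_size, max_set_size]`, scores the rest with
#' [permutation_p()] and BH-adjusts across the scored sets.
#'
#' @inheritParams permutation_p
#' @param collection Gene-set tibble (`set_id`, `description`, `members`
#'   list-column), e.g. from [read_gmt()].
#' @param min_set_size,max_set_size Post-clipping size bounds.
#' @return A `gsea_result` tibble: `set_id`, `es`, `nes`, `p_value`,
#'   `q_value`, `n_hits`.
#' @export
gsea <- function(ranked, collection, n_perm = 1000L, rng_seed = 1L,
                 weight_exponent = 1, min_set_size = 5L, max_set_size = 500L) {
  universe <- ranked$gene_id
  clipped <- map(collection$members, ~ intersect(.x, universe))
  keep <- lengths(clipped) >= min_set_size & lengths(clipped) <= max_set_size &
    lengths(clipped) < length(universe)
  if (!any(keep)) {
    res <- tibble(set_id = character(), es = numeric(), nes = numeric(),
                  p_value = numeric(), q_value = numeric(), n_hits = integer())
    return(structure(res, class = c("gsea_result", class(res)),
                     n_perm = n_perm, universe_size = length(universe)))
  }
  scored <- purrr::map2(collection$set_id[keep], clipped[keep], function(id, mem) {
    # per-set seed derived from the run seed so results do not depend on
    # collection order
    seed_i <- (rng_seed + strtoi(substr(rlang::hash(id), 1, 7), base = 16L)) %%
      .Machine$integer.max
    r <- permutation_p(ranked, mem, n_perm = n_perm, rng_seed = seed_i,
                       weight_exponent = weight_exponent)
    tibble(set_id = id, es = r$es, nes = r$nes, p_value = r$p_value,
           n_hits = r$n_hits)
  })
  res <- bind_rows(scored)
  res$q_value <- bh_adjust(res$p_value)
  res <- res[, c("set_id", "es", "nes", "p_value", "q_value", "n_hits")]
  res <- res[order(res$p_value, -abs(res$es), res$set_id), ]
  structure(res, class = c("gsea_result", class(res)),
            n_perm = n_perm, universe_size = length(universe))
}

#' Build an enrichment-map overlap graph from enrichment results
#'
#' Nodes are the gene sets passing the q-value cutoff, annotated with the
#' direction of their enrichment score; undirected edges connect set pairs
#' whose overlap coefficient `|A ∩ B| / min(|A|, |B|)` (over the ranked
#' universe) reaches `overlap_cutoff`, carrying the shared-member count — the
#' quantity an enrichment-map drawing encodes as edge thickness.
#'
#' @param results A `gsea_result` (or any tibble with `set_id`, `es`,
#'   `q_value`).
#' @param collection The gene-set collection the results came from.
#' @param universe Character vector: the ranked gene universe.
#' @param q_cutoff Significance threshold on `q_value`.
#' @param overlap_cutoff Minimum overlap coefficient for an edge.
#' @return An `enrichment_map` list with tibbles `nodes` (`set_id`,
#'   `direction`, `size`, `es`, `q_value`) and `edges` (`set_a`, `set_b`,
#'   `shared_count`, `overlap_coefficient`).
#' @export
build_enrichment_map <- function(results, collection, universe,
                                 q_cutoff = 0.1, overlap_cutoff = 0.25) {
  sig <- results[results$q_value <= q_cutoff, ]
  members <- setNames(map(collection$members, ~ intersect(.x, universe)),
                      collection$set_id)
  nodes <- tibble(
    set_id = sig$set_id,
    direction = ifelse(sig$es >= 0, "up", "down"),
    size = lengths(members[sig$set_id]),
    es = sig$es,
    q_value = sig$q_value
  )
  edges <- tibble(set_a = character(), set_b = character(),
                  shared_count = integer(), overlap_coefficient = numeric())
  if (nrow(nodes) > 1) {
    pairs <- utils::combn(sort(nodes$set_id), 2)
    rows <- map(seq_len(ncol(pairs)), function(k) {
      a <- members[[pairs[1, k]]]; b <- members[[pairs[2, k]]]
      shared <- length(intersect(a, b))
      coef <- if (min(length(a), length(b)) == 0) 0 else shared / min(length(a), length(b))
      tibble(set_a = pairs[1, k], set_b = pairs[2, k],
             shared_count = shared, overlap_coefficient = coef)
    })
    edges <- bind_rows(rows)
    edges <- edges[edges$overlap_coefficient >= overlap_cutoff & edges$shared_count > 0, ]
  }
  structure(list(nodes = nodes, edges = edges), class = "enrichment_map")
}

#' @export
print.enrichment_map <- function(x, ...) {
  cat(sprintf("enrichment_map: %d enriched sets, %d overlap edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Write an enrichment map as node and edge TSVs
#'
#' @param map An `enrichment_map`.
#' @param node_path,edge_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_enrichment_map <- function(map, node_path, edge_path) {
  readr::write_tsv(map$nodes, node_path)
  readr::write_tsv(map$edges, edge_path)
  invisible(c(node_path, edge_path))
}
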