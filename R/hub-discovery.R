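## Seed-anchored subnetwork expansion, centrality ranking and common-hub
## calling on a reference interactome.
##
## A disorder subnetwork is the reference-induced subgraph on all nodes within
## shortest-path distance <= depth of the seed set (depth 2 by default: the
## seeds plus their first and second neighbors). Combining subnetworks
## re-induces edges from the reference, so interactions bridging two disorder
## subnetworks are restored. Candidate common hubs are intermediate
## (non-seed) nodes present in at least `min_disorders` subnetworks, ranked
## by combined-network degree with betweenness then ID as tie-breaks.

#' Map a disorder seed set onto the reference network
#'
#' @param network Reference igraph.
#' @param seeds A seed set: either a character vector of IDs or a list with
#'   `disorder` and `members` (see [read_seed_set()]).
#' @return A list with `mapped` and `unmapped` ID vectors.
#' @export
map_seeds <- function(network, seeds) {
  assert_graph(network)
  members <- if (is.list(seeds)) seeds$members else seeds
  mapped <- intersect(members, node_names(network))
  unmapped <- setdiff(members, mapped)
  if (!length(mapped)) {
    abort("No seed maps to the reference network; the subnetwork is undefined.",
          class = "hubseeker_mapping_error")
  }
  if (length(unmapped)) {
    message(sprintf("map_seeds: %d of %d seed(s) not in the reference network.",
                    length(unmapped), length(members)))
  }
  list(mapped = mapped, unmapped = unmapped)
}

#' Expand a seed set into its neighborhood subnetwork
#'
#' Includes every node at shortest-path distance <= `depth` from any seed and
#' the reference edges among the included nodes. Node roles record the exact
#' distance (`seed`, `neighbor1`, `neighbor2`). Iterating first-neighbor
#' expansion `depth` times yields the same node set.
#'
#' @param network Reference igraph.
#' @param seeds Character vector of seed IDs, all present in the network.
#' @param depth Expansion depth (default 2: seeds plus their first and second
#'   neighbors).
#' @param disorder Optional label carried into the result.
#' @return A `ppi_subnetwork`: list with `disorder`, `graph` (induced
#'   igraph), `roles` (tibble `id`, `distance`, `role`) and `depth`.
#' @export
expand_subnetwork <- function(network, seeds, depth = 2L, disorder = NA_character_) {
  assert_graph(network)
  depth <- assert_scalar_int(depth, "depth", min = 0)
  if (!all(seeds %in% node_names(network))) {
    abort("All seeds must be nodes of the reference network (run map_seeds first).",
          class = "hubseeker_mapping_error")
  }
  d <- igraph::distances(network, v = seeds)
  dist_min <- apply(d, 2, min)
  keep <- names(dist_min)[dist_min <= depth]
  sub <- igraph::induced_subgraph(network, keep)
  dist_kept <- as.integer(dist_min[keep])
  roles <- tibble(
    id = keep,
    distance = dist_kept,
    role = ifelse(dist_kept == 0L, "seed", paste0("neighbor", dist_kept))
  )
  structure(list(disorder = disorder, graph = sub, roles = roles, depth = depth),
            class = "ppi_subnetwork")
}

#' @export
print.ppi_subnetwork <- function(x, ...) {
  cat(sprintf("ppi_subnetwork '%s': %d nodes (%d seeds) / %d edges, depth %d\n",
              x$disorder, igraph::vcount(x$graph), sum(x$roles$role == "seed"),
              igraph::ecount(x$graph), x$depth))
  invisible(x)
}

#' Degree and betweenness centrality table for a subnetwork
#'
#' Degree and normalised shortest-path betweenness are computed within the
#' scoped graph. Dense ranks follow `rank_key`; ties break by the other
#' measure, then lexicographic ID. `degree_then_betweenness` sorts by degree
#' with betweenness as the first tie-break.
#'
#' @param sub A `ppi_subnetwork` or a bare igraph.
#' @param rank_key `"degree"`, `"betweenness"` or `"degree_then_betweenness"`.
#' @return A tibble `id`, `degree`, `betweenness`, `rank` (dense, 1-based),
#'   sorted by rank.
#' @export
centrality_stats <- function(sub, rank_key = c("degree_then_betweenness",
                                               "degree", "betweenness")) {
  rank_key <- match.arg(rank_key)
  g <- if (inherits(sub, "ppi_subnetwork")) sub$graph else sub
  assert_graph(g, "sub")
  if (igraph::vcount(g) == 0) {
    abort("Subnetwork is empty.", class = "hubseeker_contract_error")
  }
  deg <- igraph::degree(g)
  n <- igraph::vcount(g)
  btw <- if (n > 2) {
    igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  } else {
    setNames(rep(0, n), node_names(g))
  }
  tab <- tibble(id = node_names(g), degree = as.integer(deg), betweenness = as.numeric(btw))
  key <- switch(rank_key,
    degree = order(-tab$degree, -tab$betweenness, tab$id),
    betweenness = order(-tab$betweenness, -tab$degree, tab$id),
    degree_then_betweenness = order(-tab$degree, -tab$betweenness, tab$id)
  )
  tab <- tab[key, ]
  primary <- switch(rank_key, betweenness = -tab$betweenness, -tab$degree)
  tab$rank <- dense_rank_by(primary)
  tab
}

dense_rank_by <- function(x) {
  # dense 1-based ranks over an already-sorted key
  match(x, sort(unique(x)))
}

#' Combine disorder subnetworks over their common reference
#'
#' Node set is the union of the subnetwork node sets; the edge set is
#' re-induced from the reference, restoring any reference edge between nodes
#' that entered via different subnetworks.
#'
#' @param subs List of `ppi_subnetwork` objects (or igraphs) derived from
#'   `reference`.
#' @param reference The common reference igraph.
#' @return The combined induced igraph.
#' @export
combine_subnetworks <- function(subs, reference) {
  assert_graph(reference)
  node_sets <- map(subs, function(s) {
    g <- if (inherits(s, "ppi_subnetwork")) s$graph else s
    node_names(g)
  })
  all_nodes <- unique(unlist(node_sets))
  missing <- setdiff(all_nodes, node_names(reference))
  if (length(missing)) {
    abort(sprintf("Node '%s' is not in the reference network.", missing[1]),
          class = "hubseeker_consistency_error")
  }
  igraph::induced_subgraph(reference, all_nodes)
}

#' Identify candidate common hubs across disorder subnetworks
#'
#' Candidates are intermediate nodes - never members of any seed set - that
#' appear in at least `min_disorders` of the disorder subnetworks. They are
#' ranked by degree in the combined network, with betweenness and then ID
#' breaking ties.
#'
#' @param combined Combined network from [combine_subnetworks()].
#' @param subs List of `ppi_subnetwork` objects (one per disorder).
#' @param all_seeds Character vector: union of all disorder seed IDs.
#' @param min_disorders Minimum number of subnetworks a candidate must appear
#'   in (default 6, i.e. all of them).
#' @param top_k Number of top candidates to return (`Inf` for all).
#' @return A `hub_report` tibble: `id`, `n_disorders_present`,
#'   `combined_degree`, `combined_betweenness`, `is_seed_anywhere`, `rank`,
#'   `empirical_p` (NA until [random_seed_null()] is run).
#' @export
identify_common_hubs <- function(combined, subs, all_seeds,
                                 min_disorders = length(subs), top_k = 20L) {
  assert_graph(combined, "combined")
  if (min_disorders < 1 || min_disorders > length(subs)) {
    abort("min_disorders must be between 1 and the number of subnetworks.",
          class = "hubseeker_config_error")
  }
  presence <- table(unlist(map(subs, function(s) {
    g <- if (inherits(s, "ppi_subnetwork")) s$graph else s
    node_names(g)
  })))
  cent <- centrality_stats(combined, rank_key = "degree_then_betweenness")
  report <- mutate(cent,
    n_disorders_present = as.integer(presence[.data$id]),
    is_seed_anywhere = .data$id %in% all_seeds
  )
  report$n_disorders_present[is.na(report$n_disorders_present)] <- 0L
  candidates <- filter(report, !.data$is_seed_anywhere,
                       .data$n_disorders_present >= min_disorders)
  if (nrow(candidates) == 0) {
    warn("No common-hub candidates at the requested min_disorders.")
  }
  candidates <- candidates[order(-candidates$degree, -candidates$betweenness,
                                 candidates$id), ]
  candidates$rank <- seq_len(nrow(candidates))
  out <- tibble(
    id = candidates$id,
    n_disorders_present = candidates$n_disorders_present,
    combined_degree = candidates$degree,
    combined_betweenness = candidates$betweenness,
    is_seed_anywhere = candidates$is_seed_anywhere,
    rank = candidates$rank,
    empirical_p = NA_real_
  )
  out <- head(out, n = if (is.finite(top_k)) top_k else nrow(out))
  structure(out, class = c("hub_report", class(out)))
}
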