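# Independent oracles used to check the implementation by a different route.

# Exhaustive shortest-path betweenness: enumerate every simple path between
# every ordered pair by depth-first search, keep the shortest ones, and count
# the fraction passing through each interior node. Only feasible for tiny
# graphs, which is the point.
oracle_centrality <- function(edges, nodes) {
  adj <- lapply(setNames(nodes, nodes), function(v) {
    unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))
  })
  all_paths <- function(from, to) {
    paths <- list()
    walk_on <- function(path) {
      v <- path[length(path)]
      if (v == to) {
        paths[[length(paths) + 1]] <<- path
        return(invisible())
      }
      for (u in adj[[v]]) if (!u %in% path) walk_on(c(path, u))
    }
    walk_on(from)
    paths
  }
  btw <- setNames(numeric(length(nodes)), nodes)
  n <- length(nodes)
  if (n >= 2) {
    pairs <- utils::combn(nodes, 2)
    for (k in seq_len(ncol(pairs))) {
      s <- pairs[1, k]; t <- pairs[2, k]
      paths <- all_paths(s, t)
      if (!length(paths)) next
      lens <- lengths(paths)
      shortest <- paths[lens == min(lens)]
      sigma <- length(shortest)
      interior <- unlist(lapply(shortest, function(p) p[-c(1, length(p))]))
      if (length(interior)) {
        cnt <- table(interior)
        btw[names(cnt)] <- btw[names(cnt)] + as.numeric(cnt) / sigma
      }
    }
  }
  norm <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  deg <- vapply(nodes, function(v) length(adj[[v]]), numeric(1))
  list(degree = deg, betweenness = btw / norm)
}

# Direct transliteration of the running-sum definition, computed step by step.
oracle_running_sum <- function(scores, hit, exponent) {
  n <- length(scores)
  n_hit <- sum(hit)
  w <- abs(scores)^exponent
  denom_hit <- sum(w[hit])
  rs <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    acc <- if (hit[i]) {
      acc + (if (denom_hit > 0) w[i] / denom_hit else 1 / n_hit)
    } else {
      acc - 1 / (n - n_hit)
    }
    rs[i] <- acc
  }
  rs
}

# Exact upper-tail overlap probability by enumerating every possible draw of
# |a| elements from the universe. Feasible for |U| <= 12.
oracle_overlap_p <- function(a, b, universe) {
  draws <- utils::combn(universe, length(a))
  k_obs <- length(intersect(a, b))
  hits <- apply(draws, 2, function(d) length(intersect(d, b)) >= k_obs)
  mean(hits)
}

# Small Erdos-Renyi graph with named nodes, for randomized property tests.
random_small_graph <- function(n, p = 0.4) {
  g <- igraph::sample_gnp(n, p, directed = FALSE)
  igraph::V(g)$name <- letters[seq_len(n)]
  g
}

# Minimal valid quant table for filter tests.
toy_quant <- function(protein_id, peptide_count, ctrl, trt) {
  tab <- tibble::tibble(protein_id = protein_id, peptide_count = peptide_count)
  for (j in 1:4) tab[[paste0("ctrl_", j)]] <- vapply(ctrl, `[`, numeric(1), j)
  for (j in 1:4) tab[[paste0("trt_", j)]] <- vapply(trt, `[`, numeric(1), j)
  tab
}
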