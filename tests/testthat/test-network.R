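test_that("read_network normalizes edge lists and understands SIF", {
  el <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "A\tB", "C\tC", "B\tC"), el)
  g <- suppressMessages(read_network(el))
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))  # self-loop node kept
  expect_equal(igraph::ecount(g), 2)                    # duplicate collapsed, loop dropped
  expect_true(igraph::is_simple(g))

  sif <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A pp B", "B pp C"), sif)
  gs <- read_network(sif)
  expect_equal(igraph::ecount(gs), 2)
  expect_true(igraph::are_adjacent(gs, "A", "B"))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_equal(igraph::vcount(read_network(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("only-one-column", bad)
  expect_error(read_network(bad), class = "hubseeker_parse_error")
})

test_that("network round-trips through the edge-list writer", {
  g <- generate_ppi(50, "erdos_renyi", list(p = 0.1), rng_seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(g, path)
  g2 <- read_network(path)
  key <- function(gr) {
    el <- igraph::as_edgelist(gr)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_identical(key(g2), key(g))
})

test_that("map_seeds partitions members into mapped and unmapped", {
  g <- generate_ppi(20, "erdos_renyi", list(p = 0.3), rng_seed = 1)
  ids <- igraph::V(g)$name
  all_in <- map_seeds(g, ids[1:5])
  expect_length(all_in$unmapped, 0)

  mixed <- suppressMessages(map_seeds(g, c(ids[1:3], "X1", "X2", "X3")))
  expect_setequal(mixed$mapped, ids[1:3])
  expect_setequal(mixed$unmapped, c("X1", "X2", "X3"))
  expect_equal(length(mixed$mapped) + length(mixed$unmapped), 6)

  expect_error(map_seeds(g, c("X1", "X2")), class = "hubseeker_mapping_error")
})

test_that("expansion includes exactly the nodes within the requested distance", {
  # star: center s, leaves l1..l5; seeding one leaf at depth 2 reaches all
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("s", paste0("l", 1:5))
  sub0 <- expand_subnetwork(star, "l1", depth = 0)
  expect_equal(sub0$roles$id, "l1")
  expect_equal(igraph::ecount(sub0$graph), 0)

  sub2 <- expand_subnetwork(star, "l1", depth = 2)
  expect_setequal(sub2$roles$id, igraph::V(star)$name)
  expect_equal(sub2$roles$role[sub2$roles$id == "s"], "neighbor1")
  expect_setequal(sub2$roles$id[sub2$roles$role == "neighbor2"], paste0("l", 2:5))
  # induced edges are all reference edges among included nodes
  expect_equal(igraph::ecount(sub2$graph), 5)
})

test_that("expansion roles record exact shortest-path distances and grow monotonely", {
  withr::local_seed(5)
  for (i in 1:20) {
    g <- random_small_graph(sample(5:8, 1))
    seeds <- sample(igraph::V(g)$name, sample(1:2, 1))
    nodes_prev <- character(0)
    for (depth in 0:3) {
      sub <- expand_subnetwork(g, seeds, depth = depth)
      d <- igraph::distances(g, v = seeds)
      want <- colnames(d)[apply(d, 2, min) <= depth]
      expect_setequal(sub$roles$id, want)
      expect_true(all(nodes_prev %in% sub$roles$id))  # monotone in depth
      expect_equal(sub$roles$distance,
                   as.integer(apply(d[, sub$roles$id, drop = FALSE], 2, min)))
      nodes_prev <- sub$roles$id
    }
    # large depth saturates the seed-containing components
    sat <- expand_subnetwork(g, seeds, depth = igraph::vcount(g))
    comp <- igraph::components(g)
    want <- igraph::V(g)$name[comp$membership %in%
                                unique(comp$membership[match(seeds, igraph::V(g)$name)])]
    expect_setequal(sat$roles$id, want)
  }
})

test_that("centrality matches closed-form values on canonical graphs", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("c", paste0("l", 1:4))
  cs <- centrality_stats(star)
  expect_equal(cs$degree[cs$id == "c"], 4L)
  expect_equal(cs$betweenness[cs$id == "c"], 1.0)
  expect_true(all(cs$betweenness[cs$id != "c"] == 0))
  expect_equal(cs$rank[cs$id == "c"], 1L)

  path4 <- igraph::make_graph(~ a - b, b - c, c - d)
  cp <- centrality_stats(path4)
  expect_equal(cp$betweenness[cp$id %in% c("b", "c")], c(2 / 3, 2 / 3))

  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  ck <- centrality_stats(k5)
  expect_true(all(ck$degree == 4L))
  expect_true(all(ck$betweenness == 0))
  expect_true(all(ck$rank == 1L))
})

test_that("centrality ranks are dense and tie-broken as documented", {
  # two nodes tie on degree; betweenness then ID break the ordering
  g <- igraph::make_graph(~ a - b, b - c, c - d, d - e, e - a, a - c)
  cs <- centrality_stats(g, rank_key = "degree")
  expect_equal(cs$rank, match(-cs$degree, sort(unique(-cs$degree))))
  expect_false(is.unsorted(cs$rank))
  # within equal rank, rows are ordered by betweenness desc then ID
  ties <- cs[cs$rank == max(cs$rank), ]
  expect_false(is.unsorted(rev(ties$betweenness)))
})

test_that("combining subnetworks re-induces reference edges across them", {
  # 6-node reference: two triangles joined by one bridging edge c-d
  ref <- igraph::make_graph(~ a - b, b - c, a - c, d - e, e - f, d - f, c - d)
  sub1 <- expand_subnetwork(ref, c("a"), depth = 1)   # {a,b,c}, no d
  sub2 <- expand_subnetwork(ref, c("e"), depth = 1)   # {d,e,f}, no c
  expect_false(igraph::are_adjacent(sub1$graph, "c", "b") &&
                 "d" %in% igraph::V(sub1$graph)$name)
  comb <- combine_subnetworks(list(sub1, sub2), ref)
  expect_true(igraph::are_adjacent(comb, "c", "d"))  # bridge restored
  expect_equal(igraph::ecount(comb), igraph::ecount(ref))

  # idempotence: combining copies of one subnetwork equals that subnetwork
  same <- combine_subnetworks(list(sub1, sub1), ref)
  expect_setequal(igraph::V(same)$name, igraph::V(sub1$graph)$name)
  expect_equal(igraph::ecount(same), igraph::ecount(sub1$graph))

  # union degree never drops below any per-subnetwork degree
  for (v in igraph::V(comb)$name) {
    per_sub <- purrr::map_dbl(list(sub1, sub2), function(s) {
      if (v %in% igraph::V(s$graph)$name) igraph::degree(s$graph)[v] else 0
    })
    expect_gte(igraph::degree(comb)[v], max(per_sub))
  }

  ghost <- igraph::make_graph(~ x - y)
  expect_error(combine_subnetworks(list(ghost), ref), class = "hubseeker_consistency_error")
})
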