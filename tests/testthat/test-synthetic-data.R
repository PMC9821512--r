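test_that("generate_ppi respects model limits and is deterministic", {
  # Erdos-Renyi limits: p = 0 gives no edges, p = 1 the complete graph
  g0 <- generate_ppi(10, "erdos_renyi", list(p = 0), rng_seed = 3)
  expect_equal(igraph::vcount(g0), 10)
  expect_equal(igraph::ecount(g0), 0)
  g1 <- generate_ppi(10, "erdos_renyi", list(p = 1), rng_seed = 3)
  expect_equal(igraph::ecount(g1), choose(10, 2))

  ga <- generate_ppi(500, "preferential_attachment", list(m = 3), rng_seed = 7)
  gb <- generate_ppi(500, "preferential_attachment", list(m = 3), rng_seed = 7)
  expect_identical(igraph::as_edgelist(ga), igraph::as_edgelist(gb))
  gc <- generate_ppi(500, "preferential_attachment", list(m = 3), rng_seed = 8)
  expect_false(identical(igraph::as_edgelist(ga), igraph::as_edgelist(gc)))
})

test_that("generated graphs are simple and undirected for every model", {
  for (spec in list(list(model = "preferential_attachment", params = list(m = 2)),
                    list(model = "erdos_renyi", params = list(p = 0.1)),
                    list(model = "duplication_divergence", params = list(retention = 0.4)))) {
    g <- generate_ppi(200, spec$model, spec$params, rng_seed = 11)
    expect_false(igraph::is_directed(g))
    expect_true(igraph::is_simple(g))
    expect_equal(igraph::vcount(g), 200)
  }
})

test_that("generate_ppi rejects invalid configuration", {
  expect_error(generate_ppi(5, "erdos_renyi", list(p = 0.5)), class = "hubseeker_config_error")
  expect_error(generate_ppi(100, "erdos_renyi", list(p = 2)), class = "hubseeker_config_error")
  expect_error(generate_ppi(100, "erdos_renyi"), class = "hubseeker_config_error")
  expect_error(generate_ppi(100, "duplication_divergence"), class = "hubseeker_config_error")
})

test_that("plant_hub wires one connector into every seed set and only adds edges", {
  g <- generate_ppi(30, "erdos_renyi", list(p = 0.1), rng_seed = 5)
  pl <- plant_hub(g, sizes = rep(2L, 6), links_per_set = 2, n_decoys = 0, rng_seed = 9)
  tr <- pl$truth
  expect_gte(igraph::degree(pl$network)[tr$hub_id], 12)
  # hub is an intermediate node, never a seed
  expect_false(tr$hub_id %in% unlist(tr$seed_sets))
  # conservation: every original edge survives
  orig <- igraph::as_edgelist(g)
  after <- igraph::as_edgelist(pl$network)
  key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  expect_true(all(key(orig) %in% key(after)))
  expect_identical(sort(igraph::V(pl$network)$name), sort(igraph::V(g)$name))
})

test_that("plant_hub default sizes seed 465 proteins across six disjoint sets", {
  g <- generate_ppi(2000, "preferential_attachment", list(m = 2), rng_seed = 1)
  pl <- plant_hub(g, rng_seed = 2)
  sets <- pl$truth$seed_sets
  expect_length(sets, 6)
  expect_equal(lengths(sets), c(AD = 78L, PD = 118L, HD = 46L, ALS = 39L,
                                ASD = 124L, Epilepsy = 60L))
  all_ids <- unlist(sets)
  expect_equal(length(all_ids), 465)
  expect_equal(anyDuplicated(all_ids), 0)
})

test_that("plant_hub rejects undersized networks and bad link counts", {
  g <- generate_ppi(30, "erdos_renyi", list(p = 0.2), rng_seed = 1)
  expect_error(plant_hub(g, sizes = rep(10L, 6), links_per_set = 2),
               class = "hubseeker_sizing_error")
  expect_error(plant_hub(g, sizes = rep(2L, 6), links_per_set = 0),
               class = "hubseeker_config_error")
})

test_that("quant generator plants the requested effect and missingness", {
  full <- generate_quant_table(n_proteins = 200, n_true_changed = 20,
                               missing_rate = 0, rng_seed = 4)
  ic <- paste0(rep(c("ctrl_", "trt_"), each = 4), 1:4)
  expect_false(anyNA(full$table[, ic]))
  expect_equal(sum(full$truth$changed), 20)

  # null effect: truth labels exist but the changed set has ~zero mean ratio
  nul <- generate_quant_table(n_proteins = 500, n_true_changed = 50,
                              effect_log2fc = 0, missing_rate = 0, rng_seed = 4)
  ranked <- compute_ranked_list(nul$table)
  changed <- nul$truth$protein_id[nul$truth$changed]
  expect_lt(abs(mean(ranked$score[ranked$gene_id %in% changed])), 0.1)

  # planted effect is recovered from the generator's own truth labels
  eff <- generate_quant_table(n_proteins = 1000, n_true_changed = 100,
                              effect_log2fc = 1, replicate_cv = 0.1,
                              missing_rate = 0.05, rng_seed = 4)
  ranked <- compute_ranked_list(filter_replicate_presence(eff$table))
  changed <- eff$truth$protein_id[eff$truth$changed]
  est <- mean(ranked$score[ranked$gene_id %in% changed])
  expect_gt(est, 0.8)
  expect_lt(est, 1.2)
})

test_that("multiomic generator gives the exact planted concordant count", {
  mo <- generate_multiomic(n_genes = 200, concordant_fraction = 0.25, rng_seed = 6)
  expect_equal(sum(mo$truth$concordant), 50)
  same_sign <- sign(mo$rna$log2fc) == sign(mo$protein$log2fc)
  expect_equal(sum(same_sign), 50)

  all_c <- generate_multiomic(50, 1, rng_seed = 6)
  expect_true(all(sign(all_c$rna$log2fc) == sign(all_c$protein$log2fc)))
  none <- generate_multiomic(50, 0, rng_seed = 6)
  expect_false(any(sign(none$rna$log2fc) == sign(none$protein$log2fc)))
})

test_that("bivalency generator separates classes strictly at the thresholds", {
  biv <- generate_bivalency(n_genes = 1000, bivalent_fraction = 0.3,
                            responsive_fraction = 0.3, rng_seed = 8)
  is_biv <- biv$chip$gene_id %in% biv$truth$bivalent
  expect_true(all(biv$chip$fpkm_k4[is_biv] > 1.2 & biv$chip$fpkm_k27[is_biv] > 1.2))
  expect_true(all(biv$chip$fpkm_k4[!is_biv] < 1.2 | biv$chip$fpkm_k27[!is_biv] < 1.2))
  is_resp <- biv$de$gene_id %in% biv$truth$responsive
  expect_true(all(biv$de$p_value[is_resp] < 0.05))
  expect_true(all(biv$de$p_value[!is_resp] >= 0.05))
  expect_setequal(biv$truth$overlap, intersect(biv$truth$bivalent, biv$truth$responsive))

  empty <- generate_bivalency(100, 0, 0.5, rng_seed = 8)
  expect_length(empty$truth$bivalent, 0)
  expect_length(empty$truth$overlap, 0)
})

test_that("every generator is a pure function of its seed", {
  expect_identical(generate_quant_table(rng_seed = 2), generate_quant_table(rng_seed = 2))
  expect_identical(generate_multiomic(rng_seed = 2), generate_multiomic(rng_seed = 2))
  expect_identical(generate_bivalency(rng_seed = 2), generate_bivalency(rng_seed = 2))
  g <- generate_ppi(100, "erdos_renyi", list(p = 0.05), rng_seed = 2)
  p1 <- plant_hub(g, sizes = rep(3L, 6), links_per_set = 1, rng_seed = 5)
  p2 <- plant_hub(g, sizes = rep(3L, 6), links_per_set = 1, rng_seed = 5)
  expect_identical(p1$truth, p2$truth)
  expect_identical(igraph::as_edgelist(p1$network), igraph::as_edgelist(p2$network))
})
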