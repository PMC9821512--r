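make_ranked <- function(n, scores = NULL) {
  tibble::tibble(gene_id = sprintf("g%03d", seq_len(n)),
                 score = scores %||% sort(rnorm(n), decreasing = TRUE))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("unweighted enrichment score matches the hand-computed running sum", {
  ranked <- make_ranked(10, scores = seq(5, -4))
  top2 <- enrichment_score(ranked, ranked$gene_id[1:2], weight_exponent = 0)
  expect_equal(top2$es, 1.0)
  expect_equal(top2$running_sum[1:2], c(0.5, 1.0))
  expect_true(all(diff(top2$running_sum[2:10]) < 0))

  bottom2 <- enrichment_score(ranked, ranked$gene_id[9:10], weight_exponent = 0)
  expect_equal(bottom2$es, -1.0)
  expect_equal(which.min(bottom2$running_sum), 8)  # extremum just before the first hit
})

test_that("running sum agrees with a step-by-step oracle for random sets", {
  withr::local_seed(42)
  for (i in 1:25) {
    n <- sample(8:40, 1)
    ranked <- make_ranked(n)
    n_hit <- sample(1:(n - 1), 1)
    members <- sample(ranked$gene_id, n_hit)
    expo <- sample(c(0, 1, 1.5), 1)
    got <- enrichment_score(ranked, members, weight_exponent = expo)
    want <- oracle_running_sum(ranked$score, ranked$gene_id %in% members, expo)
    expect_equal(got$running_sum, want, tolerance = 1e-12)
    expect_equal(got$es, want[which.max(abs(want))])
    # invariants: bounded score, sum returns to zero
    expect_lte(abs(got$es), 1 + 1e-12)
    expect_lt(abs(got$running_sum[n]), 1e-9)
  }
})

test_that("exponent-0 score equals the two-sample KS statistic and flips under reversal", {
  withr::local_seed(7)
  ranked <- make_ranked(50, scores = rep(1, 50))
  hitpos <- sort(sample(1:50, 6))
  es <- enrichment_score(ranked, ranked$gene_id[hitpos], weight_exponent = 0)$es
  D <- suppressWarnings(stats::ks.test(hitpos, setdiff(1:50, hitpos))$statistic)
  expect_equal(abs(es), unname(D))

  scored <- make_ranked(30)
  members <- sample(scored$gene_id, 5)
  fwd <- enrichment_score(scored, members, weight_exponent = 0)$es
  rev <- scored[nrow(scored):1, ]
  bwd <- enrichment_score(rev, members, weight_exponent = 0)$es
  expect_equal(bwd, -fwd)
})

test_that("weighted score agrees with an independent reference implementation", {
  withr::local_seed(11)
  ranked <- make_ranked(80)
  stats_vec <- stats::setNames(ranked$score, ranked$gene_id)
  for (i in 1:5) {
    idx <- sort(sample(80, 8))
    ours <- enrichment_score(ranked, ranked$gene_id[idx], weight_exponent = 1)$es
    ref <- fgsea::calcGseaStat(stats_vec, selectedStats = idx, gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("degenerate sets are rejected with an undefined-score error", {
  ranked <- make_ranked(10)
  expect_error(enrichment_score(ranked, "absent"), class = "hubseeker_undefined_score")
  expect_error(enrichment_score(ranked, ranked$gene_id), class = "hubseeker_undefined_score")
})

test_that("permutation p is deterministic, bounded below, and sane", {
  withr::local_seed(3)
  ranked <- make_ranked(100)
  members <- ranked$gene_id[1:8]  # strongly top-loaded set
  r1 <- permutation_p(ranked, members, n_perm = 200, rng_seed = 5)
  r2 <- permutation_p(ranked, members, n_perm = 200, rng_seed = 5)
  expect_identical(r1, r2)
  expect_gte(r1$p_value, 1 / 201)
  expect_lte(r1$p_value, 0.05)  # top-8 of 100 is unambiguous enrichment
  expect_gt(r1$nes, 1)
  expect_false(r1$degenerate)
})

test_that("BH adjustment matches hand computation and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.4, 5)), rep(0.4, 5))
  p <- runif(20, 0.01, 1)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 0)), class = "hubseeker_validation_error")
  expect_error(bh_adjust(c(0.5, 1.2)), class = "hubseeker_validation_error")
})

test_that("gsea over a collection recovers planted signal sets", {
  qt <- generate_quant_table(n_proteins = 300, n_true_changed = 40,
                             effect_log2fc = 1.5, rng_seed = 13)
  ranked <- compute_ranked_list(filter_replicate_presence(qt$table))
  changed <- intersect(qt$truth$protein_id[qt$truth$changed], ranked$gene_id)
  other <- setdiff(ranked$gene_id, changed)
  withr::local_seed(13)
  collection <- tibble::tibble(
    set_id = c("SIGNAL", paste0("RAND_", 1:6)),
    description = "",
    members = c(list(sample(changed, 20)),
                purrr::map(1:6, ~ sample(other, 20)))
  )
  res <- gsea(ranked, collection, n_perm = 200, rng_seed = 13)
  expect_s3_class(res, "gsea_result")
  expect_equal(res$set_id[1], "SIGNAL")
  expect_lt(res$q_value[1], 0.1)
  expect_gt(res$es[1], 0)
  # identical call reproduces identical results regardless of set order
  res_shuffled <- gsea(ranked, collection[sample(nrow(collection)), ],
                       n_perm = 200, rng_seed = 13)
  expect_equal(dplyr::arrange(tidy(res), set_id),
               dplyr::arrange(tidy(res_shuffled), set_id))
})

test_that("enrichment map applies set arithmetic and cutoffs exactly", {
  universe <- letters[1:10]
  collection <- tibble::tibble(
    set_id = c("S1", "S2", "S3", "SUB", "SUP"),
    description = "",
    members = list(c("a", "b", "c"), c("b", "c", "d"), c("h", "i", "j"),
                   c("e", "f"), c("e", "f", "g"))
  )
  results <- tibble::tibble(
    set_id = collection$set_id,
    es = c(0.8, 0.7, -0.6, 0.5, 0.4),
    q_value = c(0.01, 0.01, 0.01, 0.01, 0.01)
  )
  emap <- build_enrichment_map(results, collection, universe,
                               q_cutoff = 0.05, overlap_cutoff = 0.25)
  expect_equal(nrow(emap$nodes), 5)
  e12 <- emap$edges[emap$edges$set_a == "S1" & emap$edges$set_b == "S2", ]
  expect_equal(e12$shared_count, 2L)          # {b, c}
  expect_equal(e12$overlap_coefficient, 2 / 3)
  # subset containment gives coefficient 1 at any cutoff <= 1
  esub <- emap$edges[emap$edges$set_a == "SUB" & emap$edges$set_b == "SUP", ]
  expect_equal(esub$overlap_coefficient, 1.0)
  # disjoint significant sets share no edge
  expect_false(any(emap$edges$set_a == "S3" | emap$edges$set_b == "S3"))
  expect_equal(emap$nodes$direction[emap$nodes$set_id == "S3"], "down")

  none <- build_enrichment_map(results[0, ], collection, universe, 0.05, 0.25)
  expect_equal(nrow(none$nodes), 0)
  expect_equal(nrow(none$edges), 0)
})
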