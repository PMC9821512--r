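## Synthetic inputs with planted ground truth.
##
## Every generator is a pure function of its arguments including `rng_seed`,
## so fixtures are reproducible byte for byte and downstream stages can be
## tested against the truth records emitted alongside the data.

#' Default disorder seed-set sizes
#'
#' Sizes of the six disease seed sets used throughout (AD, PD, HD, ALS, ASD,
#' epilepsy). Their sum is 465.
#'
#' @return A named integer vector of length 6.
#' @export
default_seed_sizes <- function() {
  c(AD = 78L, PD = 118L, HD = 46L, ALS = 39L, ASD = 124L, Epilepsy = 60L)
}

#' Generate a synthetic reference protein-protein interaction network
#'
#' Three generative models are available. `preferential_attachment` (the
#' default elsewhere in the package) yields the scale-free degree distribution
#' typical of curated interactomes; `erdos_renyi` gives a homogeneous random
#' graph; `duplication_divergence` grows the graph by duplicating a random
#' node and retaining each inherited edge independently, a classic model of
#' interactome evolution.
#'
#' @param n_nodes Number of proteins (>= 10).
#' @param model One of `"preferential_attachment"`, `"erdos_renyi"`,
#'   `"duplication_divergence"`.
#' @param model_params Named list: `m` (edges per step) for preferential
#'   attachment; `p` (edge probability) for Erdos-Renyi; `retention`
#'   (edge retention probability) for duplication-divergence.
#' @param rng_seed Integer seed; identical seeds give identical graphs.
#' @return An undirected simple igraph with character node names `P0001`, ...
#' @export
generate_ppi <- function(n_nodes, model = c("preferential_attachment", "erdos_renyi",
                                            "duplication_divergence"),
                         model_params = list(), rng_seed = 1L) {
  n_nodes <- assert_scalar_int(n_nodes, "n_nodes", min = 10)
  model <- match.arg(model)
  rng_seed <- assert_scalar_int(rng_seed, "rng_seed")
  g <- withr::with_seed(rng_seed, {
    switch(model,
      preferential_attachment = {
        m <- model_params$m %||% 2
        m <- assert_scalar_int(m, "model_params$m", min = 1)
        igraph::sample_pa(n_nodes, power = 1, m = m, directed = FALSE)
      },
      erdos_renyi = {
        p <- model_params$p
        if (is.null(p)) abort("erdos_renyi needs model_params$p.", class = "hubseeker_config_error")
        p <- assert_fraction(p, "model_params$p")
        igraph::sample_gnp(n_nodes, p, directed = FALSE)
      },
      duplication_divergence = {
        ret <- model_params$retention
        if (is.null(ret)) abort("duplication_divergence needs model_params$retention.",
                                class = "hubseeker_config_error")
        ret <- assert_fraction(ret, "model_params$retention")
        sample_duplication_divergence(n_nodes, ret)
      }
    )
  })
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  igraph::V(g)$name <- sprintf("P%04d", seq_len(n_nodes))
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# duplication-divergence growth: start from a triangle, duplicate a random
# anchor node, keep each inherited edge with prob `retention`; always link the
# copy to its anchor so the graph stays connected-ish and never edgeless
sample_duplication_divergence <- function(n_nodes, retention) {
  edges <- list(c(1L, 2L), c(2L, 3L), c(1L, 3L))
  adj <- list(`1` = c(2L, 3L), `2` = c(1L, 3L), `3` = c(1L, 2L))
  for (v in 4:n_nodes) {
    anchor <- sample.int(v - 1L, 1L)
    inherited <- adj[[anchor]]
    keep <- inherited[runif(length(inherited)) < retention]
    nbrs <- unique(c(anchor, keep))
    for (u in nbrs) {
      edges[[length(edges) + 1L]] <- c(u, v)
      adj[[as.character(u)]] <- c(adj[[as.character(u)]], v)
    }
    adj[[as.character(v)]] <- nbrs
  }
  igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
}

#' Plant a multi-disease connector hub and decoy hubs in a reference network
#'
#' Samples six mutually disjoint (by default) disease seed sets from the
#' network, picks one additional low-degree node as the connector, and wires
#' it to `links_per_set` members of every seed set. Decoy hubs - nodes wired
#' heavily into a single seed set - are planted so that common-hub detection
#' can be distinguished from plain degree ranking. Edges are only ever added;
#' the input network is never shrunk.
#'
#' @param network Reference igraph from [generate_ppi()].
#' @param sizes Integer vector of six seed-set sizes
#'   (default [default_seed_sizes()]).
#' @param links_per_set Edges added from the hub into each seed set, capped
#'   at the set size (>= 1; default 50, comparable to the interaction counts
#'   of well-connected chromatin regulators in curated interactomes).
#' @param n_decoys Number of single-set decoy hubs.
#' @param decoy_links Edges from each decoy into its one seed set.
#' @param overlap Expected pairwise seed-set overlap fraction (default 0,
#'   i.e. disjoint sets).
#' @param rng_seed Integer seed.
#' @return A list with `network` (the augmented igraph) and `truth`, a list
#'   holding `hub_id`, `seed_sets` (named list of ID vectors), `decoy_hubs`
#'   and `links_per_set`.
#' @export
plant_hub <- function(network, sizes = default_seed_sizes(), links_per_set = 50L,
                      n_decoys = 3L, decoy_links = 40L, overlap = 0,
                      rng_seed = 1L) {
  assert_graph(network)
  if (length(sizes) != 6L) abort("`sizes` must have length 6.", class = "hubseeker_config_error")
  links_per_set <- assert_scalar_int(links_per_set, "links_per_set", min = 1)
  n_decoys <- assert_scalar_int(n_decoys, "n_decoys", min = 0)
  overlap <- assert_fraction(overlap, "overlap")
  rng_seed <- assert_scalar_int(rng_seed, "rng_seed")
  ids <- node_names(network)
  if (length(ids) < sum(sizes) + 1L + n_decoys) {
    abort(sprintf("Network too small: %d nodes for %d seeds + hub + %d decoys.",
                  length(ids), sum(sizes), n_decoys),
          class = "hubseeker_sizing_error")
  }
  if (is.null(names(sizes))) names(sizes) <- paste0("set", seq_along(sizes))

  withr::with_seed(rng_seed, {
    deg <- igraph::degree(network)
    # the connector must be discoverable as an intermediate node: pick it from
    # the low-degree half so its signal comes from the planted wiring alone
    hub_pool <- ids[deg <= stats::median(deg)]
    hub_id <- sample(hub_pool, 1L)

    pool <- setdiff(ids, hub_id)
    seed_sets <- vector("list", 6L)
    names(seed_sets) <- names(sizes)
    taken <- character(0)
    for (i in seq_along(sizes)) {
      n_shared <- if (i > 1L) min(round(overlap * sizes[[i]]), length(taken)) else 0L
      shared <- if (n_shared > 0) sample(taken, n_shared) else character(0)
      fresh <- sample(setdiff(pool, taken), sizes[[i]] - n_shared)
      seed_sets[[i]] <- c(shared, fresh)
      taken <- union(taken, fresh)
    }

    decoy_pool <- setdiff(pool, taken)
    decoy_hubs <- if (n_decoys > 0) sample(decoy_pool, n_decoys) else character(0)

    new_edges <- character(0)
    for (s in seed_sets) {
      tgt <- sample(s, min(links_per_set, length(s)))  # capped at the set size
      new_edges <- c(new_edges, rbind(hub_id, tgt))
    }
    for (d in decoy_hubs) {
      s <- seed_sets[[sample.int(6L, 1L)]]
      tgt <- sample(s, min(decoy_links, length(s)))
      new_edges <- c(new_edges, rbind(d, tgt))
    }
    g2 <- igraph::add_edges(network, match(new_edges, ids))
    g2 <- igraph::simplify(g2, remove.multiple = TRUE, remove.loops = TRUE)
    list(
      network = g2,
      truth = list(
        hub_id = hub_id,
        seed_sets = seed_sets,
        hub_links_per_set = links_per_set,
        decoy_hubs = decoy_hubs
      )
    )
  })
}

#' Generate a synthetic quantitative proteomics table
#'
#' Emulates a two-condition (4 control + 4 treated replicates) label-based
#' proteomics experiment: log-normal intensities around a per-protein baseline,
#' a planted log2 fold change on `n_true_changed` proteins, peptide counts
#' drawn as 1 + Poisson(`min_peptide_lambda`), and completely-at-random
#' missingness per replicate cell.
#'
#' @param n_proteins Number of proteins.
#' @param n_true_changed Number of proteins carrying the planted effect.
#' @param effect_log2fc Planted log2 fold change (treated vs control).
#' @param replicate_cv Coefficient of variation of replicate intensities.
#' @param missing_rate Probability that any single intensity cell is missing.
#' @param min_peptide_lambda Poisson mean for the peptide-count draw.
#' @param rng_seed Integer seed.
#' @return A list with `table` (tibble: `protein_id`, `peptide_count`,
#'   `ctrl_1..4`, `trt_1..4`) and `truth` (tibble: `protein_id`, `changed`).
#' @export
generate_quant_table <- function(n_proteins = 1000L, n_true_changed = 100L,
                                 effect_log2fc = 1, replicate_cv = 0.2,
                                 missing_rate = 0.05, min_peptide_lambda = 2,
                                 rng_seed = 1L) {
  n_proteins <- assert_scalar_int(n_proteins, "n_proteins", min = 1)
  n_true_changed <- assert_scalar_int(n_true_changed, "n_true_changed", min = 0)
  if (n_true_changed > n_proteins) {
    abort("n_true_changed must be <= n_proteins.", class = "hubseeker_config_error")
  }
  missing_rate <- assert_fraction(missing_rate, "missing_rate")
  rng_seed <- assert_scalar_int(rng_seed, "rng_seed")

  withr::with_seed(rng_seed, {
    ids <- sprintf("P%04d", seq_len(n_proteins))
    changed <- c(rep(TRUE, n_true_changed), rep(FALSE, n_proteins - n_true_changed))
    base <- 2^runif(n_proteins, 16, 26)          # per-protein baseline abundance
    sdlog <- sqrt(log(1 + replicate_cv^2))       # lognormal sd matching the CV
    draw <- function(mean_i) {
      m <- matrix(stats::rlnorm(n_proteins * 4, meanlog = log(mean_i) - sdlog^2 / 2,
                                sdlog = sdlog), ncol = 4)
      m[matrix(runif(n_proteins * 4) < missing_rate, ncol = 4)] <- NA_real_
      m
    }
    ctrl <- draw(base)
    trt <- draw(base * 2^(effect_log2fc * changed))
    tab <- tibble(
      protein_id = ids,
      peptide_count = 1L + rpois(n_proteins, min_peptide_lambda)
    )
    for (j in 1:4) tab[[paste0("ctrl_", j)]] <- ctrl[, j]
    for (j in 1:4) tab[[paste0("trt_", j)]] <- trt[, j]
    list(table = tab, truth = tibble(protein_id = ids, changed = changed))
  })
}

#' Generate paired RNA/protein fold-change tables with controlled concordance
#'
#' Exactly `round(concordant_fraction * n_genes)` gene pairs get matching
#' fold-change signs; all remaining pairs get opposite signs. Magnitudes are
#' half-normal, so no fold change is exactly zero.
#'
#' @param n_genes Number of genes.
#' @param concordant_fraction Fraction of sign-concordant pairs.
#' @param rng_seed Integer seed.
#' @return A list with `rna` and `protein` (tibbles: `gene_id`, `log2fc`,
#'   `p_value`) and `truth` (tibble: `gene_id`, `concordant`).
#' @export
generate_multiomic <- function(n_genes = 500L, concordant_fraction = 0.3,
                               rng_seed = 1L) {
  n_genes <- assert_scalar_int(n_genes, "n_genes", min = 1)
  concordant_fraction <- assert_fraction(concordant_fraction, "concordant_fraction")
  rng_seed <- assert_scalar_int(rng_seed, "rng_seed")
  withr::with_seed(rng_seed, {
    ids <- sprintf("G%04d", seq_len(n_genes))
    n_conc <- round(concordant_fraction * n_genes)
    concordant <- c(rep(TRUE, n_conc), rep(FALSE, n_genes - n_conc))
    sign_rna <- sample(c(-1, 1), n_genes, replace = TRUE)
    sign_prot <- ifelse(concordant, sign_rna, -sign_rna)
    mag <- function() abs(rnorm(n_genes, 0, 0.8)) + 1e-6
    rna <- tibble(gene_id = ids, log2fc = sign_rna * mag(), p_value = runif(n_genes))
    protein <- tibble(gene_id = ids, log2fc = sign_prot * mag(), p_value = runif(n_genes))
    list(rna = rna, protein = protein,
         truth = tibble(gene_id = ids, concordant = concordant))
  })
}

#' Generate ChIP bivalency and differential-expression tables with known truth
#'
#' Bivalent genes receive both H3K4me3 and H3K27me3 FPKM strictly above the
#' 1.2 calling threshold; non-bivalent genes have at least one mark strictly
#' below it. Responsive genes receive p-values strictly below 0.05; the rest
#' strictly above. Bivalency and responsiveness are assigned independently.
#'
#' @param n_genes Number of genes.
#' @param bivalent_fraction Fraction of bivalent genes.
#' @param responsive_fraction Fraction of transcriptionally responsive genes.
#' @param rng_seed Integer seed.
#' @return A list with `chip` (tibble: `gene_id`, `fpkm_k4`, `fpkm_k27`),
#'   `de` (tibble: `gene_id`, `log2fc`, `p_value`) and `truth` (list with
#'   `bivalent`, `responsive`, `overlap` ID vectors).
#' @export
generate_bivalency <- function(n_genes = 1000L, bivalent_fraction = 0.2,
                               responsive_fraction = 0.2, rng_seed = 1L) {
  n_genes <- assert_scalar_int(n_genes, "n_genes", min = 1)
  bivalent_fraction <- assert_fraction(bivalent_fraction, "bivalent_fraction")
  responsive_fraction <- assert_fraction(responsive_fraction, "responsive_fraction")
  rng_seed <- assert_scalar_int(rng_seed, "rng_seed")
  withr::with_seed(rng_seed, {
    ids <- sprintf("G%04d", seq_len(n_genes))
    n_biv <- round(bivalent_fraction * n_genes)
    n_resp <- round(responsive_fraction * n_genes)
    bivalent <- seq_len(n_genes) %in% sample.int(n_genes, n_biv)
    responsive <- seq_len(n_genes) %in% sample.int(n_genes, n_resp)

    above <- function(n) runif(n, 1.3, 8)
    below <- function(n) runif(n, 0, 1.1)
    fpkm_k4 <- above(n_genes)
    fpkm_k27 <- above(n_genes)
    low_mark <- sample.int(2L, n_genes, replace = TRUE)  # which mark to suppress
    idx <- which(!bivalent & low_mark == 1L)
    fpkm_k4[idx] <- below(length(idx))
    idx <- which(!bivalent & low_mark == 2L)
    fpkm_k27[idx] <- below(length(idx))

    p <- runif(n_genes, 0.06, 1)
    p[responsive] <- runif(sum(responsive), 1e-6, 0.049)
    chip <- tibble(gene_id = ids, fpkm_k4 = fpkm_k4, fpkm_k27 = fpkm_k27)
    de <- tibble(gene_id = ids, log2fc = rnorm(n_genes, 0, 1), p_value = p)
    list(chip = chip, de = de,
         truth = list(bivalent = ids[bivalent], responsive = ids[responsive],
                      overlap = ids[bivalent & responsive]))
  })
}
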