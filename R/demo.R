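## One-command synthetic demo: writes every pipeline input with planted
## ground truth plus a ready-to-run config.

#' Generate a complete synthetic input bundle and run configuration
#'
#' Emits a scale-free reference interactome with a planted multi-disease
#' connector and decoy hubs, six disorder seed lists (default sizes
#' 78/118/46/39/124/60), a quantitative proteomics table, gene-set GMT
#' (two sets loaded with truly changed proteins, the rest random), paired
#' RNA/protein fold-change tables, ChIP bivalency and DE tables, a truth JSON
#' and a `config.yaml` wired to the generated files. Identical `rng_seed`
#' gives byte-identical fixtures.
#'
#' @param dir Output directory (created if absent; must be writable).
#' @param n_nodes Reference network size (default 10000, the order of
#'   magnitude of a curated mammalian interactome).
#' @param sizes Six seed-set sizes (default [default_seed_sizes()]).
#' @param links_per_set Connector edges into each seed set (default 50).
#' @param n_proteins,n_true_changed,effect_log2fc Quant-table settings.
#' @param n_genes Multi-omic / bivalency table size.
#' @param concordant_fraction,bivalent_fraction,responsive_fraction Planted
#'   fractions.
#' @param n_sets,set_size Random gene-set count and size for the GMT.
#' @param n_iterations Null iterations written into the config.
#' @param n_perm GSEA permutations written into the config.
#' @param rng_seed Integer seed for every stochastic choice.
#' @return Invisibly, a list with `config_path`, `truth` and `dir`.
#' @export
make_demo <- function(dir, n_nodes = 10000L, sizes = default_seed_sizes(),
                      links_per_set = 50L, n_proteins = 1000L,
                      n_true_changed = 100L, effect_log2fc = 1,
                      n_genes = 500L, concordant_fraction = 0.3,
                      bivalent_fraction = 0.2, responsive_fraction = 0.2,
                      n_sets = 15L, set_size = 30L,
                      n_iterations = 1000L, n_perm = 1000L, rng_seed = 1L) {
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(paste0("Cannot create directory: ", dir),
                              class = "hubseeker_io_error")
  rng_seed <- assert_scalar_int(rng_seed, "rng_seed")

  ref <- generate_ppi(n_nodes, "preferential_attachment", list(m = 2),
                      rng_seed = rng_seed)
  planted <- plant_hub(ref, sizes = sizes, links_per_set = links_per_set,
                       rng_seed = rng_seed + 1L)
  write_network(planted$network, file.path(dir, "edges.tsv"))
  seed_paths <- imap(planted$truth$seed_sets, function(members, disorder) {
    p <- file.path(dir, paste0("seeds_", disorder, ".txt"))
    writeLines(sort(members), p)
    p
  })

  quant <- generate_quant_table(n_proteins = n_proteins,
                                n_true_changed = n_true_changed,
                                effect_log2fc = effect_log2fc,
                                rng_seed = rng_seed + 2L)
  readr::write_tsv(quant$table, file.path(dir, "quant.tsv"))

  # gene sets over the quant universe: two loaded with changed proteins
  collection <- withr::with_seed(rng_seed + 3L, {
    ids <- quant$table$protein_id
    changed <- quant$truth$protein_id[quant$truth$changed]
    unchanged <- setdiff(ids, changed)
    loaded <- map(1:2, function(i) {
      n_sig <- min(round(0.8 * set_size), length(changed))
      n_bg <- min(set_size - n_sig, length(unchanged))
      c(sample(changed, n_sig), sample(unchanged, n_bg))
    })
    random <- map(seq_len(max(n_sets - 2L, 0L)), function(i) sample(ids, set_size))
    tibble(
      set_id = c(sprintf("LOADED_%d", seq_along(loaded)),
                 sprintf("RANDOM_%02d", seq_along(random))),
      description = c(rep("planted signal set", length(loaded)),
                      rep("random background set", length(random))),
      members = c(loaded, random)
    )
  })
  write_gmt(collection, file.path(dir, "gene_sets.gmt"))

  mo <- generate_multiomic(n_genes = n_genes,
                           concordant_fraction = concordant_fraction,
                           rng_seed = rng_seed + 4L)
  readr::write_tsv(mo$rna, file.path(dir, "rna_fc.tsv"))
  readr::write_tsv(mo$protein, file.path(dir, "protein_fc.tsv"))

  biv <- generate_bivalency(n_genes = n_genes,
                            bivalent_fraction = bivalent_fraction,
                            responsive_fraction = responsive_fraction,
                            rng_seed = rng_seed + 5L)
  readr::write_tsv(biv$chip, file.path(dir, "chip.tsv"))
  readr::write_tsv(biv$de, file.path(dir, "de.tsv"))

  truth <- list(
    hub_id = planted$truth$hub_id,
    seed_sets = map(planted$truth$seed_sets, sort),
    hub_links_per_set = planted$truth$hub_links_per_set,
    decoy_hubs = planted$truth$decoy_hubs,
    quant_changed = quant$truth$protein_id[quant$truth$changed],
    concordant = mo$truth$gene_id[mo$truth$concordant],
    bivalent = sort(biv$truth$bivalent),
    responsive = sort(biv$truth$responsive),
    bivalent_responsive_overlap = sort(biv$truth$overlap)
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  cfg <- list(
    rng_seed = rng_seed,
    paths = list(
      edges = file.path(dir, "edges.tsv"),
      seeds = unname(as.list(unlist(seed_paths))),
      quant = file.path(dir, "quant.tsv"),
      gene_sets = file.path(dir, "gene_sets.gmt"),
      rna_fc = file.path(dir, "rna_fc.tsv"),
      protein_fc = file.path(dir, "protein_fc.tsv"),
      chip = file.path(dir, "chip.tsv"),
      de = file.path(dir, "de.tsv")
    ),
    network = list(n_iterations = n_iterations),
    gsea = list(n_perm = n_perm)
  )
  config_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, config_path)
  invisible(list(config_path = config_path, truth = truth, dir = dir))
}
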