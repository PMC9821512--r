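## Configuration-driven orchestration: one YAML config drives every stage
## (quant -> enrich -> network -> integrate) with explicit seeds, per-stage
## toggles, audited filter counts and a manifest of input/output hashes.
## Reruns with an identical config are byte-identical.

default_config <- function() {
  list(
    rng_seed = 1L,
    stages = list(quant = TRUE, enrich = TRUE, network = TRUE, integrate = TRUE),
    paths = list(edges = NULL, seeds = list(), quant = NULL, gene_sets = NULL,
                 rna_fc = NULL, protein_fc = NULL, chip = NULL, de = NULL),
    quant = list(min_peptides = 2L, min_present = 3L, n_replicates = 4L),
    gsea = list(n_perm = 1000L, weight_exponent = 1, min_set_size = 5L,
                max_set_size = 500L, q_cutoff = 0.1, overlap_cutoff = 0.25),
    network = list(depth = 2L, min_disorders = 6L, top_k = 20L,
                   n_random_seeds = 80L, n_iterations = 1000L,
                   statistic = "top1_degree"),
    integrate = list(fpkm_cutoff = 1.2, p_cutoff = 0.05, lfc_cutoff = 0.25,
                     min_abs_log2fc = 0)
  )
}

merge_config <- function(base, user, prefix = "") {
  for (key in names(user)) {
    full <- paste0(prefix, key)
    if (!key %in% names(base)) {
      abort(sprintf("Unknown config key: '%s'.", full), class = "hubseeker_config_error")
    }
    if (is.list(base[[key]]) && !key %in% c("seeds")) {
      base[[key]] <- merge_config(base[[key]], user[[key]], paste0(full, "."))
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Load and validate a pipeline run configuration
#'
#' @param config A YAML file path or a named list. Unknown keys are rejected;
#'   unspecified keys take their defaults (all thresholds at the values
#'   documented in the stage functions).
#' @return The validated config list.
#' @export
load_config <- function(config) {
  user <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(user)) abort("Config must be a YAML file or a list.",
                            class = "hubseeker_config_error")
  merge_config(default_config(), user)
}

#' Run the full analysis pipeline from a config
#'
#' Stages run in dependency order: proteomics quantification (filters +
#' ranked list), gene-set enrichment with enrichment map, PPI hub discovery
#' with the random-seed null, and multi-omic integration. Every filter
#' boundary logs rows in/out to `run_log.txt`; `manifest.json` records the
#' config, package version and MD5 of every input and output. Outputs land in
#' `out_dir`; inputs are never modified.
#'
#' @param config YAML path or list (see [load_config()]).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list of stage results (`ranked`, `gsea`, `map`,
#'   `hub_report`, `integration`, `manifest_path`).
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- load_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_add <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  need <- function(path, what) {
    if (is.null(path) || !file.exists(path)) {
      abort(sprintf("Stage input missing: %s (%s).", what, path %||% "<unset>"),
            class = "hubseeker_io_error")
    }
    path
  }
  outputs <- character(0)
  emit <- function(writer, ..., file) {
    writer(..., file.path(out_dir, file))
    outputs <<- c(outputs, file)
  }
  results <- list()

  if (isTRUE(cfg$stages$quant)) {
    qt <- read_quant_table(need(cfg$paths$quant, "quant table"))
    log_add("quant: read %d proteins", nrow(qt))
    q1 <- filter_min_peptides(qt, cfg$quant$min_peptides)
    log_add("quant: peptide filter (>= %d) %d -> %d", cfg$quant$min_peptides,
            nrow(qt), nrow(q1))
    q2 <- filter_replicate_presence(q1, cfg$quant$min_present, cfg$quant$n_replicates)
    log_add("quant: replicate filter (>= %d/%d both conditions) %d -> %d",
            cfg$quant$min_present, cfg$quant$n_replicates, nrow(q1), nrow(q2))
    ranked <- compute_ranked_list(q2)
    emit(function(x, f) write_rnk(x, f), ranked, file = "ranked.rnk")
    results$ranked <- ranked
  }

  if (isTRUE(cfg$stages$enrich)) {
    if (is.null(results$ranked)) {
      abort("enrich stage requires the quant stage.", class = "hubseeker_config_error")
    }
    collection <- read_gmt(need(cfg$paths$gene_sets, "gene sets"))
    res <- gsea(results$ranked, collection, n_perm = cfg$gsea$n_perm,
                rng_seed = cfg$rng_seed, weight_exponent = cfg$gsea$weight_exponent,
                min_set_size = cfg$gsea$min_set_size, max_set_size = cfg$gsea$max_set_size)
    log_add("enrich: scored %d of %d sets; %d at q <= %g", nrow(res),
            nrow(collection), sum(res$q_value <= cfg$gsea$q_cutoff), cfg$gsea$q_cutoff)
    emit(function(x, f) readr::write_tsv(as_tibble(x), f), res, file = "gsea_results.tsv")
    emap <- build_enrichment_map(res, collection, results$ranked$gene_id,
                                 q_cutoff = cfg$gsea$q_cutoff,
                                 overlap_cutoff = cfg$gsea$overlap_cutoff)
    emit(function(x, f) readr::write_tsv(x$nodes, f), emap, file = "enrichment_map_nodes.tsv")
    emit(function(x, f) readr::write_tsv(x$edges, f), emap, file = "enrichment_map_edges.tsv")
    results$gsea <- res
    results$map <- emap
  }

  if (isTRUE(cfg$stages$network)) {
    ref <- read_network(need(cfg$paths$edges, "reference edge list"))
    seed_files <- cfg$paths$seeds
    if (length(seed_files) == 0) abort("network stage needs seed files.",
                                       class = "hubseeker_config_error")
    seed_sets <- map(seed_files, function(f) read_seed_set(need(f, "seed list")))
    subs <- map(seed_sets, function(s) {
      m <- map_seeds(ref, s)
      log_add("network: %s mapped %d/%d seeds", s$disorder, length(m$mapped),
              length(s$members))
      sub <- expand_subnetwork(ref, m$mapped, depth = cfg$network$depth,
                               disorder = s$disorder)
      cent <- centrality_stats(sub)
      emit(function(x, f) readr::write_tsv(x, f), cent,
           file = sprintf("centrality_%s.tsv", s$disorder))
      sub
    })
    combined <- combine_subnetworks(subs, ref)
    log_add("network: combined subnetwork %d nodes / %d edges",
            igraph::vcount(combined), igraph::ecount(combined))
    emit(function(x, f) write_network(x, f), combined, file = "combined_edges.tsv")
    all_seeds <- unique(unlist(map(seed_sets, "members")))
    report <- identify_common_hubs(combined, subs, all_seeds,
                                   min_disorders = cfg$network$min_disorders,
                                   top_k = cfg$network$top_k)
    if (nrow(report) > 0 && cfg$network$n_iterations > 0) {
      report <- score_hub_specificity(
        report, ref, exclude = all_seeds, depth = cfg$network$depth,
        n_random_seeds = cfg$network$n_random_seeds,
        n_iterations = cfg$network$n_iterations,
        statistic = cfg$network$statistic, rng_seed = cfg$rng_seed
      )
      log_add("network: top hub %s (degree %d), empirical p = %.4g",
              report$id[1], report$combined_degree[1], report$empirical_p[1])
    }
    emit(function(x, f) readr::write_tsv(as_tibble(x), f), report, file = "hub_report.tsv")
    results$hub_report <- report
  }

  if (isTRUE(cfg$stages$integrate)) {
    rna <- readr::read_tsv(need(cfg$paths$rna_fc, "RNA fold changes"),
                           col_types = "cdd")
    prot <- readr::read_tsv(need(cfg$paths$protein_fc, "protein fold changes"),
                            col_types = "cdd")
    chip <- readr::read_tsv(need(cfg$paths$chip, "ChIP table"), col_types = "cdd")
    de <- readr::read_tsv(need(cfg$paths$de, "DE table"), col_types = "cdd")
    conc <- concordant_genes(rna, prot, cfg$integrate$min_abs_log2fc)
    bivalent <- call_bivalent(chip, cfg$integrate$fpkm_cutoff)
    responsive <- call_responsive(de, cfg$integrate$p_cutoff)
    defs <- de_filter(de, cfg$integrate$p_cutoff, cfg$integrate$lfc_cutoff)
    universe <- intersect(chip$gene_id, de$gene_id)
    ov <- overlap_test(intersect(bivalent, universe),
                       intersect(responsive, universe), universe)
    log_add("integrate: %d up / %d down concordant; %d bivalent, %d responsive, overlap %d (p = %.4g)",
            length(conc$up), length(conc$down), length(bivalent),
            length(responsive), length(ov$intersection), ov$hypergeometric_p)
    integration <- list(
      concordant_up = sort(conc$up), concordant_down = sort(conc$down),
      bivalent = sort(bivalent), responsive = sort(responsive),
      de_up = sort(defs$up), de_down = sort(defs$down),
      overlap = ov[c("set_a_size", "set_b_size", "universe_size", "hypergeometric_p")],
      overlap_genes = sort(ov$intersection)
    )
    emit(function(x, f) jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA,
                                             pretty = TRUE),
         integration, file = "integration.json")
    results$integration <- integration
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  outputs <- c(outputs, "run_log.txt")

  input_paths <- c(cfg$paths$edges, unlist(cfg$paths$seeds), cfg$paths$quant,
                   cfg$paths$gene_sets, cfg$paths$rna_fc, cfg$paths$protein_fc,
                   cfg$paths$chip, cfg$paths$de)
  input_paths <- input_paths[!vapply(input_paths, is.null, logical(1))]
  input_paths <- input_paths[file.exists(unlist(input_paths))]
  manifest_cfg <- cfg
  manifest_cfg$paths <- purrr::map(cfg$paths, function(p) {
    if (is.list(p)) map(p, basename) else if (is.null(p)) NULL else basename(p)
  })
  manifest <- list(
    package = "hubseeker",
    version = as.character(utils::packageVersion("hubseeker")),
    config = manifest_cfg,
    config_hash = rlang::hash(manifest_cfg),
    inputs = setNames(as.list(unname(tools::md5sum(unlist(input_paths)))),
                      basename(unlist(input_paths))),
    outputs = setNames(
      as.list(unname(tools::md5sum(file.path(out_dir, sort(outputs))))),
      sort(outputs))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  results$manifest_path <- manifest_path
  invisible(results)
}
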