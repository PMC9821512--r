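## Multi-omic integration: RNA/protein sign concordance, bivalent-chromatin
## and responsive-gene threshold calls, differential-expression filtering, and
## hypergeometric overlap tests. All thresholds are strict inequalities
## (FPKM > 1.2, p < 0.05, |log2FC| > 0.25), matching the printed rules.

validate_fc_table <- function(table, call_name, need_p = FALSE) {
  if (!all(c("gene_id", "log2fc") %in% names(table))) {
    abort(sprintf("%s: table needs columns gene_id and log2fc.", call_name),
          class = "hubseeker_schema_error")
  }
  if (need_p && !"p_value" %in% names(table)) {
    abort(sprintf("%s: table needs a p_value column.", call_name),
          class = "hubseeker_schema_error")
  }
  if (anyDuplicated(table$gene_id)) {
    abort(sprintf("%s: duplicate gene_id values.", call_name),
          class = "hubseeker_parse_error")
  }
  invisible(table)
}

#' Sign-concordant genes across RNA and protein fold changes
#'
#' Over the genes shared by both tables, `up` holds genes with both fold
#' changes strictly above `min_abs_log2fc` and `down` those with both
#' strictly below `-min_abs_log2fc`. A zero fold change in either table puts
#' a gene in neither set.
#'
#' @param rna,protein Fold-change tibbles (`gene_id`, `log2fc`).
#' @param min_abs_log2fc Magnitude threshold (default 0: sign agreement only).
#' @return A list with `up` and `down` ID vectors.
#' @export
concordant_genes <- function(rna, protein, min_abs_log2fc = 0) {
  validate_fc_table(rna, "concordant_genes")
  validate_fc_table(protein, "concordant_genes")
  shared <- intersect(rna$gene_id, protein$gene_id)
  r <- rna$log2fc[match(shared, rna$gene_id)]
  p <- protein$log2fc[match(shared, protein$gene_id)]
  list(
    up = shared[r > min_abs_log2fc & p > min_abs_log2fc],
    down = shared[r < -min_abs_log2fc & p < -min_abs_log2fc]
  )
}

#' Call bivalent genes from two-mark ChIP quantification
#'
#' A gene is bivalent when both H3K4me3 and H3K27me3 FPKM are strictly above
#' the cutoff.
#'
#' @param table Tibble with `gene_id`, `fpkm_k4`, `fpkm_k27`.
#' @param fpkm_cutoff FPKM threshold (default 1.2; strict `>`).
#' @return Character vector of bivalent gene IDs.
#' @export
call_bivalent <- function(table, fpkm_cutoff = 1.2) {
  if (!all(c("gene_id", "fpkm_k4", "fpkm_k27") %in% names(table))) {
    abort("call_bivalent: table needs gene_id, fpkm_k4, fpkm_k27.",
          class = "hubseeker_schema_error")
  }
  if (fpkm_cutoff < 0) abort("fpkm_cutoff must be >= 0.", class = "hubseeker_config_error")
  if (any(table$fpkm_k4 < 0, na.rm = TRUE) || any(table$fpkm_k27 < 0, na.rm = TRUE)) {
    abort("FPKM values must be non-negative.", class = "hubseeker_validation_error")
  }
  table$gene_id[table$fpkm_k4 > fpkm_cutoff & table$fpkm_k27 > fpkm_cutoff]
}

#' Call transcriptionally responsive genes by p-value
#'
#' @param de Fold-change tibble with a `p_value` column.
#' @param p_cutoff p-value threshold (default 0.05; strict `<`).
#' @return Character vector of responsive gene IDs.
#' @export
call_responsive <- function(de, p_cutoff = 0.05) {
  validate_fc_table(de, "call_responsive", need_p = TRUE)
  de$gene_id[de$p_value < p_cutoff]
}

#' Differential-expression filter by p-value and fold-change magnitude
#'
#' `up` = genes with `p < p_cutoff` and `log2fc > lfc_cutoff`; `down` = genes
#' with `p < p_cutoff` and `log2fc < -lfc_cutoff`. Both inequalities strict.
#'
#' @param de Fold-change tibble with `p_value`.
#' @param p_cutoff p-value threshold (default 0.05).
#' @param lfc_cutoff log2 fold-change magnitude threshold (default 0.25).
#' @return A list with `up` and `down` ID vectors.
#' @export
de_filter <- function(de, p_cutoff = 0.05, lfc_cutoff = 0.25) {
  validate_fc_table(de, "de_filter", need_p = TRUE)
  sig <- de$p_value < p_cutoff
  list(
    up = de$gene_id[sig & de$log2fc > lfc_cutoff],
    down = de$gene_id[sig & de$log2fc < -lfc_cutoff]
  )
}

#' Hypergeometric overlap test between two gene sets
#'
#' Upper-tail hypergeometric probability of observing at least the realised
#' intersection when `|a|` genes are drawn from `universe` against a marked
#' set of size `|b|`.
#'
#' @param a,b Character vectors of gene IDs, both subsets of `universe`.
#' @param universe Character vector: the background gene universe.
#' @return A list: `set_a_size`, `set_b_size`, `universe_size`,
#'   `intersection` (ID vector) and `hypergeometric_p`.
#' @export
overlap_test <- function(a, b, universe) {
  a <- unique(a); b <- unique(b); universe <- unique(universe)
  if (!all(a %in% universe) || !all(b %in% universe)) {
    abort("Both sets must be subsets of the universe.",
          class = "hubseeker_validation_error")
  }
  k <- length(intersect(a, b))
  p <- phyper(k - 1, length(a), length(universe) - length(a), length(b),
              lower.tail = FALSE)
  list(
    set_a_size = length(a),
    set_b_size = length(b),
    universe_size = length(universe),
    intersection = intersect(a, b),
    hypergeometric_p = p
  )
}
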