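## Quantitative proteomics: read, filter, rank.
##
## The table schema is one row per protein with a peptide-evidence count and
## 4 + 4 replicate intensities. Zero or empty intensity cells are recorded as
## missing; missing values are excluded from condition means, never imputed.

intensity_cols <- function(condition) paste0(condition, "_", 1:4)

validate_quant_table <- function(table, call_name) {
  needed <- c("protein_id", "peptide_count", intensity_cols("ctrl"), intensity_cols("trt"))
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols)) {
    abort(sprintf("%s: missing columns: %s", call_name, paste(missing_cols, collapse = ", ")),
          class = "hubseeker_schema_error")
  }
  if (anyDuplicated(table$protein_id)) {
    abort(sprintf("%s: duplicate protein_id values.", call_name),
          class = "hubseeker_parse_error")
  }
  invisible(table)
}

#' Read a quantitative proteomics table from TSV
#'
#' Expects a header with a protein-ID column, a peptide-count column, four
#' control-intensity columns and four treated-intensity columns (recognised by
#' names matching `protein`, `peptide`, `ctrl`/`control` and `trt`/`treat`,
#' in replicate order). Empty or zero intensity cells become missing values.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `protein_id`, `peptide_count`,
#'   `ctrl_1..ctrl_4`, `trt_1..trt_4`.
#' @export
read_quant_table <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path), class = "hubseeker_io_error")
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"))
  nm <- tolower(names(raw))
  prot <- which(grepl("protein", nm))[1]
  pep <- which(grepl("peptide", nm))[1]
  ctrl <- which(grepl("^(ctrl|control)", nm))
  trt <- which(grepl("^(trt|treat)", nm))
  if (is.na(prot) || is.na(pep) || length(ctrl) != 4 || length(trt) != 4) {
    abort("Malformed header: need a protein column, a peptide-count column, 4 control and 4 treated intensity columns.",
          class = "hubseeker_parse_error")
  }
  dup <- raw[[prot]][duplicated(raw[[prot]])]
  if (length(dup)) {
    abort(sprintf("Duplicate protein ID '%s'.", dup[1]), class = "hubseeker_parse_error")
  }
  parse_intensity <- function(x, col) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad)) abort(sprintf("Non-numeric intensity in column '%s', row %d.", col, bad[1]),
                           class = "hubseeker_parse_error")
    neg <- which(!is.na(v) & v < 0)
    if (length(neg)) abort(sprintf("Negative intensity in column '%s', row %d.", col, neg[1]),
                           class = "hubseeker_parse_error")
    v[!is.na(v) & v == 0] <- NA_real_   # zero means not quantified
    v
  }
  out <- tibble(
    protein_id = raw[[prot]],
    peptide_count = as.integer(raw[[pep]])
  )
  for (j in 1:4) out[[paste0("ctrl_", j)]] <- parse_intensity(raw[[ctrl[j]]], names(raw)[ctrl[j]])
  for (j in 1:4) out[[paste0("trt_", j)]] <- parse_intensity(raw[[trt[j]]], names(raw)[trt[j]])
  validate_quant_table(out, "read_quant_table")
}

#' Filter proteins by minimum peptide evidence
#'
#' Retains proteins identified with at least `min_peptides` peptides
#' (default 2, the usual two-peptide identification rule). Row order is
#' preserved; the filter is idempotent and commutes with
#' [filter_replicate_presence()].
#'
#' @param table Quant table (see [read_quant_table()]).
#' @param min_peptides Minimum peptide count (>= 1).
#' @return The filtered tibble.
#' @export
filter_min_peptides <- function(table, min_peptides = 2L) {
  validate_quant_table(table, "filter_min_peptides")
  min_peptides <- assert_scalar_int(min_peptides, "min_peptides", min = 1)
  dplyr::filter(table, .data$peptide_count >= min_peptides)
}

#' Filter proteins by replicate presence
#'
#' Retains proteins quantified (non-missing intensity) in at least
#' `min_present` of `n_replicates` replicates in *both* conditions — the
#' stricter per-condition reading of the at-least-3-of-4 rule.
#'
#' @param table Quant table.
#' @param min_present Minimum non-missing replicates per condition.
#' @param n_replicates Number of replicates per condition (4).
#' @return The filtered tibble.
#' @export
filter_replicate_presence <- function(table, min_present = 3L, n_replicates = 4L) {
  validate_quant_table(table, "filter_replicate_presence")
  min_present <- assert_scalar_int(min_present, "min_present", min = 0)
  n_replicates <- assert_scalar_int(n_replicates, "n_replicates", min = 1)
  if (min_present > n_replicates) {
    abort("min_present must be <= n_replicates.", class = "hubseeker_config_error")
  }
  ctrl_n <- rowSums(!is.na(as.matrix(table[, intensity_cols("ctrl")])))
  trt_n <- rowSums(!is.na(as.matrix(table[, intensity_cols("trt")])))
  table[ctrl_n >= min_present & trt_n >= min_present, ]
}

#' Summarise a quant table into a ranked fold-change list
#'
#' The score is `log2(mean treated / mean control)` over the present
#' replicates (ratio of means). All quantified proteins contribute — no
#' significance cutoff is applied — so the output feeds directly into
#' cutoff-free enrichment analysis. Rows are sorted by descending score with
#' lexicographic ID tie-break.
#'
#' @param table Quant table; every row must have at least one present
#'   intensity in each condition.
#' @return A tibble with `gene_id` and `score`, sorted for enrichment input.
#' @export
compute_ranked_list <- function(table) {
  validate_quant_table(table, "compute_ranked_list")
  ctrl <- as.matrix(table[, intensity_cols("ctrl")])
  trt <- as.matrix(table[, intensity_cols("trt")])
  ctrl_mean <- rowMeans(ctrl, na.rm = TRUE)
  trt_mean <- rowMeans(trt, na.rm = TRUE)
  bad <- which(!is.finite(ctrl_mean) | !is.finite(trt_mean))
  if (length(bad)) {
    abort(sprintf("Protein '%s' has no quantified replicates in one condition; filter first.",
                  table$protein_id[bad[1]]),
          class = "hubseeker_contract_error")
  }
  out <- tibble(gene_id = table$protein_id, score = log2(trt_mean / ctrl_mean))
  out[order(-out$score, out$gene_id), ]
}
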