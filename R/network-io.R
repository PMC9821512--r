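## Reference-network and seed-list I/O.

#' Read a protein-protein interaction network
#'
#' Accepts a two-column edge-list TSV (optional header) or a SIF file
#' (`A pp B` per line, whitespace-separated). Self-loops are dropped and
#' duplicate edges collapsed, with a message reporting how many; isolated
#' nodes named only by a self-loop are kept.
#'
#' @param path Path to the edge list or SIF file.
#' @param format `"auto"` (by extension), `"edgelist"` or `"sif"`.
#' @return An undirected simple igraph with character node names.
#' @export
read_network <- function(path, format = c("auto", "edgelist", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path), class = "hubseeker_io_error")
  if (format == "auto") {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "edgelist"
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(igraph::make_empty_graph(directed = FALSE))
  if (format == "sif") {
    fields <- strsplit(trimws(lines), "\\s+")
    bad <- which(lengths(fields) < 3)
    if (length(bad)) abort(sprintf("SIF line %d has fewer than 3 fields.", bad[1]),
                           class = "hubseeker_parse_error")
    from <- map_chr(fields, 1)
    to <- map_chr(fields, 3)
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 2)
    if (length(bad)) abort(sprintf("Edge list line %d has fewer than 2 columns.", bad[1]),
                           class = "hubseeker_parse_error")
    from <- map_chr(fields, 1)
    to <- map_chr(fields, 2)
    # tolerate a header row of column names
    if (tolower(from[1]) %in% c("from", "source", "protein_a", "node1") ||
        tolower(to[1]) %in% c("to", "target", "protein_b", "node2")) {
      from <- from[-1]; to <- to[-1]
    }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  n_loops <- sum(igraph::which_loop(g))
  n_multi <- sum(igraph::which_multiple(g))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (n_loops + n_multi > 0) {
    message(sprintf("read_network: dropped %d self-loop(s) and %d duplicate edge(s).",
                    n_loops, n_multi))
  }
  g
}

#' Write a network as a two-column edge-list TSV
#'
#' @param network An igraph object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  assert_graph(network)
  el <- igraph::as_edgelist(network)
  df <- tibble(protein_a = el[, 1], protein_b = el[, 2])
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a seed-protein list (one ID per line)
#'
#' @param path Path to the plain-text list.
#' @param disorder Label for the set; defaults to the file name stem.
#' @return A list with `disorder` and `members`.
#' @export
read_seed_set <- function(path, disorder = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path), class = "hubseeker_io_error")
  members <- unique(trimws(readLines(path, warn = FALSE)))
  members <- members[nzchar(members)]
  if (!length(members)) abort("Seed list is empty.", class = "hubseeker_parse_error")
  list(disorder = disorder %||% sub("\\.[^.]*$", "", basename(path)), members = members)
}
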