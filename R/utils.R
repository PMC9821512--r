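## shared validators and small format helpers

assert_scalar_int <- function(x, name, min = NULL) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer.", name), class = "hubseeker_config_error")
  }
  if (!is.null(min) && x < min) {
    abort(sprintf("`%s` must be >= %s.", name, min), class = "hubseeker_config_error")
  }
  as.integer(x)
}

assert_fraction <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1].", name),
          class = "hubseeker_config_error")
  }
  as.numeric(x)
}

assert_graph <- function(g, name = "network") {
  if (!igraph::is_igraph(g)) {
    abort(sprintf("`%s` must be an igraph object.", name), class = "hubseeker_type_error")
  }
  invisible(g)
}

node_names <- function(g) igraph::V(g)$name

#' Read a gene-set collection from a GMT file
#'
#' One set per line: `set_id<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `set_id`, `description` and a list-column
#'   `members` of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("GMT file not found: ", path), class = "hubseeker_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) {
    abort(sprintf("GMT line %d has fewer than 3 fields.", bad[1]), class = "hubseeker_parse_error")
  }
  out <- tibble(
    set_id = map_chr(fields, 1),
    description = map_chr(fields, 2),
    members = map(fields, ~ unique(.x[-(1:2)]))
  )
  if (anyDuplicated(out$set_id)) {
    abort("Duplicate set_id in GMT file.", class = "hubseeker_parse_error")
  }
  if (any(lengths(out$members) == 0)) {
    abort("GMT sets must have at least one member.", class = "hubseeker_parse_error")
  }
  out
}

#' Write a gene-set collection to GMT
#'
#' @param collection Tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- purrr::pmap_chr(
    list(collection$set_id, collection$description, collection$members),
    function(id, desc, mem) paste(c(id, desc, mem), collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a ranked list as a two-column .rnk file
#'
#' @param ranked Tibble with `gene_id` and `score` (see [compute_ranked_list()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rnk <- function(ranked, path) {
  readr::write_tsv(ranked[, c("gene_id", "score")], path, col_names = FALSE)
  invisible(path)
}
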