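# readers/writers for the plain-text interchange formats the screen consumes:
# GMT gene-set collections, single-column TSV gene lists, two-column TSV
# ortholog maps, and two-column TSV receptor-partner interaction tables.

#' Read and write GMT gene-set collections
#'
#' Standard GMT: one set per line, tab-separated — name, description, then
#' members. `read_gmt()` returns a named list of [gene_set()] objects (the
#' description field becomes the provenance tag).
#'
#' @param path File path.
#' @param species Species tag applied to every set in the file.
#' @return A named list of `gene_set` objects.
#' @export
read_gmt <- function(path, species = "human") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop_ic("read_gmt: malformed line in %s: %s", path,
                                substr(ln, 1, 40))
    gene_set(f[-(1:2)], name = f[1], species = species, provenance = f[2])
  })
  stats::setNames(sets, vapply(sets, function(s) s$name, ""))
}

#' @rdname read_gmt
#' @param sets A list of `gene_set` objects (or a single one).
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    desc <- if (is.character(s$provenance)) s$provenance[1] else "derived"
    paste(c(s$name, desc, s$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a single-column TSV gene list
#'
#' Expects a header line; the first column is used.
#'
#' @param path File path.
#' @param name Label for the resulting set (default: file base name).
#' @param species,provenance Passed to [gene_set()].
#' @return A `gene_set`.
#' @export
read_gene_list <- function(path, name = NULL, species = "human",
                           provenance = path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  gene_set(df[[1]], name %||% sub("\\.[^.]*$", "", basename(path)),
           species, provenance)
}

#' Read a two-column TSV ortholog map
#'
#' Columns: source symbol, target symbol (header required).
#'
#' @param path File path.
#' @inheritParams ortholog_map
#' @return An `ortholog_map`.
#' @export
read_ortholog_map <- function(path, source_species = "mouse",
                              target_species = "human",
                              unmapped = c("drop", "keep")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ortholog_map(df[[1]], df[[2]], source_species, target_species,
               unmapped = match.arg(unmapped))
}

#' Read a receptor-partner interaction table
#'
#' Two-column TSV (header required): receptor symbol, partner symbol; one row
#' per interaction. A third column, if present, is kept as the source tag.
#'
#' @param path File path.
#' @return An `interaction_table` (see [interaction_table()]).
#' @export
read_interactions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  interaction_table(df[[1]], df[[2]],
                    source = if (ncol(df) >= 3L) df[[3]] else "file")
}
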