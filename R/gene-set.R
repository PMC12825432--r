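#' Construct a gene set
#'
#' A `gene_set` is a named, species-tagged collection of normalized gene
#' symbols with a provenance record. Members are normalized with
#' [normalize_symbols()] and de-duplicated (first occurrence kept). Derived
#' sets produced by [gs_intersect()], [gs_subtract()] and [map_orthologs()]
#' carry a nested provenance recording the operation and both parents, so the
#' full parentage of any set can be reconstructed.
#'
#' @param members Character vector of gene symbols (raw; normalized here).
#' @param name Short label for the set.
#' @param species `"human"` or `"mouse"`.
#' @param provenance Free-text source tag (a string), or for derived sets a
#'   list with elements `op` and `parents`.
#' @return An object of class `gene_set`.
#' @examples
#' gene_set(c("Pdcd1", "CTLA4", "ctla4"), "demo", "human", "manual")
#' @export
gene_set <- function(members, name, species = "human", provenance = "input") {
  if (!is_string(name)) stop_ic("gene_set: name must be a single string")
  assert_species(species)
  members <- unique(normalize_symbols(members))
  structure(
    list(name = name, species = species, members = members,
         provenance = provenance),
    class = "gene_set"
  )
}

#' @export
length.gene_set <- function(x) length(x$members)

#' @export
as.character.gene_set <- function(x, ...) x$members

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s (%s), %d genes\n", x$name, x$species, length(x)))
  show <- utils::head(x$members, 6L)
  cat("  ", paste(show, collapse = ", "),
      if (length(x) > 6L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

derived_provenance <- function(op, ...) {
  parents <- lapply(list(...), function(p) {
    list(name = p$name, provenance = p$provenance)
  })
  list(op = op, parents = parents)
}

check_same_species <- function(a, b, op) {
  if (a$species != b$species) {
    stop_ic("%s: species mismatch (%s: %s vs %s: %s); map orthologs first",
            op, a$name, a$species, b$name, b$species)
  }
}

#' Set algebra on gene sets
#'
#' `gs_intersect()` returns the genes present in both sets; `gs_subtract()`
#' removes the members of `b` from `a`. Both require the two sets to be in
#' the same species and record both parents in the result's provenance.
#' Member order follows `a`.
#'
#' @param a,b `gene_set` objects of the same species.
#' @param name Optional label for the result.
#' @return A `gene_set`.
#' @export
gs_intersect <- function(a, b, name = NULL) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  check_same_species(a, b, "gs_intersect")
  out <- gene_set(a$members[a$members %in% b$members],
                  name %||% sprintf("(%s & %s)", a$name, b$name),
                  a$species,
                  derived_provenance("intersect", a, b))
  out
}

#' @rdname gs_intersect
#' @export
gs_subtract <- function(a, b, name = NULL) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  check_same_species(a, b, "gs_subtract")
  gene_set(a$members[!a$members %in% b$members],
           name %||% sprintf("(%s \\ %s)", a$name, b$name),
           a$species,
           derived_provenance("subtract", a, b))
}

#' Reconstruct the parentage of a derived gene set
#'
#' Walks the nested provenance of a `gene_set` and returns the chain of
#' operations and input source tags that produced it, deepest first.
#'
#' @param x A `gene_set`.
#' @return Character vector describing the lineage.
#' @export
provenance_chain <- function(x) {
  stopifnot(inherits(x, "gene_set"))
  walk <- function(name, prov) {
    if (is.character(prov)) {
      return(sprintf("input %s [%s]", name, prov))
    }
    kids <- unlist(lapply(prov$parents, function(p) walk(p$name, p$provenance)))
    c(kids, sprintf("%s -> %s", prov$op, name))
  }
  walk(x$name, x$provenance)
}

#' Construct an ortholog map
#'
#' An explicit, functional (one-to-one-or-dropped) mapping from gene symbols
#' in one species to symbols in another. The screen never guesses cross-
#' species matches: mouse knockout datasets are reconciled with human
#' candidate lists through a map like this one. The default used elsewhere is
#' [identity_ortholog_map()], i.e. match-after-uppercasing, because mouse and
#' human symbols differ only in case for most genes of interest.
#'
#' @param from,to Character vectors of equal length: source and target
#'   symbols (normalized here). Each source symbol may appear only once.
#' @param source_species,target_species Species tags.
#' @param unmapped What to do with symbols absent from the map when applying
#'   it: `"drop"` (default) or `"keep"` (pass through unchanged).
#' @return An object of class `ortholog_map`.
#' @export
ortholog_map <- function(from, to, source_species = "mouse",
                         target_species = "human",
                         unmapped = c("drop", "keep")) {
  unmapped <- match.arg(unmapped)
  assert_species(source_species)
  assert_species(target_species)
  from <- normalize_symbols(from)
  to <- normalize_symbols(to)
  if (length(from) != length(to)) {
    stop_ic("ortholog_map: from and to must have equal length")
  }
  dup <- duplicated(from)
  if (any(dup)) {
    stop_ic("ortholog_map: source symbol \"%s\" maps to more than one target",
            from[which(dup)[1]])
  }
  structure(
    list(pairs = stats::setNames(to, from),
         source_species = source_species,
         target_species = target_species,
         unmapped = unmapped),
    class = "ortholog_map"
  )
}

#' @rdname ortholog_map
#' @export
identity_ortholog_map <- function(source_species = "mouse",
                                  target_species = "human") {
  ortholog_map(character(0), character(0), source_species, target_species,
               unmapped = "keep")
}

#' Map a gene set into another species
#'
#' Applies an [ortholog_map()] to a `gene_set`. Unmapped symbols are dropped
#' or kept as-is according to the map's policy; the result is de-duplicated
#' (two source symbols mapping to one target yield a single member).
#'
#' @param genes A `gene_set` whose species matches the map's source species.
#' @param map An `ortholog_map`.
#' @return A `gene_set` in the map's target species.
#' @export
map_orthologs <- function(genes, map) {
  stopifnot(inherits(genes, "gene_set"), inherits(map, "ortholog_map"))
  if (genes$species != map$source_species) {
    stop_ic("map_orthologs: set species (%s) does not match map source (%s)",
            genes$species, map$source_species)
  }
  hit <- genes$members %in% names(map$pairs)
  mapped <- unname(map$pairs[genes$members[hit]])
  if (map$unmapped == "keep") mapped <- c(mapped, genes$members[!hit])
  gene_set(mapped, sprintf("%s->%s", genes$name, map$target_species),
           map$target_species,
           list(op = "map_orthologs",
                parents = list(list(name = genes$name,
                                    provenance = genes$provenance))))
}
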