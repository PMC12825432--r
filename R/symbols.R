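#' Normalize gene symbols to the package canon
#'
#' All gene identifiers handled by the screen are reduced to a single
#' deterministic canonical form before any comparison: leading/trailing
#' whitespace is trimmed, internal whitespace removed, and the symbol is
#' uppercased. The transformation is idempotent. No alias or HGNC resolution
#' is attempted beyond this; cross-species harmonization goes through an
#' explicit [ortholog_map()].
#'
#' @param x Character vector of raw gene symbols.
#' @return Character vector of normalized symbols, same length as `x`.
#' @examples
#' normalize_symbols(c("Cd200r1", " CEP55 "))
#' @export
normalize_symbols <- function(x) {
  if (length(x) == 0L) return(character(0))
  if (!is.character(x)) x <- as.character(x)
  if (anyNA(x)) stop_ic("gene symbol is NA at position %d", which(is.na(x))[1])
  out <- toupper(gsub("[[:space:]]+", "", x))
  bad <- !nzchar(out)
  if (any(bad)) {
    stop_ic("empty or whitespace-only gene symbol (raw value: \"%s\")",
            x[which(bad)[1]])
  }
  out
}

assert_species <- function(species) {
  if (!is_string(species) || !species %in% c("human", "mouse")) {
    stop_ic("species must be \"human\" or \"mouse\", got \"%s\"",
            paste(species, collapse = ","))
  }
  species
}
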