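#' Construct a differential-expression table
#'
#' One perturbation dataset's per-gene log2 fold-changes and p-values, plus
#' the metadata the screen needs: which gene (or intervention label) was
#' perturbed, the species, and a free-text description of the comparison.
#' Gene symbols are normalized; duplicate symbols are rejected by default
#' (silent merging hides upstream data faults), or merged keeping the row
#' with the smallest p-value if `duplicates = "min_p"`.
#'
#' @param dataset_id Unique string identifying the dataset.
#' @param perturbed_target Gene symbol or label of the perturbation (e.g.
#'   `"CTLA4"`, `"PDL1_KD"`, `"TUMOR_TREG"`).
#' @param species `"human"` or `"mouse"`.
#' @param data Data frame with columns `gene`, `log2fc`, `pvalue`.
#' @param comparison Free-text description of the contrast.
#' @param duplicates `"error"` (default) or `"min_p"`.
#' @return An object of class `de_table`.
#' @export
de_table <- function(dataset_id, perturbed_target, species, data,
                     comparison = "", duplicates = c("error", "min_p")) {
  duplicates <- match.arg(duplicates)
  if (!is_string(dataset_id)) stop_ic("de_table: dataset_id must be a string")
  assert_species(species)
  need <- c("gene", "log2fc", "pvalue")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    stop_ic("de_table %s: data must have columns gene, log2fc, pvalue",
            dataset_id)
  }
  data <- data.frame(gene = normalize_symbols(data$gene),
                     log2fc = as.numeric(data$log2fc),
                     pvalue = as.numeric(data$pvalue),
                     stringsAsFactors = FALSE)
  if (anyDuplicated(data$gene)) {
    if (duplicates == "error") {
      stop_ic("de_table %s: duplicate rows for gene %s (set duplicates = \"min_p\" to merge)",
              dataset_id, data$gene[duplicated(data$gene)][1])
    }
    data <- data[order(data$gene, data$pvalue), , drop = FALSE]
    data <- data[!duplicated(data$gene), , drop = FALSE]
    rownames(data) <- NULL
  }
  bad_p <- is.na(data$pvalue) | data$pvalue < 0 | data$pvalue > 1
  if (any(bad_p)) {
    stop_ic("de_table %s: pvalue outside [0,1] (or NA) for gene %s",
            dataset_id, data$gene[which(bad_p)[1]])
  }
  bad_fc <- !is.finite(data$log2fc)
  if (any(bad_fc)) {
    stop_ic("de_table %s: non-finite log2fc for gene %s",
            dataset_id, data$gene[which(bad_fc)[1]])
  }
  structure(
    list(dataset_id = dataset_id,
         perturbed_target = normalize_symbols(perturbed_target),
         species = species, comparison = comparison, data = data),
    class = "de_table"
  )
}

#' @export
print.de_table <- function(x, ...) {
  cat(sprintf("<de_table> %s: %s perturbed (%s), %d genes\n",
              x$dataset_id, x$perturbed_target, x$species, nrow(x$data)))
  invisible(x)
}

#' Read and write differential-expression tables
#'
#' The on-disk format is a TSV with columns `gene`, `log2fc`, `pvalue` and a
#' JSON sidecar (`<file>.json` by default) holding `dataset_id`,
#' `perturbed_target`, `species` and `comparison`.
#'
#' @param path Path to the TSV file.
#' @param metadata Path to the JSON sidecar, or a named list with the
#'   metadata fields; defaults to `paste0(path, ".json")`.
#' @param duplicates Passed to [de_table()].
#' @return `read_de_table()` returns a `de_table`; `write_de_table()` writes
#'   the TSV and sidecar and returns `path` invisibly.
#' @export
read_de_table <- function(path, metadata = NULL,
                          duplicates = c("error", "min_p")) {
  if (is.null(metadata)) metadata <- paste0(path, ".json")
  if (is.character(metadata)) metadata <- jsonlite::read_json(metadata)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  de_table(metadata$dataset_id, metadata$perturbed_target, metadata$species,
           df, comparison = metadata$comparison %||% "",
           duplicates = match.arg(duplicates))
}

#' @rdname read_de_table
#' @param x A `de_table`.
#' @export
write_de_table <- function(x, path) {
  stopifnot(inherits(x, "de_table"))
  utils::write.table(x$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(dataset_id = x$dataset_id,
               perturbed_target = x$perturbed_target,
               species = x$species, comparison = x$comparison)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
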