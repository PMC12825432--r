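#' Fraction of a gene panel altered under a perturbation
#'
#' Counts panel genes significantly altered in one differential-expression
#' dataset: `p < alpha` and, if `direction` is `"up"`/`"down"`, the
#' corresponding strict sign constraint; `"any"` (the default) counts either
#' direction. Genes absent from the dataset stay in the denominator — they
#' are "not measured", never "not significant" — and are reported separately.
#'
#' @param panel Non-empty `gene_set`.
#' @param dataset A [de_table()].
#' @param config A [screen_config()].
#' @param direction `"any"`, `"up"`, or `"down"`.
#' @return A `modulation_report` list: `panel`, `dataset_id`, `direction`,
#'   `n_panel`, `n_measured`, `n_altered`, `n_up`, `n_down`,
#'   `fraction_altered`, `percent` (display-rounded), `unmeasured`.
#' @export
altered_fraction <- function(panel, dataset, config = screen_config(),
                             direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(panel, "gene_set"), inherits(dataset, "de_table"))
  if (length(panel) == 0L) stop_ic("altered_fraction: empty panel")
  idx <- match(panel$members, dataset$data$gene)
  measured <- !is.na(idx)
  lfc <- dataset$data$log2fc[idx[measured]]
  p <- dataset$data$pvalue[idx[measured]]
  sig <- p < config$alpha
  n_up <- sum(sig & lfc > config$lfc_up)
  n_down <- sum(sig & lfc < config$lfc_down)
  n_altered <- switch(direction, any = sum(sig), up = n_up, down = n_down)
  structure(
    list(panel = panel$name, dataset_id = dataset$dataset_id,
         direction = direction,
         n_panel = length(panel), n_measured = sum(measured),
         n_altered = n_altered, n_up = n_up, n_down = n_down,
         fraction_altered = n_altered / length(panel),
         percent = percent_value(n_altered, length(panel),
                                 config$percent_decimals),
         unmeasured = panel$members[!measured]),
    class = "modulation_report"
  )
}

#' @export
print.modulation_report <- function(x, ...) {
  cat(sprintf("<modulation_report> %s in %s: %d of %d altered (%s%%), %d up / %d down, %d unmeasured\n",
              x$panel, x$dataset_id, x$n_altered, x$n_panel,
              format(x$percent), x$n_up, x$n_down, length(x$unmeasured)))
  invisible(x)
}

#' Per-cell-type mean expression summaries
#'
#' Arithmetic means of each gene over the cells of each labeled type, in the
#' raw units of the input matrix (no internal normalization — any
#' transformation is the caller's responsibility). Also reports the argmax
#' cell type per gene and the ratio of means between two chosen types
#' (default CD8 vs CD4 T cells); the ratio is `NA` with a flag where the
#' denominator mean is zero.
#'
#' @param matrix Numeric cells-x-genes matrix (cells in rows, gene symbols as
#'   column names).
#' @param labels Character vector, one cell-type label per row of `matrix`
#'   (no `NA`s).
#' @param genes Optional `gene_set` or character vector restricting the
#'   columns; all must be present in the matrix.
#' @param ratio Length-2 character vector: numerator and denominator cell
#'   types for the ratio, or `NULL` to skip.
#' @return A `celltype_summary` list: `means` (types x genes), `argmax_type`
#'   (named character), `ratio` (named numeric), `ratio_undefined` (genes
#'   with zero denominator mean), `ratio_types`.
#' @export
celltype_means <- function(matrix, labels, genes = NULL,
                           ratio = c("CD8_T", "CD4_T")) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop_ic("celltype_means: matrix must be a numeric matrix")
  }
  if (length(labels) != nrow(matrix)) {
    stop_ic("celltype_means: one label per cell required (%d labels, %d cells)",
            length(labels), nrow(matrix))
  }
  if (anyNA(labels) || any(!nzchar(labels))) {
    stop_ic("celltype_means: unlabeled cell at position %d",
            which(is.na(labels) | !nzchar(labels))[1])
  }
  if (!is.null(genes)) {
    want <- if (inherits(genes, "gene_set")) genes$members
            else normalize_symbols(genes)
    missing <- setdiff(want, colnames(matrix))
    if (length(missing)) {
      stop_ic("celltype_means: gene %s not in matrix columns", missing[1])
    }
    matrix <- matrix[, want, drop = FALSE]
  }
  types <- sort(unique(labels))
  means <- do.call(rbind, lapply(types, function(ty) {
    colMeans(matrix[labels == ty, , drop = FALSE])
  }))
  rownames(means) <- types
  argmax <- rownames(means)[apply(means, 2, which.max)]
  names(argmax) <- colnames(means)
  rat <- NULL; rat_undef <- character(0)
  if (!is.null(ratio)) {
    if (all(ratio %in% types)) {
      denom <- means[ratio[2], ]
      rat <- means[ratio[1], ] / denom
      rat_undef <- colnames(means)[denom == 0]
      rat[denom == 0] <- NA_real_
    } else {
      ratio <- NULL  # requested types absent; ratio skipped
    }
  }
  structure(
    list(means = means, argmax_type = argmax, ratio = rat,
         ratio_undefined = rat_undef, ratio_types = ratio),
    class = "celltype_summary"
  )
}

#' @export
print.celltype_summary <- function(x, ...) {
  cat(sprintf("<celltype_summary> %d cell types x %d genes\n",
              nrow(x$means), ncol(x$means)))
  if (!is.null(x$ratio_types)) {
    cat(sprintf("  ratio: %s / %s\n", x$ratio_types[1], x$ratio_types[2]))
  }
  invisible(x)
}
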