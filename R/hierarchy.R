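#' Score one knockout dataset against the reference checkpoint panel
#'
#' The regulatory-hierarchy score of a knockout dataset is the fraction of a
#' reference panel of well-established inhibitory checkpoints that the
#' knockout down-calls. The perturbed gene itself is excluded from its own
#' numerator (a knockout trivially depresses its own transcript; the question
#' is its effect on *other* checkpoints) while the denominator stays the full
#' panel size. A dataset classifies `HIGH` iff the unrounded fraction
#' strictly exceeds `config$hierarchy_threshold`; `score_percent` is the
#' integer display percentage.
#'
#' @param dataset A [de_table()].
#' @param reference_panel Non-empty `gene_set` of known inhibitory
#'   checkpoints (the screen uses a 25-member panel).
#' @param config A [screen_config()].
#' @return One-row data frame: `dataset_id`, `perturbed_target`,
#'   `n_reference_down`, `n_reference`, `score_fraction`, `score_percent`,
#'   `class`.
#' @export
hierarchy_score <- function(dataset, reference_panel,
                            config = screen_config()) {
  stopifnot(inherits(dataset, "de_table"),
            inherits(reference_panel, "gene_set"))
  if (length(reference_panel) == 0L) {
    stop_ic("hierarchy_score: empty reference panel")
  }
  panel <- setdiff(reference_panel$members, dataset$perturbed_target)
  idx <- match(panel, dataset$data$gene)
  measured <- !is.na(idx)
  n_down <- if (any(measured)) {
    sum(call_down(dataset$data$log2fc[idx[measured]],
                  dataset$data$pvalue[idx[measured]], config))
  } else 0L
  n_ref <- length(reference_panel)
  frac <- n_down / n_ref
  data.frame(
    dataset_id = dataset$dataset_id,
    perturbed_target = dataset$perturbed_target,
    n_reference_down = n_down,
    n_reference = n_ref,
    score_fraction = frac,
    score_percent = round_half_away(100 * frac, 0),
    class = if (frac > config$hierarchy_threshold) "HIGH" else "LOW",
    stringsAsFactors = FALSE
  )
}

#' @rdname hierarchy_score
#' @param datasets List of `de_table` objects.
#' @export
hierarchy_report <- function(datasets, reference_panel,
                             config = screen_config()) {
  out <- do.call(rbind, lapply(datasets, hierarchy_score,
                               reference_panel = reference_panel,
                               config = config))
  class(out) <- c("hierarchy_report", "data.frame")
  out
}

#' Partition knockout targets into high and low hierarchy
#'
#' Aggregates a [hierarchy_report()] over datasets sharing a perturbed
#' target. Under `"any"` (default) a target is HIGH iff any of its datasets
#' classifies HIGH; `"max"` compares the maximum per-target fraction to the
#' threshold. For a strict `>` threshold the two modes coincide; both are
#' kept so the aggregation rule is explicit in reports.
#'
#' @param report A `hierarchy_report` (every row annotated with a
#'   `perturbed_target`).
#' @param aggregation `"any"` or `"max"`.
#' @param config A [screen_config()].
#' @return List with `high`, `low` (character vectors of targets) and
#'   `table` (per-target best fraction and class).
#' @export
classify_targets <- function(report, aggregation = c("any", "max"),
                             config = screen_config()) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(report, "data.frame"))
  best <- tapply(report$score_fraction, report$perturbed_target, max)
  is_high <- switch(aggregation,
    any = tapply(report$class == "HIGH", report$perturbed_target, any),
    max = best > config$hierarchy_threshold
  )
  tab <- data.frame(
    perturbed_target = names(best),
    best_fraction = as.numeric(best),
    class = ifelse(as.logical(is_high[names(best)]), "HIGH", "LOW"),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  list(high = tab$perturbed_target[tab$class == "HIGH"],
       low = tab$perturbed_target[tab$class == "LOW"],
       table = tab)
}
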