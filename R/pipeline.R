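#' Run the full checkpoint screen end to end
#'
#' Executes the three candidate rounds and the three-round ligand triage in
#' order: (1) intersect the membrane universe with the two discovery
#' signatures and exclude known checkpoints; (2) build the down-call matrix
#' over the knockout panel and keep candidates down-called at least once;
#' (3) score each knockout target against the reference panel, classify
#' targets into high/low hierarchy, and keep candidates down-called under at
#' least k of the n high-hierarchy targets; then triage each finalist's
#' interaction partners through the membrane, APC-marker and
#' tolerogenic-upregulation filters. Optionally summarizes a gene panel's
#' modulation in additional perturbation datasets.
#'
#' The returned report's counts are all recomputed from the result tables it
#' carries, and warnings are machine-readable entries (rounding-sensitive
#' display percentages, candidates unmeasured in the high-hierarchy panel,
#' the memberships-vs-distinct ligand reconciliation).
#'
#' @param inputs Named list: `membrane`, `foxp3_up`, `treg_specific`,
#'   `known_ics`, `reference_panel` (all [gene_set()]s), `ko_datasets` (list
#'   of [de_table()]s), optionally `hierarchy_ids` (dataset ids used for
#'   hierarchy scoring; default all), `interactions`, `apc_markers`,
#'   `tolerogenic`, and `modulation` (named list of `de_table`s whose
#'   alteration of the final ligand panel is summarized). The output of
#'   [simulate_fixture()] is directly acceptable.
#' @param config A [screen_config()].
#' @param aggregation Passed to [classify_targets()].
#' @return An `ic_screen` object: `candidates`, `matrix`,
#'   `downcall_summary`, `hierarchy`, `targets`, `finalists` (character),
#'   `ligands` (a `ligand_table`, or `NULL` if no interaction inputs),
#'   `modulation` (list of [altered_fraction()] reports), `config`,
#'   `report` (per-round counts), `warnings`.
#' @export
run_screen <- function(inputs, config = screen_config(),
                       aggregation = c("any", "max")) {
  aggregation <- match.arg(aggregation)
  gs <- inputs$gene_sets %||% inputs
  cand <- build_candidates(gs$membrane, gs$foxp3_up, gs$treg_specific,
                           gs$known_ics)
  warnings <- list()

  datasets <- inputs$ko_datasets
  if (length(datasets) == 0L) {
    # degenerate run: report round-1 only, no crash
    out <- structure(list(candidates = cand, matrix = NULL,
                          downcall_summary = NULL, hierarchy = NULL,
                          targets = NULL, finalists = character(0),
                          ligands = NULL, modulation = list(),
                          config = config,
                          report = screen_report(cand, NULL, NULL, NULL,
                                                 character(0), NULL, config),
                          warnings = warnings),
                     class = "ic_screen")
    return(out)
  }

  m <- build_downcall_matrix(cand, datasets, config)
  cand <- round2_filter(m, cand)
  dsum <- downcall_summary(m)
  sens <- dsum[rounding_sensitive(dsum$n_down, dsum$n_candidates,
                                  config$percent_decimals), , drop = FALSE]
  for (i in seq_len(nrow(sens))) {
    warnings <- c(warnings, list(list(
      type = "rounding_sensitive_percent",
      dataset_id = sens$dataset_id[i],
      numerator = sens$n_down[i], denominator = sens$n_candidates[i],
      half_away = percent_value(sens$n_down[i], sens$n_candidates[i],
                                config$percent_decimals),
      truncated = trunc(100 * sens$n_down[i] / sens$n_candidates[i] *
                          10^config$percent_decimals) /
                  10^config$percent_decimals,
      note = "display percentage differs between rounding conventions")))
  }

  hids <- inputs$hierarchy_ids %||% vapply(datasets, `[[`, "", "dataset_id")
  hsets <- datasets[vapply(datasets, `[[`, "", "dataset_id") %in% hids]
  hier <- hierarchy_report(hsets, gs$reference_panel, config)
  targ <- classify_targets(hier, aggregation, config)
  cand <- round3_filter(m, targ$high, cand, config,
                        allow_n_mismatch = length(targ$high) !=
                          config$stringency_n)
  if (length(targ$high) != config$stringency_n) {
    warnings <- c(warnings, list(list(
      type = "stringency_n_mismatch",
      n_high = length(targ$high), stringency_n = config$stringency_n)))
  }
  unm <- attr(cand, "unmeasured_in_high")
  if (length(unm)) {
    warnings <- c(warnings, list(list(
      type = "unmeasured_in_high_hierarchy", genes = unm)))
  }
  finalists <- cand$gene[cand$round3_pass]

  ligands <- NULL
  if (!is.null(inputs$interactions) && length(finalists)) {
    ligands <- triage_ligands(finalists, inputs$interactions, gs$membrane,
                              inputs$apc_markers, inputs$tolerogenic, config)
    tc <- attr(ligands, "triage_counts")
    warnings <- c(warnings, list(list(
      type = "ligand_dedup_reconciliation",
      per_receptor = as.list(tc$per_receptor),
      n_memberships = tc$n_memberships, n_distinct = tc$n_distinct,
      n_shared_memberships = tc$n_shared,
      note = "sum of per-receptor lists exceeds the distinct union by the shared memberships")))
  }

  modulation <- list()
  if (!is.null(inputs$modulation) && !is.null(ligands) && nrow(ligands)) {
    panel <- gene_set(ligands$ligand, "final_ligands",
                      gs$membrane$species, "screen output")
    modulation <- lapply(inputs$modulation, altered_fraction, panel = panel,
                         config = config)
  }

  structure(
    list(candidates = cand, matrix = m, downcall_summary = dsum,
         hierarchy = hier, targets = targ, finalists = finalists,
         ligands = ligands, modulation = modulation, config = config,
         report = screen_report(cand, dsum, hier, targ, finalists, ligands,
                                config),
         warnings = warnings),
    class = "ic_screen"
  )
}

screen_report <- function(cand, dsum, hier, targ, finalists, ligands,
                          config) {
  branch <- factor(cand$branch, c("TREG_SPECIFIC", "FOXP3_UP"))
  counts <- attr(cand, "counts")
  rep <- list(
    config = config[c("alpha", "lfc_down", "lfc_up", "hierarchy_threshold",
                      "stringency_k", "stringency_n", "percent_decimals")],
    round1 = list(
      treg = sum(branch == "TREG_SPECIFIC"),
      foxp3 = sum(branch == "FOXP3_UP"),
      total = nrow(cand),
      removed_treg = counts$treg$removed,
      removed_foxp3 = counts$foxp3$removed
    )
  )
  if (!all(is.na(cand$round2_pass))) {
    rep$round2 <- list(
      treg = sum(cand$round2_pass & branch == "TREG_SPECIFIC", na.rm = TRUE),
      foxp3 = sum(cand$round2_pass & branch == "FOXP3_UP", na.rm = TRUE),
      total = sum(cand$round2_pass, na.rm = TRUE)
    )
  }
  if (!is.null(dsum)) rep$downcalls <- dsum
  if (!is.null(hier)) rep$hierarchy <- as.data.frame(hier)
  if (!is.null(targ)) rep$high_targets <- targ$high
  rep$round3 <- list(
    treg = sum(cand$round3_pass & branch == "TREG_SPECIFIC", na.rm = TRUE),
    foxp3 = sum(cand$round3_pass & branch == "FOXP3_UP", na.rm = TRUE),
    total = length(finalists),
    finalists = finalists
  )
  if (!is.null(ligands)) {
    tc <- attr(ligands, "triage_counts")
    rep$ligands <- list(
      per_receptor = as.list(tc$per_receptor),
      n_memberships = tc$n_memberships,
      n_distinct = tc$n_distinct,
      round_counts = as.data.frame(attr(ligands, "round_counts"))
    )
  }
  rep
}

#' @export
print.ic_screen <- function(x, ...) {
  r <- x$report
  cat("<ic_screen>\n")
  cat(sprintf("  round 1 candidates : %d (Treg-specific %d, FoxP3-up %d)\n",
              r$round1$total, r$round1$treg, r$round1$foxp3))
  if (!is.null(r$round2)) {
    cat(sprintf("  round 2 survivors  : %d (Treg-specific %d, FoxP3-up %d)\n",
                r$round2$total, r$round2$treg, r$round2$foxp3))
  }
  if (length(r$high_targets)) {
    cat(sprintf("  high hierarchy     : %s\n",
                paste(r$high_targets, collapse = ", ")))
  }
  cat(sprintf("  round 3 finalists  : %d%s\n", r$round3$total,
              if (r$round3$total) paste0(" (",
                paste(r$round3$finalists, collapse = ", "), ")") else ""))
  if (!is.null(r$ligands)) {
    cat(sprintf("  ligands            : %d distinct (%d memberships)\n",
                r$ligands$n_distinct, r$ligands$n_memberships))
  }
  if (length(x$warnings)) {
    cat(sprintf("  warnings           : %d (see $warnings)\n",
                length(x$warnings)))
  }
  invisible(x)
}

#' @export
summary.ic_screen <- function(object, ...) {
  print(object)
  if (!is.null(object$downcall_summary)) {
    cat("\nPer-dataset down-calls:\n")
    print(object$downcall_summary[, c("dataset_id", "perturbed_target",
                                      "n_down", "display")])
  }
  if (!is.null(object$hierarchy)) {
    cat("\nHierarchy scores:\n")
    print(as.data.frame(object$hierarchy)[, c("dataset_id",
                                              "perturbed_target",
                                              "score_percent", "class")])
  }
  for (m in object$modulation) print(m)
  invisible(object)
}

#' Persist an `ic_screen` run to disk
#'
#' Writes the candidate table and down-call matrix as TSV, the ligand table
#' as TSV, and the full report (config echo, per-round counts, hierarchy
#' table, warnings) as JSON. Every count in the JSON is recomputed from the
#' emitted tables by construction.
#'
#' @param x An `ic_screen` from [run_screen()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(x, dir) {
  stopifnot(inherits(x, "ic_screen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(x$candidates),
                     file.path(dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(x$matrix)) {
    utils::write.table(cbind(gene = rownames(x$matrix),
                             as.data.frame(unclass(x$matrix))),
                       file.path(dir, "downcall_matrix.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(x$ligands)) {
    utils::write.table(as.data.frame(x$ligands),
                       file.path(dir, "ligands.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(report = x$report, warnings = x$warnings),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
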