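#' Round 1: build the candidate table
#'
#' Intersects the plasma-membrane universe with each of the two discovery
#' signatures — FoxP3-upregulated genes and Treg-specific genes — and removes
#' the known-checkpoint exclusion list from each branch. A gene may appear in
#' both branches only if it is in both signatures. The per-branch
#' intersection sizes and removal counts are kept as attributes
#' (`attr(x, "counts")`) because the two branches can lose different numbers
#' of genes to the same exclusion list.
#'
#' @param membrane `gene_set`: plasma-membrane protein universe.
#' @param foxp3_up `gene_set`: genes upregulated in FoxP3+ cells.
#' @param treg_specific `gene_set`: Treg-specific genes.
#' @param known_ics `gene_set`: known checkpoint receptors to exclude.
#' @return A `candidate_table`: data frame with columns `gene`, `branch`
#'   (`"TREG_SPECIFIC"` or `"FOXP3_UP"`), `round1` (always `TRUE`),
#'   `round2_pass`, `round3_pass` (initialized `NA`).
#' @export
build_candidates <- function(membrane, foxp3_up, treg_specific, known_ics) {
  for (s in list(membrane, foxp3_up, treg_specific, known_ics)) {
    stopifnot(inherits(s, "gene_set"))
  }
  if (length(membrane) == 0L) {
    stop_ic("build_candidates: empty membrane universe")
  }
  fox_int <- gs_intersect(membrane, foxp3_up)
  treg_int <- gs_intersect(membrane, treg_specific)
  fox_branch <- gs_subtract(fox_int, known_ics)
  treg_branch <- gs_subtract(treg_int, known_ics)

  n <- length(treg_branch) + length(fox_branch)
  out <- data.frame(
    gene = c(treg_branch$members, fox_branch$members),
    branch = rep(c("TREG_SPECIFIC", "FOXP3_UP"),
                 c(length(treg_branch), length(fox_branch))),
    round1 = rep(TRUE, n), round2_pass = rep(NA, n),
    round3_pass = rep(NA, n),
    stringsAsFactors = FALSE
  )
  attr(out, "counts") <- list(
    treg = list(intersection = length(treg_int),
                removed = length(treg_int) - length(treg_branch),
                kept = length(treg_branch)),
    foxp3 = list(intersection = length(fox_int),
                 removed = length(fox_int) - length(fox_branch),
                 kept = length(fox_branch))
  )
  attr(out, "species") <- membrane$species
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' @export
print.candidate_table <- function(x, ...) {
  cnt <- table(factor(x$branch, c("TREG_SPECIFIC", "FOXP3_UP")))
  cat(sprintf("<candidate_table> %d candidates (TREG_SPECIFIC %d, FOXP3_UP %d)\n",
              nrow(x), cnt[1], cnt[2]))
  if (!all(is.na(x$round2_pass))) {
    cat(sprintf("  round2 survivors: %d\n", sum(x$round2_pass, na.rm = TRUE)))
  }
  if (!all(is.na(x$round3_pass))) {
    cat(sprintf("  round3 finalists: %d\n", sum(x$round3_pass, na.rm = TRUE)))
  }
  invisible(x)
}

#' Binary significance calls on one differential-expression record
#'
#' A gene is called DOWN in a dataset iff `pvalue < alpha` and
#' `log2fc < lfc_down`, both strict; `call_up()` mirrors the rule with the
#' reversed sign (`log2fc > lfc_up`). A gene at exactly `p == alpha` or
#' `log2fc == 0` (under the default cutoffs) is therefore not called.
#' Vectorized over `log2fc`/`pvalue`.
#'
#' @param log2fc,pvalue Numeric vectors (finite; `pvalue` in `[0,1]`).
#' @param config A [screen_config()].
#' @return Logical vector: `TRUE` where the call fires.
#' @examples
#' cfg <- screen_config()
#' call_down(c(-1.2, -1.2, 0), c(0.01, 0.05, 0.001), cfg)
#' @export
call_down <- function(log2fc, pvalue, config = screen_config()) {
  check_call_inputs(log2fc, pvalue)
  pvalue < config$alpha & log2fc < config$lfc_down
}

#' @rdname call_down
#' @export
call_up <- function(log2fc, pvalue, config = screen_config()) {
  check_call_inputs(log2fc, pvalue)
  pvalue < config$alpha & log2fc > config$lfc_up
}

check_call_inputs <- function(log2fc, pvalue) {
  if (any(!is.finite(log2fc))) stop_ic("call: non-finite log2fc")
  if (any(is.na(pvalue) | pvalue < 0 | pvalue > 1)) {
    stop_ic("call: pvalue outside [0,1]")
  }
  invisible(TRUE)
}

#' Round 2 screen: the candidates-by-datasets down-call matrix
#'
#' For every candidate and every knockout dataset, records `"DOWN"` (measured
#' with `p < alpha` and negative log2FC under `config`), `"NOT_DOWN"`
#' (measured, call not fired), or `"NOT_MEASURED"` (gene absent from the
#' dataset). Absence is never treated as evidence: `NOT_MEASURED` cells count
#' as not-down in every downstream filter but are reported distinctly.
#' Datasets in another species are reconciled through `orthologs` (default:
#' match after symbol normalization, i.e. case-insensitive identity).
#'
#' @param candidates A `candidate_table` from [build_candidates()].
#' @param datasets List of [de_table()] objects (the knockout panel).
#' @param config A [screen_config()].
#' @param orthologs Optional `ortholog_map` applied to datasets whose species
#'   differs from the candidates'.
#' @return A `downcall_matrix`: character matrix (genes x datasets) with a
#'   `targets` attribute naming each column's perturbed target.
#' @export
build_downcall_matrix <- function(candidates, datasets,
                                  config = screen_config(),
                                  orthologs = NULL) {
  stopifnot(inherits(candidates, "candidate_table"))
  if (length(datasets) == 0L) stop_ic("build_downcall_matrix: no datasets")
  genes <- unique(candidates$gene)
  species <- attr(candidates, "species") %||% "human"
  ids <- vapply(datasets, function(d) d$dataset_id, "")
  if (anyDuplicated(ids)) {
    stop_ic("build_downcall_matrix: duplicate dataset_id %s",
            ids[duplicated(ids)][1])
  }
  m <- matrix("NOT_MEASURED", nrow = length(genes), ncol = length(datasets),
              dimnames = list(genes, ids))
  targets <- stats::setNames(character(length(datasets)), ids)
  for (j in seq_along(datasets)) {
    d <- datasets[[j]]
    stopifnot(inherits(d, "de_table"))
    targets[j] <- d$perturbed_target
    dgenes <- d$data$gene
    if (d$species != species) {
      map <- orthologs %||% identity_ortholog_map(d$species, species)
      if (map$source_species != d$species) {
        stop_ic("build_downcall_matrix: dataset %s is %s but ortholog map source is %s",
                d$dataset_id, d$species, map$source_species)
      }
      hit <- dgenes %in% names(map$pairs)
      dgenes[hit] <- unname(map$pairs[dgenes[hit]])
      if (map$unmapped == "drop") dgenes[!hit] <- NA_character_
    }
    idx <- match(genes, dgenes)
    measured <- !is.na(idx)
    if (!any(measured)) {
      warning(sprintf("dataset %s shares no genes with the candidate list; column kept as NOT_MEASURED",
                      d$dataset_id))
      next
    }
    down <- call_down(d$data$log2fc[idx[measured]],
                      d$data$pvalue[idx[measured]], config)
    m[measured, j] <- ifelse(down, "DOWN", "NOT_DOWN")
  }
  structure(m, targets = targets, config = config, class = "downcall_matrix")
}

#' @export
print.downcall_matrix <- function(x, ...) {
  cat(sprintf("<downcall_matrix> %d candidates x %d datasets\n",
              nrow(x), ncol(x)))
  print(downcall_summary(x))
  invisible(x)
}

#' Per-dataset down-call counts and display percentages
#'
#' @param matrix A `downcall_matrix`.
#' @return Data frame: `dataset_id`, `perturbed_target`, `n_down`,
#'   `n_measured`, `n_candidates`, `percent` (of all candidates,
#'   display-rounded), `display`.
#' @export
downcall_summary <- function(matrix) {
  stopifnot(inherits(matrix, "downcall_matrix"))
  cfg <- attr(matrix, "config")
  n <- nrow(matrix)
  data.frame(
    dataset_id = colnames(matrix),
    perturbed_target = unname(attr(matrix, "targets")),
    n_down = apply(unclass(matrix) == "DOWN", 2, sum),
    n_measured = apply(unclass(matrix) != "NOT_MEASURED", 2, sum),
    n_candidates = n,
    percent = vapply(apply(unclass(matrix) == "DOWN", 2, sum),
                     percent_value, 0, denominator = n,
                     decimals = cfg$percent_decimals),
    display = vapply(apply(unclass(matrix) == "DOWN", 2, sum),
                     percent_display, "", denominator = n,
                     decimals = cfg$percent_decimals),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Round 2 filter: at least one down-call anywhere
#'
#' A candidate survives round 2 iff it has at least one `DOWN` cell across
#' the full dataset panel. Fills `round2_pass` on the candidate table.
#'
#' @param matrix A `downcall_matrix` built over the round-1 candidates.
#' @param candidates The `candidate_table` the matrix was built from.
#' @return The updated `candidate_table`.
#' @export
round2_filter <- function(matrix, candidates) {
  stopifnot(inherits(matrix, "downcall_matrix"),
            inherits(candidates, "candidate_table"))
  any_down <- apply(unclass(matrix) == "DOWN", 1, any)
  candidates$round2_pass <- unname(any_down[candidates$gene])
  candidates
}

#' Round 3 filter: k-of-n high-hierarchy stringency
#'
#' Among round-2 survivors only, counts for each candidate the number of
#' distinct high-hierarchy knockout *targets* under which it has at least one
#' `DOWN` cell (a candidate down in three datasets all perturbing the same
#' gene counts once); a candidate passes iff that count reaches
#' `config$stringency_k`. Set `count_by = "dataset"` to count datasets
#' instead of targets. Candidates unmeasured in every high-hierarchy dataset
#' are listed in `attr(result, "unmeasured_in_high")` rather than silently
#' failed.
#'
#' @param matrix A `downcall_matrix`.
#' @param high_targets Character vector of high-hierarchy perturbed targets;
#'   must have exactly `config$stringency_n` members unless
#'   `allow_n_mismatch = TRUE`.
#' @param candidates `candidate_table` with `round2_pass` filled.
#' @param config A [screen_config()].
#' @param count_by `"target"` (default) or `"dataset"`.
#' @param allow_n_mismatch Permit `length(high_targets) != stringency_n`.
#' @return The updated `candidate_table` with `round3_pass` filled
#'   (`FALSE` for round-2 failures).
#' @export
round3_filter <- function(matrix, high_targets, candidates,
                          config = screen_config(),
                          count_by = c("target", "dataset"),
                          allow_n_mismatch = FALSE) {
  count_by <- match.arg(count_by)
  stopifnot(inherits(matrix, "downcall_matrix"),
            inherits(candidates, "candidate_table"))
  high_targets <- normalize_symbols(high_targets)
  if (length(high_targets) != config$stringency_n && !allow_n_mismatch) {
    stop_ic("round3_filter: %d high-hierarchy targets supplied but stringency_n = %d (set allow_n_mismatch = TRUE to override)",
            length(high_targets), config$stringency_n)
  }
  targets <- attr(matrix, "targets")
  cols <- which(targets %in% high_targets)
  sub <- unclass(matrix)[, cols, drop = FALSE]
  coltarget <- targets[cols]

  support <- apply(sub == "DOWN", 1, function(row) {
    if (count_by == "target") length(unique(coltarget[row])) else sum(row)
  })
  unmeasured <- rownames(sub)[apply(sub == "NOT_MEASURED", 1, all)]

  pass <- support >= config$stringency_k
  r2 <- candidates$round2_pass
  if (all(is.na(r2))) stop_ic("round3_filter: run round2_filter first")
  candidates$round3_pass <- r2 & unname(pass[candidates$gene])
  attr(candidates, "high_target_support") <- support
  attr(candidates, "unmeasured_in_high") <-
    intersect(unmeasured, candidates$gene[r2])
  candidates
}
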