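#' Construct a receptor-partner interaction table
#'
#' Experimentally reported interaction partners for each finalist checkpoint
#' receptor, one row per (receptor, partner) pair. Symbols are normalized and
#' partners de-duplicated within a receptor. A receptor may list itself — a
#' potential homodimer — and such self-partnerships are retained and flagged
#' downstream, not dropped.
#'
#' @param receptor,partner Character vectors of equal length.
#' @param source Free-text provenance (recycled).
#' @return An `interaction_table` data frame.
#' @export
interaction_table <- function(receptor, partner, source = "input") {
  receptor <- normalize_symbols(receptor)
  partner <- normalize_symbols(partner)
  if (length(receptor) != length(partner)) {
    stop_ic("interaction_table: receptor and partner lengths differ")
  }
  df <- data.frame(receptor = receptor, partner = partner,
                   source = rep_len(as.character(source), length(receptor)),
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df[c("receptor", "partner")]), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("interaction_table", "data.frame")
  df
}

#' Interaction partners of one receptor
#'
#' @param interactions An `interaction_table`.
#' @param receptor Receptor symbol.
#' @param species Species tag for the returned set.
#' @return A `gene_set` of the receptor's partners.
#' @export
partners_of <- function(interactions, receptor, species = "human") {
  stopifnot(inherits(interactions, "interaction_table"))
  receptor <- normalize_symbols(receptor)
  gene_set(interactions$partner[interactions$receptor == receptor],
           sprintf("partners(%s)", receptor), species,
           sprintf("interaction table: %s", receptor))
}

#' Ligand round 1: plasma-membrane filter
#'
#' Restricts a receptor's interaction partners to the plasma-membrane
#' universe (a pure intersection; commutes with the marker filter).
#'
#' @param partners,membrane `gene_set` objects of the same species.
#' @return A `gene_set`.
#' @export
filter_membrane <- function(partners, membrane) {
  gs_intersect(partners, membrane, name = sprintf("%s & membrane",
                                                  partners$name))
}

#' Ligand round 2: antigen-presenting-cell marker filter
#'
#' Retains candidates present in at least one APC marker set and records
#' *every* matching APC type per gene — attribution is non-exclusive, so a
#' gene in both the B-cell and dendritic-cell marker sets yields two rows.
#' Counting rows (gene x APC-type attributions) therefore can exceed the
#' number of distinct genes retained; use `unique(result$gene)` for the
#' distinct-gene view.
#'
#' @param candidates A `gene_set` (or character vector) of candidate ligands.
#' @param apc_markers Named list of `gene_set` marker sets, e.g. names
#'   `macrophage`, `monocyte`, `B_cell`, `dendritic_cell`.
#' @return Data frame with columns `gene`, `apc_type`, one row per
#'   attribution, gene order preserved.
#' @export
filter_apc <- function(candidates, apc_markers) {
  if (inherits(candidates, "gene_set")) candidates <- candidates$members
  candidates <- normalize_symbols(candidates)
  if (length(apc_markers) == 0L) stop_ic("filter_apc: no APC marker sets")
  if (is.null(names(apc_markers)) || any(!nzchar(names(apc_markers)))) {
    stop_ic("filter_apc: apc_markers must be a named list")
  }
  rows <- lapply(names(apc_markers), function(ty) {
    mem <- if (inherits(apc_markers[[ty]], "gene_set")) {
      apc_markers[[ty]]$members
    } else normalize_symbols(apc_markers[[ty]])
    hit <- candidates[candidates %in% mem]
    if (length(hit)) data.frame(gene = hit, apc_type = ty,
                                stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), apc_type = character(0),
                      stringsAsFactors = FALSE)
  }
  # stable order: by candidate position, then marker-set order
  out <- out[order(match(out$gene, candidates),
                   match(out$apc_type, names(apc_markers))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ligand round 3: tolerogenic-subset upregulation filter
#'
#' A candidate ligand passes iff it is up-called (`p < alpha` and
#' `log2fc > lfc_up`, both strict) in at least one dataset contrasting a
#' tolerogenic/anti-inflammatory APC subset with its control (e.g. M2
#' macrophages vs M0). The supporting dataset ids are recorded.
#'
#' @param attributed Data frame from [filter_apc()] (columns `gene`,
#'   `apc_type`).
#' @param tolerogenic_datasets List of [de_table()] objects.
#' @param config A [screen_config()].
#' @return Data frame with one row per surviving gene: `gene`, `apc_types`
#'   (comma-collapsed), `support` (comma-collapsed dataset ids).
#' @export
filter_tolerogenic <- function(attributed, tolerogenic_datasets,
                               config = screen_config()) {
  if (!is.data.frame(attributed) ||
      !all(c("gene", "apc_type") %in% names(attributed))) {
    stop_ic("filter_tolerogenic: attributed must have columns gene, apc_type")
  }
  genes <- unique(attributed$gene)
  support <- stats::setNames(vector("list", length(genes)), genes)
  for (d in tolerogenic_datasets) {
    stopifnot(inherits(d, "de_table"))
    idx <- match(genes, d$data$gene)
    measured <- which(!is.na(idx))
    if (!length(measured)) next
    up <- call_up(d$data$log2fc[idx[measured]],
                  d$data$pvalue[idx[measured]], config)
    for (g in measured[up]) {
      support[[genes[g]]] <- c(support[[genes[g]]], d$dataset_id)
    }
  }
  keep <- genes[lengths(support) > 0L]
  out <- data.frame(
    gene = keep,
    apc_types = vapply(keep, function(g) {
      paste(sort(unique(attributed$apc_type[attributed$gene == g])),
            collapse = ",")
    }, ""),
    support = vapply(keep, function(g) paste(support[[g]], collapse = ","),
                     ""),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Merge per-receptor ligand lists into one de-duplicated table
#'
#' A ligand retained for several receptors appears once, with its receptors
#' merged; per-receptor retained counts, the total number of memberships and
#' the number of cross-receptor shared ligands are kept in
#' `attr(x, "triage_counts")` so the reconciliation between the sum of
#' per-receptor lists and the distinct count is always reported, never
#' silent.
#'
#' @param per_receptor Named list (receptor -> data frame as returned by
#'   [filter_tolerogenic()]).
#' @return A `ligand_table` data frame: `ligand`, `receptors`, `apc_types`,
#'   `support`, `self_partner` (is the ligand one of its own receptors).
#' @export
dedup_union <- function(per_receptor) {
  if (is.null(names(per_receptor))) {
    stop_ic("dedup_union: per_receptor must be a named list (receptor -> table)")
  }
  rows <- do.call(rbind, lapply(names(per_receptor), function(r) {
    df <- per_receptor[[r]]
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    cbind(receptor = r, df, stringsAsFactors = FALSE)
  }))
  per_counts <- vapply(per_receptor,
                       function(df) if (is.null(df)) 0L else nrow(df), 0L)
  if (is.null(rows)) {
    out <- data.frame(ligand = character(0), receptors = character(0),
                      apc_types = character(0), support = character(0),
                      self_partner = logical(0), stringsAsFactors = FALSE)
  } else {
    ligs <- unique(rows$gene)
    out <- data.frame(
      ligand = ligs,
      receptors = vapply(ligs, function(g) {
        paste(unique(rows$receptor[rows$gene == g]), collapse = ",")
      }, ""),
      apc_types = vapply(ligs, function(g) {
        paste(sort(unique(unlist(strsplit(rows$apc_types[rows$gene == g],
                                          ",")))), collapse = ",")
      }, ""),
      support = vapply(ligs, function(g) {
        paste(unique(unlist(strsplit(rows$support[rows$gene == g], ","))),
              collapse = ",")
      }, ""),
      stringsAsFactors = FALSE
    )
    out$self_partner <- mapply(function(g, rs) {
      g %in% strsplit(rs, ",")[[1]]
    }, out$ligand, out$receptors, USE.NAMES = FALSE)
    rownames(out) <- NULL
  }
  attr(out, "triage_counts") <- list(
    per_receptor = per_counts,
    n_memberships = sum(per_counts),
    n_distinct = nrow(out),
    n_shared = sum(per_counts) - nrow(out)
  )
  class(out) <- c("ligand_table", "data.frame")
  out
}

#' @export
print.ligand_table <- function(x, ...) {
  tc <- attr(x, "triage_counts")
  cat(sprintf("<ligand_table> %d distinct ligands (%d memberships across %d receptors, %d shared)\n",
              tc$n_distinct, tc$n_memberships, length(tc$per_receptor),
              tc$n_shared))
  invisible(x)
}

#' Full three-round ligand triage for a set of receptors
#'
#' For every receptor: interaction partners -> plasma-membrane filter ->
#' APC-marker filter -> tolerogenic-upregulation filter; then the
#' per-receptor survivor lists are merged with [dedup_union()]. Per-receptor,
#' per-round counts (partners, membrane survivors, distinct APC-passing
#' genes, APC attribution rows, final ligands) are kept in
#' `attr(x, "round_counts")`.
#'
#' @param receptors Character vector of finalist receptor symbols.
#' @param interactions An [interaction_table()].
#' @param membrane `gene_set`: plasma-membrane universe.
#' @param apc_markers Named list of APC marker `gene_set`s.
#' @param tolerogenic_datasets List of [de_table()]s (tolerogenic subset vs
#'   control contrasts).
#' @param config A [screen_config()].
#' @return A `ligand_table` (see [dedup_union()]).
#' @export
triage_ligands <- function(receptors, interactions, membrane, apc_markers,
                           tolerogenic_datasets, config = screen_config()) {
  receptors <- normalize_symbols(receptors)
  per <- stats::setNames(vector("list", length(receptors)), receptors)
  rounds <- list()
  for (r in receptors) {
    p <- partners_of(interactions, r, species = membrane$species)
    mem <- filter_membrane(p, membrane)
    apc <- filter_apc(mem, apc_markers)
    fin <- filter_tolerogenic(apc, tolerogenic_datasets, config)
    per[[r]] <- fin
    rounds[[r]] <- c(partners = length(p), membrane = length(mem),
                     apc_genes = length(unique(apc$gene)),
                     apc_attributions = nrow(apc), final = nrow(fin))
  }
  out <- dedup_union(per)
  attr(out, "round_counts") <- do.call(rbind, rounds)
  out
}
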