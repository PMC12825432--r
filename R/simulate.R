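# Seeded synthetic-data generator. The fixture spec plants every structural
# property the screen measures: set sizes and intersections, per-dataset
# down-call plans, hierarchy scores, the k-of-n support pattern of the
# finalists, and the ligand sharing that makes the per-receptor lists sum to
# more than their distinct union. Membership layout is a pure function of the
# spec; the seed only drives the numeric noise (p-values, fold-changes,
# expression values) and row order, so the same (spec, seed) pair always
# yields byte-identical files.

syms <- function(prefix, n, width = 4) {
  if (n <= 0) return(character(0))
  sprintf(paste0(prefix, "%0", width, "d"), seq_len(n))
}

derive_seed <- function(seed, idx) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(idx)
}

#' Validate a fixture specification
#'
#' A fixture spec is a nested list (normally read from YAML, see
#' [reference_fixture_spec()]) describing the planted structure of a synthetic
#' screening problem. Validation checks feasibility — every planted subset
#' must fit inside its parent, down-call quotas must cover the planned
#' survivors, the ligand sharing plan must reconcile — and fails naming the
#' violated constraint.
#'
#' @param x Nested list with components `universe`, `finalists`, `survivors`,
#'   `panel`, `datasets`, `panel_down`, `candidate_down`, `ligands`,
#'   `apc_marker_sizes`, `tolerogenic_ids`, `modulation`, `celltype`,
#'   `noise`, `alpha`. See the packaged `reference_fixture.yaml` for the
#'   full field list.
#' @return The validated spec, classed `fixture_spec`.
#' @export
fixture_spec <- function(x) {
  u <- x$universe
  chk <- function(ok, fmt, ...) if (!ok) stop_ic(paste0("fixture_spec: ", fmt), ...)
  chk(u$overlap_foxp3 <= min(u$membrane_size, u$foxp3_up_size),
      "overlap_foxp3 (%d) exceeds a parent set", u$overlap_foxp3)
  chk(u$overlap_treg <= min(u$membrane_size, u$treg_specific_size),
      "overlap_treg (%d) exceeds a parent set", u$overlap_treg)
  chk(u$excluded_foxp3 <= u$overlap_foxp3,
      "excluded_foxp3 (%d) exceeds overlap_foxp3 (%d)",
      u$excluded_foxp3, u$overlap_foxp3)
  chk(u$excluded_treg <= u$overlap_treg,
      "excluded_treg (%d) exceeds overlap_treg (%d)",
      u$excluded_treg, u$overlap_treg)

  kept_f <- u$overlap_foxp3 - u$excluded_foxp3
  kept_t <- u$overlap_treg - u$excluded_treg
  chk(x$survivors$foxp3 <= kept_f, "foxp3 survivors (%d) exceed branch size (%d)",
      x$survivors$foxp3, kept_f)
  chk(x$survivors$treg <= kept_t, "treg survivors (%d) exceed branch size (%d)",
      x$survivors$treg, kept_t)
  chk(length(x$finalists$foxp3) <= x$survivors$foxp3,
      "foxp3 finalists exceed survivors")
  chk(length(x$finalists$treg) <= x$survivors$treg,
      "treg finalists exceed survivors")

  chk(x$panel$size >= length(x$panel$targets),
      "panel size (%d) smaller than target list (%d)",
      x$panel$size, length(x$panel$targets))
  chk(all(names(x$panel_down) %in% x$panel$targets),
      "panel_down names a target outside the panel")
  chk(all(unlist(x$panel_down) <= x$panel$size - 1L),
      "a panel_down count exceeds panel size minus self")

  # candidate down-call allocation feasibility
  nf <- length(x$finalists$treg) + length(x$finalists$foxp3)
  n_nonfinal <- x$survivors$treg + x$survivors$foxp3 - nf
  high <- names(x$panel_down)[unlist(x$panel_down) / x$panel$size >
                                (x$hierarchy_threshold %||% 0.20)]
  plan_ids <- unlist(lapply(names(x$datasets), function(t) {
    sprintf("%s_KO_%d", t, seq_len(x$datasets[[t]]))
  }))
  quotas <- unlist(x$candidate_down)
  chk(all(names(quotas) %in% plan_ids),
      "candidate_down names a dataset outside the panel: %s",
      paste(setdiff(names(quotas), plan_ids), collapse = ","))
  for (id in names(quotas)) {
    tgt <- sub("_KO_\\d+$", "", id)
    extra <- if (tgt %in% high && grepl("_KO_1$", id)) quotas[[id]] - nf
             else quotas[[id]]
    chk(extra >= 0, "dataset %s: quota %d below the %d planted finalists",
        id, quotas[[id]], nf)
    chk(extra <= n_nonfinal,
        "dataset %s: non-finalist quota %d exceeds the %d non-finalist survivors",
        id, extra, n_nonfinal)
  }
  nonfinal_total <- sum(vapply(names(quotas), function(id) {
    tgt <- sub("_KO_\\d+$", "", id)
    if (tgt %in% high && grepl("_KO_1$", id)) quotas[[id]] - nf else quotas[[id]]
  }, 0))
  chk(nonfinal_total >= n_nonfinal,
      "candidate_down quotas (%d non-finalist slots) cannot cover the %d non-finalist survivors",
      nonfinal_total, n_nonfinal)

  # ligand plan reconciliation
  lg <- x$ligands
  fc <- unlist(lg$final_counts)
  treg_rec <- x$finalists$treg[1]
  chk(all(c(x$finalists$treg, x$finalists$foxp3) %in% names(fc)),
      "every finalist needs an entry in ligands$final_counts")
  chk(sum(fc) >= lg$n_distinct,
      "final_counts sum (%d) below n_distinct (%d)", sum(fc), lg$n_distinct)
  chk(lg$cross_branch_shared <= fc[[treg_rec]] - as.integer(isTRUE(lg$homodimer)),
      "cross_branch_shared exceeds the Treg receptor's shareable ligands")
  pool_size <- lg$n_distinct - fc[[treg_rec]] + lg$cross_branch_shared
  chk(pool_size >= max(fc[setdiff(names(fc), treg_rec)]),
      "a FoxP3-branch receptor's final count exceeds the distinct FoxP3 pool (%d)",
      pool_size)
  chk(sum(fc[setdiff(names(fc), treg_rec)]) >= pool_size,
      "FoxP3-branch final counts cannot consume the distinct pool")
  chk(lg$treg_membrane >= fc[[treg_rec]],
      "treg_membrane below the receptor's final ligand count")
  chk(lg$treg_partners >= lg$treg_membrane, "treg_partners below treg_membrane")
  chk(lg$foxp3_membrane >= pool_size, "foxp3_membrane below distinct finals")
  chk(lg$foxp3_partners >= lg$foxp3_membrane,
      "foxp3_partners below foxp3_membrane")
  chk(lg$treg_double_attr <= lg$treg_membrane - fc[[treg_rec]],
      "treg_double_attr exceeds non-final membrane survivors")
  chk(lg$foxp3_double_attr <= pool_size - lg$cross_branch_shared,
      "foxp3_double_attr exceeds branch-exclusive finals")
  chk(x$apc_marker_sizes$B_cell >=
        lg$treg_membrane + lg$foxp3_membrane - lg$cross_branch_shared,
      "B_cell marker set smaller than the membrane survivors it must contain")
  chk(x$apc_marker_sizes$dendritic_cell >=
        lg$treg_double_attr + lg$foxp3_double_attr,
      "dendritic_cell marker set smaller than the double-attributed genes")

  chk(x$modulation$altered <= lg$n_distinct,
      "modulation altered (%d) exceeds the ligand panel (%d)",
      x$modulation$altered, lg$n_distinct)
  chk(x$modulation$up <= x$modulation$altered,
      "modulation up exceeds altered")

  membrane_filler <- u$membrane_size - u$overlap_foxp3 - u$overlap_treg -
    (lg$n_distinct - as.integer(isTRUE(lg$homodimer))) -
    (lg$treg_membrane - fc[[treg_rec]]) - (lg$foxp3_membrane - pool_size)
  chk(membrane_filler >= 0,
      "membrane_size too small for the planted membrane blocks (short by %d)",
      -membrane_filler)

  structure(x, class = "fixture_spec")
}

#' The packaged reference fixture specification
#'
#' Reads the versioned YAML spec shipped with the package (see
#' `system.file("extdata", "reference_fixture.yaml", package =
#' "icscreen")`), optionally applies overrides, and validates it.
#'
#' @param ... Named overrides merged into the spec with [utils::modifyList()]
#'   (e.g. `noise = list(background_size = 100)`).
#' @return A `fixture_spec`.
#' @export
reference_fixture_spec <- function(...) {
  path <- system.file("extdata", "reference_fixture.yaml",
                      package = "icscreen")
  spec <- yaml::read_yaml(path)
  dots <- list(...)
  if (length(dots)) spec <- utils::modifyList(spec, dots)
  fixture_spec(spec)
}

# deterministic symbol layout: which synthetic gene plays which role.
# Pure function of the spec (no RNG).
fixture_layout <- function(spec) {
  if (!inherits(spec, "fixture_spec")) spec <- fixture_spec(spec)
  u <- spec$universe
  lg <- spec$ligands
  fc <- unlist(lg$final_counts)
  treg_rec <- spec$finalists$treg[1]
  fox_receptors <- setdiff(names(fc), treg_rec)

  kept_t <- u$overlap_treg - u$excluded_treg
  kept_f <- u$overlap_foxp3 - u$excluded_foxp3
  treg_cand <- c(spec$finalists$treg,
                 syms("TRC", kept_t - length(spec$finalists$treg), 3))
  fox_cand <- c(spec$finalists$foxp3,
                syms("FXC", kept_f - length(spec$finalists$foxp3), 3))
  excl_t <- syms("KICT", u$excluded_treg, 2)
  excl_f <- syms("KICF", u$excluded_foxp3, 3)

  panel <- c(spec$panel$targets,
             syms("ICREF", spec$panel$size - length(spec$panel$targets), 2))

  # final ligands: Treg-branch receptor's list first, then the FoxP3 pool
  n_treg_fin <- fc[[treg_rec]]
  treg_finals <- c(if (isTRUE(lg$homodimer)) treg_rec,
                   syms("LIG", n_treg_fin - as.integer(isTRUE(lg$homodimer)), 2))
  pool_size <- lg$n_distinct - n_treg_fin + lg$cross_branch_shared
  shared <- utils::tail(treg_finals, lg$cross_branch_shared)
  pool <- c(shared, syms("LGX", pool_size - lg$cross_branch_shared, 2))

  # sequential fill with wrap-around for the planned shared memberships
  fox_finals <- list(); pos <- 0L
  for (r in fox_receptors) {
    take <- ((pos + seq_len(fc[[r]]) - 1L) %% pool_size) + 1L
    fox_finals[[r]] <- pool[take]
    if (anyDuplicated(fox_finals[[r]])) {
      stop_ic("fixture layout: receptor %s would receive a duplicate ligand; sharing plan infeasible", r)
    }
    pos <- pos + fc[[r]]
  }
  if (length(unique(unlist(fox_finals))) != pool_size) {
    stop_ic("fixture layout: FoxP3 final allocation does not consume the distinct pool")
  }

  treg_mem_extra <- syms("CPM", lg$treg_membrane - n_treg_fin, 3)
  fox_mem_extra <- syms("FPM", lg$foxp3_membrane - pool_size, 3)
  treg_nonmem <- syms("CPN", lg$treg_partners - lg$treg_membrane, 3)
  fox_nonmem <- syms("FPN", lg$foxp3_partners - lg$foxp3_membrane, 4)

  split_even <- function(x, groups) {
    n <- length(groups)
    sizes <- rep(length(x) %/% n, n)
    if (length(x) %% n) sizes[seq_len(length(x) %% n)] <-
        sizes[seq_len(length(x) %% n)] + 1L
    stats::setNames(split(x, rep(seq_len(n), sizes)), groups)
  }
  fox_mem_share <- split_even(fox_mem_extra, fox_receptors)
  fox_nonmem_share <- split_even(fox_nonmem, fox_receptors)

  pool_new <- setdiff(pool, shared)
  membrane <- c(excl_f, fox_cand, excl_t, treg_cand,
                setdiff(treg_finals, treg_rec), pool_new,
                treg_mem_extra, fox_mem_extra,
                syms("MEX", u$membrane_size - u$overlap_foxp3 - u$overlap_treg -
                       (lg$n_distinct - as.integer(isTRUE(lg$homodimer))) -
                       length(treg_mem_extra) - length(fox_mem_extra), 4))
  foxp3_up <- c(excl_f, fox_cand, syms("FUX", u$foxp3_up_size - u$overlap_foxp3, 4))
  treg_specific <- c(excl_t, treg_cand,
                     syms("TSX", u$treg_specific_size - u$overlap_treg, 3))

  doubles_treg <- utils::head(treg_mem_extra, lg$treg_double_attr)
  doubles_fox <- utils::head(pool_new, lg$foxp3_double_attr)
  mem_survivors <- unique(c(treg_finals, treg_mem_extra, pool, fox_mem_extra))

  list(
    treg_cand = treg_cand, fox_cand = fox_cand,
    excl = c(excl_f, excl_t), panel = panel,
    membrane = membrane, foxp3_up = foxp3_up, treg_specific = treg_specific,
    treg_receptor = treg_rec, fox_receptors = fox_receptors,
    treg_finals = treg_finals, fox_finals = fox_finals,
    finals_distinct = unique(c(treg_finals, unlist(fox_finals))),
    treg_mem_extra = treg_mem_extra, fox_mem_share = fox_mem_share,
    treg_nonmem = treg_nonmem, fox_nonmem_share = fox_nonmem_share,
    mem_survivors = mem_survivors,
    doubles = c(doubles_treg, doubles_fox),
    background = syms("BGD", spec$noise$background_size, 3)
  )
}

# per-dataset planted call lists (pure function of the spec)
fixture_plan <- function(spec, layout = fixture_layout(spec)) {
  nf_t <- length(spec$finalists$treg); nf_f <- length(spec$finalists$foxp3)
  finalists <- c(layout$treg_cand[seq_len(nf_t)],
                 layout$fox_cand[seq_len(nf_f)])
  surv <- c(layout$treg_cand[seq_len(spec$survivors$treg)],
            layout$fox_cand[seq_len(spec$survivors$foxp3)])
  nonfinal <- setdiff(surv, finalists)

  high <- names(spec$panel_down)[unlist(spec$panel_down) / spec$panel$size >
                                   (spec$hierarchy_threshold %||% 0.20)]
  ids <- unlist(lapply(names(spec$datasets), function(t) {
    sprintf("%s_KO_%d", t, seq_len(spec$datasets[[t]]))
  }))
  targets <- sub("_KO_\\d+$", "", ids)

  down <- stats::setNames(vector("list", length(ids)), ids)
  # finalists: down in the first dataset of every high-hierarchy target
  for (t in high) down[[sprintf("%s_KO_1", t)]] <- finalists
  # non-finalist survivors: cycle through the named quotas
  ptr <- 0L
  for (id in names(spec$candidate_down)) {
    tgt <- sub("_KO_\\d+$", "", id)
    extra <- spec$candidate_down[[id]] -
      if (tgt %in% high && grepl("_KO_1$", id)) length(finalists) else 0L
    if (extra > 0L && length(nonfinal)) {
      take <- ((ptr + seq_len(extra) - 1L) %% length(nonfinal)) + 1L
      down[[id]] <- c(down[[id]], nonfinal[take])
      ptr <- ptr + extra
    }
  }
  # panel genes down-called in each target's first dataset (self excluded)
  panel_down <- stats::setNames(vector("list", length(ids)), ids)
  for (t in names(spec$panel_down)) {
    id <- sprintf("%s_KO_1", t)
    if (id %in% ids) {
      panel_down[[id]] <- utils::head(setdiff(layout$panel, t),
                                      spec$panel_down[[t]])
    }
  }
  list(ids = ids, targets = stats::setNames(targets, ids),
       hierarchy_ids = sprintf("%s_KO_1", names(spec$panel_down)),
       high_targets = high, finalists = finalists, survivors = surv,
       candidate_down = down, panel_down = panel_down)
}

#' Generate the planted gene universe and annotation sets
#'
#' Builds the synthetic gene sets the screen consumes — plasma-membrane
#' universe, FoxP3-upregulated and Treg-specific signatures, the
#' known-checkpoint exclusion list, the reference hierarchy panel and the
#' four APC marker sets — with exactly the intersection and exclusion sizes
#' the spec plants. Membership is a deterministic function of the spec; the
#' seed is accepted for interface symmetry with the other generators.
#'
#' @param spec A [fixture_spec()].
#' @param seed Integer seed.
#' @return Named list of [gene_set()]s: `membrane`, `foxp3_up`,
#'   `treg_specific`, `known_ics`, `reference_panel`, and `apc_markers` (a
#'   named list of four sets).
#' @export
simulate_universe <- function(spec, seed = 1L) {
  if (!inherits(spec, "fixture_spec")) spec <- fixture_spec(spec)
  L <- fixture_layout(spec)
  apc <- list(
    macrophage = syms("MACF", spec$apc_marker_sizes$macrophage, 3),
    monocyte = syms("MONF", spec$apc_marker_sizes$monocyte, 3),
    B_cell = c(L$mem_survivors,
               syms("BCF", spec$apc_marker_sizes$B_cell -
                      length(L$mem_survivors), 4)),
    dendritic_cell = c(L$doubles,
                       syms("DCF", spec$apc_marker_sizes$dendritic_cell -
                              length(L$doubles), 3))
  )
  list(
    membrane = gene_set(L$membrane, "membrane", provenance = "synthetic"),
    foxp3_up = gene_set(L$foxp3_up, "foxp3_up", provenance = "synthetic"),
    treg_specific = gene_set(L$treg_specific, "treg_specific",
                             provenance = "synthetic"),
    known_ics = gene_set(L$excl, "known_ics", provenance = "synthetic"),
    reference_panel = gene_set(L$panel, "reference_panel",
                               provenance = "synthetic"),
    apc_markers = lapply(stats::setNames(names(apc), names(apc)), function(ty) {
      gene_set(apc[[ty]], paste0("apc_", ty), provenance = "synthetic")
    })
  )
}

# draw DE values for one dataset: planted calls are satisfied strictly by
# construction, plan-controlled genes that are not planted are guaranteed
# quiet (p >= alpha), pure background follows the exchangeable null
# (p ~ U(0,1), log2FC ~ N(0, sd)).
draw_de <- function(genes, planted_down, planted_up, controlled, alpha, lfc_sd) {
  n <- length(genes)
  p <- stats::runif(n)
  lfc <- stats::rnorm(n, 0, lfc_sd)
  ctl <- genes %in% controlled & !(genes %in% c(planted_down, planted_up))
  p[ctl] <- alpha + stats::runif(sum(ctl)) * (1 - alpha)
  dn <- genes %in% planted_down
  p[dn] <- 1e-9 + stats::runif(sum(dn)) * alpha * 0.99
  lfc[dn] <- -stats::runif(sum(dn), 0.5, 3)
  up <- genes %in% planted_up
  p[up] <- 1e-9 + stats::runif(sum(up)) * alpha * 0.99
  lfc[up] <- stats::runif(sum(up), 0.5, 3)
  data.frame(gene = genes, log2fc = lfc, pvalue = p, stringsAsFactors = FALSE)
}

all_dataset_ids <- function(spec) {
  plan_ids <- unlist(lapply(names(spec$datasets), function(t) {
    sprintf("%s_KO_%d", t, seq_len(spec$datasets[[t]]))
  }))
  c(plan_ids, unlist(spec$tolerogenic_ids), spec$modulation$dataset_id)
}

#' Generate one differential-expression dataset
#'
#' Simulates a single dataset from the fixture plan: a knockout dataset
#' (ids `<target>_KO_<i>`), a tolerogenic APC contrast (ids in
#' `spec$tolerogenic_ids`), or the knock-down modulation dataset. Planted
#' calls hold strictly by construction (`p < alpha`, sign as planned);
#' plan-controlled genes not planted are guaranteed quiet; background genes
#' follow a uniform-p, zero-centered-log2FC null. Row order is shuffled
#' under the derived seed.
#'
#' @param spec A [fixture_spec()].
#' @param dataset_id One of the ids in the spec's plan.
#' @param seed Integer seed (a per-dataset stream is derived from it).
#' @return A [de_table()].
#' @export
simulate_de_dataset <- function(spec, dataset_id, seed = 1L) {
  if (!inherits(spec, "fixture_spec")) spec <- fixture_spec(spec)
  ids <- all_dataset_ids(spec)
  if (!dataset_id %in% ids) {
    stop_ic("simulate_de_dataset: unknown dataset_id \"%s\"", dataset_id)
  }
  L <- fixture_layout(spec)
  P <- fixture_plan(spec, L)
  set.seed(derive_seed(seed, match(dataset_id, ids)))
  alpha <- spec$alpha; lfc_sd <- spec$noise$lfc_sd
  cands <- c(L$treg_cand, L$fox_cand)

  if (dataset_id %in% P$ids) {
    target <- P$targets[[dataset_id]]
    genes <- c(cands, L$panel, L$background)
    down <- c(P$candidate_down[[dataset_id]], P$panel_down[[dataset_id]],
              target)
    df <- draw_de(genes, down, character(0), c(cands, L$panel), alpha, lfc_sd)
    meta <- list(target = target,
                 comparison = sprintf("%s knockout vs wild type", target))
  } else if (dataset_id %in% spec$tolerogenic_ids) {
    genes <- c(L$mem_survivors,
               utils::head(L$background, length(L$background) %/% 2))
    # planted support: every final ligand is up-called in one designated
    # tolerogenic contrast (the second, the B-cell-like one in the shipped
    # spec); doubly-attributed finals gain a second support dataset (the
    # third). The remaining contrasts carry background only.
    tids <- unlist(spec$tolerogenic_ids)
    k <- match(dataset_id, tids)
    up <- if (k == min(2L, length(tids))) L$finals_distinct
          else if (k == 3L) intersect(L$doubles, L$finals_distinct)
          else character(0)
    df <- draw_de(genes, character(0), up, L$mem_survivors, alpha, lfc_sd)
    meta <- list(target = dataset_id,
                 comparison = "tolerogenic subset vs control")
  } else {  # modulation knock-down dataset
    genes <- unique(c(L$finals_distinct, L$treg_receptor, L$fox_receptors,
                      L$panel, utils::head(L$background, 200)))
    altered <- utils::head(L$finals_distinct, spec$modulation$altered)
    up <- c(utils::head(altered, spec$modulation$up), L$fox_receptors)
    down <- setdiff(altered, up)
    df <- draw_de(genes, down, up,
                  c(L$finals_distinct, L$panel, L$fox_receptors),
                  alpha, lfc_sd)
    meta <- list(target = spec$modulation$dataset_id,
                 comparison = "knock-down vs control")
  }
  df <- df[sample.int(nrow(df)), , drop = FALSE]
  rownames(df) <- NULL
  de_table(dataset_id, meta$target, "human", df, comparison = meta$comparison)
}

#' Generate the interaction network, APC marker sets and tolerogenic data
#'
#' Builds the receptor-partner interaction table with the planted per-branch
#' partner counts, the four APC marker sets, and the tolerogenic contrast
#' datasets, such that the planted final ligands pass exactly the planned
#' triage rounds and the planned cross-receptor duplicates are shared
#' verbatim.
#'
#' @param spec A [fixture_spec()].
#' @param seed Integer seed.
#' @return List: `interactions` ([interaction_table()]), `apc_markers`
#'   (named list of `gene_set`s), `tolerogenic` (list of [de_table()]s).
#' @export
simulate_interactions <- function(spec, seed = 1L) {
  if (!inherits(spec, "fixture_spec")) spec <- fixture_spec(spec)
  L <- fixture_layout(spec)
  pairs <- rbind(
    data.frame(receptor = L$treg_receptor,
               partner = c(L$treg_finals, L$treg_mem_extra, L$treg_nonmem),
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(L$fox_receptors, function(r) {
      data.frame(receptor = r,
                 partner = c(L$fox_finals[[r]], L$fox_mem_share[[r]],
                             L$fox_nonmem_share[[r]]),
                 stringsAsFactors = FALSE)
    }))
  )
  uni <- simulate_universe(spec, seed)
  tol <- lapply(spec$tolerogenic_ids, function(id) {
    simulate_de_dataset(spec, id, seed)
  })
  list(interactions = interaction_table(pairs$receptor, pairs$partner,
                                        source = "synthetic"),
       apc_markers = uni$apc_markers,
       tolerogenic = tol)
}

#' Generate a labeled cell-by-gene expression matrix
#'
#' Small single-cell-style matrix over five T-cell subsets with planted
#' per-type mean expression for the reference and finalist checkpoint genes:
#' mitotic T cells carry the highest mean for every gene except CD38, and
#' the planted CD8/CD4 contrasts differ in sign across genes. Values are
#' Gaussian around the planted means, truncated at zero.
#'
#' @param spec A [fixture_spec()].
#' @param seed Integer seed.
#' @return List: `matrix` (cells x genes), `labels` (cell types), `means`
#'   (the planted type x gene means).
#' @export
simulate_celltype_matrix <- function(spec, seed = 1L) {
  if (!inherits(spec, "fixture_spec")) spec <- fixture_spec(spec)
  set.seed(derive_seed(seed, 900L))
  types <- c("CD4_T", "CD8_T", "mitotic_T", "tissue_T", "Treg")
  genes <- c("CTLA4", "KLRG1", "LAG3", "PDCD1", "TIGIT",
             spec$finalists$treg, spec$finalists$foxp3)
  means <- rbind(
    CTLA4   = c(3.0, 4.5, 9.0, 4.0, 6.5),
    KLRG1   = c(4.0, 3.0, 9.0, 3.5, 6.0),
    LAG3    = c(3.0, 2.5, 8.0, 3.0, 4.0),
    PDCD1   = c(3.0, 5.0, 9.5, 4.0, 5.5),
    TIGIT   = c(2.5, 4.0, 8.5, 3.5, 6.0)
  )
  new_means <- rbind(
    c(2.0, 3.0, 7.5, 2.5, 3.0),   # Treg-branch finalist
    c(3.5, 2.0, 4.0, 3.0, 4.5),   # CD38-like: peak outside mitotic, ratio < 1
    c(2.0, 3.0, 8.0, 3.0, 6.0),
    c(3.5, 2.5, 7.0, 3.0, 4.0),
    c(2.0, 3.5, 8.5, 2.5, 3.0),
    c(3.0, 2.0, 6.5, 2.5, 3.5),
    c(2.0, 2.5, 7.0, 2.0, 3.0)
  )
  n_new <- length(genes) - 5L
  means <- rbind(means, new_means[seq_len(n_new), , drop = FALSE])
  rownames(means) <- genes
  colnames(means) <- types

  per <- spec$celltype$cells_per_type
  labels <- rep(types, each = per)
  m <- do.call(rbind, lapply(labels, function(ty) {
    pmax(0, stats::rnorm(length(genes), means[, ty], spec$celltype$noise_sd))
  }))
  colnames(m) <- genes
  rownames(m) <- sprintf("cell%04d", seq_len(nrow(m)))
  list(matrix = m, labels = labels, means = t(means))
}

#' Generate the complete fixture
#'
#' Bundles every input the end-to-end screen needs, generated from one spec
#' and one seed.
#'
#' @param spec A [fixture_spec()]; default the packaged reference spec.
#' @param seed Integer seed.
#' @return List with `gene_sets`, `ko_datasets` (named list of
#'   [de_table()]s), `hierarchy_ids` (the one-per-target dataset ids used
#'   for hierarchy scoring), `interactions`, `apc_markers`, `tolerogenic`,
#'   `modulation` (named list), `celltype`, `config` (a [screen_config()]
#'   with the spec's alpha), and `truth` (the planted counts, for tests).
#' @export
simulate_fixture <- function(spec = reference_fixture_spec(), seed = 1L) {
  if (!inherits(spec, "fixture_spec")) spec <- fixture_spec(spec)
  L <- fixture_layout(spec)
  P <- fixture_plan(spec, L)
  uni <- simulate_universe(spec, seed)
  ko <- stats::setNames(lapply(P$ids, simulate_de_dataset, spec = spec,
                               seed = seed), P$ids)
  net <- simulate_interactions(spec, seed)
  mod <- stats::setNames(
    list(simulate_de_dataset(spec, spec$modulation$dataset_id, seed)),
    spec$modulation$dataset_id)
  list(
    gene_sets = uni[c("membrane", "foxp3_up", "treg_specific", "known_ics",
                      "reference_panel")],
    ko_datasets = ko,
    hierarchy_ids = P$hierarchy_ids,
    interactions = net$interactions,
    apc_markers = net$apc_markers,
    tolerogenic = net$tolerogenic,
    modulation = mod,
    celltype = simulate_celltype_matrix(spec, seed),
    config = screen_config(alpha = spec$alpha, seed = seed),
    truth = list(finalists = P$finalists, survivors = P$survivors,
                 high_targets = P$high_targets,
                 finals_distinct = L$finals_distinct,
                 background = L$background)
  )
}

#' Write a simulated fixture to plain-text input files
#'
#' Emits the fixture in the package's interchange formats: a GMT with the
#' gene-set collection, the APC marker GMT, TSV+JSON differential tables,
#' and the two-column interaction TSV. Useful for byte-level determinism
#' checks and for driving the pipeline from files.
#'
#' @param fixture Result of [simulate_fixture()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gmt(fixture$gene_sets, file.path(dir, "gene_sets.gmt"))
  write_gmt(fixture$apc_markers, file.path(dir, "apc_markers.gmt"))
  for (d in c(fixture$ko_datasets, fixture$tolerogenic, fixture$modulation)) {
    write_de_table(d, file.path(dir, paste0(d$dataset_id, ".tsv")))
  }
  it <- fixture$interactions
  utils::write.table(it, file.path(dir, "interactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
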