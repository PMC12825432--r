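cfg <- screen_config()

test_that("membrane filter is the intersection and commutes with the APC filter", {
  set.seed(21)
  pool <- rand_symbols(120)
  partners <- gene_set(sample(pool, 60), "partners(X)")
  membrane <- gene_set(sample(pool, 70), "mem")
  markers <- list(B_cell = gene_set(sample(pool, 50), "b"),
                  dendritic_cell = gene_set(sample(pool, 30), "dc"))
  mem_first <- filter_apc(filter_membrane(partners, membrane), markers)
  apc_first <- filter_apc(partners, markers)
  apc_then_mem <- apc_first[apc_first$gene %in% membrane$members, ]
  expect_setequal(unique(mem_first$gene), unique(apc_then_mem$gene))
  expect_setequal(filter_membrane(partners, membrane)$members,
                  naive_intersect(partners$members, membrane$members))
  # partners already on the membrane: identity
  sub <- gene_set(membrane$members[1:5], "sub")
  expect_equal(filter_membrane(sub, membrane)$members, sub$members)
})

test_that("APC attribution is non-exclusive and matches per-set membership", {
  markers <- list(B_cell = gene_set(c("L1", "L2"), "b"),
                  dendritic_cell = gene_set(c("L2", "L3"), "dc"))
  att <- filter_apc(gene_set(c("L1", "L2", "L3", "L4"), "cand"), markers)
  expect_equal(sort(att$apc_type[att$gene == "L2"]),
               c("B_cell", "dendritic_cell"))
  expect_false("L4" %in% att$gene)
  expect_equal(nrow(att), 4L)  # attribution rows, not distinct genes
  # naive recount per marker set
  for (ty in names(markers)) {
    expect_setequal(att$gene[att$apc_type == ty],
                    naive_intersect(c("L1", "L2", "L3", "L4"),
                                    markers[[ty]]$members))
  }
  expect_error(filter_apc(gene_set("L1", "x"), list()), "no APC")
  expect_error(filter_apc(gene_set("L1", "x"),
                          list(gene_set("L1", "u"))), "named")
})

test_that("tolerogenic filter requires an up-call in a listed dataset", {
  att <- data.frame(gene = c("L1", "L2", "L3"),
                    apc_type = "B_cell", stringsAsFactors = FALSE)
  m2 <- mk_de(c("L1", "L2", "L3"), c(2, -2, 2), c(0.001, 0.001, 0.5),
              id = "M2", target = "M2")
  out <- filter_tolerogenic(att, list(m2), cfg)
  expect_equal(out$gene, "L1")          # L2 down, L3 not significant
  expect_equal(out$support, "M2")
  # gene upregulated only in a dataset not supplied as tolerogenic: fails
  out0 <- filter_tolerogenic(att[att$gene == "L3", , drop = FALSE],
                             list(m2), cfg)
  expect_equal(nrow(out0), 0L)
  expect_error(filter_tolerogenic(data.frame(x = 1), list(m2), cfg),
               "columns")
})

test_that("tolerogenic pass set equals a naive per-gene scan on random fixtures", {
  set.seed(31)
  genes <- rand_symbols(40, "L")
  att <- data.frame(gene = genes, apc_type = "B_cell",
                    stringsAsFactors = FALSE)
  ds <- lapply(1:3, function(j) {
    meas <- sample(genes, 30)
    mk_de(meas, rnorm(30), runif(30), id = sprintf("TOL%d", j), target = "X1")
  })
  out <- filter_tolerogenic(att, ds, cfg)
  expected <- character(0)
  for (g in genes) {
    hit <- FALSE
    for (d in ds) {
      k <- which(d$data$gene == g)
      if (length(k) && d$data$pvalue[k] < 0.05 && d$data$log2fc[k] > 0) {
        hit <- TRUE
      }
    }
    if (hit) expected <- c(expected, g)
  }
  expect_setequal(out$gene, expected)
})

test_that("dedup_union merges receptors and reports the reconciliation", {
  rec <- function(genes) data.frame(gene = genes, apc_types = "B_cell",
                                    support = "M2", stringsAsFactors = FALSE)
  disjoint <- dedup_union(list(R1 = rec(c("L1", "L2")), R2 = rec("L3")))
  expect_equal(nrow(disjoint), 3L)
  expect_equal(attr(disjoint, "triage_counts")$n_shared, 0L)

  shared <- dedup_union(list(R1 = rec(c("L1", "L2")),
                             R2 = rec(c("L2", "L3")),
                             R3 = rec("R3")))
  expect_equal(nrow(shared), 4L)
  tc <- attr(shared, "triage_counts")
  expect_equal(tc$n_memberships, 5L)
  expect_equal(tc$n_shared, 1L)
  expect_equal(shared$receptors[shared$ligand == "L2"], "R1,R2")
  expect_true(shared$self_partner[shared$ligand == "R3"])

  # union equals the naive symbol-set union on random per-receptor lists
  set.seed(41)
  lists <- lapply(1:5, function(i) rec(sample(rand_symbols(30, "L"), 10)))
  names(lists) <- sprintf("R%d", 1:5)
  u <- dedup_union(lists)
  expect_setequal(u$ligand,
                  unique(unlist(lapply(lists, `[[`, "gene"))))
})

test_that("every triaged ligand carries receptor, APC type and support; dropping a dataset shrinks the set", {
  pc <- ref_cache()
  lig <- pc$run$ligands
  expect_true(all(nzchar(lig$receptors)))
  expect_true(all(nzchar(lig$apc_types)))
  expect_true(all(nzchar(lig$support)))
  expect_true(any(lig$self_partner))  # the planted homodimer

  # removing a tolerogenic dataset can only shrink the final set
  fewer <- triage_ligands(pc$run$finalists, pc$fix$interactions,
                          pc$fix$gene_sets$membrane, pc$fix$apc_markers,
                          pc$fix$tolerogenic[-2], pc$fix$config)
  expect_true(all(fewer$ligand %in% lig$ligand))
  expect_true(nrow(fewer) <= nrow(lig))
})
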