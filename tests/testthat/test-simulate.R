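test_that("the packaged fixture plants the exact universe structure", {
  pc <- ref_cache()
  gs <- pc$fix$gene_sets
  expect_equal(length(gs$membrane), 2202L)
  expect_equal(length(gs$foxp3_up), 1004L)
  expect_equal(length(gs$treg_specific), 431L)
  expect_equal(length(gs_intersect(gs$membrane, gs$foxp3_up)), 173L)
  expect_equal(length(gs_intersect(gs$membrane, gs$treg_specific)), 50L)
  expect_equal(length(gs$reference_panel), 25L)
})

test_that("planted down-calls are recovered exactly and strictly significant", {
  pc <- ref_cache()
  d <- pc$fix$ko_datasets$TIGIT_KO_1
  cands <- unique(pc$run$candidates$gene)
  idx <- match(cands, d$data$gene)
  down <- call_down(d$data$log2fc[idx], d$data$pvalue[idx], pc$fix$config)
  expect_equal(sum(down), 41L)
  planted <- d$data[down[match(d$data$gene, cands)] %in% TRUE, ]
  expect_true(all(planted$pvalue < 0.05))
  expect_true(all(planted$pvalue > 0))
  expect_true(all(planted$log2fc < 0))
})

test_that("background genes behave as the exchangeable null", {
  pc <- ref_cache()
  bg <- pc$fix$truth$background
  # pool the false-significance calls over several knockout datasets
  n <- 0L; hits <- 0L
  for (id in c("CTLA4_KO_2", "PDCD1_KO_2", "TIGIT_KO_2")) {
    d <- pc$fix$ko_datasets[[id]]$data
    rows <- d[d$gene %in% bg, ]
    n <- n + nrow(rows)
    hits <- hits + sum(rows$pvalue < 0.05)
  }
  expect_gt(n, 1000)
  # binomial tolerance: 4 sd around alpha * n
  expect_lt(abs(hits - 0.05 * n), 4 * sqrt(n * 0.05 * 0.95))
})

test_that("generation is a pure function of (spec, seed), byte for byte", {
  spec <- reference_fixture_spec()
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  write_fixture(simulate_fixture(spec, seed = 7), d1)
  write_fixture(simulate_fixture(spec, seed = 7), d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # a different seed changes the numeric noise
  d3 <- simulate_de_dataset(spec, "TIGIT_KO_1", seed = 8)
  d7 <- simulate_de_dataset(spec, "TIGIT_KO_1", seed = 7)
  expect_false(identical(d3$data, d7$data))
})

test_that("the spec is adjustable and planted sizes follow it", {
  spec <- reference_fixture_spec(universe = list(overlap_foxp3 = 120),
                             survivors = list(foxp3 = 40))
  uni <- simulate_universe(spec)
  expect_equal(length(gs_intersect(uni$membrane, uni$foxp3_up)), 120L)
  fix <- simulate_fixture(spec, seed = 3)
  run <- run_screen(fix, config = fix$config)
  expect_equal(run$report$round1$foxp3, 120L - 67L)
  expect_equal(run$report$round2$total, 18L + 40L)
  expect_equal(run$report$round3$total, 7L)
})

test_that("infeasible specs are rejected naming the violated constraint", {
  expect_error(reference_fixture_spec(universe = list(overlap_foxp3 = 3000)),
               "overlap_foxp3")
  expect_error(reference_fixture_spec(universe = list(excluded_treg = 60)),
               "excluded_treg")
  expect_error(reference_fixture_spec(survivors = list(treg = 200)),
               "survivors")
  expect_error(reference_fixture_spec(ligands = list(cross_branch_shared = 12)),
               "cross_branch_shared")
  expect_error(simulate_de_dataset(reference_fixture_spec(), "NOPE_KO_1"),
               "unknown dataset_id")
})

test_that("the cell-type matrix recovers the planted expression patterns", {
  pc <- ref_cache()
  ct <- pc$fix$celltype
  s <- celltype_means(ct$matrix, ct$labels)
  # mitotic T cells carry the top mean for every gene except the CD38-like one
  expect_equal(unname(s$argmax_type["CTLA4"]), "mitotic_T")
  expect_equal(unname(s$argmax_type["CEP55"]), "mitotic_T")
  expect_false(s$argmax_type["CD38"] == "mitotic_T")
  # planted CD8/CD4 contrasts keep their direction
  expect_gt(s$ratio[["CTLA4"]], 1)
  expect_lt(s$ratio[["KLRG1"]], 1)
  expect_lt(s$ratio[["CD38"]], 1)
})
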