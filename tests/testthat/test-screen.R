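cfg <- screen_config()

test_that("down- and up-calls use strict inequalities", {
  expect_true(call_down(-1.2, 0.01, cfg))
  expect_false(call_down(-1.2, 0.05, cfg))   # p == alpha is not significant
  expect_false(call_down(0, 0.001, cfg))     # zero fold-change is not down
  expect_false(call_down(0.3, 0.001, cfg))
  expect_true(call_up(1.2, 0.01, cfg))
  expect_false(call_up(1.2, 0.05, cfg))
  expect_false(call_up(0, 0.001, cfg))
  expect_error(call_down(NaN, 0.01, cfg), "non-finite")
  expect_error(call_down(-1, NA, cfg), "pvalue")
})

test_that("candidate construction matches brute-force set comprehension", {
  for (seed in 1:3) {
    set.seed(seed)
    pool <- rand_symbols(100)
    mem <- sample(pool, 70); fox <- sample(pool, 40)
    treg <- sample(pool, 30); known <- sample(pool, 10)
    cand <- build_candidates(gene_set(mem, "m"), gene_set(fox, "f"),
                             gene_set(treg, "t"), gene_set(known, "k"))
    exp_fox <- naive_subtract(naive_intersect(mem, fox), known)
    exp_treg <- naive_subtract(naive_intersect(mem, treg), known)
    expect_setequal(cand$gene[cand$branch == "FOXP3_UP"], exp_fox)
    expect_setequal(cand$gene[cand$branch == "TREG_SPECIFIC"], exp_treg)
    counts <- attr(cand, "counts")
    expect_equal(counts$foxp3$removed,
                 length(naive_intersect(mem, fox)) - length(exp_fox))
  }
})

test_that("empty exclusion list leaves raw intersections; empty universe rejected", {
  mem <- gene_set(c("A1", "A2", "A3"), "m")
  fox <- gene_set(c("A1", "A2"), "f")
  treg <- gene_set("A3", "t")
  none <- gene_set(character(0), "k")
  cand <- build_candidates(mem, fox, treg, none)
  expect_equal(sum(cand$branch == "FOXP3_UP"), 2L)
  expect_equal(sum(cand$branch == "TREG_SPECIFIC"), 1L)
  expect_error(build_candidates(gene_set(character(0), "m"), fox, treg, none),
               "empty membrane")
})

test_that("down-call matrix equals a naive per-cell recount", {
  inst <- rand_instance(11, n_genes = 20, n_ds = 4)
  m <- build_downcall_matrix(inst$candidates, inst$datasets, cfg)
  ref <- naive_matrix(unique(inst$candidates$gene), inst$datasets)
  expect_identical(unclass(m)[rownames(ref), colnames(ref)], ref)
})

test_that("all-null datasets yield no down-calls; absent genes are NOT_MEASURED", {
  cand <- build_candidates(gene_set(c("A1", "A2"), "m"),
                           gene_set(c("A1", "A2"), "f"),
                           gene_set(character(0), "t"),
                           gene_set(character(0), "k"))
  d <- mk_de("A1", -3, 1)  # p = 1: measured but never significant
  m <- build_downcall_matrix(cand, list(d), cfg)
  expect_equal(unname(unclass(m)["A1", 1]), "NOT_DOWN")
  expect_equal(unname(unclass(m)["A2", 1]), "NOT_MEASURED")
  expect_warning(
    build_downcall_matrix(cand, list(mk_de("ZZ9", -3, 0.001, id = "D2")), cfg),
    "no genes")
  s <- downcall_summary(m)
  expect_equal(s$n_down, 0L)
  expect_equal(s$n_measured, 1L)
})

test_that("round-2 survivors equal the naive any-over-row scan", {
  for (seed in 4:6) {
    inst <- rand_instance(seed, n_genes = 40, n_ds = 8)
    m <- build_downcall_matrix(inst$candidates, inst$datasets, cfg)
    cand <- round2_filter(m, inst$candidates)
    expect_setequal(unique(cand$gene[cand$round2_pass]),
                    naive_round2(unclass(m)))
  }
  # all-NOT_DOWN matrix: zero survivors
  cand0 <- build_candidates(gene_set("A1", "m"), gene_set("A1", "f"),
                            gene_set(character(0), "t"),
                            gene_set(character(0), "k"))
  m0 <- build_downcall_matrix(cand0, list(mk_de("A1", -1, 0.9)), cfg)
  expect_equal(sum(round2_filter(m0, cand0)$round2_pass), 0L)
})

test_that("k-of-n stringency enumerates all 2^5 target-support patterns correctly", {
  targets <- sprintf("HT%d", 1:5)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), 5))
  genes <- sprintf("P%02d", seq_len(nrow(patterns)))
  datasets <- lapply(1:5, function(j) {
    down_genes <- genes[patterns[[j]]]
    mk_de(genes, ifelse(genes %in% down_genes, -1, 1), 0.001,
          id = sprintf("HD%d", j), target = targets[j])
  })
  cand <- build_candidates(gene_set(genes, "m"), gene_set(genes, "f"),
                           gene_set(character(0), "t"),
                           gene_set(character(0), "k"))
  m <- build_downcall_matrix(cand, datasets, cfg)
  cand <- round2_filter(m, cand)
  cand <- round3_filter(m, targets, cand, cfg)
  expected <- rowSums(patterns) >= 3
  expect_equal(cand$round3_pass, unname(expected))
  # k = 3 boundary: exactly 2 supporting targets fails
  expect_false(cand$round3_pass[which(rowSums(patterns) == 2)[1]])
  expect_true(cand$round3_pass[which(rowSums(patterns) == 3)[1]])
})

test_that("target counting collapses multiple datasets of one knockout", {
  genes <- c("G1", "G2")
  # G1 down in three datasets all perturbing T1; G2 down once in each of T1..T3
  d <- list(
    mk_de(genes, c(-1, -1), 0.01, "A1", "T1"),
    mk_de(genes, c(-1, 1), 0.01, "A2", "T1"),
    mk_de(genes, c(-1, -1), 0.01, "A3", "T2"),
    mk_de(genes, c(1, -1), 0.01, "A4", "T3")
  )
  cand <- build_candidates(gene_set(genes, "m"), gene_set(genes, "f"),
                           gene_set(character(0), "t"),
                           gene_set(character(0), "k"))
  m <- build_downcall_matrix(cand, d, cfg)
  cand <- round2_filter(m, cand)
  cfg3 <- screen_config(stringency_k = 3, stringency_n = 3)
  by_target <- round3_filter(m, c("T1", "T2", "T3"), cand, cfg3)
  expect_equal(by_target$round3_pass, c(FALSE, TRUE))  # G1: 2 targets; G2: 3
  by_ds <- round3_filter(m, c("T1", "T2", "T3"), cand, cfg3,
                         count_by = "dataset")
  expect_equal(by_ds$round3_pass, c(TRUE, TRUE))       # G1: 3 datasets
  expect_error(round3_filter(m, c("T1", "T2"), cand, cfg3), "stringency_n")
  expect_silent(round3_filter(m, c("T1", "T2"), cand, cfg3,
                              allow_n_mismatch = TRUE))
})

test_that("round filters nest monotonically and respond monotonically to thresholds", {
  for (seed in 7:9) {
    inst <- rand_instance(seed, n_genes = 50, n_ds = 16, n_targets = 5)
    m <- build_downcall_matrix(inst$candidates, inst$datasets, cfg)
    cand <- round2_filter(m, inst$candidates)
    cand <- round3_filter(m, inst$targets, cand, cfg)
    r1 <- cand$gene
    r2 <- cand$gene[cand$round2_pass]
    r3 <- cand$gene[cand$round3_pass]
    expect_true(all(r3 %in% r2))
    expect_true(all(r2 %in% r1))

    # raising alpha never shrinks the DOWN set
    m_hi <- build_downcall_matrix(inst$candidates, inst$datasets,
                                  screen_config(alpha = 0.2))
    expect_true(all(which(unclass(m) == "DOWN") %in%
                      which(unclass(m_hi) == "DOWN")))

    # lowering k never shrinks the finalist set
    cand_k2 <- round3_filter(m, inst$targets, round2_filter(m, inst$candidates),
                             screen_config(stringency_k = 2,
                                           stringency_n = 5))
    expect_true(all(r3 %in% cand_k2$gene[cand_k2$round3_pass]))
  }
})
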