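cfg <- screen_config()

# 25-member reference panel and a knockout dataset with a planted number of
# panel genes down-called
panel25 <- gene_set(sprintf("IC%02d", 1:25), "panel")
ko_with_down <- function(n_down, target = "IC01", id = "KO1",
                         include_self_down = FALSE) {
  others <- setdiff(panel25$members, target)
  down <- others[seq_len(n_down)]
  genes <- c(panel25$members)
  lfc <- ifelse(genes %in% down, -2, 1)
  if (include_self_down) lfc[genes == target] <- -3
  mk_de(genes, lfc, 0.001, id = id, target = target)
}

test_that("hierarchy scores are panel fractions with self-exclusion", {
  h6 <- hierarchy_score(ko_with_down(6), panel25, cfg)
  expect_equal(h6$score_percent, 24)
  expect_equal(h6$n_reference, 25L)
  expect_equal(h6$class, "HIGH")
  expect_equal(hierarchy_score(ko_with_down(8), panel25, cfg)$score_percent, 32)
  expect_equal(hierarchy_score(ko_with_down(7), panel25, cfg)$score_percent, 28)

  h0 <- hierarchy_score(ko_with_down(0), panel25, cfg)
  expect_equal(h0$score_percent, 0)
  expect_equal(h0$class, "LOW")

  # the knocked-out gene's own collapse does not count toward its score
  self_dn <- hierarchy_score(ko_with_down(6, include_self_down = TRUE),
                             panel25, cfg)
  expect_equal(self_dn$n_reference_down, 6L)
})

test_that("the 20% hierarchy boundary is strict", {
  h5 <- hierarchy_score(ko_with_down(5), panel25, cfg)  # exactly 0.20
  expect_equal(h5$score_fraction, 0.20)
  expect_equal(h5$class, "LOW")
  expect_equal(hierarchy_score(ko_with_down(6), panel25, cfg)$class, "HIGH")
  expect_error(hierarchy_score(ko_with_down(5),
                               gene_set(character(0), "e"), cfg),
               "empty reference panel")
})

test_that("scores are invariant to panel ordering and dataset row ordering", {
  d <- ko_with_down(7)
  set.seed(3)
  shuf <- de_table("KO1", d$perturbed_target, "human",
                   d$data[sample.int(nrow(d$data)), ])
  panel_shuf <- gene_set(sample(panel25$members), "panel")
  expect_equal(hierarchy_score(shuf, panel_shuf, cfg)$score_percent,
               hierarchy_score(d, panel25, cfg)$score_percent)
})

test_that("target classification aggregates datasets per knockout gene", {
  reports <- hierarchy_report(
    list(ko_with_down(6, target = "IC01", id = "A1"),
         ko_with_down(3, target = "IC01", id = "A2"),   # 12%, same target
         ko_with_down(4, target = "IC02", id = "B1")),
    panel25, cfg)
  for (mode in c("any", "max")) {
    cls <- classify_targets(reports, mode, cfg)
    expect_equal(cls$high, "IC01")   # 24% and 12% -> HIGH under any/max
    expect_equal(cls$low, "IC02")
  }
})

test_that("five planted high and five low knockouts partition 5/5", {
  downs <- c(6, 8, 8, 7, 8, 5, 4, 2, 3, 1)
  targets <- sprintf("IC%02d", 1:10)
  reports <- hierarchy_report(
    mapply(ko_with_down, downs, targets, sprintf("KO%02d", 1:10),
           SIMPLIFY = FALSE),
    panel25, cfg)
  cls <- classify_targets(reports, "any", cfg)
  expect_setequal(cls$high, targets[1:5])
  expect_setequal(cls$low, targets[6:10])
  expect_equal(sort(reports$score_percent[match(targets[1:5],
                                                reports$perturbed_target)]),
               c(24, 28, 32, 32, 32))
})
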