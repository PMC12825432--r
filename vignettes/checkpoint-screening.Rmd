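---
title: "Multi-round screening for inhibitory immune checkpoints and their ligands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-round screening for inhibitory immune checkpoints and their ligands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icscreen)
```

## The screening model

CD4⁺FoxP3⁺ regulatory T cells (Tregs) suppress immune responses partly
through inhibitory immune checkpoint (IC) receptors such as PD-1 and CTLA-4.
Beyond the well-characterized checkpoints, many Treg plasma-membrane proteins
are plausible but unconfirmed inhibitory receptors. `icscreen` implements a
discovery procedure that nominates such candidates purely from tabular
transcriptomic evidence, in three rounds, followed by a three-round triage of
their candidate ligands on antigen-presenting cells (APCs).

**Round 1 — candidate generation.** Two discovery branches are intersected
with a plasma-membrane protein universe: a *Treg-specific* gene signature and
a *FoxP3-upregulated* signature. Known checkpoint receptors are then
excluded from each branch. Because the same exclusion list can hit the two
branches a different number of times, the package reports removal counts per
branch rather than assuming a single removal total.

**Round 2 — knockout down-call screening.** The premise is that inhibitory
checkpoints form co-regulated modules: knocking out (or blocking) an
established inhibitory checkpoint tends to *down*-regulate other members of
the module. For every candidate and every knockout dataset the package
records a three-valued cell: `DOWN` when the gene is measured with
`p < alpha` and `log2FC < 0` (both strict), `NOT_DOWN` when measured but not
called, and `NOT_MEASURED` when absent. A candidate survives round 2 if it
is down-called in at least one dataset of the panel.

**Hierarchy classification.** Not all knockouts are equally informative. A
knockout target is *high-hierarchy* when its dataset down-calls strictly
more than a threshold fraction (default 20%) of a reference panel of
well-established inhibitory checkpoints (default panel size 25). The
perturbed gene is excluded from its own numerator — the question is its
effect on *other* checkpoints — while the denominator stays the full panel
size, so six of twenty-five panel genes down gives 24%. Exactly 20% is LOW:
the threshold is a strict inequality.

**Round 3 — k-of-n stringency.** Among round-2 survivors, a candidate is a
finalist when it is down-called under at least *k* of the *n*
high-hierarchy knockout **targets** (defaults 3 of 5). Counting distinct
targets rather than datasets matters because several targets contribute
multiple datasets: a candidate down in three datasets that all perturb the
same gene has one independent line of evidence, not three. A per-dataset
counting mode (`count_by = "dataset"`) is provided for sensitivity analysis.

**Ligand triage.** Each finalist receptor's experimentally reported
interaction partners are filtered through three rounds: (a) presence in the
plasma-membrane universe; (b) presence in at least one of four APC marker
sets (macrophages, monocytes, B cells, dendritic cells), with
*non-exclusive* attribution — a gene may match several APC types; (c)
up-regulation (`p < alpha`, `log2FC > 0`, strict) in at least one dataset
contrasting a tolerogenic/anti-inflammatory APC subset with its control.
Per-receptor survivor lists are then merged; a ligand serving several
receptors appears once, and the reconciliation (memberships vs distinct
ligands vs shared memberships) is always reported. Receptors listing
themselves as partners (potential homodimers) are retained and flagged.

## Conventions and parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | significance threshold, strict `p < alpha` |
| `lfc_down` / `lfc_up` | 0 / 0 | log2FC cutoffs, strict; no magnitude requirement |
| `hierarchy_threshold` | 0.20 | high-hierarchy rule, strict `>` on the unrounded fraction |
| `stringency_k`, `stringency_n` | 3, 5 | k-of-n high-hierarchy support |
| `percent_decimals` | 1 | display rounding only |

Numerical conventions worth stating explicitly:

* **Strict boundaries everywhere.** `p == alpha`, `log2FC == 0`, a hierarchy
  fraction of exactly 0.20, and support of `k - 1` targets all fail their
  respective rules. The tests pin each boundary.
* **Absence is not evidence.** A gene missing from a dataset is
  `NOT_MEASURED`; it can never satisfy a down- or up-call, stays in every
  denominator, and candidates unmeasured across all high-hierarchy datasets
  are flagged in the run report instead of silently failing.
* **Display rounding is half-away-from-zero** at `percent_decimals`, and
  classification always uses unrounded fractions. Published tables in this
  literature mix rounding and truncation: 16/151 is 10.6% under
  half-away-from-zero but 10.5% truncated, and 9/151 is 6.0% vs 5.9%. Rather
  than reproducing any one convention silently, `run_screen()` logs a
  machine-readable warning for every percentage whose display depends on the
  convention.
* **Duplicate rows** in a differential table are an error by default;
  `duplicates = "min_p"` opts into keeping the most significant row. Silent
  merging hides upstream data faults.
* **Cross-species matching** is an explicit `ortholog_map`; the default
  behaviour is identity-after-uppercasing, which is what symbol
  normalization already provides for most mouse/human pairs. No alias or
  HGNC resolution is attempted.
* **Ligand dedup reconciliation.** Per-receptor retained lists legitimately
  sum to more than the distinct union when ligands serve several receptors.
  `dedup_union()` reports memberships, distinct count and shared
  memberships; on the packaged fixture these are 57, 46 and 11 (4 of the 11
  shared across the two discovery branches).
* **APC screen counting.** `filter_apc()` returns one row per (gene,
  APC type) attribution. Branch-level counts of this long table can
  *exceed* the distinct-gene count of the preceding membrane filter — on the
  packaged fixture the Treg branch goes 274 partners → 39 membrane genes →
  41 attribution rows. Distinct genes are always available via
  `unique(result$gene)`.

## The synthetic-data generator

Real inputs of this kind come from curated proteome/transcriptome resources
and public perturbation datasets that cannot be bundled. The generator
(`simulate_fixture()` and friends) emulates exactly the statistical
structure the screen consumes, from a versioned spec
(`inst/extdata/reference_fixture.yaml`):

* gene universes and annotation sets with exact planted intersection and
  exclusion sizes;
* knockout tables in which planted down-calls hold strictly by construction,
  plan-controlled genes that are not planted are guaranteed quiet
  (`p >= alpha`), and background genes follow the simplest exchangeable
  null — `p` uniform on [0, 1], log2FC normal with caller-set spread;
* an interaction network whose per-branch partner counts, membrane and APC
  survivors, tolerogenic support and cross-receptor sharing follow the plan;
* a small labeled cell-by-gene matrix with planted per-type means.

Membership layout is a pure function of the spec; the seed drives only the
numeric noise and row order, so equal (spec, seed) pairs produce
byte-identical files, and the planted counts are invariant across seeds.
The packaged spec plants the full funnel 151 → 85 → 7 candidates and
274 → 39 / 208 → 46 ligands, so every count is a regression surface
recovered by running the pipeline, not a hard-coded assertion.

Where the fixture had genuinely open choices, the shipped values are: 16
knockout datasets over 10 targets (3 each for three of the high-hierarchy
targets), hierarchy scored on the one-per-target datasets; 600 background
genes per table with log2FC spread 1.0; four tolerogenic contrasts with all
planted ligands supported by the B-cell-like contrast and doubly-attributed
ligands additionally by the dendritic-cell one; APC marker sets of a few
hundred genes each (large enough to carry the planted overlaps, small
enough to keep the whole fixture generating in well under a second); and
per-receptor partner counts on the FoxP3 branch derived by splitting the
branch total evenly, since only branch totals are pinned. These sizes keep
the complete test suite in a few seconds on one CPU.

What the generator does **not** emulate: realistic expression magnitudes,
library sizes, count distributions, gene-gene correlation, or any upstream
single-cell processing (clustering, embedding). Passing tests therefore
demonstrate that the screening logic is correct and calibrated on its
stated conventions — not that the biological discoveries would replicate on
re-curated public data.

## A worked run

```{r run}
fixture <- simulate_fixture(reference_fixture_spec(), seed = 42)
run <- run_screen(fixture, config = fixture$config)
run
```

```{r details}
run$downcall_summary[, c("dataset_id", "perturbed_target", "n_down", "display")]
run$hierarchy[, c("dataset_id", "perturbed_target", "score_percent", "class")]
head(run$ligands)
run$modulation[["PDL1_KD"]]
```

`write_run_report(run, dir)` persists the candidate table, down-call matrix
and ligand table as TSV plus a JSON report whose counts are recomputed from
those tables; re-running with identical inputs is bit-identical.

## Design choices on genuinely open points

* The exclusion arithmetic of round 1 does not determine whether the two
  branches overlap or the exclusion list matches multiply; the package
  exposes per-branch removal counts and the fixture plants a 72-member
  exclusion list (67 FoxP3-branch hits, 5 Treg-branch hits) with disjoint
  branches.
* `classify_targets()` offers `"any"` and `"max"` aggregation over a
  target's datasets; for a strict threshold they coincide, and both are kept
  so reports state the rule explicitly.
* The hierarchy score keeps the full panel size in the denominator under
  self-exclusion (6/25 → 24%), which is the only reading consistent with
  the worked percentages.
* "Significantly altered" in the modulation summary defaults to either
  direction (`direction = "any"`), with `"up"`/`"down"` available; cell-type
  expression summaries use raw matrix units and leave any normalization or
  display threshold to the caller.

## Known limitations

* Round rules are pure threshold counts; no meta-analytic combination of
  p-values across datasets is attempted, by design.
* The screen's conclusions are only as good as the supplied gene sets,
  ortholog map and interaction tables; none are re-derived.
* The generator's null is exchangeable and uncorrelated, so false-call
  calibration checks (`background ≈ alpha`) say nothing about correlated
  real-data backgrounds.
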