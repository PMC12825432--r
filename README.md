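# icscreen

Multi-round transcriptomic screening for novel inhibitory immune
checkpoints (ICs) on regulatory T cells, and for their ligands on
antigen-presenting cells (APCs).

## The problem and the method

CD4⁺FoxP3⁺ regulatory T cells (Tregs) suppress immune responses through
inhibitory checkpoint receptors (PD-1, CTLA-4, TIGIT, ...), but the full set
of Treg membrane proteins acting as checkpoints is unknown. `icscreen`
implements a discovery funnel that nominates candidates from tabular inputs
only — gene sets and differential-expression (DE) tables — in three rounds:

1. **Candidates.** Intersect a plasma-membrane universe *M* with a
   Treg-specific signature *T* and a FoxP3-upregulated signature *F*, then
   remove known checkpoints *K*: the branches are `(M ∩ T) \ K` and
   `(M ∩ F) \ K`.
2. **Knockout screening.** For candidate *g* and knockout dataset *d*, a
   down-call fires iff `p(g,d) < α` and `log2FC(g,d) < 0` (both strict,
   α = 0.05). Candidates down-called in ≥ 1 of the panel's datasets survive.
3. **Hierarchy + stringency.** A knockout target is *high-hierarchy* when
   its dataset down-calls strictly more than 20% of a 25-member reference
   panel of established inhibitory checkpoints (the perturbed gene excluded
   from its own numerator). Finalists are survivors down-called under
   ≥ k of the n high-hierarchy *targets* (default 3 of 5).

Each finalist's interaction partners are then triaged in three further
rounds — plasma-membrane localization, APC-marker membership (macrophage,
monocyte, B-cell, dendritic-cell sets, non-exclusive attribution), and
up-regulation in a tolerogenic APC subset vs control — and merged across
receptors with explicit duplicate accounting.

Because the real inputs are curated public resources that cannot be
bundled, the package ships a seeded synthetic generator
(`simulate_fixture()`) driven by a versioned spec
(`inst/extdata/reference_fixture.yaml`) that plants the complete
structure the screen is expected to recover.

## Worked example

```r
library(icscreen)

fixture <- simulate_fixture(reference_fixture_spec(), seed = 42)
run <- run_screen(fixture, config = fixture$config)
run
#> <ic_screen>
#>   round 1 candidates : 151 (Treg-specific 45, FoxP3-up 106)
#>   round 2 survivors  : 85 (Treg-specific 18, FoxP3-up 67)
#>   high hierarchy     : CTLA4, KLRG1, LAG3, PDCD1, TIGIT
#>   round 3 finalists  : 7 (CEP55, CD38, EHD4, CD200R1, PRC1, RAPH1, CD86)
#>   ligands            : 46 distinct (57 memberships)
#>   warnings           : 4 (see $warnings)
```

The funnel reads: 151 round-1 candidates (45 Treg-specific + 106
FoxP3-upregulated after removing known checkpoints), 85 survive the
knockout screen, and 7 pass the 3-of-5 high-hierarchy stringency rule. The
ligand triage keeps 46 distinct ligands for the 7 receptors; the 57
per-receptor memberships exceed 46 because 11 memberships are ligands
shared between receptors — that reconciliation, and every percentage whose
display depends on the rounding convention, is logged in `run$warnings`
rather than hidden.

```r
head(run$downcall_summary[run$downcall_summary$n_down > 0,
                          c("dataset_id", "perturbed_target", "n_down", "display")])
#>    dataset_id perturbed_target n_down display
#> 1  CTLA4_KO_1            CTLA4      7    4.6%
#> 4  PDCD1_KO_1            PDCD1      7    4.6%
#> 7  TIGIT_KO_1            TIGIT     41   27.2%
#> 10 KLRG1_KO_1            KLRG1     16   10.6%
#> 11  LAG3_KO_1             LAG3      7    4.6%
#> 12  CD47_KO_1             CD47     12    7.9%
```

For example the TIGIT knockout down-calls 41 of the 151 candidates
(27.2%); the hierarchy table (`run$hierarchy`) shows the five targets
scoring 24–32% of the reference panel and therefore classifying HIGH.
`write_run_report(run, dir)` persists all tables (TSV) plus a JSON report
whose counts are recomputed from them.

Individual stages are exposed directly — `build_candidates()`,
`build_downcall_matrix()`, `hierarchy_report()` / `classify_targets()`,
`round2_filter()` / `round3_filter()`, `triage_ligands()`,
`altered_fraction()`, `celltype_means()` — together with readers/writers
for GMT gene sets, TSV DE tables with JSON sidecars, ortholog maps and
interaction tables. See the vignette
(`vignettes/checkpoint-screening.Rmd`) for the model, conventions and
design choices.

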