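# operonscape

Gene-neighborhood (synteny) analysis of prokaryotic gene families.

`operonscape` is for comparative genomicists studying families whose members
fall into phylogenetically defined groups — the motivating case is the
nickel-iron carbon monoxide dehydrogenases ([NiFe]-CODH, clades A–F) and the
hybrid cluster proteins (HCP, classes I–III), where operon content
(maturases, one-carbon-pool enzymes, redox partners, regulators,
transporters) predicts biochemical properties such as maturase dependence
and CO/CO₂ interconversion activity. Given GFF3 genome annotations, a table
of target genes with clade labels, and functional annotations
(eggNOG-mapper / NCBI product strings), the package:

* delineates the **operon** around each target with a chain rule: up to 15
  genes on each side, consecutive-junction intergenic distance ≤ 300 bp,
  overlaps ≤ 50 bp, same strand (all configurable via `operon_params()`);
* assigns each operon member a **functional category** from prioritized,
  user-editable pattern rules over annotation text, with curated
  accession-level overrides (e.g. a manual CooJ list);
* computes assembly-level **isoform counts** and the conditional
  **co-occurrence matrix** `P(X|Y) = N_XY / N_Y`, where `N_Y` is the number
  of assemblies containing ≥ 1 member of label Y and `N_XY` the number
  containing both X and Y — asymmetric whenever marginals differ;
* summarizes **per-clade operon content**: per-target category proportions
  with a strict >10% reporting cutoff, no-neighbor fractions, operon-size
  distributions;
* ships a deterministic **synthetic-genome generator** with exact ground
  truth, so the full pipeline is testable offline.

## Worked example

Simulate 120 assemblies under the default (survey-like) regime, link targets
to their gene records, call operons, classify neighbors, and profile clade A:

```r
library(operonscape)

sim  <- simulate_assemblies(simulation_config(n_assemblies = 120, seed = 7))
link <- link_targets_to_annotations(sim$targets, sim$genes)
#> link_targets_to_annotations: 297 linked, 0 dropped

ops      <- call_all_operons(link$linked, sim$genes)
assigned <- assign_categories(sim$genes, sim$annotations)
sets     <- lapply(ops, categorize_operon, assignments = assigned)

clade_profile(ops, sets, link$linked, "A")
#> <clade_profile> A: 14 targets, 0% without neighbors
#>   one_carbon_pool              100.0%
#>   cooC                          42.9%
#>   fes_protein                   21.4%
```

14 of the 297 linked targets are clade A; every one of them has a
one-carbon-pool gene in its operon, 43% carry the nickel-insertion maturase
CooC, 21% an FeS protein — estimates of the generator's clade-A emission
probabilities (0.93 / 0.62 / 0.31) at n = 14.

```r
codh <- link$linked[link$linked$family == "CODH", ]
conditional_probability(count_by_assembly(codh))
#> <cooccurrence_matrix> P(X|Y), 6 x 6
#>      A    B    C    D    E    F
#> A 1.00 0.00 0.06 0.09 0.08 0.10
#> B 0.00 1.00 0.12 0.06 0.15 0.10
#> C 0.11 0.14 1.00 0.26 0.17 0.19
#> D 0.33 0.14 0.53 1.00 0.31 0.29
#> E 0.44 0.57 0.53 0.47 1.00 0.35
#> F 0.33 0.21 0.35 0.26 0.21 1.00
```

Column Y, row X reads "fraction of Y-containing assemblies that also
contain X": the diagonal is exactly 1, and the matrix is asymmetric —
common clades (E) co-occur in many others' columns while the reverse
probabilities stay low.

The same analysis runs as a composable pipeline over a directory
(`run_pipeline(dir, "all")` or stage by stage: `simulate`, `curate`,
`call_operons`, `classify`, `cooccur`, `profile`), writing documented TSVs
plus a `manifest.json` with the resolved parameters, input digests, seed
and per-stage record counts. A thin CLI wrapper lives at
`inst/exec/operonscape`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the installed package's full pipeline end-to-end on a simulated data
set (300 assemblies, all stages, seeded by `--seed`) and writes the results
JSON to `--out`.
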