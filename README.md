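# pufatyper

Comparative analysis of polyunsaturated fatty acid (PUFA) biosynthesis gene
repertoires in thraustochytrids — marine protists (Labyrinthulomycetes) prized
for producing DHA (C22:6 n-3) and EPA (C20:5 n-3).

Thraustochytrids make long-chain ω3-PUFAs through one or both of two routes:

* the **ELO/DES pathway**, where conventional fatty-acid synthase output
  (C16:0) is extended and desaturated by a chain of elongases (C16, C18, C20,
  Δ9) and desaturases (Δ9A, Δ4, Δ5, Δ6/Δ8, ω3, ω6/Δ9B), each desaturase
  recognisable by three short His-rich "histidine boxes" and the elongases by
  a single `HXXHH` box (`QXXHH` in the C20 group);
* the **PUFA-S pathway**, a polyketide-synthase-like complex of three
  subunits (PfaA, PfaB, PfaC) that builds C20–C22 PUFAs without
  oxygen-dependent desaturation.

From the presence/absence of 24 diagnostic genes, strains fall into four
lineages:

| lineage | rule |
|---|---|
| I | complete ELO/DES, no PUFA-S |
| II | both routes complete |
| III | PUFA-S; ELO/DES broken only at the canonical Δ9 desaturase |
| IV | PUFA-S; C18/C20 elongases (and most desaturases) also lost |

with the cytosolic acetyl-CoA source inferred from ACLY (citrate route,
lineages I/II) or cCrAT (carnitine shuttle, lineage III; undetermined in IV),
and the carotenoid genes CrtZ/CrtO tracked as accessory markers.

The package implements every stage of that analysis as reusable, tested
functions: histidine-box motif scanning and subfamily classification,
best-hit family assignment by exact local alignment (BLOSUM62, affine gaps)
against archetype libraries, presence/absence matrix construction, the
four-lineage decision rule, gene-neighborhood (microsynteny) conservation by
reciprocal best hits over ±4 flanking genes, and NJ trees with bootstrap
support and monophyly tests. A packaged matrix records the published gene
distribution for 19 thraustochytrid strains and three relatives (cells not
fixed by an explicit text statement stay `unknown`), and seeded generators
create synthetic proteomes, annotated contigs and tree-evolved sequences so
every stage runs without downloads.

## Worked example

```r
library(pufatyper)

fx  <- build_fixture_matrix()        # 22 strains x 24 genes
rep <- summarize_typing(fx)
rep
#> typing_report: 19 thraustochytrid strains | 15 with complete PUFA-S, 6 with complete ELO/DES
#> lineage counts: I=4, II=2, III=7, IV=6

subset(rep$calls, strain_id == "T. aureum ATCC 34304",
       c(lineage, acetylcoa_route, pufas_complete, elodes_complete))
#>    lineage acetylcoa_route pufas_complete elodes_complete
#> 5       II    citrate_ACLY           TRUE            TRUE
```

The 19 thraustochytrid strains split 4 / 2 / 7 / 6 across lineages I–IV; 15
carry a complete PUFA synthase and 6 a complete ELO/DES route, with
*T. aureum* (lineage II) the only species carrying both — the numbers printed
above are computed from the packaged matrix at run time.

A synthetic end-to-end run (simulate → scan → assign → type):

```r
res <- run_pipeline(out_dir = "run1", seed = 42,
                    simulate_profiles = c("I", "II", "III", "IV"))
res$report$calls$lineage
#> [1] "I"   "II"  "III" "IV"
```

## Analysis scripts

Numbered drivers under `analysis/` rerun the main analyses and write tables
to `results/`: `01_fixture_typing.R` (lineage structure of the packaged
matrix), `02_motif_families.R` (motif self-classification and its decay with
mutation rate), `03_assignment_recovery.R` (end-to-end lineage recovery and
decoy control), `04_synteny.R` (planted neighborhood-conservation recovery,
PfaA–PfaB adjacency), `05_phylogeny.R` (4-clade monophyly with bootstrap).

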