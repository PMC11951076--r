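---
title: "Typing thraustochytrid PUFA biosynthesis pathways: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing thraustochytrid PUFA biosynthesis pathways: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pufatyper)
```

## The problem and the model

Thraustochytrids synthesise long-chain ω3-PUFAs through two distinct routes.
The ELO/DES route extends palmitic acid step by step through elongases (C16,
C18, C20, Δ9) and desaturases; each desaturation consumes oxygen. The PUFA
synthase (PUFA-S) route is a polyketide-synthase-like complex (PfaA, PfaB,
PfaC) that reaches C20–C22 PUFAs anaerobically. Which route a strain carries
is legible directly from its gene repertoire, and that repertoire sorts
strains into four lineages:

* **I** — ELO/DES complete, PUFA-S absent;
* **II** — both routes complete;
* **III** — PUFA-S plus an ELO/DES set broken exactly at the canonical Δ9
  desaturase (the enzyme producing oleic acid from stearic acid);
* **IV** — PUFA-S with the C18/C20 elongases and most desaturases also lost.

The package encodes this as two predicates over a presence/absence row.
`pufas_complete` requires all three Pfa subunits. `elodes_complete` requires
the Δ9A, Δ4, Δ5 and ω3 desaturases, *either* the Δ6- or Δ8-route desaturase
(the two are alternative branches of the same route), and the C16, C18, C20
and Δ9 elongases. The four lineage predicates are evaluated I→IV with first
match winning; because the flags derive from gene presence (a complete
ELO/DES set implies the Δ9A desaturase), the predicates are mutually
exclusive over every reachable flag state, which a 64-case truth-table test
verifies exhaustively.

Genes deliberately *outside* the completeness predicate: the ω6/Δ9B
desaturase (a bifunctional omega-family enzyme, not a main-route step), the
uncharacterised U-families, and the minor C16-like elongase. Including them
would misclassify lineage III strains, whose U1/U2 desaturases are absent by
lineage definition. A `strict` switch adds ω6/Δ9B to the required set for
sensitivity analysis.

Unknown cells count as absent for typing but are carried into the call
rationale as uncertainty markers, and relatives outside the thraustochytrids
are typed only with an explicit "heuristic" caveat.

## The packaged matrix

The fixture covers 19 thraustochytrid strains (six genera) and three related
Labyrinthulomycetes against 24 panel genes. Cells are filled exclusively
from explicit per-lineage and per-gene text statements of the source study —
per-lineage strain lists, exclusivity statements (canonical Δ9 desaturase
and U2 only in I/II; U1 only in two lineage-I strains; C16-like elongase
only in I/II; ACLY only in I/II; CrtZ only in III/IV; CrtO everywhere except
*T. striatum* and *T. aureum*; cCrAT in I–III and the relatives but not IV)
— never from figure artwork. Everything else stays `unknown`
(`r sum(build_fixture_matrix()$cells == "unknown")` of 528 cells). Each
statement also exists as a machine-checkable predicate
(`fixture_consistency()`), so fixture and statements cannot drift apart.
Presence is boolean: copy-number nuances (the diploid KH105, one-or-two
cCrAT copies) live in a note field, and the truncated 422-residue ACLY of
*S.* sp. CCTCC M209059 — which lacks the N-terminal ATP/citrate/CoA binding
domains — is recorded absent for typing with the exception preserved in its
note.

## Motif signatures

Desaturases carry three histidine boxes whose shapes differ by subfamily
(First: `HRLWSH`/`HRXHH`/`HNXHH`; Front-End: `HDXGH`/`HXXXHH`/`QXEHH`, with
the thraustochytrid variant `HXXHH` accepted for the second box; Omega:
`H[ED]CGH`/`HXXHH`/`HVXHH`); elongases carry one box, `HXXHH`, with `QXXHH`
diagnostic of the C20 group. Only these subfamily-level *shapes* are
published; per-family consensus strings are not machine-recoverable. The
default registry therefore instantiates otherwise-degenerate positions with
family-specific residues (e.g. the third Front-End box becomes `QIEHH`,
`QLEHH`, `QVEHH`, ... per family). These are archetypal synthetic choices,
not measured consensus: they keep the 17 signatures pairwise separable so
the synthetic-data path is fully self-consistent, while real analyses are
expected to resolve within-subfamily identity through alignment best hits
(and may replace the registry wholesale via `read_signature_registry()`).
The Δ4 signature keeps only the canonical `HXXXHH` second box and relaxes
the flanking boxes, mirroring that group's divergence; the ω3 signature is
given its own variant set since its boxes differ markedly from the omega
canon.

Box spacing defaults to 15–300 residues between consecutive boxes — the
source gives no spacing, so the bounds are deliberately loose and
configurable. N-terminal domains are handled heuristically: the cytochrome
b5 domain via its standard heme-pocket core `HPGG` (domain knowledge, not a
fitted value) within a 150-residue window — 700 for the U3 desaturase, whose
~500-residue N-terminal extension precedes the domain; DUF3474/DUF1129 have
no default pattern and are treated as satisfied unless the user supplies
one, since bundling real profile HMMs is out of scope.

`match_signature()` enumerates every combination of one box match per slot
with ascending positions (capped at 50 matches per slot) and returns the
candidate maximising the summed literal score, preferring spacing-legal
combinations among equal scores, then minimising span, then taking the
left-most positions. The spacing preference is a deliberate numerical
choice: a chance generic-box hit adjacent to a genuine box could otherwise
win on span alone while violating spacing and veto an otherwise clean
classification.

## Family assignment

Assignment follows search practice: exact Smith–Waterman local alignment
(BLOSUM62, gap open 11 / extend 1 — standard protein-search scoring)
against a per-family archetype library, scores normalised by the
archetype's self-score. The acceptance threshold of 0.3 normalised score is
a package decision (the original search cutoffs are unstated); the
decoy-control analysis shows shuffled proteins score far below it while 5%-
and 10%-mutated members score far above, so the operating point is not
delicate. Motif evidence corroborates desaturase/elongase hits; conflicts
resolve in favour of the best hit (motif signatures within a subfamily are
archetypal placeholders) with a logged warning. C16 vs C16-like — over 50%
identical — is decided purely by the higher normalised score, which is why
both archetypes must be present in the library.

## Synteny

The neighborhood procedure takes up to four genes on each side of the
target locus in contig coordinate order (not strand-relative). Homologs
between two strains' flank sets are reciprocal best local-alignment hits
with symmetric normalisation (score over the larger self-score) at the same
0.3 threshold; each flank gene pairs at most once. Conservation is
membership-based — a homolog anywhere in the other strain's flank window
counts — with order and strand agreement reported as flags rather than
required, and counts are therefore symmetric in the strain pair. PfaA–PfaB
locus adjacency means consecutive features on one contig, any strands.
GFF-lite input is 1-based inclusive on disk (GFF convention) and 0-based
half-open in memory.

## Phylogenetics

The tree path favours transparency over sophistication. Progressive
alignment uses 3-mer cosine guide distances, an NJ guide tree rooted
canonically (alphabetically first tip; children ordered by smallest tip
label, which makes the column set invariant to input order), and
profile–profile global alignment with BLOSUM62 expected column scores under
a linear gap penalty of 8, with traceback ties resolved diagonal-first.
Distances are p-distances over mutually ungapped columns — chosen over
ML protein distances for transparency — with an optional Poisson correction
`-ln(1-p)` capped at p = 0.95; a pair with no comparable columns gets
distance 1 with a warning. NJ uses the Saitou–Nei criterion with negative
branch estimates clamped to zero. Bootstrap support is the classical
Felsenstein column bootstrap (support = fraction of replicates containing
each bipartition), a stated substitution for transfer-bootstrap methods,
not an equivalence; supports are property-tested (range, determinism,
saturation), not value-matched, since no numeric supports are published.
Monophyly of a tip set means some edge of the unrooted tree bipartitions
exactly that set. Maximum-likelihood rRNA trees are out of scope; monophyly
claims are made on NJ trees only.

## The synthetic-data generators

The generators define the study conditions for every test. Family members
are uniform-random backgrounds of 250–420 residues (PUFA-S subunits +300,
as large multidomain proteins) with the family's boxes planted left to
right at gaps of 20–60 residues — inside the legal 15–300 window — plus the
N-terminal domain motif where the family has one. The uniform background is
the simplest null that makes spurious box hits analytically quantifiable
(a fixed 5-mer with three literal positions hits a random 300-mer with
probability ≈ 300/20³ ≈ 4%). Mutation is per-site resampling from the full
alphabet: a selected site is replaced by any of the 20 residues, so rate 1
leaves expected identity exactly 1/20. Sites inside planted boxes are
spared with probability 0.9 when selected — catalytic histidines are
strongly conserved, but 0.9 is a modelling default, not a measured rate.
Decoys are residue shuffles of real members: composition preserved,
motifs and homology destroyed. Strain simulations emit one member per gene
of the lineage profile (profiles are read off the fixture as genes present
in *every* strain of the lineage) plus 10 decoys; contigs place a target
gene with four flanks per side, sharing designated flank proteins across
strains; tree evolution applies per-branch mutation with probability
`min(1, rate x branch length)`. All generator randomness flows from one
seed through stage-name-keyed substreams (`stage_seed()`), so any stage is
independently reproducible.

What the generators deliberately do not emulate: realistic amino-acid
composition, indels, rate heterogeneity, domain architecture beyond the
planted motifs, paralogy, or annotation noise. Passing tests therefore
demonstrate the pipeline's internal correctness and its behaviour under
controlled divergence — not performance on real proteomes, where archetype
quality and HMM-level domain calls would dominate.

## Problem sizes and numerical choices

The shipped analyses use desk-scale sizes chosen to exercise every code
path: 1,000 random sequences for motif-oracle agreement, 20 seeded
four-strain quartets for end-to-end recovery, 50 seeded synteny scenarios,
20 random additive matrices (4–8 taxa) for NJ exactness, 200 bootstrap
replicates on a saturated 4-tip alignment, and one 16-tip 4-clade tree
(within-clade branches 0.02, stems 0.5, rate 1) for monophyly. Determinism
rules worth knowing: box-candidate enumeration caps at 50 matches per slot
(error beyond); best-hit ties break by identity fraction then alphabetical
family; NJ joined-pair ties follow the smallest-index convention of the
underlying implementation; all TSV outputs carry a version/config-hash/seed
header and reruns are byte-identical.

## Known limitations

The motif registry's within-subfamily resolution is synthetic by design;
on real data it should be treated as a candidate filter in front of
homology evidence. Absence calls inherit the evidence layer's blind spots —
transcriptome-only strains record absence of expression, not of the gene,
which is why rows carry their evidence source and typing output flags
lower-confidence calls. The four-lineage rule is defined within
thraustochytrids; calls for relatives are heuristic. The aligner is a
minimal progressive implementation without iterative refinement and is not
a substitute for a production MSA tool on deep alignments.
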