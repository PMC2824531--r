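---
title: "Comparative genomics of cold-adapted marine bacteria: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative genomics of cold-adapted marine bacteria: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`psychrocomp` implements the comparative-genomics inference chain used to
study how bacterial genomes adapt to cold, saline, deep-sea environments:
all-vs-all protein similarity, reciprocal-best-hit (RBH) orthology, nested
core/accessory partitioning of each genome's protein-coding genes (CDS),
top-hit-taxonomy calling of laterally transferred genes, proteome
amino-acid-composition and GC-content statistics with cold-versus-warm
group contrasts, and Kimura two-parameter (K2P) distances with
neighbor-joining (NJ) trees. Every stage can be exercised end to end on a
seeded synthetic genome collection with planted ground truth, which is what
the test suite and the acceptance script do.

## The similarity layer

Protein pairs are aligned with an affine-gap Smith–Waterman aligner
(BLOSUM62; a gap of length $L$ costs $11 + L$). Raw scores $S$ are
converted to expectation values with the Karlin–Altschul form

$$E = K\,m\,n\,e^{-\lambda S},$$

with $K = 0.041$ and $\lambda = 0.267$ per raw-score unit, $m$ the query
length and $n$ the total residue count of the subject proteome. These are
ungapped-style constants applied to gapped scores — a deliberate
approximation: the pipeline's decisions depend only on thresholding at the
conventional cutoff $E \le 10^{-20}$ and on the relative order of hits, not
on calibrated E-values. Hits are ordered per query by ascending $E$, then
descending bitscore, then subject id; every tie in the pipeline is broken
deterministically this way so that "first hit" semantics are reproducible.
Residues outside the 20-letter alphabet (e.g. `X`) score as the worst-case
substitution. Externally produced hit tables in the standard 12-column
tabular format can be substituted for the built-in aligner per genome pair;
the two sources are never mixed within a pair.

## Orthology and the nested CDS partition

Two rules coexist deliberately, because they serve different purposes:

* **Presence/absence** (used for the conservation matrix) is one-way: a
  query CDS is *present* in a target genome iff it has at least one hit at
  the cutoff. This is the weaker, inclusive reading appropriate for
  "conserved in" counts.
* **Orthology** (used for set construction) is reciprocal: CDS $a$ in
  genome A and $b$ in B are orthologs iff $a$'s best hit over B is $b$ and
  $b$'s best hit over A is $a$. Because the best hit is single-valued, RBH
  pairs are automatically one-to-one.

The partition of a focal genome's CDS is a sequential deduction over a
strictly nested hierarchy of genome sets (e.g. all strains / a four-strain
clade / the closest pair). The outermost level defines the core
($\mathrm{CDS}^c$): CDS with an RBH partner in *every* other genome of the
full panel. Each inner level then takes the CDS with partners throughout
that level, minus everything already labelled; the leftover is the
strain-specific set ($\mathrm{CDS}^1$). The labels partition the focal CDS
set by construction — disjointness and exhaustiveness are asserted by
property tests against a brute-force recomputation from the raw hit
tables. We interpret "shared among all strains" per focal genome: a CDS
needs an RBH partner in every other genome, with no requirement that the
partners form a consistent clique across genomes; this matches the
per-genome accounting of the published tables. The hierarchy is
generalized to any number of nested levels.

## Lateral-transfer calls

Each focal CDS is compared against a reference panel (the other strains
plus labelled outgroup genomes). The classification applies an ordered
list of *exclusion cases*; each case removes hits from a configurable set
of close relatives, takes the surviving top match, and tests whether that
match's genome carries the case's lineage-scope tag. A CDS is called
`lateral` if *any* case's top match escapes its scope, `native` if it has
hits but no case triggers, and `no_hit` if it has no panel hit at the
cutoff at all. The default configuration encodes the two-case rule: case 1
(three sub-cases, each independently able to trigger) excludes the closest
relative, the three closest, or the four closest, with the genus as scope;
case 2 excludes the whole genus, with marine gamma-proteobacteria /
gamma-proteobacteria as scope. Lineage membership is resolved through
explicit `lineage_tags` in the metadata, never by parsing organism names,
so the rule is testable without a taxonomy service. `no_hit` genes are
reported separately and never counted as lateral — the conservative
choice. A tie between a native and a foreign top match at identical
E-value resolves by the global deterministic tie rule (bitscore, then id).

## Composition statistics

The average composition of each amino acid (ACAA) is a pooled count over
all residues of all proteins in the chosen CDS set — *not* a mean of
per-protein percentages — expressed as percent of counted residues; `X`
and other non-canonical symbols are excluded from numerator and
denominator alike. GC and A+G content are likewise pooled over the
concatenated CDS nucleotide sequences with `N` excluded. Deviation
profiles subtract the unweighted across-genome (or across-set) mean per
feature.

Group contrasts treat the *genome* as the sampling unit (never individual
proteins), with genomes weighted equally regardless of proteome size, and
use the two-sided unequal-variance Welch t-test — the default of R's
`t.test`, which is also what the original analyses invoked. Raw
per-feature p-values are reported; Benjamini–Hochberg adjustment is
available behind a flag but off by default, matching the per-amino-acid
reporting convention. A label-shuffling helper estimates the per-feature
false-positive rate for null calibration.

## Phylogenetics

K2P distance: $d = -\tfrac12\ln(1 - 2P - Q) - \tfrac14\ln(1 - 2Q)$ with
$P$ and $Q$ the observed transition and transversion proportions over
counted sites. Saturation ($1-2P-Q \le 0$ or $1-2Q \le 0$) raises an
error rather than returning `NaN`. Both pairwise deletion (drop
incomparable sites per pair) and complete deletion (drop columns with any
gap/ambiguity first) are provided, since both appear in standard
workflows. NJ follows the Saitou–Nei Q-criterion with deterministic
lexicographic tie-breaking; negative branch-length estimates are clamped
to zero with the deficit moved to the sibling edge, a common convention
that keeps newick output printable and supports monotone. Bootstrap
support resamples alignment columns with replacement under a fixed seed
and counts bipartition recovery; replicates that saturate the distance are
redrawn (and counted). Trees are `ape` `phylo` objects throughout.

## What the simulator emulates — and what it does not

The generator plants exactly the structure the analysis assumes:

* **Nested gene families.** Ancestral proteins are drawn i.i.d. from the
  baseline amino-acid frequencies; families are assigned to hierarchy
  levels (defaults: 200 core, 100 clade, 80 pair, 50 private per genome,
  17 genomes in a 17/4/2 hierarchy). Per-genome copies diverge from the
  ancestor by independent site substitutions at rate 0.15, drawn from a
  BLOSUM62-weighted replacement kernel. At that divergence two family
  members are far inside the $10^{-20}$ cutoff while unrelated proteins
  are far outside it, so planted partition labels are recoverable exactly.
* **Habitat shifts.** For cold genomes the kernel's columns are re-tilted
  by iterative proportional fitting so that the replacement marginal
  equals the baseline marginal plus `shift / divergence`. The realized
  expected cold − warm composition delta then equals the configured shift
  vector (defaults: Ala −0.8, Pro −0.3, Arg −0.5, Ile +0.6, Lys +0.4,
  Asn +0.4 percentage points, mean-centred to stay on the simplex). A
  shift that would drive any replacement frequency negative is a
  configuration error.
* **GC structure.** Proteins are reverse-translated codon by codon: the
  probability of choosing a strong-ending (G/C third base) synonymous
  codon is set so the realized GC3 meets the genome's target in
  expectation, after accounting for Met and Trp whose single codons are
  G-ending. In the GC-panel preset each genome's (private) families are
  instead drawn from the sense-codon expectation of its own base bias
  $\theta$ ($P(G)=P(C)=\theta/2$), which mechanically couples amino-acid
  usage to genome GC — Ala/Pro/Arg/Gly codons are GC-rich at the first two
  positions, Ile/Lys/Asn/Tyr are AT-rich — reproducing the classic
  correlation sign pattern without any selection model.
* **Foreign genes.** Donor-panel genomes carry their own families, never
  shared with native families, so vertical/lateral truth is unambiguous;
  planted genes and the donor's own copy are two draws at divergence 0.05
  from the donor ancestor.

The simulator deliberately omits indels, operon/intergenic structure,
rate heterogeneity across sites, codon-usage tables of real taxa and
within-genome paralogy. Passing tests therefore demonstrate that the
inference chain recovers the structure it targets when that structure is
present and separable — not that real genomes satisfy those separability
margins. Mean protein length defaults to 120 residues and bootstrap
replicates to 100: sizes chosen to keep a full desk-scale run (one CPU)
in the low minutes while leaving wide score margins; both are ordinary
config knobs.

## Numerical and degeneracy conventions

* All randomness flows from a single integer seed per generator call;
  identical configurations produce byte-identical collections and report
  files.
* Welch's test with two zero-variance groups returns $t=0, p=1$ when the
  means agree and $t=\pm\infty, p=0$ otherwise; groups of fewer than two
  genomes are an error.
* GC/amino-acid correlation requires GC spread (zero variance is an
  error); the two-genome case degenerates to $r=\pm1$ with the slope sign
  equal to the composition difference sign.
* FASTA ids are the first whitespace token of the header; duplicate ids
  within a file are a hard error, because silent de-duplication would
  corrupt every downstream set size. Hit tables must have exactly 12
  columns; extra columns are rejected rather than ignored to catch format
  drift. Coordinates are 1-based inclusive on disk, 0-based half-open
  nowhere user-visible.
* Translation is plain codon lookup (no initiator special-casing);
  codons containing `N` yield `X`, internal stops are an error naming the
  codon index, and a trailing stop is stripped.

## Interfaces

`run_pipeline()` drives simulate → hits → RBH → partition → lateral calls
→ composition (→ group contrast) from one `pipeline_config()`, writing
tab-separated reports and a run log; each stage is equally usable as a
standalone function on intermediate files, which is how externally
computed hit tables enter. The package is driven from R; the repository's
`scripts/acceptance.R` is a thin command-line wrapper that re-runs the
main computations from scratch and emits their headline numbers as JSON.

## Known limitations

Exact E-value calibration is out of scope (thresholding behaviour is what
is exercised); the aligner is exhaustive rather than seeded, so it is a
desk-scale tool, not a BLAST replacement; lateral-transfer calling is
purely top-hit-taxonomy-based (no composition or island signal); and the
group contrasts assume independent genomes, ignoring phylogenetic
autocorrelation — as did the analyses this package systematizes.
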