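# psychrocomp

Comparative genomics of cold-adapted marine bacteria, as a reusable,
tested R pipeline. The scientific question it serves: when closely related
bacterial lineages split between cold deep-sea and warmer habitats, what
does that leave in their genomes? The classic analysis chain answers with
four instruments, all implemented here:

1. **Orthology and nested gene-set partitioning.** All deduced proteins of
   a focal genome are compared all-vs-all against a strain panel
   (affine-gap Smith–Waterman, BLOSUM62, Karlin–Altschul E-values
   `E = K·m·n·exp(−λS)`, cutoff `E ≤ 1e-20`). Reciprocal best hits (RBH)
   define orthologs; a sequential deduction over a nested hierarchy of
   genome sets splits the focal CDS into the core (CDS^c — RBH partner in
   every strain), clade-shared (e.g. CDS^4), pair-shared (CDS^2) and
   strain-specific (CDS^1) sets, with the one-way presence/absence rule
   producing the "conserved in" count matrix.
2. **Lateral gene transfer by top-hit taxonomy.** Each CDS is matched
   against a reference panel under configurable strain-exclusion cases; a
   gene whose top match escapes the expected lineage scope (genus, marine
   gamma-proteobacteria, gamma-proteobacteria) after excluding close
   relatives is called laterally transferred, with its donor taxon and
   habitat recorded.
3. **Composition statistics.** Pooled average amino-acid composition
   (ACAA, % of counted residues), pooled G+C and A+G content, deviation
   profiles, per-amino-acid correlation with genome GC, and cold-vs-warm
   group contrasts with two-sided Welch t-tests (genome as the sampling
   unit).
4. **Phylogenetics.** Kimura two-parameter distances
   `d = −½·ln(1−2P−Q) − ¼·ln(1−2Q)` with pairwise or complete deletion,
   Saitou–Nei neighbor joining with deterministic tie-breaking, and seeded
   column-bootstrap support, returned as `ape` trees.

A seeded synthetic genome-collection generator plants ground truth for
every stage — nested families, GC3 gradients, habitat-linked composition
shifts realized exactly in expectation, and foreign genes from a labelled
donor panel — so the whole chain is testable end to end.

## Worked example

Simulate a 6-genome collection (hierarchy 6/3/2; 40 core, 20 clade-shared,
15 pair-shared and 10 private families per genome; 5 genes planted from
the foreign donor panel) and run the full pipeline:

```r
library(psychrocomp)
cfg <- pipeline_config(
  sim = sim_config(n_genomes = 6, clade_size = 3, pair_size = 2,
                   n_core = 40, n_clade = 20, n_pair = 15, n_private = 10,
                   mean_len = 100, n_hgt = 5, seed = 42),
  outdir = "run_demo")
res <- run_pipeline(cfg)
print(res$partition)
print(res$donors$by_taxon)
```

```
CDS partition of G01 ( 90 CDS )
  CDS_c    40
  CDS_3    20
  CDS_2    15
  CDS_1    15

                taxon habitat n
1   Parvibaculum_like    cold 2
2   Psychromonas_like    cold 1
3 Rhodospirillum_like    warm 2
```

Reading the output: the partition recovers the planted family counts
exactly — 40 core, 20 shared across the three-strain clade, 15 shared with
the closest partner only, and 15 strain-specific (the 10 private families
plus the 5 foreign genes, which by construction have no ortholog in the
strain panel). The donor summary attributes each lateral call to its
planted donor taxon with its habitat label. `run_demo/` now holds the
tab-separated reports (`partition.tsv`, `partition_summary.tsv`,
`conservation.tsv`, `origin_calls.tsv`, `donor_summary.tsv`,
`composition.tsv`) plus `run_log.txt` with per-stage counts:

```
psychrocomp 0.1.0 seed=1 cutoff=1e-20
input: 12 genomes, 575 CDS, focal=G01
hits: 520 across 22 directed tables
rbh: 255 pairs
partition: CDS_c=40 CDS_3=20 CDS_2=15 CDS_1=15
hgt: 5 lateral, 75 native, 10 no_hit
```

Rerunning with the same config is byte-identical.

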