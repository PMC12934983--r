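---
title: "CRISPR-spacer-guided MGE mining: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CRISPR-spacer-guided MGE mining: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacermine)
```

## The scientific problem

CRISPR arrays are genomic records of past infection: each spacer is a
sequence-identical copy of a fragment of a mobile genetic element (MGE)
that once invaded the host. For host lineages that are well sampled in
culture — here, hyperthermophilic archaea of the order Thermococcales,
whose repeats are uniformly 29–31 nt — the isolate-derived spacer
repertoire can be turned around and used as a query set against
environmental metagenome assemblies. A contig hit by several spacers of a
known host lineage is, with high confidence, an MGE of that lineage, even
when it encodes no recognizable viral hallmark gene. spacermine
implements this host-anchored discovery procedure as a reusable, testable
pipeline:

1. **Array mining** — detect repeat-spacer arrays in isolate genomes and
   metagenome contigs; anchor metagenomic arrays to a reference repeat
   set at ≤1 mismatch on either strand; extract and deduplicate spacers.
2. **Protospacer search** — match the spacer catalog against contigs at
   ≥90% full-length identity, masking matches that fall inside detected
   arrays.
3. **Candidate selection** — keep contigs ≥2 kbp with ≥2 hits, or ≥1 hit
   when a terminal repeat (≥20 bp, ≤10% mismatches) indicates a complete
   genome; dereplicate candidates at ≥98% ANI and ≥95% coverage.
4. **Classification** — call ORFs, cluster proteins at ≥25% identity,
   connect contigs sharing ≥5 protein clusters (weighted by total shared
   genes), and partition the gene-sharing network into communities that
   approximate MGE families.

A seeded synthetic metagenome generator with a machine-readable truth
manifest makes every stage verifiable without any external download.

## Thresholds and defaults

All numeric thresholds live in `run_config()`; the defaults are the
published values of the procedure the package implements.

| parameter | default | meaning |
|---|---|---|
| `repeat_len` | 29–31 nt | admissible CRISPR repeat lengths |
| `anchor_max_mismatch` | 1 | repeat-to-reference Hamming bound (either strand) |
| `min_identity` | 0.90 | protospacer identity over the full spacer length |
| `min_len` | 2000 nt | candidate contig length floor (both branches) |
| `min_hits` | 2 | hits required without completeness evidence |
| `tr_min_len`, `tr_max_mismatch_frac` | 20 bp, 0.10 | terminal-repeat completeness call |
| `dedup_min_ani`, `dedup_min_cov` | 0.98, 0.95 | dereplication thresholds |
| `cluster_min_identity`, `cluster_min_cov` | 0.25, 0.80 | protein clustering |
| `min_shared` | 5 | shared clusters required for a network edge |
| `core_min_frac` | 0.80 | prevalence for a core cluster |
| `representative_frac` | 0.75 | fraction of the shortest complete genome |

Array-detection internals (seed k = 8, instance divergence ≤2 against the
consensus, ≥3 repeat instances, spacer window 20–60 nt) are not dictated
by the repeat-length window alone; the defaults mirror common
CRT/MinCED-style behavior and are all configurable.

## Algorithmic choices worth knowing about

**Array boundaries.** Candidates are initiated by exact 8-mers recurring
at admissible spacing (repeat + spacer window) and the repeat is grown
only while *every* chained instance agrees at the column. Diverged
flanking instances (a decayed terminal repeat copy is common in real
arrays) are then walked in, tolerating ≤2 mismatches against the
consensus. Finally, boundary columns that are not unanimous across all
instances are trimmed: a subset of instances can, by chance, agree one
column into their flanks, and a column supported only by such a subset is
not repeat evidence. Trimming may expose a repeat outside the 29–31 nt
window, in which case the candidate is rejected rather than truncated.
This keeps boundaries exact on planted arrays and keeps the detector
comparable, array by array, to an exhaustive periodic-repeat enumerator.

**Anchoring is Hamming, not edit.** The reference filter demands an
equal-length reference within one substitution (either strand). Because
the repeat window is only 3 nt wide, indel tolerance would add almost no
sensitivity while making "distance 1" ambiguous across lengths; the
package therefore defines no cross-length match.

**Protospacer identity is full-length and ungapped.** Identity is
(L − mismatches)/L over the whole spacer. With a seed length k = 7 and
spacers ≥30 nt at ≤10% mismatches, the pigeonhole bound
k ≤ ⌊L/(m+1)⌋ guarantees that every qualifying window shares an exact
seed with the spacer, i.e. the seeded search is provably equivalent to a
full scan; the equivalence is also tested against an independent scanner.
Short-read aligners would admit gapped, partial-length matches; that
semantics is not reproducible from a threshold alone, so the package uses
the deterministic, oracle-checkable definition and exposes the threshold.

**Terminal repeats are end-anchored.** A completeness call requires the
repeat to include the first and the last base of the contig. The ITR case
reduces to a single fixed-shift comparison (position i pairs with the
complement of position n − i + 1), which one cumulative scan solves
exactly; DTR candidates are generated from exact 6-mers shared between
the two end windows — 6 satisfies the pigeonhole bound down to a 20-bp
repeat with 2 mismatches, which a longer seed would not — and verified
longest-first.

**ANI by anchor chaining.** Maximal exact matches ≥15 nt are chained
co-linearly by descending length; inter-anchor gaps ≤500 nt are closed by
banded global alignment (band 50, match +1 / mismatch −1 / gap −2,
compiled); larger gaps stay unaligned. ANI is matched over aligned
columns along the chain; coverage is measured on the shorter sequence,
matching the fragment-containment intent of dereplication (the coverage
denominator is not fixed by the published thresholds; this choice is
deliberate and configurable). Accuracy is bounded in the tests: on
substitution-diverged pairs the chained ANI stays within ±0.005 of
full dynamic-programming global-alignment identity.

**Protein clustering and the network.** ORF calling is a deterministic
six-frame longest-ORF scan under translation table 11 (start codons
ATG/GTG/TTG, ≥60 codons) — not a trained gene finder; synthetic genes are
constructed to be discoverable by exactly this rule, and every call is
re-verifiable by hand. Clustering is greedy incremental (CD-HIT style):
proteins in length order join the best-matching qualifying representative
(≥25% identity — identical columns over alignment columns of a global
BLOSUM62/affine-gap alignment — with ≥80% residue-paired coverage of both
sequences; ties to the earliest-founded cluster). Joining the *best*
qualifying representative rather than the first one encountered matters
at so permissive a threshold: a borderline ~25% match against an
unrelated cluster founded earlier would otherwise occasionally absorb a
protein away from its true family, splitting a real module. "Total shared genes", the published edge weight, is formalized
as Σ~c~ min(count~i~(c), count~j~(c)) over shared clusters c — symmetric,
and equal to the shared-cluster count for single-copy genes.

**Communities by weighted modularity.** The original analysis used a
significance-based, potentially overlapping community algorithm; this
package substitutes weighted Louvain modularity under a fixed seed and
deterministic vertex order, which is non-overlapping and reproducible.
Acceptance rests on planted-partition recovery (adjusted Rand index
against the generator's family labels), not on equivalence with the
original algorithm.

**Core genes are estimated on representative contigs.** Fragments depress
cluster prevalence mechanically (a half genome carries half the modules),
so `run_pipeline()` computes each community's core clusters over its
representative members (≥75% of the shortest complete genome), falling
back to all members when a community has no complete genome — such
communities are flagged, never silently dropped. The generic
`core_clusters()` works on any member set.

**Manual curation becomes an explicit rule.** Candidates whose ANI ≥0.98
and coverage ≥0.50 against a supplied host genome are *flagged*
host-like, not removed: an audit trail replaces silent manual triage.

## The synthetic vent metagenome

`simulate_vent_metagenome()` emulates the statistical structure the
analysis assumes, under a single seed (`sim_params()`):

- **Hosts** (3 by default, 30 kbp backgrounds) carry 1–3 CRISPR arrays of
  12–24 repeat instances. Each array uses one reference repeat — with
  probability 0.3 carrying a single substitution, the same in every
  instance, modeling strain divergence from the reference set. Spacer
  lengths are drawn from a discretized normal (median 37 nt, sd 4,
  truncated to 30–50 nt), matching the empirical size profile of
  functional crRNAs.
- **MGE families** (5 × 4 members) share 12 core protein modules whose
  target pairwise amino-acid identity is drawn per module from 0.45–0.90.
  The lower end sits above the 0.40 contract floor on purpose: at a
  target of exactly 0.40 sampling noise would cross the floor the
  contract asserts; realized pairwise identity is additionally kept ≥0.40
  by bounded resampling. Members re-encode only mutated positions of the
  ancestral codon sequence, so a zero-divergence family has byte-identical
  modules and nucleotide identity decays smoothly with protein identity.
  Every gene is a genuine ORF (ATG start, in-frame stop, ≥60 codons)
  preceded by a 12-nt insulator carrying stops in all three forward
  frames, which pins the six-frame caller to the planted coordinates.
  Half the members (exactly `round(frac × members)` per family) carry a
  DTR or ITR of 20–60 bp.
- **Protospacers** are planted by construction: ≥80% of each array's
  spacers are windows of MGE genomes (uniform position and strand) with a
  mismatch count drawn so the realized identity falls exactly inside the
  requested range (default 0.90–1.00); the remainder are random dark
  spacers. The manifest records every planted position, strand and
  mismatch count, all re-verifiable from the emitted sequences.
- **Contigs**: complete MGEs are emitted whole; incomplete MGEs and hosts
  are tiled into fragments (mean 3.5 kbp). MGE breakpoints are snapped
  into intergenic gaps so each fragment's gene content is well defined
  against the manifest; the partial-gene truncation real assemblies
  produce at contig ends is deliberately not emulated. 450 i.i.d. random
  decoys (GC 0.45) complete a ~500-contig metagenome.

What the generator does **not** model — and what passing tests therefore
do not show about real data: sequencing error and chimeras, repeat
degeneration within arrays (beyond the shared variant), PAM or
strand-acquisition bias, integrated proviruses inside host chromosomes,
gene gain/loss and rearrangement within families, partial genes at
fragment ends, and realistic GC/codon composition. The pipeline's
behavior on those phenomena must be judged on real data.

## Problem sizes in the shipped tests

The test suite validates array detection against an exhaustive enumerator
on 100 seeded 50-kbp genomes, repeat anchoring against exhaustive Hamming
on 10,000 cases, protospacer search against a full scan on ~180 kbp of
contigs, completeness calling on 150 planted ends plus 1,000 random
10-kbp contigs, ANI on 50 pairs of 3–6 kbp against full dynamic
programming, and the end-to-end scenario on seeds 1–10 of the default
generator. These sizes keep the whole suite at desk scale while
exercising every documented contract; they are choices of the package,
not limits of the method.

## Known limitations

- The ≤1-mismatch anchor is substitution-only; a repeat with a single
  indel relative to the reference set is not anchored.
- Protospacer search reports no gapped or partial-length matches; an MGE
  diverged by indels inside a protospacer is missed at the default
  threshold.
- Louvain communities are non-overlapping; an MGE genuinely shared
  between two families is forced into one.
- The greedy protein clustering and dereplication depend on their
  documented orderings; they are deterministic but, like the tools they
  mirror, not order-free.
- `detect_arrays()` reports arrays without orientation inference (no
  leader detection): spacer orientation is defined by the contig strand,
  and the catalog is deliberately not collapsed across reverse
  complements.

## A minimal worked run

```{r, eval = FALSE}
sim <- simulate_vent_metagenome(sim_params(seed = 1))
res <- run_pipeline(run_config(contigs = sim$contigs,
                               genomes = sim$host_seqs,
                               repeats = sim$reference_repeats,
                               seed = 42, out_dir = "run1"))
res$summary
res$community_table
```
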