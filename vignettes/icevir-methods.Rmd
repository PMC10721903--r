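---
title: "Methods: viral ecogenomics from cellular metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: viral ecogenomics from cellular metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

icevir re-implements, as a tested pipeline, the desk analysis used to mine
viral genomes out of *cellular* sequence data — metagenomes,
metatranscriptomes, MAGs and SAGs — in settings where no virome was
sequenced (for example seawater sampled through an ice-shelf borehole).
Upstream tools (viral scoring, gene prediction, aligners) are out of scope:
their outputs are consumed as tables with BLAST outfmt-6 semantics, and a
seeded synthetic-community generator emulates all of them with planted
ground truth so every stage can be scored end to end.

## Contig triage

A candidate contig is promoted to a bona fide viral genome fragment by a
three-round rule cascade:

1. **Length**: dsDNA, NCLDV and Lavidaviridae candidates need ≥ 10 kb; RNA
   and ssDNA viruses, whose marine representatives have genuinely tiny
   genomes, need only 1.5 kb and 2.5 kb.
2. **Gene content**: at least one viral hallmark gene, and a host:viral gene
   ratio < 1. Proviruses get the relaxed rule (one hallmark suffices);
   contigs with no hallmark genes and no host genes carry no usable signal
   and are dropped.
3. **Origin screen**: a viral-origin score (PPR-meta-like, in [0,1]) below
   `min_origin_score` rejects the contig. The source analysis reports this
   screen only qualitatively, so the cutoff defaults to the conventional
   0.5 and is configurable (set `NA` to disable).

Rules fire in that fixed order (cheapest first), which makes the rejection
reason deterministic. The ratio denominator is
`max(viral_gene_count, hallmark_count, 1)`: hallmark genes are viral genes,
and the guard avoids division by zero for contigs annotated only by
hallmarks.

## Gene-sharing network

Protein clusters (PCs) come from all-vs-all protein hits filtered at
E ≤ 1e-5 and bitscore ≥ 50, reciprocal hits merged at maximum bitscore, and
Markov clustering (MCL) at inflation 2. The MCL implementation is
sparse-matrix (expansion = matrix square, inflation = entrywise power with
column renormalisation, pruning at 1e-5, convergence at 1e-8 change, ≤ 100
iterations); clusters are the connected components of the converged flow's
support, so the output is always a partition. Self-loops are set to each
node's maximum incident weight, a standard stabilisation.

Genome pairs sharing PCs are scored with the hypergeometric tail
probability of sharing at least that many PCs given each genome's PC count
and the PC universe of the run, scaled Bonferroni-style:
`score = -log10(p * C(n_genomes, 2))`, following the vConTACT lineage.
Edges at score ≥ 1 are clustered with MCL (inflation 2); clusters with ≥ 2
genomes are viral clusters (VCs), everything else a singleton/outlier — the
singleton fraction is the endemicity proxy. VC repertoires are compared by
Jaccard similarity over PC sets.

## Intergenomic similarity and taxon demarcation

For a genome pair, similarity is 100 × (identity-weighted aligned query
bases, overlaps resolved in favour of the higher-identity hit) divided by
the mean of the two genome lengths — symmetric in expectation, bounded by
100, and averaged across the two alignment directions when both are
present. Species and genus are demarcated by single-linkage clustering at
95% and 70% (the ICTV convention for Caudoviricetes; both configurable).
Single linkage on one tree guarantees that the species partition refines
the genus partition and that raising a cutoff can only split clusters.

## Abundance and activity (KPKG)

Fragment recruitment is filtered at two tiers: species (identity ≥ 95%,
query coverage ≥ 85%) and genus (identity ≥ 70%, coverage ≥ 50%). Each read
keeps only its best hit (highest bitscore; ties to the lexicographically
smallest subject) **before** tier filtering, so the species-tier retained
set is always nested in the genus-tier set and no read is counted twice.
Recruited amount is the aligned length of the retained hit ("recruited
kilobases", not full read length). Normalisation is KPKG: recruited kb per
genome kb per metagenome (or metatranscriptome) Gb. Metatranscriptome KPKG
is reported as activity, metagenome KPKG as abundance; rankings take the
top N (default 3) per sample.

## Virus–host assignment

Evidence is typed and split into two ranks:

* **Strong** — CRISPR spacer–protospacer match (full spacer length, no
  gaps, ≤ 1 mismatch by default); shared tRNA (alignment ≥ 60 bp, identity
  ≥ 97%, mismatches < 10); AMG homology (e-value better than 5e-5, identity
  and query coverage ≥ 50%).
* **Supporting** — WisH-style k-mer Markov log-likelihood inside the
  [-1.30, -1.20] window (inclusive; natural log per nucleotide, k = 8,
  add-one smoothing, both strands trained); codon-usage Euclidean distance
  ≤ 0.05; binning co-occurrence.

One passed strong item assigns a host at the strong tier; two or more
passed supporting items assign at the supporting tier; binning alone never
assigns, because binners can misplace viral contigs on GC or coverage
alone. Among competing hosts the most strong evidence wins, then the most
passed items overall; a residual tie is reported as ambiguous and left
unassigned. The codon rule (metric and cutoff) is an artifact choice — the
source analysis names only the calculator — and is flagged as
supporting-only for that reason.

CRISPR arrays are detected CRT-style: exact 19-mer seeds recurring with a
period between repeat+spacer length bounds (repeats 19–38 bp, spacers
19–48 bp, ≥ 3 copies) are chained and extended while all copies agree.
Because an exact repeat array is an exact repeat array on both strands, a
forward-strand scan finds arrays of either orientation; repeat structure
carries no orientation signal, so coordinates and spacers are reported in
forward orientation and protospacer matching searches both strands of each
spacer. Shifted sub-arrays (possible when all spacers share a boundary
base) are suppressed in favour of the best-supported array per locus.
Copies must share the exact seed; divergent-copy arrays (> 1 mismatch
inside the seed) can be missed — planted and typical natural arrays have
near-identical copies.

The built-in Smith–Waterman aligner (match +1, mismatch −1, gap −2 per
base, both strands for DNA, deterministic tie-breaks) serves the
spacer/tRNA searches; it is guarded to queries ≤ 500 bp. Spacer matching
uses a pigeonhole exact-seed prefilter — a full-length match with ≤ m
mismatches over length L contains an exact run of `floor((L-m)/(m+1))` —
which cannot change the set of passing pairs.

# The synthetic world

The generator's defaults state the world the pipeline is tested in: 20
hosts of 100 kb, 200 viral contigs in a dsDNA-dominated class mix (59%
dsDNA, 35% ssDNA, 4% NCLDV, 1.3% Lavidaviridae, 0.7% RNA), dsDNA contig
sizes 10 kb + Gamma with mean ≈ 19.4 kb and ssDNA/RNA means ≈ 4 kb, a 3%
temperate fraction, a 56% gene-sharing singleton fraction, and 60 planted
strong-evidence virus–host pairs (20 CRISPR, 20 tRNA, 20 AMG) with AMG
orthologs at 10% amino-acid divergence. Eight decoy contigs are planted to
fail each triage rule, and one core provirus is planted with host:viral
ratio ≥ 1 to exercise the provirus relaxation.

Design choices a maintainer should know about:

* **Host composition model.** Hosts are order-2 Markov chains; per 2-mer
  context the G/C and A/T splits are Beta(6, 6) draws per host while every
  context row keeps the host's GC content exactly, so realised GC tracks
  the requested value at binomial precision *and* hosts differ enough
  compositionally for k-mer host prediction to have signal.
* **Viral composition and the likelihood window.** Viral sequences are
  drawn from a power-sharpened copy (`q^beta`, rows renormalised) of the
  composition host's transition table, with beta solved per host so the
  *expected* per-nucleotide log-likelihood under the trained k = 8 model
  equals −1.25, the midpoint of the pass window. Without sharpening, the
  smoothed k = 8 model of a moderately biased genome scores fragments near
  ln(1/4) ≈ −1.386 and the printed window would never fire; the sharpened
  world is one in which the window is meaningful.
* **Planted CRISPR coordinates are made well-posed.** After splicing an
  array into a host, the generator ensures the columns just outside the
  repeat copies are not unanimous; otherwise maximal extension would be
  ambiguous and "exact coordinates" undefined.
* **Protospacers avoid low-complexity sequence.** The sharpened model can
  emit long AT-repeats; a protospacer sampled there recurs across genomes
  and would poison precision. Spacers are sampled from windows with ≥ 16
  distinct trinucleotides — the same reason real spacer searches dust-mask
  queries.
* **Uniqueness by construction.** Host gene families, planted tRNAs and
  spacers are unique per host/pair, which is what makes precision 1.0 a
  meaningful target. Real MAGs share genes and tRNAs across taxa; a green
  host-assignment test therefore establishes correct wiring and
  thresholds, not robustness to cross-taxon homology.
* **Recruitment.** Reads carry binomial per-base errors (default 1%);
  per-virus weights are log-normal, shared across depths up to a 5%
  jitter (the planted community is depth-stable), with one virus planted
  dominant in metagenomes and one in metatranscriptomes by boosting above
  the community maximum. Junk (identity ≈ 60%) and mid-identity (80%
  identity, 60% coverage) decoy reads exercise both tier filters;
  secondary weaker hits to genus mates exercise best-hit deduplication.
  Expected KPKG per virus/sample/tier is recorded in the truth object,
  including the (tiny) loss from identity filtering of errored reads.

What the generator does **not** emulate: indel read errors and quality
profiles, cross-taxon gene homology, tRNA conservation, divergent-copy
CRISPR repeats, genuinely shared nucleotide sequence between genus mates
(inter-genome similarity is emulated at the hit-table level), and
reference-database comparisons. Tests green against this world validate
the decision logic and arithmetic of each stage, not performance on real
survey data.

# Numerical choices

* Hypergeometric tails via `phyper` (upper tail at `shared - 1`); the test
  suite checks all margins with universe ≤ 30 against direct factorial
  summation at 1e-12.
* MCL: pruning 1e-5, tolerance 1e-8, ≤ 100 iterations; non-convergence
  returns the current clustering with a warning. The suite compares 200
  random graphs (≤ 12 nodes) against an independent dense reference
  implementation.
* Smith–Waterman ties: highest score, then smallest subject end/start via
  traceback preference, then forward strand; scores are validated against
  both an exhaustive suffix-recursion oracle and `pairwiseAlignment`.
* `N` bases score as mismatches and are excluded from k-mer counts.
* Degenerate inputs error loudly: empty FASTA warns and returns empty,
  zero genomes/dataset sizes are errors, all-`X` proteins are errors.
* Seeds: every generator stage derives its RNG stream from `params$seed`
  plus a fixed offset, so single stages are reproducible in isolation.

# Known limitations

* The evidence hierarchy formalises qualitative guidance; the exact
  combination logic (counts, tie-breaks) is a package decision and
  configurable.
* The intergenomic similarity denominator (mean of the two genome lengths)
  is a reconstruction; the named tool's exact internals are not public in
  the source text.
* Whether the third-round origin screen removed or merely reported
  sub-threshold contigs is unclear in the source; it is implemented as an
  optional filter, on by default.
* Query coverage is per best HSP ("qcovhsp"), not per-subject aggregated;
  the source leaves this open.
* The WisH-style window is applied to raw mean log-likelihoods, as
  printed, not to a null-calibrated score.
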