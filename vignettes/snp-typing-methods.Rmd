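---
title: "SNP typing of multi-locus barcodes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNP typing of multi-locus barcodes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

snptyper re-implements, as one tested pipeline, an MLST-style SNP-typing
analysis of Sanger-sequenced DNA barcodes for landrace-level identification
of medicinal plants. This vignette explains the models behind each stage,
the parameters that matter, what the synthetic data generator does and does
not emulate, and the design decisions taken where the procedure left room.

## Trace quality control

A directional read carries three per-base channels: the base call, a
Phred-style quality value QV (QV 20 ≈ 1 % basecall error), and the
secondary-peak fraction (height of the second-tallest chromatogram peak
relative to the tallest).

**End trimming.** From each end the trim point advances inward until the
terminal window of 25 bases contains fewer than 3 bases that are low quality
(QV < 25) or ambiguous. The 5′ end is scanned first; the 3′ scan runs on the
remaining interval, and an interval that never satisfies the rule yields an
explicit empty-trim marker rather than an error. Trimming is idempotent:
re-trimming a retained slice changes nothing.

**Trace score (TS)** is the arithmetic mean QV of the retained bases
(TS of an empty trim is 0), classified low (0–20), medium (21–34), high
(35–100). **Contiguous read length (CRL)** is the longest run of positions
whose windowed QV exceeds 20. The windowing is a centered 20-base moving
average that shrinks at the read ends; a raw per-base variant is available
via `crl(..., smooth = FALSE)`. We chose the smoothed reading of
"quality above 20 in a window of 20 bp" because it is robust to single-base
dips and matches the intent of vendor trace-quality tools; both variants are
exercised in tests. A trace passes QC when TS ≥ 35 and CRL ≥ 200 bp, and a
region's sequencing success is the percentage of passing traces among all
traces, reported to one decimal with half-up rounding (112/116 → 96.6).

## Assembly and heterozygote calling

The reverse read is reverse-complemented and placed against the forward read
at the best ungapped offset (maximum IUPAC-compatible matches; ties prefer
the larger overlap, then the offset closest to zero). Assembly is accepted
when the overlap covers at least 80 % of the *shorter* read — the procedure
did not name the denominator; the shorter read is the conservative choice —
and at least 98 % of overlap positions match. Alignment is ungapped by
design: the loci carry substitution SNPs only, and a gapped assembler could
silently absorb indels the downstream caller must refuse.

At overlap positions a two-base IUPAC code (W/M/R/Y/S/K) is emitted iff the
secondary-peak fraction exceeds 0.40 on **both** strands and the strands
agree on the allele pair; otherwise the primary base of the higher-QV strand
is used, and a primary-base disagreement without heterozygote evidence is
counted as a conflict. Positions covered by a single strand take that
strand's call but can never be heterozygous — bidirectional confirmation is
the point of sequencing both directions. K (G/T) is accepted even though
observed-code lists often omit it: the list enumerates observations, not the
alphabet.

Each sample × locus is sequenced as two independent templates
("individuals"); both are assembled separately and their SNP-call sets must
agree, otherwise the sample × locus is flagged and excluded. The FASTQ
sidecar (`read_id`, `position`, `secondary_fraction`, `second_base`) is the
package's trace abstraction; it carries the minor-peak base identity because
FASTQ cannot, and no chromatogram format is parsed.

## Typing

SNPs are variable sites between a sample's consensus and the reference
sample's own consensus for that locus, in 1-based reference coordinates; an
IUPAC code over a pure reference base is one SNP site, and heterozygote
codes are *distinct allele symbols* throughout (A vs R is a difference, for
ST identity and for distances) — genotype states, not missing data. The SNP
columns of a combination are the union over samples of variable positions,
ordered by (locus, position); identical allele vectors share an ST, numbered
by first occurrence. ST labels are therefore input-order-dependent; only the
partition is meaningful, and tests compare partitions, never labels.
Combination reports carry SNP and ST counts (SNP counts are additive over
disjoint loci; ST counts are non-decreasing as loci are added), and the
SNP/ST association is the Pearson correlation with the two-tailed t-transform
p-value (n − 2 df). A locus with under 90 % sample coverage is dropped from
the default combination set rather than padded — the fate of the
repeat-failing locus.

## Trees

**UPGMA** is run on Hamming SNP distances (clustering on similarity or on
distance gives the same ordering; heights are reported in SNP units, merge
height d/2). Agglomeration ties break at the lexicographically lowest
cluster-index pair so runs are reproducible. The cophenetic correlation
between input and dendrogram-implied distances measures clustering fidelity;
it is exactly 1 on ultrametric input, and defined as 1 in the degenerate
no-variance case iff the dendrogram reproduces the input exactly.

**Maximum parsimony** treats each SNP column as a categorical character
(Fitch counts, computed on bitmask state sets). The search is simulated
annealing over nearest-neighbour-interchange moves from a random-addition
start, with geometric cooling — the published procedure named the method but
not the schedule, so the schedule is exposed: T₀ = 5, α = 0.95, 100
proposals per temperature, stop below 0.01. On 8-taxon problems the annealer
matches the exhaustive optimum in ≥ 95 % of seeded runs (verified against
enumeration of all 10 395 topologies). Exhaustive mode is allowed to 9 taxa.
Bootstrap resamples SNP columns (the characters the tree is built from) with
replacement and re-runs a lightened anneal per replicate; support is the
percentage of replicates containing each bipartition of the reference tree.
The rooted form places the root midpoint-style with unit edge lengths — our
reading of "root on the deepest branch by maximum branch length", which the
original software does not document.

**Minimum spanning tree.** Zero-distance taxa collapse into ST nodes (size =
membership). The MST grows Prim-style on the complete SNP-distance graph;
among weight-tied candidate edges the one whose *already-included* endpoint
has the highest priority score wins, score = 10000 × (single-SNP variants) +
10 × (double-SNP variants) counted on the full distance matrix; remaining
ties prefer the larger attaching node, then the lower ST id. Whether the
priority applies to the included or the attaching endpoint is undocumented
upstream; the included endpoint is our documented, configurable choice, and
either way the rule only resolves ties — the total weight always equals the
unconstrained minimum (asserted in tests against exhaustive Prüfer
enumeration). Groups are connected components of MST edges of weight ≤ 2
with ≥ 2 STs; founder candidates rank by single-SNP MST neighbours, then
node size.

## The synthetic panel

The generator's defaults emulate the motivating study design: 29 samples in
three species (A = 21 hosting the reference individual, B = 2, C = 6), four
informative loci of 660/714/568/818 bp with planted SNP counts
(19, 11, 4, 1), and a fifth 715 bp locus with no SNPs and a
mononucleotide-repeat failure mode. Species C is made distant by fixed
diagnostic alleles at (9, 4, 4, 1) columns; species B differs from A only at
5 of the first locus' diagnostic columns, where it carries a third allele —
so B is a near-variant of A and those 5 columns split all three species.
Remaining columns are private within-species variants dealt round-robin to
non-founder samples (founders are one third of each species, giving the
7-member founder ST), with a 0.15 chance of being planted as an IUPAC
heterozygote.

Reference composition is i.i.d. uniform ACGT (no composition model was
given); the quality profile is a flat peak (QV 55) with linear decay after
position 450 (0.03 QV/bp) plus Gaussian noise (sd 2), clipped to [0, 60].
Basecall errors follow Phred semantics — substitution probability
10^(−QV/10) per base — so errors concentrate in the low-quality tails that
trimming removes; `trace_model(noiseless = TRUE)` gives the exact noiseless
limit used by recovery tests. Heterozygous sites carry a secondary fraction
of 0.6 on both strands (above the 0.40 threshold, hence callable);
homozygous background secondary noise is uniform on [0, 0.05]. The repeat
locus carries two homopolymer runs (relative positions 0.2 and 0.8) so that
*either* read direction meets a run early in its own orientation; 66 % of
its reads lose signal downstream of the first run they meet, which lands the
locus near the ~35 % success rate that motivated dropping it.

What the generator does **not** emulate: real chromatogram signal (no AB1
parsing — quality values are inputs, never inferred), indels and structural
variation, PCR recombination or contamination, paralog-specific copy
evolution behind heterozygosity, and any composition bias. Passing tests
therefore demonstrate that the pipeline's logic is correct on data matching
its model assumptions, not that the QC thresholds are optimal for real
traces.

## Problem sizes and determinism

The default panel is 29 samples × 5 loci × 2 individuals × 2 directions =
580 reads. The analysis scripts use 200 bootstrap replicates with a
lightened per-replicate anneal (T₀ = 2, α = 0.90, 20 proposals/temperature),
a deliberate trade of replicate count against per-replicate search depth
that leaves strong splits (backed by many columns) at essentially full
support. Exhaustive cross-checks run at ≤ 8 taxa (10 395 topologies) and
≤ 8 MST nodes (≤ 262 144 spanning trees). One master seed drives everything;
per-stage seeds derive from it by stage-name hashing so stages can be re-run
in isolation, and identical configuration reproduces byte-identical
artifacts (md5 manifest).

## Known limitations

- ST numbering is first-occurrence; comparisons across runs must use the
  partition, not the labels.
- The consensus is placed on the reference by best ungapped offset; a true
  internal indel makes a locus unalignable and excluded, by design.
- Positions never covered by an accepted contig fall back to the reference
  allele in profile extraction (uncovered ≠ variant); heavily truncated
  contigs are better excluded upstream by the QC/assembly thresholds.
- The annealer guarantees no global optimum beyond the sizes where the
  exhaustive check runs; for the 19–20-ST default panel the dominant splits
  are verified structurally (species clade membership), not as a certified
  optimum.
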