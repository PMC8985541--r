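---
title: "Quantifying and validating retained introns: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and validating retained introns: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riquant)
```

## The problem and the model

Splicing removes most introns co-transcriptionally, but a subset survives
into polyadenylated transcripts. Such retained introns (RIs) almost always
contain stop codons in the reading frame — often in all three frames — so
a retained transcript cannot make full-length protein until the intron is
eventually excised. Regulated retention is therefore a post-transcriptional
switch, and comparing retention between conditions (tissue regions,
injury states) asks a quantitative question: *what fraction of a gene's
transcripts retain intron i in condition c, and does that fraction change?*

`riquant` answers it from strand-specific spliced short-read alignments.
For each annotated intron, every primary alignment is classified by how it
relates to the two splice boundaries:

* **EE** (exon–exon): the alignment's N-gap coincides exactly with the
  intron — evidence for the spliced isoform;
* **EI5**, **EI3** (exon–intron): one contiguous alignment block covers
  the donor or acceptor boundary with at least `min_overhang` nucleotides
  on each side — evidence for the retained isoform;
* **IB** (intron body): the whole alignment lies inside the intron.

The per-boundary retention estimate is a simple proportion,
`PIR5 = 100·EI5/(EI5 + EE)` and `PIR3 = 100·EI3/(EI3 + EE)`, and the
intron-level summary is the minimum of the two, **minPIR**. The minimum is
deliberately conservative: intronic mismapping, unannotated alternative
boundaries, or a residual DNA signal typically inflate one boundary only,
and a cleanly spliced second boundary then vetoes the call. Under a
mixture in which a fraction ρ of molecules retain the intron, EI and EE
counts at a boundary are binomial in ρ and 1−ρ, so PIR is a consistent
estimator of 100ρ; minPIR inherits a small negative bias of order the
binomial standard error (the minimum of two noisy unbiased estimates),
which the tests account for when checking recovery.

### The filter chain for calling an intron retained

A condition-level call requires three things to hold:

1. **Replicate support** — minPIR strictly above `pir_threshold`
   (default 25%) with at least `min_coverage` (default 10) junction reads,
   in strictly more than `replicate_fraction` (default 0.5) of the
   replicates. The strictness matters at the boundary: 2 of 4 replicates
   is not a call.
2. **Host-gene expression** — the gene's fpkm must exceed a
   data-derived background: the 95th percentile of fpkm over random
   intergenic regions, per replicate, with the gene required to clear the
   background in a majority of replicates. This prevents "retention" calls
   in genes that are barely transcribed, where a handful of intronic reads
   can dominate.
3. The condition-level PIR is computed from **pooled counts** (sum, then
   ratio), not a mean of per-replicate ratios, so deeper replicates carry
   proportionally more weight and shallow replicates cannot blow up the
   variance.

Introns with no defined minPIR in any replicate (zero denominators at a
boundary) are reported as `no_data`, distinct from `not_retained`.

Differential use is the categorical **switch rule**: an intron switches
between conditions when pooled usage is ≤ 25% in one and > 25% in the
other. This is a classification boundary, not an effect size — an intron
moving 30% → 90% does not switch. The rule's virtue is interpretability
(the intron changes retention *class*), and its boundary semantics are
checked exhaustively against a direct transcription of the sentence over
the full integer grid of PIR pairs.

### Two readings of the PIR denominator

The retention literature describes PIR both as a pure junction ratio and
as a ratio that also counts intronic-body reads as retention evidence. The
package implements both: the default `pir_mode = "junction"` uses junction
reads only; `pir_mode = "with_intronic"` adds IB reads to the numerators
after normalizing them to junction-equivalent counts
(`IB · read_length / intron_length`, the expected number of boundary reads
the same molecules would have produced). Junction-only is the default
because IB reads are the category most contaminated by mismapping and
repeats; neither mode is asserted to be "the" definition. Likewise,
whether the minPIR filter applies per replicate or to pooled counts is
ambiguous in the field; the default applies it per replicate (with the
pooled value reported), and `replicate_rule = "any_evidence"` gives the
laxer any-retention-read reading.

## Long-read validation

Short reads infer retention from boundary statistics; a single long read
carries the whole answer, because the connectivity of exons and introns is
visible in one molecule. `classify_long_reads()` calls a read **spliced**
for an intron when an alignment gap matches both boundaries within `slack`
(default 10 nt) and **retained** when the union of aligned blocks covers
both boundary windows (±`flank`, default 10 nt) without interruption and
at least `body_cov_min` (default 0.8) of the intron body. Everything else
— 5'-truncated molecules that end inside the intron, reads that only
brush a flank — is **uninformative** and excluded from validation rates.
Slack-based gap matching and union coverage (rather than exact block
matching) make the classifier robust to the small indels typical of
nanopore alignments; the monotonicity of the two thresholds (more slack
can only move reads toward spliced, stricter body coverage only away from
retained) is property-tested. Because direct RNA sequencing reads
polyadenylated molecules, a validated intron is by construction resident
in polyadenylated RNA.

An intron counts as validated with `min_support` (default 1) retained
reads among informative ones; the validation rate is computed only over
candidates with at least one informative read, with zero-read candidates
reported separately rather than silently deflating the rate.

## Feature characterization

* **Relative position**: 100 × (distance from the transcription start to
  the intron midpoint) / pre-mRNA span, measured 5'→3' on the sense
  strand. The midpoint (rather than an endpoint) makes the measure
  symmetric under strand flips, which is property-tested by mirroring a
  whole locus. The pre-mRNA span is the gene's `tx_start..tx_end`; where
  transcripts disagree the span of the union is used, a choice that keeps
  the denominator per-gene rather than per-transcript.
* **Splice-site strength**: a trainable position log-odds matrix over the
  canonical scoring windows — donor 9-mer (3 exonic + 6 intronic nt),
  acceptor 23-mer (20 intronic + 3 exonic nt) — with per-position base
  frequencies from user-supplied true sites (pseudocount 0.5) against a
  background composition, scores in log2 bits. This is a deliberate
  simplification of maximum-entropy scoring: the package's use of the
  scores is comparative (distribution shifts between intron classes), and
  a PWM preserves ordering and distribution shape for that purpose while
  requiring no external score tables. The scorer is a plain per-window
  lookup, so externally computed scores can be substituted. Fewer than 50
  training sites is refused: column frequencies from smaller sets are too
  noisy to rank mismatches reliably.
* **Stop-codon frames**: frame *f* ∈ {0,1,2} is flagged when TAA/TAG/TGA
  occurs at an offset ≡ *f* (mod 3) from the intron's first sense base.
  The implementation (one regular-expression pass with lookahead for
  overlaps) is verified for exact agreement against a brute-force
  every-position scanner, exhaustively over all short sequences and on
  random 1 kb sequences.
* **Motif profiles**: exact sense-strand matching with overlapping
  occurrences, positions expressed as percent of intron length and binned
  (default quintiles); presence/absence enrichment against a background
  intron set uses a Haldane-corrected odds ratio with Fisher's exact
  p-value, so empty cells never produce infinities. Only profiling of a
  given motif is supported — de novo discovery is a different problem.

## Editing analysis

Targeted A-to-I editing is read directly from aligned bases: inosine
pairs like guanosine, so editing at a sense-strand adenosine appears as
A>G in sense reads and T>C on the reference strand of minus-strand genes
(the pileup complements before classifying). Per site, the editing
fraction is `n_edited / (n_ref + n_edited)` over primary alignments
passing `min_mapq` (20) and `min_baseq` (20); other bases are tallied but
excluded from the denominator. Counts are raw read tallies — no PCR
amplification model is applied anywhere.

Per-read haplotypes use only **informative reads**: those covering every
site with a passing ref-or-edited call. Reads covering a subset of sites
are excluded rather than imputed — mixing partially informative reads
would make combination percentages depend on coverage geometry. Within
that subset the per-site marginals of the haplotype table equal the
per-site fractions *exactly* (both are column summaries of the same
read-by-site call matrix), which the tests assert as an identity, not a
tolerance. Combination percentages are normalized to sum to 100.

The alternative 5' splice-site readout counts junction reads for the
proximal (exon-including) versus distal (exon-skipping) acceptor choice
at the shared donor. Only the shared-donor junction is diagnostic of
inclusion: counting both junctions flanking the alternative exon would
let each including molecule vote twice and halve the apparent skipping
fraction. Between-condition comparison uses a two-proportion z-test per
site with Benjamini–Hochberg correction across sites.

## The synthetic-data generator

The generator is first-class, tested code; it defines the study
conditions under which every property is demonstrated. Defaults emulate a
four-group spinal-cord design — two regions × naïve/injured
(`AN, AI, BN, BI`), three biological replicates each — with 150 nt
strand-specific single-end short reads at 98% strandedness fidelity,
polyadenylated long reads, and a five-site editing amplicon with an
alternative 5' splice site.

Generated loci place 20 multi-exon genes (3–6 exons of 80–200 nt, introns
60–300 nt, both strands) on one chromosome with ≥ 3 kb intergenic
spacers, leaving room for the intergenic background sampling. Donor and
acceptor windows carry the consensus at 85% per-position probability with
exact GT/AG dinucleotides, so splice-model training has signal; about 10%
of introns also get a second annotated transcript with the flanking exons
merged, exercising the annotated-retention (`known_retained`) path.
Retention truth assigns each intron a class — retained everywhere (20%),
retained in a random proper subset of conditions (20%), or background —
with ρ = 0.5 for retained and ρ = 0.02 for background. The background is
deliberately nonzero: real spliceosomes leak, and a generator with
ρ = 0 everywhere would make the false-call criterion trivial.

Short reads are drawn from the (molecule, start) pool: each read's
retention pattern is sampled with probability proportional to the
pattern's probability times its number of eligible start positions, then
the start uniformly. This reproduces the fragment-yield∝length property
of real RNA-seq libraries and makes E[PIR] equal 100ρ exactly; sampling
one read per molecule instead would systematically deflate PIR, because
spliced molecules are shorter and would be overrepresented per position.
CIGARs are constructed from the known molecule structure and emitted as
already-aligned SAM — the aligner is out of scope, and what the pipeline
computes on is alignments. Long reads are full molecules with
per-molecule retention, 15% 5'-truncation (3'-anchored chemistry), and
±2 nt block-boundary jitter standing in for indel noise. Editing reads
draw a per-molecule haplotype from a configured distribution (default
ABD 35%, AB 25%, ABCD 20%, unedited 20%, hence site marginals
A=B=0.80, C=0.20, D=0.55, E=0) and skip the alternative exon with
probability 0.25.

All randomness flows from one master seed through fixed sub-seed slots
per (purpose, condition, replicate), so an identical configuration yields
byte-identical files; pipeline TSVs round floats to 6 decimals for
cross-platform byte stability.

**What the generator does not model** — and what passing tests therefore
do not show about real data: co-retention correlation between introns of
one gene (retention is independent Bernoulli per intron per molecule),
positional coverage and GC bias, realistic nanopore error profiles
(jitter is uniform and boundary-local), multi-mapping reads, PCR
duplicates, and incomplete or wrong annotation. Recovery results on
synthetic data demonstrate the estimators and filters are correct under
their own assumptions, not that those assumptions hold in any particular
tissue.

## Numerical and design choices

* Internal coordinates are 0-based half-open on the forward genomic
  strand; strand enters only for sequence extraction and donor/acceptor
  role assignment. GTF and GRanges conversions happen once, at the I/O
  boundary.
* `min_overhang` 8 nt for EE and EI evidence: the standard
  anti-mismapping guard; both fragments-vs-reads counting and the
  overhang are configuration-exposed since protocols differ.
* Gap matching for short-read EE evidence is exact (±0 nt): splice-aware
  short-read aligners report exact junctions. Long-read gap matching uses
  slack 10 nt for the opposite reason.
* Read pairs: mates vote independently and the fragment takes the union
  of their categories with EE > EI > IB precedence, so a retained
  molecule's two mates cannot double-count. Duplicates are not collapsed.
* The intergenic background percentile uses quantile type 6
  (median-unbiased linear interpolation): with 100 regions the threshold
  falls between the 95th and 96th order statistics, matching the
  "greater than 95% of regions" reading; the convention is recorded in
  the output object. Region sampling is uniform over valid start
  positions excluding gene spans ± 1 kb, seeded.
* Welch tests (splicing index, simplified gene-level DE) run on log2
  normalized values with a per-group variance floor of
  `(0.05 · mean)²`, keeping the statistic defined when replicates are
  exactly equal without inventing a shrinkage model; pseudocount 0.5 on
  counts before ratios. Significance uses uncorrected p-values for the
  headline flags (matching the thresholds stated with them), with a BH
  column reported alongside. `gene_de()` is explicitly a simplified
  self-contained stand-in (CPM normalization + Welch, flagged
  `welch_cpm_simplified` in its metadata) so synthetic end-to-end runs
  need no count-model machinery; it is not a negative-binomial method and
  should not be used as one.
* Fold-change thresholds are symmetric: |FC| means `max(FC, 1/FC)`.
* Zero-denominator PIRs are undefined and excluded downstream rather than
  clamped; a condition with no defined replicate is `no_data`.

## Problem sizes used by tests and the acceptance script

Module tests run on small loci (6–12 genes); the end-to-end calling check
uses a 50-gene, 4-condition × 3-replicate design (~170 introns,
~15,000 reads per sample), PIR recovery pools ~700–900 junction reads per
boundary per ρ, long-read validation uses 100 candidate introns at 20×,
editing uses 1,000 amplicon reads, Monte-Carlo checks use 200 repeats
(test power/size) and 500 (editing null), and the stop-codon scanner is
verified exhaustively through length 9 plus 1,000 random 1 kb sequences.
These sizes put binomial standard errors well inside the asserted
tolerances while keeping the full suite and the acceptance script each in
the minutes range on a single CPU.

## Known limitations

* Overlapping genes are handled independently per gene; a read inside two
  genes' introns contributes to both. The expression gate uses the exonic
  union per gene, so heavy overlap can couple the gates.
* The splicing-index formula here is normalized inclusion
  (feature/gene reads); exact equivalence with array-era splicing-index
  pipelines is not claimed.
* minPIR's small-sample negative bias (minimum of two noisy estimates)
  means very low-coverage introns read slightly low; the coverage filter
  bounds the effect but does not remove it.
* The PWM splice-site scorer shares geometry, not mathematics, with
  maximum-entropy scoring: it ignores inter-position dependence, which
  real splice sites have. Comparative use across intron classes is the
  supported interpretation.
* Editing haplotypes require reads spanning all sites; the analysis is
  amplicon/long-read by nature and refuses short-read input that never
  covers the full site cluster.
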