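---
title: "Methods: lncRNA discovery, small-RNA clusters and XUT calling"
author: "lncrnakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA discovery, small-RNA clusters and XUT calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncrnakit)
```

This vignette is the package's account of its methods: the models and
rules it implements, the tunable parameters and their defaults, what the
synthetic-data generators emulate (and deliberately do not), and the
numerical choices made where the design was genuinely open.

## The discovery funnel

A long noncoding RNA is defined operationally: a transcript absent from
the reference annotation, longer than 200 nt, with no detectable
protein-coding capacity, no known protein-domain or structured-RNA
similarity, and reproducible, stage-dependent expression. `run_discovery()`
applies these filters in a fixed order — novelty class, length, coding
potential, domain hits, expression, differential expression — and reports
the per-class funnel counts at each step. The final set is
order-independent; the intermediate counts are not, so the order is fixed
and logged.

### Novelty class codes

Assembled transcripts are compared against the reference with exonic
coordinates throughout (internally 0-based half-open; conversion to the
1-based inclusive GTF convention happens only at file boundaries):

* `=` — exon chain identical to a reference transcript (same strand);
* `J` — shares at least one internal splice junction with a same-strand
  reference transcript but differs in chain (a splice variant);
* `X` — at least 1 bp of *exonic* antisense overlap with a reference
  transcript. Exonic rather than locus overlap is required because
  intronic-only antisense overlap creates no sense–antisense RNA
  complementarity;
* `P` — same strand, no exonic overlap, 5′ end within the tandem window
  (default 2,000 bp, configurable) downstream of a reference 3′ end — a
  candidate run-on transcript;
* `U` — locus overlaps no reference gene locus on either strand
  (intergenic).

Multi-class conflicts are resolved by the fixed precedence
`=` > `J` > `X` > `P` > `U`; everything else is `other` and excluded
from the novel set. Classes J, P, U, X define the novel transcripts.

### Coding potential

The model is a logistic regression on three sequence features:

* **ORF length** — the longest sense-strand ATG→stop span over the three
  forward frames (the reverse strand is not searched, because stranded
  RNA-seq already resolves transcript orientation). The feature enters as
  `log10(length + 1)`, which tames the heavy length tail while preserving
  monotonicity, so the classification structure is unchanged.
* **Fickett TESTCODE** — the published position-bias and composition
  lookup tables, embedded as constants. For each base the position
  parameter is max phase count / (min phase count + 1) and the content
  parameter is the base frequency; both map through the published
  intervals and weights. One consequence of the +1 smoothing is that the
  statistic is only *nearly* invariant under sequence duplication: the
  position ratio shifts slightly as counts double and can cross a lookup
  cell (at most one cell, ~0.05).
* **Hexamer usage bias** — mean log(F_coding/F_noncoding) over the
  step-3 hexamers of the longest ORF (frame 0 of the full sequence when
  no ORF exists). Both corpora are counted with the same step so that
  identical corpora yield an exactly zero table; the coding corpus is
  in-frame because counting starts at the CDS start. Counts are
  pseudocount-smoothed (default 1), keeping all 4,096 entries finite.

**Threshold selection** follows the two-graph ROC rule: the cutoff where
the sensitivity and specificity curves intersect (minimize |sens − spec|,
ties broken by larger sens + spec, then by the lower cutoff). A sequence
scoring at or below the threshold is called noncoding — the boundary case
belongs to the noncoding side.

Where the threshold is *calibrated* is a real design choice. In-sample
coding scores are optimistically biased, because the hexamer table was
counted from those very sequences; a threshold balanced on training
scores is therefore imbalanced on held-out data (we observed a
sensitivity–specificity gap near 0.07). `fit_coding_model()` consequently
defaults to cross-fitted calibration: the corpus is split into 4
round-robin folds, each fold is scored by a model fitted without it, and
the two-graph rule is applied to the pooled out-of-fold scores. The
alternative `calibrate = "training"` applies the rule to in-sample
scores; `train_reference_model()` — the discovery path — uses it, as
that is how species-specific cutoffs of this kind are conventionally
chosen, and the discovery decision only needs to separate scores near 0
from scores near 1.

The **noncoding training corpus** is not prescribed by any single
convention; we use first-order Markov resampling of the coding sequences
(preserving dinucleotide composition in expectation) together with
intergenic fragments. Balanced-class training is the default. Perfect
separation — common when ORF length alone separates the corpora — is
detected and handled by a small ridge penalty (deterministic), with a
warning.

Pfam/Rfam filtering consumes a precomputed hit table and removes any
transcript with a hit at E-value strictly below 1e-10; no HMM search is
run. When no table is supplied the step is skipped with a log notice.

### Expression statistics

Counts are normalized by TMM effective library sizes (edgeR's
implementation: 30%/5% two-sided trims on M and A, reference sample by
upper-quartile proximity, factors rescaled to geometric mean 1). The
expression filter keeps transcripts with CPM strictly above 1 in at least
3 samples.

Differential expression uses a self-contained moderated two-sample t on
log2(CPM + 0.5): per-transcript pooled variances are shrunk toward a
scaled inverse-chi-square prior fitted across transcripts by moment
matching on the log scale, and the test uses the augmented degrees of
freedom. This is a faithful implementation of the standard
empirical-Bayes scheme, and the variance-shrinkage step is cross-checked
against limma's `squeezeVar` in the test suite; we do not claim numerical
identity with any published pipeline's full output. A transcript is DE
when q < 0.05 (Benjamini–Hochberg) *and* |log2FC| exceeds the fold gate.
The funnel's lncRNA filter is FDR-only (fold gate 1) across successive
developmental stages, matching the definition of the lncRNA set as
"differentially expressed in at least one stage"; the mRNA
characterization contrast uses the conventional 4-fold gate. Both are
config keys.

Stage profiles aggregate replicates by the arithmetic mean of RPKM. The
stage-specificity statistic is max expression / mean of the other five
stages (+∞ when the other five are zero; all-zero profiles are excluded),
and lncRNA versus mRNA distributions are compared with a two-sample
Kolmogorov–Smirnov test (asymptotic p).

Pairwise expression correlation uses Pearson r with the Fisher
z-transformation p-value — an exact test does not apply to r, so the
z-approximation is the interpretation of choice — and flags pairs with
|r| > 0.7 at p < 0.05.

### Coexpression modules

Networks are unsigned: adjacency |cor|^β. `pick_soft_threshold()` returns
the lowest power β whose scale-free topology fit index (sign-corrected R²
of log10 p(k) against log10 k over 10 connectivity bins) reaches the
target 0.80, or the argmax with a warning when no power reaches it.
Clustering is average-linkage on the dissimilarity 1 − |cor|^β with a
static cut at height 0.18 (the "corresponding to a correlation of 0.82"
reading of the cut); dynamic tree cutting is deliberately not used, so
the cut height has a direct correlation interpretation. Singleton
clusters are labeled unassigned (module 0) — with a cut height of 0 every
transcript is its own singleton and the whole set is unassigned. Module
stage profiles are reported as Z-scored means.

## Small-RNA clusters

Reads are filtered to 17–27 nt with a 5′ U (plus-strand reads starting on
a reference T; minus-strand reads ending on a reference A). Cluster
calling is strand-agnostic — sRNA duplexes span both strands — and
operates on per-base read depth: maximal runs with depth ≥ `mincov`
(default 20) become islands, and islands separated by at most `pad`
(default 22) bp merge, so a 22 bp gap merges and a 23 bp gap splits.
`mincov` is interpreted as per-base depth, matching coverage-based
callers. Ranking is by read count with a deterministic leftmost
tie-break. Read-category fractions assign each read by its 5′-end
position against gene *loci* (not exons, since sRNAs may derive from
unspliced precursors): `overlapped` where genes are annotated on both
strands, else `coding`/`noncoding`, else `intergenic`. The nearest coding
gene to a cluster is found by center-to-locus distance (0 inside the
locus, else distance to the nearer edge; ties to the leftmost gene); the
cluster CPM denominator is the filtered 5′-U read count (config flag).

## XUT calling

Xrn1-sensitive unstable transcripts are transcripts elevated in a Δxrn1
mutant after controlling for the global expression shift that
exonuclease loss induces. The normalization anchor is a housekeeping set
of ribosomal-protein (RP) genes: per stage, the factor is the *median*
over RP genes of mutant/WT mean RPKM (median rather than mean for
robustness to outlier RP genes), and WT RPKM is multiplied by it before
testing. Per stage, the moderated t on log2(RPKM + 0.5) compares the
genotypes; a transcript is a XUT when the normalized mutant/WT fold is
strictly greater than 3, q < 0.05, and its mutant mean RPKM is at least
3.0 (a floor that removes noise-driven folds at low abundance; the
boundary value 3.0 is kept). The result is the union over stages with
per-stage provenance. Stage factors are estimated independently.
Assignment to a reference transcript requires a same-strand exonic
overlap covering strictly more than half the XUT's exonic length (ties:
larger overlap, then leftmost); the lncRNA flag requires same-strand
exonic overlap above half the shorter transcript.

## What the synthetic data emulates

The generators plant every structure the pipeline is supposed to
recover, at study-like conditions chosen once:

* **Genome** (`simulate_genome_and_annotation`): 4 chromosomes of 300 kb,
  120 genes with 1–5 exons on both strands, intergenic gaps lognormal
  with median ≈ 1 kb (gene-dense, fungal-like), ~92% of genes coding with
  a planted ORF ≥ 303 nt built from non-stop codons (verified by direct
  translation in the tests). Noncoding entities — noncoding reference
  genes and the sequence under planted U/P/X transcripts — are
  rejection-sampled so their sense-strand ORF stays ≤ 150 nt, which keeps
  "noncoding" a property of the sequence rather than a label.
* **Assembled transcripts** (`simulate_assembled_transcripts`): per-class
  constructions with recorded truth — exact copies (`=`), terminal-exon
  extensions of multi-exon coding genes (`J`, coding), mono-exon
  transcripts in the tandem window (`P`), in gene-free space clear of all
  tandem windows (`U`, including a few sub-200-nt ones that exercise the
  length floor), and antisense transcripts overlapping a coding exon by
  more than 150 bp (`X`). The planted lncRNA set is the noncoding novel
  transcripts above 200 nt.
* **Stage counts** (`simulate_stage_counts`): negative-binomial counts
  (dispersion 0.1, the standard bulk RNA-seq figure) over 6 stages × 3
  replicates with mild lognormal library-size variation. Planted lncRNAs
  follow 7 archetypes — a peak at each of the six stages (fold 8) plus a
  late-induction profile rising through the second half to a definite
  final-stage peak — with 40% assigned to the meiotic-stage (S4) peak.
  Every planted lncRNA carries a stage-specific archetype and a baseline
  high enough to be quantifiable; a "planted lncRNA" that cannot be
  measured would contradict its own definition, which includes the DE
  filter. Earlier designs using a smooth geometric ramp (1.52-fold per
  step) produced planted lncRNAs genuinely undetectable by
  successive-stage testing at n = 3 — that is a property of shallow
  monotone profiles worth knowing about, but it makes an archetype
  unusable as planted truth for a funnel that requires DE.
* **Small-RNA reads** (`simulate_srna_reads`): 12 windows of 250 bp with
  1,500 reads each (post-filter depth ≈ 100, comfortably above 3×
  `mincov`), read lengths uniform on 17–27 nt, and a planted 5′-U
  fraction of 0.76 — the midpoint of the 70–82% range typical of fungal
  sRNA libraries — imposed by sampling read starts from U/non-U start
  positions; background reads (including out-of-range lengths) are
  Poisson-scattered at 2e-5/bp, far below calling threshold.
* **Xrn1 experiment** (`simulate_xrn1_experiment`): 1,500 transcripts,
  124 RP genes, 100 XUTs at folds 4–8 applied at both stages, 10
  low-abundance decoys under the RPKM floor. Only XUTs change in true
  abundance; the global confounder is planted in the *reported
  mapped-library sizes* of the mutant samples. This is the mechanism by
  which such a shift is visible at all: RPKM computed on within-annotation
  totals is compositional, and a shift applied to every transcript's
  abundance cancels identically — it can only surface through a
  denominator that is not the sum of the quantified counts, as a real
  total-mapped-reads denominator is not. RP genes are given a lower
  dispersion (0.02) than the rest (0.1): their low biological variance is
  precisely the property that qualifies housekeeping genes as
  normalization anchors. The recovered factor still sits slightly below
  the planted shift because the XUT excess mass inflates mutant totals
  (a ~2% compositional bias at the default XUT mass).

What the generators do **not** emulate: read-level sequencing (no FASTQ,
no alignment or assembly errors, so class codes are exact where real
assemblies are noisy), positional coverage biases, isoform mixtures
within a locus, batch structure, and any correlation between coding
potential and expression. Passing the planted-truth tests therefore
demonstrates that the *rules and estimators* are implemented correctly
and recover clean planted signal — not that the pipeline is robust to
assembly artifacts or degraded libraries.

## Numerical choices and degenerate inputs

* Ties in two-graph threshold selection resolve to the lower cutoff;
  probability exactly at the threshold is noncoding; overlap exactly
  100 bp is lincRNA; coverage exactly 50% is unassigned; mutant RPKM
  exactly 3.0 is kept; a gap exactly `pad` merges. All boundary
  conventions are tested exactly.
* `max_mean_ratio` returns +∞ when only one stage is expressed and
  excludes all-zero profiles; KS uses the asymptotic p; Pearson on
  constant vectors is an error, not NA.
* The moderated t falls back to an infinite-prior (fully pooled) variance
  when the log-variance moments are degenerate; the trigamma inverse is
  a Newton iteration to 1e-10.
* Perfect separation in the logistic fit switches to ridge
  (λ = 1e-3, deterministic) with a warning.
* All generators take explicit seeds, use only R's RNG, and emit
  byte-identical files on re-runs; fold assignment in cross-fitted
  calibration is round-robin, not random, so fitting is deterministic
  given the corpus order.

## Problem sizes used in the tests

The suite exercises each claim at sizes chosen for tight statistical
margins: class-code fuzzing over 540+ oracle comparisons per run; the
coding benchmark at 500 training / 500 held-out sequences per class; TMM
recovery on 6,000 genes at dispersion 0.005 with 5% ten-fold asymmetric
contamination (the trimmed-mean estimator carries a truncation bias
proportional to the M-value noise sd under one-sided contamination, so
the noise level sets the attainable accuracy); DE recovery over 50
replicates of 400 genes; module recovery on two 20-transcript blocks at
within-block r ≈ 0.95; XUT recovery at the full 1,500-transcript design.
The end-to-end funnel is checked for exact set equality with planted
truth and for byte-identical re-runs.

## Known limitations

* Class codes cover `=`/J/P/U/X plus a catch-all `other`; finer
  containment codes of assembler vocabularies are deliberately collapsed.
* The coding model is trained per genome and its threshold is
  data-dependent; thresholds are not transferable between species, and
  the package makes no attempt to reproduce any particular published
  cutoff value.
* The moderated t assumes approximately normal log-CPM within groups; at
  very low counts (< ~5) its variance model is optimistic, which is why
  planted experiments keep quantifiable baselines.
* Neighbor-context relations assume a single dominant transcript per
  gene; overlapping gene models on the same strand can yield several
  contexts for one lncRNA, all of which are reported.
* Static-height tree cutting cannot separate nested correlation
  structure; that is the price of the cut height's direct interpretation.
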