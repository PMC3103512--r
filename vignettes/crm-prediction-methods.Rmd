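---
title: "Predicting conserved cis-regulatory modules: models, parameters and calibration"
author: "crmpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting conserved cis-regulatory modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmpred)
```

## The problem

Enhancers that drive reporter expression in defined embryonic structures
are rare, and finding them by promoter bashing is slow. A practical
computational shortcut is to look for *clusters* of transcription-factor
binding sites (TFBSs) that have been preserved by purifying selection:
individual motif matches are ubiquitous by chance, but a group of
conserved matches confined to a short non-coding window is a strong
candidate cis-regulatory module (CRM). `crmpred` implements this strategy
for a teleost reference genome compared against three other teleosts, with
a second, stricter pan-vertebrate filter against human, and the downstream
statistics used to characterize the predictions and to triage them into an
injection-based enhancer assay.

## Models and procedures

### Motif model and scanning

A PWM is stored as per-position base probabilities after adding a
pseudocount of 0.01 to every count cell; this keeps all log-odds entries
finite without noticeably distorting informative positions. Scores are
log-odds in bits against a **uniform** background,
$s(i,b) = \log_2 (p_{ib} / 0.25)$. A uniform rather than local-GC
background makes scores comparable across the genome and is the convention
the rest of the scoring (thresholds, cluster sums) assumes.

Scanning covers both strands (the reverse strand via the
reverse-complemented matrix) and skips windows containing `N` or
overlapping a masked interval. Masks come from two sources that are
deliberately merged: lowercase (soft-masked repeat) runs in the FASTA and
annotated CDS intervals, restricting predictions to non-coding,
non-repetitive sequence.

The per-matrix hit threshold is a *fraction* of the maximum achievable bit
score, default 0.75. The default is intentionally permissive: individual
hits are not the selective step of the method — cluster scoring is — so the
scanner is tuned to keep marginal sites that conservation and clustering
can later corroborate. The fraction (and an absolute override) is exposed
in every scanning entry point.

### Conservation weighting

Each reference hit is projected through pairwise alignment blocks into
each comparison genome. Blocks carry a per-base monotone offset map
(CIGAR-like `M`/`D`/`I` runs); the package reads both MAF and a simple TSV
block dialect. Around the projected position a window of ±20 bp is
rescanned with the same matrix on either strand; binding-site orientation
is allowed to flip because inversions preserve function at this scale.
The combined score is

$$\mathrm{hitScore}_{aln}(m,p) = \mathrm{hitScore}_{ref} +
\max_s \max\{0,\ \mathrm{hitScore}_s - \lambda\,|\delta_s|\}$$

over the comparison species $s$ with misalignment offsets $\delta_s$. Two
design choices deserve comment:

* **Penalty form.** The method tolerates but penalizes misalignment; the
  penalty's functional form is an open choice. We use a linear
  λ bits/bp with λ = 0.1, floored at zero, because it is the simplest form
  with the right limits: λ = 0 reduces to pure eligibility within the
  20 bp window, large λ reduces to exact-position conservation. λ is a
  config parameter.
* **Absent support contributes 0**, so a strong reference hit can pass
  without conservation — conservation raises scores rather than gating
  them.

On ties among species the reported supporting species is the first in the
fixed order tetraodon, stickleback, fugu, for reproducibility; the score
itself is tie-free by construction (a max of values).

### CRM calling

Within each sequence, every run of positionally consecutive conserved hits
whose span fits in `window_bp` (default 1000) is a candidate cluster.
Window scores distinguish two regimes:

* **oligotypic** (≥ 2 distinct matrices): sum of the best hit per matrix
  over the top K = 5 matrices — one contributing hit per tag matrix;
* **homotypic** (single matrix): sum of the top K hits of that matrix, so
  single-factor clusters, which are biologically common, are not starved
  relative to oligotypic ones.

Candidates need at least `min_hits = 3` conserved hits and a score of at
least `score_threshold`; selection is greedy by descending score (leftmost
wins ties) under non-overlap, and each selected CRM is trimmed to its
outermost contributing hits. An early design used anchored fixed-width
windows (anchor + 1 kb); that lets a single distant background hit of a
second matrix demote a homotypic cluster into the oligotypic rule, and was
replaced by the consecutive-run enumeration above.

**Threshold calibration.** `score_threshold` defaults to 41 bits, fixed by
`calibrate_score_threshold()` at a 1% window-level false-positive rate on
the *null fixture*: bundles generated with zero planted clusters (so only
background hits exist), hit positions shuffled over the scannable space,
pooled over 30 null genomes of 100 kb each. The null candidate windows'
99th percentile was 40.7 bits. Calibrating on a null that includes planted
clusters would recycle their strong sites into chance windows and push the
quantile into the range of genuine clusters; the zero-planted null is the
correct model of a spurious call, which is a cluster of background hits.

Close-by CRMs (gap ≤ 500 bp) are fused and regions extended by 200 bp per
side, clipped at sequence ends, to form the regions cloned into the assay.

### Pan-vertebrate filter

Each CRM is anchored to the human orthologous neighborhood: the closest
reference gene (by midpoint-to-span distance) that has a human ortholog H
defines a search interval from H's left-flanking to right-flanking gene,
padded by 10 kb (the padding is a package choice; the flanking-gene rule
defines the neighborhood). The CRM sequence is locally aligned to the
interval on both strands under HOXD70 with affine gap costs 400 (open) and
30 (per bp), the scoring scale on which the conservation thresholds are
meaningful; `Biostrings::pairwiseAlignment` provides the Smith–Waterman
engine. A CRM passes only when the alignment score is **strictly** greater
than 2600 and percent identity over aligned columns (gaps included)
**strictly** greater than 60 — boundary values fail, and the tests pin
this with constructions scoring exactly 2600 and exactly 60% identity.
Passing CRMs are ranked by CRM score (ties by genomic position); candidate
lists are the top 10 and the fixed rank positions
20, 40, 60, 81, 100, 120, 140, 159, 180, 200 — taken verbatim, including
81 and 159, rather than regularized to multiples of 20.

### Genomic context

CRMs are summarized by their midpoint, which avoids length-induced bias.
TSS distances are binned half-open at 1, 10 and 100 kb; the gene-relative
class is intragenic when the midpoint lies in a gene span, otherwise
intergenic split at 100 kb from the nearest gene *boundary* (boundary
rather than TSS — flagged as a convention choice). Significance comes from
100 randomizations drawing the same number of intervals with the same
length multiset uniformly over the scannable (unmasked) space, matching
the prediction domain; placements overlapping masks are redrawn. Empirical
p-values use the add-one rule $(r+1)/(n+1)$, so with 100 randomizations
the smallest attainable p is $1/101 < 0.01$ and "p < 0.01" corresponds to
an observation outside all 100 nulls. By default the one-sided direction
follows the observed deviation; a fixed direction is available and is what
the calibration tests use, since a data-driven direction is by design
conservative near the null.

### Tissue enrichment

Expression terms from a richly annotated source species (zebrafish) are
transferred to reference genes through an ortholog map, keeping only the
highest-identity reference gene per source gene. Term sets are closed over
an explicit parent table ("a tissue and its subparts"); full OBO parsing
is out of scope, the closure table is the interface. Each CRM inherits the
terms of the closest flanking gene by midpoint distance, *independently of
the distance* (ties go to the upstream gene). For every term×stage pair
annotating at least 20 conserved CRMs, a 2×2 table (conserved vs
background × annotated vs not) is tested with a one-sided Fisher exact
test in the enrichment direction, computed as the exact upper
hypergeometric tail; the background is the whole predicted set minus the
conserved subset, as stated. Benjamini–Hochberg control at 5% FDR is
applied jointly across all retained term×stage pairs — the joint choice is
the conservative reading of an ambiguous convention and is stated here.

### Assay quality control

The minimal promoter's intrinsic lens expression reports injection
success, which separates injection failure from true lack of enhancer
activity. Per region, `injection_rate = n_lens / n_alive` and
`specific_rate = n_specific / n_lens`; a region is positive when the
specific rate is strictly above 0.5 **and** at least 10 fish show the
consistent pattern. Rates are pooled per region rather than per injection
batch. Sporadic enhancer-trap expression (single embryos) is excluded
upstream of `n_specific` and carries no separate statistic. Ontology
coverage divides the number of vocabulary terms labeled in at least one
line by the vocabulary size and **floors** the percentage —
20 of 32 gives 62 — a rounding convention chosen deliberately and noted
here because `round()` would give 63.

## The synthetic fixtures

`generate_fixture()` builds a deterministic bundle from a `fixture_spec()`:
the default conditions are a 100 kb reference (2 × 50 kb) with 12 genes of
2 kb, 10% repeat masking, and 10 planted site clusters across 4 species.
Planted clusters alternate homotypic (one matrix) and oligotypic (5
distinct matrices) with 6 consensus sites each, spaced 2–20 bp apart;
sites carry a per-base mutation rate of 0.05, chosen so a site typically
clears the 75% hit threshold (one mutation passes, two do not).
Comparison-species copies exist in 2 of 3 species per cluster, at planted
offsets up to 15 bp, with 0.05 additional divergence; comparison
backgrounds are otherwise independent, so support exists exactly where it
was planted. Alignment blocks are whole-sequence identity maps, emitted in
both MAF and TSV to exercise both readers. Four clusters carry an
85%-identity copy in a mirrored human neighborhood, comfortably above the
2600/60% bar for ~130 bp regions, while chance motif sharing between
clusters stays below it (the 2–20 bp spacing randomization makes chained
single-motif alignments pay full affine gap costs). Gene, ortholog,
annotation and injection tables are emitted alongside, with ground truth
in JSON.

What the fixtures do **not** emulate: realistic neutral evolution (no
phylogeny-aware substitution model, no indels within sites), realistic
repeat structure, gene-density heterogeneity, or the genome-scale hit
statistics of a 700 Mb assembly. Passing the planted-recovery tests
therefore shows the machinery is correct and calibrated under controlled
signal/noise, not that real-genome precision would match.

Problem sizes throughout (100 kb fixtures, 30 null genomes for threshold
calibration, 200 datasets × 100 randomizations for the uniformity check,
2×2 tables with totals up to 50 for the exact-test comparison) were chosen
as the smallest sizes at which the corresponding statistics are stable;
they are the package's reference conditions, not tuned per run.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; 1-based closed only at the
  GFF3 boundary and inside `IRanges` calls.
* Overlapping same-matrix hits are all kept at scan time; deduplication
  happens implicitly at CRM scoring (best-per-matrix / top-K).
* Empty inputs return empty, typed results rather than errors (empty hit
  list → no CRMs; empty CRM set → count 0 with `NA` summaries; no
  scorable injections → zeros with a warning).
* Sequences without genes classify their CRMs into the most distal
  location classes, with a warning.
* `p = 0` is impossible in randomization tests by the add-one rule;
  Fisher p of a term annotating everything is exactly 1.
* Ties: greedy CRM selection prefers the leftmost window at equal score;
  equidistant closest-gene ties go to the upstream gene; species-support
  ties report the first species in fixed order.

## The null-uniformity calibration

The location randomization is checked against its own null: datasets drawn
by the null generator itself must give approximately uniform empirical
p-values. Because the test statistic is a count fraction, the add-one p is
exactly uniform on its lattice only without ties; tie mass between the
observed count and null counts biases p upward. The calibration design
therefore uses a dense gene grid (25 genes every 4 kb, putting the <1 kb
TSS bin near probability 0.5) and 400 regions, making the count
fine-grained enough that a Kolmogorov–Smirnov test against the uniform has
no detectable deviation at the sizes used (200 datasets of 100
randomizations each, fixed direction).

## Known limitations

* The clustering scheme is a windowed top-K summary, not a probabilistic
  segmentation; scores of overlapping candidate windows are resolved
  greedily.
* The conservation step rescans projected windows rather than consuming
  precomputed comparison-genome hit lists; identical by construction, but
  it assumes the comparison genomes are available at run time.
* BLASTZ itself is not reimplemented; the Smith–Waterman/HOXD70/affine
  configuration reproduces its scoring scale on region-sized inputs only.
* Genome-scale quantities (tens of thousands of CRMs, genome-wide
  intergenic percentages, published enrichment p-values) require the full
  assemblies and annotation databases and are outside the package's
  reference conditions; the package reproduces the method's structure and
  its desk-scale statistics.
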