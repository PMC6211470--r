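---
title: "Evidence-based annotation curation: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-based annotation curation: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annocurate)
library(dplyr)
```

This vignette is the package's own account of the science it implements:
the data model, the confidence tiers and curation rules, the evaluation
statistics, the expression-comparison methods, and — because several of
these procedures are stated in the literature without operational detail —
the design choices we made where the design was genuinely open.

## The data model

An annotation is a tibble with one row per exon. Coordinates are 0-based
half-open throughout; the GFF3/GTF readers and writers convert from and to
the 1-based closed on-disk convention, and BED12 block arithmetic is
expanded on read. A single internal convention removes the whole class of
off-by-one bugs that plague mixed-coordinate pipelines; the round-trip
(write then read) is bit-exact and is tested property-style on generated
annotations.

Evidence alignments are the same exon tables plus an `evidence_class`
column — `cDNA`, `EST`, `RNAseq` (with a mandatory `tissue` label),
`protein`, `RefSeq`, `NCBI`, `other_species_refseq` — reflecting the
priority order in which annotators weigh sources: cDNA above EST above
high-confidence RNA-seq and curated annotations, above protein and
other-species annotations.

Overlap computations are strand-aware by default, with `"."` matching
either strand; every overlap entry point takes `stranded = FALSE` because
the strandedness of such comparisons is a convention, not a law. Interval
unions and intersections are computed by sorted sweep + two-pointer
merging; tests compare them against literal per-base set intersections.

## High-confidence RNA-seq and support profiles

Assembled RNA-seq transcripts are noisy; a structure is only trusted when
it recurs in **two or more distinct tissues** (replicates of one tissue do
not count). Recurrence means an identical intron chain for multi-exon
transcripts. For single-exon transcripts there is no intron chain to
compare, so we use **90% reciprocal exonic overlap**, borrowing the
magnitude of the exon-detection threshold used elsewhere in the pipeline.
The filter is idempotent: its output passes through unchanged.

A model's support profile is, per evidence class, the fraction of its
exonic bases covered by the **union** of the class's alignments —
fragments union, never sum, so two ESTs covering disjoint halves give
coverage 1.0. A class supports a model at coverage ≥ `support_threshold`.
Only the reference-annotation threshold (70% of model length) is
quantified in the guidelines we implement; we apply the same 70% to every
class as the default and expose it as a parameter. "Independent pieces of
evidence" counts supporting **classes** among {cDNA, EST, high-confidence
RNA-seq} (protein optionally, `count_protein = TRUE`) — never annotation
classes, and never individual alignments.

## The four confidence tiers

* **Level 1** — reference coverage > 0.7 *and* ≥ 2 independent evidence
  classes.
* **Level 2** — reference-supported but lacking the two independent
  evidences.
* **Level 3** — ≥ 2 independent evidence classes, no reference support.
* **Level 4** — exactly one piece of evidence, no reference support.

Two gaps in the published tiers had to be closed. First, a model supported
by the reference plus exactly one evidence class belongs to no tier as
literally stated; we assign it to level 2 (reference-dominated,
insufficient independent evidence). Besides completing the partition, this
choice keeps the whole engine idempotent: terminal-end repair lengthens
models, which can push a fragmentary EST's *fractional* coverage below
threshold, and under the alternative reading such a model would fall from
level 1 to level 4 — and be deleted — on a second pass. Second, models
with no support at all are flagged `unsupported` (level `NA`) rather than
forced into level 4; they are excluded from curated output like level 4.

## The curation rules

Level 1 reconciles a model with its matched reference model: identical
structures are kept (1.1); same intron chain but shorter ends take the
longest 5′/3′ coordinates among the reference, the model itself, and
compatible cDNA/EST/high-confidence RNA-seq alignments (1.2); different
structures go to whichever candidate is matched by more evidence
alignments, the reference winning on total absence of support (1.3);
multiple overlapping reference models are merged by exon union when they
are transcripts of one gene, otherwise the most-evidenced one is used
(1.4). End adjustment is strand-symmetric: both ends take their outermost
supported coordinate, so the minus-strand 5′ end (highest genomic
coordinate) needs no special casing — a property the tests check by
mirroring a plus-strand case.

Level 2 (reference-only models): duplicated gene ids collapse onto the
model flagged best-reference — we require the flag in the input and keep
all duplicates when none carries it, since no fallback selection is
defined; unsupported single-exon models are deleted, where "supported"
here means *any* overlapping evidence alignment (a threshold-based reading
would be vacuous: level-2 models have no threshold-level evidence support
by definition); introns that every evidence class present treats as exonic
are merged; any structural disagreement escalates the model to the level-3
rules, with the matched reference models joining the terminal-end donor
pool (they are the defining evidence of a level-2 model; this also makes
the escalated path agree with rule 1.2 should the model later qualify for
level 1).

Level 3 (novel models) applies, in order: structure replacement by the
longest other-evidence-backed cDNA when all overlapping cDNAs contradict
the model (3.4); evidence-agreed intron mergence and model separation
(3.5); exon addition (3.2); deletion of exons with no overlapping evidence
(3.3); terminal-end adjustment (3.1); and, across surviving level-3
models, isoform merging (3.6). The published order of these rules is not
stated; this order prevents deleted exons from re-triggering additions and
lets end re-adjustment see the final internal structure.

Three more choices deserve a note:

* **Exon addition** is listed as "any of" three criteria, but the first
  (one transcript evidence) subsumes the third (two transcript evidences),
  which makes the literal reading redundant. The default is the only
  non-redundant reading — (≥ 1 transcript evidence AND ≥ 1 independent
  annotation) OR ≥ 2 transcript evidences — with
  `addition_rule = "any"` preserving the literal one. Candidate exons are
  clustered at 90% reciprocal overlap; the inserted representative comes
  from the highest-priority class, ties to the longer exon, then the
  smaller start.
* **Isoform merging** needs an "overlap rate" whose denominator is
  undefined; we use genomic-span overlap relative to the **shorter** span,
  strict `> 0.7`.
* **Evidence agreement** for merge/split means: every class with at least
  one overlapping alignment agrees; absent classes abstain.

The engine visits models in (chromosome, span start, id) order and uses no
randomness, so identical inputs give identical outputs; a second pass is a
no-op on all generator fixtures. Both properties are asserted over seeded
fixtures in the test suite, along with the audit-trail guarantee that no
curated exon lacks an overlapping evidence or reference feature.

## Congruency

For annotation unit $i$ and evidence $j$: $SN = |i \cap j|/|j|$,
$SP = |i \cap j|/|i|$, $C = (SN+SP)/2$, with $|\cdot|$ counting bases.
Base sets are **exonic** even at "full gene length" level: cDNA, EST and
RNA-seq evidence cannot cover introns, so a span-based sensitivity would
saturate trivially; `congruency_pair(span = TRUE)` gives the literal
genomic-span reading. At gene level each model is paired with its
best-matching alignment per class (maximum $C$); how a gene should be
matched to one of many alignments is otherwise unspecified. At exon level
$j$ is the union of the class's exons overlapping the annotated exon.
Units with no overlapping evidence contribute (0, 0, 0) records — dropping
them would inflate the cumulative curves that compare annotation versions
(`cumulative_congruence()`, a survival curve on a 0.01-step threshold
grid).

## The assembly-stringency sweep

A reference exon is **detected** when strictly more than 90% of its bases
are covered by assembled exons, and **precisely detected** when its
matched assembled exons keep strictly less than 10% of their bases in
reference non-exonic space ("intron pollution"). Both inequalities are
strict, following the "more than"/"less than" phrasing of the definitions.
The 10% is computed on the assembled exons' bases by default — a reference
exon cannot intersect non-exonic regions of its own annotation, so the
sentence defining PDE only makes sense with the assembled exons as
denominator; `denominator = "refseq_exon"` selects the other reading.
Sensitivity is DE/MDE with MDE the count at the default (most permissive)
stringency; precision is PDE/DE, undefined (NA) when nothing is detected.
The selected stringency is the argmin of |precision − sensitivity|, ties
toward the smaller value.

The sweep generator plants a crossing: sensitivity decays as
$1 - a\sqrt{t}$ over the grid (steep where assemblies are permissive),
precision rises linearly through the crossing point. Because MDE pins
sensitivity to 1 at the default stringency, a strictly increasing
precision can never cross it there — the generator refuses a crossing at
the default value, and verifies after integer rounding that both curves
are strictly monotone and the argmin sits exactly at the requested
crossing, erroring when the reference exon count is too small to support
that (precision is quantized in units of 1/DE).

## Expression comparison

RPKM is `count × 1e9 / (length × library size)`. Quantile normalization
maps every sample onto the per-rank mean of the sorted columns, ties
receiving the mean of the reference values they span (the common
convention; the implementation delegates to limma's, which matches it).
Complexity curves average a tissue's samples, sort decreasing, divide by
the total and cumulate; they are non-decreasing, concave-incremented and
end at 1 by construction, and `complexity_summary()` reports the
genes-to-50% count that separates liver-like from cortex-like
transcriptomes. Correlations are Pearson on log2(x+1) — whether raw or
log values were intended is unstated, and log2(x+1) is the standard choice
for RPKM-scale data (`log_transform = FALSE` to disable); tissue-level
profiles average samples within (species, tissue) before the transform.
Whether clustering should use samples or tissue averages is likewise
exposed (`level`).

A tissue is **tissue-dominated** when, in both species, the nearest
neighbour (highest r) of that species' tissue profile is the same tissue
in the other species; otherwise species-dominated. This mutual
nearest-neighbour rule is our operationalization of "the same tissue of
both species clustered together"; the average-linkage dendrogram
(distance 1 − r) is attached for visual inspection.

Differential genes require a two-sided Wilcoxon rank-sum p < α (default
0.05) **and** mean fold change > 2, with a 0.01 pseudocount on both means
against division by zero. P-values come from full enumeration of group
labelings when both groups have ≤ 8 samples — valid in the presence of
ties, where the classical exact distribution is not — and from the
tie-corrected normal approximation otherwise. The two-sided value is
min(1, 2·min(lower tail, upper tail)), matching the doubling convention of
the exact test.

## What the generators emulate — and what they do not

`generate_truth()` lays non-overlapping multi-exon genes on one
chromosome. `corrupt_evidence()` gives each class its characteristic
noise: cDNAs full-length with small terminal jitter (sd 3 bp); ESTs
fragmentary (70% are consecutive-exon sub-chains, jitter sd 10 bp);
RNA-seq per tissue (70% emission per tissue, jitter sd 15 bp, 3% retained
introns, 2% false exons); reference tracks with missing genes and optional
planted terminal truncations. At zero noise every class reproduces the
truth exactly, making the whole pipeline's fixed point testable.
`generate_expression()` builds two-species tissue profiles: Zipf-weighted
dominance over a per-tissue gene ranking (exponents: liver 1.1, muscle
0.9, cortex 0.45, testis/spleen 0.6 — liver-like tissues concentrate
transcription), shared across species for conserved tissues, independently
reshuffled for 80% of genes in divergent tissues (testis, spleen), plus a
species-wide lognormal gene effect (log-sd 0.4) and replicate noise
(log-sd 0.25) over 3 replicates per (species, tissue). These scales were
chosen once as a realistic desk-scale caricature of bulk RPKM data.

The generators do **not** emulate: read-level noise or coverage,
alternative splicing beyond isoform span overlap, overlapping or nested
genes, paralogy (the ortholog map is the identity), GC or length biases in
expression, or batch effects. Passing the closed-loop tests therefore
shows the algorithms are implemented correctly and recover planted
structure under the stated noise model — not that the thresholds are
optimal for any particular genome.

## Problem sizes and numerical conventions

The test suite and the acceptance script run at desk scale, chosen to
exercise every rule while keeping a full run in minutes: 20–50 genes per
curation fixture (20 seeded fixtures for determinism/idempotence), 1000
random model pairs for the brute-force congruency comparison, 40-gene
truths (~160 exons) for sweep recovery, 400–1000 orthologs × 5 tissues ×
2 species × 3 replicates for the expression recovery checks. Default
generator scales are larger (200 genes, 1 Mb; 2000 orthologs).

Floating-point conventions: coverage and congruency are exact integer
ratios, so oracle comparisons use exact equality; complexity curves are
checked to 1e-9 at the terminal value; correlation oracles to 1e-12.
Degenerate inputs are contracts, not crashes: empty annotation files parse
to empty tables, zero detected exons give NA precision, all-zero tissues
and zero-length genes error with messages naming the offender.

## Known limitations

* Rule 1.3's "no gene model can reach this criterion" is unquantified; we
  fall back to the reference structure when neither candidate has any
  structure-matching evidence.
* The best-reference flag (rule 2.1) must be present in the input
  metadata; it is never inferred.
* Model separation (3.5) fires only when no evidence alignment crosses an
  intron while both flanks carry evidence — a conservative reading that
  will miss chimeras bridged by a single noisy alignment.
* UTR/CDS re-annotation and isoform modelling beyond span-overlap merging
  are out of scope, as are the external aligners and assemblers whose
  outputs this package consumes.
* Statistical testing of differences between cumulative congruence curves
  is left to the user; the package emits the curves.
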