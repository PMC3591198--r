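---
title: "Targeted gene-panel diagnostics for retinal dystrophies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted gene-panel diagnostics for retinal dystrophies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RetinoPanel)
```

## The diagnostic problem

Retinitis pigmentosa (RP) and related inherited retinal dystrophies are
caused by mutations in dozens of genes with autosomal dominant (AD),
autosomal recessive (AR) or X-linked (XL) inheritance, with essentially
no genotype–phenotype correlation to guide single-gene testing.  A
practical diagnostic route is a targeted capture panel: enrich the exons
(plus intron–exon boundaries, untranslated regions and proximal
promoters) of all known disease genes, sequence the enriched DNA on a
benchtop pyrosequencer, and triage the resulting variant calls down to
one or two candidate mutations per patient that can be Sanger-validated
and checked against the family.

RetinoPanel implements that computational workflow end to end: panel
target design, a pileup-level simulator of 454-style pyrosequencing
output, variant consequence annotation, a read-fraction triage cascade,
per-exon coverage analysis with coverage-based deletion detection,
pedigree cosegregation, and patient-level diagnostic classification with
cohort reporting.  A 63-gene panel catalog (942 exons) and a 23-patient
diagnostic run synopsis are packaged as plain-text fixtures so that the
cohort-level statistics can be recomputed from scratch.

## Panel design

`buildTargets()` turns gene models into capture targets using three
rules:

* each exon is extended by 50 bp on both sides, covering the
  intron–exon boundaries (and automatically the complete 3'-UTR, which
  lies inside the last exon);
* one 1000-bp promoter interval is placed immediately 5' of the
  transcription-start exon, strand-aware, covering the proximal
  promoter and the complete 5'-UTR;
* the resulting intervals are merged into a disjoint sorted cover per
  contig, with gene and origin labels unioned.

Both extents are tunable (`flankBp`, `promoterBp`, in bp).  Alternative
transcripts are handled by letting a gene model carry the union of
exon sets; targets are built from that union.  Overlapping targets of
*different* genes are also merged (interval bookkeeping treats the
panel as a base set; per-gene attribution is kept as a label union) —
the alternative, keeping per-gene duplicates, would double-count bases
in panel-size statistics.  Promoter intervals count toward the targeted
base total but never toward the exon count, which is why the packaged
catalog reports 942 exons regardless of promoter settings.

Internally all interval arithmetic uses 1-based closed
`IRanges`/`GRanges`, the native Bioconductor convention; 0-based
half-open dialects (BED, the gene-model TSV) are converted exactly once
at the I/O boundary.  Intervals that would extend below the first base
of a contig are clipped with a warning; a supplied contig length clips
on the right.

## The sequencing simulator

No public raw data accompany the diagnostic assay this package models,
so every downstream stage is exercised against a synthetic cohort
generator, `simulateCohort()`.  It emulates the *mapper output* of a
454 GS Junior run at pileup level — per-base unique depths and per-site
allele counts — rather than simulating reads and re-aligning them: the
pipeline being modelled consumes mapper output, and an aligner
re-implementation would add nothing testable.

Defaults of `simConfig()` are the run characteristics of the assay
being modelled:

| parameter | default | meaning |
|---|---|---|
| `readLenMean`, `readLenSd` | 408, 48 bp | Normal read-length profile of the pyrosequencer |
| `readLenMin` | 50 bp | truncation of the length distribution |
| `meanExonDepth` | 17 fold | expected per-base depth of a well-captured target (the observed cohort-median coverage) |
| `depthDispersion` | 0 | 0 = Poisson depths; > 0 switches to negative binomial |
| `gcDropoutThreshold`, `gcDropoutFactor` | 0.70, 0.2 | targets above 70% GC capture at 20% efficiency — GC-rich first exons are the classic capture failure |
| `subErrorRate` | 1e-3 | per-base probability of a spurious substitution row |
| `homopolymerIndelSlope` | 0.01 | per-run indel error probability `min(0.5, slope * (L - 1))` for a single-base run of length L |
| `hetAltFraction`, `homAltFraction` | 0.5, 0.99 | expected variant-read fraction for heterozygous and homozygous/hemizygous calls |

The homopolymer error model is this package's own construction —
pyrosequencing is known to be indel-prone in single-base runs, but no
quantitative per-run rate is published for this assay — so a monotone,
bounded form in run length was chosen with a small default slope.
Spurious rows (both substitution and homopolymer) carry
supporting-read counts drawn as Binomial(depth, 0.1), truncated to at
least one read, so that error rows concentrate well below the 20%
triage threshold, as real mapper noise does.  Hemizygous X-linked
variants in males use the homozygous fraction: there is only one
allele.  A `multi_exon_deletion` truth variant zeroes the depth across
its exon span and emits *no* variant row — such events are only
discoverable from coverage, which is exactly the failure mode the
coverage module exists for.

All randomness flows from one integer seed; each sample's draws come
from a substream derived from the seed and the sample index, so cohorts
are reproducible sample by sample.

What the simulator does *not* emulate: flowgrams/quality-score
distributions (the per-base quality column is a constant placeholder,
since the modelled workflow never consumes it), emulsion-PCR
duplicates, alignment artefacts, and allele-specific capture bias.
Consequently, green tests demonstrate correctness of the *pipeline
logic* under the stated statistical model, not robustness to every
artefact of real 454 data.

## Variant annotation

`classifyConsequence()` maps a variant onto a gene model, labels its
region (coding, 5'/3'-UTR, promoter, intronic/flank), and for coding
variants translates the affected codon(s) before and after the change,
strand-aware, with the standard genetic code.  Indels are classified by
length modulo 3.  Protein changes use the short panel nomenclature
(`p.RP2-E20X` style, `X` for a stop), with `del`/`dup` suffixes for
in-frame losses and duplications and `_ins<n>bp` for other in-frame
insertions.  A variant whose reference allele does not match the
reference sequence is an error, not a silent skip; a variant spanning a
splice boundary is labelled `intronic_flank` with no protein effect
(splice-effect prediction is out of scope).

Known-SNP filtering (`isKnownSnp()`) requires an exact
(contig, position, ref, alt) match: positional matching would discard
novel alleles arising at known polymorphic sites, and novel alleles are
precisely what a diagnostic panel is looking for.

The deleteriousness score is pluggable.  The default stands in for an
external protein-impact predictor, which cannot be a dependency of a
reproducible pipeline: Grantham distance for missense changes, the
maximal score (255) for truncating ones, an intermediate 100 for
in-frame indels.  Any scorer with the same signature can be injected
into `annotateVariants()`.

The "repetitive sequence" flag is operationalized as: the variant lies
in, or immediately adjoins, a single-base run of at least 6 bp
(`maxRun = 6`).  No precise criterion is published for the workflow
being modelled; 6 bp is where pyrosequencing indel rates become
problematic in practice, and the threshold is a parameter.

## The triage cascade

`filterCascade()` applies, in order: (1) restrict to coding variants;
(2) remove known SNPs; (3) keep protein-changing effects; (4) apply the
read-fraction threshold; (5) rank the survivors.  The counts of every
stage are recorded in a `FilterTrace`, mirroring the per-patient columns
of the packaged cohort synopsis (total → coding → protein-changing →
prioritized).  The stage order is fixed; the fraction step sits after
the consequence step so that the threshold acts on the candidate set
that would otherwise go to Sanger validation.  Frameshifts and in-frame
indels are retained alongside missense/nonsense because validated panel
mutations include duplications and insertions.

Three threshold policies are provided:

* **fixed** — 20% of reads must support the variant (the working
  threshold of the modelled assay);
* **stringent** — 35%, motivated by heterozygous candidates at 21–23%
  that failed Sanger validation;
* **dynamic** — start at 50% and descend in 5% steps until one or two
  candidates survive, never below a 20% floor.  The step size is this
  package's choice (no published value); the floor equals the fixed
  threshold so the dynamic policy can never be more permissive than the
  fixed one.  Comparisons use fraction ≥ threshold with a 1e-9 guard
  against floating-point drift on the 0.05 grid.

Ranking is lexicographic and deterministic: known-reported mutation
first, then compatibility with the inheritance hint (AR requires a
homozygous call or ≥ 2 heterozygous calls in one gene — a
compound-heterozygote candidate; phase is unknowable from the assay and
is not required), then deleteriousness score, then read fraction, with
(contig, position) as the final tie-break.

## Coverage analysis and deletion detection

`summarizeExons()` computes per-exon mean/median unique depth over exon
bases only — the ±50 bp flanks are excluded so that "exon coverage"
statements match exon-level bookkeeping — and flags exons whose every
base has zero depth.  Exons are indexed in transcription order (exon 1
is 5'-most), the convention used in clinical deletion nomenclature.
`cumulativeCurve()` reports, for every integer fold x from 0 to the
maximum observed depth, the percentage of targeted bases with depth
≥ x; off-target rows are dropped first.  `patientMedianDepth()` is the
median over targeted bases.  A cohort median can be taken either over
all pooled bases or as a median of per-patient medians; the two are not
identical, and the package computes per-patient medians, leaving
pooling to the caller.

`detectDeletions()` separates the two causes of a zero-covered exon.
An exon dead in *every* sample is a technical failure of the panel
(typically GC-rich first exons).  An exon zero-covered in the focal
sample but well-covered in the rest of the cohort is a deletion
candidate: the criterion is that at least `minSupport = 0.8` of the
other samples cover the exon at median depth ≥ `minCohortDepth = 5`.
Both thresholds are this package's own operationalization — the
distinction is made narratively, not numerically, in the clinical
literature — chosen so that a small cohort (10 samples) with one poorly
sequenced member still classifies correctly.  Consecutive candidate
exons within one gene merge into a single multi-exon candidate, which
is how a 3-exon genomic deletion presents.  The two output lists are
disjoint by construction.  Read-depth CNV segmentation (HMM/CBS) and
breakpoint resolution are out of scope: at 17-fold Poisson coverage the
all-zero signature is the reliable one.

## Cosegregation and diagnostic classes

`cosegregates()` tests a candidate against a genotyped family under
full penetrance and no phenocopies (a documented simplification that
matches how cosegregation is used qualitatively in diagnostic
practice): AD — every affected member carries, no unaffected member
does; AR — every affected member is homozygous (or carries both
members of a supplied compound-heterozygous pair), no unaffected member
is; XL — affected males hemizygous, unaffected males non-carriers,
affected females homozygous, unaffected females at most carriers.  With
no genotyped non-proband relative the answer is `unknown`, not a guess.
A homozygous child of two genotyped reference parents triggers a
Mendelian-inconsistency warning.

`classifyPatient()` is a deterministic decision table from an
eight-value evidence category to four diagnostic classes:

| evidence category | class |
|---|---|
| cosegregates | definite |
| family_unavailable, digenic_candidate | potential |
| reported_dominant_unconfirmed, healthy_carrier_relative | questionable |
| non_segregating, single_het_recessive, none_found | unsolved |

The category enum makes the clinical narrative machine-checkable.  One
category, `reported_dominant_unconfirmed`, exists specifically because
a previously reported dominant mutation without available relatives is
judged *questionable* while an unreported candidate in the same family
situation is judged *potential*: no computable rule separates the two
situations, so the distinction is carried as an input flag rather than
inferred.

Percentages in cohort yields round half away from zero.  Cohort
standard deviations use the n−1 (sample) denominator, which reproduces
the packaged synopsis's printed dispersions at printed precision with
n = 23.

## Packaged fixtures and their integrity

`panelGeneCatalog()` (63 genes, 942 exons; inheritance modes derived
from the pathology annotations by prefix — ADxx → AD, ARxx → AR,
Xxx → XL) and `cohortRunTable()` (23 patients; run metrics, triage
counts, candidate mutations, cosegregation calls, evidence categories)
verify an MD5 checksum on load so that silent edits of the transcribed
tables are caught.  Cells holding two candidate mutations are
semicolon-joined; the numeric `mut_cvg`/`mut_read_pct` columns carry
the first mutation's value with the full strings preserved alongside.
The count chain validated ≤ tested ≤ prioritized ≤ protein-changing ≤
coding ≤ total is validated on load and enforced when
`patientReport()` assembles new rows.

Two arithmetic quirks of the printed synopsis are worth knowing.  The
mean of the per-patient read lengths is 408.7 bp, which rounds to 409
rather than the printed 408 (the published figure was presumably
truncated or computed over raw reads); all other cohort statistics
reproduce exactly at printed precision.  And 12 definite diagnoses out
of 23 patients is 52%, not the published headline 55% (which matches
12/22, excluding the positive-control patient — but that denominator
contradicts the published 26% unsolved).  The package reports the
arithmetically consistent values.

## Problem sizes and numerical choices in the test-suite

The suite exercises: exhaustive oracles (all 576 single-base codon
changes against an independent hand-written code table; all trio
genotype assignments under AD/AR/XL against a rule-text oracle);
brute-force per-base set unions for interval arithmetic on ≤ 10 kb
instances; simulator parameter recovery at n = 1e5 draws within 3
standard errors; and deletion recovery on 50 seeded cohorts of 10
samples over a 50-exon toy gene with one implanted 2–5-exon deletion
each, requiring exact span recovery in at least 48 cohorts with zero
false positives under error-free settings.  These sizes keep the whole
suite under a minute while leaving the statistical assertions
well-powered; they are the package's own calibration, and all seeds are
fixed in the tests.

## Known limitations

* Consequence annotation is single-transcript and ignores splice-site
  effects; promoter/UTR variants are labelled but never scored.
* Segregation testing assumes full penetrance, no phenocopies, and no
  de-novo events; linkage statistics (LOD scores) are out of scope.
* The deletion detector targets complete multi-exon losses; it will not
  see heterozygous (half-depth) deletions, duplications, or partial
  exon events.
* The simulator is pileup-level: it cannot produce alignment artefacts,
  and its error models are parametric stand-ins, not fits to real runs.
* The digenic evidence category records a two-gene hypothesis; it is
  not a statistical test of digenic inheritance.
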