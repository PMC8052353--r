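---
title: "Tumor/cfDNA concordance: models, statistics and the simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor/cfDNA concordance: models, statistics and the simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfconcord)
```

## The analysis

Plasma cell-free DNA (cfDNA) of a cancer patient carries fragments shed
by every tumor lesion in the body, so a variant profile obtained from
plasma can in principle summarize the patient's whole tumor burden —
including the intertumoral heterogeneity that a single-lesion biopsy
misses. `cfconcord` implements the comparison that makes this idea
quantitative for a patient with multi-region tumor sampling (for
example, autopsy lesions) and matched plasma:

1. **Nucleotide-resolution matching.** Two calls are the same
   alteration only when chromosome, position, reference allele and
   alternate allele agree exactly after canonicalization — never merely
   the same gene. Copy-number events, which have no defining nucleotide
   change, are matched by gene symbol (`CNV:GENE` keys).
2. **Somatic filtering.** Calls whose keys occur in the matched
   germline (whole-blood) sample are subtracted from every tumor and
   cfDNA set, and analyses run on high-confidence calls only.
3. **Overlap counting.** Per lesion, the detection rate is the number
   of the lesion's somatic alterations whose key is also found in cfDNA
   divided by the lesion's total.
4. **Breadth classification.** Each alteration found in any tumor
   lesion is *truncal* (present in all lesions), *shared* (present in
   more than one but not all), or *individual* (present in exactly
   one), and its cfDNA detection status is attached. With exactly two
   lesions there is no room between "all" and "one", so two-lesion
   patients have only truncal and individual variants.
5. **VAF stratification.** Within a lesion, the variant allele
   frequencies (VAF = alt reads / (ref + alt reads)) of alterations
   detected in cfDNA are compared against those not detected
   (two-sided Mann–Whitney U, means with 95% CIs).
6. **Longitudinal dynamics.** Between a diagnosis-time and a pre-mortem
   cfDNA sample, alterations are persistent, lost or gained; variants
   found in diagnosis cfDNA and in an autopsy metastasis but never in
   the primary tumor are reported as metastasis-presaging.

## Design choices where the definitions were genuinely open

**The shared-mutation boundary.** The written classification rules in
the field are not consistent: one common phrasing demands presence "in
more than 2 sites but not all" for a shared mutation, while the
operational usage (and the only reading compatible with grouping
two-lesion patients' both-lesion variants as truncal) is "more than one
but not all". The default rule here is the latter
(`rule = "at_least_two"`): shared means present in at least two lesions
but not all. The strict literal reading is available as
`rule = "more_than_two"`; under it a variant present in exactly two of
several lesions is left with the individual (single-branch) group,
because the literal text gives it no class of its own and any other
total extension would re-create the default rule.

**CNV identity.** Copy-number calls carry no coordinates in annotated
panel exports, yet they are matched across samples and patients. Keys
for CNVs are `(gene, CNV)`; this is the only identity that is stable
across callers, and it matches how gene-level alteration tables list
them.

**Functional filter.** The filter that confines surveys to
biologically meaningful alterations keeps calls whose impact annotation
is HIGH or MODERATE (non-synonymous coding, stop gain/loss, frameshift,
splice site, in-frame indels) and drops synonymous-coding calls and
region annotations (intron, UTR, upstream/downstream, intergenic).
Gene-level CNV records carry no effect annotation and are kept; SNVs
with a missing annotation are retained but counted in a warning rather
than silently dropped either way.

**Indel representation.** All samples of a patient are assumed to come
through one calling pipeline, so indels are matched by exact string
equality after uppercasing; no left-alignment or other re-normalization
is applied, because silently rewriting alleles changes identity
semantics. (VCF multi-allelic records are split into one call per
alternate allele before keying; coordinates are used 1-based as given,
never shifted.)

**Which cfDNA sample defines detection.** When a patient has several
plasma timepoints, concordance uses the pre-mortem sample by default
(`cfdna_timepoint = "pre_mortem"`), the draw closest to the autopsy
that provides the tumor profiles; this is configurable. Germline
subtraction uses the same matched-normal set for tumors and cfDNA.

## Statistics

* **Mann–Whitney U** (`mann_whitney_u()`): exact null distribution when
  the combined sample size is at most 12 and the pooled values are
  tie-free, otherwise the normal approximation with tie correction and
  continuity correction. The switch point is configurable; 12 keeps the
  exact branch's enumeration cost trivial while covering the small
  strata that arise per lesion. A fully tied pooled sample has zero
  rank variance and is reported as p = 1.
* **Chi-square with Yates correction** (`chi_square_yates()`): for a
  2×2 table the statistic is `N(|ad−bc|−N/2)² / (product of margins)`,
  clamped at zero when `|ad−bc| ≤ N/2`; one degree of freedom. Tables
  with a zero margin are an error, and pairwise class comparisons that
  would need them are reported as absent instead.
* **Class comparisons** report both the Yates-corrected chi-square on
  the detected/undetected 2×2 table and an equal-variance two-sided
  t-test on the 0/1 detection indicators, since both appear in this
  literature; Welch is a `t.test` flag away for users who prefer it.
* **Confidence intervals** (`mean_ci95()`): t-distribution intervals by
  default — the detected stratum of a lesion can be as small as a
  handful of variants, where the normal approximation is too narrow — a
  normal-approximation method is selectable. n = 1 returns a degenerate
  point interval, flagged.
* **Correlation of detectability with tumor size**
  (`detectability_vs_size()`): Spearman primary (no reason to expect
  linearity), Pearson secondary; fewer than 3 pairs or rank-degenerate
  inputs are flagged rather than computed.
* Significance is read at two-sided α = 0.05 and no multiple-testing
  correction is applied; the per-comparison p-values are emitted so any
  correction can be layered on.
* VAFs are held as fractions in [0, 1] internally; reports print
  percentages rounded half-up to one decimal (`round_half_up()`), the
  convention of clinical tables. Base R's `round()` rounds half to
  even, which would print 0.5-boundary percentages differently than
  clinical readers expect.

## The simulator

Because multi-lesion autopsy cohorts with matched plasma are not
publicly depositable, every stage of the pipeline is exercised against
a generative model with known ground truth (`simulate_patient()`).

**Planting.** A patient has `n_lesions` lesions (default 3, the median
lesion count per patient in the kind of cohort the analysis targets:
19 lesions over 6 patients). Somatic variants are planted as 20
truncal / 50 shared / 130 individual by default — 200 variants whose
class mix (10%/25%/65%) reflects the observed dominance of
single-lesion variants in multi-region sequencing, where individual
mutations are roughly three quarters of the total and truncal the
smallest group. Truncal variants are clonal (carrying-clone prevalence
1); shared and individual variants draw a prevalence uniform on
[0.1, 1]. A lesion's true VAF is `0.5 × purity × prevalence` with
default purity 0.6, and 50 germline heterozygous polymorphisms (true
VAF 0.5) are present in every sample including plasma.

**Sequencing.** Per-site depth is negative-binomial around the
configured mean (tissue 1400×, plasma 5000×, matching the median panel
depths of the motivating study design: 1431 and 5248), with alt reads
binomial at the true VAF. A call is emitted when it reaches
`min_alt_reads = 4` and `min_vaf = 1%` — ordinary panel-calling
thresholds.

**Shedding.** Plasma mixes the lesions with configurable non-negative
weights (default equal): a variant's plasma VAF is the weighted sum of
its lesion VAFs. This alone makes breadth matter — a truncal variant
receives every lesion's weight, an individual variant only one. On top
of the binomial detection at plasma depth, a Bernoulli thinning with
probability `min(1, (2·VAF)^exponent)` (default exponent 1) makes
detection explicitly VAF-dependent. The exponent is the minimal
mechanism that produces both qualitative signatures the analysis is
meant to detect — higher detection for broader variants, higher tumor
VAF among detected variants — without asserting a quantitative shedding
law nobody has measured; defaults were chosen to reproduce orderings,
never any published aggregate percentage. Plasma also receives 30
cfDNA-only low-VAF (0.5–5%) artifact keys, emulating the plasma-only
calls real panels produce.

**Reproducibility.** A single seed feeds per-sample substreams, so
adding a sample (say, the optional diagnosis-timepoint plasma draw)
does not perturb any other sample's draws, and the same configuration
and seed are byte-identical across runs. The `noiseless = TRUE` switch
removes depth sampling, thresholds and thinning; in that limit every
planted variant is called wherever it exists, and classification must
(and does, in the tests) recover 100% of ground-truth classes.

**What the simulator does not emulate — and what passing tests show.**
Positions are uniform, not drawn from real gene models (gene labels
come from a bundled 160-gene panel list purely for realism of the
tables); there are no mutational signatures, no CNVs beyond
presence/absence, no sequencing error model beyond binomial counting
noise, no clonal phylogeny beyond the three-class structure, and lesion
purities/prevalences are independent across lesions. Tests passing on
simulator output therefore demonstrate that the set algebra,
classification, statistics and file plumbing are correct under the
stated model — not that any particular biological effect size will be
observed in real cohorts.

**Fixtures.** `generate_fixture()` builds deterministic cohorts meeting
exact set sizes (totals plus intersection), which lets printed worked
examples — a primary lesion with 891 alterations of which 9 appear
among 119 in cfDNA; 84 diagnosis-time alterations of which 17 persist
among 119 before death — be reproduced and asserted exactly.

## Problem sizes

The test suite and the acceptance script run the simulator at the
default 200-variant, 3-lesion configuration: 50 seeds for the
class-detection ordering property, 100 seeds for the VAF stratification
property, 12 seeds per depth for the depth-monotonicity check, and
exhaustive enumeration of Mann–Whitney null distributions up to
combined n = 10. These sizes give stable Monte-Carlo fractions
(binomial s.e. ≈ 3% at 50 seeds) while keeping a full run in the tens
of seconds on one CPU.

## Known limitations

* Matching is exact-key only; the same biological event represented
  differently by two callers (unnormalized indels, MNP vs successive
  SNVs) will not match. Run all samples through one pipeline.
* CNVs are presence/absence at gene level, carry no VAF, and are
  excluded from all VAF-based analyses.
* The classification is a labeling, not a phylogeny: it does not infer
  clone trees, timing, or lesion seeding order.
* Longitudinal analysis compares two timepoints; additional timepoints
  are accepted but compared pairwise.
* "Newly metastasized" for presaging variants means any metastasis
  lesion in the cohort (restrictable via `metastasis_ids`), because a
  baseline lesion inventory is not part of the data model.
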