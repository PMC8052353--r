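# cfconcord

Concordance analysis of somatic variant profiles between multi-region
tumor tissue and plasma cell-free DNA (cfDNA).

## The problem

Liquid biopsy reads tumor-derived DNA out of plasma, but not every
tumor alteration makes it into the blood. For a patient with several
sequenced tumor lesions (e.g. a primary and its metastases sampled at
autopsy) and matched plasma, the questions this package answers are:

* Which of the tumor's alterations are detectable in cfDNA, per lesion
  and overall, when alterations are matched at **nucleotide-change
  resolution** (chromosome, position, ref and alt allele — never merely
  the gene)?
* Does detectability depend on how **broadly** an alteration is present
  across lesions? Alterations are classified as **truncal** (in all
  lesions), **shared** (in more than one but not all) or **individual**
  (in exactly one), and cfDNA detection rates are compared across
  classes (Yates-corrected chi-square and t-tests on the detection
  indicators).
* Does detectability depend on the alteration's **variant allele
  frequency** in the tissue, `VAF = alt reads / (ref + alt reads)`?
  Per-lesion, VAFs of cfDNA-detected vs undetected alterations are
  compared (two-sided Mann–Whitney U, means with 95% CIs).
* How do cfDNA profiles **change over time** between diagnosis and
  death (persistent / lost / gained alterations), and which diagnosis
  cfDNA alterations **presage metastases** (present in a metastasis at
  autopsy, never in the primary)?

It is aimed at translational researchers with per-sample variant call
tables (VCF or an annotated TSV dialect) from a matched
tumor/germline/plasma design. Upstream calling and annotation are
consumed, not performed. Because such cohorts are rarely shareable, a
clonal-evolution and cfDNA-shedding simulator with complete ground
truth (`simulate_patient()`) makes the full pipeline testable end to
end.

## Worked example

Simulate a 3-lesion patient (200 somatic variants: 20 truncal, 50
shared, 130 individual; 50 germline polymorphisms; tissue 1400×,
plasma 5000×) and run the whole analysis:

```r
library(cfconcord)
sim <- simulate_patient(sim_config(seed = 7))
res <- cf_concordance(sim$cohort)
print(res)
```

```
<cf_concordance> patient SIM1: 3 tumor lesion(s), 71 cfDNA alterations
  SIM1_P           tumor   102 | both   26 | cfDNA-only   45 | detection 25.5%
  SIM1_M1          tumor    88 | both   22 | cfDNA-only   49 | detection 25.0%
  SIM1_M2          tumor   100 | both   24 | cfDNA-only   47 | detection 24.0%
<class_detection> cfDNA detection by mutation class
  truncal      10 /   20 detected (50.0%)
  shared       11 /   50 detected (22.0%)
  individual   20 /  130 detected (15.4%)
  truncal vs individual    chi-square(Yates) p=0.000958, t-test p=0.000258
  shared vs individual     chi-square(Yates) p=0.405, t-test p=0.295
  truncal vs shared        chi-square(Yates) p=0.0433, t-test p=0.0207
  cfDNA-only VAF 2.6% vs tumor-corroborated 13.8% (n=30/41)
```

Reading the output: after germline subtraction and high-confidence
filtering, the primary lesion (`SIM1_P`) carried 102 somatic
alterations of which 26 were also found among the 71 in plasma — a
25.5% detection rate. Detection falls monotonically from truncal (50%)
through shared (22%) to individual (15.4%) alterations, and the
plasma-only calls sit at much lower VAF (2.6%) than the
tumor-corroborated ones (13.8%) — the two signatures of
breadth- and VAF-dependent shedding the analysis is designed to expose.

Deterministic fixtures reproduce printed set-algebra examples exactly,
e.g. two cfDNA timepoints with 84 and 119 alterations sharing 17:

```r
co <- generate_fixture(list(diagnosis = 84, death = 119, common = 17))
compare_timepoints(cfdna_at(co, "diagnosis"), cfdna_at(co, "pre_mortem"))
```

```
<longitudinal_summary> patient FIX1
  diagnosis 84 | persistent 17 | before death 119 (lost 67, gained 102)
  persistence 20.2%
```

File-based workflows go through the command line
(`inst/scripts/cfconcord`, a thin wrapper over `cli_run()`):

```sh
cfconcord simulate --seed 7 --out sim/
cfconcord concordance --manifest sim/manifest.tsv --out results/
cfconcord report --out results/      # joins the component TSVs
```

Every stage logs its input/output counts, and `assemble_report()`
refuses (rather than reconciles) inconsistent component files.

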