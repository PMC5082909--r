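---
title: "CNV discovery and prioritization for isolated Ebstein anomaly: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNV discovery and prioritization for isolated Ebstein anomaly: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eacnv)
```

## The problem

Ebstein anomaly (EA) is a rare congenital heart defect in which the tricuspid
valve is malformed and apically displaced. Known point-mutation causes
(*MYH7*, *NKX2-5*, *GATA4*) explain only a small fraction of cases, which
motivates a genome-wide search for rare copy-number variants (CNVs) in
population-ascertained, isolated (non-syndromic) cases. `eacnv` implements
that search as a reusable, fully tested pipeline: two SNP-array CNV callers
are harmonized, calls are filtered against common-polymorphism references,
survivors are annotated and grouped into recurrent candidates, targeted
sequencing variants are triaged by allelic balance and population frequency,
and candidate-CNV genes are tested for gene-set enrichment. A seeded
synthetic-cohort generator with planted truth makes every stage testable with
no external data.

## Coordinate conventions and interval arithmetic

All coordinates are 1-based and inclusive on both ends, the convention of the
array callers and of the published candidate tables; BED input is converted
on read (and back on write). Sizes in Kb and all percentages are rounded
*half away from zero* — the rule recovered by recomputing every printed size
and percentage of the study tables (base R's `round()` rounds half to even
and would disagree on several cells). Interval unions and coverage fractions
are computed with `IRanges`; a per-base enumeration oracle in the test suite
checks `overlap_bp()` and `coverage_fraction()` on thousands of random
intervals.

## Call harmonization

* **Thresholds** (`apply_caller_thresholds()`): confidence ≥ 10 for
  PennCNV-style calls, ≥ 35 for cnvPartition-style calls (both callers'
  defaults in the study), and ≥ 3 supporting probes everywhere.
* **Merging** (`merge_adjacent_calls()`): same-sample, same-state calls merge
  when the gap is at most a fraction (default 0.2, the merge utility's
  documented default) of the merged span, iterated to a fixed point. Probe
  counts add; confidence takes the minimum (conservative: a merged call is no
  more trustworthy than its weakest piece).
* **Concordance** (`label_concordance()`): the study computed cross-caller
  concordance without stating a definition; we use the field convention of
  ≥ 50% *reciprocal* overlap with matching CNV type. The union of calls is
  retained downstream regardless of label, matching the study's "called by
  one or both algorithms".
* **ROH** (`detect_roh()`): maximal runs of homozygous genotypes, tolerating
  no-calls, broken by any heterozygote; reported at ≥ 1 Mb (the study's rule)
  and ≥ 50 homozygous probes. The probe floor is our extension: with sparse
  probes a 1 Mb span can contain almost no evidence, and the floor prevents
  such spurious segments. It is configurable.
* **Sex chromosomes**: expected ploidy is 2 on autosomes and in
  pseudoautosomal (PAR) and X-transposed (XTR) regions for both sexes, 1 on
  male X/Y outside them. CNV type (loss/gain) is always relative to expected
  ploidy.

## Candidate selection

Autosomal candidates need **≥ 10 probes**, **≥ 25 Kb**, and **strictly less
than 35%** of their span covered by the union of same-type features in *each*
reference set (common HapMap3-like CNPs, CHOP-like CNV blocks, project
controls, unrelated birth-defect cases). The 35% rule is interpreted as the
fraction of the case CNV covered (not reciprocal) — the laxer reading of
"overlap with ... polymorphisms", applied with strict inequality. Reference
features typed `both` match either CNV type.

Remaining rules:

* **DGV exclusion** (`flag_dgv_exclusion()`): excluded when ≥ 2 same-type
  DGV-like entries *each* cover ≥ 50% of the candidate. The study says only
  "substantial overlap with multiple DGV entries"; 2 entries × 50% is our
  operationalization, both knobs configurable. Entries are deliberately never
  unioned: "multiple entries" is evidence the region is commonly variant,
  while one large entry is not.
* **Sex-chromosome candidates**: ≥ 25 Kb, copy-2 calls inside PAR/XTR are
  normal diploid states and excluded, then the same reference-overlap rules
  as autosomes. This is a rule-based stand-in for the study's manual review.
* **Intensity review** (`review_flag_lrr()`): replaces manual LRR/BAF plot
  inspection. A candidate fails when the mean log-R ratio across its probes
  is below 0.1 in magnitude or shifts opposite to the called copy-number
  direction. With ≥ 25 probes and the study's LRR noise (sd 0.133) a real
  call essentially never fails and a flat artifact essentially always does;
  it is a stand-in, not a reproduction, of expert review.
* **Cross-caller dedup** (`dedupe_candidates()`): an event seen by both
  callers survives selection twice; same-sample, same-type calls with ≥ 50%
  reciprocal overlap collapse to one candidate. The representative keeps
  pennstyle coordinates on autosomes and partitionstyle coordinates on sex
  chromosomes — the coordinate provenance the published candidate table
  states.
* **Recurrence** (`count_recurrence()`): candidates in different cases with
  matching type and ≥ 50% reciprocal overlap share a CNV identifier
  (connected grouping, numbered in genomic order). The published recurrent
  pair itself overlaps only ~30% reciprocally, so the study's own notion was
  looser; the threshold is a configurable parameter
  (`recurrence_reciprocal`) and the synthetic generator plants recurrent
  pairs at identical coordinates, where any threshold agrees.

Filters are monotone in their thresholds (tested), and the full audit trail —
the first rule each call failed — is retained, which is what makes
planted-truth scoring exact.

## Variant triage

Targeted-sequencing variants carry per-allele read depths. Allelic balance
(alternate fraction) classifies each variant: `< 0.25` likely artifact (such
calls consistently failed Sanger validation in the study), `0.40–0.85`
expected heterozygote, anything else `review`. Variants must be rare —
population frequency absent or `< 0.005`; the study never prints its cutoff,
and 0.005 sits above the largest frequency it retained (2.29e-3) while
excluding common polymorphisms. Candidate-tier variants additionally require
a predicted-impact annotation (loss of function / high impact / predicted
pathogenic), which the known-gene tier does not; impact predictions are
inputs, not computations. Case-level summaries count distinct cases, and the
cardiomyopathy panel defaults to {MYH7, MYH6, TTN, TCAP, JUP} — the genes the
study discusses as autosomal-dominant cardiomyopathy genes.

## Gene-set enrichment and the enrichment map

Three query lists are built from candidate genes (all CNVs / deletions only /
duplications only), each augmented with the three known EA genes carrying a
sentinel source id. Enrichment is the one-sided hypergeometric tail (Fisher)
against a background defaulting to the union of library members; the external
service the study used reports Fisher-derived statistics, and the
hypergeometric tail is its reproducible core. Benjamini–Hochberg adjustment
is applied per library (`stats::p.adjust`; an independent step-up reference
lives in the tests). Exclusion rules follow the study: adjusted p ≥ 0.05;
overlap restricted to the known genes; overlap drawn from a single CNV
(known-gene sentinels count as one extra pseudo-source when present —
configurable); and deletion/duplication-list results whose set also survives
in the all-CNVs list. The enrichment map connects surviving sets whose member
lists have overlap coefficient `|A∩B| / min(|A|,|B|)` at or above 0.5
(inclusive cutoff: the study says "cutoff of 0.5", and an edge at exactly the
cutoff is kept); connected components are labeled by their alphabetically
smallest member so the clustering is order-independent.

## Cohort statistics

Birth prevalence is reported as "1 in N" with N rounded half away from zero
to the nearest hundred (recovered from the printed 1-in-17,300 and
1-in-39,700). Demographic comparisons use the classical Pearson chi-square
without continuity correction on categories × (population, cases) tables,
with cases included in the population column exactly as the published table
presents it. All seven printed p-values reproduce at two decimals. Two
printed population percentages (race "Other", sex "Female") are residuals to
100 rather than the value of their own printed counts; the package reports
the recomputed values (1.5, 48.7) and the tests pin both discrepancies
explicitly.

## The synthetic cohort: what it emulates, and what it does not

The generator (`generate_cohort()`) writes every input format the pipeline
reads, at desk scale:

* **Genome**: two 30 Mb autosomes plus X (20 Mb) and Y (10 Mb) with declared
  PAR/XTR sub-intervals. Real genomes are two orders of magnitude larger;
  nothing in the pipeline's logic depends on chromosome count or length.
* **Array**: ~1000 probes/Mb on a jittered regular grid — about the
  genome-wide density of the 2.5M-probe array the study used. Per-probe LRR
  is drawn around state means −0.45 (one-copy loss) / +0.3 (three-copy gain)
  with sd 0.133, the study's reported LRR deviation; BAF and genotypes are
  consistent with copy number, with background heterozygosity 0.30 and
  no-call rate 0.005.
* **Planted events** (~50 per cohort) fall in four classes: `rare_candidate`
  (the signal; 40–300 Kb, plus deliberate sub-threshold plants at 3–5.5 Kb
  and 15–22 Kb to exercise the probe and size floors), `common_cnp` (placed
  identically in both common-polymorphism reference sets), `dgv_like`
  (covered by two same-type DGV entries), and `artifact` (a call with no LRR
  shift behind it). Events occupy disjoint, well-separated slots so fates
  cannot interact, and the size classes keep a clear margin around every
  filter threshold so each event's expected fate is invariant to caller
  noise.
* **Caller noise**: per caller, events are missed with probability 0.05,
  boundaries jitter by N(0, 500 bp) clamped at ±1.25 Kb (about one probe
  spacing), calls split in two with probability 0.05 (re-merged by the
  cleaning step), ~5% of confidences fall below the caller's threshold, and
  Poisson(3) small false-positive calls (3–15 Kb, always below the candidate
  floors) are added per sample. Callers never emit calls with fewer than 3
  probes, mirroring the calling floor.
* **Variants**: true heterozygotes draw alternate reads Binomial(depth, 0.5),
  artifacts Binomial(depth, 0.1); depth is negative-binomial (mean 120,
  size 8) truncated at 30, a targeted-panel scale at which the 0.40–0.85
  band captures ≥ 95% of true heterozygotes.

Not emulated: raw intensities and genotype clustering, linkage
disequilibrium, population structure, GC waves (the study's callers adjusted
for them internally), and real transcript structure. Passing planted-truth
tests therefore demonstrates that the *decision logic* is correct under a
realistic noise model — not that the upstream callers would behave well on
real arrays.

## Problem sizes and determinism

The test suite and the acceptance script run the planted-truth property on
cohorts of 8 cases + 2 controls over the two autosomes (~60,000 probes,
~50 events) across 10–20 seeds, and the analysis scripts run one
study-scale cohort (47 cases + 3 controls, all four chromosomes). All
randomness flows from a single integer seed; a fixed seed yields
byte-identical bundles and pipeline outputs, with ordering imposed before
every write.

## Known limitations

* The DGV "multiple entries" rule, the ROH probe floor, the recurrence
  reciprocal threshold and the rarity ceiling are explicit parameters for
  quantities the study left unstated; defaults are documented above and in
  the function help.
* The intensity review emulates, but cannot reproduce, expert plot reading;
  borderline mosaic or small events that an expert would rescue are outside
  its model.
* Enrichment results depend on the gene-set library supplied; the study's
  database-snapshot-dependent counts (e.g. its 48 enriched sets) are not
  reproducible from the paper alone and are not targets of this package.
* The external phenotype-ranking step is supported only as an input-export
  filter (`export_ranking_input()`); the ranking algorithm itself is not
  reimplemented.
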