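---
title: "Methods: virtual-panel variant triage for neurodevelopmental disorders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual-panel variant triage for neurodevelopmental disorders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nddtriage)
```

## The problem

Neurodevelopmental disorders (NDDs) — intellectual disability / global
developmental delay (ID/GDD) and autism spectrum disorder (ASD) — are
genetically heterogeneous: hundreds of dominant and X-linked genes each
explain a small fraction of cases, and most diagnostic variants are *de
novo*. A targeted or virtual gene panel combined with very stringent variant
filtering can turn thousands of raw calls per patient into a handful of
reviewable candidates while keeping essentially all true diagnoses.
`nddtriage` implements such a triage pipeline end to end: a rule-based
SNV/indel filter cascade with two operating modes, dual-caller CNV consensus
filtering, HPO-based patient stratification, the cohort statistics used to
summarise diagnostic performance, and a phenotype-profiling random forest.
A synthetic-cohort generator with independently computed truth labels makes
every stage testable without access to patient data.

## The SNV filter cascade

Each called variant carries genotype evidence (read depth $d$, alternate
reads $a$, variant allele fraction $\mathrm{VAF}=a/d$), population evidence
(gnomAD allele count AC, allele frequency AF, homozygote count), and
functional annotation (consequence class, ClinVar status, per-predictor
deleteriousness calls, PROVEAN score, four splice scores). The cascade
applies, in order:

1. **Virtual-panel restriction.** Only positions inside the panel target
   regions (coding exons ±20 bp) are analysed. Internally coordinates are
   half-open 0-based; a 1-based position $p$ is inside $[s,e)$ iff
   $s < p \le e$.
2. **Quality.** *Primary mode*: discard $d < 10$ or $\mathrm{VAF} < 30\%$.
   *Re-analysis mode* (mosaic-aware): discard $d < 10$; for
   $10 \le d < 50$ discard $\mathrm{VAF} < 20\%$ (LoF) or $< 25\%$
   (non-LoF); for $d \ge 50$ keep down to $\mathrm{VAF} \ge 10\%$ so
   mosaic variants survive. Depth exactly 50 belongs to the mosaic band
   (the bands are implemented exactly as printed, half-open).
3. **Population frequency.** Discard gnomAD AC $> 4$ (strict inequality;
   AC = 4 passes; absence from gnomAD passes).
4. **Consequence.** Keep protein-affecting classes — LoF (stop gain,
   frameshift, canonical splice, start loss), stop loss, in-frame indel,
   missense — plus any variant the splice ensemble flags
   ($\max(\mathrm{SQUIRLS}, \mathrm{SpliceAI}, \mathrm{ADA},
   \mathrm{RF}) \ge 0.5$ over non-missing scores). This is the only route
   by which synonymous and intronic variants survive.
5. **Prioritisation.** A kept variant is a *candidate* if it (i) is ClinVar
   pathogenic/likely-pathogenic, (ii) is absent from gnomAD (no record or
   AC = 0), or (iii) is predicted to strongly affect protein function:
   LoF, in-frame indel with PROVEAN $\le -2.5$, missense called
   deleterious by $\ge 50\%$ of available predictors, or a splice-ensemble
   hit.

In re-analysis mode a cohort-level screen then flags gnomAD-absent variants
carried by more than three distinct cohort samples as putative recurrent
sequencing artifacts. The flag is advisory — the source describes
*highlighting*, not discarding — so statuses are unchanged, and it is only
attached to records that survived the cascade (carrier counting still uses
all carriers).

### Design choices made where the rules were open

- **Candidate rule combination.** The published (i)/(ii)/(iii) list is
  grammatically a conjunction but clinically reads as alternative routes: a
  ClinVar-pathogenic variant with gnomAD AC = 3 must not be dropped.
  `triage_thresholds(priority_mode=)` exposes both; the default is `"any"`.
- **VAF denominator.** Total depth at the site (the source never defines
  it); informative-read-only VAFs would require caller internals.
- **Zero available predictors.** The majority vote returns "not
  deleterious": absence of evidence is not evidence of deleteriousness.
- **gnomAD absence** means no matching record *or* AC = 0.
- **Off-panel variants** receive an explicit `off_panel` terminal status so
  every input row has exactly one decision.
- **Recessive extension** (`recessive_filter()`): discard gnomAD AF
  $\ge 0.1\%$ or $> 4$ homozygotes; surviving homozygotes are reported
  directly and genes with $\ge 2$ surviving heterozygous variants in one
  sample become unphased compound-het candidates — panel and exome data
  usually lack parental phase, so no phasing is attempted.

## CNV consensus filtering

CNV calls from two exome callers (caller A, XHMM-like; caller B,
ExomeDepth-like; their calling models are inputs, never re-implemented) are
filtered by:

1. **Cohort recurrence**: discard calls reciprocally sharing $\ge 80\%$ of
   their length with more than three other cohort calls. "Other" means
   calls from other samples, same CNV type; both callers' calls are pooled
   (the source is ambiguous; cross-type overlap is biologically
   meaningless here, and a sample's own second-caller call is support, not
   recurrence).
2. **Population SV**: discard calls reciprocally sharing $\ge 90\%$ with a
   same-type DGV/gnomAD-SV record of AC $> 10$ or AF $> 10^{-4}$.
   Records missing a value fail that sub-condition rather than erroring
   (DGV frequently lacks AF).
3. **Single-caller quality**: calls supported by the other caller (same
   sample, same type, reciprocal overlap $\ge 0.8$ — the only stated
   call-to-call stringency, reused because the source never defines
   caller matching) always pass; otherwise discard caller-A calls with
   Phred $< 20$ and caller-B calls with Phred $< 3$.
4. **Prioritisation**: a candidate is a dual-supported pair with caller-A
   Phred $\ge 30$ *and* caller-B Phred $\ge 20$; the two sides of a pair
   are merged into one per-sample event (union interval).

All filter predicates are evaluated against the full input call set and
statuses are assigned in stage order, which makes the filters commute on
the calls they both evaluate.

## Phenotype stratification and cohort statistics

Patients are classified by literal HPO code matching: ASD iff at least one
of the nine autism-behaviour codes is present and none of the ten ID/GDD
codes; everything else is ID/GDD (the ID codes act as a veto, and patients
without either code set default to ID/GDD, mirroring the published
classification in which all non-ASD patients form the ID/GDD subset).
Sixteen phenotype categories (metabolism, prenatal, cardiovascular, …,
behavioural, intellectual disability) are derived from a code→category map.
The published per-code assignments live in an appendix we do not have, so
the package ships a hand-curated approximate default
(`hpo_category_map_synthetic.tsv`, labelled synthetic); analyses that
depend on exact category membership should supply their own map.

Association statistics follow the combination that reproduces the published
p-values, verified before freezing the tests: 2×2 comparisons (yield by
subset, yield by sex) use the **Yates continuity-corrected** chi-square;
the sex-ratio test uses the **uncorrected** equal-proportion goodness of
fit. Effect sizes are the $\phi$ coefficient
($\phi = (ad-bc)/\sqrt{(a+b)(c+d)(a+c)(b+d)}$, satisfying
$\phi^2 n = \chi^2_{\text{uncorrected}}$) and, for the ordinal "number of
affected categories", the Glass rank-biserial correlation
$r = 2(\bar R_1 - \bar R_0)/n$ with midranks for ties (the source is
silent on ties; with no ties $r = 2U_1/(n_1 n_0) - 1$).

## The profiling forest

The profiler predicts the presence of a pathogenic variant from the 16
category flags, sex, and the number of affected categories. Because
`randomForest` is not available in the target environment — and because the
sampling scheme is what the analysis turns on — the forest is implemented
natively (Rcpp): `ntree` unpruned CART trees with Gini splits over
`mtry = floor(sqrt(p))` features; each tree draws, **per tree and without
replacement**, $\lfloor 0.8 \cdot n_{\text{minority}} \rfloor$ cases *from
each class*. The source's under-sampling description is ambiguous between
once-per-forest and per-tree balancing; per-tree was chosen because it
matches standard balanced-forest practice and keeps out-of-bag (OOB)
estimates defined for every case. Evaluation uses OOB votes at a 0.5
threshold (threshold unstated in the source), the rank-statistic AUC with a
Hanley–McNeil normal-approximation CI, and a Mann–Whitney comparison of
vote distributions (exact for small tie-free samples, otherwise normal
approximation with tie correction). Proximity between two cases is the
fraction of trees in which they share a terminal leaf; prototype analysis
clusters $1-\mathrm{PROX}$ with Ward linkage (`hclust(method = "ward.D2")`,
the Ward variant appropriate for raw dissimilarities). The published
*manual* dendrogram inspection is replaced by a reproducible rule: report
every clade of $\ge 10$ patients whose diagnosed fraction exceeds the
cohort fraction by a configurable margin (default 0.1). Leaf-prediction
ties are broken at random under the seeded RNG, so fits are exactly
reproducible from `seed`.

## The synthetic cohort: what it emulates, and what it does not

`sim_config()` defaults are the published cohort conditions: 398 patients
(247 M / 151 F), 76/398 in the ASD subset, a pathogenic plant in 114/398
patients split 106 germline SNV / 3 mosaic SNV / 5 CNV, and a background
load of 2 200 detected variants per sample — the figure implied by the
printed funnel (~6 variants/sample kept while eliminating 99.73% of
detected variants). Background attributes are drawn from *finite
categorical mixtures* (depth, nominal VAF, consequence, gnomAD AC/AF/hom
tuples, ClinVar status, predictor availability/deleterious fraction,
PROVEAN, splice-hit indicator), chosen once to roughly reproduce that
funnel; because every distribution is finite, `expected_counts()` computes
the expected per-sample totals, kept counts, candidate counts and
eliminated fraction in closed form by integrating the filter rules over the
mixture grid (alternate reads are `round(VAF · depth)`, and the same
rounding is applied on the grid, so the expectation is exact).

Planted germline variants satisfy the candidate definition *by
construction* (gnomAD-absent, strong effect, depth ≥ 100, VAF ≈ 0.5);
mosaic plants use VAF 0.10–0.25 at depth ≥ 50 and are therefore
recoverable only in re-analysis mode; artifact plants are gnomAD-absent
LoF variants shared by six samples. Truth labels for every generated
variant and CNV call are computed by a *straight-line restatement* of the
rules with literal constants (`.truth_snv()`, `.truth_cnv()`), using
different machinery from the pipeline (data.table non-equi joins and
quadratic scans instead of GenomicRanges), and never by calling the triage
functions — so pipeline-equals-truth tests are genuine dual-route checks.

The generator does **not** emulate: read-level error processes, sequence
context, linkage between variants, realistic gene-level constraint, HPO
ontology structure (codes are drawn from the literal lists and the shipped
map), or the correlation structure of real phenotypes. A green test
therefore establishes that the rules are implemented exactly as stated and
are internally consistent — not that the pipeline would achieve the
published diagnostic yield on real patients, which depends on the real
cohort and is out of reach without it.

## Numerical and testing notes

- Boundary semantics are all strict-as-printed: AC > 4 discards, score
  ≥ 0.5 is a splice hit, PROVEAN ≤ −2.5 is strong, "> 3 patients" means
  ≥ 4 carriers, depth 50 is in the mosaic band.
- Tests run on scaled-down cohorts (tens of patients, background loads of
  30–100) purely for speed; distributions are the package defaults unless
  a rule needs a dedicated construction, and the scaling is stated in the
  test files.
- The permuted-label OOB AUC calibration check averages three fixed-seed
  permutations: a single draw has null standard deviation ≈ 0.045 around
  0.5, so one unlucky permutation could leave the 0.4–0.6 band without any
  calibration defect; the acceptance band itself is unchanged.
- Re-analysis mode retains a superset of primary mode on any input: the
  depth rule is identical and every re-analysis VAF bound is ≤ 0.30. This
  dominance argument is also verified empirically as a property test.
- Run configuration files are JSON rather than YAML (no YAML parser in the
  supported dependency set).

## Known limitations

- The shipped category map is approximate; published category-level
  results cannot be reproduced exactly without the appendix map.
- Compound-het detection is unphased; a gene with two *cis* variants will
  be over-called, as in any phase-free analysis.
- The CNV caller matching rule (RO ≥ 0.8, same sample/type) is a
  reconstruction; the original matching procedure is not printed.
- `expected_counts()` assumes the default `"any"` priority mode.
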