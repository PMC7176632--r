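---
title: "Somatic variant prioritization and driver nomination in NK-cell leukemia exomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic variant prioritization and driver nomination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nkdriver)
```

## The analysis

Chronic lymphoproliferative disorder of NK cells (CLPD-NK) is an indolent
clonal expansion of large granular lymphocytes. Because hotspot mutations
in *STAT3*/*STAT5B* explain only a minority of cases, whole-exome
sequencing of purified leukemic clones against matched granulocytes is
used to chart the wider somatic landscape. `nkdriver` implements that
analysis as a reusable pipeline:

1. **Multi-caller merging** (`parse_caller_vcf()`, `merge_caller_calls()`)
   — somatic calls from MuTect, MuTect2 and Strelka2 dialects are
   normalized to a common parsimonious left-aligned key and combined by
   *union*. Union rather than intersection is deliberate: the goal of
   running three callers is discovery power for low-VAF subclonal events,
   and intersection would discard exactly those. Variants with fewer than
   10 reads in either the tumor or the normal sample are dropped; the
   symmetric gate is the conservative reading of a coverage filter on
   "regions".
2. **Filter cascade** (`run_cascade()`) — ordered, stateless filters:
   population allele frequency strictly above 5% in the patient-matched
   population (non-Finnish European or Finnish) discards; ClinVar
   `benign`/`likely_benign` discards; only predicted impact HIGH/MODERATE
   with an ensemble deleteriousness call survives; finally the VAF
   retention threshold (0.05) is applied. Because each predicate is
   stateless the retained set is order-independent; only the funnel
   attribution (each variant is charged to the *first* stage it fails)
   depends on the order.
3. **Cohort summaries** — VAF tiers (`subclonal < 0.05 <= retained < 0.1
   <= prominent`), patient-level gene recurrence, a Kruskal–Wallis test of
   VAF heterogeneity across patients, a Spearman check that mutational
   burden does not track sequencing depth, and interval-based hotspot
   screening with half-up rounded prevalences.
4. **Pathway network** (`topology_to_gene_graph()` and friends) — typed
   KEGG/Reactome-like topologies become pairwise gene connections via
   three rules: (a) edges whose endpoints resolve to genes (directly or
   through complex membership) give *direct* edges; (b) complex
   membership gives a *direct* clique; (c) paths running exclusively
   through compound intermediates give *indirect* edges. Pathway networks
   are merged non-redundantly, protein–protein interactions are overlaid
   as *predicted* edges, genes with normalized expression below 1 are
   removed, and the induced subgraph over mutated genes is exported
   (SIF/GraphML).
5. **Driver scoring** (`driver_score()`) — a weighted, monotone
   combination of max VAF, impact class, expression, recurrence and an
   external driver label, plus the validation-method rule (Sanger for
   VAF ≥ 0.2, ARMS PCR below) and approved-drug lookup.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `min_coverage` | 10 reads | depth gate, tumor *and* normal |
| `max_pop_af` | 0.05 | population AF discard threshold (strict `>`) |
| `retain_vaf` | 0.05 | retention threshold (inclusive) |
| `prominent_vaf` | 0.1 | prominence/radar threshold (inclusive) |
| `sanger_vaf` | 0.2 | Sanger eligibility (inclusive) |
| `max_compound_hops` | 3 | compound intermediates allowed for indirect edges |
| expression threshold | 1 | normalized-expression floor (value 1 kept) |

Boundary conventions were chosen once and are configurable: a population
AF of exactly 0.05 is kept (the discard rule is strictly "greater than
5%"); VAF 0.1 is prominent (the inclusive reading — the two readings are
indistinguishable on the validated-variant table, whose smallest prominent
VAF is 0.12); VAF 0.2 is Sanger-eligible ("at least 0.2").

Two annotation conventions deserve note. A variant absent from the
population database is treated as novel (kept): the filter's purpose is to
remove common germline polymorphism, and absence of evidence of
commonness is evidence of rarity at gnomAD's scale. And variants without
an ensemble missense score (frameshift, splice, stop-gain) pass the
deleteriousness filter when their predicted impact is HIGH/MODERATE:
score-less truncating classes are precisely the ones a deleteriousness
screen should keep, and the validated-variant table contains several.
Both behaviors have strict-mode switches.

## The driver score

The study evaluated driver roles qualitatively from VAF, impact, gene
function/expression and an external driver-prediction service. The
quantitative form used here is this package's own construction and is
documented as such:

$$s = w_v \min(\mathrm{VAF}_{max}/0.5,\, 1) + w_i\,[1\ \text{or}\ 0.6] +
w_e\,[\text{expressed}] + w_r\,[\text{recurrent}] + w_x\,[1, 0.5, 0]$$

with default weights (0.30, 0.20, 0.15, 0.15, 0.20). VAF saturates at
0.5 — a fully clonal heterozygous variant — so clonality above that adds
nothing. The score is bounded in [0, 1] and monotone in VAF; only those
properties, not the particular weights, are relied on anywhere.

## What the synthetic cohort emulates

`simulate_cohort()` generates the study conditions: 13 tumor–normal
pairs, Poisson depths with cohort means 159×/142× (per-patient means vary
with SD 12, centered so the cohort means are exact), binomial alt-read
sampling, 80% of somatic variants below VAF 0.05, 13–37 retained variants
per patient, clonal drivers at VAF 0.2–0.48, six planted recurrently
mutated genes, and three callers whose sensitivity is logistic in the
alt-read count (50% detection at 3, 4 and 5 reads for the three dialects)
so that the caller union measurably beats every single caller. Decoy
variants are engineered to fail exactly one cascade stage each
(population-common germline leakage, ClinVar-benign, low-impact), making
funnel attribution testable stage by stage.

Design choices worth recording:

* **Patient-specific clonal architecture.** Real leukemic cohorts show
  strongly heterogeneous VAF distributions between patients. Each
  simulated patient draws a narrow clone-specific VAF peak inside each
  configured band, a per-patient shape skew, and a subclonal/clonal
  mixture weight. Peak locations and mixture weights are *stratified*
  across patients (Latin-hypercube style) rather than drawn iid, so every
  simulated cohort — not just most — spans the architecture diversity the
  analysis is meant to detect; mixture weights and per-patient depth
  offsets are then centered so the cohort-level calibrations (80%
  subclonal, 159×/142× means) hold exactly.
* **Band conditioning and ground truth.** At 159× depth, binomial noise
  at VAF 0.05 has an SD of about 0.017, so unconditioned sampling would
  constantly shuffle variants across the retention threshold. Tiers are
  observed quantities, so the generator conditions each variant's
  realized alt count on the side of the threshold its role prescribes,
  and the truth table's `expected_pass` is computed by rule from the
  *realized* data: detected by at least one caller, both depths at the
  coverage gate, no engineered annotation decoy, observed VAF at or above
  the retention threshold. This is what makes exact (100%) cascade
  recovery a meaningful, achievable specification.
* **Determinism.** All randomness flows from one seed; per-patient
  substreams are derived deterministically, and an identical seed yields
  byte-identical bundles.

What it does **not** emulate: mutational signatures, genuine genomic
coordinates or haplotype structure, caller-specific artifact modes
(strand bias, FFPE damage), contamination, or copy-number-driven VAF
distortion. Passing the synthetic suite therefore demonstrates the
*logic* of the pipeline — merging, filtering, accounting, network
construction — not robustness to every failure mode of real exomes.

## Statistical notes

* The Kruskal–Wallis statistic uses the standard tie correction
  (`stats::kruskal.test`); an all-tied input has no rank variation and is
  reported as H = 0 with a degenerate flag rather than NaN. The test is
  applied to the full deleterious set (including sub-threshold VAFs),
  where the subclonal structure lives. Tests cross-check H against a
  directly evaluated rank-sum formula and the chi-square p-value against
  a 10,000-draw permutation oracle.
* The burden-vs-coverage check uses Spearman rank correlation (two-sided,
  alpha 0.05): both scales are skewed counts, and the question is
  monotone association, not linearity. Constant inputs return a
  degenerate flag instead of an undefined coefficient.
* Percentages are rounded half-up (5/57 → 9%, 2/13 → 15%).

## Problem sizes

The test suite and the acceptance script simulate 20-seed batches of
full-size cohorts (~1,700 planted variants each, ~34,000 records in
total), run the 10,000-permutation oracle on ten datasets of 30–70
observations, and check clique conversion for complexes of 2–8 members.
The network fixtures are deliberately small (tens of nodes) because every
assertion on them is exact set equality against a planted truth.

## Limitations

* The cohort-scale counts of the original study (thousands of raw calls
  funneling to hundreds retained) cannot be reproduced without the
  original sequence data, which is not publicly deposited; the pipeline
  is validated on worked examples from printed tables and on synthetic
  cohorts instead.
* Pathway conversion implements the three named rules only; richer
  semantics of full topology-conversion frameworks (e.g. directional
  signal propagation, stoichiometry) are out of scope.
* The driver score is a transparent linear evidence combination, not a
  trained model; its weights encode emphasis, not calibrated
  probabilities.
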