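---
title: "Methods: CFDR statistics, triage criteria and diagnostic-strategy costs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CFDR statistics, triage criteria and diagnostic-strategy costs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfdrtriage)
```

## The problem

Lynch syndrome (LS) is the most common inherited cause of colorectal cancer,
an autosomal dominant predisposition driven by germline mutations in the
mismatch-repair (MMR) genes *MLH1*, *MSH2*, *MSH6* and *PMS2*. A clinical
genetics unit receiving referrals for suspected hereditary colorectal cancer
must decide, per family, which laboratory route to take: the classical
stepwise route (tumor MMR functional analysis by microsatellite-instability
testing and/or immunohistochemistry, optionally a BRAF V600E reflex test,
then targeted germline sequencing) or direct multi-gene panel sequencing.
This package implements the quantitative machinery for that decision: a
pedigree statistic summarising familial tumor burden, triage criteria
operating on that statistic, and a cost model comparing the two laboratory
strategies, together with a synthetic cohort generator so that every stage
can be exercised and validated without clinical data.

## The CFDR / LAD statistic

For each pedigree the unit of analysis is the **cluster of first-degree
relatives (CFDR)** carrying the largest number of LS-associated tumors.
LS-associated sites are fixed: colorectal, rectal, endometrial, ovarian,
gastric, small bowel and upper urinary tract. Rectal cancer is kept as its
own code because MMR deficiency in rectal tumors is rare in sporadic disease
and therefore itself an LS indicator; any other site is coded `other` and
never counts. Metachronous and synchronous primaries count independently, so
one heavily affected individual can contribute several tumors.

The algorithm:

1. **First-degree graph.** Edges connect parent–child pairs and full
   siblings (both parents shared and recorded). Spouses are never edges;
   half-siblings are second-degree.
2. **Branch partition.** Every blood relative of the proband is assigned to
   the maternal or paternal branch, or to the *nuclear* set (the proband,
   its full siblings and their descendants, and the proband's own
   descendants), by intersecting ancestor sets: shared ancestry only through
   the mother is maternal, only through the father paternal, through both
   parents nuclear. Individuals with no common ancestor — spouses marrying
   in — are unrelated and can never join a cluster.
3. **Candidate clusters.** For each branch, the affected individuals
   (those with at least one LS-associated tumor) whose branch is that side
   or nuclear form a subgraph of the first-degree graph; its connected
   components, singletons included, are the candidates. A cluster therefore
   never spans both parental branches, and nuclear members can appear in
   candidates of both sides. Purely nuclear components arise identically on
   both sides and are kept once, labelled `nuclear`.
4. **Scoring and LAD.** A cluster's tumor count is the number of
   LS-associated tumor records over its members. Its **lowest age at
   diagnosis (LAD)** is the minimum over the cluster's own tumor ages and
   the LS-tumor ages of affected *second-degree* relatives of the proband
   (grandparents, grandchildren, aunts/uncles, nieces/nephews,
   half-siblings) whose branch matches the cluster's branch or is nuclear.
   Second-degree relatives can thus lower LAD but never raise it and never
   add to the tumor count.
5. **Selection.** The cluster with the most tumors wins; ties break by
   lower LAD, then fewer members, then lexicographic member ids, making the
   result fully deterministic.

Two points here were genuinely open design choices. First, the second-degree
set for the LAD extension is anchored on the *proband*, not on arbitrary
cluster members; the proband anchors the referral, and anchoring elsewhere
would make LAD depend on which member one asks from. Second, clusters
consist of affected individuals connected *through affected individuals
only*; an unaffected obligate carrier does not bridge two affected relatives
into one cluster. Both choices are encoded in `select_cfdr()` and exercised
against an exhaustive-subset oracle in the test suite: on pedigrees small
enough to enumerate every single-branch, first-degree-connected affected
subset (up to 8 members, 200+ random cases), the selected cluster equals the
brute-force optimum.

## Triage criteria

Probands are triaged on the pair (tumor count, LAD), in whole years:

| category    | rule                          | action                     |
|-------------|-------------------------------|----------------------------|
| `panel_a`   | 1 tumor, LAD < 40             | direct gene panel          |
| `panel_b`   | 2 tumors, LAD < 50            | direct gene panel          |
| `panel_c`   | ≥ 3 tumors, LAD < 60          | direct gene panel          |
| `mmr_first` | 1 tumor, LAD 40–49            | MMR functional test first  |
| `none`      | anything else                 | no laboratory testing      |

Boundaries are strict `<` at 40/50/60; the `mmr_first` band is the closed
integer range 40–49, so LAD 49 is `mmr_first` and LAD 50 is `none`. The
two-tumor rule as an *eligibility* criterion reads "at least two tumors",
which overlaps the three-tumor rule; reporting categories use exact counts
(1, 2, ≥ 3) so that category histograms partition a cohort. A consequence
worth stating: exactly two tumors with LAD in 50–59 is `none`. The
`mmr_first` band exists because national guidance promotes MMR functional
testing for all colorectal cancer diagnosed before 50; a deficient tumor in
that band continues to targeted sequencing, with the gene count taken from
the immunohistochemistry pattern (a lost heterodimer pair MLH1/PMS2 or
MSH2/MSH6 means two genes, a single lost protein one, MSI positivity
without informative staining all four).

The classifier is checked by an exhaustive sweep over tumor counts 1–6 and
LAD 20–70: every cell maps to exactly one category, and eligibility is
monotone in LAD at fixed count.

## The historical stepwise cascade

The comparison baseline is a reconstruction of the stepwise work-up, since
only aggregate analysis counts — not per-patient routing rules — are
available: MMR functional analysis first; on deficiency with the MLH1/PMS2
staining pattern and BRAF testing available, a BRAF V600E reflex test whose
positive result indicates sporadic MLH1 promoter methylation and stops the
cascade; otherwise sequencing of 1–4 genes guided by the staining pattern.
MSH2/MSH6 loss never triggers BRAF, which only discriminates MLH1-methylated
sporadic tumors. The tree is configurable (`workup_config()`): the BRAF era
flag, the MSI-only gene count, and explicit per-proband overrides for
referrals that went straight to germline sequencing. Fixture cohorts may
bypass the tree entirely by supplying analysis counts directly, which is how
the published cost table is reproduced.

## Cost model

All prices are whole 2012-level euros: MMR functional analysis 356, BRAF
V600E 640, Sanger sequencing of 1/2/3/4 genes 556/1022/1422/1689, gene
panel 1648. Money stays in integer arithmetic end to end; a strategy total
is the sum of count × unit price over line items held in a fixed declared
order, so reports are byte-stable. The comparison statistic is the excess
fraction `total_B / total_A − 1`, also displayed as an integer percent
(rounded half away from zero). Currency conversion is outside the engine —
the table is already in euros — and any price can be overridden from a
YAML/JSON table for sensitivity analysis.

## The synthetic cohort generator

`generate_cohort()` emulates the referral cohort the pipeline is meant for;
its defaults *are* the study conditions and are not tuned per run:

* **Cohort composition.** 372 probands; 13% carry a pathogenic MMR-gene
  mutation, split MSH2 0.46 / MLH1 0.31 / MSH6 0.21 / PMS2 0.02.
* **Pedigree topology.** Three generations: four grandparents, the parents
  with 0–3 aunts/uncles per side, the proband with 0–3 siblings. Deeper or
  consanguineous pedigrees are out of scope.
* **Segregation.** In a carrier family the mutation enters through one
  grandparent on a random side and segregates dominantly (transmission
  1/2); the connecting parent and the proband are forced carriers because
  the referral is conditioned on the proband's phenotype.
* **Onset.** Carrier tumor ages are drawn per gene from normal
  distributions truncated to [18, 90], means 37/39/42/44 years for
  MLH1/MSH2/MSH6/PMS2. The spread is set to a quarter of the observed
  per-gene range (6.25/8.75/4.25), the simplest distribution consistent
  with a reported mean and range; PMS2, observed only once, gets an assumed
  SD of 5.
* **Burden.** The carrier branch carries `1 + Poisson(intensity − 1)`
  LS tumors (intensities 4.3/3.4/3.2/2 by gene), spread over carriers with
  the proband always keeping one, so every carrier proband is affected and
  the per-gene burden ordering MLH1 > MSH2 > MSH6 > PMS2 is built in.
* **Sporadic background.** Non-carrier relatives acquire a sporadic tumor
  with probability 0.12 (5% of them at non-LS sites), onset ~N(52, 10)
  truncated to [25, 90]; a non-carrier proband gets one (8% of the time
  two) sporadic LS-site tumors. 15% of sporadic colorectal tumors are
  MMR-deficient via MLH1 methylation, and 60% of those are BRAF-positive —
  the midpoint of the reported 20–50% BRAF-negative share.
* **Assays.** A carrier's tumor shows deficiency with sensitivity 47/48,
  staining follows the heterodimer (MLH1 drags PMS2, MSH2 drags MSH6);
  about 1% of probands (4/372) skip tumor testing for direct sequencing;
  the BRAF reflex assay covers 16% of MLH1/PMS2-deficient tumors
  (reflecting its late introduction in the emulated era); 8% of
  proficient-tumor probands are screened anyway on clinical suspicion.
  The last three rates are calibration knobs: the emulated study reports
  aggregate assay counts (368 tested, 15 BRAF, 114 screened), not
  per-patient rules, so realistic rates were fixed once from those
  aggregates.

What the generator does **not** emulate: real mutation spectra or
variant-level data, EPCAM deletions (absent from the emulated cohort),
MLH1-methylation assays, ascertainment drift over a 17-year referral window,
and the detailed correlation structure of real family histories. Passing
tests therefore show that the pipeline's logic is correct and calibrated
against its own generative model — not that the criteria would achieve the
same sensitivity on another clinic's referrals. Cohort-level means of the
real data (2.5 tumors, LAD 47) are approached but not targeted; no generator
parameter is fitted to them.

Under the defaults the simulated cohort reproduces the qualitative finding
that motivated the criteria: MMR-deficient clusters carry more tumors at
lower ages (both Mann–Whitney p-values far below 0.05 at n = 2000), and the
generator recovers its own carrier fraction, sporadic deficiency rate and
per-gene onset means within three Monte-Carlo standard errors at n = 5000.

## Statistical notes

`mann_whitney_u()` computes U from midranks. With no ties and
`n1 · n2 ≤ 400` the two-tailed p-value is exact, from the Mann–Whitney null
distribution; otherwise a normal approximation with tie-corrected variance
and a 0.5 continuity correction is used, and the method applied is recorded
in the result. The exact branch is verified against a brute-force
enumeration of all group labelings for n ≤ 5 per group and against the
reference exact Wilcoxon test; the approximation stays within 0.02 of the
exact p on small samples, and the test holds its type-I error within three
binomial standard errors of the nominal 0.05 over 400 null simulations.
Display percentages round half away from zero to integers; exact fractions
are retained internally.

## Numerical and interface choices

* Ages are integer whole years throughout; no dates are stored or parsed.
* PED input accepts tab- and space-delimited files; `0` and the empty
  string both denote a missing parent; sexes are coded 1/2/0. The PED
  phenotype column, a placeholder in the 6-column dialect, marks the
  proband (value 2, exactly one per family) — the pedigree model requires a
  unique proband and standard PED has nowhere else to carry it.
* Pedigrees with an unaffected proband are accepted at parse but excluded
  from CFDR statistics, mirroring the exclusion of referrals without tissue
  from a symptomatic individual.
* Parsing is order-independent and validation rejects dangling parents,
  parentage cycles and duplicate `(individual, tumor_index)` pairs with the
  offending identifiers named.
* Problem sizes used by the checks — 200+ oracle pedigrees, a 372-proband
  default cohort, 2000 probands for the direction test, 5000 for parameter
  recovery, 400 null replicates — were chosen so each property is measured
  with comfortable Monte-Carlo margins while the whole suite stays quick to
  run.

## Limitations

The historical cascade is a reconstruction from aggregate counts; per-patient
routing in the emulated era involved clinical judgment the model cannot
recover, which is why fixture cohorts drive the published-cost reproduction
directly from analysis counts. The criteria themselves were tailored
retrospectively to one region's referrals; as with the original proposal,
they should not be transferred to another clinical setting without
independent validation — in particular, late-onset MSH6/PMS2 families and
recessive MUTYH-associated polyposis cases with sparse family history can
escape family-history-based selection entirely.
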