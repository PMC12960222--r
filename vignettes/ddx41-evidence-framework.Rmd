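---
title: "Quantitative evidence for DDX41 variant classification"
author: "ddx41curate authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative evidence for DDX41 variant classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddx41curate)
```

## The problem

Germline *DDX41* variants are the most common cause of hereditary
predisposition to MDS/AML, but they are hard to classify: disease onset is
late, penetrance is incomplete, several variants are ancestry-specific
founder alleles, and no validated functional assay exists. Under baseline
ACMG/AMP curation the large majority of reported missense variants end up
as variants of uncertain significance (VUS).

*DDX41* does, however, offer an unusually informative piece of biology: in
carriers who develop myeloid malignancy, the malignant clone very often
acquires a **somatic second hit** in *DDX41* — most commonly the missense
variant R525H, or one of a small set of recurrent hotspots (G530D, P321L,
T227M, E345D, G530S, D344E). In patients *without* a deleterious germline
variant, somatic *DDX41* variants are rare and skew toward non-recurrent or
multiple hits. This package turns that asymmetry, together with
case-enrichment and computational-prediction evidence, into quantitative,
reproducible ACMG/AMP evidence codes.

## The OddsPath model (PP4)

For one germline variant observed in $N$ somatic-evaluable carriers, each
carrier's somatic finding is classified into one of four categories:

* $n_1$ — a single hit that is a registry hotspot ("single recurrent"),
* $n_2$ — a single non-hotspot hit,
* $n_3$ — two or more hits,
* $n_0$ — no somatic hit.

The model treats $(n_1, n_2, n_3, n_0)$ as a multinomial draw under two
hypotheses with category probabilities $p^{\mathrm{path}}$ (the variant is
deleterious) and $p^{\mathrm{null}}$ (it is not). The multinomial
coefficient is identical under both hypotheses, so the likelihood ratio —
the *odds of pathogenicity* — reduces to

$$\mathrm{OddsPath} \;=\; \prod_{k}
  \left(\frac{p^{\mathrm{path}}_k}{p^{\mathrm{null}}_k}\right)^{n_k},$$

which factorizes over carriers: every additional hit-free carrier
multiplies the evidence by $p^{\mathrm{path}}_0 / p^{\mathrm{null}}_0
\approx 0.31$, every hotspot carrier by $\approx 252$. An empty tally gives
exactly 1 (no evidence either way). The posterior probability of
pathogenicity follows from a prior $\pi$ via Tavtigian's formula,

$$\mathrm{Post} = \frac{\mathrm{OddsPath} \cdot \pi}
  {(\mathrm{OddsPath} - 1)\,\pi + 1},$$

and the OddsPath maps onto evidence strength through the Tavtigian bands
(supporting $\ge 2.08$, moderate $\ge 4.33$, strong $\ge 18.7$, very strong
$\ge 350$; half-open on the left).

### Default parameters

The default category probabilities are the frequencies observed in
aggregated MDS/AML case series:

```{r}
multinomial_model()
```

`p_path` comes from carriers of the most common established pathogenic
variants (single recurrent, single non-recurrent and multiple hits in 58%,
10% and 0.7% of evaluable carriers), `p_null` from cases without a germline
*DDX41* variant (0.23%, 0.20% and 0.14%); the "none" entries are
complements. `estimate_model_from_cohort()` is the explicit re-derivation
path for laboratories that want cohort-specific vectors; the defaults are
fixed model parameters, not re-fit at every call.

**Prior.** The default prior of 0.10 was chosen because it reproduces the
reference conversion pair for this model — an isolated carrier with one
hotspot hit has $\mathrm{OddsPath} = 0.58/0.0023 \approx 252$ and
$\mathrm{Post} = 25.2/26.1 \approx 0.97$:

```{r}
op <- likelihood_ratio(pattern_counts(1, 0, 0, 0))
c(oddspath = op, posterior = posterior_from_oddspath(op, 0.10))
```

This is a calibration anchor, not a clinical prevalence claim; the prior is
exposed in `multinomial_model()`.

**Why a likelihood ratio and not presence/absence.** The
presence-based comparator (`original_pp4()`) awards strong evidence to any
hotspot co-occurrence. The multinomial model is more stringent for sparse
or diluted observations: one hotspot among four evaluable carriers gives
$252 \cdot 0.3148^3 \approx 7.9$ — moderate, not strong — and 39 carriers
with only three non-recurrent hits fall far below supporting
($\approx 10^{-13}$), because 36 hit-free carriers are themselves evidence
against a deleterious allele.

### Numerical guards

* The ratio is computed in log space; zero counts contribute nothing even
  when a category probability is zero.
* A category observed with $p^{\mathrm{null}}_k = 0$ would claim infinite
  evidence; `likelihood_ratio()` refuses it with an error rather than
  returning `Inf`.
* Because the null probabilities are small empirical frequencies, the
  returned ratio is capped (default $10^6$, with a warning). The cap never
  changes a band — anything near it is already "very strong" — but keeps
  reports and downstream arithmetic finite. `oddspath_grid()` applies the
  same cap silently.

## Case enrichment with ancestry matching (PS4)

`haldane_or()` computes the odds ratio of a carrier/non-carrier by
case/control 2×2 table with the Haldane continuity correction (0.5 added
to every cell, unconditionally by default — the convention that reproduces
the reference aggregate OR of 346 from the cells 800/538/139/32499), and a
normal-approximation CI on the log odds ratio. Evidence strength is read
from the **lower** CI bound through the same Tavtigian bands, so small
carrier counts with huge point estimates still yield weak evidence.

Controls are population allele-count tables (gnomAD-like structure:
ancestry group, AC, AN). Control carriers are approximated as AC
heterozygotes, so the control table contributes AC exposed and
$\mathrm{AN}/2 - \mathrm{AC}$ unexposed individuals; for a rare
autosomal-dominant predisposition allele the all-heterozygote assumption
is innocuous.

**Founder variants.** Using pooled controls overestimates enrichment for
alleles concentrated in one ancestry group. `variant_ps4()` therefore
builds, besides the overall table, an ancestry-restricted table for every
group with at least `min_carriers` carriers (default 3), and when a single
non-reference group holds at least `dominant_fraction` of carriers
(default 2/3) the final strength is the *minimum* of the overall and the
matched strength. The 2/3 trigger is this package's explicit choice — the
downgrade behaviour it implements is described in the field by outcome
rather than algorithm — and both knobs sit in `ps4_policy()`. Carriers
with unknown ancestry can never be matched and never trigger the
downgrade.

Prevalence summaries use Wilson score intervals (`prop.test` without
continuity correction): robust at small counts, and indistinguishable from
the Wald interval at the cohort sizes where the reference prevalences
(4.0%, 3.2% with CI 3.0–3.4%) are quoted. Pairwise group comparisons use
two-sided Fisher exact tests under the probability-mass convention (the
sum of outcomes no more probable than the observed table) with
Benjamini–Hochberg adjustment across all pairs.

## Computational prediction (PP3/BP4)

Truth sets for calibrating missense predictors are built from orthogonal
evidence, never from the scores themselves: pathogenic = germline missense
variants with at least one carrier showing a single recurrent somatic hit
(excluding variants flagged as splice-region, where the mechanism may be
splicing); benign = population-database missense variants absent from the
aggregated case series. `roc_auc()` and `delong_compare()` wrap pROC — the
standard ROC implementation in this field — and expose the empirical AUC
(identical to the Mann–Whitney concordance statistic), its DeLong CI, and
the paired DeLong test for comparing two tools on the same variants. The
Youden threshold is maximized over all observed score values with ties
broken toward the higher (more specific) threshold.

`assign_pp3_bp4()` applies supporting-strength PP3/BP4 at fixed cutoffs:
AlphaMissense $\ge 0.792$ / $\le 0.169$ (the calibrated recommendation;
the default tool) or REVEL $\ge 0.7$ / $\le 0.3$. A SpliceAI max delta
score at or above 0.2 (a common clinical convention; the source analyses
name the tool but not a cutoff) overrides the missense score: PP3 applies
and BP4 is suppressed. PP3/BP4 are fixed at supporting strength;
calibrated-strength extensions are deliberately out of scope.

## Combining evidence

`combine_codes()` uses the Bayesian point scale (supporting = 1,
moderate = 2, strong = 4, very strong = 8; benign supporting = −1) with
tier bands P $\ge 10$, LP 6–9, VUS 0–5, LB −6…−1, B $\le$ −7. The point
system was chosen over the categorical 2015 combining rules because the
evidence strengths produced here are Tavtigian-scaled by construction, and
it is consistent with the anchor example PVS1 + PM2\_supporting
$= 8 + 1 = 9 \rightarrow$ LP. PS4 and PP4 are combined as independent
codes even though both draw on case data, mirroring how the two criteria
are applied in parallel in practice; PP4 may contribute up to very strong
(8 points).

`curate_variant()` is a pure composition of the individual operations —
the report it returns contains every intermediate (pattern counts,
OddsPath, per-ancestry odds ratios, each code's rationale, the carrier
list and the config snapshot), and manual overrides replace a computed
strength only with an explicit audit note.

## Cohort handling choices

* **Aggregation key.** Variants are keyed by normalized protein change
  when available, falling back to HGVSc (`variant_key()`): aggregated
  series count e.g. E345D across two distinct codon changes, and
  frameshifts across indel notations. A config switch forces strict HGVSc
  keying.
* **Evaluability.** Published series rarely state which carriers had
  somatic sequencing. `somatic_evaluable` defaults to `TRUE` and is
  dropped to `FALSE` only when flagged; per-source review of this flag is
  recommended, since misclassification directly rescales $n_0$.
* **Non-cohort deduplication.** Case reports outside consecutive cohorts
  are merged by `merge_noncohort()`: cases without somatic hits are always
  retained; a case with somatic hits is retained only if no cohort case
  with the same germline variant reports the identical somatic
  protein-change set; previously merged case ids are skipped, making the
  merge idempotent.
* **Dual-variant carriers** contribute their somatic pattern to each
  carried variant's tally.

## The synthetic-cohort generator

`generate_cohort()` emulates the statistical structure the analyses
assume: a patient series with a realistic diagnosis mix (63% MDS/AML, 15%
other myeloid, 10% cytopenias, 2% lymphoid, 10% excluded) and ancestry mix
(55% NFE, 30% EAS, 10% other, 5% unknown); a variant catalog with
per-ancestry carrier frequencies including an EAS-concentrated
founder-style frameshift; somatic patterns drawn from the multinomial
model (pathogenic vector for carriers of generating-class pathogenic
variants, null vector otherwise, so non-carriers show rare somatic-only
hits); binomial control allele counts at gnomAD-scale allele numbers; and
class-separated Beta score distributions (a single value is treated as a
point mass for degenerate checks). Each logical component — cases,
controls, scores — draws from its own stream derived from the master seed,
so adding one component never perturbs another.

Two deliberate simplifications: each synthetic case carries **at most one**
catalog variant (dual carriers are below 1% of real series, and allowing
independent co-carriage at test-scale frequencies would attribute one
variant's second hits to another), and hotspot identity within the
"single recurrent" category is drawn from fixed relative weights
dominated by R525H. The generator does not simulate reads, VAF kinetics,
clonal evolution, or detection sensitivity — so passing recovery tests
demonstrates statistical correctness of the pipeline, not robustness to
the reporting heterogeneity of real literature data.

### Problem sizes used in the test suite

The packaged tests run recovery at desk scale, chosen once: pattern-
frequency checks on 10 000 simulated carriers (three Monte-Carlo standard
errors); band recovery at 5, 25 and 100 carriers over 200 replicates
(at five carriers a lone non-recurrent hit can leave a true pathogenic
variant below supporting, and a chance hotspot can just lift a benign one
over it, so the documented tolerance there is 95%; at 25 and 100 carriers
recovery is exact across all replicates); and end-to-end curation on 200
replicate 500-case cohorts with catalog carrier frequencies enriched to
5%/2% so that pathogenic variants regularly reach ten carriers.

## Known limitations

* The model is calibrated on established deleterious variants; alleles
  with lower penetrance or atypical somatic association patterns (the
  recurrent-hit germline alleles R525H and P321L themselves being the
  notorious examples) are outside its assumptions.
* PS4 ancestry matching is only as good as the reported ancestry labels;
  unreported ancestry is never imputed.
* PVS1 is a type-level policy table, not an exon-level NMD decision tree;
  PM1/PM5/PS1/BS1/BS2 are not implemented because the framework does not
  exercise them.
* Exact cell definitions behind individual published per-variant odds
  ratios are not all recoverable from printed summaries; only the
  aggregate second-hit association is pinned numerically.
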