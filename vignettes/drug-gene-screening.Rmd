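---
title: "Subtype-stratified drug–gene correlation screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtype-stratified drug–gene correlation screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmacoscreen)
library(dplyr)
```

## The problem

Large cancer cell line panels pair basal gene-expression profiles
(CCLE/DepMap-style RNA-seq, log2(TPM+1)) with drug-response screens
(GDSC-style area under the dose–response curve, AUC, where higher AUC means
a more resistant line). A gene whose expression consistently tracks AUC
across many drugs of a target-pathway category — say, inhibitors of DNA
replication or mitosis — is a candidate biomarker of sensitivity (negative
association) or resistance (positive association) to that drug class. The
motivating application is mitochondrial chaperones (TRAP1, HSPD1, HSPE1,
CLPP, SPG7, HTRA2, AFG3L2, ...), but the machinery is gene-agnostic.

Tissue of origin confounds pan-cancer correlations: lineages differ in both
baseline expression and drug response. The screen therefore stratifies by
tissue subtype and only ever correlates within a subtype.

## The statistic

For each gene $g$, drug $d$ and subtype $s$, over the $n$ cell lines of $s$
that have both an AUC for $d$ and an expression profile:

$$r_{gds} = \mathrm{cor}(\text{expr}_g,\ \text{AUC}_d), \qquad
Z_{gds} = \operatorname{atanh}(r_{gds})\,\sqrt{n-3}.$$

The $\sqrt{n-3}$ factor is the reciprocal of the asymptotic standard
deviation of $\operatorname{atanh}(r)$ under the null, so $Z$ is
approximately standard normal whatever the group size, and one fixed cutoff
is meaningful across groups of different $n$. The operating cutoff is
$|Z| \ge 1.7$, which carries a two-sided standard-normal tail mass of
$2(1-\Phi(1.7)) \approx 0.089$; `permutation_null()` +
`empirical_cutoff()` can re-derive the cutoff empirically (shuffling AUC
within each group, expression fixed — a scheme chosen because it preserves
the group's expression structure and AUC marginal) and lands at ~1.7 on
null data, which is why the fixed constant is the default and calibration
an optional validation (`calibrate = TRUE`).

Significant correlations are aggregated per gene, drug category $c$ and
direction into the global score

$$\text{Score}_{global}(g, c, \pm) =
  100 \cdot \frac{\#\{(d,s): d \in c,\ Z_{gds} \text{ beyond } \pm 1.7\}}
                 {n_{\text{drugs}}(c)\cdot n_{\text{subtypes}}},$$

computed separately for the sensitivity (negative $Z$) and resistance
(positive $Z$) directions. A score is called significant when it exceeds
the 95th percentile (type-7, linear-interpolation quantile; strict
inequality) of the score distribution of its direction taken over *all*
genes in the expression matrix — a focused panel is always judged against
the genome-wide background (`add_score_significance(reference = ...)`).
Per-subtype contributions then report, for each subtype, the percentage of
the category's drugs tested in that subtype that are significant,
identifying the cancer types driving a score.

No multiple-testing correction is applied at the single-correlation level:
the method is not meant to certify individual drug–gene pairs but to
surface categories in which a gene shows many coherent (possibly slight)
correlations; the permutation null plus the genome-wide score quantile are
the calibration devices.

### Counting conventions

Three denominators were genuinely open design choices:

* **Global score.** The denominator is the full
  $n_{\text{drugs}}(c) \times n_{\text{subtypes}}$, even when some
  (drug, subtype) combinations produced no valid group — untested
  combinations count as non-significant, which makes scores conservative.
  $n_{\text{subtypes}}$ is fixed once per run (distinct subtypes across
  all retained groups), not per category.
* **Undefined correlations.** A gene constant within a group, or a drug
  with constant AUC, gives an undefined $r$. The record is kept with
  `r`/`z` set to `NA` and both flags `FALSE`: the drug *was* tested, so it
  stays in the global denominator but can never enter a numerator.
* **Subtype contributions.** The denominator is the number of category
  drugs with a *valid correlation in that subtype* (subtypes differ in
  drug coverage), not the category size. Both counts are returned
  (`n_sig_subtype`, `n_drugs_tested`) so the other convention can be
  recomputed.

## Cohort curation

Defaults (all exposed in `default_config()`):

| parameter | default | meaning |
|---|---|---|
| `category_merges` | EGFR→ErbBs, IGF1R→RTK, "Other, kinases"→Kinases | pathway-level category merges, applied before size filtering; chained renames rejected |
| `min_drugs_per_category` | 10 | categories below this, plus "Other"/"Unclassified"/unassigned drugs, are removed |
| `excluded_tissues` | blood, bone, soft tissue | solid-tumour focus; case-insensitive |
| `min_lines_per_group` | 10 | minimum cell lines per (drug, subtype) group, applied *after* the expression join, since correlations are computed per drug |
| `z_cutoff` | 1.7 | two-sided significance cutoff on $Z$ |
| `score_tail_fraction` | 0.05 | upper-tail fraction for the score cutoff |
| `tail_mass` | 0.0446 | per-tail mass for `empirical_cutoff()`; chosen so a standard-normal null reproduces 1.7 |

Cell lines are matched between tables by exact normalised identifier only
(upper-cased genes, whitespace-trimmed line ids); fuzzy matching silently
mis-joins, dropped lines are merely logged. Expression values are consumed
as released (log2 scale); no re-transformation is attempted.

## Numerical choices

* Perfect correlations ($r = \pm 1$, common in tiny fixtures) are clamped
  to $\pm(1 - 10^{-7})$ before `atanh`, giving a large finite $Z$ rather
  than an error or infinity.
* `fisher_z()` requires $n \ge 4$ so $\sqrt{n-3}$ is real and positive;
  the cohort filter keeps groups far above this anyway.
* Quantiles (score cutoff, empirical $Z$ cutoff) use R's default type-7
  linear interpolation; significance comparisons are strict (`>`), so an
  all-equal score distribution calls nothing significant.
* Hierarchical clustering (`hierarchical_order()`) uses Euclidean distance
  with unweighted average linkage (UPGMA) — the common clustermap defaults;
  both are arguments. Missing cells (drug untested in a subtype) are
  filled with 0 ("no evidence") for the distance computation only, rather
  than dropping rows, which would erase part of the subtype roster. Labels
  are sorted before clustering so the tree does not depend on input order;
  ties break by label order.

## The synthetic-data generator

`generate_dataset()` emulates the *shape and correlation structure* of a
CCLE + GDSC panel: a genes × lines log2 expression matrix (per-gene means
uniform in [1, 8] log2 units, within-gene sd 1, truncated at 0), a full
drugs × lines AUC table (Normal with mean 0.85, sd 0.08 — resistant-skewed,
clipped to (0, 1]), a drug catalog with evenly-sized categories, and one
tissue per subtype. Planted effects inject a chosen population correlation
$\rho$ between one gene and a fraction of one category's drugs in chosen
subtypes, by blending the standardised gene signal (weight $\rho$) with
independent noise (weight $\sqrt{1-\rho^2}$) before the affine map to AUC
scale. Effects are planted at the correlation level, not via dose–response
simulation: the screen consumes AUC only, so the correlation structure is
the sufficient statistic.

Deliberate non-realism — what passing tests do *not* show about real data:
every drug is tested on every line (real panels are sparse); AUC noise is
Gaussian rather than the skewed, multimodal mixture real screens show;
expression is uncorrelated across genes (no co-expression modules), so the
genome-wide score distribution is better behaved than with real gene-gene
correlation; there are no batch effects and no lineage-specific expression
shifts. Two small artefacts of the chosen scales are documented rather than
hidden: about 3% of AUC draws exceed 1 and are clipped (the generator warns
whenever clipping reaches 1%; measured attenuation of planted correlations
is negligible), and low-mean genes feel the truncation at 0.

Default dimensions (200 genes, 3 × 20 drugs, 6 subtypes × 25 lines) are
the package's standard validation scenario: planting $\rho = -0.6$ between
one gene and 80% of one category in 3 of 6 subtypes yields a sensitivity
score near 40% against a genome-wide 5% cutoff near 8%, and the planted
subtypes are recovered as the top-3 contributors in essentially every
seed. The test suite runs this at 50 seeds, the no-effect null calibration
at 10,000 (gene, drug, subtype) records with 30 lines per group, and the
brute-force oracle comparison at 5 × 4 × 2 — sizes chosen so the whole
suite completes in about a minute on one core while keeping Monte-Carlo
error well inside the asserted bands.

## Known limitations

* Correlation is not causation; the screen ranks hypotheses, it does not
  establish mechanism, and immortalised lines may not represent tumours.
* Scores compare categories within one run; they are not calibrated across
  panels with different subtype rosters or category sizes.
* Cluster-adjacency conclusions (which genes or subtypes group together)
  are checked only under the default metric/linkage; other settings may
  reorder leaves.
* The external-data path (real DepMap/GDSC releases) exercises the same
  code but expects the user to supply the downloads; no network access is
  ever attempted.
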