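---
title: "Modelling immune evasion and ICI response from bulk expression signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling immune evasion and ICI response from bulk expression signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iciscore)
```

## The problem

In urothelial carcinoma, response to anti-PD-L1 checkpoint blockade is
heterogeneous and poorly predicted by single biomarkers. Two observations
motivate the model in this package. First, tumors fall along a
luminal-to-basal differentiation axis, measurable from bulk RNA-seq with a
subtype gene panel such as BASE47. Second, an immunosuppressive
tumor-associated macrophage population (here called Macro-C3, marked by genes
such as *IDO1* and *CD274*) accumulates in basal tumors together with
exhausted CD8+ T cells. The macrophage signature score consequently carries
two opposite meanings depending on where a tumor sits on the subtype axis: in
luminal-leaning tumors it tracks an active (and therefore ICI-responsive)
immune compartment, while in strongly basal tumors it measures the evasion
machinery that keeps T cells dysfunctional, and response decouples from the
score.

`iciscore` implements the scoring machinery around that idea: single-sample
enrichment scoring of the four signatures, the log(basal/luminal) subtype
axis, a regression-intersection model that locates the point where the
macrophage signal overtakes cytotoxicity, and a piecewise ICI response score.
Synthetic-data generators with the same statistical structure make the whole
pipeline testable end to end without access to any patient cohort.

## Signature scoring

Scores are computed by single-sample gene-set enrichment (ssGSEA) on
log-normalized TPM, `log2(TPM + 1)`. For each sample, genes are ranked by
expression (descending, ties broken by gene name so results are
platform-independent) and the enrichment score is

$$ES(S) = \sum_{i=1}^{G}\left[\frac{\sum_{k \le i,\, g_k \in S} w_k}
{\sum_{g \in S} w_g} - \frac{\#\{k \le i : g_k \notin S\}}{G - |S|}\right],$$

with rank-power weights $w_k = r_k^{\alpha}$ ($r_k$ = within-sample
expression rank, $\alpha$ = 0.25 by default, exposed as an argument). Because
the weights are functions of ranks only, scores are invariant to any strictly
increasing per-sample transform of expression; at $\alpha = 0$ the statistic
is a pure rank statistic. No cross-sample normalization is hidden inside the
scoring step: mapping raw (possibly negative) enrichment scores onto a
positive interval is the explicit `rescale_scores()` operation (affine onto
$[0.01, 1]$), which is required before the basal/luminal ratio is taken. The
normalization applied is carried on every score vector as a tag.

The subtype axis is $r_i = \log(b_i / l_i)$ (natural log) of the rescaled
basal and luminal scores. Swapping the two gene sets negates the axis
exactly; this antisymmetry is asserted in the tests.

## The evasion model

With cytotoxicity and Macro-C3 scores z-scored (sample SD, $n-1$
denominator), two ordinary least-squares lines are fitted against the
subtype axis $r$:

$$L_C:\; Z(C) = \beta_{0C} + \beta_{1C}\, r, \qquad
  L_M:\; Z(M) = \beta_{0M} + \beta_{1M}\, r,$$

and their intersection $(a, b)$ is the cohort threshold:
$a = (\beta_{0M} - \beta_{0C}) / (\beta_{1C} - \beta_{1M})$. Below $a$,
cytotoxicity exceeds the macrophage signal; at or above it the order flips.
The piecewise ICI response score is

$$s_i = \begin{cases} m_i & r_i < a \\ \min_j m_j & r_i \ge a, \end{cases}$$

i.e. samples in the evasion regime are floored to the cohort-minimum
Macro-C3 score. The threshold comparison is strict (`< a`), and a published
cohort threshold (e.g. 0.294 for the IMvigor210 scoring conventions) can be
supplied to `predict()` in place of the fitted one — it is an input, never a
constant baked into the package.

One property worth stating explicitly: an OLS line always passes through
$(\bar{x}, \bar{y})$, and a z-scored response has $\bar{y} = 0$, so when both
responses are z-scored on the same samples, both lines pass through
$(\bar{r}, 0)$ and the intersection abscissa equals the cohort mean
log-ratio exactly (whenever the slopes differ). The intersection estimator
is therefore an estimator of the *center of the cohort's subtype-axis
distribution*; its clinical content rests on the empirical fact that the
responder-fraction curve bends near that point. The fitter itself is generic
and reproduces textbook intersections for non-z-scored inputs (the tests pin
`y = 2x + 1` vs `y = -x + 4` to $(1, 3)$ at $10^{-9}$).

The responder-fraction curve evaluates, at 256 evenly spaced cutoffs
spanning the observed axis range, the cumulative fraction of responders
among samples at or below the cutoff. The cumulative form is self-checking —
at the maximal cutoff it equals the cohort responder rate exactly — which is
why it is the default; a sliding-window variant (window fraction 0.2 of the
axis range) is available for local rates.

## What the synthetic cohorts emulate

`generate_bulk_cohort()` draws a latent basal axis $t_i$ uniform with unit
half-width centered on the generating threshold (so $[-1, 1]$ at the default
threshold 0). On the log2 scale, basal-signature genes rise along the axis
(slope 2), luminal genes fall (slope −2), and the Macro-C3 and cytotoxicity
genes rise with configurable slopes (default 1.5), all with Gaussian noise
(SD 0.3); values are exponentiated and column-rescaled to TPM. Rank-based
scoring downstream only needs this monotone structure, which is why a
Gaussian-on-log-scale model is sufficient.

Centering the axis on the threshold is a deliberate consequence of the
mean-pinning property above: the regression intersection identifies the
center of the axis distribution, so the generating threshold is only
identifiable when the cohort is centered on it — which is also the
configuration in which a threshold is clinically interesting (both regimes
populated). Recovery is asserted on the latent scale by mapping the fitted
$a$ back through a calibration regression of the true axis on the estimated
log-ratio; with $n = 400$ and default noise the mean absolute error over 20
seeds is well under 0.05.

Response labels are drawn with probability
$\mathrm{logit}^{-1}(\mathrm{logit}(p_0) + \lambda z_i)$ below the
threshold, where $z_i$ is the standardized latent macrophage score,
$p_0 = 0.3$ and $\lambda = 2$ by default; at or above the threshold the same
expression is evaluated at the cohort-minimum $z$ — a constant low baseline
decoupled from the sample's own score, mirroring the piecewise scoring rule.
Defining the baseline through the same link (rather than as a free constant)
makes $\lambda = 0$ collapse the whole cohort to a single probability, so
null cohorts are exactly null: the ICI-score AUC averages 0.50 over 50
seeds, inside the [0.45, 0.55] calibration band.

The defaults are chosen for test power, not biological realism: no published
effect size links the basal program to macrophage infiltration at the
gene-expression level. Likewise the generators do not emulate batch
effects, ambient RNA, doublets, or realistic library-size variation — passing
tests demonstrate that the *rules and estimators* are implemented correctly,
not that they will perform at any particular level on real cohorts.

The single-cell generator uses negative-binomial counts (dispersion 0.5,
log-normal library factors), cluster markers with 8-fold boosted means,
mitochondrial genes scaled to about 8% of UMIs in healthy cells, and
ligand/receptor genes expressed in configurable per-cluster cell fractions.
Low-quality cells violating each QC rule can be planted relative to a stated
QC reference, and are recorded so tests can assert exact removal.

## Single-cell rules

* **QC**: genes expressed in more than 3 cells are kept first; cells are then
  removed if they have more than 5000 expressed genes, 200 or fewer expressed
  genes, or more than 25% mitochondrial UMIs. Boundaries are strict in those
  directions (exactly 200 genes removed, exactly 5000 kept, mito fraction
  exactly 0.25 kept). The rule order (gene filter before cell rules) is a
  convention; the report also records the counts the opposite order would
  produce, so order sensitivity is visible rather than silent.
* **High-confidence DEGs**: a gene passes for a subtype only if *every*
  sample of that subtype shows a log2 fold change above 0.8 (strict) over the
  average of the other subtype's samples, computed on log2-scale per-sample
  mean expression. The all-samples quantifier makes the call robust to a
  single dominant patient; no gene can pass in both directions.
* **Compartment proportions**: per-sample share of a target cluster within a
  compartment (e.g. immunosuppressive macrophages among myeloid cells);
  samples with fewer than 100 compartment cells are flagged excluded rather
  than dropped silently.

## Ligand–receptor screen

Interaction strength between a sender and receiver cluster is the arithmetic
mean of the ligand's mean log-normalized expression over sender cells and
the receptor's over receiver cells, gated unless each gene is expressed in
strictly more than 10% of its cluster's cells. Significance is by label
permutation over all cells (1000 by default) with the add-one convention
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(n_{\text{perm}} + 1)$, so $p$
is never zero; an exact mode enumerates all distinct label assignments on
tiny inputs and is checked against independent enumeration in the tests. A
within-sample stratified permutation is available. The screen correlating
per-sample interaction strengths with the exhausted-T-cell fraction uses
two-sided Pearson tests at $\alpha = 0.05$, skipping constant strength
vectors, with no multiplicity correction by default (Benjamini–Hochberg can
be applied to the returned p-values).

## Numerical choices and degenerate inputs

* Ties in expression break by gene name; ties in AUC scores get 0.5 credit
  (Mann–Whitney), making the AUC equal to the trapezoidal integral of the
  stored ROC curve exactly.
* Quartile boundaries sit at empirical 25/50/75 percentiles with ties
  assigned to the lower quartile, so Q1-vs-Q4 contrasts are reproducible.
* Fisher's exact test uses probability ordering with a $1 + 10^{-7}$
  relative tolerance in the "at least as extreme" comparison (the standard
  guard against floating-point noise); zero-margin tables return $p = 1$;
  the odds ratio is the sample OR with Haldane correction only when a cell
  is zero.
* Parallel fitted lines ($|\Delta\text{slope}| < 10^{-12}$), constant score
  vectors, constant log-ratios, single-class label vectors and double log
  transforms are errors, not warnings.
* Every stochastic function takes an explicit integer seed and restores the
  caller's RNG state; identical configuration and seed give bit-identical
  output.

## Problem sizes used in the checks

The bundled tests and the acceptance script run on synthetic cohorts of 400
samples × 500 genes (20 seeds for threshold recovery and the piecewise-vs-raw
AUC comparison, 50 for null calibration) and single-cell bundles of 60–120
genes × 30–300 cells, sizes at which every property they assert is stable
from seed to seed while the whole suite stays fast.

## Known limitations

The package does not compute TIDE (an external comparator score can be
supplied as a column for side-by-side AUCs), does not perform clustering,
integration, annotation or differential testing of single cells beyond the
stated rules, and provides no uncertainty interval on the fitted threshold
(a bootstrap can be layered on `fit_evasion_model` by the user). The
published IMvigor210 threshold of 0.294 depends on that cohort and its exact
scoring conventions and is treated purely as an optional override input.
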