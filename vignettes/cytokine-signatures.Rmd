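---
title: "Cytokine signature discovery with PLS: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cytokine signature discovery with PLS: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytosig)
library(dplyr)
```

# The problem

Cytokine signaling in the brain is highly interdependent: dozens of secreted
messengers rise and fall together, and single-analyte statistics cannot
resolve which coordinated pattern tracks a phenotype such as advancing
amyloid pathology. `cytosig` implements the multivariate workflow used for
this class of problem: multiplex bead-immunoassay panels (e.g. a 32-plex
mouse cytokine/chemokine kit measured on hippocampal homogenates of 5xFAD
and wild-type mice at 30/60/120/180 days) are cleaned, modeled with partial
least squares (PLS), and condensed into a *signature* — the set of cytokines
with above-average contribution to the model, each with a direction. The
package also implements the downstream readouts used to validate what such a
signature does to neurons: nCounter-style gene-count normalization with
differential-expression filtering, Mito Stress Test oxygen-consumption-rate
(OCR) metrics, and interaction-network pruning.

Every stage can be exercised on synthetic data with planted ground truth, so
signature recovery, type-I error and metric extraction are testable without
any instrument export.

# Cleaning multiplex immunoassay data

Plate readings arrive as one interpolated concentration (pg/mL) per well
with a bead count. The pipeline applies, in fixed order:

1. **Detection-limit censoring** (default 3.2 pg/mL, strict `<`): readings
   below the limit are set to 0. Applied per reading, before triplicate
   resolution, matching instrument exports that are censored upstream.
2. **Bead-count filter** (default minimum 20, strict `<`): readings from too
   few beads are unreliable and removed.
3. **Triplicate resolution**: within each technical triplicate the closest
   pair (distance $d$) is found; the remaining replicate is removed iff its
   distance to *each* member of that pair strictly exceeds $2d$. Pairs and
   singletons are exempt; at most one replicate is ever removed.
4. **Averaging** of surviving replicates.
5. **Sparse-cytokine removal**: an analyte is dropped iff more than half its
   sample values are zero *and* the zeros do not partition between
   experimental groups. "Does not partition" is operationalized as a Fisher
   exact test of zero/nonzero x group at $\alpha = 0.05$ — exact at these
   sample sizes, where a chi-square approximation would not be.

Two properties of the triplicate rule are worth knowing. First, it is a
gap-ratio test: for three i.i.d. Gaussian-noise replicates the extreme gap
exceeds twice the pair gap about two-thirds of the time, so the rule
routinely trims ordinary triplicates down to their tightest pair — that is
its job, not a malfunction — and a planted, strongly displaced replicate is
removed essentially always. Second, the majority-zero rule is evaluated on
*averaged sample values*, not on raw replicate readings; the source
procedure does not pin this down and the averaged reading is the quantity
carried into modeling. Every removal (reading or analyte) is logged and the
counts reconcile exactly (`cleaning_log()`).

# The PLS model

Predictors are mean-centered and unit-variance scaled (SD with the $n-1$
denominator; constant columns are dropped with a warning). A numeric
response gives PLS regression (PLSR); a class response gives PLS-DA with one
scaled indicator column per class and argmax classification (ties break to
the first sorted label). Components are extracted by NIPALS with deflation
of X only — standard PLS2 behaviour, and for a two-class response the inner
loop has a closed-form fixed point because the scaled dummy matrix has rank
one. The first weight vector maximizes covariance between the predictor
projection and the response under a unit-norm constraint; scores are
mutually orthogonal; regression coefficients reproduce the score-space fit
exactly.

**Cross-validated LV selection.** Repeated random sub-sampling: test sets of
round(n/3) when $n > 30$, else round(n/5) (rounding half away from zero; the
unassigned $n = 30$ boundary goes to the conservative smaller test set),
re-drawn independently for each of 100 iterations, with models of 1-5 latent
variables fitted on each training set. The metric is RMSECV
$\sqrt{\sum_j (P_j - A_j)^2 / n}$ for PLSR and classification accuracy for
PLS-DA; the LV count with the best mean metric wins, ties to the smaller
count. Splits are not stratified beyond a class-presence guard (a split is
redrawn if a class would vanish from training — at most 100 attempts).

**Permutation significance.** Responses are shuffled among samples, the same
CV procedure is re-run at the fixed, previously chosen LV count, and the
real model's mean metric is compared with the null distribution's mean and
SD: $z = (\text{real} - \mu_0)/\sigma_0$ (sign flipped for RMSECV) and a
one-tailed upper normal tail gives $p$. This is the mean/SD convention, not
the empirical rank, so $p$ can be far below $1/B$; the number of
permutations (default 1000, configurable) controls only the precision of
$\mu_0, \sigma_0$. Calibration was checked by simulation: with no planted
effect the test rejects at close to the nominal 5%.

**Orthogonalization.** For interpretability, fitted models are rotated so
LV1 carries all of the response-predictive covariation (target-projection
style): in the orthonormalized score basis the fitted-response direction
becomes the first axis and the rest of the basis is completed by QR. The
testable contracts — and the ones asserted in the test suite — are that
predictions are unchanged to machine precision and that LV2+ scores are
exactly uncorrelated with the fitted response. Which named variant (target
projection vs an OPLS predictive component) one calls this differs only in
basis conventions.

**VIP and the signature.** Variable importance in projection,
$\mathrm{VIP}_j = \sqrt{p \sum_a SS_a w_{aj}^2 / \sum_a SS_a}$, is computed
from the *pre-rotation* components: VIP on a rotated predictive+orthogonal
decomposition is ambiguous in the literature, so the rotation-invariant
convention is used. $\sum_j \mathrm{VIP}_j^2 = p$ always; for a 1-LV model
only LV1 enters, and the second latent direction that the scores plot shows
for such models is computed for visualization only. The signature is the set
of variables with VIP strictly greater than 1, annotated with LV1 loading
and direction relative to the positive response pole (increasing response,
or the designated positive class — by default the first sorted label).

# Count normalization and differential expression

Counts below 20 are raised to 20 so fold changes share a baseline; each
sample is then scaled by the positive-control geometric-mean factor and the
housekeeping geometric-mean factor (reference: the mean of per-sample
geometric means, the nSolver-style convention — the procedure's source names
the software but not the arithmetic). Housekeeping genes are eligible only
if they have at least 100 counts in *every* sample (the stricter of the two
readings of "counts under 100") and a CV of at most 10%. Differential
expression per endogenous gene: log2 fold change of group means on the
normalized scale and a two-tailed Welch t-test on log2 counts (n = 3 per
group; whether the upstream software tested linear or log counts is not
stated, so the scale is a flag with log2 the default). Genes are kept at
p <= 0.05 — no multiple-testing correction, matching the procedure being
reproduced — and then dropped if both group means are below 30 (too close to
the background threshold). Normalization is performed separately per
cell-type batch, never pooled.

One consequence of the mean-of-geometric-means reference: rescaling a single
lane rescales the whole normalized plate by one common factor (the reference
moves), so per-lane equivariance holds for profile *shape*, fold changes and
p values — and that is what the tests assert.

# Mito Stress Test metrics

From each well's phase-labelled OCR trace (baseline, post-oligomycin,
post-FCCP, post-rotenone/antimycin A):

| metric | formula |
|---|---|
| non-mitochondrial | median OCR after rotenone/antimycin A |
| basal | median baseline OCR − non-mito |
| ATP production | basal − minimum OCR after oligomycin |
| maximal | maximum OCR after FCCP − non-mito |
| proton leak | minimum OCR after oligomycin − non-mito |

The ATP-production row mixes the background-subtracted basal with the *raw*
post-oligomycin minimum — one non-mito term away from the vendor convention.
It is implemented verbatim as the default, with
`atp_convention = "vendor"` available, because the text does not resolve
whether the mixing is intentional. Well QC excludes near-zero wells (default
threshold 5 pmol O2/min — the procedure gives no number, so this is the
package's choice, configurable) and wells whose post-FCCP maximum does not
exceed the post-oligomycin minimum. OCR is normalized to per-well protein
mass rescaled by the plate mean; biological replicates (independent assays
of 5-10 wells) are well-averages; final metrics are divided by the
replicate's non-mitochondrial respiration (the multiplicative reading of
"normalized to non-mitochondrial respiration", the only one that removes a
batch scale); treatments are compared with two-tailed pooled-variance
Student's t-tests at $\alpha = 0.05$ (Welch by flag).

# Interaction networks

Significantly differentially expressed genes become nodes (sized by log2
fold change, signed up/down); edges are gene pairs with interaction score at
least 0.4 — the common medium-confidence convention, since the source
procedure does not state its cutoff — and isolated sub-networks of 4 or
fewer genes are removed. Pruning is idempotent and is tested against a
brute-force union-find oracle. Querying any interaction database is out of
scope: edge tables are inputs.

# The synthetic-data generators

`simulate_cytokine_study()` draws log-normal concentrations with unit
marginal log-SD, composed of a per-cytokine baseline (median ~50 pg/mL), a
planted shift of `effect_size` log-SD units on the signature cytokines (by
genotype, or linear in standardized age when `age_trend = TRUE`), shared
latent noise factors carrying 40% of the log variance (inducing the
cytokine-cytokine correlation that motivates PLS), and idiosyncratic noise.
Each cell becomes three replicates with multiplicative noise of CV
`triplicate_cv`; planted outlier replicates are displaced 4-fold so the
triplicate rule fires unambiguously; low-bead events draw a bead count below
20. Defaults (20 samples/group, 32 cytokines, effect 2 SD, 3 up + 2 down
planted, CV 10%, outlier rate 2%, low-bead rate 1%) mirror the cohort scale
and panel of the motivating study design. The generator never censors —
zeroing sub-detection readings is the cleaner's job.

`simulate_ocr_trace()` draws piecewise-constant traces over the four
injection phases plus Gaussian noise, so every Mito Stress Test metric has a
closed-form expectation. `simulate_count_matrix()` draws negative-binomial
endogenous genes (default dispersion 0.1, baseline ~500 counts),
high-mean/low-CV housekeeping genes, a fixed positive-control ladder scaled
by per-sample library factors, and planted fold changes.

What the generators deliberately do *not* emulate: plate spatial effects,
standard-curve interpolation error, instrument drift, heavy-tailed or
zero-inflated count noise, and cytokine-specific detection limits. Passing
tests therefore demonstrate correctness of the algorithms under the stated
noise model, not robustness to every artefact of real instrument data.

Each generator takes its seed from its spec and restores the global RNG
state, so studies are reproducible and composable.

# Numerical choices and degenerate inputs

- Tolerances: score orthogonality is asserted at 1e-8 (relative), prediction
  invariance under rotation at 1e-10, equation identities at 1e-12.
- SDs use the $n-1$ denominator everywhere.
- Constant predictor columns: dropped with a warning by `pls_fit()`; inside
  CV folds they are neutralized (zero weight) silently, since a fold can
  make any column constant.
- Rank: `n_lv` may not exceed $\min(n-1, p)$; if a CV training fold has
  lower rank, the unreachable LV counts are skipped for that fold and the
  per-LV means use the folds that supported them.
- Zero-variance comparisons: a t-test between two constant equal groups
  reports p = 1; constant unequal groups are flagged rather than given a
  fabricated p.
- Permutation SD of zero raises an error (p undefined) rather than
  returning 0 or 1.
- Ties: CV metric ties choose the smaller LV count; classification ties
  choose the first sorted class; the triplicate rule's strict inequality
  keeps a replicate sitting exactly at twice the pair distance.

# Problem sizes used by the test and acceptance runs

Simulation-based checks use the study conditions above with these
Monte-Carlo sizes, chosen to give stable rates: signature recovery and
permutation power over 100 independent studies (CV with 25 iterations for
selection; permutation tests with 60 shuffles of 50-iteration CV); type-I
calibration of the permutation test over 200 null studies (60 shuffles of
15-iteration CV — calibration is invariant to the iteration count because
real and null metrics share it); DE null calibration on one 2000-gene panel;
OCR t-test calibration over 500 replicate experiments. The acceptance script
re-runs the full chains at the procedure's own settings (5 LV sweep, 100 CV
iterations, 200 permutations) on single studies plus a 20-study recovery
rate.

# Known limitations

- The permutation p uses a normal approximation to the null; with very few
  permutations or a strongly skewed null metric the tail probability is
  approximate (the empirical rank is deliberately not used, to match the
  procedure being reproduced).
- PLS-DA is implemented for the two-class case that the workflow needs;
  multi-class dummy coding works mechanically but has no dedicated tests.
- The sparse-cytokine Fisher test treats each analyte independently; no
  cross-analyte multiplicity control is applied (none is applied in the
  reproduced procedure either).
- Reproducing the published model metrics requires the original normalized
  cytokine table, which is distributed only as a supplementary PDF of the
  source publication and is not bundled here; the pipeline accepts such a
  table as a wide CSV once converted.

# A worked example

```{r example, eval = FALSE}
study <- simulate_cytokine_study(cytokine_sim_spec(seed = 7))
cleaned <- clean_cytokines(study)
analysis <- run_discrimination_model(cleaned, response = "genotype",
                                     n_permutations = 200, seed = 42)
print(analysis)
autoplot(analysis, data = cleaned, colour = "genotype", shape = "sex")
plot_loadings(analysis$model)
```
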