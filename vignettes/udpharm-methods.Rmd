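---
title: "Methods: uniform-design herb-formula effect and mediation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uniform-design herb-formula effect and mediation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(udpharm)
```

# The problem

Multi-herb formulations act through many ingredients at once, and animal
studies of such formulations face a combinatorial wall: varying six herb
doses over seven levels each would need $7^6$ groups in a full factorial.
Uniform experimental design compresses this to seven formulation runs spread
evenly over the dose space, and the analysis then has to extract
herb-by-herb structure from very few, highly structured observations. This
package implements that full analysis chain for a gastric-mucosal-injury
setting: a six-herb formulation (ZR, GCR, LAR, CR, FF, PR) administered to
rats in ten groups (healthy control, ethanol-injury model, the reference
formulation, and seven uniform-design variants; five animals per group),
with pharmacological endpoints, liver markers, gut-microbiota genus
abundances and serum HPLC peak areas measured per animal.

The chain has five statistical stages, each exposed as ordinary functions
and composed by `run_pipeline()`:

1. **Design** — good-lattice-point (GLP) construction of the $U_7(7^6)$
   table and linear mapping of levels onto per-herb dose ranges.
2. **Scoring** — macroscopic ulcer-index scoring and entropy-weight-method
   (EWM) composite efficacy indices.
3. **Dose-effect models (SPRA)** — LASSO screening plus bidirectional
   stepwise refinement over linear, quadratic and interaction dose terms.
4. **Mediator screening (PLSR/VIP)** — NIPALS partial least squares of the
   mediator blocks on the composite indices, keeping predictors with
   VIP > 1.
5. **Path analysis (pSEM)** — piecewise structural equation models per
   outcome, tested through the d-separation basis set and Fisher's C.

A synthetic-study generator (`simulate_study()`) reproduces this data
structure with known ground truth, so every stage has parameter-recovery
tests.

# Design construction

`glp_design(n, s)` uses the good-lattice-point rule
$\ell_{ij} = ((i\,g_j - 1) \bmod n) + 1$ with generators $g_j$ coprime with
$n$; every column is a permutation of $1..n$. When generators are not
supplied, the subset minimising the centered $L_2$ discrepancy (Hickernell's
closed form, `centered_l2_discrepancy()`) is chosen, with lexicographic
tie-breaking. For $n = 7$ and six factors all six candidate generators are
used, which is the canonical $U_7(7^6)$ table.

Dose ranges are not part of the published table; the defaults span the
reference formulation dose ±50% per herb (ZR 4 g, GCR 6 g, LAR 9 g, CR 6 g,
FF 4 g, PR 6 g), and level-to-dose mapping is linear and equally spaced —
both overridable. Interspecies scaling uses the body-surface-area rule
`bsa_convert(dose_g, mass_kg, factor)` with the standard rat factor 6.3
(35 g / 70 kg × 6.3 = 3.15 g/kg/day). The printed human dose per kilogram
in the source material is internally inconsistent (0.664 × 6.3 ≠ 3.15); the
implementation follows the arithmetic that reproduces both printed
endpoints, 0.5 g/kg × 6.3.

# Scoring

`ulcer_index()` scores each hemorrhagic lesion 0–5 by length band
(punctate → 1, < 2 mm → 2, 2–3 mm → 3, 3–4 mm → 4, > 4 mm → 5), doubles the
score when erosion width exceeds 1 mm, and sums over lesions. Two published
ambiguities are resolved explicitly: band edges are closed on the left of
each stated range ([2, 3], (3, 4]), and "small, round" lesions are flagged
by a `punctate` indicator defaulting to length < 1 mm.

Composite indices follow the entropy weight method. Each component is
min–max normalized with an orientation: $(W - W_{\min})/(W_{\max} -
W_{\min})$ when higher values are favorable, and the reflected form
$(W_{\max} - W)/(W_{\max} - W_{\min})$ when lower values are favorable.
(The source prints the same expression for both cases — an evident
typesetting duplication; the reflection is the standard EWM convention
consistent with the stated meaning of negative indicators.) Weights are
Shannon-entropy weights over the normalized matrix,
$E_j = (1 - e_j)/\sum_k (1 - e_k)$ with
$e_j = -\tfrac{1}{\ln n}\sum_i p_{ij}\ln p_{ij}$, $0\ln 0 = 0$; a constant
column has entropy 1 and weight 0. The six published composites (MRS, RF,
GIC, SIC, LF, HIC) ship as fixtures in `published_composites()` with their
printed weights; whether weights are recomputed per analysis or taken from
the spec is the caller's choice (`composite_spec(weights = ...)`). The
min–max envelope is taken over all scored samples, and EWM weights are
computed on per-animal values — both defaults the data source leaves
unstated.

# Dose-effect models (SPRA)

For each response (typically a composite index), the modelled observation
is the mean over the animals of each design run. The 27 candidate terms for
six herbs are the linear, quadratic and pairwise-interaction terms; doses
are Z-scored before expansion and term columns Z-scored after, so reported
coefficients are standardized and invariant to dose units. LASSO
(`glmnet`) with leave-one-out cross-validation over the seven run means
screens candidates at the penalty minimising CV error; bidirectional
stepwise search then minimises AIC, evaluating every single-term addition
(restricted to the screen's survivors) and deletion per iteration, with
ties preferring deletion and then lexicographic order. Selected-term counts
are capped at $n - 2$ so reported models keep residual degrees of freedom.

**A limitation stated plainly:** with seven runs, the 27 polynomial terms
are heavily aliased (absolute correlations up to 0.96 between interaction
terms). The package's recovery experiment (`spra_recovery()`, also run by
`scripts/acceptance.R`) measures how often the exact causal term set is
re-identified under known sparse truth; exact identification is unreliable
in this regime for any screening-plus-stepwise selector, and the fitted
models should be read the way the radar displays are meant: as standardized
effect summaries of a well-fitting predictive model, not as certificates of
the unique causal term set. Sign recovery, conditional on the support being
found, is essentially perfect in the same experiment.

# PLSR and VIP screening

`nipals_plsr()` implements NIPALS with X-deflation on autoscaled blocks:
weights $w_a$ unit-norm, scores mutually orthogonal, per-component
explained Y-variance measured as the reduction in deflated-Y sum of
squares. Convergence requires a relative score change below $10^{-10}$
(up to 2000 iterations per component; close eigenvalue pairs in
noise-dominated components converge slowly, which is why the cap is
generous). The component count follows the cumulative-explained-variance
rule: the smallest $A$ with cumulative explained Y-variance above 0.80,
fitted incrementally so no deeper components are extracted than the rule
needs; in the orchestrated pipeline $A$ is additionally capped at 5.
VIP scores use the standard weighted-share form
$\mathrm{VIP}_j = \sqrt{p \sum_a SS_a w_{ja}^2 / \sum_a SS_a}$, whose mean
square is exactly 1; predictors with VIP strictly greater than 1 are
screened in. Genus abundances enter as relative abundances after
autoscaling (no CLR or log transform, matching the source's stated
processing), and columns with missing values are rejected rather than
imputed.

# Piecewise SEM

The initial DAG per outcome wires every selected dose term to the outcome
and to every VIP-screened mediator, and every mediator to the outcome. One
Gaussian OLS is fitted per non-exogenous node on its parents. Global
adequacy uses Shipley's d-separation basis set: one independence claim per
non-adjacent pair, the topologically later variable regressed on the other
plus the union of both nodes' parents, and the claim p-value taken from the
two-sided t-test on that coefficient. Claims between two parentless
(exogenous) nodes are excluded — the design's polynomial terms are
correlated by construction, and their covariance is free, not a model
claim; this matches standard piecewise-SEM practice and is the only
convention under which the published models' small degrees of freedom are
attainable. Fisher's $C = -2\sum \ln p_i$ is referred to $\chi^2_{2k}$;
a saturated model scores $(C, df, p) = (0, 0, 1)$, and claim p-values of
exactly zero are clamped at $10^{-300}$. Model parsimony is reported as
$AIC = C + 2K$ with $K$ counting slopes, intercepts and residual variances
across component models. Pruning removes the single worst path with
$p \ge \alpha$ (default 0.05), refits, and repeats — one at a time to avoid
order artifacts.

The pipeline fits one path model per outcome rather than one merged DAG:
the union of selected terms across outcomes generally exceeds the rank the
seven design runs can support, and the per-outcome structure is also how
the path diagrams are presented.

# The synthetic-study generator

`study_config()` fixes the study conditions: 10 groups × 5 animals, the
$U_7(7^6)$ design with the default dose ranges, sparse true effect models
on the standardized term scale, and three known mediation paths (a liver
marker, one genus among ten, one peak among eighteen). Endpoint noise is
independent Gaussian with SD 0.25 on the standardized effect scale —
matching the linear-model assumptions of every downstream stage. Control
and model groups are generated from healthy/injured baselines rather than
the dose model. Mediator latents are built to approximately unit variance
(path contribution plus complementary noise), so declared path coefficients
read as standardized strengths; genus latents pass through a per-row
softmax (rows sum to 1) and peak latents are exponentiated (positive
areas).

What the generator does **not** emulate: compositional count noise and
sequencing depth in real microbiome data, heavy-tailed or heteroscedastic
assay noise, inter-animal correlation within cages, and any pharmacokinetic
nonlinearity beyond the declared polynomial terms. Passing recovery tests
therefore demonstrate that the machinery is correct under its own model
assumptions, not that real studies of this size identify term sets
reliably — the aliasing limitation above applies to the real design too.

Effect sizes (standardized magnitudes near 1, noise SD 0.25) were chosen
once as a regime a well-powered formulation screen should resolve, and the
Monte-Carlo experiment sizes (100 seeds for recovery, 500 replicates for
claim calibration, n = 200 per pSEM replicate) keep the full validation
suite within a few minutes on one core.

# Numerical conventions

* Z-scoring uses the sample standard deviation; degenerate (constant)
  columns raise errors rather than silently producing NaN.
* Stepwise ties: deletion preferred, then lexicographic term order; the
  search is capped at 50 accepted moves.
* Rank-deficient starting sets (aliased terms) are trimmed by dropping the
  weakest term (smallest |correlation| with the response) until the OLS fit
  is full-rank.
* Spearman p-values use the t approximation on $n - 2$ df with average
  ranks for ties; constant variables yield missing cells, not errors;
  Benjamini–Hochberg adjustment is computed but applied only on request,
  matching the unadjusted presentation of the source heatmaps.
* All randomness flows from explicit seeds; re-running any stage with the
  same configuration reproduces byte-identical CSV output.
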