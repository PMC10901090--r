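---
title: "Methods: compartmental kinetics of 13C-SCFA incorporation into glucose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartmental kinetics of 13C-SCFA incorporation into glucose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutflux)
```

This vignette is the package's own account of its methods: the model and its
assumptions, the numerical choices, what the synthetic-data generator does
and does not emulate, and the design decisions that were genuinely open.

## The measurement problem

Short-chain fatty acids (SCFA) — acetate, propionate, butyrate — are the
main products of gut-microbial fermentation. When a known bolus of
position-labelled ¹³C-SCFA is delivered into the intestinal lumen, the label
re-appears in plasma glucose; the shape of the three enrichment curves (one
per source SCFA, distinguishable by their isotopologue patterns) carries the
kinetics of uptake, conversion and loss. Two quantitative questions are
addressed:

1. *Attribution*: which SCFA produced the observed glucose and citrate
   labelling, and how efficiently per delivered mmol?
2. *Kinetics*: what are the apparent rate constants, and what fraction of
   each delivered tracer is incorporated into glucose?

## Stage 1 — natural-abundance correction

GC-MS reports the raw fractional abundances m0..m+n of a fragment. About
1.07% of all carbon is ¹³C, so even unlabelled molecules populate m+1, m+2,
…. With tracer-labelled carbons fixed, the remaining carbons are
independently ¹³C with probability `p13C`; the observed distribution is the
true excess distribution convolved with a binomial kernel, `m = C x`, where
column j of `C` is the binomial pmf over the n−j non-tracer carbons shifted
by j. `correct_natural_abundance()` inverts this by least squares.

Numerical choices:

* **Carbon-only matrix.** Derivatisation heteroatoms (Si, O of TBDMS/acetate
  derivatives) also have isotopes; whether to include them depends on the
  fragment. The matrix builder takes a pluggable abundance model
  (`natural_abundance_model()`), and the carbon-only default is the minimal
  assumption. Correction with heteroatom terms can be added without touching
  the inversion.
* **Sign constraints.** Measurement noise can push an unconstrained solution
  to negative labelled fractions, which are unphysical. The solver (an
  active-set non-negative least squares on M⁺¹..M⁺ⁿ after projecting out the
  M⁰ column) leaves M⁰ unconstrained — the excess M⁰ legitimately drops when
  labelled species displace the monoisotopic peak — and renormalises the
  result to sum to 1.
* Luminal SCFA spectra are typically *not* corrected (quantitative label
  patterns are hard to evaluate there); the pipeline corrects only MID
  groups flagged as raw, so luminal tables can simply be stored as-is.

The round trip convolve→correct recovers any non-negative excess MID to
1e-8, and `p13C = 0` gives the identity — both are tested.

## Stage 2 — source attribution

Each SCFA produces a characteristic glucose isotopologue pattern through
gluconeogenesis, fixed by stoichiometry and by carbon scrambling at the
symmetric fumarate intermediate:

| source | glucose pattern | stoichiometry |
|---|---|---|
| [1-¹³C₁]-acetate | ½ M⁰ + ½ M⁺¹ | 1 |
| [1,2,3-¹³C₃]-propionate | ½ M⁺² + ½ M⁺³ | 1 |
| [1,2,3,4-¹³C₄]-butyrate | ½ M⁺¹ + ½ M⁺² | 2 (two acetyl-CoA) |

For citrate: acetate → M⁺¹, butyrate → 2 × M⁺²; no propionate route is
modelled, so the citrate design has two columns by construction.

`attribute_sources()` regresses the excess MID on these columns over
M⁺¹..M⁺ⁿ only. Excluding the M⁰ row was an open choice: excess M⁰ is the
complement of the labelled fractions, so including it would double-count
every observation; dropping it while keeping the acetate column's M⁺¹ weight
at ½ keeps coefficients on the per-molecule scale. Coefficients are
constrained non-negative by default (physical amounts; `nonneg = FALSE`
gives the unconstrained solution). The glucose design's restricted columns
overlap (butyrate shares M⁺¹ with acetate and M⁺² with propionate), so the
solver reports the design condition number alongside the unique
least-squares solution.

Dose normalisation — `coefficient / (stoichiometry × delivered mmol)`,
rescaled by the delivered acetate amount — is implemented on a per-mmol
basis, the natural reading when doses are known in mmol.

Metabolite classes with no modelled route (amino acids, fatty acids,
acyl-carnitines) get a threshold screen (`screen_enrichment()`, default
excess 0.005) rather than a design matrix; propionyl-carnitine M⁺³ is the
canonical positive hit.

## Stage 3 — the compartment model

The ODE system (see `?scfa_ode`) is linear with a block-triangular
structure: each SCFA branch is an absorption–elimination chain, with one
extra liver compartment for acetate only (its appearance in glucose is too
slow for a single lumped step). Assumptions worth stating:

* first-order kinetics throughout (tracer doses are small perturbations);
* constant plasma volume `V = 0.15 L/kg` × body weight;
* a single glucose clearance `k2` regardless of label source;
* no SCFA interconversion (none is observed in luminal label patterns);
* pools are *labelled-glucose equivalents*: the equations are agnostic to
  whether `G` counts molecules or labelled-carbon equivalents, and curves
  are documented as mM labelled-glucose equivalents per source.

Integration uses `deSolve::lsoda` (stiff-capable; the constants span two
orders of magnitude) with rtol 1e-8 / atol 1e-12. Against the closed-form
two-exponential (Bateman) solution for the propionate branch and a
matrix-exponential oracle for the full system, the integrator agrees to
1e-7, and label is conserved on every branch to 1e-6 relative — both are
tested, as is non-negativity of the curves for random non-negative
constants.

## Stage 4 — identifiability and estimation

**Sensitivities.** `sensitivity_matrix()` computes
S<sub>ij</sub> = (∂Ŷ<sub>i</sub>/∂θ<sub>j</sub>) · θ<sub>j</sub>/w<sub>i</sub>
by central differences (relative step 1e-6; a parameter at 0 yields a zero
column and is flagged structurally unidentifiable). The parameter scaling by
θ<sub>j</sub> gives relative sensitivities. For the observation scale
w<sub>i</sub> the package defaults to the curve-wise maximum — the variable
scaling of classical sensitivity/collinearity analysis. Weighting by the
across-subject sd instead (`weighting = "sd"`) is offered for consistency
with the fit objective, but it systematically inflates apparent
identifiability here: the across-subject sd grows roughly with the signal,
which flattens the scaled sensitivities and lowers every collinearity index.
Under the default scaling the reference regime identifies at most six of the
eight constants; that structure, not the sd-weighted one, is what the
estimation scheme is built around.

**Collinearity.** For a subset of columns normalised to unit length,
γ = 1/√λ<sub>min</sub>(ŜᵀŜ). γ = 1 means orthogonal effects; γ = ∞ exact
linear dependence; γ < 20 is the conventional identifiability cut-off
(configurable). `identifiable_subsets()` enumerates all 247 subsets of sizes
2–8 exhaustively — no heuristics are needed at this scale.

**Fixing the data-poor pair.** `kLa` is fixed first: the liver pool is never
observed, so the data cannot pin it. The companion is chosen by
`select_second_fixed()` as the parameter whose fixing minimises the
collinearity index of the remaining six — the strongest reading of "minimal
collinearity if fixed together with kLa" (an alternative, minimising over
all subsets, is weaker and was not adopted). Values for the fixed pair come
from `grid_fix()`: each grid pair is held fixed, the six free constants are
*refit*, and pairs are ranked by the unweighted residual objective. The
objective is exposed in two forms — the plain sum of squared residuals and
√(SSR/n) — which rank identically (monotone transform); the literal sum is
used for ranking. The default grid is 50 log-spaced points on [1e-4, 1] plus
0 (rate constants are scale parameters); note the full default grid means
2601 refits, a batch-scale computation — interactive use and the tests use
small focused grids. Ties are broken toward the smallest `kLa`, then `k0p`.

**Fitting.** The six free constants are estimated by bound-constrained
Levenberg–Marquardt (`minpack.lm::nls.lm`) on residuals weighted by the
per-point sd (across subjects for averaged fits; curves without sd fall
back to a single pooled scale per curve, its maximum). Defaults: bounds
[0, 1] min⁻¹, start 0.01 min⁻¹ — rate constants above 1/min are outside the
physiological range of this system, and 0.01 is mid-range on the log scale.
Standard errors come from the asymptotic covariance of the weighted
Jacobian; p-values are two-sided t-tests against zero. A free parameter
resting on a bound triggers a warning since its asymptotic inference is
invalid. Noiseless synthetic data are recovered to better than 0.1% relative
in all six constants from a 2× perturbed start (tested), and the fit is
invariant to curve row order.

## Stage 5 — fractional dose contribution

Two routes, verified equivalent:

* ratio of rate constants, f = k₁ₓ/(k₁ₓ+k₀ₓ);
* pharmacokinetic, f = AUC × CL / dose with CL = k₂V, provided the AUC
  covers the whole curve.

`model_auc()` carries the integral of each glucose pool as an extra ODE
state (accurate to solver tolerance, unlike a trapezoid on a sampled grid)
up to the time where every gut pool has decayed below 1e-6 of its dose, then
adds the exact analytic tail of the linear system: every remaining
gut/liver mmol destined for glucose, divided by V, washes out at k₂. The
two routes agree to ≤ 1e-6 for random non-degenerate constants (tested on
100 draws), and a truncated AUC underestimates — both directions of the
claim are tested. A plain `auc_trapezoid()` exists for raw-data diagnostics.

## The synthetic-data generator

No clinical tracer data are distributed, so `generator_config()` defines the
emulated study conditions once:

* dose 9.6 / 4 / 0.9 mmol, computed from the infusate composition
  (0.96 / 0.40 / 0.09 M in 10 mL) rather than the rounded nominal 10/4/1;
* 8 subjects, body weight 75 ± 10 kg truncated at 50 kg;
* sampling every 15 min from −15 to 210 min around delivery;
* truth constants `reference_rate_constants()`: kLa = 0.0071,
  k0p = 0.0109 min⁻¹, the remaining six chosen so the fractional
  incorporations are exactly 0.12 / 0.23 / 0.79 with k2 = 0.015 min⁻¹
  (fractional glucose turnover of ≈2 mg/kg/min at 5 mM and 0.15 L/kg),
  k0a = 0.04 (most acetate is lost to oxidation/exchange) and k0b = 0.002
  (butyrate loss smallest). With these, acetate-derived glucose peaks last
  (~120 min vs ~75/~90) and `k1b` is the largest incorporation constant —
  the qualitative regime the model was built for. These are generator
  conventions, not cohort estimates;
* inter-subject log-normal spread on all constants, CV 0.2 (median = truth);
* additive Gaussian noise, sd = 5% of each curve's maximum, clipped at 0 —
  a typical GC-MS enrichment precision;
* MIDs composed from plateau labelling coefficients (glucose
  0.004/0.010/0.012, chosen to give M⁺² > M⁺¹ > M⁺³ as observed in plasma
  glucose; citrate 0.008/0.015; propionyl-carnitine excess only at M⁺³),
  convolved with natural abundance, 1% multiplicative noise, renormalised.

All randomness flows from the single seed (R's default Mersenne-Twister),
so every dataset is reproducible bit-for-bit.

**What passing tests do and do not show.** The generator draws i.i.d.
Gaussian noise around the model's own trajectories; real data add
within-subject autocorrelation, glucose pool-size drift (the model assumes
steady state), analytical drift between batches, and model error (e.g. SCFA
interconversion below detection, first-pass effects). Recovery of the
generator truth therefore validates the *estimator* — its identifiability
logic, objectives and numerics — not the biological correctness of the
three-compartment topology for any particular cohort.

## Problem sizes and runtimes

The test-suite and acceptance computations use the study-scale sizes the
package targets: 16 × 3 observations per subject, 8-subject cohorts, 50-seed
Monte-Carlo recovery, 100-draw equivalence checks, 247-subset exhaustive
collinearity analyses, and small focused grids for `grid_fix()`. The whole
suite runs in well under a minute on one core.

## Known limitations

* The kinetic analysis is per-tracer and linear; it cannot describe
  saturable uptake or dose-dependent clearance.
* `kLa` and its companion are *fixed*, not estimated; their grid values
  inherit the flatness of the objective in those directions, and
  uncertainty in the fixed pair is not propagated into the reported
  standard errors.
* Fits to averaged curves estimate average-cohort kinetics; with log-normal
  inter-subject spread the averaged curve is not generated by any single
  parameter set, so averaged-fit constants are a well-defined summary, not
  a subject-level truth.
* The attribution designs encode complete fumarate scrambling and the
  stated stoichiometries; partial scrambling or alternative routes
  (e.g. propionate→citrate) would require new design columns.
* Breath ¹³CO₂, luminal SCFA kinetics and microbiota composition are out of
  scope.
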