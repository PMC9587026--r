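---
title: "Methods: a mechanistic feedback model of insulin-glucose homeostasis and its structure-parameter estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: insulin-glucose feedback model and SPINA estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinacarb)
```

## The model and its assumptions

`spinacarb` describes fasting insulin-glucose homeostasis as a closed
loop of two concentration states, glucose G and insulin I, each governed
by a first-order pharmacokinetic ("ASIA") element

$$\frac{dy}{dt} = \alpha\, x(t) - \beta\, y(t), \qquad \alpha = 1/V_D,$$

where x(t) is the rate feeding the compartment, $V_D$ the volume of
distribution and $\beta$ the elimination rate constant
($\beta = \ln 2 / t_{1/2}$). At steady state each element reduces to a
linear gain $G = \alpha/\beta$ in s/L; the glucose and insulin gains are
called $G_1$ and $G_3$.

The loop couples the two states through three structural motifs:

* **Secretion** (stimulating, saturable):
  $S = G_\beta G / (D_\beta + G)$. $G_\beta$ is the maximal secretory
  capacity of the beta cells, $D_\beta$ the glucose EC50.
* **Receptor/effector signalling** (stimulating, saturable): the
  proximal signal $M = G_R I/(D_R + I)$ and the dimensionless distal
  signal $N = G_E M$. $G_R$ is the receptor gain, $D_R$ the insulin
  EC50, $G_E$ a constant effector gain. The split into M and N keeps
  $G_E$ a pure gain with N dimensionless; only the product chain is
  identifiable from steady-state data, so this factorisation is a
  modelling convention, not an extra assumption.
* **Regulated production** (inhibiting, divisive):
  $Q = P/(1 + N)$, non-competitive inhibition of the constitutive
  hepatic production P. Glucose arrival is $R = W + Q$, with W the
  intestinal absorption rate (0 when fasting).

The dynamic system integrated by the simulator is therefore

$$\frac{dG}{dt} = \alpha_G\,(W(t) + Q(t)) - \beta_G G, \qquad
  \frac{dI}{dt} = \alpha_I\, S(t) - \beta_I I.$$

Assumptions worth keeping in mind: single well-mixed compartments per
analyte, time-invariant structure parameters, no incretin, glucagon,
somatostatin, cortisol, cytokine or autonomic inputs, and saturation
kinetics of the Michaelis-Menten/Langmuir form for both stimulating
paths.

## Reference parameters

The default parameter set describes a healthy reference subject:

| symbol | meaning | default | unit |
|---|---|---|---|
| $\alpha_G$ | glucose dilution factor ($1/V_D$) | 0.11 | 1/L |
| $\beta_G$ | glucose elimination rate constant | 7.1e-4 | 1/s |
| $G_\beta$ | beta-cell secretory capacity | 2.8 | pmol/s |
| $D_\beta$ | glucose EC50 at beta cells | 7 | mmol/L |
| $\alpha_I$ | insulin dilution factor | 0.2 | 1/L |
| $\beta_I$ | insulin elimination rate constant | 3.4e-3 | 1/s |
| $G_R$ | insulin receptor gain | 2.3 | mol/s |
| $D_R$ | insulin EC50 at its receptor | 1.6 | nmol/L |
| $G_E$ | effector gain | 50 | s/mol |
| $P$ | constitutive glucose production | 150 | µmol/s |
| $W$ | intestinal absorption (fasting) | 0 | µmol/s |

Internally everything is strict SI (mol/L, mol/s, s); the mixed pmol /
nmol / mmol scales above exist only at the I/O boundary
(`load_parameters()`, `compute_panel()`, printing). This prevents the
silent factor-of-10³ errors that mixed-unit formulas invite. Insulin
unit conversion defaults to 6.0 pmol/L per µU/mL and glucose to
18.018 mg/dL per mmol/L; both are configurable via `unit_convention()`
because laboratories differ (6.945 is also in use for insulin), and no
single convention can be inferred from fasting data itself.

## The equifinal steady state

With W = 0 the loop collapses to a scalar map for glucose,

$$G \mapsto \frac{G_1 P}{1 + K_1 G/(K_2 + G)}, \qquad
K_1 = \frac{G_E G_R G_3 G_\beta}{D_R + G_3 G_\beta},\quad
K_2 = \frac{D_R D_\beta}{D_R + G_3 G_\beta},$$

whose fixed point satisfies $(1+K_1)G^2 + (K_2 - G_1P)G - G_1K_2P = 0$.
Because the constant term is negative for every valid parameter set,
the two roots have opposite signs and the positive root is the unique
fasting glucose level; insulin follows from
$I = G_3 G_\beta G/(D_\beta + G)$. `equifinal_state()` evaluates this
closed form; `fixed_point_iteration()` iterates the map directly
(default tolerance 1e-12 mol/L, cap 10⁶ iterations) and serves as an
independent numerical oracle — the test suite checks their agreement to
1e-8 relative over 1000 random parameter sets spanning roughly half to
four times the reference gains. The map's time index is treated purely
as an iteration counter: the package never uses it as a time-domain
integrator, which is what the ODE simulator is for.

At the reference parameters the steady state is G ≈ 4.34 mmol/L and
I ≈ 63 pmol/L — values the test suite recomputes, not quotes.

## The SPINA estimators and their comparators

Solving the steady-state relations for the two gains gives the
structure-parameter (SPINA) estimators from a single fasting pair:

$$\hat G_\beta = \frac{I\,(D_\beta + G)}{G_3\, G}, \qquad
\hat G_R = \frac{G_1 P (D_R + I)}{G_E\, I\, G} - \frac{D_R}{G_E I}
  - \frac{1}{G_E}.$$

These are exact algebraic inversions: applied to the noiseless
equifinal (G, I) of any parameter set they return the generating
$G_\beta$ and $G_R$ to floating-point accuracy (the round-trip identity
the acceptance checks enforce at 1e-9 relative). The model constants
they need ($G_1, G_3, P, D_\beta, D_R, G_E$) always come from an
explicit `spina_parameters()` object, so the estimators are
recalibratable.

Comparators are implemented in their conventional units: HOMA-IR =
I·G/22.5 (µU/mL × mmol/L), HOMA-Beta = 20·I/(G − 3.5), QUICKI =
1/(log₁₀I + log₁₀G) (µU/mL, mg/dL). HOMA-Beta is undefined for glucose
≤ 3.5 mmol/L; `compute_panel()` flags such records as `blind_zone` and
never reports a negative value as valid, while the SPINA estimators
remain finite there. A SPINA-GR estimate can be negative when a sample
implies glucose above the open-loop value $G_1P$ — inconsistent with
the fasting model; it is returned unclipped with a `negative` flag so
no information is destroyed.

## The simulator

Integration uses the classical fixed-step 4th-order Runge-Kutta scheme
(via `deSolve`), default step 1 s. The system is a smooth two-state ODE
whose fastest time constant ($1/\beta_I \approx 294$ s) is orders of
magnitude above any permitted step (dt ≤ 60 s), so a fixed step keeps
runs cheap and bit-deterministic; the suite checks that halving dt moves
the terminal state by < 1e-4 relative. Protocols:

* *fasting*: W ≡ 0;
* *oGTT*: single-exponential absorption
  $W(t) = f D k_a e^{-k_a t}$, defaults 75 g dose, bioavailability
  f = 0.8, $k_a$ = 1/1800 s⁻¹ (absorption half-life ≈ 21 min). The true
  post-prandial absorption profile is more complex; this declared,
  configurable default trades realism for reproducibility and conserves
  the absorbed dose exactly ($\int W = fD$);
* *ivGTT*: an instantaneous bolus applied between steps as a
  concentration jump of dose × $\alpha_G$, which is exactly what
  $\alpha = 1/V_D$ dilution semantics dictate (default 0.3 g/kg ×
  70 kg).

Convergence tests start the fasting loop from a 4 × 3 grid of initial
conditions (glucose 0.1–20 mmol/L, insulin 0–1000 pmol/L) and require
the terminal state to match the quadratic root within 0.1% after
50 000 s (≈ 35 glucose elimination half-lives) at dt = 5 s — sizes
chosen so the whole grid integrates in seconds while leaving the
transient at least 10/min(β) of settling time.

## The statistics layer

The validation statistics mirror what a biomarker-validation analysis
needs: Kruskal-Wallis across diagnostic groups with post-hoc pairwise
Mann-Whitney tests and Benjamini-Hochberg correction (R's standard
implementations; `wilcox.test` uses its own exact-below-50/approximate
convention), Spearman correlation with midrank ties, Bland-Altman
agreement (bias, 1.96·SD limits, proportional-bias slope from OLS of
differences on pair means), and Zou's MOVER confidence interval for the
difference of two dependent overlapping correlations, implemented from
the published construction since no installed package provides it.
Tests are two-sided with α = 0.05 reporting.

Repeatability is summarised by the ergodicity statistic

$$e = \frac{\mathrm{Var}_{inter}}{\mathrm{Var}_{intra} +
  \mathrm{Var}_{inter}},$$

with unbiased (n−1) variances: $\mathrm{Var}_{inter}$ of the subject
means and $\mathrm{Var}_{intra}$ the unweighted mean of within-subject
variances. This is the standard repeatability decomposition; other
pooling conventions (weighting by repeat count) exist, and the choice
is documented here precisely so users can compare. Subjects with fewer
than two repeats are excluded with a warning. e is invariant under
shifting and rescaling the measurements, and e → 1 as within-subject
noise vanishes.

## The synthetic-cohort generator

`synthesize_cohort()` emulates the statistical structure of fasting
validation cohorts: each subject gets a $(G_R, G_\beta)$ pair,
the noiseless fasting (G, I) follows from the closed-form steady state,
and each visit adds independent multiplicative log-normal assay noise
with $\sigma = \sqrt{\log(1 + CV^2)}$, so the stated CV is matched
exactly. Defaults encode the study conditions the package tests under:
insulin assay CV 10.2% (a chemiluminescence immunoassay precision
figure), glucose CV 2% (typical of glucose-oxidase chemistry),
log-normal between-subject dispersion with geometric SD 1.5 for both
gains (no published population dispersion exists for these parameters;
1.5 gives the right order of spread for fasting insulin and was fixed
once, before any test was written). Strata are defined purely by
parameter shifts — `prediabetes` halves $G_R$, `diabetes` halves $G_R$
and scales $G_\beta$ by 0.6 — keeping ground truth unambiguous; no
glycaemic threshold labelling is attempted.

With `coupling = "hyperbolic"`, $G_\beta = \kappa/G_R$ times log-normal
scatter (geometric SD 1.2), $\kappa$ defaulting to the product of the
healthy medians (2.8 pmol/s × 2.3 mol/s) so the normal stratum stays
centred on the reference parameters. This reproduces, with one
interpretable constant, the compensatory geometry in which beta-cell
output rises as insulin sensitivity falls; in a 2000-subject coupled
cohort the recovered indices show a strong negative rank correlation
(the acceptance script recomputes it).

What the generator does **not** emulate: demographic structure (age,
sex, BMI), oGTT or HbA1c covariates, non-steady-state physiology,
assay-specific error shapes beyond a constant CV, or missingness.
Passing tests on these cohorts therefore demonstrate internal
consistency of the estimators and statistics under the model's own
assumptions — not clinical validity on real populations.

## Numerical and design choices, in one place

* Canonical SI units internally; conversions only at I/O boundaries.
* Quadratic solved with the explicit formula; the discriminant is
  provably positive for valid parameters and guarded by an internal
  assertion.
* Fixed-point oracle: plain iteration, tol 1e-12 mol/L default; the
  map is a contraction throughout the tested parameter ranges.
* RK4, fixed step, default 1 s; boluses as inter-step state jumps.
* HOMA-blind zone: flagged `NA` in vector/panel context, typed error
  (`spina_blind_zone_error`) for scalar calls.
* Negative SPINA-GR: flagged, never clipped.
* Scalar index calls fail loudly on domain violations; vectorised calls
  degrade to `NA` so cohort pipelines keep running.
* All generator randomness flows from one seed recorded in the output;
  the caller's RNG state is restored afterwards.
* Problem sizes in the checks: 1000 random parameter sets for the
  inversion and oracle identities, 12 initial conditions × 10⁴ RK4
  steps for equifinality, 1000 subjects for noise recovery, 2000 for
  the coupling geometry — large enough for stable medians, small enough
  to run in well under a minute.

## Known limitations

The model omits incretins, glucagon, somatostatin, glucocorticoids,
thyroid hormones, cytokines, adipokines, the gut microbiome and
autonomic control; it cannot attribute an individual's parameters to
any of these modifiers. The estimators assume steady-state fasting
samples — values computed from non-fasting or dynamically perturbed
samples inherit no guarantee. The oGTT absorption profile is a
declared stylisation, adequate for qualitative tolerance-test
behaviour, not for fitting real oGTT curves. And the synthetic cohorts
are model-consistent by construction, so recovery results bound assay
noise propagation only, not structural misspecification.
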