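# spinacarb

Mechanistic modelling and structure-parameter inference for
insulin–glucose homeostasis.

## The problem

Fasting glucose and insulin are held in a tight band by a nonlinear
feedback loop: glucose stimulates pancreatic beta cells to secrete
insulin, and insulin suppresses hepatic glucose production through its
receptor. Clinicians routinely summarise this loop with fasting indices
(HOMA-Beta, HOMA-IR, QUICKI), but those are empirical ratios with known
failure modes — most notably the "HOMA-blind zone", where HOMA-Beta is
undefined or negative for fasting glucose ≤ 3.5 mmol/L even though
beta-cell activity may be high.

`spinacarb` implements a compact mechanistic alternative and the
estimators it induces. It is aimed at metabolic researchers who want
model-based biomarkers of beta-cell function and insulin sensitivity
from single fasting samples, plus the simulation and statistical
machinery to validate them.

## The model

Concentrations arise from rates through first-order pharmacokinetic
("ASIA") elements, dy/dt = α·x(t) − β·y(t) with α = 1/V_D, which at
steady state act as linear gains G₁ = α_G/β_G (glucose) and
G₃ = α_I/β_I (insulin). The loop couples them through two saturable
motifs and one divisive inhibition:

- secretion: S = G_β·G/(D_β + G) (Michaelis–Menten)
- receptor/effector: N = G_E·G_R·I/(D_R + I)
- regulated production: Q = P/(1 + N) (non-competitive inhibition)
- glucose arrival: R = W + Q

At the fasting steady state (W = 0) glucose solves the quadratic
(1 + K₁)G² + (K₂ − G₁P)G − G₁K₂P = 0 with
K₁ = G_E·G_R·G₃·G_β/(D_R + G₃·G_β) and K₂ = D_R·D_β/(D_R + G₃·G_β);
the positive root is the unique *equifinal* glucose level reached from
any initial condition. Inverting the loop at that steady state yields
the structure-parameter (SPINA) estimators from one fasting pair (G, I):

- **SPINA-GBeta** (secretory capacity, pmol/s):
  Ĝ_β = I·(D_β + G)/(G₃·G)
- **SPINA-GR** (insulin receptor gain / sensitivity, mol/s):
  Ĝ_R = G₁P·(D_R + I)/(G_E·I·G) − D_R/(G_E·I) − 1/G_E

Both are defined on the whole positive (G, I) plane — including the
HOMA-blind zone.

## Worked example

```r
library(spinacarb)

p <- spina_parameters()        # healthy reference parameters
print(equifinal_state(p))
#> Equifinal fasting steady state
#>   K1 = 10.7333, K2 = 6.3467 mmol/L
#>   G(inf) = 4.3377 mmol/L
#>   I(inf) = 63.01 pmol/L

# a synthetic cohort: 500 subjects, 2 visits, 10% with reduced gains
coh <- synthesize_cohort(cohort_spec(500, n_repeats = 2, seed = 42,
         group_mix = c(normal = 0.9, prediabetes = 0.05, diabetes = 0.05)))
panel <- compute_panel(coh)
head(panel[, 1:9], 3)
#>   subject_id visit glucose_mmol_L insulin_pmol_L spina_gbeta_pmol_s
#> 1      S0001     1          2.687         68.761              4.215
#> 2      S0001     2          2.592         65.162              4.100
#> 3      S0002     1          4.128         73.380              3.363
#>   spina_gr_mol_s homa_beta homa_ir quicki
#> 1          3.713        NA   1.368  0.364
#> 2          4.072        NA   1.251  0.370
#> 3          2.112   389.605   2.244  0.338
```

Subject S0001 sits in the HOMA-blind zone (glucose 2.7 mmol/L):
HOMA-Beta is `NA` (flagged `blind_zone` in the panel) while SPINA-GBeta
is still defined. The validation-statistics layer then quantifies group
separation and repeatability:

```r
gc <- group_comparison(panel$spina_gr_mol_s, coh$group)
#> Kruskal-Wallis H = 165.98, p = 9.1e-37
ergodicity(panel$spina_gr_mol_s, panel$subject_id)
#> Ergodicity e = 0.9350 (var_inter 1.082, var_intra 0.07526, 500 subjects)
parameter_recovery_report(coh)
#> median |rel err|: GBeta 0.067, GR 0.069
```

SPINA-GR is sharply reduced in the reduced-gain strata; the high
repeatability e means between-subject variance dominates assay noise
(individual metabolic "set points"); and under the stated assay CVs
(insulin 10.2%, glucose 2%) the estimators recover the generating gains
with a median error of about 7%.

A time-domain simulation of an oral glucose tolerance test:

```r
traj <- simulate_homeostasis(p, make_protocol("ogtt", dose = 75),
                             t_end = 10800, dt = 10)
summarize_trajectory(traj)
```

There is also a small command-line interface (`exec/spinacarb`) with
subcommands `steady-state`, `simulate`, `indices`, `synth` and `stats`.

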