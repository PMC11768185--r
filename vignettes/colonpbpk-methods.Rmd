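---
title: "Methods: whole-body PBPK modelling of colorectal-cancer drugs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-body PBPK modelling of colorectal-cancer drugs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonpbpk)
```

## Scope and scientific problem

First-line chemotherapy for metastatic colorectal cancer combines
intravenous 5-fluorouracil (5-FU) and leucovorin with either oxaliplatin
(FOLFOX) or irinotecan (FOLFIRI). Plasma pharmacokinetics of these drugs
are well documented, but exposure at the site of action — the wall of the
colon — cannot be sampled ethically and must be predicted mechanistically.
`colonpbpk` implements a whole-body physiologically-based pharmacokinetic
(PBPK) platform for the four drugs and their tracked active metabolites
(SN-38 from irinotecan via carboxylesterase, dihydrofluorouracil (FUH2)
from 5-FU via dihydropyrimidine dehydrogenase, folitixorin from leucovorin
via methylenetetrahydrofolate reductase; oxaliplatin forms its active
species non-enzymatically and is not expanded).

## Body structure

Each solid organ is divided into four sub-compartments: blood cells,
plasma, interstitial space and cellular space. The blood-cell and plasma
spaces flow; plasma exchanges with the interstitial space across the
endothelium at a permeability–surface-area product `PS_endo` acting on
unbound concentrations (the interstitial space holds the same binding
proteins as plasma at a ratio of 0.37, hence a higher unbound fraction);
the interstitial space exchanges with the cellular space at `PS_cell`
against the intracellular partition coefficient Kp. Amounts are carried in
µmol, concentrations in µmol/L, time in minutes.

The organ set comprises lung, brain, heart, kidney, stomach, small
intestine, the four colon segments (ascending, transverse, descending,
sigmoid), liver, spleen, pancreas, muscle, skin, bone and fat, plus venous
and arterial blood pools. The splanchnic organs (stomach, small intestine,
colon segments, spleen, pancreas) drain into the liver through the portal
vein; all other organs drain into the venous pool, which passes through
the lung into the arterial pool. The loop flow equals the sum of the
systemic organ flows, which makes the flow field exactly conservative;
cardiac output is retained only as a capacity bound in validation.

The reference tables (73-kg male; 60-kg female as the male table scaled by
60/73 for volumes and (60/73)^0.75 for flows) are shipped as CSV and are
deliberately explicit rather than tied to any proprietary physiology
database: every number the model uses can be inspected and tested. The
total large intestine is split equally across the four colon segments;
because the segments are parameterised identically their exposures agree
by construction, which matches the physiological observation that flow and
volume per unit tissue are similar along the colon. Colon sub-compartment
volume fractions are 0.13 vascular, 0.73 interstitial and 0.14
intracellular. Age is carried as a covariate but does not alter organ
parameters beyond the weight and sex scaling: no age–physiology mapping is
asserted.

## Tissue partitioning

Partition coefficients are computed from tissue composition and compound
physicochemistry with a Rodgers–Rowland-type treatment, written out in
full here because it is the package's own realisation (tissue-composition
methods differ in detail between implementations and no claim of parity
with any particular software product is made).

Only the neutral unbound species crosses membranes, so at equilibrium its
aqueous concentration is common to all phases. Per unit neutral aqueous
concentration, a phase with composition fractions f (water, neutral lipid,
phospholipid, binding protein) at pH holds

```
T(comp, pH) = f_water (1 + I(pH))
            + P f_nl
            + (0.3 P + 0.7) f_pl
            + K_prot f_prot
            + [ionised bases] KA_ap f_pl I(pH)
```

with `P = 10^logP` and `I(pH)` the ionised:neutral ratio from the
Henderson–Hasselbalch relation (`10^(pKa-pH)` for bases, `10^(pH-pKa)` for
acids). The last term is the electrostatic association of ionised base
with acidic membrane phospholipids; its affinity constant `KA_ap`
(default 500) is the one deliberately phenomenological constant in the
scheme, chosen once so that a logP 3.2 weak base shows Kp > 1 in every
solid organ including bone, as lipophilic weak bases do. The protein
affinity `K_prot` is not a free parameter: it is solved from the plasma
composition row so that the measured plasma unbound fraction fu is
reproduced exactly, `fu = (1 + I_plasma)/T(plasma, pH 7.4)`. The
intracellular-to-plasma coefficient is then

```
Kp = fu * T(tissue, pH_ic) / (1 + I_plasma)
```

with intracellular pH 7.0, plasma pH 7.4 and red-cell pH 7.2 (standard
values; configurable). `f_protein` in the shipped composition table means
albumin-equivalent *binding* protein, which is small inside cells — the
plasma binding proteins are extracellular — and this is what keeps
strongly bound hydrophilic compounds (oxaliplatin, fu = 0.1) below Kp = 1
in tissue while leaving the construction exact in the limits the tests
pin down: Kp = 1 for a neutral unbound compound in plasma-like tissue, and
Kp equal to the water fraction in lipid- and protein-free tissue. Kp is
monotone non-decreasing in logP at fixed composition. The blood-cell:
plasma ratio uses the same machinery on the red-cell composition row and
is independent of hematocrit, which only enters blood-level aggregation.

With the built-in registry this yields the qualitative pattern expected
from lipophilicity: the weak base irinotecan (logP 3.2) partitions above
unity in all solid organs, while 5-FU, oxaliplatin and leucovorin
(logP −0.89, −0.47, −3.2) stay below unity everywhere. Oxaliplatin carries
no pKa entry and is treated as neutral.

## Permeability

Organ-level PS base values (2 L/min per L tissue endothelial, 1 L/min per
L cellular) are scaled by a two-coefficient compound factor
`10^(0.2 logP) (400/MW)^0.5`. These defaults are intentionally large
(near flow-limited): printed whole-body data do not identify organ
permeabilities, and for non-eliminating organs the infinite-time exposure
ratios between sub-compartments are exactly PS-independent (each
sub-compartment's net exchange integrates to zero), so the reported AUC
aggregations do not hinge on this correlation. Both coefficients and the
base values are configuration.

## Elimination and metabolism

Clearance entries keep their printed units and are converted at assembly:
per-kg entries (mL/min/kg, L/h/kg) scale with body weight, absolute
entries (mL/min, L/h) do not. Renal clearance acts on the *unbound* kidney
plasma concentration (glomerular filtration and most secretion act on
unbound drug; a total-concentration option is available). Biliary,
enzymatic and metabolite total clearances are sited in the liver
intracellular space and act on the unbound aqueous-equivalent
concentration `fu C_cell / Kp`, the same driver as the saturable term.
Oxaliplatin's total clearance (2.5 L/h) is assigned to the renal route, as
its elimination is exclusively renal; SN-38 and FUH2 total clearances are
hepatic.

5-FU catabolism by DPD is Michaelis–Menten: the printed Vmax
(22.5 mL/min/g tissue) is read as intrinsic clearance at saturation per
gram of liver, so `Vmax [µmol/min] = vmax × liver mass [g] × Km [µmol/L]
/ 1000` with Km = 3.17 µmol/L (nmol/mL and µmol/L coincide numerically).
The alternative reading (µmol/min/g) is switchable in configuration; the
interpretation is isolated in one place. 90% of the DPD flux appears as
FUH2, the remainder is counted as untracked catabolites. Irinotecan's CES
flux forms SN-38 mole-for-mole (the CYP3A4 route to inactive metabolites
is not tracked as an entity; its loss is absorbed in the configurable
conversion fraction). Formed metabolite appears in the liver intracellular
space.

The registry carries the printed parameter table verbatim, including
entries the validator flags loudly but does not alter: the malformed
metabolite lipophilicity "3.1.4" (used as 3.1), irinotecan per-kg
clearances far too large to be plasma clearances, and solubilities printed
in mg/L where other rows use mg/mL. These flags are warnings by design —
the registry's job is fidelity to the printed table, the validator's job
is honesty about its oddities.

## Dosing and integration

Dosing is intravenous only: boluses are state jumps on venous plasma,
infusions are constant-rate forcing terms. The integrator (lsoda, relative
tolerance 1e-8, absolute 1e-10 µmol) is restarted at every dose start and
stop so discontinuities are honoured exactly. The default reporting grid
is geometric (`sim_time_grid()`): a bolus mixes out of the venous pool on
a sub-minute time scale and a uniform grid visibly inflates
trapezoid-based AUCs of the venous spike. Mass balance — body burden plus
cumulative eliminations against administered dose, with conversion tracked
mole-for-mole — closes to better than 1e-6 (typically 1e-12) and is
asserted across compounds and regimens.

Red-cell partitioning is kinetic: the blood-cell space relaxes towards
`k_rbc ×` plasma at a first-order rate (default 5/min), so blood-cell
exposure is a genuine model output rather than an algebraic scaling.

## Virtual population

Populations draw sex by deterministic quota, age and weight uniformly over
the specified ranges (defaults n = 1000, 50% female, ages 25–80, weights
37.5–130 kg). Uniform sampling is the least-informative choice consistent
with stated ranges. Organ volumes scale linearly with weight, flows with
weight^0.75. Elimination variability is lognormal with mean 1 and a 50%
coefficient of variation by default (`sdlog = sqrt(log(1+cv^2))`,
`meanlog = -sdlog^2/2`), drawn per route; lognormality guarantees
positivity where a normal law would not. Generation is bit-reproducible
given a seed.

## Exposure metrics and aggregation

AUC uses the linear-up/log-down trapezoid; extrapolation to infinity adds
`C_last/λz` with λz from an unweighted log-linear regression over the
terminal tail, the tail chosen to maximise adjusted R² among candidates of
at least three points after the peak. Ties for tmax break to the earliest
time. Vascular exposure is the hematocrit-weighted mean of blood-cell and
plasma AUCs (hematocrit 0.47); total-organ exposure weights the vascular,
interstitial and intracellular AUCs by the volume fractions
(0.13/0.73/0.14 for colon). The colon report assembles these per segment
together with the colon/plasma exposure ratio against venous plasma.

## Model qualification

Fold error is predicted/observed; AFE is its geometric mean,
`10^mean(log10 FE)`; AAFE is `10^mean(|log10 FE|)` (base-10 logarithms
throughout, fixed by the `10^` prefactor of the definitions). AFE is
satisfactory in [0.8, 1.25], acceptable in [0.5, 0.8) or (1.25, 2], poor
outside; AAFE is satisfactory up to 1.25, acceptable up to 2, poor above.
Observed zeros are excluded with a recorded count — the log-domain
statistics are undefined at zero and no offset convention is imposed.
Predictions are matched to observation times by linear interpolation.
Visual predictive checks take pointwise percentiles (default 5/50/95) of a
simulated ensemble on a common grid; an observation is an outlier when
strictly outside the interpolated band. The inner "fold-error" line of the
goodness-of-fit plot defaults to 1.5; it is a diagnostic guide distinct
from the 2-fold qualification bound, whose value is not standardised.

## Synthetic data: what it does and does not show

The generator emulates the statistical structure of literature-compiled
PK datasets: multiple studies with heterogeneous dose levels, mixed bolus
and infusion regimens, jittered sampling schedules, profile-kind labels
(individual/mean/pooled) and multiplicative lognormal residual noise —
concentrations are strictly positive and fold-error metrics live in log
space, so a log-normal residual is the natural choice. A manifest records
the generating seed and true clearances for recovery tests.

What passing these tests shows: the simulate → corrupt → evaluate loop is
self-consistent (AFE ≈ 1; AAFE ≈ `10^(0.798 sd_log)` by the half-normal
mean identity), VPC coverage behaves as constructed, and a single
clearance multiplier is recoverable from 200 noisy observations at
sd_log = 0.1 within 5% when sampling spans the elimination phase. What it
does not show: agreement with real clinical data — real datasets carry
unit heterogeneity, assay limits, digitisation error, inter-study
population differences and model misspecification that the generator
deliberately does not emulate. Study-level qualification tables against
digitised clinical observations are therefore out of scope here.

## Problem sizes and numerical choices in the shipped tests

The test suite and the results script use a reference-male 1 mg bolus on a
400-point geometric grid to 3000 min for the per-drug exploration;
population checks use n = 1000 for bounds and coefficient-of-variation
recovery, a 120-individual ensemble (three residual replicates) against 80
simulated observation individuals for VPC coverage, and 204 observations
for clearance recovery. These sizes were chosen as the smallest at which
the Monte-Carlo error of each check is comfortably below its assertion
band.

## Known limitations

* No oral absorption, lymph flow, transporter kinetics or binding
  kinetics; no tumour compartment (healthy colon wall only).
* CYP/enzyme activity is localised entirely to liver; organ-level enzyme
  expression profiles are not modelled.
* The partitioning scheme is a composition-based approximation; its
  absolute Kp values should be read as order-of-magnitude predictions,
  with the cross-compound ordering being the robust output.
* Printed per-kg clearances for irinotecan are used as printed despite
  their implausible magnitude; the whole-body model self-limits through
  flow, so they effectively behave as high-extraction settings.
* The female reference is a scaled male table; sex-specific composition
  differences are not represented.
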