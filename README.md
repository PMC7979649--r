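# cavalflow

Non-invasive hepatic haemodynamics for rodent MRI studies, as an R
package plus a reproducible analysis workflow. The liver's dual blood
supply — portal vein (PV) and hepatic artery (HA) — reorganises in
cirrhosis, but the rodent hepatic artery is too small to measure
directly with phase-contrast MRI (PC-MRI). **Caval subtraction**
estimates what cannot be imaged from what can:

```
TLBF = Q(supra-hepatic IVC) − Q(infra-hepatic IVC)      total liver blood flow
Q_HA = TLBF − Q(portal vein)                            hepatic arterial flow
HA fraction = 100 · Q_HA / TLBF                         (%)
```

with flows normalised to explanted liver weight (ml/min/100 g). Around
that estimator the package implements the full measurement chain used in
preclinical cirrhosis studies:

* **`pcmri_flow`** — velocity decoding from opposite-flow-encoded phase
  pairs (`v = wrap((φ⁺ − φ⁻)/2) · Venc/π`, which cancels background
  phase errors), ROI flow integration, cycle-mean flow;
* **`caval`** — the subtraction estimator, HA fraction, liver-weight
  normalisation, with negative estimates flagged rather than clipped;
* **`cine`** — left-ventricular systolic function from short-axis
  segmentation masks by the method of discs (EDV/ESV/SV/CO/EF, LV mass
  at 1.05 g/cm³, cardiac and LV-mass indices);
* **`cohort_stats`** — Welch t tests, mixed-design repeated-measures
  two-way ANOVA (interaction F via change scores, F = t²), Bonferroni
  post hoc paired comparisons, attrition-adjusted sample sizes;
* **`phantom`** — digital phantoms with exact ground truth: pulsatile
  Poiseuille vessels obeying supra = infra + PV + HA by construction, a
  truncated-ellipsoid LV, and cohort simulators parameterised by
  published sham/bile-duct-ligation summary statistics.

It is aimed at preclinical imaging scientists who want a tested,
scanner-free reference implementation of the caval subtraction chain,
and at anyone needing a PC-MRI/cine phantom with analytic oracles.

## Worked example

The default phantom encodes a sham-operated rat: PV 29.9 ml/min,
infra-hepatic IVC 38.2 ml/min, HA 11.9 ml/min, so the supra-hepatic IVC
carries 80.0 ml/min and true TLBF is 41.8 ml/min.

```r
library(cavalflow)

specs   <- hepatic_vessel_specs()          # PV 29.9 / infra 38.2 / HA 11.9
phantom <- synthesize_pcmri(specs, pixel_spacing = 0.208, matrix_size = 64,
                            background = c(0.10, 0.05, -0.05, 0.02, 0, 0.02),
                            noise_sd = 0.05, seed = 1)
flows <- lapply(phantom$datasets, function(d)
  mean_flow(flow_curve(d, phantom$rois[[d$vessel]])))
hepatic_haemodynamics(pv_flow = flows$pv, supra_flow = flows$supra_ivc,
                      infra_flow = flows$infra_ivc, liver_weight = 15)
```

Output (seed 1; 0.208 mm pixels, 0.05 rad phase noise):

```
PV    29.90 ml/min (truth 29.9)
TLBF  41.72 ml/min (truth 41.8)
HA    11.81 ml/min (truth 11.9)  -> HA fraction 28.3%
Normalised to the 15 g liver: PV 199, TLBF 278, HA 79 ml/min/100 g
```

i.e. the chain recovers PV flow to 0.0%, TLBF to 0.2% and the
subtraction-amplified HA estimate to 0.8% under realistic noise. The
worked example in closed form: `estimate_ha(tlbf = 41.8, pv = 29.9)`
returns **11.9 ml/min**, and `attrition_adjust(6, 0.30)` returns **9**
— the projected group size when 6 completers must survive 30% attrition.

The full workflow is scripted under `analysis/`
(`01_simulate_phantoms.R` → `05_cohort_statistics.R`); each driver
prints what it found and writes its tables under `results/`. The cine
driver, for instance, recovers the prescribed LV (EDV 0.66 ml, ESV
0.25 ml, EF 62.1%) to within 1.5% at the protocol's 6 × 2 mm slice
geometry, and the cohort driver detects the simulated baseline PV-flow
difference at p ≈ 2 × 10⁻⁵ and the terlipressin cohort × timepoint
interaction on every hepatic parameter. `run_pipeline()` executes the
same chain end-to-end with a manifest, deterministically per seed.

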