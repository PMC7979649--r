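---
title: "Methods: caval subtraction PC-MRI, cine volumetry and cohort statistics on digital phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: caval subtraction PC-MRI, cine volumetry and cohort statistics on digital phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavalflow)
```

## The measurement problem

The liver receives blood from two sources: the portal vein (PV) and the
hepatic artery (HA). When PV flow falls, a healthy liver compensates by
raising HA flow (the hepatic arterial buffer response); in cirrhosis this
response is thought to fail. Studying it requires total liver blood flow
(TLBF) and HA flow, but in rodents the hepatic artery is too small to
measure directly with phase-contrast MRI (PC-MRI).

Caval subtraction sidesteps this. All hepatic venous outflow enters the
inferior vena cava (IVC) between the infra-hepatic supra-renal and
supra-hepatic sub-cardiac levels, so

$$\widehat{TLBF} = Q_{supra} - Q_{infra}, \qquad
  \widehat{Q}_{HA} = \widehat{TLBF} - Q_{PV},$$

with both IVC flows and PV flow measured by routine 2D cine PC-MRI. The HA
fraction is $100\,\widehat{Q}_{HA}/\widehat{TLBF}$, and flows are
normalised to explanted liver weight (ml/min/100 g) for between-cohort
comparison. This package implements that chain — phase decoding, ROI flow
integration, caval subtraction, short-axis cine left-ventricular (LV)
volumetry, and the cohort statistics — and, because no scanner data ship
with it, digital phantoms with exact ground truth for every stage.

## Phase-contrast decoding

Each acquisition stores, per cardiac phase, a magnitude image and two
phase maps acquired with opposite flow-encoding gradients. We adopt the
convention $\varphi_\pm = \pm\pi v/V_{enc} + b$, where $b$ is a smooth
background phase error (eddy currents, field inhomogeneity) common to
both encodings; $|\Delta\varphi| = 2\pi$ at $v = V_{enc}$, the standard
aliasing boundary. The decoder forms the half-difference, wraps it into
$(-\pi, \pi]$ and scales:

$$\hat v = \mathrm{wrap}\!\left(\tfrac{\varphi_+ - \varphi_-}{2}\right)
  \frac{V_{enc}}{\pi}.$$

The subtraction cancels $b$ exactly, and the decode is exact for
$|v| < V_{enc}$ provided neither stored map crosses the $(-\pi,\pi]$ wrap
boundary, i.e. while $|\pi v/V_{enc} + b + \varepsilon| < \pi$. Values
landing exactly on the boundary are flagged with a warning; no phase
unwrapping is attempted — the acquisition protocol prevents wrap by
choosing $V_{enc}$ per vessel (33 cm/s for PV and infra-hepatic IVC,
66 cm/s supra-hepatically), and the phantom generator refuses
specifications whose peak velocity reaches $V_{enc}$. The vendor's actual
phase-difference scaling is not published for this protocol; the
$\pm\pi v/V_{enc}$ convention is asserted here because it pins the
decoder's scale to the aliasing boundary.

ROI flow is the pixel sum $Q = \sum_{roi} v\,\Delta A$ converted to
ml/min (cm/s × cm² × 60), and the cycle-mean flow is the unweighted mean
over cardiac phases (uniform prospective-gating sampling assumed; whether
time-averaging precedes or follows the caval subtraction is immaterial
because both operations are linear). Flow sign follows the positive
encoding direction; callers orient ROIs so physiological flow is
positive. Negative TLBF or HA estimates — which arise in practice when
measurement error exceeds the true difference — are retained and flagged,
never clipped, because clipping would bias cohort means. HA fraction is
computed per subject and then averaged across subjects, matching
per-cohort tables that report means of per-animal values.

## The phase-contrast phantom

Each vessel is a straight cylinder with fully developed Poiseuille flow:
the parabolic profile gives the closed-form flux
$Q = v_{max}\pi r^2/2$, so recovered flows can be checked against an
analytic oracle. The waveform is a raised sinusoid
$Q_k = \bar Q(1 + a\cos 2\pi k/n)$ — the true rodent waveforms are
unpublished and irrelevant to the subtraction identities, and sampling a
full cycle makes the sample mean equal $\bar Q$ to machine precision.
The supra-hepatic IVC waveform is constructed as infra-hepatic + PV + HA,
so conservation ($Q_{supra} = Q_{infra} + Q_{PV} + Q_{HA}$, hence
TLBF = PV + HA) holds exactly by construction, per phase and in the mean.

Pixels belong to a vessel by centre-point test, with no subpixel
antialiasing; the resulting integration error is first-order at the
vessel wall but small because the parabolic profile vanishes there
(measured: ≈0.16% at the protocol's 0.208 mm pixels for a 1.4 mm radius
vessel, <0.03% at 0.1 mm). Convergence tests therefore use finer grids,
not antialiasing. Noise is independent Gaussian on each phase map
(magnitude maps noiseless) — the simplest model that exercises the
estimator; 0.05 rad is the default. Background phase errors are 2D
polynomials (up to quadratic) in normalised image coordinates, amplitudes
of a few tenths of a radian, which keeps all stored phases inside the
wrap boundary given the default flows (peak $|\varphi| \approx 0.7\pi$).

Default phantom conditions reproduce a sham-operated rat worked example:
PV 29.9 ml/min, infra-hepatic IVC 38.2 ml/min, HA 11.9 ml/min (so
supra-hepatic IVC 80.0 ml/min and TLBF 41.8 ml/min), 12 cardiac phases,
0.208 × 0.208 mm pixels, liver 15 g, body 470 g. Radii (1.4–1.6 mm) are
typical rodent calibres chosen so peak velocities sit safely below each
vessel's $V_{enc}$; pulsatility 0.2 is a moderate venous value.

## Cine LV phantom and volumetry

LV volumes use the method of discs: per phase,
$V = \sum_{slices} A_{slice} \times t$, summed over however many slices
are provided (apex to mitral valve orifice; no basal-slice inclusion
heuristic). End-diastole and end-systole are the maximum and minimum of
the endocardial volume curve rather than fixed frame indices, because
frame timing is not part of the mask exchange format. Derived parameters
follow their definitions: SV = EDV − ESV, CO = SV × HR,
EF = 100 SV/EDV, LV mass = (epicardial − endocardial volume at the EDV
phase) × 1.05 g/cm³, and cardiac index / LV mass index divide by body
weight. Using the ED phase for mass (rather than a cycle average) follows
the printed definition of myocardial volume "at end diastole"; the
phantom's shell volume is constant over the cycle, so the choice is
untestable there and documented as a convention.

The phantom LV is a truncated half-ellipsoid of circular cross-section
whose long axis spans the slice stack
($L = n_{slices} \times t$). The cavity volume follows a raised cosine
from EDV (phase 0) to ESV (mid-cycle); the in-plane radius is solved from
$V = \tfrac{2}{3}\pi R^2 L$ per phase, and the epicardial surface
encloses cavity + wall volume at every phase, so the myocardial shell is
exactly volume-constant. Defaults are the sham cohort means: EDV 0.66 ml,
ESV 0.25 ml, wall 0.857 ml (0.90 g at 1.05 g/cm³), 6 × 2 mm slices,
0.313 × 0.625 mm pixels, 20 phases, 333 bpm, 470 g body weight.

Two discretisation errors add: a through-plane bias from sampling disc
areas at slice centres (−$t^2/8L^2$ relative for the half-ellipsoid,
≈0.35% at 6 × 2 mm), and an in-plane pixelation error. Only the latter
shrinks with pixel size, so resolution-convergence checks compare the
pixelated volume against the analytic disc-summation reference
(`disc_reference_volume()`) at the same slice geometry; comparing against
the prescribed continuous volume instead can be non-monotone when the two
error terms partially cancel. At the default geometry all of EDV, ESV, EF
and wall mass land within ~1.5% of prescription.

## Cohort simulation

The simulator draws per-subject baselines from
$\mathcal N(\mu_g, SEM_g\sqrt{n_g})$ — the subject-level SD implied by a
printed group SEM at its group size — and adds a within-subject change
with mean and SD likewise taken from printed change ± SE summaries,
correlated with the subject's baseline (default correlation 0.5, a
moderate value typical of repeated haemodynamic measurements; the printed
tables do not constrain it). Built-in parameter tables carry the
published sham/BDL baseline summaries and the terlipressin and LPS
response summaries (`default_cohort_parameters()`), with the group sizes
each SEM refers to (baseline 16/18; terlipressin responses n = 6/6; LPS
completers 9/6). Simulated cohorts default to n = 9 per group, the
study's attrition-adjusted projected size. Different parameters of the
same subject are drawn independently — the generator reproduces each
parameter's marginal moments, not the cross-parameter correlation
structure (PV flow and TLBF of a real animal are strongly dependent), so
passing tests say nothing about multivariate behaviour on real data.
Likewise the phantoms contain no motion, gating jitter, k-space effects
or segmentation error, so recovery tests demonstrate correctness of the
estimator chain, not robustness to real acquisition artefacts.

## Statistics

Baseline between-cohort comparisons use Welch's unpaired t test
(Welch–Satterthwaite df). Intervention responses use the mixed-design
repeated-measures two-way ANOVA (between factor cohort, within factor
timepoint). For the 2 × 2 design the cohort × timepoint interaction F on
$(1, N-2)$ df equals the squared pooled two-sample t on per-subject
change scores; that change-score formulation is how the F is computed,
because it remains exact for unbalanced cohorts, and it is cross-checked
in the tests against both `stats::aov()` with an `Error(subject/time)`
stratum and a brute-force sums-of-squares decomposition. Post hoc
baseline-vs-post paired t tests run within each cohort with Bonferroni
adjustment for the family of 2 comparisons — the only reading of
"post hoc Tukey tests using Bonferroni's correction" consistent with
per-cohort p values in a 2 × 2 design. Subjects missing a timepoint are
dropped per parameter with a warning (complete-case analysis, mirroring
the reduced post-LPS group sizes). Sample-size attrition inflation is
$\lceil n/(1-rate)\rceil$, computed with a $10^{-9}$ tolerance so float
artefacts such as $7/0.7 = 10.000\ldots002$ do not over-inflate.

```{r stats-example}
attrition_adjust(6, 0.30)
tbl <- synthesize_cohort(
  cohort_sim_spec(default_cohort_parameters("terlipressin"),
                  n_per_group = 9), seed = 3)
mixed_anova(tbl, "tlbf")
```

## Numerical and design choices

* **Units** are fixed at module boundaries: cm/s (velocity), mm
  (geometry), ml/min (flow), g (weights), bpm. Converters live only in
  the I/O layer.
* **Determinism**: every stochastic generator takes a seed and restores
  the caller's RNG state; a fixed seed gives bit-identical arrays and
  byte-identical pipeline CSVs.
* **Degenerate inputs**: zero-pulsatility waveforms, EDV = ESV (static
  heart, EF = 0), zero-variance cohorts, and zero-variance change scores
  (interaction F defined as 0 when cohort means also agree, ∞ otherwise)
  are all handled explicitly; TLBF = 0 makes HA fraction an error rather
  than an Inf.
* **Interchange formats**: NIfTI for image stacks (double precision on
  write, so round trips are lossless), CSV for curves and tables, JSON
  for metadata and ground truth.
* **Problem sizes**: the bundled tests and drivers run phantoms at
  24–80 pixel grids with 4–12 phases, the cine stack at the protocol's
  128 × 64 × 6 × 20 geometry (and one 2× refinement), 100-phantom
  conservation sweeps, and 500–1000-replicate simulation studies for the
  type-I error and power-style checks; all sizes chosen to characterise
  the estimators well while keeping a full run in the order of seconds
  to a minute per suite.

## Known limitations

Centre-point masks mean single-pixel partial-volume effects are
unmodelled; the decoder cannot recover flows past the wrap boundary and
does not attempt unwrapping; the cine phantom's circular cross-section
and constant-length contraction are idealisations (real LVs shorten
longitudinally); the LPS parameter set describes unequal completer
groups, which the simulator honours via per-cohort `n`, but premature
demise is otherwise unmodelled. None of these affect the algebraic
identities (conservation, TLBF = PV + HA, F = t²), which hold exactly by
construction and are enforced in the test suite.
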