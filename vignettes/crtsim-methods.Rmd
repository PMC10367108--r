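---
title: "Models and methods behind crtsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crtsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`crtsim` predicts where on the left-ventricular (LV) epicardium a
resynchronization-therapy (CRT) pacing lead should go. This vignette is the
package's own account of the models it implements, the parameters that
matter, the choices made where the design was genuinely open, and what the
synthetic test bed does and does not establish about real data.

## 1. Synthetic anatomy

Patient-specific ventricular meshes from tomographic imaging are replaced by
a parametric idealization: the LV is a thick-walled prolate ellipsoid
truncated at its equatorial plane (the base), and the RV is a thinner
crescent shell wrapped around a 120° septal sector of the LV epicardium. The
septum is therefore a sector of the LV wall whose right face is RV
endocardium, and the RV free wall shares nodes with the LV along its
attachment rims, so the two ventricles form one conducting mesh. A
structured hexahedral grid is split into tetrahedra through cell centers,
with quad faces split along the diagonal through their smallest node index
so neighbouring cells always conform.

Default dimensions describe the dilated hearts of a CRT population: LV
endocardial short semi-axis 33 mm (an end-diastolic diameter of 66 mm), long
semi-axis 72 mm, wall 8 mm; RV cavity depth 12 mm, free wall 3.5 mm, giving
the RV roughly one sixth of the myocardial volume. In the physics cohort the
LV radius is scaled per patient by the drawn EDD.

**Fibers.** The helix angle rotates linearly with transmural depth from +60°
at the endocardium to −60° at the epicardium, the standard rule-based
convention. The transmural element layers sample that rule *inclusively*
(depths 0, ½, 1 for the default three layers): a cell-centered sampling
would truncate the represented helix range to ±30° and roughly halve the
apex-to-base conduction speed, a discretization artifact rather than a
modelling choice.

**Parcellation.** The AHA 17-segment scheme is computed from the stored
anatomical frame (long axis, septal axis, apex, base center), so it is
invariant under rigid motion of the mesh together with its frame. Septal
segments are fixed to {2, 3, 8, 9, 14}. Scar and fibrosis are annotated at
whole-segment, transmural granularity — the same granularity as expert
annotation on the AHA scheme; whether clinical scar is transmural is not
knowable at that granularity, and transmural is the conservative choice for
a conduction obstacle.

## 2. Conduction: anisotropic eikonal model

Activation times solve the anisotropic eikonal equation with a per-element
speed tensor: `v_f` along the fiber and `v_f / 4` across it (the 4:1
velocity anisotropy), both scaled by √κ where κ is a dimensionless global
conductivity multiplier, by √0.5 in fibrosis (conductivity reduced by half),
and zero in scar. The √· mapping from conductivity factors to speeds is the
monodomain reduction; a proportional mapping is available as a config
alternative so the ambiguity is contained in one switch.

The solver is a compiled fast-iterative method with exact local updates on
tetrahedra (face, edge and vertex candidates from the constrained
minimization of the arrival-time functional), label-correcting sweeps and a
node-update tolerance of 1e-6 ms. On slab benchmarks it reproduces analytic
travel times to well under 1% even at 5 mm resolution; an independent
Dijkstra oracle on a densified edge graph bounds its error in the tests.

`v_f` defaults to 0.7 mm/ms, frozen once so that the scar-free default
anatomy at κ = 1 yields a baseline LBBB QRS duration of about 153 ms —
inside the 150–190 ms range that defines the modelled population. Unreached
nodes (tissue enclosed by scar) carry `NA` in memory and the documented
sentinel −1 in VTK exports, and are excluded from every feature statistic.

## 3. Baseline LBBB and biventricular pacing

Complete left bundle branch block is modelled structurally: the fractal
Purkinje tree is grown only from the right bundle. Branches are directed
walks on the RV endocardial surface graph (so the tree crosses naturally
between the septal face and the free wall), with binary branching at ±30°
(±5° seeded jitter), initial branch length 20 mm, decay 0.8, and six
generations — enough terminals (32) to blanket the coarse RV endocardium.
Conduction in the tree is 3 mm/ms from the His node; terminals couple to
their nearest RV endocardial node with zero junction delay (the tree is
otherwise insulated from the myocardium, and no retrograde coupling exists).

BiV pacing ignores the tree entirely and stimulates all nodes within 2 mm of
the RV electrode (onset 0) and of the LV electrode (onset = VV delay,
default 0). The default RV electrode is apical–septal, where clinical apical
leads contact. Personalizing κ separately per protocol against the
clinically recorded QRS durations is essential, not cosmetic: with ~30
distributed Purkinje sources, baseline LBBB can activate the ventricles
faster than two point electrodes at equal κ, so the fitted BiV multiplier
comes out systematically higher than the LBBB one — the single global
parameter absorbs everything the pacing protocol changes. Only under
per-protocol κ does the clinical resynchronization pattern (TAT95 and QRSd
dropping under pacing) emerge, and that is how the cohort pipeline and the
trend tests run.

## 4. Pseudo-ECG and QRS duration

Each element depolarizes along a fixed template action potential (rest
−85 mV, 1 ms upstroke to +25 mV, 250 ms plateau, cosine repolarization)
shifted by its activation time; only the upstroke shapes the QRS, which is
the only fitted observable. Electrode potentials follow the
infinite-homogeneous-medium pseudo-ECG: the sum over elements of volume ×
∇V~m~ · ∇(1/r). This deliberately replaces personalized torso/lung lead
fields, which require patient CT; QRS duration and its trends survive the
simplification, absolute morphology does not. Nine electrodes on a
parametric torso shell define the standard 12 leads; the Einthoven identity
II − I − III = 0 holds by construction and is asserted to 1e-9.

QRS onset/offset: the root-mean-square across-lead derivative is compared to
2% of its maximum; above-threshold runs closer than 5 ms are merged and the
window spans the first to the last crossing, a "maximum QRSd across leads"
convention. Threshold and debounce are config entries. Sampling step 1 ms.

κ fitting brackets the monotone map κ → QRSd by bisection inside
[0.2, 1.5], stopping when the target is matched within 2 ms and the bracket
is narrower than 0.02; an unattainable target returns the nearest bound with
a boundary flag rather than an error, because boundary hits are informative
in a cohort.

## 5. Dyssynchrony features

* `TAT95` — smallest time by which ≥95% of the non-scar tissue *volume* has
  activated (volume-weighted percentile of element times); `TAT` is the
  100% version.
* `AD_RVLV` — max LV free-wall element time minus max RV free-wall element
  time. The per-ventricle *maximum* is used (the natural reading of "total
  activation time" per ventricle); the septum belongs to neither free wall.
* `AD_STLV` — (volume-weighted mean LV free-wall time − mean septal time) /
  TAT, with TAT at 100%, not TAT95 — the normalizer is the full
  activation time, a distinct quantity from the 95% percentile.
* `LAT area` — the top 10% of LV epicardial activation times at baseline;
  the fraction is a config entry because "late-activated area" has no
  canonical quantification.
* Distances (site→scar, site→LAT area, RV↔LV electrodes) are unit-speed
  isotropic-eikonal travel times through the mesh, one consistent
  convention for all of them including `D_PS`. A missing scar yields a
  missing distance, imputed downstream with the training-set maximum
  (farthest-from-scar semantics), never zero.

## 6. Response classifier

Preprocessing standardizes non-categorical columns, imputes missing values
with the column maximum, drops zero-variance columns with a warning, and
removes the later-listed member of any pair with |Pearson r| > 0.85.
Leave-one-out cross-validation recomputes preprocessing statistics and
feature selection inside every fold; three selectors are provided —
univariate ranking, L1-path entry order, recursive elimination — three
standard methods covering the main selection families. The final model is a plain maximum-likelihood logistic regression
on the seven default features (LVEF, BMI, EDD, scar distance, baseline
TAT95, baseline and paced AD_RVLV); no hyperparameter search anywhere; a
weak ridge penalty replaces the MLE only under perfect separation, with a
warning. The ML-score is the fitted probability; the patient-level cutoff
defaults to 0.51 (the maximum-accuracy operating point) while score maps
are colored at the natural probability midpoint 0.5 — two different roles,
so they are distinct config entries.

## 7. Bayesian optimization of the pacing site

Candidates are LV epicardial nodes outside septal segments and scar. The
initial design evaluates the center of every eligible AHA segment (12 on a
scar-free model). The surrogate is a zero-mean Gaussian process with a
squared-exponential kernel on 3D Euclidean coordinates — the candidate
surface is smooth at the 5–100 mm length scales allowed, and no kernel was
prescribed; a geodesic kernel is a noted extension. The length scale
maximizes the marginal likelihood, the signal variance is profiled, and the
noise floor of 1e-6 keeps the posterior interpolating (|μ(x~i~) − y~i~| <
1e-6 at data). The acquisition is the upper confidence bound μ + 2σ
(μ − 2σ when minimizing TAT95); it is maximized node-wise over the
candidates, and the search stops when two consecutive iterations pick the
same node — exact node identity by default, with an optional distance
tolerance (< 2 mm) for finer meshes. Failed site evaluations score 0, which
steers the search away without aborting a patient. Each iteration costs
exactly one model evaluation, so a patient costs ≈ 12 + (iterations)
simulations.

## 8. Synthetic cohort

Two tiers separate statistical correctness from simulator fidelity. The
*statistical tier* draws covariates from truncated normals on the cohort
scale (LVEF ~ N(26, 6)%, BMI ~ N(29, 5), EDD ~ N(66, 9) mm), latent
dyssynchrony features on the scales the physics tier itself produces for
this anatomy (baseline TAT95 ~ N(167, 12) ms, inter-ventricular delays
~ N(29, 11) and N(29, 14) ms, scar distances 5-45 mm) — so a classifier
trained on one tier scores the other sensibly — and labels from a known
logistic ground truth β\* with the intercept calibrated to a 42% response
prevalence; it exists so parameter-recovery and cross-validation tests have
an exact oracle. The *physics tier* runs the full model chain per patient
(anatomy scaled by EDD, per-protocol κ fit to drawn pre/post QRS durations
of ~180/~158 ms, simulation, feature extraction). Reference LV lead
segments prefer the lateral wall (88%), mirroring clinical placement.

What passing tests on this cohort show: the statistical machinery is
correct (honest cross-validation, consistent estimation, chance-level AUC
under permutation) and the physics chain produces features with the right
structure and trends. What they cannot show: that the classifier's
coefficients or its clinical accuracy transfer to real patients — the
synthetic joint distribution is deliberately simple (independent
covariates, no measurement noise, idealized anatomy).

## 9. Numerical choices and limitations

* Solver tolerance 1e-6 ms; BO ties broken toward the lowest node index;
  GP noise floor 1e-6; all procedures deterministic given their seeds.
* Default problem sizes — ~1.5k nodes / 8k tetrahedra per heart, 57-patient
  statistical cohorts, 3–5-patient physics cohorts in the pipeline tests —
  were chosen so a full patient (baseline + 12 design sites + BO to
  convergence) completes in about a minute on one CPU.
* Not modelled: torso-specific lead fields, repolarization and T-waves,
  ionic-model dynamics beyond a fixed template, electromechanics,
  coronary-vein access constraints on the LV lead, VV/AV delay
  optimization, and any claim about the real cohort's clinical statistics.
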