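---
title: "Methods: dosimetry of interstitial multicatheter breast brachytherapy"
author: "apbidose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosimetry of interstitial multicatheter breast brachytherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`apbidose` reconstructs, as tested code, the dosimetric analysis of
accelerated partial breast irradiation (APBI) delivered by interstitial
multicatheter HDR Ir-192 brachytherapy with intraoperative free-hand
implantation: TG-43 dose calculation over implant geometries, DVH-based
plan-quality indices with clinical constraint checking, a simplified photon
Monte Carlo quantifying the backscatter deficit at the tissue-air interface
(the physical mechanism behind planning-system skin-dose overestimation),
and a synthetic patient cohort that emulates the study conditions, including
radiochromic-film-like skin point measurements.  The original patient CT
plans and film scans are not public; everything here runs on generated
data.

## Dose model

Dose rates follow the AAPM TG-43 formalism in an unbounded water medium:

$$\dot D(r,\theta) = S_K \,\Lambda\, \frac{G(r,\theta)}{G(r_0,\theta_0)}\,
  g_L(r)\, F(r,\theta),$$

with air-kerma strength $S_K$ (U), dose-rate constant $\Lambda$
(cGy h$^{-1}$ U$^{-1}$), reference point $(r_0,\theta_0) = (1\,\mathrm{cm},
90^\circ)$, the line-source geometry factor
$G_L = \beta/(L r \sin\theta)$ (on-axis limit $1/(r^2 - L^2/4)$), the radial
dose function $g_L$ and the 2-D anisotropy function $F$.  Units are fixed:
cm for source geometry, mm for patient space, seconds for dwell times, cGy
per fraction for dose; unit conversion is confined to the source module.

Numerical choices:

* $g_L$ is interpolated log-linearly in $r$ (linear in $\log g$), constant
  below the first node and log-linearly extrapolated beyond the last;
  $F$ is bilinear on its $(r,\theta)$ grid with $r$ clamped to the table.
  Both policies are conservative and recorded so plans are auditable.
* Grid dose is the exact superposition over all dwells (no approximation),
  computed in compiled code; chunking cannot change results.  Voxels closer
  than 1 mm to a dwell are evaluated at 1 mm and counted in a
  `capped_voxels` attribute — clinical planning systems likewise do not
  claim near-field validity, and the cap keeps DVHs finite.
* Since no consensus dataset is bundled, the package ships a unit-test
  source (point mode, $g \equiv 1$, $F \equiv 1$, so that
  $\dot D = S_K \Lambda / r^2$ exactly) and a synthetic line source with
  smooth Ir-192-like tables (`synthetic_ir192_source()`), clearly labelled
  synthetic.  Real tables load from the documented CSV dialect.

## Implant geometry and anatomy

Free-hand needles are rigid, so catheters are straight, parallel to the
longitudinal axis, arranged in one or two planes parallel to the (locally
planar) skin: in-plane spacing 1.5-2 cm, second plane offset laterally by
half the spacing (triangular geometry), plane separation 15 mm.  Dwells
step 5 mm with a 5 mm tip retraction — typical afterloader practice; the
study does not state these, so they are package defaults recorded in plan
output.  Buttons coincide with the catheter path endpoints; skin-region
geometry uses their skin projection.

The TPS skin region is the quadrilateral whose short sides are the extreme
button positions along the catheter direction and whose long sides parallel
the outermost catheters' skin projections displaced 1 cm outward, extruded
from the skin surface to a 3 mm inner margin.  With a single catheter the
quadrilateral degenerates to a 2 cm strip.  Involved ribs are the rib slab
under that footprint.  Margins (CTV = cavity + 2 cm, PTV = CTV + 5 mm) are
Euclidean and isotropic with a voxel-center convention; the general
`expand_margin()` uses an exact squared Euclidean distance transform.

The synthetic anatomy is deliberately minimal but exposes every reported
metric: an ellipsoidal breast dome (apex at the skin above the implant,
base on the chest wall, lateral semi-axis 1.6 x height), a 20 mm chest
slab whose first 5 mm is the rib layer, a 45 mm lung slab starting 25 mm
below the breast base with its medial part taken as heart.  CTV/PTV are
cropped to breast tissue between 10 mm below the skin and 6 mm above the
chest wall, and the cropped fraction is recorded — the study does not state
its cropping policy, so the generator's is explicit instead.

## Optimization

The planning system's inverse optimizer is unspecified in the source
material, so the package uses the simplest auditable stand-in: geometric
weighting (dwell weight inversely proportional to the summed dose rate
received from all other dwells), optionally refined by nonnegative least
squares of dose against the prescription at ~200 seeded PTV boundary
points, followed by a global time scale found by bisection (0.1% tolerance)
so that 95% of the PTV receives 95% of the 340 cGy per-fraction
prescription.  Coverage is monotone in the scale, which the bisection
asserts.  No attempt is made to reproduce a commercial optimizer beyond
that coverage rule.

## Interface Monte Carlo

TG-43 assumes full scatter; near the skin the missing backscatter makes it
overestimate dose.  The package quantifies this with an analog photon MC in
water (kerma approximation, no electron transport): exponential free paths
from the tabulated total attenuation, Klein-Nishina scattering on free
electrons (Kahn sampling), everything else treated as local absorption;
Rayleigh and binding effects are ignored — second-order for a deficit
*ratio* at 0.38 MeV, the mean Ir-192 energy used for the monoenergetic
default.  Water coefficients are the standard NIST tabulation packaged as
CSV, log-log interpolated.  Air is modelled as vacuum: a photon whose free
flight ends beyond the skin plane never returns.

Point tallies use the next-event (point-detector) estimator of collision
kerma.  The full-water and half-space estimates are scored from the *same*
histories: the half-space tally simply stops crediting a history once it
crosses the interface.  This makes the deficit
$100\,(D_\mathrm{full}-D_\mathrm{half})/D_\mathrm{full}$ a fully correlated
ratio (the primary term cancels exactly), with batch-means standard
errors.  Useful corollaries: with scattering disabled the tally equals
$E\,(\mu_{en}/\rho)\,e^{-\mu r}/(4\pi r^2)$ identically, and in full-water
geometry the deficit is identically zero.  Energy is conserved per history
(deposited + escaped + below-cutoff = emitted), which a test asserts to
machine precision.

The phantom experiments are reproduced geometrically: two parallel
catheters 2 cm apart at 5/10/15/20 mm depth with a surface tally above one
catheter, and a perpendicular-film variant with catheters 2 cm deep and a
tally line across the surface trace of the film plane.  The source text
gives two inconsistent depth lists (5/10/20 vs 5/10/15 mm), so the depth
list is an argument defaulting to 5/10/15/20 mm.  The measured film values
are physical data and are never asserted as MC equalities; the package
asserts sign, depth monotonicity, the full-scatter null, the primary-beam
closed form, and an order-of-magnitude band (deficit at 15-20 mm depth
within 5-35%).

## Synthetic cohort and film emulation

The generator's defaults are the study conditions: 17 patients, two-plane
implants, 340 cGy x 10 fractions, and cavity-size/depth distributions
chosen once so that PTV volumes span the reported range (about 32-125 cc
at the top end; the generator produces roughly 80-135 cc — the smallest
clinical PTVs arise from individual anatomy the minimal dome geometry
cannot reach, which is a documented limitation, and the checks require
range overlap).  Feasibility is enforced by rejection sampling with logged
rejection counts: the shallow catheter plane stays at least 18 mm below
the skin (the clinical hard floor is 5 mm), the deep plane at least 16 mm
above the chest wall, and draws whose cropped PTV would exceed a 135 cc
eligibility cap are rejected, mirroring the size limits of partial-breast
irradiation protocols.

The film emulator computes the TPS skin dose as D50% of the skin region,
then applies a depth-dependent backscatter deficit and multiplicative
lognormal noise ($\sigma = 0.03$, the scale of film dosimetry error):

$$D_\mathrm{meas} = D_\mathrm{TPS}\,(1 - \mathrm{deficit}(d))\,
  e^{\sigma Z}.$$

The default deficit model is a logistic in the shallowest-catheter depth,
$A/(1+e^{-(d-d_0)/s})$ with $A = 0.33$, $d_0 = 15$ mm, $s = 8$ mm,
calibrated once so the cohort's overestimation ratios fall in the measured
15-33% range with a median near 20%; an MC-derived lookup can be plugged
in via `deficit_from_mc()`.  Parameter recovery fits the asymptote by
exact least squares with the model shape held fixed: over the narrow
clinical depth range the logistic is sampled on a short arc, so a joint
$(A, d_0)$ fit at $n = 17$ is ill-conditioned; the amplitude-only fit
recovers $A$ to within a few percent per cohort.

What passing these checks shows — and does not show — about real data: the
generator reproduces the *structure* of the study (geometry, prescription,
index identities, constraint logic, a depth-dependent film deficit) but
not patient-specific anatomy, seroma, catheter curvature, or film response
physics.  Dose-heterogeneity indices in particular come out higher
(median DNR near 0.55) than the clinical plans (0.30): covering the
synthetic slab-like targets from two planes demands hotter central dose
than the real, individually shaped targets did.  Agreement with the
reported per-patient tables is therefore not asserted anywhere; identities
(DHI + DNR = 1, COIN <= CI), ranges, and trends are.

## Problem sizes and determinism

Default per-case grids use 2.5 mm isotropic voxels over the breast and OAR
slabs (roughly 300k voxels); the Monte Carlo defaults to 2 x 10^6
histories for the deficit study and 25-50 batches for standard errors.
These sizes make a full cohort-plus-MC analysis a matter of minutes on one
core while keeping voxel-quantum effects within the stated tolerances.
Every random stage (cohort draws, surface-point sampling, MC transport)
takes an explicit seed, is restored-state isolated, and reruns
bit-identically; `run_all()` writes a manifest with the seeds, sizes and
per-stage timing.

## Known limitations

* TG-43 in water everywhere: no heterogeneity corrections (that inadequacy
  near the skin is exactly what the interface MC quantifies).
* Kerma approximation and free-electron Compton; no Rayleigh, no
  spectrum — adequate for deficit ratios, not for absolute dosimetry.
* Planar local skin and analytic dome anatomy; no image-based contours,
  no DICOM-RT.
* The optimizer is a transparent stand-in, not a replication of any
  commercial algorithm.
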