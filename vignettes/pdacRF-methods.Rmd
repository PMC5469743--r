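---
title: "Modeling RF-enhanced chemotherapy of hypovascular pancreatic tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling RF-enhanced chemotherapy of hypovascular pancreatic tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Pancreatic ductal adenocarcinoma (PDAC) responds poorly to gemcitabine
(Gem) largely because the drug cannot reach the tumor cells: PDAC lesions
are hypovascular and fibrotic, and a small hydrophilic drug that
extravasates from the sparse capillaries is consumed within a few tens of
micrometers of the vessel wall. Non-invasive radiofrequency (RF) field
exposure (13.56 MHz, capacitively coupled, non-thermal) transiently alters
tumor-cell phenotype — cells round up and cell–cell contacts loosen —
which measurably increases both the diffusive penetration of small
molecules into 3D tissue and their extravasation across tumor vasculature.

`pdacRF` implements a two-dimensional continuum model of a hypovascular
PDAC lesion and asks the quantitative question: *if RF multiplies the
drug's diffusive penetration `D` and its vascular extravasation transfer
rate `TR`, how much additional tumor regression does a Gem bolus produce,
and which of the two transport parameters dominates?* The package also
implements the image-quantification procedures used to measure these
transport quantities (radial intensity profiles of spheroids,
nuclear-stain blob segmentation with area gates, positive-area fractions,
and distance transforms to vessel masks), together with synthetic-image
generators that carry planted ground truth so every quantification
operation can be validated by round-trip.

## Model structure

The lesion lives on a regular node-centered grid (default 140 × 140 nodes
at `h` = 10 µm, i.e. a 1.4 mm square of tissue). Two volume fractions
describe the tumor: viable tissue `phi` and necrotic debris `nec`; a node
belongs to the lesion when `phi + nec > 0.5`. The coupled update per
macro step (default 1 h) is:

1. **Oxygen** `sigma` solves a quasi-steady reaction–diffusion equation,
   `0 = div(D_eff grad sigma) + TR_O2 * vessels * (1 - sigma) -
   lambda_u * phi * sigma - lambda_d * sigma`, with the domain edge held
   at the host value. Lesion nodes are labeled *proliferating*
   (`sigma >= sigma_P`), *hypoxic*, or *necrotic* (`sigma < sigma_N` or
   debris-dominated).
2. **Angiogenesis**: hypoxic tissue produces a diffusible angiogenic
   factor; capillary segments in high-factor regions emit sprout tips
   that perform a chemotactically biased lattice random walk (softmax of
   the factor difference, with ECM drag), branch stochastically, and fuse
   with any vessel they encounter outside their own trail. Matrix-degrading
   enzymes produced by viable tumor slowly degrade the ECM density field,
   which hinders all diffusivities as `D/(1 + alpha * E)`.
3. **Perfusion by connectivity**: only vessels conductively connected to
   the extratumoral host network carry blood and deliver species. The
   initial capillary bed is a regular grid; intratumoral segments are
   removed with probability `p_prune` = 0.8 (hypovascularization), and
   capillaries newly engulfed by the growing lesion collapse with the same
   probability. Anastomosed sprout paths can reconnect isolated regions.
4. **Drug transport** during a dose window: plasma concentration decays as
   `exp(-t / tau)` with `tau` = 1.5 h (>90% washed out within 3.6 h), and
   the interstitial field is re-solved quasi-steadily at sub-steps (its
   equilibration time, ~0.1–0.2 h, is much shorter than the washout). A
   cell-associated exposure field `u` loads from the interstitial
   concentration (`tau_load` = 1 h) and clears slowly (`tau_ret` = 24 h),
   representing intracellular retention of the active metabolite.
5. **Pharmacodynamic kill**: viable tissue dies at rate
   `k_kill * u / (c50 + u)`, weighted by cell-cycle activity — full rate
   in proliferating tissue, 10% in hypoxic (quiescent) tissue, none in
   necrotic regions. Killed cells join the necrotic pool and are cleared
   by lysis; they are not removed instantly.
6. **Growth mechanics**: the net volume source (mitosis − apoptosis −
   lysis) drives an oncotic pressure via a single-phase Darcy closure,
   `mobility * lap(P) = -S`, tissue moves with `u = -mobility grad P`,
   and the volume fractions are advected conservatively (first-order
   upwind) with hypoxia-driven necrosis below `sigma_N`.

### Why the response peaks ~48 h after a bolus

Three deliberate mechanisms produce the delayed regression minimum:
retained exposure keeps killing for about a day after the plasma has
washed out; killed cells become debris that must be lysed (default
`lambda_lys` = 0.08 /h, a ~9 h half-life) before the lesion's support
shrinks; and peripheral death re-oxygenates the interior, recruiting
quiescent cells into the cycle where the retained drug can kill them — an
inward-moving erosion cascade. The same cycle-specificity is what makes
the spheroid calibration meaningful (below).

### RF modulation

An RF-flagged dose multiplies the drug's relative penetration and
transfer rate by `1 + s_k (f - 1)` with `f_D = f_TR = 1.75` by default
(the measured +75%). Susceptibility `s_k = max(floor, 1 - delta (k - 1))`
declines by `delta` = 0.025 per exposure (a 10% decline after four
treatments), disabled for single-dose comparisons and enabled for the
weekly protocol.

## Parameterization

Only *relative* transport magnitudes are available, so oxygen anchors the
scales: penetration length `L_O2` = 100 µm with uptake 1 /h fixes the
reference diffusivity `D_ref` = 1e4 µm²/h, and `TR_O2` = 5 /h. The drug's
relative penetration 0.20 then reproduces the measured ~20 µm penetration
by construction, via `D = P_rel² D_ref (lambda_u / lambda_ref)` so that
`L = sqrt(D / lambda_u) = P_rel L_O2` for any uptake rate. Drug uptake is
fast (`lambda_u` = 5 /h, avid nucleoside transport) and includes necrotic
debris (the drug, like the DAPI surrogate used to measure its transport,
binds nucleic acids that persist in dead cells); oxygen is consumed only
by viable tissue.

Two calibrations are part of the method:

* **Kill rate** (`calibrate_kill()`): `k_kill` is bisected until an
  avascular 200-µm spheroid bathed in drug at 1.0 (≡100 µM) for 72 h
  loses 70% ± 1% of its viable mass — the EC70 datum. With cycle-weighted
  kill, the bath first eliminates the oxygenated cycling rim and then
  erodes inward as debris lyses and oxygen penetrates deeper, so the
  calibrated rate is substantial (0.30 /h) rather than being driven to
  zero by an unphysical runaway kill front. The shipped default
  `default_k_kill()` is this calibration's result.
* **Tissue thresholds** (`gen_pretreatment_lesion()`): `sigma_P` and
  `sigma_N` are set by quantile matching of the oxygen distribution over
  lesion nodes so that the reference pre-treatment lesion is 25%
  proliferating / 58% hypoxic / 17% necrotic; the printed composition,
  not the thresholds, is the observable.

The growth rate `lambda_mit` = 0.030 /h was chosen so that inter-dose
regrowth matches the weekly-protocol context (an untreated control
roughly doubles its radius in 3–4 weeks, consistent with ectopic PANC-1
xenografts): with substantially slower growth, the calibrated per-dose
kill always overwhelms regrowth and weekly drug-alone dosing eradicates
the lesion, qualitatively contradicting the reference behavior in which
weekly drug alone fails to restrain growth.

The pre-treatment lesion is grown untreated from a 300-µm seed to 400 µm
(about 9 days of simulated time), which also lets the angiogenic network
mature; heterogeneous ECM comes from smoothed seeded Gaussian noise
(mean 0.6, sd 0.15).

## What the synthetic generators emulate

* `gen_spheroid_image()`: radial exponential penetration profiles with a
  planted decay length and multiplicative microscopy-like noise.
* `gen_ivm_pair()`: intravital-style image pairs whose intensity decays
  from a vessel mask with 10 µm (pre) vs 20 µm (post-RF) lengths.
* `gen_blob_image()`: nuclear-stain blobs with known rasterized areas,
  merged-component bookkeeping and edge flags for the segmentation gates.
* `gen_cell_areas()`: paired cell areas with a planted retraction
  fraction clearly straddling the 33% criterion.

They are pure functions of (spec, seed) and carry their ground truth, so
passing round-trip tests demonstrates that the *quantification operations*
are correct — not that real microscopy (with its optics, uneven
illumination and segmentation ambiguity) would be recovered equally well.

## Numerical choices

Five-point finite differences; quasi-steady systems solved by sparse
supernodal Cholesky after eliminating Dirichlet nodes (the operator is an
M-matrix, so a discrete maximum principle holds); the pressure operator
is constant-coefficient and its factorization is cached. The explicit
drug stepper is an exponential-Euler scheme (exact local reaction,
explicit diffusion, `dt <= h²/(4 max D)`) whose fixed point is exactly
the discrete quasi-steady solution; the main loop instead re-solves the
quasi-steady drug system at sub-steps of the plasma decay, because the
penetration-maximized case would need explicit steps of ~5e-4 h.
Advection uses conservative first-order upwinding under a CFL guard with
proportional rescaling if `phi + nec` would exceed 1. Ties in the sprout
direction choice are resolved by the fixed neighbor order east, north,
west, south through a single categorical draw. All randomness flows
through explicit seeds; identical seed and configuration reproduce
trajectories bit-for-bit.

Default problem sizes (140 × 140 nodes, 1-h macro steps, 4-h angiogenesis
cadence, 12-h dose windows with 4 drug sub-steps) were chosen so a full
single-treatment comparison runs in minutes on one CPU while keeping the
capillary spacing (100 µm) and the 20-µm drug penetration resolvable.

## Known limitations

* The model is two-dimensional; fractions and radii are area-based.
* Under repeated weekly dosing the model's per-dose effect compounds:
  regrown tissue is more proliferative (hence more drug-sensitive) and
  the angiogenic network keeps re-delivering drug to the shrinking
  lesion. As a result, weekly drug-alone dosing restrains the simulated
  lesion far more than the reference behavior (which shows continued
  growth to 166% of initial radius by week 6), and weekly RF-enhanced
  dosing eradicates the lesion rather than holding it near 60% of its
  initial radius. Capturing multi-dose tolerance alongside the
  single-dose response appears to require an acquired-chemoresistance
  mechanism for which no quantitative basis was available; we chose not
  to invent one, and report the weekly outcomes as the model produces
  them.
* Vessels removed by pruning never regrow after the lesion regresses
  (no vascular normalization of vacated tissue).
* The PD model ignores dose-rate effects within a bolus (exposure is the
  driver) and drug resistance; RF resistance only attenuates the
  transport enhancement.

## Reproducing the headline numbers

`scripts/acceptance.R` re-runs, from scratch: the EC70 calibration, the
reference-lesion generation, the five single-treatment cases, the weekly
protocol arms and the calibration-closure check, and writes the resulting
quantities as JSON. See the README for the command line.
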