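---
title: "Quantifying egg-chamber development from intravital imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying egg-chamber development from intravital imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovoquant)
```

`ovoquant` analyses time-lapse fluorescence imaging of *Drosophila*
oogenesis inside the intact female. An egg chamber — 15 polyploid nurse
cells plus one oocyte wrapped in a somatic follicle epithelium — traverses
stages 2–14 over a few days, growing exponentially, importing yolk during
vitellogenesis (stages 8–10), and finally receiving the entire nurse-cell
cytoplasm during "dumping" (stage 11). The package covers five analysis
tasks around such data, plus a synthetic-data generator that produces every
input with exact ground truth.

## 1. The steady-state timeline model

An ovariole is an assembly line: at steady state the rate at which eggs
leave it equals the rate at which chambers advance. From three dissection
observables — eggs laid per female per day ($E$), ovarioles per female
($O$), and chambers per ovariole ($EO$) — the per-ovariole egg production
rate and the total transit time follow:

$$\mathrm{EPR} = E/O, \qquad G = \frac{EO}{\mathrm{EPR}} \times 24\ \mathrm{h}.$$

Under the same steady-state assumption, the probability that a randomly
sampled fixed chamber sits in stage $s$ is proportional to the time spent
there, so stage durations are $G_s = f_s\, G$ with $f_s$ the observed stage
frequencies.

```{r timeline}
epr <- compute_epr(51.5, 35.63)      # E, O from the colony survey
G   <- compute_total_duration(5.2, epr)
tl  <- stage_durations(default_stage_frequencies(), G)
c(EPR = round(epr, 2), G = round(G), Gs8 = round(tl$schedule$duration_h[7], 2))
```

A numerical subtlety worth stating: every intermediate is carried at full
precision and rounded only for display. With stage-8 frequency 0.077,
$G_s = 0.077 \times 86.34 = 6.65$ h; rounding $G$ to 86 h first would give
6.62 h, which is not reproducible against the conventional report.

Only the stage-8 frequency (0.077) is an established benchmark; the
remaining entries of `default_stage_frequencies()` are a fixed, plausible
unimodal distribution over stages 2–14 (longer early/mid stages, brief
terminal stages) summing to 1. They parameterize the generator, not the
estimators, which always use whatever frequencies the data provide.

## 2. Exponential growth curves and age assignment

Midsection area (the chamber's cross-section at its widest z-slice) is the
standard size proxy, because late chambers cannot be imaged to full depth.
Its growth is modelled as $A(t) = A_0 e^{kt}$; the reference curve has
$A_0 = 273\ \mu\mathrm{m}^2$, $k = 0.06/\mathrm{h}$. A second curve of the
same form describes the oocyte's share of the midsection
($O_0 = 0.318$, $k' = 0.07/\mathrm{h}$), useful in vitellogenic stages
where size alone is nutrition-limited.

Fitting is ordinary least squares on $\log(\text{value})$ versus age — a
multiplicative error model. Areas are positive and growth compounds, so
noise is naturally multiplicative; the fit is also deterministic and has a
closed form, which keeps parameter-recovery tests exact. Ages for fixed
chambers are the stage *midpoint* ages (cumulative start plus half the
stage duration) — the unbiased within-stage placement when only the stage
is known.

Age assignment for a live chamber inverts the curve at the first observed
value ($t_0 = \ln(v/A_0)/k$); later samples keep their acquisition offsets.
`align_trace(by = "auto")` aligns by oocyte percent when the first oocyte
fraction is ≥ 0.30 (the stage-8-completion benchmark) and by area
otherwise. `percent_of_expected()` then reports observed/expected size —
the standard way to quantify growth slow-down under an imaging protocol.

One coordinate decision: the two curves do not share a time origin. At the
area curve's stage-8 age the oocyte-percent curve would predict far above
1 if started at stage 2; its amplitude (0.318) instead matches the
oocyte's share at stage-8 completion, so the generator anchors the oocyte
clock there ($t_{oo} = 0$ at the end of stage 8). Ages inferred by
inverting the oocyte curve are on that clock.

## 3. 3D nuclear segmentation

The segmentation chain reproduces a classic macro pipeline, in this fixed
order: separable Gaussian blur (sigma in *pixel/slice* units, default
(5, 5, 1) — the chain operates on the grid, not in µm), a single global
Otsu threshold from a 256-bin histogram (foreground strictly above; ties
in between-class variance broken toward the lower threshold),
morphological refinement (erode, dilate, open, close, fill-holes
per-slice then in 3D, digital ball of radius 1), and 26-connected 3D
component labelling (components below 27 voxels — a 3×3×3 block —
discarded). Labelling is the one compiled step (`src/label3d.cpp`);
everything else is vectorized R.

Two invariants matter more than the individual steps:

* **Measurements come from the unprocessed stack.** Blur and morphology
  shape the label set only. Any change of processing parameters that
  leaves the label set unchanged leaves every measured total untouched.
* **The threshold is checked against an oracle.** The Otsu implementation
  is verified in the test suite against an independent exhaustive scan of
  all 255 splits of the same histogram.

A resolution limit worth knowing: with the low-tie-break rule the Otsu
threshold settles slightly below the half-maximum of a blurred object, so
masks carry a sub-voxel outward dilation (~0.15 µm under the test
conditions). The relative volume error is ≈ $3d/r$, negligible for
nurse-scale nuclei (≤ 1% at $r = 10\ \mu$m) but material for small
follicle nuclei (~10% at $r = 4\ \mu$m). Integrated intensities are immune
(the surrounding background contributes ~0), which is why intensity-based
quantities are preferred downstream.

`midsection_area()` automates the manual outline: per z-slice, the chamber
cross-section is the filled convex hull of follicle-nucleus centroids (the
follicle shell defines the boundary); the slice with maximal hull area is
the midsection. Chambers are near-convex through stage 10, where the proxy
is used. `register_translation()` aligns frames by the FFT cross-correlation
peak of maximum-intensity projections — integer-pixel, translation-only.

## 4. Region-based normalized quantification

Named regions follow the field's conventions: NCN (nurse-cell nuclei), NCC
(nurse-cell cytoplasm), AO/PO (anterior/posterior oocyte cytoplasm), and a
follicle-nucleus reference. Regional concentrations are mean raw
intensities in a square ROI (default 20 px) replicated over 3 z-slices
3 µm apart starting 9 µm below the follicle border; yolk totals sum the
oocyte mask from the top surface through the midsection (half the chamber,
because full depth is unreachable in older chambers).

Every value is normalized by the follicle statistic *of the same frame*
(total for yolk totals, mean for concentrations). Because signal and
reference share all global factors, the ratio cancels exposure changes and
photobleaching exactly — the test suite asserts invariance to arbitrary
per-frame gains at 1e-12.

ROI placement is deterministic where the original workflow was manual:
among candidate positions satisfying the region's membership and distance
constraints (nuclear-free box; NCC within 17 µm of the nurse–oocyte
interface on the nurse side; AO the same on the oocyte side; PO within
17 µm of the posterior half of the oocyte boundary), the placer takes the
candidate whose centre is farthest from any nuclear voxel, ties broken by
smallest (y, x). Infeasible constraints raise an error naming the region.
Distances are evaluated at the ROI centre; the pixel pitch comes from
stack metadata, never a hard-coded calibration.

## 5. The dumping-flux model

Histone redistribution during dumping is emulated by a linear compartment
chain

$$\mathrm{nuclei} \xrightarrow{k_1} \mathrm{NCC} \xrightarrow{k_2}
\mathrm{AO} \xrightarrow{k_3} \mathrm{PO},$$

solved exactly as $x(t) = e^{At}x(0)$ (matrix exponential), so ground
truth carries no integrator error; forward Euler is retained only as a
cross-check (and refuses $k\,\Delta t \ge 1$). With no degradation the
four totals sum to the initial nuclear total to machine precision at every
frame. Nuclear *volume* decays at an independent rate, so the
concentration total/volume can rise transiently when shrinkage outpaces
signal loss — the behaviour `nuclear_concentration_series()` quantifies.

One structural fact about this chain: the PO inflow is $k_3 \cdot
\mathrm{AO}(t)$, so the PO accumulation *rate* peaks exactly when AO
peaks, never earlier; the PO *level* keeps rising long after. The
qualitative signature asserted in tests is therefore: NCN strictly
decreasing, NCC and AO rising then falling (NCC peaking first), and the
PO series peaking later than AO's.

Default rates ($k_1 = 0.8$, $k_2 = 0.5$, $k_3 = 0.3$ h⁻¹, shrink
0.25 h⁻¹, 12 h at 0.25 h steps) were chosen once so that all of those
phases fall inside the simulated window; the acquisition noise level
defaults to 0 because no noise statistics are established for this
protocol — tests inject their own noise where a property needs it.

## 6. Follicle-cell kinematics

Egg chambers rotate about their anterior–posterior axis. For a cell
tracked in the mid-focal plane, angular displacement uses the projection
approximation $\theta = \arctan\!\big((y - y_{mid})/r\big)\cdot 180/\pi$
and angular velocity is the arithmetic mean of $\Delta\theta/\Delta t$.
The approximation is accurate near the midline and degrades toward the
chamber edge; samples with $|y - y_{mid}| > 0.9\,r$ are flagged rather
than silently used. Mean speed is arc length over time in µm/min.

The generator places cells on a circle of radius $r$ with phases centred
on zero (the small-angle regime the estimator assumes). Over a 1-h track
at 28.5°/h the estimator recovers the rate to ~3% — the residual bias is
the $\cos\phi/(1+\sin^2\phi)$ projection factor averaged over the phase
excursion, which the 5% recovery tolerance accommodates.

## What the generator does and does not emulate

The synthetic module reproduces the *statistical structure* the analysis
assumes: Poisson-count survey tables around the published colony means,
lognormal multiplicative area noise (CV is the single noise knob),
ellipsoidal chambers with voxelized spherical nuclei and a 30%-oocyte
midsection benchmark, uniform-concentration compartments driven by the
exact ODE solution, and noiseless circular tracks with optional positional
jitter. It deliberately does not model optics (no PSF, scattering, or
depth attenuation), nucleus shape variation, chamber packing deformation,
or staging error. Passing tests therefore validate the estimators against
their own model assumptions — they bound algorithmic error, not
instrument effects on real data.

Problem sizes in the shipped tests and acceptance script (phantoms of
roughly 55×110×130 voxels at 0.5–1 µm pitch, 49-frame dumping series,
500-chamber surveys) were chosen as the smallest grids on which the
geometric tolerances above are resolution-limited rather than
sampling-limited.

## Degenerate inputs and numerical choices

* Constant stacks have no Otsu threshold — error, not a guess.
* Empty follicle reference or zero reference intensity — error (the
  normalization is undefined).
* A vanished nuclear label terminates a concentration series with a flag.
* Fill-holes runs per z-slice before 3D so slab-like cavities at the stack
  boundary are still closed.
* Seeds: every generator takes an explicit seed and restores the caller's
  RNG state; identical seeds give byte-identical outputs.
* Chamber phantom packing uses greedy farthest-point placement with
  multi-restart; if the requested nurse nuclei cannot be packed at
  $2r + \mathrm{clearance}$ separation the generator errors, naming the
  constraint, rather than overlapping nuclei.

## Known limitations

* The convex-hull midsection underestimates non-convex (post-stage-10)
  chambers; the label-volume path should be preferred there.
* The compartment model is first-order and well-mixed; it reproduces
  ordering and conservation properties, not absolute transfer kinetics.
* Stage calls are inputs throughout; no image-based staging is attempted.
* Registration is integer-pixel and translational only.
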