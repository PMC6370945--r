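---
title: "Quantifying planar polarity, endosomal puncta and FRAP kinetics in mosaic wings"
author: "wingpol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying planar polarity, endosomal puncta and FRAP kinetics in mosaic wings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingpol)
```

## The biological problem

Planar cell polarity (PCP) proteins such as Flamingo (Fmi) and Strabismus
localize asymmetrically at apicolateral junctions of the pupal wing
epithelium, and their junctional levels depend on endosomal recycling.
Experiments on this system are mosaic: a clone of mutant cells (e.g. lacking
a recycling component such as Snx27 or retromer) sits inside wild-type
tissue, and every readout is a within-wing contrast — mutant versus
wild-type membrane intensity, polarity, endosomal puncta, antibody
internalization kinetics, or FRAP recovery. `wingpol` implements that whole
measurement chain on label-mask + fluorescence-stack inputs, plus a
synthetic-data generator that stands in for the raw microscopy, so each
stage can be validated against known ground truth.

## Membrane quantification and per-cell polarity

The junctional plane is taken as the pixelwise mean of the `k = 3` brightest
z slices, where brightness is the mean intensity over membrane pixels.
Selecting slices by membrane-masked brightness is a deterministic
operationalization of choosing slices "around the apicolateral junctions" by
eye; ties resolve toward the apical side, and the chosen slices need not be
consecutive.

The membrane skeleton consists of 0-label pixels with at least two distinct
cells in their 3×3 neighbourhood. Each skeleton pixel is tagged by the
genotypes of its adjacent cells; membranes on the clone border are shared
between genotypes and are counted in neither region, so region means are
computed over genotype-pure membrane only. Cells touching the image border
or an excluded region are dropped from per-cell summaries because their
boundary sampling is incomplete.

Per-cell polarity uses the *maximum asymmetry ratio*: for each candidate
axis $\theta$ on a 1° grid, boundary samples within 45° (axially) of
$\theta$ form one class and the rest the other, and
$R(\theta)$ is the ratio of mean intensities. The magnitude is
$M = \max_\theta \max(R, 1/R) \ge 1$ and the angle is the axis achieving it
(mod 180°, ties to the smallest axis). Axes whose window or complement is
empty are skipped. Whether the historical implementation weighted by edge
length or intensity sum is not documented; unweighted pixel means are used
here, and an intensity-weighted nematic order parameter
($m = |\sum I e^{2i\psi}| / \sum I$, computed over 15° $\psi$ bins)
is kept as a cross-check — the two statistics rank cells with Spearman
$\rho > 0.95$ on synthetic wings. The binning matters: on a pixelated
polygon the raw resultant is dominated by the boundary's own sampling
anisotropy rather than the signal.

Angle dispersion uses standard axial statistics: angles are doubled, the
mean resultant length $\bar R$ computed, and the spread reported as
$\tfrac12\sqrt{-2\ln\bar R}$ in degrees; $\bar R = 0$ (e.g. an antipodal
pair) is flagged as maximal dispersion rather than given a number.

Per-wing clone statistics follow the original analysis: the mutant/wild-type
ratio of mean membrane intensity is tested against 1.0 with a one-sample t
test across wings, and within-wing region contrasts use paired t tests.

## The synthetic wing and what it does (and does not) emulate

`make_lattice()` builds cells as nearest-centre regions of a jittered
hexagonal point set with a 1-px-wide membrane (a pixel is membrane where its
label differs from its left or top neighbour), and grows a contiguous mutant
clone from a central cell to the requested fraction. The row pitch is
rounded to an integer so the jitter-free lattice is exactly periodic —
interior cells are congruent, which gives clean symmetry tests — at the cost
of ~2% vertical compression relative to an ideal hexagonal packing.

`render_membrane_stack()` gives each membrane pixel the expectation
$B \, s(\text{region}) \, (1 + a\cos 2(\psi_p - \theta_{\rm true}))\,
z_{\rm profile}[z]$, where $\psi_p$ is the axial centroid-to-pixel direction
of the pixel's *owning* (nearest-centre) cell. Defaults are chosen for
realism at the imaging scale of such experiments: 100 nm pixels put a
4–5 µm wing cell at ~45 px diameter (`cell_diameter_px = 45`); amplitude
`a = 0.5` produces polarity magnitudes around 1.5–1.7, in the range seen for
core PCP stainings; and two lognormal effects (whole-wing brightness and a
per-wing relative mutant-region effect, both SD 0.15 on the log scale)
reproduce the wing-to-wing ratio dispersion such clone experiments report
(CV ≈ 0.15). The mutant clone enters only as an intensity scale and, for
puncta fields, a density/size difference — no trafficking dynamics are
simulated.

One geometric honesty note. A membrane pixel is shared by two cells, and the
two centroid-to-pixel directions are mirror images about the junction
normal, so no single rendered value can be consistent with both cells'
$\psi$ definitions at once. Together with the three-axis structure of
hexagonal boundaries this limits *per-cell* angle recovery: on noiseless
wings individual cells deviate from the injected axis by several degrees
(occasionally 15–20°, systematically pulled by the window estimator's
interaction with the edge-class structure), while the *per-wing* axial mean
is accurate to a degree or two. Tests therefore pin the wing-level estimate
(the unit of analysis in this kind of study) and treat the per-cell estimate
as an envelope, within half the 30° inter-normal spacing. Passing these
tests shows the estimator tracks the injected signal on this idealized
epithelium; real wings add segmentation error, curvature and inhomogeneous
staining that the generator does not model.

## Internalization time courses and puncta

Extracellular-label time courses are summed over each genotype's region,
laser-off background is subtracted (per pixel), and readings are divided by
the genotype's mean 0-min value, so the 0-min group mean is exactly 1 by
construction. Later chase times are compared to the 0-min control with
one-way ANOVA followed by Dunnett's many-to-one comparisons.

Intracellular puncta are detected with the area-fraction rule: the threshold
$t^\*$ is the smallest observed wild-type intensity such that the fraction
of wild-type pixels strictly above it is at most the target (1% by
default) — the $(1-\text{target})$ empirical quantile with "higher"
interpolation. With discrete intensities an exact 1% may be unattainable, so
ties resolve *downward* in area (achieved fraction ≤ target, and
> target − 1/N for continuous data). The same threshold is then applied to
the mutant region of the same wing; the API enforces this by making the
mutant path take $t^\*$ as an input. Puncta are 8-connected components above
threshold (diagonal contacts count; `min_area` defaults to 1 but 3–4 is
sensible against single-pixel noise), and per-wing mutant/wild-type ratios
of count (normalized per unit region area, since clone and wild-type regions
differ in size), mean area and mean intensity are tested against 1.0.

The 1% rule presumes the brightest percentile is dominated by puncta; in a
plane whose top percentile is mostly noise the detected "puncta" are noise
specks by construction. The generator's defaults (bright Gaussian blobs over
a dim background) respect that regime.

## FRAP preprocessing, fitting and model comparison

The acquisition protocol is fixed by the experiment: 3 pre-bleach frames at
2 frames/s, a 1 s bleach that carries no samples, then 5 frames at 5 s,
10 at 10 s and 26 at 15 s — 41 post-bleach frames with $t = 0$ at the first
and the last at 510 s. Preprocessing double-normalizes: background is
subtracted from both the bleached-region trace and an unbleached reference,
the trace is divided framewise by the reference's relative decay (the
acquisition-bleaching correction; the original method is unnamed, and a
reference-ROI double normalization is the standard choice), and finally by
the mean of its own corrected pre-bleach values — which is therefore exactly
1. Frames that drifted out of focus can be masked from fitting.

Recovery is fitted as exponential association,
$I(t) = Y_0 + \sum_i A_i(1 - e^{-k_i t})$, order 1 or 2, by multi-start
Levenberg–Marquardt over a grid of rate pairs spanning 1/500–1 s⁻¹. Rates
are constrained positive and reported with $k_1 > k_2$ (swapping components
resolves label switching); a fit with coincident rates is flagged
degenerate. Plateau and amplitudes are deliberately *unconstrained*, as in
standard curve-fitting software: the extra-sum-of-squares F test
$$F = \frac{(SS_1 - SS_2)/(p_2 - p_1)}{SS_2/(n - p_2)}$$
presumes unconstrained least squares, and a non-negativity bound active at
the boundary censors the null improvement — measured empirically, the
two-phase-vs-one-phase selection rejects a true one-phase model in ~1% of
null simulations when $A_2 \ge 0$ is enforced versus ~4–5% unconstrained.
The order-2 fit is additionally seeded with the order-1 solution so the
nested fit can never end up worse.

Genotype comparisons average traces per genotype and fit both curves
jointly: a null model sharing the selected component's parameters
(fast = $A_1,k_1$; slow = $A_2,k_2$; or all) against the fully
genotype-specific model, compared by the same F test. Because the mapping of
"first/second phase" to parameters is a modelling choice, both per-component
contrasts and the omnibus comparison are exposed rather than hard-coding
one.

## Statistical kernel

All tests report statistic, df, two-sided p and the star convention
(≤0.05 \*, ≤0.01 \*\*, ≤0.001 \*\*\*). The unpaired t defaults to the
equal-variance (Student) form, with Welch available. Normality is screened
with the D'Agostino–Pearson K² omnibus test (implemented from the published
skewness/kurtosis transformations, since no installed R package provides
it; it matches the reference implementation to 10 significant digits) and
only when $n \ge 8$ — smaller samples are reported "not-assessed" and
analyzed parametrically, matching practice for small per-wing samples. The
K² reference distribution is asymptotic and mildly anticonservative even at
n = 500, which the calibration tests acknowledge. Dunnett comparisons use
the single-step multivariate-t adjustment from **multcomp**; with a single
comparison they reduce exactly to the pooled two-sample t test.

## Numerical and design choices

* Coordinates are (row, col), z apical-first; all angles in degrees, axial
  (mod 180°). Clone rasters use 0 = excluded, 1 = wild-type, 2 = mutant.
* Intensities are doubles internally regardless of on-disk depth; 8/16-bit
  TIFFs round-trip losslessly, float stacks are stored as 32-bit scaled to
  [0, 1] with the scale in a JSON sidecar (single-precision round-trip).
* Slice-selection ties go apical; polarity-axis ties go to the smallest
  axis; threshold ties go to the smaller achieved area.
* Degenerate inputs error loudly rather than silently: zero-variance t
  tests, cells with fewer than 8 boundary samples (skipped with a warning),
  empty angular classes on every axis, references that hit background.
* Test problem sizes are chosen to exercise each property at desk scale:
  5×5–6×6-cell wings, 30-wing ratio cohorts, 200-trace FRAP recovery sets
  and 1000-rep calibration loops; the type-I bands are ±2 standard errors
  of the nominal 5%.

## Known limitations

* No segmentation: label masks are inputs (real pipelines produce them with
  a dedicated tool), and the generator's Voronoi lattice is a geometric
  surrogate, not a mechanical tissue model.
* No optics: puncta are Gaussian blobs without a PSF model; membrane signal
  has no blur, so synthetic validation does not cover deconvolution or
  bleed-through effects.
* Per-cell polarity angles on hexagonal lattices carry the systematic
  geometry bias discussed above; wing-level summaries are the reliable
  readout.
* FRAP is trace-based only; no reaction–diffusion modelling, and the
  acquisition-bleaching reference is assumed available.
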