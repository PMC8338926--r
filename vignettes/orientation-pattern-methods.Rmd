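---
title: "Quantifying retinal microvascular orientation patterns: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal microvascular orientation patterns: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octapattern)
```

## The measurement problem

En face OCTA renders retinal blood flow as a grayscale map in which vessels
appear as bright tubular ridges on a darker background. The most common
quantitative read-out, *vessel density* (the masked vessel fraction of a
region), ignores how the vasculature is organised. This package quantifies
the *orientation pattern*: at every pixel it estimates the local vessel
axis, accumulates those axes into an angular distribution per anatomical
sector of the macula, and summarises each distribution by three numbers —
preferred orientation, vessel anisotropy, and vessel area — alongside
vessel density.

## Per-pixel orientation from the Hessian

A vessel cross-section is modelled as a Gaussian profile of standard
deviation $s$: an ideal tube
$I_0(x,y) = \tfrac{1}{2\pi s^2}\exp(-x^2/2s^2)$. Its Hessian at a ridge
point is diagonal with one zero eigenvalue whose eigenvector points along
the tube: intensity curves sharply *across* a vessel and not at all *along*
it. The per-pixel vessel axis is therefore the eigenvector of the
smallest-magnitude eigenvalue $\lambda_1$ of the smoothed image Hessian
($|\lambda_1| \le |\lambda_2|$).

Derivatives are taken in Gaussian scale space: the image is convolved with
analytic second-derivative-of-Gaussian kernels at each scale $\sigma$ of a
grid, with reflect padding at the borders. From the eigenvalues two
classical measures are formed — the tubularity ratio
$R = |\lambda_1|/|\lambda_2|$ and the structure strength
$S = \sqrt{\lambda_1^2 + \lambda_2^2}$ — and combined into the vesselness
response
$$\rho = \exp\!\left(-\frac{R^2}{2\beta^2}\right)
        \left(1 - \exp\!\left(-\frac{S^2}{2\gamma^2}\right)\right),$$
zeroed where the sign of $\lambda_2$ contradicts the bright-on-dark
polarity. The per-pixel maximum of $\rho$ over the scale grid gives the
response map; the argmax scale $\sigma_0$ estimates the vessel half-width
and the orientation $\theta_0$ is read out at that scale.

### Scale normalization (and why the exponent is 1.5)

Raw Gaussian-derivative magnitudes shrink with $\sigma$, so responses must
be normalized by $\sigma^p$ before the cross-scale maximum; with $p = 0$
the smallest scale always wins. For a Gaussian ridge of width $s$, the
normalized across-ridge curvature is
$\sigma^p \, s\,(s^2+\sigma^2)^{-3/2}$ (up to amplitude), maximised at
$\sigma = s\sqrt{p/(3-p)}$. The package defaults to $p = 1.5$, the
classical ridge-detection choice, which makes the selected scale equal the
profile width ($\sigma_0 = s$) so the width read-out is direct; $p = 2$
(full second-order normalization) would shift selection to
$\sigma_0 = \sqrt{2}\,s$. The exponent is exposed as
`filter_params(scale_power=)`.

### The contrast gate $\gamma$

With `gamma = "auto"` the package uses a *single* $\gamma$ — half the
maximum Hessian Frobenius norm over all pixels and scales of the image
being filtered. A per-scale $\gamma$ would renormalise each scale by its
own maximum; since the strongest vessel pixel *is* that maximum at every
scale, its response would saturate identically everywhere on the grid and
the argmax would degenerate to the first scale. One global gate keeps the
$S$-term monotone in the scale-normalized structure strength, so the
cross-scale maximum genuinely selects width.

### Defaults

| parameter | default | meaning |
|---|---|---|
| $\sigma$ grid | 1.0–4.0 px, step 0.5 | vessel half-widths covered (at ~85 px/mm: ~12–47 µm) |
| $\beta$ | 0.5 | blob suppression |
| $\gamma$ | `"auto"` | contrast suppression, adapts per scan |
| `scale_power` | 1.5 | ridge-type scale normalization |
| truncation | $3\sigma$ | kernel support |

These are working defaults for ~6 mm / 512 px en face scans, not claimed
to match any particular instrument; all are overridable.

Orientation is undefined (and excluded from all histograms) at isotropic
pixels: $|\lambda_1| = |\lambda_2|$ or a vanishing Hessian. Angles follow
the display convention — degrees counter-clockwise from the rightward
image axis with y up — folded axially into $[0°, 180°)$. A border band of
width $\lceil 3\sigma_{max}\rceil$ px is affected by reflect padding and is
reported as `border_px` in the result.

## Vessel mask

A global Otsu threshold (256 bins, matching 8-bit export provenance)
minimises within-class intensity variance; ties resolve to the lower
threshold, and class statistics use exact per-bin intensity sums so the
chosen edge coincides with an exhaustive search over the raw values. The
default vessel mask is the *conjunction* of an Otsu mask on the raw image
and an Otsu mask on the vesselness response: the pure intensity mask admits
bright noise, the pure vesselness mask admits low-contrast ridge artifacts,
and either pure mode remains available (`mask_mode`).

## Sector geometry

The analysis region is a 5-mm disk centred on the macula (user-supplied
centre; the 6 × 6 mm scan margin is trimmed deliberately), split into eight
equal-area 45° wedges labelled NS, SN, ST, TS, TI, IT, IN, NI by the
nasal/superior/temporal/inferior axes. For a right eye the nasal axis
points to the image right and labels proceed counter-clockwise from it;
for a left eye the geometry is the exact mirror, so labels proceed
clockwise from a leftward nasal axis and the N↔T swap holds pixel for
pixel. Whether the first wedge sits counter-clockwise or clockwise of the
nasal axis is a convention the anatomy alone does not fix; the one above
is stated in every output. Wedges are half-open, assigned by pixel-centre
angle, so each disk pixel belongs to exactly one sector.

## Orientation distribution and pattern metrics

Within each sector, every masked vessel pixel with defined orientation
$\theta$ adds one count at $\theta$ and one at $\theta + 180°$ (orientation
is head–tail symmetric), over 1° bins by default, unsmoothed. The
histogram is drawn as a closed polar curve with the raw per-bin count as
radius, and summarised by:

* **vessel area** — the shoelace-formula area of the 360-vertex polygon
  (pixel², since the radius is a pixel count). Computing the polygon area
  rather than rasterising the plotted curve is deterministic and
  resolution-independent; tests pin the two to within 2 %.
* **preferred orientation** and **anisotropy** — from the second central
  moments of the filled polygon: the moment-equivalent ellipse's major-axis
  angle (folded to $[0°,180°)$) and major/minor axis ratio ($\ge 1$; 1 for
  an isotropic mesh). For a degenerate polygon (all mass on one axis) the
  ellipse collapses; preferred orientation then falls back to the axial
  circular mean and anisotropy is reported as infinite. An exactly
  isotropic distribution has no major axis and preferred orientation is
  reported as `NA`.

Vessel density is the masked fraction of the sector. Note the moment
ellipse weights the curve by $r^4$, so the anisotropy is deliberately
sensitive to concentrated orientation mass.

## Statistics

Per-sector metrics across subjects are summarised by mean, SD and range;
for preferred orientation the axial circular mean and SD
(angle-doubling statistics) are reported alongside the arithmetic ones,
which remain common in practice but mislead when values straddle the
0°/180° wrap. Group comparisons use the Mann–Whitney U test with exact
enumeration p-values for small samples (min group ≤ 8, total ≤ 25; valid
under ties via midranks) and a tie-corrected normal approximation
otherwise; associations use Pearson correlation with a t-based p-value.
No multiplicity correction is applied. Cohort modelling beyond this
(e.g. mixed-effects models over sectors) is left to downstream tools; the
frozen-schema CSV export exists for exactly that.

## Synthetic scenes and what they do (and do not) show

`scene_spec()` / `random_scene_spec()` / `render_scene()` build
OCTA-like phantoms with exact ground truth: Gaussian-profile tubes
(straight lines, finite segments, arcs, or closed loops) composited by
per-pixel maximum — a crossing is no brighter than its brightest vessel —
floored at a background level, with optional additive Gaussian noise and
clipping, all fixed by a seed. Ground truth (tangent orientation, width,
half-maximum footprint, crossing flags) is defined on the rendered
footprint; crossings, where orientation is multi-valued, are excluded from
scoring, as is a 2-px image border band.

Default geometry: a 427-px canvas at the 6 mm / 512 px pitch, i.e. the
5-mm analysis disk fills the canvas, so sector pixel counts — and hence
vessel-area magnitudes — are realistic. The `"uniform"` orientation model
draws angles by stratified sampling (one jittered angle per equal-width
stratum, permuted), so moderate tube counts already give flat axial
histograms.

The canonical isotropic ensemble uses **closed loops** of capillary-lobule
scale (radius ~80–190 µm at the standard pitch). This is a deliberate
choice: a closed loop's tangent covers every axial angle uniformly, so a
loop ensemble is isotropic in *every* subregion by construction. Straight
full-span chords are not: a chord's length inside a 45° wedge depends on
its orientation (radial chords run long), and a single straight vessel
contributes a one-bin spike that the $r^4$-weighted moment ellipse
amplifies — measured sector anisotropies reached 4 with 200 globally
uniform chords, versus 1.0–1.3 with loops.

What these phantoms do **not** emulate: OCT speckle and projection
artifacts, signal-strength gradients, capillary-network topology
(branching, perfusion), layer structure, or pathology. Passing the
synthetic suite demonstrates the estimator's geometric fidelity — it says
nothing about segmentation quality on clinical scans, which should be
validated separately.

## Numerical choices, degenerate inputs, problem sizes

* Convolutions: separable, analytic derivative kernels, reflect padding;
  the second-derivative kernel is mean-subtracted so constants are
  annihilated exactly. Kernels below $\sigma = 0.5$ px alias and are
  rejected.
* Cross-scale ties resolve to the smallest scale; a featureless image
  (structure below 10⁻⁸) returns an identically zero response rather than
  amplifying rounding noise through the adaptive $\gamma$.
* Eigen ties and zero Hessians yield `NA` orientation and are excluded
  downstream; a constant image is a degenerate-input error for Otsu; an
  empty sector∩mask intersection yields an all-zero distribution with a
  warning and `NA` metrics for that sector.
* The test suite and examples run on 96–256 px canvases for speed; the
  isotropy and end-to-end fixtures use the full 427-px geometry. A full
  427-px analysis takes on the order of a second.

## Known limitations

* Orientation is estimated at the vesselness argmax scale only; at vessel
  junctions and crossings it is single-valued by construction.
* The macula centre must be supplied for clinical images; the package does
  not locate the foveal avascular zone (a vesselness-minimum centroid can
  serve as a diagnostic starting point, not as ground truth).
* Vessel-area magnitudes depend on mask behaviour and bin width; compare
  them only within a fixed configuration.
* Full-thickness en face analysis only; no per-layer quantification, no
  tortuosity index, no registration between visits.
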