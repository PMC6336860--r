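---
title: "Quantifying giant-vesicle budding: models, parameters, and what the synthetic tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying giant-vesicle budding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesiclebud)
```

## The measurement problem

Giant unilamellar vesicles (GVs) that synthesize new membrane lipids in situ
can grow, deform into a pear shape, and pinch off a daughter vesicle. The
experimental signature that *membrane synthesis* (rather than, say, osmotic
swelling) drives this process is purely geometric: over the budding episode
the membrane **surface area grows by roughly 20% while the enclosed volume
stays constant**. Extracting that signature from phase-contrast time-lapse
movies is the job of this package.

The measurement model is deliberately minimal. A budding cross-section is
treated as **two superimposed circles** — Sec. 1, the mother body, and
Sec. 2, the bud — and the three-dimensional shape is assumed **rotationally
symmetric** about the line joining the two centers. A frame is therefore
summarized by three lengths: the section radii $r_1, r_2$ and the center
distance $d$. Everything else is derived.

## Geometry of two intersecting spheres

For $|r_1 - r_2| < d < r_1 + r_2$ the spheres intersect in a circle (the
*neck*) lying in the radical plane, at signed distance
$x_1 = (d^2 + r_1^2 - r_2^2)/(2d)$ from center 1 and $x_2 = d - x_1$ from
center 2. The derived quantities are

* neck radius $a = \sqrt{r_1^2 - x_1^2}$;
* exposed surface area $S = 2\pi r_1 (r_1 + x_1) + 2\pi r_2 (r_2 + x_2)$,
  the sum of the two spherical caps — the internal lens is not membrane, so
  it is excluded (the source study does not state this convention; the
  exposed-caps choice is the physically meaningful one after the two
  compartments fuse);
* union volume $V = \tfrac{4}{3}\pi(r_1^3 + r_2^3) - V_{\text{lens}}$ with
  the standard spherical-cap lens term;
* neck angle $\theta = 180^\circ - \varphi$, where
  $\cos\varphi = (r_1^2 + r_2^2 - d^2)/(2 r_1 r_2)$ is the angle at a neck
  point between the two radii. With this supplement convention $\theta \to
  180^\circ$ when the bud merges back into the mother and $\theta \to
  0^\circ$ as the neck pinches off, so $\theta$ decreases monotonically in
  $d$ — matching the reported anticorrelation between $\theta$ and $d$.

Degenerate configurations are handled explicitly: `contained` and
`internally_tangent` reduce to the larger sphere, `externally_tangent` and
`disjoint` to two full spheres, and class boundaries are decided within a
relative tolerance of $10^{-9}$ so that $S$ and $V$ are continuous across
them. Coincident circles ($d = 0$, $r_1 = r_2$) are a single sphere, not an
error. The closed forms are validated against an independent Monte-Carlo
rejection-sampling oracle (`monte_carlo_union_volume`) at $10^6$ points over
a grid spanning all classes.

## From image to circles

The original analysis fitted the two circles *manually* in ImageJ, five
times per frame, and averaged. This package substitutes a deterministic
automated pipeline that honors the same intent:

1. **Segmentation.** The membrane appears as a dark ring with a bright
   phase halo. After normalization and light smoothing, an Otsu threshold
   isolates the ring, the largest connected component is kept (a comparable
   second component is a hard failure — one vesicle per frame), holes are
   filled, and a marching-squares boundary of the silhouette is taken.
2. **Sub-pixel ridge refinement.** Each boundary vertex is moved onto the
   intensity minimum of the ring along the local inward normal, by an
   iterated Gaussian-weighted parabola fit to *raw pixel values* near the
   normal line. Interpolated line profiles were rejected: bilinear
   interpolation biases the valley position by up to 0.4 px in
   grid-diagonal directions. The refined contour is resampled to 1-px arc
   length and oriented counter-clockwise.
3. **Neck detection.** Curvature from 7-point Savitzky-Golay derivatives
   (after circular Gaussian pre-smoothing, $\sigma = 1.5$ points) locates
   the two deepest concavities; candidates must be more concave than
   $-1/r_\mathrm{eff}$ and separated by at least 10 points along both arcs.
   Fewer than two candidates means *pre-budding*: the frame is fit as a
   single circle and masked out of the $\theta$ and $d$ series — a signal,
   not an error.
4. **Two-circle fit.** The contour is split at the neck points, a guard
   band of 5 points around each neck point is discarded (the neck belongs
   to neither sphere), gross radial outliers of a first-pass fit are
   trimmed (ridge refinement can land on the wrong membrane where the two
   rings overlap), and each arc is fitted with a Taubin algebraic circle
   fit — exact on true circle points for any arc span $\ge 60^\circ$. The
   five-repeat manual averaging is emulated by averaging `n_repeats = 5`
   bootstrap resamples of the arc points.
5. **Focus QC.** The focus score is the mean gradient magnitude in a 3-px
   band around the contour, normalized by the frame intensity range. The
   keep threshold (default 0.11) was calibrated once on a synthetic blur
   series: sharp renders score about 0.14–0.17, defocused ones
   ($\sigma \ge 3$ px) at or below about 0.09. The original criterion was a
   human judgment call; this score is its operationalization.

Sec. 1 is the larger circle at the first budding frame; afterwards labels
follow nearest-center continuity, so a mother that shrinks below its bud
keeps its identity.

## Time series and statistics

`build_series` normalizes $S$ and $V$ to the first kept frame and both
radii to the first kept-frame mother radius (all three are exactly 1
there). Pre-budding and contained frames contribute as single spheres but
are masked in $\theta$ and $d$.

The headline comparison is a **Mann-Whitney U test** between the first and
final 15% of kept frames (the study does not define its "first and final
data sets"; 15% windows match the stable ends of the published
time-courses, and the fraction is configurable). The test is exact — full
enumeration of all $\binom{n_1+n_2}{n_1}$ labelings with midranks — for
$n_1+n_2 \le 12$, otherwise a tie-corrected normal approximation with
continuity correction. Testing is two-sided at $\alpha = 0.05$ (neither
sidedness nor level is stated in the source). The $\theta$–$d$ association
uses **Spearman** rank correlation, because only a monotone relationship is
claimed.

## The synthetic world

The generator states the world the analysis is supposed to detect, with
three imposed constraints per frame:

1. $V(t) = V_0 \cdot \mathrm{vf}^{\,t/T}$ (volume factor $\mathrm{vf} = 1$:
   conservation is *imposed*, mirroring the osmolarity argument, not
   derived from osmosis);
2. $A(t)$ ramps smoothly (smoothstep) from $A_0$ to $1.2\,A_0$ over the
   600-s episode;
3. the bud-to-mother ratio follows
   $\rho(s) = 0.3 + 0.45\cdot\mathrm{smoothstep}(s)$.

Given $(V, A, \rho)$ the configuration is recovered by 1-d root finding on
the scale-free isoperimetric ratio $A^3/(36\pi V^2)$, which runs from 1
(single sphere) to $(1+\rho^2)^3/(1+\rho^3)^2$ (two separate spheres) as
the centers separate; tolerance $10^{-13}$, so volume is conserved to
machine precision and the final relative area equals the growth factor to
$10^{-6}$.

Three generator choices deserve justification:

* **$\rho_{\max} = 0.75$.** At conserved volume the maximum relative area
  reachable with ratio $\rho$ is $((1+\rho^2)^3/(1+\rho^3)^2)^{1/3}$; at
  $\rho = 0.6$ this is 1.194 — a 1.2-fold area ramp is *infeasible*. The
  default final ratio is therefore 0.75 (bound 1.236), and infeasible
  configurations raise an error naming the first failing time.
* **$\rho_0 = 0.3 > 0$.** A ratio ramp starting at zero makes the early
  required protrusion fraction non-increasing, which forces the center
  distance to *fall* just after onset — contradicting the monotone neck
  closure the trajectory must exhibit ($d$ strictly up, $\theta$ strictly
  down, here $159^\circ \to 42^\circ$). Starting the bud at a finite,
  resolvable size matches the experimental situation: analysis begins once
  a bud is visible.
* **No terminal plateau.** On an area-and-volume plateau the solver no
  longer pins the shape, and monotonicity of $d$ and $\theta$ is not
  guaranteed; the ramp simply ends at `duration`.

Default scales: mother radius 4 µm (the analyzed mothers were 7–10 µm in
diameter), 600 s episode, 10 s frame interval, bud onset at 60 s.

The renderer mimics phase contrast to first order only: gray background
(level 180 of 255), dark ring (depth 90, Gaussian ridge profile centered
exactly on the true disc boundary), bright halo just outside (height 25 at
3 px), slightly darker interior (−10), the experimentally observed paler
bud (ring contrast attenuated 40%), additive Gaussian pixel noise
($\sigma = 3$ levels), per-frame focus jitter (blur
$\sigma \sim \mathcal{N}(0.8, 0.4)$ px, clipped to 0.3–2.5), and occasional
strongly defocused frames ($\sigma = 6$ px) for QC testing. No optics
simulation; no multi-vesicle scenes.

For the 500-seed statistical calibrations, rendering every movie would be
wasteful; `simulate_measured_series` perturbs the ground-truth lengths with
i.i.d. multiplicative Gaussian noise of 1% per frame — the stated fit-noise
world, consistent with the end-to-end scatter of the imaging pipeline at
default settings. The no-growth null is a constant single sphere: in this
shape family, budding without area growth at conserved volume is
geometrically impossible, so a constant shape is the faithful null.

## Numerical choices

* Class-boundary tolerance $10^{-9}$ relative; trajectory root-finding
  $10^{-13}$; circle-fit Newton stops at $10^{-14}$ relative.
* The Monte-Carlo oracle uses a seeded, restored RNG (it never perturbs the
  caller's stream); bootstrap repeats draw from the ambient RNG so that a
  single `set.seed` (or the CLI `--seed`) makes entire runs byte-identical.
* Ties in the U test use midranks in both the exact and approximate
  branches; the permutation distribution of $U$ is symmetric about
  $n_1 n_2/2$ even under ties, which the two-sided exact p exploits.
* Degenerate inputs are classed conditions (`vb_*`), mapped by the CLI to
  exit codes 1 (config), 2 (input), 3 (insufficient data).

## What a green test does and does not establish

The synthetic movies share the statistical *structure* the analysis
assumes: one vesicle, stationary, dark ring on gray background, noise
i.i.d. within frames, focus drift uncorrelated across frames, and shapes
drawn exactly from the two-sphere family. Real movies violate several of
these (membrane fluctuations, neighboring vesicles and debris, drift,
non-spherical mothers — which the original study excluded by hand). A green
suite therefore establishes correctness of the *computation* —
geometry, fitting, statistics — and recoverability under the stated world,
not performance on arbitrary field data.

Known limitations worth stating plainly:

* The ridge definition carries a small constant operational offset
  (~0.1 px inward at default rendering, from the asymmetric
  halo/interior profile and blur curvature). Relative series cancel its
  constant part, but as the mother/bud composition changes a residual
  drift of a few tenths of a percent survives in $V_{\text{rel}}$. With
  realistic per-frame noise this is far below the detection threshold; on
  *noiseless or near-noiseless* movies the first-vs-final volume test can
  flag that operational drift as significant. That behavior is a property
  of any sub-pixel operational boundary definition, not a bug in the
  statistics.
* Buds smaller than about 15 px radius are recovered with >1% radius error
  (short arcs, overlapping rings near the neck); the barely-emerged-bud
  regime is deliberately classified pre-budding instead.
* The movie-timing ambiguity in the source protocol means seconds-per-frame
  is always a required calibration input, never inferred.

## Reproducing the analysis

```{r, eval = FALSE}
library(vesiclebud)

movie <- render_movie(sim_config(seed = 1), render_config(),
                      out_dir = "movie")
res <- cmd_analyze(analysis_config(
  input = "movie/frames.tif", out_dir = "out",
  subsample = 1, um_per_px = 0.2, s_per_frame = 10, seed = 1))
res$stats$S_rel$verdict   # "distinguishable"
res$stats$V_rel$verdict   # "indistinguishable"
res$stats$theta_d_spearman  # ~ -0.99
cmd_evaluate("movie/truth.csv", "out")
```

These are the same calls the test suite and `scripts/acceptance.R` make;
the vignette states no number the tests do not themselves compute.
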