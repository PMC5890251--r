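---
title: "Measuring epithelial-mesenchymal border tortuosity with a local-global active contour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring epithelial-mesenchymal border tortuosity with a local-global active contour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

During feather branching, the basal keratinocytes of the follicle epithelium
lose the dense fringe of filopodia (thin protrusions, roughly 2-10 um long,
3-5 per cell) that they extend into the mesenchyme before branching. The
package quantifies the geometric consequence of that change in 2-D sections:
the epithelial-mesenchymal (E-M) border is segmented, traced as a calibrated
polyline, and summarized by its tortuosity

\[
\lambda / d,
\]

the arc length of the border divided by the straight-line distance between
its endpoints. A filopodia-fringed border has a much larger \(\lambda/d\)
than a smooth post-branch border, so the statistic is a 2-D proxy for the
epithelial surface area available before and after branching. Because the
border is irregular at the scale of the protrusions, \(\lambda\) is
scale-dependent — the classical coastline effect — which is why the pixel
calibration of every measurement is part of the result, not a nuisance
detail.

`emtort` implements the complete chain: a synthetic phantom generator with
analytically known border geometry, the segmentation model, subpixel border
extraction, the tortuosity statistic, and the two-group comparison. The
workflow scripts under `analysis/` run the chain end to end on the default
synthetic dataset.

## Segmentation model

Given an image \(I : \Omega \to \mathbb{R}\) and a level-set function
\(\phi\) whose zero level set is the evolving curve, the segmentation
minimizes

\[
\begin{aligned}
F(\phi, c_1, c_2, f_1, f_2)
= {} & \lambda_1 \int |I - c_1|^2 H(\phi)\,dx
 + \lambda_2 \int |I - c_2|^2 (1 - H(\phi))\,dx \\
 & + \eta_1 \iint K_\sigma(x - y)\, |I(y) - f_1(x)|^2 H(\phi(y))\,dy\,dx \\
 & + \eta_2 \iint K_\sigma(x - y)\, |I(y) - f_2(x)|^2 (1 - H(\phi(y)))\,dy\,dx \\
 & + \nu \int \delta(\phi)\, |\nabla \phi|\,dx,
\end{aligned}
\]

a hybrid of the Chan-Vese piecewise-constant model (global means \(c_1,
c_2\)) and local binary fitting (kernel-weighted local fits \(f_1(x),
f_2(x)\) under a Gaussian \(K_\sigma\)), with a length penalty weighted
\(\nu\). The Heaviside and Dirac factors are regularized as

\[
H_\varepsilon(x) = \tfrac12\left(1 + \tfrac{2}{\pi}
  \arctan\tfrac{x}{\varepsilon}\right),
\qquad
\delta_\varepsilon(x) = \frac{1}{\pi}\,
  \frac{\varepsilon}{\varepsilon^2 + x^2} .
\]

Minimization alternates closed-form coefficient updates — \(c_{1,2}\) are
the \(H_\varepsilon\)-weighted phase means, \(f_{1,2}\) are ratios of
Gaussian convolutions — with fixed-step gradient descent
\(\phi_{k+1} = \phi_k - \alpha \nabla_\phi F(\phi_k)\).

### The gradient is the exact discrete gradient

The package differentiates the *discretized* energy exactly, rather than
discretizing the continuum Euler-Lagrange expression. Concretely, the
length-term gradient contains both \(\delta_\varepsilon'(\phi)|\nabla\phi|\)
and the exact adjoint of the replicate-padded central-difference operators
(which equals minus the central divergence at interior pixels). The two
forms agree in the continuum limit, but only the exact discrete form matches
central finite differences of the implemented energy to rounding accuracy —
and that finite-difference agreement is enforced by the test suite on random
instances, which pins the whole implementation: any inconsistency between
the coded energy and the coded gradient fails the oracle.

Two published inconsistencies in this model family had to be resolved: the
weight symbols attached to the global and local terms are sometimes swapped
between the energy and its printed gradient, and the divergence term
sometimes carries an undefined edge-indicator function \(g\). The package
treats the energy as authoritative, derives the gradient from it
self-consistently, and takes \(g \equiv 1\) (pure length regularization,
matching the \(\nu\) term).

### Numerical choices

* Integrals are plain pixel sums; \(\sigma\) and \(\varepsilon\) are in
  pixel units (\(\varepsilon = 1\) against a binary-step initialization of
  amplitude 2).
* All convolutions (local fits, local data terms) use zero padding, so the
  double integral over \(\Omega \times \Omega\) is computed exactly as
  written and stays consistent with the analytic gradient; replicate
  padding would let boundary pixels enter the sums with inflated
  multiplicity. Finite differences of \(\phi\) use replicate padding.
* The local-term kernel integrals are evaluated by expanding
  \(|I(y)-f(x)|^2\) into three convolutions per phase (`K*1`, `K*f`,
  `K*f^2`), shared between the energy and the gradient; a literal
  double-loop evaluation is kept in the test suite as the oracle.
* \(|\nabla\phi|\) is floored at \(10^{-10}\) in the length-term
  denominator; local-fit denominators are floored at \(10^{-8}\) of the
  kernel mass with the global mean as fallback.
* The Gaussian kernel is truncated at \(4\sigma\) and renormalized to unit
  sum; the separable convolution is implemented in compiled code (the
  padding contract above is load-bearing for the oracles, so the
  convolution is part of the package rather than delegated).

### Step length, stopping, and the Heaviside tails

With intensities on \([0, 1]\) the data-term scale is \(10^{-2}\) to
\(10^{-1}\), so useful step lengths are of order 10; the default is
\(\alpha = 20\), and the descent property (monotone energy trace) is
verified in the tests at small \(\alpha\), where gradient descent is
guaranteed to descend.

The arctan-regularized Heaviside has algebraic tails: as \(|\phi|\) grows,
\(H_\varepsilon\) keeps saturating and the energy keeps creeping downward
(relative changes of a few \(10^{-5}\) per iteration) long after the zero
level set has stopped moving. A pure energy-change criterion therefore
rarely fires at practical tolerances. The evolution consequently stops on
either of two signals: relative energy change below `tol` for `tol_window`
consecutive iterations, or an *interface-stationarity* rule — no pixel of
\(\phi\) changes sign for `stable_window` (default 30) consecutive
iterations, after at least `min_iter` (default 50) iterations. The guard
exists because sign flips are rare events early in a run (the descent must
first drain \(|\phi|\) in a misclassified region before any pixel flips).

The optional per-iteration Gaussian smoothing of \(\phi\) (a common
stabilizer for local-fitting level sets) is **off** by default: on phantoms
it progressively erases protrusions a few pixels wide — precisely the
structures this package exists to measure — while the plain iteration is
stable at the default step length and resolves them exactly (Dice 1.000 on
noiseless phantoms).

### Default weights, and what the local terms can and cannot do

The defaults are local-dominant: \(\lambda_1 = \lambda_2 = 0.05\),
\(\eta_1 = \eta_2 = 1\), \(\nu = 0.1\), \(\sigma = 3\) px. In micrographs
with intensity inhomogeneity the two tissues are separable locally but not
globally, so the local fitting terms carry the evidence; the weak global
terms act only as a prior against degenerate labelings. The length weight
\(\nu = 0.1\) is large enough to remove isolated noise speckles (for which
the local data terms are neutral, since both local fits adapt to the local
mean) yet small enough to preserve 5-px-wide filopodia, whose long straight
sides carry no curvature penalty.

A property worth stating plainly, because the package's own experiments
demonstrate it: *local fitting does not rescue a bad initialization.* A
misclassified region that is locally consistent — for example the far wedge
that global thresholding produces under a strong linear bias field — is a
stable configuration for the local terms too, because \(f_1, f_2\) adapt to
whatever is currently labeled; no step length or kernel width escapes it.
The local terms' genuine advantage appears when the contour starts near the
true border: they then lock it in place under bias fields that pull the
global model away. The documented protocol for inhomogeneous images is
therefore a border-proximal initialization (`init = "rect"` with an
approximate user box, the same requirement stated in the local-binary-
fitting literature), while clean two-phase images can use the automatic
Otsu initialization. The bias-field validation in the test suite encodes
exactly this contrast: the global-only model in its automatic configuration
fails (Dice < 0.9), the full model under the documented protocol reaches
Dice >= 0.95 on the same image — and the suite does *not* claim the full
model fixes a threshold initialization, because it does not.

## Border extraction and the tortuosity statistic

The zero level set of the converged \(\phi\) is traced by marching squares
with linear interpolation (via `grDevices::contourLines`), yielding
subpixel vertices that are scaled to micrometers using the image-style
coordinate convention (origin top-left, x rightward, y downward, pixel
(i, j) centered at \(((j-0.5)p, (i-0.5)p)\) for pixel size \(p\)). When
only a binary mask is available, the contour is traced on the signed
distance transform instead (distance to background minus distance to
foreground), which places the border midway between opposite-phase pixel
centers rather than on pixel edges and removes most of the staircase bias
in \(\lambda\).

Contour pieces are clipped to the region of interest; among the pieces, the
longest open piece connecting the two designated ROI sides (left and right
by default, matching a border that spans the field of view) is *the*
border. \(\lambda\) is its polygonal arc length, \(d\) the distance between
its two ROI-edge endpoints — the simplest reading of "linear distance",
stated here so users can align alternative protocols. Group comparison uses
a two-tailed two-sample t-test (pooled variance by default, Welch
optional), with the percent decrease defined on group means,
\(100 (\bar r_\text{pre} - \bar r_\text{post}) / \bar r_\text{pre}\);
printed group means of 11 and 6 give 45.5%, the arithmetic behind a rounded
"about 50%" decrease.

## The phantom generator

No micrographs are distributed with the package, so validation runs on
two-phase phantoms whose border geometry is known in closed form. The
ground truth *is* a polyline: \(\lambda\) is its exact polygonal arc
length, computed from the generating geometry, never re-measured off the
raster.

* **Pre-branch** phantoms fringe a flat baseline with triangular filopodia.
  Lengths are uniform on 2-10 um (the published morphometric range). The
  linear density is drawn per phantom from 0.6-1.0 per um, which encodes
  3-5 filopodia per basal cell with a cell width of ~5 um — an assumption,
  since published morphometry reports per-cell counts, not cell widths;
  5 um (basal keratinocytes are 5-10 um wide) reproduces the reported
  pre-branch tortuosity regime (\(\lambda/d \approx 7\)-13, mean ~10),
  whereas a 10 um cell width would cap \(\lambda/d\) near 7. The base
  width is 1.0 um: at the default calibration of 0.2 um/px that is 5 px,
  comfortably above the 3 px floor below which the rasterized protrusion
  tips fall below the sampling limit.
* **Post-branch** phantoms carry a few deep rounded lobes (branch
  cross-sections: vertical walls joined by a semicircular tip, depth 22-38
  um, width 10 um), giving \(\lambda/d \approx 4\)-6.5. Shallow
  semicircular scalloping is available as a shape option but cannot exceed
  \(\lambda/d = \pi/2\), so it is not the default.
* Protrusion bases are placed by an exact uniform hard-rod model (no
  overlap, no rejection sampling); infeasible densities raise an error
  naming the maximum feasible density.
* Rasterization assigns each pixel the intensity of the phase containing
  its center, then adds an optional smooth bias field (linear gradient, or
  a quadratic ridge peaking at mid-height — the shape used to exercise the
  local fitting terms) and seeded Gaussian noise (default sd 0.05), clipped
  to \([0, 1]\).
* `ratio_phantom_spec()` builds calibration phantoms whose \(\lambda/d\)
  equals a prescribed target exactly: evenly spaced identical
  capsule-shaped protrusions with the depth solved in closed form. The
  capsule shape is deliberate — its smallest boundary feature is the tip
  radius (1.5 um, 7.5 px at the default calibration), so the recovery
  study measures the pipeline rather than the raster. Sharp triangular
  calibration teeth would instead be dominated by subpixel tip loss
  (measured at 12-16% of \(\lambda\) at high targets with *perfect*
  segmentation), which is informative about the sampling limit but not
  about the measurement chain.

Everything is seeded: identical (spec, seed) pairs are bit-identical, and
dataset seeds derive deterministically from one master seed.

What the phantoms do not emulate: real histology texture (nuclei,
cytoplasm granularity), multi-layer epithelium, TEM-scale membrane detail,
section-preparation artifacts, or borders that fold back on themselves
(profiles are single-valued in x except for the lobes' vertical walls).
Passing tests therefore demonstrate correctness of the geometry, the
optimization and the measurement chain under controlled conditions — not
performance on stained sections, where staining variability and
out-of-plane structure add error sources the generator does not model.

## Accuracy, resolution, and problem sizes

Measured \(\lambda/d\) is limited by rasterization, not segmentation: on
noiseless defaults the segmentation reproduces the mask exactly (Dice
1.000) while the measured ratio still underestimates the analytic truth by
several percent, because the subpixel protrusion tips simply are not in the
raster. The recovery error shrinks as the grid is refined; the resolution
study (`analysis/04_resolution_study.R`, and the corresponding acceptance
checks) quantifies the mean absolute relative error at 0.2 and 0.1 um/px
across targets \(\lambda/d \in \{2, 4.5, 8, 12, 16\}\). Mean error is the
monotonicity metric: at the finest grid the per-target errors reach the
sub-percent level where per-item ordering is numerical noise.

The shipped problem sizes — 40 x 60 um phantoms at 0.2 um/px (200 x 300
px), n = 10 per group, 200-iteration caps — were chosen so the full
simulate-segment-measure-compare cycle and the whole validation suite run
in minutes on a single core while keeping every protrusion at least 5 px
wide; they are package defaults, not scientific constants, and scale up
cleanly.

## Known limitations

* \(\lambda/d\) is measured per image and compared with a plain two-sample
  t-test; no nesting of sections within follicles is modeled.
* The energy is nonconvex; all claims are initialization-dependent, as
  discussed above.
* The model is two-phase and 2-D by design; multi-region or 3-D
  segmentation is out of scope.
* The arctan Heaviside couples every pixel to the contour with algebraic
  weight; runs that need a strictly compact update band should use a
  different regularization family, which this package deliberately does not
  implement because the energy above is the model under study.
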