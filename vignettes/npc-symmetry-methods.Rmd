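---
title: "Quantifying NPC eightfold symmetry from SMLM localizations: methods and design"
author: "npcfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying NPC eightfold symmetry from SMLM localizations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npcfold)
```

## The problem

Single-molecule localization microscopy (SMLM) resolves the nuclear pore
complex (NPC) as a ring of localization clusters. In a top view of the
nuclear envelope, a nucleoporin of the Y-complex (Nup96, Nup133) labels the
eight corners of the cytoplasmic and nuclear rings; in a cross-section
("side view") the two rings appear as two axially separated bands. Because
labeling is incomplete and fluorophores blink, a single imaged pore shows
only a subset of its corners, each as a small cloud of localizations.
`npcfold` implements the particle-based analysis that turns such data into
per-pore statistics:

1. **Particle extraction** — all localizations within 130 nm of a picked
   center form one particle, re-expressed relative to that center.
2. **Rotational alignment** — particles are iteratively registered to a
   pooled template, with a random multiple-of-45° rotation applied to every
   particle after each iteration so the template's residual asymmetries
   cannot imprint a preferred corner on partially labeled pores.
3. **Symmetry statistic** — aligned events are converted to polar
   coordinates, gated to radii 50–70 nm, pooled into an angular histogram,
   and fitted with a sine of period $\pi/4$:
   $I(\theta) = A + B\,\sin(8\theta + \varphi)$.
   The eight minima of the fitted sine cut the circle into eight sectors.
   For each pore, a sector is *occupied* when its localization count
   strictly exceeds half the pore's mean count per sector; the **subunit
   count** is the number of occupied sectors (0–8).
4. **Profiles** — radial distributions of the fused "superparticle"
   (counts per annulus area), and axial side-view profiles fitted with a
   sum of two Gaussians whose separation estimates the inter-ring distance
   and whose midpoint anchors per-particle axial alignment.
5. **Density** — NPC centers per unit area of a polygonal region of
   interest (shoelace area, boundary-inclusive counting).

All coordinates are nanometers throughout.

## The synthetic generator

The paper-scale analysis runs on microscope data that a desk-scale package
cannot reproduce, so every stage here is verified against a generative
model with full ground truth ([`NPCModel()`], [`simulateParticle()`]):

* eight corner sites on a ring (default radius 60 nm, the midpoint of the
  50–70 nm analysis annulus), each carrying `copiesPerCorner` fluorophore
  sites (default 4);
* independent Bernoulli labeling per site (default efficiency 0.6, a
  typical effective value for SNAP/HaloTag-labeled Nup reference
  standards);
* per labeled site a geometric number of localizations on $\{1,2,\dots\}$
  (default mean 3) — the simplest one-parameter heavy-tailed blink law;
* isotropic Gaussian localization error (default $\sigma_{xy}$ = 5 nm
  lateral, $\sigma_z$ = 10 nm axial);
* uniform Poisson background on the 130-nm picking disc (default
  10 events/µm²), so simulation and particle extraction compose;
* side views place each site on the nuclear or cytoplasmic ring
  ($z = \mp$ `ringSeparation`/2, default 50 nm apart).

The generator does **not** emulate camera noise, PSF shape, drift,
multi-emitter fitting artifacts, or chromatic effects; passing tests
therefore demonstrate correctness of the analysis on idealized
localizations, not robustness to raw-data pathologies. Upstream
corrections (drift, spectral unmixing) are out of scope and assumed done.

The analytic companion [`theoreticalSubunitDistribution()`] gives the
exact expectation for the recovery experiments: with per-site labeling
$p$ and $c$ copies per corner, a corner is detectable with
$q = 1-(1-p)^c$ and the subunit count of an ideal pore is
$\mathrm{Binomial}(8, q)$.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| pick radius | 130 | nm | canonical picking radius around each NPC center |
| analysis annulus | 50–70 | nm | brackets the Y-complex ring; rejects central channel and far background |
| symmetry fold | 8 | — | sine period $\pi/4$ |
| rotation grid | 1 | deg | registration resolution; error ≤ grid/2 |
| angular bin | 2 | deg | histogram resolution for template and sine fit |
| convergence tol | 0.5 | deg | mean absolute non-symmetry update per iteration |
| max iterations | 20 | — | alignment cap; cohorts converge in ~3–5 |
| render pixel size | 15 / 5 | nm | single-color / multicolor 2D histograms |

## Numerical and convention choices

These conventions are unstated in the method's verbal description; they
are fixed here and asserted by tests:

* **Annulus gate closed on both ends** (`50 ≤ r ≤ 70`); **pick disc
  closed** (`d ≤ 130`); **sector intervals half-open**, the opening edge
  included, the wraparound sector closing the circle; **histogram pixels
  half-open** with origin at the extent's lower-left corner.
* **Occupancy ties are unoccupied**: "higher than half of the mean" is
  implemented strictly, so a count exactly at threshold does not count.
  An all-zero pore scores 0 subunits (threshold 0, strict comparison).
* **Sine fit in closed form.** With the frequency fixed at 8, least
  squares over $(A, B, \varphi)$ linearizes to
  $A + C\sin 8\theta + D\cos 8\theta$; $B = \sqrt{C^2+D^2} \ge 0$ is a
  phase convention, not a constraint, and the fit is the exact global
  minimizer (tested against a dense brute-force phase grid). The sine is
  fitted once on the pooled cohort histogram and its edges applied to
  every pore; a zero-amplitude fit has no minima and falls back to edges
  at $k\pi/4$ with a warning.
* **Angular binning divides 360°, not 45°.** Sector counts are computed
  from raw event angles, never from histogram bins, so bins need not tile
  sectors; requiring only that bins tile the circle keeps the familiar 2°
  default. (A divides-45 rule would exclude 2°, since 45/2 is not an
  integer.)
* **Registration uses linear (cloud-in-cell) binning plus linear
  interpolation.** Templates are built by splitting each event's weight
  between the two nearest bin centers and are evaluated by circular
  linear interpolation. The resulting cross-correlation kernel is
  symmetric about zero lag, so rotation estimates carry no binning bias
  and are accurate to the rotation grid (±0.5° at the 1° default), not to
  the bin width. Ties in the grid search break to the smallest
  non-negative angle.
* **Template initialization from pooled unaligned data**: rotationally
  blurred but unbiased; single-particle seeding was rejected as
  seed-dependent. Reported rotations are reduced modulo 45° because
  rotations differing by a symmetry multiple are observationally
  equivalent for the eightfold reference channel; the coimaged-channel
  transform uses the same reduced rotations, keeping the two channels'
  common frame consistent.
* **Recentering** uses the algebraic (Kåsa) least-squares circle fit by
  default — the annulus gate is center-sensitive and NPC particles are
  ring-shaped; degenerate geometry (fewer than 3 events, collinear
  events) falls back to the centroid with a warning. Events pushed
  outside the pick radius by the shift are dropped and counted.
* **Two-Gaussian fits** run Levenberg–Marquardt from a peak-pair
  initializer (two most separated local maxima ≥ 20% of the peak), with a
  one-sided-moments fallback when that initializer is degenerate; means
  are ordered on output and fits whose means collapse within one bin are
  flagged as single-mode. Side-view orientation (which ring is "up") is
  symmetric in the generator; axis flips are exposed as a hook
  (`flipFun`) for data with a genuinely asymmetric reference channel.
* **Seeding**: every stochastic stage draws from its own stream whose
  seed derives deterministically from a master seed and a fixed label
  ([`deriveSeed()`]), so adding a stage never perturbs another; the
  random 45° draws use a dedicated stream so they can be disabled for
  ablation without changing anything else.

## The alignment engine is a deliberate substitution

The original workflow registers particles with an all-to-all GPU particle
fusion engine. That tool's published interface, not its internal
mathematics, defines the method, and an all-to-all registration is far
beyond desk scale. `npcfold` therefore uses iterative template alignment
— circular cross-correlation of annulus-gated angular histograms,
rotation-only after recentering — while retaining the defining
anti-bias step: the per-iteration random $n\cdot45°$ rotation of every
particle, $n \in [0,7]$. Translation is handled once, by recentering
before alignment; the annulus statistic tolerates a few nm of residual
centering error at the default binning. No scale, mirror, or 3D search is
performed.

## Recovery experiments and their conditions

The packaged tests and `scripts/acceptance.R` recompute, at these sizes:

* **Perfect-labeling recovery** (n = 500 pores, full pipeline from random
  phases): labeling 1, one copy per corner, one localization per site,
  $\sigma_{xy}$ = 2 nm, no background — the regime in which the occupancy
  rule must score 8/8 on every pore.
* **Binomial recovery ladder** (n = 2000 per labeling, p = 0.3–0.9):
  particles are generated in the common frame (fixed phase) and scored by
  the symmetry module. This isolates the statistic: a pore with ~2.4
  labeled corners carries no alignable eightfold signal on its own, so
  the alignment path is validated separately on fully labeled cohorts.
  One localization per site keeps the threshold rule exact — with
  geometric blinking, a corner that blinks once while others blink often
  falls below the half-mean threshold, which is a real property of the
  statistic rather than a recovery failure.
* **Rotation coherence** (n = 100 noiseless pores): circular SD of
  aligned phase residuals, modulo 45°.
* **Axial separation** (20 seeds × 30 side-view pores, separation 50 nm,
  $\sigma_z$ = 5 nm): per-particle two-Gaussian fits, midpoint alignment,
  fit of the averaged profile.
* **Density recovery** (200 replicates at 10 µm⁻² on a 10 µm² ROI), plus
  a deterministic 100-centers case that must return exactly 10.0.

These sizes keep the whole suite within a couple of minutes on one core
while leaving the statistical checks well-powered.

## Known limitations

* The alignment template method can lock onto a local optimum for very
  sparse particles; such pores still contribute events but their
  individual rotations are noisy. The paper-scale all-to-all fusion is
  not reproduced.
* The occupancy statistic conflates labeling efficiency with blink-count
  dispersion (see above); cohort-level interpretation requires the
  generative context.
* No statistical comparison between cohorts (t-tests across conditions)
  is provided; the package stops at per-cohort distributions.
* The manual "in focus, top view" particle selection of real workflows
  has no quantitative counterpart here; an eccentricity-style filter can
  be layered on `minTotal`, which only gates total gated counts.

## A worked example

```{r example, eval = FALSE}
model <- NPCModel(labelingEfficiency = 1, copiesPerCorner = 1,
                  blinksMean = 1, locPrecisionXY = 2, backgroundDensity = 0)
cohort <- simulateCohort(model, 100, phasePolicy = "random", seed = 1)
# lay particles out on a grid, as if picked from one cell
centers <- cbind(((seq_len(100) - 1) %% 10) * 1000,
                 ((seq_len(100) - 1) %/% 10) * 1000)
evs <- do.call(rbind, lapply(seq_len(100), function(i) {
  ev <- eventData(cohort[[i]]$table)
  ev$x <- ev$x + centers[i, 1]; ev$y <- ev$y + centers[i, 2]; ev
}))
tab <- LocalizationTable(x = evs$x, y = evs$y)
res <- runSymmetryAnalysis(tab, centers)
res$summary$distribution
res$sineFit
```
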