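# npcfold

Particle-based analysis of nuclear pore complex (NPC) eightfold symmetry in
single-molecule localization microscopy (SMLM) data, written for
microscopists and image analysts who quantify nucleoporin organization from
localization tables rather than raw camera frames.

## What it computes

An SMLM image of the nuclear envelope shows each NPC as a ring of
localization clusters. Because labeling is incomplete, a single pore shows
only some of its eight corners. `npcfold` quantifies that per-pore
completeness:

1. **Extract** the localizations within 130 nm of each picked center, and
   refine the center with a least-squares circle fit.
2. **Align** all particles rotationally to a pooled template, applying a
   random n·45° rotation (n = 0..7) to every particle after each iteration
   so the template cannot bias partially labeled pores toward its own
   residual asymmetries.
3. **Score symmetry**: convert aligned events to polar coordinates, keep
   radii 50–70 nm, fit the pooled angle histogram with
   I(θ) = A + B·sin(8θ + φ) (period π/4, frequency fixed), cut the circle
   into eight sectors at the sine minima, and call a sector *occupied* when
   its count strictly exceeds half that pore's mean count per sector. The
   **subunit count** of a pore is its number of occupied sectors (0–8).
4. **Profiles and density**: radial distributions of the fused
   superparticle (counts per annulus area); axial "side view" profiles
   fitted with a sum of two Gaussians whose separation estimates the
   inter-ring distance; NPC surface density inside a polygonal ROI.

A synthetic NPC generator (Bernoulli labeling per fluorophore site,
geometric blink counts, Gaussian localization error, Poisson background)
with full ground truth backs every stage, including the closed-form oracle:
with per-site labeling p and c copies per corner, an ideal pore's subunit
count is Binomial(8, q), q = 1 − (1 − p)^c.

## Worked example

Simulate 100 pores under the default model (60 nm ring, 4 copies per
corner, 60% labeling, mean 3 blinks, σ_xy = 5 nm, 10 background events/µm²),
lay them out like picks from one cell, and run the full pipeline:

```r
library(npcfold)
model <- NPCModel()  # defaults as above
cohort <- simulateCohort(model, 100, phasePolicy = "random", seed = 1)
centers <- cbind(((seq_len(100) - 1) %% 10) * 1000,
                 ((seq_len(100) - 1) %/% 10) * 1000)
evs <- do.call(rbind, lapply(seq_len(100), function(i) {
  ev <- eventData(cohort[[i]]$table)
  ev$x <- ev$x + centers[i, 1]; ev$y <- ev$y + centers[i, 2]; ev
}))
tab <- LocalizationTable(x = evs$x, y = evs$y)
res <- runSymmetryAnalysis(tab, centers)
res$alignment
#> AlignmentResult: 100 particles, 5860 events fused
#>   3 iteration(s), converged: TRUE; 0 particle(s) flagged
res$sineFit
#> SineFit (period pi/4): I(theta) = 30.556 + 46.763 * sin(8*theta + 0.9406), rss 5.523e+04
round(res$summary$distribution, 2)
#>    0    1    2    3    4    5    6    7    8
#> 0.00 0.00 0.00 0.01 0.04 0.23 0.35 0.27 0.10
```

Reading the output: alignment converged in 3 iterations and pooled all
5860 events; the strong sine modulation (B ≈ 1.5·A) confirms a coherent
eightfold pattern in the pooled histogram; and the subunit-count
distribution peaks at 6–7 of 8 corners. With 60% labeling of 4 copies a
corner is detectable with probability q = 1 − 0.4⁴ ≈ 0.97 (ideal mean
7.8 subunits); the measured mean of ~6.1 is lower because geometric blink
dispersion and background push weak corners below the strict half-mean
occupancy threshold — the statistic's real behavior, quantifiable here
because the generator provides ground truth.

File-based equivalents (`cmdSimulate`, `cmdSymmetry`, `cmdProfile`,
`cmdDensity`) run the same stages from a YAML config and write per-NPC
tables, cohort summaries, JSON-lines logs and the resolved config;
`inst/scripts/npcfold.R` wraps them for the shell.

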