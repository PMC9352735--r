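---
title: "Decoding curvilinear self-motion from spiral-space MSTd populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding curvilinear self-motion from spiral-space MSTd populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spiralpath)
```

## The scientific problem

An observer travelling along a circular path experiences optic flow that
mixes a translational component (expansion away from the heading) with a
rotational component (the view sweeping as the path curves). Three
parameters describe this situation: the path curvature $\kappa = 1/r$, the
path sign (clockwise or counterclockwise seen from above), and the gaze
offset — a fixed yaw of the eye relative to the instantaneous path tangent.
Neurons in primate area MSTd are tuned to large-field flow patterns on the
radial–spiral–concentric continuum ("spiral space"), and this package asks,
computationally, whether a population of such units carries enough
information to read those three parameters back out with simple linear
decoders — and whether units tuned to radial expansion alone suffice.

`spiralpath` implements the whole chain: a self-motion flow simulator, a
template-matching MT → MSTd population model with recurrent dynamics, lasso
decoders for gaze offset and curvature plus a linear SVM for path sign, and
the model-comparison machinery (sub-population decoders, AIC, bootstrap
error bars, regression-weight tuning summaries).

## Flow simulation

`simulate_flow()` renders 10-frame, 64 × 64 sequences through a pinhole
camera with a 90° × 90° field of view, 1.61 m above a 2000-dot ground plane
(or inside a 2000-dot 3D cloud), translating at 3 m/s along a circular path.
Image position is expressed through the tangent mapping of the field of
view, and the per-dot motion is the exact first-order rigid-motion flow
(translation plus yaw rotation), converted to angular velocity in deg/s.
Conventions: positive $u$ rightward, positive $v$ upward, positive yaw
rightward, so a clockwise path has yaw rate $+v/r$. The gaze offset is a
constant yaw of the camera relative to the path tangent, so the rotational
flow equals the path's yaw rate regardless of gaze.

Choices the simulation fixes that its sources leave open:

* **Frame timing.** Frames are 1/30 s apart; flow is instantaneous angular
  velocity rather than inter-frame displacement. Only relative dynamics
  matter downstream because the neural model is driven per frame.
* **Rasterization.** Each dot writes its flow vector to the nearest pixel;
  when two dots collide the nearer one wins; dotless pixels carry zero flow
  and are masked out. This preserves the sparse dot structure the MT stage
  expects instead of interpolating a dense field.
* **Dot replacement.** Dots leaving the field of view or the 1–50 m depth
  range are redrawn uniformly from the visible region, keeping dot density
  stationary and the visible count exactly 2000.
* **Test-set mirroring.** The test design samples clockwise trials (radii
  from a Gaussian-kernel density estimate of the training radii, Silverman
  bandwidth, 0.1 m granularity; gaze uniform on ±35°) and adds mirror
  trials with flipped sign and negated gaze. Dot placement in the mirror
  trials is independent; only the path parameters mirror.
* **Training grid.** Nine gaze offsets evenly partition ±35° (step 8.75°),
  crossed with the 50-radius geometric ladder `generate_radii()` and both
  signs: exactly 900 trials.

The flow equations are verified against a finite-difference oracle (project
the dot at $t \pm \delta$, difference the angular positions), an exact
mirror-symmetry identity, and the straight-path limit.

## The MT stage

Each of the 64 × 64 pixels hosts 24 direction channels × 5 speed channels.
Speed tuning is log-normal (Table parameters: bandwidth $\sigma_v \sim
N(1.16, 0.5)$ truncated positive, offset $s_0 \sim \mathrm{Exp}(0.25$
deg/s$)$, preferred speeds uniform within five octave-spaced bins from 0.5
to 32 deg/s); direction tuning is von Mises with shape $\eta = 3$. The net
input is the product of the two curves; empty pixels drive nothing.
Activation follows the shunting leaky integrator $\dot m = -m + (1 - m)I$
and the output is scaled by a depressing synaptic efficacy $h$ with
$\dot h = \tau(1 - h(1 + \kappa h))$, $\tau = 0.1$, $\kappa = 10$, which
compresses sustained signals toward $h^* m^*$.

Numerical choices: forward Euler with $dt = 0.1$ model-time units and 10
steps per video frame, state starting at $m = 0$, $h = 1$. Because the
input is constant within a frame, the package advances the (affine) Euler
recurrence in closed form — bit-for-bit the same iterate, an order of
magnitude faster. Since the efficacy dynamics are autonomous and all
synapses start fresh, $h$ is tracked as a single scalar. Speed parameters
are drawn per (position, speed channel) and shared across the 24 direction
channels at a site, keeping direction channels comparable. The von Mises
shape $\eta = 3$ gives a 79.5° full width at half maximum (sometimes
described as approximating 90°); the formula is implemented as specified.

## The MSTd stage

The template bank spans a closed ring of 84 patterns: four arms of 21
spiralities ($\lambda \in \{0, 0.05, \ldots, 1\}$) covering CCW and CW
full-field spirals and CW and CCW lower hemi-field ("ground flow")
spirals, each replicated over a 16 × 16 grid of preferred centers of motion
(CoM) — 21,504 units. A template's preferred flow at pixel $(x, y)$ with
CoM $(i, j)$ blends radial and circular fields:
$(1-\lambda)\,(x-i,\, y-j) + \lambda\zeta\,(y-j,\, -(x-i))$, with
$\zeta = \pm 1$ the rotation sign. Hemi-field templates are blind above
their CoM. Note that radial ($\lambda = 0$) and concentric
($\lambda = 1$) patterns each appear once per arm, so the ring joins
smoothly; the radial-only decoding population is defined as one full-field
radial pattern's 256 units.

Each template receives 200 sparse MT connections: locations drawn uniformly
from the template's valid region, direction channels drawn uniformly from
the 24. A connection contributes only when its sampled direction falls in
the 15°-wide bin of the template's flow angle at that location
(the only reading of the bin inequality that partitions the circle); its
weight decays with squared CoM distance at rate $10^{-3}$/pixel² and is
normalized by the connection count and the pooled-cell count $64^2$. At
each sampled site the MT output is divided by the maximum across direction
channels (sites with no dot contribute zero), equalizing dominant motions
across the field before CoM weighting. Hemi-field templates whose CoM sits
near the bottom of the grid have fewer valid pixels than connections and
are sampled with replacement, keeping the normalization uniform.

Three layers then process the matched input: Layer 1a averages it in time
(shunting integrator); Layer 1b pools over neighboring CoMs (truncated 2D
Gaussian, $\sigma = 5$ grid units, radius 4, renormalized to unit mass at
every position so constant fields pass unchanged) and around the pattern
ring (wrapped 1D Gaussian, $\sigma = 1.5$, radius 3); a per-pattern
adaptive threshold subtracts the integrated CoM-mean, and Layer 2 is a
recurrent competitive field with transfer function $f(w) = w^2$, decay 10,
and excitatory bound 3. The decoders read the 21,504 Layer-2 activations at
the end of frame 10.

Two points where the implementation had to resolve its sources:

* **Layer-2 discrepancy term.** The excitatory/inhibitory normalization
  terms are built from the rectified discrepancy between feedforward input
  and activation. Written as $\max(z - I, 0)$ the layer provably never
  leaves the silent state (every excitatory term vanishes at rest), so the
  package uses $\max(I - z, 0)$: units are fed in proportion to their unmet
  input and inhibited by the unmet input of units tuned to other patterns,
  which is what lets the layer approximately conserve total activation.
* **Contrast enhancement is mild.** With decay 10 and bound 3 the
  quadratic feedback is a small perturbation: integrating a two-unit system
  with 2:1 inputs gives a steady activation ratio of 1.997 — ordering
  preserved, no winner-take-all sharpening. The tests freeze this computed
  value rather than a nominal claim.

## Decoding and evaluation

Gaze offset (degrees) and path curvature (1/m, unsigned — the sign is a
separate read-out) are decoded by lasso regressions: predictors are
standardized internally for the regularization path, folds are stratified
by path sign and radius quantile under a fixed seed, and the selected
penalty is the largest whose five-fold CV error is within one standard
error of the minimum (the conventional sparsest-within-1-SE reading). Path
sign is a linear SVM. Sub-population decoders restrict the eligible units:
radial only (256), concentric only ($|\lambda| = 1$), and thirds of the
strictly intermediate spiralities — equal-width bands $(0, 1/3]$,
$(1/3, 2/3]$, $(2/3, 1)$, pooling CW with CCW by $|\lambda|$. The
support-limited full model is capped at the radial-only support and selects
the densest admissible point of the path, so it genuinely carries the same
number of free parameters as the reference rather than re-sparsifying
below it.

Accuracy is summarized by the mean absolute error, and curvature error
additionally as the path error: the difference in visual angle between the
true and decoded circular paths at 10 m, $\theta = \pm \arcsin(d\kappa/2)$
(checked against a numeric circle-intersection oracle). Decoded curvatures
tighter than the 10 m chord are reported at the limiting 90° angle. Model
comparison uses the Gaussian least-squares AIC, $n \log(\mathrm{RSS}/n) +
2k$ with $k$ the support plus intercept, on the training residuals; error
bars come from refitting on 50 bootstrap resamples of the training set and
recomputing the test MAE. Tuning summaries report each $|\lambda|$ group's
share of the total absolute regression weight and histogram the included
units' CoM eccentricity in three concentric square bands of the 16 × 16
grid (center 4 × 4, middle ring to 10 × 10, outer ring) — the band edges
are a reporting choice, since no canonical partition of the visual field
exists at this grid size.

## Problem sizes and what the tests show

`run_full_experiment()` defaults to the reference configuration (900 / 500
trials, 200 connections per template); that run takes hours on one CPU. The
test suite and `scripts/acceptance.R` exercise the identical code path at a
reduced size chosen for desk-scale verification — 90 training and 50 test
trials with 50 connections per template — where the qualitative
model-comparison pattern (full-population decoders beating radial-only on
both targets, on path error, on sign classification, and with a far smaller
selected fraction of units) is reproduced. Two fine-grained reference
properties do not survive this reduction: with only a few dozen nonzero
weights split across 21 spirality groups the weight-share histogram is
dominated by selection noise (so concentric units are not reliably the
single largest group), and with a radial-only support of ~2 units the
support-limited model is too constrained to sit strictly between radial and
full for gaze. These appear in the acceptance suite as failing expectations
by design; `scripts/full_reproduction.R` runs the full configuration for
readers with the compute budget.

The synthetic data are noiseless rigid-motion flow over idealized dot
scenes: no luminance front end, no motion-energy extraction, no eye
movements or efference copy, no binocular disparity, no independently
moving objects. Passing tests therefore certify the encoder–decoder chain
and its comparisons on the simulated conditions, not performance on natural
video.

## Known limitations

* The MSTd net input's direction sampling keeps, in expectation, 1/24 of
  the drawn connections (those whose random direction matches the template
  bin); this follows the sparse-connectivity recipe as specified, and at
  small connection counts it is the dominant noise source in unit tuning.
* The per-pattern adaptive threshold and the layer-wide activation
  conservation make absolute Layer-2 activations very small; decoding is
  scale-free, but anyone exporting activations should not interpret the
  absolute magnitudes.
* The 3D-cloud comparison selects test trials near 43 m and 107 m radii
  and ≥ 180 m; at reduced test-set sizes some groups can be empty and are
  then omitted from the report.
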