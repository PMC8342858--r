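---
title: "Modelling glutamate escape in sphere-packed neuropil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling glutamate escape in sphere-packed neuropil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuropilsim)
```

## The question

Excitatory synapses are often wrapped by perisynaptic astrocyte processes
whose membranes are dense with high-affinity glutamate transporters
(GLT-1). Two very different mechanisms could keep synaptically released
glutamate from acting at a distance: *geometric hindrance* — narrow,
tortuous extracellular gaps slow diffusion — and *surface binding* —
transporter-bearing membranes capture molecules that touch them. This
package implements a Brownian-dynamics Monte Carlo model that lets the two
be compared quantitatively in the same synthetic tissue.

The tissue model is deliberately minimal: a 3 µm cube of neuropil is
filled with randomly positioned, randomly sized, *overlapping* spheres
representing cellular elements. Overlap produces irregular concave and
convex surfaces and blind diffusion pockets, which regular lattices lack.
The complementary space — the pores between spheres — is the extracellular
space, with porosity $\alpha$ (extracellular volume fraction; about 0.2 in
adult brain) and occupied fraction $\beta = 1 - \alpha$.

## The medium generator

`generate_medium(beta_target, ...)` samples sphere centroids uniformly
over the arena cube and diameters uniformly over 20–100 nm, the scale of
fine neurites and astroglial processes. The initial count comes from the
Poisson coverage relation $\beta = 1 - e^{-n\bar v/V}$ (with $\bar v$ the
mean sphere volume); because spheres protruding through the arena faces
lose part of their volume to the outside, the achieved $\beta$ — always
measured empirically, by scattering $10^5$ uniform test points and
counting those inside any sphere — can differ from this estimate, so the
fill is repeated with the count adjusted proportionally to the remaining
relative error until the estimate is within 5 % relative of the target
(at most 50 passes, then an explicit failure). Raising the test-point
count to $10^6$ moves the estimate by well under 1 % relative, so the 5 %
band is a property of the packing, not the estimator.

Two regions are kept clear of sphere material: the coordinate origin (the
release site) and, when configured, a cylindrical synaptic cleft (default
320 nm wide, 20 nm high, axis $+z$) centred on the origin. Both are
enforced by rejecting candidate spheres during sampling rather than by
deleting spheres afterwards, which would bias the packing low near the
target; `insert_cleft()` additionally removes any intersecting sphere, so
either construction order gives a clean cleft. The cleft's two discs
represent the pre- and postsynaptic membranes: they reflect particles and
never bind them (the model assumes receptor numbers inside the cleft are
negligible relative to the released molecules), while the lateral rim is
open.

Collision queries run against a uniform-grid cell list. Each sphere is
registered in every grid cell its bounding box — inflated by the capture
shell — touches, so classifying a particle endpoint needs only the
spheres listed in the endpoint's own cell. A 50 nm cell edge (half the
largest sphere diameter) balances list length against cell count; the
query semantics are independent of this constant, and tests verify exact
agreement with brute-force scans over all spheres.

## The stepping rule

Particles perform independent Brownian steps. Over a time step
$\Delta t$, each coordinate moves by $s\,\delta\,\Delta_{1D}$ where
$\delta \sim U(-1, 1)$ independently per axis and per step,
$\Delta_{1D} = \sqrt{2 D \Delta t}$ is the elementary rms displacement of
the Einstein relation, and $D = 0.65\ \mu m^2/ms$ is the measured
glutamate diffusion coefficient in interstitial fluid. Two choices of the
scale factor $s$ are provided:

* `step_rule = "literal"` uses $s = 2$, which makes the *average* step
  magnitude equal $\Delta_{1D}$ per axis but gives a per-axis variance of
  $\tfrac{4}{3}\,(2 D \Delta t)$, i.e. an effective diffusion coefficient
  of $\tfrac{4}{3} D \approx 0.867\ \mu m^2/ms$;
* `step_rule = "calibrated"` (the default) uses $s = \sqrt 3$, so the
  per-axis step variance is exactly $2 D \Delta t$ and the
  MSD-measured coefficient equals the nominal $D$.

The calibrated rule is the default because the effective $D$ is meant to
be verified against the nominal value at regular intervals; the literal
rule is retained for comparison, and `measure_effective_D()` distinguishes
the two to within a few percent. Uniform (rather than Gaussian)
increments converge to the same diffusion limit over the $\sim 10^4$ steps
of a run and bound the maximum single-step displacement, which matters for
the tunnelling argument below.

`choose_timestep()` returns the largest $\Delta t \le 10^{-4}$ ms such
that the maximum elementary displacement $2\Delta_{1D}$ does not exceed
half the smallest obstacle feature (smallest sphere diameter or cleft
height). With 20 nm minimum spheres and $D = 0.65$ this gives
$\Delta t \approx 1.9\times10^{-5}$ ms, i.e. about 52 000 steps per
millisecond, and guarantees a particle cannot pass through the smallest
sphere in one step.

## Surface interactions

A candidate endpoint is classified against the obstacles:

* **Capture.** If the endpoint lies within the ±3 nm *catchment shell* of
  a sphere surface (a thickness comparable to $\Delta_{1D}$, representing
  the reach of membrane transporters), a Bernoulli draw with probability
  `p_bind` decides permanent capture; a captured particle is projected
  onto the nearest point of that sphere and never moves again. Permanence
  is the right approximation on this time scale: transporter unbinding
  and translocation are orders of magnitude slower than the < 1 ms
  diffusion window.
* **Elastic collision.** Without capture, a move whose endpoint
  penetrates a sphere deeper than the shell — or penetrates at all —
  is cancelled and the displacement redrawn, up to 10 times, after which
  the particle rests for that step. Redraw (rather than specular
  reflection) is the natural companion of an isotropic displacement
  vector and avoids numerical deadlocks in the blind pockets that
  overlapping spheres create. An endpoint in the outer half of the shell
  that fails the capture draw is a legitimate free position and is kept:
  otherwise the shell would act as a 3 nm repulsive skin on every sphere
  and add spurious hindrance at `p_bind = 0`, where the model must reduce
  to purely geometric obstruction.
* **Cleft discs** always reflect (path-crossing test, since the discs are
  infinitely thin) and never capture.
* **Arena faces** reflect by folding (default) or absorb and count the
  particle as escaped (`boundary_mode = "absorb-count"`). The boundary
  condition mostly affects histogram tails at late times; the absorb
  mode quantifies that sensitivity.

`p_bind` encodes the astroglial fraction of all membrane surfaces: 0.3
for cerebellar molecular layer, 0.13 for hippocampal CA1, 1 for a
hypothetical fully transporter-coated medium. The default
(`binding_mode = "per-encounter"`) draws the Bernoulli independently at
every encounter, treating the glial/non-glial identity of each membrane
patch as arbitrary; `binding_mode = "per-sphere"` instead labels a
fraction `p_bind` of whole spheres as astroglial at run start (those
capture with probability 1, the rest never). The two interpretations
bracket the anatomical truth — patches smaller than, or as large as,
whole cellular elements — and can be compared directly.

## Observables

* `histogram_scatter()` bins all non-escaped particles (free plus bound,
  as a saturating optical sensor would see them) along one axis, 60 bins
  across the arena (50 nm bins).
* `fit_gaussian_sigma()` fits $A\,e^{-x^2/2\sigma^2}$ to the counts by
  unweighted least squares (Levenberg–Marquardt; optional Poisson
  weights) and reports the dispersion $\sigma$; if the optimiser fails or
  fewer than five bins are occupied it falls back to the count-weighted
  sample standard deviation and clears `fit_ok`. In dense media the true
  profile is visibly skewed by obstacle aggregates; $\sigma$ is then a
  summary of spread, not a claim of normality.
* `capture_statistics()` reports where bound molecules were captured,
  under two metrics: distance from the origin, and distance beyond the
  cleft edge. The second is the meaningful "distance from the synapse"
  when a cleft is present, because the transporter-free cleft spans
  160 nm laterally and no capture can occur closer to the origin than
  that. "The bulk" is summarised by the median, with 75/90/95 %
  quantiles alongside.
* `measure_effective_D()` regresses the free-particle MSD on $6t$.
  Verification runs use an empty arena and restrict the regression to
  $t \le 0.2$ ms: the centre-to-boundary characteristic time is
  $r^2/6D \approx 0.58$ ms, and including later samples under reflecting
  boundaries biases the slope low by roughly 10 %.

## Choices where the design was open

* **Fitted $\sigma$ at late times in open media.** By 1 ms the free
  dispersion $\sqrt{2Dt} \approx 1.14\ \mu m$ is comparable to the 1.5 µm
  half-width, so the 1 ms histogram in an $\alpha = 0.7$ medium is
  boundary-flattened and its fitted $\sigma$ overstates the spread. The
  hindrance comparison between porosities is therefore best read at the
  0.1 ms checkpoint, and the package's own acceptance test does so; the
  1 ms values are still reported.
* **$\sigma$ is fitted to the 1D marginal histogram of the x axis**, as
  the histograms are drawn; radial averaging would mix the cleft axis
  into the lateral spread.
* **Seeds.** A scenario takes one integer seed; the medium uses it
  directly and the dynamics use `seed + 1000003`, so a single integer
  reproduces a whole realisation bit for bit. Single realisations (not
  seed averages) are the primary output, since an "average synapse
  geometry" smooths away exactly the outlier architecture of interest;
  averaging across seeds is still used where a scalar with Monte Carlo
  error is wanted.
* **Problem sizes.** Unit tests run reduced arenas (1.5 µm cubes) and
  short windows (tens of µs), which leave every invariant intact;
  full-scale checks (3 µm, 2000 particles, 1 ms, ≥ 3 seeds) live in the
  acceptance test file and the acceptance script.

## What the generator does and does not emulate

The synthetic medium reproduces the volume fraction, the 20–100 nm
feature scale, and the irregular connectivity of neuropil, including
diffusion dead-ends. It does not reproduce sheet-like astroglial
lamellae, aligned axon bundles, or any specific reconstructed geometry;
obstacles are isotropic spheres, and transporter surfaces are either
scattered uniformly (per-encounter) or attached to whole sphere-shaped
elements (per-sphere). Consequently, passing tests show that *given* a
brain-like porosity and astroglial surface fraction, binding dominates
escape control; they do not certify escape profiles for any particular
reconstructed synapse. Receptor binding inside the cleft, transporter
unbinding and translocation, repetitive release, and electrodiffusion are
all outside the model's scope.

## A worked micro-example

```{r example}
cl <- cleft()
m <- insert_cleft(generate_medium(0.8, arena_half_width = 0.75, seed = 1,
                                  cleft = cl), cl)
m

cfg <- simulation_config(n_particles = 500, t_total = 0.1,
                         checkpoint_times = c(0.05, 0.1), p_bind = 0.3,
                         seed = 2)
run <- run_simulation(cfg, m)
summarize_run(run)
capture_statistics(run)
```

The table shows the immobilisation typical of brain-like conditions: the
bound fraction saturates within a fraction of the run, and captures
cluster within tens of nanometres of the cleft edge, long before the
molecules could sample the rest of the arena.
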