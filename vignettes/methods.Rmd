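---
title: "Methods: models, parameters and design choices in pengwinter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in pengwinter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pengwinter)
```

# Scope

`pengwinter` analyses satellite telemetry of wide-ranging marine predators
during the non-breeding season: Argos fix quality control, state-space
smoothing with multiple track imputation, hexagonal habitat-utilization
distributions (HUD) and overlap indices, migration-strategy
classification, environmental covariate extraction, and an isocline-based
habitat-area index. This vignette documents the models, the parameters
that matter, the numerical choices, and what the synthetic validation
does and does not demonstrate.

# The movement model

## Continuous-time correlated random walk

Each axis of the working plane carries an Ornstein–Uhlenbeck velocity
process: `dv = -beta v dt + sigma dW`, integrated to position. The two
parameters are

* `beta` (1/day) — the rate at which velocity decorrelates. `1/beta` is
  the persistence time of directed movement; the default optimizer start
  of 1/day corresponds to day-scale persistence, typical of swimming
  seabirds.
* `sigma` (km/day^1.5) — velocity volatility. The stationary per-axis
  speed scale is `sigma / sqrt(2 beta)`; e.g. `beta = 1`, `sigma = 30`
  gives ~21 km/day per axis, i.e. a few tenths of m/s sustained.

The axes share `(beta, sigma)` (isotropic movement) and are independent
given the parameters, so the likelihood separates per axis. The exact
Gaussian transition over an arbitrary gap is used throughout — the model
is continuous-time, so irregular Argos sampling needs no interpolation.

Observations are fix positions with isotropic Gaussian error whose
standard deviation depends on the Argos location class; the defaults
(km) are `3: 0.25, 2: 0.5, 1: 1.5, 0: 5, A: 5, B: 10`, a
literature-typical scale for these quality codes. Argos services do not
publish a single error model, so the sds are configurable, and
`fit_ctcrw(fit_error_scale = TRUE)` can estimate a common multiplier;
the default keeps the class sds fixed, which is the usual practice when
ellipse information is only used for screening.

## Initialization and fitting

The state at the first fix time is initialized at the fix with its class
variance for position and a diffuse (1e6 km²/day²) variance for velocity,
and the first fix is then assimilated like any other observation. The
likelihood is maximized over `log(beta)`, `log(sigma)` by BFGS from a
moment-based start and one jittered restart; non-convergence after both
flags the fit and the deployment is excluded downstream with a recorded
reason. Fitting uses only the fix times; the smoother afterwards runs on
the union of fix times and the regular output clock.

## Numerical choices

* **Working plane.** All state-space math, hexagonal grids and areas live
  in a south-polar Lambert azimuthal equal-area projection (sphere radius
  6371 km, central meridian 60°W). Winter tracks here span 170°W–25°W;
  a polar equal-area plane has no dateline seam and makes planar areas
  true spherical areas. Lon/lat appears only at I/O boundaries.
* **Transition coefficients** use `expm1` and switch to the series
  `sigma² (Δ³/3 − βΔ⁴/4)` for the position innovation variance when
  `βΔ < 1e-4`, where the closed form cancels catastrophically.
* **Covariance updates** use the Joseph form and explicit symmetric
  storage `(p11, p12, p22)`, so filter and smoother covariances stay
  symmetric positive semi-definite; smoother gains invert 2×2 predicted
  covariances with a 1e-12 ridge guard against degenerate (near-zero
  process noise) cases.
* **Imputation** draws whole tracks jointly by simulation smoothing
  (simulate an unconditional state path and observations, smooth them,
  and add the simulated smoothing error to the real smoothed mean) —
  draws are samples of the joint smoothing law, not independent per-time
  noise. Draws are seeded per deployment by hashing the deployment id
  into the run seed, so results do not depend on processing order.

# Quality control

Three filters, applied in order per deployment:

1. drop class-`Z` fixes and fixes with unspecified error ellipses
   (missing or non-positive semi-major axis; the predicate is
   configurable);
2. a recursive forward speed filter at 2.5 m/s: walking forward from the
   release site (a trusted anchor with its release time), a fix is
   dropped when the great-circle speed from the last retained fix exceeds
   the bound. The threshold is inclusive, removal is deterministic, and
   re-filtering a filtered track changes nothing (idempotence). The
   choice of the anchored forward scheme is a design decision: it is
   deterministic, order-independent at ties, and matches the "constant
   swim speed" framing; whether the original analyses trusted the release
   site as anchor is not documented, so the anchor (and its time) are
   explicit arguments.
3. retain deployments whose span from first to last remaining fix is at
   least 7 days. Duration is measured first-fix-to-last-fix (the span of
   location estimates), not release-to-last-fix.

Great-circle distances use the haversine formula with radius 6371 km
everywhere in the package.

# HUD, overlap, classification

* **Hexagons** are flat-top, anchored at the projection origin, with
  25-km centroid spacing; every cell has exact area √3/2·25² =
  541.266 km². Points map to cells by exact axial (cube) rounding —
  equivalent to nearest-centroid with a deterministic boundary rule.
* **Occupancy is binary per individual**: a bird is present in a
  (month, cell) if any of its 100 imputed positions falls there; visit
  weights are retained but do not enter the overlap index. Inter-colony
  overlap requires ≥ 2 distinct colonies in a cell; intra-colony overlap
  requires ≥ 2 distinct individuals of the colony — a bird co-occurring
  with itself across draws is never overlap.
* **Classification**: a track is `local` when its whole smoothed mean
  path stays within 500 km of the tagging site; otherwise the sign of the
  dateline-unwrapped net longitudinal displacement at the time of maximum
  distance decides east vs west, falling back to the final displacement
  when that is exactly zero. Distances are evaluated on the smoothed mean
  path — the natural deterministic per-deployment summary; per-draw
  variants are possible but non-normative.
* **Swim speeds**: monthly net displacement over elapsed time inside
  closed calendar-month windows, averaged with weights equal to days
  tracked per month; the maximum daily speed uses single-day net
  displacements over 86400 s. Months (or days) with fewer than two
  positions are excluded.

# Environmental fields and habitat area

Gridded fields are regular lon/lat rasters with **cell-center
registration** (the first center half a step inside the extent), the
convention of the satellite products this emulates; nearest-cell lookup
serves along-track matching, and hexagon means average the grid centers
falling inside each cell (with a flagged nearest-center fallback for
hexagons smaller than a grid cell).

The two-part monthly habitat index is: open water = {SST ≤ 2 °C} ∩
{SIC < 5 %}, and marginal ice zone = {5 % ≤ SIC ≤ 50 %}, both restricted
to 180°W–0°W and land-clipped. The SST bound is inclusive and the
open-water SIC bound exclusive so the two parts partition cleanly and can
never intersect. Isoclines are extracted as marching-squares contour
lines and closed against the domain boundary into oriented region
polygons (region interior on the left; holes clockwise). Region
intersections are contoured from the pointwise maximum of the signed
level-set fields — equivalent to polygon intersection up to sub-cell
interpolation — and land differencing clips region rings against the
convex components of the land mask (Sutherland–Hodgman), which is why the
synthetic mask emits convex polygons. Areas are signed shoelace sums of
densified rings projected into the equal-area plane. A rasterized
cell-count evaluation (`method = "raster"`), with exact spherical lon/lat
cell areas, serves as the independent cross-check; its discretization
error scales with the cell-to-band-width ratio, which motivates the
synthetic grid's 0.05° latitude step (≈ 5.6 km) — fine enough that the
narrowest seasonal band (~2.9° of latitude) is resolved to well under the
2 % agreement the validation asserts.

For ice residence, a fix "in ice" has matched daily SIC ≥ 5 % — the MIZ
outer limit used elsewhere in the index; the threshold is configurable
since the original choice is not documented. Each fix owns the interval
to the next fix.

# The synthetic data generator

The generator defines the study conditions and is itself tested code:

* **Deployments**: three colonies at the real tagging coordinates
  (Admiralty Bay 58.469°W 62.236°S, Cape Shirreff 60.789°W 62.460°S,
  Cierva Cove 60.984°W 64.143°S); the study-shaped fixture deploys
  40 adults and 10 juveniles split 10/20/20, with transmission lifetimes
  drawn per colony/stage/behaviour group from the reported duration
  ranges and short (3–5 day) lifetimes for the non-viable deployments, so
  the 7-day filter retains exactly 34 adults and 7 juveniles. Behaviour
  composition matches the reported pattern: no eastbound Cierva Cove
  birds, no westbound juveniles.
* **Movement**: local birds follow the CTCRW plus position mean-reversion
  toward the colony (rate 0.1/day; the stationary spread then has the
  closed form `sigma² / (2 a b (a+b))` per axis, ≈ 43 km at defaults —
  comfortably inside the 500-km local radius, and consistent with
  reported local maximum distances of tens to a few hundred km).
  Migrants follow the CTCRW in a front-following frame with a constant
  along-front drift (default 25 km/day ≈ 0.29 m/s, the scale of reported
  migrant net speeds) along a latitude-constant synthetic SACCF at 62°S,
  with cross-front mean-reversion (0.05/day). All integration uses the
  exact discretization of the coupled linear system (matrix exponential
  in closed form), not Euler steps.
* **Observation**: fixes occur only in the 12:00–18:00 UTC duty window,
  Poisson-many per day (mean 6, matching the reported ~6/day), at
  positions linearly interpolated on the 2-h truth clock, with isotropic
  class errors; class-Z fixes are grossly corrupted (≥ 500 km) and a
  3 % fraction of fixes lack ellipse fields. Timestamps are whole
  seconds, as Argos reports them.
* **Environment**: SST is linear in latitude (0.32 °C/deg, −3.5 °C at
  75°S) with a ±0.8 °C seasonal cycle peaking in February; SIC is a
  logistic front of width 1.5° whose 50 % isocline rides
  `−68 + 5 cos(2π(m − 9)/12)` degrees, advancing north from March to a
  September maximum; bathymetry has a −400 m shelf band at colony
  latitudes inside a −4000 m basin; zonal currents are a Gaussian ACC jet.
  Daily fields add a field-wide AR(1) perturbation (φ = 0.8, sd 1 % SIC)
  to the month's field, clipped to [0, 100], keeping daily and monthly
  fields consistent by construction. All parameters are carried on the
  grid-set object so tests can invert isocline positions in closed form.

**What this does not emulate**: real Argos error is elliptical and
autocorrelated with satellite-pass geometry; real ice edges and fronts
meander zonally; coastlines are not convex rectangles; tag failure can
correlate with behaviour. Passing the validation therefore demonstrates
the correctness of the algorithms under known conditions — filters,
likelihoods, smoothers, geometry and indices do what they claim — not
that the biological quantities of any real system are reproduced.
Headline biological results (overlap percentages, in-ice SIC means,
distance/speed tables, habitat-area series) depend on the real telemetry
and satellite products and are out of desk-scale reach by design.

# Validation problem sizes

The test suite runs the pipeline at sizes chosen to exercise every code
path while keeping the default run in minutes: 50 replicate 200-day
tracks for parameter recovery (median |relative error| of both CTCRW
parameters < 15 %), 2000 smoothing draws at a node against the analytic
smoother variance (±10 %), 200 simulated tracks per behaviour for
classification (zero east/west confusion, ≥ 95 % local recall, including
an antimeridian-crossing westbound case), the 50-deployment fixture for
retention accounting (34 adults + 7 juveniles = 41 retained; 15 % adult
and 30 % juvenile removal), ≤ 4-fix instances for exact
Kalman-vs-joint-Gaussian equivalence (1e-8 relative), and multi-month
polygon-vs-raster habitat-area comparisons (2 %). End-to-end pipeline
tests run a 4-deployment subset with 4 imputation draws; the API defaults
remain the study values (100 draws, all deployments).

# Known limitations

* The speed filter is the anchored recursive forward scheme; other
  published variants (backward passes, RMS multi-point tests) would
  retain slightly different fix sets.
* The polygon habitat-area route requires convex land-mask components;
  non-convex masks need either pre-decomposition or the raster method.
* Hexagon covariate means are center-in-cell, not area-weighted — a
  deliberate simplification given 541 km² cells over ≤ 0.5° grids.
* `error_scale` is a single shared multiplier; per-class error estimation
  is not attempted.
* Monthly overlap treats a track as present in every month it spans; very
  short month fragments therefore count as full presence, as in the
  binary-occupancy convention.
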