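# pengwinter

Winter-migration analysis for satellite-tracked penguins (and other
wide-ranging marine predators). The package implements, as reusable and
tested R functions, the full analysis chain used to study how chinstrap
penguins (*Pygoscelis antarctica*) from Antarctic Peninsula colonies
disperse across the Southern Ocean outside the breeding season:

1. **Track quality control** — screening raw Argos fixes by location class
   (drop `Z`) and unspecified error ellipses, a conservative constant-speed
   filter (2.5 m/s, McConnell-style recursive forward pass anchored at the
   release site), and retention of deployments with at least 7 days of
   locations.
2. **State-space smoothing and multiple imputation** — a continuous-time
   correlated random walk (CTCRW) fitted per deployment by maximum
   likelihood, smoothed to a 2-h clock, and used to draw 100 alternative
   tracks from the joint smoothing distribution so location uncertainty
   propagates into every downstream map and index.
3. **Habitat-utilization distributions (HUD)** — imputed positions pooled
   onto an equal-area hexagonal grid with 25-km centroid spacing
   (cell area √3/2 · 25² ≈ 541 km²), monthly, with inter- and
   intra-colony overlap indices (area where ≥ 2 individuals co-occur over
   total occupied area).
4. **Migration classification** — local / east / west bins from the
   500-km radius rule and the dateline-safe net direction of travel, plus
   deployment summaries (duration, maximum great-circle distance,
   month-weighted net swim speeds).
5. **Environmental context** — per-hexagon means and along-track daily
   matching of SST, sea-ice concentration (SIC), bathymetry and surface
   currents; ice-residence fractions; and a two-part monthly habitat-area
   index: open water between the 2 °C isotherm and the 5 % SIC isocline,
   and the marginal ice zone (5–50 % SIC), as land-clipped isocline
   polygons measured in an equal-area plane.

A synthetic-data module generates study-shaped telemetry (duty-cycled
12:00–18:00 UTC Argos sampling with class-dependent error, three colonies,
local/east/west behaviours) and analytic environmental fields (logistic
sea-ice front, latitude-linear SST with a seasonal cycle), so the entire
pipeline runs, and is validated, without any external data product.

## The model at the core

Per axis of the working plane (a south-polar Lambert azimuthal equal-area
projection, km), the CTCRW state is position–velocity $(p, v)$ with
Ornstein–Uhlenbeck velocity:

$$dv = -\beta\, v\, dt + \sigma\, dW, \qquad dp = v\, dt$$

with exact discretization over a gap $\Delta$:

$$v' = e^{-\beta\Delta} v + \varepsilon_v,\quad
p' = p + \tfrac{1-e^{-\beta\Delta}}{\beta} v + \varepsilon_p,$$

$$\operatorname{Var}(\varepsilon_p) = \tfrac{\sigma^2}{\beta^2}\left(
\Delta - \tfrac{2(1-e^{-\beta\Delta})}{\beta} +
\tfrac{1-e^{-2\beta\Delta}}{2\beta}\right),\quad
\operatorname{Var}(\varepsilon_v) = \tfrac{\sigma^2(1-e^{-2\beta\Delta})}{2\beta},\quad
\operatorname{Cov} = \tfrac{\sigma^2(1-e^{-\beta\Delta})^2}{2\beta^2}.$$

Argos fixes observe $p$ with class-dependent Gaussian error. `fit_ctcrw()`
maximizes the exact Kalman-filter likelihood over $(\log\beta, \log\sigma)$
and returns a classed object with `print`, `summary`, `coef`, `logLik`,
`predict` (RTS-smoothed 2-h path), `residuals` (standardized innovations)
and `simulate` (joint smoothing-distribution draws via simulation
smoothing) methods.

## Worked example

```r
library(pengwinter)

cfg <- sim_config(seed = 42)
dep <- list(deployment_id = "cs-01", colony = "Cape Shirreff",
            lon = -60.789, lat = -62.46,
            release_time = as.POSIXct("2017-02-19", tz = "UTC"),
            duration_days = 120)

track <- simulate_true_track(dep, "west", cfg)    # truth, 2-h clock
fixes <- observe_argos(track, cfg)                # duty-cycled Argos fixes
clean <- speed_filter(filter_quality(fixes), vmax = 2.5,
                      anchor = c(dep$lon, dep$lat),
                      anchor_time = dep$release_time)
nrow(fixes); nrow(clean)
#> [1] 696
#> [1] 401

fit <- fit_ctcrw(clean, release_time = dep$release_time)
fit
#> Continuous-time correlated random walk fit
#>   deployment: cs-01  (401 fixes, 119.7 days)
#>   beta  = 0.5567 1/day
#>   sigma = 26.07 km/day^1.5
#>   log-likelihood: -2499.71   converged: TRUE

imp  <- impute_tracks(fit, n_draws = 100, seed = 7)
path <- predict(fit)
max_distance(path, c(dep$lon, dep$lat))           # 2604 km from the colony
classify_migration(path, c(dep$lon, dep$lat))     # "west"
swim_speeds(path)$mean_daily                      # 0.26 m/s net
```

The QC pass keeps 401 of 696 fixes (class-Z, missing-ellipse and
speed-violating fixes removed); the fitted velocity autocorrelation decays
at β ≈ 0.56/day and the imputation yields 100 plausible 2-h tracks whose
spread reflects the Argos error. The bird travelled ~2600 km westward, so
it is binned as a westbound migrant with a 0.26 m/s net swim speed —
squarely in the range reported for westbound adults in this system.

`make_fixture(seed)` builds the full 50-deployment study-shaped dataset
(40 adults, 10 juveniles across Admiralty Bay, Cape Shirreff and Cierva
Cove) and `run_pipeline()` chains QC → state-space fits → imputation →
HUD/overlap → classification → habitat areas into one reproducible run
with a manifest.

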