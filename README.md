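# nanodomain

Point-pattern analysis of single-molecule localization microscopy
(PALM/STORM) data for membrane-protein **nanodomains** — sub-diffraction
clusters some tens of nanometers across, such as those formed by the
dopamine transporter in presynaptic membranes.

Localization data are treacherous to cluster: one fluorophore blinks
several times, so even randomly placed molecules produce apparent
clusters. This package implements the full analysis chain that deals with
that:

- **Blink/duplicate correction** — activation-cycle filtering ("present in
  imaging frame 1, gone by frame 3", ±1-pixel repeat removal),
  consecutive-frame merging, photon thresholds (200 for Dronpa/PALM, 1000
  for STORM dyes), fiducial drift correction.
- **Two-stage DBSCAN** — monomer filter (ε = 60 nm, MinPts = 10), then
  cluster assignment (ε = 30 nm, MinPts = 20), reporting the **clustered
  fraction** (% of total localizations) — the primary per-image statistic.
- **Cluster geometry** — convex hulls (Andrew's monotone chain), shoelace
  areas, equal-area-circle diameters, lognormal size-distribution fits
  with cumulative curves.
- **Nanocluster verification** — Gaussian cluster mask (σ = 80 nm, cut off
  at 40 nm, threshold 2.5) giving the relative mask area η and normalized
  in-mask density ρ/ρ₀, compared against the random-blinking reference

  ρ/ρ₀ = 1 + 1.4 η⁴

  Data whose fitted quartic coefficient far exceeds 1.4 indicate true
  nanoclusters; random multi-blinking data reproduce it.
- **Nearest-neighbor density maps** (30 nm radius).
- **Coordinate-based colocalization (CBC)** for dual-color data:
  per-localization scores in [−1, 1] from rank-correlated, edge-corrected
  neighbor curves.
- **Pipeline & statistics** — manifest-driven per-image runs, group
  comparisons with t-tests / one- and two-way ANOVA + Bonferroni
  post-tests.
- **Synthetic data generator** — clustered membranes (70 nm median
  domains), geometric multi-blinking, localization jitter, 4-frame
  activation cycles, dual channels, drift and fiducials — with complete
  ground truth, so every stage is testable.

## Worked example

Simulate a half-clustered membrane (3000 emitters, 70 nm domains,
geometric blinks with mean 4, 10 nm jitter), cluster it, and size the
domains:

```r
library(nanodomain)

cfg <- simulation_config(
  n_emitters = 3000, clustered_fraction_true = 0.5,
  n_domains = round(0.5 * 3000 / 16),
  domain_diameter_log_sigma = 0, blink_mean = 4, jitter_sigma = 10,
  seed = 7
)
ds <- generate_dataset(cfg)
ds$table
#> Localization table: 12168 localizations, 9937 frame(s), 1 channel(s)
#>   x: [1.4, 9998.0] nm, y: [7.9, 10001.6] nm

assignment <- two_stage_cluster(ds$table)
assignment
#> DBSCAN assignment: 12168 localizations, 98 cluster(s), 51.6% clustered
#>   epsilon = 30 nm, MinPts = 20; 5071 core, 1205 border, 5892 noise

geometry <- cluster_sizes(assignment, ds$table)
fit <- fit_size_distribution(geometry, variable = "diameter")
fit
#> Lognormal diameter fit: n = 98, log_mu = 4.2588, log_sigma = 0.2202
#>   median diameter = 70.7 nm
```

The measured clustered fraction (51.6%) recovers the simulated truth
(50%), and the fitted median diameter (70.7 nm) recovers the 70 nm domain
size.

Verify that a *random* multi-blinking titration sits on the reference
curve (a real experiment would titrate label density instead):

```r
densities <- exp(seq(log(30), log(420), length.out = 10))
titration <- lapply(1:10, function(i) {
  generate_dataset(simulation_config(
    n_emitters = round(densities[i] * 100), clustered_fraction_true = 0,
    n_domains = 0, jitter_sigma = 15, seed = 100 + i))$table
})
verification <- verify_clustering(titration,
                                  mask_params(roi = c(0, 10000, 0, 10000)))
verification
#> Cluster verification over 10 datasets: verdict 'random' (p = 0.00945)
#>   fitted rho/rho0 = 1 + c * eta^4 with c = 1.013 (random reference: c = 1.4)
```

The fitted coefficient is near the random calibration, so the apparent
clusters in these datasets are blinking artifacts, not nanodomains.
`plot(verification)` draws the η–ρ/ρ₀ scatter with the reference curve;
see the methods vignette (`vignettes/nanodomain-methods.Rmd`) for the
modeling choices and their rationale.

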