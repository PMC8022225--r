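# tracksearch

Quantitative analysis of the DNA target search of bacterial DNA-binding
proteins from photoactivated single-molecule tracking data.

DNA-binding proteins — polymerases, repressors, topoisomerases, repair
factors, nucleoid-associated proteins — locate their chromosomal targets
by alternating 3D diffusion with frequent, sub-frame non-specific DNA
binding. Single-molecule tracking sees this only indirectly: each short
trajectory yields an *apparent* diffusion coefficient

D\*ᵢ = (1 / 4nΔt) Σₖ [(xₖ₊₁−xₖ)² + (yₖ₊₁−yₖ)²],  n = 4 steps,

biased by localization error (+σ²/Δt), motion blur (×2/3 in the
unconfined limit), and confinement in the µm-sized cell. `tracksearch`
provides the full chain that turns track tables into an unbiased
three-state picture of a protein population:

* **Simulator** (`simulate_tracks`) — confined Brownian motion in
  spherocylindrical or outline-derived 3D cell volumes, with two-state
  (bound/free) interconversion, 100 sub-frames of motion blur per frame,
  exponential photobleaching, and Gaussian localization noise; the
  synthetic-data engine behind all inference and tests (Rcpp core).
* **Synthetic imaging** (`render_movie`, `detect_candidates`,
  `localize`) — Poisson camera rendering, difference-of-Gaussians spot
  detection, elliptical Gaussian fitting.
* **Tracking** (`link_tracks`) — minimum-total-distance linking within a
  0.48 µm window, exact per-frame assignment, 1-frame gap memory.
* **D\* statistics** (`dstar_sample`, `dstar_pdf`, `fit_single`,
  `fit_mixture`, `bootstrap_cells`) — the Gamma sampling law of D\*,
  maximum-likelihood one/two-species fits, cell-level bootstrap CIs.
* **Inference** (`match_unbiased_D`, `estimate_phi`,
  `partition_states`, `total_bound`) — simulation matching for the
  unbiased D and for the transiently DNA-bound time fraction Φ;
  three-state partitioning (long-lived bound / transiently bound /
  free).
* **Scaling & occupancy** (`fit_power_law`, `predict_Dfree`,
  `chromosome_occupancy`) — the mass-scaling law D_free = c·M^α of free
  diffusion in chromosome-free cells and the fraction of the chromosome
  occluded by bound proteins.
* **Oscillations** (`build_kymograph`, `fit_period`,
  `wavelength_from_profile`) — kymograph period/wavelength analysis for
  pole-to-pole protein oscillations.

## Worked example

Mass scaling and state partitioning from the bundled reference table of
11 *E. coli* DNA-binding proteins:

```r
library(tracksearch)

ref  <- dbp_reference()
meas <- ref[ref$dfree_measured, ]          # 5 proteins measured in
fit  <- fit_power_law(meas$mass_kda, meas$d_free)  # chromosome-free cells
fit
#> scaling_fit: D = 220 * M^(-0.74)  [n = 5]
predict_Dfree(48, fit)                     # HU heterodimer
#> [1] 12.4

round(partition_states(A_immobile = 0.45, phi = 0.87))  # RNA polymerase
#> pct_long_lived  pct_transient       pct_free
#>             45             48              7
round(total_bound(0.45, 0.87))
#> [1] 93

rec <- with(ref, data.frame(protein, copies_per_cell,
                            frac_long_lived = pct_long_lived / 100,
                            frac_transient  = pct_transient / 100,
                            footprint_bp))
chromosome_occupancy(rec, genome_bp = 6.9e6)
#> occupancy_result: 2 Mb occupied (29.0% of 6.9 Mb; long-lived 12.3%,
#>                   transient 16.8%)
```

The exponent α ≈ −0.74 is far steeper than the Stokes–Einstein −1/3:
even without the chromosome, the crowded cytoplasm sieves proteins by
size. The occupancy estimate says that these 11 proteins alone occlude
roughly 29% of the chromosomal DNA at any instant.

A full synthetic loop — simulate a population at known ground truth,
fit the two-species mixture, re-infer Φ by simulation matching, and
partition:

```r
cfg <- list(truth = list(A_immobile = 0.45, phi = 0.85, D_free = 2.7),
            n_tracks = 10000, seed = 42, cells = list(n_cells = 10),
            phi_grid = seq(0, 1, by = 0.02), n_tracks_per_grid = 5000)
report <- run_pipeline(cfg)
round(report$mixture$A, 3); round(report$phi, 3)
#> [1] 0.476
#> [1] 0.844
round(unlist(report$partition), 1)
#> pct_long_lived  pct_transient       pct_free
#>           47.6           44.2            8.1
```

Both state fractions come back within a few percentage points of the
ground truth (A = 0.45, Φ = 0.85).

## Documentation

The methods vignette (`vignettes/target-search-methods.Rmd`) describes
the model and its assumptions, every tunable parameter with units and
defaults, the boundary/initial-condition conventions of the simulator,
what the synthetic data does and does not emulate, and known
limitations.
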