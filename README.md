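# catchbond

Single-molecule force spectroscopy (SMFS) analysis and multi-state
catch-bond modeling in R.

Receptor:ligand complexes probed by AFM-based SMFS — the motivating
system is the sperm-egg adhesion complex Izumo1:Juno — can unbind
through several pathways: constant-speed pulling yields a multimodal
rupture-force distribution (pathways P0 < P1 < P2), and force-clamp
measurements show bond lifetimes that *increase* with force over part
of the force range (a catch bond) before decreasing again. `catchbond`
implements the full analysis stack for such data together with the
kinetic modeling used to interpret it:

* **Polymer elasticity**: freely rotating chain (FRC) with Kuhn length
  `a = b(1+cos γ)/((1−cos γ)cos(γ/2))` and the piecewise
  force–extension law used to transform curves into contour-length
  space; Marko–Siggia worm-like chain (WLC) for simulation.
* **Curve pipeline**: baseline subtraction, sawtooth-peak detection,
  automated prefiltering (early peaks / no peaks / >9 peaks),
  fingerprint identification (four unfolding peaks at 50–80 pN adding
  32 nm of contour, terminal rupture at ~190 nm), rupture-record and
  loading-rate extraction, force-clamp trace filtering and
  setpoint/lifetime estimation.
* **Pathway classification**: Gaussian mixtures (1–4 components, BIC)
  on standardised sqrt-transformed rupture forces, with
  reclassification of a spurious fourth component and per-speed
  pathway proportions ± SEM.
* **Energy landscapes**: histogram transformation of binned rupture
  forces into force-dependent off-rates
  `k_off(F_k) = h_k r(F_k) / ((h_k/2 + Σ_{i>k} h_i) ΔF)`, fitted with
  the Dudko–Hummer–Szabo model (`ν = 1/2` cusp or `ν = 1/3`
  linear-cubic, Levenberg–Marquardt from 10,000 random starts) and the
  Bell–Evans model `F = (kBT/Δx) ln[r_f Δx/(k0 kBT)]`.
* **Kinetic Monte Carlo**: a reversible three-state bond
  (N → I1 → I2 with rupture edges P0/P1/P2, all Bell kinetics
  `k(F) = k0 e^{βFΔx}`) simulated under constant-speed and force-clamp
  protocols, plus random-search least-squares fitting of the
  experimentally invisible transition barriers and a
  reversible-vs-irreversible model comparison.
* **Statistics**: Shapiro–Wilk screening, Kruskal–Wallis with Dunn
  (Šidák) or pairwise Wilcoxon post hocs, compact letter displays, and
  Hill-equation K_D fitting for titration data.
* **Synthetic data**: generators for force–extension curves, clamp
  traces, rupture tables and titrations with per-event ground truth,
  so every stage is testable without instrument data.

## Worked example

Simulate a three-state complex at the four experimental pulling speeds
(800–6400 nm/s), classify pathways, and fit both landscape models:

```r
library(catchbond)

model <- state_model(
  rupture = list(P0 = be_params(0.1, 1.2),   # k0 (1/s), delta_x (nm)
                 P1 = be_params(0.3, 0.3),
                 P2 = be_params(0.05, 0.1)),
  forward = list(N_I1 = be_params(0.2, 1.2), I1_I2 = be_params(0.15, 0.3)))

rec <- generate_rupture_dataset(model, n_per_speed = 400, seed = 7)
rec <- rec[!rec$censored, ]

g <- reclassify_fourth_component(fit_pathway_gmm(rec$rupture_force, seed = 1))
g
#> <gmm_result> 3 components (n = 1600)
#>   weight mean_pN variance
#> 1  0.348    22.7   0.0093
#> 2  0.434    95.4   0.0351
#> 3  0.219   400.2   0.0974

rec$pathway <- pathway_assignments(g)$pathway
fit_be(rec[rec$pathway == "P1", ])
#> <be_params> k0 = 0.823838 1/s, delta_x = 0.299717 nm
```

The mixture recovers the three generating pathways (rupture-force modes
near 23, 95 and 400 pN) and the Bell–Evans fit of the P1 records
returns `delta_x` within 0.1% of the generating 0.3 nm (`k0`, entering
only through the intercept, is exponentially more uncertain). The same
records feed the DHS route:

```r
h <- off_rate_histogram(rec[rec$pathway == "P1",
                            c("rupture_force", "loading_rate")])
fit_dhs(h, nu = 1/2, n_starts = 300, optimize_top = 30, seed = 2)
#> <dhs_params> nu = 0.5: k0 = 0.07345 1/s, dx = 0.4403 nm, dG = 19.38 kBT (SSR 0.607)
```

Catch-bond behaviour under force clamp, with the reversible reference
landscape:

```r
sim <- simulate_force_clamp(default_state_model(),
                            force_clamp_config(seq(10, 110, 20),
                                               replicates = 300, seed = 13))
sim$summary[, c("setpoint", "mean_lifetime", "freq_P0", "freq_P2")]
```

Mean lifetime rises from milliseconds at 10 pN to ~1 s near 50 pN and
falls again — the slip-catch-slip signature — while the rupture flux
shifts from P0 to the mechanically stable P2.

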