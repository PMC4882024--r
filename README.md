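# stagepp

Spatial point-pattern analysis of mapped forest-plot censuses, built to
answer one question: how much of a species' aggregated distribution is due
to **environmental filtering** and how much to **dispersal limitation**, and
how does that balance shift across life stages (sapling → juvenile →
adult)?

Both processes produce clumped stem maps, so aggregation alone identifies
neither. `stagepp` implements a three-method framework that separates them:

1. **Species–habitat association under a Poisson-cluster null.** A Thomas
   process (parents with intensity κ, Gaussian offspring displacement sd σ,
   mean offspring μ; `K(r) = πr² + (1 − e^{−r²/4σ²})/κ`) is fitted to each
   pattern by minimum contrast over 0–100 m, so dispersal-like clumping is
   part of the null. 999 simulations give per-habitat density bounds; an
   observed density above the rank-based upper bound of the central 99%
   interval is a positive association. Habitats are the seven-class
   scheme on 20-m quadrats (disturbed; valley/slope/ridge by convexity with
   breaks −2 and 2 m; low/high split at 450 m elevation).
2. **Dispersal limitation under a heterogeneous Poisson null.** A
   log-linear intensity `log ρ(u) = μ + H(u)βᵀ` on principal components of
   seven kriged environmental surfaces (elevation, convexity, slope, total
   C, N, P, pH at 5-m resolution) is fitted by Berman–Turner quadrature
   with stepwise term selection. If the observed inhomogeneous pair
   correlation rises above the pointwise 95% rank envelope of 199 model
   simulations anywhere in 0–20 m, residual (non-habitat) clustering —
   read: dispersal limitation — is flagged.
3. **Joint Cox model with variance decomposition.** Both terms in one
   model, `log Λ(u) = μ + H(u)βᵀ + D(u)`, with `D` a Matérn-covariance
   Gaussian residual, estimated by the two-step composite-likelihood /
   minimum-contrast approach. The proportion of log-intensity variance
   explained by environment is `PVE = V_env / (V_env + σ²_D)` and
   `PVD = 1 − PVE` exactly.

A synthetic-plot generator (`make_terrain`, `make_soils`, `make_community`)
produces a full 500 × 400 m world — corner-post elevations with ~300 m
relief, ~1,300 soil samples, a disturbed-corner mask, and multi-species
multi-stage stem tables from environment-thinned Thomas processes — with a
ground-truth ledger (true PVE, cluster parameters, preferred habitats) for
every downstream test.

## Worked example

```r
library(stagepp)
bundle <- make_community(n_species = 3,
                         syndrome_mix = c(animal = 2, wind = 1,
                                          gravity_ballistic = 0),
                         abundance_range = c(200, 400), seed = 7)
prep <- prepare_environment(bundle$terrain$posts, bundle$soils$samples,
                            bundle$window, bundle$disturbed_mask)
cfg <- pipeline_config(n_sim_assoc = 199, n_sim_disp = 99, n_sim_gof = 19,
                       n_sim_screen = 99)   # scaled down for a quick demo
res <- run_full_analysis(bundle$stems, prep$env, prep$habitat_map,
                         bundle$syndromes, config = cfg, seed = 7)
print(res)
```

```
stage summary over 3 species
     stage n_species pct_habitat_associated pct_dispersal_limited mean_pve
1  sapling         3                   33.3                 100.0    0.122
2 juvenile         3                  100.0                 100.0    0.331
3    adult         3                  100.0                  66.7    0.853
```

Reading: at the sapling stage one species in three shows a positive habitat
association and every species is flagged dispersal-limited; by the adult
stage all are habitat-associated, only two thirds remain
dispersal-limited, and the mean PVE rises from 0.12 to 0.85 — the two
stage trends the framework is designed to expose. (`res$species` holds the
per-species records; two adult residual terms were dropped by model
selection, reporting PVE = 1 for those species and inflating the adult
mean — the truth ledger `bundle$truth` has generating true PVE of roughly
0.06 → 0.3 → 0.65.)

`write_results(res, "out/")` writes the per-species and community tables
plus a JSON run manifest; `exec/stagepp` provides `synth` and `run`
subcommands for file-based runs.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the models and
their assumptions, every tunable default (edge corrections, kernel
bandwidth, stepwise criterion, kriging model, rank bounds), what the
synthetic generator does and does not emulate, and known limitations.
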