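# isletnet

Functional connectivity analysis of pancreatic beta cells from
multicellular calcium imaging.

Beta cells in an islet of Langerhans are coupled through gap junctions and
respond to glucose with coordinated cytosolic Ca²⁺ oscillations. Given one
fluorescence trace per cell (ROI) and the cell positions, `isletnet`
reconstructs the islet's *functional network* — cells are connected when
the Pearson correlation of their signals over a time window exceeds a
threshold — and characterizes it with graph theory. It is aimed at
physiologists and quantitative biologists analyzing time-lapse recordings
of coupled cell populations, and at anyone who needs a tested reference
implementation of correlation-threshold network analysis.

## What it computes

For traces $x_i(t)$ over a window of $n$ frames:

- correlation matrix $R_{ij} = \sum_t (x_i - \bar x_i)(x_j - \bar x_j) /
  (n \sigma_i \sigma_j)$, and its mean over all cell pairs, $R_{avg}$;
- the critical correlation at significance $p$,
  $R_{crit} = t_c / \sqrt{n - 2 + t_c^2}$ with $t_c$ the two-tailed
  t-quantile at $n - 2$ df; networks are thresholded at $R_{th} > R_{crit}$
  (default $R_{th} = 0.75$, edges where $R_{ij} > R_{th}$ strictly);
- node degrees $k_i$, clustering $C_i = 2T_i/(k_i(k_i{-}1))$, global
  efficiency $E_{glob} = \langle 1/d_{ij} \rangle$ (disconnected pairs
  contribute 0), matched $G(n,m)$ random-graph references
  $C_{rand}, E_{rand}$, and small-world-ness
  $S = (C_{avg}/C_{rand}) / (E_{rand}/E_{glob})$;
- normalized cumulative degree distributions $G(k)$ with power-law,
  exponential and truncated power-law fits ranked by $r^2$;
- distance-resolved summaries (distance-correlation 2D histograms, binned
  $R_{avg}(l)$, hub link lengths, clustering vs link length);
- sliding-window time courses of $R_{avg}$, $k_{avg}$, $C_{avg}$,
  $E_{glob}$;
- multi-islet medians/ranges and paired regime statistics (Friedman, then
  exact Wilcoxon signed-rank with Bonferroni 0.05/3).

Recordings are segmented into five protocol regimes — LG1 (low glucose),
ON (activation), HG (sustained high-glucose activity), OFF (deactivation),
LG2 (low glucose again) — and preprocessing covers photobleaching
correction (linear + exponential drift fitted on baseline regimes), F/F₀
normalization, unit rescaling, and classification of beta vs non-beta vs
unresponsive cells from their response phenotype.

A synthetic generator (`sim_params()`, `generate_geometry()`,
`simulate_traces()`) produces islet geometries and traces with the
statistical structure the analysis assumes — driven activation with
per-cell delays, plateau oscillations phase-lagged by a traveling calcium
wave, spatially coherent local fluctuations, common-mode and per-cell
noise, bleaching drift — so the entire pipeline runs and is validated with
no external data. See the methods vignette
(`vignettes/isletnet-methods.Rmd`) for the model and every design choice.

## Worked example

```r
library(isletnet)

p      <- sim_params(n_cells = 60, seed = 3)   # one synthetic islet
geom   <- generate_geometry(p)
traces <- simulate_traces(geom, p)             # raw fluorescence, 900 frames
res    <- analyze_islet(traces, geom, p$schedule, seed = 3)
res$summary
```

```
 regime n_cells R_avg  k_avg C_avg E_glob  C_rand E_rand clustering_ratio efficiency_ratio    S mean_link_um hub_link_um
    LG1      55 0.246  0.909 0.132 0.0265 0.00445 0.0321            29.58             1.21 24.4        106.3       106.3
     ON      55 0.749 31.782 0.817 0.7879      NA     NA               NA               NA   NA        100.4       103.1
     HG      55 0.428  5.709 0.617 0.3198 0.10621 0.4642             5.81             1.45  4.0         34.0        34.7
    OFF      55 0.969 54.000 1.000 1.0000      NA     NA               NA               NA   NA         99.4        98.7
    LG2      55 0.255  0.836 0.105 0.0224 0.00321 0.0264            32.83             1.18 27.9        108.5       108.5
```

Reading the table: 55 of 60 cells classified as beta; pairwise correlation
is highest in the externally driven ON/OFF transients (0.75, 0.97),
intermediate under sustained stimulation (HG, 0.43) and low at rest
(≈0.25). The HG network is moderately dense (mean degree 5.7), strongly
clustered relative to its random reference (ratio 5.8) at comparable
integration (efficiency ratio 1.45), hence small-world ($S = 4.0$), and its
links are short (34 µm, under two cell diameters) while the sparse
low-glucose links are distance-indifferent (~107 µm). ON/OFF rows carry no
random-reference columns: near-complete driven graphs make those ratios
degenerate.

A full nine-islet study with paired statistics and pooled degree fits:

```r
st <- run_study(n_islets = 9, seed = 1)
st$aggregate$table1    # medians across islets, LG1/HG/LG2
st$stats               # Friedman + exact Wilcoxon, Bonferroni 0.05/3
st$degree_fits$HG      # cumulative degree-distribution models
```

```
 regime C_avg E_glob C_rand E_rand clustering_ratio efficiency_ratio    S
    LG1 0.171 0.0332 0.0125  0.171            12.11             3.66 2.74
     HG 0.676 0.3024 0.0937  0.460             7.06             1.52 4.36
    LG2 0.190 0.0445 0.0162  0.171            10.89             4.12 2.47

                model      A alpha kappa    r2  best
1           power_law  0.101  1.20    NA 0.619 FALSE
2         exponential  2.325    NA 0.252 0.896 FALSE
3 truncated_power_law 26.268 -1.09 0.148 0.964  TRUE
```

Stimulation raises clustering and efficiency (HG vs both LG regimes,
flagged significant), LG1 vs LG2 is never significant (the effect is
reversible), and the pooled HG cumulative degree distribution is best
described by an exponentially truncated power law — the broad-scale
network signature.

There is also a command-line front end:

```sh
Rscript inst/scripts/isletnet simulate --out fixtures --n-islets 9 --seed 7
Rscript inst/scripts/isletnet analyze  --fixture fixtures/islet_01 --out out
Rscript inst/scripts/isletnet study    --out study --n-islets 9 --seed 7
```

Every run writes `config_echo.json` with all parameters and seeds; reruns
are byte-identical.

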