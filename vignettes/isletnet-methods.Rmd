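---
title: "Functional beta-cell networks from calcium imaging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional beta-cell networks from calcium imaging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletnet)
```

## The problem

Pancreatic beta cells are electrically coupled through gap junctions and
respond to a glucose stimulus with coordinated cytosolic calcium
oscillations. Multicellular calcium imaging of an islet cross-section yields
one fluorescence trace per cell (ROI); the question is how the *functional*
organization of the syncytium — who is synchronized with whom — relates to
its physical layout, and whether it shows small-world structure rather than
the purely nearest-neighbour coupling a regular lattice would suggest.

`isletnet` implements the complete analysis chain: trace conditioning,
response-based cell classification, Pearson-correlation network extraction
at a significance-checked threshold, graph-theoretic characterization
against a matched random-graph reference, distance-resolved spatial
analyses, sliding-window temporal analyses, and multi-islet statistics. A
synthetic-data generator emulating the essential statistical structure of
islet recordings makes the pipeline runnable and testable end to end
without any external data.

## The recording model and its regimes

A recording is segmented into five half-open regimes: low glucose before
stimulation (`LG1`, default [0, 300) s), activation (`ON`, [300, 420)),
sustained high-glucose activity (`HG`, [600, 1000)), deactivation (`OFF`,
[1080, 1200)), and low glucose after stimulation (`LG2`, [1400, 1800)),
at a 0.5 Hz frame rate. Gaps between regimes cover perifusion transients
and are excluded. The half-open convention means the default `HG` slice
holds exactly 200 frames and `ON` exactly 60.

## Trace conditioning

**Photobleaching.** Dye bleaching is modelled as a multiplicative drift and
corrected per cell by dividing out a least-squares fit of
$d(t) = c_0 + c_1 t + c_2 e^{-t/\tau}$ — a linear plus exponential
combination. The fit uses only the baseline (LG1 + LG2) samples: fitting
the whole trace would absorb the glucose response into the drift estimate.
Since the model is linear in $(c_0, c_1, c_2)$ for fixed $\tau$, the
correction profiles $\tau$ over a log-spaced grid (30–3000 s) and refines
the minimum by golden-section search. This is deterministic and cannot fail
to converge; if the fitted drift is non-positive anywhere, the cell falls
back to a linear-only fit and is flagged.

**Normalization.** Traces are expressed as $F/F_0$ with $F_0$ the mean over
the first 60 s of LG1 ("initial level" is all the protocol pins down; a
window average is more robust than a single frame). For network analysis
each trace is then affinely rescaled to the unit interval. Pearson
correlation is invariant under this map — the package asserts equality of
correlation matrices before and after rescaling to 1e-12 — so rescaling is
cosmetic, standardizing plots and thresholds.

**Classification.** Beta cells are identified by their canonical response:
quiet in low glucose, sustained rise under high glucose (default: HG mean
> 1.2 x LG1 mean), reversible (LG2 mean within ±20% of LG1). The
oscillation criterion is a threshold-crossing count on the linearly
detrended LG1 segment: the fraction of frames deviating more than $m = 3$
noise scales. One subtlety: the noise scale must *not* be the standard
deviation of the detrended segment itself — a pure oscillation never
exceeds ~1.4 of its own SD, so that statistic cannot flag an oscillating
cell at any multiplier. The package instead estimates the noise scale from
first differences, $\hat\sigma = \mathrm{MAD}(\Delta x)/\sqrt{2}$, which a
slow oscillation barely inflates; slow large excursions then register as
crossings. Cells oscillating in LG1 (alpha/delta-like) are labelled
`non_beta`, cells with no HG response `unresponsive`; both are excluded
from network analysis.

## Network construction

The correlation matrix $R_{ij}$ is the Pearson product-moment coefficient
between the unit-rescaled traces of cells $i$ and $j$ over the frames of a
regime (or sliding window). Significance of a coefficient at window length
$n$ follows from the t-statistic $t = R\sqrt{(n-2)/(1-R^2)}$; inverting at
the two-tailed critical value gives
$R_{crit} = t_c/\sqrt{n - 2 + t_c^2}$. At $p < 0.001$ this yields
$R_{crit} \approx 0.45$ for a 100-s window ($n = 50$) and $\approx 0.62$
for $n = 25$; the functions expose $n$ explicitly rather than hard-coding a
window length. Two-tailed inversion is used as the conservative standard.

Two cells are connected iff $R_{ij}$ *strictly* exceeds a positive
threshold $R_{th}$ (default 0.75, well above the critical correlation of
every default regime window; a sub-significant choice is recorded as a
warning). The graph is simple, undirected and unweighted; isolated nodes
are retained; negative correlations never create edges. Correlations of
constant (dead) traces are recorded as 0 and flagged rather than raising an
error, so one dead ROI cannot abort an islet.

## Graph metrics

* **Clustering** $C_i = 2T_i/(k_i(k_i-1))$, with $C_i = 0$ for degree < 2
  (included in $C_{avg}$, keeping the average defined on sparse low-glucose
  networks).
* **Global efficiency** $E_{glob} = \langle 1/d_{ij}\rangle$ over ordered
  pairs, with disconnected pairs contributing zero. This inverse-distance
  (Latora–Marchiori) form is chosen because low-glucose networks contain
  isolated nodes, for which the reciprocal of the mean shortest path would
  be undefined.
* **Random reference**: uniform $G(n, m)$ graphs with exactly the same
  node and edge counts (hence mean degree), 100 seeded realizations by
  default; the ensemble means give $C_{rand}$ and $E_{rand}$. The expected
  clustering of this ensemble equals the edge density, which the test suite
  uses as a calibration check.
* **Small-world-ness**
  $S = (C_{avg}/C_{rand}) / (E_{rand}/E_{glob})$, typically > 1 in small
  worlds. Zero denominators yield a flagged undefined result rather than
  infinities.
* **Degree structure**: cumulative distributions $G(k)$ (fraction of nodes
  with degree $\ge k$, weak inequality) on degrees normalized per islet by
  that islet's $k_{max}$, evaluated on a common grid and averaged across
  islets. Three decay models are fitted in log-$G$ space over points with
  $G > 0$ — power law, exponential, exponentially truncated power law — all
  linear in their parameters there, ranked by $r^2$ on the fitted scale.
  The truncated model nests the other two, so with any curvature in the
  data it attains the highest $r^2$; that is exactly the broad-scale
  signature being tested for.

On thresholded networks, raising $R_{th}$ provably shrinks the edge set,
the mean degree and the global efficiency, and can only raise the mean
weight of the surviving edges. Mean clustering decreases as a strong trend
but is *not* pointwise monotone: pruning a non-triangle edge of a node with
few neighbours can raise that node's $C_i$. The test suite therefore
asserts strict monotonicity for the provable quantities and a monotone
decreasing trend (negative rank correlation with the threshold, endpoint
decrease) for $C_{avg}$.

## Spatial analyses

Euclidean distances between ROI centroids feed four views: 2D histograms
of pair counts over (distance, correlation) bins with explicit overflow
accounting (the total always equals $N(N-1)/2$); distance-binned mean
correlation (empty bins are `NA`, never zero); mean length of links
incident to hub cells (the top `ceiling(0.2 N)` nodes by degree, ties
broken deterministically by cell id, each link counted once); and mean
incident-link length as a function of the local clustering coefficient.
Default bin widths are 10 µm in distance, 0.05 in correlation and 0.1 in
$C_i$ — display-scale choices, as no analysis decision depends on them.

## The synthetic generator

The generator replaces unavailable recordings with traces that have the
statistical structure the analysis assumes. Geometry: dart-throwing
placement in a disc of radius $d\sqrt{n/2}$ (mean nearest-neighbour
spacing about one 20-µm cell diameter) with minimum spacing $0.8d$;
non-beta cells are confined to the outermost 1.5-diameter annulus, as in
mouse islets.

Beta-cell dynamics, as a fraction of baseline:

$$s_i(t) = 1 + g_i(t)\left[A + m\sin\!\big(2\pi(t - d_i/v)/T\big) + f_i(t)\right]
 + a_i h(t)$$

with a smoothstep activation/deactivation gate $g_i$ (per-cell onset delays
up to 30 s after the glucose step, shorter deactivation delays — the gate is
exactly zero before onset, so no stimulus leaks into the baseline), plateau
elevation $A = 1$, oscillation period $T = 40$ s (chosen so at least ten
cycles fit the 400-s HG window at 0.5 Hz; no period is pinned down by the
protocol), and wave phase lags $d_i/v$ given by the distance to a randomly
placed wave source at a speed drawn log-uniformly from 20–200 µm/s per
realization, reflecting that wave velocities span a broad range.
$f_i$ is a spatially coherent Gaussian-kernel field (correlation length
25 µm, AR(1) in time) that makes nearby cells genuinely more similar than
the wave alone would, and $h$ a weak islet-wide slow fluctuation.

Raw fluorescence is $F_i(t) = F_{0,i}\,[s_i(t)\,b(t) + g^{c}_i \eta(t) +
\varepsilon_i(t)]$ with multiplicative bleaching
$b(t) = (1 - at)(1 - b_e(1 - e^{-t/\tau}))$ — precisely the linear +
exponential family the corrector inverts — per-cell i.i.d. Gaussian noise,
and a frame-wide common-mode fluctuation $\eta$ (illumination/focus
jitter) to which each cell couples with a skewed gain
$g^c_i = 0.1 + 1.4u^3$. The common-mode term is what gives low-glucose
frames their residual pairwise correlation (about 0.2 on average, with a
weakly connected tail of high-gain cells); being spectrally flat it does
not trigger the oscillation classifier, which a slow shared fluctuation of
the required amplitude necessarily would. Non-beta cells oscillate in low
glucose (amplitude 0.3, period 35 s) and ignore the stimulus, exercising
the classification filter.

Amplitudes (oscillation 0.15, local field 0.18, common-mode 0.05, noise
0.03 of baseline) were fixed once so that the generator reproduces the
qualitative and approximate quantitative regime profile reported for real
islets: mean pairwise correlation around 0.2 in low glucose, 0.4 under
sustained stimulation, highest during the driven activation/deactivation
transients; short-link-dominated, small-world high-glucose networks; and
sparse, distance-independent low-glucose networks.

What the generator does **not** emulate: bursting/spike-shaped (non-
sinusoidal) oscillation waveforms, pink or photon-counting noise, motion
artefacts, 3D structure, capillary geometry, or any biophysical
(channel/gap-junction) mechanism. Passing tests therefore validate the
*analysis pipeline* under the stated statistical assumptions, not any
biological claim about real islets.

## Multi-islet studies and statistics

`run_study()` simulates islets with 45–90 cells (drawn per islet so pooling
spans different network orders; nine islets by default, matching the usual
scale of such studies), analyzes each, aggregates per-regime medians and
min–max ranges, and compares LG1/HG/LG2 with Friedman tests (islets as
blocks) followed by paired two-sided Wilcoxon signed-rank tests (exact
distribution for up to 25 islets) for LG1–HG, HG–LG2 and LG1–LG2 at the
Bonferroni level $0.05/3 = 0.0167$. Post hoc p-values are always computed
but flagged unlicensed when the Friedman test is not significant. The
driven ON/OFF transients are analyzed for correlation and degree but
excluded from small-world aggregation and degree fits: their near-complete
graphs make the random-reference ratios degenerate. Aggregate ratio
columns are medians of per-islet ratios (not ratios of medians). Metrics
undefined in some islet-regime cell (link lengths of an edgeless network)
are excluded from the paired tests rather than imputed.

Determinism: every stochastic step (geometry, traces, random reference,
islet sizes) derives from explicit integer seeds; a study rerun from its
echoed configuration reproduces results bit for bit.

## Worked example

```{r example, eval = FALSE}
p <- sim_params(n_cells = 60, seed = 3)
geom <- generate_geometry(p)
traces <- simulate_traces(geom, p)
res <- analyze_islet(traces, geom, p$schedule, seed = 3)
res$summary

st <- run_study(n_islets = 9, seed = 1)
st$aggregate$table1
st$stats
st$degree_fits$HG
```

Problem sizes in the shipped tests — islets of 25–90 cells, 900-frame
recordings, 100-realization random references, nine-islet studies — are the
package's default study conditions; all results in the README were produced
by the commands shown there.

## Known limitations

* The oscillation classifier is a crossing count, not spectral; it flags
  any large slow excursion, which is the desired behaviour for the
  alpha-cell phenotype but would also flag strongly drifting cells whose
  drift survives bleach correction.
* $E_{glob}$ comparisons across networks of very different density are
  only meaningful through the matched random reference, as in the S ratio.
* The degree-model ranking inherits the nesting caveat above; it
  establishes the *shape family* (power law with cutoff), not a sharp
  model selection, mirroring the $r^2$ methodology it reproduces.
* Wave speed, oscillation period and all generator amplitudes are
  plausible stand-ins where the underlying protocol reports none; they are
  package defaults, not measured values.
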