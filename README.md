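# dictyoswarm

Starving *Dictyostelium discoideum* amoebae relay pulses of cAMP from cell
to cell and chemotax along the resulting gradients, turning tens of
thousands of independent cells into a single aggregate.  `dictyoswarm` is
an R package for studying that transition *in silico*: it provides a
coarse-grained agent-based model of pulsed cAMP relay (rear-biased
secretion, threshold-gated chemotaxis, a 6-min refractory period with
heading lock, volume exclusion, and mutant variants), together with the
statistical toolkit used to ask whether the aggregating collective behaves
like a system near a critical point.  It is aimed at quantitative/systems
biologists who want a tested, scriptable implementation of these
diagnostics for simulated or tracked-cell data.

## What it computes

For per-frame positions `r_i` and velocities `v_i`:

* density pair correlation
  `g(r) = A/(N(N-1)) * 1/(2*pi*r*a) * sum_{i!=j} delta(r - r_ij)`;
* nonconnected directional correlation
  `C_nc(r) = sum u_i.u_j delta(r - r_ij) / sum delta(r - r_ij)` with
  `u_i = v_i/|v_i|` (the order parameter), and its connected counterpart
  `C_c(r)` computed on velocity fluctuations about each cell's local
  neighborhood mean, normalized per neighborhood;
* correlation length `xi0`, the first zero crossing of `C(r)`;
* susceptibility `chi = (1/N) sum_{i!=j} du_i.du_j theta(xi0 - r_ij)`;
* finite-size scaling of `xi0` with the neighborhood radius, rescaled
  nearest-neighbor distances, and curve collapse of `C_c(r/xi0)`;
* the Fourier-space spatial information `kSI = H_kS - I_kS` of a binarized
  image of cells (a Shannon-entropy deficit relative to an
  uncorrelated-pixel reference), plus a compression proxy;
* centroid detection (h-extended maxima) and gated nearest-neighbor track
  linking;
* a zero-dimensional FitzHugh–Nagumo excitable cAMP unit with
  external-cAMP-dependent degradation (relay, refractoriness, and sustained
  oscillation above a threshold drive).

Synthetic-data generators (CSR and Thomas point processes, direction fields
with known correlation length, rendered fluorescence-like images) make
every analysis testable without experimental data.

## Worked example

```r
library(dictyoswarm)

cfg <- swarm_config(n_cells = 250, box_length = 275, seed = 1)
print(density_ml(250, 275))        # 0.5 monolayers
log <- run_swarm(cfg, t_end = 330, record_every = 1)

summary <- collective_summary(log)          # per-frame xi0, chi, NN distance
window <- streaming_window(summary)         # 50 min centered on the chi peak
scaling <- scaling_analysis(log, 275 / c(10, 8, 6, 4, 2), window)
print(scaling)

ksi <- spatial_information_series(log)
cat("kSI start vs end:", round(ksi$ksi[2]), round(tail(ksi$ksi, 1)), "\n")
```

A representative run prints

```
[1] 0.5008765
  n_cells       r_c  mean_xi0        se n_frames
1     250  27.50000  7.537536 0.2093762       51
2     250  34.37500  8.994845 0.3834221       51
3     250  45.83333 11.287533 0.5693605       51
4     250  68.75000 13.201739 0.7596496       51
5     250 137.50000 15.862578 1.1764229       51
kSI start vs end: 83746 85994
```

The correlation length grows with the neighborhood radius instead of
saturating — the finite-size-scaling signature of near-critical collective
motion — and the spatial information rises as the cells aggregate.

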