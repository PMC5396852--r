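---
title: "Coarse-grained aggregation and its criticality diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained aggregation and its criticality diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`dictyoswarm` simulates starvation-induced aggregation of *Dictyostelium
discoideum* with point-like agents in a periodic square box.  Each cell
secretes cAMP whose spatial profile is an exponential,
$c(r) = A\,e^{-\lambda r}\,w(\theta)$, with decay constant
$\lambda = 0.1\,\mu m^{-1}$.  The weight $w$ encodes rear-biased release:
$w(\theta) = \cos\theta$ for angles within 90 degrees of the
opposite-to-motion direction and $0$ over the whole front.  A cell senses
the sum of all other cells' profiles (never its own) and the analytic
gradient of that sum.

Three rules drive the dynamics:

* **Firing.** A quiescent cell whose sensed concentration reaches the
  threshold $c_1$ emits a pulse for `pulse_duration` = 1 min.  The pulse
  amplitude ramps up linearly over `pulse_rise_time` = 0.5 min and decays as
  $e^{-t/3\,\mathrm{min}}$.  Firing is followed by a 6-min refractory period
  during which the cell can neither fire again nor repolarize: it keeps the
  heading it had chosen at fire onset throughout firing and refractoriness.
  Because that heading was selected while the cell was climbing the gradient
  of the incoming pulse, the locked run carries the cell towards the signal
  source — the model's resolution of the back-of-the-wave problem.
* **Movement.** A quiescent cell extends one of two candidate pseudopods,
  obtained by rotating its heading by $\pm 27.5^\circ$ (a $55^\circ$ angle
  between pseudopods).  If the sensed gradient magnitude is at least
  $\nabla c_2$ the candidate with the larger concentration at the stepped
  position wins (ties break uniformly at random); otherwise the choice is
  random.  Displacement per step is `speed * dt`.
* **Exclusion and crowding.** Pairs closer than 3 um are separated
  symmetrically along their joining axis, except inside densely packed
  neighborhoods (more than `packing_threshold` neighbors within three
  exclusion radii), where exclusion is lifted so that mounds can form;
  cells in such neighborhoods also move at a reduced speed
  (`crowding_slowdown`), standing in for crowding inside the aggregate.
  Without the slowdown, aggregate members — which sit above $c_1$
  permanently and refire every cycle — churn their own aggregate apart with
  6-min ballistic runs.

Sensing noise is multiplicative Gaussian (sd 2 % for wild type), applied to
the concentration and to the gradient magnitude after field summation and
before the threshold tests; the high-noise variant multiplies the sd by 10.

## Calibration of the thresholds and amplitudes

The concentration scale is arbitrary; what matters are three ratios, chosen
once and kept fixed (see `calibrate_thresholds()`):

* **Ignition.** $c_1 = 4$ with leak amplitude 1 means an isolated cell can
  never fire from its own leakage (self-secretion is excluded from the sum),
  the smooth background leak field of a monolayer (mean $\approx 1.3$ at
  1 ML) stays well below threshold, and a compact cluster of about seven
  cells at contact distance with rears turned inward crosses it.  Ignition
  is therefore gated on genuine density clusters.  A lower threshold,
  reachable by four or five contact neighbors, proved unworkable: it sits
  within a few standard deviations of the monolayer background, the whole
  population then ignites continuously, and — because every close encounter
  triggers a locked ballistic run — threshold-coupled firing actively
  disperses every forming cluster.
* **Relay range.** The pulse amplitude (10) is about $2.5\times c_1$, so a
  fresh pulse can trigger a rear-facing neighbor out to
  $\ln(A/c_1)/\lambda \approx 9\,\mu m$ — roughly one contact distance.
  Relay waves therefore travel along dense groups and streams rather than
  jumping across empty space, and box-wide excitation only appears once the
  population is connected.
* **Chemotaxis gate.** $\nabla c_2 = 0.05$ sits an order of magnitude below
  the gradient associated with the firing threshold, giving an approaching
  cell a window of tens of steps in which it is gradient-guided but not yet
  firing; the heading locked at fire onset is then informative.  It also
  lets cells chase the leak trails of near neighbors, which is how streams
  and the first clusters form.

The pulse rise time exists because an instantaneous-onset pulse relays one
hop per integration step, making the wave speed an artifact of `dt`; a
finite release time sets the relay latency physically and keeps the
acceptance properties stable under halving or doubling of `dt`.

Cell speed defaults to 5 um/min, the typical pre-aggregation crawl speed of
*Dictyostelium*; at twice that, the 7-min locked run after each pulse spans
70 um, which exceeds aggregate diameters and disperses them.

The uniform-secretion variant conserves the total emitted amount: the rear
cosine weight integrates to 2 over the circle, so the radially symmetric
weight is $1/\pi$.  The asynchronous variant replaces the firing rule with
Poisson pulse onsets whose rate should be matched to a paired wild-type run
(`matched_async_rate()`), and draws each refractory duration uniformly from
0.5–1.5 times the 6-min base.

# Correlation statistics

All statistics operate on per-frame positions and velocities (velocities
are displacements between recorded frames divided by the recording
interval, minimum-image under periodic boundaries).

* `pair_correlation()` implements the ring-binned density pair correlation
  $g(r) = \frac{A}{N(N-1)}\frac{1}{2\pi r a}\sum_{i \ne j}\delta(r-r_{ij})$
  with ring radii at integer multiples of the discretization constant $a$
  (the ring at $ka$ collects distances in $[ka - a/2,\,ka + a/2)$).  Under
  complete spatial randomness with toroidal distances its expectation is 1
  at every $r$.
* `nonconnected_correlation()` averages $\vec u_i \cdot \vec u_j$ over cell
  pairs binned by distance (half-open bins $[ka,(k{+}1)a)$), with
  $\vec u_i$ the unit direction of motion — the order parameter.
* `directional_fluctuations()` computes, for each focal cell, the velocity
  fluctuation about the mean of its neighborhood (all cells within $r_c$,
  focal included), normalized by the root-mean-square fluctuation of that
  same neighborhood.  The local (rather than global) mean removes the bulk
  drift towards the aggregate that would otherwise masquerade as
  correlation.  The normalization is per neighborhood, so the unit-mean
  property of the fluctuations holds within each neighborhood rather than
  globally.  A cell with no neighbor within $r_c$ is flagged unusable; a
  neighborhood with identical velocities yields zero fluctuations but stays
  usable.
* `connected_correlation()` is the same binned average evaluated on the
  normalized fluctuations, with pairs restricted to $r_{ij} \le r_c$.
* `correlation_length()` returns the first downward zero crossing of a
  profile by linear interpolation between adjacent bins; an all-positive
  profile returns the largest bin center flagged `censored`.
* `susceptibility()` evaluates
  $\chi = \frac{1}{N}\sum_{i \ne j}\delta\vec u_i\cdot\delta\vec u_j\,
  \theta(\xi_0 - r_{ij})$ literally over usable cells.
* `collapse_profiles()` interpolates each profile onto a common
  $r/\xi_0 \in [0.2, 1]$ grid, normalizes at the first grid point, and
  reports the root-mean-square deviation of the curves from their pointwise
  mean.  Normalizing on the common grid (rather than at each profile's own
  first bin, whose $r/\xi_0$ position differs between profiles) is what
  makes exactly self-similar families collapse exactly.
* `scaling_analysis()` repeats the connected-correlation length for a set
  of neighborhood radii over a time window, reporting means and standard
  errors with frames treated as independent.  Note that the local-mean
  estimator confines the zero crossing to the neighborhood, so even fields
  with a short intrinsic correlation length show a mild growth of $\xi_0$
  with $r_c$; the discriminating signal is that near-critical motion tracks
  $r_c$ strongly while short-range fields saturate well below it.

Defaults follow the conventions used throughout: bin width 3 um (the
volume-exclusion length; 10.7 um is the cell minor axis scale appropriate
for experimental-style tracks), neighborhood radius $L/6$ for simulated
boxes ($L/4$ for tracked movies), and a 50-min streaming window centered on
the maximum of the 10-frame-smoothed $\chi(t)$ (150 min for movies).

# Spatial information

`spatial_information()` quantifies the order of a binarized image of cells
in Fourier space.  The binary image is lifted to its two-level
representation (each pixel a $\pm 1$ level indicator), which gives every
image of a given shape the same histogram and exactly $N_{px}$ units of
spectral power; a unitary 2-D DFT follows.  Under the uncorrelated-pixel
null each coefficient's real and imaginary part is Gaussian with variance
$\sigma^2 = N_{px}/(2 N_{px}) = 1/2$.  The reference entropy $H_{kS}$ is
the entropy of that Gaussian discretized into bins of width $\sigma/100$
over $\pm 10\sigma$, counted once per scored part; $I_{kS}$ sums
$-\log_2$ of the Gaussian bin mass at each observed part; and
$kSI = H_{kS} - I_{kS}$.  All coefficients except DC are scored, including
the Hermitian-redundant ones, exactly as the transform yields them; bin
masses in the far tails are computed from upper-tail probabilities
(a naive difference of CDFs cancels catastrophically beyond $\approx
8\sigma$), and parts beyond $\pm 10\sigma$ are clamped to the edge bin with
a $10^{-300}$ probability floor.  By Parseval's theorem the total spectral
power is fixed, so for uncorrelated pixels $kSI \approx 0$ (the residual
level-density offset is characterized by `ksi_calibration()`), while
clustering concentrates power into few, clamped coefficients and drives
$kSI$ up.  `compression_proxy()` offers an independent, compressor-based
view of the same ordering.

# Tracking

`detect_centroids()` computes the h-extended-maxima mask (regional maxima
standing at least `h` — default 10 % of the dynamic range — above their
surroundings, via grayscale morphological reconstruction by dilation),
labels connected components, and merges centroids closer than `min_sep`.
`link_frames()` links each centroid to its nearest neighbor in the next
frame, accepts links under the 10.7-um gate, and resolves conflicts
greedily by ascending distance with losers left unlinked; ties break on the
lower point index, making the result independent of input order.  There is
no gap closing and no birth/death model.

# Synthetic data

The `fixtures` generators make every analysis testable without external
data: uniform (CSR) and Thomas-cluster point patterns; unit direction
fields with exponential spatial covariance $e^{-d/\zeta}$ sampled by
covariance factorization (adequate for the few thousand points used here);
Gaussian-spot renderings of marked subpopulations (default 1 px/um, 2-um
spots, emulating a 10 % marked fraction); and a cluster-tightening image
ladder in which the same offspring draws are contracted towards their
parents, so clustering increases strictly while the point count is fixed.
These fixtures emulate the geometry and sampling of fluorescence movies but
not their photophysics: no background inhomogeneity, bleaching, or
out-of-focus light, so passing tests validate the estimators, not the
imaging pipeline.

# Problem sizes and numerical choices

The package's own test and reproduction runs use a 275-um box with 250–600
cells — the same densities as the reference 389-um setups (0.5–1.2
monolayers, 1 ML = 6,600 cells/mm^2) at about half the cell count — with
330–660 simulated minutes recorded at 1-min intervals.  Field sums are
truncated where the peak pulse amplitude has decayed to $10^{-3} c_1$
(about 90 um by default, capped at half the box) using a cell-linked
neighbor grid; the gradient is analytic, never finite-differenced; all
randomness flows through R's RNG so a seed fixes a run bitwise.

# Known limitations

* The asynchronous (random-pulsing) variant aggregates into very tight
  frozen clusters in this implementation — random pulses act as effective
  beacons for gradient-chasing neighbors — and so ends with *higher* final
  spatial information than wild type, although its communication range
  ($\xi_0$) is reduced as expected.  The wild-type advantage in final-state
  order is therefore not reproduced against this variant.
* The susceptibility peak grows only weakly with cell count at the default
  calibration; the chase-dominated aggregation pathway that makes the
  wild type robust produces weaker synchronized-wave signatures than a
  wave-dominated parameterization would.
* Aggregates are dynamic: members keep pulsing and cycling, so late-time
  spatial information fluctuates; medians over the final frames are used
  wherever a "final" value is needed.
* Against the uniform-secretion and adhesion variants the wild type's
  advantage in final spatial information is marginal at the tested scale,
  and the uniform variant can match or slightly exceed the wild-type
  correlation length.
* Along very finely stepped cluster-tightening ladders (adjacent spreads
  differing by only a few percent) the kSI difference between neighboring
  frames falls below the estimator's granularity, so strict pointwise
  monotonicity can fail by a fraction of a permille even though the overall
  trend is strong.
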