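---
title: "Cross-subject dynamic causal cortical connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-subject dynamic causal cortical connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortconn)
```

# The problem

Scalp EEG mixes the activity of many cortical generators through volume
conduction, so directed ("who drives whom") interactions between brain
regions cannot be read off channel-space signals: a single cortical source
appears in many electrodes at once and fabricates instantaneous
correlations. `cortconn` implements a pipeline that (i) cleans channel
data, (ii) maps it onto a fixed cortical source space shared by every
subject, (iii) collapses each region of interest (ROI) to one
representative current signal, (iv) fits short sliding-window vector
autoregressive (VAR) models to the ROI ensemble, (v) converts them into a
spectro-temporal directed connectivity measure (the short-time direct
directed transfer function, SdDTF), and (vi) decides which connections are
statistically reliable at the group level with a condition-mixing
permutation scheme under false-discovery-rate control. Because the source
space is fixed, network nodes mean the same thing in every subject, which
is what makes the group statistics well-posed.

A synthetic-cohort generator with fully known ground truth accompanies
every stage, so each claim the package makes is testable against an
oracle.

# Forward model

The head is modeled as three concentric spherical shells (brain, skull,
scalp) with boundary radii 0.087 / 0.092 / 0.100 m and conductivities
0.33, 0.022 and 0.33 S/m (scalp, skull, cortex). The cortical source
space is a subdivided icosahedral sphere of radius 0.082 m
(`10 * 4^s + 2` vertices at subdivision level `s`; the package default is
`s = 3`, 642 vertices, and the test suite mostly uses `s = 2`, 162
vertices). Dipoles sit at mesh vertices with fixed radial (surface-normal)
orientation, the standard constraint motivated by the columnar geometry of
cortical pyramidal cells; this reduces the unknowns per gridpoint from
three to one.

The lead field is computed analytically: for a radial unit dipole in a
layered conductor with an insulating exterior, the surface potential is a
Legendre series whose per-degree coefficients solve a small linear system
per spherical-harmonic degree (continuity of potential and radial current
at each interface, zero current at the scalp). The series is truncated at
degree 140, where the geometric factor `(0.082/0.1)^n` bounds the
truncation error below 1e-6 relative; the per-degree systems are
row/column equilibrated because `u^n` and `u^-(n+1)` terms span many
orders of magnitude at high degree. In the equal-conductivity limit the
implementation agrees with the closed-form homogeneous-sphere dipole
potential to better than 1e-6 relative (this is a unit test).

The spatial penalty is the discrete surface Laplacian of the mesh. The
default is the uniform graph Laplacian (degree minus adjacency); a
cotangent-weighted version is available (`surface_laplacian(...,
"cotangent")`). Both are symmetric positive semidefinite with the
constant vector in their null space.

Nine ROIs are shipped by default: bilateral inferior occipital, superior
parietal and precentral (motor) regions, plus three midline regions
(anterior cingulate, supplementary motor area, precuneus) whose left and
right gridpoint sets are merged, because spatially regularized inverse
solutions blur current across the medial fissure and treating the halves
as separate nodes would fabricate interhemispheric coupling. Each ROI is
the set of vertices within 24 mm of its seed direction(s); overlaps
resolve to the nearest seed.

# Source localization

The inverse problem is the cortically constrained, Laplacian-regularized
minimum-norm (cLORETA) solution

\[
J = T\,\Phi,\qquad
T = (K^\top K + \lambda^2 H^\top H)^{-1} K^\top ,
\]

with `K` the lead field, `H` the surface Laplacian and `Phi` one epoch of
channel data. `cloreta_transform()` is the direct dense implementation of
this formula; the pipeline uses `cloreta_operator()`, which factors the
problem once per head model through the push-through identity
`(K'K + l^2 L)^{-1} K' = L^{-1} K' (K L^{-1} K' + l^2 I)^{-1}` and an
eigendecomposition of the channel-space matrix `K L^{-1} K'`, making the
transform, the GCV curve and the evidence iteration O(C^2) per lambda
instead of O(G^3). `L = H'H` gains a relative ridge of 1e-9 on its
diagonal to remove the constant null vector; the two paths agree to 1e-7
relative (tested).

Two numerical choices deserve explanation:

* **Gain (depth) weighting.** The electrode cap covers only part of the
  sphere, so lead-field column norms vary strongly across the mesh and
  the raw minimum-norm solution is biased toward high-gain gridpoints: on
  the 162-vertex model, roughly one in ten upper-hemisphere vertices
  mislocalizes *even with noise-free data*. `cloreta_operator()` therefore
  normalizes lead-field columns to unit gain by default, which removes the
  bias completely (noise-free recovery becomes exact for every vertex
  under the cap). Source amplitudes are then in gain-normalized units;
  this is immaterial downstream because ROI signals are re-standardized
  before modeling. The bare `cloreta_transform()` contract stays
  unweighted.
* **Lambda grid.** GCV is invariant to the overall scale of `Phi` (both
  its numerator and the location of its minimum), so the 30-point
  log-spaced lambda grid is anchored to the spectrum of `K L^{-1} K'`
  rather than to the epoch amplitude.

The regularization parameter is selected per epoch: first by generalized
cross-validation (grid minimizer of
`||(I - K T(lambda)) Phi||_F^2 / trace(I - K T(lambda))^2`), then
optionally refined by an expectation-maximization fixed point on the
two-variance-component hierarchical model `Phi = K J + e`,
`e ~ N(0, sigma^2 I)`, `J ~ N(0, tau^2 L^{-1})`, whose evidence-optimal
`lambda = sigma/tau`. The EM updates are computed in the same eigenbasis,
the marginal likelihood is asserted non-decreasing at every step, and a
parameter-recovery simulation (data generated from the model at known
variance ratio) recovers `lambda^2` within a few percent in the median.
Per-epoch re-estimation lets spatial regularization breathe with epoch
amplitude; a property test checks it never degrades average
reconstruction error relative to one global lambda on heteroscedastic
epochs.

Each ROI is collapsed to the time series of its maximum-power gridpoint
(mean squared current, aggregated over all of a subject's epochs by
default, ties to the lowest vertex index). The per-subject scope keeps
the representative gridpoint fixed across epochs, which the
trial-ensemble VAR estimation requires; a per-epoch scope is available
for exploration.

# Sliding-window MVAR modeling

ROI signals are detrended per trial (linear), standardized per trial and
channel, then ensemble-normalized (per-timepoint mean removal and
variance scaling across trials). Models are estimated in sliding windows
(default 550 ms length, 10 ms step at 128 Hz, i.e. 70- and 1-sample
windows) with the Vieira-Morf lattice: order-recursive estimation of
forward/backward reflection matrices under geometric-mean normalization,
with error covariances accumulated *across* the trial ensemble rather
than by concatenating trials (concatenation would fabricate cross-trial
transitions). The lattice is implemented in compiled code and one pass
yields every order up to the maximum, which the order-selection stage
exploits. Estimates agree with an ordinary-least-squares VAR oracle
within sampling tolerance on long single-trial data (tested at orders 1
and 3).

The model order is chosen by evaluating six information criteria (AIC,
corrected AIC, Schwarz-Bayes, Hannan-Quinn, the log of Akaike's final
prediction error, and Rissanen's minimum description length) over orders
1-30, averaging each criterion's curve across windows, taking each
curve's argmin, averaging the six argmins and rounding down. Penalties
use the total sample count `n = N w`; Rissanen's criterion counts the
`M(M+1)/2` innovation-covariance parameters in addition to the `p M^2`
coefficients, which distinguishes its penalty constant from
Schwarz-Bayes. The two conditions select their orders independently.

Validation per window: the log spectral radius of the companion matrix
(negative means stable); percent consistency
`PC = 100 (1 - ||r_sim - r_real|| / ||r_real||)` comparing stacked
auto/cross-correlations (lags 0..p) of the data against a
matched-size ensemble simulated from the fitted model; and residual
whiteness via the autocorrelation band check plus three multivariate
portmanteau statistics (Box-Pierce, Ljung-Box, Li-McLeod) with
`M^2 (h - p)` degrees of freedom and `h = min(20, T/4)` lags. On white
residuals the Ljung-Box test holds its nominal 5% level within +-3
points (tested over 200 replicates); mildly nonlinear data reproduce the
characteristic validation pattern of real EEG current — whiteness fails
while consistency stays around 90%.

# SdDTF connectivity

For each window, the VAR transfer matrix
`H(f) = (I - sum_k A_k e^{-i 2 pi f k / fs})^{-1}`, the cross-spectrum
`S(f) = H Sigma H^H / fs` and the partial coherence
`P_ij = G_ij / sqrt(G_ii G_jj)` with `G = S^{-1}` are evaluated on a
fixed frequency grid (default 2-50 Hz in 1-Hz steps). The SdDTF is

\[
\eta^2_{j\to i}(f,t) \;=\;
\frac{|H_{ij}(f,t)|^2\,|P_{ij}(f,t)|^2}
     {\sum_f \sum_{kl} |H_{kl}(f,t)|^2\,|P_{kl}(f,t)|^2},
\]

the squared-magnitude convention, under which the values sum exactly to
one over all pairs and frequencies within a window (asserted to 1e-10).
A literal variant with an unsquared numerator over the same denominator
is available and flagged in the output metadata; the squared form is the
default because it matches the established SdDTF literature and yields
the exact normalization. The denominator sums over *all* node pairs
including the diagonal; diagonal entries are kept internally (they carry
the normalization mass) and masked when tensors are written, since
self-flow has no physical meaning here.

The partial-coherence factor is what makes the measure *direct*: on a
simulated chain 1 → 2 → 3, the spurious 1 → 3 flow is suppressed by more
than three orders of magnitude relative to a plain DTF computed from the
same transfer matrices (tested). Frequency-specific coupling lands where
it should: a driver resonant at 16 Hz produces an SdDTF peak within 2 Hz
of 16 Hz. Coupling that switches off mid-epoch decays across windows
with the expected window-length lag.

# Group permutation statistics

Per subject and condition, the observed statistic is the SdDTF tensor of
that condition's trial ensemble; the group observed statistic is the
cross-subject mean. The null ensemble mixes conditions: each permutation
replicate draws, without replacement, a trial set of the evaluated
condition's size containing equal numbers of control and test trials
(odd sizes alternate the extra draw), and the full sliding-window
MVAR + SdDTF computation is re-run on it. Replicates are averaged across
subjects position-wise (pairing by replicate index, exchangeable under
the null) and sorted, giving the surrogate distribution at every
(pair, frequency, window) position. P-values are two-sided ranks,
`p = 2 min(r_hi, r_lo) / (R + 1)` capped at one; under the null they are
uniform (KS-tested at 2000 positions). Multiple comparisons are handled
by Benjamini-Hochberg step-up, by default pooled over every off-diagonal
position of a condition's tensor.

One arithmetic constraint matters in small designs: with `R`
permutations the smallest attainable two-sided p-value is `2/(R+1)`, so
a globally pooled step-up over `m` positions can only ever reject if
roughly `2m/(alpha (R+1))` positions carry floor p-values. A single
localized effect can therefore be undetectable under global pooling at
any realistic `R` — not for lack of power but by rank arithmetic. For
that regime the pooling scope is configurable
(`fdr_bh(..., scope = "per_pair")` corrects within each directed pair),
and the planted-edge recovery analysis uses per-pair pooling.

The condition contrast is `masked(test) - masked(control)`: entries that
fail FDR in a condition contribute zero, and positive values mean
stronger connectivity in the test condition. Because the SdDTF is
normalized within windows, planting extra causal mass on one edge
necessarily lowers the relative values of other pairs; difference maps
should be read with that coupling in mind.

# Synthetic cohort

The generator emulates a multi-subject, two-condition reach-vs-lift-style
experiment: nine ROI-anchored source nodes follow a stable VAR(2) with
sparse directed baseline coupling shared by both conditions, plus one
condition-specific planted edge (anterior cingulate → left motor cortex,
coefficient 0.4) active only during the planning regime (the first
500 ms of the epoch); regimes are piecewise-constant coefficient sets
switching at 0.5 s. Trials are independent realizations with Gaussian
innovations and a burn-in of `10 p` samples. Sources project to 64
electrodes (deterministic Fibonacci cap montage) through the spherical
lead field, with white sensor noise at 10 dB SNR. Across subjects,
coupling coefficients are jittered by a ±10% factor drawn once per edge
and shared between the condition networks, so condition-shared edges
stay identical within a subject — independent per-condition jitter would
plant spurious contrasts. Unstable jitter draws are rejected and
resampled. Trial counts default to 96 control / 192 test per subject
and are configurable, so cohorts with other control/test splits (or a
different total) are one argument away. Artifact injection (frontal rank-1 blink transients,
single-channel impulse spikes) is a separate, optional step that gives
the kurtosis-rejection and ICA stages something real to do.

What the generator does **not** emulate: 1/f background spectra beyond
AR coloring, correlated sensor noise, volume-conducted subcortical
sources, electrode digitization error, or nonstationarity beyond the
two-regime coefficient switch. Passing tests on this cohort therefore
demonstrate the pipeline's correctness and calibration under its own
assumptions, not its robustness to every pathology of real EEG.

# Channel cleaning and IC clustering

Band-pass filtering (default 1-55 Hz) uses a Hamming-window linear-phase
FIR kernel applied in a single pass with group-delay compensation —
exactly zero-phase, which matters because phase distortion would
masquerade as time-lagged causality downstream. The kernel length adapts
to the low edge (about `3.3 fs / low` taps, capped by the epoch length).
Average re-referencing, kurtosis-based channel/trial rejection
(|Z| > 5, fully automated with an override list and an audit log), plain
Infomax ICA (logistic nonlinearity, natural gradient on sphered data,
annealed learning rate, deterministic per seed), equivalent-dipole
screening of components (exhaustive scan over mesh gridpoints with the
forward model's radial orientation; retain residual variance <= 0.15),
back-projection of retained components, and anti-aliased integer-factor
downsampling (cutoff 0.42 of the target rate) complete the channel
stage. The downsampling passband is 0-0.42 `fs_new` by design: content
between the cutoff and the new Nyquist (e.g. mains-adjacent 60 Hz when
resampling to 128 Hz) is deliberately attenuated rather than preserved.

For ROI definition from data, each pooled IC is described by seven
feature blocks — scalp map, ERP, log power spectrum, ERSP, ITC,
ERP-image (trials x time resampled to a fixed 16 x 32 grid), and
equivalent-dipole location. Each block is PCA-reduced on the pooled set,
scaled to unit total variance (the blocks have incommensurate units and
no principled relative weighting), concatenated and PCA-reduced again to
10 dimensions. K-means (Lloyd, k-means++ seeding, 20 restarts, best
within-cluster sum of squares, Euclidean metric) with K = 14 groups the
ICs; `K` is exposed and the within-cluster dispersion is returned so
alternative K values can be compared. Cluster centroids are labeled by
the nearest ROI seed; clusters whose member dipoles split substantially
(>= 25%) across a bilateral region pair receive both labels, and merged
midline regions yield a single label by construction. ERSP baselines
default to the full epoch (gain model) and are configurable.

# Problem sizes and determinism

All randomness flows through explicit seeds; subject runs, cohort
generation and the full statistics stage are bit-reproducible. The test
suite and the acceptance script use desk-scale problem sizes chosen to
exercise every code path on one CPU in minutes: the 162-vertex head
model, 24/48 trials per condition, 100-ms window steps (5 windows per
1-s epoch), a 4-Hz frequency grid and 100 permutations for cohort-level
analyses, with the full-resolution defaults (642 vertices, 96/192
trials, 10-ms steps, 1-Hz grid, 300 permutations) retained as package
defaults for real analyses. Planted-edge sensitivity is evaluated over
20 regenerated cohorts.

# Known limitations

* The spherical three-shell head model preserves the structure of the
  inverse problem but not individual head geometry; anatomical accuracy
  of localization is out of scope.
* Fixed radial dipole orientation restricts the current model; oblique
  sources project onto the radial basis.
* The Vieira-Morf lattice is unregularized; the data-to-parameter ratio
  guard (>= 10:1) is a warning, not a cure, for short windows with many
  nodes.
* Linear VAR dynamics cannot capture nonlinear coupling; the whiteness
  tests are expected to flag this on real data (and do so on synthetic
  data with mild nonlinearity) while percent consistency stays high.
* Rank p-values are floor-limited at `2/(R+1)`; see the pooling-scope
  discussion above.
* EDF support is limited to the package's own single-record 16-bit
  writer/reader, intended for interchange of moderate recordings, not as
  a general EDF implementation.
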