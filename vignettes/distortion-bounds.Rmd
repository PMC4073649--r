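---
title: "Bounding the spatial distortion of MEG source images with harmonic anatomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounding the spatial distortion of MEG source images with harmonic anatomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megharmonics)
```

## The model

MEG sensor data are modelled linearly, $Y = KJ + \epsilon$, with $Y$ the
$N_c \times N_t$ channel-by-sample matrix, $K$ the lead field mapping $N_d$
cortical dipoles (fixed orientation, along the outward surface normal) to
the channels, $J$ the source currents, and $\epsilon$ zero-mean Gaussian
sensor noise with covariance $h_0 I$. Sources are a priori zero-mean
Gaussian with covariance $Q$. Two prior families are implemented:

* **MNM** (minimum norm): $Q = h\,I_{N_d}$ — every source equally likely,
  minimal total energy; a single regularisation hyperparameter.
* **MSP** (multiple sparse priors): $Q = \sum_i h_i C_i$, where each
  $C_i = q_i q_i^\top$ is the rank-1 outer product of a connected cortical
  patch profile (Gaussian in geodesic distance, FWHM ~10 mm, truncated at
  3 standard deviations) and most optimised $h_i$ end up at zero.

Given $Q$, the posterior mean current is
$\hat J = Q K^\top (\Sigma_\epsilon + K Q K^\top)^{-1} Y$. Hyperparameters
are optimised by maximising the variational free energy $F$, a lower bound
on $\log p(Y)$ that trades off accuracy against complexity. With fixed
weights and flat hyperpriors $F$ is exactly the Gaussian log marginal
likelihood of $Y$ under $\Sigma = h_0 I + K Q K^\top$ — the correctness
anchor the test suite checks against an independently coded closed form.
With the default log-normal hyperpriors (mean $-8$, precision $1/256$ per
log-weight), a Laplace complexity term (hyperprior energy plus a
posterior-volume term from the Fisher information of the log-weights) is
subtracted, so models that recruit more components pay an Occam penalty.

The ascent runs on $\lambda = \log h$ (guaranteeing positivity) by
Fisher-scored steps with step-halving, accepting only steps that increase
$F$, to convergence at $\Delta F < 10^{-4}$ or 128 iterations. For MSP the
active set is grown greedily: starting from the noise-only model,
candidates are ranked by the estimated free-energy gain of adding them at
the current fit (the squared evidence gradient at zero weight over its
curvature — a matching-pursuit criterion recomputed after every accepted
addition, so sources masked by already-explained variance surface once
their masker is in the model), and an addition is kept only if the
re-optimised $F$ increases. The trial budget, active-set cap and stall
limit are `control` parameters with defaults 32, 12 and 6.

## The harmonic surface family and the distortion bound

Each hemisphere carries a spherical chart $\omega = (\theta, \phi)$ and its
three coordinate functions are expanded in real orthonormal spherical
harmonics (Condon–Shortley phase; $(l, m)$-lexicographic column order):
coefficients are fitted once at $L_{\max}$ per hemisphere and coordinate by
ridge-stabilised least squares (relative ridge $10^{-10}$), and surfaces of
any order $L$ are rebuilt by truncation with degree weights
$e^{-l(l+1)\sigma}$. The default bandwidth is $\sigma = 0$ (pure
truncation): the smoothing kernel of the original weighted-Fourier-series
formulation is available but truncation isolates the effect of harmonic
order, which is the quantity under study. All family members share vertex
count, ordering and topology, so the per-vertex displacement
$d_L[i] = \lVert x_L[i] - x_{L_{\max}}[i] \rVert$ is well defined; the
**spatial distortion** of surface $L$ is the 95th percentile of $d_L$
(linear-interpolation quantile convention, which the formulation leaves
unspecified).

Inverting the same data on every family member yields log evidences
$F_L$. Under flat model priors the pairwise posterior against the reference
anatomy is $p(m{=}L \mid Y) = 1/(1 + e^{F_{\mathrm{ref}} - F_L})$; the
**HDH** is the largest $L$ with $p < 0.05$ (the "20 times less likely"
line). The curve need not be monotone, and the highest sub-threshold order
is taken even when intermediate orders sit above threshold. The HDH
surface's distortion is the empirical bound. Models above the HDH receive a
fixed-effects softmax posterior over summed (pooled) log evidences;
evidence from independent repetitions or data segments pools by elementwise
summation. Per-model posteriors of the per-vertex log power ratio between
two windows (Gaussian approximation around $\hat J$ with the retained
diagonal posterior source variance, integrated by seeded Monte Carlo, 1000
draws by default) combine with those weights into a joint probability of a
power decrease at each vertex within the distortion bound. The choice of a
posterior-variance Gaussian approximation — rather than trial resampling —
for the modulation density is a declared design decision; the original
formulation does not specify one.

## Synthetic anatomy and what it does (not) emulate

No study data are deposited, so the generator replaces the MRI-derived
cortical mesh:

* Each hemisphere is a subdivided icosahedron (level 3, 642 vertices per
  hemisphere at desk scale; 2562 at paper scale) whose three coordinate
  functions are perturbed by seeded band-limited harmonic fields —
  degree-$l$ coefficients i.i.d. normal with standard deviation
  $a_l/\sqrt{2l+1}$, default spectrum $a_l = 12/l$ mm for $l \le 12$ on a
  50 mm base radius, hemispheres offset $\pm 25$ mm laterally. Perturbing
  the *coordinates* rather than the radius keeps the surface exactly
  band-limited at $L_{\mathrm{content}}$ (a radial field multiplies the
  degree-1 direction field and leaks into degree $L_{\mathrm{content}}+1$),
  which is what makes the exact-recovery tests meaningful. The defaults
  give ~7 mm RMS displacement — gyral-scale undulation on a
  hemisphere-scale sphere — with the star-shape guard that the perturbation
  stays below the base radius.
* Sensors are radially oriented point magnetometers on a Fibonacci spiral
  covering 55 % of a 120 mm sphere — not the axial gradiometers with
  synthetic third-order gradiometry of a real acquisition. The framework's
  claims are sensor-agnostic; point magnetometers keep the forward model
  closed-form.
* The conductor is a homogeneous sphere with the exact current-dipole
  solution (radial dipoles silent), not a realistic single-shell model.
  Physical constants are folded into one gain scale (the lead field is
  normalised to unit RMS entry), making SNR handling unit-free.

Consequently, passing tests demonstrate the *machinery* — evidence
arithmetic, distortion geometry, prior-dependent anatomical sensitivity —
under idealised anatomy, sensors and conductor. They do not demonstrate
robustness to coregistration error, conductor mis-specification,
correlated (non-white) sensor noise, or sulcal geometry, none of which the
generator emulates.

## The simulation harness

`run_experiment()` reproduces the study protocol: 3 patch sources drawn
from the MSP library without replacement (or many extentless point sources,
or none), each with a unit-variance white time course of 161 samples at
200 Hz, synthesised into a single trial at 0 dB — the signal scale is set
so the channel-average signal power equals the *nominal* noise variance,
making the ratio exact by construction. Every repetition is inverted on
every family surface under each method; log evidences are pooled over
repetitions; pairwise posteriors, the HDH and its distortion bound are
tabulated per scenario and method.

Two design points deserve emphasis:

* **Shared projection.** Dimensionality is reduced to 60 spatial modes
  (100 at paper scale) from the SVD of the *reference* model's lead field,
  and 16 temporal modes of the projected data. All candidate anatomies in
  one comparison are projected through the same spatial projector — log
  evidences of models seeing different data are not commensurable. Whether
  the original analysis shared projectors is not stated; sharing is the
  choice here because pairwise evidence differences require it.
* **Controls.** The noise-only scenario is reconstructed with MSP; the
  permuted-lead-field control (channel rows of every model's lead field
  permuted by one seeded permutation per repetition, data untouched) is run
  under MNM, matching the original presentation of that control. Under MSP
  the permuted control is *not* flat at 0 dB: the greedy search can exploit
  chance alignments between scrambled lead-field patterns and structured
  data, scattering evidence differences by tens of log units — a known
  limitation of high-dimensional prior optimisation noted in the source
  material's discussion of MSP's flexibility.

Determinism: every stochastic stage derives its seed from the master seed
by a fixed counter scheme (`master + 100000*scenario + 1000*rep + stage`),
so identical configs give bit-identical result tables.

## Numerical choices and problem sizes

* Spherical harmonics via the stable fully-normalised three-term Legendre
  recursion; quadrature orthonormality holds to $10^{-6}$ and better at all
  orders used.
* Degenerate inputs: empty distortion vectors, non-positive-definite
  covariances, sensors inside the source sphere, sources at the conductor
  centre (flagged zero columns), rank-deficient parameterisations and
  over-requested eigenmodes (clipped with a warning) all error or warn
  explicitly rather than propagating silently.
* The desk-scale defaults — 1284 vertices, 128 channels, 128 patches,
  $L_{\max} = 20$, 8 repetitions — were chosen so a full scenario suite
  runs in minutes on one core; paper-scale values (2562-vertex hemispheres,
  274 channels, 512 patches, $L_{\max} = 42$, 100 spatial modes, 16
  repetitions) are reachable through `default_config("paper")`. Vertex
  counts follow icosphere granularity (642/2562 per hemisphere), the
  closest realisable sizes to the nominal targets.
* Discrete vertex normals (area-weighted incident-face average) carry
  $O(\mathrm{edge})$ error at irregular-valence vertices — about
  $3\times10^{-3}$ radians on a 10242-vertex sphere — which is immaterial
  to the forward model but worth knowing when comparing against analytic
  normals.

## Known limitations

Single-subject/random-effects comparison, realistic conductors, EEG lead
fields, temporal priors and beamformer-style inverses are out of scope. The
hyperprior settings and greedy schedule are declared defaults, not values
from the source formulation (which cites external derivations for both).
Explained variance is reported in the reduced space (with a spatial-mode
variant exposed alongside), as the space in which the computation is
defined here.
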