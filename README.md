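# megharmonics

Empirical spatial-distortion bounds for MEG source reconstructions, without
functional ground truth.

## The problem

MEG source imaging converts magnetic fields measured outside the head into
estimates of cortical current flow. Because the inverse problem is
ill-posed, the spatial accuracy of the resulting images is normally
unknowable — the true current distribution is never available. But one thing
*is* known: neuronal currents arise in grey matter, oriented normal to the
cortical sheet. If a functional estimate is accurate, an accurate anatomical
model should support it better than a distorted one; if the estimate is
noise, a brain-shaped cortex should explain it no better than an ellipsoid.

`megharmonics` turns that idea into a quantitative bound:

1. **Harmonic surface family.** Each cortical hemisphere, carried on a
   spherical chart ω = (θ, φ), is expressed as a weighted Fourier series of
   real spherical harmonics S\_lm,

   x(ω) = Σ\_{l≤L} Σ\_{m=−l..l} e^{−l(l+1)σ} f\_lm S\_lm(ω),

   giving a nested family of surfaces from an ellipsoid (L = 1) up to the
   full anatomy (L = Lmax), all with identical vertex count and topology.
   The **spatial distortion** of surface L is the 95th percentile of the
   per-vertex Euclidean displacement d\_L from the full surface.

2. **Bayesian source inversion.** Sensor data Y = KJ + ε are inverted on
   every surface under a parametric-empirical-Bayes model with prior source
   covariance Q = Σ\_i h\_i C\_i — an identity matrix for the minimum-norm
   model (MNM), or an optimised mixture of ~10 mm cortical patch components
   for multiple sparse priors (MSP). Hyperparameters h are optimised by
   variational free energy F ≈ log p(Y), the accuracy–complexity trade-off.

3. **Model comparison.** Under flat model priors, the posterior that
   surface L beats the full anatomy is p(m = L | Y) = 1/(1 + exp(F\_ref −
   F\_L)); a deficit of 3 log units makes a model ~20 times less likely
   (p < 0.05). The **highest distinguishable harmonic (HDH)** is the largest
   L still rejected at that threshold; its spatial distortion is an
   empirical upper bound on the displacement of the functional image.
   Models above the HDH get a fixed-effects (softmax) posterior, which can
   be combined with per-vertex power-modulation posteriors into joint
   statements like "probability 0.94 of a power decrease here, to within
   ±6 mm".

Because no deposited study data exist, the package ships a first-class
synthetic-anatomy module: band-limited two-hemisphere cortices with known
harmonic content, helmet-like Fibonacci sensor arrays, and an exact
spherical-conductor forward model, plus a harness reproducing the
three simulation scenarios (3 smooth patches, many point sources, pure
noise, each at 0 dB SNR) and the permuted-lead-field negative control.

## Worked example

```r
library(megharmonics)

cortex <- generate_synthetic_cortex(n_vertices = 642, seed = 42)
fit <- fit_wfs(cortex, Lmax = 20)
fam <- harmonic_family(fit, c(1, 2, 4, 6, 8, 10, 12, 16, 20))
fam$distortion
#>        L distortion_mm
#>    <int>         <dbl>
#>  1     1      6.95e+ 0
#>  2     2      5.65e+ 0
#>  3     4      3.56e+ 0
#>  4     6      2.50e+ 0
#>  5     8      1.83e+ 0
#>  6    10      1.22e+ 0
#>  7    12      3.72e-10
#>  8    16      3.50e-10
#>  9    20      0
```

The truncated surfaces deviate by up to ~7 mm at L = 1 and become exact at
the generator's content order (12). Running the simulation experiment —
3 patch sources at 0 dB, inverted under both prior sets on every surface,
4 repetitions pooled — takes a few seconds at this scale:

```r
cfg <- default_config(seed = 42)
cfg$L_values <- c(1:6, 8, 10, 12, 16, 20)
cfg$n_repetitions <- 4
cfg$scenarios <- list(scenario_spec("patches"),
                      scenario_spec("noise_only", methods = "MSP"))
run_experiment(cfg)$comparison
#>   scenario   method   hdh indistinguishable distortion_bound_mm map_L
#> 1 patches_3  MSP       10 FALSE                            1.22    12
#> 2 patches_3  MNM        2 FALSE                            5.65     4
#> 3 noise_only MSP        0 TRUE                               NA     4
```

Read: the MSP reconstruction of sparse patch data is sensitive to anatomy —
surfaces up to L = 10 are rejected, bounding its spatial distortion at
±1.2 mm. The minimum-norm reconstruction of the same data barely
distinguishes cortical models (HDH = 2, bound ±5.7 mm), and pure noise
distinguishes none: without useful functional data, no cortical model is
any worse than the true one. `autoplot()` on the experiment draws the
evidence curves; `tidy()`/`glance()` return the result tables.

A thin command-line front end (`inst/cli/megharmonics`) exposes
`synth-cortex`, `decompose`, `simulate` and `report` subcommands over the
same functions.

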