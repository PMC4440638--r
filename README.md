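# binsparse

Hierarchical sparse coding of natural binaural sounds, and the
opponent-channel spatial code it gives rise to.

## What this package is for

In mammalian auditory cortex, sound-source azimuth is represented by
two populations of broadly tuned neurons: tuning peaks crowd the
far-lateral positions (around ±90°) and the steepest tuning slopes sit
at the interaural midline, where localization is behaviorally sharpest.
`binsparse` is for computational neuroscientists who want to study how
this *opponent-channel code* can emerge, unsupervised, from the
statistics of natural binaural sound.

The package implements a two-layer generative model:

1. **Layer 1** learns a complete sparse dictionary of short sound
   epochs, `x_t = Σᵢ cᵢ Θᵢₜ + η`, under a Cauchy prior
   (`E = σ⁻²Σ(x−x̂)² + λΣ log(1+c²)`), then pairs every atom with its
   Hilbert transform. Each ear's epoch is then described by
   non-negative amplitudes `aᵢ` and wrapped phases `φᵢ` per complex
   atom — phase being a sub-cycle temporal displacement, the currency
   of binaural hearing.
2. **Layer 2** jointly encodes concatenated left/right log-amplitudes
   and the interaural phase differences `Δφ = wrap(φ_L − φ_R)` of the
   low-frequency channels (spectral peak < 750 Hz, ≥ 1 cycle per
   epoch):

   ```
   aₙ   = Σᵢ sᵢ Bᵢₙ   + Gaussian noise        (σ₂² = 2)
   Δφₘ  = |w| Σᵢ sᵢ ξᵢₘ + von Mises noise      (κ = 2)
   ```

   with shared sparse coefficients `s` (Cauchy prior, λ₂ = 1) and a
   per-epoch phase multiplier `w` under an approximately uniform band
   prior. The energy minimized by MAP inference is
   `σ₂⁻²Σ(a−â)² − κΣ cos(Δφ−Δφ̂) + λ₂Σ log(1+s²) + λ_w(|w−μ_w|/α)^β`.

Around the model, the package provides a synthetic binaural scene
generator (Woodworth spherical-head ITD, frequency-dependent head
shadow, ambient/transient/harmonic sources; WAV I/O included), the
18-sector circling probe protocol, tuning-curve estimation with k-means
opponent clustering, and Gaussian-classifier population decoding with
confusion-matrix mutual information.

## Worked example

The whole pipeline — synthetic 60 s walk, two-layer training, circling
probe, tuning, clustering, decoding — runs at desk scale in a few
minutes:

```r
library(binsparse)
study <- opponent_channel_study(seed = 1)
print(study)
#> Opponent-channel study (seed 1): T = 64, 32 layer-1 atoms, M = 64
#>   IPD channels: 29; clusters: 31 / 33 units
#>   cluster 1 centroid mean: -90 deg
#>   cluster 2 centroid mean: +93 deg
#>   max-slope positions (|rho|-filtered, n = 18): mode +0 deg, median |.| 20 deg
#>   mean IPD, left-hemifield probes: -0.418 rad
#>   median single-unit MI: 0.05 bits; best population MI: 2.07 bits
```

Reading those numbers: the tuning curves of the 64 learned units split
into two near-equal clusters whose high-activation centroids average
−90° and +93° — one population per hemifield, the opponent-channel
signature. The most frequent maximal-slope position is 0°: sensitivity
to *changes* in position is finest at the interaural midline even
though no unit prefers the midline. Left-hemifield probes drive the
selected low-frequency channels to a negative mean phase difference
(left ear leading). Single units are nearly uninformative about
position (median 0.05 bits of a 4.17-bit ceiling) while the population
read-out, with response averaging, reaches 2.07 bits — spatial
information lives in the population, not the single unit.

Individual stages are ordinary fitted-model objects if you want to
work with them directly:

```r
cfg    <- scene_config(seed = 1)
stream <- make_training_stream(60, cfg)
pairs  <- extract_epochs(stream, T = 64, count = 5000, seed = 2)
mono   <- pool_epochs(pairs)
pca    <- fit_project_pca(mono / sqrt(mean(mono^2)), n_reject = 9)
l1     <- fit_layer1(pca$x, n_atoms = 32, n_iter = 2000, seed = 3)
summary(l1)
plot(l1)                        # atoms with their quadrature partners
sel    <- select_channels(l1)   # low-frequency IPD channels
```

A command-line entry point for the generator alone is included:

```sh
Rscript inst/scripts/simulate.R --mode walk   --seed 1 --duration 60 --out walk.wav
Rscript inst/scripts/simulate.R --mode circle --seed 1 --duration 72 --out circle.wav
```

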