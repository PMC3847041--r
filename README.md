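# adherens

Quantification of adherens junction dynamics from live-cell fluorescence
microscopy.

Cadherins hold epithelial and neuronal tissue together through cell-cell
junctions whose molecular interfaces (the strand-swap *trans* dimer, the
X-dimer intermediate, and the lateral *cis* interface) differ in calcium
sensitivity and kinetics. Experiments probing these interfaces in living
cells produce four kinds of quantitative readout, and this package
implements the complete analysis chain for each:

* **Spectral FRET** — per-pixel linear unmixing of lambda-mode emission
  stacks into donor/acceptor abundances (non-negative least squares against
  reference spectra), then either the acceptor-photobleach ratio
  `(I_postDonor − I_preDonor) / I_postDonor` over a junction ROI, or a
  baseline-normalized acceptor/donor ratio trace around a Ca²⁺-chelation
  event (`FRET_before` / `FRET_after`).
* **Junction tracking** — watershed cell segmentation connected through
  (x, y, t) so every cell keeps one identity, junctions identified as the
  suprathreshold pixels whose two closest cell centers form a given pair;
  the pair key *is* the junction identity, so tracks survive gaps in space
  and time. Derived: junction counts over time, birth frames, lifetimes,
  junction-mean intensity traces.
* **Kinetics** — the three fitted models: constant baseline + linear rise
  (assembly rate, junctions/min), exponential decay to a plateau
  (disassembly τ, min), and constant baseline + rising double exponential
  (spheroid roundness trajectory; τ_fast in h).
* **Spheroid morphometrics** — mask segmentation of transmitted-light
  movies, moment-based roundness `4·Area/(π·major_axis²)`, calcium
  dose-response summaries, straightened cryo-section intensity profiles
  (hollow-core detection) and peripheral laminin intensity.

Because the underlying microscopy is not redistributable, the package ships
a synthetic-microscopy generator for every input class — spectral FRET
scenes, ratiometric series, assembly/disassembly movies, spheroid movies,
section images — with known ground truth and published per-genotype
parameters in a fixture registry (`fixture_params()`), so each estimator is
validated end-to-end by closed-loop parameter recovery.

## Worked example

```r
library(adherens)

## acceptor-bleach FRET on a synthetic wild-type scene (true ratio 0.199)
sc <- generate_fret_scene(scene_params(fret_ratio_true = 0.199,
                                       noise_sd = 0.02, seed = 1))
donor    <- build_reference_spectrum(sc$pre, sc$truth$donor_roi, "donor")
acceptor <- build_reference_spectrum(sc$pre, sc$truth$acceptor_roi, "acceptor")
acceptor_bleach_fret(unmix(sc$pre,  list(donor, acceptor)),
                     unmix(sc$post, list(donor, acceptor)),
                     sc$truth$junction_mask, sc$truth$bleach_roi)
#> Acceptor-bleach FRET: 19.8%  (donor 0.961 -> 1.199)

## disassembly kinetics: movie -> junction-mean trace -> exponential fit
trace <- generate_disassembly_trace(disassembly_params(tau_true = 2.63,
                                                       noise_sd = 0.02,
                                                       seed = 1))
fit_exp_decay(trace, fit_start = 15)
#> FitResult[exp_decay] rss=1.66e-05
#>   plateau=0.8991  amplitude=0.1  tau=2.79  fit_start=15

## junction assembly: movie -> full tracker -> counts and lifetimes
gen <- generate_assembly_movie(assembly_params(rate_true = 0.203, seed = 1))
run <- track_junctions(gen$movie)
curve <- assembly_curve(run$tracks, run$times)
tail(curve$values, 1)
#> [1] 16
```

The bleach ratio (19.8% against a generating 19.9%) is the donor
dequenching fraction at the junction; the fitted τ (2.79 min from a single
noisy 5-min-sampled trace, generating value 2.63) is the junction
disassembly time constant after chelator addition; the count curve feeds
`fit_baseline_linear()`, whose slope is the assembly rate.

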