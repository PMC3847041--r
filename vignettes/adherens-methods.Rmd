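---
title: "Quantifying adherens junction dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying adherens junction dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adherens)
```

# Scope

`adherens` quantifies cadherin-based cell-cell junction behaviour from
live-cell fluorescence microscopy across four assay families: spectral
(lambda-mode) FRET, time-lapse junction assembly/disassembly, and
3D-spheroid morphometrics. Because raw microscopy of this kind is rarely
redistributable, the package pairs every estimator with a synthetic-scene
generator carrying known ground truth, so the whole pipeline is validated by
closed-loop parameter recovery: generate a scene with a known parameter, run
the estimator, compare. This vignette describes the models, the tunable
parameters and their defaults, the numerical choices, and what the synthetic
validation does and does not demonstrate about real data.

# Spectral unmixing and the FRET estimators

Lambda-mode acquisition records, per pixel, emission intensity in spectral
bands (by default twelve 8.7 nm bands from 473 nm, the detection range of
the original acquisitions). With reference emission spectra for the donor
(Cerulean-like, peak ~475 nm) and acceptor (Venus-like, ~528 nm), each
pixel's spectrum $y \in \mathbb{R}^B$ is decomposed as

$$ y \approx S\,c, \qquad c \ge 0, $$

where $S$ holds the unit-norm reference spectra and $c$ the fluorophore
abundances. We solve this per pixel by non-negative least squares rather
than unconstrained regression: abundances are physical intensities, and the
constraint suppresses noise-driven negative excursions in dim regions. The
implementation solves the unconstrained system for all pixels in one pass
and re-solves only pixels with negative coefficients with an active-set
NNLS; tests verify agreement with an exhaustive active-set enumeration to
1e-9. Reference spectra are measured from single-fluorophore junction ROIs
(background-subtracted, L2-normalized); collinear spectra (condition number
above 1e6) are rejected.

Backgrounds are estimated per band as the histogram mode of the dimmest 10%
of pixels — robust to bright foreground and to skew, at the price of being a
global (not local) estimate; scenes with strong shading would need a local
background model, which is out of scope.

**Acceptor-bleach FRET.** Photobleaching the acceptor inside a junction ROI
dequenches the donor; the FRET ratio is

$$ \mathrm{FRET} = \frac{I_\mathrm{post} - I_\mathrm{pre}}{I_\mathrm{post}} $$

over mean unmixed donor abundance in the junction mask. Before computing the
ratio the bleach itself is verified: mean acceptor abundance in the bleach
region must drop by at least 50% (high-power bleaching is near-complete;
the guard catches failed bleaches). The estimator is invariant to global
intensity scaling, and on noiseless synthetic scenes recovers the generating
ratio exactly, because the generator implements precisely the inverse model:
junction donor quenched by $1-E$, acceptor zeroed after the bleach.

**Ratiometric FRET.** For chelation time courses the per-frame
acceptor/donor junction ratio is normalized so the pre-event baseline
averages 100%. `fret_before` is the mean over all pre-event frames;
`fret_after` defaults to the last 25% of frames, by which time the
post-event relaxation (generator time constant 3 s against a 23 s post-event
window) has settled. Both windows are configurable, since summary windows
are a reporting convention rather than a physical quantity. Frames with
non-positive donor mean are flagged and excluded rather than propagated.

# Junction detection and tracking

Junctions are detected and tracked with a cell-pair identity scheme:

1. **Central projection** — per frame, the pixelwise maximum of the two
   z-planes nearest the stack center.
2. **Threshold mask** — Otsu threshold plus removal of components smaller
   than `min_area` (default 5 px). For movies the Otsu level is computed
   once on the pooled movie histogram (`movie_otsu()`): a frame acquired
   before any junction exists has no bright-structure mode, and a per-frame
   level would fall between background and dim membrane, flooding the mask.
3. **Cell segmentation in (x, y, t)** — the marker channel (nuclei where
   available) is smoothed (Gaussian, sigma 2 px), thresholded, and
   distance-transformed; a watershed is computed per frame and basins are
   connected through time by mutual-best pixel overlap between consecutive
   frames. Each connected basin is one cell with one persistent id. Frames
   are stacked at unit spacing along t; with the default 2-min interval this
   corresponds to the 1 px per frame-interval anisotropy convention. When
   two cells merge, the larger-overlap basin carries its identity on and the
   other identity ends; the mutual-best rule prevents retroactive identity
   fusion.
4. **Two-closest-neighbor map** — every pixel is labelled with the unordered
   pair of its two nearest cell centers (ties broken toward ascending id).
   The junction between cells $i$ and $j$ lives in the $\{i,j\}$ region, so
   a junction's identity is the pair key itself: a junction that drops below
   threshold for some frames, or is spatially fragmented, rejoins the same
   track automatically. The per-pixel search is a small C++ kernel; tests
   compare it against a literal per-pixel brute force.
5. **Distance mask** — pixels farther than `max_dist` (default 30 µm) from
   every center are discarded, trimming far-field two-closest regions.
6. **Extraction** — junction pixels per frame are
   `threshold & distance & (pair map = key)`; presence means at least
   `min_area` pixels. Tracks touching the image border, and pairs whose
   cells merge or drop out of the segmentation, are flagged `excluded` —
   the automated counterpart of the manual curation of incomplete or merged
   segmentations that this kind of pipeline otherwise requires.

Derived statistics: the assembly curve (junction count per frame), junction
lifetime (percent of frames present within an observation window, by
convention 60-120 min), and junction-mean intensity traces. Intensity traces
use a holdover rule — frames where the junction is absent reuse the most
recent known pixel set — so disassembling junctions keep a defined trace to
fit.

# Kinetic models

Three models cover the fitted dynamics; all are least squares, and all
profile the nonlinear structure so that only 1-2 parameters are optimized
numerically, with the rest solved linearly:

* **Assembly**: constant baseline then linear growth,
  $f(t) = b + m\,(t - t_0)_+$. The breakpoint $t_0$ is profiled by
  exhaustive discrete search over sample times (each candidate is a closed
  form); tests verify equality with an independent `lm()`-per-candidate
  search. The slope $m$ is the assembly rate in junctions/min. Discrete
  profiling means a breakpoint between samples is rounded to a neighbor —
  at the assays' native sampling this is well below other error sources.
* **Disassembly**: $I(t) = I_\infty + A e^{-(t-t_\mathrm{start})/\tau}$ for
  $t \ge t_\mathrm{start}$. For fixed $\tau$ the model is linear in
  $(I_\infty, A)$, so $\tau$ is optimized on a log scale from multiple
  log-spaced starts (1, 5, 20, 80 sampling intervals), keeping the best RSS:
  exponential fits are initialization-sensitive and this multi-start
  reliably escapes shallow minima. `fit_start` defaults to the chelation
  event; a construct whose decay starts late is handled by shifting
  `fit_start` by the onset lag (the registry stores a 10-min lag for the
  X-dimer-deficient mutant, generalizing that one-off adjustment into a
  config field). Rising or flat traces leave $\tau$ unidentifiable and are
  reported `converged = FALSE` rather than with a spurious constant.
* **Spheroid formation**: constant baseline then a rising double
  exponential,
  $R(t) = R_\infty - A_f e^{-(t-t_0)/\tau_f} - A_s e^{-(t-t_0)/\tau_s}$,
  fitted up to `t_max` (20 h by convention); continuity at $t_0$ ties the
  baseline to $R_\infty - A_f - A_s$. $(\tau_f, \tau_s)$ are optimized with
  the three linear parameters profiled out, from a small grid of starts,
  with a dense local re-scan of breakpoint candidates around the coarse
  winner. $\tau_f$, the fast constant, summarizes formation speed;
  $\tau_s$ is reported but weakly identified when it approaches the fit
  window, which is expected and harmless for the fast-constant readout.
  Fits where $\tau_f$ and $\tau_s$ collapse within 5% of each other are
  flagged unidentifiable.

All fits are equivariant to affine rescaling of the value axis (parameters
transform correspondingly), verified by property tests.

# Spheroid morphometrics

**Roundness** is the moment-based shape descriptor
$4A/(\pi\,\mathrm{major}^2)$, where the major axis is that of the
second-moment-equivalent ellipse ($\mathrm{major} = 4\sqrt{\lambda_
\mathrm{max}}$). It is 1 for a disk, $b/a$ for an ellipse, $3/\pi$ for a
square, rotation- and scale-invariant within discretization tolerance
(±0.02), and insensitive to boundary roughness — appropriate for compacting
aggregates. The exact descriptor used by the original acquisition software
is not documented, so absolute values are calibrated through the fixture
registry while comparisons between genotypes are robust to the choice;
circularity $4\pi A/P^2$ is provided as an alternative in
`spheroid_metrics()`.

**Segmentation** of transmitted-light spheroid frames is a deterministic
threshold/morphology chain (Otsu, closing, hole filling, largest component
above a minimum size) with a contrast guard that rejects frames whose
fore/background separation is within twice the pooled class spread —
frames without an object otherwise split their own noise. A trained pixel
classifier could substitute here; downstream metrics depend only on the
mask. Failed frames are flagged and linearly interpolated; more than 50%
failures is a quality error.

**Cryo-section profiles.** Sections are straightened along three diameters
through the mask centroid (0/60/120 degrees — "three axes" fixed as the
symmetric choice), sampling a 99-px-wide perpendicular band, binning into
100 bins along the axis and normalizing to the profile maximum. With 100
bins, bins 30-50 form the central band used to detect hollow cores; on
noiseless synthetic sections the hollow flag is perfectly classified by
thresholding the central-bin level at 0.5. Peripheral laminin is measured
over a morphological ring (mask dilated minus eroded), with laminin-positive
pixels detected by Otsu inside the ring and their background-subtracted mean
reported, so the measure is independent of the ring width chosen.

# The synthetic-scene generators

Each generator renders the minimal scene its estimator needs, carries its
generating parameters as ground truth, and is bit-reproducible under a
seed. Camera noise is Gaussian with sd proportional to the signal (a
shot-noise approximation) plus a constant read-noise floor; noise is
per-pixel, so junction-mean traces inherit noise reduced by the square root
of the junction pixel count, exactly as in the real assays. Emission
spectra are Gaussians (donor 475 nm, acceptor 528 nm, sd 25 nm) — the
simplest shape preserving realistic spectral overlap, since only the
detection range of the original experiment is known.

Defaults mirror the study conditions: 2-min frames for 2 h assembly movies
(30-min baseline before the first junctions), 5-min frames with a 15-min
baseline for 75-min disassembly movies, 5-min frames for 48-h spheroid
movies, 100-ms-scale ratiometric sampling over 35 s with the chelator at
12 s, 512-px/106-µm lambda geometry. Values not reported anywhere —
camera noise level, junction signal-to-background, spheroid starting
roundness and time constants — are free parameters fixed once at realistic
levels (2% multiplicative noise; junction:membrane:background about
1:0.12:0.02; wild-type spheroid start 0.15, tau 1.5 h and 10 h) and
recorded in the fixture registry (`fixture_registry()`), which otherwise
transcribes the published per-genotype summary statistics.

Specific modelling choices:

* **Assembly movies** place stationary cells on a jittered square grid
  (default 25 cells, 128x128 px); junction births are an inhomogeneous
  Poisson process whose intensity is `rate_true / presence_fraction` after
  the baseline, so that the presence-thinned *observed* count grows at
  `rate_true` — the quantity the count-curve slope estimates. Born
  junctions are present per frame with probability `presence_fraction`,
  which both exercises track-identity persistence through gaps and makes
  the lifetime statistic's ground truth explicit. Eligible junction sites
  are rook-adjacent cell pairs (40 for the default grid), comfortably above
  the ~22 expected births so site exhaustion is negligible. Cells do not
  move: motility would exercise the watershed tracking more strongly
  (drifting and merging cells are covered by dedicated tests instead) but
  would make birth-time ground truth ambiguous. The z-stack is rendered
  with 2 planes (the two the central projection uses); synthetic scenes are
  optically flat, so additional planes add data volume without information.
* **Spheroid movies** render an ellipse of constant area whose axis ratio
  equals the target roundness (for an ellipse the moment-based roundness
  *is* the axis ratio, making the trajectory controllable in closed form),
  decorated with small 5-fold lobes that shrink as compaction proceeds; the
  rendered-mask roundness tracks the declared baseline-plus-double-
  exponential trajectory within 0.02. External calcium maps to the
  roundness plateau through a declared logistic
  (`ca_roundness_map()`: lo 0.012, hi 0.623, midpoint 0.029 mM, scale
  0.25 mM), calibrated once against the published wild-type 20-h dose
  series and then frozen.
* **Section images** are a line lattice filling a disk (annulus when
  hollow, inner radius 0.75 of the section radius so the hollow core is
  wide relative to the 99-px straightening band) plus a peripheral laminin
  ring.

**What the closed loop shows — and what it does not.** Passing closed-loop
recovery demonstrates that the estimators are consistent and unbiased under
the generative model and the published acquisition geometry, and that the
full chains (rendering, segmentation, tracking, fitting) compose correctly.
It does not demonstrate robustness to everything real microscopy adds:
uneven illumination, focus drift, motile and dividing cells, autofluorescent
debris, bleaching of the imaging fluorophore itself, or spectral bleed
beyond the two-fluorophore model. The exclusion heuristics and guards
(bleach verification, contrast guards, merge flagging) are the designed
entry points for such data, but their thresholds would need tuning on real
material.

# Problem sizes

The validation protocols run at the published ensemble sizes where these
are stated — 35/32/29/33/8 acceptor-bleach scenes per genotype, 8
ratiometric series, 50 disassembly traces, 200 assembly fields of view, 50
lifetime tracks, 10 spheroid movies plus 4 per calcium dose — on desk-scale
images (64-256 px). Unit and property tests use smaller instances of the
same protocols.
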