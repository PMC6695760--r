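---
title: "Models and methods behind pmspt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pmspt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pmspt` implements the quantitative readouts used to characterize
plasma-membrane (PM) receptor dynamics in live-cell fluorescence
microscopy: single-particle tracking (SPT) of TIRF movies with
MSD-based diffusion estimation, membrane dwell-time measurement,
confocal internalization quantification, and FLIM-FRET lifetime
analysis. This vignette records the models, the estimators, the default
parameters, and the design decisions taken where the methodology was
genuinely open — together with what the simulation-based validation does
and does not establish.

## The synthetic-microscopy simulator

No raw data of this kind is bundled; instead every analysis stage is
validated against a simulator whose hidden state is known exactly.

**TIRF movies** (`simulate_tirf_movie`). Particles appear by a
memoryless Poisson birth process (`birth_rate_per_frame`), live for
exponentially distributed dwell times (`dwell_mean_s`), and perform 2D
Brownian motion with per-axis step variance $2D\Delta t$. Each live
particle is rendered as a pixel-integrated Gaussian PSF
(`psf_sigma_px`, default 1.2 px) carrying `photons_per_spot` expected
photons per frame; the camera model is
$\mathrm{Poisson}(\lambda) + \mathcal{N}(0, \sigma_\mathrm{read})$,
clipped at zero and quantized to 16 bit. Particles that step outside
the field are killed and recorded as deaths — simpler bookkeeping than
reflection, and irrelevant to interior statistics. Defaults follow the
imaging regime the analyses target: frame interval 0.15 s, pixel size
0.1 μm (a typical EM-CCD/100× combination; the pixel size is a
convention, all outputs are calibrated through it), $D = 2\times10^{-3}$
μm²/s, mean dwell 2 s. An alternative 1.5 s frame interval is sometimes
quoted for this kind of acquisition; the interval is an explicit
parameter everywhere and nothing in the package assumes either value.

**Confocal stacks** (`simulate_confocal_stack`). A cylindrical cell:
every body slice carries a bright PM wall ring plus cytoplasmic puncta,
with the per-slice photon budget split so that a fraction
`internal_fraction` of the noiseless signal is cytoplasmic — in each
slice and in the whole volume. Membrane and cytoplasm components are
rendered and blurred separately, so the recorded truth fraction is exact
up to kernel edge losses. The cylindrical geometry is a deliberate
simplification: it makes the sub-stack ratio measured at depth equal to
the volume-level truth, so recovery errors measure the estimator, not
the cell shape. Puncta keep a 12-px margin from the wall so membrane and
cytoplasmic photons stay separable after blur, as endosomes and cortex
are at real confocal resolution.

**TCSPC decays** (`simulate_flim`). Per-pixel photon counts are Poisson;
arrival times are exponential with the pixel's true lifetime, truncated
to the acquisition window (default 25 ns, 250 bins) by inverse-CDF
sampling, then binned. No instrument response function is modelled; the
truncation is the only departure from a pure exponential and the fitting
side handles it analytically.

All randomness in one simulation call flows from a single seed;
identical parameters and seed give bit-identical stacks and truth
records.

## Spot detection and linking

Detection is Laplacian-of-Gaussian band-passing at the PSF scale,
strict 8-neighbour local maxima, and least-squares 2D Gaussian
refinement (amplitude, subpixel centre, width, offset) in a
$(4\sigma+1)^2$ window. Two filters make the detector robust at
single-molecule SNR:

* the fitted width must fall in $[0.78, 1.5]\times$ the PSF sigma —
  single-pixel noise spikes fit arbitrarily narrow Gaussians with large
  amplitudes and would otherwise pass any amplitude threshold, while
  real spots at realistic photon counts fit within a narrow band around
  the true PSF scale;
* the SNR is the fitted amplitude over a robust (MAD) estimate of the
  fit residuals in the window annulus more than $2\sigma$ from the
  centre: the annulus excludes the spot's own shot noise, and the MAD
  keeps a neighbouring spot clipping the window corner from
  masquerading as background noise.

Linking is greedy nearest-neighbour with gap closing: candidate pairs
are gated at `max_disp_px` per frame step (a $g$-frame gap scales the
gate to $g\,\cdot$`max_disp_px`), sorted by distance with deterministic
tie-breaks (distance, then track id, then detection id), and assigned
one-to-one. This is intentionally simpler than full multiple-hypothesis
cost-matrix tracking: at the sparse densities the analyses target
(~$10^{-3}$ spots/px²), the downstream statistics are insensitive to
linker sophistication, and the determinism makes results reproducible
to the bit. There is no merge/split handling; simulated particles do
not merge. Detection validation runs at a few $10^{-4}$ spots/px²:
above roughly $2\times10^{-3}$ spots/px² an increasing share of spots
has a neighbour within the PSF overlap radius, and no single-emitter
detector can separate them — losses there reflect geometry, not the
implementation.

## MSD, diffusion coefficient, motion range, population peak

`compute_msd` is the time-averaged (within-trajectory) MSD: for lag
$k$, the mean squared displacement over all localization pairs exactly
$k$ frames apart. Pairing is on true frame numbers, so gap-closed
missing frames simply contribute no pairs. `fit_diffusion` fits an
ordinary least-squares line with free intercept through the first
`n_lags` MSD points; $D$ = slope/4 for 2D diffusion, and the intercept
absorbs (and estimates) static localization noise. Negative slopes are
clamped to $D = 0$ and flagged rather than dropped, keeping population
counts interpretable.

Two numerical choices matter and are worth recording:

* **`n_lags` defaults to 2.** For pure Brownian motion with small
  localization error, two fitting points minimize the variance of the
  short-lag slope estimate (the classic optimal-fit-length result for
  MSD fitting); more lags add strongly correlated, high-variance points
  that widen — and skew — the per-trajectory $D$ distribution.
* **Population summaries use tracks with ≥ 15 localizations.** The
  per-trajectory $\hat D$ distribution is right-skewed for short
  tracks, so the *peak* $\hat G$ of a Gaussian fitted to its histogram
  sits well below the true $D$ even though the mean is unbiased; at 15+
  frames the skew is mild and $\hat G$ recovers the simulated $D$
  within ~10% (truth positions) and ~15% (full pipeline), as the
  acceptance suite verifies. Both choices are configurable
  (`trajectory_dynamics(n_lags =)`, `dynamics$min_track_frames` in the
  pipeline configuration).

`motion_range` is the maximum pairwise distance among a trajectory's
positions. `fit_population_peak` histograms a per-trajectory statistic
(Freedman–Diaconis binning by default; the bin rule is overridable),
fits a single Gaussian to bin centres/counts by least squares, and
reports the fitted mean as $\hat G$. A single population is assumed, as
in the analyses this mirrors; the fit RMSE is reported so poor
single-Gaussian descriptions are visible, and degenerate (zero-width)
or scant (< 50 values) inputs are refused rather than fitted.

Trajectory pooling: population fits pool trajectories across the field
of view (the per-cell averaging used in figure-level statistics is
available by running conditions separately and comparing with
`compare_conditions`).

## Dwell times

The dwell of a tracked particle is measured from its normalized
fluorescence trace: the longest contiguous run above `threshold_frac`
(default 0.5, the half-maximum convention) times the frame interval.
The estimate is invariant to positive scaling of the trace. Runs
touching the first or last frame are flagged censored and excluded from
means (counted separately). Two systematic effects and their handling:

* frame discretization adds about half a frame interval (+0.075 s at
  0.15 s) to the mean — negligible against the 2 s scale;
* *excluding censored tracks biases the mean low*, because long dwells
  are the ones that hit the recording end. At a 15 s recording with a
  2 s mean dwell this bias is ~15%; dwell-recovery simulations
  therefore use a 60 s (400-frame) observation window, where it falls
  to ~3%. Kymographs (`build_kymograph`: bilinear line sampling,
  averaged over a perpendicular width) are provided as the
  visualization and cross-check; the dwell statistic itself comes from
  trajectories, which carry the same information without manual band
  measurement.

## Internalization

`select_analysis_slices` locates the apical surface (first slice whose
mean exceeds the dimmest slice's mean by a configurable factor) and
keeps slices 2–3 μm below it (defaults; 0.5 μm steps are typical).
`internalized_fraction` is background-subtracted cytoplasm intensity
over whole-cell intensity, averaged per slice (so each optical section
weighs equally; pooled summation is available). Background is the mode
of pixels outside the cell mask — robust to sparse bright debris.

Masks are an explicit input, as they are in practice (hand-drawn or
threshold-derived ROIs). `segment_cell` provides automatic Otsu
segmentation with morphological closing and hole filling; its PM ring
defaults to 8 px so it covers a few-pixel membrane plus its PSF-blur
tails — with a narrow ring, blurred membrane photons land in the
cytoplasm mask and inflate the fraction. Automatic segmentation needs a
visible membrane: in the degenerate all-internalized limit there is no
membrane signal to segment, so validation of that limit uses
geometry-derived masks while membrane-visible fractions are validated
with the automatic path as well.

## FLIM-FRET

`fit_pixel_lifetime` maximizes the multinomial likelihood of the binned
counts under an exponential truncated to the window — binning and
truncation are part of the model, so the estimator needs no tail-start
or IRF heuristics and corrects the downward bias of the naive
mean-arrival-time estimate ($W e^{-W/\tau}/(1-e^{-W/\tau})$, about
0.34 ns at an 8 ns window for τ = 2.5 ns; `truncated_exp_mean` gives
the closed form). A log-linear least-squares fallback is kept as a
cross-check. Pixels under `min_photons` (default 100, a stability
floor) are flagged unfit, not errors. ROI averages are photon-weighted
so dim pixels do not dominate. Lifetime maps render on an absolute
navy→red scale fixed at 2.1–2.7 ns: the same τ always maps to the same
color, out-of-range values clamp, unfit pixels are black.

FRET efficiency is $E = (1 - \tau_{DA}/\tau_D)\times 100$, the standard
lifetime-based form. Negative values (τ recovering toward the donor
value) are reported and flagged, not suppressed — they are the
diagnostic for dissociation-type experiments. Only monoexponential
decays are modelled; bound/free bi-exponential mixtures and phasor
analysis are out of scope.

## Condition comparison and reproducibility

`compare_conditions` reports per-condition mean ± SD and n, and
pairwise Welch two-sample t-tests with Holm correction. Welch is used
deliberately (treatment arms rarely share variances), and no
multiple-range procedure is implemented — pairwise Welch + Holm is the
better-specified replacement. The replicate unit (particle, cell,
seedling) is the caller's choice: the function takes per-replicate
values per condition and does not guess the hierarchy.

`run_pipeline` ties simulate → track → dynamics → dwell together per
condition and writes a manifest (package version, seed, full
configuration, MD5 checksum of every output). A run can be re-executed
from its manifest alone and verified checksum-for-checksum; the test
suite asserts bit-identical repeats.

## Problem sizes and limitations

Validation simulations are sized to keep the full suite fast while
leaving the statistics well-determined: diffusion recovery uses a
128×128 px, 500-frame movie yielding 500+ usable tracks; dwell recovery
uses 1500 traces per condition; detection quality ~600 spot
instances; FLIM maps 36–64 pixels at 10⁴ photons each. These sizes are
stated here as the package's validation design.

What passing these simulations does **not** show: robustness to
non-Brownian motion (confinement, flow, hop diffusion), photobleaching
and blinking, spatially varying background, cell-shape irregularity,
multi-exponential decays, or instrument response functions — none of
which the generator emulates. The package measures what the models
describe; on real data those effects need checking before the numbers
are taken at face value.
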