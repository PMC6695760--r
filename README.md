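# pmspt — plasma-membrane single-particle tracking and receptor dynamics

`pmspt` quantifies the membrane dynamics of fluorescently tagged
plasma-membrane (PM) receptors from three kinds of light-microscopy data,
the way they are measured in plant G-protein signalling studies (e.g.
hormone-induced endocytosis of a 7TM regulator and its dissociation from
the Gα subunit):

* **TIRF time-lapse movies** — diffraction-limited spots are detected with
  subpixel 2D-Gaussian fits, linked into trajectories, and summarized by
  the time-averaged mean square displacement `MSD(kΔt)`, the diffusion
  coefficient `D = slope/4` of the short-lag MSD–t line, the motion range
  (largest displacement during the particle's lifetime), and the peak `Ĝ`
  of a Gaussian fitted to the per-trajectory histogram — the population
  summary used for treatment comparisons.
* **Membrane dwell times** — the residence time of a particle on the PM,
  read from kymographs or directly from trajectory lifetimes; the trace
  operationalization is the longest contiguous run above half-maximum of
  the normalized fluorescence trace times the frame interval.
* **Confocal Z-stacks** — the internalized fraction of a PM protein, as
  background-subtracted cytoplasm intensity over whole-cell intensity in
  optical sections 2–3 μm below the apical surface.
* **FLIM-FRET** — per-pixel monoexponential lifetimes `τ` fitted by
  maximum likelihood on binned, window-truncated TCSPC histograms;
  photon-weighted ROI means; fixed-scale (2.1–2.7 ns, navy→red) lifetime
  maps; and FRET efficiency `E = (1 − τ_DA/τ_D) × 100`.

Because raw microscopy of this kind is rarely deposited, the package ships
a **synthetic-microscopy simulator** with exact ground truth: membrane
particles undergoing 2D Brownian diffusion (per-axis step variance
`2DΔt`) with exponential dwell times, rendered as Gaussian PSFs under
Poisson + read noise; confocal cell volumes with a controllable
internalized signal fraction; and truncated-exponential TCSPC decays.
Every analysis stage is validated by recovering the simulator's hidden
parameters.

## Worked example

```r
library(pmspt)

params <- tirf_sim_params(field_size_px = c(96, 96), n_frames = 150,
                          diffusion_um2_s = 2e-3, dwell_mean_s = 2.0,
                          birth_rate_per_frame = 1.5, seed = 7)
sim <- simulate_tirf_movie(params)
sim$stack
#> image_stack: 150 frame(s) of 96 x 96 px, 0.1 um/px, dt = 0.15 s
#>   intensity range [0, 104]

traj <- track_movie(sim$stack, psf_sigma_px = 1.2, snr_threshold = 5)
traj
#> trajectories: 159 track(s), 2422 localization(s), dt = 0.15 s

dyn <- trajectory_dynamics(traj)
fit_population_peak(dyn$D_um2_s[dyn$n_frames >= 15], "diffusion_coefficient")
#> population_fit (diffusion_coefficient): peak = 0.001929, width = 0.0009934, n = 65, fit RMSE = 0.879

dw <- dwell_from_trajectories(traj, n_frames(sim$stack))
summarize_dwell(dw, "CK")
#> dwell [CK]: 2.23 +/- 1.59 s (n = 122, 37 censored excluded)
```

The population peak recovers the simulated `D = 2×10⁻³ μm²/s` to within a
few percent, and the mean dwell of uncensored tracks sits near the
simulated 2 s exponential mean. The FLIM side works the same way:

```r
fl  <- simulate_flim(flim_sim_params(2.53, map_size_px = c(8, 8),
                                     photons_per_pixel = 1e4, seed = 7))
roi <- roi_lifetime(fit_lifetime_map(fl))
sprintf("ROI lifetime: %.3f +/- %.3f ns", roi$mean_ns, roi$sd_ns)
#> "ROI lifetime: 2.532 +/- 0.025 ns"
fret_efficiency(roi$mean_ns, 2.36)
#> 6.797...   # percent
```

A command-line umbrella lives at `inst/cli/pmspt.R`
(`simulate | track | dynamics | dwell | internalize | flim | compare | run`),
and `run_pipeline()` executes simulate → track → dynamics → dwell for
several conditions, writing a manifest (seed, parameters, MD5 checksums)
that makes runs reproducible bit for bit.

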