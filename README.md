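# moltrack

Single-molecule tracking, photobleaching-based molecular counting and
two-colour colocalisation for fluorescence image stacks.

`moltrack` is for microscopists who acquire rapid-photobleaching widefield
image sequences of fluorescently tagged proteins and want numbers out: how many labelled molecules are in each diffraction-limited
assembly, whether the assembly population has an oligomeric repeat unit,
how fast assemblies move, how many molecules a nucleus holds, and whether
tracks in two colour channels sit on top of each other more often than
chance allows.

## The method in brief

A focus in frame *t* is a local intensity maximum measured by aperture
photometry: integrated intensity *I* inside a 5 px radius mask, background
from the remainder of a 17 × 17 px window, and a per-pixel signal-to-noise
ratio

    SNR = (I / n_mask) / sd(background)

so a single YFP of characteristic brightness *B* = 76 photons spread over a
~30 px footprint on a 26 photons/px autofluorescent background is expected
at SNR = (76/30)/sqrt(26) = 0.50. Foci are refined to sub-pixel precision
by iterative elliptical Gaussian masking, linked into tracks
(nearest suitable neighbour within 8 px, width ratio 0.5–2, intensity
ratio 0.5–3), and sifted: at least 3 consecutive foci and mean SNR above a
threshold calibrated from single-molecule and noise-only controls.

Counting is ratiometric: *B* is the modal Chung–Kennedy-filtered terminal
intensity of tracks that bleach to their last step, and the stoichiometry
of a track is *S* = *I₀*/*B*, with *I₀* extrapolated from its first five
foci back to the first exposure. Periodicity of a stoichiometry
distribution is the modal nearest-neighbour interval between kernel
density peaks, calibrated against 100 simulated aperiodic sets (uniform on
1–30 molecules, 95th-percentile null). Diffusivity is a quarter of the
initial MSD slope; two foci colocalise when their Gaussian intensity
overlap is ≥ 50% (~3 px) within 7 px for ≥ 3 frames, against a
`1 − exp(−λπr²)` chance expectation. Brunner–Munzel and Fisher exact tests
cover the inference. A full image simulator (Brownian assemblies, stepwise
per-fluorophore bleaching, Poisson + read noise, affine camera) provides
ground truth for every stage.

## Worked example

Calibrate brightness on a sparse single-molecule control, then count
molecules in simulated dimer-built assemblies:

```r
library(moltrack)
cam <- camera_model(gain = 0.6, offset = 100)

ctrl <- simulate_single_molecule_control(n_emitters = 14, brightness = 76,
  background = 2, bleach_prob = 0.03, n_frames = 150, field_size = 96,
  camera = cam, seed = 2)
ctrl_tracks <- track_stack(ctrl$stack, camera = cam, snr_threshold = 0.4)
(B <- estimate_characteristic_brightness(ctrl_tracks))
#> characteristic molecular brightness: 79.7 +/- 1.1 photons/frame (n = 35 tracks)

sim <- simulate_stack(sim_params(
  n_assemblies = 12, stoichiometry = list(subunit = 2, mean_multiple = 4),
  brightness = 76, background = 5, bleach_prob = 0.02, diffusivity = 0.05,
  n_frames = 60, field_size = 96, camera = cam), seed = 7)
tracks <- track_stack(sim$stack, camera = cam, snr_threshold = 0.4)
length(unique(tracks$track_id))
#> [1] 16

S <- vapply(split_tracks(tracks), function(tr)
  if (nrow(tr) >= 3 && min(tr$frame) <= 3) stoichiometry(tr, B$B)
  else NA_real_, 0)
mean(S, na.rm = TRUE)     # molecules per assembly (simulated truth: 7.5)
#> [1] 5.8

D <- vapply(split_tracks(tracks), function(tr)
  if (nrow(tr) >= 5) as.numeric(diffusivity(tr, 53, 10)) else NA_real_, 0)
median(D, na.rm = TRUE)   # um^2/s (simulated truth: 0.05)
#> [1] 0.048
mean(matches_reference(D[!is.na(D)]))  # none at the 0.20 +/- 0.07 reference
#> [1] 0
```

The recovered brightness is within 5% of the simulated 76 photons/frame;
the mean stoichiometry of early-starting tracks underestimates the true
7.5 because some fluorophores bleach before the first detection — the
known late-start bias the package flags. Periodicity analysis of a
population of such stoichiometries (`periodicity_analysis()` against
`null_threshold()`) recovers the dimeric repeat; see the vignette.

## Documentation

The methods vignette (`vignettes/molecular-counting.Rmd`) describes the
models, parameter choices, calibration logic, simulator assumptions and
known limitations. Every exported function carries roxygen documentation.
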