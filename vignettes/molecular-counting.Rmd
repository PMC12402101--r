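---
title: "Counting molecules in tracked assemblies: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting molecules in tracked assemblies: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moltrack)
```

# The measurement problem

`moltrack` analyses rapid-photobleaching fluorescence image sequences in
which individual protein assemblies appear as sub-diffraction foci. From a
short movie (tens to hundreds of frames at ~10 ms exposure) it extracts,
per tracked assembly: the number of labelled molecules (stoichiometry), the
diffusion coefficient, and — across a population of assemblies — the
oligomeric repeat unit of the stoichiometry distribution. Nucleus-level
totals (protein copy number, concentration) and two-colour colocalisation
complete the picture. Everything is testable against a bundled simulator
that generates image stacks with per-fluorophore ground truth.

The processing chain is: camera counts → photons → per-frame focus
detection → frame-to-frame linking → track sifting → intensity analysis
(brightness calibration, stoichiometry) → population analyses
(periodicity, mobility, quantification, colocalisation).

# Camera model and units

Pixel values are converted with the affine detector response
`photons = (counts − offset) × gain` (defaults: gain 0.6 photoelectrons per
count, offset 100 counts, matching a back-illuminated sCMOS in 16-bit
mode). Photoelectrons are reported as photons, the convention used when
brightness is printed as "photons (counts)"; quantum efficiency is not
re-applied. Brightness values quoted as background-subtracted are converted
with the gain alone, because the offset cancels in the subtraction — this
is what makes 140 counts correspond to 84 photons and 172 counts to 103.2.
Negative photon values after conversion are preserved so that background
statistics remain unbiased.

Coordinates are 0-based with `(x, y) = (column, row)` and pixel centres at
integers; sub-pixel positions are continuous.

# Detection and photometry

Candidate foci are strict 8-connected local maxima of a lightly smoothed
copy of the frame (Gaussian, 1 px) — smoothing only steers the search; all
photometry uses the raw frame. Each candidate is measured by aperture
photometry: the intensity `I` is the pixel sum inside a circular mask of
radius 5 px minus the mask area times the mean of the background region,
which is the remainder of the 17 × 17 px window. The signal-to-noise ratio
is the per-pixel form

```
snr = (I / n_mask) / sd(background)
```

The per-pixel normalisation is chosen over total-intensity-over-sd because
it reproduces the worked expectation for a single YFP: 76 photons spread
over an effective 30 px footprint on a 26 photons/px Poisson background
gives `(76/30)/sqrt(26) = 0.50`, the scale on which the 0.35–0.50 sifting
thresholds live. The total form remains available behind
`snr_mode = "total"`. Note the distinction between the integration mask
(radius 5, ~81 px) and the effective signal footprint (~30 px): the mask is
deliberately generous so that `I` is aperture-complete.

Candidates whose 17 × 17 window leaves the frame are discarded; maxima
closer than the integration radius are merged to the brighter one.
Candidates above a permissive SNR of 0.2 are refined to sub-pixel precision
by iterative Gaussian-mask centroiding (mask sigma starts at the nominal
PSF sigma; convergence when the centroid moves < 0.01 px, cap 20
iterations; non-converged candidates are dropped). Elliptical semi-axes are
estimated from mask-weighted second moments with the mask-induced shrinkage
inverted analytically (`v = s²w²/(s²+w²)` for signal width `s` under mask
width `w`). On simulated spots this agrees with a full nonlinear
least-squares Gaussian fit to within 5%, at a small fraction of the cost,
and per-axis localisation error tracks `sigma_PSF/sqrt(N)` within a factor
of about 1.5.

# Linking and sifting

Foci in consecutive frames are linked when centroids lie within 8 px, the
width ratio (new/old, mean of the semi-axes) is in [0.5, 2] and the
intensity ratio (new/old) in [0.5, 3]. Candidate links are resolved
greedily in ascending distance ("nearest suitable neighbour"); each focus
joins at most one track; there is no gap closing — "consecutive" is read
literally. The ratio bands are directional as stated; a symmetric variant
is available via `symmetric_ratios = TRUE`.

Sifting keeps tracks with at least 3 consecutive foci and mean focus SNR
above the strict threshold. The mean was chosen as the per-track aggregator
(the alternative — minimum, or all-foci-above — is stricter than the way
per-track SNR is reported downstream). The strict threshold itself is
calibrated from controls by `determine_snr_threshold()`: scan thresholds
over the observed range and return the value where retained tracks per
acquisition are equally frequent in a single-molecule positive control and
a noise-only negative control (linear interpolation at the crossing, ties
toward the higher threshold; fully separated controls return a flagged
midpoint). Under the default simulated conditions this lands in the
0.35–0.50 working band.

# Brightness, stoichiometry and photobleaching

The characteristic molecular brightness `B` — photons per frame from one
fluorophore, the unit step of photobleaching — is the mode of a kernel
density over Chung–Kennedy-filtered terminal track intensities. The CK
filter replaces each point with a variance-weighted blend of backward and
forward window means (window `W = 10` samples, weight exponent `p = 2`,
inverse-variance to the power `p`; both unstated in the source method and
exposed in the API), which smooths flat stretches while leaving ideal step
edges intact. Terminal levels above 2.5× the running median are excluded
as tracks that vanished mid-bleach (by diffusion or overlap) rather than
bleaching to the last step; the KDE bandwidth is 0.3× the median terminal
level, wide enough to merge shot noise but narrower than the factor-2 gap
to unresolved dimers. The standard error is a bootstrap over tracks.
Fewer than 10 qualifying tracks is an error instructing the caller to pool
acquisitions — brightness is internally calibrated within each dataset.

Two bias sources are worth knowing about, both reproduced and bounded by
the simulator tests rather than corrected: at threshold-level SNR,
detection drops the dimmest frames and biases terminal levels up by ~8%
(within the estimator's 10% recovery specification); at high emitter
density, neighbours inflate the background annulus and bias intensities
down by a few percent. The brightness calibration protocol therefore wants
sparse fields, as in the bundled positive controls.

Initial track intensity `I0` is a straight-line extrapolation of the first
(up to) 5 focus intensities back to the first exposure frame. Linear was
chosen over exponential back-projection as the minimal model over so short
a window (the two differ by < 5% when the window is much shorter than the
bleach decay time; exponential projection is available when a fitted decay
constant is supplied). A positive fitted slope falls back to the mean —
photobleaching cannot brighten a track. Stoichiometry is `S = I0 / B`,
continuous and unrounded; it is gain-invariant by construction since `I0`
and `B` scale together. Tracks starting later than a quarter of the
photobleach decay time are flagged biased-low. The decay time itself comes
from a single-exponential fit (free offset) to an integrated intensity
series.

# Stoichiometry periodicity

If assemblies share an oligomeric substructure, the stoichiometry
distribution carries equally spaced peaks, and the repeat unit is the
typical nearest-neighbour peak spacing. The pipeline:

1. Gaussian KDE of the stoichiometries, kernel sd 0.3 molecules — the
   standard error (±14%) of the single-molecule brightness. The wider 0.6
   (the ±30% single-molecule spread at the sifting threshold) oversmooths
   the analysis and is kept for display KDEs only. Grid step ≤ 0.05
   molecules; peak finding is strict local maxima with no prominence
   filter (the kernel does the smoothing).
2. Nearest-neighbour intervals between sorted peaks. The interval
   uncertainty is `u = 0.6·sqrt(mean S)/sqrt(n_intervals)`, with
   `n_intervals` counted before discarding; intervals below `u` are
   intra-peak sampling noise and are dropped.
3. A second KDE over the retained intervals with kernel sd `u`, normalised
   to unit area so profiles are comparable across sets — the interval
   profile. Its modal value is the candidate periodicity; the s.e.m. of
   the retained intervals lying where the profile exceeds the null curve
   is its uncertainty.

The null is 100 aperiodic sets of 10^4 stoichiometries uniform on [1, 30],
processed identically; the null curve is the pointwise 95th percentile of
their profiles. One calibration subtlety is resolved in favour of actual
type-I control: a fresh aperiodic sample exceeds a *pointwise* 95th
percentile envelope *somewhere* far more often than 5% of the time (many
correlated grid points are compared), so gating on any exceedance
mislabels roughly 1 in 7 aperiodic samples as periodic. The decision
therefore uses the maximal excess of the profile over the curve, compared
against the 95th percentile of that same functional across the null sets
(`excess_95`, carried by the null object). Because the identical statistic
is evaluated on test and null sets, the false-periodicity rate is 5% by
construction — measured at 4–7% over independent seed blocks — while
perfectly periodic constructions (exact multiples of 4 with 0.1 noise)
remain detected even when their interval uncertainty, and hence their
profile height, differs strongly from the null's.

Sampling the peaks needs at least `14 × mean(S)` values (undersampled
inputs are analysed but flagged), a requirement that scales with
`sqrt(mean S)` through `u`; replicate sets too small on their own are
handled by `bootstrap_periodicity()`, which analyses every pair of
replicates whose union meets the rule and reports the spread of modal
periodicities.

# Mobility

Per-track diffusivity is a quarter of the slope of the time-averaged MSD
over its first lags (2D random walk). Four fit lags are the default — the
"initial portion" is not pinned down by the source method; fewer lags are
noisier, more lags bend under confinement — with a free intercept that
absorbs static localisation error (the fitted intercept recovers
`4·sigma_loc²` on simulated data). Negative fitted slopes map to `D = 0`
with a flag so they can be excluded from means rather than deleted.
`matches_reference()` implements the closed measurement-error window
around a reference mobility, by default `0.20 ± 0.07 µm²/s`, i.e.
`[0.13, 0.27]`. Simulated 18-frame tracks at `D = 0.20` show a per-track
scatter of ~0.06–0.08 µm²/s, reproducing the scale of that per-track
error. The fastest followable diffusivity is bounded by the 8 px linking
radius: faster tracks fragment.

# Nuclear quantification

Integrated nuclear intensity sums offset- and gain-converted photons over
the nucleus mask in the first fluorescence frame (pre-bleach; a multi-frame
average with exponential back-correction is available when a decay
constant is supplied) and divides by `B`, giving molecular equivalents.
Total protein number subtracts the unlabelled-control mean scaled by the
ratio of mean segment areas — the correction multiplies the control mean,
as the method states, and is applied at dataset level. Copy-number
correction divides by the labelled fraction (an equal-expressing unlabelled
allele gives fraction 0.5, so 31% labelled-only doubles to 62%).
Concentration assumes prolate spheroidal nuclei aligned in the image
plane: the in-plane major semi-axis is the unique long axis,
`V = (4/3)·pi·a·b²`, and `c = N/(V·N_A)`. Mask ellipses come from second
central moments (for a filled ellipse the eigenvalues are `a²/4`, `b²/4`);
single-pixel or collinear masks are errors, not zero axes.

# Two-colour colocalisation

Channels are registered by a least-squares affine transform from ≥ 3
matched bead localisations. Reference-locus candidates are the slow
(`D ≤ D_ref`), bright (`S` above threshold) tracks, capped at the 8
brightest per nucleus. The intensity overlap of two foci is the normalised
cross-correlation of their fitted elliptical Gaussians at the measured
separation — for circular spots `exp(−d²/(2(σ1²+σ2²)))` — chosen because
it makes the 50% overlap criterion correspond to ~3 px at typical widths
of ~1.6 px, the equivalence the criterion is quoted with. A pair is
colocalised over maximal runs of ≥ 3 matched frames with overlap ≥ 50% and
separation ≤ 7 px; residence time is run length × the per-channel frame
interval (2× the camera interval under alternating excitation, with frames
matched at nearest timestamps). The chance-coincidence expectation is the
Poisson nearest-neighbour form `P = 1 − exp(−λπr²)`; simulated independent
channels reproduce it. A pre-acquisition best-focus frame can be replayed
as a static sequence to recover reference loci bleached before the
alternating acquisition; recovered static tracks are deduplicated against
live tracks within 1 px.

# Inference

`brunner_munzel()` implements the two-sided rank test of the relative
effect `P(X < Y) + 0.5·P(X = Y)` with mid-ranks, the studentised statistic
and Satterthwaite degrees of freedom; a permutation reference is available
for samples under ~10 (the t-approximation is the default, matching common
practice at the sample sizes involved — which variant the original
analysis used is not recorded). Its type-I error at α = 0.01 is inside
[0.005, 0.02] over 10^4 null simulations. `fisher_exact()` wraps the exact
conditional test (two-tailed by summing tables no more probable than the
observed one — conventions differ, so this is stated); its p-values equal
a direct hypergeometric enumeration. `bonferroni_adjust(0.05, 5) = 0.01`
reproduces the pre-registered significance level, and
`significance_marker()` formats the ns/*/**/*** bands.

# The simulator: what it does and does not emulate

`simulate_stack()` renders each surviving fluorophore as a pixel-integrated
symmetric 2D Gaussian (sigma ≈ 170 nm FWHM equivalent at 53 nm pixels) of
expected `B` photons at its assembly's position; assemblies take isotropic
Gaussian steps of per-axis variance `2·D·Δt` with reflecting boundaries
(keeping density constant for colocalisation nulls); fluorophores bleach
independently with per-frame probability `p_b` (binary, no blinking by
default); uniform background, Poisson shot noise over the expected photon
image, Gaussian read noise, then the affine count conversion with
rounding. All fluorophores of an assembly are coincident, as assemblies
sit far below the diffraction limit. Ground truth (positions,
stoichiometries, bleach frames, expected signal) is recorded before noise.

Defaults mirror the study conditions: brightness 76 photons/frame (YFP
class), background 26 photons/px (root-tip autofluorescence at 514 nm; the
in-vitro-like controls use 1–5), gain 0.6, offset 100, 53 nm pixels, 10 ms
frames. The positive-control noise for simulated stoichiometries defaults
to 0.6 molecules — the single-molecule spread at threshold — as the source
value is not stated.

Not emulated: optical aberrations, defocus/3D structure, nuclear texture,
pixel-dependent sCMOS noise maps, and fluorophore blinking. Passing tests
therefore demonstrate correctness of the analysis chain under an idealised
but statistically faithful image model, not robustness to the full optical
complexity of tissue data.

# Problem sizes used in the tests

The test and acceptance runs use 96 px fields, 10–25 emitters, 40–150
frames and 10-field PPV batches; periodicity uses the full 10^4-value sets
and 100-set nulls; statistical calibrations use 10^2–10^4 replicates.
These sizes give Monte-Carlo errors comfortably inside the asserted
tolerances while keeping a full run under a minute for the unit suite and
under a minute for the acceptance script.

# Known limitations

Greedy nearest-neighbour linking (no gap closing, no motion model) is
faithful to the method but fragments tracks at high density or fast
diffusion; stoichiometries from late-starting tracks are biased low and
only flagged; brightness calibration inherits detection selection at
threshold-level SNR (~+8%, documented above); the periodicity null is
specific to the uniform [1, 30] aperiodic model; and the prolate-spheroid
volume is a geometric idealisation of real nuclei.
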