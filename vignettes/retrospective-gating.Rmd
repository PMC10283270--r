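---
title: "Retrospective gating of beating-heart Z-movies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrospective gating of beating-heart Z-movies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beatsync)
```

# The model and its assumptions

Light-sheet acquisition of a beating larval zebrafish heart records one
time-lapse ("Z-movie") per axial depth while the heart keeps beating.
Retrospective gating rests on two assumptions:

1. **Quasi-periodicity.** Cardiomyocytes return to (nearly) the same
   position after each cycle; beat-to-beat period variability in
   zebrafish larvae is on the order of one percent. Synchronization is
   therefore a one-dimensional phase-estimation problem per movie.
2. **Frame granularity.** Cycle lengths and phase offsets are handled
   as integer frame counts and the output volume copies input pixels
   verbatim. No temporal interpolation is performed, so the
   reconstruction never invents intensities; the cost is a ±half-frame
   phase quantization (2.5 ms at 200 fps).

The similarity score throughout is the raw sum of squared intensity
differences (SSD) between equal-shaped clips, computed in double
precision on unnormalized intensities. SSD assumes comparable intensity
ranges across the compared clips — true for the phantom by construction
and reasonable within one acquisition; an optional mean-scaling for
bleaching-affected real data is deliberately **not** applied by default
so that the score stays a pure copy-compare primitive.

## Cycle-length estimation

`estimate_cycle_length()` seeds the search with the three-cycle frame
count `N` (peak-systole 1 → 4), giving `L = N/3 · E` ms at exposure `E`.
Candidates are the integers in `round(0.85·L/E) … round(1.15·L/E)`; each
candidate `P` is scored by comparing every frame `t ≥ P` with frame
`t − P` ("back-projection onto the previous cycle") and summing the SSD.
Two reading choices the source procedure leaves open were resolved as
follows:

* **Adjacent cycles only.** Frames are compared at lag exactly `P`
  rather than across all cycle pairs; under period jitter, more distant
  cycles drift further apart and would blur the minimum.
* **Normalization.** The summed score is divided by the number of
  compared frame pairs `(n − P)`. Without this, larger candidates
  compare fewer pairs and are systematically favoured. A partial final
  cycle contributes its comparable frames rather than being discarded.

Ties break toward the candidate nearest `L/E`, then toward the smaller
candidate — deterministic by construction.

## Automated peak-systole counting

The manual three-cycle count is automated by a contraction proxy: the
SSD of a short 5-frame leading clip against the clip starting at every
frame. The proxy dips each time the movie revisits the reference phase.
A 5-frame clip (rather than a single frame) averages noise over five
frame pairs while keeping the dip sharp, because motion mismatch
accumulates over the clip instead of being smoothed away. The period
guess that sets the minimum dip separation comes from a frame-level lag
scan (mean SSD at every lag), not from the proxy's spectrum: a 1D
summary can be nearly symmetric under half-period phase reflection,
whereas the full scene repeats only at the true period. Among
local minima of the lag scan within 10 % of the dip depth the smallest
lag wins, so a double-period dip never masks the fundamental. Anchors
are proxy minima below the median, non-maximum-suppressed at half the
period guess; `N` is the span from the first to the fourth anchor. When
fewer than four anchors exist (static or aperiodic movies) the caller
must supply `N` manually.

Automated counting (and the reference cycle length) uses the movie with
the strongest temporal intensity modulation rather than the first movie:
edge slices of a stack that barely intersect the heart have too weak a
contraction signal under noise.

## Phase alignment

For each consecutive pair, a reference clip of `clip_cycles` (default 3)
cycles starting at `S` (default 0) is compared against the next movie's
clip at `S + D` for all integer `D ∈ [0, P)` — the full period, since
starting phases are arbitrary. With 300-frame movies, `P = 80` and
3-cycle clips, the full offset band cannot fit
(`S + (P−1) + 3P > 300`); rather than failing, the clip is truncated to
the longest length admitting the full band (never below one cycle).

**Triple-movie comparison.** The pairwise score of each candidate `D` is
augmented with `min over D₂ of [SSD(ref, after_next @ S+D₂) +
SSD(next @ S+D, after_next @ S+D₂)]`. The combination rule (a plain sum
of the three pairwise SSDs at consistent offsets) is the simplest
monotone aggregate; the adversarial construction in
`adversarial_series()` — a middle slice whose content shared with its
predecessor carries a stronger echo at a false phase while its content
shared with its successor pulses at the true phase — is the regression
test that this rule escapes a pairwise optimum.

**Sub-frame accumulation.** Each pair's offset is refined on the SSD
valley by quadratic interpolation of the minimum and its two (cyclic)
neighbours, clamped to ±0.5 frames; refined differences accumulate
continuously along the z-chain and are rounded once per slice. Rounding
each pair independently would random-walk the absolute offset by
`~0.3·√z` frames across the stack. The refinement is skipped when the
valley bottom is an exact zero (a bit-exact periodic match needs no
refinement), which keeps noise-free recovery exact. Final offsets are
integers (frame-copy semantics are preserved); all SSD searches remain
integer searches.

**Degenerate input.** A pair whose candidate scores are all equal (to a
relative 10⁻⁹) — e.g. a motion-free movie — is flagged and assigned
`D = 0` rather than raising an error, so a batch run over a series with
dead slices completes with diagnostics instead of aborting.

**Per-slice cycle disagreement.** Each movie's own cycle-length estimate
is recorded in the result for diagnostics, but the retained window and
all alignment searches use the reference movie's length: the assembled
volume needs one common window, and a per-slice window would break the
copy semantics.

## Assembly and the retained window

`assemble_4d()` emits `T = retained_cycles · P` timepoints (default 3
cycles, matching a 300-frame acquisition that covers 3–5 cycles);
timepoint `t`, slice `z` is movie `z`'s frame `offset[z] + t`. If any
slice's window overruns its movie, assembly fails with an explicit
window-overflow error — silently wrapping would splice non-adjacent
beats. Phase zero of the output is the reference movie's phase at `S`;
re-anchoring to end-systole is a post-hoc relabelling
(`anchor_end_systole()`) because the anchor choice is presentational.

## Parallelism contract

Cycle estimation per movie and alignment per pair are independent
deterministic tasks distributed over `parallel::mclapply`. The contract,
enforced by test, is bit-identical output for any worker count —
parallelism changes speed, never results.

# The phantom: what it emulates, and what it does not

`generate_series()` emulates the acquisition protocol: per-slice
recording of a quasi-periodic scene with unknown per-slice starting
phase, per-cycle period jitter (piecewise-constant phase velocity — one
period drawn per cycle, matching the gating assumption that cells return
to their positions at cycle boundaries), anisotropic Gaussian blur, and
additive Gaussian noise quantized to 16-bit counts.

Defaults mirror the target acquisition: 300 frames per movie at 200 fps
(E = 5 ms), 400 ms mean period (P = 80 frames, 3.75 cycles per movie),
1 µm axial step, anisotropic blur from the measured lateral/axial
resolutions (FWHM 1.26/2.48 µm → σ 0.535/1.053 µm). The spatial scene is
a deliberately miniature two-chamber heart (48 × 48 × 20 µm at 1 µm
pixels, 40 nuclei by default) so that full series render in seconds;
20 slices stands in for the 100–200 of a real acquisition, and the
chambers span (nearly) the whole axial range so every slice images
cardiac content, as in an acquisition that scans the heart volume.

Geometry: two ellipsoidal shells (ventricle, atrium) joined by an
atrioventricular-canal ring, nuclei fixed on the shells with an enforced
minimum pairwise separation (worst-phase), per-nucleus brightness drawn
once. The contraction waveform is a raised cosine of a monotonically
warped phase, `w(p) = (1 − cos 2πu)/2` with
`u = p + 0.35·(1 − cos 2πp)/(2π)`:

* smooth and periodic with zero velocity at end-systole/end-diastole;
* the warp makes systole faster than diastole, as in a real cardiac
  cycle — and, importantly for synchronization, removes the phase
  reflection symmetry `scene(φ) = scene(−φ)` that a plain cosine would
  have, under which two distinct phases render identically and phase
  anchors become ambiguous.

The atrium contracts in anti-phase with 1.5× the ventricular amplitude
(largest atrial displacement — a phantom convention echoing the imaging
observation, not a biological claim); the AVC ring co-moves with the
ventricle at 0.4× amplitude. No quantitative motion amplitudes are
available to copy, so `contraction_amplitude` (default 0.15) is a free
parameter and the tracking tests sweep it rather than assuming one
value.

A single seed drives named substreams (geometry, phases, per-slice
periods, per-slice noise), so enabling noise never perturbs the
geometry draw. `phase_offsets = "random"` draws continuous uniform
starting phases (used for the jitter/noise recovery conditions and the
uniformity test); `"random_grid"` draws them uniformly on the frame grid
`k/P`, which makes *exact* frame-level recovery well defined — with
continuous phases, frame-integer alignment can only ever be correct to
±1 frame. "5 % noise" in the validation conditions means
`noise_sigma = 150` counts = 5 % of the nominal nucleus peak intensity
(3000 counts).

Not emulated: light-sheet shadowing and scattering, sample-induced
aberrations, blood cells and hemodynamics, photobleaching, intensity
drift. Tests passing on the phantom therefore demonstrate the
*algorithmic* properties (recovery, determinism, robustness to the
modelled noise and jitter) — not performance on optical artefacts the
phantom does not contain.

The ground truth carries per-slice starting phases, realized per-cycle
periods, the full phase-at-frame matrix, per-nucleus trajectories versus
phase, region labels, and noise-free reference volumes on one canonical
cycle; the last make the end-to-end check exact, because a noise-free
grid-phase reconstruction must equal the reference volumes voxel for
voxel.

# PSF calibration

`generate_beads()` places sub-voxel anisotropic Gaussian beads
(σ = FWHM/2√(2 ln 2)) with rejection-sampled pairwise separation of at
least five FWHM in a 256 × 256 × 75-voxel volume (≈ 83 × 83 × 75 µm at
the default 0.325/0.325/1 µm voxels, echoing a ~300 × 300 × 75 µm bead
calibration volume at desk scale). `measure_fwhm()` fits a Gaussian with
constant offset to the 1D profile through each detected bead — the
standard bead-calibration estimator; the paper-style alternative of a
direct half-maximum reading survives as the fallback when the fit fails,
flagged as such. "Lateral" averages the x and y profile measurements,
since in-plane calibration does not distinguish them. The reported FWHM
is the raw image-domain width: no deconvolution of the ~0.53 µm bead
diameter is attempted, matching how such calibrations are usually
reported. Sampling limits: for σ below ~1.5 voxels the discrete profile
under-constrains the fit; the default axial step (1 µm) puts the axial
σ at ≈ 1.05 voxels, where fits on noise-free phantoms remain exact but
noisy real data would benefit from finer z-sampling.

# Segmentation, tracking, and their scores

`segment_nuclei()` is the classical pipeline: global threshold (Otsu on
a 256-bin histogram, or fixed), Euclidean distance transform of the
foreground, seeds at distance-transform maxima non-maximum-suppressed at
`min_seed_separation_um`, seeded region growing over the foreground
(watershed-style splitting of touching nuclei via `EBImage::propagate`),
small-component removal, consecutive renumbering in scan order.
Centroids are intensity-weighted: binary centroids are sensitive to how
the watershed boundary splits touching nuclei. The distance transform is
computed in index space; at the default near-isotropic phantom voxels
the anisotropy correction would be negligible.

`link_tracks()` is greedy globally-sorted nearest-neighbour assignment
between consecutive timepoints with a hard distance gate, chosen over a
learned tracker deliberately: it is fully deterministic, dependency-free
and analysable — when the inter-frame displacement is below half the
minimum nucleus spacing, greedy assignment is provably optimal, which is
exactly the regime the perfect-tracking test constructs. No gap closing
or track merging is performed; a vanished nucleus ends its track with a
flagged gap and a reappearance starts a new track. The interface (label
volumes in, tracks out) is tracker-agnostic so a learned tracker can be
slotted in later.

`score_tracking()` counts a truth cell as correct when exactly one track
centroid lies within the match radius at every timepoint and it is the
same track throughout; FN are truth cells unmatched at some timepoint,
FP are tracks never matched by any truth cell. The published ~80 %
accuracy figure for learned tracking was measured on manually annotated
real data that is not reproducible here; no claim of matching it is
made, and the phantom-based score is the substitute surface.

# Metrics

Velocity uses central differences on interior points (one-sided at the
ends); the estimator is swappable (`method = "forward"`) since the
source does not state one. The central-difference error on smooth
trajectories is bounded by `max|x‴|·dt²/6`, asserted against analytic
sinusoids. Displacement is Euclidean distance from the `t = 0` centroid;
pairwise distance is per-timepoint Euclidean distance with `NA` where
either track has a gap.

Surface area uses a marching-tetrahedra triangulation of the 0.5-level
of the label mask: each grid cube is split into six tetrahedra around
its main diagonal (a face-consistent decomposition, hence watertight
meshes and a well-defined divergence-theorem volume). Binary masks are
pre-smoothed with a 0.6-voxel Gaussian before extraction: the raw
staircase surface overestimates the area of smooth bodies (≈ +28 % on a
voxelized sphere), while heavier smoothing erodes sharp corners; at
0.6 voxels both a 20-voxel-radius sphere and a 20-voxel cube recover
their analytic SA:V to within 5 %, the characterization the acceptance
test re-runs. Cell volume is the voxel count times the voxel volume
(exact for the discrete mask), so `sav_ratio` is definitionally
`surface/volume`. SA:V is computed on *nucleus* label masks — the
structures the images actually contain — with no claim about whole-cell
morphology. Fixed-volume sphere-minimality of SA:V is checked against an
elongated ellipsoid of equal voxel volume.

# Validation problem sizes

The test suite and the end-to-end checks run on deliberately small
instances: 20 slices × 150 frames (P = 30, five cycles) for offset
recovery — exact recovery on grid phases, and ≥ 95 % of slices within
±1 frame across five seeds under 1 % period jitter with 5 % intensity
noise; a 20-slice × 300-frame five-cycle phantom for the
three-retained-cycles contract; 60 beads for FWHM recovery within 5 %;
25 nuclei × 16 phases for perfect easy-regime tracking, with a
four-point contraction-amplitude sweep (worst-phase separation held
fixed) for the degradation trend; and 100 random clips for exact SSD
oracle agreement. These sizes were chosen so the full suite runs in
about a minute while every check remains statistically meaningful at its
stated tolerance.

# Known limitations

* Offsets are integer frames; sub-frame *reconstruction* (temporal
  interpolation) is out of scope by design.
* SSD on raw intensities assumes stable illumination; bleaching or gain
  drift across slices would need the (unimplemented-by-default)
  intensity normalization flag.
* The chain alignment anchors at the first movie; a slice with no
  cardiac content inside the clip window yields a degeneracy flag, and
  everything beyond a *sequence* of dead slices would align only up to
  the information those slices carry.
* The tracker does not handle mitosis, gap closing, or appearance
  changes beyond centroid distance.
* The phantom's optical model is additive Gaussian blobs plus Gaussian
  noise; conclusions about scattering, shadowing, or deep-tissue
  contrast loss cannot be drawn from it.
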