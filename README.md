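# beatsync

Retrospective cardiac gating and 4D reconstruction for light-sheet
Z-movies of the beating zebrafish heart, with a ground-truthed synthetic
phantom, PSF calibration, nuclei segmentation/tracking, and single-cell
contractility metrics.

## The problem

A light-sheet microscope images a larval zebrafish heart one axial plane
at a time: at each depth `z` it records a short time-lapse (a
**Z-movie**, e.g. 300 frames at 200 fps) while the heart keeps beating,
then steps 1 µm deeper and records the next movie. Consecutive movies
therefore start at unknown, unrelated cardiac phases, and the stack
cannot be viewed as a 4D volume as acquired. Because the heartbeat is
quasi-periodic (beat-to-beat period variability ≈ 1 %), the movies can
be re-synchronized *after* acquisition — retrospective gating — and
stacked into a time-resolved 3D reconstruction of the full cycle.

## The algorithm

For equal-shaped image clips `A`, `B` the similarity score is the sum of
squared differences

```
SSD(A, B) = Σ_t Σ_xy (A_t(x,y) − B_t(x,y))²
```

1. **Cycle length.** Count the frames `N` spanning the first to the
   fourth peak-systolic frame (three cycles); the average cycle length
   is `L = N/3 · E` with exposure `E` ms/frame. Integer candidate
   lengths spanning `0.85 L … 1.15 L` are scored by back-projecting
   every frame onto its counterpart one candidate period earlier
   (normalized SSD); the minimiser is the movie's cycle length `P` in
   frames. `find_peak_systole()` automates the manual count.
2. **Phase alignment.** A reference clip of ~3 cycles starting at frame
   `S` is cropped from movie `z`; clips of the same length are cropped
   from movie `z+1` at `S + D` for every integer phase offset
   `D ∈ [0, P)`, and the SSD-minimising `D` aligns the pair. To avoid
   spurious local optima, the score of each `D` additionally includes
   the best consistent first↔third and second↔third clip SSDs against
   movie `z+2` (triple-movie comparison). Per-pair offsets are refined
   to sub-frame precision on the SSD valley, accumulated along the
   chain, and rounded once per slice.
3. **Assembly.** Timepoint `t`, slice `z` of the output volume is a
   verbatim copy of movie `z`'s frame `offset[z] + t` — no
   interpolation — for `T = 3 · P` timepoints (three complete retained
   cycles).

Per-movie estimation and per-pair alignment are independent tasks;
`workers = k` parallelises them with bit-identical results.

Around the core, the package provides bead-volume PSF calibration
(`psf_report()`), watershed nuclei segmentation and greedy
nearest-neighbour tracking (`segment_nuclei()`, `link_tracks()`),
contractility metrics (velocity, pairwise distance, surface-area:volume
ratio via marching-tetrahedra iso-surfaces, OBJ mesh export), and a
synthetic beating-heart phantom (`generate_series()`) whose complete
ground truth — per-slice starting phases, per-cycle periods, nucleus
trajectories, noise-free reference volumes — validates every stage.

## Worked example

Simulate a 20-slice acquisition (150 frames/movie at 200 fps, 150 ms
period ⇒ `P = 30` frames, 5 cycles per movie) with random per-slice
starting phases, then synchronize it:

```r
library(beatsync)
cfg <- phantom_config(n_slices = 20, n_frames = 150, frame_rate = 200,
                      period_ms = 150, phase_offsets = "random_grid",
                      n_nuclei = 30, seed = 5)
sim <- generate_series(cfg)
res <- synchronize(sim$series)
print(res$sync)
#> Sync result: 20 slices, cycle 30 frames, retained 3 cycles (90 frames)
#>   offsets: 0 12 25 17 26 6 7 25 0 28 29 29 29 2 21 18 27 9 25 28
round(sim$truth$phase_offsets * 30)  # ground truth (as relative offsets):
#> 0 12 25 17 26 6 7 25 0 28 29 29 29 2 21 18 27 9 25 28   -- 20/20 exact
print(res$volume)
#> 4D reconstruction: 90 timepoints (dt = 5 ms), volume 48 x 48 x 20, voxel (1, 1, 1) um
```

The recovered per-slice offsets reproduce the phantom's hidden starting
phases exactly, and the assembled 90 timepoints are three complete
cardiac cycles. The automated systole count on the same data gives

```r
fp <- find_peak_systole(sim$series$movies[[10]])
fp$peaks[1:4]            #> 0 30 60 90
cycle_length_ms(fp$N, 5) #> 150   (ms, = N/3 * E)
```

A full simulate → sync → track → metrics run from one config:

```r
run_pipeline(list(seed = 4,
                  phantom = list(n_slices = 10, n_frames = 150, period_ms = 150,
                                 phase_offsets = "random_grid", n_nuclei = 15,
                                 frame_size = c(40L, 40L))),
             out_root = "run1")
```

A thin command-line front end over the same functions lives at
`inst/cli/beatsync.R` (subcommands `simulate`, `sync`, `calibrate-psf`,
`track`, `metrics`, `run`).

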