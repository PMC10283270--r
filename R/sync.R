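## Retrospective synchronization.
##
## All clip comparisons reduce to sums of per-frame SSDs. For speed these
## are computed through per-frame Gram matrices,
##   ssd(a_i, b_j) = |a_i|^2 + |b_j|^2 - 2 a_i . b_j,
## which for the integer-valued intensities the package stores is exact
## (every term is an integer below 2^53), i.e. identical to the direct
## per-pixel sum, not an approximation.

.frame_gram <- function(A, B) {
  da <- dim(A); db <- dim(B)
  stopifnot(identical(da[1:2], db[1:2]))
  XA <- matrix(A, prod(da[1:2]), da[3])
  XB <- matrix(B, prod(db[1:2]), db[3])
  G <- outer(colSums(XA^2), colSums(XB^2), "+") - 2 * crossprod(XA, XB)
  G[G < 0] <- 0
  G
}

## W[i, j] = sum_{u=0..len-1} G[i+u, j+u]; NA where the window overruns.
.diag_window_sums <- function(G, len) {
  n1 <- nrow(G); n2 <- ncol(G)
  W <- matrix(NA_real_, n1, n2)
  for (k in (1 - n1):(n2 - 1)) {
    i <- seq.int(max(1L, 1L - k), min(n1, n2 - k))
    if (length(i) < len) next
    j <- i + k
    v <- G[cbind(i, j)]
    cs <- cumsum(v)
    m <- length(v) - len + 1L
    ws <- cs[seq.int(len, length(v))] -
      c(0, cs[seq_len(length(v) - len)])
    W[cbind(i[seq_len(m)], j[seq_len(m)])] <- ws
  }
  W
}

#' Sum of squared differences between two image clips
#'
#' The similarity score driving both cycle estimation and phase
#' alignment: the sum over all frames and pixels of the squared intensity
#' difference, computed in double precision. Symmetric, non-negative, and
#' zero iff the clips are identical.
#'
#' @param clip_a,clip_b Numeric arrays of identical shape (any
#'   dimensionality; typically `h x w x t`).
#' @return A single non-negative number.
#' @examples
#' ssd(array(0, c(2, 2, 1)), array(1, c(2, 2, 1)))  # 4
#' @export
ssd <- function(clip_a, clip_b) {
  if (!identical(dim(clip_a), dim(clip_b)))
    stop("shape mismatch: clips must have identical dimensions")
  sum((clip_a - clip_b)^2)
}

#' Average cardiac cycle length from a systolic frame count
#'
#' `L = N/3 * E`: `N` frames span the first to the fourth peak-systolic
#' frame, i.e. three full cycles, at exposure `E` milliseconds per frame.
#'
#' @param N Frame count between the first and fourth peak-systolic frames
#'   (>= 3).
#' @param E Exposure time per frame in milliseconds.
#' @return The average cycle length in milliseconds.
#' @examples
#' cycle_length_ms(240, 5)  # 400 ms at 200 fps
#' @export
cycle_length_ms <- function(N, E) {
  stopifnot(is.numeric(N), N >= 3, is.numeric(E), E > 0)
  N / 3 * E
}

#' Estimate a Z-movie's cycle length by within-movie back-projection
#'
#' Candidate integer cycle lengths spanning `band` times the formula
#' value `L = N/3 * E` are scored by back-projecting every frame onto its
#' predecessor one candidate period earlier: the score of candidate `P`
#' is the summed SSD between frames `t` and `t - P` over all valid `t`,
#' normalized by the number of compared frame pairs so that different
#' candidate lengths are comparable. The candidate with the smallest
#' normalized score wins; ties break toward the candidate nearest `L/E`,
#' then toward the smaller length.
#'
#' @param movie A [zmovie()].
#' @param N Frame count between first and fourth peak-systolic frames
#'   (manual count or [find_peak_systole()]).
#' @param E Exposure per frame (ms); defaults to the movie metadata.
#' @param band Candidate band as fractions of `L` (default 0.85-1.15).
#' @param min_cycles Minimum complete cycles the movie must contain at
#'   each candidate length (default 2).
#' @return An object of class `cycle_estimate` with fields `L_ms`, `N`,
#'   `E`, `candidate_lengths`, `ssd_per_candidate`, `best_length_frames`.
#' @export
estimate_cycle_length <- function(movie, N, E = movie$meta$exposure_ms,
                                  band = c(0.85, 1.15), min_cycles = 2) {
  stopifnot(inherits(movie, "zmovie"), length(band) == 2L, band[1] <= band[2])
  L_ms <- cycle_length_ms(N, E)
  Lf <- L_ms / E
  n <- n_frames(movie)
  cands <- seq.int(round(band[1] * Lf), round(band[2] * Lf))
  cands <- cands[cands >= 2 & n >= min_cycles * cands]
  if (!length(cands))
    stop("movie too short for the candidate band: empty candidate set")
  G <- .frame_gram(movie$frames, movie$frames)
  scores <- vapply(cands, function(P) {
    i <- seq_len(n - P)
    sum(G[cbind(i, i + P)]) / (n - P)
  }, 0)
  best <- order(scores, abs(cands - Lf), cands)[1]
  structure(list(L_ms = L_ms, N = N, E = E,
                 candidate_lengths = cands,
                 ssd_per_candidate = scores,
                 best_length_frames = cands[best]),
            class = "cycle_estimate")
}

#' @export
print.cycle_estimate <- function(x, ...) {
  cat(sprintf("Cycle estimate: L = %.4g ms (N = %g, E = %.4g ms); best length %d frames over %d candidates [%d..%d]\n",
              x$L_ms, x$N, x$E, x$best_length_frames,
              length(x$candidate_lengths),
              min(x$candidate_lengths), max(x$candidate_lengths)))
  invisible(x)
}

#' Detect peak-systolic frames and the three-cycle span N
#'
#' Automates the manual frame count entering `L = N/3 * E`. A 1D
#' contraction proxy is computed per frame (the SSD of each frame against
#' frame 0, which dips each time the heart revisits frame 0's phase); an
#' initial period guess comes from the proxy's dominant Fourier
#' component, and proxy minima separated by at least half that guess are
#' taken as same-phase anchors. `N` is the span from the first to the
#' fourth anchor, i.e. three cycles.
#'
#' @param movie A [zmovie()].
#' @param min_separation_frac Minimum anchor separation as a fraction of
#'   the period guess (default 0.5).
#' @return List with `peaks` (0-based frame indices), `N`, and the
#'   per-frame `proxy` signal.
#' @export
find_peak_systole <- function(movie, min_separation_frac = 0.5) {
  stopifnot(inherits(movie, "zmovie"))
  n <- n_frames(movie)
  G <- .frame_gram(movie$frames, movie$frames)
  ## contraction proxy: SSD of a short leading clip against the clip
  ## starting at every frame. Compared to a single-frame proxy this
  ## averages noise over K frame pairs while keeping the dip at a
  ## phase-match sharp (motion mismatch accumulates over the clip
  ## instead of being blurred away).
  K <- min(5L, n - 1L)
  W <- .diag_window_sums(G, K)
  s <- W[1, seq_len(n - K + 1)]
  if (max(s) <= 1e-9 * max(1, G[1, 1] + sum(movie$frames[, , 1]^2)))
    stop("fewer than 4 peaks: movie shows no periodic motion")
  ns <- length(s)
  ## period guess from a frame-level lag scan (mean SSD between frames a
  ## lag apart): dips only where the full scene repeats, so it is not
  ## fooled by half-period near-symmetries of a 1D summary. Among local
  ## minima within 10 percent of the dip depth the smallest lag wins, so
  ## a double-period dip never masks the fundamental.
  lags <- 3:floor(n / 2)
  sc <- vapply(lags, function(P) {
    i <- seq_len(n - P)
    sum(G[cbind(i, i + P)]) / (n - P)
  }, 0)
  rel <- (sc - min(sc)) / max(max(sc) - min(sc), 1e-12)
  nl <- length(sc)
  lmin <- which(c(FALSE, sc[2:(nl - 1)] <= sc[1:(nl - 2)] &
                    sc[2:(nl - 1)] <= sc[3:nl], FALSE) & rel < 0.1)
  guess <- if (length(lmin)) lags[lmin[1]] else lags[which.min(sc)]
  min_sep <- max(2, min_separation_frac * guess)
  is_min <- c(TRUE, s[2:(ns - 1)] <= s[1:(ns - 2)] & s[2:(ns - 1)] <= s[3:ns], TRUE)
  is_min <- is_min & s <= median(s)   # anchors sit in dissimilarity dips
  ord <- order(s)[is_min[order(s)]]
  picked <- integer(0)
  for (t in ord) {
    if (!length(picked) || min(abs(picked - t)) >= min_sep)
      picked <- c(picked, t)
  }
  peaks <- sort(picked) - 1L   # 0-based
  if (length(peaks) < 4L)
    stop("fewer than 4 peaks: supply N manually")
  list(peaks = peaks, N = peaks[4] - peaks[1], proxy = s)
}

#' Align one Z-movie pair (optionally anchored by a third movie)
#'
#' Crops a reference clip of about `clip_cycles` cardiac cycles starting
#' at frame `S` and searches the integer phase offset `D` in
#' `[0, L_frames)` minimizing the SSD between the reference clip and the
#' next movie's clip starting at `S + D`. When `after_next` is supplied,
#' each candidate's score additionally includes the best consistent
#' first-third and second-third clip SSDs over a matching offset search
#' in the third movie, which guards the pairwise search against spurious
#' local optima. Ties break toward the smaller `D`.
#'
#' If a movie is too short to admit the full offset band at the requested
#' clip length, the clip is truncated to the longest length that does
#' (never below one cycle).
#'
#' @param ref,next_movie,after_next [zmovie()] objects (`after_next`
#'   optional).
#' @param S 0-based start frame of the reference clip.
#' @param L_frames Cycle length in frames (>= 2).
#' @param clip_cycles Clip length in cycles (default 3).
#' @return An object of class `alignment_candidate`: fields `S`, `D`,
#'   `ssd` (pairwise score at the chosen `D`), `ssd_cross13`,
#'   `ssd_cross23`, `total_per_candidate`, `ssd_per_candidate`,
#'   `degenerate`, `clip_length`.
#' @export
align_pair <- function(ref, next_movie, after_next = NULL, S = 0L,
                       L_frames, clip_cycles = 3) {
  stopifnot(inherits(ref, "zmovie"), inherits(next_movie, "zmovie"))
  if (L_frames < 2) stop("L_frames must be at least 2")
  n <- min(n_frames(ref), n_frames(next_movie),
           if (!is.null(after_next)) n_frames(after_next) else Inf)
  clip_len <- min(clip_cycles * L_frames, n - S - (L_frames - 1))
  if (clip_len < L_frames)
    stop("clip out of bounds: movies too short for the offset search window")
  Ds <- 0:(L_frames - 1)
  G12 <- .frame_gram(ref$frames, next_movie$frames)
  rows <- seq.int(S + 1, S + clip_len)
  ssd12 <- vapply(Ds, function(D) sum(G12[cbind(rows, rows + D)]), 0)
  degenerate <- (max(ssd12) - min(ssd12)) <= 1e-9 * max(ssd12[1], 1)

  if (!is.null(after_next)) {
    stopifnot(inherits(after_next, "zmovie"))
    G13 <- .frame_gram(ref$frames, after_next$frames)
    ssd13 <- vapply(Ds, function(D2) sum(G13[cbind(rows, rows + D2)]), 0)
    W23 <- .diag_window_sums(.frame_gram(next_movie$frames, after_next$frames),
                             clip_len)
    cross <- vapply(Ds, function(D) {
      tot <- ssd13 + W23[cbind(S + D + 1, S + Ds + 1)]
      b <- which.min(tot)
      c(tot[b], ssd13[b], tot[b] - ssd13[b])
    }, numeric(3))
    total <- ssd12 + cross[1, ]
  } else {
    total <- ssd12
    cross <- NULL
  }
  best <- if (degenerate) 1L else which.min(total)
  ## sub-frame refinement of the SSD valley by quadratic interpolation
  ## (cyclic neighbours; offsets are modular). Skipped when the dip is an
  ## exact zero match — nothing to refine — and for degenerate pairs.
  ## Downstream the refined differences accumulate continuously and are
  ## rounded once per slice, so per-pair rounding never random-walks
  ## along the z chain.
  L <- length(Ds)
  t0 <- total[best]
  ta <- total[(best - 2L) %% L + 1L]
  tb <- total[best %% L + 1L]
  denom <- ta - 2 * t0 + tb
  delta <- if (!degenerate && t0 > 1e-9 * max(total) && denom > 0)
    max(-0.5, min(0.5, 0.5 * (ta - tb) / denom)) else 0
  structure(list(S = as.integer(S), D = Ds[best],
                 D_frac = Ds[best] + delta,
                 ssd = ssd12[best],
                 ssd_cross13 = if (is.null(cross)) NA_real_ else cross[2, best],
                 ssd_cross23 = if (is.null(cross)) NA_real_ else cross[3, best],
                 ssd_per_candidate = ssd12,
                 total_per_candidate = total,
                 degenerate = degenerate,
                 clip_length = as.integer(clip_len)),
            class = "alignment_candidate")
}

#' @export
print.alignment_candidate <- function(x, ...) {
  cat(sprintf("Alignment: D = %d (S = %d, clip %d frames), ssd = %.6g%s%s\n",
              x$D, x$S, x$clip_length, x$ssd,
              if (!is.na(x$ssd_cross13)) sprintf(", cross13 = %.6g, cross23 = %.6g",
                                                 x$ssd_cross13, x$ssd_cross23) else "",
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

## Movie with the strongest temporal intensity modulation: edge slices of
## a stack may barely intersect the heart, making their contraction proxy
## too weak for automated peak counting under noise.
.motion_rich_movie <- function(series) {
  which.max(vapply(series$movies, function(m) {
    s <- colSums(matrix(m$frames, ncol = dim(m$frames)[3]))
    stats::var(s)
  }, 0))
}

.apply_workers <- function(X, FUN, workers) {
  res <- if (workers <= 1L) lapply(X, FUN)
  else parallel::mclapply(X, FUN, mc.cores = workers, mc.preschedule = TRUE)
  err <- vapply(res, inherits, TRUE, "try-error")
  if (any(err)) stop(attr(res[[which(err)[1]]], "condition"))
  res
}

#' Align a whole Z-stack series to a common starting phase
#'
#' Applies [align_pair()] to every consecutive movie pair (anchoring each
#' pair with the movie after next when available and `use_third` is
#' `TRUE`), and accumulates the per-pair offsets into per-slice start
#' offsets modulo the cycle length: `offset[0] = S0`,
#' `offset[z+1] = (offset[z] + D_z) mod L`.
#'
#' @param series A [zstack_series()] with >= 2 movies.
#' @param L_frames Reference cycle length in frames.
#' @param S0 Start offset of the reference (first) movie.
#' @param use_third Use the triple-movie comparison (default `TRUE`).
#' @param clip_cycles Clip length in cycles for each pairwise search.
#' @param retained_cycles Cycles retained by [assemble_4d()] (default 3).
#' @param per_slice_lengths Optional per-slice cycle lengths (diagnostic;
#'   the retained window always uses the reference length).
#' @param workers Parallel workers for the independent pairwise searches;
#'   results are identical for any worker count.
#' @return An object of class `sync_result`: per-slice `offsets` (frames)
#'   and `cycle_length_frames`, per-pair `D`, SSD diagnostics and
#'   degeneracy flags, `retained_cycles` and `clip_length_frames`.
#' @export
align_series <- function(series, L_frames, S0 = 0L, use_third = TRUE,
                         clip_cycles = 3, retained_cycles = 3,
                         per_slice_lengths = NULL, workers = 1L) {
  stopifnot(inherits(series, "zstack_series"))
  nz <- length(series$movies)
  if (nz < 2L) stop("need at least 2 movies to align")
  cands <- .apply_workers(seq_len(nz - 1L), function(z) {
    third <- if (use_third && z + 2L <= nz) series$movies[[z + 2L]] else NULL
    align_pair(series$movies[[z]], series$movies[[z + 1L]], third,
               S = S0, L_frames = L_frames, clip_cycles = clip_cycles)
  }, workers)
  D <- vapply(cands, `[[`, 0L, "D")
  D_frac <- vapply(cands, `[[`, 0, "D_frac")
  offsets <- integer(nz)
  offsets[1] <- as.integer(S0)
  cum <- as.numeric(S0)
  for (z in seq_len(nz - 1L)) {
    cum <- cum + D_frac[z]
    offsets[z + 1L] <- as.integer(round(cum)) %% as.integer(L_frames)
  }
  structure(list(offsets = offsets,
                 cycle_length_frames = if (is.null(per_slice_lengths))
                   rep(as.integer(L_frames), nz) else as.integer(per_slice_lengths),
                 ref_length_frames = as.integer(L_frames),
                 D_per_pair = D,
                 ssd_per_pair = vapply(cands, `[[`, 0, "ssd"),
                 degenerate = vapply(cands, `[[`, TRUE, "degenerate"),
                 retained_cycles = as.integer(retained_cycles),
                 clip_length_frames = as.integer(retained_cycles * L_frames),
                 S0 = as.integer(S0),
                 pair_candidates = cands),
            class = "sync_result")
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf("Sync result: %d slices, cycle %d frames, retained %d cycles (%d frames)\n",
              length(x$offsets), x$ref_length_frames, x$retained_cycles,
              x$clip_length_frames))
  cat("  offsets:", paste(x$offsets, collapse = " "), "\n")
  if (any(x$degenerate))
    cat("  degenerate pairs:", paste(which(x$degenerate), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.sync_result <- function(object, ...) {
  cat(sprintf("Slices: %d | cycle length: %d frames | retained window: %d frames\n",
              length(object$offsets), object$ref_length_frames,
              object$clip_length_frames))
  cat(sprintf("Per-pair D: min %d, median %g, max %d | degenerate pairs: %d\n",
              min(object$D_per_pair), median(object$D_per_pair),
              max(object$D_per_pair), sum(object$degenerate)))
  cat(sprintf("Pairwise SSD at chosen offsets: %.4g (median)\n",
              median(object$ssd_per_pair)))
  invisible(object)
}

#' @export
plot.sync_result <- function(x, ...) {
  plot(seq_along(x$offsets) - 1L, x$offsets, type = "s",
       xlab = "slice (z index)", ylab = "start offset (frames)",
       main = "Recovered per-slice phase offsets", ...)
  points(seq_along(x$offsets) - 1L, x$offsets, pch = 20)
  invisible(x)
}

#' Assemble the synchronized 4D reconstruction
#'
#' Output timepoint `t`, slice `z` is a verbatim copy of movie `z`'s
#' frame at `offset[z] + t` (no interpolation); `T = retained_cycles x
#' cycle length` timepoints are produced.
#'
#' @param series The [zstack_series()].
#' @param sync A [align_series()] result covering every slice.
#' @return A [volume4d()] with voxel size from the series metadata.
#' @export
assemble_4d <- function(series, sync) {
  stopifnot(inherits(series, "zstack_series"), inherits(sync, "sync_result"))
  nz <- length(series$movies)
  if (length(sync$offsets) != nz) stop("sync does not cover every slice")
  T_out <- sync$clip_length_frames
  lens <- vapply(series$movies, n_frames, 0L)
  if (any(sync$offsets + T_out > lens))
    stop("window overflow: retained window exceeds movie length at slice(s) ",
         paste(which(sync$offsets + T_out > lens) - 1L, collapse = ", "))
  d <- dim(series$movies[[1]]$frames)[1:2]
  vols <- lapply(seq_len(T_out), function(t) {
    v <- array(0, c(d, nz))
    for (z in seq_len(nz))
      v[, , z] <- series$movies[[z]]$frames[, , sync$offsets[z] + t]
    v
  })
  m <- series$meta
  volume4d(vols, time_step = m$exposure_ms,
           voxel_size = c(m$pixel_size_xy, m$pixel_size_xy, m$step_size_z))
}

#' Retrospectively synchronize a Z-stack series end to end
#'
#' Orchestrates the full gating pipeline: peak-systole counting on the
#' reference movie (unless `N` is given), per-movie cycle-length
#' estimation, iterative cross-movie phase alignment, and 4D assembly.
#' Per-movie and per-pair computations are independent tasks; the result
#' is bit-identical for any `workers` count and across repeated runs.
#'
#' @param series A [zstack_series()].
#' @param N Frame count across three cycles in the reference movie; if
#'   `NULL`, measured by [find_peak_systole()].
#' @param band Candidate band for cycle estimation.
#' @param retained_cycles Complete cycles kept in the output (default 3).
#' @param clip_cycles Clip length (cycles) for alignment searches.
#' @param use_third Triple-movie anti-local-optimum comparison.
#' @param workers Parallel workers.
#' @param S0 Reference start frame.
#' @param min_cycles Minimum cycles per candidate in estimation.
#' @return List with `sync` (a `sync_result`, carrying the per-movie
#'   `cycle_estimates`) and `volume` (a [volume4d()]).
#' @export
synchronize <- function(series, N = NULL, band = c(0.85, 1.15),
                        retained_cycles = 3, clip_cycles = 3,
                        use_third = TRUE, workers = 1L, S0 = 0L,
                        min_cycles = 2) {
  stopifnot(inherits(series, "zstack_series"))
  E <- series$meta$exposure_ms
  ref_movie <- .motion_rich_movie(series)
  if (is.null(N))
    N <- find_peak_systole(series$movies[[ref_movie]])$N
  est <- .apply_workers(series$movies, function(m)
    estimate_cycle_length(m, N = N, E = E, band = band, min_cycles = min_cycles),
    workers)
  ## the reference cycle length comes from the movie with the strongest
  ## cardiac signal; edge slices may barely intersect the heart
  L_ref <- est[[ref_movie]]$best_length_frames
  sync <- align_series(series, L_frames = L_ref, S0 = S0,
                       use_third = use_third, clip_cycles = clip_cycles,
                       retained_cycles = retained_cycles,
                       per_slice_lengths = vapply(est, `[[`, 0L, "best_length_frames"),
                       workers = workers)
  sync$cycle_estimates <- est
  sync$N <- N
  list(sync = sync, volume = assemble_4d(series, sync))
}
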