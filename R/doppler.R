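#' Power Doppler volume
#'
#' Sums the per-voxel signal power `|u|^2` over the frames of a
#' reconstructed (and clutter-filtered) ensemble. The sum of magnitudes
#' `|u|` is available behind `magnitude = TRUE`; power is the default as it
#' is proportional to local blood volume. Frame order does not affect the
#' result.
#'
#' @param stack A [volume_stack()].
#' @param magnitude Sum `|u|` instead of `|u|^2`.
#' @return A nonnegative real 3D array.
#' @export
power_doppler <- function(stack, magnitude = FALSE) {
  .assert(stack$n_frames >= 1, "need at least one frame")
  d <- dim(stack$u)
  M <- Mod(matrix(stack$u, prod(d[1:3]), d[4]))
  pdi <- if (magnitude) rowSums(M) else rowSums(M^2)
  array(pdi, d[1:3])
}

#' Color Doppler volume (lag autocorrelation phase)
#'
#' Per-voxel phase of the lag-`lag` temporal autocorrelation
#' `arg sum_n u(n) u(n + lag)*`, using only pairs of frames whose original
#' acquisition indices are exactly `lag` apart (gaps from invalid frames are
#' skipped). Positive phase corresponds to motion away from the probe.
#'
#' @param stack A [volume_stack()].
#' @param lag Temporal lag in frames (>= 1).
#' @return A real 3D array of phases in (-pi, pi].
#' @export
color_doppler <- function(stack, lag = 1) {
  .assert(lag >= 1, "lag must be >= 1")
  idx <- stack$frame_index
  j2 <- match(idx + lag, idx)
  pairs <- which(!is.na(j2))
  .assert(length(pairs) >= 1,
          "no frame pairs at the requested lag (insufficient valid frames)")
  d <- dim(stack$u)
  M <- matrix(stack$u, prod(d[1:3]), d[4])
  acc <- rowSums(M[, pairs, drop = FALSE] *
                   Conj(M[, j2[pairs], drop = FALSE]))
  array(Arg(acc), d[1:3])
}

#' Subframe running-average reconstruction
#'
#' Reconstructs a separate subframe from each consecutive set of `subset`
#' transmissions and forms a running (sliding-window) sum over
#' `N_t / subset` consecutive subframes, so that each output image still
#' compounds all `N_t` orthogonal transmissions but successive images are
#' separated by only `subset` transmissions. This raises the effective
#' ensemble rate for the lag-1 autocorrelation. The output count is
#' `(N_t / subset) * N_f - (N_t / subset - 1)`.
#'
#' @param acq An [acquisition_tensor()] (only valid frames are used; for
#'   the lag bookkeeping the valid frames must be consecutive).
#' @param op A [imaging_operator()] (typically phase-only).
#' @param subset Transmissions per subframe (`N_t` divisible by it).
#' @return A [volume_stack()] of the windowed subframe images.
#' @export
subframe_stack <- function(acq, op, subset) {
  Nt <- ncol(op$scheme$H)
  .assert(Nt %% subset == 0, "subset must divide the transmission count")
  G <- Nt %/% subset
  frames <- which(acq$valid)
  .assert(length(frames) >= 1, "no valid frames")
  NF <- length(frames)
  g <- op$grid$dims
  sub <- array(0 + 0i, c(prod(g), G * NF))
  for (grp in seq_len(G)) {
    cols <- (grp - 1) * subset + seq_len(subset)
    op_g <- imaging_operator(op$cal, .subset_scheme(op$scheme, cols),
                             op$grid, phase_only = op$phase_only,
                             amplitude_floor = op$amplitude_floor,
                             pad_factor = op$pad_factor, cutoff = op$cutoff)
    ug <- .op_pass(op_g, acq$v[, cols, , frames, drop = FALSE],
                   adjoint = TRUE)
    # subframe (f, grp) sits at time index (f - 1) * G + grp
    sub[, (seq_len(NF) - 1) * G + grp] <- matrix(ug, prod(g), NF)
  }
  n_out <- G * NF - (G - 1)
  u <- array(0 + 0i, c(prod(g), n_out))
  for (wdx in seq_len(n_out)) {
    u[, wdx] <- rowSums(sub[, wdx + seq_len(G) - 1, drop = FALSE])
  }
  dim(u) <- c(g, n_out)
  rate <- if (is.finite(acq$frame_rate)) acq$frame_rate * G else NA_real_
  volume_stack(u, op$grid, frame_index = seq_len(n_out),
               frame_rate = rate,
               provenance = list(method = "subframe", subset = subset,
                                 window = G))
}

#' Axial velocity from the color Doppler phase
#'
#' Standard Doppler phase-to-velocity conversion
#' `w = phase * c * frame_rate / (4 pi f_center)`; `nyquist_velocity()`
#' gives the unambiguous limit `c * frame_rate / (4 f_center)`.
#'
#' @param cdi Phase volume from [color_doppler()].
#' @param f_center Doppler centre frequency, Hz.
#' @param frame_rate Ensemble frame rate, Hz.
#' @param c Sound speed, m/s.
#' @return A velocity map in m/s (positive away from the probe).
#' @export
axial_velocity <- function(cdi, f_center, frame_rate, c = 1500) {
  .assert(frame_rate > 0, "frame_rate must be positive")
  cdi * c * frame_rate / (4 * pi * f_center)
}

#' @rdname axial_velocity
#' @export
nyquist_velocity <- function(f_center, frame_rate, c = 1500) {
  c * frame_rate / (4 * f_center)
}

#' Doppler product container
#'
#' @param pdi Nonnegative power Doppler volume.
#' @param cdi Phase volume in (-pi, pi] (or NULL).
#' @param n_frames_used Frames compounded.
#' @param lag Autocorrelation lag.
#' @return An object of class `cusi_doppler`.
#' @export
doppler_products <- function(pdi, cdi = NULL, n_frames_used, lag = 1L) {
  .assert(all(pdi >= 0), "PDI must be nonnegative")
  if (!is.null(cdi)) {
    .assert(max(abs(cdi)) <= pi + 1e-12, "CDI phases must lie in (-pi, pi]")
  }
  structure(list(pdi = pdi, cdi = cdi, n_frames_used = n_frames_used,
                 lag = as.integer(lag)),
            class = "cusi_doppler")
}
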