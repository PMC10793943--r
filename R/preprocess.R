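#' Acquisition arithmetic utilities
#'
#' `count_frequency_bins()` gives the number of unique positive-frequency
#' DFT bins of an `n_samples` real record after decimating the spectrum by
#' `downsample`: `(n_samples / 2) / downsample` (512 samples at half-band
#' sampling, decimated by 2, yield the 128 reconstruction frequencies).
#' `imaging_depth()` converts a record length to two-way imaging depth,
#' `n_samples * c / (2 f_sample)`. `ensemble_rate()` is the effective
#' volume rate of a frame ensemble.
#'
#' @param n_samples Samples per record (even).
#' @param downsample Spectral decimation factor (>= 1).
#' @return `count_frequency_bins`: an integer bin count.
#' @export
count_frequency_bins <- function(n_samples, downsample = 1) {
  .assert(n_samples >= 2 && n_samples %% 2 == 0, "n_samples must be even")
  .assert(downsample >= 1, "downsample must be >= 1")
  nb <- (n_samples / 2) / downsample
  .assert(nb == round(nb), "downsample must divide n_samples / 2")
  as.integer(nb)
}

#' @rdname count_frequency_bins
#' @param f_sample Sampling rate, Hz.
#' @param c Sound speed, m/s.
#' @return `imaging_depth`: depth in metres.
#' @export
imaging_depth <- function(n_samples, f_sample, c) {
  .assert(n_samples >= 0 && f_sample > 0 && c > 0,
          "arguments must be positive")
  n_samples * c / (2 * f_sample)
}

#' @rdname count_frequency_bins
#' @param n_frames Number of frames in the ensemble.
#' @param duration Acquisition duration, seconds.
#' @param rounded Return the rounded-integer convenience form.
#' @return `ensemble_rate`: rate in Hz.
#' @export
ensemble_rate <- function(n_frames, duration, rounded = FALSE) {
  .assert(duration > 0, "duration must be positive")
  r <- n_frames / duration
  if (rounded) round(r) else r
}

#' Preprocessing filter report
#'
#' @param n_frames_in,n_frames_out Frame counts before/after.
#' @param discarded_singular_values Clutter components removed.
#' @param cutoff_fraction SVD cutoff fraction.
#' @param jitter_threshold Lag-1 difference threshold used.
#' @return An object of class `cusi_filter_report`.
#' @export
filter_report <- function(n_frames_in, n_frames_out,
                          discarded_singular_values = 0L,
                          cutoff_fraction = NA_real_,
                          jitter_threshold = NA_real_) {
  .assert(n_frames_out <= n_frames_in, "cannot gain frames by filtering")
  structure(list(n_frames_in = n_frames_in, n_frames_out = n_frames_out,
                 discarded_singular_values = discarded_singular_values,
                 cutoff_fraction = cutoff_fraction,
                 jitter_threshold = jitter_threshold),
            class = "cusi_filter_report")
}

#' @export
print.cusi_filter_report <- function(x, ...) {
  cat(sprintf(
    "cusi filter report: %d -> %d frames, %d singular values discarded\n",
    x$n_frames_in, x$n_frames_out, x$discarded_singular_values))
  invisible(x)
}

#' Flag frames subject to jitter or instability
#'
#' Evaluates the lag-1 difference norm `d(n) = ||v_n - v_{n-1}||_2` over
#' consecutive valid frames and flags any difference exceeding
#' `median(d) + k * MAD(d)`; since a spike in `d` cannot be attributed to
#' either frame of the pair, both adjacent frames are flagged. The first
#' frame, which has no difference of its own, inherits the validity of its
#' successor. The rule is scale-free and idempotent.
#'
#' @param acq An [acquisition_tensor()].
#' @param k Robust threshold multiplier (must be positive).
#' @return A list with the updated `tensor` and a [filter_report()].
#' @export
detect_unstable_frames <- function(acq, k = 5) {
  vids <- which(acq$valid)
  .assert(length(vids) >= 2, "need at least two valid frames")
  .assert(k > 0, "k must be positive (k <= 0 flags everything)")
  d <- dim(acq$v)
  vm <- matrix(acq$v[, , , vids], prod(d[1:3]), length(vids))
  dn <- sqrt(colSums(Mod(vm[, -1, drop = FALSE] -
                           vm[, -ncol(vm), drop = FALSE])^2))
  thr <- stats::median(dn) + k * stats::mad(dn)
  valid <- acq$valid
  bad <- which(dn > thr)
  for (j in bad) {
    valid[vids[j]] <- FALSE
    valid[vids[j + 1]] <- FALSE
  }
  valid[vids[1]] <- valid[vids[1]] && valid[vids[2]]
  acq$valid <- valid
  list(tensor = acq,
       report = filter_report(length(vids), sum(valid),
                              jitter_threshold = thr))
}

#' Invalidate the unstable prefix of every acquisition block
#'
#' Hardware instability at block starts is handled by marking the first
#' `n_drop` frames of every contiguous block of `block` frames invalid.
#' A trailing partial block is handled by the same prefix rule (with a
#' warning when `block` does not divide the frame count).
#'
#' @param acq An [acquisition_tensor()].
#' @param block Frames per block.
#' @param n_drop Frames to drop from each block prefix (`0 <= n_drop < block`).
#' @return The updated [acquisition_tensor()].
#' @export
drop_block_prefix <- function(acq, block = 100, n_drop = 64) {
  .assert(n_drop >= 0 && n_drop < block, "need 0 <= n_drop < block")
  nf <- acq$n_frames
  if (nf %% block != 0) {
    warning("frame count is not a multiple of the block size; ",
            "the trailing partial block is prefix-dropped too")
  }
  if (n_drop > 0) {
    starts <- seq(1, nf, by = block)
    for (s in starts) {
      acq$valid[seq(s, min(s + n_drop - 1, nf))] <- FALSE
    }
  }
  acq$block <- block
  acq
}

#' Number of singular values removed by the clutter cutoff
#'
#' `floor(cutoff_fraction * n_sv)` — the convention that discards 5226 of
#' 8041 singular values at a 65% cutoff.
#'
#' @param n_sv Number of singular values.
#' @param cutoff_fraction Fraction of leading components to discard.
#' @return Integer discard count.
#' @export
svd_discard_count <- function(n_sv, cutoff_fraction) {
  .assert(cutoff_fraction >= 0 && cutoff_fraction <= 1,
          "cutoff_fraction must lie in [0, 1]")
  as.integer(floor(cutoff_fraction * n_sv))
}

#' SVD clutter filter
#'
#' Separates slowly varying (tissue) signal from blood signal: the valid
#' frames are reshaped to a `(N_w N_t N_e, N_f)` casorati matrix, its
#' economy SVD is computed, and the largest
#' `floor(cutoff_fraction * n_sv)` singular components are zeroed before
#' reconstituting the tensor. The output is exactly orthogonal to the
#' discarded subspace. Invalid frames do not participate and are left
#' untouched (still flagged invalid).
#'
#' @param acq An [acquisition_tensor()].
#' @param cutoff_fraction Fraction of leading singular values to discard
#'   (default 0.65).
#' @return A list with the filtered `tensor` and a [filter_report()].
#' @export
svd_clutter_filter <- function(acq, cutoff_fraction = 0.65) {
  vids <- which(acq$valid)
  .assert(length(vids) >= 2, "need at least two valid frames")
  d <- dim(acq$v)
  M <- matrix(acq$v[, , , vids], prod(d[1:3]), length(vids))
  nd <- svd_discard_count(min(dim(M)), cutoff_fraction)
  if (nd > 0) {
    sv <- svd(M, nu = nd, nv = nd)
    M <- M - sv$u %*% (sv$d[seq_len(nd)] * t(Conj(sv$v)))
    acq$v[, , , vids] <- M
  }
  list(tensor = acq,
       report = filter_report(length(vids), length(vids),
                              discarded_singular_values = nd,
                              cutoff_fraction = cutoff_fraction))
}

#' SVD clutter filter on a reconstructed ensemble
#'
#' The same truncation applied after reconstruction: the volume stack is
#' reshaped to `(n_voxels, n_frames)` and the leading singular components
#' are removed. Because reconstruction is linear and frame-wise, filtering
#' before or after reconstruction is near-equivalent when the clutter
#' subspace is well separated.
#'
#' @param stack A [volume_stack()].
#' @inheritParams svd_clutter_filter
#' @return A list with the filtered `stack` and a [filter_report()].
#' @export
svd_filter_volumes <- function(stack, cutoff_fraction = 0.65) {
  d <- dim(stack$u)
  .assert(d[4] >= 2, "need at least two frames")
  M <- matrix(stack$u, prod(d[1:3]), d[4])
  nd <- svd_discard_count(min(dim(M)), cutoff_fraction)
  if (nd > 0) {
    sv <- svd(M, nu = nd, nv = nd)
    M <- M - sv$u %*% (sv$d[seq_len(nd)] * t(Conj(sv$v)))
    stack$u <- array(M, d)
  }
  list(stack = stack,
       report = filter_report(d[4], d[4],
                              discarded_singular_values = nd,
                              cutoff_fraction = cutoff_fraction))
}
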