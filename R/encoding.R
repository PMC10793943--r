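#' Transmit encoding schemes
#'
#' An encoding scheme pairs a transmit apodization matrix `H`
#' (`n_elements x n_transmissions`) with a per-element delay vector `T`
#' (always zero in the schemes provided here, retained so delay-based
#' focusing stays expressible). `hadamard_scheme()` builds the
#' Sylvester-Hadamard matrix of +/-1 codes, which satisfies
#' `t(H) %*% H = n * I` exactly and is trivially realized in hardware by
#' flipping driver polarity; `identity_scheme()` is the plain synthetic
#' aperture where each element transmits alone.
#'
#' @param n Number of elements / transmissions (a power of 2 for the
#'   Sylvester construction).
#' @return An object of class `cusi_scheme` with elements `H`, `T`,
#'   `n_tx_per_volume`.
#' @export
hadamard_scheme <- function(n) {
  .assert(n >= 1 && n == as.integer(n) && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L,
          "n must be a power of 2 (Sylvester construction)")
  H <- matrix(1, 1, 1)
  while (nrow(H) < n) H <- rbind(cbind(H, H), cbind(H, -H))
  .new_scheme(H)
}

#' @rdname hadamard_scheme
#' @export
identity_scheme <- function(n) {
  .assert(n >= 1, "n must be >= 1")
  .new_scheme(diag(n))
}

.new_scheme <- function(H, T = rep(0, nrow(H))) {
  .assert(all(is.finite(T)), "delays must be finite")
  structure(list(H = H, T = T, n_tx_per_volume = ncol(H)),
            class = "cusi_scheme")
}

#' @export
print.cusi_scheme <- function(x, ...) {
  cat(sprintf("cusi encoding scheme: %d elements x %d transmissions\n",
              nrow(x$H), ncol(x$H)))
  invisible(x)
}

# Scheme with a subset of transmit columns (used for subframe processing
# and compounding studies).
.subset_scheme <- function(scheme, cols) {
  .new_scheme(scheme$H[, cols, drop = FALSE], scheme$T)
}

#' Forward field of one encoded transmission
#'
#' The field of transmission `n_t` at frequency index `n_w` is the
#' apodization-weighted, delay-phased sum of the per-element calibration
#' fields: `sum_ne H[ne, nt] p_ne exp(-i 2 pi f T[ne])`.
#'
#' @param cal A [synthesize_calibration()] container.
#' @param scheme A [hadamard_scheme()] or [identity_scheme()].
#' @param n_t Transmission index (1-based).
#' @param n_w Frequency index (1-based).
#' @return A [planar_field()] at the calibration plane.
#' @export
transmit_field <- function(cal, scheme, n_t, n_w) {
  d <- dim(cal$fields)
  .assert(n_t >= 1 && n_t <= ncol(scheme$H), "transmission index out of range")
  .assert(n_w >= 1 && n_w <= d[3], "frequency index out of range")
  .assert(nrow(scheme$H) == d[4],
          "scheme element count does not match the calibration")
  f <- cal$freqs$freqs[n_w]
  wts <- scheme$H[, n_t] * exp(-1i * 2 * pi * f * scheme$T)
  P <- matrix(cal$fields[, , n_w, ], d[1] * d[2], d[4])
  planar_field(matrix(P %*% wts, d[1], d[2]), cal$plane_spacing,
               depth = cal$z_plane, frequency = f)
}

#' Decode Hadamard-encoded channel data
#'
#' Multiplies the transmission axis of an acquisition tensor by the inverse
#' of the transmit apodization matrix, recovering single-element-transmit
#' data. Provided for channel-domain processing and SNR studies; the imaging
#' operator instead folds `H` into the model so reconstruction needs no
#' explicit decoding.
#'
#' @param acq A [acquisition_tensor()] (dimensions `(N_w, N_t, N_e, N_f)`).
#' @param scheme The encoding scheme used on transmit (must be invertible).
#' @return The decoded acquisition tensor, with an identity scheme attached.
#' @export
hadamard_decode <- function(acq, scheme) {
  H <- scheme$H
  .assert(nrow(H) == ncol(H), "scheme must be square to decode")
  Hinv <- tryCatch(solve(t(H)), error = function(e) {
    stop("encoding matrix is singular", call. = FALSE)
  })
  d <- dim(acq$v)
  .assert(d[2] == ncol(H), "transmission axis does not match the scheme")
  vp <- aperm(acq$v, c(2, 1, 3, 4))
  vp <- Hinv %*% matrix(vp, d[2], prod(d[-2]))
  dim(vp) <- c(d[2], d[1], d[3], d[4])
  acq$v <- aperm(vp, c(2, 1, 3, 4))
  acq$scheme <- identity_scheme(ncol(H))
  acq
}
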