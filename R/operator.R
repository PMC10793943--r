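#' Matrix-free imaging operator
#'
#' Realizes the linear acquisition model `v = A u` without ever materializing
#' `A`. Each row of `A`, indexed by (frequency, transmission, element),
#' contains the pulse-echo signature `p_ne(x) p_nt(x)` of every voxel: the
#' per-element calibration field times the encoded transmit field, evaluated
#' depth slice by depth slice. Element fields are stepped between depths
#' with the angular-spectrum propagator on a zero-padded plane; the angular
#' cutoff is applied against the cumulative distance from the calibration
#' plane, so a streamed multi-slice pass is exactly equivalent to
#' reconstructing each slice independently.
#'
#' With `phase_only = TRUE`, every entry of the model is normalized to unit
#' modulus (`A_new = exp(i arg(A))`), which reweights the sensitivity to
#' unity for each voxel; entries with modulus below
#' `amplitude_floor * max(modulus)` within a frequency-depth block are zeroed
#' instead, since their phase is numerically meaningless.
#'
#' @param cal A [synthesize_calibration()] container (or a measured
#'   calibration in the same layout).
#' @param scheme A transmit encoding scheme ([hadamard_scheme()] etc.).
#' @param grid An [image_grid()]; its lateral lattice must coincide with the
#'   calibration-plane lattice (same spacing, voxel centres on plane sample
#'   points) and lie within the plane extent.
#' @param phase_only Use the phase-only (matched-filter) model.
#' @param amplitude_floor Relative modulus below which phase-only entries
#'   are zeroed.
#' @param pad_factor Zero-padding ratio for the propagation transforms.
#' @param cutoff Apply the angular cutoff during depth stepping.
#' @return An object of class `cusi_operator`.
#' @export
imaging_operator <- function(cal, scheme, grid, phase_only = FALSE,
                             amplitude_floor = 1e-6, pad_factor = 2,
                             cutoff = TRUE) {
  d <- dim(cal$fields)
  .assert(nrow(scheme$H) == d[4],
          "scheme element count does not match the calibration")
  .assert(abs(grid$spacing - cal$plane_spacing) < 1e-12,
          "grid spacing must equal the calibration plane spacing")
  gx <- grid$origin[1] + (seq_len(grid$dims[1]) - 1) * grid$spacing
  gy <- grid$origin[2] + (seq_len(grid$dims[2]) - 1) * grid$spacing
  tol <- 1e-6 * grid$spacing
  ix <- vapply(gx, function(v) {
    i <- which.min(abs(cal$x - v))
    if (abs(cal$x[i] - v) > tol) NA_integer_ else i
  }, integer(1))
  iy <- vapply(gy, function(v) {
    i <- which.min(abs(cal$y - v))
    if (abs(cal$y[i] - v) > tol) NA_integer_ else i
  }, integer(1))
  .assert(!anyNA(ix) && !anyNA(iy),
          "image grid must lie on the calibration-plane lattice and within its extent")
  structure(list(cal = cal, scheme = scheme, grid = grid,
                 phase_only = phase_only, amplitude_floor = amplitude_floor,
                 pad_factor = pad_factor, cutoff = cutoff,
                 ix = ix, iy = iy),
            class = "cusi_operator")
}

#' @export
print.cusi_operator <- function(x, ...) {
  d <- dim(x$cal$fields)
  cat(sprintf(
    "cusi imaging operator: %d freq x %d tx x %d el rows -> %s voxels%s\n",
    d[3], ncol(x$scheme$H), d[4], paste(x$grid$dims, collapse = " x "),
    if (x$phase_only) " (phase-only)" else ""))
  invisible(x)
}

# Core streamed pass shared by forward and adjoint application. `x` carries
# a trailing frame axis so frame batches share the depth stepping:
#   adjoint = TRUE : x is v (N_w, N_t, N_e, N_F) -> u (gx, gy, gz, N_F)
#   adjoint = FALSE: x is u (gx, gy, gz, N_F)    -> v (N_w, N_t, N_e, N_F)
.op_pass <- function(op, x, adjoint) {
  cal <- op$cal
  H <- op$scheme$H
  dcal <- dim(cal$fields)
  nx <- dcal[1]; ny <- dcal[2]; Nw <- dcal[3]; Ne <- dcal[4]
  Nt <- ncol(H)
  g <- op$grid$dims
  npix <- g[1] * g[2]
  NF <- length(x) / if (adjoint) (Nw * Nt * Ne) else prod(g)
  .assert(NF == round(NF), "input shape inconsistent with the operator")
  NF <- as.integer(NF)
  if (adjoint) {
    xv <- array(x, c(Nw, Nt, Ne, NF))
    out <- array(0 + 0i, c(npix, g[3], NF))
  } else {
    xv <- array(x, c(npix, g[3], NF))
    out <- array(0 + 0i, c(Nw, Nt, Ne, NF))
  }
  np1 <- ceiling(nx * op$pad_factor); np2 <- ceiling(ny * op$pad_factor)
  kg <- .as_kgrids(np1, np2, cal$plane_spacing)
  D <- min(np1, np2) * cal$plane_spacing
  sx <- seq_len(nx); sy <- seq_len(ny)
  zs <- op$grid$z_offset + (seq_len(g[3]) - 1) * op$grid$spacing
  fcols <- function(f) (f - 1L) * Ne + seq_len(Ne)
  for (w in seq_len(Nw)) {
    k <- 2 * pi * cal$freqs$freqs[w] / op$cal$probe$c_medium
    P <- array(0 + 0i, c(np1, np2, Ne))
    P[sx, sy, ] <- cal$fields[, , w, ]
    zcur <- 0
    for (iz in seq_len(g[3])) {
      dstep <- zs[iz] - zcur
      if (dstep > 1e-15) {
        Hs <- .as_propagator(kg$kr2, k, dstep, cutoff_distance = zs[iz],
                             D = D, cutoff = op$cutoff)
        for (ne in seq_len(Ne)) P[, , ne] <- .ifft2(stats::fft(P[, , ne]) * Hs)
        zcur <- zs[iz]
      }
      Pg <- P[op$ix, op$iy, , drop = FALSE]
      dim(Pg) <- c(npix, Ne)
      PTg <- Pg %*% H
      if (!op$phase_only) {
        if (adjoint) {
          V <- matrix(xv[w, , , ], Nt, Ne * NF)
          Q <- Conj(PTg) %*% V
          for (f in seq_len(NF)) {
            out[, iz, f] <- out[, iz, f] +
              rowSums(Conj(Pg) * Q[, fcols(f), drop = FALSE])
          }
        } else {
          for (f in seq_len(NF)) {
            out[w, , , f] <- out[w, , , f] + t(PTg) %*% (Pg * xv[, iz, f])
          }
        }
      } else {
        m <- 0
        for (ne in seq_len(Ne)) m <- max(m, max(Mod(Pg[, ne] * PTg)))
        if (m > 0) {
          flo <- op$amplitude_floor * m
          for (ne in seq_len(Ne)) {
            B <- Pg[, ne] * PTg
            aB <- Mod(B)
            B <- B / pmax(aB, flo)
            B[aB < flo] <- 0 + 0i
            if (adjoint) {
              out[, iz, ] <- out[, iz, ] +
                Conj(B) %*% matrix(xv[w, , ne, ], Nt, NF)
            } else {
              out[w, , ne, ] <- out[w, , ne, ] +
                t(B) %*% matrix(xv[, iz, ], npix, NF)
            }
          }
        }
      }
    }
  }
  if (adjoint) {
    dim(out) <- c(g[1], g[2], g[3], NF)
  }
  out
}

#' Apply the imaging operator
#'
#' `forward_apply()` evaluates `v = A u` for one volume; `adjoint_apply()`
#' evaluates `u = A^H v` for one frame of channel data. The two share one
#' traversal with conjugation reversed, so they form an exact adjoint pair.
#'
#' @param op A [imaging_operator()].
#' @param volume Complex 3D array on the operator's grid.
#' @param v_frame Complex array `(N_w, N_t, N_e)` of one frame's data.
#' @return `forward_apply`: an `(N_w, N_t, N_e)` array; `adjoint_apply`: a
#'   complex volume on the grid.
#' @export
forward_apply <- function(op, volume) {
  .assert(length(volume) == prod(op$grid$dims),
          "volume shape does not match the operator grid")
  out <- .op_pass(op, volume, adjoint = FALSE)
  dim(out) <- dim(out)[1:3]
  out
}

#' @rdname forward_apply
#' @export
adjoint_apply <- function(op, v_frame) {
  d <- dim(op$cal$fields)
  .assert(length(v_frame) == d[3] * ncol(op$scheme$H) * d[4],
          "frame data shape does not match the operator")
  out <- .op_pass(op, v_frame, adjoint = TRUE)
  dim(out) <- dim(out)[1:3]
  out
}

#' Reconstructed volume ensemble
#'
#' Container for a stack of complex reconstructed volumes
#' `u(x, y, z, frame)` with provenance.
#'
#' @param u Complex array `(n_x, n_y, n_z, n_frames)`.
#' @param grid The [image_grid()] of the reconstruction.
#' @param frame_index Original acquisition frame index of each volume.
#' @param frame_times Acquisition times, seconds.
#' @param frame_rate Nominal frame rate, Hz.
#' @param provenance List describing the solver and its parameters.
#' @return An object of class `cusi_volumes`.
#' @export
volume_stack <- function(u, grid, frame_index = seq_len(dim(u)[4]),
                         frame_times = NULL, frame_rate = NA_real_,
                         provenance = list()) {
  if (length(dim(u)) == 3) dim(u) <- c(dim(u), 1)
  .assert(length(dim(u)) == 4, "u must be a 4D array")
  .assert(all(dim(u)[1:3] == grid$dims), "u shape does not match the grid")
  structure(list(u = u, grid = grid, frame_index = frame_index,
                 frame_times = frame_times, frame_rate = frame_rate,
                 n_frames = dim(u)[4], provenance = provenance),
            class = "cusi_volumes")
}

#' @export
print.cusi_volumes <- function(x, ...) {
  cat(sprintf("cusi volume stack: %s voxels x %d frames (%s)\n",
              paste(x$grid$dims, collapse = " x "), x$n_frames,
              if (length(x$provenance)) x$provenance$method else "unknown"))
  invisible(x)
}
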