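#' Scatterer phantoms
#'
#' A phantom is a set of point scatterers per frame: a positions array
#' `(n_scatterers, 3, n_frames)` in metres, complex reflectivities, and an
#' optional blood/tissue label per scatterer.
#'
#' @param positions Array `(n_s, 3, n_f)` of scatterer positions, metres.
#' @param amplitudes Complex reflectivity per scatterer.
#' @param labels Optional character vector (`"blood"` / `"tissue"`).
#' @param frame_rate Frame rate of the motion, Hz (NA for static phantoms).
#' @return An object of class `cusi_phantom`.
#' @export
phantom <- function(positions, amplitudes = NULL, labels = NULL,
                    frame_rate = NA_real_) {
  if (length(dim(positions)) == 2) dim(positions) <- c(dim(positions), 1)
  .assert(length(dim(positions)) == 3 && dim(positions)[2] == 3,
          "positions must be an (n_s, 3, n_f) array")
  .assert(all(is.finite(positions)), "positions must be finite")
  n_s <- dim(positions)[1]
  if (is.null(amplitudes)) amplitudes <- rep(1 + 0i, n_s)
  .assert(length(amplitudes) == n_s && all(is.finite(Mod(amplitudes))),
          "amplitudes must be finite, one per scatterer")
  structure(list(positions = positions, amplitudes = amplitudes + 0i,
                 labels = labels, n_frames = dim(positions)[3],
                 n_scatterers = n_s, frame_rate = frame_rate),
            class = "cusi_phantom")
}

#' @export
print.cusi_phantom <- function(x, ...) {
  cat(sprintf("cusi phantom: %d scatterers x %d frames\n",
              x$n_scatterers, x$n_frames))
  invisible(x)
}

#' Single-frame spiral phantom
#'
#' Unit-amplitude scatterers tracing a constant-radius 3D helix through a
#' box, the standard test object for comparing bare-aperture and
#' coded-aperture imaging. Endpoints lie on the z faces of the box.
#'
#' @param extent Box size `(e_x, e_y, e_z)` in metres.
#' @param n_points Number of scatterers (>= 2).
#' @param turns Number of helix turns.
#' @param center Box centre `(x, y, z)`, metres.
#' @param radius Helix radius, metres (default 40% of the lateral extent).
#' @return A [phantom()] with one frame.
#' @export
spiral_phantom <- function(extent, n_points = 1000, turns = 3,
                           center = c(0, 0, extent[3] / 2),
                           radius = 0.4 * min(extent[1:2])) {
  .assert(n_points >= 2, "n_points must be >= 2")
  s <- seq(0, 1, length.out = n_points)
  th <- 2 * pi * turns * s
  pos <- cbind(center[1] + radius * cos(th),
               center[2] + radius * sin(th),
               center[3] + (s - 0.5) * extent[3])
  phantom(array(pos, c(n_points, 3, 1)))
}

#' Analytic helix arc length
#'
#' Closed-form length of the [spiral_phantom()] centreline,
#' `sqrt((2 pi turns r)^2 + h^2)`.
#'
#' @param turns Number of turns.
#' @param radius Helix radius, metres.
#' @param height Axial extent, metres.
#' @return Arc length in metres.
#' @export
helix_length <- function(turns, radius, height) {
  sqrt((2 * pi * turns * radius)^2 + height^2)
}

#' Advecting flow-tube phantom
#'
#' Scatterers seeded uniformly inside a cylindrical tube advect along the
#' tube axis by `speed / frame_rate` per frame (wrapping at the tube ends).
#' An optional static cloud of stronger "tissue" scatterers (amplitude
#' `1 / static_fraction`) fills a surrounding box, providing the clutter
#' that the SVD filter must remove.
#'
#' @param tube List with `start`, `end` (3-vectors, metres) and `radius`.
#' @param speed Advection speed along the axis, m/s (signed: positive from
#'   `start` towards `end`).
#' @param n_frames Number of frames.
#' @param frame_rate Frame rate, Hz.
#' @param density Scatterer density, per cubic millimetre.
#' @param seed RNG seed; the phantom is deterministic per seed.
#' @param static_fraction Blood-to-tissue amplitude ratio; 0 disables the
#'   static cloud.
#' @param static_box Optional list `(center, size)` for the cloud, metres.
#' @param static_density Cloud density, per cubic millimetre.
#' @return A [phantom()] with `n_frames` frames.
#' @export
flow_phantom <- function(tube, speed, n_frames, frame_rate, density = 50,
                         seed = 1, static_fraction = 0, static_box = NULL,
                         static_density = density) {
  .assert(frame_rate > 0, "frame_rate must be positive")
  .assert(n_frames >= 1, "n_frames must be >= 1")
  start <- tube$start; end <- tube$end; r <- tube$radius
  axis <- end - start
  L <- sqrt(sum(axis^2))
  .assert(L > 0 && r > 0, "tube is empty")
  u <- axis / L
  # orthonormal frame transverse to the tube axis
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  vol_mm3 <- pi * r^2 * L * 1e9
  n_s <- max(2L, round(density * vol_mm3))
  rng <- .with_seed(seed, {
    list(t0 = stats::runif(n_s) * L,
         rad = r * sqrt(stats::runif(n_s)),
         ang = 2 * pi * stats::runif(n_s),
         cloud = if (static_fraction > 0 && !is.null(static_box)) {
           nc <- max(1L, round(static_density * prod(static_box$size) * 1e9))
           sweep(matrix(stats::runif(3 * nc) - 0.5, nc, 3) %*%
                   diag(static_box$size), 2, static_box$center, "+")
         } else NULL)
  })
  n_c <- if (is.null(rng$cloud)) 0L else nrow(rng$cloud)
  pos <- array(NA_real_, c(n_s + n_c, 3, n_frames))
  off <- outer(rng$rad * cos(rng$ang), e1) + outer(rng$rad * sin(rng$ang), e2)
  for (f in seq_len(n_frames)) {
    tf <- (rng$t0 + speed * (f - 1) / frame_rate) %% L
    pos[seq_len(n_s), , f] <- sweep(outer(tf, u) + off, 2, start, "+")
    if (n_c > 0) pos[n_s + seq_len(n_c), , f] <- rng$cloud
  }
  amps <- c(rep(1 + 0i, n_s),
            rep(if (static_fraction > 0) 1 / static_fraction else 0, n_c))
  phantom(pos, amps,
          labels = c(rep("blood", n_s), rep("tissue", n_c)),
          frame_rate = frame_rate)
}

#' Deposit scatterers onto an image grid
#'
#' Spreads each scatterer's complex amplitude over the eight surrounding
#' voxels by trilinear interpolation, so sub-voxel frame-to-frame motion
#' produces smooth Doppler phase.
#'
#' @param phan A [phantom()].
#' @param grid A [image_grid()].
#' @param frame Frame index (1-based).
#' @return A complex 3D array of grid reflectivity.
#' @export
deposit_phantom <- function(phan, grid, frame = 1) {
  .assert(frame >= 1 && frame <= phan$n_frames, "frame index out of range")
  pos <- phan$positions[, , frame, drop = FALSE]
  dim(pos) <- dim(pos)[1:2]
  rel <- position_to_voxel(grid, pos)
  dims <- grid$dims
  .assert(all(rel >= -1e-9) &&
            all(sweep(rel, 2, dims - 1, "-") <= 1e-9),
          "scatterer outside the image grid")
  rel <- pmin(pmax(rel, 0), matrix(rep(dims - 1, each = nrow(rel)), ncol = 3) - 1e-12)
  i0 <- floor(rel)
  fr <- rel - i0
  vol_re <- numeric(prod(dims))
  vol_im <- numeric(prod(dims))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (cx * fr[, 1] + (1 - cx) * (1 - fr[, 1])) *
      (cy * fr[, 2] + (1 - cy) * (1 - fr[, 2])) *
      (cz * fr[, 3] + (1 - cz) * (1 - fr[, 3]))
    li <- 1 + (i0[, 1] + cx) + dims[1] * ((i0[, 2] + cy) +
                                            dims[2] * (i0[, 3] + cz))
    contrib <- w * phan$amplitudes
    agg_re <- rowsum(Re(contrib), li)
    agg_im <- rowsum(Im(contrib), li)
    at <- as.integer(rownames(agg_re))
    vol_re[at] <- vol_re[at] + agg_re[, 1]
    vol_im[at] <- vol_im[at] + agg_im[, 1]
  }
  array(complex(real = vol_re, imaginary = vol_im), dims)
}
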