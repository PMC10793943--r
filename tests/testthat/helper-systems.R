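# Shared desk-scale imaging systems and independent oracles.
# Fixtures are built once per test run and cached.

.fix_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fix_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fix_cache)
  }
  get(name, envir = .fix_cache, inherits = FALSE)
}

# Tiny 2x2-element system for dense-matrix oracles (seconds to build).
tiny_system <- function() fixture("tiny", {
  probe <- probe_geometry(2, 2, pitch = 1.25e-3)
  freqs <- make_frequency_grid(15.625e6, 0.5, 4)
  mask <- generate_mask(3, extent = 4e-3, spacing = 100e-6,
                        feature_size = 400e-6)
  cal <- synthesize_calibration(probe, mask, freqs, plane_extent = 4e-3,
                                plane_spacing = 100e-6, z_plane = 6e-3)
  grid <- image_grid(c(8, 8, 3), 100e-6, z_offset = 2e-4)
  list(probe = probe, freqs = freqs, mask = mask, cal = cal, grid = grid,
       scheme = hadamard_scheme(4))
})

# Well-conditioned 2x2 system on a coarse plane for solver oracles.
solver_system <- function() fixture("solver", {
  probe <- probe_geometry(2, 2, pitch = 1.25e-3)
  freqs <- make_frequency_grid(15.625e6, 0.5, 6)
  mask <- generate_mask(3, extent = 4.8e-3, spacing = 200e-6,
                        feature_size = 450e-6)
  cal <- synthesize_calibration(probe, mask, freqs, plane_extent = 4.8e-3,
                                plane_spacing = 200e-6, z_plane = 6e-3)
  grid <- image_grid(c(4, 4, 2), 200e-6, z_offset = 3e-4)
  op <- imaging_operator(cal, hadamard_scheme(4), grid)
  A <- materialize_A(op)
  list(cal = cal, grid = grid, op = op, A = A)
})

# 4x4-element masked/bare pair at the physical band, used for imaging
# comparisons (Fig.-1B-style) and point recovery.
desk_system <- function() fixture("desk", {
  probe <- probe_geometry(4, 4)
  freqs <- make_frequency_grid(15.625e6, 0.5, 8)
  mask <- generate_mask(2, extent = 8e-3, spacing = 80e-6)
  cal_m <- synthesize_calibration(probe, mask, freqs, plane_extent = 8e-3,
                                  plane_spacing = 80e-6, z_plane = 12e-3)
  cal_b <- synthesize_calibration(probe, NULL, freqs, plane_extent = 8e-3,
                                  plane_spacing = 80e-6, z_plane = 12e-3)
  list(probe = probe, freqs = freqs, mask = mask,
       cal = cal_m, cal_bare = cal_b, scheme = hadamard_scheme(16))
})

# Low-frequency (4 MHz) system for Doppler phase studies: the voxel
# spacing there satisfies 2 k spacing < pi so gridded sub-voxel motion
# carries an unaliased lag-1 phase.
doppler_system <- function() fixture("doppler", {
  probe <- probe_geometry(4, 4, f_center = 4e6)
  freqs <- make_frequency_grid(4e6, 0.5, 6)
  mask <- generate_mask(2, extent = 6.4e-3, spacing = 50e-6,
                        feature_size = 500e-6)
  cal <- synthesize_calibration(probe, mask, freqs, plane_extent = 6.4e-3,
                                plane_spacing = 50e-6, z_plane = 12e-3,
                                n_cycles = 3)
  grid <- image_grid(c(28, 28, 20), 50e-6, z_offset = 0.5e-3)
  ctr <- voxel_position(grid, (grid$dims - 1) / 2)
  # tube length is 4 half-wavelengths at 4 MHz so scatterer wrap-around
  # is phase-coherent
  tube <- list(start = c(ctr[1], ctr[2], grid$origin[3] + 2 * 50e-6),
               end = c(ctr[1], ctr[2], grid$origin[3] + 17 * 50e-6),
               radius = 0.35e-3)
  xs <- grid$origin[1] + (seq_len(28) - 1) * 50e-6
  zs <- grid$origin[3] + (seq_len(20) - 1) * 50e-6
  r2 <- outer((xs - ctr[1])^2, (xs - ctr[2])^2, "+")
  intube <- array(FALSE, grid$dims)
  for (k in seq_len(20)) {
    intube[, , k] <- (r2 <= (0.3e-3)^2) &
      (zs[k] >= tube$start[3]) & (zs[k] <= tube$end[3])
  }
  list(probe = probe, freqs = freqs, cal = cal, grid = grid,
       scheme = hadamard_scheme(16), tube = tube, intube = intube,
       frame_rate = 500, f_doppler = 4e6)
})

# Independent dense materialization of the imaging model: per depth, each
# element field is propagated from the calibration plane in a single
# angular-spectrum step, and every matrix entry is assembled by explicit
# scalar loops (no shared accumulation code with the operator).
materialize_A <- function(op) {
  cal <- op$cal
  g <- op$grid$dims
  H <- op$scheme$H
  d <- dim(cal$fields)
  Nw <- d[3]; Ne <- d[4]; Nt <- ncol(H)
  gx <- op$grid$origin[1] + (seq_len(g[1]) - 1) * op$grid$spacing
  gy <- op$grid$origin[2] + (seq_len(g[2]) - 1) * op$grid$spacing
  ix <- vapply(gx, function(v) which.min(abs(cal$x - v)), integer(1))
  iy <- vapply(gy, function(v) which.min(abs(cal$y - v)), integer(1))
  zs <- op$grid$origin[3] + (seq_len(g[3]) - 1) * op$grid$spacing
  A <- matrix(0 + 0i, Nw * Nt * Ne, prod(g))
  for (k in seq_len(g[3])) {
    # element fields at this depth, stepped independently per element
    P <- vector("list", Ne)
    for (ne in seq_len(Ne)) {
      P[[ne]] <- lapply(seq_len(Nw), function(w) {
        fl <- planar_field(cal$fields[, , w, ne], cal$plane_spacing, 0,
                           cal$freqs$freqs[w])
        if (zs[k] > 0) {
          angular_spectrum_step(fl, zs[k], cal$probe$c_medium,
                                pad_factor = op$pad_factor,
                                cutoff = op$cutoff)$values
        } else {
          fl$values
        }
      })
    }
    for (jy in seq_len(g[2])) for (jx in seq_len(g[1])) {
      col <- (k - 1) * g[1] * g[2] + (jy - 1) * g[1] + jx
      for (w in seq_len(Nw)) for (nt in seq_len(Nt)) for (ne in seq_len(Ne)) {
        pnt <- 0 + 0i
        for (e in seq_len(Ne)) {
          pnt <- pnt + H[e, nt] * P[[e]][[w]][ix[jx], iy[jy]]
        }
        row <- (ne - 1) * Nt * Nw + (nt - 1) * Nw + w
        A[row, col] <- P[[ne]][[w]][ix[jx], iy[jy]] * pnt
      }
    }
  }
  if (op$phase_only) {
    aA <- Mod(A)
    flo <- op$amplitude_floor * max(aA)
    A <- A / pmax(aA, flo)
    A[aA < flo] <- 0 + 0i
  }
  A
}

# First Rayleigh-Sommerfeld integral by direct summation (diffraction
# oracle for the angular-spectrum propagator).
rayleigh_sommerfeld <- function(field, d, c) {
  v <- field$values
  n1 <- nrow(v); n2 <- ncol(v)
  k <- 2 * pi * field$frequency / c
  out <- matrix(0 + 0i, n1, n2)
  X <- matrix(field$x, n1, n2)
  Y <- matrix(field$y, n1, n2, byrow = TRUE)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    r <- sqrt((field$x[i] - X)^2 + (field$y[j] - Y)^2 + d^2)
    kern <- (d / r) * (1i * k + 1 / r) * exp(-1i * k * r) / (2 * pi * r)
    out[i, j] <- sum(v * kern) * field$spacing^2
  }
  planar_field(out, field$spacing, field$depth + d, field$frequency)
}

rel_l2 <- function(a, b) sqrt(sum(Mod(a - b)^2) / max(sum(Mod(b)^2), 1e-300))

rand_cplx <- function(n) {
  complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
}
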