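#' System-matrix correlation map around a voxel
#'
#' For a chosen voxel's model column (its noiseless pulse-echo signature
#' across all frequency/transmission/element rows), computes the magnitude
#' of the normalized complex correlation with every voxel's column over a
#' surrounding region. The map equals 1 at the chosen voxel; its decay sets
#' the resolution and its outliers the side lobes. The correlation
#' factorizes per frequency into an element-field and a transmit-field
#' inner product, which is how it is evaluated here without materializing
#' any columns.
#'
#' @param op A [imaging_operator()] (the raw amplitude model is analyzed).
#' @param voxel 1-based voxel index `(i, j, k)` on the operator grid.
#' @param region_extent Region size `(e_x, e_y, e_z)` in metres, centred on
#'   the voxel; must lie within the grid.
#' @return A 3D array of correlation magnitudes over the region, with
#'   attributes `spacing`, `peak` (1-based index of the chosen voxel within
#'   the region) and `offset` (1-based grid index of the region corner).
#' @export
system_correlation_map <- function(op, voxel, region_extent) {
  g <- op$grid$dims
  sp <- op$grid$spacing
  .assert(length(voxel) == 3 && all(voxel >= 1) && all(voxel <= g),
          "voxel must be a 1-based index inside the grid")
  half <- floor(region_extent / sp / 2)
  lo <- voxel - half
  hi <- voxel + half
  .assert(all(lo >= 1) && all(hi <= g), "region extends beyond the grid")
  rg <- hi - lo + 1
  cal <- op$cal
  H <- op$scheme$H
  dcal <- dim(cal$fields)
  nx <- dcal[1]; ny <- dcal[2]; Nw <- dcal[3]; Ne <- dcal[4]
  np1 <- ceiling(nx * op$pad_factor); np2 <- ceiling(ny * op$pad_factor)
  kg <- .as_kgrids(np1, np2, cal$plane_spacing)
  D <- min(np1, np2) * cal$plane_spacing
  sx <- seq_len(nx); sy <- seq_len(ny)
  ixr <- op$ix[lo[1]:hi[1]]; iyr <- op$iy[lo[2]:hi[2]]
  npr <- rg[1] * rg[2]
  ix0 <- op$ix[voxel[1]]; iy0 <- op$iy[voxel[2]]
  z0 <- op$grid$z_offset + (voxel[3] - 1) * sp
  zs <- op$grid$z_offset + (lo[3]:hi[3] - 1) * sp
  num <- array(0 + 0i, c(npr, rg[3]))
  den <- array(0, c(npr, rg[3]))
  den0 <- 0
  for (w in seq_len(Nw)) {
    k <- 2 * pi * cal$freqs$freqs[w] / cal$probe$c_medium
    S <- array(0 + 0i, c(np1, np2, Ne))
    S[sx, sy, ] <- cal$fields[, , w, ]
    for (ne in seq_len(Ne)) S[, , ne] <- stats::fft(S[, , ne])
    # fields at the chosen voxel's depth
    e0 <- complex(Ne)
    Hs0 <- if (z0 > 0) .as_propagator(kg$kr2, k, z0, z0, D, op$cutoff) else NULL
    for (ne in seq_len(Ne)) {
      fld <- if (is.null(Hs0)) .ifft2z(S[, , ne]) else .ifft2(S[, , ne] * Hs0)
      e0[ne] <- fld[ix0, iy0]
    }
    t0 <- as.vector(crossprod(H, e0))
    den0 <- den0 + sum(Mod(e0)^2) * sum(Mod(t0)^2)
    for (izr in seq_along(zs)) {
      z <- zs[izr]
      Hs <- if (z > 0) .as_propagator(kg$kr2, k, z, z, D, op$cutoff) else NULL
      Pg <- matrix(0 + 0i, npr, Ne)
      for (ne in seq_len(Ne)) {
        fld <- if (is.null(Hs)) .ifft2z(S[, , ne]) else .ifft2(S[, , ne] * Hs)
        Pg[, ne] <- fld[ixr, iyr]
      }
      PTg <- Pg %*% H
      ce <- Pg %*% Conj(e0)
      ct <- PTg %*% Conj(t0)
      num[, izr] <- num[, izr] + ce * ct
      den[, izr] <- den[, izr] +
        rowSums(Mod(Pg)^2) * rowSums(Mod(PTg)^2)
    }
  }
  .assert(den0 > 0, "chosen voxel lies outside the insonified zone")
  cmap <- Mod(num) / sqrt(den * den0)
  cmap[den == 0] <- 0
  cmap <- array(cmap, rg)
  attr(cmap, "spacing") <- sp
  attr(cmap, "peak") <- as.integer(voxel - lo + 1)
  attr(cmap, "offset") <- as.integer(lo)
  cmap
}

# inverse FFT of an already-transformed spectrum back to the spatial field
# (no propagation), used at z = 0
.ifft2z <- function(S) .ifft2(S)

#' Resolution and side-lobe analysis of a correlation map
#'
#' Full width at half maximum along each axis through the map peak (0.5
#' crossings located by linear interpolation between samples), and the peak
#' secondary side lobe: the maximum value outside the contiguous main lobe,
#' defined as the 6 dB (value > 0.5) region connected to the peak, in dB.
#'
#' @param cmap A [system_correlation_map()] (or any 3D array with an
#'   interior peak equal to its maximum).
#' @param spacing Sample spacing, metres.
#' @param sidelobe_floor_db Value reported when no signal exists outside
#'   the main lobe.
#' @return An object of class `cusi_resolution` with fields
#'   `lateral_fwhm_x`, `lateral_fwhm_y`, `axial_fwhm` (metres),
#'   `peak_secondary_sidelobe_db`, `voxel` (peak index).
#' @export
resolution_from_map <- function(cmap, spacing = attr(cmap, "spacing"),
                                sidelobe_floor_db = -120) {
  d <- dim(cmap)
  pk <- which(cmap == max(cmap), arr.ind = TRUE)[1, ]
  .assert(all(pk > 1 | d == 1) && all(pk < d | d == 1),
          "map peak lies on the region boundary")
  pkv <- cmap[pk[1], pk[2], pk[3]]
  half_width <- function(prof, ipk) {
    # distance from the peak to the 0.5 * peak crossing on each side,
    # located by linear interpolation between samples
    hw <- function(vals) {
      vv <- c(pkv, vals)
      below <- which(vv < 0.5 * pkv)
      if (!length(below)) return(length(vals))  # never falls below: bound
      j <- below[1]
      (j - 2) + (vv[j - 1] - 0.5 * pkv) / (vv[j - 1] - vv[j])
    }
    right <- if (ipk < length(prof)) hw(prof[(ipk + 1):length(prof)]) else 0.5
    left <- if (ipk > 1) hw(prof[(ipk - 1):1]) else 0.5
    (left + right) * spacing
  }
  fx <- half_width(cmap[, pk[2], pk[3]], pk[1])
  fy <- half_width(cmap[pk[1], , pk[3]], pk[2])
  fz <- half_width(cmap[pk[1], pk[2], ], pk[3])
  # contiguous 6 dB main lobe by flood fill (6-connectivity)
  inlobe <- cmap > 0.5 * pkv
  lobe <- array(FALSE, d)
  queue <- matrix(pk, ncol = 3)
  lobe[pk[1], pk[2], pk[3]] <- TRUE
  steps <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (nrow(queue) > 0) {
    cur <- queue[1, , drop = FALSE]
    queue <- queue[-1, , drop = FALSE]
    for (s in seq_len(6)) {
      nb <- cur + steps[s, , drop = FALSE]
      if (all(nb >= 1) && all(nb <= d) &&
          inlobe[nb[1], nb[2], nb[3]] && !lobe[nb[1], nb[2], nb[3]]) {
        lobe[nb[1], nb[2], nb[3]] <- TRUE
        queue <- rbind(queue, nb)
      }
    }
  }
  outside <- cmap[!lobe]
  sl <- if (length(outside) && max(outside) > 0) {
    20 * log10(max(outside) / pkv)
  } else {
    sidelobe_floor_db
  }
  structure(list(lateral_fwhm_x = fx, lateral_fwhm_y = fy, axial_fwhm = fz,
                 peak_secondary_sidelobe_db = max(sl, sidelobe_floor_db),
                 voxel = pk),
            class = "cusi_resolution")
}

#' @export
print.cusi_resolution <- function(x, ...) {
  cat(sprintf(
    "cusi resolution: FWHM x %.1f um, y %.1f um, z %.1f um; side lobe %.1f dB\n",
    x$lateral_fwhm_x * 1e6, x$lateral_fwhm_y * 1e6, x$axial_fwhm * 1e6,
    x$peak_secondary_sidelobe_db))
  invisible(x)
}

#' Measured SNR gain of Hadamard transmit encoding
#'
#' Simulates noisy point-scatterer channel data twice — once with
#' single-element (identity) transmits and once with full Hadamard
#' apodization at equal per-entry noise — decodes the Hadamard set with the
#' inverse encoding matrix, and reports the measured fold improvement in
#' amplitude SNR (peak signal magnitude over the measured noise std at the
#' channel level). Orthogonal averaging over all elements predicts
#' `sqrt(N_e)`.
#'
#' @param cal A [synthesize_calibration()] container.
#' @param grid An [image_grid()] for the scatterer.
#' @param noise_sigma Noise std per complex tensor entry (> 0).
#' @param n_trials Number of noise realizations (>= 10).
#' @param seed RNG seed.
#' @param scatterer Optional scatterer position (defaults to the grid
#'   centre voxel).
#' @return A list with `ratio`, `snr_encoded`, `snr_single`, `n_elements`,
#'   `n_trials`.
#' @export
snr_gain <- function(cal, grid, noise_sigma, n_trials = 100, seed = 1,
                     scatterer = NULL) {
  .assert(n_trials >= 10, "n_trials must be >= 10")
  .assert(noise_sigma > 0,
          "noise_sigma must be positive (noiseless SNR is ill-defined)")
  ne <- dim(cal$fields)[4]
  if (is.null(scatterer)) {
    scatterer <- voxel_position(grid, floor((grid$dims - 1) / 2))
  }
  phan <- phantom(array(scatterer, c(1, 3, 1)))
  sch_i <- identity_scheme(ne)
  sch_h <- hadamard_scheme(ne)
  v_i <- simulate_acquisition(cal, sch_i, phan, grid, noise_sigma = 0)
  v_h <- simulate_acquisition(cal, sch_h, phan, grid, noise_sigma = 0)
  peak <- max(Mod(v_i$v))
  .assert(peak > 0, "zero signal at the scatterer")
  nent <- length(v_i$v)
  acc <- .with_seed(seed, {
    ss_single <- 0
    ss_dec <- 0
    for (tr in seq_len(n_trials)) {
      n_i <- array(.cnoise(nent, noise_sigma), dim(v_i$v))
      n_h <- array(.cnoise(nent, noise_sigma), dim(v_h$v))
      vh <- v_h
      vh$v <- vh$v + n_h
      dec <- hadamard_decode(vh, sch_h)
      ss_single <- ss_single + sum(Mod(n_i)^2)
      ss_dec <- ss_dec + sum(Mod(dec$v - v_i$v)^2)
    }
    c(ss_single, ss_dec)
  })
  sd_single <- sqrt(acc[1] / (n_trials * nent))
  sd_dec <- sqrt(acc[2] / (n_trials * nent))
  list(ratio = (peak / sd_dec) / (peak / sd_single),
       snr_encoded = peak / sd_dec,
       snr_single = peak / sd_single,
       n_elements = ne, n_trials = n_trials)
}

#' Fraction of field energy outside a centred window
#'
#' `1 - sum |p|^2 inside / sum |p|^2 total` for a centred rectangular
#' window — the quantity that motivates funnelling the transmitted field
#' onto the cranial imaging window.
#'
#' @param field A [planar_field()].
#' @param window Window size `(w_x, w_y)`, metres (smaller than the field
#'   extent).
#' @return The outside-energy fraction in `[0, 1]`.
#' @export
energy_outside_window <- function(field, window) {
  if (length(window) == 1) window <- c(window, window)
  .assert(window[1] <= diff(range(field$x)) + field$spacing &&
            window[2] <= diff(range(field$y)) + field$spacing,
          "window larger than the field extent")
  p2 <- Mod(field$values)^2
  tot <- sum(p2)
  .assert(tot > 0, "field has no energy")
  inx <- abs(field$x) <= window[1] / 2 + 1e-12
  iny <- abs(field$y) <= window[2] / 2 + 1e-12
  1 - sum(p2[inx, iny]) / tot
}

#' Lateral k-space coverage of the calibration fields
#'
#' 2D spatial-frequency power spectra of the per-element calibration
#' fields, summed over frequencies, plus the aggregate over elements and
#' the spectral second moment of each map (a scalar measure of how broadly
#' an element samples k-space; the encoding mask increases it).
#'
#' @param cal A [synthesize_calibration()] container.
#' @return A list with `per_element` (array `(n_x, n_y, N_e)`), `aggregate`,
#'   `kx`, `ky` (rad/m, unshifted DFT order), `second_moments` (per
#'   element, rad^2/m^2) and `aggregate_second_moment`.
#' @export
kspace_coverage <- function(cal) {
  d <- dim(cal$fields)
  nx <- d[1]; ny <- d[2]
  kx <- 2 * pi * .fftfreq(nx, cal$plane_spacing)
  ky <- 2 * pi * .fftfreq(ny, cal$plane_spacing)
  kr2 <- outer(kx^2, ky^2, "+")
  per <- array(0, c(nx, ny, d[4]))
  for (ne in seq_len(d[4])) {
    acc <- matrix(0, nx, ny)
    for (w in seq_len(d[3])) {
      acc <- acc + Mod(stats::fft(cal$fields[, , w, ne]))^2
    }
    per[, , ne] <- acc
  }
  agg <- apply(per, c(1, 2), sum)
  m2 <- apply(per, 3, function(s) sum(s * kr2) / sum(s))
  list(per_element = per, aggregate = agg, kx = kx, ky = ky,
       second_moments = m2,
       aggregate_second_moment = sum(agg * kr2) / sum(agg))
}
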