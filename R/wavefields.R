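#' Monochromatic planar field
#'
#' A complex acoustic field sampled on a lateral (x, y) grid at a single
#' frequency and depth. Values are stored as an `n_x x n_y` complex matrix
#' with x along rows; coordinates are cell-centred and symmetric about the
#' aperture axis.
#'
#' @param values Complex matrix of field values, indexed `[x, y]`.
#' @param spacing Lateral sample spacing, metres.
#' @param depth Depth of the plane (z from the calibration plane), metres.
#' @param frequency Acoustic frequency, Hz.
#' @return An object of class `cusi_field`.
#' @export
planar_field <- function(values, spacing, depth = 0, frequency) {
  .assert(is.matrix(values), "values must be a matrix")
  .assert(all(is.finite(Re(values))) && all(is.finite(Im(values))),
          "field values must be finite")
  .assert(.is_scalar_num(spacing) && spacing > 0, "spacing must be positive")
  .assert(.is_scalar_num(frequency) && frequency > 0,
          "frequency must be positive")
  values <- values + 0i
  structure(list(values = values, spacing = spacing, depth = depth,
                 frequency = frequency,
                 x = (seq_len(nrow(values)) - (nrow(values) + 1) / 2) * spacing,
                 y = (seq_len(ncol(values)) - (ncol(values) + 1) / 2) * spacing),
            class = "cusi_field")
}

#' @export
print.cusi_field <- function(x, ...) {
  cat(sprintf("cusi planar field: %d x %d @ %.3g um, %.4g MHz, z = %.3g mm\n",
              nrow(x$values), ncol(x$values), x$spacing * 1e6,
              x$frequency / 1e6, x$depth * 1e3))
  invisible(x)
}

#' Aperture-plane piston field of one element
#'
#' Baffled-piston approximation at z = 0+: unit amplitude over the element's
#' square footprint (half-open on the +x/+y side so a kerf-less lattice tiles
#' the aperture exactly), zero elsewhere.
#'
#' @param probe A [probe_geometry()] object.
#' @param element Element index (1-based, x-fastest over the lattice).
#' @param extent Lateral extent of the field grid, metres (scalar or pair);
#'   must cover the element footprint.
#' @param spacing Field grid spacing, metres.
#' @param frequency Frequency tag for the returned field, Hz.
#' @return A [planar_field()] at depth `-z_plane` of the probe face frame
#'   (stored as depth 0 of the aperture plane).
#' @export
piston_field <- function(probe, element, extent, spacing,
                         frequency = probe$f_center) {
  .assert(element >= 1 && element <= probe$n_elements,
          "element index outside the lattice")
  if (length(extent) == 1) extent <- c(extent, extent)
  x <- .axis_coords(extent[1], spacing)
  y <- .axis_coords(extent[2], spacing)
  ctr <- element_positions(probe)[element, ]
  w <- probe$element_width
  .assert(ctr[1] - w / 2 >= min(x) - spacing && ctr[1] + w / 2 <= max(x) + spacing &&
            ctr[2] - w / 2 >= min(y) - spacing && ctr[2] + w / 2 <= max(y) + spacing,
          "field grid does not cover the element footprint")
  inx <- x >= ctr[1] - w / 2 & x < ctr[1] + w / 2
  iny <- y >= ctr[2] - w / 2 & y < ctr[2] + w / 2
  planar_field(outer(inx, iny) + 0i, spacing, depth = 0, frequency = frequency)
}

#' Apply the encoding mask as a thin phase screen
#'
#' Multiplies the field pointwise by `exp(-i 2 pi f dt(x, y))` with the
#' thickness-dependent delay `dt = h (1/c_mask - 1/c_medium)`. Amplitude is
#' unchanged: internal mask reverberations and transmission losses are not
#' modelled. The mask thickness is resampled onto the field grid by bilinear
#' interpolation when the grids differ.
#'
#' @param field A [planar_field()].
#' @param mask A [generate_mask()] surface (must cover the field grid).
#' @param c_medium Sound speed of the surrounding medium, m/s.
#' @return The phase-shifted [planar_field()].
#' @export
apply_phase_screen <- function(field, mask, c_medium) {
  .assert(.is_scalar_num(c_medium) && c_medium > 0,
          "c_medium must be positive")
  .assert(mask$c_mask > 0, "mask sound speed must be positive")
  same <- length(mask$x) == length(field$x) && length(mask$y) == length(field$y) &&
    max(abs(mask$x - field$x)) < 1e-12 && max(abs(mask$y - field$y)) < 1e-12
  h <- if (same) mask$thickness else {
    .interp2(mask$x, mask$y, mask$thickness, field$x, field$y)
  }
  dt <- h * (1 / mask$c_mask - 1 / c_medium)
  field$values <- field$values * exp(-1i * 2 * pi * field$frequency * dt)
  field
}

# Spectral-domain building blocks shared by angular_spectrum_step and the
# imaging operator. Time convention exp(+i 2 pi f t); propagation towards +z
# multiplies each plane-wave component by exp(-i kz d), evanescent components
# decay as exp(-|d| kappa).
.as_kgrids <- function(np1, np2, spacing) {
  kx <- 2 * pi * .fftfreq(np1, spacing)
  ky <- 2 * pi * .fftfreq(np2, spacing)
  list(kr2 = outer(kx^2, ky^2, "+"))
}

.as_propagator <- function(kr2, k, d, cutoff_distance, D, cutoff = TRUE) {
  kz <- sqrt(pmax(k^2 - kr2, 0))
  kap <- sqrt(pmax(kr2 - k^2, 0))
  H <- exp(-1i * d * kz - abs(d) * kap)
  if (cutoff) {
    kc <- k * D / sqrt(D^2 + cutoff_distance^2)
    H[kr2 > kc^2] <- 0
  }
  H
}

#' Angular-spectrum propagation between parallel planes
#'
#' Propagates a monochromatic planar field over a distance `d` by filtering
#' its 2D spatial-frequency spectrum: propagating components acquire the
#' phase `exp(-i d sqrt(k^2 - kx^2 - ky^2))`, evanescent components decay as
#' `exp(-|d| sqrt(kx^2 + ky^2 - k^2))`, and components beyond the angular
#' cutoff `kc = k D / sqrt(D^2 + d^2)` (D the padded lateral dimension) are
#' zeroed to remove undersampled and evanescent spatial frequencies. The
#' field is zero-padded by `pad_factor` before transforming and cropped
#' after, suppressing wraparound.
#'
#' @param field A [planar_field()].
#' @param d Signed propagation distance, metres (negative for backward).
#' @param c Sound speed, m/s.
#' @param pad_factor Zero-padding ratio (>= 1).
#' @param cutoff Apply the angular cutoff (disable only for energy studies).
#' @return The propagated [planar_field()] at `depth + d`.
#' @export
angular_spectrum_step <- function(field, d, c, pad_factor = 2, cutoff = TRUE) {
  .assert(.is_scalar_num(d), "d must be finite")
  .assert(.is_scalar_num(c) && c > 0, "c must be finite and positive")
  .assert(pad_factor >= 1, "pad_factor must be >= 1")
  v <- field$values
  n1 <- nrow(v); n2 <- ncol(v)
  np1 <- ceiling(n1 * pad_factor); np2 <- ceiling(n2 * pad_factor)
  P <- matrix(0 + 0i, np1, np2)
  P[seq_len(n1), seq_len(n2)] <- v
  k <- 2 * pi * field$frequency / c
  kg <- .as_kgrids(np1, np2, field$spacing)
  D <- min(np1, np2) * field$spacing
  H <- .as_propagator(kg$kr2, k, d, cutoff_distance = d, D = D, cutoff = cutoff)
  out <- .ifft2(stats::fft(P) * H)[seq_len(n1), seq_len(n2)]
  planar_field(out, field$spacing, depth = field$depth + d,
               frequency = field$frequency)
}

#' Transmit pulse spectrum
#'
#' Complex spectral weights of an `n_cycles` sine toneburst evaluated on the
#' reconstruction frequency grid (closed-form finite-burst Fourier
#' transform), shaped by a Gaussian element response of -6 dB fractional
#' width `element_bw` centred at `element_center`, and normalized to unit
#' peak magnitude.
#'
#' @param n_cycles Number of toneburst cycles (>= 1).
#' @param f_center Toneburst centre frequency, Hz.
#' @param freqs A [make_frequency_grid()] object.
#' @param element_bw -6 dB fractional bandwidth of the element response.
#' @param element_center Centre of the element response, Hz.
#' @return Complex weight vector of length `freqs$n_freq`.
#' @export
pulse_spectrum <- function(n_cycles = 5, f_center = 15.625e6, freqs,
                           element_bw = 0.65, element_center = f_center) {
  .assert(n_cycles >= 1, "n_cycles must be >= 1")
  .assert(f_center > 0 && element_center > 0, "frequencies must be positive")
  f <- freqs$freqs
  Tb <- n_cycles / f_center
  a <- 2 * pi * f_center
  b <- 2 * pi * f
  # integral_0^T sin(a t) exp(-i b t) dt
  dm <- a - b
  t1 <- ifelse(abs(dm) < 1e-9 * a, Tb,
               (exp(1i * dm * Tb) - 1) / (1i * dm))
  t2 <- (exp(-1i * (a + b) * Tb) - 1) / (-1i * (a + b))
  w <- (t1 - t2) / (2i)
  if (is.finite(element_bw)) {
    half <- element_bw * element_center / 2
    sigma <- half / sqrt(2 * log(10^(6 / 20)))
    w <- w * exp(-(f - element_center)^2 / (2 * sigma^2))
  }
  w / max(Mod(w))
}

#' Synthetic per-element calibration fields
#'
#' Computes the forward field of every probe element on the calibration
#' plane: aperture-plane piston field, thin phase screen of the encoding
#' mask, angular-spectrum propagation to `z_plane`, scaled by the transmit
#' pulse spectrum. This synthetic system generator stands in for the
#' one-time hydrophone calibration of the physical system; the reconstruction
#' only requires that simulation and model share identical fields.
#'
#' @param probe A [probe_geometry()] object.
#' @param mask A [generate_mask()] surface, or `NULL` for the bare probe.
#' @param freqs A [make_frequency_grid()] object.
#' @param plane_extent Lateral extent of the calibration plane, metres.
#' @param plane_spacing Sample spacing of the plane, metres.
#' @param z_plane Depth of the plane from the probe face, metres (the 12 mm
#'   default reflects the imaging offset beyond which the per-element fields
#'   overlap enough for a well-conditioned reconstruction).
#' @param n_cycles Transmit toneburst cycles.
#' @param pad_factor Zero-padding for the propagation transforms.
#' @return An object of class `cusi_calibration` with `fields` (complex
#'   array `(n_x, n_y, n_freq, n_elements)`), `pulse_weights`, plane and
#'   probe metadata.
#' @export
synthesize_calibration <- function(probe, mask, freqs,
                                   plane_extent = c(12e-3, 12e-3),
                                   plane_spacing = 40e-6, z_plane = 12e-3,
                                   n_cycles = 5, pad_factor = 2) {
  if (length(plane_extent) == 1) plane_extent <- c(plane_extent, plane_extent)
  .assert(z_plane >= 0, "z_plane must be >= 0")
  .assert(plane_extent[1] >= probe$aperture[1] &&
            plane_extent[2] >= probe$aperture[2],
          "calibration plane must cover the probe aperture")
  x <- .axis_coords(plane_extent[1], plane_spacing)
  y <- .axis_coords(plane_extent[2], plane_spacing)
  nx <- length(x); ny <- length(y)
  pw <- pulse_spectrum(n_cycles, freqs$f_center, freqs,
                       element_bw = probe$fractional_bw,
                       element_center = probe$f_center)
  fields <- array(0 + 0i, c(nx, ny, freqs$n_freq, probe$n_elements))
  for (ne in seq_len(probe$n_elements)) {
    pf <- piston_field(probe, ne, plane_extent, plane_spacing)
    for (w in seq_len(freqs$n_freq)) {
      fld <- planar_field(pf$values, plane_spacing, depth = 0,
                          frequency = freqs$freqs[w])
      if (!is.null(mask) && mask$height_range > 0) {
        fld <- apply_phase_screen(fld, mask, probe$c_medium)
      }
      if (z_plane > 0) {
        fld <- angular_spectrum_step(fld, z_plane, probe$c_medium, pad_factor)
      }
      fields[, , w, ne] <- fld$values * pw[w]
    }
  }
  structure(list(fields = fields, freqs = freqs, pulse_weights = pw,
                 plane_spacing = plane_spacing, plane_extent = plane_extent,
                 x = x, y = y, z_plane = z_plane, probe = probe,
                 mask_seed = if (is.null(mask)) NULL else mask$seed,
                 mask_height = if (is.null(mask)) 0 else mask$height_range,
                 pad_factor = pad_factor),
            class = "cusi_calibration")
}

#' @export
print.cusi_calibration <- function(x, ...) {
  d <- dim(x$fields)
  cat(sprintf(
    "cusi calibration: %d elements x %d frequencies on %d x %d plane @ %.3g um, z = %.3g mm\n",
    d[4], d[3], d[1], d[2], x$plane_spacing * 1e6, x$z_plane * 1e3))
  invisible(x)
}

#' Hard aperture window
#'
#' Clips a planar field to a centred rectangular window (zero outside),
#' emulating the confinement of the transmitted field by a waveguide for
#' energy studies. Waveguide internals (taper, internal reflections) are not
#' modelled.
#'
#' @param field A [planar_field()].
#' @param window Window size `(w_x, w_y)` in metres.
#' @return The clipped [planar_field()].
#' @export
apply_aperture_window <- function(field, window) {
  if (length(window) == 1) window <- c(window, window)
  inx <- abs(field$x) <= window[1] / 2 + 1e-12
  iny <- abs(field$y) <= window[2] / 2 + 1e-12
  field$values <- field$values * outer(inx, iny)
  field
}
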