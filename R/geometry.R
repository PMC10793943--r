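#' Matrix-probe geometry
#'
#' Describes the undersampled matrix probe: a fully populated, kerf-less
#' lattice of acoustically large square elements. Defaults follow the 8 x 8,
#' 1.25 mm pitch, 13.8 MHz probe used throughout the package.
#'
#' @param n_x,n_y Element counts per lateral axis.
#' @param pitch Lateral element spacing in metres.
#' @param element_width Lateral element size in metres (kerf-less when equal
#'   to `pitch`).
#' @param f_center Element centre frequency in Hz.
#' @param fractional_bw -6 dB fractional bandwidth of the element response.
#' @param c_medium Sound speed in the coupling medium, m/s.
#'
#' @return An object of class `cusi_probe`.
#' @export
probe_geometry <- function(n_x = 8L, n_y = 8L, pitch = 1.25e-3,
                           element_width = 1.25e-3, f_center = 13.8e6,
                           fractional_bw = 0.65, c_medium = 1500) {
  .assert(n_x >= 1 && n_y >= 1, "element counts must be positive")
  for (v in list(pitch, element_width, f_center, fractional_bw, c_medium)) {
    .assert(.is_scalar_num(v) && v > 0,
            "all probe lengths, frequencies and speeds must be positive")
  }
  .assert(element_width <= pitch, "element_width must not exceed pitch")
  structure(list(
    n_x = as.integer(n_x), n_y = as.integer(n_y),
    pitch = pitch, element_width = element_width,
    f_center = f_center, fractional_bw = fractional_bw,
    c_medium = c_medium,
    n_elements = as.integer(n_x * n_y),
    aperture = c(n_x * pitch, n_y * pitch)
  ), class = "cusi_probe")
}

#' @export
print.cusi_probe <- function(x, ...) {
  cat(sprintf("cusi probe: %d x %d elements, pitch %.3g mm, %.4g MHz (%.0f%% BW)\n",
              x$n_x, x$n_y, x$pitch * 1e3, x$f_center / 1e6,
              100 * x$fractional_bw))
  invisible(x)
}

#' Element centre positions
#'
#' Lateral centre coordinates of each element, aperture-centred, with the
#' element index running x-fastest over the lattice.
#'
#' @param probe A [probe_geometry()] object.
#' @return A `n_elements x 2` matrix of (x, y) positions in metres.
#' @export
element_positions <- function(probe) {
  ex <- (seq_len(probe$n_x) - (probe$n_x + 1) / 2) * probe$pitch
  ey <- (seq_len(probe$n_y) - (probe$n_y + 1) / 2) * probe$pitch
  cbind(x = rep(ex, times = probe$n_y), y = rep(ey, each = probe$n_x))
}

#' Evenly spaced frequency grid over a fractional band
#'
#' `n_freq` frequencies spanning `f_center * (1 +/- fractional_band / 2)`,
#' endpoints inclusive. The default reproduces the 128 reconstruction
#' frequencies of a 50% band about 15.625 MHz.
#'
#' @param f_center Band centre frequency, Hz.
#' @param fractional_band Fractional width of the band (0 < b < 2).
#' @param n_freq Number of frequencies.
#' @return An object of class `cusi_freqs` with elements `freqs`, `f_center`,
#'   `fractional_band`, `n_freq`.
#' @export
make_frequency_grid <- function(f_center = 15.625e6, fractional_band = 0.5,
                                n_freq = 128L) {
  .assert(.is_scalar_num(f_center) && f_center > 0, "f_center must be positive")
  .assert(.is_scalar_num(fractional_band) && fractional_band > 0 &&
            fractional_band < 2, "fractional_band must lie in (0, 2)")
  .assert(n_freq >= 1, "n_freq must be >= 1")
  freqs <- if (n_freq == 1) f_center else {
    seq(f_center * (1 - fractional_band / 2),
        f_center * (1 + fractional_band / 2), length.out = n_freq)
  }
  structure(list(freqs = freqs, f_center = f_center,
                 fractional_band = fractional_band,
                 n_freq = as.integer(n_freq)),
            class = "cusi_freqs")
}

#' @export
print.cusi_freqs <- function(x, ...) {
  cat(sprintf("cusi frequency grid: %d frequencies, %.4g - %.4g MHz\n",
              x$n_freq, min(x$freqs) / 1e6, max(x$freqs) / 1e6))
  invisible(x)
}

#' Isotropic image grid
#'
#' Voxel-centred, 0-based imaging grid. The grid frame places z = 0 at the
#' calibration plane with z increasing away from the probe; `z_offset` is the
#' depth of the first reconstructed plane beyond the calibration plane.
#'
#' @param dims Integer vector `(n_x, n_y, n_z)` of voxel counts.
#' @param spacing Isotropic voxel size, metres.
#' @param z_offset Depth of the first plane beyond the calibration plane, m.
#' @param center Lateral (x, y) centre of the grid footprint, metres.
#' @return An object of class `cusi_grid` with `origin` (first voxel centre),
#'   `spacing` and `dims`.
#' @export
image_grid <- function(dims, spacing = 40e-6, z_offset = 0, center = c(0, 0)) {
  .assert(length(dims) == 3 && all(dims >= 1), "dims must be three positive counts")
  .assert(.is_scalar_num(spacing) && spacing > 0, "spacing must be positive")
  .assert(.is_scalar_num(z_offset) && z_offset >= 0, "z_offset must be >= 0")
  dims <- as.integer(dims)
  origin <- c(center[1] - (dims[1] - 1) / 2 * spacing,
              center[2] - (dims[2] - 1) / 2 * spacing,
              z_offset)
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 z_offset = z_offset),
            class = "cusi_grid")
}

#' @export
print.cusi_grid <- function(x, ...) {
  cat(sprintf("cusi image grid: %d x %d x %d voxels @ %.3g um, z offset %.3g mm\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing * 1e6,
              x$z_offset * 1e3))
  invisible(x)
}

#' Voxel index to position and back
#'
#' 0-based voxel index `(i, j, k)` maps exactly to
#' `origin + spacing * (i, j, k)`.
#'
#' @param grid A [image_grid()] object.
#' @param index Integer matrix (n x 3) or vector of 0-based voxel indices.
#' @return `voxel_position`: an n x 3 matrix of positions (m);
#'   `position_to_voxel`: an n x 3 matrix of fractional 0-based indices.
#' @export
voxel_position <- function(grid, index) {
  idx <- if (is.matrix(index)) index else matrix(index, ncol = 3)
  sweep(idx * grid$spacing, 2, grid$origin, "+")
}

#' @rdname voxel_position
#' @param position An n x 3 matrix of positions in metres.
#' @export
position_to_voxel <- function(grid, position) {
  pos <- if (is.matrix(position)) position else matrix(position, ncol = 3)
  sweep(pos, 2, grid$origin, "-") / grid$spacing
}

#' Random smooth encoding-mask surface
#'
#' Generates the thickness map h(x, y) of the plastic encoding mask: white
#' noise filtered with an isotropic Gaussian kernel whose width is calibrated
#' so the surface autocorrelation FWHM equals `feature_size`, then min-max
#' rescaled to `height_range`. A raised-cosine taper ring of width
#' `taper_width` flattens the surface towards the border with zero gradient
#' at both ends, avoiding sharp discontinuities that would diffract.
#'
#' Defaults reproduce the fabricated mask statistics: ~370 um lateral
#' features, 1.2 mm total height variation, over a 12 mm x 12 mm footprint.
#'
#' @param seed RNG seed; the surface is a pure function of all arguments.
#' @param feature_size Target autocorrelation FWHM, metres (>= 2 * spacing).
#' @param height_range Total height variation max - min, metres (>= 0).
#' @param extent Lateral extent `(x, y)` in metres.
#' @param spacing Lateral grid spacing, metres.
#' @param c_mask Sound speed in the mask material, m/s (Rexolite default).
#' @param taper_width Width of the border taper ring, metres.
#' @return An object of class `cusi_mask` carrying the thickness map and
#'   grid metadata.
#' @export
generate_mask <- function(seed, feature_size = 370e-6, height_range = 1.2e-3,
                          extent = c(12e-3, 12e-3), spacing = 40e-6,
                          c_mask = 2337, taper_width = 1e-3) {
  if (length(extent) == 1) extent <- c(extent, extent)
  for (v in list(feature_size, height_range, spacing, c_mask, taper_width)) {
    .assert(.is_scalar_num(v), "mask parameters must be finite")
  }
  .assert(spacing > 0 && c_mask > 0, "spacing and c_mask must be positive")
  .assert(height_range >= 0, "height_range must be >= 0")
  .assert(feature_size >= 2 * spacing,
          "feature_size below 2 * spacing cannot be resolved on the mask grid")
  x <- .axis_coords(extent[1], spacing)
  y <- .axis_coords(extent[2], spacing)
  nx <- length(x); ny <- length(y)
  if (height_range == 0) {
    h <- matrix(0, nx, ny)
  } else {
    z <- .with_seed(seed, matrix(stats::rnorm(nx * ny), nx, ny))
    # Gaussian-filtered white noise has a Gaussian autocorrelation of width
    # sigma * sqrt(2); calibrate sigma so the ACF FWHM equals feature_size.
    sigma <- feature_size / (2 * sqrt(2 * log(2))) / sqrt(2)
    kx <- .fftfreq(nx, spacing)
    ky <- .fftfreq(ny, spacing)
    Gk <- exp(-2 * pi^2 * sigma^2 * outer(kx^2, ky^2, "+"))
    h <- Re(stats::fft(stats::fft(z) * Gk, inverse = TRUE)) / (nx * ny)
    ramp <- function(t) ifelse(t >= taper_width, 1,
                               0.5 - 0.5 * cos(pi * pmax(t, 0) / taper_width))
    wx <- ramp(pmin(x - (-extent[1] / 2), extent[1] / 2 - x))
    wy <- ramp(pmin(y - (-extent[2] / 2), extent[2] / 2 - y))
    h <- h * outer(wx, wy)
    h <- h - min(h)
    h <- h / max(h) * height_range
  }
  structure(list(thickness = h, spacing = spacing, extent = extent,
                 x = x, y = y, c_mask = c_mask, feature_size = feature_size,
                 height_range = height_range, seed = seed,
                 taper_width = taper_width),
            class = "cusi_mask")
}

#' @export
print.cusi_mask <- function(x, ...) {
  cat(sprintf(
    "cusi encoding mask: %.3g x %.3g mm @ %.3g um, features %.3g um, height %.3g mm\n",
    x$extent[1] * 1e3, x$extent[2] * 1e3, x$spacing * 1e6,
    x$feature_size * 1e6, x$height_range * 1e3))
  invisible(x)
}
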