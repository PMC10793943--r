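test_that("correlation maps peak at the chosen voxel and ignore global scale", {
  sys <- tiny_system()
  op <- imaging_operator(sys$cal, sys$scheme, sys$grid)
  cm <- system_correlation_map(op, c(4, 4, 2), c(4e-4, 4e-4, 2e-4))
  pk <- attr(cm, "peak")
  expect_equal(cm[pk[1], pk[2], pk[3]], 1, tolerance = 1e-9)
  expect_lte(max(cm), 1 + 1e-9)
  # invariant to global phase/scale of the calibration
  cal2 <- sys$cal
  cal2$fields <- cal2$fields * (0.3 + 0.4i)
  op2 <- imaging_operator(cal2, sys$scheme, sys$grid)
  cm2 <- system_correlation_map(op2, c(4, 4, 2), c(4e-4, 4e-4, 2e-4))
  expect_lt(max(abs(cm - cm2)), 1e-9)
  expect_error(system_correlation_map(op, c(1, 1, 1), c(4e-4, 4e-4, 0)),
               "region")
})

test_that("correlation map of a symmetric unmasked aperture is mirror-symmetric", {
  probe <- probe_geometry(2, 2, pitch = 1e-3, element_width = 1e-3)
  freqs <- make_frequency_grid(15.625e6, 0.5, 3)
  cal <- synthesize_calibration(probe, NULL, freqs, plane_extent = 4e-3,
                                plane_spacing = 100e-6, z_plane = 5e-3)
  grid <- image_grid(c(10, 10, 1), 100e-6, z_offset = 4e-4)
  op <- imaging_operator(cal, hadamard_scheme(4), grid)
  # centred voxel of an even grid lies off-lattice; use a symmetric probe
  # with the region centred on the aperture axis between voxels 5/6
  cm <- system_correlation_map(op, c(5, 5, 1), c(8e-4, 8e-4, 0))
  # reflect about the aperture centre: voxel (5,5) maps to (6,6)
  cm_ref <- system_correlation_map(op, c(6, 6, 1), c(8e-4, 8e-4, 0))
  expect_lt(max(abs(cm - cm_ref[rev(seq_len(dim(cm_ref)[1])),
                                rev(seq_len(dim(cm_ref)[2])), ,
                                drop = FALSE])), 1e-6)
})

test_that("resolution report recovers known widths and side lobes", {
  sp <- 40e-6
  xs <- (1:41 - 21) * sp
  sig <- 3 * sp
  g <- exp(-outer(outer(xs^2, xs^2, "+"), xs^2, "+") / (2 * sig^2))
  r <- resolution_from_map(g, sp)
  fw_true <- 2 * sqrt(2 * log(2)) * sig
  expect_lt(abs(r$lateral_fwhm_x - fw_true), sp)
  expect_lt(abs(r$lateral_fwhm_y - fw_true), sp)
  expect_lt(abs(r$axial_fwhm - fw_true), sp)
  # a discrete main lobe plus an isolated spike: the spike is the peak
  # secondary side lobe
  g2 <- array(0, c(41, 41, 41))
  g2[21, 21, 21] <- 1
  g2[20:22, 21, 21] <- c(0.7, 1, 0.7)
  g2[21, 20:22, 21] <- c(0.7, 1, 0.7)
  g2[21, 21, 20:22] <- c(0.7, 1, 0.7)
  g2[35, 21, 21] <- 0.25
  r2 <- resolution_from_map(g2, sp)
  expect_equal(r2$peak_secondary_sidelobe_db, 20 * log10(0.25),
               tolerance = 1e-6)
  # single nonzero voxel: FWHM of one grid step, floored side lobe
  d <- array(0, c(9, 9, 9))
  d[5, 5, 5] <- 1
  rd <- resolution_from_map(d, sp)
  expect_lte(rd$lateral_fwhm_x, sp + 1e-12)
  expect_equal(rd$peak_secondary_sidelobe_db, -120)
  # peak on the boundary is rejected
  b <- array(0, c(5, 5, 5))
  b[1, 3, 3] <- 1
  expect_error(resolution_from_map(b, sp), "boundary")
})

test_that("axial resolution beats lateral for a broadband masked system", {
  sys <- desk_system()
  # short excitation: the full 50% band contributes
  cal <- synthesize_calibration(sys$probe, sys$mask, sys$freqs,
                                plane_extent = 8e-3, plane_spacing = 80e-6,
                                z_plane = 12e-3, n_cycles = 1)
  grid <- image_grid(c(24, 24, 12), 80e-6, z_offset = 0.4e-3)
  op <- imaging_operator(cal, sys$scheme, grid)
  cm <- system_correlation_map(op, c(12, 12, 6), c(1.2e-3, 1.2e-3, 8e-4))
  r <- resolution_from_map(cm)
  expect_lt(r$axial_fwhm, (r$lateral_fwhm_x + r$lateral_fwhm_y) / 2)
  expect_lte(r$peak_secondary_sidelobe_db, 0)
})

test_that("lateral resolution degrades with depth beyond the offset", {
  sys <- desk_system()
  grid <- image_grid(c(24, 24, 40), 80e-6, z_offset = 0.4e-3)
  op <- imaging_operator(sys$cal, sys$scheme, grid)
  fw <- vapply(c(3, 37), function(k) {
    cm <- system_correlation_map(op, c(12, 12, k), c(1.2e-3, 1.2e-3, 0))
    r <- resolution_from_map(cm)
    (r$lateral_fwhm_x + r$lateral_fwhm_y) / 2
  }, numeric(1))
  expect_gt(fw[2], fw[1])
})

test_that("energy outside the imaging window follows the area ratio at d = 0", {
  probe <- probe_geometry()
  ap <- Reduce(`+`, lapply(1:64, function(e) {
    piston_field(probe, e, 12e-3, 40e-6)$values
  }))
  fld <- planar_field(ap, 40e-6, 0, 13.8e6)
  expect_equal(energy_outside_window(fld, c(8e-3, 6e-3)), 0.52,
               tolerance = 1e-12)
  # full-extent window: nothing outside
  expect_equal(energy_outside_window(fld, c(12e-3, 12e-3)), 0)
  # after propagating to the 12 mm offset the outside fraction stays >= 40%
  stp <- angular_spectrum_step(fld, 12e-3, 1500)
  expect_gte(energy_outside_window(stp, c(8e-3, 6e-3)), 0.40)
  expect_error(energy_outside_window(fld, c(20e-3, 6e-3)), "window")
})

test_that("k-space coverage maps satisfy Parseval and flag directional elements", {
  sys <- tiny_system()
  ks <- kspace_coverage(sys$cal)
  d <- dim(sys$cal$fields)
  spatial <- sum(Mod(sys$cal$fields)^2)
  expect_equal(sum(ks$aggregate) / (d[1] * d[2]), spatial,
               tolerance = 1e-9)
  # bare probe concentrates spectral energy near DC
  cal_b <- synthesize_calibration(sys$probe, NULL, sys$freqs,
                                  plane_extent = 4e-3,
                                  plane_spacing = 100e-6, z_plane = 6e-3)
  ks_b <- kspace_coverage(cal_b)
  lowk <- sqrt(outer(ks_b$kx^2, ks_b$ky^2, "+")) < max(abs(ks_b$kx)) / 4
  expect_gt(sum(ks_b$aggregate[lowk]) / sum(ks_b$aggregate), 0.5)
  expect_gt(ks$aggregate_second_moment, ks_b$aggregate_second_moment)
})
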