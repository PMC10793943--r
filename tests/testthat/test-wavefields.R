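test_that("piston fields tile the kerf-less aperture", {
  probe <- probe_geometry()
  f1 <- piston_field(probe, 1, 12e-3, 40e-6)
  nz <- which(Mod(f1$values) > 0, arr.ind = TRUE)
  # the 1.25 mm element is 31.25 cells wide on the 40 um lattice, so the
  # discretized square sits within half a cell of the lattice position
  ctr <- c(mean(f1$x[range(nz[, 1])]), mean(f1$y[range(nz[, 2])]))
  expect_lt(max(abs(ctr - c(-4.375e-3, -4.375e-3))), 20e-6 + 1e-12)
  expect_lt(abs(diff(range(f1$x[nz[, 1]])) + 40e-6 - 1.25e-3), 40e-6)
  # energy = element area / cell area, to the cell-quantization error
  expect_equal(sum(Mod(f1$values)^2), (1.25e-3 / 40e-6)^2,
               tolerance = 2 * 40e-6 / 1.25e-3)
  # all 64 pistons sum to uniform 1 over the 10 x 10 mm aperture
  ap <- Reduce(`+`, lapply(1:64, function(e) {
    piston_field(probe, e, 12e-3, 40e-6)$values
  }))
  inside <- abs(f1$x) < 5e-3 - 1e-9
  expect_true(all(Mod(ap[inside, inside] - 1) < 1e-12))
  expect_true(all(Mod(ap[!inside, !inside]) < 1e-12))
  expect_error(piston_field(probe, 65, 12e-3, 40e-6), "lattice")
})

test_that("phase screen applies the thickness-dependent delay only", {
  probe <- probe_geometry()
  f <- planar_field(matrix(1 + 0i, 50, 50), 40e-6, 0, 15.625e6)
  m0 <- generate_mask(1, height_range = 0, extent = 2.4e-3, spacing = 40e-6,
                      feature_size = 370e-6)
  expect_equal(apply_phase_screen(f, m0, 1500)$values, f$values)
  # constant thickness: a single global phase, amplitude unchanged
  mc <- m0
  mc$thickness[] <- 1.2e-3
  out <- apply_phase_screen(f, mc, 1500)
  dt <- 1.2e-3 * (1 / 2337 - 1 / 1500)
  expect_equal(dt, -2.865e-7, tolerance = 2e-3)
  expected <- exp(-1i * 2 * pi * 15.625e6 * dt)
  expect_lt(max(Mod(out$values - expected)), 1e-12)
  expect_equal(Mod(out$values), Mod(f$values))
  # phase magnitude ~ 2 pi * 4.48 rad at 15.625 MHz
  expect_equal(abs(2 * pi * 15.625e6 * dt), 2 * pi * 4.477, tolerance = 1e-3)
  # random mask changes phase pointwise, never amplitude
  mr <- generate_mask(4, extent = 2.4e-3, spacing = 40e-6,
                      feature_size = 370e-6)
  outr <- apply_phase_screen(f, mr, 1500)
  expect_equal(Mod(outr$values), Mod(f$values), tolerance = 1e-12)
  expect_error(apply_phase_screen(f, mr, -10), "positive")
})

test_that("angular spectrum step is the identity at d = 0 for band-limited fields", {
  # Gaussian chosen confined both spatially (no pad-edge discontinuity)
  # and spectrally (no content beyond the d = 0 cutoff at k)
  xs <- (seq_len(48) - 24.5) * 80e-6
  g <- outer(exp(-xs^2 / (2 * 0.25e-3^2)), exp(-xs^2 / (2 * 0.25e-3^2)))
  f <- planar_field(g + 0i, 80e-6, 0, 8e6)
  out <- angular_spectrum_step(f, 0, 1500)
  expect_lt(max(Mod(out$values - f$values)), 1e-12)
})

test_that("on-axis plane-wave phase follows exp(-i k d)", {
  f <- planar_field(matrix(1 + 0i, 32, 32), 40e-6, 0, 8e6)
  # unpadded: the uniform field is a pure DC component
  out <- angular_spectrum_step(f, 1.5e-3, 1500, pad_factor = 1)
  expect_lt(max(Mod(out$values - exp(-1i * 2 * pi * 8e6 * 1.5e-3 / 1500))),
            1e-12)
})

test_that("propagation matches the Rayleigh-Sommerfeld oracle within 3% RMS", {
  xs <- (seq_len(64) - 32.5) * 40e-6
  src <- outer(exp(-xs^2 / (2 * 0.4e-3^2)), exp(-xs^2 / (2 * 0.4e-3^2)))
  f <- planar_field(src + 0i, 40e-6, 0, 5e6)
  asf <- angular_spectrum_step(f, 6e-3, 1500, pad_factor = 4)
  rso <- rayleigh_sommerfeld(f, 6e-3, 1500)
  ctr <- 16:48
  rms <- sqrt(mean((Mod(asf$values[ctr, ctr]) - Mod(rso$values[ctr, ctr]))^2))
  expect_lt(rms / sqrt(mean(Mod(rso$values[ctr, ctr])^2)), 0.03)
})

test_that("energy is conserved without cutoff and the step is reciprocal", {
  xs <- (seq_len(64) - 32.5) * 40e-6
  g <- outer(exp(-xs^2 / (2 * 0.3e-3^2)), exp(-xs^2 / (2 * 0.3e-3^2)))
  f <- planar_field(g + 0i, 40e-6, 0, 10e6)
  fwd <- angular_spectrum_step(f, 1e-3, 1500, cutoff = FALSE)
  expect_lt(abs(sum(Mod(fwd$values)^2) / sum(Mod(f$values)^2) - 1), 1e-6)
  back <- angular_spectrum_step(fwd, -1e-3, 1500, cutoff = FALSE)
  expect_lt(rel_l2(back$values, f$values), 1e-3)
  expect_error(angular_spectrum_step(f, Inf, 1500), "finite")
  expect_error(angular_spectrum_step(f, 1e-3, -1), "positive")
})

test_that("pulse spectrum peaks at the toneburst centre and matches a DFT oracle", {
  fg <- make_frequency_grid(15.625e6, 0.5, 64)
  # with the element response centred on the toneburst, the peak sits at
  # the toneburst centre frequency
  w <- pulse_spectrum(5, 15.625e6, fg, 0.65)
  df <- diff(fg$freqs)[1]
  expect_lt(abs(fg$freqs[which.max(Mod(w))] - 15.625e6), df + 1e-9)
  # detuned element response pulls the peak between the two centres
  wd <- pulse_spectrum(5, 15.625e6, fg, 0.65, element_center = 13.8e6)
  pk <- fg$freqs[which.max(Mod(wd))]
  expect_gt(pk, 13.8e6)
  expect_lt(pk, 15.625e6 + df)
  # closed-form toneburst transform vs a dense Riemann-sum DFT oracle
  w1 <- pulse_spectrum(1, 15.625e6, fg, Inf)
  Tb <- 1 / 15.625e6
  ts <- seq(0, Tb, length.out = 20001)
  orc <- vapply(fg$freqs, function(f) {
    sum(sin(2 * pi * 15.625e6 * ts) * exp(-1i * 2 * pi * f * ts)) *
      (ts[2] - ts[1])
  }, complex(1))
  orc <- orc / max(Mod(orc))
  expect_lt(max(Mod(w1 - orc)), 1e-6)
  expect_equal(max(Mod(w)), 1)
})

test_that("long tonebursts concentrate spectral energy", {
  # on a grid whose bin spacing exceeds the 50-cycle main-lobe half width,
  # three bins capture nearly all the energy
  fg <- make_frequency_grid(15.625e6, 0.5, 25)
  w <- pulse_spectrum(50, 15.625e6, fg, Inf)
  e <- Mod(w)^2
  top <- order(e, decreasing = TRUE)[1:3]
  expect_gt(sum(e[top]) / sum(e), 0.9)
  # energy concentration increases with burst length
  w5 <- pulse_spectrum(5, 15.625e6, fg, Inf)
  e5 <- Mod(w5)^2
  expect_gt(sum(e[top]) / sum(e),
            sum(e5[order(e5, decreasing = TRUE)[1:3]]) / sum(e5))
})

test_that("synthetic calibration is deterministic and the mask broadens k-space", {
  sys <- desk_system()
  cal2 <- synthesize_calibration(sys$probe, sys$mask, sys$freqs,
                                 plane_extent = 8e-3, plane_spacing = 80e-6,
                                 z_plane = 12e-3)
  expect_identical(sys$cal$fields, cal2$fields)
  ks_m <- kspace_coverage(sys$cal)
  ks_b <- kspace_coverage(sys$cal_bare)
  # bare elements are directional: spectral second moment far below masked
  expect_true(all(ks_m$second_moments > ks_b$second_moments))
  expect_gt(ks_m$aggregate_second_moment, 2 * ks_b$aggregate_second_moment)
})

test_that("near-probe voxels are insonified by far fewer elements", {
  # the imaging offset exists because element fields need distance to
  # diverge and overlap; close to the probe each lateral position only
  # sees the element(s) directly above it
  probe <- probe_geometry()  # the full 8 x 8 lattice
  mask <- generate_mask(1, extent = 12e-3, spacing = 80e-6)
  freqs <- make_frequency_grid(15.625e6, 0.5, 2)
  coverage <- vapply(c(3e-3, 12e-3), function(zp) {
    cal <- synthesize_calibration(probe, mask, freqs,
                                  plane_extent = 12e-3,
                                  plane_spacing = 80e-6, z_plane = zp)
    ctr <- c(75, 75)  # grid centre of the 150 x 150 plane
    en <- vapply(seq_len(64), function(ne) {
      sum(Mod(cal$fields[ctr[1] + (-2:2), ctr[2] + (-2:2), , ne])^2)
    }, numeric(1))
    sum(en)^2 / sum(en^2)  # participation ratio: effective element count
  }, numeric(1))
  expect_lt(coverage[1], coverage[2] / 2)
  expect_gt(coverage[2], 16)  # at the offset a large share of the 64 matter
})

test_that("aperture window clips energy outside the waveguide footprint", {
  f <- planar_field(matrix(1 + 0i, 100, 100), 100e-6, 0, 13.8e6)
  w <- apply_aperture_window(f, 7e-3)
  inx <- abs(f$x) <= 3.5e-3
  expect_true(all(Mod(w$values[!inx, ]) == 0))
  expect_true(all(Mod(w$values[inx, inx]) == 1))
})
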