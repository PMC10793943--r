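# small synthetic acquisition tensors for the frame bookkeeping utilities
make_acq <- function(nf, fill = NULL, nw = 2, nt = 3, ne = 2) {
  v <- if (is.null(fill)) {
    array(rand_cplx(nw * nt * ne * nf), c(nw, nt, ne, nf))
  } else {
    array(fill, c(nw, nt, ne, nf))
  }
  acquisition_tensor(v, make_frequency_grid(15.625e6, 0.5, nw),
                     cusi:::.new_scheme(matrix(stats::rnorm(ne * nt), ne, nt)),
                     frame_rate = 100)
}

test_that("frequency-bin and depth bookkeeping reproduce the acquisition arithmetic", {
  expect_equal(count_frequency_bins(512, 2), 128L)
  expect_equal(count_frequency_bins(512, 1), 256L)
  # enumeration oracle: positive-frequency bins of an 8-sample real record
  # are at indices 1..4 (excluding DC); decimating by 2 keeps 2 of them
  bins <- seq_len(8 / 2)
  expect_equal(count_frequency_bins(8, 2), length(bins[bins %% 2 == 0]))
  expect_error(count_frequency_bins(511, 2), "even")
  expect_error(count_frequency_bins(8, 3), "divide")
  expect_equal(imaging_depth(512, 15.625e6, 1500), 24.576e-3)
  expect_equal(imaging_depth(0, 1e6, 1500), 0)
  expect_equal(imaging_depth(2, 1500, 1500), 1)
  expect_equal(ensemble_rate(8041, 60, rounded = TRUE), 134)
  expect_equal(ensemble_rate(24400, 60, rounded = TRUE), 407)
  expect_equal(ensemble_rate(0, 60), 0)
})

test_that("jitter detection flags spikes robustly and is idempotent", {
  set.seed(7)
  acq <- make_acq(12, fill = 1 + 0i)
  # identical frames: nothing flagged
  res <- detect_unstable_frames(acq, k = 5)
  expect_true(all(res$tensor$valid))
  expect_equal(res$report$n_frames_out, 12)
  # a single frame with x100 amplitude is flagged (with its neighbours)
  acq2 <- acq
  acq2$v[, , , 6] <- 100
  res2 <- detect_unstable_frames(acq2, k = 5)
  expect_false(res2$tensor$valid[6])
  expect_true(all(res2$tensor$valid[c(1:4, 8:12)]))
  # a second pass flags nothing new
  res3 <- detect_unstable_frames(res2$tensor, k = 5)
  expect_identical(res3$tensor$valid, res2$tensor$valid)
  expect_error(detect_unstable_frames(acq, k = 0), "positive")
})

test_that("block-prefix dropping invalidates the unstable start of each block", {
  acq <- make_acq(200)
  out <- drop_block_prefix(acq, block = 100, n_drop = 64)
  expect_equal(sum(out$valid), 72)
  expect_true(all(!out$valid[1:64]))
  expect_true(all(out$valid[65:100]))
  expect_true(all(!out$valid[101:164]))
  # one block
  one <- drop_block_prefix(make_acq(100), 100, 64)
  expect_equal(which(one$valid), 65:100)
  # drop 0 changes nothing
  expect_true(all(drop_block_prefix(make_acq(100), 100, 0)$valid))
  # partial trailing block warns and applies the same rule
  expect_warning(pb <- drop_block_prefix(make_acq(150), 100, 64), "partial")
  expect_equal(sum(pb$valid), 36)
  expect_error(drop_block_prefix(make_acq(100), 100, 100), "n_drop")
})

test_that("SVD discard count uses the floor convention", {
  expect_equal(svd_discard_count(8041, 0.65), 5226L)
  expect_equal(svd_discard_count(16, 0), 0L)
  expect_equal(svd_discard_count(16, 1), 16L)
  expect_error(svd_discard_count(10, 1.5), "cutoff_fraction")
})

test_that("SVD clutter filter removes the static subspace and keeps flow", {
  nw <- 4; nt <- 4; ne <- 4; nf <- 16
  set.seed(1)
  s <- rand_cplx(nw * nt * ne)
  s <- 1000 * s / sqrt(sum(Mod(s)^2))       # strong static tissue signature
  m <- rand_cplx(nw * nt * ne)
  m <- m / sqrt(sum(Mod(m)^2))              # weak moving-scatterer signature
  phs <- 2 * pi * (0:(nf - 1)) / nf         # full-circle Doppler rotation
  v <- array(0 + 0i, c(nw, nt, ne, nf))
  for (f in seq_len(nf)) v[, , , f] <- array(s + m * exp(1i * phs[f]),
                                             c(nw, nt, ne))
  acq <- acquisition_tensor(v, make_frequency_grid(15.625e6, 0.5, nw),
                            hadamard_scheme(4), frame_rate = 100)
  res <- svd_clutter_filter(acq, 1 / 16)
  expect_equal(res$report$discarded_singular_values, 1L)
  Fm <- matrix(res$tensor$v, nw * nt * ne, nf)
  Bm <- matrix(v, nw * nt * ne, nf)
  # oracle by explicit projection onto the known signatures
  stat_energy <- function(M) sum(Mod(crossprod(Conj(s / 1000), M))^2)
  expect_lt(10 * log10(stat_energy(Fm) / stat_energy(Bm)), -40)
  dop <- function(M) {
    sig <- vapply(seq_len(nf), function(f) sum(Conj(m) * M[, f]), complex(1))
    sum(Mod(sig - mean(sig))^2)
  }
  expect_gt(10 * log10(dop(Fm) / dop(Bm)), -3)
  # output orthogonal to the discarded singular subspace
  sv <- svd(Bm, nu = 1, nv = 0)
  expect_lt(max(Mod(Conj(t(sv$u)) %*% Fm)) / sqrt(sum(Mod(Bm)^2)), 1e-8)
  # filtering commutes with global scaling
  acq3 <- acq
  acq3$v <- 3 * acq3$v
  res3 <- svd_clutter_filter(acq3, 1 / 16)
  expect_lt(max(Mod(res3$tensor$v - 3 * res$tensor$v)), 1e-9)
  # cutoff 0 leaves the tensor unchanged
  res0 <- svd_clutter_filter(acq, 0)
  expect_lt(rel_l2(res0$tensor$v, acq$v), 1e-9)
})

test_that("clutter filtering before or after reconstruction agrees on the PDI", {
  # reconstruction is linear and frame-wise, so removing an identifiable
  # clutter component commutes with it. The clutter (static scatterer
  # signature, constant in time) and flow (rotating phase, zero temporal
  # mean) components are made spatially orthogonal in both the channel and
  # the image domain, so both SVD filters isolate the same subspace; the
  # residual mismatch otherwise scales with the signatures' overlap.
  sys <- tiny_system()
  grid <- sys$grid
  op <- imaging_operator(sys$cal, sys$scheme, grid, phase_only = TRUE)
  ph <- phantom(array(voxel_position(grid, c(3, 4, 1)), c(1, 3, 1)))
  s <- as.vector(simulate_acquisition(sys$cal, sys$scheme, ph, grid)$v[, , , 1])
  g <- as.vector(forward_apply(op, adjoint_apply(op, array(s, c(4, 4, 4)))))
  b1 <- s / sqrt(sum(Mod(s)^2))
  g2 <- g - sum(Conj(b1) * g) * b1
  b2 <- g2 / sqrt(sum(Mod(g2)^2))
  set.seed(2)
  m <- rand_cplx(64)
  m <- m - sum(Conj(b1) * m) * b1 - sum(Conj(b2) * m) * b2
  m <- m / sqrt(sum(Mod(m)^2)) * sqrt(sum(Mod(s)^2)) / 50
  nf <- 8
  v <- array(0i, c(4, 4, 4, nf))
  for (f in seq_len(nf)) {
    v[, , , f] <- array(200 * s + m * exp(2i * pi * (f - 1) / nf),
                        c(4, 4, 4))
  }
  acq <- acquisition_tensor(v, sys$cal$freqs, sys$scheme, frame_rate = 100)
  cutoff <- 1 / 8
  pre <- matched_filter(svd_clutter_filter(acq, cutoff)$tensor, op)
  post <- svd_filter_volumes(matched_filter(acq, op), cutoff)$stack
  pdi_pre <- power_doppler(pre)
  pdi_post <- power_doppler(post)
  expect_lt(max(abs(pdi_pre - pdi_post)) / max(pdi_post), 0.01)
})
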