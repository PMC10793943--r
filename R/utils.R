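# Internal helpers shared across modules. All physical quantities are SI.

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

.is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# global RNG state. All stochastic operations in the package flow through
# this, so no stage reads or advances the global stream.
.with_seed <- function(seed, code) {
  .assert(.is_scalar_num(seed), "seed must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# DFT sample frequencies (cycles per unit), numpy-style ordering.
.fftfreq <- function(n, d = 1) {
  .assert(n >= 1, "n must be >= 1")
  pos <- seq.int(0L, ceiling(n / 2) - 1L)
  neg <- if (n > 1) seq.int(-floor(n / 2), -1L) else integer(0)
  c(pos, neg) / (n * d)
}

.ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

# Circular complex white Gaussian noise with total std `sigma` per entry
# (sqrt(E|n|^2) = sigma).
.cnoise <- function(n, sigma) {
  complex(real = stats::rnorm(n, sd = sigma / sqrt(2)),
          imaginary = stats::rnorm(n, sd = sigma / sqrt(2)))
}

.l2 <- function(x) sqrt(sum(Mod(x)^2))

.cdot <- function(x, y) sum(Conj(x) * y)

# Cell-centered symmetric lateral coordinates for an extent/spacing pair.
.axis_coords <- function(extent, spacing) {
  n <- round(extent / spacing)
  .assert(n >= 1, "extent must cover at least one grid cell")
  (seq_len(n) - (n + 1) / 2) * spacing
}

# Bilinear interpolation of z (nx x ny, sampled at x, y ascending) at the
# tensor grid xi x yi. Points must lie inside [min(x), max(x)] etc. within
# a small tolerance (clamped).
.interp2 <- function(x, y, z, xi, yi) {
  tol <- 1e-9 * max(diff(range(x)), diff(range(y)))
  .assert(min(xi) >= min(x) - tol && max(xi) <= max(x) + tol &&
            min(yi) >= min(y) - tol && max(yi) <= max(y) + tol,
          "interpolation target grid extends beyond the source grid")
  xi <- pmin(pmax(xi, min(x)), max(x))
  yi <- pmin(pmax(yi, min(y)), max(y))
  ix <- findInterval(xi, x, rightmost.closed = TRUE)
  iy <- findInterval(yi, y, rightmost.closed = TRUE)
  ix <- pmin(pmax(ix, 1L), length(x) - 1L)
  iy <- pmin(pmax(iy, 1L), length(y) - 1L)
  tx <- (xi - x[ix]) / (x[ix + 1L] - x[ix])
  ty <- (yi - y[iy]) / (y[iy + 1L] - y[iy])
  TX <- matrix(tx, length(xi), length(yi))
  TY <- matrix(ty, length(xi), length(yi), byrow = TRUE)
  z00 <- z[cbind(rep(ix, length(yi)), rep(iy, each = length(xi)))]
  z10 <- z[cbind(rep(ix + 1L, length(yi)), rep(iy, each = length(xi)))]
  z01 <- z[cbind(rep(ix, length(yi)), rep(iy + 1L, each = length(xi)))]
  z11 <- z[cbind(rep(ix + 1L, length(yi)), rep(iy + 1L, each = length(xi)))]
  out <- (1 - TX) * (1 - TY) * z00 + TX * (1 - TY) * z10 +
    (1 - TX) * TY * z01 + TX * TY * z11
  matrix(out, length(xi), length(yi))
}
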