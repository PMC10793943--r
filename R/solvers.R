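#' Solver configuration
#'
#' @param method One of `"matched"`, `"lsmr"`, `"twist"`.
#' @param max_iter Iteration cap (the early-stopped iterate is the
#'   regularizer for LSMR; 8 is where the reconstruction stops changing
#'   appreciably before noise fitting sets in).
#' @param lambda_factor TwIST regularization as a fraction of
#'   `max |A^H v|` (default 0.2).
#' @param debias Run a conjugate-gradient least-squares refit on the
#'   nonzero support after TwIST converges.
#' @param tolerance Relative convergence tolerance.
#' @return An object of class `cusi_solver_config`.
#' @export
solver_config <- function(method = c("matched", "lsmr", "twist"),
                          max_iter = 8, lambda_factor = 0.2, debias = TRUE,
                          tolerance = 1e-8) {
  method <- match.arg(method)
  .assert(max_iter >= 1, "max_iter must be >= 1")
  .assert(lambda_factor >= 0, "lambda_factor must be >= 0")
  structure(list(method = method, max_iter = as.integer(max_iter),
                 lambda_factor = lambda_factor, debias = debias,
                 tolerance = tolerance),
            class = "cusi_solver_config")
}

#' Phase-only matched-filter reconstruction
#'
#' Reconstructs every valid frame as `u = A_new^H v` with the phase-only
#' model `A_new = exp(i arg(A))`: the data are correlated against each
#' voxel's unit-modulus pulse-echo signature. Invalid frames are skipped.
#' Frames are batched through a single streamed operator pass, and results
#' are independent of frame order.
#'
#' @param acq An [acquisition_tensor()].
#' @param op A phase-only [imaging_operator()].
#' @return A [volume_stack()] of the valid frames.
#' @export
matched_filter <- function(acq, op) {
  .assert(isTRUE(op$phase_only),
          "matched_filter requires a phase-only imaging_operator")
  frames <- which(acq$valid)
  .assert(length(frames) >= 1, "no valid frames to reconstruct")
  d <- dim(acq$v)
  u <- .op_pass(op, acq$v[, , , frames, drop = FALSE], adjoint = TRUE)
  volume_stack(u, op$grid, frame_index = frames,
               frame_times = acq$frame_times[frames],
               frame_rate = acq$frame_rate,
               provenance = list(method = "matched", phase_only = TRUE))
}

# Matrix-free LSMR (Fong & Saunders 2011) for min ||b - A x||_2 over complex
# operators. Returns the iterate at max_iter together with the per-iteration
# residual-norm estimates (monotonically non-increasing by construction).
.lsmr <- function(Afun, AHfun, b, max_iter, atol = 1e-10, btol = 1e-10) {
  beta <- .l2(b)
  u <- if (beta > 0) b / beta else b
  v <- AHfun(u)
  alpha <- .l2(v)
  if (alpha > 0) v <- v / alpha
  zetabar <- alpha * beta
  alphabar <- alpha
  rho <- 1; rhobar <- 1; cbar <- 1; sbar <- 0
  h <- v; hbar <- 0 * v; x <- 0 * v
  betadd <- beta; betad <- 0
  rhodold <- 1; tautildeold <- 0; thetatilde <- 0; zeta <- 0; dacc <- 0
  normr_hist <- numeric(0)
  if (zetabar == 0) return(list(x = x, residuals = beta, iterations = 0L))
  for (itn in seq_len(max_iter)) {
    u <- Afun(v) - alpha * u
    beta <- .l2(u)
    if (beta > 0) {
      u <- u / beta
      v <- AHfun(u) - beta * v
      alpha <- .l2(v)
      if (alpha > 0) v <- v / alpha
    }
    rhoold <- rho
    rho <- sqrt(alphabar^2 + beta^2)
    cc <- alphabar / rho
    ss <- beta / rho
    thetanew <- ss * alpha
    alphabar <- cc * alpha
    rhobarold <- rhobar
    zetaold <- zeta
    thetabar <- sbar * rho
    rhotemp <- cbar * rho
    rhobar <- sqrt(rhotemp^2 + thetanew^2)
    cbar <- rhotemp / rhobar
    sbar <- thetanew / rhobar
    zeta <- cbar * zetabar
    zetabar <- -sbar * zetabar
    hbar <- h - (thetabar * rho / (rhoold * rhobarold)) * hbar
    x <- x + (zeta / (rho * rhobar)) * hbar
    h <- v - (thetanew / rho) * h
    # residual-norm recurrence (damp = 0)
    betahat <- cc * betadd
    betadd <- -ss * betadd
    thetatildeold <- thetatilde
    rhotildeold <- sqrt(rhodold^2 + thetabar^2)
    ctildeold <- rhodold / rhotildeold
    stildeold <- thetabar / rhotildeold
    thetatilde <- stildeold * rhobar
    rhodold <- ctildeold * rhobar
    betad <- -stildeold * betad + ctildeold * betahat
    tautildeold <- (zetaold - thetatildeold * tautildeold) / rhotildeold
    taud <- (zeta - thetatilde * tautildeold) / rhodold
    normr <- sqrt(dacc + (betad - taud)^2 + betadd^2)
    normr_hist <- c(normr_hist, normr)
    if (!all(is.finite(Mod(x)))) {
      stop("LSMR diverged: non-finite iterate at iteration ", itn,
           call. = FALSE)
    }
    if (normr <= btol * normr_hist[1] + atol) break
  }
  list(x = x, residuals = normr_hist, iterations = length(normr_hist))
}

.op_funs <- function(op) {
  g <- op$grid$dims
  d <- dim(op$cal$fields)
  list(
    A = function(x) as.vector(forward_apply(op, array(x, g))),
    AH = function(y) as.vector(adjoint_apply(
      op, array(y, c(d[3], ncol(op$scheme$H), d[4])))),
    n_vox = prod(g)
  )
}

#' Least-squares reconstruction of one frame (LSMR)
#'
#' Minimizes `||v - A u||_2^2` with the LSMR Krylov solver on the
#' matrix-free operator, returning the iterate at `cfg$max_iter`; early
#' stopping acts as the regularizer. The estimated residual norm is recorded
#' per iteration and is non-increasing.
#'
#' @param v_frame One frame of channel data, `(N_w, N_t, N_e)`.
#' @param op A [imaging_operator()] (amplitude model; not phase-only).
#' @param cfg A [solver_config()].
#' @return A list with `volume` (complex 3D array), `residuals`,
#'   `iterations`.
#' @export
lsmr_solve <- function(v_frame, op, cfg = solver_config(method = "lsmr")) {
  fns <- .op_funs(op)
  res <- .lsmr(fns$A, fns$AH, as.vector(v_frame), cfg$max_iter,
               atol = 0, btol = cfg$tolerance)
  list(volume = array(res$x, op$grid$dims), residuals = res$residuals,
       iterations = res$iterations)
}

# Power iteration for the largest singular value of the operator; seeded
# internally so the estimate is deterministic.
.op_norm <- function(Afun, AHfun, n, iters = 12) {
  x <- .with_seed(1717, complex(real = stats::rnorm(n),
                                imaginary = stats::rnorm(n)))
  x <- x / .l2(x)
  s2 <- 0
  for (i in seq_len(iters)) {
    y <- AHfun(Afun(x))
    s2 <- .l2(y)
    if (s2 == 0) return(1)
    x <- y / s2
  }
  sqrt(s2)
}

.soft <- function(x, t) {
  a <- Mod(x)
  sc <- ifelse(a > t, (a - t) / pmax(a, .Machine$double.xmin), 0)
  x * sc
}

#' Sparsity-promoting reconstruction of one frame (TwIST)
#'
#' Minimizes `||v - A u||_2^2 + lambda ||u||_1` with the two-step iterative
#' shrinkage/thresholding algorithm, using complex magnitude
#' soft-thresholding and `lambda = lambda_factor * max |A^H v|`. The
#' operator is rescaled to unit spectral norm internally (power-iteration
#' estimate) as the algorithm requires; a monotone safeguard falls back to
#' the plain IST step whenever the two-step update would increase the
#' objective, so the recorded objective is non-increasing. With
#' `cfg$debias`, a conjugate-gradient least-squares refit restricted to the
#' nonzero support follows.
#'
#' @inheritParams lsmr_solve
#' @return A list with `volume`, `objective` (per-iteration values),
#'   `lambda`, and `support_size`.
#' @export
twist_solve <- function(v_frame, op, cfg = solver_config(method = "twist")) {
  fns <- .op_funs(op)
  b <- as.vector(v_frame)
  s <- .op_norm(fns$A, fns$AH, fns$n_vox) * 1.02
  if (s == 0) s <- 1
  As <- function(x) fns$A(x) / s
  AHs <- function(y) fns$AH(y) / s
  lambda <- cfg$lambda_factor * max(Mod(fns$AH(b)))
  lt <- lambda / s
  objective <- function(x) {
    r <- b - As(x)
    0.5 * sum(Mod(r)^2) + lt * sum(Mod(x))
  }
  # TwIST two-step coefficients from the published defaults
  lam1 <- 1e-4
  rho0 <- (1 - lam1) / (1 + lam1)
  alph <- 2 / (1 + sqrt(1 - rho0^2))
  bet <- alph * 2 / (1 + lam1)
  xm1 <- rep(0 + 0i, fns$n_vox)
  x <- .soft(AHs(b), lt)
  obj <- c(objective(xm1), objective(x))
  if (obj[2] > obj[1]) {
    x <- xm1
    obj[2] <- obj[1]
  }
  for (it in seq_len(max(0, cfg$max_iter - 1))) {
    grad_point <- x + AHs(b - As(x))
    xist <- .soft(grad_point, lt)
    xtw <- (1 - alph) * xm1 + (alph - bet) * x + bet * xist
    fist <- objective(xist)
    ftw <- objective(xtw)
    if (ftw <= tail(obj, 1)) {
      xnew <- xtw; fnew <- ftw
    } else if (fist <= tail(obj, 1)) {
      xnew <- xist; fnew <- fist
    } else {
      xnew <- x; fnew <- tail(obj, 1)
    }
    if (!all(is.finite(Mod(xnew)))) {
      stop("TwIST diverged: non-finite iterate", call. = FALSE)
    }
    xm1 <- x
    x <- xnew
    obj <- c(obj, fnew)
    if (length(obj) > 2 &&
        abs(obj[length(obj) - 1] - fnew) <= cfg$tolerance * abs(obj[2] + 1e-300)) {
      break
    }
  }
  support <- Mod(x) > 0
  if (cfg$debias && any(support)) {
    x <- .debias_cg(As, AHs, b, x, support,
                    iters = min(50, cfg$max_iter * 4))
  }
  list(volume = array(x / s, op$grid$dims), objective = obj,
       lambda = lambda, support_size = sum(support))
}

# CG on the normal equations restricted to the support (Figueiredo-style
# debiasing step).
.debias_cg <- function(As, AHs, b, x0, support, iters = 30, tol = 1e-10) {
  msk <- as.numeric(support)
  x <- x0 * msk
  r <- b - As(x)
  g <- AHs(r) * msk
  p <- g
  gg <- sum(Mod(g)^2)
  if (gg == 0) return(x)
  for (i in seq_len(iters)) {
    q <- As(p)
    qq <- sum(Mod(q)^2)
    if (qq == 0) break
    alpha <- gg / qq
    x <- x + alpha * p
    r <- r - alpha * q
    g <- AHs(r) * msk
    gg_new <- sum(Mod(g)^2)
    if (gg_new <= tol * gg) {
      gg <- gg_new
      break
    }
    p <- g + (gg_new / gg) * p
    gg <- gg_new
  }
  x
}
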