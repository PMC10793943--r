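#' Frequency-domain acquisition tensor
#'
#' Channel data `v` with dimensions `(N_w, N_t, N_e, N_f)`: frequency,
#' transmission, receive element, frame; plus per-frame validity flags and
#' acquisition metadata.
#'
#' @param v Complex 4D array `(N_w, N_t, N_e, N_f)`.
#' @param freqs The [make_frequency_grid()] the data live on.
#' @param scheme The transmit encoding scheme used.
#' @param frame_times Acquisition time of each frame, seconds.
#' @param frame_rate Nominal volume rate, Hz.
#' @param valid Logical validity flag per frame.
#' @param block Frames per contiguous hardware block (for prefix dropping).
#' @return An object of class `cusi_acquisition`.
#' @export
acquisition_tensor <- function(v, freqs, scheme, frame_times = NULL,
                               frame_rate = NA_real_, valid = NULL,
                               block = NULL) {
  .assert(length(dim(v)) == 4, "v must be a 4D array (N_w, N_t, N_e, N_f)")
  d <- dim(v)
  .assert(d[1] == freqs$n_freq, "frequency axis does not match the grid")
  .assert(d[2] == ncol(scheme$H) && d[3] == nrow(scheme$H),
          "transmission/element axes do not match the scheme")
  .assert(all(is.finite(Mod(v))), "tensor values must be finite")
  if (is.null(valid)) valid <- rep(TRUE, d[4])
  if (is.null(frame_times)) {
    frame_times <- if (is.finite(frame_rate)) (seq_len(d[4]) - 1) / frame_rate
    else rep(NA_real_, d[4])
  }
  structure(list(v = v, freqs = freqs, scheme = scheme,
                 frame_times = frame_times, frame_rate = frame_rate,
                 valid = valid, block = block, n_frames = d[4]),
            class = "cusi_acquisition")
}

#' @export
print.cusi_acquisition <- function(x, ...) {
  d <- dim(x$v)
  cat(sprintf(
    "cusi acquisition: %d freq x %d tx x %d el x %d frames (%d valid)\n",
    d[1], d[2], d[3], d[4], sum(x$valid)))
  invisible(x)
}

#' Simulate a coded-wavefield acquisition
#'
#' Synthesizes frequency-domain channel data `v = A u (+ noise)` for every
#' phantom frame: scatterers are deposited on the image grid by trilinear
#' spreading and pushed through the forward imaging operator (pulse-echo
#' reciprocity product of element and encoded transmit fields, accumulated
#' depth slice by depth slice), then circular complex white Gaussian noise
#' of std `noise_sigma` per entry is added.
#'
#' @param cal A [synthesize_calibration()] container.
#' @param scheme A transmit encoding scheme.
#' @param phan A [phantom()] whose scatterers lie inside `grid`.
#' @param grid The [image_grid()] used for deposition and the model.
#' @param noise_sigma Noise std per complex tensor entry (0 for noiseless).
#' @param seed RNG seed for the noise.
#' @param frame_rate Frame rate recorded in the tensor (defaults to the
#'   phantom's).
#' @param pad_factor,cutoff Passed to the internal [imaging_operator()].
#' @return An [acquisition_tensor()] of shape
#'   `(N_w, N_t, N_e, n_frames)`.
#' @export
simulate_acquisition <- function(cal, scheme, phan, grid, noise_sigma = 0,
                                 seed = 1, frame_rate = phan$frame_rate,
                                 pad_factor = 2, cutoff = TRUE) {
  op <- imaging_operator(cal, scheme, grid, phase_only = FALSE,
                         pad_factor = pad_factor, cutoff = cutoff)
  nf <- phan$n_frames
  g <- grid$dims
  u <- array(0 + 0i, c(g, nf))
  for (f in seq_len(nf)) u[, , , f] <- deposit_phantom(phan, grid, f)
  v <- .op_pass(op, u, adjoint = FALSE)
  if (noise_sigma > 0) {
    v <- v + .with_seed(seed, array(.cnoise(length(v), noise_sigma), dim(v)))
  }
  acquisition_tensor(v, cal$freqs, scheme, frame_rate = frame_rate)
}
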