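#' Default pipeline configuration
#'
#' A nested list with every tunable of the simulation/reconstruction
#' pipeline. Probe, mask, frequency and calibration-plane defaults are the
#' physical system constants (8 x 8 probe at 13.8 MHz, 370 um / 1.2 mm mask,
#' 128 frequencies over a 50% band about 15.625 MHz, 12 x 12 mm calibration
#' plane at 40 um, 12 mm offset). Acquisition and grid defaults are a
#' desk-scale study (small frame counts, sub-64^3 grids) suitable for a
#' single CPU; scale them up explicitly for full-size runs.
#'
#' @return A nested configuration list.
#' @export
default_config <- function() {
  list(
    probe = list(nx = 8L, ny = 8L, pitch = 1.25e-3, element_width = 1.25e-3,
                 f_center = 13.8e6, fractional_bw = 0.65, c = 1500),
    mask = list(seed = 1L, feature_size = 370e-6, height_range = 1.2e-3,
                extent = 12e-3, spacing = 40e-6, c_mask = 2337),
    freq = list(n = 128L, center = 15.625e6, band = 0.5),
    plane = list(extent = 12e-3, spacing = 40e-6, z = 12e-3),
    pulse = list(n_cycles = 5L),
    grid = list(spacing = 40e-6, dims = c(64L, 64L, 64L), z_offset = 0.5e-3),
    phantom = list(type = "flow", speed = 2e-3, radius = 0.5e-3,
                   density = 30, seed = 7L, static_fraction = 0),
    acquisition = list(n_frames = 12L, frame_rate = 400, noise_sigma = 0,
                       seed = 11L, scheme = "hadamard", block = 100L),
    preprocess = list(cutoff = 0.65, jitter_k = 5, block = 100L, drop = 0L,
                      clutter_filter = FALSE),
    reconstruct = list(method = "matched", iters = 8L, lambda_factor = 0.2,
                       phase_only = TRUE, pad_factor = 2),
    doppler = list(lag = 1L, subset = NA_integer_, pdi = TRUE, cdi = TRUE)
  )
}

# Recursively merge a user configuration over the defaults.
.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration
#'
#' Loads a YAML configuration file and merges it over [default_config()];
#' `config` may also be a list (merged directly) or `NULL` (defaults).
#'
#' @param config Path to a YAML file, a list, or `NULL`.
#' @return The merged configuration list.
#' @export
read_config <- function(config = NULL) {
  base <- default_config()
  if (is.null(config)) return(base)
  user <- if (is.character(config)) {
    .assert(file.exists(config), paste0("no such config file: ", config))
    yaml::read_yaml(config)
  } else {
    .assert(is.list(config), "config must be a path or a list")
    config
  }
  .merge_config(base, user)
}

.cfg_probe <- function(cfg) {
  probe_geometry(cfg$probe$nx, cfg$probe$ny, cfg$probe$pitch,
                 cfg$probe$element_width, cfg$probe$f_center,
                 cfg$probe$fractional_bw, cfg$probe$c)
}

.cfg_grid <- function(cfg) {
  image_grid(cfg$grid$dims, cfg$grid$spacing, cfg$grid$z_offset)
}

#' Build the synthetic imaging system from a configuration
#'
#' Generates the encoding mask and synthesizes the per-element calibration
#' fields; optionally writes the calibration container and a run manifest.
#'
#' @param config Configuration (path, list or `NULL`; see [read_config()]).
#' @param out Optional output directory.
#' @param seed Optional override of the mask seed.
#' @return The `cusi_calibration` container, invisibly when writing.
#' @export
cusi_simulate_system <- function(config = NULL, out = NULL, seed = NULL) {
  cfg <- read_config(config)
  if (!is.null(seed)) cfg$mask$seed <- as.integer(seed)
  t0 <- proc.time()[["elapsed"]]
  probe <- .cfg_probe(cfg)
  mask <- if (cfg$mask$height_range > 0) {
    generate_mask(cfg$mask$seed, cfg$mask$feature_size,
                  cfg$mask$height_range, cfg$mask$extent, cfg$mask$spacing,
                  cfg$mask$c_mask)
  } else NULL
  freqs <- make_frequency_grid(cfg$freq$center, cfg$freq$band, cfg$freq$n)
  cal <- synthesize_calibration(probe, mask, freqs,
                                plane_extent = cfg$plane$extent,
                                plane_spacing = cfg$plane$spacing,
                                z_plane = cfg$plane$z,
                                n_cycles = cfg$pulse$n_cycles)
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    cal_path <- file.path(out, "calibration.rds")
    write_container(cal, cal_path)
    write_manifest(file.path(out, "manifest-system.json"), cfg,
                   seeds = list(mask = cfg$mask$seed),
                   timings = list(simulate_system =
                                    proc.time()[["elapsed"]] - t0),
                   files = cal_path)
    return(invisible(cal))
  }
  cal
}

.cfg_phantom <- function(cfg, grid) {
  p <- cfg$phantom
  ctr <- voxel_position(grid, (grid$dims - 1) / 2)
  zspan <- (grid$dims[3] - 1) * grid$spacing
  if (identical(p$type, "spiral")) {
    ext <- (grid$dims - 5) * grid$spacing
    spiral_phantom(ext, n_points = if (is.null(p$n_points)) 400 else p$n_points,
                   turns = if (is.null(p$turns)) 3 else p$turns,
                   center = ctr)
  } else {
    tube <- list(start = c(ctr[1], ctr[2], grid$origin[3] + 0.2 * zspan),
                 end = c(ctr[1], ctr[2], grid$origin[3] + 0.8 * zspan),
                 radius = p$radius)
    flow_phantom(tube, p$speed, cfg$acquisition$n_frames,
                 cfg$acquisition$frame_rate, density = p$density,
                 seed = p$seed, static_fraction = p$static_fraction,
                 static_box = if (p$static_fraction > 0) {
                   list(center = ctr,
                        size = (grid$dims - 2) * grid$spacing)
                 } else NULL)
  }
}

#' Run the full simulation-to-Doppler pipeline
#'
#' Synthesizes (or loads) the calibration, simulates an acquisition of the
#' configured phantom, preprocesses it (jitter rejection, block-prefix
#' drop, optional SVD clutter filter), reconstructs every valid frame and
#' forms the Doppler products. All stage outputs plus a manifest are
#' written when `out` is given.
#'
#' @param config Configuration (path, list or `NULL`).
#' @param out Optional output directory.
#' @param cal Optional pre-built calibration container (or path).
#' @param seed Optional override of the acquisition noise seed.
#' @return A list with `cal`, `acq`, `volumes`, `doppler`, `reports`.
#' @export
cusi_pipeline <- function(config = NULL, out = NULL, cal = NULL,
                          seed = NULL) {
  cfg <- read_config(config)
  if (!is.null(seed)) cfg$acquisition$seed <- as.integer(seed)
  timings <- list()
  tick <- function() proc.time()[["elapsed"]]
  t0 <- tick()
  if (is.character(cal)) cal <- read_container(cal, "cusi_calibration")
  if (is.null(cal)) cal <- cusi_simulate_system(cfg)
  timings$system <- tick() - t0

  grid <- .cfg_grid(cfg)
  scheme <- if (identical(cfg$acquisition$scheme, "identity")) {
    identity_scheme(cal$probe$n_elements)
  } else {
    hadamard_scheme(cal$probe$n_elements)
  }
  phan <- .cfg_phantom(cfg, grid)
  t0 <- tick()
  acq <- simulate_acquisition(cal, scheme, phan, grid,
                              noise_sigma = cfg$acquisition$noise_sigma,
                              seed = cfg$acquisition$seed,
                              frame_rate = cfg$acquisition$frame_rate,
                              pad_factor = cfg$reconstruct$pad_factor)
  timings$simulate <- tick() - t0

  t0 <- tick()
  reports <- list()
  if (cfg$preprocess$drop > 0) {
    acq <- drop_block_prefix(acq, cfg$preprocess$block, cfg$preprocess$drop)
  }
  if (acq$n_frames >= 2) {
    js <- detect_unstable_frames(acq, cfg$preprocess$jitter_k)
    acq <- js$tensor
    reports$jitter <- js$report
  }
  if (isTRUE(cfg$preprocess$clutter_filter)) {
    cs <- svd_clutter_filter(acq, cfg$preprocess$cutoff)
    acq <- cs$tensor
    reports$clutter <- cs$report
  }
  timings$preprocess <- tick() - t0

  t0 <- tick()
  method <- cfg$reconstruct$method
  if (identical(method, "matched")) {
    op <- imaging_operator(cal, scheme, grid, phase_only = TRUE,
                           pad_factor = cfg$reconstruct$pad_factor)
    vols <- if (is.finite(cfg$doppler$subset) && !is.na(cfg$doppler$subset)) {
      subframe_stack(acq, op, cfg$doppler$subset)
    } else {
      matched_filter(acq, op)
    }
  } else {
    op <- imaging_operator(cal, scheme, grid, phase_only = FALSE,
                           pad_factor = cfg$reconstruct$pad_factor)
    frames <- which(acq$valid)
    u <- array(0 + 0i, c(grid$dims, length(frames)))
    cfg_s <- solver_config(method = method, max_iter = cfg$reconstruct$iters,
                           lambda_factor = cfg$reconstruct$lambda_factor)
    for (j in seq_along(frames)) {
      vf <- acq$v[, , , frames[j]]
      sol <- if (identical(method, "lsmr")) {
        lsmr_solve(vf, op, cfg_s)
      } else {
        twist_solve(vf, op, cfg_s)
      }
      u[, , , j] <- sol$volume
    }
    vols <- volume_stack(u, grid, frame_index = frames,
                         frame_times = acq$frame_times[frames],
                         frame_rate = acq$frame_rate,
                         provenance = list(method = method))
  }
  timings$reconstruct <- tick() - t0

  t0 <- tick()
  pdi <- if (isTRUE(cfg$doppler$pdi)) power_doppler(vols) else NULL
  cdi <- if (isTRUE(cfg$doppler$cdi) && vols$n_frames > cfg$doppler$lag) {
    color_doppler(vols, cfg$doppler$lag)
  } else NULL
  dop <- doppler_products(pdi, cdi, n_frames_used = vols$n_frames,
                          lag = cfg$doppler$lag)
  timings$doppler <- tick() - t0

  result <- list(cal = cal, acq = acq, volumes = vols, doppler = dop,
                 reports = reports, config = cfg, timings = timings)
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    paths <- c(acquisition = file.path(out, "acquisition.rds"),
               volumes = file.path(out, "volumes.rds"),
               doppler = file.path(out, "doppler.rds"))
    write_container(acq, paths[["acquisition"]])
    write_container(vols, paths[["volumes"]])
    write_container(dop, paths[["doppler"]])
    if (!is.null(pdi)) {
      export_volume(pdi, file.path(out, "pdi.tif"))
    }
    if (length(reports)) {
      jsonlite::write_json(lapply(reports, unclass),
                           file.path(out, "filter-reports.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    write_manifest(file.path(out, "manifest-pipeline.json"), cfg,
                   seeds = list(mask = cfg$mask$seed,
                                phantom = cfg$phantom$seed,
                                noise = cfg$acquisition$seed),
                   timings = timings, files = paths)
  }
  result
}
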