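#' Container persistence
#'
#' All pipeline stages exchange self-describing classed containers
#' (calibration, acquisition, volume stack, Doppler products) serialized as
#' single `.rds` files; any stage can run from a container alone without
#' the original configuration.
#'
#' @param object A cusi container object.
#' @param path Destination path.
#' @return `write_container`: the path, invisibly. `read_container`: the
#'   object.
#' @export
write_container <- function(object, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(object, path)
  invisible(path)
}

#' @rdname write_container
#' @param expect Optional class name to require on read.
#' @export
read_container <- function(path, expect = NULL) {
  .assert(file.exists(path), paste0("no such container: ", path))
  obj <- readRDS(path)
  if (!is.null(expect)) {
    .assert(inherits(obj, expect),
            paste0("container is not a ", expect, " object"))
  }
  obj
}

#' Run manifest
#'
#' Every pipeline run writes one JSON manifest recording the configuration
#' snapshot, the named seeds, package version, per-stage wall-clock timings
#' and the paths plus MD5 content hashes of all containers read or written.
#' Reruns with identical configuration and seeds produce identical output
#' hashes for deterministic stages.
#'
#' @param path Manifest destination (JSON).
#' @param config Configuration list snapshot.
#' @param seeds Named list of seeds used.
#' @param timings Named list of stage timings, seconds.
#' @param files Character vector of container paths to hash.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config, seeds = list(), timings = list(),
                           files = character(0)) {
  files <- files[file.exists(files)]
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("cusi")),
    config = config,
    seeds = seeds,
    timings_s = timings,
    files = lapply(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)),
           bytes = file.info(f)$size)
    })
  )
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Export a volume as a multi-page TIFF (or CSV slices)
#'
#' Writes a real 3D volume as a 32-bit multi-page TIFF, one page per
#' z-slice. Values are affinely mapped to [0, 1] for storage; the range is
#' recorded in a JSON sidecar so `import_volume()` restores the original
#' values within float precision. With `db = TRUE` the volume is first
#' converted to decibels relative to its maximum and clipped at `db_floor`.
#' `format = "csv"` writes one CSV per slice instead.
#'
#' @param volume Real 3D array (use `Mod()` for complex volumes).
#' @param path Output path (`.tif` or a directory for CSV slices).
#' @param format `"tiff"` or `"csv"`.
#' @param db Export in dB relative to the volume maximum.
#' @param db_floor Clip floor for dB export.
#' @return The main output path, invisibly.
#' @export
export_volume <- function(volume, path, format = c("tiff", "csv"),
                          db = FALSE, db_floor = -60) {
  format <- match.arg(format)
  .assert(length(dim(volume)) == 3, "volume must be a 3D array")
  .assert(all(is.finite(volume)), "volume must be finite")
  v <- volume
  if (db) {
    mx <- max(v)
    .assert(mx > 0, "dB export needs a positive maximum")
    v <- pmax(20 * log10(pmax(v, 0) / mx + 10^((db_floor - 20) / 20)),
              db_floor)
  }
  if (format == "csv") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_len(dim(v)[3])) {
      utils::write.csv(v[, , k],
                       file.path(path, sprintf("slice_%03d.csv", k)),
                       row.names = FALSE)
    }
    return(invisible(path))
  }
  rng <- range(v)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(dim(v)[3]), function(k) {
    (t(v[, , k]) - rng[1]) / scale
  })
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(list(min = rng[1], max = rng[2],
                            dims = dim(v), db = db),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname export_volume
#' @export
import_volume <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  scale <- if (meta$max > meta$min) meta$max - meta$min else 1
  v <- array(NA_real_, meta$dims)
  for (k in seq_along(pages)) v[, , k] <- t(pages[[k]]) * scale + meta$min
  v
}
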