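# File formats: multi-page TIFF hyperstacks with a JSON sidecar carrying
# channel names, voxel sizes and the intensity scale; CSV spot and count
# tables; 16-bit TIFF label maps.

sidecar_path <- function(path) paste0(path, ".json")

#' Write an image stack as a multi-page TIFF hyperstack
#'
#' Pages are ordered channel-major (all z-slices of channel 1, then channel
#' 2, ...). Intensities are stored as 16-bit samples scaled by a
#' power-of-two intensity scale; the scale, channel names, slice count and
#' voxel sizes go to a JSON sidecar (`<path>.json`) so the file round-trips
#' without guessing.
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  # power-of-two scale (division exact in binary floating point) and
  # explicit 16-bit quantisation in R: write(read(x)) is voxel-identical
  scale <- 2^ceiling(log2(max(1, vapply(stack$channels, max, numeric(1)))))
  pages <- list()
  for (ch in names(stack$channels)) {
    vol <- round(stack$channels[[ch]] / scale * 65535) / 65535
    for (z in seq_len(dim(vol)[1])) {
      pages[[length(pages) + 1]] <- vol[z, , ]
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  jsonlite::write_json(
    list(
      channels = names(stack$channels),
      n_z = dim(stack$channels[[1]])[1],
      voxel_size_nm = stack$voxel_size_nm,
      intensity_scale = scale
    ),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read an image stack from a multi-page TIFF
#'
#' Metadata (channel names, slice count, voxel sizes, intensity scale) is
#' taken from the JSON sidecar written by [write_stack()] when present;
#' a `config` list can supply or override it (`channels`, `n_z`,
#' `voxel_size_nm`, `intensity_scale`). When both give voxel sizes and they
#' disagree, the config wins with a warning.
#'
#' @param path TIFF path.
#' @param config Optional metadata list overriding the sidecar.
#' @return An `image_stack`.
#' @export
read_stack <- function(path, config = NULL) {
  if (!file.exists(path)) abort(sprintf("cannot read stack: '%s' does not exist", path))
  meta <- if (file.exists(sidecar_path(path))) {
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  } else {
    list()
  }
  if (!is.null(config$voxel_size_nm) && !is.null(meta$voxel_size_nm) &&
      !isTRUE(all.equal(as.numeric(config$voxel_size_nm),
                        as.numeric(meta$voxel_size_nm)))) {
    warn(sprintf(
      "voxel sizes in config (%s) differ from stack metadata (%s); using config",
      paste(config$voxel_size_nm, collapse = "/"),
      paste(meta$voxel_size_nm, collapse = "/")
    ))
  }
  channels <- config$channels %||% meta$channels
  voxel <- config$voxel_size_nm %||% meta$voxel_size_nm
  scale <- config$intensity_scale %||% meta$intensity_scale %||% 1
  if (is.null(channels) || is.null(voxel)) {
    abort(sprintf(
      "cannot read stack '%s': channel names and voxel sizes must come from the sidecar or the config",
      path
    ))
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  n_ch <- length(channels)
  if (length(pages) %% n_ch != 0) {
    abort(sprintf(
      "cannot read stack '%s': %d pages are not divisible by %d channels",
      path, length(pages), n_ch
    ))
  }
  n_z <- length(pages) %/% n_ch
  if (!is.null(meta$n_z) && meta$n_z != n_z) {
    abort(sprintf("stack '%s': sidecar declares %d z-slices but file implies %d",
                  path, meta$n_z, n_z))
  }
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  chans <- list()
  for (c in seq_len(n_ch)) {
    vol <- array(0, c(n_z, ny, nx))
    for (z in seq_len(n_z)) {
      vol[z, , ] <- pages[[(c - 1) * n_z + z]] * scale
    }
    chans[[channels[c]]] <- vol
  }
  structure(list(channels = chans, voxel_size_nm = as.numeric(voxel)),
            class = "image_stack")
}

#' Write / read an integer label map as 16-bit TIFF
#'
#' @param map Integer matrix (labels, background 0); values must fit in 16
#'   bits.
#' @param path TIFF path.
#' @return `path` (write) or the integer matrix (read).
#' @export
write_label_map <- function(map, path) {
  stopifnot(max(map) < 65536)
  tiff::writeTIFF(map / 65535, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write a ground truth to a directory
#'
#' Molecule table as CSV, label maps as 16-bit TIFF, configuration echo as
#' JSON.
#'
#' @param ground_truth A `ground_truth`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(ground_truth$molecules, file.path(dir, "molecules.csv"))
  write_label_map(ground_truth$maps$nuclear_labels,
                  file.path(dir, "nuclear_labels.tif"))
  write_label_map(ground_truth$maps$cell_labels,
                  file.path(dir, "cell_labels.tif"))
  cfg <- ground_truth$config
  jsonlite::write_json(
    cfg[!vapply(cfg, is.null, logical(1))],
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Spot and classification tables on disk
#'
#' Plain CSV with a header row; coordinates in nm.
#'
#' @param spots A spot or classified-spot tibble.
#' @param path CSV path.
#' @return `path` (writers, invisibly) or a tibble (readers).
#' @export
write_spots_csv <- function(spots, path) {
  readr::write_csv(as_tibble(spots), path)
  invisible(path)
}

#' @rdname write_spots_csv
#' @export
read_spots_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
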