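# 3D spot detection: scale-normalised Laplacian-of-Gaussian filtering of a
# z-stack channel, local-maxima extraction with non-maximum suppression,
# and subpixel refinement by intensity-weighted centroid.

#' Detection parameters
#'
#' @param sigma_nm Named numeric `(z, xy)`: expected spot scale in nm
#'   (typically the PSF sigma).
#' @param threshold Absolute response threshold, or `"auto"` to calibrate
#'   with [auto_threshold()].
#' @param min_separation_voxels Non-maximum-suppression radius: maxima are
#'   required to dominate a `(2k+1)^3` neighbourhood (default 1, i.e.
#'   3x3x3).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(sigma_nm = c(z = 350, xy = 170),
                             threshold = "auto",
                             min_separation_voxels = 1) {
  sigma_nm <- c(z = unname(sigma_nm[["z"]]), xy = unname(sigma_nm[["xy"]]))
  stopifnot(all(sigma_nm > 0), min_separation_voxels >= 1)
  if (!identical(threshold, "auto")) {
    stopifnot(is.numeric(threshold), threshold > 0)
  }
  structure(
    list(sigma_nm = sigma_nm, threshold = threshold,
         min_separation_voxels = as.integer(min_separation_voxels)),
    class = "detection_params"
  )
}

# separable 1D convolution along one axis of a 3D array, replicate borders
convolve_axis <- function(a, kernel, axis) {
  dims <- dim(a)
  n <- dims[axis]
  half <- (length(kernel) - 1L) / 2L
  out <- array(0, dims)
  for (m in seq_along(kernel)) {
    off <- m - 1L - half
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    shifted <- switch(axis,
      a[idx, , , drop = FALSE],
      a[, idx, , drop = FALSE],
      a[, , idx, drop = FALSE]
    )
    out <- out + kernel[m] * shifted
  }
  out
}

gaussian_kernel_1d <- function(sigma_vox) {
  half <- max(1L, ceiling(4 * sigma_vox))
  k <- dnorm(seq(-half, half), sd = sigma_vox)
  k / sum(k)
}

#' Scale-normalised Laplacian-of-Gaussian blob filter
#'
#' Smooths the volume with an anisotropic Gaussian at the expected spot
#' scale and applies the negated, scale-normalised Laplacian
#' `-(sigma_z^2 d2/dz2 + sigma_y^2 d2/dy2 + sigma_x^2 d2/dx2)`, so that a
#' bright diffraction-limited blob of matching scale yields a positive peak
#' at its centre whose height is invariant to the (anisotropic) scale.
#' Sigmas are converted to voxel units per axis using the voxel sizes.
#'
#' @param volume 3D numeric array `(z, y, x)`.
#' @param sigma_nm Named numeric `(z, xy)` spot scale in nm.
#' @param voxel_size_nm Numeric `(z, y, x)` voxel size in nm.
#' @return Response array, same shape as `volume`.
#' @export
blob_filter <- function(volume, sigma_nm, voxel_size_nm) {
  stopifnot(length(dim(volume)) == 3, all(voxel_size_nm > 0))
  sig <- c(sigma_nm[["z"]], sigma_nm[["xy"]], sigma_nm[["xy"]])
  sigma_vox <- sig / voxel_size_nm
  if (any(sigma_vox < 0.5)) {
    abort(sprintf(
      "sigma (%s voxels) is below half a voxel in at least one axis: the spot scale is undersampled",
      paste(sprintf("%.2f", sigma_vox), collapse = ", ")
    ))
  }
  sm <- volume
  for (a in 1:3) sm <- convolve_axis(sm, gaussian_kernel_1d(sigma_vox[a]), a)
  d2 <- c(1, -2, 1)
  resp <- array(0, dim(volume))
  for (a in 1:3) {
    resp <- resp - sigma_vox[a]^2 * convolve_axis(sm, d2, a)
  }
  resp
}

# separable max filter with window 2k+1 per axis (replicate borders)
max_filter <- function(a, k) {
  dims <- dim(a)
  for (axis in 1:3) {
    n <- dims[axis]
    out <- a
    for (off in setdiff(seq(-k, k), 0L)) {
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)
      shifted <- switch(axis,
        a[idx, , , drop = FALSE],
        a[, idx, , drop = FALSE],
        a[, , idx, drop = FALSE]
      )
      out <- pmax(out, shifted)
    }
    a <- out
  }
  a
}

# local maxima voxel indices (matrix z,y,x of 1-based indices) with positive
# response. Two maxima inside one suppression window necessarily tie in
# value, so only exact ties need deduplication: within each tied group the
# lowest (z, y, x) voxel of a window is kept.
local_maxima_idx <- function(resp, k) {
  mx <- max_filter(resp, k)
  cand <- which(resp == mx & resp > 0, arr.ind = TRUE) # cols: z, y, x
  if (nrow(cand) <= 1) return(cand)
  vals <- resp[cand]
  tied <- vals %in% vals[duplicated(vals)]
  if (!any(tied)) return(cand)
  keep_tied <- rep(TRUE, sum(tied))
  tc <- cand[tied, , drop = FALSE]
  tv <- vals[tied]
  ord <- order(tv, tc[, 1], tc[, 2], tc[, 3])
  tc <- tc[ord, , drop = FALSE]
  tv <- tv[ord]
  for (i in seq_len(nrow(tc))[-1]) {
    j <- i - 1L
    while (j >= 1 && tv[j] == tv[i]) {
      if (keep_tied[j] &&
          abs(tc[j, 1] - tc[i, 1]) <= k &&
          abs(tc[j, 2] - tc[i, 2]) <= k &&
          abs(tc[j, 3] - tc[i, 3]) <= k) {
        keep_tied[i] <- FALSE
        break
      }
      j <- j - 1L
    }
  }
  rbind(cand[!tied, , drop = FALSE], tc[keep_tied, , drop = FALSE])
}

#' Automatic detection threshold from the response plateau
#'
#' Sweeps candidate thresholds logarithmically between the 90th percentile
#' and the maximum of the response, counts local maxima above each, and
#' returns the (geometric) midpoint of the longest run of candidates over
#' which the count is stable (relative change below 5% per step). A valid
#' plateau must span at least a factor 1.5 in threshold with a non-zero
#' count; volumes without such a plateau (e.g. pure noise) raise an error
#' asking for an absolute threshold.
#'
#' @param response Response volume from [blob_filter()].
#' @param min_separation_voxels Non-maximum-suppression radius used for the
#'   counts.
#' @param n_steps Number of candidate thresholds.
#' @return The calibrated threshold (a positive scalar).
#' @export
auto_threshold <- function(response, min_separation_voxels = 1, n_steps = 40) {
  hi <- max(response)
  if (!is.finite(hi) || hi <= 0) {
    abort("cannot calibrate: response has no positive values; supply an absolute threshold")
  }
  lo <- quantile(response, 0.90, names = FALSE)
  lo <- max(lo, 1e-9 * hi)
  if (lo >= hi) {
    abort("cannot calibrate: response has no dynamic range; supply an absolute threshold")
  }
  thr <- exp(seq(log(lo), log(hi), length.out = n_steps))
  peaks <- local_maxima_idx(response, min_separation_voxels)
  vals <- response[peaks]
  counts <- vapply(thr, function(t) sum(vals >= t), numeric(1))
  if (sum(counts > 0) < 3) {
    abort("cannot calibrate: fewer than 3 candidate thresholds with non-zero counts; supply an absolute threshold")
  }
  rel <- abs(diff(counts)) / pmax(counts[-length(counts)], 1)
  stable <- rel < 0.05 & counts[-length(counts)] > 0
  runs <- rle(stable)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  best <- NULL
  for (r in which(runs$values)) {
    s <- starts[r]
    e <- ends[r] + 1 # run of length L covers candidates s..(e)
    if (thr[e] / thr[s] < 1.5) next
    if (is.null(best) || (e - s) > (best[2] - best[1])) best <- c(s, e)
  }
  if (is.null(best)) {
    abort("cannot calibrate: no stable spot-count plateau found (is this pure noise?); supply an absolute threshold")
  }
  sqrt(thr[best[1]] * thr[best[2]])
}

#' Detect diffraction-limited spots in one channel
#'
#' Applies [blob_filter()], takes response local maxima above the threshold
#' (absolute, or auto-calibrated from the response plateau), refines each to
#' subpixel precision by an intensity-weighted centroid of the (positive)
#' response in a 3x3x3 window, and reports physical coordinates in nm.
#'
#' @param volume 3D numeric array `(z, y, x)`, or an `image_stack` together
#'   with `channel`.
#' @param voxel_size_nm Numeric `(z, y, x)` voxel size in nm (taken from the
#'   stack when `volume` is an `image_stack`).
#' @param params A [detection_params()].
#' @param channel Channel name: selects the volume from an `image_stack`
#'   and labels the output.
#' @return A tibble of spots sorted by decreasing quality, with columns
#'   `channel`, `z_nm`, `y_nm`, `x_nm`, `peak_intensity` (raw volume value
#'   at the maximum) and `quality` (response value). The threshold used is
#'   stored in the `threshold` attribute.
#' @export
detect_spots <- function(volume, voxel_size_nm = NULL,
                         params = detection_params(), channel = NA_character_) {
  if (inherits(volume, "image_stack")) {
    stopifnot(!is.na(channel), channel %in% names(volume$channels))
    voxel_size_nm <- volume$voxel_size_nm
    volume <- volume$channels[[channel]]
  }
  stopifnot(length(dim(volume)) == 3, !is.null(voxel_size_nm))
  empty <- tibble(
    channel = character(0), z_nm = numeric(0), y_nm = numeric(0),
    x_nm = numeric(0), peak_intensity = numeric(0), quality = numeric(0)
  )
  if (length(volume) == 0) return(empty)
  resp <- blob_filter(volume, params$sigma_nm, voxel_size_nm)
  thr <- if (identical(params$threshold, "auto")) {
    auto_threshold(resp, params$min_separation_voxels)
  } else {
    params$threshold
  }
  k <- params$min_separation_voxels
  peaks <- local_maxima_idx(resp, k)
  if (nrow(peaks) > 0) peaks <- peaks[resp[peaks] >= thr, , drop = FALSE]
  if (nrow(peaks) == 0) {
    out <- empty
    attr(out, "threshold") <- thr
    return(out)
  }
  dims <- dim(resp)
  pos <- matrix(NA_real_, nrow(peaks), 3)
  for (i in seq_len(nrow(peaks))) {
    ctr <- peaks[i, ]
    rng <- lapply(1:3, function(a) max(1, ctr[a] - 1):min(dims[a], ctr[a] + 1))
    w <- pmax(resp[rng[[1]], rng[[2]], rng[[3]], drop = FALSE], 0)
    if (sum(w) == 0) w[] <- 1
    for (a in 1:3) {
      marg <- apply(w, a, sum)
      pos[i, a] <- (sum(rng[[a]] * marg) / sum(marg) - 0.5) * voxel_size_nm[a]
    }
  }
  out <- tibble(
    channel = channel,
    z_nm = pos[, 1], y_nm = pos[, 2], x_nm = pos[, 3],
    peak_intensity = volume[peaks],
    quality = resp[peaks]
  ) |>
    arrange(dplyr::desc(.data$quality))
  attr(out, "threshold") <- thr
  out
}

#' Detect spots in several channels of a stack
#'
#' @param stack An `image_stack`.
#' @param channels Channel names to process (default: all but `DAPI`).
#' @param params A [detection_params()] shared across channels.
#' @return Named list of spot tibbles, one per channel.
#' @export
detect_stack <- function(stack, channels = setdiff(names(stack$channels), "DAPI"),
                         params = detection_params()) {
  stopifnot(inherits(stack, "image_stack"))
  purrr::map(
    rlang::set_names(channels),
    function(ch) detect_spots(stack, params = params, channel = ch)
  )
}
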