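# Synthetic circFISH scenes: cell geometry, molecule sampling with ground
# truth, and rendering to multi-channel z-stacks.

RNA_CLASSES <- c("linear", "circular", "fragment")

#' Generate non-overlapping elliptical nuclei and cell territories
#'
#' Nuclei are random rotated ellipses placed with rejection sampling so that
#' no two overlap; the cell territory of each nucleus is the nearest-nucleus
#' partition of the field (in the normalised ellipse metric), clipped to a
#' `dilation_factor`-fold dilation of the nucleus. Every nuclear pixel lies
#' inside its own cell territory by construction. Nuclei are placed with a
#' margin so territories do not touch the field border.
#'
#' @param config A [sim_config()].
#' @return An object of class `cell_label_map`: list with integer matrices
#'   `nuclear_labels` and `cell_labels` of shape `(n_y, n_x)` (background =
#'   0), the nucleus parameter table in `nuclei`, plus `field_shape` and
#'   `voxel_size_nm`.
#' @export
generate_cells <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_config_seed(config, 1L, generate_cells_impl(config))
}

generate_cells_impl <- function(config) {
  ny <- config$field_shape[2]
  nx <- config$field_shape[3]
  n <- config$n_cells
  ax <- config$nucleus_axes_px
  margin <- ceiling(config$dilation_factor * ax[2]) + 2

  if (2 * margin >= min(ny, nx)) {
    abort("field too small to place nuclei: increase field_shape or shrink nucleus_axes_px")
  }

  nuclei <- tibble(
    cell_id = integer(0), cy = numeric(0), cx = numeric(0),
    a = numeric(0), b = numeric(0), theta = numeric(0)
  )
  tries <- 0L
  max_tries <- 500L * n
  while (nrow(nuclei) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      abort(sprintf(
        "could not place %d non-overlapping nuclei after %d attempts; use a larger field",
        n, max_tries
      ))
    }
    a <- runif(1, ax[1], ax[2])
    b <- runif(1, ax[1], ax[2])
    cy <- runif(1, margin, ny - margin)
    cx <- runif(1, margin, nx - margin)
    r <- max(a, b)
    if (nrow(nuclei) > 0) {
      d <- sqrt((nuclei$cy - cy)^2 + (nuclei$cx - cx)^2)
      if (any(d <= r + pmax(nuclei$a, nuclei$b) + 2)) next
    }
    nuclei <- bind_rows(nuclei, tibble(
      cell_id = nrow(nuclei) + 1L, cy = cy, cx = cx, a = a, b = b,
      theta = runif(1, 0, pi)
    ))
  }

  dmin <- matrix(Inf, ny, nx)
  lab <- matrix(0L, ny, nx)
  for (i in seq_len(n)) {
    p <- nuclei[i, ]
    R <- ceiling(config$dilation_factor * max(p$a, p$b)) + 1
    ys <- max(1, floor(p$cy - R)):min(ny, ceiling(p$cy + R))
    xs <- max(1, floor(p$cx - R)):min(nx, ceiling(p$cx + R))
    dy <- outer(ys - p$cy, rep(1, length(xs)))
    dx <- outer(rep(1, length(ys)), xs - p$cx)
    u <- cos(p$theta) * dx + sin(p$theta) * dy
    v <- -sin(p$theta) * dx + cos(p$theta) * dy
    m <- sqrt((u / p$a)^2 + (v / p$b)^2)
    sub_d <- dmin[ys, xs]
    take <- m < sub_d
    sub_d[take] <- m[take]
    dmin[ys, xs] <- sub_d
    sub_l <- lab[ys, xs]
    sub_l[take] <- i
    lab[ys, xs] <- sub_l
  }

  nuclear <- lab
  nuclear[dmin > 1] <- 0L
  cells <- lab
  cells[dmin > config$dilation_factor] <- 0L

  structure(
    list(
      nuclear_labels = nuclear,
      cell_labels = cells,
      nuclei = nuclei,
      field_shape = config$field_shape,
      voxel_size_nm = config$voxel_size_nm
    ),
    class = "cell_label_map"
  )
}

#' @export
print.cell_label_map <- function(x, ...) {
  cat(sprintf(
    "<cell_label_map> %d x %d px, %d cell(s)\n",
    nrow(x$cell_labels), ncol(x$cell_labels),
    length(setdiff(unique(as.vector(x$cell_labels)), 0L))
  ))
  invisible(x)
}

#' Sample molecules with exact ground truth
#'
#' Per cell and RNA class, the molecule count is Poisson with the configured
#' mean (negative binomial when `dispersion` is set). Each molecule is
#' nuclear with probability `nuclear_fraction[class]`, placed uniformly over
#' the corresponding 2D compartment of its cell with z uniform over the
#' stack depth. When `min_separation_nm > 0`, placements closer than that to
#' an already placed molecule of the same cell are rejected (bounded
#' retries).
#'
#' @param config A [sim_config()].
#' @param maps A `cell_label_map` from [generate_cells()].
#' @return An object of class `ground_truth`: list with the `molecules`
#'   tibble (`molecule_id`, `cell_id`, `rna_class`, `z_nm`, `y_nm`, `x_nm`,
#'   `compartment`), the label `maps` and the `config`.
#' @export
sample_molecules <- function(config, maps) {
  stopifnot(inherits(config, "sim_config"), inherits(maps, "cell_label_map"))
  with_config_seed(config, 2L, sample_molecules_impl(config, maps))
}

sample_molecules_impl <- function(config, maps) {
  ny <- nrow(maps$cell_labels)
  vz <- config$voxel_size_nm[1]
  vy <- config$voxel_size_nm[2]
  vx <- config$voxel_size_nm[3]
  depth_nm <- config$field_shape[1] * vz
  cell_ids <- sort(setdiff(unique(as.vector(maps$cell_labels)), 0L))

  in_cell <- maps$cell_labels != 0L
  idx_all <- which(in_cell)
  pool_cell <- split(idx_all, maps$cell_labels[idx_all])
  is_nuc <- maps$nuclear_labels != 0L

  rows <- list()
  for (cid in cell_ids) {
    px <- pool_cell[[as.character(cid)]]
    nuc_px <- px[is_nuc[px]]
    cyt_px <- px[!is_nuc[px]]
    placed <- NULL
    for (cls in RNA_CLASSES) {
      mu <- config$mean_counts[[cls]]
      if (mu <= 0) next
      n <- if (is.null(config$dispersion)) {
        rpois(1, mu)
      } else {
        rnbinom(1, size = config$dispersion, mu = mu)
      }
      if (n == 0) next
      nuclear <- runif(n) < config$nuclear_fraction[[cls]]
      # nuclear draw falls back to cytoplasm if a compartment is empty
      if (length(nuc_px) == 0) nuclear[] <- FALSE
      if (length(cyt_px) == 0) nuclear[] <- TRUE
      pos <- matrix(NA_real_, n, 3)
      for (k in seq_len(n)) {
        pool <- if (nuclear[k]) nuc_px else cyt_px
        ok <- FALSE
        for (try in 1:200) {
          i <- pool[sample.int(length(pool), 1)]
          py <- ((i - 1) %% ny) + 1
          pxx <- ((i - 1) %/% ny) + 1
          cand <- c(runif(1, 0, depth_nm),
                    (py - 1 + runif(1)) * vy,
                    (pxx - 1 + runif(1)) * vx)
          if (config$min_separation_nm > 0 && !is.null(placed) && nrow(placed) > 0) {
            d2 <- (placed[, 1] - cand[1])^2 + (placed[, 2] - cand[2])^2 +
              (placed[, 3] - cand[3])^2
            if (min(d2) < config$min_separation_nm^2) next
          }
          pos[k, ] <- cand
          ok <- TRUE
          break
        }
        if (!ok) {
          abort("could not satisfy min_separation_nm after 200 retries; lower the density or the separation")
        }
        placed <- rbind(placed, pos[k, , drop = FALSE])
      }
      rows[[length(rows) + 1]] <- tibble(
        cell_id = cid,
        rna_class = cls,
        z_nm = pos[, 1], y_nm = pos[, 2], x_nm = pos[, 3],
        compartment = ifelse(nuclear, "nuclear", "cytoplasmic")
      )
    }
  }

  molecules <- if (length(rows)) bind_rows(rows) else tibble(
    cell_id = integer(0), rna_class = character(0),
    z_nm = numeric(0), y_nm = numeric(0), x_nm = numeric(0),
    compartment = character(0)
  )
  molecules <- mutate(molecules, molecule_id = row_number(), .before = 1)
  new_ground_truth(molecules, maps, config)
}

new_ground_truth <- function(molecules, maps, config) {
  structure(list(molecules = molecules, maps = maps, config = config),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  counts <- table(factor(x$molecules$rna_class, RNA_CLASSES))
  cat(sprintf(
    "<ground_truth> %d molecules (linear %d / circular %d / fragment %d) in %d cell(s)\n",
    nrow(x$molecules), counts["linear"], counts["circular"], counts["fragment"],
    length(unique(x$molecules$cell_id))
  ))
  invisible(x)
}

#' Ground truth with molecules scattered uniformly over the field
#'
#' A cell-free scene for detector benchmarking: molecules of each class are
#' placed uniformly in the field (within `margin_nm` of the borders, with an
#' optional minimum pairwise separation). `cell_id` and `compartment` are
#' `NA`.
#'
#' @param n_per_class Named integer vector over
#'   `c("linear", "circular", "fragment")` (missing classes = 0).
#' @param config A [sim_config()].
#' @param min_separation_nm Minimum pairwise 3D distance (0 = none).
#' @param margin_nm Numeric `(z, xy)` placement margin from the volume
#'   borders, in nm.
#' @return A `ground_truth` object.
#' @export
uniform_ground_truth <- function(n_per_class, config,
                                 min_separation_nm = 0,
                                 margin_nm = c(z = 0, xy = 0)) {
  stopifnot(inherits(config, "sim_config"))
  extent <- config$field_shape * config$voxel_size_nm
  lo <- c(margin_nm[["z"]], margin_nm[["xy"]], margin_nm[["xy"]])
  hi <- extent - lo
  stopifnot(all(hi > lo))
  cls <- rep(RNA_CLASSES, times = vapply(
    RNA_CLASSES, function(k) as.integer(n_per_class[k] %||% 0L) %|NA|% 0L,
    integer(1)
  ))
  n <- length(cls)
  pos <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    for (try in 1:500) {
      cand <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]), runif(1, lo[3], hi[3]))
      if (min_separation_nm > 0 && k > 1) {
        prev <- pos[seq_len(k - 1), , drop = FALSE]
        d2 <- (prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 + (prev[, 3] - cand[3])^2
        if (min(d2) < min_separation_nm^2) next
      }
      pos[k, ] <- cand
      break
    }
    if (anyNA(pos[k, ])) abort("could not satisfy min_separation_nm; lower n or the separation")
  }
  molecules <- tibble(
    molecule_id = seq_len(n), cell_id = NA_integer_, rna_class = cls,
    z_nm = pos[, 1], y_nm = pos[, 2], x_nm = pos[, 3],
    compartment = NA_character_
  )
  maps <- structure(
    list(
      nuclear_labels = matrix(0L, config$field_shape[2], config$field_shape[3]),
      cell_labels = matrix(0L, config$field_shape[2], config$field_shape[3]),
      nuclei = tibble(), field_shape = config$field_shape,
      voxel_size_nm = config$voxel_size_nm
    ),
    class = "cell_label_map"
  )
  new_ground_truth(molecules, maps, config)
}

`%|NA|%` <- function(x, y) ifelse(is.na(x), y, x)

#' Render a ground truth to a multi-channel z-stack
#'
#' Each molecule contributes an anisotropic 3D Gaussian (the PSF model of a
#' diffraction-limited emitter) with peak `spot_amplitude`. Linear molecules
#' emit in both PL and PC (the full-length transcript carries both probe
#' sets); circular molecules emit only in PC; fragments only in PL. The PC
#' rendering of every molecule is offset by a per-molecule registration
#' jitter `~ Normal(0, registration_sd_nm)` per axis, modelling channel
#' registration error. DAPI is the nuclear mask extruded through z. With
#' `noise = TRUE`, Poisson shot noise is applied to signal + background and
#' Gaussian read noise added, clipped at 0.
#'
#' @param ground_truth A `ground_truth` object.
#' @param config A [sim_config()]; defaults to the one inside the ground
#'   truth.
#' @param noise Apply Poisson + read noise?
#' @return An object of class `image_stack`: list with named 3D arrays
#'   (`(z, y, x)`) in `channels` (`PL`, `PC`, `DAPI`) and `voxel_size_nm`.
#' @export
render <- function(ground_truth, config = ground_truth$config, noise = TRUE) {
  stopifnot(inherits(ground_truth, "ground_truth"), inherits(config, "sim_config"))
  with_config_seed(config, 3L, render_impl(ground_truth, config, noise))
}

render_impl <- function(ground_truth, config, noise) {
  dims <- config$field_shape
  vox <- config$voxel_size_nm
  sigma <- c(config$psf_sigma_nm[["z"]], config$psf_sigma_nm[["xy"]],
             config$psf_sigma_nm[["xy"]])
  chan <- list(
    PL = array(0, dims),
    PC = array(0, dims),
    DAPI = array(0, dims)
  )
  mol <- ground_truth$molecules
  if (nrow(mol) > 0) {
    jitter <- matrix(rnorm(3 * nrow(mol), 0, config$registration_sd_nm),
                     ncol = 3)
    for (k in seq_len(nrow(mol))) {
      p <- c(mol$z_nm[k], mol$y_nm[k], mol$x_nm[k])
      cls <- mol$rna_class[k]
      if (cls %in% c("linear", "fragment")) {
        chan$PL <- add_gaussian_spot(chan$PL, p, config$spot_amplitude, sigma, vox)
      }
      if (cls %in% c("linear", "circular")) {
        chan$PC <- add_gaussian_spot(chan$PC, p + jitter[k, ],
                                     config$spot_amplitude, sigma, vox)
      }
    }
  }
  nuc <- ground_truth$maps$nuclear_labels != 0L
  dapi_plane <- matrix(0, dims[2], dims[3])
  dapi_plane[nuc] <- config$dapi_amplitude
  for (z in seq_len(dims[1])) chan$DAPI[z, , ] <- dapi_plane

  for (nm in names(chan)) {
    signal <- chan[[nm]] + config$background_level
    if (noise) {
      v <- rpois(length(signal), lambda = as.vector(signal)) +
        rnorm(length(signal), 0, config$read_noise_sd)
      signal <- array(pmax(v, 0), dims)
    }
    chan[[nm]] <- signal
  }
  structure(list(channels = chan, voxel_size_nm = vox), class = "image_stack")
}

# add one anisotropic Gaussian (peak = amp) to a (z,y,x) volume; voxel
# centres sit at (i - 0.5) * voxel_size for 1-based index i
add_gaussian_spot <- function(vol, pos_nm, amp, sigma_nm, voxel_nm,
                              extent_sigmas = 4) {
  dims <- dim(vol)
  idx <- vector("list", 3)
  g <- vector("list", 3)
  for (a in 1:3) {
    c0 <- pos_nm[a] / voxel_nm[a] + 0.5 # fractional 1-based index of centre
    half <- ceiling(extent_sigmas * sigma_nm[a] / voxel_nm[a])
    rng <- max(1, floor(c0 - half)):min(dims[a], ceiling(c0 + half))
    if (length(rng) == 0) return(vol)
    centers <- (rng - 0.5) * voxel_nm[a]
    idx[[a]] <- rng
    g[[a]] <- exp(-((centers - pos_nm[a])^2) / (2 * sigma_nm[a]^2))
  }
  block <- amp * (g[[1]] %o% g[[2]] %o% g[[3]])
  vol[idx[[1]], idx[[2]], idx[[3]]] <-
    vol[idx[[1]], idx[[2]], idx[[3]]] + block
  vol
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_stack> channels %s, %d x %d x %d voxels (%g/%g/%g nm)\n",
              paste(names(x$channels), collapse = "/"),
              d[1], d[2], d[3],
              x$voxel_size_nm[1], x$voxel_size_nm[2], x$voxel_size_nm[3]))
  invisible(x)
}

#' Idealised spot tables from a ground truth
#'
#' Skips the rendering/detection round trip and emits the spot positions a
#' perfect detector would report: linear molecules give one PL and one PC
#' spot (the PC copy offset by registration jitter), circular molecules a PC
#' spot, fragments a PL spot; an optional isotropic localisation error is
#' added per spot. Used for large-replicate classification studies where
#' rendering every stack would dominate runtime.
#'
#' @param ground_truth A `ground_truth`.
#' @param config A [sim_config()] (for the registration jitter SD).
#' @param localization_sd_nm Per-axis localisation error SD in nm.
#' @return Named list of spot tibbles (`PL`, `PC`) with columns `channel`,
#'   `z_nm`, `y_nm`, `x_nm`, `peak_intensity`, `quality`, `molecule_id`,
#'   `rna_class`.
#' @export
simulate_spot_tables <- function(ground_truth, config = ground_truth$config,
                                 localization_sd_nm = 0) {
  mol <- ground_truth$molecules
  mk <- function(df, channel, jitter_sd) {
    n <- nrow(df)
    noise <- function(sd) if (sd > 0) rnorm(n, 0, sd) else rep(0, n)
    tibble(
      channel = channel,
      z_nm = df$z_nm + noise(jitter_sd) + noise(localization_sd_nm),
      y_nm = df$y_nm + noise(jitter_sd) + noise(localization_sd_nm),
      x_nm = df$x_nm + noise(jitter_sd) + noise(localization_sd_nm),
      peak_intensity = config$spot_amplitude,
      quality = 1,
      molecule_id = df$molecule_id,
      rna_class = df$rna_class
    )
  }
  list(
    PL = mk(filter(mol, .data$rna_class %in% c("linear", "fragment")), "PL", 0),
    PC = mk(filter(mol, .data$rna_class %in% c("linear", "circular")), "PC",
            config$registration_sd_nm)
  )
}

#' In-situ RNase R digestion of a ground truth
#'
#' RNase R is a processive exoribonuclease that degrades linear RNA from its
#' free end but cannot engage the closed circle, so linear molecules and
#' fragments decay quickly while circular molecules persist (prolonged
#' exposure does erode circles too, hence the finite circular half-life).
#' Each molecule of class `c` survives independently with probability
#' `2^(-t / half_life(c))`; fragments decay with the linear half-life. With
#' a fixed `seed` the survivor sets are nested across increasing `t_hours`
#' (the same uniform draws drive every timepoint).
#'
#' @param ground_truth A `ground_truth`.
#' @param t_hours Digestion time in hours (>= 0).
#' @param linear_half_life_h,circular_half_life_h Exponential-decay
#'   half-lives (hours); circular >> linear by default.
#' @param seed Optional integer seed for the survival draws.
#' @return A `ground_truth` containing the surviving molecules.
#' @export
apply_rnase_r <- function(ground_truth, t_hours,
                          linear_half_life_h = 1, circular_half_life_h = 48,
                          seed = NULL) {
  stopifnot(inherits(ground_truth, "ground_truth"))
  if (t_hours < 0) abort("t_hours must be >= 0")
  stopifnot(linear_half_life_h > 0, circular_half_life_h > 0)
  half_life <- c(linear = linear_half_life_h, circular = circular_half_life_h,
                 fragment = linear_half_life_h)
  mol <- ground_truth$molecules
  draws <- if (is.null(seed)) runif(nrow(mol)) else {
    withr::with_seed(seed, runif(nrow(mol)))
  }
  p <- 2^(-t_hours / half_life[mol$rna_class])
  keep <- draws < p
  new_ground_truth(mol[keep, , drop = FALSE], ground_truth$maps,
                   ground_truth$config)
}

#' shRNA knockdown of one RNA class
#'
#' An shRNA against the back-splice junction depletes only the circular
#' isoform (or, against a linear-only exon junction, only the linear
#' isoform). Molecules of `target_class` survive with probability
#' `1 - efficiency`; all other classes are untouched.
#'
#' @param ground_truth A `ground_truth`.
#' @param target_class `"linear"` or `"circular"`.
#' @param efficiency Knockdown efficiency in `[0, 1]`.
#' @param seed Optional integer seed for the survival draws.
#' @return A `ground_truth` containing the surviving molecules.
#' @export
apply_knockdown <- function(ground_truth, target_class = c("circular", "linear"),
                            efficiency, seed = NULL) {
  stopifnot(inherits(ground_truth, "ground_truth"))
  target_class <- match.arg(target_class)
  stopifnot(efficiency >= 0, efficiency <= 1)
  mol <- ground_truth$molecules
  draws <- if (is.null(seed)) runif(nrow(mol)) else {
    withr::with_seed(seed, runif(nrow(mol)))
  }
  keep <- mol$rna_class != target_class | draws < (1 - efficiency)
  new_ground_truth(mol[keep, , drop = FALSE], ground_truth$maps,
                   ground_truth$config)
}

#' Simulate a complete scene
#'
#' Convenience wrapper: [generate_cells()], [sample_molecules()] and
#' (optionally) [render()] in one call.
#'
#' @param config A [sim_config()].
#' @param render_stack Also render the image stack?
#' @param noise Passed to [render()].
#' @return List with `maps`, `ground_truth` and (when requested) `stack`.
#' @export
simulate_scene <- function(config, render_stack = TRUE, noise = TRUE) {
  maps <- generate_cells(config)
  gt <- sample_molecules(config, maps)
  out <- list(maps = maps, ground_truth = gt)
  if (render_stack) out$stack <- render(gt, config, noise = noise)
  out
}
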