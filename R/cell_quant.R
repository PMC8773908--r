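# Per-cell quantification: DAPI nuclear segmentation, spot-to-cell
# assignment, per-cell class counts, condition summaries with 95% CIs and
# Student's t-test comparisons, and nuclear/cytoplasmic fractions.

#' Segment nuclei from a DAPI channel
#'
#' Max-projects the DAPI stack over z, Gaussian-smooths, thresholds with
#' Otsu's method, fills holes, removes small objects, and splits touching
#' nuclei by watershed on the distance transform. Cell territories are then
#' grown from the nuclei over a fixed-radius dilation of the nuclear mask
#' (a nearest-nucleus partition), standing in for an unavailable membrane
#' stain.
#'
#' @param dapi 3D array `(z, y, x)`, a 2D matrix `(y, x)`, or an
#'   `image_stack` with a `DAPI` channel.
#' @param smooth_sigma_px Gaussian smoothing sigma in pixels.
#' @param min_area_px Minimum nuclear area; smaller objects are dropped.
#' @param dilation_px Radius (pixels) of the nuclear dilation bounding the
#'   cell territories.
#' @param watershed_tolerance Minimum distance-map depth between two object
#'   maxima for them to be split (passed to [EBImage::watershed()]).
#' @param voxel_size_nm Recorded in the result for downstream conversions.
#' @return A `cell_label_map` (integer `nuclear_labels` and `cell_labels`
#'   matrices sharing label ids; background = 0).
#' @export
segment_nuclei <- function(dapi, smooth_sigma_px = 1, min_area_px = 60,
                           dilation_px = 25, watershed_tolerance = 2,
                           voxel_size_nm = c(200, 130, 130)) {
  if (inherits(dapi, "image_stack")) {
    if (!"DAPI" %in% names(dapi$channels)) {
      abort("stack has no 'DAPI' channel; nuclear segmentation needs one")
    }
    voxel_size_nm <- dapi$voxel_size_nm
    dapi <- dapi$channels[["DAPI"]]
  }
  proj <- if (length(dim(dapi)) == 3) apply(dapi, c(2, 3), max) else dapi
  rng <- range(proj)
  if (diff(rng) <= 0) abort("zero nuclei found: DAPI image is constant")
  norm <- (proj - rng[1]) / diff(rng)
  sm <- EBImage::gblur(norm, sigma = smooth_sigma_px)
  sm <- (sm - min(sm)) / max(diff(range(sm)), .Machine$double.eps)
  mask <- sm > EBImage::otsu(EBImage::Image(sm))
  mask <- EBImage::fillHull(mask)
  labels <- EBImage::watershed(EBImage::distmap(mask),
                               tolerance = watershed_tolerance, ext = 1)
  labels <- EBImage::imageData(labels)
  sizes <- table(labels[labels > 0])
  keep <- as.integer(names(sizes)[sizes >= min_area_px])
  if (length(keep) == 0) abort("zero nuclei found after size filtering")
  relabel <- integer(max(labels) + 1L)
  relabel[keep + 1L] <- seq_along(keep)
  nuclear <- matrix(relabel[labels + 1L], nrow(labels), ncol(labels))

  brush_size <- 2L * as.integer(dilation_px) + 1L
  territory_mask <- EBImage::dilate(nuclear > 0, EBImage::makeBrush(brush_size, "disc"))
  cells <- EBImage::propagate(
    EBImage::Image(matrix(0, nrow(nuclear), ncol(nuclear))),
    seeds = EBImage::Image(nuclear),
    mask = territory_mask, lambda = 1e-2
  )
  cells <- matrix(as.integer(EBImage::imageData(cells)), nrow(nuclear), ncol(nuclear))

  structure(
    list(
      nuclear_labels = nuclear, cell_labels = cells, nuclei = NULL,
      field_shape = c(NA_integer_, nrow(nuclear), ncol(nuclear)),
      voxel_size_nm = voxel_size_nm
    ),
    class = "cell_label_map"
  )
}

#' Assign spots to cells and compartments
#'
#' Each spot receives the cell label at its (y, x) pixel and the compartment
#' `nuclear` or `cytoplasmic` from the nuclear mask there (a 2D call, on the
#' max-projected masks). Spots over background are flagged unassigned and
#' excluded from per-cell statistics downstream.
#'
#' @param spots A tibble with `y_nm`, `x_nm` columns ([classify_spots()]
#'   output or any spot table).
#' @param maps A `cell_label_map`.
#' @param voxel_size_nm Numeric `(z, y, x)` used to convert nm to pixels;
#'   defaults to the one recorded in `maps`.
#' @return `spots` with added columns `cell_id` (`NA` on background),
#'   `compartment` and `assigned`.
#' @export
assign_spots <- function(spots, maps, voxel_size_nm = maps$voxel_size_nm) {
  stopifnot(inherits(maps, "cell_label_map"))
  ny <- nrow(maps$cell_labels)
  nx <- ncol(maps$cell_labels)
  py <- pmin(pmax(floor(spots$y_nm / voxel_size_nm[2]) + 1L, 1L), ny)
  px <- pmin(pmax(floor(spots$x_nm / voxel_size_nm[3]) + 1L, 1L), nx)
  lin <- py + (px - 1L) * ny
  cell <- maps$cell_labels[lin]
  nuc <- maps$nuclear_labels[lin]
  spots |>
    mutate(
      cell_id = dplyr::if_else(cell > 0L, as.integer(cell), NA_integer_),
      compartment = dplyr::if_else(nuc > 0L, "nuclear", "cytoplasmic"),
      assigned = cell > 0L
    )
}

#' Per-cell class counts
#'
#' Tallies assigned spots per cell and RNA class, split by compartment.
#' Every labelled cell appears, including zero-count cells; unassigned
#' spots are excluded. Cells whose territory touches the image border can
#' be excluded (they are partially observed).
#'
#' @param spots A tibble with columns `class`, `cell_id`, `compartment`
#'   (e.g. [assign_spots()] output, or [molecules_as_spots()] for ground
#'   truth).
#' @param maps Optional `cell_label_map` supplying the full set of cell ids
#'   (and border information); when absent, ids observed in `spots` are
#'   used.
#' @param exclude_border Drop cells touching the image border (needs
#'   `maps`)?
#' @param classes Class levels to tally.
#' @return A tibble with one row per cell x class: `cell_id`, `class`, `n`,
#'   `n_nuclear`, `nuclear_fraction` (`NA` when `n` is 0).
#' @export
per_cell_counts <- function(spots, maps = NULL, exclude_border = TRUE,
                            classes = c("linear", "circular", "fragment")) {
  stopifnot(all(c("class", "cell_id", "compartment") %in% names(spots)))
  spots <- filter(spots, !is.na(.data$cell_id))
  ids <- if (!is.null(maps)) {
    sort(setdiff(unique(as.vector(maps$cell_labels)), 0L))
  } else {
    sort(unique(spots$cell_id))
  }
  if (!is.null(maps) && exclude_border) {
    m <- maps$cell_labels
    border <- unique(c(m[1, ], m[nrow(m), ], m[, 1], m[, ncol(m)]))
    ids <- setdiff(ids, border)
    spots <- filter(spots, .data$cell_id %in% ids)
  }
  tallied <- spots |>
    filter(.data$class %in% classes) |>
    group_by(.data$cell_id, .data$class) |>
    summarise(
      n = n(),
      n_nuclear = sum(.data$compartment == "nuclear"),
      .groups = "drop"
    )
  grid <- tidyr::expand_grid(
    cell_id = as.integer(ids),
    class = factor(classes, levels = classes)
  ) |>
    mutate(class = as.character(.data$class))
  grid |>
    left_join(tallied, by = c("cell_id", "class")) |>
    mutate(
      n = tidyr::replace_na(.data$n, 0L),
      n_nuclear = tidyr::replace_na(.data$n_nuclear, 0L),
      nuclear_fraction = dplyr::if_else(.data$n > 0, .data$n_nuclear / .data$n,
                                        NA_real_)
    )
}

#' Ground-truth molecules as an assigned spot table
#'
#' Reshapes a `ground_truth` molecule table to the column contract of
#' [per_cell_counts()], bypassing imaging: `rna_class` becomes `class` and
#' every molecule is assigned to its true cell and compartment.
#'
#' @param ground_truth A `ground_truth`.
#' @return A tibble with `class`, `cell_id`, `compartment` and position
#'   columns.
#' @export
molecules_as_spots <- function(ground_truth) {
  ground_truth$molecules |>
    mutate(class = .data$rna_class, assigned = !is.na(.data$cell_id)) |>
    dplyr::select("class", "cell_id", "compartment", "z_nm", "y_nm", "x_nm",
                  "assigned")
}

star_code <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Summarise per-cell counts across conditions
#'
#' Per condition and class: mean molecules per cell with a 95% confidence
#' interval (normal approximation, `1.96 * SD / sqrt(n)`). Conditions are
#' compared pairwise per class with a two-sided two-sample Student's t-test
#' (pooled variance), annotated with the conventional star codes
#' (`***` p < 0.001, `*` p < 0.05, `ns` otherwise).
#'
#' @param counts Per-cell counts as from [per_cell_counts()], with an added
#'   `condition` column (see [bind_conditions()]).
#' @param min_cells Minimum recommended cells per condition; fewer draws a
#'   warning (averages over too few cells are unstable).
#' @return An object of class `circfish_summary` with components `stats`
#'   (tibble: condition, class, n_cells, mean_per_cell, sd, ci95_halfwidth)
#'   and `comparisons` (tibble: class, condition_a, condition_b, t_statistic,
#'   df, p_value, stars). Use [tidy()] / [glance()] to extract.
#' @export
summarize_conditions <- function(counts, min_cells = 100) {
  stopifnot(all(c("condition", "cell_id", "class", "n") %in% names(counts)))
  stats <- counts |>
    group_by(.data$condition, .data$class) |>
    summarise(
      n_cells = dplyr::n_distinct(.data$cell_id),
      mean_per_cell = mean(.data$n),
      sd = sd(.data$n),
      .groups = "drop"
    ) |>
    mutate(ci95_halfwidth = 1.96 * .data$sd / sqrt(.data$n_cells))

  small <- stats |>
    dplyr::distinct(.data$condition, .data$n_cells) |>
    filter(.data$n_cells < min_cells)
  if (nrow(small) > 0) {
    warn(sprintf(
      "condition(s) with fewer than %d cells: %s",
      min_cells,
      paste(sprintf("%s (%d)", small$condition, small$n_cells), collapse = ", ")
    ), class = "circfish_few_cells")
  }

  conditions <- unique(counts$condition)
  comparisons <- list()
  if (length(conditions) >= 2) {
    pairs <- utils::combn(conditions, 2, simplify = FALSE)
    for (pr in pairs) {
      for (cls in unique(counts$class)) {
        a <- counts$n[counts$condition == pr[1] & counts$class == cls]
        b <- counts$n[counts$condition == pr[2] & counts$class == cls]
        if (length(a) < 2 || length(b) < 2) {
          warn(sprintf(
            "t-test skipped for class '%s' (%s vs %s): a condition has fewer than 2 cells",
            cls, pr[1], pr[2]
          ), class = "circfish_ttest_skipped")
          next
        }
        tt <- if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
          # degenerate identical samples: t.test errors on zero variance
          list(statistic = 0, parameter = length(a) + length(b) - 2, p.value = 1)
        } else {
          t.test(a, b, var.equal = TRUE)
        }
        comparisons[[length(comparisons) + 1]] <- tibble(
          class = cls, condition_a = pr[1], condition_b = pr[2],
          t_statistic = unname(tt$statistic), df = unname(tt$parameter),
          p_value = tt$p.value, stars = star_code(tt$p.value)
        )
      }
    }
  }
  comparisons <- if (length(comparisons)) bind_rows(comparisons) else tibble(
    class = character(0), condition_a = character(0), condition_b = character(0),
    t_statistic = numeric(0), df = numeric(0), p_value = numeric(0),
    stars = character(0)
  )
  structure(
    list(stats = stats, comparisons = comparisons, min_cells = min_cells),
    class = "circfish_summary"
  )
}

#' Combine per-cell counts from several conditions
#'
#' @param ... Named per-cell count tibbles (names become the `condition`
#'   column), or a single named list.
#' @return One tibble with a `condition` column.
#' @export
bind_conditions <- function(...) {
  lst <- list(...)
  if (length(lst) == 1 && is.list(lst[[1]]) && !is.data.frame(lst[[1]])) {
    lst <- lst[[1]]
  }
  stopifnot(!is.null(names(lst)), all(names(lst) != ""))
  bind_rows(purrr::imap(lst, function(df, nm) mutate(df, condition = nm))) |>
    dplyr::relocate("condition")
}

#' @export
print.circfish_summary <- function(x, ...) {
  cat("<circfish_summary>\n")
  print(x$stats, ...)
  if (nrow(x$comparisons)) {
    cat("comparisons:\n")
    print(x$comparisons, ...)
  }
  invisible(x)
}

#' @describeIn summarize_conditions Tidy the summary: per-condition stats
#'   (`type = "stats"`, default) or pairwise comparisons
#'   (`type = "comparisons"`).
#' @param x A `circfish_summary`.
#' @param type Which component to return.
#' @param ... Unused.
#' @method tidy circfish_summary
#' @export
tidy.circfish_summary <- function(x, type = c("stats", "comparisons"), ...) {
  switch(match.arg(type), stats = x$stats, comparisons = x$comparisons)
}

#' @describeIn summarize_conditions One-row overview of the summary.
#' @method glance circfish_summary
#' @export
glance.circfish_summary <- function(x, ...) {
  tibble(
    n_conditions = dplyr::n_distinct(x$stats$condition),
    n_classes = dplyr::n_distinct(x$stats$class),
    total_cells = sum(dplyr::distinct(x$stats, .data$condition, .data$n_cells)$n_cells),
    n_comparisons = nrow(x$comparisons),
    n_significant = sum(x$comparisons$stars %in% c("*", "***"))
  )
}

#' Nuclear/cytoplasmic localisation fractions per class
#'
#' Mean over cells of the per-cell nuclear fraction (cells with zero
#' molecules of a class carry no information about its localisation and are
#' excluded), with a 95% CI (`1.96 * SD / sqrt(n)`); the cytoplasmic
#' fraction is its complement. A class absent from every cell is reported
#' as `NA` (undefined).
#'
#' @param counts Per-cell counts from [per_cell_counts()], optionally with a
#'   `condition` column (fractions are then computed per condition).
#' @return A tibble: (`condition`,) `class`, `n_cells`,
#'   `nuclear_fraction`, `ci95_halfwidth`, `cytoplasmic_fraction`.
#' @export
localization_fractions <- function(counts) {
  grouping <- intersect(c("condition", "class"), names(counts))
  levels <- dplyr::distinct(counts, across(all_of(grouping)))
  stats <- counts |>
    filter(.data$n > 0) |>
    group_by(across(all_of(grouping))) |>
    summarise(
      n_cells = n(),
      nf_mean = mean(.data$nuclear_fraction),
      nf_sd = sd(.data$nuclear_fraction),
      .groups = "drop"
    )
  levels |>
    left_join(stats, by = grouping) |>
    mutate(
      n_cells = tidyr::replace_na(.data$n_cells, 0L),
      nuclear_fraction = .data$nf_mean,
      ci95_halfwidth = dplyr::if_else(
        .data$n_cells > 1, 1.96 * .data$nf_sd / sqrt(.data$n_cells), NA_real_
      ),
      cytoplasmic_fraction = 1 - .data$nuclear_fraction
    ) |>
    dplyr::select(all_of(grouping), "n_cells", "nuclear_fraction",
                  "ci95_halfwidth", "cytoplasmic_fraction")
}
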