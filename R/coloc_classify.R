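# Two-channel colocalization: match PL and PC spots within a physical
# radius and classify every spot as full-length linear RNA (colocalized),
# circular RNA (PC-only) or linear fragment (PL-only).

#' Match PL and PC spots within a physical radius
#'
#' Enumerates all cross-channel pairs with 3D Euclidean distance (in nm) at
#' most `radius_nm` (inclusive), sorts them by increasing distance (ties by
#' lower PL index, then lower PC index) and greedily accepts pairs whose
#' endpoints are both still unmatched, yielding a deterministic one-to-one
#' matching. With `one_to_one = FALSE`, each spot is instead paired with its
#' nearest in-radius counterpart regardless of whether that counterpart is
#' claimed by others (many-to-one).
#'
#' @param pl_spots,pc_spots Spot tibbles with columns `z_nm`, `y_nm`,
#'   `x_nm` (e.g. from [detect_spots()]).
#' @param radius_nm Colocalization radius in nm (default 250, the
#'   counterpart rule of the method).
#' @param one_to_one Enforce a one-to-one matching (default)?
#' @param in_plane Use 2D (y, x) distances instead of 3D?
#' @return An object of class `match_result`: list with `pairs` (tibble
#'   `pl`, `pc`, `distance_nm`), `unmatched_pl`, `unmatched_pc` (integer row
#'   indices into the inputs) and `radius_nm`.
#' @export
match_spots <- function(pl_spots, pc_spots, radius_nm = 250,
                        one_to_one = TRUE, in_plane = FALSE) {
  stopifnot(radius_nm >= 0)
  n_pl <- nrow(pl_spots)
  n_pc <- nrow(pc_spots)
  empty <- tibble(pl = integer(0), pc = integer(0), distance_nm = numeric(0))
  if (n_pl == 0 || n_pc == 0) {
    return(new_match_result(empty, seq_len(n_pl), seq_len(n_pc), radius_nm))
  }
  d2 <- outer(pl_spots$y_nm, pc_spots$y_nm, "-")^2 +
    outer(pl_spots$x_nm, pc_spots$x_nm, "-")^2
  if (!in_plane) d2 <- d2 + outer(pl_spots$z_nm, pc_spots$z_nm, "-")^2
  hit <- which(d2 <= radius_nm^2, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(new_match_result(empty, seq_len(n_pl), seq_len(n_pc), radius_nm))
  }
  cand <- tibble(
    pl = hit[, 1], pc = hit[, 2],
    distance_nm = sqrt(d2[hit])
  ) |>
    arrange(.data$distance_nm, .data$pl, .data$pc)

  if (one_to_one) {
    pl_free <- rep(TRUE, n_pl)
    pc_free <- rep(TRUE, n_pc)
    take <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (pl_free[cand$pl[i]] && pc_free[cand$pc[i]]) {
        take[i] <- TRUE
        pl_free[cand$pl[i]] <- FALSE
        pc_free[cand$pc[i]] <- FALSE
      }
    }
    pairs <- cand[take, , drop = FALSE]
  } else {
    # nearest in-radius counterpart for each PL spot; PC spots with any
    # in-radius PL counterpart count as matched
    pairs <- cand |>
      group_by(.data$pl) |>
      dplyr::slice_min(.data$distance_nm, n = 1, with_ties = FALSE) |>
      ungroup()
  }
  new_match_result(
    pairs,
    setdiff(seq_len(n_pl), pairs$pl),
    setdiff(seq_len(n_pc), if (one_to_one) pairs$pc else cand$pc),
    radius_nm
  )
}

new_match_result <- function(pairs, unmatched_pl, unmatched_pc, radius_nm) {
  structure(
    list(pairs = pairs, unmatched_pl = as.integer(unmatched_pl),
         unmatched_pc = as.integer(unmatched_pc), radius_nm = radius_nm),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> %d pair(s) within %g nm; %d PL-only, %d PC-only\n",
    nrow(x$pairs), x$radius_nm, length(x$unmatched_pl), length(x$unmatched_pc)
  ))
  invisible(x)
}

#' Classify spots as linear, circular or fragment
#'
#' A matched PL/PC pair is one full-length linear transcript (reported at
#' the midpoint of the two spots); an unmatched PC spot is a circular RNA;
#' an unmatched PL spot is a linear fragment. The conservation identities
#' `linear + circular = #PC` and `linear + fragment = #PL` always hold.
#'
#' @param pl_spots,pc_spots Spot tibbles with `z_nm`, `y_nm`, `x_nm`.
#' @param radius_nm Colocalization radius in nm.
#' @param match Optional precomputed [match_spots()] result for these spot
#'   lists (must index into them consistently).
#' @param ... Passed to [match_spots()] when `match` is `NULL`.
#' @return A tibble of class `classified_spots` with columns `class`
#'   (`linear`/`circular`/`fragment`), `z_nm`, `y_nm`, `x_nm` and
#'   `pair_distance_nm` (`NA` for unpaired spots). Class counts are in the
#'   `counts` attribute.
#' @export
classify_spots <- function(pl_spots, pc_spots, radius_nm = 250,
                           match = NULL, ...) {
  if (is.null(match)) {
    match <- match_spots(pl_spots, pc_spots, radius_nm = radius_nm, ...)
  }
  idx <- c(match$pairs$pl, match$unmatched_pl)
  if (length(idx) != nrow(pl_spots) || anyDuplicated(idx) ||
      (length(idx) && max(idx) > nrow(pl_spots))) {
    abort("match result is inconsistent with pl_spots")
  }
  idx <- c(match$pairs$pc, match$unmatched_pc)
  if (length(idx) != nrow(pc_spots) || anyDuplicated(idx) ||
      (length(idx) && max(idx) > nrow(pc_spots))) {
    abort("match result is inconsistent with pc_spots")
  }
  linear <- tibble(
    class = rep("linear", nrow(match$pairs)),
    z_nm = (pl_spots$z_nm[match$pairs$pl] + pc_spots$z_nm[match$pairs$pc]) / 2,
    y_nm = (pl_spots$y_nm[match$pairs$pl] + pc_spots$y_nm[match$pairs$pc]) / 2,
    x_nm = (pl_spots$x_nm[match$pairs$pl] + pc_spots$x_nm[match$pairs$pc]) / 2,
    pair_distance_nm = match$pairs$distance_nm
  )
  circular <- tibble(
    class = rep("circular", length(match$unmatched_pc)),
    z_nm = pc_spots$z_nm[match$unmatched_pc],
    y_nm = pc_spots$y_nm[match$unmatched_pc],
    x_nm = pc_spots$x_nm[match$unmatched_pc],
    pair_distance_nm = NA_real_
  )
  fragment <- tibble(
    class = rep("fragment", length(match$unmatched_pl)),
    z_nm = pl_spots$z_nm[match$unmatched_pl],
    y_nm = pl_spots$y_nm[match$unmatched_pl],
    x_nm = pl_spots$x_nm[match$unmatched_pl],
    pair_distance_nm = NA_real_
  )
  out <- bind_rows(linear, circular, fragment)
  class(out) <- c("classified_spots", class(out))
  attr(out, "counts") <- c(
    linear = nrow(linear), circular = nrow(circular), fragment = nrow(fragment)
  )
  attr(out, "radius_nm") <- match$radius_nm
  out
}

#' Class counts of a classification
#'
#' @param classified A `classified_spots` tibble.
#' @return Named integer vector over `linear`, `circular`, `fragment`.
#' @export
class_counts <- function(classified) {
  counts <- attr(classified, "counts")
  if (is.null(counts)) {
    counts <- vapply(
      c("linear", "circular", "fragment"),
      function(k) sum(classified$class == k), numeric(1)
    )
  }
  counts
}

#' Per-channel circRNA counts for multiplexed PC-only imaging
#'
#' After RNase R digestion only circular RNAs remain, so several circRNAs
#' can be counted simultaneously with one PC probe set per channel and no
#' cross-channel matching: every channel is an independent circRNA count.
#' Optionally, cross-channel spot pairs within `radius_nm` are reported as
#' bleed-through warnings (they indicate chromatic bleed or mis-stripped
#' probes, not a classification).
#'
#' @param pc_spot_lists Named list of spot tibbles, one per circRNA channel.
#' @param radius_nm Radius used for the bleed-through check.
#' @param check_bleed Run the cross-channel proximity check?
#' @return A tibble with one row per channel: `channel`, `n_spots`,
#'   `n_bleed_warnings` (in-radius cross-channel counterparts, 0 when the
#'   check is off).
#' @export
multiplex_counts <- function(pc_spot_lists, radius_nm = 250, check_bleed = TRUE) {
  stopifnot(is.list(pc_spot_lists), length(pc_spot_lists) >= 1)
  nms <- names(pc_spot_lists) %||% paste0("PC", seq_along(pc_spot_lists))
  bleed <- rep(0L, length(pc_spot_lists))
  if (check_bleed && length(pc_spot_lists) > 1) {
    for (i in seq_along(pc_spot_lists)) {
      others <- bind_rows(pc_spot_lists[-i])
      if (nrow(others) == 0 || nrow(pc_spot_lists[[i]]) == 0) next
      m <- match_spots(pc_spot_lists[[i]], others, radius_nm = radius_nm)
      bleed[i] <- nrow(m$pairs)
      if (bleed[i] > 0) {
        warn(sprintf(
          "channel %s: %d spot(s) have an in-radius counterpart in another circRNA channel (possible bleed-through)",
          nms[i], bleed[i]
        ), class = "circfish_bleed_through")
      }
    }
  }
  tibble(
    channel = nms,
    n_spots = unname(vapply(pc_spot_lists, nrow, integer(1))),
    n_bleed_warnings = bleed
  )
}
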