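# Probe design: partition a transcript into circRNA-specific (PC) and
# linear-only (PL) target regions, then tile antisense oligo probes under
# length / GC / spacing constraints.

#' Build a transcript model
#'
#' A transcript model holds the spliced transcript sequence, its exon
#' structure in transcript coordinates, and which exons are circularised by
#' back-splicing. It is the substrate for discriminating probe design:
#' circularised exons are shared between the circular and linear isoforms,
#' all other exons are unique to the linear isoform.
#'
#' @param gene_id Identifier string, e.g. `"ZNF609"`.
#' @param spliced_sequence Spliced transcript sequence 5'->3', alphabet
#'   `A C G T U` (case-insensitive; `U` is converted to `T` internally).
#' @param exons Data frame with columns `start`, `end`: ordered exon
#'   intervals in transcript coordinates, 0-based half-open. Exons must be
#'   sorted, contiguous (each `start` equals the previous `end`) and cover
#'   the whole sequence.
#' @param circ_exon_indices Integer vector of 1-based exon indices that
#'   compose the circRNA; must be a non-empty, contiguous, proper subset of
#'   the exons.
#'
#' @return An object of class `transcript_model`.
#' @examples
#' tm <- transcript_model(
#'   "demo",
#'   strrep("ACGT", 30),
#'   tibble::tibble(start = c(0, 60), end = c(60, 120)),
#'   circ_exon_indices = 1
#' )
#' @export
transcript_model <- function(gene_id, spliced_sequence, exons, circ_exon_indices) {
  stopifnot(is.character(gene_id), length(gene_id) == 1)
  spliced_sequence <- validate_sequence(spliced_sequence)
  exons <- as_tibble(exons)
  stopifnot(all(c("start", "end") %in% names(exons)), nrow(exons) >= 1)
  exons <- dplyr::select(exons, "start", "end")
  if (any(exons$end <= exons$start)) {
    abort("exon intervals must be non-empty with end > start")
  }
  if (exons$start[1] != 0 ||
      (nrow(exons) > 1 && any(exons$start[-1] != exons$end[-nrow(exons)])) ||
      exons$end[nrow(exons)] != nchar(spliced_sequence)) {
    abort("exons must be sorted, contiguous, and cover [0, sequence length)")
  }
  circ <- sort(unique(as.integer(circ_exon_indices)))
  if (length(circ) == 0) abort("circ_exon_indices must be non-empty")
  if (any(circ < 1 | circ > nrow(exons))) {
    abort("circ_exon_indices out of range")
  }
  if (length(circ) == nrow(exons)) {
    abort("no linear-only region: all exons are circularized")
  }
  if (length(circ) > 1 && any(diff(circ) != 1)) {
    abort("circ_exon_indices must form a contiguous run of exons")
  }
  structure(
    list(
      gene_id = gene_id,
      spliced_sequence = spliced_sequence,
      exons = exons,
      circ_exon_indices = circ
    ),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf(
    "<transcript_model> %s: %d nt, %d exons, circRNA = exon(s) %s\n",
    x$gene_id, nchar(x$spliced_sequence), nrow(x$exons),
    paste(range(x$circ_exon_indices), collapse = "-")
  ))
  invisible(x)
}

# uppercase, U->T, error naming the first offending position
validate_sequence <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  bad <- regexpr("[^ACGT]", x)
  if (bad > 0) {
    abort(sprintf(
      "invalid character '%s' in sequence at position %d (expected A/C/G/T/U)",
      substr(x, bad, bad), as.integer(bad)
    ))
  }
  x
}

#' Partition a transcript into PC and PL target regions
#'
#' The PC (probe circular) region is the union of the circularised exons:
#' probes there bind both the circular and the linear isoform. The PL
#' (probe linear) region is the union of all non-circularised exons: probes
#' there bind only the full-length linear transcript. The two regions are
#' disjoint and together cover the transcript.
#'
#' @param transcript A [transcript_model()].
#' @return A list with elements `pc_region` and `pl_region`, each a tibble
#'   of disjoint intervals (`start`, `end`, 0-based half-open) merged into
#'   maximal contiguous runs.
#' @export
partition_target_regions <- function(transcript) {
  stopifnot(inherits(transcript, "transcript_model"))
  circ <- transcript$circ_exon_indices
  idx <- seq_len(nrow(transcript$exons))
  list(
    pc_region = merge_contiguous(transcript$exons[idx %in% circ, ]),
    pl_region = merge_contiguous(transcript$exons[!idx %in% circ, ])
  )
}

# merge adjacent (start == previous end) intervals into maximal runs
merge_contiguous <- function(iv) {
  iv <- dplyr::arrange(as_tibble(iv), .data$start)
  if (nrow(iv) <= 1) return(iv)
  run <- cumsum(c(0L, as.integer(iv$start[-1] != iv$end[-nrow(iv)])))
  iv |>
    dplyr::group_by(run = run) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    dplyr::select("start", "end")
}

#' Greedy probe tiling over one target sequence
#'
#' Tiles antisense probes left to right: at the cursor, the window of
#' `probe_len` nucleotides is evaluated; if its GC fraction is within
#' `gc_bounds` (inclusive; or the filter is off) a probe is emitted and the
#' cursor advances by `probe_len + min_gap`, otherwise the cursor advances by
#' one. The emitted probe sequence is the reverse complement of the target
#' window, reported in the DNA alphabet. The inter-probe gap prevents
#' fluorophore quenching between adjacently bound probes.
#'
#' @param region_sequence Target region sequence, 5'->3' (A/C/G/T/U).
#' @param probe_len Probe length in nt; must be within 18-20 (default 20).
#' @param min_gap Minimum gap between adjacent probe binding sites (nt).
#' @param gc_bounds Inclusive GC-fraction window, default `c(0.35, 0.55)`.
#' @param gc_filter Apply the GC window? When `FALSE` every window is
#'   accepted and the tiling achieves [max_probe_count()] probes.
#' @param region_offset Transcript coordinate of the first base of
#'   `region_sequence`; probe coordinates are reported relative to the
#'   transcript by adding this offset.
#' @param set_label Optional `"PL"`/`"PC"` label attached to each probe.
#' @param fluor Optional fluorophore name attached to each probe.
#'
#' @return A tibble with one row per probe: `target_start`, `target_end`
#'   (0-based half-open, transcript coordinates), `sequence`, `gc_fraction`,
#'   `set_label`, `fluor`. The attribute `low_probe_count` is `TRUE` (with a
#'   warning) when fewer than 15 probes are emitted, the minimum generally
#'   needed for a discrete diffraction-limited spot.
#' @examples
#' tile_probes(strrep("ACGT", 25))
#' @export
tile_probes <- function(region_sequence, probe_len = 20, min_gap = 2,
                        gc_bounds = c(0.35, 0.55), gc_filter = TRUE,
                        region_offset = 0, set_label = NA_character_,
                        fluor = NA_character_) {
  region_sequence <- validate_sequence(region_sequence)
  stopifnot(probe_len >= 18, probe_len <= 20, min_gap >= 0,
            length(gc_bounds) == 2, gc_bounds[1] <= gc_bounds[2])
  L <- nchar(region_sequence)
  starts <- integer(0)
  cursor <- 0L
  while (cursor + probe_len <= L) {
    window <- substr(region_sequence, cursor + 1L, cursor + probe_len)
    gc <- gc_fraction(window)
    if (!gc_filter || (gc >= gc_bounds[1] && gc <= gc_bounds[2])) {
      starts <- c(starts, cursor)
      cursor <- cursor + probe_len + as.integer(min_gap)
    } else {
      cursor <- cursor + 1L
    }
  }
  windows <- if (length(starts)) {
    substring(region_sequence, starts + 1L, starts + probe_len)
  } else {
    character(0)
  }
  probes <- tibble(
    target_start = starts + as.integer(region_offset),
    target_end = starts + as.integer(region_offset) + as.integer(probe_len),
    sequence = reverse_complement(windows),
    gc_fraction = vapply(windows, gc_fraction, numeric(1), USE.NAMES = FALSE),
    set_label = set_label,
    fluor = fluor
  )
  low <- nrow(probes) < 15
  if (low) {
    warn(sprintf(
      "only %d probe(s) emitted (< 15); the target may be too short or too GC-skewed for a robust smFISH signal",
      nrow(probes)
    ), class = "circfish_low_probe_count")
  }
  attr(probes, "low_probe_count") <- low
  probes
}

gc_fraction <- function(x) {
  n <- nchar(x)
  if (n == 0) return(NA_real_)
  as.integer(Biostrings::letterFrequency(Biostrings::DNAString(x), "GC")) / n
}

reverse_complement <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Closed-form tiling capacity
#'
#' Maximum number of probes of length `probe_len`, separated by gaps of
#' `gap` nt, that fit in a target of length `L`:
#' `floor((L + gap) / (probe_len + gap))`. Equals the [tile_probes()] count
#' with the GC filter off.
#'
#' @param L Target length (nt).
#' @param probe_len Probe length (nt).
#' @param gap Inter-probe gap (nt).
#' @return Integer probe capacity (0 when `L < probe_len`).
#' @export
max_probe_count <- function(L, probe_len, gap) {
  stopifnot(L >= 1, probe_len >= 1, gap >= 0)
  if (L < probe_len) return(0L)
  as.integer((L + gap) %/% (probe_len + gap))
}

#' Minimum target length for a probe set
#'
#' Length of target RNA required to accommodate `n_probes` probes of
#' `probe_len` nt with `gap`-nt spacing:
#' `n_probes * probe_len + (n_probes - 1) * gap`. With the recommended
#' minimum of 15-20 probes of 20 nt and 2 nt gaps this lands in the
#' 300-450 nt range, which is why very short circRNAs cannot be imaged by
#' exon tiling.
#'
#' @param n_probes Number of probes (>= 1).
#' @param probe_len Probe length (nt), default 20.
#' @param gap Inter-probe gap (nt), default 2.
#' @return Integer minimum target length in nt.
#' @examples
#' min_target_length(15) # 328
#' @export
min_target_length <- function(n_probes, probe_len = 20, gap = 2) {
  stopifnot(n_probes >= 1)
  as.integer(n_probes * probe_len + (n_probes - 1) * gap)
}

#' Design PL and PC probe sets for a transcript
#'
#' Partitions the transcript with [partition_target_regions()] (or uses
#' caller-restricted regions, e.g. to skip exons close to the circularised
#' run) and tiles each maximal contiguous region with [tile_probes()].
#' Probes may span exon-exon junctions inside one region but never cross
#' from one region into the other; the back-splice junction itself is never
#' targeted.
#'
#' @param transcript A [transcript_model()].
#' @inheritParams tile_probes
#' @param pl_region,pc_region Optional interval tibbles (`start`, `end`)
#'   overriding the automatic partition, e.g. to restrict PL to a subset of
#'   the non-circularised exons.
#' @param pl_fluor,pc_fluor Fluorophore names recorded per set.
#' @return A tibble of probes for both sets with columns `gene_id`,
#'   `set_label`, `probe_index`, `target_start`, `target_end`, `sequence`,
#'   `gc_fraction`, `fluor`.
#' @export
design_probes <- function(transcript, probe_len = 20, min_gap = 2,
                          gc_bounds = c(0.35, 0.55), gc_filter = TRUE,
                          pl_region = NULL, pc_region = NULL,
                          pl_fluor = "TexasRed", pc_fluor = "Cy5") {
  stopifnot(inherits(transcript, "transcript_model"))
  regions <- partition_target_regions(transcript)
  pc_region <- merge_contiguous(pc_region %||% regions$pc_region)
  pl_region <- merge_contiguous(pl_region %||% regions$pl_region)

  tile_region <- function(region, label, fluor) {
    sets <- purrr::pmap(region, function(start, end) {
      seq <- substr(transcript$spliced_sequence, start + 1, end)
      suppressWarnings(tile_probes(
        seq, probe_len = probe_len, min_gap = min_gap, gc_bounds = gc_bounds,
        gc_filter = gc_filter, region_offset = start,
        set_label = label, fluor = fluor
      ))
    })
    out <- bind_rows(sets)
    if (nrow(out) < 15) {
      warn(sprintf("%s set has only %d probe(s) (< 15)", label, nrow(out)),
           class = "circfish_low_probe_count")
    }
    out
  }

  bind_rows(
    tile_region(pc_region, "PC", pc_fluor),
    tile_region(pl_region, "PL", pl_fluor)
  ) |>
    group_by(.data$set_label) |>
    mutate(probe_index = row_number()) |>
    ungroup() |>
    mutate(gene_id = transcript$gene_id) |>
    dplyr::select("gene_id", "set_label", "probe_index", "target_start",
                  "target_end", "sequence", "gc_fraction", "fluor")
}

#' Read a transcript model from FASTA plus an exon table
#'
#' @param fasta_path FASTA file with the spliced transcript sequence (first
#'   record is used unless `gene_id` selects one by name).
#' @param exon_path Tab-separated exon table with columns `gene_id`,
#'   `exon_index` (1-based), `start`, `end` (0-based half-open transcript
#'   coordinates) and `in_circle` (0/1).
#' @param gene_id Optional gene to select when files contain several.
#' @return A [transcript_model()].
#' @export
read_transcript_model <- function(fasta_path, exon_path, gene_id = NULL) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  exons <- readr::read_tsv(exon_path, show_col_types = FALSE)
  stopifnot(all(c("gene_id", "exon_index", "start", "end", "in_circle") %in% names(exons)))
  gene_id <- gene_id %||% sub("\\s.*$", "", names(seqs)[1])
  hit <- which(sub("\\s.*$", "", names(seqs)) == gene_id)
  if (length(hit) == 0) abort(sprintf("gene '%s' not found in %s", gene_id, fasta_path))
  exons <- exons |> filter(.data$gene_id == !!gene_id) |> arrange(.data$exon_index)
  if (nrow(exons) == 0) abort(sprintf("gene '%s' not found in %s", gene_id, exon_path))
  transcript_model(
    gene_id, as.character(seqs[[hit[1]]]),
    dplyr::select(exons, "start", "end"),
    circ_exon_indices = exons$exon_index[exons$in_circle == 1]
  )
}

#' Write probes as FASTA
#'
#' Headers follow `gene|set_label|index|start-end`.
#'
#' @param probes Probe tibble from [design_probes()] or [tile_probes()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_probe_fasta <- function(probes, path) {
  headers <- sprintf(
    "%s|%s|%d|%d-%d",
    probes$gene_id %||% "probe", probes$set_label,
    probes$probe_index %||% seq_len(nrow(probes)),
    probes$target_start, probes$target_end
  )
  set <- Biostrings::DNAStringSet(probes$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write probes as TSV
#'
#' @inheritParams write_probe_fasta
#' @return `path`, invisibly.
#' @export
write_probe_tsv <- function(probes, path) {
  readr::write_tsv(probes, path)
  invisible(path)
}
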