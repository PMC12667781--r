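#' Extract candidate intervals from coverage
#'
#' Maximal runs of consecutive positions whose depth is at least `min_depth`,
#' per chromosome and strand. These contiguous well-covered regions ("read
#' groups") are the units on which the enrichment test is later run.
#'
#' @param tracks A `parclip_tracks` tibble ([build_tracks()]).
#' @param min_depth Minimum per-base read depth, default 3.
#' @return A tibble with `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, sorted.
#' @export
extract_regions <- function(tracks, min_depth = 3L) {
  stopifnot(min_depth >= 1)
  tr <- tracks[tracks$depth >= min_depth, , drop = FALSE]
  if (nrow(tr) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character()))
  }
  tr %>%
    dplyr::arrange(.data$chrom, .data$strand, .data$pos) %>%
    dplyr::group_by(.data$chrom, .data$strand) %>%
    dplyr::mutate(run = cumsum(c(1L, diff(.data$pos) != 1L))) %>%
    dplyr::group_by(.data$chrom, .data$strand, .data$run) %>%
    dplyr::summarise(start = min(.data$pos), end = max(.data$pos) + 1L,
                     .groups = "drop") %>%
    dplyr::arrange(.data$chrom, .data$start, .data$strand) %>%
    dplyr::select("chrom", "start", "end", "strand")
}

#' Merge nearby intervals
#'
#' Unions intervals on the same chromosome and strand whose gap is at most
#' `gap` bases; the default 0 merges book-ended intervals only.
#'
#' @param intervals A tibble with `chrom`, `start`, `end`, `strand`.
#' @param gap Maximum separating gap to bridge, default 0.
#' @return Sorted, non-overlapping intervals in the same shape.
#' @export
merge_adjacent <- function(intervals, gap = 0L) {
  stopifnot(gap >= 0)
  if (nrow(intervals) == 0) return(intervals[, c("chrom", "start", "end", "strand")])
  gr <- intervals_to_granges(intervals)
  red <- GenomicRanges::reduce(gr, min.gapwidth = gap + 1L,
                               ignore.strand = FALSE)
  granges_to_intervals(red) %>%
    dplyr::arrange(.data$chrom, .data$start, .data$strand)
}

#' Split intervals wider than a maximum width
#'
#' Very long covered stretches (repetitive elements, mapping artifacts,
#' partial strand bleed-through) would otherwise be tested as single
#' implausibly long binding sites; most RBP footprints are well under 50 nt.
#' An interval of width `L > max_width` is tiled by `ceiling(L / max_width)`
#' contiguous pieces of near-equal width (differing by at most 1 base), so no
#' systematically tiny terminal fragment is produced.
#'
#' @inheritParams merge_adjacent
#' @param max_width Maximum output interval width, default 50.
#' @return Intervals all of width `<= max_width`; the pieces of each input
#'   tile it exactly.
#' @export
split_max_width <- function(intervals, max_width = 50L) {
  stopifnot(max_width >= 1)
  if (nrow(intervals) == 0) return(intervals)
  L <- intervals$end - intervals$start
  k <- as.integer(ceiling(L / max_width))
  rows <- rep(seq_len(nrow(intervals)), k)
  piece <- sequence(k)                       # 1..k within each interval
  w <- (L %/% k)[rows] + (piece <= (L %% k)[rows])
  cw <- cumsum(w)
  prev_tot <- rep(c(0L, cw[cumsum(k)][-length(k)]), k)
  ends <- intervals$start[rows] + (cw - prev_tot)
  pieces <- tibble::tibble(
    chrom = intervals$chrom[rows], start = as.integer(ends - w),
    end = as.integer(ends), strand = intervals$strand[rows]
  )
  dplyr::arrange(pieces, .data$chrom, .data$start, .data$strand)
}

#' Quantify per-interval mismatch metrics
#'
#' Sums the track columns over each interval: `n_bases` (total sequenced
#' bases, the Poisson exposure), `o_t2c` (observed T-to-C), `other_mm`
#' (background mismatches) and `max_depth`. Intervals with no coverage get
#' all-zero metrics and `covered = FALSE`.
#'
#' @inheritParams merge_adjacent
#' @param tracks A `parclip_tracks` tibble.
#' @return A tibble of read groups: `chrom`, `start`, `end`, `name`
#'   (`RG<i>`), `score` (= `o_t2c`), `strand`, `n_bases`, `o_t2c`,
#'   `other_mm`, `max_depth`, `covered`.
#' @export
quantify_groups <- function(intervals, tracks) {
  base <- tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    name = character(), score = integer(), strand = character(),
    n_bases = integer(), o_t2c = integer(), other_mm = integer(),
    max_depth = integer(), covered = logical()
  )
  if (nrow(intervals) == 0) return(base)
  iv <- dplyr::arrange(intervals, .data$chrom, .data$start, .data$strand)
  gr <- intervals_to_granges(iv)
  cols <- GenomicRanges::GRanges(
    tracks$chrom, IRanges::IRanges(tracks$pos + 1L, width = 1L),
    strand = tracks$strand
  )
  hit <- GenomicRanges::findOverlaps(gr, cols, ignore.strand = FALSE)
  agg <- if (length(hit) == 0) {
    tibble::tibble(grp = integer(), n_bases = integer(), o_t2c = integer(),
                   other_mm = integer(), max_depth = integer())
  } else tibble::tibble(
    grp = S4Vectors::queryHits(hit),
    depth = tracks$depth[S4Vectors::subjectHits(hit)],
    t2c = tracks$t2c[S4Vectors::subjectHits(hit)],
    other = tracks$other_mm[S4Vectors::subjectHits(hit)]
  ) %>%
    dplyr::group_by(.data$grp) %>%
    dplyr::summarise(n_bases = sum(.data$depth), o_t2c = sum(.data$t2c),
                     other_mm = sum(.data$other), max_depth = max(.data$depth),
                     .groups = "drop")
  out <- iv
  out$n_bases <- out$o_t2c <- out$other_mm <- out$max_depth <- 0L
  out$n_bases[agg$grp] <- as.integer(agg$n_bases)
  out$o_t2c[agg$grp] <- as.integer(agg$o_t2c)
  out$other_mm[agg$grp] <- as.integer(agg$other_mm)
  out$max_depth[agg$grp] <- as.integer(agg$max_depth)
  out$covered <- out$n_bases > 0L
  out$name <- paste0("RG", seq_len(nrow(out)))
  out$score <- out$o_t2c
  out[, names(base)]
}

#' Derive quantified read groups from tracks in one call
#'
#' Chains [extract_regions()], [merge_adjacent()], [split_max_width()] and
#' [quantify_groups()] with the default parameters of the caller.
#'
#' @inheritParams extract_regions
#' @inheritParams merge_adjacent
#' @inheritParams split_max_width
#' @return The quantified read-group tibble (see [quantify_groups()]).
#' @export
find_read_groups <- function(tracks, min_depth = 3L, gap = 0L,
                             max_width = 50L) {
  extract_regions(tracks, min_depth) %>%
    merge_adjacent(gap) %>%
    split_max_width(max_width) %>%
    quantify_groups(tracks)
}

intervals_to_granges <- function(iv) {
  GenomicRanges::GRanges(iv$chrom,
                         IRanges::IRanges(iv$start + 1L, iv$end),
                         strand = iv$strand)
}

granges_to_intervals <- function(gr) {
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Write read groups or clusters as extended BED
#'
#' Standard BED6 columns (name/score/strand) followed by whatever metric
#' columns the tibble carries.
#'
#' @param groups A read-group or cluster tibble.
#' @param out Output path.
#' @return `out`, invisibly.
#' @export
write_groups_bed <- function(groups, out) {
  cols <- intersect(
    c("chrom", "start", "end", "name", "score", "strand", "n_bases",
      "o_t2c", "other_mm", "max_depth", "expected", "p_value", "q_value"),
    names(groups)
  )
  readr::write_tsv(as.data.frame(groups)[, cols, drop = FALSE], out,
                   col_names = FALSE)
  invisible(out)
}
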