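#' Write one metric of a mismatch track as bedGraph
#'
#' Emits a 4-column bedGraph (0-based half-open) for the chosen per-base
#' metric of one strand, run-length merging adjacent positions with equal
#' values. All covered positions are written, including zero values, so the
#' three per-strand files (`depth`, `t2c`, `other_mm`) are positionally
#' consistent and [read_bedgraph_pair()] can invert them exactly.
#'
#' @param tracks A `parclip_tracks` tibble from [build_tracks()].
#' @param which Metric to export: `"depth"`, `"t2c"` or `"other_mm"`.
#' @param out Output path.
#' @param strand Which strand to export, `"+"` or `"-"`.
#' @return `out`, invisibly.
#' @export
write_bedgraph <- function(tracks, which = c("depth", "t2c", "other_mm"),
                           out, strand = "+") {
  which <- match.arg(which)
  stopifnot(strand %in% c("+", "-"))
  tr <- tracks[tracks$strand == strand, , drop = FALSE]
  gr <- track_metric_granges(tr, which)
  rtracklayer::export(gr, out, format = "bedGraph")
  invisible(out)
}

# Run-length merge per-base values into intervals (GRanges with score).
track_metric_granges <- function(tr, which) {
  if (nrow(tr) == 0) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$score <- numeric(0)
    return(gr)
  }
  tr <- dplyr::arrange(tr, .data$chrom, .data$pos)
  val <- tr[[which]]
  # new run when chrom changes, positions are non-adjacent, or value changes
  brk <- c(TRUE, tr$chrom[-1] != tr$chrom[-nrow(tr)] |
                 tr$pos[-1] != tr$pos[-nrow(tr)] + 1L |
                 val[-1] != val[-nrow(tr)])
  run <- cumsum(brk)
  starts <- tapply(tr$pos, run, min)
  ends <- tapply(tr$pos, run, max) + 1L
  GenomicRanges::GRanges(
    tr$chrom[brk],
    IRanges::IRanges(start = as.integer(starts) + 1L, end = as.integer(ends)),
    score = val[brk]
  )
}

#' Reconstruct a mismatch track from its bedGraph triple
#'
#' Inverse of [write_bedgraph()] applied to the three metric files of one
#' strand. `ref_base` cannot be recovered from bedGraph and is returned as
#' `NA`.
#'
#' @param depth_bg,t2c_bg,other_bg Paths to the depth, T-to-C and
#'   other-mismatch bedGraph files written by [write_bedgraph()].
#' @param strand Strand label for the reconstructed track.
#' @return A `parclip_tracks` tibble.
#' @export
read_bedgraph_pair <- function(depth_bg, t2c_bg, other_bg, strand = "+") {
  depth <- bedgraph_per_base(depth_bg, "depth")
  t2c <- bedgraph_per_base(t2c_bg, "t2c")
  other <- bedgraph_per_base(other_bg, "other_mm")
  out <- depth %>%
    dplyr::left_join(t2c, by = c("chrom", "pos")) %>%
    dplyr::left_join(other, by = c("chrom", "pos"))
  stray <- c(
    setdiff(paste(t2c$chrom, t2c$pos), paste(depth$chrom, depth$pos)),
    setdiff(paste(other$chrom, other$pos), paste(depth$chrom, depth$pos))
  )
  if (length(stray) > 0)
    stop("mismatch values at uncovered position(s), first offender: ",
         stray[1], call. = FALSE)
  out <- out %>%
    dplyr::mutate(
      t2c = as.integer(tidyr::replace_na(.data$t2c, 0)),
      other_mm = as.integer(tidyr::replace_na(.data$other_mm, 0)),
      depth = as.integer(.data$depth),
      strand = strand, ref_base = NA_character_
    ) %>%
    dplyr::arrange(.data$chrom, .data$pos) %>%
    dplyr::select("chrom", "pos", "strand", "ref_base", "depth", "t2c",
                  "other_mm")
  new_parclip_tracks(out)
}

bedgraph_per_base <- function(path, name) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  hit <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  if (length(hit) > 0) {
    i <- S4Vectors::queryHits(hit)[1]
    stop("overlapping intervals in ", path, ", first offending position: ",
         as.character(GenomicRanges::seqnames(gr))[i], ":",
         GenomicRanges::start(gr)[i] - 1L, call. = FALSE)
  }
  w <- GenomicRanges::width(gr)
  tibble::tibble(
    chrom = rep(as.character(GenomicRanges::seqnames(gr)), w),
    pos = unlist(lapply(seq_along(gr), function(i) {
      seq.int(GenomicRanges::start(gr)[i] - 1L,
              GenomicRanges::end(gr)[i] - 1L)
    }), use.names = FALSE),
    !!name := rep(S4Vectors::mcols(gr)$score, w)
  )
}
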