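#' Build strand-specific per-base mismatch tracks from a BAM file
#'
#' The substrate of the whole caller: for every covered genomic position and
#' strand, count the quality-passing read bases (`depth`), the strand-local
#' T-to-C mismatches (`t2c`, the crosslink signal), and all other mismatches
#' pooled over the remaining 11 substitution types (`other_mm`, the
#' background). Strand-local means minus-strand reference and read bases are
#' complemented before classification, so a minus-strand T-to-C is a
#' reference-space A-to-G — the orientation in which 4SU crosslink chemistry
#' acts on the transcript.
#'
#' Reads are filtered to primary alignments (SAM flag 0x100 clear) with
#' `MAPQ >= min_mapq`; the plus track takes reads with the reverse bit (0x10)
#' clear, the minus track reads with it set. Duplicate-marked (0x400) and
#' supplementary (0x800) records are excluded by default. Individual bases
#' below `min_baseq`, read-base `N`s, and reference `N` positions are excluded
#' from depth and mismatch counts alike; insertions and deletions are ignored,
#' and spliced gaps (CIGAR `N`) contribute nothing. The per-position depth
#' cap is set to 10^7, far above any realistic coverage, so all genomic
#' regions are captured in full.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param fasta Path to the reference genome FASTA (a `.fai` index is created
#'   if absent).
#' @param min_mapq Minimum mapping quality, default 55. With STAR-style
#'   alignments (unique mappers get MAPQ 255) this keeps uniquely mapped
#'   reads only.
#' @param min_baseq Minimum base quality, default 20; applied to both the
#'   depth denominator and the mismatch numerator.
#' @param exclude_duplicates,exclude_supplementary Drop flag-0x400 /
#'   flag-0x800 records (default `TRUE`).
#' @return A tibble of class `parclip_tracks` with columns `chrom`, `pos`
#'   (0-based), `strand`, `ref_base` (strand-local), `depth`, `t2c`,
#'   `other_mm`, sorted by chrom, pos, strand, at most one row per
#'   (chrom, pos, strand). Attributes record the source BAM and filters.
#' @examples
#' \dontrun{
#' tracks <- build_tracks("sample.bam", "genome.fa")
#' dplyr::filter(tracks, t2c > 0)
#' }
#' @export
build_tracks <- function(bam, fasta, min_mapq = 55L, min_baseq = 20L,
                         exclude_duplicates = TRUE,
                         exclude_supplementary = TRUE) {
  stopifnot(file.exists(bam), file.exists(fasta))
  if (!file.exists(paste0(bam, ".bai")) && !file.exists(sub("\\.bam$", ".bai", bam)))
    stop("BAM index not found for ", bam, " (expected .bai); sort and index first",
         call. = FALSE)

  flag <- Rsamtools::scanBamFlag(
    isSecondaryAlignment = FALSE,
    isDuplicate = if (exclude_duplicates) FALSE else NA,
    isSupplementaryAlignment = if (exclude_supplementary) FALSE else NA
  )
  pp <- Rsamtools::PileupParam(
    max_depth = 10000000L, min_base_quality = as.integer(min_baseq),
    min_mapq = as.integer(min_mapq), min_nucleotide_depth = 1L,
    distinguish_strands = TRUE, distinguish_nucleotides = TRUE,
    ignore_query_Ns = TRUE, include_deletions = FALSE,
    include_insertions = FALSE
  )
  p <- Rsamtools::pileup(bam,
    scanBamParam = Rsamtools::ScanBamParam(flag = flag),
    pileupParam = pp
  )

  if (nrow(p) == 0) {
    out <- tibble::tibble(
      chrom = character(), pos = integer(), strand = character(),
      ref_base = character(), depth = integer(), t2c = integer(),
      other_mm = integer()
    )
    return(new_parclip_tracks(out, bam, min_mapq, min_baseq))
  }

  p$seqnames <- as.character(p$seqnames)
  p$strand <- as.character(p$strand)
  p$nucleotide <- as.character(p$nucleotide)
  p <- p[p$nucleotide %in% BASES, , drop = FALSE]

  refs <- load_reference(fasta, unique(p$seqnames))
  p$ref <- lookup_ref_base(refs, p$seqnames, p$pos)
  p <- p[p$ref %in% BASES, , drop = FALSE]  # drop reference-N columns

  is_minus <- p$strand == "-"
  ref_loc <- ifelse(is_minus, complement_base(p$ref), p$ref)
  nuc_loc <- ifelse(is_minus, complement_base(p$nucleotide), p$nucleotide)
  is_t2c <- ref_loc == "T" & nuc_loc == "C"
  is_mm <- nuc_loc != ref_loc

  # aggregate nucleotide-level rows to one row per (chrom, pos, strand);
  # rowsum() is much faster than a grouped summarise at this row count
  key <- paste(p$seqnames, p$strand, p$pos)
  agg <- rowsum(cbind(depth = p$count,
                      t2c = ifelse(is_t2c, p$count, 0L),
                      other_mm = ifelse(is_mm & !is_t2c, p$count, 0L)),
                key)
  first <- !duplicated(key)
  idx <- match(key[first], rownames(agg))
  out <- tibble::tibble(
    chrom = p$seqnames[first], pos = p$pos[first] - 1L,
    strand = p$strand[first], ref_base = ref_loc[first],
    depth = as.integer(agg[idx, "depth"]),
    t2c = as.integer(agg[idx, "t2c"]),
    other_mm = as.integer(agg[idx, "other_mm"])
  ) %>%
    dplyr::arrange(.data$chrom, .data$pos, .data$strand)

  new_parclip_tracks(out, bam, min_mapq, min_baseq)
}

new_parclip_tracks <- function(tbl, bam = NA_character_, min_mapq = NA,
                               min_baseq = NA) {
  structure(tbl,
    class = c("parclip_tracks", class(tibble::as_tibble(tbl))),
    source_bam = bam, min_mapq = min_mapq, min_baseq = min_baseq
  )
}

# Read whole chromosome sequences once; positions are then O(1) lookups.
load_reference <- function(fasta, chroms) {
  fai <- paste0(fasta, ".fai")
  if (!file.exists(fai)) Rsamtools::indexFa(fasta)
  fa <- Rsamtools::FaFile(fasta)
  available <- GenomeInfoDb::seqnames(Rsamtools::seqinfo(fa))
  missing <- setdiff(chroms, available)
  if (length(missing) > 0)
    stop("chromosome(s) absent from reference FASTA: ",
         paste(missing, collapse = ", "), call. = FALSE)
  lens <- GenomeInfoDb::seqlengths(Rsamtools::seqinfo(fa))[chroms]
  gr <- GenomicRanges::GRanges(chroms, IRanges::IRanges(1L, lens))
  seqs <- Rsamtools::scanFa(fa, gr)
  lapply(setNames(seq_along(chroms), chroms), function(i) {
    strsplit(toupper(as.character(seqs[[i]])), "", fixed = TRUE)[[1]]
  })
}

lookup_ref_base <- function(refs, chrom, pos1) {
  out <- character(length(chrom))
  for (cm in names(refs)) {
    i <- chrom == cm
    out[i] <- refs[[cm]][pos1[i]]
  }
  out
}
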