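#' Collapse reads into distinct-sequence records
#'
#' PAR-CLIP libraries are collapsed to distinct sequences before alignment to
#' remove PCR duplicates. Each distinct sequence becomes one record whose
#' `copy_count` is its multiplicity in the raw input.
#'
#' @param reads A character vector of read sequences, or a data frame with a
#'   `sequence` column (e.g. the output of [read_reads()]).
#' @return A tibble with columns `read_id`, `sequence`, `copy_count`, ordered
#'   by descending `copy_count` then lexicographic sequence. `read_id` is
#'   `seq<i>_<copy_count>`, the usual collapsed-FASTA convention.
#' @details Sequences are uppercased before collapsing; `N` is retained and
#'   collapsed by exact string match. Characters outside `A,C,G,T,N` are an
#'   error naming the offending read.
#' @examples
#' collapse_reads(c("ACGT", "acgt", "TTTT"))
#' @export
collapse_reads <- function(reads) {
  if (is.data.frame(reads)) reads <- reads$sequence
  reads <- toupper(as.character(reads))
  if (length(reads) == 0) {
    return(tibble::tibble(read_id = character(), sequence = character(),
                          copy_count = integer()))
  }
  bad <- grepl("[^ACGTN]", reads)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("read ", i, " contains non-nucleotide characters: ", reads[i],
         call. = FALSE)
  }
  tab <- table(reads)
  out <- tibble::tibble(sequence = names(tab), copy_count = as.integer(tab)) %>%
    dplyr::arrange(dplyr::desc(.data$copy_count), .data$sequence)
  out$read_id <- paste0("seq", seq_len(nrow(out)), "_", out$copy_count)
  out[, c("read_id", "sequence", "copy_count")]
}

#' Trim fixed-length UMIs from both read ends
#'
#' Removes `umi5_len` leading and `umi3_len` trailing bases from every
#' sequence. Adapter removal is assumed to have happened upstream (an external
#' trimmer); only the fixed-length unique molecular identifier is handled here.
#'
#' @param records A tibble of read records ([collapse_reads()] output, or any
#'   data frame with a `sequence` column).
#' @param umi5_len,umi3_len Non-negative integers, bases to strip from the 5'
#'   and 3' ends.
#' @return `records` with trimmed sequences; all other columns preserved.
#' @export
trim_umi <- function(records, umi5_len = 0L, umi3_len = 0L) {
  stopifnot(is.data.frame(records), umi5_len >= 0, umi3_len >= 0)
  if (nrow(records) == 0) return(records)
  len <- nchar(records$sequence)
  if (any(umi5_len + umi3_len >= len)) {
    i <- which(umi5_len + umi3_len >= len)[1]
    stop("UMI lengths (", umi5_len, " + ", umi3_len,
         ") leave no sequence for read ", i, " (length ", len[i], ")",
         call. = FALSE)
  }
  records$sequence <- substr(records$sequence, umi5_len + 1L, len - umi3_len)
  records
}

#' Drop reads shorter than a minimum length
#'
#' Very short inserts align promiscuously, so reads under `min_len` bases
#' (default 13) are removed both after collapsing and again after UMI
#' trimming.
#'
#' @param records A data frame with a `sequence` column.
#' @param min_len Minimum retained sequence length, default 13.
#' @return The retained rows, original order preserved.
#' @export
filter_min_length <- function(records, min_len = 13L) {
  stopifnot(is.data.frame(records), min_len >= 1)
  records[nchar(records$sequence) >= min_len, , drop = FALSE]
}

#' Read sequences from FASTQ or FASTA
#'
#' @param path FASTQ/FASTA file, optionally gzipped; format sniffed from the
#'   extension (`.fq`/`.fastq` vs anything else).
#' @return A tibble with `read_id` and `sequence`.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  tibble::tibble(read_id = names(ss), sequence = unname(as.character(ss)))
}

#' Write collapsed records as FASTA
#'
#' Record names encode the copy count (`id_count`) so collapsing
#' round-trips through the file.
#'
#' @param records Output of [collapse_reads()] (columns `read_id`,
#'   `sequence`, `copy_count`).
#' @param path Output path; `.gz` suffix enables compression.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(records, path) {
  ss <- Biostrings::DNAStringSet(records$sequence)
  names(ss) <- records$read_id
  Biostrings::writeXStringSet(ss, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Preprocess a raw read file: collapse, trim UMIs, length-filter
#'
#' Applies the preprocessing chain in order: uppercase + exact-duplicate
#' collapsing, minimum-length filter, fixed-length UMI trimming, and the
#' length filter once more (trimming can push reads under the threshold).
#'
#' @inheritParams read_reads
#' @inheritParams trim_umi
#' @inheritParams filter_min_length
#' @param out Optional path for a collapsed FASTA of the result.
#' @return The processed tibble of read records.
#' @export
preprocess_reads <- function(path, umi5_len = 0L, umi3_len = 0L,
                             min_len = 13L, out = NULL) {
  rec <- read_reads(path) %>%
    collapse_reads() %>%
    filter_min_length(min_len) %>%
    trim_umi(umi5_len, umi3_len) %>%
    filter_min_length(min_len)
  if (!is.null(out)) write_collapsed_fasta(rec, out)
  rec
}
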