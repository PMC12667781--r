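# Shared fixtures: hand-built SAM/BAM alignments and an independent
# per-read pileup oracle used to cross-check the Rsamtools-backed path.

# reads: tibble with qname, flag, chrom, pos (1-based), mapq, seq, qual
# (Phred+33 string, same length as seq). refs: named list of reference
# strings. Writes a coordinate-sorted SAM and converts to indexed BAM.
fixture_bam <- function(reads, refs,
                        dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fa <- file.path(dir, "ref.fa")
  ss <- Biostrings::DNAStringSet(unlist(refs))
  names(ss) <- names(refs)
  Biostrings::writeXStringSet(ss, fa)
  Rsamtools::indexFa(fa)
  sam <- file.path(dir, "aln.sam")
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", names(refs), "\tLN:", nchar(refs)))
  reads <- reads[order(match(reads$chrom, names(refs)), reads$pos), ]
  body <- if (nrow(reads) > 0) {
    paste(reads$qname, reads$flag, reads$chrom, reads$pos, reads$mapq,
          paste0(nchar(reads$seq), "M"), "*", 0, 0, reads$seq, reads$qual,
          sep = "\t")
  } else character(0)
  writeLines(c(header, body), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "aln"), overwrite = TRUE)
  list(bam = bam, fasta = fa, reads = reads, refs = refs)
}

# Independent oracle: a naive per-read, per-base walk over the reference.
# Mirrors the documented filter semantics without touching the pileup path.
naive_tracks <- function(reads, refs, min_mapq = 55, min_baseq = 20) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  acc <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(reads))) {
    flag <- reads$flag[i]
    if (bitwAnd(flag, 0x100) != 0 || bitwAnd(flag, 0x400) != 0 ||
        bitwAnd(flag, 0x800) != 0) next
    if (reads$mapq[i] < min_mapq) next
    strand <- if (bitwAnd(flag, 0x10) != 0) "-" else "+"
    seq <- strsplit(reads$seq[i], "")[[1]]
    qual <- utf8ToInt(reads$qual[i]) - 33L
    refc <- strsplit(refs[[reads$chrom[i]]], "")[[1]]
    for (k in seq_along(seq)) {
      if (qual[k] < min_baseq) next
      gpos <- reads$pos[i] + k - 1L
      rb <- refc[gpos]
      bb <- seq[k]
      if (rb == "N" || bb == "N") next
      rl <- if (strand == "-") comp[[rb]] else rb
      bl <- if (strand == "-") comp[[bb]] else bb
      key <- paste(reads$chrom[i], gpos - 1L, strand, sep = "\r")
      cur <- if (!is.null(acc[[key]])) acc[[key]]
             else list(d = 0L, t2c = 0L, mm = 0L, ref = rl)
      cur$d <- cur$d + 1L
      if (rl == "T" && bl == "C") cur$t2c <- cur$t2c + 1L
      else if (rl != bl) cur$mm <- cur$mm + 1L
      acc[[key]] <- cur
    }
  }
  keys <- ls(acc)
  if (length(keys) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          strand = character(), ref_base = character(),
                          depth = integer(), t2c = integer(),
                          other_mm = integer()))
  }
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  tibble::tibble(
    chrom = parts[, 1], pos = as.integer(parts[, 2]), strand = parts[, 3],
    ref_base = vapply(keys, function(k) acc[[k]]$ref, ""),
    depth = vapply(keys, function(k) acc[[k]]$d, 0L),
    t2c = vapply(keys, function(k) acc[[k]]$t2c, 0L),
    other_mm = vapply(keys, function(k) acc[[k]]$mm, 0L)
  ) |> dplyr::arrange(chrom, pos, strand)
}

# Random small alignment: reads over a random reference with substitutions,
# Ns, a spread of MAPQ and base qualities, and occasional secondary /
# duplicate / supplementary flags.
random_fixture_reads <- function(refs, n_reads, read_len = 12) {
  bases <- c("A", "C", "G", "T")
  out <- lapply(seq_len(n_reads), function(i) {
    chrom <- sample(names(refs), 1)
    L <- nchar(refs[[chrom]])
    pos <- sample.int(L - read_len + 1L, 1)
    seq <- strsplit(substr(refs[[chrom]], pos, pos + read_len - 1L), "")[[1]]
    nmut <- stats::rbinom(1, read_len, 0.1)
    if (nmut > 0) {
      at <- sample.int(read_len, nmut)
      seq[at] <- vapply(seq[at],
                        function(b) sample(setdiff(c(bases, "N"), b), 1), "")
    }
    flag <- sample(c(0L, 16L), 1)
    extra <- sample(c(0L, 0L, 0L, 0L, 256L, 1024L, 2048L), 1)
    qual <- intToUtf8(33L + sample(c(10L, 25L, 40L), read_len, replace = TRUE),
                      multiple = FALSE)
    tibble::tibble(qname = paste0("r", i), flag = flag + extra, chrom = chrom,
                   pos = pos, mapq = sample(c(10L, 60L, 255L), 1,
                                            prob = c(0.2, 0.4, 0.4)),
                   seq = paste(seq, collapse = ""), qual = qual)
  })
  dplyr::bind_rows(out)
}

random_reference <- function(n_chrom = 1, len = 200) {
  refs <- lapply(seq_len(n_chrom), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  })
  names(refs) <- paste0("chr", seq_len(n_chrom))
  refs
}

# Brute-force tail oracle: direct pmf summation, independent of ppois
# upper-tail code path.
pois_tail_oracle <- function(observed, lambda) {
  if (observed == 0) return(1)
  kmax <- max(observed + 100, ceiling(lambda + 30 * sqrt(lambda) + 100))
  sum(stats::dpois(observed:kmax, lambda))
}

# Brute-force BH: sort, p * m / rank, cumulative min from the largest rank.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

truth_granges <- function(sites) {
  GenomicRanges::GRanges(sites$chrom,
                         IRanges::IRanges(sites$start + 1L, sites$end),
                         strand = sites$strand)
}
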