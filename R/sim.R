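#' Configuration for the synthetic PAR-CLIP generator
#'
#' Fully parameterizes a truth-known simulation: a random reference
#' chromosome, non-overlapping planted crosslink sites where strand-local
#' reference-T positions read as C at `conversion_rate`, a uniform
#' background substitution process (each base corrupted with probability
#' `error_rate`, the erroneous base uniform over the 3 alternatives — under
#' uniform composition exactly 11/12 of such errors are non-T-to-C), and
#' ungapped single-end reads at configurable depth on both strands.
#'
#' @param seed Integer seed; identical configs give byte-identical outputs.
#' @param genome_length Reference length in bases.
#' @param base_composition Named probabilities for `A,C,G,T` (default
#'   uniform).
#' @param n_sites Number of planted binding sites.
#' @param site_width Site width in bases, default 25.
#' @param conversion_rate Probability that a read base over a strand-local
#'   reference-T inside a site reads as C, default 0.3.
#' @param error_rate Per-base probability of a uniform substitution error,
#'   default 0.001.
#' @param read_length Read length in bases, default 30.
#' @param site_depth Reads per planted site, default 15.
#' @param background_depth Mean off-site coverage, default 8.
#' @param minus_strand_fraction Probability a site (or background read) is
#'   on the minus strand, default 0.5.
#' @param chrom Name of the simulated chromosome.
#' @return A list of class `parclip_sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_length = 200000L,
                       base_composition = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25),
                       n_sites = 50L, site_width = 25L,
                       conversion_rate = 0.3, error_rate = 0.001,
                       read_length = 30L, site_depth = 15L,
                       background_depth = 8, minus_strand_fraction = 0.5,
                       chrom = "chrSim") {
  probs <- c(conversion_rate, error_rate, minus_strand_fraction,
             base_composition)
  stopifnot(all(probs >= 0), all(probs <= 1),
            abs(sum(base_composition) - 1) < 1e-8,
            site_width <= read_length, read_length <= genome_length,
            n_sites >= 0, site_depth >= 0, background_depth >= 0)
  structure(
    list(seed = as.integer(seed), genome_length = as.integer(genome_length),
         base_composition = base_composition, n_sites = as.integer(n_sites),
         site_width = as.integer(site_width),
         conversion_rate = conversion_rate, error_rate = error_rate,
         read_length = as.integer(read_length),
         site_depth = as.integer(site_depth),
         background_depth = background_depth,
         minus_strand_fraction = minus_strand_fraction, chrom = chrom),
    class = "parclip_sim_config"
  )
}

with_sim_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate the simulated reference chromosome
#'
#' @param config A `parclip_sim_config`.
#' @param fasta Optional path; when given, the sequence is written as FASTA
#'   (and faidx-indexed).
#' @return The reference sequence as a single character string.
#' @export
sim_reference <- function(config, fasta = NULL) {
  if (config$base_composition[["T"]] == 0 && config$conversion_rate > 0)
    warning("base composition has no T but conversion_rate > 0; ",
            "no conversions can occur")
  seq <- with_sim_seed(config$seed, {
    paste(sample(BASES, config$genome_length, replace = TRUE,
                 prob = config$base_composition[BASES]), collapse = "")
  })
  if (!is.null(fasta)) {
    ss <- Biostrings::DNAStringSet(seq)
    names(ss) <- config$chrom
    Biostrings::writeXStringSet(ss, fasta)
    Rsamtools::indexFa(fasta)
  }
  seq
}

#' Plant non-overlapping crosslink sites on the reference
#'
#' Each site is `site_width` bases wide, assigned a strand by
#' `minus_strand_fraction`, and required to contain at least 3 strand-local
#' reference-T positions (genome T on plus, genome A on minus) so that
#' conversions are possible.
#'
#' @inheritParams sim_reference
#' @param reference The reference string from [sim_reference()].
#' @return A BED6-shaped truth tibble (`chrom`, `start`, `end`, `name`,
#'   `score`, `strand`), sorted by start.
#' @export
sim_sites <- function(config, reference) {
  if (config$n_sites == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          score = integer(), strand = character()))
  }
  gchars <- strsplit(reference, "", fixed = TRUE)[[1]]
  w <- config$site_width
  with_sim_seed(config$seed + 1L, {
    placed_start <- integer(0)
    placed_strand <- character(0)
    attempts <- 0L
    max_attempts <- 200L * config$n_sites
    while (length(placed_start) < config$n_sites) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("could not place ", config$n_sites, " non-overlapping sites ",
             "after ", max_attempts, " attempts; reduce n_sites or ",
             "site_width, or increase genome_length", call. = FALSE)
      s <- sample.int(config$genome_length - w + 1L, 1L) - 1L
      if (any(s < placed_start + w & s + w > placed_start)) next
      strand <- if (stats::runif(1) < config$minus_strand_fraction) "-" else "+"
      t_base <- if (strand == "+") "T" else "A"
      if (sum(gchars[(s + 1L):(s + w)] == t_base) < 3L) next
      placed_start <- c(placed_start, s)
      placed_strand <- c(placed_strand, strand)
    }
    ord <- order(placed_start)
    tibble::tibble(
      chrom = config$chrom, start = placed_start[ord],
      end = placed_start[ord] + w,
      name = paste0("site", seq_along(ord)), score = 0L,
      strand = placed_strand[ord]
    )
  })
}

#' Simulate reads and write them as SAM
#'
#' Site reads fully cover their site at `site_depth`; background reads are
#' placed uniformly at `background_depth` mean coverage. Strand-local
#' reference-T bases inside a site flip to C with `conversion_rate`
#' (genome-space A-to-G on minus sites); every base is then independently
#' corrupted at `error_rate`, uniformly over the 3 alternative bases. Reads
#' are ungapped, primary, MAPQ 255, with constant base quality; minus reads
#' carry SAM flag 16 (sequence stored in reference orientation, as SAM
#' requires). The SAM is coordinate-sorted.
#'
#' @inheritParams sim_sites
#' @param sites The truth tibble from [sim_sites()].
#' @param sam Output SAM path.
#' @param fastq Optional FASTQ path for the raw (strand-local) reads.
#' @return A tibble of the simulated reads (`qname`, `flag`, `pos` 0-based,
#'   `strand`, `seq` in reference orientation), invisibly.
#' @export
sim_reads <- function(config, reference, sites, sam, fastq = NULL) {
  L <- config$genome_length
  rl <- config$read_length
  gchars <- strsplit(reference, "", fixed = TRUE)[[1]]

  reads <- with_sim_seed(config$seed + 2L, {
    # background reads
    n_bg <- as.integer(round(L * config$background_depth / rl))
    bg_start <- if (n_bg > 0) sample.int(L - rl + 1L, n_bg, replace = TRUE) - 1L
                else integer(0)
    bg_strand <- if (n_bg > 0)
      ifelse(stats::runif(n_bg) < config$minus_strand_fraction, "-", "+")
      else character(0)

    # site reads: start uniform in the window that fully covers the site
    st_start <- integer(0); st_strand <- character(0); st_site <- integer(0)
    if (nrow(sites) > 0 && config$site_depth > 0) {
      for (i in seq_len(nrow(sites))) {
        lo <- max(0L, sites$end[i] - rl)
        hi <- min(sites$start[i], L - rl)
        s <- lo + sample.int(hi - lo + 1L, config$site_depth,
                             replace = TRUE) - 1L
        st_start <- c(st_start, s)
        st_strand <- c(st_strand, rep(sites$strand[i], config$site_depth))
        st_site <- c(st_site, rep(i, config$site_depth))
      }
    }

    start <- c(bg_start, st_start)
    strand <- c(bg_strand, st_strand)
    site_of <- c(rep(NA_integer_, length(bg_start)), st_site)
    n <- length(start)
    if (n == 0) {
      tibble::tibble(qname = character(), flag = integer(), pos = integer(),
                     strand = character(), seq = character())
    } else {
      # read bases as an rl x n character matrix, reference orientation
      idx <- outer(seq_len(rl) - 1L, start, `+`) + 1L
      m <- matrix(gchars[idx], nrow = rl)

      # crosslink conversions inside the covered site
      if (length(st_site) > 0 && config$conversion_rate > 0) {
        for (j in seq_along(st_site)) {
          col <- length(bg_start) + j
          i <- st_site[j]
          t_base <- if (sites$strand[i] == "+") "T" else "A"
          c_base <- if (sites$strand[i] == "+") "C" else "G"
          gpos <- start[col] + seq_len(rl) - 1L
          in_site <- gpos >= sites$start[i] & gpos < sites$end[i]
          target <- which(in_site & m[, col] == t_base)
          if (length(target) > 0) {
            flip <- target[stats::runif(length(target)) < config$conversion_rate]
            m[flip, col] <- c_base
          }
        }
      }

      # uniform background errors
      if (config$error_rate > 0) {
        err <- which(stats::runif(rl * n) < config$error_rate)
        if (length(err) > 0) {
          cur <- m[err]
          alt <- vapply(cur, function(b) sample(setdiff(BASES, b), 1L), "")
          m[err] <- alt
        }
      }

      seqs <- apply(m, 2, paste, collapse = "")
      ord <- order(start)
      tibble::tibble(
        qname = paste0("read", seq_len(n)[ord]),
        flag = ifelse(strand[ord] == "-", 16L, 0L),
        pos = start[ord], strand = strand[ord], seq = seqs[ord]
      )
    }
  })

  write_sam(reads, config, sam)
  if (!is.null(fastq)) {
    local_seq <- ifelse(reads$strand == "-", revcomp(reads$seq), reads$seq)
    qual <- strrep("I", rl)
    readr::write_lines(
      paste0("@", reads$qname, "\n", local_seq, "\n+\n", qual), fastq)
  }
  invisible(reads)
}

write_sam <- function(reads, config, sam) {
  rl <- config$read_length
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    paste0("@SQ\tSN:", config$chrom, "\tLN:", config$genome_length),
    "@PG\tID:parclipr\tPN:parclipr"
  )
  body <- if (nrow(reads) > 0) {
    paste(reads$qname, reads$flag, config$chrom, reads$pos + 1L, 255L,
          paste0(rl, "M"), "*", 0L, 0L, reads$seq, strrep("I", rl),
          sep = "\t")
  } else character(0)
  readr::write_lines(c(header, body), sam)
  invisible(sam)
}

#' Convert a SAM file to sorted, indexed BAM
#'
#' Thin wrapper used to feed simulator output (or any SAM fixture) into the
#' pileup step.
#'
#' @param sam Path to a SAM file with header.
#' @param prefix Destination prefix; writes `<prefix>.bam` and its index.
#' @return The BAM path.
#' @export
sam_to_bam <- function(sam, prefix = sub("\\.sam$", "", sam)) {
  Rsamtools::asBam(sam, prefix, overwrite = TRUE, indexDestination = TRUE)
}

#' Toy GTF with known structure for annotation tests
#'
#' Emits four genes on the simulated chromosome: a two-exon protein-coding
#' gene with 5'UTR/CDS/3'UTR (hence one intron), a miRNA gene on the minus
#' strand, and a pair of overlapping protein-coding genes to exercise the
#' multigenic tag. Coordinates are fixed and returned as a truth table.
#'
#' @inheritParams sim_reference
#' @param gtf Output GTF path.
#' @return A truth tibble (`gene_id`, `gene_name`, `biotype`, `strand`,
#'   `feature`, `start`, `end`; 0-based half-open), invisibly; the GTF file
#'   is the main product.
#' @export
sim_gtf <- function(config, gtf) {
  stopifnot(config$genome_length >= 2000)
  chrom <- config$chrom
  truth <- tibble::tribble(
    ~gene_id, ~gene_name, ~biotype, ~strand, ~feature, ~start, ~end,
    "SIMG1", "CODA", "protein_coding", "+", "gene", 100L, 1100L,
    "SIMG1", "CODA", "protein_coding", "+", "exon", 100L, 400L,
    "SIMG1", "CODA", "protein_coding", "+", "exon", 700L, 1100L,
    "SIMG1", "CODA", "protein_coding", "+", "five_prime_utr", 100L, 200L,
    "SIMG1", "CODA", "protein_coding", "+", "CDS", 200L, 400L,
    "SIMG1", "CODA", "protein_coding", "+", "CDS", 700L, 1000L,
    "SIMG1", "CODA", "protein_coding", "+", "three_prime_utr", 1000L, 1100L,
    "SIMG2", "MIRX", "miRNA", "-", "gene", 1300L, 1400L,
    "SIMG2", "MIRX", "miRNA", "-", "exon", 1300L, 1400L,
    "SIMG3", "OVLA", "protein_coding", "+", "gene", 1500L, 1700L,
    "SIMG3", "OVLA", "protein_coding", "+", "exon", 1500L, 1700L,
    "SIMG3", "OVLA", "protein_coding", "+", "CDS", 1500L, 1700L,
    "SIMG4", "OVLB", "protein_coding", "+", "gene", 1600L, 1800L,
    "SIMG4", "OVLB", "protein_coding", "+", "exon", 1600L, 1800L,
    "SIMG4", "OVLB", "protein_coding", "+", "CDS", 1600L, 1800L
  )
  attrs <- function(id, name, biotype, feature) {
    a <- paste0('gene_id "', id, '"; gene_name "', name,
                '"; gene_biotype "', biotype, '";')
    if (feature != "gene")
      a <- paste0(a, ' transcript_id "', id, '.t1";')
    a
  }
  lines <- purrr::pmap_chr(truth, function(gene_id, gene_name, biotype,
                                           strand, feature, start, end) {
    paste(chrom, "sim", feature, start + 1L, end, ".", strand, ".",
          attrs(gene_id, gene_name, biotype, feature), sep = "\t")
  })
  readr::write_lines(lines, gtf)
  invisible(truth)
}

#' Run the full simulator and write all outputs
#'
#' @inheritParams sim_reference
#' @param out_prefix Path prefix; writes `<prefix>.fa` (+ `.fai`),
#'   `<prefix>.sam`, `<prefix>.truth.bed`, `<prefix>.gtf` and
#'   `<prefix>.config.json`.
#' @param bam Also convert the SAM to a sorted, indexed BAM (default
#'   `TRUE`).
#' @return A list with the output `paths`, the `sites` truth tibble, the
#'   `reads` tibble and the reference string, invisibly.
#' @export
simulate_parclip <- function(config, out_prefix, bam = TRUE) {
  paths <- list(
    fasta = paste0(out_prefix, ".fa"), sam = paste0(out_prefix, ".sam"),
    truth = paste0(out_prefix, ".truth.bed"),
    gtf = paste0(out_prefix, ".gtf"),
    config = paste0(out_prefix, ".config.json")
  )
  reference <- sim_reference(config, paths$fasta)
  sites <- sim_sites(config, reference)
  reads <- sim_reads(config, reference, sites, paths$sam)
  readr::write_tsv(sites, paths$truth, col_names = FALSE)
  if (config$genome_length >= 2000) sim_gtf(config, paths$gtf)
  jsonlite::write_json(unclass(config), paths$config, auto_unbox = TRUE)
  if (bam) paths$bam <- sam_to_bam(paths$sam, out_prefix)
  invisible(list(paths = paths, config = config, reference = reference,
                 sites = sites, reads = reads))
}
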