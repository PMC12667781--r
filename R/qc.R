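#' Twelve-type substitution spectrum of a BAM file
#'
#' Counts every single-nucleotide mismatch type in strand-local base space
#' (minus-strand pairs complemented), under the same quality filters as
#' [build_tracks()], optionally restricted to columns at or above a minimum
#' depth (no restriction by default). In a PAR-CLIP library T-to-C should be
#' the modal substitution; a flat spectrum indicates failed crosslinking.
#'
#' @inheritParams build_tracks
#' @param min_depth Only count columns with at least this depth; default 0
#'   (no limit).
#' @return A tibble of class `parclip_spectrum` with one row per ordered
#'   substitution `ref_base != read_base` over `A,C,G,T` (12 rows):
#'   `ref_base`, `read_base`, `count`, `fraction` (of all mismatches).
#'   Attribute `total_bases` holds the depth denominator.
#' @export
substitution_spectrum <- function(bam, fasta, min_depth = 0L, min_mapq = 55L,
                                  min_baseq = 20L) {
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isDuplicate = FALSE,
                                 isSupplementaryAlignment = FALSE)
  pp <- Rsamtools::PileupParam(
    max_depth = 10000000L, min_base_quality = as.integer(min_baseq),
    min_mapq = as.integer(min_mapq), min_nucleotide_depth = 1L,
    distinguish_strands = TRUE, distinguish_nucleotides = TRUE,
    ignore_query_Ns = TRUE, include_deletions = FALSE,
    include_insertions = FALSE
  )
  p <- Rsamtools::pileup(bam,
    scanBamParam = Rsamtools::ScanBamParam(flag = flag), pileupParam = pp)

  grid <- tidyr::expand_grid(ref_base = BASES, read_base = BASES) %>%
    dplyr::filter(.data$ref_base != .data$read_base)

  if (nrow(p) == 0) {
    out <- grid %>% dplyr::mutate(count = 0L, fraction = 0)
    return(structure(out, class = c("parclip_spectrum", class(out)),
                     total_bases = 0))
  }
  p$seqnames <- as.character(p$seqnames)
  p$strand <- as.character(p$strand)
  p$nucleotide <- as.character(p$nucleotide)
  p <- p[p$nucleotide %in% BASES, , drop = FALSE]
  refs <- load_reference(fasta, unique(p$seqnames))
  p$ref <- lookup_ref_base(refs, p$seqnames, p$pos)
  p <- p[p$ref %in% BASES, , drop = FALSE]

  key <- paste(p$seqnames, p$strand, p$pos)
  depth_by_col <- rowsum(p$count, key)
  total_bases <- sum(p$count[depth_by_col[match(key, rownames(depth_by_col))] >= min_depth])
  if (min_depth > 0) {
    p <- p[depth_by_col[match(key, rownames(depth_by_col))] >= min_depth, ,
           drop = FALSE]
  }

  minus <- p$strand == "-"
  ref_loc <- ifelse(minus, complement_base(p$ref), p$ref)
  nuc_loc <- ifelse(minus, complement_base(p$nucleotide), p$nucleotide)
  mm <- ref_loc != nuc_loc
  counts <- tibble::tibble(ref_base = ref_loc[mm], read_base = nuc_loc[mm],
                           n = p$count[mm]) %>%
    dplyr::group_by(.data$ref_base, .data$read_base) %>%
    dplyr::summarise(count = sum(.data$n), .groups = "drop")
  out <- grid %>%
    dplyr::left_join(counts, by = c("ref_base", "read_base")) %>%
    dplyr::mutate(count = as.integer(tidyr::replace_na(.data$count, 0)))
  tot <- sum(out$count)
  out$fraction <- if (tot > 0) out$count / tot else 0
  structure(out, class = c("parclip_spectrum", class(tibble::tibble())),
            total_bases = total_bases)
}

#' @method autoplot parclip_spectrum
#' @export
autoplot.parclip_spectrum <- function(object, ...) {
  df <- tibble::as_tibble(object) %>%
    dplyr::mutate(sub = paste0(.data$ref_base, ">", .data$read_base),
                  t2c = .data$sub == "T>C")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sub, y = .data$count,
                                   fill = .data$t2c)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = "substitution (strand-local)", y = "count",
                  title = "Single-nucleotide substitution spectrum")
}

#' Export a normalized mismatch signal track
#'
#' Writes the chosen mismatch signal (`T2C` or the pooled 11-type `nonT2C`)
#' of one strand as bedGraph, either raw counts or CPM
#' (`count * 1e6 / library_size`). If `out` ends in `.bw` and a
#' chromosome-sizes file is supplied, a bigWig is written instead; without
#' sizes it falls back to bedGraph with a warning.
#'
#' @param tracks A `parclip_tracks` tibble.
#' @param which `"T2C"` or `"nonT2C"`.
#' @param normalization `"raw"` or `"CPM"`.
#' @param library_size Number of quality-passing uniquely mapped reads; the
#'   CPM denominator. Required for CPM.
#' @param out Output path (`.bedGraph`, or `.bw` with `chrom_sizes`).
#' @param strand `"+"` or `"-"`.
#' @param chrom_sizes Optional two-column chromosome-sizes file (needed for
#'   bigWig output).
#' @return The path written, invisibly.
#' @export
export_mismatch_track <- function(tracks, which = c("T2C", "nonT2C"),
                                  normalization = c("raw", "CPM"),
                                  library_size = NULL, out, strand = "+",
                                  chrom_sizes = NULL) {
  which <- match.arg(which)
  normalization <- match.arg(normalization)
  col <- if (which == "T2C") "t2c" else "other_mm"
  tr <- tracks[tracks$strand == strand, , drop = FALSE]
  tr <- tibble::as_tibble(tr)
  val <- tr[[col]]
  if (normalization == "CPM") {
    if (is.null(library_size) || library_size <= 0)
      stop("CPM normalization needs a positive library_size", call. = FALSE)
    val <- val * 1e6 / library_size
  }
  tr$signal <- val
  tr <- tr[tr$signal != 0, , drop = FALSE]
  gr <- track_metric_granges(tr, "signal")

  want_bw <- grepl("\\.bw$|\\.bigwig$", out, ignore.case = TRUE)
  if (want_bw) {
    if (is.null(chrom_sizes)) {
      warning("no chromosome-sizes file supplied; writing bedGraph instead")
      out <- sub("\\.bw$|\\.bigwig$", ".bedGraph", out, ignore.case = TRUE)
    } else {
      cs <- readr::read_tsv(chrom_sizes, col_names = c("chrom", "size"),
                            show_col_types = FALSE)
      GenomeInfoDb::seqlevels(gr) <- cs$chrom
      GenomeInfoDb::seqlengths(gr) <- setNames(cs$size, cs$chrom)
      rtracklayer::export(gr, out, format = "bigWig")
      return(invisible(out))
    }
  }
  rtracklayer::export(gr, out, format = "bedGraph")
  invisible(out)
}

#' Overlap matrix of two or three BED interval sets
#'
#' Coordinate mode assigns every interval of every set to a membership
#' combination: it belongs to combination `S` iff it overlaps (>= 1 bp,
#' strand-matched) at least one interval of every other set in `S` and none
#' outside `S`. Because multi-way interval Venn counts are ill-defined
#' without a convention, counts are reported per set
#' (`view = "per_set"`) and additionally for the fragments of the merged
#' union of all intervals (`view = "union"`). Gene mode does exact set
#' algebra over the distinct gene identifiers found in the `gene_name`
#' column (7th column and beyond of annotated BED files).
#'
#' @param beds A named list (2 or 3 elements) of BED6/annotated-BED paths or
#'   interval tibbles.
#' @param mode `"coordinate"` or `"gene"`.
#' @return A tibble of class `parclip_overlap`: `combination` (e.g.
#'   `"a&b"`), `view`, `set` (per-set view only), `count`.
#' @export
compare_beds <- function(beds, mode = c("coordinate", "gene")) {
  mode <- match.arg(mode)
  if (length(beds) < 2 || length(beds) > 3)
    stop("compare_beds accepts 2 or 3 input sets; this is the highest limit",
         call. = FALSE)
  if (is.null(names(beds)) || any(names(beds) == ""))
    names(beds) <- paste0("set", seq_along(beds))
  tbls <- lapply(beds, function(b) {
    if (is.character(b)) read_bed6(b) else tibble::as_tibble(b)
  })
  nms <- names(tbls)

  if (mode == "gene") {
    sets <- lapply(tbls, function(t) {
      col <- intersect(c("gene_name", "X8", "X7"), names(t))[1]
      if (is.na(col)) stop("gene mode needs an annotation column", call. = FALSE)
      setdiff(unique(t[[col]]), ".")
    })
    combos <- membership_combos(nms)
    counts <- vapply(combos, function(cmb) {
      inside <- Reduce(intersect, sets[cmb])
      outside <- unique(unlist(sets[setdiff(nms, cmb)]))
      length(setdiff(inside, outside))
    }, integer(1))
    out <- tibble::tibble(combination = vapply(combos, paste, "", collapse = "&"),
                          view = "gene", set = NA_character_, count = counts)
    return(structure(out, class = c("parclip_overlap", class(out))))
  }

  grs <- lapply(tbls, intervals_to_granges)
  member_of <- function(gr) {
    m <- vapply(nms, function(o) {
      GenomicRanges::countOverlaps(gr, grs[[o]], ignore.strand = FALSE) > 0
    }, logical(length(gr)))
    if (length(gr) == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, nms))
    apply(m, 1, function(r) paste(nms[r], collapse = "&"))
  }
  per_set <- purrr::imap_dfr(grs, function(gr, nm) {
    tibble::tibble(set = nm, combination = member_of(gr))
  }) %>%
    dplyr::count(.data$combination, .data$set, name = "count") %>%
    dplyr::mutate(view = "per_set")

  union_gr <- GenomicRanges::reduce(do.call(c, unname(grs)),
                                    ignore.strand = FALSE)
  union_counts <- tibble::tibble(combination = member_of(union_gr)) %>%
    dplyr::count(.data$combination, name = "count") %>%
    dplyr::mutate(view = "union", set = NA_character_)

  out <- dplyr::bind_rows(per_set, union_counts) %>%
    dplyr::select("combination", "view", "set", "count")
  structure(out, class = c("parclip_overlap", class(tibble::tibble())))
}

membership_combos <- function(nms) {
  unlist(lapply(seq_along(nms), function(k) {
    asplit(utils::combn(nms, k), 2)
  }), recursive = FALSE)
}

#' Per-gene T-to-C matrix and inter-sample correlation
#'
#' Sums per-cluster observed T-to-C counts by gene within each sample, then
#' correlates samples over the union of genes (a gene absent from a sample
#' counts 0).
#'
#' @param samples A named list of annotated cluster tibbles (or paths to
#'   9+-column annotated BED files) carrying `o_t2c` (or BED column 8 as
#'   gene name and score as count) and `gene_id`/`gene_name`.
#' @param method Correlation method, `"spearman"` (rank, default) or
#'   `"pearson"` (linear).
#' @return A list of class `parclip_gene_cor`: `matrix` (tibble, gene x
#'   sample T-to-C totals) and `correlation` (sample x sample matrix).
#' @export
gene_t2c_matrix <- function(samples, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (is.null(names(samples)) || any(names(samples) == ""))
    names(samples) <- paste0("sample", seq_along(samples))
  long <- purrr::imap_dfr(samples, function(s, nm) {
    t <- if (is.character(s)) read_bed6(s) else tibble::as_tibble(s)
    gene_col <- intersect(c("gene_id", "X9", "gene_name", "X8"), names(t))[1]
    cnt_col <- intersect(c("o_t2c", "score"), names(t))[1]
    if (is.na(gene_col) || is.na(cnt_col))
      stop("sample ", nm, " lacks gene/count columns", call. = FALSE)
    tibble::tibble(sample = nm, gene = t[[gene_col]],
                   t2c = as.numeric(t[[cnt_col]]))
  }) %>%
    dplyr::filter(.data$gene != ".") %>%
    dplyr::group_by(.data$sample, .data$gene) %>%
    dplyr::summarise(t2c = sum(.data$t2c), .groups = "drop")
  if (nrow(long) == 0)
    stop("no shared gene universe: no annotated genes in any sample",
         call. = FALSE)
  wide <- tidyr::pivot_wider(long, names_from = "sample",
                             values_from = "t2c", values_fill = 0) %>%
    dplyr::arrange(.data$gene)
  for (nm in setdiff(names(samples), names(wide))) wide[[nm]] <- 0
  m <- as.matrix(wide[, names(samples), drop = FALSE])
  rownames(m) <- wide$gene
  cc <- stats::cor(m, method = method)
  structure(list(matrix = wide, correlation = cc),
            class = "parclip_gene_cor")
}

#' @method autoplot parclip_gene_cor
#' @export
autoplot.parclip_gene_cor <- function(object, ...) {
  cc <- object$correlation
  df <- tibble::as_tibble(as.table(cc), .name_repair = "minimal")
  names(df) <- c("sample1", "sample2", "r")
  ggplot2::ggplot(df, ggplot2::aes(.data$sample1, .data$sample2,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$r, 2))) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(NA, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Per-gene T-to-C correlation between samples")
}
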