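#' Build a queryable feature index from an ENSEMBL-style GTF
#'
#' Parses gene, transcript-feature and exon records, converts the GTF's
#' 1-based closed coordinates to 0-based half-open, and derives per-gene
#' intron intervals as the gene span minus the union of the gene's exons.
#' 5'/3' UTRs come from explicit `five_prime_utr` / `three_prime_utr`
#' records; for GTF dialects that only emit `UTR`, sidedness is inferred from
#' position relative to the gene's CDS extent on its strand.
#'
#' @param gtf Path to a GTF file (plain or gzipped) with `gene_id`,
#'   `gene_name` and `gene_biotype` attributes; absent `gene_name` falls
#'   back to `gene_id`.
#' @return An object of class `parclip_feature_index`: a list with `genes`
#'   (GRanges of gene spans with `gene_id`, `gene_name`, `biotype`) and
#'   `features` (GRanges typed `three_prime_utr` / `CDS` /
#'   `five_prime_utr` / `intron` with `gene_id`).
#' @export
build_feature_index <- function(gtf) {
  gr <- rtracklayer::import(gtf, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (!("gene_id" %in% names(md)))
    stop("GTF lacks gene_id attributes: ", gtf, call. = FALSE)
  if (!("gene_name" %in% names(md))) md$gene_name <- md$gene_id
  md$gene_name <- ifelse(is.na(md$gene_name), md$gene_id, md$gene_name)
  if (!("gene_biotype" %in% names(md))) {
    md$gene_biotype <- if ("gene_type" %in% names(md)) md$gene_type
                       else "protein_coding"
  }
  S4Vectors::mcols(gr) <- md
  type <- as.character(md$type)

  genes <- gr[type == "gene"]
  if (length(genes) == 0) {
    # no explicit gene records: derive spans from exons per gene_id
    ex_all <- gr[type == "exon"]
    sp <- split(ex_all, S4Vectors::mcols(ex_all)$gene_id)
    genes <- unlist(GenomicRanges::GRangesList(lapply(sp, range)))
    ids <- names(genes)
    first <- match(ids, S4Vectors::mcols(ex_all)$gene_id)
    S4Vectors::mcols(genes)$gene_id <- ids
    S4Vectors::mcols(genes)$gene_name <-
      S4Vectors::mcols(ex_all)$gene_name[first]
    S4Vectors::mcols(genes)$gene_biotype <-
      S4Vectors::mcols(ex_all)$gene_biotype[first]
  }
  gene_md <- S4Vectors::mcols(genes)
  genes_out <- GenomicRanges::granges(genes)
  S4Vectors::mcols(genes_out) <- S4Vectors::DataFrame(
    gene_id = gene_md$gene_id, gene_name = gene_md$gene_name,
    biotype = gene_md$gene_biotype
  )

  feat <- list(
    three_prime_utr = gr[type == "three_prime_utr"],
    CDS = gr[type == "CDS"],
    five_prime_utr = gr[type == "five_prime_utr"]
  )

  # dialect with bare "UTR" records: side-classify against the CDS extent
  utr <- gr[type == "UTR"]
  if (length(utr) > 0 &&
      length(feat$three_prime_utr) + length(feat$five_prime_utr) == 0) {
    cds <- gr[type == "CDS"]
    cds_by_gene <- split(GenomicRanges::granges(cds),
                         S4Vectors::mcols(cds)$gene_id)
    cds_range <- unlist(GenomicRanges::GRangesList(lapply(cds_by_gene, range)))
    idx <- match(S4Vectors::mcols(utr)$gene_id, names(cds_range))
    ok <- !is.na(idx)
    utr <- utr[ok]; idx <- idx[ok]
    minus <- as.character(GenomicRanges::strand(utr)) == "-"
    after_cds <- GenomicRanges::start(utr) >= GenomicRanges::end(cds_range)[idx]
    is3 <- ifelse(minus, !after_cds &
                    GenomicRanges::end(utr) <= GenomicRanges::start(cds_range)[idx],
                  after_cds)
    feat$three_prime_utr <- utr[is3]
    feat$five_prime_utr <- utr[!is3]
  }

  exons <- gr[type == "exon"]
  introns <- derive_introns(genes_out, exons)

  mk <- function(g, label) {
    out <- GenomicRanges::granges(g)
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      feature = if (length(out)) rep(label, length(out)) else character(),
      gene_id = if (length(out)) as.character(S4Vectors::mcols(g)$gene_id)
                else character()
    )
    out
  }
  features <- c(
    mk(feat$three_prime_utr, "3'UTR"),
    mk(feat$CDS, "CDS"),
    mk(feat$five_prime_utr, "5'UTR"),
    introns
  )
  structure(list(genes = genes_out, features = features),
            class = "parclip_feature_index")
}

derive_introns <- function(genes, exons) {
  if (length(exons) == 0 || length(genes) == 0) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(feature = character(),
                                                  gene_id = character())
    return(out)
  }
  ex_by_gene <- split(GenomicRanges::granges(exons),
                      S4Vectors::mcols(exons)$gene_id)
  ids <- S4Vectors::mcols(genes)$gene_id
  pieces <- lapply(seq_along(genes), function(i) {
    exu <- ex_by_gene[[ids[i]]]
    if (is.null(exu)) return(GenomicRanges::granges(genes[i]))
    GenomicRanges::setdiff(GenomicRanges::granges(genes[i]),
                           GenomicRanges::reduce(exu),
                           ignore.strand = FALSE)
  })
  n <- vapply(pieces, length, integer(1))
  out <- unlist(GenomicRanges::GRangesList(pieces))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    feature = rep("intron", sum(n)), gene_id = rep(ids, n)
  )
  out
}

#' Annotate intervals against a feature index
#'
#' Strand-matched, minimum 1 bp overlap. An interval overlapping more than
#' one distinct gene is tagged `multigenic`; one overlapping a single
#' non-protein-coding gene gets that gene's biotype (miRNA, rRNA, lncRNA,
#' ...); one overlapping a single coding gene gets the highest-priority
#' feature it touches, in the order 3'UTR > CDS > 5'UTR > intron; no gene
#' overlap yields `intergenic` with gene fields `"."`.
#'
#' @param intervals A tibble with `chrom`, `start`, `end`, `strand`
#'   (0-based half-open); extra columns pass through.
#' @param index A `parclip_feature_index` from [build_feature_index()].
#' @param stranded Require matching strand for overlap (default `TRUE`).
#' @return `intervals` with appended columns `feature`, `gene_name`,
#'   `gene_id`, row order preserved.
#' @export
annotate_intervals <- function(intervals, index, stranded = TRUE) {
  stopifnot(inherits(index, "parclip_feature_index"))
  out <- tibble::as_tibble(intervals)
  out$feature <- "intergenic"
  out$gene_name <- "."
  out$gene_id <- "."
  if (nrow(out) == 0) return(out)

  gr <- intervals_to_granges(out)
  gh <- GenomicRanges::findOverlaps(gr, index$genes,
                                    ignore.strand = !stranded)
  if (length(gh) == 0) return(out)
  gmd <- S4Vectors::mcols(index$genes)
  hits <- tibble::tibble(
    q = S4Vectors::queryHits(gh),
    gene_id = gmd$gene_id[S4Vectors::subjectHits(gh)],
    gene_name = gmd$gene_name[S4Vectors::subjectHits(gh)],
    biotype = gmd$biotype[S4Vectors::subjectHits(gh)]
  ) %>% dplyr::distinct(.data$q, .data$gene_id, .keep_all = TRUE)

  per_q <- hits %>%
    dplyr::group_by(.data$q) %>%
    dplyr::summarise(n_genes = dplyr::n(),
                     gene_id = .data$gene_id[1],
                     gene_name = .data$gene_name[1],
                     biotype = .data$biotype[1], .groups = "drop")

  multi <- per_q$n_genes > 1
  out$feature[per_q$q[multi]] <- "multigenic"
  out$gene_name[per_q$q[multi]] <- "."
  out$gene_id[per_q$q[multi]] <- "."

  single <- per_q[!multi, , drop = FALSE]
  if (nrow(single) > 0) {
    out$gene_id[single$q] <- single$gene_id
    out$gene_name[single$q] <- single$gene_name
    noncoding <- single$biotype != "protein_coding"
    out$feature[single$q[noncoding]] <- single$biotype[noncoding]

    coding <- single[!noncoding, , drop = FALSE]
    if (nrow(coding) > 0) {
      fh <- GenomicRanges::findOverlaps(gr[coding$q], index$features,
                                        ignore.strand = !stranded)
      fmd <- S4Vectors::mcols(index$features)
      prio <- c(`3'UTR` = 1L, CDS = 2L, `5'UTR` = 3L, intron = 4L)
      fhits <- tibble::tibble(
        i = S4Vectors::queryHits(fh),
        feature = fmd$feature[S4Vectors::subjectHits(fh)],
        f_gene = fmd$gene_id[S4Vectors::subjectHits(fh)]
      )
      fhits <- fhits[fhits$f_gene == coding$gene_id[fhits$i], , drop = FALSE]
      if (nrow(fhits) > 0) {
        best <- fhits %>%
          dplyr::group_by(.data$i) %>%
          dplyr::summarise(feature = .data$feature[which.min(prio[.data$feature])],
                           .groups = "drop")
        out$feature[coding$q[best$i]] <- best$feature
      }
      # coding gene hit but none of its typed features: fall back to intron
      missed <- setdiff(seq_len(nrow(coding)),
                        if (nrow(fhits)) unique(fhits$i) else integer())
      out$feature[coding$q[missed]] <- "intron"
    }
  }
  out
}

#' Annotate a BED6 file against a GTF
#'
#' Reads a 6-column BED, annotates every row, and writes a 9-column file:
#' the input columns 1-6 in their original order plus `feature`,
#' `gene_name`, `gene_id`.
#'
#' @param bed Path to a BED6 file.
#' @param gtf Path to the annotation GTF (plain or gzipped).
#' @param out Output path.
#' @param stranded Passed to [annotate_intervals()].
#' @return The annotated tibble, invisibly; the file is the main product.
#' @export
annotate_bed <- function(bed, gtf, out, stranded = TRUE) {
  iv <- read_bed6(bed)
  idx <- build_feature_index(gtf)
  ann <- annotate_intervals(iv, idx, stranded = stranded)
  readr::write_tsv(ann[, c("chrom", "start", "end", "name", "score",
                           "strand", "feature", "gene_name", "gene_id")],
                   out, col_names = FALSE)
  invisible(ann)
}

#' Read a BED6 file as a tibble
#'
#' @param path BED file with at least 6 columns; extra columns are kept as
#'   `X7`, `X8`, ...
#' @return A tibble with `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed6 <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (nrow(df) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          score = character(), strand = character()))
  }
  if (ncol(df) < 6)
    stop("not a BED6 file (", ncol(df), " columns): ", path, call. = FALSE)
  s <- suppressWarnings(as.integer(df$X2))
  e <- suppressWarnings(as.integer(df$X3))
  bad <- which(is.na(s) | is.na(e) | !(df$X6 %in% c("+", "-", ".")))
  if (length(bad) > 0)
    stop("malformed BED line ", bad[1], " in ", path, call. = FALSE)
  out <- tibble::tibble(chrom = df$X1, start = s, end = e, name = df$X4,
                        score = df$X5, strand = df$X6)
  extra <- setdiff(names(df), paste0("X", 1:6))
  for (nm in extra) out[[nm]] <- df[[nm]]
  out
}
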