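test_that("substitution spectrum counts strand-local mismatch types", {
  # reads identical to reference: all 12 counts zero
  refs <- list(chr1 = "ACGTACGTACGTACGTACGT")
  reads <- tibble::tibble(qname = "r1", flag = 0L, chrom = "chr1", pos = 1L,
                          mapq = 60L, seq = "ACGTACGT", qual = "IIIIIIII")
  fx <- fixture_bam(reads, refs)
  sp <- substitution_spectrum(fx$bam, fx$fasta)
  expect_equal(nrow(sp), 12)
  expect_true(all(sp$count == 0))

  # single T-to-C at a reference T
  reads2 <- tibble::tibble(qname = "r1", flag = 0L, chrom = "chr1", pos = 1L,
                           mapq = 60L, seq = "ACGCACGT", qual = "IIIIIIII")
  fx2 <- fixture_bam(reads2, refs)
  sp2 <- substitution_spectrum(fx2$bam, fx2$fasta)
  expect_equal(sp2$count[sp2$ref_base == "T" & sp2$read_base == "C"], 1L)
  expect_equal(sum(sp2$count), 1L)

  # reverse-strand A>G in reference space counts as strand-local T>C
  reads3 <- tibble::tibble(qname = "r1", flag = 16L, chrom = "chr1",
                           pos = 1L, mapq = 60L, seq = "GCGTACGT",
                           qual = "IIIIIIII")
  fx3 <- fixture_bam(reads3, refs)
  sp3 <- substitution_spectrum(fx3$bam, fx3$fasta)
  expect_equal(sp3$count[sp3$ref_base == "T" & sp3$read_base == "C"], 1L)
})

test_that("spectrum totals agree with the mismatch tracks at equal filters", {
  set.seed(14)
  refs <- random_reference(len = 150)
  reads <- random_fixture_reads(refs, 40)
  fx <- fixture_bam(reads, refs)
  sp <- substitution_spectrum(fx$bam, fx$fasta)
  tr <- build_tracks(fx$bam, fx$fasta)
  expect_equal(sum(sp$count), sum(tr$t2c) + sum(tr$other_mm))
  expect_equal(attr(sp, "total_bases"), sum(tr$depth))
  expect_s3_class(autoplot(sp), "ggplot")
})

test_that("simulated PAR-CLIP data makes T-to-C the modal substitution", {
  d <- withr::local_tempdir()
  cfg <- sim_config(seed = 21, genome_length = 8000, n_sites = 12,
                    background_depth = 4)
  sim <- simulate_parclip(cfg, file.path(d, "s"))
  sp <- substitution_spectrum(sim$paths$bam, sim$paths$fasta)
  t2c_row <- sp$ref_base == "T" & sp$read_base == "C"
  expect_equal(which.max(sp$count), which(t2c_row))
  expect_gt(sp$fraction[t2c_row], 0.5)
})

test_that("CPM export scales raw counts by 1e6 / library size", {
  tr <- parclipr:::new_parclip_tracks(tibble::tibble(
    chrom = "chr1", pos = c(5L, 9L), strand = "+", ref_base = "T",
    depth = c(4L, 2L), t2c = c(1L, 0L), other_mm = c(0L, 2L)
  ))
  d <- withr::local_tempdir()
  raw <- file.path(d, "raw.bg"); cpm <- file.path(d, "cpm.bg")
  export_mismatch_track(tr, "T2C", "raw", out = raw, strand = "+")
  export_mismatch_track(tr, "T2C", "CPM", library_size = 2e6, out = cpm,
                        strand = "+")
  v_raw <- rtracklayer::import(raw, format = "bedGraph")
  v_cpm <- rtracklayer::import(cpm, format = "bedGraph")
  expect_equal(v_raw$score, 1)
  expect_equal(v_cpm$score, 0.5)   # 1 * 1e6 / 2e6
  expect_equal(GenomicRanges::start(v_cpm), 6L)

  # zero-signal track writes an empty file
  none <- file.path(d, "none.bg")
  export_mismatch_track(tr[tr$t2c < 0, ], "T2C", "raw", out = none,
                        strand = "+")
  expect_equal(length(grep("^track", readLines(none), invert = TRUE)), 0)

  # bigWig requested without chrom sizes falls back to bedGraph
  expect_warning(
    export_mismatch_track(tr, "T2C", "raw", out = file.path(d, "x.bw"),
                          strand = "+"),
    "chromosome-sizes"
  )
  expect_true(file.exists(file.path(d, "x.bedGraph")))
})

test_that("compare_beds counts overlap combinations", {
  a <- tibble::tibble(chrom = "chr1", start = c(0L, 100L), end = c(50L, 150L),
                      name = "x", score = 0L, strand = "+")
  # a vs itself: everything in the intersection
  self <- compare_beds(list(a = a, b = a))
  per <- self[self$view == "per_set", ]
  expect_true(all(per$combination == "a&b"))
  expect_equal(sum(per$count), 4)

  # disjoint sets: nothing shared
  b <- dplyr::mutate(a, start = start + 1000L, end = end + 1000L)
  dis <- compare_beds(list(a = a, b = b))
  expect_false(any(grepl("&", dis$combination[dis$count > 0])))

  # strand-matched: antisense intervals do not overlap
  c_ <- dplyr::mutate(a, strand = "-")
  anti <- compare_beds(list(a = a, b = c_))
  expect_false(any(grepl("&", anti$combination[anti$count > 0])))

  expect_error(compare_beds(list(a, a, a, a)), "highest limit")
})

test_that("3-set coordinate counts match a brute-force sweep oracle", {
  set.seed(17)
  mk <- function(n) {
    s <- sample(0:400, n)
    tibble::tibble(chrom = "chr1", start = s, end = s + sample(5:30, n, TRUE),
                   name = "x", score = 0L, strand = "+")
  }
  sets <- list(a = mk(15), b = mk(12), c = mk(18))
  got <- compare_beds(sets)
  per <- got[got$view == "per_set", ]
  ov <- function(iv, set) {
    any(iv$start < set$end & iv$end > set$start)
  }
  for (nm in names(sets)) {
    for (i in seq_len(nrow(sets[[nm]]))) {
      iv <- sets[[nm]][i, ]
      memb <- names(sets)[vapply(sets, function(s) ov(iv, s), TRUE)]
      cmb <- paste(memb, collapse = "&")
      row <- per[per$set == nm & per$combination == cmb, ]
      expect_equal(nrow(row), 1)
    }
    # every interval of the set is in exactly one combination
    expect_equal(sum(per$count[per$set == nm]), nrow(sets[[nm]]))
  }
  # symmetry under permutation up to relabeling
  perm <- compare_beds(sets[c("c", "a", "b")])
  expect_equal(sum(perm$count[perm$view == "per_set"]),
               sum(per$count))
})

test_that("gene mode does set algebra over gene identifiers", {
  mk <- function(genes) {
    tibble::tibble(chrom = "chr1", start = 0L, end = 10L, name = "x",
                   score = 0L, strand = "+", feature = "CDS",
                   gene_name = genes, gene_id = genes)
  }
  out <- compare_beds(list(a = mk(c("g1", "g2", "g3")),
                           b = mk(c("g2", "g3", "g4"))), mode = "gene")
  expect_equal(out$count[out$combination == "a&b"], 2L)
  expect_equal(out$count[out$combination == "a"], 1L)
  expect_equal(out$count[out$combination == "b"], 1L)
})

test_that("per-gene T-to-C matrix and correlation are computed correctly", {
  s1 <- tibble::tibble(gene_id = c("g1", "g1", "g2", "g3"),
                       o_t2c = c(3, 2, 8, 1))
  s2 <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                       o_t2c = c(4, 9, 3))
  out <- gene_t2c_matrix(list(A = s1, B = s2), method = "pearson")
  expect_equal(out$matrix$A[out$matrix$gene == "g1"], 5)
  # hand-computed Pearson correlation of (5,8,1) vs (4,9,3)
  expect_equal(out$correlation["A", "B"],
               stats::cor(c(5, 8, 1), c(4, 9, 3)), tolerance = 1e-12)

  # duplicated sample: off-diagonal 1
  dup <- gene_t2c_matrix(list(A = s1, B = s1))
  expect_equal(unname(dup$correlation["A", "B"]), 1)

  # one sample: 1x1 unit matrix
  one <- gene_t2c_matrix(list(A = s1))
  expect_equal(dim(one$correlation), c(1L, 1L))
  expect_equal(unname(one$correlation[1, 1]), 1)

  # a gene absent from one sample counts zero there
  s3 <- tibble::tibble(gene_id = "g9", o_t2c = 5)
  z <- gene_t2c_matrix(list(A = s1, B = s3))
  expect_equal(z$matrix$B[z$matrix$gene == "g1"], 0)

  expect_error(gene_t2c_matrix(list(A = s1[0, ], B = s2[0, ])), "gene")
  expect_s3_class(autoplot(out), "ggplot")
})
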