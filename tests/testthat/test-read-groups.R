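cov_track <- function(depths, strand = "+", chrom = "chr1") {
  keep <- depths > 0
  parclipr:::new_parclip_tracks(tibble::tibble(
    chrom = chrom, pos = which(keep) - 1L, strand = strand, ref_base = "A",
    depth = as.integer(depths[keep]), t2c = 0L, other_mm = 0L
  ))
}

test_that("extract_regions thresholds depth into maximal runs", {
  tr <- cov_track(c(0, 0, 3, 4, 5, 0, 2, 3))
  out <- extract_regions(tr, min_depth = 3)
  expect_equal(out$start, c(2L, 7L))
  expect_equal(out$end, c(5L, 8L))

  expect_equal(nrow(extract_regions(cov_track(rep(0, 10)), 3)), 0)

  # min_depth 1 recovers the covered footprint exactly
  d <- c(0, 1, 2, 0, 0, 5, 1, 0, 2)
  out <- extract_regions(cov_track(d), 1)
  covered <- sort(unlist(Map(seq, out$start, out$end - 1)))
  expect_equal(covered, which(d > 0) - 1L)
})

test_that("merge_adjacent unions book-ended and gapped intervals", {
  iv <- tibble::tibble(chrom = "chr1", start = c(10L, 20L), end = c(20L, 30L),
                       strand = "+")
  out <- merge_adjacent(iv, gap = 0)
  expect_equal(out$start, 10L)
  expect_equal(out$end, 30L)

  iv2 <- tibble::tibble(chrom = "chr1", start = c(10L, 25L),
                        end = c(20L, 30L), strand = "+")
  expect_equal(merge_adjacent(iv2, gap = 0), iv2)
  expect_equal(nrow(merge_adjacent(iv2, gap = 5)), 1)

  # strands never merge across each other
  iv3 <- tibble::tibble(chrom = "chr1", start = c(10L, 20L),
                        end = c(20L, 30L), strand = c("+", "-"))
  expect_equal(nrow(merge_adjacent(iv3)), 2)
})

test_that("merge_adjacent matches a brute-force union oracle on random sets", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    start <- sort(sample(0:200, n, replace = TRUE))
    iv <- tibble::tibble(chrom = "chr1", start = start,
                         end = start + sample(1:20, n, replace = TRUE),
                         strand = "+")
    gap <- sample(0:3, 1)
    got <- merge_adjacent(iv, gap)
    # oracle: sequential sweep over start-sorted intervals
    merged <- list(); cur <- NULL
    for (j in seq_len(n)) {
      if (is.null(cur)) cur <- c(iv$start[j], iv$end[j])
      else if (iv$start[j] - cur[2] <= gap) cur[2] <- max(cur[2], iv$end[j])
      else { merged <- c(merged, list(cur)); cur <- c(iv$start[j], iv$end[j]) }
    }
    merged <- c(merged, list(cur))
    want <- do.call(rbind, merged)
    expect_equal(got$start, want[, 1])
    expect_equal(got$end, want[, 2])
  }
})

test_that("split_max_width tiles exactly with near-equal pieces", {
  one <- tibble::tibble(chrom = "chr1", start = 0L, end = 40L, strand = "+")
  expect_equal(split_max_width(one, 50), one)

  wide <- tibble::tibble(chrom = "chr1", start = 0L, end = 120L, strand = "+")
  out <- split_max_width(wide, 50)
  expect_equal(out$start, c(0L, 40L, 80L))
  expect_equal(out$end, c(40L, 80L, 120L))

  set.seed(4)
  for (i in 1:30) {
    L <- sample(1:400, 1)
    s <- sample(0:1000, 1)
    iv <- tibble::tibble(chrom = "c", start = s, end = s + L, strand = "+")
    mw <- sample(1:60, 1)
    out <- split_max_width(iv, mw)
    w <- out$end - out$start
    expect_true(all(w <= mw))
    expect_true(max(w) - min(w) <= 1)                  # near-equal
    expect_equal(nrow(out), ceiling(L / mw))
    expect_equal(out$start[-1], out$end[-nrow(out)])   # contiguous tiling
    expect_equal(out$start[1], s)
    expect_equal(out$end[nrow(out)], s + L)
  }
})

test_that("quantify_groups sums track columns per interval", {
  tr <- parclipr:::new_parclip_tracks(tibble::tibble(
    chrom = "chr1", pos = 10:12, strand = "+", ref_base = "T",
    depth = c(3L, 4L, 5L), t2c = c(0L, 2L, 1L), other_mm = c(1L, 0L, 0L)
  ))
  iv <- tibble::tibble(chrom = "chr1", start = 10L, end = 13L, strand = "+")
  out <- quantify_groups(iv, tr)
  expect_equal(out$n_bases, 12L)
  expect_equal(out$o_t2c, 3L)
  expect_equal(out$other_mm, 1L)
  expect_equal(out$max_depth, 5L)
  expect_equal(out$score, out$o_t2c)
  expect_true(out$covered)

  # uncovered interval: zero metrics, flagged
  far <- tibble::tibble(chrom = "chr1", start = 100L, end = 110L,
                        strand = "+")
  out <- quantify_groups(far, tr)
  expect_equal(out$n_bases, 0L)
  expect_false(out$covered)

  expect_equal(nrow(quantify_groups(iv[0, ], tr)), 0)

  # strand mismatch contributes nothing
  minus_iv <- tibble::tibble(chrom = "chr1", start = 10L, end = 13L,
                             strand = "-")
  expect_equal(quantify_groups(minus_iv, tr)$n_bases, 0L)
})

test_that("group sums match a per-position loop oracle on random tracks", {
  set.seed(12)
  for (i in 1:10) {
    pos <- sort(sample(0:300, 150))
    tr <- parclipr:::new_parclip_tracks(tibble::tibble(
      chrom = "chr1", pos = pos, strand = "+", ref_base = "T",
      depth = sample(1:8, 150, replace = TRUE),
      t2c = sample(0:3, 150, replace = TRUE),
      other_mm = sample(0:2, 150, replace = TRUE)
    ))
    iv <- extract_regions(tr, 2) |> merge_adjacent() |> split_max_width(25)
    got <- quantify_groups(iv, tr)
    for (j in sample(nrow(iv), min(5, nrow(iv)))) {
      sel <- tr$pos >= iv$start[j] & tr$pos < iv$end[j]
      expect_equal(got$n_bases[j], sum(tr$depth[sel]))
      expect_equal(got$o_t2c[j], sum(tr$t2c[sel]))
      expect_equal(got$other_mm[j], sum(tr$other_mm[sel]))
    }
    # groups on one strand never overlap
    expect_true(all(iv$start[-1] >= iv$end[-nrow(iv)]))
  }
})
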