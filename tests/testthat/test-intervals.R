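test_that("BED parsing maps fields, preserves order, and reports bad lines", {
  x <- read_bed(c("chr1\t100\t300\tpk1", "chr2\t0\t50"), text = TRUE)
  expect_equal(x$chrom, c("chr1", "chr2"))
  expect_equal(x$start, c(100, 0))
  expect_equal(x$end, c(300, 50))
  expect_equal(x$name, c("pk1", NA))

  expect_equal(nrow(read_bed(character(), text = TRUE)), 0L)
  expect_equal(nrow(read_bed(c("# c", "track name=x"), text = TRUE)), 0L)

  expect_error(read_bed("chr1\t300\t100", text = TRUE), "line 1")
  expect_error(read_bed(c("chr1\t0\t10", "chr1\t5"), text = TRUE), "line 2")
  expect_error(read_bed("chr1\tx\t100", text = TRUE), "line 1")
})

test_that("BED round-trips through write and read", {
  withr::with_seed(1, {
    n <- 40
    x <- intervals(sample(c("chr1", "chr2"), n, TRUE),
                   start = sample(0:5000, n),
                   name = sprintf("p%d", 1:n),
                   strand = sample(c("+", "-", "."), n, TRUE),
                   end = 0)
    x$end <- x$start + sample(1:500, n)
  })
  f <- withr::local_tempfile()
  write_bed(x, f)
  expect_equal(read_bed(f), x)
})

test_that("centre windows are centre-anchored, clamped, and width-stable", {
  expect_equal(
    center_window(intervals("chr1", 100, 106), 100)[, c("start", "end")],
    tibble::tibble(start = 3, end = 203))
  # clamped at both chromosome edges, never discarded
  clamped <- center_window(intervals("chr1", 0, 6), 100,
                           chrom_sizes = c(chr1 = 10000))
  expect_equal(c(clamped$start, clamped$end), c(0, 103))
  hi <- center_window(intervals("chr1", 9990, 10000), 100,
                      chrom_sizes = c(chr1 = 10000))
  expect_equal(c(hi$start, hi$end), c(9895, 10000))
  # already centred at that width: identity
  same <- center_window(intervals("chr1", 100, 300), 100)
  expect_equal(c(same$start, same$end), c(100, 300))
})

test_that("overlap removal drops exclusion hits and whole mutual clusters", {
  loci <- intervals("chr1", c(0, 500), c(200, 700))
  kept <- remove_overlapping(loci, intervals("chr1", 150, 160))
  expect_equal(kept$start, 500)

  # half-open: touching intervals share no bp
  expect_equal(nrow(remove_overlapping(intervals("chr1", 0, 100),
                                       intervals("chr1", 100, 200))), 1L)

  # both members of a mutually overlapping pair are dropped
  loci <- intervals("chr1", c(0, 199, 600), c(200, 399, 800))
  kept <- remove_overlapping(loci, loci[0, ], remove_mutual = TRUE)
  expect_equal(kept$start, 600)
})

test_that("overlap removal result is clean under an exhaustive pairwise scan", {
  withr::with_seed(4, {
    for (rep in 1:5) {
      loci <- intervals("chr1", s <- sample(0:3000, 60), s + sample(50:200, 60, TRUE))
      excl <- intervals("chr1", s2 <- sample(0:3000, 15), s2 + 100)
      kept <- remove_overlapping(loci, excl, remove_mutual = TRUE)
      pair_ov <- function(a, b) a$start < b$end & b$start < a$end
      for (i in seq_len(nrow(kept))) {
        expect_false(any(pair_ov(kept[i, ], excl)))
        others <- kept[-i, ]
        if (nrow(others) > 0) expect_false(any(pair_ov(kept[i, ], others)))
      }
    }
  })
})

test_that("random regions honour width, bounds, seed, and length-proportional sampling", {
  sizes <- tibble::tibble(chrom = c("cA", "cB"), size = c(1e6, 3e6))
  expect_equal(nrow(sample_random_regions(sizes, 0, 200)), 0L)
  a <- sample_random_regions(sizes, 500, 200, seed = 9)
  b <- sample_random_regions(sizes, 500, 200, seed = 9)
  expect_identical(a, b)
  expect_true(all(a$end - a$start == 200))
  sz <- sizes$size[match(a$chrom, sizes$chrom)]
  expect_true(all(a$start >= 0 & a$end <= sz))

  big <- sample_random_regions(sizes, 10000, 200, seed = 10)
  p <- 3 / 4  # expected share on the 3 Mb chromosome
  phat <- mean(big$chrom == "cB")
  expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / 10000))

  expect_error(sample_random_regions(sizes, 5, 5e6), "width exceeds")
})

test_that("TSS proximity uses centre distance with an inclusive threshold", {
  tss <- tibble::tibble(chrom = "chr1", pos = c(5600, 6200), gene = c("g1", "g2"),
                        strand = "+")
  peaks <- intervals("chr1", c(4900, 4900), c(5100, 5100))
  res <- classify_tss_proximity(peaks, tss)
  expect_equal(res$tss_class[1], "TSS")  # 600 <= 1000
  res2 <- classify_tss_proximity(intervals("chr1", 4900, 5100),
                                 tibble::tibble(chrom = "chr1", pos = 6200,
                                                gene = "g", strand = "+"))
  expect_equal(res2$tss_class, "non-TSS")
  res3 <- classify_tss_proximity(intervals("chr1", 4900, 5100),
                                 tibble::tibble(chrom = "chr1", pos = 5000,
                                                gene = "g", strand = "+"))
  expect_equal(res3$tss_dist, 0)
  expect_equal(res3$tss_class, "TSS")
  expect_warning(out <- classify_tss_proximity(peaks, tss[0, ]), "non-TSS")
  expect_true(all(out$tss_class == "non-TSS"))
})

test_that("peak-to-gene assignment respects the distance cap and tie-breaks", {
  peak <- intervals("chr1", 9900, 10100)
  tss <- tibble::tibble(chrom = "chr1", pos = c(15000, 130000),
                        gene = c("geneA", "geneB"), strand = "+")
  expect_equal(assign_peaks_to_genes(peak, tss)$gene, "geneA")
  far <- tibble::tibble(chrom = "chr1", pos = 115000, gene = "geneX", strand = "+")
  expect_true(is.na(assign_peaks_to_genes(peak, far)$gene))
  # equidistant: smaller coordinate wins, then name
  tie <- tibble::tibble(chrom = "chr1", pos = c(9000, 11000),
                        gene = c("geneA", "geneB"), strand = "+")
  expect_equal(assign_peaks_to_genes(peak, tie)$gene, "geneA")
  tie2 <- tibble::tibble(chrom = "chr1", pos = c(9000, 9000),
                         gene = c("geneZ", "geneB"), strand = "+")
  expect_equal(assign_peaks_to_genes(peak, tie2)$gene, "geneB")
})

test_that("peak-set comparison partitions both inputs and allows multi-overlap", {
  ov <- compare_peak_sets(intervals("chr1", 0, 100), intervals("chr1", 50, 150))
  expect_equal(nrow(ov$shared_a), 1L)
  expect_equal(nrow(ov$b_only), 0L)

  ov2 <- compare_peak_sets(intervals("chr1", 0, 100), intervals("chr1", 200, 300))
  expect_equal(nrow(ov2$a_only), 1L)
  expect_equal(nrow(ov2$b_only), 1L)

  ov3 <- compare_peak_sets(intervals("chr1", c(0, 90), c(100, 180)),
                           intervals("chr1", 95, 96))
  expect_equal(nrow(ov3$shared_a), 2L)

  withr::with_seed(2, {
    a <- intervals("chr1", s <- sample(0:9000, 80), s + 150)
    b <- intervals("chr1", s2 <- sample(0:9000, 60), s2 + 150)
  })
  ov4 <- compare_peak_sets(a, b)
  expect_equal(nrow(ov4$shared_a) + nrow(ov4$a_only), nrow(a))
  expect_equal(nrow(ov4$shared_b) + nrow(ov4$b_only), nrow(b))
  expect_equal(sum(tidy(ov4)$n), nrow(a) + nrow(b))
})
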