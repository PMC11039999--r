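test_that("consensus scanning handles strands, palindromes, and N correctly", {
  # palindromic AP-1 heptamer: one collapsed site on +
  ap1 <- scan_motif("TGACTCA", "TGASTCA")
  expect_equal(nrow(ap1), 1L)
  expect_equal(c(ap1$start, ap1$strand), c("0", "+"))
  # without collapsing the physical site appears once per strand
  expect_equal(nrow(scan_motif("TGACTCA", "TGASTCA", collapse_palindromes = FALSE)), 2L)

  fwd <- scan_motif("AGATAA", "WGATAR")
  expect_equal(c(fwd$start, fwd$strand, fwd$name), c("0", "+", "AGATAA"))

  rev <- scan_motif("TTATCT", "WGATAR")
  expect_equal(c(rev$start, rev$strand, rev$name), c("0", "-", "AGATAA"))

  # genome N satisfies no non-N pattern code
  expect_equal(nrow(scan_motif("NGATAN", "WGATAR")), 0L)
  expect_error(scan_motif("ACGT", "WGAXAR"), "IUPAC")
})

test_that("scanner agrees with the regex oracle on random sequences", {
  patterns <- c("WGATAR", "TGASTCA", "CANNTG", "TTGACW", "VHDB", "GGGCGG")
  withr::with_seed(13, {
    for (rep in 1:10) {
      seq <- random_seq(10000, with_n = TRUE)
      for (pat in patterns) {
        got <- scan_motif(seq, pat)
        want <- oracle_scan(seq, pat)
        expect_equal(as.integer(got$start), want$start,
                     info = sprintf("%s rep %d", pat, rep))
        expect_equal(got$strand, want$strand, info = pat)
      }
    }
  })
})

test_that("sampling loci exclude ChIP peaks and mutually overlapping windows", {
  sites <- intervals("chr1", c(1000, 5000, 5150), c(1006, 5006, 5156))
  # lone site far from peaks: one 200 bp locus
  lone <- build_sampling_loci(sites[1, ], intervals("chr1", 1, 2)[0, ])
  expect_equal(lone$end - lone$start, 200)
  # window overlapping a ChIP peak by 1 bp is removed
  peak_touch <- intervals("chr1", 1102, 1200)  # locus is [903, 1103)
  expect_equal(nrow(build_sampling_loci(sites[1, ], peak_touch)), 0L)
  peak_clear <- intervals("chr1", 1103, 1200)
  expect_equal(nrow(build_sampling_loci(sites[1, ], peak_clear)), 1L)
  # two sites 150 bp apart: windows overlap, both removed
  both <- build_sampling_loci(sites, intervals("chr1", 1, 2)[0, ])
  expect_equal(both$start, 903)

  withr::with_seed(21, {
    ms <- intervals("chr1", s <- sample(500:20000, 150), s + 6)
    pk <- intervals("chr1", s2 <- sample(500:20000, 30), s2 + 300)
  })
  loci <- build_sampling_loci(ms, pk)
  hits_peak <- vapply(seq_len(nrow(loci)), function(i)
    any(loci$start[i] < pk$end & pk$start < loci$end[i]), NA)
  expect_false(any(hits_peak))
  ov_self <- vapply(seq_len(nrow(loci)), function(i)
    sum(loci$start[i] < loci$end & loci$start < loci$end[i]), 0)
  expect_true(all(ov_self == 1))  # only the self-overlap
})

test_that("Mann-Whitney U matches exhaustive pair enumeration", {
  mw <- mann_whitney_u(c(5, 6, 7), c(1, 2, 3))
  expect_equal(mw$U, 9)  # complete separation of 3 x 3 pairs
  expect_equal(mw$U, oracle_U(c(5, 6, 7), c(1, 2, 3)))

  same <- mann_whitney_u(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$U, 9 / 2)
  expect_true(same$degenerate)
  expect_equal(same$p, 1)

  withr::with_seed(17, {
    for (rep in 1:25) {
      n1 <- sample(1:8, 1); n2 <- sample(1:8, 1)
      x <- sample(0:10, n1, replace = TRUE)
      y <- sample(0:10, n2, replace = TRUE)
      expect_equal(mann_whitney_u(x, y)$U, oracle_U(x, y))
    }
  })
  # shifting one group onto the other gives the central U
  x <- c(1, 4, 9); y <- x + 2
  expect_equal(mann_whitney_u(x, y - 2)$U, length(x) * length(y) / 2)
})

test_that("enrichment report separates signal loci from background", {
  loci <- intervals("chr1", c(100, 400, 700), c(300, 600, 900))
  bg <- intervals("chr1", c(2000, 2300, 2600), c(2200, 2500, 2800))
  ev <- events_at(c(rep(150, 5), rep(450, 6), rep(750, 7),
                    rep(2100, 1), rep(2400, 2), rep(2700, 3)))
  enr <- sampling_enrichment(ev, loci, bg)
  g <- glance(enr)
  expect_equal(g$U, 9)
  expect_equal(g$median_loci, 6)
  expect_equal(g$median_background, 2)
  expect_equal(nrow(tidy(enr)), 6L)
  expect_warning(sampling_enrichment(events_at(numeric(0)), loci, bg), "identical")
})

test_that("expected spacing matches exhaustive k-mer enumeration", {
  expect_equal(expected_motif_spacing("N"), 1)
  # degenerate GATA hexamer: 8 of 4096 k-mers match either strand
  expect_equal(oracle_kmer_matches("WGATAR"), 8)
  expect_equal(expected_motif_spacing("WGATAR"), 4096 / 8)
  # palindromic AP-1 consensus: forward and reverse-complement match sets
  # coincide, so collapsing halves the count (oracle decides the constant)
  expect_equal(oracle_kmer_matches("TGASTCA"), 2)
  expect_equal(oracle_kmer_matches("TGASTCA", collapse = FALSE), 4)
  expect_equal(expected_motif_spacing("TGASTCA"), 16384 / 2)
  expect_equal(expected_motif_spacing("TGASTCA", collapse_palindromes = FALSE),
               16384 / 4)
  # non-uniform base composition
  bf <- c(A = 0.4, C = 0.1, G = 0.1, T = 0.4)
  p_fwd <- 0.8 * 0.1 * 0.4 * 0.4 * 0.4 * 0.5
  expect_equal(expected_motif_spacing("WGATAR", base_freq = bf), 1 / (2 * p_fwd))
  expect_error(expected_motif_spacing("A", both_strands = FALSE,
                                      base_freq = c(A = 0, C = 0.5, G = 0.25, T = 0.25)),
               "zero")
})
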