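test_that("scale factor is target over total and rejects empty libraries", {
  expect_equal(scale_factor(5e6), 2)
  expect_equal(scale_factor(1e7), 1)
  expect_equal(scale_factor(2e7), 0.5)
  expect_error(scale_factor(0), "positive")
})

test_that("window counts follow half-open arithmetic and conserve totals", {
  ev <- events_at(c(175, 300))
  expect_equal(count_in_window(ev, intervals("chr1", 100, 200)), 1L)
  expect_equal(count_in_window(ev, intervals("chr1", 400, 500)), 0L)
  expect_equal(count_in_window(ev, intervals("chr1", 0, 1000)), 2L)
  # boundary: start inclusive, end exclusive
  expect_equal(count_in_window(events_at(c(100, 200)), intervals("chr1", 100, 200)), 1L)
})

test_that("signal matrix places one central event in the centre bin", {
  anchor <- intervals("chr1", 5000, 5100)  # centre 5050
  sm <- build_signal_matrix(events_at(5050), anchor, flank = 1000, bin = 10)
  expect_equal(dim(sm), c(1L, 200L))
  expect_equal(unname(which(sm$values[1, ] == 1)), 101L)  # bin [0,10) after the centre
  expect_equal(sum(sm$values), 1)

  empty <- suppressWarnings(build_signal_matrix(events_at(numeric(0)), anchor))
  expect_equal(sum(empty$values), 0)
  expect_error(build_signal_matrix(events_at(5050), anchor, flank = 1000, bin = 7),
               "divisible")
  expect_warning(build_signal_matrix(events_at(1, chrom = "chrX"), anchor), "zero")
})

test_that("signal matrix equals the naive per-position recount", {
  withr::with_seed(8, {
    anchors <- intervals("chr1", s <- sample(1500:8500, 50), s + sample(10:400, 50, TRUE))
    ev <- events_at(sample(0:9999, 4000, replace = TRUE))
  })
  sm <- build_signal_matrix(ev, anchors, flank = 500, bin = 25)
  expect_equal(unname(sm$values), oracle_matrix(ev, anchors, 500, 25))
  # doubling every event doubles every entry
  sm2 <- build_signal_matrix(dplyr::bind_rows(ev, ev), anchors, flank = 500, bin = 25)
  expect_equal(sm2$values, 2 * sm$values)
})

test_that("metaplot is the per-anchor mean and respects linear mixing", {
  sm <- build_signal_matrix(events_at(c(100, 140)),
                            intervals("chr1", c(95, 135), c(105, 145)),
                            flank = 20, bin = 10)
  prof <- metaplot(sm)
  expect_equal(prof$signal, unname(colMeans(sm$values)))
  # permutation invariance
  smp <- build_signal_matrix(events_at(c(100, 140)),
                             intervals("chr1", c(135, 95), c(145, 105)),
                             flank = 20, bin = 10)
  expect_equal(metaplot(smp)$signal, prof$signal)
  # single anchor: profile is that row
  one <- build_signal_matrix(events_at(100), intervals("chr1", 95, 105),
                             flank = 20, bin = 10)
  expect_equal(metaplot(one)$signal, unname(one$values[1, ]))
  expect_error(metaplot(build_signal_matrix(events_at(1), intervals("x", 1, 2)[0, ])),
               "empty")
})

test_that("reference normalization is a pseudocounted antisymmetric log2 ratio", {
  withr::with_seed(3, {
    anchors <- intervals("chr1", s <- sample(1000:8000, 10), s + 100)
    a <- events_at(sample(0:9999, 500, TRUE))
    b <- events_at(sample(0:9999, 800, TRUE))
  })
  ma <- build_signal_matrix(a, anchors, flank = 200, bin = 20)
  mb <- build_signal_matrix(b, anchors, flank = 200, bin = 20)
  self <- normalize_to_reference(ma, ma)
  expect_true(all(self$values == 0))
  expect_equal(self$units, "log2_ratio")
  expect_equal(log2((3 + 1) / (1 + 1)), 1)  # the defining arithmetic
  expect_equal(normalize_to_reference(ma, mb)$values,
               -normalize_to_reference(mb, ma)$values)
  short <- build_signal_matrix(a, anchors, flank = 200, bin = 40)
  expect_error(normalize_to_reference(ma, short), "match")
})

test_that("spacing estimation recovers the period of a synthetic phased profile", {
  offs <- seq(-995, 995, by = 10)
  prof <- tibble::tibble(offset = offs,
                         signal = cos(2 * pi * offs / 190) + 1)
  expect_equal(estimate_spacing(prof), 190)
})

test_that("bedGraph output is run-length merged and round-trips position sums", {
  f <- withr::local_tempfile()
  counter <- tibble::tibble(chrom = "chr1", pos = c(100, 101), count = c(2, 2))
  write_bedgraph(counter, f)
  expect_equal(readLines(f), "chr1\t100\t102\t2")

  write_bedgraph(events_at(numeric(0)), f)
  expect_equal(length(readLines(f)), 0L)

  withr::with_seed(5, ev <- events_at(sample(0:500, 2000, replace = TRUE)))
  write_bedgraph(ev, f, scale_factor = 0.5)
  bg <- read_bedgraph(f)
  expect_true(all(diff(bg$start) > 0))
  expect_equal(sum(bg$value * (bg$end - bg$start)), nrow(ev) * 0.5)
  # per-position recovery through the parser
  expanded <- rep(bg$value, bg$end - bg$start)
  names(expanded) <- unlist(Map(seq, bg$start, bg$end - 1))
  tab <- table(ev$pos)
  expect_equal(unname(expanded[names(tab)]), unname(as.numeric(tab) * 0.5))
})

test_that("matrix conservation: total equals in-window event multiplicity", {
  withr::with_seed(6, {
    anchors <- intervals("chr1", s <- sample(600:9000, 30), s + 50)
    ev <- events_at(sample(0:9999, 3000, TRUE))
  })
  sm <- build_signal_matrix(ev, anchors, flank = 500, bin = 10)
  win <- center_window(anchors, 500)
  expect_equal(sum(sm$values), sum(count_in_window(ev, win)))
})
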