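# Windowed normalized coverage ratios, the resampling band, window
# classification, and repeat density.

make_depth <- function(chrom, depths_by_sample, start_pos = 1L) {
  n <- length(depths_by_sample[[1]])
  dt <- data.table::data.table(chrom = chrom, pos = seq(start_pos, length.out = n))
  for (id in names(depths_by_sample)) dt[[id]] <- depths_by_sample[[id]]
  dt
}

test_that("window means follow the tiling and absent-position rules", {
  d <- make_depth("c1", list(S1 = rep(7L, 100)))
  wm <- window_means(d, w = 100)
  expect_equal(wm$S1, 7)

  # depth 10 over the first half of a window, nothing over the second
  d <- make_depth("c1", list(S1 = rep(10L, 50)))
  wm <- window_means(d, w = 100, chrom_lengths = c(c1 = 100))
  expect_equal(wm$S1, 5)

  # windows with no rows at all have mean 0; final partial window flagged
  d <- make_depth("c1", list(S1 = rep(2L, 100)))
  wm <- window_means(d, w = 40, chrom_lengths = c(c1 = 130))
  expect_equal(nrow(wm), 4)
  expect_equal(wm$S1, c(2, 2, 2 * 20 / 40, 0))
  expect_identical(wm$partial, c(FALSE, FALSE, FALSE, TRUE))
  expect_identical(wm$n_pos, c(40L, 40L, 20L, 0L))

  # unsorted input and unknown samples are rejected
  expect_error(window_means(d[c(2, 1, 3:100), ], w = 40), "not sorted")
  expect_error(window_means(d, w = 40, samples = zw_samples(1, 0)),
               "unknown sample")
})

test_that("normalization by the representative autosome scales and is idempotent", {
  s <- zw_samples(1, 1, 10)
  d <- data.table::data.table(
    chrom = rep(c("auto", "sexchr"), each = 100),
    pos = rep(1:100, 2),
    F01 = c(rep(20L, 100), rep(10L, 100)),
    M01 = c(rep(8L, 100), rep(8L, 100)))
  wm <- window_means(d, w = 100)
  norm <- normalize_samples(wm, s, "auto")
  # autosomal mean 20, window mean 10 -> 0.5
  expect_equal(norm$wm$F01[norm$wm$chrom == "sexchr"], 0.5)
  expect_equal(norm$samples$norm_factor, c(20, 8))
  # each sample's normalized autosome mean is 1
  expect_equal(norm$wm$F01[norm$wm$chrom == "auto"], 1, tolerance = 1e-9)
  expect_equal(norm$wm$M01[norm$wm$chrom == "auto"], 1, tolerance = 1e-9)

  # idempotence: normalizing an already-normalized table changes nothing
  norm2 <- normalize_samples(norm$wm, s, "auto")
  expect_equal(as.data.frame(norm2$wm), as.data.frame(norm$wm))

  # scale invariance: doubling one sample's whole track changes nothing
  d2 <- data.table::copy(d); d2$F01 <- d2$F01 * 2L
  norm3 <- normalize_samples(window_means(d2, w = 100), s, "auto")
  expect_equal(norm3$wm$F01, norm$wm$F01)

  # zero autosomal coverage errors with the sample named
  d0 <- data.table::copy(d); d0$M01[1:100] <- 0L
  expect_error(normalize_samples(window_means(d0, w = 100), s, "auto"), "M01")
})

test_that("log2 ratios have the hemizygous expectation and exact antisymmetry", {
  s <- zw_samples(2, 2, 10)
  wm <- data.table::data.table(
    chrom = "c1", start = c(0L, 100L, 200L, 300L), end = c(100L, 200L, 300L, 400L),
    partial = FALSE, n_pos = 100L,
    F01 = c(1, 0.5, 0.8, 0.01), F02 = c(1, 0.5, 0.8, 0.01),
    M01 = c(1, 1, 0.6, 0.02), M02 = c(1, 1, 0.6, 0.02))
  win <- fm_log2_ratio(wm, s, eps = 0.001, floor = 0.1)
  # equal group means -> 0
  expect_equal(win$log2_ratio[1], 0)
  # hemizygous Z-specific expectation: 0.5 vs 1.0 -> ~ -1
  expect_equal(win$log2_ratio[2], -1, tolerance = 0.005)
  # both groups under the floor -> missing
  expect_identical(win$class[4], "missing")
  expect_true(is.na(win$log2_ratio[4]))

  # swapping sex labels negates every nonmissing value exactly
  s_swap <- s; s_swap$sex <- rev(s_swap$sex)
  data.table::setnames(wm, c("F01", "F02", "M01", "M02"),
                       c("M01", "M02", "F01", "F02"))
  win_swap <- fm_log2_ratio(wm, s, eps = 0.001, floor = 0.1)
  expect_identical(win$log2_ratio[!is.na(win$log2_ratio)],
                   -win_swap$log2_ratio[!is.na(win_swap$log2_ratio)])

  expect_error(fm_log2_ratio(wm, zw_samples(4, 0)), "each sex")
})

test_that("the resampling band is degenerate, symmetric and convergent as it should be", {
  mkwin <- function(x) data.table::data.table(
    chrom = "auto", start = seq_along(x) * 100L - 100L,
    end = seq_along(x) * 100L, partial = FALSE,
    mean_F = 1, mean_M = 1, log2_ratio = x, class = NA_character_)

  # all zeros -> band (0, 0)
  b <- autosome_band(mkwin(rep(0, 20)), "auto", n_boot = 50, seed = 1)
  expect_identical(c(b$lower, b$upper), c(0, 0))

  # symmetric +/- x values -> band symmetric about 0
  b <- autosome_band(mkwin(rep(c(-0.3, 0.3), 25)), "auto", n_boot = 2000, seed = 1)
  expect_equal(b$lower, -b$upper, tolerance = 0.02)

  # band endpoints converge to the direct sample percentiles as n_boot grows
  set.seed(42)
  x <- rnorm(200, 0, 0.1)
  b_big <- autosome_band(mkwin(x), "auto", n_boot = 10000, seed = 1)
  direct <- quantile(x, c(0.025, 0.975), type = 6, names = FALSE)
  expect_equal(c(b_big$lower, b_big$upper), direct, tolerance = 0.05)

  expect_error(autosome_band(mkwin(rep(0, 5)), "auto"), "at least 10")
})

test_that("window classification matches the band/threshold rules", {
  band <- structure(list(lower = -0.2, upper = 0.2), class = "zw_band")
  w <- data.table::data.table(
    chrom = "c1", start = 0:4 * 100L, end = 1:5 * 100L, partial = FALSE,
    mean_F = 1, mean_M = 1,
    log2_ratio = c(0, -1, -0.3, 2, NA), class = NA_character_)
  w$class[5] <- "missing"
  cls <- classify_windows(w, band, z_threshold = -0.5, w_threshold = 0.5)
  expect_identical(cls$class,
                   c("PAR/autosomal", "Z-specific", "ambiguous",
                     "W-specific", "missing"))
  # exhaustive and mutually exclusive over nonmissing windows
  expect_false(anyNA(cls$class))
})

test_that("repeat density is the per-window union fraction", {
  win <- data.frame(chrom = "c1", start = c(0L, 10000L), end = c(10000L, 20000L))
  expect_equal(repeat_density(data.frame(chrom = character(),
                                         start = integer(), end = integer()),
                              win), c(0, 0))
  # full window covered
  rep1 <- data.frame(chrom = "c1", start = 0L, end = 10000L)
  expect_equal(repeat_density(rep1, win), c(1, 0))
  # two overlapping 6-kb repeats with an 8-kb union -> 0.8
  rep2 <- data.frame(chrom = "c1", start = c(1000L, 3000L),
                     end = c(7000L, 9000L))
  expect_equal(repeat_density(rep2, win), c(0.8, 0))
})

test_that("malformed BED input is rejected with its line number", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("c1\t0\t100", "c1\txx\t200"), f)
  expect_error(read_bed(f), "line 2")
  writeLines(c("c1\t0\t100", "c1\t500\t200"), f)
  expect_error(read_bed(f), "line 2")
  writeLines(c("c1\t0\t100\tname1"), f)
  bed <- read_bed(f)
  expect_identical(bed$start, 0L)
  expect_identical(bed$end, 100L)
})
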