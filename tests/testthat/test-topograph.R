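# Band power against periodogram oracles, scalp interpolation, image
# encoding and the hemisphere split.

seg_from <- function(data, fs, channels = paste0("ch", seq_len(nrow(data)))) {
  structure(list(data = data, fs = fs, start_time = 0,
                 channel_names = channels,
                 subject_id = "S1", trial_id = "T1", label = "a"),
            class = "eeg_segment")
}

periodogram_band <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / (fs * n)
  f <- (seq_len(n) - 1) * fs / n
  sel <- f <= fs / 2 & f >= lo & f < hi
  mean(p[sel])
}

test_that("a pure alpha sinusoid concentrates power in the alpha band", {
  fs <- 128
  t <- seq(0, 15, by = 1 / fs)[1:(15 * fs)]
  x <- rbind(sin(2 * pi * 10 * t))
  bp <- band_power(seg_from(x, fs))
  expect_gt(bp[1, 1], 10 * bp[1, 2])  # alpha >> beta
  expect_gt(bp[1, 1], 10 * bp[1, 3])  # alpha >> gamma
  # and the multitaper total stays within 20% of the plain periodogram
  oracle <- periodogram_band(x[1, ], fs, 8, 13)
  expect_equal(unname(bp[1, 1]), oracle, tolerance = 0.2)
})

test_that("an all-zero signal has exactly zero band power", {
  bp <- band_power(seg_from(matrix(0, 2, 512), 128))
  expect_identical(unname(bp), matrix(0, 2, 3))
})

test_that("white noise has roughly flat per-Hz power", {
  # averaged over seeds, mean PSD in 30-50 Hz matches 8-13 Hz
  fs <- 128
  withr::with_seed(2, {
    ratios <- replicate(40, {
      x <- matrix(stats::rnorm(4 * fs), 1)
      bp <- band_power(seg_from(x, fs))
      bp[1, 3] / bp[1, 1]
    })
  })
  expect_equal(mean(ratios), 1, tolerance = 0.15)
})

test_that("bands beyond Nyquist are rejected", {
  expect_error(band_power(seg_from(matrix(0, 1, 256), 64),
                          band_edges = list(c(30, 40))), "Nyquist")
})

test_that("scalp interpolation reproduces constants, peaks and midpoints", {
  mon <- standard_montage()
  ch <- mon$positions$channel
  # constant field
  v <- stats::setNames(rep(3.5, length(ch)), ch)
  f <- interpolate_scalp(v, mon)
  g <- (seq_len(64) - 0.5) / 64 * 2 - 1
  inside <- outer(rev(g), g, function(y, x) x^2 + y^2 <= 1)
  expect_equal(range(f[inside]), c(3.5, 3.5), tolerance = 1e-6)
  expect_true(all(f[!inside] == 0))

  # single active electrode: the field maximum lands at its pixel
  v <- stats::setNames(rep(0, length(ch)), ch)
  v["C3"] <- 1
  f <- interpolate_scalp(v, mon)
  pos <- mon$positions[mon$positions$channel == "C3", ]
  ij <- which(f == max(f), arr.ind = TRUE)[1, ]
  px <- g[ij[2]]; py <- rev(g)[ij[1]]
  expect_lt(sqrt((px - pos$x)^2 + (py - pos$y)^2), 2.5 * (2 / 64))

  # two electrodes on a diameter, values 0 and 1: midpoint is ~0.5
  v <- c(T7 = 0, T8 = 1)
  f <- interpolate_scalp(v, mon)
  expect_equal(f[32, 32], 0.5, tolerance = 0.1)

  # electrode values are reproduced at their own grid locations
  withr::with_seed(4, v <- stats::setNames(stats::rnorm(length(ch)), ch))
  f <- interpolate_scalp(v, mon)
  for (nm in c("Cz", "F3", "O2")) {
    p <- mon$positions[mon$positions$channel == nm, ]
    i <- which.min(abs(rev(g) - p$y)); j <- which.min(abs(g - p$x))
    expect_equal(f[i, j], unname(v[nm]), tolerance = 0.25)
  }
})

test_that("interpolation requires montage coverage", {
  mon <- standard_montage(c("Cz", "C3", "C4", "Fz"))
  expect_error(interpolate_scalp(c(Pz = 1, Cz = 0), mon), "montage position")
})

test_that("image encoding is an exact per-band min-max map", {
  f <- matrix(2, 64, 64)
  f[1, 1] <- 4; f[2, 1] <- 3
  img <- encode_image(list(f, matrix(0, 64, 64), matrix(7, 64, 64)))
  expect_s3_class(img, "band_topograph")
  expect_identical(img$image[1, 1, 1], 255L)
  expect_identical(img$image[1, 2, 1], 128L)  # 127.5 rounds away from zero
  expect_identical(img$image[1, 3, 1], 0L)
  # degenerate (constant) bands map to all zeros
  expect_true(all(img$image[2, , ] == 0L))
  expect_true(all(img$image[3, , ] == 0L))
  expect_error(encode_image(list(matrix(NaN, 2, 2))), "finite")
})

test_that("encoding is invariant to positive affine transforms", {
  withr::with_seed(5, f <- matrix(stats::rnorm(64^2), 64, 64))
  a <- encode_image(list(f, f, f))
  b <- encode_image(list(3.7 * f + 11, 0.01 * f - 2, f))
  expect_identical(a$image, b$image)
})

test_that("hemisphere split and concatenation is a bitwise identity", {
  withr::with_seed(6, {
    img <- encode_image(list(matrix(stats::rnorm(64^2), 64),
                             matrix(stats::rnorm(64^2), 64),
                             matrix(stats::rnorm(64^2), 64)))
  })
  hp <- split_hemispheres(img)
  expect_identical(dim(hp$left), c(3L, 64L, 32L))
  expect_identical(dim(hp$right), c(3L, 64L, 32L))
  rejoined <- array(0L, c(3, 64, 64))
  rejoined[, , 1:32] <- hp$left
  rejoined[, , 33:64] <- hp$right
  expect_identical(rejoined, img$image)

  # mirror-symmetric image: left equals the horizontal mirror of right
  sym <- img
  sym$image[, , 33:64] <- sym$image[, , 32:1]
  hs <- split_hemispheres(sym)
  expect_identical(hs$left, hs$right[, , 32:1, drop = FALSE])

  # a delta at column 5 stays in the left half
  delta <- img
  delta$image[] <- 0L
  delta$image[1, 10, 5] <- 200L
  hd <- split_hemispheres(delta)
  expect_identical(sum(hd$right), 0L)
  expect_identical(hd$left[1, 10, 5], 200L)
})

test_that("the segment-to-topograph pipeline is deterministic", {
  fs <- 128
  mon <- standard_montage(n = 8)
  withr::with_seed(7, {
    x <- matrix(stats::rnorm(8 * 4 * fs), 8)
  })
  seg <- seg_from(x, fs, mon$positions$channel)
  t1 <- segment_topograph(seg, mon)
  t2 <- segment_topograph(seg, mon)
  expect_identical(t1$image, t2$image)
  expect_true(all(t1$image >= 0L & t1$image <= 255L))
  expect_identical(t1$label, "a")
})

test_that("topograph datasets round-trip through the on-disk layout", {
  ds <- tiny_dataset()
  dir <- withr::local_tempdir()
  save_topographs(ds, dir)
  back <- load_topographs(dir)
  expect_identical(back$images, ds$images)
  expect_identical(back$meta$subject_id, ds$meta$subject_id)
  expect_identical(back$meta$label, ds$meta$label)
})
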