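test_that("block means equal the naive double-loop computation", {
  # worked 4x4 example, block size 2
  img <- fish_image(matrix(1:16, 4, 4, byrow = FALSE), matrix(TRUE, 4, 4))
  bm <- block_quantify(img, 2)
  expect_equal(sort(as.vector(bm$values)), c(3.5, 5.5, 11.5, 13.5))

  naive_blocks <- function(x, mask, bs) {
    nby <- ceiling(nrow(x) / bs); nbx <- ceiling(ncol(x) / bs)
    out <- matrix(NA_real_, nby, nbx)
    for (i in seq_len(nby)) for (j in seq_len(nbx)) {
      rows <- ((i - 1) * bs + 1):min(i * bs, nrow(x))
      cols <- ((j - 1) * bs + 1):min(j * bs, ncol(x))
      vals <- x[rows, cols][mask[rows, cols]]
      if (length(vals)) out[i, j] <- mean(vals)
    }
    out
  }
  for (k in 1:10) {
    dims <- retinotopo:::with_seed(200 + k, c(sample(20:47, 1), sample(20:47, 1)))
    x <- retinotopo:::with_seed(300 + k, matrix(runif(prod(dims)), dims[1], dims[2]))
    mask <- retinotopo:::with_seed(400 + k, matrix(runif(prod(dims)) > 0.3, dims[1], dims[2]))
    if (!any(mask)) next
    bm <- block_quantify(fish_image(x, mask), 7)  # partial edge blocks
    expect_equal(bm$values, naive_blocks(x, mask, 7), tolerance = 1e-12)
  }

  # blocks fully outside the mask are missing; empty masks error out
  m2 <- matrix(TRUE, 4, 4); m2[3:4, 3:4] <- FALSE
  bm2 <- block_quantify(fish_image(matrix(1, 4, 4), m2), 2)
  expect_true(is.na(bm2$values[2, 2]))
  expect_error(block_quantify(fish_image(matrix(1, 4, 4), matrix(FALSE, 4, 4))),
               "empty mask")
})

test_that("[0,1] normalization is exact, idempotent, and affine-invariant", {
  img <- fish_image(matrix(c(2, 4, 6, 2, 4, 6), 2, 3, byrow = TRUE), matrix(TRUE, 2, 3))
  bm <- block_quantify(img, 1)
  nm <- normalize01(bm)
  expect_equal(nm$values[1, ], c(0, 0.5, 1))
  expect_equal(normalize01(nm)$values, nm$values)               # idempotent
  aff <- bm; aff$values <- 3 * bm$values + 7
  expect_equal(normalize01(aff)$values, nm$values)              # affine invariance
  const <- bm; const$values[] <- 2
  expect_error(normalize01(const), "constant")
})

test_that("axis normalization rescales per line and flags degenerate lines", {
  vals <- matrix(c(1, 3, 2, 2, 0, 8), nrow = 3)
  img <- fish_image(vals, matrix(TRUE, 3, 2))
  bm <- block_quantify(img, 1)
  cn <- axis_normalize(bm, "column")
  # per-column hand rescale: col1 (1,3,2) -> (0,1,.5); col2 (2,0,8) -> (.25,0,1)
  expect_equal(cn$values[, 1], c(0, 1, 0.5))
  expect_equal(cn$values[, 2], c(0.25, 0, 1))

  rn <- axis_normalize(bm, "row")
  expect_equal(rn$values[1, ], c(0, 1))

  # constant column is skipped with a flag; single defined block likewise
  vals2 <- matrix(c(2, 2, 2, 1, 5, NA), nrow = 3)
  bm2 <- bm; bm2$values <- vals2
  expect_warning(cn2 <- axis_normalize(bm2, "column"), "skipped")
  expect_true(all(is.na(cn2$values[, 1])))
  expect_equal(attr(cn2, "skipped_lines"), 1L)
  bm3 <- bm; bm3$values <- matrix(c(NA, NA, 4, 1, 5, 9), nrow = 3)
  expect_warning(cn3 <- axis_normalize(bm3, "column"), "skipped")
  expect_true(all(is.na(cn3$values[, 1])))
})

test_that("strip width follows the stated pixel rounding", {
  expect_identical(strip_width_px(), 1539)
  expect_identical(strip_width_px(500, 0.5), 1000)
})

test_that("strip profiles are origin-anchored with exact translation behavior", {
  vals <- matrix(rep(1:10, each = 10), 10, 10)   # constant along rows
  img <- fish_image(vals, matrix(TRUE, 10, 10), pixel_size_um = 1)
  bm <- set_origin(block_quantify(img, 1), 5, 5)
  p <- extract_strip_profile(bm, "DV", strip_width_um = 3, signal_fraction = 0.8)
  expect_equal(p$mean, rep(c(4, 5, 6) |> mean(), 10))  # strip cols 4:6
  expect_equal(p$spread, rep(1, 10))
  expect_equal(p$position, (1:10 - 5) * 1)
  expect_equal(attr(p, "origin"), 0)

  # constant region: flat profile with zero SD
  cimg <- fish_image(matrix(2, 8, 8), matrix(TRUE, 8, 8), pixel_size_um = 1)
  cp <- extract_strip_profile(set_origin(block_quantify(cimg, 1), 4, 4), "DV",
                              strip_width_um = 2)
  expect_equal(diff(range(cp$mean)), 0)
  expect_equal(max(cp$spread), 0)

  # shifting the origin by k blocks shifts positions by exactly k*bs*px um
  bm2 <- set_origin(bm, 7, 5)
  p2 <- extract_strip_profile(bm2, "DV", strip_width_um = 3, signal_fraction = 0.8)
  expect_equal(p2$position, p$position - 2 * 1 * 1)
  expect_error(set_origin(bm, 11, 2), "outside")
  expect_error(extract_strip_profile(block_quantify(img, 1), "DV"), "origin unset")
})

test_that("the signal-fraction filter drops background-dominated positions", {
  # 10-column strip; row 1 has 7/10 defined (70%), row 2 has 8/10 (80%)
  vals <- matrix(1, 4, 10)
  vals[1, 1:3] <- NA
  vals[2, 1:2] <- NA
  img <- fish_image(matrix(1, 4, 10), matrix(TRUE, 4, 10), pixel_size_um = 1)
  bm <- set_origin(block_quantify(img, 1), 2, 5)
  bm$values <- vals
  p <- extract_strip_profile(bm, "DV", strip_width_um = 12, signal_fraction = 0.8)
  expect_false(-1 %in% p$position)            # row 1 dropped
  expect_true(0 %in% p$position)              # row 2 retained at exactly 80%
})

test_that("profile aggregation averages across aligned samples", {
  p1 <- profile_1d(c(0, 1), c(0, 2), c(0, 0), c(5, 5), origin = 0)
  p2 <- profile_1d(c(0, 1), c(2, 0), c(0, 0), c(5, 5), origin = 0)
  agg <- aggregate_profiles(list(p1, p2), step_um = 1, spread = "sd")
  expect_equal(agg$mean, c(1, 1))
  expect_equal(agg$spread, c(sqrt(2), sqrt(2)))
  expect_equal(agg$coverage, c(2L, 2L))

  # identical profiles: mean reproduces the input with zero SEM
  agg2 <- aggregate_profiles(list(p1, p1), step_um = 1)
  expect_equal(agg2$mean, p1$mean)
  expect_equal(agg2$spread, c(0, 0))

  # a position covered by one sample keeps its mean, spread missing
  p3 <- profile_1d(c(0, 1, 2), c(1, 1, 7), c(0, 0, 0), c(5, 5, 5), origin = 0)
  agg3 <- aggregate_profiles(list(p1, p3), step_um = 1)
  expect_equal(agg3$mean[3], 7)
  expect_true(is.na(agg3$spread[3]))
  expect_equal(agg3$coverage[3], 1L)
})

test_that("TIFF round trip feeds the quantification unchanged", {
  x <- retinotopo:::with_seed(9, matrix(runif(900), 30, 30))
  mask <- outer(1:30, 1:30, function(i, j) (i - 15)^2 + (j - 15)^2 < 180)
  dir <- withr::local_tempdir()
  tiff::writeTIFF(x, file.path(dir, "img.tif"), bits.per.sample = 32)
  tiff::writeTIFF(mask * 1, file.path(dir, "mask.tif"))
  img <- read_fish_image(file.path(dir, "img.tif"), file.path(dir, "mask.tif"))
  expect_equal(img$intensity, x, tolerance = 1e-6)
  expect_equal(img$mask, mask, ignore_attr = TRUE)
  bm <- block_quantify(img, 5)
  expect_equal(bm$values, block_quantify(fish_image(x, mask), 5)$values,
               tolerance = 1e-6)
})
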