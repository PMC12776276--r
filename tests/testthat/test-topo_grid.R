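make_scored <- function(nt, dv, counts = NULL) {
  n <- length(nt)
  counts <- counts %||% matrix(10L, n, 2)
  ds <- toy_dataset(counts)
  scores <- tibble::tibble(cell = ds$cells, nt_score = nt, dv_score = dv)
  list(ds = ds, scores = scores)
}

test_that("species presets carry the published grid parameters", {
  ck <- species_preset("chicken")
  hu <- species_preset("human")
  mo <- species_preset("mouse")
  expect_equal(c(ck$grid_size, ck$min_cells, ck$min_counts, ck$sigma), c(51, 3, 20, 1))
  expect_equal(c(hu$grid_size, hu$min_cells, hu$min_counts, hu$sigma), c(40, 3, 15, 1))
  expect_equal(c(mo$grid_size, mo$min_cells, mo$min_counts, mo$sigma), c(51, 5, 30, 1))
  expect_equal(ck$grid_size^2, 2601)
  expect_equal(hu$grid_size^2, 1600)
})

test_that("binning follows the half-open convention with the last bin closed", {
  f <- make_scored(nt = c(0, 0.4, 1, 0.3, 1), dv = c(0, 0, 1, 0.9, 0))
  p <- species_preset("custom", grid_size = 2, min_cells = 1, min_counts = 0)
  g <- build_grid(f$scores, f$ds, p)
  # enumeration oracle: edges [0, .5, 1]; [e1, e2) except last bin closed
  expect_equal(g$assignment$ix, c(1L, 1L, 2L, 1L, 2L))
  expect_equal(g$assignment$iy, c(1L, 1L, 2L, 2L, 1L))
  expect_equal(sum(g$n_cells), 5)           # cells partition across bins
  expect_equal(g$n_cells[1, 1], 2)
  expect_equal(g$n_cells[2, 2], 1)
  expect_error(build_grid(make_scored(rep(0.5, 3), c(0, 1, 2))$scores, f$ds, p),
               "cells")
  same <- make_scored(rep(0.5, 5), c(0, 0.1, 0.5, 0.9, 1))
  expect_error(build_grid(same$scores, same$ds, p), "degenerate NT")
})

test_that("validity thresholds are monotone: raising them never adds valid bins", {
  b <- benchmark_scored()
  base <- b$grid
  for (delta in list(c(2, 0), c(0, 15), c(4, 30))) {
    p <- species_preset("custom", grid_size = base$G,
                        min_cells = base$preset$min_cells + delta[1],
                        min_counts = base$preset$min_counts + delta[2])
    stricter <- build_grid(b$scores, b$bundle$ds, p)
    expect_true(all(base$valid[stricter$valid]))
  }
})

test_that("gene maps are per-bin arithmetic means of normalized expression", {
  # equal per-cell totals so gene g02 has constant normalized expression
  counts <- rbind(c(0L, 4L, 12L), c(2L, 4L, 10L), c(9L, 4L, 3L))
  f <- make_scored(nt = c(0.1, 0.2, 0.9), dv = c(0.1, 0.2, 0.9), counts = counts)
  p <- species_preset("custom", grid_size = 2, min_cells = 1, min_counts = 0)
  g <- build_grid(f$scores, f$ds, p)
  m <- gene_map(g, f$ds, "g01")
  # bin (1,1) holds cells 1 and 2: mean of their normalized values
  expect_equal(m$values[1, 1], mean(as.numeric(f$ds$norm[1:2, 1])))
  expect_equal(m$values[2, 2], as.numeric(f$ds$norm[3, 1]))
  expect_true(is.na(m$values[1, 2]) && is.na(m$values[2, 1]))  # empty bins missing
  expect_error(gene_map(g, f$ds, "nope"), "unknown gene")

  # constant gene -> every valid bin equals the constant
  m2 <- gene_map(g, f$ds, "g02")
  vals <- m2$values[g$valid]
  expect_true(all(abs(vals - vals[1]) < 1e-12))
})

test_that("mask-aware smoothing preserves constants and matches the kernel oracle", {
  const <- manual_map(matrix(3.7, 9, 9))
  sm <- smooth_map(const, 1.0)
  expect_equal(sm$smoothed, matrix(3.7, 9, 9), tolerance = 1e-12)

  # unit impulse on a fully valid grid: center equals the kernel center weight
  imp <- matrix(0, 11, 11); imp[6, 6] <- 1
  sm2 <- smooth_map(manual_map(imp), 1.0)
  r <- 4
  k1 <- exp(-(-r:r)^2 / 2)
  K <- outer(k1, k1); K <- K / sum(K)
  expect_equal(sm2$smoothed[6, 6], K[r + 1, r + 1], tolerance = 1e-12)
  expect_equal(sm2$smoothed[6, 7], K[r + 1, r + 2], tolerance = 1e-12)

  # kernel truncated at 4*sigma loses under 1e-5 of its discrete mass
  # (2e-6 per 1D factor), and the interior convolution numerator carries
  # exactly the truncated kernel's mass
  k4 <- exp(-(-4:4)^2 / 2)
  kfull <- exp(-(-50:50)^2 / 2)
  expect_lt(abs(1 - sum(k4)^2 / sum(kfull)^2), 1e-5)
  nc <- retinotopo:::normalized_convolution(imp, matrix(TRUE, 11, 11), 1.0)
  expect_equal(sum(nc$numerator), sum(k4)^2, tolerance = 1e-12)

  # smoothing a noisy field contracts its variance
  noisy <- manual_map(retinotopo:::with_seed(4, matrix(rnorm(400), 20, 20)))
  expect_lt(var(as.vector(smooth_map(noisy, 1.0)$smoothed)),
            var(as.vector(noisy$values)))

  # missing bins stay missing when unreachable by the kernel
  far <- matrix(NA_real_, 21, 21); far[1, 1] <- 1; far[21, 21] <- 2
  sm3 <- smooth_map(manual_map(far), 1.0)
  expect_true(is.na(sm3$smoothed[11, 11]))
})

test_that("percentile clipping matches the interpolation definition and caps values", {
  vals <- matrix(as.numeric(1:100), 10, 10)
  m <- manual_map(vals)
  m$smoothed <- vals; m$sigma <- 0  # clip the raw field directly
  clipped <- clip_map(m, 95)
  # independent sorted-rank linear interpolation oracle
  h <- (100 - 1) * 0.95 + 1
  srt <- sort(as.numeric(vals))
  expected <- srt[floor(h)] + (h - floor(h)) * (srt[ceiling(h)] - srt[floor(h)])
  expect_equal(clipped$clipped_max, expected)
  expect_equal(max(clipped$smoothed), clipped$clipped_max)
  expect_equal(sum(clipped$smoothed == clipped$clipped_max), 5)

  unclipped <- clip_map(m, 100)
  expect_equal(unclipped$smoothed, vals)
  expect_equal(unclipped$clipped_max, 100)
})

test_that("grid sensitivity compares resolutions on shared scores", {
  cfg <- synth_config(list(spot = list(type = "central_spot", center = c(0.3, 0), width = 0.3),
                           f1 = "flat", f2 = "flat", f3 = "flat", f4 = "flat"),
                      n_cells = 3000, n_embryos = 2, seed = 11)
  sim <- simulate_cells(cfg)
  ds <- normalize_counts(sim$ds)
  scores <- tibble::tibble(cell = ds$cells, nt_score = sim$truth$u, dv_score = sim$truth$v)
  maps <- grid_sensitivity(scores, ds, "spot", sizes = c(20, 100),
                           preset = species_preset("custom", min_cells = 1))
  expect_length(maps, 2)
  expect_equal(dim(maps$G20$values), c(20, 20))
  expect_equal(dim(maps$G100$values), c(100, 100))
  expect_equal(prod(dim(maps$G20$values)), 400)
  expect_equal(prod(dim(maps$G100$values)), 10000)
  # the spot is localized at both resolutions (scores here are the true positions)
  for (m in maps) {
    G <- m$G
    am <- arrayInd(which.max(ifelse(is.na(m$smoothed), -Inf, m$smoothed)), c(G, G))
    true_ix <- findInterval(0.3, seq(min(sim$truth$u), max(sim$truth$u), length.out = G + 1),
                            rightmost.closed = TRUE)
    true_iy <- findInterval(0, seq(min(sim$truth$v), max(sim$truth$v), length.out = G + 1),
                            rightmost.closed = TRUE)
    expect_lte(max(abs(am - c(true_iy, true_ix))), ceiling(G / 10))
  }
})
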