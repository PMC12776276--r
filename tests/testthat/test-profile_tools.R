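make_profile <- function(positions, values, coverage = NULL) {
  profile_1d(positions, values, rep(0, length(positions)),
             coverage %||% rep(10L, length(positions)))
}

test_that("axis profiles record bin means, coverage, and the low-confidence flag", {
  # 150 cells on a 3-bin DV axis: bins hold 50 / 51 / 49 cells
  n <- 150
  dv <- c(rep(0.1, 50), rep(0.5, 51), rep(0.9, 49))
  counts <- cbind(rep(c(2L, 4L, 8L), times = c(50, 51, 49)), 10L)
  ds <- toy_dataset(counts)
  scores <- tibble::tibble(cell = ds$cells, dv_score = dv,
                           nt_score = seq(0, 1, length.out = n))
  p <- axis_profile_from_cells(scores, ds, "g01", axis = "DV", n_bins = 3,
                               min_cells = 50)
  expect_equal(nrow(p), 3)
  expect_equal(p$coverage, c(50L, 51L, 49L))
  expect_equal(p$low_confidence, c(TRUE, FALSE, TRUE))  # needs more than 50 cells
  expect_equal(p$mean[1], mean(as.numeric(ds$norm[1:50, 1])))

  # default bin count of the published profiles
  p50 <- axis_profile_from_cells(scores, ds, "g01", axis = "DV")
  expect_equal(nrow(p50), 50)

  # a constant normalized gene gives a flat profile (equal totals per cell)
  ds2 <- toy_dataset(matrix(5L, n, 3))
  p2 <- axis_profile_from_cells(scores, ds2, "g02", axis = "DV", n_bins = 3)
  expect_equal(diff(range(p2$mean)), 0)
  expect_error(axis_profile_from_cells(scores, ds, "nope", "DV"), "unknown gene")
})

test_that("interpolation is exact on nodes, linear between, and never extrapolates", {
  p1 <- make_profile(c(0, 2), c(0, 10))
  p2 <- make_profile(c(0, 1, 2), c(5, 5, 5))
  pm <- interpolate_to_common_axis(list(a = p1, b = p2), step = 1)
  expect_equal(attr(pm, "positions"), c(0, 1, 2))
  expect_equal(unname(pm["a", ]), c(0, 5, 10))   # midpoint of the line
  expect_equal(unname(pm["b", ]), c(5, 5, 5))    # identity on its own nodes

  # profile covering [1, 3] has no value at 0 (no extrapolation)
  p3 <- make_profile(c(1, 3), c(1, 3))
  pm2 <- interpolate_to_common_axis(list(a = p1, c = p3), step = 1)
  expect_true(is.na(pm2["c", 1]))
  expect_equal(unname(pm2["c", 2:3]), c(1, 2))
  expect_error(interpolate_to_common_axis(list(p1), 1), "at least 2")
})

test_that("profile correlations are masked, symmetric, unit-diagonal", {
  pm <- rbind(
    g1 = c(1, 2, 3, 4, 5),
    g2 = c(1, 2, 3, 4, 5),
    g3 = c(5, 4, 3, 2, 1),
    g4 = c(1, 2, NA, 4, 6)
  )
  attr(pm, "positions") <- 1:5
  C <- profile_correlation_matrix(pm)
  expect_equal(C["g1", "g2"], 1)
  expect_equal(C["g1", "g3"], -1)
  expect_equal(C, t(C))
  expect_equal(diag(C), rep(1, 4), ignore_attr = TRUE)
  # masked entry equals the hand computation over the 4 joint positions
  expect_equal(C["g1", "g4"], cor(c(1, 2, 4, 5), c(1, 2, 4, 6)))

  short <- rbind(a = c(1, 2, NA, NA, NA), b = c(2, 1, NA, NA, NA))
  expect_true(is.na(profile_correlation_matrix(short)["a", "b"]))
  flat <- rbind(a = c(1, 2, 3, 4, 5), b = rep(2, 5))
  expect_warning(Cf <- profile_correlation_matrix(flat), "zero-variance")
  expect_true(is.na(Cf["a", "b"]))
})

# independent O(n^3) average-linkage oracle
average_linkage_oracle <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < bd) { bd <- d; best <- c(i, j) }
    }
    heights <- c(heights, bd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

test_that("average-linkage heights match an independent agglomeration oracle", {
  D <- retinotopo:::with_seed(5, {
    M <- matrix(runif(36), 6, 6)
    D <- (M + t(M)) / 2; diag(D) <- 0; D
  })
  rownames(D) <- colnames(D) <- paste0("g", 1:6)
  cl <- cluster_profiles(1 - D)
  expect_equal(sort(cl$hclust$height), sort(average_linkage_oracle(D)),
               tolerance = 1e-12)
})

test_that("identical profiles merge first at height zero and NAs are imputed", {
  pm <- rbind(g1 = c(1, 2, 3, 4), g2 = c(1, 2, 3, 4), g3 = c(4, 3, 2, 1))
  C <- profile_correlation_matrix(pm)
  cl <- cluster_profiles(C)
  expect_equal(cl$hclust$height[1], 0, tolerance = 1e-12)
  first_pair <- sort(cl$hclust$labels[-cl$hclust$merge[1, ]])
  expect_identical(first_pair, c("g1", "g2"))

  C2 <- C; C2["g1", "g3"] <- C2["g3", "g1"] <- NA
  expect_warning(cluster_profiles(C2), "imputed")
  expect_error(cluster_profiles(matrix(1, 1, 1)), "at least 2")
})

test_that("optimal leaf ordering matches exhaustive search over dendrogram flips", {
  # all orderings consistent with the tree = independent flip of each merge
  all_orders <- function(hc) {
    expand_node <- function(id) {
      if (id < 0) return(list(-id))
      L <- expand_node(hc$merge[id, 1])
      R <- expand_node(hc$merge[id, 2])
      out <- list()
      for (l in L) for (r in R) out <- c(out, list(c(l, r)), list(c(r, l)))
      out
    }
    expand_node(nrow(hc$merge))
  }
  for (n in 5:8) {
    D <- retinotopo:::with_seed(40 + n, {
      M <- matrix(runif(n * n), n, n); D <- (M + t(M)) / 2; diag(D) <- 0; D
    })
    rownames(D) <- colnames(D) <- paste0("g", seq_len(n))
    cl <- cluster_profiles(1 - D)
    best <- min(vapply(all_orders(cl$hclust),
                       function(o) retinotopo:::adjacent_distance_sum(D, o),
                       numeric(1)))
    expect_equal(cl$adjacent_sum, best, tolerance = 1e-12)
    # and never worse than the unordered dendrogram traversal
    expect_lte(cl$adjacent_sum,
               retinotopo:::adjacent_distance_sum(D, cl$hclust$order) + 1e-12)
  }
})

test_that("cross-modal comparison recovers shared shapes across samplings", {
  f <- function(x) exp(-(x - 0.6)^2 / 0.02)
  fish <- list(FGF8SIM = make_profile(seq(0, 1000, by = 50), f(seq(0, 1, by = 0.05))))
  scrna <- list(fgf8sim = make_profile(seq(-2, 2, length.out = 31),
                                       f(seq(0, 1, length.out = 31))))
  res <- cross_modal_compare(fish, scrna)
  expect_equal(res$gene, "FGF8SIM")
  expect_gt(res$r, 0.99)

  ident <- list(g = make_profile(1:10, sin(1:10)))
  expect_equal(cross_modal_compare(ident, list(g = ident$g))$r, 1.0)

  flat <- list(g = make_profile(1:5, rep(1, 5)))
  expect_warning(res2 <- cross_modal_compare(flat, list(g = flat$g)), "constant")
  expect_true(is.na(res2$r))
})

test_that("newick export reflects the dendrogram topology", {
  pm <- rbind(g1 = c(1, 2, 3, 4), g2 = c(1.1, 2, 3, 4), g3 = c(4, 3, 2, 1))
  cl <- cluster_profiles(profile_correlation_matrix(pm))
  nwk <- clustering_newick(cl)
  expect_match(nwk, "^\\(.*\\);$")
  expect_true(all(vapply(c("g1", "g2", "g3"), grepl, logical(1), x = nwk)))
})
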