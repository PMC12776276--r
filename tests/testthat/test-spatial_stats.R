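test_that("Moran's I matches analytic cases", {
  chk <- manual_map(matrix(c(1, -1, -1, 1), 2, 2))
  w_rook <- spatial_weights(chk, style = "rook")
  expect_identical(morans_I(chk, w_rook), -1)

  expect_error(morans_I(manual_map(matrix(2, 3, 3)),
                        spatial_weights(matrix(TRUE, 3, 3))),
               "zero variance")

  # null expectation: average I over random permutations concentrates
  # near -1/(n-1)
  base <- manual_map(matrix(as.numeric(1:36), 6, 6))
  w <- spatial_weights(base)
  Is <- retinotopo:::with_seed(2, {
    vapply(1:300, function(i) {
      m <- base; m$values[] <- sample(m$values)
      morans_I(m, w)
    }, numeric(1))
  })
  expect_lt(abs(mean(Is) - (-1 / 35)), 0.02)
})

test_that("Moran's I equals the brute-force double sum on random masked fields", {
  for (i in 1:40) {
    vals <- retinotopo:::with_seed(100 + i, {
      v <- matrix(rnorm(36), 6, 6)
      v[sample(36, 8)] <- NA
      v
    })
    m <- manual_map(vals)
    for (style in c("queen", "rook")) {
      w <- spatial_weights(m, style = style)
      expect_equal(morans_I(m, w),
                   morans_I_bruteforce(vals, !is.na(vals), style),
                   tolerance = 1e-12)
    }
  }
})

test_that("permutation p-values hit their attainable extremes", {
  # smooth gradient: observed I above all 999 permutations -> minimum p
  grad <- manual_map(outer(1:8, 1:8, `+`) + 0)
  w <- spatial_weights(grad)
  res <- morans_test(grad, w, n_perm = 999, seed = 1)
  expect_equal(res$p_value, 1 / 1000)
  expect_equal(res$n, 64)

  # checkerboard (strong negative autocorrelation): one-sided p near 1
  chk <- manual_map(outer(1:8, 1:8, function(i, j) (-1)^(i + j)) + 0)
  res2 <- morans_test(chk, spatial_weights(chk, style = "rook"), n_perm = 199, seed = 1)
  expect_gte(res2$p_value, 0.95)

  # determinism under a fixed seed
  expect_identical(res$p_value, morans_test(grad, w, n_perm = 999, seed = 1)$p_value)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.031), 0.031)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("cosine similarity over jointly defined bins matches hand arithmetic", {
  a <- manual_map(matrix(c(1, 2, 2, NA), 2, 2))
  b <- manual_map(matrix(c(2, 1, 2, NA), 2, 2))
  expect_equal(cosine_similarity(a, b), 8 / 9)
  expect_equal(cosine_similarity(a, a), 1.0)
  disj <- manual_map(matrix(c(0, 1, 0, 1), 2, 2))
  orth <- manual_map(matrix(c(1, 0, 1, 0), 2, 2))
  expect_equal(cosine_similarity(disj, orth), 0.0)
  expect_warning(res <- cosine_similarity(disj, manual_map(matrix(0, 2, 2))),
                 "zero-norm")
  expect_true(is.na(res))
})

test_that("Pearson map similarity applies the r > 0.9, p < 0.001 rule", {
  x <- matrix(as.numeric(1:25), 5, 5)
  a <- manual_map(x)
  b <- manual_map(2 * x + 1)
  res <- pearson_spatial(a, b)
  expect_equal(res$r, 1.0)
  expect_true(res$similar)
  expect_equal(pearson_spatial(a, manual_map(-x))$r, -1.0)

  # high r over too few bins is not significant at p < 0.001
  small_a <- manual_map(matrix(c(1, 2, 3, 4.2), 2, 2))
  small_b <- manual_map(matrix(c(1.1, 2, 3.2, 4), 2, 2))
  res2 <- pearson_spatial(small_a, small_b)
  expect_gt(res2$r, 0.9)
  expect_false(res2$similar)
  expect_error(pearson_spatial(a, manual_map(matrix(1, 5, 5))), "zero variance")
})

test_that("greedy anchor selection recovers archetypes and respects its caps", {
  arch <- list(
    dorsal = "dorsal_gradient", ventral = "ventral_gradient",
    spot = list(type = "central_spot", center = c(0.3, 0), width = 0.3),
    dorsal_dup1 = "dorsal_gradient", ventral_dup1 = "ventral_gradient",
    spot_dup1 = list(type = "central_spot", center = c(0.3, 0), width = 0.3)
  )
  M <- archetype_patterns(arch, noise = 0.02)
  stats <- tibble::tibble(gene = names(arch),
                          I = c(0.9, 0.85, 0.8, 0.7, 0.65, 0.6),
                          significant = TRUE)
  as <- select_anchors(stats, M, A_max = 20, tau_redundancy = 0.9)
  expect_identical(as$anchors, c("dorsal", "ventral", "spot"))
  asn <- as$assignment
  expect_identical(asn$anchor[asn$gene == "dorsal_dup1"], "dorsal")
  expect_identical(asn$anchor[asn$gene == "ventral_dup1"], "ventral")
  expect_identical(asn$anchor[asn$gene == "spot_dup1"], "spot")

  # anchors are pairwise dissimilar below the redundancy threshold
  C <- retinotopo:::cosine_matrix(M[, as$anchors])
  expect_true(all(C[upper.tri(C)] < as$tau_redundancy))

  # single significant gene -> sole anchor; none -> error
  one <- select_anchors(stats[3, ], M[, 3, drop = FALSE])
  expect_identical(one$anchors, "spot")
  expect_error(select_anchors(dplyr::mutate(stats, significant = FALSE), M),
               "no significant")

  # A_max truncates even with mutually dissimilar patterns
  ortho <- diag(30)[, 1:30]
  colnames(ortho) <- paste0("p", 1:30)
  stats30 <- tibble::tibble(gene = colnames(ortho), I = seq(1, 0.5, length.out = 30),
                            significant = TRUE)
  expect_length(select_anchors(stats30, ortho, A_max = 20)$anchors, 20)
})

test_that("anchor grouping merges mutual nearest neighbors transitively", {
  # constructed similarity structure: a1 and a2 at cosine 0.8 (mutual NN,
  # below the 0.97 redundancy cut), b1 orthogonal; each anchor gets two
  # members at cosine ~0.99
  e <- diag(10)
  mem <- function(v, k) 0.99 * v + sqrt(1 - 0.99^2) * e[, k]
  a1 <- e[, 1]; a2 <- 0.8 * e[, 1] + 0.6 * e[, 2]; b1 <- e[, 3]
  M <- cbind(a1 = a1, a2 = a2, b1 = b1,
             a1m1 = mem(a1, 4), a1m2 = mem(a1, 5),
             a2m1 = mem(a2, 6), a2m2 = mem(a2, 7),
             b1m1 = mem(b1, 8), b1m2 = mem(b1, 9))
  stats <- tibble::tibble(gene = colnames(M),
                          I = seq(0.95, 0.55, length.out = ncol(M)),
                          significant = TRUE)
  as <- select_anchors(stats, M, tau_redundancy = 0.97)
  expect_identical(as$anchors, c("a1", "a2", "b1"))
  grouped <- group_anchors(as, min_members = 2)
  expect_length(grouped$anchor_groups, 2)   # {a1, a2} merged, b1 alone
  ga <- vapply(grouped$anchor_groups, function(g) "a1" %in% g, logical(1))
  expect_setequal(grouped$anchor_groups[[which(ga)]], c("a1", "a2"))
  expect_false("b1" %in% grouped$anchor_groups[[which(ga)]])

  # an anchor without members forms no cluster and stays single
  lone <- select_anchors(
    tibble::tibble(gene = c("x", "y"), I = c(0.9, 0.8), significant = TRUE),
    cbind(x = e[, 1], y = e[, 2]),
    tau_redundancy = 0.9
  )
  lg <- group_anchors(lone, min_members = 2)
  expect_false(any(lg$forms_cluster))
  expect_length(lg$anchor_groups, 2)
})
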