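# Shared fixtures, all generated in code. The full-size benchmark bundle is
# expensive, so it is built lazily once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# full-size benchmark bundle (20,000 cells, 500 decoys) with scores, grid
# and weights, shared by the recovery and calibration suites
benchmark_scored <- function(seed = 0) {
  key <- paste0("bench_", seed)
  if (is.null(.fixture_cache[[key]])) {
    b <- make_benchmark_suite(seed = seed)
    scores <- compute_axis_scores(b$ds, b$gene_sets, seed = seed)
    grid <- build_grid(scores, b$ds, species_preset("chicken"))
    .fixture_cache[[key]] <- list(
      bundle = b, scores = scores, grid = grid,
      weights = spatial_weights(grid)
    )
  }
  .fixture_cache[[key]]
}

# mean latent (u, v) position of each occupied grid bin, for mapping grid
# indices back to ground truth
bin_truth_positions <- function(grid, truth) {
  tb <- grid$assignment
  uv <- truth[match(tb$cell, truth$cell), c("u", "v")]
  list(
    bin = sort(unique(tb$bin)),
    u = tapply(uv$u, tb$bin, mean),
    v = tapply(uv$v, tb$bin, mean)
  )
}

# small dataset with hand-controllable counts; meta has one embryo unless given
toy_dataset <- function(counts, embryo = NULL, normalize = TRUE, scale = 1e4) {
  n <- nrow(counts)
  cells <- sprintf("c%03d", seq_len(n))
  genes <- sprintf("g%02d", seq_len(ncol(counts)))
  meta <- tibble::tibble(embryo_id = embryo %||% rep("e1", n))
  ds <- cell_dataset(counts, cells, genes, meta)
  if (normalize) ds <- normalize_counts(ds, scale) else ds
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random small dataset with Poisson counts (never zero-total)
random_dataset <- function(n_cells, n_genes, seed = 1, lambda = 5) {
  counts <- retinotopo:::with_seed(seed, {
    matrix(stats::rpois(n_cells * n_genes, lambda), n_cells, n_genes) + 1L
  })
  toy_dataset(counts)
}

# a gene_map built directly from a value matrix (all finite entries valid),
# bypassing the binning stage, for analytic spatial tests
manual_map <- function(values, gene = "toy") {
  valid <- !is.na(values)
  grid <- list(G = nrow(values),
               x_edges = seq(0, 1, length.out = ncol(values) + 1),
               y_edges = seq(0, 1, length.out = nrow(values) + 1),
               valid = valid)
  retinotopo:::new_gene_map(gene, values, grid)
}

# pattern matrix of archetype fields sampled on a disk-masked grid, one
# column per named archetype, with optional additive noise
archetype_patterns <- function(arch_list, G = 15, noise = 0, seed = 1) {
  cx <- seq(-1, 1, length.out = G)
  uu <- matrix(rep(cx, each = G), G); vv <- matrix(rep(cx, times = G), G)
  valid <- uu^2 + vv^2 <= 1
  M <- retinotopo:::with_seed(seed, {
    vapply(arch_list, function(a) {
      f <- archetype_value(a, uu[valid], vv[valid])
      f + rnorm(sum(valid), 0, noise)
    }, numeric(sum(valid)))
  })
  colnames(M) <- names(arch_list)
  M
}

# brute-force O(n^2) Moran's I oracle over a masked matrix field
morans_I_bruteforce <- function(values, valid, style = "queen") {
  idx <- which(valid)
  pos <- arrayInd(idx, dim(valid))
  z <- values[idx] - mean(values[idx])
  n <- length(z)
  num <- 0; W <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dy <- abs(pos[i, 1] - pos[j, 1]); dx <- abs(pos[i, 2] - pos[j, 2])
    w <- if (style == "queen") (dy <= 1 && dx <= 1) else ((dy + dx) == 1)
    if (w) { num <- num + z[i] * z[j]; W <- W + 1 }
  }
  (n / W) * num / sum(z^2)
}
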