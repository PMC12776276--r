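#' Discretize scored cells into a 2D spatial grid
#'
#' Bins cells over (NT.Score, DV.Score) into a regular `G x G` grid with
#' equal-width bins spanning the observed score range of each axis. Bin
#' intervals are half-open `[e_i, e_{i+1})` with the final bin closed, so
#' max-score cells are assigned. Grid cells with at least `min_cells` member
#' cells and `min_counts` total raw transcript counts form the validity mask
#' used by all downstream map operations.
#'
#' @param scores An `axis_scores` tibble (needs `cell`, `nt_score`, `dv_score`).
#' @param ds The matching `cell_dataset`.
#' @param preset A `species_preset` giving grid size and validity thresholds.
#' @return A `topo_grid` with bin edges, per-cell assignment, per-bin cell
#'   and transcript counts, and the validity mask. Matrix layout: rows are
#'   DV bins (index `iy`), columns NT bins (`ix`), both ascending in score.
#' @export
build_grid <- function(scores, ds, preset = species_preset("chicken")) {
  stopifnot(inherits(preset, "species_preset"), inherits(ds, "cell_dataset"))
  if (!all(c("cell", "nt_score", "dv_score") %in% names(scores))) {
    abort("scores must contain cell, nt_score and dv_score columns")
  }
  ord <- match(ds$cells, scores$cell)
  if (any(is.na(ord))) abort("scores and dataset do not share the same cells")
  x <- scores$nt_score[ord]
  y <- scores$dv_score[ord]
  G <- preset$grid_size
  if (diff(range(x)) == 0) abort("degenerate NT axis: all nt_score values identical")
  if (diff(range(y)) == 0) abort("degenerate DV axis: all dv_score values identical")
  x_edges <- seq(min(x), max(x), length.out = G + 1)
  y_edges <- seq(min(y), max(y), length.out = G + 1)
  ix <- findInterval(x, x_edges, rightmost.closed = TRUE)
  iy <- findInterval(y, y_edges, rightmost.closed = TRUE)
  bin <- (ix - 1L) * G + iy  # column-major over [iy, ix]
  n_cells <- matrix(tabulate(bin, nbins = G * G), nrow = G)
  totals <- Matrix::rowSums(ds$counts)
  tc <- numeric(G * G)
  agg <- rowsum(totals, bin)
  tc[as.integer(rownames(agg))] <- agg[, 1]
  total_counts <- matrix(tc, nrow = G)
  valid <- n_cells >= preset$min_cells & total_counts >= preset$min_counts
  structure(
    list(
      G = G, x_edges = x_edges, y_edges = y_edges,
      assignment = tibble(cell = ds$cells, ix = ix, iy = iy, bin = bin),
      n_cells = n_cells, total_counts = total_counts, valid = valid,
      preset = preset
    ),
    class = "topo_grid"
  )
}

#' @export
print.topo_grid <- function(x, ...) {
  cat(sprintf("<topo_grid> %dx%d (%d bins), %d valid, %d cells assigned [%s preset]\n",
              x$G, x$G, x$G^2, sum(x$valid), nrow(x$assignment), x$preset$species))
  invisible(x)
}

#' @export
#' @method glance topo_grid
glance.topo_grid <- function(x, ...) {
  tibble(grid_size = x$G, n_bins = x$G^2, n_valid = sum(x$valid),
         n_cells = nrow(x$assignment), species = x$preset$species)
}

#' Per-bin tibble view of a grid
#'
#' @param x A `topo_grid`.
#' @param ... Unused.
#' @return Tibble with one row per bin: indices, bin centers in score units,
#'   cell/transcript counts and validity.
#' @export
#' @method tidy topo_grid
tidy.topo_grid <- function(x, ...) {
  cx <- (x$x_edges[-1] + x$x_edges[-(x$G + 1)]) / 2
  cy <- (x$y_edges[-1] + x$y_edges[-(x$G + 1)]) / 2
  tibble(
    iy = rep(seq_len(x$G), times = x$G),
    ix = rep(seq_len(x$G), each = x$G),
    nt_center = rep(cx, each = x$G),
    dv_center = rep(cy, times = x$G),
    n_cells = as.vector(x$n_cells),
    total_counts = as.vector(x$total_counts),
    valid = as.vector(x$valid)
  )
}

# sparse bins x cells incidence matrix restricted to nothing (all bins)
bin_incidence <- function(grid) {
  Matrix::sparseMatrix(
    i = grid$assignment$bin, j = seq_len(nrow(grid$assignment)),
    x = 1, dims = c(grid$G^2, nrow(grid$assignment))
  )
}

# mean normalized expression per bin for many genes at once:
# returns (G*G) x n_genes dense matrix, NA on invalid bins
bin_means <- function(grid, ds, gene_idx) {
  S <- bin_incidence(grid)
  sums <- as.matrix(S %*% ds$norm[, gene_idx, drop = FALSE])
  n <- as.vector(grid$n_cells)
  means <- sums / ifelse(n == 0, NA_real_, n)
  means[!as.vector(grid$valid), ] <- NA_real_
  means
}

#' Mean-expression map of one gene on a grid
#'
#' @param grid A `topo_grid`.
#' @param ds The matching normalized `cell_dataset`.
#' @param gene Gene symbol (case-insensitive).
#' @return A `gene_map` whose `values` matrix holds the mean normalized
#'   expression of the gene over each valid bin's member cells (`NA` on
#'   invalid bins); `smoothed` is filled by [smooth_map()].
#' @export
gene_map <- function(grid, ds, gene) {
  stopifnot(inherits(grid, "topo_grid"))
  gi <- match_genes(gene, ds$genes)
  if (is.na(gi)) abort(paste0("unknown gene: ", gene))
  vals <- matrix(bin_means(grid, ds, gi)[, 1], nrow = grid$G)
  new_gene_map(ds$genes[gi], vals, grid)
}

new_gene_map <- function(gene, values, grid) {
  structure(
    list(gene = gene, values = values, smoothed = NULL, sigma = NULL,
         clipped_max = NULL, clip_percentile = NULL,
         G = grid$G, x_edges = grid$x_edges, y_edges = grid$y_edges,
         valid = grid$valid,
         n_cells = if (is.null(grid$n_cells)) NULL else grid$n_cells),
    class = "gene_map"
  )
}

#' @export
print.gene_map <- function(x, ...) {
  cat(sprintf("<gene_map> %s on %dx%d grid (%d valid bins)%s%s\n",
              x$gene, x$G, x$G, sum(x$valid),
              if (is.null(x$smoothed)) "" else sprintf(", smoothed sigma=%.2f", x$sigma),
              if (is.null(x$clipped_max)) "" else sprintf(", clipped at p%.0f", x$clip_percentile)))
  invisible(x)
}

#' Long tibble view of a gene map
#'
#' @param x A `gene_map`.
#' @param ... Unused.
#' @return Tibble with bin indices, raw and (if computed) smoothed values.
#' @export
#' @method tidy gene_map
tidy.gene_map <- function(x, ...) {
  out <- tibble(
    gene = x$gene,
    iy = rep(seq_len(x$G), times = x$G),
    ix = rep(seq_len(x$G), each = x$G),
    valid = as.vector(x$valid),
    value = as.vector(x$values)
  )
  out$smoothed <- if (is.null(x$smoothed)) NA_real_ else as.vector(x$smoothed)
  out
}

# truncated isotropic Gaussian kernel, SD sigma in grid units
gaussian_kernel <- function(sigma, radius = ceiling(4 * sigma)) {
  g <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# normalized (mask-aware) convolution: K*(values on mask) / K*(mask);
# returns NA where the denominator is zero
normalized_convolution <- function(values, mask, sigma) {
  G1 <- nrow(values); G2 <- ncol(values)
  r <- ceiling(4 * sigma)
  k1 <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  vm <- ifelse(mask, values, 0)
  mm <- ifelse(mask, 1, 0)
  num <- matrix(0, G1, G2)
  den <- matrix(0, G1, G2)
  for (dy in -r:r) {
    ys <- max(1, 1 + dy):min(G1, G1 + dy)   # destination rows
    yo <- ys - dy                            # source rows
    wy <- k1[dy + r + 1]
    for (dx in -r:r) {
      xs <- max(1, 1 + dx):min(G2, G2 + dx)
      xo <- xs - dx
      w <- wy * k1[dx + r + 1]
      num[ys, xs] <- num[ys, xs] + w * vm[yo, xo]
      den[ys, xs] <- den[ys, xs] + w * mm[yo, xo]
    }
  }
  out <- num / den
  out[den == 0] <- NA_real_
  list(smoothed = out, numerator = num, denominator = den)
}

#' Mask-aware Gaussian smoothing of a gene map
#'
#' Applies normalized convolution with an isotropic Gaussian kernel of SD
#' `sigma` grid units (truncated at radius `ceiling(4*sigma)`): the raw
#' values on valid bins are convolved and renormalized by the convolved
#' validity mask, so missing bins neither leak zeros in nor absorb mass.
#'
#' @param map A `gene_map`.
#' @param sigma Kernel SD in grid units (default 1.0).
#' @return The map with its `smoothed` layer filled (defined wherever the
#'   convolved mask is positive).
#' @export
smooth_map <- function(map, sigma = 1.0) {
  stopifnot(inherits(map, "gene_map"))
  assert_scalar_num(sigma, "sigma", lower = .Machine$double.eps)
  defined <- map$valid & !is.na(map$values)
  nc <- normalized_convolution(map$values, defined, sigma)
  map$smoothed <- nc$smoothed
  map$sigma <- sigma
  map
}

#' Percentile-clip a smoothed gene map
#'
#' Caps the smoothed layer at the given percentile of its defined values
#' (linear-interpolation percentile definition) so a few extreme bins do not
#' compress the dynamic range.
#'
#' @param map A smoothed `gene_map`.
#' @param percentile Clip percentile in (0, 100]; default 94.
#' @return The map with `smoothed` clipped and `clipped_max` recorded.
#' @export
clip_map <- function(map, percentile = 94) {
  stopifnot(inherits(map, "gene_map"))
  if (percentile <= 0 || percentile > 100) abort("percentile must be in (0, 100]")
  if (is.null(map$smoothed)) map <- smooth_map(map)
  vals <- map$smoothed[!is.na(map$smoothed)]
  if (!length(vals)) abort("map has no defined bins to clip")
  cmax <- as.numeric(stats::quantile(vals, percentile / 100, type = 7))
  map$smoothed[!is.na(map$smoothed) & map$smoothed > cmax] <- cmax
  map$clipped_max <- cmax
  map$clip_percentile <- percentile
  map
}

#' Reconstruct a gene's topographic map end to end
#'
#' Convenience wrapper: bin means, Gaussian smoothing, percentile clip, with
#' parameters taken from the grid's species preset.
#'
#' @inheritParams gene_map
#' @param clip Apply the preset's percentile clip (default TRUE).
#' @return A smoothed (and clipped) `gene_map`.
#' @export
reconstruct_map <- function(grid, ds, gene, clip = TRUE) {
  m <- smooth_map(gene_map(grid, ds, gene), grid$preset$sigma)
  if (clip) m <- clip_map(m, grid$preset$clip_percentile)
  m
}

#' Compare reconstructions across grid resolutions
#'
#' Rebuilds the grid at each requested resolution (same scores, same
#' thresholds) and returns one smoothed map per resolution, for assessing
#' the noise/detail trade-off of coarse versus fine grids.
#'
#' @inheritParams build_grid
#' @param gene Gene symbol to map.
#' @param sizes Integer vector of grid sizes (each >= 2).
#' @return Named list of smoothed `gene_map`s, one per size.
#' @export
grid_sensitivity <- function(scores, ds, gene, sizes = c(20, 100),
                             preset = species_preset("chicken")) {
  if (any(sizes < 2)) abort("every grid size must be >= 2")
  out <- lapply(sizes, function(G) {
    p <- species_preset("custom", grid_size = G, min_cells = preset$min_cells,
                        min_counts = preset$min_counts, sigma = preset$sigma,
                        clip_percentile = preset$clip_percentile)
    g <- build_grid(scores, ds, p)
    smooth_map(gene_map(g, ds, gene), p$sigma)
  })
  names(out) <- paste0("G", sizes)
  out
}

#' Export a gene map as delimited matrix plus JSON sidecar
#'
#' @param map A `gene_map`.
#' @param path Output TSV path for the smoothed matrix; a `.json` sidecar
#'   with edges and parameters is written alongside.
#' @return Invisibly, the two paths.
#' @export
write_gene_map <- function(map, path) {
  vals <- if (is.null(map$smoothed)) map$values else map$smoothed
  write.table(vals, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  sidecar <- sub("\\.[^.]*$", "", path)
  sidecar <- paste0(sidecar, ".json")
  jsonlite::write_json(
    list(gene = map$gene, G = map$G, x_edges = map$x_edges, y_edges = map$y_edges,
         sigma = map$sigma, clip_percentile = map$clip_percentile,
         clipped_max = map$clipped_max),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(c(path, sidecar))
}
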