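#' Construct a 1D profile
#'
#' Shared container for one-dimensional axis profiles: per-position mean
#' signal with a dispersion measure and a coverage count, used both for
#' score-space expression profiles and micrometer-space FISH intensity
#' profiles.
#'
#' @param positions Strictly increasing numeric vector (um for FISH,
#'   score units or bin index for scRNA-seq).
#' @param mean Per-position mean signal.
#' @param spread Per-position dispersion (SD or SEM, see `spread_label`).
#' @param coverage Per-position contributing cells/pixels/samples.
#' @param spread_label `"sd"` or `"sem"`.
#' @param origin Position of the reference point (0 for origin-anchored
#'   profiles, `NA` when no origin applies).
#' @param low_confidence Optional logical flag per position.
#' @return A `profile_1d` tibble.
#' @export
profile_1d <- function(positions, mean, spread, coverage,
                       spread_label = "sd", origin = NA_real_,
                       low_confidence = NULL) {
  if (any(diff(positions) <= 0)) abort("positions must be strictly increasing")
  stopifnot(length(mean) == length(positions), length(spread) == length(positions),
            length(coverage) == length(positions))
  if (any(coverage < 0, na.rm = TRUE)) abort("coverage must be non-negative")
  out <- tibble(position = positions, mean = mean, spread = spread,
                coverage = as.integer(coverage))
  if (!is.null(low_confidence)) out$low_confidence <- low_confidence
  structure(out, class = c("profile_1d", class(out)),
            spread_label = spread_label, origin = origin)
}

#' @export
print.profile_1d <- function(x, ...) {
  cat(sprintf("<profile_1d> %d positions [%g, %g], spread = %s\n",
              nrow(x), min(x$position), max(x$position), attr(x, "spread_label")))
  NextMethod()
}

#' 1D axis expression profile from scored cells
#'
#' Bins cells along one composite axis score into `n_bins` equal-width bins
#' and records the mean normalized expression of a gene per bin, its SD and
#' the number of contributing cells. Bins covered by `min_cells` cells or
#' fewer are flagged low-confidence (they are kept, dashed in plots).
#'
#' @param scores An `axis_scores` tibble.
#' @param ds The matching normalized `cell_dataset`.
#' @param gene Gene symbol.
#' @param axis `"DV"` or `"NT"`.
#' @param n_bins Number of axis bins (default 50).
#' @param min_cells Low-confidence coverage threshold (default 50; a bin
#'   needs *more* than this many cells to be trusted).
#' @return A `profile_1d` with positions at the bin centers in score units.
#' @export
axis_profile_from_cells <- function(scores, ds, gene, axis = c("DV", "NT"),
                                    n_bins = 50, min_cells = 50) {
  axis <- match.arg(axis)
  assert_scalar_num(n_bins, "n_bins", lower = 2)
  assert_scalar_num(min_cells, "min_cells", lower = 0)
  gi <- match_genes(gene, ds$genes)
  if (is.na(gi)) abort(paste0("unknown gene: ", gene))
  if (is.null(ds$norm)) abort("dataset has no normalized layer; run normalize_counts() first")
  ord <- match(ds$cells, scores$cell)
  if (anyNA(ord)) abort("scores and dataset do not share the same cells")
  s <- if (axis == "DV") scores$dv_score[ord] else scores$nt_score[ord]
  if (diff(range(s)) == 0) abort("degenerate axis: all scores identical")
  edges <- seq(min(s), max(s), length.out = n_bins + 1)
  b <- findInterval(s, edges, rightmost.closed = TRUE)
  expr <- as.numeric(ds$norm[, gi])
  mn <- sdv <- rep(NA_real_, n_bins)
  cov <- tabulate(b, nbins = n_bins)
  for (k in which(cov > 0)) {
    v <- expr[b == k]
    mn[k] <- mean(v)
    sdv[k] <- if (length(v) > 1) stats::sd(v) else 0
  }
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  profile_1d(centers, mn, sdv, cov, spread_label = "sd",
             low_confidence = cov <= min_cells)
}

#' Interpolate profiles onto a common axis
#'
#' Linearly interpolates each profile onto a shared position grid spanning
#' the union of the profiles' ranges at the given step. Positions outside a
#' profile's observed range stay missing (no extrapolation).
#'
#' @param profiles Named list of `profile_1d` objects (>= 2, each with >= 2
#'   positions).
#' @param step Spacing of the common axis, in the profiles' position units.
#' @return A `profile_matrix`: genes/samples x positions numeric matrix with
#'   the common positions as attribute `"positions"`.
#' @export
interpolate_to_common_axis <- function(profiles, step) {
  if (length(profiles) < 2) abort("need at least 2 profiles")
  assert_scalar_num(step, "step", lower = .Machine$double.eps)
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    names(profiles) <- paste0("profile_", seq_along(profiles))
  }
  for (p in profiles) {
    if (nrow(p) < 2) abort("each profile needs at least 2 positions")
    if (any(diff(p$position) <= 0)) abort("profile positions must be strictly increasing")
  }
  lo <- min(vapply(profiles, function(p) min(p$position), numeric(1)))
  hi <- max(vapply(profiles, function(p) max(p$position), numeric(1)))
  common <- seq(lo, hi, by = step)
  rows <- vapply(profiles, function(p) {
    ok <- !is.na(p$mean)
    stats::approx(p$position[ok], p$mean[ok], xout = common, rule = 1)$y
  }, numeric(length(common)))
  pm <- t(rows)
  rownames(pm) <- names(profiles)
  structure(pm, positions = common, class = c("profile_matrix", "matrix", "array"))
}

#' Long tibble view of a profile matrix
#'
#' @param x A `profile_matrix`.
#' @param ... Unused.
#' @return Tibble with `gene`, `position`, `value`.
#' @export
#' @method tidy profile_matrix
tidy.profile_matrix <- function(x, ...) {
  tibble(
    gene = rep(rownames(x), times = ncol(x)),
    position = rep(attr(x, "positions"), each = nrow(x)),
    value = as.vector(unclass(x))
  )
}

#' Masked pairwise Pearson correlation of profiles
#'
#' Each entry is computed over positions where both profiles are observed;
#' entries with fewer than 3 joint positions, or a zero-variance profile on
#' the joint support, are missing (with a warning for the latter).
#'
#' @param pm A `profile_matrix` (>= 2 rows).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
profile_correlation_matrix <- function(pm) {
  if (nrow(pm) < 2) abort("need at least 2 profiles")
  n <- nrow(pm)
  C <- diag(1, n)
  dimnames(C) <- list(rownames(pm), rownames(pm))
  warned <- FALSE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    keep <- !is.na(pm[i, ]) & !is.na(pm[j, ])
    if (sum(keep) < 3) {
      C[i, j] <- C[j, i] <- NA_real_
      next
    }
    a <- pm[i, keep]; b <- pm[j, keep]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      if (!warned) {
        warn("zero-variance profile over joint support: correlation set to NA")
        warned <- TRUE
      }
      C[i, j] <- C[j, i] <- NA_real_
    } else {
      C[i, j] <- C[j, i] <- stats::cor(a, b)
    }
  }
  C
}

#' Correlation-based hierarchical clustering with optimal leaf ordering
#'
#' Converts a profile correlation matrix to distances (`1 - r`; missing
#' correlations imputed as 0 correlation, with a warning), clusters with
#' average linkage, and reorders the dendrogram leaves by exact
#' dynamic-programming optimal leaf ordering, minimizing the total distance
#' between adjacent leaves subject to the tree.
#'
#' @param corr Symmetric correlation matrix (>= 2 rows).
#' @return A `profile_clustering` list: the `hclust` object, the optimal
#'   `leaf_order` (labels), the distance matrix used, and the adjacent
#'   distance sum of the optimal order.
#' @export
cluster_profiles <- function(corr) {
  corr <- as.matrix(corr)
  if (nrow(corr) < 2) abort("need at least 2 leaves to cluster")
  if (anyNA(corr)) {
    warn("missing correlations imputed as 0 before clustering")
    corr[is.na(corr)] <- 0
  }
  D <- 1 - corr
  diag(D) <- 0
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  ord <- olo_order(hc, D)
  structure(
    list(hclust = hc, leaf_order = rownames(corr)[ord], order_idx = ord,
         distance = D, adjacent_sum = adjacent_distance_sum(D, ord)),
    class = "profile_clustering"
  )
}

#' @export
print.profile_clustering <- function(x, ...) {
  cat(sprintf("<profile_clustering> %d leaves, optimal adjacent-distance sum %.4f\n",
              length(x$leaf_order), x$adjacent_sum))
  cat("  order:", paste(x$leaf_order, collapse = " "), "\n")
  invisible(x)
}

#' Newick export of a profile clustering
#'
#' @param clust A `profile_clustering`.
#' @return Newick string with merge heights as branch lengths.
#' @export
clustering_newick <- function(clust) {
  hc <- clust$hclust
  labs <- hc$labels
  build <- function(id, parent_h) {
    if (id < 0) {
      sprintf("%s:%g", labs[-id], parent_h)
    } else {
      h <- hc$height[id]
      sprintf("(%s,%s):%g", build(hc$merge[id, 1], h), build(hc$merge[id, 2], h),
              parent_h - h)
    }
  }
  root <- nrow(hc$merge)
  h <- hc$height[root]
  paste0("(", build(hc$merge[root, 1], h), ",", build(hc$merge[root, 2], h), ");")
}

#' Cross-modal gene profile comparison
#'
#' Compares each shared gene's FISH intensity profile with its scRNA-seq
#' reconstruction profile. Positions and values of both profiles are
#' rescaled to \[0, 1\] (the two modalities have incommensurate units), the
#' denser profile is linearly interpolated onto the sparser profile's
#' positions, and per-gene Pearson r is reported.
#'
#' @param fish,scrna Named lists of `profile_1d` objects (names are gene
#'   symbols, matched case-insensitively).
#' @param gene_pairs Optional two-column data frame (`fish`, `scrna`) naming
#'   the pairs to compare; defaults to the shared gene names.
#' @return Tibble with `gene`, `r`, `n_positions` (NA r with a warning for
#'   constant profiles).
#' @export
cross_modal_compare <- function(fish, scrna, gene_pairs = NULL) {
  if (is.null(gene_pairs)) {
    shared <- intersect(symbol_key(names(fish)), symbol_key(names(scrna)))
    if (!length(shared)) abort("no shared genes between the two modalities")
    gene_pairs <- tibble(
      fish = names(fish)[match(shared, symbol_key(names(fish)))],
      scrna = names(scrna)[match(shared, symbol_key(names(scrna)))]
    )
  }
  rescale01 <- function(x) {
    r <- range(x, na.rm = TRUE)
    if (diff(r) == 0) return(rep(NA_real_, length(x)))
    (x - r[1]) / diff(r)
  }
  purrr::pmap_dfr(gene_pairs, function(fish_gene, scrna_gene, ...) {
    pf <- fish[[fish_gene]]; ps <- scrna[[scrna_gene]]
    prep <- function(p) {
      ok <- !is.na(p$mean)
      list(x = rescale01(p$position[ok]), y = rescale01(p$mean[ok]))
    }
    a <- prep(pf); b <- prep(ps)
    if (all(is.na(a$y)) || all(is.na(b$y))) {
      warn(sprintf("constant profile for %s: cross-modal r undefined", fish_gene))
      return(tibble(gene = fish_gene, r = NA_real_, n_positions = 0L))
    }
    if (length(a$x) > length(b$x)) {
      yi <- stats::approx(a$x, a$y, xout = b$x, rule = 1)$y
      ya <- yi; yb <- b$y
    } else {
      yi <- stats::approx(b$x, b$y, xout = a$x, rule = 1)$y
      ya <- a$y; yb <- yi
    }
    keep <- !is.na(ya) & !is.na(yb)
    tibble(gene = fish_gene, r = stats::cor(ya[keep], yb[keep]),
           n_positions = sum(keep))
  })
}

#' Extract a 1D cross-section profile from a gene map
#'
#' Averages the smoothed map along the orthogonal axis to produce a profile
#' along DV (row means) or NT (column means), used for cross-modal
#' comparison against FISH strip profiles.
#'
#' @param map A smoothed `gene_map`.
#' @param axis `"DV"` or `"NT"`.
#' @return A `profile_1d` in score units (bin centers).
#' @export
map_axis_profile <- function(map, axis = c("DV", "NT")) {
  axis <- match.arg(axis)
  vals <- if (is.null(map$smoothed)) map$values else map$smoothed
  if (axis == "DV") {
    centers <- (map$y_edges[-1] + map$y_edges[-(map$G + 1)]) / 2
    mn <- rowMeans(vals, na.rm = TRUE)
    cov <- rowSums(!is.na(vals))
    sdv <- apply(vals, 1, stats::sd, na.rm = TRUE)
  } else {
    centers <- (map$x_edges[-1] + map$x_edges[-(map$G + 1)]) / 2
    mn <- colMeans(vals, na.rm = TRUE)
    cov <- colSums(!is.na(vals))
    sdv <- apply(vals, 2, stats::sd, na.rm = TRUE)
  }
  keep <- cov > 0
  profile_1d(centers[keep], mn[keep], sdv[keep], cov[keep], spread_label = "sd")
}
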