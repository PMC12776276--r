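#' Contiguity weights over the valid bins of a grid
#'
#' Binary spatial weights on the lattice of valid grid cells: queen
#' (8-neighbor, default) or rook (4-neighbor) contiguity, restricted to
#' valid bins.
#'
#' @param x A `topo_grid` or `gene_map` (anything carrying a `valid` mask),
#'   or a logical matrix.
#' @param style `"queen"` or `"rook"`.
#' @return A `spatial_weights` list: sparse symmetric adjacency `A` over the
#'   valid bins, total weight `W`, the linear indices of the valid bins and
#'   the grid dimensions.
#' @export
spatial_weights <- function(x, style = c("queen", "rook")) {
  style <- match.arg(style)
  valid <- if (is.matrix(x) && is.logical(x)) x else x$valid
  G1 <- nrow(valid); G2 <- ncol(valid)
  idx <- which(valid)                      # linear indices, column-major
  pos <- arrayInd(idx, c(G1, G2))
  id_of <- matrix(0L, G1, G2)
  id_of[idx] <- seq_along(idx)
  offs <- if (style == "queen") {
    cbind(dy = c(-1, -1, -1, 0, 0, 1, 1, 1), dx = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dy = c(-1, 1, 0, 0), dx = c(0, 0, -1, 1))
  }
  ii <- integer(0); jj <- integer(0)
  for (k in seq_len(nrow(offs))) {
    ny <- pos[, 1] + offs[k, 1]
    nx <- pos[, 2] + offs[k, 2]
    ok <- ny >= 1 & ny <= G1 & nx >= 1 & nx <= G2
    ok[ok] <- valid[cbind(ny[ok], nx[ok])]
    ii <- c(ii, id_of[cbind(pos[ok, 1], pos[ok, 2])])
    jj <- c(jj, id_of[cbind(ny[ok], nx[ok])])
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(length(idx), length(idx)))
  structure(list(A = A, W = sum(A), valid_idx = idx, dim = c(G1, G2), style = style),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("<spatial_weights> %s contiguity, %d bins, W = %g\n",
              x$style, length(x$valid_idx), x$W))
  invisible(x)
}

# values of a map on the valid bins (smoothed layer when available)
map_valid_values <- function(map, layer = c("auto", "smoothed", "raw")) {
  layer <- match.arg(layer)
  v <- switch(layer,
    auto = if (is.null(map$smoothed)) map$values else map$smoothed,
    smoothed = map$smoothed,
    raw = map$values
  )
  if (is.null(v)) abort("map has no smoothed layer; run smooth_map() first")
  v[map$valid]
}

# Moran's I of a plain numeric vector given weights
morans_I_vec <- function(z, weights) {
  n <- length(z)
  if (n < 2) abort("need at least 2 valid bins")
  z <- z - mean(z)
  s2 <- sum(z^2)
  if (s2 == 0) abort("zero variance: Moran's I undefined for a constant field")
  (n / weights$W) * sum(z * as.numeric(weights$A %*% z)) / s2
}

#' Moran's I spatial autocorrelation of a gene map
#'
#' `I = (n/W) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the (smoothed)
#' map values centered over valid bins and `w` binary contiguity weights.
#'
#' @param map A `gene_map` (its smoothed layer is used when present).
#' @param weights `spatial_weights` built on the same validity mask.
#' @return Moran's I (a single finite number).
#' @export
morans_I <- function(map, weights) {
  z <- map_valid_values(map)
  if (length(z) != length(weights$valid_idx)) {
    abort("weights were built on a different validity mask than the map")
  }
  if (anyNA(z)) abort("map has undefined values on valid bins")
  morans_I_vec(z, weights)
}

# sparse row-normalized smoothing operator over valid bins: applies the
# truncated Gaussian normalized convolution, restricted valid -> valid
build_smoother <- function(valid, sigma) {
  G1 <- nrow(valid); G2 <- ncol(valid)
  r <- ceiling(4 * sigma)
  k1 <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  idx <- which(valid)
  pos <- arrayInd(idx, c(G1, G2))
  id_of <- matrix(0L, G1, G2)
  id_of[idx] <- seq_along(idx)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (dy in -r:r) for (dx in -r:r) {
    ny <- pos[, 1] + dy
    nx <- pos[, 2] + dx
    ok <- ny >= 1 & ny <= G1 & nx >= 1 & nx <= G2
    ok[ok] <- valid[cbind(ny[ok], nx[ok])]
    ii <- c(ii, id_of[cbind(pos[ok, 1], pos[ok, 2])])
    jj <- c(jj, id_of[cbind(ny[ok], nx[ok])])
    xx <- c(xx, rep(k1[dy + r + 1] * k1[dx + r + 1], sum(ok)))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(length(idx), length(idx)))
  S / Matrix::rowSums(S)
}

# permutation Moran's I machinery for a matrix of raw valid-bin value
# vectors (columns = genes).
#
# Two calibration subtleties, both handled here:
#  * the smoothing is re-applied to every permutation (if sigma not NULL),
#    so the null distribution carries the smoothing-induced lattice
#    autocorrelation instead of mistaking it for signal;
#  * raw bin means are heteroskedastic (variance ~ 1/n_cells) and cell
#    density is itself spatially smooth, so raw values are not exchangeable
#    under the null. The test therefore permutes variance-standardized
#    residuals y_i = sqrt(n_i) * (x_i - mean(x)), which are exchangeable
#    for a spatially flat gene, and uses I of the smoothed standardized
#    field as the test statistic. The reported I remains Moran's I of the
#    smoothed expression map itself.
morans_perm_test <- function(raw_vals, valid, weights, sigma, n_perm, seed,
                             n_cells = NULL) {
  n <- nrow(raw_vals)
  S <- if (!is.null(sigma)) build_smoother(valid, sigma) else NULL
  I_of_cols <- function(M) {
    M <- sweep(M, 2, colMeans(M))
    den <- colSums(M^2)
    num <- colSums(M * as.matrix(weights$A %*% M))
    ifelse(den == 0, NA_real_, (n / weights$W) * num / den)
  }
  obs_field <- if (is.null(S)) raw_vals else as.matrix(S %*% raw_vals)
  I_obs <- I_of_cols(obs_field)

  w_std <- if (is.null(n_cells)) rep(1, n) else sqrt(n_cells)
  std_vals <- sweep(raw_vals, 2, colMeans(raw_vals)) * w_std
  stat_obs <- I_of_cols(if (is.null(S)) std_vals else as.matrix(S %*% std_vals))

  perm_idx <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  })
  exceed <- integer(ncol(raw_vals))
  # per-gene permuted fields; permutations shared across genes
  for (g in seq_len(ncol(raw_vals))) {
    if (is.na(stat_obs[g])) { exceed[g] <- NA_integer_; next }
    V <- matrix(std_vals[, g][perm_idx], nrow = n)
    field <- if (is.null(S)) V else as.matrix(S %*% V)
    exceed[g] <- sum(I_of_cols(field) >= stat_obs[g], na.rm = TRUE)
  }
  list(I = I_obs, p = (1 + exceed) / (1 + n_perm), n = n)
}

#' Permutation test for spatial autocorrelation of one map
#'
#' One-sided test for positive spatial autocorrelation. The binned values
#' are variance-standardized (`sqrt(n_cells) * (x - mean)`, exchangeable
#' under a spatially flat gene despite unequal bin occupancy), permuted
#' across valid bins, and the map's Gaussian smoothing is re-applied to
#' each permutation so the null carries the smoothing-induced lattice
#' autocorrelation; `p = (1 + #{I_perm >= I_obs}) / (1 + n_perm)` on the
#' smoothed standardized fields. The reported `I` is Moran's I of the
#' smoothed expression map.
#'
#' @param map A `gene_map`.
#' @param weights Matching `spatial_weights`.
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed RNG seed.
#' @return One-row tibble: `gene`, `I`, `n` (valid bins), `p_value`.
#' @export
morans_test <- function(map, weights, n_perm = 999, seed = 0) {
  assert_scalar_num(n_perm, "n_perm", lower = 99)
  raw <- map$values[map$valid]
  if (anyNA(raw)) abort("map has undefined raw values on valid bins")
  if (var(raw) == 0) abort("zero variance: Moran's I undefined for a constant field")
  nc <- if (is.null(map$n_cells)) NULL else map$n_cells[map$valid]
  res <- morans_perm_test(matrix(raw, ncol = 1), map$valid, weights,
                          map$sigma, n_perm, seed, n_cells = nc)
  tibble(gene = map$gene, I = res$I[1], n = res$n, p_value = res$p[1])
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR q-values (wrapper over [stats::p.adjust()] with
#' range validation).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length.
#' @export
bh_adjust <- function(p_values) {
  ok <- is.na(p_values) | (p_values >= 0 & p_values <= 1)
  if (!all(ok)) abort("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Scan all genes for spatially variable expression
#'
#' Builds the binned mean map of every gene, smooths it with the preset's
#' Gaussian kernel, and runs the permutation Moran's I test
#' (see [morans_test()]); q-values are BH-adjusted over the testable genes
#' and significance is called at `q < alpha`.
#'
#' @param grid A `topo_grid`.
#' @param ds The matching normalized `cell_dataset`.
#' @param genes Genes to test (default: all genes of the dataset).
#' @param n_perm Permutations per gene (default 999).
#' @param seed RNG seed (one shared permutation set across genes).
#' @param alpha Significance threshold on the q-value (default 0.01, the
#'   SVG retention threshold).
#' @param style Contiguity style for the weights.
#' @return Tibble with `gene`, `I`, `n`, `p_value`, `q_value`,
#'   `significant`, ordered as the input genes; the smoothed valid-bin
#'   pattern matrix is attached as attribute `"patterns"` for anchor
#'   selection.
#' @export
svg_scan <- function(grid, ds, genes = NULL, n_perm = 999, seed = 0,
                     alpha = 0.01, style = "queen") {
  genes <- genes %||% ds$genes
  gi <- match_genes(genes, ds$genes)
  if (anyNA(gi)) abort(paste0("unknown genes: ", paste(genes[is.na(gi)], collapse = ", ")))
  weights <- spatial_weights(grid, style = style)
  means <- bin_means(grid, ds, gi)          # (G*G) x n_genes, NA off-valid
  raw <- means[as.vector(grid$valid), , drop = FALSE]
  sds <- apply(raw, 2, stats::sd)
  testable <- !is.na(sds) & sds > 0
  res <- morans_perm_test(raw[, testable, drop = FALSE], grid$valid, weights,
                          grid$preset$sigma, n_perm, seed,
                          n_cells = grid$n_cells[grid$valid])
  out <- tibble(gene = ds$genes[gi], I = NA_real_, n = nrow(raw),
                p_value = NA_real_)
  out$I[testable] <- res$I
  out$p_value[testable] <- res$p
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- !is.na(out$q_value) & out$q_value < alpha
  S <- build_smoother(grid$valid, grid$preset$sigma)
  patterns <- as.matrix(S %*% raw)
  colnames(patterns) <- out$gene
  attr(out, "patterns") <- patterns
  attr(out, "alpha") <- alpha
  attr(out, "valid") <- grid$valid
  out
}

#' Cosine similarity of two gene maps
#'
#' Computed over the bins where both maps are defined (smoothed layers when
#' present).
#'
#' @param map_a,map_b `gene_map`s on the same grid.
#' @return Cosine similarity in \[-1, 1\], or `NA` (with a warning) when
#'   either vector has zero norm.
#' @export
cosine_similarity <- function(map_a, map_b) {
  a <- map_valid_values(map_a)
  b <- map_valid_values(map_b)
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) abort("maps share no defined bins")
  cosine_vec(a[keep], b[keep])
}

cosine_vec <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    warn("zero-norm pattern: cosine similarity undefined")
    return(NA_real_)
  }
  sum(a * b) / (na * nb)
}

#' Pearson correlation of two gene maps
#'
#' Pearson r over jointly defined bins with the exact two-sided t-test;
#' maps are flagged spatially similar at `r > 0.9` and `p < 0.001`.
#'
#' @param map_a,map_b `gene_map`s on the same grid.
#' @return One-row tibble: `r`, `p_value`, `n_bins`, `similar`.
#' @export
pearson_spatial <- function(map_a, map_b) {
  a <- map_valid_values(map_a)
  b <- map_valid_values(map_b)
  keep <- !is.na(a) & !is.na(b)
  if (sum(keep) < 3) abort("need at least 3 jointly defined bins")
  a <- a[keep]; b <- b[keep]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) abort("zero variance in one of the maps")
  ct <- stats::cor.test(a, b, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n_bins = sum(keep),
         similar = unname(ct$estimate) > 0.9 & ct$p.value < 0.001)
}

# extract an n_valid x n_genes pattern matrix from svg_scan output or a
# named list of gene_maps
pattern_matrix <- function(maps) {
  if (is.matrix(maps)) return(maps)
  if (is.data.frame(maps) && !is.null(attr(maps, "patterns"))) return(attr(maps, "patterns"))
  if (is.list(maps)) {
    cols <- lapply(maps, map_valid_values)
    m <- do.call(cbind, cols)
    colnames(m) <- vapply(maps, function(x) x$gene, character(1))
    return(m)
  }
  abort("cannot extract spatial patterns from this object")
}

cosine_matrix <- function(M) {
  keep <- stats::complete.cases(M)
  M <- M[keep, , drop = FALSE]
  nrm <- sqrt(colSums(M^2))
  C <- crossprod(M) / outer(nrm, nrm)
  C[!is.finite(C)] <- NA_real_
  C
}

#' Greedy selection of spatial anchor genes
#'
#' Scans significant genes in order of decreasing Moran's I (ties broken by
#' input order); a gene becomes an anchor iff its maximum cosine similarity
#' to all anchors selected so far is below `tau_redundancy`. Selection stops
#' at `A_max` anchors or exhaustion. Every significant gene is then assigned
#' to its most-similar anchor.
#'
#' @param stats Tibble from [svg_scan()] (or with columns `gene`, `I`,
#'   `significant`).
#' @param maps Spatial patterns: the `svg_scan` result itself, a pattern
#'   matrix, or a named list of smoothed `gene_map`s. Defaults to `stats`.
#' @param A_max Maximum number of anchors (default 20).
#' @param tau_redundancy Cosine redundancy threshold in (0, 1), default 0.9.
#' @return An `anchor_set`: ordered anchors, per-gene assignment with
#'   similarity, and member counts.
#' @export
select_anchors <- function(stats, maps = stats, A_max = 20, tau_redundancy = 0.9) {
  assert_scalar_num(A_max, "A_max", lower = 1)
  if (tau_redundancy <= 0 || tau_redundancy >= 1) abort("tau_redundancy must be in (0, 1)")
  M <- pattern_matrix(maps)
  sig <- stats[!is.na(stats$I) & stats$significant, , drop = FALSE]
  if (!nrow(sig)) abort("no significant spatially variable genes to anchor")
  sig <- sig[order(-sig$I, seq_len(nrow(sig))), , drop = FALSE]
  M <- M[, sig$gene, drop = FALSE]
  C <- cosine_matrix(M)
  anchors <- character(0)
  for (g in sig$gene) {
    if (length(anchors) >= A_max) break
    if (!length(anchors) || max(C[g, anchors], na.rm = TRUE) < tau_redundancy) {
      anchors <- c(anchors, g)
    }
  }
  sim_to_anchor <- C[sig$gene, anchors, drop = FALSE]
  best <- anchors[max.col(sim_to_anchor, ties.method = "first")]
  assignment <- tibble(
    gene = sig$gene,
    anchor = best,
    similarity = sim_to_anchor[cbind(seq_len(nrow(sig)), match(best, anchors))],
    I = sig$I
  )
  structure(
    list(anchors = anchors, assignment = assignment,
         anchor_groups = NULL, tau_redundancy = tau_redundancy,
         member_counts = table(factor(assignment$anchor, levels = anchors)),
         patterns = M),
    class = "anchor_set"
  )
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("<anchor_set> %d anchors over %d genes (tau = %.2f)\n",
              length(x$anchors), nrow(x$assignment), x$tau_redundancy))
  if (!is.null(x$anchor_groups)) {
    cat(sprintf("  %d groups: %s\n", length(x$anchor_groups),
                paste(vapply(x$anchor_groups, paste, character(1), collapse = "+"),
                      collapse = " | ")))
  }
  invisible(x)
}

#' Per-gene tibble view of an anchor set
#'
#' @param x An `anchor_set`.
#' @param ... Unused.
#' @return The assignment tibble (gene, anchor, similarity, I) with a
#'   `group` column when anchors have been grouped.
#' @export
#' @method tidy anchor_set
tidy.anchor_set <- function(x, ...) {
  out <- x$assignment
  if (!is.null(x$anchor_groups)) {
    gid <- rep(seq_along(x$anchor_groups), lengths(x$anchor_groups))
    names(gid) <- unlist(x$anchor_groups)
    out$group <- unname(gid[out$anchor])
  }
  out
}

#' Group anchors by mutual nearest neighbors
#'
#' An anchor forms a cluster iff at least `min_members` assigned genes
#' (excluding itself) have similarity `>= tau_redundancy` to it. Two
#' cluster-forming anchors are merged iff each is the other's most-similar
#' anchor (mutual nearest neighbor); merges propagate transitively.
#' Non-cluster-forming anchors remain singleton groups.
#'
#' @param anchors An `anchor_set` from [select_anchors()].
#' @param maps Optional pattern source (defaults to the patterns stored in
#'   the anchor set).
#' @param min_members Minimum member genes for an anchor to form a cluster
#'   (default 2).
#' @return The `anchor_set` with `anchor_groups` (list of anchor vectors)
#'   and a `forms_cluster` flag per anchor.
#' @export
group_anchors <- function(anchors, maps = NULL, min_members = 2) {
  stopifnot(inherits(anchors, "anchor_set"))
  M <- if (is.null(maps)) anchors$patterns else pattern_matrix(maps)
  a <- anchors$anchors
  asn <- anchors$assignment
  members_ok <- vapply(a, function(an) {
    sum(asn$anchor == an & asn$gene != an & asn$similarity >= anchors$tau_redundancy)
  }, numeric(1))
  forms_cluster <- members_ok >= min_members
  groups <- as.list(a)
  if (length(a) > 1) {
    C <- cosine_matrix(M[, a, drop = FALSE])
    diag(C) <- -Inf
    nn <- a[max.col(C, ties.method = "first")]
    names(nn) <- a
    parent <- stats::setNames(seq_along(a), a)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_along(a)) {
      j <- match(nn[a[i]], a)
      if (forms_cluster[i] && forms_cluster[j] && nn[a[j]] == a[i]) {
        parent[find(i)] <- find(j)
      }
    }
    roots <- vapply(seq_along(a), find, numeric(1))
    groups <- split(a, roots)
    groups <- groups[order(vapply(groups, function(g) match(g[1], a), numeric(1)))]
    names(groups) <- NULL
  }
  anchors$anchor_groups <- groups
  anchors$forms_cluster <- stats::setNames(forms_cluster, a)
  anchors
}

#' Write an SVG table and anchor report
#'
#' @param stats Tibble from [svg_scan()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_svg_table <- function(stats, path) {
  write.table(as.data.frame(stats), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_svg_table
#' @param anchors An `anchor_set`.
#' @export
write_anchor_report <- function(anchors, path) {
  jsonlite::write_json(
    list(
      anchors = anchors$anchors,
      tau_redundancy = anchors$tau_redundancy,
      member_counts = as.list(anchors$member_counts),
      groups = anchors$anchor_groups %||% list(),
      assignment = anchors$assignment
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
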