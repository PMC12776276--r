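#' Define a grid region from a marker gene map
#'
#' Selects the bins whose smoothed marker expression is at or above the
#' `q_region` quantile over valid bins — the automated counterpart of
#' manually circling a marker-enriched territory (HAA, nasal-most, ...).
#' An explicit bin list can be supplied instead via `bins`.
#'
#' @param map A smoothed `gene_map` of the region marker.
#' @param q_region Quantile threshold in (0, 1); default 0.95.
#' @param bins Optional explicit two-column matrix/data frame of (iy, ix)
#'   bin indices, bypassing the quantile rule.
#' @return A `region_spec` with the selected bin set.
#' @export
define_region <- function(map, q_region = 0.95, bins = NULL) {
  stopifnot(inherits(map, "gene_map"))
  if (!is.null(bins)) {
    bins <- as.matrix(bins)[, 1:2, drop = FALSE]
    ok <- map$valid[bins]
    if (!all(ok)) abort("explicit bin list includes invalid bins")
    if (!nrow(bins)) abort("empty region")
    return(structure(list(marker_gene = map$gene, bins = bins, rule = "explicit",
                          q_region = NA_real_, G = map$G),
                     class = "region_spec"))
  }
  if (q_region <= 0 || q_region >= 1) abort("q_region must be in (0, 1)")
  if (is.null(map$smoothed)) map <- smooth_map(map)
  vals <- map$smoothed
  vals[!map$valid] <- NA_real_
  defined <- which(!is.na(vals))
  if (!length(defined)) abort("no defined bins")
  if (stats::sd(vals[defined]) == 0) abort("constant map: no enrichment to threshold")
  thr <- stats::quantile(vals[defined], q_region, type = 7)
  sel <- defined[vals[defined] >= thr]
  if (!length(sel)) abort("empty region at this quantile")
  structure(list(marker_gene = map$gene,
                 bins = arrayInd(sel, c(map$G, map$G)),
                 rule = "quantile", q_region = q_region, G = map$G),
            class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("<region_spec> marker %s: %d bins (%s rule%s)\n",
              x$marker_gene, nrow(x$bins), x$rule,
              if (is.na(x$q_region)) "" else sprintf(", q = %.2f", x$q_region)))
  invisible(x)
}

#' Pseudobulk cells by embryo and region membership
#'
#' Sums raw counts of all cells from each embryo inside (`in`) and outside
#' (`out`) the region. Pseudobulks with 100 cells or fewer are flagged
#' excluded and skipped by the DE test.
#'
#' @param ds A `cell_dataset`.
#' @param grid The `topo_grid` the region was defined on.
#' @param region A `region_spec`.
#' @param min_pb_cells Exclusion threshold: a pseudobulk must have *more*
#'   than this many cells (default 100; set 0 to disable for toy data).
#' @return A `pseudobulk` object: `info` tibble (embryo_id, group, n_cells,
#'   excluded) and matching `counts` matrix (rows = pseudobulks).
#' @export
pseudobulk <- function(ds, grid, region, min_pb_cells = 100) {
  stopifnot(inherits(region, "region_spec"), inherits(grid, "topo_grid"))
  in_bins <- (region$bins[, 2] - 1L) * grid$G + region$bins[, 1]
  in_region <- grid$assignment$bin %in% in_bins
  embryo <- as.character(ds$meta$embryo_id)
  both <- tapply(in_region, embryo, function(x) any(x) && any(!x))
  if (!any(both, na.rm = TRUE)) abort("no embryo has cells both inside and outside the region")
  group <- ifelse(in_region, "in", "out")
  key <- paste(embryo, group, sep = "\r")
  keys <- sort(unique(key))
  S <- Matrix::sparseMatrix(i = match(key, keys), j = seq_along(key), x = 1,
                            dims = c(length(keys), length(key)))
  counts <- as.matrix(S %*% ds$counts)
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  info <- tibble(
    embryo_id = parts[, 1], group = parts[, 2],
    n_cells = as.integer(tabulate(match(key, keys), nbins = length(keys)))
  )
  info$excluded <- info$n_cells <= min_pb_cells
  rownames(counts) <- paste(info$embryo_id, info$group, sep = "_")
  colnames(counts) <- ds$genes
  structure(list(info = info, counts = counts, region = region,
                 min_pb_cells = min_pb_cells),
            class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf("<pseudobulk> %d pseudobulks (%d retained) x %d genes; region marker %s\n",
              nrow(x$info), sum(!x$info$excluded), ncol(x$counts),
              x$region$marker_gene))
  invisible(x)
}

#' @export
#' @method tidy pseudobulk
tidy.pseudobulk <- function(x, ...) x$info

#' Negative-binomial differential expression, in-region vs out
#'
#' Per-gene Gamma-Poisson (negative binomial) GLM on the retained
#' pseudobulks: log link, design `~ group`, offset `log(total counts)`,
#' per-gene ML dispersion, Wald test on the group coefficient. Genes
#' significant at `|log2FC| > 1` and BH `q < 0.05`. Genes whose NB fit does
#' not converge fall back to a Poisson GLM (flagged in the result).
#'
#' @param pb A `pseudobulk` object.
#' @return Tibble per tested gene: `gene`, `mean_expr` (mean count over
#'   retained pseudobulks), `log2_fc` (in vs out), `p_value`, `q_value`,
#'   `significant`, `method`. All-zero genes are excluded and listed in the
#'   `"excluded_genes"` attribute.
#' @export
nb_glm_test <- function(pb) {
  stopifnot(inherits(pb, "pseudobulk"))
  keep <- !pb$info$excluded
  info <- pb$info[keep, , drop = FALSE]
  counts <- pb$counts[keep, , drop = FALSE]
  if (sum(info$group == "in") < 2 || sum(info$group == "out") < 2) {
    abort("need at least 2 retained pseudobulks per group")
  }
  group <- factor(info$group, levels = c("out", "in"))
  off <- log(rowSums(counts))
  nonzero <- colSums(counts) > 0
  res <- purrr::map_dfr(which(nonzero), function(j) {
    y <- counts[, j]
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(y ~ group + offset(off))),
      error = function(e) NULL
    )
    method <- "nb"
    if (is.null(fit) || !fit$converged) {
      fit <- suppressWarnings(stats::glm(y ~ group + offset(off), family = stats::poisson()))
      method <- "poisson"
    }
    sm <- summary(fit)$coefficients
    tibble(
      gene = colnames(counts)[j],
      mean_expr = mean(y),
      log2_fc = unname(sm["groupin", "Estimate"]) / log(2),
      p_value = unname(sm["groupin", ncol(sm)]),
      method = method
    )
  })
  res$q_value <- bh_adjust(res$p_value)
  res$significant <- abs(res$log2_fc) > 1 & res$q_value < 0.05
  attr(res, "excluded_genes") <- colnames(counts)[!nonzero]
  res
}

#' Highlight table for a volcano plot
#'
#' Ranks enriched (positive fold-change) genes by q-value, breaking ties by
#' `|log2FC|` then symbol order, drops symbols with the exclusion prefix
#' (default `"LOC"`, uncurated locus identifiers), and keeps the top
#' `top_k`.
#'
#' @param results DE result tibble from [nb_glm_test()].
#' @param top_k Number of genes to highlight (default 5).
#' @param exclude_prefix Symbol prefix to drop (default `"LOC"`).
#' @return Tibble of the highlighted genes (possibly empty, with a warning
#'   when nothing qualifies).
#' @export
volcano_table <- function(results, top_k = 5, exclude_prefix = "LOC") {
  if (!nrow(results)) abort("empty DE results")
  cand <- results[results$log2_fc > 0 & !startsWith(results$gene, exclude_prefix), , drop = FALSE]
  if (!nrow(cand)) {
    warn("no enriched genes left after prefix exclusion")
    return(cand)
  }
  cand <- cand[order(cand$q_value, -abs(cand$log2_fc), cand$gene), , drop = FALSE]
  head(cand, top_k)
}

#' Write DE results as TSV
#'
#' @param results DE result tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_de_results <- function(results, path) {
  write.table(as.data.frame(results), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
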