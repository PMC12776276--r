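#' Per-cell module score for a marker gene set
#'
#' Scores every cell for a gene signature as the mean normalized expression
#' of the set genes minus the mean of expression-matched control genes. Genes
#' are ranked by average normalized expression and split into `n_bins`
#' equal-frequency bins (ties broken by gene order); for each set gene,
#' `n_ctrl` controls are drawn from its bin (without replacement, falling
#' back to replacement when the bin is smaller than `n_ctrl`), and the
#' per-gene control pools are concatenated, duplicates allowed.
#'
#' @param ds A normalized `cell_dataset` (see [normalize_counts()]).
#' @param gene_set Character vector of marker symbols; matched
#'   case-insensitively. At least one must resolve.
#' @param n_bins Number of expression bins (default 24).
#' @param n_ctrl Controls drawn per set gene (default 100).
#' @param seed RNG seed for the control draws; scores are deterministic given
#'   the seed.
#' @return Numeric vector, one score per cell.
#' @export
compute_module_score <- function(ds, gene_set, n_bins = 24, n_ctrl = 100, seed = 0) {
  stopifnot(inherits(ds, "cell_dataset"))
  if (is.null(ds$norm)) abort("dataset has no normalized layer; run normalize_counts() first")
  assert_scalar_num(n_bins, "n_bins", lower = 2)
  assert_scalar_num(n_ctrl, "n_ctrl", lower = 1)
  n_genes <- length(ds$genes)
  if (n_bins > n_genes) abort(sprintf("n_bins (%d) exceeds gene count (%d)", n_bins, n_genes))
  idx <- match_genes(gene_set, ds$genes)
  if (all(is.na(idx))) {
    abort(paste0("no gene of the set resolves in the dataset: ", paste(gene_set, collapse = ", ")))
  }
  if (any(is.na(idx))) {
    warn(paste0("unresolved set genes dropped from scoring: ",
                paste(gene_set[is.na(idx)], collapse = ", ")))
    idx <- idx[!is.na(idx)]
  }

  gene_bin <- expression_bins(ds, n_bins)
  ctrl_idx <- with_seed(seed, {
    unlist(lapply(idx, function(g) {
      pool <- setdiff(which(gene_bin == gene_bin[g]), g)
      if (!length(pool)) pool <- which(gene_bin == gene_bin[g])
      if (length(pool) >= n_ctrl) sample(pool, n_ctrl) else sample(pool, n_ctrl, replace = TRUE)
    }))
  })

  set_mean <- Matrix::rowSums(ds$norm[, idx, drop = FALSE]) / length(idx)
  # duplicates in the control pool carry weight, so sum per unique column scaled by multiplicity
  tab <- table(ctrl_idx)
  cols <- as.integer(names(tab))
  w <- as.numeric(tab)
  ctrl_mean <- as.numeric(ds$norm[, cols, drop = FALSE] %*% w) / length(ctrl_idx)
  as.numeric(set_mean - ctrl_mean)
}

# equal-frequency expression bins on the rank of per-gene mean normalized
# expression; ties broken by gene order
expression_bins <- function(ds, n_bins) {
  means <- Matrix::colMeans(ds$norm)
  ord <- order(means, seq_along(means))
  pos <- integer(length(means))
  pos[ord] <- seq_along(means)
  as.integer(ceiling(pos * n_bins / length(means)))
}

#' Composite dorso-ventral and naso-temporal positional scores
#'
#' Computes the four axis module scores (dorsal, ventral, nasal, temporal)
#' and the composite coordinates `dv_score = dorsal - ventral` and
#' `nt_score = nasal - temporal` for every cell.
#'
#' @param ds A normalized `cell_dataset`.
#' @param sets A `gene_set_spec` with the four marker sets.
#' @inheritParams compute_module_score
#' @return An `axis_scores` tibble with one row per cell: `cell`, the four
#'   axis scores, `dv_score`, `nt_score`, plus the dataset's metadata
#'   columns. Scoring parameters are recorded as attributes
#'   (`seed`, `n_bins`, `n_ctrl`).
#' @export
compute_axis_scores <- function(ds, sets, n_bins = 24, n_ctrl = 100, seed = 0) {
  stopifnot(inherits(sets, "gene_set_spec"))
  axes <- c("dorsal", "ventral", "nasal", "temporal")
  scores <- lapply(axes, function(ax) {
    compute_module_score(ds, sets[[ax]], n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
  })
  names(scores) <- paste0(axes, "_score")
  out <- tibble(cell = ds$cells, !!!scores)
  out$dv_score <- out$dorsal_score - out$ventral_score
  out$nt_score <- out$nasal_score - out$temporal_score
  out <- dplyr::bind_cols(out, ds$meta[setdiff(names(ds$meta), names(out))])
  structure(out, class = c("axis_scores", class(out)),
            seed = seed, n_bins = n_bins, n_ctrl = n_ctrl)
}

#' @export
#' @method glance axis_scores
glance.axis_scores <- function(x, ...) {
  tibble(
    n_cells = nrow(x),
    n_bins = attr(x, "n_bins"),
    n_ctrl = attr(x, "n_ctrl"),
    seed = attr(x, "seed"),
    dv_range = diff(range(x$dv_score)),
    nt_range = diff(range(x$nt_score))
  )
}

#' Per-group distribution summary of axis scores
#'
#' QC summary of the score distributions, grouped by a metadata column
#' (e.g. embryo or library), for checking that positional scores are stable
#' across batches.
#'
#' @param scores An `axis_scores` tibble.
#' @param by Name of a metadata column present in `scores`.
#' @return Long tibble with one row per group x score: `n`, `mean`, `sd`,
#'   and the 0/25/50/75/100% quantiles.
#' @export
score_distribution_summary <- function(scores, by = "embryo_id") {
  if (!by %in% names(scores)) abort(paste0("unknown metadata key: ", by))
  cols <- c("dorsal_score", "ventral_score", "nasal_score", "temporal_score",
            "dv_score", "nt_score")
  scores |>
    as_tibble() |>
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "score", values_to = "value") |>
    dplyr::group_by(.data[[by]], .data$score) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = stats::sd(.data$value),
      q0 = stats::quantile(.data$value, 0),
      q25 = stats::quantile(.data$value, 0.25),
      q50 = stats::quantile(.data$value, 0.5),
      q75 = stats::quantile(.data$value, 0.75),
      q100 = stats::quantile(.data$value, 1),
      .groups = "drop"
    )
}

#' Write axis scores as a tab-delimited per-cell table
#'
#' @param scores An `axis_scores` tibble.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_axis_scores <- function(scores, path) {
  write.table(as.data.frame(scores), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
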