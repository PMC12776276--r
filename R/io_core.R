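#' Construct a cell dataset
#'
#' Bundles a sparse cell-by-gene UMI count matrix with per-cell metadata and,
#' optionally, a matching log-normalized expression layer. This is the shared
#' container consumed by all downstream stages (axis scoring, gridding,
#' pseudobulk differential expression).
#'
#' @param counts Cell-by-gene matrix of non-negative integer UMI counts
#'   (dense or `Matrix` sparse); rows are cells.
#' @param cells Character vector of unique cell identifiers.
#' @param genes Character vector of gene symbols, unique after case-folding.
#' @param meta Data frame of per-cell metadata with at least `embryo_id`;
#'   `library_id` and `species` are carried when present.
#' @param norm Optional normalized layer with the same dimensions as `counts`.
#' @return An object of class `cell_dataset`.
#' @export
cell_dataset <- function(counts, cells, genes, meta, norm = NULL) {
  counts <- as_sparse(counts)
  if (nrow(counts) != length(cells)) {
    abort(sprintf("counts has %d rows but %d cell ids were given", nrow(counts), length(cells)))
  }
  if (ncol(counts) != length(genes)) {
    abort(sprintf("counts has %d columns but %d gene symbols were given", ncol(counts), length(genes)))
  }
  if (anyDuplicated(symbol_key(genes))) {
    dup <- genes[duplicated(symbol_key(genes))]
    abort(paste0("gene symbols not unique after case-folding: ", paste(unique(dup), collapse = ", ")))
  }
  if (anyDuplicated(cells)) abort("cell identifiers must be unique")
  x <- counts@x
  if (any(x < 0) || !all(is_wholenumber(x))) {
    abort("counts must be non-negative integers")
  }
  meta <- as_tibble(meta)
  if (nrow(meta) != length(cells)) abort("meta must have one row per cell")
  if (!"embryo_id" %in% names(meta)) abort("meta must contain an `embryo_id` column")
  if (any(is.na(meta$embryo_id)) || any(!nzchar(as.character(meta$embryo_id)))) {
    abort("every cell needs a non-empty embryo_id")
  }
  if (!is.null(norm)) {
    norm <- as_sparse(norm)
    if (!identical(dim(norm), dim(counts))) abort("norm layer dimensions must match counts")
  }
  rownames(counts) <- cells
  colnames(counts) <- genes
  if (!is.null(norm)) dimnames(norm) <- dimnames(counts)
  structure(
    list(counts = counts, norm = norm, cells = cells, genes = genes, meta = meta,
         norm_scale = NULL),
    class = "cell_dataset"
  )
}

#' @export
print.cell_dataset <- function(x, ...) {
  cat(sprintf("<cell_dataset> %d cells x %d genes; %d embryos; normalized: %s\n",
              length(x$cells), length(x$genes),
              length(unique(x$meta$embryo_id)),
              if (is.null(x$norm)) "no" else sprintf("yes (scale %s)", format(x$norm_scale))))
  invisible(x)
}

#' @export
dim.cell_dataset <- function(x) dim(x$counts)

#' Summary of a cell dataset
#'
#' @param x A `cell_dataset`.
#' @param ... Unused.
#' @return One-row tibble with cell/gene/embryo counts and total UMIs.
#' @export
#' @method glance cell_dataset
glance.cell_dataset <- function(x, ...) {
  tibble(
    n_cells = length(x$cells),
    n_genes = length(x$genes),
    n_embryos = length(unique(x$meta$embryo_id)),
    total_counts = sum(x$counts),
    normalized = !is.null(x$norm)
  )
}

#' Read a cell dataset from MatrixMarket + annotation files
#'
#' Reads the on-disk layout this package also writes: a MatrixMarket
#' coordinate matrix plus tab-delimited gene, cell, and per-cell metadata
#' tables (all with headers).
#'
#' @param matrix_path Path to the `.mtx` counts matrix.
#' @param genes_path Path to a TSV with a `gene` column.
#' @param cells_path Path to a TSV with a `cell` column.
#' @param meta_path Path to a TSV with per-cell metadata (incl. `embryo_id`).
#' @param orientation Either `"cells_x_genes"` (default) or
#'   `"genes_x_cells"`; the matrix is transposed internally so the in-memory
#'   orientation is always cells x genes.
#' @return A `cell_dataset`.
#' @export
read_cell_dataset <- function(matrix_path, genes_path, cells_path, meta_path,
                              orientation = c("cells_x_genes", "genes_x_cells")) {
  orientation <- match.arg(orientation)
  m <- Matrix::readMM(matrix_path)
  if (orientation == "genes_x_cells") m <- Matrix::t(m)
  genes <- read.delim(genes_path, stringsAsFactors = FALSE)
  cells <- read.delim(cells_path, stringsAsFactors = FALSE)
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  if (!"gene" %in% names(genes)) abort("genes file needs a `gene` column")
  if (!"cell" %in% names(cells)) abort("cells file needs a `cell` column")
  if (nrow(m) != nrow(cells)) {
    abort(sprintf("matrix has %d cell rows but cells file has %d entries", nrow(m), nrow(cells)))
  }
  if (ncol(m) != nrow(genes)) {
    abort(sprintf("matrix has %d gene columns but genes file has %d entries", ncol(m), nrow(genes)))
  }
  cell_dataset(m, cells$cell, genes$gene, meta)
}

#' Write a cell dataset to MatrixMarket + annotation files
#'
#' @param ds A `cell_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cell_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "cell_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    matrix = file.path(dir, "matrix.mtx"),
    genes = file.path(dir, "genes.tsv"),
    cells = file.path(dir, "cells.tsv"),
    meta = file.path(dir, "meta.tsv")
  )
  Matrix::writeMM(ds$counts, paths["matrix"])
  write.table(data.frame(gene = ds$genes), paths["genes"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(cell = ds$cells), paths["cells"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(ds$meta), paths["meta"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Log-normalize UMI counts
#'
#' Per-cell size normalization followed by a log transform, the convention of
#' standard single-cell toolkits: each cell's counts are divided by the cell
#' total, multiplied by `scale`, and passed through `log(1 + x)`.
#'
#' @param ds A `cell_dataset`.
#' @param scale Size-normalization scale factor; default 10,000.
#' @return The dataset with its `norm` layer (re)computed; counts unchanged.
#' @export
normalize_counts <- function(ds, scale = 1e4) {
  stopifnot(inherits(ds, "cell_dataset"))
  assert_scalar_num(scale, "scale", lower = .Machine$double.eps)
  totals <- Matrix::rowSums(ds$counts)
  if (any(totals == 0)) {
    abort(paste0("cells with zero total counts cannot be normalized: ",
                 paste(ds$cells[totals == 0], collapse = ", ")))
  }
  norm <- ds$counts
  norm@x <- norm@x * (scale / totals[norm@i + 1L])
  norm@x <- log1p(norm@x)
  ds$norm <- norm
  ds$norm_scale <- scale
  ds
}

#' Read a five-column ortholog table
#'
#' @param path TSV with columns `source_species`, `source_symbol`,
#'   `target_species`, `target_symbol`, `source_db`.
#' @return Tibble with those columns.
#' @export
read_ortholog_table <- function(path) {
  tab <- as_tibble(read.delim(path, stringsAsFactors = FALSE))
  need <- c("source_species", "source_symbol", "target_species", "target_symbol", "source_db")
  miss <- setdiff(need, names(tab))
  if (length(miss)) abort(paste0("ortholog table missing columns: ", paste(miss, collapse = ", ")))
  tab
}

#' Map gene symbols between species via an offline ortholog table
#'
#' For each query symbol the mapping from the highest-priority database that
#' covers it is used (primary database first, then the fallback); symbols
#' covered by no database are reported as unmapped, never silently dropped.
#'
#' @param table Ortholog table (see [read_ortholog_table()]).
#' @param genes Character vector of source-species symbols to map.
#' @param source,target Species labels; must differ.
#' @param db_priority Database precedence, highest first.
#' @return List with `mapping` (named character vector, source -> target) and
#'   `unmapped` (character vector of symbols with no mapping).
#' @export
map_orthologs <- function(table, genes, source, target,
                          db_priority = c("mygene", "biomart")) {
  if (identical(source, target)) abort("source and target species must differ")
  tab <- table[table$source_species == source & table$target_species == target, , drop = FALSE]
  mapping <- character(0)
  resolved <- rep(FALSE, length(genes))
  for (db in db_priority) {
    sub <- tab[tab$source_db == db, , drop = FALSE]
    if (!nrow(sub)) next
    key <- paste(sub$source_species, symbol_key(sub$source_symbol), sub$target_species)
    dup <- duplicated(key) & !duplicated(paste(key, sub$target_symbol))
    if (any(dup)) {
      abort(paste0("conflicting duplicate ortholog rows in database '", db, "' for: ",
                   paste(unique(sub$source_symbol[dup]), collapse = ", ")))
    }
    idx <- match(symbol_key(genes), symbol_key(sub$source_symbol))
    hit <- !is.na(idx) & !resolved
    mapping[genes[hit]] <- sub$target_symbol[idx[hit]]
    resolved <- resolved | hit
  }
  list(mapping = mapping, unmapped = genes[!resolved])
}

#' Load dorsal/ventral/nasal/temporal marker gene sets
#'
#' Reads a YAML file with keys `species`, `dorsal`, `ventral`, `nasal`,
#' `temporal`, each axis key holding a list of gene symbols. The package ships
#' the chicken defaults under `inst/extdata/gene_sets_chicken.yaml`.
#'
#' @param path Path to the YAML config; defaults to the shipped chicken sets.
#' @return A `gene_set_spec` list with the four marker sets.
#' @export
load_gene_sets <- function(path = system.file("extdata", "gene_sets_chicken.yaml",
                                              package = "retinotopo")) {
  cfg <- yaml::read_yaml(path)
  axes <- c("dorsal", "ventral", "nasal", "temporal")
  miss <- setdiff(axes, names(cfg))
  if (length(miss)) abort(paste0("gene-set config missing keys: ", paste(miss, collapse = ", ")))
  sets <- lapply(cfg[axes], function(x) as.character(unlist(x)))
  gene_set_spec(sets$dorsal, sets$ventral, sets$nasal, sets$temporal,
                species = cfg$species %||% "unknown")
}

#' Construct a marker gene-set specification
#'
#' @param dorsal,ventral,nasal,temporal Non-empty, mutually disjoint character
#'   vectors of marker symbols for the four retinal axes.
#' @param species Species label.
#' @return A `gene_set_spec`.
#' @export
gene_set_spec <- function(dorsal, ventral, nasal, temporal, species = "unknown") {
  sets <- list(dorsal = dorsal, ventral = ventral, nasal = nasal, temporal = temporal)
  for (nm in names(sets)) {
    if (!length(sets[[nm]])) abort(paste0("gene set '", nm, "' is empty"))
  }
  keys <- lapply(sets, symbol_key)
  for (i in 1:3) for (j in (i + 1):4) {
    shared <- intersect(keys[[i]], keys[[j]])
    if (length(shared)) {
      abort(sprintf("gene sets '%s' and '%s' overlap: %s",
                    names(sets)[i], names(sets)[j], paste(shared, collapse = ", ")))
    }
  }
  structure(c(sets, list(species = species)), class = "gene_set_spec")
}

#' @export
print.gene_set_spec <- function(x, ...) {
  cat(sprintf("<gene_set_spec> species: %s\n", x$species))
  for (nm in c("dorsal", "ventral", "nasal", "temporal")) {
    cat(sprintf("  %-8s (%d): %s\n", nm, length(x[[nm]]), paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' Resolve a gene-set spec against a dataset
#'
#' Matches all four sets case-insensitively against the dataset's genes and
#' reports unresolvable symbols with a warning record rather than dropping
#' them silently.
#'
#' @param sets A `gene_set_spec`.
#' @param ds A `cell_dataset`.
#' @return Tibble with columns `axis`, `symbol`, `resolved`, `gene_index`.
#' @export
resolve_gene_sets <- function(sets, ds) {
  stopifnot(inherits(sets, "gene_set_spec"), inherits(ds, "cell_dataset"))
  out <- purrr::map_dfr(c("dorsal", "ventral", "nasal", "temporal"), function(ax) {
    idx <- match_genes(sets[[ax]], ds$genes)
    tibble(axis = ax, symbol = sets[[ax]], resolved = !is.na(idx), gene_index = idx)
  })
  if (any(!out$resolved)) {
    warn(paste0("unresolved marker symbols: ",
                paste(out$symbol[!out$resolved], collapse = ", ")))
  }
  out
}

#' Species-specific reconstruction presets
#'
#' Grid resolution and validity thresholds tuned per species for retinal
#' progenitor density: chicken 51x51 with >=3 cells and >=20 transcript
#' counts per grid cell, human 40x40 with >=3 and >=15, mouse 51x51 with
#' >=5 and >=30; all with sigma = 1.0 grid-unit smoothing and a 94th
#' percentile clip.
#'
#' @param species `"chicken"`, `"human"`, or `"mouse"`, or `"custom"` with
#'   explicit values.
#' @param grid_size,min_cells,min_counts,sigma,clip_percentile Overrides for
#'   a custom preset.
#' @return A `species_preset` list.
#' @export
species_preset <- function(species = c("chicken", "human", "mouse", "custom"),
                           grid_size = NULL, min_cells = NULL, min_counts = NULL,
                           sigma = NULL, clip_percentile = NULL) {
  species <- match.arg(species)
  defaults <- switch(species,
    chicken = list(grid_size = 51L, min_cells = 3L, min_counts = 20L, sigma = 1.0, clip_percentile = 94),
    human   = list(grid_size = 40L, min_cells = 3L, min_counts = 15L, sigma = 1.0, clip_percentile = 94),
    mouse   = list(grid_size = 51L, min_cells = 5L, min_counts = 30L, sigma = 1.0, clip_percentile = 94),
    custom  = list(grid_size = 51L, min_cells = 1L, min_counts = 0L, sigma = 1.0, clip_percentile = 94)
  )
  p <- list(
    species = species,
    grid_size = as.integer(grid_size %||% defaults$grid_size),
    min_cells = as.integer(min_cells %||% defaults$min_cells),
    min_counts = as.integer(min_counts %||% defaults$min_counts),
    sigma = sigma %||% defaults$sigma,
    clip_percentile = clip_percentile %||% defaults$clip_percentile
  )
  if (p$grid_size < 2) abort("grid_size must be >= 2")
  if (p$min_cells < 1) abort("min_cells must be >= 1")
  if (p$min_counts < 0) abort("min_counts must be >= 0")
  if (p$sigma <= 0) abort("sigma must be > 0")
  if (p$clip_percentile <= 0 || p$clip_percentile > 100) abort("clip_percentile must be in (0, 100]")
  structure(p, class = "species_preset")
}

#' @export
print.species_preset <- function(x, ...) {
  cat(sprintf("<species_preset> %s: %dx%d grid, >=%d cells, >=%d counts, sigma %.2f, clip p%.0f\n",
              x$species, x$grid_size, x$grid_size, x$min_cells, x$min_counts,
              x$sigma, x$clip_percentile))
  invisible(x)
}
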