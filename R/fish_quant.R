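#' Construct a FISH flat-mount image
#'
#' Grayscale intensity array plus a same-shape binary mask marking retinal
#' tissue (foreground). Images are assumed pre-oriented: nasal to the right,
#' ventral at the bottom, optic fissure at ~90 degrees.
#'
#' @param intensity 2D non-negative numeric matrix.
#' @param mask Logical (or 0/1) matrix of the same shape; TRUE = tissue.
#' @param pixel_size_um Physical pixel size (default 0.3248 um/px).
#' @param orientation Orientation tag, recorded only.
#' @return A `fish_image`.
#' @export
fish_image <- function(intensity, mask, pixel_size_um = 0.3248,
                       orientation = "nasal-right-ventral-bottom") {
  intensity <- as.matrix(intensity)
  mask <- as.matrix(mask) > 0
  if (!identical(dim(intensity), dim(mask))) abort("intensity and mask shapes differ")
  if (any(intensity < 0, na.rm = TRUE)) abort("intensity must be non-negative")
  assert_scalar_num(pixel_size_um, "pixel_size_um", lower = .Machine$double.eps)
  structure(list(intensity = intensity, mask = mask,
                 pixel_size_um = pixel_size_um, orientation = orientation),
            class = "fish_image")
}

#' @export
print.fish_image <- function(x, ...) {
  cat(sprintf("<fish_image> %dx%d px (%.4f um/px), %.1f%% foreground\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size_um,
              100 * mean(x$mask)))
  invisible(x)
}

#' Read a grayscale TIFF and matching mask
#'
#' @param path Path to a single-channel grayscale TIFF.
#' @param mask_path Path to a same-shape mask TIFF (nonzero = tissue).
#' @inheritParams fish_image
#' @return A `fish_image`.
#' @export
read_fish_image <- function(path, mask_path, pixel_size_um = 0.3248,
                            orientation = "nasal-right-ventral-bottom") {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  msk <- tiff::readTIFF(mask_path)
  if (length(dim(msk)) == 3) msk <- msk[, , 1]
  fish_image(img, msk > 0, pixel_size_um, orientation)
}

#' Optional FIJI-style pre-filters
#'
#' Off by default: quantification operates on raw images. `outlier_radius` /
#' `outlier_threshold` replace foreground pixels deviating from their local
#' median by more than the threshold; `blur_radius` applies mask-aware
#' Gaussian smoothing (SD = radius/2); `subtract_background` subtracts the
#' mean background (non-mask) intensity, flooring at 0.
#'
#' @param img A `fish_image`.
#' @param outlier_radius,outlier_threshold Median-deviation outlier removal
#'   (e.g. radius 2 or 5 px at threshold 50); `NULL` disables.
#' @param blur_radius Gaussian blur radius in px (e.g. 5); `NULL` disables.
#' @param subtract_background Subtract mean background intensity.
#' @return The filtered `fish_image`.
#' @export
preprocess_fish <- function(img, outlier_radius = NULL, outlier_threshold = 50,
                            blur_radius = NULL, subtract_background = FALSE) {
  stopifnot(inherits(img, "fish_image"))
  x <- img$intensity
  if (!is.null(outlier_radius)) {
    r <- as.integer(outlier_radius)
    med <- matrix(NA_real_, nrow(x), ncol(x))
    fg <- which(img$mask, arr.ind = TRUE)
    for (k in seq_len(nrow(fg))) {
      i <- fg[k, 1]; j <- fg[k, 2]
      nb <- x[max(1, i - r):min(nrow(x), i + r), max(1, j - r):min(ncol(x), j + r)]
      med[i, j] <- stats::median(nb[img$mask[max(1, i - r):min(nrow(x), i + r),
                                             max(1, j - r):min(ncol(x), j + r)]])
    }
    out <- img$mask & !is.na(med) & abs(x - med) > outlier_threshold
    x[out] <- med[out]
  }
  if (!is.null(blur_radius)) {
    x <- normalized_convolution(x, img$mask, blur_radius / 2)$smoothed
    x[!img$mask] <- img$intensity[!img$mask]
    x[is.na(x)] <- 0
  }
  if (subtract_background && any(!img$mask)) {
    x <- pmax(x - mean(img$intensity[!img$mask]), 0)
  }
  img$intensity <- x
  img
}

#' Block-wise quantification of a masked image
#'
#' Tiles the image from the top-left with `block_size_px` x `block_size_px`
#' blocks (edge blocks partial) and records the mean intensity over the
#' foreground pixels of each block; blocks with no foreground are missing.
#'
#' @param img A `fish_image`.
#' @param block_size_px Block side in pixels (default 25).
#' @return A `block_map`.
#' @export
block_quantify <- function(img, block_size_px = 25) {
  stopifnot(inherits(img, "fish_image"))
  assert_scalar_num(block_size_px, "block_size_px", lower = 1)
  if (!any(img$mask)) abort("empty mask: nothing to quantify")
  bs <- as.integer(block_size_px)
  nr <- nrow(img$intensity); nc <- ncol(img$intensity)
  nby <- ceiling(nr / bs); nbx <- ceiling(nc / bs)
  by <- ceiling(row(img$intensity) / bs)
  bx <- ceiling(col(img$intensity) / bs)
  bid <- (bx - 1L) * nby + by
  fg <- img$mask
  sums <- numeric(nby * nbx)
  cnts <- numeric(nby * nbx)
  agg_s <- rowsum(img$intensity[fg], bid[fg])
  agg_n <- rowsum(rep(1, sum(fg)), bid[fg])
  sums[as.integer(rownames(agg_s))] <- agg_s[, 1]
  cnts[as.integer(rownames(agg_n))] <- agg_n[, 1]
  vals <- matrix(ifelse(cnts > 0, sums / cnts, NA_real_), nrow = nby)
  structure(list(values = vals, n_foreground = matrix(cnts, nrow = nby),
                 block_size_px = bs, pixel_size_um = img$pixel_size_um,
                 origin = NULL),
            class = "block_map")
}

#' @export
print.block_map <- function(x, ...) {
  cat(sprintf("<block_map> %dx%d blocks of %d px (%.4f um/px), %d defined%s\n",
              nrow(x$values), ncol(x$values), x$block_size_px, x$pixel_size_um,
              sum(!is.na(x$values)),
              if (is.null(x$origin)) "" else sprintf(", origin (%d, %d)",
                                                     x$origin[1], x$origin[2])))
  invisible(x)
}

#' Long tibble view of a block map
#'
#' @param x A `block_map`.
#' @param ... Unused.
#' @return Tibble with block indices, positions (um, relative to origin when
#'   set) and values.
#' @export
#' @method tidy block_map
tidy.block_map <- function(x, ...) {
  um <- x$block_size_px * x$pixel_size_um
  oy <- if (is.null(x$origin)) 0 else x$origin[1]
  ox <- if (is.null(x$origin)) 0 else x$origin[2]
  tibble(
    row = rep(seq_len(nrow(x$values)), times = ncol(x$values)),
    col = rep(seq_len(ncol(x$values)), each = nrow(x$values)),
    y_um = (rep(seq_len(nrow(x$values)), times = ncol(x$values)) - oy) * um,
    x_um = (rep(seq_len(ncol(x$values)), each = nrow(x$values)) - ox) * um,
    value = as.vector(x$values)
  )
}

#' Rescale a block map to [0, 1]
#'
#' Min-max normalization over the defined blocks; idempotent and invariant
#' to affine transforms of the input.
#'
#' @param bm A `block_map`.
#' @return The normalized map.
#' @export
normalize01 <- function(bm) {
  stopifnot(inherits(bm, "block_map"))
  v <- bm$values[!is.na(bm$values)]
  if (length(v) < 2 || diff(range(v)) == 0) abort("constant map: cannot rescale to [0, 1]")
  r <- range(v)
  bm$values <- (bm$values - r[1]) / diff(r)
  bm
}

#' Per-column or per-row normalization of a block map
#'
#' Min-max rescales each line (column for DV emphasis, row for NT emphasis)
#' over its defined blocks. Lines with fewer than 2 defined blocks, or
#' constant over their defined blocks, are left missing and flagged with a
#' warning.
#'
#' @param bm A `block_map`.
#' @param axis `"column"` or `"row"`.
#' @return The axis-normalized map; skipped lines in attribute
#'   `"skipped_lines"`.
#' @export
axis_normalize <- function(bm, axis = c("column", "row")) {
  axis <- match.arg(axis)
  stopifnot(inherits(bm, "block_map"))
  v <- bm$values
  if (axis == "row") v <- t(v)
  skipped <- integer(0)
  for (j in seq_len(ncol(v))) {
    ok <- !is.na(v[, j])
    if (sum(ok) < 2 || diff(range(v[ok, j])) == 0) {
      if (any(ok)) skipped <- c(skipped, j)
      v[, j] <- NA_real_
      next
    }
    r <- range(v[ok, j])
    v[, j] <- (v[, j] - r[1]) / diff(r)
  }
  if (length(skipped)) {
    warn(sprintf("%d %s(s) skipped in axis normalization (constant or single block)",
                 length(skipped), axis))
  }
  if (axis == "row") v <- t(v)
  bm$values <- v
  attr(bm, "skipped_lines") <- skipped
  bm
}

#' Set the origin of a block map
#'
#' Records a user-defined reference point (0, 0), typically the HAA center;
#' all profile positions are subsequently reported in micrometers relative
#' to it.
#'
#' @param bm A `block_map`.
#' @param row,col Block coordinates of the origin.
#' @return The map with its origin set.
#' @export
set_origin <- function(bm, row, col) {
  stopifnot(inherits(bm, "block_map"))
  if (row < 1 || row > nrow(bm$values) || col < 1 || col > ncol(bm$values)) {
    abort(sprintf("origin (%d, %d) outside the %dx%d block map",
                  row, col, nrow(bm$values), ncol(bm$values)))
  }
  bm$origin <- c(row = as.integer(row), col = as.integer(col))
  bm
}

#' Strip width in pixels
#'
#' The pixel width of an extraction strip: `round(strip_width_um /
#' pixel_size_um)` (1539 px at the 500 um / 0.3248 um-per-px defaults).
#'
#' @param strip_width_um Strip width in micrometers (default 500).
#' @param pixel_size_um Pixel size (default 0.3248).
#' @return Integer pixel width.
#' @export
strip_width_px <- function(strip_width_um = 500, pixel_size_um = 0.3248) {
  round(strip_width_um / pixel_size_um)
}

#' Origin-anchored strip profile of a block map
#'
#' Extracts a strip of width `strip_width_um` centered on the origin line
#' (vertical for the DV profile, horizontal for NT; width in pixels is
#' `round(strip_width_um / pixel_size_um)`, 1539 px at defaults) and
#' averages defined blocks across the strip at every position. Positions
#' where the defined-block fraction falls below `signal_fraction` are
#' dropped as background-dominated edge positions.
#'
#' @param bm A `block_map` with its origin set.
#' @param axis `"DV"` (profile along rows) or `"NT"` (along columns).
#' @param strip_width_um Strip width in micrometers (default 500).
#' @param signal_fraction Minimum fraction of defined blocks per position
#'   (default 0.8).
#' @return A `profile_1d` with positions in micrometers relative to the
#'   origin, per-position mean and SD over the strip's defined blocks, and
#'   block coverage.
#' @export
extract_strip_profile <- function(bm, axis = c("DV", "NT"),
                                  strip_width_um = 500, signal_fraction = 0.8) {
  axis <- match.arg(axis)
  stopifnot(inherits(bm, "block_map"))
  if (is.null(bm$origin)) abort("origin unset: call set_origin() first")
  assert_scalar_num(strip_width_um, "strip_width_um", lower = .Machine$double.eps)
  if (signal_fraction <= 0 || signal_fraction > 1) abort("signal_fraction must be in (0, 1]")
  width_px <- strip_width_px(strip_width_um, bm$pixel_size_um)
  half_px <- width_px / 2
  bs <- bm$block_size_px
  v <- bm$values
  if (axis == "NT") {
    v <- t(v)
    o_line <- bm$origin["col"]; o_cross <- bm$origin["row"]
  } else {
    o_line <- bm$origin["row"]; o_cross <- bm$origin["col"]
  }
  # strip columns: blocks whose centers lie within half the strip width of
  # the origin line's center, in pixels
  centers_px <- (seq_len(ncol(v)) - 0.5) * bs
  origin_px <- (o_cross - 0.5) * bs
  strip_cols <- which(abs(centers_px - origin_px) <= half_px)
  if (!length(strip_cols)) abort("strip contains no blocks")
  sub <- v[, strip_cols, drop = FALSE]
  n_def <- rowSums(!is.na(sub))
  frac <- n_def / length(strip_cols)
  keep <- frac >= signal_fraction
  if (!any(keep)) abort("no position passes the signal fraction filter")
  pos_um <- (seq_len(nrow(v)) - o_line) * bs * bm$pixel_size_um
  mn <- rowMeans(sub, na.rm = TRUE)
  sdv <- apply(sub, 1, function(z) if (sum(!is.na(z)) > 1) stats::sd(z, na.rm = TRUE) else 0)
  profile_1d(pos_um[keep], mn[keep], sdv[keep], n_def[keep],
             spread_label = "sd", origin = 0)
}

#' Average origin-aligned profiles across flat mounts
#'
#' Interpolates each profile onto a common axis (union of ranges at
#' `step_um`) and records the per-position mean, SEM or SD across samples,
#' and sample count. Positions covered by a single sample keep their mean
#' with missing spread.
#'
#' @param profiles List of >= 2 origin-aligned `profile_1d` objects.
#' @param step_um Common axis step in micrometers (default: the block pitch
#'   of the first profile's source, 25 px x 0.3248 um = 8.12 um).
#' @param spread `"sem"` (default) or `"sd"`.
#' @return A `profile_1d` whose coverage column counts contributing samples.
#' @export
aggregate_profiles <- function(profiles, step_um = 25 * 0.3248,
                               spread = c("sem", "sd")) {
  spread <- match.arg(spread)
  if (length(profiles) < 2) abort("need at least 2 profiles to aggregate")
  pm <- interpolate_to_common_axis(profiles, step_um)
  n <- colSums(!is.na(pm))
  keep <- n >= 1
  mn <- colMeans(pm, na.rm = TRUE)[keep]
  sdv <- apply(pm, 2, function(z) {
    k <- sum(!is.na(z))
    if (k < 2) return(NA_real_)
    s <- stats::sd(z, na.rm = TRUE)
    if (spread == "sem") s / sqrt(k) else s
  })[keep]
  profile_1d(attr(pm, "positions")[keep], mn, sdv, n[keep],
             spread_label = spread, origin = 0)
}

#' Write a block map (TSV + JSON sidecar) or profile (TSV)
#'
#' @param bm A `block_map`.
#' @param path Output TSV path; a `.json` sidecar records origin, pixel and
#'   block size.
#' @return Invisibly, the paths.
#' @export
write_block_map <- function(bm, path) {
  write.table(bm$values, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  sidecar <- paste0(sub("\\.[^.]*$", "", path), ".json")
  jsonlite::write_json(
    list(block_size_px = bm$block_size_px, pixel_size_um = bm$pixel_size_um,
         origin = bm$origin, n_rows = nrow(bm$values), n_cols = ncol(bm$values)),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(c(path, sidecar))
}

#' @rdname write_block_map
#' @param profile A `profile_1d`.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(distance_um = profile$position,
                   intensity = profile$mean,
                   spread = profile$spread,
                   coverage = profile$coverage)
  names(df)[3] <- attr(profile, "spread_label") %||% "sd"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
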