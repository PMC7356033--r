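# Internal image helpers shared by the rendering, detection, uranaffin and
# tilt modules. Images are plain numeric matrices in [0, 1]; row = image row
# (y), col = image column (x). Reported pixel coordinates are 0-based.

#' Shape features of labelled connected components
#'
#' Computes, per label, the pixel area, centroid, second moments, an
#' equivalent-circle diameter, a perimeter estimate and two roundness
#' statistics. The perimeter is the count of exposed 4-neighbour pixel edges
#' scaled by pi/4, which converts the Manhattan boundary length of a smooth
#' blob to its Euclidean length, so a rendered disk scores a circularity
#' (`4*pi*area/perimeter^2`) close to 1. `moment_circ` is
#' `area / (2*pi*msd)` with `msd` the mean squared distance of component
#' pixels from their centroid; it is exactly 1 for a continuous disk and is
#' rotation stable, so it is used as the splitting trigger.
#'
#' @param lab Integer label matrix (0 = background), e.g. from
#'   [EBImage::bwlabel()].
#' @return data.frame with one row per label: `label, area_px, row_px,
#'   col_px` (0-based centroids), `perimeter_px, circularity, moment_circ,
#'   aspect_ratio`.
#' @keywords internal
component_features <- function(lab) {
  lab <- as_label_matrix(lab)
  idx <- which(lab > 0)
  if (!length(idx)) {
    return(data.frame(label = integer(), area_px = numeric(),
                      row_px = numeric(), col_px = numeric(),
                      perimeter_px = numeric(), circularity = numeric(),
                      moment_circ = numeric(), aspect_ratio = numeric()))
  }
  l <- lab[idx]
  nr <- nrow(lab)
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  agg <- rowsum(cbind(1, r, c, r^2, c^2, r * c), l)
  labs <- as.integer(rownames(agg))
  area <- agg[, 1]
  cr <- agg[, 2] / area
  cc <- agg[, 3] / area
  vrr <- agg[, 4] / area - cr^2
  vcc <- agg[, 5] / area - cc^2
  vrc <- agg[, 6] / area - cr * cc
  msd <- vrr + vcc
  # eigenvalues of the 2x2 covariance -> principal axis lengths
  tr <- vrr + vcc
  dt <- sqrt(pmax((vrr - vcc)^2 + 4 * vrc^2, 0))
  l1 <- (tr + dt) / 2
  l2 <- pmax((tr - dt) / 2, 1e-9)
  aspect <- sqrt(l1 / l2)

  # exposed 4-neighbour edges per foreground pixel (image border counts as
  # background); evaluated over foreground pixels only, not the whole image
  nc_img <- ncol(lab)
  neighbour_bg <- function(offset, at_border) {
    out <- rep.int(TRUE, length(idx))
    ok <- !at_border
    out[ok] <- lab[idx[ok] + offset] == 0L
    out
  }
  edges <- neighbour_bg(-1L, r == 1L) + neighbour_bg(1L, r == nr) +
    neighbour_bg(-nr, c == 1L) + neighbour_bg(nr, c == nc_img)
  per_counts <- rowsum(as.numeric(edges), l)[, 1]
  perimeter <- (pi / 4) * per_counts
  circ <- ifelse(perimeter > 0, 4 * pi * area / perimeter^2, NA_real_)

  data.frame(
    label = labs,
    area_px = as.numeric(area),
    row_px = cr - 1,
    col_px = cc - 1,
    perimeter_px = perimeter,
    circularity = circ,
    moment_circ = as.numeric(area / (2 * pi * pmax(msd, 1e-9))),
    aspect_ratio = aspect
  )
}

# EBImage returns Image objects; keep plain integer matrices internally.
as_label_matrix <- function(lab) {
  if (inherits(lab, "Image")) lab <- EBImage::imageData(lab)
  storage.mode(lab) <- "integer"
  lab
}

# Label a binary matrix. Values > 0 are foreground.
label_components <- function(bin) {
  as_label_matrix(EBImage::bwlabel(bin * 1))
}

# Paint a filled disk of continuous centre (row0, col0) (0-based) and radius
# r px into `img` (modified copy returned). A pixel belongs to the disk when
# its centre lies inside the circle, which makes the painted area an unbiased
# estimate of pi*r^2 under uniform sub-pixel placement.
paint_disk <- function(img, row0, col0, r, value) {
  nr <- nrow(img); nc <- ncol(img)
  r1 <- max(1L, floor(row0 + 1 - r)); r2 <- min(nr, ceiling(row0 + 1 + r))
  c1 <- max(1L, floor(col0 + 1 - r)); c2 <- min(nc, ceiling(col0 + 1 + r))
  if (r1 > r2 || c1 > c2) return(img)
  dr2 <- ((r1:r2) - 1 - row0)^2
  dc2 <- ((c1:c2) - 1 - col0)^2
  m <- outer(dr2, dc2, "+") <= r^2
  sub <- img[r1:r2, c1:c2, drop = FALSE]
  sub[m] <- value
  img[r1:r2, c1:c2] <- sub
  img
}

# As paint_disk but only paints pixels that are TRUE in `mask` (same
# dimensions as img). Used for alpha-granule shadows, which live inside the
# platelet footprint.
paint_disk_masked <- function(img, mask, row0, col0, r, value) {
  nr <- nrow(img); nc <- ncol(img)
  r1 <- max(1L, floor(row0 + 1 - r)); r2 <- min(nr, ceiling(row0 + 1 + r))
  c1 <- max(1L, floor(col0 + 1 - r)); c2 <- min(nc, ceiling(col0 + 1 + r))
  if (r1 > r2 || c1 > c2) return(img)
  dr2 <- ((r1:r2) - 1 - row0)^2
  dc2 <- ((c1:c2) - 1 - col0)^2
  m <- outer(dr2, dc2, "+") <= r^2 & mask[r1:r2, c1:c2]
  sub <- img[r1:r2, c1:c2, drop = FALSE]
  sub[m] <- value
  img[r1:r2, c1:c2] <- sub
  img
}

# As paint_disk but adds `value` where the disk falls (used by the tilt
# renderer where overlapping projections accumulate intensity).
add_disk <- function(img, row0, col0, r, value) {
  nr <- nrow(img); nc <- ncol(img)
  r1 <- max(1L, floor(row0 + 1 - r)); r2 <- min(nr, ceiling(row0 + 1 + r))
  c1 <- max(1L, floor(col0 + 1 - r)); c2 <- min(nc, ceiling(col0 + 1 + r))
  if (r1 > r2 || c1 > c2) return(img)
  dr2 <- ((r1:r2) - 1 - row0)^2
  dc2 <- ((c1:c2) - 1 - col0)^2
  m <- outer(dr2, dc2, "+") <= r^2
  sub <- img[r1:r2, c1:c2, drop = FALSE]
  sub[m] <- sub[m] + value
  img[r1:r2, c1:c2] <- sub
  img
}

# Paint an axis-aligned filled ellipse (used by the tilt renderer for
# projected ellipsoids).
paint_ellipse_add <- function(img, row0, col0, a_row, a_col, value) {
  nr <- nrow(img); nc <- ncol(img)
  r1 <- max(1L, floor(row0 + 1 - a_row)); r2 <- min(nr, ceiling(row0 + 1 + a_row))
  c1 <- max(1L, floor(col0 + 1 - a_col)); c2 <- min(nc, ceiling(col0 + 1 + a_col))
  if (r1 > r2 || c1 > c2) return(img)
  dr2 <- (((r1:r2) - 1 - row0) / a_row)^2
  dc2 <- (((c1:c2) - 1 - col0) / a_col)^2
  m <- outer(dr2, dc2, "+") <= 1
  sub <- img[r1:r2, c1:c2, drop = FALSE]
  sub[m] <- sub[m] + value
  img[r1:r2, c1:c2] <- sub
  img
}

# Fast median over a subsample of x (detection thresholds only need ~1%
# precision; sorting every footprint pixel of every platelet is wasteful).
subsampled_median <- function(x, max_n = 20000L) {
  n <- length(x)
  if (n > max_n) x <- x[seq.int(1L, n, length.out = max_n)]
  stats::median(x)
}

#' Write a grayscale image or stack as 16-bit TIFF
#'
#' @param frames A numeric matrix in `[0, 1]` or a list of such matrices
#'   (written as a multi-page stack, one page per frame).
#' @param path Output file.
#' @export
write_image_tiff <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    f[f < 0] <- 0; f[f > 1] <- 1
    f
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a grayscale TIFF (possibly multi-page) as matrices in [0, 1]
#'
#' @param path TIFF file.
#' @return A list of numeric matrices, one per page.
#' @export
read_image_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p
  })
}
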