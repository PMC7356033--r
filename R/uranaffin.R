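# Uranaffin thin-section granule typing. Uranyl-acetate-reacted granules
# show a stained membrane ring; the developmental stage is read from the
# dense core inside it: Type 1 = solid core filling more than 50% of the
# interior, Type 2 = solid core filling 50% or less, Type 3 = fragmented
# core (two or more pieces, regardless of fill), Type 4 = empty sac (no
# core).

#' Assign a developmental type to one measured granule
#'
#' Fragmentation overrides the fill threshold (Type 3 is defined by
#' fragmentation alone); "more than 50%" is strict, so a fill fraction of
#' exactly 0.5 maps to Type 2.
#'
#' @param core_fragments Count of connected dense-core components.
#' @param fill_fraction Core area divided by interior area, in `[0, 1]`.
#' @return Integer type 1-4.
#' @export
type_granule <- function(core_fragments, fill_fraction) {
  if (!is.finite(fill_fraction) || fill_fraction < 0 || fill_fraction > 1) {
    stop("fill_fraction outside [0, 1]: measurement error", call. = FALSE)
  }
  if (core_fragments == 0 && fill_fraction > 0) {
    stop("inconsistent measurement: no core fragments but positive fill",
         call. = FALSE)
  }
  if (core_fragments >= 2) return(3L)
  if (core_fragments == 0) return(4L)
  if (fill_fraction > 0.5) 1L else 2L
}

#' Render a synthetic uranaffin thin-section field
#'
#' Draws `n_granules` membrane rings at non-overlapping positions; each
#' granule's interior is populated according to a type drawn from
#' `type_mix`: Type 1 a single concentric core covering >50% of the
#' interior, Type 2 a single core covering <50%, Type 3 two to four core
#' fragments, Type 4 an empty interior.
#'
#' @param type_mix Numeric vector of 4 non-negative fractions summing to 1.
#' @param n_granules Number of granules to draw.
#' @param seed Integer seed.
#' @param nm_per_px Pixel calibration (default 2).
#' @param ring_radius_nm Range of outer granule radii in nm.
#' @param noise_sd Additive noise.
#' @return List: `image` (matrix), `truth` (data.frame `granule_id, type,
#'   row_px, col_px, outer_r_px, fill_fraction, core_fragments`), and the
#'   intensity levels used.
#' @export
render_uranaffin_section <- function(type_mix, n_granules, seed = 1L,
                                     nm_per_px = 2,
                                     ring_radius_nm = c(90, 150),
                                     noise_sd = 0.01) {
  if (length(type_mix) != 4 || any(type_mix < 0)) {
    stop("type_mix must be 4 non-negative fractions", call. = FALSE)
  }
  if (abs(sum(type_mix) - 1) > 1e-8) {
    stop("type_mix must sum to 1", call. = FALSE)
  }
  stopifnot(n_granules >= 1)
  set.seed(as.integer(seed))
  levels <- list(background = 0.88, lumen = 0.78, ring = 0.35, core = 0.10)
  ring_w <- 4
  r_out <- stats::runif(n_granules, ring_radius_nm[1] / nm_per_px,
                        ring_radius_nm[2] / nm_per_px)
  types <- sample(1:4, n_granules, replace = TRUE, prob = type_mix)
  # grid-ish layout with jitter keeps placement trivially non-overlapping
  per_row <- ceiling(sqrt(n_granules))
  cell <- 2 * max(r_out) + 14
  side <- as.integer(ceiling(per_row * cell + 20))
  img <- matrix(levels$background, side, side)
  truth <- data.frame(granule_id = seq_len(n_granules), type = types,
                      row_px = NA_real_, col_px = NA_real_,
                      outer_r_px = r_out, fill_fraction = 0,
                      core_fragments = 0L)
  for (i in seq_len(n_granules)) {
    gr <- (i - 1) %/% per_row
    gc <- (i - 1) %% per_row
    row0 <- 10 + gr * cell + cell / 2 + stats::runif(1, -3, 3)
    col0 <- 10 + gc * cell + cell / 2 + stats::runif(1, -3, 3)
    truth$row_px[i] <- row0
    truth$col_px[i] <- col0
    img <- paint_disk(img, row0, col0, r_out[i], levels$ring)
    r_in <- r_out[i] - ring_w
    img <- paint_disk(img, row0, col0, r_in, levels$lumen)
    interior_area <- pi * r_in^2
    ty <- types[i]
    if (ty == 1 || ty == 2) {
      f <- if (ty == 1) stats::runif(1, 0.55, 0.85) else stats::runif(1, 0.15, 0.45)
      rc <- r_in * sqrt(f)
      img <- paint_disk(img, row0, col0, rc, levels$core)
      truth$fill_fraction[i] <- f
      truth$core_fragments[i] <- 1L
    } else if (ty == 3) {
      k <- sample(2:4, 1)
      f <- stats::runif(1, 0.15, 0.45)
      rc <- r_in * sqrt(f / k)
      # place fragments on a small ring so they stay separated
      ang <- stats::runif(1, 0, 2 * pi) + 2 * pi * seq_len(k) / k
      rad <- r_in - rc - 3
      for (j in seq_len(k)) {
        img <- paint_disk(img, row0 + rad * sin(ang[j]),
                          col0 + rad * cos(ang[j]), rc, levels$core)
      }
      truth$fill_fraction[i] <- k * pi * rc^2 / interior_area
      truth$core_fragments[i] <- k
    }
  }
  if (noise_sd > 0) {
    img <- img + matrix(stats::rnorm(side * side, 0, noise_sd), side, side)
    img[img < 0] <- 0; img[img > 1] <- 1
  }
  list(image = img, truth = truth, levels = levels)
}

#' Measure uranaffin granules in a thin-section image
#'
#' Segments membrane rings by an intensity window, fills each ring to get
#' the full granule region, takes the interior as the filled region minus
#' the ring, and segments the dense core as interior pixels darker than
#' `core_frac` times the mean ring intensity.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param ring_range Intensity window `(lo, hi)` capturing membrane pixels
#'   but not core pixels.
#' @param core_frac Core threshold as a fraction of the mean ring intensity
#'   (default 0.5).
#' @param min_area_px Minimum filled-region area to count as a granule.
#' @return data.frame `granule_id, row_px, col_px, interior_area_px,
#'   core_area_px, core_fragments, fill_fraction, assigned_type`.
#' @export
measure_uranaffin <- function(image, ring_range = c(0.22, 0.55),
                              core_frac = 0.5, min_area_px = 200) {
  ring_mask <- image > ring_range[1] & image < ring_range[2]
  if (!any(ring_mask)) {
    return(data.frame(granule_id = integer(), row_px = numeric(),
                      col_px = numeric(), interior_area_px = numeric(),
                      core_area_px = numeric(), core_fragments = integer(),
                      fill_fraction = numeric(), assigned_type = integer()))
  }
  lab <- label_components(ring_mask)
  filled <- as_label_matrix(EBImage::fillHull(lab))
  ft <- component_features(filled)
  ft <- ft[ft$area_px >= min_area_px, , drop = FALSE]
  # per-label bounding boxes so each granule is analysed in its own window
  idx <- which(filled > 0)
  l <- filled[idx]
  nr <- nrow(filled)
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  bb_r1 <- tapply(rr, l, min); bb_r2 <- tapply(rr, l, max)
  bb_c1 <- tapply(cc, l, min); bb_c2 <- tapply(cc, l, max)
  rows <- lapply(seq_len(nrow(ft)), function(i) {
    key <- as.character(ft$label[i])
    rs <- bb_r1[[key]]:bb_r2[[key]]
    cs <- bb_c1[[key]]:bb_c2[[key]]
    region <- filled[rs, cs, drop = FALSE] == ft$label[i]
    img_w <- image[rs, cs, drop = FALSE]
    ring_w <- ring_mask[rs, cs, drop = FALSE] & region
    interior <- region & !ring_w
    n_int <- sum(interior)
    if (n_int == 0) return(NULL)
    core_thr <- core_frac * mean(img_w[ring_w])
    core <- interior & img_w < core_thr
    core_area <- sum(core)
    frag <- if (core_area > 0) max(label_components(core)) else 0L
    fill <- core_area / n_int
    data.frame(granule_id = i, row_px = ft$row_px[i], col_px = ft$col_px[i],
               interior_area_px = n_int, core_area_px = core_area,
               core_fragments = as.integer(frag), fill_fraction = fill,
               assigned_type = type_granule(frag, fill))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame()
  out
}

#' Compare granule type distributions between two groups
#'
#' Standard 4-category contingency chi-square on the two count vectors.
#'
#' @param counts_a,counts_b Integer vectors of length 4 (counts of Types
#'   1-4).
#' @return List `statistic, df, p_value, expected`.
#' @export
compare_type_distributions <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == 4, length(counts_b) == 4)
  if (sum(counts_a) == 0 || sum(counts_b) == 0) {
    stop("zero-total group: type distribution undefined", call. = FALSE)
  }
  tab <- rbind(a = counts_a, b = counts_b)
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  if (ncol(tab) < 2) {
    # identical degenerate distributions: no evidence of difference
    return(list(statistic = 0, df = 0, p_value = 1,
                expected = tab))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ct$expected <= 0)) {
    stop("expected counts must be > 0", call. = FALSE)
  }
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), expected = ct$expected)
}
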