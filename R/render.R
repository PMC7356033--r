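# Whole-mount renderer: turns a simulated cohort into per-platelet grayscale
# images with exact ground truth. The optical model is deliberately simple --
# flat platelet footprint, near-saturated dark granule disks, faint
# alpha-granule shadows, optional opaque grid-bar bands, additive Gaussian
# noise -- because the downstream modules only need images whose truth is
# known exactly.

#' Rendering parameters for whole-mount images
#'
#' Intensities are on a 0 (black) to 1 (white) scale. Defaults give granules
#' a contrast of ~0.5 against the platelet footprint while alpha-granule
#' shadows sit at ~22% of that contrast, so a relative dark threshold
#' separates the two without per-image tuning.
#'
#' @param nm_per_px Pixel calibration (default 2 nm/px).
#' @param background,footprint,granule,shadow,band Intensities of the carbon
#'   film background, platelet footprint, dense granule disks, alpha-granule
#'   shadows, and grid-bar occlusion bands.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param n_shadows Alpha-granule shadows drawn per platelet.
#' @param shadow_diameter_nm Range of shadow diameters (nm).
#' @param footprint_radius_nm Range of platelet footprint radii (nm).
#' @param margin_px Blank margin around the footprint.
#' @export
render_params <- function(nm_per_px = 2,
                          background = 0.88,
                          footprint = 0.55,
                          granule = 0.06,
                          shadow = 0.44,
                          band = 0.03,
                          noise_sd = 0.02,
                          n_shadows = 8,
                          shadow_diameter_nm = c(150, 300),
                          footprint_radius_nm = c(270, 340),
                          margin_px = 12) {
  stopifnot(nm_per_px > 0, noise_sd >= 0)
  list(nm_per_px = nm_per_px, background = background, footprint = footprint,
       granule = granule, shadow = shadow, band = band, noise_sd = noise_sd,
       n_shadows = n_shadows, shadow_diameter_nm = shadow_diameter_nm,
       footprint_radius_nm = footprint_radius_nm, margin_px = margin_px)
}

#' Lay out a simulated cohort on per-platelet canvases
#'
#' Assigns every platelet a circular footprint and every granule a continuous
#' (row, col) centre inside it, by rejection sampling with a minimum
#' centre-to-centre separation so rendered disks do not merge. The footprint
#' radius is enlarged when a platelet carries many or unusually large
#' granules so that placement stays feasible. A fraction `artifact_rate` of
#' platelets is flagged as occluded by a grid bar; these are rendered with an
#' opaque vertical band crossing the footprint.
#'
#' Granules smaller than one rendered pixel trigger a warning but stay in the
#' truth table (they probe the detection limit).
#'
#' @param sim A [simulate_cohort()] result.
#' @param params [render_params()].
#' @param artifact_rate Fraction of platelets occluded by a grid bar.
#' @param seed Integer seed for placement randomness.
#' @return Object of class `wholemount_truth`: `platelets` (geometry and
#'   occlusion flags; 0-based pixel coordinates), `granules` (truth centres
#'   and diameters), `params`, `seed`.
#' @export
layout_wholemount <- function(sim, params = render_params(),
                              artifact_rate = 0, seed = 1L) {
  stopifnot(inherits(sim, "cohort_sim"), artifact_rate >= 0, artifact_rate <= 1)
  set.seed(as.integer(seed))
  npp <- params$nm_per_px
  plt <- sim$platelets
  gr <- sim$granules
  if (any(gr$diameter_nm < npp)) {
    warning(sum(gr$diameter_nm < npp),
            " granule(s) smaller than one rendered pixel; kept in truth")
  }
  n_plt <- nrow(plt)
  r_px_all <- gr$diameter_nm / 2 / npp
  # platelet geometry
  Rmin <- params$footprint_radius_nm[1] / npp
  Rmax <- params$footprint_radius_nm[2] / npp
  R <- stats::runif(n_plt, Rmin, Rmax)
  occluded <- stats::runif(n_plt) < artifact_rate

  key <- paste(plt$patient_id, plt$platelet_id)
  gkey <- factor(paste(gr$patient_id, gr$platelet_id), levels = key)
  gsplit <- split(seq_len(nrow(gr)), gkey)

  grow <- numeric(nrow(gr))
  gcol <- numeric(nrow(gr))
  side <- integer(n_plt)
  band_col <- rep(NA_real_, n_plt)
  band_w <- rep(NA_real_, n_plt)

  for (i in seq_len(n_plt)) {
    gi <- gsplit[[i]]
    r_px <- r_px_all[gi]
    Ri <- R[i]
    if (length(r_px)) {
      # keep disk packing below ~35% so sequential placement stays feasible
      Ri <- max(Ri, max(r_px) + 24, sqrt(sum((r_px + 2)^2) / 0.35))
    }
    s <- as.integer(ceiling(2 * (Ri + params$margin_px)))
    side[i] <- s
    ctr <- (s - 1) / 2   # 0-based canvas centre
    n <- length(r_px)
    if (n) {
      # place largest granules first: sequential placement then succeeds at
      # much higher packing fractions
      ord <- order(r_px, decreasing = TRUE)
      pr <- numeric(n); pc <- numeric(n)
      for (k in seq_len(n)) {
        g <- ord[k]
        placed <- FALSE
        for (try in seq_len(500)) {
          th <- stats::runif(1, 0, 2 * pi)
          rr <- sqrt(stats::runif(1)) * max(Ri - r_px[g] - 4, 1)
          cand_r <- ctr + rr * sin(th)
          cand_c <- ctr + rr * cos(th)
          ok <- TRUE
          if (k > 1) {
            prev <- ord[seq_len(k - 1)]
            d2 <- (cand_r - pr[prev])^2 + (cand_c - pc[prev])^2
            ok <- all(d2 >= (r_px[g] + r_px[prev] + 3)^2)
          }
          if (ok) { pr[g] <- cand_r; pc[g] <- cand_c; placed <- TRUE; break }
        }
        if (!placed) { pr[g] <- cand_r; pc[g] <- cand_c }
      }
      grow[gi] <- pr
      gcol[gi] <- pc
    }
    if (occluded[i]) {
      band_w[i] <- stats::runif(1, 70, 110)
      band_col[i] <- stats::runif(1, ctr - Ri, ctr + Ri - band_w[i] / 2)
    }
  }

  platelets <- data.frame(
    patient_id = plt$patient_id,
    platelet_id = plt$platelet_id,
    n_granules = plt$n_granules,
    side_px = side,
    centre_px = (side - 1) / 2,
    footprint_r_px = pmax(R, vapply(seq_len(n_plt), function(i) {
      gi <- gsplit[[i]]
      if (length(gi)) max(r_px_all[gi] + 24, sqrt(sum((r_px_all[gi] + 2)^2) / 0.35)) else 0
    }, numeric(1))),
    occluded = occluded,
    band_col_px = band_col,
    band_width_px = band_w
  )
  granules <- data.frame(
    patient_id = gr$patient_id,
    platelet_id = gr$platelet_id,
    granule_id = gr$granule_id,
    diameter_nm = gr$diameter_nm,
    row_px = grow,
    col_px = gcol
  )
  structure(list(platelets = platelets, granules = granules,
                 params = params, seed = as.integer(seed)),
            class = "wholemount_truth")
}

# Render a single platelet from its truth rows. Internal workhorse; noise is
# drawn from the current RNG stream so callers control seeding.
render_platelet_image <- function(plt_row, gran_rows, params) {
  s <- plt_row$side_px
  ctr <- plt_row$centre_px
  R <- plt_row$footprint_r_px
  img <- matrix(params$background, s, s)
  d2 <- ((seq_len(s) - 1) - ctr)^2
  mask <- outer(d2, d2, "+") <= R^2
  img[mask] <- params$footprint
  # alpha-granule shadows: faint gray blobs inside the footprint
  npp <- params$nm_per_px
  if (params$n_shadows > 0) {
    rs <- stats::runif(params$n_shadows, params$shadow_diameter_nm[1],
                       params$shadow_diameter_nm[2]) / 2 / npp
    th <- stats::runif(params$n_shadows, 0, 2 * pi)
    rr <- sqrt(stats::runif(params$n_shadows)) * pmax(R - rs - 2, 1)
    for (k in seq_len(params$n_shadows)) {
      srow <- ctr + rr[k] * sin(th[k])
      scol <- ctr + rr[k] * cos(th[k])
      # shadows only darken footprint pixels
      img <- paint_disk_masked(img, mask, srow, scol, rs[k], params$shadow)
    }
  }
  if (nrow(gran_rows)) {
    r_px <- gran_rows$diameter_nm / 2 / npp
    for (g in seq_len(nrow(gran_rows))) {
      img <- paint_disk(img, gran_rows$row_px[g], gran_rows$col_px[g],
                        r_px[g], params$granule)
    }
  }
  if (isTRUE(plt_row$occluded) && !is.na(plt_row$band_col_px)) {
    c1 <- max(1L, as.integer(plt_row$band_col_px) + 1L)
    c2 <- min(s, as.integer(plt_row$band_col_px + plt_row$band_width_px) + 1L)
    if (c1 <= c2) img[, c1:c2] <- params$band
  }
  if (params$noise_sd > 0) {
    # adding a plain vector keeps dim() and avoids a matrix() allocation;
    # clipping to [0, 1] is deferred to TIFF export (the detector is
    # threshold-based and indifferent to slight out-of-range values)
    img <- img + stats::rnorm(s * s, 0, params$noise_sd)
  }
  list(image = img, mask = mask)
}

#' Render whole-mount images for a laid-out cohort
#'
#' Materialises images for the requested platelets. Intended for inspection,
#' TIFF export and unit tests; the cohort-scale measurement driver
#' ([measure_wholemount_cohort()]) renders platelets one at a time internally
#' instead of holding thousands of frames in memory.
#'
#' @param truth A [layout_wholemount()] result.
#' @param patients,platelets Optional subsets (vectors of ids).
#' @param seed Seed for the noise and shadow draw.
#' @return List with one element per platelet: `patient_id, platelet_id,
#'   image, mask` plus the truth rows used. Truth is emitted unmodified.
#' @export
render_wholemount <- function(truth, patients = NULL, platelets = NULL,
                              seed = 1L) {
  stopifnot(inherits(truth, "wholemount_truth"))
  set.seed(as.integer(seed))
  plt <- truth$platelets
  keep <- rep(TRUE, nrow(plt))
  if (!is.null(patients)) keep <- keep & plt$patient_id %in% patients
  if (!is.null(platelets)) keep <- keep & plt$platelet_id %in% platelets
  idx <- which(keep)
  out <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    g <- truth$granules[truth$granules$patient_id == plt$patient_id[i] &
                          truth$granules$platelet_id == plt$platelet_id[i], ,
                        drop = FALSE]
    ri <- render_platelet_image(plt[i, ], g, truth$params)
    out[[j]] <- list(patient_id = plt$patient_id[i],
                     platelet_id = plt$platelet_id[i],
                     image = ri$image, mask = ri$mask, truth = g)
  }
  out
}
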