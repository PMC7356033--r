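# Dense-granule detection in whole-mount images: relative dark threshold
# inside the platelet footprint, connected components, size and circularity
# gates, optional distance-transform watershed to split touching granules.

#' Detection configuration
#'
#' @param nm_per_px Pixel calibration used to convert areas to equivalent
#'   diameters.
#' @param dark_threshold Relative threshold: pixels darker than
#'   `dark_threshold * median(footprint intensity)` are granule candidates.
#'   Granules render near-saturated dark while alpha-granule shadows keep at
#'   least ~75% of the footprint intensity, so the default 0.5 separates them
#'   without per-image tuning.
#' @param absolute_threshold Optional absolute intensity threshold in
#'   `[0, 1]`; overrides the relative rule when given.
#' @param min_diameter_nm,max_diameter_nm Equivalent-diameter size gate
#'   (default 60-400 nm, bracketing the 123-152 nm range of group means with
#'   headroom).
#' @param min_circularity Components with `4*pi*area/perimeter^2` below this
#'   are discarded (after an optional split attempt).
#' @param split_touching Attempt a distance-transform watershed split on
#'   components whose moment circularity suggests merged disks.
#' @param split_trigger Moment-circularity level below which a component is
#'   treated as possibly merged (a clean disk scores ~1, a touching pair
#'   ~0.65-0.8).
#' @export
detection_config <- function(nm_per_px = 2,
                             dark_threshold = 0.5,
                             absolute_threshold = NULL,
                             min_diameter_nm = 60,
                             max_diameter_nm = 400,
                             min_circularity = 0.6,
                             split_touching = TRUE,
                             split_trigger = 0.9) {
  stopifnot(nm_per_px > 0)
  if (!(min_diameter_nm < max_diameter_nm)) {
    stop("min_diameter_nm must be < max_diameter_nm", call. = FALSE)
  }
  if (min_circularity < 0 || min_circularity > 1) {
    stop("min_circularity must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(absolute_threshold) &&
      (absolute_threshold <= 0 || absolute_threshold >= 1)) {
    stop("absolute_threshold outside the intensity range (0, 1)",
         call. = FALSE)
  }
  list(nm_per_px = nm_per_px, dark_threshold = dark_threshold,
       absolute_threshold = absolute_threshold,
       min_diameter_nm = min_diameter_nm, max_diameter_nm = max_diameter_nm,
       min_circularity = min_circularity, split_touching = split_touching,
       split_trigger = split_trigger)
}

# Watershed split of one candidate component; fragments below the minimum
# size gate are re-merged to their nearest neighbour fragment (tie-break for
# over-segmentation). Returns a features data.frame in the parent image frame.
split_component <- function(bin_sub, offset_row, offset_col, min_area_px) {
  dm <- EBImage::distmap(bin_sub * 1)
  ws <- as_label_matrix(EBImage::watershed(dm, tolerance = 1, ext = 1))
  nfrag <- max(ws)
  if (nfrag < 2) {
    ft <- component_features(bin_sub * 1L)
  } else {
    ft <- component_features(ws)
    small <- ft$area_px < min_area_px
    if (any(small) && any(!small)) {
      for (s in which(small)) {
        others <- which(!small)
        d2 <- (ft$row_px[others] - ft$row_px[s])^2 +
          (ft$col_px[others] - ft$col_px[s])^2
        tgt <- others[which.min(d2)]
        ws[ws == ft$label[s]] <- ft$label[tgt]
      }
      ft <- component_features(ws)
    }
  }
  ft$row_px <- ft$row_px + offset_row
  ft$col_px <- ft$col_px + offset_col
  ft
}

#' Detect dense granules within a platelet footprint
#'
#' Pixels darker than the threshold inside the mask are grouped into
#' connected components; components that look like merged disks are
#' optionally split by a watershed on the distance transform; components
#' failing the size or circularity gate are discarded. Each surviving
#' component yields one measurement with the equivalent-circle diameter
#' `2 * sqrt(area/pi) * nm_per_px`.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param mask Logical matrix of the platelet footprint (same dimensions).
#' @param config [detection_config()].
#' @return data.frame `granule_id, row_px, col_px` (0-based centroid),
#'   `area_px, equivalent_diameter_nm, circularity`. Empty mask gives an
#'   empty result.
#' @export
detect_granules <- function(image, mask, config = detection_config()) {
  if (!all(dim(image) == dim(mask))) {
    stop("image and mask dimensions differ", call. = FALSE)
  }
  empty <- data.frame(granule_id = integer(), row_px = numeric(),
                      col_px = numeric(), area_px = numeric(),
                      equivalent_diameter_nm = numeric(),
                      circularity = numeric())
  if (!any(mask)) return(empty)
  thr <- if (!is.null(config$absolute_threshold)) {
    config$absolute_threshold
  } else {
    config$dark_threshold * subsampled_median(image[mask])
  }
  bin <- image < thr & mask
  if (!any(bin)) return(empty)
  lab <- label_components(bin)
  ft <- component_features(lab)
  npp <- config$nm_per_px
  min_area <- pi / 4 * (config$min_diameter_nm / npp)^2
  # drop speckle well below the gate before any splitting
  ft <- ft[ft$area_px >= min_area / 4, , drop = FALSE]
  if (!nrow(ft)) return(empty)

  out <- vector("list", nrow(ft))
  for (i in seq_len(nrow(ft))) {
    fi <- ft[i, ]
    if (config$split_touching && fi$moment_circ < config$split_trigger) {
      comp <- lab == fi$label
      rows <- range(which(rowSums(comp) > 0))
      cols <- range(which(colSums(comp) > 0))
      sub <- comp[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
      out[[i]] <- split_component(sub, rows[1] - 1, cols[1] - 1, min_area)
    } else {
      out[[i]] <- fi
    }
  }
  ft <- do.call(rbind, out)
  d_nm <- 2 * sqrt(ft$area_px / pi) * npp
  keep <- d_nm >= config$min_diameter_nm & d_nm <= config$max_diameter_nm &
    ft$circularity >= config$min_circularity
  ft <- ft[keep, , drop = FALSE]
  d_nm <- d_nm[keep]
  if (!nrow(ft)) return(empty)
  data.frame(granule_id = seq_len(nrow(ft)),
             row_px = ft$row_px, col_px = ft$col_px,
             area_px = ft$area_px,
             equivalent_diameter_nm = d_nm,
             circularity = pmin(ft$circularity, 1.2))
}

#' Detect a grid-bar occlusion band
#'
#' Grid bars render as opaque full-height (or full-width) bands. A platelet
#' is flagged when a run of at least `min_run` consecutive columns or rows
#' has mean intensity below `level`.
#'
#' @param image Numeric matrix.
#' @param level Mean-intensity cutoff for a band line (default 0.2; bands are
#'   near black while any line crossing the footprint stays above ~0.5).
#' @param min_run Minimum run length in pixels.
#' @return TRUE if a band is present.
#' @export
detect_occlusion_band <- function(image, level = 0.2, min_run = 20) {
  for (means in list(colMeans(image), rowMeans(image))) {
    dark <- means < level
    if (any(dark)) {
      r <- rle(dark)
      if (any(r$lengths[r$values] >= min_run)) return(TRUE)
    }
  }
  FALSE
}

#' Render and measure an entire cohort
#'
#' The cohort-scale driver: renders each platelet in turn (never holding the
#' full image set in memory), applies the grid-bar artifact test, detects and
#' measures granules on included platelets, and collects per-platelet records
#' and per-granule measurements.
#'
#' @param truth A [layout_wholemount()] result.
#' @param config [detection_config()]; its `nm_per_px` should match the
#'   render calibration.
#' @param seed Seed for rendering noise.
#' @param use_truth_exclusions Use the generator's occlusion flags instead of
#'   the image-based band test (the two agree on synthetic data; the band
#'   test is the default because real input has no truth flags).
#' @return Object of class `wholemount_measurements`: `records` (one row per
#'   platelet: `patient_id, platelet_id, included, exclusion_reason,
#'   n_granules`) and `measurements` (one row per detected granule).
#' @export
measure_wholemount_cohort <- function(truth, config = detection_config(),
                                      seed = 1L,
                                      use_truth_exclusions = FALSE) {
  stopifnot(inherits(truth, "wholemount_truth"))
  set.seed(as.integer(seed))
  plt <- truth$platelets
  gr <- truth$granules
  gkey <- factor(paste(gr$patient_id, gr$platelet_id),
                 levels = paste(plt$patient_id, plt$platelet_id))
  gsplit <- split(seq_len(nrow(gr)), gkey)
  n <- nrow(plt)
  included <- logical(n)
  reason <- character(n)
  n_det <- integer(n)
  meas <- vector("list", n)
  for (i in seq_len(n)) {
    g <- gr[gsplit[[i]], , drop = FALSE]
    ri <- render_platelet_image(plt[i, ], g, truth$params)
    occ <- if (use_truth_exclusions) isTRUE(plt$occluded[i]) else
      detect_occlusion_band(ri$image)
    if (occ) {
      included[i] <- FALSE
      reason[i] <- "grid_bar_occlusion"
      next
    }
    det <- detect_granules(ri$image, ri$mask, config)
    included[i] <- TRUE
    reason[i] <- "none"
    n_det[i] <- nrow(det)
    if (nrow(det)) {
      det$patient_id <- plt$patient_id[i]
      det$platelet_id <- plt$platelet_id[i]
      meas[[i]] <- det
    }
  }
  measurements <- do.call(rbind, meas[!vapply(meas, is.null, logical(1))])
  if (is.null(measurements)) {
    measurements <- data.frame(granule_id = integer(), row_px = numeric(),
                               col_px = numeric(), area_px = numeric(),
                               equivalent_diameter_nm = numeric(),
                               circularity = numeric(),
                               patient_id = integer(), platelet_id = integer())
  }
  records <- data.frame(
    patient_id = plt$patient_id,
    platelet_id = plt$platelet_id,
    included = included,
    exclusion_reason = ifelse(included, "none", reason),
    n_granules = n_det
  )
  structure(list(records = records, measurements = measurements,
                 config = config, seed = as.integer(seed)),
            class = "wholemount_measurements")
}

#' Granules per platelet over included platelets
#'
#' The enumeration statistic: total granules across included platelets
#' divided by the number of included platelets, per patient. Excluded
#' platelets (grid-bar occlusion or preparation artifact) contribute nothing.
#'
#' @param records Per-platelet records (`patient_id, included, n_granules`).
#' @return data.frame `patient_id, n_platelets_counted, n_excluded,
#'   total_granules, dg_per_platelet`.
#' @export
enumerate_platelets <- function(records) {
  stopifnot(all(c("patient_id", "included", "n_granules") %in% names(records)))
  out <- lapply(split(records, records$patient_id), function(r) {
    inc <- r[r$included, , drop = FALSE]
    if (!nrow(inc)) {
      stop("patient ", r$patient_id[1],
           ": zero included platelets, DG/PL undefined", call. = FALSE)
    }
    data.frame(patient_id = r$patient_id[1],
               n_platelets_counted = nrow(inc),
               n_excluded = sum(!r$included),
               total_granules = sum(inc$n_granules),
               dg_per_platelet = sum(inc$n_granules) / nrow(inc))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$patient_id), , drop = FALSE]
}

#' Select platelets for diameter measurement
#'
#' Mirrors the photographing rule of the whole-mount protocol: up to
#' `target_n` included platelets per patient, each carrying at least
#' `min_dg` detected granules, chosen by a seeded uniform draw. If fewer
#' qualify, all qualifying platelets are returned with a warning.
#'
#' @param records Per-platelet records from [measure_wholemount_cohort()].
#' @param min_dg Minimum granule count for a platelet to qualify (default 4).
#' @param target_n Platelets to photograph per patient (default 12; the
#'   protocol used 12 random fields containing 12-20 platelets).
#' @param seed Integer seed.
#' @return `records` with an added logical column `sized`.
#' @export
select_platelets_for_sizing <- function(records, min_dg = 4, target_n = 12,
                                        seed = 1L) {
  set.seed(as.integer(seed))
  records$sized <- FALSE
  short <- 0L
  for (pid in unique(records$patient_id)) {
    idx <- which(records$patient_id == pid & records$included &
                   records$n_granules >= min_dg)
    if (length(idx) < target_n) {
      short <- short + 1L
      take <- idx
    } else {
      take <- sample(idx, target_n)
    }
    records$sized[take] <- TRUE
  }
  if (short > 0) {
    warning(short, " patient(s) had fewer than ", target_n,
            " platelets with >= ", min_dg, " granules; all qualifying ",
            "platelets used")
  }
  records
}
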