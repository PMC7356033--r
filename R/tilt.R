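# Tilt-series geometry: projections of spheres embedded in a thick slab at a
# sequence of stage tilt angles, and the decision rule that distinguishes a
# single sphere from superimposed spheres or a genuinely non-spherical body.
#
# Geometry model: a single in-plane tilt axis (the image x/column axis).
# Tilting by theta displaces each body's projected centre along the
# perpendicular (row) axis by z * sin(theta), with z measured from the slab
# mid-plane; the coordinate along the tilt axis is unchanged. A sphere
# projects to a disk of its own radius at every angle; an axis-aligned
# ellipsoid projects to an ellipse whose out-of-plane semi-axis mixes with
# the in-plane one as sqrt(b^2 cos^2 + c^2 sin^2).

#' Specify a tilt scene
#'
#' @param spheres data.frame `x_nm, y_nm, z_nm, r_nm`: positions (x along
#'   the tilt axis, y perpendicular, z the depth within the slab measured
#'   from its lower face) and radii. May have zero rows.
#' @param ellipsoids Optional data.frame `x_nm, y_nm, z_nm, a_nm, b_nm,
#'   c_nm` of axis-aligned ellipsoids (semi-axes along x, y, z).
#' @param slab_thickness_nm Section thickness (750-1000 nm for high-voltage
#'   work).
#' @param tilt_angles_deg Strictly increasing tilt angles in degrees.
#' @param nm_per_px Pixel calibration.
#' @param frame_nm `c(width, height)` of the imaged field in nm; defaults to
#'   a frame that accommodates all projections at every angle.
#' @return Object of class `tilt_scene`.
#' @export
tilt_scene <- function(spheres,
                       ellipsoids = NULL,
                       slab_thickness_nm = 900,
                       tilt_angles_deg = c(0, 15, 30, 45),
                       nm_per_px = 2,
                       frame_nm = NULL) {
  stopifnot(is.data.frame(spheres),
            slab_thickness_nm > 0, nm_per_px > 0)
  if (is.unsorted(tilt_angles_deg, strictly = TRUE)) {
    stop("tilt_angles_deg must be strictly increasing", call. = FALSE)
  }
  if (nrow(spheres)) {
    bad <- spheres$z_nm - spheres$r_nm < 0 |
      spheres$z_nm + spheres$r_nm > slab_thickness_nm
    if (any(bad)) {
      stop(sum(bad), " sphere(s) do not fit inside the slab", call. = FALSE)
    }
  }
  if (!is.null(ellipsoids) && nrow(ellipsoids)) {
    bad <- ellipsoids$z_nm - ellipsoids$c_nm < 0 |
      ellipsoids$z_nm + ellipsoids$c_nm > slab_thickness_nm
    if (any(bad)) {
      stop("ellipsoid(s) do not fit inside the slab", call. = FALSE)
    }
  }
  origin_nm <- c(0, 0)  # (x, y) of the frame's pixel (0, 0)
  if (is.null(frame_nm)) {
    zmax <- slab_thickness_nm / 2
    smax <- sin(max(abs(tilt_angles_deg)) * pi / 180)
    ys <- c(if (nrow(spheres)) c(spheres$y_nm - spheres$r_nm - zmax * smax,
                                 spheres$y_nm + spheres$r_nm + zmax * smax),
            if (!is.null(ellipsoids) && nrow(ellipsoids))
              c(ellipsoids$y_nm - ellipsoids$b_nm - ellipsoids$c_nm - zmax * smax,
                ellipsoids$y_nm + ellipsoids$b_nm + ellipsoids$c_nm + zmax * smax))
    xs <- c(if (nrow(spheres)) c(spheres$x_nm - spheres$r_nm,
                                 spheres$x_nm + spheres$r_nm),
            if (!is.null(ellipsoids) && nrow(ellipsoids))
              c(ellipsoids$x_nm - ellipsoids$a_nm,
                ellipsoids$x_nm + ellipsoids$a_nm))
    if (!length(xs)) { xs <- c(0, 100); ys <- c(0, 100) }
    pad <- 30 * nm_per_px
    origin_nm <- c(min(xs) - pad, min(ys) - pad)
    frame_nm <- c(diff(range(xs)) + 2 * pad, diff(range(ys)) + 2 * pad)
  }
  structure(list(spheres = spheres, ellipsoids = ellipsoids,
                 slab_thickness_nm = slab_thickness_nm,
                 tilt_angles_deg = tilt_angles_deg,
                 nm_per_px = nm_per_px, frame_nm = frame_nm,
                 origin_nm = origin_nm),
            class = "tilt_scene")
}

#' Render the projection stack of a tilt scene
#'
#' One frame per tilt angle. Projected disks accumulate intensity where they
#' overlap, mimicking mass-thickness contrast in a thick section.
#'
#' @param scene A [tilt_scene()].
#' @return Object of class `tilt_series`: `angles_deg`, `frames` (list of
#'   matrices; intensity 0 = empty), `nm_per_px`, `scene`.
#' @export
render_tilt_series <- function(scene) {
  stopifnot(inherits(scene, "tilt_scene"))
  npp <- scene$nm_per_px
  w <- as.integer(ceiling(scene$frame_nm[1] / npp))
  h <- as.integer(ceiling(scene$frame_nm[2] / npp))
  zmid <- scene$slab_thickness_nm / 2
  origin <- if (is.null(scene$origin_nm)) c(0, 0) else scene$origin_nm
  frames <- lapply(scene$tilt_angles_deg, function(theta) {
    s <- sin(theta * pi / 180)
    img <- matrix(0, h, w)
    sp <- scene$spheres
    if (nrow(sp)) {
      for (i in seq_len(nrow(sp))) {
        row0 <- (sp$y_nm[i] + (sp$z_nm[i] - zmid) * s - origin[2]) / npp
        col0 <- (sp$x_nm[i] - origin[1]) / npp
        r_px <- sp$r_nm[i] / npp
        if (row0 - r_px < 0 || row0 + r_px > h - 1 ||
            col0 - r_px < 0 || col0 + r_px > w - 1) {
          stop(sprintf("projection falls outside the %dx%d px frame", h, w),
               call. = FALSE)
        }
        img <- add_disk(img, row0, col0, r_px, 0.4)
      }
    }
    el <- scene$ellipsoids
    if (!is.null(el) && nrow(el)) {
      co <- cos(theta * pi / 180)
      for (i in seq_len(nrow(el))) {
        b_eff <- sqrt(el$b_nm[i]^2 * co^2 + el$c_nm[i]^2 * s^2)
        row0 <- (el$y_nm[i] + (el$z_nm[i] - zmid) * s - origin[2]) / npp
        col0 <- (el$x_nm[i] - origin[1]) / npp
        if (row0 - b_eff / npp < 0 || row0 + b_eff / npp > h - 1 ||
            col0 - el$a_nm[i] / npp < 0 || col0 + el$a_nm[i] / npp > w - 1) {
          stop(sprintf("projection falls outside the %dx%d px frame", h, w),
               call. = FALSE)
        }
        img <- paint_ellipse_add(img, row0, col0, b_eff / npp,
                                 el$a_nm[i] / npp, 0.4)
      }
    }
    pmin(img, 1)
  })
  structure(list(angles_deg = scene$tilt_angles_deg, frames = frames,
                 nm_per_px = npp, scene = scene),
            class = "tilt_series")
}

# Blob statistics for one frame: label connected projections and measure.
frame_blobs <- function(frame, nm_per_px, min_area_px = 20) {
  bin <- frame > 0.05
  if (!any(bin)) {
    return(data.frame(blob = integer(), row_px = numeric(),
                      col_px = numeric(), area_px = numeric(),
                      equivalent_diameter_nm = numeric(),
                      aspect_ratio = numeric()))
  }
  ft <- component_features(label_components(bin))
  ft <- ft[ft$area_px >= min_area_px, , drop = FALSE]
  data.frame(blob = seq_len(nrow(ft)), row_px = ft$row_px,
             col_px = ft$col_px, area_px = ft$area_px,
             equivalent_diameter_nm = 2 * sqrt(ft$area_px / pi) * nm_per_px,
             aspect_ratio = ft$aspect_ratio)
}

#' Per-angle blob table for a tilt series
#'
#' Labels the projected blobs of every frame, assigns each blob to an
#' apparent object (objects are defined by the blobs of the frame whose
#' angle is closest to zero; assignment across angles is by nearest
#' centroid along the tilt axis, which tilting leaves unchanged), and
#' reports each blob's aspect ratio and equivalent diameter.
#'
#' @param series A `tilt_series` (from [render_tilt_series()]) or a list
#'   with `angles_deg`, `frames`, `nm_per_px`.
#' @return data.frame `angle_deg, object_id, blob, row_px, col_px, area_px,
#'   equivalent_diameter_nm, aspect_ratio`. Empty frames yield no rows.
#' @export
circularity_profile <- function(series) {
  angles <- series$angles_deg
  frames <- series$frames
  if (length(frames) != length(angles)) {
    stop("one frame per angle required", call. = FALSE)
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("frames of unequal size", call. = FALSE)
  }
  ref_i <- which.min(abs(angles))
  ref <- frame_blobs(frames[[ref_i]], series$nm_per_px)
  out <- lapply(seq_along(angles), function(i) {
    b <- frame_blobs(frames[[i]], series$nm_per_px)
    if (!nrow(b)) return(NULL)
    if (nrow(ref)) {
      b$object_id <- vapply(b$col_px, function(x)
        ref$blob[which.min(abs(ref$col_px - x))], integer(1))
    } else {
      b$object_id <- b$blob
    }
    b$angle_deg <- angles[i]
    b
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    return(data.frame(angle_deg = numeric(), object_id = integer(),
                      blob = integer(), row_px = numeric(),
                      col_px = numeric(), area_px = numeric(),
                      equivalent_diameter_nm = numeric(),
                      aspect_ratio = numeric()))
  }
  out[, c("angle_deg", "object_id", "blob", "row_px", "col_px", "area_px",
          "equivalent_diameter_nm", "aspect_ratio")]
}

#' Sphericity verdict for each apparent object in a tilt series
#'
#' An apparent object is `single_sphere` when it remains one blob with
#' aspect ratio at most `aspect_tol` at every angle; `superimposed_spheres`
#' when some angle resolves it into two or more blobs that are each round
#' (aspect at most `aspect_tol`) and separated by at least `split_margin`
#' pixels; `non_spherical` otherwise (persistent elongation that never
#' splits).
#'
#' @param series A `tilt_series`.
#' @param aspect_tol Roundness tolerance on the blob aspect ratio
#'   (default 1.15).
#' @param split_margin Minimum centroid separation, in px, for two blobs to
#'   count as a genuine split (default 2).
#' @return data.frame `object_id, verdict, max_aspect, max_blobs` plus an
#'   `evidence` attribute holding the full [circularity_profile()] table.
#'   Requires at least 3 angles spanning at least 30 degrees.
#' @export
analyze_tilt_series <- function(series, aspect_tol = 1.15, split_margin = 2) {
  angles <- series$angles_deg
  if (length(angles) < 3 || diff(range(angles)) < 30) {
    stop("need >= 3 tilt angles spanning >= 30 degrees", call. = FALSE)
  }
  prof <- circularity_profile(series)
  if (!nrow(prof)) {
    return(structure(data.frame(object_id = integer(), verdict = character(),
                                max_aspect = numeric(), max_blobs = integer()),
                     evidence = prof))
  }
  res <- lapply(split(prof, prof$object_id), function(p) {
    by_angle <- split(p, p$angle_deg)
    n_blobs <- vapply(by_angle, nrow, integer(1))
    round_split <- vapply(by_angle, function(a) {
      if (nrow(a) < 2) return(FALSE)
      sep <- max(stats::dist(cbind(a$row_px, a$col_px)))
      all(a$aspect_ratio <= aspect_tol) && sep >= split_margin
    }, logical(1))
    always_single_round <- all(n_blobs == 1) &&
      all(p$aspect_ratio <= aspect_tol)
    verdict <- if (always_single_round) {
      "single_sphere"
    } else if (any(round_split)) {
      "superimposed_spheres"
    } else {
      "non_spherical"
    }
    data.frame(object_id = p$object_id[1], verdict = verdict,
               max_aspect = max(p$aspect_ratio),
               max_blobs = max(n_blobs))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, evidence = prof)
}
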