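# Per-patient storage-pool morphometry: sphere volumes, mean dense-granule
# volume (MDGV), total dense-granule volume per platelet (TDGV), and granule
# size-distribution summaries.

#' Volume of a sphere from its diameter
#'
#' `(4/3) * pi * r^3` with `r = d/2`, i.e. `(pi/6) * d^3`. Granules are
#' treated as spheres; the tilt-series module exists to justify that
#' assumption.
#'
#' @param diameter_nm Diameter(s) in nm, `>= 0`.
#' @return Volume(s) in nm^3.
#' @export
sphere_volume <- function(diameter_nm) {
  if (any(diameter_nm < 0, na.rm = TRUE)) {
    stop("diameter must be >= 0", call. = FALSE)
  }
  (pi / 6) * diameter_nm^3
}

#' Per-patient storage-pool profile
#'
#' Computes the patient's DG/PL over included platelets, then the diameter
#' and volume statistics over granules measured on the sized platelet
#' subset. MDGV pools all sized granules for the patient (the sum of granule
#' volumes divided by the number of granules evaluated -- granule-weighted,
#' not a mean of per-platelet means). TDGV is the product
#' `MDGV * dg_per_platelet`, exactly.
#'
#' With an empty sized subset the diameter and volume fields are `NA`
#' (marked unavailable, never silent zeros).
#'
#' @param records Per-platelet records for one patient (must contain
#'   `included`, `n_granules`, and a logical `sized` column, e.g. from
#'   [select_platelets_for_sizing()]).
#' @param measurements Granule measurements for the same patient
#'   (`platelet_id, equivalent_diameter_nm`).
#' @param volume_cut_nm3 Fixed cut for the small-granule fraction
#'   (default 1.5e6 nm^3).
#' @return One-row data.frame (a `PatientProfile`): `patient_id,
#'   n_platelets_counted, dg_per_platelet, n_granules_sized,
#'   mean_diameter_nm, se_diameter, mdgv_nm3, tdgv_nm3, fraction_small`.
#' @export
profile_patient <- function(records, measurements, volume_cut_nm3 = 1.5e6) {
  stopifnot(length(unique(records$patient_id)) == 1,
            "sized" %in% names(records))
  enum <- enumerate_platelets(records)
  sized_ids <- records$platelet_id[records$sized]
  m <- measurements[measurements$platelet_id %in% sized_ids, , drop = FALSE]
  n_sized <- nrow(m)
  if (n_sized == 0) {
    mean_d <- NA_real_; se_d <- NA_real_
    mdgv <- NA_real_; frac_small <- NA_real_
  } else {
    d <- m$equivalent_diameter_nm
    mean_d <- mean(d)
    se_d <- if (n_sized > 1) stats::sd(d) / sqrt(n_sized) else NA_real_
    v <- sphere_volume(d)
    mdgv <- mean(v)
    frac_small <- mean(v < volume_cut_nm3)
  }
  data.frame(
    patient_id = records$patient_id[1],
    n_platelets_counted = enum$n_platelets_counted,
    dg_per_platelet = enum$dg_per_platelet,
    n_granules_sized = n_sized,
    mean_diameter_nm = mean_d,
    se_diameter = se_d,
    mdgv_nm3 = mdgv,
    tdgv_nm3 = mdgv * enum$dg_per_platelet,
    fraction_small = frac_small
  )
}

#' Profile every patient in a measured cohort
#'
#' Applies the sizing selection and [profile_patient()] across a cohort.
#'
#' @param measured A `wholemount_measurements` object from
#'   [measure_wholemount_cohort()], or a list with `records` and
#'   `measurements` data.frames.
#' @param min_dg,target_n,seed Passed to [select_platelets_for_sizing()].
#' @param volume_cut_nm3 Passed to [profile_patient()].
#' @return data.frame of patient profiles, one row per patient.
#' @export
profile_cohort <- function(measured, min_dg = 4, target_n = 12, seed = 1L,
                           volume_cut_nm3 = 1.5e6) {
  rec <- select_platelets_for_sizing(measured$records, min_dg = min_dg,
                                     target_n = target_n, seed = seed)
  out <- lapply(split(seq_len(nrow(rec)), rec$patient_id), function(idx) {
    r <- rec[idx, , drop = FALSE]
    m <- measured$measurements[
      measured$measurements$patient_id == r$patient_id[1], , drop = FALSE]
    profile_patient(r, m, volume_cut_nm3 = volume_cut_nm3)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$patient_id), , drop = FALSE]
}

#' Profiles straight from generator truth
#'
#' Bypasses rendering and detection: treats the simulated truth table as the
#' measurement table. Used for fast large-cohort experiments where the
#' question is statistical (classification, group comparison), not about the
#' imaging pipeline. The same sizing rule is applied so profiles are
#' comparable with the rendered path.
#'
#' @param sim A [simulate_cohort()] result.
#' @param min_dg,target_n,seed,volume_cut_nm3 As in [profile_cohort()].
#' @export
profile_cohort_from_truth <- function(sim, min_dg = 4, target_n = 12,
                                      seed = 1L, volume_cut_nm3 = 1.5e6) {
  stopifnot(inherits(sim, "cohort_sim"))
  records <- data.frame(
    patient_id = sim$platelets$patient_id,
    platelet_id = sim$platelets$platelet_id,
    included = TRUE,
    exclusion_reason = "none",
    n_granules = sim$platelets$n_granules
  )
  measurements <- data.frame(
    patient_id = sim$granules$patient_id,
    platelet_id = sim$granules$platelet_id,
    granule_id = sim$granules$granule_id,
    equivalent_diameter_nm = sim$granules$diameter_nm
  )
  profile_cohort(list(records = records, measurements = measurements),
                 min_dg = min_dg, target_n = target_n, seed = seed,
                 volume_cut_nm3 = volume_cut_nm3)
}

#' Granule volume distribution and small-granule fraction
#'
#' Bins granule volumes and reports the fraction below the fixed cut, per
#' group when a grouping vector is supplied.
#'
#' @param volumes_nm3 Granule volumes (nm^3), or diameters via
#'   `sphere_volume()` upstream.
#' @param group Optional grouping vector (same length).
#' @param volume_cut_nm3 Cut for the small fraction (default 1.5e6 nm^3).
#' @param breaks Histogram breaks in nm^3 (default 20 bins spanning the
#'   data).
#' @return List with `fraction_small` (named by group) and `histogram`
#'   (data.frame `group, bin_lo, bin_hi, count`).
#' @export
size_distribution <- function(volumes_nm3, group = NULL,
                              volume_cut_nm3 = 1.5e6, breaks = 20) {
  stopifnot(length(volumes_nm3) >= 1)
  if (is.null(group)) group <- rep("all", length(volumes_nm3))
  if (length(breaks) == 1) {
    breaks <- seq(0, max(volumes_nm3) * 1.0001, length.out = breaks + 1)
  }
  frac <- vapply(split(volumes_nm3, group),
                 function(v) mean(v < volume_cut_nm3), numeric(1))
  hist_list <- lapply(names(frac), function(gname) {
    v <- volumes_nm3[group == gname]
    cts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                    nbins = length(breaks) - 1)
    data.frame(group = gname, bin_lo = breaks[-length(breaks)],
               bin_hi = breaks[-1], count = cts)
  })
  list(fraction_small = frac, histogram = do.call(rbind, hist_list),
       volume_cut_nm3 = volume_cut_nm3)
}
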