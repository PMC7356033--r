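# Control reference ranges and storage-pool category assignment.
#
# Categories: NORMAL, CLASSIC_DSPD (count deficiency), MGSPD (normal count,
# mean granule diameter below the control range), ELEVATED_DG. An SPVD flag
# (storage pool volume deficiency: TDGV below the control range) is carried
# independently of the primary category.

GRANULE_CATEGORIES <- c("NORMAL", "CLASSIC_DSPD", "MGSPD", "ELEVATED_DG")

REFERENCE_METRICS <- c("dg_per_platelet", "mean_diameter_nm", "tdgv_nm3")

#' Build control reference ranges
#'
#' For each metric, computes the control mean, the standard error of the mean
#' (`sd/sqrt(n)`), and bounds `mean +/- k * SE`. The published procedure set
#' normal values as a range of 3 standard errors of the mean around the
#' control average; `spread = "sd"` is available for the alternative reading
#' where the band is built from standard deviations instead.
#'
#' @param control_profiles data.frame of control patient profiles (from
#'   [profile_cohort()] or built by hand) containing the metric columns.
#' @param metrics Metric columns to build ranges for.
#' @param k Number of spread units on each side (default 3).
#' @param spread `"se"` (default) or `"sd"`.
#' @return data.frame of class `reference_ranges`: `metric, n, mean, se,
#'   lower, upper`.
#' @export
build_reference <- function(control_profiles,
                            metrics = REFERENCE_METRICS,
                            k = 3, spread = c("se", "sd")) {
  spread <- match.arg(spread)
  if (nrow(control_profiles) < 2) {
    stop("at least 2 control profiles are required (SE undefined otherwise)",
         call. = FALSE)
  }
  rows <- lapply(metrics, function(mt) {
    x <- control_profiles[[mt]]
    if (is.null(x)) stop("missing metric column: ", mt, call. = FALSE)
    x <- x[is.finite(x)]
    n <- length(x)
    if (n < 2) stop("metric ", mt, ": fewer than 2 finite control values",
                    call. = FALSE)
    se <- stats::sd(x) / sqrt(n)
    if (se <= 0) {
      stop("metric ", mt, ": zero spread among controls, range degenerate",
           call. = FALSE)
    }
    half <- if (spread == "se") k * se else k * stats::sd(x)
    data.frame(metric = mt, n = n, mean = mean(x), se = se,
               lower = mean(x) - half, upper = mean(x) + half)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("reference_ranges", class(out))
  out
}

#' Reference ranges from published summary statistics
#'
#' Builds the same structure as [build_reference()] directly from group
#' means and standard errors (e.g. a published control row), for use when
#' raw control profiles are not available.
#'
#' @param means,ses Named numeric vectors (names = metrics).
#' @param n Number of control subjects the summaries came from.
#' @param k Spread multiplier (default 3).
#' @export
reference_from_summary <- function(means, ses, n, k = 3) {
  stopifnot(length(means) == length(ses), !is.null(names(means)))
  if (any(ses <= 0)) stop("standard errors must be > 0", call. = FALSE)
  out <- data.frame(metric = names(means), n = n, mean = as.numeric(means),
                    se = as.numeric(ses),
                    lower = as.numeric(means - k * ses),
                    upper = as.numeric(means + k * ses))
  class(out) <- c("reference_ranges", class(out))
  out
}

range_row <- function(ranges, metric) {
  r <- ranges[ranges$metric == metric, , drop = FALSE]
  if (nrow(r) != 1) stop("reference range missing for metric: ", metric,
                         call. = FALSE)
  r
}

#' Classify one patient profile
#'
#' Precedence: (1) DG/PL below the count range -> `CLASSIC_DSPD`; (2) DG/PL
#' above the count range -> `ELEVATED_DG`; (3) otherwise mean granule
#' diameter below the diameter range -> `MGSPD`; (4) otherwise `NORMAL`.
#' Values exactly at a bound count as within range. The SPVD flag is set iff
#' TDGV falls below the TDGV lower bound, independently of the primary
#' category. A profile without diameter statistics can still receive the
#' count-based categories but is flagged indeterminate for MGSPD.
#'
#' @param profile One-row data.frame or list with `dg_per_platelet`,
#'   `mean_diameter_nm`, `tdgv_nm3`.
#' @param ranges A `reference_ranges` object covering those metrics.
#' @return List: `category` (factor over the four categories), `spvd`
#'   (logical, NA when TDGV unavailable), `mgspd_indeterminate` (TRUE when
#'   the diameter was unavailable and the count was in range).
#' @export
classify_patient <- function(profile, ranges) {
  cnt <- profile$dg_per_platelet
  dia <- profile$mean_diameter_nm
  tdgv <- profile$tdgv_nm3
  rc <- range_row(ranges, "dg_per_platelet")
  rd <- range_row(ranges, "mean_diameter_nm")
  rt <- range_row(ranges, "tdgv_nm3")
  if (!is.finite(cnt)) stop("dg_per_platelet unavailable", call. = FALSE)
  indeterminate <- FALSE
  if (cnt < rc$lower) {
    cat_lab <- "CLASSIC_DSPD"
  } else if (cnt > rc$upper) {
    cat_lab <- "ELEVATED_DG"
  } else if (is.finite(dia)) {
    cat_lab <- if (dia < rd$lower) "MGSPD" else "NORMAL"
  } else {
    cat_lab <- "NORMAL"
    indeterminate <- TRUE
  }
  spvd <- if (is.finite(tdgv)) tdgv < rt$lower else NA
  list(category = factor(cat_lab, levels = GRANULE_CATEGORIES),
       spvd = spvd, mgspd_indeterminate = indeterminate)
}

#' Classify a cohort and summarise category proportions
#'
#' @param profiles data.frame of patient profiles.
#' @param ranges A `reference_ranges` object.
#' @return List:
#' \describe{
#'   \item{labels}{data.frame `patient_id, category, spvd_flag,
#'     dg_per_platelet, mean_diameter_nm, tdgv_nm3`.}
#'   \item{counts}{named integer vector over the four categories.}
#'   \item{proportions}{list with `pct_normal_count` (share of patients whose
#'     count is not deficient, i.e. everyone except CLASSIC_DSPD, as a
#'     percentage of all patients) and `pct_mgspd_of_normal_count` (MGSPD
#'     share of the normal-count subset). `NA` for an empty cohort.}
#' }
#' @export
classify_cohort <- function(profiles, ranges) {
  n <- nrow(profiles)
  if (is.null(n) || n == 0) {
    counts <- stats::setNames(integer(4), GRANULE_CATEGORIES)
    return(list(labels = data.frame(), counts = counts,
                proportions = list(pct_normal_count = NA_real_,
                                   pct_mgspd_of_normal_count = NA_real_)))
  }
  res <- lapply(seq_len(n), function(i) classify_patient(profiles[i, ], ranges))
  category <- factor(vapply(res, function(r) as.character(r$category),
                            character(1)), levels = GRANULE_CATEGORIES)
  labels <- data.frame(
    patient_id = profiles$patient_id,
    category = category,
    spvd_flag = vapply(res, function(r) r$spvd, logical(1)),
    dg_per_platelet = profiles$dg_per_platelet,
    mean_diameter_nm = profiles$mean_diameter_nm,
    tdgv_nm3 = profiles$tdgv_nm3
  )
  counts <- table(category)
  counts <- stats::setNames(as.integer(counts), names(counts))
  n_normal_count <- n - counts[["CLASSIC_DSPD"]]
  proportions <- list(
    pct_normal_count = 100 * n_normal_count / n,
    pct_mgspd_of_normal_count = if (n_normal_count > 0)
      100 * counts[["MGSPD"]] / n_normal_count else NA_real_
  )
  list(labels = labels, counts = counts, proportions = proportions)
}
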