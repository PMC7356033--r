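test_that("known disks are detected with diameters within one pixel", {
  diams <- c(80, 100, 140, 180, 250)
  sim <- make_sim(list(diams))
  truth <- layout_wholemount(sim, params = render_params(noise_sd = 0),
                             seed = 41)
  f <- render_wholemount(truth, seed = 42)[[1]]
  det <- detect_granules(f$image, f$mask)
  expect_identical(nrow(det), 5L)
  expect_true(all(abs(sort(det$equivalent_diameter_nm) - sort(diams)) <= 2))
  expect_true(all(det$circularity > 0.9))
})

test_that("a blank platelet yields zero detections and empty mask is legal", {
  sim <- make_sim(list(numeric(0)))
  truth <- layout_wholemount(sim, seed = 43)
  f <- render_wholemount(truth, seed = 44)[[1]]
  expect_identical(nrow(detect_granules(f$image, f$mask)), 0L)
  expect_identical(
    nrow(detect_granules(f$image, matrix(FALSE, nrow(f$image), ncol(f$image)))),
    0L)
})

test_that("touching disks are split by the watershed when enabled", {
  img <- matrix(0.55, 300, 300)
  mask <- matrix(TRUE, 300, 300)
  r <- 35
  # overlap of 20% of the radius: centre distance 1.8 r
  img <- granulovol:::paint_disk(img, 150, 150 - 0.9 * r, r, 0.06)
  img <- granulovol:::paint_disk(img, 150, 150 + 0.9 * r, r, 0.06)
  det_split <- detect_granules(img, mask,
                               detection_config(split_touching = TRUE))
  expect_identical(nrow(det_split), 2L)
  det_merged <- detect_granules(img, mask,
                                detection_config(split_touching = FALSE))
  expect_identical(nrow(det_merged), 1L)
})

test_that("configuration is validated", {
  expect_error(detection_config(min_diameter_nm = 400, max_diameter_nm = 60),
               "min_diameter_nm")
  expect_error(detection_config(min_circularity = 1.4), "min_circularity")
  expect_error(detection_config(absolute_threshold = 1.5),
               "intensity range")
  img <- matrix(0.5, 10, 10)
  expect_error(detect_granules(img, matrix(TRUE, 5, 5)), "dimensions")
})

test_that("detection recall and precision are 1 on clean renders", {
  set.seed(45)
  diam_sets <- replicate(12, runif(sample(2:8, 1), 80, 250), simplify = FALSE)
  sim <- make_sim(diam_sets)
  truth <- layout_wholemount(sim, params = render_params(noise_sd = 0),
                             seed = 46)
  frames <- render_wholemount(truth, seed = 47)
  for (f in frames) {
    det <- detect_granules(f$image, f$mask)
    expect_identical(nrow(det), nrow(f$truth))   # recall and precision
    if (nrow(det)) {
      # each detection sits on a truth centre
      for (k in seq_len(nrow(det))) {
        d2 <- (f$truth$row_px - det$row_px[k])^2 +
          (f$truth$col_px - det$col_px[k])^2
        expect_lt(min(d2), 4)
      }
    }
  }
})

test_that("diameter bias is below one rendered pixel across 80-250 nm", {
  sizes <- seq(80, 250, by = 10)
  sim <- make_sim(rep(list(sizes), 3))
  truth <- layout_wholemount(sim, params = render_params(noise_sd = 0),
                             seed = 48)
  frames <- render_wholemount(truth, seed = 49)
  err <- c()
  for (f in frames) {
    det <- detect_granules(f$image, f$mask)
    expect_identical(nrow(det), length(sizes))
    err <- c(err, sort(det$equivalent_diameter_nm) - sort(sizes))
  }
  expect_lt(abs(mean(err)), 2)       # bias < 1 px at 2 nm/px
  expect_lt(max(abs(err)), 2.5)      # worst single-granule discretisation
})

test_that("measurements are invariant under translation and 90-degree rotation", {
  sim <- make_sim(list(c(90, 130, 170, 210)))
  truth <- layout_wholemount(sim, params = render_params(noise_sd = 0),
                             seed = 50)
  f <- render_wholemount(truth, seed = 51)[[1]]
  base <- sort(detect_granules(f$image, f$mask)$area_px)

  rot90 <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  det_rot <- detect_granules(rot90(f$image), rot90(f$mask))
  expect_identical(sort(det_rot$area_px), base)

  pad <- function(m, fill) {
    out <- matrix(fill, nrow(m) + 17, ncol(m) + 9)
    out[18:(nrow(m) + 17), 10:(ncol(m) + 9)] <- m
    out
  }
  det_tr <- detect_granules(pad(f$image, 0.88), pad(f$mask, FALSE))
  expect_identical(sort(det_tr$area_px), base)
})

test_that("granule size does not depend on platelet granule count", {
  # one shared diameter distribution: low-count and high-count platelets
  # must show no systematic size difference
  spec <- calibrated_cohort_spec("control", 40)
  sim <- simulate_cohort(spec, seed = 52)
  cnt <- sim$platelets$n_granules[
    match(paste(sim$granules$patient_id, sim$granules$platelet_id),
          paste(sim$platelets$patient_id, sim$platelets$platelet_id))]
  lo <- sim$granules$diameter_nm[cnt >= 1 & cnt <= 4]
  hi <- sim$granules$diameter_nm[cnt > 10]
  expect_gt(length(lo), 50)
  expect_gt(length(hi), 50)
  expect_gt(t.test(lo, hi)$p.value, 0.01)
})

test_that("enumeration divides granules by included platelets only", {
  records <- data.frame(
    patient_id = 1,
    platelet_id = 1:5,
    included = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    n_granules = c(5L, 3L, 4L, 4L, 9L)
  )
  enum <- enumerate_platelets(records)
  expect_equal(enum$dg_per_platelet, 16 / 4)
  expect_equal(enum$n_excluded, 1)
  records$included <- FALSE
  expect_error(enumerate_platelets(records), "zero included")
})

test_that("DG/PL equals total granules over 100 platelets", {
  counts <- rep(c(5L, 4L), 50)
  counts[1] <- counts[1] + 14L   # total 464
  records <- data.frame(patient_id = 1, platelet_id = 1:100,
                        included = TRUE, n_granules = counts)
  expect_equal(enumerate_platelets(records)$dg_per_platelet, 4.64)
})

test_that("occluded platelets are auto-excluded and contribute no granules", {
  spec <- calibrated_cohort_spec("control", 1, platelets_per_patient = 30)
  sim <- simulate_cohort(spec, seed = 53)
  truth <- layout_wholemount(sim, artifact_rate = 0.3, seed = 54)
  meas <- measure_wholemount_cohort(truth, seed = 55)
  expect_identical(meas$records$included, !truth$platelets$occluded)
  excluded <- meas$records$platelet_id[!meas$records$included]
  expect_false(any(meas$measurements$platelet_id %in% excluded))
  expect_true(all(meas$records$exclusion_reason[!meas$records$included] ==
                    "grid_bar_occlusion"))
})

test_that("sizing selection honours the minimum-count rule and seed", {
  records <- data.frame(
    patient_id = 1, platelet_id = 1:100, included = TRUE,
    n_granules = rep(c(2L, 6L), 50)
  )
  sel1 <- select_platelets_for_sizing(records, min_dg = 4, target_n = 12,
                                      seed = 7)
  expect_identical(sum(sel1$sized), 12L)
  expect_true(all(sel1$n_granules[sel1$sized] >= 4))
  sel2 <- select_platelets_for_sizing(records, min_dg = 4, target_n = 12,
                                      seed = 7)
  expect_identical(sel1$sized, sel2$sized)
  # not enough qualifying platelets: take all, with a warning
  few <- records[records$n_granules >= 4, ][1:5, ]
  expect_warning(sel3 <- select_platelets_for_sizing(few, target_n = 12,
                                                     seed = 8),
                 "fewer than")
  expect_identical(sum(sel3$sized), 5L)
  # none qualifying: empty selection
  none <- records[records$n_granules < 4, ]
  expect_warning(sel4 <- select_platelets_for_sizing(none, target_n = 12,
                                                     seed = 9))
  expect_identical(sum(sel4$sized), 0L)
})

test_that("fresh and shipped control samples do not differ", {
  fresh_spec <- cohort_spec("fresh", 35, 100, 40, 0.110, 133.6, 0.371)
  ship_spec <- cohort_spec("shipped", 35, 100, 40, 0.1075, 133.6, 0.371)
  fresh <- profile_cohort_from_truth(simulate_cohort(fresh_spec, seed = 56))
  ship <- profile_cohort_from_truth(simulate_cohort(ship_spec, seed = 57))
  p <- wilcox.test(fresh$dg_per_platelet, ship$dg_per_platelet,
                   exact = FALSE)$p.value
  expect_gt(p, 0.05)
})
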