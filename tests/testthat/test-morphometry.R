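test_that("sphere volume follows (pi/6) d^3", {
  expect_equal(sphere_volume(143.14), 1.536e6, tolerance = 1e-3)
  expect_equal(sphere_volume(123.36), 0.983e6, tolerance = 1e-3)
  expect_identical(sphere_volume(0), 0)
  expect_error(sphere_volume(-1), ">= 0")
  # cubing law: doubling the diameter multiplies the volume by exactly 8
  d <- c(60, 100, 143.14, 200)
  expect_equal(sphere_volume(2 * d), 8 * sphere_volume(d))
  # strictly increasing
  expect_true(all(diff(sphere_volume(seq(10, 400, by = 5))) > 0))
})

test_that("patient profile computes MDGV and the TDGV product rule", {
  records <- data.frame(patient_id = 1, platelet_id = 1:10, included = TRUE,
                        n_granules = 4L, sized = TRUE)
  meas <- data.frame(platelet_id = rep(1:10, each = 4),
                     equivalent_diameter_nm = 100)
  p <- profile_patient(records, meas)
  expect_equal(p$dg_per_platelet, 4)
  expect_equal(p$mdgv_nm3, 5.236e5, tolerance = 1e-3)
  expect_equal(p$tdgv_nm3, 2.094e6, tolerance = 1e-3)
  expect_equal(p$fraction_small, 1)
})

test_that("a single sized granule leaves the SE unavailable", {
  records <- data.frame(patient_id = 1, platelet_id = 1, included = TRUE,
                        n_granules = 1L, sized = TRUE)
  meas <- data.frame(platelet_id = 1, equivalent_diameter_nm = 137)
  p <- profile_patient(records, meas)
  expect_equal(p$mean_diameter_nm, 137)
  expect_true(is.na(p$se_diameter))
})

test_that("an empty sized subset yields NA diameter fields, not zeros", {
  records <- data.frame(patient_id = 1, platelet_id = 1:3, included = TRUE,
                        n_granules = 2L, sized = FALSE)
  meas <- data.frame(platelet_id = integer(),
                     equivalent_diameter_nm = numeric())
  p <- profile_patient(records, meas)
  expect_true(is.na(p$mean_diameter_nm))
  expect_true(is.na(p$mdgv_nm3))
  expect_true(is.na(p$tdgv_nm3))
  expect_equal(p$dg_per_platelet, 2)
})

test_that("mixed diameters show the Jensen gap over the volume of the mean", {
  records <- data.frame(patient_id = 1, platelet_id = 1, included = TRUE,
                        n_granules = 2L, sized = TRUE)
  meas <- data.frame(platelet_id = c(1, 1),
                     equivalent_diameter_nm = c(100, 180))
  p <- profile_patient(records, meas)
  # brute-force average of the two volumes
  expect_equal(p$mdgv_nm3, mean((pi / 6) * c(100, 180)^3))
  expect_equal(p$mdgv_nm3, 1.789e6, tolerance = 1e-3)
  expect_gt(p$mdgv_nm3, sphere_volume(mean(c(100, 180))))
  expect_equal(sphere_volume(140), 1.437e6, tolerance = 1e-3)
})

test_that("profiles match a brute-force recomputation from the raw tables", {
  spec <- calibrated_cohort_spec("control", 6, platelets_per_patient = 40)
  sim <- simulate_cohort(spec, seed = 61)
  prof <- profile_cohort_from_truth(sim, seed = 62)
  # naive per-patient recomputation straight from the truth tables,
  # re-running only the seeded selection
  records <- data.frame(patient_id = sim$platelets$patient_id,
                        platelet_id = sim$platelets$platelet_id,
                        included = TRUE, exclusion_reason = "none",
                        n_granules = sim$platelets$n_granules)
  sel <- select_platelets_for_sizing(records, min_dg = 4, target_n = 12,
                                     seed = 62)
  for (pid in unique(sim$platelets$patient_id)) {
    plt <- sim$platelets[sim$platelets$patient_id == pid, ]
    dgpl <- sum(plt$n_granules) / nrow(plt)
    sized_ids <- sel$platelet_id[sel$patient_id == pid & sel$sized]
    d <- sim$granules$diameter_nm[sim$granules$patient_id == pid &
                                    sim$granules$platelet_id %in% sized_ids]
    mdgv <- 0
    for (x in d) mdgv <- mdgv + (pi / 6) * x^3
    mdgv <- mdgv / length(d)
    row <- prof[prof$patient_id == pid, ]
    expect_equal(row$dg_per_platelet, dgpl)
    expect_equal(row$mdgv_nm3, mdgv)
    expect_equal(row$tdgv_nm3, mdgv * dgpl)
    expect_equal(row$mean_diameter_nm, mean(d))
  }
})

test_that("the TDGV product identity holds exactly for every profile", {
  spec <- calibrated_cohort_spec("mgspd", 15)
  prof <- profile_cohort_from_truth(simulate_cohort(spec, seed = 63),
                                    seed = 64)
  expect_equal(prof$tdgv_nm3, prof$mdgv_nm3 * prof$dg_per_platelet)
})

test_that("size distribution reports fixed-cut fractions per group", {
  all_small <- rep(sphere_volume(100), 20)   # 0.524e6 < 1.5e6
  all_big <- rep(sphere_volume(180), 20)     # 3.05e6 > 1.5e6
  sd1 <- size_distribution(all_small)
  expect_equal(unname(sd1$fraction_small), 1)
  sd2 <- size_distribution(all_big)
  expect_equal(unname(sd2$fraction_small), 0)
  both <- size_distribution(c(all_small, all_big),
                            group = rep(c("s", "b"), each = 20))
  expect_equal(unname(both$fraction_small["s"]), 1)
  expect_equal(unname(both$fraction_small["b"]), 0)
  expect_equal(sum(both$histogram$count), 40)
})

test_that("the small-granule fraction matches the lognormal closed form", {
  spec <- calibrated_cohort_spec("control", 30)
  sim <- simulate_cohort(spec, seed = 65)
  v <- sphere_volume(sim$granules$diameter_nm)
  d_cut <- (6 * 1.5e6 / pi)^(1 / 3)
  expected <- plnorm(d_cut, log(133.6), 0.371)
  emp <- mean(v < 1.5e6)
  se <- sqrt(expected * (1 - expected) / length(v))
  expect_lt(abs(emp - expected), 3 * se + 1e-6)
})
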