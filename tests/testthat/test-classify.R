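test_that("reference ranges are mean +/- 3 SE", {
  ref <- paper_control_reference()
  cnt <- ref[ref$metric == "dg_per_platelet", ]
  expect_equal(cnt$lower, 4.31, tolerance = 1e-9)
  expect_equal(cnt$upper, 4.97, tolerance = 1e-9)
  dia <- ref[ref$metric == "mean_diameter_nm", ]
  expect_equal(dia$lower, 138.46, tolerance = 1e-9)
  # stored bounds always reproduce mean +/- 3 se
  expect_equal(ref$lower, ref$mean - 3 * ref$se)
  expect_equal(ref$upper, ref$mean + 3 * ref$se)
})

test_that("reference construction rejects degenerate controls", {
  one <- data.frame(patient_id = 1, dg_per_platelet = 4.5,
                    mean_diameter_nm = 140, tdgv_nm3 = 1e7)
  expect_error(build_reference(one), "at least 2")
  two_same <- rbind(one, one)
  expect_error(build_reference(two_same), "zero spread")
})

test_that("build_reference computes SE-based bounds from profiles", {
  set.seed(71)
  ctrl <- data.frame(patient_id = 1:30,
                     dg_per_platelet = rnorm(30, 4.6, 0.7),
                     mean_diameter_nm = rnorm(30, 143, 5),
                     tdgv_nm3 = rnorm(30, 1.08e7, 2e6))
  ref <- build_reference(ctrl)
  x <- ctrl$dg_per_platelet
  r <- ref[ref$metric == "dg_per_platelet", ]
  expect_equal(r$se, sd(x) / sqrt(30))
  expect_equal(r$lower, mean(x) - 3 * sd(x) / sqrt(30))
  # SD-based alternative widens the band
  ref_sd <- build_reference(ctrl, spread = "sd")
  expect_lt(ref_sd[1, "lower"], ref[1, "lower"])
})

test_that("published group-mean profiles classify into their categories", {
  ref <- paper_control_reference()
  dspd <- classify_patient(list(dg_per_platelet = 2.25,
                                mean_diameter_nm = 151.9,
                                tdgv_nm3 = 3.88e6), ref)
  expect_equal(as.character(dspd$category), "CLASSIC_DSPD")
  expect_true(dspd$spvd)

  mg <- classify_patient(list(dg_per_platelet = 4.31,
                              mean_diameter_nm = 123.36,
                              tdgv_nm3 = 5.99e6), ref)
  expect_equal(as.character(mg$category), "MGSPD")
  expect_true(mg$spvd)

  elev <- classify_patient(list(dg_per_platelet = 6.64,
                                mean_diameter_nm = 141.76,
                                tdgv_nm3 = 14.23e6), ref)
  expect_equal(as.character(elev$category), "ELEVATED_DG")
  expect_false(elev$spvd)

  norm <- classify_patient(list(dg_per_platelet = 4.55,
                                mean_diameter_nm = 150.0,
                                tdgv_nm3 = 11.59e6), ref)
  expect_equal(as.character(norm$category), "NORMAL")
  expect_false(norm$spvd)
})

test_that("boundary values count as within range", {
  ref <- reference_from_summary(
    means = c(dg_per_platelet = 5, mean_diameter_nm = 140, tdgv_nm3 = 1e7),
    ses = c(dg_per_platelet = 0.5, mean_diameter_nm = 2, tdgv_nm3 = 5e5),
    n = 10)
  at_lower <- classify_patient(list(dg_per_platelet = 3.5,
                                    mean_diameter_nm = 140,
                                    tdgv_nm3 = 1e7), ref)
  expect_equal(as.character(at_lower$category), "NORMAL")
  at_dia <- classify_patient(list(dg_per_platelet = 5,
                                  mean_diameter_nm = 134,
                                  tdgv_nm3 = 1e7), ref)
  expect_equal(as.character(at_dia$category), "NORMAL")
  expect_false(at_dia$spvd)
})

test_that("count deficiency takes precedence over small diameters", {
  ref <- paper_control_reference()
  both <- classify_patient(list(dg_per_platelet = 2.0,
                                mean_diameter_nm = 120,
                                tdgv_nm3 = 3e6), ref)
  expect_equal(as.character(both$category), "CLASSIC_DSPD")
})

test_that("a missing diameter limits classification to count categories", {
  ref <- paper_control_reference()
  res <- classify_patient(list(dg_per_platelet = 4.6,
                               mean_diameter_nm = NA_real_,
                               tdgv_nm3 = NA_real_), ref)
  expect_equal(as.character(res$category), "NORMAL")
  expect_true(res$mgspd_indeterminate)
  expect_true(is.na(res$spvd))
  low <- classify_patient(list(dg_per_platelet = 2.0,
                               mean_diameter_nm = NA_real_,
                               tdgv_nm3 = NA_real_), ref)
  expect_equal(as.character(low$category), "CLASSIC_DSPD")
  expect_false(low$mgspd_indeterminate)
})

test_that("lowering the diameter can only move a label toward MGSPD", {
  ref <- paper_control_reference()
  labels <- vapply(seq(160, 110, by = -1), function(d) {
    as.character(classify_patient(list(dg_per_platelet = 4.6,
                                       mean_diameter_nm = d,
                                       tdgv_nm3 = 1.0e7), ref)$category)
  }, character(1))
  expect_true(all(labels %in% c("NORMAL", "MGSPD")))
  first_mg <- match("MGSPD", labels)
  expect_false(is.na(first_mg))
  expect_true(all(labels[first_mg:length(labels)] == "MGSPD"))
})

test_that("classification is total and order-independent", {
  set.seed(72)
  profs <- data.frame(
    patient_id = 1:40,
    dg_per_platelet = runif(40, 1.5, 7.5),
    mean_diameter_nm = runif(40, 110, 160),
    tdgv_nm3 = runif(40, 3e6, 1.5e7)
  )
  ref <- paper_control_reference()
  a <- classify_cohort(profs, ref)
  expect_false(any(is.na(a$labels$category)))
  perm <- sample(40)
  b <- classify_cohort(profs[perm, ], ref)
  expect_identical(as.character(a$labels$category)[perm],
                   as.character(b$labels$category))
})

test_that("cohort proportions reproduce the published arithmetic", {
  # 1080 subjects: 499 count-deficient, and of the 581 with normal counts
  # 165 microgranular, 328 normal, 88 elevated
  profs <- data.frame(
    patient_id = seq_len(1080),
    dg_per_platelet = c(rep(2.2, 499), rep(4.5, 165 + 328), rep(6.8, 88)),
    mean_diameter_nm = c(rep(150, 499), rep(120, 165), rep(150, 328),
                         rep(142, 88)),
    tdgv_nm3 = 1e7
  )
  cls <- classify_cohort(profs, paper_control_reference())
  expect_identical(unname(cls$counts["CLASSIC_DSPD"]), 499L)
  expect_identical(unname(cls$counts["MGSPD"]), 165L)
  expect_equal(round(cls$proportions$pct_normal_count, 1), 53.8)
  expect_equal(round(cls$proportions$pct_mgspd_of_normal_count, 1), 28.4)
})

test_that("an empty cohort yields zero counts and undefined proportions", {
  cls <- classify_cohort(data.frame(), paper_control_reference())
  expect_true(all(cls$counts == 0))
  expect_true(is.na(cls$proportions$pct_normal_count))
})

test_that("strongly separated groups recover their generating labels", {
  ctrl <- profile_cohort_from_truth(
    simulate_cohort(calibrated_cohort_spec("control", 49), seed = 73),
    seed = 74)
  ref <- build_reference(ctrl)
  for (g in c("dspd", "elevated")) {
    prof <- suppressWarnings(profile_cohort_from_truth(
      simulate_cohort(calibrated_cohort_spec(g, 50), seed = 75), seed = 76))
    cls <- classify_cohort(prof, ref)
    want <- if (g == "dspd") "CLASSIC_DSPD" else "ELEVATED_DG"
    expect_gte(mean(cls$labels$category == want), 0.9)
  }
})
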