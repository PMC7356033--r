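single_sphere_scene <- function(angles = c(0, 20, 40)) {
  tilt_scene(data.frame(x_nm = 300, y_nm = 300, z_nm = 450, r_nm = 80),
             slab_thickness_nm = 900, tilt_angles_deg = angles)
}

stacked_pair_scene <- function(angles = c(0, 15, 30, 45)) {
  tilt_scene(data.frame(x_nm = c(500, 500), y_nm = c(500, 500),
                        z_nm = c(200, 700), r_nm = c(75, 75)),
             slab_thickness_nm = 900, tilt_angles_deg = angles)
}

test_that("scene validation enforces slab fit and ordered angles", {
  expect_error(
    tilt_scene(data.frame(x_nm = 0, y_nm = 0, z_nm = 40, r_nm = 75),
               slab_thickness_nm = 900),
    "slab")
  expect_error(
    tilt_scene(data.frame(x_nm = 0, y_nm = 0, z_nm = 450, r_nm = 75),
               tilt_angles_deg = c(0, 30, 30)),
    "increasing")
})

test_that("a single sphere projects to one unchanged disk at every angle", {
  series <- render_tilt_series(single_sphere_scene())
  prof <- circularity_profile(series)
  expect_identical(nrow(prof), 3L)           # one blob per angle
  expect_true(all(prof$aspect_ratio < 1.05))
  d <- prof$equivalent_diameter_nm
  expect_lt(diff(range(d)) / mean(d), 0.02)  # diameter varies < 2%
  expect_lt(abs(mean(d) - 160) / 160, 0.02)
  v <- analyze_tilt_series(series)
  expect_identical(as.character(v$verdict), "single_sphere")
})

test_that("zero-tilt projection equals a depth-free brute-force projection", {
  scene <- stacked_pair_scene()
  series <- render_tilt_series(scene)
  f0 <- series$frames[[which(series$angles_deg == 0)]]
  # independent oracle: full-grid pixel-centre test per sphere, ignoring z
  h <- nrow(f0); w <- ncol(f0)
  npp <- scene$nm_per_px
  oracle <- matrix(0, h, w)
  for (i in seq_len(nrow(scene$spheres))) {
    row0 <- (scene$spheres$y_nm[i] - scene$origin_nm[2]) / npp
    col0 <- (scene$spheres$x_nm[i] - scene$origin_nm[1]) / npp
    r_px <- scene$spheres$r_nm[i] / npp
    dr2 <- ((seq_len(h) - 1) - row0)^2
    dc2 <- ((seq_len(w) - 1) - col0)^2
    oracle <- oracle + 0.4 * (outer(dr2, dc2, "+") <= r_px^2)
  }
  oracle <- pmin(oracle, 1)
  expect_equal(f0, oracle)
})

test_that("superimposed spheres split at the predicted tilt separation", {
  series <- render_tilt_series(stacked_pair_scene())
  prof <- circularity_profile(series)
  # perfectly stacked pair merges into one circular blob at zero tilt
  p0 <- prof[prof$angle_deg == 0, ]
  expect_identical(nrow(p0), 1L)
  expect_lt(p0$aspect_ratio, 1.05)
  # at 15 degrees the shift (129 nm) is below 2r: still one, now elongated
  p15 <- prof[prof$angle_deg == 15, ]
  expect_identical(nrow(p15), 1L)
  expect_gt(p15$aspect_ratio, 1.15)
  # at 30 degrees the centres separate by dz*sin(30) = 250 nm > 2r
  p30 <- prof[prof$angle_deg == 30, ]
  expect_identical(nrow(p30), 2L)
  sep_nm <- abs(diff(p30$row_px)) * series$nm_per_px
  expect_lt(abs(sep_nm - 250), 10)
  expect_true(all(abs(p30$equivalent_diameter_nm - 150) < 5))
  v <- analyze_tilt_series(series)
  expect_identical(as.character(v$verdict), "superimposed_spheres")
})

test_that("laterally offset overlapping disks read as one elongated blob", {
  scene <- tilt_scene(data.frame(x_nm = c(500, 500), y_nm = c(450, 550),
                                 z_nm = c(200, 700), r_nm = c(75, 75)),
                      slab_thickness_nm = 900,
                      tilt_angles_deg = c(0, 15, 30, 45))
  series <- render_tilt_series(scene)
  prof <- circularity_profile(series)
  p0 <- prof[prof$angle_deg == 0, ]
  expect_identical(nrow(p0), 1L)
  expect_gt(p0$aspect_ratio, 1.15)   # union of two offset disks
  v <- analyze_tilt_series(series)
  expect_identical(as.character(v$verdict), "superimposed_spheres")
})

test_that("a prolate ellipsoid stays elongated and never splits", {
  scene <- tilt_scene(
    data.frame(x_nm = numeric(), y_nm = numeric(), z_nm = numeric(),
               r_nm = numeric()),
    ellipsoids = data.frame(x_nm = 400, y_nm = 400, z_nm = 450,
                            a_nm = 80, b_nm = 160, c_nm = 80),
    slab_thickness_nm = 900, tilt_angles_deg = c(0, 15, 30, 45))
  series <- render_tilt_series(scene)
  v <- analyze_tilt_series(series)
  expect_identical(as.character(v$verdict), "non_spherical")
  expect_identical(v$max_blobs, 1L)
  expect_gt(v$max_aspect, 1.15)
})

test_that("verdicts match generator truth across scene configurations", {
  # dz * sin(max angle) > 2r for the pairs; singles confirmed single
  configs <- list(
    list(z = c(150, 750), r = 70, want = "superimposed_spheres"),
    list(z = c(250, 650), r = 60, want = "superimposed_spheres"),
    list(z = 450, r = 100, want = "single_sphere"),
    list(z = 300, r = 55, want = "single_sphere")
  )
  for (cf in configs) {
    sp <- data.frame(x_nm = rep(600, length(cf$z)),
                     y_nm = rep(600, length(cf$z)),
                     z_nm = cf$z, r_nm = cf$r)
    series <- render_tilt_series(
      tilt_scene(sp, slab_thickness_nm = 900,
                 tilt_angles_deg = c(0, 15, 30, 45, 60)))
    v <- analyze_tilt_series(series)
    expect_identical(as.character(v$verdict), cf$want)
  }
})

test_that("tilt-series input errors are reported", {
  series <- render_tilt_series(single_sphere_scene())
  expect_error(analyze_tilt_series(
    list(angles_deg = c(0, 10), frames = series$frames[1:2],
         nm_per_px = 2)), "angles")
  broken <- series
  broken$frames[[2]] <- broken$frames[[2]][-1, ]
  expect_error(circularity_profile(broken), "unequal")
  # projection pushed outside an explicit small frame
  sc <- tilt_scene(data.frame(x_nm = 500, y_nm = 500, z_nm = 700, r_nm = 75),
                   slab_thickness_nm = 900,
                   tilt_angles_deg = c(0, 20, 40, 60),
                   frame_nm = c(700, 700))
  expect_error(render_tilt_series(sc), "outside the .* frame")
})

test_that("an empty scene yields empty frames and an empty profile", {
  sc <- tilt_scene(data.frame(x_nm = numeric(), y_nm = numeric(),
                              z_nm = numeric(), r_nm = numeric()),
                   tilt_angles_deg = c(0, 20, 40))
  series <- render_tilt_series(sc)
  expect_identical(nrow(circularity_profile(series)), 0L)
})
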