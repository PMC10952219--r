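make_small_field <- function(spec = locus_spec("elliptic", 0.6, 0.2,
                                               steady_offset = c(0.1, 0)),
                             radii = c(2e-3, 5e-3),
                             az = c(0, pi / 3, pi),
                             n_samples = 36) {
  make_disc_field(spec, radii, az, n_samples = n_samples)
}

test_that("CSV field files round-trip losslessly", {
  fld <- make_small_field()
  path <- withr::local_tempfile(fileext = ".csv")
  write_field(fld, path)
  back <- read_field(path)
  expect_equal(back$points$x, fld$points$x, tolerance = 1e-12)
  for (i in seq_along(fld$series)) {
    expect_equal(back$series[[i]]$vectors, fld$series[[i]]$vectors,
                 tolerance = 1e-12)
    expect_equal(back$series[[i]]$times, fld$series[[i]]$times,
                 tolerance = 1e-12)
    expect_equal(back$series[[i]]$period, fld$series[[i]]$period,
                 tolerance = 1e-9)
  }
})

test_that("multi-cycle inputs are truncated to the final cycle", {
  s <- make_locus(locus_spec("elliptic", 1, 0.5), n_samples = 24,
                  period = 0.4)
  n <- length(s$times)
  df <- data.frame(
    point_id = 1, x_m = 5e-3, y_m = 0,
    time_s = c(s$times, s$times + 0.4, s$times + 0.8),
    tau_x_pa = rep(s$vectors[, 1], 3),
    tau_y_pa = rep(s$vectors[, 2], 3),
    tau_z_pa = rep(s$vectors[, 3], 3)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  fld <- read_field(path, period = 0.4)
  expect_equal(length(fld$series[[1]]$times), n)
  expect_equal(min(fld$series[[1]]$times), 0.8, tolerance = 1e-9)
  expect_equal(fld$series[[1]]$vectors, s$vectors, tolerance = 1e-12)
  expect_match(paste(attr(fld, "log"), collapse = " "), "truncated")
})

test_that("malformed field files raise explicit format errors", {
  fld <- make_small_field()
  path <- withr::local_tempfile(fileext = ".csv")
  write_field(fld, path)
  df <- utils::read.csv(path)
  df$tau_z_pa <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE)
  expect_error(read_field(path2), "tau_z_pa")

  # ragged time axes across points
  df3 <- utils::read.csv(path)
  df3 <- df3[!(df3$point_id == 2 & df3$time_s == max(df3$time_s)), ]
  path3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df3, path3, row.names = FALSE)
  expect_error(read_field(path3), "point 2")

  expect_error(read_field(path, format = "vtk-series"), "not supported")
})

test_that("radial profiles of symmetric fields collapse to the single-radius values", {
  fld <- make_disc_field(locus_spec("circular", 0.3, 0.3),
                         mesh_radii = c(2e-3, 5e-3, 8e-3),
                         mesh_azimuths = seq(0, 2 * pi, length.out = 7)[-7],
                         n_samples = 90)
  prof <- radial_profile(fld, n_bins = 10, r_max = 10e-3, shape = FALSE)
  occ <- prof[prof$n > 0, ]
  expect_equal(nrow(occ), 3)
  expect_true(all(abs(occ$osi_mean - 0.5) < 1e-9))
  expect_true(all(occ$osi_sd < 1e-6))
  expect_true(all(occ$tawss_sd < 1e-6 * occ$tawss_mean))
  # empty bins are reported, not interpolated
  expect_true(all(is.na(prof$osi_mean[prof$n == 0])))
})

test_that("annular (masked-centre) fields leave inner bins empty", {
  fld <- make_disc_field(scenario_profile("cc_like"),
                         mesh_radii = seq(4.2e-3, 10.8e-3, length.out = 6),
                         mesh_azimuths = c(0, pi),
                         n_samples = 60)
  prof <- radial_profile(fld, n_bins = 11, r_max = 11e-3, shape = FALSE)
  inner <- prof[prof$r_hi <= 4e-3, ]
  expect_true(all(inner$n == 0))
  expect_true(any(prof$n > 0))
})

test_that("a single-point field occupies exactly one bin", {
  fld <- make_disc_field(locus_spec("steady", steady_offset = c(0.2, 0.1)),
                         mesh_radii = 5e-3, mesh_azimuths = 0,
                         n_samples = 36)
  prof <- radial_profile(fld, n_bins = 10, r_max = 10e-3, shape = FALSE)
  expect_equal(sum(prof$n), 1L)
  b <- which(prof$n == 1)
  expect_lt(abs(prof$tawss_mean[b] - tawss(fld$series[[1]])), 1e-12)
})

test_that("metric maps expose symmetry and symmetry breaking", {
  radii <- c(3e-3, 6e-3)
  az <- seq(0, 2 * pi, length.out = 9)[-9]
  flat <- make_disc_field(locus_spec("circular", 0.5, 0.5), radii, az,
                          n_samples = 90)
  maps <- metric_maps(flat, shape = FALSE)
  for (r in radii) {
    v <- maps$tawss[maps$r == r]
    expect_lt(max(v) - min(v), 1e-9)
  }
  tilted <- make_tilted_field(locus_spec("circular", 0.5, 0.5), radii, az,
                              modulation_depth = 0.5,
                              modulation_phase = az[3],
                              n_samples = 90)
  tmaps <- metric_maps(tilted, shape = FALSE)
  ex <- field_extrema(tmaps, "tawss")
  expect_equal(ex$max$theta[1], az[3])
  expect_lt(max(tmaps$osi) - min(tmaps$osi), 1e-12)
})

test_that("the pipeline runs end to end on the bundled scenarios", {
  out <- withr::local_tempdir()
  res <- run_pipeline(list(
    well = list(label = "control", well_radius_mm = 11.05,
                mean_depth_mm = 2),
    field = list(scenario = "control_like", n_radii = 10, n_azimuths = 4,
                 n_samples = 90),
    profile = list(n_bins = 10)
  ), out_dir = out, seed = 1)
  expect_equal(res$characterization$Re, 2466)
  expect_equal(res$characterization$E, 0.45)
  prof <- res$profile
  occ <- prof[prof$n > 0, ]
  # multidirectional centre: OSI at the 0.5 ceiling, SI near 1
  expect_gt(occ$osi_mean[1], 0.48)
  expect_gt(occ$si_mean[1], 0.99)
  # shape index declines from centre to edge
  expect_lt(occ$si_mean[nrow(occ)], 0.35)
  expect_true(all(diff(occ$si_mean) < 1e-9))
  expect_true(file.exists(file.path(out, "profile.csv")))
  expect_true(file.exists(file.path(out, "maps.csv")))
  expect_true(file.exists(file.path(out, "characterization.csv")))

  # determinism: identical config and seed give identical numbers
  res2 <- run_pipeline(list(
    field = list(scenario = "control_like", n_radii = 10, n_azimuths = 4,
                 n_samples = 90),
    profile = list(n_bins = 10)
  ), seed = 1)
  expect_equal(res2$profile, res$profile)
})

test_that("a suspended-cylinder-like scenario keeps CFI near 2/pi under the cylinder", {
  res <- run_pipeline(list(
    field = list(scenario = "sc_like", n_radii = 8, n_azimuths = 4,
                 n_samples = 120, r_max_mm = 10.5),
    profile = list(n_bins = 8)
  ), seed = 1)
  under <- res$maps[res$maps$r <= 8.5e-3, ]
  expect_true(all(abs(under$cfi - 2 / pi) < 0.01))
  expect_true(all(abs(under$osi - 0.5) < 0.02))
})
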