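circular_series <- function(amp = 1, n = 360) {
  make_locus(locus_spec("circular", amp, amp), n_samples = n)
}

test_that("TAWSS matches hand values for constant-magnitude and steady flows", {
  expect_equal(tawss(circular_series()), 1, tolerance = 1e-12)
  s345 <- steady_series(c(0.3, 0.4, 0))
  expect_equal(tawss(s345), 0.5, tolerance = 1e-12)
  # uniaxial sinusoid: cycle-mean of |sin| = 2/pi
  un <- make_locus(locus_spec("uniaxial_oscillatory", 1), n_samples = 360)
  expect_equal(tawss(un), 2 / pi, tolerance = 1e-3)
})

test_that("MagMeanWSS is the magnitude of the cycle-mean vector", {
  expect_lt(mag_mean_wss(circular_series()), 1e-12)
  expect_equal(mag_mean_wss(steady_series(c(0.3, 0.4, 0))), 0.5,
               tolerance = 1e-12)
  un <- make_locus(locus_spec("uniaxial_oscillatory", 1), n_samples = 360)
  expect_lt(mag_mean_wss(un), 1e-12)
})

test_that("OSI spans its analytic range and is undefined for a zero series", {
  expect_equal(osi(circular_series()), 0.5, tolerance = 1e-12)
  expect_equal(osi(steady_series(c(0.3, 0.4, 0))), 0, tolerance = 1e-12)
  un <- make_locus(locus_spec("uniaxial_oscillatory", 1), n_samples = 360)
  expect_equal(osi(un), 0.5, tolerance = 1e-12)
  zero <- steady_series(c(0, 0, 0))
  expect_error(osi(zero), class = "wellshear_zero_tawss")
})

test_that("transWSS vanishes for steady flow and needs a mean direction", {
  expect_lt(transwss(steady_series(c(0.3, 0.4, 0))), 1e-12)
  expect_error(transwss(circular_series()),
               class = "wellshear_degenerate_reference")
  # circular locus with a shrinking steady offset: transWSS/TAWSS -> 2/pi
  ratio <- vapply(c(1e-1, 1e-2, 1e-3), function(off) {
    s <- make_locus(locus_spec("circular", 1, 1,
                               steady_offset = c(off, 0)), n_samples = 360)
    transwss(s) / tawss(s)
  }, numeric(1))
  expect_lt(abs(ratio[3] - 2 / pi), 1e-3)
  expect_true(all(diff(abs(ratio - 2 / pi)) < 0))
})

test_that("transWSS of an oscillation nearly perpendicular to the mean equals its TAWSS", {
  # oscillation along the tangential axis plus a tiny radial bias: the
  # reference direction is radial and the whole oscillation is cross-flow
  s <- make_locus(locus_spec("uniaxial_oscillatory", 1,
                             steady_offset = c(0, 1e-6)), n_samples = 360)
  expect_equal(transwss(s) / tawss(s), 1, tolerance = 1e-3)
  # agrees with the defining integral evaluated directly
  m <- mean_wss_vector(s)
  p <- c(-m[2], m[1], 0) / sqrt(sum(m[1:2]^2))
  expect_equal(transwss(s), mean(abs(s$vectors %*% p)), tolerance = 1e-12)
})

test_that("CFI reaches 2/pi for near-circular loci and 0 for aligned oscillation", {
  s <- make_locus(locus_spec("circular", 1, 1, steady_offset = c(1e-3, 0)),
                  n_samples = 360)
  expect_equal(round(as.numeric(cfi(s)), 2), 0.64)
  expect_lt(as.numeric(cfi(steady_series(c(0.3, 0.4, 0)))), 1e-12)
  aligned <- make_locus(locus_spec("uniaxial_oscillatory", 1,
                                   steady_offset = c(0.1, 0)),
                        n_samples = 360)
  expect_lt(as.numeric(cfi(aligned)), 1e-12)
})

test_that("axis-minimized metrics handle steady, circular and uniaxial limits", {
  st <- steady_series(c(0, 0.7, 0))  # flow along the tangential direction
  tm <- transwss_min(st)
  expect_lt(tm$value, 1e-12)
  expect_equal(tm$axis, pi / 2, tolerance = 1e-6)

  circ <- circular_series()
  tc <- transwss_min(circ)
  expect_equal(tc$value, (2 / pi) * tawss(circ), tolerance = 1e-4)
  expect_true(tc$flat)
  expect_true(is.na(tc$axis))
  cc <- cfi_min(circ)
  expect_equal(round(cc$value, 2), 0.64)

  un <- make_locus(locus_spec("uniaxial_oscillatory", 1), n_samples = 360)
  tu <- transwss_min(un)
  expect_lt(tu$value, 1e-12)
  expect_equal(tu$axis, pi / 2, tolerance = 1e-6)
  expect_lt(cfi_min(un)$value, 1e-12)
})

test_that("axis minimization agrees with an exhaustive fine-grid search", {
  ell <- make_locus(locus_spec("elliptic", 2, 1), n_samples = 180,
                    frame = wss_frame(0.7))
  expect_equal(transwss_min(ell)$value,
               oracle_axis_min(ell, normalized = FALSE)$value,
               tolerance = 1e-4)
  expect_equal(cfi_min(ell)$value,
               oracle_axis_min(ell, normalized = TRUE)$value,
               tolerance = 1e-4)
})

test_that("the modal direction picks the most populated orientation bin", {
  st <- steady_series(c(0.5, 0, 0))  # along the local radial direction
  md <- modal_direction(st)
  expect_equal(md$angle, pi / 18)  # centre of the bin containing 0 rad
  expect_false(md$tie)

  # half-sample phase offset keeps sample directions off the bin edges
  circ <- make_locus(locus_spec("circular", 1, 1), n_samples = 360,
                     phase = 0.5 / 360)
  mc <- modal_direction(circ)  # 360 samples over 18 bins: uniform, tied
  expect_true(mc$tie)
  expect_true(all(mc$counts == 20))

  biased <- make_locus(locus_spec("elliptic", 1, 0.2, asymmetry = 0.5),
                       n_samples = 360)
  mb <- modal_direction(biased)
  # oracle: histogram the in-plane angles directly
  comp <- series_components(biased)
  ang <- atan2(comp[, "tangential"], comp[, "radial"]) %% (2 * pi)
  counts <- tabulate(pmin(floor(ang / (2 * pi / 18)) + 1, 18), 18)
  expect_equal(mb$counts, counts)
  expect_equal(mb$angle, (which.max(counts) - 0.5) * 2 * pi / 18)
})

test_that("compute_metric_set bundles the metrics with explicit undefineds", {
  ms <- compute_metric_set(circular_series())
  expect_equal(ms$osi, 0.5, tolerance = 1e-9)
  expect_equal(round(ms$cfi_min, 2), 0.64)
  expect_lt(ms$mag_mean_wss, 1e-12)
  expect_equal(ms$transwss_min, 0.64 * ms$tawss, tolerance = 1e-2)
  expect_true(is.na(ms$transwss))
  expect_true(is.na(ms$cfi))
  expect_setequal(names(ms$undefined),
                  c("transwss", "cfi", "dir_mean"))
  expect_true(ms$flat_axis)

  st <- compute_metric_set(steady_series(c(0.5, 0.5, 0) / sqrt(2)))
  expect_equal(st$osi, 0)
  expect_lt(st$transwss, 1e-12)
  expect_lt(st$cfi, 1e-12)
  expect_lt(st$transwss_min, 1e-12)
  expect_lt(st$cfi_min, 1e-12)
  expect_equal(st$dir_mean, pi / 4, tolerance = 1e-9)
  # modal bin contains the flow direction
  expect_lt(abs(st$dir_modal - pi / 4), pi / 18)
})

test_that("in-plane rotation shifts directions and leaves scalars fixed", {
  s <- make_locus(locus_spec("elliptic", 1, 0.4, asymmetry = 0.3,
                             steady_offset = c(0.2, 0.1)), n_samples = 180)
  delta <- pi / 6
  ms0 <- compute_metric_set(s)
  ms1 <- compute_metric_set(rotate_series(s, delta))
  for (m in c("tawss", "mag_mean_wss", "osi", "transwss", "cfi",
              "transwss_min", "cfi_min")) {
    expect_equal(ms1[[m]], ms0[[m]], tolerance = 1e-9, info = m)
  }
  expect_equal((ms1$dir_mean - ms0$dir_mean) %% (2 * pi), delta,
               tolerance = 1e-9)
  expect_equal((ms1$dir_transwss_min - ms0$dir_transwss_min) %% pi, delta,
               tolerance = 1e-6)
  expect_equal((ms1$dir_cfi_min - ms0$dir_cfi_min) %% pi, delta,
               tolerance = 1e-6)
})

test_that("cycle averages converge under sample doubling", {
  for (spec in list(locus_spec("elliptic", 1, 0.5, steady_offset = c(0.2, 0)),
                    locus_spec("circular", 1, 1,
                               steady_offset = c(0.05, 0)))) {
    ms1 <- compute_metric_set(make_locus(spec, n_samples = 360))
    ms2 <- compute_metric_set(make_locus(spec, n_samples = 720))
    for (m in c("tawss", "mag_mean_wss", "osi", "transwss", "cfi",
                "transwss_min", "cfi_min")) {
      expect_equal(ms2[[m]], ms1[[m]], tolerance = 1e-4, info = m)
    }
  }
})
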