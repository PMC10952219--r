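# Independent oracles and generators used across the test files.

# Exhaustive grid minimization of the cycle-average absolute cross-flow
# over the in-plane axis angle, straight from the defining integral.
# Deliberately independent of the package's refined minimizer.
oracle_axis_min <- function(series, normalized = FALSE, step_deg = 0.05) {
  comp <- series_components(series)
  a <- comp[, "radial"]
  b <- comp[, "tangential"]
  if (normalized) {
    mag <- sqrt(rowSums(series$vectors^2))
    keep <- mag > 0
    a <- a[keep] / mag[keep]
    b <- b[keep] / mag[keep]
  }
  phi <- seq(0, pi, by = step_deg * pi / 180)
  vals <- vapply(phi, function(p) mean(abs(b * cos(p) - a * sin(p))),
                 numeric(1))
  list(value = min(vals), axis = phi[which.min(vals)])
}

# Exact ellipse perimeter by numerical quadrature of the arc-length
# integral (independent of the Ramanujan approximation in the package).
oracle_ellipse_perimeter <- function(a, b) {
  stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                   0, 2 * pi, rel.tol = 1e-12)$value
}

# Points sampled exactly on a rotated, translated ellipse.
ellipse_points <- function(a, b, angle = 0, center = c(0, 0), n = 72) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- a * cos(th)
  y <- b * sin(th)
  cbind(center[1] + x * cos(angle) - y * sin(angle),
        center[2] + x * sin(angle) + y * cos(angle))
}

# A constant-vector series built directly (not via the generator), for
# checking metrics against hand values.
steady_series <- function(vec, n = 72, period = 0.4, frame = wss_frame()) {
  wss_series(times = (seq_len(n) - 1) * period / n,
             vectors = matrix(rep(vec, each = n), ncol = 3),
             period = period, frame = frame)
}

# Rotate a series' stress vectors in-plane (about the wall normal) by
# `angle`, keeping the frame fixed, so all direction metrics should shift
# by `angle` while scalar metrics stay put.
rotate_series <- function(series, angle) {
  Rm <- matrix(c(cos(angle), sin(angle), 0,
                 -sin(angle), cos(angle), 0,
                 0, 0, 1), nrow = 3)
  wss_series(series$times, series$vectors %*% t(Rm),
             series$period, series$frame)
}

# Randomized locus for property suites: any regime, random amplitudes,
# bias and offset; offsets keep the mean direction defined except for the
# deliberately degenerate circular case. `noise = FALSE` restricts the
# family to smooth loci, needed when comparing against grid oracles whose
# resolution assumes a smooth objective.
random_series <- function(seed, n_samples = 120, noise = TRUE,
                          regimes = c("circular", "elliptic",
                                      "uniaxial_oscillatory", "steady")) {
  set.seed(seed)
  regime <- sample(regimes, 1)
  amp_t <- runif(1, 0.05, 1)
  amp_r <- if (regime == "circular") amp_t else runif(1, 0.05, 1)
  spec <- locus_spec(
    regime,
    amplitude_tangential = amp_t,
    amplitude_radial = amp_r,
    steady_offset = if (regime == "steady") runif(2, -1, 1)
                    else runif(2, -0.3, 0.3),
    asymmetry = if (regime %in% c("elliptic", "uniaxial_oscillatory"))
      runif(1, 0, 0.6) else 0,
    noise_sd = if (noise) sample(c(0, 0.02), 1) else 0,
    seed = seed
  )
  make_locus(spec, n_samples = n_samples,
             frame = wss_frame(runif(1, 0, 2 * pi)))
}

# Metric set with errors mapped to NA, for property loops.
safe_metrics <- function(series) {
  compute_metric_set(series)
}
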