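#' Parametric description of a single-point WSS locus
#'
#' The tip of the instantaneous WSS vector at one point of the well base
#' traces a closed curve (the polar locus) over one cycle. Four regimes
#' cover the shapes produced by swirling-well flow:
#'
#' * `"circular"` — the vector rotates at constant rate with constant
#'   magnitude (purely multidirectional flow, seen at the well centre and
#'   under a suspended cylinder);
#' * `"elliptic"` — an axis-aligned ellipse in the tangential/radial plane,
#'   optionally time-warped so the vector spends more of the cycle pointing
#'   in the wave-travel (negative tangential) direction, as at the well
#'   edge;
#' * `"uniaxial_oscillatory"` — back-and-forth motion along the tangential
#'   axis (zero mean when `asymmetry = 0`);
#' * `"steady"` — a constant vector.
#'
#' Amplitudes are in Pa and refer to the polar-plot coordinates: positive
#' tangential values point against the wave direction, positive radial
#' values point away from the well centre.
#'
#' @param regime One of `"circular"`, `"elliptic"`, `"uniaxial_oscillatory"`,
#'   `"steady"`.
#' @param amplitude_tangential Semi-axis along the tangential direction, Pa.
#' @param amplitude_radial Semi-axis along the radial direction, Pa. Must
#'   equal `amplitude_tangential` for the circular regime.
#' @param steady_offset Length-2 numeric `(tangential, radial)` offset in Pa
#'   added to the locus (the whole locus for `"steady"`).
#' @param asymmetry In `[0, 1)`: strength of the time warp that biases the
#'   elliptic and uniaxial regimes toward the negative tangential
#'   direction. 0 = uniform phase speed.
#' @param noise_sd Standard deviation of per-component Gaussian noise, Pa.
#' @param seed Integer seed used when `noise_sd > 0`.
#' @return An object of class `locus_spec`.
#' @export
#' @examples
#' locus_spec("circular", amplitude_tangential = 1, amplitude_radial = 1)
locus_spec <- function(regime = c("circular", "elliptic",
                                  "uniaxial_oscillatory", "steady"),
                       amplitude_tangential = 0,
                       amplitude_radial = 0,
                       steady_offset = c(0, 0),
                       asymmetry = 0,
                       noise_sd = 0,
                       seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(is.numeric(amplitude_tangential), length(amplitude_tangential) == 1,
            is.numeric(amplitude_radial), length(amplitude_radial) == 1,
            is.numeric(steady_offset), length(steady_offset) == 2,
            is.numeric(asymmetry), length(asymmetry) == 1,
            is.numeric(noise_sd), length(noise_sd) == 1, noise_sd >= 0)
  if (amplitude_tangential < 0 || amplitude_radial < 0) {
    stop("locus amplitudes must be non-negative", call. = FALSE)
  }
  if (asymmetry < 0 || asymmetry >= 1) {
    stop("`asymmetry` must lie in [0, 1)", call. = FALSE)
  }
  if (regime == "circular") {
    if (amplitude_tangential != amplitude_radial) {
      stop("circular regime requires equal tangential and radial amplitudes",
           call. = FALSE)
    }
    if (asymmetry != 0) {
      stop("circular regime rotates at constant rate; `asymmetry` must be 0",
           call. = FALSE)
    }
  }
  structure(
    list(regime = regime,
         amplitude_tangential = amplitude_tangential,
         amplitude_radial = amplitude_radial,
         steady_offset = as.numeric(steady_offset),
         asymmetry = asymmetry,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "locus_spec"
  )
}

# Phase warp: monotone map of cycle fraction u in [0,1) to phase in
# [0, 2pi), slowing down near phase pi so more samples fall at negative
# tangential values when alpha > 0. dpsi/du = 2pi (1 + alpha cos(2 pi u))
# stays positive for alpha < 1.
locus_phase <- function(u, alpha) {
  2 * pi * u + alpha * sin(2 * pi * u)
}

# Evaluate the locus in polar-plot coordinates at cycle fractions u.
# Returns a matrix with columns (tangential, radial).
locus_plot_coords <- function(spec, u) {
  switch(spec$regime,
    circular = {
      psi <- 2 * pi * u
      cbind(spec$amplitude_tangential * cos(psi),
            spec$amplitude_radial * sin(psi))
    },
    elliptic = {
      psi <- locus_phase(u, spec$asymmetry)
      cbind(spec$amplitude_tangential * cos(psi),
            spec$amplitude_radial * sin(psi))
    },
    uniaxial_oscillatory = {
      psi <- locus_phase(u, spec$asymmetry)
      cbind(spec$amplitude_tangential * cos(psi), rep(0, length(u)))
    },
    steady = cbind(rep(0, length(u)), rep(0, length(u)))
  )
}

#' Generate one point's WSS time series
#'
#' Builds a [wss_series()] whose polar locus follows `spec`. Samples are
#' uniform in time, covering exactly one cycle. The generated in-plane
#' stress components are converted from the polar-plot sign convention to
#' the local frame: a component plotted negative-tangential points along
#' the wave-travel direction.
#'
#' @param spec A [locus_spec()].
#' @param n_samples Number of samples per cycle (at least 8). Default 360.
#' @param period Cycle period in s. Default 0.4 (150 rpm).
#' @param frame The local surface frame ([wss_frame()]).
#' @param phase Time-origin offset as a fraction of the cycle; the series is
#'   the spec evaluated at cycle fractions `(k-1)/n + phase`. Used to apply
#'   the azimuthal phase shift of rotating-wave fields.
#' @return A [wss_series()].
#' @export
#' @examples
#' s <- make_locus(locus_spec("circular", 1, 1))
#' range(sqrt(rowSums(s$vectors^2)))  # constant 1 Pa
make_locus <- function(spec, n_samples = 360, period = 0.4,
                       frame = wss_frame(), phase = 0) {
  stopifnot(inherits(spec, "locus_spec"))
  if (n_samples < 8) {
    stop("`n_samples` must be at least 8", call. = FALSE)
  }
  u <- (seq_len(n_samples) - 1) / n_samples + phase
  pc <- locus_plot_coords(spec, u)
  pc[, 1] <- pc[, 1] + spec$steady_offset[1]
  pc[, 2] <- pc[, 2] + spec$steady_offset[2]
  if (spec$noise_sd > 0) {
    pc <- pc + with_local_seed(spec$seed, {
      matrix(stats::rnorm(2 * n_samples, sd = spec$noise_sd), ncol = 2)
    })
  }
  # plot tangential -> frame tangential: wave direction plots negative
  a_t <- -frame$wave_direction * pc[, 1]
  a_r <- pc[, 2]
  vectors <- outer(a_r, frame$radial) + outer(a_t, frame$tangential)
  times <- (seq_len(n_samples) - 1) * period / n_samples
  wss_series(times, vectors, period, frame)
}

# Run code with a private RNG state so generation is reproducible without
# disturbing the caller's random stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Field of WSS series on a polar mesh of the well base
#'
#' Generates a rotating-wave disc field: every point at radius `r`
#' experiences the same temporal pattern of WSS magnitude and direction,
#' phase-shifted by azimuth. The series at `(r, theta)` is the series at
#' `(r, 0)` with its time origin shifted by `theta / omega` (where
#' `omega = 2 pi / period` is the wave's angular rate) and its frame rotated
#' to the local radial/tangential directions; the relation is exact by
#' construction for noiseless specs.
#'
#' @param radial_profile Either a single [locus_spec()] applied at every
#'   radius or a function `r -> locus_spec` (r in m).
#' @param mesh_radii Radii of the mesh rings, m, all positive.
#' @param mesh_azimuths Azimuths of the mesh spokes, rad.
#' @param period Cycle period, s.
#' @param n_samples Samples per cycle.
#' @param wave_direction +1 (counter-clockwise) or -1.
#' @return An object of class `wss_field`: a list with a `points` data frame
#'   (`id`, `x`, `y`, `r`, `theta`), a parallel list `series` of
#'   [wss_series()], and metadata.
#' @export
#' @examples
#' fld <- make_disc_field(locus_spec("circular", 0.3, 0.3),
#'                        mesh_radii = c(2e-3, 5e-3),
#'                        mesh_azimuths = c(0, pi))
make_disc_field <- function(radial_profile, mesh_radii, mesh_azimuths,
                            period = 0.4, n_samples = 360,
                            wave_direction = 1) {
  if (length(mesh_radii) == 0 || length(mesh_azimuths) == 0) {
    stop("mesh must contain at least one radius and one azimuth",
         call. = FALSE)
  }
  if (any(mesh_radii <= 0)) {
    stop("mesh radii must be positive", call. = FALSE)
  }
  spec_at <- if (is.function(radial_profile)) {
    radial_profile
  } else if (inherits(radial_profile, "locus_spec")) {
    function(r) radial_profile
  } else {
    stop("`radial_profile` must be a locus_spec or a function of radius",
         call. = FALSE)
  }
  grid <- expand.grid(r = mesh_radii, theta = mesh_azimuths,
                      KEEP.OUT.ATTRS = FALSE)
  n_pts <- nrow(grid)
  series <- vector("list", n_pts)
  for (i in seq_len(n_pts)) {
    r <- grid$r[i]
    theta <- grid$theta[i]
    spec <- spec_at(r)
    if (spec$noise_sd > 0) {
      # independent noise per point, still reproducible
      spec$seed <- spec$seed + i
    }
    series[[i]] <- make_locus(spec, n_samples = n_samples, period = period,
                              frame = wss_frame(theta, wave_direction),
                              phase = theta / (2 * pi))
  }
  points <- data.frame(
    id = seq_len(n_pts),
    x = grid$r * cos(grid$theta),
    y = grid$r * sin(grid$theta),
    r = grid$r,
    theta = grid$theta %% (2 * pi)
  )
  structure(
    list(points = points, series = series, period = period,
         n_samples = n_samples, wave_direction = wave_direction,
         tilt = NULL),
    class = "wss_field"
  )
}

#' Field with tilt-broken azimuthal symmetry
#'
#' Tilting the well base breaks the rotating-wave symmetry: stress
#' amplitudes become azimuth-dependent. This generator emulates the effect
#' by scaling the stress vectors of a symmetric disc field at `(r, theta)`
#' by `1 + modulation_depth * cos(theta - modulation_phase)`, so amplitudes
#' are largest at azimuth `modulation_phase` (the high point of the base).
#' `modulation_depth = 0` reduces exactly to [make_disc_field()].
#'
#' @inheritParams make_disc_field
#' @param modulation_depth In `[0, 1)`: relative amplitude modulation.
#' @param modulation_phase Azimuth of maximum amplitude, rad.
#' @return A `wss_field` with tilt metadata.
#' @export
make_tilted_field <- function(radial_profile, mesh_radii, mesh_azimuths,
                              modulation_depth, modulation_phase = 0,
                              period = 0.4, n_samples = 360,
                              wave_direction = 1) {
  if (modulation_depth < 0 || modulation_depth >= 1) {
    stop("`modulation_depth` must lie in [0, 1)", call. = FALSE)
  }
  fld <- make_disc_field(radial_profile, mesh_radii, mesh_azimuths,
                         period = period, n_samples = n_samples,
                         wave_direction = wave_direction)
  if (modulation_depth > 0) {
    gain <- 1 + modulation_depth * cos(fld$points$theta - modulation_phase)
    for (i in seq_along(fld$series)) {
      fld$series[[i]]$vectors <- fld$series[[i]]$vectors * gain[i]
    }
  }
  fld$tilt <- list(modulation_depth = modulation_depth,
                   modulation_phase = modulation_phase)
  fld
}

#' Demonstration radial regimes for standard well variants
#'
#' Radial profiles (functions `r -> locus_spec`) that mimic the qualitative
#' structure of flow in the standard well variants:
#'
#' * `"control_like"` — near-circular loci of constant amplitude out to
#'   7 mm, then progressively elongated, forward-biased elliptic loci
#'   toward the edge (multidirectional centre, near-uniaxial edge);
#' * `"sc_like"` — near-circular loci of reduced amplitude across the span
#'   of a suspended cylinder (0 to 8.5 mm), elongated loci outside it;
#' * `"cc_like"` — an annular channel (4 to 11.05 mm): amplitudes grow from
#'   zero at the cylinder wall, loci strongly tangential throughout.
#'
#' Amplitudes are order-of-magnitude representative (tenths of Pa); the
#' shapes, not the absolute CFD magnitudes, are what these profiles
#' emulate. The circular regimes carry a small (2 percent of amplitude)
#' steady tangential bias in the wave direction: real rotating-wave loci
#' are only approximately centred on the origin, and the bias keeps the
#' mean-vector reference direction (hence transWSS and the CFI) defined
#' while leaving OSI within a percent of its 0.5 ceiling.
#'
#' @param name One of `"control_like"`, `"sc_like"`, `"cc_like"`.
#' @return A function mapping radius (m) to a [locus_spec()].
#' @export
#' @examples
#' prof <- scenario_profile("control_like")
#' prof(2e-3)$regime
scenario_profile <- function(name = c("control_like", "sc_like", "cc_like")) {
  name <- match.arg(name)
  ramp <- function(r, r0, r1) min(1, max(0, (r - r0) / (r1 - r0)))
  switch(name,
    control_like = function(r) {
      if (r <= 7e-3) {
        locus_spec("circular", 0.3, 0.3, steady_offset = c(-0.006, 0))
      } else {
        s <- ramp(r, 7e-3, 10.5e-3)
        locus_spec("elliptic",
                   amplitude_tangential = 0.3 + 0.6 * s,
                   amplitude_radial = 0.3 * (1 - s) + 0.03 * s,
                   asymmetry = 0.4 * s)
      }
    },
    sc_like = function(r) {
      if (r <= 8.5e-3) {
        locus_spec("circular", 0.1, 0.1, steady_offset = c(-0.002, 0))
      } else {
        locus_spec("elliptic", amplitude_tangential = 0.25,
                   amplitude_radial = 0.03, asymmetry = 0.3)
      }
    },
    cc_like = function(r) {
      s <- ramp(r, 4e-3, 5.5e-3)
      locus_spec("elliptic",
                 amplitude_tangential = 0.5 * s,
                 amplitude_radial = 0.06 * s,
                 asymmetry = 0.3)
    }
  )
}

#' @export
print.wss_field <- function(x, ...) {
  cat(sprintf("WSS field: %d points, %d samples/cycle, period %.4g s\n",
              nrow(x$points), x$n_samples, x$period))
  if (!is.null(x$tilt) && x$tilt$modulation_depth > 0) {
    cat(sprintf("  tilt modulation: depth %.2f, phase %.2f rad\n",
                x$tilt$modulation_depth, x$tilt$modulation_phase))
  }
  invisible(x)
}
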