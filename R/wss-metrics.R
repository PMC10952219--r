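#' @title Scalar WSS metrics over one cycle
#'
#' @description
#' Seven established metrics reduce a cycle of instantaneous WSS vectors
#' to scalars. With uniform periodic sampling every cycle average is
#' computed as the plain arithmetic mean over the samples (for a periodic
#' integrand this equals the trapezoidal rule on the closed cycle).
#'
#' * `tawss()` — time-average of the vector magnitude.
#' * `mag_mean_wss()` — magnitude of the time-averaged vector.
#' * `osi()` — oscillatory shear index `0.5 * (1 - MagMeanWSS / TAWSS)`,
#'   in `[0, 0.5]`.
#' * `transwss()` — time-average of the absolute component perpendicular
#'   (within the wall plane) to the mean-vector direction.
#' * `cfi()` — as `transwss()` but with unit-normalized instantaneous
#'   vectors, in `[0, 1]`.
#'
#' `osi()` is undefined when the series is identically zero; `transwss()`
#' and `cfi()` are undefined when the mean vector vanishes (no reference
#' direction) — both raise classed errors rather than returning 0, because
#' a silent 0 means the opposite (purely unidirectional flow).
#'
#' @param series A [wss_series()].
#' @return A scalar (Pa for `tawss`, `mag_mean_wss`, `transwss`;
#'   dimensionless for `osi`, `cfi`).
#' @name wss_metrics
NULL

stop_undefined <- function(msg, class) {
  stop(structure(class = c(class, "wellshear_undefined_metric",
                           "error", "condition"),
                 list(message = msg, call = NULL)))
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Threshold below which the mean vector is treated as having no usable
# direction (relative to the overall stress scale).
.mean_dir_rtol <- 1e-10

#' @rdname wss_metrics
#' @export
tawss <- function(series) {
  stopifnot(inherits(series, "wss_series"))
  mean(sqrt(rowSums(series$vectors^2)))
}

#' Cycle-mean WSS vector
#'
#' @param series A [wss_series()].
#' @return The time-averaged stress vector (length 3, Pa).
#' @export
mean_wss_vector <- function(series) {
  stopifnot(inherits(series, "wss_series"))
  colMeans(series$vectors)
}

#' @rdname wss_metrics
#' @export
mag_mean_wss <- function(series) {
  sqrt(sum(mean_wss_vector(series)^2))
}

#' @rdname wss_metrics
#' @export
osi <- function(series) {
  ta <- tawss(series)
  if (ta <= 0) {
    stop_undefined("OSI undefined: TAWSS is zero (identically zero series)",
                   "wellshear_zero_tawss")
  }
  0.5 * (1 - mag_mean_wss(series) / ta)
}

# Unit vector perpendicular (in the wall plane) to the mean WSS direction,
# i.e. n x tau_mean / |tau_mean|. Errors when the mean vector is too small
# to define a direction.
cross_reference <- function(series) {
  m <- mean_wss_vector(series)
  mag_m <- sqrt(sum(m^2))
  ta <- tawss(series)
  if (ta <= 0 || mag_m <= .mean_dir_rtol * ta) {
    stop_undefined(
      "reference direction undefined: mean WSS vector vanishes",
      "wellshear_degenerate_reference")
  }
  cross3(series$frame$normal, m / mag_m)
}

#' @rdname wss_metrics
#' @export
transwss <- function(series) {
  p <- cross_reference(series)
  mean(abs(series$vectors %*% p))
}

#' @rdname wss_metrics
#' @export
cfi <- function(series) {
  p <- cross_reference(series)
  mag <- sqrt(rowSums(series$vectors^2))
  keep <- mag > 0
  if (!any(keep)) {
    stop_undefined("CFI undefined: all samples have zero magnitude",
                   "wellshear_zero_tawss")
  }
  u <- series$vectors[keep, , drop = FALSE] / mag[keep]
  out <- mean(abs(u %*% p))
  attr(out, "excluded_samples") <- sum(!keep)
  out
}

# Cycle-average absolute cross-flow past an in-plane axis at angle phi
# (measured from the local radial direction toward the tangential one).
# With a right-handed frame (radial, tangential, normal) the cross
# component of a vector with in-plane components (a, b) past the axis
# (cos phi, sin phi) is b cos(phi) - a sin(phi). `normalized` divides each
# sample by its full vector magnitude (zero-magnitude samples excluded).
axis_cross_mean <- function(series, phi, normalized = FALSE) {
  comp <- series_components(series)
  a <- comp[, "radial"]
  b <- comp[, "tangential"]
  if (normalized) {
    mag <- sqrt(rowSums(series$vectors^2))
    keep <- mag > 0
    if (!any(keep)) {
      stop_undefined("CFImin undefined: all samples have zero magnitude",
                     "wellshear_zero_tawss")
    }
    a <- a[keep] / mag[keep]
    b <- b[keep] / mag[keep]
  }
  colMeans(abs(outer(b, cos(phi)) - outer(a, sin(phi))))
}

# Minimize axis_cross_mean over the axis angle. The objective has period
# pi and is piecewise smooth with kinks at the sample directions (where
# one sample's cross component changes sign); its minimum lies either at
# a kink or at an interior smooth point. Both are covered: the kink
# angles are evaluated exactly, and a quarter-degree grid locates the
# competitive smooth basins which stats::optimize then refines (near-ties
# between basins would otherwise make the result depend on grid
# alignment). An objective whose variation does not exceed the sampling
# quadrature ripple (e.g. a uniformly sampled circular locus) leaves the
# axis indeterminate, reported as NA with `flat = TRUE`.
minimize_axis_cross <- function(series, normalized) {
  comp <- series_components(series)
  mag <- sqrt(rowSums(series$vectors^2))
  keep <- mag > 0
  kinks <- unique(atan2(comp[keep, "tangential"], comp[keep, "radial"]) %% pi)
  n_grid <- 720L
  grid <- seq(0, pi, length.out = n_grid + 1)[-(n_grid + 1)]
  fg <- axis_cross_mean(series, grid, normalized)
  fk <- if (length(kinks)) axis_cross_mean(series, kinks, normalized) else Inf
  fmax <- max(fg)
  best_val <- min(fg)
  best_axis <- grid[which.min(fg)]
  if (min(fk) < best_val) {
    best_val <- min(fk)
    best_axis <- kinks[which.min(fk)]
  }
  # anisotropy below the quadrature ripple of n uniform samples is not
  # resolvable: report the axis as indeterminate
  flat_tol <- max(1e-9, 0.5 * (pi / max(sum(keep), 8))^2)
  if (fmax - best_val <= flat_tol * max(fmax, .Machine$double.eps)) {
    return(list(value = best_val, axis = NA_real_, flat = TRUE))
  }
  step <- pi / n_grid
  is_lo <- fg <= c(fg[-1], fg[1]) & fg <= c(fg[n_grid], fg[-n_grid])
  cand <- which(is_lo & fg <= min(fg) + 0.05 * (fmax - min(fg)))
  if (length(cand) > 8L) cand <- cand[order(fg[cand])][1:8]
  f1 <- function(phi) axis_cross_mean(series, phi, normalized)
  for (i in cand) {
    opt <- stats::optimize(f1, interval = c(grid[i] - step, grid[i] + step),
                           tol = 1e-10)
    if (opt$objective < best_val) {
      best_val <- opt$objective
      best_axis <- opt$minimum %% pi
    }
  }
  list(value = best_val, axis = best_axis, flat = FALSE)
}

#' Axis-minimized transverse WSS and cross-flow index
#'
#' `transwss_min()` minimizes the cycle-average absolute cross-flow over
#' the in-plane reference axis instead of using the mean-vector direction;
#' it models cells that orient so as to minimize the flow across them.
#' `cfi_min()` is the magnitude-independent (unit-normalized) equivalent.
#' Both are defined even when the mean WSS vector vanishes.
#'
#' @param series A [wss_series()].
#' @return A list with `value` (Pa for `transwss_min`, dimensionless for
#'   `cfi_min`), `axis` (minimizing axis angle in `[0, pi)`, measured from
#'   the local radial direction, `NA` when the objective is flat) and
#'   `flat` (logical: `TRUE` when every axis gives the same value, as for a
#'   perfectly circular locus).
#' @export
#' @examples
#' s <- make_locus(locus_spec("circular", 1, 1))
#' cfi_min(s)$value  # 2/pi for a circular locus
transwss_min <- function(series) {
  stopifnot(inherits(series, "wss_series"))
  minimize_axis_cross(series, normalized = FALSE)
}

#' @rdname transwss_min
#' @export
cfi_min <- function(series) {
  stopifnot(inherits(series, "wss_series"))
  minimize_axis_cross(series, normalized = TRUE)
}

#' Modal WSS direction
#'
#' Divides the instantaneous WSS vectors of one cycle into `n_bins`
#' direction bins of equal width over `[0, 2*pi)` (left-closed, angles
#' measured from the local radial direction toward the tangential one) and
#' returns the centre of the most populated bin. Zero-magnitude samples,
#' whose direction is undefined, are excluded. Ties are broken toward the
#' lower bin index and flagged.
#'
#' @param series A [wss_series()].
#' @param n_bins Number of orientation bins (default 18, i.e. 20 degrees).
#' @return A list with `angle` (bin centre, rad in `[0, 2*pi)`), `tie`
#'   (logical) and `counts` (integer vector of bin occupancies).
#' @export
modal_direction <- function(series, n_bins = 18) {
  stopifnot(inherits(series, "wss_series"), n_bins >= 2)
  comp <- series_components(series)
  mag <- sqrt(rowSums(series$vectors^2))
  keep <- mag > 0
  ang <- atan2(comp[keep, "tangential"], comp[keep, "radial"]) %% (2 * pi)
  width <- 2 * pi / n_bins
  idx <- pmin(floor(ang / width) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  best <- which.max(counts)
  list(
    angle = (best - 0.5) * width,
    tie = sum(counts == counts[best]) > 1L,
    counts = counts
  )
}

#' All WSS metrics and characteristic directions for one point
#'
#' Computes the seven scalar metrics (TAWSS, MagMeanWSS, OSI, transWSS,
#' CFI, transWSSmin, CFImin) and the four characteristic directions (mean,
#' modal, and the axes minimizing transWSS and the CFI). Metrics that are
#' undefined for the given series (OSI for an identically zero series;
#' transWSS and CFI when the mean vector vanishes, as for purely
#' multidirectional flow) are recorded as `NA` with a reason in
#' `$undefined`, never silently as 0.
#'
#' @param series A [wss_series()].
#' @param n_bins Orientation bins for the modal direction.
#' @return An object of class `wss_metric_set`: a list with the metric
#'   values, direction angles (rad; directions in `[0, 2*pi)`, minimizing
#'   axes in `[0, pi)`), the mean stress vector, and bookkeeping fields
#'   `undefined` (named character), `modal_tie`, `flat_axis`,
#'   `excluded_samples`.
#' @export
#' @examples
#' ms <- compute_metric_set(make_locus(locus_spec("circular", 1, 1)))
#' ms$osi        # 0.5
#' ms$cfi_min    # 2/pi
compute_metric_set <- function(series, n_bins = 18) {
  stopifnot(inherits(series, "wss_series"))
  undefined <- character(0)
  grab <- function(name, expr) {
    tryCatch(expr, wellshear_undefined_metric = function(e) {
      undefined[[name]] <<- conditionMessage(e)
      NA_real_
    })
  }
  ta <- tawss(series)
  m <- mean_wss_vector(series)
  mm <- sqrt(sum(m^2))
  comp_m <- c(sum(m * series$frame$radial), sum(m * series$frame$tangential))
  osi_v <- grab("osi", osi(series))
  trans_v <- grab("transwss", transwss(series))
  excluded <- 0L
  cfi_v <- grab("cfi", {
    v <- cfi(series)
    excluded <- attr(v, "excluded_samples")
    as.numeric(v)
  })
  tmin <- transwss_min(series)
  cmin <- grab("cfi_min", cfi_min(series))
  cmin_axis <- if (is.list(cmin)) cmin$axis else NA_real_
  cmin_flat <- if (is.list(cmin)) cmin$flat else FALSE
  cmin_value <- if (is.list(cmin)) cmin$value else cmin
  modal <- modal_direction(series, n_bins)
  dir_mean <- if (mm > .mean_dir_rtol * max(ta, .Machine$double.eps)) {
    atan2(comp_m[2], comp_m[1]) %% (2 * pi)
  } else {
    undefined[["dir_mean"]] <- "mean WSS vector vanishes"
    NA_real_
  }
  structure(
    list(
      tawss = ta,
      mag_mean_wss = mm,
      osi = osi_v,
      transwss = trans_v,
      cfi = cfi_v,
      transwss_min = tmin$value,
      cfi_min = cmin_value,
      dir_mean = dir_mean,
      dir_modal = modal$angle,
      dir_transwss_min = tmin$axis,
      dir_cfi_min = cmin_axis,
      mean_vector = m,
      undefined = undefined,
      modal_tie = modal$tie,
      flat_axis = tmin$flat || cmin_flat,
      excluded_samples = excluded
    ),
    class = "wss_metric_set"
  )
}

#' @export
print.wss_metric_set <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else format(signif(v, 4))
  cat("WSS metric set\n")
  cat(sprintf("  TAWSS %s Pa   MagMeanWSS %s Pa   OSI %s\n",
              fmt(x$tawss), fmt(x$mag_mean_wss), fmt(x$osi)))
  cat(sprintf("  transWSS %s Pa   CFI %s\n", fmt(x$transwss), fmt(x$cfi)))
  cat(sprintf("  transWSSmin %s Pa   CFImin %s\n",
              fmt(x$transwss_min), fmt(x$cfi_min)))
  if (length(x$undefined)) {
    cat("  undefined:", paste(names(x$undefined), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.wss_metric_set <- function(x, ...) {
  data.frame(
    tawss = x$tawss, mag_mean_wss = x$mag_mean_wss, osi = x$osi,
    transwss = x$transwss, cfi = x$cfi,
    transwss_min = x$transwss_min, cfi_min = x$cfi_min,
    dir_mean = x$dir_mean, dir_modal = x$dir_modal,
    dir_transwss_min = x$dir_transwss_min, dir_cfi_min = x$dir_cfi_min,
    modal_tie = x$modal_tie, flat_axis = x$flat_axis,
    excluded_samples = x$excluded_samples
  )
}
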