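#' Polar locus of a WSS series
#'
#' Projects a point's instantaneous WSS vectors into the locus coordinates
#' used for polar plots: the first coordinate is tangential, the second
#' radial. Sign conventions: negative radial values indicate components
#' pointing toward the well centre; negative tangential values indicate
#' components pointing along the wave-travel direction.
#'
#' @param series A [wss_series()].
#' @return An object of class `polar_locus`: a list with `points` (an
#'   `n x 2` matrix, columns `tangential` and `radial`, Pa) and
#'   `sample_interval` (s).
#' @export
#' @examples
#' loc <- locus_from_series(make_locus(locus_spec("circular", 1, 1)))
#' range(rowSums(loc$points^2))  # unit circle
locus_from_series <- function(series) {
  stopifnot(inherits(series, "wss_series"))
  fr <- series$frame
  if (is.null(fr$radial) || is.null(fr$tangential)) {
    stop("series frame does not define radial/tangential directions",
         call. = FALSE)
  }
  comp <- series_components(series)
  pts <- cbind(
    tangential = -fr$wave_direction * comp[, "tangential"],
    radial = comp[, "radial"]
  )
  structure(
    list(points = pts,
         sample_interval = series$period / nrow(pts)),
    class = "polar_locus"
  )
}

#' Fit an ellipse to a polar locus
#'
#' Direct least-squares conic fit constrained to an ellipse (the
#' numerically stable formulation of the Fitzgibbon method), applied to
#' the closed curve traced by the WSS vector tip. Near-collinear loci, to
#' which no ellipse can be fitted, are returned as a zero-minor-axis
#' segment along the principal direction with `degenerate` set, rather
#' than failing.
#'
#' @param locus A [polar_locus()], or an `n x 2` matrix of points.
#' @return An object of class `ellipse_fit`: list with `center` (length
#'   2), `semi_major`, `semi_minor`, `orientation` (rad, angle of the
#'   major axis in `[0, pi)`), `area`, `perimeter`, `rms_residual`
#'   (Sampson-distance RMS, 0 for degenerate fits), `degenerate`.
#' @export
#' @examples
#' th <- seq(0, 2 * pi, length.out = 65)[-65]
#' fit_ellipse(cbind(2 * cos(th), sin(th)))
fit_ellipse <- function(locus) {
  pts <- if (inherits(locus, "polar_locus")) locus$points else as.matrix(locus)
  stopifnot(is.numeric(pts), ncol(pts) == 2)
  if (nrow(pts) < 6) {
    stop("ellipse fitting needs at least 6 points", call. = FALSE)
  }
  ctr <- colMeans(pts)
  x <- pts[, 1] - ctr[1]
  y <- pts[, 2] - ctr[2]
  # collinearity check via principal components
  sv <- svd(cbind(x, y), nu = 0)
  if (sv$d[2] <= 1e-9 * max(sv$d[1], .Machine$double.eps)) {
    return(segment_fit(pts, ctr, sv))
  }
  co <- tryCatch(fit_ellipse_conic(x, y), error = function(e) NULL)
  if (is.null(co)) {
    return(segment_fit(pts, ctr, sv))
  }
  geom <- conic_to_geometry(co)
  if (is.null(geom)) {
    return(segment_fit(pts, ctr, sv))
  }
  structure(
    list(
      center = geom$center + ctr,
      semi_major = geom$semi_major,
      semi_minor = geom$semi_minor,
      orientation = geom$orientation,
      area = pi * geom$semi_major * geom$semi_minor,
      perimeter = ellipse_perimeter(geom$semi_major, geom$semi_minor),
      rms_residual = sampson_rms(co, x, y),
      degenerate = FALSE
    ),
    class = "ellipse_fit"
  )
}

# Least-squares segment for loci the ellipse fit cannot represent.
segment_fit <- function(pts, ctr, sv) {
  dir <- sv$v[, 1]
  proj <- (pts[, 1] - ctr[1]) * dir[1] + (pts[, 2] - ctr[2]) * dir[2]
  half <- max(abs(proj))
  perp <- -(pts[, 1] - ctr[1]) * dir[2] + (pts[, 2] - ctr[2]) * dir[1]
  structure(
    list(
      center = ctr,
      semi_major = half,
      semi_minor = 0,
      orientation = atan2(dir[2], dir[1]) %% pi,
      area = 0,
      perimeter = 4 * half,
      rms_residual = sqrt(mean(perp^2)),
      degenerate = TRUE
    ),
    class = "ellipse_fit"
  )
}

# Stable direct ellipse-specific least squares (quadratic/linear split).
# Input coordinates are already centred. Returns conic coefficients
# (a, b, c, d, e, f) for a x^2 + b xy + c y^2 + d x + e y + f = 0.
fit_ellipse_conic <- function(x, y) {
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T_ <- -solve(S3, t(S2))
  M <- S1 + S2 %*% T_
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  # keep the eigenvector satisfying the ellipse constraint 4ac - b^2 > 0
  cond <- 4 * Re(ev$vectors[1, ]) * Re(ev$vectors[3, ]) -
    Re(ev$vectors[2, ])^2
  ok <- which(cond > 0 & abs(Im(ev$values)) < 1e-8)
  if (length(ok) == 0) stop("no ellipse solution")
  a1 <- Re(ev$vectors[, ok[1]])
  c(a1, as.vector(T_ %*% a1))
}

# Geometric parameters of an ellipse from conic coefficients.
conic_to_geometry <- function(co) {
  a <- co[1]; b <- co[2]; cc <- co[3]; d <- co[4]; e <- co[5]; f <- co[6]
  det2 <- 4 * a * cc - b^2
  if (det2 <= 0) return(NULL)
  x0 <- (b * e - 2 * cc * d) / det2
  y0 <- (b * d - 2 * a * e) / det2
  f0 <- f + (d * x0 + e * y0) / 2
  A33 <- matrix(c(a, b / 2, b / 2, cc), 2)
  ed <- eigen(A33, symmetric = TRUE)
  rhs <- -f0
  if (rhs / ed$values[1] <= 0 || rhs / ed$values[2] <= 0) return(NULL)
  ax <- sqrt(rhs / ed$values)
  i_major <- which.max(ax)             # conic scale sign is arbitrary, so
  semi_major <- ax[i_major]            # pick the axis lengths directly
  semi_minor <- ax[-i_major]
  major_vec <- ed$vectors[, i_major]
  list(center = c(x0, y0),
       semi_major = semi_major,
       semi_minor = semi_minor,
       orientation = atan2(major_vec[2], major_vec[1]) %% pi)
}

# Sampson (gradient-weighted algebraic) distance RMS of centred points.
sampson_rms <- function(co, x, y) {
  q <- co[1] * x^2 + co[2] * x * y + co[3] * y^2 +
    co[4] * x + co[5] * y + co[6]
  gx <- 2 * co[1] * x + co[2] * y + co[4]
  gy <- co[2] * x + 2 * co[3] * y + co[5]
  g <- sqrt(gx^2 + gy^2)
  g[g == 0] <- .Machine$double.eps
  sqrt(mean((q / g)^2))
}

#' Ellipse perimeter (Ramanujan's second approximation)
#'
#' Relative error below 1e-9 for aspect ratios up to about 2:1 and below
#' 1e-4 even at 20:1; exact for circles and for degenerate
#' (zero-minor-axis) segments, where the closed-curve perimeter is
#' `4 * semi_major`.
#'
#' @param semi_major,semi_minor Ellipse semi-axes.
#' @return The perimeter.
#' @export
ellipse_perimeter <- function(semi_major, semi_minor) {
  stopifnot(semi_major >= 0, semi_minor >= 0)
  a <- semi_major; b <- semi_minor
  if (a + b == 0) return(0)
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Shape Index of a fitted ellipse
#'
#' `SI = 4 * pi * A / P^2` with area `A` and perimeter `P` of the fitted
#' ellipse: 1 for a circle (fully multidirectional locus), 0 for a straight
#' line (uniaxial locus). Degenerate (segment) fits return 0.
#'
#' @param fit An [fit_ellipse()] result.
#' @return SI in `[0, 1]`.
#' @export
#' @examples
#' th <- seq(0, 2 * pi, length.out = 65)[-65]
#' shape_index(fit_ellipse(cbind(cos(th), sin(th))))  # 1
shape_index <- function(fit) {
  stopifnot(inherits(fit, "ellipse_fit"))
  if (fit$degenerate) return(0)
  if (fit$perimeter <= 0) {
    stop("shape index undefined: zero perimeter", call. = FALSE)
  }
  si <- 4 * pi * fit$area / fit$perimeter^2
  min(max(si, 0), 1)
}

#' @export
print.ellipse_fit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("Degenerate locus: segment of half-length %.4g Pa at %.3f rad\n",
                x$semi_major, x$orientation))
  } else {
    cat(sprintf("Ellipse fit: semi-axes (%.4g, %.4g) Pa at %.3f rad, rms %.2g\n",
                x$semi_major, x$semi_minor, x$orientation, x$rms_residual))
  }
  invisible(x)
}
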