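#' Local surface frame at a point on the well base
#'
#' At a point at azimuth `theta` on the (horizontal) well base the local
#' frame consists of the outward radial unit vector, the counter-clockwise
#' tangential unit vector and the upward wall normal. `wave_direction`
#' records the sense in which the swirling wave travels around the well
#' (+1 counter-clockwise, -1 clockwise); it fixes the sign convention of
#' polar loci, where components pointing along the wave direction are
#' plotted negative.
#'
#' @param azimuth Azimuth of the point in rad, measured counter-clockwise
#'   from the +x axis.
#' @param wave_direction +1 or -1.
#' @return A list with unit vectors `radial`, `tangential`, `normal` and the
#'   scalar `wave_direction`, of class `wss_frame`.
#' @export
wss_frame <- function(azimuth = 0, wave_direction = 1) {
  stopifnot(is.numeric(azimuth), length(azimuth) == 1,
            wave_direction %in% c(-1, 1))
  structure(
    list(
      radial = c(cos(azimuth), sin(azimuth), 0),
      tangential = c(-sin(azimuth), cos(azimuth), 0),
      normal = c(0, 0, 1),
      wave_direction = wave_direction
    ),
    class = "wss_frame"
  )
}

#' One point's wall shear stress time series over one cycle
#'
#' Holds uniformly sampled instantaneous WSS vectors (tau_x, tau_y, tau_z,
#' in Pa, global coordinates) covering exactly one cycle of period `period`,
#' together with the local surface frame of the point. Sample k is taken at
#' time `(k-1) * period / n`; the sample at `period` is the same as the one
#' at 0 and is not stored.
#'
#' @param times Sample times in s, uniformly spaced, starting anywhere in
#'   the cycle; `max(times) - min(times)` plus one sampling interval must
#'   equal `period`.
#' @param vectors An `n x 3` numeric matrix of stress vectors in Pa.
#' @param period Cycle period T in s.
#' @param frame A [wss_frame()].
#' @return An object of class `wss_series`.
#' @export
wss_series <- function(times, vectors, period, frame = wss_frame()) {
  vectors <- as.matrix(vectors)
  n <- length(times)
  if (n < 8) stop("a wss_series needs at least 8 samples", call. = FALSE)
  stopifnot(is.numeric(period), period > 0,
            nrow(vectors) == n, ncol(vectors) == 3,
            inherits(frame, "wss_frame"))
  dt <- diff(times)
  if (any(abs(dt - dt[1]) > 1e-9 * period)) {
    stop("sample times must be uniformly spaced", call. = FALSE)
  }
  span <- max(times) - min(times) + dt[1]
  if (abs(span - period) > 1e-9 * period) {
    stop("samples must cover exactly one cycle: span + dt != period",
         call. = FALSE)
  }
  ortho <- c(
    sum(frame$normal^2) - 1,
    sum(frame$normal * frame$radial),
    sum(frame$normal * frame$tangential)
  )
  if (any(abs(ortho) > 1e-9)) {
    stop("frame normal must be unit length and orthogonal to the surface",
         call. = FALSE)
  }
  structure(
    list(times = as.numeric(times), vectors = unname(vectors),
         period = period, frame = frame),
    class = "wss_series"
  )
}

#' In-plane components of a series in its local frame
#'
#' Projects each stored 3-vector onto the local radial and tangential unit
#' directions. The normal component is returned too (zero for flow over a
#' flat base).
#'
#' @param series A [wss_series()].
#' @return An `n x 3` matrix with columns `radial`, `tangential`, `normal`.
#' @export
series_components <- function(series) {
  stopifnot(inherits(series, "wss_series"))
  fr <- series$frame
  out <- cbind(
    radial = as.vector(series$vectors %*% fr$radial),
    tangential = as.vector(series$vectors %*% fr$tangential),
    normal = as.vector(series$vectors %*% fr$normal)
  )
  out
}

#' @export
print.wss_series <- function(x, ...) {
  cat(sprintf("WSS time series: %d samples over one cycle of %.4g s\n",
              length(x$times), x$period))
  mag <- sqrt(rowSums(x$vectors^2))
  cat(sprintf("  |tau| range %.4g - %.4g Pa\n", min(mag), max(mag)))
  invisible(x)
}
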