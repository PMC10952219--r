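#' Fluid properties of the culture medium
#'
#' Bundles the physical properties of the liquid (and the overlying air)
#' needed to characterize a swirling-well configuration. All values are SI.
#'
#' @param density_liquid Liquid density in kg/m^3. Default 1003 (culture
#'   medium at 37 degrees C).
#' @param density_air Air density in kg/m^3. Default 1.1115.
#' @param dynamic_viscosity Dynamic viscosity of the liquid in Pa.s. Default
#'   0.78e-3 (medium at 37 degrees C).
#' @param kinematic_viscosity Optional kinematic viscosity override in m^2/s.
#'   When supplied it takes precedence over `dynamic_viscosity /
#'   density_liquid`; used for dextran-thickened media where the kinematic
#'   value is what is reported.
#' @param surface_tension Surface tension in N/m. Default 0.072 (water or
#'   unsupplemented medium); serum-supplemented medium is closer to 0.047.
#'
#' @return An object of class `fluid_properties`.
#' @export
#' @examples
#' fluid_properties()
#' fluid_properties(kinematic_viscosity = 2.2e-6)
fluid_properties <- function(density_liquid = 1003,
                             density_air = 1.1115,
                             dynamic_viscosity = 0.78e-3,
                             kinematic_viscosity = NULL,
                             surface_tension = 0.072) {
  stopifnot(
    is.numeric(density_liquid), density_liquid > 0,
    is.numeric(density_air), density_air > 0,
    is.numeric(dynamic_viscosity), dynamic_viscosity > 0,
    is.numeric(surface_tension), surface_tension > 0
  )
  if (density_liquid <= density_air) {
    stop("`density_liquid` must exceed `density_air`", call. = FALSE)
  }
  if (!is.null(kinematic_viscosity)) {
    stopifnot(is.numeric(kinematic_viscosity), kinematic_viscosity > 0)
  }
  structure(
    list(
      density_liquid = density_liquid,
      density_air = density_air,
      dynamic_viscosity = dynamic_viscosity,
      kinematic_viscosity = kinematic_viscosity,
      surface_tension = surface_tension
    ),
    class = "fluid_properties"
  )
}

#' Kinematic viscosity of a fluid
#'
#' Returns the kinematic viscosity override when one was supplied, otherwise
#' `dynamic_viscosity / density_liquid`.
#'
#' @param fluid A [fluid_properties()] object.
#' @return Kinematic viscosity in m^2/s.
#' @export
kinematic_viscosity <- function(fluid) {
  stopifnot(inherits(fluid, "fluid_properties"))
  if (!is.null(fluid$kinematic_viscosity)) {
    return(fluid$kinematic_viscosity)
  }
  fluid$dynamic_viscosity / fluid$density_liquid
}

#' Central cylinder descriptors
#'
#' A well may contain no cylinder, a cylinder attached to its base (which
#' masks the base under its footprint and confines flow to an annular
#' channel), or a cylinder suspended a small gap above the base (the base
#' under it remains wetted).
#'
#' @param radius Cylinder radius in m.
#' @param gap Gap between the cylinder base and the well base in m
#'   (suspended cylinders only).
#' @return A cylinder descriptor of class `well_cylinder`.
#' @export
cylinder_none <- function() {
  structure(list(type = "none"), class = "well_cylinder")
}

#' @rdname cylinder_none
#' @export
cylinder_attached <- function(radius) {
  stopifnot(is.numeric(radius), radius > 0)
  structure(list(type = "attached", radius = radius), class = "well_cylinder")
}

#' @rdname cylinder_none
#' @export
cylinder_suspended <- function(radius, gap) {
  stopifnot(is.numeric(radius), radius > 0, is.numeric(gap), gap > 0)
  structure(list(type = "suspended", radius = radius, gap = gap),
            class = "well_cylinder")
}

#' Swirling-well model configuration
#'
#' Describes one model variant: the well geometry, the orbital motion of the
#' shaker platform, an optional central cylinder, an optional tilt of the
#' base, and the fluid. All lengths in m, angular rate in rad/s.
#'
#' @param well_radius Well radius R in m.
#' @param mean_depth Average liquid depth d in m.
#' @param orbital_radius Orbit radius a of the shaker platform in m.
#'   Default 5e-3.
#' @param angular_rate Angular velocity omega of the orbit in rad/s.
#'   Default `150 * pi / 30` (150 rpm).
#' @param gravity Gravitational acceleration in m/s^2.
#' @param cylinder A cylinder descriptor ([cylinder_none()],
#'   [cylinder_attached()], [cylinder_suspended()]).
#' @param tilt_angle Tilt of the well base in degrees (0 = horizontal).
#' @param fluid A [fluid_properties()] object.
#' @param label Optional character label for printing.
#'
#' @return An object of class `well_config`.
#' @export
#' @examples
#' cfg <- well_config(well_radius = 11.05e-3, mean_depth = 2e-3)
#' dimensionless_groups(cfg)
well_config <- function(well_radius,
                        mean_depth,
                        orbital_radius = 5e-3,
                        angular_rate = 150 * pi / 30,
                        gravity = 9.81,
                        cylinder = cylinder_none(),
                        tilt_angle = 0,
                        fluid = fluid_properties(),
                        label = NULL) {
  stopifnot(
    is.numeric(well_radius), well_radius > 0,
    is.numeric(mean_depth), mean_depth > 0,
    is.numeric(orbital_radius), orbital_radius >= 0,
    is.numeric(angular_rate), angular_rate >= 0,
    is.numeric(gravity), gravity > 0,
    inherits(cylinder, "well_cylinder"),
    is.numeric(tilt_angle), tilt_angle >= 0,
    inherits(fluid, "fluid_properties")
  )
  if (cylinder$type != "none" && cylinder$radius >= well_radius) {
    stop("cylinder radius must be smaller than the well radius", call. = FALSE)
  }
  structure(
    list(
      well_radius = well_radius,
      mean_depth = mean_depth,
      orbital_radius = orbital_radius,
      angular_rate = angular_rate,
      gravity = gravity,
      cylinder = cylinder,
      tilt_angle = tilt_angle,
      fluid = fluid,
      label = label
    ),
    class = "well_config"
  )
}

#' Characteristic length of a well configuration
#'
#' The well radius R for a plain well; for wells containing a central
#' cylinder (attached or suspended) the flow is confined to an annular
#' channel and the channel width `R_well - R_cylinder` is used instead.
#'
#' @param config A [well_config()] object.
#' @return Characteristic length in m.
#' @export
characteristic_length <- function(config) {
  stopifnot(inherits(config, "well_config"))
  if (config$cylinder$type == "none") {
    config$well_radius
  } else {
    config$well_radius - config$cylinder$radius
  }
}

#' Dimensionless characterization of a well configuration
#'
#' Computes the six dimensionless groups that characterize swirling-well
#' flow: eccentricity E = a/L, forcing F = a w^2 / g, shallowness
#' Gamma = d/L, Reynolds number Re = L^2 w / nu, Bond number
#' Bo = (rho_l - rho_a) g (2L)^2 / sigma and Weber number
#' We = rho_l U^2 (2L) / sigma, where L is the characteristic length
#' (channel width for wells with a cylinder, otherwise the well radius) and
#' U = R w is the linear velocity at the edge of the well.
#'
#' @param config A [well_config()] object.
#' @return An object of class `dimensionless_groups`: a list with elements
#'   `E`, `F_`, `Gamma`, `Re`, `Bo`, `We`, `characteristic_length` (m) and
#'   `U` (m/s). The forcing number is stored as `F_` to avoid the base
#'   `FALSE` alias.
#' @export
dimensionless_groups <- function(config) {
  stopifnot(inherits(config, "well_config"))
  L <- characteristic_length(config)
  nu <- kinematic_viscosity(config$fluid)
  if (!is.finite(L) || L <= 0) {
    stop("invalid configuration: non-positive characteristic length",
         call. = FALSE)
  }
  if (!is.finite(nu) || nu <= 0) {
    stop("invalid configuration: non-positive kinematic viscosity",
         call. = FALSE)
  }
  a <- config$orbital_radius
  w <- config$angular_rate
  g <- config$gravity
  rho_l <- config$fluid$density_liquid
  rho_a <- config$fluid$density_air
  sigma <- config$fluid$surface_tension
  U <- config$well_radius * w
  structure(
    list(
      E = a / L,
      F_ = a * w^2 / g,
      Gamma = config$mean_depth / L,
      Re = L^2 * w / nu,
      Bo = (rho_l - rho_a) * g * (2 * L)^2 / sigma,
      We = rho_l * U^2 * (2 * L) / sigma,
      characteristic_length = L,
      U = U
    ),
    class = "dimensionless_groups"
  )
}

#' @export
print.dimensionless_groups <- function(x, ...) {
  cat("Dimensionless groups (L =", format(x$characteristic_length * 1e3),
      "mm, U =", format(signif(x$U, 4)), "m/s)\n")
  cat(sprintf("  E  = %.2f   F     = %.2f   Gamma = %.2f\n",
              x$E, x$F_, x$Gamma))
  cat(sprintf("  Re = %.0f   Bo    = %.0f   We    = %.0f\n",
              x$Re, x$Bo, x$We))
  invisible(x)
}

#' Characterize a configuration as a summary-table row
#'
#' Computes the dimensionless groups and rounds them to the precision
#' customarily reported: two decimals for E, F and Gamma, nearest integer
#' for Re, Bo and We.
#'
#' @param config A [well_config()] object.
#' @return A one-row data frame with columns `label`, `nu_mm2_s`, `d_mm`,
#'   `L_mm`, `Bo`, `We`, `Re`, `E`, `F`, `Gamma`.
#' @export
#' @examples
#' characterize_row(swirling_well_preset("control"))
characterize_row <- function(config) {
  stopifnot(inherits(config, "well_config"))
  dg <- dimensionless_groups(config)
  data.frame(
    label = if (is.null(config$label)) NA_character_ else config$label,
    nu_mm2_s = kinematic_viscosity(config$fluid) * 1e6,
    d_mm = config$mean_depth * 1e3,
    L_mm = dg$characteristic_length * 1e3,
    Bo = round(dg$Bo),
    We = round(dg$We),
    Re = round(dg$Re),
    E = round(dg$E, 2),
    F = round(dg$F_, 2),
    Gamma = round(dg$Gamma, 2),
    stringsAsFactors = FALSE
  )
}

#' Preset swirling-well configurations
#'
#' Ready-made [well_config()] objects for the standard single well of a
#' 12-well plate (11.05 mm radius, 150 rpm orbit of 5 mm radius) and its
#' common variants: increased medium volume, an 8 mm diameter cylinder
#' attached to the base ("cc"), an 18 mm diameter cylinder suspended 1 or
#' 2 mm above the base ("sc1", "sc2"), the suspended-cylinder model with
#' dextran-thickened medium, and tilted wells.
#'
#' Surface tension defaults to 0.072 N/m (unsupplemented medium) for the
#' plain and tilted wells and 0.047 N/m (serum-supplemented medium) for all
#' wells with a cylinder.
#'
#' @param name One of `"control"`, `"volume_1151"`, `"volume_1534"`,
#'   `"cc"`, `"sc1"`, `"sc2"`, `"sc2_nu2.2"`, `"sc2_nu3.4"`, `"sc2_nu4.0"`,
#'   `"tilt_767_2.5"`, `"tilt_767_5"`, `"tilt_1534_5"`, `"tilt_1534_10"`.
#' @return A [well_config()] object.
#' @export
#' @examples
#' characterize_row(swirling_well_preset("cc"))
swirling_well_preset <- function(name = c(
  "control", "volume_1151", "volume_1534", "cc", "sc1", "sc2",
  "sc2_nu2.2", "sc2_nu3.4", "sc2_nu4.0",
  "tilt_767_2.5", "tilt_767_5", "tilt_1534_5", "tilt_1534_10")) {
  name <- match.arg(name)
  R <- 11.05e-3
  water <- fluid_properties()            # sigma 0.072
  serum <- fluid_properties(surface_tension = 0.047)
  dextran <- function(nu) fluid_properties(surface_tension = 0.047,
                                           kinematic_viscosity = nu)
  base <- function(d, fl = water, cyl = cylinder_none(), tilt = 0) {
    well_config(well_radius = R, mean_depth = d, cylinder = cyl,
                tilt_angle = tilt, fluid = fl, label = name)
  }
  switch(name,
    control      = base(2e-3),
    volume_1151  = base(3e-3),
    volume_1534  = base(4e-3),
    cc           = base(2e-3, serum, cylinder_attached(4e-3)),
    sc1          = base(5e-3, serum, cylinder_suspended(9e-3, 1e-3)),
    sc2          = base(5e-3, serum, cylinder_suspended(9e-3, 2e-3)),
    "sc2_nu2.2"  = base(5e-3, dextran(2.2e-6), cylinder_suspended(9e-3, 2e-3)),
    "sc2_nu3.4"  = base(5e-3, dextran(3.4e-6), cylinder_suspended(9e-3, 2e-3)),
    "sc2_nu4.0"  = base(5e-3, dextran(4.0e-6), cylinder_suspended(9e-3, 2e-3)),
    "tilt_767_2.5"  = base(2e-3, tilt = 2.5),
    "tilt_767_5"    = base(2e-3, tilt = 5),
    "tilt_1534_5"   = base(4e-3, tilt = 5),
    "tilt_1534_10"  = base(4e-3, tilt = 10)
  )
}

#' Read a well configuration from a YAML file
#'
#' The file uses explicit unit suffixes in key names. Recognized keys:
#' `well_radius_mm`, `mean_depth_mm`, `orbital_radius_mm`,
#' `angular_rate_rad_s` (or `rpm`), `gravity_m_s2`, `tilt_angle_deg`,
#' `cylinder:` (`type`, `radius_mm`, `gap_mm`), and a `fluid:` block with
#' `density_liquid_kg_m3`, `density_air_kg_m3`, `dynamic_viscosity_pa_s`,
#' `kinematic_viscosity_mm2_s`, `surface_tension_n_m`.
#'
#' @param path Path to a YAML file.
#' @return A [well_config()] object.
#' @export
read_well_config <- function(path) {
  raw <- yaml::read_yaml(path)
  well_config_from_list(raw)
}

#' @rdname read_well_config
#' @param x A named list with the keys documented for [read_well_config()].
#' @export
well_config_from_list <- function(x) {
  stopifnot(is.list(x))
  grab <- function(key, default = NULL) {
    if (!is.null(x[[key]])) x[[key]] else default
  }
  fl <- x$fluid
  fluid <- fluid_properties(
    density_liquid = if (!is.null(fl$density_liquid_kg_m3))
      fl$density_liquid_kg_m3 else 1003,
    density_air = if (!is.null(fl$density_air_kg_m3))
      fl$density_air_kg_m3 else 1.1115,
    dynamic_viscosity = if (!is.null(fl$dynamic_viscosity_pa_s))
      fl$dynamic_viscosity_pa_s else 0.78e-3,
    kinematic_viscosity = if (!is.null(fl$kinematic_viscosity_mm2_s))
      fl$kinematic_viscosity_mm2_s * 1e-6 else NULL,
    surface_tension = if (!is.null(fl$surface_tension_n_m))
      fl$surface_tension_n_m else 0.072
  )
  cyl <- x$cylinder
  cylinder <- if (is.null(cyl) || identical(cyl$type, "none")) {
    cylinder_none()
  } else if (identical(cyl$type, "attached")) {
    cylinder_attached(cyl$radius_mm * 1e-3)
  } else if (identical(cyl$type, "suspended")) {
    cylinder_suspended(cyl$radius_mm * 1e-3, cyl$gap_mm * 1e-3)
  } else {
    stop("unknown cylinder type: ", cyl$type, call. = FALSE)
  }
  rate <- if (!is.null(x$angular_rate_rad_s)) {
    x$angular_rate_rad_s
  } else if (!is.null(x$rpm)) {
    x$rpm * pi / 30
  } else {
    150 * pi / 30
  }
  well_config(
    well_radius = grab("well_radius_mm") * 1e-3,
    mean_depth = grab("mean_depth_mm") * 1e-3,
    orbital_radius = grab("orbital_radius_mm", 5) * 1e-3,
    angular_rate = rate,
    gravity = grab("gravity_m_s2", 9.81),
    cylinder = cylinder,
    tilt_angle = grab("tilt_angle_deg", 0),
    fluid = fluid,
    label = grab("label")
  )
}

#' @export
print.well_config <- function(x, ...) {
  cat("Swirling-well configuration",
      if (!is.null(x$label)) paste0("(", x$label, ")"), "\n")
  cat(sprintf("  well radius %.2f mm, mean depth %.2f mm, orbit %.1f mm @ %.3f rad/s\n",
              x$well_radius * 1e3, x$mean_depth * 1e3,
              x$orbital_radius * 1e3, x$angular_rate))
  if (x$cylinder$type != "none") {
    cat(sprintf("  %s cylinder, radius %.1f mm%s\n", x$cylinder$type,
                x$cylinder$radius * 1e3,
                if (x$cylinder$type == "suspended")
                  sprintf(", gap %.1f mm", x$cylinder$gap * 1e3) else ""))
  }
  if (x$tilt_angle > 0) cat(sprintf("  tilt %.1f deg\n", x$tilt_angle))
  invisible(x)
}
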