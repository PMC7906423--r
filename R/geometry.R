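#' Idealized atrial chamber geometry
#'
#' Builds the desk-scale computational domain: a 2D rectangular chamber on a
#' uniform square-cell grid with two venous inlet ports (SVC and IVC) on the
#' left wall, a tricuspid-valve (TV) outlet port on the right wall, and
#' no-slip walls elsewhere. Each port is a slot of boundary faces carrying an
#' out-of-plane depth chosen so that the port's area equals its physiological
#' target (a circular cross-section of the given diameter for SVC/IVC, the
#' prescribed valve area for the TV); the interior slab depth is set so the
#' chamber volume matches `target_volume`.
#'
#' @param Lx,Ly chamber extents [m].
#' @param h grid spacing [m]; `Lx` and `Ly` must be (near) multiples of `h`.
#' @param svc_diameter,ivc_diameter inlet diameters [m]; defaults 17.06 mm
#'   and 16.89 mm.
#' @param tv_area outlet area [m^2]; default 9.95 cm^2.
#' @param target_volume chamber volume [m^3] used to set the interior slab
#'   depth; default 175.27 mL.
#' @param svc_center,ivc_center,tv_center port centres as fractions of the
#'   wall length.
#' @param dimensionality only `"2D"` is supported by the solver; 3D analytic
#'   fields are handled by the metrics and synthetic-data layers.
#' @return Object of class `chamber_geometry`.
#' @export
chamber_geometry <- function(Lx = 0.08, Ly = 0.06, h = 0.002,
                             svc_diameter = 17.06e-3,
                             ivc_diameter = 16.89e-3,
                             tv_area = 9.95e-4,
                             target_volume = 175.27e-6,
                             svc_center = 0.75, ivc_center = 0.25,
                             tv_center = 0.5,
                             dimensionality = "2D") {
  if (!identical(dimensionality, "2D")) {
    stop("the chamber solver supports dimensionality = \"2D\" only; ",
         "3D fields are available through make_field()", call. = FALSE)
  }
  nx <- round(Lx / h); ny <- round(Ly / h)
  if (abs(nx * h - Lx) > 1e-9 || abs(ny * h - Ly) > 1e-9) {
    stop("Lx and Ly must be integer multiples of h", call. = FALSE)
  }
  if (min(svc_diameter, ivc_diameter) <= 0 || tv_area <= 0) {
    stop("port dimensions must be positive", call. = FALSE)
  }
  b0 <- target_volume / (Lx * Ly)
  svc_area <- pi * svc_diameter^2 / 4
  ivc_area <- pi * ivc_diameter^2 / 4
  tv_width <- sqrt(4 * tv_area / pi)  # equivalent-diameter slot
  geom <- structure(
    list(kind = "chamber", dimensionality = "2D",
         Lx = Lx, Ly = Ly, h = h, nx = nx, ny = ny, b0 = b0,
         periodic_x = FALSE, body_force = c(0, 0),
         volume = target_volume, patches = list(), catheter = NULL),
    class = "chamber_geometry")
  geom <- add_slot_patch(geom, "svc", "xmin", svc_center * Ly, svc_diameter,
                         area = svc_area, kind = "pressure_inlet")
  geom <- add_slot_patch(geom, "ivc", "xmin", ivc_center * Ly, ivc_diameter,
                         area = ivc_area, kind = "pressure_inlet")
  geom <- add_slot_patch(geom, "tv", "xmax", tv_center * Ly, tv_width,
                         area = tv_area, kind = "pressure_outlet")
  check_patches_disjoint(geom)
  geom
}

#' Plane-channel verification geometry
#'
#' A periodic-in-x channel of height `H` bounded by two no-slip walls and
#' driven by a uniform streamwise body force, the standard plane-Poiseuille
#' verification case for the solver.
#'
#' @param H channel height [m].
#' @param ny cells across the channel.
#' @param nx cells along the channel (periodic), small by default.
#' @param dpdx driving pressure gradient magnitude [Pa/m]; applied as body
#'   force `dpdx` in +x.
#' @return Object of class `chamber_geometry` with `kind = "channel"`.
#' @export
channel_geometry <- function(H = 0.02, ny = 16, nx = 4, dpdx = 1) {
  h <- H / ny
  structure(
    list(kind = "channel", dimensionality = "2D",
         Lx = nx * h, Ly = H, h = h, nx = nx, ny = ny, b0 = 1,
         periodic_x = TRUE, body_force = c(dpdx, 0),
         volume = nx * h * H, patches = list(), catheter = NULL),
    class = "chamber_geometry")
}

# Add a slot patch of boundary faces on one side. `center` and `width` are in
# metres along the wall; if `area` is given the out-of-plane depth is set so
# width_actual * depth == area (facets sum exactly to the target area).
add_slot_patch <- function(geom, name, side, center, width,
                           area = NULL, kind, flow = NA_real_,
                           depth = NULL) {
  h <- geom$h
  nmax <- if (side %in% c("xmin", "xmax")) geom$ny else geom$nx
  wall_len <- if (side %in% c("xmin", "xmax")) geom$Ly else geom$Lx
  if (center < 0 || center > wall_len) {
    stop(sprintf("patch '%s' centre outside the wall", name), call. = FALSE)
  }
  n <- max(1L, round(width / h))
  j0 <- round(center / h - n / 2)
  faces <- (j0 + 1L):(j0 + n)
  if (faces[1] < 1L || faces[n] > nmax) {
    stop(sprintf("patch '%s' does not fit on side %s", name, side),
         call. = FALSE)
  }
  width_actual <- n * h
  if (is.null(depth)) {
    depth <- if (is.null(area)) geom$b0 else area / width_actual
  }
  geom$patches[[name]] <- list(
    name = name, side = side, kind = kind, faces = faces,
    width = width_actual, depth = depth, area = width_actual * depth,
    flow = flow)
  check_patches_disjoint(geom)
  geom
}

check_patches_disjoint <- function(geom) {
  for (side in c("xmin", "xmax", "ymin", "ymax")) {
    used <- integer(0)
    for (p in geom$patches) {
      if (p$side != side) next
      if (length(intersect(used, p$faces))) {
        stop(sprintf("patches overlap on side %s", side), call. = FALSE)
      }
      used <- c(used, p$faces)
    }
  }
  invisible(TRUE)
}

# Facet table for a patch: facet centre coordinates, outward unit normal and
# facet area vector magnitude (h * depth per facet).
patch_facets <- function(geom, name) {
  p <- geom$patches[[name]]
  if (is.null(p)) stop(sprintf("no patch named '%s'", name), call. = FALSE)
  h <- geom$h
  k <- seq_along(p$faces)
  cc <- (p$faces - 0.5) * h
  out <- switch(p$side,
    xmin = data.frame(x = 0,       y = cc, nx = -1, ny = 0),
    xmax = data.frame(x = geom$Lx, y = cc, nx = 1,  ny = 0),
    ymin = data.frame(x = cc, y = 0,       nx = 0,  ny = -1),
    ymax = data.frame(x = cc, y = geom$Ly, nx = 0,  ny = 1))
  out$area <- h * p$depth
  out$facet <- k
  out
}

#' Tip sampling volume
#'
#' Rectangular prism anchored at the catheter venous tip over which the
#' shear-stress burden is evaluated. `length` extends into the chamber from
#' the tip, `width` along the wall (centred on the venous port, wide enough
#' to enclose all venous orifices), and `height` out of plane.
#'
#' @param length,width,height prism dimensions [mm].
#' @return Object of class `tip_volume`.
#' @export
tip_volume <- function(length, width, height) {
  if (min(length, width, height) <= 0) {
    stop("tip volume dimensions must be positive", call. = FALSE)
  }
  structure(list(length = length, width = width, height = height),
            class = "tip_volume")
}

# Table of per-design defaults: operating points and tip prisms.
catheter_design_defaults <- function(design) {
  switch(design,
    A = list(label = "A_step_sideholes", tip_length = 290, outer_diameter = 15.5,
             lumen_area = 7.8, arterial_pressure = -250, arterial_flow = 350,
             side_hole_count = 2, tip_gap = 10,
             tip = tip_volume(4.5, 25, 6), mode = "reverse"),
    B = list(label = "B_step", tip_length = 290, outer_diameter = 15.5,
             lumen_area = 7.8, arterial_pressure = -250, arterial_flow = 380,
             side_hole_count = 0, tip_gap = 10,
             tip = tip_volume(8, 10, 6), mode = "reverse"),
    C = list(label = "C_split", tip_length = 152, outer_diameter = 15,
             lumen_area = 3.5, arterial_pressure = -250, arterial_flow = 360,
             side_hole_count = 0, tip_gap = 14,
             tip = tip_volume(7, 7, 7), mode = "standard"),
    D = list(label = "D_symmetric", tip_length = 240, outer_diameter = 16,
             lumen_area = 7.8, arterial_pressure = -188, arterial_flow = 370,
             side_hole_count = 0, tip_gap = 4,
             tip = tip_volume(13, 9, 5.5), mode = "standard"),
    stop(sprintf("unknown catheter design '%s'", design), call. = FALSE))
}

#' Catheter configuration
#'
#' Describes one of four tip designs: A (step tip with side holes), B (step
#' tip), C (split tip), D (symmetric tip), together with its operating point
#' and placement. Dimension defaults per design: tip length 290/290/152/240
#' mm, outer diameter 15.5/15.5/15/16 Fr, lumen area 7.8/7.8/3.5/7.8 mm^2
#' for A/B/C/D; arterial gauge pressures -250 mmHg (A, B, C) and -188 mmHg
#' (D) with achieved arterial flows 350/380/360/370 ml/min; tip prisms
#' 4.5x25x6, 8x10x6, 7x7x7 and 13x9x5.5 mm. Step designs default to reverse
#' mode (venous and arterial lumens swapped relative to their as-built
#' roles).
#'
#' @param design `"A"`, `"B"`, `"C"` or `"D"`.
#' @param operating a [catheter_operating_point()]; defaults per design.
#' @param tip_position `"position1"` (mid chamber), `"position2"` (tip
#'   translated toward the wall) or `"position3"` (tip rotated about its
#'   axis; asymmetric-tip designs only).
#' @param tip_gap along-wall distance between the venous exit and the
#'   arterial intake [mm]; defaults per design.
#' @param side_hole_count number of side holes (design A only).
#' @param tip a [tip_volume()]; defaults per design.
#' @param tip_length,outer_diameter,lumen_area overrides of the design
#'   dimensions [mm, Fr, mm^2].
#' @return Object of class `catheter_config`.
#' @export
catheter_config <- function(design = c("A", "B", "C", "D"),
                            operating = NULL,
                            tip_position = c("position1", "position2",
                                             "position3"),
                            tip_gap = NULL,
                            side_hole_count = NULL,
                            tip = NULL,
                            tip_length = NULL, outer_diameter = NULL,
                            lumen_area = NULL) {
  design <- match.arg(design)
  tip_position <- match.arg(tip_position)
  d <- catheter_design_defaults(design)
  if (is.null(operating)) {
    operating <- catheter_operating_point(
      arterial_gauge_pressure = d$arterial_pressure,
      arterial_flow = d$arterial_flow, mode = d$mode)
  }
  side_hole_count <- side_hole_count %||% d$side_hole_count
  if (design != "A" && side_hole_count > 0) {
    stop("side holes are only defined for design A", call. = FALSE)
  }
  if (tip_position == "position3" && design == "D") {
    stop("position3 (tip rotation) is undefined for the symmetric design D",
         call. = FALSE)
  }
  la <- lumen_area %||% d$lumen_area
  if (!(la > 0)) stop("lumen_area must be positive", call. = FALSE)
  structure(
    list(design = design, label = d$label,
         tip_length = tip_length %||% d$tip_length,
         outer_diameter = outer_diameter %||% d$outer_diameter,
         lumen_area = la,
         operating = operating, tip_position = tip_position,
         tip_gap = tip_gap %||% d$tip_gap,
         side_hole_count = side_hole_count,
         tip = tip %||% d$tip),
    class = "catheter_config")
}

#' @export
print.catheter_config <- function(x, ...) {
  cat(sprintf("Catheter %s (%s), %s, %s mode\n", x$design, x$label,
              x$tip_position, x$operating$mode))
  cat(sprintf("  lumen area %g mm^2, venous flow %g ml/min, arterial flow %g ml/min\n",
              x$lumen_area, x$operating$venous_flow, x$operating$arterial_flow))
  cat(sprintf("  tip volume %g x %g x %g mm\n",
              x$tip$length, x$tip$width, x$tip$height))
  invisible(x)
}

#' Jet speed through a lumen
#'
#' Mean exit velocity `Q / A` for a lumen flow `Q` [ml/min] through a lumen
#' area `A` [mm^2].
#'
#' @param flow_mlmin lumen flow [ml/min].
#' @param lumen_area_mm2 lumen cross-section [mm^2].
#' @return Velocity [m/s].
#' @export
lumen_jet_speed <- function(flow_mlmin, lumen_area_mm2) {
  convert_units(flow_mlmin, "mlmin_to_m3s") / (lumen_area_mm2 * 1e-6)
}

#' Insert a catheter into the chamber geometry
#'
#' Represents the catheter by boundary source/sink patches on the top wall
#' (the catheter enters through the SVC side of the chamber): a venous jet
#' patch with prescribed inflow `venous_flow` across the lumen area (jet
#' speed `Q/A`), an arterial sink patch with prescribed outflow at the
#' design's operating flow, and, for design A, side-hole sub-patches that
#' split the venous flow (default: half through the end hole, half through
#' the side holes). `position2` translates the tip toward the right wall;
#' `position3` mirrors the tip arrangement about its axis. Reverse mode
#' swaps the along-wall ordering of the venous and arterial ports.
#'
#' @param geom a [chamber_geometry()].
#' @param catheter a [catheter_config()].
#' @param end_hole_fraction fraction of venous flow through the end hole
#'   when side holes are present.
#' @return The geometry with catheter patches added and the catheter
#'   recorded in `$catheter`.
#' @export
place_catheter <- function(geom, catheter, end_hole_fraction = 0.5) {
  stopifnot(inherits(geom, "chamber_geometry"),
            inherits(catheter, "catheter_config"))
  if (geom$kind != "chamber") {
    stop("catheters can only be placed in a chamber geometry", call. = FALSE)
  }
  op <- catheter$operating
  h <- geom$h
  A_lumen <- catheter$lumen_area * 1e-6            # m^2
  gap <- catheter$tip_gap * 1e-3                   # m
  center <- switch(catheter$tip_position,
                   position1 = 0.50 * geom$Lx,
                   position2 = 0.78 * geom$Lx,
                   position3 = 0.50 * geom$Lx)
  # along-wall offsets of the venous exit and arterial intake
  off <- c(venous = -gap / 2, arterial = +gap / 2)
  if (op$mode == "reverse") off <- -off
  if (catheter$tip_position == "position3") off <- -off  # mirrored tip
  Q_v <- convert_units(op$venous_flow, "mlmin_to_m3s")
  Q_a <- convert_units(op$arterial_flow, "mlmin_to_m3s")
  jet <- Q_v / A_lumen
  n_sh <- catheter$side_hole_count
  if (n_sh > 0) {
    f_end <- end_hole_fraction
    # side holes split the remaining flow equally; equal jet speed is kept by
    # giving each sub-patch an area proportional to its flow share
    A_end <- A_lumen * f_end
    A_sh <- A_lumen * (1 - f_end) / n_sh
    geom <- add_port(geom, "cath_venous", center + off["venous"],
                     A_end, "catheter_venous", flow = Q_v * f_end)
    sh_span <- 3e-3  # side holes sit proximal of the end hole
    away <- sign(off["venous"] - off["arterial"])  # away from the intake
    for (s in seq_len(n_sh)) {
      geom <- add_port(geom, paste0("cath_side_", s),
                       center + off["venous"] + away * s * sh_span,
                       A_sh, "catheter_venous",
                       flow = Q_v * (1 - f_end) / n_sh)
    }
  } else {
    geom <- add_port(geom, "cath_venous", center + off["venous"],
                     A_lumen, "catheter_venous", flow = Q_v)
  }
  geom <- add_port(geom, "cath_arterial", center + off["arterial"],
                   A_lumen, "catheter_arterial", flow = Q_a)
  check_patches_disjoint(geom)
  geom$catheter <- catheter
  geom$jet_speed <- jet
  geom
}

# a catheter port on the top wall: slot of >= 1 faces whose total area is the
# lumen sub-area, so the prescribed normal speed flow/area reproduces the
# lumen flow exactly
add_port <- function(geom, name, center_x, area, kind, flow) {
  w <- sqrt(area)  # near-square orifice footprint
  add_slot_patch(geom, name, "ymax", center_x, w, area = area,
                 kind = kind, flow = flow)
}

#' @export
print.chamber_geometry <- function(x, ...) {
  cat(sprintf("%s geometry: %g x %g m, h = %g m (%d x %d cells)\n",
              x$kind, x$Lx, x$Ly, x$h, x$nx, x$ny))
  for (p in x$patches) {
    cat(sprintf("  patch %-14s %-17s side %-4s %2d faces, area %.4g m^2\n",
                p$name, paste0("(", p$kind, ")"), p$side, length(p$faces),
                p$area))
  }
  if (!is.null(x$catheter)) {
    cat(sprintf("  catheter %s at %s, jet speed %.3g m/s\n",
                x$catheter$design, x$catheter$tip_position, x$jet_speed))
  }
  invisible(x)
}
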