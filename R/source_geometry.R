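# TG-43 coordinate convention: origin at the geometric centre of the active
# core, z axis along the source axis with +z toward the distal capsule tip
# (the cable sits at theta near 180 deg); theta is the polar angle from +z,
# r the distance from the origin in cm.  Reference point: r0 = 1 cm,
# theta0 = 90 deg.

#' TG-43 reference coordinates
#' @export
tg43_reference <- function() list(r0_cm = 1, theta0_deg = 90)

#' Geometric model of the HDR source
#'
#' Nested finite cylinders: an iridium core (0.6 mm diameter, 3.5 mm long)
#' inside an AISI 316L capsule (0.9 mm outer diameter) with a flat distal tip,
#' and a 6 cm AISI 304 cylinder for the proximal drive cable.  The capsule tip
#' and proximal thicknesses and the cable dimensions are configurable; the
#' defaults follow the published engineering drawing of the source.  All
#' lengths in cm.  Points on a region boundary belong to the inner region.
#'
#' @param core_radius,core_length iridium core (default 0.03 and 0.35).
#' @param capsule_radius capsule outer radius (default 0.045).
#' @param tip_thickness distal steel thickness along the axis (default 0.062).
#' @param proximal_thickness proximal steel between core and cable (default 0.040).
#' @param cable_radius,cable_length drive cable (defaults 0.045 and 6).
#' @param bare if `TRUE` the source structure is removed entirely
#'   (verification runs with a bare point source).
#' @return an object of class `source_model`.
#' @export
source_model <- function(core_radius = 0.03, core_length = 0.35,
                         capsule_radius = 0.045, tip_thickness = 0.062,
                         proximal_thickness = 0.040, cable_radius = 0.045,
                         cable_length = 6, bare = FALSE) {
  stopifnot(core_length > 0, core_radius > 0)
  if (core_radius >= capsule_radius) {
    stop("core radius must be smaller than the capsule outer radius",
         call. = FALSE)
  }
  structure(list(core_radius = core_radius, core_length = core_length,
                 capsule_radius = capsule_radius, tip_thickness = tip_thickness,
                 proximal_thickness = proximal_thickness,
                 cable_radius = cable_radius, cable_length = cable_length,
                 bare = bare), class = "source_model")
}

#' Phantom specification
#'
#' @param medium `"water"` (80 cm cube by default), `"air"` (sphere, 150 cm
#'   radius by default) or `"vacuum"` (sphere).
#' @param shape `"cube"` or `"sphere"`.
#' @param size half-width of the cube or radius of the sphere, cm.
#' @export
phantom_spec <- function(medium = c("water", "air", "vacuum"),
                         shape = NULL, size = NULL) {
  medium <- match.arg(medium)
  if (is.null(shape)) shape <- if (medium == "water") "cube" else "sphere"
  if (is.null(size)) size <- switch(medium, water = 40, air = 150, vacuum = 60)
  stopifnot(shape %in% c("cube", "sphere"), size > 0)
  structure(list(medium = medium, shape = shape, size = size,
                 vacuum = identical(medium, "vacuum")), class = "phantom_spec")
}

.material_names <- c("Ir", "316L", "304", NA, NA)  # indexed by region + 1

.region_to_material <- function(region, phantom) {
  out <- character(length(region))
  out[region == 0L] <- "Ir"
  out[region == 1L] <- "316L"
  out[region == 2L] <- "304"
  out[region == 3L] <- phantom$medium
  out[region < 0L] <- "outside"
  out
}

#' Sample emission positions uniformly in the core volume
#'
#' Inverse-CDF sampling in (rho^2, phi, z).
#'
#' @param n number of points.
#' @param model a `source_model`.
#' @param seed integer seed for the engine's own generator.
#' @return an `n x 3` matrix of (x, y, z) in cm.
#' @export
sample_core_position <- function(n, model = source_model(), seed = 1) {
  cpp_sample_core(as.integer(n), unclass(model), as.double(seed))
}

#' Trace material path segments along a ray
#'
#' Exact cylinder/plane intersections; returns the ordered list of
#' (material, length) segments from `origin` along `direction`, up to the
#' phantom boundary or up to `target` if given.  Segment lengths sum to the
#' ray length.
#'
#' @param origin,direction numeric length-3; direction need not be normalised
#'   but must be non-zero.
#' @param model a `source_model`; `phantom` a `phantom_spec`.
#' @param target optional end point of the ray.
#' @return data frame with `material` and `length` (cm); attribute
#'   `ray_length`.
#' @export
trace_path <- function(origin, direction, model = source_model(),
                       phantom = phantom_spec("water"), target = NULL) {
  res <- cpp_trace_path(as.double(origin), as.double(direction),
                        unclass(model), unclass(phantom),
                        if (is.null(target)) NULL else as.double(target))
  out <- data.frame(material = .region_to_material(res$material, phantom),
                    length = res$length, stringsAsFactors = FALSE)
  attr(out, "ray_length") <- res$ray_length
  out
}

#' Material at a point
#'
#' Consistent with [trace_path()]: boundary points belong to the inner region.
#'
#' @inheritParams trace_path
#' @param point numeric length-3, cm.
#' @export
locate_material <- function(point, model = source_model(),
                            phantom = phantom_spec("water")) {
  .region_to_material(cpp_locate(as.double(point), unclass(model),
                                 unclass(phantom)), phantom)
}
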