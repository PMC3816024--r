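#' Spherical cavity chamber scene
#'
#' Two concentric spheres centred at the origin: an air cavity of radius
#' `inner_radius` inside a graphite wall of outer radius `outer_radius`,
#' surrounded by ambient air, irradiated by a point source at
#' `(0, 0, -source_distance)`. The central electrode is not modelled.
#'
#' @param inner_radius,outer_radius cavity and wall outer radii, cm
#'   (0 < inner < outer).
#' @param wall_material,cavity_material,ambient_material [material()] objects;
#'   defaults are packaged graphite and air.
#' @param source_distance source-to-centre distance, cm (> `outer_radius`).
#' @param name label used in comparison tables.
#' @return An object of class `irk_chamber`.
#' @export
chamber_spec <- function(inner_radius, outer_radius,
                         wall_material = load_material("graphite"),
                         cavity_material = load_material("air"),
                         ambient_material = load_material("air"),
                         source_distance = 100, name = "chamber") {
  if (!(inner_radius > 0 && inner_radius < outer_radius)) {
    abort("need 0 < inner_radius < outer_radius")
  }
  if (source_distance <= outer_radius) {
    abort("source_distance must exceed outer_radius")
  }
  structure(
    list(name = name, inner_radius = inner_radius,
         outer_radius = outer_radius,
         wall_thickness = outer_radius - inner_radius,
         wall_material = wall_material, cavity_material = cavity_material,
         ambient_material = ambient_material,
         source_distance = source_distance),
    class = "irk_chamber")
}

#' @export
print.irk_chamber <- function(x, ...) {
  cat(sprintf(
    "<irk_chamber> %s: r_in %.3f cm, r_out %.3f cm (wall %.3f cm, %s %.3g g cm^-3), source at %.4g cm\n",
    x$name, x$inner_radius, x$outer_radius, x$wall_thickness,
    x$wall_material$name, x$wall_material$density, x$source_distance))
  invisible(x)
}

#' Packaged standard-chamber geometries
#'
#' The three spherical graphite primary-standard chambers compared in this
#' package, built from their published inner/outer radii and graphite
#' densities: the INER chamber (2.899/3.200 cm, 1.78 g cm^-3), the NIST
#' 50cc-1 chamber (2.305/2.670 cm, 1.73 g cm^-3), and the NPL chamber
#' (2.910/3.290 cm, 1.75 g cm^-3), each with a point source at 100 cm.
#'
#' @param source_distance source-to-centre distance, cm.
#' @return An `irk_chamber`.
#' @export
iner_chamber <- function(source_distance = 100) {
  chamber_spec(2.899, 3.200, load_material("graphite", density = 1.78),
               source_distance = source_distance, name = "INER")
}

#' @rdname iner_chamber
#' @export
nist_50cc1_chamber <- function(source_distance = 100) {
  chamber_spec(2.305, 2.670, load_material("graphite", density = 1.73),
               source_distance = source_distance, name = "NIST 50cc-1")
}

#' @rdname iner_chamber
#' @export
npl_chamber <- function(source_distance = 100) {
  chamber_spec(2.910, 3.290, load_material("graphite", density = 1.75),
               source_distance = source_distance, name = "NPL")
}

#' Encapsulated cylindrical source geometry
#'
#' The HDR Ir-192 source: a metallic iridium cylinder (the active core)
#' sealed inside a stainless-steel capsule. Dimensions default to the
#' microSelectron Classic source: core 3.5 mm long, 0.6 mm diameter;
#' capsule 5.0 mm long with 250 um radial wall.
#'
#' @param core_length,core_diameter active core dimensions, cm.
#' @param capsule_outer_length capsule length, cm.
#' @param capsule_radial_thickness capsule radial wall thickness, cm.
#' @param core_material,capsule_material [material()] objects.
#' @return An object of class `irk_capsule`.
#' @export
capsule_spec <- function(core_length = 0.35, core_diameter = 0.06,
                         capsule_outer_length = 0.50,
                         capsule_radial_thickness = 0.025,
                         core_material = load_material("iridium"),
                         capsule_material = load_material("steel316")) {
  dims <- c(core_length, core_diameter, capsule_outer_length,
            capsule_radial_thickness)
  if (any(dims <= 0)) abort("all capsule dimensions must be > 0")
  if (core_length > capsule_outer_length) {
    abort("core does not fit inside the capsule (length)")
  }
  structure(
    list(core_length = core_length, core_radius = core_diameter / 2,
         capsule_outer_length = capsule_outer_length,
         capsule_inner_radius = core_diameter / 2,
         capsule_outer_radius = core_diameter / 2 + capsule_radial_thickness,
         core_material = core_material, capsule_material = capsule_material),
    class = "irk_capsule")
}

#' Cylindrical phantom with an axial air cavity
#'
#' A PMMA cylinder (axis along z, base at z = 0) with a coaxial cylindrical
#' air cavity running its full height, emulating a body cavity (esophagus,
#' bronchus) holding a displaced brachytherapy source. Defaults: radius
#' 10 cm, height 14 cm, cavity radius 1 cm, source height 7 cm.
#'
#' @param radius,height phantom dimensions, cm.
#' @param cavity_radius axial cavity radius, cm (< `radius`).
#' @param body_material,cavity_material [material()] objects.
#' @param source_height height of the source plane, cm (inside the phantom).
#' @return An object of class `irk_phantom`.
#' @export
phantom_spec <- function(radius = 10, height = 14, cavity_radius = 1,
                         body_material = load_material("pmma"),
                         cavity_material = load_material("air"),
                         source_height = 7) {
  if (cavity_radius >= radius) abort("cavity_radius must be < radius")
  if (!(source_height > 0 && source_height < height)) {
    abort("source_height must lie inside the phantom height")
  }
  structure(
    list(radius = radius, height = height, cavity_radius = cavity_radius,
         body_material = body_material, cavity_material = cavity_material,
         source_height = source_height),
    class = "irk_phantom")
}

#' @export
print.irk_phantom <- function(x, ...) {
  cat(sprintf(
    "<irk_phantom> r %.3g cm, h %.3g cm, cavity r %.3g cm (%s body), source height %.3g cm\n",
    x$radius, x$height, x$cavity_radius, x$body_material$name,
    x$source_height))
  invisible(x)
}

#' Read and write scene specifications as YAML
#'
#' Scene specs serialize to a flat key-value YAML file (lengths in cm,
#' densities in g cm^-3); materials are stored by packaged name plus density.
#'
#' @param x an `irk_chamber` or `irk_phantom`.
#' @param path file path.
#' @export
write_scene_yaml <- function(x, path) {
  if (inherits(x, "irk_chamber")) {
    y <- list(kind = "chamber", name = x$name,
              inner_radius = x$inner_radius, outer_radius = x$outer_radius,
              source_distance = x$source_distance,
              wall_material = x$wall_material$name,
              wall_density = x$wall_material$density,
              cavity_material = x$cavity_material$name,
              ambient_material = x$ambient_material$name)
  } else if (inherits(x, "irk_phantom")) {
    y <- list(kind = "phantom", radius = x$radius, height = x$height,
              cavity_radius = x$cavity_radius,
              source_height = x$source_height,
              body_material = x$body_material$name,
              cavity_material = x$cavity_material$name)
  } else {
    abort("write_scene_yaml() supports chamber and phantom specs")
  }
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @rdname write_scene_yaml
#' @export
read_scene_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (identical(y$kind, "chamber")) {
    chamber_spec(y$inner_radius, y$outer_radius,
                 wall_material = load_material(y$wall_material,
                                               density = y$wall_density),
                 cavity_material = load_material(y$cavity_material),
                 ambient_material = load_material(y$ambient_material),
                 source_distance = y$source_distance, name = y$name)
  } else if (identical(y$kind, "phantom")) {
    phantom_spec(y$radius, y$height, y$cavity_radius,
                 body_material = load_material(y$body_material),
                 cavity_material = load_material(y$cavity_material),
                 source_height = y$source_height)
  } else {
    abort(sprintf("unknown scene kind '%s' in %s", y$kind %||% "?", path))
  }
}
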