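#' Beam geometry of a bistatic optical sensor
#'
#' Describes the probing laser beam: a circular cross-section of diameter
#' `beam_diameter` propagating over `path_length` between emitter and
#' receiver. The beam cross-section area `A` enters the extinction
#' cross-section retrieval and the probe volume `V = A * L` normalises
#' aerial density.
#'
#' Defaults correspond to a 50.8 mm beam over a 36 m emitter-receiver
#' separation.
#'
#' @param beam_diameter Beam diameter in meters.
#' @param path_length Emitter-to-receiver distance in meters.
#' @return An object of class `beam_geometry`: a list with elements
#'   `beam_diameter`, `path_length`, `area` (m^2) and `volume` (m^3).
#' @examples
#' g <- beam_geometry()
#' g$area    # pi * (0.0254)^2
#' g$volume  # area * 36
#' @export
beam_geometry <- function(beam_diameter = 0.0508, path_length = 36) {
  stopifnot_scalar(beam_diameter, "beam_diameter", positive = TRUE)
  stopifnot_scalar(path_length, "path_length", positive = TRUE)
  area <- pi * (beam_diameter / 2)^2
  structure(
    list(beam_diameter = beam_diameter, path_length = path_length,
         area = area, volume = area * path_length),
    class = "beam_geometry"
  )
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf("Beam geometry: d = %.4g m, L = %.4g m\n", x$beam_diameter,
              x$path_length))
  cat(sprintf("  cross-section area A = %.6g m^2\n", x$area))
  cat(sprintf("  probe volume       V = %.6g m^3\n", x$volume))
  invisible(x)
}

#' Probe volume surveyed by the sensor
#'
#' The air volume surveyed by the beam, `V = pi * (d/2)^2 * L`. All transit
#' occupancy is normalised by this volume when converting to aerial density.
#'
#' @param geometry A [beam_geometry()] object.
#' @return Probe volume in cubic meters.
#' @export
probe_volume <- function(geometry = beam_geometry()) {
  if (!inherits(geometry, "beam_geometry")) {
    stop("'geometry' must be a beam_geometry object")
  }
  geometry$volume
}
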