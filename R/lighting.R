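# Hemispherical diffuse sky, directed sun and the scenario sweep.
#
# Conventions: right-handed coordinates, z up, lengths in metres.  Altitude
# is measured from the horizon, azimuth clockwise from north (+y), so east
# is +x.  Sources are described by the direction *towards* the sky and by
# their horizontal-plane irradiance; the tracer converts to normal-plane
# irradiance internally.

#' Unit vector towards a sky position
#'
#' @param altitude_deg Altitude above the horizon, degrees.
#' @param azimuth_deg Azimuth clockwise from north (+y), degrees.
#' @return Length-3 unit vector with non-negative z.
#' @export
sky_direction <- function(altitude_deg, azimuth_deg) {
  a <- altitude_deg * pi / 180
  z <- azimuth_deg * pi / 180
  c(cos(a) * sin(z), cos(a) * cos(z), sin(a))
}

#' Discretized uniform-radiance sky hemisphere
#'
#' 108 directed sources at the centers of a 9 (altitude) x 12 (azimuth)
#' partition of the hemisphere.  Per-source horizontal irradiance follows
#' the closed-form cosine-projected solid angle of its segment under a
#' uniform (isotropic) sky radiance: a ring spanning altitudes
#' \[h0, h1\] carries (sin^2 h1 - sin^2 h0) / 2 of the total per unit
#' azimuth fraction, and the 12 segments of a ring share it equally.  The
#' horizontal irradiances sum to `E_diffuse` exactly.
#'
#' @param E_diffuse Total diffuse horizontal irradiance
#'   (micromol m-2 s-1; any non-negative scale).
#' @return A tibble of class `hemisphere_model` with columns `source_id`,
#'   `altitude_deg`, `azimuth_deg`, `E_horizontal`.
#' @export
#' @examples
#' hs <- build_hemisphere(350)
#' nrow(hs); sum(hs$E_horizontal)
build_hemisphere <- function(E_diffuse = 1) {
  stopifnot(E_diffuse >= 0)
  alt_edges <- seq(0, 90, by = 10)
  ring_w <- diff(sin(alt_edges * pi / 180)^2) / 2  # sums to 1/2
  ring_w <- ring_w / sum(ring_w)
  grid <- expand.grid(azimuth_deg = seq(15, 345, by = 30),
                      altitude_deg = seq(5, 85, by = 10))
  grid$E_horizontal <- E_diffuse *
    ring_w[match(grid$altitude_deg, seq(5, 85, by = 10))] / 12
  out <- tibble::tibble(source_id = seq_len(nrow(grid)),
                        altitude_deg = grid$altitude_deg,
                        azimuth_deg = grid$azimuth_deg,
                        E_horizontal = grid$E_horizontal)
  structure(out, class = c("hemisphere_model", class(out)),
            E_diffuse = E_diffuse)
}

#' Horizontal-plane irradiance of a directed source
#'
#' @param E_normal Irradiance on a plane normal to the beam.
#' @param altitude_deg Source altitude, degrees.
#' @return `E_normal * sin(altitude)`.
#' @export
direct_horizontal_irradiance <- function(E_normal, altitude_deg) {
  E_normal * sin(altitude_deg * pi / 180)
}

#' The 360-scenario lighting sweep
#'
#' Cartesian product of direct fraction (0.1 to 1.0 in steps of 0.1), sun
#' azimuth (0, 90, 180, 270 degrees) and sun altitude (10 to 90 degrees in
#' 10-degree steps), with constant global horizontal irradiance
#' `E_global = E_diffuse + E_direct` and identical relative (D65 photon)
#' spectra for both components.  The pure-diffuse case is not part of the
#' 360 combinations (the sun direction is then meaningless); obtain it
#' separately with [pure_diffuse_scenario()].
#'
#' @param E_global Global horizontal irradiance (default 1000
#'   micromol m-2 s-1; all reported statistics are scale-free).
#' @return A tibble with one row per scenario: `scenario_id`, `q_direct`,
#'   `sun_azimuth_deg`, `sun_altitude_deg`, `E_global`, `E_direct`,
#'   `E_diffuse`.
#' @export
#' @examples
#' nrow(scenario_sweep())
scenario_sweep <- function(E_global = 1000) {
  stopifnot(E_global > 0)
  g <- expand.grid(q_direct = (1:10) / 10,
                   sun_azimuth_deg = c(0, 90, 180, 270),
                   sun_altitude_deg = seq(10, 90, by = 10))
  g <- g[order(g$q_direct, g$sun_azimuth_deg, g$sun_altitude_deg), ]
  tibble::tibble(scenario_id = sprintf("q%03.0f_az%03d_alt%02d",
                                       g$q_direct * 100,
                                       g$sun_azimuth_deg,
                                       g$sun_altitude_deg),
                 q_direct = g$q_direct,
                 sun_azimuth_deg = g$sun_azimuth_deg,
                 sun_altitude_deg = g$sun_altitude_deg,
                 E_global = E_global,
                 E_direct = g$q_direct * E_global,
                 E_diffuse = (1 - g$q_direct) * E_global)
}

#' @rdname scenario_sweep
#' @export
pure_diffuse_scenario <- function(E_global = 1000) {
  tibble::tibble(scenario_id = "q000", q_direct = 0,
                 sun_azimuth_deg = NA_real_, sun_altitude_deg = NA_real_,
                 E_global = E_global, E_direct = 0, E_diffuse = E_global)
}

#' Write a scenario table CSV
#'
#' @param scenarios A scenario tibble.
#' @param path Output path.
#' @export
write_scenarios_csv <- function(scenarios, path) {
  readr::write_csv(
    scenarios[c("scenario_id", "q_direct", "sun_azimuth_deg",
                "sun_altitude_deg", "E_global")], path)
  invisible(path)
}

# All active sources of a scenario as one table: the 108 sky segments
# scaled to E_diffuse plus (for q > 0) the sun.  Used by the tracer.
scenario_sources <- function(scenario) {
  stopifnot(nrow(scenario) == 1)
  sky <- build_hemisphere(scenario$E_diffuse)
  src <- tibble::tibble(altitude_deg = sky$altitude_deg,
                        azimuth_deg = sky$azimuth_deg,
                        E_horizontal = sky$E_horizontal)
  if (scenario$q_direct > 0) {
    src <- dplyr::bind_rows(src, tibble::tibble(
      altitude_deg = scenario$sun_altitude_deg,
      azimuth_deg = scenario$sun_azimuth_deg,
      E_horizontal = scenario$E_direct))
  }
  src[src$E_horizontal > 0, , drop = FALSE]
}
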