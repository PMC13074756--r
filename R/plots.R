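# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot spectral leaf optics
#'
#' Reflectance-related parameters per bin and side; for Phong optics the
#' hemispherical reflectance at the 40-degree anchor is shown alongside
#' kd, ks and tau.
#'
#' @param object A `leaf_optics` table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.leaf_optics <- function(object, ...) {
  if (optics_mode(object) == "phong") {
    d40 <- dhr(object, 40)
    df <- tibble::as_tibble(object) |>
      dplyr::mutate(dhr40 = d40$dhr) |>
      tidyr::pivot_longer(dplyr::all_of(c("kd", "ks", "tau", "dhr40")),
                          names_to = "parameter")
  } else {
    df <- tibble::as_tibble(object) |>
      tidyr::pivot_longer(dplyr::all_of(c("rho", "tau")),
                          names_to = "parameter")
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$bin_center_nm, .data$value,
                                   colour = .data$parameter)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~side) +
    ggplot2::labs(x = "wavelength (nm)", y = "value",
                  title = "Spectral leaf optics") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.leaf_optics
#' @export
autoplot.phong_fit <- function(object, ...) {
  df <- object$fit |>
    tidyr::pivot_longer(dplyr::all_of(c("nrmse_phong", "nrmse_diffuse")),
                        names_to = "model", values_to = "nrmse") |>
    dplyr::mutate(model = sub("nrmse_", "", .data$model))
  ggplot2::ggplot(df, ggplot2::aes(.data$bin_center_nm, .data$nrmse,
                                   colour = .data$model)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~side) +
    ggplot2::labs(x = "wavelength (nm)", y = "NRMSE",
                  title = "Phong vs diffuse model fit error") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.leaf_optics
#' @export
autoplot.tally_result <- function(object, ...) {
  df <- object$absorbed |>
    dplyr::group_by(.data$leaf_order, .data$bin_center_nm) |>
    dplyr::summarise(flux = sum(.data$flux), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$bin_center_nm, .data$flux,
                                   colour = factor(.data$leaf_order))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)",
                  y = "absorbed photon flux (µmol s⁻¹)",
                  colour = "leaf order",
                  title = sprintf("Absorbed spectral photon flux (%s)",
                                  object$meta$scenario_id)) +
    ggplot2::theme_minimal()
}

#' In-plane radiant intensity plot
#'
#' Normalized radiant intensity I = cos(theta_r) * f for one or more
#' optics rows at a fixed incidence angle, the standard way to visualize
#' how strongly a leaf BRDF departs from the diffuse cosine lobe.
#'
#' @param optics A Phong `leaf_optics` table.
#' @param bins Bin centers to show (default: 445, 555, 655, 735 nm).
#' @param side Leaf side.
#' @param theta_i_deg Incidence angle.
#' @return A ggplot.
#' @export
plot_radiant_intensity <- function(optics, bins = c(445, 555, 655, 735),
                                   side = "adaxial", theta_i_deg = 40) {
  df <- purrr::map_dfr(bins, function(b) {
    r <- optics_row(optics, b, side)
    radiant_intensity_profile(r$kd, r$ks, r$n_exp, theta_i_deg) |>
      dplyr::mutate(bin_center_nm = b,
                    intensity = .data$intensity / max(.data$intensity))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$theta_r_deg, .data$intensity,
                                   colour = factor(.data$bin_center_nm))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = theta_i_deg, linetype = 3) +
    ggplot2::labs(x = "reflection angle (deg)",
                  y = "normalized radiant intensity",
                  colour = "bin (nm)",
                  title = sprintf("Radiant intensity at %g deg incidence",
                                  theta_i_deg)) +
    ggplot2::theme_minimal()
}

#' Plot grouped MAPE results from a study bundle
#'
#' @param bundle A `study_bundle`.
#' @param dimension Grouping column, e.g. "leaf_order" or "q_direct".
#' @return A ggplot.
#' @export
plot_mape <- function(bundle, dimension = "q_direct") {
  df <- bundle$metrics$mape_sensor_band |>
    dplyr::group_by(.data$band, .data$side,
                    dplyr::across(dplyr::all_of(dimension))) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data[[dimension]], .data$mean,
                                   colour = .data$band)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se),
                             size = 0.2) +
    ggplot2::facet_wrap(~side) +
    ggplot2::labs(y = "MAPE (%)",
                  title = "Phong vs diffuse deviation of sensor flux") +
    ggplot2::theme_minimal()
}
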