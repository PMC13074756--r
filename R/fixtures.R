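# Packaged cucumber-like leaf optics and gonioreflectometer-style sample
# synthesis.
#
# The fixture curves are synthetic stand-ins shaped like measured cucumber
# leaf optics: strong pigment absorption in blue and red (low reflectance
# and transmittance), weak absorption in green, and very weak absorption
# beyond the red edge (far-red highest), with the specular share of
# reflectance largest where the diffuse (subsurface) component is most
# strongly absorbed, i.e. in blue and red.

logistic <- function(x) 1 / (1 + exp(-x))

fixture_rho_curve <- function(wl, side) {
  base <- 0.055 +
    0.105 * exp(-((wl - 552) / 34)^2) +
    0.40 * logistic((wl - 712) / 9)
  if (side == "abaxial") pmin(base * 1.12, 0.5) else base
}

fixture_tau_curve <- function(wl, side) {
  0.042 +
    0.135 * exp(-((wl - 558) / 38)^2) +
    0.42 * logistic((wl - 714) / 9)
}

# surface (wax) specular weight: largest in blue, secondary bump in red,
# smallest in green/far-red where subsurface diffuse scattering dominates
fixture_ks_curve <- function(wl, side) {
  base <- 0.016 + 0.014 * exp(-((wl - 460) / 40)^2) +
    0.008 * exp(-((wl - 660) / 40)^2)
  if (side == "abaxial") 0.6 * base else base
}

#' Packaged cucumber-like leaf and stem optics
#'
#' Returns the synthetic reference optics used throughout the package's
#' simulations and tests: a Phong parameter table per bin and leaf side,
#' its spectrally equivalent diffuse table (Lambertian reflectance matched
#' to DHR at 40 degrees), and a broadband stem reflectance (stems are
#' non-transmitting).  Hemispherical reflectance plus transmittance is
#' ordered far-red > green > red >= blue, and the specular fraction
#' ks/(kd+ks) is largest in blue and red.
#'
#' @param grid Spectral grid (default 30 x 10 nm over 440-740 nm).
#' @return List with `phong` ([phong_optics()]), `diffuse`
#'   ([diffuse_optics()]), `stem_reflectance` (scalar).
#' @export
#' @examples
#' fx <- fixture_optics()
#' head(fx$phong)
fixture_optics <- function(grid = spectral_grid()) {
  rows <- list()
  for (side in c("adaxial", "abaxial")) {
    wl <- grid$centers
    rho <- fixture_rho_curve(wl, side)     # target DHR at 40 degrees
    tau <- fixture_tau_curve(wl, side)
    ks <- fixture_ks_curve(wl, side)
    n_exp <- rep(if (side == "adaxial") 15 else 7, length(wl))
    a40 <- vapply(n_exp, lobe_albedo, numeric(1), theta_i_deg = 40)
    kd <- pmax(0, rho - ks * a40)
    rows[[side]] <- tibble::tibble(
      bin_center_nm = wl, side = side,
      kd = kd, ks = ks, n_exp = n_exp, tau = tau)
  }
  phong <- phong_optics(dplyr::bind_rows(rows))
  list(phong = phong,
       diffuse = diffuse_equivalent(phong),
       stem_reflectance = 0.18)
}

#' Synthesize a gonioreflectometer-style BRDF sample set
#'
#' Evaluates the true Phong optics on a factorial angle grid and applies
#' multiplicative Gaussian noise, emulating the structure of a
#' gonioreflectometer measurement campaign.  The per-bin reference
#' hemispherical reflectance is the exact DHR of the truth at 40 degrees,
#' so the truth parameters lie inside the constrained family that
#' [fit_phong()] searches.
#'
#' @param truth A Phong [phong_optics()] table.
#' @param theta_i_deg,theta_r_deg,phi_r_deg Angle grid (crossed).
#' @param noise_sd Relative noise standard deviation (>= 0).
#' @return A [brdf_samples()] set.
#' @export
synth_gonio_fixture <- function(truth,
                                theta_i_deg = c(20, 40, 60),
                                theta_r_deg = seq(0, 80, by = 10),
                                phi_r_deg = c(0, 45, 90, 135, 180),
                                noise_sd = 0) {
  stopifnot(optics_mode(truth) == "phong", noise_sd >= 0)
  ang <- expand.grid(theta_i_deg = theta_i_deg, theta_r_deg = theta_r_deg,
                     phi_r_deg = phi_r_deg)
  samples <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    r <- truth[i, ]
    cos_a <- cos_alpha_gonio(ang$theta_i_deg, ang$theta_r_deg, ang$phi_r_deg)
    f <- r$kd / pi + r$ks * (r$n_exp + 2) / (2 * pi) * cos_a^r$n_exp
    f <- pmax(0, f * (1 + rnorm(length(f), 0, noise_sd)))
    tibble::tibble(bin_center_nm = r$bin_center_nm, side = r$side,
                   theta_i_deg = ang$theta_i_deg,
                   theta_r_deg = ang$theta_r_deg,
                   phi_r_deg = ang$phi_r_deg,
                   brdf_sr_inv = f)
  })
  d40 <- dhr(truth, 40)
  rho_ref <- tibble::tibble(bin_center_nm = d40$bin_center_nm,
                            side = d40$side, rho_ref = d40$dhr)
  tau <- truth |>
    tibble::as_tibble() |>
    dplyr::select(dplyr::all_of(c("bin_center_nm", "side", "tau")))
  brdf_samples(samples, rho_ref, tau)
}
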