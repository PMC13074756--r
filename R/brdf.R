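# Modified-Phong leaf BRDF: evaluation, hemispherical integrals and
# interaction sampling.
#
# The BRDF model is the energy-normalized modified Phong form
#
#   f(wi, wo) = kd/pi + ks * (n+2)/(2*pi) * max(0, cos(alpha))^n
#
# with alpha the angle between wo and the mirror direction of wi.  It is
# reciprocal, and at normal incidence its directional-hemispherical
# reflectance (DHR) is exactly kd + ks.  At oblique incidence part of the
# specular lobe dips below the horizon, so DHR(theta_i) = kd + ks * A(n,
# theta_i) with A <= 1 the above-horizon energy fraction of the lobe.

# ---- direction helpers (leaf-local frame, surface normal = +z) ------------

#' Unit direction from zenith / azimuth angles
#'
#' @param theta_deg Polar angle from the surface normal, degrees.
#' @param phi_deg Azimuth in the surface plane, degrees.
#' @return Numeric length-3 unit vector in the local frame (normal = +z).
#' @export
dir_from_angles <- function(theta_deg, phi_deg = 0) {
  th <- theta_deg * pi / 180
  ph <- phi_deg * pi / 180
  c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}

mirror_dir <- function(w) c(-w[1], -w[2], w[3])

# ---- optics containers ----------------------------------------------------

#' Per-bin, per-side leaf optical parameter tables
#'
#' `phong_optics()` holds, for each spectral bin and each leaf side
#' (adaxial/abaxial): `kd` (hemispherical albedo of the diffuse term), `ks`
#' (specular lobe weight), `n_exp` (Phong shininess) and `tau` (diffuse
#' transmittance).  `diffuse_optics()` holds `rho` (Lambertian reflectance)
#' and `tau`.  Both validate non-negativity and energy closure: reflected
#' plus transmitted fraction may not exceed 1 (a small tolerance, 1% up to
#' 40 degrees incidence and 6% at grazing angles, absorbs the mild
#' energy-conservation slack inherent to the Phong lobe).
#'
#' @param tbl A data frame with columns `bin_center_nm`, `side`, and `kd`,
#'   `ks`, `n_exp`, `tau` (Phong) or `rho`, `tau` (diffuse).
#' @param check Validate energy closure (default TRUE).
#' @return A tibble of class `leaf_optics` with attribute `mode`.
#' @export
phong_optics <- function(tbl, check = TRUE) {
  need <- c("bin_center_nm", "side", "kd", "ks", "n_exp", "tau")
  stopifnot(all(need %in% names(tbl)))
  out <- tibble::as_tibble(tbl[need])
  stopifnot(all(out$kd >= 0), all(out$ks >= 0), all(out$tau >= 0),
            all(out$n_exp >= 0))
  out <- structure(out, class = c("leaf_optics", class(out)), mode = "phong")
  if (check) validate_optics(out)
  out
}

#' @rdname phong_optics
#' @export
diffuse_optics <- function(tbl, check = TRUE) {
  need <- c("bin_center_nm", "side", "rho", "tau")
  stopifnot(all(need %in% names(tbl)))
  out <- tibble::as_tibble(tbl[need])
  stopifnot(all(out$rho >= 0), all(out$tau >= 0))
  if (check && any(out$rho + out$tau > 1 + 1e-9)) {
    stop("diffuse optics violate rho + tau <= 1")
  }
  structure(out, class = c("leaf_optics", class(out)), mode = "diffuse")
}

optics_mode <- function(optics) attr(optics, "mode")

validate_optics <- function(optics, theta_grid = seq(0, 85, by = 5)) {
  if (optics_mode(optics) == "diffuse") {
    if (any(optics$rho + optics$tau > 1 + 1e-9)) {
      stop("diffuse optics violate rho + tau <= 1")
    }
    return(invisible(optics))
  }
  for (i in seq_len(nrow(optics))) {
    a <- lobe_albedo(optics$n_exp[i], theta_grid)
    dhr <- optics$kd[i] + optics$ks[i] * a
    tot <- dhr + optics$tau[i]
    tol <- ifelse(theta_grid <= 40, 1.01, 1.06)
    if (any(tot > tol)) {
      stop(sprintf(
        "optics row %d (bin %g, %s) violates energy closure: DHR+tau = %.3f at theta_i = %g",
        i, optics$bin_center_nm[i], optics$side[i],
        max(tot), theta_grid[which.max(tot - tol)]))
    }
  }
  invisible(optics)
}

optics_row <- function(optics, bin_center_nm, side) {
  i <- which(abs(optics$bin_center_nm - bin_center_nm) < 1e-6 &
               optics$side == side)
  if (length(i) != 1) stop("no unique optics row for bin ", bin_center_nm,
                           ", side ", side)
  optics[i, ]
}

# ---- evaluation -----------------------------------------------------------

#' Evaluate the modified-Phong BRDF
#'
#' @param kd,ks,n_exp Phong parameters (see [phong_optics()]).
#' @param wi,wo Unit directions in the leaf-local frame (normal = +z), both
#'   pointing away from the surface and in the upper hemisphere.
#' @return BRDF value in 1/sr (vectorized over parameter vectors).
#' @export
#' @examples
#' phong_eval(0.3, 0, 10, dir_from_angles(40), dir_from_angles(20)) # 0.3/pi
phong_eval <- function(kd, ks, n_exp, wi, wo) {
  if (wi[3] <= 0 || wo[3] <= 0) {
    stop("wi and wo must lie in the upper hemisphere of the surface normal")
  }
  cos_a <- pmax(0, sum(wo * mirror_dir(wi)))
  kd / pi + ks * (n_exp + 2) / (2 * pi) * cos_a^n_exp
}

#' In-plane radiant intensity profile
#'
#' Radiant intensity I(theta_r) = cos(theta_r) * f(theta_r; theta_i) in the
#' plane of incidence.  The cosine projection shifts the specular peak of
#' the intensity curve towards the surface normal: for finite shininess the
#' argmax lies strictly between 0 and theta_i.
#'
#' @param kd,ks,n_exp Phong parameters.
#' @param theta_i_deg Incidence angle, degrees, in \[0, 90).
#' @param theta_r_deg Reflection angles at which to evaluate (default a
#'   0.5-degree grid over -90..90; negative = same side as the source,
#'   positive = specular side).
#' @return A tibble with `theta_r_deg`, `brdf`, `intensity`.
#' @export
radiant_intensity_profile <- function(kd, ks, n_exp, theta_i_deg,
                                      theta_r_deg = seq(-90, 90, by = 0.5)) {
  stopifnot(theta_i_deg >= 0, theta_i_deg < 90)
  wi <- dir_from_angles(theta_i_deg, 180)  # source azimuth 180: mirror at phi 0
  f <- vapply(theta_r_deg, function(tr) {
    wo <- dir_from_angles(abs(tr), if (tr >= 0) 0 else 180)
    if (wo[3] <= 0) wo[3] <- 1e-12
    phong_eval(kd, ks, n_exp, wi, wo)
  }, numeric(1))
  tibble::tibble(
    theta_r_deg = theta_r_deg,
    brdf = f,
    intensity = cos(pmin(abs(theta_r_deg), 90) * pi / 180) * f
  )
}

# ---- hemispherical integrals ----------------------------------------------

# Gauss-Legendre nodes/weights on [a, b] (Golub-Welsch via symmetric
# tridiagonal eigendecomposition; deterministic, no external dependency).
# Memoized per order since the same rule is reused across bins and angles.
.gl_cache <- new.env(parent = emptyenv())

gauss_legendre <- function(n, a = 0, b = 1) {
  stopifnot(n >= 2)
  key <- as.character(n)
  cached <- .gl_cache[[key]]
  if (!is.null(cached)) {
    return(list(nodes = (b - a) / 2 * cached$x + (a + b) / 2,
                weights = (b - a) / 2 * cached$w))
  }
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  .gl_cache[[key]] <- list(x = x[ord], w = w[ord])
  list(nodes = (b - a) / 2 * x[ord] + (a + b) / 2,
       weights = (b - a) / 2 * w[ord])
}

#' Above-horizon energy fraction of the Phong lobe
#'
#' A(n, theta_i) is the fraction of the energy-normalized specular lobe
#' (including the outgoing cosine projection) that lands above the surface
#' horizon when the mirror direction sits at zenith angle theta_i.  DHR of
#' the Phong BRDF is `kd + ks * A(n_exp, theta_i)`; A(n, 0) = 1.
#'
#' Computed by fixed-order quadrature in the lobe frame: substituting
#' v = cos(alpha)^(n+1) concentrates the nodes in the lobe so the same
#' order resolves shininess from 0.5 to 500.  Gauss-Legendre in v crossed
#' with a uniform (periodic trapezoid) azimuth rule.
#'
#' @param n_exp Shininess exponent (scalar).
#' @param theta_i_deg Incidence angle(s), degrees.
#' @param n_gl Gauss-Legendre order (>= 8).
#' @param n_az Azimuth nodes (>= 8).
#' @return Numeric vector of A values in \[0, 1\].
#' @export
lobe_albedo <- function(n_exp, theta_i_deg, n_gl = 64, n_az = 128) {
  if (n_gl < 8 || n_az < 8) stop("quadrature order too low")
  gl <- gauss_legendre(n_gl, 0, 1)
  cos_a <- gl$nodes^(1 / (n_exp + 1))
  sin_a <- sqrt(pmax(0, 1 - cos_a^2))
  beta <- (seq_len(n_az) - 0.5) / n_az * 2 * pi
  ti <- theta_i_deg * pi / 180
  vapply(ti, function(t) {
    # cos(theta_o) of a lobe direction (alpha, beta) around the mirror axis
    cz <- outer(cos_a, rep(cos(t), n_az)) -
      outer(sin_a, cos(beta)) * sin(t)
    mean_az <- rowMeans(pmax(cz, 0))
    (n_exp + 2) / (n_exp + 1) * sum(gl$weights * mean_az)
  }, numeric(1))
}

#' Directional-hemispherical reflectance of leaf optics
#'
#' @param optics A `leaf_optics` table.
#' @param theta_i_deg Incidence angle(s), degrees, in \[0, 90).
#' @param n_gl,n_az Quadrature orders passed to [lobe_albedo()].
#' @return A tibble `bin_center_nm, side, theta_i_deg, dhr`.
#' @export
#' @examples
#' op <- phong_optics(tibble::tibble(bin_center_nm = 555, side = "adaxial",
#'                                   kd = 0.2, ks = 0.1, n_exp = 50, tau = 0.1))
#' dhr(op, 0)  # kd + ks = 0.3
dhr <- function(optics, theta_i_deg, n_gl = 64, n_az = 128) {
  stopifnot(all(theta_i_deg >= 0), all(theta_i_deg < 90))
  rows <- lapply(seq_len(nrow(optics)), function(i) {
    r <- if (optics_mode(optics) == "diffuse") {
      rep(optics$rho[i], length(theta_i_deg))
    } else {
      optics$kd[i] +
        optics$ks[i] * lobe_albedo(optics$n_exp[i], theta_i_deg, n_gl, n_az)
    }
    tibble::tibble(bin_center_nm = optics$bin_center_nm[i],
                   side = optics$side[i],
                   theta_i_deg = theta_i_deg, dhr = r)
  })
  dplyr::bind_rows(rows)
}

#' Spectrally equivalent diffuse optics
#'
#' Replaces the Phong BRDF of each bin/side by the Lambertian reflectance
#' that reflects the same hemispherical fraction at the 40-degree
#' calibration incidence: rho = DHR(40 deg).  Transmittance is copied
#' unchanged.  This is the "diffuse equivalent" against which BRDF effects
#' are measured.
#'
#' @param optics A Phong `leaf_optics` table.
#' @param theta_anchor_deg Anchor incidence angle (default 40).
#' @return A diffuse `leaf_optics` table.
#' @export
diffuse_equivalent <- function(optics, theta_anchor_deg = 40) {
  stopifnot(optics_mode(optics) == "phong")
  d <- dhr(optics, theta_anchor_deg)
  out <- optics |>
    dplyr::mutate(rho = d$dhr) |>
    dplyr::select(dplyr::all_of(c("bin_center_nm", "side", "rho", "tau")))
  if (any(out$rho + out$tau > 1 + 1e-9)) {
    stop("diffuse equivalent violates rho + tau <= 1; input optics invalid")
  }
  diffuse_optics(out)
}

# ---- interaction sampling (reference implementation) ----------------------

# The compiled tracer re-implements this scheme; this R version is the
# readable reference used in tests for distributional checks.

sample_cosine_hemisphere <- function(u1, u2) {
  r <- sqrt(u1)
  ph <- 2 * pi * u2
  c(r * cos(ph), r * sin(ph), sqrt(1 - u1))
}

# Sample the outgoing direction of the specular branch: density proportional
# to cos(alpha)^n * cos(theta_o) above the horizon, by rejection from the
# bare cos^n lobe with acceptance probability cos(theta_o).
sample_phong_lobe <- function(n_exp, wm, max_tries = 1000) {
  # orthonormal frame around the mirror axis wm
  a <- if (abs(wm[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- a - sum(a * wm) * wm; t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(wm[2] * t1[3] - wm[3] * t1[2],
          wm[3] * t1[1] - wm[1] * t1[3],
          wm[1] * t1[2] - wm[2] * t1[1])
  for (k in seq_len(max_tries)) {
    ca <- runif(1)^(1 / (n_exp + 1))
    sa <- sqrt(1 - ca^2)
    ph <- 2 * pi * runif(1)
    d <- sa * cos(ph) * t1 + sa * sin(ph) * t2 + ca * wm
    if (d[3] > 0 && runif(1) < d[3]) return(d)
  }
  stop("phong lobe sampling failed to accept")
}

#' Sample one photon-surface interaction event
#'
#' Given leaf optics for one bin/side and an incoming direction, samples
#' the interaction outcome of an analog photon: diffuse reflection (cosine
#' weighted), specular reflection (from the cos^n lobe about the mirror
#' direction, restricted above the horizon and cosine-projected),
#' Lambertian transmission into the opposite hemisphere, or absorption.
#' Event probabilities per bin are kd, ks * A(n, theta_i), tau and the
#' remainder, so the Monte-Carlo reflected fraction reproduces
#' [dhr()] exactly in expectation; specular energy clipped by the horizon
#' counts as absorbed.
#'
#' @param optics A `leaf_optics` table (Phong or diffuse).
#' @param bin_center_nm,side Which optics row to use.
#' @param wi Incoming direction (unit, upper hemisphere, pointing away from
#'   the surface).
#' @return A list with `event` (one of "diffuse", "specular", "transmit",
#'   "absorb") and `wo` (unit direction, or NULL for absorption;
#'   transmitted directions have negative z).
#' @export
sample_interaction <- function(optics, bin_center_nm, side, wi) {
  stopifnot(wi[3] > 0)
  row <- optics_row(optics, bin_center_nm, side)
  theta_i <- acos(pmin(1, wi[3])) * 180 / pi
  if (optics_mode(optics) == "diffuse") {
    p <- c(diffuse = row$rho, specular = 0, transmit = row$tau)
  } else {
    p <- c(diffuse = row$kd,
           specular = row$ks * lobe_albedo(row$n_exp, theta_i),
           transmit = row$tau)
  }
  if (sum(p) > 1 + 1e-9) stop("interaction probabilities exceed 1")
  u <- runif(1)
  cum <- cumsum(p)
  if (u < cum[1]) {
    list(event = "diffuse",
         wo = sample_cosine_hemisphere(runif(1), runif(1)))
  } else if (u < cum[2]) {
    list(event = "specular",
         wo = sample_phong_lobe(row$n_exp, mirror_dir(wi)))
  } else if (u < cum[3]) {
    d <- sample_cosine_hemisphere(runif(1), runif(1))
    list(event = "transmit", wo = c(d[1], d[2], -d[3]))
  } else {
    list(event = "absorb", wo = NULL)
  }
}
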