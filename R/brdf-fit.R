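# Per-wavelength fitting of the modified-Phong BRDF to
# gonioreflectometer-style sample sets.
#
# Geometry convention for tabulated samples: the incident direction lies at
# azimuth 180 deg, so its mirror direction sits at azimuth 0; `phi_r_deg` is
# the outgoing azimuth relative to that specular half-plane.  Hence
#   cos(alpha) = sin(theta_r) sin(theta_i) cos(phi_r) + cos(theta_r) cos(theta_i).

#' Assemble a BRDF sample set
#'
#' @param samples Tibble with columns `bin_center_nm`, `side`,
#'   `theta_i_deg`, `theta_r_deg`, `phi_r_deg`, `brdf_sr_inv`.
#' @param rho_ref Tibble with `bin_center_nm`, `side`, `rho_ref`: the
#'   measured hemispherical reflectance per bin at the 40-degree
#'   calibration incidence.
#' @param tau Optional tibble `bin_center_nm`, `side`, `tau` of diffuse
#'   transmittance (defaults to 0 for all bins).
#' @return A list of class `brdf_samples`.
#' @export
brdf_samples <- function(samples, rho_ref, tau = NULL) {
  need <- c("bin_center_nm", "side", "theta_i_deg", "theta_r_deg",
            "phi_r_deg", "brdf_sr_inv")
  stopifnot(all(need %in% names(samples)),
            all(c("bin_center_nm", "side", "rho_ref") %in% names(rho_ref)))
  if (any(samples$brdf_sr_inv < 0)) stop("BRDF samples must be non-negative")
  if (any(samples$theta_i_deg < 0 | samples$theta_i_deg > 90) ||
      any(samples$theta_r_deg < 0 | samples$theta_r_deg > 90)) {
    stop("angles out of range")
  }
  if (any(rho_ref$rho_ref < 0 | rho_ref$rho_ref > 1)) {
    stop("rho_ref must lie in [0, 1]")
  }
  if (is.null(tau)) {
    tau <- rho_ref |>
      dplyr::select(dplyr::all_of(c("bin_center_nm", "side"))) |>
      dplyr::mutate(tau = 0)
  }
  structure(list(samples = tibble::as_tibble(samples),
                 rho_ref = tibble::as_tibble(rho_ref),
                 tau = tibble::as_tibble(tau)),
            class = "brdf_samples")
}

#' @export
print.brdf_samples <- function(x, ...) {
  cat(sprintf("<brdf_samples: %d records, %d bin/side groups>\n",
              nrow(x$samples),
              nrow(unique(x$samples[c("bin_center_nm", "side")]))))
  invisible(x)
}

cos_alpha_gonio <- function(theta_i_deg, theta_r_deg, phi_r_deg) {
  ti <- theta_i_deg * pi / 180
  tr <- theta_r_deg * pi / 180
  pr <- phi_r_deg * pi / 180
  pmax(0, sin(tr) * sin(ti) * cos(pr) + cos(tr) * cos(ti))
}

# Least-squares objective for one bin/side group, parameterized so the
# DHR(anchor) = rho_ref constraint holds exactly:
#   ks = u * s_max(n) * rho_ref / A(n, anchor),  kd = rho_ref * (1 - u * s_max)
# with s_max(n) chosen so normal-incidence closure kd + ks + tau <= 1.01.
fit_one_bin <- function(f_meas, cos_a, rho_ref, tau, anchor_deg = 40,
                        n_starts = 5) {
  s_max_of <- function(a40) {
    if (rho_ref <= 0) return(0)
    excess <- rho_ref * (1 / a40 - 1)
    if (excess <= 1e-12) return(1)
    min(1, max(0, (1.01 - tau - rho_ref) / excess))
  }
  params_of <- function(u, logn) {
    u <- unname(u)
    n <- unname(exp(logn))
    a40 <- lobe_albedo(n, anchor_deg)
    s <- u * s_max_of(a40)
    ks <- s * rho_ref / a40
    kd <- rho_ref * (1 - s)
    list(kd = kd, ks = ks, n = n)
  }
  sse <- function(par) {
    p <- params_of(par[1], par[2])
    f_mod <- p$kd / pi + p$ks * (p$n + 2) / (2 * pi) * cos_a^p$n
    sum((f_mod - f_meas)^2)
  }
  starts <- cbind(u = 0.5, logn = log(exp(seq(log(0.5), log(500),
                                              length.out = n_starts))))
  best <- NULL
  conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    o <- tryCatch(
      optim(starts[i, ], sse, method = "L-BFGS-B",
            lower = c(0, log(0.5)), upper = c(1, log(500)),
            control = list(maxit = 300)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) {
      best <- o
      conv <- conv || o$convergence == 0
    }
  }
  # diffuse member (u = 0) of the same constrained family
  sse_diffuse <- sum((rho_ref / pi - f_meas)^2)
  if (is.null(best) || best$value > sse_diffuse) {
    best <- list(par = c(0, log(1)), value = sse_diffuse)
    conv <- TRUE
  }
  p <- params_of(best$par[1], best$par[2])
  mbar <- mean(f_meas)
  list(kd = p$kd, ks = p$ks, n_exp = p$n,
       nrmse_phong = sqrt(best$value / length(f_meas)) / mbar,
       nrmse_diffuse = sqrt(sse_diffuse / length(f_meas)) / mbar,
       converged = conv)
}

#' Fit per-bin Phong parameters to a BRDF sample set
#'
#' For every (bin, side) group, minimizes the sum of squared deviations
#' between the modified-Phong model and the measured BRDF values over
#' (`kd`, `ks`, `n_exp`), subject to the hemispherical-reflectance anchor
#' DHR(40 deg) = `rho_ref` (held exactly by construction) and energy
#' closure.  A bounded multi-start search over log-spaced shininess values
#' guards against the multimodal n landscape.  The best constant
#' (Lambertian, ks = 0) model satisfying the same anchor is fitted
#' alongside; because it is a nested member of the constrained family, its
#' NRMSE is never smaller than the Phong NRMSE.
#'
#' NRMSE is the RMSE divided by the mean measured BRDF of the group.
#'
#' @param x A [brdf_samples()] set (>= 8 samples and >= 2 incidence angles
#'   per group).
#' @param anchor_deg Calibration incidence angle (default 40).
#' @param n_starts Number of multi-start shininess seeds.
#' @return An object of class `phong_fit`: list with `optics` (a Phong
#'   [phong_optics()] table) and `fit` (per-group NRMSE and convergence
#'   flags).
#' @export
fit_phong <- function(x, anchor_deg = 40, n_starts = 5) {
  stopifnot(inherits(x, "brdf_samples"))
  groups <- x$samples |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("bin_center_nm", "side")))) |>
    dplyr::group_split()
  rows <- purrr::map(groups, function(g) {
    key <- g[1, c("bin_center_nm", "side")]
    if (nrow(g) < 8 || length(unique(g$theta_i_deg)) < 2) {
      stop(sprintf("bin %g/%s: need >= 8 samples over >= 2 incidence angles",
                   key$bin_center_nm, key$side))
    }
    rr <- dplyr::inner_join(key, x$rho_ref,
                            by = c("bin_center_nm", "side"))
    tt <- dplyr::inner_join(key, x$tau, by = c("bin_center_nm", "side"))
    if (nrow(rr) != 1) stop("missing rho_ref for bin ", key$bin_center_nm)
    tau <- if (nrow(tt) == 1) tt$tau else 0
    if (rr$rho_ref + tau > 1) {
      stop(sprintf("bin %g/%s: rho_ref + tau > 1, infeasible",
                   key$bin_center_nm, key$side))
    }
    cos_a <- cos_alpha_gonio(g$theta_i_deg, g$theta_r_deg, g$phi_r_deg)
    f <- fit_one_bin(g$brdf_sr_inv, cos_a, rr$rho_ref, tau, anchor_deg,
                     n_starts)
    tibble::tibble(
      bin_center_nm = key$bin_center_nm, side = key$side,
      kd = f$kd, ks = f$ks, n_exp = f$n_exp, tau = tau,
      rho_ref = rr$rho_ref,
      nrmse_phong = f$nrmse_phong, nrmse_diffuse = f$nrmse_diffuse,
      n_samples = nrow(g), converged = f$converged
    )
  }) |> dplyr::bind_rows() |>
    dplyr::arrange(.data$side, .data$bin_center_nm)
  if (any(!rows$converged)) {
    warning("fit did not converge for ", sum(!rows$converged), " group(s)")
  }
  optics <- phong_optics(rows[c("bin_center_nm", "side", "kd", "ks",
                                "n_exp", "tau")])
  structure(list(optics = optics, fit = rows), class = "phong_fit")
}

#' @export
print.phong_fit <- function(x, ...) {
  cat(sprintf(
    "<phong_fit: %d bin/side groups; mean NRMSE phong %.3f, diffuse %.3f>\n",
    nrow(x$fit), mean(x$fit$nrmse_phong), mean(x$fit$nrmse_diffuse)))
  invisible(x)
}

#' Tidy a Phong fit
#'
#' @param x A `phong_fit`.
#' @param ... Unused.
#' @return Per-group parameter and error tibble.
#' @export
tidy.phong_fit <- function(x, ...) x$fit

#' @export
glance.phong_fit <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x$fit),
    mean_nrmse_phong = mean(x$fit$nrmse_phong),
    mean_nrmse_diffuse = mean(x$fit$nrmse_diffuse),
    all_converged = all(x$fit$converged)
  )
}

# generics (broom not a dependency)
#' @export
tidy <- function(x, ...) UseMethod("tidy")
#' @export
glance <- function(x, ...) UseMethod("glance")

# ---- CSV interfaces -------------------------------------------------------

#' Read / write BRDF sample sets and optics tables as CSV
#'
#' `read_brdf_samples_csv` expects a sample file with columns
#' `bin_center_nm,side,theta_i_deg,theta_r_deg,phi_r_deg,brdf_sr_inv` and a
#' reference file `bin_center_nm,side,rho_ref` (optionally `tau`).
#' Optics tables are flat CSVs `bin_center_nm,side,kd,ks,n_exp,tau`
#' (Phong) or `bin_center_nm,side,rho,tau` (diffuse).
#'
#' @param samples_path,rho_ref_path,path File paths.
#' @return See each function.
#' @export
read_brdf_samples_csv <- function(samples_path, rho_ref_path) {
  s <- readr::read_csv(samples_path, show_col_types = FALSE)
  r <- readr::read_csv(rho_ref_path, show_col_types = FALSE)
  tau <- if ("tau" %in% names(r)) r[c("bin_center_nm", "side", "tau")] else NULL
  brdf_samples(s, r[c("bin_center_nm", "side", "rho_ref")], tau)
}

#' @rdname read_brdf_samples_csv
#' @param x A `brdf_samples` set or `leaf_optics` table.
#' @export
write_brdf_samples_csv <- function(x, samples_path, rho_ref_path) {
  stopifnot(inherits(x, "brdf_samples"))
  readr::write_csv(x$samples, samples_path)
  readr::write_csv(dplyr::left_join(x$rho_ref, x$tau,
                                    by = c("bin_center_nm", "side")),
                   rho_ref_path)
  invisible(samples_path)
}

#' @rdname read_brdf_samples_csv
#' @export
write_optics_csv <- function(x, path) {
  stopifnot(inherits(x, "leaf_optics"))
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}

#' @rdname read_brdf_samples_csv
#' @export
read_optics_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if ("kd" %in% names(x)) phong_optics(x) else diffuse_optics(x)
}
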