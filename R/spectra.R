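# Spectral discretization, D65 photon weighting and band aggregation.
#
# All spectral quantities in the package live on a common grid of contiguous
# 10 nm bins spanning 440-740 nm (30 bins).  Results are aggregated into the
# four horticultural bands blue/green/red/far-red for analysis.

#' CIE D65 relative spectral power distribution, 440-740 nm at 5 nm
#'
#' The standard daylight illuminant tabulation (relative spectral power,
#' normalized to 100 at 560 nm), restricted to the simulated wavelength
#' range.  Embedded so that no external data file or download is needed.
#'
#' @return A tibble with columns `wavelength_nm` and `value`.
#' @export
#' @examples
#' d65_spd()
d65_spd <- function() {
  tibble::tibble(
    wavelength_nm = seq(440, 740, by = 5),
    value = c(
      104.865, 110.936, 117.008, 117.410, 117.812, 116.336, 114.861,
      115.392, 115.923, 112.367, 108.811, 109.082, 109.354, 108.578,
      107.802, 106.296, 104.790, 106.239, 107.689, 106.047, 104.405,
      104.225, 104.046, 102.023, 100.000,  98.167,  96.334,  96.061,
       95.788,  92.237,  88.686,  89.346,  90.006,  89.803,  89.599,
       88.649,  87.699,  85.494,  83.289,  83.494,  83.699,  81.863,
       80.027,  80.121,  80.215,  81.246,  82.278,  80.281,  78.284,
       74.003,  69.721,  70.665,  71.609,  72.979,  74.349,  67.977,
       61.604,  65.745,  69.886,  72.486,  75.087
    )
  )
}

#' Construct the spectral bin grid
#'
#' The default grid divides 440-740 nm into 30 contiguous 10 nm bins, the
#' discretization used for all simulations.  Alternative uniform grids over
#' the same range (e.g. 60 x 5 nm) are allowed for refinement checks.
#'
#' @param n_bins Number of uniform bins between `lo` and `hi`.
#' @param lo,hi Range edges in nm.
#' @return An object of class `spectral_grid`: list with `edges` (n+1),
#'   `centers` (n) and `width`.
#' @export
#' @examples
#' g <- spectral_grid()
#' g$centers[1:3]
spectral_grid <- function(n_bins = 30, lo = 440, hi = 740) {
  stopifnot(n_bins >= 1, hi > lo)
  edges <- seq(lo, hi, length.out = n_bins + 1)
  structure(
    list(edges = edges,
         centers = (head(edges, -1) + tail(edges, -1)) / 2,
         width = (hi - lo) / n_bins),
    class = "spectral_grid"
  )
}

#' @export
print.spectral_grid <- function(x, ...) {
  cat(sprintf("<spectral_grid: %d bins of %g nm over [%g, %g] nm>\n",
              length(x$centers), x$width, x$edges[1], x$edges[length(x$edges)]))
  invisible(x)
}

n_bins <- function(grid) length(grid$centers)

validate_grid <- function(grid) {
  stopifnot(inherits(grid, "spectral_grid"))
  e <- grid$edges
  if (any(diff(e) <= 0)) stop("spectral grid edges must be strictly ascending")
  invisible(grid)
}

#' The four-band aggregation scheme
#'
#' Horticultural band division: blue \[440, 500), green \[500, 600),
#' red \[600, 700) and far-red \[700, 740\].  Intervals are half-open on the
#' right except far-red, so every 10 nm bin of the default grid maps to
#' exactly one band.
#'
#' @return A tibble with columns `band`, `lo_nm`, `hi_nm`.
#' @export
band_scheme <- function() {
  tibble::tibble(
    band = factor(c("blue", "green", "red", "far_red"),
                  levels = c("blue", "green", "red", "far_red")),
    lo_nm = c(440, 500, 600, 700),
    hi_nm = c(500, 600, 700, 740)
  )
}

#' Map grid bins to bands
#'
#' @param grid A [spectral_grid()].
#' @param scheme A band scheme tibble, see [band_scheme()].
#' @return A factor of length `n_bins(grid)` giving the band of each bin.
#' @export
bin_bands <- function(grid = spectral_grid(), scheme = band_scheme()) {
  validate_grid(grid)
  lo <- head(grid$edges, -1); hi <- tail(grid$edges, -1)
  band <- rep(NA_character_, length(lo))
  for (i in seq_len(nrow(scheme))) {
    inside <- lo >= scheme$lo_nm[i] - 1e-9 & hi <= scheme$hi_nm[i] + 1e-9
    band[inside & is.na(band)] <- as.character(scheme$band[i])
  }
  if (anyNA(band)) {
    stop("grid bin straddles a band boundary; bands require aligned bin edges")
  }
  factor(band, levels = levels(scheme$band))
}

#' D65 photon-flux bin weights
#'
#' Relative photon flux per spectral bin under the D65 illuminant,
#' normalized to sum to one.  Photon flux is proportional to the spectral
#' power times the wavelength (photon energy hc/lambda), so each bin weight
#' is the integral of S(lambda) * lambda over the bin.  The embedded 5 nm
#' D65 table is linearly interpolated to 1 nm before trapezoidal
#' integration, which removes any dependence on bin-center approximations.
#'
#' @param grid A [spectral_grid()] lying inside 440-740 nm.
#' @return A tibble with `bin_center_nm` and `weight` (sums to 1).
#' @export
#' @examples
#' w <- d65_photon_weights()
#' sum(w$weight)
d65_photon_weights <- function(grid = spectral_grid()) {
  validate_grid(grid)
  spd <- d65_spd()
  rng <- range(spd$wavelength_nm)
  if (grid$edges[1] < rng[1] - 1e-9 ||
      grid$edges[length(grid$edges)] > rng[2] + 1e-9) {
    stop("grid extends outside the embedded D65 table (440-740 nm)")
  }
  w <- vapply(seq_len(n_bins(grid)), function(i) {
    lo <- grid$edges[i]; hi <- grid$edges[i + 1]
    x <- seq(lo, hi, by = 1)
    if (x[length(x)] < hi) x <- c(x, hi)
    y <- approx(spd$wavelength_nm, spd$value, xout = x)$y * x
    sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  }, numeric(1))
  tibble::tibble(bin_center_nm = grid$centers, weight = w / sum(w))
}

#' Aggregate a per-bin spectral vector into bands
#'
#' Band values are plain sums of member-bin values, so totals are conserved
#' exactly.
#'
#' @param v A data frame with columns `bin_center_nm` and one or more value
#'   columns, or a numeric vector aligned to `grid`.
#' @param grid The grid the values live on.
#' @param scheme Band scheme.
#' @return A tibble with `band` and the summed value columns.
#' @export
#' @examples
#' band_aggregate(d65_photon_weights())
band_aggregate <- function(v, grid = spectral_grid(), scheme = band_scheme()) {
  if (is.numeric(v) && is.null(dim(v))) {
    v <- tibble::tibble(bin_center_nm = grid$centers, value = v)
  }
  stopifnot(is.data.frame(v), "bin_center_nm" %in% names(v))
  bands <- tibble::tibble(
    bin_center_nm = grid$centers,
    band = bin_bands(grid, scheme)
  )
  v |>
    dplyr::inner_join(bands, by = "bin_center_nm") |>
    dplyr::group_by(dplyr::across(dplyr::all_of("band"))) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric) &
                                     !dplyr::any_of("bin_center_nm"), sum),
                     .groups = "drop")
}

#' Read / write a two-column spectrum CSV
#'
#' Plain `wavelength_nm,value` files with a header and ascending
#' wavelengths.
#'
#' @param path File path.
#' @return `read_spectrum_csv` returns a tibble with `wavelength_nm`,
#'   `value`; the writer returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("wavelength_nm", "value") %in% names(x))) {
    stop("spectrum CSV needs columns wavelength_nm,value")
  }
  if (is.unsorted(x$wavelength_nm, strictly = TRUE)) {
    stop("wavelengths must be strictly ascending")
  }
  tibble::as_tibble(x[c("wavelength_nm", "value")])
}

#' @rdname read_spectrum_csv
#' @param spec A tibble with `wavelength_nm` and `value`.
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(all(c("wavelength_nm", "value") %in% names(spec)))
  readr::write_csv(spec[c("wavelength_nm", "value")], path)
  invisible(path)
}
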