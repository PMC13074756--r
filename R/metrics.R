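# Evaluation statistics: indirect-light proportion, MAPE between paired
# Phong and diffuse runs, band fractions, quantiles, paired t-tests and
# grouped aggregation.

#' Indirect-light proportion
#'
#' eta = 1 - E_without / E_with, where `e_without` is a tally from a run
#' with reflections disabled (direct light only) and `e_with` the matching
#' tally with reflections enabled.  Monte-Carlo noise can push eta slightly
#' below zero; the raw value is returned (consumers may clamp for display).
#'
#' @param e_without,e_with Non-negative tallies; `e_with` must be positive.
#' @return eta (vectorized).
#' @export
#' @examples
#' indirect_fraction(96, 100)  # 0.04
indirect_fraction <- function(e_without, e_with) {
  if (any(e_with <= 0)) stop("e_with must be positive")
  if (any(e_without < 0)) stop("e_without must be non-negative")
  1 - e_without / e_with
}

#' Mean absolute percentage error of paired values
#'
#' MAPE = 100/n * sum(|phong - diffuse| / diffuse), computed per group.
#' Taking absolute values prevents positive and negative deviations from
#' cancelling.  Records with a zero denominator are undefined; they are
#' dropped with their count reported in the `n_dropped` column.
#'
#' @param pairs A data frame with columns `phong` and `diffuse` plus any
#'   grouping columns.
#' @param group_by Character vector of grouping column names (empty = one
#'   overall group).
#' @return A tibble with the grouping columns, `mape` (percent), `n`, and
#'   `n_dropped`.
#' @export
#' @examples
#' mape(tibble::tibble(phong = c(101, 99), diffuse = c(100, 100)))
mape <- function(pairs, group_by = character()) {
  stopifnot(all(c("phong", "diffuse") %in% names(pairs)))
  if (nrow(pairs) == 0) stop("empty pair set")
  pairs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(
      n_dropped = sum(.data$diffuse == 0),
      n = sum(.data$diffuse != 0),
      mape = 100 * mean(abs(.data$phong[.data$diffuse != 0] -
                              .data$diffuse[.data$diffuse != 0]) /
                          .data$diffuse[.data$diffuse != 0]),
      .groups = "drop") |>
    dplyr::relocate(dplyr::all_of(c("mape", "n", "n_dropped")),
                    .after = dplyr::last_col())
}

#' Per-band share of a spectral tally
#'
#' The relative contribution of each band is its photon flux (density)
#' divided by the total over all four bands; shares sum to one per record
#' group.
#'
#' @param tallies Data frame with `bin_center_nm`, a `value` column and
#'   optional id columns.
#' @param value Name of the value column.
#' @param group_by Id columns defining one record (e.g. sensor_id).
#' @param grid,scheme Spectral grid and band scheme.
#' @param drop_zero Drop record groups whose total flux is zero (their
#'   shares are undefined, e.g. a fully shaded sensor); the dropped count
#'   is attached as attribute `n_dropped`.  With `drop_zero = FALSE` a
#'   zero-total group is an error.
#' @return Tibble with the id columns, `band`, `value` and `share`.
#' @export
band_fraction <- function(tallies, value = "value", group_by = character(),
                          grid = spectral_grid(), scheme = band_scheme(),
                          drop_zero = TRUE) {
  stopifnot(value %in% names(tallies))
  bands <- tibble::tibble(bin_center_nm = grid$centers,
                          band = bin_bands(grid, scheme))
  out <- tallies |>
    dplyr::inner_join(bands, by = "bin_center_nm") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_by, "band")))) |>
    dplyr::summarise(value = sum(.data[[value]]), .groups = "drop_last") |>
    dplyr::mutate(share = .data$value / sum(.data$value)) |>
    dplyr::ungroup()
  bad <- !is.finite(out$share)
  if (any(bad)) {
    if (!drop_zero || all(bad)) stop("zero total flux in a record group")
    out <- out[!bad, , drop = FALSE]
  }
  structure(out, n_dropped = sum(bad) / nlevels(bands$band))
}

#' Quantiles Q25 / Q50 / Q90
#'
#' Linear-interpolation (type 7) quantiles of a numeric vector.
#'
#' @param values Numeric, non-empty.
#' @param probs Probabilities (default 0.25, 0.5, 0.9).
#' @return A named numeric vector.
#' @export
tally_quantiles <- function(values, probs = c(0.25, 0.5, 0.9)) {
  if (length(values) < 1) stop("empty input")
  setNames(quantile(values, probs, type = 7, names = FALSE),
           paste0("Q", round(probs * 100)))
}

#' Paired t-test on matched tallies
#'
#' Standard paired t statistic on the differences, df = n - 1, two-sided
#' p-value.
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @return A tibble with `t`, `df`, `p_value`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (sd(d) == 0) stop("zero-variance differences: t statistic undefined")
  tt <- t.test(x, y, paired = TRUE)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, mean_diff = mean(d))
}

#' Build a paired comparison frame from two tally results
#'
#' Aligns two runs of the same scene and scenario (e.g. Phong vs diffuse
#' optics, or reflections on vs off) record by record.
#'
#' @param a,b `tally_result` objects (a = numerator/"phong"/"with", b =
#'   denominator/"diffuse"/"without").
#' @param quantity "absorbed" or "sensors".
#' @param names Column names for the two value columns.
#' @return A tibble keyed by plant/leaf/bin (and sensor columns for
#'   sensor tallies) with the two paired value columns.
#' @export
pair_tallies <- function(a, b, quantity = c("absorbed", "sensors"),
                         names = c("phong", "diffuse")) {
  quantity <- match.arg(quantity)
  keys <- if (quantity == "absorbed") {
    c("plant", "leaf_order", "bin_center_nm")
  } else {
    c("sensor_id", "plant", "leaf_order", "side", "point", "bin_center_nm")
  }
  ta <- if (quantity == "absorbed") a$absorbed else a$sensors
  tb <- if (quantity == "absorbed") b$absorbed else b$sensors
  val <- if (quantity == "absorbed") "flux" else "ppfd"
  out <- dplyr::inner_join(
    ta[c(keys, val)] |> dplyr::rename(!!names[1] := dplyr::all_of(val)),
    tb[c(keys, val)] |> dplyr::rename(!!names[2] := dplyr::all_of(val)),
    by = keys)
  if (nrow(out) != nrow(ta) || nrow(out) != nrow(tb)) {
    stop("tally results do not align record by record")
  }
  out
}

#' Grouped summary of a comparison metric
#'
#' Group means with standard errors over any of the study's analysis
#' dimensions (leaf order, direct fraction, sun altitude, leaf side,
#' arrangement), optionally restricted to centrally positioned plants.
#'
#' @param results A tibble that contains a `value` column and the grouping
#'   columns.
#' @param dimension Column name(s) to group by.
#' @param central_only If TRUE, keep only rows whose `plant` is listed in
#'   `central`.
#' @param central Integer plant ids regarded as central.
#' @return Tibble with the grouping columns, `mean`, `se`, `n`.
#' @export
aggregate_metric <- function(results, dimension, central_only = FALSE,
                             central = NULL) {
  if (!all(dimension %in% names(results))) {
    stop("unknown dimension: ",
         paste(setdiff(dimension, names(results)), collapse = ", "))
  }
  if (central_only) {
    if (is.null(central)) stop("central plant ids required")
    results <- dplyr::filter(results, .data$plant %in% central)
  }
  results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(dimension))) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = sd(.data$value) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
}
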