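# Study orchestration: configuration, seeded paired runs over arrangements
# and scenarios, and the summary tables of the evaluation.

#' Derive a reproducible child seed
#'
#' Counter-based integer hashing (Knuth multiplicative steps) so each
#' (arrangement, scenario, replicate) combination gets an independent
#' stream while paired runs (Phong vs diffuse, reflection on vs off)
#' deliberately share the replicate seed for common random numbers.
#'
#' @param root Root seed (integer).
#' @param ... Integer counters.
#' @return A positive integer below 2^31.
#' @export
derive_seed <- function(root, ...) {
  h <- as.numeric(root) %% 2147483647
  for (k in c(...)) {
    h <- (h * 48271 + as.numeric(k) * 16807 + 12345) %% 2147483647
  }
  as.integer(h + 1)
}

#' Study run configuration
#'
#' @param seed Root seed for everything (canopy generation and ray seeds).
#' @param n_rays Rays per replicate run.
#' @param n_reps Replicates per run (averaged; default 3).
#' @param max_depth Reflection depth cap (default 50).
#' @param arrangements Subset of c("single", "grid3x3", "grid4x3").
#' @param scenarios A scenario tibble (rows of [scenario_sweep()]); default
#'   is the stratified desk-scale subset: all direct fractions at azimuth
#'   0 and altitudes 10/50/90 degrees.
#' @param include_baseline Add the pure-diffuse (q = 0) baseline run.
#' @param E_global Global horizontal irradiance.
#' @param spacing Plant spacing (m).
#' @param with_sensors Trace sensor nodes (needed for the spectral
#'   photon-flux-density metrics).
#' @param sensor_offset,sensor_radius Sensor geometry (m).
#' @param out_dir Optional output directory for CSV artifacts + manifest.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_rays = 2e6, n_reps = 3, max_depth = 50,
                       arrangements = c("single", "grid3x3", "grid4x3"),
                       scenarios = NULL, include_baseline = TRUE,
                       E_global = 1000, spacing = 0.2, with_sensors = TRUE,
                       sensor_offset = 0.005, sensor_radius = 0.0025,
                       out_dir = NULL) {
  if (is.null(scenarios)) {
    scenarios <- scenario_subset(scenario_sweep(E_global),
                                 azimuth = 0, altitude = c(10, 50, 90))
  }
  stopifnot(n_rays >= 1e4, n_reps >= 1, max_depth >= 1, nrow(scenarios) >= 1,
            all(arrangements %in% c("single", "grid3x3", "grid4x3")),
            E_global > 0, spacing > 0)
  structure(list(seed = seed, n_rays = n_rays, n_reps = n_reps,
                 max_depth = max_depth, arrangements = arrangements,
                 scenarios = scenarios, include_baseline = include_baseline,
                 E_global = E_global, spacing = spacing,
                 with_sensors = with_sensors,
                 sensor_offset = sensor_offset,
                 sensor_radius = sensor_radius, out_dir = out_dir),
            class = "run_config")
}

#' Filter the scenario sweep
#'
#' @param sweep A scenario tibble.
#' @param q_direct,azimuth,altitude Optional value sets to keep.
#' @return The filtered tibble (error if empty).
#' @export
scenario_subset <- function(sweep, q_direct = NULL, azimuth = NULL,
                            altitude = NULL) {
  out <- sweep
  near <- function(x, set) {
    vapply(x, function(v) any(abs(v - set) < 1e-9), logical(1))
  }
  if (!is.null(q_direct)) out <- out[near(out$q_direct, q_direct), ]
  if (!is.null(azimuth)) out <- out[near(out$sun_azimuth_deg, azimuth), ]
  if (!is.null(altitude)) out <- out[near(out$sun_altitude_deg, altitude), ]
  if (nrow(out) == 0) stop("scenario selector resolves to an empty set")
  out
}

#' Serialize / deserialize a run configuration as YAML
#'
#' @param config A `run_config`.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$scenarios <- as.list(as.data.frame(config$scenarios))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  sc <- tibble::as_tibble(lapply(x$scenarios, unlist))
  x$scenarios <- sc
  x$out_dir <- x$out_dir %||% NULL
  do.call(run_config, x[setdiff(names(x), character())])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

spectrum_total <- function(tbl, value, keys) {
  tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(total = sum(.data[[value]]), .groups = "drop")
}

#' Run the full comparison study
#'
#' For every arrangement and scenario the four tracer runs of the design
#' are executed -- {Phong, diffuse-equivalent} optics x {full transport,
#' single-reflection baseline} -- with common per-replicate seeds, averaged
#' over replicates, and reduced to the study's metric tables:
#'
#' * `eta_leaf`: per-leaf multiple-reflection (indirect) proportion
#'   (Phong full vs single-reflection run, spectrum integrated), with
#'   arrangement/scenario/central-plant keys,
#' * `mape_absorbed`: per-leaf MAPE of spectrum-integrated absorbed flux
#'   between the paired Phong and diffuse runs,
#' * `mape_sensor_band`: per-sensor-band MAPE of photon flux density,
#' * `band_share`: per-band share of sensor photon flux (Phong run),
#' * `quantile_table`: MAPE distribution by band, side and direct
#'   fraction (mean, SE, Q25/Q50/Q90),
#' * `max_mape`: maximum group-mean MAPE by band/side/dimension.
#'
#' @param config A [run_config()].
#' @param optics Optional list(phong=, diffuse=, stem_reflectance=) as
#'   returned by [fixture_optics()] (the default).
#' @return A list of class `study_bundle` with `config`, `metrics` (list
#'   of tibbles) and `runs_meta`.
#' @export
run_study <- function(config = run_config(), optics = fixture_optics()) {
  stopifnot(inherits(config, "run_config"))
  scen <- config$scenarios
  if (config$include_baseline) {
    scen <- dplyr::bind_rows(pure_diffuse_scenario(config$E_global), scen)
  }
  grid <- spectral_grid()
  eta_rows <- list(); mape_rows <- list(); sens_mape_rows <- list()
  share_rows <- list(); meta_rows <- list()
  for (ai in seq_along(config$arrangements)) {
    arr <- config$arrangements[ai]
    set.seed(derive_seed(config$seed, ai, 424243))
    scene <- assemble_canopy(arr, spacing = config$spacing)
    index <- build_index(scene)
    sensors <- if (config$with_sensors) {
      sensor_nodes(scene, config$sensor_offset, config$sensor_radius)
    } else NULL
    for (si in seq_len(nrow(scen))) {
      sc1 <- scen[si, ]
      seeds <- vapply(seq_len(config$n_reps),
                      function(r) derive_seed(config$seed, ai, si, r),
                      integer(1))
      runs <- list()
      for (mode in c("phong", "diffuse")) {
        for (scat in c("full", "single_reflection")) {
          runs[[paste(mode, scat)]] <- run_replicates(
            index, sc1,
            optics = if (mode == "phong") optics$phong else optics$diffuse,
            n_reps = config$n_reps, seeds = seeds,
            n_rays = config$n_rays, max_depth = config$max_depth,
            scattering = scat, sensors = sensors,
            stem_reflectance = optics$stem_reflectance, grid = grid)
          meta_rows[[length(meta_rows) + 1]] <- tibble::tibble(
            arrangement = arr, scenario_id = sc1$scenario_id,
            optics_mode = mode, scattering = scat,
            seeds = paste(seeds, collapse = ","))
        }
      }
      keyfix <- function(tbl) dplyr::mutate(
        tbl, arrangement = arr, scenario_id = sc1$scenario_id,
        q_direct = sc1$q_direct, sun_altitude_deg = sc1$sun_altitude_deg,
        central = .data$plant %in% index$central)
      # indirect proportion per leaf (Phong on vs off)
      pw <- spectrum_total(runs[["phong full"]]$absorbed, "flux",
                           c("plant", "leaf_order"))
      po <- spectrum_total(runs[["phong single_reflection"]]$absorbed, "flux",
                           c("plant", "leaf_order"))
      eta_rows[[length(eta_rows) + 1]] <-
        dplyr::inner_join(pw, po, by = c("plant", "leaf_order"),
                          suffix = c("_with", "_without")) |>
        dplyr::filter(.data$total_with > 0) |>
        dplyr::mutate(value = indirect_fraction(.data$total_without,
                                                .data$total_with)) |>
        keyfix()
      # absorbed-flux MAPE per leaf (paired Phong vs diffuse, refl. on)
      pr <- pair_tallies(runs[["phong full"]], runs[["diffuse full"]],
                         "absorbed")
      mape_rows[[length(mape_rows) + 1]] <- pr |>
        dplyr::group_by(.data$plant, .data$leaf_order) |>
        dplyr::summarise(phong = sum(.data$phong),
                         diffuse = sum(.data$diffuse), .groups = "drop") |>
        dplyr::filter(.data$diffuse > 0) |>
        dplyr::mutate(value = 100 * abs(.data$phong - .data$diffuse) /
                        .data$diffuse) |>
        keyfix()
      if (!is.null(sensors)) {
        sp <- pair_tallies(runs[["phong full"]], runs[["diffuse full"]],
                           "sensors")
        bands <- tibble::tibble(bin_center_nm = grid$centers,
                                band = bin_bands(grid))
        spb <- sp |>
          dplyr::inner_join(bands, by = "bin_center_nm") |>
          dplyr::group_by(.data$sensor_id, .data$plant, .data$leaf_order,
                          .data$side, .data$band) |>
          dplyr::summarise(phong = sum(.data$phong),
                           diffuse = sum(.data$diffuse), .groups = "drop")
        tot <- spb |>
          dplyr::group_by(.data$sensor_id, .data$plant, .data$leaf_order,
                          .data$side) |>
          dplyr::summarise(phong = sum(.data$phong),
                           diffuse = sum(.data$diffuse), .groups = "drop") |>
          dplyr::mutate(band = factor("total",
                                      c(levels(bands$band), "total")))
        spb$band <- factor(spb$band, c(levels(bands$band), "total"))
        sens_mape_rows[[length(sens_mape_rows) + 1]] <-
          dplyr::bind_rows(spb, tot) |>
          dplyr::filter(.data$diffuse > 0) |>
          dplyr::mutate(value = 100 * abs(.data$phong - .data$diffuse) /
                          .data$diffuse) |>
          keyfix()
        share_rows[[length(share_rows) + 1]] <-
          band_fraction(runs[["phong full"]]$sensors, value = "ppfd",
                        group_by = c("sensor_id", "plant", "leaf_order",
                                     "side"), grid = grid) |>
          dplyr::select(-dplyr::all_of("value")) |>
          dplyr::rename(value = "share") |>
          keyfix()
      }
    }
  }
  metrics <- list(
    eta_leaf = dplyr::bind_rows(eta_rows),
    mape_absorbed = dplyr::bind_rows(mape_rows),
    mape_sensor_band = dplyr::bind_rows(sens_mape_rows),
    band_share = dplyr::bind_rows(share_rows)
  )
  metrics$quantile_table <- quantile_table(metrics$mape_sensor_band)
  metrics$max_mape <- max_mape_table(metrics)
  bundle <- structure(list(config = config, metrics = metrics,
                           runs_meta = dplyr::bind_rows(meta_rows)),
                      class = "study_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

quantile_table <- function(sensor_mape) {
  if (is.null(sensor_mape) || nrow(sensor_mape) == 0) return(NULL)
  sensor_mape |>
    dplyr::group_by(.data$band, .data$side, .data$q_direct) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = sd(.data$value) / sqrt(dplyr::n()),
      Q25 = quantile(.data$value, 0.25, type = 7, names = FALSE),
      Q50 = quantile(.data$value, 0.50, type = 7, names = FALSE),
      Q90 = quantile(.data$value, 0.90, type = 7, names = FALSE),
      n = dplyr::n(), .groups = "drop")
}

max_mape_table <- function(metrics) {
  out <- list()
  if (nrow(metrics$mape_absorbed) > 0) {
    for (dim in c("leaf_order", "q_direct", "sun_altitude_deg")) {
      g <- aggregate_metric(metrics$mape_absorbed, dim)
      out[[length(out) + 1]] <- tibble::tibble(
        quantity = "absorbed_flux", band = "total", side = NA_character_,
        dimension = dim, max_mape = max(g$mean),
        at = as.character(g[[dim]][which.max(g$mean)]),
        se = g$se[which.max(g$mean)])
    }
  }
  if (!is.null(metrics$mape_sensor_band) &&
      nrow(metrics$mape_sensor_band) > 0) {
    for (dim in c("leaf_order", "q_direct")) {
      g <- metrics$mape_sensor_band |>
        dplyr::group_by(.data$band, .data$side,
                        dplyr::across(dplyr::all_of(dim))) |>
        dplyr::summarise(mean = mean(.data$value),
                         se = sd(.data$value) / sqrt(dplyr::n()),
                         .groups = "drop") |>
        dplyr::group_by(.data$band, .data$side) |>
        dplyr::slice_max(.data$mean, n = 1, with_ties = FALSE) |>
        dplyr::ungroup()
      out[[length(out) + 1]] <- tibble::tibble(
        quantity = "sensor_ppfd", band = as.character(g$band),
        side = g$side, dimension = dim, max_mape = g$mean,
        at = as.character(g[[dim]]), se = g$se)
    }
  }
  dplyr::bind_rows(out)
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle: %d arrangement(s), %d scenario rows>\n",
              length(x$config$arrangements),
              nrow(x$config$scenarios) + x$config$include_baseline))
  invisible(x)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle$metrics)) {
    tbl <- bundle$metrics[[nm]]
    if (!is.null(tbl) && nrow(tbl) > 0) {
      readr::write_csv(tbl, file.path(out_dir, paste0(nm, ".csv")))
    }
  }
  readr::write_csv(bundle$runs_meta, file.path(out_dir, "runs_meta.csv"))
  cfg <- bundle$config
  manifest <- list(
    seed = cfg$seed, n_rays = cfg$n_rays, n_reps = cfg$n_reps,
    max_depth = cfg$max_depth, arrangements = cfg$arrangements,
    n_scenarios = nrow(cfg$scenarios),
    include_baseline = cfg$include_baseline,
    E_global = cfg$E_global, spacing = cfg$spacing,
    package_version = as.character(utils::packageVersion("canopytrace")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Summarize a study bundle
#'
#' A pure function of the bundle: reports the maximum MAPE per band/side/
#' dimension, the peak leaf-order-mean indirect proportion, and the mean
#' green-band share of sensor flux among majority-direct scenarios.
#'
#' @param bundle A `study_bundle`.
#' @param quiet Suppress printing.
#' @return A list of summary tibbles, invisibly when printing.
#' @export
report <- function(bundle, quiet = FALSE) {
  stopifnot(inherits(bundle, "study_bundle"))
  m <- bundle$metrics
  if (nrow(m$eta_leaf) == 0) stop("incomplete bundle: no eta records")
  eta_by_order <- m$eta_leaf |>
    dplyr::group_by(.data$leaf_order) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
  green <- NULL
  if (!is.null(m$band_share) && nrow(m$band_share) > 0) {
    g <- dplyr::filter(m$band_share, .data$q_direct > 0.5,
                       .data$band == "green")
    if (nrow(g) > 0) {
      green <- tibble::tibble(mean_share = mean(g$value),
                              se = sd(g$value) / sqrt(nrow(g)),
                              n = nrow(g))
    }
  }
  out <- list(max_mape = m$max_mape,
              eta_by_leaf_order = eta_by_order,
              eta_peak = max(eta_by_order$mean),
              green_share_majority_direct = green)
  if (!quiet) {
    cat("Peak leaf-order-mean indirect proportion:",
        sprintf("%.2f%%", 100 * out$eta_peak), "\n")
    if (!is.null(green)) {
      cat("Green-band share (scenarios > 50% direct):",
          sprintf("%.1f%%", 100 * green$mean_share), "\n")
    }
    if (nrow(m$max_mape) > 0) {
      cat("Max absorbed-flux MAPE:",
          sprintf("%.2f%%",
                  max(m$max_mape$max_mape[m$max_mape$quantity ==
                                            "absorbed_flux"])), "\n")
    }
  }
  invisible(out)
}
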