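# R interface to the compiled forward tracer: scene indexing, sensor
# placement, tracing and replicate averaging.

#' Build a triangle index of a canopy scene
#'
#' Flattens the scene into a tagged triangle soup ready for the compiled
#' tracer: every triangle carries its plant id, organ (leaf/stem) and leaf
#' order.  The adaxial leaf side is the front face of the stored winding;
#' the tracer resolves the struck side per hit from the face orientation.
#'
#' @param scene A [assemble_canopy()] scene.
#' @return A list of class `scene_index` with `vertices`, `faces` (1-based),
#'   `tags` tibble, `leaf_areas`, `n_plants`, `ground_radius`.
#' @export
build_index <- function(scene) {
  stopifnot(inherits(scene, "canopy_scene"))
  if (length(scene$plants) == 0) stop("empty scene")
  verts <- list(); faces <- list(); tags <- list()
  off <- 0L
  areas <- list()
  for (i in seq_along(scene$plants)) {
    p <- scene$plants[[i]]
    for (l in p$architecture$leaves) {
      v <- sweep(l$mesh$vertices, 2, p$position, "+")
      verts[[length(verts) + 1]] <- v
      faces[[length(faces) + 1]] <- l$mesh$faces + off
      tags[[length(tags) + 1]] <- tibble::tibble(
        plant = i, organ = "leaf", leaf_order = l$order,
        n = nrow(l$mesh$faces))
      areas[[length(areas) + 1]] <- tibble::tibble(
        plant = i, leaf_order = l$order, area_m2 = l$area)
      off <- off + nrow(v)
    }
    v <- sweep(p$architecture$stem$vertices, 2, p$position, "+")
    verts[[length(verts) + 1]] <- v
    faces[[length(faces) + 1]] <- p$architecture$stem$faces + off
    tags[[length(tags) + 1]] <- tibble::tibble(
      plant = i, organ = "stem", leaf_order = 0L,
      n = nrow(p$architecture$stem$faces))
    off <- off + nrow(v)
  }
  tag_tbl <- dplyr::bind_rows(tags)
  tag_expanded <- tag_tbl[rep(seq_len(nrow(tag_tbl)), tag_tbl$n), 1:3]
  structure(list(
    vertices = do.call(rbind, verts),
    faces = do.call(rbind, faces),
    tags = tibble::as_tibble(tag_expanded),
    leaf_areas = dplyr::bind_rows(areas),
    n_plants = length(scene$plants),
    central = scene$central,
    layout = scene$layout,
    ground_radius = scene$ground_radius
  ), class = "scene_index")
}

#' @export
print.scene_index <- function(x, ...) {
  cat(sprintf("<scene_index: %d triangles, %d plants (%s)>\n",
              nrow(x$faces), x$n_plants, x$layout))
  invisible(x)
}

tags_matrix <- function(index) {
  cbind(index$tags$plant,
        ifelse(index$tags$organ == "stem", 1L, 0L),
        index$tags$leaf_order)
}

vertex_normal <- function(mesh, vi) {
  touch <- which(mesh$faces[, 1] == vi | mesh$faces[, 2] == vi |
                   mesh$faces[, 3] == vi)
  if (length(touch) == 0) return(c(0, 0, 1))
  n <- face_normals(mesh)[touch, , drop = FALSE]
  a <- triangle_areas(mesh$vertices, mesh$faces)[touch]
  v <- colSums(n * a)
  v / sqrt(sum(v^2))
}

#' Place virtual sensor nodes around every leaf
#'
#' Three reference points per leaf side: the area centroid of the lamina
#' and the midrib points at one and two thirds of the midrib arclength.
#' Each sensor is a passive disk offset from the surface along the local
#' lamina normal (adaxial: +normal, abaxial: -normal), facing away from the
#' leaf; sensors never occlude or scatter rays.
#'
#' @param scene A `canopy_scene`.
#' @param offset Offset from the leaf surface in m (default 0.005).
#' @param radius Sensor disk radius in m (default 0.0025, area about
#'   19.6 mm2 -- small relative to any leaf yet large enough to collect a
#'   usable tally at desk-scale ray budgets).
#' @return A tibble of class `sensor_nodes`: `sensor_id`, `plant`,
#'   `leaf_order`, `side`, `point` (centroid/mid13/mid23), position `x,y,z`,
#'   facing `nx,ny,nz`, `radius`.
#' @export
sensor_nodes <- function(scene, offset = 0.005, radius = 0.0025) {
  stopifnot(inherits(scene, "canopy_scene"))
  rows <- list()
  for (i in seq_along(scene$plants)) {
    p <- scene$plants[[i]]
    for (l in p$architecture$leaves) {
      m <- l$mesh
      ar <- triangle_areas(m$vertices, m$faces)
      fc <- (m$vertices[m$faces[, 1], , drop = FALSE] +
               m$vertices[m$faces[, 2], , drop = FALSE] +
               m$vertices[m$faces[, 3], , drop = FALSE]) / 3
      centroid <- colSums(fc * ar) / sum(ar)
      ncent <- colSums(face_normals(m) * ar)
      ncent <- ncent / sqrt(sum(ncent^2))
      mid <- m$vertices[l$midrib_idx, , drop = FALSE]
      s <- c(0, cumsum(sqrt(rowSums(diff(mid)^2))))
      pts <- list(
        centroid = list(p0 = centroid, n = ncent),
        mid13 = local({
          vi <- l$midrib_idx[which.min(abs(s - max(s) / 3))]
          list(p0 = m$vertices[vi, ], n = vertex_normal(m, vi))
        }),
        mid23 = local({
          vi <- l$midrib_idx[which.min(abs(s - 2 * max(s) / 3))]
          list(p0 = m$vertices[vi, ], n = vertex_normal(m, vi))
        })
      )
      for (nm in names(pts)) {
        for (side in c("adaxial", "abaxial")) {
          sgn <- if (side == "adaxial") 1 else -1
          pos <- pts[[nm]]$p0 + sgn * offset * pts[[nm]]$n + p$position
          rows[[length(rows) + 1]] <- tibble::tibble(
            plant = i, leaf_order = l$order, side = side, point = nm,
            x = pos[1], y = pos[2], z = pos[3],
            nx = sgn * pts[[nm]]$n[1], ny = sgn * pts[[nm]]$n[2],
            nz = sgn * pts[[nm]]$n[3], radius = radius)
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, sensor_id = dplyr::row_number(),
                       .before = 1)
  structure(out, class = c("sensor_nodes", class(out)))
}

# per-side parameter matrices + above-horizon lobe fraction tables for C++
optics_matrices <- function(optics, grid = spectral_grid()) {
  mode <- optics_mode(optics)
  out <- list(mode = mode)
  atab_cache <- list()
  for (side in c("adaxial", "abaxial")) {
    rows <- optics[optics$side == side, , drop = FALSE]
    rows <- rows[match(grid$centers, rows$bin_center_nm), , drop = FALSE]
    if (anyNA(rows$bin_center_nm)) {
      stop("optics do not cover every grid bin for side ", side)
    }
    if (mode == "diffuse") {
      out[[side]] <- cbind(rows$rho, rows$tau)
      out[[paste0("atab_", side)]] <- matrix(1, 1, 91)
    } else {
      out[[side]] <- cbind(rows$kd, rows$ks, rows$n_exp, rows$tau)
      atab <- matrix(0, nrow(rows), 91)
      for (b in seq_len(nrow(rows))) {
        key <- sprintf("%.8g", rows$n_exp[b])
        if (is.null(atab_cache[[key]])) {
          atab_cache[[key]] <- lobe_albedo(rows$n_exp[b], 0:90)
        }
        atab[b, ] <- atab_cache[[key]]
      }
      out[[paste0("atab_", side)]] <- atab
    }
  }
  out
}

sensors_matrix <- function(sensors) {
  if (is.null(sensors) || nrow(sensors) == 0) {
    return(matrix(numeric(0), 0, 7))
  }
  as.matrix(sensors[c("x", "y", "z", "nx", "ny", "nz", "radius")])
}

#' Trace a lighting scenario through a canopy
#'
#' Forward Monte-Carlo transport of `n_rays` analog photon packets emitted
#' from all active sources of the scenario (the 108-segment diffuse sky
#' scaled to `E_diffuse`, plus the directed sun for `q_direct > 0`), each
#' packet carrying one spectral bin drawn from the D65 photon spectrum.
#' Leaves scatter according to the supplied optics (Phong or diffuse),
#' stems reflect diffusely with a broadband reflectance and never
#' transmit, the ground absorbs everything, and passive sensor disks count
#' crossing flux.
#'
#' Four scattering modes are supported.  `"full"` is ordinary transport.
#' `"single_reflection"` permits at most one reflection event per path
#' (diffuse transmission unrestricted); comparing it against `"full"`
#' isolates the multiply *reflected* contribution, which is what the
#' indirect-light proportion quantifies.  `"no_reflection"` disables every
#' reflection branch (leaf diffuse and specular, stem) while leaving leaf
#' transmission active.  `"none"` ends every path at its first surface
#' interaction, so tallies contain only unscattered source light.
#' Suppressed scatter weight is tallied as truncated in the restricted
#' modes.
#'
#' @param index A [build_index()] scene index.
#' @param scenario One row of [scenario_sweep()] or
#'   [pure_diffuse_scenario()].
#' @param optics A `leaf_optics` table covering both sides of every grid
#'   bin.
#' @param n_rays Number of rays (>= 1e4 for any meaningful tally).
#' @param max_depth Maximum number of surface interactions per path
#'   (default 50); residual weight at the cap is tallied as truncated.
#' @param scattering One of "full", "single_reflection", "no_reflection",
#'   "none" (see above).
#' @param sensors Optional [sensor_nodes()] table.
#' @param stem_reflectance Broadband stem reflectance.
#' @param seed Integer seed; the same seed reproduces the identical ray
#'   set, and paired runs that share a seed share rays until their physics
#'   diverges (common random numbers).
#' @param grid,spectrum Spectral grid and per-bin source weights (default
#'   D65 photon weights; all sources share this relative spectrum).
#' @return A list of class `tally_result`: tibbles `absorbed` (per plant,
#'   leaf order and bin, micromol s-1), `stems`, `sensors` (photon flux
#'   density per sensor and bin, micromol m-2 s-1), `ledger` (per-bin
#'   energy bookkeeping) and `meta`.
#' @export
trace <- function(index, scenario, optics, n_rays = 2e6, max_depth = 50,
                  scattering = c("full", "single_reflection",
                                 "no_reflection", "none"),
                  sensors = NULL,
                  stem_reflectance = 0.18, seed = 1,
                  grid = spectral_grid(),
                  spectrum = d65_photon_weights(grid)) {
  stopifnot(inherits(index, "scene_index"), nrow(scenario) == 1)
  scattering <- match.arg(scattering)
  if (n_rays < 1e4) stop("n_rays must be at least 1e4")
  om <- optics_matrices(optics, grid)
  src <- scenario_sources(scenario)
  dirs <- t(vapply(seq_len(nrow(src)),
                   function(i) -sky_direction(src$altitude_deg[i],
                                              src$azimuth_deg[i]),
                   numeric(3)))
  power <- src$E_horizontal / sin(src$altitude_deg * pi / 180)
  smat <- sensors_matrix(sensors)
  res <- trace_cpp(index$vertices, index$faces - 1L, tags_matrix(index),
                   index$n_plants, index$ground_radius,
                   om$adaxial, om$abaxial, om$atab_adaxial, om$atab_abaxial,
                   om$mode == "diffuse", stem_reflectance,
                   dirs, power, spectrum$weight, smat,
                   n_rays, as.integer(max_depth),
                   c(full = 0L, no_reflection = 1L, none = 2L,
                     single_reflection = 3L)[[scattering]],
                   as.numeric(seed))
  B <- n_bins(grid)
  absorbed <- tidyr::expand_grid(
    plant = seq_len(index$n_plants),
    leaf_order = 1:5,
    bin_center_nm = grid$centers) |>
    dplyr::mutate(flux = res$leaf_abs)
  stems <- tidyr::expand_grid(plant = seq_len(index$n_plants),
                              bin_center_nm = grid$centers) |>
    dplyr::mutate(flux = res$stem_abs)
  sens_tbl <- NULL
  if (!is.null(sensors) && nrow(sensors) > 0) {
    sens_tbl <- tidyr::expand_grid(
      sensor_id = sensors$sensor_id,
      bin_center_nm = grid$centers) |>
      dplyr::mutate(ppfd = res$sensors) |>
      dplyr::left_join(
        sensors[c("sensor_id", "plant", "leaf_order", "side", "point")],
        by = "sensor_id") |>
      dplyr::relocate(dplyr::all_of(c("plant", "leaf_order", "side",
                                      "point")), .after = "sensor_id")
  }
  ledger <- tibble::tibble(
    bin_center_nm = grid$centers,
    emitted = res$emitted,
    absorbed_leaf = rowSums(matrix(res$leaf_abs, nrow = B)),
    absorbed_stem = rowSums(matrix(res$stem_abs, nrow = B)),
    ground = res$ground,
    escaped = res$escaped,
    truncated = res$truncated)
  structure(list(
    absorbed = absorbed, stems = stems, sensors = sens_tbl, ledger = ledger,
    meta = list(n_rays = n_rays, seed = seed, scattering = scattering,
                optics_mode = optics_mode(optics),
                scenario_id = scenario$scenario_id,
                max_depth = max_depth, n_replicates = 1L)
  ), class = "tally_result")
}

#' @export
print.tally_result <- function(x, ...) {
  cat(sprintf(
    "<tally_result: scenario %s, %s optics, scattering %s, %.3g rays x %d rep(s)>\n",
    x$meta$scenario_id, x$meta$optics_mode, x$meta$scattering,
    x$meta$n_rays, x$meta$n_replicates))
  with(x$ledger, cat(sprintf(
    "  emitted %.4g | leaf %.4g | stem %.4g | ground %.4g | escaped %.4g | truncated %.4g\n",
    sum(emitted), sum(absorbed_leaf), sum(absorbed_stem), sum(ground),
    sum(escaped), sum(truncated))))
  invisible(x)
}

#' Tidy a tally result
#'
#' @param x A `tally_result`.
#' @param quantity "absorbed" (default) or "sensors".
#' @param ... Unused.
#' @return The requested tibble with run metadata columns attached.
#' @export
tidy.tally_result <- function(x, quantity = c("absorbed", "sensors"), ...) {
  quantity <- match.arg(quantity)
  tbl <- if (quantity == "absorbed") x$absorbed else x$sensors
  if (is.null(tbl)) stop("no sensor tallies in this result")
  dplyr::mutate(tbl, scenario_id = x$meta$scenario_id,
                optics_mode = x$meta$optics_mode,
                scattering = x$meta$scattering)
}

#' @export
glance.tally_result <- function(x, ...) {
  l <- x$ledger
  tibble::tibble(
    scenario_id = x$meta$scenario_id,
    optics_mode = x$meta$optics_mode,
    scattering = x$meta$scattering,
    n_rays = x$meta$n_rays,
    emitted = sum(l$emitted),
    absorbed_leaf = sum(l$absorbed_leaf),
    absorbed_stem = sum(l$absorbed_stem),
    ground = sum(l$ground),
    escaped = sum(l$escaped),
    truncated = sum(l$truncated),
    ledger_gap = abs(sum(l$emitted) - sum(l$absorbed_leaf) -
                       sum(l$absorbed_stem) - sum(l$ground) -
                       sum(l$escaped) - sum(l$truncated)))
}

#' Average several replicate runs
#'
#' Runs `trace()` once per seed and averages all tallies; the spread
#' between replicates is retained as an empirical standard error.
#'
#' @param index,scenario,optics,... Passed to [trace()].
#' @param seeds Integer vector of per-replicate seeds (length = number of
#'   replicates, default 3 consecutive seeds from `seed_base`).
#' @param seed_base First seed when `seeds` is not given.
#' @param n_reps Number of replicates.
#' @return A `tally_result` whose value columns are replicate means, with
#'   `se` columns added.
#' @export
run_replicates <- function(index, scenario, optics, n_reps = 3,
                           seeds = NULL, seed_base = 1, ...) {
  stopifnot(n_reps >= 1)
  if (is.null(seeds)) seeds <- seed_base + seq_len(n_reps) - 1
  stopifnot(length(seeds) == n_reps)
  runs <- lapply(seeds, function(s) trace(index, scenario, optics,
                                          seed = s, ...))
  if (n_reps == 1) return(runs[[1]])
  avg <- runs[[1]]
  comb <- function(get) {
    vals <- vapply(runs, get, numeric(length(get(runs[[1]]))))
    list(mean = rowMeans(vals),
         se = apply(vals, 1, sd) / sqrt(n_reps))
  }
  a <- comb(function(r) r$absorbed$flux)
  avg$absorbed$flux <- a$mean; avg$absorbed$se <- a$se
  s <- comb(function(r) r$stems$flux)
  avg$stems$flux <- s$mean; avg$stems$se <- s$se
  if (!is.null(avg$sensors)) {
    p <- comb(function(r) r$sensors$ppfd)
    avg$sensors$ppfd <- p$mean; avg$sensors$se <- p$se
  }
  for (col in c("emitted", "absorbed_leaf", "absorbed_stem", "ground",
                "escaped", "truncated")) {
    avg$ledger[[col]] <- rowMeans(vapply(runs, function(r) r$ledger[[col]],
                                         numeric(nrow(avg$ledger))))
  }
  avg$meta$n_replicates <- n_reps
  avg$meta$seed <- seeds
  avg
}

#' Serialize tally results to a long CSV
#'
#' @param x A `tally_result`.
#' @param path Output file.
#' @export
write_tally_csv <- function(x, path) {
  ab <- tidy(x, "absorbed") |>
    dplyr::mutate(side = NA_character_, sensor_id = NA_integer_,
                  quantity = "absorbed_flux") |>
    dplyr::rename(value = "flux")
  rows <- ab
  if (!is.null(x$sensors)) {
    se <- tidy(x, "sensors") |>
      dplyr::mutate(quantity = "sensor_ppfd") |>
      dplyr::rename(value = "ppfd")
    rows <- dplyr::bind_rows(ab, se)
  }
  if (!"se" %in% names(rows)) rows$se <- NA_real_
  readr::write_csv(
    rows[c("scenario_id", "optics_mode", "scattering", "plant",
           "leaf_order", "side", "sensor_id", "bin_center_nm", "quantity",
           "value", "se")], path)
  invisible(path)
}
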