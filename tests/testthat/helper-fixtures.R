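# Shared builders for small deterministic test scenes and optics.

# flat uniform optics across the whole grid (both sides)
uniform_phong <- function(kd, ks, n_exp, tau, grid = spectral_grid()) {
  phong_optics(tidyr::expand_grid(bin_center_nm = grid$centers,
                                  side = c("adaxial", "abaxial")) |>
                 dplyr::mutate(kd = kd, ks = ks, n_exp = n_exp, tau = tau))
}

uniform_diffuse <- function(rho, tau, grid = spectral_grid()) {
  diffuse_optics(tidyr::expand_grid(bin_center_nm = grid$centers,
                                    side = c("adaxial", "abaxial")) |>
                   dplyr::mutate(rho = rho, tau = tau))
}

# a "scene" consisting of explicit unit-square horizontal leaves at given
# heights, each its own leaf order on one plant
square_leaf <- function(z, half = 0.5) {
  list(vertices = rbind(c(-half, -half, z), c(half, -half, z),
                        c(half, half, z), c(-half, half, z)),
       faces = rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
}

slab_scene <- function(heights, half = 0.5, ground_radius = 1e-6) {
  leaves <- lapply(seq_along(heights), function(k) {
    list(order = k, mesh = square_leaf(heights[k], half),
         area = (2 * half)^2, attach = c(0, 0, heights[k]),
         midrib_idx = c(1L, 2L))
  })
  structure(list(plants = list(list(
    architecture = list(height = max(heights),
                        stem = list(vertices = matrix(0, 0, 3),
                                    faces = matrix(0L, 0, 3)),
                        leaves = leaves),
    position = c(0, 0, 0))),
    layout = "single", spacing = 0.2, central = 1L,
    ground_radius = ground_radius), class = "canopy_scene")
}

# pad a scene with tiny dummy leaves below the ground plane so that every
# order 1..5 exists (the tracer tallies five orders per plant); they are
# never reached because the black ground absorbs first
slab_index <- function(heights, half = 0.5, ...) {
  sc <- slab_scene(heights, half = half, ...)
  leaves <- sc$plants[[1]]$architecture$leaves
  for (k in seq(length(heights) + 1, 5)) {
    if (k > 5) break
    leaves[[k]] <- list(order = k, mesh = square_leaf(-0.001, half = 1e-4),
                        area = 4e-8, attach = c(0, 0, -0.001),
                        midrib_idx = c(1L, 2L))
  }
  sc$plants[[1]]$architecture$leaves <- leaves[1:5]
  build_index(sc)
}

# an index with no geometry at all, for open-field sensor checks
empty_index <- function() {
  structure(list(vertices = matrix(0, 0, 3), faces = matrix(0L, 0, 3),
                 tags = tibble::tibble(plant = integer(),
                                       organ = character(),
                                       leaf_order = integer()),
                 leaf_areas = tibble::tibble(), n_plants = 1L, central = 1L,
                 layout = "single", ground_radius = 0),
            class = "scene_index")
}

horizontal_sensor <- function(z = 0.5, up = TRUE, radius = 0.05) {
  tibble::tibble(sensor_id = 1L, plant = 1L, leaf_order = 1L,
                 side = if (up) "adaxial" else "abaxial",
                 point = "centroid", x = 0, y = 0, z = z,
                 nx = 0, ny = 0, nz = if (up) 1 else -1, radius = radius)
}

one_scenario <- function(q, alt = 50, az = 0, E = 1000) {
  if (q == 0) return(pure_diffuse_scenario(E))
  scenario_subset(scenario_sweep(E), q_direct = q, azimuth = az,
                  altitude = alt)
}

total_by_leaf <- function(tl) {
  tl$absorbed |>
    dplyr::group_by(plant, leaf_order) |>
    dplyr::summarise(flux = sum(flux), .groups = "drop")
}
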