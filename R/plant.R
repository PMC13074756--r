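# Parametric generator for cucumber-like five-leaf plants.
#
# Laminae are cordate-outline surfaces swept over a curved (drooping)
# midrib and triangulated on a regular parameter grid; stems are faceted
# cylinders.  The generator emulates the habit of young five-leaf cucumber
# plants: leaf order increases with attachment height, per-leaf area rises
# from order 1 to 4 and drops for the youngest leaf, and adjacent leaves
# overlap in vertical projection so that inter-leaf shading occurs.

#' Synthesis parameters for plant generation
#'
#' Defaults target the study conditions: mean plant height 0.212 m with
#' 0.03 m standard deviation, and a per-plant one-sided leaf area of
#' 0.185 m2 so a 3x3 grid at 0.2 m spacing has a leaf area index of 4.625
#' in expectation.
#'
#' @param mean_height,height_sd Plant height distribution (m).
#' @param leaf_area_total Target one-sided leaf area per plant (m2).
#' @param leaf_area_fractions Share of the total area per leaf order 1-5;
#'   rises to order 4 and drops at the youngest.
#' @param area_jitter_sd Multiplicative (lognormal-free, clipped Gaussian)
#'   jitter of per-leaf areas.
#' @param phyllotaxis_deg Azimuth step between successive leaves.
#' @param phyllotaxis_jitter_sd Azimuth jitter (degrees).
#' @param inclination_deg Midrib take-off inclination above the horizontal.
#' @param inclination_jitter_sd Inclination jitter (degrees).
#' @param droop_deg Total downward bend of the midrib tip relative to its
#'   take-off direction (degrees).
#' @param stem_radius Stem cylinder radius (m).
#' @param n_u,n_v Lamina grid resolution along / across the midrib.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(mean_height = 0.212, height_sd = 0.03,
                         leaf_area_total = 0.185,
                         leaf_area_fractions = c(0.17, 0.21, 0.24, 0.26, 0.12),
                         area_jitter_sd = 0.06,
                         phyllotaxis_deg = 144,
                         phyllotaxis_jitter_sd = 10,
                         inclination_deg = 28,
                         inclination_jitter_sd = 7,
                         droop_deg = 55,
                         stem_radius = 0.004,
                         n_u = 9, n_v = 6) {
  stopifnot(mean_height > 0, height_sd >= 0, leaf_area_total > 0,
            length(leaf_area_fractions) == 5,
            abs(sum(leaf_area_fractions) - 1) < 1e-6,
            stem_radius > 0, n_u >= 3, n_v >= 2)
  structure(as.list(environment()), class = "synth_params")
}

triangle_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c <- vertices[faces[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

mesh_area <- function(mesh) sum(triangle_areas(mesh$vertices, mesh$faces))

# Build one lamina in its local frame: midrib along +x azimuth, attachment
# at the origin.  Returns mesh with consistent winding whose geometric
# normals point to the adaxial (upper) side for a flat leaf.
build_lamina <- function(length_m, incl_deg, droop_deg, n_u, n_v) {
  u <- seq(0, 1, length.out = n_u + 1)
  # midrib polyline: pitch decreases quadratically from take-off to droop
  psi <- (incl_deg - droop_deg * u^2) * pi / 180
  du <- diff(u) * length_m
  seg <- cbind(cos(psi[-1]) * du, 0, sin(psi[-1]) * du)
  mid <- rbind(c(0, 0, 0), apply(seg, 2, cumsum))
  # cordate-ish width profile, broadest near the base third
  w <- 0.62 * length_m * sin(pi * pmin(1, u^0.85))^0.75
  # midrib lies in the xz-plane, so the horizontal lateral direction is +y
  lat <- cbind(rep(0, n_u + 1), rep(1, n_u + 1), 0)
  v <- seq(-1, 1, length.out = n_v + 1)
  nv1 <- n_v + 1
  verts <- matrix(0, (n_u + 1) * nv1, 3)
  # transverse V-fold scales with the droop parameter: a leaf generated
  # without curvature is exactly planar
  fold <- 0.25 * droop_deg / 55
  for (i in seq_len(n_u + 1)) {
    for (j in seq_len(nv1)) {
      dip <- fold * w[i] * v[j]^2
      verts[(i - 1) * nv1 + j, ] <- mid[i, ] +
        v[j] * w[i] / 2 * lat[i, ] + c(0, 0, -dip)
    }
  }
  faces <- matrix(0L, 0, 3)
  for (i in seq_len(n_u)) {
    for (j in seq_len(n_v)) {
      p00 <- (i - 1) * nv1 + j
      p01 <- p00 + 1
      p10 <- i * nv1 + j
      p11 <- p10 + 1
      faces <- rbind(faces, c(p00, p10, p11), c(p00, p11, p01))
    }
  }
  mesh <- list(vertices = verts, faces = faces)
  # ensure winding gives upward-pointing (adaxial) normals overall
  nrm <- face_normals(mesh)
  if (sum(nrm[, 3] * triangle_areas(verts, faces)) < 0) {
    mesh$faces <- faces[, c(1, 3, 2)]
  }
  drop_degenerate(mesh)
}

face_normals <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  n / pmax(len, 1e-300)
}

drop_degenerate <- function(mesh, min_area = 1e-12) {
  keep <- triangle_areas(mesh$vertices, mesh$faces) > min_area
  mesh$faces <- mesh$faces[keep, , drop = FALSE]
  mesh
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

build_stem <- function(height, radius, n_facets = 8) {
  th <- seq(0, 2 * pi, length.out = n_facets + 1)[-(n_facets + 1)]
  ring0 <- cbind(radius * cos(th), radius * sin(th), 0)
  ring1 <- cbind(radius * cos(th), radius * sin(th), height)
  apex <- c(0, 0, height + radius)
  verts <- rbind(ring0, ring1, apex)
  faces <- matrix(0L, 0, 3)
  for (k in seq_len(n_facets)) {
    k2 <- if (k == n_facets) 1L else k + 1L
    faces <- rbind(faces,
                   c(k, k2, n_facets + k2),
                   c(k, n_facets + k2, n_facets + k),
                   c(n_facets + k, n_facets + k2, 2L * n_facets + 1L))
  }
  list(vertices = verts, faces = faces)
}

#' Generate one cucumber-like plant
#'
#' Deterministic given the parameters and the R random-number state
#' (`set.seed()` before calling for reproducibility).
#'
#' @param params A [synth_params()] list.
#' @return A list of class `plant_architecture` with `height`, `stem`
#'   (mesh), and `leaves`: one entry per order 1-5 holding the lamina
#'   `mesh`, its exact one-sided `area` (m2, summed triangle areas) and
#'   `attach` point.
#' @export
#' @examples
#' set.seed(1)
#' p <- generate_plant()
#' vapply(p$leaves, `[[`, numeric(1), "area")
generate_plant <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  height <- max(0.05, rnorm(1, params$mean_height, params$height_sd))
  node_frac <- c(0.28, 0.46, 0.62, 0.77, 0.92)
  phi0 <- runif(1, 0, 360)
  areas <- params$leaf_area_total * params$leaf_area_fractions *
    pmax(0.5, 1 + rnorm(5, 0, params$area_jitter_sd))
  leaves <- vector("list", 5)
  for (k in 1:5) {
    incl <- params$inclination_deg + rnorm(1, 0, params$inclination_jitter_sd)
    incl <- min(max(incl, 5), 60)
    droop <- params$droop_deg * runif(1, 0.8, 1.2)
    phi <- phi0 + (k - 1) * params$phyllotaxis_deg +
      rnorm(1, 0, params$phyllotaxis_jitter_sd)
    # unit-length lamina, then scale to the target area
    lam <- build_lamina(1, incl, droop, params$n_u, params$n_v)
    scale <- sqrt(areas[k] / mesh_area(lam))
    lam$vertices <- lam$vertices * scale
    # petiole attachment on the stem at the node height
    attach <- c(params$stem_radius, 0, height * node_frac[k])
    lam$vertices <- t(rot_z(phi) %*% t(sweep(lam$vertices, 2, attach, "+")))
    # midrib vertex indices (v = 0 column of the parameter grid): used to
    # place near-leaf sensor reference points
    nv1 <- params$n_v + 1
    j_mid <- params$n_v %/% 2 + 1
    leaves[[k]] <- list(order = k, mesh = lam,
                        area = mesh_area(lam),
                        attach = as.numeric(rot_z(phi) %*% attach),
                        midrib_idx = (seq_len(params$n_u + 1) - 1) * nv1 + j_mid)
  }
  structure(list(height = height,
                 stem = build_stem(height, params$stem_radius),
                 leaves = leaves,
                 params = params),
            class = "plant_architecture")
}

#' @export
print.plant_architecture <- function(x, ...) {
  cat(sprintf("<plant_architecture: height %.3f m, leaf area %.4f m2>\n",
              x$height, sum(vapply(x$leaves, `[[`, numeric(1), "area"))))
  invisible(x)
}

plant_leaf_area <- function(plant) {
  sum(vapply(plant$leaves, `[[`, numeric(1), "area"))
}
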