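# Canopy assembly, leaf area index and mesh import/export.

layout_positions <- function(layout, spacing) {
  switch(layout,
    single = list(pos = matrix(c(0, 0), 1, 2), central = 1L),
    grid3x3 = {
      g <- as.matrix(expand.grid(x = (-1:1) * spacing, y = (-1:1) * spacing))
      list(pos = g, central = which(g[, 1] == 0 & g[, 2] == 0))
    },
    grid4x3 = {
      g <- as.matrix(expand.grid(x = (c(-1.5, -0.5, 0.5, 1.5)) * spacing,
                                 y = (-1:1) * spacing))
      list(pos = g, central = which(abs(g[, 1]) == 0.5 * spacing & g[, 2] == 0))
    },
    stop("unknown layout: ", layout)
  )
}

#' Assemble a canopy scene
#'
#' Places independently generated plants on a regular lattice above a
#' zero-reflectance ground plane at z = 0 (a black disk three times the
#' canopy footprint; since its reflectance is exactly zero its extent only
#' bounds the scene).  Central plants are the interior plant of the 3x3
#' grid and the two interior plants of the 4x3 grid.
#'
#' @param layout One of "single", "grid3x3", "grid4x3".
#' @param spacing Lattice spacing in m (default 0.2).
#' @param params Plant synthesis parameters, see [synth_params()].
#' @return A list of class `canopy_scene`: `plants` (each with an
#'   `architecture` and `position`), `layout`, `spacing`, `central`
#'   (indices), `ground_radius`.
#' @export
#' @examples
#' set.seed(7)
#' sc <- assemble_canopy("grid3x3")
#' length(sc$plants); sc$central
assemble_canopy <- function(layout = c("single", "grid3x3", "grid4x3"),
                            spacing = 0.2, params = synth_params()) {
  layout <- match.arg(layout)
  if (spacing <= 0) stop("spacing must be positive")
  lp <- layout_positions(layout, spacing)
  plants <- lapply(seq_len(nrow(lp$pos)), function(i) {
    list(architecture = generate_plant(params),
         position = c(lp$pos[i, 1], lp$pos[i, 2], 0))
  })
  footprint <- max(sqrt(rowSums(lp$pos^2))) + spacing
  structure(list(plants = plants, layout = layout, spacing = spacing,
                 central = lp$central,
                 ground_radius = 3 * max(footprint, spacing)),
            class = "canopy_scene")
}

#' @export
print.canopy_scene <- function(x, ...) {
  cat(sprintf("<canopy_scene: %s, %d plants at %.2f m spacing, %d central>\n",
              x$layout, length(x$plants), x$spacing, length(x$central)))
  invisible(x)
}

#' Leaf area index of a grid canopy
#'
#' One-sided leaf area per unit ground area, the ground area being
#' `n_plants * spacing^2`.  Undefined (error) for single-plant layouts.
#'
#' @param scene A [assemble_canopy()] scene with a grid layout.
#' @return LAI (dimensionless).
#' @export
lai <- function(scene) {
  stopifnot(inherits(scene, "canopy_scene"))
  if (scene$layout == "single") {
    stop("LAI is undefined for the single-plant layout")
  }
  total <- sum(vapply(scene$plants,
                      function(p) plant_leaf_area(p$architecture),
                      numeric(1)))
  total / (length(scene$plants) * scene$spacing^2)
}

# ---- mesh export / import -------------------------------------------------

#' Export a canopy scene as Wavefront OBJ or PLY
#'
#' One named object per organ: `plant{i}_leaf{order}` and `plant{i}_stem`.
#' Triangles only.
#'
#' @param scene A `canopy_scene`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_canopy_obj <- function(scene, path) {
  con <- file(path, "w")
  on.exit(close(con))
  off <- 0L
  for (i in seq_along(scene$plants)) {
    p <- scene$plants[[i]]
    parts <- c(lapply(p$architecture$leaves, function(l) {
      list(name = sprintf("plant%d_leaf%d", i, l$order), mesh = l$mesh)
    }), list(list(name = sprintf("plant%d_stem", i),
                  mesh = p$architecture$stem)))
    for (part in parts) {
      v <- sweep(part$mesh$vertices, 2, p$position, "+")
      writeLines(sprintf("o %s", part$name), con)
      writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
      f <- part$mesh$faces + off
      writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
      off <- off + nrow(v)
    }
  }
  invisible(path)
}

#' @rdname write_canopy_obj
#' @export
write_canopy_ply <- function(scene, path) {
  verts <- list(); faces <- list(); off <- 0L
  for (i in seq_along(scene$plants)) {
    p <- scene$plants[[i]]
    meshes <- c(lapply(p$architecture$leaves, `[[`, "mesh"),
                list(p$architecture$stem))
    for (m in meshes) {
      verts[[length(verts) + 1]] <- sweep(m$vertices, 2, p$position, "+")
      faces[[length(faces) + 1]] <- m$faces + off
      off <- off + nrow(m$vertices)
    }
  }
  v <- do.call(rbind, verts); f <- do.call(rbind, faces)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' Read a triangle-only Wavefront OBJ file
#'
#' @param path OBJ file.
#' @return A named list of meshes (`vertices`, `faces`), one per `o` object.
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  verts <- matrix(numeric(0), 0, 3)
  out <- list()
  cur_name <- "object"
  cur_faces <- matrix(integer(0), 0, 3)
  flush_obj <- function() {
    if (nrow(cur_faces) > 0) {
      idx <- sort(unique(as.vector(cur_faces)))
      remap <- match(cur_faces, idx)
      out[[cur_name]] <<- list(
        vertices = verts[idx, , drop = FALSE],
        faces = matrix(remap, ncol = 3))
    }
  }
  for (ln in lines) {
    if (startsWith(ln, "o ")) {
      flush_obj()
      cur_name <- sub("^o ", "", ln)
      cur_faces <- matrix(integer(0), 0, 3)
    } else if (startsWith(ln, "v ")) {
      verts <- rbind(verts, as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2:4]))
    } else if (startsWith(ln, "f ")) {
      ids <- strsplit(trimws(ln), "\\s+")[[1]][-1]
      ids <- as.integer(sub("/.*", "", ids))
      if (length(ids) != 3) stop("only triangle faces are supported")
      cur_faces <- rbind(cur_faces, ids)
    }
  }
  flush_obj()
  out
}
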