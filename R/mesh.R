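# Triangulated surface meshes: construction, validation, I/O.

#' Surface mesh constructor
#'
#' A `surface_mesh` is a triangulated surface: an `n x 3` matrix of vertex
#' coordinates in millimetres and an `m x 3` integer matrix of faces (vertex
#' index triples). An optional `mirror_map` records a left-right vertex
#' correspondence: `mirror_map[i]` is the vertex whose position is the
#' x-negated position of vertex `i`.
#'
#' @param vertices numeric matrix, `n x 3`, coordinates in mm.
#' @param faces integer matrix, `m x 3`, 1-based vertex indices.
#' @param mirror_map optional integer vector of length `n`; must be an
#'   involution pairing x-negated coordinates.
#' @param validate check invariants (face indices, edge-connectivity,
#'   mirror involution)?
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, mirror_map = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L)
  mesh <- structure(
    list(vertices = vertices, faces = faces, mirror_map = mirror_map),
    class = "surface_mesh"
  )
  if (validate) validate_mesh(mesh)
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$mirror_map)) ", mirrored" else ""))
  invisible(x)
}

#' Validate surface mesh invariants
#'
#' Checks face-index validity, edge connectivity of the vertex graph, and
#' (when present) that `mirror_map` is an involution pairing x-negated
#' coordinates within tolerance.
#'
#' @param mesh a `surface_mesh`.
#' @param tol relative tolerance for the mirror-coordinate check.
#' @return `TRUE`, invisibly; errors on violation.
#' @export
validate_mesh <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices; f <- mesh$faces
  if (any(f < 1L) || any(f > nrow(v)))
    stop("face indices out of range")
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    stop("degenerate face (repeated vertex)")
  e <- mesh_edges(mesh)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(v) - igraph::vcount(g)))
  if (igraph::count_components(g) != 1L)
    stop("mesh is not edge-connected")
  mm <- mesh$mirror_map
  if (!is.null(mm)) {
    if (length(mm) != nrow(v) || any(mm[mm] != seq_len(nrow(v))))
      stop("mirror_map is not an involution")
    mirrored <- v[mm, , drop = FALSE]
    mirrored[, 1] <- -mirrored[, 1]
    scale <- max(abs(v))
    if (max(abs(mirrored - v)) > tol * scale)
      stop("mirror_map does not pair x-negated coordinates")
  }
  invisible(TRUE)
}

#' Unique undirected edges of a mesh
#' @param mesh a `surface_mesh`.
#' @return integer matrix, one row per unique undirected edge.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Per-face triangle areas
#' @param mesh a `surface_mesh`.
#' @return numeric vector of face areas (mm^2).
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], ] - v[f[, 1], ]
  b <- v[f[, 3], ] - v[f[, 1], ]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Barycentric (lumped) vertex areas
#'
#' One third of the total area of the triangles incident to each vertex;
#' identical to the diagonal of the lumped FEM mass matrix.
#'
#' @param mesh a `surface_mesh`.
#' @return numeric vector of vertex areas (mm^2).
#' @export
vertex_areas <- function(mesh) {
  fa <- face_areas(mesh)
  n <- nrow(mesh$vertices)
  third <- rep(fa / 3, 3)
  idx <- c(mesh$faces)
  agg <- rowsum(third, idx)
  out <- numeric(n)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# icosahedron with poles on the x axis (so a vertex sits exactly at (-r,0,0))
icosahedron_xpole <- function() {
  # poles +-1 on z, two pentagonal rings; then permute (x,y,z) -> (z,x,y)
  t <- (1 + sqrt(5)) / 2
  lat <- atan(1 / 2)
  ring1 <- t(vapply(0:4, function(k) {
    a <- 2 * pi * k / 5
    c(cos(lat) * cos(a), cos(lat) * sin(a), sin(lat))
  }, numeric(3)))
  ring2 <- t(vapply(0:4, function(k) {
    a <- 2 * pi * (k + 0.5) / 5
    c(cos(lat) * cos(a), cos(lat) * sin(a), -sin(lat))
  }, numeric(3)))
  v <- rbind(c(0, 0, 1), ring1, ring2, c(0, 0, -1))
  f <- matrix(NA_integer_, 20, 3)
  for (k in 0:4) {
    k1 <- 2 + k; k2 <- 2 + (k + 1) %% 5          # ring1
    k3 <- 7 + k; k4 <- 7 + (k + 1) %% 5          # ring2
    f[k + 1, ]  <- c(1, k1, k2)                  # top cap
    f[k + 6, ]  <- c(k1, k3, k2)
    f[k + 11, ] <- c(k2, k3, k4)
    f[k + 16, ] <- c(12, k4, k3)                 # bottom cap
  }
  v <- v[, c(3, 1, 2)]  # (x,y,z) <- (z,x,y): poles now at (+-1, 0, 0)
  list(vertices = v, faces = f)
}

# one round of midpoint subdivision followed by projection to the unit sphere
subdivide_sphere <- function(v, f) {
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  uk <- !duplicated(key)
  ue <- e[uk, , drop = FALSE]
  mid <- (v[ue[, 1], ] + v[ue[, 2], ]) / 2
  mid <- mid / sqrt(rowSums(mid^2))
  mid_idx <- nrow(v) + match(key, key[uk])
  m12 <- mid_idx[seq_len(nrow(f))]
  m23 <- mid_idx[nrow(f) + seq_len(nrow(f))]
  m31 <- mid_idx[2 * nrow(f) + seq_len(nrow(f))]
  nf <- rbind(
    cbind(f[, 1], m12, m31),
    cbind(f[, 2], m23, m12),
    cbind(f[, 3], m31, m23),
    cbind(m12, m23, m31)
  )
  list(vertices = rbind(v, mid), faces = nf)
}

#' Icosphere mesh
#'
#' Closed triangulated sphere obtained by repeated midpoint subdivision of an
#' icosahedron with projection back to the sphere. Vertex count is
#' `10 * 4^subdivisions + 2`. Used as validation geometry for the eigenmode
#' solver (the Laplace-Beltrami spectrum of the sphere is known in closed
#' form).
#'
#' @param subdivisions non-negative integer number of subdivision rounds.
#' @param radius sphere radius (mm).
#' @return a `surface_mesh`.
#' @export
make_sphere_mesh <- function(subdivisions, radius = 1) {
  stopifnot(subdivisions >= 0, radius > 0)
  ico <- icosahedron_xpole()
  v <- ico$vertices; f <- ico$faces
  s <- subdivisions
  while (s > 0) {
    sub <- subdivide_sphere(v, f)
    v <- sub$vertices; f <- sub$faces
    s <- s - 1
  }
  surface_mesh(v * radius, f)
}

#' Two-lobe bihemispheric surface
#'
#' A smooth stand-in for the infant cortical surface at term-equivalent age:
#' two mirrored ellipsoidal lobes (icospheres scaled by `lobe_semi_axes`)
#' offset by `+-(gap/2 + x semi-axis)` along x. The medial pole vertex of each
#' lobe and its five incident faces are removed and the two pentagonal rings
#' are stitched by a thin 10-triangle band, so the mesh is a single connected
#' component; this keeps the first eigenmode global and the second mode
#' left-right antisymmetric. `mirror_map` pairs every vertex with its
#' x-negated twin.
#'
#' @param lobe_semi_axes positive lengths (mm) of the ellipsoid semi-axes
#'   (x, y, z); default `c(60, 45, 40)`.
#' @param gap inter-hemispheric gap (mm) between the medial ends of the lobes.
#' @param subdivisions icosphere subdivision level per lobe.
#' @return a `surface_mesh` with `mirror_map` populated.
#' @export
make_bihemispheric_mesh <- function(lobe_semi_axes = c(60, 45, 40), gap = 6,
                                    subdivisions = 3) {
  if (any(lobe_semi_axes <= 0)) stop("degenerate semi-axes")
  sph <- make_sphere_mesh(subdivisions, 1)
  v <- sph$vertices; f <- sph$faces
  # medial pole of the right lobe: the vertex at exactly (-1, 0, 0)
  pole <- which.min(v[, 1])
  ring <- setdiff(unique(c(f[rowSums(f == pole) > 0, ])), pole)
  # order ring circularly by angle in the (y, z) plane
  ring <- ring[order(atan2(v[ring, 3], v[ring, 2]))]
  keep_f <- f[rowSums(f == pole) == 0, , drop = FALSE]
  # drop the pole vertex, reindex
  keep_v <- setdiff(seq_len(nrow(v)), pole)
  remap <- integer(nrow(v)); remap[keep_v] <- seq_along(keep_v)
  vr <- v[keep_v, , drop = FALSE]
  fr <- matrix(remap[keep_f], ncol = 3)
  ring <- remap[ring]
  # scale to ellipsoid and shift right
  vr <- sweep(vr, 2, lobe_semi_axes, "*")
  shift <- gap / 2 + lobe_semi_axes[1]
  vr[, 1] <- vr[, 1] + shift
  nv <- nrow(vr)
  # left lobe: mirror x, reverse face orientation
  vl <- vr; vl[, 1] <- -vl[, 1]
  fl <- fr[, c(1, 3, 2)] + nv
  ring_l <- ring + nv
  # stitch pentagonal rings (same circular order on both sides)
  band <- do.call(rbind, lapply(seq_along(ring), function(k) {
    k2 <- if (k == length(ring)) 1L else k + 1L
    rbind(c(ring[k], ring_l[k], ring[k2]),
          c(ring_l[k], ring_l[k2], ring[k2]))
  }))
  vertices <- rbind(vr, vl)
  faces <- rbind(fr, fl, band)
  mirror_map <- c(seq_len(nv) + nv, seq_len(nv))
  mesh <- surface_mesh(vertices, faces, mirror_map = mirror_map)
  attr(mesh, "lobe") <- rep(c("R", "L"), each = nv)
  attr(mesh, "lobe_faces") <- c(rep("R", nrow(fr)), rep("L", nrow(fl)),
                                rep("band", nrow(band)))
  mesh
}

#' Hemisphere label per vertex
#'
#' @param mesh a bihemispheric `surface_mesh`.
#' @return character vector, `"L"` or `"R"` per vertex.
#' @export
hemisphere_of <- function(mesh) {
  lab <- attr(mesh, "lobe")
  if (is.null(lab)) lab <- ifelse(mesh$vertices[, 1] < 0, "L", "R")
  lab
}

#' Write a mesh as ASCII PLY
#' @param mesh a `surface_mesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(v)),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices", "end_header"
  ), con)
  writeLines(apply(format(v, digits = 17, trim = TRUE), 1, paste, collapse = " "), con)
  writeLines(paste(3, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY mesh
#' @param path PLY file path.
#' @return a `surface_mesh` (no mirror map).
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  endh <- which(lines == "end_header")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
  vtxt <- lines[endh + seq_len(nv)]
  ftxt <- lines[endh + nv + seq_len(nf)]
  v <- matrix(as.numeric(unlist(strsplit(vtxt, " "))), ncol = 3, byrow = TRUE)
  fraw <- matrix(as.integer(unlist(strsplit(ftxt, " "))), ncol = 4, byrow = TRUE)
  surface_mesh(v, fraw[, 2:4] + 1L)
}

#' Write a mesh as OFF
#' @inheritParams write_ply
#' @return `path`, invisibly.
#' @export
write_off <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("OFF", sprintf("%d %d 0", nrow(v), nrow(f))), con)
  writeLines(apply(format(v, digits = 17, trim = TRUE), 1, paste, collapse = " "), con)
  writeLines(paste(3, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' Read an OFF mesh
#' @param path OFF file path.
#' @return a `surface_mesh` (no mirror map).
#' @export
read_off <- function(path) {
  lines <- readLines(path)
  stopifnot(lines[1] == "OFF")
  counts <- as.integer(strsplit(lines[2], " ")[[1]])
  nv <- counts[1]; nf <- counts[2]
  v <- matrix(as.numeric(unlist(strsplit(lines[2 + seq_len(nv)], " "))),
              ncol = 3, byrow = TRUE)
  fraw <- matrix(as.integer(unlist(strsplit(lines[2 + nv + seq_len(nf)], " "))),
                 ncol = 4, byrow = TRUE)
  surface_mesh(v, fraw[, 2:4] + 1L)
}
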