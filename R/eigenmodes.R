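# Laplace-Beltrami eigenmodes on a triangular mesh by linear finite elements.
#
# The Helmholtz problem  div grad m_j = -k_j^2 m_j  on the surface is
# discretized with the cotangent stiffness matrix K and barycentric lumped
# mass matrix M, giving the generalized symmetric eigenproblem
# K m = k^2 M m. Modes are mass-orthonormal (m_i' M m_j = delta_ij).

#' Assemble the FEM Laplace-Beltrami operator
#'
#' Linear finite elements: the stiffness matrix uses the classical cotangent
#' weights (one half of the cotangent of each angle opposite an edge) and the
#' mass matrix is lumped barycentrically (one third of the incident triangle
#' area per vertex). The stiffness matrix is the discrete Dirichlet energy,
#' i.e. positive semi-definite with the constant vector in its null space.
#'
#' @param mesh a `surface_mesh` without degenerate (zero-area) triangles.
#' @return an object of class `laplace_operator`: list with sparse symmetric
#'   `stiffness` and diagonal `mass` (both vertex x vertex), and the total
#'   surface `area`.
#' @export
assemble_laplace_beltrami <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  n <- nrow(v)
  fa <- face_areas(mesh)
  bad <- which(fa <= 1e-12 * stats::median(fa))
  if (length(bad))
    stop("degenerate triangle at face index ", bad[1])
  # cotangent at the vertex opposite each edge
  cot_at <- function(apex, p, q) {
    u <- v[p, , drop = FALSE] - v[apex, , drop = FALSE]
    w <- v[q, , drop = FALSE] - v[apex, , drop = FALSE]
    dotp <- rowSums(u * w)
    # |u x w| = 2 * area of the triangle
    dotp / (2 * fa)
  }
  c3 <- cot_at(f[, 3], f[, 1], f[, 2])  # opposite edge (1,2)
  c1 <- cot_at(f[, 1], f[, 2], f[, 3])  # opposite edge (2,3)
  c2 <- cot_at(f[, 2], f[, 3], f[, 1])  # opposite edge (3,1)
  ii <- c(f[, 1], f[, 2], f[, 3])
  jj <- c(f[, 2], f[, 3], f[, 1])
  ww <- c(c3, c1, c2) / 2
  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                            dims = c(n, n))
  K <- Matrix::Diagonal(n, Matrix::rowSums(W)) - W
  M <- Matrix::Diagonal(n, vertex_areas(mesh))
  structure(list(stiffness = K, mass = M, area = sum(fa)),
            class = "laplace_operator")
}

#' @export
print.laplace_operator <- function(x, ...) {
  cat(sprintf("laplace_operator: %d vertices, surface area %.2f\n",
              nrow(x$stiffness), x$area))
  invisible(x)
}

# deterministic sign convention: largest-|entry| component positive,
# ties broken by the lowest vertex index
fix_mode_signs <- function(modes) {
  for (j in seq_len(ncol(modes))) {
    m <- modes[, j]
    i <- which.max(abs(m))  # which.max returns the first (lowest) index on ties
    if (m[i] < 0) modes[, j] <- -m
  }
  modes
}

#' Solve for the smallest Laplace-Beltrami eigenmodes
#'
#' Solves `K m = k^2 M m` as the symmetric eigenproblem of
#' `M^{-1/2} K M^{-1/2}` (exact with the lumped diagonal mass matrix) by a
#' dense symmetric eigendecomposition, returning the `n_modes` smallest
#' eigenpairs. The first eigenvalue of a connected closed surface is 0 with a
#' constant mode. Modes are mass-orthonormal and sign-fixed (largest-magnitude
#' entry positive, ties to the lowest vertex index) so repeated solves are
#' bit-reproducible.
#'
#' @param op a `laplace_operator` from [assemble_laplace_beltrami()].
#' @param n_modes number of modes, `1 <= n_modes <=` vertex count.
#' @param mesh optional `surface_mesh`; when supplied (with a mirror map), the
#'   modes are symmetry-labelled via [classify_symmetry()].
#' @return an object of class `eigenmode_basis`: list with `modes`
#'   (vertex x `n_modes`), `eigenvalues` (`k^2`, 1/mm^2, ascending),
#'   `mass` (diagonal of M) and `symmetry` labels.
#' @export
solve_eigenmodes <- function(op, n_modes, mesh = NULL) {
  n <- nrow(op$stiffness)
  if (n_modes < 1 || n_modes > n) stop("n_modes out of range")
  d <- Matrix::diag(op$mass)
  if (any(d <= 0)) stop("mass matrix not positive definite")
  s <- 1 / sqrt(d)
  S <- Matrix::Diagonal(n, s) %*% op$stiffness %*% Matrix::Diagonal(n, s)
  S <- as.matrix(Matrix::forceSymmetric(S))
  ee <- eigen(S, symmetric = TRUE)
  idx <- seq(n, n - n_modes + 1)        # ascending eigenvalues
  lambda <- ee$values[idx]
  lambda[abs(lambda) < 1e-10] <- pmax(lambda[abs(lambda) < 1e-10], 0)
  modes <- ee$vectors[, idx, drop = FALSE] * s
  # mass-orthonormal by construction: modes' M modes = vectors' vectors = I
  modes <- fix_mode_signs(modes)
  basis <- structure(list(
    modes = modes,
    eigenvalues = lambda,
    mass = d,
    symmetry = rep("unclassified", n_modes)
  ), class = "eigenmode_basis")
  if (!is.null(mesh) && !is.null(mesh$mirror_map))
    basis <- classify_symmetry(basis, mesh)
  basis
}

#' @export
print.eigenmode_basis <- function(x, ...) {
  cat(sprintf("eigenmode_basis: %d modes on %d vertices\n",
              ncol(x$modes), nrow(x$modes)))
  cat("  k^2:", format(utils::head(x$eigenvalues, 6), digits = 4), "...\n")
  invisible(x)
}

#' Label modes as symmetric / antisymmetric under the mirror map
#'
#' A mode is `symmetric` if `||m(mirror) - m|| / ||m|| < tol`, `antisymmetric`
#' if `||m(mirror) + m|| / ||m|| < tol`, otherwise `unclassified`.
#'
#' @param basis an `eigenmode_basis`.
#' @param mesh the `surface_mesh` with `mirror_map`.
#' @param tol relative residual tolerance (default 0.1).
#' @return the basis with the `symmetry` field filled in.
#' @export
classify_symmetry <- function(basis, mesh, tol = 0.1) {
  mm <- mesh$mirror_map
  if (is.null(mm)) stop("mesh has no mirror_map")
  labels <- vapply(seq_len(ncol(basis$modes)), function(j) {
    m <- basis$modes[, j]
    nm <- sqrt(sum(m^2))
    rs <- sqrt(sum((m[mm] - m)^2)) / nm
    ra <- sqrt(sum((m[mm] + m)^2)) / nm
    if (rs < tol) "symmetric" else if (ra < tol) "antisymmetric" else "unclassified"
  }, character(1))
  basis$symmetry <- labels
  basis
}

#' Mode indices for the four-mode field model
#'
#' The field model superposes the global constant mode, the left-right
#' antisymmetric mode (weight fixed at 0) and the first two bilaterally
#' symmetric higher modes (the anteroposterior patterns). Because modes 3-5
#' of the two-lobe geometry are nearly degenerate, their spectral order can
#' swap between mesh resolutions; this helper selects them by symmetry label
#' instead of raw index.
#'
#' @param basis an `eigenmode_basis` with symmetry labels (solve with
#'   `mesh =` or run [classify_symmetry()]).
#' @return integer vector of four mode indices: constant, antisymmetric,
#'   first and second symmetric higher modes.
#' @export
model_modes <- function(basis) {
  lab <- basis$symmetry
  if (all(lab == "unclassified"))
    stop("basis has no symmetry labels; run classify_symmetry() first")
  anti <- which(lab == "antisymmetric")
  sym <- setdiff(which(lab == "symmetric"), 1L)
  if (!length(anti) || length(sym) < 2)
    stop("basis needs at least one antisymmetric and two symmetric higher ",
         "modes; solve for more modes")
  c(1L, anti[1], sym[1], sym[2])
}

#' Area-weighted parcel means of the eigenmodes
#'
#' Entry `(p, j)` is the lumped-mass (vertex-area) weighted mean of mode `j`
#' over the vertices of parcel `p`; this is the bridge from vertex-level modes
#' to parcel-level signal amplitudes.
#'
#' Mode values are scaled by `scaling`: the default `"rms"` rescales each
#' mode to unit mass-weighted root-mean-square amplitude over the surface
#' (the constant first mode becomes exactly 1 everywhere), so that a mode
#' weight `a_j` is the oscillation amplitude relative to unit-SD noise — the
#' dimensionless signal-to-noise convention the moment-matching fit assumes.
#' `"mass"` keeps the raw mass-orthonormal modes.
#'
#' The `noise_sd` attribute gives the per-parcel SD of the parcel projection
#' of unit-SD white noise (parcels are disjoint, so projected noise is
#' independent across parcels). By default it emulates the source density of
#' the reference pipeline — 8014 cortical dipoles, so each parcel averages
#' `8014 x area share` (~125) independent sources and its noise SD is
#' `1/sqrt(n sources)` — rather than the (resolution-dependent) vertex count
#' of the mesh in hand; pass `n_sources = NULL` to use the mesh's own
#' vertices as the noise discretization.
#'
#' @param basis an `eigenmode_basis`.
#' @param parcellation a `parcellation` on the same mesh.
#' @param mesh the shared `surface_mesh`.
#' @param scaling `"rms"` (default) or `"mass"`.
#' @param n_sources effective number of noise sources on the whole surface
#'   (default 8014); `NULL` for mesh-vertex noise.
#' @param mode_order optional integer vector selecting/reordering mode
#'   columns (e.g. [model_modes()] so that columns 1-4 are the model's
#'   constant, antisymmetric and two symmetric modes).
#' @return a `n_parcels x n_modes` matrix (class `parcel_mode_matrix`) with
#'   attributes `noise_sd` and `parcel_area`.
#' @export
parcel_mode_values <- function(basis, parcellation, mesh,
                               scaling = c("rms", "mass"),
                               n_sources = 8014, mode_order = NULL) {
  scaling <- match.arg(scaling)
  if (length(parcellation$vertex_to_parcel) != nrow(basis$modes))
    stop("parcellation and basis disagree on vertex count")
  w <- vertex_areas(mesh)
  v2p <- parcellation$vertex_to_parcel
  np <- parcellation$n_parcels
  if (any(tabulate(v2p, np) == 0L)) stop("empty parcel")
  wsum <- as.numeric(rowsum(w, v2p))
  modes <- basis$modes
  if (scaling == "rms") modes <- modes * sqrt(sum(w))
  PM <- rowsum(modes * w, v2p) / wsum
  # projection operator rows: A[p, v] = w_v / wsum_p for v in parcel p
  # => Cov(A eta)_pq = sum_v A_pv A_qv for unit vertex noise; block-diagonal
  # by parcel (parcels are disjoint), so it is diagonal:
  nvar <- if (is.null(n_sources)) {
    as.numeric(rowsum(w^2, v2p)) / wsum^2
  } else {
    1 / (n_sources * wsum / sum(wsum))
  }
  PM <- as.matrix(PM)
  dimnames(PM) <- NULL
  if (!is.null(mode_order)) PM <- PM[, mode_order, drop = FALSE]
  structure(PM, class = c("parcel_mode_matrix", "matrix"),
            noise_sd = sqrt(nvar), parcel_area = wsum)
}

#' Persist an eigenmode basis as a directory container
#'
#' Writes `modes.tsv` (vertex x J), `eigenvalues.tsv`, `labels.tsv` and
#' `meta.json` (including an md5 checksum of the mesh for provenance) under
#' `dir`.
#'
#' @param basis an `eigenmode_basis`.
#' @param dir output directory (created if absent).
#' @param mesh optional mesh used to record a provenance checksum.
#' @return `dir`, invisibly.
#' @export
write_eigenmode_basis <- function(basis, dir, mesh = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(basis$modes, file.path(dir, "modes.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(k2 = basis$eigenvalues),
                     file.path(dir, "eigenvalues.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(label = basis$symmetry),
                     file.path(dir, "labels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  checksum <- NA_character_
  if (!is.null(mesh)) {
    tmp <- tempfile(); on.exit(unlink(tmp))
    saveRDS(list(mesh$vertices, mesh$faces), tmp)
    checksum <- unname(tools::md5sum(tmp))
  }
  jsonlite::write_json(list(n_modes = ncol(basis$modes),
                            n_vertices = nrow(basis$modes),
                            mesh_md5 = checksum),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read an eigenmode basis written by [write_eigenmode_basis()]
#' @param dir container directory.
#' @return an `eigenmode_basis` (mass diagonal not restored).
#' @export
read_eigenmode_basis <- function(dir) {
  modes <- as.matrix(utils::read.table(file.path(dir, "modes.tsv"), sep = "\t"))
  dimnames(modes) <- NULL
  structure(list(
    modes = modes,
    eigenvalues = utils::read.table(file.path(dir, "eigenvalues.tsv"),
                                    header = TRUE, sep = "\t")$k2,
    mass = NULL,
    symmetry = utils::read.table(file.path(dir, "labels.tsv"),
                                 header = TRUE, sep = "\t",
                                 colClasses = "character")$label
  ), class = "eigenmode_basis")
}
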