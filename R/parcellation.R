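# Bilaterally symmetric cortical parcellation on a mirrored mesh.

#' Symmetric parcellation of a bihemispheric mesh
#'
#' Parcels are grown on the right lobe by farthest-point seeding followed by
#' geodesic nearest-seed assignment (graph distances along mesh edges), then
#' mirrored to the left lobe through `mirror_map`. With the default
#' `n_pairs = 29` this yields the 58-region scheme (29 bilaterally symmetric
#' pairs) used throughout the package. Parcels `1..n_pairs` lie in the right
#' hemisphere and parcel `p` is paired with parcel `p + n_pairs`.
#'
#' @param mesh a `surface_mesh` with `mirror_map`.
#' @param n_pairs number of left-right parcel pairs (default 29).
#' @return an object of class `parcellation` with fields `vertex_to_parcel`
#'   (integer per vertex), `parcel_pairs` (`n_pairs x 2` matrix),
#'   `centroids` (`2*n_pairs x 3`, unweighted vertex means, mm),
#'   `hemisphere` (`"R"`/`"L"` per parcel) and `n_parcels`.
#' @export
make_symmetric_parcellation <- function(mesh, n_pairs = 29) {
  if (is.null(mesh$mirror_map)) stop("mesh has no mirror_map")
  hemi <- hemisphere_of(mesh)
  right <- which(hemi == "R")
  if (n_pairs > length(right))
    stop("too many pairs for vertex count: ", n_pairs, " > ", length(right))
  # geodesic distances within the right lobe
  e <- mesh_edges(mesh)
  keep <- hemi[e[, 1]] == "R" & hemi[e[, 2]] == "R"
  er <- e[keep, , drop = FALSE]
  len <- sqrt(rowSums((mesh$vertices[er[, 1], , drop = FALSE] -
                       mesh$vertices[er[, 2], , drop = FALSE])^2))
  remap <- integer(nrow(mesh$vertices)); remap[right] <- seq_along(right)
  g <- igraph::graph_from_edgelist(cbind(remap[er[, 1]], remap[er[, 2]]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(right) - igraph::vcount(g)))
  igraph::E(g)$weight <- len
  # farthest-point seeding, deterministic: first seed = lowest vertex index
  seeds <- integer(n_pairs)
  seeds[1] <- 1L
  dmin <- as.numeric(igraph::distances(g, v = seeds[1]))
  if (n_pairs > 1) {
    for (k in 2:n_pairs) {
      seeds[k] <- which.max(dmin)  # ties: lowest index (which.max convention)
      dk <- as.numeric(igraph::distances(g, v = seeds[k]))
      dmin <- pmin(dmin, dk)
    }
  }
  dseed <- igraph::distances(g, v = seeds)  # n_pairs x n_right
  assign_r <- apply(dseed, 2, which.min)    # ties: lowest seed id
  v2p <- integer(nrow(mesh$vertices))
  v2p[right] <- assign_r
  v2p[mesh$mirror_map[right]] <- assign_r + n_pairs
  n_parcels <- 2L * n_pairs
  centroids <- t(vapply(seq_len(n_parcels), function(p) {
    colMeans(mesh$vertices[v2p == p, , drop = FALSE])
  }, numeric(3)))
  structure(list(
    vertex_to_parcel = v2p,
    parcel_pairs = cbind(right = seq_len(n_pairs),
                         left = seq_len(n_pairs) + n_pairs),
    centroids = centroids,
    hemisphere = rep(c("R", "L"), each = n_pairs),
    n_parcels = n_parcels
  ), class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("parcellation: %d parcels (%d bilateral pairs)\n",
              x$n_parcels, nrow(x$parcel_pairs)))
  invisible(x)
}

#' Validate a parcellation against its mesh
#' @param parcellation a `parcellation`.
#' @param mesh the `surface_mesh` it was built on.
#' @return `TRUE`, invisibly; errors on violation.
#' @export
validate_parcellation <- function(parcellation, mesh) {
  v2p <- parcellation$vertex_to_parcel
  if (length(v2p) != nrow(mesh$vertices)) stop("vertex count mismatch")
  if (any(v2p < 1L | v2p > parcellation$n_parcels)) stop("unassigned vertex")
  counts <- tabulate(v2p, parcellation$n_parcels)
  if (any(counts == 0L)) stop("empty parcel")
  pp <- parcellation$parcel_pairs
  if (!setequal(c(pp), seq_len(parcellation$n_parcels)))
    stop("parcel_pairs is not a perfect matching")
  invisible(TRUE)
}

#' Write parcellation as TSV + JSON metadata
#'
#' Vertex assignments go to `<path>.tsv` (columns `vertex_id`, `parcel_id`);
#' pairs and centroids go to `<path>.json`.
#'
#' @param parcellation a `parcellation`.
#' @param path output path stem (no extension).
#' @return `path`, invisibly.
#' @export
write_parcellation <- function(parcellation, path) {
  tab <- data.frame(vertex_id = seq_along(parcellation$vertex_to_parcel),
                    parcel_id = parcellation$vertex_to_parcel)
  utils::write.table(tab, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  meta <- list(parcel_pairs = parcellation$parcel_pairs,
               centroids = parcellation$centroids,
               hemisphere = parcellation$hemisphere,
               n_parcels = parcellation$n_parcels)
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' Read a parcellation written by [write_parcellation()]
#' @param path path stem used at write time.
#' @return a `parcellation`.
#' @export
read_parcellation <- function(path) {
  tab <- utils::read.table(paste0(path, ".tsv"), header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(
    vertex_to_parcel = as.integer(tab$parcel_id[order(tab$vertex_id)]),
    parcel_pairs = matrix(as.integer(meta$parcel_pairs), ncol = 2,
                          dimnames = list(NULL, c("right", "left"))),
    centroids = matrix(as.numeric(meta$centroids), ncol = 3),
    hemisphere = as.character(meta$hemisphere),
    n_parcels = as.integer(meta$n_parcels)
  ), class = "parcellation")
}

#' Toy source-leakage operator
#'
#' A parcel-by-parcel mixing matrix emulating source-reconstruction
#' cross-talk: mixing weight decays as a Gaussian of the Euclidean centroid
#' distance at length scale `spread`, with rows normalized to sum to one.
#' `spread = 0` returns the identity; as `spread` grows the rows approach the
#' uniform distribution.
#'
#' @param parcellation a `parcellation` (centroids are used).
#' @param spread kernel length scale (mm), `>= 0`.
#' @param seed accepted for interface stability; the kernel is deterministic
#'   and the argument is unused.
#' @return an object of class `leakage_operator`: list with `mixing`
#'   (row-stochastic matrix) and `spread`.
#' @export
make_toy_leakage_operator <- function(parcellation, spread, seed = NULL) {
  if (spread < 0) stop("spread must be >= 0")
  n <- parcellation$n_parcels
  if (spread == 0) {
    W <- diag(n)
  } else {
    d <- as.matrix(stats::dist(parcellation$centroids))
    W <- exp(-d^2 / (2 * spread^2))
    W <- W / rowSums(W)
    dimnames(W) <- NULL
  }
  structure(list(mixing = W, spread = spread), class = "leakage_operator")
}

#' @export
print.leakage_operator <- function(x, ...) {
  cat(sprintf("leakage_operator: %d parcels, spread %.1f mm\n",
              nrow(x$mixing), x$spread))
  invisible(x)
}
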