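#' Triangulated spherical surface mesh
#'
#' Builds an icosphere: a regular icosahedron whose triangles are repeatedly
#' subdivided (each into four, midpoints projected back to the sphere). The
#' result stands in for a cortical surface atlas at desk scale. Per-vertex
#' areas are computed as one third of the summed areas of the incident
#' triangles, so vertex areas partition the total (flat-triangle) mesh area
#' exactly. A polar cap of vertices is marked excluded, emulating the medial
#' wall that is removed from all vertex-wise computation.
#'
#' @param n_subdivisions Number of 4-fold triangle subdivisions (>= 0);
#'   vertex counts are 12, 42, 162, 642, 2562, ...
#' @param seed Optional integer; when given, the sphere receives a random
#'   rigid rotation (so bump placement and the exclusion cap vary between
#'   seeds) and the mesh is otherwise deterministic in all inputs.
#' @param radius Sphere radius, in the length unit of the analysis
#'   (millimetres for brain-scale meshes). Default 1.
#' @param exclusion_frac Fraction of vertices (nearest the south pole)
#'   flagged excluded. Default 0.05.
#' @return An object of class `surf_mesh`: list with `coordinates` (V x 3),
#'   `triangles` (F x 3, 1-based), `vertex_areas` (length V, positive),
#'   `exclusion_mask` (length V logical, TRUE = excluded), `radius`.
#' @export
make_mesh <- function(n_subdivisions, seed = NULL, radius = 1,
                      exclusion_frac = 0.05) {
  stopifnot(n_subdivisions >= 0, radius > 0,
            exclusion_frac >= 0, exclusion_frac < 1)
  phi <- (1 + sqrt(5)) / 2
  verts <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  verts <- verts / sqrt(rowSums(verts^2))
  tris <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))

  for (s in seq_len(n_subdivisions)) {
    midpoint_cache <- new.env(hash = TRUE)
    vlist <- lapply(seq_len(nrow(verts)), function(i) verts[i, ])
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      idx <- midpoint_cache[[key]]
      if (is.null(idx)) {
        m <- (vlist[[a]] + vlist[[b]]) / 2
        m <- m / sqrt(sum(m^2))
        vlist[[length(vlist) + 1]] <<- m
        idx <- length(vlist)
        midpoint_cache[[key]] <- idx
      }
      idx
    }
    new_tris <- matrix(0L, nrow = 4L * nrow(tris), ncol = 3L)
    for (f in seq_len(nrow(tris))) {
      a <- tris[f, 1]; b <- tris[f, 2]; c3 <- tris[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      new_tris[4 * f - 3, ] <- c(a, ab, ca)
      new_tris[4 * f - 2, ] <- c(b, bc, ab)
      new_tris[4 * f - 1, ] <- c(c3, ca, bc)
      new_tris[4 * f, ]     <- c(ab, bc, ca)
    }
    verts <- do.call(rbind, vlist)
    tris <- new_tris
  }

  if (!is.null(seed)) {
    old <- .Random.seed_save()
    set.seed(as.integer(seed))
    qr_m <- qr(matrix(stats::rnorm(9), 3, 3))
    R <- qr.Q(qr_m)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    verts <- verts %*% R
    .Random.seed_restore(old)
  }
  verts <- verts * radius

  storage.mode(tris) <- "integer"
  areas <- triangle_areas(verts, tris)
  vareas <- vertex_areas_from_triangles(nrow(verts), tris, areas)

  n_excl <- floor(exclusion_frac * nrow(verts))
  excl <- rep(FALSE, nrow(verts))
  if (n_excl > 0) {
    # cap nearest the (rotated-frame) south pole
    excl[order(verts[, 3])[seq_len(n_excl)]] <- TRUE
  }

  structure(
    list(coordinates = verts, triangles = tris, vertex_areas = vareas,
         exclusion_mask = excl, radius = radius),
    class = "surf_mesh")
}

#' Flat triangulated patch (for smoothing validation)
#'
#' Regular triangular-lattice patch in the z = 0 plane. Useful for checking
#' that graph heat diffusion reproduces a planar Gaussian kernel.
#'
#' @param nx,ny Grid dimensions (vertices per side).
#' @param spacing Lattice spacing (same unit as smoothing FWHM).
#' @return A `surf_mesh` (no vertices excluded).
#' @export
make_flat_patch <- function(nx, ny, spacing = 1) {
  stopifnot(nx >= 2, ny >= 2, spacing > 0)
  ij <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  # offset alternate rows for equilateral-ish triangles
  x <- (ij$i - 1) * spacing + ifelse(ij$j %% 2 == 0, spacing / 2, 0)
  y <- (ij$j - 1) * spacing * sqrt(3) / 2
  verts <- cbind(x, y, 0)
  idx <- function(i, j) (j - 1L) * nx + i
  tris <- list()
  for (j in seq_len(ny - 1)) {
    for (i in seq_len(nx - 1)) {
      a <- idx(i, j); b <- idx(i + 1, j)
      c3 <- idx(i, j + 1); d <- idx(i + 1, j + 1)
      if (j %% 2 == 1) {
        tris[[length(tris) + 1]] <- c(a, b, c3)
        tris[[length(tris) + 1]] <- c(b, d, c3)
      } else {
        tris[[length(tris) + 1]] <- c(a, b, d)
        tris[[length(tris) + 1]] <- c(a, d, c3)
      }
    }
  }
  tris <- do.call(rbind, tris)
  storage.mode(tris) <- "integer"
  verts <- unname(verts)
  areas <- triangle_areas(verts, tris)
  structure(
    list(coordinates = verts, triangles = tris,
         vertex_areas = vertex_areas_from_triangles(nrow(verts), tris, areas),
         exclusion_mask = rep(FALSE, nrow(verts)), radius = NA_real_),
    class = "surf_mesh")
}

triangle_areas <- function(verts, tris) {
  e1 <- verts[tris[, 2], , drop = FALSE] - verts[tris[, 1], , drop = FALSE]
  e2 <- verts[tris[, 3], , drop = FALSE] - verts[tris[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

vertex_areas_from_triangles <- function(V, tris, tri_areas) {
  va <- numeric(V)
  third <- tri_areas / 3
  for (k in 1:3) {
    acc <- tapply(third, tris[, k], sum)
    va[as.integer(names(acc))] <- va[as.integer(names(acc))] + acc
  }
  va
}

#' Undirected edge list of a mesh
#'
#' @param mesh A `surf_mesh`.
#' @return Two-column integer matrix of unique vertex pairs (i < j).
#' @export
mesh_edges <- function(mesh) {
  tris <- mesh$triangles
  e <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' @export
print.surf_mesh <- function(x, ...) {
  cat(sprintf("surf_mesh: %d vertices, %d triangles, %d excluded, total area %.4g\n",
              nrow(x$coordinates), nrow(x$triangles),
              sum(x$exclusion_mask), sum(x$vertex_areas)))
  invisible(x)
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
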