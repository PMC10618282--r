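#' Triangulated closed-surface mesh
#'
#' Builds a `triangle_mesh` from vertex coordinates and triangle indices and
#' computes per-facet geometry (unit normals, areas, centroids,
#' circumradii).  Facet orientation follows the winding of the index
#' triples: the normal is `(v2-v1) x (v3-v1)`, normalized.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in meters.
#' @param triangles integer matrix, f x 3, 1-based vertex indices.
#' @return An object of class `triangle_mesh` with components `vertices`,
#'   `triangles`, `normals`, `areas`, `centroids`, `circumradii`.
#' @export
triangle_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be an f x 3 matrix")
  nv <- nrow(vertices)
  if (any(triangles < 1L) || any(triangles > nv))
    stop("triangle indices out of range 1..", nv)
  if (any(triangles[, 1] == triangles[, 2] |
          triangles[, 2] == triangles[, 3] |
          triangles[, 3] == triangles[, 1]))
    stop("degenerate triangles (repeated vertex index)")
  v1 <- vertices[triangles[, 1], , drop = FALSE]
  v2 <- vertices[triangles[, 2], , drop = FALSE]
  v3 <- vertices[triangles[, 3], , drop = FALSE]
  e1 <- v2 - v1
  e2 <- v3 - v1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  twoA <- sqrt(rowSums(nrm^2))
  if (any(twoA <= 0)) {
    bad <- which(twoA <= 0)
    stop("zero-area facets at indices: ", paste(utils::head(bad, 20),
                                                collapse = ", "))
  }
  areas <- twoA / 2
  normals <- nrm / twoA
  centroids <- (v1 + v2 + v3) / 3
  a <- sqrt(rowSums((v2 - v1)^2))
  b <- sqrt(rowSums((v3 - v2)^2))
  cc <- sqrt(rowSums((v1 - v3)^2))
  circumradii <- a * b * cc / (4 * areas)
  structure(list(vertices = vertices, triangles = triangles,
                 normals = normals, areas = areas, centroids = centroids,
                 circumradii = circumradii),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d facets, total area %.6g m^2\n",
              nrow(x$vertices), nrow(x$triangles), sum(x$areas)))
  invisible(x)
}

# f x 9 facet-vertex matrix (v1 | v2 | v3), the layout the C++ kernels use
facet_matrix <- function(mesh) {
  cbind(mesh$vertices[mesh$triangles[, 1], , drop = FALSE],
        mesh$vertices[mesh$triangles[, 2], , drop = FALSE],
        mesh$vertices[mesh$triangles[, 3], , drop = FALSE])
}

undirected_edge_keys <- function(triangles) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Closed-manifold validation report
#'
#' Checks that every edge is shared by exactly two triangles (closedness),
#' that the two incident triangles traverse each shared edge in opposite
#' directions (consistent orientation), and reports the genus from the Euler
#' characteristic and the signed enclosed volume (positive when normals
#' point outward).  The function reports and never throws.
#'
#' @param mesh a [triangle_mesh()].
#' @return list with `is_closed`, `is_oriented`, `outward`, `genus`,
#'   `signed_volume`, `n_components`, `boundary_edges` (0 x 2 matrix when
#'   closed).
#' @export
validate_closed_manifold <- function(mesh) {
  tri <- mesh$triangles
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  ukey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(ukey)
  is_closed <- all(cnt == 2L)
  boundary <- e[ukey %in% names(cnt)[cnt == 1L], , drop = FALSE]
  # orientation: each undirected edge must appear once per direction
  dkey <- paste(e[, 1], e[, 2])
  is_oriented <- is_closed && !anyDuplicated(dkey)
  # connected components by union-find over vertices
  nv <- nrow(mesh$vertices)
  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(e))) {
    a <- find(e[k, 1]); b <- find(e[k, 2])
    if (a != b) parent[a] <- b
  }
  used <- unique(as.vector(tri))
  ncomp <- length(unique(vapply(used, find, integer(1))))
  V <- length(used)
  E <- length(cnt)
  F <- nrow(tri)
  chi <- V - E + F
  genus <- if (is_closed) as.integer(round((2 * ncomp - chi) / 2)) else NA_integer_
  v1 <- mesh$vertices[tri[, 1], , drop = FALSE]
  v2 <- mesh$vertices[tri[, 2], , drop = FALSE]
  v3 <- mesh$vertices[tri[, 3], , drop = FALSE]
  vol <- sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
             v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
             v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
  list(is_closed = is_closed, is_oriented = is_oriented,
       outward = is_oriented && vol > 0, genus = genus,
       signed_volume = vol, n_components = ncomp,
       boundary_edges = boundary)
}

#' Uniform 1:4 midpoint subdivision
#'
#' Splits every triangle at its edge midpoints into four coplanar children;
#' applied three times this yields the 1:64 uniform refinement used for
#' reference solutions.  Without reprojection the surface (shape, total
#' area, enclosed volume) is unchanged to rounding.  For synthetic sphere
#' models `project_radius` moves the new midpoint vertices back onto the
#' sphere of that radius.
#'
#' @param mesh a closed-manifold [triangle_mesh()].
#' @param project_radius optional sphere radius for vertex reprojection.
#' @return the refined `triangle_mesh` with 4x the facet count.
#' @export
subdivide_1to4 <- function(mesh, project_radius = NULL) {
  tri <- mesh$triangles
  nf <- nrow(tri)
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  first <- !duplicated(ekey)
  eid <- match(ekey, ekey[first])
  if (any(tabulate(eid) != 2L))
    stop("subdivide_1to4 requires a closed 2-manifold mesh")
  V <- mesh$vertices
  mids <- (V[e[first, 1], , drop = FALSE] + V[e[first, 2], , drop = FALSE]) / 2
  if (!is.null(project_radius)) {
    r <- sqrt(rowSums(mids^2))
    mids <- mids * (project_radius / r)
  }
  nv <- nrow(V)
  m12 <- nv + eid[seq_len(nf)]
  m23 <- nv + eid[nf + seq_len(nf)]
  m31 <- nv + eid[2 * nf + seq_len(nf)]
  newtri <- rbind(cbind(tri[, 1], m12, m31),
                  cbind(m12, tri[, 2], m23),
                  cbind(m31, m23, tri[, 3]),
                  cbind(m12, m23, m31))
  triangle_mesh(rbind(V, mids), newtri)
}

# icosahedron with vertices on the unit sphere, outward orientation
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  triangle_mesh(v, f)
}

#' Icosphere
#'
#' Icosahedron-based sphere triangulation with `20 * 4^level` facets; all
#' vertices lie exactly on the sphere of the given radius and normals point
#' outward.
#'
#' @param radius sphere radius in meters.
#' @param level number of 1:4 subdivisions applied to the icosahedron.
#' @return a `triangle_mesh`.
#' @export
icosphere <- function(radius = 1, level = 0L) {
  if (radius <= 0) stop("radius must be > 0")
  m <- icosahedron()
  for (i in seq_len(level)) m <- subdivide_1to4(m, project_radius = 1)
  triangle_mesh(m$vertices * radius, m$triangles)
}

#' Nested multilayer sphere surfaces
#'
#' Synthetic stand-in for MRI-derived head interfaces: one icosphere per
#' radius, all centered at the origin, outward-oriented.
#'
#' @param radii strictly decreasing positive radii in meters
#'   (outermost first).
#' @param subdiv_level subdivision level of every icosphere.
#' @return list of `triangle_mesh`, outermost first.
#' @export
make_nested_spheres <- function(radii, subdiv_level = 3L) {
  if (any(radii <= 0)) stop("radii must be > 0")
  if (length(radii) > 1 && any(diff(radii) >= 0))
    stop("radii must be strictly decreasing (outermost first)")
  if (subdiv_level < 0) stop("subdiv_level must be >= 0")
  lapply(radii, icosphere, level = subdiv_level)
}

#' Points on a sphere (icosphere vertices)
#'
#' Convenience observation set: the unique vertices of an icosphere, useful
#' as a "midsurface"-style evaluation locus in spherical models.
#'
#' @param radius sphere radius in meters.
#' @param level icosphere subdivision level (`10 * 4^level + 2` points).
#' @return n x 3 matrix of points.
#' @export
sphere_points <- function(radius = 1, level = 2L) {
  icosphere(radius, level)$vertices
}

# winding-number point-in-mesh test via summed signed solid angles
point_in_mesh <- function(mesh, points) {
  tri9 <- facet_matrix(mesh)
  apply(as.matrix(points), 1, function(p) {
    r1 <- sweep(tri9[, 1:3, drop = FALSE], 2, p)
    r2 <- sweep(tri9[, 4:6, drop = FALSE], 2, p)
    r3 <- sweep(tri9[, 7:9, drop = FALSE], 2, p)
    l1 <- sqrt(rowSums(r1^2)); l2 <- sqrt(rowSums(r2^2)); l3 <- sqrt(rowSums(r3^2))
    cr <- cbind(r1[, 2] * r2[, 3] - r1[, 3] * r2[, 2],
                r1[, 3] * r2[, 1] - r1[, 1] * r2[, 3],
                r1[, 1] * r2[, 2] - r1[, 2] * r2[, 1])
    num <- rowSums(cr * r3)
    den <- l1 * l2 * l3 + rowSums(r1 * r2) * l3 + rowSums(r1 * r3) * l2 +
      rowSums(r2 * r3) * l1
    abs(sum(2 * atan2(num, den))) > 2 * pi
  })
}
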