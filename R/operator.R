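supported_precisions <- c(1e-1, 1e-2, 1e-3, 1e-4, 1e-5, 1e-6)

check_precision <- function(precision) {
  k <- which(abs(log10(precision) - log10(supported_precisions)) < 1e-6)
  if (!length(k))
    stop("precision must be one of ", paste(supported_precisions,
                                            collapse = ", "))
  supported_precisions[k]
}

# near-pair radius multiplier eta as a function of the far-field precision:
# facets closer than eta*(rho_m + rho_n) get analytic panel integrals, the
# rest centroid point charges.  eta = 5 at the 1e-4 default; tighter
# precisions enlarge the analytic zone because the panel -> point-charge
# substitution, not the summation backend, limits the accuracy there.
near_eta <- function(precision) {
  eta <- c(`-1` = 2, `-2` = 3, `-3` = 4, `-4` = 5, `-5` = 14, `-6` = 40)
  eta[[as.character(round(log10(precision)))]]
}

# Barnes-Hut acceptance parameter for the treecode backend (octupole-order
# expansions, error ~ theta^4 with a small prefactor).  The 1/R potential
# kernel (coil sums) converges more slowly in theta than the gradient
# kernel, so it uses a one-notch-tighter table.
tree_theta <- function(precision, kernel = c("field", "potential")) {
  kernel <- match.arg(kernel)
  th <- if (kernel == "field")
    c(`-1` = 0.80, `-2` = 0.55, `-3` = 0.36, `-4` = 0.23, `-5` = 0.145,
      `-6` = 0.095)
  else
    c(`-1` = 0.55, `-2` = 0.36, `-3` = 0.23, `-4` = 0.145, `-5` = 0.095,
      `-6` = 0.06)
  th[[as.character(round(log10(precision)))]]
}

# symmetric barycentric quadrature rules on the unit triangle
tri_quadrature <- function(order) {
  if (order == 1) {
    list(bary = matrix(1 / 3, 1, 3), w = 1)
  } else if (order == 3) {
    list(bary = rbind(c(2 / 3, 1 / 6, 1 / 6),
                      c(1 / 6, 2 / 3, 1 / 6),
                      c(1 / 6, 1 / 6, 2 / 3)),
         w = rep(1 / 3, 3))
  } else if (order == 7) {
    a1 <- 0.0597158717897698
    b1 <- 0.4701420641051151
    a2 <- 0.7974269853530873
    b2 <- 0.1012865073234563
    list(bary = rbind(c(1 / 3, 1 / 3, 1 / 3),
                      c(a1, b1, b1), c(b1, a1, b1), c(b1, b1, a1),
                      c(a2, b2, b2), c(b2, a2, b2), c(b2, b2, a2)),
         w = c(0.225, rep(0.1323941527885062, 3),
               rep(0.1259391805448272, 3)))
  } else {
    stop("supported quadrature orders: 1 (centroid), 3, 7 (degree 5)")
  }
}

#' Analytic E-field of a uniformly charged triangle
#'
#' Closed-form field of a flat triangle carrying unit scaled surface charge
#' density (solid-angle plus edge-potential terms, including the `1/(4 pi)`
#' factor).  For points on the triangle's own plane the normal component is
#' the principal value: zero, with the in-plane components retained.  The
#' two one-sided limits at an interior facet point differ by exactly
#' `+/- n/2`.
#'
#' @param tri_vertices 3 x 3 matrix with rows v1, v2, v3 (meters).
#' @param points n x 3 matrix of evaluation points.
#' @return n x 3 matrix; multiply by a scaled charge density in V/m to get
#'   V/m.
#' @export
triangle_field_analytic <- function(tri_vertices, points) {
  tri_vertices <- as.matrix(tri_vertices)
  if (!all(dim(tri_vertices) == c(3, 3)))
    stop("tri_vertices must be a 3 x 3 matrix (rows v1, v2, v3)")
  e1 <- tri_vertices[2, ] - tri_vertices[1, ]
  e2 <- tri_vertices[3, ] - tri_vertices[1, ]
  cr <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  if (sqrt(sum(cr^2)) <= 0) stop("zero-area triangle")
  tri9 <- matrix(c(tri_vertices[1, ], tri_vertices[2, ], tri_vertices[3, ]),
                 1, 9)
  cpp_tri_field_points(tri9, 1.0, as.matrix(points))
}

#' Discretized boundary operator
#'
#' Matrix-free representation of the system matrix
#' `A_mn = 1/2 delta_mn - (K_m/A_m) n_m . integral over (t_m, t_n)` of the
#' Coulomb kernel: near facet pairs (centroid distance below
#' `eta * (rho_m + rho_n)`, `rho` the facet circumradius) are integrated
#' analytically; all other interactions use centroid point charges summed
#' by the chosen backend.  The near-field corrections are precomputed once
#' as a sparse matrix.
#'
#' @param head a `head_model`.
#' @param precision far-field relative accuracy, one of 1e-1 ... 1e-6.
#' @param backend `"exact"` (pairwise summation) or `"tree"` (Barnes-Hut).
#' @param quadrature_order outer (observation-facet) quadrature order:
#'   1 = centroid collocation (default), 3, or 7 (degree-5 rule).
#' @return object of class `bem_operator`.
#' @export
bem_operator <- function(head, precision = 1e-4,
                         backend = c("exact", "tree"),
                         quadrature_order = 1) {
  backend <- match.arg(backend)
  precision <- check_precision(precision)
  eta <- near_eta(precision)
  qr_ <- tri_quadrature(quadrature_order)
  pairs <- cpp_near_pairs(head$centroids, head$circumradii, eta)
  vals <- cpp_near_values(head$tri9, head$centroids, head$normals,
                          head$areas, head$K, pairs$i, pairs$j, qr_$bary,
                          qr_$w)
  N <- head$n_facets
  near <- Matrix::sparseMatrix(i = pairs$i, j = pairs$j, x = vals,
                               dims = c(N, N))
  structure(list(head = head, precision = precision, eta = eta,
                 backend = backend, quadrature_order = quadrature_order,
                 near = near, n_near_pairs = length(pairs$i)),
            class = "bem_operator")
}

#' @export
print.bem_operator <- function(x, ...) {
  cat(sprintf(
    "bem_operator: N = %d, backend = %s, precision = %g, eta = %g, %d near pairs (avg %.1f/facet)\n",
    x$head$n_facets, x$backend, x$precision, x$eta, x$n_near_pairs,
    x$n_near_pairs / x$head$n_facets))
  invisible(x)
}

#' Apply the boundary operator to a charge vector
#'
#' Computes `A %*% x` without forming `A`: far interactions as centroid
#' point charges `q_n = x_n A_n` summed exactly or by the treecode, plus
#' the precomputed sparse analytic near-field corrections.
#'
#' @param op a [bem_operator()].
#' @param x numeric vector of length N (scaled charge density, V/m).
#' @return numeric vector `A %*% x`.
#' @export
apply_operator <- function(op, x) {
  head <- op$head
  if (length(x) != head$n_facets) stop("x must have length ", head$n_facets)
  q <- x * head$areas
  Efar <- if (op$backend == "exact")
    cpp_point_charge_field(head$centroids, q, head$centroids, TRUE)
  else
    cpp_tree_field(head$centroids, q, head$centroids,
                   tree_theta(op$precision), TRUE)
  0.5 * x - head$K * rowSums(head$normals * Efar) +
    as.numeric(op$near %*% x)
}

#' Dense system matrix
#'
#' Explicit assembly of `A` with analytic inner (source-facet) integrals
#' and quadrature of the stated order over the observation facet.
#' Diagonal entries are exactly 1/2 (the principal-value field of a flat
#' facet has no normal component on its own plane).
#'
#' @param head a `head_model`.
#' @param quadrature_order observation-facet quadrature order (1, 3 or 7).
#' @param cap maximum N for dense storage.
#' @return N x N numeric matrix.
#' @export
assemble_dense <- function(head, quadrature_order = 1, cap = 20000) {
  N <- head$n_facets
  if (N > cap)
    stop("N = ", N, " exceeds the dense cap (", cap,
         "); use the matrix-free operator (bem_operator/apply_operator)")
  qr_ <- tri_quadrature(quadrature_order)
  cpp_assemble_dense(head$tri9, head$normals, head$K, qr_$bary, qr_$w)
}

#' Right-hand side from a coil
#'
#' `b_m = K_m n_m . <E_p>_{t_m}`, the facet-averaged primary coil field
#' (order 1 = centroid evaluation).
#'
#' @param head a `head_model`.
#' @param coil a [coil_model()].
#' @param quadrature_order facet-averaging quadrature order (1, 3 or 7).
#' @return numeric vector of length N, V/m.
#' @export
build_rhs <- function(head, coil, quadrature_order = 1) {
  qr_ <- tri_quadrature(quadrature_order)
  N <- head$n_facets
  acc <- matrix(0, N, 3)
  for (q in seq_along(qr_$w)) {
    pts <- qr_$bary[q, 1] * head$tri9[, 1:3, drop = FALSE] +
      qr_$bary[q, 2] * head$tri9[, 4:6, drop = FALSE] +
      qr_$bary[q, 3] * head$tri9[, 7:9, drop = FALSE]
    acc <- acc + qr_$w[q] * primary_efield(coil, pts)
  }
  head$K * rowSums(head$normals * acc)
}
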