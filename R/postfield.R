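#' Total E-field at observation points
#'
#' `E_total = E_primary + E_secondary` off the interfaces, the secondary
#' field being the Coulomb field of the solved facet charges: analytic
#' panel integrals for near facets, centroid point charges for far ones
#' (`backend = "hybrid"`, using the solving operator's precision when
#' available), or analytic integrals for every facet
#' (`backend = "exact"`, the default).  Points closer to a facet than
#' `guard` times its circumradius are rejected with an error naming the
#' facet: limiting interface values must be obtained with
#' [interface_fields()].
#'
#' @param sol a [charge_solution()].
#' @param points n x 3 matrix of observation points, meters.
#' @param backend `"exact"` or `"hybrid"`.
#' @param guard distance guard in units of the local facet circumradius.
#' @return object of class `field_samples` with `points`, `E_total`,
#'   `E_primary`, `E_secondary`.
#' @export
total_field <- function(sol, points, backend = c("exact", "hybrid"),
                        guard = 0.1) {
  backend <- match.arg(backend)
  points <- as.matrix(points)
  head <- sol$head
  eta <- if (!is.null(sol$operator)) sol$operator$eta else near_eta(1e-4)
  # free-space points lack the dominant identity term that absorbs far-field
  # noise in the operator rows, so the analytic zone is three times larger
  rho_pts <- rep(mean(head$circumradii), nrow(points))
  Es <- cpp_secondary_field(head$tri9, head$centroids, head$areas,
                            head$circumradii, sol$c, points, rho_pts,
                            3 * eta, backend == "exact", guard)
  Ep <- if (is.null(sol$coil)) matrix(0, nrow(points), 3) else
    primary_efield(sol$coil, points)
  structure(list(points = points, E_total = Ep + Es, E_primary = Ep,
                 E_secondary = Es),
            class = "field_samples")
}

#' @export
print.field_samples <- function(x, ...) {
  mag <- sqrt(rowSums(x$E_total^2))
  cat(sprintf("field_samples: %d points, |E| max %.4g, mean %.4g V/m\n",
              nrow(x$points), max(mag), mean(mag)))
  invisible(x)
}

#' Limiting interface fields (jump relation)
#'
#' At facet centroids the one-sided limits are the continuous part (primary
#' field plus principal-value Coulomb sum over all facets, the self facet
#' contributing only its in-plane principal value) plus the local planar
#' charge sheet: `E_in = E_cont - n c / 2`, `E_out = E_cont + n c / 2`, so
#' that `n . (E_out - E_in) = c` holds exactly by construction.
#'
#' @param sol a [charge_solution()].
#' @param facet_indices facets to evaluate (default: all).
#' @param quadrature_order facet-averaging order for the continuous part;
#'   defaults to the order the solving operator used, so the audit sees the
#'   same discretization the solver enforced.
#' @return list with `E_in`, `E_out`, `E_continuous` (n x 3 matrices) and
#'   `indices`.
#' @export
interface_fields <- function(sol, facet_indices = NULL,
                             quadrature_order = NULL) {
  head <- sol$head
  idx <- if (is.null(facet_indices)) seq_len(head$n_facets) else
    as.integer(facet_indices)
  if (any(idx < 1L | idx > head$n_facets)) stop("facet index out of range")
  eta <- if (!is.null(sol$operator)) sol$operator$eta else near_eta(1e-4)
  if (is.null(quadrature_order))
    quadrature_order <- if (!is.null(sol$operator))
      sol$operator$quadrature_order else 1
  qr_ <- tri_quadrature(quadrature_order)
  tri9 <- head$tri9[idx, , drop = FALSE]
  Es <- matrix(0, length(idx), 3)
  Ep <- matrix(0, length(idx), 3)
  for (q in seq_along(qr_$w)) {
    pts <- qr_$bary[q, 1] * tri9[, 1:3, drop = FALSE] +
      qr_$bary[q, 2] * tri9[, 4:6, drop = FALSE] +
      qr_$bary[q, 3] * tri9[, 7:9, drop = FALSE]
    Es <- Es + qr_$w[q] *
      cpp_secondary_field(head$tri9, head$centroids, head$areas,
                          head$circumradii, sol$c, pts,
                          head$circumradii[idx], eta, FALSE, 0)
    if (!is.null(sol$coil))
      Ep <- Ep + qr_$w[q] * primary_efield(sol$coil, pts)
  }
  Ec <- Ep + Es
  half <- head$normals[idx, , drop = FALSE] * (sol$c[idx] / 2)
  list(E_in = Ec - half, E_out = Ec + half, E_continuous = Ec,
       indices = idx)
}

#' Current-continuity residual
#'
#' Audits the quasistatic boundary condition
#' `sigma_in n.E_in = sigma_out n.E_out` facet by facet:
#' `residual_m = |sigma_in n.E_in - sigma_out n.E_out| /
#' ((sigma_in + sigma_out) * field_scale)` with `field_scale` the RMS
#' magnitude of the average interface field.  Reported, never thrown.
#'
#' @param sol a [charge_solution()].
#' @return list with per-facet `residual`, `max`, `rms`, `field_scale`.
#' @export
continuity_residual <- function(sol) {
  head <- sol$head
  f <- interface_fields(sol)
  n_in <- rowSums(head$normals * f$E_in)
  n_out <- rowSums(head$normals * f$E_out)
  Eavg <- (f$E_in + f$E_out) / 2
  scale <- sqrt(mean(rowSums(Eavg^2)))
  if (scale == 0) scale <- 1   # zero-field model: absolute residual
  res <- abs(head$sigma_in * n_in - head$sigma_out * n_out) /
    ((head$sigma_in + head$sigma_out) * scale)
  list(residual = res, max = max(res), rms = sqrt(mean(res^2)),
       field_scale = scale)
}

#' Vector and magnitude field errors
#'
#' Relative 2-norm differences between two fields over the same point set:
#' `error_total = ||E_ref - E_test|| / ||E_ref||` (stacked vector 2-norm)
#' and `error_mag = || |E_ref| - |E_test| || / || |E_ref| ||`.  An optional
#' trim fraction removes the largest local deviations before the norms
#' (per metric), and optional weights (e.g. facet areas) weight the
#' squared terms.
#'
#' @param E_ref,E_test n x 3 matrices.
#' @param trim fraction in [0, 1) of largest local errors to discard.
#' @param weights optional non-negative weights of length n.
#' @return named vector `c(error_total, error_mag)`.
#' @export
field_errors <- function(E_ref, E_test, trim = 0, weights = NULL) {
  E_ref <- as.matrix(E_ref)
  E_test <- as.matrix(E_test)
  if (!all(dim(E_ref) == dim(E_test))) stop("field dimensions differ")
  n <- nrow(E_ref)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (all(E_ref == 0)) stop("reference field is identically zero")
  keep_after_trim <- function(localerr) {
    k <- floor(trim * n)
    if (k == 0) rep(TRUE, n) else
      rank(-localerr, ties.method = "first") > k
  }
  d2 <- rowSums((E_ref - E_test)^2)
  keep <- keep_after_trim(sqrt(d2))
  et <- sqrt(sum(w[keep] * d2[keep]) /
               sum(w[keep] * rowSums(E_ref[keep, , drop = FALSE]^2)))
  mref <- sqrt(rowSums(E_ref^2))
  mtest <- sqrt(rowSums(E_test^2))
  dm <- (mref - mtest)^2
  keep <- keep_after_trim(sqrt(dm))
  em <- sqrt(sum(w[keep] * dm[keep]) / sum(w[keep] * mref[keep]^2))
  c(error_total = et, error_mag = em)
}

#' Select points in a spherical region of interest
#'
#' Closed ball: points at exactly `radius` from the target are included.
#'
#' @param points n x 3 matrix.
#' @param target ROI center, meters.
#' @param radius ROI radius, meters (the conventional reporting ROI is
#'   0.02 m).
#' @return integer indices of the selected points.
#' @export
roi_select <- function(points, target, radius = 0.02) {
  if (radius <= 0) stop("radius must be > 0")
  points <- as.matrix(points)
  d2 <- rowSums(sweep(points, 2, as.numeric(target))^2)
  which(d2 <= radius^2)
}

#' Export field samples as delimited text
#'
#' Writes `x y z Ex Ey Ez |E|` (tab-separated, header line).
#'
#' @param fs a `field_samples` object.
#' @param path output path.
#' @export
write_field_samples <- function(fs, path) {
  mag <- sqrt(rowSums(fs$E_total^2))
  tab <- cbind(fs$points, fs$E_total, mag)
  colnames(tab) <- c("x", "y", "z", "Ex", "Ey", "Ez", "Emag")
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Export field samples as legacy VTK polydata (for visualization)
#'
#' @param fs a `field_samples` object.
#' @param path output `.vtk` path.
#' @export
write_field_vtk <- function(fs, path) {
  n <- nrow(fs$points)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "tmsbem field samples",
               "ASCII", "DATASET POLYDATA", sprintf("POINTS %d double", n)),
             con)
  utils::write.table(fs$points, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("VERTICES %d %d", n, 2 * n), con)
  utils::write.table(cbind(1L, seq_len(n) - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(c(sprintf("POINT_DATA %d", n), "VECTORS E_total double"), con)
  utils::write.table(fs$E_total, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
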