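# Analytic total E-field inside a spherically symmetric conductor under
# external coil excitation.
#
# For any radial conductivity profile sigma(r) > 0 inside radius R and an
# external quasistatic source, the interior total field is
# E = E_p - grad(phi) with phi harmonic inside and dphi/dr = rhat.E_p on
# r = R (no current crosses the outer surface).  Because r.E_p is itself
# harmonic (E_p is divergence-free and curl of a harmonic vector
# potential), matching the radial derivative on the surface cancels the
# radial component at *every* interior radius: the induced field is purely
# tangential and independent of the conductivity profile.

#' Spherically symmetric conductor model
#'
#' Layer radii and conductivities are carried only to assert
#' profile-independence; the analytic interior field depends on the outer
#' radius alone.
#'
#' @param radii strictly decreasing layer radii, meters (outermost first).
#' @param sigmas conductivities of the enclosed media, S/m (all > 0).
#' @return object of class `sphere_model`.
#' @export
sphere_model <- function(radii, sigmas) {
  if (any(diff(radii) >= 0)) stop("radii must be strictly decreasing")
  if (any(sigmas <= 0)) stop("interior conductivities must be > 0")
  structure(list(outer_radius = radii[1], radii = radii, sigmas = sigmas),
            class = "sphere_model")
}

# fully normalized associated Legendre functions Ptilde_lm(x) (so that the
# real spherical harmonics sqrt(2-delta_m0) * Ptilde_lm * {cos,sin}(m phi)
# are orthonormal on the sphere) and their theta-derivatives.
# Returns n x ncoef matrices, column index lm_index(l, m).
legendre_normalized <- function(x, lmax, derivative = TRUE) {
  n <- length(x)
  u <- sqrt(pmax(1 - x^2, 0))          # sin(theta) >= 0
  ncoef <- (lmax + 1) * (lmax + 2) / 2
  P <- matrix(0, n, ncoef)
  idx <- function(l, m) l * (l + 1) / 2 + m + 1
  P[, idx(0, 0)] <- sqrt(1 / (4 * pi))
  if (lmax >= 1) {
    for (m in seq_len(lmax)) {
      P[, idx(m, m)] <- u * sqrt((2 * m + 1) / (2 * m)) *
        P[, idx(m - 1, m - 1)]
    }
    for (m in 0:(lmax - 1)) {
      P[, idx(m + 1, m)] <- x * sqrt(2 * m + 3) * P[, idx(m, m)]
    }
    for (m in 0:lmax) {
      if (m + 2 > lmax) next
      for (l in (m + 2):lmax) {
        a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
        b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
        P[, idx(l, m)] <- a * (x * P[, idx(l - 1, m)] -
                                 b * P[, idx(l - 2, m)])
      }
    }
  }
  if (!derivative) return(list(P = P, index = idx))
  dP <- matrix(0, n, ncoef)
  usafe <- pmax(u, 1e-300)
  for (l in seq_len(lmax)) {
    for (m in 0:l) {
      low <- if (l - 1 >= m) P[, idx(l - 1, m)] else 0
      dP[, idx(l, m)] <- (l * x * P[, idx(l, m)] -
                            sqrt((2 * l + 1) / (2 * l - 1)) *
                            sqrt(l^2 - m^2) * low) / usafe
    }
  }
  list(P = P, dP = dP, index = idx)
}

#' Analytic interior E-field of a spherically symmetric conductor
#'
#' Computes the total induced field at interior points for an arbitrary
#' external coil: the surface Neumann data `rhat . E_p` on the sphere is
#' expanded in real spherical harmonics (Gauss-Legendre x uniform azimuth
#' quadrature), the interior harmonic potential is reconstructed degree by
#' degree, and `E = E_p - grad(phi)` is evaluated with analytic angular
#' derivatives.  The radial component of the result vanishes identically
#' and the field is independent of the internal conductivity profile.
#'
#' @param coil a [coil_model()]; every element must lie strictly outside
#'   the sphere.
#' @param points interior observation points (n x 3, strictly inside
#'   radius `R`).
#' @param R outer sphere radius in meters, or a [sphere_model()].
#' @param lmax spherical-harmonic degree cap.
#' @param tail_tol maximum tolerated relative contribution of the last
#'   five degrees at the outermost observation radius; exceeding it raises
#'   an error suggesting a larger `lmax`.
#' @return n x 3 matrix of total E-field vectors, V/m.
#' @export
analytic_sphere_efield <- function(coil, points, R, lmax = 60,
                                   tail_tol = 1e-6) {
  if (inherits(R, "sphere_model")) R <- R$outer_radius
  points <- as.matrix(points)
  rcoil <- sqrt(rowSums(coil$positions^2))
  if (any(rcoil <= R))
    stop("all coil elements must lie strictly outside the sphere")
  rpts <- sqrt(rowSums(points^2))
  if (any(rpts >= R))
    stop("all observation points must lie strictly inside the sphere")

  # surface quadrature grid
  ntheta <- lmax + 1
  nphi <- 2 * lmax + 2
  gl <- pracma::gaussLegendre(ntheta, -1, 1)
  ct <- gl$x
  st <- sqrt(1 - ct^2)
  phis <- 2 * pi * (seq_len(nphi) - 1) / nphi
  grid <- cbind(rep(st, nphi) * cos(rep(phis, each = ntheta)),
                rep(st, nphi) * sin(rep(phis, each = ntheta)),
                rep(ct, nphi))
  Ep_surf <- primary_efield(coil, R * grid)
  g <- matrix(rowSums(Ep_surf * grid), ntheta, nphi)  # rhat . E_p on r = R

  # azimuthal Fourier components, then theta projections
  dphi <- 2 * pi / nphi
  cosm <- outer(phis, 0:lmax, function(p, m) cos(m * p))
  sinm <- outer(phis, 0:lmax, function(p, m) sin(m * p))
  Gc <- g %*% cosm * dphi         # ntheta x (lmax+1)
  Gs <- g %*% sinm * dphi
  leg <- legendre_normalized(ct, lmax, derivative = FALSE)
  idx <- leg$index
  wP <- leg$P * gl$w              # quadrature-weighted basis
  # coefficients of g in the orthonormal real spherical harmonics
  gc <- matrix(0, lmax + 1, lmax + 1)  # [l+1, m+1], cos family (m = 0 incl.)
  gs <- matrix(0, lmax + 1, lmax + 1)  # sin family (m >= 1)
  for (l in seq_len(lmax)) {
    for (m in 0:l) {
      pw <- wP[, idx(l, m)]
      fac <- if (m == 0) 1 else sqrt(2)
      gc[l + 1, m + 1] <- fac * sum(pw * Gc[, m + 1])
      if (m > 0) gs[l + 1, m + 1] <- fac * sum(pw * Gs[, m + 1])
    }
  }
  # interior potential coefficients: phi = sum a_lm (r/R)^l Y_lm with
  # dphi/dr|_R = g  =>  a_lm = R g_lm / l  (l = 0 absent: net flux is 0)
  total_sq <- sum(gc^2) + sum(gs^2)
  Ep_pts <- unname(primary_efield(coil, points))
  # purely tangential primary field (e.g. a coaxial loop): no induced charge
  if (total_sq <= 1e-24 * 4 * pi * mean(Ep_surf^2)) return(Ep_pts)

  # tail check at the outermost observation radius
  rmax <- max(rpts)
  lvec <- seq_len(lmax)
  el <- (rowSums(gc^2) + rowSums(gs^2))[-1]          # per-degree energy of g
  amp <- el * (rmax / R)^(2 * (lvec - 1))            # ~ |grad phi|^2 weight
  tail_frac <- sum(amp[lvec > lmax - 5]) / sum(amp)
  if (tail_frac > tail_tol)
    stop(sprintf(
      "spherical-harmonic tail fraction %.2e exceeds %.2e: increase lmax",
      tail_frac, tail_tol))

  # evaluate grad(phi) at the interior points
  np <- nrow(points)
  ctp <- ifelse(rpts > 0, points[, 3] / rpts, 1)
  ctp <- pmin(pmax(ctp, -1), 1)
  stp <- sqrt(1 - ctp^2)
  # the polar-coordinate singularity at the z-axis is removable (the field
  # is smooth there); nudge such points a hair off the pole instead of
  # dividing near-cancelling Legendre recurrences by sin(theta) ~ 0
  pole <- stp < 1e-7
  if (any(pole)) {
    stp[pole] <- 1e-7
    ctp[pole] <- sign(ctp[pole]) * sqrt(1 - 1e-14)
  }
  php <- atan2(points[, 2], points[, 1])
  legp <- legendre_normalized(ctp, lmax, derivative = TRUE)
  dr <- dth <- dph <- numeric(np)
  stp_safe <- pmax(stp, 1e-12)
  for (l in seq_len(lmax)) {
    radial <- rpts^(l - 1) / R^l        # (r/R)^l / r, finite at r = 0
    for (m in 0:l) {
      fac <- if (m == 0) 1 else sqrt(2)
      ac <- R * gc[l + 1, m + 1] / l
      as_ <- if (m > 0) R * gs[l + 1, m + 1] / l else 0
      if (ac == 0 && as_ == 0) next
      cm <- cos(m * php)
      sm <- sin(m * php)
      ang <- ac * cm + as_ * sm
      dang <- m * (-ac * sm + as_ * cm)
      Pl <- legp$P[, legp$index(l, m)]
      dPl <- legp$dP[, legp$index(l, m)]
      dr <- dr + l * radial * fac * Pl * ang
      dth <- dth + radial * fac * dPl * ang
      dph <- dph + radial * fac * Pl * dang / stp_safe
    }
  }
  rhat <- cbind(stp * cos(php), stp * sin(php), ctp)
  that <- cbind(ctp * cos(php), ctp * sin(php), -stp)
  phat <- cbind(-sin(php), cos(php), 0)
  grad_phi <- rhat * dr + that * dth + phat * dph
  unname(Ep_pts - grad_phi)
}
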