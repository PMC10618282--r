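# Shared fixtures and independent oracles, all built in code.

# smallest closed mesh: a tetrahedron
tetra_mesh <- function(scale = 0.01) {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) * scale
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  triangle_mesh(v, f)
}

cross3v <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# --- independent brute-force oracles (pure R, no package kernels) --------

subdiv_tri_list <- function(tris) {
  out <- vector("list", 4 * length(tris))
  for (i in seq_along(tris)) {
    t <- tris[[i]]
    a <- t[[1]]; b <- t[[2]]; cc <- t[[3]]
    ab <- (a + b) / 2; bc <- (b + cc) / 2; ca <- (cc + a) / 2
    out[[4 * i - 3]] <- list(a, ab, ca)
    out[[4 * i - 2]] <- list(ab, b, bc)
    out[[4 * i - 1]] <- list(ca, bc, cc)
    out[[4 * i]] <- list(ab, bc, ca)
  }
  out
}

tri_cents_areas <- function(tris) {
  n <- length(tris)
  C <- matrix(0, n, 3)
  A <- numeric(n)
  for (i in seq_len(n)) {
    t <- tris[[i]]
    C[i, ] <- (t[[1]] + t[[2]] + t[[3]]) / 3
    A[i] <- 0.5 * sqrt(sum(cross3v(t[[2]] - t[[1]], t[[3]] - t[[1]])^2))
  }
  list(C = C, A = A)
}

# centroid-rule field of a unit charge density on one triangle, level L
oracle_tri_field_level <- function(v1, v2, v3, p, L) {
  tris <- list(list(v1, v2, v3))
  for (i in seq_len(L)) tris <- subdiv_tri_list(tris)
  ca <- tri_cents_areas(tris)
  d <- sweep(-ca$C, 2, p, "+")
  r3 <- rowSums(d^2)^1.5
  colSums(ca$A * d / r3) / (4 * pi)
}

# Richardson-extrapolated (O(h^2) eliminated twice) field oracle
oracle_tri_field <- function(v1, v2, v3, p) {
  I3 <- oracle_tri_field_level(v1, v2, v3, p, 3)
  I4 <- oracle_tri_field_level(v1, v2, v3, p, 4)
  I5 <- oracle_tri_field_level(v1, v2, v3, p, 5)
  (16 * (4 * I5 - I4) / 3 - (4 * I4 - I3) / 3) / 15
}

# exact double integral of the kernel over a facet pair (unit density on
# t_n, integrated over t_m), Richardson-extrapolated centroid rule
oracle_pair_integral <- function(tm, tn, L) {
  Tm <- list(tm)
  Tn <- list(tn)
  for (i in seq_len(L)) {
    Tm <- subdiv_tri_list(Tm)
    Tn <- subdiv_tri_list(Tn)
  }
  m <- tri_cents_areas(Tm)
  n <- tri_cents_areas(Tn)
  E <- matrix(0, nrow(m$C), 3)
  for (j in seq_len(nrow(n$C))) {
    d <- sweep(m$C, 2, n$C[j, ], "-")
    r3 <- rowSums(d^2)^1.5
    E <- E + n$A[j] * d / r3
  }
  colSums(E * m$A) / (4 * pi)
}

oracle_pair_integral_rich <- function(tm, tn) {
  I3 <- oracle_pair_integral(tm, tn, 3)
  I4 <- oracle_pair_integral(tm, tn, 4)
  I5 <- oracle_pair_integral(tm, tn, 5)
  (16 * (4 * I5 - I4) / 3 - (4 * I4 - I3) / 3) / 15
}

# Biot-Savart magnetic field of the coil elements (independent of any
# package kernel); moments act as I dl with unit current
oracle_biot_savart <- function(positions, moments, p) {
  B <- c(0, 0, 0)
  for (j in seq_len(nrow(positions))) {
    d <- p - positions[j, ]
    B <- B + 1e-7 * cross3v(moments[j, ], d) / sum(d^2)^1.5
  }
  B
}

# --- shared expensive fixtures (computed lazily, once per run) -----------

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

std_radius <- 0.092

std_coil <- function() {
  place_coil(build_figure8_coil(),
             target = c(0.02, 0.01, sqrt(std_radius^2 - 0.02^2 - 0.01^2)),
             axis_dir = c(-0.2, -0.1, -1), handle_dir = c(1, 0, 0),
             standoff = 0.01)
}

homog_sphere_model <- function(level) {
  build_head_model(interface(icosphere(std_radius, level), 0.275, 0,
                             "sphere"))
}

# solved homogeneous sphere at subdivision `level`, degree-5 quadrature
solved_homog <- function(level, backend = "tree") {
  fixture(paste0("homog_L", level), function() {
    hm <- homog_sphere_model(level)
    op <- bem_operator(hm, backend = backend, quadrature_order = 7)
    b <- build_rhs(hm, std_coil(), quadrature_order = 7)
    solve_iterative(op, b, coil = std_coil())
  })
}

# same model solved at centroid collocation (quadrature order 1), where the
# continuity audit is exactly the collocated equation residual
solved_homog_q1 <- function(level) {
  fixture(paste0("homog_q1_L", level), function() {
    hm <- homog_sphere_model(level)
    op <- bem_operator(hm)
    b <- build_rhs(hm, std_coil())
    solve_iterative(op, b, coil = std_coil())
  })
}

mid_observation_points <- function() sphere_points(0.7 * std_radius, 2)
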