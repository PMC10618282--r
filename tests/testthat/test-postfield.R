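test_that("zero charge gives E_total = E_primary exactly", {
  hm <- build_head_model(interface(icosphere(std_radius, 2), 0.275, 0, "s"))
  sol <- charge_solution(rep(0, hm$n_facets), hm, std_coil())
  pts <- mid_observation_points()
  fs <- total_field(sol, pts)
  expect_true(all(fs$E_secondary == 0))
  expect_identical(fs$E_total, fs$E_primary)
  expect_equal(fs$E_primary, primary_efield(std_coil(), pts),
               tolerance = 1e-12)
})

test_that("a single charged facet looks like a point charge from afar", {
  m <- tetra_mesh(0.01)
  hm <- build_head_model(interface(m, 0.3, 0, "t"))
  x <- c(1, 0, 0, 0)  # one facet charged
  sol <- charge_solution(x, hm)
  p <- matrix(c(0.5, 0.4, 0.45), 1)
  fs <- total_field(sol, p)
  d <- as.numeric(p) - hm$centroids[1, ]
  Epc <- hm$areas[1] * d / sum(d^2)^1.5 / (4 * pi)
  expect_equal(as.numeric(fs$E_secondary), Epc, tolerance = 1e-3)
})

test_that("fast near/far secondary field matches all-analytic summation", {
  rep_ <- solved_homog(3)
  sol <- rep_$solution
  set.seed(17)
  u <- matrix(rnorm(300), ncol = 3)
  pts <- 0.8 * std_radius * u / sqrt(rowSums(u^2)) *
    runif(100, 0.3, 0.95)
  Eh <- total_field(sol, pts, backend = "hybrid")$E_secondary
  Ee <- total_field(sol, pts, backend = "exact")$E_secondary
  rel <- sqrt(sum((Eh - Ee)^2)) / sqrt(sum(Ee^2))
  expect_lte(rel, sol$operator$precision)
})

test_that("points violating the surface distance guard are rejected by name", {
  hm <- build_head_model(interface(icosphere(std_radius, 2), 0.275, 0, "s"))
  sol <- charge_solution(rep(1, hm$n_facets), hm)
  expect_error(total_field(sol, matrix(hm$centroids[5, ], 1)),
               "distance guard")
})

test_that("interface jump identity n.(E_out - E_in) = c holds exactly", {
  rep_ <- solved_homog(3)
  sol <- rep_$solution
  hm <- sol$head
  f <- interface_fields(sol)
  jump <- rowSums(hm$normals * (f$E_out - f$E_in))
  expect_equal(jump, sol$c, tolerance = 1e-15)
  # hand-made jump arithmetic: c = 2 with continuous normal component 1
  one <- build_head_model(interface(tetra_mesh(0.01), 0.3, 0, "t"))
  s1 <- charge_solution(rep(2, 4), one)
  f1 <- interface_fields(s1, 1)
  expect_equal(rowSums(one$normals[1, , drop = FALSE] *
                         (f1$E_out - f1$E_in)), 2, tolerance = 1e-14)
})

test_that("total field approaching a facet from outside tends to E_out", {
  rep_ <- solved_homog(3)
  sol <- rep_$solution
  hm <- sol$head
  i <- 7L
  # the centroid-collocation limit is what a point on the centroid-normal
  # ray converges to; the planar-sheet picture needs d << facet size
  f <- interface_fields(sol, i, quadrature_order = 1)
  n <- hm$normals[i, ]
  dists <- c(2, 0.8, 0.3) * hm$circumradii[i]
  errs <- vapply(dists, function(d) {
    p <- matrix(hm$centroids[i, ] + d * n, 1)
    Et <- total_field(sol, p, backend = "exact")$E_total
    sqrt(sum((Et - f$E_out)^2)) / sqrt(sum(f$E_out^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.2)
})

test_that("continuity residual reflects the solve quality", {
  rep_ <- solved_homog_q1(3)
  cr <- continuity_residual(rep_$solution)
  expect_lt(cr$rms, 1e-5)
  # unsolved charges violate the boundary condition
  hm <- rep_$solution$head
  bad <- charge_solution(rep(0, hm$n_facets), hm, std_coil(),
                         rep_$solution$operator)
  expect_gt(continuity_residual(bad)$rms, 1e-3)
  # zero-contrast model with zero charge satisfies it identically
  hm0 <- build_head_model(interface(icosphere(0.05, 1), 0.3, 0.3, "s"))
  s0 <- charge_solution(rep(0, hm0$n_facets), hm0, std_coil())
  expect_identical(continuity_residual(s0)$max, 0)
})

test_that("continuity residual improves ~ 100x from tol 1e-4 to 1e-8", {
  rep_ <- solved_homog_q1(3)
  op <- rep_$solution$operator
  b <- build_rhs(op$head, std_coil())
  s4 <- solve_iterative(op, b, tol = 1e-4, coil = std_coil())$solution
  s8 <- solve_iterative(op, b, tol = 1e-8, coil = std_coil())$solution
  r4 <- continuity_residual(s4)$rms
  r8 <- continuity_residual(s8)$rms
  expect_gt(r4 / r8, 1e2)
})

test_that("field error metrics satisfy their exact identities", {
  set.seed(23)
  E <- matrix(rnorm(90), ncol = 3)
  expect_equal(field_errors(E, E), c(error_total = 0, error_mag = 0))
  expect_equal(field_errors(E, 0 * E), c(error_total = 1, error_mag = 1))
  e <- field_errors(E, -E)
  expect_equal(unname(e[1]), 2, tolerance = 1e-15)
  expect_equal(unname(e[2]), 0, tolerance = 1e-15)
  expect_error(field_errors(0 * E, E), "zero")
  # trimming drops the largest local deviation
  E2 <- E
  E2[5, ] <- E2[5, ] + 100
  expect_lt(field_errors(E, E2, trim = 0.05)[1], field_errors(E, E2)[1])
  # area weights change the norm accordingly
  w <- runif(30, 0.5, 2)
  ew <- field_errors(E, E2, weights = w)
  expect_equal(unname(ew[1]),
               sqrt(sum(w * rowSums((E - E2)^2)) / sum(w * rowSums(E^2))))
})

test_that("ROI selection is a closed ball", {
  pts <- rbind(c(0, 0, 0), c(0.02, 0, 0), c(0.0201, 0, 0), c(0, 0.01, 0))
  idx <- roi_select(pts, c(0, 0, 0), 0.02)
  expect_identical(idx, c(1L, 2L, 4L))     # boundary point included
  expect_identical(roi_select(pts, c(5, 5, 5), 1e6), 1:4)
  expect_identical(roi_select(matrix(c(1, 2, 3), 1), c(1, 2, 3), 0.02), 1L)
  expect_error(roi_select(pts, c(0, 0, 0), -1), "radius")
})

test_that("field export formats write one row per observation point", {
  hm <- build_head_model(interface(icosphere(0.05, 1), 0.3, 0, "s"))
  sol <- charge_solution(rep(1, hm$n_facets), hm)
  pts <- sphere_points(0.02, 1)
  fs <- total_field(sol, pts)
  f1 <- tempfile(fileext = ".tsv")
  write_field_samples(fs, f1)
  tab <- utils::read.table(f1, header = TRUE)
  expect_identical(nrow(tab), nrow(pts))
  expect_equal(tab$Emag, sqrt(rowSums(fs$E_total^2)), tolerance = 1e-6)
  f2 <- tempfile(fileext = ".vtk")
  write_field_vtk(fs, f2)
  expect_true(any(grepl("POINTS 42 double", readLines(f2))))
  unlink(c(f1, f2))
})
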