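test_that("figure-8 wings are closed loops with the stated element count", {
  coil <- build_figure8_coil(radius = 0.035, turns = 1,
                             segments_per_turn = 64)
  expect_identical(nrow(coil$positions), 128L)
  # per-wing moment sum vanishes (closed polygonal loop)
  expect_lt(max(abs(colSums(coil$moments[1:64, ]))), 1e-12)
  expect_lt(max(abs(colSums(coil$moments[65:128, ]))), 1e-12)
  # doubling the segment count doubles elements; chord length sum -> 2 pi r
  c2 <- build_figure8_coil(radius = 0.035, segments_per_turn = 128)
  expect_identical(nrow(c2$positions), 256L)
  len64 <- sum(sqrt(rowSums(coil$moments[1:64, ]^2)))
  len128 <- sum(sqrt(rowSums(c2$moments[1:128, ]^2)))
  expect_lt(abs(len128 - 2 * pi * 0.035), abs(len64 - 2 * pi * 0.035))
  expect_equal(len128, 2 * pi * 0.035, tolerance = 1e-3)
})

test_that("opposite wing winding adds the B-field constructively between the wings", {
  # under the wing crossing the two adjacent current paths run parallel,
  # so the per-wing Biot-Savart fields align (the transverse component
  # doubles, the axial components cancel on the axis by symmetry);
  # same-sense winding would make them cancel instead
  coil <- build_figure8_coil(radius = 0.035, segments_per_turn = 64,
                             wing_separation = 0.07)
  left <- 1:64
  right <- 65:128
  center <- c(0, 0, 0.01)   # on the coil axis, off the winding plane
  Bl <- oracle_biot_savart(coil$positions[left, ], coil$moments[left, ],
                           center)
  Br <- oracle_biot_savart(coil$positions[right, ], coil$moments[right, ],
                           center)
  cosang <- sum(Bl * Br) / sqrt(sum(Bl^2) * sum(Br^2))
  expect_gt(cosang, 0.5)
  expect_gt(sqrt(sum((Bl + Br)^2)), max(sqrt(sum(Bl^2)), sqrt(sum(Br^2))))
  expect_identical(sign(Bl[1]), sign(Br[1]))     # transverse: constructive
  expect_lt(abs(Bl[3] + Br[3]),                  # axial: cancels on axis
            0.01 * sqrt(sum((Bl + Br)^2)))
  # control: same-sense wings interfere destructively at the center
  Br_same <- oracle_biot_savart(coil$positions[right, ],
                                -coil$moments[right, ], center)
  expect_lt(sum(Bl * Br_same) / sqrt(sum(Bl^2) * sum(Br_same^2)), 0)
})

test_that("coil placement is rigid and matches the stated conventions", {
  coil <- build_figure8_coil()
  ident <- place_coil(coil, c(0, 0, 0), c(0, 0, -1), c(1, 0, 0), 0)
  expect_equal(ident$positions, coil$positions, tolerance = 1e-12)
  expect_equal(ident$moments, coil$moments, tolerance = 1e-12)

  shifted <- place_coil(coil, c(0, 0, 0), c(0, 0, -1), c(1, 0, 0), 0.01)
  expect_equal(shifted$positions,
               sweep(coil$positions, 2, c(0, 0, 0.01), "+"),
               tolerance = 1e-12)

  set.seed(2)
  axis <- rnorm(3); handle <- rnorm(3)
  placed <- place_coil(coil, rnorm(3), axis, handle, 0.02)
  i <- c(1, 10, 50); j <- c(5, 77, 100)
  d0 <- sqrt(rowSums((coil$positions[i, ] - coil$positions[j, ])^2))
  d1 <- sqrt(rowSums((placed$positions[i, ] - placed$positions[j, ])^2))
  expect_equal(d1, d0, tolerance = 1e-12)
  # moments rotated, not scaled
  expect_equal(sqrt(rowSums(placed$moments^2)), sqrt(rowSums(coil$moments^2)),
               tolerance = 1e-12)
})

test_that("primary field matches the hand-evaluated single-element value", {
  # single element, moment (0,0,0.01) m at the origin, observation at
  # (0.1,0,0), dI/dt = 9.4e7 A/s:
  # E = -(1e-7)(9.4e7)(0.01/0.1) zhat = (0, 0, -0.94) V/m
  coil <- coil_model(matrix(0, 1, 3), matrix(c(0, 0, 0.01), 1), didt = 9.4e7)
  E <- primary_efield(coil, matrix(c(0.1, 0, 0), 1))
  expect_equal(as.numeric(E), c(0, 0, -0.94), tolerance = 1e-12)
})

test_that("primary field is linear in didt and additive over elements", {
  set.seed(4)
  pos <- matrix(rnorm(9, sd = 0.05), 3)
  mom <- matrix(rnorm(9, sd = 0.01), 3)
  pts <- matrix(rnorm(15, sd = 0.2), 5)
  c_all <- coil_model(pos, mom, didt = 9.4e7)
  E_all <- primary_efield(c_all, pts)
  E_sum <- Reduce(`+`, lapply(1:3, function(j)
    primary_efield(coil_model(pos[j, , drop = FALSE],
                              mom[j, , drop = FALSE], didt = 9.4e7), pts)))
  expect_equal(E_all, E_sum, tolerance = 1e-12)
  c0 <- coil_model(pos, mom, didt = 0)
  expect_true(all(primary_efield(c0, pts) == 0))
  c2 <- coil_model(pos, mom, didt = 2 * 9.4e7)
  expect_equal(primary_efield(c2, pts), 2 * E_all, tolerance = 1e-12)
})

test_that("primary field is divergence-free: flux through icospheres -> 0", {
  coil <- std_coil()
  flux <- vapply(2:4, function(lv) {
    m <- icosphere(0.05, lv)
    E <- primary_efield(coil, m$centroids)
    sum(rowSums(E * m$normals) * m$areas) /
      sum(abs(rowSums(E * m$normals)) * m$areas)
  }, numeric(1))
  expect_lt(abs(flux[3]), 1e-4)
  expect_lt(abs(flux[3]), abs(flux[1]))
})

test_that("treecode coil summation meets the requested precision", {
  coil <- place_coil(build_figure8_coil(segments_per_turn = 128, turns = 4),
                     c(0.01, 0.02, 0.089), c(-0.1, -0.2, -1), c(1, 0, 0),
                     0.008)
  pts <- sphere_points(0.085, 3)
  E_exact <- primary_efield(coil, pts, backend = "exact")
  for (p in c(1e-2, 1e-4, 1e-6)) {
    E_tree <- primary_efield(coil, pts, backend = "tree", precision = p)
    rel <- sqrt(sum((E_tree - E_exact)^2)) / sqrt(sum(E_exact^2))
    expect_lte(rel, p)
  }
})

test_that("coil CSV round trip preserves the model and supports didt override", {
  coil <- build_figure8_coil(didt = 9.4e7, name = "test8")
  f <- tempfile(fileext = ".csv")
  write_coil_csv(coil, f)
  c2 <- read_coil_csv(f)
  expect_equal(c2$positions, coil$positions, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(c2$moments, coil$moments, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(c2$didt, 9.4e7)
  expect_identical(c2$name, "test8")
  c3 <- read_coil_csv(f, didt = 1e8)
  expect_identical(c3$didt, 1e8)
  unlink(f)
})
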