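test_that("STL round trip preserves facet count and areas", {
  m <- tetra_mesh()
  for (ascii in c(FALSE, TRUE)) {
    f <- tempfile(fileext = ".stl")
    write_stl(m, f, ascii = ascii)
    m2 <- load_stl(f)
    expect_equal(nrow(m2$triangles), 4L)
    expect_equal(nrow(m2$vertices), 4L)
    expect_equal(sort(m2$areas), sort(m$areas),
                 tolerance = if (ascii) 1e-9 else 1e-6)
    rep_ <- validate_closed_manifold(m2)
    expect_true(rep_$is_closed)
    unlink(f)
  }
})

test_that("unit icosahedron STL reloads with the closed-form surface area", {
  ico <- icosphere(1, 0)
  f <- tempfile(fileext = ".stl")
  write_stl(ico, f, ascii = TRUE)
  m <- load_stl(f)
  expect_equal(nrow(m$triangles), 20L)
  # icosahedron with unit circumradius: edge a = 4/sqrt(10 + 2 sqrt(5)),
  # surface area 5 sqrt(3) a^2
  a <- 4 / sqrt(10 + 2 * sqrt(5))
  expect_equal(sum(m$areas), 5 * sqrt(3) * a^2, tolerance = 1e-6)
  unlink(f)
})

test_that("binary STL written by the package reloads bit-compatibly at float32", {
  m <- icosphere(0.1, 1)
  f <- tempfile(fileext = ".stl")
  write_stl(m, f)
  m2 <- load_stl(f)
  expect_equal(nrow(m2$triangles), nrow(m$triangles))
  expect_equal(m2$areas, m$areas, tolerance = 1e-6)
  unlink(f)
})

test_that("inward-wound STL is flipped on load with a warning", {
  m <- tetra_mesh()
  flipped <- triangle_mesh(m$vertices, m$triangles[, c(1, 3, 2)])
  f <- tempfile(fileext = ".stl")
  write_stl(flipped, f)
  expect_warning(m2 <- load_stl(f), "wound inward")
  expect_gt(validate_closed_manifold(m2)$signed_volume, 0)
  unlink(f)
})

test_that("manifold validation reports closedness, orientation and volume", {
  ico <- icosphere(0.1, 2)
  rep_ <- validate_closed_manifold(ico)
  expect_true(rep_$is_closed)
  expect_true(rep_$is_oriented)
  expect_true(rep_$outward)
  expect_identical(rep_$genus, 0L)
  expect_equal(rep_$signed_volume, 4 / 3 * pi * 0.1^3, tolerance = 0.05)

  open_mesh <- triangle_mesh(ico$vertices, ico$triangles[-1, , drop = FALSE])
  rep_o <- validate_closed_manifold(open_mesh)
  expect_false(rep_o$is_closed)
  expect_gt(nrow(rep_o$boundary_edges), 0)

  inward <- triangle_mesh(ico$vertices, ico$triangles[, c(1, 3, 2)])
  rep_i <- validate_closed_manifold(inward)
  expect_lt(rep_i$signed_volume, 0)
  expect_false(rep_i$outward)
})

test_that("1:4 subdivision multiplies facets by 4 and preserves geometry", {
  m <- tetra_mesh()
  s1 <- subdivide_1to4(m)
  expect_identical(nrow(s1$triangles), 4L * nrow(m$triangles))
  expect_equal(sum(s1$areas), sum(m$areas), tolerance = 1e-12)
  expect_equal(validate_closed_manifold(s1)$signed_volume,
               validate_closed_manifold(m)$signed_volume, tolerance = 1e-12)
  # three applications give the 1:64 refinement
  s3 <- subdivide_1to4(subdivide_1to4(s1))
  expect_identical(nrow(s3$triangles), 64L * nrow(m$triangles))
  # child areas of each parent sum to the parent area
  parent_area <- s1$areas
  child_sum <- rowSums(matrix(subdivide_1to4(s1)$areas, ncol = 4))
  expect_equal(child_sum, parent_area, tolerance = 1e-12)
})

test_that("subdivision rejects non-manifold input", {
  m <- tetra_mesh()
  open_mesh <- triangle_mesh(m$vertices, m$triangles[-1, , drop = FALSE])
  expect_error(subdivide_1to4(open_mesh), "manifold")
})

test_that("icosphere volume converges to the sphere monotonically from below", {
  vols <- vapply(0:3, function(l)
    validate_closed_manifold(icosphere(0.1, l))$signed_volume, numeric(1))
  exact <- 4 / 3 * pi * 0.1^3
  expect_true(all(diff(vols) > 0))
  expect_true(all(vols < exact))
  expect_equal(vols[4], exact, tolerance = 6e-3)
})

test_that("nested spheres have the stated facet counts, nesting and area", {
  ms <- make_nested_spheres(c(0.1), 4)
  expect_identical(nrow(ms[[1]]$triangles), 5120L)
  ms4 <- make_nested_spheres(c(0.092, 0.086, 0.080, 0.078), 3)
  expect_length(ms4, 4)
  expect_true(all(vapply(ms4, function(m) nrow(m$triangles), integer(1)) ==
                    1280L))
  # every inner vertex strictly inside the next-outer sphere surface
  for (k in 2:4) {
    r <- sqrt(rowSums(ms4[[k]]$vertices^2))
    expect_true(all(r < c(0.092, 0.086, 0.080)[k - 1]))
  }
  # level-5 sphere area within 0.1% of 4 pi R^2
  m5 <- icosphere(0.1, 5)
  expect_equal(sum(m5$areas), 4 * pi * 0.1^2, tolerance = 1e-3)
  expect_error(make_nested_spheres(c(0.08, 0.09), 1), "decreasing")
})

test_that("head-model contrasts follow (s_in - s_out)/(s_in + s_out)", {
  m <- icosphere(0.05, 1)
  h0 <- build_head_model(interface(m, 0.3, 0.3, "zero"))
  expect_true(all(h0$K == 0))
  h1 <- build_head_model(interface(m, 0.3, 0, "air"))
  expect_true(all(h1$K == 1))
  h2 <- build_head_model(interface(m, 0.3, 0.1, "half"))
  expect_true(all(abs(h2$K - 0.5) < 1e-15))
  expect_error(interface(m, 0, 0), "contrast undefined")
  # |K| <= 1 for any non-negative conductivities
  set.seed(5)
  for (i in 1:20) {
    s <- runif(2, 0, 10)
    h <- build_head_model(interface(m, s[1], s[2], "rand"))
    expect_lte(max(abs(h$K)), 1)
  }
})

test_that("head manifest (YAML + STL files) reproduces the in-memory model", {
  dir <- tempfile()
  dir.create(dir)
  ms <- make_nested_spheres(c(0.092, 0.086), 1)
  write_stl(ms[[1]], file.path(dir, "outer.stl"))
  write_stl(ms[[2]], file.path(dir, "inner.stl"))
  manifest <- file.path(dir, "model.yaml")
  yaml::write_yaml(list(interfaces = list(
    list(stl = "outer.stl", name = "scalp", sigma_in = 0.465, sigma_out = 0),
    list(stl = "inner.stl", name = "skull", sigma_in = 0.010,
         sigma_out = 0.465))), manifest)
  hm <- read_head_manifest(manifest)
  expect_identical(hm$n_facets, 160L)
  expect_equal(unique(hm$K), c(1, (0.010 - 0.465) / (0.010 + 0.465)),
               tolerance = 1e-12)
  expect_equal(sum(hm$areas),
               sum(ms[[1]]$areas) + sum(ms[[2]]$areas), tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})

test_that("millimeter STL files are rescaled by unit_scale", {
  m <- icosphere(90, 1)  # "millimeter" sphere
  f <- tempfile(fileext = ".stl")
  write_stl(m, f)
  m2 <- load_stl(f, unit_scale = 1e-3)
  expect_equal(max(sqrt(rowSums(m2$vertices^2))), 0.09, tolerance = 1e-6)
  unlink(f)
})
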