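test_that("mesh_volume matches closed forms for exact polyhedra", {
  expect_equal(mesh_volume(make_box_mesh(10, 10, 10)), 1)            # cm^3
  expect_equal(mesh_volume(tetra_mesh(10)) * 1000, 1000 / 6)         # mm^3
  expect_equal(mesh_volume(make_box_mesh(2, 30, 0.5)) * 1000, 30)
})

test_that("mesh_volume approximates the sphere within discretisation error", {
  e <- make_ellipsoid_mesh(10, 10, 10, subdivisions = 4)
  expect_lt(abs(mesh_volume(e$mesh) - 4 / 3 * pi) / (4 / 3 * pi), 0.005)
})

test_that("mesh_volume is invariant under rigid motion", {
  withr::local_seed(42)
  m <- make_ellipsoid_mesh(10, 5, 2, subdivisions = 2)$mesh
  v0 <- mesh_volume(m)
  for (k in 1:5) {
    m2 <- rigid_transform(m, random_rotation(), stats::rnorm(3, sd = 100))
    expect_lt(abs(mesh_volume(m2) - v0) / v0, 1e-9)
  }
})

test_that("mesh_volume is additive over disjoint closed components", {
  a <- make_box_mesh(10, 10, 10)
  b <- make_box_mesh(5, 5, 5, origin = c(100, 0, 0))
  expect_equal(mesh_volume(merge_meshes(a, b)),
               mesh_volume(a) + mesh_volume(b))
})

test_that("reversing all face windings leaves |volume| unchanged", {
  m <- make_box_mesh(10, 10, 10)
  m$faces <- m$faces[, c(1, 3, 2)]
  expect_equal(mesh_volume(m), 1)
})

test_that("inconsistent orientation is repaired by propagation", {
  m <- make_ellipsoid_mesh(10, 10, 10, subdivisions = 2)$mesh
  v0 <- mesh_volume(m)
  flip <- seq(1, nrow(m$faces), by = 3)
  m$faces[flip, ] <- m$faces[flip, c(1, 3, 2)]
  expect_equal(mesh_volume(m), v0)
})

test_that("open meshes error in strict mode, naming the boundary edges", {
  m <- make_box_mesh(10, 10, 10)
  m$faces <- m$faces[-1, ]  # puncture one triangle: 3 boundary edges
  expect_error(mesh_volume(m), "3 boundary edge")
  expect_warning(v <- mesh_volume(m, strict = FALSE), "approximate")
  expect_true(attr(v, "flagged"))
  expect_gt(as.numeric(v), 0)
})

test_that("linear_distance is a metric on finite points", {
  expect_equal(linear_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(linear_distance(c(1, 2, 3), c(4, 6, 3)), 5)
  expect_equal(linear_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(linear_distance(c(0, 0, 0), c(3, 4, 0)),
               linear_distance(c(3, 4, 0), c(0, 0, 0)))
  expect_error(linear_distance(c(0, 0), c(1, 1, 1)), "length-3")
  expect_error(linear_distance(c(0, 0, Inf), c(1, 1, 1)), "finite")
})

test_that("polyline_length sums segments and bounds the chord", {
  expect_equal(polyline_length(rbind(c(0, 0, 0), c(10, 0, 0))), 10)
  expect_equal(polyline_length(rbind(c(0, 0, 0), c(3, 4, 0), c(3, 4, 12))), 17)
  qc <- quarter_circle(10, 100)
  expect_lt(abs(polyline_length(qc) - 5 * pi) / (5 * pi), 0.001)
  # chord bound
  expect_gte(polyline_length(qc), linear_distance(qc[1, ], qc[100, ]))
  expect_error(polyline_length(rbind(c(0, 0, 0))), "k >= 2")
})

test_that("polyline_length is monotone under point insertion", {
  withr::local_seed(7)
  base <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0))
  l0 <- polyline_length(base)
  for (k in 1:10) {
    extra <- matrix(stats::runif(3, -5, 15), 1)
    at <- sample(2:nrow(base), 1)
    augmented <- rbind(base[seq_len(at - 1), ], extra,
                       base[at:nrow(base), ])
    expect_gte(polyline_length(augmented), l0)
  }
})

test_that("triangle_mesh validates its invariants", {
  expect_error(triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                             rbind(c(1, 1, 2))), "Degenerate")
  expect_error(triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0)),
                             rbind(c(1, 2, 3))), "non-existent")
  expect_error(triangle_mesh(rbind(c(0, 0, NA), c(1, 0, 0), c(0, 1, 0)),
                             rbind(c(1, 2, 3))), "finite")
})
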