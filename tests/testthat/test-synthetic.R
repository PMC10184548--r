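test_that("ellipsoid meshes carry the analytic volume and converge to it", {
  e <- make_ellipsoid_mesh(10, 5, 2, subdivisions = 3)
  expect_equal(e$true_volume_cm3, 4 / 3 * pi * 100 / 1000)
  expect_true(mesh_is_closed(e$mesh))
  # inscribed polyhedron: strictly below the smooth volume at every level
  vols <- vapply(1:4, function(s) {
    mesh_volume(make_ellipsoid_mesh(10, 10, 10, s)$mesh)
  }, numeric(1))
  expect_true(all(vols < 4 / 3 * pi))
  expect_true(all(diff(vols) > 0))  # monotone convergence from below
  expect_lt(abs(vols[4] - 4 / 3 * pi) / (4 / 3 * pi), 0.005)
  expect_error(make_ellipsoid_mesh(-1, 1, 1), "> 0")
  expect_error(make_ellipsoid_mesh(1, 1, 1, subdivisions = 0), ">= 1")
})

test_that("tube meshes are watertight with near-cylindrical volume", {
  straight <- make_tube_mesh(rbind(c(0, 0, 0), c(20, 0, 0)), radius = 1)
  expect_true(mesh_is_closed(straight$mesh))
  expect_equal(straight$true_length_mm, 20)
  vol_mm3 <- mesh_volume(straight$mesh) * 1000
  expect_lt(abs(vol_mm3 - pi * 20) / (pi * 20), 0.01)
  # exact prism volume for the inscribed 32-gon cross-section
  expect_equal(vol_mm3, 0.5 * 32 * sin(2 * pi / 32) * 20, tolerance = 1e-9)

  bent <- make_tube_mesh(quarter_circle(10, 100), radius = 0.5)
  expect_true(mesh_is_closed(bent$mesh))
  expect_lt(abs(bent$true_length_mm - 5 * pi) / (5 * pi), 0.001)
  expect_false(bent$self_intersecting)

  expect_error(make_tube_mesh(rbind(c(1, 1, 1), c(1, 1, 1)), 1), "Degenerate")
  expect_warning(
    make_tube_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0)), radius = 8),
    "self-intersect")
})

test_that("cohorts are reproducible under a fixed seed", {
  a <- make_specimen_cohort(50, seed = 1)
  b <- make_specimen_cohort(50, seed = 1)
  expect_identical(a, b)
  c2 <- make_specimen_cohort(50, seed = 2)
  expect_false(identical(a$ecd_mm, c2$ecd_mm))
  expect_error(make_specimen_cohort(0, 1), ">= 1")
  expect_error(make_specimen_cohort(5, 1, ranges = list(ecd_mm = c(5, -2))),
               "positive ordered")
  expect_error(make_specimen_cohort(5, 1, ranges = list(bogus = c(1, 2))),
               "Unknown range")
})

test_that("pipeline outputs equal cohort ground truths to 1e-9 relative", {
  cohort <- make_specimen_cohort(120, seed = 11)
  rel <- function(a, b) max(abs(a - b) / abs(b))
  est <- hearing_estimate(cohort$ecd_mm, cohort$bcl_mm)
  expect_lt(rel(est$best_range_hz, cohort$true_best_hz), 1e-9)
  expect_lt(rel(est$mean_freq_hz, cohort$true_mean_hz), 1e-9)
  mass <- body_mass_bipedal(cohort$femoral_circumference_mm)$mass_g
  expect_lt(rel(mass, cohort$true_body_mass_g), 1e-9)
  expect_lt(rel(req(brain_mass_from_endocast(cohort$endocast_volume_cm3,
                                             0.37), mass),
                cohort$true_req_37), 1e-9)
  expect_lt(rel(req(brain_mass_from_endocast(cohort$endocast_volume_cm3,
                                             0.50), mass),
                cohort$true_req_50), 1e-9)
  expect_lt(rel(olfactory_ratio(cohort$bulb_length_mm,
                                cohort$cerebrum_diameter_mm),
                cohort$true_olfactory_pct), 1e-9)
  expect_lt(rel(midbrain_medulla_ratio(cohort$midbrain_length_mm,
                                       cohort$medulla_length_mm),
                cohort$true_midbrain_ratio), 1e-9)
})

test_that("default cohort ranges keep best frequencies in the observed band", {
  cohort <- make_specimen_cohort(200, seed = 3)
  expect_true(all(cohort$ecd_mm >= 6 & cohort$ecd_mm <= 20))
  expect_true(all(cohort$bcl_mm >= 15 & cohort$bcl_mm <= 110))
  expect_true(all(cohort$true_best_hz >= 2000 & cohort$true_best_hz <= 4800))
})

test_that("REQ recovered from a synthetic endocast mesh matches the truth", {
  e <- make_ellipsoid_mesh(80, 30, 25, subdivisions = 4, name = "endocast")
  mass <- 2011000
  req_mesh <- req(brain_mass_from_endocast(mesh_volume(e$mesh), 0.5), mass)
  req_true <- req(brain_mass_from_endocast(e$true_volume_cm3, 0.5), mass)
  expect_lt(abs(req_mesh - req_true) / req_true, 0.005)
})
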