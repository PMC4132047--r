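# analytic two-sphere oracle: accessible area of two expanded spheres at
# center distance d (spherical-cap closed form)
two_sphere_area <- function(r1, r2, d, probe) {
  R1 <- r1 + probe
  R2 <- r2 + probe
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  cap <- function(Ra, Rb) {
    cosb <- (d^2 + Ra^2 - Rb^2) / (2 * d * Ra)
    2 * pi * Ra^2 * (1 + cosb)
  }
  cap(R1, R2) + cap(R2, R1)
}

sphere_tbl <- function(...) {
  m <- rbind(...)
  tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3], vdw_radius = m[, 4])
}

test_that("a single sphere reproduces its analytic area", {
  sh <- shrake_rupley(sphere_tbl(c(0, 0, 0, 0.17)), probe = 0.14,
                      n_points = 960)
  expect_equal(sh$total_area, 4 * pi * 0.31^2, tolerance = 0.01)
})

test_that("non-interacting and overlapping sphere pairs match closed forms", {
  far <- shrake_rupley(sphere_tbl(c(0, 0, 0, 0.17), c(2, 0, 0, 0.17)),
                       probe = 0.14, n_points = 960)
  expect_equal(far$total_area, 2 * 4 * pi * 0.31^2, tolerance = 1e-6)

  for (d in c(0.20, 0.35, 0.55)) {
    got <- shrake_rupley(sphere_tbl(c(0, 0, 0, 0.17), c(d, 0, 0, 0.15)),
                         probe = 0.14, n_points = 960)$total_area
    expect_equal(got, two_sphere_area(0.17, 0.15, d, 0.14), tolerance = 0.01)
  }
})

test_that("coincident duplicate atoms are handled without crashing", {
  dup <- shrake_rupley(sphere_tbl(c(0, 0, 0, 0.17), c(0, 0, 0, 0.17)),
                       probe = 0.14, n_points = 240)
  expect_true(all(is.finite(dup$per_atom$area)))
  expect_lte(dup$total_area, 4 * pi * 0.31^2 + 1e-9)
})

test_that("contact area follows the inclusion-exclusion definition", {
  comp <- small_composite()
  am <- structure_phase(comp, "amorphous")
  cr <- structure_phase(comp, "crystalline")
  ct <- contact_area(am, cr, n_points = 480)
  expect_gt(ct$area_contact, 0)
  expect_gt(ct$n_contact, 0)
  # direct recomputation from three independent SASA calls
  s1 <- shrake_rupley(am, 0.14, 480)$total_area
  s2 <- shrake_rupley(cr, 0.14, 480)$total_area
  s12 <- shrake_rupley(dplyr::bind_rows(am, cr), 0.14, 480)$total_area
  expect_equal(ct$area_contact, (s1 + s2 - s12) / 2, tolerance = 1e-12)
})

test_that("contact area is symmetric and vanishes for disjoint bodies", {
  comp <- small_composite()
  am <- structure_phase(comp, "amorphous")
  cr <- structure_phase(comp, "crystalline")
  ab <- contact_area(am, cr, n_points = 240)
  ba <- contact_area(cr, am, n_points = 240)
  expect_identical(ab$area_contact, ba$area_contact)
  expect_identical(ab$n_contact, ba$n_contact)

  far <- am
  far$z <- far$z + 50
  off <- contact_area(far, cr, n_points = 240)
  expect_equal(off$area_contact, 0)
  expect_equal(off$n_contact, 0L)

  empty <- contact_area(am[0, ], cr, n_points = 240)
  expect_equal(empty$area_contact, 0)
  expect_equal(empty$n_contact, 0L)
})

test_that("a body against its own copy is completely buried", {
  cr <- structure_phase(small_composite(), "crystalline")
  s <- shrake_rupley(cr, 0.14, 240)$total_area
  self <- contact_area(cr, cr, n_points = 240)
  expect_equal(self$area_contact, s, tolerance = 1e-9)
})

test_that("pulling a bundle away never increases the contact area", {
  spec <- small_spec()
  cr <- build_crystal_unit(spec)
  z0 <- max(cr$z) + 0.35 + 0.8 # just outside the +z face
  areas <- vapply(c(0, 0.3, 0.8, 2, 6), function(dz) {
    b <- build_amorphous_bundle(spec, anchor = c(mean(range(cr$x)), 0,
                                                 z0 + dz))
    contact_area(b, cr, n_points = 240)$area_contact
  }, numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
})

test_that("the sphere sampling is converged at the default point count", {
  comp <- small_composite()
  a960 <- shrake_rupley(comp, 0.14, 960)$total_area
  a4000 <- shrake_rupley(comp, 0.14, 4000)$total_area
  expect_equal(a960, a4000, tolerance = 0.005)
})
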