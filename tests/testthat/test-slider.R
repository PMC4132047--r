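test_that("radial return reproduces the 1D bilinear closed form", {
  card <- elastoplastic_card(youngs = 20, poisson = 0.3, yield = 2,
                             tangent = 2, hardening_mix = 0)
  E <- 20e9; Et <- 2e9; sy <- 2e9

  # elastic branch: exactly linear
  st <- uni_step(NULL, 0.005, card)
  expect_equal(st$stress[1], E * 0.005, tolerance = 1e-10)
  expect_equal(st$ep, 0)

  # monotone pull past yield: bilinear with tangent modulus Et
  state <- NULL; eps <- 0
  for (i in 1:60) { state <- uni_step(state, 0.005, card); eps <- eps + 0.005 }
  expect_equal(state$stress[1], sy + Et * (eps - sy / E), tolerance = 1e-4)
})

test_that("kinematic hardening shows the Bauschinger effect", {
  card <- elastoplastic_card(youngs = 20, poisson = 0.3, yield = 2,
                             tangent = 2, hardening_mix = 1)
  sy <- 2e9
  state <- NULL
  for (i in 1:40) state <- uni_step(state, 0.005, card)
  sig_fwd <- state$stress[1]
  prev <- state
  rev_yield <- NA
  for (i in 1:600) {
    nxt <- uni_step(prev, -0.0004, card)
    if (nxt$ep > prev$ep + 1e-12) { rev_yield <- nxt$stress[1]; break }
    prev <- nxt
  }
  # reverse yield at (forward stress - 2 sigma_y): shift = twice the
  # backstress magnitude
  expect_equal(rev_yield, sig_fwd - 2 * sy, tolerance = 2e-3)
})

test_that("the viscoelastic update matches the relaxation kernel", {
  vc <- viscoelastic_card(bulk = 4, G0 = 1, Ginf = 0.2, beta = 1e8)
  g0 <- 0.01

  # instantaneous step: G0 * gamma; long-time: Ginf * gamma
  st <- viscoelastic_update(c(0, 0, 0, g0), NULL, vc, dt = 1e-13)
  expect_equal(st$stress[4], 1e9 * g0, tolerance = 1e-4)
  nst <- 4000; dt <- 3e-8 / nst
  for (i in seq_len(nst)) st <- viscoelastic_update(c(0, 0, 0, 0), st, vc, dt)
  Gt <- 0.2e9 + 0.8e9 * exp(-1e8 * 3e-8)
  expect_equal(st$stress[4], Gt * g0, tolerance = 1e-4)
  st2 <- st
  for (i in 1:2000) st2 <- viscoelastic_update(c(0, 0, 0, 0), st2, vc, 1e-7)
  expect_equal(st2$stress[4], 0.2e9 * g0, tolerance = 1e-4)

  # G0 = Ginf: pure elasticity, no dissipation
  ve <- viscoelastic_card(bulk = 4, G0 = 0.5, Ginf = 0.5, beta = 1e8)
  se <- viscoelastic_update(c(0.001, 0, 0, 0.002), NULL, ve, 1e-9)
  expect_equal(se$stress[4], 0.5e9 * 0.002, tolerance = 1e-12)
  expect_equal(se$dissipation, 0)
})

test_that("constant shear rate approaches the analytic steady ramp", {
  vc <- viscoelastic_card(bulk = 4, G0 = 1, Ginf = 0.2, beta = 1e8)
  rate <- 1e6
  dt <- 1e-11
  st <- NULL; tt <- 0
  for (i in 1:20000) {
    st <- viscoelastic_update(c(0, 0, 0, rate * dt), st, vc, dt)
    tt <- tt + dt
  }
  pred <- 0.2e9 * rate * tt + 0.8e9 * rate / 1e8
  expect_equal(st$stress[4], pred, tolerance = 1e-4)
  # fine-dt reference
  st2 <- NULL
  for (i in 1:80000) st2 <- viscoelastic_update(c(0, 0, 0, rate * dt / 4),
                                                st2, vc, dt / 4)
  expect_equal(st$stress[4], st2$stress[4], tolerance = 1e-5)
})

test_that("film traction is Newtonian and opposes the motion", {
  fc <- film_card(eta = 200, h = 1)
  expect_equal(film_traction(1, fc), -2e11)
  expect_identical(film_traction(0, fc), 0)
  for (dv in c(-3, -0.1, 0.2, 5)) {
    expect_equal(sign(film_traction(dv, fc)), -sign(dv))
  }
  expect_error(film_card(eta = -1), "> 0")
})

test_that("a quiescent slider develops no stress", {
  r0 <- run_slider_case(slider_case(0, duration = 2e-9))
  expect_equal(r0$steady$tau_interface, 0)
  expect_equal(r0$steady$vm_crystal, 0)
  expect_equal(r0$steady$vm_amorphous, 0)
})

test_that("the rigid-slider limit reproduces the Couette closed form", {
  rigid <- elastoplastic_card(youngs = 2e7, yield = 2e6, tangent = 2e6)
  rigid_ve <- viscoelastic_card(bulk = 4e6, G0 = 1e6, Ginf = 2e5)
  film <- film_card(eta = 200, h = 100)
  res <- run_slider_case(slider_case(1), crystal = rigid,
                         amorphous = rigid_ve, film = film)
  expect_equal(abs(res$steady$tau_interface), 200 * 1 / 100e-9,
               tolerance = 0.01)
  expect_lt(res$energy_error, 0.01)
  # 2x mesh refinement moves the answer by < 2%
  res2 <- run_slider_case(slider_case(1, el = 25), crystal = rigid,
                          amorphous = rigid_ve, film = film)
  expect_equal(res2$steady$tau_interface, res$steady$tau_interface,
               tolerance = 0.02)
})

test_that("the energy ledger closes on a deforming run", {
  res <- run_slider_case(slider_case(1))
  expect_lt(res$energy_error, 0.01)
  h <- res$history
  expect_true(all(diff(h$D_film) >= 0)) # film dissipation is monotone
  expect_true(all(h$vm_crystal >= 0 & is.finite(h$vm_crystal)))
})

test_that("stability and penetration guards raise errors", {
  expect_error(run_slider_case(slider_case(1), dt = 1e-9),
               "stability bound")
  expect_error(
    run_slider_case(slider_case(20, load_angle = 60, slide_distance = 8000),
                    kpen = 1e10),
    "penetration")
})
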