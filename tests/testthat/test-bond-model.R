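test_that("the force-velocity law obeys its structural limits", {
  p0 <- bond_params(U_bond = 0)
  V <- c(0.01, 0.5, 5)
  expect_equal(force_velocity(V, p0), p0$xi0 * V * 1e12, tolerance = 1e-9)
  expect_identical(force_velocity(0, bond_params()), 0)

  p <- bond_params()
  expect_equal(force_velocity(-V, p), -force_velocity(V, p), tolerance = 1e-9)

  # strictly increasing over the working range
  grid <- 10^seq(-5, log10(20), length.out = 40)
  expect_true(all(diff(force_velocity(grid, p)) > 0))
})

test_that("closed form and Fokker-Planck quadrature oracle agree", {
  V <- 10^seq(-4, log10(20), length.out = 7)
  for (ub in c(0, 8.4)) {
    p <- bond_params(U_bond = ub)
    expect_equal(force_velocity(V, p), fp_oracle(V, p), tolerance = 0.005)
  }
})

test_that("the low-velocity limit shows the Zwanzig corrugation factor", {
  p <- bond_params(U_bond = 4, m = 2) # well depth 8 kT -> u = 4
  xi_eff <- fp_oracle(1e-6, p) * 1e-12 / 1e-6
  expect_equal(xi_eff, p$xi0 * besselI(4, 0)^2, tolerance = 1e-3)

  expect_equal(viscous_limit(bond_params(U_bond = 0)), 1e-12)
  xs <- vapply(c(2, 4, 8.4, 12), function(u) {
    viscous_limit(bond_params(U_bond = u))
  }, numeric(1))
  expect_true(all(diff(xs) > 0))
  # limit consistency with the oracle
  p2 <- bond_params()
  expect_equal(fp_oracle(1e-6, p2) * 1e-12 / 1e-6, viscous_limit(p2),
               tolerance = 1e-3)
})

test_that("Brownian-dynamics runs reproduce the mobility law", {
  pts <- list(bond_params(U_bond = 2), bond_params(U_bond = 4, ma = 0.8),
              bond_params(U_bond = 6, ma = 2))
  for (p in pts) {
    # pick a force in the corrugated regime and compare mean velocities
    Vref <- 0.1
    Fg <- force_velocity(Vref, p) * p$m # group force, pN
    bd <- washboard_bd(Fg, p, n_steps = 4e5, n_burn = 4e4, seed = 11)
    expect_lt(abs(bd$velocity - Vref), 3 * bd$se + 0.02 * Vref)
  }
})

test_that("preset viscous limits reproduce the interface/amorphous contrast", {
  r <- viscous_limit(bond_preset("amorphous")) /
    viscous_limit(bond_preset("interface"))
  expect_gt(r, 30)
  expect_lt(r, 80)
})

test_that("parameter validation rejects unphysical inputs", {
  expect_error(bond_params(ma = -1), "ma > 0")
  expect_error(bond_params(m = 0.5), "m >= 1")
  expect_error(bond_params(xi0 = 0), "xi0 > 0")
  expect_error(bond_params(U_bond = NA), "finite")
  expect_error(force_velocity(Inf, bond_params()), "finite")
})

test_that("noiseless synthetic data are fitted back exactly in every mode", {
  p <- bond_params()
  V <- c(0.02, 0.05, 0.2, 0.5, 2, 5, 20)
  ds <- tibble::tibble(velocity = V, f_res = force_velocity(V, p),
                       f_res_sem = 0)
  f1 <- fit_bond_model(ds, "fix_Ubond")
  expect_equal(f1$params$ma, 1.32, tolerance = 1e-3)
  expect_lt(f1$chi2, 1e-4)
  f2 <- fit_bond_model(ds, "fix_ma")
  expect_equal(f2$params$U_bond, 8.4, tolerance = 1e-3)
  f3 <- fit_bond_model(ds, "free", init = bond_params(ma = 1.9, U_bond = 6))
  expect_equal(f3$params$ma, 1.32, tolerance = 5e-3)
  expect_equal(f3$params$U_bond, 8.4, tolerance = 5e-3)
})

test_that("fit input contracts are enforced", {
  p <- bond_params()
  ds3 <- tibble::tibble(velocity = c(0.1, 1, 10),
                        f_res = force_velocity(c(0.1, 1, 10), p),
                        f_res_sem = 1)
  expect_error(fit_bond_model(ds3), ">= 4 velocities")
  ds4 <- tibble::tibble(velocity = c(0.1, 0.5, 1, 10),
                        f_res = force_velocity(c(0.1, 0.5, 1, 10), p),
                        f_res_sem = c(0, 1, 1, 1))
  expect_error(fit_bond_model(ds4), "degenerate weights")
})

test_that("tidy and glance expose the fitted parameters", {
  p <- bond_params()
  V <- c(0.02, 0.2, 2, 20)
  ds <- tibble::tibble(velocity = V, f_res = force_velocity(V, p),
                       f_res_sem = 0)
  fit <- fit_bond_model(ds, "fix_Ubond")
  td <- tidy(fit)
  expect_setequal(td$term, c("ma", "U_bond"))
  expect_false(td$fixed[td$term == "ma"])
  gl <- glance(fit)
  expect_equal(gl$mode, "fix_Ubond")
  expect_true(is.finite(gl$xi_visc_res))
})
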