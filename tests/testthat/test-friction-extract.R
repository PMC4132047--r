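test_that("peak_force recovers deterministic and noisy plateaus", {
  tri <- tibble::tibble(force_pN = c(seq(0, 100, by = 2), seq(98, 0, by = -2)))
  expect_equal(peak_force(tri, smooth_window = 1), 100)
  cst <- tibble::tibble(force_pN = rep(42, 300))
  for (w in c(1, 10, 50, 300)) expect_equal(peak_force(cst, w), 42)

  set.seed(1)
  sigma <- 5
  noisy <- tibble::tibble(force_pN = 100 + rnorm(2000, sd = sigma))
  w <- 50
  expect_lt(abs(peak_force(noisy, w) - 100), 4 * sigma / sqrt(w))

  expect_error(peak_force(tibble::tibble(force_pN = numeric())), "empty")
})

# hand-built replicate traces with constant forces
fake_traces <- function(tot, wat, velocities = c(0.1, 0.5, 2, 10)) {
  rows <- list()
  for (iv in seq_along(velocities)) {
    for (r in seq_along(tot[[iv]])) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        force_pN = rep(tot[[iv]][r], 60), velocity = velocities[iv],
        replica = r, kind = "total")
      rows[[length(rows) + 1]] <- tibble::tibble(
        force_pN = rep(wat[[iv]][r], 60), velocity = velocities[iv],
        replica = r, kind = "water_only")
    }
  }
  dplyr::bind_rows(rows)
}

test_that("aggregation computes replica means, SEMs and the difference", {
  tot <- rep(list(c(10, 12, 14, 12)), 4)
  wat <- rep(list(c(2, 2, 2, 2)), 4)
  ds <- aggregate_traces(fake_traces(tot, wat), n_contact = 4, n_total = 10)
  expect_equal(ds$F_total, rep(12, 4))
  expect_equal(ds$F_total_sem, rep(sd(c(10, 12, 14, 12)) / 2, 4))
  expect_equal(ds$F_ac, rep(10, 4))
  expect_equal(ds$F_ac_sem, rep(sqrt(ds$F_total_sem[1]^2 + 0), 4))
  expect_equal(ds$f_res, rep(10 / 4, 4))
  # decomposition closure is exact for the means
  expect_equal(ds$F_total, ds$F_water + ds$F_ac)

  # equal total and water forces give identically zero interface friction
  ds0 <- aggregate_traces(fake_traces(tot, tot), n_contact = 4, n_total = 10)
  expect_true(all(ds0$F_ac == 0))
})

test_that("aggregation rejects unusable inputs", {
  tot <- rep(list(c(10, 12, 14, 12)), 4)
  one_rep <- fake_traces(rep(list(10), 4), rep(list(2), 4))
  expect_error(aggregate_traces(one_rep, n_contact = 4, n_total = 10),
               ">= 2 replicas")
  mism <- fake_traces(tot, rep(list(c(2, 2, 2, 2)), 4))
  mism <- dplyr::filter(mism, !(kind == "water_only" & velocity == 2))
  expect_error(aggregate_traces(mism, n_contact = 4, n_total = 10),
               "velocity grid")
})

test_that("the zero-intercept water law recovers its slope", {
  V <- c(0.1, 0.5, 2, 10)
  n_tot <- 10
  tot <- lapply(V, function(v) rep(5 + n_tot * 1e-12 * v * 1e12, 4))
  wat <- lapply(V, function(v) rep(n_tot * 1e-12 * v * 1e12, 4))
  ds <- aggregate_traces(fake_traces(tot, wat), n_contact = 4, n_total = n_tot)
  wl <- fit_water_law(ds)
  expect_equal(wl$xi_water, 1e-12, tolerance = 1e-12)

  # all-zero forces: zero slope
  z <- lapply(V, function(v) rep(0, 4))
  dz <- aggregate_traces(fake_traces(z, z), n_contact = 4, n_total = n_tot)
  expect_equal(fit_water_law(dz)$xi_water, 0)

  expect_error(fit_water_law(ds[1:2, ], n_total = n_tot), ">= 3")
})

test_that("stress conversion follows tau = F/A with correct units", {
  tot <- rep(list(rep(1002, 4)), 4)
  wat <- rep(list(rep(2, 4)), 4)
  ds <- aggregate_traces(fake_traces(tot, wat), n_contact = 10, n_total = 10)
  st <- to_stress(ds, area = 100, d_shear = 0.5)
  expect_equal(st$tau_MPa, rep(10, 4)) # 1000 pN / 100 nm^2 = 10 MPa
  st2 <- to_stress(ds, area = 200, d_shear = 0.5)
  expect_equal(st2$tau_MPa, st$tau_MPa / 2)
  expect_error(to_stress(ds, area = 0), "> 0")

  # per-residue apparent viscosity: (f_res/V) * d_shear/(A/N) in SI
  i <- 1
  eta_exp <- (st$f_res[i] * 1e-12 / st$velocity[i]) *
    (0.5e-9 / (100e-18 / 10))
  expect_equal(st$eta_res[i], eta_exp, tolerance = 1e-12)
})
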