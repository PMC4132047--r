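test_that("pure viscous drag balances the spring at steady state", {
  # no corrugation, no contact: mean plateau force = N_total * xi_w * V
  tr <- simulate_water_pull(pull_protocol(2, seed = 3), study_truth())
  pred <- 1344 * 1e-12 * 2 * 1e12 # pN
  expect_equal(mean(tr$force_pN), pred, tolerance = 0.02)

  # doubling the velocity doubles the steady force
  tr2 <- simulate_water_pull(pull_protocol(4, seed = 3), study_truth())
  expect_equal(mean(tr2$force_pN) / mean(tr$force_pN), 2, tolerance = 0.05)

  # the mean force normalized by N_total V recovers xi_w
  xi_hat <- mean(tr$force_pN) * 1e-12 / (1344 * 2)
  expect_equal(xi_hat, 1e-12, tolerance = 0.05)
})

test_that("zero temperature gives deterministic identical replicas", {
  pr <- pull_protocol(1, temperature = 0, seed = 5)
  t1 <- simulate_pull(pr, study_truth(), replica = 1)
  t2 <- simulate_pull(pr, study_truth(), replica = 2)
  expect_equal(t1$force_pN, t2$force_pN, tolerance = 0)
  # force sits at the deterministic steady value on the hold plateau
  p <- bond_params()
  pred <- 68 * force_velocity(1, p) + 1344e-12 * 1 * 1e12
  plateau <- t1$force_pN[t1$bundle_pos_nm < 5.0]
  expect_equal(max(abs(plateau - pred)) / pred, 0, tolerance = 1e-3)
})

test_that("peak forces at study conditions match the steady bond model", {
  # amorphous-crystalline part: mean peak difference within 3 SEM of the
  # model's steady force at the same velocity
  pr <- pull_protocol(2, seed = 17)
  tot <- vapply(1:4, function(r) {
    peak_force(simulate_pull(pr, study_truth(), replica = r))
  }, numeric(1))
  wat <- vapply(1:4, function(r) {
    peak_force(simulate_water_pull(pull_protocol(2, seed = 170 + r),
                                   study_truth()))
  }, numeric(1))
  fac <- mean(tot) - mean(wat)
  sem <- sqrt(stats::var(tot) / 4 + stats::var(wat) / 4)
  pred <- 68 * force_velocity(2, bond_params())
  expect_lt(abs(fac - pred), 3 * sem + 0.01 * pred)
})

test_that("two seeds differ in detail but agree in the mean", {
  a <- simulate_water_pull(pull_protocol(1, seed = 1), study_truth())
  b <- simulate_water_pull(pull_protocol(1, seed = 2), study_truth())
  expect_false(isTRUE(all.equal(a$force_pN, b$force_pN)))
  pooled_se <- sqrt(stats::var(a$force_pN) / nrow(a) +
                      stats::var(b$force_pN) / nrow(b))
  # means agree within a few standard errors (samples are correlated, so
  # the naive SE underestimates; allow a wide but bounded band)
  expect_lt(abs(mean(a$force_pN) - mean(b$force_pN)),
            10 * pooled_se + 0.02 * mean(a$force_pN))
})

test_that("the bundle coordinate obeys fluctuation-dissipation", {
  # bond contribution off: position variance about the drift = kT / k_spring
  pr <- pull_protocol(0.05, seed = 23)
  v <- unlist(lapply(1:8, function(r) {
    tr <- simulate_water_pull(pull_protocol(0.05, seed = 23 + r),
                              study_truth())
    stats::resid(stats::lm(bundle_pos_nm ~ time_ps, data = tr)) * 1e-9
  }))
  kk <- 7 * 830 * 1e-12 / 1e-9 # N/m
  expect_equal(mean(v^2), 1.380649e-23 * 300 / kk, tolerance = 0.10)
})

test_that("datasets have the right shape, determinism and monotone forces", {
  vel <- c(0.02, 0.05, 0.2, 0.5, 2, 5, 20)
  tr <- generate_dataset(vel, pull_protocol(1, n_replicas = 4),
                         study_truth(), seed = 9)
  key <- dplyr::distinct(tr[, c("velocity", "replica", "kind")])
  expect_equal(nrow(key), 7 * 4 * 2)

  tr2 <- generate_dataset(vel, pull_protocol(1, n_replicas = 4),
                          study_truth(), seed = 9)
  expect_identical(as.data.frame(tr), as.data.frame(tr2))

  ds <- aggregate_traces(tr)
  expect_true(all(diff(ds$F_total) > 0))
  expect_true(all(diff(ds$F_water) > 0))

  expect_error(generate_dataset(c(0.5, 200), pull_protocol(1),
                                study_truth(), seed = 1),
               "velocities")
})

test_that("trace CSV round trip is lossless", {
  tr <- generate_dataset(c(0.5, 5), pull_protocol(1, n_replicas = 2),
                         study_truth(), seed = 4)
  dir <- tempfile("traces")
  on.exit(unlink(dir, recursive = TRUE))
  write_traces(tr, dir)
  back <- read_traces(dir)
  expect_equal(nrow(back), nrow(tr))
  m <- dplyr::arrange(back, velocity, kind, replica, time_ps)
  o <- dplyr::arrange(tibble::as_tibble(tr), velocity, kind, replica, time_ps)
  expect_equal(m$force_pN, o$force_pN, tolerance = 1e-9)
})

test_that("protocol validation and the stability bound are enforced", {
  expect_error(pull_protocol(-1), "velocity")
  expect_error(pull_protocol(1, spring_k = 0), "spring_k")
  pr <- pull_protocol(1, dt = 1) # far above the stable bound
  expect_error(simulate_pull(pr, study_truth()), "stable bound")
})
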