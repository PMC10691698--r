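test_that("mean-field trajectory solves the balance equation", {
  p <- const_params(beta = 0.25)
  # pure exponential decay: f = 0, n(4) = 100 e^-1
  dec <- mean_field_trajectory(weekly_profile(rep(0, 168)), p, 100, c(2, 4))
  expect_equal(dec$count[2], 100 * exp(-1), tolerance = 1e-9)
  expect_equal(dec$count[1], 100 * exp(-0.5), tolerance = 1e-9)
  # fixed point: starting at f/beta stays there
  fp <- mean_field_trajectory(flat_profile(14), p, 14 / 0.25, seq(0, 72, 0.5))
  expect_equal(fp$count, rep(56, length(fp$count)), tolerance = 1e-9)
  # convergence to f/beta from 0
  cv <- mean_field_trajectory(flat_profile(14), p, 0, c(100, 200))
  expect_equal(cv$count[2], 56, tolerance = 1e-6)
  expect_error(mean_field_trajectory(flat_profile(), p, -1, 0:10), "non-negative")
  expect_error(mean_field_trajectory(flat_profile(), p, 5, numeric(0)), "non-empty")
})

test_that("weekly average of the periodic mean-field orbit matches f/beta", {
  p <- table1_params()
  prof <- flat_profile(14)
  n0 <- edcrowd:::mean_field_periodic_start(prof, p)
  orbit <- mean_field_trajectory(prof, p, n0, seq(0, 168, by = 0.25))
  target <- mean_field_fixed_point(14, mean_exit_rate(p))  # 54.93
  expect_equal(mean(orbit$count[-1]), target, tolerance = 0.02)
  # periodicity: one week later the orbit closes
  expect_equal(orbit$count[1], orbit$count[length(orbit$count)], tolerance = 1e-9)
})

test_that("fixed point is linear in flux and rejects bad rates", {
  expect_equal(mean_field_fixed_point(14, 0.2549), 54.9, tolerance = 1e-3)
  expect_equal(mean_field_fixed_point(0, 0.25), 0)
  expect_equal(mean_field_fixed_point(28, 0.2549),
               2 * mean_field_fixed_point(14, 0.2549))
  expect_error(mean_field_fixed_point(14, 0), "positive")
})

test_that("mean-field trajectory scales linearly with the flux (n0 = 0)", {
  p <- table1_params()
  prof <- calibrated_profile()
  t1 <- mean_field_trajectory(prof, p, 0, 0:167)$count
  t3 <- mean_field_trajectory(weekly_profile(3 * prof$flux), p, 0, 0:167)$count
  expect_equal(t3, 3 * t1, tolerance = 1e-9)
})

test_that("exact birth-death simulator reproduces known laws", {
  # empty system with no inflow stays empty
  z <- simulate_exact(weekly_profile(rep(0, 168)), const_params(sigma2 = 0),
                      n0 = 0, horizon = 100, seed = 1, output = "hourly")
  expect_true(all(z$count == 0))
  # M/M/inf stationary law: Poisson(f/beta) so mean = variance = 56
  s <- simulate_exact(flat_profile(14), const_params(0.25, sigma2 = 0),
                      n0 = 56, horizon = 1.2e5, seed = 2, output = "hourly")
  x <- s$count[-(1:100)]
  expect_equal(mean(x), 56, tolerance = 0.02)
  expect_equal(var(x) / mean(x), 1, tolerance = 0.05)
  expect_error(simulate_exact(flat_profile(), table1_params(), 5, 10),
               "sigma2")
})

test_that("pure-death first-passage time matches the harmonic sum", {
  # mean time for 5 -> 0 at beta = 0.25: sum_k 1/(beta k) = 9.1333 h
  prof0 <- weekly_profile(rep(0, 168))
  p <- const_params(0.25, sigma2 = 0)
  set.seed(42)
  ext <- replicate(1e4, {
    ev <- simulate_exact(prof0, p, n0 = 5, horizon = 400)
    max(ev$time_h)
  })
  expect_equal(mean(ext), sum(1 / (0.25 * (1:5))), tolerance = 0.025)
})

test_that("noise-free Langevin matches the closed-form mean field", {
  p0 <- ed_params(beta = table1_params()$beta, sigma1 = 0, sigma2 = 0)
  prof <- calibrated_profile()
  sl <- simulate_langevin(prof, p0, n0 = 50, horizon = 48, dt = 0.005, seed = 1)
  mf <- mean_field_trajectory(prof, p0, 50, 0:48)
  rel <- abs(sl$count - mf$count) / mf$count
  expect_lt(max(rel), 0.005)
})

test_that("Langevin agrees with the exact birth-death oracle (KL < 0.02)", {
  p <- const_params(0.25, sigma1 = 1, sigma2 = 0)
  prof <- flat_profile(14)
  ex <- simulate_exact(prof, p, n0 = 56, horizon = 1.2e5, seed = 3,
                       output = "hourly")$count[-(1:100)]
  set.seed(4)
  lg <- as.numeric(edcrowd:::langevin_hourly_matrix(prof, p, 600))
  expect_gte(length(lg), 1e5)
  expect_lt(histogram_kl(lg, ex), 0.02)
  # stationary moments match the Poisson law
  expect_equal(mean(lg), 56, tolerance = 0.02)
  expect_equal(var(lg) / 56, 1, tolerance = 0.05)
})

test_that("systematic noise inflates the stationary variance", {
  prof <- flat_profile(14)
  v0 <- var(as.numeric({
    set.seed(5); edcrowd:::langevin_hourly_matrix(prof, const_params(0.25, 1, 0), 1200)
  }))
  v1 <- var(as.numeric({
    set.seed(5); edcrowd:::langevin_hourly_matrix(prof, const_params(0.25, 1, 0.36), 1200)
  }))
  expect_gt(v1, v0 * 1.2)
})

test_that("halving the step changes hourly ensemble means by < 0.5%", {
  p <- table1_params()
  prof <- calibrated_profile()
  set.seed(6)
  m1 <- colMeans(edcrowd:::langevin_hourly_matrix(prof, p, 3000, dt = 0.02))
  set.seed(6)
  m2 <- colMeans(edcrowd:::langevin_hourly_matrix(prof, p, 3000, dt = 0.01))
  expect_lt(mean(abs(m1 - m2) / m2), 0.005)
})

test_that("identical seeds give bit-identical trajectories; none negative", {
  prof <- calibrated_profile()
  p <- table1_params(sigma2 = 1.2)
  a <- simulate_langevin(prof, p, 5, 72, n_realizations = 20, seed = 9)
  b <- simulate_langevin(prof, p, 5, 72, n_realizations = 20, seed = 9)
  expect_identical(a, b)
  expect_true(all(a$count >= 0))
  e1 <- simulate_exact(prof, const_params(sigma2 = 0), 10, 200, seed = 9)
  e2 <- simulate_exact(prof, const_params(sigma2 = 0), 10, 200, seed = 9)
  expect_identical(e1, e2)
  expect_true(all(e1$count >= 0))
  expect_error(simulate_langevin(prof, p, 5, 10, dt = -0.1), "positive")
})

test_that("ensemble statistics: hand arithmetic and the Poisson property", {
  two <- tibble::tibble(realization = c(1, 2), time_h = c(10, 10),
                        count = c(50, 60))
  st <- ensemble_stats(two)
  expect_equal(st$hourly$mean, 55)
  expect_equal(st$hourly$std, 5)   # population STD convention
  # identical realizations have zero spread
  same <- tibble::tibble(realization = rep(1:3, each = 2),
                         time_h = rep(c(1, 2), 3), count = rep(c(7, 9), 3))
  expect_true(all(ensemble_stats(same)$hourly$std == 0))
  expect_equal(sum(st$histogram$prob), 1)
  expect_error(ensemble_stats(list()), "empty")
  # exact-simulator ensemble at stationarity: per-hour mean ~ variance
  p <- const_params(0.25, sigma2 = 0)
  set.seed(10)
  sims <- purrr::map(1:300, function(i) {
    s <- simulate_exact(flat_profile(14), p, 56, 48, output = "hourly")
    dplyr::mutate(tibble::as_tibble(s), realization = i)
  })
  st2 <- ensemble_stats(dplyr::bind_rows(sims), sample_times = 24:48)
  pooled_var <- mean(st2$hourly$std^2)
  expect_equal(pooled_var / mean(st2$hourly$mean), 1, tolerance = 0.1)
})
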