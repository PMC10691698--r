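reduced_grid <- list(sigma1 = c(0.8, 1.0, 1.2, 1.4),
                     sigma2 = c(0.15, 0.35, 0.55))

test_that("exit-rate fit recovers the generating rates from noise-free means", {
  prof <- calibrated_profile()
  truth <- table1_params()
  n0 <- edcrowd:::mean_field_periodic_start(prof, truth)
  means <- mean_field_trajectory(prof, truth, n0, 0:167)
  occ_stats <- tibble::tibble(weekly_hour = 0:167, mean = means$count,
                              std = 0, n_obs = 1)
  fit <- fit_betas(occ_stats, prof)
  expect_equal(unname(fit$beta), unname(truth$beta), tolerance = 1e-3)
  expect_gt(fit$r_squared, 0.9999)
  expect_true(all(fit$halfwidth >= 0))
})

test_that("exit-rate fit is invariant to jointly scaling flux and occupancy", {
  prof <- calibrated_profile()
  truth <- table1_params()
  n0 <- edcrowd:::mean_field_periodic_start(prof, truth)
  means <- mean_field_trajectory(prof, truth, n0, 0:167)$count
  fit1 <- fit_betas(tibble::tibble(weekly_hour = 0:167, mean = means), prof)
  fit2 <- fit_betas(tibble::tibble(weekly_hour = 0:167, mean = 2 * means),
                    weekly_profile(2 * prof$flux))
  expect_equal(fit2$beta, fit1$beta, tolerance = 1e-3)
})

test_that("noise grid MLE recovers a sigma sitting on the grid", {
  prof <- calibrated_profile()
  beta <- table1_params()$beta
  truth <- ed_params(beta = beta, sigma1 = 1.0, sigma2 = 0.35)
  set.seed(100)
  S_data <- tibble::tibble(
    weekly_hour = 0:167,
    std = apply(edcrowd:::langevin_hourly_matrix(prof, truth, 1500), 2,
                edcrowd:::pop_sd)
  )
  fit <- noise_mle(S_data, beta, prof, grid_spec = reduced_grid,
                   n_realizations = 300, refine_realizations = 300,
                   refine_step = 0.1, seed = 101, dt = 0.02)
  expect_lte(abs(fit$sigma[["sigma1"]] - 1.0), 0.1)
  expect_lte(abs(fit$sigma[["sigma2"]] - 0.35), 0.1)
  # argmin contract: reported MSE is the surface minimum
  expect_equal(fit$p2, min(fit$surface$mse))
  expect_true(all(fit$surface$mse >= 0))
})

test_that("an optimum outside the grid raises a boundary warning", {
  prof <- flat_profile(14)
  beta <- const_params(0.25)$beta
  S_data <- tibble::tibble(weekly_hour = 0:167, std = 40)  # far above model STDs
  expect_warning(
    noise_mle(S_data, beta, prof,
              grid_spec = list(sigma1 = c(0.8, 1.0), sigma2 = c(0.1, 0.2)),
              n_realizations = 50, refine_realizations = 50,
              refine_step = 0.1, seed = 1, dt = 0.05),
    class = "edcrowd_boundary_warning")
})

test_that("Gaussian uncertainty reproduces the quadratic-profile closed form", {
  w1 <- 0.2; w2 <- 0.1; mse0 <- 0.5; n <- 168
  ax1 <- seq(0.8, 1.2, by = 0.05); ax2 <- seq(0.3, 0.5, by = 0.05)
  surface <- dplyr::bind_rows(
    tibble::tibble(sigma1 = ax1, sigma2 = 0.4,
                   mse = mse0 * (1 + (ax1 - 1)^2 / w1^2), pass = "refine"),
    tibble::tibble(sigma1 = 1, sigma2 = ax2,
                   mse = mse0 * (1 + (ax2 - 0.4)^2 / w2^2), pass = "refine")
  )
  fit <- structure(list(sigma = c(sigma1 = 1, sigma2 = 0.4), p2 = mse0,
                        surface = surface, n_points = n),
                   class = "ed_noise_fit")
  unc <- mle_uncertainty(fit)
  expect_equal(unc[["sigma1"]], w1 / sqrt(n), tolerance = 1e-6)
  expect_equal(unc[["sigma2"]], w2 / sqrt(n), tolerance = 1e-6)
  # flat profile: no curvature, uncertainty undefined
  flat <- dplyr::mutate(surface, mse = mse0)
  fit_flat <- structure(list(sigma = c(sigma1 = 1, sigma2 = 0.4), p2 = mse0,
                             surface = flat, n_points = n),
                        class = "ed_noise_fit")
  expect_error(mle_uncertainty(fit_flat), "flat|non-unimodal")
})

test_that("refitting data regenerated at the fitted parameters is stable", {
  prof <- calibrated_profile()
  truth <- table1_params()
  log1 <- generate_visit_log(prof, truth, n_weeks = 60, seed = 200)
  fit1 <- suppressWarnings(
    ed_fit(log1, grid_spec = reduced_grid, n_realizations = 150,
           refine_realizations = 200, refine_step = 0.05, seed = 201,
           dt = 0.02))
  # recovery leg: within 5% on each exit rate
  expect_lt(max(abs(fit1$params$beta - truth$beta) / truth$beta), 0.05)
  # idempotence leg: regenerate at the fitted parameters and refit
  # (the generator needs sigma1 >= 1, so clamp the regeneration truth there)
  p_regen <- ed_params(beta = fit1$params$beta,
                       sigma1 = max(1, fit1$params$sigma1),
                       sigma2 = fit1$params$sigma2)
  log2 <- generate_visit_log(prof, p_regen, n_weeks = 60, seed = 202)
  fit2 <- suppressWarnings(
    ed_fit(log2, grid_spec = reduced_grid, n_realizations = 150,
           refine_realizations = 200, refine_step = 0.05, seed = 203,
           dt = 0.02))
  expect_lt(max(abs(fit2$params$beta - p_regen$beta) / p_regen$beta), 0.05)
  expect_lte(abs(fit2$params$sigma1 - p_regen$sigma1), 0.1)
  expect_lte(abs(fit2$params$sigma2 - p_regen$sigma2), 0.05)
  # tidy/glance expose all six parameters with uncertainties
  td <- tidy(fit1)
  expect_equal(nrow(td), 6)
  expect_true(all(td$std.error > 0))
  expect_equal(glance(fit1)$sigma2, fit1$params$sigma2)
})
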