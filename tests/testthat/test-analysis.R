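test_that("tail probability counts strict exceedances with binomial error", {
  expect_warning(
    tp <- tail_probability(c(100, 130, 150, 90), 120),
    class = "edcrowd_precision_warning")
  expect_equal(tp$prob, 0.5)
  expect_equal(tp$se, sqrt(0.25 / 4))
  # threshold below the sample minimum
  expect_warning(tp1 <- tail_probability(c(10, 20, 30), 5),
                 class = "edcrowd_precision_warning")
  expect_equal(tp1$prob, 1)
})

test_that("tail probabilities are monotone and pool consistently", {
  prof <- calibrated_profile()
  ens <- simulate_stationary_week(prof, table1_params(),
                                  n_realizations = 1500, seed = 30)
  probs <- vapply(c(80, 100, 120, 140),
                  function(th) tail_probability(ens, th)$prob, numeric(1))
  expect_true(all(diff(probs) <= 0))
  # pooled tail equals the hour-weighted mean of per-hour tails
  per_hour <- ens |>
    dplyr::group_by(weekly_hour) |>
    dplyr::summarise(p = mean(count > 100))
  expect_equal(tail_probability(ens, 100)$prob, mean(per_hour$p),
               tolerance = 1e-12)
  # shift filter restricts the sample
  tp_m <- tail_probability(ens, 100, shifts = "morning")
  expect_equal(tp_m$n_samples, 1500 * 56)
})

test_that("relative-crowding distribution normalises and handles point mass", {
  sm <- tidyr::expand_grid(week = 0:9, weekday = 0:6,
                           shift = c("morning", "afternoon", "night")) |>
    dplyr::mutate(t_start = week * 168 + weekday * 24 +
                    c(morning = 0, afternoon = 8, night = 16)[shift],
                  patient_hours = 440)
  xd <- patient_hours_distribution(sm)
  expect_equal(sum(xd$histogram$prob), 1)
  expect_true(all(xd$x == 1))                      # equal shifts: x = 1
  expect_equal(length(xd$x), 10 * 10)              # top-10 filter kept 10/21
  rt <- relative_tail(xd, delta = c(0.2, 0.4))
  expect_equal(rt$prob, c(0, 0))
})

test_that("elasticity scan is anchored at 1 and monotone in arrival flux", {
  prof <- calibrated_profile()
  p <- table1_params()
  el <- elasticity_scan(prof, p, "arrival_flux", deltas = c(0, 0.05, 0.1),
                        threshold = 120, n_realizations = 2000, seed = 31)
  expect_equal(el$ratio[el$delta == 0], 1)
  expect_equal(el$ratio_se[el$delta == 0], 0)
  expect_true(all(diff(el$ratio) > 0))   # more arrivals, more overcrowding
  expect_error(elasticity_scan(prof, p, "arrival_flux", deltas = c(0.05, 0.1)),
               "baseline")
})

test_that("a +10% flux raises mean occupancy by 10% but the tail much more", {
  prof <- calibrated_profile()
  p <- table1_params()
  set.seed(32)
  m0 <- mean(edcrowd:::langevin_hourly_matrix(prof, p, 2000))
  set.seed(32)
  m1 <- mean(edcrowd:::langevin_hourly_matrix(
    weekly_profile(1.1 * prof$flux), p, 2000))
  expect_equal(m1 / m0, 1.10, tolerance = 0.005)
  el <- elasticity_scan(prof, p, "arrival_flux", deltas = c(0, 0.1),
                        threshold = 120, n_realizations = 3000, seed = 33)
  expect_gt(el$ratio[el$delta == 0.1], 2)   # strongly non-linear response
})

test_that("shortening stays beats damping systematic noise at the baseline", {
  prof <- calibrated_profile()
  p <- table1_params()
  el_los <- elasticity_scan(prof, p, "length_of_stay", deltas = c(-20, 0),
                            threshold = 120, n_realizations = 3000, seed = 34)
  el_sig <- elasticity_scan(prof, p, "sigma2", deltas = c(-0.15, 0),
                            threshold = 120, n_realizations = 3000, seed = 34)
  drop_los <- 1 - el_los$ratio[el_los$delta == -20]
  drop_sig <- 1 - el_sig$ratio[el_sig$delta == -0.15]
  expect_gt(drop_los, drop_sig)
  expect_gt(drop_sig, 0)
})

test_that("overcrowding report assembles tails and relative tails", {
  prof <- calibrated_profile()
  ens <- simulate_stationary_week(prof, table1_params(),
                                  n_realizations = 1500, seed = 35)
  log <- generate_visit_log(prof, table1_params(), n_weeks = 20, seed = 36)
  rep <- overcrowding_report(ens, summaries = shift_summaries(log))
  expect_equal(rep$tails$level, c("severe", "dangerous"))
  expect_true(all(rep$tails$prob >= 0 & rep$tails$prob <= 1))
  expect_gte(rep$tails$prob[1], rep$tails$prob[2])
  expect_equal(rep$tails$hours_per_year, rep$tails$prob * 8766)
  expect_equal(nrow(rep$relative_tails), 2)
  expect_gte(rep$relative_tails$prob[1], rep$relative_tails$prob[2])
})

test_that("plot methods return ggplot objects", {
  prof <- calibrated_profile()
  expect_s3_class(autoplot(prof), "ggplot")
  sim <- simulate_langevin(prof, table1_params(), 55, 168,
                           n_realizations = 30, seed = 37)
  expect_s3_class(autoplot(ensemble_stats(sim)), "ggplot")
  el <- elasticity_scan(prof, table1_params(), "arrival_flux",
                        deltas = c(0, 0.1), threshold = 100,
                        n_realizations = 1000, seed = 38)
  expect_s3_class(autoplot(el), "ggplot")
})
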