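# Gaussian half-width of a likelihood profile L(x) = C exp[-(n/2) MSE(x)/MSE*]
# near its minimum: with MSE(x) ~ MSE*(1 + (x - x*)^2 / w^2), the profile is
# Gaussian with STD w/sqrt(n). `curv` is d2(MSE)/dx2 at the minimum.
gaussian_halfwidth <- function(mse_star, curv, n) {
  # curvature indistinguishable from zero at the MSE's own scale is flat
  if (!is.finite(curv) || curv <= 1e-8 * mse_star)
    abort("uncertainty undefined: likelihood profile is flat or non-unimodal")
  w2 <- 2 * mse_star / curv
  sqrt(w2 / n)
}

#' Fit per-day-group exit rates from mean-field dynamics
#'
#' Stage one of the two-stage estimation: the four exit rates (Sunday,
#' midweek, Friday, Saturday) are chosen to minimise the squared deviation
#' between the mean-field weekly trajectory (piecewise-constant rates,
#' given arrival profile, periodic initial condition) and the observed
#' per-weekly-hour occupancy means. The fit is a simultaneous 4-parameter
#' least squares, since the mean-field solution couples adjacent days
#' through the initial condition. 1-STD intervals come from the curvature
#' of the mean-squared-error profile along each rate, via the Gaussian
#' likelihood \eqn{L \propto \exp[-(n/2)\,MSE(\beta)/MSE^*]}.
#'
#' @param occ_stats hourly occupancy statistics (tibble with
#'   `weekly_hour` and `mean`), e.g. from [hourly_occupancy()].
#' @param profile the arrival profile to drive the mean-field model;
#'   normally the empirical hourly arrival flux means (see
#'   [hourly_flux()] and [as_weekly_profile()]).
#' @param init optional starting values (named like `ed_params()$beta`).
#' @return A list of class `ed_beta_fit`: `beta` (named vector),
#'   `halfwidth` (1-STD intervals), `mse`, `r_squared`, `fitted`
#'   (tibble `weekly_hour`, `mean`, `fitted`).
#' @export
fit_betas <- function(occ_stats, profile, init = NULL) {
  stats_df <- dplyr::arrange(tibble::as_tibble(occ_stats), .data$weekly_hour)
  if (!all(0:167 %in% stats_df$weekly_hour))
    abort("`occ_stats` must cover all 168 weekly hours")
  obs <- stats_df$mean
  flux <- profile_flux(profile)
  if (is.null(init)) {
    # crude per-group inversion f_bar/n_bar as a starting point
    grp <- day_group_of(0:167)
    init <- vapply(day_groups(), function(g) {
      mean(flux[grp == g]) / max(mean(obs[grp == g]), 1e-6)
    }, numeric(1))
  }
  model_means <- function(beta) {
    p <- ed_params(beta = setNames(beta, day_groups()), sigma1 = 0, sigma2 = 0)
    n0 <- mean_field_periodic_start(profile, p)
    mean_field_trajectory(profile, p, n0, 0:167)$count
  }
  objective <- function(logb) mean((obs - model_means(exp(logb)))^2)
  opt <- optim(log(init), objective, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  beta <- setNames(exp(opt$par), day_groups())
  mse_star <- opt$value
  n <- length(obs)
  if (!is.finite(mse_star) || opt$convergence != 0)
    abort("estimation failure: exit-rate objective did not converge")

  # curvature of MSE along each beta axis (others held at the optimum)
  halfwidth <- vapply(seq_along(beta), function(i) {
    d <- max(1e-4, 0.01 * beta[i])
    up <- dn <- beta
    up[i] <- beta[i] + d; dn[i] <- max(beta[i] - d, 1e-8)
    m_up <- mean((obs - model_means(up))^2)
    m_dn <- mean((obs - model_means(dn))^2)
    curv <- (m_up + m_dn - 2 * mse_star) / d^2
    gaussian_halfwidth(mse_star, curv, n)
  }, numeric(1))
  fitted <- model_means(beta)
  structure(list(beta = beta, halfwidth = setNames(halfwidth, day_groups()),
                 mse = mse_star, r_squared = r_squared(obs, fitted),
                 fitted = tibble::tibble(weekly_hour = 0:167, mean = obs,
                                         fitted = fitted)),
            class = "ed_beta_fit")
}

#' Convert hourly flux statistics to a weekly profile
#'
#' Uses the per-weekly-hour mean arrival counts as the deterministic
#' arrival flux, the empirical-profile convention of the estimation
#' procedure.
#'
#' @param flux_stats an `ed_hourly_stats` tibble from [hourly_flux()].
#' @return A [weekly_profile()].
#' @export
as_weekly_profile <- function(flux_stats) {
  df <- dplyr::arrange(tibble::as_tibble(flux_stats), .data$weekly_hour)
  weekly_profile(df$mean)
}

default_sigma_grid <- function() {
  list(sigma1 = seq(0.6, 1.6, by = 0.1), sigma2 = seq(0.05, 0.75, by = 0.1))
}

#' Grid maximum likelihood for the noise magnitudes
#'
#' Stage two of the estimation: for every candidate
#' \eqn{\sigma = (\sigma_1, \sigma_2)} on a grid, simulates an ensemble of
#' stationary weeks, computes the model's hour-by-hour occupancy STD
#' \eqn{S(\sigma, t_i)}, and scores the candidate by the mean squared
#' error against the data STD \eqn{S_i}. Under a Gaussian observation
#' model the maximum-likelihood point is the MSE argmin, and the fitted
#' observation-noise variance is \eqn{p^2 = MSE(\sigma^*)}. A second pass
#' refines the grid around the coarse argmin at step 0.025. Common random
#' numbers (one seed for every grid point) keep the surface smooth so the
#' argmin is well defined.
#'
#' @param S_data hourly occupancy STDs: tibble with `weekly_hour` and
#'   `std`, e.g. from [hourly_occupancy()].
#' @param betas fitted exit rates: an `ed_beta_fit`, an [ed_params()]
#'   object, or a named numeric vector.
#' @param profile the arrival profile (see [fit_betas()]).
#' @param grid_spec list with numeric vectors `sigma1` and `sigma2`.
#' @param n_realizations ensemble size per grid point (coarse pass;
#'   the refinement pass uses `refine_realizations`).
#' @param refine_realizations ensemble size for the refinement pass.
#' @param refine_step grid step of the refinement pass.
#' @param seed integer seed reused at every grid point.
#' @param dt Langevin step (hours).
#' @return A list of class `ed_noise_fit`: `sigma` (named argmin),
#'   `p2`, `surface` (tibble `sigma1`, `sigma2`, `mse`, `pass`),
#'   `n_points` (number of hourly points scored).
#' @export
noise_mle <- function(S_data, betas, profile, grid_spec = default_sigma_grid(),
                      n_realizations = 500, refine_realizations = 800,
                      refine_step = 0.025, seed = 1, dt = 0.01) {
  beta <- if (inherits(betas, "ed_beta_fit")) betas$beta
          else if (inherits(betas, "ed_params")) betas$beta
          else betas
  df <- dplyr::arrange(tibble::as_tibble(S_data), .data$weekly_hour)
  if (!all(0:167 %in% df$weekly_hour)) abort("`S_data` must cover all 168 weekly hours")
  S_i <- df$std
  n_pts <- length(S_i)

  mse_at <- function(s1, s2, n_real) {
    p <- ed_params(beta = beta, sigma1 = s1, sigma2 = s2)
    set.seed(seed)  # common random numbers across grid points
    m <- langevin_hourly_matrix(profile, p, n_real, dt = dt)
    S_model <- apply(m, 2, pop_sd)
    mean((S_i - S_model)^2)
  }
  eval_grid <- function(g1, g2, n_real, pass) {
    grid <- tidyr::expand_grid(sigma1 = g1, sigma2 = g2)
    grid$mse <- purrr::map2_dbl(grid$sigma1, grid$sigma2, mse_at, n_real = n_real)
    grid$pass <- pass
    grid
  }

  coarse <- eval_grid(grid_spec$sigma1, grid_spec$sigma2, n_realizations, "coarse")
  best <- coarse[which.min(coarse$mse), ]
  if (best$sigma1 %in% range(grid_spec$sigma1) ||
      best$sigma2 %in% range(grid_spec$sigma2)) {
    warn(paste0("argmin on the grid boundary (sigma1 = ", best$sigma1,
                ", sigma2 = ", best$sigma2, "); enlarge `grid_spec`"),
         class = "edcrowd_boundary_warning")
  }
  step1 <- if (length(grid_spec$sigma1) > 1) diff(grid_spec$sigma1)[1] else 0.1
  step2 <- if (length(grid_spec$sigma2) > 1) diff(grid_spec$sigma2)[1] else 0.1
  g1 <- seq(max(best$sigma1 - step1, 0), best$sigma1 + step1, by = refine_step)
  g2 <- seq(max(best$sigma2 - step2, 0), best$sigma2 + step2, by = refine_step)
  fine <- eval_grid(g1, g2, refine_realizations, "refine")
  best_f <- fine[which.min(fine$mse), ]

  structure(list(
    sigma = c(sigma1 = best_f$sigma1, sigma2 = best_f$sigma2),
    p2 = best_f$mse,
    surface = dplyr::bind_rows(coarse, fine),
    n_points = n_pts,
    beta = beta
  ), class = "ed_noise_fit")
}

#' Gaussian uncertainty of the noise-magnitude estimates
#'
#' For each noise magnitude, the 1-D likelihood profile along its axis
#' (the other coordinate held at the optimum) is
#' \eqn{L(\sigma_i) = C\exp[-(n/2)\,MSE(\sigma_i)/MSE(\sigma^*)]}; a
#' quadratic fit of the MSE profile near the minimum turns this into a
#' Gaussian whose STD is the reported half-width.
#'
#' @param fit an `ed_noise_fit` from [noise_mle()].
#' @param n number of hourly data points behind the MSE (defaults to the
#'   fit's `n_points`).
#' @return Named numeric vector of 1-STD half-widths for `sigma1` and
#'   `sigma2`.
#' @export
mle_uncertainty <- function(fit, n = fit$n_points) {
  surf <- dplyr::filter(fit$surface, .data$pass == "refine")
  out <- vapply(c("sigma1", "sigma2"), function(ax) {
    other <- setdiff(c("sigma1", "sigma2"), ax)
    prof <- surf[abs(surf[[other]] - fit$sigma[[other]]) < 1e-9, ]
    prof <- prof[order(prof[[ax]]), ]
    if (nrow(prof) < 3) abort("uncertainty undefined: refinement profile too short")
    x <- prof[[ax]] - fit$sigma[[ax]]
    qfit <- lm(prof$mse ~ x + I(x^2))
    curv <- 2 * unname(coef(qfit)[3])
    gaussian_halfwidth(fit$p2, curv, n)
  }, numeric(1))
  setNames(out, c("sigma1", "sigma2"))
}

#' Two-stage parameter estimation from a visit log
#'
#' Runs the full pipeline: empirical arrival profile and hourly occupancy
#' statistics from the log, mean-field exit-rate fit per day group, then
#' grid maximum likelihood for the noise magnitudes with Gaussian
#' uncertainties.
#'
#' @inheritParams occupancy_from_log
#' @param ... passed to [noise_mle()] (`grid_spec`, `n_realizations`,
#'   `seed`, ...).
#' @return A list of class `ed_fit`: `params` (an [ed_params()]),
#'   `uncertainties` (named vector for all six parameters), `beta_fit`,
#'   `noise_fit`, `diagnostics` (R-squared of the mean fit, `p2`).
#' @examples
#' \donttest{
#' prof <- calibrate_profile(ed_params(), seed = 1, n_realizations = 100)
#' log <- generate_visit_log(prof, ed_params(), n_weeks = 20, seed = 2)
#' fit <- ed_fit(log, n_realizations = 100, refine_realizations = 100)
#' tidy(fit)
#' }
#' @export
ed_fit <- function(log, ...) {
  flux_stats <- hourly_flux(log, "arrival")
  occ_stats <- hourly_occupancy(log)
  profile <- as_weekly_profile(flux_stats)
  beta_fit <- fit_betas(occ_stats, profile)
  noise_fit <- noise_mle(occ_stats, beta_fit, profile, ...)
  sig_unc <- mle_uncertainty(noise_fit)
  params <- ed_params(beta = beta_fit$beta,
                      sigma1 = noise_fit$sigma[["sigma1"]],
                      sigma2 = noise_fit$sigma[["sigma2"]])
  structure(list(
    params = params,
    uncertainties = c(beta_fit$halfwidth, sig_unc),
    beta_fit = beta_fit, noise_fit = noise_fit,
    diagnostics = list(r_squared_mean = beta_fit$r_squared, p2 = noise_fit$p2)
  ), class = "ed_fit")
}

#' @export
print.ed_fit <- function(x, ...) {
  cat("Two-stage ED crowding model fit\n")
  print(tidy(x))
  cat(sprintf("  mean-fit R^2 %.3f, p^2 %.3g\n",
              x$diagnostics$r_squared_mean, x$diagnostics$p2))
  invisible(x)
}

#' Tidy and glance methods for fitted objects
#'
#' @param x an `ed_fit` object.
#' @param ... unused.
#' @return `tidy()`: a tibble with one row per parameter (`term`,
#'   `estimate`, `std.error`). `glance()`: a one-row tibble of fit
#'   diagnostics.
#' @method tidy ed_fit
#' @export
tidy.ed_fit <- function(x, ...) {
  est <- c(x$params$beta, sigma1 = x$params$sigma1, sigma2 = x$params$sigma2)
  terms <- c(paste0("beta_", day_groups()), "sigma1", "sigma2")
  tibble::tibble(term = terms, estimate = unname(est),
                 std.error = unname(x$uncertainties[c(day_groups(), "sigma1", "sigma2")]))
}

#' @rdname tidy.ed_fit
#' @method glance ed_fit
#' @export
glance.ed_fit <- function(x, ...) {
  tibble::tibble(r.squared.mean = x$diagnostics$r_squared_mean,
                 p2 = x$diagnostics$p2,
                 sigma1 = x$params$sigma1, sigma2 = x$params$sigma2)
}
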