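new_occupancy <- function(time_h, count, kind = c("sampled", "step")) {
  kind <- match.arg(kind)
  tibble::new_tibble(tibble::tibble(time_h = time_h, count = count),
                     class = "ed_occupancy", kind = kind,
                     week_epoch = "Sunday 07:00")
}

#' Mean-field occupancy trajectory
#'
#' Solves \eqn{d\bar n/dt = f(t) - \beta(t)\bar n} with piecewise-constant
#' hourly arrival flux and per-day-group exit rate, by exact propagation
#' across hour bins: within a bin with constant \eqn{f, \beta},
#' \eqn{\bar n(t+\tau) = \bar n(t)e^{-\beta\tau} + (f/\beta)(1 - e^{-\beta\tau})}.
#'
#' @param profile a [weekly_profile()]; extended periodically beyond one week.
#' @param params an [ed_params()] object (only the exit rates are used).
#' @param n0 initial occupancy (patients, >= 0).
#' @param t_grid increasing numeric vector of times (hours since the week
#'   epoch, >= 0) at which to report the trajectory.
#' @return A tibble of class `ed_occupancy` with columns `time_h`, `count`.
#' @examples
#' prof <- weekly_profile(rep(14, 168))
#' mean_field_trajectory(prof, ed_params(), n0 = 0, t_grid = 0:48)
#' @export
mean_field_trajectory <- function(profile, params, n0, t_grid) {
  if (length(t_grid) == 0) abort("`t_grid` must be non-empty")
  if (is.unsorted(t_grid, strictly = FALSE) || any(t_grid < 0))
    abort("`t_grid` must be non-decreasing and non-negative")
  if (length(n0) != 1 || is.na(n0) || n0 < 0) abort("`n0` must be a single non-negative number")
  flux <- profile_flux(profile)
  bh <- beta_hourly(params)

  out <- numeric(length(t_grid))
  n <- n0
  hour <- 0L
  gi <- 1L
  step_to <- function(n, f, b, tau) n * exp(-b * tau) + (f / b) * (1 - exp(-b * tau))
  t_max <- t_grid[length(t_grid)]
  repeat {
    idx <- (hour %% 168L) + 1L
    # grid points inside [hour, hour+1)
    while (gi <= length(t_grid) && t_grid[gi] < hour + 1) {
      out[gi] <- step_to(n, flux[idx], bh[idx], t_grid[gi] - hour)
      gi <- gi + 1L
    }
    if (gi > length(t_grid) && t_max < hour + 1) break
    n <- step_to(n, flux[idx], bh[idx], 1)
    hour <- hour + 1L
    if (hour > t_max + 1) {  # catch grid points exactly at the final boundary
      while (gi <= length(t_grid)) { out[gi] <- n; gi <- gi + 1L }
      break
    }
  }
  new_occupancy(t_grid, out, kind = "sampled")
}

#' Mean-field fixed point
#'
#' With constant arrival flux and exit rate the mean occupancy relaxes, on
#' a timescale \eqn{1/\beta}, to the stable fixed point
#' \eqn{n^* = \bar f/\bar\beta}.
#'
#' @param f_bar mean arrival flux (patients/hour).
#' @param beta_bar mean exit rate (1/hour, > 0).
#' @return The fixed-point occupancy \eqn{\bar f/\bar\beta} (patients).
#' @examples
#' mean_field_fixed_point(14, mean_exit_rate(ed_params()))
#' @export
mean_field_fixed_point <- function(f_bar, beta_bar) {
  if (length(beta_bar) != 1 || is.na(beta_bar) || beta_bar <= 0)
    abort("`beta_bar` must be a single positive number")
  f_bar / beta_bar
}

# occupancy at weekly hour 0 on the periodic mean-field orbit:
# one week of propagation is affine, n(168) = A*n0 + B, so solve n = A*n + B
mean_field_periodic_start <- function(profile, params) {
  b0 <- mean_field_trajectory(profile, params, 0, 168)$count
  b1 <- mean_field_trajectory(profile, params, 1, 168)$count
  A <- b1 - b0
  b0 / (1 - A)
}

#' Exact event-driven birth-death simulation
#'
#' Simulates the master-equation dynamics exactly: births (arrivals) at
#' rate \eqn{f(t)} and per-capita deaths (exits) at rate \eqn{\beta(t)},
#' both piecewise constant per hour, via the Gillespie algorithm with
#' redraws at rate breakpoints. This is the brute-force oracle for the
#' demographic-noise-only model (\eqn{\sigma_1 = 1}, \eqn{\sigma_2 = 0});
#' `params$sigma2` must be 0 and `params$sigma1` is ignored.
#'
#' @inheritParams mean_field_trajectory
#' @param n0 integer initial occupancy (>= 0).
#' @param horizon simulation length in hours.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param output `"events"` returns the full piecewise-constant trajectory
#'   (one row per event); `"hourly"` returns on-the-hour samples only
#'   (memory-light, for long runs).
#' @param sample_times sampling grid for `output = "hourly"`; defaults to
#'   every hour in `[0, horizon]`.
#' @param max_events guard against runaway event counts.
#' @return A tibble of class `ed_occupancy` (`kind` attribute `"step"` for
#'   events, `"sampled"` for hourly output).
#' @examples
#' prof <- weekly_profile(rep(14, 168))
#' sim <- simulate_exact(prof, ed_params(sigma2 = 0), n0 = 56, horizon = 168,
#'                       seed = 1)
#' @export
simulate_exact <- function(profile, params, n0, horizon, seed = NULL,
                           output = c("events", "hourly"),
                           sample_times = NULL, max_events = 5e7) {
  output <- match.arg(output)
  if (length(n0) != 1 || is.na(n0) || n0 < 0 || n0 != round(n0))
    abort("`n0` must be a single non-negative integer")
  if (horizon <= 0) abort("`horizon` must be positive")
  if (params$sigma2 != 0)
    abort("the exact birth-death simulator covers demographic noise only; `params$sigma2` must be 0")
  flux <- profile_flux(profile)
  bh <- beta_hourly(params)
  if (!is.null(seed)) set.seed(seed)
  if (output == "events") {
    ev <- .gillespie_events(flux, bh, n0, horizon, as.integer(max_events))
    new_occupancy(ev$time_h, ev$count, kind = "step")
  } else {
    if (is.null(sample_times)) sample_times <- seq(0, floor(horizon))
    cnt <- .gillespie_sample(flux, bh, n0, horizon, as.numeric(sample_times))
    new_occupancy(as.numeric(sample_times), cnt, kind = "sampled")
  }
}

#' Langevin simulation of ED occupancy
#'
#' Integrates the stochastic differential equation
#' \deqn{dn = [f(t) - \beta(t) n]\,dt + \sigma_1\sqrt{f(t) + \beta(t) n}\,dW_1
#'       - \sigma_2\,\beta(t)\,n\,dW_2}
#' by Euler-Maruyama in the Ito convention: per step, each white-noise
#' channel contributes an independent Gaussian increment with standard
#' deviation \eqn{\sigma_i\sqrt{dt}}. The square-root argument is clamped
#' at zero and any post-step negative occupancy is reflected to its
#' absolute value, so trajectories stay non-negative (typical occupancy is
#' far from 0, so the reflection bias is negligible).
#'
#' @inheritParams mean_field_trajectory
#' @param horizon simulation length in hours.
#' @param dt time step in hours (> 0); default 0.01.
#' @param n_realizations number of independent trajectories.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param sample_times times (hours) at which to record; defaults to every
#'   hour in `[0, horizon]`. Snapped to the nearest step.
#' @return A tibble with columns `realization`, `time_h`, `count`.
#' @examples
#' prof <- weekly_profile(rep(14, 168))
#' sim <- simulate_langevin(prof, ed_params(), n0 = 56, horizon = 24,
#'                          n_realizations = 10, seed = 1)
#' @export
simulate_langevin <- function(profile, params, n0, horizon, dt = 0.01,
                              n_realizations = 1, seed = NULL,
                              sample_times = NULL) {
  if (length(dt) != 1 || is.na(dt) || dt <= 0) abort("`dt` must be a single positive number")
  if (n_realizations < 1) abort("`n_realizations` must be >= 1")
  if (length(n0) != 1 || is.na(n0) || n0 < 0) abort("`n0` must be a single non-negative number")
  if (horizon <= 0) abort("`horizon` must be positive")
  flux <- profile_flux(profile)
  bh <- beta_hourly(params)
  n_steps <- as.integer(round(horizon / dt))
  if (is.null(sample_times)) sample_times <- seq(0, floor(horizon))
  keep <- as.integer(round(sample_times / dt))
  if (any(keep < 0 | keep > n_steps)) abort("`sample_times` must lie within [0, horizon]")
  ord <- order(keep)
  if (!is.null(seed)) set.seed(seed)
  m <- .langevin_core(flux, bh, n0, dt, n_steps, params$sigma1, params$sigma2,
                      as.integer(n_realizations), keep[ord])
  tibble::tibble(
    realization = rep(seq_len(n_realizations), times = length(keep)),
    time_h = rep(keep[ord] * dt, each = n_realizations),
    count = as.numeric(m)
  ) |> dplyr::arrange(.data$realization, .data$time_h)
}

# stationary hourly samples of a simulated week: matrix n_real x 168,
# column j = weekly hour j-1. Starts on the periodic mean-field orbit and
# discards `warmup_h` hours before recording.
langevin_hourly_matrix <- function(profile, params, n_realizations,
                                   dt = 0.01, warmup_h = 24, n0 = NULL) {
  flux <- profile_flux(profile)
  bh <- beta_hourly(params)
  if (is.null(n0)) n0 <- mean_field_periodic_start(profile, params)
  horizon <- warmup_h + 168
  n_steps <- as.integer(round(horizon / dt))
  times <- seq(warmup_h, warmup_h + 167)
  keep <- as.integer(round(times / dt))
  m <- .langevin_core(flux, bh, n0, dt, n_steps, params$sigma1, params$sigma2,
                      as.integer(n_realizations), keep)
  wh <- times %% 168
  m[, order(wh), drop = FALSE]
}

#' Hourly ensemble statistics
#'
#' Reduces an ensemble of occupancy trajectories to per-weekly-hour mean
#' and STD (population convention, dividing by the number of
#' realizations), plus a pooled occupancy histogram over integer bins.
#'
#' @param realizations a tibble as returned by [simulate_langevin()]
#'   (columns `realization`, `time_h`, `count`), or a list of
#'   `ed_occupancy` tibbles sharing a common grid.
#' @param sample_times optional subset of times (hours) to use.
#' @return An object of class `ed_ensemble_stats`: a list with `hourly`
#'   (tibble: `weekly_hour`, `mean`, `std`, `n_obs`), `histogram` (tibble:
#'   `count`, `prob`, summing to 1), and `n_realizations`.
#' @export
ensemble_stats <- function(realizations, sample_times = NULL) {
  if (is.list(realizations) && !is.data.frame(realizations)) {
    if (length(realizations) == 0) abort("empty ensemble")
    realizations <- dplyr::bind_rows(
      purrr::imap(realizations, ~ dplyr::mutate(tibble::as_tibble(.x), realization = .y))
    )
  }
  if (!all(c("realization", "time_h", "count") %in% names(realizations)))
    abort("`realizations` must have columns realization, time_h, count")
  if (nrow(realizations) == 0) abort("empty ensemble")
  df <- tibble::as_tibble(realizations)
  if (!is.null(sample_times)) {
    df <- dplyr::filter(df, .data$time_h %in% sample_times)
    if (nrow(df) == 0) abort("no samples at the requested `sample_times`")
  }
  hourly <- df |>
    dplyr::mutate(weekly_hour = floor(weekly_hour(.data$time_h))) |>
    dplyr::group_by(.data$weekly_hour) |>
    dplyr::summarise(mean = mean(.data$count), std = pop_sd(.data$count),
                     n_obs = dplyr::n(), .groups = "drop")
  pooled <- round(df$count)
  tab <- table(factor(pooled, levels = seq(min(pooled), max(pooled))))
  histogram <- tibble::tibble(count = as.integer(names(tab)),
                              prob = as.numeric(tab) / sum(tab))
  structure(list(hourly = hourly, histogram = histogram,
                 n_realizations = dplyr::n_distinct(df$realization)),
            class = "ed_ensemble_stats")
}

#' @export
print.ed_ensemble_stats <- function(x, ...) {
  cat(sprintf("Hourly ensemble statistics over %d realizations\n", x$n_realizations))
  cat(sprintf("  pooled occupancy mean %.1f, STD %.1f\n",
              sum(x$histogram$count * x$histogram$prob),
              sqrt(sum(x$histogram$count^2 * x$histogram$prob) -
                   sum(x$histogram$count * x$histogram$prob)^2)))
  print(x$hourly, n = 5)
  invisible(x)
}
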