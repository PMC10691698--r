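as_hours <- function(t) {
  if (inherits(t, "POSIXct")) ts_to_hours(t) else as.numeric(t)
}

#' Momentary occupancy reconstructed from a visit log
#'
#' The occupancy at time `t` is the number of visits with
#' `arrival <= t < departure` (half-open membership, so a patient is
#' counted out at the departure instant).
#'
#' @param log an `ed_visit_log` tibble (see [generate_visit_log()],
#'   [read_visit_log()]).
#' @param t_grid times at which to count: hours since the week epoch
#'   (Sunday 07:00 of the log's first week) or POSIXct.
#' @return A tibble of class `ed_occupancy` with columns `time_h`, `count`.
#' @examples
#' prof <- weekly_profile(rep(14, 168))
#' log <- generate_visit_log(prof, ed_params(), n_weeks = 1, seed = 1)
#' occupancy_from_log(log, t_grid = 0:167)
#' @export
occupancy_from_log <- function(log, t_grid) {
  t_grid <- as_hours(t_grid)
  if (length(t_grid) == 0) abort("`t_grid` must be non-empty")
  per <- log_period(log)
  if (any(t_grid < per["start"] - 1e-9) || any(t_grid > per["end"] + 1e-9))
    abort("`t_grid` lies outside the log period")
  if (nrow(log) == 0) return(new_occupancy(t_grid, rep(0, length(t_grid))))
  arr <- sort(as_hours(log$arrival_ts))
  dep <- sort(as_hours(log$departure_ts))
  cnt <- findInterval(t_grid, arr) - findInterval(t_grid, dep)
  new_occupancy(t_grid, cnt, kind = "sampled")
}

hourly_stats_of <- function(counts) {
  counts |>
    dplyr::group_by(.data$weekly_hour) |>
    dplyr::summarise(mean = mean(.data$value), std = pop_sd(.data$value),
                     n_obs = dplyr::n(), .groups = "drop")
}

#' Hourly arrival or exit flux and its weekly statistics
#'
#' Counts arrivals (or exits) in each half-open hourly bin `[h, h+1)`,
#' binned by the event's own timestamp, then summarises each of the 168
#' weekly hours across weeks (mean and population STD; weeks with zero
#' events count as zeros).
#'
#' @inheritParams occupancy_from_log
#' @param kind count `"arrival"` or `"exit"` events.
#' @return A tibble of class `ed_hourly_stats` with columns `weekly_hour`,
#'   `mean`, `std`, `n_obs`, and attribute `weekly_counts` (tibble
#'   `week`, `weekly_hour`, `value`).
#' @export
hourly_flux <- function(log, kind = c("arrival", "exit")) {
  kind <- match.arg(kind)
  ts <- if (kind == "arrival") log$arrival_ts else log$departure_ts
  h <- as_hours(ts)
  per <- log_period(log)
  h <- h[h >= per["start"] & h < per["end"]]  # half-open period membership
  weeks <- seq(floor(per["start"] / 168), ceiling(per["end"] / 168) - 1)
  counts <- tibble::tibble(
    week = floor(h / 168),
    weekly_hour = as.integer(floor(h) %% 168)
  ) |>
    dplyr::count(.data$week, .data$weekly_hour, name = "value") |>
    tidyr::complete(week = weeks, weekly_hour = 0:167,
                    fill = list(value = 0L))
  out <- hourly_stats_of(counts)
  tibble::new_tibble(out, class = "ed_hourly_stats", weekly_counts = counts,
                     kind = kind)
}

#' Hourly occupancy statistics from a visit log
#'
#' Samples the momentary occupancy on the hour throughout the log period
#' and summarises each weekly hour across weeks (mean and population STD).
#'
#' @inheritParams occupancy_from_log
#' @return A tibble of class `ed_hourly_stats` with columns `weekly_hour`,
#'   `mean`, `std`, `n_obs`.
#' @export
hourly_occupancy <- function(log) {
  per <- log_period(log)
  marks <- seq(ceiling(per["start"]), ceiling(per["end"]) - 1)
  occ <- occupancy_from_log(log, marks)
  counts <- tibble::tibble(
    week = floor(occ$time_h / 168),
    weekly_hour = as.integer(floor(occ$time_h) %% 168),
    value = occ$count
  )
  out <- hourly_stats_of(counts)
  tibble::new_tibble(out, class = "ed_hourly_stats", weekly_counts = counts,
                     kind = "occupancy")
}

#' Patient hours: integrated occupancy over a window
#'
#' The patient-hours metric is \eqn{C = \int_T^{T+\Delta T} n(t)\,dt}, the
#' accumulated presence over a time window (100 patients present for an
#' entire 8-hour shift give C = 800). Event (`"step"`) series are
#' integrated exactly as piecewise-constant; sampled series use the
#' trapezoid rule with linear interpolation at the window edges.
#'
#' @param occupancy an `ed_occupancy` tibble.
#' @param window numeric `c(start, end)` in hours, within the series span.
#' @return Patient hours (a single number).
#' @export
patient_hours <- function(occupancy, window) {
  if (length(window) != 2 || window[2] <= window[1])
    abort("`window` must be c(start, end) with end > start")
  tt <- occupancy$time_h; cc <- occupancy$count
  if (window[1] < tt[1] - 1e-9 || window[2] > tt[length(tt)] + 1e-9) {
    if (identical(attr(occupancy, "kind"), "step")) {
      # a step series stays at its last value until the period end
      tt <- c(tt, max(tt[length(tt)], window[2]))
      cc <- c(cc, cc[length(cc)])
    } else {
      abort("`window` lies outside the occupancy series")
    }
  }
  if (identical(attr(occupancy, "kind"), "step")) {
    bp <- c(window[1], tt[tt > window[1] & tt < window[2]], window[2])
    val <- cc[pmax(findInterval(bp[-length(bp)], tt), 1)]
    sum(val * diff(bp))
  } else {
    inside <- tt > window[1] & tt < window[2]
    xs <- c(window[1], tt[inside], window[2])
    ys <- stats::approx(tt, cc, xout = xs, rule = 2)$y
    sum((ys[-1] + ys[-length(ys)]) / 2 * diff(xs))
  }
}

#' Per-shift patient hours for a whole log
#'
#' Splits the log period into consecutive 8-hour shifts (morning 07-15,
#' afternoon 15-23, night 23-07) and computes the exact patient hours of
#' each from the visit intervals.
#'
#' @inheritParams occupancy_from_log
#' @return A tibble of class `ed_shift_summary` with columns `week`,
#'   `weekday` (0 = Sunday), `shift`, `t_start` (hours), `patient_hours`.
#' @export
shift_summaries <- function(log) {
  per <- log_period(log)
  starts <- seq(per["start"], per["end"] - 8, by = 8)
  arr <- sort(as_hours(log$arrival_ts))
  dep <- sort(as_hours(log$departure_ts))
  # cumulative integral of n(t): I(t) = sum_i max(0, min(t, dep_i) - arr_i)
  cum_int <- function(t) {
    ia <- findInterval(t, arr); id <- findInterval(t, dep)
    (t * ia - c(0, cumsum(arr))[ia + 1]) - (t * id - c(0, cumsum(dep))[id + 1])
  }
  C <- cum_int(starts + 8) - cum_int(starts)
  tibble::new_tibble(
    tibble::tibble(
      week = as.integer(floor(starts / 168)),
      weekday = weekday_of(starts),
      shift = shift_of(starts),
      t_start = as.numeric(starts),
      patient_hours = C
    ),
    class = "ed_shift_summary"
  )
}

#' Relative crowding per shift
#'
#' Fills in \eqn{x = C_{shift}/\langle C\rangle}: each shift's patient
#' hours divided by the mean patient hours over all occurrences of the
#' same weekly shift (same weekday and shift label).
#'
#' @param summaries an `ed_shift_summary` tibble (see [shift_summaries()]).
#' @return The input with an added column `relative`.
#' @export
relative_crowding <- function(summaries) {
  if (nrow(summaries) == 0) abort("`summaries` must be non-empty")
  out <- summaries |>
    dplyr::group_by(.data$weekday, .data$shift) |>
    dplyr::mutate(relative = .data$patient_hours / mean(.data$patient_hours)) |>
    dplyr::ungroup()
  if (any(!is.finite(out$relative)))
    abort("undefined relative crowding: a weekly shift has zero mean patient hours")
  tibble::new_tibble(out, class = "ed_shift_summary")
}

#' Cohort survival curve and exponential exit-rate fit
#'
#' For the cohort of patients arriving within one hour of `cohort_start`,
#' computes the fraction still present at later times. The exit process is
#' modelled as Poisson, so the curve should decay exponentially; `beta_hat`
#' is minus the slope of a least-squares line through the log remaining
#' fraction, fitted over the span where the fraction is at least
#' `fit_floor` (default 0.05).
#'
#' @inheritParams occupancy_from_log
#' @param cohort_start start of the one-hour arrival window (hours since
#'   epoch, or POSIXct).
#' @param t_max follow-up span in hours.
#' @param by time resolution of the curve in hours.
#' @param fit_floor smallest remaining fraction included in the fit.
#' @return A list of class `ed_survival`: `curve` (tibble `t_h`,
#'   `elapsed_h`, `frac`), `beta_hat` (1/hour), `n_cohort`.
#' @export
survival_curve <- function(log, cohort_start, t_max = 24, by = 0.5,
                           fit_floor = 0.05) {
  t0 <- as_hours(cohort_start)
  arr <- as_hours(log$arrival_ts)
  in_cohort <- arr >= t0 & arr < t0 + 1
  if (!any(in_cohort)) abort("empty cohort: no arrivals in [cohort_start, cohort_start + 1h)")
  dep <- as_hours(log$departure_ts)[in_cohort]
  grid <- seq(t0 + 1, t0 + t_max, by = by)  # measure from the end of the arrival hour
  frac <- vapply(grid, function(t) mean(dep > t), numeric(1))
  curve <- tibble::tibble(t_h = grid, elapsed_h = grid - t0, frac = frac)
  usable <- frac >= fit_floor & frac > 0
  beta_hat <- NA_real_
  if (sum(usable) >= 2) {
    fit <- lm(log(frac[usable]) ~ grid[usable])
    beta_hat <- -unname(coef(fit)[2])
  }
  structure(list(curve = curve, beta_hat = beta_hat,
                 n_cohort = sum(in_cohort)),
            class = "ed_survival")
}

#' @export
print.ed_survival <- function(x, ...) {
  cat(sprintf("Cohort survival: n = %d, fitted exit rate %.4g /h (LOS %.3g h)\n",
              x$n_cohort, x$beta_hat, 1 / x$beta_hat))
  invisible(x)
}

#' Goodness-of-fit: Kullback-Leibler divergence and R-squared
#'
#' `kl_divergence()` computes \eqn{KL(p\Vert q) = \sum_i p_i \log(p_i/q_i)}
#' (nats) for two probability vectors on a shared support.
#' `histogram_kl()` bins two integer-valued sample vectors on their union
#' support with add-one-half smoothing of the counts before normalising
#' (so empty bins never produce infinities), then applies
#' `kl_divergence()`. `r_squared()` is \eqn{1 - SS_{res}/SS_{tot}}.
#'
#' @param p,q probability vectors on a shared support (each sums to 1).
#' @return A single number (nats for the divergences).
#' @examples
#' kl_divergence(c(0.5, 0.5), c(0.9, 0.1)) # ~0.511
#' @export
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) abort("`p` and `q` must share a support")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    abort("`p` and `q` must each sum to 1")
  pos <- p > 0
  if (any(q[pos] == 0)) abort("divergence undefined: q = 0 where p > 0")
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' @rdname kl_divergence
#' @param x,y numeric sample vectors (rounded to integer bins).
#' @export
histogram_kl <- function(x, y) {
  x <- round(x); y <- round(y)
  support <- seq(min(x, y), max(x, y))
  cx <- tabulate(factor(x, levels = support), nbins = length(support)) + 0.5
  cy <- tabulate(factor(y, levels = support), nbins = length(support)) + 0.5
  kl_divergence(cx / sum(cx), cy / sum(cy))
}

#' @rdname kl_divergence
#' @param obs,pred observed and predicted numeric vectors.
#' @export
r_squared <- function(obs, pred) {
  if (length(obs) != length(pred)) abort("`obs` and `pred` must have the same length")
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}
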