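#' Stationary weekly ensemble of hourly occupancy samples
#'
#' Simulates `n_realizations` statistically stationary weeks with the
#' Langevin model and records the occupancy on the hour at each of the
#' 168 weekly hours. Each trajectory starts on the periodic mean-field
#' orbit and discards a warm-up transient before recording.
#'
#' @inheritParams simulate_langevin
#' @param warmup_h warm-up length in hours discarded before recording
#'   (default 24, about six relaxation times \eqn{1/\beta}).
#' @return A tibble of class `ed_week_ensemble` with columns
#'   `realization`, `weekly_hour`, `count`.
#' @export
simulate_stationary_week <- function(profile, params, n_realizations = 1e4,
                                     dt = 0.01, seed = NULL, warmup_h = 24) {
  if (!is.null(seed)) set.seed(seed)
  m <- langevin_hourly_matrix(profile, params, n_realizations, dt = dt,
                              warmup_h = warmup_h)
  tibble::new_tibble(
    tibble::tibble(
      realization = rep(seq_len(nrow(m)), times = 168),
      weekly_hour = rep(0:167, each = nrow(m)),
      count = as.numeric(m)
    ),
    class = "ed_week_ensemble"
  )
}

#' Overcrowding tail probability
#'
#' The fraction of hourly occupancy samples strictly exceeding a
#' threshold, with its binomial standard error. Severe and dangerous
#' overcrowding correspond to about 120 and 140 patients. Samples are
#' pooled across the whole week by default; `shifts` restricts to given
#' shift labels (requires a `weekly_hour` column).
#'
#' @param samples a numeric vector of occupancy samples, or a tibble with
#'   a `count` column (e.g. from [simulate_stationary_week()]).
#' @param threshold occupancy threshold in patients.
#' @param shifts optional character vector among `morning`, `afternoon`,
#'   `night`.
#' @return A one-row tibble: `threshold`, `n_samples`, `prob`, `se`.
#' @export
tail_probability <- function(samples, threshold, shifts = NULL) {
  if (is.data.frame(samples)) {
    df <- samples
    if (!is.null(shifts)) {
      if (!"weekly_hour" %in% names(df))
        abort("`shifts` filtering needs a `weekly_hour` column")
      df <- dplyr::filter(df, shift_of(.data$weekly_hour) %in% shifts)
    }
    x <- df$count
  } else {
    if (!is.null(shifts)) abort("`shifts` filtering needs a tibble input")
    x <- as.numeric(samples)
  }
  n <- length(x)
  if (n < 1000)
    warn(sprintf("only %d samples: tail probability will be imprecise", n),
         class = "edcrowd_precision_warning")
  p <- mean(x > threshold)
  tibble::tibble(threshold = threshold, n_samples = n, prob = p,
                 se = sqrt(p * (1 - p) / n))
}

#' The ten most crowded weekly shifts
#'
#' Sunday through Thursday, morning and afternoon.
#' @return A tibble with columns `weekday` (0-4) and `shift`.
#' @export
top10_shifts <- function() {
  tidyr::expand_grid(weekday = 0:4, shift = c("morning", "afternoon"))
}

#' Distribution of relative shift crowding
#'
#' Histogram and empirical CDF of the relative crowding
#' \eqn{x = C_{shift}/\langle C\rangle}, by default restricted to the ten
#' most crowded weekly shifts (Sunday-Thursday morning and afternoon).
#'
#' @param summaries an `ed_shift_summary` with a `relative` column (see
#'   [relative_crowding()]).
#' @param top10 restrict to the ten most crowded weekly shifts.
#' @param binwidth histogram bin width in units of x.
#' @return A list of class `ed_x_distribution`: `histogram` (tibble
#'   `x_mid`, `prob`, summing to 1), `x` (the raw values), and
#'   `tail_prob(delta)` handled by [relative_tail()].
#' @export
patient_hours_distribution <- function(summaries, top10 = TRUE,
                                       binwidth = 0.1) {
  if (!"relative" %in% names(summaries))
    summaries <- relative_crowding(summaries)
  df <- tibble::as_tibble(summaries)
  if (top10) df <- dplyr::semi_join(df, top10_shifts(), by = c("weekday", "shift"))
  if (nrow(df) == 0) abort("no shifts left after filtering")
  x <- df$relative
  breaks <- seq(0, ceiling(max(x) / binwidth) * binwidth + binwidth, by = binwidth)
  h <- hist(x, breaks = breaks, plot = FALSE)
  structure(list(
    histogram = tibble::tibble(x_mid = h$mids, prob = h$counts / sum(h$counts)),
    x = x
  ), class = "ed_x_distribution")
}

#' Relative-overcrowding tail probability
#'
#' \eqn{P(x > 1 + \delta)}: the probability that a shift's patient hours
#' exceed its weekly-shift average by more than `delta`.
#'
#' @param xdist an `ed_x_distribution` from [patient_hours_distribution()],
#'   or a numeric vector of relative crowding values.
#' @param delta numeric vector of relative excesses (default 0.2 and 0.4,
#'   the severe and dangerous relative thresholds).
#' @return A tibble: `delta`, `prob`, `se`, `n_samples`.
#' @export
relative_tail <- function(xdist, delta = c(0.2, 0.4)) {
  x <- if (inherits(xdist, "ed_x_distribution")) xdist$x else as.numeric(xdist)
  purrr::map_dfr(delta, function(d) {
    p <- mean(x > 1 + d)
    tibble::tibble(delta = d, prob = p,
                   se = sqrt(p * (1 - p) / length(x)), n_samples = length(x))
  })
}

apply_knob <- function(profile, params, knob, delta) {
  switch(knob,
    arrival_flux = list(profile = weekly_profile(profile_flux(profile) * (1 + delta)),
                        params = params),
    length_of_stay = {
      los <- 1 / params$beta + delta / 60  # delta in minutes
      if (any(los <= 0)) abort("length-of-stay change drives a day group non-positive")
      list(profile = profile,
           params = ed_params(beta = 1 / los, sigma1 = params$sigma1,
                              sigma2 = params$sigma2))
    },
    sigma2 = list(profile = profile,
                  params = ed_params(beta = params$beta, sigma1 = params$sigma1,
                                     sigma2 = params$sigma2 * (1 + delta)))
  )
}

#' Elasticity of overcrowding to a model parameter
#'
#' Scans one knob — a uniform scaling of the arrival flux, a change of the
#' typical length of stay \eqn{1/\beta} in minutes (applied to all day
#' groups), or a scaling of the systematic noise \eqn{\sigma_2} — and
#' reports the ratio of the overcrowding tail probability
#' \eqn{P(n > n_s)} to its baseline (delta = 0) value. The same seed is
#' reused at every delta (common random numbers), so ratio curves are
#' smooth in the scan variable.
#'
#' @inheritParams simulate_stationary_week
#' @param knob one of `"arrival_flux"` (delta is a fraction, e.g. 0.1 for
#'   +10%), `"length_of_stay"` (delta in minutes added to \eqn{1/\beta}),
#'   `"sigma2"` (delta is a fraction).
#' @param deltas numeric scan grid; must include 0.
#' @param threshold overcrowding threshold \eqn{n_s} (patients); 120 is
#'   the onset of severe overcrowding, 140 dangerous.
#' @return A tibble of class `ed_elasticity`: `delta`, `prob`, `se`,
#'   `ratio`, `ratio_se`, with attributes `knob` and `threshold`.
#' @export
elasticity_scan <- function(profile, params, knob = c("arrival_flux",
                                                      "length_of_stay", "sigma2"),
                            deltas, threshold = 120, n_realizations = 1e4,
                            dt = 0.01, seed = 1) {
  knob <- match.arg(knob)
  if (!any(abs(deltas) < 1e-12)) abort("`deltas` must include 0 (the baseline)")
  rows <- purrr::map_dfr(deltas, function(d) {
    mod <- apply_knob(profile, params, knob, d)
    set.seed(seed)  # common random numbers across deltas
    m <- langevin_hourly_matrix(mod$profile, mod$params, n_realizations, dt = dt)
    x <- as.numeric(m)
    p <- mean(x > threshold)
    tibble::tibble(delta = d, prob = p, se = sqrt(p * (1 - p) / length(x)))
  })
  base <- rows[abs(rows$delta) < 1e-12, ]
  if (base$prob == 0)
    abort("baseline tail probability is 0 in the sample; increase `n_realizations`")
  out <- rows |>
    dplyr::mutate(ratio = .data$prob / base$prob,
                  ratio_se = .data$ratio *
                    sqrt((.data$se / pmax(.data$prob, .Machine$double.xmin))^2 +
                         (base$se / base$prob)^2))
  out$ratio_se[abs(out$delta) < 1e-12] <- 0
  tibble::new_tibble(out, class = "ed_elasticity", knob = knob,
                     threshold = threshold)
}

#' Overcrowding report
#'
#' Absolute-threshold tail probabilities (severe ~120, dangerous ~140
#' patients) from pooled hourly occupancy samples, and, when shift
#' summaries are supplied, relative-overcrowding tails
#' \eqn{P(x > 1 + \delta)}.
#'
#' @param samples hourly occupancy samples (vector or tibble with a
#'   `count` column).
#' @param thresholds named numeric vector of occupancy thresholds.
#' @param summaries optional `ed_shift_summary` for the relative tails.
#' @param delta relative-excess grid for the relative tails.
#' @return A list of class `ed_overcrowding_report`: `tails` (tibble),
#'   `relative_tails` (tibble or NULL), `hours_per_year` convenience
#'   conversion (probability x 8766).
#' @export
overcrowding_report <- function(samples,
                                thresholds = c(severe = 120, dangerous = 140),
                                summaries = NULL, delta = c(0.2, 0.4)) {
  tails <- purrr::imap_dfr(thresholds, function(th, nm) {
    dplyr::mutate(tail_probability(samples, th), level = nm, .before = 1)
  })
  tails$hours_per_year <- tails$prob * 8766
  rel <- if (!is.null(summaries))
    relative_tail(patient_hours_distribution(summaries), delta = delta)
  structure(list(tails = tails, relative_tails = rel),
            class = "ed_overcrowding_report")
}

#' @export
print.ed_overcrowding_report <- function(x, ...) {
  cat("Overcrowding report (pooled hourly samples)\n")
  print(x$tails)
  if (!is.null(x$relative_tails)) {
    cat("Relative overcrowding P(x > 1 + delta):\n")
    print(x$relative_tails)
  }
  invisible(x)
}
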