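#' Weekly arrival profile
#'
#' A deterministic arrival flux \eqn{f(t)} (patients/hour) for each of the
#' 168 hours of the week, anchored at Sunday 07:00 (weekly hour 0).
#'
#' @param flux numeric vector of length 168, all values >= 0.
#' @return A tibble of class `ed_profile` with columns `weekly_hour`
#'   (0-167) and `flux`.
#' @examples
#' weekly_profile(rep(14, 168))
#' @export
weekly_profile <- function(flux) {
  flux <- as.numeric(flux)
  if (length(flux) != 168) abort("`flux` must have exactly 168 hourly values")
  if (anyNA(flux) || any(flux < 0)) abort("all flux values must be non-negative")
  tibble::new_tibble(
    tibble::tibble(weekly_hour = 0:167, flux = flux),
    class = "ed_profile", week_epoch = "Sunday 07:00"
  )
}

profile_flux <- function(profile) {
  if (!is.data.frame(profile) || !all(c("weekly_hour", "flux") %in% names(profile)))
    abort("`profile` must be a weekly profile with columns weekly_hour and flux")
  fl <- profile$flux[order(profile$weekly_hour)]
  if (length(fl) != 168) abort("`profile` must cover all 168 weekly hours")
  fl
}

#' Trapezoid daily arrival shape
#'
#' A day's arrival flux as a trapezoid: a quiet night level, a linear
#' morning ramp, a daytime plateau, and an evening ramp back down.
#' Breakpoints are hour offsets within the 07:00-anchored day, so
#' `ramp_up_start = 1` means the ramp begins at 08:00 local time.
#'
#' @param night_level,day_level flux levels in patients/hour (>= 0).
#' @param ramp_up_start,plateau_start,ramp_down_start,night_start ordered
#'   breakpoints in `[0, 24]` (hours after 07:00).
#' @return An object of class `ed_day_shape`.
#' @examples
#' sh <- trapezoid_shape(night_level = 5, day_level = 24)
#' day_shape_flux(sh)
#' @export
trapezoid_shape <- function(night_level, day_level, ramp_up_start = 1,
                            plateau_start = 4, ramp_down_start = 13,
                            night_start = 18) {
  if (night_level < 0 || day_level < 0) abort("flux levels must be non-negative")
  bp <- c(ramp_up_start, plateau_start, ramp_down_start, night_start)
  if (any(diff(bp) < 0) || bp[1] < 0 || bp[4] > 24)
    abort("breakpoints must be ordered within the 24-hour day")
  structure(list(night_level = night_level, day_level = day_level,
                 ramp_up_start = ramp_up_start, plateau_start = plateau_start,
                 ramp_down_start = ramp_down_start, night_start = night_start),
            class = "ed_day_shape")
}

# trapezoid "day weight" lambda(o) in [0,1]: flux = night + (day-night)*lambda
trapezoid_lambda <- function(shape, o) {
  up <- shape$ramp_up_start; pl <- shape$plateau_start
  dn <- shape$ramp_down_start; ni <- shape$night_start
  lam <- numeric(length(o))
  ramp_up <- o >= up & o < pl
  if (pl > up) lam[ramp_up] <- (o[ramp_up] - up) / (pl - up)
  lam[o >= pl & o < dn] <- 1
  ramp_dn <- o >= dn & o < ni
  if (ni > dn) lam[ramp_dn] <- 1 - (o[ramp_dn] - dn) / (ni - dn)
  lam
}

#' @rdname trapezoid_shape
#' @param shape an `ed_day_shape`.
#' @return `day_shape_flux()`: 24 hourly flux values (each the average of
#'   the trapezoid over its half-open hour bin).
#' @export
day_shape_flux <- function(shape) {
  # average the piecewise-linear shape over each [h, h+1) at minute marks
  fine <- rep(0:23, each = 60) + (rep(0:59, times = 24) + 0.5) / 60
  lam <- trapezoid_lambda(shape, fine)
  lam_h <- colMeans(matrix(lam, nrow = 60))
  shape$night_level + (shape$day_level - shape$night_level) * lam_h
}

#' Build a weekly profile from weekday and weekend day shapes
#'
#' The Israeli workweek runs Sunday-Thursday; Friday and Saturday form the
#' quiet weekend. The weekday shape is used for days 0-4 and the weekend
#' shape for days 5-6.
#'
#' @param weekday_shape,weekend_shape [trapezoid_shape()] objects.
#' @return An [weekly_profile()] object.
#' @examples
#' build_reference_profile(trapezoid_shape(5, 24), trapezoid_shape(4, 18))
#' @export
build_reference_profile <- function(weekday_shape, weekend_shape) {
  wd <- day_shape_flux(weekday_shape)
  we <- day_shape_flux(weekend_shape)
  weekly_profile(c(rep(wd, 5), rep(we, 2)))
}

# population standard deviation (ensemble convention used throughout)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Calibrate a trapezoid weekly profile to flux and occupancy moments
#'
#' Searches the trapezoid family (weekday night/day levels plus a weekend
#' scale factor) for a profile whose 168 hourly flux values match the
#' target mean and STD, and whose induced Langevin occupancy (under
#' `params`) matches the target hourly occupancy mean and STD. The flux
#' moments are matched analytically (the hourly flux is linear in the two
#' levels); the weekend scale is then chosen by simulating a small
#' ensemble per candidate with common random numbers, so the search is
#' deterministic given `seed`.
#'
#' Default targets are the reference ED's moments: hourly arrival flux mean 14,
#' STD 8; hourly occupancy mean 55, STD 27.
#'
#' @param params an [ed_params()] object.
#' @param targets named list with `flux_mean`, `flux_std`, `occ_mean`,
#'   `occ_std`.
#' @param seed integer seed controlling the calibration ensembles.
#' @param n_realizations ensemble size per candidate weekend scale.
#' @param dt Langevin time step (hours).
#' @param weekend_scales candidate weekend/weekday flux ratios.
#' @return An [weekly_profile()] with attribute `calibration`: a list with
#'   the chosen shapes, the weekend scale, and the achieved moments.
#' @export
calibrate_profile <- function(params,
                              targets = list(flux_mean = 14, flux_std = 8,
                                             occ_mean = 55, occ_std = 27),
                              seed = 1, n_realizations = 400, dt = 0.02,
                              weekend_scales = seq(0.45, 1, by = 0.05)) {
  stopifnot(all(c("flux_mean", "flux_std", "occ_mean", "occ_std") %in% names(targets)))
  if (any(unlist(targets) < 0)) abort("targets must be non-negative")
  shape_of <- function(n, d) trapezoid_shape(n, d)

  # flux basis for a given weekend scale r: flux = a*u + b*v with
  # u the night-level basis and v the day-level basis
  basis <- function(r) {
    u_day <- day_shape_flux(shape_of(1, 0))
    v_day <- day_shape_flux(shape_of(0, 1))
    list(u = c(rep(u_day, 5), rep(r * u_day, 2)),
         v = c(rep(v_day, 5), rep(r * v_day, 2)))
  }

  solve_levels <- function(r) {
    bs <- basis(r)
    mu <- mean(bs$u); mv <- mean(bs$v)
    a_of <- function(b) (targets$flux_mean - b * mv) / mu
    g <- function(b) pop_sd(a_of(b) * bs$u + b * bs$v) - targets$flux_std
    b_flat <- targets$flux_mean / (mu + mv)  # minimal-contrast level
    b_max <- targets$flux_mean / mv          # night level zero
    if (g(b_max) < 0) return(NULL)           # STD unreachable with a >= 0
    lo <- if (g(b_flat) <= 0) b_flat else 0
    if (g(lo) > 0) return(NULL)
    b <- stats::uniroot(g, c(lo, b_max), tol = 1e-8)$root
    a <- a_of(b)
    if (a < 0) return(NULL)
    list(a = a, b = b, r = r)
  }

  if (targets$flux_std == 0) {
    # degenerate target: only the flat profile (uniform day shape, no
    # weekend contrast) has zero flux spread
    bs1 <- basis(1)
    b_flat <- targets$flux_mean / (mean(bs1$u) + mean(bs1$v))
    candidates <- list(list(a = b_flat, b = b_flat, r = 1))
  } else {
    candidates <- purrr::compact(purrr::map(weekend_scales, solve_levels))
  }
  if (length(candidates) == 0) {
    abort("calibration failure: flux targets unreachable within the trapezoid family")
  }

  occ_stats_of <- function(cand) {
    prof <- build_reference_profile(shape_of(cand$a, cand$b),
                                    shape_of(cand$r * cand$a, cand$r * cand$b))
    set.seed(seed)  # common random numbers across candidates
    samp <- langevin_hourly_matrix(prof, params, n_realizations, dt = dt)
    c(mean = mean(samp), std = pop_sd(as.numeric(samp)))
  }
  occ <- purrr::map(candidates, occ_stats_of)
  resid <- purrr::map_dbl(occ, ~ abs(.x[["std"]] - targets$occ_std))
  best <- which.min(resid)
  cand <- candidates[[best]]

  wd <- shape_of(cand$a, cand$b)
  we <- shape_of(cand$r * cand$a, cand$r * cand$b)
  prof <- build_reference_profile(wd, we)

  achieved <- list(flux_mean = mean(prof$flux), flux_std = pop_sd(prof$flux),
                   occ_mean = unname(occ[[best]]["mean"]),
                   occ_std = unname(occ[[best]]["std"]))
  ok <- abs(achieved$flux_mean - targets$flux_mean) <= 0.02 * targets$flux_mean &&
    (targets$flux_std == 0 || abs(achieved$flux_std - targets$flux_std) <= 0.10 * targets$flux_std) &&
    abs(achieved$occ_mean - targets$occ_mean) <= 0.03 * targets$occ_mean &&
    (targets$occ_std == 0 || abs(achieved$occ_std - targets$occ_std) <= 0.10 * targets$occ_std)
  if (!ok) {
    abort(paste0("calibration failure: best residuals flux mean ",
                 signif(achieved$flux_mean, 4), ", flux STD ",
                 signif(achieved$flux_std, 4), ", occupancy mean ",
                 signif(achieved$occ_mean, 4), ", occupancy STD ",
                 signif(achieved$occ_std, 4)))
  }
  attr(prof, "calibration") <- list(weekday_shape = wd, weekend_shape = we,
                                    weekend_scale = cand$r, achieved = achieved,
                                    targets = targets, seed = seed)
  prof
}
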