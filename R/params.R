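#' Model parameters: exit rates by day group and noise magnitudes
#'
#' Bundles the four per-day-group exit rates \eqn{\beta} (per hour) with the
#' demographic and systematic noise magnitudes \eqn{\sigma_1, \sigma_2}.
#' The defaults are the fitted values for a large Israeli ED: Sunday 0.224,
#' midweek (Mon-Thu) 0.244, Friday 0.280, Saturday 0.304 per hour,
#' \eqn{\sigma_1 = 1.1}, \eqn{\sigma_2 = 0.36}.
#'
#' @param beta named numeric vector of exit rates per hour with names
#'   `sunday`, `midweek`, `friday`, `saturday`; all must be positive.
#' @param sigma1 demographic noise magnitude (dimensionless, >= 0).
#'   \eqn{\sigma_1 = 1} corresponds to pure Poisson discreteness.
#' @param sigma2 systematic noise magnitude (dimensionless, >= 0).
#' @return An object of class `ed_params`.
#' @examples
#' p <- ed_params()
#' mean_length_of_stay(p) # about 3.9 hours
#' @export
ed_params <- function(beta = c(sunday = 0.224, midweek = 0.244,
                               friday = 0.280, saturday = 0.304),
                      sigma1 = 1.1, sigma2 = 0.36) {
  beta <- beta[day_groups()]
  if (anyNA(beta)) {
    abort("`beta` must be a named vector with names sunday, midweek, friday, saturday")
  }
  if (any(beta <= 0)) abort("all exit rates `beta` must be positive")
  if (length(sigma1) != 1 || is.na(sigma1) || sigma1 < 0) abort("`sigma1` must be a single non-negative number")
  if (length(sigma2) != 1 || is.na(sigma2) || sigma2 < 0) abort("`sigma2` must be a single non-negative number")
  structure(list(beta = beta, sigma1 = sigma1, sigma2 = sigma2),
            class = "ed_params")
}

#' @export
print.ed_params <- function(x, ...) {
  cat("ED model parameters\n")
  cat(sprintf("  beta (1/h): sunday %.3f, midweek %.3f, friday %.3f, saturday %.3f\n",
              x$beta[["sunday"]], x$beta[["midweek"]], x$beta[["friday"]],
              x$beta[["saturday"]]))
  cat(sprintf("  sigma1 %.3g (demographic), sigma2 %.3g (systematic)\n",
              x$sigma1, x$sigma2))
  invisible(x)
}

day_groups <- function() c("sunday", "midweek", "friday", "saturday")

# number of days in each group over one week
day_group_weights <- function() c(sunday = 1, midweek = 4, friday = 1, saturday = 1)

#' Day group, shift and weekly hour conventions
#'
#' The week is anchored at Sunday 07:00 (weekly hour 0). Days run 07:00 to
#' 07:00; day groups are Sunday, midweek (Monday-Thursday), Friday,
#' Saturday. Shifts are morning (07-15), afternoon (15-23) and night
#' (23-07).
#'
#' @param t numeric time in hours since the week epoch (may exceed one
#'   week; extended periodically).
#' @return `weekly_hour()`: the hour within the week in `[0, 168)`.
#'   `day_group_of()`: a character vector of day-group labels.
#'   `shift_of()`: a character vector in `morning`, `afternoon`, `night`.
#'   `weekday_of()`: integer day-of-week index, 0 = Sunday ... 6 = Saturday.
#' @examples
#' weekly_hour(170.5)
#' day_group_of(c(0, 30, 125, 150))
#' shift_of(c(0, 9, 20))
#' @export
weekly_hour <- function(t) t %% 168

#' @rdname weekly_hour
#' @export
day_group_of <- function(t) {
  d <- weekday_of(t)
  dplyr::case_when(d == 0 ~ "sunday",
                   d <= 4 ~ "midweek",
                   d == 5 ~ "friday",
                   TRUE ~ "saturday")
}

#' @rdname weekly_hour
#' @export
weekday_of <- function(t) as.integer(weekly_hour(t) %/% 24)

#' @rdname weekly_hour
#' @export
shift_of <- function(t) {
  o <- weekly_hour(t) %% 24
  dplyr::case_when(o < 8 ~ "morning", o < 16 ~ "afternoon", TRUE ~ "night")
}

# per-weekly-hour beta lookup (length 168), piecewise constant per day group
beta_hourly <- function(params) {
  unname(params$beta[day_group_of(0:167)])
}

#' Day-weighted mean exit rate and derived mean quantities
#'
#' The week has one Sunday, four midweek days, one Friday and one Saturday,
#' so the day-weighted mean exit rate is
#' \eqn{\bar\beta = (\beta_{Sun} + 4\beta_{Mid} + \beta_{Fri} + \beta_{Sat})/7}.
#' The typical length of stay is \eqn{1/\bar\beta}.
#'
#' @param params an [ed_params()] object.
#' @return A single number: `mean_exit_rate()` in 1/hour,
#'   `mean_length_of_stay()` in hours.
#' @examples
#' mean_exit_rate(ed_params())
#' @export
mean_exit_rate <- function(params) {
  w <- day_group_weights()
  sum(params$beta[names(w)] * w) / sum(w)
}

#' @rdname mean_exit_rate
#' @export
mean_length_of_stay <- function(params) 1 / mean_exit_rate(params)

#' Read and write a model configuration file
#'
#' The configuration is a YAML file holding the model parameters, the
#' weekly arrival profile (168 hourly flux values), and simulation settings
#' (`dt`, `horizon_weeks`, `n_realizations`, `seed`).
#'
#' @param path file path.
#' @param params an [ed_params()] object.
#' @param profile an [ed_profile] (see [weekly_profile()]), or `NULL`.
#' @param settings named list of simulation settings.
#' @return `read_ed_config()`: a list with elements `params`, `profile`,
#'   `settings`. `write_ed_config()`: `path`, invisibly.
#' @export
write_ed_config <- function(path, params, profile = NULL, settings = list()) {
  cfg <- list(
    params = list(beta = as.list(params$beta), sigma1 = params$sigma1,
                  sigma2 = params$sigma2),
    profile = if (!is.null(profile)) as.numeric(profile$flux),
    settings = settings
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_ed_config
#' @export
read_ed_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  params <- ed_params(beta = unlist(cfg$params$beta),
                      sigma1 = cfg$params$sigma1, sigma2 = cfg$params$sigma2)
  profile <- if (!is.null(cfg$profile)) weekly_profile(as.numeric(cfg$profile))
  list(params = params, profile = profile, settings = cfg$settings)
}
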