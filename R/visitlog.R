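# Week epoch as wall-clock time: Sunday 2013-01-06 07:00 UTC.
ED_EPOCH <- as.POSIXct("2013-01-06 07:00:00", tz = "UTC")

hours_to_ts <- function(h) ED_EPOCH + round(h * 3600)
ts_to_hours <- function(ts) as.numeric(difftime(ts, ED_EPOCH, units = "hours"))

#' Generate a synthetic ED visit log
#'
#' Simulates individual patient visits over `n_weeks` weeks: arrivals
#' follow a nonhomogeneous Poisson process with the profile's hourly
#' intensity (constant within each hour), and each patient exits with an
#' hourly-updated hazard \eqn{\beta(t)} modulated by two noise channels.
#'
#' Systematic noise: every hour a multiplier \eqn{1 + \epsilon_k},
#' \eqn{\epsilon_k \sim N(0, \sigma_2)} (clamped below at 0), shared by
#' all present patients, scales the exit hazard — the agent-level
#' counterpart of the white systematic noise at 1-hour resolution.
#'
#' Demographic noise beyond Poisson discreteness (\eqn{\sigma_1 > 1}):
#' independent hourly jitters on the arrival intensity (variance
#' \eqn{(\sigma_1^2 - 1)/f}) and on the shared exit hazard (variance
#' \eqn{(\sigma_1^2 - 1)/(\beta n)}) inflate the birth and death
#' fluctuations so that, in the diffusion limit, the demographic variance
#' is \eqn{\sigma_1^2 (f + \beta n)}. Values \eqn{\sigma_1 < 1} are not
#' representable by independent thinning noise and are rejected.
#'
#' Timestamps have minute resolution; departures are forced at least one
#' minute after arrival. Patients still present at the period end are
#' truncated there and flagged in the `truncated` column.
#'
#' @param profile a [weekly_profile()].
#' @param params an [ed_params()] object (`sigma1 >= 1` required here).
#' @param n_weeks number of weeks to simulate (>= 1).
#' @param seed integer seed, or `NULL`.
#' @return A tibble of class `ed_visit_log` with columns `visit_id`,
#'   `arrival_ts`, `departure_ts` (POSIXct, minute resolution) and
#'   `truncated`; attributes `period_start`, `period_end` (POSIXct) and
#'   `meta` (generation settings).
#' @examples
#' prof <- weekly_profile(rep(14, 168))
#' log <- generate_visit_log(prof, ed_params(), n_weeks = 2, seed = 1)
#' @export
generate_visit_log <- function(profile, params, n_weeks, seed = NULL) {
  if (length(n_weeks) != 1 || is.na(n_weeks) || n_weeks < 1)
    abort("`n_weeks` must be >= 1")
  if (params$sigma1 < 1)
    abort("the agent-level generator requires `sigma1` >= 1 (Poisson discreteness already contributes sigma1 = 1)")
  flux <- profile_flux(profile)
  bh <- beta_hourly(params)
  if (!is.null(seed)) set.seed(seed)

  n_hours <- as.integer(168 * n_weeks)
  extra <- params$sigma1^2 - 1
  # per-patient state, grown in blocks
  cap <- as.integer(ceiling(sum(flux) * n_weeks * 1.25) + 1000)
  arr <- numeric(cap); dep <- rep(NA_real_, cap)
  n_pat <- 0L
  active <- integer(0)  # indices of patients currently present

  for (k in seq_len(n_hours) - 1L) {
    wh <- k %% 168L
    f <- flux[wh + 1L]; b <- bh[wh + 1L]
    # arrivals: Poisson with hourly intensity jitter realizing sigma1 > 1
    amult <- if (extra > 0 && f > 0) max(0, 1 + rnorm(1, 0, sqrt(extra / f))) else 1
    n_new <- rpois(1, f * amult)
    if (n_new > 0) {
      if (n_pat + n_new > cap) {
        grow <- max(cap, n_new)
        arr <- c(arr, numeric(grow)); dep <- c(dep, rep(NA_real_, grow))
        cap <- cap + grow
      }
      idx_new <- n_pat + seq_len(n_new)
      arr[idx_new] <- k + sort(runif(n_new))
      n_pat <- n_pat + n_new
      active <- c(active, idx_new)
    }
    if (length(active) == 0) next
    # shared hourly exit-hazard multipliers: systematic + demographic jitter
    m_sys <- if (params$sigma2 > 0) max(0, 1 + rnorm(1, 0, params$sigma2)) else 1
    n_cur <- length(active)
    m_dem <- if (extra > 0 && b * n_cur > 0)
      max(0, 1 + rnorm(1, 0, sqrt(extra / (b * n_cur)))) else 1
    h <- b * m_sys * m_dem
    if (h <= 0) next
    pres_start <- pmax(arr[active], k)   # arrivals mid-hour wait their share
    cand <- pres_start + rexp(n_cur) / h
    gone <- cand < k + 1
    if (any(gone)) {
      dep[active[gone]] <- cand[gone]
      active <- active[!gone]
    }
  }
  truncated <- rep(FALSE, n_pat)
  if (length(active) > 0) {
    dep[active] <- n_hours
    truncated[active] <- TRUE
  }

  arr <- arr[seq_len(n_pat)]; dep <- dep[seq_len(n_pat)]
  # minute resolution, departures strictly after arrivals
  arr_m <- floor(arr * 60)
  dep_m <- pmax(floor(dep * 60), arr_m + 1)
  ord <- order(arr_m)
  log <- tibble::new_tibble(
    tibble::tibble(
      visit_id = sprintf("V%07d", seq_len(n_pat)),
      arrival_ts = ED_EPOCH + arr_m[ord] * 60,
      departure_ts = ED_EPOCH + dep_m[ord] * 60,
      truncated = truncated[ord]
    ),
    class = "ed_visit_log",
    period_start = ED_EPOCH, period_end = hours_to_ts(n_hours),
    meta = list(n_weeks = n_weeks, seed = seed, params = params,
                flux = flux)
  )
  log
}

log_period <- function(log) {
  ps <- attr(log, "period_start"); pe <- attr(log, "period_end")
  if (is.null(ps)) ps <- min(log$arrival_ts)
  if (is.null(pe)) pe <- max(log$departure_ts)
  c(start = ts_to_hours(ps), end = ts_to_hours(pe))
}

#' Read and write visit logs as CSV
#'
#' The CSV has columns `visit_id`, `arrival_ts`, `departure_ts`
#' (ISO-8601, minute precision, UTC) and optionally `truncated`. A YAML
#' sidecar (`<path>.meta.yaml`) records the period bounds and, when
#' written from a generated log, the generation settings.
#'
#' @param log an `ed_visit_log` tibble.
#' @param path CSV file path.
#' @return `write_visit_log()`: `path`, invisibly. `read_visit_log()`: an
#'   `ed_visit_log` tibble.
#' @export
write_visit_log <- function(log, path) {
  out <- dplyr::mutate(
    tibble::as_tibble(log),
    arrival_ts = format(.data$arrival_ts, "%Y-%m-%dT%H:%M", tz = "UTC"),
    departure_ts = format(.data$departure_ts, "%Y-%m-%dT%H:%M", tz = "UTC")
  )
  readr::write_csv(out, path)
  meta <- attr(log, "meta")
  side <- list(
    period_start = format(attr(log, "period_start"), "%Y-%m-%dT%H:%M", tz = "UTC"),
    period_end = format(attr(log, "period_end"), "%Y-%m-%dT%H:%M", tz = "UTC"),
    n_weeks = meta$n_weeks, seed = meta$seed,
    params = if (!is.null(meta$params))
      list(beta = as.list(meta$params$beta), sigma1 = meta$params$sigma1,
           sigma2 = meta$params$sigma2),
    flux = meta$flux
  )
  yaml::write_yaml(side, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_visit_log
#' @export
read_visit_log <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("visit_id", "arrival_ts", "departure_ts") %in% names(df)))
    abort("visit-log CSV must have columns visit_id, arrival_ts, departure_ts")
  parse_ts <- function(x) as.POSIXct(x, tz = "UTC",
                                     tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                                    "%Y-%m-%dT%H:%M",
                                                    "%Y-%m-%d %H:%M:%OS",
                                                    "%Y-%m-%d %H:%M"))
  if (!inherits(df$arrival_ts, "POSIXct")) df$arrival_ts <- parse_ts(df$arrival_ts)
  if (!inherits(df$departure_ts, "POSIXct")) df$departure_ts <- parse_ts(df$departure_ts)
  if (any(df$departure_ts <= df$arrival_ts))
    abort("invalid visit log: departures must be strictly after arrivals")
  if (is.null(df$truncated)) df$truncated <- FALSE
  df <- dplyr::arrange(df, .data$arrival_ts)
  ps <- min(df$arrival_ts); pe <- max(df$departure_ts)
  meta_path <- paste0(path, ".meta.yaml")
  meta <- NULL
  if (file.exists(meta_path)) {
    side <- yaml::read_yaml(meta_path)
    if (!is.null(side$period_start)) ps <- parse_ts(side$period_start)
    if (!is.null(side$period_end)) pe <- parse_ts(side$period_end)
    meta <- side
  }
  tibble::new_tibble(df, class = "ed_visit_log",
                     period_start = ps, period_end = pe, meta = meta)
}
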