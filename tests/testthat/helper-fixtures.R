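# Shared fixtures, all built in code.

flat_profile <- function(f = 14) weekly_profile(rep(f, 168))

const_params <- function(beta = 0.25, sigma1 = 1, sigma2 = 0) {
  ed_params(beta = c(sunday = beta, midweek = beta, friday = beta,
                     saturday = beta),
            sigma1 = sigma1, sigma2 = sigma2)
}

table1_params <- function(sigma1 = 1.1, sigma2 = 0.36) {
  ed_params(sigma1 = sigma1, sigma2 = sigma2)
}

# hand-built visit log from arrival/departure times in hours since epoch
make_log <- function(arr_h, dep_h, period = NULL) {
  epoch <- edcrowd:::ED_EPOCH
  if (is.null(period)) period <- c(0, 168 * ceiling(max(dep_h) / 168))
  ord <- order(arr_h)
  tibble::new_tibble(
    tibble::tibble(
      visit_id = sprintf("V%04d", seq_along(arr_h)),
      arrival_ts = epoch + round(arr_h[ord] * 3600),
      departure_ts = epoch + round(dep_h[ord] * 3600),
      truncated = FALSE
    ),
    class = "ed_visit_log",
    period_start = epoch + period[1] * 3600,
    period_end = epoch + period[2] * 3600
  )
}

# calibrated reference profile, computed once per test run
calibrated_profile <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibrate_profile(table1_params(), seed = 11)
    cache
  }
})
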