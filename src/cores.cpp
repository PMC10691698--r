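#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Hour index into a 168-value weekly table for time t (hours since the
// week epoch, Sunday 07:00). Periodic extension beyond one week.
static inline int week_idx(double t) {
  int h = (int)std::floor(t);
  h %= 168;
  if (h < 0) h += 168;
  return h;
}

//' @noRd
// [[Rcpp::export(name = ".langevin_core")]]
NumericMatrix langevin_core(NumericVector flux, NumericVector beta_hourly,
                            double n0, double dt, int n_steps,
                            double sigma1, double sigma2, int n_real,
                            IntegerVector keep_steps) {
  if (flux.size() != 168 || beta_hourly.size() != 168)
    stop("flux and beta_hourly must have length 168");
  const int n_keep = keep_steps.size();
  NumericMatrix out(n_real, n_keep);
  const double sdt = std::sqrt(dt);

  // precompute per-step rate lookups (piecewise constant per hour)
  std::vector<double> f_step(n_steps), b_step(n_steps);
  for (int k = 0; k < n_steps; ++k) {
    int idx = week_idx(k * dt);
    f_step[k] = flux[idx];
    b_step[k] = beta_hourly[idx];
  }

  for (int r = 0; r < n_real; ++r) {
    double n = n0;
    int ki = 0;
    // record step 0 if requested
    while (ki < n_keep && keep_steps[ki] == 0) { out(r, ki) = n; ++ki; }
    for (int k = 0; k < n_steps; ++k) {
      const double f = f_step[k], b = b_step[k];
      const double drift = f - b * n;
      double diff2 = f + b * n;          // demographic diffusion, clamped
      if (diff2 < 0.0) diff2 = 0.0;
      const double z1 = norm_rand(), z2 = norm_rand();
      n += drift * dt + sigma1 * std::sqrt(diff2) * sdt * z1
                      - sigma2 * b * n * sdt * z2;
      if (n < 0.0) n = -n;               // reflect at the origin
      while (ki < n_keep && keep_steps[ki] == k + 1) { out(r, ki) = n; ++ki; }
    }
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".gillespie_sample")]]
NumericVector gillespie_sample(NumericVector flux, NumericVector beta_hourly,
                               double n0, double horizon,
                               NumericVector sample_times) {
  if (flux.size() != 168 || beta_hourly.size() != 168)
    stop("flux and beta_hourly must have length 168");
  const int n_s = sample_times.size();
  NumericVector out(n_s);
  double t = 0.0, n = n0;
  int si = 0;
  while (si < n_s && sample_times[si] <= t) { out[si] = n; ++si; }
  while (t < horizon && si < n_s) {
    const int idx = week_idx(t);
    const double f = flux[idx], b = beta_hourly[idx];
    const double rate = f + b * n;
    const double bound = std::floor(t) + 1.0;  // rates constant inside the hour
    double t_next;
    if (rate <= 0.0) {
      t_next = bound;
    } else {
      const double wait = exp_rand() / rate;
      t_next = t + wait;
      if (t_next >= bound) t_next = bound;
      else {
        // record samples passed over before the jump
        while (si < n_s && sample_times[si] <= t_next) { out[si] = n; ++si; }
        if (unif_rand() * rate < f) n += 1.0; else n -= 1.0;
        t = t_next;
        continue;
      }
    }
    while (si < n_s && sample_times[si] <= t_next) { out[si] = n; ++si; }
    t = t_next;
  }
  while (si < n_s) { out[si] = n; ++si; }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".gillespie_events")]]
List gillespie_events(NumericVector flux, NumericVector beta_hourly,
                      double n0, double horizon, int max_events) {
  if (flux.size() != 168 || beta_hourly.size() != 168)
    stop("flux and beta_hourly must have length 168");
  std::vector<double> times;
  std::vector<double> counts;
  times.reserve(1024); counts.reserve(1024);
  double t = 0.0, n = n0;
  times.push_back(t); counts.push_back(n);
  int ev = 0;
  while (t < horizon) {
    const int idx = week_idx(t);
    const double f = flux[idx], b = beta_hourly[idx];
    const double rate = f + b * n;
    const double bound = std::floor(t) + 1.0;
    if (rate <= 0.0) { t = bound; continue; }
    const double wait = exp_rand() / rate;
    if (t + wait >= bound) { t = bound; continue; }
    t += wait;
    if (t >= horizon) break;
    if (unif_rand() * rate < f) n += 1.0; else n -= 1.0;
    times.push_back(t); counts.push_back(n);
    if (++ev >= max_events)
      stop("event budget exceeded (%d events); shorten the horizon", max_events);
  }
  return List::create(_["time_h"] = wrap(times), _["count"] = wrap(counts));
}
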