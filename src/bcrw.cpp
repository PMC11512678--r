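#include <Rcpp.h>
using namespace Rcpp;

// Von Mises sampler, Best & Fisher (1979) wrapped-Cauchy envelope.
// Uses R's RNG so results are governed by set.seed().
static double rvonmises1(double mu, double kappa) {
  if (kappa < 1e-7) {
    return mu + (unif_rand() * 2.0 - 1.0) * M_PI;
  }
  double a = 1.0 + std::sqrt(1.0 + 4.0 * kappa * kappa);
  double b = (a - std::sqrt(2.0 * a)) / (2.0 * kappa);
  double r = (1.0 + b * b) / (2.0 * b);
  double f = 0.0;
  for (;;) {
    double u1 = unif_rand();
    double z = std::cos(M_PI * u1);
    f = (1.0 + r * z) / (r + z);
    double c = kappa * (r - f);
    double u2 = unif_rand();
    if (c * (2.0 - c) - u2 > 0.0) break;
    if (std::log(c / u2) + 1.0 - c >= 0.0) break;
  }
  double u3 = unif_rand();
  double theta = (u3 > 0.5 ? 1.0 : -1.0) * std::acos(f) + mu;
  // wrap to [-pi, pi)
  theta -= 2.0 * M_PI * std::floor((theta + M_PI) / (2.0 * M_PI));
  return theta;
}

// [[Rcpp::export]]
NumericVector rvonmises_cpp(int n, double mu, double kappa) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rvonmises1(mu, kappa);
  return out;
}

// Biased correlated random walk in a local planar frame (meters, origin at
// the release point; x east, y north). Each second the heading is drawn
// from a von Mises centred on the circular mixture of the previous heading
// (weight 1 - w) and the current bearing toward home offset by a
// site-specific deflection (weight w). During the escape phase w = 0.
// Stop episodes emit near-zero speeds in place. Reported positions carry
// Gaussian GPS noise; reported speed is the true step speed in km/h.
//
// home_x/home_y: home loft in the local frame. Returns a matrix with
// columns x, y (noisy, meters) and speed_kmh, one row per 1 Hz fix.
// [[Rcpp::export]]
NumericMatrix bcrw_simulate_cpp(double w, double kappa,
                                double speed_mean_kmh, double speed_sd_kmh,
                                double home_x, double home_y,
                                double bias_offset_rad,
                                double stop_rate_per_min,
                                double stop_mean_s,
                                int escape_s,
                                double gps_noise_sd,
                                double exit_distance_m,
                                int max_steps) {
  std::vector<double> xs, ys, vs;
  xs.reserve(1024); ys.reserve(1024); vs.reserve(1024);
  double x = 0.0, y = 0.0;
  double heading = unif_rand() * 2.0 * M_PI - M_PI;
  double p_stop = stop_rate_per_min / 60.0;
  int stop_left = 0;
  for (int t = 0; t < max_steps; ++t) {
    double v_kmh;
    if (stop_left > 0) {
      --stop_left;
      v_kmh = unif_rand() * 3.0;  // near-stationary, under the 5 km/h cut
    } else {
      if (t >= escape_s && unif_rand() < p_stop && stop_mean_s > 0) {
        stop_left = 1 + (int)(R::rgeom(1.0 / stop_mean_s));
        v_kmh = unif_rand() * 3.0;
      } else {
        v_kmh = R::rnorm(speed_mean_kmh, speed_sd_kmh);
        if (v_kmh < 6.0) v_kmh = 6.0;  // keep flight above the stop cut
      }
    }
    double w_eff = (t < escape_s) ? 0.0 : w;
    double goal = std::atan2(home_x - x, home_y - y) + bias_offset_rad;
    double mx = w_eff * std::sin(goal) + (1.0 - w_eff) * std::sin(heading);
    double my = w_eff * std::cos(goal) + (1.0 - w_eff) * std::cos(heading);
    double target = std::atan2(mx, my);
    heading = rvonmises1(target, kappa);
    double step = v_kmh / 3.6;  // m per 1 s tick
    if (stop_left > 0) step = v_kmh / 3.6 * 0.2;  // shuffling on the spot
    x += step * std::sin(heading);
    y += step * std::cos(heading);
    xs.push_back(x + R::rnorm(0.0, gps_noise_sd));
    ys.push_back(y + R::rnorm(0.0, gps_noise_sd));
    vs.push_back(v_kmh);
    if (std::sqrt(x * x + y * y) >= exit_distance_m) break;
  }
  int n = (int)xs.size();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = xs[i];
    out(i, 1) = ys[i];
    out(i, 2) = vs[i];
  }
  colnames(out) = CharacterVector::create("x", "y", "speed_kmh");
  return out;
}
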