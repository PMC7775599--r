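#include <Rcpp.h>
using namespace Rcpp;

// Position integrator for the synthetic swimming model.
//
// All randomness is drawn in R and passed in, so the kernel is a pure
// deterministic function of its inputs. Step i (i >= 1) moves the larva by
// step_len[i] mm. Moving steps mix, with weight kappa, a wall-tangential
// direction (sign held fixed, jittered by tang_noise) with an isotropic
// direction; a moving step proposed beyond r_max is reflected radially
// (r -> 2*r_max - r). Quiescent (non-moving) jitter steps that would leave
// the well are simply not taken, so sub-threshold jitter can never produce
// a supra-threshold reflected displacement.
//
// [[Rcpp::export]]
List walk_positions_cpp(int n, double x0, double y0,
                        NumericVector step_len, LogicalVector moving,
                        NumericVector u_mix, NumericVector angle_iso,
                        NumericVector tang_noise, double kappa,
                        double r_max, double tang_sign) {
  NumericVector x(n), y(n);
  double cx = x0, cy = y0;
  x[0] = cx; y[0] = cy;
  for (int i = 1; i < n; ++i) {
    double L = step_len[i];
    double theta;
    bool mov = moving[i];
    double r = std::sqrt(cx * cx + cy * cy);
    if (mov && u_mix[i] < kappa && r > 0.05) {
      theta = std::atan2(cy, cx) + tang_sign * M_PI_2 + tang_noise[i];
    } else {
      theta = angle_iso[i];
    }
    double px = cx + L * std::cos(theta);
    double py = cy + L * std::sin(theta);
    double rn = std::sqrt(px * px + py * py);
    if (rn > r_max) {
      if (mov) {
        double scale = (2.0 * r_max - rn) / rn;
        if (scale < 0.0) scale = 0.0;  // pathological overshoot: pin to center
        px *= scale; py *= scale;
      } else {
        px = cx; py = cy;              // jitter step rejected at the wall
      }
    }
    cx = px; cy = py;
    x[i] = cx; y[i] = cy;
  }
  return List::create(_["x"] = x, _["y"] = y);
}
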