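#include <Rcpp.h>
using namespace Rcpp;

// Truncated-normal axis angle on (-pi/2, pi/2) via inverse-CDF, so the number
// of RNG draws per rescue is fixed (one) and runs are reproducible.
static inline double sample_theta(double spread) {
  if (spread <= 0.0) return 0.0;
  double lo = R::pnorm(-M_PI_2, 0.0, spread, 1, 0);
  double hi = R::pnorm(M_PI_2, 0.0, spread, 1, 0);
  double u = lo + unif_rand() * (hi - lo);
  return R::qnorm(u, 0.0, spread, 1, 0);
}

// Monte-Carlo time integration of the nucleus-centering model.
//
// Each step: (1) contact flags and per-filament pushing forces (polymerization
// force capped by Euler buckling with the frozen-at-contact reference length),
// (2) filament growth/shrinkage and catastrophe bookkeeping, (3) forward-Euler
// update of the nucleus position and rotation with series-combined drag
// (Stokes sphere + anisotropic slender-body drag of the longest filament per
// anchor). Uses R's RNG stream; the caller seeds it.
// [[Rcpp::export(name = ".centering_core")]]
List centering_core(List cfg, List init) {
  const double L = cfg["half_length"], Rh = cfg["half_width"];
  const double rnuc = cfg["nucleus_radius"], rmt = cfg["mt_radius"];
  const double eta = cfg["viscosity"];
  const double vg = cfg["v_grow"], vc = cfg["v_contact"], vs = cfg["v_shrink"];
  const double fs = cfg["stall_force"], kappa = cfg["flexural_rigidity"];
  const double Ncat = cfg["shape"], Tcat = cfg["timescale"],
               tau0 = cfg["tau0"];
  const double dt = cfg["dt"], duration = cfg["duration"];
  const double theta_spread = cfg["theta_spread"];
  const bool correlated = cfg["correlated"];
  const int cat_mode = cfg["cat_mode"]; // 0 = clock, 1 = hazard
  const int record_every = cfg["record_every"];

  NumericVector psi = clone(as<NumericVector>(init["psi"]));
  NumericVector theta = clone(as<NumericVector>(init["theta"]));
  NumericVector len = clone(as<NumericVector>(init["length"]));
  IntegerVector phase = clone(as<IntegerVector>(init["phase"])); // 0 grow 1 shrink
  NumericVector tau = clone(as<NumericVector>(init["drawn_tau"]));
  NumericVector clock = clone(as<NumericVector>(init["cat_clock"]));
  NumericVector lio = clone(as<NumericVector>(init["buckling_ref"]));
  IntegerVector side = as<IntegerVector>(init["side"]);   // +1 right, -1 left
  IntegerVector anchor = as<IntegerVector>(init["anchor"]); // 1-based anchor id
  IntegerVector pair = as<IntegerVector>(init["pair"]);   // 0-based partner, -1 none
  double x = as<double>(init["x"]), y = as<double>(init["y"]);
  double om = as<double>(init["omega"]);

  const int n = psi.size();
  int n_anchor = 0;
  for (int i = 0; i < n; ++i) if (anchor[i] > n_anchor) n_anchor = anchor[i];

  const double znt = 6.0 * M_PI * eta * rnuc;           // nucleus translation
  const double znr = 8.0 * M_PI * eta * rnuc * rnuc * rnuc; // nucleus rotation
  const double kpi2 = kappa * M_PI * M_PI;
  const double fp = fs * (1.0 - vc / vg);
  const double v_ratio = vc / vg;
  const double mean_free = Ncat * Tcat;
  const double hazard_load =
      std::max(1.0, mean_free /
                        (tau0 + (std::max(mean_free, tau0) - tau0) * v_ratio));
  const double xmax = L - rnuc;
  const double ymax = (Rh > rnuc) ? (Rh - rnuc) : 0.0;

  const long nsteps = (long)std::floor(duration / dt + 0.5);
  const long nrec = nsteps / record_every + 1;
  NumericVector rt(nrec), rx(nrec), ry(nrec), rom(nrec), rsx(nrec), rsy(nrec);
  long irec = 0;
  long clamp_events = 0;

  std::vector<double> best_len(n_anchor), best_th(n_anchor);
  std::vector<char> contact(n);

  // record t = 0
  rt[irec] = 0.0; rx[irec] = x; ry[irec] = y; rom[irec] = om;
  rsx[irec] = x + rnuc * std::cos(om); rsy[irec] = y + rnuc * std::sin(om);
  ++irec;

  for (long s = 1; s <= nsteps; ++s) {
    // --- forces from current configuration -------------------------------
    double Fx = 0.0, Fy = 0.0, Tz = 0.0;
    for (int i = 0; i < n; ++i) {
      contact[i] = 0;
      if (phase[i] != 0 || len[i] <= 0.0) continue;
      const double a = om + psi[i];
      const double ax = x + rnuc * std::cos(a);
      const double ay = y + rnuc * std::sin(a);
      const double dx = side[i] * std::cos(theta[i]);
      const double dy = std::sin(theta[i]);
      const double tipx = ax + len[i] * dx;
      bool hit = (side[i] > 0) ? (tipx >= L) : (tipx <= -L);
      if (!hit) continue;
      contact[i] = 1;
      if (!R_finite(lio[i])) {
        double reach = (side[i] > 0) ? (L - ax) / dx : (-L - ax) / dx;
        lio[i] = std::max(reach, 1e-6);
      }
      double fe = std::max(kpi2 / (len[i] * len[i]),
                           kpi2 / (lio[i] * lio[i]));
      double f = std::min(fp, fe);
      const double fxi = -f * dx, fyi = -f * dy;
      Fx += fxi; Fy += fyi;
      Tz += (ax - x) * fyi - (ay - y) * fxi;
    }

    // --- drag: longest filament per anchor --------------------------------
    for (int k = 0; k < n_anchor; ++k) best_len[k] = 0.0;
    for (int i = 0; i < n; ++i) {
      const int k = anchor[i] - 1;
      if (len[i] > best_len[k]) { best_len[k] = len[i]; best_th[k] = theta[i]; }
    }
    double zpar = 0.0, zperp = 0.0;
    for (int k = 0; k < n_anchor; ++k) {
      if (best_len[k] <= 0.0) continue;
      const double pc = best_len[k] * std::fabs(std::cos(best_th[k]));
      const double ps = best_len[k] * std::fabs(std::sin(best_th[k]));
      if (pc > 0.0) {
        const double d = std::log(pc / (2.0 * rmt)) - 0.2;
        if (d > 0.0) zpar += 2.0 * M_PI * eta * pc / d;
      }
      if (ps > 0.0) {
        const double d = std::log(ps / (2.0 * rmt)) + 0.84;
        if (d > 0.0) zperp += 4.0 * M_PI * eta * ps / d;
      }
    }
    const double zx = (zpar > 0.0) ? 1.0 / (1.0 / znt + 1.0 / zpar) : znt;
    const double zy = (zperp > 0.0) ? 1.0 / (1.0 / znt + 1.0 / zperp) : znt;

    // --- nucleus forward Euler -------------------------------------------
    x += Fx / zx * dt;
    y += Fy / zy * dt;
    om += Tz / znr * dt;
    // x clamp is a numerical guard (counted; zero in healthy runs); the y
    // clamp is the transverse confinement by the side walls (not an error).
    if (x > xmax) { x = xmax; ++clamp_events; }
    if (x < -xmax) { x = -xmax; ++clamp_events; }
    if (y > ymax) y = ymax;
    if (y < -ymax) y = -ymax;

    // --- filament update --------------------------------------------------
    for (int i = 0; i < n; ++i) {
      if (phase[i] == 0) {
        if (contact[i]) {
          len[i] += vc * dt;
          if (cat_mode == 0) {
            double resc = tau0 + (std::max(tau[i], tau0) - tau0) * v_ratio;
            double rate = std::max(1.0, tau[i] / resc);
            clock[i] += rate * dt;
            if (clock[i] >= tau[i]) phase[i] = 1;
          } else {
            double age = clock[i];
            clock[i] += dt;
            double log_s = R::pgamma(age, Ncat, Tcat, 0, 1);
            double log_p = R::dgamma(age, Ncat, Tcat, 1);
            double pe = -std::expm1(-hazard_load * dt *
                                    std::exp(log_p - log_s));
            if (unif_rand() < pe) phase[i] = 1;
          }
        } else {
          len[i] += vg * dt;
          if (cat_mode == 0) {
            clock[i] += dt;
            if (clock[i] >= tau[i]) phase[i] = 1;
          } else {
            double age = clock[i];
            clock[i] += dt;
            double log_s = R::pgamma(age, Ncat, Tcat, 0, 1);
            double log_p = R::dgamma(age, Ncat, Tcat, 1);
            double pe = -std::expm1(-dt * std::exp(log_p - log_s));
            if (unif_rand() < pe) phase[i] = 1;
          }
        }
      } else {
        len[i] -= vs * dt;
        if (len[i] <= 0.0) { // instantaneous rescue at zero length
          len[i] = 0.0;
          phase[i] = 0;
          clock[i] = 0.0;
          lio[i] = NA_REAL;
          if (correlated && side[i] < 0 && pair[i] >= 0) {
            theta[i] = theta[pair[i]];
            tau[i] = tau[pair[i]];
          } else {
            theta[i] = sample_theta(theta_spread);
            tau[i] = R::rgamma(Ncat, Tcat);
          }
        }
      }
    }

    if (!R_finite(x) || !R_finite(y) || !R_finite(om))
      stop("non-finite nucleus state at step %ld", s);

    if (s % record_every == 0) {
      rt[irec] = s * dt; rx[irec] = x; ry[irec] = y; rom[irec] = om;
      rsx[irec] = x + rnuc * std::cos(om);
      rsy[irec] = y + rnuc * std::sin(om);
      ++irec;
    }
  }

  return List::create(
      _["time"] = rt, _["x"] = rx, _["y"] = ry, _["omega"] = rom,
      _["spb_x"] = rsx, _["spb_y"] = rsy,
      _["clamp_events"] = (double)clamp_events,
      _["final"] = List::create(
          _["psi"] = psi, _["theta"] = theta, _["length"] = len,
          _["phase"] = phase, _["drawn_tau"] = tau, _["cat_clock"] = clock,
          _["buckling_ref"] = lio, _["side"] = side, _["anchor"] = anchor,
          _["pair"] = pair, _["x"] = x, _["y"] = y, _["omega"] = om));
}

// Catastrophe ages of an ensemble of independent filaments stepped to their
// first catastrophe, either by the drawn-time clock or by the age-dependent
// hazard. `in_contact` applies the force-dependent clock acceleration
// throughout (permanent-contact ensemble).
// [[Rcpp::export(name = ".catastrophe_age_sample")]]
NumericVector catastrophe_age_sample(int n, double dt, double shape,
                                     double timescale, double tau0,
                                     double v_ratio, bool in_contact,
                                     int cat_mode) {
  NumericVector out(n);
  const double mean_free = shape * timescale;
  const double hazard_load =
      in_contact ? std::max(1.0, mean_free /
                                     (tau0 + (std::max(mean_free, tau0) - tau0) *
                                                 v_ratio))
                 : 1.0;
  for (int i = 0; i < n; ++i) {
    if (cat_mode == 0) {
      double tau = R::rgamma(shape, timescale);
      double rate = 1.0;
      if (in_contact) {
        double resc = tau0 + (std::max(tau, tau0) - tau0) * v_ratio;
        rate = std::max(1.0, tau / resc);
      }
      double clock = 0.0, t = 0.0;
      while (clock < tau) { clock += rate * dt; t += dt; }
      out[i] = t;
    } else {
      double age = 0.0;
      for (;;) {
        double log_s = R::pgamma(age, shape, timescale, 0, 1);
        double log_p = R::dgamma(age, shape, timescale, 1);
        double pe = -std::expm1(-hazard_load * dt * std::exp(log_p - log_s));
        age += dt;
        if (unif_rand() < pe) break;
      }
      out[i] = age;
    }
  }
  return out;
}
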