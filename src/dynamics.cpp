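#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Genotype order everywhere: 00, 0D, DD, 0B, DB, BB.  Allele order: 0, D, B.
// Index map: 0 = 00, 1 = 0D, 2 = DD, 3 = 0B, 4 = DB, 5 = BB.

// Per-genotype gamete allele distribution.  Germline conversion biases the
// gametes of 0D and DB heterozygotes; zygote conversion leaves gametes
// Mendelian (the conversion is applied to newly formed zygotes instead).
static void gamete_rows(bool zygote_timing, double cD, double cB,
                        double G[6][3]) {
  for (int g = 0; g < 6; ++g)
    for (int a = 0; a < 3; ++a) G[g][a] = 0.0;
  G[0][0] = 1.0;                                     // 00
  if (zygote_timing) { G[1][0] = 0.5; G[1][1] = 0.5; }
  else { G[1][0] = 0.5 * (1.0 - cD); G[1][1] = 0.5 * (1.0 + cD); }
  G[2][1] = 1.0;                                     // DD
  G[3][0] = 0.5; G[3][2] = 0.5;                      // 0B: brake spares WT
  if (zygote_timing) { G[4][1] = 0.5; G[4][2] = 0.5; }
  else { G[4][1] = 0.5 * (1.0 - cB); G[4][2] = 0.5 * (1.0 + cB); }
  G[5][2] = 1.0;                                     // BB
  (void)cB;
}

// V_g: production of genotype-g zygotes by random union of fecundity-weighted
// gametes.  x_a = sum_g beta_g (n_g/N) gamma_g(a); V_aa = x_a^2,
// V_ab = 2 x_a x_b.  Under zygote-timing conversion, converted heterozygous
// zygotes are transferred to the corresponding homozygote class.
static void zygote_V(const double *n, double N, const double *beta,
                     bool zygote_timing, double cD, double cB, double *V) {
  double G[6][3];
  gamete_rows(zygote_timing, cD, cB, G);
  double x[3] = {0.0, 0.0, 0.0};
  for (int g = 0; g < 6; ++g) {
    if (n[g] == 0.0) continue;
    double w = beta[g] * n[g] / N;
    for (int a = 0; a < 3; ++a) x[a] += w * G[g][a];
  }
  V[0] = x[0] * x[0];
  V[1] = 2.0 * x[0] * x[1];
  V[2] = x[1] * x[1];
  V[3] = 2.0 * x[0] * x[2];
  V[4] = 2.0 * x[1] * x[2];
  V[5] = x[2] * x[2];
  if (zygote_timing) {
    V[2] += cD * V[1]; V[1] *= (1.0 - cD);
    V[5] += cB * V[4]; V[4] *= (1.0 - cB);
  }
}

static void density_rhs(const double *n, const double *omega, const double *d,
                        const double *beta, bool zygote_timing, double cD,
                        double cB, double K, double *dn) {
  double N = 0.0;
  for (int g = 0; g < 6; ++g) N += n[g];
  if (N <= 0.0) {
    for (int g = 0; g < 6; ++g) dn[g] = 0.0;
    return;
  }
  double V[6];
  zygote_V(n, N, beta, zygote_timing, cD, cB, V);
  double growth = N * std::max(0.0, 1.0 - N / K);  // births clamped when N >= K
  for (int g = 0; g < 6; ++g) dn[g] = omega[g] * V[g] * growth - d[g] * n[g];
}

static inline double drive_freq(const double *n, double N) {
  return (n[2] + 0.5 * n[1] + 0.5 * n[4]) / N;
}

// [[Rcpp::export]]
NumericVector density_rhs_cpp(NumericVector n, NumericVector omega,
                              NumericVector d, NumericVector beta,
                              bool zygote_timing, double cD, double cB,
                              double K) {
  NumericVector out(6);
  density_rhs(REAL(n), REAL(omega), REAL(d), REAL(beta), zygote_timing, cD,
              cB, K, REAL(out));
  return out;
}

// Explicit Euler with fixed step dt.  After each step any genotype density
// below thr is set to zero (critical extinction density).  The brake release
// fires once, at the first step boundary (including t = 0) where the drive
// allele frequency reaches fI, adding N0B wild-type/brake heterozygotes.
// [[Rcpp::export]]
List euler_integrate_cpp(NumericVector init, NumericVector omega,
                         NumericVector d, NumericVector beta,
                         bool zygote_timing, double cD, double cB, double K,
                         double dt, double thr, double tmax,
                         bool brake_enabled, double fI, double N0B,
                         int record_every) {
  double n[6], dn[6];
  for (int g = 0; g < 6; ++g) n[g] = init[g];
  const double *om = REAL(omega), *dd = REAL(d), *bb = REAL(beta);

  long nsteps = (long)std::ceil(tmax / dt - 1e-9);
  if (record_every < 1) record_every = 1;
  long nrec_max = nsteps / record_every + 3;
  NumericVector rec_t(nrec_max);
  NumericMatrix rec_n(nrec_max, 6);
  NumericVector first_zero(6, NA_REAL);
  long irec = 0;
  bool fired = false;
  double brake_time = NA_REAL;
  double t = 0.0;
  std::string reason = "tmax";

  double N = 0.0;
  for (int g = 0; g < 6; ++g) N += n[g];
  // trigger check at t = 0
  if (brake_enabled && !fired && N > 0.0 && drive_freq(n, N) >= fI) {
    n[3] += N0B;
    fired = true;
    brake_time = 0.0;
    N += N0B;
  }
  rec_t[irec] = 0.0;
  for (int g = 0; g < 6; ++g) rec_n(irec, g) = n[g];
  ++irec;

  for (long step = 1; step <= nsteps; ++step) {
    density_rhs(n, om, dd, bb, zygote_timing, cD, cB, K, dn);
    bool bad = false;
    for (int g = 0; g < 6; ++g) {
      n[g] += dt * dn[g];
      if (n[g] < 0.0) n[g] = 0.0;  // Euler overshoot guard
      if (!R_finite(n[g])) bad = true;
    }
    t = step * dt;
    if (bad) {
      reason = "nonfinite";
      break;
    }
    if (thr > 0.0) {
      for (int g = 0; g < 6; ++g)
        if (n[g] > 0.0 && n[g] < thr) n[g] = 0.0;
    }
    N = 0.0;
    for (int g = 0; g < 6; ++g) {
      N += n[g];
      if (n[g] == 0.0 && ISNA(first_zero[g])) first_zero[g] = t;
    }
    if (brake_enabled && !fired && N > 0.0 && drive_freq(n, N) >= fI) {
      n[3] += N0B;
      fired = true;
      brake_time = t;
      N += N0B;
      if (!ISNA(first_zero[3])) first_zero[3] = NA_REAL;
    }
    bool last = (step == nsteps) || (N == 0.0);
    if (step % record_every == 0 || last) {
      rec_t[irec] = t;
      for (int g = 0; g < 6; ++g) rec_n(irec, g) = n[g];
      ++irec;
    }
    if (N == 0.0) {
      reason = "extinct";
      break;
    }
  }
  if (reason == "nonfinite") {
    // record the last finite state time for diagnostics
    rec_t[irec - 1] = rec_t[irec - 1];
  }

  NumericVector out_t(irec);
  NumericMatrix out_n(irec, 6);
  for (long i = 0; i < irec; ++i) {
    out_t[i] = rec_t[i];
    for (int g = 0; g < 6; ++g) out_n(i, g) = rec_n(i, g);
  }
  NumericVector fin(6);
  for (int g = 0; g < 6; ++g) fin[g] = n[g];
  return List::create(_["t"] = out_t, _["states"] = out_n,
                      _["final"] = fin, _["t_end"] = t,
                      _["brake_fired"] = fired, _["brake_time"] = brake_time,
                      _["first_zero"] = first_zero, _["reason"] = reason);
}

static double total_propensity(const double *n, double N, const double *omega,
                               const double *d, const double *beta,
                               bool zygote_timing, double cD, double cB,
                               double K, double *prop) {
  // prop[0..5]: births per genotype; prop[6..11]: deaths per genotype
  double V[6];
  zygote_V(n, N, beta, zygote_timing, cD, cB, V);
  double growth = N * std::max(0.0, 1.0 - N / K);
  double tot = 0.0;
  for (int g = 0; g < 6; ++g) {
    prop[g] = omega[g] * V[g] * growth;
    prop[6 + g] = d[g] * n[g];
    tot += prop[g] + prop[6 + g];
  }
  return tot;
}

// [[Rcpp::export]]
NumericVector ssa_propensities_cpp(NumericVector counts, NumericVector omega,
                                   NumericVector d, NumericVector beta,
                                   bool zygote_timing, double cD, double cB,
                                   double K) {
  double n[6], prop[12];
  double N = 0.0;
  for (int g = 0; g < 6; ++g) { n[g] = counts[g]; N += n[g]; }
  NumericVector out(12);
  if (N <= 0.0) return out;
  total_propensity(n, N, REAL(omega), REAL(d), REAL(beta), zygote_timing, cD,
                   cB, K, prop);
  for (int k = 0; k < 12; ++k) out[k] = prop[k];
  return out;
}

// Repeated single-event draws from a FIXED state (for distributional checks
// of the event-choice and waiting-time laws).  Returns event index (1..12,
// births then deaths) and exponential waiting time for each draw.
// [[Rcpp::export]]
List ssa_draws_cpp(NumericVector counts, NumericVector omega, NumericVector d,
                   NumericVector beta, bool zygote_timing, double cD,
                   double cB, double K, int ndraws) {
  double n[6], prop[12];
  double N = 0.0;
  for (int g = 0; g < 6; ++g) { n[g] = counts[g]; N += n[g]; }
  if (N <= 0.0) stop("empty population: no events possible");
  double tot = total_propensity(n, N, REAL(omega), REAL(d), REAL(beta),
                                zygote_timing, cD, cB, K, prop);
  if (tot <= 0.0) stop("total propensity is zero");
  IntegerVector ev(ndraws);
  NumericVector wt(ndraws);
  for (int i = 0; i < ndraws; ++i) {
    wt[i] = R::rexp(1.0 / tot);
    double u = unif_rand() * tot, acc = 0.0;
    int k = 0;
    for (; k < 12; ++k) {
      acc += prop[k];
      if (u <= acc) break;
    }
    if (k == 12) k = 11;
    ev[i] = k + 1;
  }
  return List::create(_["event"] = ev, _["wait"] = wt, _["total_rate"] = tot);
}

// Exact Gillespie simulation of the birth-death system.  Counts are integer;
// the brake release adds N0B 0B individuals at the first event boundary where
// the drive frequency reaches fI.  Optional trajectory thinning records the
// state that was current at each multiple of record_dt.
// [[Rcpp::export]]
List ssa_run_cpp(IntegerVector init, NumericVector omega, NumericVector d,
                 NumericVector beta, bool zygote_timing, double cD, double cB,
                 double K, double tmax, bool brake_enabled, double fI,
                 int N0B, double record_dt, double max_events) {
  long long n[6];
  for (int g = 0; g < 6; ++g) n[g] = init[g];
  const double *om = REAL(omega), *dd = REAL(d), *bb = REAL(beta);
  double t = 0.0, brake_time = NA_REAL;
  bool fired = false;
  double prop[12], nn[6];
  double ev_count = 0.0;

  bool record = record_dt > 0.0;
  std::vector<double> rt;
  std::vector<double> rn;
  double next_rec = 0.0;
  long long N = 0;
  for (int g = 0; g < 6; ++g) N += n[g];

  auto maybe_fire = [&](void) {
    if (!brake_enabled || fired || N <= 0) return;
    double pD = (n[2] + 0.5 * n[1] + 0.5 * n[4]) / (double)N;
    if (pD >= fI) {
      n[3] += N0B;
      N += N0B;
      fired = true;
      brake_time = t;
    }
  };
  auto record_upto = [&](double tnew) {
    if (!record) return;
    while (next_rec <= tnew + 1e-12 && next_rec <= tmax) {
      rt.push_back(next_rec);
      for (int g = 0; g < 6; ++g) rn.push_back((double)n[g]);
      next_rec += record_dt;
    }
  };

  maybe_fire();
  record_upto(0.0);

  std::string reason = "tmax";
  while (true) {
    if (N == 0) { reason = "extinct"; break; }
    for (int g = 0; g < 6; ++g) nn[g] = (double)n[g];
    double tot = total_propensity(nn, (double)N, om, dd, bb, zygote_timing,
                                  cD, cB, K, prop);
    if (tot <= 0.0) { reason = "absorbed"; break; }
    double tnew = t + R::rexp(1.0 / tot);
    if (tnew >= tmax) {
      record_upto(tmax);
      t = tmax;
      break;
    }
    record_upto(tnew);
    t = tnew;
    double u = unif_rand() * tot, acc = 0.0;
    int k = 0;
    for (; k < 12; ++k) {
      acc += prop[k];
      if (u <= acc) break;
    }
    if (k == 12) k = 11;
    if (k < 6) { n[k] += 1; N += 1; }
    else { n[k - 6] -= 1; N -= 1; }
    maybe_fire();
    ev_count += 1.0;
    if (ev_count >= max_events) { reason = "max_events"; break; }
  }
  if (reason == "extinct" || reason == "absorbed") record_upto(tmax);

  IntegerVector fin(6);
  for (int g = 0; g < 6; ++g) fin[g] = (int)n[g];
  List traj = R_NilValue;
  if (record) {
    int m = (int)rt.size();
    NumericVector tt(m);
    NumericMatrix st(m, 6);
    for (int i = 0; i < m; ++i) {
      tt[i] = rt[i];
      for (int g = 0; g < 6; ++g) st(i, g) = rn[(size_t)i * 6 + g];
    }
    traj = List::create(_["t"] = tt, _["states"] = st);
  }
  return List::create(_["final"] = fin, _["t_end"] = t,
                      _["brake_fired"] = fired, _["brake_time"] = brake_time,
                      _["n_events"] = ev_count, _["reason"] = reason,
                      _["trajectory"] = traj);
}

// Fixed-step integration of the two-allele frequency dynamics in the
// vanishing-density limit (logistic factor 1), with renormalisation each
// step.  Frequencies ordered (f00, f0D, fDD).  Stops early once the drive
// frequency crosses `p_low` from above (boundary escape established).
// [[Rcpp::export]]
List freq2_integrate_cpp(NumericVector f0, NumericVector omega,
                         NumericVector d, NumericVector beta,
                         bool zygote_timing, double cD, double cB,
                         double dt, double tmax, double p_low) {
  double n[6] = {f0[0], f0[1], f0[2], 0.0, 0.0, 0.0};
  double dn[6];
  const double *om = REAL(omega), *dd = REAL(d), *bb = REAL(beta);
  long nsteps = (long)std::ceil(tmax / dt - 1e-9);
  double t = 0.0, pD = 0.0;
  bool escaped = false;
  for (long s = 1; s <= nsteps; ++s) {
    // per-capita rates at unit total density, no density regulation
    density_rhs(n, om, dd, bb, zygote_timing, cD, cB, 1e300, dn);
    double tot = dn[0] + dn[1] + dn[2];
    for (int g = 0; g < 3; ++g) {
      n[g] += dt * (dn[g] - n[g] * tot);
      if (n[g] < 0.0) n[g] = 0.0;
    }
    double s3 = n[0] + n[1] + n[2];
    for (int g = 0; g < 3; ++g) n[g] /= s3;
    t = s * dt;
    pD = n[2] + 0.5 * n[1];
    if (pD < p_low) { escaped = true; break; }
  }
  return List::create(_["f"] = NumericVector::create(n[0], n[1], n[2]),
                      _["p_D"] = pD, _["t"] = t, _["escaped"] = escaped);
}
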