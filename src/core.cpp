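#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Occupancy threshold below which an institutional level is treated as empty:
// fitness ratios are undefined there, so flows into such levels carry only the
// fitness-independent innovation rate mu.
static const double OCC_TOL = 1e-12;

// ---------------------------------------------------------------------------
// Mean-field master-equation right-hand side.
//
// G is an (n+1) x L matrix: row i = number of adopters (0..n), column j =
// institutional level l_min + j.  dG receives the time derivative.
//
// Behavioural diffusion within groups (level-scaled SIS contagion driven by
// local adopters plus the global field R), relaxation, and fitness-biased
// institutional switching between adjacent levels.
// ---------------------------------------------------------------------------
// Fitness exponentials depend only on the parameters, so the integrators
// precompute exp(b*i) and exp(-c*lev) tables once per run.
struct FitTables {
  std::vector<double> expb;  // exp(b * i), i = 0..n
  std::vector<double> expc;  // exp(-c * lev) per level column
  FitTables(int n, int L, int l_min, double b, double cost)
      : expb(n + 1), expc(L) {
    for (int i = 0; i <= n; ++i) expb[i] = std::exp(b * i);
    for (int j = 0; j < L; ++j) expc[j] = std::exp(-cost * (l_min + j));
  }
};

static void rhs(const double* G, double* dG, int n, int L, int l_min,
                double beta, double gamma, double rho, double mu,
                const FitTables& ft) {
  const int ni = n + 1;

  // Global diffusion field R = rho * mean adopters per group.
  double R = 0.0;
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < ni; ++i) R += i * G[i + j * ni];
  R *= rho;

  // Perceived fitness Z_l = occupancy-weighted mean of exp(b i - c l).
  std::vector<double> Z(L), occ(L);
  for (int j = 0; j < L; ++j) {
    double num = 0.0, den = 0.0;
    for (int i = 0; i < ni; ++i) {
      const double g = G[i + j * ni];
      num += ft.expb[i] * g;
      den += g;
    }
    occ[j] = den;
    Z[j] = (den > OCC_TOL) ? num * ft.expc[j] / den : ft.expc[j];
  }

  for (int k = 0; k < ni * L; ++k) dG[k] = 0.0;

  // Diffusion + relaxation, written as paired flows so mass is conserved
  // exactly: adoption (i -> i+1) at rate l*beta*(i+R)*(n-i), relaxation
  // (i -> i-1) at rate gamma*i.
  for (int j = 0; j < L; ++j) {
    const int lev = l_min + j;
    for (int i = 0; i < ni; ++i) {
      const double g = G[i + j * ni];
      if (g == 0.0) continue;
      if (i < n) {
        const double f = lev * beta * (i + R) * (n - i) * g;
        dG[i + j * ni] -= f;
        dG[i + 1 + j * ni] += f;
      }
      if (i > 0) {
        const double f = gamma * i * g;
        dG[i + j * ni] -= f;
        dG[i - 1 + j * ni] += f;
      }
    }
  }

  // Institutional switching between adjacent levels. Per-group rate
  // rho*[max(Z_target/Z_source - 1, 0) + mu]; flows into an unoccupied
  // target level carry only rho*mu. Boundary levels simply lack the
  // corresponding neighbour flow.
  for (int j = 0; j + 1 < L; ++j) {
    double up, down;  // per-group rates j -> j+1 and j+1 -> j
    if (occ[j] > OCC_TOL && occ[j + 1] > OCC_TOL) {
      up = rho * (std::max(Z[j + 1] / Z[j] - 1.0, 0.0) + mu);
      down = rho * (std::max(Z[j] / Z[j + 1] - 1.0, 0.0) + mu);
    } else {
      up = rho * mu;
      down = rho * mu;
    }
    for (int i = 0; i < ni; ++i) {
      const double gj = G[i + j * ni];
      const double gj1 = G[i + (j + 1) * ni];
      const double f = up * gj - down * gj1;
      dG[i + j * ni] -= f;
      dG[i + (j + 1) * ni] += f;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_total_rhs(NumericMatrix G, int n, int l_min, double beta,
                            double gamma, double rho, double b, double cost,
                            double mu) {
  const int L = G.ncol();
  NumericMatrix dG(G.nrow(), L);
  FitTables ft(n, L, l_min, b, cost);
  rhs(G.begin(), dG.begin(), n, L, l_min, beta, gamma, rho, mu, ft);
  return dG;
}

// Classical fixed-step RK4 with post-step hygiene: clip tiny negatives
// (integration noise), abort on entries below -1e-9 (step too large),
// renormalize when drift in total mass exceeds 1e-12.
struct StepResult {
  bool ok;
  int n_clipped;
  int n_renorm;
};

static StepResult rk4_step(std::vector<double>& G, double dt, int n, int L,
                           int l_min, double beta, double gamma, double rho,
                           double mu, const FitTables& ft,
                           std::vector<double>& k1, std::vector<double>& k2,
                           std::vector<double>& k3, std::vector<double>& k4,
                           std::vector<double>& tmp) {
  const int m = (int)G.size();
  rhs(G.data(), k1.data(), n, L, l_min, beta, gamma, rho, mu, ft);
  for (int k = 0; k < m; ++k) tmp[k] = G[k] + 0.5 * dt * k1[k];
  rhs(tmp.data(), k2.data(), n, L, l_min, beta, gamma, rho, mu, ft);
  for (int k = 0; k < m; ++k) tmp[k] = G[k] + 0.5 * dt * k2[k];
  rhs(tmp.data(), k3.data(), n, L, l_min, beta, gamma, rho, mu, ft);
  for (int k = 0; k < m; ++k) tmp[k] = G[k] + dt * k3[k];
  rhs(tmp.data(), k4.data(), n, L, l_min, beta, gamma, rho, mu, ft);

  StepResult res = {true, 0, 0};
  double sum = 0.0;
  for (int k = 0; k < m; ++k) {
    G[k] += dt / 6.0 * (k1[k] + 2.0 * k2[k] + 2.0 * k3[k] + k4[k]);
    if (G[k] < 0.0) {
      if (G[k] < -1e-9) {
        res.ok = false;
        return res;
      }
      G[k] = 0.0;
      ++res.n_clipped;
    }
    sum += G[k];
  }
  if (std::abs(sum - 1.0) > 1e-12 && sum > 0.0) {
    for (int k = 0; k < m; ++k) G[k] /= sum;
    res.n_renorm = 1;
  }
  return res;
}

static double mean_adopters(const std::vector<double>& G, int ni, int L) {
  double s = 0.0;
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < ni; ++i) s += i * G[i + j * ni];
  return s;
}

// [[Rcpp::export]]
List cpp_integrate(NumericMatrix G0, int n, int l_min, double beta,
                   double gamma, double rho, double b, double cost, double mu,
                   double t_end, double dt, double record_every) {
  const int ni = G0.nrow(), L = G0.ncol(), m = ni * L;
  std::vector<double> G(G0.begin(), G0.end());
  std::vector<double> k1(m), k2(m), k3(m), k4(m), tmp(m);
  FitTables ft(n, L, l_min, b, cost);

  const long n_steps = (long)std::ceil(t_end / dt - 1e-9);
  const long rec_stride = std::max(1L, (long)std::llround(record_every / dt));
  const long n_rec = n_steps / rec_stride + 1;

  NumericVector times(n_rec);
  NumericVector states(m * n_rec);
  states.attr("dim") = IntegerVector::create(ni, L, n_rec);
  int clipped = 0, renorm = 0;

  long r = 0;
  times[r] = 0.0;
  std::copy(G.begin(), G.end(), states.begin());
  ++r;

  for (long s = 1; s <= n_steps; ++s) {
    StepResult sr = rk4_step(G, dt, n, L, l_min, beta, gamma, rho, mu, ft,
                             k1, k2, k3, k4, tmp);
    if (!sr.ok)
      return List::create(_["ok"] = false, _["t_fail"] = s * dt);
    clipped += sr.n_clipped;
    renorm += sr.n_renorm;
    if (s % rec_stride == 0 && r < n_rec) {
      times[r] = s * dt;
      std::copy(G.begin(), G.end(), states.begin() + r * m);
      ++r;
    }
  }
  return List::create(_["ok"] = true, _["times"] = times,
                      _["states"] = states, _["n_clipped"] = clipped,
                      _["n_renorm"] = renorm);
}

// Integrate until t >= t_min and |<i>(t) - <i>(t - delta_t)| < tol, or until
// t_cap with converged = false.
// [[Rcpp::export]]
List cpp_run_steady(NumericMatrix G0, int n, int l_min, double beta,
                    double gamma, double rho, double b, double cost, double mu,
                    double dt, double t_min, double delta_i_tol,
                    double delta_t, double t_cap) {
  const int ni = G0.nrow(), L = G0.ncol(), m = ni * L;
  std::vector<double> G(G0.begin(), G0.end());
  std::vector<double> k1(m), k2(m), k3(m), k4(m), tmp(m);
  FitTables ft(n, L, l_min, b, cost);

  const long win = std::max(1L, (long)std::llround(delta_t / dt));
  std::vector<double> buf(win + 1);
  buf[0] = mean_adopters(G, ni, L);

  const long max_steps = (long)std::ceil(t_cap / dt - 1e-9);
  const long min_steps = (long)std::ceil(t_min / dt - 1e-9);
  bool converged = false;
  long s = 0;
  while (s < max_steps) {
    StepResult sr = rk4_step(G, dt, n, L, l_min, beta, gamma, rho, mu, ft,
                             k1, k2, k3, k4, tmp);
    ++s;
    if (!sr.ok)
      return List::create(_["ok"] = false, _["t_fail"] = s * dt);
    const double mi = mean_adopters(G, ni, L);
    buf[s % (win + 1)] = mi;
    if (s >= min_steps && s >= win) {
      const double prev = buf[(s - win) % (win + 1)];
      if (std::abs(mi - prev) < delta_i_tol) {
        converged = true;
        break;
      }
    }
  }
  NumericMatrix Gout(ni, L);
  std::copy(G.begin(), G.end(), Gout.begin());
  return List::create(_["ok"] = true, _["G"] = Gout, _["t"] = s * dt,
                      _["converged"] = converged);
}

// ---------------------------------------------------------------------------
// Exact event-driven (Gillespie) simulation of M explicit groups.
//
// The ensemble state is stored as integer counts C[i, j]: number of groups
// with i adopters at level l_min + j (groups are exchangeable, so state
// counts are a lossless representation). Per-group event rates mirror the
// mean-field terms with R and Z recomputed from the instantaneous empirical
// state after every event; aggregates are maintained incrementally.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_gillespie(IntegerMatrix C0, int n, int l_min, double beta,
                   double gamma, double rho, double b, double cost, double mu,
                   NumericVector record_times) {
  const int ni = C0.nrow(), L = C0.ncol();
  const int T = record_times.size();
  std::vector<long> C(C0.begin(), C0.end());
  long M = 0;
  for (int k = 0; k < ni * L; ++k) M += C[k];

  std::vector<double> expb(ni);
  for (int i = 0; i < ni; ++i) expb[i] = std::exp(b * i);
  std::vector<double> expc(L);
  for (int j = 0; j < L; ++j) expc[j] = std::exp(-cost * (l_min + j));

  // Aggregates: S = total adopters; A1 = sum lev*i*(n-i); A2 = sum lev*(n-i);
  // per-level group counts and sum of exp(b*i).
  double S = 0.0, A1 = 0.0, A2 = 0.0;
  std::vector<double> sumExp(L, 0.0);
  std::vector<long> cnt(L, 0);
  for (int j = 0; j < L; ++j) {
    const int lev = l_min + j;
    for (int i = 0; i < ni; ++i) {
      const long c = C[i + j * ni];
      if (!c) continue;
      S += (double)c * i;
      A1 += (double)c * lev * i * (n - i);
      A2 += (double)c * lev * (n - i);
      sumExp[j] += c * expb[i];
      cnt[j] += c;
    }
  }

  NumericVector out(ni * L * T);
  out.attr("dim") = IntegerVector::create(ni, L, T);
  double t = 0.0;
  int rec = 0;
  std::vector<double> up(L, 0.0), dn(L, 0.0);

  auto record_now = [&](int idx) {
    for (int k = 0; k < ni * L; ++k) out[k + idx * ni * L] = C[k] / (double)M;
  };

  RNGScope scope;
  const double t_end = record_times[T - 1];
  while (true) {
    const double Rhat = rho * S / M;
    const double rate_adopt = beta * (A1 + Rhat * A2);
    const double rate_aband = gamma * S;
    double rate_lvl = 0.0;
    for (int j = 0; j + 1 < L; ++j) {
      double u, d;
      if (cnt[j] > 0 && cnt[j + 1] > 0) {
        const double Zj = sumExp[j] * expc[j] / cnt[j];
        const double Zj1 = sumExp[j + 1] * expc[j + 1] / cnt[j + 1];
        u = rho * (std::max(Zj1 / Zj - 1.0, 0.0) + mu);
        d = rho * (std::max(Zj / Zj1 - 1.0, 0.0) + mu);
      } else {
        u = rho * mu;
        d = rho * mu;
      }
      up[j] = u * cnt[j];
      dn[j + 1] = d * cnt[j + 1];
      rate_lvl += up[j] + dn[j + 1];
    }
    const double total = rate_adopt + rate_aband + rate_lvl;

    if (total <= 0.0) {  // frozen state: fill remaining records
      while (rec < T) record_now(rec++);
      break;
    }
    const double tau = -std::log(unif_rand()) / total;
    while (rec < T && record_times[rec] <= t + tau) record_now(rec++);
    t += tau;
    if (rec >= T || t > t_end) break;

    double u = unif_rand() * total;
    if (u < rate_adopt) {
      // pick state (i, j) with prob proportional to C*lev*(i+Rhat)*(n-i)
      double target = u / beta;  // cumulate un-scaled by beta
      int pi = -1, pj = -1;
      double acc = 0.0;
      for (int j = 0; j < L && pi < 0; ++j) {
        const int lev = l_min + j;
        if (!lev || !cnt[j]) continue;
        for (int i = 0; i < n; ++i) {
          const long c = C[i + j * ni];
          if (!c) continue;
          acc += (double)c * lev * (i + Rhat) * (n - i);
          if (acc >= target) {
            pi = i;
            pj = j;
            break;
          }
        }
      }
      if (pi < 0) {  // numerical slack: take last feasible state
        for (int j = L - 1; j >= 0 && pi < 0; --j)
          for (int i = n - 1; i >= 0; --i)
            if (C[i + j * ni] > 0 && (l_min + j) > 0) {
              pi = i;
              pj = j;
              break;
            }
        if (pi < 0) continue;
      }
      const int lev = l_min + pj;
      C[pi + pj * ni]--;
      C[pi + 1 + pj * ni]++;
      S += 1.0;
      A1 += lev * ((double)(pi + 1) * (n - pi - 1) - (double)pi * (n - pi));
      A2 -= lev;
      sumExp[pj] += expb[pi + 1] - expb[pi];
    } else if (u < rate_adopt + rate_aband) {
      double target = (u - rate_adopt) / gamma;
      int pi = -1, pj = -1;
      double acc = 0.0;
      for (int j = 0; j < L && pi < 0; ++j)
        for (int i = 1; i < ni; ++i) {
          const long c = C[i + j * ni];
          if (!c) continue;
          acc += (double)c * i;
          if (acc >= target) {
            pi = i;
            pj = j;
            break;
          }
        }
      if (pi < 0) {
        for (int j = L - 1; j >= 0 && pi < 0; --j)
          for (int i = n; i >= 1; --i)
            if (C[i + j * ni] > 0) {
              pi = i;
              pj = j;
              break;
            }
        if (pi < 0) continue;
      }
      const int lev = l_min + pj;
      C[pi + pj * ni]--;
      C[pi - 1 + pj * ni]++;
      S -= 1.0;
      A1 += lev * ((double)(pi - 1) * (n - pi + 1) - (double)pi * (n - pi));
      A2 += lev;
      sumExp[pj] += expb[pi - 1] - expb[pi];
    } else {
      // level-change event: first find the (j, direction) bucket, then a
      // uniform group within the source level (rates are i-independent).
      double rem = u - rate_adopt - rate_aband;
      int src = -1, dst = -1;
      for (int j = 0; j + 1 < L; ++j) {
        if (rem < up[j]) {
          src = j;
          dst = j + 1;
          break;
        }
        rem -= up[j];
        if (rem < dn[j + 1]) {
          src = j + 1;
          dst = j;
          break;
        }
        rem -= dn[j + 1];
      }
      if (src < 0) continue;  // numerical slack
      // choose i within level src proportional to C[i, src]
      long pick = (long)std::floor(unif_rand() * cnt[src]);
      if (pick >= cnt[src]) pick = cnt[src] - 1;
      int pi = -1;
      long acc = 0;
      for (int i = 0; i < ni; ++i) {
        acc += C[i + src * ni];
        if (pick < acc) {
          pi = i;
          break;
        }
      }
      if (pi < 0) continue;
      const int dlev = dst - src;  // +1 or -1 in column index == level units
      C[pi + src * ni]--;
      C[pi + dst * ni]++;
      cnt[src]--;
      cnt[dst]++;
      sumExp[src] -= expb[pi];
      sumExp[dst] += expb[pi];
      A1 += dlev * (double)pi * (n - pi);
      A2 += dlev * (double)(n - pi);
    }
  }
  while (rec < T) record_now(rec++);
  return List::create(_["states"] = out, _["t_final"] = t);
}
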