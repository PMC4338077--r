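#include <Rcpp.h>
using namespace Rcpp;

// Bimorphic birth-death simulator with mutation for the N-person signaling
// game. Strategies are rows of `geno` (columns: sigma_alpha, sigma_beta,
// a0, a1). Fitness uses the exact hypergeometric expectation (precomputed
// in `omega_tbl`) whenever at most two strategies are present; with three or
// more (transient under small mutation) it falls back to averaging the
// payoff over sampled groups.

struct GamePars {
  int N, M;
  double c, cS, F, lambda, gamma;
  bool loner;
};

// Payoff of one member of a group with k cooperators, before signaling costs.
static inline double base_payoff(bool coop, int k, bool alpha, const GamePars &gp) {
  double Feff = alpha ? gp.F : 0.0;
  double hit = (k >= gp.M) ? 1.0 : 0.0;
  if (!gp.loner) {
    double share = Feff * k * gp.c / gp.N * hit;
    return coop ? share - gp.c : share;
  }
  return coop ? Feff * gp.c * hit - gp.c : 0.0;
}

// Focal payoff in a sampled group under one state; majority ties are
// resolved by an actual coin flip.
static double group_state_payoff(const IntegerMatrix &geno,
                                 const std::vector<int> &members, int focal_idx,
                                 bool alpha, const GamePars &gp) {
  int scol = alpha ? 0 : 1;
  int ones = 0;
  for (int s : members) ones += geno(s, scol);
  int maj;
  if (2 * ones > gp.N) maj = 1;
  else if (2 * ones < gp.N) maj = 0;
  else maj = (unif_rand() < 0.5) ? 1 : 0;
  int acol = 2 + maj;
  int k = 0;
  for (int s : members) k += geno(s, acol);
  int fs = members[focal_idx];
  bool coop = geno(fs, acol) == 1;
  double pay = base_payoff(coop, k, alpha, gp);
  if (geno(fs, scol) == 1) pay -= gp.cS;
  return pay;
}

// Mean payoff of individual `focal` over n_samples randomly assembled groups.
static double sampled_fitness(const IntegerVector &state, int focal,
                              const IntegerMatrix &geno, const GamePars &gp,
                              int n_samples, std::vector<int> &pool) {
  int Z = state.size();
  // pool = indices != focal
  int m = 0;
  for (int i = 0; i < Z; ++i) if (i != focal) pool[m++] = i;
  double total = 0.0;
  std::vector<int> members(gp.N);
  for (int s = 0; s < n_samples; ++s) {
    // partial Fisher-Yates draw of N-1 distinct co-players
    for (int d = 0; d < gp.N - 1; ++d) {
      int r = d + (int)(unif_rand() * (m - d));
      if (r >= m) r = m - 1;
      std::swap(pool[d], pool[r]);
      members[d] = state[pool[d]];
    }
    members[gp.N - 1] = state[focal];
    double pa = (gp.lambda > 0.0)
      ? group_state_payoff(geno, members, gp.N - 1, true, gp) : 0.0;
    double pb = (gp.lambda < 1.0)
      ? group_state_payoff(geno, members, gp.N - 1, false, gp) : 0.0;
    total += gp.lambda * pa + (1.0 - gp.lambda) * pb;
  }
  return total / n_samples;
}

// [[Rcpp::export]]
List cpp_run_simulation(IntegerMatrix geno, NumericVector omega_tbl,
                        int Z, int N, int M, double c, double cS, double F,
                        double lambda, double gamma, bool loner,
                        double mu, double steps, double burn_in,
                        IntegerVector init_state, int n_group_samples,
                        double thin, bool exact_ok) {
  GamePars gp{N, M, c, cS, F, lambda, gamma, loner};
  int nS = geno.nrow();
  IntegerVector state = clone(init_state); // 0-based strategy codes
  std::vector<double> counts(nS, 0.0);
  int n_present = 0;
  for (int i = 0; i < Z; ++i) counts[state[i]] += 1;
  for (int s = 0; s < nS; ++s) if (counts[s] > 0) ++n_present;

  std::vector<double> freq(nS, 0.0), mono(nS, 0.0);
  std::vector<int> pool(Z);
  double retained = 0.0, mono_total = 0.0;
  std::vector<double> traj;
  long long n_traj = 0, thin_countdown = 0;

  // omega_tbl[u + nS*v + nS*nS*(k-1)]: fitness of a u-individual when the
  // population holds k u's and Z-k v's
  auto exact_fitness = [&](int s, int other) {
    int k = (int)counts[s];
    return omega_tbl[s + nS * other + (long long)nS * nS * (k - 1)];
  };

  auto set_strategy = [&](int i, int snew) {
    int sold = state[i];
    if (sold == snew) return;
    counts[sold] -= 1;
    if (counts[sold] == 0) --n_present;
    if (counts[snew] == 0) ++n_present;
    counts[snew] += 1;
    state[i] = snew;
  };

  for (double t = 0; t < steps; ++t) {
    int i = (int)(unif_rand() * Z); if (i >= Z) i = Z - 1;
    int j;
    do { j = (int)(unif_rand() * Z); if (j >= Z) j = Z - 1; } while (j == i);
    int si = state[i], sj = state[j];
    if (si != sj) {
      double wi, wj;
      if (exact_ok && n_present <= 2) {
        wi = exact_fitness(si, sj);
        wj = exact_fitness(sj, si);
      } else {
        wi = sampled_fitness(state, i, geno, gp, n_group_samples, pool);
        wj = sampled_fitness(state, j, geno, gp, n_group_samples, pool);
      }
      double p = 1.0 / (1.0 + std::exp(-gamma * (wj - wi)));
      if (unif_rand() < p) set_strategy(i, sj);
    }
    if (mu > 0.0 && unif_rand() < mu) {
      int snew = (int)(unif_rand() * nS); if (snew >= nS) snew = nS - 1;
      set_strategy(i, snew);
    }
    if (t >= burn_in) {
      retained += 1;
      for (int s = 0; s < nS; ++s) freq[s] += counts[s];
      if (n_present == 1) { mono[state[0]] += 1; mono_total += 1; }
      if (thin > 0 && thin_countdown-- <= 0) {
        thin_countdown = (long long)thin - 1;
        traj.push_back(t);
        for (int s = 0; s < nS; ++s) traj.push_back(counts[s]);
        ++n_traj;
      }
    }
  }
  for (int s = 0; s < nS; ++s) freq[s] /= retained * Z;
  NumericVector occ(nS);
  for (int s = 0; s < nS; ++s) occ[s] = mono[s] / retained;

  List out = List::create(
    _["frequencies"] = NumericVector(freq.begin(), freq.end()),
    _["monomorphic_occupancy"] = occ,
    _["monomorphic_fraction"] = mono_total / retained,
    _["retained_steps"] = retained,
    _["final_state"] = state);
  if (thin > 0) {
    NumericMatrix tm(nS + 1, n_traj, traj.begin());
    out["trajectory"] = transpose(tm);
  }
  return out;
}
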