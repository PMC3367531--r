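// Replica-exchange Monte Carlo over sequence space with the generalized
// energy G(S) = sum_structures E_contact(S, X) - E_R * ln N_perm(S).
// Single-site substitution proposals; incremental energy and permutation
// bookkeeping. Used for both sequence design (one structure) and the
// biased joint two-structure ensemble behind the rate estimator.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
List mc_sample_cpp(int L, int n_letters, List contact_list, NumericMatrix eps,
                   NumericVector temps, double E_R, int n_sweeps, int burn_in,
                   int exchange_interval, int record_every, int seed,
                   IntegerMatrix init_seqs) {
  const int n_struct = contact_list.size();
  const int n_temps = temps.size();
  if (n_temps < 1) stop("empty temperature ladder");
  for (int t = 0; t < n_temps; ++t)
    if (temps[t] <= 0.0) stop("temperatures must be positive");

  // per-structure neighbour lists
  std::vector<std::vector<std::vector<int>>> nb(
      n_struct, std::vector<std::vector<int>>(L));
  for (int s = 0; s < n_struct; ++s) {
    IntegerMatrix cm = contact_list[s];
    for (int r = 0; r < cm.nrow(); ++r) {
      int i = cm(r, 0), j = cm(r, 1);
      if (i < 0 || j < 0 || i >= L || j >= L) stop("contact index out of range");
      nb[s][i].push_back(j);
      nb[s][j].push_back(i);
    }
  }

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_int_distribution<int> site_d(0, L - 1);
  std::uniform_int_distribution<int> letter_d(0, n_letters - 2);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // replica states
  std::vector<std::vector<int>> seqs(n_temps, std::vector<int>(L));
  for (int t = 0; t < n_temps; ++t) {
    if (init_seqs.nrow() == n_temps) {
      for (int i = 0; i < L; ++i) seqs[t][i] = init_seqs(t, i);
    } else {
      std::uniform_int_distribution<int> any(0, n_letters - 1);
      for (int i = 0; i < L; ++i) seqs[t][i] = any(rng);
    }
  }
  std::vector<std::vector<int>> counts(n_temps, std::vector<int>(n_letters, 0));
  std::vector<std::vector<double>> E(n_temps, std::vector<double>(n_struct, 0.0));
  std::vector<double> lnperm(n_temps, 0.0);
  for (int t = 0; t < n_temps; ++t) {
    for (int i = 0; i < L; ++i) counts[t][seqs[t][i]]++;
    for (int s = 0; s < n_struct; ++s) {
      IntegerMatrix cm = contact_list[s];
      double e = 0.0;
      for (int r = 0; r < cm.nrow(); ++r)
        e += eps(seqs[t][cm(r, 0)], seqs[t][cm(r, 1)]);
      E[t][s] = e;
    }
    double lp = std::lgamma(L + 1.0);
    for (int a = 0; a < n_letters; ++a) lp -= std::lgamma(counts[t][a] + 1.0);
    lnperm[t] = lp;
  }

  const int n_rec =
      (n_sweeps > burn_in) ? (n_sweeps - burn_in + record_every - 1) / record_every : 0;
  std::vector<IntegerMatrix> rec_seqs;
  std::vector<NumericMatrix> rec_E;
  std::vector<NumericVector> rec_lnp;
  for (int t = 0; t < n_temps; ++t) {
    rec_seqs.push_back(IntegerMatrix(n_rec, L));
    rec_E.push_back(NumericMatrix(n_rec, n_struct));
    rec_lnp.push_back(NumericVector(n_rec));
  }

  std::vector<long> acc(n_temps, 0), tries(n_temps, 0);
  long swap_acc = 0, swap_tries = 0;
  int rec_i = 0;

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int t = 0; t < n_temps; ++t) {
      const double T = temps[t];
      for (int m = 0; m < L; ++m) {
        int site = site_d(rng);
        int old_l = seqs[t][site];
        int r = letter_d(rng);
        int new_l = (r >= old_l) ? r + 1 : r;
        double dlnp = std::log((double)counts[t][old_l]) -
                      std::log((double)counts[t][new_l] + 1.0);
        double dG = -E_R * dlnp;
        std::vector<double> dE(n_struct, 0.0);
        for (int s = 0; s < n_struct; ++s) {
          double d = 0.0;
          for (int p : nb[s][site])
            d += eps(new_l, seqs[t][p]) - eps(old_l, seqs[t][p]);
          dE[s] = d;
          dG += d;
        }
        ++tries[t];
        if (dG <= 0.0 || unif(rng) < std::exp(-dG / T)) {
          seqs[t][site] = new_l;
          counts[t][old_l]--;
          counts[t][new_l]++;
          lnperm[t] += dlnp;
          for (int s = 0; s < n_struct; ++s) E[t][s] += dE[s];
          ++acc[t];
        }
      }
    }
    if (n_temps > 1 && exchange_interval > 0 &&
        (sweep + 1) % exchange_interval == 0) {
      for (int t = 0; t + 1 < n_temps; ++t) {
        double Gi = -E_R * lnperm[t], Gj = -E_R * lnperm[t + 1];
        for (int s = 0; s < n_struct; ++s) { Gi += E[t][s]; Gj += E[t + 1][s]; }
        // swap ratio exp((beta_i - beta_j) (G_i - G_j))
        double larg = (1.0 / temps[t] - 1.0 / temps[t + 1]) * (Gi - Gj);
        ++swap_tries;
        if (larg >= 0.0 || unif(rng) < std::exp(larg)) {
          std::swap(seqs[t], seqs[t + 1]);
          std::swap(counts[t], counts[t + 1]);
          std::swap(E[t], E[t + 1]);
          std::swap(lnperm[t], lnperm[t + 1]);
          ++swap_acc;
        }
      }
    }
    if (sweep >= burn_in && (sweep - burn_in) % record_every == 0) {
      for (int t = 0; t < n_temps; ++t) {
        for (int i = 0; i < L; ++i) rec_seqs[t](rec_i, i) = seqs[t][i];
        for (int s = 0; s < n_struct; ++s) rec_E[t](rec_i, s) = E[t][s];
        rec_lnp[t][rec_i] = lnperm[t];
      }
      ++rec_i;
    }
  }

  List per_temp(n_temps);
  for (int t = 0; t < n_temps; ++t) {
    per_temp[t] = List::create(
        Named("seqs") = rec_seqs[t], Named("E") = rec_E[t],
        Named("log_n_perm") = rec_lnp[t], Named("temperature") = temps[t],
        Named("acceptance") = tries[t] ? (double)acc[t] / tries[t] : NA_REAL);
  }
  return List::create(
      Named("replicas") = per_temp,
      Named("swap_acceptance") =
          swap_tries ? (double)swap_acc / swap_tries : NA_REAL,
      Named("n_records") = rec_i);
}
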