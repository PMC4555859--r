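#include <chrono>

#include "moves.h"

using namespace Rcpp;
using namespace gwfold;

namespace {

struct Ind {
  std::vector<int> dirs;
  double e;
};

double score_dirs(const std::vector<int> &dirs, const std::vector<int> &seq,
                  const double *E) {
  std::vector<P3> c;
  decode(dirs, c);
  OccMap occ;
  if (build_occ(c, occ) >= 0) stop("internal error: invalid conformation");
  return contact_energy(c, occ, seq, E);
}

std::vector<int> r_dirs(const IntegerVector &directions) {
  std::vector<int> d(directions.size());
  for (int k = 0; k < directions.size(); ++k) {
    int v = directions[k];
    if (v == NA_INTEGER || v < 1 || v > 12)
      stop("direction index outside 1..12 in initial population");
    d[k] = v - 1;
  }
  return d;
}

}  // namespace

// Full genetic-algorithm run. Guidance selection/replacement uses `guidE`;
// the incumbent best is additionally re-scored under `bmE` for reporting.
// All randomness is drawn from R's RNG. Operator codes in the trajectory:
// 1 = pull, 2 = crossover, 3 = diagonal, 4 = rotation.
// [[Rcpp::export]]
List run_ga_cpp(IntegerVector seq_codes, NumericMatrix guidE, NumericMatrix bmE,
                int pop_size, NumericVector probs, int threshold,
                int max_generations, double max_evaluations,
                double time_budget, bool exhaustive, int chain_restarts,
                int rot_retries, int move_retries, int recovery_retries,
                Nullable<List> init_population) {
  const int n = seq_codes.size();
  const double *GE = REAL(guidE);
  const double *BE = REAL(bmE);
  std::vector<int> seq(seq_codes.begin(), seq_codes.end());

  std::vector<Ind> pop(pop_size);
  long long evals = 0;
  if (init_population.isNotNull()) {
    List ip(init_population);
    if (ip.size() != pop_size)
      stop("initial population size does not match pop_size");
    for (int i = 0; i < pop_size; ++i) {
      pop[i].dirs = r_dirs(ip[i]);
      if ((int)pop[i].dirs.size() != n - 1)
        stop("initial conformation length does not match sequence");
    }
  } else {
    for (int i = 0; i < pop_size; ++i)
      pop[i].dirs = chain_growth(n, chain_restarts);
  }
  for (int i = 0; i < pop_size; ++i) {
    pop[i].e = score_dirs(pop[i].dirs, seq, GE);
    ++evals;
  }

  int best_i = 0;
  for (int i = 1; i < pop_size; ++i)
    if (pop[i].e < pop[best_i].e) best_i = i;
  std::vector<int> best_dirs = pop[best_i].dirs;
  double best_g = pop[best_i].e;
  double best_bm = score_dirs(best_dirs, seq, BE);
  const double init_best_g = best_g;
  const double init_best_bm = best_bm;

  int tracking = 0, shuffle = 1, generation = 0, recoveries = 0;
  bool recovered_before = false, new_best_since_recovery = false;
  long long applied[4] = {0, 0, 0, 0}, accepted[4] = {0, 0, 0, 0};

  std::vector<double> traj;  // 8 columns per generation
  const auto t0 = std::chrono::steady_clock::now();
  auto elapsed = [&t0]() {
    return std::chrono::duration<double>(std::chrono::steady_clock::now() - t0)
        .count();
  };

  while (true) {
    if (max_generations >= 0 && generation >= max_generations) break;
    if (max_evaluations >= 0 && (double)evals >= max_evaluations) break;
    if (time_budget > 0 && elapsed() >= time_budget) break;
    ++generation;

    // one operator per generation, drawn from the configured distribution
    double u = unif_rand(), cum = 0.0;
    int op = 3;
    for (int k = 0; k < 4; ++k) {
      cum += probs[k];
      if (u < cum) {
        op = k;
        break;
      }
    }
    ++applied[op];

    for (int i = 0; i < pop_size; ++i) {
      Cand cand;
      cand.feasible = false;
      if (op == 0) {
        cand = exhaustive ? exhaustive_pull(pop[i].dirs, seq, GE, evals)
                          : random_pull(pop[i].dirs, seq, GE, move_retries,
                                        evals);
      } else if (op == 1) {
        int j = (int)(unif_rand() * (pop_size - 1));
        if (j >= pop_size - 1) j = pop_size - 2;
        if (j >= i) ++j;
        cand = exhaustive
                   ? exhaustive_crossover(pop[i].dirs, pop[j].dirs, seq, GE,
                                          evals)
                   : random_crossover(pop[i].dirs, pop[j].dirs, seq, GE,
                                      evals);
      } else if (op == 2) {
        cand = exhaustive ? exhaustive_diagonal(pop[i].dirs, seq, GE, evals)
                          : random_diagonal(pop[i].dirs, seq, GE, move_retries,
                                            evals);
      } else {
        cand = exhaustive ? exhaustive_rotation(pop[i].dirs, seq, GE,
                                                rot_retries, evals)
                          : random_rotation(pop[i].dirs, seq, GE, rot_retries,
                                            evals);
      }
      // elitist replacement: the child survives only on strict improvement
      if (cand.feasible && cand.energy < pop[i].e) {
        pop[i].dirs = cand.dirs;
        pop[i].e = cand.energy;
        ++accepted[op];
      }
    }

    best_i = 0;
    for (int i = 1; i < pop_size; ++i)
      if (pop[i].e < pop[best_i].e) best_i = i;
    double best_cur = pop[best_i].e;
    if (best_cur < best_g) {
      best_g = best_cur;
      best_dirs = pop[best_i].dirs;
      best_bm = score_dirs(best_dirs, seq, BE);
      tracking = 0;
      new_best_since_recovery = true;
    } else {
      ++tracking;
    }

    int recovered = 0;
    if (tracking > threshold) {
      recovered = 1;
      ++recoveries;
      if (recovered_before && !new_best_since_recovery) ++shuffle;
      recovered_before = true;
      new_best_since_recovery = false;
      int kpulls = shuffle * std::max(1, n / 10);
      for (int i = 0; i < pop_size; ++i) {
        for (int k = 0; k < kpulls; ++k)
          random_pull_inplace(pop[i].dirs, recovery_retries);
        pop[i].e = score_dirs(pop[i].dirs, seq, GE);
        ++evals;
      }
      tracking = 0;
    }

    traj.push_back((double)generation);
    traj.push_back((double)(op + 1));
    traj.push_back(best_cur);
    traj.push_back(best_g);
    traj.push_back(best_bm);
    traj.push_back((double)evals);
    traj.push_back(elapsed());
    traj.push_back((double)recovered);
    Rcpp::checkUserInterrupt();
  }

  int nrow = (int)(traj.size() / 8);
  NumericMatrix tm(nrow, 8);
  for (int r = 0; r < nrow; ++r)
    for (int c = 0; c < 8; ++c) tm(r, c) = traj[r * 8 + c];
  colnames(tm) = CharacterVector::create("generation", "operator",
                                         "best_current", "best_global",
                                         "best_global_bm", "evaluations",
                                         "elapsed", "recovery");

  IntegerVector bd((int)best_dirs.size());
  for (int k = 0; k < (int)best_dirs.size(); ++k) bd[k] = best_dirs[k] + 1;
  List pop_out(pop_size);
  NumericVector pop_e(pop_size);
  for (int i = 0; i < pop_size; ++i) {
    IntegerVector di((int)pop[i].dirs.size());
    for (int k = 0; k < (int)pop[i].dirs.size(); ++k) di[k] = pop[i].dirs[k] + 1;
    pop_out[i] = di;
    pop_e[i] = pop[i].e;
  }

  return List::create(
      _["best_directions"] = bd, _["best_energy"] = best_g,
      _["best_energy_bm"] = best_bm, _["initial_best_energy"] = init_best_g,
      _["initial_best_energy_bm"] = init_best_bm,
      _["evaluations"] = (double)evals, _["generations"] = generation,
      _["trajectory"] = tm, _["operators_applied"] = NumericVector(
          std::begin(applied), std::end(applied)),
      _["operators_accepted"] = NumericVector(std::begin(accepted),
                                              std::end(accepted)),
      _["shuffle_parameter"] = shuffle, _["recoveries"] = recoveries,
      _["elapsed"] = elapsed(), _["population"] = pop_out,
      _["population_energies"] = pop_e);
}
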