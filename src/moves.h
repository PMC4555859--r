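#pragma once

#include "lattice.h"

namespace gwfold {

struct Cand {
  std::vector<int> dirs;
  double energy;
  bool feasible;
};

// Build the coordinates that result from pulling residue i (0-based) to
// `target`, dragging residues on the `d` side (+1: towards the tail, -1:
// towards the head) along the old chain until adjacency is restored.
// Construction always succeeds; validity is decided by eval_coords().
void construct_pull(const std::vector<P3> &coords, int i, int d,
                    const P3 &target, std::vector<P3> &out);

// Exhaustive operator application: enumerate the operator's parameter space,
// score every valid candidate under E, and return the minimum-energy one
// (ties broken by enumeration order). `n_evals` accumulates one tick per
// scored candidate. When no candidate is feasible, best.feasible is false.
Cand exhaustive_pull(const std::vector<int> &dirs, const std::vector<int> &seq,
                     const double *E, long long &n_evals);
Cand exhaustive_diagonal(const std::vector<int> &dirs,
                         const std::vector<int> &seq, const double *E,
                         long long &n_evals);
Cand exhaustive_rotation(const std::vector<int> &dirs,
                         const std::vector<int> &seq, const double *E,
                         int retries, long long &n_evals);
Cand exhaustive_crossover(const std::vector<int> &dirs1,
                          const std::vector<int> &dirs2,
                          const std::vector<int> &seq, const double *E,
                          long long &n_evals);

// Non-exhaustive (single random application) variants.
Cand random_pull(const std::vector<int> &dirs, const std::vector<int> &seq,
                 const double *E, int retries, long long &n_evals);
Cand random_diagonal(const std::vector<int> &dirs, const std::vector<int> &seq,
                     const double *E, int retries, long long &n_evals);
Cand random_rotation(const std::vector<int> &dirs, const std::vector<int> &seq,
                     const double *E, int retries, long long &n_evals);
Cand random_crossover(const std::vector<int> &dirs1,
                      const std::vector<int> &dirs2,
                      const std::vector<int> &seq, const double *E,
                      long long &n_evals);

// One random feasible pull applied in place (no scoring); used by the
// random-walk stagnation recovery. Returns false if no feasible pull was
// found within `retries` attempts.
bool random_pull_inplace(std::vector<int> &dirs, int retries);

}  // namespace gwfold
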