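#include "moves.h"

using namespace Rcpp;

namespace gwfold {

void construct_pull(const std::vector<P3> &coords, int i, int d,
                    const P3 &target, std::vector<P3> &out) {
  const int n = (int)coords.size();
  out = coords;
  out[i] = target;
  P3 prev = coords[i];
  for (int j = i + d; j >= 0 && j < n; j += d) {
    // Residue j keeps its place once it is already adjacent to the new
    // position of its neighbour on the pulled-from side.
    if (adjacent(out[j - d], coords[j])) break;
    P3 tmp = coords[j];
    out[j] = prev;
    prev = tmp;
  }
}

namespace {

struct BestCoords {
  std::vector<P3> coords;
  double energy;
  bool feasible;
  BestCoords() : energy(0), feasible(false) {}
  inline void offer(const std::vector<P3> &c, double e) {
    if (!feasible || e < energy) {
      coords = c;
      energy = e;
      feasible = true;
    }
  }
};

Cand finish(const BestCoords &best) {
  Cand out;
  out.feasible = best.feasible;
  out.energy = best.energy;
  if (best.feasible && !encode(best.coords, out.dirs))
    stop("internal error: best candidate failed to re-encode");
  return out;
}

// Enumerate pull targets for residue i pulled towards side d: the free
// neighbours of the anchor-side chain neighbour, or of residue i itself
// when i is the end being pulled (no anchor).
void pull_targets(const std::vector<P3> &coords, const OccMap &occ, int i,
                  int d, std::vector<P3> &targets) {
  const int n = (int)coords.size();
  int anchor = i - d;
  const P3 &base = (anchor >= 0 && anchor < n) ? coords[anchor] : coords[i];
  targets.clear();
  for (int k = 0; k < 12; ++k) {
    P3 t{base.x + BV[k][0], base.y + BV[k][1], base.z + BV[k][2]};
    if (occ.find(pack(t.x, t.y, t.z)) == occ.end()) targets.push_back(t);
  }
}

// Diagonal-move targets: free points adjacent to both chain neighbours of
// an interior residue (at most 4 on the FCC lattice), or any free neighbour
// of the single chain neighbour of a terminal residue.
void diagonal_targets(const std::vector<P3> &coords, const OccMap &occ, int i,
                      std::vector<P3> &targets) {
  const int n = (int)coords.size();
  targets.clear();
  const P3 &base = (i == 0) ? coords[1] : coords[i - 1];
  for (int k = 0; k < 12; ++k) {
    P3 t{base.x + BV[k][0], base.y + BV[k][1], base.z + BV[k][2]};
    if (occ.find(pack(t.x, t.y, t.z)) != occ.end()) continue;
    if (i > 0 && i < n - 1 && !adjacent(t, coords[i + 1])) continue;
    targets.push_back(t);
  }
}

// One re-sampled suffix per start position; each re-sample is retried until
// the conformation validates or the retry budget is spent.
bool rotate_suffix(Workspace &ws, const std::vector<int> &dirs, int start,
                   int retries, std::vector<int> &out, std::vector<P3> &c) {
  const int L = (int)dirs.size();
  for (int a = 0; a < retries; ++a) {
    out = dirs;
    for (int k = start; k < L; ++k) {
      int d = (int)(unif_rand() * 12.0);
      if (d > 11) d = 11;
      out[k] = d;
    }
    decode(out, c);
    if (valid_coords(ws, c)) return true;
  }
  return false;
}

}  // namespace

Cand exhaustive_pull(const std::vector<int> &dirs, const std::vector<int> &seq,
                     const double *E, long long &n_evals) {
  std::vector<P3> coords;
  decode(dirs, coords);
  OccMap occ;
  build_occ(coords, occ);
  const int n = (int)coords.size();
  Workspace ws;
  ws.init(n);
  BestCoords best;
  std::vector<P3> targets, scratch;
  double e;
  for (int i = 0; i < n; ++i) {
    for (int side = 0; side < 2; ++side) {
      int d = side == 0 ? 1 : -1;
      pull_targets(coords, occ, i, d, targets);
      for (size_t t = 0; t < targets.size(); ++t) {
        construct_pull(coords, i, d, targets[t], scratch);
        if (score_coords(ws, scratch, seq, E, e)) {
          ++n_evals;
          best.offer(scratch, e);
        }
      }
    }
  }
  return finish(best);
}

Cand exhaustive_diagonal(const std::vector<int> &dirs,
                         const std::vector<int> &seq, const double *E,
                         long long &n_evals) {
  std::vector<P3> coords;
  decode(dirs, coords);
  OccMap occ;
  build_occ(coords, occ);
  const int n = (int)coords.size();
  Workspace ws;
  ws.init(n);
  BestCoords best;
  std::vector<P3> targets, scratch;
  double e;
  for (int i = 0; i < n; ++i) {
    diagonal_targets(coords, occ, i, targets);
    for (size_t t = 0; t < targets.size(); ++t) {
      scratch = coords;
      scratch[i] = targets[t];
      if (score_coords(ws, scratch, seq, E, e)) {
        ++n_evals;
        best.offer(scratch, e);
      }
    }
  }
  return finish(best);
}

Cand exhaustive_rotation(const std::vector<int> &dirs,
                         const std::vector<int> &seq, const double *E,
                         int retries, long long &n_evals) {
  Cand best;
  best.feasible = false;
  const int L = (int)dirs.size();
  Workspace ws;
  ws.init(L + 1);
  std::vector<int> cdirs;
  std::vector<P3> c;
  double e;
  for (int s = 0; s < L; ++s) {
    if (!rotate_suffix(ws, dirs, s, retries, cdirs, c)) continue;
    if (!score_coords(ws, c, seq, E, e)) continue;  // always succeeds
    ++n_evals;
    if (!best.feasible || e < best.energy) {
      best.dirs = cdirs;
      best.energy = e;
      best.feasible = true;
    }
  }
  return best;
}

Cand exhaustive_crossover(const std::vector<int> &dirs1,
                          const std::vector<int> &dirs2,
                          const std::vector<int> &seq, const double *E,
                          long long &n_evals) {
  Cand best;
  best.feasible = false;
  const int L = (int)dirs1.size();
  Workspace ws;
  ws.init(L + 1);
  std::vector<int> child(L);
  std::vector<P3> c;
  double e;
  for (int cut = 1; cut < L; ++cut) {
    for (int which = 0; which < 2; ++which) {
      const std::vector<int> &head = which == 0 ? dirs1 : dirs2;
      const std::vector<int> &tail = which == 0 ? dirs2 : dirs1;
      for (int k = 0; k < cut; ++k) child[k] = head[k];
      for (int k = cut; k < L; ++k) child[k] = tail[k];
      decode(child, c);
      if (score_coords(ws, c, seq, E, e)) {
        ++n_evals;
        if (!best.feasible || e < best.energy) {
          best.dirs = child;
          best.energy = e;
          best.feasible = true;
        }
      }
    }
  }
  return best;
}

Cand random_pull(const std::vector<int> &dirs, const std::vector<int> &seq,
                 const double *E, int retries, long long &n_evals) {
  Cand out;
  out.feasible = false;
  std::vector<P3> coords, scratch;
  decode(dirs, coords);
  OccMap occ;
  build_occ(coords, occ);
  const int n = (int)coords.size();
  Workspace ws;
  ws.init(n);
  double e;
  for (int a = 0; a < retries; ++a) {
    int i = (int)(unif_rand() * n);
    if (i > n - 1) i = n - 1;
    int d = unif_rand() < 0.5 ? 1 : -1;
    int k = (int)(unif_rand() * 12.0);
    if (k > 11) k = 11;
    int anchor = i - d;
    const P3 &base = (anchor >= 0 && anchor < n) ? coords[anchor] : coords[i];
    P3 t{base.x + BV[k][0], base.y + BV[k][1], base.z + BV[k][2]};
    if (occ.find(pack(t.x, t.y, t.z)) != occ.end()) continue;
    construct_pull(coords, i, d, t, scratch);
    if (score_coords(ws, scratch, seq, E, e)) {
      ++n_evals;
      if (!encode(scratch, out.dirs))
        stop("internal error: pull candidate failed to re-encode");
      out.energy = e;
      out.feasible = true;
      return out;
    }
  }
  return out;
}

Cand random_diagonal(const std::vector<int> &dirs, const std::vector<int> &seq,
                     const double *E, int retries, long long &n_evals) {
  Cand out;
  out.feasible = false;
  std::vector<P3> coords, scratch;
  decode(dirs, coords);
  OccMap occ;
  build_occ(coords, occ);
  const int n = (int)coords.size();
  Workspace ws;
  ws.init(n);
  std::vector<P3> targets;
  double e;
  for (int a = 0; a < retries; ++a) {
    int i = (int)(unif_rand() * n);
    if (i > n - 1) i = n - 1;
    diagonal_targets(coords, occ, i, targets);
    if (targets.empty()) continue;
    int t = (int)(unif_rand() * targets.size());
    if (t >= (int)targets.size()) t = (int)targets.size() - 1;
    scratch = coords;
    scratch[i] = targets[t];
    if (score_coords(ws, scratch, seq, E, e)) {
      ++n_evals;
      if (!encode(scratch, out.dirs))
        stop("internal error: diagonal candidate failed to re-encode");
      out.energy = e;
      out.feasible = true;
      return out;
    }
  }
  return out;
}

Cand random_rotation(const std::vector<int> &dirs, const std::vector<int> &seq,
                     const double *E, int retries, long long &n_evals) {
  Cand out;
  out.feasible = false;
  const int L = (int)dirs.size();
  int s = (int)(unif_rand() * L);
  if (s > L - 1) s = L - 1;
  Workspace ws;
  ws.init(L + 1);
  std::vector<int> cdirs;
  std::vector<P3> c;
  if (!rotate_suffix(ws, dirs, s, retries, cdirs, c)) return out;
  double e;
  score_coords(ws, c, seq, E, e);
  ++n_evals;
  out.dirs = cdirs;
  out.energy = e;
  out.feasible = true;
  return out;
}

Cand random_crossover(const std::vector<int> &dirs1,
                      const std::vector<int> &dirs2,
                      const std::vector<int> &seq, const double *E,
                      long long &n_evals) {
  Cand out;
  out.feasible = false;
  const int L = (int)dirs1.size();
  if (L < 2) return out;
  int cut = 1 + (int)(unif_rand() * (L - 1));
  if (cut > L - 1) cut = L - 1;
  int which = unif_rand() < 0.5 ? 0 : 1;
  const std::vector<int> &head = which == 0 ? dirs1 : dirs2;
  const std::vector<int> &tail = which == 0 ? dirs2 : dirs1;
  std::vector<int> child(L);
  for (int k = 0; k < cut; ++k) child[k] = head[k];
  for (int k = cut; k < L; ++k) child[k] = tail[k];
  std::vector<P3> c;
  decode(child, c);
  Workspace ws;
  ws.init(L + 1);
  double e;
  if (!score_coords(ws, c, seq, E, e)) return out;
  ++n_evals;
  out.dirs = child;
  out.energy = e;
  out.feasible = true;
  return out;
}

bool random_pull_inplace(std::vector<int> &dirs, int retries) {
  std::vector<P3> coords, scratch;
  decode(dirs, coords);
  OccMap occ;
  build_occ(coords, occ);
  const int n = (int)coords.size();
  Workspace ws;
  ws.init(n);
  std::vector<int> cdirs;
  for (int a = 0; a < retries; ++a) {
    int i = (int)(unif_rand() * n);
    if (i > n - 1) i = n - 1;
    int d = unif_rand() < 0.5 ? 1 : -1;
    int k = (int)(unif_rand() * 12.0);
    if (k > 11) k = 11;
    int anchor = i - d;
    const P3 &base = (anchor >= 0 && anchor < n) ? coords[anchor] : coords[i];
    P3 t{base.x + BV[k][0], base.y + BV[k][1], base.z + BV[k][2]};
    if (occ.find(pack(t.x, t.y, t.z)) != occ.end()) continue;
    construct_pull(coords, i, d, t, scratch);
    if (!valid_coords(ws, scratch)) continue;
    if (!encode(scratch, cdirs)) continue;
    dirs = cdirs;
    return true;
  }
  return false;
}

}  // namespace gwfold

using namespace gwfold;

static std::vector<int> dirs0(const IntegerVector &directions) {
  std::vector<int> d(directions.size());
  for (int k = 0; k < directions.size(); ++k) {
    int v = directions[k];
    if (v == NA_INTEGER || v < 1 || v > 12)
      stop("direction index %d at position %d is outside 1..12", v, k + 1);
    d[k] = v - 1;
  }
  return d;
}

static IntegerVector dirs1(const std::vector<int> &d) {
  IntegerVector out((int)d.size());
  for (int k = 0; k < (int)d.size(); ++k) out[k] = d[k] + 1;
  return out;
}

// Single pull-move application: residue (1-based), drag side +1 (tail) or
// -1 (head), explicit target point. Returns the new direction string or
// NULL when infeasible.
// [[Rcpp::export]]
SEXP pull_move_cpp(IntegerVector directions, int residue, int side,
                   IntegerVector target) {
  std::vector<int> d = dirs0(directions);
  std::vector<P3> coords, scratch;
  decode(d, coords);
  OccMap occ;
  if (build_occ(coords, occ) >= 0) stop("conformation is not self-avoiding");
  const int n = (int)coords.size();
  int i = residue - 1;
  if (i < 0 || i >= n) stop("residue index out of range");
  P3 t{target[0], target[1], target[2]};
  if (occ.find(pack(t.x, t.y, t.z)) != occ.end()) return R_NilValue;
  int anchor = i - side;
  if (anchor >= 0 && anchor < n && !adjacent(t, coords[anchor]))
    return R_NilValue;
  if (!(anchor >= 0 && anchor < n) && !adjacent(t, coords[i]))
    return R_NilValue;
  construct_pull(coords, i, side, t, scratch);
  Workspace ws;
  ws.init(n);
  if (!valid_coords(ws, scratch)) return R_NilValue;
  std::vector<int> cdirs;
  if (!encode(scratch, cdirs)) return R_NilValue;
  return dirs1(cdirs);
}

// [[Rcpp::export]]
SEXP diagonal_move_cpp(IntegerVector directions, int residue,
                       IntegerVector target) {
  std::vector<int> d = dirs0(directions);
  std::vector<P3> coords;
  decode(d, coords);
  OccMap occ;
  if (build_occ(coords, occ) >= 0) stop("conformation is not self-avoiding");
  const int n = (int)coords.size();
  int i = residue - 1;
  if (i < 0 || i >= n) stop("residue index out of range");
  P3 t{target[0], target[1], target[2]};
  if (occ.find(pack(t.x, t.y, t.z)) != occ.end()) return R_NilValue;
  if (i > 0 && !adjacent(t, coords[i - 1])) return R_NilValue;
  if (i < n - 1 && !adjacent(t, coords[i + 1])) return R_NilValue;
  std::vector<P3> scratch = coords;
  scratch[i] = t;
  Workspace ws;
  ws.init(n);
  if (!valid_coords(ws, scratch)) return R_NilValue;
  std::vector<int> cdirs;
  if (!encode(scratch, cdirs)) return R_NilValue;
  return dirs1(cdirs);
}

// [[Rcpp::export]]
SEXP rotation_cpp(IntegerVector directions, int start, int retries) {
  std::vector<int> d = dirs0(directions);
  if (start < 1 || start > (int)d.size()) stop("start index out of range");
  Workspace ws;
  ws.init(d.size() + 1);
  std::vector<int> cdirs;
  std::vector<P3> c;
  if (!gwfold::rotate_suffix(ws, d, start - 1, retries, cdirs, c))
    return R_NilValue;
  return dirs1(cdirs);
}

// Apply k successive random feasible pull moves (no scoring).
// [[Rcpp::export]]
IntegerVector perturb_pulls_cpp(IntegerVector directions, int k, int retries) {
  std::vector<int> d = dirs0(directions);
  for (int a = 0; a < k; ++a) random_pull_inplace(d, retries);
  return dirs1(d);
}

// op: 1 = pull, 2 = crossover, 3 = diagonal, 4 = rotation.
// [[Rcpp::export]]
List exhaustive_move_cpp(int op, IntegerVector directions,
                         Nullable<IntegerVector> partner,
                         IntegerVector seq_codes, NumericMatrix E,
                         int rot_retries) {
  std::vector<int> d = dirs0(directions);
  if ((int)d.size() + 1 != seq_codes.size())
    stop("sequence length does not match conformation length");
  std::vector<int> s(seq_codes.begin(), seq_codes.end());
  long long n_evals = 0;
  Cand best;
  if (op == 1) {
    best = exhaustive_pull(d, s, REAL(E), n_evals);
  } else if (op == 2) {
    if (partner.isNull()) stop("crossover requires a partner conformation");
    std::vector<int> d2 = dirs0(IntegerVector(partner));
    if (d2.size() != d.size()) stop("parent conformations differ in length");
    best = exhaustive_crossover(d, d2, s, REAL(E), n_evals);
  } else if (op == 3) {
    best = exhaustive_diagonal(d, s, REAL(E), n_evals);
  } else if (op == 4) {
    best = exhaustive_rotation(d, s, REAL(E), rot_retries, n_evals);
  } else {
    stop("unknown operator code %d", op);
  }
  return List::create(
      _["feasible"] = best.feasible,
      _["directions"] = best.feasible ? (SEXP)dirs1(best.dirs) : R_NilValue,
      _["energy"] = best.feasible ? best.energy : NA_REAL,
      _["n_evaluations"] = (double)n_evals);
}
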