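#include "lattice.h"

using namespace Rcpp;

namespace gwfold {

std::vector<int> chain_growth(int n, int max_restarts) {
  std::vector<int> dirs(n - 1);
  std::vector<P3> coords;
  OccMap occ;
  for (int attempt = 0; attempt <= max_restarts; ++attempt) {
    coords.assign(1, P3{0, 0, 0});
    occ.clear();
    occ.emplace(pack(0, 0, 0), 0);
    bool dead = false;
    for (int k = 0; k < n - 1; ++k) {
      int free_dirs[12], nfree = 0;
      const P3 &h = coords.back();
      for (int d = 0; d < 12; ++d) {
        int64_t key = pack(h.x + BV[d][0], h.y + BV[d][1], h.z + BV[d][2]);
        if (occ.find(key) == occ.end()) free_dirs[nfree++] = d;
      }
      if (nfree == 0) {
        dead = true;
        break;
      }
      int pick = (int)(unif_rand() * nfree);
      if (pick >= nfree) pick = nfree - 1;
      int d = free_dirs[pick];
      P3 nxt{h.x + BV[d][0], h.y + BV[d][1], h.z + BV[d][2]};
      coords.push_back(nxt);
      occ.emplace(pack(nxt.x, nxt.y, nxt.z), (int)coords.size() - 1);
      dirs[k] = d;
    }
    if (!dead) return dirs;
  }
  stop("chain growth failed after %d restarts", max_restarts);
}

}  // namespace gwfold

using namespace gwfold;

static std::vector<int> dirs_from_r(const IntegerVector &directions) {
  std::vector<int> d(directions.size());
  for (int k = 0; k < directions.size(); ++k) {
    int v = directions[k];
    if (v == NA_INTEGER || v < 1 || v > 12)
      stop("direction index %d at position %d is outside 1..12", v, k + 1);
    d[k] = v - 1;
  }
  return d;
}

// [[Rcpp::export]]
IntegerMatrix decode_cpp(IntegerVector directions, IntegerVector origin) {
  std::vector<int> d = dirs_from_r(directions);
  std::vector<P3> c;
  decode(d, c);
  IntegerMatrix out((int)c.size(), 3);
  for (int i = 0; i < (int)c.size(); ++i) {
    out(i, 0) = c[i].x + origin[0];
    out(i, 1) = c[i].y + origin[1];
    out(i, 2) = c[i].z + origin[2];
  }
  return out;
}

// Returns 0 for a valid (self-avoiding) walk, else the 1-based index of the
// first residue occupying an already-used point.
// [[Rcpp::export]]
int validate_cpp(IntegerVector directions) {
  std::vector<int> d = dirs_from_r(directions);
  std::vector<P3> c;
  decode(d, c);
  OccMap occ;
  int col = build_occ(c, occ);
  return col < 0 ? 0 : col + 1;
}

// All contact pairs (a, b), a < b, b - a > 1, as a 2-column 1-based matrix.
// [[Rcpp::export]]
IntegerMatrix contacts_cpp(IntegerVector directions) {
  std::vector<int> d = dirs_from_r(directions);
  std::vector<P3> c;
  decode(d, c);
  OccMap occ;
  if (build_occ(c, occ) >= 0)
    stop("conformation is not self-avoiding");
  std::vector<std::pair<int, int>> pairs;
  for (size_t i = 0; i < c.size(); ++i) {
    for (int k = 0; k < 12; ++k) {
      int64_t key =
          pack(c[i].x + BV[k][0], c[i].y + BV[k][1], c[i].z + BV[k][2]);
      OccMap::const_iterator it = occ.find(key);
      if (it != occ.end() && it->second > (int)i + 1)
        pairs.push_back(std::make_pair((int)i + 1, it->second + 1));
    }
  }
  std::sort(pairs.begin(), pairs.end());
  IntegerMatrix out((int)pairs.size(), 2);
  for (int r = 0; r < (int)pairs.size(); ++r) {
    out(r, 0) = pairs[r].first;
    out(r, 1) = pairs[r].second;
  }
  return out;
}

// [[Rcpp::export]]
double energy_cpp(IntegerVector directions, IntegerVector seq_codes,
                  NumericMatrix E) {
  std::vector<int> d = dirs_from_r(directions);
  if ((int)d.size() + 1 != seq_codes.size())
    stop("sequence length (%d) does not match conformation length (%d)",
         (int)seq_codes.size(), (int)d.size() + 1);
  std::vector<P3> c;
  decode(d, c);
  OccMap occ;
  if (build_occ(c, occ) >= 0)
    stop("conformation is not self-avoiding");
  std::vector<int> s(seq_codes.begin(), seq_codes.end());
  return contact_energy(c, occ, s, REAL(E));
}

// [[Rcpp::export]]
IntegerVector chain_growth_cpp(int n, int max_restarts) {
  std::vector<int> d = chain_growth(n, max_restarts);
  IntegerVector out((int)d.size());
  for (int k = 0; k < (int)d.size(); ++k) out[k] = d[k] + 1;
  return out;
}
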