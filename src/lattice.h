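#pragma once

#include <Rcpp.h>
#include <cstdint>
#include <cstdlib>
#include <unordered_map>
#include <vector>

namespace gwfold {

// The 12 FCC basis vectors, in the conventional printed order v1..v12.
// Every vector has components in {-1,0,1} and L1 norm 2; the set is closed
// under negation (v2 = -v1, v4 = -v3, ...).
static const int BV[12][3] = {
    {1, 1, 0},  {-1, -1, 0}, {-1, 1, 0}, {1, -1, 0},
    {0, 1, 1},  {0, 1, -1},  {0, -1, 1}, {0, -1, -1},
    {1, 0, 1},  {-1, 0, 1},  {1, 0, -1}, {-1, 0, -1}};

struct P3 {
  int x, y, z;
};

inline bool operator==(const P3 &a, const P3 &b) {
  return a.x == b.x && a.y == b.y && a.z == b.z;
}

// Pack integer coordinates into a single 64-bit key. Coordinates are bounded
// by the chain length (anchored at the origin), far below the 2^19 offset.
inline int64_t pack(int x, int y, int z) {
  const int64_t OFF = 1 << 19;
  return ((int64_t)(x + OFF) << 42) | ((int64_t)(y + OFF) << 21) |
         (int64_t)(z + OFF);
}

inline bool adjacent(const P3 &a, const P3 &b) {
  int dx = a.x - b.x, dy = a.y - b.y, dz = a.z - b.z;
  if (dx < -1 || dx > 1 || dy < -1 || dy > 1 || dz < -1 || dz > 1)
    return false;
  return std::abs(dx) + std::abs(dy) + std::abs(dz) == 2;
}

// Index (0-based) of the basis vector equal to (dx,dy,dz), or -1.
inline int dir_index(int dx, int dy, int dz) {
  for (int k = 0; k < 12; ++k)
    if (BV[k][0] == dx && BV[k][1] == dy && BV[k][2] == dz) return k;
  return -1;
}

typedef std::unordered_map<int64_t, int> OccMap;

// Decode 0-based direction codes into coordinates anchored at the origin.
inline void decode(const std::vector<int> &dirs, std::vector<P3> &out) {
  size_t n = dirs.size() + 1;
  out.resize(n);
  out[0] = P3{0, 0, 0};
  for (size_t k = 0; k < dirs.size(); ++k) {
    int d = dirs[k];
    out[k + 1].x = out[k].x + BV[d][0];
    out[k + 1].y = out[k].y + BV[d][1];
    out[k + 1].z = out[k].z + BV[d][2];
  }
}

// Re-encode coordinates as direction codes; false if any step is not a
// basis vector (chain constraint violated).
inline bool encode(const std::vector<P3> &c, std::vector<int> &dirs) {
  dirs.resize(c.size() - 1);
  for (size_t k = 0; k + 1 < c.size(); ++k) {
    int d = dir_index(c[k + 1].x - c[k].x, c[k + 1].y - c[k].y,
                      c[k + 1].z - c[k].z);
    if (d < 0) return false;
    dirs[k] = d;
  }
  return true;
}

// Build the occupancy map point -> residue index (0-based). Returns the
// 0-based index of the first residue that collides with an earlier one,
// or -1 if the walk is self-avoiding.
inline int build_occ(const std::vector<P3> &c, OccMap &occ) {
  occ.clear();
  occ.reserve(c.size() * 2);
  for (size_t i = 0; i < c.size(); ++i) {
    auto r = occ.emplace(pack(c[i].x, c[i].y, c[i].z), (int)i);
    if (!r.second) return (int)i;
  }
  return -1;
}

// Sum of matrix entries over all contacts: residue pairs (i,j), j > i+1,
// whose points are FCC-adjacent. E is a 20x20 column-major matrix indexed by
// 0-based residue codes; symmetric, so orientation does not matter.
inline double contact_energy(const std::vector<P3> &c, const OccMap &occ,
                             const std::vector<int> &seq, const double *E) {
  double tot = 0.0;
  const size_t n = c.size();
  for (size_t i = 0; i < n; ++i) {
    for (int k = 0; k < 12; ++k) {
      int64_t key =
          pack(c[i].x + BV[k][0], c[i].y + BV[k][1], c[i].z + BV[k][2]);
      OccMap::const_iterator it = occ.find(key);
      if (it != occ.end()) {
        int j = it->second;
        if (j > (int)i + 1) tot += E[seq[i] + 20 * seq[j]];
      }
    }
  }
  return tot;
}

// Validate + score a coordinate candidate in one pass. On success fills the
// re-encoded direction codes and the energy; returns false for any chain or
// self-avoidance violation.
inline bool eval_coords(const std::vector<P3> &c, const std::vector<int> &seq,
                        const double *E, std::vector<int> &dirs_out,
                        double &energy_out) {
  if (!encode(c, dirs_out)) return false;
  OccMap occ;
  if (build_occ(c, occ) >= 0) return false;
  energy_out = contact_energy(c, occ, seq, E);
  return true;
}

// Reusable open-addressing occupancy table for the candidate-scoring hot
// path: linear probing over a power-of-two slot array, with a generation
// stamp so that clearing between candidates is O(1).
struct FlatOcc {
  std::vector<int64_t> keys;
  std::vector<int> vals;
  std::vector<uint32_t> stamps;
  uint32_t gen;
  size_t mask;

  void init(size_t n) {
    size_t cap = 16;
    while (cap < 8 * n) cap <<= 1;
    keys.assign(cap, 0);
    vals.assign(cap, 0);
    stamps.assign(cap, 0);
    gen = 0;
    mask = cap - 1;
  }
  void clear() {
    if (++gen == 0) {
      std::fill(stamps.begin(), stamps.end(), 0u);
      gen = 1;
    }
  }
  static inline size_t hash64(int64_t k) {
    uint64_t x = (uint64_t)k;
    x ^= x >> 33;
    x *= 0xff51afd7ed558ccdULL;
    x ^= x >> 29;
    return (size_t)x;
  }
  // false when the key is already present (collision)
  inline bool insert(int64_t key, int val) {
    size_t h = hash64(key) & mask;
    while (stamps[h] == gen) {
      if (keys[h] == key) return false;
      h = (h + 1) & mask;
    }
    stamps[h] = gen;
    keys[h] = key;
    vals[h] = val;
    return true;
  }
  inline int find(int64_t key) const {
    size_t h = hash64(key) & mask;
    while (stamps[h] == gen) {
      if (keys[h] == key) return vals[h];
      h = (h + 1) & mask;
    }
    return -1;
  }
};

// Scoring workspace shared across the candidates of one operator sweep.
struct Workspace {
  FlatOcc occ;
  std::vector<P3> scratch;
  void init(size_t n) { occ.init(n); }
};

// Validate (chain bonds + self-avoidance) and score coordinates against the
// workspace table. Direction re-encoding is deferred to the accepted best.
inline bool score_coords(Workspace &ws, const std::vector<P3> &c,
                         const std::vector<int> &seq, const double *E,
                         double &energy_out) {
  const size_t n = c.size();
  for (size_t k = 0; k + 1 < n; ++k)
    if (!adjacent(c[k], c[k + 1])) return false;
  ws.occ.clear();
  for (size_t i = 0; i < n; ++i)
    if (!ws.occ.insert(pack(c[i].x, c[i].y, c[i].z), (int)i)) return false;
  double tot = 0.0;
  for (size_t i = 0; i < n; ++i) {
    for (int k = 0; k < 12; ++k) {
      int j = ws.occ.find(
          pack(c[i].x + BV[k][0], c[i].y + BV[k][1], c[i].z + BV[k][2]));
      if (j > (int)i + 1) tot += E[seq[i] + 20 * seq[j]];
    }
  }
  energy_out = tot;
  return true;
}

// Validity only (bonds + self-avoidance), same workspace mechanics.
inline bool valid_coords(Workspace &ws, const std::vector<P3> &c) {
  const size_t n = c.size();
  for (size_t k = 0; k + 1 < n; ++k)
    if (!adjacent(c[k], c[k + 1])) return false;
  ws.occ.clear();
  for (size_t i = 0; i < n; ++i)
    if (!ws.occ.insert(pack(c[i].x, c[i].y, c[i].z), (int)i)) return false;
  return true;
}

// Random chain-growth: grow the walk one step at a time, sampling uniformly
// among directions leading to unoccupied points; restart on dead ends.
// Uses R's RNG (unif_rand) so results are reproducible under set.seed().
std::vector<int> chain_growth(int n, int max_restarts);

}  // namespace gwfold
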