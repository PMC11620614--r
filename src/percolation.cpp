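// Core of the sequence-space site-percolation simulator.
//
// Sequences of length L over an A-letter alphabet are indexed by their
// mixed-radix encoding (base A, position 0 least significant).  Functional
// status is assigned lazily: a counter-based hash of (seed, index) yields a
// uniform deviate that is compared against P_fs, so no A^L matrix is ever
// materialised and the assignment is identical across runs and platforms.
// Thresholding the *same* deviates at two occupation probabilities gives the
// monotone coupling used by the phase-transition sweep.

#include <Rcpp.h>
#include <cstdint>
#include <queue>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Uniform deviate in [0, 1) for one site, deterministic in (seed, index).
static inline double site_u(uint64_t seed_mix, uint64_t idx) {
  uint64_t h = splitmix64(seed_mix ^ splitmix64(idx));
  return (h >> 11) * (1.0 / 9007199254740992.0); // 2^-53
}

static inline uint64_t mix_seed(double seed) {
  return splitmix64(static_cast<uint64_t>(seed) + 0x51DE5FA5ULL);
}

// Single-substitution targets of code c (0-based) under the transition rule.
// rule 0: full (all A-1 other letters); rule 1: restricted, symmetric cyclic
// offsets supplied by the caller (guaranteed symmetric at construction).
struct Transitions {
  int A;
  int rule;
  std::vector<int> offsets; // used when rule == 1

  void targets(int c, std::vector<int>& out) const {
    out.clear();
    if (rule == 0) {
      for (int a = 0; a < A; ++a)
        if (a != c) out.push_back(a);
    } else {
      for (int d : offsets) {
        int a = c + d;
        a %= A;
        if (a < 0) a += A;
        out.push_back(a);
      }
    }
  }
};

static inline uint64_t encode(const std::vector<int>& codes, int A) {
  uint64_t idx = 0;
  for (int i = (int)codes.size() - 1; i >= 0; --i)
    idx = idx * (uint64_t)A + (uint64_t)codes[i];
  return idx;
}

static inline void decode(uint64_t idx, int L, int A, std::vector<int>& codes) {
  for (int i = 0; i < L; ++i) {
    codes[i] = (int)(idx % (uint64_t)A);
    idx /= (uint64_t)A;
  }
}

static inline int hamming(const std::vector<int>& a, const IntegerVector& b) {
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i)
    if (a[i] != b[(R_xlen_t)i]) ++d;
  return d;
}

// [[Rcpp::export(name = ".cpp_site_uniforms")]]
NumericVector cpp_site_uniforms(double seed, NumericVector idx) {
  uint64_t sm = mix_seed(seed);
  R_xlen_t n = idx.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = site_u(sm, (uint64_t)idx[i]);
  return out;
}

// Breadth-first traversal of the functional cluster containing `start0`
// (0-based codes).  Each sequence is hashed and examined at most once.
// Stops when `cap` functional members have been found (capped = true).
// When tol >= 0 the search also tests every functional member against the
// target sequence and exits early on a hit within Hamming distance tol.
// [[Rcpp::export(name = ".cpp_bfs")]]
List cpp_bfs(int L, int A, int rule, IntegerVector offsets,
             double p_fs, double seed, IntegerVector start0,
             double cap, bool force_start,
             IntegerVector target0, int tol, bool collect) {
  Transitions tr;
  tr.A = A;
  tr.rule = rule;
  tr.offsets = as<std::vector<int>>(offsets);

  uint64_t sm = mix_seed(seed);
  std::vector<int> codes(start0.begin(), start0.end());
  uint64_t start_idx = encode(codes, A);
  bool track_target = tol >= 0;

  std::unordered_set<uint64_t> examined; // every sequence ever hashed
  std::queue<uint64_t> frontier;
  std::vector<double> members;

  auto functional = [&](uint64_t idx) -> bool {
    if (force_start && idx == start_idx) return true;
    return site_u(sm, idx) < p_fs;
  };

  bool found = false;
  double size = 0;
  bool capped = false;

  examined.insert(start_idx);
  if (functional(start_idx)) {
    size = 1;
    frontier.push(start_idx);
    if (collect) members.push_back((double)start_idx);
    // every cluster member is functional (the forced start by construction),
    // so any member within tol of the target terminates a CFP
    if (track_target && hamming(codes, target0) <= tol) found = true;
  }

  std::vector<int> targets;
  std::vector<int> ncodes(L);

  while (!frontier.empty() && !found && !capped) {
    uint64_t cur = frontier.front();
    frontier.pop();
    decode(cur, L, A, codes);
    for (int pos = 0; pos < L && !found && !capped; ++pos) {
      uint64_t base = 1;
      for (int i = 0; i < pos; ++i) base *= (uint64_t)A;
      tr.targets(codes[pos], targets);
      for (int a : targets) {
        uint64_t nb = cur + base * (uint64_t)(a - codes[pos]);
        if (!examined.insert(nb).second) continue;
        if (site_u(sm, nb) < p_fs) {
          size += 1;
          if (collect) members.push_back((double)nb);
          if (track_target) {
            ncodes = codes;
            ncodes[pos] = a;
            if (hamming(ncodes, target0) <= tol) {
              found = true;
              break;
            }
          }
          if (size >= cap) {
            capped = true;
            break;
          }
          frontier.push(nb);
        }
      }
    }
  }

  List out = List::create(_["size"] = size, _["capped"] = capped,
                          _["found"] = found);
  if (collect) out["members"] = NumericVector(members.begin(), members.end());
  return out;
}
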