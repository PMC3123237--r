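// Per-seed MINE pipeline: breadth-first growth under the vwp/msp admission
// rules, iterative culling, optional trim. The graph arrives in CSR form
// (offsets + flat neighbour array, 1-based vertex ids, neighbours sorted
// ascending so index order is the byte-lexicographic tie-breaking order).

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

namespace {

inline double mod_value(double e_in, double e_out) {
  if (e_in == 0) return 0.0;
  if (e_out == 0) return R_PosInf;
  return e_in / e_out;
}

// Does `nw` exceed `old + sign * old * msp`?  sign = -1: no-decrease test
// (admission criterion A); sign = +1: strict improvement (criterion B,
// culling). +Inf conventions: finite vs +Inf is a decrease (fails both);
// +Inf vs +Inf is "no change" (passes the no-decrease test only when the
// tolerance is positive, never an improvement).
inline bool mod_improves(double nw, double old_mod, int sign, double msp) {
  if (old_mod == R_PosInf) {
    if (nw == R_PosInf) return sign < 0 && msp > 0;
    return false;
  }
  return nw > old_mod + sign * old_mod * msp;
}

struct Csr {
  const int* off;  // length n + 1, 0-based offsets into nbr
  const int* nbr;  // 1-based vertex ids
  int n;
  int deg(int v) const { return off[v] - off[v - 1]; }         // v is 1-based
  const int* begin(int v) const { return nbr + off[v - 1]; }
  const int* end(int v) const { return nbr + off[v]; }
};

int count_in(const Csr& g, int v, const std::vector<char>& in_cl) {
  int k = 0;
  for (const int* p = g.begin(v); p != g.end(v); ++p) k += in_cl[*p - 1];
  return k;
}

void cull(const Csr& g, std::vector<char>& in_cl, double& e_in, double& e_out,
          double msp) {
  // fixed point: scan members in ascending (lexicographic) order, remove the
  // first whose removal improves modularity beyond the tolerance, restart.
  std::vector<int> mem;
  for (int v = 1; v <= g.n; ++v)
    if (in_cl[v - 1]) mem.push_back(v);
  bool removed = true;
  while (removed) {
    removed = false;
    double old_mod = mod_value(e_in, e_out);
    for (size_t i = 0; i < mem.size(); ++i) {
      int v = mem[i];
      int k = count_in(g, v, in_cl);
      double ni = e_in - k;
      double no = e_out - (g.deg(v) - k) + k;
      if (mod_improves(mod_value(ni, no), old_mod, +1, msp)) {
        in_cl[v - 1] = 0;
        e_in = ni;
        e_out = no;
        mem.erase(mem.begin() + i);
        removed = true;
        break;
      }
    }
  }
}

void trim(const Csr& g, std::vector<char>& in_cl, double& e_in,
          double& e_out) {
  // single simultaneous pass against the pre-pass membership
  std::vector<int> drop;
  for (int v = 1; v <= g.n; ++v) {
    if (in_cl[v - 1] && count_in(g, v, in_cl) < 2) drop.push_back(v);
  }
  for (size_t i = 0; i < drop.size(); ++i) in_cl[drop[i] - 1] = 0;
  // recompute counts from scratch
  e_in = 0;
  e_out = 0;
  for (int v = 1; v <= g.n; ++v) {
    if (!in_cl[v - 1]) continue;
    int k = count_in(g, v, in_cl);
    e_in += k;
    e_out += g.deg(v) - k;
  }
  e_in /= 2;
}

}  // namespace

// [[Rcpp::export(name = ".mine_grow_core")]]
IntegerVector mine_grow_core(IntegerVector offsets, IntegerVector neighbours,
                             NumericVector weights, int seed, double vwp,
                             double msp, bool do_cull, bool do_trim) {
  Csr g{offsets.begin(), neighbours.begin(),
        static_cast<int>(offsets.size()) - 1};
  std::vector<char> in_cl(g.n, 0), visited(g.n, 0);
  std::vector<int> qn, qs;
  qn.reserve(64);
  qs.reserve(64);
  in_cl[seed - 1] = 1;
  visited[seed - 1] = 1;
  double e_in = 0, e_out = g.deg(seed);
  for (const int* p = g.begin(seed); p != g.end(seed); ++p) {
    qn.push_back(*p);
    qs.push_back(seed);
  }
  for (size_t head = 0; head < qn.size(); ++head) {
    int nd = qn[head], src = qs[head];
    if (visited[nd - 1]) continue;
    visited[nd - 1] = 1;
    int k = count_in(g, nd, in_cl);
    double ni = e_in + k;
    double no = e_out - k + (g.deg(nd) - k);
    double old_mod = mod_value(e_in, e_out);
    double new_mod = mod_value(ni, no);
    bool w_ok = weights[nd - 1] >= weights[src - 1] * (1.0 - vwp);
    bool admit = (w_ok && mod_improves(new_mod, old_mod, -1, msp)) ||
                 mod_improves(new_mod, old_mod, +1, msp);
    if (admit) {
      in_cl[nd - 1] = 1;
      e_in = ni;
      e_out = no;
      for (const int* p = g.begin(nd); p != g.end(nd); ++p) {
        if (!in_cl[*p - 1] && !visited[*p - 1]) {
          qn.push_back(*p);
          qs.push_back(nd);
        }
      }
    }
  }
  if (do_cull) cull(g, in_cl, e_in, e_out, msp);
  if (do_trim) trim(g, in_cl, e_in, e_out);
  std::vector<int> mem;
  for (int v = 1; v <= g.n; ++v)
    if (in_cl[v - 1]) mem.push_back(v);
  return wrap(mem);
}

// [[Rcpp::export(name = ".mine_trim_core")]]
IntegerVector mine_trim_core(IntegerVector offsets, IntegerVector neighbours,
                             IntegerVector members) {
  Csr g{offsets.begin(), neighbours.begin(),
        static_cast<int>(offsets.size()) - 1};
  std::vector<char> in_cl(g.n, 0);
  for (int i = 0; i < members.size(); ++i) in_cl[members[i] - 1] = 1;
  double e_in = 0, e_out = 0;
  trim(g, in_cl, e_in, e_out);
  std::vector<int> mem;
  for (int v = 1; v <= g.n; ++v)
    if (in_cl[v - 1]) mem.push_back(v);
  return wrap(mem);
}
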