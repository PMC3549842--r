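#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Signed permutation matrices (the 48 elements of the octahedral group) and
// their action on a lattice basis.  Both the FCC and the cubic basis are
// closed under all 48, but closure is verified rather than assumed.

struct SignedPerm { int perm[3]; int sign[3]; };

static std::vector<SignedPerm> all_signed_perms() {
  std::vector<SignedPerm> out;
  int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
  for (int p = 0; p < 6; ++p)
    for (int s = 0; s < 8; ++s) {
      SignedPerm sp;
      for (int a = 0; a < 3; ++a) {
        sp.perm[a] = perms[p][a];
        sp.sign[a] = (s >> a) & 1 ? -1 : 1;
      }
      out.push_back(sp);
    }
  return out;
}

static inline void apply_sp(const SignedPerm& sp, const int v[3], int out[3]) {
  for (int a = 0; a < 3; ++a) out[a] = sp.sign[a] * v[sp.perm[a]];
}

// Index of vector v in the basis, or -1.
static int basis_index(const IntegerMatrix& basis, const int v[3]) {
  for (int i = 0; i < basis.nrow(); ++i)
    if (basis(i, 0) == v[0] && basis(i, 1) == v[1] && basis(i, 2) == v[2]) return i;
  return -1;
}

// For each symmetry op closed on the basis, the induced permutation of
// basis indices (0-based).  Rows = ops, cols = basis indices.
static std::vector<std::vector<int>> direction_perms(const IntegerMatrix& basis) {
  std::vector<std::vector<int>> perms;
  int nb = basis.nrow();
  for (const SignedPerm& sp : all_signed_perms()) {
    std::vector<int> dp(nb);
    bool ok = true;
    for (int b = 0; b < nb && ok; ++b) {
      int v[3] = {basis(b, 0), basis(b, 1), basis(b, 2)}, w[3];
      apply_sp(sp, v, w);
      int idx = basis_index(basis, w);
      if (idx < 0) ok = false; else dp[b] = idx;
    }
    if (ok) perms.push_back(dp);
  }
  return perms;
}

// [[Rcpp::export]]
List cpp_lattice_symmetries(const IntegerMatrix& basis) {
  List out;
  for (const SignedPerm& sp : all_signed_perms()) {
    bool ok = true;
    for (int b = 0; b < basis.nrow() && ok; ++b) {
      int v[3] = {basis(b, 0), basis(b, 1), basis(b, 2)}, w[3];
      apply_sp(sp, v, w);
      if (basis_index(basis, w) < 0) ok = false;
    }
    if (!ok) continue;
    IntegerMatrix m(3, 3);
    for (int a = 0; a < 3; ++a) m(a, sp.perm[a]) = sp.sign[a];
    out.push_back(m);
  }
  return out;
}

// Depth-first enumeration of self-avoiding walks from the origin.  With
// canonical reduction, only direction sequences that are lexicographically
// minimal over the induced symmetry permutations are emitted — exactly one
// representative per rotation/reflection class (translation is quotiented
// by anchoring at the origin).
struct SawDfs {
  const IntegerMatrix& basis;
  int n, nb, side, off;
  std::vector<int> grid;               // occupant index + 1, 0 = free
  std::vector<int> dirs;               // current direction sequence
  std::vector<int> px, py, pz;         // current walk
  std::vector<std::vector<int>> dperms;
  bool reduce;
  const LogicalVector* is_h;           // when scoring energy
  int best_contacts;
  double count;
  std::vector<int>* collect;           // flattened walks, or NULL

  SawDfs(const IntegerMatrix& basis_, int n_, bool reduce_)
      : basis(basis_), n(n_), nb(basis_.nrow()), reduce(reduce_),
        is_h(nullptr), best_contacts(0), count(0.0), collect(nullptr) {
    side = 2 * n + 1; off = n;
    grid.assign((size_t)side * side * side, 0);
    px.assign(n, 0); py.assign(n, 0); pz.assign(n, 0);
    if (reduce) dperms = direction_perms(basis);
  }

  inline int& cell(int x, int y, int z) {
    return grid[(size_t)(x + off) + side * ((size_t)(y + off) + side * (z + off))];
  }

  void emit(int placed) {
    count += 1.0;
    if (collect)
      for (int i = 0; i < placed; ++i) {
        collect->push_back(px[i]); collect->push_back(py[i]); collect->push_back(pz[i]);
      }
  }

  // active: indices into dperms whose image of the prefix equals the prefix
  void recurse(int placed, std::vector<int>& active, int h_contacts) {
    if (placed == n) { emit(placed); return; }
    int cx = px[placed - 1], cy = py[placed - 1], cz = pz[placed - 1];
    for (int d = 0; d < nb; ++d) {
      int x = cx + basis(d, 0), y = cy + basis(d, 1), z = cz + basis(d, 2);
      if (cell(x, y, z)) continue;
      std::vector<int> next_active;
      if (reduce) {
        bool minimal = true;
        for (int gi : active) {
          int dg = dperms[gi][d];
          if (dg < d) { minimal = false; break; }
          if (dg == d) next_active.push_back(gi);
        }
        if (!minimal) continue;
      }
      int hc = h_contacts;
      if (is_h && (*is_h)[placed]) {
        for (int b = 0; b < nb; ++b) {
          int j = cell(x + basis(b, 0), y + basis(b, 1), z + basis(b, 2));
          if (j > 0 && j - 1 <= placed - 2 && (*is_h)[j - 1]) ++hc;
        }
        // bound: even packing every remaining monomer cannot beat best?
        // (no pruning: desk-scale n keeps full enumeration cheap and exact)
      }
      px[placed] = x; py[placed] = y; pz[placed] = z;
      cell(x, y, z) = placed + 1;
      dirs.push_back(d);
      if (is_h && placed == n - 1 && hc > best_contacts) best_contacts = hc;
      if (placed == n - 1) emit(placed + 1);
      else recurse(placed + 1, reduce ? next_active : active, hc);
      dirs.pop_back();
      cell(x, y, z) = 0;
    }
  }

  void run() {
    cell(0, 0, 0) = 1;
    if (n == 1) { emit(1); return; }
    std::vector<int> active;
    if (reduce)
      for (size_t g = 0; g < dperms.size(); ++g) active.push_back((int)g);
    recurse(1, active, 0);
  }
};

// [[Rcpp::export]]
double cpp_saw_count(int n, const IntegerMatrix& basis, bool reduce) {
  SawDfs dfs(basis, n, reduce);
  dfs.run();
  return dfs.count;
}

// [[Rcpp::export]]
IntegerMatrix cpp_enumerate_saws(int n, const IntegerMatrix& basis, bool reduce) {
  SawDfs dfs(basis, n, reduce);
  std::vector<int> flat;
  dfs.collect = &flat;
  dfs.run();
  int nw = flat.size() / 3;
  IntegerMatrix out(nw, 3);
  for (int i = 0; i < nw; ++i) {
    out(i, 0) = flat[3 * i]; out(i, 1) = flat[3 * i + 1]; out(i, 2) = flat[3 * i + 2];
  }
  return out;
}

// Exhaustive optimum of the HP energy over all self-avoiding walks of the
// sequence, using symmetry-reduced enumeration (energy is an isometry
// invariant, so one representative per class suffices).
// [[Rcpp::export]]
List cpp_optimal_energy(const LogicalVector& is_h, const IntegerMatrix& basis) {
  int n = is_h.size();
  SawDfs dfs(basis, n, true);
  dfs.is_h = &is_h;
  dfs.run();
  return List::create(_["energy"] = -dfs.best_contacts,
                      _["n_walks"] = dfs.count);
}
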