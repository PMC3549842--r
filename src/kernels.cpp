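#include <Rcpp.h>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

// Coordinates are small signed integers; pack a lattice point into one
// 64-bit key (exact for |coord| < 2^20, far beyond any chain we handle).
static inline int64_t pack_point(int x, int y, int z) {
  const int64_t off = 1 << 20;
  return (int64_t)(x + off) | ((int64_t)(y + off) << 21) | ((int64_t)(z + off) << 42);
}

// Membership test for "q - p is a basis vector".  Basis components are in
// [-1, 1] for the lattices we support, so a 125-slot table indexed by the
// shifted difference is exact and branch-cheap.
struct BasisSet {
  bool tab[125];
  BasisSet(const IntegerMatrix& basis) {
    for (int i = 0; i < 125; ++i) tab[i] = false;
    for (int i = 0; i < basis.nrow(); ++i)
      tab[(basis(i, 0) + 2) + 5 * (basis(i, 1) + 2) + 25 * (basis(i, 2) + 2)] = true;
  }
  inline bool contact(int dx, int dy, int dz) const {
    if (dx < -2 || dx > 2 || dy < -2 || dy > 2 || dz < -2 || dz > 2) return false;
    return tab[(dx + 2) + 5 * (dy + 2) + 25 * (dz + 2)];
  }
};

// Raw column views of an n x 3 integer coordinate matrix.
struct Coords {
  const int *x, *y, *z;
  int n;
  Coords(const IntegerMatrix& m) : x(m.begin()), y(m.begin() + m.nrow()),
                                   z(m.begin() + 2 * m.nrow()), n(m.nrow()) {}
};

static inline double dv_term(double d, bool literal) {
  double dv = literal ? d * d - 2.0 : d - 2.0;
  return dv * dv;
}

// [[Rcpp::export]]
int cpp_hp_energy(const IntegerMatrix& coords, const LogicalVector& is_h,
                  const IntegerMatrix& basis) {
  BasisSet bs(basis);
  Coords c(coords);
  const int* h = is_h.begin();
  int contacts = 0;
  for (int i = 0; i < c.n; ++i) {
    if (!h[i]) continue;
    int xi = c.x[i], yi = c.y[i], zi = c.z[i];
    for (int j = i + 2; j < c.n; ++j) {
      if (!h[j]) continue;
      if (bs.contact(c.x[j] - xi, c.y[j] - yi, c.z[j] - zi)) ++contacts;
    }
  }
  return -contacts;
}

// [[Rcpp::export]]
double cpp_fitness(const IntegerMatrix& coords, const LogicalVector& is_h,
                   bool literal) {
  Coords c(coords);
  const int* h = is_h.begin();
  double f = 0.0;
  for (int i = 0; i < c.n; ++i) {
    if (!h[i]) continue;
    double xi = c.x[i], yi = c.y[i], zi = c.z[i];
    for (int j = i + 2; j < c.n; ++j) {
      if (!h[j]) continue;
      double dx = c.x[j] - xi, dy = c.y[j] - yi, dz = c.z[j] - zi;
      f += dv_term(dx * dx + dy * dy + dz * dz, literal);
    }
  }
  return f;
}

static double delta_fitness_raw(const Coords& c, const int* h, int i0,
                                int nx, int ny, int nz, bool literal) {
  if (!h[i0]) return 0.0;
  double xo = c.x[i0], yo = c.y[i0], zo = c.z[i0];
  double delta = 0.0;
  for (int j = 0; j < c.n; ++j) {
    if (j >= i0 - 1 && j <= i0 + 1) continue;  // consecutive or self
    if (!h[j]) continue;
    double xj = c.x[j], yj = c.y[j], zj = c.z[j];
    double dxo = xo - xj, dyo = yo - yj, dzo = zo - zj;
    double dxn = nx - xj, dyn = ny - yj, dzn = nz - zj;
    delta += dv_term(dxn * dxn + dyn * dyn + dzn * dzn, literal) -
             dv_term(dxo * dxo + dyo * dyo + dzo * dzo, literal);
  }
  return delta;
}

// Fitness change from relocating monomer i0 (0-based) to np; touches only
// pairs involving i0.
// [[Rcpp::export]]
double cpp_delta_fitness(const IntegerMatrix& coords, const LogicalVector& is_h,
                         int i0, const IntegerVector& np, bool literal) {
  Coords c(coords);
  return delta_fitness_raw(c, is_h.begin(), i0, np[0], np[1], np[2], literal);
}

// [[Rcpp::export]]
int cpp_delta_energy(const IntegerMatrix& coords, const LogicalVector& is_h,
                     int i0, const IntegerVector& np, const IntegerMatrix& basis) {
  if (!is_h[i0]) return 0;
  BasisSet bs(basis);
  Coords c(coords);
  const int* h = is_h.begin();
  int xo = c.x[i0], yo = c.y[i0], zo = c.z[i0];
  int before = 0, after = 0;
  for (int j = 0; j < c.n; ++j) {
    if (j >= i0 - 1 && j <= i0 + 1) continue;
    if (!h[j]) continue;
    if (bs.contact(c.x[j] - xo, c.y[j] - yo, c.z[j] - zo)) ++before;
    if (bs.contact(c.x[j] - np[0], c.y[j] - np[1], c.z[j] - np[2])) ++after;
  }
  return before - after;  // energy_new - energy_old = -(after) + before
}

// All single-monomer moves for monomers of the requested type: target free
// and in contact with both chain neighbours (chain ends: the single
// neighbour, when allow_end_moves).  Returns a matrix with columns
// i (1-based), x, y, z, delta-fitness (0 for P moves).
// [[Rcpp::export]]
NumericMatrix cpp_generate_moves(const IntegerMatrix& coords, const LogicalVector& is_h,
                                 const IntegerMatrix& basis, bool want_h,
                                 bool allow_end_moves, bool literal) {
  Coords c(coords);
  const int* h = is_h.begin();
  int n = c.n, nb = basis.nrow();
  BasisSet bs(basis);
  std::unordered_set<int64_t> occ;
  occ.reserve(n * 2);
  for (int i = 0; i < n; ++i) occ.insert(pack_point(c.x[i], c.y[i], c.z[i]));

  std::vector<double> out;
  for (int i = 0; i < n; ++i) {
    if ((bool)h[i] != want_h) continue;
    if ((i == 0 || i == n - 1) && !allow_end_moves) continue;
    if (n == 1) continue;
    int anchor = (i == 0) ? 1 : i - 1;           // enumerate neighbours of one anchor
    bool interior = (i > 0 && i < n - 1);
    int ax = c.x[anchor], ay = c.y[anchor], az = c.z[anchor];
    int rx = 0, ry = 0, rz = 0;
    if (interior) { rx = c.x[i + 1]; ry = c.y[i + 1]; rz = c.z[i + 1]; }
    for (int b = 0; b < nb; ++b) {
      int qx = ax + basis(b, 0), qy = ay + basis(b, 1), qz = az + basis(b, 2);
      if (interior && !bs.contact(qx - rx, qy - ry, qz - rz)) continue;
      if (occ.count(pack_point(qx, qy, qz))) continue;
      double delta = want_h ? delta_fitness_raw(c, h, i, qx, qy, qz, literal) : 0.0;
      out.push_back(i + 1); out.push_back(qx); out.push_back(qy); out.push_back(qz);
      out.push_back(delta);
    }
  }
  int nm = out.size() / 5;
  NumericMatrix res(nm, 5);
  double* rp = res.begin();
  for (int r = 0; r < nm; ++r)
    for (int col = 0; col < 5; ++col) rp[r + (size_t)col * nm] = out[r * 5 + col];
  colnames(res) = CharacterVector::create("i", "x", "y", "z", "delta");
  return res;
}

// First-occurrence canonical encoding straight from coordinates.  `lut`
// maps the shifted step key (dx+1) + 3(dy+1) + 9(dz+1) to the 1-based
// basis index (NA for non-basis steps).
// [[Rcpp::export]]
IntegerVector cpp_noniso_coords(const IntegerMatrix& coords,
                                const IntegerVector& lut) {
  Coords c(coords);
  int n = c.n;
  if (n < 2) return IntegerVector(0);
  IntegerVector out(n - 1);
  int map[20];
  for (int i = 0; i < 20; ++i) map[i] = -1;
  int cnt = 0;
  const int* pl = lut.begin();
  int* po = out.begin();
  for (int i = 0; i < n - 1; ++i) {
    int dx = c.x[i + 1] - c.x[i], dy = c.y[i + 1] - c.y[i], dz = c.z[i + 1] - c.z[i];
    if (dx < -1 || dx > 1 || dy < -1 || dy > 1 || dz < -1 || dz > 1)
      stop("chain constraint violated at step %d", i + 1);
    int d = pl[(dx + 1) + 3 * (dy + 1) + 9 * (dz + 1)];
    if (d == NA_INTEGER) stop("chain constraint violated at step %d", i + 1);
    if (map[d] < 0) map[d] = cnt++;
    po[i] = map[d];
  }
  return out;
}

// [[Rcpp::export]]
int cpp_hamming(const IntegerVector& a, const IntegerVector& b) {
  int n = a.size(), d = 0;
  const int *pa = a.begin(), *pb = b.begin();
  for (int i = 0; i < n; ++i) d += (pa[i] != pb[i]);
  return d;
}

// True iff some stored column of `mem` (first `used` columns, one encoding
// per column) is within `proximity` symbol mismatches of `code`.
// [[Rcpp::export]]
bool cpp_match_any(const IntegerVector& code, const IntegerMatrix& mem,
                   int used, int proximity) {
  int len = code.size();
  const int* pc = code.begin();
  const int* base = mem.begin();
  for (int col = 0; col < used; ++col) {
    int d = 0;
    const int* pm = base + (size_t)col * mem.nrow();
    for (int i = 0; i < len; ++i) {
      d += (pc[i] != pm[i]);
      if (d > proximity) break;
    }
    if (d <= proximity) return true;
  }
  return false;
}
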