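// Determinant-based configuration interaction for closed-shell references:
// CISD (all single+double substitutions out of the RHF determinant) and full
// CI by string enumeration for few-electron systems.  Determinants are 64-bit
// occupation masks per spin; the Hamiltonian is assembled sparse via the
// Slater-Condon rules and the ground state extracted with a Lanczos solver.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

typedef uint64_t u64;

struct Det { u64 a, b; };

inline int popcnt(u64 x) { return __builtin_popcountll(x); }

inline void occ_list(u64 m, std::vector<int>& out) {
  out.clear();
  while (m) { int p = __builtin_ctzll(m); out.push_back(p); m &= m - 1; }
}

// parity sign for a^dagger_q a_p acting on mask (p occupied, q empty)
inline double exc_sign(u64 mask, int p, int q) {
  int lo = std::min(p, q) + 1, hi = std::max(p, q);
  if (lo >= hi) return 1.0;
  u64 window = (((u64)1 << hi) - 1) & ~((((u64)1 << lo)) - 1);
  return (popcnt(mask & window) % 2) ? -1.0 : 1.0;
}

struct Ints {
  const double* h;    // norb x norb
  const double* eri;  // chemist (pq|rs), norb^4
  int n;
  double H(int p, int q) const { return h[p + (size_t)n * q]; }
  double V(int p, int q, int r, int s) const {  // (pq|rs)
    return eri[p + (size_t)n * (q + (size_t)n * (r + (size_t)n * s))];
  }
};

double diag_elem(const Det& d, const Ints& I, const std::vector<int>& oa,
                 const std::vector<int>& ob) {
  double e = 0.0;
  for (int p : oa) e += I.H(p, p);
  for (int p : ob) e += I.H(p, p);
  for (size_t i = 0; i < oa.size(); ++i)
    for (size_t j = i + 1; j < oa.size(); ++j)
      e += I.V(oa[i], oa[i], oa[j], oa[j]) - I.V(oa[i], oa[j], oa[j], oa[i]);
  for (size_t i = 0; i < ob.size(); ++i)
    for (size_t j = i + 1; j < ob.size(); ++j)
      e += I.V(ob[i], ob[i], ob[j], ob[j]) - I.V(ob[i], ob[j], ob[j], ob[i]);
  for (int p : oa)
    for (int q : ob) e += I.V(p, p, q, q);
  return e;
}

// Hamiltonian element between dets differing by exactly one alpha (or beta)
// spin orbital; `same` is the mask of the exciting spin in det I, p occupied
// in I only, q in J only; oa/ob are the occupied lists of det I.
double single_elem(const Ints& I, u64 same_mask, int p, int q,
                   const std::vector<int>& occ_same, const std::vector<int>& occ_other) {
  double v = I.H(p, q);
  for (int r : occ_same) {
    if (r == p) continue;
    v += I.V(p, q, r, r) - I.V(p, r, r, q);
  }
  for (int r : occ_other) v += I.V(p, q, r, r);
  return exc_sign(same_mask, p, q) * v;
}

// element between dets differing by a same-spin double p<q -> r<s
double double_same(const Ints& I, u64 mask, int p, int q, int r, int s) {
  double s1 = exc_sign(mask, p, r);
  u64 m1 = (mask ^ ((u64)1 << p)) | ((u64)1 << r);
  double s2 = exc_sign(m1, q, s);
  return s1 * s2 * (I.V(p, r, q, s) - I.V(p, s, q, r));
}

double double_opp(const Ints& I, u64 amask, u64 bmask, int p, int r, int q, int s) {
  return exc_sign(amask, p, r) * exc_sign(bmask, q, s) * I.V(p, r, q, s);
}

// classify a determinant pair; returns excitation degree (0,1,2) or -1
inline int degree(const Det& x, const Det& y) {
  int d = popcnt(x.a ^ y.a) + popcnt(x.b ^ y.b);
  if (d > 4) return -1;
  return d / 2;
}

double ham_elem(const Det& di, const Det& dj, const Ints& I,
                const std::vector<int>& oa, const std::vector<int>& ob) {
  u64 da = di.a ^ dj.a, db = di.b ^ dj.b;
  int na = popcnt(da), nb = popcnt(db);
  if (na + nb == 2) {  // single
    if (na == 2) {
      int p = __builtin_ctzll(da & di.a), q = __builtin_ctzll(da & dj.a);
      return single_elem(I, di.a, p, q, oa, ob);
    } else {
      int p = __builtin_ctzll(db & di.b), q = __builtin_ctzll(db & dj.b);
      return single_elem(I, di.b, p, q, ob, oa);
    }
  }
  // double
  if (na == 4) {
    u64 mi = da & di.a, mj = da & dj.a;
    int p = __builtin_ctzll(mi); mi &= mi - 1;
    int q = __builtin_ctzll(mi);
    int r = __builtin_ctzll(mj); mj &= mj - 1;
    int s = __builtin_ctzll(mj);
    return double_same(I, di.a, p, q, r, s);
  }
  if (nb == 4) {
    u64 mi = db & di.b, mj = db & dj.b;
    int p = __builtin_ctzll(mi); mi &= mi - 1;
    int q = __builtin_ctzll(mi);
    int r = __builtin_ctzll(mj); mj &= mj - 1;
    int s = __builtin_ctzll(mj);
    return double_same(I, di.b, p, q, r, s);
  }
  // one alpha + one beta
  int p = __builtin_ctzll(da & di.a), r = __builtin_ctzll(da & dj.a);
  int q = __builtin_ctzll(db & di.b), s = __builtin_ctzll(db & dj.b);
  return double_opp(I, di.a, di.b, p, r, q, s);
}

void gen_cisd(int norb, int nocc, std::vector<Det>& dets) {
  u64 ref = ((u64)1 << nocc) - 1;
  dets.push_back({ref, ref});
  std::vector<std::pair<int,int>> sx;  // (occ, virt)
  for (int i = 0; i < nocc; ++i)
    for (int a = nocc; a < norb; ++a) sx.push_back({i, a});
  auto ex1 = [&](u64 m, int i, int a) { return (m ^ ((u64)1 << i)) | ((u64)1 << a); };
  for (auto& s : sx) dets.push_back({ex1(ref, s.first, s.second), ref});  // alpha singles
  for (auto& s : sx) dets.push_back({ref, ex1(ref, s.first, s.second)}); // beta singles
  // same-spin doubles
  for (int i = 0; i < nocc; ++i)
    for (int j = i + 1; j < nocc; ++j)
      for (int a = nocc; a < norb; ++a)
        for (int b = a + 1; b < norb; ++b) {
          u64 m = ex1(ex1(ref, i, a), j, b);
          dets.push_back({m, ref});
          dets.push_back({ref, m});
        }
  // opposite-spin doubles
  for (auto& s1 : sx)
    for (auto& s2 : sx)
      dets.push_back({ex1(ref, s1.first, s1.second), ex1(ref, s2.first, s2.second)});
}

void gen_fci(int norb, int nocc, std::vector<Det>& dets) {
  std::vector<u64> strings;
  std::vector<int> idx(nocc);
  for (int i = 0; i < nocc; ++i) idx[i] = i;
  while (true) {
    u64 m = 0;
    for (int i : idx) m |= (u64)1 << i;
    strings.push_back(m);
    int k = nocc - 1;
    while (k >= 0 && idx[k] == norb - nocc + k) --k;
    if (k < 0) break;
    ++idx[k];
    for (int j = k + 1; j < nocc; ++j) idx[j] = idx[j - 1] + 1;
  }
  for (u64 a : strings)
    for (u64 b : strings) dets.push_back({a, b});
}

}  // namespace

// Solve the CI problem.  h: norb x norb MO core Hamiltonian; eri: norb^4
// chemist-notation MO integrals; mode "cisd" or "fci".  Returns electronic
// energy, the CI vector, the determinant count and the spin-summed 1-RDM in
// the MO basis.
// [[Rcpp::export]]
List cpp_ci_solve(arma::mat h, NumericVector eri, int norb, int nocc,
                  std::string mode, double tol = 1e-10) {
  if (norb > 63) stop("CI engine supports at most 63 orbitals");
  Ints I{h.memptr(), REAL(eri), norb};
  std::vector<Det> dets;
  if (mode == "fci") gen_fci(norb, nocc, dets);
  else gen_cisd(norb, nocc, dets);
  size_t dim = dets.size();
  if (dim > 200000) stop("CI space too large (%d determinants)", (int)dim);

  std::vector<std::vector<int>> oa(dim), ob(dim);
  for (size_t i = 0; i < dim; ++i) { occ_list(dets[i].a, oa[i]); occ_list(dets[i].b, ob[i]); }

  arma::vec evec;
  double e0;
  if (dim <= 1200) {
    arma::mat H(dim, dim, arma::fill::zeros);
    for (size_t i = 0; i < dim; ++i) {
      H(i, i) = diag_elem(dets[i], I, oa[i], ob[i]);
      for (size_t j = i + 1; j < dim; ++j) {
        if (degree(dets[i], dets[j]) < 0) continue;
        double v = ham_elem(dets[i], dets[j], I, oa[i], ob[i]);
        H(i, j) = H(j, i) = v;
      }
    }
    arma::vec ev; arma::mat V;
    arma::eig_sym(ev, V, H);
    e0 = ev(0);
    evec = V.col(0);
  } else {
    // sparse assembly
    std::vector<arma::uword> ri, cj;
    std::vector<double> vals;
    ri.reserve(dim * 40); cj.reserve(dim * 40); vals.reserve(dim * 40);
    for (size_t i = 0; i < dim; ++i) {
      double d = diag_elem(dets[i], I, oa[i], ob[i]);
      ri.push_back(i); cj.push_back(i); vals.push_back(d);
      for (size_t j = i + 1; j < dim; ++j) {
        if (degree(dets[i], dets[j]) < 0) continue;
        double v = ham_elem(dets[i], dets[j], I, oa[i], ob[i]);
        if (v == 0.0) continue;
        ri.push_back(i); cj.push_back(j); vals.push_back(v);
        ri.push_back(j); cj.push_back(i); vals.push_back(v);
      }
    }
    arma::umat locs(2, ri.size());
    for (size_t k = 0; k < ri.size(); ++k) { locs(0, k) = ri[k]; locs(1, k) = cj[k]; }
    arma::sp_mat H(locs, arma::vec(vals), dim, dim);
    arma::vec ev; arma::mat V;
    arma::eigs_opts opts;
    opts.tol = tol;
    opts.maxiter = 100000;
    bool ok = arma::eigs_sym(ev, V, H, 1, "sa", opts);
    if (!ok || ev.n_elem < 1) stop("sparse CI eigensolver failed to converge");
    e0 = ev(0);
    evec = V.col(0);
  }
  if (evec(0) < 0) evec = -evec;  // fix global phase to positive reference weight

  // spin-summed 1-RDM
  arma::mat rdm(norb, norb, arma::fill::zeros);
  for (size_t i = 0; i < dim; ++i) {
    double c2 = evec(i) * evec(i);
    for (int p : oa[i]) rdm(p, p) += c2;
    for (int p : ob[i]) rdm(p, p) += c2;
  }
  for (size_t i = 0; i < dim; ++i) {
    for (size_t j = i + 1; j < dim; ++j) {
      u64 da = dets[i].a ^ dets[j].a, db = dets[i].b ^ dets[j].b;
      int na = popcnt(da), nb = popcnt(db);
      if (na + nb != 2) continue;
      double cc = evec(i) * evec(j);
      if (cc == 0.0) continue;
      int p, q; double sgn;
      if (na == 2) {
        p = __builtin_ctzll(da & dets[i].a);
        q = __builtin_ctzll(da & dets[j].a);
        sgn = exc_sign(dets[i].a, p, q);
      } else {
        p = __builtin_ctzll(db & dets[i].b);
        q = __builtin_ctzll(db & dets[j].b);
        sgn = exc_sign(dets[i].b, p, q);
      }
      rdm(p, q) += sgn * cc;
      rdm(q, p) += sgn * cc;
    }
  }

  return List::create(_["energy"] = e0, _["rdm1"] = rdm,
                      _["n_det"] = (double)dim, _["c0"] = evec(0));
}
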