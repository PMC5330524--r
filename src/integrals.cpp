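// Gaussian-basis molecular integrals via the McMurchie-Davidson (Hermite
// expansion) scheme: overlap, kinetic, nuclear attraction, two-electron
// repulsion, analytic Fourier transforms of AO pair densities, and pointwise
// AO evaluation with derivatives.  Cartesian shells, any angular momentum
// the recursions support (tested through d).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Shell {
  int l;                    // angular momentum
  arma::vec3 A;             // center, bohr
  std::vector<double> exps;
  std::vector<double> coefs; // include primitive norms; contraction renormalized in R
  int nbf() const { return (l + 1) * (l + 2) / 2; }
};

// Cartesian component ordering: lx descending, then ly descending.
inline void components(int l, std::vector<std::array<int,3>>& out) {
  out.clear();
  for (int lx = l; lx >= 0; --lx)
    for (int ly = l - lx; ly >= 0; --ly)
      out.push_back({lx, ly, l - lx - ly});
}

std::vector<Shell> parse_basis(const List& basis) {
  std::vector<Shell> shells;
  for (R_xlen_t i = 0; i < basis.size(); ++i) {
    List sh = basis[i];
    Shell s;
    s.l = as<int>(sh["l"]);
    NumericVector A = sh["center"];
    s.A = {A[0], A[1], A[2]};
    s.exps  = as<std::vector<double>>(sh["exps"]);
    s.coefs = as<std::vector<double>>(sh["coefs"]);
    shells.push_back(s);
  }
  return shells;
}

int count_bf(const std::vector<Shell>& shells) {
  int n = 0;
  for (auto& s : shells) n += s.nbf();
  return n;
}

// 1-D Hermite expansion coefficients E[t + (Lt+1)*(i + (imax+1)*j)]
// for x^i_A x^j_B Gaussian product about P.
struct Etab {
  int imax, jmax, tmax;
  std::vector<double> E;
  double& at(int i, int j, int t) { return E[t + (size_t)(tmax + 1) * (i + (size_t)(imax + 1) * j)]; }
  double get(int i, int j, int t) const {
    if (t < 0 || t > i + j) return 0.0;
    return E[t + (size_t)(tmax + 1) * (i + (size_t)(imax + 1) * j)];
  }
};

Etab build_E(int imax, int jmax, double a, double b, double AB) {
  Etab T;
  T.imax = imax; T.jmax = jmax; T.tmax = imax + jmax;
  T.E.assign((size_t)(T.tmax + 1) * (imax + 1) * (jmax + 1), 0.0);
  double p = a + b, mu = a * b / p;
  double PA = -b / p * AB;  // P - A with AB = A - B
  double PB =  a / p * AB;  // P - B
  T.at(0, 0, 0) = std::exp(-mu * AB * AB);
  for (int i = 0; i <= imax; ++i) {
    for (int j = 0; j <= jmax; ++j) {
      if (i == 0 && j == 0) continue;
      for (int t = 0; t <= i + j; ++t) {
        double v;
        if (i > 0) {
          v = (t > 0 ? T.get(i - 1, j, t - 1) / (2.0 * p) : 0.0)
            + PA * T.get(i - 1, j, t)
            + (t + 1) * T.get(i - 1, j, t + 1);
        } else {
          v = (t > 0 ? T.get(i, j - 1, t - 1) / (2.0 * p) : 0.0)
            + PB * T.get(i, j - 1, t)
            + (t + 1) * T.get(i, j - 1, t + 1);
        }
        T.at(i, j, t) = v;
      }
    }
  }
  return T;
}

// Boys function F_m(x) for m = 0..mmax.
void boys(int mmax, double x, std::vector<double>& F) {
  F.assign(mmax + 1, 0.0);
  if (x < 1e-13) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0);
    return;
  }
  if (x > 35.0) {
    F[0] = 0.5 * std::sqrt(M_PI / x);
    double ex = (x < 700.0) ? std::exp(-x) : 0.0;
    for (int m = 0; m < mmax; ++m) F[m + 1] = ((2 * m + 1) * F[m] - ex) / (2.0 * x);
    return;
  }
  // series at mmax, then downward recursion
  double ex = std::exp(-x);
  double term = 1.0 / (2.0 * mmax + 1.0), sum = term;
  for (int k = 1; k < 400; ++k) {
    term *= 2.0 * x / (2.0 * mmax + 2.0 * k + 1.0);
    sum += term;
    if (term < 1e-17 * sum) break;
  }
  F[mmax] = ex * sum;
  for (int m = mmax; m > 0; --m) F[m - 1] = (2.0 * x * F[m] + ex) / (2.0 * m - 1.0);
}

// Hermite Coulomb integrals R^0_{tuv} by recursion.
double hermite_R(int t, int u, int v, int n, double p,
                 double X, double Y, double Z, const std::vector<double>& F) {
  if (t == 0 && u == 0 && v == 0) {
    double val = F[n];
    double f = -2.0 * p;
    for (int k = 0; k < n; ++k) val *= f;
    return val;
  }
  if (t > 0) {
    double r = X * hermite_R(t - 1, u, v, n + 1, p, X, Y, Z, F);
    if (t > 1) r += (t - 1) * hermite_R(t - 2, u, v, n + 1, p, X, Y, Z, F);
    return r;
  }
  if (u > 0) {
    double r = Y * hermite_R(t, u - 1, v, n + 1, p, X, Y, Z, F);
    if (u > 1) r += (u - 1) * hermite_R(t, u - 2, v, n + 1, p, X, Y, Z, F);
    return r;
  }
  double r = Z * hermite_R(t, u, v - 1, n + 1, p, X, Y, Z, F);
  if (v > 1) r += (v - 1) * hermite_R(t, u, v - 2, n + 1, p, X, Y, Z, F);
  return r;
}

inline double dfact(int n) {       // (2n-1)!! with n>=0 meaning odd double factorial
  double r = 1.0;
  for (int k = 2 * n - 1; k > 1; k -= 2) r *= k;
  return r;
}

}  // namespace

// Primitive normalization constant for Cartesian (i,j,k), exponent a.
// [[Rcpp::export]]
double cpp_prim_norm(double a, int i, int j, int k) {
  int l = i + j + k;
  double num = std::pow(2.0 * a / M_PI, 0.75) * std::pow(4.0 * a, 0.5 * l);
  return num / std::sqrt(dfact(i) * dfact(j) * dfact(k));
}

// Overlap and kinetic matrices.
// [[Rcpp::export]]
List cpp_overlap_kinetic(List basis) {
  auto shells = parse_basis(basis);
  int n = count_bf(shells);
  arma::mat S(n, n, arma::fill::zeros), T(n, n, arma::fill::zeros);
  std::vector<std::array<int,3>> ci, cj;

  int ioff = 0;
  for (size_t si = 0; si < shells.size(); ++si) {
    const Shell& sa = shells[si];
    components(sa.l, ci);
    int joff = 0;
    for (size_t sj = 0; sj < shells.size(); ++sj) {
      const Shell& sb = shells[sj];
      components(sb.l, cj);
      arma::vec3 AB = sa.A - sb.A;
      for (size_t pa = 0; pa < sa.exps.size(); ++pa) {
        for (size_t pb = 0; pb < sb.exps.size(); ++pb) {
          double a = sa.exps[pa], b = sb.exps[pb];
          double p = a + b;
          double cc = sa.coefs[pa] * sb.coefs[pb];
          double sp = std::sqrt(M_PI / p);
          // need j+2 for kinetic
          Etab Ex = build_E(sa.l, sb.l + 2, a, b, AB[0]);
          Etab Ey = build_E(sa.l, sb.l + 2, a, b, AB[1]);
          Etab Ez = build_E(sa.l, sb.l + 2, a, b, AB[2]);
          for (size_t u = 0; u < ci.size(); ++u) {
            for (size_t v = 0; v < cj.size(); ++v) {
              int i1 = ci[u][0], j1 = ci[u][1], k1 = ci[u][2];
              int i2 = cj[v][0], j2 = cj[v][1], k2 = cj[v][2];
              double Sx = Ex.get(i1, i2, 0) * sp;
              double Sy = Ey.get(j1, j2, 0) * sp;
              double Sz = Ez.get(k1, k2, 0) * sp;
              auto D2 = [&](Etab& E, int ii, int jj) {
                double t = 4.0 * b * b * E.get(ii, jj + 2, 0)
                         - 2.0 * b * (2 * jj + 1) * E.get(ii, jj, 0);
                if (jj >= 2) t += jj * (jj - 1) * E.get(ii, jj - 2, 0);
                return t * sp;
              };
              double Tx = -0.5 * D2(Ex, i1, i2);
              double Ty = -0.5 * D2(Ey, j1, j2);
              double Tz = -0.5 * D2(Ez, k1, k2);
              S(ioff + u, joff + v) += cc * Sx * Sy * Sz;
              T(ioff + u, joff + v) += cc * (Tx * Sy * Sz + Sx * Ty * Sz + Sx * Sy * Tz);
            }
          }
        }
      }
      joff += sb.nbf();
    }
    ioff += sa.nbf();
  }
  return List::create(_["S"] = S, _["T"] = T);
}

// Nuclear attraction matrix for nuclei (Z, position).
// [[Rcpp::export]]
arma::mat cpp_nuclear(List basis, NumericVector Zs, NumericMatrix pos) {
  auto shells = parse_basis(basis);
  int n = count_bf(shells);
  arma::mat V(n, n, arma::fill::zeros);
  std::vector<std::array<int,3>> ci, cj;
  std::vector<double> F;

  int ioff = 0;
  for (size_t si = 0; si < shells.size(); ++si) {
    const Shell& sa = shells[si];
    components(sa.l, ci);
    int joff = 0;
    for (size_t sj = 0; sj < shells.size(); ++sj) {
      const Shell& sb = shells[sj];
      components(sb.l, cj);
      arma::vec3 AB = sa.A - sb.A;
      int ltot = sa.l + sb.l;
      for (size_t pa = 0; pa < sa.exps.size(); ++pa) {
        for (size_t pb = 0; pb < sb.exps.size(); ++pb) {
          double a = sa.exps[pa], b = sb.exps[pb];
          double p = a + b;
          double cc = sa.coefs[pa] * sb.coefs[pb];
          arma::vec3 P = (a * sa.A + b * sb.A) / p;
          Etab Ex = build_E(sa.l, sb.l, a, b, AB[0]);
          Etab Ey = build_E(sa.l, sb.l, a, b, AB[1]);
          Etab Ez = build_E(sa.l, sb.l, a, b, AB[2]);
          for (int nuc = 0; nuc < Zs.size(); ++nuc) {
            arma::vec3 C = {pos(nuc, 0), pos(nuc, 1), pos(nuc, 2)};
            arma::vec3 PC = P - C;
            double r2 = arma::dot(PC, PC);
            boys(ltot, p * r2, F);
            for (size_t u = 0; u < ci.size(); ++u) {
              for (size_t v = 0; v < cj.size(); ++v) {
                int i1 = ci[u][0], j1 = ci[u][1], k1 = ci[u][2];
                int i2 = cj[v][0], j2 = cj[v][1], k2 = cj[v][2];
                double sum = 0.0;
                for (int t = 0; t <= i1 + i2; ++t)
                  for (int uu = 0; uu <= j1 + j2; ++uu)
                    for (int vv = 0; vv <= k1 + k2; ++vv) {
                      double e = Ex.get(i1, i2, t) * Ey.get(j1, j2, uu) * Ez.get(k1, k2, vv);
                      if (e == 0.0) continue;
                      sum += e * hermite_R(t, uu, vv, 0, p, PC[0], PC[1], PC[2], F);
                    }
                V(ioff + u, joff + v) += -Zs[nuc] * cc * (2.0 * M_PI / p) * sum;
              }
            }
          }
        }
      }
      joff += sb.nbf();
    }
    ioff += sa.nbf();
  }
  return V;
}

// Full two-electron repulsion tensor in chemist notation (mu nu | la si),
// returned as an nbf^4 vector, index mu + n*(nu + n*(la + n*si)).
// [[Rcpp::export]]
NumericVector cpp_eri(List basis) {
  auto shells = parse_basis(basis);
  int n = count_bf(shells);
  size_t n2 = (size_t)n * n;
  NumericVector out((R_xlen_t)(n2 * n2));
  double* eri = REAL(out);
  std::vector<std::array<int,3>> c1, c2, c3, c4;
  std::vector<double> F;

  std::vector<int> off(shells.size());
  { int o = 0; for (size_t i = 0; i < shells.size(); ++i) { off[i] = o; o += shells[i].nbf(); } }
  int ns = shells.size();

  for (int s1 = 0; s1 < ns; ++s1)
  for (int s2 = 0; s2 <= s1; ++s2)
  for (int s3 = 0; s3 <= s1; ++s3)
  for (int s4 = 0; s4 <= (s3 == s1 ? s2 : s3); ++s4) {
    const Shell &A = shells[s1], &B = shells[s2], &C = shells[s3], &D = shells[s4];
    components(A.l, c1); components(B.l, c2); components(C.l, c3); components(D.l, c4);
    int na = A.nbf(), nb = B.nbf(), nc = C.nbf(), nd = D.nbf();
    std::vector<double> block((size_t)na * nb * nc * nd, 0.0);
    arma::vec3 AB = A.A - B.A, CD = C.A - D.A;
    int ltot = A.l + B.l + C.l + D.l;

    for (size_t pa = 0; pa < A.exps.size(); ++pa)
    for (size_t pb = 0; pb < B.exps.size(); ++pb) {
      double a = A.exps[pa], b = B.exps[pb], p = a + b;
      arma::vec3 P = (a * A.A + b * B.A) / p;
      double cab = A.coefs[pa] * B.coefs[pb];
      Etab Ex1 = build_E(A.l, B.l, a, b, AB[0]);
      Etab Ey1 = build_E(A.l, B.l, a, b, AB[1]);
      Etab Ez1 = build_E(A.l, B.l, a, b, AB[2]);
      for (size_t pc = 0; pc < C.exps.size(); ++pc)
      for (size_t pd = 0; pd < D.exps.size(); ++pd) {
        double c = C.exps[pc], d = D.exps[pd], q = c + d;
        arma::vec3 Q = (c * C.A + d * D.A) / q;
        double ccd = C.coefs[pc] * D.coefs[pd];
        double alpha = p * q / (p + q);
        arma::vec3 PQ = P - Q;
        double r2 = arma::dot(PQ, PQ);
        boys(ltot, alpha * r2, F);
        double pref = 2.0 * std::pow(M_PI, 2.5) / (p * q * std::sqrt(p + q)) * cab * ccd;
        Etab Ex2 = build_E(C.l, D.l, c, d, CD[0]);
        Etab Ey2 = build_E(C.l, D.l, c, d, CD[1]);
        Etab Ez2 = build_E(C.l, D.l, c, d, CD[2]);
        size_t idx = 0;
        for (int u1 = 0; u1 < na; ++u1)
        for (int u2 = 0; u2 < nb; ++u2)
        for (int u3 = 0; u3 < nc; ++u3)
        for (int u4 = 0; u4 < nd; ++u4, ++idx) {
          int i1 = c1[u1][0], j1 = c1[u1][1], k1 = c1[u1][2];
          int i2 = c2[u2][0], j2 = c2[u2][1], k2 = c2[u2][2];
          int i3 = c3[u3][0], j3 = c3[u3][1], k3 = c3[u3][2];
          int i4 = c4[u4][0], j4 = c4[u4][1], k4 = c4[u4][2];
          double sum = 0.0;
          for (int t1 = 0; t1 <= i1 + i2; ++t1)
          for (int v1 = 0; v1 <= j1 + j2; ++v1)
          for (int w1 = 0; w1 <= k1 + k2; ++w1) {
            double e1 = Ex1.get(i1, i2, t1) * Ey1.get(j1, j2, v1) * Ez1.get(k1, k2, w1);
            if (e1 == 0.0) continue;
            for (int t2 = 0; t2 <= i3 + i4; ++t2)
            for (int v2 = 0; v2 <= j3 + j4; ++v2)
            for (int w2 = 0; w2 <= k3 + k4; ++w2) {
              double e2 = Ex2.get(i3, i4, t2) * Ey2.get(j3, j4, v2) * Ez2.get(k3, k4, w2);
              if (e2 == 0.0) continue;
              double sgn = ((t2 + v2 + w2) % 2 == 0) ? 1.0 : -1.0;
              sum += e1 * e2 * sgn *
                hermite_R(t1 + t2, v1 + v2, w1 + w2, 0, alpha, PQ[0], PQ[1], PQ[2], F);
            }
          }
          block[idx] += pref * sum;
        }
      }
    }

    // scatter with 8-fold permutational symmetry
    size_t idx = 0;
    for (int u1 = 0; u1 < na; ++u1)
    for (int u2 = 0; u2 < nb; ++u2)
    for (int u3 = 0; u3 < nc; ++u3)
    for (int u4 = 0; u4 < nd; ++u4, ++idx) {
      int mu = off[s1] + u1, nu = off[s2] + u2, la = off[s3] + u3, si = off[s4] + u4;
      double v = block[idx];
      auto put = [&](int a1, int a2, int a3, int a4) {
        eri[a1 + (size_t)n * (a2 + (size_t)n * (a3 + (size_t)n * a4))] = v;
      };
      put(mu, nu, la, si); put(nu, mu, la, si); put(mu, nu, si, la); put(nu, mu, si, la);
      put(la, si, mu, nu); put(si, la, mu, nu); put(la, si, nu, mu); put(si, la, nu, mu);
    }
  }
  out.attr("dim") = IntegerVector::create(n, n, n, n);
  return out;
}

// Analytic Fourier transform of AO pair densities:
//   I_h[mu,nu] = integral chi_mu(r) chi_nu(r) exp(2*pi*i q.r) dr
// for each row q (bohr^-1) of qmat.  I_h is complex symmetric for real AOs,
// so only the lower triangle is stored: returns (n*(n+1)/2 x nq) with
// column-major packed order (column j holds rows j..n-1).
// [[Rcpp::export]]
arma::cx_mat cpp_ft_blocks(List basis, arma::mat qmat) {
  auto shells = parse_basis(basis);
  int n = count_bf(shells);
  int nq = qmat.n_rows;
  std::vector<size_t> coloff(n);
  for (int j = 0; j < n; ++j) coloff[j] = (size_t)j * n - (size_t)j * (j - 1) / 2 - j;
  // packed index of (i >= j): coloff[j] + i
  arma::cx_mat out((size_t)n * (n + 1) / 2, nq, arma::fill::zeros);
  std::vector<std::array<int,3>> ci, cj;
  const std::complex<double> I(0.0, 1.0);

  int ioff = 0;
  for (size_t si = 0; si < shells.size(); ++si) {
    const Shell& sa = shells[si];
    components(sa.l, ci);
    int joff = 0;
    for (size_t sj = 0; sj <= si; ++sj) {
      const Shell& sb = shells[sj];
      components(sb.l, cj);
      arma::vec3 AB = sa.A - sb.A;
      for (size_t pa = 0; pa < sa.exps.size(); ++pa) {
        for (size_t pb = 0; pb < sb.exps.size(); ++pb) {
          double a = sa.exps[pa], b = sb.exps[pb], p = a + b;
          double cc = sa.coefs[pa] * sb.coefs[pb];
          arma::vec3 P = (a * sa.A + b * sb.A) / p;
          Etab Ex = build_E(sa.l, sb.l, a, b, AB[0]);
          Etab Ey = build_E(sa.l, sb.l, a, b, AB[1]);
          Etab Ez = build_E(sa.l, sb.l, a, b, AB[2]);
          double pref0 = cc * std::pow(M_PI / p, 1.5);
          int tmax = sa.l + sb.l;
          std::vector<std::complex<double>> Kpow(tmax + 1);
          for (int h = 0; h < nq; ++h) {
            double Kx = 2.0 * M_PI * qmat(h, 0);
            double Ky = 2.0 * M_PI * qmat(h, 1);
            double Kz = 2.0 * M_PI * qmat(h, 2);
            double K2 = Kx * Kx + Ky * Ky + Kz * Kz;
            double damp = std::exp(-K2 / (4.0 * p));
            if (damp * pref0 < 1e-16 && damp * pref0 > -1e-16) continue;
            double phase = Kx * P[0] + Ky * P[1] + Kz * P[2];
            std::complex<double> pref = pref0 * damp *
              std::complex<double>(std::cos(phase), std::sin(phase));
            // powers of (i K_axis)
            std::vector<std::complex<double>> px(tmax + 1), py(tmax + 1), pz(tmax + 1);
            px[0] = py[0] = pz[0] = 1.0;
            for (int t = 1; t <= tmax; ++t) {
              px[t] = px[t - 1] * (I * Kx);
              py[t] = py[t - 1] * (I * Ky);
              pz[t] = pz[t - 1] * (I * Kz);
            }
            for (size_t u = 0; u < ci.size(); ++u) {
              for (size_t v = 0; v < cj.size(); ++v) {
                int i1 = ci[u][0], j1 = ci[u][1], k1 = ci[u][2];
                int i2 = cj[v][0], j2 = cj[v][1], k2 = cj[v][2];
                std::complex<double> fx = 0.0, fy = 0.0, fz = 0.0;
                for (int t = 0; t <= i1 + i2; ++t) fx += Ex.get(i1, i2, t) * px[t];
                for (int t = 0; t <= j1 + j2; ++t) fy += Ey.get(j1, j2, t) * py[t];
                for (int t = 0; t <= k1 + k2; ++t) fz += Ez.get(k1, k2, t) * pz[t];
                std::complex<double> val = pref * fx * fy * fz;
                size_t mu = ioff + u, nu = joff + v;
                if (mu < nu) { if (si == sj) continue; std::swap(mu, nu); }
                out(coloff[nu] + mu, h) += val;
              }
            }
          }
        }
      }
      joff += sb.nbf();
    }
    ioff += sa.nbf();
  }
  return out;
}

// AO values on a set of points (npts x 3, bohr).  Returns npts x nbf.
// [[Rcpp::export]]
arma::mat cpp_ao_values(List basis, arma::mat pts) {
  auto shells = parse_basis(basis);
  int n = count_bf(shells);
  size_t np = pts.n_rows;
  arma::mat out(np, n, arma::fill::zeros);
  std::vector<std::array<int,3>> ci;

  int ioff = 0;
  for (auto& sh : shells) {
    components(sh.l, ci);
    for (size_t ip = 0; ip < np; ++ip) {
      double dx = pts(ip, 0) - sh.A[0];
      double dy = pts(ip, 1) - sh.A[1];
      double dz = pts(ip, 2) - sh.A[2];
      double r2 = dx * dx + dy * dy + dz * dz;
      double rad = 0.0;
      for (size_t pp = 0; pp < sh.exps.size(); ++pp)
        rad += sh.coefs[pp] * std::exp(-sh.exps[pp] * r2);
      if (rad == 0.0) continue;
      for (size_t u = 0; u < ci.size(); ++u) {
        double ang = 1.0;
        for (int t = 0; t < ci[u][0]; ++t) ang *= dx;
        for (int t = 0; t < ci[u][1]; ++t) ang *= dy;
        for (int t = 0; t < ci[u][2]; ++t) ang *= dz;
        out(ip, ioff + u) += ang * rad;
      }
    }
    ioff += sh.nbf();
  }
  return out;
}

// AO value, gradient and Hessian at a single point.
// Returns nbf x 10: value, dx, dy, dz, dxx, dxy, dxz, dyy, dyz, dzz.
// [[Rcpp::export]]
arma::mat cpp_ao_derivs(List basis, arma::vec pt) {
  auto shells = parse_basis(basis);
  int n = count_bf(shells);
  arma::mat out(n, 10, arma::fill::zeros);
  std::vector<std::array<int,3>> ci;

  auto g012 = [](double x, int i, double a, double* g) {
    // g[0..2]: x^i e^{-a x^2} and first two derivatives
    double xi = 1.0;                       // x^i
    for (int t = 0; t < i; ++t) xi *= x;
    double xim1 = (i >= 1) ? ((i == 1) ? 1.0 : std::pow(x, i - 1)) : 0.0;
    double xim2 = (i >= 2) ? ((i == 2) ? 1.0 : std::pow(x, i - 2)) : 0.0;
    double ex = std::exp(-a * x * x);
    g[0] = xi * ex;
    g[1] = (i * xim1 - 2.0 * a * x * xi) * ex;
    g[2] = (i * (i - 1) * xim2 - 2.0 * a * (2 * i + 1) * xi + 4.0 * a * a * x * x * xi) * ex;
  };

  int ioff = 0;
  for (auto& sh : shells) {
    components(sh.l, ci);
    double dx = pt[0] - sh.A[0], dy = pt[1] - sh.A[1], dz = pt[2] - sh.A[2];
    for (size_t pp = 0; pp < sh.exps.size(); ++pp) {
      double a = sh.exps[pp], c = sh.coefs[pp];
      for (size_t u = 0; u < ci.size(); ++u) {
        double gx[3], gy[3], gz[3];
        g012(dx, ci[u][0], a, gx);
        g012(dy, ci[u][1], a, gy);
        g012(dz, ci[u][2], a, gz);
        int r = ioff + u;
        out(r, 0) += c * gx[0] * gy[0] * gz[0];
        out(r, 1) += c * gx[1] * gy[0] * gz[0];
        out(r, 2) += c * gx[0] * gy[1] * gz[0];
        out(r, 3) += c * gx[0] * gy[0] * gz[1];
        out(r, 4) += c * gx[2] * gy[0] * gz[0];
        out(r, 5) += c * gx[1] * gy[1] * gz[0];
        out(r, 6) += c * gx[1] * gy[0] * gz[1];
        out(r, 7) += c * gx[0] * gy[2] * gz[0];
        out(r, 8) += c * gx[0] * gy[1] * gz[1];
        out(r, 9) += c * gx[0] * gy[0] * gz[2];
      }
    }
    ioff += sh.nbf();
  }
  return out;
}
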