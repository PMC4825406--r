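// Molecular integrals over contracted Cartesian Gaussians (s, p, d)
// via McMurchie-Davidson Hermite expansion.
//
// Conventions:
//  - all coordinates arriving here are in bohr;
//  - shells are primitive-normalized on the R side; the per-component
//    contracted normalization is also applied on the R side;
//  - Cartesian component order within a shell: s; x,y,z;
//    xx,xy,xz,yy,yz,zz.
//  - attraction integrals are returned as sum_c q_c (i|1/r_c|j), i.e. the
//    *positive* Coulomb kernel; the sign convention for electrons is
//    applied by the caller.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

static const int MAXL = 2;           // angular momentum ceiling (d functions)
static const double BOYS_SWITCH = 35.0;  // series below, asymptotic above

// ---------------------------------------------------------------- Boys F_n
// F_n(x) = int_0^1 t^{2n} exp(-x t^2) dt.
// x < BOYS_SWITCH: evaluate F_nmax with the exp(-x)-damped ascending series
//   F_n(x) = e^-x * sum_i (2x)^i / ((2n+1)(2n+3)...(2n+2i+1)),
// then recur downward (stable).  x >= BOYS_SWITCH: F_0 ~ sqrt(pi/x)/2 with
// the exp(-x) tail below machine precision, then recur upward (stable for
// x >> n).
static void boys(int nmax, double x, double *F) {
  if (x < 1e-14) {
    for (int n = 0; n <= nmax; ++n) F[n] = 1.0 / (2.0 * n + 1.0);
    return;
  }
  if (x < BOYS_SWITCH) {
    double term = 1.0 / (2.0 * nmax + 1.0);
    double sum = term;
    for (int i = 1; i < 300; ++i) {
      term *= 2.0 * x / (2.0 * nmax + 2.0 * i + 1.0);
      sum += term;
      if (term < 1e-17 * sum) break;
    }
    double ex = std::exp(-x);
    F[nmax] = ex * sum;
    for (int n = nmax - 1; n >= 0; --n)
      F[n] = (2.0 * x * F[n + 1] + ex) / (2.0 * n + 1.0);
  } else {
    F[0] = 0.5 * std::sqrt(M_PI / x);
    double ex = std::exp(-x);
    for (int n = 0; n < nmax; ++n)
      F[n + 1] = ((2.0 * n + 1.0) * F[n] - ex) / (2.0 * x);
  }
}

// --------------------------------------------- Hermite expansion E_t^{ij}
// One dimension.  E indexed [i][j][t], i<=imax, j<=jmax, t<=i+j.
struct Etab {
  int imax, jmax;
  std::vector<double> v;  // (imax+1)*(jmax+1)*(imax+jmax+1)
  double &at(int i, int j, int t) {
    return v[(i * (jmax + 1) + j) * (imax + jmax + 1) + t];
  }
  double get(int i, int j, int t) const {
    if (t < 0 || t > i + j) return 0.0;
    return v[(i * (jmax + 1) + j) * (imax + jmax + 1) + t];
  }
};

static void hermite_E(int imax, int jmax, double a, double b,
                      double A, double B, Etab &E) {
  E.imax = imax; E.jmax = jmax;
  E.v.assign((imax + 1) * (jmax + 1) * (imax + jmax + 1), 0.0);
  double p = a + b, mu = a * b / p;
  double P = (a * A + b * B) / p;
  double XAB = A - B, XPA = P - A, XPB = P - B;
  E.at(0, 0, 0) = std::exp(-mu * XAB * XAB);
  for (int i = 0; i <= imax; ++i) {
    for (int j = 0; j <= jmax; ++j) {
      if (i == 0 && j == 0) continue;
      for (int t = 0; t <= i + j; ++t) {
        double val;
        if (i > 0) {
          val = (1.0 / (2.0 * p)) * E.get(i - 1, j, t - 1)
              + XPA * E.get(i - 1, j, t)
              + (t + 1.0) * E.get(i - 1, j, t + 1);
        } else {
          val = (1.0 / (2.0 * p)) * E.get(i, j - 1, t - 1)
              + XPB * E.get(i, j - 1, t)
              + (t + 1.0) * E.get(i, j - 1, t + 1);
        }
        E.at(i, j, t) = val;
      }
    }
  }
}

// ------------------------------------------ Hermite Coulomb integrals R_tuv
// R^0_{tuv}(p, PC) built by downward recursion in the auxiliary index.
struct Rtab {
  int tmax, umax, vmax;
  std::vector<double> v;
  double &at(int t, int u, int w) {
    return v[(t * (umax + 1) + u) * (vmax + 1) + w];
  }
};

static void hermite_R(int tmax, int umax, int vmax, double p,
                      double PCx, double PCy, double PCz, Rtab &R) {
  int nmax = tmax + umax + vmax;
  double T = p * (PCx * PCx + PCy * PCy + PCz * PCz);
  std::vector<double> F(nmax + 1);
  boys(nmax, T, F.data());
  // Rn[n][t][u][v] computed by DP over n descending
  int dt = tmax + 1, du = umax + 1, dv = vmax + 1;
  std::vector<double> cur(dt * du * dv, 0.0), nxt(dt * du * dv, 0.0);
  // start at n = nmax with only (0,0,0) valid; iterate n downward filling
  // entries with t+u+v <= nmax-n
  for (int n = nmax; n >= 0; --n) {
    std::fill(nxt.begin(), nxt.end(), 0.0);
    double base = std::pow(-2.0 * p, n) * F[n];
    for (int t = 0; t <= tmax; ++t)
      for (int u = 0; u <= umax; ++u)
        for (int w = 0; w <= vmax; ++w) {
          if (t + u + w > nmax - n) continue;
          double val;
          if (t == 0 && u == 0 && w == 0) {
            val = base;
          } else if (t > 0) {
            val = (t > 1 ? (t - 1) * cur[((t - 2) * du + u) * dv + w] : 0.0)
                + PCx * cur[((t - 1) * du + u) * dv + w];
          } else if (u > 0) {
            val = (u > 1 ? (u - 1) * cur[(t * du + (u - 2)) * dv + w] : 0.0)
                + PCy * cur[(t * du + (u - 1)) * dv + w];
          } else {
            val = (w > 1 ? (w - 1) * cur[(t * du + u) * dv + (w - 2)] : 0.0)
                + PCz * cur[(t * du + u) * dv + (w - 1)];
          }
          nxt[(t * du + u) * dv + w] = val;
        }
    std::swap(cur, nxt);
  }
  R.tmax = tmax; R.umax = umax; R.vmax = vmax;
  R.v = cur;
}

// ------------------------------------------------------- shell bookkeeping
// Cartesian components (lx,ly,lz) for angular momentum l.
static void components(int l, std::vector<std::array<int, 3>> &comp) {
  comp.clear();
  for (int lx = l; lx >= 0; --lx)
    for (int ly = l - lx; ly >= 0; --ly)
      comp.push_back({lx, ly, l - lx - ly});
}

struct Shell {
  int l;
  double x, y, z;                  // centre, bohr
  std::vector<double> exps, coefs; // primitive-normalized
  int offset;                      // first basis-function index (0-based)
  int ncomp() const { return (l + 1) * (l + 2) / 2; }
};

static std::vector<Shell> unpack_shells(const IntegerVector &sl,
                                        const NumericVector &sx,
                                        const NumericVector &sy,
                                        const NumericVector &sz,
                                        const IntegerVector &nprim,
                                        const NumericVector &exps,
                                        const NumericVector &coefs) {
  int ns = sl.size();
  std::vector<Shell> shells(ns);
  int off = 0, poff = 0;
  for (int s = 0; s < ns; ++s) {
    shells[s].l = sl[s];
    shells[s].x = sx[s]; shells[s].y = sy[s]; shells[s].z = sz[s];
    int np = nprim[s];
    shells[s].exps.assign(exps.begin() + poff, exps.begin() + poff + np);
    shells[s].coefs.assign(coefs.begin() + poff, coefs.begin() + poff + np);
    poff += np;
    shells[s].offset = off;
    off += shells[s].ncomp();
  }
  return shells;
}

static int total_nbf(const std::vector<Shell> &sh) {
  int n = 0;
  for (auto &s : sh) n += s.ncomp();
  return n;
}

// ------------------------------------------------- one-electron shell pairs
// block(ca, cb) of overlap and kinetic for a shell pair
static void pair_overlap_kinetic(const Shell &A, const Shell &B,
                                 std::vector<double> &Sblk,
                                 std::vector<double> &Tblk) {
  std::vector<std::array<int, 3>> ca, cb;
  components(A.l, ca); components(B.l, cb);
  int na = ca.size(), nb = cb.size();
  Sblk.assign(na * nb, 0.0);
  Tblk.assign(na * nb, 0.0);
  for (size_t ia = 0; ia < A.exps.size(); ++ia) {
    for (size_t ib = 0; ib < B.exps.size(); ++ib) {
      double a = A.exps[ia], b = B.exps[ib];
      double p = a + b, cc = A.coefs[ia] * B.coefs[ib];
      double sp = std::sqrt(M_PI / p);
      Etab Ex, Ey, Ez;
      // jmax+2 for the kinetic shifted overlaps
      hermite_E(A.l, B.l + 2, a, b, A.x, B.x, Ex);
      hermite_E(A.l, B.l + 2, a, b, A.y, B.y, Ey);
      hermite_E(A.l, B.l + 2, a, b, A.z, B.z, Ez);
      for (int m = 0; m < na; ++m) {
        for (int n = 0; n < nb; ++n) {
          int l1 = ca[m][0], m1 = ca[m][1], n1 = ca[m][2];
          int l2 = cb[n][0], m2 = cb[n][1], n2 = cb[n][2];
          double sx = Ex.get(l1, l2, 0) * sp;
          double sy = Ey.get(m1, m2, 0) * sp;
          double sz = Ez.get(n1, n2, 0) * sp;
          // 1-D kinetic: T_ij = -2b^2 S_{i,j+2} + b(2j+1) S_ij
          //              - j(j-1)/2 S_{i,j-2}
          double tx = -2.0 * b * b * Ex.get(l1, l2 + 2, 0) * sp
                      + b * (2.0 * l2 + 1.0) * sx
                      - 0.5 * l2 * (l2 - 1.0) *
                        (l2 >= 2 ? Ex.get(l1, l2 - 2, 0) * sp : 0.0);
          double ty = -2.0 * b * b * Ey.get(m1, m2 + 2, 0) * sp
                      + b * (2.0 * m2 + 1.0) * sy
                      - 0.5 * m2 * (m2 - 1.0) *
                        (m2 >= 2 ? Ey.get(m1, m2 - 2, 0) * sp : 0.0);
          double tz = -2.0 * b * b * Ez.get(n1, n2 + 2, 0) * sp
                      + b * (2.0 * n2 + 1.0) * sz
                      - 0.5 * n2 * (n2 - 1.0) *
                        (n2 >= 2 ? Ez.get(n1, n2 - 2, 0) * sp : 0.0);
          Sblk[m * nb + n] += cc * sx * sy * sz;
          Tblk[m * nb + n] += cc * (tx * sy * sz + sx * ty * sz + sx * sy * tz);
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_overlap_kinetic(IntegerVector sl, NumericVector sx, NumericVector sy,
                         NumericVector sz, IntegerVector nprim,
                         NumericVector exps, NumericVector coefs) {
  auto shells = unpack_shells(sl, sx, sy, sz, nprim, exps, coefs);
  int n = total_nbf(shells);
  NumericMatrix S(n, n), T(n, n);
  std::vector<double> Sblk, Tblk;
  for (size_t A = 0; A < shells.size(); ++A) {
    for (size_t B = A; B < shells.size(); ++B) {
      pair_overlap_kinetic(shells[A], shells[B], Sblk, Tblk);
      int na = shells[A].ncomp(), nb = shells[B].ncomp();
      for (int m = 0; m < na; ++m)
        for (int nn = 0; nn < nb; ++nn) {
          int i = shells[A].offset + m, j = shells[B].offset + nn;
          S(i, j) = S(j, i) = Sblk[m * nb + nn];
          T(i, j) = T(j, i) = Tblk[m * nb + nn];
        }
    }
  }
  return List::create(_["S"] = S, _["T"] = T);
}

// ------------------------------------------------------ nuclear attraction
// returns sum_c q_c (i | 1/|r-Rc| | j)  (positive kernel)
// [[Rcpp::export]]
NumericMatrix cpp_attraction(IntegerVector sl, NumericVector sx,
                             NumericVector sy, NumericVector sz,
                             IntegerVector nprim, NumericVector exps,
                             NumericVector coefs, NumericMatrix chg_pos,
                             NumericVector chg_q) {
  auto shells = unpack_shells(sl, sx, sy, sz, nprim, exps, coefs);
  int n = total_nbf(shells);
  NumericMatrix V(n, n);
  int nc = chg_q.size();
  if (nc == 0) return V;
  std::vector<std::array<int, 3>> ca, cb;
  for (size_t A = 0; A < shells.size(); ++A) {
    for (size_t B = A; B < shells.size(); ++B) {
      const Shell &shA = shells[A], &shB = shells[B];
      components(shA.l, ca); components(shB.l, cb);
      int na = ca.size(), nb = cb.size();
      std::vector<double> blk(na * nb, 0.0);
      for (size_t ia = 0; ia < shA.exps.size(); ++ia) {
        for (size_t ib = 0; ib < shB.exps.size(); ++ib) {
          double a = shA.exps[ia], b = shB.exps[ib];
          double p = a + b, cc = shA.coefs[ia] * shB.coefs[ib];
          double Px = (a * shA.x + b * shB.x) / p;
          double Py = (a * shA.y + b * shB.y) / p;
          double Pz = (a * shA.z + b * shB.z) / p;
          Etab Ex, Ey, Ez;
          hermite_E(shA.l, shB.l, a, b, shA.x, shB.x, Ex);
          hermite_E(shA.l, shB.l, a, b, shA.y, shB.y, Ey);
          hermite_E(shA.l, shB.l, a, b, shA.z, shB.z, Ez);
          int L = shA.l + shB.l;
          double pref = cc * 2.0 * M_PI / p;
          Rtab R;
          for (int c = 0; c < nc; ++c) {
            hermite_R(L, L, L, p, Px - chg_pos(c, 0), Py - chg_pos(c, 1),
                      Pz - chg_pos(c, 2), R);
            double q = chg_q[c];
            for (int m = 0; m < na; ++m) {
              for (int nn = 0; nn < nb; ++nn) {
                int l1 = ca[m][0], m1 = ca[m][1], n1 = ca[m][2];
                int l2 = cb[nn][0], m2 = cb[nn][1], n2 = cb[nn][2];
                double s = 0.0;
                for (int t = 0; t <= l1 + l2; ++t)
                  for (int u = 0; u <= m1 + m2; ++u)
                    for (int w = 0; w <= n1 + n2; ++w)
                      s += Ex.get(l1, l2, t) * Ey.get(m1, m2, u) *
                           Ez.get(n1, n2, w) * R.at(t, u, w);
                blk[m * nb + nn] += pref * q * s;
              }
            }
          }
        }
      }
      for (int m = 0; m < na; ++m)
        for (int nn = 0; nn < nb; ++nn) {
          int i = shA.offset + m, j = shB.offset + nn;
          V(i, j) = V(j, i) = blk[m * nb + nn];
        }
    }
  }
  return V;
}

// ------------------------------------------------ two-electron shell quartet
static void quartet(const Shell &A, const Shell &B, const Shell &C,
                    const Shell &D, std::vector<double> &blk) {
  std::vector<std::array<int, 3>> ca, cb, cc_, cd;
  components(A.l, ca); components(B.l, cb);
  components(C.l, cc_); components(D.l, cd);
  int na = ca.size(), nb = cb.size(), ncc = cc_.size(), nd = cd.size();
  blk.assign(na * nb * ncc * nd, 0.0);
  int Lb = A.l + B.l, Lk = C.l + D.l;
  for (size_t ia = 0; ia < A.exps.size(); ++ia)
  for (size_t ib = 0; ib < B.exps.size(); ++ib) {
    double a = A.exps[ia], b = B.exps[ib];
    double p = a + b;
    double Px = (a * A.x + b * B.x) / p;
    double Py = (a * A.y + b * B.y) / p;
    double Pz = (a * A.z + b * B.z) / p;
    Etab Ex1, Ey1, Ez1;
    hermite_E(A.l, B.l, a, b, A.x, B.x, Ex1);
    hermite_E(A.l, B.l, a, b, A.y, B.y, Ey1);
    hermite_E(A.l, B.l, a, b, A.z, B.z, Ez1);
    double cab = A.coefs[ia] * B.coefs[ib];
    for (size_t ic = 0; ic < C.exps.size(); ++ic)
    for (size_t id = 0; id < D.exps.size(); ++id) {
      double c = C.exps[ic], d = D.exps[id];
      double q = c + d;
      double Qx = (c * C.x + d * D.x) / q;
      double Qy = (c * C.y + d * D.y) / q;
      double Qz = (c * C.z + d * D.z) / q;
      Etab Ex2, Ey2, Ez2;
      hermite_E(C.l, D.l, c, d, C.x, D.x, Ex2);
      hermite_E(C.l, D.l, c, d, C.y, D.y, Ey2);
      hermite_E(C.l, D.l, c, d, C.z, D.z, Ez2);
      double alpha = p * q / (p + q);
      Rtab R;
      hermite_R(Lb + Lk, Lb + Lk, Lb + Lk, alpha,
                Px - Qx, Py - Qy, Pz - Qz, R);
      double pref = cab * C.coefs[ic] * D.coefs[id] *
                    2.0 * std::pow(M_PI, 2.5) / (p * q * std::sqrt(p + q));
      int idx = 0;
      for (int m = 0; m < na; ++m)
      for (int nn = 0; nn < nb; ++nn)
      for (int o = 0; o < ncc; ++o)
      for (int r = 0; r < nd; ++r, ++idx) {
        int l1 = ca[m][0] + cb[nn][0];   // max t (bra, x)
        int m1 = ca[m][1] + cb[nn][1];
        int n1 = ca[m][2] + cb[nn][2];
        int l2 = cc_[o][0] + cd[r][0];
        int m2 = cc_[o][1] + cd[r][1];
        int n2 = cc_[o][2] + cd[r][2];
        double s = 0.0;
        for (int t = 0; t <= l1; ++t) {
          double ex1 = Ex1.get(ca[m][0], cb[nn][0], t);
          if (ex1 == 0.0) continue;
          for (int u = 0; u <= m1; ++u) {
            double ey1 = Ey1.get(ca[m][1], cb[nn][1], u);
            if (ey1 == 0.0) continue;
            for (int w = 0; w <= n1; ++w) {
              double ez1 = Ez1.get(ca[m][2], cb[nn][2], w);
              if (ez1 == 0.0) continue;
              double e1 = ex1 * ey1 * ez1;
              for (int tt = 0; tt <= l2; ++tt) {
                double ex2 = Ex2.get(cc_[o][0], cd[r][0], tt);
                if (ex2 == 0.0) continue;
                for (int uu = 0; uu <= m2; ++uu) {
                  double ey2 = Ey2.get(cc_[o][1], cd[r][1], uu);
                  if (ey2 == 0.0) continue;
                  for (int ww = 0; ww <= n2; ++ww) {
                    double ez2 = Ez2.get(cc_[o][2], cd[r][2], ww);
                    if (ez2 == 0.0) continue;
                    double sign = ((tt + uu + ww) % 2 == 0) ? 1.0 : -1.0;
                    s += e1 * ex2 * ey2 * ez2 * sign *
                         R.at(t + tt, u + uu, w + ww);
                  }
                }
              }
            }
          }
        }
        blk[idx] += pref * s;
      }
    }
  }
}

// full ERI tensor (chemist notation (ij|kl)), raw normalization
// [[Rcpp::export]]
NumericVector cpp_eri_tensor(IntegerVector sl, NumericVector sx,
                             NumericVector sy, NumericVector sz,
                             IntegerVector nprim, NumericVector exps,
                             NumericVector coefs) {
  auto shells = unpack_shells(sl, sx, sy, sz, nprim, exps, coefs);
  int n = total_nbf(shells);
  NumericVector out((R_xlen_t)n * n * n * n);
  out.attr("dim") = IntegerVector::create(n, n, n, n);
  double *eri = out.begin();
  size_t N = n;
  std::vector<double> blk;
  int ns = shells.size();
  for (int A = 0; A < ns; ++A)
  for (int B = A; B < ns; ++B)
  for (int C = A; C < ns; ++C)
  for (int D = (C == A ? B : C); D < ns; ++D) {
    quartet(shells[A], shells[B], shells[C], shells[D], blk);
    int na = shells[A].ncomp(), nb = shells[B].ncomp();
    int nc = shells[C].ncomp(), nd = shells[D].ncomp();
    int idx = 0;
    for (int m = 0; m < na; ++m)
    for (int nn = 0; nn < nb; ++nn)
    for (int o = 0; o < nc; ++o)
    for (int r = 0; r < nd; ++r, ++idx) {
      size_t i = shells[A].offset + m, j = shells[B].offset + nn;
      size_t k = shells[C].offset + o, l = shells[D].offset + r;
      double v = blk[idx];
      eri[i + N * (j + N * (k + N * l))] = v;
      eri[j + N * (i + N * (k + N * l))] = v;
      eri[i + N * (j + N * (l + N * k))] = v;
      eri[j + N * (i + N * (l + N * k))] = v;
      eri[k + N * (l + N * (i + N * j))] = v;
      eri[l + N * (k + N * (i + N * j))] = v;
      eri[k + N * (l + N * (j + N * i))] = v;
      eri[l + N * (k + N * (j + N * i))] = v;
    }
  }
  return out;
}

// single shell-quartet block, raw normalization (on-demand / generator mode)
// [[Rcpp::export]]
NumericVector cpp_eri_quartet(IntegerVector sl, NumericVector sx,
                              NumericVector sy, NumericVector sz,
                              IntegerVector nprim, NumericVector exps,
                              NumericVector coefs, int A, int B, int C, int D) {
  auto shells = unpack_shells(sl, sx, sy, sz, nprim, exps, coefs);
  int ns = shells.size();
  if (A < 0 || B < 0 || C < 0 || D < 0 || A >= ns || B >= ns || C >= ns ||
      D >= ns)
    stop("shell quartet index out of range");
  std::vector<double> blk;
  quartet(shells[A], shells[B], shells[C], shells[D], blk);
  NumericVector out(blk.size());
  out.attr("dim") = IntegerVector::create(shells[D].ncomp(),
                                          shells[C].ncomp(),
                                          shells[B].ncomp(),
                                          shells[A].ncomp());
  std::copy(blk.begin(), blk.end(), out.begin());
  return out;
}

// direct-SCF J/K build: loops shell quartets, never stores the tensor.
// P is the (raw-normalization-scaled) density; returns J_ij = sum (ij|kl)P_kl
// and K_ij = sum (ik|jl) P_kl.
// [[Rcpp::export]]
List cpp_jk_direct(IntegerVector sl, NumericVector sx, NumericVector sy,
                   NumericVector sz, IntegerVector nprim, NumericVector exps,
                   NumericVector coefs, NumericMatrix P) {
  auto shells = unpack_shells(sl, sx, sy, sz, nprim, exps, coefs);
  int n = total_nbf(shells);
  if (P.nrow() != n || P.ncol() != n) stop("density dimension mismatch");
  NumericMatrix J(n, n), K(n, n);
  std::vector<double> blk;
  int ns = shells.size();
  for (int A = 0; A < ns; ++A)
  for (int B = 0; B < ns; ++B)
  for (int C = 0; C < ns; ++C)
  for (int D = 0; D < ns; ++D) {
    quartet(shells[A], shells[B], shells[C], shells[D], blk);
    int na = shells[A].ncomp(), nb = shells[B].ncomp();
    int nc = shells[C].ncomp(), nd = shells[D].ncomp();
    int idx = 0;
    for (int m = 0; m < na; ++m)
    for (int nn = 0; nn < nb; ++nn)
    for (int o = 0; o < nc; ++o)
    for (int r = 0; r < nd; ++r, ++idx) {
      int i = shells[A].offset + m, j = shells[B].offset + nn;
      int k = shells[C].offset + o, l = shells[D].offset + r;
      double v = blk[idx];
      J(i, j) += v * P(k, l);
      K(i, k) += v * P(j, l);
    }
  }
  return List::create(_["J"] = J, _["K"] = K);
}
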