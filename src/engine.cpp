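// Core compute kernels: energies, forces, overdamped Langevin (Brownian)
// integration with rigid groups, and Metropolis Monte Carlo sampling of
// coarse-grained bead systems in reduced units (lengths in sigma, energies
// in kBT, times in tau_B = gamma*sigma^2/kBT).
//
// The system is passed from R as a "pack": plain vectors/matrices prepared by
// packSystem().  All indices arriving from R are 1-based and converted here.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <array>
#include <cmath>
#include <cstdint>
#include <functional>
#include <queue>
#include <tuple>

using namespace Rcpp;

static const double PI_ = 3.14159265358979323846;

struct Bias {
  int type;                 // 0 = com_z, 1 = com_xy (radial from (x0,y0))
  std::vector<int> idx;
  std::vector<double> w;    // weights, sum to 1 (mass fractions)
  double k, c, x0, y0;
};

struct CvSpec {
  int type;                 // -1 none, 0 com_z, 1 com_xy
  std::vector<int> idx;
  std::vector<double> w;
  double x0, y0;
};

struct Sys {
  int n;
  double Lx, Ly, Lz;
  double cap;               // pair force-capping factor (r clamped to cap*s)
  double fMax;              // cap on |dV/dr| of pair/wall terms (BD safety)
  std::vector<double> radius, mass, gamma;
  std::vector<int> fixedb, grp;   // grp: -1 free, else group id
  // bonded terms
  std::vector<std::array<int,2>> bondIdx;
  std::vector<std::array<double,2>> bondPar;     // k, r0
  std::vector<std::array<int,3>> angIdx;
  std::vector<std::array<double,2>> angPar;      // k, theta0 (rad)
  std::vector<std::array<int,4>> dihIdx;
  std::vector<std::array<double,2>> dihPar;      // k, phi0 (rad)
  // pair tables (dense n x n, column-major like R)
  std::vector<double> pEps, pS, pRcut, pShift;
  std::vector<double> pS2, pRcut2;    // squared, for the fast path
  // walls: per bead, lower and upper (s, eps, rcut, active, shift)
  std::vector<std::array<double,5>> wallLo, wallHi;
  // rigid groups
  std::vector<std::vector<int>> groups;
  std::vector<double> gammaT, gammaR;
  // biases
  std::vector<Bias> biases;
  CvSpec cv;
  // chain bookkeeping for MC moves
  std::vector<int> chain;                       // ordered mobile chain beads
  std::vector<std::vector<int>> pivotTails;     // tail bead sets per chain pos
  std::vector<std::array<int,3>> crank;         // (bead, prev, next)
  int tiltPivot = -1;                           // anchor of global tilt moves
  std::vector<int> tiltSet;                     // beads rotated by a tilt
  // per-bead adjacency of bonded terms
  std::vector<std::vector<int>> bondsOf, angsOf, dihsOf, biasesOf;
};

static std::vector<int> asIdx0(SEXP v) {
  IntegerVector iv(v);
  std::vector<int> out(iv.size());
  for (int i = 0; i < iv.size(); ++i) out[i] = iv[i] - 1;
  return out;
}

static Sys buildSys(const List& pack) {
  Sys S;
  NumericMatrix pos = pack["pos"];
  S.n = pos.nrow();
  NumericVector box = pack["box"];
  S.Lx = box[0]; S.Ly = box[1]; S.Lz = box[2];
  S.cap = as<double>(pack["capFactor"]);
  S.fMax = pack.containsElementNamed("forceCap")
    ? as<double>(pack["forceCap"]) : 500.0;
  S.radius = as<std::vector<double>>(pack["radius"]);
  S.mass   = as<std::vector<double>>(pack["mass"]);
  S.gamma  = as<std::vector<double>>(pack["gamma"]);
  IntegerVector fx = pack["fixed"];
  S.fixedb = as<std::vector<int>>(fx);
  IntegerVector gr = pack["grp"];   // 0 for free, else 1-based group id
  S.grp.resize(S.n);
  for (int i = 0; i < S.n; ++i) S.grp[i] = gr[i] - 1;

  NumericMatrix B = pack["bonds"];
  for (int r = 0; r < B.nrow(); ++r) {
    S.bondIdx.push_back({(int)B(r,0)-1, (int)B(r,1)-1});
    S.bondPar.push_back({B(r,2), B(r,3)});
  }
  NumericMatrix A = pack["angles"];
  for (int r = 0; r < A.nrow(); ++r) {
    S.angIdx.push_back({(int)A(r,0)-1, (int)A(r,1)-1, (int)A(r,2)-1});
    S.angPar.push_back({A(r,3), A(r,4)});
  }
  NumericMatrix D = pack["dihedrals"];
  for (int r = 0; r < D.nrow(); ++r) {
    S.dihIdx.push_back({(int)D(r,0)-1, (int)D(r,1)-1, (int)D(r,2)-1, (int)D(r,3)-1});
    S.dihPar.push_back({D(r,4), D(r,5)});
  }

  NumericMatrix pe = pack["pairEps"], ps = pack["pairS"], pr = pack["pairRcut"];
  S.pEps.assign(pe.begin(), pe.end());
  S.pS.assign(ps.begin(), ps.end());
  S.pRcut.assign(pr.begin(), pr.end());
  S.pShift.resize(S.n * (size_t)S.n, 0.0);
  S.pS2.resize(S.pEps.size());
  S.pRcut2.resize(S.pEps.size());
  for (size_t q = 0; q < S.pEps.size(); ++q) {
    double rc = S.pRcut[q];
    S.pS2[q] = S.pS[q] * S.pS[q];
    S.pRcut2[q] = rc * rc;
    if (rc > 0) {
      double sr6 = std::pow(S.pS[q] / rc, 6);
      S.pShift[q] = 4.0 * S.pEps[q] * (sr6 * sr6 - sr6);
    }
  }

  NumericMatrix W = pack["wall"];   // n x 8: loS,loEps,loRcut,loAct,hiS,...
  bool shifted = as<bool>(pack["wallShifted"]);
  S.wallLo.resize(S.n); S.wallHi.resize(S.n);
  for (int i = 0; i < S.n; ++i) {
    for (int side = 0; side < 2; ++side) {
      double s = W(i, 4*side), eps = W(i, 4*side+1),
             rc = W(i, 4*side+2), act = W(i, 4*side+3);
      double sh = 0.0;
      if (act > 0 && shifted && rc > 0) {
        double sr6 = std::pow(s / rc, 6);
        sh = 4.0 * eps * (sr6 * sr6 - sr6);
      }
      std::array<double,5> wp = {s, eps, rc, act, sh};
      if (side == 0) S.wallLo[i] = wp; else S.wallHi[i] = wp;
    }
  }

  List gl = pack["groups"];
  for (int g = 0; g < gl.size(); ++g) S.groups.push_back(asIdx0(gl[g]));
  S.gammaT = as<std::vector<double>>(pack["gammaT"]);
  S.gammaR = as<std::vector<double>>(pack["gammaR"]);

  List bl = pack["biases"];
  for (int b = 0; b < bl.size(); ++b) {
    List one = bl[b];
    Bias bi;
    std::string ty = as<std::string>(one["type"]);
    bi.type = (ty == "com_z") ? 0 : 1;
    bi.idx = asIdx0(one["idx"]);
    bi.w = as<std::vector<double>>(one["w"]);
    bi.k = as<double>(one["k"]);
    bi.c = as<double>(one["center"]);
    bi.x0 = one.containsElementNamed("x0") ? as<double>(one["x0"]) : 0.0;
    bi.y0 = one.containsElementNamed("y0") ? as<double>(one["y0"]) : 0.0;
    S.biases.push_back(bi);
  }

  S.cv.type = -1;
  if (pack.containsElementNamed("cv")) {
    List cv = pack["cv"];
    if (cv.size() > 0) {
      std::string ty = as<std::string>(cv["type"]);
      S.cv.type = (ty == "com_z") ? 0 : 1;
      S.cv.idx = asIdx0(cv["idx"]);
      S.cv.w = as<std::vector<double>>(cv["w"]);
      S.cv.x0 = cv.containsElementNamed("x0") ? as<double>(cv["x0"]) : 0.0;
      S.cv.y0 = cv.containsElementNamed("y0") ? as<double>(cv["y0"]) : 0.0;
    }
  }

  if (pack.containsElementNamed("chain")) S.chain = asIdx0(pack["chain"]);
  if (pack.containsElementNamed("pivotTails")) {
    List pt = pack["pivotTails"];
    for (int p = 0; p < pt.size(); ++p) S.pivotTails.push_back(asIdx0(pt[p]));
  }
  if (pack.containsElementNamed("tiltPivot")) {
    S.tiltPivot = as<int>(pack["tiltPivot"]) - 1;
    S.tiltSet = asIdx0(pack["tiltSet"]);
  }
  if (pack.containsElementNamed("crank")) {
    NumericMatrix ck = pack["crank"];
    for (int r = 0; r < ck.nrow(); ++r)
      S.crank.push_back({(int)ck(r,0)-1, (int)ck(r,1)-1, (int)ck(r,2)-1});
  }

  S.bondsOf.resize(S.n); S.angsOf.resize(S.n);
  S.dihsOf.resize(S.n); S.biasesOf.resize(S.n);
  for (size_t t = 0; t < S.bondIdx.size(); ++t)
    for (int m = 0; m < 2; ++m) S.bondsOf[S.bondIdx[t][m]].push_back(t);
  for (size_t t = 0; t < S.angIdx.size(); ++t)
    for (int m = 0; m < 3; ++m) S.angsOf[S.angIdx[t][m]].push_back(t);
  for (size_t t = 0; t < S.dihIdx.size(); ++t)
    for (int m = 0; m < 4; ++m) S.dihsOf[S.dihIdx[t][m]].push_back(t);
  for (size_t t = 0; t < S.biases.size(); ++t)
    for (int i : S.biases[t].idx) S.biasesOf[i].push_back(t);
  return S;
}

typedef std::vector<std::array<double,3>> Coords;

static Coords asCoords(const NumericMatrix& m) {
  Coords x(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) x[i] = {m(i,0), m(i,1), m(i,2)};
  return x;
}

static NumericMatrix asMatrix(const Coords& x) {
  NumericMatrix m(x.size(), 3);
  for (size_t i = 0; i < x.size(); ++i)
    for (int d = 0; d < 3; ++d) m(i, d) = x[i][d];
  return m;
}

// minimum-image displacement a - b (periodic in x, y only)
static inline void mindiff(const Sys& S, const std::array<double,3>& a,
                           const std::array<double,3>& b, double* d) {
  d[0] = a[0] - b[0]; d[1] = a[1] - b[1]; d[2] = a[2] - b[2];
  d[0] -= S.Lx * std::round(d[0] / S.Lx);
  d[1] -= S.Ly * std::round(d[1] / S.Ly);
}

// pair energy from the squared distance (no sqrt/pow on the fast path)
static inline double pairEnergy2(const Sys& S, int i, int j, double r2) {
  size_t q = (size_t)j * S.n + i;
  double rc2 = S.pRcut2[q];
  if (rc2 <= 0 || r2 >= rc2) return 0.0;
  double s2 = S.pS2[q];
  double c2 = S.cap * S.cap * s2;
  if (r2 < c2) r2 = c2;
  double sr2 = s2 / r2;
  double sr6 = sr2 * sr2 * sr2;
  return 4.0 * S.pEps[q] * (sr6 * sr6 - sr6) - S.pShift[q];
}

// -(dV/dr)/r of the pair term: multiply by the displacement vector to get
// the force on bead i; magnitude capped at fMax
static inline double pairFOverR(const Sys& S, int i, int j, double r2) {
  size_t q = (size_t)j * S.n + i;
  double rc2 = S.pRcut2[q];
  if (rc2 <= 0 || r2 >= rc2) return 0.0;
  double s2 = S.pS2[q];
  double c2 = S.cap * S.cap * s2;
  double r2c = (r2 < c2) ? c2 : r2;
  double sr2 = s2 / r2c;
  double sr6 = sr2 * sr2 * sr2;
  double fOverR = 24.0 * S.pEps[q] * (2.0 * sr6 * sr6 - sr6) / r2c;
  if (fOverR * fOverR * r2 > S.fMax * S.fMax) {
    double lim = S.fMax / std::sqrt(std::max(r2, 1e-12));
    fOverR = (fOverR > 0) ? lim : -lim;
  }
  return fOverR;
}

static inline double wallEnergy1(const std::array<double,5>& w, double d,
                                 double cap) {
  if (w[3] <= 0) return 0.0;
  if (d >= w[2]) return 0.0;
  double dm = cap * w[0];
  if (d < dm) d = dm;
  double sr2 = (w[0] / d) * (w[0] / d);
  double sr6 = sr2 * sr2 * sr2;
  return 4.0 * w[1] * (sr6 * sr6 - sr6) - w[4];
}

static inline double wallDvdd(const std::array<double,5>& w, double d,
                              double cap, double fMax) {
  if (w[3] <= 0 || d >= w[2]) return 0.0;
  double dm = cap * w[0];
  if (d < dm) d = dm;
  double sr2 = (w[0] / d) * (w[0] / d);
  double sr6 = sr2 * sr2 * sr2;
  double dv = -24.0 * w[1] * (2.0 * sr6 * sr6 - sr6) / d;
  if (dv < -fMax) dv = -fMax;
  if (dv > fMax) dv = fMax;
  return dv;
}

static double angleTheta(const Sys& S, const Coords& x, int i, int j, int k) {
  double a[3], b[3];
  mindiff(S, x[i], x[j], a);
  mindiff(S, x[k], x[j], b);
  double na = std::sqrt(a[0]*a[0]+a[1]*a[1]+a[2]*a[2]);
  double nb = std::sqrt(b[0]*b[0]+b[1]*b[1]+b[2]*b[2]);
  double c = (a[0]*b[0]+a[1]*b[1]+a[2]*b[2]) / (na*nb);
  if (c > 1.0) c = 1.0; if (c < -1.0) c = -1.0;
  return std::acos(c);
}

static double dihedralPhi(const Sys& S, const Coords& x,
                          int i, int j, int k, int l) {
  double b1[3], b2[3], b3[3];
  mindiff(S, x[j], x[i], b1);
  mindiff(S, x[k], x[j], b2);
  mindiff(S, x[l], x[k], b3);
  double n1[3] = {b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2],
                  b1[0]*b2[1]-b1[1]*b2[0]};
  double n2[3] = {b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2],
                  b2[0]*b3[1]-b2[1]*b3[0]};
  double m1[3] = {n1[1]*n2[2]-n1[2]*n2[1], n1[2]*n2[0]-n1[0]*n2[2],
                  n1[0]*n2[1]-n1[1]*n2[0]};
  double nb2 = std::sqrt(b2[0]*b2[0]+b2[1]*b2[1]+b2[2]*b2[2]);
  double y = (m1[0]*b2[0]+m1[1]*b2[1]+m1[2]*b2[2]) / nb2;
  double xx = n1[0]*n2[0]+n1[1]*n2[1]+n1[2]*n2[2];
  return std::atan2(y, xx);
}

static inline double wrapAngle(double a) {
  while (a > PI_) a -= 2.0 * PI_;
  while (a <= -PI_) a += 2.0 * PI_;
  return a;
}

static double cvValue(const Sys& S, const Coords& x, const CvSpec& cv) {
  if (cv.type < 0) return NA_REAL;
  if (cv.type == 0) {
    double z = 0;
    for (size_t m = 0; m < cv.idx.size(); ++m) z += cv.w[m] * x[cv.idx[m]][2];
    return z;
  }
  double X = 0, Y = 0;
  for (size_t m = 0; m < cv.idx.size(); ++m) {
    X += cv.w[m] * x[cv.idx[m]][0];
    Y += cv.w[m] * x[cv.idx[m]][1];
  }
  double dx = X - cv.x0, dy = Y - cv.y0;
  return std::sqrt(dx*dx + dy*dy);
}

static double biasEnergy(const Sys& S, const Coords& x, const Bias& b) {
  CvSpec cv; cv.type = b.type; cv.idx = b.idx; cv.w = b.w;
  cv.x0 = b.x0; cv.y0 = b.y0;
  double v = cvValue(S, x, cv);
  double d = v - b.c;
  return 0.5 * b.k * d * d;
}

// full potential energy with per-term decomposition
static void energyAll(const Sys& S, const Coords& x, double* terms) {
  double eb = 0, ea = 0, ed = 0, ep = 0, ew = 0, ebias = 0;
  for (size_t t = 0; t < S.bondIdx.size(); ++t) {
    double d[3];
    mindiff(S, x[S.bondIdx[t][0]], x[S.bondIdx[t][1]], d);
    double r = std::sqrt(d[0]*d[0]+d[1]*d[1]+d[2]*d[2]);
    double dr = r - S.bondPar[t][1];
    eb += 0.5 * S.bondPar[t][0] * dr * dr;
  }
  for (size_t t = 0; t < S.angIdx.size(); ++t) {
    double th = angleTheta(S, x, S.angIdx[t][0], S.angIdx[t][1], S.angIdx[t][2]);
    double dth = th - S.angPar[t][1];
    ea += 0.5 * S.angPar[t][0] * dth * dth;
  }
  for (size_t t = 0; t < S.dihIdx.size(); ++t) {
    double ph = dihedralPhi(S, x, S.dihIdx[t][0], S.dihIdx[t][1],
                            S.dihIdx[t][2], S.dihIdx[t][3]);
    double dp = wrapAngle(ph - S.dihPar[t][1]);
    ed += 0.5 * S.dihPar[t][0] * dp * dp;
  }
  for (int i = 0; i < S.n; ++i) {
    for (int j = i + 1; j < S.n; ++j) {
      size_t q = (size_t)j * S.n + i;
      if (S.pRcut2[q] <= 0) continue;
      double d[3];
      mindiff(S, x[i], x[j], d);
      double r2 = d[0]*d[0]+d[1]*d[1]+d[2]*d[2];
      if (r2 >= S.pRcut2[q]) continue;
      ep += pairEnergy2(S, i, j, r2);
    }
    ew += wallEnergy1(S.wallLo[i], x[i][2], S.cap);
    ew += wallEnergy1(S.wallHi[i], S.Lz - x[i][2], S.cap);
  }
  for (const Bias& b : S.biases) ebias += biasEnergy(S, x, b);
  terms[0] = eb; terms[1] = ea; terms[2] = ed;
  terms[3] = ep; terms[4] = ew; terms[5] = ebias;
}

static double energyTotal(const Sys& S, const Coords& x) {
  double t[6];
  energyAll(S, x, t);
  return t[0]+t[1]+t[2]+t[3]+t[4]+t[5];
}

// analytic forces; returns total potential energy
static double forcesAll(const Sys& S, const Coords& x, Coords& F) {
  for (int i = 0; i < S.n; ++i) F[i] = {0,0,0};
  double E = 0;
  // bonds
  for (size_t t = 0; t < S.bondIdx.size(); ++t) {
    int i = S.bondIdx[t][0], j = S.bondIdx[t][1];
    double d[3];
    mindiff(S, x[i], x[j], d);
    double r = std::sqrt(d[0]*d[0]+d[1]*d[1]+d[2]*d[2]);
    double dr = r - S.bondPar[t][1];
    E += 0.5 * S.bondPar[t][0] * dr * dr;
    double f = -S.bondPar[t][0] * dr / std::max(r, 1e-12);
    for (int c = 0; c < 3; ++c) { F[i][c] += f*d[c]; F[j][c] -= f*d[c]; }
  }
  // angles
  for (size_t t = 0; t < S.angIdx.size(); ++t) {
    int i = S.angIdx[t][0], j = S.angIdx[t][1], k = S.angIdx[t][2];
    double a[3], b[3];
    mindiff(S, x[i], x[j], a);
    mindiff(S, x[k], x[j], b);
    double na = std::sqrt(a[0]*a[0]+a[1]*a[1]+a[2]*a[2]);
    double nb = std::sqrt(b[0]*b[0]+b[1]*b[1]+b[2]*b[2]);
    double cth = (a[0]*b[0]+a[1]*b[1]+a[2]*b[2]) / (na*nb);
    if (cth > 1.0) cth = 1.0; if (cth < -1.0) cth = -1.0;
    double th = std::acos(cth);
    double sth = std::sqrt(1.0 - cth*cth);
    double dth = th - S.angPar[t][1];
    E += 0.5 * S.angPar[t][0] * dth * dth;
    if (sth < 1e-8) sth = 1e-8;
    double coef = S.angPar[t][0] * dth / sth;   // dV/dtheta * 1/sin
    for (int c = 0; c < 3; ++c) {
      double dci = (b[c]/(na*nb)) - cth * a[c]/(na*na);
      double dck = (a[c]/(na*nb)) - cth * b[c]/(nb*nb);
      // dtheta/dxi = -(1/sin) dcos/dxi, F = -dV/dx
      double Fi = coef * dci;
      double Fk = coef * dck;
      F[i][c] += Fi;
      F[k][c] += Fk;
      F[j][c] -= Fi + Fk;
    }
  }
  // dihedrals (GROMACS-style force distribution)
  for (size_t t = 0; t < S.dihIdx.size(); ++t) {
    int i = S.dihIdx[t][0], j = S.dihIdx[t][1],
        k = S.dihIdx[t][2], l = S.dihIdx[t][3];
    double b1[3], b2[3], b3[3];
    mindiff(S, x[j], x[i], b1);
    mindiff(S, x[k], x[j], b2);
    mindiff(S, x[l], x[k], b3);
    double n1[3] = {b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2],
                    b1[0]*b2[1]-b1[1]*b2[0]};
    double n2[3] = {b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2],
                    b2[0]*b3[1]-b2[1]*b3[0]};
    double m1[3] = {n1[1]*n2[2]-n1[2]*n2[1], n1[2]*n2[0]-n1[0]*n2[2],
                    n1[0]*n2[1]-n1[1]*n2[0]};
    double nb2 = std::sqrt(b2[0]*b2[0]+b2[1]*b2[1]+b2[2]*b2[2]);
    double y = (m1[0]*b2[0]+m1[1]*b2[1]+m1[2]*b2[2]) / nb2;
    double xx = n1[0]*n2[0]+n1[1]*n2[1]+n1[2]*n2[2];
    double phi = std::atan2(y, xx);
    double dp = wrapAngle(phi - S.dihPar[t][1]);
    E += 0.5 * S.dihPar[t][0] * dp * dp;
    double dVdphi = S.dihPar[t][0] * dp;
    double n1sq = n1[0]*n1[0]+n1[1]*n1[1]+n1[2]*n1[2];
    double n2sq = n2[0]*n2[0]+n2[1]*n2[1]+n2[2]*n2[2];
    if (n1sq < 1e-16 || n2sq < 1e-16) continue;   // collinear: no torque
    double Fi[3], Fl[3];
    // dphi/dx_i = -|b2| n1 / |n1|^2 and dphi/dx_l = +|b2| n2 / |n2|^2
    for (int c = 0; c < 3; ++c) {
      Fi[c] =  dVdphi * nb2 / n1sq * n1[c];
      Fl[c] = -dVdphi * nb2 / n2sq * n2[c];
    }
    // with b1 = rj - ri, b2 = rk - rj, b3 = rl - rk the inner gradients are
    // g_j = (-1 - t) g_i + s g_l and g_k = t g_i + (-1 - s) g_l
    double tt = (b1[0]*b2[0]+b1[1]*b2[1]+b1[2]*b2[2]) / (nb2*nb2);
    double ss = (b3[0]*b2[0]+b3[1]*b2[1]+b3[2]*b2[2]) / (nb2*nb2);
    for (int c = 0; c < 3; ++c) {
      double Fj = (-1.0 - tt)*Fi[c] + ss*Fl[c];
      double Fk = tt*Fi[c] + (-1.0 - ss)*Fl[c];
      F[i][c] += Fi[c];
      F[j][c] += Fj;
      F[k][c] += Fk;
      F[l][c] += Fl[c];
    }
  }
  // pairs
  for (int i = 0; i < S.n; ++i) {
    for (int j = i + 1; j < S.n; ++j) {
      size_t q = (size_t)j * S.n + i;
      if (S.pRcut2[q] <= 0) continue;
      double d[3];
      mindiff(S, x[i], x[j], d);
      double r2 = d[0]*d[0]+d[1]*d[1]+d[2]*d[2];
      if (r2 >= S.pRcut2[q]) continue;
      E += pairEnergy2(S, i, j, r2);
      double f = pairFOverR(S, i, j, r2);
      for (int c = 0; c < 3; ++c) { F[i][c] += f*d[c]; F[j][c] -= f*d[c]; }
    }
  }
  // walls
  for (int i = 0; i < S.n; ++i) {
    double dlo = x[i][2];
    E += wallEnergy1(S.wallLo[i], dlo, S.cap);
    F[i][2] += -wallDvdd(S.wallLo[i], dlo, S.cap, S.fMax);
    double dhi = S.Lz - x[i][2];
    E += wallEnergy1(S.wallHi[i], dhi, S.cap);
    F[i][2] += wallDvdd(S.wallHi[i], dhi, S.cap, S.fMax);
  }
  // biases
  for (const Bias& b : S.biases) {
    if (b.type == 0) {
      double Z = 0;
      for (size_t m = 0; m < b.idx.size(); ++m) Z += b.w[m] * x[b.idx[m]][2];
      double d = Z - b.c;
      E += 0.5 * b.k * d * d;
      for (size_t m = 0; m < b.idx.size(); ++m)
        F[b.idx[m]][2] -= b.k * d * b.w[m];
    } else {
      double X = 0, Y = 0;
      for (size_t m = 0; m < b.idx.size(); ++m) {
        X += b.w[m] * x[b.idx[m]][0];
        Y += b.w[m] * x[b.idx[m]][1];
      }
      double dx = X - b.x0, dy = Y - b.y0;
      double rho = std::sqrt(dx*dx + dy*dy);
      double d = rho - b.c;
      E += 0.5 * b.k * d * d;
      if (rho > 1e-10) {
        double gx = b.k * d * dx / rho, gy = b.k * d * dy / rho;
        for (size_t m = 0; m < b.idx.size(); ++m) {
          F[b.idx[m]][0] -= gx * b.w[m];
          F[b.idx[m]][1] -= gy * b.w[m];
        }
      }
    }
  }
  return E;
}

// ------------------------- exported: energy/forces -------------------------

// [[Rcpp::export]]
List cg_energy(List pack, NumericMatrix pos) {
  Sys S = buildSys(pack);
  Coords x = asCoords(pos);
  double t[6];
  energyAll(S, x, t);
  return List::create(_["total"] = t[0]+t[1]+t[2]+t[3]+t[4]+t[5],
                      _["bond"] = t[0], _["angle"] = t[1],
                      _["dihedral"] = t[2], _["pair"] = t[3],
                      _["wall"] = t[4], _["bias"] = t[5]);
}

// [[Rcpp::export]]
List cg_forces(List pack, NumericMatrix pos) {
  Sys S = buildSys(pack);
  Coords x = asCoords(pos);
  Coords F(S.n);
  double E = forcesAll(S, x, F);
  return List::create(_["forces"] = asMatrix(F), _["energy"] = E);
}

// raw (optionally unshifted) wall potential, for checking the LJ node
// [[Rcpp::export]]
double cg_wall_potential(double d, double s, double eps, double rcut,
                         bool shifted) {
  if (d >= rcut) return 0.0;
  double sr6 = std::pow(s / d, 6);
  double v = 4.0 * eps * (sr6 * sr6 - sr6);
  if (shifted) {
    double cr6 = std::pow(s / rcut, 6);
    v -= 4.0 * eps * (cr6 * cr6 - cr6);
  }
  return v;
}

// [[Rcpp::export]]
double cg_cv(List pack, NumericMatrix pos) {
  Sys S = buildSys(pack);
  Coords x = asCoords(pos);
  return cvValue(S, x, S.cv);
}

// --------------------------- rigid-group helpers ---------------------------

struct Quat { double w, x, y, z; };

static Quat quatMul(const Quat& a, const Quat& b) {
  return {a.w*b.w - a.x*b.x - a.y*b.y - a.z*b.z,
          a.w*b.x + a.x*b.w + a.y*b.z - a.z*b.y,
          a.w*b.y - a.x*b.z + a.y*b.w + a.z*b.x,
          a.w*b.z + a.x*b.y - a.y*b.x + a.z*b.w};
}

static void quatNormalize(Quat& q) {
  double n = std::sqrt(q.w*q.w + q.x*q.x + q.y*q.y + q.z*q.z);
  q.w /= n; q.x /= n; q.y /= n; q.z /= n;
}

static Quat quatFromRotvec(double vx, double vy, double vz) {
  double a = std::sqrt(vx*vx + vy*vy + vz*vz);
  if (a < 1e-14) return {1, 0, 0, 0};
  double s = std::sin(0.5 * a) / a;
  return {std::cos(0.5 * a), vx*s, vy*s, vz*s};
}

static void quatRotate(const Quat& q, const double* v, double* out) {
  // out = R(q) v
  double t2 = q.w*q.x, t3 = q.w*q.y, t4 = q.w*q.z,
         t5 = -q.x*q.x, t6 = q.x*q.y, t7 = q.x*q.z,
         t8 = -q.y*q.y, t9 = q.y*q.z, t10 = -q.z*q.z;
  out[0] = 2.0*((t8+t10)*v[0] + (t6-t4)*v[1] + (t3+t7)*v[2]) + v[0];
  out[1] = 2.0*((t4+t6)*v[0] + (t5+t10)*v[1] + (t9-t2)*v[2]) + v[1];
  out[2] = 2.0*((t7-t3)*v[0] + (t2+t9)*v[1] + (t5+t8)*v[2]) + v[2];
}

// ------------------------------ BD integrator ------------------------------

// [[Rcpp::export]]
List cg_bd_run(List pack, NumericMatrix startPos, int nSteps, double dt,
               int sampleEvery, int seed, double temperature,
               IntegerVector trackBeads, int trackEvery) {
  Sys S = buildSys(pack);
  Coords x = asCoords(startPos);
  Coords F(S.n);
  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  int nG = S.groups.size();
  std::vector<std::array<double,3>> gCom(nG);
  std::vector<Quat> gQ(nG);
  std::vector<std::vector<std::array<double,3>>> gRel(nG);
  std::vector<double> gMass(nG, 0.0);
  for (int g = 0; g < nG; ++g) {
    gQ[g] = {1,0,0,0};
    double cx=0, cy=0, cz=0, M=0;
    for (int i : S.groups[g]) {
      cx += S.mass[i]*x[i][0]; cy += S.mass[i]*x[i][1]; cz += S.mass[i]*x[i][2];
      M += S.mass[i];
    }
    gCom[g] = {cx/M, cy/M, cz/M};
    gMass[g] = M;
    for (int i : S.groups[g])
      gRel[g].push_back({x[i][0]-gCom[g][0], x[i][1]-gCom[g][1],
                         x[i][2]-gCom[g][2]});
  }
  std::vector<int> inGroup(S.n, 0);
  for (int g = 0; g < nG; ++g) for (int i : S.groups[g]) inGroup[i] = 1;

  int nSamp = (sampleEvery > 0) ? nSteps / sampleEvery + 1 : 1;
  NumericVector frames(Dimension(S.n, 3, nSamp));
  NumericVector energies(nSamp);
  int nTrack = trackBeads.size();
  int nTrackSamp = (trackEvery > 0 && nTrack > 0) ? nSteps / trackEvery + 1 : 0;
  NumericMatrix track(std::max(nTrackSamp, 0), std::max(nTrack, 0));
  NumericVector cvTrack(S.cv.type >= 0 && trackEvery > 0
                        ? nSteps / trackEvery + 1 : 0);

  auto record = [&](int sidx, double E) {
    for (int i = 0; i < S.n; ++i)
      for (int c = 0; c < 3; ++c)
        frames[(size_t)sidx * S.n * 3 + (size_t)c * S.n + i] = x[i][c];
    energies[sidx] = E;
  };
  auto recordTrack = [&](int tidx) {
    for (int b = 0; b < nTrack; ++b) track(tidx, b) = x[trackBeads[b]-1][2];
    if (cvTrack.size() > 0) cvTrack[tidx] = cvValue(S, x, S.cv);
  };

  double E0 = energyTotal(S, x);
  int sidx = 0, tidx = 0;
  record(sidx++, E0);
  if (nTrackSamp > 0 || cvTrack.size() > 0) recordTrack(tidx++);

  // Leimkuhler-Matthews (BAOAB-limit) update: the noise added per step is
  // the average of the current and previous Gaussian draws, giving
  // second-order configurational sampling accuracy at Euler cost.
  double sqrt2dt = std::sqrt(2.0 * temperature * dt);
  std::vector<std::array<double,3>> noisePrev(S.n);
  for (int i = 0; i < S.n; ++i)
    noisePrev[i] = {gauss(rng), gauss(rng), gauss(rng)};
  std::vector<std::array<double,3>> noiseTPrev(nG), noiseRPrev(nG);
  for (int g = 0; g < nG; ++g) {
    noiseTPrev[g] = {gauss(rng), gauss(rng), gauss(rng)};
    noiseRPrev[g] = {gauss(rng), gauss(rng), gauss(rng)};
  }
  for (int step = 1; step <= nSteps; ++step) {
    double E = forcesAll(S, x, F);
    if (!std::isfinite(E))
      stop("potential energy diverged at step %d; reduce dt", step);
    // free beads
    for (int i = 0; i < S.n; ++i) {
      if (S.fixedb[i] || inGroup[i]) continue;
      double g = S.gamma[i];
      double amp = sqrt2dt / std::sqrt(g);
      for (int c = 0; c < 3; ++c) {
        double xi = gauss(rng);
        x[i][c] += F[i][c] * dt / g + amp * 0.5 * (xi + noisePrev[i][c]);
        noisePrev[i][c] = xi;
      }
    }
    // rigid groups: translate by net force, rotate by net torque
    for (int g = 0; g < nG; ++g) {
      double Fx=0, Fy=0, Fz=0, Tx=0, Ty=0, Tz=0;
      for (int i : S.groups[g]) {
        Fx += F[i][0]; Fy += F[i][1]; Fz += F[i][2];
        double rx = x[i][0]-gCom[g][0], ry = x[i][1]-gCom[g][1],
               rz = x[i][2]-gCom[g][2];
        Tx += ry*F[i][2] - rz*F[i][1];
        Ty += rz*F[i][0] - rx*F[i][2];
        Tz += rx*F[i][1] - ry*F[i][0];
      }
      double gt = S.gammaT[g], gr = S.gammaR[g];
      double ampT = sqrt2dt / std::sqrt(gt);
      double nT[3] = {gauss(rng), gauss(rng), gauss(rng)};
      gCom[g][0] += Fx * dt / gt + ampT * 0.5 * (nT[0] + noiseTPrev[g][0]);
      gCom[g][1] += Fy * dt / gt + ampT * 0.5 * (nT[1] + noiseTPrev[g][1]);
      gCom[g][2] += Fz * dt / gt + ampT * 0.5 * (nT[2] + noiseTPrev[g][2]);
      for (int c = 0; c < 3; ++c) noiseTPrev[g][c] = nT[c];
      double ampR = sqrt2dt / std::sqrt(gr);
      double nR[3] = {gauss(rng), gauss(rng), gauss(rng)};
      double wx = Tx * dt / gr + ampR * 0.5 * (nR[0] + noiseRPrev[g][0]);
      double wy = Ty * dt / gr + ampR * 0.5 * (nR[1] + noiseRPrev[g][1]);
      double wz = Tz * dt / gr + ampR * 0.5 * (nR[2] + noiseRPrev[g][2]);
      for (int c = 0; c < 3; ++c) noiseRPrev[g][c] = nR[c];
      Quat dq = quatFromRotvec(wx, wy, wz);
      gQ[g] = quatMul(dq, gQ[g]);
      quatNormalize(gQ[g]);
      for (size_t m = 0; m < S.groups[g].size(); ++m) {
        int i = S.groups[g][m];
        double v[3];
        quatRotate(gQ[g], gRel[g][m].data(), v);
        x[i][0] = gCom[g][0] + v[0];
        x[i][1] = gCom[g][1] + v[1];
        x[i][2] = gCom[g][2] + v[2];
      }
    }
    if (sampleEvery > 0 && step % sampleEvery == 0)
      record(sidx++, energyTotal(S, x));
    if (trackEvery > 0 && (nTrackSamp > 0 || cvTrack.size() > 0)
        && step % trackEvery == 0)
      recordTrack(tidx++);
  }

  frames.attr("dim") = Dimension(S.n, 3, nSamp);
  return List::create(_["frames"] = frames, _["energies"] = energies,
                      _["finalPos"] = asMatrix(x), _["track"] = track,
                      _["cv"] = cvTrack,
                      _["trackInterval"] = (double)trackEvery * dt,
                      _["frameInterval"] = (double)sampleEvery * dt);
}

// ------------------------- event-run merge filter --------------------------

// Absorb runs shorter than minFrames into their surroundings, shortest
// first (ties: earliest).  Runs alternate in state; flipping a run merges
// it with both neighbours.  Returns the filtered (lengths, values).
// [[Rcpp::export]]
List cg_merge_runs(IntegerVector lengths, LogicalVector values,
                   int minFrames) {
  int n = lengths.size();
  std::vector<long long> len(n);
  std::vector<int> val(n), prev(n), next(n), alive(n, 1);
  std::vector<long long> version(n, 0);
  for (int i = 0; i < n; ++i) {
    len[i] = lengths[i];
    val[i] = values[i] ? 1 : 0;
    prev[i] = i - 1;
    next[i] = (i + 1 < n) ? i + 1 : -1;
  }
  typedef std::tuple<long long, int, long long> Entry;  // len, idx, version
  std::priority_queue<Entry, std::vector<Entry>, std::greater<Entry>> heap;
  for (int i = 0; i < n; ++i) heap.push(Entry(len[i], i, 0));
  int nAlive = n;
  while (!heap.empty() && nAlive > 1) {
    Entry e = heap.top(); heap.pop();
    int i = std::get<1>(e);
    if (!alive[i] || std::get<2>(e) != version[i] ||
        std::get<0>(e) != len[i]) continue;
    if (len[i] >= minFrames) break;
    int l = prev[i], r = next[i];
    if (l >= 0 && r >= 0) {
      len[l] += len[i] + len[r];
      alive[i] = alive[r] = 0;
      nAlive -= 2;
      next[l] = next[r];
      if (next[r] >= 0) prev[next[r]] = l;
      ++version[l];
      heap.push(Entry(len[l], l, version[l]));
    } else if (l >= 0) {
      len[l] += len[i];
      alive[i] = 0;
      --nAlive;
      next[l] = -1;
      ++version[l];
      heap.push(Entry(len[l], l, version[l]));
    } else if (r >= 0) {
      len[r] += len[i];
      alive[i] = 0;
      --nAlive;
      prev[r] = -1;
      ++version[r];
      heap.push(Entry(len[r], r, version[r]));
    } else break;
  }
  std::vector<double> outLen;
  std::vector<int> outVal;
  int head = 0;
  while (head < n && !alive[head]) ++head;
  for (int i = head; i >= 0; i = next[i]) {
    outLen.push_back((double)len[i]);
    outVal.push_back(val[i]);
  }
  return List::create(_["lengths"] = wrap(outLen), _["values"] = wrap(outVal));
}

// ------------------------------- MC sampler --------------------------------

struct DeltaCtx {
  std::vector<int> moved;       // moved bead indices
  std::vector<int> isMoved;     // 0/1 mask
  std::vector<int> stamp;       // term-dedup stamps
};

// energy of all terms touching the moved set, at current coordinates;
// rigidMove: moved set transforms rigidly, so moved-moved pairs are skipped
static double localEnergy(const Sys& S, const Coords& x, DeltaCtx& ctx,
                          bool rigidMove,
                          std::vector<int>& seenB, std::vector<int>& seenA,
                          std::vector<int>& seenD, std::vector<int>& seenBi,
                          int tag) {
  double E = 0;
  for (int i : ctx.moved) {
    for (int t : S.bondsOf[i]) {
      if (seenB[t] == tag) continue;
      seenB[t] = tag;
      int a = S.bondIdx[t][0], b = S.bondIdx[t][1];
      if (rigidMove && ctx.isMoved[a] && ctx.isMoved[b]) continue;
      double d[3];
      mindiff(S, x[a], x[b], d);
      double r = std::sqrt(d[0]*d[0]+d[1]*d[1]+d[2]*d[2]);
      double dr = r - S.bondPar[t][1];
      E += 0.5 * S.bondPar[t][0] * dr * dr;
    }
    for (int t : S.angsOf[i]) {
      if (seenA[t] == tag) continue;
      seenA[t] = tag;
      if (rigidMove && ctx.isMoved[S.angIdx[t][0]] &&
          ctx.isMoved[S.angIdx[t][1]] && ctx.isMoved[S.angIdx[t][2]]) continue;
      double th = angleTheta(S, x, S.angIdx[t][0], S.angIdx[t][1],
                             S.angIdx[t][2]);
      double dth = th - S.angPar[t][1];
      E += 0.5 * S.angPar[t][0] * dth * dth;
    }
    for (int t : S.dihsOf[i]) {
      if (seenD[t] == tag) continue;
      seenD[t] = tag;
      if (rigidMove && ctx.isMoved[S.dihIdx[t][0]] &&
          ctx.isMoved[S.dihIdx[t][1]] && ctx.isMoved[S.dihIdx[t][2]] &&
          ctx.isMoved[S.dihIdx[t][3]]) continue;
      double ph = dihedralPhi(S, x, S.dihIdx[t][0], S.dihIdx[t][1],
                              S.dihIdx[t][2], S.dihIdx[t][3]);
      double dp = wrapAngle(ph - S.dihPar[t][1]);
      E += 0.5 * S.dihPar[t][0] * dp * dp;
    }
    for (int t : S.biasesOf[i]) {
      if (seenBi[t] == tag) continue;
      seenBi[t] = tag;
      E += biasEnergy(S, x, S.biases[t]);
    }
    // pairs moved-vs-unmoved (and moved-moved once, if not rigid)
    for (int j = 0; j < S.n; ++j) {
      if (j == i) continue;
      if (ctx.isMoved[j] && (rigidMove || j < i)) continue;
      size_t q = (size_t)std::max(i,j) * S.n + std::min(i,j);
      if (S.pRcut2[q] <= 0) continue;
      double d[3];
      mindiff(S, x[i], x[j], d);
      double r2 = d[0]*d[0]+d[1]*d[1]+d[2]*d[2];
      if (r2 >= S.pRcut2[q]) continue;
      E += pairEnergy2(S, std::min(i,j), std::max(i,j), r2);
    }
    E += wallEnergy1(S.wallLo[i], x[i][2], S.cap);
    E += wallEnergy1(S.wallHi[i], S.Lz - x[i][2], S.cap);
  }
  return E;
}

// [[Rcpp::export]]
List cg_mc_run(List pack, NumericMatrix startPos, int nSweeps, int sampleEvery,
               int seed, List moveParams, IntegerVector trackBeads,
               int trackEvery) {
  Sys S = buildSys(pack);
  Coords x = asCoords(startPos);
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::normal_distribution<double> gauss(0.0, 1.0);

  double dBead = as<double>(moveParams["dispBead"]);
  double dGroupT = as<double>(moveParams["dispGroup"]);
  double dGroupR = as<double>(moveParams["rotGroup"]);
  double dPivot = as<double>(moveParams["pivotAngle"]);
  int nPivotPerSweep = as<int>(moveParams["pivotsPerSweep"]);
  double dTilt = as<double>(moveParams["tiltAngle"]);
  int nTiltPerSweep = as<int>(moveParams["tiltsPerSweep"]);

  int nG = S.groups.size();
  std::vector<int> inGroup(S.n, 0);
  for (int g = 0; g < nG; ++g) for (int i : S.groups[g]) inGroup[i] = 1;
  std::vector<int> freeBeads;
  for (int i = 0; i < S.n; ++i)
    if (!S.fixedb[i] && !inGroup[i]) freeBeads.push_back(i);

  DeltaCtx ctx;
  ctx.isMoved.assign(S.n, 0);
  std::vector<int> seenB(S.bondIdx.size(), -1), seenA(S.angIdx.size(), -1),
                   seenD(S.dihIdx.size(), -1), seenBi(S.biases.size(), -1);
  int tag = 0;

  std::vector<double> att(6, 0.0), acc(6, 0.0);
  Coords xOld;   // stash of moved beads' old positions
  std::vector<int> movedStash;

  auto tryMove = [&](const std::vector<int>& moved, bool rigid, int mtype,
                     const std::function<void()>& apply) {
    att[mtype] += 1;
    ctx.moved = moved;
    for (int i : moved) ctx.isMoved[i] = 1;
    ++tag;
    double e0 = localEnergy(S, x, ctx, rigid, seenB, seenA, seenD, seenBi, tag);
    movedStash = moved;
    xOld.resize(moved.size());
    for (size_t m = 0; m < moved.size(); ++m) xOld[m] = x[moved[m]];
    apply();
    ++tag;
    double e1 = localEnergy(S, x, ctx, rigid, seenB, seenA, seenD, seenBi, tag);
    double dE = e1 - e0;
    bool ok = (dE <= 0) || (unif(rng) < std::exp(-dE));
    if (!ok) {
      for (size_t m = 0; m < moved.size(); ++m) x[moved[m]] = xOld[m];
    } else {
      acc[mtype] += 1;
    }
    for (int i : moved) ctx.isMoved[i] = 0;
  };

  int nSamp = (sampleEvery > 0) ? nSweeps / sampleEvery + 1 : 1;
  NumericVector frames(Dimension(S.n, 3, nSamp));
  int nTrack = trackBeads.size();
  int nTrackSamp = (trackEvery > 0 && nTrack > 0) ? nSweeps / trackEvery + 1 : 0;
  NumericMatrix track(std::max(nTrackSamp, 0), std::max(nTrack, 0));
  NumericVector cvTrack(S.cv.type >= 0 && trackEvery > 0
                        ? nSweeps / trackEvery + 1 : 0);
  auto record = [&](int sidx) {
    for (int i = 0; i < S.n; ++i)
      for (int c = 0; c < 3; ++c)
        frames[(size_t)sidx * S.n * 3 + (size_t)c * S.n + i] = x[i][c];
  };
  auto recordTrack = [&](int tidx) {
    for (int b = 0; b < nTrack; ++b) track(tidx, b) = x[trackBeads[b]-1][2];
    if (cvTrack.size() > 0) cvTrack[tidx] = cvValue(S, x, S.cv);
  };
  int sidx = 0, tidx = 0;
  record(sidx++);
  if (nTrackSamp > 0 || cvTrack.size() > 0) recordTrack(tidx++);

  for (int sweep = 1; sweep <= nSweeps; ++sweep) {
    // single-bead displacements
    for (size_t b = 0; b < freeBeads.size(); ++b) {
      int i = freeBeads[(size_t)(unif(rng) * freeBeads.size()) % freeBeads.size()];
      tryMove({i}, false, 0, [&]() {
        for (int c = 0; c < 3; ++c)
          x[i][c] += dBead * (2.0 * unif(rng) - 1.0);
      });
    }
    // rigid-group translation + rotation about group COM
    for (int g = 0; g < nG; ++g) {
      tryMove(S.groups[g], true, 1, [&]() {
        double tx = dGroupT * (2.0*unif(rng)-1.0);
        double ty = dGroupT * (2.0*unif(rng)-1.0);
        double tz = dGroupT * (2.0*unif(rng)-1.0);
        for (int i : S.groups[g]) {
          x[i][0] += tx; x[i][1] += ty; x[i][2] += tz;
        }
      });
      tryMove(S.groups[g], true, 2, [&]() {
        double vx = gauss(rng), vy = gauss(rng), vz = gauss(rng);
        double nv = std::sqrt(vx*vx+vy*vy+vz*vz);
        double ang = dGroupR * (2.0*unif(rng)-1.0);
        Quat q = quatFromRotvec(vx/nv*ang, vy/nv*ang, vz/nv*ang);
        double cx=0, cy=0, cz=0, M=0;
        for (int i : S.groups[g]) {
          cx += S.mass[i]*x[i][0]; cy += S.mass[i]*x[i][1];
          cz += S.mass[i]*x[i][2]; M += S.mass[i];
        }
        cx /= M; cy /= M; cz /= M;
        for (int i : S.groups[g]) {
          double v[3] = {x[i][0]-cx, x[i][1]-cy, x[i][2]-cz}, o[3];
          quatRotate(q, v, o);
          x[i][0] = cx+o[0]; x[i][1] = cy+o[1]; x[i][2] = cz+o[2];
        }
      });
    }
    // crankshaft rotations of interior chain beads
    for (size_t m = 0; m < S.crank.size(); ++m) {
      const auto& ck = S.crank[(size_t)(unif(rng) * S.crank.size())
                               % S.crank.size()];
      int i = ck[0], p = ck[1], q2 = ck[2];
      tryMove({i}, false, 3, [&]() {
        double ax = x[q2][0]-x[p][0], ay = x[q2][1]-x[p][1],
               az = x[q2][2]-x[p][2];
        double na = std::sqrt(ax*ax+ay*ay+az*az);
        if (na < 1e-12) return;
        double ang = PI_ * (2.0*unif(rng)-1.0);
        Quat q = quatFromRotvec(ax/na*ang, ay/na*ang, az/na*ang);
        double v[3] = {x[i][0]-x[p][0], x[i][1]-x[p][1], x[i][2]-x[p][2]}, o[3];
        quatRotate(q, v, o);
        x[i][0] = x[p][0]+o[0]; x[i][1] = x[p][1]+o[1]; x[i][2] = x[p][2]+o[2];
      });
    }
    // pivot: rotate the tail beyond a random chain bead about it
    for (int pv = 0; pv < nPivotPerSweep && S.pivotTails.size() > 0; ++pv) {
      int p = (size_t)(unif(rng) * S.pivotTails.size()) % S.pivotTails.size();
      const std::vector<int>& tail = S.pivotTails[p];
      if (tail.empty()) continue;
      int pivotBead = S.chain[p];
      tryMove(tail, true, 4, [&]() {
        double vx = gauss(rng), vy = gauss(rng), vz = gauss(rng);
        double nv = std::sqrt(vx*vx+vy*vy+vz*vz);
        double ang = dPivot * (2.0*unif(rng)-1.0);
        Quat q = quatFromRotvec(vx/nv*ang, vy/nv*ang, vz/nv*ang);
        double px = x[pivotBead][0], py = x[pivotBead][1], pz = x[pivotBead][2];
        for (int i : tail) {
          double v[3] = {x[i][0]-px, x[i][1]-py, x[i][2]-pz}, o[3];
          quatRotate(q, v, o);
          x[i][0] = px+o[0]; x[i][1] = py+o[1]; x[i][2] = pz+o[2];
        }
      });
    }
    // global tilt: rotate every mobile bead about the tether anchor
    for (int tv = 0; tv < nTiltPerSweep && S.tiltPivot >= 0; ++tv) {
      tryMove(S.tiltSet, true, 5, [&]() {
        double vx = gauss(rng), vy = gauss(rng), vz = gauss(rng);
        double nv = std::sqrt(vx*vx+vy*vy+vz*vz);
        double ang = dTilt * (2.0*unif(rng)-1.0);
        Quat q = quatFromRotvec(vx/nv*ang, vy/nv*ang, vz/nv*ang);
        double px = x[S.tiltPivot][0], py = x[S.tiltPivot][1],
               pz = x[S.tiltPivot][2];
        for (int i : S.tiltSet) {
          double v[3] = {x[i][0]-px, x[i][1]-py, x[i][2]-pz}, o[3];
          quatRotate(q, v, o);
          x[i][0] = px+o[0]; x[i][1] = py+o[1]; x[i][2] = pz+o[2];
        }
      });
    }
    if (sampleEvery > 0 && sweep % sampleEvery == 0) record(sidx++);
    if (trackEvery > 0 && (nTrackSamp > 0 || cvTrack.size() > 0)
        && sweep % trackEvery == 0)
      recordTrack(tidx++);
  }

  frames.attr("dim") = Dimension(S.n, 3, nSamp);
  CharacterVector mnames = CharacterVector::create(
      "displace", "groupTranslate", "groupRotate", "crankshaft", "pivot",
      "tilt");
  NumericVector attv(att.begin(), att.end()), accv(acc.begin(), acc.end());
  attv.names() = mnames; accv.names() = mnames;
  return List::create(_["frames"] = frames, _["finalPos"] = asMatrix(x),
                      _["track"] = track, _["cv"] = cvTrack,
                      _["attempted"] = attv, _["accepted"] = accv,
                      _["finalEnergy"] = energyTotal(S, x));
}
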