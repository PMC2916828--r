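// Numeric core: quaternion-method optimal rigid superposition and the
// branch-and-bound enumeration of maximum-size unit correspondences.
//
// The search keeps incremental coordinate sums along the DFS path, so each
// node costs one fast top-eigenvalue evaluation of the 4x4 key matrix
// (Newton iteration on its characteristic quartic, started above the top
// root) instead of a full eigendecomposition.  Hot paths use flat arrays.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <vector>
#include <algorithm>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Build Horn's 4x4 key matrix from the cross-covariance of the centred point
// sets; its top eigenvalue lambda gives rmsd^2 = (Ga + Gb - 2*lambda)/n and
// the corresponding eigenvector is the optimal rotation quaternion.
static void quat_core(const arma::mat& A, const arma::mat& B,
                      arma::mat& R, arma::vec& t, double& rmsd) {
  const int n = A.n_rows;
  arma::rowvec ca = arma::mean(A, 0), cb = arma::mean(B, 0);
  if (n == 1) {
    R = arma::eye(3, 3);
    t = (ca - cb).t();
    rmsd = 0.0;
    return;
  }
  arma::mat Ac = A.each_row() - ca;
  arma::mat Bc = B.each_row() - cb;
  double Ga = arma::accu(Ac % Ac), Gb = arma::accu(Bc % Bc);
  arma::mat S = Ac.t() * Bc; // S(i,j) = sum_k a_k(i) * b_k(j)
  double Sxx = S(0,0), Sxy = S(0,1), Sxz = S(0,2);
  double Syx = S(1,0), Syy = S(1,1), Syz = S(1,2);
  double Szx = S(2,0), Szy = S(2,1), Szz = S(2,2);
  arma::mat K(4, 4);
  K(0,0) =  Sxx + Syy + Szz;
  K(0,1) = K(1,0) = Syz - Szy;
  K(0,2) = K(2,0) = Szx - Sxz;
  K(0,3) = K(3,0) = Sxy - Syx;
  K(1,1) =  Sxx - Syy - Szz;
  K(1,2) = K(2,1) = Sxy + Syx;
  K(1,3) = K(3,1) = Szx + Sxz;
  K(2,2) = -Sxx + Syy - Szz;
  K(2,3) = K(3,2) = Syz + Szy;
  K(3,3) = -Sxx - Syy + Szz;

  arma::vec eval;
  arma::mat evec;
  arma::eig_sym(eval, evec, K);
  const double lambda = eval(3);
  arma::vec q = evec.col(3);
  const double q0 = q(0), q1 = q(1), q2 = q(2), q3 = q(3);
  R.set_size(3, 3);
  R(0,0) = q0*q0 + q1*q1 - q2*q2 - q3*q3;
  R(0,1) = 2.0 * (q1*q2 - q0*q3);
  R(0,2) = 2.0 * (q1*q3 + q0*q2);
  R(1,0) = 2.0 * (q1*q2 + q0*q3);
  R(1,1) = q0*q0 - q1*q1 + q2*q2 - q3*q3;
  R(1,2) = 2.0 * (q2*q3 - q0*q1);
  R(2,0) = 2.0 * (q1*q3 - q0*q2);
  R(2,1) = 2.0 * (q2*q3 + q0*q1);
  R(2,2) = q0*q0 - q1*q1 - q2*q2 + q3*q3;
  // the eigen-quaternion of K built from S = Ac'Bc rotates frame a onto b;
  // we report the inverse: the proper rotation taking b onto a
  R = R.t();

  double ms = (Ga + Gb - 2.0 * lambda) / n;
  rmsd = ms > 0.0 ? std::sqrt(ms) : 0.0;
  t = ca.t() - R * cb.t();
}

// [[Rcpp::export]]
List cpp_superpose(const arma::mat& A, const arma::mat& B) {
  if (A.n_rows != B.n_rows) stop("point lists differ in length");
  if (A.n_rows == 0) stop("empty point lists");
  arma::mat R;
  arma::vec t;
  double rmsd;
  quat_core(A, B, R, t, rmsd);
  return List::create(_["rotation"] = R, _["translation"] = t,
                      _["rmsd"] = rmsd);
}

namespace {

// running sums of the current partial correspondence
struct Accum {
  double sA[3] = {0, 0, 0}, sB[3] = {0, 0, 0};
  double saa = 0.0, sbb = 0.0;
  double M[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0}; // row-major sum a_i b_i^T
  int n = 0;
};

// top eigenvalue of the traceless symmetric key matrix via Newton on its
// characteristic quartic l^4 + c2 l^2 + c1 l + c0, started at
// (Ga+Gb)/2 >= lambda_max (monotone convergence from above)
static double key_lambda_max(const double S[9], double start) {
  double K[4][4];
  const double Sxx = S[0], Sxy = S[1], Sxz = S[2];
  const double Syx = S[3], Syy = S[4], Syz = S[5];
  const double Szx = S[6], Szy = S[7], Szz = S[8];
  K[0][0] =  Sxx + Syy + Szz;
  K[0][1] = K[1][0] = Syz - Szy;
  K[0][2] = K[2][0] = Szx - Sxz;
  K[0][3] = K[3][0] = Sxy - Syx;
  K[1][1] =  Sxx - Syy - Szz;
  K[1][2] = K[2][1] = Sxy + Syx;
  K[1][3] = K[3][1] = Szx + Sxz;
  K[2][2] = -Sxx + Syy - Szz;
  K[2][3] = K[3][2] = Syz + Szy;
  K[3][3] = -Sxx - Syy + Szz;

  double tr2 = 0.0;
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) tr2 += K[i][j] * K[i][j];
  double K2[4][4];
  for (int i = 0; i < 4; ++i)
    for (int j = i; j < 4; ++j) {
      double s = 0.0;
      for (int k = 0; k < 4; ++k) s += K[i][k] * K[k][j];
      K2[i][j] = K2[j][i] = s;
    }
  double tr3 = 0.0;
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) tr3 += K2[i][j] * K[j][i];
  auto det3 = [&](int r0, int r1, int r2, int c0, int c1, int c2) {
    return K[r0][c0] * (K[r1][c1] * K[r2][c2] - K[r1][c2] * K[r2][c1])
         - K[r0][c1] * (K[r1][c0] * K[r2][c2] - K[r1][c2] * K[r2][c0])
         + K[r0][c2] * (K[r1][c0] * K[r2][c1] - K[r1][c1] * K[r2][c0]);
  };
  const double det = K[0][0] * det3(1, 2, 3, 1, 2, 3)
                   - K[0][1] * det3(1, 2, 3, 0, 2, 3)
                   + K[0][2] * det3(1, 2, 3, 0, 1, 3)
                   - K[0][3] * det3(1, 2, 3, 0, 1, 2);
  const double c2 = -0.5 * tr2;
  const double c1 = -tr3 / 3.0;
  const double c0 = det;

  double l = start > 0.0 ? start : 1e-12;
  const double tol = 1e-12 * (std::fabs(start) + 1.0);
  for (int it = 0; it < 60; ++it) {
    const double l2 = l * l;
    const double p = l2 * l2 + c2 * l2 + c1 * l + c0;
    const double dp = 4.0 * l2 * l + 2.0 * c2 * l + c1;
    if (dp == 0.0) break;
    const double step = p / dp;
    l -= step;
    if (std::fabs(step) < tol) break;
  }
  return l;
}

static double accum_rmsd(const Accum& ac) {
  const int n = ac.n;
  if (n <= 1) return 0.0;
  const double inv = 1.0 / n;
  const double Ga = ac.saa - (ac.sA[0]*ac.sA[0] + ac.sA[1]*ac.sA[1] +
                              ac.sA[2]*ac.sA[2]) * inv;
  const double Gb = ac.sbb - (ac.sB[0]*ac.sB[0] + ac.sB[1]*ac.sB[1] +
                              ac.sB[2]*ac.sB[2]) * inv;
  if (n == 2) {
    // two pairs: each point sits |dA - dB|/2 off after optimal alignment
    const double dA = std::sqrt(std::max(0.0, 2.0 * Ga));
    const double dB = std::sqrt(std::max(0.0, 2.0 * Gb));
    return std::fabs(dA - dB) / 2.0;
  }
  double S[9];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      S[3 * i + j] = ac.M[3 * i + j] - ac.sA[i] * ac.sB[j] * inv;
  const double lambda = key_lambda_max(S, 0.5 * (Ga + Gb));
  const double ms = (Ga + Gb - 2.0 * lambda) * inv;
  return ms > 0.0 ? std::sqrt(ms) : 0.0;
}

struct SearchState {
  const double* Ax; const double* Ay; const double* Az;
  const double* Bx; const double* By; const double* Bz;
  int nA = 0, nB = 0;
  std::vector<double> DA, DB;        // row-major point distance matrices
  std::vector<int> cand_ua, cand_ub; // unit ids per candidate
  std::vector<int> cand_off;         // offset into flat point-pair arrays
  std::vector<int> cand_len;
  std::vector<int> flat_ia, flat_ib; // 0-based point rows, concatenated
  double threshold;
  int max_solutions;
  double node_budget;
  double nodes = 0.0;
  bool budget_exceeded = false;
  int best = 0;
  std::vector<std::vector<int>> sols;
  std::vector<double> sol_rmsd;
  std::vector<char> usedA, usedB;
};

// largest |d_A - d_B| over the cross point pairs of two candidates (intra
// pairs when c1 == c2)
static inline double max_dist_diff(const SearchState& st, int c1, int c2) {
  const int o1 = st.cand_off[c1], l1 = st.cand_len[c1];
  const int o2 = st.cand_off[c2], l2 = st.cand_len[c2];
  double m = 0.0;
  for (int p = 0; p < l1; ++p) {
    const int a1 = st.flat_ia[o1 + p], b1 = st.flat_ib[o1 + p];
    const double* da = &st.DA[(size_t)a1 * st.nA];
    const double* db = &st.DB[(size_t)b1 * st.nB];
    for (int q = 0; q < l2; ++q) {
      const double d = std::fabs(da[st.flat_ia[o2 + q]] - db[st.flat_ib[o2 + q]]);
      if (d > m) m = d;
    }
  }
  return m;
}

static inline void accum_add(const SearchState& st, Accum& ac, int c) {
  const int o = st.cand_off[c], l = st.cand_len[c];
  for (int k = 0; k < l; ++k) {
    const int ra = st.flat_ia[o + k], rb = st.flat_ib[o + k];
    const double ax = st.Ax[ra], ay = st.Ay[ra], az = st.Az[ra];
    const double bx = st.Bx[rb], by = st.By[rb], bz = st.Bz[rb];
    ac.sA[0] += ax; ac.sA[1] += ay; ac.sA[2] += az;
    ac.sB[0] += bx; ac.sB[1] += by; ac.sB[2] += bz;
    ac.saa += ax*ax + ay*ay + az*az;
    ac.sbb += bx*bx + by*by + bz*bz;
    ac.M[0] += ax*bx; ac.M[1] += ax*by; ac.M[2] += ax*bz;
    ac.M[3] += ay*bx; ac.M[4] += ay*by; ac.M[5] += ay*bz;
    ac.M[6] += az*bx; ac.M[7] += az*by; ac.M[8] += az*bz;
    ac.n += 1;
  }
}

// canonical-order depth-first growth: a candidate set is explored through
// its unique ascending-id chain, every link of which must itself stay under
// the rmsd threshold
static void dfs(SearchState& st, std::vector<int>& cur, int last,
                const Accum& ac) {
  if (st.budget_exceeded) return;
  const int nc = st.cand_ua.size();
  const int csz = static_cast<int>(cur.size());
  for (int c = last + 1; c < nc; ++c) {
    if (st.usedA[st.cand_ua[c]] || st.usedB[st.cand_ub[c]]) continue;

    // distance-compatibility bound: if the grown set superimposes with
    // rmsd <= t then every point pair satisfies |d_A - d_B| <= t*sqrt(2N);
    // a violating pair can never yield an admissible set, so skip the
    // evaluation (this short-circuits the rmsd criterion, it never changes
    // which sets are admissible)
    const int npts = ac.n + st.cand_len[c];
    const double bound = st.threshold * std::sqrt(2.0 * npts);
    bool ok = true;
    for (int k = 0; k < csz; ++k) {
      if (max_dist_diff(st, cur[k], c) > bound) { ok = false; break; }
    }
    if (!ok) continue;
    if (st.cand_len[c] > 1 && max_dist_diff(st, c, c) > bound) continue;

    st.nodes += 1.0;
    if (st.nodes > st.node_budget) { st.budget_exceeded = true; return; }

    Accum nac(ac);
    accum_add(st, nac, c);
    const double rmsd = accum_rmsd(nac);
    if (rmsd > st.threshold) continue;

    cur.push_back(c);
    const int sz = csz + 1;
    if (sz > st.best) {
      st.best = sz;
      st.sols.clear();
      st.sol_rmsd.clear();
    }
    if (sz == st.best &&
        static_cast<int>(st.sols.size()) < st.max_solutions) {
      st.sols.push_back(cur);
      st.sol_rmsd.push_back(rmsd);
    }

    st.usedA[st.cand_ua[c]] = 1;
    st.usedB[st.cand_ub[c]] = 1;
    dfs(st, cur, c, nac);
    cur.pop_back();
    st.usedA[st.cand_ua[c]] = 0;
    st.usedB[st.cand_ub[c]] = 0;
    if (st.budget_exceeded) return;
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_find_matches(const arma::mat& A, const arma::mat& B,
                      IntegerVector cand_ua, IntegerVector cand_ub,
                      List cand_ia, List cand_ib,
                      double threshold, int max_solutions,
                      double node_budget) {
  SearchState st;
  st.threshold = threshold;
  st.max_solutions = max_solutions;
  st.node_budget = node_budget;
  st.nA = A.n_rows;
  st.nB = B.n_rows;

  // column pointers (arma is column-major)
  st.Ax = A.colptr(0); st.Ay = A.colptr(1); st.Az = A.colptr(2);
  st.Bx = B.colptr(0); st.By = B.colptr(1); st.Bz = B.colptr(2);

  const int nc = cand_ua.size();
  if (nc > 65535) stop("too many candidate pairings (> 65535)");
  st.cand_ua.resize(nc);
  st.cand_ub.resize(nc);
  st.cand_off.resize(nc);
  st.cand_len.resize(nc);
  int maxA = -1, maxB = -1;
  for (int c = 0; c < nc; ++c) {
    st.cand_ua[c] = cand_ua[c];
    st.cand_ub[c] = cand_ub[c];
    maxA = std::max(maxA, st.cand_ua[c]);
    maxB = std::max(maxB, st.cand_ub[c]);
    IntegerVector ia = cand_ia[c], ib = cand_ib[c];
    st.cand_off[c] = st.flat_ia.size();
    st.cand_len[c] = ia.size();
    st.flat_ia.insert(st.flat_ia.end(), ia.begin(), ia.end());
    st.flat_ib.insert(st.flat_ib.end(), ib.begin(), ib.end());
  }
  st.usedA.assign(maxA + 1, 0);
  st.usedB.assign(maxB + 1, 0);

  st.DA.assign((size_t)st.nA * st.nA, 0.0);
  st.DB.assign((size_t)st.nB * st.nB, 0.0);
  for (int i = 0; i < st.nA; ++i)
    for (int j = 0; j < st.nA; ++j) {
      const double dx = st.Ax[i] - st.Ax[j], dy = st.Ay[i] - st.Ay[j],
                   dz = st.Az[i] - st.Az[j];
      st.DA[(size_t)i * st.nA + j] = std::sqrt(dx*dx + dy*dy + dz*dz);
    }
  for (int i = 0; i < st.nB; ++i)
    for (int j = 0; j < st.nB; ++j) {
      const double dx = st.Bx[i] - st.Bx[j], dy = st.By[i] - st.By[j],
                   dz = st.Bz[i] - st.Bz[j];
      st.DB[(size_t)i * st.nB + j] = std::sqrt(dx*dx + dy*dy + dz*dz);
    }

  std::vector<int> cur;
  Accum ac;
  if (nc > 0) dfs(st, cur, -1, ac);

  List sets(st.sols.size());
  NumericVector rmsds(st.sols.size());
  for (size_t i = 0; i < st.sols.size(); ++i) {
    IntegerVector s(st.sols[i].begin(), st.sols[i].end());
    sets[i] = s + 1; // 1-based candidate ids for R
    rmsds[i] = st.sol_rmsd[i];
  }
  return List::create(_["sets"] = sets, _["rmsds"] = rmsds,
                      _["best_size"] = st.best,
                      _["n_nodes"] = st.nodes,
                      _["budget_exceeded"] = st.budget_exceeded);
}
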