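// Pairwise sums for the normalized kernelized Stein discrepancy (NKSD).
//
// All heavy O(N^2) accumulations live here; the R layer only prepares score
// matrices / Jacobians and post-processes the sums. Kernels are radial per
// block: rbf k_b = exp(-r2_b / (2 h^2)) and inverse multiquadric
// k_b = (1 + r2_b / h^2)^(-1/2), combined multiplicatively across blocks.
// Sums over unordered pairs use Kahan compensated accumulation so results
// are deterministic and stable for large N. Data are transposed to d x N on
// entry so the inner loops touch contiguous memory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Kahan {
  double s, c;
  Kahan() : s(0.0), c(0.0) {}
  inline void add(double x) {
    double y = x - c;
    double t = s + y;
    c = (t - s) - y;
    s = t;
  }
};

// k_b, dk_b/dr2, d2k_b/dr2^2 for one block
inline void kernel_block(double r2, double h2, int family, double &k,
                         double &kp, double &kpp) {
  if (family == 0) { // rbf
    k = std::exp(-r2 / (2.0 * h2));
    kp = -k / (2.0 * h2);
    kpp = k / (4.0 * h2 * h2);
  } else { // imq
    double a = 1.0 + r2 / h2;
    double am = 1.0 / std::sqrt(a);
    k = am;
    kp = -0.5 / h2 * am / a;                 // -(1/(2 h^2)) a^(-3/2)
    kpp = 0.75 / (h2 * h2) * am / (a * a);   // (3/(4 h^4)) a^(-5/2)
  }
}

// Per-pair kernel pieces for a pair of contiguous columns xi, xj (length d):
// overall k, per-coordinate grad_y k (written into gy), and the trace of the
// mixed second-derivative matrix. grad_x k = -grad_y k for radial kernels.
inline void pair_kernel(const double *xi, const double *xj, int d, double h2,
                        int family, const int *block, int nb, double *r2b,
                        double *kb, double *kpb, const int *db, double &ktot,
                        double *gy, double &tr) {
  for (int b = 0; b < nb; ++b) r2b[b] = 0.0;
  for (int c = 0; c < d; ++c) {
    double dc = xi[c] - xj[c];
    r2b[block[c]] += dc * dc;
  }
  ktot = 1.0;
  tr = 0.0;
  double kppb;
  for (int b = 0; b < nb; ++b) {
    kernel_block(r2b[b], h2, family, kb[b], kpb[b], kppb);
    ktot *= kb[b];
    // tr contribution gets the ktot/k_b prefactor after the product is known
    kb[b] = (kb[b] == 0.0) ? 1e-300 : kb[b];
    r2b[b] = -2.0 * db[b] * kpb[b] - 4.0 * r2b[b] * kppb; // reuse as tr_b
  }
  for (int b = 0; b < nb; ++b) tr += (ktot / kb[b]) * r2b[b];
  for (int c = 0; c < d; ++c) {
    int b = block[c];
    gy[c] = (ktot / kb[b]) * (-2.0 * (xi[c] - xj[c]) * kpb[b]);
  }
}

struct BlockInfo {
  std::vector<int> id;  // 0-based block id per coordinate
  std::vector<int> size;
  int nb;
  BlockInfo(const arma::ivec &block, int d) {
    id.resize(d);
    nb = 0;
    for (int c = 0; c < d; ++c) {
      id[c] = block[c] - 1;
      nb = std::max(nb, block[c]);
    }
    size.assign(nb, 0);
    for (int c = 0; c < d; ++c) size[id[c]] += 1;
  }
};

} // namespace

// Sum over i != j of the Stein u-function and of the kernel.
// X: N x d data, S: N x d score matrix s_q(X_i).
// [[Rcpp::export]]
List cpp_nksd_sums(const arma::mat &X, const arma::mat &S, double h2,
                   int family, const arma::ivec &block) {
  const int N = X.n_rows, d = X.n_cols;
  const arma::mat Xt = X.t(), St = S.t();
  BlockInfo bi(block, d);
  std::vector<double> r2b(bi.nb), kb(bi.nb), kpb(bi.nb), gy(d);
  Kahan num, den;
  int bad_i = -1, bad_j = -1;
  for (int i = 0; i < N; ++i) {
    const double *xi = Xt.colptr(i), *si = St.colptr(i);
    for (int j = i + 1; j < N; ++j) {
      const double *xj = Xt.colptr(j), *sj = St.colptr(j);
      double k, tr;
      pair_kernel(xi, xj, d, h2, family, bi.id.data(), bi.nb, r2b.data(),
                  kb.data(), kpb.data(), bi.size.data(), k, gy.data(), tr);
      double ss = 0.0, sg = 0.0;
      for (int c = 0; c < d; ++c) {
        ss += si[c] * sj[c];
        sg += (si[c] - sj[c]) * gy[c];
      }
      double u = ss * k + sg + tr;
      if (!std::isfinite(u) && bad_i < 0) { bad_i = i + 1; bad_j = j + 1; }
      num.add(2.0 * u);
      den.add(2.0 * k);
    }
  }
  return List::create(_["num"] = num.s, _["den"] = den.s,
                      _["bad_i"] = bad_i, _["bad_j"] = bad_j);
}

// Exponential-family quadratic sums. Score s_theta(x) = g(x) + T(x)' theta,
// with T(x) the m x d Jacobian of the sufficient statistic. Accumulates raw
// (unnormalized) sums over ordered pairs i != j:
//   Asum = sum k_ij T_i T_j'
//   Bsum = sum [ T_i (g_j k_ij + w_ij) + T_j (g_i k_ij - w_ij) ]
//   Csum = sum [ g_i'g_j k_ij + (g_i - g_j)' w_ij + tr_ij ]
//   den  = sum k_ij
// where w_ij = grad_y k(x_i, x_j). Tarr: m x d x N cube (single slice when
// t_constant).
// [[Rcpp::export]]
List cpp_expfam_sums(const arma::mat &X, const arma::cube &Tarr,
                     const arma::mat &G, double h2, int family,
                     const arma::ivec &block, bool t_constant) {
  const int N = X.n_rows, d = X.n_cols;
  const int m = Tarr.n_rows;
  const arma::mat Xt = X.t(), Gt = G.t();
  BlockInfo bi(block, d);
  std::vector<double> r2b(bi.nb), kb(bi.nb), kpb(bi.nb), gy(d);
  arma::mat Asum(m, m, arma::fill::zeros);
  arma::vec Bsum(m, arma::fill::zeros);
  arma::vec bi_buf(m), bj_buf(m);
  Kahan Csum, den;
  arma::mat TiTj(m, m);
  for (int i = 0; i < N; ++i) {
    const double *xi = Xt.colptr(i), *gi = Gt.colptr(i);
    const arma::mat &Ti = t_constant ? Tarr.slice(0) : Tarr.slice(i);
    for (int j = i + 1; j < N; ++j) {
      const double *xj = Xt.colptr(j), *gj = Gt.colptr(j);
      const arma::mat &Tj = t_constant ? Tarr.slice(0) : Tarr.slice(j);
      double k, tr;
      pair_kernel(xi, xj, d, h2, family, bi.id.data(), bi.nb, r2b.data(),
                  kb.data(), kpb.data(), bi.size.data(), k, gy.data(), tr);
      // b_i = g_j k + w, b_j = g_i k - w (length-d vectors), then
      // Bsum += 2 (T_i b_i + T_j b_j)
      double gg = 0.0, dgw = 0.0;
      for (int c = 0; c < d; ++c) {
        gg += gi[c] * gj[c];
        dgw += (gi[c] - gj[c]) * gy[c];
      }
      Csum.add(2.0 * (gg * k + dgw + tr));
      den.add(2.0 * k);
      bi_buf.zeros(); bj_buf.zeros();
      for (int c = 0; c < d; ++c) {
        double b1 = gj[c] * k + gy[c];
        double b2 = gi[c] * k - gy[c];
        for (int r = 0; r < m; ++r) {
          bi_buf[r] += Ti(r, c) * b1;
          bj_buf[r] += Tj(r, c) * b2;
        }
      }
      Bsum += 2.0 * (bi_buf + bj_buf);
      if (!t_constant) {
        TiTj = Ti * Tj.t();
        Asum += k * (TiTj + TiTj.t());
      }
    }
  }
  if (t_constant) {
    // constant Jacobian: sum k T T' factors out of the pair loop
    const arma::mat &T0 = Tarr.slice(0);
    Asum = den.s * (T0 * T0.t());
  }
  return List::create(_["Asum"] = Asum, _["Bsum"] = Bsum,
                      _["Csum"] = Csum.s, _["den"] = den.s);
}

// Pair statistics for models whose score is linear in x: s(x) = M x with M
// symmetric (e.g. zero-mean Gaussians, pPCA). The NKSD numerator is then
//   tr(M' M P) + 2 tr(M Q) + K0
// with P = sum_{i != j} k x_j x_i' (symmetric), Q = sum over unordered pairs
// of sym((x_i - x_j) w_ij'), K0 = sum tr_ij, den = sum k_ij (ordered sums).
// [[Rcpp::export]]
List cpp_linear_stats(const arma::mat &X, double h2, int family,
                      const arma::ivec &block) {
  const int N = X.n_rows, d = X.n_cols;
  const arma::mat Xt = X.t();
  BlockInfo bi(block, d);
  std::vector<double> r2b(bi.nb), kb(bi.nb), kpb(bi.nb), gy(d);
  arma::mat P(d, d, arma::fill::zeros), Q(d, d, arma::fill::zeros);
  Kahan K0, den;
  for (int i = 0; i < N; ++i) {
    const double *xi = Xt.colptr(i);
    for (int j = i + 1; j < N; ++j) {
      const double *xj = Xt.colptr(j);
      double k, tr;
      pair_kernel(xi, xj, d, h2, family, bi.id.data(), bi.nb, r2b.data(),
                  kb.data(), kpb.data(), bi.size.data(), k, gy.data(), tr);
      for (int c2 = 0; c2 < d; ++c2) {
        for (int c1 = 0; c1 < d; ++c1) {
          P(c1, c2) += k * (xi[c1] * xj[c2] + xj[c1] * xi[c2]);
          double dq = (xi[c1] - xj[c1]) * gy[c2];
          Q(c1, c2) += 0.5 * dq;
          Q(c2, c1) += 0.5 * dq;
        }
      }
      K0.add(2.0 * tr);
      den.add(2.0 * k);
    }
  }
  return List::create(_["P"] = P, _["Q"] = Q, _["K0"] = K0.s,
                      _["den"] = den.s);
}
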