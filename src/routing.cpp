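// Dynamic-routing inner loops. Everything around these (convolutions,
// capsule affine maps, the dense head) is plain BLAS and stays in R; the
// per-capsule softmax/weighted-sum/agreement sweeps are the only part that
// needs tight loops. Samples are processed one at a time so a sample's
// prediction vectors stay cache-resident across all routing iterations.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double squash_scale(double n, int variant) {
  // variant 0: |v| = n^2/(1+n^2); variant 1 ("as printed"): |v| = n/(1+n^2)
  return variant == 0 ? n / (1.0 + n * n) : 1.0 / (1.0 + n * n);
}

// U: (B*Pp) x (J*D) x C cube of prediction vectors, rows sample-major
// (Pp positions per sample, contiguous). Returns the routed weighted sums,
// squashed outputs, their norms, and the final coupling coefficients.
// [[Rcpp::export(name = ".routing_fwd_cpp")]]
List routing_fwd_cpp(const arma::cube& U, int B, int Pp, int J, int D,
                     int iters, int variant) {
  const int C = U.n_slices;
  const int JD = J * D;
  arma::cube cc(B * Pp, J, C);
  arma::mat S(B, JD), V(B, JD), hidn(B, J);

  std::vector<double> blog(Pp * J * C), ccl(Pp * J * C), Sb(JD), Vb(JD);

  for (int b = 0; b < B; ++b) {
    const int r0 = b * Pp;
    std::fill(blog.begin(), blog.end(), 0.0);

    for (int it = 0; it < iters; ++it) {
      // row-wise softmax of the logits, all channels
      for (int c = 0; c < C; ++c) {
        const double* bl = &blog[c * Pp * J];
        double* cl = &ccl[c * Pp * J];
        for (int p = 0; p < Pp; ++p) {
          double mx = bl[p];
          for (int j = 1; j < J; ++j) mx = std::max(mx, bl[j * Pp + p]);
          double sum = 0.0;
          for (int j = 0; j < J; ++j) {
            const double e = std::exp(bl[j * Pp + p] - mx);
            cl[j * Pp + p] = e;
            sum += e;
          }
          for (int j = 0; j < J; ++j) cl[j * Pp + p] /= sum;
        }
      }
      // weighted sums s_j
      std::fill(Sb.begin(), Sb.end(), 0.0);
      for (int c = 0; c < C; ++c) {
        const double* cl = &ccl[c * Pp * J];
        for (int j = 0; j < J; ++j) {
          const double* ccol = cl + j * Pp;
          for (int d = 0; d < D; ++d) {
            const double* ucol = U.slice(c).colptr(j * D + d) + r0;
            double acc = 0.0;
            for (int p = 0; p < Pp; ++p) acc += ucol[p] * ccol[p];
            Sb[j * D + d] += acc;
          }
        }
      }
      // squash
      for (int j = 0; j < J; ++j) {
        double n2 = 0.0;
        for (int d = 0; d < D; ++d) n2 += Sb[j * D + d] * Sb[j * D + d];
        const double nn = std::sqrt(n2);
        const double h = squash_scale(nn, variant);
        hidn(b, j) = nn;
        for (int d = 0; d < D; ++d) Vb[j * D + d] = Sb[j * D + d] * h;
      }
      // agreement update (skipped after the last iteration)
      if (it < iters - 1) {
        for (int c = 0; c < C; ++c) {
          double* bl = &blog[c * Pp * J];
          for (int j = 0; j < J; ++j) {
            double* bcol = bl + j * Pp;
            for (int d = 0; d < D; ++d) {
              const double* ucol = U.slice(c).colptr(j * D + d) + r0;
              const double v = Vb[j * D + d];
              for (int p = 0; p < Pp; ++p) bcol[p] += ucol[p] * v;
            }
          }
        }
      }
    }
    for (int d = 0; d < JD; ++d) {
      S(b, d) = Sb[d];
      V(b, d) = Vb[d];
    }
    for (int c = 0; c < C; ++c) {
      const double* cl = &ccl[c * Pp * J];
      for (int j = 0; j < J; ++j) {
        double* dst = cc.slice(c).colptr(j) + r0;
        std::copy(cl + j * Pp, cl + (j + 1) * Pp, dst);
      }
    }
  }
  return List::create(_["S"] = S, _["V"] = V, _["hid_n"] = hidn, _["cc"] = cc);
}

// Gradient of the routed weighted sum wrt the prediction vectors, with the
// coupling coefficients held fixed: dU(r, jD+d, c) = dS(b(r), jD+d) * cc(r, j, c)
// [[Rcpp::export(name = ".routing_bwd_cpp")]]
arma::cube routing_bwd_cpp(const arma::cube& cc, const arma::mat& dS,
                           int Pp, int D) {
  const int n = cc.n_rows;
  const int J = cc.n_cols;
  const int C = cc.n_slices;
  const int B = n / Pp;
  arma::cube dU(n, J * D, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& Cc = cc.slice(c);
    arma::mat& dUc = dU.slice(c);
    for (int j = 0; j < J; ++j) {
      const double* ccol = Cc.colptr(j);
      for (int d = 0; d < D; ++d) {
        const int col = j * D + d;
        const double* scol = dS.colptr(col);
        double* ducol = dUc.colptr(col);
        for (int b = 0, r = 0; b < B; ++b) {
          const double sb = scol[b];
          for (int p = 0; p < Pp; ++p, ++r) ducol[r] = sb * ccol[r];
        }
      }
    }
  }
  return dU;
}
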