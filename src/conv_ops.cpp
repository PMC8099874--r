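// Fused kernels for the two-layer spectrogram CNN. Convolutions are
// lowered to GEMM via an internal im2col (never materialised on the R
// side); the backward pass recomputes the forward activations so that only
// the input spectrogram and the parameter gradients cross the R/C++
// boundary. An in-place Adam step avoids repeated megabyte allocations in
// the training loop.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Weight layout (shared with the R side): W is a (kh*kw*C) x F matrix,
// element (c*kh*kw + j*kh + i, f) holds tap (i, j) of input channel c for
// filter f. Biases are length-F vectors.

// Patch matrix: row (oi + oj*oh) holds the patch with top-left (oi, oj).
static arma::mat im2col(const arma::cube& X, const int kh, const int kw) {
  const int oh = X.n_rows - kh + 1, ow = X.n_cols - kw + 1;
  const int C = X.n_slices;
  arma::mat P(oh * ow, kh * kw * C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& Xc = X.slice(c);
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        double* col = P.colptr(c * kh * kw + j * kh + i);
        for (int oj = 0; oj < ow; ++oj) {
          const double* src = Xc.colptr(oj + j) + i;
          std::memcpy(col + oj * oh, src, oh * sizeof(double));
        }
      }
  }
  return P;
}

// Adjoint of im2col: scatter-add patch-matrix gradients onto the input.
static arma::cube col2im(const arma::mat& G, const int H, const int W,
                         const int C, const int kh, const int kw) {
  const int oh = H - kh + 1, ow = W - kw + 1;
  arma::cube X(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& Xc = X.slice(c);
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        const double* col = G.colptr(c * kh * kw + j * kh + i);
        for (int oj = 0; oj < ow; ++oj) {
          double* dst = Xc.colptr(oj + j) + i;
          const double* src = col + oj * oh;
          for (int oi = 0; oi < oh; ++oi) dst[oi] += src[oi];
        }
      }
  }
  return X;
}

// conv + bias + ReLU; optionally keeps the patch matrix for reuse in the
// backward pass.
static arma::cube conv_relu(const arma::cube& X, const arma::mat& W,
                            const arma::vec& b, const int kh, const int kw,
                            arma::mat* keep_patches = nullptr) {
  const int oh = X.n_rows - kh + 1, ow = X.n_cols - kw + 1;
  const int F = W.n_cols;
  arma::mat P = im2col(X, kh, kw);
  arma::mat Z = P * W;
  Z.each_row() += b.t();
  Z.transform([](double v) { return v > 0 ? v : 0; });
  if (keep_patches) *keep_patches = std::move(P);
  arma::cube Y(oh, ow, F);
  std::memcpy(Y.memptr(), Z.memptr(), Z.n_elem * sizeof(double));
  return Y;
}

static void maxpool(const arma::cube& X, const int p, arma::cube& Y,
                    arma::ucube& idx) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int oh = H / p, ow = W / p;
  Y.set_size(oh, ow, C);
  idx.set_size(oh, ow, C);
  for (int c = 0; c < C; ++c)
    for (int oj = 0; oj < ow; ++oj)
      for (int oi = 0; oi < oh; ++oi) {
        double best = -arma::datum::inf;
        unsigned int best_idx = 0;
        for (int j = oj * p; j < (oj + 1) * p; ++j)
          for (int i = oi * p; i < (oi + 1) * p; ++i)
            if (X(i, j, c) > best) {
              best = X(i, j, c);
              best_idx = i + j * H;
            }
        Y(oi, oj, c) = best;
        idx(oi, oj, c) = best_idx;
      }
}

static arma::cube maxpool_bwd(const arma::cube& G, const arma::ucube& idx,
                              const int H, const int W) {
  arma::cube X(H, W, G.n_slices, arma::fill::zeros);
  for (unsigned int c = 0; c < G.n_slices; ++c) {
    double* slice = X.slice_memptr(c);
    for (unsigned int k = 0; k < G.n_rows * G.n_cols; ++k)
      slice[idx.slice(c)(k)] += G.slice(c)(k);
  }
  return X;
}

// Flat view of a cube as a (pixels x slices) matrix without copying.
static arma::mat cube_as_mat(arma::cube& X) {
  return arma::mat(X.memptr(), X.n_rows * X.n_cols, X.n_slices, false);
}

// Forward pass of the convolutional stack for one single-channel input:
// conv1 + ReLU -> pool -> conv2 + ReLU -> pool -> flatten. With
// want_a2 = TRUE also returns the post-ReLU conv2 maps and the pool-2
// argmax (needed for Grad-CAM).
// [[Rcpp::export]]
List cpp_conv_stack_fwd(const arma::mat& x, const arma::mat& W1,
                        const arma::vec& b1, const arma::mat& W2,
                        const arma::vec& b2, const int k1, const int k2,
                        const int pool, const bool want_a2) {
  arma::cube X(x.n_rows, x.n_cols, 1);
  X.slice(0) = x;
  arma::cube A1 = conv_relu(X, W1, b1, k1, k1);
  arma::cube P1, A2, P2;
  arma::ucube am1, am2;
  maxpool(A1, pool, P1, am1);
  A2 = conv_relu(P1, W2, b2, k2, k2);
  maxpool(A2, pool, P2, am2);
  arma::vec flat(P2.memptr(), P2.n_elem);
  if (!want_a2) return List::create(_["flat"] = flat);
  return List::create(_["flat"] = flat, _["A2"] = A2, _["argmax2"] = am2);
}

// Backward pass through the convolutional stack for one sample. The
// forward activations are recomputed internally; `dflat` is the loss
// gradient at the flattened pool-2 output. Returns the conv parameter
// gradients and, when want_dx = TRUE, the gradient at the input.
// [[Rcpp::export]]
List cpp_conv_stack_bwd(const arma::mat& x, const arma::mat& W1,
                        const arma::vec& b1, const arma::mat& W2,
                        const arma::vec& b2, const int k1, const int k2,
                        const int pool, const arma::vec& dflat,
                        const bool want_dx) {
  arma::cube X(x.n_rows, x.n_cols, 1);
  X.slice(0) = x;
  arma::mat patches1, patches2;
  arma::cube A1 = conv_relu(X, W1, b1, k1, k1, &patches1);
  arma::cube P1, A2, P2;
  arma::ucube am1, am2;
  maxpool(A1, pool, P1, am1);
  A2 = conv_relu(P1, W2, b2, k2, k2, &patches2);
  maxpool(A2, pool, P2, am2);

  arma::cube dP2(const_cast<double*>(dflat.memptr()), P2.n_rows, P2.n_cols,
                 P2.n_slices, false);
  arma::cube dZ2c = maxpool_bwd(dP2, am2, A2.n_rows, A2.n_cols);
  // ReLU mask: post-activation value > 0 iff pre-activation > 0 (a.e.)
  dZ2c.elem(arma::find(A2 <= 0)).zeros();
  arma::mat dZ2 = cube_as_mat(dZ2c);
  arma::mat dW2 = patches2.t() * dZ2;
  arma::vec db2 = arma::sum(dZ2, 0).t();
  arma::cube dP1 = col2im(dZ2 * W2.t(), P1.n_rows, P1.n_cols, P1.n_slices,
                          k2, k2);
  arma::cube dZ1c = maxpool_bwd(dP1, am1, A1.n_rows, A1.n_cols);
  dZ1c.elem(arma::find(A1 <= 0)).zeros();
  arma::mat dZ1 = cube_as_mat(dZ1c);
  arma::mat dW1 = patches1.t() * dZ1;
  arma::vec db1 = arma::sum(dZ1, 0).t();
  if (!want_dx) {
    return List::create(_["W1"] = dW1, _["b1"] = db1, _["W2"] = dW2,
                        _["b2"] = db2);
  }
  arma::cube dX = col2im(dZ1 * W1.t(), X.n_rows, X.n_cols, 1, k1, k1);
  return List::create(_["W1"] = dW1, _["b1"] = db1, _["W2"] = dW2,
                      _["b2"] = db2, _["dX"] = dX.slice(0));
}

// Standalone max pooling (used by Grad-CAM unpooling and tests).
// [[Rcpp::export]]
List cpp_maxpool(const arma::cube& X, const int p) {
  arma::cube Y; arma::ucube idx;
  if ((int)X.n_rows / p < 1 || (int)X.n_cols / p < 1)
    stop("pool size larger than input");
  maxpool(X, p, Y, idx);
  return List::create(_["out"] = Y, _["argmax"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bwd(const arma::cube& G, const arma::ucube& argmax,
                           const int H, const int W) {
  return maxpool_bwd(G, argmax, H, W);
}

// One fused, in-place Adam step over matched lists of parameters,
// gradients and first/second moment buffers. The caller owns all four
// lists exclusively (they are duplicated once at the start of training),
// so in-place mutation is safe and avoids reallocating the large dense
// weight matrices on every step.
// [[Rcpp::export]]
void cpp_adam_step(List params, List grads, List m, List v, const int t,
                   const double lr, const double beta1, const double beta2,
                   const double eps) {
  const double bc1 = 1.0 - std::pow(beta1, t);
  const double bc2 = 1.0 - std::pow(beta2, t);
  CharacterVector nms = grads.names();
  for (int i = 0; i < grads.size(); ++i) {
    std::string nm = as<std::string>(nms[i]);
    NumericVector p = params[nm], g = grads[nm], mi = m[nm], vi = v[nm];
    const R_xlen_t n = p.size();
    for (R_xlen_t k = 0; k < n; ++k) {
      mi[k] = beta1 * mi[k] + (1.0 - beta1) * g[k];
      vi[k] = beta2 * vi[k] + (1.0 - beta2) * g[k] * g[k];
      p[k] -= lr * (mi[k] / bc1) / (std::sqrt(vi[k] / bc2) + eps);
    }
  }
}
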