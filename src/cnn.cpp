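// Compact CNN engine for sector classification: four conv(3x3, same) ->
// ReLU -> maxpool(2x2) -> batch-norm stages, then three fully-connected
// layers with dropout and a sigmoid output. Dense linear algebra via
// Armadillo (im2col + GEMM for the convolutions). Dropout draws from R's
// RNG so training is reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::umat;
using arma::uword;

static const double BN_EPS = 1e-5;

// Activations are stored as (C, H*W*N) matrices, column index n*H*W + p
// with p = i + j*H (column-major spatial), single implicit channel axis.
// The im2col matrix uses row index k*C + c (kernel-offset-major), so that
// each kernel offset contributes one contiguous channel block per column;
// convolution weight matrices use the matching column layout.

static mat im2col_batch(const mat& A, int C, int H, int W, int N) {
  const int HW = H * W;
  mat K(C * 9, (uword)HW * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const uword off = (uword)n * HW;
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double* dst = K.colptr(off + i + (uword)j * H);
        for (int dj = -1; dj <= 1; ++dj) {
          const int jj = j + dj;
          if (jj < 0 || jj >= W) continue;
          for (int di = -1; di <= 1; ++di) {
            const int ii = i + di;
            if (ii < 0 || ii >= H) continue;
            const int k = (di + 1) * 3 + (dj + 1);
            std::memcpy(dst + (uword)k * C,
                        A.colptr(off + ii + (uword)jj * H),
                        sizeof(double) * C);
          }
        }
      }
    }
  }
  return K;
}

static mat col2im_batch(const mat& G, int C, int H, int W, int N) {
  const int HW = H * W;
  mat dA(C, (uword)HW * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const uword off = (uword)n * HW;
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const double* src = G.colptr(off + i + (uword)j * H);
        for (int dj = -1; dj <= 1; ++dj) {
          const int jj = j + dj;
          if (jj < 0 || jj >= W) continue;
          for (int di = -1; di <= 1; ++di) {
            const int ii = i + di;
            if (ii < 0 || ii >= H) continue;
            const int k = (di + 1) * 3 + (dj + 1);
            double* dst = dA.colptr(off + ii + (uword)jj * H);
            const double* s = src + (uword)k * C;
            for (int c = 0; c < C; ++c) dst[c] += s[c];
          }
        }
      }
    }
  }
  return dA;
}

static inline void relu_inplace(mat& X) {
  double* p = X.memptr();
  const uword n = X.n_elem;
  for (uword i = 0; i < n; ++i)
    if (p[i] < 0) p[i] = 0;
}

// zero entries of D where the forward activation A was not positive
static inline void relu_mask(mat& D, const mat& A) {
  double* d = D.memptr();
  const double* a = A.memptr();
  const uword n = D.n_elem;
  for (uword i = 0; i < n; ++i)
    if (a[i] <= 0) d[i] = 0;
}

static void pool_fwd(const mat& Y, int H, int W, int N, mat& P, umat& AM) {
  const int Ho = H / 2, Wo = W / 2, HWo = Ho * Wo, HW = H * W;
  const int C = Y.n_rows;
  P.set_size(C, (uword)HWo * N);
  AM.set_size(C, (uword)HWo * N);
  for (int n = 0; n < N; ++n)
    for (int j2 = 0; j2 < Wo; ++j2)
      for (int i2 = 0; i2 < Ho; ++i2) {
        const uword ocol = (uword)n * HWo + i2 + (uword)j2 * Ho;
        const uword p00 = (uword)n * HW + 2 * i2 + (uword)(2 * j2) * H;
        const uword cand[4] = {p00, p00 + 1, p00 + (uword)H, p00 + (uword)H + 1};
        for (int c = 0; c < C; ++c) {
          double best = Y(c, cand[0]);
          uword bi = cand[0];
          for (int t = 1; t < 4; ++t) {
            const double v = Y(c, cand[t]);
            if (v > best) { best = v; bi = cand[t]; }
          }
          P(c, ocol) = best;
          AM(c, ocol) = bi;
        }
      }
}

static mat pool_bwd(const mat& dP, const umat& AM, int C, uword ncolY) {
  mat dY(C, ncolY, arma::fill::zeros);
  for (uword col = 0; col < dP.n_cols; ++col)
    for (int c = 0; c < C; ++c)
      dY(c, AM(c, col)) += dP(c, col);
  return dY;
}

static mat dropout_mask(uword r, uword c, double rate) {
  mat M(r, c);
  const double keep = 1.0 - rate;
  for (uword i = 0; i < r * c; ++i)
    M(i) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
  return M;
}

static mat input_to_mat(const arma::cube& X) {
  const int H = X.n_rows, W = X.n_cols, N = X.n_slices;
  mat A(1, (uword)H * W * N);
  for (int n = 0; n < N; ++n)
    A.cols((uword)n * H * W, (uword)(n + 1) * H * W - 1) =
      arma::vectorise(X.slice(n)).t();
  return A;
}

static std::string nm(const char* base, int s) {
  return std::string(base) + std::to_string(s);
}

// Forward pass in inference mode: batch-norm uses the running statistics,
// dropout is disabled. Returns one sigmoid score per input patch.
// [[Rcpp::export]]
NumericVector cnn_forward_cpp(List params, const arma::cube& X,
                              List bn_mean, List bn_var) {
  const int N = X.n_slices;
  int H = X.n_rows, W = X.n_cols, C = 1;
  mat cur = input_to_mat(X);
  for (int s = 1; s <= 4; ++s) {
    const mat Wc = as<mat>(params[nm("Wc", s)]);
    const vec bc = as<vec>(params[nm("bc", s)]);
    const vec g = as<vec>(params[nm("gamma", s)]);
    const vec be = as<vec>(params[nm("beta", s)]);
    const vec rmu = as<vec>(bn_mean[s - 1]);
    const vec rvar = as<vec>(bn_var[s - 1]);
    mat K = im2col_batch(cur, C, H, W, N);
    mat Y = Wc * K;
    Y.each_col() += bc;
    relu_inplace(Y);
    mat P;
    umat AM;
    pool_fwd(Y, H, W, N, P, AM);
    const vec istd = 1.0 / arma::sqrt(rvar + BN_EPS);
    P.each_col() -= rmu;
    P.each_col() %= (istd % g);
    P.each_col() += be;
    cur = std::move(P);
    H /= 2; W /= 2; C = Wc.n_rows;
  }
  const int HWl = H * W, Df = C * HWl;
  mat F(Df, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int p = 0; p < HWl; ++p)
        F(c * HWl + p, n) = cur(c, (uword)n * HWl + p);
  mat A1 = as<mat>(params["Wf1"]) * F;
  A1.each_col() += as<vec>(params["bf1"]);
  relu_inplace(A1);
  mat A2 = as<mat>(params["Wf2"]) * A1;
  A2.each_col() += as<vec>(params["bf2"]);
  relu_inplace(A2);
  mat Z3 = as<mat>(params["Wf3"]) * A2;
  Z3.each_col() += as<vec>(params["bf3"]);
  NumericVector out(N);
  for (int n = 0; n < N; ++n) out[n] = 1.0 / (1.0 + std::exp(-Z3(0, n)));
  return out;
}

// Convolutional forward pass in batch-statistics mode, returning the
// per-stage batch-norm channel means and (biased) variances. Used to
// calibrate the running statistics after training, when few optimizer
// steps have been taken and momentum-averaged statistics are still stale.
// [[Rcpp::export]]
List cnn_batch_stats_cpp(List params, const arma::cube& X) {
  const int N = X.n_slices;
  int H = X.n_rows, W = X.n_cols, C = 1;
  mat cur = input_to_mat(X);
  List means(4), vars(4);
  for (int s = 1; s <= 4; ++s) {
    const mat Wc = as<mat>(params[nm("Wc", s)]);
    const vec bc = as<vec>(params[nm("bc", s)]);
    const vec g = as<vec>(params[nm("gamma", s)]);
    const vec be = as<vec>(params[nm("beta", s)]);
    mat K = im2col_batch(cur, C, H, W, N);
    mat Y = Wc * K;
    Y.each_col() += bc;
    relu_inplace(Y);
    mat P;
    umat AM;
    pool_fwd(Y, H, W, N, P, AM);
    const vec mu = arma::mean(P, 1);
    P.each_col() -= mu;
    const vec var = arma::mean(arma::square(P), 1);
    means[s - 1] = mu;
    vars[s - 1] = var;
    const vec istd = 1.0 / arma::sqrt(var + BN_EPS);
    P.each_col() %= (istd % g);
    P.each_col() += be;
    cur = std::move(P);
    H /= 2; W /= 2; C = Wc.n_rows;
  }
  return List::create(_["mean"] = means, _["var"] = vars);
}

// One training forward/backward pass on a batch: batch-norm uses batch
// statistics (returned so the caller can update running averages), dropout
// active. Returns the regularized loss, the scores, and gradients for
// every parameter (L2 gradient included for conv/FC weights).
// [[Rcpp::export]]
List cnn_train_step_cpp(List params, const arma::cube& X, const arma::vec& y,
                        double l2, double dropout_rate) {
  const int N = X.n_slices;
  std::vector<int> Hs(5), Ws(5), Cs(5);
  Hs[0] = X.n_rows; Ws[0] = X.n_cols; Cs[0] = 1;

  std::vector<mat> Ks(4), Yr(4), Xh(4), Wcs(4);
  std::vector<umat> AMs(4);
  std::vector<vec> istds(4), gammas(4), bmu(4), bvar(4);

  mat cur = input_to_mat(X);
  for (int s = 0; s < 4; ++s) {
    Wcs[s] = as<mat>(params[nm("Wc", s + 1)]);
    const vec bc = as<vec>(params[nm("bc", s + 1)]);
    gammas[s] = as<vec>(params[nm("gamma", s + 1)]);
    const vec be = as<vec>(params[nm("beta", s + 1)]);
    Ks[s] = im2col_batch(cur, Cs[s], Hs[s], Ws[s], N);
    mat Y = Wcs[s] * Ks[s];
    Y.each_col() += bc;
    relu_inplace(Y);
    mat P;
    pool_fwd(Y, Hs[s], Ws[s], N, P, AMs[s]);
    Yr[s] = std::move(Y);
    const vec mu = arma::mean(P, 1);
    P.each_col() -= mu;
    const vec var = arma::mean(arma::square(P), 1);
    const vec istd = 1.0 / arma::sqrt(var + BN_EPS);
    P.each_col() %= istd;           // P is now xhat
    Xh[s] = P;                       // keep normalized activations
    P.each_col() %= gammas[s];
    P.each_col() += be;
    bmu[s] = mu; bvar[s] = var; istds[s] = istd;
    Hs[s + 1] = Hs[s] / 2; Ws[s + 1] = Ws[s] / 2; Cs[s + 1] = Wcs[s].n_rows;
    cur = std::move(P);
  }

  const int Hl = Hs[4], Wl = Ws[4], Cl = Cs[4];
  const int HWl = Hl * Wl, Df = Cl * HWl;
  mat F(Df, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cl; ++c)
      for (int p = 0; p < HWl; ++p)
        F(c * HWl + p, n) = cur(c, (uword)n * HWl + p);

  const mat Wf1 = as<mat>(params["Wf1"]), Wf2 = as<mat>(params["Wf2"]),
            Wf3 = as<mat>(params["Wf3"]);
  const vec bf1 = as<vec>(params["bf1"]), bf2 = as<vec>(params["bf2"]),
            bf3 = as<vec>(params["bf3"]);

  // dropout on the input of each fully-connected layer
  const mat D0 = dropout_mask(Df, N, dropout_rate);
  const mat Fd = F % D0;
  mat A1 = Wf1 * Fd;
  A1.each_col() += bf1;
  relu_inplace(A1);
  const mat D1 = dropout_mask(A1.n_rows, N, dropout_rate);
  const mat A1d = A1 % D1;
  mat A2 = Wf2 * A1d;
  A2.each_col() += bf2;
  relu_inplace(A2);
  const mat D2 = dropout_mask(A2.n_rows, N, dropout_rate);
  const mat A2d = A2 % D2;
  mat Z3 = Wf3 * A2d;
  Z3.each_col() += bf3;

  arma::rowvec pr(N);
  double bce = 0.0;
  for (int n = 0; n < N; ++n) {
    double p = 1.0 / (1.0 + std::exp(-Z3(0, n)));
    pr(n) = p;
    const double pc = std::min(std::max(p, 1e-12), 1.0 - 1e-12);
    bce += -(y(n) * std::log(pc) + (1.0 - y(n)) * std::log(1.0 - pc));
  }
  bce /= N;
  double reg = 0.0;
  for (int s = 0; s < 4; ++s) reg += arma::accu(arma::square(Wcs[s]));
  reg += arma::accu(arma::square(Wf1)) + arma::accu(arma::square(Wf2)) +
         arma::accu(arma::square(Wf3));
  const double loss = bce + l2 * reg;

  // ---- backward ----
  arma::rowvec dz3 = (pr - y.t()) / N;
  const mat dWf3 = dz3 * A2d.t() + 2.0 * l2 * Wf3;
  vec dbf3(1);
  dbf3(0) = arma::accu(dz3);
  mat dA2 = (Wf3.t() * dz3) % D2;
  relu_mask(dA2, A2);
  const mat dWf2 = dA2 * A1d.t() + 2.0 * l2 * Wf2;
  const vec dbf2 = arma::sum(dA2, 1);
  mat dA1 = (Wf2.t() * dA2) % D1;
  relu_mask(dA1, A1);
  const mat dWf1 = dA1 * Fd.t() + 2.0 * l2 * Wf1;
  const vec dbf1 = arma::sum(dA1, 1);
  const mat dF = (Wf1.t() * dA1) % D0;

  mat dB(Cl, (uword)HWl * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cl; ++c)
      for (int p = 0; p < HWl; ++p)
        dB(c, (uword)n * HWl + p) = dF(c * HWl + p, n);

  List grads;
  grads["Wf1"] = dWf1; grads["bf1"] = dbf1;
  grads["Wf2"] = dWf2; grads["bf2"] = dbf2;
  grads["Wf3"] = dWf3; grads["bf3"] = dbf3;

  for (int s = 3; s >= 0; --s) {
    const double M = (double)Xh[s].n_cols;
    const vec dgamma = arma::sum(dB % Xh[s], 1);
    const vec dbeta = arma::sum(dB, 1);
    mat dxh = dB;
    dxh.each_col() %= gammas[s];
    const vec s1 = arma::sum(dxh, 1);
    const vec s2 = arma::sum(dxh % Xh[s], 1);
    mat dP = dxh * M;
    dP.each_col() -= s1;
    mat xs = Xh[s];
    xs.each_col() %= s2;
    dP -= xs;
    dP.each_col() %= (istds[s] / M);
    mat dY = pool_bwd(dP, AMs[s], Cs[s + 1], (uword)Hs[s] * Ws[s] * N);
    relu_mask(dY, Yr[s]);
    const mat dWc = dY * Ks[s].t() + 2.0 * l2 * Wcs[s];
    const vec dbc = arma::sum(dY, 1);
    grads[nm("Wc", s + 1)] = dWc;
    grads[nm("bc", s + 1)] = dbc;
    grads[nm("gamma", s + 1)] = dgamma;
    grads[nm("beta", s + 1)] = dbeta;
    if (s > 0) {
      const mat G = Wcs[s].t() * dY;
      dB = col2im_batch(G, Cs[s], Hs[s], Ws[s], N);
    }
  }

  return List::create(
    _["loss"] = loss, _["bce"] = bce,
    _["probs"] = NumericVector(pr.begin(), pr.end()),
    _["grads"] = grads,
    _["batch_mean"] = List::create(bmu[0], bmu[1], bmu[2], bmu[3]),
    _["batch_var"] = List::create(bvar[0], bvar[1], bvar[2], bvar[3]));
}
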