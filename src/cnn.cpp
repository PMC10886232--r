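// Minimal 2-D convolutional network: the fixed stack
//   [conv(k x k, valid) -> ReLU -> maxpool(p x p)] x B
//   -> flatten -> dropout -> dense(ReLU) -> dense(1, sigmoid)
// with exact backpropagation, used for binary spectrogram classification.
// Convolutions are im2col + GEMM; pooling drops any remainder rows/cols
// (valid pooling), so a 256 input with blocks (16,4,3),(32,4,3),(64,4,2)
// produces 84x84x16, 27x27x32, 12x12x64 feature maps.
//
// Weight layout (R list, in order):
//   per block: W (Cout x k*k*Cin), b (Cout)
//   dense1:    W (dense_width x flat), b (dense_width)
//   dense2:    W (1 x dense_width), b (1)
// Dropout masks are drawn from R's RNG so training is reproducible under
// set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Patch matrix: rows index (ki, kj, c), columns index output pixel
// q = j*Ho + i (column-major over the valid-conv output grid).
static mat im2col(const cube& a, const int k) {
  const int Ho = a.n_rows - k + 1, Wo = a.n_cols - k + 1, C = a.n_slices;
  mat cols(k * k * C, Ho * Wo);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int r = c * k * k + kj * k + ki;
        for (int j = 0; j < Wo; ++j) {
          const double* src = a.slice_colptr(c, j + kj) + ki;
          double* dst = cols.colptr(j * Ho) + r;
          for (int i = 0; i < Ho; ++i) dst[(size_t)i * cols.n_rows] = src[i];
        }
      }
  return cols;
}

// Adjoint of im2col: scatter-add column gradients back onto the input grid.
static cube col2im(const mat& dcols, const int H, const int W, const int C, const int k) {
  const int Ho = H - k + 1, Wo = W - k + 1;
  cube da(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int r = c * k * k + kj * k + ki;
        for (int j = 0; j < Wo; ++j) {
          double* dst = da.slice_colptr(c, j + kj) + ki;
          const double* src = dcols.colptr(j * Ho) + r;
          for (int i = 0; i < Ho; ++i) dst[i] += src[(size_t)i * dcols.n_rows];
        }
      }
  return da;
}

struct PoolOut {
  cube out;
  umat argmax; // linear index into the pre-pool cube, one row per slice
};

static PoolOut maxpool(const cube& a, const int p) {
  const int Ho = a.n_rows / p, Wo = a.n_cols / p, C = a.n_slices;
  PoolOut res;
  res.out.set_size(Ho, Wo, C);
  res.argmax.set_size(C, Ho * Wo);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = -datum::inf;
        uword bi = 0;
        for (int dj = 0; dj < p; ++dj)
          for (int di = 0; di < p; ++di) {
            const int ri = i * p + di, rj = j * p + dj;
            const double v = a(ri, rj, c);
            if (v > best) { best = v; bi = (uword)c * a.n_rows * a.n_cols + (uword)rj * a.n_rows + ri; }
          }
        res.out(i, j, c) = best;
        res.argmax(c, (uword)j * Ho + i) = bi;
      }
  return res;
}

struct Fwd {
  std::vector<cube> act;      // post-pool activation entering each block (act[0] = input)
  std::vector<mat>  cols;     // im2col of act[b]
  std::vector<mat>  convpre;  // pre-ReLU conv output (Cout x Ho*Wo)
  std::vector<PoolOut> pools;
  vec flat, flat_dropped, mask, h1pre, h1;
  double prob;
};

static cube mat_to_cube(const mat& Z, int Ho, int Wo) {
  // Z is Cout x (Ho*Wo); Z.t() memory layout matches an Ho x Wo x Cout cube.
  mat Zt = Z.t();
  return cube(Zt.memptr(), Ho, Wo, Z.n_rows);
}

static Fwd forward_one(const mat& img, const Rcpp::List& weights,
                       const imat& blocks, const double dropout_rate,
                       const bool training) {
  const int B = blocks.n_rows;
  Fwd f;
  cube a(img.n_rows, img.n_cols, 1);
  a.slice(0) = img;
  for (int b = 0; b < B; ++b) {
    f.act.push_back(a);
    const int k = blocks(b, 1), p = blocks(b, 2);
    const mat W = Rcpp::as<mat>(weights[2 * b]);
    const vec bias = Rcpp::as<vec>(weights[2 * b + 1]);
    mat cols = im2col(a, k);
    mat Z = W * cols;
    Z.each_col() += bias;
    f.convpre.push_back(Z);
    mat A = clamp(Z, 0.0, datum::inf); // ReLU
    const int Ho = a.n_rows - k + 1, Wo = a.n_cols - k + 1;
    cube ac = mat_to_cube(A, Ho, Wo);
    PoolOut po = maxpool(ac, p);
    f.pools.push_back(po);
    f.cols.push_back(std::move(cols));
    a = po.out;
  }
  f.act.push_back(a);
  f.flat = vectorise(a);
  if (training && dropout_rate > 0) {
    f.mask.set_size(f.flat.n_elem);
    for (uword i = 0; i < f.mask.n_elem; ++i)
      f.mask(i) = (R::unif_rand() < dropout_rate) ? 0.0 : 1.0 / (1.0 - dropout_rate);
    f.flat_dropped = f.flat % f.mask;
  } else {
    f.mask = vec(f.flat.n_elem, fill::ones);
    f.flat_dropped = f.flat;
  }
  const mat W1 = Rcpp::as<mat>(weights[2 * B]);
  const vec b1 = Rcpp::as<vec>(weights[2 * B + 1]);
  const mat W2 = Rcpp::as<mat>(weights[2 * B + 2]);
  const vec b2 = Rcpp::as<vec>(weights[2 * B + 3]);
  f.h1pre = W1 * f.flat_dropped + b1;
  f.h1 = clamp(f.h1pre, 0.0, datum::inf);
  const double z = as_scalar(W2 * f.h1) + b2(0);
  f.prob = 1.0 / (1.0 + std::exp(-z));
  return f;
}

// [[Rcpp::export]]
Rcpp::List cnn_forward_batch(const Rcpp::List& images, const Rcpp::List& weights,
                             const arma::imat& blocks) {
  const int N = images.size();
  vec probs(N);
  for (int n = 0; n < N; ++n) {
    Fwd f = forward_one(Rcpp::as<mat>(images[n]), weights, blocks, 0.0, false);
    probs(n) = f.prob;
  }
  return Rcpp::List::create(Rcpp::Named("probs") = probs);
}

// One minibatch: forward, mean binary cross-entropy loss, and mean
// gradients for every weight tensor.
// [[Rcpp::export]]
Rcpp::List cnn_batch_grad(const Rcpp::List& images, const arma::vec& y,
                          const Rcpp::List& weights, const arma::imat& blocks,
                          const double dropout_rate) {
  Rcpp::RNGScope rngScope;
  const int N = images.size(), B = blocks.n_rows;
  const double eps = 1e-12;
  std::vector<mat> gW(2 * B + 2);
  std::vector<vec> gb(2 * B + 2);
  for (int b = 0; b < B; ++b) {
    gW[b] = zeros<mat>(Rcpp::as<mat>(weights[2 * b]).n_rows, Rcpp::as<mat>(weights[2 * b]).n_cols);
    gb[b] = zeros<vec>(Rcpp::as<vec>(weights[2 * b + 1]).n_elem);
  }
  gW[B] = zeros<mat>(Rcpp::as<mat>(weights[2 * B]).n_rows, Rcpp::as<mat>(weights[2 * B]).n_cols);
  gb[B] = zeros<vec>(Rcpp::as<vec>(weights[2 * B + 1]).n_elem);
  gW[B + 1] = zeros<mat>(Rcpp::as<mat>(weights[2 * B + 2]).n_rows, Rcpp::as<mat>(weights[2 * B + 2]).n_cols);
  gb[B + 1] = zeros<vec>(Rcpp::as<vec>(weights[2 * B + 3]).n_elem);

  double loss = 0.0;
  vec probs(N);
  const mat W1 = Rcpp::as<mat>(weights[2 * B]);
  const mat W2 = Rcpp::as<mat>(weights[2 * B + 2]);

  for (int n = 0; n < N; ++n) {
    Fwd f = forward_one(Rcpp::as<mat>(images[n]), weights, blocks, dropout_rate, true);
    probs(n) = f.prob;
    const double p = std::min(std::max(f.prob, eps), 1.0 - eps);
    loss += -(y(n) * std::log(p) + (1.0 - y(n)) * std::log(1.0 - p));

    // output layer: dL/dz = p - y
    const double dz2 = f.prob - y(n);
    gW[B + 1] += dz2 * f.h1.t();
    gb[B + 1](0) += dz2;
    vec dh1 = W2.t() * dz2;
    dh1.elem(find(f.h1pre <= 0)).zeros();
    gW[B] += dh1 * f.flat_dropped.t();
    gb[B] += dh1;
    vec dflat = (W1.t() * dh1) % f.mask;

    // back through the blocks
    cube da = cube(dflat.memptr(), f.act[B].n_rows, f.act[B].n_cols, f.act[B].n_slices);
    for (int b = B - 1; b >= 0; --b) {
      const int k = blocks(b, 1);
      const cube& ain = f.act[b];
      const int Ho = ain.n_rows - k + 1, Wo = ain.n_cols - k + 1;
      const int Cout = blocks(b, 0);
      // unpool: route gradient to the stored argmax positions
      cube dpre(Ho, Wo, Cout, fill::zeros);
      const PoolOut& po = f.pools[b];
      for (int c = 0; c < Cout; ++c)
        for (uword q = 0; q < po.out.n_rows * po.out.n_cols; ++q) {
          const uword j = q / po.out.n_rows, i = q % po.out.n_rows;
          dpre(po.argmax(c, q)) += da(i, j, c);
        }
      // ReLU mask, back to Cout x (Ho*Wo)
      mat dZ(Cout, Ho * Wo);
      for (int c = 0; c < Cout; ++c)
        for (int q = 0; q < Ho * Wo; ++q)
          dZ(c, q) = (f.convpre[b](c, q) > 0) ? dpre((uword)c * Ho * Wo + q) : 0.0;
      gW[b] += dZ * f.cols[b].t();
      gb[b] += sum(dZ, 1);
      if (b > 0) {
        const mat Wb = Rcpp::as<mat>(weights[2 * b]);
        mat dcols = Wb.t() * dZ;
        da = col2im(dcols, ain.n_rows, ain.n_cols, ain.n_slices, k);
      }
    }
  }

  Rcpp::List grads(2 * B + 4);
  for (int b = 0; b < B; ++b) {
    grads[2 * b] = gW[b] / N;
    grads[2 * b + 1] = gb[b] / N;
  }
  grads[2 * B] = gW[B] / N;
  grads[2 * B + 1] = gb[B] / N;
  grads[2 * B + 2] = gW[B + 1] / N;
  grads[2 * B + 3] = gb[B + 1] / N;
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss / N,
    Rcpp::Named("probs") = probs,
    Rcpp::Named("grads") = grads
  );
}
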