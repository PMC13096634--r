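// Compact CNN engine: two 3x3 conv blocks (ReLU + 2x2 max-pool), a dense
// hidden layer with inverted dropout, and a softmax output. Written against
// RcppArmadillo with im2col + GEMM convolutions, templated on the scalar
// type: training and prediction run in single precision (the GEMMs dominate
// and sgemm is ~2x dgemm), the gradient-check entry point in double. All
// randomness (weight init, shuffling, dropout) comes from R's RNG so
// set.seed() on the R side makes training bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Dims {
  int S;       // input side length
  int F1, F2;  // filters in conv block 1 / 2 (F2 = 2*F1)
  int C1, Q1;  // conv1 output side, pooled side
  int C2, Q2;  // conv2 output side, pooled side
  int flat;    // flattened length Q2*Q2*F2
  int dense;   // hidden units
  int K;       // classes
};

Dims make_dims(int S, int F1, int dense, int K) {
  Dims d;
  d.S = S; d.F1 = F1; d.F2 = 2 * F1;
  d.C1 = S - 2; d.Q1 = d.C1 / 2;
  d.C2 = d.Q1 - 2; d.Q2 = d.C2 / 2;
  if (d.C1 < 2 || d.C2 < 2 || d.Q2 < 1)
    Rcpp::stop("input size %d is too small for two conv blocks", S);
  d.flat = d.Q2 * d.Q2 * d.F2;
  d.dense = dense; d.K = K;
  return d;
}

template <typename T>
struct Net {
  Mat<T> W1, W2, W3, W4;
  Col<T> b1, b2, b3, b4;
};

template <typename T>
struct Work {  // per-sample buffers, allocated once
  Mat<T> img, col1, Z1, P1, col2, Z2, P2, dR1, dR2, dcol2, dP1, dP2, dZ1, dZ2;
  umat AM1, AM2;
  Col<T> fvec, hpre, h, mask, hd, logits, prob;
  Mat<T> gW1, gW2, gW3, gW4;
  Col<T> gb1, gb2, gb3, gb4;
};

template <typename T>
Work<T> make_work(const Dims& d) {
  Work<T> w;
  w.img.set_size(d.S, d.S);
  w.col1.set_size(d.C1 * d.C1, 9);
  w.Z1.set_size(d.C1 * d.C1, d.F1);
  w.P1.set_size(d.Q1 * d.Q1, d.F1);
  w.AM1.set_size(d.Q1 * d.Q1, d.F1);
  w.col2.set_size(d.C2 * d.C2, 9 * d.F1);
  w.Z2.set_size(d.C2 * d.C2, d.F2);
  w.P2.set_size(d.Q2 * d.Q2, d.F2);
  w.AM2.set_size(d.Q2 * d.Q2, d.F2);
  w.fvec.set_size(d.flat);
  w.mask.set_size(d.dense);
  w.gW1.set_size(9, d.F1); w.gW2.set_size(9 * d.F1, d.F2);
  w.gW3.set_size(d.flat, d.dense); w.gW4.set_size(d.dense, d.K);
  w.gb1.set_size(d.F1); w.gb2.set_size(d.F2);
  w.gb3.set_size(d.dense); w.gb4.set_size(d.K);
  w.dR1.set_size(d.C1 * d.C1, d.F1);
  w.dR2.set_size(d.C2 * d.C2, d.F2);
  w.dcol2.set_size(d.C2 * d.C2, 9 * d.F1);
  w.dP1.set_size(d.Q1 * d.Q1, d.F1);
  return w;
}

template <typename T>
void zero_grads(Work<T>& w) {
  w.gW1.zeros(); w.gW2.zeros(); w.gW3.zeros(); w.gW4.zeros();
  w.gb1.zeros(); w.gb2.zeros(); w.gb3.zeros(); w.gb4.zeros();
}

// column-major image patch extraction: output position p = i + j*C,
// patch element k = di + dj*3 (+ 9*f for the second block)
template <typename T>
void im2col_1(const Mat<T>& img, int C1, Mat<T>& out) {
  for (int dj = 0; dj < 3; ++dj)
    for (int di = 0; di < 3; ++di) {
      const int k = di + dj * 3;
      for (int j = 0; j < C1; ++j) {
        const T* src = img.colptr(j + dj) + di;
        T* dst = out.colptr(k) + j * C1;
        std::copy(src, src + C1, dst);
      }
    }
}

template <typename T>
void im2col_2(const Mat<T>& P1, int Q1, int C2, int F1, Mat<T>& out) {
  for (int f = 0; f < F1; ++f) {
    const T* map = P1.colptr(f);  // Q1*Q1 map, column-major
    for (int dj = 0; dj < 3; ++dj)
      for (int di = 0; di < 3; ++di) {
        const int k = di + dj * 3 + 9 * f;
        for (int j = 0; j < C2; ++j) {
          const T* src = map + (j + dj) * Q1 + di;
          T* dst = out.colptr(k) + j * C2;
          std::copy(src, src + C2, dst);
        }
      }
  }
}

template <typename T>
void maxpool(const Mat<T>& R, int C, int Q, Mat<T>& P, umat& AM) {
  const int F = R.n_cols;
  for (int f = 0; f < F; ++f) {
    const T* src = R.colptr(f);
    for (int pj = 0; pj < Q; ++pj)
      for (int pi = 0; pi < Q; ++pi) {
        uword best = (2 * pi) + (2 * pj) * C;
        T bv = src[best];
        const uword cand[3] = {(uword)((2 * pi + 1) + (2 * pj) * C),
                               (uword)((2 * pi) + (2 * pj + 1) * C),
                               (uword)((2 * pi + 1) + (2 * pj + 1) * C)};
        for (int c = 0; c < 3; ++c)
          if (src[cand[c]] > bv) { bv = src[cand[c]]; best = cand[c]; }
        P(pi + pj * Q, f) = bv;
        AM(pi + pj * Q, f) = best;
      }
  }
}

// forward pass for one image; returns loss for label y (or just fills prob
// when y < 0). dropout toggles the pre-filled inverted-dropout mask.
template <typename T>
double forward(const Net<T>& net, const Dims& d, Work<T>& w, int y, bool dropout) {
  im2col_1(w.img, d.C1, w.col1);
  w.Z1 = w.col1 * net.W1;
  w.Z1.each_row() += net.b1.t();
  Mat<T> R1 = clamp(w.Z1, T(0), std::numeric_limits<T>::max());
  maxpool(R1, d.C1, d.Q1, w.P1, w.AM1);
  im2col_2(w.P1, d.Q1, d.C2, d.F1, w.col2);
  w.Z2 = w.col2 * net.W2;
  w.Z2.each_row() += net.b2.t();
  Mat<T> R2 = clamp(w.Z2, T(0), std::numeric_limits<T>::max());
  maxpool(R2, d.C2, d.Q2, w.P2, w.AM2);
  w.fvec = vectorise(w.P2);
  w.hpre = net.W3.t() * w.fvec + net.b3;
  w.h = clamp(w.hpre, T(0), std::numeric_limits<T>::max());
  w.hd = dropout ? Col<T>(w.h % w.mask) : w.h;
  w.logits = net.W4.t() * w.hd + net.b4;
  Col<T> shifted = w.logits - w.logits.max();
  w.prob = exp(shifted);
  w.prob /= accu(w.prob);
  if (y < 0) return 0.0;
  return -std::log(std::max((double)w.prob(y), 1e-12));
}

template <typename T>
void backward(const Net<T>& net, const Dims& d, Work<T>& w, int y, bool dropout) {
  Col<T> dlog = w.prob;
  dlog(y) -= T(1);
  w.gW4 += w.hd * dlog.t();
  w.gb4 += dlog;
  Col<T> dhd = net.W4 * dlog;
  if (dropout) dhd %= w.mask;
  Col<T> dh = dhd % conv_to<Col<T>>::from(w.hpre > T(0));
  w.gW3 += w.fvec * dh.t();
  w.gb3 += dh;
  Col<T> df = net.W3 * dh;
  w.dP2 = reshape(df, d.Q2 * d.Q2, d.F2);
  w.dR2.zeros();
  for (int f = 0; f < d.F2; ++f)
    for (int q = 0; q < d.Q2 * d.Q2; ++q)
      w.dR2(w.AM2(q, f), f) += w.dP2(q, f);
  w.dZ2 = w.dR2 % conv_to<Mat<T>>::from(w.Z2 > T(0));
  w.gW2 += w.col2.t() * w.dZ2;
  w.gb2 += sum(w.dZ2, 0).t();
  w.dcol2 = w.dZ2 * net.W2.t();
  w.dP1.zeros();
  for (int f = 0; f < d.F1; ++f)
    for (int dj = 0; dj < 3; ++dj)
      for (int di = 0; di < 3; ++di) {
        const int k = di + dj * 3 + 9 * f;
        for (int j = 0; j < d.C2; ++j)
          for (int i = 0; i < d.C2; ++i)
            w.dP1((i + di) + (j + dj) * d.Q1, f) += w.dcol2(i + j * d.C2, k);
      }
  w.dR1.zeros();
  for (int f = 0; f < d.F1; ++f)
    for (int q = 0; q < d.Q1 * d.Q1; ++q)
      w.dR1(w.AM1(q, f), f) += w.dP1(q, f);
  w.dZ1 = w.dR1 % conv_to<Mat<T>>::from(w.Z1 > T(0));
  w.gW1 += w.col1.t() * w.dZ1;
  w.gb1 += sum(w.dZ1, 0).t();
}

template <typename T>
void load_image(const mat& X, int row, int S, Mat<T>& img) {
  // each row of X is one column-major S x S image
  for (int j = 0; j < S; ++j)
    for (int i = 0; i < S; ++i)
      img(i, j) = (T)X(row, i + j * S);
}

template <typename T>
Mat<T> rnorm_mat(int r, int c, double sd) {
  Mat<T> m(r, c);
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i)
      m(i, j) = (T)(R::norm_rand() * sd);
  return m;
}

template <typename T>
Net<T> init_net(const Dims& d) {  // He initialization, zero biases
  Net<T> n;
  n.W1 = rnorm_mat<T>(9, d.F1, std::sqrt(2.0 / 9.0));
  n.W2 = rnorm_mat<T>(9 * d.F1, d.F2, std::sqrt(2.0 / (9.0 * d.F1)));
  n.W3 = rnorm_mat<T>(d.flat, d.dense, std::sqrt(2.0 / d.flat));
  n.W4 = rnorm_mat<T>(d.dense, d.K, std::sqrt(2.0 / d.dense));
  n.b1.zeros(d.F1); n.b2.zeros(d.F2); n.b3.zeros(d.dense); n.b4.zeros(d.K);
  return n;
}

template <typename T>
Net<T> net_from_list(const Rcpp::List& L) {
  Net<T> n;
  n.W1 = conv_to<Mat<T>>::from(Rcpp::as<mat>(L["W1"]));
  n.W2 = conv_to<Mat<T>>::from(Rcpp::as<mat>(L["W2"]));
  n.W3 = conv_to<Mat<T>>::from(Rcpp::as<mat>(L["W3"]));
  n.W4 = conv_to<Mat<T>>::from(Rcpp::as<mat>(L["W4"]));
  n.b1 = conv_to<Col<T>>::from(Rcpp::as<vec>(L["b1"]));
  n.b2 = conv_to<Col<T>>::from(Rcpp::as<vec>(L["b2"]));
  n.b3 = conv_to<Col<T>>::from(Rcpp::as<vec>(L["b3"]));
  n.b4 = conv_to<Col<T>>::from(Rcpp::as<vec>(L["b4"]));
  return n;
}

template <typename T>
Rcpp::List net_to_list(const Net<T>& n) {
  return Rcpp::List::create(
      Rcpp::Named("W1") = conv_to<mat>::from(n.W1),
      Rcpp::Named("b1") = conv_to<vec>::from(n.b1),
      Rcpp::Named("W2") = conv_to<mat>::from(n.W2),
      Rcpp::Named("b2") = conv_to<vec>::from(n.b2),
      Rcpp::Named("W3") = conv_to<mat>::from(n.W3),
      Rcpp::Named("b3") = conv_to<vec>::from(n.b3),
      Rcpp::Named("W4") = conv_to<mat>::from(n.W4),
      Rcpp::Named("b4") = conv_to<vec>::from(n.b4));
}

template <typename T>
struct Adam {
  Mat<T> mW1, mW2, mW3, mW4, vW1, vW2, vW3, vW4;
  Col<T> mb1, mb2, mb3, mb4, vb1, vb2, vb3, vb4;
  long t = 0;
  void init(const Net<T>& n) {
    mW1 = zeros<Mat<T>>(size(n.W1)); vW1 = mW1;
    mW2 = zeros<Mat<T>>(size(n.W2)); vW2 = mW2;
    mW3 = zeros<Mat<T>>(size(n.W3)); vW3 = mW3;
    mW4 = zeros<Mat<T>>(size(n.W4)); vW4 = mW4;
    mb1 = zeros<Col<T>>(size(n.b1)); vb1 = mb1;
    mb2 = zeros<Col<T>>(size(n.b2)); vb2 = mb2;
    mb3 = zeros<Col<T>>(size(n.b3)); vb3 = mb3;
    mb4 = zeros<Col<T>>(size(n.b4)); vb4 = mb4;
  }
};

template <typename M, typename T>
void adam_step(M& w, M& m, M& v, const M& g, T lr, long t) {
  const T b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  const T c1 = 1 - std::pow(b1, (T)t), c2 = 1 - std::pow(b2, (T)t);
  w -= lr * (m / c1) / (sqrt(v / c2) + eps);
}

}  // namespace

typedef float train_t;  // training/prediction scalar type

// [[Rcpp::export]]
Rcpp::List cpp_cnn_train(const arma::mat& X, const Rcpp::IntegerVector& y,
                         int input_size, int filters1, int dense_units,
                         int n_classes, double learning_rate, int batch_size,
                         double dropout, std::string optimizer, int epochs,
                         Rcpp::Nullable<Rcpp::List> init_weights = R_NilValue) {
  typedef train_t T;
  const int n = X.n_rows;
  if ((int)y.size() != n) Rcpp::stop("length(y) must match nrow(X)");
  Dims d = make_dims(input_size, filters1, dense_units, n_classes);
  if ((int)X.n_cols != d.S * d.S) Rcpp::stop("ncol(X) must equal input_size^2");
  Net<T> net = init_weights.isNotNull()
                   ? net_from_list<T>(Rcpp::List(init_weights))
                   : init_net<T>(d);
  Adam<T> adam;
  const bool use_adam = (optimizer == "adam");
  if (use_adam) adam.init(net);
  Work<T> w = make_work<T>(d);
  const bool use_dropout = dropout > 0.0;
  std::vector<double> epoch_loss;
  epoch_loss.reserve(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    Rcpp::IntegerVector perm = Rcpp::sample(n, n, false);  // R RNG shuffle
    double loss_sum = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      const int stop = std::min(start + batch_size, n);
      const int B = stop - start;
      zero_grads(w);
      for (int b = start; b < stop; ++b) {
        const int idx = perm[b] - 1;
        load_image(X, idx, d.S, w.img);
        if (use_dropout)
          for (int k = 0; k < d.dense; ++k)
            w.mask(k) = (R::unif_rand() >= dropout) ? (T)(1.0 / (1.0 - dropout)) : (T)0;
        loss_sum += forward(net, d, w, y[idx], use_dropout);
        backward(net, d, w, y[idx], use_dropout);
      }
      const T lr = (T)learning_rate, inv = (T)(1.0 / B);
      if (use_adam) {
        ++adam.t;
        adam_step(net.W1, adam.mW1, adam.vW1, Mat<T>(w.gW1 * inv), lr, adam.t);
        adam_step(net.W2, adam.mW2, adam.vW2, Mat<T>(w.gW2 * inv), lr, adam.t);
        adam_step(net.W3, adam.mW3, adam.vW3, Mat<T>(w.gW3 * inv), lr, adam.t);
        adam_step(net.W4, adam.mW4, adam.vW4, Mat<T>(w.gW4 * inv), lr, adam.t);
        adam_step(net.b1, adam.mb1, adam.vb1, Col<T>(w.gb1 * inv), lr, adam.t);
        adam_step(net.b2, adam.mb2, adam.vb2, Col<T>(w.gb2 * inv), lr, adam.t);
        adam_step(net.b3, adam.mb3, adam.vb3, Col<T>(w.gb3 * inv), lr, adam.t);
        adam_step(net.b4, adam.mb4, adam.vb4, Col<T>(w.gb4 * inv), lr, adam.t);
      } else {  // plain SGD
        net.W1 -= lr * inv * w.gW1;
        net.W2 -= lr * inv * w.gW2;
        net.W3 -= lr * inv * w.gW3;
        net.W4 -= lr * inv * w.gW4;
        net.b1 -= lr * inv * w.gb1;
        net.b2 -= lr * inv * w.gb2;
        net.b3 -= lr * inv * w.gb3;
        net.b4 -= lr * inv * w.gb4;
      }
      Rcpp::checkUserInterrupt();
    }
    epoch_loss.push_back(loss_sum / n);
  }
  Rcpp::List out = net_to_list(net);
  out["epoch_loss"] = epoch_loss;
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_cnn_predict(const Rcpp::List& weights, const arma::mat& X,
                          int input_size) {
  typedef train_t T;
  Net<T> net = net_from_list<T>(weights);
  const int F1 = net.W1.n_cols, dense = net.W3.n_cols, K = net.W4.n_cols;
  Dims d = make_dims(input_size, F1, dense, K);
  if ((int)X.n_cols != d.S * d.S) Rcpp::stop("ncol(X) must equal input_size^2");
  Work<T> w = make_work<T>(d);
  mat probs(X.n_rows, K);
  for (uword i = 0; i < X.n_rows; ++i) {
    load_image(X, i, d.S, w.img);
    forward(net, d, w, -1, false);
    probs.row(i) = conv_to<rowvec>::from(w.prob.t());
  }
  return probs;
}

// mean loss and gradients over a dataset with dropout off, in double
// precision; used for finite-difference gradient verification.
// [[Rcpp::export]]
Rcpp::List cpp_cnn_loss_grad(const Rcpp::List& weights, const arma::mat& X,
                             const Rcpp::IntegerVector& y, int input_size) {
  Net<double> net = net_from_list<double>(weights);
  const int F1 = net.W1.n_cols, dense = net.W3.n_cols, K = net.W4.n_cols;
  Dims d = make_dims(input_size, F1, dense, K);
  const int n = X.n_rows;
  Work<double> w = make_work<double>(d);
  zero_grads(w);
  double loss = 0.0;
  for (int i = 0; i < n; ++i) {
    load_image(X, i, d.S, w.img);
    loss += forward(net, d, w, y[i], false);
    backward(net, d, w, y[i], false);
  }
  const double inv = 1.0 / n;
  return Rcpp::List::create(
      Rcpp::Named("loss") = loss * inv,
      Rcpp::Named("gW1") = mat(w.gW1 * inv), Rcpp::Named("gb1") = vec(w.gb1 * inv),
      Rcpp::Named("gW2") = mat(w.gW2 * inv), Rcpp::Named("gb2") = vec(w.gb2 * inv),
      Rcpp::Named("gW3") = mat(w.gW3 * inv), Rcpp::Named("gb3") = vec(w.gb3 * inv),
      Rcpp::Named("gW4") = mat(w.gW4 * inv), Rcpp::Named("gb4") = vec(w.gb4 * inv));
}
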