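// Patch CNN core: two valid convolutions with ReLU, two max pools
// (stride = kernel), fully connected head, softmax cross-entropy.
// Layout conventions (must match the R reference used in tests):
//  - images / feature maps are arma::cube (rows, cols, channels), column-major;
//  - im2col row index r = ki + kj*kh + c*kh*kw (ki fastest), column index
//    q = oi + oj*oh (output row fastest);
//  - weight matrix W is (n_filters x kh*kw*channels), one filter per row;
//  - the flattened pool-2 output is arma::vectorise(cube), i.e. column-major
//    within each channel slice, channels last.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat im2col(const cube& img, const int kh, const int kw) {
  const int h = img.n_rows, w = img.n_cols, C = img.n_slices;
  const int oh = h - kh + 1, ow = w - kw + 1;
  mat col(kh * kw * C, oh * ow);
  for (int c = 0; c < C; ++c) {
    const mat& sl = img.slice(c);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kj * kh + c * kh * kw;
        // gather the oh x ow block starting at (ki, kj), column-major
        mat blk = sl.submat(ki, kj, ki + oh - 1, kj + ow - 1);
        col.row(r) = vectorise(blk).t();
      }
    }
  }
  return col;
}

static cube col2im(const mat& dcol, const int h, const int w, const int C,
                   const int kh, const int kw) {
  const int oh = h - kh + 1, ow = w - kw + 1;
  cube dimg(h, w, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& sl = dimg.slice(c);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kj * kh + c * kh * kw;
        mat add = reshape(dcol.row(r).t(), oh, ow);
        sl.submat(ki, kj, ki + oh - 1, kj + ow - 1) += add;
      }
    }
  }
  return dimg;
}

// max pool with stride = kernel; records flat argmax index into the input cube
static cube maxpool(const cube& in, const int k, ucube& argmax) {
  const int oh = in.n_rows / k, ow = in.n_cols / k, C = in.n_slices;
  cube out(oh, ow, C);
  argmax.set_size(oh, ow, C);
  for (int c = 0; c < C; ++c) {
    for (int oj = 0; oj < ow; ++oj) {
      for (int oi = 0; oi < oh; ++oi) {
        double best = -datum::inf; int bi = 0, bj = 0;
        for (int dj = 0; dj < k; ++dj) {
          for (int di = 0; di < k; ++di) {
            const int i = oi * k + di, j = oj * k + dj;
            const double v = in(i, j, c);
            if (v > best) { best = v; bi = i; bj = j; }
          }
        }
        out(oi, oj, c) = best;
        argmax(oi, oj, c) = (uword)(bi + bj * in.n_rows + c * in.n_rows * in.n_cols);
      }
    }
  }
  return out;
}

struct Weights {
  mat W1, W2, W3;
  vec b1, b2, b3;
  int kh1, kw1, kh2, kw2, p1, p2;
};

static Weights unpack(const Rcpp::List& wl) {
  Weights w;
  w.W1 = Rcpp::as<mat>(wl["W1"]); w.b1 = Rcpp::as<vec>(wl["b1"]);
  w.W2 = Rcpp::as<mat>(wl["W2"]); w.b2 = Rcpp::as<vec>(wl["b2"]);
  w.W3 = Rcpp::as<mat>(wl["W3"]); w.b3 = Rcpp::as<vec>(wl["b3"]);
  Rcpp::IntegerVector g = wl["geom"]; // kh1, kw1, p1, kh2, kw2, p2
  w.kh1 = g[0]; w.kw1 = g[1]; w.p1 = g[2]; w.kh2 = g[3]; w.kw2 = g[4]; w.p2 = g[5];
  return w;
}

struct FwdCache {
  mat col1, col2;
  cube a1, r1, p1c, a2, r2, p2c;
  ucube am1, am2;
  vec flat, probs, logits;
};

static void forward_one(const cube& x, const Weights& w, FwdCache& fc) {
  const int h = x.n_rows, wd = x.n_cols;
  const int oh1 = h - w.kh1 + 1, ow1 = wd - w.kw1 + 1;
  fc.col1 = im2col(x, w.kh1, w.kw1);
  mat z1 = w.W1 * fc.col1;            // F1 x oh1*ow1
  z1.each_col() += w.b1;
  fc.a1 = cube(oh1, ow1, w.W1.n_rows);
  for (uword f = 0; f < w.W1.n_rows; ++f)
    fc.a1.slice(f) = reshape(z1.row(f).t(), oh1, ow1);
  fc.r1 = fc.a1; fc.r1.transform([](double v){ return v > 0 ? v : 0.0; });
  fc.p1c = maxpool(fc.r1, w.p1, fc.am1);

  const int oh2 = fc.p1c.n_rows - w.kh2 + 1, ow2 = fc.p1c.n_cols - w.kw2 + 1;
  fc.col2 = im2col(fc.p1c, w.kh2, w.kw2);
  mat z2 = w.W2 * fc.col2;
  z2.each_col() += w.b2;
  fc.a2 = cube(oh2, ow2, w.W2.n_rows);
  for (uword f = 0; f < w.W2.n_rows; ++f)
    fc.a2.slice(f) = reshape(z2.row(f).t(), oh2, ow2);
  fc.r2 = fc.a2; fc.r2.transform([](double v){ return v > 0 ? v : 0.0; });
  fc.p2c = maxpool(fc.r2, w.p2, fc.am2);

  fc.flat = vectorise(fc.p2c);
  fc.logits = w.W3 * fc.flat + w.b3;
  vec sh = fc.logits - fc.logits.max();
  vec e = exp(sh);
  fc.probs = e / accu(e);
}

// [[Rcpp::export]]
arma::mat cnn_forward_cpp(const arma::cube& X, const Rcpp::List& wl) {
  Weights w = unpack(wl);
  const int N = X.n_slices;
  mat probs(N, w.W3.n_rows);
  FwdCache fc;
  for (int n = 0; n < N; ++n) {
    cube x(X.n_rows, X.n_cols, 1);
    x.slice(0) = X.slice(n);
    forward_one(x, w, fc);
    probs.row(n) = fc.probs.t();
  }
  return probs;
}

// Weighted softmax cross-entropy loss + gradients over a batch.
// y is 0-based class index; cw the per-class loss weight.
// [[Rcpp::export]]
Rcpp::List cnn_grad_cpp(const arma::cube& X, const arma::ivec& y,
                        const Rcpp::List& wl, const arma::vec& cw) {
  Weights w = unpack(wl);
  const int N = X.n_slices;
  mat gW1(size(w.W1), fill::zeros), gW2(size(w.W2), fill::zeros),
      gW3(size(w.W3), fill::zeros);
  vec gb1(size(w.b1), fill::zeros), gb2(size(w.b2), fill::zeros),
      gb3(size(w.b3), fill::zeros);
  double loss = 0.0, wsum = 0.0;
  mat probs(N, w.W3.n_rows);
  FwdCache fc;
  for (int n = 0; n < N; ++n) wsum += cw((uword)y(n));

  for (int n = 0; n < N; ++n) {
    cube x(X.n_rows, X.n_cols, 1);
    x.slice(0) = X.slice(n);
    forward_one(x, w, fc);
    probs.row(n) = fc.probs.t();
    const uword yi = (uword)y(n);
    const double wi = cw(yi);
    loss += -wi * std::log(std::max(fc.probs(yi), 1e-300));

    vec dlog = fc.probs;
    dlog(yi) -= 1.0;
    dlog *= wi / wsum;

    gW3 += dlog * fc.flat.t();
    gb3 += dlog;
    vec dflat = w.W3.t() * dlog;

    // pool2 backward
    cube dr2(size(fc.r2), fill::zeros);
    {
      const double* dp = dflat.memptr();
      for (uword k = 0; k < fc.p2c.n_elem; ++k)
        dr2(fc.am2(k)) += dp[k];
    }
    // relu2 backward
    for (uword k = 0; k < dr2.n_elem; ++k)
      if (fc.a2(k) <= 0) dr2(k) = 0;
    // conv2 backward
    const int oh2 = fc.a2.n_rows, ow2 = fc.a2.n_cols;
    mat dz2(w.W2.n_rows, oh2 * ow2);
    for (uword f = 0; f < w.W2.n_rows; ++f)
      dz2.row(f) = vectorise(dr2.slice(f)).t();
    gW2 += dz2 * fc.col2.t();
    gb2 += sum(dz2, 1);
    mat dcol2 = w.W2.t() * dz2;
    cube dp1 = col2im(dcol2, fc.p1c.n_rows, fc.p1c.n_cols, fc.p1c.n_slices,
                      w.kh2, w.kw2);
    // pool1 backward
    cube dr1(size(fc.r1), fill::zeros);
    {
      for (uword k = 0; k < fc.p1c.n_elem; ++k)
        dr1(fc.am1(k)) += dp1(k);
    }
    // relu1 backward
    for (uword k = 0; k < dr1.n_elem; ++k)
      if (fc.a1(k) <= 0) dr1(k) = 0;
    // conv1 backward
    const int oh1 = fc.a1.n_rows, ow1 = fc.a1.n_cols;
    mat dz1(w.W1.n_rows, oh1 * ow1);
    for (uword f = 0; f < w.W1.n_rows; ++f)
      dz1.row(f) = vectorise(dr1.slice(f)).t();
    gW1 += dz1 * fc.col1.t();
    gb1 += sum(dz1, 1);
  }
  loss /= wsum;
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("probs") = probs,
    Rcpp::Named("gW1") = gW1, Rcpp::Named("gb1") = gb1,
    Rcpp::Named("gW2") = gW2, Rcpp::Named("gb2") = gb2,
    Rcpp::Named("gW3") = gW3, Rcpp::Named("gb3") = gb3);
}
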