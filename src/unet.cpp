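// Compact CPU U-Net for 3-class semantic segmentation of microscopy patches.
// Encoder-decoder with skip connections; each level is two 3x3 convolutions,
// each followed by per-channel normalization and PReLU; 2x2 max-pool down,
// nearest-neighbour x2 up; softmax head trained with soft Dice loss and Adam.
// Normalization uses the current patch's statistics in both training and
// inference (batch of one), which keeps prediction deterministic.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace arma;

static const double NORM_EPS = 1e-5;
static const double ADAM_EPS = 1e-8;
static const double DICE_EPS = 1e-7;

// ---- 3x3 same-padding im2col ----------------------------------------------

static mat im2col3(const cube& X) {
  const uword H = X.n_rows, W = X.n_cols, C = X.n_slices;
  mat cols(C * 9, H * W, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    const mat& Xc = X.slice(c);
    for (int di = -1; di <= 1; ++di) {
      for (int dj = -1; dj <= 1; ++dj) {
        uword r = c * 9 + (di + 1) * 3 + (dj + 1);
        mat S(H, W, fill::zeros);
        uword i0 = (di < 0) ? 1 : 0, i1 = (di > 0) ? H - 1 : H;
        uword j0 = (dj < 0) ? 1 : 0, j1 = (dj > 0) ? W - 1 : W;
        if (i1 > i0 && j1 > j0) {
          S.submat(i0, j0, i1 - 1, j1 - 1) =
            Xc.submat(i0 + di, j0 + dj, i1 - 1 + di, j1 - 1 + dj);
        }
        cols.row(r) = vectorise(S).t();
      }
    }
  }
  return cols;
}

static cube col2im3(const mat& dcols, uword H, uword W, uword C) {
  cube dX(H, W, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    for (int di = -1; di <= 1; ++di) {
      for (int dj = -1; dj <= 1; ++dj) {
        uword r = c * 9 + (di + 1) * 3 + (dj + 1);
        mat Dr = reshape(dcols.row(r).t(), H, W);
        uword i0 = (di < 0) ? 1 : 0, i1 = (di > 0) ? H - 1 : H;
        uword j0 = (dj < 0) ? 1 : 0, j1 = (dj > 0) ? W - 1 : W;
        if (i1 > i0 && j1 > j0) {
          dX.slice(c).submat(i0 + di, j0 + dj, i1 - 1 + di, j1 - 1 + dj) +=
            Dr.submat(i0, j0, i1 - 1, j1 - 1);
        }
      }
    }
  }
  return dX;
}

static cube rows_to_cube(const mat& Z, uword H, uword W) {
  cube out(H, W, Z.n_rows);
  for (uword c = 0; c < Z.n_rows; ++c) out.slice(c) = reshape(Z.row(c).t(), H, W);
  return out;
}

static mat cube_to_rows(const cube& X) {
  mat Z(X.n_slices, X.n_rows * X.n_cols);
  for (uword c = 0; c < X.n_slices; ++c) Z.row(c) = vectorise(X.slice(c)).t();
  return Z;
}

// ---- parameter holder -------------------------------------------------------

struct Param {
  mat w, g, m, v;
  explicit Param(uword r = 0, uword c = 0) : w(r, c, fill::zeros),
    g(r, c, fill::zeros), m(r, c, fill::zeros), v(r, c, fill::zeros) {}
};

// ---- conv 3x3 + per-channel norm + PReLU -----------------------------------

struct ConvBlock {
  uword cin, cout;
  bool with_norm_act;
  Param W, b, gamma, beta, alpha;
  // caches
  mat cols, xhat, ybn;
  vec istd;
  uword H = 0, Wd = 0;

  ConvBlock(uword cin_, uword cout_, bool norm_act, std::mt19937_64& rng)
      : cin(cin_), cout(cout_), with_norm_act(norm_act),
        W(cout_, cin_ * 9), b(cout_, 1),
        gamma(cout_, 1), beta(cout_, 1), alpha(cout_, 1) {
    std::normal_distribution<double> nd(0.0, std::sqrt(2.0 / (cin_ * 9)));
    for (uword i = 0; i < W.w.n_elem; ++i) W.w(i) = nd(rng);
    gamma.w.fill(1.0);
    alpha.w.fill(0.25);
  }

  cube forward(const cube& X) {
    H = X.n_rows;
    Wd = X.n_cols;
    cols = im2col3(X);
    mat Z = W.w * cols;
    Z.each_col() += b.w.col(0);
    if (!with_norm_act) {
      ybn = Z;
      return rows_to_cube(Z, H, Wd);
    }
    vec mu = mean(Z, 1);
    vec va = mean(square(Z), 1) - square(mu);
    istd = 1.0 / sqrt(va + NORM_EPS);
    xhat = Z;
    xhat.each_col() -= mu;
    xhat.each_col() %= istd;
    ybn = xhat;
    ybn.each_col() %= gamma.w.col(0);
    ybn.each_col() += beta.w.col(0);
    mat out = ybn;
    for (uword c = 0; c < cout; ++c) {
      double a = alpha.w(c, 0);
      out.row(c) = max(ybn.row(c), zeros<rowvec>(ybn.n_cols)) +
                   a * min(ybn.row(c), zeros<rowvec>(ybn.n_cols));
    }
    return rows_to_cube(out, H, Wd);
  }

  cube backward(const cube& dOut) {
    mat dY = cube_to_rows(dOut);
    mat dZ;
    if (with_norm_act) {
      mat dybn(size(dY));
      for (uword c = 0; c < cout; ++c) {
        double a = alpha.w(c, 0);
        rowvec yb = ybn.row(c);
        rowvec dy = dY.row(c);
        // PReLU: out = yb>0 ? yb : a*yb  =>  d a = sum(dy * yb * (yb<=0))
        rowvec neg = conv_to<rowvec>::from(yb <= 0.0);
        alpha.g(c, 0) += accu(dy % yb % neg);
        dybn.row(c) = dy % (1.0 - neg) + a * (dy % neg);
      }
      // norm backward (per channel over all pixels)
      const double N = static_cast<double>(dY.n_cols);
      mat dxhat = dybn;
      dxhat.each_col() %= gamma.w.col(0);
      gamma.g.col(0) += sum(dybn % xhat, 1);
      beta.g.col(0) += sum(dybn, 1);
      vec sum_dxhat = sum(dxhat, 1);
      vec sum_dxhat_xhat = sum(dxhat % xhat, 1);
      dZ = dxhat * N;
      dZ.each_col() -= sum_dxhat;
      mat xs = xhat;
      xs.each_col() %= sum_dxhat_xhat;
      dZ -= xs;
      dZ.each_col() %= istd / N;
    } else {
      dZ = dY;
    }
    W.g += dZ * cols.t();
    b.g.col(0) += sum(dZ, 1);
    mat dcols = W.w.t() * dZ;
    return col2im3(dcols, H, Wd, cin);
  }

  void params(std::vector<Param*>& out) {
    out.push_back(&W);
    out.push_back(&b);
    if (with_norm_act) {
      out.push_back(&gamma);
      out.push_back(&beta);
      out.push_back(&alpha);
    }
  }
};

// ---- 1x1 conv head ----------------------------------------------------------

struct Conv1x1 {
  Param W, b;
  mat xin;
  uword H = 0, Wd = 0, cin;
  Conv1x1(uword cin_, uword cout_, std::mt19937_64& rng)
      : W(cout_, cin_), b(cout_, 1), cin(cin_) {
    std::normal_distribution<double> nd(0.0, std::sqrt(2.0 / cin_));
    for (uword i = 0; i < W.w.n_elem; ++i) W.w(i) = nd(rng);
  }
  cube forward(const cube& X) {
    H = X.n_rows;
    Wd = X.n_cols;
    xin = cube_to_rows(X);
    mat Z = W.w * xin;
    Z.each_col() += b.w.col(0);
    return rows_to_cube(Z, H, Wd);
  }
  cube backward(const cube& dOut) {
    mat dZ = cube_to_rows(dOut);
    W.g += dZ * xin.t();
    b.g.col(0) += sum(dZ, 1);
    return rows_to_cube(W.w.t() * dZ, H, Wd);
  }
  void params(std::vector<Param*>& out) {
    out.push_back(&W);
    out.push_back(&b);
  }
};

// ---- pooling / upsampling ---------------------------------------------------

static cube maxpool2(const cube& X, ucube& argmax) {
  uword H = X.n_rows / 2, W = X.n_cols / 2, C = X.n_slices;
  cube out(H, W, C);
  argmax.set_size(H, W, C);
  for (uword c = 0; c < C; ++c) {
    for (uword j = 0; j < W; ++j) {
      for (uword i = 0; i < H; ++i) {
        double best = -datum::inf;
        uword bi = 0;
        for (uword dj = 0; dj < 2; ++dj) {
          for (uword di = 0; di < 2; ++di) {
            double v = X(2 * i + di, 2 * j + dj, c);
            if (v > best) {
              best = v;
              bi = (2 * j + dj) * X.n_rows + (2 * i + di);
            }
          }
        }
        out(i, j, c) = best;
        argmax(i, j, c) = bi;
      }
    }
  }
  return out;
}

static cube maxpool2_back(const cube& dOut, const ucube& argmax, uword H, uword W) {
  cube dX(H, W, dOut.n_slices, fill::zeros);
  for (uword c = 0; c < dOut.n_slices; ++c) {
    for (uword j = 0; j < dOut.n_cols; ++j) {
      for (uword i = 0; i < dOut.n_rows; ++i) {
        dX.slice(c)(argmax(i, j, c)) += dOut(i, j, c);
      }
    }
  }
  return dX;
}

static cube upsample2(const cube& X) {
  cube out(X.n_rows * 2, X.n_cols * 2, X.n_slices);
  for (uword c = 0; c < X.n_slices; ++c) {
    for (uword j = 0; j < X.n_cols; ++j) {
      for (uword i = 0; i < X.n_rows; ++i) {
        double v = X(i, j, c);
        out(2 * i, 2 * j, c) = v;
        out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v;
        out(2 * i + 1, 2 * j + 1, c) = v;
      }
    }
  }
  return out;
}

static cube upsample2_back(const cube& dOut) {
  cube dX(dOut.n_rows / 2, dOut.n_cols / 2, dOut.n_slices);
  for (uword c = 0; c < dOut.n_slices; ++c) {
    for (uword j = 0; j < dX.n_cols; ++j) {
      for (uword i = 0; i < dX.n_rows; ++i) {
        dX(i, j, c) = dOut(2 * i, 2 * j, c) + dOut(2 * i + 1, 2 * j, c) +
                      dOut(2 * i, 2 * j + 1, c) + dOut(2 * i + 1, 2 * j + 1, c);
      }
    }
  }
  return dX;
}

// ---- the network ------------------------------------------------------------

struct UNet {
  std::vector<uword> depths;
  uword n_classes = 3;
  std::vector<ConvBlock> enc1, enc2;   // two conv blocks per encoder level
  std::vector<ConvBlock> upc;          // conv after upsampling
  std::vector<ConvBlock> dec1, dec2;   // two conv blocks per decoder level
  Conv1x1* head = nullptr;
  long step_count = 0;

  // caches
  std::vector<cube> skips;
  std::vector<ucube> pool_arg;
  std::vector<uword> pool_H, pool_W;
  cube probs, target;

  UNet(const std::vector<uword>& depths_, uword in_ch, uint64_t seed)
      : depths(depths_) {
    std::mt19937_64 rng(seed);
    uword L = depths.size();
    uword prev = in_ch;
    for (uword l = 0; l < L; ++l) {
      enc1.emplace_back(prev, depths[l], true, rng);
      enc2.emplace_back(depths[l], depths[l], true, rng);
      prev = depths[l];
    }
    for (uword l = 0; l + 1 < L; ++l) {
      uword lo = L - 2 - l;  // decoder built from deep to shallow
      upc.emplace_back(depths[lo + 1], depths[lo], true, rng);
      dec1.emplace_back(2 * depths[lo], depths[lo], true, rng);
      dec2.emplace_back(depths[lo], depths[lo], true, rng);
    }
    head = new Conv1x1(depths[0], n_classes, rng);
  }
  ~UNet() { delete head; }

  std::vector<Param*> all_params() {
    std::vector<Param*> out;
    for (auto& b : enc1) b.params(out);
    for (auto& b : enc2) b.params(out);
    for (auto& b : upc) b.params(out);
    for (auto& b : dec1) b.params(out);
    for (auto& b : dec2) b.params(out);
    head->params(out);
    return out;
  }

  cube forward(const cube& x) {
    uword L = depths.size();
    skips.assign(L - 1, cube());
    pool_arg.assign(L - 1, ucube());
    pool_H.assign(L - 1, 0);
    pool_W.assign(L - 1, 0);
    cube a = x;
    for (uword l = 0; l < L; ++l) {
      a = enc1[l].forward(a);
      a = enc2[l].forward(a);
      if (l + 1 < L) {
        skips[l] = a;
        pool_H[l] = a.n_rows;
        pool_W[l] = a.n_cols;
        a = maxpool2(a, pool_arg[l]);
      }
    }
    for (uword d = 0; d < L - 1; ++d) {
      uword lo = L - 2 - d;
      a = upsample2(a);
      a = upc[d].forward(a);
      cube cat(a.n_rows, a.n_cols, skips[lo].n_slices + a.n_slices);
      for (uword c = 0; c < skips[lo].n_slices; ++c) cat.slice(c) = skips[lo].slice(c);
      for (uword c = 0; c < a.n_slices; ++c) cat.slice(skips[lo].n_slices + c) = a.slice(c);
      a = dec1[d].forward(cat);
      a = dec2[d].forward(a);
    }
    return head->forward(a);
  }

  cube softmax(const cube& logits) {
    cube p = logits;
    for (uword j = 0; j < p.n_cols; ++j) {
      for (uword i = 0; i < p.n_rows; ++i) {
        double mx = -datum::inf;
        for (uword c = 0; c < p.n_slices; ++c) mx = std::max(mx, p(i, j, c));
        double s = 0;
        for (uword c = 0; c < p.n_slices; ++c) {
          double e = std::exp(p(i, j, c) - mx);
          p(i, j, c) = e;
          s += e;
        }
        for (uword c = 0; c < p.n_slices; ++c) p(i, j, c) /= s;
      }
    }
    return p;
  }

  // Soft Dice loss averaged over the classes present in the target (classes
  // with no target pixels are skipped: their 0/0 Dice term has a vanishing
  // gradient, and softmax coupling already drives them to zero as the
  // present classes are fit). Returns the loss and fills dLogits.
  double dice_loss(const cube& logits, const cube& T, cube& dLogits) {
    cube P = softmax(logits);
    probs = P;
    uword C = P.n_slices;
    vec sp(C), st(C), spt(C), dice(C);
    double n_present = 0;
    for (uword c = 0; c < C; ++c) {
      sp(c) = accu(P.slice(c));
      st(c) = accu(T.slice(c));
      spt(c) = accu(P.slice(c) % T.slice(c));
      dice(c) = (2 * spt(c) + DICE_EPS) / (sp(c) + st(c) + DICE_EPS);
      if (st(c) > 0) n_present += 1;
    }
    if (n_present == 0) n_present = C;
    double loss = 0;
    for (uword c = 0; c < C; ++c) if (st(c) > 0) loss += dice(c);
    loss = 1.0 - loss / n_present;
    cube dP(size(P), fill::zeros);
    for (uword c = 0; c < C; ++c) {
      if (st(c) == 0) continue;
      double denom = sp(c) + st(c) + DICE_EPS;
      dP.slice(c) = -(2.0 * T.slice(c) * denom - (2 * spt(c) + DICE_EPS)) /
                    (denom * denom) / n_present;
    }
    // softmax backward
    dLogits.set_size(size(P));
    mat inner(P.n_rows, P.n_cols, fill::zeros);
    for (uword c = 0; c < C; ++c) inner += dP.slice(c) % P.slice(c);
    for (uword c = 0; c < C; ++c) dLogits.slice(c) = P.slice(c) % (dP.slice(c) - inner);
    return loss;
  }

  void backward(const cube& dLogits) {
    uword L = depths.size();
    cube d = head->backward(dLogits);
    std::vector<cube> dskip(L - 1);
    for (long d_i = static_cast<long>(L) - 2; d_i >= 0; --d_i) {
      uword dd = static_cast<uword>(d_i);
      uword lo = L - 2 - dd;
      d = dec2[dd].backward(d);
      d = dec1[dd].backward(d);
      uword cs = depths[lo];
      cube dcat_skip(d.n_rows, d.n_cols, cs);
      cube dcat_up(d.n_rows, d.n_cols, d.n_slices - cs);
      for (uword c = 0; c < cs; ++c) dcat_skip.slice(c) = d.slice(c);
      for (uword c = cs; c < d.n_slices; ++c) dcat_up.slice(c - cs) = d.slice(c);
      dskip[lo] = dcat_skip;
      d = upc[dd].backward(dcat_up);
      d = upsample2_back(d);
    }
    for (long l_i = static_cast<long>(L) - 1; l_i >= 0; --l_i) {
      uword l = static_cast<uword>(l_i);
      if (l + 1 < L) {
        d = maxpool2_back(d, pool_arg[l], pool_H[l], pool_W[l]);
        d += dskip[l];
      }
      d = enc2[l].backward(d);
      d = enc1[l].backward(d);
    }
  }

  void adam_step(double lr, double b1 = 0.9, double b2 = 0.999) {
    ++step_count;
    double c1 = 1.0 - std::pow(b1, static_cast<double>(step_count));
    double c2 = 1.0 - std::pow(b2, static_cast<double>(step_count));
    for (Param* p : all_params()) {
      p->m = b1 * p->m + (1 - b1) * p->g;
      p->v = b2 * p->v + (1 - b2) * square(p->g);
      p->w -= lr * (p->m / c1) / (sqrt(p->v / c2) + ADAM_EPS);
      p->g.zeros();
    }
  }

  void zero_grads() {
    for (Param* p : all_params()) p->g.zeros();
  }
};

// ---- R interface ------------------------------------------------------------

static cube mat_to_cube(const Rcpp::NumericMatrix& img) {
  cube x(img.nrow(), img.ncol(), 1);
  std::copy(img.begin(), img.end(), x.slice(0).begin());
  return x;
}

static cube onehot(const Rcpp::IntegerMatrix& labels, uword C) {
  cube t(labels.nrow(), labels.ncol(), C, fill::zeros);
  for (int j = 0; j < labels.ncol(); ++j) {
    for (int i = 0; i < labels.nrow(); ++i) {
      t(i, j, labels(i, j)) = 1.0;
    }
  }
  return t;
}

// [[Rcpp::export(name = ".unet_create")]]
SEXP unet_create(Rcpp::IntegerVector depths, int seed) {
  std::vector<uword> d(depths.begin(), depths.end());
  Rcpp::XPtr<UNet> ptr(new UNet(d, 1, static_cast<uint64_t>(seed)), true);
  return ptr;
}

// [[Rcpp::export(name = ".unet_train_step")]]
double unet_train_step(SEXP net, Rcpp::NumericMatrix img,
                       Rcpp::IntegerMatrix labels, double lr) {
  Rcpp::XPtr<UNet> p(net);
  cube x = mat_to_cube(img);
  cube t = onehot(labels, p->n_classes);
  cube logits = p->forward(x);
  cube dlog;
  double loss = p->dice_loss(logits, t, dlog);
  p->backward(dlog);
  p->adam_step(lr);
  return loss;
}

// [[Rcpp::export(name = ".unet_loss")]]
double unet_loss(SEXP net, Rcpp::NumericMatrix img, Rcpp::IntegerMatrix labels) {
  Rcpp::XPtr<UNet> p(net);
  cube x = mat_to_cube(img);
  cube t = onehot(labels, p->n_classes);
  cube logits = p->forward(x);
  cube dlog;
  double loss = p->dice_loss(logits, t, dlog);
  p->zero_grads();
  return loss;
}

// Analytic parameter gradients of the Dice loss at the current weights
// (forward + backward, no optimizer step); used by gradient-check tests.
// [[Rcpp::export(name = ".unet_grads")]]
Rcpp::List unet_grads(SEXP net, Rcpp::NumericMatrix img, Rcpp::IntegerMatrix labels) {
  Rcpp::XPtr<UNet> p(net);
  p->zero_grads();
  cube x = mat_to_cube(img);
  cube t = onehot(labels, p->n_classes);
  cube logits = p->forward(x);
  cube dlog;
  p->dice_loss(logits, t, dlog);
  p->backward(dlog);
  std::vector<Param*> ps = p->all_params();
  Rcpp::List out(ps.size());
  for (size_t i = 0; i < ps.size(); ++i) {
    Rcpp::NumericMatrix m(ps[i]->g.n_rows, ps[i]->g.n_cols);
    std::copy(ps[i]->g.begin(), ps[i]->g.end(), m.begin());
    out[i] = m;
  }
  p->zero_grads();
  return out;
}

// [[Rcpp::export(name = ".unet_predict")]]
Rcpp::NumericVector unet_predict(SEXP net, Rcpp::NumericMatrix img) {
  Rcpp::XPtr<UNet> p(net);
  cube x = mat_to_cube(img);
  cube logits = p->forward(x);
  cube pr = p->softmax(logits);
  Rcpp::NumericVector out(pr.n_elem);
  std::copy(pr.begin(), pr.end(), out.begin());
  out.attr("dim") = Rcpp::IntegerVector::create(pr.n_rows, pr.n_cols, pr.n_slices);
  return out;
}

// [[Rcpp::export(name = ".unet_get_params")]]
Rcpp::List unet_get_params(SEXP net) {
  Rcpp::XPtr<UNet> p(net);
  std::vector<Param*> ps = p->all_params();
  Rcpp::List out(ps.size());
  for (size_t i = 0; i < ps.size(); ++i) {
    Rcpp::NumericMatrix m(ps[i]->w.n_rows, ps[i]->w.n_cols);
    std::copy(ps[i]->w.begin(), ps[i]->w.end(), m.begin());
    out[i] = m;
  }
  return out;
}

// [[Rcpp::export(name = ".unet_set_params")]]
void unet_set_params(SEXP net, Rcpp::List weights) {
  Rcpp::XPtr<UNet> p(net);
  std::vector<Param*> ps = p->all_params();
  if (static_cast<size_t>(weights.size()) != ps.size()) {
    Rcpp::stop("weight list length does not match this architecture");
  }
  for (size_t i = 0; i < ps.size(); ++i) {
    Rcpp::NumericMatrix m = weights[i];
    if (static_cast<uword>(m.nrow()) != ps[i]->w.n_rows ||
        static_cast<uword>(m.ncol()) != ps[i]->w.n_cols) {
      Rcpp::stop("weight %d has wrong shape", static_cast<int>(i) + 1);
    }
    std::copy(m.begin(), m.end(), ps[i]->w.begin());
  }
}

// [[Rcpp::export(name = ".unet_n_params")]]
double unet_n_params(SEXP net) {
  Rcpp::XPtr<UNet> p(net);
  double n = 0;
  for (Param* q : p->all_params()) n += q->w.n_elem;
  return n;
}
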