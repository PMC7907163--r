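// Numerical core: plug-in mutual information on binned series, and the
// SGD training loop of the dual-head MLP (noise + dropout + batch norm +
// ReLU stack + two sigmoid heads, L1 on the first dense layer).
#include <RcppArmadillo.h>
#include <cstdint>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Self-contained deterministic RNG (mt19937_64 + Box-Muller) so training is
// reproducible bit-for-bit for a given seed on any platform.
struct Rng {
  std::mt19937_64 eng;
  bool has_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) : eng(seed) {}
  double unif() {  // (0, 1)
    uint64_t x = eng();
    return ((x >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u = unif(), v = unif();
    double r = std::sqrt(-2.0 * std::log(u));
    double a = 6.283185307179586476925286766559 * v;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
  int integer(int n) {  // 0 .. n-1
    return (int)(unif() * n) % n;
  }
};

// [[Rcpp::export]]
arma::mat xmi_matrix_cpp(const arma::imat& binned, int bins, int lag = 0) {
  const int t_full = binned.n_rows, n = binned.n_cols;
  const int t = t_full - std::abs(lag);
  if (t < bins) stop("too few time points for the requested lag");
  arma::mat out(n, n, arma::fill::zeros);
  arma::mat joint(bins, bins);
  const double log2e = 1.4426950408889634;
  for (int a = 0; a < n; ++a) {
    for (int b = a; b < n; ++b) {
      joint.zeros();
      for (int s = 0; s < t; ++s) {
        int ia = binned(lag >= 0 ? s : s - lag, a) - 1;
        int ib = binned(lag >= 0 ? s + lag : s, b) - 1;
        joint(ia, ib) += 1.0;
      }
      joint /= (double)t;
      arma::vec pa = arma::sum(joint, 1);
      arma::rowvec pb = arma::sum(joint, 0);
      double mi = 0.0;
      for (int ia = 0; ia < bins; ++ia)
        for (int ib = 0; ib < bins; ++ib) {
          double p = joint(ia, ib);
          if (p > 0.0) mi += p * std::log(p / (pa(ia) * pb(ib))) * log2e;
        }
      out(a, b) = mi;
      out(b, a) = mi;
    }
  }
  return out;
}

static inline arma::mat sigmoid(const arma::mat& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

static double bce(const arma::vec& p, const arma::vec& y) {
  arma::vec q = arma::clamp(p, 1e-7, 1.0 - 1e-7);
  return arma::mean(-y % arma::log(q) - (1.0 - y) % arma::log(1.0 - q));
}

struct Layer {
  arma::mat W;
  arma::rowvec b, gamma, beta, rmean, rvar;
  // velocities
  arma::mat vW;
  arma::rowvec vb, vgamma, vbeta;
  // caches
  arma::mat A, Ahat, Z, H;
  arma::rowvec mu, varr;
};

struct Head {
  arma::vec w; double b;
  arma::vec vw; double vb;
};

static void bn_forward_train(Layer& L, const arma::mat& X, double eps,
                             double bn_momentum) {
  L.A = X * L.W;
  L.A.each_row() += L.b;
  L.mu = arma::mean(L.A, 0);
  arma::mat C = L.A;
  C.each_row() -= L.mu;
  L.varr = arma::mean(arma::square(C), 0);
  L.Ahat = C;
  L.Ahat.each_row() /= arma::sqrt(L.varr + eps);
  L.Z = L.Ahat;
  L.Z.each_row() %= L.gamma;
  L.Z.each_row() += L.beta;
  L.H = arma::clamp(L.Z, 0.0, arma::datum::inf);
  L.rmean = bn_momentum * L.rmean + (1.0 - bn_momentum) * L.mu;
  L.rvar = bn_momentum * L.rvar + (1.0 - bn_momentum) * L.varr;
}

static arma::mat bn_forward_infer(const Layer& L, const arma::mat& X,
                                  double eps) {
  arma::mat A = X * L.W;
  A.each_row() += L.b;
  A.each_row() -= L.rmean;
  A.each_row() /= arma::sqrt(L.rvar + eps);
  A.each_row() %= L.gamma;
  A.each_row() += L.beta;
  return arma::clamp(A, 0.0, arma::datum::inf);
}

// Backward through ReLU + BN + dense. Returns gradient wrt the layer input
// unless `need_dx` is false. Applies momentum update in place.
static arma::mat layer_backward_update(Layer& L, const arma::mat& Xin,
                                       const arma::mat& dH, double eps,
                                       double lr, double mom, double l1,
                                       bool need_dx) {
  const double n = (double)dH.n_rows;
  arma::mat dZ = dH % (L.Z > 0);
  arma::rowvec dgamma = arma::sum(dZ % L.Ahat, 0);
  arma::rowvec dbeta = arma::sum(dZ, 0);
  arma::mat dAhat = dZ;
  dAhat.each_row() %= L.gamma;
  arma::rowvec istd = 1.0 / arma::sqrt(L.varr + eps);
  arma::rowvec s1 = arma::sum(dAhat, 0);
  arma::rowvec s2 = arma::sum(dAhat % L.Ahat, 0);
  arma::mat dA = n * dAhat;
  dA.each_row() -= s1;
  arma::mat tmp = L.Ahat;
  tmp.each_row() %= s2;
  dA -= tmp;
  dA.each_row() %= istd / n;
  arma::mat dW = Xin.t() * dA;
  if (l1 > 0.0) dW += l1 * arma::sign(L.W);
  arma::rowvec db = arma::sum(dA, 0);
  arma::mat dX;
  if (need_dx) dX = dA * L.W.t();
  L.vW = mom * L.vW - lr * dW;            L.W += L.vW;
  L.vb = mom * L.vb - lr * db;            L.b += L.vb;
  L.vgamma = mom * L.vgamma - lr * dgamma; L.gamma += L.vgamma;
  L.vbeta = mom * L.vbeta - lr * dbeta;   L.beta += L.vbeta;
  return dX;
}

static List layer_state(const Layer& L) {
  return List::create(_["W"] = L.W, _["b"] = L.b, _["gamma"] = L.gamma,
                      _["beta"] = L.beta, _["rmean"] = L.rmean,
                      _["rvar"] = L.rvar);
}

// [[Rcpp::export]]
List mlp_train_cpp(const arma::mat& Xtr, const arma::mat& Ytr,
                   const arma::mat& Xval, const arma::mat& Yval,
                   List init, List hyper, int seed) {
  const double lr0 = as<double>(hyper["learning_rate"]);
  const double decay = as<double>(hyper["decay"]);
  const double mom = as<double>(hyper["momentum"]);
  const int batch = as<int>(hyper["batch_size"]);
  const int max_epochs = as<int>(hyper["max_epochs"]);
  const int patience = as<int>(hyper["patience"]);
  const double noise_sd = as<double>(hyper["noise_sd"]);
  const double dropout = as<double>(hyper["dropout_rate"]);
  const double l1 = as<double>(hyper["l1_coefficient"]);
  const double bn_momentum = as<double>(hyper["bn_momentum"]);
  const double eps = as<double>(hyper["bn_eps"]);

  const int n = Xtr.n_rows;
  Layer L[3];
  List lw = init["layers"];
  for (int l = 0; l < 3; ++l) {
    List s = lw[l];
    L[l].W = as<arma::mat>(s["W"]);
    L[l].b = as<arma::rowvec>(s["b"]);
    L[l].gamma = as<arma::rowvec>(s["gamma"]);
    L[l].beta = as<arma::rowvec>(s["beta"]);
    L[l].rmean = as<arma::rowvec>(s["rmean"]);
    L[l].rvar = as<arma::rowvec>(s["rvar"]);
    L[l].vW = arma::zeros(L[l].W.n_rows, L[l].W.n_cols);
    L[l].vb = arma::zeros<arma::rowvec>(L[l].b.n_elem);
    L[l].vgamma = arma::zeros<arma::rowvec>(L[l].gamma.n_elem);
    L[l].vbeta = arma::zeros<arma::rowvec>(L[l].beta.n_elem);
  }
  Head hg, hl;
  List hgs = init["head_group"], hls = init["head_lex"];
  hg.w = as<arma::vec>(hgs["w"]); hg.b = as<double>(hgs["b"]);
  hl.w = as<arma::vec>(hls["w"]); hl.b = as<double>(hls["b"]);
  hg.vw = arma::zeros(hg.w.n_elem); hg.vb = 0.0;
  hl.vw = arma::zeros(hl.w.n_elem); hl.vb = 0.0;

  Rng rng((uint64_t)seed * 2654435761ULL + 1ULL);

  auto infer = [&](const arma::mat& X) {
    arma::mat H = X;
    for (int l = 0; l < 3; ++l) H = bn_forward_infer(L[l], H, eps);
    arma::vec pg = sigmoid(H * hg.w + hg.b);
    arma::vec pl = sigmoid(H * hl.w + hl.b);
    return std::make_pair(pg, pl);
  };

  double best_val = arma::datum::inf;
  int best_epoch = -1, wait = 0, epochs_run = 0;
  // snapshot of the best state for restore-best early stopping
  List best_state = R_NilValue;
  auto snapshot = [&]() {
    return List::create(
        _["layers"] = List::create(layer_state(L[0]), layer_state(L[1]),
                                   layer_state(L[2])),
        _["head_group"] = List::create(_["w"] = hg.w, _["b"] = hg.b),
        _["head_lex"] = List::create(_["w"] = hl.w, _["b"] = hl.b));
  };

  std::vector<double> h_train, h_vg, h_vl, h_vg_acc, h_vl_acc;
  auto acc = [](const arma::vec& p, const arma::vec& y) {
    return arma::mean(arma::conv_to<arma::vec>::from((p >= 0.5) ==
                                                     (y >= 0.5)));
  };
  arma::uvec order = arma::regspace<arma::uvec>(0, n - 1);

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    double lr = lr0 / (1.0 + decay * epoch);
    // Fisher-Yates shuffle with our RNG
    for (int i = n - 1; i > 0; --i) {
      int j = rng.integer(i + 1);
      std::swap(order[i], order[j]);
    }
    double epoch_loss = 0.0;
    int n_batches = 0;
    for (int start = 0; start < n; start += batch) {
      int stop_ = std::min(start + batch, n);
      arma::uvec idx = order.subvec(start, stop_ - 1);
      arma::mat X = Xtr.rows(idx);
      arma::vec yg = Ytr.col(0); yg = yg.elem(idx);
      arma::vec yl = Ytr.col(1); yl = yl.elem(idx);
      const int b = X.n_rows;
      // input perturbation: Gaussian noise then inverted dropout
      if (noise_sd > 0.0)
        for (arma::uword k = 0; k < X.n_elem; ++k) X[k] += noise_sd * rng.norm();
      if (dropout > 0.0) {
        const double keep = 1.0 - dropout;
        for (arma::uword k = 0; k < X.n_elem; ++k)
          X[k] = (rng.unif() < keep) ? X[k] / keep : 0.0;
      }
      arma::mat H = X;
      for (int l = 0; l < 3; ++l) {
        bn_forward_train(L[l], H, eps, bn_momentum);
        H = L[l].H;
      }
      arma::vec pg = sigmoid(H * hg.w + hg.b);
      arma::vec pl = sigmoid(H * hl.w + hl.b);
      epoch_loss += bce(pg, yg) + bce(pl, yl) + l1 * arma::accu(arma::abs(L[0].W));
      ++n_batches;
      // heads
      arma::vec dzg = (pg - yg) / (double)b;
      arma::vec dzl = (pl - yl) / (double)b;
      arma::vec dwg = H.t() * dzg; double dbg = arma::accu(dzg);
      arma::vec dwl = H.t() * dzl; double dbl = arma::accu(dzl);
      arma::mat dH = dzg * hg.w.t() + dzl * hl.w.t();
      hg.vw = mom * hg.vw - lr * dwg; hg.w += hg.vw;
      hg.vb = mom * hg.vb - lr * dbg; hg.b += hg.vb;
      hl.vw = mom * hl.vw - lr * dwl; hl.w += hl.vw;
      hl.vb = mom * hl.vb - lr * dbl; hl.b += hl.vb;
      // hidden stack, last to first
      dH = layer_backward_update(L[2], L[1].H, dH, eps, lr, mom, 0.0, true);
      dH = layer_backward_update(L[1], L[0].H, dH, eps, lr, mom, 0.0, true);
      layer_backward_update(L[0], X, dH, eps, lr, mom, l1, false);
    }
    if (!std::isfinite(epoch_loss))
      stop("non-finite training loss at epoch %d", epoch + 1);
    epochs_run = epoch + 1;
    auto pv = infer(Xval);
    double vg = bce(pv.first, Yval.col(0));
    double vl = bce(pv.second, Yval.col(1));
    h_train.push_back(epoch_loss / n_batches);
    h_vg.push_back(vg);
    h_vl.push_back(vl);
    h_vg_acc.push_back(acc(pv.first, Yval.col(0)));
    h_vl_acc.push_back(acc(pv.second, Yval.col(1)));
    if (vl < best_val - 1e-12) {
      best_val = vl;
      best_epoch = epoch;
      best_state = snapshot();
      wait = 0;
    } else if (++wait > patience) break;
  }
  if (best_epoch >= 0) {  // restore best weights (running stats included)
    List bs = best_state;
    List lw2 = bs["layers"];
    for (int l = 0; l < 3; ++l) {
      List s = lw2[l];
      L[l].W = as<arma::mat>(s["W"]); L[l].b = as<arma::rowvec>(s["b"]);
      L[l].gamma = as<arma::rowvec>(s["gamma"]);
      L[l].beta = as<arma::rowvec>(s["beta"]);
      L[l].rmean = as<arma::rowvec>(s["rmean"]);
      L[l].rvar = as<arma::rowvec>(s["rvar"]);
    }
    List g2 = bs["head_group"], l2 = bs["head_lex"];
    hg.w = as<arma::vec>(g2["w"]); hg.b = as<double>(g2["b"]);
    hl.w = as<arma::vec>(l2["w"]); hl.b = as<double>(l2["b"]);
  }
  auto pv = infer(Xval);
  return List::create(
      _["layers"] = List::create(layer_state(L[0]), layer_state(L[1]),
                                 layer_state(L[2])),
      _["head_group"] = List::create(_["w"] = hg.w, _["b"] = hg.b),
      _["head_lex"] = List::create(_["w"] = hl.w, _["b"] = hl.b),
      _["epochs_trained"] = epochs_run,
      _["best_epoch"] = best_epoch + 1,
      _["best_val_lex_loss"] = best_val,
      _["history"] = DataFrame::create(_["train_loss"] = h_train,
                                       _["val_group_loss"] = h_vg,
                                       _["val_lex_loss"] = h_vl,
                                       _["val_group_acc"] = h_vg_acc,
                                       _["val_lex_acc"] = h_vl_acc),
      _["val_prob_group"] = pv.first,
      _["val_prob_lex"] = pv.second);
}
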