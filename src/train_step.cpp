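// Fused training step for the convolutional Q-network.
//
// Mirrors the R reference implementation (qnet_forward / qnet_backward /
// qnet_adam_step / soft_update) exactly: valid 3x3 convolutions with
// rectifier nonlinearities shrink the window to 1x1, the channel vector is
// concatenated with the normalised age, and one fully connected layer maps
// to the action values. Weight rows are channel-major: row c*9 + k holds the
// kernel entry for input channel c at patch offset k (k column-major over
// the 3x3 patch). The double Q-learning target, Huber loss, backward pass,
// Adam update and soft target update all run in one call so no activation
// caches cross the R/C++ boundary.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Params {
  std::vector<arma::mat> W; // per conv layer
  std::vector<arma::vec> b;
  arma::mat fcW;
  arma::vec fcb;
};

Params read_params(const List& net) {
  Params p;
  List layers = net["layers"];
  for (int l = 0; l < layers.size(); ++l) {
    List ly = layers[l];
    p.W.push_back(as<arma::mat>(ly["W"]));
    p.b.push_back(as<arma::vec>(ly["b"]));
  }
  List fc = net["fc"];
  p.fcW = as<arma::mat>(fc["W"]);
  p.fcb = as<arma::vec>(fc["b"]);
  return p;
}

void write_params(List& net, const Params& p) {
  List layers = net["layers"];
  for (size_t l = 0; l < p.W.size(); ++l) {
    List ly = layers[l];
    ly["W"] = wrap(p.W[l]);
    ly["b"] = wrap(p.b[l]);
    layers[l] = ly;
  }
  net["layers"] = layers;
  List fc = net["fc"];
  fc["W"] = wrap(p.fcW);
  fc["b"] = wrap(p.fcb);
  net["fc"] = fc;
}

// im2col gather for a valid 3x3 convolution on an H x H input: A is
// (H*H*B) x cin sample-major; returns (Ho*Ho*B) x (9*cin) with Ho = H - 2.
// Within a fixed offset and output column the source cells are contiguous,
// so the copy runs in memcpy strips of length Ho.
arma::mat gather(const arma::mat& A, int H, int B) {
  const int Ho = H - 2, S = H * H, P = Ho * Ho;
  const int cin = A.n_cols;
  arma::mat Pm(P * B, 9 * cin);
  for (int c = 0; c < cin; ++c) {
    const double* src = A.colptr(c);
    for (int k = 0; k < 9; ++k) {
      const int di = k % 3, dj = k / 3;
      double* dst = Pm.colptr(c * 9 + k);
      for (int b = 0; b < B; ++b) {
        const double* s0 = src + b * S + di;
        double* d0 = dst + b * P;
        for (int oj = 0; oj < Ho; ++oj) {
          std::memcpy(d0 + oj * Ho, s0 + (oj + dj) * H,
                      Ho * sizeof(double));
        }
      }
    }
  }
  return Pm;
}

// Scatter-add of dPm back onto the previous activation gradient.
arma::mat scatter(const arma::mat& dPm, int H, int B, int cin) {
  const int Ho = H - 2, S = H * H, P = Ho * Ho;
  arma::mat dA(S * B, cin, arma::fill::zeros);
  for (int c = 0; c < cin; ++c) {
    double* dst = dA.colptr(c);
    for (int k = 0; k < 9; ++k) {
      const int di = k % 3, dj = k / 3;
      const double* src = dPm.colptr(c * 9 + k);
      for (int b = 0; b < B; ++b) {
        double* d0 = dst + b * S + di;
        const double* s0 = src + b * P;
        for (int oj = 0; oj < Ho; ++oj) {
          double* d = d0 + (oj + dj) * H;
          const double* s = s0 + oj * Ho;
          for (int i = 0; i < Ho; ++i) d[i] += s[i];
        }
      }
    }
  }
  return dA;
}

// Forward pass; optionally keeps patch matrices and masks for backward.
arma::mat forward(const Params& par, const std::vector<int>& H,
                  const arma::mat& obs, const arma::vec& age,
                  std::vector<arma::mat>* Pms, std::vector<arma::umat>* masks) {
  const int B = obs.n_rows;
  arma::mat A(obs.n_cols * B, 1);
  for (int b = 0; b < B; ++b) {
    for (arma::uword p = 0; p < obs.n_cols; ++p) {
      A(b * obs.n_cols + p, 0) = obs(b, p);
    }
  }
  for (size_t l = 0; l < par.W.size(); ++l) {
    arma::mat Pm = gather(A, H[l], B);
    arma::mat Z = Pm * par.W[l];
    Z.each_row() += par.b[l].t();
    if (Pms) {
      Pms->push_back(std::move(Pm));
      masks->push_back(Z > 0);
    }
    A = arma::clamp(Z, 0.0, arma::datum::inf);
  }
  // final spatial extent is 1: A is B x C
  arma::mat F = arma::join_rows(A, age);
  arma::mat Q = F * par.fcW;
  Q.each_row() += par.fcb.t();
  if (Pms) Pms->push_back(std::move(F)); // stash head features last
  return Q;
}

template <typename T>
void adam_one(T& p, const T& g, T& m, T& v, double lr, double b1, double b2,
              double eps, double bc1, double bc2) {
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  p -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
}

} // namespace

// One fused training epoch: for each batch in turn, compute the double-Q
// target, Huber loss, backprop, Adam update and soft target update. All
// parameter and optimiser state stays native across the inner steps and is
// written back to R once; fully deterministic given the batches.
// [[Rcpp::export(name = ".cpp_train_epoch")]]
List cpp_train_epoch(List online_in, List target_in, List batches, List geom,
                     double gamma, double lr, double beta2, double tau) {
  // deep copies: preserve R's value semantics (the caller's networks, which
  // may alias each other right after initialisation, must not be mutated)
  List online = clone(online_in);
  List target = clone(target_in);
  Params on = read_params(online);
  Params tg = read_params(target);

  IntegerVector Hvec = geom["H"];
  std::vector<int> H(Hvec.begin(), Hvec.end());
  const int L = on.W.size();

  // native optimiser state, written back after the last step
  List opt = online["opt"];
  int t = as<int>(opt["t"]);
  const double b1 = 0.9, eps = 1e-8;
  List mL = opt["m"], vL = opt["v"];
  List m_layers = mL["layers"], v_layers = vL["layers"];
  Params m, v;
  for (int l = 0; l < L; ++l) {
    List ml = m_layers[l], vl = v_layers[l];
    m.W.push_back(as<arma::mat>(ml["W"]));
    m.b.push_back(as<arma::vec>(ml["b"]));
    v.W.push_back(as<arma::mat>(vl["W"]));
    v.b.push_back(as<arma::vec>(vl["b"]));
  }
  List mfc = mL["fc"], vfc = vL["fc"];
  m.fcW = as<arma::mat>(mfc["W"]); m.fcb = as<arma::vec>(mfc["b"]);
  v.fcW = as<arma::mat>(vfc["W"]); v.fcb = as<arma::vec>(vfc["b"]);

  NumericVector losses(batches.size());
  for (int step = 0; step < batches.size(); ++step) {
  List batch = batches[step];
  arma::mat obs = as<arma::mat>(batch["obs"]);
  arma::mat nxt = as<arma::mat>(batch["next_obs"]);
  arma::vec age = as<arma::vec>(batch["age"]);
  arma::vec nage = as<arma::vec>(batch["next_age"]);
  arma::ivec action = as<arma::ivec>(batch["action"]);
  arma::vec reward = as<arma::vec>(batch["reward"]);
  arma::ivec terminal = as<arma::ivec>(batch["terminal"]);
  const int B = obs.n_rows;

  // one fused online forward over [obs; next_obs]: the double-Q action
  // selection uses the second half, the cached activations of the first
  // half feed the backward pass (sample-major layout keeps the first B
  // samples in the leading rows of every layer)
  std::vector<arma::mat> Pms;
  std::vector<arma::umat> masks;
  arma::mat Q2 = forward(on, H, arma::join_cols(obs, nxt),
                         arma::join_cols(age, nage), &Pms, &masks);
  arma::mat qt = forward(tg, H, nxt, nage, nullptr, nullptr);
  arma::vec y(B);
  for (int i = 0; i < B; ++i) {
    arma::uword astar;
    Q2.row(B + i).max(astar);
    y(i) = reward(i) +
      (terminal(i) ? 0.0 : gamma * qt(i, astar));
  }
  arma::mat Q = Q2.rows(0, B - 1);
  arma::mat F = Pms.back().rows(0, B - 1);
  Pms.pop_back();
  for (int l = 0; l < L; ++l) {
    const int PB = (H[l] - 2) * (H[l] - 2) * B;
    Pms[l] = Pms[l].rows(0, PB - 1);
    masks[l] = masks[l].rows(0, PB - 1);
  }

  arma::vec err(B), dl(B);
  double loss = 0.0;
  for (int i = 0; i < B; ++i) {
    err(i) = Q(i, action(i) - 1) - y(i);
    const double a = std::abs(err(i));
    loss += (a <= 1.0) ? 0.5 * err(i) * err(i) : a - 0.5;
    dl(i) = std::max(-1.0, std::min(1.0, err(i))) / B;
  }
  loss /= B;
  if (!std::isfinite(loss)) stop("non-finite training loss; aborting");

  // backward
  arma::mat dQ(B, Q.n_cols, arma::fill::zeros);
  for (int i = 0; i < B; ++i) dQ(i, action(i) - 1) = dl(i);
  arma::mat gfcW = F.t() * dQ;
  arma::vec gfcb = arma::sum(dQ, 0).t();
  arma::mat dF = dQ * on.fcW.t();
  arma::mat dA = dF.cols(0, dF.n_cols - 2);
  std::vector<arma::mat> gW(L);
  std::vector<arma::vec> gb(L);
  for (int l = L - 1; l >= 0; --l) {
    arma::mat dZ = dA % arma::conv_to<arma::mat>::from(masks[l]);
    gW[l] = Pms[l].t() * dZ;
    gb[l] = arma::sum(dZ, 0).t();
    if (l > 0) {
      arma::mat dPm = dZ * on.W[l].t();
      dA = scatter(dPm, H[l], B, on.W[l - 1].n_cols);
    }
  }

  // Adam
  t += 1;
  const double bc1 = 1 - std::pow(b1, t);
  const double bc2 = 1 - std::pow(beta2, t);
  for (int l = 0; l < L; ++l) {
    adam_one(on.W[l], gW[l], m.W[l], v.W[l], lr, b1, beta2, eps, bc1, bc2);
    adam_one(on.b[l], gb[l], m.b[l], v.b[l], lr, b1, beta2, eps, bc1, bc2);
  }
  adam_one(on.fcW, gfcW, m.fcW, v.fcW, lr, b1, beta2, eps, bc1, bc2);
  adam_one(on.fcb, gfcb, m.fcb, v.fcb, lr, b1, beta2, eps, bc1, bc2);

  // soft target update
  for (int l = 0; l < L; ++l) {
    tg.W[l] = tau * on.W[l] + (1 - tau) * tg.W[l];
    tg.b[l] = tau * on.b[l] + (1 - tau) * tg.b[l];
  }
  tg.fcW = tau * on.fcW + (1 - tau) * tg.fcW;
  tg.fcb = tau * on.fcb + (1 - tau) * tg.fcb;
  losses[step] = loss;
  } // end of step loop

  for (int l = 0; l < L; ++l) {
    List ml = m_layers[l], vl = v_layers[l];
    ml["W"] = wrap(m.W[l]); ml["b"] = wrap(m.b[l]);
    vl["W"] = wrap(v.W[l]); vl["b"] = wrap(v.b[l]);
    m_layers[l] = ml; v_layers[l] = vl;
  }
  mfc["W"] = wrap(m.fcW); mfc["b"] = wrap(m.fcb);
  vfc["W"] = wrap(v.fcW); vfc["b"] = wrap(v.fcb);
  mL["fc"] = mfc; vL["fc"] = vfc;
  mL["layers"] = m_layers; vL["layers"] = v_layers;
  opt["m"] = mL; opt["v"] = vL; opt["t"] = t;
  online["opt"] = opt;

  write_params(online, on);
  write_params(target, tg);
  return List::create(_["online"] = online, _["target"] = target,
                      _["loss"] = losses);
}


// In-place row writes into preallocated replay storage. The matrices are
// owned exclusively by the buffer environment, so writing through the
// pointer avoids R's copy-on-write of the whole allocation.
// [[Rcpp::export(name = ".cpp_write_rows")]]
void cpp_write_rows(NumericMatrix M, IntegerVector pos, NumericMatrix block) {
  const int m = pos.size(), nc = M.ncol(), nr = M.nrow();
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < m; ++i) M[j * nr + (pos[i] - 1)] = block[j * m + i];
  }
}

// [[Rcpp::export(name = ".cpp_write_num")]]
void cpp_write_num(NumericVector v, IntegerVector pos, NumericVector vals) {
  for (int i = 0; i < pos.size(); ++i) v[pos[i] - 1] = vals[i];
}

// [[Rcpp::export(name = ".cpp_write_int")]]
void cpp_write_int(IntegerVector v, IntegerVector pos, IntegerVector vals) {
  for (int i = 0; i < pos.size(); ++i) v[pos[i] - 1] = vals[i];
}

// [[Rcpp::export(name = ".cpp_write_lgl")]]
void cpp_write_lgl(LogicalVector v, IntegerVector pos, LogicalVector vals) {
  for (int i = 0; i < pos.size(); ++i) v[pos[i] - 1] = vals[i];
}
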