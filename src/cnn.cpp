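// Compact deterministic CNN engine specialised to the package's five
// network variants: 3x3 same-padding convolutions (im2col + GEMM),
// batch normalisation, 2x2 max pooling, inverted dropout, dense layers,
// softmax cross-entropy and Adam/SGD training.  All randomness flows
// from a single 64-bit Mersenne Twister seeded from R, and execution is
// single-threaded, so runs are reproducible bit-for-bit given a seed.
//
// Activations for a batch of B samples are stored as a (B*S) x C matrix
// with sample-major row blocks: row b*S + s holds spatial position s
// (column-major within the image) of sample b, one column per channel.
// This layout makes batch normalisation a per-column operation and
// turns convolution into one GEMM per layer over the whole batch.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::umat;
using arma::uword;

namespace {

struct Layer {
  std::string kind;
  int out = 0;          // conv out_channels / dense units
  int ksize = 3;        // conv kernel side (odd)
  int window = 2;       // maxpool window
  double rate = 0.0;    // dropout rate
  std::string activation = "linear";
  // shape bookkeeping (filled by inferShapes)
  int inH = 0, inW = 0, inC = 0, outH = 0, outW = 0, outC = 0;
  int inS() const { return inH * inW; }
  int outS() const { return outH * outW; }
};

std::vector<Layer> parseLayers(const List& layers) {
  std::vector<Layer> L;
  for (int i = 0; i < layers.size(); ++i) {
    List sp = layers[i];
    Layer ly;
    ly.kind = as<std::string>(sp["kind"]);
    if (ly.kind == "conv") {
      ly.out = as<int>(sp["out_channels"]);
      ly.ksize = as<int>(sp["kernel_size"]);
      ly.activation = as<std::string>(sp["activation"]);
    } else if (ly.kind == "dense") {
      ly.out = as<int>(sp["units"]);
      ly.activation = as<std::string>(sp["activation"]);
    } else if (ly.kind == "maxpool") {
      ly.window = as<int>(sp["window"]);
    } else if (ly.kind == "dropout") {
      ly.rate = as<double>(sp["rate"]);
    } else if (ly.kind != "batchnorm" && ly.kind != "flatten") {
      stop("unknown layer kind: %s", ly.kind);
    }
    L.push_back(ly);
  }
  return L;
}

void inferShapes(std::vector<Layer>& L, int H, int W, int C) {
  for (auto& ly : L) {
    ly.inH = H; ly.inW = W; ly.inC = C;
    if (ly.kind == "conv") {
      C = ly.out;                       // same padding keeps H, W
    } else if (ly.kind == "maxpool") {
      H /= ly.window; W /= ly.window;   // floor division, overhang dropped
    } else if (ly.kind == "flatten") {
      C = H * W * C; H = 1; W = 1;
    } else if (ly.kind == "dense") {
      if (H != 1 || W != 1) stop("dense layer requires flattened input");
      C = ly.out;
    }
    ly.outH = H; ly.outW = W; ly.outC = C;
  }
}

// im2col for 'same' zero padding, stride 1.  Column order of M:
// ((dx+p)*k + (dy+p)) * C + c, matching the conv weight row order.
mat im2col(const mat& A, int B, int H, int W, int C, int k) {
  const int p = k / 2, S = H * W;
  mat M(static_cast<uword>(B) * S, static_cast<uword>(k) * k * C,
        arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const uword r0 = static_cast<uword>(b) * S;
    for (int dx = -p; dx <= p; ++dx) {
      const int cc0 = std::max(0, -dx), cc1 = std::min(W - 1, W - 1 - dx);
      for (int dy = -p; dy <= p; ++dy) {
        const int rr0 = std::max(0, -dy), rr1 = std::min(H - 1, H - 1 - dy);
        if (rr1 < rr0) continue;
        const uword colBase =
            (static_cast<uword>(dx + p) * k + (dy + p)) * C;
        for (int c = 0; c < C; ++c) {
          const uword col = colBase + c;
          for (int cc = cc0; cc <= cc1; ++cc) {
            M.submat(r0 + rr0 + static_cast<uword>(cc) * H, col,
                     r0 + rr1 + static_cast<uword>(cc) * H, col) =
                A.submat(r0 + rr0 + dy + static_cast<uword>(cc + dx) * H,
                         c,
                         r0 + rr1 + dy + static_cast<uword>(cc + dx) * H,
                         c);
          }
        }
      }
    }
  }
  return M;
}

// transpose of im2col: scatter-add dM back onto the input layout
mat col2im(const mat& dM, int B, int H, int W, int C, int k) {
  const int p = k / 2, S = H * W;
  mat dA(static_cast<uword>(B) * S, C, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const uword r0 = static_cast<uword>(b) * S;
    for (int dx = -p; dx <= p; ++dx) {
      const int cc0 = std::max(0, -dx), cc1 = std::min(W - 1, W - 1 - dx);
      for (int dy = -p; dy <= p; ++dy) {
        const int rr0 = std::max(0, -dy), rr1 = std::min(H - 1, H - 1 - dy);
        if (rr1 < rr0) continue;
        const uword colBase =
            (static_cast<uword>(dx + p) * k + (dy + p)) * C;
        for (int c = 0; c < C; ++c) {
          const uword col = colBase + c;
          for (int cc = cc0; cc <= cc1; ++cc) {
            dA.submat(r0 + rr0 + dy + static_cast<uword>(cc + dx) * H, c,
                      r0 + rr1 + dy + static_cast<uword>(cc + dx) * H, c) +=
                dM.submat(r0 + rr0 + static_cast<uword>(cc) * H, col,
                          r0 + rr1 + static_cast<uword>(cc) * H, col);
          }
        }
      }
    }
  }
  return dA;
}

constexpr double BN_EPS = 1e-5;
constexpr double BN_MOMENTUM = 0.9;

struct Cache {              // per-layer forward cache for one batch
  mat M;                    // conv: im2col matrix
  mat out;                  // conv/dense: post-activation (relu mask)
  mat xhat;                 // batchnorm: normalised input
  rowvec invstd;            // batchnorm
  umat amax;                // maxpool: argmax spatial index (within block)
  mat mask;                 // dropout
  mat in;                   // dense: input matrix (B x Cin)
};

class Engine {
public:
  std::vector<Layer> L;
  std::vector<std::vector<mat>> Wts;   // trainable + running stats
  std::mt19937_64 rng;
  int nclass = 4;

  Engine(const List& layers, int H, int W, int C, uint64_t seed)
      : rng(seed) {
    L = parseLayers(layers);
    inferShapes(L, H, W, C);
    nclass = L.back().outC;
  }

  void initWeights() {
    std::normal_distribution<double> gauss(0.0, 1.0);
    Wts.clear();
    for (const auto& ly : L) {
      std::vector<mat> w;
      if (ly.kind == "conv" || ly.kind == "dense") {
        const int fanIn = (ly.kind == "conv")
                              ? ly.ksize * ly.ksize * ly.inC
                              : ly.inC;
        // He initialisation for relu layers, Glorot-style for the rest
        const double sd = (ly.activation == "relu")
                              ? std::sqrt(2.0 / fanIn)
                              : std::sqrt(1.0 / fanIn);
        mat Wm(fanIn, ly.out);
        for (uword j = 0; j < Wm.n_cols; ++j)      // fixed traversal order
          for (uword i = 0; i < Wm.n_rows; ++i) Wm(i, j) = sd * gauss(rng);
        w.push_back(Wm);
        w.push_back(mat(1, ly.out, arma::fill::zeros));  // bias
      } else if (ly.kind == "batchnorm") {
        w.push_back(mat(1, ly.inC, arma::fill::ones));   // gamma
        w.push_back(mat(1, ly.inC, arma::fill::zeros));  // beta
        w.push_back(mat(1, ly.inC, arma::fill::zeros));  // running mean
        w.push_back(mat(1, ly.inC, arma::fill::ones));   // running var
      }
      Wts.push_back(std::move(w));
    }
  }

  void setWeights(const List& weights) {
    Wts.clear();
    for (int i = 0; i < weights.size(); ++i) {
      List wl = weights[i];
      std::vector<mat> w;
      for (int j = 0; j < wl.size(); ++j) w.push_back(as<mat>(wl[j]));
      Wts.push_back(std::move(w));
    }
  }

  List getWeights() const {
    List out(Wts.size());
    for (size_t i = 0; i < Wts.size(); ++i) {
      List wl(Wts[i].size());
      for (size_t j = 0; j < Wts[i].size(); ++j) wl[j] = Wts[i][j];
      out[i] = wl;
    }
    return out;
  }

  // forward pass; returns logits (B x nclass)
  mat forward(const mat& X0, int B, bool training, bool useDropout,
              std::vector<Cache>* caches) {
    mat A = X0;
    for (size_t li = 0; li < L.size(); ++li) {
      const Layer& ly = L[li];
      Cache ch;
      if (ly.kind == "conv") {
        mat M = im2col(A, B, ly.inH, ly.inW, ly.inC, ly.ksize);
        A = M * Wts[li][0];
        A.each_row() += Wts[li][1].row(0);
        if (ly.activation == "relu") A.transform([](double v) {
          return v > 0.0 ? v : 0.0;
        });
        if (caches) { ch.M = std::move(M); ch.out = A; }
      } else if (ly.kind == "batchnorm") {
        const double n = static_cast<double>(A.n_rows);
        if (training) {
          rowvec mu = arma::mean(A, 0);
          mat cent = A;
          cent.each_row() -= mu;
          rowvec va = arma::mean(arma::square(cent), 0);
          rowvec invstd = 1.0 / arma::sqrt(va + BN_EPS);
          mat xhat = cent;
          xhat.each_row() %= invstd;
          Wts[li][2] = BN_MOMENTUM * Wts[li][2] + (1.0 - BN_MOMENTUM) * mu;
          Wts[li][3] = BN_MOMENTUM * Wts[li][3] + (1.0 - BN_MOMENTUM) * va;
          A = xhat;
          A.each_row() %= Wts[li][0].row(0);
          A.each_row() += Wts[li][1].row(0);
          if (caches) { ch.xhat = std::move(xhat); ch.invstd = invstd; }
        } else {
          rowvec invstd = 1.0 / arma::sqrt(Wts[li][3].row(0) + BN_EPS);
          A.each_row() -= Wts[li][2].row(0);
          A.each_row() %= (invstd % Wts[li][0].row(0));
          A.each_row() += Wts[li][1].row(0);
        }
        (void)n;
      } else if (ly.kind == "maxpool") {
        const int w = ly.window, H = ly.inH, Ho = ly.outH, Wo = ly.outW;
        const int So = ly.outS();
        mat Y(static_cast<uword>(B) * So, ly.inC);
        umat amax(static_cast<uword>(B) * So, ly.inC);
        for (int b = 0; b < B; ++b) {
          const uword ri = static_cast<uword>(b) * ly.inS();
          const uword ro = static_cast<uword>(b) * So;
          for (int c = 0; c < ly.inC; ++c) {
            for (int oc = 0; oc < Wo; ++oc) {
              for (int orow = 0; orow < Ho; ++orow) {
                double best = -arma::datum::inf; uword bestIdx = 0;
                for (int jc = oc * w; jc < oc * w + w; ++jc) {
                  for (int jr = orow * w; jr < orow * w + w; ++jr) {
                    const uword sIn = jr + static_cast<uword>(jc) * H;
                    const double v = A(ri + sIn, c);
                    if (v > best) { best = v; bestIdx = sIn; }
                  }
                }
                const uword sOut = orow + static_cast<uword>(oc) * Ho;
                Y(ro + sOut, c) = best;
                amax(ro + sOut, c) = bestIdx;
              }
            }
          }
        }
        A = std::move(Y);
        if (caches) ch.amax = std::move(amax);
      } else if (ly.kind == "dropout") {
        if (training && useDropout && ly.rate > 0.0) {
          const double q = 1.0 - ly.rate;
          std::uniform_real_distribution<double> unif(0.0, 1.0);
          mat mask(A.n_rows, A.n_cols);
          for (uword j = 0; j < mask.n_cols; ++j)
            for (uword i = 0; i < mask.n_rows; ++i)
              mask(i, j) = (unif(rng) < q) ? 1.0 / q : 0.0;
          A %= mask;
          if (caches) ch.mask = std::move(mask);
        } else if (caches) {
          ch.mask = mat(A.n_rows, A.n_cols, arma::fill::ones);
        }
      } else if (ly.kind == "flatten") {
        const int S = ly.inS(), C = ly.inC;
        mat F(B, static_cast<uword>(S) * C);
        for (int b = 0; b < B; ++b) {
          const mat block = A.rows(static_cast<uword>(b) * S,
                                   static_cast<uword>(b) * S + S - 1);
          F.row(b) = arma::vectorise(block).t();   // feature = s + c*S
        }
        A = std::move(F);
      } else if (ly.kind == "dense") {
        if (caches) ch.in = A;
        A = A * Wts[li][0];
        A.each_row() += Wts[li][1].row(0);
        if (ly.activation == "relu") A.transform([](double v) {
          return v > 0.0 ? v : 0.0;
        });
        if (caches) ch.out = A;
      }
      if (caches) (*caches)[li] = std::move(ch);
    }
    return A;   // logits of final dense (softmax applied by the caller)
  }

  // softmax cross-entropy; fills probs, returns mean loss
  static double softmaxLoss(const mat& logits, const arma::ivec& y,
                            mat& probs) {
    probs = logits;
    double loss = 0.0;
    for (uword i = 0; i < probs.n_rows; ++i) {
      rowvec r = probs.row(i);
      const double m = r.max();
      r = arma::exp(r - m);
      const double s = arma::accu(r);
      r /= s;
      probs.row(i) = r;
      loss -= std::log(std::max(r(y(i)), 1e-300));
    }
    return loss / probs.n_rows;
  }

  // backward pass from softmax CE; returns gradients parallel to Wts
  std::vector<std::vector<mat>> backward(const mat& probs,
                                         const arma::ivec& y, int B,
                                         std::vector<Cache>& caches) {
    std::vector<std::vector<mat>> G(L.size());
    mat dA = probs;
    for (uword i = 0; i < dA.n_rows; ++i) dA(i, y(i)) -= 1.0;
    dA /= static_cast<double>(dA.n_rows);
    for (int li = static_cast<int>(L.size()) - 1; li >= 0; --li) {
      const Layer& ly = L[li];
      Cache& ch = caches[li];
      if (ly.kind == "dense") {
        if (ly.activation == "relu")
          dA %= arma::conv_to<mat>::from(ch.out > 0.0);
        G[li].resize(2);
        G[li][0] = ch.in.t() * dA;
        G[li][1] = arma::sum(dA, 0);
        dA = dA * Wts[li][0].t();
      } else if (ly.kind == "flatten") {
        const int S = ly.inS(), C = ly.inC;
        mat dPrev(static_cast<uword>(B) * S, C);
        for (int b = 0; b < B; ++b) {
          dPrev.rows(static_cast<uword>(b) * S,
                     static_cast<uword>(b) * S + S - 1) =
              arma::reshape(dA.row(b).t(), S, C);
        }
        dA = std::move(dPrev);
      } else if (ly.kind == "dropout") {
        dA %= ch.mask;
      } else if (ly.kind == "maxpool") {
        mat dPrev(static_cast<uword>(B) * ly.inS(), ly.inC,
                  arma::fill::zeros);
        const int So = ly.outS();
        for (int b = 0; b < B; ++b) {
          const uword ri = static_cast<uword>(b) * ly.inS();
          const uword ro = static_cast<uword>(b) * So;
          for (int c = 0; c < ly.inC; ++c)
            for (int s = 0; s < So; ++s)
              dPrev(ri + ch.amax(ro + s, c), c) += dA(ro + s, c);
        }
        dA = std::move(dPrev);
      } else if (ly.kind == "batchnorm") {
        const double n = static_cast<double>(dA.n_rows);
        rowvec dbeta = arma::sum(dA, 0);
        rowvec dgamma = arma::sum(dA % ch.xhat, 0);
        mat t = dA * n;
        t.each_row() -= dbeta;
        mat xg = ch.xhat;
        xg.each_row() %= dgamma;
        t -= xg;
        t.each_row() %= (Wts[li][0].row(0) % ch.invstd) / n;
        G[li].resize(4);
        G[li][0] = dgamma;
        G[li][1] = dbeta;
        G[li][2] = mat(1, ly.inC, arma::fill::zeros);  // running stats
        G[li][3] = mat(1, ly.inC, arma::fill::zeros);  // are not trained
        dA = std::move(t);
      } else if (ly.kind == "conv") {
        if (ly.activation == "relu")
          dA %= arma::conv_to<mat>::from(ch.out > 0.0);
        G[li].resize(2);
        G[li][0] = ch.M.t() * dA;
        G[li][1] = arma::sum(dA, 0);
        mat dM = dA * Wts[li][0].t();
        dA = col2im(dM, B, ly.inH, ly.inW, ly.inC, ly.ksize);
      }
    }
    return G;
  }
};

// assemble the engine-layout input matrix for a set of sample indices
mat gatherBatch(const arma::cube& X, const std::vector<int>& idx) {
  const int S = X.n_rows * X.n_cols;
  mat A(static_cast<uword>(idx.size()) * S, 1);
  for (size_t b = 0; b < idx.size(); ++b)
    A.submat(b * S, 0, b * S + S - 1, 0) = arma::vectorise(X.slice(idx[b]));
  return A;
}

}  // namespace

// [[Rcpp::export]]
List cnn_init_weights(List layers, int in_h, int in_w, int in_c, int seed) {
  Engine eng(layers, in_h, in_w, in_c,
             static_cast<uint64_t>(static_cast<uint32_t>(seed)));
  eng.initWeights();
  return eng.getWeights();
}

// [[Rcpp::export]]
List cnn_train(List layers, List weights, const arma::cube& X,
               const arma::ivec& y, const arma::cube& Xval,
               const arma::ivec& yval, int epochs, int batch_size,
               double lr, std::string optimizer, int seed) {
  const int n = X.n_slices;
  Engine eng(layers, X.n_rows, X.n_cols, 1,
             static_cast<uint64_t>(static_cast<uint32_t>(seed)) + 0x9E3779B9ULL);
  eng.setWeights(weights);

  // Adam state parallel to the weight list
  std::vector<std::vector<mat>> M(eng.Wts.size()), V(eng.Wts.size());
  for (size_t i = 0; i < eng.Wts.size(); ++i)
    for (size_t j = 0; j < eng.Wts[i].size(); ++j) {
      M[i].push_back(mat(arma::size(eng.Wts[i][j]), arma::fill::zeros));
      V[i].push_back(mat(arma::size(eng.Wts[i][j]), arma::fill::zeros));
    }
  const double b1 = 0.9, b2 = 0.999, adamEps = 1e-8;
  long step = 0;

  vec trLoss(epochs), trAcc(epochs), vaLoss(epochs), vaAcc(epochs);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), eng.rng);
    double lossSum = 0.0; long correct = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int end = std::min(n, start + batch_size);
      std::vector<int> idx(order.begin() + start, order.begin() + end);
      const int B = static_cast<int>(idx.size());
      arma::ivec yb(B);
      for (int b = 0; b < B; ++b) yb(b) = y(idx[b]);
      mat A0 = gatherBatch(X, idx);
      std::vector<Cache> caches(eng.L.size());
      mat logits = eng.forward(A0, B, true, true, &caches);
      mat probs;
      const double loss = Engine::softmaxLoss(logits, yb, probs);
      if (!std::isfinite(loss))
        stop("non-finite training loss at epoch %d", ep + 1);
      lossSum += loss * B;
      for (int b = 0; b < B; ++b)
        if (static_cast<arma::sword>(probs.row(b).index_max()) == yb(b))
          ++correct;
      auto G = eng.backward(probs, yb, B, caches);
      ++step;
      const double corr =
          std::sqrt(1.0 - std::pow(b2, step)) / (1.0 - std::pow(b1, step));
      for (size_t i = 0; i < eng.Wts.size(); ++i) {
        if (eng.L[i].kind == "batchnorm") {
          for (int j = 0; j < 2; ++j) {
            if (optimizer == "adam") {
              M[i][j] = b1 * M[i][j] + (1 - b1) * G[i][j];
              V[i][j] = b2 * V[i][j] + (1 - b2) * arma::square(G[i][j]);
              eng.Wts[i][j] -= lr * corr * M[i][j] /
                               (arma::sqrt(V[i][j]) + adamEps);
            } else {
              eng.Wts[i][j] -= lr * G[i][j];
            }
          }
        } else if (!G[i].empty()) {
          for (size_t j = 0; j < G[i].size(); ++j) {
            if (optimizer == "adam") {
              M[i][j] = b1 * M[i][j] + (1 - b1) * G[i][j];
              V[i][j] = b2 * V[i][j] + (1 - b2) * arma::square(G[i][j]);
              eng.Wts[i][j] -= lr * corr * M[i][j] /
                               (arma::sqrt(V[i][j]) + adamEps);
            } else {
              eng.Wts[i][j] -= lr * G[i][j];
            }
          }
        }
      }
    }
    trLoss(ep) = lossSum / n;
    trAcc(ep) = static_cast<double>(correct) / n;

    // validation at epoch end (inference mode)
    const int nv = Xval.n_slices;
    if (nv > 0) {
      double vLossSum = 0.0; long vCorrect = 0;
      for (int start = 0; start < nv; start += batch_size) {
        const int end = std::min(nv, start + batch_size);
        std::vector<int> idx;
        for (int i = start; i < end; ++i) idx.push_back(i);
        const int B = static_cast<int>(idx.size());
        arma::ivec yb(B);
        for (int b = 0; b < B; ++b) yb(b) = yval(idx[b]);
        mat logits = eng.forward(gatherBatch(Xval, idx), B, false, false,
                                 nullptr);
        mat probs;
        vLossSum += Engine::softmaxLoss(logits, yb, probs) * B;
        for (int b = 0; b < B; ++b)
          if (static_cast<arma::sword>(probs.row(b).index_max()) == yb(b))
            ++vCorrect;
      }
      vaLoss(ep) = vLossSum / nv;
      vaAcc(ep) = static_cast<double>(vCorrect) / nv;
    } else {
      vaLoss(ep) = arma::datum::nan;
      vaAcc(ep) = arma::datum::nan;
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(_["weights"] = eng.getWeights(),
                      _["loss"] = trLoss, _["accuracy"] = trAcc,
                      _["val_loss"] = vaLoss, _["val_accuracy"] = vaAcc);
}

// [[Rcpp::export]]
arma::mat cnn_predict_probs(List layers, List weights, const arma::cube& X,
                            int batch_size) {
  const int n = X.n_slices;
  Engine eng(layers, X.n_rows, X.n_cols, 1, 1);
  eng.setWeights(weights);
  mat probs(n, eng.nclass);
  for (int start = 0; start < n; start += batch_size) {
    const int end = std::min(n, start + batch_size);
    std::vector<int> idx;
    for (int i = start; i < end; ++i) idx.push_back(i);
    const int B = static_cast<int>(idx.size());
    mat logits = eng.forward(gatherBatch(X, idx), B, false, false, nullptr);
    for (int b = 0; b < B; ++b) {
      rowvec r = logits.row(b);
      r = arma::exp(r - r.max());
      probs.row(start + b) = r / arma::accu(r);
    }
  }
  return probs;
}

// Loss and analytic gradients for one batch with dropout disabled and
// batch statistics in use: the hook for finite-difference gradient checks.
// [[Rcpp::export]]
List cnn_loss_grad(List layers, List weights, const arma::cube& X,
                   const arma::ivec& y) {
  const int B = X.n_slices;
  Engine eng(layers, X.n_rows, X.n_cols, 1, 1);
  eng.setWeights(weights);
  std::vector<int> idx;
  for (int i = 0; i < B; ++i) idx.push_back(i);
  std::vector<Cache> caches(eng.L.size());
  mat logits = eng.forward(gatherBatch(X, idx), B, true, false, &caches);
  mat probs;
  const double loss = Engine::softmaxLoss(logits, y, probs);
  auto G = eng.backward(probs, y, B, caches);
  List gl(G.size());
  for (size_t i = 0; i < G.size(); ++i) {
    List wl(G[i].size());
    for (size_t j = 0; j < G[i].size(); ++j) wl[j] = G[i][j];
    gl[i] = wl;
  }
  return List::create(_["loss"] = loss, _["gradients"] = gl);
}

// Loss only, with the same conventions as cnn_loss_grad (used by the
// finite-difference side of the gradient check).
// [[Rcpp::export]]
double cnn_loss_only(List layers, List weights, const arma::cube& X,
                     const arma::ivec& y) {
  const int B = X.n_slices;
  Engine eng(layers, X.n_rows, X.n_cols, 1, 1);
  eng.setWeights(weights);
  std::vector<int> idx;
  for (int i = 0; i < B; ++i) idx.push_back(i);
  mat logits = eng.forward(gatherBatch(X, idx), B, true, false, nullptr);
  mat probs;
  return Engine::softmaxLoss(logits, y, probs);
}
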