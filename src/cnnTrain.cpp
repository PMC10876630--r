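// Minibatch Adam training of the fused multi-branch conv classifier
// (concat fusion).  Mirrors the R reference implementation in
// R/nnEngine.R; all randomness (shuffling, dropout) is drawn from R's
// RNG so runs are reproducible from set.seed().

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static const double BN_EPS = 1e-5;
static const double BN_MOM = 0.9;

enum Act { TANH, SIGMOID, RELU, ELU, LINEAR };

static int actId(const std::string &name) {
  if (name == "tanh") return TANH;
  if (name == "sigmoid") return SIGMOID;
  if (name == "relu") return RELU;
  if (name == "elu") return ELU;
  if (name == "linear") return LINEAR;
  stop("unknown activation '%s'", name);
}

static arma::fmat actF(const arma::fmat &z, int id) {
  switch (id) {
  case TANH: return arma::tanh(z);
  case SIGMOID: return 1.0 / (1.0 + arma::exp(-z));
  case RELU: return arma::clamp(z, 0.0, arma::datum::inf);
  case ELU: {
    arma::fmat a = z;
    a.for_each([](float &v) { if (v < 0) v = std::expm1(v); });
    return a;
  }
  default: return z;
  }
}

// derivative given pre-activation z and activation a
static arma::fmat actDf(const arma::fmat &z, const arma::fmat &a, int id) {
  switch (id) {
  case TANH: return 1.0 - a % a;
  case SIGMOID: return a % (1.0 - a);
  case RELU: return arma::conv_to<arma::fmat>::from(z > 0.0);
  case ELU: {
    arma::fmat d(z.n_rows, z.n_cols);
    for (arma::uword i = 0; i < z.n_elem; ++i)
      d(i) = z(i) > 0 ? 1.0 : a(i) + 1.0;
    return d;
  }
  default: return arma::ones<arma::fmat>(z.n_rows, z.n_cols);
  }
}

struct DenseLayer {
  arma::fmat W;
  arma::frowvec b, gamma, beta, runMean, runVar;
  bool bn;
};

struct Branch {
  bool useConv;
  int kernel, filters, convAct, denseAct;
  double dropout;
  arma::fmat convW;          // kernel x filters
  arma::frowvec convB;
  std::vector<DenseLayer> dense;
};

struct BranchCache {
  arma::fmat convZ, convA;
  std::vector<arma::fmat> Hin, Y, A, Zhat, mask;
  std::vector<arma::frowvec> mu, va;
};

struct BranchGrad {
  arma::fmat convW;
  arma::frowvec convB;
  std::vector<arma::fmat> W;
  std::vector<arma::frowvec> b, gamma, beta;
};

static arma::fmat convForward(const arma::fmat &X, const arma::fmat &W,
                             const arma::frowvec &b) {
  int k = W.n_rows, f = W.n_cols;
  int Lc = X.n_cols - k + 1;
  arma::fmat out(X.n_rows, Lc * f);
  for (int j = 0; j < f; ++j) {
    arma::fmat block(X.n_rows, Lc, arma::fill::value(b(j)));
    for (int t = 0; t < k; ++t)
      block += W(t, j) * X.cols(t, t + Lc - 1);
    out.cols(j * Lc, (j + 1) * Lc - 1) = block;
  }
  return out;
}

static arma::fmat branchForward(const Branch &br, const arma::fmat &X,
                               bool training, BranchCache *cache) {
  arma::fmat H;
  if (br.useConv) {
    arma::fmat Z = convForward(X, br.convW, br.convB);
    arma::fmat A = actF(Z, br.convAct);
    if (cache) { cache->convZ = Z; cache->convA = A; }
    H = A;
  } else {
    H = X;
  }
  size_t nl = br.dense.size();
  if (cache) {
    cache->Hin.resize(nl); cache->Y.resize(nl); cache->A.resize(nl);
    cache->Zhat.resize(nl); cache->mask.resize(nl);
    cache->mu.resize(nl); cache->va.resize(nl);
  }
  for (size_t i = 0; i < nl; ++i) {
    const DenseLayer &ly = br.dense[i];
    arma::fmat Z = H * ly.W;
    Z.each_row() += ly.b;
    if (cache) cache->Hin[i] = std::move(H);
    arma::fmat Y;
    if (ly.bn) {
      arma::frowvec mu, va;
      if (training) {
        mu = arma::mean(Z, 0);
        va = arma::mean(Z % Z, 0) - mu % mu;
        va.for_each([](float &v) { if (v < 0) v = 0; });
        if (cache) { cache->mu[i] = mu; cache->va[i] = va; }
      } else {
        mu = ly.runMean; va = ly.runVar;
      }
      arma::fmat Zhat = Z;
      Zhat.each_row() -= mu;
      Zhat.each_row() /= arma::sqrt(va + BN_EPS);
      Y = Zhat;
      Y.each_row() %= ly.gamma;
      Y.each_row() += ly.beta;
      if (cache) cache->Zhat[i] = Zhat;
    } else {
      Y = Z;
    }
    arma::fmat A = actF(Y, br.denseAct);
    if (cache) { cache->Y[i] = Y; cache->A[i] = A; }
    if (training && br.dropout > 0) {
      double inv = 1.0 / (1.0 - br.dropout);
      arma::fmat mask(A.n_rows, A.n_cols);
      float *mp = mask.memptr(), *ap = A.memptr();
      for (arma::uword e = 0; e < mask.n_elem; ++e) {
        double v = (unif_rand() >= br.dropout) ? inv : 0.0;
        mp[e] = v;
        ap[e] *= v;
      }
      if (cache) cache->mask[i] = std::move(mask);
    }
    H = A;
  }
  return H;
}

static void branchBackward(const Branch &br, const arma::fmat &X,
                           const BranchCache &cache, arma::fmat dOut,
                           BranchGrad &g) {
  size_t nl = br.dense.size();
  g.W.resize(nl); g.b.resize(nl); g.gamma.resize(nl); g.beta.resize(nl);
  arma::fmat dH = dOut;
  for (int i = nl - 1; i >= 0; --i) {
    const DenseLayer &ly = br.dense[i];
    arma::fmat dA = dH;
    if (br.dropout > 0) dA %= cache.mask[i];
    arma::fmat dY = dA % actDf(cache.Y[i], cache.A[i], br.denseAct);
    arma::fmat dZ;
    if (ly.bn) {
      double n = dY.n_rows;
      g.gamma[i] = arma::sum(dY % cache.Zhat[i], 0);
      g.beta[i] = arma::sum(dY, 0);
      arma::fmat dZhat = dY;
      dZhat.each_row() %= ly.gamma;
      arma::frowvec mZ = arma::mean(dZhat, 0);
      arma::frowvec mZZ = arma::mean(dZhat % cache.Zhat[i], 0);
      dZ = dZhat;
      dZ.each_row() -= mZ;
      dZ -= cache.Zhat[i] % arma::repmat(mZZ, n, 1);
      dZ.each_row() /= arma::sqrt(cache.va[i] + BN_EPS);
    } else {
      dZ = dY;
    }
    g.W[i] = cache.Hin[i].t() * dZ;
    g.b[i] = arma::sum(dZ, 0);
    dH = dZ * ly.W.t();
  }
  if (br.useConv) {
    arma::fmat dPre = dH % actDf(cache.convZ, cache.convA, br.convAct);
    int k = br.kernel, f = br.filters;
    int Lc = X.n_cols - k + 1;
    g.convW.set_size(k, f);
    g.convB.set_size(f);
    for (int j = 0; j < f; ++j) {
      arma::fmat block = dPre.cols(j * Lc, (j + 1) * Lc - 1);
      g.convB(j) = arma::accu(block);
      for (int t = 0; t < k; ++t)
        g.convW(t, j) = arma::accu(block % X.cols(t, t + Lc - 1));
    }
  }
}

struct Adam {
  std::vector<arma::fmat> m, v;
  std::vector<arma::fmat *> targets;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;

  void registerMat(arma::fmat *p) {
    targets.push_back(p);
    m.push_back(arma::zeros<arma::fmat>(p->n_rows, p->n_cols));
    v.push_back(arma::zeros<arma::fmat>(p->n_rows, p->n_cols));
  }
  void step(const std::vector<arma::fmat> &grads, double lr) {
    ++t;
    double c1 = 1.0 - std::pow(b1, (double)t);
    double c2 = 1.0 - std::pow(b2, (double)t);
    double sc2 = std::sqrt(c2);
    for (size_t i = 0; i < targets.size(); ++i) {
      float *mp = m[i].memptr(), *vp = v[i].memptr(),
             *pp = targets[i]->memptr();
      const float *gp = grads[i].memptr();
      arma::uword ne = m[i].n_elem;
      for (arma::uword e = 0; e < ne; ++e) {
        mp[e] = b1 * mp[e] + (1.0 - b1) * gp[e];
        vp[e] = b2 * vp[e] + (1.0 - b2) * gp[e] * gp[e];
        pp[e] -= lr * (mp[e] / c1) / (std::sqrt(vp[e]) / sc2 + eps);
      }
    }
  }
};

static Branch parseBranch(const List &spec, const List &params) {
  Branch br;
  br.useConv = as<bool>(spec["useConv"]);
  br.kernel = as<int>(spec["convKernel"]);
  br.filters = as<int>(spec["convFilters"]);
  br.convAct = actId(as<std::string>(spec["convActivation"]));
  br.denseAct = actId(as<std::string>(spec["denseActivation"]));
  br.dropout = as<double>(spec["dropout"]);
  bool bn = as<bool>(spec["batchNorm"]);
  if (br.useConv) {
    br.convW = as<arma::fmat>(params["convW"]);
    br.convB = as<arma::frowvec>(params["convB"]);
  }
  List dense = params["dense"];
  for (int i = 0; i < dense.size(); ++i) {
    List ly = dense[i];
    DenseLayer d;
    d.W = as<arma::fmat>(ly["W"]);
    d.b = as<arma::frowvec>(ly["b"]);
    d.bn = bn;
    if (bn) {
      d.gamma = as<arma::frowvec>(ly["gamma"]);
      d.beta = as<arma::frowvec>(ly["beta"]);
      d.runMean = as<arma::frowvec>(ly["runMean"]);
      d.runVar = as<arma::frowvec>(ly["runVar"]);
    }
    br.dense.push_back(d);
  }
  return br;
}

static List exportBranch(const Branch &br, List tmpl) {
  List out = clone(tmpl);
  if (br.useConv) {
    out["convW"] = wrap(br.convW);
    out["convB"] = NumericVector(br.convB.begin(), br.convB.end());
  }
  List dense = out["dense"];
  for (size_t i = 0; i < br.dense.size(); ++i) {
    List ly = dense[i];
    const DenseLayer &d = br.dense[i];
    ly["W"] = wrap(d.W);
    ly["b"] = NumericVector(d.b.begin(), d.b.end());
    if (d.bn) {
      ly["gamma"] = NumericVector(d.gamma.begin(), d.gamma.end());
      ly["beta"] = NumericVector(d.beta.begin(), d.beta.end());
      ly["runMean"] = NumericVector(d.runMean.begin(), d.runMean.end());
      ly["runVar"] = NumericVector(d.runVar.begin(), d.runVar.end());
    }
    dense[i] = ly;
  }
  out["dense"] = dense;
  return out;
}

// [[Rcpp::export(name = ".cnnTrainConcat")]]
List cnnTrainConcat(List Xs, IntegerVector y, List specs, List params,
                    List XsVal, IntegerVector yVal, int nEvents, int epochs,
                    int batchSize, double lr, int patience, bool useVal) {
  RNGScope rng;
  int nb = Xs.size();
  std::vector<arma::fmat> X(nb), Xv(nb);
  for (int i = 0; i < nb; ++i) X[i] = as<arma::fmat>(Xs[i]);
  if (useVal)
    for (int i = 0; i < nb; ++i) Xv[i] = as<arma::fmat>(XsVal[i]);
  int n = y.size();

  List branchParams = params["branches"];
  std::vector<Branch> branches(nb);
  for (int i = 0; i < nb; ++i)
    branches[i] = parseBranch(specs[i], branchParams[i]);
  List head = params["head"];
  arma::fmat headW = as<arma::fmat>(head["W"]);
  arma::frowvec headB = as<arma::frowvec>(head["b"]);

  // Adam over every tensor, collected in a fixed registration order.
  // rowvec parameters are updated through 1-row matrix shims; the shim
  // vector is pre-reserved so registered pointers stay valid.
  Adam adam;
  std::vector<arma::fmat> shims;
  shims.reserve(512);
  std::vector<arma::frowvec *> shimSrc;
  auto reg = [&](arma::fmat *p) { adam.registerMat(p); };
  auto regRow = [&](arma::frowvec *p) {
    shims.push_back(arma::fmat(*p));
    shimSrc.push_back(p);
    adam.registerMat(&shims.back());
  };
  for (int i = 0; i < nb; ++i) {
    Branch &br = branches[i];
    if (br.useConv) { reg(&br.convW); regRow(&br.convB); }
    for (size_t l = 0; l < br.dense.size(); ++l) {
      reg(&br.dense[l].W); regRow(&br.dense[l].b);
      if (br.dense[l].bn) {
        regRow(&br.dense[l].gamma); regRow(&br.dense[l].beta);
      }
    }
  }
  reg(&headW); regRow(&headB);

  // widths for splitting the fused gradient
  std::vector<int> widths(nb);
  for (int i = 0; i < nb; ++i)
    widths[i] = branches[i].dense.back().W.n_cols;

  int nBatches = (n + batchSize - 1) / batchSize;
  arma::dmat histOut(epochs, 4);
  histOut.fill(arma::datum::nan);
  int histRows = 0;

  double bestAcc = -1.0;
  int bestEpoch = 0;
  bool haveBest = false;
  List bestParams;

  auto snapshot = [&]() {
    // sync shims back before exporting
    for (size_t s = 0; s < shims.size(); ++s) *shimSrc[s] = shims[s].row(0);
    List bp(nb);
    for (int i = 0; i < nb; ++i)
      bp[i] = exportBranch(branches[i], branchParams[i]);
    bp.attr("names") = branchParams.attr("names");
    return List::create(_["branches"] = bp,
                        _["head"] = List::create(
                          _["W"] = wrap(headW),
                          _["b"] = NumericVector(headB.begin(), headB.end())));
  };

  for (int epoch = 1; epoch <= epochs; ++epoch) {
    // Fisher-Yates shuffle driven by R's RNG
    arma::uvec ord(n);
    for (int i = 0; i < n; ++i) ord(i) = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord(i), ord(j));
    }
    double lossSum = 0.0;
    for (int b = 0; b < nBatches; ++b) {
      int lo = b * batchSize;
      int hi = std::min(n, lo + batchSize) - 1;
      arma::uvec idx = ord.subvec(lo, hi);
      int m = idx.n_elem;

      // sync rowvec shims into the branch structs for forward use
      for (size_t s = 0; s < shims.size(); ++s) *shimSrc[s] = shims[s].row(0);

      std::vector<arma::fmat> Xb(nb);
      std::vector<BranchCache> caches(nb);
      arma::fmat Fmat;
      for (int i = 0; i < nb; ++i) {
        Xb[i] = X[i].rows(idx);
        arma::fmat out = branchForward(branches[i], Xb[i], true, &caches[i]);
        Fmat = (i == 0) ? out : arma::join_rows(Fmat, out);
      }
      arma::fmat logits = Fmat * headW;
      logits.each_row() += headB;
      logits.each_col() -= arma::max(logits, 1);
      arma::fmat P = arma::exp(logits);
      P.each_col() /= arma::sum(P, 1);

      double loss = 0.0;
      arma::fmat dLogits = P;
      for (int r = 0; r < m; ++r) {
        int cls = y[idx(r)];
        double p = std::max((double)P(r, cls), 1e-12);
        loss -= std::log(p);
        dLogits(r, cls) -= 1.0;
      }
      loss /= m;
      if (!std::isfinite(loss))
        stop("training diverged: non-finite loss at epoch %d", epoch);
      lossSum += loss * m;
      dLogits /= m;

      // gradients, in the same registration order as Adam targets
      std::vector<arma::fmat> grads;
      grads.reserve(adam.targets.size());
      arma::fmat gHeadW = Fmat.t() * dLogits;
      arma::frowvec gHeadB = arma::sum(dLogits, 0);
      arma::fmat dF = dLogits * headW.t();
      int offset = 0;
      std::vector<BranchGrad> bg(nb);
      for (int i = 0; i < nb; ++i) {
        arma::fmat dOut = dF.cols(offset, offset + widths[i] - 1);
        offset += widths[i];
        branchBackward(branches[i], Xb[i], caches[i], dOut, bg[i]);
        // batch-norm running stats
        for (size_t l = 0; l < branches[i].dense.size(); ++l) {
          DenseLayer &ly = branches[i].dense[l];
          if (ly.bn) {
            ly.runMean = BN_MOM * ly.runMean + (1 - BN_MOM) * caches[i].mu[l];
            ly.runVar = BN_MOM * ly.runVar + (1 - BN_MOM) * caches[i].va[l];
          }
        }
      }
      for (int i = 0; i < nb; ++i) {
        Branch &br = branches[i];
        if (br.useConv) {
          grads.push_back(bg[i].convW);
          grads.push_back(arma::fmat(bg[i].convB));
        }
        for (size_t l = 0; l < br.dense.size(); ++l) {
          grads.push_back(bg[i].W[l]);
          grads.push_back(arma::fmat(bg[i].b[l]));
          if (br.dense[l].bn) {
            grads.push_back(arma::fmat(bg[i].gamma[l]));
            grads.push_back(arma::fmat(bg[i].beta[l]));
          }
        }
      }
      grads.push_back(gHeadW);
      grads.push_back(arma::fmat(gHeadB));
      adam.step(grads, lr);
    }
    double trainLoss = lossSum / n;
    double valLoss = arma::datum::nan, valAcc = arma::datum::nan;
    if (useVal) {
      for (size_t s = 0; s < shims.size(); ++s) *shimSrc[s] = shims[s].row(0);
      arma::fmat Fv;
      for (int i = 0; i < nb; ++i) {
        arma::fmat out = branchForward(branches[i], Xv[i], false, nullptr);
        Fv = (i == 0) ? out : arma::join_rows(Fv, out);
      }
      arma::fmat logits = Fv * headW;
      logits.each_row() += headB;
      logits.each_col() -= arma::max(logits, 1);
      arma::fmat P = arma::exp(logits);
      P.each_col() /= arma::sum(P, 1);
      double vl = 0.0; int correct = 0;
      for (int r = 0; r < (int)P.n_rows; ++r) {
        int cls = yVal[r];
        vl -= std::log(std::max((double)P(r, cls), 1e-12));
        if ((int)P.row(r).index_max() == cls) ++correct;
      }
      valLoss = vl / P.n_rows;
      valAcc = (double)correct / P.n_rows;
    }
    histOut(histRows, 0) = epoch;
    histOut(histRows, 1) = trainLoss;
    histOut(histRows, 2) = valLoss;
    histOut(histRows, 3) = valAcc;
    ++histRows;
    if (useVal) {
      if (valAcc > bestAcc + 1e-9) {
        bestAcc = valAcc;
        bestEpoch = epoch;
        bestParams = snapshot();
        haveBest = true;
      } else if (epoch - bestEpoch >= patience) {
        break;
      }
    }
    Rcpp::checkUserInterrupt();
  }

  List outParams = (useVal && haveBest) ? bestParams : snapshot();
  return List::create(_["params"] = outParams,
                      _["history"] = wrap(histOut.rows(0, histRows - 1)));
}
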