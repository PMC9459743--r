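// Compiled forward/backward kernels for the dilated TCN frame classifier.
//
// A batch of n windows of W frames is stacked position-major into an
// (n*W) x C matrix: rows (t-1)*n+1 .. t*n hold window position t of every
// window. A dilated kernel tap with offset o maps the contiguous position
// block [t0, t1] onto [t0+o, t1+o], so the whole convolution is an im2col
// block copy followed by a single GEMM per layer. The pure-R implementation
// in R/tcn.R is the reference; these kernels must produce the same numbers
// (up to BLAS summation order) and are verified against it in the tests.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Config {
  int k, W, nblocks, layers, nclasses;
  arma::ivec channels, dilations;
};

Config read_config(const List& cfg) {
  Config c;
  c.k = as<int>(cfg["kernel_size"]);
  c.W = as<int>(cfg["window_size"]);
  c.nblocks = as<int>(cfg["n_blocks"]);
  c.layers = as<int>(cfg["layers_per_block"]);
  c.nclasses = as<int>(cfg["n_classes"]);
  c.channels = as<arma::ivec>(cfg["channels"]);
  c.dilations = as<arma::ivec>(cfg["dilations"]);
  return c;
}

std::string pname(int b, int l, const char* what) {
  char buf[32];
  snprintf(buf, sizeof(buf), "b%d_l%d_%s", b + 1, l + 1, what);
  return std::string(buf);
}
std::string bname(int b, const char* what) {
  char buf[32];
  snprintf(buf, sizeof(buf), "b%d_proj_%s", b + 1, what);
  return std::string(buf);
}

struct LayerCache {
  arma::mat Xcat;   // im2col input, (n*W) x (k*cin)
  arma::mat mask;   // ReLU mask as 0/1 doubles
  int cin;
};
struct BlockCache {
  arma::mat input;
  std::vector<LayerCache> layers;
};

// im2col for one dilated layer: tap j occupies column block j*cin..(j+1)*cin-1
arma::mat im2col(const arma::mat& X, int n, int W, int k, int dil, int cin) {
  arma::mat Xcat(n * W, k * cin, arma::fill::zeros);
  for (int j = 0; j < k; ++j) {
    const int off = dil * ((j + 1) - (k + 1) / 2);
    const int t0 = std::max(0, -off), t1 = std::min(W - 1, W - 1 - off);
    if (t0 > t1) continue;
    Xcat.submat(t0 * n, j * cin, (t1 + 1) * n - 1, (j + 1) * cin - 1) =
      X.rows((t0 + off) * n, (t1 + 1 + off) * n - 1);
  }
  return Xcat;
}

// forward through the temporal blocks; X is consumed and replaced
void run_blocks(arma::mat& X, const List& params, const Config& cfg, int n,
                std::vector<BlockCache>* caches) {
  const int W = cfg.W, k = cfg.k;
  for (int b = 0; b < cfg.nblocks; ++b) {
    const int dil = cfg.dilations[b];
    arma::mat inp = X;
    BlockCache bc;
    for (int l = 0; l < cfg.layers; ++l) {
      const int cin = X.n_cols;
      const arma::mat Wl = as<arma::mat>(params[pname(b, l, "W")]);
      const arma::rowvec bias = as<arma::rowvec>(params[pname(b, l, "b")]);
      LayerCache lc;
      lc.cin = cin;
      lc.Xcat = im2col(X, n, W, k, dil, cin);
      arma::mat Z = lc.Xcat * Wl;
      Z.each_row() += bias;
      lc.mask = arma::conv_to<arma::mat>::from(Z > 0);
      X = Z % lc.mask;
      if (caches) bc.layers.push_back(std::move(lc));
    }
    if (params.containsElementNamed(bname(b, "W").c_str())) {
      const arma::mat Wp = as<arma::mat>(params[bname(b, "W")]);
      const arma::rowvec bp = as<arma::rowvec>(params[bname(b, "b")]);
      arma::mat res = inp * Wp;
      res.each_row() += bp;
      X += res;
    } else {
      X += inp;
    }
    if (caches) {
      bc.input = std::move(inp);
      caches->push_back(std::move(bc));
    }
  }
}

// flatten (n*W) x cl position-major features to n x (W*cl), channel fastest
// within each position (column (t-1)*cl + c), and its inverse
arma::mat flatten_head(const arma::mat& X, int n, int W) {
  const int cl = X.n_cols;
  arma::mat Xh(n, W * cl);
  for (int t = 0; t < W; ++t) {
    Xh.cols(t * cl, (t + 1) * cl - 1) = X.rows(t * n, (t + 1) * n - 1);
  }
  return Xh;
}
arma::mat unflatten_head(const arma::mat& dXh, int n, int W, int cl) {
  arma::mat dX(n * W, cl);
  for (int t = 0; t < W; ++t) {
    dX.rows(t * n, (t + 1) * n - 1) = dXh.cols(t * cl, (t + 1) * cl - 1);
  }
  return dX;
}

arma::mat head_probs(const arma::mat& Xh, const List& params) {
  const arma::mat Wh = as<arma::mat>(params["head_W"]);
  const arma::rowvec bh = as<arma::rowvec>(params["head_b"]);
  arma::mat logits = Xh * Wh;
  logits.each_row() += bh;
  logits.each_col() -= arma::max(logits, 1);
  arma::mat P = arma::exp(logits);
  P.each_col() /= arma::sum(P, 1);
  return P;
}

}  // namespace

// [[Rcpp::export(name = ".tcn_probs_cpp")]]
arma::mat tcn_probs_cpp(const arma::mat& x0, int n, const List& params,
                        const List& config) {
  Config cfg = read_config(config);
  arma::mat X = x0;
  run_blocks(X, params, cfg, n, nullptr);
  return head_probs(flatten_head(X, n, cfg.W), params);
}

// One combined forward/backward pass over a minibatch: summed cross-entropy,
// number of correct argmax predictions, and gradients of the mean loss named
// like the R parameter list.
// [[Rcpp::export(name = ".tcn_step_cpp")]]
List tcn_step_cpp(const arma::mat& x0, int n, const arma::ivec& y,
                  const List& params, const List& config) {
  Config cfg = read_config(config);
  const int W = cfg.W, k = cfg.k;
  std::vector<BlockCache> caches;
  arma::mat X = x0;
  run_blocks(X, params, cfg, n, &caches);
  const int cl = X.n_cols;
  arma::mat Xh = flatten_head(X, n, W);
  arma::mat P = head_probs(Xh, params);

  double loss = 0;
  int correct = 0;
  arma::mat dlogits = P;
  for (int i = 0; i < n; ++i) {
    const int cls = y[i] - 1;
    loss += -std::log(std::max(P(i, cls), 1e-12));
    arma::uword amax;
    P.row(i).max(amax);
    if ((int)amax == cls) ++correct;
    dlogits(i, cls) -= 1.0;
  }
  dlogits /= n;

  List grads;
  const arma::mat Wh = as<arma::mat>(params["head_W"]);
  grads["head_W"] = arma::mat(Xh.t() * dlogits);
  grads["head_b"] = arma::vec(arma::sum(dlogits, 0).t());
  arma::mat dX = unflatten_head(dlogits * Wh.t(), n, W, cl);

  for (int b = cfg.nblocks - 1; b >= 0; --b) {
    const BlockCache& bc = caches[b];
    const int dil = cfg.dilations[b];
    arma::mat dInp;
    if (params.containsElementNamed(bname(b, "W").c_str())) {
      const arma::mat Wp = as<arma::mat>(params[bname(b, "W")]);
      grads[bname(b, "W")] = arma::mat(bc.input.t() * dX);
      grads[bname(b, "b")] = arma::vec(arma::sum(dX, 0).t());
      dInp = dX * Wp.t();
    } else {
      dInp = dX;
    }
    arma::mat dA = dX;
    for (int l = cfg.layers - 1; l >= 0; --l) {
      const LayerCache& lc = bc.layers[l];
      const arma::mat Wl = as<arma::mat>(params[pname(b, l, "W")]);
      arma::mat dZ = dA % lc.mask;
      grads[pname(b, l, "b")] = arma::vec(arma::sum(dZ, 0).t());
      grads[pname(b, l, "W")] = arma::mat(lc.Xcat.t() * dZ);
      arma::mat dXcat = dZ * Wl.t();
      arma::mat dprev(n * W, lc.cin, arma::fill::zeros);
      for (int j = 0; j < k; ++j) {
        const int off = dil * ((j + 1) - (k + 1) / 2);
        const int t0 = std::max(0, -off), t1 = std::min(W - 1, W - 1 - off);
        if (t0 > t1) continue;
        dprev.rows((t0 + off) * n, (t1 + 1 + off) * n - 1) +=
          dXcat.submat(t0 * n, j * lc.cin, (t1 + 1) * n - 1,
                       (j + 1) * lc.cin - 1);
      }
      dA = std::move(dprev);
    }
    dX = dA + dInp;
  }

  return List::create(_["loss_sum"] = loss, _["n_correct"] = correct,
                      _["grads"] = grads);
}
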