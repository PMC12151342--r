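// Minimal feed-forward network used as the swim-probability encoder:
// one linear "convolutional" layer (20 units spanning the full history of
// both input channels), two Swish dense layers (64 units), linear logit
// output. Trained with minibatch Adam on binary cross-entropy with L2
// weight decay and inverted dropout. All randomness flows through R's RNG
// so fits are reproducible under set.seed(). Single-precision arithmetic
// keeps minibatch updates and full-data passes memory-light; weights are
// returned as doubles.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// in-place logistic
static inline void sigmoid_ip(fmat& x) {
  x.transform([](float v) { return 1.0f / (1.0f + std::exp(-v)); });
}

static fmat r_randn_f(unsigned int nr, unsigned int nc, double sd) {
  fmat out(nr, nc);
  for (uword j = 0; j < nc; ++j)
    for (uword i = 0; i < nr; ++i)
      out(i, j) = (float) (R::norm_rand() * sd);
  return out;
}

// fast local generator for dropout masks, seeded from R's RNG per batch so
// the whole fit stays reproducible under set.seed()
static inline uint64_t splitmix64(uint64_t& s) {
  uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e9b5ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

// Bernoulli keep-mask scaled by 1/keep (inverted dropout)
static void r_dropmask(fmat& out, double drop, uint64_t& state) {
  const float inv = (float) (1.0 / (1.0 - drop));
  const uint64_t thresh = (uint64_t) ((1.0 - drop) * 18446744073709551615.0);
  float* ptr = out.memptr();
  const uword n = out.n_elem;
  for (uword i = 0; i < n; ++i) ptr[i] = (splitmix64(state) < thresh) ? inv : 0.0f;
}

// Fisher-Yates shuffle using R's RNG
static uvec r_shuffle(unsigned int n) {
  uvec idx = regspace<uvec>(0, n - 1);
  for (uword i = n - 1; i > 0; --i) {
    uword j = (uword) std::floor(R::unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx(i), idx(j));
  }
  return idx;
}

struct AdamState {
  fmat m, v;
  AdamState(unsigned int nr, unsigned int nc)
    : m(nr, nc, fill::zeros), v(nr, nc, fill::zeros) {}
};

static void adam_step(fmat& w, const fmat& g, AdamState& st, float lr,
                      float b1, float b2, float eps, int t) {
  st.m = b1 * st.m + (1.0f - b1) * g;
  st.v = b2 * st.v + (1.0f - b2) * (g % g);
  const float c1 = 1.0f - std::pow(b1, (float) t);
  const float c2 = 1.0f - std::pow(b2, (float) t);
  w -= lr * (st.m / c1) / (sqrt(st.v / c2) + eps);
}

// [[Rcpp::export]]
Rcpp::List nn_train(const arma::mat& X, const arma::vec& y,
                    int n_conv, int n_dense, int epochs, int batch,
                    double lr, double weight_decay, double dropout) {
  const uword n = X.n_rows, p = X.n_cols;
  if (y.n_elem != n) Rcpp::stop("length(y) must equal nrow(X)");
  if (epochs < 1 || batch < 1) Rcpp::stop("epochs and batch must be positive");
  const fmat Xf = conv_to<fmat>::from(X);
  const fvec yf = conv_to<fvec>::from(y);
  const float lrf = (float) lr, wd = (float) weight_decay;

  // Glorot-normal initialization
  fmat W1 = r_randn_f(p, n_conv, std::sqrt(2.0 / (p + n_conv)));
  frowvec b1(n_conv, fill::zeros);
  fmat W2 = r_randn_f(n_conv, n_dense, std::sqrt(2.0 / (n_conv + n_dense)));
  frowvec b2(n_dense, fill::zeros);
  fmat W3 = r_randn_f(n_dense, n_dense, std::sqrt(2.0 / (2.0 * n_dense)));
  frowvec b3(n_dense, fill::zeros);
  fmat W4 = r_randn_f(n_dense, 1, std::sqrt(2.0 / (n_dense + 1)));
  float b4 = 0.0f;

  AdamState sW1(p, n_conv), sW2(n_conv, n_dense), sW3(n_dense, n_dense),
      sW4(n_dense, 1), sb1(1, n_conv), sb2(1, n_dense), sb3(1, n_dense),
      sb4(1, 1);
  const float be1 = 0.9f, be2 = 0.999f, eps = 1e-8f;
  int t = 0;
  vec loss_hist(epochs, fill::zeros);
  const bool use_drop = dropout > 0.0;

  for (int ep = 0; ep < epochs; ++ep) {
    uvec ord = r_shuffle(n);
    double ep_loss = 0.0;
    uword done = 0;
    while (done < n) {
      const uword bend = std::min<uword>(done + batch, n);
      const uvec idx = ord.subvec(done, bend - 1);
      const fmat Xb = Xf.rows(idx);
      const fvec yb = yf.elem(idx);
      const uword nb = Xb.n_rows;

      // forward; Si caches sigmoid(Zi) so Swish and its derivative share it
      fmat M1(nb, n_conv, fill::none), M2(nb, n_dense, fill::none),
          M3(nb, n_dense, fill::none);
      if (use_drop) {
        uint64_t st = (uint64_t) std::floor(R::unif_rand() * 9.007199254740992e15);
        r_dropmask(M1, dropout, st);
        r_dropmask(M2, dropout, st);
        r_dropmask(M3, dropout, st);
      } else {
        M1.ones();
        M2.ones();
        M3.ones();
      }
      fmat D1 = Xb * W1;
      D1.each_row() += b1;
      D1 %= M1; // conv layer is linear

      fmat Z2 = D1 * W2;
      Z2.each_row() += b2;
      fmat S2 = Z2;
      sigmoid_ip(S2);
      fmat D2 = Z2 % S2 % M2; // swish(Z2) with dropout

      fmat Z3 = D2 * W3;
      Z3.each_row() += b3;
      fmat S3 = Z3;
      sigmoid_ip(S3);
      fmat D3 = Z3 % S3 % M3;

      fvec logit = D3 * W4 + b4;
      fvec pr = logit;
      pr.transform([](float v) { return 1.0f / (1.0f + std::exp(-v)); });
      // BCE accumulated in double; pr holds sigmoid(logit)
      for (uword i = 0; i < nb; ++i) {
        const double q = yb(i) > 0.5f ? (double) pr(i) : 1.0 - (double) pr(i);
        ep_loss += -std::log(std::max(q, 1e-12));
      }

      // backward
      fvec g4 = (pr - yb) / (float) nb; // dL/dlogit
      fmat dW4 = D3.t() * g4 + wd * W4;
      const float db4 = accu(g4);

      // swish'(z) = s(z) * (1 + z * (1 - s(z))), reusing cached S3/S2
      fmat G3 = (g4 * W4.t());
      G3 %= M3;
      G3 %= S3 % (1.0f + Z3 % (1.0f - S3));
      fmat dW3 = D2.t() * G3 + wd * W3;
      frowvec db3 = sum(G3, 0);

      fmat G2 = G3 * W3.t();
      G2 %= M2;
      G2 %= S2 % (1.0f + Z2 % (1.0f - S2));
      fmat dW2 = D1.t() * G2 + wd * W2;
      frowvec db2 = sum(G2, 0);

      fmat G1 = G2 * W2.t();
      G1 %= M1;
      fmat dW1 = Xb.t() * G1 + wd * W1;
      frowvec db1 = sum(G1, 0);

      ++t;
      adam_step(W1, dW1, sW1, lrf, be1, be2, eps, t);
      adam_step(W2, dW2, sW2, lrf, be1, be2, eps, t);
      adam_step(W3, dW3, sW3, lrf, be1, be2, eps, t);
      adam_step(W4, dW4, sW4, lrf, be1, be2, eps, t);
      fmat wb1 = b1, wb2 = b2, wb3 = b3, wb4(1, 1);
      wb4(0, 0) = b4;
      fmat gb1 = db1, gb2 = db2, gb3 = db3, gb4(1, 1);
      gb4(0, 0) = db4;
      adam_step(wb1, gb1, sb1, lrf, be1, be2, eps, t);
      adam_step(wb2, gb2, sb2, lrf, be1, be2, eps, t);
      adam_step(wb3, gb3, sb3, lrf, be1, be2, eps, t);
      adam_step(wb4, gb4, sb4, lrf, be1, be2, eps, t);
      b1 = wb1.row(0);
      b2 = wb2.row(0);
      b3 = wb3.row(0);
      b4 = wb4(0, 0);

      done = bend;
    }
    loss_hist(ep) = ep_loss / (double) n;
  }

  return Rcpp::List::create(
      Rcpp::Named("W1") = conv_to<mat>::from(W1),
      Rcpp::Named("b1") = conv_to<rowvec>::from(b1),
      Rcpp::Named("W2") = conv_to<mat>::from(W2),
      Rcpp::Named("b2") = conv_to<rowvec>::from(b2),
      Rcpp::Named("W3") = conv_to<mat>::from(W3),
      Rcpp::Named("b3") = conv_to<rowvec>::from(b3),
      Rcpp::Named("W4") = conv_to<mat>::from(W4),
      Rcpp::Named("b4") = (double) b4,
      Rcpp::Named("loss") = loss_hist);
}

// forward pass without dropout -> logit per sample (double precision)
// [[Rcpp::export]]
arma::vec nn_forward(const Rcpp::List& w, const arma::mat& X) {
  mat W1 = w["W1"], W2 = w["W2"], W3 = w["W3"], W4 = w["W4"];
  rowvec b1 = w["b1"], b2 = w["b2"], b3 = w["b3"];
  double b4 = w["b4"];
  mat H = X * W1;
  H.each_row() += b1;
  H = H * W2;
  H.each_row() += b2;
  H.transform([](double z) { return z / (1.0 + std::exp(-z)); }); // swish
  H = H * W3;
  H.each_row() += b3;
  H.transform([](double z) { return z / (1.0 + std::exp(-z)); });
  return H * W4 + b4;
}

// gradient of the output logit with respect to every input, one row per
// sample (dropout off) -- the receptive-field primitive
// [[Rcpp::export]]
arma::mat nn_input_grad(const Rcpp::List& w, const arma::mat& X) {
  mat W1 = w["W1"], W2 = w["W2"], W3 = w["W3"], W4 = w["W4"];
  rowvec b1 = w["b1"], b2 = w["b2"], b3 = w["b3"];
  const uword n = X.n_rows;
  mat Z2 = X * W1;
  Z2.each_row() += b1;
  Z2 = Z2 * W2;
  Z2.each_row() += b2;
  mat S2 = 1.0 / (1.0 + exp(-Z2));
  mat Z3 = (Z2 % S2) * W3;
  Z3.each_row() += b3;
  mat S3 = 1.0 / (1.0 + exp(-Z3));

  mat G3 = repmat(W4.t(), n, 1) % (S3 % (1.0 + Z3 % (1.0 - S3)));
  mat G2 = (G3 * W3.t()) % (S2 % (1.0 + Z2 % (1.0 - S2)));
  return (G2 * W2.t()) * W1.t();
}

// Null distribution of the fish-level bootstrap KS test. Drawing whole fish
// with replacement means each bootstrap sample is a weighted multiset of
// the pooled values, so after presorting the pool once (tagging every value
// with its fish), each bootstrap statistic is a single O(N) weighted-ECDF
// walk -- no per-bootstrap sorting. Fish draws use R's RNG.
// [[Rcpp::export]]
arma::vec ks_boot_null(const arma::vec& pooled, const arma::uvec& fish_id,
                       int n_fish, int na, int nb, int n_boot) {
  const uword n = pooled.n_elem;
  uvec ord = stable_sort_index(pooled);
  vec v_sorted(n);
  uvec f_sorted(n);
  for (uword i = 0; i < n; ++i) {
    v_sorted(i) = pooled(ord(i));
    f_sorted(i) = fish_id(ord(i));
  }
  std::vector<double> wa(n_fish), wb(n_fish);
  vec out(n_boot);
  for (int t = 0; t < n_boot; ++t) {
    std::fill(wa.begin(), wa.end(), 0.0);
    std::fill(wb.begin(), wb.end(), 0.0);
    double tot_a = 0.0, tot_b = 0.0;
    for (int k = 0; k < na; ++k) {
      int f = (int) std::floor(R::unif_rand() * n_fish);
      if (f >= n_fish) f = n_fish - 1;
      wa[f] += 1.0;
    }
    for (int k = 0; k < nb; ++k) {
      int f = (int) std::floor(R::unif_rand() * n_fish);
      if (f >= n_fish) f = n_fish - 1;
      wb[f] += 1.0;
    }
    for (uword i = 0; i < n; ++i) {
      tot_a += wa[f_sorted(i)];
      tot_b += wb[f_sorted(i)];
    }
    double cum_a = 0.0, cum_b = 0.0, d = 0.0;
    for (uword i = 0; i < n; ++i) {
      cum_a += wa[f_sorted(i)];
      cum_b += wb[f_sorted(i)];
      if (i + 1 < n && v_sorted(i + 1) == v_sorted(i)) continue; // tie run
      double diff = std::fabs(cum_a / tot_a - cum_b / tot_b);
      if (diff > d) d = diff;
    }
    out(t) = d;
  }
  return out;
}

// two-sample Kolmogorov-Smirnov statistic (sup |ECDF_a - ECDF_b|),
// tie-safe; used inside the fish-level bootstrap where it is called
// hundreds of thousands of times
// [[Rcpp::export]]
double ks_stat_cpp(arma::vec a, arma::vec b) {
  a = sort(a);
  b = sort(b);
  const uword na = a.n_elem, nb = b.n_elem;
  if (na == 0 || nb == 0) Rcpp::stop("empty sample");
  double d = 0.0;
  uword i = 0, j = 0;
  while (i < na && j < nb) {
    double z = std::min(a(i), b(j));
    while (i < na && a(i) <= z) ++i;
    while (j < nb && b(j) <= z) ++j;
    double diff = std::fabs((double) i / na - (double) j / nb);
    if (diff > d) d = diff;
  }
  return d;
}
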