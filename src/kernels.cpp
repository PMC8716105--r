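// Core numerical kernels: Bernoulli release-mask sampling and the
// forward/backward passes of the stochastic-release multilayer network.
//
// All stochasticity flows through a dedicated counter-seeded xoshiro256++
// generator so that a mask drawn for (seed, example) is bit-exact across
// calls and across the fused-batch vs per-example code paths. R-level code
// derives these seeds from R's global RNG.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Xoshiro256pp {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  explicit Xoshiro256pp(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform double in [0, 1), 53-bit resolution
  double unif() { return (next() >> 11) * 0x1.0p-53; }
};

inline uint64_t as_seed(double seed) {
  return static_cast<uint64_t>(seed);
}

// Forward pass for one example; if sample, draws one fresh mask per synapse.
// Masks are stored flat per layer (idx = j * fan_in + i). Returns final
// softmax probabilities in `out`; fills preacts/acts for every layer.
void forward_one(const std::vector<const double*> &m,
                 const std::vector<const double*> &p,
                 const std::vector<int> &sizes,
                 const double *x,
                 bool sample,
                 Xoshiro256pp *rng,
                 std::vector<std::vector<double> > &acts,
                 std::vector<std::vector<double> > &preacts,
                 std::vector<std::vector<unsigned char> > &masks) {
  const int L = static_cast<int>(sizes.size()) - 1;
  acts[0].assign(x, x + sizes[0]);
  for (int l = 0; l < L; ++l) {
    const int nin = sizes[l], nout = sizes[l + 1];
    const double *ml = m[l], *pl = p[l];
    const std::vector<double> &a = acts[l];
    std::vector<double> &z = preacts[l];
    z.assign(nout, 0.0);
    if (sample) {
      std::vector<unsigned char> &r = masks[l];
      r.resize(static_cast<size_t>(nin) * nout);
      for (int j = 0; j < nout; ++j) {
        const double *mj = ml + static_cast<size_t>(j) * nin;
        const double *pj = pl + static_cast<size_t>(j) * nin;
        unsigned char *rj = r.data() + static_cast<size_t>(j) * nin;
        double s = 0.0;
        for (int i = 0; i < nin; ++i) {
          unsigned char ri = rng->unif() < pj[i] ? 1 : 0;
          rj[i] = ri;
          if (ri) s += mj[i] * a[i];
        }
        z[j] = s;
      }
    } else {
      for (int j = 0; j < nout; ++j) {
        const double *mj = ml + static_cast<size_t>(j) * nin;
        const double *pj = pl + static_cast<size_t>(j) * nin;
        double s = 0.0;
        for (int i = 0; i < nin; ++i) s += pj[i] * mj[i] * a[i];
        z[j] = s;
      }
    }
    std::vector<double> &anext = acts[l + 1];
    anext.assign(nout, 0.0);
    if (l < L - 1) {  // rectifier
      for (int j = 0; j < nout; ++j) anext[j] = z[j] > 0.0 ? z[j] : 0.0;
    } else {          // softmax readout
      double zmax = z[0];
      for (int j = 1; j < nout; ++j) if (z[j] > zmax) zmax = z[j];
      double tot = 0.0;
      for (int j = 0; j < nout; ++j) { anext[j] = std::exp(z[j] - zmax); tot += anext[j]; }
      for (int j = 0; j < nout; ++j) anext[j] /= tot;
    }
  }
}

void unpack_net(List ms, List ps,
                std::vector<const double*> &m,
                std::vector<const double*> &p,
                std::vector<int> &sizes) {
  const int L = ms.size();
  m.resize(L); p.resize(L); sizes.resize(L + 1);
  for (int l = 0; l < L; ++l) {
    NumericMatrix mm = ms[l], pm = ps[l];
    m[l] = mm.begin(); p[l] = pm.begin();
    sizes[l] = mm.nrow();
    if (l == L - 1) sizes[L] = mm.ncol();
    if (pm.nrow() != mm.nrow() || pm.ncol() != mm.ncol())
      stop("p and m shapes disagree in layer %d", l + 1);
    if (l > 0 && mm.nrow() != sizes[l]) stop("layer shapes do not compose");
  }
}

} // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_sample_mask(NumericMatrix p, double seed) {
  Xoshiro256pp rng(as_seed(seed));
  const int nr = p.nrow(), nc = p.ncol();
  IntegerMatrix r(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      r(i, j) = rng.unif() < p(i, j) ? 1 : 0;
  return r;
}

// [[Rcpp::export]]
List cpp_forward_example(List ms, List ps, NumericVector x,
                         bool sample, double seed) {
  std::vector<const double*> m, p;
  std::vector<int> sizes;
  unpack_net(ms, ps, m, p, sizes);
  const int L = static_cast<int>(sizes.size()) - 1;
  if (x.size() != sizes[0]) stop("input length does not match first-layer fan-in");

  std::vector<std::vector<double> > acts(L + 1), preacts(L);
  std::vector<std::vector<unsigned char> > masks(L);
  Xoshiro256pp rng(as_seed(seed));
  forward_one(m, p, sizes, x.begin(), sample, &rng, acts, preacts, masks);

  List ra(L + 1), rz(L), rm(L);
  for (int l = 0; l <= L; ++l) ra[l] = NumericVector(acts[l].begin(), acts[l].end());
  for (int l = 0; l < L; ++l) {
    rz[l] = NumericVector(preacts[l].begin(), preacts[l].end());
    if (sample) {
      IntegerMatrix mk(sizes[l], sizes[l + 1]);
      for (size_t k = 0; k < masks[l].size(); ++k) mk[k] = masks[l][k];
      rm[l] = mk;
    }
  }
  return List::create(_["activations"] = ra, _["preactivations"] = rz,
                      _["masks"] = sample ? (SEXP)rm : R_NilValue,
                      _["output"] = ra[L]);
}

// Batch-mean gradient of the cross-entropy loss with respect to the
// *expected* strengths wbar = p*m. In sampled mode the gradient flows
// through the drawn masks (dL/dm uses r, then dL/dwbar = dL/dm / p);
// in expected mode the network is evaluated at wbar directly.
// Optionally accumulates the per-example squared gradient (diagonal
// empirical Fisher). Example e uses RNG seed = seed + e.
// [[Rcpp::export]]
List cpp_batch_grad(List ms, List ps, NumericMatrix X, IntegerVector y,
                    bool sample, double seed, bool want_fisher) {
  std::vector<const double*> m, p;
  std::vector<int> sizes;
  unpack_net(ms, ps, m, p, sizes);
  const int L = static_cast<int>(sizes.size()) - 1;
  const int n = X.nrow();
  if (X.ncol() != sizes[0]) stop("input dimension does not match first-layer fan-in");
  const int ncls = sizes[L];
  for (int e = 0; e < n; ++e)
    if (y[e] < 0 || y[e] >= ncls) stop("label out of range");

  List g(L), gsq(L);
  std::vector<double*> gptr(L), g2ptr(L);
  for (int l = 0; l < L; ++l) {
    NumericMatrix gm(sizes[l], sizes[l + 1]);
    g[l] = gm; gptr[l] = gm.begin();
    if (want_fisher) {
      NumericMatrix g2(sizes[l], sizes[l + 1]);
      gsq[l] = g2; g2ptr[l] = g2.begin();
    }
  }

  std::vector<std::vector<double> > acts(L + 1), preacts(L);
  std::vector<std::vector<unsigned char> > masks(L);
  std::vector<double> xrow(sizes[0]);
  IntegerVector pred(n);
  double loss = 0.0;
  int ncorrect = 0;

  // deltas w.r.t. preactivations, per layer
  std::vector<std::vector<double> > delta(L);
  for (int l = 0; l < L; ++l) delta[l].resize(sizes[l + 1]);

  for (int e = 0; e < n; ++e) {
    for (int i = 0; i < sizes[0]; ++i) xrow[i] = X(e, i);
    Xoshiro256pp rng(as_seed(seed) + static_cast<uint64_t>(e));
    forward_one(m, p, sizes, xrow.data(), sample, &rng, acts, preacts, masks);

    const std::vector<double> &out = acts[L];
    int am = 0;
    for (int j = 1; j < ncls; ++j) if (out[j] > out[am]) am = j;
    pred[e] = am;
    if (am == y[e]) ++ncorrect;
    double py = out[y[e]];
    loss += -std::log(py > 1e-300 ? py : 1e-300);

    std::vector<double> &dl = delta[L - 1];
    for (int j = 0; j < ncls; ++j) dl[j] = out[j] - (j == y[e] ? 1.0 : 0.0);

    for (int l = L - 1; l >= 0; --l) {
      const int nin = sizes[l], nout = sizes[l + 1];
      const std::vector<double> &a = acts[l];
      const std::vector<double> &dj = delta[l];
      std::vector<double> da;
      const bool need_da = l > 0;
      if (need_da) da.assign(nin, 0.0);
      double *gl = gptr[l];
      double *g2l = want_fisher ? g2ptr[l] : 0;
      const double *ml = m[l], *pl = p[l];
      for (int j = 0; j < nout; ++j) {
        const double d = dj[j];
        const size_t off = static_cast<size_t>(j) * nin;
        const double *mj = ml + off, *pj = pl + off;
        double *gj = gl + off;
        if (sample) {
          const unsigned char *rj = masks[l].data() + off;
          for (int i = 0; i < nin; ++i) {
            if (rj[i]) {
              const double ge = d * a[i] / pj[i];  // dL/dwbar = (dL/dm)/p
              gj[i] += ge;
              if (want_fisher) g2l[off + i] += ge * ge;
              if (need_da) da[i] += mj[i] * d;
            }
          }
        } else {
          for (int i = 0; i < nin; ++i) {
            const double ge = d * a[i];
            gj[i] += ge;
            if (want_fisher) g2l[off + i] += ge * ge;
            if (need_da) da[i] += pj[i] * mj[i] * d;
          }
        }
      }
      if (need_da) {
        std::vector<double> &dprev = delta[l - 1];
        const std::vector<double> &zprev = preacts[l - 1];
        for (int i = 0; i < nin; ++i)
          dprev[i] = zprev[i] > 0.0 ? da[i] : 0.0;
      }
    }
  }

  const double inv_n = 1.0 / n;
  for (int l = 0; l < L; ++l) {
    NumericMatrix gm = g[l];
    for (R_xlen_t k = 0; k < gm.size(); ++k) gm[k] *= inv_n;
    if (want_fisher) {
      NumericMatrix g2 = gsq[l];
      for (R_xlen_t k = 0; k < g2.size(); ++k) g2[k] *= inv_n;
    }
  }

  return List::create(_["g"] = g,
                      _["fisher"] = want_fisher ? (SEXP)gsq : R_NilValue,
                      _["loss"] = loss * inv_n,
                      _["accuracy"] = static_cast<double>(ncorrect) * inv_n,
                      _["pred"] = pred);
}

// Class scores for a batch. mode: 0 = expected weights, 1 = sampled release
// averaged over K fresh mask draws. Example e, draw k uses seed + e*K + k.
// [[Rcpp::export]]
NumericMatrix cpp_evaluate_scores(List ms, List ps, NumericMatrix X,
                                  int mode, int K, double seed) {
  std::vector<const double*> m, p;
  std::vector<int> sizes;
  unpack_net(ms, ps, m, p, sizes);
  const int L = static_cast<int>(sizes.size()) - 1;
  const int n = X.nrow(), ncls = sizes[L];
  if (X.ncol() != sizes[0]) stop("input dimension does not match first-layer fan-in");
  if (mode == 1 && K < 1) stop("K must be >= 1");

  NumericMatrix scores(n, ncls);
  std::vector<std::vector<double> > acts(L + 1), preacts(L);
  std::vector<std::vector<unsigned char> > masks(L);
  std::vector<double> xrow(sizes[0]);

  for (int e = 0; e < n; ++e) {
    for (int i = 0; i < sizes[0]; ++i) xrow[i] = X(e, i);
    if (mode == 0) {
      Xoshiro256pp rng(0);
      forward_one(m, p, sizes, xrow.data(), false, &rng, acts, preacts, masks);
      for (int j = 0; j < ncls; ++j) scores(e, j) = acts[L][j];
    } else {
      for (int k = 0; k < K; ++k) {
        Xoshiro256pp rng(as_seed(seed) +
                         static_cast<uint64_t>(e) * static_cast<uint64_t>(K) +
                         static_cast<uint64_t>(k));
        forward_one(m, p, sizes, xrow.data(), true, &rng, acts, preacts, masks);
        for (int j = 0; j < ncls; ++j) scores(e, j) += acts[L][j] / K;
      }
    }
  }
  return scores;
}

// One fused metaplasticity + strength update for a single layer,
// elementwise-identical to update_release_probabilities() followed by
// update_expected_strengths() in R (same operation order per element).
// Returns list(m, p, frozen). `p_learn` is the array the threshold rule
// drives (transmission p, or the ghost array); `p_trans` the transmitting
// probabilities (equal to p_learn except in ghost mode, where they are
// fixed and p_dynamics applies to the ghost array only).
// [[Rcpp::export]]
List cpp_apply_update(NumericMatrix m, NumericMatrix p_learn,
                      NumericMatrix p_trans, LogicalMatrix frozen,
                      NumericMatrix g,
                      double p_up, double p_down, double g_lim,
                      double p_min, double p_freeze, double eta0,
                      bool consolidation, bool p_dynamics, bool ghost) {
  const R_xlen_t n = m.size();
  NumericMatrix m_new(m.nrow(), m.ncol());
  NumericMatrix pl_new(m.nrow(), m.ncol());
  LogicalMatrix fr_new(m.nrow(), m.ncol());

  for (R_xlen_t k = 0; k < n; ++k) {
    const double pl_old = p_learn[k];
    const double pt_old = ghost ? p_trans[k] : pl_old;
    bool fr = frozen[k];
    double pl = pl_old;
    if (p_dynamics && !fr) {
      const double delta = std::abs(g[k]) > g_lim ? p_up : -p_down;
      pl = pl_old + delta;
      if (pl < p_min) pl = p_min;
      if (pl > 1.0) pl = 1.0;
      if (consolidation && pl >= p_freeze) { pl = p_freeze; fr = true; }
    }
    pl_new[k] = pl;
    fr_new[k] = fr;
    const double pt = ghost ? pt_old : pl;        // transmission p after step
    const double eta_eff = consolidation ? eta0 * (1.0 - pl_old) : eta0;
    const double wbar = pt_old * m[k] - eta_eff * g[k];
    m_new[k] = wbar / pt;
  }
  return List::create(_["m"] = m_new, _["p_learn"] = pl_new,
                      _["frozen"] = fr_new,
                      _["p_trans"] = ghost ? (SEXP)p_trans : (SEXP)pl_new);
}
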