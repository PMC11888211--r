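#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// State layout shared with the R side: 0-based index = class*N*K + r*K + k,
// class 0 = non-chimeric (U), class 1 = chimeric (C).
//
// Symbol codes: 0=A 1=C 2=G 3=T. Reference code 4 = gap or N (never matches,
// so a query base opposite it scores m/3). Observation code 4 = neutral
// ('-' or N), emitted with probability 1 by every state.

static inline double emit_p(int refc, int obsc, double m) {
  if (obsc == 4) return 1.0;
  return (refc == obsc) ? (1.0 - m) : (m / 3.0);
}

// Scaled Forward pass with the structured-transition linear recursion.
// Per column the three aggregates (global sum, same-class same-reference sum,
// both-class same-reference sum) are precomputed, so per-column work is O(NK).
// [[Rcpp::export]]
List cpp_forward(const IntegerVector& obs, const IntegerMatrix& refcodes,
                 const NumericMatrix& rates, double psi, double mu,
                 bool keep_alpha = false) {
  const int N = refcodes.nrow(), L = obs.size(), K = rates.ncol();
  if (rates.nrow() != N) stop("rates must have one row per reference");
  if (refcodes.ncol() != L) stop("observation length does not match MSA width");
  const int NK = N * K, S = 2 * NK;
  // with a single reference (or rate class) the corresponding branch is
  // vacuous and its mass folds back into the self transition
  const double stay = 1.0 - ((N > 1) ? psi : 0.0) - ((K > 1) ? mu : 0.0);
  const double muc = (K > 1) ? mu / (K - 1) : 0.0;
  const double psic = (N > 1) ? psi / ((double)(N - 1) * K) : 0.0;

  std::vector<double> a(S, 0.0), anew(S, 0.0);
  std::vector<double> Scls(2 * N), Sstar(N);
  NumericVector scales(L);
  NumericMatrix alpha;
  if (keep_alpha) alpha = NumericMatrix(L, S);
  double logev = 0.0, nops = 0.0;

  double c = 0.0;
  for (int r = 0; r < N; ++r) {
    const int refc = refcodes(r, 0);
    for (int k = 0; k < K; ++k) {
      a[r * K + k] = emit_p(refc, obs[0], rates(r, k)) / NK;
      a[NK + r * K + k] = 0.0;
      c += a[r * K + k];
      nops += 1.0;
    }
  }
  if (c <= 0.0)
    stop("forward pass degenerate: zero total likelihood at column 1");
  for (int i = 0; i < S; ++i) a[i] /= c;
  scales[0] = c;
  logev = std::log(c);
  if (keep_alpha) for (int i = 0; i < S; ++i) alpha(0, i) = a[i];

  for (int t = 1; t < L; ++t) {
    double total = 0.0;
    for (int cls = 0; cls < 2; ++cls)
      for (int r = 0; r < N; ++r) {
        const int base = cls * NK + r * K;
        double s = 0.0;
        for (int k = 0; k < K; ++k) s += a[base + k];
        Scls[cls * N + r] = s;
        total += s;
      }
    for (int r = 0; r < N; ++r) Sstar[r] = Scls[r] + Scls[N + r];

    c = 0.0;
    for (int cls = 0; cls < 2; ++cls)
      for (int r = 0; r < N; ++r) {
        const int base = cls * NK + r * K;
        const double same = Scls[cls * N + r];
        const double cross = (cls == 1) ? (total - Sstar[r]) * psic : 0.0;
        const int refc = refcodes(r, t);
        for (int k = 0; k < K; ++k) {
          const int j = base + k;
          const double pre = a[j] * stay + (same - a[j]) * muc + cross;
          anew[j] = pre * emit_p(refc, obs[t], rates(r, k));
          c += anew[j];
          nops += 1.0;
        }
      }
    if (c <= 0.0)
      stop("forward pass degenerate: zero total likelihood at column %d", t + 1);
    for (int i = 0; i < S; ++i) a[i] = anew[i] / c;
    scales[t] = c;
    logev += std::log(c);
    if (keep_alpha) for (int i = 0; i < S; ++i) alpha(t, i) = a[i];
  }

  double post = 0.0;
  for (int i = NK; i < S; ++i) post += a[i];
  if (post < 0.0) post = 0.0;
  if (post > 1.0) post = 1.0;
  List out = List::create(
      _["log_evidence"] = logev,
      _["log_chimeric_mass"] = (post > 0.0) ? logev + std::log(post) : R_NegInf,
      _["posterior"] = post,
      _["scale_factors"] = scales,
      _["n_ops"] = nops);
  if (keep_alpha) out["alpha"] = alpha;
  return out;
}

// [[Rcpp::export]]
List cpp_forward_batch(const IntegerMatrix& obsmat, const IntegerMatrix& refcodes,
                       const NumericMatrix& rates, double psi, double mu) {
  const int nq = obsmat.ncol();
  NumericVector post(nq), logev(nq);
  for (int q = 0; q < nq; ++q) {
    if (q % 256 == 0) Rcpp::checkUserInterrupt();
    List r = cpp_forward(obsmat(_, q), refcodes, rates, psi, mu, false);
    post[q] = as<double>(r["posterior"]);
    logev[q] = as<double>(r["log_evidence"]);
  }
  return List::create(_["posterior"] = post, _["log_evidence"] = logev);
}

// Scaled backward pass, consistent with the forward scale factors, so that
// sum_i alpha_hat_t(i) * beta_hat_t(i) == 1 at every column.
// [[Rcpp::export]]
NumericMatrix cpp_backward(const IntegerVector& obs, const IntegerMatrix& refcodes,
                           const NumericMatrix& rates, double psi, double mu,
                           const NumericVector& scales) {
  const int N = refcodes.nrow(), L = obs.size(), K = rates.ncol();
  const int NK = N * K, S = 2 * NK;
  const double stay = 1.0 - ((N > 1) ? psi : 0.0) - ((K > 1) ? mu : 0.0);
  const double muc = (K > 1) ? mu / (K - 1) : 0.0;
  const double psic = (N > 1) ? psi / ((double)(N - 1) * K) : 0.0;

  NumericMatrix beta(L, S);
  std::vector<double> w(S), Wcls(2 * N);
  for (int i = 0; i < S; ++i) beta(L - 1, i) = 1.0;

  for (int t = L - 2; t >= 0; --t) {
    double WCtotal = 0.0;
    for (int cls = 0; cls < 2; ++cls)
      for (int r = 0; r < N; ++r) {
        const int base = cls * NK + r * K;
        const int refc = refcodes(r, t + 1);
        double s = 0.0;
        for (int k = 0; k < K; ++k) {
          w[base + k] = emit_p(refc, obs[t + 1], rates(r, k)) * beta(t + 1, base + k);
          s += w[base + k];
        }
        Wcls[cls * N + r] = s;
        if (cls == 1) WCtotal += s;
      }
    const double ct1 = scales[t + 1];
    for (int cls = 0; cls < 2; ++cls)
      for (int r = 0; r < N; ++r) {
        const int base = cls * NK + r * K;
        const double same = Wcls[cls * N + r];
        // outgoing chimeric mass: into C states of every other reference
        const double cross = (WCtotal - Wcls[N + r]) * psic;
        for (int k = 0; k < K; ++k) {
          const int i = base + k;
          beta(t, i) = (w[i] * stay + (same - w[i]) * muc + cross) / ct1;
        }
      }
  }
  return beta;
}

// Fused E-step for the Baum-Welch (K==1, two states per reference) variant:
// forward + backward + posterior state occupancies, accumulating per-reference
// expected mismatch and informative-emission counts over all queries.
// [[Rcpp::export]]
List cpp_bw_estep(const IntegerMatrix& obsmat, const IntegerMatrix& refcodes,
                  const NumericVector& rates, double psi) {
  const int N = refcodes.nrow(), L = refcodes.ncol(), nq = obsmat.ncol();
  if (obsmat.nrow() != L) stop("observation length does not match MSA width");
  if (rates.size() != N) stop("need one rate per reference");
  const int S = 2 * N;
  const double stay = 1.0 - ((N > 1) ? psi : 0.0);
  const double psic = (N > 1) ? psi / (double)(N - 1) : 0.0;

  NumericVector mism(N), emis(N), post(nq);
  double loglik = 0.0;
  std::vector<double> alpha((size_t)L * S), scales(L), a(S), anew(S),
      beta(S), betanew(S), w(S), gam(S);

  for (int q = 0; q < nq; ++q) {
    if (q % 64 == 0) Rcpp::checkUserInterrupt();
    // forward
    double c = 0.0;
    for (int r = 0; r < N; ++r) {
      a[r] = emit_p(refcodes(r, 0), obsmat(0, q), rates[r]) / N;
      a[N + r] = 0.0;
      c += a[r];
    }
    if (c <= 0.0) stop("forward pass degenerate: zero total likelihood at column 1");
    for (int i = 0; i < S; ++i) { a[i] /= c; alpha[i] = a[i]; }
    scales[0] = c;
    double lev = std::log(c);
    for (int t = 1; t < L; ++t) {
      double total = 0.0;
      for (int i = 0; i < S; ++i) total += a[i];
      c = 0.0;
      for (int r = 0; r < N; ++r) {
        const double sstar = a[r] + a[N + r];
        const double b = emit_p(refcodes(r, t), obsmat(t, q), rates[r]);
        anew[r] = a[r] * stay * b;
        anew[N + r] = (a[N + r] * stay + (total - sstar) * psic) * b;
        c += anew[r] + anew[N + r];
      }
      if (c <= 0.0)
        stop("forward pass degenerate: zero total likelihood at column %d", t + 1);
      for (int i = 0; i < S; ++i) { a[i] = anew[i] / c; alpha[(size_t)t * S + i] = a[i]; }
      scales[t] = c;
      lev += std::log(c);
    }
    double p = 0.0;
    for (int r = 0; r < N; ++r) p += a[N + r];
    if (p < 0.0) p = 0.0;
    if (p > 1.0) p = 1.0;
    post[q] = p;
    loglik += lev;

    // backward + occupancy accumulation
    for (int i = 0; i < S; ++i) beta[i] = 1.0;
    for (int t = L - 1; t >= 0; --t) {
      double gs = 0.0;
      for (int i = 0; i < S; ++i) {
        gam[i] = alpha[(size_t)t * S + i] * beta[i];
        gs += gam[i];
      }
      const int obsc = obsmat(t, q);
      if (obsc != 4 && gs > 0.0) {
        for (int r = 0; r < N; ++r) {
          const double g = (gam[r] + gam[N + r]) / gs;
          emis[r] += g;
          if (refcodes(r, t) != obsc) mism[r] += g;
        }
      }
      if (t == 0) break;
      // beta at t-1 from beta at t
      double WCtotal = 0.0;
      for (int r = 0; r < N; ++r) {
        const double b = emit_p(refcodes(r, t), obsmat(t, q), rates[r]);
        w[r] = b * beta[r];
        w[N + r] = b * beta[N + r];
        WCtotal += w[N + r];
      }
      const double ct = scales[t];
      for (int r = 0; r < N; ++r) {
        const double cross = (WCtotal - w[N + r]) * psic;
        betanew[r] = (w[r] * stay + cross) / ct;
        betanew[N + r] = (w[N + r] * stay + cross) / ct;
      }
      beta = betanew;
    }
  }
  return List::create(_["mismatches"] = mism, _["emissions"] = emis,
                      _["loglik"] = loglik, _["posteriors"] = post);
}

// Log-space Viterbi with the same aggregate trick (max instead of sum).
// Ties between predecessors are broken toward the lowest state index, which
// matches a dense argmax scanned in ascending state order.
// [[Rcpp::export]]
List cpp_viterbi(const IntegerVector& obs, const IntegerMatrix& refcodes,
                 const NumericMatrix& rates, double psi, double mu) {
  const int N = refcodes.nrow(), L = obs.size(), K = rates.ncol();
  const int NK = N * K, S = 2 * NK;
  const double lstay =
      std::log(1.0 - ((N > 1) ? psi : 0.0) - ((K > 1) ? mu : 0.0));
  const bool has_mu = (K > 1 && mu > 0.0);
  const bool has_psi = (N > 1 && psi > 0.0);
  const double lmu = has_mu ? std::log(mu / (K - 1)) : R_NegInf;
  const double lpsi = has_psi ? std::log(psi / ((double)(N - 1) * K)) : R_NegInf;

  std::vector<double> d(S), dnew(S);
  IntegerMatrix bp(L, S);

  for (int r = 0; r < N; ++r) {
    const int refc = refcodes(r, 0);
    for (int k = 0; k < K; ++k) {
      const double b = emit_p(refc, obs[0], rates(r, k));
      d[r * K + k] = (b > 0.0) ? -std::log((double)NK) + std::log(b) : R_NegInf;
      d[NK + r * K + k] = R_NegInf;
      bp(0, r * K + k) = -1;
      bp(0, NK + r * K + k) = -1;
    }
  }

  std::vector<double> g1v(2 * N), g2v(2 * N);
  std::vector<int> g1i(2 * N), g2i(2 * N);

  for (int t = 1; t < L; ++t) {
    // top-2 per (class, reference) group over rate classes, first-max ties
    for (int g = 0; g < 2 * N; ++g) {
      g1v[g] = g2v[g] = R_NegInf;
      g1i[g] = g2i[g] = -1;
    }
    // global best pair over distinct references (any class, any rate)
    double b1v = R_NegInf, b2v = R_NegInf;
    int b1i = -1, b2i = -1, b1r = -1;
    for (int i = 0; i < S; ++i) {
      const int rem = i % NK;
      const int r = rem / K;
      const int cls = i / NK;
      const int g = cls * N + r;
      const double v = d[i];
      if (v > g1v[g]) { g2v[g] = g1v[g]; g2i[g] = g1i[g]; g1v[g] = v; g1i[g] = i; }
      else if (v > g2v[g]) { g2v[g] = v; g2i[g] = i; }
      if (v > b1v) {
        if (r != b1r) { b2v = b1v; b2i = b1i; }
        b1v = v; b1i = i; b1r = r;
      } else if (r != b1r && v > b2v) {
        b2v = v; b2i = i;
      }
    }
    for (int cls = 0; cls < 2; ++cls)
      for (int r = 0; r < N; ++r) {
        const int base = cls * NK + r * K;
        const int g = cls * N + r;
        const int refc = refcodes(r, t);
        for (int k = 0; k < K; ++k) {
          const int j = base + k;
          double bestv = d[j] + lstay;
          int besti = j;
          if (has_mu) {
            const double cv = (g1i[g] == j) ? g2v[g] : g1v[g];
            const int ci = (g1i[g] == j) ? g2i[g] : g1i[g];
            if (ci >= 0) {
              const double v = cv + lmu;
              if (v > bestv || (v == bestv && ci < besti)) { bestv = v; besti = ci; }
            }
          }
          if (cls == 1 && has_psi) {
            const double cv = (b1r != r) ? b1v : b2v;
            const int ci = (b1r != r) ? b1i : b2i;
            if (ci >= 0) {
              const double v = cv + lpsi;
              if (v > bestv || (v == bestv && ci < besti)) { bestv = v; besti = ci; }
            }
          }
          const double b = emit_p(refc, obs[t], rates(r, k));
          dnew[j] = (b > 0.0 && bestv > R_NegInf) ? bestv + std::log(b) : R_NegInf;
          bp(t, j) = besti;
        }
      }
    d = dnew;
  }

  double bestv = R_NegInf;
  int best = -1;
  for (int i = 0; i < S; ++i)
    if (d[i] > bestv) { bestv = d[i]; best = i; }
  if (best < 0)
    stop("viterbi degenerate: no path with nonzero probability");

  IntegerVector path(L);
  int cur = best;
  for (int t = L - 1; t >= 0; --t) {
    path[t] = cur + 1;  // 1-based for R
    cur = bp(t, cur);
  }
  return List::create(_["path"] = path, _["log_path_prob"] = bestv);
}
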