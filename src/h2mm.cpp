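// Photon-by-photon HMM engine.
//
// Observations are photon stream indices; between consecutive photons the
// hidden chain advances by the integer inter-photon gap (in clock ticks),
// so the effective transition kernel between photons i-1 and i is A^dt.
// The E-step must also account for transitions occurring during the
// unobserved ticks inside each gap; those expectations are accumulated
// exactly with a doubling recursion (see count_tensor_sum below), never by
// expanding the chain tick-by-tick.
//
// The hot paths run on flat row-major buffers with a dense per-photon gap
// index (built once per call): q is small (<= ~8) while T reaches 1e5-1e6,
// so per-photon allocation, not arithmetic, is what must be avoided.

#include <RcppArmadillo.h>
#include <unordered_map>
#include <vector>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

typedef std::vector<double> dvec;

// C = A * B, q x q row-major
static inline void matmul(const double* A, const double* B, double* C, int q) {
  for (int i = 0; i < q; ++i) {
    for (int j = 0; j < q; ++j) C[i * q + j] = 0.0;
    for (int k = 0; k < q; ++k) {
      const double a = A[i * q + k];
      if (a == 0.0) continue;
      const double* Bk = B + k * q;
      double* Ci = C + i * q;
      for (int j = 0; j < q; ++j) Ci[j] += a * Bk[j];
    }
  }
}

struct GapTable {
  std::vector<long> values;          // distinct gaps, ascending
  std::vector<int> photon_gap_id;    // per photon; -1 for gap 0 / burst start
};

static GapTable build_gap_table(const NumericVector& gaps,
                                const IntegerVector& lens) {
  GapTable gt;
  gt.photon_gap_id.assign(gaps.size(), -1);
  std::unordered_map<long, int> idx;
  int off = 0;
  for (int b = 0; b < lens.size(); ++b) {
    for (int i = 1; i < lens[b]; ++i) {
      long d = (long)gaps[off + i];
      if (d <= 0) continue;
      auto it = idx.find(d);
      if (it == idx.end()) {
        it = idx.emplace(d, (int)gt.values.size()).first;
        gt.values.push_back(d);
      }
      gt.photon_gap_id[off + i] = it->second;
    }
    off += lens[b];
  }
  return gt;
}

// powers[g] = A^values[g] (row-major), by binary exponentiation from the
// squared powers A^(2^k)
static std::vector<dvec> gap_powers(const double* A, int q,
                                    const std::vector<long>& values) {
  std::vector<dvec> out(values.size());
  long maxd = 1;
  for (long v : values) if (v > maxd) maxd = v;
  std::vector<dvec> pow2;
  pow2.push_back(dvec(A, A + q * q));
  while ((1L << (pow2.size() - 1)) < maxd) {
    dvec nxt(q * q);
    matmul(pow2.back().data(), pow2.back().data(), nxt.data(), q);
    pow2.push_back(std::move(nxt));
  }
  dvec tmp(q * q);
  for (size_t g = 0; g < values.size(); ++g) {
    long d = values[g];
    dvec acc;
    int k = 0;
    while (d > 0) {
      if (d & 1L) {
        if (acc.empty()) acc = pow2[k];
        else {
          matmul(acc.data(), pow2[k].data(), tmp.data(), q);
          acc.swap(tmp);
        }
      }
      d >>= 1; ++k;
    }
    out[g] = std::move(acc);
  }
  return out;
}

// S(d) = sum_{tau=0}^{d-1} P^tau U P^(d-1-tau) by the doubling composition
// S(d1+d2) = S(d1) P^d2 + P^d1 S(d2). With P = A^T and U the accumulated
// pairwise weights for gap d, the expected number of k->l transitions
// inside all gaps of length d is A_kl * S(d)[k,l].
static void count_tensor_sum(const double* P, const double* U, long d, int q,
                             double* S) {
  int hi = 63;
  while (hi > 0 && !((d >> hi) & 1L)) --hi;
  dvec Pacc(P, P + q * q), t1(q * q), t2(q * q), Sv(U, U + q * q);
  for (int b = hi - 1; b >= 0; --b) {
    // double: S <- S*Pacc + Pacc*S ; Pacc <- Pacc^2
    matmul(Sv.data(), Pacc.data(), t1.data(), q);
    matmul(Pacc.data(), Sv.data(), t2.data(), q);
    for (int i = 0; i < q * q; ++i) Sv[i] = t1[i] + t2[i];
    matmul(Pacc.data(), Pacc.data(), t1.data(), q);
    Pacc.swap(t1);
    if ((d >> b) & 1L) {  // append one: S <- S*P + Pacc*U ; Pacc <- Pacc*P
      matmul(Sv.data(), P, t1.data(), q);
      matmul(Pacc.data(), U, t2.data(), q);
      for (int i = 0; i < q * q; ++i) Sv[i] = t1[i] + t2[i];
      matmul(Pacc.data(), P, t1.data(), q);
      Pacc.swap(t1);
    }
  }
  std::copy(Sv.begin(), Sv.end(), S);
}

struct EStepResult {
  double loglik = 0.0;
  bool finite = true;
  dvec prior_counts, trans_counts, emis_counts, gamma, burst_loglik;
};

// Scaled forward-backward over flattened bursts. streams: 0-based stream
// per photon; gaps: ticks since the previous photon (first photon of each
// burst carries 0); lens: photons per burst.
static EStepResult fb_estep(const arma::vec& prior, const arma::mat& trans,
                            const arma::mat& emis, const IntegerVector& streams,
                            const NumericVector& gaps, const IntegerVector& lens,
                            bool want_gamma, bool want_counts,
                            const GapTable& gt) {
  const int q = trans.n_rows, r = emis.n_cols;
  const int Ttot = streams.size(), nb = lens.size();
  EStepResult res;
  res.prior_counts.assign(q, 0.0);
  res.trans_counts.assign(q * q, 0.0);
  res.emis_counts.assign(q * r, 0.0);
  res.burst_loglik.assign(nb, 0.0);
  if (want_gamma) res.gamma.assign((size_t)Ttot * q, 0.0);

  // row-major copies
  dvec A(q * q), B(q * r), pri(q);
  for (int i = 0; i < q; ++i) {
    pri[i] = prior[i];
    for (int j = 0; j < q; ++j) A[i * q + j] = trans(i, j);
    for (int k = 0; k < r; ++k) B[i * r + k] = emis(i, k);
  }

  std::vector<dvec> Ad = gap_powers(A.data(), q, gt.values);
  std::vector<dvec> U;
  std::vector<char> Uused(gt.values.size(), 0);
  if (want_counts) U.assign(gt.values.size(), dvec());

  dvec alpha((size_t)Ttot * q), cs(Ttot), beta(q), beta_new(q), w(q);
  int off = 0;
  for (int b = 0; b < nb; ++b) {
    const int T = lens[b];
    // forward
    for (int i = 0; i < T; ++i) {
      const double* brow = B.data() + 0;
      const int y = streams[off + i];
      double* ai = alpha.data() + (size_t)(off + i) * q;
      if (i == 0) {
        for (int s = 0; s < q; ++s) ai[s] = pri[s] * B[s * r + y];
      } else {
        const int gid = gt.photon_gap_id[off + i];
        const double* ap = alpha.data() + (size_t)(off + i - 1) * q;
        if (gid < 0) {  // zero gap: identity propagation
          for (int s = 0; s < q; ++s) ai[s] = ap[s] * B[s * r + y];
        } else {
          const double* M = Ad[gid].data();
          for (int s = 0; s < q; ++s) {
            double acc = 0.0;
            for (int a = 0; a < q; ++a) acc += ap[a] * M[a * q + s];
            ai[s] = acc * B[s * r + y];
          }
        }
      }
      double c = 0.0;
      for (int s = 0; s < q; ++s) c += ai[s];
      if (!(c > 0.0) || !std::isfinite(c)) {
        res.finite = false;
        res.loglik = R_NegInf;
        return res;
      }
      const double inv = 1.0 / c;
      for (int s = 0; s < q; ++s) ai[s] *= inv;
      cs[off + i] = c;
      const double lc = std::log(c);
      res.loglik += lc;
      res.burst_loglik[b] += lc;
      (void)brow;
    }
    if (want_counts || want_gamma) {
      // backward, accumulating gamma / pairwise xi weights on the fly
      for (int s = 0; s < q; ++s) beta[s] = 1.0;
      for (int i = T - 1; i >= 0; --i) {
        const double* ai = alpha.data() + (size_t)(off + i) * q;
        const int y = streams[off + i];
        if (want_gamma) {
          double* gi = res.gamma.data() + (size_t)(off + i) * q;
          for (int s = 0; s < q; ++s) gi[s] = ai[s] * beta[s];
        }
        if (want_counts) {
          for (int s = 0; s < q; ++s) {
            const double g = ai[s] * beta[s];
            res.emis_counts[s * r + y] += g;
            if (i == 0) res.prior_counts[s] += g;
          }
        }
        if (i > 0) {
          const double invc = 1.0 / cs[off + i];
          for (int s = 0; s < q; ++s) w[s] = B[s * r + y] * beta[s] * invc;
          const int gid = gt.photon_gap_id[off + i];
          const double* ap = alpha.data() + (size_t)(off + i - 1) * q;
          if (gid < 0) {
            for (int s = 0; s < q; ++s) beta[s] = w[s];
          } else {
            if (want_counts) {
              // U_d(a,b) += alpha_{i-1}(a) * w(b); xi_ab = U_ab * (A^d)_ab
              if (!Uused[gid]) { U[gid].assign(q * q, 0.0); Uused[gid] = 1; }
              double* Ug = U[gid].data();
              for (int a = 0; a < q; ++a) {
                const double av = ap[a];
                for (int s = 0; s < q; ++s) Ug[a * q + s] += av * w[s];
              }
            }
            const double* M = Ad[gid].data();
            for (int a = 0; a < q; ++a) {
              double acc = 0.0;
              const double* Ma = M + a * q;
              for (int s = 0; s < q; ++s) acc += Ma[s] * w[s];
              beta_new[a] = acc;
            }
            beta.swap(beta_new);
          }
        }
      }
    }
    off += T;
  }

  if (want_counts) {
    dvec P(q * q), S(q * q);
    for (int i = 0; i < q; ++i)
      for (int j = 0; j < q; ++j) P[i * q + j] = A[j * q + i];
    for (size_t g = 0; g < gt.values.size(); ++g) {
      if (!Uused[g]) continue;
      count_tensor_sum(P.data(), U[g].data(), gt.values[g], q, S.data());
      for (int i = 0; i < q * q; ++i) res.trans_counts[i] += A[i] * S[i];
    }
  }
  return res;
}

// [[Rcpp::export]]
List cpp_forward_backward(arma::vec prior, arma::mat trans, arma::mat emis,
                          IntegerVector streams, NumericVector gaps,
                          IntegerVector lens, bool want_gamma = true) {
  const int q = trans.n_rows, r = emis.n_cols;
  EStepResult res = fb_estep(prior, trans, emis, streams, gaps, lens,
                             want_gamma, true, build_gap_table(gaps, lens));
  NumericMatrix tc(q, q), ec(q, r);
  NumericVector pc(q);
  if (res.finite) {
    for (int i = 0; i < q; ++i) {
      pc[i] = res.prior_counts[i];
      for (int j = 0; j < q; ++j) tc(i, j) = res.trans_counts[i * q + j];
      for (int k = 0; k < r; ++k) ec(i, k) = res.emis_counts[i * r + k];
    }
  }
  SEXP gma = R_NilValue;
  if (want_gamma && res.finite) {
    NumericMatrix G(streams.size(), q);
    for (int i = 0; i < streams.size(); ++i)
      for (int s = 0; s < q; ++s) G(i, s) = res.gamma[(size_t)i * q + s];
    gma = G;
  }
  return List::create(
    _["loglik"] = res.loglik, _["finite"] = res.finite,
    _["burst_loglik"] = NumericVector(res.burst_loglik.begin(),
                                      res.burst_loglik.end()),
    _["prior_counts"] = pc, _["trans_counts"] = tc, _["emis_counts"] = ec,
    _["gamma"] = gma);
}

// [[Rcpp::export]]
double cpp_loglik(arma::vec prior, arma::mat trans, arma::mat emis,
                  IntegerVector streams, NumericVector gaps,
                  IntegerVector lens) {
  EStepResult res = fb_estep(prior, trans, emis, streams, gaps, lens,
                             false, false, build_gap_table(gaps, lens));
  return res.loglik;
}

// One Baum-Welch step; returns the re-estimated model and the
// log-likelihood of the INPUT model. Starved rows are kept unchanged.
// [[Rcpp::export]]
List cpp_em_step(arma::vec prior, arma::mat trans, arma::mat emis,
                 IntegerVector streams, NumericVector gaps,
                 IntegerVector lens) {
  const int q = trans.n_rows, r = emis.n_cols;
  EStepResult res = fb_estep(prior, trans, emis, streams, gaps, lens,
                             false, true, build_gap_table(gaps, lens));
  LogicalVector starved(q);
  if (!res.finite)
    return List::create(_["prior"] = prior, _["trans"] = trans,
                        _["emis"] = emis, _["loglik"] = res.loglik,
                        _["finite"] = false, _["starved"] = starved);
  double psum = 0.0;
  for (int i = 0; i < q; ++i) psum += res.prior_counts[i];
  NumericVector pnew(q);
  NumericMatrix tnew(q, q), enew(q, r);
  for (int i = 0; i < q; ++i) {
    pnew[i] = res.prior_counts[i] / psum;
    double ts = 0.0, es = 0.0;
    for (int j = 0; j < q; ++j) ts += res.trans_counts[i * q + j];
    for (int k = 0; k < r; ++k) es += res.emis_counts[i * r + k];
    for (int j = 0; j < q; ++j)
      tnew(i, j) = ts > 1e-12 ? res.trans_counts[i * q + j] / ts
                              : trans(i, j);
    for (int k = 0; k < r; ++k)
      enew(i, k) = es > 1e-12 ? res.emis_counts[i * r + k] / es
                              : emis(i, k);
    if (es <= 1e-12) starved[i] = true;
  }
  return List::create(_["prior"] = pnew, _["trans"] = tnew,
                      _["emis"] = enew, _["loglik"] = res.loglik,
                      _["finite"] = true, _["starved"] = starved);
}

// Full EM loop: iterate Baum-Welch steps until the absolute log-likelihood
// improvement drops below tol or max_iter is reached. Returns the final
// model, the log-likelihood trace (of each visited model, final model
// included) and convergence bookkeeping. Mirrors repeated cpp_em_step
// calls exactly, with the per-call setup amortized.
// [[Rcpp::export]]
List cpp_em_run(arma::vec prior, arma::mat trans, arma::mat emis,
                IntegerVector streams, NumericVector gaps,
                IntegerVector lens, int max_iter, double tol) {
  const int q = trans.n_rows, r = emis.n_cols;
  GapTable gt = build_gap_table(gaps, lens);
  std::vector<double> trace;
  bool converged = false, any_starved = false;
  int iter = 0;
  double ll_prev = NA_REAL;
  while (iter < max_iter) {
    EStepResult res = fb_estep(prior, trans, emis, streams, gaps, lens,
                               false, true, gt);
    if (!res.finite)
      return List::create(_["finite"] = false, _["loglik"] = res.loglik,
                          _["prior"] = prior, _["trans"] = trans,
                          _["emis"] = emis);
    trace.push_back(res.loglik);
    double psum = 0.0;
    for (int i = 0; i < q; ++i) psum += res.prior_counts[i];
    for (int i = 0; i < q; ++i) {
      prior[i] = res.prior_counts[i] / psum;
      double ts = 0.0, es = 0.0;
      for (int j = 0; j < q; ++j) ts += res.trans_counts[i * q + j];
      for (int k = 0; k < r; ++k) es += res.emis_counts[i * r + k];
      if (ts > 1e-12)
        for (int j = 0; j < q; ++j) trans(i, j) = res.trans_counts[i * q + j] / ts;
      if (es > 1e-12)
        for (int k = 0; k < r; ++k) emis(i, k) = res.emis_counts[i * r + k] / es;
      else any_starved = true;
    }
    ++iter;
    if (!ISNA(ll_prev) && std::fabs(res.loglik - ll_prev) < tol) {
      converged = true;
      break;
    }
    ll_prev = res.loglik;
  }
  EStepResult fin = fb_estep(prior, trans, emis, streams, gaps, lens,
                             false, false, gt);
  trace.push_back(fin.loglik);
  return List::create(_["finite"] = fin.finite, _["loglik"] = fin.loglik,
                      _["prior"] = prior, _["trans"] = trans,
                      _["emis"] = emis,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["converged"] = converged, _["niter"] = iter,
                      _["starved"] = any_starved);
}

// Viterbi decoding with A^dt gap factors, in log space.
// [[Rcpp::export]]
List cpp_viterbi(arma::vec prior, arma::mat trans, arma::mat emis,
                 IntegerVector streams, NumericVector gaps,
                 IntegerVector lens) {
  const int q = trans.n_rows, r = emis.n_cols;
  const int Ttot = streams.size(), nb = lens.size();
  IntegerVector path(Ttot);
  NumericVector burst_logpost(nb);
  double total = 0.0;

  dvec A(q * q), logB(q * r), logpri(q);
  for (int i = 0; i < q; ++i) {
    logpri[i] = std::log(prior[i]);
    for (int j = 0; j < q; ++j) A[i * q + j] = trans(i, j);
    for (int k = 0; k < r; ++k) logB[i * r + k] = std::log(emis(i, k));
  }
  GapTable gt = build_gap_table(gaps, lens);
  std::vector<dvec> Ad = gap_powers(A.data(), q, gt.values);
  for (auto& M : Ad)
    for (double& v : M) v = std::log(v);

  dvec delta((size_t)Ttot * q), dprev(q);
  std::vector<int> back((size_t)Ttot * q);
  int off = 0;
  for (int b = 0; b < nb; ++b) {
    const int T = lens[b];
    for (int i = 0; i < T; ++i) {
      const int y = streams[off + i];
      double* di = delta.data() + (size_t)(off + i) * q;
      if (i == 0) {
        for (int s = 0; s < q; ++s) di[s] = logpri[s] + logB[s * r + y];
      } else {
        const double* dp = delta.data() + (size_t)(off + i - 1) * q;
        const int gid = gt.photon_gap_id[off + i];
        int* bi = back.data() + (size_t)(off + i) * q;
        if (gid < 0) {  // zero gap: log A^0 = log I (diagonal path only)
          for (int s = 0; s < q; ++s) {
            di[s] = dp[s] + logB[s * r + y];
            bi[s] = s;
          }
        } else {
          const double* M = Ad[gid].data();
          for (int s = 0; s < q; ++s) {
            double best = R_NegInf;
            int arg = 0;
            for (int a = 0; a < q; ++a) {
              const double v = dp[a] + M[a * q + s];
              if (v > best) { best = v; arg = a; }
            }
            di[s] = best + logB[s * r + y];
            bi[s] = arg;
          }
        }
      }
    }
    const double* dl = delta.data() + (size_t)(off + T - 1) * q;
    int s = 0;
    for (int k = 1; k < q; ++k) if (dl[k] > dl[s]) s = k;
    burst_logpost[b] = dl[s];
    total += dl[s];
    for (int i = T - 1; i >= 0; --i) {
      path[off + i] = s;
      if (i > 0) s = back[(size_t)(off + i) * q + s];
    }
    off += T;
  }
  return List::create(_["path"] = path, _["logpost"] = total,
                      _["burst_logpost"] = burst_logpost);
}

// Exact d-th power of the per-tick transition matrix.
// [[Rcpp::export]]
arma::mat cpp_transition_power(arma::mat trans, double dt) {
  const int q = trans.n_rows;
  if (dt == 0) return arma::eye(q, q);
  dvec A(q * q);
  for (int i = 0; i < q; ++i)
    for (int j = 0; j < q; ++j) A[i * q + j] = trans(i, j);
  std::vector<long> vals(1, (long)dt);
  std::vector<dvec> P = gap_powers(A.data(), q, vals);
  arma::mat out(q, q);
  for (int i = 0; i < q; ++i)
    for (int j = 0; j < q; ++j) out(i, j) = P[0][i * q + j];
  return out;
}
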