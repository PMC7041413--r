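#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---- small helpers -------------------------------------------------------

// nearest grid index for x in [0,1], round half up, clamped to 1..n
static inline int encode_idx(double x, int n) {
  int a = (int)std::floor(x * n + 0.5);
  if (a < 1) a = 1;
  if (a > n) a = n;
  return a;
}

// sorted 1-based axis interval [a-k/2, a+k/2], clamped or wrapped
static std::vector<int> axis_interval(int a, int k, int n, bool circular) {
  int h = k / 2;
  std::vector<int> out;
  if (circular) {
    if (2 * h + 1 >= n) {
      out.resize(n);
      for (int j = 0; j < n; ++j) out[j] = j + 1;
      return out;
    }
    out.reserve(2 * h + 1);
    for (int j = a - h; j <= a + h; ++j) {
      int w = ((j - 1) % n + n) % n + 1;
      out.push_back(w);
    }
    std::sort(out.begin(), out.end());
  } else {
    int lo = std::max(1, a - h), hi = std::min(n, a + h);
    out.reserve(hi - lo + 1);
    for (int j = lo; j <= hi; ++j) out.push_back(j);
  }
  return out;
}

// membership of axis index j in the width-k window centred at b
static inline bool in_window(int j, int b, int h, int n, bool circular) {
  if (circular) {
    int d = ((j - b) % n + n) % n;  // 0..n-1
    return d <= h || d >= n - h;
  }
  return j >= b - h && j <= b + h;
}

// window sums along every axis of a flat (column-major) d-dim array,
// window half-width h = k/2 per axis
static std::vector<double> box_sum_nd(const std::vector<double>& s, int n,
                                      int d, int k, bool circular) {
  int h = k / 2;
  std::vector<double> cur(s), nxt(s.size());
  std::vector<double> pre(n + 1);
  long total = 1;
  for (int j = 0; j < d; ++j) total *= n;
  for (int ax = 0; ax < d; ++ax) {
    long stride = 1;
    for (int j = 0; j < ax; ++j) stride *= n;
    long nblocks = total / ((long)n * stride);
    for (long blk = 0; blk < nblocks; ++blk) {
      for (long off = 0; off < stride; ++off) {
        long base = blk * n * stride + off;
        pre[0] = 0.0;
        for (int t = 0; t < n; ++t) pre[t + 1] = pre[t] + cur[base + t * stride];
        double tot = pre[n];
        for (int t = 0; t < n; ++t) {
          int b = t + 1;  // 1-based centre along this axis
          double v;
          if (circular && 2 * h + 1 >= n) {
            v = tot;
          } else if (circular) {
            int lo = b - h, hi = b + h;  // may leave 1..n
            if (lo < 1) {
              v = (pre[hi] - pre[0]) + (pre[n] - pre[lo - 1 + n]);
            } else if (hi > n) {
              v = (pre[n] - pre[lo - 1]) + (pre[hi - n] - pre[0]);
            } else {
              v = pre[hi] - pre[lo - 1];
            }
          } else {
            int lo = std::max(1, b - h), hi = std::min(n, b + h);
            v = pre[hi] - pre[lo - 1];
          }
          nxt[base + t * stride] = v;
        }
      }
    }
    std::swap(cur, nxt);
  }
  return cur;
}

// argmax with uniform tie-breaking; consumes exactly one unif_rand()
static long argmax_tie(const std::vector<double>& w) {
  double mx = w[0];
  for (size_t j = 1; j < w.size(); ++j) if (w[j] > mx) mx = w[j];
  std::vector<long> ties;
  for (size_t j = 0; j < w.size(); ++j) if (w[j] == mx) ties.push_back((long)j);
  double u = unif_rand();
  long idx = (long)(u * ties.size());
  if (idx >= (long)ties.size()) idx = (long)ties.size() - 1;
  return ties[idx];
}

// ---- exported primitives -------------------------------------------------

// [[Rcpp::export(name = ".cpp_box_sum")]]
NumericVector cpp_box_sum(NumericVector s, int n, int d, int k, bool circular) {
  std::vector<double> v(s.begin(), s.end());
  std::vector<double> out = box_sum_nd(v, n, d, k, circular);
  return NumericVector(out.begin(), out.end());
}

// One attractor activation with per-synapse Bernoulli transmission.
// P: (flat A neurons) x (flat B neurons) probability matrix, rows: 1-based
// flat indices of the active input bump. Returns the 1-based flat centre of
// the winning width-kB bump in B (and optionally all window scores).
// [[Rcpp::export(name = ".cpp_activate_bernoulli")]]
List cpp_activate_bernoulli(NumericMatrix P, IntegerVector rows, int nB,
                            int dB, int kB, bool circular,
                            bool return_scores = false) {
  long nflat = P.ncol();
  int nA = P.nrow();
  std::vector<double> s(nflat, 0.0);
  for (long j = 0; j < nflat; ++j) {
    const double* col = &P[(size_t)j * nA];
    double acc = 0.0;
    for (int r = 0; r < rows.size(); ++r) {
      double p = col[rows[r] - 1];
      if (p <= 0.0) continue;
      if (p >= 1.0) { acc += 1.0; continue; }
      if (unif_rand() < p) acc += 1.0;
    }
    s[j] = acc;
  }
  std::vector<double> w = box_sum_nd(s, nB, dB, kB, circular);
  long b = argmax_tie(w);
  List out = List::create(_["center"] = (int)(b + 1));
  if (return_scores) out["scores"] = NumericVector(w.begin(), w.end());
  return out;
}

// Clipped reinforce-type probability update on a block I x J of the synapse
// matrix, in place. Probabilities stay inside [0.1, 0.9].
// [[Rcpp::export(name = ".cpp_policy_update")]]
void cpp_policy_update(NumericMatrix P, IntegerVector rows, IntegerVector cols,
                       double G, double beta) {
  double bg = beta * G;
  for (int c = 0; c < cols.size(); ++c) {
    double* col = &P[(size_t)(cols[c] - 1) * P.nrow()];
    for (int r = 0; r < rows.size(); ++r) {
      double p = col[rows[r] - 1];
      if (G >= 0) p += (0.9 - p) * std::min(bg, 1.0);
      else        p += (p - 0.1) * std::max(bg, -1.0);
      col[rows[r] - 1] = p;
    }
  }
}

// ---- counter-based training phase (theory algorithms, d_A = d_B = 1) ----

// One static phase: M samples, counter updates over I x J, final pruning of
// non-positive counters. live/counters are modified in place (pass copies).
// [[Rcpp::export(name = ".cpp_theory_phase")]]
List cpp_theory_phase(IntegerMatrix live, IntegerMatrix counters, int M,
                      int kA, int kB, double ph, double Lhat,
                      Function feedback, bool circularA, bool circularB) {
  int nA = live.nrow(), nB = live.ncol();
  int hB = kB / 2;
  std::vector<double> s(nB), w;
  for (int m = 0; m < M; ++m) {
    double x = unif_rand();
    int a = encode_idx(x, nA);
    std::vector<int> I = axis_interval(a, kA, nA, circularA);
    // binomial transmission: all live synapses share probability ph
    for (int j = 0; j < nB; ++j) {
      int cnt = 0;
      for (size_t r = 0; r < I.size(); ++r) cnt += live[(I[r] - 1) + (size_t)j * nA];
      s[j] = cnt > 0 ? R::rbinom(cnt, ph) : 0.0;
    }
    w = box_sum_nd(s, nB, 1, kB, circularB);
    int b = (int)argmax_tie(w) + 1;
    double y = (double)b / nB;
    double L = as<double>(feedback(x, y));
    int delta = (L <= Lhat) ? 1 : -1;
    for (size_t r = 0; r < I.size(); ++r) {
      int i = I[r] - 1;
      for (int j = 0; j < nB; ++j) {
        if (in_window(j + 1, b, hB, nB, circularB))
          counters[i + (size_t)j * nA] += delta;
      }
    }
  }
  for (size_t q = 0; q < (size_t)nA * nB; ++q) {
    if (live[q] && counters[q] <= 0) live[q] = 0;
  }
  return List::create(_["live"] = live, _["counters"] = counters);
}

// ---- adaptive simulation algorithm (d_A = d_B = 1) -----------------------

struct RowState {
  std::vector<int> cols;  // sorted live output columns (1-based)
  std::vector<int> dct;   // parallel inactivity counters
};

// Full training loop of the simulation algorithm: per-neuron running error
// thresholds, immediate error-driven pruning, inactivity pruning,
// consolidation, adaptive or static bump width, stopping on mean threshold.
// code: 0 = pruned, 1 = live at p_init, 2 = consolidated (p = 1).
// [[Rcpp::export(name = ".cpp_adaptive_train")]]
List cpp_adaptive_train(IntegerMatrix code, IntegerMatrix dmat,
                        NumericVector Lhat0, LogicalVector cons0,
                        Function feedback, double alpha, double pinit,
                        int thetaPrune, int thetaSyn, double ell,
                        bool variantStatic, int kStatic, int kBStatic,
                        double cA, double cB, int maxSamples, int evalM,
                        IntegerVector checkpoints, bool circularA,
                        bool circularB) {
  int nA = code.nrow(), nB = code.ncol();
  std::vector<RowState> rows(nA);
  std::vector<bool> cons(nA);
  std::vector<double> Lhat(Lhat0.begin(), Lhat0.end());
  for (int i = 0; i < nA; ++i) {
    cons[i] = cons0[i];
    for (int j = 0; j < nB; ++j) {
      if (code[i + (size_t)j * nA] > 0) {
        rows[i].cols.push_back(j + 1);
        rows[i].dct.push_back(dmat[i + (size_t)j * nA]);
      }
    }
  }
  double LhatSum = 0.0;
  for (int i = 0; i < nA; ++i) LhatSum += Lhat[i];

  std::vector<double> cnt1(nB), cnt05(nB), s(nB), w;
  // one activation; returns winner b (1-based) and widths used; no updates
  auto activate_once = [&](double x, int& kA_out, int& kB_out) {
    int a = encode_idx(x, nA);
    int kA, kB;
    if (variantStatic) { kA = kStatic; kB = kBStatic; }
    else {
      int cnt = (int)rows[a - 1].cols.size();
      kA = std::max(1, (int)std::floor(cA * cnt));
      kB = std::max(1, (int)std::floor(cB * cnt));
    }
    if (kA > nA) kA = nA;
    if (kB > nB) kB = nB;
    kA_out = kA; kB_out = kB;
    std::vector<int> I = axis_interval(a, kA, nA, circularA);
    std::fill(cnt1.begin(), cnt1.end(), 0.0);
    std::fill(cnt05.begin(), cnt05.end(), 0.0);
    for (size_t r = 0; r < I.size(); ++r) {
      RowState& rw = rows[I[r] - 1];
      if (cons[I[r] - 1]) {
        for (size_t q = 0; q < rw.cols.size(); ++q) cnt1[rw.cols[q] - 1] += 1.0;
      } else {
        for (size_t q = 0; q < rw.cols.size(); ++q) cnt05[rw.cols[q] - 1] += 1.0;
      }
    }
    for (int j = 0; j < nB; ++j) {
      s[j] = cnt1[j];
      if (cnt05[j] > 0) s[j] += R::rbinom(cnt05[j], pinit);
    }
    w = box_sum_nd(s, nB, 1, kB, circularB);
    int b = (int)argmax_tie(w) + 1;
    return b;
  };

  std::vector<double> curve_sample, curve_err, curve_lhat, curve_live, curve_k;
  auto record_point = [&](int sample) {
    double errSum = 0.0, kSum = 0.0;
    int kA, kB;
    for (int e = 0; e < evalM; ++e) {
      double x = unif_rand();
      int b = activate_once(x, kA, kB);
      double y = (double)b / nB;
      errSum += as<double>(feedback(x, y));
      kSum += kA;
    }
    double liveSum = 0.0;
    for (int i = 0; i < nA; ++i) liveSum += rows[i].cols.size();
    curve_sample.push_back(sample);
    curve_err.push_back(errSum / evalM);
    curve_lhat.push_back(LhatSum / nA);
    curve_live.push_back(liveSum / nA);
    curve_k.push_back(kSum / evalM);
  };

  int nextCk = 0, reseeds = 0, samples = 0;
  bool converged = false;
  for (int t = 1; t <= maxSamples; ++t) {
    samples = t;
    double x = unif_rand();
    int kA, kB;
    int b = activate_once(x, kA, kB);
    int a = encode_idx(x, nA);
    double y = (double)b / nB;
    double L = as<double>(feedback(x, y));
    int hB = kB / 2;
    std::vector<int> I = axis_interval(a, kA, nA, circularA);
    for (size_t r = 0; r < I.size(); ++r) {
      int i = I[r];
      RowState& rw = rows[i - 1];
      double pre = Lhat[i - 1];
      if (cons[i - 1]) {  // consolidated: threshold keeps tracking, p frozen
        Lhat[i - 1] = alpha * L + (1 - alpha) * pre;
        LhatSum += Lhat[i - 1] - pre;
        continue;
      }
      // (1) error-driven pruning of the co-active block, pre-update L-hat
      if (L >= pre) {
        size_t keep = 0;
        for (size_t q = 0; q < rw.cols.size(); ++q) {
          if (!in_window(rw.cols[q], b, hB, nB, circularB)) {
            rw.cols[keep] = rw.cols[q];
            rw.dct[keep] = rw.dct[q];
            ++keep;
          }
        }
        rw.cols.resize(keep);
        rw.dct.resize(keep);
      }
      // (2) running-average threshold update
      Lhat[i - 1] = alpha * L + (1 - alpha) * pre;
      LhatSum += Lhat[i - 1] - pre;
      // (3) inactivity bookkeeping and pruning
      size_t keep = 0;
      for (size_t q = 0; q < rw.cols.size(); ++q) {
        if (in_window(rw.cols[q], b, hB, nB, circularB)) {
          rw.cols[keep] = rw.cols[q];
          rw.dct[keep] = 0;
          ++keep;
        } else if (rw.dct[q] + 1 < thetaPrune) {
          rw.cols[keep] = rw.cols[q];
          rw.dct[keep] = rw.dct[q] + 1;
          ++keep;
        }
      }
      rw.cols.resize(keep);
      rw.dct.resize(keep);
      // (4) consolidation when the row has shrunk below theta_syn
      if (keep > 0 && (int)keep < thetaSyn) {
        cons[i - 1] = true;
      } else if (keep == 0) {
        // degenerate row: re-seed a centred exploration band
        int j0 = encode_idx((double)i / nA, nB);
        std::vector<int> band = axis_interval(j0, thetaSyn, nB, circularB);
        rw.cols = band;
        rw.dct.assign(band.size(), 0);
        ++reseeds;
      }
    }
    if (nextCk < checkpoints.size() && t == checkpoints[nextCk]) {
      record_point(t);
      ++nextCk;
    }
    if (LhatSum / nA < ell) { converged = true; break; }
  }
  record_point(samples);

  IntegerMatrix codeOut(nA, nB), dOut(nA, nB);
  for (int i = 0; i < nA; ++i) {
    int v = cons[i] ? 2 : 1;
    for (size_t q = 0; q < rows[i].cols.size(); ++q) {
      codeOut[i + (size_t)(rows[i].cols[q] - 1) * nA] = v;
      dOut[i + (size_t)(rows[i].cols[q] - 1) * nA] = rows[i].dct[q];
    }
  }
  return List::create(
    _["code"] = codeOut, _["d"] = dOut,
    _["L_hat"] = NumericVector(Lhat.begin(), Lhat.end()),
    _["consolidated"] = LogicalVector(cons.begin(), cons.end()),
    _["curve"] = DataFrame::create(
      _["sample"] = curve_sample, _["error"] = curve_err,
      _["mean_L_hat"] = curve_lhat, _["mean_live"] = curve_live,
      _["mean_k"] = curve_k),
    _["samples"] = samples, _["converged"] = converged,
    _["reseeds"] = reseeds);
}
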