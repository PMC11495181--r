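#include <Rcpp.h>
using namespace Rcpp;

// Bin index for a lag given bin width and half-count n (bins centred at
// k*bin for k in [-n, n], half-open [lo, hi)). Returns -1 if outside.
static inline int lag_bin(double lag, double bin, int nhalf) {
  double idx = std::floor(lag / bin + 0.5);
  if (idx < -nhalf || idx > nhalf) return -1;
  return static_cast<int>(idx) + nhalf;
}

// Cross-correlogram counts: counts[b] = #{(i,j): tgt[j] - ref[i] in bin b}.
// Both inputs must be sorted ascending. Two-pointer sweep, O(n + pairs).
// [[Rcpp::export(name = ".corrCounts")]]
IntegerVector corr_counts(NumericVector ref, NumericVector tgt,
                          double bin, int nhalf) {
  int nb = 2 * nhalf + 1;
  IntegerVector counts(nb);
  double maxlag = (nhalf + 0.5) * bin;
  R_xlen_t lo = 0, nt = tgt.size();
  for (R_xlen_t i = 0; i < ref.size(); ++i) {
    double r = ref[i];
    while (lo < nt && tgt[lo] < r - maxlag) ++lo;
    for (R_xlen_t j = lo; j < nt && tgt[j] < r + maxlag; ++j) {
      int b = lag_bin(tgt[j] - r, bin, nhalf);
      if (b >= 0) ++counts[b];
    }
  }
  return counts;
}

// Gamma(shape, scale) deviate by Marsaglia-Tsang squeeze (shape >= 1),
// with the Ahrens-Dieter boost for shape < 1. Draws from R's RNG so
// set.seed() in R governs reproducibility.
static inline double rgamma_mt(double shape, double scale) {
  if (shape < 1.0) {
    double u = unif_rand();
    return rgamma_mt(shape + 1.0, scale) * std::pow(u, 1.0 / shape);
  }
  double d = shape - 1.0 / 3.0, c = 1.0 / std::sqrt(9.0 * d);
  for (;;) {
    double x = norm_rand();
    double v = 1.0 + c * x;
    if (v <= 0) continue;
    v = v * v * v;
    double u = unif_rand();
    if (u < 1.0 - 0.0331 * x * x * x * x) return d * v * scale;
    if (std::log(u) < 0.5 * x * x + d * (1.0 - v + std::log(v)))
      return d * v * scale;
  }
}

// One gamma-ISI surrogate train: i.i.d. Gamma(shape, scale) intervals laid
// end-to-end from t_first, truncated at t_end (spike times < t_end).
static std::vector<double> gamma_train(double t_first, double t_end,
                                       double shape, double scale) {
  std::vector<double> out;
  double t = t_first;
  double mean_isi = shape * scale;
  size_t guess = mean_isi > 0
    ? static_cast<size_t>((t_end - t_first) / mean_isi * 1.1) + 16 : 256;
  out.reserve(guess);
  while (true) {
    out.push_back(t);
    t += rgamma_mt(shape, scale);
    if (t >= t_end) break;
  }
  return out;
}

// [[Rcpp::export(name = ".gammaTrain")]]
NumericVector gamma_train_r(double t_first, double t_end, double shape,
                            double scale) {
  std::vector<double> v = gamma_train(t_first, t_end, shape, scale);
  return wrap(v);
}

// Surrogate correlogram count matrix: n_surr rows, one per surrogate pair
// (independent gamma-ISI surrogates of the reference and target trains).
// Draws from R's RNG, so set.seed() in R governs reproducibility.
// Batch of gamma-ISI surrogate trains as a list of numeric vectors.
// [[Rcpp::export(name = ".gammaTrains")]]
List gamma_trains(double t_first, double t_end, double shape, double scale,
                  int n) {
  List out(n);
  for (int i = 0; i < n; ++i)
    out[i] = wrap(gamma_train(t_first, t_end, shape, scale));
  return out;
}

// Correlogram counts for paired lists of (pre-generated) surrogate
// trains: row s is the correlogram of ref_list[s] vs tgt_list[s].
// [[Rcpp::export(name = ".corrCountsPairList")]]
IntegerMatrix corr_counts_pair_list(List ref_list, List tgt_list,
                                    double bin, int nhalf) {
  int n = ref_list.size();
  int nb = 2 * nhalf + 1;
  IntegerMatrix counts(n, nb);
  double maxlag = (nhalf + 0.5) * bin;
  for (int s = 0; s < n; ++s) {
    NumericVector r = ref_list[s], t = tgt_list[s];
    R_xlen_t lo = 0, nt = t.size();
    for (R_xlen_t i = 0; i < r.size(); ++i) {
      double rr = r[i];
      while (lo < nt && t[lo] < rr - maxlag) ++lo;
      for (R_xlen_t j = lo; j < nt && t[j] < rr + maxlag; ++j) {
        int b = lag_bin(t[j] - rr, bin, nhalf);
        if (b >= 0) ++counts(s, b);
      }
    }
    if ((s & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return counts;
}

// Running-median detrend of a vector (window k, truncated at the
// edges; lower median for even-length edge windows). The same routine
// is applied to observed and surrogate correlograms so the feature
// statistic and its null are treated identically.
static std::vector<double> detrend_one(const double* v, int n, int k) {
  int h = k / 2;
  std::vector<double> out(n), buf;
  buf.reserve(k);
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - h), hi = std::min(n - 1, i + h);
    buf.assign(v + lo, v + hi + 1);
    size_t mid = (buf.size() - 1) / 2;
    std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
    out[i] = v[i] - buf[mid];
  }
  return out;
}

// [[Rcpp::export(name = ".detrendVec")]]
NumericVector detrend_vec(NumericVector v, int k) {
  return wrap(detrend_one(v.begin(), v.size(), k));
}

// [[Rcpp::export(name = ".detrendRows")]]
NumericMatrix detrend_rows(IntegerMatrix m, int k) {
  int nr = m.nrow(), nc = m.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> row(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) row[j] = m(i, j);
    std::vector<double> d = detrend_one(row.data(), nc, k);
    for (int j = 0; j < nc; ++j) out(i, j) = d[j];
  }
  return out;
}

static inline double quantile7(std::vector<double>& s, double p) {
  // type-7 sample quantile on a sorted copy
  double h = (s.size() - 1) * p;
  size_t lo = static_cast<size_t>(std::floor(h));
  size_t hi = std::min(lo + 1, s.size() - 1);
  return s[lo] + (h - lo) * (s[hi] - s[lo]);
}

// Band statistics from a detrended surrogate matrix: per-bin mean and
// 2.5/97.5 percentiles, plus each surrogate's signed maximum departure
// from the per-bin mean (max-statistic null for feature p-values).
static List band_stats(const NumericMatrix& Sd) {
  int nr = Sd.nrow(), nc = Sd.ncol();
  NumericVector mu(nc), lo(nc), hi(nc);
  std::vector<double> col(nr);
  for (int j = 0; j < nc; ++j) {
    double s = 0;
    for (int i = 0; i < nr; ++i) { col[i] = Sd(i, j); s += col[i]; }
    mu[j] = s / nr;
    std::sort(col.begin(), col.end());
    lo[j] = quantile7(col, 0.025);
    hi[j] = quantile7(col, 0.975);
  }
  // per-surrogate signed maximum departures, studentized by that
  // surrogate's own residual SD so the null statistic matches the
  // detectability index measured on the observed correlogram
  NumericVector maxPos(nr), maxNeg(nr);
  for (int i = 0; i < nr; ++i) {
    double mp = R_NegInf, mn = R_NegInf, ss = 0, s2 = 0;
    for (int j = 0; j < nc; ++j) {
      double d = Sd(i, j) - mu[j];
      ss += d; s2 += d * d;
      if (d > mp) mp = d;
      if (-d > mn) mn = -d;
    }
    double sd = std::sqrt(std::max(1e-300,
                 (s2 - ss * ss / nc) / (nc - 1)));
    maxPos[i] = mp / sd; maxNeg[i] = mn / sd;
  }
  return List::create(_["mu"] = mu, _["lo"] = lo, _["hi"] = hi,
                      _["maxPos"] = maxPos, _["maxNeg"] = maxNeg);
}

// [[Rcpp::export(name = ".surrogateBandStats")]]
List surrogate_band_stats(IntegerMatrix m, int k) {
  int nr = m.nrow(), nc = m.ncol();
  NumericMatrix Sd(nr, nc);
  std::vector<double> row(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) row[j] = m(i, j);
    std::vector<double> d = detrend_one(row.data(), nc, k);
    for (int j = 0; j < nc; ++j) Sd(i, j) = d[j];
  }
  return band_stats(Sd);
}

// Fused path for pairs whose trains are used only once: generate the
// gamma-ISI surrogate pair, count, detrend, and accumulate band
// statistics without materializing surrogate trains in R.
// [[Rcpp::export(name = ".surrogatePairStats")]]
List surrogate_pair_stats(double ref_first, double ref_end,
                          double ref_shape, double ref_scale,
                          double tgt_first, double tgt_end,
                          double tgt_shape, double tgt_scale,
                          int n_surr, double bin, int nhalf, int k) {
  int nb = 2 * nhalf + 1;
  NumericMatrix Sd(n_surr, nb);
  double maxlag = (nhalf + 0.5) * bin;
  std::vector<double> row(nb);
  for (int s = 0; s < n_surr; ++s) {
    std::vector<double> sr = gamma_train(ref_first, ref_end,
                                         ref_shape, ref_scale);
    std::vector<double> st = gamma_train(tgt_first, tgt_end,
                                         tgt_shape, tgt_scale);
    std::fill(row.begin(), row.end(), 0.0);
    size_t lo = 0, nt = st.size();
    for (size_t i = 0; i < sr.size(); ++i) {
      double r = sr[i];
      while (lo < nt && st[lo] < r - maxlag) ++lo;
      for (size_t j = lo; j < nt && st[j] < r + maxlag; ++j) {
        int b = lag_bin(st[j] - r, bin, nhalf);
        if (b >= 0) row[b] += 1.0;
      }
    }
    std::vector<double> d = detrend_one(row.data(), nb, k);
    for (int j = 0; j < nb; ++j) Sd(s, j) = d[j];
    if ((s & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return band_stats(Sd);
}

// [[Rcpp::export(name = ".surrogateCorrCounts")]]
IntegerMatrix surrogate_corr_counts(double ref_first, double ref_end,
                                    double ref_shape, double ref_scale,
                                    double tgt_first, double tgt_end,
                                    double tgt_shape, double tgt_scale,
                                    int n_surr, double bin, int nhalf) {
  int nb = 2 * nhalf + 1;
  IntegerMatrix counts(n_surr, nb);
  double maxlag = (nhalf + 0.5) * bin;
  for (int s = 0; s < n_surr; ++s) {
    std::vector<double> sr = gamma_train(ref_first, ref_end,
                                         ref_shape, ref_scale);
    std::vector<double> st = gamma_train(tgt_first, tgt_end,
                                         tgt_shape, tgt_scale);
    size_t lo = 0, nt = st.size();
    for (size_t i = 0; i < sr.size(); ++i) {
      double r = sr[i];
      while (lo < nt && st[lo] < r - maxlag) ++lo;
      for (size_t j = lo; j < nt && st[j] < r + maxlag; ++j) {
        int b = lag_bin(st[j] - r, bin, nhalf);
        if (b >= 0) ++counts(s, b);
      }
    }
    if ((s & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return counts;
}
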