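// Mutation-selection simulator core.
//
// Sequences are integer-coded (A=0..T=3), concatenated, each circular in
// its own coordinate frame. Position sampling is proportional to the
// per-position mean of the three alternate-allele rates (two-stage: first
// the position, then the allele proportional to its rate), maintained in a
// Fenwick tree so each accepted substitution costs O(log n) plus a +/-3 nt
// neighbourhood update. Under protein constraint a proposal is rejected
// and fully redrawn whenever it changes the translation or the mutated
// codon is a stop; only accepted substitutions advance time.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Fenwick {
  int n;
  std::vector<double> t;
  explicit Fenwick(int n_) : n(n_), t(n_ + 1, 0.0) {}
  void add(int i, double d) {
    for (++i; i <= n; i += i & -i) t[i] += d;
  }
  double total() const {
    double s = 0;
    int i = n;
    for (; i > 0; i -= i & -i) s += t[i];
    return s;
  }
  // smallest index with prefix sum > u
  int find(double u) const {
    int pos = 0, log = 1;
    while ((1 << log) <= n) ++log;
    for (int pw = 1 << (log - 1); pw > 0; pw >>= 1) {
      if (pos + pw <= n && t[pos + pw] <= u) {
        pos += pw;
        u -= t[pos];
      }
    }
    return pos;  // 0-based
  }
};

struct Genome {
  std::vector<int> seq;          // concatenated bases
  std::vector<int> off, len;     // per-sequence offset and length
  std::vector<int> seq_of;       // position -> sequence id
  const double* rates;           // 16384 x 4, column-major
  std::vector<double> rowsum;    // per-heptamer sum of 3 alternate rates
  std::vector<double> site;      // cached per-position mean rate
  Fenwick fw;
  bool constrain;
  const int* aa64;               // amino acid id per codon, stop = -1

  Genome(IntegerVector seq_, IntegerVector len_, NumericMatrix rates_,
         IntegerVector aa_, bool constrain_)
      : seq(seq_.begin(), seq_.end()), rates(rates_.begin()),
        fw((int)seq_.size()), constrain(constrain_), aa64(aa_.begin()) {
    int n = seq.size();
    int start = 0;
    for (int s = 0; s < len_.size(); ++s) {
      off.push_back(start);
      len.push_back(len_[s]);
      for (int j = 0; j < len_[s]; ++j) seq_of.push_back(s);
      start += len_[s];
    }
    if (start != n) stop("sequence lengths do not sum to total length");
    rowsum.assign(16384, 0.0);
    for (int h = 0; h < 16384; ++h)
      for (int b = 0; b < 4; ++b) rowsum[h] += rates[h + 16384 * b];
    site.assign(n, 0.0);
    for (int p = 0; p < n; ++p) {
      site[p] = rowsum[hept(p)] / 3.0;
      fw.add(p, site[p]);
    }
  }

  inline int local(int p, int s) const { return p - off[s]; }

  // heptamer index centred at global position p, wrapping in its sequence
  inline int hept(int p) const {
    int s = seq_of[p], L = len[s], l = p - off[s];
    int idx = 0;
    for (int d = -3; d <= 3; ++d) {
      int q = l + d;
      q %= L;
      if (q < 0) q += L;
      idx = idx * 4 + seq[off[s] + q];
    }
    return idx;
  }

  inline int codon_start(int l) const { return l - l % 3; }

  // would substituting base b at global position p be accepted?
  bool acceptable(int p, int b) const {
    if (!constrain) return true;
    int s = seq_of[p], l = p - off[s], c0 = codon_start(l);
    int o = off[s];
    int cod[3] = {seq[o + c0], seq[o + c0 + 1], seq[o + c0 + 2]};
    int old_idx = cod[0] * 16 + cod[1] * 4 + cod[2];
    cod[l - c0] = b;
    int new_idx = cod[0] * 16 + cod[1] * 4 + cod[2];
    if (aa64[new_idx] < 0) return false;           // creates a stop codon
    return aa64[new_idx] == aa64[old_idx];         // amino acid unchanged
  }

  void apply(int p, int b) {
    int s = seq_of[p], L = len[s], l = p - off[s];
    seq[p] = b;
    for (int d = -3; d <= 3; ++d) {
      int q = (l + d) % L;
      if (q < 0) q += L;
      int g = off[s] + q;
      double nw = rowsum[hept(g)] / 3.0;
      fw.add(g, nw - site[g]);
      site[g] = nw;
    }
  }

  // one accepted substitution; returns number of rejected proposals
  long step(long max_reject) {
    long rejected = 0;
    for (;;) {
      double u = unif_rand() * fw.total();
      int p = fw.find(u);
      if (p >= (int)seq.size()) p = (int)seq.size() - 1;
      int h = hept(p);
      int ref = seq[p];
      double r[4], tot = 0;
      for (int b = 0; b < 4; ++b) {
        r[b] = (b == ref) ? 0.0 : rates[h + 16384 * b];
        tot += r[b];
      }
      double v = unif_rand() * tot, acc = 0;
      int b = -1;
      for (int k = 0; k < 4; ++k) {
        acc += r[k];
        if (v <= acc && r[k] > 0) { b = k; break; }
      }
      if (b < 0) { for (int k = 3; k >= 0; --k) if (r[k] > 0) { b = k; break; } }
      if (acceptable(p, b)) {
        apply(p, b);
        return rejected;
      }
      if (++rejected > max_reject)
        stop("no acceptable substitution found after %d rejected proposals; "
             "the constrained genome appears deadlocked", (long)max_reject);
    }
  }

  // overlapping hexamer counts, circular per sequence
  void hex_counts(double* out) const {
    for (int s = 0; s < (int)off.size(); ++s) {
      int L = len[s], o = off[s];
      if (L < 6) continue;
      // rolling index over circularized sequence
      int idx = 0;
      for (int j = 0; j < 6; ++j) idx = idx * 4 + seq[o + j % L];
      out[idx] += 1;
      for (int start = 1; start < L; ++start) {
        int drop = seq[o + (start - 1) % L];
        int add = seq[o + (start + 5) % L];
        idx = (idx - drop * 1024) * 4 + add;
        out[idx] += 1;
      }
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List sim_run_cpp(IntegerVector seq, IntegerVector seq_len,
                 NumericMatrix rates, IntegerVector aa64, bool constrain,
                 int n_records, int steps_per_record, double max_reject) {
  Genome g(seq, seq_len, rates, aa64, constrain);
  int n = seq.size();
  NumericMatrix hex(n_records + 1, 4096);
  NumericVector mean_erm(n_records + 1);
  NumericVector accepted(n_records + 1), rejected_total(1);
  std::vector<double> hc(4096);
  long rej = 0;

  std::fill(hc.begin(), hc.end(), 0.0);
  g.hex_counts(hc.data());
  for (int k = 0; k < 4096; ++k) hex(0, k) = hc[k];
  mean_erm[0] = g.fw.total() / n;
  accepted[0] = 0;

  for (int r = 1; r <= n_records; ++r) {
    for (int s = 0; s < steps_per_record; ++s) rej += g.step((long)max_reject);
    std::fill(hc.begin(), hc.end(), 0.0);
    g.hex_counts(hc.data());
    for (int k = 0; k < 4096; ++k) hex(r, k) = hc[k];
    mean_erm[r] = g.fw.total() / n;
    accepted[r] = (double)r * steps_per_record;
    Rcpp::checkUserInterrupt();
  }
  rejected_total[0] = (double)rej;
  return List::create(_["final_seq"] = IntegerVector(g.seq.begin(), g.seq.end()),
                      _["hex_counts"] = hex, _["mean_erm"] = mean_erm,
                      _["accepted"] = accepted,
                      _["rejected"] = rejected_total);
}

// Occupancy of the embedded jump chain on a single short circular sequence:
// the state (base-4 index of the whole sequence) is tallied after every
// accepted substitution once burn_in substitutions have elapsed.
// [[Rcpp::export]]
NumericVector sim_occupancy_cpp(IntegerVector seq, NumericMatrix rates,
                                IntegerVector aa64, bool constrain,
                                double burn_in, double n_steps,
                                double max_reject) {
  int L = seq.size();
  if (L > 10) stop("occupancy tracking is for short sequences (L <= 10)");
  IntegerVector len(1, L);
  Genome g(seq, len, rates, aa64, constrain);
  int n_states = 1;
  for (int j = 0; j < L; ++j) n_states *= 4;
  NumericVector counts(n_states);
  for (double t = 0; t < burn_in; ++t) g.step((long)max_reject);
  for (double t = 0; t < n_steps; ++t) {
    g.step((long)max_reject);
    int st = 0;
    for (int j = 0; j < L; ++j) st = st * 4 + g.seq[j];
    counts[st] += 1;
    if (((long)t & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return counts;
}

// Slow full-recompute reference for the per-position mean-rate cache.
// [[Rcpp::export]]
NumericVector site_means_cpp(IntegerVector seq, IntegerVector seq_len,
                             NumericMatrix rates) {
  IntegerVector aa(64, 0);
  Genome g(seq, seq_len, rates, aa, false);
  return NumericVector(g.site.begin(), g.site.end());
}
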