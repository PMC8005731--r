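#include <Rcpp.h>
#include <unordered_set>
#include <unordered_map>
#include <map>
#include <cstring>
#include <algorithm>
using namespace Rcpp;

// 2-bit encoding; k-mers with non-ACGT bases are skipped everywhere.
static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Canonical k-mer codes per window start; -1 marks invalid (non-ACGT) windows.
static std::vector<long long> canonical_kmers(const char* s, int n, int k) {
  std::vector<long long> out;
  if (n < k) return out;
  out.assign(n - k + 1, -1);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0; // length of current run of valid bases
  for (int i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | (((uint64_t)(3 - b)) << (2 * (k - 1)));
    ++valid;
    if (valid >= k) {
      uint64_t canon = fwd < rev ? fwd : rev;
      out[i - k + 1] = (long long)canon;
    }
  }
  return out;
}

struct SpanStats {
  double overlap;   // fraction of the sequence covered by shared-k-mer spans
  double identity;  // (hits / positions inside spans)^(1/k)
};

// Coverage-based overlap/identity from per-position hit flags.
static SpanStats span_stats(const std::vector<long long>& kmers,
                            const std::vector<char>& hit,
                            int seq_len, int k, int bridge_gap) {
  SpanStats st = {0.0, 0.0};
  long long covered = 0;
  int span_start = -1, span_end = -1; // [start, end) in bases
  std::vector<std::pair<int,int>> spans;
  int n_pos = (int)kmers.size();
  for (int i = 0; i < n_pos; ++i) {
    if (!hit[i]) continue;
    if (span_start < 0) { span_start = i; span_end = i + k; }
    else if (i <= span_end + bridge_gap) { span_end = i + k; }
    else { spans.push_back({span_start, span_end}); span_start = i; span_end = i + k; }
  }
  if (span_start >= 0) spans.push_back({span_start, span_end});
  // runs of shared k-mers near the ends extend to them: divergence clusters
  // at sequence boundaries otherwise mask genuinely homologous termini
  if (!spans.empty()) {
    if (spans.front().first <= bridge_gap) spans.front().first = 0;
    if (seq_len - spans.back().second <= bridge_gap)
      spans.back().second = seq_len;
  }
  long long hits = 0, pos_in = 0;
  for (auto& sp : spans) {
    covered += sp.second - sp.first;
    for (int i = sp.first; i < sp.second && i < n_pos; ++i) {
      if (kmers[i] >= 0) { ++pos_in; if (hit[i]) ++hits; }
    }
  }
  st.overlap = (double)covered / (double)seq_len;
  if (st.overlap > 1.0) st.overlap = 1.0;
  if (pos_in > 0 && hits > 0)
    st.identity = std::pow((double)hits / (double)pos_in, 1.0 / (double)k);
  return st;
}

// [[Rcpp::export(name = ".cpp_containment")]]
NumericVector cpp_containment(std::string a, std::string b, int k, int bridge_gap) {
  // shorter sequence measured against the longer; equal lengths: the
  // lexicographically smaller string plays "shorter" so the result is
  // symmetric in input order.
  const std::string* shorter = &a;
  const std::string* longer = &b;
  if (a.size() > b.size() || (a.size() == b.size() && a > b)) {
    shorter = &b; longer = &a;
  }
  std::vector<long long> lk = canonical_kmers(longer->c_str(), (int)longer->size(), k);
  std::unordered_set<uint64_t> idx;
  for (long long c : lk) if (c >= 0) idx.insert((uint64_t)c);
  std::vector<long long> sk = canonical_kmers(shorter->c_str(), (int)shorter->size(), k);
  std::vector<char> hit(sk.size(), 0);
  for (size_t i = 0; i < sk.size(); ++i)
    if (sk[i] >= 0 && idx.count((uint64_t)sk[i])) hit[i] = 1;
  SpanStats st = span_stats(sk, hit, (int)shorter->size(), k, bridge_gap);
  return NumericVector::create(_["identity"] = st.identity,
                               _["overlap"] = st.overlap);
}

// Greedy longest-first clustering. `seqs` must arrive sorted by
// (length desc, id asc); returns 1-based index of each member's
// representative within that order, plus identity/overlap vs it.
// [[Rcpp::export(name = ".cpp_greedy_cluster")]]
List cpp_greedy_cluster(CharacterVector seqs, int k,
                        double min_identity, double min_overlap,
                        int bridge_gap) {
  int n = seqs.size();
  IntegerVector rep(n);
  NumericVector ident(n), ovl(n);
  std::unordered_map<uint64_t, std::vector<int>> index; // kmer -> rep input idx
  std::vector<int> reps;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::vector<long long> km = canonical_kmers(s.c_str(), (int)s.size(), k);
    // collect hit positions per candidate representative, rep order preserved
    std::map<int, std::vector<int>> cand; // key = founding order index
    std::unordered_map<int,int> rep2ord;
    for (size_t r = 0; r < reps.size(); ++r) rep2ord[reps[r]] = (int)r;
    for (size_t p = 0; p < km.size(); ++p) {
      if (km[p] < 0) continue;
      auto it = index.find((uint64_t)km[p]);
      if (it == index.end()) continue;
      for (int ridx : it->second) cand[rep2ord[ridx]].push_back((int)p);
    }
    int chosen = -1; double ci = 0.0, co = 0.0;
    for (auto& kv : cand) {
      std::vector<char> hit(km.size(), 0);
      for (int p : kv.second) hit[p] = 1;
      SpanStats st = span_stats(km, hit, (int)s.size(), k, bridge_gap);
      if (st.identity >= min_identity && st.overlap >= min_overlap) {
        chosen = reps[kv.first]; ci = st.identity; co = st.overlap;
        break; // first (longest-first founding order) passing cluster
      }
    }
    if (chosen < 0) {
      reps.push_back(i);
      std::unordered_set<uint64_t> uniq;
      for (long long c : km) if (c >= 0) uniq.insert((uint64_t)c);
      for (uint64_t c : uniq) index[c].push_back(i);
      rep[i] = i + 1; ident[i] = 1.0; ovl[i] = 1.0;
    } else {
      rep[i] = chosen + 1; ident[i] = ci; ovl[i] = co;
    }
  }
  return List::create(_["representative"] = rep, _["identity"] = ident,
                      _["overlap"] = ovl);
}

// Pseudo-assignment: each read goes to the representative sharing the most
// of its distinct canonical k-mers, if that share >= min_frac; ties resolve
// to the smallest index (callers pass reps sorted by length desc, id asc).
// [[Rcpp::export(name = ".cpp_assign_reads")]]
IntegerVector cpp_assign_reads(CharacterVector reads, CharacterVector reps,
                               int k, double min_frac) {
  std::unordered_map<uint64_t, std::vector<int>> index;
  int nr = reps.size();
  for (int r = 0; r < nr; ++r) {
    std::string s = as<std::string>(reps[r]);
    std::vector<long long> km = canonical_kmers(s.c_str(), (int)s.size(), k);
    std::unordered_set<uint64_t> uniq;
    for (long long c : km) if (c >= 0) uniq.insert((uint64_t)c);
    for (uint64_t c : uniq) index[c].push_back(r);
  }
  int n = reads.size();
  IntegerVector out(n);
  std::vector<int> counts(nr, 0);
  std::vector<int> touched;
  std::vector<uint64_t> uniq;
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    int len = (int)LENGTH(STRING_ELT(reads, i));
    std::vector<long long> km = canonical_kmers(s, len, k);
    uniq.clear();
    for (long long c : km) if (c >= 0) uniq.push_back((uint64_t)c);
    std::sort(uniq.begin(), uniq.end());
    uniq.erase(std::unique(uniq.begin(), uniq.end()), uniq.end());
    touched.clear();
    for (uint64_t c : uniq) {
      auto it = index.find(c);
      if (it == index.end()) continue;
      for (int r : it->second) {
        if (counts[r] == 0) touched.push_back(r);
        counts[r]++;
      }
    }
    int best = -1, best_n = 0;
    for (int r : touched) {
      if (counts[r] > best_n || (counts[r] == best_n && r < best)) {
        best = r; best_n = counts[r];
      }
    }
    for (int r : touched) counts[r] = 0;
    if (best >= 0 && !uniq.empty() &&
        (double)best_n >= min_frac * (double)uniq.size())
      out[i] = best + 1;
    else
      out[i] = 0;
  }
  return out;
}

// Longest exact terminal direct repeat (prefix == suffix), searched from
// min(len/2, 2000) downward; 0 when none of length >= min_repeat exists.
// [[Rcpp::export(name = ".cpp_terminal_repeat")]]
int cpp_terminal_repeat(std::string seq, int min_repeat) {
  int n = (int)seq.size();
  int cap = n / 2; if (cap > 2000) cap = 2000;
  const char* s = seq.c_str();
  for (int L = cap; L >= min_repeat; --L)
    if (std::memcmp(s, s + n - L, L) == 0) return L;
  return 0;
}

// Fraction of the query's distinct canonical k-mers present in each target.
// [[Rcpp::export(name = ".cpp_kmer_fraction_in")]]
NumericVector cpp_kmer_fraction_in(std::string query, CharacterVector targets,
                                   int k) {
  std::vector<long long> km = canonical_kmers(query.c_str(), (int)query.size(), k);
  std::unordered_set<uint64_t> uniq;
  for (long long c : km) if (c >= 0) uniq.insert((uint64_t)c);
  int nt = targets.size();
  NumericVector out(nt);
  for (int t = 0; t < nt; ++t) {
    std::string s = as<std::string>(targets[t]);
    std::vector<long long> tk = canonical_kmers(s.c_str(), (int)s.size(), k);
    std::unordered_set<uint64_t> tset;
    for (long long c : tk) if (c >= 0) tset.insert((uint64_t)c);
    long long sh = 0;
    for (uint64_t c : uniq) if (tset.count(c)) ++sh;
    out[t] = uniq.empty() ? 0.0 : (double)sh / (double)uniq.size();
  }
  return out;
}
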