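// Suffix-array engine for irredundant / underlying common pattern extraction
// between two sets of documents (reads and, optionally, their transform
// strings).  Documents are concatenated with per-position unique sentinels so
// matches never cross read boundaries; non-ACGT symbols are mapped to unique
// sentinels and therefore break matches.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Gsa {
  std::vector<int> text;              // 1..4 = A,C,G,T; >=5 unique sentinels
  std::vector<int> sa, rnk, lcp;      // lcp[i] = lcp(sa[i-1], sa[i]), lcp[0]=0
  std::vector<int> doc_of;            // document index per text position
  std::vector<int> doc_start, doc_len, doc_set;
  std::vector<int> cum1;              // # set-1 suffixes among sa[0..i)
  int n = 0, ndoc = 0;
  std::vector<int> logt;              // RMQ over lcp
  std::vector<std::vector<int>> st;
};

inline int base_code(char c) {
  switch (c) {
    case 'A': return 1; case 'C': return 2;
    case 'G': return 3; case 'T': return 4;
  }
  return 0;
}

void build_text(const CharacterVector& docs, const IntegerVector& dset, Gsa& g) {
  g.ndoc = docs.size();
  size_t total = 0;
  for (int d = 0; d < g.ndoc; ++d) total += LENGTH(STRING_ELT(docs, d)) + 1;
  g.text.reserve(total);
  g.doc_start.resize(g.ndoc);
  g.doc_len.resize(g.ndoc);
  g.doc_set.resize(g.ndoc);
  int sentinel = 5;
  for (int d = 0; d < g.ndoc; ++d) {
    const char* s = CHAR(STRING_ELT(docs, d));
    int len = LENGTH(STRING_ELT(docs, d));
    g.doc_start[d] = static_cast<int>(g.text.size());
    g.doc_len[d] = len;
    g.doc_set[d] = dset[d];
    for (int i = 0; i < len; ++i) {
      int c = base_code(s[i]);
      g.text.push_back(c ? c : sentinel++);
    }
    g.text.push_back(sentinel++);     // document terminator
  }
  g.n = static_cast<int>(g.text.size());
  g.doc_of.assign(g.n, 0);
  for (int d = 0; d < g.ndoc; ++d)
    for (int i = g.doc_start[d]; i <= g.doc_start[d] + g.doc_len[d]; ++i)
      g.doc_of[i] = d;
}

// O(n log n) prefix-doubling suffix array with counting sorts (robust to
// highly repetitive inputs, unlike direct suffix comparison).
void build_sa(Gsa& g) {
  const int n = g.n;
  g.sa.assign(n, 0);
  std::vector<int> rank_(g.text.begin(), g.text.end());
  std::vector<int> tmp(n), new_rank(n), cnt;
  int maxv = *std::max_element(rank_.begin(), rank_.end());
  cnt.assign(maxv + 2, 0);
  for (int i = 0; i < n; ++i) cnt[rank_[i] + 1]++;
  for (int v = 0; v <= maxv; ++v) cnt[v + 1] += cnt[v];
  for (int i = 0; i < n; ++i) g.sa[cnt[rank_[i]]++] = i;
  if (n == 1) return;
  for (int k = 1;; k <<= 1) {
    int p = 0;
    for (int i = n - k; i < n; ++i) tmp[p++] = i;
    for (int i = 0; i < n; ++i)
      if (g.sa[i] >= k) tmp[p++] = g.sa[i] - k;
    int m = *std::max_element(rank_.begin(), rank_.end());
    cnt.assign(m + 2, 0);
    for (int i = 0; i < n; ++i) cnt[rank_[i] + 1]++;
    for (int v = 0; v <= m; ++v) cnt[v + 1] += cnt[v];
    for (int i = 0; i < n; ++i) g.sa[cnt[rank_[tmp[i]]]++] = tmp[i];
    new_rank[g.sa[0]] = 0;
    for (int i = 1; i < n; ++i) {
      int a = g.sa[i - 1], b = g.sa[i];
      int a2 = a + k < n ? rank_[a + k] : -1;
      int b2 = b + k < n ? rank_[b + k] : -1;
      bool eq = rank_[a] == rank_[b] && a2 == b2;
      new_rank[b] = new_rank[a] + (eq ? 0 : 1);
    }
    rank_.swap(new_rank);
    if (rank_[g.sa[n - 1]] == n - 1) break;
  }
}

void build_lcp(Gsa& g) {
  const int n = g.n;
  g.rnk.assign(n, 0);
  for (int i = 0; i < n; ++i) g.rnk[g.sa[i]] = i;
  g.lcp.assign(n, 0);
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (g.rnk[i] > 0) {
      int j = g.sa[g.rnk[i] - 1];
      while (i + h < n && j + h < n && g.text[i + h] == g.text[j + h]) ++h;
      g.lcp[g.rnk[i]] = h;
      if (h) --h;
    } else {
      h = 0;
    }
  }
  g.cum1.assign(n + 1, 0);
  for (int i = 0; i < n; ++i)
    g.cum1[i + 1] = g.cum1[i] + (g.doc_set[g.doc_of[g.sa[i]]] == 1 ? 1 : 0);
}

void build_rmq(Gsa& g) {
  const int n = g.n;
  g.logt.assign(n + 1, 0);
  for (int i = 2; i <= n; ++i) g.logt[i] = g.logt[i / 2] + 1;
  int K = g.logt[n] + 1;
  g.st.assign(K, std::vector<int>());
  g.st[0] = g.lcp;
  for (int j = 1; j < K; ++j) {
    g.st[j].resize(n);
    for (int i = 0; i + (1 << j) <= n; ++i)
      g.st[j][i] = std::min(g.st[j - 1][i], g.st[j - 1][i + (1 << (j - 1))]);
  }
}

inline int rmq(const Gsa& g, int l, int r) {  // min of lcp[l..r], l <= r
  int j = g.logt[r - l + 1];
  return std::min(g.st[j][l], g.st[j][r - (1 << j) + 1]);
}

// SA interval of the word text[pos .. pos+k): all suffixes sharing that prefix.
std::pair<int, int> word_interval_rank(const Gsa& g, int r, int k) {
  int a = 0, b = r;
  while (a < b) {
    int mid = (a + b) / 2;
    if (rmq(g, mid + 1, r) >= k) b = mid; else a = mid + 1;
  }
  int lo = a;
  a = r; b = g.n - 1;
  while (a < b) {
    int mid = (a + b + 1) / 2;
    if (rmq(g, r + 1, mid) >= k) a = mid; else b = mid - 1;
  }
  return std::make_pair(lo, a);
}

// ms[p] = length of the longest word starting at p that also occurs somewhere
// in the documents of the other set (the matching statistic against the other
// set); 0 at sentinel positions.
void matching_stats(const Gsa& g, std::vector<int>& ms) {
  const int n = g.n;
  const long INF = 1L << 40;
  ms.assign(n, 0);
  long run[3] = {0, -1, -1};
  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      if (run[1] >= 0 && g.lcp[i] < run[1]) run[1] = g.lcp[i];
      if (run[2] >= 0 && g.lcp[i] < run[2]) run[2] = g.lcp[i];
    }
    int s = g.doc_set[g.doc_of[g.sa[i]]];
    long o = run[3 - s];
    if (o >= 0 && o > ms[g.sa[i]]) ms[g.sa[i]] = static_cast<int>(o);
    run[s] = INF;
  }
  run[1] = -1; run[2] = -1;
  for (int i = n - 1; i >= 0; --i) {
    if (i < n - 1) {
      if (run[1] >= 0 && g.lcp[i + 1] < run[1]) run[1] = g.lcp[i + 1];
      if (run[2] >= 0 && g.lcp[i + 1] < run[2]) run[2] = g.lcp[i + 1];
    }
    int s = g.doc_set[g.doc_of[g.sa[i]]];
    long o = run[3 - s];
    if (o >= 0 && o > ms[g.sa[i]]) ms[g.sa[i]] = static_cast<int>(o);
    run[s] = INF;
  }
}

// Positions whose maximal shared word has an occurrence not contained in a
// longer shared word's occurrence: within each document the reach p + ms[p]
// is non-decreasing, and an occurrence (p, ms[p]) is uncovered exactly when
// its reach strictly exceeds every earlier reach in the same document.
void uncovered_candidates(const Gsa& g, const std::vector<int>& ms,
                          std::vector<std::pair<int, int>>& out) {
  for (int d = 0; d < g.ndoc; ++d) {
    int s = g.doc_start[d], e = s + g.doc_len[d];
    int runmax = -1;
    for (int p = s; p < e; ++p) {
      int m = ms[p];
      int reach = p + m;
      if (m >= 1 && reach > runmax) out.push_back(std::make_pair(p, m));
      if (reach > runmax) runmax = reach;
    }
  }
}

struct Pattern {            // one distinct irredundant word
  int lo, hi, k;            // SA interval and word length
  int minpos;               // earliest global occurrence position
  int occ1, occ2;
  double logpw;
};

// Full pipeline up to the distinct irredundant words, with per-word stats.
void irredundant_core(const CharacterVector& docs, const IntegerVector& dset,
                      const NumericVector& pi, const NumericMatrix& trans,
                      Gsa& g, std::vector<Pattern>& pats) {
  build_text(docs, dset, g);
  build_sa(g);
  build_lcp(g);
  build_rmq(g);
  std::vector<int> ms;
  matching_stats(g, ms);
  std::vector<std::pair<int, int>> cand;
  uncovered_candidates(g, ms, cand);

  double lpi[5], lA[5][5];
  for (int a = 1; a <= 4; ++a) {
    lpi[a] = std::log(pi[a - 1]);
    for (int b = 1; b <= 4; ++b) lA[a][b] = std::log(trans(a - 1, b - 1));
  }

  // Deduplicate candidate occurrences into distinct words: sorted by
  // (length, suffix rank), two candidates of equal length are the same word
  // exactly when every LCP between their ranks is >= the length.
  std::vector<std::pair<int, int>> ck;   // (k, rank)
  ck.reserve(cand.size());
  for (size_t i = 0; i < cand.size(); ++i)
    ck.push_back(std::make_pair(cand[i].second, g.rnk[cand[i].first]));
  std::sort(ck.begin(), ck.end());
  ck.erase(std::unique(ck.begin(), ck.end()), ck.end());
  std::vector<std::pair<int, int>> heads;  // (rank, k) of each distinct word
  for (size_t i = 0; i < ck.size(); ++i) {
    if (i > 0 && ck[i].first == ck[i - 1].first &&
        rmq(g, ck[i - 1].second + 1, ck[i].second) >= ck[i].first)
      continue;                            // same word as the previous entry
    heads.push_back(std::make_pair(ck[i].second, ck[i].first));
  }

  pats.clear();
  pats.reserve(heads.size());
  for (size_t i = 0; i < heads.size(); ++i) {
    Pattern p;
    p.k = heads[i].second;
    std::pair<int, int> iv = word_interval_rank(g, heads[i].first, p.k);
    p.lo = iv.first;
    p.hi = iv.second;
    p.occ1 = g.cum1[p.hi + 1] - g.cum1[p.lo];
    p.occ2 = (p.hi - p.lo + 1) - p.occ1;
    int mp = g.n;
    for (int j = p.lo; j <= p.hi; ++j)
      if (g.sa[j] < mp) mp = g.sa[j];
    p.minpos = mp;
    double lp = lpi[g.text[mp]];
    for (int t = 1; t < p.k; ++t) lp += lA[g.text[mp + t - 1]][g.text[mp + t]];
    p.logpw = lp;
    pats.push_back(p);
  }
}

std::string word_of(const Gsa& g, const Pattern& p) {
  static const char bases[5] = {'?', 'A', 'C', 'G', 'T'};
  std::string w(p.k, '?');
  for (int t = 0; t < p.k; ++t) w[t] = bases[g.text[p.minpos + t]];
  return w;
}

// Priority: longer first, then rarer (smaller p_w), then earlier first
// occurrence, then lexicographically smaller (= smaller SA interval start,
// since equal-length distinct words sort lexicographically with their
// intervals).
struct PriorityLess {
  const std::vector<Pattern>* pats;
  bool operator()(int a, int b) const {
    const Pattern& x = (*pats)[a];
    const Pattern& y = (*pats)[b];
    if (x.k != y.k) return x.k > y.k;
    if (x.logpw != y.logpw) return x.logpw < y.logpw;
    if (x.minpos != y.minpos) return x.minpos < y.minpos;
    return x.lo < y.lo;
  }
};

}  // namespace

// [[Rcpp::export]]
List irredundant_cpp(CharacterVector docs, IntegerVector doc_set) {
  NumericVector pi(4, 0.25);
  NumericMatrix trans(4, 4);
  std::fill(trans.begin(), trans.end(), 0.25);
  Gsa g;
  std::vector<Pattern> pats;
  irredundant_core(docs, doc_set, pi, trans, g, pats);

  int np = static_cast<int>(pats.size());
  CharacterVector words(np);
  IntegerVector len(np), occ1(np), occ2(np);
  size_t nocc = 0;
  for (int i = 0; i < np; ++i) nocc += pats[i].hi - pats[i].lo + 1;
  IntegerVector o_pat(nocc), o_doc(nocc), o_off(nocc), o_set(nocc);
  size_t q = 0;
  for (int i = 0; i < np; ++i) {
    words[i] = word_of(g, pats[i]);
    len[i] = pats[i].k;
    occ1[i] = pats[i].occ1;
    occ2[i] = pats[i].occ2;
    std::vector<int> ps;
    for (int j = pats[i].lo; j <= pats[i].hi; ++j) ps.push_back(g.sa[j]);
    std::sort(ps.begin(), ps.end());
    for (size_t j = 0; j < ps.size(); ++j) {
      int d = g.doc_of[ps[j]];
      o_pat[q] = i + 1;
      o_doc[q] = d + 1;
      o_off[q] = ps[j] - g.doc_start[d];
      o_set[q] = g.doc_set[d];
      ++q;
    }
  }
  return List::create(
      _["word"] = words, _["length"] = len,
      _["occ1"] = occ1, _["occ2"] = occ2,
      _["occ_pattern"] = o_pat, _["occ_doc"] = o_doc,
      _["occ_offset"] = o_off, _["occ_set"] = o_set);
}

// [[Rcpp::export]]
List underlying_cpp(CharacterVector docs, IntegerVector doc_set,
                    NumericVector pi, NumericMatrix trans,
                    bool return_words = false) {
  Gsa g;
  std::vector<Pattern> pats;
  irredundant_core(docs, doc_set, pi, trans, g, pats);
  int np = static_cast<int>(pats.size());

  std::vector<int> ord(np);
  for (int i = 0; i < np; ++i) ord[i] = i;
  PriorityLess cmp;
  cmp.pats = &pats;
  std::sort(ord.begin(), ord.end(), cmp);

  // Greedy location-vector pass: an occurrence is untied iff every one of its
  // cells is still free; untied occurrences are claimed progressively (in
  // position order) so the accepted claims are pairwise disjoint, including
  // between overlapping occurrences of the same word.
  std::vector<uint8_t> occupied(g.n, 0);
  std::vector<int> acc_idx, acc_u1, acc_u2;
  std::vector<int> claim_buf;
  for (int oi = 0; oi < np; ++oi) {
    const Pattern& p = pats[ord[oi]];
    std::vector<int> ps;
    ps.reserve(p.hi - p.lo + 1);
    for (int j = p.lo; j <= p.hi; ++j) ps.push_back(g.sa[j]);
    std::sort(ps.begin(), ps.end());
    claim_buf.clear();
    int u1 = 0, u2 = 0;
    for (size_t j = 0; j < ps.size(); ++j) {
      int pos = ps[j];
      bool free = true;
      for (int c = pos; c < pos + p.k; ++c)
        if (occupied[c]) { free = false; break; }
      if (!free) continue;
      for (int c = pos; c < pos + p.k; ++c) occupied[c] = 1;
      claim_buf.push_back(pos);
      if (g.doc_set[g.doc_of[pos]] == 1) ++u1; else ++u2;
    }
    if (u1 >= 1 && u2 >= 1) {
      acc_idx.push_back(ord[oi]);
      acc_u1.push_back(u1);
      acc_u2.push_back(u2);
    } else {
      for (size_t j = 0; j < claim_buf.size(); ++j)
        for (int c = claim_buf[j]; c < claim_buf[j] + p.k; ++c) occupied[c] = 0;
    }
  }

  int na = static_cast<int>(acc_idx.size());
  IntegerVector len(na), u1v(na), u2v(na), occ1(na), occ2(na);
  NumericVector pw(na);
  CharacterVector words(return_words ? na : 0);
  for (int i = 0; i < na; ++i) {
    const Pattern& p = pats[acc_idx[i]];
    len[i] = p.k;
    u1v[i] = acc_u1[i];
    u2v[i] = acc_u2[i];
    occ1[i] = p.occ1;
    occ2[i] = p.occ2;
    pw[i] = std::exp(p.logpw);
    if (return_words) words[i] = word_of(g, p);
  }
  List out = List::create(
      _["length"] = len, _["untied1"] = u1v, _["untied2"] = u2v,
      _["occ1"] = occ1, _["occ2"] = occ2, _["pw"] = pw,
      _["n_irredundant"] = np);
  if (return_words) out["word"] = words;
  return out;
}
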