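#include <Rcpp.h>
#include <vector>
#include <algorithm>

// Linear-time suffix array construction (SA-IS) over an integer alphabet,
// plus Kasai's linear-time LCP. The input sequence must end with a unique
// sentinel that is strictly smaller than every other symbol; the R wrappers
// append it.

namespace {

typedef std::vector<int> ivec;

inline bool is_lms(const std::vector<bool>& t, int i) {
  return i > 0 && t[i] && !t[i - 1];
}

void get_counts(const ivec& s, ivec& cnt, int K) {
  cnt.assign(K, 0);
  for (size_t i = 0; i < s.size(); ++i) cnt[s[i]]++;
}

void get_buckets(const ivec& cnt, ivec& bkt, bool end) {
  int sum = 0;
  bkt.assign(cnt.size(), 0);
  for (size_t i = 0; i < cnt.size(); ++i) {
    sum += cnt[i];
    bkt[i] = end ? sum : sum - cnt[i];
  }
}

void induce(const ivec& s, ivec& sa, const std::vector<bool>& t, int K) {
  const int n = (int)s.size();
  ivec cnt, bkt;
  get_counts(s, cnt, K);
  // induce L-type from sorted LMS / previous pass
  get_buckets(cnt, bkt, false);
  for (int i = 0; i < n; ++i) {
    int j = sa[i] - 1;
    if (sa[i] > 0 && !t[j]) sa[bkt[s[j]]++] = j;
  }
  // induce S-type right-to-left
  get_buckets(cnt, bkt, true);
  for (int i = n - 1; i >= 0; --i) {
    int j = sa[i] - 1;
    if (sa[i] > 0 && t[j]) sa[--bkt[s[j]]] = j;
  }
}

// s: values in [0, K), s[n-1] == 0 is the unique sentinel.
void sais(const ivec& s, ivec& sa, int K) {
  const int n = (int)s.size();
  sa.assign(n, -1);
  if (n == 1) { sa[0] = 0; return; }
  std::vector<bool> t(n);
  t[n - 1] = true;
  for (int i = n - 2; i >= 0; --i)
    t[i] = (s[i] < s[i + 1]) || (s[i] == s[i + 1] && t[i + 1]);

  ivec cnt, bkt;
  get_counts(s, cnt, K);
  get_buckets(cnt, bkt, true);
  // stage 1: place LMS suffixes at bucket ends, induce-sort LMS substrings
  for (int i = 1; i < n; ++i)
    if (is_lms(t, i)) sa[--bkt[s[i]]] = i;
  induce(s, sa, t, K);

  // compact sorted LMS positions into the front of sa
  int n1 = 0;
  for (int i = 0; i < n; ++i)
    if (is_lms(t, sa[i])) sa[n1++] = sa[i];

  // name LMS substrings in sa[n1..n)
  std::fill(sa.begin() + n1, sa.end(), -1);
  int name = 0, prev = -1;
  for (int i = 0; i < n1; ++i) {
    int pos = sa[i];
    bool diff = false;
    if (prev < 0) {
      diff = true;
    } else {
      for (int d = 0; d < n; ++d) {
        if (s[pos + d] != s[prev + d] || t[pos + d] != t[prev + d]) {
          diff = true;
          break;
        }
        if (d > 0 && (is_lms(t, pos + d) || is_lms(t, prev + d))) {
          if (!(is_lms(t, pos + d) && is_lms(t, prev + d))) diff = true;
          break;
        }
      }
    }
    if (diff) { ++name; prev = pos; }
    sa[n1 + pos / 2] = name - 1;
  }
  ivec s1;
  s1.reserve(n1);
  ivec pos1;
  pos1.reserve(n1);
  for (int i = n1; i < n; ++i)
    if (sa[i] >= 0) s1.push_back(sa[i]);
  for (int i = 1; i < n; ++i)
    if (is_lms(t, i)) pos1.push_back(i);

  // stage 2: sort LMS suffixes (recurse if names are not yet unique)
  ivec sa1;
  if (name < n1) {
    sais(s1, sa1, name);
  } else {
    sa1.assign(n1, 0);
    for (int i = 0; i < n1; ++i) sa1[s1[i]] = i;
  }

  // stage 3: induce the full SA from sorted LMS suffixes
  sa.assign(n, -1);
  get_buckets(cnt, bkt, true);
  for (int i = n1 - 1; i >= 0; --i) {
    int j = pos1[sa1[i]];
    sa[--bkt[s[j]]] = j;
  }
  induce(s, sa, t, K);
}

} // namespace

// [[Rcpp::export(name = ".sais_sa")]]
Rcpp::IntegerVector sais_sa(Rcpp::IntegerVector codes) {
  // codes: values >= 1; a 0 sentinel is appended here
  const int n = codes.size();
  ivec s(n + 1);
  int K = 1;
  for (int i = 0; i < n; ++i) {
    if (codes[i] < 1) Rcpp::stop("symbol codes must be >= 1");
    s[i] = codes[i];
    if (codes[i] + 1 > K) K = codes[i] + 1;
  }
  s[n] = 0;
  ivec sa;
  sais(s, sa, K);
  // drop the sentinel suffix (always rank 0)
  Rcpp::IntegerVector out(n);
  for (int i = 1; i <= n; ++i) out[i - 1] = sa[i];
  return out;
}

// [[Rcpp::export(name = ".kasai_lcp")]]
Rcpp::IntegerVector kasai_lcp(Rcpp::IntegerVector codes, Rcpp::IntegerVector sa) {
  const int n = codes.size();
  if (sa.size() != n) Rcpp::stop("suffix array length must match text length");
  ivec rank(n), lcp(n, 0);
  for (int i = 0; i < n; ++i) rank[sa[i]] = i;
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (rank[i] > 0) {
      int j = sa[rank[i] - 1];
      while (i + h < n && j + h < n && codes[i + h] == codes[j + h]) ++h;
      lcp[rank[i]] = h;
      if (h > 0) --h;
    } else {
      h = 0;
    }
  }
  return Rcpp::IntegerVector(lcp.begin(), lcp.end());
}
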