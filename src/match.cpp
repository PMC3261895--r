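// Core string-matching engine: exhaustive window scans and a pigeonhole
// seed index for counting k-mer occurrences within m substitutions, on
// the forward strand and (in DNA mode) the reverse complement.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <climits>

using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'N': return 'N';
    default:  return '\0';
  }
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    char x = comp_base(r[i]);
    if (x == '\0')
      stop("invalid base '%s' in DNA string", std::string(1, r[i]).c_str());
    r[i] = x;
  }
  return r;
}

struct GenomeView {
  std::vector<std::string> seqs;
  std::vector<int> offs;   // global 0-based start of each contig
  std::vector<int> cid;    // contig id per global position
  long long n;
  bool dna;

  void load(const CharacterVector& contigs, bool dna_) {
    dna = dna_;
    n = 0;
    for (int i = 0; i < contigs.size(); ++i) {
      std::string s = as<std::string>(contigs[i]);
      offs.push_back((int)n);
      n += (long long)s.size();
      seqs.push_back(std::move(s));
    }
    if (n > INT_MAX) stop("reference too large for this build");
    cid.resize((size_t)n);
    for (size_t c = 0; c < seqs.size(); ++c)
      std::fill(cid.begin() + offs[c],
                cid.begin() + offs[c] + seqs[c].size(), (int)c);
  }

  // Hamming(window at g, pat) <= m, early exit.  Window assumed in-bounds.
  inline bool ham_le(int g, const std::string& pat, int m) const {
    int c = cid[g], p = g - offs[c];
    const char* s = seqs[c].data() + p;
    int bad = 0;
    for (size_t j = 0; j < pat.size(); ++j)
      if (s[j] != pat[j] && ++bad > m) return false;
    return true;
  }
};

// Window validity at length k: fits in its contig and, in DNA mode,
// contains no N (an N window can never match anything).
static std::vector<char> valid_windows(const GenomeView& G, int k) {
  std::vector<char> v((size_t)G.n, 0);
  for (size_t c = 0; c < G.seqs.size(); ++c) {
    const std::string& s = G.seqs[c];
    int L = (int)s.size();
    if (L < k) continue;
    if (G.dna) {
      std::vector<int> pre(L + 1, 0);
      for (int i = 0; i < L; ++i) pre[i + 1] = pre[i] + (s[i] == 'N');
      for (int p = 0; p + k <= L; ++p)
        if (pre[p + k] - pre[p] == 0) v[G.offs[c] + p] = 1;
    } else {
      for (int p = 0; p + k <= L; ++p) v[G.offs[c] + p] = 1;
    }
  }
  return v;
}

static void brute_query(const GenomeView& G, const std::vector<char>& valid,
                        const std::string& q, int m,
                        long long& count, std::vector<int>& P) {
  count = 0;
  P.clear();
  std::string qr;
  if (G.dna) {
    if (q.find('N') != std::string::npos) return;
    qr = cpp_revcomp(q);
  }
  for (long long g = 0; g < G.n; ++g) {
    if (!valid[(size_t)g]) continue;
    bool hf = G.ham_le((int)g, q, m);
    bool hr = G.dna ? G.ham_le((int)g, qr, m) : false;
    if (hf) ++count;
    if (hr) ++count;
    if (hf || hr) P.push_back((int)g);
  }
}

// Pigeonhole seed index: the query is split into m+1 chunks; any window
// within m mismatches matches at least one chunk exactly, so hash lookups
// on the chunks enumerate a superset of candidates, verified by Hamming.
struct SeedIndex {
  const GenomeView& G;
  int k, m;
  std::vector<int> coff, clen;
  std::vector< std::unordered_map<std::string, std::vector<int> > > maps;
  std::vector<char> valid;
  std::vector<int> stamp;
  int stamp_id;

  SeedIndex(const GenomeView& g, int k_, int m_)
      : G(g), k(k_), m(m_), stamp_id(0) {
    valid = valid_windows(G, k);
    int parts = m + 1;
    int base = k / parts, rem = k % parts, off = 0;
    for (int c = 0; c < parts; ++c) {
      int len = base + (c < rem ? 1 : 0);
      coff.push_back(off);
      clen.push_back(len);
      off += len;
    }
    maps.resize(parts);
    for (size_t c = 0; c < G.seqs.size(); ++c) {
      const std::string& s = G.seqs[c];
      for (int p = 0; p + k <= (int)s.size(); ++p) {
        int gp = G.offs[c] + p;
        if (!valid[gp]) continue;
        for (int ch = 0; ch < parts; ++ch)
          maps[ch][s.substr(p + coff[ch], clen[ch])].push_back(gp);
      }
    }
    stamp.assign((size_t)G.n, 0);
  }

  // All windows with Hamming(window, pat) <= m (forward comparison only).
  void gather(const std::string& pat, std::vector<int>& hits) {
    ++stamp_id;
    for (size_t ch = 0; ch < maps.size(); ++ch) {
      std::unordered_map<std::string, std::vector<int> >::const_iterator it =
          maps[ch].find(pat.substr(coff[ch], clen[ch]));
      if (it == maps[ch].end()) continue;
      const std::vector<int>& cand = it->second;
      for (size_t j = 0; j < cand.size(); ++j) {
        int gp = cand[j];
        if (stamp[gp] == stamp_id) continue;
        stamp[gp] = stamp_id;
        if (G.ham_le(gp, pat, m)) hits.push_back(gp);
      }
    }
  }

  void query(const std::string& q, long long& count, std::vector<int>& P) {
    count = 0;
    P.clear();
    if (G.dna && q.find('N') != std::string::npos) return;
    std::vector<int> hf, hr;
    gather(q, hf);
    if (G.dna) gather(cpp_revcomp(q), hr);
    count = (long long)hf.size() + (long long)hr.size();
    P = hf;
    P.insert(P.end(), hr.begin(), hr.end());
    std::sort(P.begin(), P.end());
    P.erase(std::unique(P.begin(), P.end()), P.end());
  }
};

// [[Rcpp::export]]
List cpp_count_matches(CharacterVector contigs, std::string query, int m,
                       bool dna) {
  GenomeView G;
  G.load(contigs, dna);
  std::vector<char> valid = valid_windows(G, (int)query.size());
  long long count;
  std::vector<int> P;
  brute_query(G, valid, query, m, count, P);
  return List::create(_["count"] = (double)count, _["positions"] = wrap(P));
}

// [[Rcpp::export]]
List cpp_indexed_matches(CharacterVector contigs, CharacterVector queries,
                         int m, bool dna) {
  GenomeView G;
  G.load(contigs, dna);
  if (queries.size() == 0) return List(0);
  int k = (int)as<std::string>(queries[0]).size();
  SeedIndex idx(G, k, m);
  List out(queries.size());
  long long count;
  std::vector<int> P;
  for (int i = 0; i < queries.size(); ++i) {
    std::string q = as<std::string>(queries[i]);
    if ((int)q.size() != k)
      stop("all queries in one batch must share the same length");
    idx.query(q, count, P);
    out[i] = List::create(_["count"] = (double)count,
                          _["positions"] = wrap(P));
  }
  return out;
}

// Frequency computation.  With t = Inf (disabled) every valid position is
// queried directly, which yields exact counts; with finite t, whenever a
// query's match-position set P has |P| >= t its occurrence count is
// propagated to all members of P (max rule on positions already set), and
// positions found non-zero are skipped.
// [[Rcpp::export]]
IntegerVector cpp_frequency_track(CharacterVector contigs, int k, int m,
                                  double t, bool dna) {
  GenomeView G;
  G.load(contigs, dna);
  SeedIndex idx(G, k, m);
  IntegerVector F((int)G.n);  // zero-initialised
  bool approx = R_finite(t);
  long long count;
  std::vector<int> P;
  long long done = 0;
  for (size_t c = 0; c < G.seqs.size(); ++c) {
    const std::string& s = G.seqs[c];
    for (int p = 0; p + k <= (int)s.size(); ++p) {
      int g = G.offs[c] + p;
      if (!idx.valid[g]) continue;
      if (F[g] != 0) continue;
      if ((++done & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
      idx.query(s.substr(p, k), count, P);
      int cnt = count > INT_MAX ? INT_MAX : (int)count;
      F[g] = cnt;
      if (approx && (double)P.size() >= t) {
        for (size_t j = 0; j < P.size(); ++j) {
          int g2 = P[j];
          F[g2] = (F[g2] == 0) ? cnt : std::max(F[g2], cnt);
        }
      }
    }
  }
  return F;
}

// Exhaustive per-position frequencies at the requested global positions;
// the independent reference implementation used to validate the indexed
// engine and the propagation algorithm.
// [[Rcpp::export]]
IntegerVector cpp_brute_frequencies(CharacterVector contigs, int k, int m,
                                    bool dna, IntegerVector at) {
  GenomeView G;
  G.load(contigs, dna);
  std::vector<char> valid = valid_windows(G, k);
  IntegerVector out(at.size());
  long long count;
  std::vector<int> P;
  for (int i = 0; i < at.size(); ++i) {
    int g = at[i];
    if (g < 0 || g >= (int)G.n) stop("position out of range");
    if ((i & 0xFF) == 0) Rcpp::checkUserInterrupt();
    if (!valid[g]) {
      out[i] = 0;
      continue;
    }
    int c = G.cid[g], p = g - G.offs[c];
    brute_query(G, valid, G.seqs[c].substr(p, k), m, count, P);
    out[i] = count > INT_MAX ? INT_MAX : (int)count;
  }
  return out;
}
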