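// Compiled kernels: k-mer counting, suffix-prefix overlap DP, and the
// seed-and-extend read mapper. Everything here is deterministic.
#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string rc(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (auto& c : out) c = comp(c);
  return out;
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  R_xlen_t n = x.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    out[i] = rc(as<std::string>(x[i]));
  }
  return out;
}

// Count every window of k consecutive non-N bases across all reads.
// canonical: count min(kmer, revcomp(kmer)) instead of the forward form.
// [[Rcpp::export]]
List count_kmers_cpp(CharacterVector reads, int k, bool canonical) {
  std::unordered_map<std::string, int> tab;
  tab.reserve(1 << 20);
  long long total = 0;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    if (reads[i] == NA_STRING) continue;
    std::string s = as<std::string>(reads[i]);
    int L = (int)s.size();
    if (L < k) continue;
    // next position at or after j that is N, to skip N-spanning windows fast
    int next_n = -1;
    for (int j = 0; j + k <= L; ++j) {
      if (next_n < j) {
        next_n = L; // none found yet beyond j
        for (int t = j; t < L; ++t) if (s[t] == 'N') { next_n = t; break; }
      }
      if (next_n < j + k) { j = next_n; continue; } // loop ++ moves past the N
      std::string km = s.substr(j, k);
      if (canonical) {
        std::string r = rc(km);
        if (r < km) km = r;
      }
      ++tab[km];
      ++total;
    }
  }
  std::vector<std::string> keys;
  keys.reserve(tab.size());
  for (auto& kv : tab) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  CharacterVector kmers(keys.size());
  IntegerVector counts(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    kmers[i] = keys[i];
    counts[i] = tab[keys[i]];
  }
  return List::create(_["kmer"] = kmers, _["count"] = counts,
                      _["total"] = (double)total);
}

// Suffix(a)-vs-prefix(b) overlap by edit-distance DP.
// dp[x][y] = min edits aligning some suffix of a[0..x) to b[0..y)
// (row 0 of a is free: the alignment may start anywhere in a).
// Returns c(best_overlap_len, best_edits, containment_edits) where
//   best_overlap_len: the qualifying y >= min_len (dp[la][y] / y < max_rate)
//   with the lowest edit fraction, longest first among ties (0 if none);
//   picking by edit fraction rather than raw length keeps an exact junction
//   from being stretched by a qualifying spurious indel;
//   containment_edits: min over x of dp[x][lb] (b aligned entirely within a),
//                      -1 if b is empty.
// [[Rcpp::export]]
IntegerVector overlap_dp_cpp(std::string a, std::string b,
                             int min_len, double max_rate) {
  int la = (int)a.size(), lb = (int)b.size();
  std::vector<int> prev(lb + 1), cur(lb + 1);
  for (int y = 0; y <= lb; ++y) prev[y] = y; // x = 0: align b prefix to nothing
  int cont = (lb > 0) ? prev[lb] : -1;
  for (int x = 1; x <= la; ++x) {
    cur[0] = 0; // free start anywhere in a
    for (int y = 1; y <= lb; ++y) {
      int sub = prev[y - 1] + (a[x - 1] == b[y - 1] ? 0 : 1);
      int del = prev[y] + 1;
      int ins = cur[y - 1] + 1;
      cur[y] = std::min(sub, std::min(del, ins));
    }
    if (lb > 0 && cur[lb] < cont) cont = cur[lb];
    std::swap(prev, cur);
  }
  int bestL = 0, bestE = -1;
  for (int y = lb; y >= min_len && y >= 1; --y) {
    int e = prev[y];
    if ((double)e / (double)y >= max_rate) continue;
    // lower edit fraction wins; compare e/y < bestE/bestL without division
    if (bestL == 0 || (long long)e * bestL < (long long)bestE * y) {
      bestL = y; bestE = e;
    }
  }
  return IntegerVector::create(bestL, bestE, cont);
}

// ---- seed-and-extend mapper ----------------------------------------------

struct Hit { int contig, start, end, edits, span, strand; };

// Smith-Waterman (match +1, mismatch -3, gap -5) of read vs a contig window;
// returns aligned contig span (w0-based), read span and edit count of the
// best-scoring local alignment, via traceback.
static bool sw_extend(const std::string& rd, const std::string& win,
                      int& c0, int& c1, int& edits, int& rspan) {
  const int MATCH = 1, MIS = -3, GAP = -5;
  int n = (int)rd.size(), m = (int)win.size();
  if (n == 0 || m == 0) return false;
  std::vector<int> H((n + 1) * (m + 1), 0);
  std::vector<unsigned char> tb((n + 1) * (m + 1), 0); // 0 stop,1 diag,2 up,3 left
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int sc = (rd[i - 1] == win[j - 1] && rd[i - 1] != 'N') ? MATCH : MIS;
      int d = H[(i - 1) * (m + 1) + j - 1] + sc;
      int u = H[(i - 1) * (m + 1) + j] + GAP;
      int l = H[i * (m + 1) + j - 1] + GAP;
      int v = std::max(0, std::max(d, std::max(u, l)));
      unsigned char t = 0;
      if (v == d && v > 0) t = 1;
      else if (v == u && v > 0) t = 2;
      else if (v == l && v > 0) t = 3;
      H[i * (m + 1) + j] = v;
      tb[i * (m + 1) + j] = t;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  if (best <= 0) return false;
  int i = bi, j = bj, e = 0;
  while (i > 0 && j > 0 && tb[i * (m + 1) + j] != 0) {
    unsigned char t = tb[i * (m + 1) + j];
    if (t == 1) {
      if (rd[i - 1] != win[j - 1]) ++e;
      --i; --j;
    } else if (t == 2) { ++e; --i; }
    else { ++e; --j; }
  }
  c0 = j;        // 0-based start in window
  c1 = bj;       // 0-based exclusive end in window
  edits = e;
  rspan = bi - i;
  return true;
}

// Map reads to contigs: exact seeds of length seed_len located by a hash
// index, candidates grouped by (contig, strand, diagonal cluster), extended
// by local alignment; a placement is kept when its aligned read span is at
// least min_span and its edit fraction is at most max_err.
// Coordinates returned are 1-based closed on the forward contig strand.
// [[Rcpp::export]]
DataFrame map_reads_cpp(CharacterVector reads, CharacterVector contigs,
                        int seed_len, double max_err, int min_span) {
  std::unordered_map<std::string, std::vector<std::pair<int, int>>> index;
  std::vector<std::string> ctg(contigs.size());
  for (R_xlen_t c = 0; c < contigs.size(); ++c) {
    ctg[c] = as<std::string>(contigs[c]);
    const std::string& s = ctg[c];
    for (int p = 0; p + seed_len <= (int)s.size(); ++p) {
      std::string seed = s.substr(p, seed_len);
      if (seed.find('N') != std::string::npos) continue;
      index[seed].push_back({(int)c, p});
    }
  }
  std::vector<int> out_read, out_contig, out_start, out_end, out_edits;
  std::vector<int> out_strand;
  const int PAD = 8;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string fw = as<std::string>(reads[r]);
    for (int strand = 0; strand < 2; ++strand) {
      std::string s = strand == 0 ? fw : rc(fw);
      int L = (int)s.size();
      if (L < seed_len) continue;
      // candidate diagonals per contig
      std::unordered_map<int, std::vector<int>> diags;
      std::vector<int> offs;
      for (int off = 0; off + seed_len <= L; off += seed_len) offs.push_back(off);
      if (offs.empty() || offs.back() != L - seed_len) offs.push_back(L - seed_len);
      for (int off : offs) {
        std::string seed = s.substr(off, seed_len);
        if (seed.find('N') != std::string::npos) continue;
        auto it = index.find(seed);
        if (it == index.end()) continue;
        for (auto& cp : it->second) diags[cp.first].push_back(cp.second - off);
      }
      for (auto& kv : diags) {
        int c = kv.first;
        std::vector<int>& ds = kv.second;
        std::sort(ds.begin(), ds.end());
        ds.erase(std::unique(ds.begin(), ds.end()), ds.end());
        size_t i = 0;
        while (i < ds.size()) {
          size_t j = i;
          while (j + 1 < ds.size() && ds[j + 1] - ds[j] <= PAD) ++j;
          int dlo = ds[i], dhi = ds[j];
          int clen = (int)ctg[c].size();
          int w0 = std::max(0, dlo - PAD);
          int w1 = std::min(clen, dhi + L + PAD);
          if (w1 > w0) {
            std::string win = ctg[c].substr(w0, w1 - w0);
            int c0, c1, e, rspan;
            if (sw_extend(s, win, c0, c1, e, rspan) &&
                rspan >= min_span &&
                (double)e <= max_err * (double)rspan) {
              out_read.push_back((int)r + 1);
              out_contig.push_back(c + 1);
              out_start.push_back(w0 + c0 + 1); // 1-based
              out_end.push_back(w0 + c1);       // closed
              out_strand.push_back(strand);
              out_edits.push_back(e);
            }
          }
          i = j + 1;
        }
      }
    }
  }
  CharacterVector strands(out_strand.size());
  for (size_t i = 0; i < out_strand.size(); ++i)
    strands[i] = out_strand[i] == 0 ? "+" : "-";
  return DataFrame::create(
    _["read"] = out_read, _["contig"] = out_contig,
    _["start"] = out_start, _["end"] = out_end,
    _["strand"] = strands, _["edits"] = out_edits,
    _["stringsAsFactors"] = false);
}

// Full Smith-Waterman score/span with configurable scores; used by the
// evaluation module for small inputs when Biostrings is bypassed in tests.
// Returns c(score, q0, q1, s0, s1) with 1-based closed coordinates,
// or zeros when the best score is <= 0.
// [[Rcpp::export]]
NumericVector local_align_cpp(std::string q, std::string s,
                              double match, double mismatch, double gap) {
  int n = (int)q.size(), m = (int)s.size();
  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<unsigned char> tb((n + 1) * (m + 1), 0);
  double best = 0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double sc = (q[i - 1] == s[j - 1] && q[i - 1] != 'N') ? match : mismatch;
      double d = H[(i - 1) * (m + 1) + j - 1] + sc;
      double u = H[(i - 1) * (m + 1) + j] + gap;
      double l = H[i * (m + 1) + j - 1] + gap;
      double v = std::max(0.0, std::max(d, std::max(u, l)));
      unsigned char t = 0;
      if (v > 0) { if (v == d) t = 1; else if (v == u) t = 2; else t = 3; }
      H[i * (m + 1) + j] = v;
      tb[i * (m + 1) + j] = t;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  if (best <= 0) return NumericVector::create(0, 0, 0, 0, 0);
  int i = bi, j = bj;
  while (i > 0 && j > 0 && tb[i * (m + 1) + j] != 0) {
    unsigned char t = tb[i * (m + 1) + j];
    if (t == 1) { --i; --j; } else if (t == 2) { --i; } else { --j; }
  }
  return NumericVector::create(best, i + 1, bi, j + 1, bj);
}
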