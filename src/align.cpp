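#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <string>
using namespace Rcpp;

// Banded local (Smith-Waterman) alignment with affine gaps.
// Scoring convention: gap_open is the cost of the FIRST gapped base,
// gap_ext of each additional one (a length-L gap costs gap_open+(L-1)*gap_ext).
// Identity = matching columns / aligned columns; terminal gaps never appear
// in a local alignment, matching the documented identity definition.

static const int NEG = -1000000000;

struct Aln {
  int score, matches, cols;
  int qstart, qend, sstart, send; // 1-based inclusive; qend<qstart => empty
  Aln() : score(0), matches(0), cols(0), qstart(1), qend(0), sstart(1), send(0) {}
};

// traceback byte: bits 0-1 M origin (0 start,1 M,2 X,3 Y),
// bit 2 X origin (0 M,1 X), bit 3 Y origin (0 M,1 Y)
static Aln sw_align(const char *q, int m, const char *s, int n,
                    int match, int mismatch, int gap_open, int gap_ext,
                    int band) {
  Aln out;
  if (m == 0 || n == 0) return out;
  if (band < 0) band = std::max(m, n);
  static std::vector<int> M, X, Y;
  static std::vector<unsigned char> TB;
  size_t sz = (size_t)(m + 1) * (n + 1);
  if (M.size() < sz) { M.resize(sz); X.resize(sz); Y.resize(sz); TB.resize(sz); }
  const int W = n + 1;
#define IDX(i, j) ((size_t)(i) * W + (j))
  // row 0 padding within reach of row 1
  {
    int hi = std::min(n, 1 + band);
    for (int j = 0; j <= hi; ++j) { M[IDX(0, j)] = 0; X[IDX(0, j)] = NEG; Y[IDX(0, j)] = NEG; }
  }
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(1, i - band), jhi = std::min(n, i + band);
    if (jlo > jhi) continue;
    // pad this row's left edge and (for the diagonal read of row i+1) right edge
    if (jlo - 1 >= 0) { M[IDX(i, jlo - 1)] = 0; X[IDX(i, jlo - 1)] = NEG; Y[IDX(i, jlo - 1)] = NEG; }
    if (jhi + 1 <= n) { M[IDX(i, jhi + 1)] = 0; X[IDX(i, jhi + 1)] = NEG; Y[IDX(i, jhi + 1)] = NEG; }
    for (int j = jlo; j <= jhi; ++j) {
      size_t c = IDX(i, j), d = IDX(i - 1, j - 1), u = IDX(i - 1, j), l = IDX(i, j - 1);
      int sub = (q[i - 1] == s[j - 1]) ? match : mismatch;
      // M: diagonal from best of {0, M, X, Y}
      int mo = 0, dbest = 0;
      if (M[d] > dbest) { dbest = M[d]; mo = 1; }
      if (X[d] > dbest) { dbest = X[d]; mo = 2; }
      if (Y[d] > dbest) { dbest = Y[d]; mo = 3; }
      M[c] = dbest + sub;
      // X: gap in subject (consume query base)
      int xo = 0, xv = (M[u] > NEG / 2) ? M[u] + gap_open : NEG;
      int xe = (X[u] > NEG / 2) ? X[u] + gap_ext : NEG;
      if (xe > xv) { xv = xe; xo = 1; }
      X[c] = xv;
      // Y: gap in query (consume subject base)
      int yo = 0, yv = (M[l] > NEG / 2) ? M[l] + gap_open : NEG;
      int ye = (Y[l] > NEG / 2) ? Y[l] + gap_ext : NEG;
      if (ye > yv) { yv = ye; yo = 1; }
      Y[c] = yv;
      TB[c] = (unsigned char)(mo | (xo << 2) | (yo << 3));
      if (M[c] > best) { best = M[c]; bi = i; bj = j; }
    }
  }
  if (best <= 0) return out;
  out.score = best; out.qend = bi; out.send = bj;
  int i = bi, j = bj, state = 0; // 0=M,1=X,2=Y
  while (true) {
    size_t c = IDX(i, j);
    unsigned char t = TB[c];
    if (state == 0) {
      out.cols++;
      if (q[i - 1] == s[j - 1]) out.matches++;
      int mo = t & 3;
      int pi = i - 1, pj = j - 1;
      if (mo == 0) { out.qstart = i; out.sstart = j; break; }
      state = mo - 1; i = pi; j = pj;
    } else if (state == 1) { // X: query base vs gap
      out.cols++;
      state = ((t >> 2) & 1) ? 1 : 0;
      i = i - 1;
    } else { // Y: gap vs subject base
      out.cols++;
      state = ((t >> 3) & 1) ? 1 : 0;
      j = j - 1;
    }
  }
#undef IDX
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_align(std::string q, std::string s,
                        int match = 1, int mismatch = -2,
                        int gap_open = -5, int gap_ext = -2,
                        int band = -1) {
  Aln a = sw_align(q.c_str(), (int)q.size(), s.c_str(), (int)s.size(),
                   match, mismatch, gap_open, gap_ext, band);
  double id = a.cols > 0 ? (double)a.matches / a.cols : 0.0;
  double cov = q.size() > 0 && a.qend >= a.qstart
                   ? (double)(a.qend - a.qstart + 1) / q.size()
                   : 0.0;
  int minlen = std::min((int)q.size(), (int)s.size());
  int span = std::max(a.cols, minlen);
  double gid = span > 0 ? (double)a.matches / span : 0.0;
  return NumericVector::create(
      _["score"] = a.score, _["matches"] = a.matches, _["cols"] = a.cols,
      _["identity"] = id, _["identity_global"] = gid, _["coverage"] = cov,
      _["qstart"] = a.qstart, _["qend"] = a.qend,
      _["sstart"] = a.sstart, _["send"] = a.send);
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// distinct k-mers of a sequence, 2-bit encoded (k <= 15)
static void kmer_set(const std::string &s, int k, std::vector<uint32_t> &out) {
  out.clear();
  int n = (int)s.size();
  if (n < k) return;
  uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  uint32_t cur = 0;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int b = base_code(s[i]);
    if (b < 0) { run = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint32_t)b) & mask;
    if (++run >= k) out.push_back(cur);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
}

// Rank references by shared distinct k-mers, align the top candidates, return
// up to top_n alignments per query ordered by (score desc, ref index asc).
// band_extra: band = band_extra + |len(q) - len(ref)|.
// [[Rcpp::export]]
DataFrame cpp_search(CharacterVector queries, CharacterVector refs,
                     int k = 8, int top_n = 2,
                     int match = 1, int mismatch = -2,
                     int gap_open = -5, int gap_ext = -2,
                     int band_extra = 16) {
  int nr = refs.size(), nq = queries.size();
  std::vector<std::string> rseq(nr);
  std::unordered_map<uint32_t, std::vector<int>> postings;
  std::vector<uint32_t> tmp;
  for (int r = 0; r < nr; ++r) {
    rseq[r] = as<std::string>(refs[r]);
    kmer_set(rseq[r], k, tmp);
    for (uint32_t km : tmp) postings[km].push_back(r);
  }
  std::vector<int> counts(nr, 0);
  std::vector<int> touched;
  std::vector<int> q_out; std::vector<int> r_out; std::vector<int> rank_out;
  std::vector<double> sc_out, id_out, cov_out, sh_out;
  for (int qi = 0; qi < nq; ++qi) {
    std::string qs = as<std::string>(queries[qi]);
    kmer_set(qs, k, tmp);
    touched.clear();
    for (uint32_t km : tmp) {
      auto it = postings.find(km);
      if (it == postings.end()) continue;
      for (int r : it->second) {
        if (counts[r] == 0) touched.push_back(r);
        counts[r]++;
      }
    }
    std::sort(touched.begin(), touched.end(), [&](int a, int b) {
      if (counts[a] != counts[b]) return counts[a] > counts[b];
      return a < b;
    });
    int ncand = std::min((int)touched.size(), top_n);
    std::vector<std::pair<Aln, int>> alns;
    for (int c = 0; c < ncand; ++c) {
      int r = touched[c];
      int band = band_extra + std::abs((int)qs.size() - (int)rseq[r].size());
      Aln a = sw_align(qs.c_str(), (int)qs.size(), rseq[r].c_str(),
                       (int)rseq[r].size(), match, mismatch, gap_open,
                       gap_ext, band);
      alns.push_back(std::make_pair(a, r));
    }
    std::stable_sort(alns.begin(), alns.end(),
                     [](const std::pair<Aln, int> &a, const std::pair<Aln, int> &b) {
                       if (a.first.score != b.first.score)
                         return a.first.score > b.first.score;
                       return a.second < b.second;
                     });
    for (size_t c = 0; c < alns.size(); ++c) {
      const Aln &a = alns[c].first;
      q_out.push_back(qi + 1);
      r_out.push_back(alns[c].second + 1);
      rank_out.push_back((int)c + 1);
      sc_out.push_back(a.score);
      id_out.push_back(a.cols > 0 ? (double)a.matches / a.cols : 0.0);
      cov_out.push_back(qs.size() > 0 && a.qend >= a.qstart
                            ? (double)(a.qend - a.qstart + 1) / qs.size()
                            : 0.0);
      sh_out.push_back(counts[alns[c].second]);
    }
    for (int r : touched) counts[r] = 0;
  }
  return DataFrame::create(
      _["query"] = q_out, _["ref"] = r_out, _["rank"] = rank_out,
      _["score"] = sc_out, _["identity"] = id_out, _["coverage"] = cov_out,
      _["shared_kmers"] = sh_out, _["stringsAsFactors"] = false);
}

// Greedy clustering of reads (already sorted, highest quality first) against
// accumulating representatives. Candidates ordered by shared distinct k-mers;
// a read joins the first representative reaching the identity threshold, new
// representatives are founded after `maxrejects` failed alignments (UCLUST-
// style reject cap). The join criterion normalizes matches by the full span
// max(aligned columns, min(sequence lengths)) so that short spurious local
// matches between unrelated sequences can never satisfy the threshold; it
// implies plain alignment identity >= threshold. Returns 1-based OTU index
// per read, in founding order.
// [[Rcpp::export]]
IntegerVector cpp_greedy_cluster(CharacterVector seqs, double threshold = 0.96,
                                 int k = 8, int maxrejects = 32,
                                 int match = 1, int mismatch = -2,
                                 int gap_open = -5, int gap_ext = -2,
                                 int band_extra = 16) {
  int n = seqs.size();
  IntegerVector assign(n);
  std::unordered_map<uint32_t, std::vector<int>> postings; // kmer -> rep ids
  std::vector<std::string> repseq;
  std::vector<int> counts; // per-rep shared kmer counts
  std::vector<int> touched;
  std::vector<uint32_t> tmp;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    kmer_set(s, k, tmp);
    touched.clear();
    for (uint32_t km : tmp) {
      auto it = postings.find(km);
      if (it == postings.end()) continue;
      for (int r : it->second) {
        if (counts[r] == 0) touched.push_back(r);
        counts[r]++;
      }
    }
    std::sort(touched.begin(), touched.end(), [&](int a, int b) {
      if (counts[a] != counts[b]) return counts[a] > counts[b];
      return a < b;
    });
    int hit = -1, rejects = 0;
    for (int r : touched) {
      int band = band_extra + std::abs((int)s.size() - (int)repseq[r].size());
      Aln a = sw_align(s.c_str(), (int)s.size(), repseq[r].c_str(),
                       (int)repseq[r].size(), match, mismatch, gap_open,
                       gap_ext, band);
      int span = std::max(a.cols,
                          std::min((int)s.size(), (int)repseq[r].size()));
      double id = span > 0 ? (double)a.matches / span : 0.0;
      if (id >= threshold) { hit = r; break; }
      if (++rejects >= maxrejects) break;
    }
    for (int r : touched) counts[r] = 0;
    if (hit >= 0) {
      assign[i] = hit + 1;
    } else {
      int r = (int)repseq.size();
      repseq.push_back(s);
      counts.push_back(0);
      for (uint32_t km : tmp) postings[km].push_back(r);
      assign[i] = r + 1;
    }
  }
  return assign;
}
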