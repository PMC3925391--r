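#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// mean Phred score of each quality string (offset-encoded, Sanger = 33)
// [[Rcpp::export]]
NumericVector cpp_mean_phred(CharacterVector quals, int offset = 33) {
  int n = quals.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (quals[i] == NA_STRING) { out[i] = NA_REAL; continue; }
    const char *s = CHAR(quals[i]);
    long sum = 0; int len = 0;
    for (; s[len] != '\0'; ++len) sum += (int)(unsigned char)s[len] - offset;
    out[i] = len > 0 ? (double)sum / len : NA_REAL;
  }
  return out;
}

// number of substitutions between `pattern` and the prefix (from_end = false)
// or suffix (from_end = true) of each sequence; -1 if shorter than pattern
// [[Rcpp::export]]
IntegerVector cpp_pattern_mismatch(CharacterVector seqs, std::string pattern,
                                   bool from_end = false) {
  int n = seqs.size(), pl = (int)pattern.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    if (seqs[i] == NA_STRING) { out[i] = NA_INTEGER; continue; }
    const char *s = CHAR(seqs[i]);
    int sl = (int)LENGTH(seqs[i]);
    if (sl < pl) { out[i] = -1; continue; }
    int off = from_end ? sl - pl : 0, mm = 0;
    for (int j = 0; j < pl; ++j)
      if (s[off + j] != pattern[j]) mm++;
    out[i] = mm;
  }
  return out;
}

// Apply per-base substitution errors and homopolymer indels (454-style:
// at positions repeating the previous template base, duplicate or drop the
// base with probability hp_rate, 50/50). Uses R's RNG.
// [[Rcpp::export]]
CharacterVector cpp_mutate_seqs(CharacterVector seqs, double sub_rate,
                                double hp_rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  int n = seqs.size();
  CharacterVector out(n);
  std::string buf;
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(seqs[i]);
    int sl = (int)LENGTH(seqs[i]);
    buf.clear();
    buf.reserve(sl + 8);
    for (int j = 0; j < sl; ++j) {
      char c = s[j];
      bool hp = j > 0 && s[j] == s[j - 1];
      if (hp && hp_rate > 0 && unif_rand() < hp_rate) {
        if (unif_rand() < 0.5) continue;    // deletion in the run
        buf.push_back(c);                   // insertion: duplicate base
      }
      if (sub_rate > 0 && unif_rand() < sub_rate) {
        int b = (int)(unif_rand() * 3.0);
        if (b > 2) b = 2;
        int orig = 0;
        switch (c) { case 'C': orig = 1; break; case 'G': orig = 2; break;
                     case 'T': orig = 3; break; default: orig = 0; }
        int pick = b < orig ? b : b + 1;
        c = bases[pick];
      }
      buf.push_back(c);
    }
    out[i] = buf;
  }
  return out;
}

// Per-base Phred quality strings: base QVs ~ round(N(mean_i, sd)), clamped to
// [2, 40], Sanger offset 33. Uses R's RNG.
// [[Rcpp::export]]
CharacterVector cpp_phred_strings(IntegerVector lens, NumericVector means,
                                  double sd = 2.0, int offset = 33) {
  int n = lens.size();
  CharacterVector out(n);
  std::string buf;
  for (int i = 0; i < n; ++i) {
    int L = lens[i];
    buf.clear();
    buf.reserve(L);
    for (int j = 0; j < L; ++j) {
      int q = (int)std::lround(means[i] + sd * norm_rand());
      if (q < 2) q = 2;
      if (q > 40) q = 40;
      buf.push_back((char)(offset + q));
    }
    out[i] = buf;
  }
  return out;
}
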