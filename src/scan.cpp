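#include <Rcpp.h>
#include <string>
#include <algorithm>
using namespace Rcpp;

static std::string rc(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (char& c : out) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default:  c = 'N'; break;
    }
  }
  return out;
}

// Exhaustive ungapped Hamming scan over every offset of every unigene (both
// orientations unless revcomp is false). Reference/validation scanner for the
// seeded counter: returns the 1-based index of the unique best-scoring
// unigene for each read, or NA when no placement is within max_mismatch or
// the best score is tied across distinct unigenes. 'N' never matches.
// [[Rcpp::export]]
IntegerVector hamming_scan_assign(CharacterVector reads, CharacterVector refs,
                                  int max_mismatch, bool revcomp) {
  int nr = reads.size(), nf = refs.size();
  std::vector<std::string> ref(nf);
  for (int j = 0; j < nf; ++j) ref[j] = as<std::string>(refs[j]);
  IntegerVector out(nr, NA_INTEGER);

  for (int i = 0; i < nr; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    int m = fwd.size();
    std::vector<std::string> oris;
    oris.push_back(fwd);
    if (revcomp) oris.push_back(rc(fwd));
    int best = max_mismatch + 1, best_ref = -1;
    bool multi = false;
    for (const std::string& rd : oris) {
      for (int j = 0; j < nf; ++j) {
        int L = ref[j].size();
        for (int off = 0; off + m <= L; ++off) {
          int cap = std::min(best, max_mismatch);
          int mm = 0;
          for (int p = 0; p < m; ++p) {
            char a = rd[p], b = ref[j][off + p];
            if (a == 'N' || b == 'N' || a != b) {
              if (++mm > cap) break;
            }
          }
          if (mm > cap) continue;
          if (mm < best) {
            best = mm; best_ref = j; multi = false;
          } else if (mm == best && j != best_ref) {
            multi = true;
          }
        }
      }
    }
    if (best <= max_mismatch && !multi) out[i] = best_ref + 1;
  }
  return out;
}
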