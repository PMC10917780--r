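// PWM scanning of peak sequences on both strands.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline int base_index(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // N or other: window is skipped
  }
}

// `lo` is the width x 4 log-odds matrix (columns A, C, G, T) for the forward
// strand; the reverse strand is scored with the reverse-complemented matrix.
// Offsets in the result are 0-based; strand is "+" or "-".
// [[Rcpp::export]]
DataFrame scan_sequences_cpp(CharacterVector seqs, NumericMatrix lo,
                             double threshold) {
  const int w = lo.nrow();
  if (lo.ncol() != 4) stop("log-odds matrix must have 4 columns");
  // reverse complement matrix: rc[i][b] = lo[w-1-i][3-b]
  NumericMatrix rc(w, 4);
  for (int i = 0; i < w; ++i)
    for (int b = 0; b < 4; ++b) rc(i, b) = lo(w - 1 - i, 3 - b);

  std::vector<int> seq_idx;
  std::vector<int> offset;
  std::vector<std::string> strand;
  std::vector<double> score;

  for (int s = 0; s < seqs.size(); ++s) {
    const std::string str = as<std::string>(seqs[s]);
    const int len = static_cast<int>(str.size());
    if (len < w) continue;
    std::vector<int> code(len);
    for (int i = 0; i < len; ++i) code[i] = base_index(str[i]);
    for (int off = 0; off + w <= len; ++off) {
      double fwd = 0.0, rev = 0.0;
      bool ok = true;
      for (int i = 0; i < w; ++i) {
        const int b = code[off + i];
        if (b < 0) { ok = false; break; }
        fwd += lo(i, b);
        rev += rc(i, b);
      }
      if (!ok) continue;
      if (fwd >= threshold) {
        seq_idx.push_back(s + 1);
        offset.push_back(off);
        strand.push_back("+");
        score.push_back(fwd);
      }
      if (rev >= threshold) {
        seq_idx.push_back(s + 1);
        offset.push_back(off);
        strand.push_back("-");
        score.push_back(rev);
      }
    }
  }
  return DataFrame::create(_["seq_index"] = seq_idx, _["offset"] = offset,
                           _["strand"] = strand, _["score"] = score,
                           _["stringsAsFactors"] = false);
}
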