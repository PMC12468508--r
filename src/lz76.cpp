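#include <Rcpp.h>
using namespace Rcpp;

// LZ76 exhaustive-history parsing of a binary sequence.
//
// Scanning left to right, the current word grows while it still occurs as a
// substring of the already-scanned text minus its last character (equivalently:
// while it matches at some earlier start position; overlap with the current
// word is allowed). On first novelty the word is emitted; a terminal partial
// word is counted. Returns the word lengths in parse order.
//
// [[Rcpp::export(name = ".lz76_word_lengths")]]
IntegerVector lz76_word_lengths(IntegerVector bits) {
  const int n = bits.size();
  std::vector<int> lengths;
  int pos = 0;
  std::vector<int> cand, keep;
  while (pos < n) {
    // candidate earlier start positions matching the current 1-symbol word
    cand.clear();
    for (int p = 0; p < pos; ++p)
      if (bits[p] == bits[pos]) cand.push_back(p);
    int len = 1;
    while (!cand.empty() && pos + len < n) {
      keep.clear();
      for (size_t i = 0; i < cand.size(); ++i)
        if (bits[cand[i] + len] == bits[pos + len]) keep.push_back(cand[i]);
      if (keep.empty()) {      // extension is novel: emit word of length len+1
        ++len;
        cand.clear();
        break;
      }
      cand.swap(keep);
      ++len;
    }
    // cases: novel single symbol (cand empty, len 1); novel extension
    // (break above); or end of sequence while still matching (terminal word)
    lengths.push_back(len);
    pos += len;
  }
  return wrap(lengths);
}
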