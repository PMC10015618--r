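#include <Rcpp.h>
using namespace Rcpp;

// Greedy left-anchored packing of callable positions into fixed-content
// blocks: starting at the leftmost unused callable base, take the next
// `block_span` callable bases; emit the block iff its genomic span is at most
// `max_span`, otherwise restart at the next callable base after the failed
// start. Returns 1-based indices (into `pos`) of the first member of each
// emitted block.
// [[Rcpp::export(name = ".cpp_cut_blocks")]]
IntegerVector cpp_cut_blocks(IntegerVector pos, int block_span, int max_span) {
  const int n = pos.size();
  std::vector<int> starts;
  int i = 0;
  while (i + block_span - 1 < n) {
    const int span = pos[i + block_span - 1] - pos[i] + 1;
    if (span <= max_span) {
      starts.push_back(i + 1);
      i += block_span;
    } else {
      ++i;
    }
  }
  return wrap(starts);
}
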