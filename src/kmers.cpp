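#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <cstdint>
using namespace Rcpp;

static inline int base_code(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;  // N or anything else resets the window
    }
}

// Canonical k-mer depth histogram over a set of reads.
// Returns a two-column integer matrix (depth, n_distinct), sorted by depth.
// [[Rcpp::export(name = ".kmer_hist_cpp")]]
IntegerMatrix kmer_hist_cpp(CharacterVector reads, int k) {
    if (k < 2 || k > 31) stop("k must be in [2, 31]");
    std::unordered_map<uint64_t, int32_t> counts;
    counts.reserve(1 << 20);
    const uint64_t mask = (1ULL << (2 * k)) - 1;
    const int shift = 2 * (k - 1);
    for (R_xlen_t r = 0; r < reads.size(); ++r) {
        const char* s = CHAR(STRING_ELT(reads, r));
        uint64_t fwd = 0, rev = 0;
        int valid = 0;
        for (const char* p = s; *p; ++p) {
            int c = base_code(*p);
            if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
            fwd = ((fwd << 2) | (uint64_t)c) & mask;
            rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
            if (++valid >= k) {
                uint64_t canon = fwd < rev ? fwd : rev;
                ++counts[canon];
            }
        }
    }
    std::map<int32_t, int32_t> hist;  // ordered: depth -> n distinct k-mers
    for (const auto& kv : counts) ++hist[kv.second];
    IntegerMatrix out(hist.size(), 2);
    R_xlen_t i = 0;
    for (const auto& kv : hist) {
        out(i, 0) = kv.first;
        out(i, 1) = kv.second;
        ++i;
    }
    colnames(out) = CharacterVector::create("depth", "count");
    return out;
}
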