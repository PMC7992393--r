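#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static inline int base_code2(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
    }
}

// (k,w) canonical minimizer sketch of one sequence. k <= 15 so the 2k-bit
// canonical code fits a non-negative R integer. Positions are 0-based starts
// of the k-mer. Consecutive duplicate (code,pos) picks are collapsed.
// [[Rcpp::export(name = ".minimizers_cpp")]]
List minimizers_cpp(std::string seq, int k, int w) {
    if (k < 2 || k > 15) stop("k must be in [2, 15]");
    if (w < 1) stop("w must be >= 1");
    const int n = (int)seq.size();
    const int nk = n - k + 1;
    std::vector<uint32_t> code;
    std::vector<int> kpos;
    if (nk > 0) {
        const uint32_t mask = (1U << (2 * k)) - 1;
        const int shift = 2 * (k - 1);
        uint32_t fwd = 0, rev = 0;
        int valid = 0;
        for (int i = 0; i < n; ++i) {
            int c = base_code2(seq[i]);
            if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
            fwd = ((fwd << 2) | (uint32_t)c) & mask;
            rev = (rev >> 2) | ((uint32_t)(3 - c) << shift);
            if (++valid >= k) {
                code.push_back(fwd < rev ? fwd : rev);
                kpos.push_back(i - k + 1);
            }
        }
    }
    std::vector<int> mhash, mpos;
    const int m = (int)code.size();
    if (m > 0) {
        int last_pos = -1;
        for (int i = 0; i + w <= m || (i == 0 && m < w); ++i) {
            int lim = std::min(i + w, m);
            int best = i;
            for (int j = i + 1; j < lim; ++j)
                if (code[j] < code[best]) best = j;
            if (kpos[best] != last_pos) {
                mhash.push_back((int)code[best]);
                mpos.push_back(kpos[best]);
                last_pos = kpos[best];
            }
            if (m < w) break;  // short sequence: single window
        }
    }
    return List::create(_["hash"] = wrap(mhash), _["pos"] = wrap(mpos));
}
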