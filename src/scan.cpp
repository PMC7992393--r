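#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'X';  // never matches (N has no reliable partner)
    }
}

// Inverted-repeat (hairpin) scan. For every start i and span s in
// [span_min, span_max], report the largest stem t with t >= min_stem,
// loop = s - 2t in [0, max_loop] (max_loop < 0 means unconstrained) and
// at most max_mismatch mispaired stem positions. Coordinates 0-based
// half-open. One row per (start, span) that admits a valid stem.
// [[Rcpp::export(name = ".hairpin_scan_cpp")]]
DataFrame hairpin_scan_cpp(std::string seq, int span_min, int span_max,
                           int min_stem, int max_mismatch, int max_loop) {
    const int n = (int)seq.size();
    std::vector<int> vs, ve, vstem, vloop, vmm;
    for (int i = 0; i + span_min <= n; ++i) {
        for (int s = span_min; s <= span_max && i + s <= n; ++s) {
            const int tmax = s / 2;
            int best_t = -1, best_mm = -1;
            int mm = 0;
            for (int t = 1; t <= tmax; ++t) {
                if (seq[i + t - 1] != comp_base(seq[i + s - t])) ++mm;
                if (mm > max_mismatch) break;
                int loop = s - 2 * t;
                if (t >= min_stem && (max_loop < 0 || loop <= max_loop)) {
                    best_t = t;
                    best_mm = mm;
                }
            }
            if (best_t > 0) {
                vs.push_back(i);
                ve.push_back(i + s);
                vstem.push_back(best_t);
                vloop.push_back(s - 2 * best_t);
                vmm.push_back(best_mm);
            }
        }
    }
    return DataFrame::create(_["start"] = wrap(vs), _["end"] = wrap(ve),
                             _["stem"] = wrap(vstem), _["loop"] = wrap(vloop),
                             _["mismatches"] = wrap(vmm));
}

// Best sub-terminal inverted repeat between a 5' window and a 3' window:
// the longest pair (i in w5, j in w3) with w3[j..j+len) equal to the
// reverse complement of w5[i..i+len) up to max_mismatch mismatches.
// Ties broken by proximity to the termini (small i, large j+len), then
// by small i. Returns integer(0) when nothing reaches min_len, else
// c(i, j, len, mm) with 0-based i, j.
// [[Rcpp::export(name = ".subtir_scan_cpp")]]
IntegerVector subtir_scan_cpp(std::string w5, std::string w3,
                              int min_len, int max_mismatch) {
    const int n5 = (int)w5.size(), n3 = (int)w3.size();
    const int max_len = std::min(n5, n3);
    for (int len = max_len; len >= min_len; --len) {
        int best_i = -1, best_j = -1, best_mm = 0, best_tie = 0;
        for (int i = 0; i + len <= n5; ++i) {
            for (int j = 0; j + len <= n3; ++j) {
                int mm = 0;
                bool ok = true;
                for (int t = 0; t < len; ++t) {
                    // revcomp(w5[i..i+len))[t] corresponds to w5[i+len-1-t]
                    if (w3[j + t] != comp_base(w5[i + len - 1 - t])) {
                        if (++mm > max_mismatch) { ok = false; break; }
                    }
                }
                if (!ok) continue;
                int tie = i + (n3 - (j + len));
                if (best_i < 0 || tie < best_tie ||
                    (tie == best_tie && i < best_i)) {
                    best_i = i; best_j = j; best_mm = mm; best_tie = tie;
                }
            }
        }
        if (best_i >= 0)
            return IntegerVector::create(best_i, best_j, len, best_mm);
    }
    return IntegerVector(0);
}
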