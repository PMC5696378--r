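#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Bit-parallel bitap (shift-and) with Hamming (substitution-only) mismatch
// counting. Bit j of R[d] is set when the pattern prefix of length j+1
// matches the text window ending at the current position with <= d
// mismatches. Patterns are limited to one machine word (64 bases).

static inline int base_idx(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1; // N and friends never match
    }
}

// Returns {position (0-based), mismatches} of the leftmost hit with
// <= k mismatches, or {-1, -1}. Ties at a position resolved to the
// smallest mismatch count.
static void bitap_one(const char* text, int n, const char* pat, int m,
                      int k, int* out_pos, int* out_mm) {
    *out_pos = -1;
    *out_mm = -1;
    if (m == 0 || m > n) return;
    uint64_t mask[4] = {0, 0, 0, 0};
    for (int j = 0; j < m; ++j) {
        int b = base_idx(pat[j]);
        if (b >= 0) mask[b] |= (uint64_t(1) << j);
        // non-ACGT pattern char: matches nothing
    }
    const uint64_t hit_bit = uint64_t(1) << (m - 1);
    std::vector<uint64_t> R(k + 1, 0);
    std::vector<uint64_t> Rnew(k + 1, 0);
    for (int i = 0; i < n; ++i) {
        int b = base_idx(text[i]);
        uint64_t chmask = (b >= 0) ? mask[b] : 0;
        Rnew[0] = ((R[0] << 1) | 1) & chmask;
        for (int d = 1; d <= k; ++d) {
            // extend with a match, or extend the (d-1)-level with a substitution
            Rnew[d] = (((R[d] << 1) | 1) & chmask) | ((R[d - 1] << 1) | 1);
        }
        for (int d = 0; d <= k; ++d) {
            if (Rnew[d] & hit_bit) {
                *out_pos = i - m + 1;
                *out_mm = d;
                return;
            }
        }
        std::swap(R, Rnew);
    }
}

// [[Rcpp::export(name = ".bitap_search_cpp")]]
IntegerVector bitap_search_cpp(std::string text, std::string pattern, int k) {
    if (pattern.size() > 64)
        stop("pattern longer than 64 bases exceeds machine-word capacity; chunk the pattern");
    if (k < 0) stop("max_mismatch must be >= 0");
    int pos, mm;
    bitap_one(text.c_str(), (int)text.size(), pattern.c_str(),
              (int)pattern.size(), k, &pos, &mm);
    return IntegerVector::create(pos, mm);
}

// Leftmost best hit per read across an ordered pattern set; among hits at the
// same position the earlier pattern wins (A, B, rcA, rcB order). If no full
// pattern hits, a read-end suffix overlap with a pattern *prefix* of at least
// `min_suffix` bases and <= `suffix_mm` mismatches is reported with
// pattern_id offset by 1000 (suffix mode marker).
// Returns an n x 3 integer matrix: position, mismatches, pattern index
// (1-based; +1000 in suffix mode), with -1 rows for no hit.
// [[Rcpp::export(name = ".linker_scan_cpp")]]
IntegerMatrix linker_scan_cpp(CharacterVector reads, CharacterVector patterns,
                              int k, int min_suffix, int suffix_mm) {
    int n = reads.size(), np = patterns.size();
    std::vector<std::string> pats(np);
    for (int p = 0; p < np; ++p) {
        pats[p] = as<std::string>(patterns[p]);
        if (pats[p].size() > 64) stop("pattern longer than 64 bases");
    }
    IntegerMatrix out(n, 3);
    for (int i = 0; i < n; ++i) {
        const char* txt = CHAR(STRING_ELT(reads, i));
        int len = LENGTH(STRING_ELT(reads, i));
        int best_pos = -1, best_mm = -1, best_pat = -1;
        for (int p = 0; p < np; ++p) {
            int pos, mm;
            bitap_one(txt, len, pats[p].c_str(), (int)pats[p].size(), k,
                      &pos, &mm);
            if (pos >= 0 && (best_pos < 0 || pos < best_pos)) {
                best_pos = pos; best_mm = mm; best_pat = p + 1;
            }
        }
        if (best_pos < 0 && min_suffix > 0) {
            // suffix of read vs prefix of pattern, overlap in [min_suffix, m-1];
            // leftmost qualifying start wins, earlier pattern breaks ties
            for (int p = 0; p < np; ++p) {
                int m = (int)pats[p].size();
                int max_ov = std::min(m - 1, len);
                for (int ov = max_ov; ov >= min_suffix; --ov) {
                    int start = len - ov, mm = 0;
                    for (int j = 0; j < ov && mm <= suffix_mm; ++j)
                        if (txt[start + j] != pats[p][j]) ++mm;
                    if (mm <= suffix_mm) {
                        if (best_pos < 0 || start < best_pos) {
                            best_pos = start; best_mm = mm; best_pat = p + 1001;
                        }
                        break;
                    }
                }
            }
        }
        out(i, 0) = best_pos;
        out(i, 1) = best_mm;
        out(i, 2) = best_pat;
    }
    return out;
}
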