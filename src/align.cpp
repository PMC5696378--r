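#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Naive exact-match aligner for synthetic genomes: a k-mer seed index over
// the forward strand, full-length exact verification of each tag and of its
// reverse complement. Any exact occurrence of a tag necessarily matches at
// its first k bases, so the seed lookup is exhaustive for tags >= k.

static inline int base2bits(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
    }
}

static inline char comp(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default: return 'N';
    }
}

// status codes: 1 = unique, 2 = multi, 3 = unmapped
// Returns an n x 4 integer matrix: chrom index (1-based), start (0-based,
// leftmost), strand (1 = '+', -1 = '-'), status.
// [[Rcpp::export(name = ".align_tags_cpp")]]
IntegerMatrix align_tags_cpp(CharacterVector chrom_seqs, CharacterVector tags,
                             int k) {
    int nc = chrom_seqs.size();
    std::vector<const char*> seq(nc);
    std::vector<int> slen(nc);
    for (int c = 0; c < nc; ++c) {
        seq[c] = CHAR(STRING_ELT(chrom_seqs, c));
        slen[c] = LENGTH(STRING_ELT(chrom_seqs, c));
    }
    if (k < 1 || k > 31) stop("seed length k must be in [1, 31]");

    // index: packed k-mer -> positions encoded as chrom * 2^34 + pos
    std::unordered_map<uint64_t, std::vector<uint64_t> > index;
    uint64_t kmask = (k == 32) ? ~uint64_t(0) : ((uint64_t(1) << (2 * k)) - 1);
    for (int c = 0; c < nc; ++c) {
        uint64_t key = 0;
        int run = 0; // valid-base run length
        for (int i = 0; i < slen[c]; ++i) {
            int b = base2bits(seq[c][i]);
            if (b < 0) { run = 0; key = 0; continue; }
            key = ((key << 2) | (uint64_t)b) & kmask;
            if (++run >= k) {
                uint64_t posval = (uint64_t(c) << 34) | uint64_t(i - k + 1);
                index[key].push_back(posval);
            }
        }
    }

    int n = tags.size();
    IntegerMatrix out(n, 4);
    std::string rc;
    for (int t = 0; t < n; ++t) {
        const char* tag = CHAR(STRING_ELT(tags, t));
        int tlen = LENGTH(STRING_ELT(tags, t));
        int nhits = 0, hit_chrom = -1, hit_pos = -1, hit_strand = 0;
        if (tlen >= k) {
            for (int strand = 0; strand < 2 && nhits < 2; ++strand) {
                const char* q = tag;
                if (strand == 1) {
                    rc.assign(tlen, 'N');
                    for (int i = 0; i < tlen; ++i)
                        rc[tlen - 1 - i] = comp(tag[i]);
                    q = rc.c_str();
                }
                uint64_t key = 0;
                bool ok = true;
                for (int i = 0; i < k; ++i) {
                    int b = base2bits(q[i]);
                    if (b < 0) { ok = false; break; }
                    key = (key << 2) | (uint64_t)b;
                }
                if (!ok) continue;
                auto it = index.find(key);
                if (it == index.end()) continue;
                for (uint64_t pv : it->second) {
                    int c = (int)(pv >> 34);
                    int p = (int)(pv & ((uint64_t(1) << 34) - 1));
                    if (p + tlen > slen[c]) continue;
                    bool match = true;
                    for (int i = k; i < tlen; ++i) {
                        if (seq[c][p + i] != q[i]) { match = false; break; }
                    }
                    if (match) {
                        ++nhits;
                        if (nhits == 1) {
                            hit_chrom = c; hit_pos = p;
                            hit_strand = (strand == 0) ? 1 : -1;
                        }
                        if (nhits >= 2) break;
                    }
                }
            }
        }
        if (nhits == 1) {
            out(t, 0) = hit_chrom + 1;
            out(t, 1) = hit_pos;
            out(t, 2) = hit_strand;
            out(t, 3) = 1;
        } else {
            out(t, 0) = NA_INTEGER;
            out(t, 1) = NA_INTEGER;
            out(t, 2) = NA_INTEGER;
            out(t, 3) = (nhits >= 2) ? 2 : 3;
        }
    }
    return out;
}
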