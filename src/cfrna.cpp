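#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// 2-bit encode a k-mer; returns -1 if any base is not ACGT. k <= 31.
static inline int64_t encode_kmer(const char* s, int k) {
    int64_t code = 0;
    for (int i = 0; i < k; ++i) {
        int b;
        switch (s[i]) {
        case 'A': b = 0; break;
        case 'C': b = 1; break;
        case 'G': b = 2; break;
        case 'T': b = 3; break;
        default: return -1;
        }
        code = (code << 2) | b;
    }
    return code;
}

// mismatches between a and b over m bases, early exit once budget exceeded
static inline int mm_count(const char* a, const char* b, int m, int budget) {
    int mm = 0;
    for (int i = 0; i < m; ++i) {
        if (a[i] != b[i]) {
            if (++mm > budget) return mm;
        }
    }
    return mm;
}

struct Hit {
    int ref;    // 0-based reference index
    int start;  // 0-based offset
    int mm;
};

// End-to-end placement of each read on the forward strand of each reference,
// at most max_mm mismatches, best (minimum-mismatch) stratum only.
// Seed-and-verify: for <=1 mismatch and read length >= 2k, one of the two
// disjoint k-mer seeds at read offsets 0 and k is exact (pigeonhole); shorter
// reads fall back to a full scan. N never matches (N in read or reference
// counts as a mismatch at that position).
// [[Rcpp::export]]
DataFrame cpp_align(CharacterVector reads, CharacterVector refs,
                    int k, int max_mm) {
    int nref = refs.size();
    std::vector<std::string> R(nref);
    for (int i = 0; i < nref; ++i) R[i] = as<std::string>(refs[i]);

    // index all reference k-mers
    std::unordered_map<int64_t, std::vector<std::pair<int, int> > > index;
    for (int r = 0; r < nref; ++r) {
        int L = (int)R[r].size();
        for (int o = 0; o + k <= L; ++o) {
            int64_t code = encode_kmer(R[r].c_str() + o, k);
            if (code >= 0) index[code].push_back(std::make_pair(r, o));
        }
    }

    std::vector<int> out_read, out_ref, out_start, out_mm;
    int nreads = reads.size();
    std::vector<Hit> hits;
    for (int q = 0; q < nreads; ++q) {
        std::string rd = as<std::string>(reads[q]);
        int L = (int)rd.size();
        if (L == 0) continue;
        hits.clear();
        int best = max_mm + 1;
        if (L >= 2 * k) {
            // candidate starts from the two seeds, deduplicated
            std::vector<std::pair<int, int> > cands;
            for (int s = 0; s < 2; ++s) {
                int off = s * k;
                int64_t code = encode_kmer(rd.c_str() + off, k);
                if (code < 0) continue;
                std::unordered_map<int64_t,
                    std::vector<std::pair<int, int> > >::iterator it =
                    index.find(code);
                if (it == index.end()) continue;
                for (size_t j = 0; j < it->second.size(); ++j) {
                    int r = it->second[j].first;
                    int start = it->second[j].second - off;
                    if (start < 0 || start + L > (int)R[r].size()) continue;
                    cands.push_back(std::make_pair(r, start));
                }
            }
            std::sort(cands.begin(), cands.end());
            cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
            for (size_t j = 0; j < cands.size(); ++j) {
                int r = cands[j].first, start = cands[j].second;
                int mm = mm_count(rd.c_str(), R[r].c_str() + start, L, max_mm);
                if (mm <= max_mm) {
                    Hit h; h.ref = r; h.start = start; h.mm = mm;
                    hits.push_back(h);
                    if (mm < best) best = mm;
                }
            }
        } else {
            // full scan for short reads
            for (int r = 0; r < nref; ++r) {
                int Lr = (int)R[r].size();
                for (int start = 0; start + L <= Lr; ++start) {
                    int mm = mm_count(rd.c_str(), R[r].c_str() + start, L,
                                      max_mm);
                    if (mm <= max_mm) {
                        Hit h; h.ref = r; h.start = start; h.mm = mm;
                        hits.push_back(h);
                        if (mm < best) best = mm;
                    }
                }
            }
        }
        // best stratum only, ordered by (ref, start)
        for (size_t j = 0; j < hits.size(); ++j) {
            if (hits[j].mm == best) {
                out_read.push_back(q + 1);
                out_ref.push_back(hits[j].ref + 1);
                out_start.push_back(hits[j].start);
                out_mm.push_back(hits[j].mm);
            }
        }
    }
    return DataFrame::create(_["read"] = out_read, _["ref"] = out_ref,
                             _["start"] = out_start,
                             _["mismatches"] = out_mm);
}

// Locate the 3' adapter in each read: full internal matches or prefix matches
// reaching the read end, minimum min_match bases, at most
// floor(max_error_rate * matchlen) mismatches. Preference: longest match
// first, ties broken by the rightmost start. Returns 0-based cut position
// (adapter start), or -1 when no acceptable match exists.
// [[Rcpp::export]]
IntegerVector cpp_adapter_pos(CharacterVector reads, std::string adapter,
                              double max_error_rate, int min_match) {
    int alen = (int)adapter.size();
    int n = reads.size();
    IntegerVector cut(n);
    for (int i = 0; i < n; ++i) {
        std::string rd = as<std::string>(reads[i]);
        int L = (int)rd.size();
        int best_m = -1, best_p = -1;
        for (int p = 0; p + min_match <= L; ++p) {
            int m = std::min(alen, L - p);
            int budget = (int)(max_error_rate * m);
            int mm = mm_count(rd.c_str() + p, adapter.c_str(), m, budget);
            if (mm <= budget) {
                if (m > best_m || (m == best_m && p > best_p)) {
                    best_m = m; best_p = p;
                }
            }
        }
        cut[i] = best_p;  // -1 when unmatched
    }
    return cut;
}

// Per-read retained range after trimming low-quality bases (phred < threshold)
// from both ends. Returns an n x 2 matrix of 0-based [start, end).
// [[Rcpp::export]]
IntegerMatrix cpp_qual_range(CharacterVector quals, int threshold,
                             int offset) {
    int n = quals.size();
    IntegerMatrix out(n, 2);
    for (int i = 0; i < n; ++i) {
        std::string q = as<std::string>(quals[i]);
        int L = (int)q.size();
        int a = 0, b = L;
        while (b > a && (int)q[b - 1] - offset < threshold) --b;
        while (a < b && (int)q[a] - offset < threshold) ++a;
        out(i, 0) = a;
        out(i, 1) = b;
    }
    return out;
}

// Overlap placement of r2rc (reverse-complemented mate 2) against r1: r2rc
// starts at 0-based shift s inside r1, the overlap spans
// m = min(n1 - s, n2) bases and must satisfy m >= min_overlap and mismatch
// rate <= max_mm_rate. Mate-1 bases past the end of r2rc are read-through
// into tail/adapter and are discarded by the caller. Shifts are scanned in
// increasing order, so the first acceptable placement has the maximal
// overlap. Returns the shift per pair (-1 when no acceptable placement).
// [[Rcpp::export]]
IntegerVector cpp_overlap(CharacterVector r1, CharacterVector r2rc,
                          int min_overlap, double max_mm_rate) {
    int n = r1.size();
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        std::string a = as<std::string>(r1[i]);
        std::string b = as<std::string>(r2rc[i]);
        int n1 = (int)a.size(), n2 = (int)b.size();
        int found = -1;
        for (int s = 0; s <= n1 - min_overlap; ++s) {
            int m = std::min(n1 - s, n2);
            if (m < min_overlap) break;
            int budget = (int)(max_mm_rate * m);
            int mm = mm_count(a.c_str() + s, b.c_str(), m, budget);
            if (mm <= budget) { found = s; break; }
        }
        out[i] = found;
    }
    return out;
}
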