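#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 2-bit base encoding; -1 for anything that is not A/C/G/T.
static inline int base2bits(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static inline char comp(char c) {
    switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
    }
}

// [[Rcpp::export(rng = false)]]
std::string revcomp_cpp(std::string s) {
    std::string out(s.rbegin(), s.rend());
    for (size_t i = 0; i < out.size(); ++i) out[i] = comp(out[i]);
    return out;
}

// [[Rcpp::export(rng = false)]]
CharacterVector revcomp_vec(CharacterVector x) {
    const R_xlen_t n = x.size();
    CharacterVector out(n);
    std::string buf;
    for (R_xlen_t i = 0; i < n; ++i) {
        const char *s = CHAR(STRING_ELT(x, i));
        const int len = LENGTH(STRING_ELT(x, i));
        buf.assign(len, 'N');
        for (int j = 0; j < len; ++j) buf[j] = comp(s[len - 1 - j]);
        out[i] = buf;
    }
    return out;
}

// Scan query sequences (forward and reverse-complement) against an index of
// k-mers that occur exactly once across the forward strand of the target.
// Returns one row per hit: query index, strand, position in the
// strand-oriented query frame, target index, target position (all 0-based).
// k-mers containing non-ACGT characters are skipped on both sides.
// [[Rcpp::export(rng = false)]]
DataFrame anchor_scan(CharacterVector query_seqs, CharacterVector target_seqs, int k) {
    if (k < 1 || k > 31) stop("k must be in [1, 31]");
    const uint64_t mask = (k == 32) ? ~uint64_t(0) : ((uint64_t(1) << (2 * k)) - 1);

    // value: packed (target index << 40) | position, or UINT64_MAX for non-unique
    std::unordered_map<uint64_t, uint64_t> index;
    const uint64_t DUP = ~uint64_t(0);
    {
        size_t total = 0;
        for (int t = 0; t < target_seqs.size(); ++t) total += LENGTH(STRING_ELT(target_seqs, t));
        index.reserve(total);
    }
    for (int t = 0; t < target_seqs.size(); ++t) {
        std::string seq = as<std::string>(target_seqs[t]);
        uint64_t kmer = 0; int run = 0;
        for (size_t i = 0; i < seq.size(); ++i) {
            int b = base2bits(seq[i]);
            if (b < 0) { run = 0; kmer = 0; continue; }
            kmer = ((kmer << 2) | uint64_t(b)) & mask;
            if (++run >= k) {
                uint64_t pos = (uint64_t(t) << 40) | uint64_t(i + 1 - k);
                auto it = index.find(kmer);
                if (it == index.end()) index.emplace(kmer, pos);
                else it->second = DUP;
            }
        }
    }

    std::vector<int> qidx, qpos, tidx, tpos;
    std::vector<int> strand; // 1 = '+', -1 = '-'
    for (int q = 0; q < query_seqs.size(); ++q) {
        std::string fwd = as<std::string>(query_seqs[q]);
        for (int sdir = 0; sdir < 2; ++sdir) {
            std::string seq = (sdir == 0) ? fwd : revcomp_cpp(fwd);
            uint64_t kmer = 0; int run = 0;
            for (size_t i = 0; i < seq.size(); ++i) {
                int b = base2bits(seq[i]);
                if (b < 0) { run = 0; kmer = 0; continue; }
                kmer = ((kmer << 2) | uint64_t(b)) & mask;
                if (++run >= k) {
                    auto it = index.find(kmer);
                    if (it != index.end() && it->second != DUP) {
                        qidx.push_back(q + 1);
                        strand.push_back(sdir == 0 ? 1 : -1);
                        qpos.push_back(int(i + 1 - k));
                        tidx.push_back(int(it->second >> 40) + 1);
                        tpos.push_back(int(it->second & ((uint64_t(1) << 40) - 1)));
                    }
                }
            }
        }
    }
    return DataFrame::create(_["qidx"] = qidx, _["strand"] = strand,
                             _["qpos"] = qpos, _["tidx"] = tidx, _["tpos"] = tpos);
}

// Gap-free mismatch count of each query string laid on `target` at `starts`
// (0-based). Bases falling outside the target count as mismatches.
// [[Rcpp::export(rng = false)]]
IntegerVector count_mismatches(std::string target, IntegerVector starts,
                               CharacterVector queries) {
    if (starts.size() != queries.size()) stop("starts and queries differ in length");
    const R_xlen_t n = starts.size();
    IntegerVector out(n);
    const int tlen = int(target.size());
    for (R_xlen_t i = 0; i < n; ++i) {
        const char *qs = CHAR(STRING_ELT(queries, i));
        const int ql = LENGTH(STRING_ELT(queries, i));
        const int s = starts[i];
        int nm = 0;
        for (int j = 0; j < ql; ++j) {
            const int tj = s + j;
            if (tj < 0 || tj >= tlen || target[tj] != qs[j]) ++nm;
        }
        out[i] = nm;
    }
    return out;
}

// Mismatch count between target[tstart, tstart+len) and query[qstart, qstart+len)
// without materializing substrings; used for chain identity on long spans.
// [[Rcpp::export(rng = false)]]
int span_mismatches(std::string query, int qstart, std::string target, int tstart, int len) {
    int nm = 0;
    const int ql = int(query.size()), tl = int(target.size());
    for (int j = 0; j < len; ++j) {
        const int qj = qstart + j, tj = tstart + j;
        if (qj < 0 || qj >= ql || tj < 0 || tj >= tl || query[qj] != target[tj]) ++nm;
    }
    return nm;
}
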