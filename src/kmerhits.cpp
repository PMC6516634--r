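#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <string>

using namespace Rcpp;

// Genome-wide canonical k-mer occurrence counting (strand-collapsed) and
// per-oligo maximum-hit queries, as used by the probe occurrence filter.

static inline int base2bits(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
    }
}

static inline uint64_t rc_kmer(uint64_t x, int k) {
    uint64_t r = 0;
    for (int i = 0; i < k; ++i) {
        r = (r << 2) | (3ULL - (x & 3ULL));
        x >>= 2;
    }
    return r;
}

static inline uint64_t canon_kmer(uint64_t x, int k) {
    uint64_t r = rc_kmer(x, k);
    return x < r ? x : r;
}

typedef std::unordered_map<uint64_t, uint32_t> KmerMap;

// [[Rcpp::export]]
SEXP build_kmer_counter_cpp(CharacterVector seqs, int k) {
    if (k < 4 || k > 31) stop("k must be in 4..31");
    const uint64_t mask = (1ULL << (2 * k)) - 1;
    XPtr<KmerMap> ptr(new KmerMap(), true);
    for (int i = 0; i < seqs.size(); ++i) {
        std::string s = as<std::string>(seqs[i]);
        uint64_t h = 0; int valid = 0;
        for (size_t j = 0; j < s.size(); ++j) {
            int b = base2bits(s[j]);
            if (b < 0) { valid = 0; h = 0; continue; }
            h = ((h << 2) | (uint64_t)b) & mask;
            if (++valid >= k) ++(*ptr)[canon_kmer(h, k)];
        }
    }
    ptr.attr("k") = k;
    return ptr;
}

// count of one whole k-mer per element
// [[Rcpp::export]]
IntegerVector kmer_hits_cpp(SEXP counter, CharacterVector kmers) {
    XPtr<KmerMap> ptr(counter);
    int k = as<int>(ptr.attr("k"));
    const uint64_t mask = (1ULL << (2 * k)) - 1;
    IntegerVector out(kmers.size());
    for (int i = 0; i < kmers.size(); ++i) {
        std::string s = as<std::string>(kmers[i]);
        if ((int)s.size() != k) stop("k-mer length mismatch");
        uint64_t h = 0; bool ok = true;
        for (int j = 0; j < k; ++j) {
            int b = base2bits(s[j]);
            if (b < 0) { ok = false; break; }
            h = ((h << 2) | (uint64_t)b) & mask;
        }
        if (!ok) { out[i] = NA_INTEGER; continue; }
        auto it = ptr->find(canon_kmer(h, k));
        out[i] = (it == ptr->end()) ? 0 : (int)it->second;
    }
    return out;
}

// max occurrence count over all k-mers contained in each sequence
// [[Rcpp::export]]
IntegerVector max_window_kmer_hits_cpp(SEXP counter, CharacterVector seqs) {
    XPtr<KmerMap> ptr(counter);
    int k = as<int>(ptr.attr("k"));
    const uint64_t mask = (1ULL << (2 * k)) - 1;
    IntegerVector out(seqs.size());
    for (int i = 0; i < seqs.size(); ++i) {
        std::string s = as<std::string>(seqs[i]);
        int best = 0;
        uint64_t h = 0; int valid = 0;
        for (size_t j = 0; j < s.size(); ++j) {
            int b = base2bits(s[j]);
            if (b < 0) { valid = 0; h = 0; continue; }
            h = ((h << 2) | (uint64_t)b) & mask;
            if (valid + 1 >= k) {
                auto it = ptr->find(canon_kmer(h, k));
                int c = (it == ptr->end()) ? 0 : (int)it->second;
                if (c > best) best = c;
            }
            ++valid;
        }
        out[i] = best;
    }
    return out;
}

// distinct k-mer count in the table (diagnostics)
// [[Rcpp::export]]
double kmer_counter_size_cpp(SEXP counter) {
    XPtr<KmerMap> ptr(counter);
    return (double)ptr->size();
}
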