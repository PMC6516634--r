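#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// Minimal de Bruijn assembler on canonical k-mers: count k-mers, drop those
// below min_count, emit maximal non-branching paths (unitigs), then clip
// tips (short unitigs with exactly one dead end).

static inline int base2bits(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
    }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

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

struct Graph {
    int k;
    uint64_t mask;
    KmerMap kmers; // canonical -> count

    bool has(uint64_t oriented) const {
        return kmers.find(canon_kmer(oriented, k)) != kmers.end();
    }
    // successors of an oriented k-mer (append base on the right)
    int succ(uint64_t x, uint64_t *out) const {
        int n = 0;
        for (uint64_t b = 0; b < 4; ++b) {
            uint64_t y = ((x << 2) | b) & mask;
            if (has(y)) out[n++] = y;
        }
        return n;
    }
    // predecessors (prepend base on the left)
    int pred(uint64_t x, uint64_t *out) const {
        int n = 0;
        for (uint64_t b = 0; b < 4; ++b) {
            uint64_t y = (b << (2 * (k - 1))) | (x >> 2);
            if (has(y)) out[n++] = y;
        }
        return n;
    }
};

static std::string decode_kmer(uint64_t x, int k) {
    std::string s(k, 'A');
    for (int i = k - 1; i >= 0; --i) { s[i] = BITS2BASE[x & 3]; x >>= 2; }
    return s;
}

// [[Rcpp::export]]
List assemble_debruijn_cpp(CharacterVector reads, int k, int min_count) {
    if (k < 5 || k > 31 || k % 2 == 0) stop("k must be odd and in 5..31");
    Graph g;
    g.k = k;
    g.mask = (1ULL << (2 * k)) - 1;
    // count canonical k-mers
    for (int i = 0; i < reads.size(); ++i) {
        std::string s = as<std::string>(reads[i]);
        if ((int)s.size() < k) continue;
        uint64_t h = 0; int valid = 0;
        for (size_t j = 0; j < s.size(); ++j) {
            int b = base2bits(s[j]);
            if (b < 0) { valid = 0; h = 0; continue; }
            h = ((h << 2) | (uint64_t)b) & g.mask;
            if (++valid >= k) ++g.kmers[canon_kmer(h, k)];
        }
    }
    for (auto it = g.kmers.begin(); it != g.kmers.end();) {
        if ((int)it->second < min_count) it = g.kmers.erase(it);
        else ++it;
    }

    std::unordered_set<uint64_t> visited;
    visited.reserve(g.kmers.size() * 2);
    std::vector<std::string> contigs;
    std::vector<double> meancov;
    std::vector<int> front_deg, back_deg;
    uint64_t nb[4];

    std::vector<uint64_t> keys;
    keys.reserve(g.kmers.size());
    for (auto &kv : g.kmers) keys.push_back(kv.first);
    std::sort(keys.begin(), keys.end()); // deterministic traversal order

    for (uint64_t start : keys) {
        if (visited.count(start)) continue;
        visited.insert(start);
        uint64_t cur = start;
        std::string seq = decode_kmer(start, k);
        double cov = g.kmers[start];
        long ncov = 1;
        // extend right
        while (true) {
            int ns = g.succ(cur, nb);
            if (ns != 1) break;
            uint64_t y = nb[0];
            uint64_t tmp[4];
            if (g.pred(y, tmp) != 1) break;
            uint64_t cy = canon_kmer(y, k);
            if (visited.count(cy)) break;
            visited.insert(cy);
            seq.push_back(BITS2BASE[y & 3]);
            cov += g.kmers[cy]; ++ncov;
            cur = y;
        }
        uint64_t right_end = cur;
        // extend left
        cur = start;
        while (true) {
            int np = g.pred(cur, nb);
            if (np != 1) break;
            uint64_t y = nb[0];
            uint64_t tmp[4];
            if (g.succ(y, tmp) != 1) break;
            uint64_t cy = canon_kmer(y, k);
            if (visited.count(cy)) break;
            visited.insert(cy);
            seq.insert(seq.begin(), BITS2BASE[(y >> (2 * (k - 1))) & 3]);
            cov += g.kmers[cy]; ++ncov;
            cur = y;
        }
        uint64_t left_end = cur;
        contigs.push_back(seq);
        meancov.push_back(cov / ncov);
        front_deg.push_back(g.pred(left_end, nb));
        back_deg.push_back(g.succ(right_end, nb));
    }

    // tip clipping: a unitig shorter than 2k attached on exactly one side
    std::vector<std::string> keep;
    std::vector<double> keepcov;
    for (size_t i = 0; i < contigs.size(); ++i) {
        bool front_dead = front_deg[i] == 0;
        bool back_dead = back_deg[i] == 0;
        bool tip = (int)contigs[i].size() < 2 * k && (front_dead != back_dead);
        if (!tip) { keep.push_back(contigs[i]); keepcov.push_back(meancov[i]); }
    }
    return List::create(_["sequence"] = wrap(keep), _["mean_cov"] = wrap(keepcov));
}
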