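#include <Rcpp.h>
#include <cstring>
#include <cstdint>
#include <unordered_map>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// Tandem-unit scanning of reads.  A run is a maximal stretch where the
// sequence equals itself shifted by the unit length; only primitive units
// (not themselves a repeat of a shorter unit) are reported, and overlapping
// runs of different unit lengths are resolved longest-span-first.

static inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
    }
}

static std::string revcomp_str(const std::string &s) {
    std::string r(s.rbegin(), s.rend());
    for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
    return r;
}

// lexicographic minimum over rotations of the unit and of its reverse
// complement: the canonical representative of the rotation/strand class
static std::string canon_unit_str(const std::string &u) {
    std::string best = u;
    std::string r = revcomp_str(u);
    const size_t n = u.size();
    for (size_t i = 0; i < n; ++i) {
        std::string a = u.substr(i) + u.substr(0, i);
        if (a < best) best = a;
        std::string b = r.substr(i) + r.substr(0, i);
        if (b < best) best = b;
    }
    return best;
}

// a unit is primitive if no proper divisor length generates it
static bool is_primitive(const std::string &u) {
    const size_t n = u.size();
    for (size_t d = 1; d < n; ++d) {
        if (n % d != 0) continue;
        bool all = true;
        for (size_t i = d; i < n && all; ++i)
            if (u[i] != u[i - d]) all = false;
        if (all) return false;
    }
    return true;
}

struct TandemRun {
    int start;   // 0-based
    int span;
    int ulen;
    int copies;
    std::string unit; // canonical
};

// first index in [i, limit) where s[idx] != s[idx + u], or limit if none;
// compares 8 bytes at a time
static inline int scan_match_end(const char *s, int i, int limit, int u) {
    while (i + 8 <= limit) {
        uint64_t a, b;
        memcpy(&a, s + i, 8);
        memcpy(&b, s + i + u, 8);
        uint64_t z = a ^ b;
        if (z == 0) { i += 8; continue; }
#if defined(__GNUC__)
        return i + (__builtin_ctzll(z) >> 3);
#else
        while (s[i] == s[i + u]) ++i;
        return i;
#endif
    }
    while (i < limit && s[i] == s[i + u]) ++i;
    return i;
}

// first index in [i, limit) where s[idx] == s[idx + u], or limit if none
static inline int scan_next_match(const char *s, int i, int limit, int u) {
    while (i + 8 <= limit) {
        uint64_t a, b;
        memcpy(&a, s + i, 8);
        memcpy(&b, s + i + u, 8);
        uint64_t z = a ^ b;
        // detect a zero byte in z
        uint64_t hit = (z - 0x0101010101010101ULL) & ~z & 0x8080808080808080ULL;
        if (hit == 0) { i += 8; continue; }
#if defined(__GNUC__)
        return i + (__builtin_ctzll(hit) >> 3);
#else
        while (i < limit && s[i] != s[i + u]) ++i;
        return i;
#endif
    }
    while (i < limit && s[i] != s[i + u]) ++i;
    return i;
}

static void scan_one(const char *sp, int L, int max_unit, int min_copies,
                     std::vector<TandemRun> &out, std::vector<TandemRun> &cand,
                     std::vector<char> &occupied) {
    out.clear();
    cand.clear();
    std::string s(sp, L);
    for (int u = 1; u <= max_unit; ++u) {
        int limit = L - u; // shift positions are [0, L-u)
        int i = scan_next_match(sp, 0, limit, u);
        while (i < limit) {
                int j = scan_match_end(sp, i, limit, u);
                // matched shift positions are [i, j); run covers [i, j + u)
                int span = (j - i) + u;
                int copies = span / u;
                if (copies >= min_copies) {
                    std::string unit = s.substr(i, u);
                    bool ok = is_primitive(unit);
                    if (ok) {
                        for (int p = i; p < i + span && ok; ++p)
                            if (s[p] != 'A' && s[p] != 'C' && s[p] != 'G' && s[p] != 'T')
                                ok = false;
                    }
                    if (ok) {
                        TandemRun r;
                        r.start = i; r.span = span; r.ulen = u;
                        r.copies = copies; r.unit = canon_unit_str(unit);
                        cand.push_back(r);
                    }
                }
                i = scan_next_match(sp, j + 1, limit, u);
        }
    }
    // longest-span-first greedy resolution of overlaps; ties broken by
    // shorter unit, then by start coordinate
    std::sort(cand.begin(), cand.end(), [](const TandemRun &a, const TandemRun &b) {
        if (a.span != b.span) return a.span > b.span;
        if (a.ulen != b.ulen) return a.ulen < b.ulen;
        return a.start < b.start;
    });
    occupied.assign(L, 0);
    for (const TandemRun &r : cand) {
        bool free_ = true;
        for (int p = r.start; p < r.start + r.span && free_; ++p)
            if (occupied[p]) free_ = false;
        if (!free_) continue;
        for (int p = r.start; p < r.start + r.span; ++p) occupied[p] = true;
        out.push_back(r);
    }
    std::sort(out.begin(), out.end(), [](const TandemRun &a, const TandemRun &b) {
        return a.start < b.start;
    });
}

// [[Rcpp::export]]
DataFrame tandem_runs_cpp(CharacterVector reads, int max_unit, int min_copies) {
    std::vector<int> read_idx, start, span, copies;
    std::vector<std::string> unit;
    std::vector<TandemRun> runs, cand;
    std::vector<char> occ;
    for (int i = 0; i < reads.size(); ++i) {
        SEXP el = STRING_ELT(reads, i);
        scan_one(CHAR(el), (int)LENGTH(el), max_unit, min_copies, runs, cand, occ);
        for (const TandemRun &r : runs) {
            read_idx.push_back(i + 1);
            unit.push_back(r.unit);
            copies.push_back(r.copies);
            start.push_back(r.start);
            span.push_back(r.span);
        }
    }
    return DataFrame::create(_["read"] = read_idx, _["unit"] = unit,
                             _["copies"] = copies, _["start"] = start,
                             _["span"] = span,
                             _["stringsAsFactors"] = false);
}

// aggregated copy counts per canonical unit over all reads
// [[Rcpp::export]]
NumericVector tandem_count_cpp(CharacterVector reads, int max_unit, int min_copies) {
    std::unordered_map<std::string, double> acc;
    std::vector<TandemRun> runs, cand;
    std::vector<char> occ;
    for (int i = 0; i < reads.size(); ++i) {
        SEXP el = STRING_ELT(reads, i);
        scan_one(CHAR(el), (int)LENGTH(el), max_unit, min_copies, runs, cand, occ);
        for (const TandemRun &r : runs) acc[r.unit] += r.copies;
    }
    NumericVector out(acc.size());
    CharacterVector nm(acc.size());
    int k = 0;
    for (auto &kv : acc) { nm[k] = kv.first; out[k] = kv.second; ++k; }
    out.names() = nm;
    return out;
}

// [[Rcpp::export]]
CharacterVector canonical_unit_cpp(CharacterVector units) {
    CharacterVector out(units.size());
    for (int i = 0; i < units.size(); ++i) {
        std::string u = as<std::string>(units[i]);
        if (u.empty()) stop("empty unit");
        for (char c : u)
            if (c != 'A' && c != 'C' && c != 'G' && c != 'T')
                stop("unit contains a non-ACGT symbol");
        out[i] = canon_unit_str(u);
    }
    return out;
}
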