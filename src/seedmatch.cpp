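#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// Seeded ungapped matching of query sequences against a set of target
// sequences.  Exact seed k-mers nominate (target, diagonal) candidates;
// each candidate is scored by ungapped match count over the overlap of the
// query with the target along that diagonal.  Used both for read-to-family
// assignment and for projecting assembled contigs onto a genome.

static inline int base2bits(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
    }
}

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

struct Posting { uint32_t target; uint32_t pos; };

struct SeedIndex {
    int seed_len;
    std::unordered_map<uint64_t, std::vector<Posting> > map;
};

static void build_index(const std::vector<std::string> &targets, int seed_len,
                        int max_occ, SeedIndex &idx) {
    idx.seed_len = seed_len;
    const uint64_t mask = (seed_len == 32) ? ~0ULL : ((1ULL << (2 * seed_len)) - 1);
    for (size_t t = 0; t < targets.size(); ++t) {
        const std::string &s = targets[t];
        if ((int)s.size() < seed_len) continue;
        uint64_t h = 0; int valid = 0;
        for (size_t i = 0; i < s.size(); ++i) {
            int b = base2bits(s[i]);
            if (b < 0) { valid = 0; h = 0; continue; }
            h = ((h << 2) | (uint64_t)b) & mask;
            if (++valid >= seed_len) {
                std::vector<Posting> &v = idx.map[h];
                if ((int)v.size() < max_occ)
                    v.push_back({(uint32_t)t, (uint32_t)(i + 1 - seed_len)});
            }
        }
    }
}

struct Hit {
    int target = -1;       // 0-based
    long diag = 0;         // tpos - qpos
    int strand = 0;        // +1 / -1 (query strand)
    int score = -1;        // matches in overlap
    int overlap = 0;
    long tstart = 0;
    long qstart = 0;
};

// [[Rcpp::export]]
List seed_match_cpp(CharacterVector queries, CharacterVector targets,
                    int seed_len, int seed_step, int max_occ, int max_cand) {
    if (seed_len < 4 || seed_len > 32) stop("seed_len must be in 4..32");
    if (seed_step < 1) stop("seed_step must be >= 1");
    std::vector<std::string> tg(targets.size());
    for (int i = 0; i < targets.size(); ++i) tg[i] = as<std::string>(targets[i]);
    SeedIndex idx;
    build_index(tg, seed_len, max_occ, idx);
    const uint64_t mask = (seed_len == 32) ? ~0ULL : ((1ULL << (2 * seed_len)) - 1);

    const int nq = queries.size();
    IntegerVector r_target(nq, NA_INTEGER), r_score(nq, 0), r_overlap(nq, 0),
        r_strand(nq, NA_INTEGER), r_sec_target(nq, 0), r_sec_locus(nq, 0);
    NumericVector r_tstart(nq, NA_REAL), r_qstart(nq, NA_REAL), r_qlen(nq, 0.0);

    std::vector<long long> raw;                    // posting keys
    std::vector<std::pair<long long, int> > votes; // key -> votes
    for (int q = 0; q < nq; ++q) {
        std::string fw = as<std::string>(queries[q]);
        const int qlen = (int)fw.size();
        r_qlen[q] = qlen;
        if (qlen < seed_len) continue;
        Hit best, sec_other_target, sec_other_locus;
        std::vector<Hit> hits;
        for (int st = 0; st < 2; ++st) {
            std::string qs = (st == 0) ? fw : revcomp_str(fw);
            int strand = (st == 0) ? 1 : -1;
            // collect diagonal votes (sorted run-length count)
            raw.clear();
            int last = qlen - seed_len;
            for (int off = 0; off <= last; off += seed_step) {
                uint64_t h = 0; bool ok = true;
                for (int j = 0; j < seed_len; ++j) {
                    int b = base2bits(qs[off + j]);
                    if (b < 0) { ok = false; break; }
                    h = ((h << 2) | (uint64_t)b) & mask;
                }
                if (ok) {
                    auto it = idx.map.find(h);
                    if (it != idx.map.end())
                        for (const Posting &p : it->second)
                            raw.push_back(((long long)p.target << 24) +
                                          ((long long)p.pos - off + (1LL << 22)));
                }
                if (off != last && off + seed_step > last) off = last - seed_step; // force last
            }
            if (raw.empty()) continue;
            std::sort(raw.begin(), raw.end());
            votes.clear();
            for (size_t a = 0; a < raw.size();) {
                size_t b = a;
                while (b < raw.size() && raw[b] == raw[a]) ++b;
                votes.push_back(std::make_pair(raw[a], (int)(b - a)));
                a = b;
            }
            int ncand = std::min((int)votes.size(), max_cand);
            std::partial_sort(votes.begin(), votes.begin() + ncand, votes.end(),
                              [](const std::pair<long long,int> &a,
                                 const std::pair<long long,int> &b) {
                                  if (a.second != b.second) return a.second > b.second;
                                  return a.first < b.first;
                              });
            for (int c = 0; c < ncand; ++c) {
                long long key = votes[c].first;
                int t = (int)(key >> 24);
                long diag = (long)(key & ((1LL << 24) - 1)) - (1L << 22);
                const std::string &ts = tg[t];
                long tlen = (long)ts.size();
                long q0 = std::max(0L, -diag);
                long q1 = std::min((long)qlen, tlen - diag);
                if (q1 - q0 < seed_len) continue;
                int matches = 0;
                for (long j = q0; j < q1; ++j)
                    if (qs[j] == ts[j + diag]) ++matches;
                Hit h2;
                h2.target = t; h2.diag = diag; h2.strand = strand;
                h2.score = matches; h2.overlap = (int)(q1 - q0);
                h2.tstart = q0 + diag; h2.qstart = q0;
                hits.push_back(h2);
            }
        }
        // best hit and the two flavours of runner-up; ties broken by target,
        // then diagonal, then strand so results are order-independent
        for (const Hit &h : hits) {
            if (h.score > best.score) { best = h; continue; }
            if (h.score == best.score && best.target >= 0) {
                if (h.target < best.target ||
                    (h.target == best.target &&
                     (h.diag < best.diag ||
                      (h.diag == best.diag && h.strand > best.strand))))
                    best = h;
            }
        }
        for (const Hit &h : hits) {
            if (h.target != best.target && h.score > sec_other_target.score)
                sec_other_target = h;
            bool same_locus = (h.target == best.target && h.strand == best.strand &&
                               labs(h.diag - best.diag) < (long)(qlen / 2));
            // a co-located opposite-strand or shifted placement that covers a
            // distinct interval counts as a different locus
            if (h.target == best.target && h.strand != best.strand) {
                long ov = std::min(h.tstart + h.overlap, best.tstart + best.overlap) -
                          std::max(h.tstart, best.tstart);
                same_locus = (ov > (long)(qlen / 2));
            }
            if (!same_locus && !(h.target == best.target && h.strand == best.strand &&
                                 h.diag == best.diag) &&
                h.score > sec_other_locus.score)
                sec_other_locus = h;
        }
        if (best.target >= 0) {
            r_target[q] = best.target + 1;
            r_score[q] = best.score;
            r_overlap[q] = best.overlap;
            r_strand[q] = best.strand;
            r_tstart[q] = (double)best.tstart;
            r_qstart[q] = (double)best.qstart;
            r_sec_target[q] = std::max(0, sec_other_target.score);
            r_sec_locus[q] = std::max(0, sec_other_locus.score);
        }
    }
    return List::create(_["target"] = r_target, _["score"] = r_score,
                        _["overlap"] = r_overlap, _["strand"] = r_strand,
                        _["tstart"] = r_tstart, _["qstart"] = r_qstart,
                        _["qlen"] = r_qlen,
                        _["second_target_score"] = r_sec_target,
                        _["second_locus_score"] = r_sec_locus);
}
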