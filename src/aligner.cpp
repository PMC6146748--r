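#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <string>
#include <cstdint>

using namespace Rcpp;

// Seed-and-extend local aligner used for fragment-based ANI and read
// recruitment. Exact k-mer seeds locate candidate diagonals; each candidate
// is extended with banded affine-gap Smith-Waterman and the best-scoring
// local alignment over both strands is returned. Gap of length k costs
// gap_open + k * gap_ext (the convention of Biostrings::pairwiseAlignment,
// against which the aligner is cross-checked in the tests).

static const int NEG = -1073741824 / 2; // -inf sentinel, safe from overflow

static inline int base2bit(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static std::string revcomp(const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (auto& c : r) {
        switch (c) {
        case 'A': case 'a': c = 'T'; break;
        case 'C': case 'c': c = 'G'; break;
        case 'G': case 'g': c = 'C'; break;
        case 'T': case 't': c = 'A'; break;
        default: c = 'N';
        }
    }
    return r;
}

typedef std::unordered_map<uint32_t, std::vector<int> > KmerIndex;

// positions (0-based) of every exact k-mer over {A,C,G,T}; k-mers touching
// other letters are skipped
static KmerIndex build_index(const std::string& s, int k) {
    KmerIndex idx;
    const int n = (int)s.size();
    if (n < k) return idx;
    const uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
    uint32_t key = 0;
    int run = 0; // valid bases accumulated
    for (int i = 0; i < n; ++i) {
        int b = base2bit(s[i]);
        if (b < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint32_t)b) & mask;
        if (++run >= k) idx[key].push_back(i - k + 1);
    }
    return idx;
}

struct Hit {
    int score, matches, columns, q_start, q_end, s_start, s_end;
    bool found;
    Hit() : score(0), matches(0), columns(0), q_start(0), q_end(0),
            s_start(0), s_end(0), found(false) {}
};

// banded affine local alignment centred on diagonal d (subject = query + d);
// coordinates in/out are 0-based
static Hit banded_sw(const std::string& q, const std::string& s, int d, int w,
                     int match, int mismatch, int go, int ge) {
    const int Lq = (int)q.size(), Ls = (int)s.size();
    const int bw = 2 * w + 1;
    Hit best;
    std::vector<int> H((size_t)(Lq + 1) * bw, NEG);
    std::vector<int> E((size_t)(Lq + 1) * bw, NEG);
    std::vector<int> F((size_t)(Lq + 1) * bw, NEG);
    // row 0: alignment may start before any query base
    for (int b = 0; b < bw; ++b) {
        int j = d + b - w;
        if (j >= 0 && j <= Ls) H[b] = 0;
    }
    int bi = -1, bj = -1, bscore = 0;
    for (int i = 1; i <= Lq; ++i) {
        int jmin = std::max(1, i + d - w);
        int jmax = std::min(Ls, i + d + w);
        if (jmin > jmax) continue;
        size_t row = (size_t)i * bw, prow = (size_t)(i - 1) * bw;
        for (int j = jmin; j <= jmax; ++j) {
            int b = j - (i + d) + w;
            int hd = (i - 1 == 0 || j - 1 == 0) ? 0 : H[prow + b];
            int sub = NEG;
            if (hd > NEG / 2) {
                int qb = base2bit(q[i - 1]), sb = base2bit(s[j - 1]);
                sub = hd + ((qb >= 0 && qb == sb) ? match : mismatch);
            }
            int e = NEG;
            if (b - 1 >= 0) {
                int hopen = H[row + b - 1];
                int eext = E[row + b - 1];
                if (hopen > NEG / 2) e = hopen - go - ge;
                if (eext > NEG / 2) e = std::max(e, eext - ge);
            }
            int f = NEG;
            if (b + 1 < bw) {
                int hopen = H[prow + b + 1];
                int fext = F[prow + b + 1];
                if (hopen > NEG / 2) f = hopen - go - ge;
                if (fext > NEG / 2) f = std::max(f, fext - ge);
            }
            E[row + b] = e;
            F[row + b] = f;
            int h = std::max(0, std::max(sub, std::max(e, f)));
            H[row + b] = h;
            if (h > bscore) { bscore = h; bi = i; bj = j; }
        }
    }
    if (bscore <= 0) return best;
    // traceback
    int i = bi, j = bj, matches = 0, columns = 0;
    int state = 0; // 0 = H, 1 = E (gap in query), 2 = F (gap in subject)
    while (true) {
        int b = j - (i + d) + w;
        size_t row = (size_t)i * bw, prow = (size_t)(i - 1) * bw;
        if (state == 0) {
            int h = H[row + b];
            if (h == 0) break;
            int hd = (i - 1 == 0 || j - 1 == 0) ? 0 : H[prow + b];
            int qb = base2bit(q[i - 1]), sb = base2bit(s[j - 1]);
            int sub = (qb >= 0 && qb == sb) ? match : mismatch;
            if (hd > NEG / 2 && h == hd + sub) {
                ++columns;
                if (qb >= 0 && qb == sb) ++matches;
                --i; --j;
            } else if (h == E[row + b]) {
                state = 1;
            } else {
                state = 2;
            }
        } else if (state == 1) {
            // consumed subject base j, gap column in query
            ++columns;
            int e = E[row + b];
            int hprev = (b - 1 >= 0) ? H[row + b - 1] : NEG;
            int eprev = (b - 1 >= 0) ? E[row + b - 1] : NEG;
            --j;
            if (hprev > NEG / 2 && e == hprev - go - ge) state = 0;
            else if (eprev > NEG / 2 && e == eprev - ge) state = 1;
            else break; // should not happen
        } else {
            ++columns;
            int f = F[row + b];
            int hprev = (b + 1 < bw) ? H[prow + b + 1] : NEG;
            int fprev = (b + 1 < bw) ? F[prow + b + 1] : NEG;
            --i;
            if (hprev > NEG / 2 && f == hprev - go - ge) state = 0;
            else if (fprev > NEG / 2 && f == fprev - ge) state = 2;
            else break;
        }
        if (i < 0 || j < 0) break;
    }
    best.found = true;
    best.score = bscore;
    best.matches = matches;
    best.columns = columns;
    best.q_start = i;      // 0-based, half-open [q_start, q_end)
    best.q_end = bi;
    best.s_start = j;
    best.s_end = bj;
    return best;
}

struct Diag { int d; int hits; };

// candidate diagonals for one query orientation, clustered within the band
// half-width; returns representatives ordered by seed support
static std::vector<int> candidate_diagonals(const std::string& q,
                                            const KmerIndex& idx, int k, int w,
                                            int max_diags, int max_pos_per_kmer) {
    std::unordered_map<int, int> counts;
    const int n = (int)q.size();
    if (n >= k) {
        const uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
        uint32_t key = 0;
        int run = 0;
        for (int i = 0; i < n; ++i) {
            int b = base2bit(q[i]);
            if (b < 0) { run = 0; key = 0; continue; }
            key = ((key << 2) | (uint32_t)b) & mask;
            if (++run >= k) {
                KmerIndex::const_iterator it = idx.find(key);
                if (it != idx.end() && (int)it->second.size() <= max_pos_per_kmer) {
                    int qpos = i - k + 1;
                    for (size_t m = 0; m < it->second.size(); ++m)
                        counts[it->second[m] - qpos]++;
                }
            }
        }
    }
    std::vector<Diag> diags;
    diags.reserve(counts.size());
    for (std::unordered_map<int, int>::iterator it = counts.begin();
         it != counts.end(); ++it)
        diags.push_back({it->first, it->second});
    std::sort(diags.begin(), diags.end(),
              [](const Diag& a, const Diag& b) { return a.d < b.d; });
    // cluster diagonals closer than w; representative = most-supported member
    std::vector<Diag> reps;
    size_t i = 0;
    while (i < diags.size()) {
        size_t j = i;
        Diag rep = diags[i];
        int total = diags[i].hits;
        while (j + 1 < diags.size() && diags[j + 1].d - diags[j].d <= w) {
            ++j;
            total += diags[j].hits;
            if (diags[j].hits > rep.hits) rep = diags[j];
        }
        reps.push_back({rep.d, total});
        i = j + 1;
    }
    std::sort(reps.begin(), reps.end(),
              [](const Diag& a, const Diag& b) {
                  return a.hits > b.hits || (a.hits == b.hits && a.d < b.d);
              });
    std::vector<int> out;
    for (size_t m = 0; m < reps.size() && (int)m < max_diags; ++m)
        out.push_back(reps[m].d);
    return out;
}

static Hit align_one(const std::string& q, const std::string& subject,
                     const KmerIndex& idx, int k, double band_frac,
                     int match, int mismatch, int go, int ge, int max_diags,
                     int& strand_out) {
    int Lq = (int)q.size();
    int w = std::max(16, (int)std::lround(band_frac * Lq));
    Hit best;
    strand_out = 0;
    for (int strand = 0; strand < 2; ++strand) {
        std::string qq = strand == 0 ? q : revcomp(q);
        std::vector<int> diags =
            candidate_diagonals(qq, idx, k, w, max_diags, 256);
        for (size_t m = 0; m < diags.size(); ++m) {
            Hit h = banded_sw(qq, subject, diags[m], w, match, mismatch, go, ge);
            if (h.found && (!best.found || h.score > best.score)) {
                best = h;
                strand_out = strand;
            }
        }
    }
    return best;
}

// [[Rcpp::export(name = ".cpp_align_batch")]]
List cpp_align_batch(CharacterVector queries, std::string subject, int k,
                     double band_frac, int match, int mismatch, int gap_open,
                     int gap_ext, int max_diags) {
    const int n = queries.size();
    KmerIndex idx = build_index(subject, k);
    LogicalVector found(n);
    IntegerVector score(n), matches(n), columns(n), q_start(n), q_end(n),
        s_start(n), s_end(n);
    CharacterVector strand(n);
    for (int i = 0; i < n; ++i) {
        std::string q = as<std::string>(queries[i]);
        int st = 0;
        Hit h = align_one(q, subject, idx, k, band_frac, match, mismatch,
                          gap_open, gap_ext, max_diags, st);
        found[i] = h.found;
        if (h.found) {
            score[i] = h.score;
            matches[i] = h.matches;
            columns[i] = h.columns;
            if (st == 1) {
                // report coordinates on the forward query strand
                int lq = (int)q.size();
                q_start[i] = lq - h.q_end;
                q_end[i] = lq - h.q_start;
            } else {
                q_start[i] = h.q_start;
                q_end[i] = h.q_end;
            }
            s_start[i] = h.s_start;
            s_end[i] = h.s_end;
            strand[i] = st == 0 ? "+" : "-";
        } else {
            score[i] = NA_INTEGER;
            matches[i] = NA_INTEGER;
            columns[i] = NA_INTEGER;
            q_start[i] = NA_INTEGER;
            q_end[i] = NA_INTEGER;
            s_start[i] = NA_INTEGER;
            s_end[i] = NA_INTEGER;
            strand[i] = NA_STRING;
        }
    }
    return List::create(_["found"] = found, _["score"] = score,
                        _["matches"] = matches, _["columns"] = columns,
                        _["q_start"] = q_start, _["q_end"] = q_end,
                        _["s_start"] = s_start, _["s_end"] = s_end,
                        _["strand"] = strand);
}
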