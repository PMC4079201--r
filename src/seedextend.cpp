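#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline int baseCode(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
    }
}

struct Hsp {
    long long sstart, send;   // 0-based half-open on subject
    long long qstart, qend;   // 0-based half-open on query
    long long score, matches, len;
};

// Ungapped X-drop extension of an exact seed match, BLASTN-style.
// query is searched as given; the caller handles the minus strand by passing
// the reverse complement of the query.  Returns one HSP per surviving
// (seed, diagonal) extension; overlap resolution happens in R.
// [[Rcpp::export(name = ".seed_extend")]]
DataFrame seed_extend_cpp(std::string query, std::string subject,
                          int seed_len, int match, int mismatch, int xdrop) {
    long long qn = (long long)query.size(), sn = (long long)subject.size();
    if (seed_len < 1 || seed_len > 31) stop("seed_len must be in [1, 31]");
    if (qn < seed_len) stop("query shorter than seed length");
    const char *q = query.c_str(), *s = subject.c_str();

    // index query seeds: code -> query start positions
    const uint64_t mask = ((uint64_t)1 << (2 * seed_len)) - 1;
    std::unordered_map<uint64_t, std::vector<int> > index;
    {
        uint64_t code = 0;
        int run = 0;
        for (long long i = 0; i < qn; ++i) {
            int c = baseCode(q[i]);
            if (c < 0) { run = 0; code = 0; continue; }
            code = ((code << 2) | (uint64_t)c) & mask;
            if (++run >= seed_len)
                index[code].push_back((int)(i - seed_len + 1));
        }
    }

    // per-diagonal high-water mark: skip seeds inside an already-extended HSP
    std::unordered_map<long long, long long> diagEnd;
    std::vector<Hsp> hsps;

    uint64_t code = 0;
    int run = 0;
    for (long long j = 0; j < sn; ++j) {
        int c = baseCode(s[j]);
        if (c < 0) { run = 0; code = 0; continue; }
        code = ((code << 2) | (uint64_t)c) & mask;
        if (++run < seed_len) continue;
        auto it = index.find(code);
        if (it == index.end()) continue;
        long long spos = j - seed_len + 1;
        for (int qpos : it->second) {
            long long diag = spos - qpos;
            auto de = diagEnd.find(diag);
            if (de != diagEnd.end() && spos < de->second) continue;

            // extend right from the seed end
            long long best = 0, cur = 0, bestExt = 0, bestMat = 0, mat = 0;
            long long qi = qpos + seed_len, si = spos + seed_len;
            long long ext = 0;
            while (qi < qn && si < sn) {
                int a = baseCode(q[qi]), b = baseCode(s[si]);
                if (a < 0 || b < 0) break;
                cur += (a == b) ? match : mismatch;
                mat += (a == b);
                ++ext; ++qi; ++si;
                if (cur > best) { best = cur; bestExt = ext; bestMat = mat; }
                if (best - cur > xdrop) break;
            }
            long long rScore = best, rExt = bestExt, rMat = bestMat;

            // extend left from the seed start
            best = 0; cur = 0; bestExt = 0; bestMat = 0; mat = 0; ext = 0;
            qi = qpos - 1; si = spos - 1;
            while (qi >= 0 && si >= 0) {
                int a = baseCode(q[qi]), b = baseCode(s[si]);
                if (a < 0 || b < 0) break;
                cur += (a == b) ? match : mismatch;
                mat += (a == b);
                ++ext; --qi; --si;
                if (cur > best) { best = cur; bestExt = ext; bestMat = mat; }
                if (best - cur > xdrop) break;
            }
            long long lScore = best, lExt = bestExt, lMat = bestMat;

            Hsp h;
            h.qstart = qpos - lExt;
            h.qend   = qpos + seed_len + rExt;
            h.sstart = spos - lExt;
            h.send   = spos + seed_len + rExt;
            h.len    = h.send - h.sstart;
            h.score  = (long long)seed_len * match + lScore + rScore;
            h.matches = seed_len + lMat + rMat;
            hsps.push_back(h);
            diagEnd[diag] = h.send;
        }
    }

    R_xlen_t m = (R_xlen_t)hsps.size();
    NumericVector sstart(m), send(m), qstart(m), qend(m), score(m),
        matches(m), len(m);
    for (R_xlen_t i = 0; i < m; ++i) {
        sstart[i] = (double)hsps[i].sstart;
        send[i] = (double)hsps[i].send;
        qstart[i] = (double)hsps[i].qstart;
        qend[i] = (double)hsps[i].qend;
        score[i] = (double)hsps[i].score;
        matches[i] = (double)hsps[i].matches;
        len[i] = (double)hsps[i].len;
    }
    return DataFrame::create(
        _["sstart"] = sstart, _["send"] = send, _["qstart"] = qstart,
        _["qend"] = qend, _["score"] = score, _["matches"] = matches,
        _["length"] = len);
}
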