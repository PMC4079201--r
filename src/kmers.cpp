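#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// 2-bit base encoding; anything not ACGT (upper case) is invalid and breaks
// the current window.  Encoded order A<C<G<T matches lexicographic order, so
// min(code, rc_code) is the lexicographically smaller of kmer/revcomp.
static inline int baseCode(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
    }
}

// k <= 26 so that the code fits exactly in a double (4^26 = 2^52 < 2^53);
// counts and codes cross the R boundary as numeric vectors.
static const int KMAX = 26;

static void checkK(int k) {
    if (k < 1 || k > KMAX)
        stop("k must be in [1, %d]", KMAX);
}

// Roll over one sequence, calling emit(pos0, code) at every window of k
// consecutive ACGT bases.  canonical: code = min(forward, revcomp).
template <typename F>
static void scanSeq(const char *s, R_xlen_t n, int k, bool canonical, F emit) {
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    const int shift = 2 * (k - 1);
    uint64_t fwd = 0, rc = 0;
    int run = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
        int c = baseCode(s[i]);
        if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)c) & mask;
        rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
        if (++run >= k) {
            uint64_t code = canonical ? (fwd < rc ? fwd : rc) : fwd;
            emit(i - k + 1, code);
        }
    }
}

// [[Rcpp::export(name = ".kmer_count")]]
List kmer_count_cpp(CharacterVector seqs, int k, bool canonical) {
    checkK(k);
    std::unordered_map<uint64_t, double> tab;
    double totalLength = 0, nWindows = 0;
    for (R_xlen_t j = 0; j < seqs.size(); ++j) {
        const char *s = CHAR(STRING_ELT(seqs, j));
        R_xlen_t n = LENGTH(STRING_ELT(seqs, j));
        totalLength += (double)n;
        scanSeq(s, n, k, canonical, [&](R_xlen_t, uint64_t code) {
            tab[code] += 1.0;
            nWindows += 1.0;
        });
    }
    R_xlen_t m = (R_xlen_t)tab.size();
    NumericVector codes(m), counts(m);
    R_xlen_t i = 0;
    for (auto &kv : tab) {
        codes[i] = (double)kv.first;
        counts[i] = kv.second;
        ++i;
    }
    return List::create(_["code"] = codes, _["count"] = counts,
                        _["total_length"] = totalLength,
                        _["n_windows"] = nWindows);
}

// Per-position scan of one sequence: 0-based start positions of each valid
// window and the (canonical) code at that position.
// [[Rcpp::export(name = ".kmer_scan")]]
List kmer_scan_cpp(std::string seq, int k, bool canonical) {
    checkK(k);
    std::vector<int> pos;
    std::vector<double> codes;
    pos.reserve(seq.size());
    codes.reserve(seq.size());
    scanSeq(seq.c_str(), (R_xlen_t)seq.size(), k, canonical,
            [&](R_xlen_t p, uint64_t code) {
                pos.push_back((int)p);
                codes.push_back((double)code);
            });
    return List::create(_["pos"] = wrap(pos), _["code"] = wrap(codes));
}

// [[Rcpp::export(name = ".kmer_decode")]]
CharacterVector kmer_decode_cpp(NumericVector codes, int k) {
    checkK(k);
    static const char B[] = "ACGT";
    CharacterVector out(codes.size());
    std::string buf(k, 'A');
    for (R_xlen_t i = 0; i < codes.size(); ++i) {
        uint64_t code = (uint64_t)codes[i];
        for (int j = k - 1; j >= 0; --j) {
            buf[j] = B[code & 3ULL];
            code >>= 2;
        }
        out[i] = buf;
    }
    return out;
}

// Hash lookup of query codes in a (code, count) table; absent -> 0.
// [[Rcpp::export(name = ".kmer_lookup")]]
NumericVector kmer_lookup_cpp(NumericVector query, NumericVector codes,
                              NumericVector counts) {
    std::unordered_map<uint64_t, double> tab;
    tab.reserve((size_t)codes.size() * 2);
    for (R_xlen_t i = 0; i < codes.size(); ++i)
        tab[(uint64_t)codes[i]] = counts[i];
    NumericVector out(query.size());
    for (R_xlen_t i = 0; i < query.size(); ++i) {
        auto it = tab.find((uint64_t)query[i]);
        out[i] = (it == tab.end()) ? 0.0 : it->second;
    }
    return out;
}

// Forward (non-canonical) integer codes per position, NA at windows touching
// a non-ACGT base.  Used by the autocorrelation period finder (k <= 15).
// [[Rcpp::export(name = ".kmer_codes_at")]]
IntegerVector kmer_codes_at_cpp(std::string seq, int k) {
    if (k < 1 || k > 15) stop("k must be in [1, 15]");
    R_xlen_t n = (R_xlen_t)seq.size();
    R_xlen_t m = n - k + 1;
    if (m < 1) return IntegerVector(0);
    IntegerVector out(m, NA_INTEGER);
    scanSeq(seq.c_str(), n, k, false, [&](R_xlen_t p, uint64_t code) {
        out[p] = (int)code;
    });
    return out;
}
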