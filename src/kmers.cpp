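// Core k-mer machinery: canonical counting, unitig extension, depth
// annotation and contaminant-share scoring. Sequences are 2-bit encoded
// in unsigned __int128 so any odd k <= 63 fits (17 for spectra, 41 for
// assembly). Windows containing non-ACGT characters are skipped.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

typedef unsigned __int128 u128;

struct U128Hash {
    size_t operator()(const u128& x) const {
        uint64_t lo = (uint64_t)x;
        uint64_t hi = (uint64_t)(x >> 64);
        // splitmix-style mix; hi is zero for k <= 32 which is fine
        uint64_t z = lo ^ (hi * 0x9E3779B97F4A7C15ULL);
        z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
        z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
        return (size_t)(z ^ (z >> 31));
    }
};

typedef std::unordered_map<u128, uint32_t, U128Hash> KmerMap;
typedef std::unordered_set<u128, U128Hash> KmerSet;

static inline int base2bits(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    }
    return -1;
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

static inline u128 kmask(int k) {
    return (((u128)1) << (2 * k)) - 1;
}

static u128 rc_code(u128 x, int k) {
    u128 r = 0;
    for (int i = 0; i < k; ++i) {
        r = (r << 2) | (3 - (unsigned)(x & 3));
        x >>= 2;
    }
    return r;
}

static std::string decode(u128 x, int k) {
    std::string s(k, 'A');
    for (int i = k - 1; i >= 0; --i) {
        s[i] = BITS2BASE[(unsigned)(x & 3)];
        x >>= 2;
    }
    return s;
}

static void check_k(int k) {
    if (k < 3 || k > 63) stop("k must be between 3 and 63");
}

// Visit every N-free window of every sequence, calling f(canonical code).
template <typename F>
static void for_each_canonical(const CharacterVector& seqs, int k, F f) {
    const u128 mask = kmask(k);
    const int shift = 2 * (k - 1);
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        if (seqs[i] == NA_STRING) continue;
        const char* s = CHAR(seqs[i]);
        int n = (int)LENGTH(seqs[i]);
        u128 fwd = 0, rev = 0;
        int valid = 0;
        for (int j = 0; j < n; ++j) {
            int b = base2bits(s[j]);
            if (b < 0) { valid = 0; continue; }
            fwd = ((fwd << 2) | (unsigned)b) & mask;
            rev = (rev >> 2) | ((u128)(3 - b) << shift);
            if (++valid >= k) f(fwd < rev ? fwd : rev);
        }
    }
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
    CharacterVector out(seqs.size());
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        if (seqs[i] == NA_STRING) { out[i] = NA_STRING; continue; }
        const char* s = CHAR(seqs[i]);
        int n = (int)LENGTH(seqs[i]);
        std::string r(n, 'N');
        for (int j = 0; j < n; ++j) {
            char c = s[n - 1 - j], o;
            switch (c) {
            case 'A': o = 'T'; break; case 'a': o = 't'; break;
            case 'C': o = 'G'; break; case 'c': o = 'g'; break;
            case 'G': o = 'C'; break; case 'g': o = 'c'; break;
            case 'T': o = 'A'; break; case 't': o = 'a'; break;
            default:  o = c;
            }
            r[j] = o;
        }
        out[i] = r;
    }
    return out;
}

// Depth histogram of canonical k-mer occurrence counts.
// Returns list(depth = integer, species = numeric), depth ascending.
// [[Rcpp::export]]
List kmer_hist_cpp(CharacterVector seqs, int k) {
    check_k(k);
    KmerMap counts;
    for_each_canonical(seqs, k, [&](u128 c) { ++counts[c]; });
    std::unordered_map<uint32_t, double> hist;
    for (const auto& kv : counts) hist[kv.second] += 1.0;
    std::vector<uint32_t> depths;
    depths.reserve(hist.size());
    for (const auto& kv : hist) depths.push_back(kv.first);
    std::sort(depths.begin(), depths.end());
    IntegerVector d(depths.size());
    NumericVector n(depths.size());
    for (size_t i = 0; i < depths.size(); ++i) {
        d[i] = (int)depths[i];
        n[i] = hist[depths[i]];
    }
    return List::create(_["depth"] = d, _["species"] = n);
}

// Sorted unique canonical k-mers as strings (small inputs: contaminant DBs).
// [[Rcpp::export]]
CharacterVector canonical_kmers_cpp(CharacterVector seqs, int k) {
    check_k(k);
    KmerSet set;
    for_each_canonical(seqs, k, [&](u128 c) { set.insert(c); });
    std::vector<u128> v(set.begin(), set.end());
    std::sort(v.begin(), v.end());
    CharacterVector out(v.size());
    for (size_t i = 0; i < v.size(); ++i) out[i] = decode(v[i], k);
    return out;
}

// Per-read fraction of N-free k-mers found in a database k-mer set.
// Reads with no valid window get NA.
// [[Rcpp::export]]
NumericVector kmer_share_cpp(CharacterVector reads, CharacterVector db_kmers,
                             int k) {
    check_k(k);
    KmerSet db;
    const u128 mask = kmask(k);
    for (R_xlen_t i = 0; i < db_kmers.size(); ++i) {
        const char* s = CHAR(db_kmers[i]);
        if ((int)LENGTH(db_kmers[i]) != k)
            stop("database k-mer %d has length != k", (int)(i + 1));
        u128 f = 0;
        for (int j = 0; j < k; ++j) {
            int b = base2bits(s[j]);
            if (b < 0) stop("database k-mer %d contains non-ACGT", (int)(i + 1));
            f = ((f << 2) | (unsigned)b) & mask;
        }
        u128 r = rc_code(f, k);
        db.insert(f < r ? f : r);
    }
    const int shift = 2 * (k - 1);
    NumericVector out(reads.size());
    for (R_xlen_t i = 0; i < reads.size(); ++i) {
        if (reads[i] == NA_STRING) { out[i] = NA_REAL; continue; }
        const char* s = CHAR(reads[i]);
        int n = (int)LENGTH(reads[i]);
        u128 fwd = 0, rev = 0;
        int valid = 0;
        long total = 0, hits = 0;
        for (int j = 0; j < n; ++j) {
            int b = base2bits(s[j]);
            if (b < 0) { valid = 0; continue; }
            fwd = ((fwd << 2) | (unsigned)b) & mask;
            rev = (rev >> 2) | ((u128)(3 - b) << shift);
            if (++valid >= k) {
                ++total;
                if (db.count(fwd < rev ? fwd : rev)) ++hits;
            }
        }
        out[i] = total > 0 ? (double)hits / (double)total : NA_REAL;
    }
    return out;
}

// Mean read-k-mer depth across each contig's N-free windows; k-mers absent
// from the reads count as depth 0. Contigs without a valid window get NA.
// [[Rcpp::export]]
NumericVector mean_kmer_depth_cpp(CharacterVector contigs,
                                  CharacterVector reads, int k) {
    check_k(k);
    KmerMap counts;
    for_each_canonical(reads, k, [&](u128 c) { ++counts[c]; });
    const u128 mask = kmask(k);
    const int shift = 2 * (k - 1);
    NumericVector out(contigs.size());
    for (R_xlen_t i = 0; i < contigs.size(); ++i) {
        if (contigs[i] == NA_STRING) { out[i] = NA_REAL; continue; }
        const char* s = CHAR(contigs[i]);
        int n = (int)LENGTH(contigs[i]);
        u128 fwd = 0, rev = 0;
        int valid = 0;
        double sum = 0;
        long total = 0;
        for (int j = 0; j < n; ++j) {
            int b = base2bits(s[j]);
            if (b < 0) { valid = 0; continue; }
            fwd = ((fwd << 2) | (unsigned)b) & mask;
            rev = (rev >> 2) | ((u128)(3 - b) << shift);
            if (++valid >= k) {
                ++total;
                KmerMap::const_iterator it =
                    counts.find(fwd < rev ? fwd : rev);
                if (it != counts.end()) sum += it->second;
            }
        }
        out[i] = total > 0 ? sum / (double)total : NA_REAL;
    }
    return out;
}

// ---- unitig assembly ------------------------------------------------------

struct Ori {  // an oriented k-mer: forward code + its reverse complement
    u128 f, r;
    u128 canon() const { return f < r ? f : r; }
};

// oriented right-neighbours of x whose canonical form is in S
static int right_exts(const Ori& x, const KmerSet& S, int k, Ori out[4]) {
    const u128 mask = kmask(k);
    const int shift = 2 * (k - 1);
    int cnt = 0;
    for (unsigned b = 0; b < 4; ++b) {
        Ori y;
        y.f = ((x.f << 2) | b) & mask;
        y.r = (x.r >> 2) | ((u128)(3 - b) << shift);
        if (S.count(y.canon())) out[cnt++] = y;
    }
    return cnt;
}

static int left_exts(const Ori& x, const KmerSet& S, int k, Ori out[4]) {
    const u128 mask = kmask(k);
    const int shift = 2 * (k - 1);
    int cnt = 0;
    for (unsigned a = 0; a < 4; ++a) {
        Ori y;
        y.f = (x.f >> 2) | ((u128)a << shift);
        y.r = ((x.r << 2) | (3 - a)) & mask;
        if (S.count(y.canon())) out[cnt++] = y;
    }
    return cnt;
}

// Maximal non-branching paths over canonical k-mers with count >= min_count.
// Each unitig is reported once, in the lexicographically smaller of its two
// orientations; output sorted by decreasing length then sequence.
// [[Rcpp::export]]
CharacterVector build_unitigs_cpp(CharacterVector reads, int k,
                                  int min_count) {
    check_k(k);
    if (k % 2 == 0) stop("k must be odd");
    if (min_count < 1) stop("min_count must be >= 1");
    KmerMap counts;
    for_each_canonical(reads, k, [&](u128 c) { ++counts[c]; });
    KmerSet S;
    std::vector<u128> order;  // deterministic seed order
    {
        std::vector<u128> all;
        all.reserve(counts.size());
        for (const auto& kv : counts)
            if ((int)kv.second >= min_count) all.push_back(kv.first);
        std::sort(all.begin(), all.end());
        for (u128 c : all) S.insert(c);
        order.swap(all);
    }
    KmerSet visited;
    std::vector<std::string> unitigs;
    Ori cand[4], chk[4];
    for (u128 seed : order) {
        if (visited.count(seed)) continue;
        visited.insert(seed);
        Ori start;
        start.f = seed;
        start.r = rc_code(seed, k);
        std::string right, left;  // bases appended right / prepended left
        Ori x = start;
        while (true) {  // extend rightwards
            if (right_exts(x, S, k, cand) != 1) break;
            Ori y = cand[0];
            if (visited.count(y.canon())) break;
            if (left_exts(y, S, k, chk) != 1) break;
            visited.insert(y.canon());
            right.push_back(BITS2BASE[(unsigned)(y.f & 3)]);
            x = y;
        }
        x = start;
        while (true) {  // extend leftwards
            if (left_exts(x, S, k, cand) != 1) break;
            Ori y = cand[0];
            if (visited.count(y.canon())) break;
            if (right_exts(y, S, k, chk) != 1) break;
            visited.insert(y.canon());
            left.push_back(BITS2BASE[(unsigned)((y.f >> (2 * (k - 1))) & 3)]);
            x = y;
        }
        std::reverse(left.begin(), left.end());
        std::string seq = left + decode(seed, k) + right;
        // canonical orientation of the whole unitig
        std::string rc(seq.size(), 'A');
        for (size_t j = 0; j < seq.size(); ++j) {
            char c = seq[seq.size() - 1 - j];
            rc[j] = c == 'A' ? 'T' : c == 'C' ? 'G' : c == 'G' ? 'C' : 'A';
        }
        unitigs.push_back(std::min(seq, rc));
    }
    std::sort(unitigs.begin(), unitigs.end(),
              [](const std::string& a, const std::string& b) {
                  if (a.size() != b.size()) return a.size() > b.size();
                  return a < b;
              });
    return wrap(unitigs);
}
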