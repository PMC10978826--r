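#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

// Local (Smith-Waterman) alignment with affine gap penalties, plus a
// traceback that reports the number of identical columns and the total
// number of alignment columns (gap columns included) -- the quantities
// behind the BLAST-style percent identity. A gap of length k costs
// gap_open + k * gap_extend, matching the convention of
// Biostrings::pairwiseAlignment(gapOpening=, gapExtension=).
//
// Only the four unambiguous bases can score a match or count as an
// identity; any column involving an ambiguity code (N, R, Y, ...) is a
// mismatch column.
//
// Scores live in rolling rows (three states: M diagonal, E gap-in-query,
// F gap-in-subject); the traceback is packed into one byte per cell
// (2 bits per state) to keep the working set small.

static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static std::vector<int> encode(const std::string &s) {
    std::vector<int> v(s.size());
    for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
    return v;
}

struct AlnResult {
    int score;
    int identities;
    int length; // alignment columns, gaps included
};

// Traceback byte: bits 0-1 = predecessor of M (0 start, 1 M, 2 E, 3 F);
// bits 2-3 = predecessor of E (moves left); bits 4-5 = predecessor of F
// (moves up). Ties break deterministically: M prefers M > F > E, E prefers
// staying in E, F prefers staying in F.
static AlnResult sw_align(const std::vector<int> &ca,
                          const std::vector<int> &cb, int match,
                          int mismatch, int gap_open, int gap_extend,
                          std::vector<unsigned char> &tb) {
    const int n = (int)ca.size(), m = (int)cb.size();
    const int NEG = std::numeric_limits<int>::min() / 4;
    const int oc = gap_open + gap_extend; // cost of the first gap column

    if (tb.size() < (size_t)n * m) tb.resize((size_t)n * m);
    std::vector<int> Mp(m + 1, 0), Ep(m + 1, NEG), Fp(m + 1, NEG);
    std::vector<int> Mc(m + 1), Ec(m + 1), Fc(m + 1);

    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
        unsigned char *trow = tb.data() + (size_t)(i - 1) * m;
        Mc[0] = 0;
        Ec[0] = NEG;
        Fc[0] = NEG;
        const int ai = ca[i - 1];
        for (int j = 1; j <= m; ++j) {
            const int s = (ai >= 0 && ai == cb[j - 1]) ? match : mismatch;

            // M: best predecessor among M/E/F at (i-1, j-1)
            const int dM = Mp[j - 1], dE = Ep[j - 1], dF = Fp[j - 1];
            int dbest = dM, mpred = 1;
            if (dF > dbest) { dbest = dF; mpred = 3; }
            if (dE > dbest) { dbest = dE; mpred = 2; }
            if (dbest <= 0) { dbest = 0; mpred = 0; }
            const int mv = dbest + s;
            Mc[j] = mv > 0 ? mv : 0;

            // E: gap in a, extends leftwards along b
            const int eE = Ec[j - 1] - gap_extend;
            const int eM = Mc[j - 1] - oc;
            const int eF = Fc[j - 1] - oc;
            int ev = eE, epred = 2;
            if (eM > ev) { ev = eM; epred = 1; }
            if (eF > ev) { ev = eF; epred = 3; }
            Ec[j] = ev;

            // F: gap in b, extends downwards along a
            const int fF = Fp[j] - gap_extend;
            const int fM = Mp[j] - oc;
            const int fE = Ep[j] - oc;
            int fv = fF, fpred = 3;
            if (fM > fv) { fv = fM; fpred = 1; }
            if (fE > fv) { fv = fE; fpred = 2; }
            Fc[j] = fv;

            trow[j - 1] =
                (unsigned char)(mpred | (epred << 2) | (fpred << 4));

            if (Mc[j] > best) { best = Mc[j]; bi = i; bj = j; }
        }
        Mp.swap(Mc);
        Ep.swap(Ec);
        Fp.swap(Fc);
    }

    AlnResult res;
    res.score = best;
    res.identities = 0;
    res.length = 0;
    if (best <= 0) return res; // no positive-scoring local alignment

    int i = bi, j = bj, state = 1; // optimal local alignments end in M
    while (true) {
        const unsigned char t = tb[(size_t)(i - 1) * m + (j - 1)];
        if (state == 1) {
            res.length += 1;
            if (ca[i - 1] >= 0 && ca[i - 1] == cb[j - 1]) res.identities++;
            const int pred = t & 3;
            --i;
            --j;
            if (pred == 0) break;
            state = pred;
        } else if (state == 2) { // E: gap column consuming b[j-1]
            res.length += 1;
            state = (t >> 2) & 3;
            --j;
        } else { // F: gap column consuming a[i-1]
            res.length += 1;
            state = (t >> 4) & 3;
            --i;
        }
    }
    return res;
}

// [[Rcpp::export(name = ".sw_align_one")]]
IntegerVector sw_align_one(std::string a, std::string b, int match,
                           int mismatch, int gap_open, int gap_extend) {
    std::vector<int> ca = encode(a), cb = encode(b);
    std::vector<unsigned char> tb;
    AlnResult r = sw_align(ca, cb, match, mismatch, gap_open, gap_extend, tb);
    return IntegerVector::create(_["score"] = r.score,
                                 _["identities"] = r.identities,
                                 _["length"] = r.length);
}

// All-vs-all identity over both strands. `seqs` and `rcseqs` are the
// forward and reverse-complemented sequences (reverse complements computed
// in R via Biostrings). Each unordered pair is aligned once, so the
// resulting matrices are exactly symmetric. Diagonal = self-hit (pident
// 100, length = sequence width, strand +).
// [[Rcpp::export(name = ".sw_identity_matrix")]]
List sw_identity_matrix(CharacterVector seqs, CharacterVector rcseqs,
                        int match, int mismatch, int gap_open,
                        int gap_extend) {
    const int n = seqs.size();
    NumericMatrix pident(n, n);
    IntegerMatrix alen(n, n);
    LogicalMatrix minus(n, n);
    std::vector<std::string> raw(n);
    std::vector<std::vector<int> > fw(n), rc(n);
    for (int i = 0; i < n; ++i) {
        raw[i] = as<std::string>(seqs[i]);
        fw[i] = encode(raw[i]);
        rc[i] = encode(as<std::string>(rcseqs[i]));
    }
    std::vector<unsigned char> tb;
    for (int i = 0; i < n; ++i) {
        pident(i, i) = 100.0;
        alen(i, i) = (int)fw[i].size();
        for (int j = i + 1; j < n; ++j) {
            // canonical argument order (lexicographically smaller sequence
            // first) so results are independent of input ordering even when
            // co-optimal alignments tie
            const bool swap = raw[j] < raw[i];
            const int a = swap ? j : i, b = swap ? i : j;
            AlnResult f = sw_align(fw[a], fw[b], match, mismatch, gap_open,
                                   gap_extend, tb);
            AlnResult r = sw_align(fw[a], rc[b], match, mismatch, gap_open,
                                   gap_extend, tb);
            const bool use_rev = r.score > f.score; // tie -> plus strand
            const AlnResult &bestr = use_rev ? r : f;
            const double pid = bestr.length > 0
                ? 100.0 * bestr.identities / bestr.length : 0.0;
            pident(i, j) = pident(j, i) = pid;
            alen(i, j) = alen(j, i) = bestr.length;
            minus(i, j) = minus(j, i) = use_rev;
        }
        Rcpp::checkUserInterrupt();
    }
    return List::create(_["pident"] = pident, _["length"] = alen,
                        _["minus"] = minus);
}
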