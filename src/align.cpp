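#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Profile-profile dynamic-programming alignment with linear gap penalties.
//
// A and B are 4 x n matrices of per-column A/C/G/T frequencies (IUPAC codes
// contribute 1/|base set| to each member base; gap characters contribute
// nothing, so column sums are <= 1).  The substitution score between two
// columns is the expected pairwise score
//   sum_{x,y} fA[x] fB[y] * (x == y ? match : mismatch)
// and the penalty for aligning a column against a gap is `gap` scaled by the
// column occupancy (its frequency sum), which reduces to the plain
// match/mismatch/gap scheme when both profiles are single ungapped sequences.
//
// Tie-breaking is fixed: diagonal, then up (consume A), then left (consume B),
// so results are fully deterministic.  local = true gives Smith-Waterman with
// a zero floor; the reported cell is the first best cell in row-major order.
//
// Returns list(score, a_cols, b_cols): a_cols/b_cols are 1-based column
// indices into A and B for each output column, 0 meaning a gap.
// [[Rcpp::export]]
List profile_align_cpp(NumericMatrix A, NumericMatrix B,
                       double match, double mismatch, double gap,
                       bool local) {
    if (A.nrow() != 4 || B.nrow() != 4)
        stop("profiles must have 4 rows (A, C, G, T)");
    const int na = A.ncol(), nb = B.ncol();
    const double* Ap = &A(0, 0);
    const double* Bp = &B(0, 0);

    std::vector<double> sumB(nb);
    for (int j = 0; j < nb; ++j) {
        const double* c = Bp + 4 * j;
        sumB[j] = c[0] + c[1] + c[2] + c[3];
    }

    // pointers: 0 = start/stop, 1 = diag, 2 = up, 3 = left
    std::vector<unsigned char> ptr((size_t)(na + 1) * (nb + 1), 0);
    std::vector<double> prev(nb + 1), cur(nb + 1);

    prev[0] = 0.0;
    for (int j = 1; j <= nb; ++j) {
        prev[j] = local ? 0.0 : prev[j - 1] + gap * sumB[j - 1];
        if (!local) ptr[j] = 3;
    }

    double best = 0.0;
    int best_i = 0, best_j = 0;

    for (int i = 1; i <= na; ++i) {
        const double* ac = Ap + 4 * (i - 1);
        const double a0 = ac[0], a1 = ac[1], a2 = ac[2], a3 = ac[3];
        const double sa = a0 + a1 + a2 + a3;
        const double gapA = gap * sa;
        unsigned char* prow = &ptr[(size_t)i * (nb + 1)];

        cur[0] = local ? 0.0 : prev[0] + gapA;
        if (!local) prow[0] = 2;
        for (int j = 1; j <= nb; ++j) {
            const double* bc = Bp + 4 * (j - 1);
            const double dot = a0 * bc[0] + a1 * bc[1] + a2 * bc[2]
                             + a3 * bc[3];
            const double sub = match * dot
                             + mismatch * (sa * sumB[j - 1] - dot);
            const double sd = prev[j - 1] + sub;
            const double su = prev[j] + gapA;
            const double sl = cur[j - 1] + gap * sumB[j - 1];

            double s;
            unsigned char p;
            if (sd >= su && sd >= sl)      { s = sd; p = 1; }
            else if (su >= sl)             { s = su; p = 2; }
            else                           { s = sl; p = 3; }
            if (local && s <= 0.0)         { s = 0.0; p = 0; }

            cur[j] = s;
            prow[j] = p;
            if (local && s > best) { best = s; best_i = i; best_j = j; }
        }
        std::swap(prev, cur);
    }

    int i = local ? best_i : na;
    int j = local ? best_j : nb;
    double score = local ? best : prev[nb];

    std::vector<int> ra, rb;
    while (i > 0 || j > 0) {
        unsigned char p = ptr[(size_t)i * (nb + 1) + j];
        if (p == 0) break;           // local start
        if (p == 1)      { ra.push_back(i); rb.push_back(j); --i; --j; }
        else if (p == 2) { ra.push_back(i); rb.push_back(0); --i; }
        else             { ra.push_back(0); rb.push_back(j); --j; }
    }
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());

    return List::create(_["score"] = score,
                        _["a_cols"] = IntegerVector(ra.begin(), ra.end()),
                        _["b_cols"] = IntegerVector(rb.begin(), rb.end()));
}

// Global-alignment score and identity statistics for every pair of integer-
// encoded sequences (values 0..14 indexing the IUPAC codes; the score table
// `subs` is 15 x 15 expected pairwise scores).  Returns, for each pair
// (i < j, column-major order), the number of matched identical characters,
// the number of alignment columns, and the number of columns aligning two
// residues.  Used for guide trees and subgroup clustering, where only these
// statistics (not the alignments) are needed.
// [[Rcpp::export]]
List pairwise_stats_cpp(List seqs, NumericMatrix subs, double gap) {
    const int n = seqs.size();
    if (subs.nrow() != 15 || subs.ncol() != 15)
        stop("substitution table must be 15 x 15");
    const double* S = &subs(0, 0);
    std::vector<std::vector<int> > enc(n);
    for (int i = 0; i < n; ++i) {
        IntegerVector v = seqs[i];
        enc[i].assign(v.begin(), v.end());
    }
    const int npair = n * (n - 1) / 2;
    IntegerVector matches(npair), columns(npair), paired(npair);
    int q = 0;
    for (int i = 0; i < n - 1; ++i) for (int j = i + 1; j < n; ++j, ++q) {
        const std::vector<int>& a = enc[i];
        const std::vector<int>& b = enc[j];
        const int na = (int)a.size(), nb = (int)b.size();
        std::vector<double> prev(nb + 1), cur(nb + 1);
        std::vector<unsigned char> ptr((size_t)(na + 1) * (nb + 1), 0);
        for (int jj = 1; jj <= nb; ++jj) { prev[jj] = jj * gap; ptr[jj] = 3; }
        for (int ii = 1; ii <= na; ++ii) {
            unsigned char* prow = &ptr[(size_t)ii * (nb + 1)];
            cur[0] = prev[0] + gap;
            prow[0] = 2;
            const double* srow = S + 15 * a[ii - 1];   // column of subs
            for (int jj = 1; jj <= nb; ++jj) {
                const double sd = prev[jj - 1] + srow[b[jj - 1]];
                const double su = prev[jj] + gap;
                const double sl = cur[jj - 1] + gap;
                double s;
                unsigned char p;
                if (sd >= su && sd >= sl)      { s = sd; p = 1; }
                else if (su >= sl)             { s = su; p = 2; }
                else                           { s = sl; p = 3; }
                cur[jj] = s;
                prow[jj] = p;
            }
            std::swap(prev, cur);
        }
        int ii = na, jj = nb, m = 0, cols = 0, pr = 0;
        while (ii > 0 || jj > 0) {
            unsigned char p = ptr[(size_t)ii * (nb + 1) + jj];
            ++cols;
            if (p == 1) {
                ++pr;
                if (a[ii - 1] == b[jj - 1]) ++m;
                --ii; --jj;
            } else if (p == 2) --ii;
            else --jj;
        }
        matches[q] = m; columns[q] = cols; paired[q] = pr;
    }
    return List::create(_["matches"] = matches, _["columns"] = columns,
                        _["paired"] = paired);
}
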