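#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Simplified base-pair maximization folder: weighted Nussinov dynamic
// program over pair pseudo-energies (G:C -3, A:T/U -2, G:T/U -1 kcal/mol,
// minimum hairpin loop of 3 nt). It is a coarse stand-in energy model for
// fast, dependency-free folding; the nearest-neighbor backend (RNAfold) is
// the default where available. Criteria in the prediction module are meant
// to be used with several kcal/mol margin so the backends agree on verdicts.

static double pair_energy(char a, char b) {
    if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
    if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return -2.0;
    if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return -1.0;
    return 1.0; // disallowed
}

static void traceback(const std::vector<std::vector<double> >& E,
                      const std::string& s, int i, int j,
                      std::string& db, int minloop) {
    if (i >= j) return;
    double e = E[i][j];
    if (E[i + 1][j] == e) { traceback(E, s, i + 1, j, db, minloop); return; }
    if (E[i][j - 1] == e) { traceback(E, s, i, j - 1, db, minloop); return; }
    double pe = pair_energy(s[i], s[j]);
    if (pe < 0 && j - i > minloop &&
        E[i + 1][j - 1] + pe == e) {
        db[i] = '(';
        db[j] = ')';
        traceback(E, s, i + 1, j - 1, db, minloop);
        return;
    }
    for (int k = i + 1; k < j; ++k) {
        if (E[i][k] + E[k + 1][j] == e) {
            traceback(E, s, i, k, db, minloop);
            traceback(E, s, k + 1, j, db, minloop);
            return;
        }
    }
}

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int minloop = 3) {
    int n = (int) seq.size();
    std::string db(n, '.');
    if (n < 2) return List::create(_["structure"] = db, _["mfe"] = 0.0);
    std::vector<std::vector<double> > E(n, std::vector<double>(n, 0.0));
    for (int len = 2; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            int j = i + len - 1;
            double best = E[i + 1][j];
            if (E[i][j - 1] < best) best = E[i][j - 1];
            double pe = pair_energy(seq[i], seq[j]);
            if (pe < 0 && j - i > minloop) {
                double cand = E[i + 1][j - 1] + pe;
                if (cand < best) best = cand;
            }
            for (int k = i + 1; k < j; ++k) {
                double cand = E[i][k] + E[k + 1][j];
                if (cand < best) best = cand;
            }
            E[i][j] = best;
        }
    }
    traceback(E, seq, 0, n - 1, db, minloop);
    return List::create(_["structure"] = db, _["mfe"] = E[0][n - 1]);
}
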