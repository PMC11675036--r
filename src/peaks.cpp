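#include <Rcpp.h>
using namespace Rcpp;

// Topographic prominence of a strict local maximum at index p (0-based).
static double prominence(const double* x, int n, int p) {
    double h = x[p];
    double lmin = h, rmin = h;
    for (int i = p - 1; i >= 0 && x[i] <= h; --i)
        if (x[i] < lmin) lmin = x[i];
    for (int i = p + 1; i < n && x[i] <= h; ++i)
        if (x[i] < rmin) rmin = x[i];
    return h - std::max(lmin, rmin);
}

// Count peaks in each column of x: strict local maxima with prominence
// >= prominence_k * sd(column), minimum spacing minsep samples (higher
// peaks claimed first). Mirrors the pure-R reference counter.
// [[Rcpp::export]]
IntegerVector count_peaks_bulk(NumericMatrix x, double prominence_k,
                               int minsep) {
    int nt = x.nrow(), nc = x.ncol();
    IntegerVector out(nc);
    std::vector<int> cand;
    for (int j = 0; j < nc; ++j) {
        const double* col = &x(0, j);
        double s = 0.0, m = 0.0;
        for (int t = 0; t < nt; ++t) m += col[t];
        m /= nt;
        for (int t = 0; t < nt; ++t) s += (col[t] - m) * (col[t] - m);
        s = std::sqrt(s / (nt - 1));
        // SD at numerical-noise level = motionless pixel, not a beat
        if (!(s >= 1e-8)) { out[j] = 0; continue; }
        double thr = prominence_k * s;
        cand.clear();
        for (int t = 1; t < nt - 1; ++t)
            if (col[t] > col[t - 1] && col[t] > col[t + 1] &&
                prominence(col, nt, t) >= thr)
                cand.push_back(t);
        if (minsep <= 1 || cand.size() < 2) {
            out[j] = (int) cand.size();
            continue;
        }
        // greedy by descending height, earlier index wins ties
        std::vector<int> order(cand.size());
        for (size_t i = 0; i < cand.size(); ++i) order[i] = (int) i;
        std::sort(order.begin(), order.end(), [&](int a, int b) {
            if (col[cand[a]] != col[cand[b]])
                return col[cand[a]] > col[cand[b]];
            return cand[a] < cand[b];
        });
        std::vector<int> taken;
        for (int oi : order) {
            int p = cand[oi];
            bool ok = true;
            for (int q : taken)
                if (std::abs(q - p) < minsep) { ok = false; break; }
            if (ok) taken.push_back(p);
        }
        out[j] = (int) taken.size();
    }
    return out;
}
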