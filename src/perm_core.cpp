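#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// median of buf (modified in place); matches stats::median for doubles
static double buf_median(std::vector<double> &buf) {
    const size_t m = buf.size();
    if (m % 2 == 1) {
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
        return buf[m / 2];
    }
    std::nth_element(buf.begin(), buf.begin() + m / 2 - 1, buf.end());
    const double lo = buf[m / 2 - 1];
    const double hi = *std::min_element(buf.begin() + m / 2, buf.end());
    return (lo + hi) / 2.0;
}

// Permutation null of the max-statistic: B random reassignments of the pooled
// values to groups of the given sizes; returns max over all group pairs of
// |median_i - median_j| for each permutation. Uses R's RNG stream, so results
// are reproducible via set.seed() on the R side.
// [[Rcpp::export]]
NumericVector perm_max_median_diff(NumericVector pooled, IntegerVector sizes,
                                   int B) {
    const int n = pooled.size();
    const int k = sizes.size();
    std::vector<int> offs(k + 1, 0);
    for (int g = 0; g < k; ++g) {
        if (sizes[g] < 1) stop("all group sizes must be >= 1");
        offs[g + 1] = offs[g] + sizes[g];
    }
    if (offs[k] != n) stop("group sizes must sum to length(pooled)");
    if (B < 1) stop("B must be >= 1");

    std::vector<double> work(pooled.begin(), pooled.end());
    std::vector<double> med(k), buf;
    NumericVector D(B);
    RNGScope scope;
    for (int b = 0; b < B; ++b) {
        if ((b & 255) == 0) Rcpp::checkUserInterrupt();
        for (int i = n - 1; i > 0; --i) {  // Fisher-Yates
            int j = static_cast<int>(R_unif_index(i + 1));
            std::swap(work[i], work[j]);
        }
        for (int g = 0; g < k; ++g) {
            buf.assign(work.begin() + offs[g], work.begin() + offs[g + 1]);
            med[g] = buf_median(buf);
        }
        double mx = 0.0;
        for (int g = 0; g < k; ++g)
            for (int h = g + 1; h < k; ++h)
                mx = std::max(mx, std::fabs(med[g] - med[h]));
        D[b] = mx;
    }
    return D;
}
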