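#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Degree-preserving double-edge swaps on one bipartite layer.
//
// `a` and `b` are parallel vectors of endpoint ids (side A / side B of the
// layer). A swap picks two edges (a_i, b_i), (a_j, b_j) and proposes
// (a_i, b_j), (a_j, b_i); it is rejected when it would collapse endpoints or
// create a parallel edge, so per-node degree on each side — and therefore the
// full degree sequence and node typing — is invariant. Uses R's RNG stream so
// set.seed() makes replicates reproducible.
// [[Rcpp::export(name = ".rewire_layer_cpp")]]
IntegerMatrix rewire_layer_cpp(IntegerVector a, IntegerVector b, int attempts) {
    int m = a.size();
    IntegerVector ra = clone(a), rb = clone(b);
    if (m < 2 || attempts <= 0) {
        IntegerMatrix out(m, 2);
        for (int i = 0; i < m; ++i) { out(i, 0) = ra[i]; out(i, 1) = rb[i]; }
        return out;
    }
    long long span = 0;
    for (int i = 0; i < m; ++i) {
        if (ra[i] > span) span = ra[i];
        if (rb[i] > span) span = rb[i];
    }
    span += 1;
    std::unordered_set<long long> present;
    present.reserve(m * 2);
    for (int i = 0; i < m; ++i) present.insert((long long)ra[i] * span + rb[i]);

    for (int t = 0; t < attempts; ++t) {
        int i = (int)(unif_rand() * m);
        int j = (int)(unif_rand() * m);
        if (i >= m) i = m - 1;
        if (j >= m) j = m - 1;
        if (i == j) continue;
        int ai = ra[i], bi = rb[i], aj = ra[j], bj = rb[j];
        if (ai == aj || bi == bj) continue;
        long long k1 = (long long)ai * span + bj;
        long long k2 = (long long)aj * span + bi;
        if (present.count(k1) || present.count(k2)) continue;
        present.erase((long long)ai * span + bi);
        present.erase((long long)aj * span + bj);
        present.insert(k1);
        present.insert(k2);
        rb[i] = bj;
        rb[j] = bi;
    }
    IntegerMatrix out(m, 2);
    for (int i = 0; i < m; ++i) { out(i, 0) = ra[i]; out(i, 1) = rb[i]; }
    return out;
}
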