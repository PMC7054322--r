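// LINE-style graph embedding: alias sampling + negative-sampling SGD.
// Self-contained RNG (splitmix64 -> xorshift128+) so training is
// bit-reproducible for a given seed, independent of R's RNG state.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Rng {
    uint64_t s0, s1;
    explicit Rng(uint64_t seed) {
        // splitmix64 to spread a small seed over the state
        auto sm = [&seed]() {
            uint64_t z = (seed += 0x9E3779B97F4A7C15ULL);
            z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
            z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
            return z ^ (z >> 31);
        };
        s0 = sm(); s1 = sm();
        if (s0 == 0 && s1 == 0) s1 = 1;
    }
    uint64_t next() {
        uint64_t x = s0, y = s1;
        s0 = y;
        x ^= x << 23;
        s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
        return s1 + y;
    }
    double unif() {  // in [0, 1)
        return (next() >> 11) * (1.0 / 9007199254740992.0);
    }
    int below(int n) { return (int)(unif() * n); }
};

// Vose alias table for O(1) weighted draws
struct Alias {
    std::vector<double> prob;
    std::vector<int> alias;
    void build(const std::vector<double>& w) {
        int n = w.size();
        prob.assign(n, 0.0); alias.assign(n, 0);
        double tot = 0.0;
        for (double x : w) tot += x;
        std::vector<double> p(n);
        for (int i = 0; i < n; ++i) p[i] = w[i] * n / tot;
        std::vector<int> small, large;
        small.reserve(n); large.reserve(n);
        for (int i = 0; i < n; ++i)
            (p[i] < 1.0 ? small : large).push_back(i);
        while (!small.empty() && !large.empty()) {
            int s = small.back(); small.pop_back();
            int l = large.back(); large.pop_back();
            prob[s] = p[s]; alias[s] = l;
            p[l] = (p[l] + p[s]) - 1.0;
            (p[l] < 1.0 ? small : large).push_back(l);
        }
        while (!large.empty()) { prob[large.back()] = 1.0; large.pop_back(); }
        while (!small.empty()) { prob[small.back()] = 1.0; small.pop_back(); }
    }
    int draw(Rng& rng) const {
        int i = rng.below(prob.size());
        return rng.unif() < prob[i] ? i : alias[i];
    }
};

inline double sigmoid(double x) {
    if (x > 35.0) return 1.0;
    if (x < -35.0) return 0.0;
    return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// [[Rcpp::export]]
List cpp_build_alias(NumericVector w) {
    Alias a;
    a.build(std::vector<double>(w.begin(), w.end()));
    return List::create(_["prob"] = NumericVector(a.prob.begin(), a.prob.end()),
                        _["alias"] = IntegerVector(a.alias.begin(), a.alias.end()));
}

// [[Rcpp::export]]
IntegerVector cpp_alias_draw(NumericVector prob, IntegerVector alias,
                             int n, double seed) {
    Alias a;
    a.prob.assign(prob.begin(), prob.end());
    a.alias.assign(alias.begin(), alias.end());
    Rng rng((uint64_t)seed);
    IntegerVector out(n);
    for (int t = 0; t < n; ++t) out[t] = a.draw(rng) + 1;  // 1-based
    return out;
}

// One SGD pass of LINE training over `nsamples` edge draws.
// ei/ej: 0-based endpoints of undirected edges, w: weights, nv: node count.
// order: 1 = first-order only, 2 = second-order only, 3 = joint (per draw,
// second-order with probability alpha else first-order).
// Returns vertex matrix V, context matrix C (0x0 unless order involves 2),
// the initial matrices, and counters of update types.
// [[Rcpp::export]]
List cpp_line_train(IntegerVector ei, IntegerVector ej, NumericVector w,
                    int nv, int dim, int order, double alpha,
                    double nsamples, int negative, double rho0,
                    double seed) {
    const int ne = ei.size();
    if (ne < 1) stop("empty edge list");
    Rng rng((uint64_t)seed);

    Alias edgeAlias;
    edgeAlias.build(std::vector<double>(w.begin(), w.end()));

    // noise distribution for negatives: degree^0.75
    std::vector<double> deg(nv, 0.0);
    for (int e = 0; e < ne; ++e) {
        deg[ei[e]] += w[e];
        deg[ej[e]] += w[e];
    }
    std::vector<double> noise(nv);
    for (int v = 0; v < nv; ++v) noise[v] = std::pow(deg[v], 0.75);
    Alias nodeAlias;
    nodeAlias.build(noise);

    const bool hasCtx = (order != 1);
    std::vector<double> V((size_t)nv * dim), C;
    for (auto& x : V) x = (rng.unif() - 0.5) / dim;
    if (hasCtx) C.assign((size_t)nv * dim, 0.0);  // contexts start at zero
    std::vector<double> V0 = V, C0 = C;

    const long long T = (long long)nsamples;
    std::vector<double> err(dim);
    long long nFirst = 0, nSecond = 0;

    for (long long t = 0; t < T; ++t) {
        double rho = rho0 * (1.0 - 0.99 * (double)t / (double)T);
        int e = edgeAlias.draw(rng);
        int i = ei[e], j = ej[e];
        if (rng.unif() < 0.5) std::swap(i, j);  // random orientation

        bool second = (order == 2) || (order == 3 && rng.unif() < alpha);
        double* vi = &V[(size_t)i * dim];
        std::fill(err.begin(), err.end(), 0.0);

        if (!second) {
            ++nFirst;
            // positive target j plus `negative` noise nodes, all on V
            for (int d = 0; d <= negative; ++d) {
                int target; double label;
                if (d == 0) { target = j; label = 1.0; }
                else {
                    target = nodeAlias.draw(rng);
                    if (target == i || target == j) continue;
                    label = 0.0;
                }
                double* vt = &V[(size_t)target * dim];
                double dot = 0.0;
                for (int c = 0; c < dim; ++c) dot += vi[c] * vt[c];
                double g = (label - sigmoid(dot)) * rho;
                for (int c = 0; c < dim; ++c) {
                    err[c] += g * vt[c];
                    vt[c] += g * vi[c];
                }
            }
        } else {
            ++nSecond;
            // positive context j plus noise contexts, all on C
            for (int d = 0; d <= negative; ++d) {
                int target; double label;
                if (d == 0) { target = j; label = 1.0; }
                else {
                    target = nodeAlias.draw(rng);
                    if (target == i || target == j) continue;
                    label = 0.0;
                }
                double* ct = &C[(size_t)target * dim];
                double dot = 0.0;
                for (int c = 0; c < dim; ++c) dot += vi[c] * ct[c];
                double g = (label - sigmoid(dot)) * rho;
                for (int c = 0; c < dim; ++c) {
                    err[c] += g * ct[c];
                    ct[c] += g * vi[c];
                }
            }
        }
        for (int c = 0; c < dim; ++c) vi[c] += err[c];
    }

    auto toMat = [&](const std::vector<double>& src) {
        if (src.empty()) return NumericMatrix(0, dim);
        NumericMatrix m(nv, dim);
        for (int v = 0; v < nv; ++v)
            for (int c = 0; c < dim; ++c)
                m(v, c) = src[(size_t)v * dim + c];
        return m;
    };
    return List::create(_["vertex"] = toMat(V), _["context"] = toMat(C),
                        _["vertex0"] = toMat(V0), _["context0"] = toMat(C0),
                        _["nFirst"] = (double)nFirst,
                        _["nSecond"] = (double)nSecond);
}
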