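#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// Global efficiency of the surviving subgraph via level-synchronous
// BFS over bitset rows: frontiers expand word-parallel, and each BFS
// level k contributes popcount(frontier)/k to the inverse-distance
// sum. Disconnected pairs contribute 0; N <= 1 returns 0.
static double ge_bits(const std::vector<uint64_t> &adj,
                      const std::vector<uint64_t> &alive,
                      int n, int W, int n_alive,
                      std::vector<uint64_t> &visited,
                      std::vector<uint64_t> &frontier,
                      std::vector<uint64_t> &next) {
    if (n_alive <= 1) return 0.0;
    double total = 0.0;
    for (int s = 0; s < n; ++s) {
        if (!(alive[s >> 6] & (1ULL << (s & 63)))) continue;
        std::fill(visited.begin(), visited.end(), 0ULL);
        std::fill(frontier.begin(), frontier.end(), 0ULL);
        visited[s >> 6] |= 1ULL << (s & 63);
        frontier[s >> 6] |= 1ULL << (s & 63);
        int level = 0;
        for (;;) {
            std::fill(next.begin(), next.end(), 0ULL);
            for (int w = 0; w < W; ++w) {
                uint64_t bits = frontier[w];
                while (bits) {
                    int u = (w << 6) + __builtin_ctzll(bits);
                    bits &= bits - 1;
                    const uint64_t *row = &adj[(size_t)u * W];
                    for (int ww = 0; ww < W; ++ww) next[ww] |= row[ww];
                }
            }
            ++level;
            int cnt = 0;
            for (int ww = 0; ww < W; ++ww) {
                next[ww] &= alive[ww] & ~visited[ww];
                visited[ww] |= next[ww];
                cnt += __builtin_popcountll(next[ww]);
            }
            if (cnt == 0) break;
            total += (double)cnt / level;
            frontier.swap(next);
        }
    }
    return total / ((double)n_alive * (n_alive - 1));
}

// [[Rcpp::export(name = ".attack_curve_engine")]]
List attack_curve_engine(IntegerMatrix a, bool adaptive) {
    const int n = a.nrow();
    if (n == 0)
        return List::create(_["ge"] = NumericVector(0),
                            _["order"] = IntegerVector(0));
    const int W = (n + 63) / 64;
    std::vector<uint64_t> adj((size_t)n * W, 0ULL), alive(W, 0ULL);
    std::vector<int> deg(n, 0);
    for (int i = 0; i < n; ++i) {
        alive[i >> 6] |= 1ULL << (i & 63);
        for (int j = 0; j < n; ++j)
            if (i != j && a(i, j) != 0) {
                adj[(size_t)i * W + (j >> 6)] |= 1ULL << (j & 63);
                ++deg[i];
            }
    }

    // static mode ranks by initial degree once, ties by ascending index
    std::vector<int> static_order(n);
    for (int i = 0; i < n; ++i) static_order[i] = i;
    if (!adaptive)
        std::stable_sort(static_order.begin(), static_order.end(),
                         [&deg](int x, int y) { return deg[x] > deg[y]; });

    std::vector<uint64_t> visited(W), frontier(W), nxt(W);
    NumericVector ge(n);
    IntegerVector order(n - 1);
    int n_alive = n;

    ge[0] = ge_bits(adj, alive, n, W, n_alive, visited, frontier, nxt);
    for (int k = 1; k < n; ++k) {
        int victim = -1;
        if (adaptive) {
            int best = -1;
            for (int i = 0; i < n; ++i)
                if ((alive[i >> 6] & (1ULL << (i & 63))) && deg[i] > best) {
                    best = deg[i];
                    victim = i;
                }
        } else {
            for (int idx = 0; idx < n; ++idx) {
                int cand = static_order[idx];
                if (alive[cand >> 6] & (1ULL << (cand & 63))) {
                    victim = cand;
                    break;
                }
            }
        }
        alive[victim >> 6] &= ~(1ULL << (victim & 63));
        --n_alive;
        const uint64_t *row = &adj[(size_t)victim * W];
        for (int w = 0; w < W; ++w) {
            uint64_t bits = row[w] & alive[w];
            while (bits) {
                int u = (w << 6) + __builtin_ctzll(bits);
                bits &= bits - 1;
                --deg[u];
            }
        }
        order[k - 1] = victim + 1;
        ge[k] = ge_bits(adj, alive, n, W, n_alive, visited, frontier,
                        nxt);
    }
    return List::create(_["ge"] = ge, _["order"] = order);
}

// [[Rcpp::export(name = ".global_efficiency_engine")]]
double global_efficiency_engine(IntegerMatrix a) {
    const int n = a.nrow();
    if (n <= 1) return 0.0;
    const int W = (n + 63) / 64;
    std::vector<uint64_t> adj((size_t)n * W, 0ULL), alive(W, 0ULL);
    for (int i = 0; i < n; ++i) {
        alive[i >> 6] |= 1ULL << (i & 63);
        for (int j = 0; j < n; ++j)
            if (i != j && a(i, j) != 0)
                adj[(size_t)i * W + (j >> 6)] |= 1ULL << (j & 63);
    }
    std::vector<uint64_t> visited(W), frontier(W), nxt(W);
    return ge_bits(adj, alive, n, W, n, visited, frontier, nxt);
}
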