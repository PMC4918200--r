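#include <Rcpp.h>
using namespace Rcpp;

// pair weight lookup; 0 = not pairable
static inline int pair_w(char a, char b, int wGC, int wAU, int wGU) {
    if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return wGC;
    if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return wAU;
    if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return wGU;
    return 0;
}

// Weighted base-pair maximization (Nussinov-style interval DP) with a
// deterministic traceback: at each interval the 5'-most base is tried
// against partners k from the 3' end downward before being left
// unpaired, so co-optimal structures resolve identically every run.
// [[Rcpp::export(name = ".nussinov_cpp")]]
List nussinov_cpp(std::string seq, int wGC, int wAU, int wGU, int min_loop) {
    int n = seq.size();
    if (n == 0) return List::create(_["score"] = 0,
                                    _["i"] = IntegerVector(0),
                                    _["j"] = IntegerVector(0));
    std::vector<int> N((size_t)n * n, 0);
    auto at = [&](int i, int j) -> int& { return N[(size_t)i * n + j]; };
    for (int len = min_loop + 2; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            int j = i + len - 1;
            int best = at(i + 1, j); // i unpaired
            for (int k = i + min_loop + 1; k <= j; ++k) {
                int w = pair_w(seq[i], seq[k], wGC, wAU, wGU);
                if (!w) continue;
                int inner = (k - i > min_loop + 1) ? at(i + 1, k - 1) : 0;
                int outer = (k < j) ? at(k + 1, j) : 0;
                int cand = inner + w + outer;
                if (cand > best) best = cand;
            }
            at(i, j) = best;
        }
    }
    // traceback: i ascending, partner k tried from j descending
    std::vector<int> pi, pj;
    std::vector<std::pair<int, int>> stack;
    stack.push_back({0, n - 1});
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (i >= j || j - i <= min_loop) continue;
        bool paired = false;
        for (int k = j; k >= i + min_loop + 1; --k) {
            int w = pair_w(seq[i], seq[k], wGC, wAU, wGU);
            if (!w) continue;
            int inner = (k - i > min_loop + 1) ? at(i + 1, k - 1) : 0;
            int outer = (k < j) ? at(k + 1, j) : 0;
            if (inner + w + outer == at(i, j)) {
                pi.push_back(i); pj.push_back(k);
                if (k < j) stack.push_back({k + 1, j});
                stack.push_back({i + 1, k - 1});
                paired = true;
                break;
            }
        }
        if (!paired) stack.push_back({i + 1, j});
    }
    return List::create(_["score"] = at(0, n - 1),
                        _["i"] = wrap(pi), _["j"] = wrap(pj));
}
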