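#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// adjacency: list of 1-based integer vectors, one per feature
static std::vector<std::vector<int> > as_adj(const List& adjacency) {
    int n = adjacency.size();
    std::vector<std::vector<int> > adj(n);
    for (int i = 0; i < n; ++i) {
        IntegerVector v = adjacency[i];
        adj[i].reserve(v.size());
        for (int j = 0; j < v.size(); ++j) adj[i].push_back(v[j] - 1);
    }
    return adj;
}

// connected components of the supra-threshold set; 0 = below threshold
static int label_components_impl(const std::vector<std::vector<int> >& adj,
                                 const std::vector<char>& supra,
                                 std::vector<int>& labels) {
    int n = supra.size();
    std::fill(labels.begin(), labels.end(), 0);
    int next = 0;
    std::vector<int> stack;
    for (int i = 0; i < n; ++i) {
        if (!supra[i] || labels[i] != 0) continue;
        ++next;
        labels[i] = next;
        stack.push_back(i);
        while (!stack.empty()) {
            int f = stack.back();
            stack.pop_back();
            const std::vector<int>& nb = adj[f];
            for (size_t k = 0; k < nb.size(); ++k) {
                int g = nb[k];
                if (supra[g] && labels[g] == 0) {
                    labels[g] = next;
                    stack.push_back(g);
                }
            }
        }
    }
    return next;
}

// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(NumericVector map, double threshold,
                               List adjacency) {
    int n = map.size();
    std::vector<std::vector<int> > adj = as_adj(adjacency);
    std::vector<char> supra(n);
    for (int i = 0; i < n; ++i) supra[i] = map[i] >= threshold;
    std::vector<int> labels(n);
    label_components_impl(adj, supra, labels);
    return IntegerVector(labels.begin(), labels.end());
}

// TFCE for a non-negative map: sum over thresholds h = dh, 2dh, ... of
// e(f,h)^E * h^H * dh, with e(f,h) the extent of the supra-threshold
// component containing f
// [[Rcpp::export(name = ".tfce_nonneg")]]
NumericVector tfce_nonneg(NumericVector map, List adjacency,
                          double E, double H, double dh) {
    int n = map.size();
    NumericVector out(n);
    double mx = 0.0;
    for (int i = 0; i < n; ++i) {
        if (!R_finite(map[i]) || map[i] < 0)
            stop("tfce input must be finite and non-negative");
        if (map[i] > mx) mx = map[i];
    }
    if (mx == 0.0) return out;
    std::vector<std::vector<int> > adj = as_adj(adjacency);
    std::vector<char> supra(n);
    std::vector<int> labels(n);
    int nsteps = (int)std::floor(mx / dh + 1e-9);
    for (int step = 1; step <= nsteps; ++step) {
        double h = step * dh;
        for (int i = 0; i < n; ++i) supra[i] = map[i] >= h;
        int ncomp = label_components_impl(adj, supra, labels);
        if (ncomp == 0) continue;
        std::vector<int> sizes(ncomp + 1, 0);
        for (int i = 0; i < n; ++i) if (labels[i] > 0) ++sizes[labels[i]];
        double hH = std::pow(h, H) * dh;
        for (int i = 0; i < n; ++i) {
            if (labels[i] > 0)
                out[i] += std::pow((double)sizes[labels[i]], E) * hH;
        }
    }
    return out;
}
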