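// Max-flow/min-cut on a 4-neighbour pixel grid (Dinic's algorithm).
//
// Used by the differentiating-nuclei segmenter: one node per pixel plus a
// virtual source (dark/foreground) and sink (bright/background). Terminal
// capacities carry the unary data terms, grid edges the contrast-modulated
// smoothness terms. Returns the source-side (foreground) partition of the
// minimum cut.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

namespace {

struct Dinic {
    int n;
    std::vector<int> to, nxt, head, level, iter;
    std::vector<double> cap;

    explicit Dinic(int n_) : n(n_), head(n_, -1), level(n_), iter(n_) {}

    void addEdge(int u, int v, double c, double c_rev) {
        to.push_back(v); cap.push_back(c);     nxt.push_back(head[u]); head[u] = to.size() - 1;
        to.push_back(u); cap.push_back(c_rev); nxt.push_back(head[v]); head[v] = to.size() - 1;
    }

    bool bfs(int s, int t) {
        std::fill(level.begin(), level.end(), -1);
        std::queue<int> q;
        level[s] = 0; q.push(s);
        while (!q.empty()) {
            int u = q.front(); q.pop();
            for (int e = head[u]; e != -1; e = nxt[e]) {
                if (cap[e] > 1e-12 && level[to[e]] < 0) {
                    level[to[e]] = level[u] + 1;
                    q.push(to[e]);
                }
            }
        }
        return level[t] >= 0;
    }

    double dfs(int u, int t, double f) {
        if (u == t) return f;
        for (int &e = iter[u]; e != -1; e = nxt[e]) {
            int v = to[e];
            if (cap[e] > 1e-12 && level[v] == level[u] + 1) {
                double d = dfs(v, t, std::min(f, cap[e]));
                if (d > 0) {
                    cap[e] -= d;
                    cap[e ^ 1] += d;
                    return d;
                }
            }
        }
        return 0.0;
    }

    void run(int s, int t) {
        const double INF = std::numeric_limits<double>::max();
        while (bfs(s, t)) {
            for (int i = 0; i < n; ++i) iter[i] = head[i];
            while (dfs(s, t, INF) > 0) {}
        }
    }

    // nodes reachable from s in the residual graph = source side of the cut
    std::vector<char> sourceSide(int s) {
        std::vector<char> vis(n, 0);
        std::queue<int> q;
        vis[s] = 1; q.push(s);
        while (!q.empty()) {
            int u = q.front(); q.pop();
            for (int e = head[u]; e != -1; e = nxt[e]) {
                if (cap[e] > 1e-12 && !vis[to[e]]) {
                    vis[to[e]] = 1;
                    q.push(to[e]);
                }
            }
        }
        return vis;
    }
};

} // namespace

// [[Rcpp::export(name = ".gridMinCut")]]
LogicalMatrix gridMinCut(NumericMatrix capSrc, NumericMatrix capSnk,
                         NumericMatrix wRight, NumericMatrix wDown) {
    const int nr = capSrc.nrow(), nc = capSrc.ncol();
    if (capSnk.nrow() != nr || capSnk.ncol() != nc)
        stop("terminal capacity matrices must have identical dimensions");
    if (wRight.nrow() != nr || wRight.ncol() != nc - 1)
        stop("wRight must be nr x (nc-1)");
    if (wDown.nrow() != nr - 1 || wDown.ncol() != nc)
        stop("wDown must be (nr-1) x nc");

    const int N = nr * nc, S = N, T = N + 1;
    Dinic g(N + 2);
    g.to.reserve(4 * N + 4 * N);

    for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
            const int p = c * nr + r;
            if (capSrc(r, c) > 0) g.addEdge(S, p, capSrc(r, c), 0.0);
            if (capSnk(r, c) > 0) g.addEdge(p, T, capSnk(r, c), 0.0);
            if (c + 1 < nc && wRight(r, c) > 0)
                g.addEdge(p, (c + 1) * nr + r, wRight(r, c), wRight(r, c));
            if (r + 1 < nr && wDown(r, c) > 0)
                g.addEdge(p, c * nr + r + 1, wDown(r, c), wDown(r, c));
        }
    }
    g.run(S, T);
    std::vector<char> side = g.sourceSide(S);

    LogicalMatrix fg(nr, nc);
    for (int c = 0; c < nc; ++c)
        for (int r = 0; r < nr; ++r)
            fg(r, c) = side[c * nr + r] != 0;
    return fg;
}

// [[Rcpp::export(name = ".labelConnected8")]]
IntegerMatrix labelConnected8(LogicalMatrix mask) {
    const int nr = mask.nrow(), nc = mask.ncol();
    IntegerMatrix lab(nr, nc);
    int next = 0;
    std::vector<int> stack;
    static const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
    static const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
    for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
            if (!mask(r, c) || lab(r, c)) continue;
            ++next;
            lab(r, c) = next;
            stack.push_back(c * nr + r);
            while (!stack.empty()) {
                int p = stack.back(); stack.pop_back();
                int pr = p % nr, pc = p / nr;
                for (int k = 0; k < 8; ++k) {
                    int qr = pr + dr[k], qc = pc + dc[k];
                    if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
                    if (mask(qr, qc) && !lab(qr, qc)) {
                        lab(qr, qc) = next;
                        stack.push_back(qc * nr + qr);
                    }
                }
            }
        }
    }
    return lab;
}
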