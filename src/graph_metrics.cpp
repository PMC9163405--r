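#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// BFS distances from src over a binary adjacency matrix (n small).
static void bfs_dist(const umat& adj, int n, int src, ivec& dist) {
  dist.fill(-1);
  dist(src) = 0;
  std::vector<int> q;
  q.reserve(n);
  q.push_back(src);
  for (size_t h = 0; h < q.size(); ++h) {
    int v = q[h];
    for (int w = 0; w < n; ++w) {
      if (adj(v, w) && dist(w) < 0) {
        dist(w) = dist(v) + 1;
        q.push_back(w);
      }
    }
  }
}

// Global efficiency of an adjacency matrix: mean over ordered pairs of
// 1/d(i,j), with 0 for disconnected pairs.
static double glob_eff(const umat& adj, int n) {
  if (n < 2) return 0.0;
  ivec dist(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    bfs_dist(adj, n, i, dist);
    for (int j = 0; j < n; ++j)
      if (j != i && dist(j) > 0) acc += 1.0 / dist(j);
  }
  return acc / ((double) n * (n - 1));
}

struct Metrics { double eglob, eloc, cp, lp; int disc_pairs; };

static Metrics compute_metrics(const umat& adj, int n) {
  Metrics m{0, 0, 0, 0, 0};
  ivec dist(n);
  double sumd = 0.0;
  int npairs = 0, ndisc = 0;
  double acc_inv = 0.0;
  for (int i = 0; i < n; ++i) {
    bfs_dist(adj, n, i, dist);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (dist(j) > 0) {
        acc_inv += 1.0 / dist(j);
        sumd += dist(j);
        ++npairs;
      } else {
        ++ndisc;
      }
    }
  }
  m.eglob = (n >= 2) ? acc_inv / ((double) n * (n - 1)) : 0.0;
  m.lp = (npairs > 0) ? sumd / npairs : 0.0;
  m.disc_pairs = ndisc / 2;

  // clustering coefficient and local efficiency
  double cp_acc = 0.0, el_acc = 0.0;
  for (int i = 0; i < n; ++i) {
    uvec nb = find(adj.col(i));
    int k = nb.n_elem;
    if (k < 2) continue;
    // triangles among neighbors
    int t = 0;
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        if (adj(nb(a), nb(b))) ++t;
    cp_acc += 2.0 * t / ((double) k * (k - 1));
    // neighborhood subgraph efficiency
    umat sub(k, k);
    for (int a = 0; a < k; ++a)
      for (int b = 0; b < k; ++b)
        sub(a, b) = adj(nb(a), nb(b));
    el_acc += glob_eff(sub, k);
  }
  m.cp = cp_acc / n;
  m.eloc = el_acc / n;
  return m;
}

// [[Rcpp::export]]
Rcpp::List graph_metrics_cpp(const arma::umat& adj) {
  int n = adj.n_rows;
  Metrics m = compute_metrics(adj, n);
  return Rcpp::List::create(
      Rcpp::Named("E_glob") = m.eglob, Rcpp::Named("E_loc") = m.eloc,
      Rcpp::Named("C_p") = m.cp, Rcpp::Named("L_p") = m.lp,
      Rcpp::Named("n_disconnected_pairs") = m.disc_pairs);
}

// Binarize a symmetric edge-value vector (upper triangle, row-major) at
// sparsity S: keep the nearbyint(S*E) largest strictly positive edges,
// ties broken by lower edge index. Returns the adjacency matrix.
static umat binarize_edges(const vec& ev, int n, double S) {
  const int E = ev.n_elem;
  int m = (int) std::nearbyint(S * E);  // round-half-even
  // stable sort by value descending (stable => lower index wins ties)
  uvec ord = stable_sort_index(ev, "descend");
  umat adj(n, n, fill::zeros);
  int kept = 0;
  for (int r = 0; r < E && kept < m; ++r) {
    int e = ord(r);
    if (ev(e) <= 0) break;  // only positive edges
    // edge index -> (i, j), upper triangle row-major
    int i = 0, off = e;
    while (off >= n - 1 - i) { off -= n - 1 - i; ++i; }
    int j = i + 1 + off;
    adj(i, j) = 1;
    adj(j, i) = 1;
    ++kept;
  }
  return adj;
}

// [[Rcpp::export]]
arma::umat binarize_edges_cpp(const arma::vec& ev, int n, double S) {
  return binarize_edges(ev, n, S);
}

// For a stack of windowed edge vectors (windows x E), binarize each window
// at every sparsity in `grid`, compute E_glob, E_loc, C_p, L_p, and return
// the trapezoidal AUC over the grid: a windows x 4 matrix.
// [[Rcpp::export]]
arma::mat windowed_metric_auc_cpp(const arma::mat& stack, int n,
                                  const arma::vec& grid) {
  const int W = stack.n_rows, G = grid.n_elem;
  mat out(W, 4, fill::zeros);
  mat vals(G, 4);
  for (int w = 0; w < W; ++w) {
    vec ev = stack.row(w).t();
    for (int g = 0; g < G; ++g) {
      umat adj = binarize_edges(ev, n, grid(g));
      Metrics m = compute_metrics(adj, n);
      vals(g, 0) = m.eglob; vals(g, 1) = m.eloc;
      vals(g, 2) = m.cp;    vals(g, 3) = m.lp;
    }
    for (int c = 0; c < 4; ++c) {
      double auc = 0.0;
      for (int g = 0; g + 1 < G; ++g)
        auc += 0.5 * (vals(g, c) + vals(g + 1, c)) * (grid(g + 1) - grid(g));
      out(w, c) = auc;
    }
  }
  return out;
}
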