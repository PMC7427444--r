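// Core ERGM machinery: sufficient statistics, per-dyad change statistics,
// and the Metropolis edge-toggle sampler.  All functions take a "layout"
// list built by stat_layout() on the R side, which maps model terms to
// columns of the statistic vector:
//   labels    : integer node labels (0-based) or empty when no mixing terms
//   mix_col   : L x L integer matrix, 0-based statistic column per unordered
//               label cell, -1 for the dropped reference cell
//   cov       : n x p numeric covariate matrix (0 columns when unused)
//   cov_col   : length-p statistic columns for the nodal covariates
//   match_id  : integer cluster ids (empty when no nodematch term)
//   match_col : statistic column for nodematch, -1 when absent
//   decay     : GWESP decay lambda, negative when no GWESP term
//   gwesp_col : statistic column for GWESP, -1 when absent
//   n_terms   : total statistic length
#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Layout {
  bool has_mix = false;
  std::vector<int> labels;
  IntegerMatrix mix_col;
  NumericMatrix cov;
  std::vector<int> cov_col;
  bool has_match = false;
  std::vector<int> match_id;
  int match_col = -1;
  bool has_gwesp = false;
  double decay = -1.0;
  int gwesp_col = -1;
  int n_terms = 0;
};

Layout parse_layout(const List& l) {
  Layout L;
  IntegerVector labels = l["labels"];
  if (labels.size() > 0) {
    L.has_mix = true;
    L.labels.assign(labels.begin(), labels.end());
    L.mix_col = as<IntegerMatrix>(l["mix_col"]);
  }
  L.cov = as<NumericMatrix>(l["cov"]);
  IntegerVector cc = l["cov_col"];
  L.cov_col.assign(cc.begin(), cc.end());
  IntegerVector mid = l["match_id"];
  if (mid.size() > 0) {
    L.has_match = true;
    L.match_id.assign(mid.begin(), mid.end());
    L.match_col = as<int>(l["match_col"]);
  }
  double decay = as<double>(l["decay"]);
  if (decay >= 0.0) {
    L.has_gwesp = true;
    L.decay = decay;
    L.gwesp_col = as<int>(l["gwesp_col"]);
  }
  L.n_terms = as<int>(l["n_terms"]);
  return L;
}

// dense 0/1 adjacency held flat, row-major
struct Graph {
  int n;
  std::vector<uint8_t> a;
  Graph(int n_) : n(n_), a((size_t)n_ * n_, 0) {}
  inline uint8_t at(int i, int j) const { return a[(size_t)i * n + j]; }
  inline void set(int i, int j, uint8_t v) {
    a[(size_t)i * n + j] = v;
    a[(size_t)j * n + i] = v;
  }
};

Graph graph_from_matrix(const IntegerMatrix& adj) {
  int n = adj.nrow();
  Graph g(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) g.a[(size_t)i * n + j] = adj(i, j) ? 1 : 0;
  return g;
}

inline int common_neighbours(const Graph& g, int i, int j) {
  const uint8_t* ri = &g.a[(size_t)i * g.n];
  const uint8_t* rj = &g.a[(size_t)j * g.n];
  int c = 0;
  for (int m = 0; m < g.n; ++m) c += ri[m] & rj[m];
  return c;
}

// Change statistic for adding edge (i,j) to the graph with that edge
// ABSENT; edge state in g may be either (corrected internally).
void add_delta(const Graph& g, int i, int j, const Layout& L, double* out) {
  for (int t = 0; t < L.n_terms; ++t) out[t] = 0.0;
  out[0] = 1.0;  // edges
  if (L.has_mix) {
    int col = L.mix_col(L.labels[i], L.labels[j]);
    if (col >= 0) out[col] += 1.0;
  }
  for (size_t p = 0; p < L.cov_col.size(); ++p)
    out[L.cov_col[p]] += L.cov(i, p) + L.cov(j, p);
  if (L.has_match && L.match_id[i] == L.match_id[j]) out[L.match_col] += 1.0;
  if (L.has_gwesp) {
    const double u = 1.0 - std::exp(-L.decay);
    const double el = std::exp(L.decay);
    const int eij = g.at(i, j);  // subtract if present: esp excludes edge ij
    double d = 0.0;
    int c = 0;
    for (int k = 0; k < g.n; ++k) {
      if (!(g.at(i, k) && g.at(j, k))) continue;
      ++c;
      // edges (i,k) and (j,k) each gain one shared partner
      int eik = common_neighbours(g, i, k) - eij;
      int ejk = common_neighbours(g, j, k) - eij;
      d += std::pow(u, (double)eik) + std::pow(u, (double)ejk);
    }
    d += el * (1.0 - std::pow(u, (double)c));
    out[L.gwesp_col] += d;
  }
}

void full_stats(const Graph& g, const Layout& L, double* out) {
  const int n = g.n;
  for (int t = 0; t < L.n_terms; ++t) out[t] = 0.0;
  const double u = L.has_gwesp ? 1.0 - std::exp(-L.decay) : 0.0;
  const double el = L.has_gwesp ? std::exp(L.decay) : 0.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (!g.at(i, j)) continue;
      out[0] += 1.0;
      if (L.has_mix) {
        int col = L.mix_col(L.labels[i], L.labels[j]);
        if (col >= 0) out[col] += 1.0;
      }
      for (size_t p = 0; p < L.cov_col.size(); ++p)
        out[L.cov_col[p]] += L.cov(i, p) + L.cov(j, p);
      if (L.has_match && L.match_id[i] == L.match_id[j]) out[L.match_col] += 1.0;
      if (L.has_gwesp) {
        int c = common_neighbours(g, i, j);
        if (c > 0) out[L.gwesp_col] += el * (1.0 - std::pow(u, (double)c));
      }
    }
  }
}

void esp_hist(const Graph& g, std::vector<int>& hist) {
  std::fill(hist.begin(), hist.end(), 0);
  for (int i = 0; i < g.n - 1; ++i)
    for (int j = i + 1; j < g.n; ++j)
      if (g.at(i, j)) hist[common_neighbours(g, i, j)]++;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_change_stats(IntegerMatrix adj, int i, int j, List layout) {
  Layout L = parse_layout(layout);
  Graph g = graph_from_matrix(adj);
  NumericVector out(L.n_terms);
  add_delta(g, i, j, L, REAL(out));
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_full_stats(IntegerMatrix adj, List layout) {
  Layout L = parse_layout(layout);
  Graph g = graph_from_matrix(adj);
  NumericVector out(L.n_terms);
  full_stats(g, L, REAL(out));
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_esp_counts(IntegerMatrix adj) {
  Graph g = graph_from_matrix(adj);
  std::vector<int> hist(std::max(1, g.n - 1), 0);
  esp_hist(g, hist);
  return IntegerVector(hist.begin(), hist.end());
}

// Change-statistic design matrix over all dyads i<j (row order: (0,1),
// (0,2), ..., column-compatible with cpp_change_stats) plus the observed
// dyad states; the maximum pseudo-likelihood fit is a logistic regression
// of y on X.
// [[Rcpp::export]]
List cpp_mple_matrix(IntegerMatrix adj, List layout) {
  Layout L = parse_layout(layout);
  Graph g = graph_from_matrix(adj);
  const int n = g.n;
  const int nd = n * (n - 1) / 2;
  NumericMatrix X(nd, L.n_terms);
  IntegerVector y(nd);
  std::vector<double> row(L.n_terms);
  int r = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j, ++r) {
      add_delta(g, i, j, L, row.data());
      for (int t = 0; t < L.n_terms; ++t) X(r, t) = row[t];
      y[r] = g.at(i, j);
    }
  }
  return List::create(_["X"] = X, _["y"] = y);
}

// Metropolis-Hastings sampler over uniform dyad-toggle proposals.
// Records n_samples statistic vectors, one every `thin` proposals after
// `burnin` proposals.  Optional extras per retained sample: ESP histogram,
// graph code (dyad bitmask, requires n*(n-1)/2 <= 50), full adjacency.
// [[Rcpp::export]]
List cpp_sample(IntegerMatrix adj_init, List layout, NumericVector theta,
                double burnin, double thin, int n_samples, int seed,
                bool collect_esp, bool collect_codes, bool collect_graphs) {
  Layout L = parse_layout(layout);
  Graph g = graph_from_matrix(adj_init);
  const int n = g.n;
  const int nd = n * (n - 1) / 2;
  if (collect_codes && nd > 50) stop("graph codes need n(n-1)/2 <= 50 dyads");

  std::vector<int> di(nd), dj(nd);
  {
    int r = 0;
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j, ++r) { di[r] = i; dj[r] = j; }
  }

  std::vector<double> stats(L.n_terms), delta(L.n_terms);
  full_stats(g, L, stats.data());

  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_int_distribution<int> pick(0, nd - 1);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  NumericMatrix S(n_samples, L.n_terms);
  NumericMatrix E;
  if (collect_esp) E = NumericMatrix(n_samples, std::max(1, n - 1));
  NumericVector codes;
  if (collect_codes) codes = NumericVector(n_samples);
  List graphs(collect_graphs ? n_samples : 0);
  std::vector<int> hist(std::max(1, n - 1));

  double accepted = 0.0, total = 0.0, dens_sum = 0.0;
  const double max_edges = (double)nd;
  auto step = [&]() {
    int d = pick(rng);
    int i = di[d], j = dj[d];
    add_delta(g, i, j, L, delta.data());
    double lr = 0.0;
    for (int t = 0; t < L.n_terms; ++t) lr += theta[t] * delta[t];
    bool present = g.at(i, j);
    if (present) lr = -lr;
    ++total;
    if (lr >= 0.0 || unif(rng) < std::exp(lr)) {
      ++accepted;
      g.set(i, j, present ? 0 : 1);
      double sgn = present ? -1.0 : 1.0;
      for (int t = 0; t < L.n_terms; ++t) stats[t] += sgn * delta[t];
    }
  };

  for (double s = 0; s < burnin; ++s) step();
  for (int k = 0; k < n_samples; ++k) {
    for (double s = 0; s < thin; ++s) step();
    for (int t = 0; t < L.n_terms; ++t) S(k, t) = stats[t];
    dens_sum += stats[0] / max_edges;
    if (collect_esp) {
      esp_hist(g, hist);
      for (size_t b = 0; b < hist.size(); ++b) E(k, b) = hist[b];
    }
    if (collect_codes) {
      double code = 0.0, bit = 1.0;
      for (int d = 0; d < nd; ++d, bit *= 2.0)
        if (g.at(di[d], dj[d])) code += bit;
      codes[k] = code;
    }
    if (collect_graphs) {
      IntegerMatrix A(n, n);
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j) A(i, j) = g.at(i, j);
      graphs[k] = A;
    }
  }

  IntegerMatrix final_adj(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) final_adj(i, j) = g.at(i, j);

  return List::create(
      _["stats"] = S,
      _["esp"] = collect_esp ? (SEXP)E : (SEXP)R_NilValue,
      _["codes"] = collect_codes ? (SEXP)codes : (SEXP)R_NilValue,
      _["graphs"] = collect_graphs ? (SEXP)graphs : (SEXP)R_NilValue,
      _["final_adj"] = final_adj,
      _["accept_rate"] = total > 0 ? accepted / total : 0.0,
      _["mean_density"] = n_samples > 0 ? dens_sum / n_samples : 0.0);
}
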