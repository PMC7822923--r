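#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Discrete Bayesian-network machinery: BDeu family scores and a
// Metropolis-Hastings sampler over DAG structures with edge-level
// multiplicative priors (used to encode the DNA -> RNA direction carried
// by cis-eQTL anchors) and forced ("strong") prior edges.
//
// Data layout: D is nodes x samples, states coded 0..k-1 per node.

static double bdeu_family(const IntegerMatrix& D,
                          const IntegerVector& nstates,
                          int node,
                          const std::vector<int>& parents,
                          double ess) {
  const int n_samples = D.ncol();
  const int r = nstates[node];
  long q = 1;
  for (size_t p = 0; p < parents.size(); ++p) q *= nstates[parents[p]];
  std::vector<double> counts((size_t)q * r, 0.0);
  for (int s = 0; s < n_samples; ++s) {
    long j = 0, stride = 1;
    for (size_t p = 0; p < parents.size(); ++p) {
      j += (long)D(parents[p], s) * stride;
      stride *= nstates[parents[p]];
    }
    counts[(size_t)j * r + D(node, s)] += 1.0;
  }
  const double aj = ess / (double)q;
  const double ajk = ess / ((double)q * r);
  double score = 0.0;
  for (long j = 0; j < q; ++j) {
    double nj = 0.0;
    for (int k = 0; k < r; ++k) nj += counts[(size_t)j * r + k];
    if (nj == 0.0) continue;  // empty parent configuration contributes 0
    score += R::lgammafn(aj) - R::lgammafn(aj + nj);
    for (int k = 0; k < r; ++k) {
      double njk = counts[(size_t)j * r + k];
      if (njk > 0.0)
        score += R::lgammafn(ajk + njk) - R::lgammafn(ajk);
    }
  }
  return score;
}

// [[Rcpp::export(name = ".bdeu_family_score")]]
double bdeu_family_score(IntegerMatrix D, IntegerVector nstates,
                         int node, IntegerVector parents, double ess) {
  std::vector<int> par(parents.begin(), parents.end());
  return bdeu_family(D, nstates, node, par, ess);
}

// Is `to` reachable from `from` by directed edges? Iterative DFS over
// sparse child lists; `seen` is caller-provided scratch (reset here).
static bool has_path(const std::vector< std::vector<int> >& children,
                     int from, int to,
                     std::vector<char>& seen, std::vector<int>& stack) {
  if (from == to) return true;
  std::fill(seen.begin(), seen.end(), 0);
  stack.clear();
  stack.push_back(from);
  seen[from] = 1;
  while (!stack.empty()) {
    int u = stack.back();
    stack.pop_back();
    for (size_t t = 0; t < children[u].size(); ++t) {
      int v = children[u][t];
      if (!seen[v]) {
        if (v == to) return true;
        seen[v] = 1;
        stack.push_back(v);
      }
    }
  }
  return false;
}

static void erase_val(std::vector<int>& v, int x) {
  for (size_t t = 0; t < v.size(); ++t)
    if (v[t] == x) { v[t] = v.back(); v.pop_back(); return; }
}

// One MCMC chain over DAG structures.  A move type is drawn uniformly
// (add / delete / reverse); add draws a uniform ordered node pair, delete
// and reverse draw a uniform existing edge, and the Hastings ratio for the
// changing proposal neighborhoods is included.  strong(i,j) = 1 forces
// edge i->j: present in the seed, never deleted or reversed.
// forbidden(i,j) = 1 blocks i->j.  log_w(i,j) is the log of the
// multiplicative structure-prior weight on edge i->j.
// Returns the final sampled adjacency matrix (a DAG).
// [[Rcpp::export(name = ".bn_mcmc_chain")]]
IntegerMatrix bn_mcmc_chain(IntegerMatrix D, IntegerVector nstates,
                            NumericMatrix log_w, IntegerMatrix strong,
                            IntegerMatrix forbidden, int n_steps,
                            int max_parents, double ess) {
  const int n = D.nrow();
  const double N = (double)n * (n - 1);
  std::vector< std::vector<char> > adj(n, std::vector<char>(n, 0));
  std::vector< std::vector<int> > parents(n), children(n);
  std::vector<char> seen(n, 0);
  std::vector<int> stack;
  stack.reserve(n);
  std::vector< std::pair<int,int> > edges;  // current edge list

  // seed graph = strong-prior edges (acyclicity validated in R)
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (strong(i, j)) {
        adj[i][j] = 1; parents[j].push_back(i); children[i].push_back(j);
        edges.push_back(std::make_pair(i, j));
      }

  std::vector<double> fam(n);
  for (int v = 0; v < n; ++v) fam[v] = bdeu_family(D, nstates, v, parents[v], ess);

  RNGScope scope;
  for (int step = 0; step < n_steps; ++step) {
    double u_move = unif_rand();
    if (u_move < 1.0 / 3.0) {  // ----- add -----
      int i = (int)(unif_rand() * n);
      if (i >= n) i = n - 1;
      int j = (int)(unif_rand() * (n - 1));
      if (j >= n - 1) j = n - 2;
      if (j >= i) ++j;
      if (adj[i][j] || forbidden(i, j)) continue;
      if ((int)parents[j].size() >= max_parents) continue;
      if (has_path(children, j, i, seen, stack)) continue;
      std::vector<int> newpar = parents[j];
      newpar.push_back(i);
      double newfam = bdeu_family(D, nstates, j, newpar, ess);
      double delta = newfam - fam[j] + log_w(i, j);
      // q(delete e | G') / q(add e | G) = (1/m') / (1/N)
      double log_hastings = std::log(N / (double)(edges.size() + 1));
      if (std::log(unif_rand()) < delta + log_hastings) {
        adj[i][j] = 1; parents[j] = newpar; fam[j] = newfam;
        children[i].push_back(j);
        edges.push_back(std::make_pair(i, j));
      }
    } else if (edges.size() > 0) {
      int k = (int)(unif_rand() * edges.size());
      if (k >= (int)edges.size()) k = edges.size() - 1;
      int i = edges[k].first, j = edges[k].second;
      if (strong(i, j)) continue;
      if (u_move < 2.0 / 3.0) {  // ----- delete -----
        std::vector<int> newpar;
        for (size_t t = 0; t < parents[j].size(); ++t)
          if (parents[j][t] != i) newpar.push_back(parents[j][t]);
        double newfam = bdeu_family(D, nstates, j, newpar, ess);
        double delta = newfam - fam[j] - log_w(i, j);
        double log_hastings = std::log((double)edges.size() / N);
        if (std::log(unif_rand()) < delta + log_hastings) {
          adj[i][j] = 0; parents[j] = newpar; fam[j] = newfam;
          erase_val(children[i], j);
          edges[k] = edges.back(); edges.pop_back();
        }
      } else {  // ----- reverse i->j to j->i -----
        if (forbidden(j, i)) continue;
        if ((int)parents[i].size() >= max_parents) continue;
        erase_val(children[i], j);
        bool cyc = has_path(children, i, j, seen, stack);
        children[i].push_back(j);
        if (cyc) continue;
        std::vector<int> newpar_j;
        for (size_t t = 0; t < parents[j].size(); ++t)
          if (parents[j][t] != i) newpar_j.push_back(parents[j][t]);
        std::vector<int> newpar_i = parents[i];
        newpar_i.push_back(j);
        double newfam_j = bdeu_family(D, nstates, j, newpar_j, ess);
        double newfam_i = bdeu_family(D, nstates, i, newpar_i, ess);
        double delta = newfam_j + newfam_i - fam[j] - fam[i]
          - log_w(i, j) + log_w(j, i);
        if (std::log(unif_rand()) < delta) {  // m unchanged: ratio 1
          adj[i][j] = 0; adj[j][i] = 1;
          parents[j] = newpar_j; parents[i] = newpar_i;
          fam[j] = newfam_j; fam[i] = newfam_i;
          erase_val(children[i], j); children[j].push_back(i);
          edges[k] = std::make_pair(j, i);
        }
      }
    }
  }

  IntegerMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      out(i, j) = adj[i][j] ? 1 : 0;
  return out;
}
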