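#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Felsenstein pruning log-likelihood over site patterns with k discrete
// equal-probability rate categories.  The GTR generator is supplied through
// its spectral decomposition Q = U diag(lam) Uinv, so transition matrices
// P(t) = U diag(exp(lam * t)) Uinv are rebuilt cheaply per edge and
// category.  Tip partials already encode ambiguity codes (1 for every
// compatible state).
//
// nodes are numbered 1..nnode (tips first); 'order' lists internal nodes in
// postorder; 'child1'/'child2' give their children; 'len' is the length of
// the edge above each node (unused for the root).
// [[Rcpp::export]]
double cpp_pruning_loglik(int ntip, int nnode, int root,
                          IntegerVector order, IntegerVector child1,
                          IntegerVector child2, NumericVector len,
                          NumericMatrix tippart, NumericVector weights,
                          NumericVector pi, NumericMatrix U,
                          NumericMatrix Uinv, NumericVector lam,
                          NumericVector crates) {
  const int npat = tippart.ncol();
  const int k = crates.size();
  std::vector<double> partial((size_t)4 * npat * nnode);
  std::vector<double> sitelik(npat, 0.0);
  double P[16];

  for (int c = 0; c < k; ++c) {
    const double rate = crates[c];
    // seed tips
    for (int t = 0; t < ntip; ++t)
      for (int p = 0; p < npat; ++p)
        for (int s = 0; s < 4; ++s)
          partial[((size_t)t * npat + p) * 4 + s] = tippart(4 * t + s, p);

    for (int oi = 0; oi < order.size(); ++oi) {
      const int node = order[oi] - 1;
      const int kids[2] = { child1[oi] - 1, child2[oi] - 1 };
      double *pn = &partial[(size_t)node * npat * 4];
      for (int p = 0; p < npat; ++p)
        for (int s = 0; s < 4; ++s) pn[p * 4 + s] = 1.0;
      for (int ci = 0; ci < 2; ++ci) {
        const int ch = kids[ci];
        const double t = len[ch] * rate;
        double e[4];
        for (int s = 0; s < 4; ++s) e[s] = std::exp(lam[s] * t);
        for (int i = 0; i < 4; ++i)
          for (int j = 0; j < 4; ++j) {
            double acc = 0.0;
            for (int s = 0; s < 4; ++s) acc += U(i, s) * e[s] * Uinv(s, j);
            P[i * 4 + j] = acc;
          }
        const double *pc = &partial[(size_t)ch * npat * 4];
        for (int p = 0; p < npat; ++p) {
          const double *v = &pc[p * 4];
          for (int i = 0; i < 4; ++i) {
            double acc = 0.0;
            for (int j = 0; j < 4; ++j) acc += P[i * 4 + j] * v[j];
            pn[p * 4 + i] *= acc;
          }
        }
      }
    }
    const double *pr = &partial[(size_t)(root - 1) * npat * 4];
    for (int p = 0; p < npat; ++p) {
      double acc = 0.0;
      for (int s = 0; s < 4; ++s) acc += pi[s] * pr[p * 4 + s];
      sitelik[p] += acc / k;
    }
  }
  double ll = 0.0;
  for (int p = 0; p < npat; ++p) {
    if (sitelik[p] <= 0.0) return R_NegInf;
    ll += weights[p] * std::log(sitelik[p]);
  }
  return ll;
}

// Joint per-locus evaluation used by the MCMC sampler: embeds the gene tree
// in the species tree (species-MRCA and population per node), accumulates
// per-population coalescent waiting-time and survival terms for the MSC log
// density, converts coalescent times plus per-population rates into branch
// lengths via the segment decomposition, and (optionally) computes the
// pruning log-likelihood.  Node ages give a valid postorder directly
// (parents are strictly older), so no explicit traversal bookkeeping is
// needed.  Returns ok = false when the embedding is invalid (a coalescence
// below the floor of its population), in which case the move is rejected.
// [[Rcpp::export]]
List cpp_locus_eval(IntegerVector gpar, NumericVector gage,
                    IntegerVector gspecies,
                    IntegerVector spar, NumericVector stau,
                    NumericVector stheta, int sroot,
                    NumericVector rates, bool usedata,
                    NumericMatrix tippart, NumericVector weights,
                    NumericVector pi, NumericMatrix U, NumericMatrix Uinv,
                    NumericVector lam, NumericVector crates) {
  const int n = gspecies.size();
  const int gn = gpar.size();
  const int sn = spar.size();

  // internal gene nodes in ascending age = postorder
  std::vector<int> ints;
  for (int i = n; i < gn; ++i) ints.push_back(i);
  std::sort(ints.begin(), ints.end(),
            [&](int a, int b) { return gage[a] < gage[b]; });

  // children of gene nodes
  std::vector<int> gc1(gn, -1), gc2(gn, -1);
  int groot = -1;
  for (int i = 0; i < gn; ++i) {
    int p = gpar[i] - 1;
    if (p < 0) { groot = i; continue; }
    if (gc1[p] < 0) gc1[p] = i; else gc2[p] = i;
  }

  // species-tree MRCA per gene node (walk-up marking)
  std::vector<int> spm(gn), mark(sn, -1);
  for (int i = 0; i < n; ++i) spm[i] = gspecies[i] - 1;
  for (int oi = 0; oi < (int)ints.size(); ++oi) {
    int id = ints[oi];
    int a = spm[gc1[id]], b = spm[gc2[id]];
    int x = a;
    while (x >= 0) { mark[x] = id; x = spar[x] - 1; }
    x = b;
    while (x >= 0 && mark[x] != id) x = spar[x] - 1;
    spm[id] = (x >= 0) ? x : (sroot - 1);
  }

  // population per gene node
  std::vector<int> pop(gn);
  bool ok = true;
  for (int i = 0; i < gn; ++i) {
    double t = gage[i];
    int p = spm[i];
    if (t < stau[p]) { ok = false; break; }
    while (spar[p] - 1 >= 0 && stau[spar[p] - 1] <= t) p = spar[p] - 1;
    pop[i] = p;
  }
  if (!ok)
    return List::create(_["ok"] = false, _["lnMSC"] = R_NegInf,
                        _["lnL"] = R_NegInf, _["TL"] = NA_REAL,
                        _["lengths"] = NumericVector(0));

  // branch lengths via segments
  NumericVector len(gn);
  double TL = 0.0;
  for (int i = 0; i < gn; ++i) {
    int pa = gpar[i] - 1;
    if (pa < 0) continue;
    double t1 = gage[pa], enter = gage[i], l = 0.0;
    int p = pop[i];
    while (spar[p] - 1 >= 0 && stau[spar[p] - 1] < t1) {
      l += (stau[spar[p] - 1] - enter) * rates[p];
      enter = stau[spar[p] - 1];
      p = spar[p] - 1;
    }
    l += (t1 - enter) * rates[p];
    len[i] = l;
    TL += l;
  }

  // MSC log density: per-population event lists
  std::vector<int> ncoal(sn, 0), n_in(sn, 0);
  for (int oi = 0; oi < (int)ints.size(); ++oi) ncoal[pop[ints[oi]]]++;
  for (int i = 0; i < n; ++i) n_in[gspecies[i] - 1]++;
  // species-tree nodes ascending by tau (tips first: tau 0)
  std::vector<int> sord(sn);
  for (int i = 0; i < sn; ++i) sord[i] = i;
  std::sort(sord.begin(), sord.end(),
            [&](int a, int b) { return stau[a] < stau[b]; });
  // accumulate n_in for internal populations (children are earlier in sord)
  for (int oi = 0; oi < sn; ++oi) {
    int j = sord[oi];
    if (spar[j] - 1 >= 0) n_in[spar[j] - 1] += n_in[j] - ncoal[j];
  }
  double lnMSC = 0.0;
  for (int j = 0; j < sn; ++j) {
    int m = n_in[j];
    if (m < 2 && ncoal[j] == 0) continue;
    double theta = stheta[j];
    double upper = (spar[j] - 1 >= 0) ? stau[spar[j] - 1] : R_PosInf;
    // events in this population, ascending (ints is age-sorted)
    double t = stau[j];
    for (int oi = 0; oi < (int)ints.size(); ++oi) {
      int id = ints[oi];
      if (pop[id] != j) continue;
      lnMSC += std::log(2.0 / theta) -
               (m * (m - 1.0) / theta) * (gage[id] - t);
      t = gage[id];
      m--;
    }
    if (R_FINITE(upper)) lnMSC -= (m * (m - 1.0) / theta) * (upper - t);
    else if (m != 1) { lnMSC = R_NegInf; break; }
  }

  double lnL = 0.0;
  if (usedata && R_FINITE(lnMSC)) {
    IntegerVector order(ints.size()), ch1(ints.size()), ch2(ints.size());
    for (int i = 0; i < (int)ints.size(); ++i) {
      order[i] = ints[i] + 1;
      ch1[i] = gc1[ints[i]] + 1;
      ch2[i] = gc2[ints[i]] + 1;
    }
    lnL = cpp_pruning_loglik(n, gn, groot + 1, order, ch1, ch2, len,
                             tippart, weights, pi, U, Uinv, lam, crates);
  }
  return List::create(_["ok"] = true, _["lnMSC"] = lnMSC, _["lnL"] = lnL,
                      _["TL"] = TL, _["lengths"] = len,
                      _["pop"] = IntegerVector(pop.begin(), pop.end()) + 1,
                      _["spm"] = IntegerVector(spm.begin(), spm.end()) + 1);
}
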