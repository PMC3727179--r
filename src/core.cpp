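// Hot core of the subnetwork search: plug-in mutual information on binned
// activity, greedy seed expansion, and the three permutation nulls.
// All randomness goes through R's RNG so set.seed() governs every draw.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

typedef std::vector<std::vector<int> > AdjList;

static AdjList as_adj(const List& adj) {
  AdjList a(adj.size());
  for (R_xlen_t i = 0; i < adj.size(); ++i) {
    IntegerVector v = adj[i];
    a[i].assign(v.begin(), v.end());
  }
  return a;
}

// uniform integer in [0, n)
static int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

static void fisher_yates(std::vector<int>& x) {
  for (int i = (int)x.size() - 1; i > 0; --i) {
    int j = runif_int(i + 1);
    std::swap(x[i], x[j]);
  }
}

// Plug-in MI (bits) between equal-width-binned activity and a binary class.
// Constant activity carries no information and scores 0 by convention.
static double mi_bits(const double* act, const int* cls, int n, int nbins) {
  double lo = act[0], hi = act[0];
  for (int i = 1; i < n; ++i) {
    if (act[i] < lo) lo = act[i];
    if (act[i] > hi) hi = act[i];
  }
  if (!(hi > lo)) return 0.0;
  std::vector<int> joint(2 * nbins, 0);
  int rowc[2] = {0, 0};
  double w = hi - lo;
  for (int i = 0; i < n; ++i) {
    int b = (int)((act[i] - lo) / w * nbins);
    if (b >= nbins) b = nbins - 1;
    if (b < 0) b = 0;
    joint[2 * b + cls[i]]++;
    rowc[cls[i]]++;
  }
  double mi = 0.0, dn = (double)n;
  for (int b = 0; b < nbins; ++b) {
    int nb = joint[2 * b] + joint[2 * b + 1];
    if (nb == 0) continue;
    for (int c = 0; c < 2; ++c) {
      int nbc = joint[2 * b + c];
      if (nbc == 0) continue;
      double pbc = nbc / dn;
      mi += pbc * std::log2(pbc * dn * dn / ((double)nb * (double)rowc[c]));
    }
  }
  return mi < 0 ? 0.0 : mi;
}

// [[Rcpp::export]]
double cpp_mi(NumericVector act, IntegerVector cls, int nbins) {
  if (act.size() != cls.size()) stop("activity and class vectors differ in length");
  std::vector<double> a(act.begin(), act.end());
  std::vector<int> c(cls.begin(), cls.end());
  return mi_bits(a.data(), c.data(), (int)a.size(), nbins);
}

struct SearchParams {
  int maxd;       // max graph distance of any member from the seed
  double rate;    // minimum relative MI improvement to accept a candidate
  int maxsize;    // maximum member count
  int nbins;      // histogram bins for the activity
};

// Greedy expansion from one seed. Z is samples x genes (column g = gene g's
// z-scores, contiguous); rowmap[g] gives the column actually used for gene g
// (identity normally; a permutation under the gene-null). lexrank breaks score
// ties deterministically (smaller rank = lexicographically smaller gene id).
static double greedy_from_seed(const double* Z, int nsamp, int ngene,
                               const std::vector<int>& cls, const AdjList& adj,
                               const std::vector<int>& lexrank,
                               const int* rowmap, int seed,
                               const SearchParams& P,
                               std::vector<int>* out_members) {
  // BFS ball of radius maxd around the seed
  std::vector<int> dist(ngene, -1);
  std::vector<int> queue;
  queue.reserve(64);
  queue.push_back(seed);
  dist[seed] = 0;
  for (size_t qi = 0; qi < queue.size(); ++qi) {
    int u = queue[qi];
    if (dist[u] == P.maxd) continue;
    for (size_t k = 0; k < adj[u].size(); ++k) {
      int v = adj[u][k];
      if (dist[v] < 0) {
        dist[v] = dist[u] + 1;
        queue.push_back(v);
      }
    }
  }

  std::vector<char> inmember(ngene, 0);
  std::vector<int> members;
  members.push_back(seed);
  inmember[seed] = 1;

  std::vector<double> actsum(nsamp), act(nsamp);
  const double* zs = Z + (size_t)rowmap[seed] * nsamp;
  for (int i = 0; i < nsamp; ++i) actsum[i] = zs[i];
  double cur = mi_bits(actsum.data(), cls.data(), nsamp, P.nbins);

  std::vector<char> incand(ngene, 0);
  std::vector<int> cand;
  while ((int)members.size() < P.maxsize) {
    // candidates: eligible neighbours of the current member set
    cand.clear();
    for (size_t mi_ = 0; mi_ < members.size(); ++mi_) {
      int u = members[mi_];
      for (size_t k = 0; k < adj[u].size(); ++k) {
        int v = adj[u][k];
        if (!inmember[v] && !incand[v] && dist[v] >= 0 && dist[v] <= P.maxd) {
          incand[v] = 1;
          cand.push_back(v);
        }
      }
    }
    if (cand.empty()) break;
    int best = -1;
    double best_mi = 0.0;
    double ksz = (double)members.size() + 1.0;
    for (size_t ci = 0; ci < cand.size(); ++ci) {
      int g = cand[ci];
      const double* zg = Z + (size_t)rowmap[g] * nsamp;
      for (int i = 0; i < nsamp; ++i) act[i] = (actsum[i] + zg[i]) / ksz;
      double m = mi_bits(act.data(), cls.data(), nsamp, P.nbins);
      if (best < 0 || m > best_mi ||
          (m == best_mi && lexrank[g] < lexrank[best])) {
        best = g;
        best_mi = m;
      }
    }
    for (size_t ci = 0; ci < cand.size(); ++ci) incand[cand[ci]] = 0;
    // relative-gain stop rule; a zero current score accepts any strict gain
    double gain = best_mi - cur;
    bool accept = (cur > 0.0) ? (gain >= P.rate * cur) : (gain > 0.0);
    if (!accept) break;
    const double* zb = Z + (size_t)rowmap[best] * nsamp;
    for (int i = 0; i < nsamp; ++i) actsum[i] += zb[i];
    members.push_back(best);
    inmember[best] = 1;
    cur = best_mi;
  }
  if (out_members) {
    std::sort(members.begin(), members.end());
    *out_members = members;
  }
  return cur;
}

// [[Rcpp::export]]
List cpp_search_seeds(NumericMatrix zt, IntegerVector cls, List adj,
                      IntegerVector seeds, IntegerVector lexrank, int maxd,
                      double rate, int maxsize, int nbins) {
  int nsamp = zt.nrow(), ngene = zt.ncol();
  AdjList A = as_adj(adj);
  std::vector<int> C(cls.begin(), cls.end());
  std::vector<int> LR(lexrank.begin(), lexrank.end());
  std::vector<int> id(ngene);
  for (int g = 0; g < ngene; ++g) id[g] = g;
  SearchParams P = {maxd, rate, maxsize, nbins};

  int ns = seeds.size();
  List members(ns);
  NumericVector scores(ns);
  std::vector<int> mem;
  for (int s = 0; s < ns; ++s) {
    scores[s] = greedy_from_seed(REAL(zt), nsamp, ngene, C, A, LR, id.data(),
                                 seeds[s], P, &mem);
    IntegerVector mv(mem.size());
    for (size_t k = 0; k < mem.size(); ++k) mv[k] = mem[k] + 1;  // 1-based
    members[s] = mv;
  }
  return List::create(_["members"] = members, _["score"] = scores);
}

// Sample a connected induced subgraph of k nodes by uniform-frontier growth
// from a uniformly chosen start node; retries if growth gets stuck.
// Returns true on success and fills `out`.
static bool random_connected(const AdjList& adj, int ngene, int k,
                             std::vector<int>& out) {
  for (int attempt = 0; attempt < 200; ++attempt) {
    out.clear();
    std::vector<char> in(ngene, 0);
    std::vector<int> frontier;
    int start = runif_int(ngene);
    out.push_back(start);
    in[start] = 1;
    for (size_t j = 0; j < adj[start].size(); ++j) frontier.push_back(adj[start][j]);
    while ((int)out.size() < k && !frontier.empty()) {
      int pick = runif_int((int)frontier.size());
      int v = frontier[pick];
      frontier[pick] = frontier.back();
      frontier.pop_back();
      if (in[v]) continue;
      in[v] = 1;
      out.push_back(v);
      for (size_t j = 0; j < adj[v].size(); ++j)
        if (!in[adj[v][j]]) frontier.push_back(adj[v][j]);
    }
    if ((int)out.size() == k) return true;
  }
  return false;
}

static double set_mi(const double* Z, int nsamp, const std::vector<int>& set,
                     const std::vector<int>& cls, int nbins,
                     std::vector<double>& buf) {
  double k = (double)set.size();
  std::fill(buf.begin(), buf.end(), 0.0);
  for (size_t j = 0; j < set.size(); ++j) {
    const double* zg = Z + (size_t)set[j] * nsamp;
    for (int i = 0; i < nsamp; ++i) buf[i] += zg[i];
  }
  for (int i = 0; i < nsamp; ++i) buf[i] /= k;
  return mi_bits(buf.data(), cls.data(), nsamp, nbins);
}

// Three one-sided permutation p-values per candidate, add-one estimator.
// Columns: gene-null, label-null, random-subnetwork-null.
// research_* = re-run the greedy search from the candidate's seed under the
// permuted data (selection-aware null); otherwise score-level recomputation.
// [[Rcpp::export]]
NumericMatrix cpp_permutation_pvalues(NumericMatrix zt, IntegerVector cls,
                                      List adj, List members,
                                      IntegerVector seeds, NumericVector scores,
                                      IntegerVector lexrank, int maxd,
                                      double rate, int maxsize, int nbins,
                                      int nperm, bool research_gene,
                                      bool research_label) {
  int nsamp = zt.nrow(), ngene = zt.ncol();
  AdjList A = as_adj(adj);
  std::vector<int> C(cls.begin(), cls.end());
  std::vector<int> LR(lexrank.begin(), lexrank.end());
  std::vector<int> id(ngene);
  for (int g = 0; g < ngene; ++g) id[g] = g;
  SearchParams P = {maxd, rate, maxsize, nbins};
  const double* Z = REAL(zt);

  int nc = members.size();
  NumericMatrix pv(nc, 3);
  std::vector<double> buf(nsamp);
  std::vector<int> perm(ngene), cperm(C), sub;

  for (int ci = 0; ci < nc; ++ci) {
    IntegerVector mv = members[ci];
    std::vector<int> mem(mv.size());
    for (R_xlen_t k = 0; k < mv.size(); ++k) mem[k] = mv[k] - 1;
    double obs = scores[ci];
    int seed = seeds[ci];
    int ge = 0, la = 0, ra = 0;

    for (int p = 0; p < nperm; ++p) {
      // (1) gene-null: permute the assignment of z-score rows to gene ids
      double s_gene;
      if (research_gene) {
        for (int g = 0; g < ngene; ++g) perm[g] = g;
        fisher_yates(perm);
        s_gene = greedy_from_seed(Z, nsamp, ngene, C, A, LR, perm.data(), seed,
                                  P, NULL);
      } else {
        sub.resize(mem.size());
        // random distinct rows standing in for the members
        for (int g = 0; g < ngene; ++g) perm[g] = g;
        for (size_t k = 0; k < mem.size(); ++k) {
          int j = k + runif_int(ngene - (int)k);
          std::swap(perm[k], perm[j]);
          sub[k] = perm[k];
        }
        s_gene = set_mi(Z, nsamp, sub, C, nbins, buf);
      }
      if (s_gene >= obs) ge++;

      // (2) label-null: permute the class labels
      cperm = C;
      fisher_yates(cperm);
      double s_lab;
      if (research_label) {
        s_lab = greedy_from_seed(Z, nsamp, ngene, cperm, A, LR, id.data(),
                                 seed, P, NULL);
      } else {
        s_lab = set_mi(Z, nsamp, mem, cperm, nbins, buf);
      }
      if (s_lab >= obs) la++;

      // (3) random-subnetwork-null: same-size random connected subgraph on
      // the unpermuted data; an unsampleable size counts as a tie
      if (random_connected(A, ngene, (int)mem.size(), sub)) {
        if (set_mi(Z, nsamp, sub, C, nbins, buf) >= obs) ra++;
      } else {
        ra++;
      }
    }
    pv(ci, 0) = (1.0 + ge) / (1.0 + nperm);
    pv(ci, 1) = (1.0 + la) / (1.0 + nperm);
    pv(ci, 2) = (1.0 + ra) / (1.0 + nperm);
  }
  return pv;
}
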