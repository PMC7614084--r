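// Amalgamated conditional-clade likelihood under the linear birth-death
// (duplication-loss) model with discrete WGD retention events.
//
// For a single lineage at a point of the species tree, W[c] is the
// probability that it evolves into exactly the observed gene set of clade c
// (every other descendant unobserved). Along a branch W obeys
//   dW[c]/ds = (2*lambda*eps(s) - (lambda+mu)) W[c]
//              + lambda * sum_splits p(c1,c2|c) W[c1] W[c2]
// where eps(s) is the extinction probability at height s, available in
// closed form from the birth-death generating function; the linear part is
// the single-surviving-lineage propagator G'(eps0, s). The ODE is integrated
// with classical RK4. Speciation nodes combine the two child branches with
// the CCD split weights; WGD marks apply eps' = (1-q) eps + q eps^2 and the
// corresponding retention terms for W. The geometric(eta) root prior on
// {1,2,...} is integrated analytically, amalgamating up to two observed
// root subtrees, and the likelihood is conditioned on at least one observed
// gene in each root-child clade.
//
// The species tree and the family CCDs are parsed once into a persistent
// model object (external pointer); MCMC re-evaluates the likelihood on it
// with new parameter vectors without any re-parsing or re-allocation.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

struct BD {
  double lam, mu;
  inline void ab(double t, double &alpha, double &beta) const {
    if (std::fabs(lam - mu) < 1e-10) {
      double x = 0.5 * (lam + mu) * t;
      alpha = x / (1.0 + x);
      beta = alpha;
    } else if (mu < 1e-14) {
      alpha = 0.0;
      beta = 1.0 - std::exp(-lam * t);
    } else {
      double e = std::exp((lam - mu) * t);
      alpha = mu * (e - 1.0) / (lam * e - mu);
      beta = lam * alpha / mu;
    }
  }
  inline double G(double s, double t) const {
    double a, b; ab(t, a, b);
    return a + (1.0 - a) * (1.0 - b) * s / (1.0 - b * s);
  }
  inline double Gp(double s, double t) const {
    double a, b; ab(t, a, b);
    double d = 1.0 - b * s;
    return (1.0 - a) * (1.0 - b) / (d * d);
  }
};

struct Ccd {
  int n_clades;
  int root;
  std::vector<int> mask, leaf_species, sstart, slen, sc1, sc2;
  std::vector<double> sp;
  // per species-tree node: indices of the clades whose species fit in the
  // node's subtree (the only clades with non-zero W there); built once
  std::vector<std::vector<int> > act;
};

struct Tree {
  int n, ntip, root;
  std::vector<int> parent, child1, child2, smask, postorder;
  std::vector<double> len;
  std::vector<std::vector<int> > wgd_idx;
  std::vector<std::vector<double> > wgd_s;
};

struct Model {
  Tree tr;
  std::vector<Ccd> fams;
  std::vector<double> mult, pobs;
  // reusable scratch
  std::vector<std::vector<double> > Wtop;
  std::vector<double> eps_top, k1, k2, k3, k4, tmp, Wnew;
  std::vector<char> active;
  // committed per-family state for partial re-evaluation: W at the branch
  // top and extinction probability per node, plus the family log-likelihood
  bool has_cache = false;
  std::vector<std::vector<std::vector<double> > > cW;   // [fam][node][clade]
  std::vector<std::vector<double> > cEps;               // [fam][node]
  std::vector<double> cLL;                              // [fam]
  // last evaluation (candidate) awaiting commit
  std::vector<int> last_nodes;
  std::vector<std::vector<std::vector<double> > > sW;
  std::vector<std::vector<double> > sEps;
  std::vector<double> sLL;
};

static void propagate_segment(Model &M, const Ccd &fam,
                              const std::vector<int> &act, std::vector<double> &W,
                              const BD &bd, double eps0, double dt, int steps) {
  if (dt <= 0.0 || act.empty()) return;
  double h = dt / steps;
  std::vector<double> &k1 = M.k1, &k2 = M.k2, &k3 = M.k3, &k4 = M.k4, &tmp = M.tmp;
  size_t na = act.size();
  for (int st = 0; st < steps; ++st) {
    double s0 = st * h;
    auto deriv = [&](const std::vector<double> &V, double s, std::vector<double> &out) {
      double eps = bd.G(eps0, s);
      double lin = 2.0 * bd.lam * eps - (bd.lam + bd.mu);
      for (size_t a = 0; a < na; ++a) {
        int c = act[a];
        double acc = lin * V[c];
        int s0i = fam.sstart[c], l = fam.slen[c];
        double dup = 0.0;
        for (int k = s0i; k < s0i + l; ++k) dup += fam.sp[k] * V[fam.sc1[k]] * V[fam.sc2[k]];
        out[c] = acc + bd.lam * dup;
      }
    };
    deriv(W, s0, k1);
    for (size_t a = 0; a < na; ++a) { int c = act[a]; tmp[c] = W[c] + 0.5 * h * k1[c]; }
    deriv(tmp, s0 + 0.5 * h, k2);
    for (size_t a = 0; a < na; ++a) { int c = act[a]; tmp[c] = W[c] + 0.5 * h * k2[c]; }
    deriv(tmp, s0 + 0.5 * h, k3);
    for (size_t a = 0; a < na; ++a) { int c = act[a]; tmp[c] = W[c] + h * k3[c]; }
    deriv(tmp, s0 + h, k4);
    for (size_t a = 0; a < na; ++a) {
      int c = act[a];
      W[c] += h / 6.0 * (k1[c] + 2.0 * k2[c] + 2.0 * k3[c] + k4[c]);
      if (W[c] < 0.0) W[c] = 0.0;
    }
  }
}

// Evaluate one family's log-likelihood. When `affected` is non-null, only
// the flagged species-tree nodes are recomputed (candidate values written to
// the scratch slots M.sW / M.sEps); unflagged nodes are read from the
// committed cache. With `affected` null everything is recomputed into the
// scratch slots.
static double family_loglik(Model &M, int fi, const std::vector<char> *affected,
                            const std::vector<double> &lam,
                            const std::vector<double> &mu,
                            const std::vector<double> &qv,
                            double eta, int steps) {
  const Tree &tr = M.tr;
  const Ccd &fam = M.fams[fi];
  int nc = fam.n_clades;
  if ((int)M.k1.size() < nc) {
    M.k1.resize(nc); M.k2.resize(nc); M.k3.resize(nc); M.k4.resize(nc);
    M.tmp.resize(nc); M.Wnew.resize(nc); M.active.resize(nc);
  }
  std::vector<std::vector<double> > &sW = M.sW[fi];
  std::vector<double> &sEps = M.sEps[fi];
  std::vector<std::vector<double> > &cW = M.cW[fi];
  std::vector<double> &cEps = M.cEps[fi];
  for (size_t oi = 0; oi < tr.postorder.size(); ++oi) {
    int v = tr.postorder[oi];
    if (affected != NULL && !(*affected)[v]) continue;
    std::vector<double> &W = sW[v];
    W.assign(nc, 0.0);
    double eps;
    int f = tr.child1[v], g = tr.child2[v];
    const std::vector<double> *Wf = NULL, *Wg = NULL;
    double ef = 0.0, eg = 0.0;
    if (f >= 0) {
      Wf = (affected == NULL || (*affected)[f]) ? &sW[f] : &cW[f];
      Wg = (affected == NULL || (*affected)[g]) ? &sW[g] : &cW[g];
      ef = (affected == NULL || (*affected)[f]) ? sEps[f] : cEps[f];
      eg = (affected == NULL || (*affected)[g]) ? sEps[g] : cEps[g];
    }
    if (f < 0) {                                 // tip
      eps = 1.0 - M.pobs[v];
      for (int c = 0; c < nc; ++c)
        if (fam.leaf_species[c] == v) W[c] = M.pobs[v];
    } else {                                     // speciation node
      eps = ef * eg;
      const std::vector<int> &act = fam.act[v];
      for (size_t a = 0; a < act.size(); ++a) {
        int c = act[a];
        double acc = (*Wf)[c] * eg + (*Wg)[c] * ef;
        int s0i = fam.sstart[c], l = fam.slen[c];
        for (int k = s0i; k < s0i + l; ++k) {
          acc += fam.sp[k] * ((*Wf)[fam.sc1[k]] * (*Wg)[fam.sc2[k]] +
                              (*Wf)[fam.sc2[k]] * (*Wg)[fam.sc1[k]]);
        }
        W[c] = acc;
      }
    }
    if (v == tr.root) {
      double WG = W[fam.root];
      double split_term = 0.0;
      int s0i = fam.sstart[fam.root], l = fam.slen[fam.root];
      for (int k = s0i; k < s0i + l; ++k)
        split_term += fam.sp[k] * W[fam.sc1[k]] * W[fam.sc2[k]];
      double e0 = ef * eg;
      double A = 1.0 / (1.0 - (1.0 - eta) * e0);
      double Lu = eta * A * A * WG +
                  2.0 * eta * (1.0 - eta) * A * A * A * split_term;
      auto gg = [&](double z) { return eta * z / (1.0 - (1.0 - eta) * z); };
      double Pobs = 1.0 - gg(ef) - gg(eg) + gg(e0);
      if (Lu <= 0.0 || Pobs <= 0.0) return R_NegInf;
      return std::log(Lu) - std::log(Pobs);
    }
    BD bd; bd.lam = lam[v]; bd.mu = mu[v];
    const std::vector<int> &act = fam.act[v];
    double L = tr.len[v];
    const std::vector<int> &widx = tr.wgd_idx[v];
    const std::vector<double> &ws = tr.wgd_s[v];
    double s_cur = 0.0;
    for (size_t m = 0; m < widx.size(); ++m) {
      double dt = ws[m] - s_cur;
      int nst = std::max(2, (int)std::ceil(steps * dt / std::max(L, 1e-12)));
      // RK4 stability for stiff (high-rate) proposals: h*(lam+mu) <~ 1
      nst = std::max(nst, (int)std::ceil(2.0 * (bd.lam + bd.mu) * dt));
      if (nst > 20000) nst = 20000;
      propagate_segment(M, fam, act, W, bd, eps, dt, nst);
      double eps_mark = bd.G(eps, dt);
      double q = qv[widx[m]];
      std::vector<double> &Wnew = M.Wnew;
      for (size_t a = 0; a < act.size(); ++a) {
        int c = act[a];
        double acc = (1.0 - q) * W[c] + q * 2.0 * eps_mark * W[c];
        int s0i = fam.sstart[c], lsp = fam.slen[c];
        double spl = 0.0;
        for (int k = s0i; k < s0i + lsp; ++k)
          spl += fam.sp[k] * W[fam.sc1[k]] * W[fam.sc2[k]];
        Wnew[c] = acc + q * spl;
      }
      for (size_t a = 0; a < act.size(); ++a) W[act[a]] = Wnew[act[a]];
      eps = (1.0 - q) * eps_mark + q * eps_mark * eps_mark;
      s_cur = ws[m];
    }
    double dt = L - s_cur;
    int nst = std::max(2, (int)std::ceil(steps * dt / std::max(L, 1e-12)));
    // RK4 stability for stiff (high-rate) proposals: h*(lam+mu) <~ 1
    nst = std::max(nst, (int)std::ceil(2.0 * (bd.lam + bd.mu) * dt));
    if (nst > 20000) nst = 20000;
    propagate_segment(M, fam, act, W, bd, eps, dt, nst);
    sEps[v] = bd.G(eps, dt);
  }
  return R_NegInf; // unreachable
}

static void model_alloc_state(Model &M) {
  int nf = M.fams.size(), n = M.tr.n;
  M.cW.assign(nf, std::vector<std::vector<double> >(n));
  M.cEps.assign(nf, std::vector<double>(n, 1.0));
  M.cLL.assign(nf, R_NegInf);
  M.sW.assign(nf, std::vector<std::vector<double> >(n));
  M.sEps.assign(nf, std::vector<double>(n, 1.0));
  M.sLL.assign(nf, R_NegInf);
  M.has_cache = false;
}

static Tree parse_tree(List tree_spec, IntegerVector wgd_node, NumericVector wgd_pos) {
  Tree tr;
  tr.n = as<int>(tree_spec["n"]);
  tr.ntip = as<int>(tree_spec["ntip"]);
  tr.root = as<int>(tree_spec["root"]) - 1;
  IntegerVector par = tree_spec["parent"];
  IntegerMatrix ch = tree_spec["children"];
  NumericVector len = tree_spec["length"];
  IntegerVector po = tree_spec["postorder"];
  IntegerVector sm = tree_spec["smask"];
  tr.parent.resize(tr.n); tr.child1.resize(tr.n); tr.child2.resize(tr.n);
  tr.len.resize(tr.n); tr.smask.resize(tr.n);
  for (int i = 0; i < tr.n; ++i) {
    tr.parent[i] = par[i] - 1;
    tr.child1[i] = ch(i, 0) - 1;
    tr.child2[i] = ch(i, 1) - 1;
    tr.len[i] = len[i];
    tr.smask[i] = sm[i];
  }
  tr.postorder.assign(po.begin(), po.end());
  for (size_t i = 0; i < tr.postorder.size(); ++i) tr.postorder[i] -= 1;
  tr.wgd_idx.resize(tr.n); tr.wgd_s.resize(tr.n);
  for (int m = 0; m < wgd_node.size(); ++m) {
    int v = wgd_node[m] - 1;
    tr.wgd_idx[v].push_back(m);
    tr.wgd_s[v].push_back(wgd_pos[m] * tr.len[v]);
  }
  for (int v = 0; v < tr.n; ++v) {
    for (size_t a = 0; a + 1 < tr.wgd_s[v].size(); ++a)
      for (size_t b = a + 1; b < tr.wgd_s[v].size(); ++b)
        if (tr.wgd_s[v][b] < tr.wgd_s[v][a]) {
          std::swap(tr.wgd_s[v][a], tr.wgd_s[v][b]);
          std::swap(tr.wgd_idx[v][a], tr.wgd_idx[v][b]);
        }
  }
  return tr;
}

static Ccd parse_ccd(List cc, const Tree &tr) {
  Ccd f;
  f.n_clades = as<int>(cc["n_clades"]);
  f.root = as<int>(cc["root"]);
  f.mask = as<std::vector<int> >(cc["mask"]);
  f.leaf_species = as<std::vector<int> >(cc["leaf_species"]);
  f.sstart = as<std::vector<int> >(cc["split_start"]);
  f.slen = as<std::vector<int> >(cc["split_len"]);
  f.sc1 = as<std::vector<int> >(cc["split_c1"]);
  f.sc2 = as<std::vector<int> >(cc["split_c2"]);
  f.sp = as<std::vector<double> >(cc["split_p"]);
  f.act.resize(tr.n);
  for (int v = 0; v < tr.n; ++v)
    for (int c = 0; c < f.n_clades; ++c)
      if ((f.mask[c] & tr.smask[v]) == f.mask[c]) f.act[v].push_back(c);
  return f;
}

// [[Rcpp::export]]
SEXP dlwgd_build_cpp(List tree_spec, IntegerVector wgd_node, NumericVector wgd_pos,
                     List ccds, NumericVector mult, NumericVector p_obs_tip) {
  Model *M = new Model();
  M->tr = parse_tree(tree_spec, wgd_node, wgd_pos);
  for (int i = 0; i < ccds.size(); ++i) M->fams.push_back(parse_ccd(ccds[i], M->tr));
  M->mult.assign(mult.begin(), mult.end());
  M->pobs.assign(p_obs_tip.begin(), p_obs_tip.end());
  model_alloc_state(*M);
  XPtr<Model> p(M, true);
  return p;
}

// Evaluate the total log-likelihood on a built model. `changed` lists the
// 1-based species-tree nodes whose branch parameters changed since the last
// committed state: only those nodes and their root paths are recomputed
// (empty => full recomputation). Candidate values stay in scratch until
// dlwgd_commit_cpp() is called; an uncommitted evaluation leaves the
// committed state untouched, which is exactly the Metropolis reject path.
// [[Rcpp::export]]
double dlwgd_eval_cpp(SEXP model_ptr, NumericVector lambda, NumericVector mu,
                      double eta, NumericVector q, int steps = 10,
                      IntegerVector changed = IntegerVector::create()) {
  XPtr<Model> M(model_ptr);
  std::vector<double> lam(lambda.begin(), lambda.end());
  std::vector<double> muv(mu.begin(), mu.end());
  std::vector<double> qv(q.begin(), q.end());
  bool partial = M->has_cache && changed.size() > 0;
  std::vector<char> affected(M->tr.n, partial ? 0 : 1);
  M->last_nodes.clear();
  if (partial) {
    for (int i = 0; i < changed.size(); ++i) {
      int v = changed[i] - 1;
      while (v >= 0 && !affected[v]) { affected[v] = 1; v = M->tr.parent[v]; }
    }
    affected[M->tr.root] = 1;
  }
  for (int v = 0; v < M->tr.n; ++v) if (affected[v]) M->last_nodes.push_back(v);
  const std::vector<char> *aff = partial ? &affected : NULL;
  double total = 0.0;
  bool bad = false;
  for (size_t i = 0; i < M->fams.size(); ++i) {
    double ll = family_loglik(*M, i, aff, lam, muv, qv, eta, steps);
    M->sLL[i] = ll;
    if (!R_finite(ll)) { bad = true; break; }
    total += M->mult[i] * ll;
  }
  return bad ? R_NegInf : total;
}

// adopt the last evaluation as the committed state
// [[Rcpp::export]]
void dlwgd_commit_cpp(SEXP model_ptr) {
  XPtr<Model> M(model_ptr);
  for (size_t i = 0; i < M->fams.size(); ++i) {
    for (size_t k = 0; k < M->last_nodes.size(); ++k) {
      int v = M->last_nodes[k];
      M->cW[i][v] = M->sW[i][v];
      M->cEps[i][v] = M->sEps[i][v];
    }
    M->cLL[i] = M->sLL[i];
  }
  M->has_cache = true;
}

// [[Rcpp::export]]
NumericVector dlwgd_eval_by_family_cpp(SEXP model_ptr, NumericVector lambda,
                                       NumericVector mu, double eta,
                                       NumericVector q, int steps = 10) {
  XPtr<Model> M(model_ptr);
  std::vector<double> lam(lambda.begin(), lambda.end());
  std::vector<double> muv(mu.begin(), mu.end());
  std::vector<double> qv(q.begin(), q.end());
  NumericVector out(M->fams.size());
  for (size_t i = 0; i < M->fams.size(); ++i)
    out[i] = family_loglik(*M, i, NULL, lam, muv, qv, eta, steps);
  return out;
}

// one-shot convenience entry point (builds, evaluates, frees)
// [[Rcpp::export]]
double dlwgd_loglik_cpp(List tree_spec, NumericVector lambda, NumericVector mu,
                        NumericVector p_obs_tip, double eta, NumericVector q,
                        IntegerVector wgd_node, NumericVector wgd_pos,
                        List ccds, NumericVector mult, int steps = 10) {
  Model M;
  M.tr = parse_tree(tree_spec, wgd_node, wgd_pos);
  for (int i = 0; i < ccds.size(); ++i) M.fams.push_back(parse_ccd(ccds[i], M.tr));
  M.mult.assign(mult.begin(), mult.end());
  M.pobs.assign(p_obs_tip.begin(), p_obs_tip.end());
  model_alloc_state(M);
  std::vector<double> lam(lambda.begin(), lambda.end());
  std::vector<double> muv(mu.begin(), mu.end());
  std::vector<double> qv(q.begin(), q.end());
  double total = 0.0;
  for (size_t i = 0; i < M.fams.size(); ++i) {
    double ll = family_loglik(M, i, NULL, lam, muv, qv, eta, steps);
    if (!R_finite(ll)) return R_NegInf;
    total += M.mult[i] * ll;
  }
  return total;
}

// per-family log-likelihoods (diagnostics; e.g. spotting families that are
// structurally impossible under the two-subtree root amalgamation)
// [[Rcpp::export]]
NumericVector dlwgd_loglik_by_family_cpp(List tree_spec, NumericVector lambda,
                                         NumericVector mu, NumericVector p_obs_tip,
                                         double eta, NumericVector q,
                                         IntegerVector wgd_node, NumericVector wgd_pos,
                                         List ccds, int steps = 10) {
  Model M;
  M.tr = parse_tree(tree_spec, wgd_node, wgd_pos);
  for (int i = 0; i < ccds.size(); ++i) M.fams.push_back(parse_ccd(ccds[i], M.tr));
  M.pobs.assign(p_obs_tip.begin(), p_obs_tip.end());
  model_alloc_state(M);
  std::vector<double> lam(lambda.begin(), lambda.end());
  std::vector<double> muv(mu.begin(), mu.end());
  std::vector<double> qv(q.begin(), q.end());
  NumericVector out(M.fams.size());
  for (size_t i = 0; i < M.fams.size(); ++i)
    out[i] = family_loglik(M, i, NULL, lam, muv, qv, eta, steps);
  return out;
}
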