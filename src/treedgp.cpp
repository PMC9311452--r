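#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Cross-covariance parameters on the expanded domain D x Xi.
struct ThetaC {
  vec sigma1;   // length q, may be negative
  vec sigma2;   // length q, nonnegative
  vec phi_i;    // length q, spatial decay of the independent components
  mat delta;    // q x q symmetric latent distances, zero diagonal
  double alpha, beta, phi;
};

static ThetaC theta_from_list(const Rcpp::List& th) {
  ThetaC t;
  t.sigma1 = Rcpp::as<vec>(th["sigma1"]);
  t.sigma2 = Rcpp::as<vec>(th["sigma2"]);
  t.phi_i  = Rcpp::as<vec>(th["phi_i"]);
  t.delta  = Rcpp::as<mat>(th["delta"]);
  t.alpha  = Rcpp::as<double>(th["alpha"]);
  t.beta   = Rcpp::as<double>(th["beta_cov"]);
  t.phi    = Rcpp::as<double>(th["phi"]);
  return t;
}

// Base correlation on the expanded domain:
// C(h, Delta) = (1 + alpha Delta)^(-beta) * exp(-phi h (1 + alpha Delta)^(-beta/2))
static inline double kcorr(double h, double Delta, double alpha, double beta,
                           double phi) {
  const double g = std::pow(1.0 + alpha * Delta, -beta);
  return g * std::exp(-phi * h * std::sqrt(g));
}

// Cross-covariance between variables vi and vj at spatial distance h.
// Same variable: sigma_i1^2 C(h, 0) + sigma_i2^2 exp(-phi_i h);
// different variables: sigma_i1 sigma_j1 C(h, delta_ij).  The per-pair
// amplitude/decay coefficients are tabulated once per theta so that matrix
// assembly needs only exp() calls.
struct ThetaTab {
  mat a1, c1, a2, c2;  // entry = a1 exp(-c1 h) + a2 exp(-c2 h)
};

static ThetaTab theta_tab(const ThetaC& t) {
  const uword q = t.sigma1.n_elem;
  ThetaTab tab;
  tab.a1.set_size(q, q); tab.c1.set_size(q, q);
  tab.a2.zeros(q, q);    tab.c2.zeros(q, q);
  for (uword i = 0; i < q; ++i) {
    for (uword j = 0; j < q; ++j) {
      if (i == j) {
        tab.a1(i, i) = t.sigma1(i) * t.sigma1(i);
        tab.c1(i, i) = t.phi;
        tab.a2(i, i) = t.sigma2(i) * t.sigma2(i);
        tab.c2(i, i) = t.phi_i(i);
      } else {
        const double g = std::pow(1.0 + t.alpha * t.delta(i, j), -t.beta);
        tab.a1(i, j) = t.sigma1(i) * t.sigma1(j) * g;
        tab.c1(i, j) = t.phi * std::sqrt(g);
      }
    }
  }
  return tab;
}

static inline double cov_entry_tab(double h, int vi, int vj,
                                   const ThetaTab& tab) {
  const uword i = vi - 1, j = vj - 1;
  double v = tab.a1(i, j) * std::exp(-tab.c1(i, j) * h);
  const double a2 = tab.a2(i, j);
  if (a2 != 0.0) v += a2 * std::exp(-tab.c2(i, j) * h);
  return v;
}

static inline double cov_entry(double h, int vi, int vj, const ThetaC& t) {
  if (vi == vj) {
    const int i = vi - 1;
    return t.sigma1(i) * t.sigma1(i) * std::exp(-t.phi * h) +
           t.sigma2(i) * t.sigma2(i) * std::exp(-t.phi_i(i) * h);
  }
  const double d = t.delta(vi - 1, vj - 1);
  return t.sigma1(vi - 1) * t.sigma1(vj - 1) * kcorr(h, d, t.alpha, t.beta, t.phi);
}

// [[Rcpp::export(name = ".cov_block_arma")]]
arma::mat cov_block_arma(const arma::mat& X1, const arma::ivec& v1,
                         const arma::mat& X2, const arma::ivec& v2,
                         const Rcpp::List& theta) {
  const ThetaC t = theta_from_list(theta);
  const ThetaTab tab = theta_tab(t);
  mat out(X1.n_rows, X2.n_rows);
  for (uword j = 0; j < X2.n_rows; ++j) {
    for (uword i = 0; i < X1.n_rows; ++i) {
      const double h = norm(X1.row(i) - X2.row(j), 2);
      out(i, j) = cov_entry_tab(h, v1(i), v2(j), tab);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Packed DAG with cached per-node distance matrices and two factor slots
// (current / proposal) so that Metropolis proposals do not clobber the
// factors the w-sweep is using.
// ---------------------------------------------------------------------------

struct NodeFactors {
  mat H;        // n_i x J_i conditional mean operator
  mat Rinv;     // n_i x n_i inverse of conditional covariance
  mat RinvH;    // cached R^{-1} H (message passing)
  mat RcholL;   // lower Cholesky of R
  mat Cpinv;    // J_i x J_i parent precision C_[i]^{-1}
  double logdetR = 0.0;
  bool has_rinv = false;
};

struct NodeC {
  uvec locs;        // 0-based expanded-location indices
  uvec parents;     // 0-based node indices, level-ascending
  uvec children;    // 0-based node indices
  uvec par_locs;    // concat of parents' locs
  uvec par_offset;  // column offset of each parent's block inside H
  ivec vself, vpar; // cached variable indices of locs / par_locs
  int level = 0;
  // 0 = root (no parents), 1 = single parent, 2 = nested (parents ==
  // Pa[last parent] + {last parent}), 3 = general (direct dense inverse)
  int prec_mode = 0;
};

struct DagPack {
  mat coords;
  ivec vindex;
  std::vector<NodeC> nodes;
  std::vector<mat> dist_self;   // per node: pairwise distances within node
  std::vector<mat> dist_par;    // per node: distances node x parent locations
  std::vector<NodeFactors> cur, prop;
  bool has_cur = false;
  double jitter_rel = 1e-9;
};

static ivec subset_iv(const ivec& v, const uvec& idx) {
  ivec out(idx.n_elem);
  for (uword i = 0; i < idx.n_elem; ++i) out(i) = v(idx(i));
  return out;
}

static mat dist_block(const mat& A, const mat& B) {
  mat out(A.n_rows, B.n_rows);
  for (uword j = 0; j < B.n_rows; ++j)
    for (uword i = 0; i < A.n_rows; ++i)
      out(i, j) = norm(A.row(i) - B.row(j), 2);
  return out;
}

// Covariance block from a cached distance matrix.  Node locations are
// ordered variable-major, so the row variable index is piecewise constant:
// each (row-run, column) stretch uses scalar coefficients and a tight
// branch-free exp loop.
static mat cov_from_dist(const mat& D, const ivec& va, const ivec& vb,
                         const ThetaTab& tab) {
  const uword nr = D.n_rows, nc = D.n_cols;
  mat out(nr, nc);
  // row runs of constant variable
  std::vector<uword> starts;
  starts.push_back(0);
  for (uword i = 1; i < nr; ++i) {
    if (va(i) != va(i - 1)) starts.push_back(i);
  }
  const uword nruns = starts.size();
  starts.push_back(nr);
  for (uword j = 0; j < nc; ++j) {
    const uword cj = vb(j) - 1;
    const double* dcol = D.colptr(j);
    double* ocol = out.colptr(j);
    for (uword r = 0; r < nruns; ++r) {
      const uword i0 = starts[r], i1 = starts[r + 1];
      const uword ci = va(i0) - 1;
      const double a1 = tab.a1(ci, cj), c1 = tab.c1(ci, cj);
      const double a2 = tab.a2(ci, cj), c2 = tab.c2(ci, cj);
      if (a2 != 0.0) {
        for (uword i = i0; i < i1; ++i) {
          ocol[i] = a1 * std::exp(-c1 * dcol[i]) +
                    a2 * std::exp(-c2 * dcol[i]);
        }
      } else {
        for (uword i = i0; i < i1; ++i) {
          ocol[i] = a1 * std::exp(-c1 * dcol[i]);
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".dag_pack_build")]]
SEXP dag_pack_build(const arma::mat& coords, const arma::ivec& vindex,
                    const Rcpp::List& node_locs, const Rcpp::List& node_parents,
                    const Rcpp::List& node_children,
                    const arma::ivec& levels, const arma::ivec& prec_mode) {
  Rcpp::XPtr<DagPack> p(new DagPack(), true);
  p->coords = coords;
  p->vindex = vindex;
  const int m = node_locs.size();
  p->nodes.resize(m);
  p->dist_self.resize(m);
  p->dist_par.resize(m);
  p->cur.resize(m);
  p->prop.resize(m);
  for (int i = 0; i < m; ++i) {
    NodeC& nd = p->nodes[i];
    nd.locs = Rcpp::as<uvec>(node_locs[i]) - 1;
    nd.parents = Rcpp::as<uvec>(node_parents[i]) - 1;
    nd.children = Rcpp::as<uvec>(node_children[i]) - 1;
    nd.level = levels(i);
    nd.prec_mode = prec_mode(i);
    uword J = 0;
    for (uword k = 0; k < nd.parents.n_elem; ++k)
      J += p->nodes[nd.parents(k)].locs.n_elem;  // parents precede in order
    nd.par_locs.set_size(J);
    nd.par_offset.set_size(nd.parents.n_elem);
    uword off = 0;
    for (uword k = 0; k < nd.parents.n_elem; ++k) {
      const uvec& pl = p->nodes[nd.parents(k)].locs;
      nd.par_offset(k) = off;
      nd.par_locs.subvec(off, off + pl.n_elem - 1) = pl;
      off += pl.n_elem;
    }
    nd.vself = subset_iv(p->vindex, nd.locs);
    nd.vpar = subset_iv(p->vindex, nd.par_locs);
    const mat Xi = coords.rows(nd.locs);
    p->dist_self[i] = dist_block(Xi, Xi);
    if (J > 0) p->dist_par[i] = dist_block(Xi, coords.rows(nd.par_locs));
  }
  return p;
}

static mat chol_lower_jittered(mat R, double base_jitter, const char* what,
                               int node_id) {
  const double md = mean(R.diag());
  double jit = base_jitter * (md > 0 ? md : 1.0);
  mat L;
  for (int k = 0; k < 6; ++k) {
    if (chol(L, R + jit * eye(R.n_rows, R.n_cols), "lower")) return L;
    jit *= 100.0;
  }
  Rcpp::stop("Cholesky of %s failed at node %d even after jitter escalation",
             what, node_id + 1);
  return L;  // not reached
}

// Compute all node factors for theta into a slot, level-by-level.
static void node_rinv(NodeFactors& f) {
  const mat Li = inv(trimatl(f.RcholL));
  f.Rinv = Li.t() * Li;
  f.has_rinv = true;
}

// Compute all node factors for theta into a slot, level-by-level.  For
// childless nodes R^{-1} is not needed to evaluate the density (nor to
// propagate the parent-precision recursion), so it is deferred until the
// slot becomes current (see complete_rinv).
static void compute_factors(DagPack& dp, const ThetaC& t,
                            std::vector<NodeFactors>& slot) {
  const ThetaTab tab = theta_tab(t);
  const int m = dp.nodes.size();
  for (int j = 0; j < m; ++j) {
    const NodeC& nd = dp.nodes[j];
    NodeFactors& f = slot[j];
    const uword n = nd.locs.n_elem;
    const uword J = nd.par_locs.n_elem;
    mat Cj = cov_from_dist(dp.dist_self[j], nd.vself, nd.vself, tab);
    if (J == 0) {
      f.H.set_size(n, 0);
      f.Cpinv.set_size(0, 0);
      f.RcholL = chol_lower_jittered(Cj, dp.jitter_rel, "C_i (root)", j);
    } else {
      // parent precision C_[j]^{-1}
      if (nd.prec_mode == 2) {
        // parents = Pa[p] + {p} for p = last parent; assemble 2x2 block form
        const int pid = nd.parents(nd.parents.n_elem - 1);
        NodeFactors& fp = slot[pid];
        if (!fp.has_rinv) node_rinv(fp);
        const uword Jp = fp.Cpinv.n_rows;
        const uword np = dp.nodes[pid].locs.n_elem;
        f.Cpinv.set_size(Jp + np, Jp + np);
        const mat RiH = fp.Rinv * fp.H;            // np x Jp
        f.Cpinv.submat(0, 0, Jp - 1, Jp - 1) = fp.Cpinv + fp.H.t() * RiH;
        f.Cpinv.submat(0, Jp, Jp - 1, Jp + np - 1) = -RiH.t();
        f.Cpinv.submat(Jp, 0, Jp + np - 1, Jp - 1) = -RiH;
        f.Cpinv.submat(Jp, Jp, Jp + np - 1, Jp + np - 1) = fp.Rinv;
      } else if (nd.prec_mode == 1 &&
                 dp.nodes[nd.parents(0)].parents.n_elem == 0) {
        // single root parent: C_[j] = C_p = R_p, so reuse its inverse
        NodeFactors& fp = slot[nd.parents(0)];
        if (!fp.has_rinv) node_rinv(fp);
        f.Cpinv = fp.Rinv;
      } else {
        // direct inverse of the assembled parent covariance
        const mat Xp = dp.coords.rows(nd.par_locs);
        const mat Cpar = cov_from_dist(dist_block(Xp, Xp), nd.vpar, nd.vpar,
                                       tab);
        const mat Lp = chol_lower_jittered(Cpar, dp.jitter_rel, "C_[j]", j);
        const mat Lpi = inv(trimatl(Lp));
        f.Cpinv = Lpi.t() * Lpi;
      }
      const mat Cjp = cov_from_dist(dp.dist_par[j], nd.vself, nd.vpar, tab);
      f.H = Cjp * f.Cpinv;
      mat R = Cj - f.H * Cjp.t();
      R = 0.5 * (R + R.t());
      f.RcholL = chol_lower_jittered(R, dp.jitter_rel, "R_j", j);
    }
    f.has_rinv = false;
    f.logdetR = 2.0 * sum(log(f.RcholL.diag()));
  }
}

static void complete_rinv(DagPack& dp, std::vector<NodeFactors>& slot) {
  for (size_t j = 0; j < dp.nodes.size(); ++j) {
    if (!slot[j].has_rinv) node_rinv(slot[j]);
    if (slot[j].H.n_cols > 0) slot[j].RinvH = slot[j].Rinv * slot[j].H;
    else slot[j].RinvH.set_size(slot[j].Rinv.n_rows, 0);
  }
}

// [[Rcpp::export(name = ".dag_factors_update")]]
void dag_factors_update(SEXP ptr, const Rcpp::List& theta, bool proposal) {
  Rcpp::XPtr<DagPack> p(ptr);
  const ThetaC t = theta_from_list(theta);
  compute_factors(*p, t, proposal ? p->prop : p->cur);
  if (!proposal) {
    complete_rinv(*p, p->cur);
    p->has_cur = true;
  }
}

// [[Rcpp::export(name = ".dag_swap_slots")]]
void dag_swap_slots(SEXP ptr) {
  Rcpp::XPtr<DagPack> p(ptr);
  std::swap(p->cur, p->prop);
  complete_rinv(*p, p->cur);
  p->has_cur = true;
}

static double log_density_slot(const DagPack& dp,
                               const std::vector<NodeFactors>& slot,
                               const vec& w) {
  const double log2pi = std::log(2.0 * M_PI);
  double ld = 0.0;
  for (size_t j = 0; j < dp.nodes.size(); ++j) {
    const NodeC& nd = dp.nodes[j];
    const NodeFactors& f = slot[j];
    vec r = w.elem(nd.locs);
    if (nd.par_locs.n_elem > 0) r -= f.H * w.elem(nd.par_locs);
    const vec y = solve(trimatl(f.RcholL), r);
    ld += -0.5 * (nd.locs.n_elem * log2pi + f.logdetR + dot(y, y));
  }
  return ld;
}

// [[Rcpp::export(name = ".dag_log_density")]]
double dag_log_density(SEXP ptr, const arma::vec& w, bool proposal) {
  Rcpp::XPtr<DagPack> p(ptr);
  return log_density_slot(*p, proposal ? p->prop : p->cur, w);
}

// One full Gibbs sweep over all nodes (level-ascending) for the latent field,
// for the diagonal-loading data model: each observed row loads exactly one
// expanded location with coefficient z.  dinv is 1/tau_j^2 at observed
// locations and 0 elsewhere (the zero-filled D-tilde convention), ytilde is
// y - x'beta at observed locations (0 elsewhere).
// [[Rcpp::export(name = ".dag_w_sweep")]]
arma::vec dag_w_sweep(SEXP ptr, const arma::vec& w_in, const arma::vec& ytilde,
                      const arma::vec& dinv, const arma::vec& zcoef) {
  Rcpp::XPtr<DagPack> p(ptr);
  if (!p->has_cur) Rcpp::stop("node factors have not been computed");
  vec w = w_in;
  const std::vector<NodeFactors>& fac = p->cur;
  for (size_t i = 0; i < p->nodes.size(); ++i) {
    const NodeC& nd = p->nodes[i];
    const NodeFactors& f = fac[i];
    const uword n = nd.locs.n_elem;
    mat P = f.Rinv;
    vec b(n, fill::zeros);
    if (nd.par_locs.n_elem > 0) b = f.Rinv * (f.H * w.elem(nd.par_locs));
    for (uword k = 0; k < n; ++k) {
      const uword loc = nd.locs(k);
      const double di = dinv(loc);
      if (di > 0.0) {
        const double z = zcoef(loc);
        P(k, k) += z * z * di;
        b(k) += z * di * ytilde(loc);
      }
    }
    for (uword c = 0; c < nd.children.n_elem; ++c) {
      const uword cid = nd.children(c);
      const NodeC& cn = p->nodes[cid];
      const NodeFactors& fc = fac[cid];
      // locate this node's block inside the child's H
      uword off = 0;
      bool found = false;
      for (uword k = 0; k < cn.parents.n_elem; ++k) {
        if (cn.parents(k) == i) { off = cn.par_offset(k); found = true; break; }
      }
      if (!found) Rcpp::stop("child/parent bookkeeping mismatch");
      const mat Hic = fc.H.cols(off, off + n - 1);
      vec wtil = w.elem(cn.locs) - fc.H * w.elem(cn.par_locs) + Hic * w.elem(nd.locs);
      const mat RinvHic = fc.RinvH.cols(off, off + n - 1);  // n_c x n
      P += Hic.t() * RinvHic;
      b += RinvHic.t() * wtil;
    }
    P = 0.5 * (P + P.t());
    mat U;
    if (!chol(U, P)) {
      P.diag() += 1e-8 * mean(P.diag());
      if (!chol(U, P)) Rcpp::stop("full-conditional precision not PD at node %d", i + 1);
    }
    const vec mu = solve(trimatu(U), solve(trimatl(U.t()), b));
    Rcpp::NumericVector zr = Rcpp::rnorm(n);
    const vec zz(zr.begin(), n);
    w.elem(nd.locs) = mu + solve(trimatu(U), zz);
  }
  return w;
}

// Materialise the factors of a slot as an R list (for tests and for the
// R-level block algebra, which operates on small problems).
// [[Rcpp::export(name = ".dag_factors_list")]]
Rcpp::List dag_factors_list(SEXP ptr, bool proposal) {
  Rcpp::XPtr<DagPack> p(ptr);
  const std::vector<NodeFactors>& slot = proposal ? p->prop : p->cur;
  const int m = p->nodes.size();
  Rcpp::List out(m);
  for (int j = 0; j < m; ++j) {
    const NodeFactors& f = slot[j];
    mat R = f.RcholL * f.RcholL.t();
    out[j] = Rcpp::List::create(
        Rcpp::Named("H") = f.H, Rcpp::Named("R") = R,
        Rcpp::Named("Rinv") = f.Rinv, Rcpp::Named("parent_precision") = f.Cpinv,
        Rcpp::Named("logdetR") = f.logdetR);
  }
  return out;
}
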