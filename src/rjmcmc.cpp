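// Reversible-jump MCMC over multi-regime Ornstein-Uhlenbeck allometric
// regressions. The R wrapper (R/rjmcmc.R) prepares the tree summaries
// (preorder edge table for regime painting, postorder edge table for the
// pruning likelihood, root-to-tip path segments for the regime weights);
// this file owns the sampler loop and its likelihood.
//
// Likelihood: with a fixed root, the OU covariance on an ultrametric tree
// of depth T is sigma2/(2 alpha) * exp(-2 alpha (T - t_a)) *
// (1 - exp(-2 alpha t_a)) for MRCA height t_a — a Brownian covariance on
// a tree whose node heights are warped by t -> (exp(-2a(T-t)) -
// exp(-2aT))/(2a). The log-density is therefore computed by Felsenstein
// pruning in O(n), with only non-positive exponents (numerically safe for
// any alpha > 0).
//
// Conventions: edges are 0-based indices into a preorder edge table
// (parents before children); regime 0 is the ancestral (root) regime and
// shift j (0-based) owns regime j+1. Uses R's RNG so chains are
// reproducible from set.seed().

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct TreeData {
  int n, nedge, nnode;          // tips, edges, total nodes (tips first)
  std::vector<double> x, y, depth;
  double tmax;
  std::vector<int> seg_tip, seg_edge;
  std::vector<double> seg_t0, seg_t1;
  std::vector<int> parent_edge;     // preorder; -1 when stemming from root
  std::vector<int> po_parent, po_child;   // postorder edges, 0-based nodes
  std::vector<double> po_t0, po_t1;       // heights of their ends
  std::vector<std::vector<int>> neighbors; // adjacent edges per edge
  int root;
};

struct Priors {
  double alpha_scale, sigma_scale, pois_mean, theta_mean, theta_sd,
      beta_mean, beta_sd;
  int max_shifts, n_branch;
};

double half_cauchy_lpdf(double v, double scale) {
  if (v <= 0) return R_NegInf;
  return std::log(2.0 / (M_PI * scale)) - std::log1p((v / scale) * (v / scale));
}

// painting from shift assignments, preorder pass
void repaint(const TreeData& td, const std::vector<int>& shift_of,
             std::vector<int>& regime) {
  for (int e = 0; e < td.nedge; ++e) {
    if (shift_of[e] > 0) {
      regime[e] = shift_of[e];
    } else {
      regime[e] = td.parent_edge[e] >= 0 ? regime[td.parent_edge[e]] : 0;
    }
  }
}

// n x K regime weights: E[y_i] = sum_k W(i,k) (theta_k + beta_k x_i)
void weight_matrix(const TreeData& td, const std::vector<int>& regime,
                   double alpha, int k_regimes, std::vector<double>& w) {
  w.assign((size_t)td.n * k_regimes, 0.0);
  for (size_t s = 0; s < td.seg_tip.size(); ++s) {
    int tip = td.seg_tip[s];
    double ti = td.depth[tip];
    w[(size_t)regime[td.seg_edge[s]] * td.n + tip] +=
        std::exp(-alpha * (ti - td.seg_t1[s])) -
        std::exp(-alpha * (ti - td.seg_t0[s]));
  }
  for (int i = 0; i < td.n; ++i) w[i] += std::exp(-alpha * td.depth[i]);
}

// O(n) pruning log-density of y - mu under the fixed-root OU covariance
double ou_prune_loglik(const TreeData& td, const std::vector<double>& mu,
                       double alpha, double sigma2,
                       std::vector<double>& v, std::vector<double>& d,
                       std::vector<double>& v1, std::vector<double>& b1,
                       std::vector<int>& seen) {
  const double inv2a = 1.0 / (2.0 * alpha);
  for (int i = 0; i < td.n; ++i) { v[i] = td.y[i] - mu[i]; d[i] = 0.0; }
  std::fill(seen.begin(), seen.end(), 0);
  double logdet = 0.0, q = 0.0;
  for (int e = 0; e < td.nedge; ++e) {
    int p = td.po_parent[e], c = td.po_child[e];
    // warped branch length (non-positive exponents only)
    double wl = inv2a * (std::exp(-2.0 * alpha * (td.tmax - td.po_t1[e])) -
                         std::exp(-2.0 * alpha * (td.tmax - td.po_t0[e])));
    double bp = wl + d[c];
    if (seen[p] == 0) {
      v1[p] = v[c]; b1[p] = bp; seen[p] = 1;
    } else {
      double tot = b1[p] + bp;
      if (tot <= 0) return R_NegInf;   // degenerate (zero-length cherry)
      double contrast = v1[p] - v[c];
      logdet += std::log(tot);
      q += contrast * contrast / tot;
      v[p] = (v1[p] * bp + v[c] * b1[p]) / tot;
      d[p] = b1[p] * bp / tot;
      seen[p] = 1;  // stays merged (binary tree: exactly two children)
    }
  }
  int r = td.root;
  if (d[r] <= 0) return R_NegInf;
  logdet += std::log(d[r]);
  q += v[r] * v[r] / d[r];
  return -0.5 * (td.n * std::log(2.0 * M_PI) + td.n * std::log(sigma2) +
                 logdet + q / sigma2);
}

struct State {
  double alpha, sigma2;
  std::vector<double> theta, beta;      // index 0 = root regime
  std::vector<int> shift_edges;         // shift j owns regime j+1
  std::vector<int> shift_of, regime;    // per edge
  std::vector<double> w, mu;
  double loglik, logprior;
  int k() const { return (int)shift_edges.size(); }
};

double log_prior_state(const State& st, const Priors& pr, double pois_lognorm) {
  int k = st.k();
  if (k > pr.max_shifts) return R_NegInf;
  double lp = half_cauchy_lpdf(st.alpha, pr.alpha_scale) +
              half_cauchy_lpdf(st.sigma2, pr.sigma_scale);
  for (size_t j = 0; j < st.theta.size(); ++j) {
    lp += R::dnorm(st.theta[j], pr.theta_mean, pr.theta_sd, 1);
    lp += R::dnorm(st.beta[j], pr.beta_mean, pr.beta_sd, 1);
  }
  lp += R::dpois(k, pr.pois_mean, 1) - pois_lognorm;
  lp -= R::lchoose(pr.n_branch, k);
  return lp;
}

void refresh_mean(const TreeData& td, State& st) {
  int kk = st.k() + 1;
  st.mu.assign(td.n, 0.0);
  for (int k = 0; k < kk; ++k) {
    const double th = st.theta[k], be = st.beta[k];
    const double* wcol = &st.w[(size_t)k * td.n];
    for (int i = 0; i < td.n; ++i) st.mu[i] += wcol[i] * (th + be * td.x[i]);
  }
}

struct Scratch {
  std::vector<double> v, d, v1, b1;
  std::vector<int> seen;
  void init(int nnode) {
    v.assign(nnode, 0.0); d.assign(nnode, 0.0);
    v1.assign(nnode, 0.0); b1.assign(nnode, 0.0);
    seen.assign(nnode, 0);
  }
};

// full refresh after an alpha or painting change
void refresh_all(const TreeData& td, State& st, Scratch& sc, bool prior_only) {
  if (prior_only) { st.loglik = 0.0; return; }
  weight_matrix(td, st.regime, st.alpha, st.k() + 1, st.w);
  refresh_mean(td, st);
  st.loglik = ou_prune_loglik(td, st.mu, st.alpha, st.sigma2,
                              sc.v, sc.d, sc.v1, sc.b1, sc.seen);
}

TreeData read_tree_data(List tree_data) {
  TreeData td;
  td.x = as<std::vector<double>>(tree_data["x"]);
  td.y = as<std::vector<double>>(tree_data["y"]);
  td.depth = as<std::vector<double>>(tree_data["depth"]);
  td.n = (int)td.x.size();
  td.tmax = *std::max_element(td.depth.begin(), td.depth.end());
  td.seg_tip = as<std::vector<int>>(tree_data["seg_tip"]);
  td.seg_edge = as<std::vector<int>>(tree_data["seg_edge"]);
  td.seg_t0 = as<std::vector<double>>(tree_data["seg_t0"]);
  td.seg_t1 = as<std::vector<double>>(tree_data["seg_t1"]);
  td.nedge = as<int>(tree_data["nedge"]);
  td.parent_edge = as<std::vector<int>>(tree_data["parent_edge"]);
  td.po_parent = as<std::vector<int>>(tree_data["po_parent"]);
  td.po_child = as<std::vector<int>>(tree_data["po_child"]);
  td.po_t0 = as<std::vector<double>>(tree_data["po_t0"]);
  td.po_t1 = as<std::vector<double>>(tree_data["po_t1"]);
  td.nnode = as<int>(tree_data["nnode"]);
  td.root = td.n;  // ape numbering: root = first non-tip node
  // edge adjacency (parent edge + child edges) for the local slide move
  td.neighbors.assign(td.nedge, {});
  for (int e = 0; e < td.nedge; ++e) {
    int p = td.parent_edge[e];
    if (p >= 0) {
      td.neighbors[e].push_back(p);
      td.neighbors[p].push_back(e);
    }
  }
  return td;
}

} // namespace

// Standalone fast likelihood used for parity checks against the dense
// reference implementation in R.
// [[Rcpp::export]]
double ou_loglik_fast(List tree_data, IntegerVector regime, double alpha,
                      double sigma2, NumericVector theta, NumericVector beta) {
  TreeData td = read_tree_data(tree_data);
  State st;
  st.alpha = alpha; st.sigma2 = sigma2;
  st.theta = as<std::vector<double>>(theta);
  st.beta = as<std::vector<double>>(beta);
  st.regime = as<std::vector<int>>(regime);
  st.shift_edges.assign(st.theta.size() - 1, 0); // only k() matters here
  Scratch sc; sc.init(td.nnode);
  refresh_all(td, st, sc, false);
  return st.loglik;
}

// [[Rcpp::export]]
List rjmcmc_chain(List tree_data, List prior, List control) {
  RNGScope scope;
  TreeData td = read_tree_data(tree_data);

  Priors pr;
  pr.alpha_scale = as<double>(prior["alpha_scale"]);
  pr.sigma_scale = as<double>(prior["sigma_scale"]);
  pr.pois_mean = as<double>(prior["pois_mean"]);
  pr.max_shifts = as<int>(prior["max_shifts"]);
  pr.n_branch = as<int>(prior["n_branch"]);
  pr.theta_mean = as<double>(prior["theta_mean"]);
  pr.theta_sd = as<double>(prior["theta_sd"]);
  pr.beta_mean = as<double>(prior["beta_mean"]);
  pr.beta_sd = as<double>(prior["beta_sd"]);
  double pois_lognorm = 0.0;
  {
    double s = 0.0;
    for (int k = 0; k <= pr.max_shifts; ++k) s += R::dpois(k, pr.pois_mean, 0);
    pois_lognorm = std::log(s);
  }

  const int n_iter = as<int>(control["n_iter"]);
  const int thin = as<int>(control["thin"]);
  const bool prior_only = as<bool>(control["prior_only"]);
  const int adapt_until = as<int>(control["adapt_until"]);
  double step_alpha = as<double>(control["step_alpha"]);
  double step_sigma = as<double>(control["step_sigma"]);
  double step_theta = as<double>(control["step_theta"]);
  double step_beta = as<double>(control["step_beta"]);

  Scratch sc; sc.init(td.nnode);
  State st;
  st.alpha = as<double>(control["init_alpha"]);
  st.sigma2 = as<double>(control["init_sigma2"]);
  st.theta.push_back(as<double>(control["init_theta"]));
  st.beta.push_back(as<double>(control["init_beta"]));
  st.shift_of.assign(td.nedge, 0);
  st.regime.assign(td.nedge, 0);
  repaint(td, st.shift_of, st.regime);
  refresh_all(td, st, sc, prior_only);
  st.logprior = log_prior_state(st, pr, pois_lognorm);
  if (!prior_only && !R_finite(st.loglik)) {
    stop("initial likelihood not finite (check branch lengths)");
  }

  const int n_samp = n_iter / thin;
  NumericMatrix trace(n_samp, 7);
  colnames(trace) = CharacterVector::create("alpha", "sigma2", "k", "loglik",
                                            "logprior", "theta_root", "beta_root");
  IntegerMatrix shift_edge_out(n_samp, pr.max_shifts);
  NumericMatrix shift_theta_out(n_samp, pr.max_shifts);
  NumericMatrix shift_beta_out(n_samp, pr.max_shifts);
  std::fill(shift_edge_out.begin(), shift_edge_out.end(), NA_INTEGER);
  std::fill(shift_theta_out.begin(), shift_theta_out.end(), NA_REAL);
  std::fill(shift_beta_out.begin(), shift_beta_out.end(), NA_REAL);

  const int n_moves = 8;
  std::vector<int> prop_count(n_moves, 0), acc_count(n_moves, 0);
  std::vector<int> win_prop(n_moves, 0), win_acc(n_moves, 0);
  int samp = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    int move = (int)std::floor(unif_rand() * n_moves);
    if (move >= n_moves) move = n_moves - 1;
    ++prop_count[move]; ++win_prop[move];
    bool accepted = false;

    if (move == 0) { // alpha log random walk
      double alpha_new = st.alpha * std::exp(step_alpha * norm_rand());
      State cand = st;
      cand.alpha = alpha_new;
      refresh_all(td, cand, sc, prior_only);
      cand.logprior = log_prior_state(cand, pr, pois_lognorm);
      double log_a = cand.loglik + cand.logprior - st.loglik - st.logprior +
                     std::log(alpha_new / st.alpha); // Jacobian of log-walk
      if (R_finite(cand.loglik) && std::log(unif_rand()) < log_a) {
        st = std::move(cand);
        accepted = true;
      }
    } else if (move == 1) { // sigma2 log random walk
      double s_new = st.sigma2 * std::exp(step_sigma * norm_rand());
      double ll_new = prior_only ? 0.0
          : ou_prune_loglik(td, st.mu, st.alpha, s_new,
                            sc.v, sc.d, sc.v1, sc.b1, sc.seen);
      State tmp = st; tmp.sigma2 = s_new;
      double lp_new = log_prior_state(tmp, pr, pois_lognorm);
      double log_a = ll_new + lp_new - st.loglik - st.logprior +
                     std::log(s_new / st.sigma2);
      if (std::log(unif_rand()) < log_a) {
        st.sigma2 = s_new; st.loglik = ll_new; st.logprior = lp_new;
        accepted = true;
      }
    } else if (move == 2 || move == 3) { // theta / beta random walk
      int j = (int)std::floor(unif_rand() * (st.k() + 1));
      if (j > st.k()) j = st.k();
      State cand = st;
      if (move == 2) cand.theta[j] += step_theta * norm_rand();
      else cand.beta[j] += step_beta * norm_rand();
      if (prior_only) { cand.loglik = 0.0; }
      else {
        refresh_mean(td, cand);
        cand.loglik = ou_prune_loglik(td, cand.mu, cand.alpha, cand.sigma2,
                                      sc.v, sc.d, sc.v1, sc.b1, sc.seen);
      }
      cand.logprior = log_prior_state(cand, pr, pois_lognorm);
      double log_a = cand.loglik + cand.logprior - st.loglik - st.logprior;
      if (std::log(unif_rand()) < log_a) { st = std::move(cand); accepted = true; }
    } else if (move == 4) { // birth
      int k = st.k();
      int nfree = td.nedge - k;
      if (k < pr.max_shifts && nfree > 0) {
        int pick = (int)std::floor(unif_rand() * nfree);
        int edge = -1;
        for (int e = 0, seen_free = 0; e < td.nedge; ++e) {
          if (st.shift_of[e] == 0 && seen_free++ == pick) { edge = e; break; }
        }
        double theta_new = R::rnorm(pr.theta_mean, pr.theta_sd);
        double beta_new = R::rnorm(pr.beta_mean, pr.beta_sd);
        State cand = st;
        cand.shift_edges.push_back(edge);
        cand.shift_of[edge] = cand.k();
        cand.theta.push_back(theta_new);
        cand.beta.push_back(beta_new);
        repaint(td, cand.shift_of, cand.regime);
        refresh_all(td, cand, sc, prior_only);
        // prior-draw proposal for (theta, beta) and the location/selection
        // terms cancel; what remains is the Poisson pmf ratio
        double log_a = cand.loglik - st.loglik +
                       std::log(pr.pois_mean) - std::log((double)k + 1.0);
        if (std::log(unif_rand()) < log_a) {
          st = std::move(cand);
          st.logprior = log_prior_state(st, pr, pois_lognorm);
          accepted = true;
        }
      }
    } else if (move == 5) { // death
      int k = st.k();
      if (k > 0) {
        int j = (int)std::floor(unif_rand() * k);
        if (j >= k) j = k - 1;
        State cand = st;
        cand.shift_edges.erase(cand.shift_edges.begin() + j);
        cand.theta.erase(cand.theta.begin() + j + 1);
        cand.beta.erase(cand.beta.begin() + j + 1);
        std::fill(cand.shift_of.begin(), cand.shift_of.end(), 0);
        for (int m = 0; m < cand.k(); ++m) cand.shift_of[cand.shift_edges[m]] = m + 1;
        repaint(td, cand.shift_of, cand.regime);
        refresh_all(td, cand, sc, prior_only);
        double log_a = cand.loglik - st.loglik +
                       std::log((double)k) - std::log(pr.pois_mean);
        if (std::log(unif_rand()) < log_a) {
          st = std::move(cand);
          st.logprior = log_prior_state(st, pr, pois_lognorm);
          accepted = true;
        }
      }
    } else if (move == 6) { // relocate a shift to a free branch (symmetric)
      int k = st.k();
      int nfree = td.nedge - k;
      if (k > 0 && nfree > 0) {
        int j = (int)std::floor(unif_rand() * k);
        if (j >= k) j = k - 1;
        int pick = (int)std::floor(unif_rand() * nfree);
        int edge = -1;
        for (int e = 0, seen_free = 0; e < td.nedge; ++e) {
          if (st.shift_of[e] == 0 && seen_free++ == pick) { edge = e; break; }
        }
        State cand = st;
        cand.shift_of[cand.shift_edges[j]] = 0;
        cand.shift_edges[j] = edge;
        cand.shift_of[edge] = j + 1;
        repaint(td, cand.shift_of, cand.regime);
        refresh_all(td, cand, sc, prior_only);
        double log_a = cand.loglik - st.loglik;
        if (std::log(unif_rand()) < log_a) {
          st = std::move(cand);
          st.logprior = log_prior_state(st, pr, pois_lognorm);
          accepted = true;
        }
      }
    } else { // slide a shift to an adjacent free branch (local refinement)
      int k = st.k();
      if (k > 0) {
        int j = (int)std::floor(unif_rand() * k);
        if (j >= k) j = k - 1;
        int cur = st.shift_edges[j];
        std::vector<int> free_nb;
        for (int nb : td.neighbors[cur]) {
          if (st.shift_of[nb] == 0) free_nb.push_back(nb);
        }
        if (!free_nb.empty()) {
          int pick = (int)std::floor(unif_rand() * free_nb.size());
          if (pick >= (int)free_nb.size()) pick = (int)free_nb.size() - 1;
          int edge = free_nb[pick];
          State cand = st;
          cand.shift_of[cur] = 0;
          cand.shift_edges[j] = edge;
          cand.shift_of[edge] = j + 1;
          repaint(td, cand.shift_of, cand.regime);
          refresh_all(td, cand, sc, prior_only);
          // Hastings correction for unequal neighbour counts
          int rev_nb = 0;
          for (int nb : td.neighbors[edge]) {
            if (cand.shift_of[nb] == 0) ++rev_nb;
          }
          double log_a = cand.loglik - st.loglik +
                         std::log((double)free_nb.size()) -
                         std::log((double)rev_nb);
          if (rev_nb > 0 && std::log(unif_rand()) < log_a) {
            st = std::move(cand);
            st.logprior = log_prior_state(st, pr, pois_lognorm);
            accepted = true;
          }
        }
      }
    }

    if (accepted) { ++acc_count[move]; ++win_acc[move]; }

    // step-size adaptation during burn-in only (frozen afterwards so the
    // post-burn-in kernel satisfies detailed balance)
    if (iter <= adapt_until && iter % 50 == 0) {
      auto tune = [](double s, int acc, int prop) {
        if (prop == 0) return s;
        double rate = (double)acc / prop;
        double out = s * std::exp(0.5 * (rate - 0.3));
        return std::min(std::max(out, 1e-4), 10.0);
      };
      step_alpha = tune(step_alpha, win_acc[0], win_prop[0]);
      step_sigma = tune(step_sigma, win_acc[1], win_prop[1]);
      step_theta = tune(step_theta, win_acc[2], win_prop[2]);
      step_beta = tune(step_beta, win_acc[3], win_prop[3]);
      std::fill(win_prop.begin(), win_prop.end(), 0);
      std::fill(win_acc.begin(), win_acc.end(), 0);
    }

    if (iter % thin == 0) {
      trace(samp, 0) = st.alpha;
      trace(samp, 1) = st.sigma2;
      trace(samp, 2) = st.k();
      trace(samp, 3) = st.loglik;
      trace(samp, 4) = st.logprior;
      trace(samp, 5) = st.theta[0];
      trace(samp, 6) = st.beta[0];
      for (int m = 0; m < st.k(); ++m) {
        shift_edge_out(samp, m) = st.shift_edges[m];
        shift_theta_out(samp, m) = st.theta[m + 1];
        shift_beta_out(samp, m) = st.beta[m + 1];
      }
      ++samp;
    }
    if (iter % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector acc_rate(n_moves);
  for (int m = 0; m < n_moves; ++m) {
    acc_rate[m] = prop_count[m] ? (double)acc_count[m] / prop_count[m] : NA_REAL;
  }
  acc_rate.names() = CharacterVector::create(
      "alpha", "sigma2", "theta", "beta", "birth", "death", "relocate",
      "slide");
  return List::create(_["trace"] = trace,
                      _["shift_edges"] = shift_edge_out,
                      _["shift_theta"] = shift_theta_out,
                      _["shift_beta"] = shift_beta_out,
                      _["acceptance"] = acc_rate,
                      _["steps"] = NumericVector::create(
                          _["alpha"] = step_alpha, _["sigma"] = step_sigma,
                          _["theta"] = step_theta, _["beta"] = step_beta));
}
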