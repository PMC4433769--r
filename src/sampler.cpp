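// Adaptive Metropolis-within-Gibbs sampler for the mapping-ratio
// meta-analysis models.  One scalar random-walk block per parameter:
// mu, log(sigma), each basic mapping ratio, log(phi), each per-arm
// random effect delta, and (random-mapping variant) each trial-specific
// ratio.  Step sizes adapt toward a target acceptance rate during
// burn-in only, so the post-burn-in chain is a valid MH chain.
//
// Uses R's RNG throughout: runs are reproducible from set.seed() on the
// R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Model {
  arma::vec y;
  std::vector<arma::mat> Vinv;           // per trial
  std::vector<arma::uvec> trial_obs;     // obs indices per trial (0-based)
  arma::ivec obs_trial, obs_delta, obs_inst, obs_bt, delta_trial,
      bt_inst, bt_trial;
  std::vector<arma::ivec> beta_trials;   // per non-ref instrument: trials
  std::vector<arma::ivec> beta_bts;      // per non-ref instrument: bt ids
  int M, D, B, variant;                  // 0 fixed, 1 random, 2 ratios_one
  double mu_sd, beta_sd, sigma_upper, phi_upper;
  bool sigma_prior_var;                  // uniform prior on sigma^2?
  bool ratio_log;                        // trial ratios lognormal about beta?

  int nb() const { return variant == 2 ? 0 : M - 1; }
  bool has_phi() const { return variant == 1; }
  int i_mu() const { return 0; }
  int i_ls() const { return 1; }
  int i_beta0() const { return 2; }
  int i_lphi() const { return 2 + nb(); }
  int i_delta0() const { return 2 + nb() + (has_phi() ? 1 : 0); }
  int i_bt0() const { return i_delta0() + D; }
  int npar() const { return i_bt0() + B; }
};

const double BT_SD_FLOOR = 1e-12;  // guard for phi*|beta| -> 0

class Sampler {
 public:
  Sampler(const Model& m, arma::vec init) : m_(m), x_(init) {
    theta_.set_size(m_.y.n_elem);
    q_.set_size(m_.Vinv.size());
    refresh_all();
  }

  // mapping factor for one observation under the current state
  double map_factor(int j) const {
    int k = m_.obs_inst[j];
    if (k == 0 || m_.variant == 2) return 1.0;
    if (m_.variant == 0) return x_[m_.i_beta0() + (k - 1)];
    return x_[m_.i_bt0() + m_.obs_bt[j]];
  }

  void refresh_theta(int j) { theta_[j] = map_factor(j) * x_[m_.i_delta0() + m_.obs_delta[j]]; }

  double trial_quad(int t) const {
    const arma::uvec& idx = m_.trial_obs[t];
    arma::vec r(idx.n_elem);
    for (arma::uword a = 0; a < idx.n_elem; ++a)
      r[a] = m_.y[idx[a]] - theta_[idx[a]];
    return arma::as_scalar(r.t() * m_.Vinv[t] * r);
  }

  void refresh_all() {
    for (arma::uword j = 0; j < theta_.n_elem; ++j) refresh_theta(j);
    for (size_t t = 0; t < m_.Vinv.size(); ++t) q_[t] = trial_quad(t);
  }

  double total_dev() const { return arma::accu(q_); }

  // --- conditional log targets (terms depending on the block only) ---

  double lp_mu(double mu) const {
    double sigma = std::exp(x_[m_.i_ls()]);
    double s = 0.0;
    for (int d = 0; d < m_.D; ++d) {
      double z = x_[m_.i_delta0() + d] - mu;
      s -= 0.5 * z * z / (sigma * sigma);
    }
    return s - 0.5 * mu * mu / (m_.mu_sd * m_.mu_sd);
  }

  double lp_lsigma(double ls) const {
    double sigma = std::exp(ls);
    if (sigma >= m_.sigma_upper) return -arma::datum::inf;
    double mu = x_[m_.i_mu()], s = 0.0;
    for (int d = 0; d < m_.D; ++d) {
      double z = x_[m_.i_delta0() + d] - mu;
      s += -std::log(sigma) - 0.5 * z * z / (sigma * sigma);
    }
    if (m_.sigma_prior_var) s += ls;  // density prop. to sigma
    return s + ls;  // log-Jacobian of the log transform
  }

  // hierarchical term of all trial ratios for instrument k (0-based).
  // Natural scale: bt ~ N(beta, (phi*|beta|)^2); log scale: bt
  // lognormal with log-SD phi about log(beta) (CV ~ phi for small phi).
  double lp_bt_hier_k(int k, double beta_k, double phi) const {
    double s = 0.0;
    const arma::ivec& ids = m_.beta_bts[k];
    if (m_.ratio_log) {
      if (beta_k <= 0) return -arma::datum::inf;
      double sd = std::max(phi, BT_SD_FLOOR);
      for (arma::uword a = 0; a < ids.n_elem; ++a) {
        double bt = x_[m_.i_bt0() + ids[a]];
        if (bt <= 0) return -arma::datum::inf;
        double z = std::log(bt) - std::log(beta_k);
        s += -std::log(bt) - std::log(sd) - 0.5 * z * z / (sd * sd);
      }
      return s;
    }
    double sd = std::max(phi * std::fabs(beta_k), BT_SD_FLOOR);
    for (arma::uword a = 0; a < ids.n_elem; ++a) {
      double z = x_[m_.i_bt0() + ids[a]] - beta_k;
      s += -std::log(sd) - 0.5 * z * z / (sd * sd);
    }
    return s;
  }

  double lp_lphi(double lphi) const {
    double phi = std::exp(lphi);
    if (phi >= m_.phi_upper) return -arma::datum::inf;
    double s = 0.0;
    for (int k = 0; k < m_.nb(); ++k)
      s += lp_bt_hier_k(k, x_[m_.i_beta0() + k], phi);
    return s + lphi;
  }

  // --- block updates ---

  bool update_mu(double step) {
    double cur = x_[m_.i_mu()], prop = cur + step * R::norm_rand();
    double dlp = lp_mu(prop) - lp_mu(cur);
    if (accept(dlp)) { x_[m_.i_mu()] = prop; return true; }
    return false;
  }

  bool update_lsigma(double step) {
    double cur = x_[m_.i_ls()], prop = cur + step * R::norm_rand();
    double dlp = lp_lsigma(prop) - lp_lsigma(cur);
    if (accept(dlp)) { x_[m_.i_ls()] = prop; return true; }
    return false;
  }

  bool update_beta(int k, double step) {
    int ix = m_.i_beta0() + k;
    double cur = x_[ix], prop = cur + step * R::norm_rand();
    double prior = (-0.5 * prop * prop + 0.5 * cur * cur) /
                   (m_.beta_sd * m_.beta_sd);
    if (m_.variant == 1) {
      double phi = std::exp(x_[m_.i_lphi()]);
      double dlp = prior + lp_bt_hier_k(k, prop, phi) - lp_bt_hier_k(k, cur, phi);
      if (accept(dlp)) { x_[ix] = prop; return true; }
      return false;
    }
    // fixed mapping: likelihood of trials reporting instrument k changes
    x_[ix] = prop;
    const arma::ivec& trials = m_.beta_trials[k];
    double dlp = prior;
    std::vector<double> qnew(trials.n_elem);
    for (arma::uword a = 0; a < trials.n_elem; ++a) {
      int t = trials[a];
      const arma::uvec& idx = m_.trial_obs[t];
      for (arma::uword b = 0; b < idx.n_elem; ++b) refresh_theta(idx[b]);
      qnew[a] = trial_quad(t);
      dlp += -0.5 * (qnew[a] - q_[t]);
    }
    if (accept(dlp)) {
      for (arma::uword a = 0; a < trials.n_elem; ++a) q_[trials[a]] = qnew[a];
      return true;
    }
    x_[ix] = cur;
    for (arma::uword a = 0; a < trials.n_elem; ++a) {
      const arma::uvec& idx = m_.trial_obs[trials[a]];
      for (arma::uword b = 0; b < idx.n_elem; ++b) refresh_theta(idx[b]);
    }
    return false;
  }

  bool update_lphi(double step) {
    double cur = x_[m_.i_lphi()], prop = cur + step * R::norm_rand();
    double dlp = lp_lphi(prop) - lp_lphi(cur);
    if (accept(dlp)) { x_[m_.i_lphi()] = prop; return true; }
    return false;
  }

  bool update_delta(int d, double step) {
    int ix = m_.i_delta0() + d, t = m_.delta_trial[d];
    double mu = x_[m_.i_mu()], sigma = std::exp(x_[m_.i_ls()]);
    double cur = x_[ix], prop = cur + step * R::norm_rand();
    double prior = (-0.5 * (prop - mu) * (prop - mu) +
                    0.5 * (cur - mu) * (cur - mu)) / (sigma * sigma);
    x_[ix] = prop;
    const arma::uvec& idx = m_.trial_obs[t];
    for (arma::uword b = 0; b < idx.n_elem; ++b)
      if (m_.obs_delta[idx[b]] == d) refresh_theta(idx[b]);
    double qnew = trial_quad(t);
    if (accept(prior - 0.5 * (qnew - q_[t]))) { q_[t] = qnew; return true; }
    x_[ix] = cur;
    for (arma::uword b = 0; b < idx.n_elem; ++b)
      if (m_.obs_delta[idx[b]] == d) refresh_theta(idx[b]);
    return false;
  }

  // log density of one trial ratio given its mean ratio and phi
  double lp_bt_single(double bt, double beta_k, double phi) const {
    if (m_.ratio_log) {
      if (bt <= 0 || beta_k <= 0) return -arma::datum::inf;
      double sd = std::max(phi, BT_SD_FLOOR);
      double z = std::log(bt) - std::log(beta_k);
      return -std::log(bt) - std::log(sd) - 0.5 * z * z / (sd * sd);
    }
    double sd = std::max(phi * std::fabs(beta_k), BT_SD_FLOOR);
    double z = bt - beta_k;
    return -std::log(sd) - 0.5 * z * z / (sd * sd);
  }

  bool update_bt(int b, double step) {
    int ix = m_.i_bt0() + b, t = m_.bt_trial[b], k = m_.bt_inst[b];
    double beta_k = x_[m_.i_beta0() + k];
    double phi = std::exp(x_[m_.i_lphi()]);
    double cur = x_[ix], prop = cur + step * R::norm_rand();
    double prior = lp_bt_single(prop, beta_k, phi) -
                   lp_bt_single(cur, beta_k, phi);
    x_[ix] = prop;
    const arma::uvec& idx = m_.trial_obs[t];
    for (arma::uword a = 0; a < idx.n_elem; ++a)
      if (m_.obs_bt[idx[a]] == b) refresh_theta(idx[a]);
    double qnew = trial_quad(t);
    if (accept(prior - 0.5 * (qnew - q_[t]))) { q_[t] = qnew; return true; }
    x_[ix] = cur;
    for (arma::uword a = 0; a < idx.n_elem; ++a)
      if (m_.obs_bt[idx[a]] == b) refresh_theta(idx[a]);
    return false;
  }

  // Joint translation of a mean ratio and all its trial ratios
  // (random-mapping variant).  Single-site updates mix slowly when phi
  // is small because every trial ratio is tethered to its mean; moving
  // them together leaves the hierarchical residuals unchanged and
  // restores good mixing along the ridge.  Natural scale shifts
  // additively; log scale multiplicatively (with Jacobian).
  bool update_beta_joint(int k, double step) {
    int ixb = m_.i_beta0() + k;
    const arma::ivec& ids = m_.beta_bts[k];
    const arma::ivec& trials = m_.beta_trials[k];
    double s = step * R::norm_rand();
    double phi = std::exp(x_[m_.i_lphi()]);
    double cur_b = x_[ixb];
    arma::vec cur_bt(ids.n_elem);
    for (arma::uword a = 0; a < ids.n_elem; ++a)
      cur_bt[a] = x_[m_.i_bt0() + ids[a]];

    double prop_b;
    arma::vec prop_bt(ids.n_elem);
    double jac = 0.0;
    if (m_.ratio_log) {
      double f = std::exp(s);
      prop_b = cur_b * f;
      prop_bt = cur_bt * f;
      jac = (1.0 + (double)ids.n_elem) * s;
    } else {
      prop_b = cur_b + s;
      prop_bt = cur_bt + s;
    }

    double dlp = jac +
        (-0.5 * prop_b * prop_b + 0.5 * cur_b * cur_b) /
            (m_.beta_sd * m_.beta_sd);
    for (arma::uword a = 0; a < ids.n_elem; ++a) {
      dlp += lp_bt_single(prop_bt[a], prop_b, phi) -
             lp_bt_single(cur_bt[a], cur_b, phi);
    }
    if (!std::isfinite(dlp)) return false;

    x_[ixb] = prop_b;
    for (arma::uword a = 0; a < ids.n_elem; ++a)
      x_[m_.i_bt0() + ids[a]] = prop_bt[a];
    std::vector<double> qnew(trials.n_elem);
    for (arma::uword a = 0; a < trials.n_elem; ++a) {
      int t = trials[a];
      const arma::uvec& idx = m_.trial_obs[t];
      for (arma::uword b = 0; b < idx.n_elem; ++b) refresh_theta(idx[b]);
      qnew[a] = trial_quad(t);
      dlp += -0.5 * (qnew[a] - q_[t]);
    }
    if (accept(dlp)) {
      for (arma::uword a = 0; a < trials.n_elem; ++a) q_[trials[a]] = qnew[a];
      return true;
    }
    x_[ixb] = cur_b;
    for (arma::uword a = 0; a < ids.n_elem; ++a)
      x_[m_.i_bt0() + ids[a]] = cur_bt[a];
    for (arma::uword a = 0; a < trials.n_elem; ++a) {
      const arma::uvec& idx = m_.trial_obs[trials[a]];
      for (arma::uword b = 0; b < idx.n_elem; ++b) refresh_theta(idx[b]);
    }
    return false;
  }

  static bool accept(double dlp) {
    if (dlp >= 0) return true;
    if (!std::isfinite(dlp)) return false;
    return std::log(R::unif_rand()) < dlp;
  }

  const arma::vec& state() const { return x_; }

 private:
  const Model& m_;
  arma::vec x_;      // internal scale: sigma, phi as logs
  arma::vec theta_;  // current expected observations
  arma::vec q_;      // current per-trial quadratic forms
};

}  // namespace

// [[Rcpp::export(name = ".mwg_chain")]]
List mwg_chain(List model, NumericVector init, List cfg) {
  Model m;
  m.y = as<arma::vec>(model["y"]);
  List vinv = model["Vinv"];
  List tobs = model["trial_obs"];
  for (int t = 0; t < vinv.size(); ++t) {
    m.Vinv.push_back(as<arma::mat>(vinv[t]));
    m.trial_obs.push_back(as<arma::uvec>(tobs[t]));
  }
  m.obs_trial = as<arma::ivec>(model["obs_trial"]);
  m.obs_delta = as<arma::ivec>(model["obs_delta"]);
  m.obs_inst = as<arma::ivec>(model["obs_inst"]);
  m.obs_bt = as<arma::ivec>(model["obs_bt"]);
  m.delta_trial = as<arma::ivec>(model["delta_trial"]);
  m.bt_inst = as<arma::ivec>(model["bt_inst"]);
  m.bt_trial = as<arma::ivec>(model["bt_trial"]);
  List btr = model["beta_trials"], bbt = model["beta_bts"];
  for (int k = 0; k < btr.size(); ++k) {
    m.beta_trials.push_back(as<arma::ivec>(btr[k]));
    m.beta_bts.push_back(as<arma::ivec>(bbt[k]));
  }
  m.M = as<int>(model["M"]);
  m.D = as<int>(model["D"]);
  m.B = as<int>(model["B"]);
  m.variant = as<int>(model["variant"]);
  m.mu_sd = as<double>(model["mu_sd"]);
  m.beta_sd = as<double>(model["beta_sd"]);
  m.sigma_upper = as<double>(model["sigma_upper"]);
  m.phi_upper = as<double>(model["phi_upper"]);
  m.sigma_prior_var = as<bool>(model["sigma_prior_var"]);
  m.ratio_log = as<bool>(model["ratio_log"]);

  const int n_burn = as<int>(cfg["n_burn"]);
  const int n_keep = as<int>(cfg["n_keep"]);
  const int thin = as<int>(cfg["thin"]);
  const int adapt_interval = as<int>(cfg["adapt_interval"]);
  const double target = as<double>(cfg["target_accept"]);

  const int P = m.npar();
  if (init.size() != P) stop("init has wrong length");
  Sampler s(m, as<arma::vec>(init));

  // block table: 0 mu, 1 lsigma, betas, (lphi), deltas, bts
  // one block per parameter, plus the joint (beta, trial ratios)
  // translation blocks in the random-mapping variant
  const int n_joint = (m.variant == 1) ? m.nb() : 0;
  const int n_blocks = P + n_joint;
  arma::vec step0 = as<arma::vec>(model["step_init"]);
  if ((int)step0.n_elem != n_blocks) stop("step_init has wrong length");
  arma::vec lstep = arma::log(step0);
  arma::ivec acc(n_blocks, arma::fill::zeros), att(n_blocks, arma::fill::zeros);
  arma::vec acc_total(n_blocks, arma::fill::zeros);
  arma::vec att_total(n_blocks, arma::fill::zeros);

  const int n_iter = n_burn + n_keep * thin;
  arma::mat draws(n_keep, P);
  arma::vec resdev(n_keep);
  int kept = 0, batch = 0;

  for (int it = 0; it < n_iter; ++it) {
    bool burn = it < n_burn;
    int b = 0;
    auto tally = [&](int blk, bool a) {
      ++att[blk];
      if (a) ++acc[blk];
      if (!burn) { ++att_total[blk]; if (a) ++acc_total[blk]; }
    };
    tally(b, s.update_mu(std::exp(lstep[b]))); ++b;
    tally(b, s.update_lsigma(std::exp(lstep[b]))); ++b;
    for (int k = 0; k < m.nb(); ++k) {
      tally(b, s.update_beta(k, std::exp(lstep[b]))); ++b;
    }
    if (m.has_phi()) { tally(b, s.update_lphi(std::exp(lstep[b]))); ++b; }
    for (int d = 0; d < m.D; ++d) {
      tally(b, s.update_delta(d, std::exp(lstep[b]))); ++b;
    }
    for (int bt = 0; bt < m.B; ++bt) {
      tally(b, s.update_bt(bt, std::exp(lstep[b]))); ++b;
    }
    for (int k = 0; k < n_joint; ++k) {
      tally(b, s.update_beta_joint(k, std::exp(lstep[b]))); ++b;
    }

    if (burn && (it + 1) % adapt_interval == 0) {
      ++batch;
      double gain = std::min(0.05, 1.0 / std::sqrt((double)batch));
      for (int blk = 0; blk < n_blocks; ++blk) {
        if (att[blk] > 0) {
          double rate = (double)acc[blk] / att[blk];
          lstep[blk] += (rate > target ? gain : -gain);
        }
        acc[blk] = att[blk] = 0;
      }
    }
    if (it == n_burn - 1) { acc.zeros(); att.zeros(); }

    if (!burn && ((it - n_burn + 1) % thin == 0)) {
      arma::vec st = s.state();
      st[m.i_ls()] = std::exp(st[m.i_ls()]);
      if (m.has_phi()) st[m.i_lphi()] = std::exp(st[m.i_lphi()]);
      draws.row(kept) = st.t();
      resdev[kept] = s.total_dev();
      ++kept;
    }
  }

  arma::vec rates(n_blocks);
  for (int blk = 0; blk < n_blocks; ++blk) {
    rates[blk] = att_total[blk] > 0 ? acc_total[blk] / att_total[blk]
                                    : arma::datum::nan;
  }
  return List::create(_["draws"] = draws,
                      _["resdev"] = resdev,
                      _["accept_rate"] = rates,
                      _["log_step"] = lstep);
}
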