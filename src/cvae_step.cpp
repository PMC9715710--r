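// Hot path of the training loop: joint forward/backward pass of the coupled
// VAE plus the entropic unbalanced transport solve on the minibatch.
// Mirrors the reference implementation in R/model.R (cvae_step); the R
// version is kept as the slow oracle and the two are compared in the tests.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static const double BN_EPS = 1e-5;
static const double LOGVAR_CLAMP = 10.0;

// entropic unbalanced OT by multiplicative scaling; recenter = IPOT-style
// proximal kernel re-centering. Matches R's solve_uot().
static arma::mat solve_uot_core(const arma::mat& C,
                                const arma::vec& a, const arma::vec& b,
                                double eps, double rho,
                                int outer_iters, int inner_iters,
                                double tol, bool recenter,
                                const arma::mat* plan_init) {
  const arma::uword bx = C.n_rows;
  arma::mat K = arma::exp(-C / eps);
  K.transform([](double v) { return v < 1e-300 ? 1e-300 : v; });
  const double f = rho / (rho + eps);
  arma::mat Tm = plan_init ? *plan_init : (a * b.t());
  arma::vec beta(C.n_cols, arma::fill::value(1.0 / bx));
  arma::vec alpha(C.n_rows, arma::fill::ones);
  auto clamp_div = [](arma::vec v) {
    v.transform([](double x) { return x < 1e-280 ? 1e-280 : x; });
    return v;
  };
  if (recenter) {
    for (int l = 0; l < outer_iters; ++l) {
      arma::mat G = Tm % K;
      G.transform([](double v) { return v < 1e-300 ? 1e-300 : v; });
      for (int i = 0; i < inner_iters; ++i) {
        alpha = arma::pow(a / clamp_div(G * beta), f);
        beta = arma::pow(b / clamp_div(G.t() * alpha), f);
      }
      arma::mat Tn = G;
      Tn.each_col() %= alpha;
      Tn.each_row() %= beta.t();
      double rel2 = arma::accu(arma::square(Tn - Tm)) /
        std::max(arma::accu(arma::square(Tm)), 1e-300);
      Tm = Tn;
      if (rel2 < tol * tol) break;
    }
  } else {
    const int max_sweeps = outer_iters * inner_iters;
    arma::vec beta_chk = beta;
    int l = 0;
    while (l < max_sweeps) {
      int todo = std::min(10, max_sweeps - l);
      for (int i = 0; i < todo; ++i, ++l) {
        alpha = arma::pow(a / clamp_div(K * beta), f);
        beta = arma::pow(b / clamp_div(K.t() * alpha), f);
      }
      double rel = arma::abs(beta / beta_chk - 1.0).max();
      beta_chk = beta;
      if (rel < tol) break;
    }
    Tm = K;
    Tm.each_col() %= alpha;
    Tm.each_row() %= beta.t();
  }
  if (!Tm.is_finite()) stop("non-finite transport plan (cost/epsilon too large)");
  return Tm;
}

// [[Rcpp::export(name = ".solve_uot_cpp")]]
arma::mat solve_uot_cpp(const arma::mat& C, const arma::vec& a,
                        const arma::vec& b, double eps, double rho,
                        int outer_iters, int inner_iters, double tol,
                        bool recenter, Nullable<NumericMatrix> plan_init) {
  if (plan_init.isNotNull()) {
    arma::mat pi = as<arma::mat>(plan_init.get());
    return solve_uot_core(C, a, b, eps, rho, outer_iters, inner_iters, tol,
                          recenter, &pi);
  }
  return solve_uot_core(C, a, b, eps, rho, outer_iters, inner_iters, tol,
                        recenter, nullptr);
}

struct EncFwd {
  arma::mat h1, h2, mu, lv, sigma;
  arma::umat clamp_mask;
};

static EncFwd encode_fwd_cpp(const List& par, const arma::mat& x) {
  EncFwd e;
  arma::mat W1 = par["enc_W1"], W2 = par["enc_W2"],
    Wmu = par["enc_Wmu"], Wlv = par["enc_Wlv"];
  arma::rowvec b1 = as<arma::rowvec>(par["enc_b1"]),
    b2 = as<arma::rowvec>(par["enc_b2"]),
    bmu = as<arma::rowvec>(par["enc_bmu"]),
    blv = as<arma::rowvec>(par["enc_blv"]);
  e.h1 = x * W1; e.h1.each_row() += b1;
  e.h1.transform([](double v) { return v > 0 ? v : 0.0; });
  e.h2 = e.h1 * W2; e.h2.each_row() += b2;
  e.h2.transform([](double v) { return v > 0 ? v : 0.0; });
  e.mu = e.h2 * Wmu; e.mu.each_row() += bmu;
  arma::mat lv_raw = e.h2 * Wlv; lv_raw.each_row() += blv;
  e.clamp_mask = (lv_raw > -LOGVAR_CLAMP) % (lv_raw < LOGVAR_CLAMP);
  e.lv = arma::clamp(lv_raw, -LOGVAR_CLAMP, LOGVAR_CLAMP);
  e.sigma = arma::exp(0.5 * e.lv);
  return e;
}

static double bce_sum(const arma::mat& target, const arma::mat& p) {
  arma::mat pc = arma::clamp(p, 1e-12, 1.0 - 1e-12);
  return -arma::accu(target % arma::log(pc) +
                     (1.0 - target) % arma::log1p(-pc));
}

static arma::mat sqdist_cpp(const arma::mat& A, const arma::mat& B) {
  arma::mat d = arma::repmat(arma::sum(arma::square(A), 1), 1, B.n_rows) +
    arma::repmat(arma::sum(arma::square(B), 1).t(), A.n_rows, 1) -
    2.0 * A * B.t();
  d.transform([](double v) { return v > 0 ? v : 0.0; });
  return d;
}

// [[Rcpp::export(name = ".cvae_step_cpp")]]
List cvae_step_cpp(const arma::mat& xc, const arma::mat& xs,
                   const arma::mat& yc, const arma::mat& ys,
                   List par, List bn, CharacterVector ids,
                   double lambda_kl, double lambda_s, double gamma,
                   double uot_epsilon, double uot_rho,
                   int uot_outer, int uot_inner, double uot_tol,
                   bool uot_recenter,
                   Nullable<NumericVector> a_in, Nullable<NumericVector> b_in,
                   const arma::mat& noise_x, const arma::mat& noise_y,
                   Nullable<NumericMatrix> plan_init,
                   bool update_bn, double bn_momentum) {
  const std::string id_x = as<std::string>(ids[0]);
  const std::string id_y = as<std::string>(ids[1]);
  List grads = List::create();
  List bn_out = clone(bn);

  struct Side {
    const arma::mat *c, *s, *noise;
    std::string id;
    EncFwd enc;
    arma::mat z, p, uhat, ps;
    arma::rowvec inv_sd, gma;
    int nB;
  };
  Side S[2];
  S[0] = {&xc, &xs, &noise_x, id_x};
  S[1] = {&yc, &ys, &noise_y, id_y};

  arma::mat decW = par["dec_W"];
  arma::rowvec decb = as<arma::rowvec>(par["dec_b"]);

  // forward
  for (int k = 0; k < 2; ++k) {
    Side& sd = S[k];
    sd.nB = sd.c->n_rows;
    sd.enc = encode_fwd_cpp(par, *sd.c);
    sd.z = sd.enc.mu + sd.enc.sigma % (*sd.noise);
    arma::mat u = sd.z * decW; u.each_row() += decb;
    arma::rowvec m = arma::mean(u, 0);
    arma::rowvec v = arma::mean(arma::square(u), 0) - arma::square(m);
    v.transform([](double x) { return x > 0 ? x : 0.0; });
    sd.gma = as<arma::rowvec>(par[std::string("bn_gamma_") + sd.id]);
    arma::rowvec bta = as<arma::rowvec>(par[std::string("bn_beta_") + sd.id]);
    sd.inv_sd = 1.0 / arma::sqrt(v + BN_EPS);
    sd.uhat = u;
    sd.uhat.each_row() -= m;
    sd.uhat.each_row() %= sd.inv_sd;
    arma::mat act = sd.uhat;
    act.each_row() %= sd.gma;
    act.each_row() += bta;
    sd.p = 1.0 / (1.0 + arma::exp(-act));
    if (update_bn) {
      List br = bn_out[sd.id];
      double unb = sd.nB > 1 ? double(sd.nB) / (sd.nB - 1) : 1.0;
      arma::rowvec rm = as<arma::rowvec>(br["mean"]);
      arma::rowvec rv = as<arma::rowvec>(br["var"]);
      rm = (1 - bn_momentum) * rm + bn_momentum * m;
      rv = (1 - bn_momentum) * rv + bn_momentum * v * unb;
      br["mean"] = NumericVector(rm.begin(), rm.end());
      br["var"] = NumericVector(rv.begin(), rv.end());
      bn_out[sd.id] = br;
    }
    arma::mat Ws = par[std::string("spec_W_") + sd.id];
    arma::rowvec bs = as<arma::rowvec>(par[std::string("spec_b_") + sd.id]);
    arma::mat us = sd.z * Ws; us.each_row() += bs;
    sd.ps = 1.0 / (1.0 + arma::exp(-us));
  }

  // transport plan on the posteriors (detached)
  arma::mat C = sqdist_cpp(S[0].enc.mu, S[1].enc.mu) +
    sqdist_cpp(S[0].enc.sigma, S[1].enc.sigma);
  arma::vec a = a_in.isNotNull() ? as<arma::vec>(a_in.get())
    : arma::vec(C.n_rows, arma::fill::value(1.0 / C.n_rows));
  arma::vec b = b_in.isNotNull() ? as<arma::vec>(b_in.get())
    : arma::vec(C.n_cols, arma::fill::value(1.0 / C.n_cols));
  arma::mat plan;
  if (plan_init.isNotNull()) {
    arma::mat pi = as<arma::mat>(plan_init.get());
    plan = solve_uot_core(C, a, b, uot_epsilon, uot_rho, uot_outer,
                          uot_inner, uot_tol, uot_recenter, &pi);
  } else {
    plan = solve_uot_core(C, a, b, uot_epsilon, uot_rho, uot_outer,
                          uot_inner, uot_tol, uot_recenter, nullptr);
  }
  double loss_uot = arma::accu(C % plan);

  // loss
  double loss_elbo = 0.0;
  for (int k = 0; k < 2; ++k) {
    Side& sd = S[k];
    double kl = 0.5 * arma::accu(arma::square(sd.enc.mu) +
                                 arma::square(sd.enc.sigma) - 1.0 - sd.enc.lv);
    loss_elbo += bce_sum(*sd.c, sd.p) / sd.nB +
      lambda_s * bce_sum(*sd.s, sd.ps) / sd.nB +
      lambda_kl * kl / sd.nB;
  }
  double loss_total = loss_elbo + gamma * loss_uot;

  // backward
  arma::vec rs = arma::sum(plan, 1);
  arma::vec cs = arma::sum(plan, 0).t();
  arma::mat g_encW1(as<arma::mat>(par["enc_W1"]).n_rows,
                    as<arma::mat>(par["enc_W1"]).n_cols, arma::fill::zeros);
  arma::mat W2 = par["enc_W2"], Wmu = par["enc_Wmu"], Wlv = par["enc_Wlv"];
  arma::mat g_encW2(W2.n_rows, W2.n_cols, arma::fill::zeros);
  arma::mat g_Wmu(Wmu.n_rows, Wmu.n_cols, arma::fill::zeros);
  arma::mat g_Wlv(Wlv.n_rows, Wlv.n_cols, arma::fill::zeros);
  arma::rowvec g_b1(g_encW1.n_cols, arma::fill::zeros),
    g_b2(W2.n_cols, arma::fill::zeros),
    g_bmu(Wmu.n_cols, arma::fill::zeros),
    g_blv(Wlv.n_cols, arma::fill::zeros);
  arma::mat g_decW(decW.n_rows, decW.n_cols, arma::fill::zeros);
  arma::rowvec g_decb(decW.n_cols, arma::fill::zeros);

  for (int k = 0; k < 2; ++k) {
    Side& sd = S[k];
    const int nB = sd.nB;

    arma::mat dA = (sd.p - *sd.c) / nB;
    arma::rowvec g_bn_gamma = arma::sum(dA % sd.uhat, 0);
    arma::rowvec g_bn_beta = arma::sum(dA, 0);
    arma::mat duh = dA; duh.each_row() %= sd.gma;
    arma::rowvec s1 = arma::sum(duh, 0) / nB;
    arma::rowvec s2 = arma::sum(duh % sd.uhat, 0) / nB;
    arma::mat dU = duh;
    dU.each_row() -= s1;
    arma::mat uh_s2 = sd.uhat;
    uh_s2.each_row() %= s2;
    dU -= uh_s2;
    dU.each_row() %= sd.inv_sd;
    g_decW += sd.z.t() * dU;
    g_decb += arma::sum(dU, 0);
    arma::mat dz = dU * decW.t();

    arma::mat Ws = par[std::string("spec_W_") + sd.id];
    arma::mat dUs = lambda_s * (sd.ps - *sd.s) / nB;
    arma::mat g_specW = sd.z.t() * dUs;
    arma::rowvec g_specb = arma::sum(dUs, 0);
    dz += dUs * Ws.t();

    arma::mat dmu = dz;
    arma::mat dsig = dz % (*sd.noise);
    dmu += lambda_kl * sd.enc.mu / nB;
    arma::mat dlv_kl = lambda_kl * 0.5 *
      (arma::square(sd.enc.sigma) - 1.0) / nB;

    if (k == 0) {
      dmu += gamma * 2.0 * (sd.enc.mu.each_col() % rs - plan * S[1].enc.mu);
      dsig += gamma * 2.0 *
        (sd.enc.sigma.each_col() % rs - plan * S[1].enc.sigma);
    } else {
      dmu += gamma * 2.0 * (sd.enc.mu.each_col() % cs - plan.t() * S[0].enc.mu);
      dsig += gamma * 2.0 *
        (sd.enc.sigma.each_col() % cs - plan.t() * S[0].enc.sigma);
    }

    arma::mat dlv = (dsig % (0.5 * sd.enc.sigma) + dlv_kl) %
      arma::conv_to<arma::mat>::from(sd.enc.clamp_mask);

    g_Wmu += sd.enc.h2.t() * dmu;
    g_bmu += arma::sum(dmu, 0);
    g_Wlv += sd.enc.h2.t() * dlv;
    g_blv += arma::sum(dlv, 0);
    arma::mat dh2 = (dmu * Wmu.t() + dlv * Wlv.t());
    dh2 %= arma::conv_to<arma::mat>::from(sd.enc.h2 > 0);
    g_encW2 += sd.enc.h1.t() * dh2;
    g_b2 += arma::sum(dh2, 0);
    arma::mat dh1 = dh2 * W2.t();
    dh1 %= arma::conv_to<arma::mat>::from(sd.enc.h1 > 0);
    g_encW1 += sd.c->t() * dh1;
    g_b1 += arma::sum(dh1, 0);

    grads[std::string("bn_gamma_") + sd.id] =
      NumericVector(g_bn_gamma.begin(), g_bn_gamma.end());
    grads[std::string("bn_beta_") + sd.id] =
      NumericVector(g_bn_beta.begin(), g_bn_beta.end());
    grads[std::string("spec_W_") + sd.id] = wrap(g_specW);
    grads[std::string("spec_b_") + sd.id] =
      NumericVector(g_specb.begin(), g_specb.end());
  }

  grads["enc_W1"] = wrap(g_encW1);
  grads["enc_b1"] = NumericVector(g_b1.begin(), g_b1.end());
  grads["enc_W2"] = wrap(g_encW2);
  grads["enc_b2"] = NumericVector(g_b2.begin(), g_b2.end());
  grads["enc_Wmu"] = wrap(g_Wmu);
  grads["enc_bmu"] = NumericVector(g_bmu.begin(), g_bmu.end());
  grads["enc_Wlv"] = wrap(g_Wlv);
  grads["enc_blv"] = NumericVector(g_blv.begin(), g_blv.end());
  grads["dec_W"] = wrap(g_decW);
  grads["dec_b"] = NumericVector(g_decb.begin(), g_decb.end());

  return List::create(_["loss_total"] = loss_total,
                      _["loss_elbo"] = loss_elbo,
                      _["loss_uot"] = loss_uot,
                      _["grads"] = grads,
                      _["bn"] = bn_out,
                      _["plan"] = wrap(plan),
                      _["mu_x"] = wrap(S[0].enc.mu),
                      _["mu_y"] = wrap(S[1].enc.mu));
}
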