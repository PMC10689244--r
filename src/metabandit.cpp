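// Compiled cores: the two tight sequential loops of the package —
// the recurrent actor-critic (forward pass + truncated BPTT gradients)
// and the forgetting Q-learning likelihood. All random number draws stay
// on the R side; every function here is deterministic in its inputs.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

static inline vec softmax2(const vec& z) {
  vec s = z - z.max();
  vec e = arma::exp(s);
  return e / arma::accu(e);
}

// Forward pass for one trial: two parallel tanh recurrent subnetworks
// (actor, critic) receiving the same input. The 3-element input x0 is
// presented only at the first step of the trial; later steps get zeros.
// `inact` holds 0-based indices into the concatenated 100 units
// (0..n-1 actor, n..2n-1 critic) whose activations are forced to zero at
// the trial's final step (the pattern the action readout sees).
// [[Rcpp::export]]
List agent_trial_forward_cpp(const List& params,
                             const arma::vec& ya0, const arma::vec& yc0,
                             const arma::vec& x0, int nsteps,
                             const arma::ivec& inact) {
  mat Wxa = params["Wx_a"]; mat Wya = params["Wy_a"]; vec ba = params["b_a"];
  mat Wxc = params["Wx_c"]; mat Wyc = params["Wy_c"]; vec bc = params["b_c"];
  const int n = Wya.n_rows;
  mat ya(n, nsteps), yc(n, nsteps);
  vec a = ya0, c = yc0;
  vec xzero = arma::zeros<vec>(x0.n_elem);
  for (int s = 0; s < nsteps; ++s) {
    const vec& x = (s == 0) ? x0 : xzero;
    a = arma::tanh(Wxa * x + Wya * a + ba);
    c = arma::tanh(Wxc * x + Wyc * c + bc);
    if (s == nsteps - 1) {
      for (arma::uword k = 0; k < inact.n_elem; ++k) {
        int u = inact[k];
        if (u < n) a[u] = 0.0; else c[u - n] = 0.0;
      }
    }
    ya.col(s) = a;
    yc.col(s) = c;
  }
  return List::create(_["ya"] = ya, _["yc"] = yc);
}

// One unroll segment of the A2C objective.
//
//   X           3 x T inputs (nonzero columns only at trial-first steps)
//   ya0, yc0    recurrent states entering the segment
//   action_pos  1-based step indices (within the segment) where an action
//               was sampled; `actions` in {1,2} (left, right)
//   rewards     per-step rewards (nonzero only at action steps)
//   vboot       bootstrap state value at the segment boundary (0 at end
//               of session); treated as a constant
//
// Returns are computed backward: R_T = r_T + gamma * vboot,
// R_t = r_t + gamma * R_{t+1} (the n-step discounted return truncated at
// the segment boundary). The advantage at an action step is
// delta = R_t - V(s_t).
//
// Policy loss (action steps):  -ln pi(a_t|s_t) * delta - beta_e * H(pi)
// Value loss  (every step):     beta_v * 0.5 * (R_t - V(s_t))^2
//
// Gradients follow the actor-critic convention: delta and R_t are
// constants under differentiation, so the actor gradient is
// -dlnpi/dtheta_a * delta - beta_e dH/dtheta_a and the critic gradient is
// -beta_v * delta * dV/dtheta_c. When `A_fixed`/`R_fixed` are supplied the
// losses are evaluated with those constants instead (this makes the loss a
// plain function of the parameters, used by the finite-difference check).
// [[Rcpp::export]]
List a2c_segment_cpp(const List& params, const arma::mat& X,
                     const arma::vec& ya0, const arma::vec& yc0,
                     const arma::ivec& action_pos, const arma::ivec& actions,
                     const arma::vec& rewards, double vboot,
                     double gamma, double beta_e, double beta_v,
                     bool want_grads = true,
                     Nullable<NumericVector> A_fixed = R_NilValue,
                     Nullable<NumericVector> R_fixed = R_NilValue) {
  mat Wxa = params["Wx_a"]; mat Wya = params["Wy_a"]; vec ba = params["b_a"];
  mat Wxc = params["Wx_c"]; mat Wyc = params["Wy_c"]; vec bc = params["b_c"];
  mat Wpi = params["W_pi"]; vec bpi = params["b_pi"];
  mat Wv  = params["W_v"];  vec bv  = params["b_v"];
  const int n = Wya.n_rows;
  const int T = X.n_cols;
  const int nA = action_pos.n_elem;

  // forward
  mat ya(n, T), yc(n, T);
  {
    vec a = ya0, c = yc0;
    for (int t = 0; t < T; ++t) {
      a = arma::tanh(Wxa * X.col(t) + Wya * a + ba);
      c = arma::tanh(Wxc * X.col(t) + Wyc * c + bc);
      ya.col(t) = a;
      yc.col(t) = c;
    }
  }
  vec V(T);
  for (int t = 0; t < T; ++t) V[t] = arma::as_scalar(Wv * yc.col(t)) + bv[0];

  // returns and advantages
  vec Rt(T);
  if (R_fixed.isNotNull()) {
    Rt = as<arma::vec>(R_fixed.get());
  } else {
    double acc = vboot;
    for (int t = T - 1; t >= 0; --t) {
      acc = rewards[t] + gamma * acc;
      Rt[t] = acc;
    }
  }
  vec Adv(nA);
  if (A_fixed.isNotNull()) {
    Adv = as<arma::vec>(A_fixed.get());
  } else {
    for (int k = 0; k < nA; ++k) {
      int t = action_pos[k] - 1;
      Adv[k] = Rt[t] - V[t];
    }
  }

  // losses
  double Lpi = 0.0, Lv = 0.0;
  mat P(2, nA);
  for (int k = 0; k < nA; ++k) {
    int t = action_pos[k] - 1;
    vec logits = Wpi * ya.col(t) + bpi;
    vec p = softmax2(logits);
    P.col(k) = p;
    double H = -arma::accu(p % arma::log(p));
    int a = actions[k] - 1;
    Lpi += -std::log(p[a]) * Adv[k] - beta_e * H;
  }
  for (int t = 0; t < T; ++t) {
    double d = Rt[t] - V[t];
    Lv += beta_v * 0.5 * d * d;
  }

  List out = List::create(
    _["loss_pi"] = Lpi, _["loss_v"] = Lv, _["loss_tot"] = Lpi + Lv,
    _["returns"] = Rt, _["advantages"] = Adv,
    _["ya_end"] = vec(ya.col(T - 1)), _["yc_end"] = vec(yc.col(T - 1)));
  if (!want_grads) return out;

  // backward
  mat dWxa(arma::size(Wxa), arma::fill::zeros), dWya(arma::size(Wya), arma::fill::zeros);
  vec dba(n, arma::fill::zeros);
  mat dWxc(arma::size(Wxc), arma::fill::zeros), dWyc(arma::size(Wyc), arma::fill::zeros);
  vec dbc(n, arma::fill::zeros);
  mat dWpi(arma::size(Wpi), arma::fill::zeros); vec dbpi(2, arma::fill::zeros);
  mat dWv(arma::size(Wv), arma::fill::zeros);   vec dbv(1, arma::fill::zeros);

  mat dya(n, T, arma::fill::zeros), dyc(n, T, arma::fill::zeros);

  // value head: dL/dV_t = -beta_v * (R_t - V_t)
  for (int t = 0; t < T; ++t) {
    double dV = -beta_v * (Rt[t] - V[t]);
    dWv += dV * yc.col(t).t();
    dbv[0] += dV;
    dyc.col(t) += Wv.t() * dV;
  }
  // policy head at action steps
  for (int k = 0; k < nA; ++k) {
    int t = action_pos[k] - 1;
    vec p = P.col(k);
    double H = -arma::accu(p % arma::log(p));
    int a = actions[k] - 1;
    vec dlogit(2);
    for (int j = 0; j < 2; ++j) {
      double onehot = (j == a) ? 1.0 : 0.0;
      dlogit[j] = Adv[k] * (p[j] - onehot)            // -ln pi(a) * A term
                + beta_e * p[j] * (std::log(p[j]) + H); // -beta_e * H term
    }
    dWpi += dlogit * ya.col(t).t();
    dbpi += dlogit;
    dya.col(t) += Wpi.t() * dlogit;
  }
  // BPTT through both subnets
  vec carry_a(n, arma::fill::zeros), carry_c(n, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    vec da = dya.col(t) + carry_a;
    vec dz = da % (1.0 - arma::square(ya.col(t)));
    const vec yprev = (t == 0) ? ya0 : vec(ya.col(t - 1));
    dWxa += dz * X.col(t).t();
    dWya += dz * yprev.t();
    dba += dz;
    carry_a = Wya.t() * dz;

    vec dc = dyc.col(t) + carry_c;
    vec dzc = dc % (1.0 - arma::square(yc.col(t)));
    const vec cprev = (t == 0) ? yc0 : vec(yc.col(t - 1));
    dWxc += dzc * X.col(t).t();
    dWyc += dzc * cprev.t();
    dbc += dzc;
    carry_c = Wyc.t() * dzc;
  }

  out["grads"] = List::create(
    _["Wx_a"] = dWxa, _["Wy_a"] = dWya, _["b_a"] = dba,
    _["Wx_c"] = dWxc, _["Wy_c"] = dWyc, _["b_c"] = dbc,
    _["W_pi"] = dWpi, _["b_pi"] = dbpi,
    _["W_v"] = dWv, _["b_v"] = dbv);
  return out;
}

// Negative log-likelihood (plus optional L2 penalty) of the forgetting
// Q-learning model run forward over one session.
//   par     (alpha_rew, alpha_unr, omega, beta_dq, beta0[, beta_c])
//   choices 1 = left, 2 = right, 0 = no choice (miss/alarm; skipped)
//   use     0/1 mask of trials contributing likelihood terms (CV folds)
// Chosen value updated with outcome-dependent learning rate; unchosen
// value decays by (1 - omega) per choice trial. The deep-RL variant adds
// beta_c * C(t-1) inside the logistic, C being the previous actual choice
// (+1 left / -1 right, 0 before the first choice).
// [[Rcpp::export]]
double rl_negloglik_cpp(const arma::vec& par, const arma::ivec& choices,
                        const arma::ivec& rewards, bool deeprl,
                        double q0, double lambda, const arma::ivec& use) {
  const double ar = par[0], au = par[1], om = par[2], bdq = par[3], b0 = par[4];
  const double bcp = deeprl ? par[5] : 0.0;
  double qL = q0, qR = q0, nll = 0.0;
  int prev = 0;
  const int T = choices.n_elem;
  for (int t = 0; t < T; ++t) {
    int c = choices[t];
    if (c == 0) continue;
    double z = bdq * (b0 + bcp * prev + qL - qR);
    double pL = 1.0 / (1.0 + std::exp(-z));
    double p = (c == 1) ? pL : 1.0 - pL;
    if (use[t]) nll -= std::log(std::max(p, 1e-12));
    double r = rewards[t];
    double a = (r > 0.5) ? ar : au;
    if (c == 1) {
      qL += a * (r - qL);
      qR *= (1.0 - om);
      prev = 1;
    } else {
      qR += a * (r - qR);
      qL *= (1.0 - om);
      prev = -1;
    }
  }
  if (lambda > 0.0) nll += 0.5 * lambda * arma::dot(par, par);
  return nll;
}

// Per-trial value series implied by the model: Q_L(t), Q_R(t) before the
// trial-t update, and P_L(t) under the fitted policy.
// [[Rcpp::export]]
NumericMatrix rl_qseries_cpp(const arma::vec& par, const arma::ivec& choices,
                             const arma::ivec& rewards, bool deeprl, double q0) {
  const double ar = par[0], au = par[1], om = par[2], bdq = par[3], b0 = par[4];
  const double bcp = deeprl ? par[5] : 0.0;
  double qL = q0, qR = q0;
  int prev = 0;
  const int T = choices.n_elem;
  NumericMatrix out(T, 3);
  for (int t = 0; t < T; ++t) {
    out(t, 0) = qL;
    out(t, 1) = qR;
    double z = bdq * (b0 + bcp * prev + qL - qR);
    out(t, 2) = 1.0 / (1.0 + std::exp(-z));
    int c = choices[t];
    if (c == 0) continue;
    double r = rewards[t];
    double a = (r > 0.5) ? ar : au;
    if (c == 1) {
      qL += a * (r - qL);
      qR *= (1.0 - om);
      prev = 1;
    } else {
      qR += a * (r - qR);
      qL *= (1.0 - om);
      prev = -1;
    }
  }
  colnames(out) = CharacterVector::create("Q_L", "Q_R", "P_L");
  return out;
}
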