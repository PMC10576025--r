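#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Strength-computation module (SCM) core: valid-mode 1D cross-correlation
// over one-hot channels, learned per-position bias, softplus, sum. Four
// SCMs (inclusion/skipping x sequence/structure) feed a learned
// scalar-to-PSI link. Forward pass, Bernoulli-KL loss and analytic
// gradients live here; the Adam loop drives this from R.
//
// Channel conventions (fixed package-wide):
//   sequence SCM input:  4 channels, order A,C,G,U
//   structure SCM input: 8 channels, order [seq A,C,G,U | "(",".",")" | wobble]
// Integer encodings: sequence 0..3 (A,C,G,U); structure 0..2 ("(",".",")").

static inline double softplus(double t) {
  if (t > 30.0) return t;
  if (t < -30.0) return std::exp(t);
  return std::log1p(std::exp(t));
}

static inline double sigmoid(double t) {
  if (t >= 0) {
    double e = std::exp(-t);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(t);
  return e / (1.0 + e);
}

struct ScmView {
  int w, c, k, P;
  const double *alpha;  // (w, c, k) column-major
  const double *beta;   // (P, k) column-major
  bool is_struct;
};

static ScmView scm_view(const List &scm, int d, bool is_struct) {
  ScmView v;
  NumericVector alpha = scm["alpha"];
  NumericMatrix beta = scm["beta"];
  IntegerVector dim = alpha.attr("dim");
  v.w = dim[0]; v.c = dim[1]; v.k = dim[2];
  v.P = d - v.w + 1;
  if (beta.nrow() != v.P || beta.ncol() != v.k)
    stop("position-bias shape (%d x %d) inconsistent with kernel (expected %d x %d)",
         beta.nrow(), beta.ncol(), v.P, v.k);
  if (v.w > d) stop("filter width %d exceeds input length %d", v.w, d);
  v.alpha = REAL(alpha);
  v.beta = REAL(beta);
  v.is_struct = is_struct;
  return v;
}

// raw strengths z (P x k, column-major) for one record
static void compute_z(const ScmView &S, const int *s, const int *st,
                      const int *wo, std::vector<double> &z) {
  const int w = S.w, c = S.c, k = S.k, P = S.P;
  for (int f = 0; f < k; ++f) {
    const double *af = S.alpha + (size_t) w * c * f;
    for (int p = 0; p < P; ++p) {
      double acc = 0.0;
      if (!S.is_struct) {
        for (int i = 0; i < w; ++i) acc += af[i + w * s[p + i]];
      } else {
        for (int i = 0; i < w; ++i) {
          int pos = p + i;
          acc += af[i + w * s[pos]];
          acc += af[i + w * (4 + st[pos])];
          if (wo[pos]) acc += af[i + w * 7];
        }
      }
      z[p + P * f] = acc;
    }
  }
}

struct TunerPrime { double nu, eta; };

struct TunerFullView {
  int h;
  const double *W1, *b1, *W2, *b2, *w3;
  double b3, r;
};

static TunerFullView tuner_full_view(const List &tuner) {
  TunerFullView v;
  NumericVector W1 = tuner["W1"], b1 = tuner["b1"], b2 = tuner["b2"], w3 = tuner["w3"];
  NumericMatrix W2 = tuner["W2"];
  v.h = W1.size();
  v.W1 = REAL(W1); v.b1 = REAL(b1);
  v.W2 = REAL(W2); v.b2 = REAL(b2);
  v.w3 = REAL(w3);
  v.b3 = as<double>(tuner["b3"]);
  v.r = as<double>(tuner["r"]);
  return v;
}

// forward through the full tuner; stores hidden activations for backprop
static double tuner_full_u(const TunerFullView &T, double x,
                           std::vector<double> &h1, std::vector<double> &h2) {
  const int h = T.h;
  for (int i = 0; i < h; ++i) h1[i] = std::tanh(T.W1[i] * x + T.b1[i]);
  for (int i = 0; i < h; ++i) {
    double acc = T.b2[i];
    for (int j = 0; j < h; ++j) acc += T.W2[i + h * j] * h1[j];
    h2[i] = std::tanh(acc);
  }
  double u = T.b3 + T.r * x;
  for (int i = 0; i < h; ++i) u += T.w3[i] * h2[i];
  return u;
}

static double tuner_full_dudx(const TunerFullView &T, double x,
                              const std::vector<double> &h1,
                              const std::vector<double> &h2) {
  const int h = T.h;
  double du = T.r;
  for (int i = 0; i < h; ++i) {
    double g2 = T.w3[i] * (1.0 - h2[i] * h2[i]);
    for (int j = 0; j < h; ++j)
      du += g2 * T.W2[i + h * j] * (1.0 - h1[j] * h1[j]) * T.W1[j];
  }
  return du;
}

static const int SCM_SIGN[4] = {+1, +1, -1, -1};  // incl_seq, incl_struct, skip_seq, skip_struct
static const bool SCM_IS_STRUCT[4] = {false, true, false, true};

// [[Rcpp::export]]
List cpp_model_eval(IntegerMatrix seqm, IntegerMatrix structm, IntegerMatrix wobm,
                    List scms, double B, List tuner, bool use_struct) {
  const int n = seqm.nrow(), d = seqm.ncol();
  std::vector<ScmView> V;
  for (int m = 0; m < 4; ++m) {
    if (!use_struct && SCM_IS_STRUCT[m]) { V.push_back(ScmView()); continue; }
    V.push_back(scm_view(scms[m], d, SCM_IS_STRUCT[m]));
  }
  std::string ttype = as<std::string>(tuner["type"]);
  TunerPrime TP = {0, 0};
  TunerFullView TF;
  if (ttype == "prime") { TP.nu = as<double>(tuner["nu"]); TP.eta = as<double>(tuner["eta"]); }
  else TF = tuner_full_view(tuner);

  NumericMatrix totals(n, 4);
  NumericVector delta(n), psi(n);
  std::vector<int> s(d), st(d), wo(d);
  std::vector<double> z, h1, h2;
  if (ttype == "full") { h1.resize(TF.h); h2.resize(TF.h); }

  for (int r = 0; r < n; ++r) {
    for (int pos = 0; pos < d; ++pos) {
      s[pos] = seqm(r, pos);
      if (use_struct) { st[pos] = structm(r, pos); wo[pos] = wobm(r, pos); }
    }
    double dlt = B;
    for (int m = 0; m < 4; ++m) {
      if (!use_struct && SCM_IS_STRUCT[m]) continue;
      const ScmView &S = V[m];
      z.resize((size_t) S.P * S.k);
      compute_z(S, s.data(), st.data(), wo.data(), z);
      double tot = 0.0;
      for (int f = 0; f < S.k; ++f)
        for (int p = 0; p < S.P; ++p)
          tot += softplus(z[p + S.P * f] + S.beta[p + S.P * f]);
      totals(r, m) = tot;
      dlt += SCM_SIGN[m] * tot;
    }
    delta[r] = dlt;
    if (ttype == "prime") psi[r] = sigmoid(TP.nu * dlt + TP.eta);
    else psi[r] = sigmoid(tuner_full_u(TF, dlt, h1, h2));
  }
  return List::create(_["totals"] = totals, _["delta"] = delta, _["psi"] = psi);
}

// Bernoulli KL(p || q) with q clipped to [eps, 1-eps]; 0*log(0) == 0
static inline double bern_kl(double p, double q, double eps) {
  if (q < eps) q = eps;
  if (q > 1.0 - eps) q = 1.0 - eps;
  double out = 0.0;
  if (p > 0) out += p * std::log(p / q);
  if (p < 1) out += (1.0 - p) * std::log((1.0 - p) / (1.0 - q));
  return out;
}

// [[Rcpp::export]]
List cpp_loss_grad(IntegerMatrix seqm, IntegerMatrix structm, IntegerMatrix wobm,
                   IntegerVector rows, NumericVector psi_obs,
                   List scms, double B, List tuner, bool use_struct,
                   double lambda_act, double lambda_smooth, double eps_clip,
                   bool want_grad) {
  const int n = seqm.nrow(), d = seqm.ncol(), nb = rows.size();
  if (n == 0 || nb == 0) stop("empty batch");
  std::vector<ScmView> V;
  for (int m = 0; m < 4; ++m) {
    if (!use_struct && SCM_IS_STRUCT[m]) { V.push_back(ScmView()); continue; }
    V.push_back(scm_view(scms[m], d, SCM_IS_STRUCT[m]));
  }
  std::string ttype = as<std::string>(tuner["type"]);
  TunerPrime TP = {0, 0};
  TunerFullView TF;
  if (ttype == "prime") { TP.nu = as<double>(tuner["nu"]); TP.eta = as<double>(tuner["eta"]); }
  else TF = tuner_full_view(tuner);

  // gradient accumulators
  List galpha(4), gbeta(4);
  std::vector<double*> ga(4, (double*) 0), gb(4, (double*) 0);
  if (want_grad) {
    for (int m = 0; m < 4; ++m) {
      if (!use_struct && SCM_IS_STRUCT[m]) continue;
      const ScmView &S = V[m];
      NumericVector a((size_t) S.w * S.c * S.k);
      a.attr("dim") = IntegerVector::create(S.w, S.c, S.k);
      NumericMatrix b(S.P, S.k);
      galpha[m] = a; gbeta[m] = b;
      ga[m] = REAL(a); gb[m] = REAL(b);
    }
  }
  double gB = 0.0, gnu = 0.0, geta = 0.0;
  std::vector<double> gW1, gb1, gW2, gb2, gw3;
  double gb3 = 0.0, gr = 0.0;
  if (ttype == "full") {
    gW1.assign(TF.h, 0.0); gb1.assign(TF.h, 0.0);
    gW2.assign((size_t) TF.h * TF.h, 0.0); gb2.assign(TF.h, 0.0);
    gw3.assign(TF.h, 0.0);
  }

  double kl_sum = 0.0, act_sum = 0.0;
  std::vector<int> s(d), st(d), wo(d);
  // per-record z for each SCM (kept for the backward pass)
  std::vector<std::vector<double> > zb(4);
  std::vector<double> h1, h2, dz2(0), dh1(0);
  if (ttype == "full") { h1.resize(TF.h); h2.resize(TF.h); dz2.resize(TF.h); dh1.resize(TF.h); }

  const double inv_nb = 1.0 / (double) nb;

  for (int bi = 0; bi < nb; ++bi) {
    int r = rows[bi] - 1;
    if (r < 0 || r >= n) stop("batch row index out of range");
    double p_obs = psi_obs[r];
    for (int pos = 0; pos < d; ++pos) {
      s[pos] = seqm(r, pos);
      if (use_struct) { st[pos] = structm(r, pos); wo[pos] = wobm(r, pos); }
    }

    double dlt = B, act_r = 0.0;
    for (int m = 0; m < 4; ++m) {
      if (!use_struct && SCM_IS_STRUCT[m]) continue;
      const ScmView &S = V[m];
      zb[m].resize((size_t) S.P * S.k);
      compute_z(S, s.data(), st.data(), wo.data(), zb[m]);
      double tot = 0.0;
      for (size_t idx = 0; idx < zb[m].size(); ++idx)
        tot += softplus(zb[m][idx] + S.beta[idx]);
      act_r += tot;
      dlt += SCM_SIGN[m] * tot;
    }

    double q, dudx = 1.0;
    if (ttype == "prime") {
      q = sigmoid(TP.nu * dlt + TP.eta);
    } else {
      double u = tuner_full_u(TF, dlt, h1, h2);
      q = sigmoid(u);
    }
    kl_sum += bern_kl(p_obs, q, eps_clip);
    act_sum += act_r;
    if (!want_grad) continue;

    // dL/du through the sigmoid + KL: (q - p)
    double gu = (q - p_obs) * inv_nb;
    double gdelta;
    if (ttype == "prime") {
      gnu += gu * dlt;
      geta += gu;
      gdelta = gu * TP.nu;
    } else {
      // backprop through MLP + residual
      const int h = TF.h;
      for (int i = 0; i < h; ++i) gw3[i] += gu * h2[i];
      gb3 += gu;
      gr += gu * dlt;
      for (int i = 0; i < h; ++i) dz2[i] = gu * TF.w3[i] * (1.0 - h2[i] * h2[i]);
      for (int j = 0; j < h; ++j) {
        double acc = 0.0;
        for (int i = 0; i < h; ++i) {
          gW2[i + h * j] += dz2[i] * h1[j];
          acc += TF.W2[i + h * j] * dz2[i];
        }
        dh1[j] = acc;
      }
      for (int j = 0; j < h; ++j) {
        double dz1 = dh1[j] * (1.0 - h1[j] * h1[j]);
        gW1[j] += dz1 * dlt;
        gb1[j] += dz1;
      }
      for (int i = 0; i < h; ++i) gb2[i] += dz2[i];
      gdelta = gu * tuner_full_dudx(TF, dlt, h1, h2);
    }
    gB += gdelta;

    for (int m = 0; m < 4; ++m) {
      if (!use_struct && SCM_IS_STRUCT[m]) continue;
      const ScmView &S = V[m];
      // coefficient on each post-softplus strength: prediction term +
      // activity term (activity is the plain sum, strengths being positive)
      double coef = gdelta * SCM_SIGN[m] + lambda_act * inv_nb;
      if (coef == 0.0) continue;
      const int w = S.w, c = S.c, k = S.k, P = S.P;
      double *gaf_all = ga[m], *gbf = gb[m];
      for (int f = 0; f < k; ++f) {
        double *gaf = gaf_all + (size_t) w * c * f;
        for (int p = 0; p < P; ++p) {
          size_t idx = p + (size_t) P * f;
          double gpre = coef * sigmoid(zb[m][idx] + S.beta[idx]);
          gbf[idx] += gpre;
          if (!S.is_struct) {
            for (int i = 0; i < w; ++i) gaf[i + w * s[p + i]] += gpre;
          } else {
            for (int i = 0; i < w; ++i) {
              int pos = p + i;
              gaf[i + w * s[pos]] += gpre;
              gaf[i + w * (4 + st[pos])] += gpre;
              if (wo[pos]) gaf[i + w * 7] += gpre;
            }
          }
        }
      }
    }
  }

  // smoothness penalty on position biases (first differences along position)
  double smooth = 0.0;
  for (int m = 0; m < 4; ++m) {
    if (!use_struct && SCM_IS_STRUCT[m]) continue;
    const ScmView &S = V[m];
    for (int f = 0; f < S.k; ++f) {
      const double *col = S.beta + (size_t) S.P * f;
      double *gcol = want_grad ? gb[m] + (size_t) S.P * f : (double*) 0;
      for (int p = 0; p + 1 < S.P; ++p) {
        double diff = col[p + 1] - col[p];
        smooth += diff * diff;
        if (want_grad && lambda_smooth > 0) {
          gcol[p + 1] += lambda_smooth * 2.0 * diff;
          gcol[p]     -= lambda_smooth * 2.0 * diff;
        }
      }
    }
  }

  double kl = kl_sum * inv_nb, act = act_sum * inv_nb;
  double loss = kl + lambda_act * act + lambda_smooth * smooth;

  List out = List::create(_["loss"] = loss, _["kl"] = kl, _["activity"] = act,
                          _["smoothness"] = smooth);
  if (want_grad) {
    List gtuner;
    if (ttype == "prime") {
      gtuner = List::create(_["nu"] = gnu, _["eta"] = geta);
    } else {
      NumericMatrix W2g(TF.h, TF.h);
      std::copy(gW2.begin(), gW2.end(), W2g.begin());
      gtuner = List::create(_["W1"] = NumericVector(gW1.begin(), gW1.end()),
                            _["b1"] = NumericVector(gb1.begin(), gb1.end()),
                            _["W2"] = W2g,
                            _["b2"] = NumericVector(gb2.begin(), gb2.end()),
                            _["w3"] = NumericVector(gw3.begin(), gw3.end()),
                            _["b3"] = gb3, _["r"] = gr);
    }
    out["grads"] = List::create(_["alpha"] = galpha, _["beta"] = gbeta,
                                _["B"] = gB, _["tuner"] = gtuner);
  }
  return out;
}

// Per-record diagnostic maps: raw (z), pre-activation (z + beta) and
// post-softplus strengths for each SCM.
// [[Rcpp::export]]
List cpp_strength_maps(IntegerVector s_, IntegerVector st_, IntegerVector wo_,
                       List scms, bool use_struct) {
  const int d = s_.size();
  std::vector<int> s(d), st(d, 1), wo(d, 0);
  for (int i = 0; i < d; ++i) s[i] = s_[i];
  if (use_struct)
    for (int i = 0; i < d; ++i) { st[i] = st_[i]; wo[i] = wo_[i]; }
  List out(4);
  std::vector<double> z;
  for (int m = 0; m < 4; ++m) {
    if (!use_struct && SCM_IS_STRUCT[m]) continue;
    ScmView S = scm_view(scms[m], d, SCM_IS_STRUCT[m]);
    z.resize((size_t) S.P * S.k);
    compute_z(S, s.data(), st.data(), wo.data(), z);
    NumericMatrix zraw(S.P, S.k), pre(S.P, S.k), strengths(S.P, S.k);
    for (int f = 0; f < S.k; ++f)
      for (int p = 0; p < S.P; ++p) {
        size_t idx = p + (size_t) S.P * f;
        zraw(p, f) = z[idx];
        pre(p, f) = z[idx] + S.beta[idx];
        strengths(p, f) = softplus(pre(p, f));
      }
    out[m] = List::create(_["z"] = zraw, _["pre"] = pre, _["strengths"] = strengths);
  }
  out.attr("names") = CharacterVector::create("incl_seq", "incl_struct",
                                              "skip_seq", "skip_struct");
  return out;
}
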