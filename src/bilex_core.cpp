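// Core numerical kernels: SOM competition and training, Hebbian link updates,
// exposure-driven paired-map training, lexical-access evaluation, and the
// per-session treatment loop. All randomness comes from R's RNG (unif_rand),
// so a single set.seed() in R governs every stochastic choice made here.
//
// Hot loops work on transposed copies (columns = units / link rows) so that
// every inner loop walks contiguous memory; R-facing matrices keep the
// units-by-dimension convention and are transposed at entry/exit.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// squared grid distance between row-major unit indices on an (nr x nc) grid
static inline double grid_dist2(int u, int v, int nc) {
  const double dr = (double)(u / nc) - (double)(v / nc);
  const double dc = (double)(u % nc) - (double)(v % nc);
  return dr * dr + dc * dc;
}

// ---- transposed-layout primitives (Wt: dim x units, columns contiguous) ----

// alive unit minimizing Euclidean distance to v (ties -> lowest index),
// with partial-distance pruning; -1 if no unit is alive
static int winner_t(const arma::mat& Wt, const arma::uvec& alive,
                    const double* v) {
  const int U = (int)Wt.n_cols, D = (int)Wt.n_rows;
  int best = -1;
  double bestd = std::numeric_limits<double>::infinity();
  for (int u = 0; u < U; ++u) {
    if (!alive[u]) continue;
    const double* w = Wt.colptr(u);
    double d = 0.0;
    int k = 0;
    for (; k + 4 <= D; k += 4) {
      const double d0 = w[k] - v[k], d1 = w[k + 1] - v[k + 1];
      const double d2 = w[k + 2] - v[k + 2], d3 = w[k + 3] - v[k + 3];
      d += d0 * d0 + d1 * d1 + d2 * d2 + d3 * d3;
      if (d >= bestd) break;
    }
    if (d < bestd) {
      for (; k < D; ++k) { const double dd = w[k] - v[k]; d += dd * dd; }
      if (d < bestd) { best = u; bestd = d; }
    }
  }
  return best;
}

// SOM update toward v with Gaussian neighbourhood truncated at 3 sigma
static void som_update_t(arma::mat& Wt, const arma::uvec& alive, int nc,
                         const double* v, int winner, double rate,
                         double sigma) {
  if (winner < 0 || rate <= 0.0) return;
  const int U = (int)Wt.n_cols, D = (int)Wt.n_rows;
  const double cut2 = 9.0 * sigma * sigma;
  const double den = 2.0 * sigma * sigma;
  for (int u = 0; u < U; ++u) {
    if (!alive[u]) continue;
    const double d2 = grid_dist2(u, winner, nc);
    if (d2 > cut2) continue;
    const double h = rate * std::exp(-d2 / den);
    double* w = Wt.colptr(u);
    for (int k = 0; k < D; ++k) w[k] += h * (v[k] - w[k]);
  }
}

// Gaussian activation bump (peak 1, truncated at 3 sigma, zero on dead units)
static void bump_t(double* a, int U, int nc, int winner, double sigma,
                   const arma::uvec& alive) {
  std::fill(a, a + U, 0.0);
  if (winner < 0) return;
  const double cut2 = 9.0 * sigma * sigma;
  const double den = 2.0 * sigma * sigma;
  for (int u = 0; u < U; ++u) {
    if (!alive[u]) continue;
    const double d2 = grid_dist2(u, winner, nc);
    if (d2 <= cut2) a[u] = std::exp(-d2 / den);
  }
}

// Hebbian update on a transposed link matrix Lt (targets x sources):
// Lt[v,u] += rate * a_src[u] * a_tgt[v], then each touched source column is
// renormalized to unit sum. Dead-target entries are kept at zero by the
// callers (a_tgt is zero there and lesioning zeroes them), so the plain
// column sum equals the sum over alive targets.
static void hebb_t(arma::mat& Lt, const double* a_src, const double* a_tgt,
                   double rate, int S, int T) {
  if (rate <= 0.0) return;
  double tsum = 0.0;
  for (int v = 0; v < T; ++v) tsum += a_tgt[v];
  if (tsum <= 0.0) return;
  for (int u = 0; u < S; ++u) {
    if (a_src[u] <= 0.0) continue;
    double* col = Lt.colptr(u);
    const double r = rate * a_src[u];
    double s = 0.0;
    for (int v = 0; v < T; ++v) { col[v] += r * a_tgt[v]; s += col[v]; }
    if (s > 0.0) for (int v = 0; v < T; ++v) col[v] /= s;
  }
}

// activation evoked through links: a_tgt = sum_u a_src[u] * Lt.col(u),
// exploiting the sparse support of the source bump
static void transfer_t(double* a_tgt, const arma::mat& Lt,
                       const double* a_src, int S, int T) {
  std::fill(a_tgt, a_tgt + T, 0.0);
  for (int u = 0; u < S; ++u) {
    if (a_src[u] <= 0.0) continue;
    const double* col = Lt.colptr(u);
    const double w = a_src[u];
    for (int v = 0; v < T; ++v) a_tgt[v] += w * col[v];
  }
}

static void peak_normalize(double* a, int n) {
  double m = 0.0;
  for (int i = 0; i < n; ++i) if (a[i] > m) m = a[i];
  if (m > 0.0) for (int i = 0; i < n; ++i) a[i] /= m;
}

// index of maximal activation among alive units, ties -> lowest index
static int argmax_alive(const double* a, const arma::uvec& alive, int n) {
  int best = -1;
  double bestv = 0.0;
  for (int u = 0; u < n; ++u) {
    if (!alive[u]) continue;
    if (best < 0 || a[u] > bestv) { best = u; bestv = a[u]; }
  }
  return best;
}

// Fisher-Yates shuffle driven by R's RNG
static void shuffle_vec(std::vector<int>& y) {
  for (int i = (int)y.size() - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(y[i], y[j]);
  }
}

// ---- exported helpers on the R-facing (units x dim) layout ----

// [[Rcpp::export]]
int cpp_find_winner(const arma::mat& W, const arma::uvec& alive,
                    const arma::rowvec& v) {
  const arma::mat Wt = W.t();
  const arma::vec vv = v.t();
  return winner_t(Wt, alive, vv.memptr());
}

// [[Rcpp::export]]
arma::mat cpp_som_train_step(const arma::mat& W, const arma::uvec& alive,
                             int nc, const arma::rowvec& v, double rate,
                             double sigma) {
  arma::mat Wt = W.t();
  const arma::vec vv = v.t();
  const int w = winner_t(Wt, alive, vv.memptr());
  som_update_t(Wt, alive, nc, vv.memptr(), w, rate, sigma);
  return Wt.t();
}

// [[Rcpp::export]]
arma::vec cpp_activation_bump(int n_units, int nc, int winner, double sigma,
                              const arma::uvec& alive) {
  arma::vec a(n_units);
  bump_t(a.memptr(), n_units, nc, winner, sigma, alive);
  return a;
}

// [[Rcpp::export]]
arma::mat cpp_hebbian_update(const arma::mat& W, const arma::vec& a_src,
                             const arma::vec& a_tgt, double rate,
                             const arma::uvec& alive_tgt) {
  arma::mat Lt = W.t();
  arma::vec at = a_tgt;
  for (arma::uword v = 0; v < at.n_elem; ++v) if (!alive_tgt[v]) at[v] = 0.0;
  hebb_t(Lt, a_src.memptr(), at.memptr(), rate, (int)W.n_rows,
         (int)W.n_cols);
  return Lt.t();
}

// [[Rcpp::export]]
double cpp_quant_error(const arma::mat& W, const arma::uvec& alive,
                       const arma::mat& vecs) {
  const arma::mat Wt = W.t();
  const arma::mat Vt = vecs.t();
  double tot = 0.0;
  for (arma::uword i = 0; i < Vt.n_cols; ++i) {
    const int w = winner_t(Wt, alive, Vt.colptr(i));
    if (w < 0) return NA_REAL;
    const arma::vec d = Wt.col(w) - Vt.col(i);
    tot += arma::dot(d, d);
  }
  return tot / (double)Vt.n_cols;
}

// Unit labelling: every alive unit gets the id of its nearest word vector;
// units that are some word's winner get that word instead (nearest such word
// when several words share a winner). Dead units are labelled NA.
// [[Rcpp::export]]
IntegerVector cpp_relabel(const arma::mat& W, const arma::uvec& alive,
                          const arma::mat& vecs,
                          const IntegerVector& word_ids) {
  const arma::mat Wt = W.t();
  const arma::mat Vt = vecs.t();
  const int U = (int)Wt.n_cols;
  IntegerVector labels(U, NA_INTEGER);
  std::vector<double> claim_d(U, 0.0);
  std::vector<int> claim_w(U, -1);
  for (arma::uword i = 0; i < Vt.n_cols; ++i) {
    const int w = winner_t(Wt, alive, Vt.colptr(i));
    if (w < 0) continue;
    const arma::vec d = Wt.col(w) - Vt.col(i);
    const double dd = arma::dot(d, d);
    if (claim_w[w] < 0 || dd < claim_d[w]) { claim_w[w] = (int)i; claim_d[w] = dd; }
  }
  for (int u = 0; u < U; ++u) {
    if (!alive[u]) continue;
    if (claim_w[u] >= 0) { labels[u] = word_ids[claim_w[u]]; continue; }
    int best = -1; double bestd = 0.0;
    for (arma::uword i = 0; i < Vt.n_cols; ++i) {
      const arma::vec d = Wt.col(u) - Vt.col(i);
      const double dd = arma::dot(d, d);
      if (best < 0 || dd < bestd) { best = (int)i; bestd = dd; }
    }
    labels[u] = word_ids[best];
  }
  return labels;
}

// Naming rule: present each semantic vector, transfer the winner bump
// through the semantic->phonetic links, and check that the most active
// alive phonetic unit carries the word's label.
// [[Rcpp::export]]
List cpp_name_words(const arma::mat& semW, const arma::uvec& semAlive, int ncs,
                    const arma::mat& L, const arma::uvec& phonAlive,
                    const IntegerVector& phonLabels, const arma::mat& semVecs,
                    const IntegerVector& ids, double act_sigma) {
  const arma::mat Wt = semW.t();
  const arma::mat Lt = L.t();
  const arma::mat Vt = semVecs.t();
  const int S = (int)Wt.n_cols, T = (int)Lt.n_rows;
  const int n = (int)Vt.n_cols;
  std::vector<double> a(S), ap(T);
  LogicalVector correct(n);
  IntegerVector win(n);
  for (int i = 0; i < n; ++i) {
    const int ws = winner_t(Wt, semAlive, Vt.colptr(i));
    if (ws < 0) { correct[i] = false; win[i] = NA_INTEGER; continue; }
    bump_t(a.data(), S, ncs, ws, act_sigma, semAlive);
    transfer_t(ap.data(), Lt, a.data(), S, T);
    const int u = argmax_alive(ap.data(), phonAlive, T);
    if (u < 0) { correct[i] = false; win[i] = NA_INTEGER; continue; }
    win[i] = u;
    correct[i] = (phonLabels[u] != NA_INTEGER && phonLabels[u] == ids[i]);
  }
  return List::create(_["correct"] = correct, _["winner"] = win);
}

// Translation: phonetic input in the source language, transfer through the
// phonetic->phonetic links, check the label of the most active target unit.
// [[Rcpp::export]]
List cpp_translate_words(const arma::mat& srcW, const arma::uvec& srcAlive,
                         int ncp, const arma::mat& L,
                         const arma::uvec& tgtAlive,
                         const IntegerVector& tgtLabels,
                         const arma::mat& srcVecs, const IntegerVector& ids,
                         double act_sigma) {
  const arma::mat Wt = srcW.t();
  const arma::mat Lt = L.t();
  const arma::mat Vt = srcVecs.t();
  const int S = (int)Wt.n_cols, T = (int)Lt.n_rows;
  const int n = (int)Vt.n_cols;
  std::vector<double> a(S), ap(T);
  LogicalVector correct(n);
  IntegerVector win(n);
  for (int i = 0; i < n; ++i) {
    const int ws = winner_t(Wt, srcAlive, Vt.colptr(i));
    if (ws < 0) { correct[i] = false; win[i] = NA_INTEGER; continue; }
    bump_t(a.data(), S, ncp, ws, act_sigma, srcAlive);
    transfer_t(ap.data(), Lt, a.data(), S, T);
    const int u = argmax_alive(ap.data(), tgtAlive, T);
    if (u < 0) { correct[i] = false; win[i] = NA_INTEGER; continue; }
    win[i] = u;
    correct[i] = (tgtLabels[u] != NA_INTEGER && tgtLabels[u] == ids[i]);
  }
  return List::create(_["correct"] = correct, _["winner"] = win);
}

// Simulated semantic-association trial: winners for target and both options
// on the semantic map; the distinguishing feature is the dimension where the
// two options' winner vectors differ most (ties -> lowest index); choose the
// option closer to the target on that feature (ties -> option a).
// Returns 0 for option a, 1 for option b, -1 if the map is destroyed.
// [[Rcpp::export]]
IntegerVector cpp_papt_choose(const arma::mat& semW, const arma::uvec& semAlive,
                              const arma::mat& tVecs, const arma::mat& aVecs,
                              const arma::mat& bVecs) {
  const arma::mat Wt = semW.t();
  const arma::mat Tt = tVecs.t(), At = aVecs.t(), Bt = bVecs.t();
  const int n = (int)Tt.n_cols;
  IntegerVector choice(n);
  for (int i = 0; i < n; ++i) {
    const int wt = winner_t(Wt, semAlive, Tt.colptr(i));
    const int wa = winner_t(Wt, semAlive, At.colptr(i));
    const int wb = winner_t(Wt, semAlive, Bt.colptr(i));
    if (wt < 0 || wa < 0 || wb < 0) { choice[i] = -1; continue; }
    const double* vt = Wt.colptr(wt);
    const double* va = Wt.colptr(wa);
    const double* vb = Wt.colptr(wb);
    int f = 0; double bestd = -1.0;
    for (arma::uword k = 0; k < Wt.n_rows; ++k) {
      const double d = std::fabs(va[k] - vb[k]);
      if (d > bestd) { bestd = d; f = (int)k; }
    }
    const double da = std::fabs(va[f] - vt[f]);
    const double db = std::fabs(vb[f] - vt[f]);
    choice[i] = (da <= db) ? 0 : 1;
  }
  return choice;
}

// One chunk of exposure-driven training: words and languages sampled per the
// epoch proportions, paired SOM training of semantic + exposed phonetic map,
// Hebbian updates of the semantic<->exposed links, and training of the
// phonetic<->phonetic links from the activation evoked in the unexposed map.
// [[Rcpp::export]]
List cpp_train_exposure_chunk(const arma::mat& semW, const arma::uvec& semAlive,
                              int ncs, const arma::mat& semVecs,
                              const arma::mat& p1W, const arma::uvec& p1Alive,
                              const arma::mat& p2W, const arma::uvec& p2Alive,
                              int ncp, const arma::mat& p1Vecs,
                              const arma::mat& p2Vecs,
                              const arma::mat& L_s1, const arma::mat& L_1s,
                              const arma::mat& L_s2, const arma::mat& L_2s,
                              const arma::mat& L_12, const arma::mat& L_21,
                              int n_pres, double p_L2, double rate_sem,
                              double sigma_sem, double rate_phon,
                              double sigma_phon, double hebb_rate,
                              double act_sigma) {
  arma::mat semWt = semW.t(), p1Wt = p1W.t(), p2Wt = p2W.t();
  const arma::mat semVt = semVecs.t(), p1Vt = p1Vecs.t(), p2Vt = p2Vecs.t();
  // transposed links: Lt_xy has shape (targets of y) x (sources of x)
  arma::mat Lt_s1 = L_s1.t(), Lt_1s = L_1s.t(), Lt_s2 = L_s2.t(),
            Lt_2s = L_2s.t(), Lt_12 = L_12.t(), Lt_21 = L_21.t();
  const int N = (int)semVt.n_cols;
  const int S = (int)semWt.n_cols;
  const int P = (int)p1Wt.n_cols;
  std::vector<double> a_sem(S), a_exp(P), a_un(P);

  for (int t = 0; t < n_pres; ++t) {
    int w = (int)std::floor(unif_rand() * N);
    if (w >= N) w = N - 1;
    const bool l2 = (unif_rand() < p_L2);
    arma::mat& pWt = l2 ? p2Wt : p1Wt;
    const arma::uvec& pAlive = l2 ? p2Alive : p1Alive;
    const arma::mat& pVt = l2 ? p2Vt : p1Vt;
    arma::mat& Lt_sp = l2 ? Lt_s2 : Lt_s1;   // sem -> exposed
    arma::mat& Lt_ps = l2 ? Lt_2s : Lt_1s;   // exposed -> sem
    arma::mat& Lt_su = l2 ? Lt_s1 : Lt_s2;   // sem -> unexposed
    arma::mat& Lt_pq = l2 ? Lt_21 : Lt_12;   // exposed -> unexposed
    arma::mat& Lt_qp = l2 ? Lt_12 : Lt_21;   // unexposed -> exposed

    const int ws = winner_t(semWt, semAlive, semVt.colptr(w));
    const int wp = winner_t(pWt, pAlive, pVt.colptr(w));
    som_update_t(semWt, semAlive, ncs, semVt.colptr(w), ws, rate_sem,
                 sigma_sem);
    som_update_t(pWt, pAlive, ncp, pVt.colptr(w), wp, rate_phon, sigma_phon);
    if (ws < 0 || wp < 0) continue;

    bump_t(a_sem.data(), S, ncs, ws, act_sigma, semAlive);
    bump_t(a_exp.data(), P, ncp, wp, act_sigma, pAlive);
    hebb_t(Lt_sp, a_sem.data(), a_exp.data(), hebb_rate, S, P);
    hebb_t(Lt_ps, a_exp.data(), a_sem.data(), hebb_rate, P, S);

    // indirect activation of the unexposed phonetic map via sem->unexposed
    transfer_t(a_un.data(), Lt_su, a_sem.data(), S, P);
    peak_normalize(a_un.data(), P);
    hebb_t(Lt_pq, a_exp.data(), a_un.data(), hebb_rate, P, P);
    hebb_t(Lt_qp, a_un.data(), a_exp.data(), hebb_rate, P, P);
  }
  return List::create(_["semW"] = semWt.t(), _["p1W"] = p1Wt.t(),
                      _["p2W"] = p2Wt.t(), _["L_s1"] = Lt_s1.t(),
                      _["L_1s"] = Lt_1s.t(), _["L_s2"] = Lt_s2.t(),
                      _["L_2s"] = Lt_2s.t(), _["L_12"] = Lt_12.t(),
                      _["L_21"] = Lt_21.t());
}

// One treatment session: semantic retraining, treated-language retrieval
// training, conditional cross-language link retraining (steps 3a/3b), then a
// naming probe of the treatment set in both languages. Condition masks are
// evaluated at the start of the session.
// [[Rcpp::export]]
List cpp_run_session(const arma::mat& semW, const arma::uvec& semAlive,
                     int ncs, const arma::mat& semVecs, const arma::mat& p1W,
                     const arma::uvec& p1Alive, const arma::mat& p2W,
                     const arma::uvec& p2Alive, int ncp,
                     const arma::mat& p1Vecs, const arma::mat& p2Vecs,
                     const IntegerVector& p1Labels,
                     const IntegerVector& p2Labels,
                     const arma::mat& L_s1, const arma::mat& L_1s,
                     const arma::mat& L_s2, const arma::mat& L_2s,
                     const arma::mat& L_12, const arma::mat& L_21,
                     const IntegerVector& treat_rows,
                     const IntegerVector& word_ids, int treated_lang,
                     double r1, double r2, double r3a, double r3b,
                     int cond3a, int cond3b, double act_sigma,
                     double sigma_treat) {
  arma::mat semWt = semW.t(), p1Wt = p1W.t(), p2Wt = p2W.t();
  const arma::mat semVt = semVecs.t(), p1Vt = p1Vecs.t(), p2Vt = p2Vecs.t();
  arma::mat Lt_s1 = L_s1.t(), Lt_1s = L_1s.t(), Lt_s2 = L_s2.t(),
            Lt_2s = L_2s.t(), Lt_12 = L_12.t(), Lt_21 = L_21.t();
  const int S = (int)semWt.n_cols, P = (int)p1Wt.n_cols;
  const bool t2 = (treated_lang == 2);
  arma::mat& trWt = t2 ? p2Wt : p1Wt;
  const arma::uvec& trAlive = t2 ? p2Alive : p1Alive;
  const arma::uvec& unAlive = t2 ? p1Alive : p2Alive;
  const arma::mat& trVt = t2 ? p2Vt : p1Vt;
  const IntegerVector& trLabels = t2 ? p2Labels : p1Labels;
  const IntegerVector& unLabels = t2 ? p1Labels : p2Labels;
  arma::mat& Lt_str = t2 ? Lt_s2 : Lt_s1;
  arma::mat& Lt_trs = t2 ? Lt_2s : Lt_1s;
  arma::mat& Lt_sun = t2 ? Lt_s1 : Lt_s2;
  arma::mat& Lt_uns = t2 ? Lt_1s : Lt_2s;
  arma::mat& Lt_trun = t2 ? Lt_21 : Lt_12;
  arma::mat& Lt_untr = t2 ? Lt_12 : Lt_21;

  const int n = treat_rows.size();
  std::vector<double> a_sem(S), a_tr(P), a_un(P), ap(P);

  // condition masks at session start
  LogicalVector named(n), transl(n);
  for (int i = 0; i < n; ++i) {
    const int r = treat_rows[i];
    named[i] = false;
    const int ws = winner_t(semWt, semAlive, semVt.colptr(r));
    if (ws >= 0) {
      bump_t(a_sem.data(), S, ncs, ws, act_sigma, semAlive);
      transfer_t(ap.data(), Lt_str, a_sem.data(), S, P);
      const int u = argmax_alive(ap.data(), trAlive, P);
      named[i] = (u >= 0 && trLabels[u] != NA_INTEGER &&
                  trLabels[u] == word_ids[r]);
    }
    transl[i] = false;
    const int wt = winner_t(trWt, trAlive, trVt.colptr(r));
    if (wt >= 0) {
      bump_t(a_tr.data(), P, ncp, wt, act_sigma, trAlive);
      transfer_t(ap.data(), Lt_trun, a_tr.data(), P, P);
      const int u = argmax_alive(ap.data(), unAlive, P);
      transl[i] = (u >= 0 && unLabels[u] != NA_INTEGER &&
                   unLabels[u] == word_ids[r]);
    }
  }
  auto passes = [&](int cond, int i) {
    return cond == 2 || (cond == 0 && named[i]) || (cond == 1 && transl[i]);
  };

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;

  // step 1: semantic retraining on the treatment words
  shuffle_vec(ord);
  for (int k = 0; k < n; ++k) {
    const int r = treat_rows[ord[k]];
    const int ws = winner_t(semWt, semAlive, semVt.colptr(r));
    som_update_t(semWt, semAlive, ncs, semVt.colptr(r), ws, r1, sigma_treat);
  }
  // step 2: treated-language retrieval (maps + sem<->treated links)
  shuffle_vec(ord);
  for (int k = 0; k < n; ++k) {
    const int r = treat_rows[ord[k]];
    const int ws = winner_t(semWt, semAlive, semVt.colptr(r));
    const int wp = winner_t(trWt, trAlive, trVt.colptr(r));
    som_update_t(semWt, semAlive, ncs, semVt.colptr(r), ws, r2, sigma_treat);
    som_update_t(trWt, trAlive, ncp, trVt.colptr(r), wp, r2, sigma_treat);
    if (ws < 0 || wp < 0) continue;
    bump_t(a_sem.data(), S, ncs, ws, act_sigma, semAlive);
    bump_t(a_tr.data(), P, ncp, wp, act_sigma, trAlive);
    hebb_t(Lt_str, a_sem.data(), a_tr.data(), r2, S, P);
    hebb_t(Lt_trs, a_tr.data(), a_sem.data(), r2, P, S);
  }
  // step 3a: treated-phonetic activation -> untreated map; retrain
  // sem<->untreated links
  if (r3a > 0.0) {
    shuffle_vec(ord);
    for (int k = 0; k < n; ++k) {
      const int i = ord[k];
      if (!passes(cond3a, i)) continue;
      const int r = treat_rows[i];
      const int wp = winner_t(trWt, trAlive, trVt.colptr(r));
      const int ws = winner_t(semWt, semAlive, semVt.colptr(r));
      if (wp < 0 || ws < 0) continue;
      bump_t(a_tr.data(), P, ncp, wp, act_sigma, trAlive);
      transfer_t(a_un.data(), Lt_trun, a_tr.data(), P, P);
      peak_normalize(a_un.data(), P);
      bump_t(a_sem.data(), S, ncs, ws, act_sigma, semAlive);
      hebb_t(Lt_sun, a_sem.data(), a_un.data(), r3a, S, P);
      hebb_t(Lt_uns, a_un.data(), a_sem.data(), r3a, P, S);
    }
  }
  // step 3b: semantic activation -> untreated map; retrain phonetic<->
  // phonetic links
  if (r3b > 0.0) {
    shuffle_vec(ord);
    for (int k = 0; k < n; ++k) {
      const int i = ord[k];
      if (!passes(cond3b, i)) continue;
      const int r = treat_rows[i];
      const int ws = winner_t(semWt, semAlive, semVt.colptr(r));
      const int wp = winner_t(trWt, trAlive, trVt.colptr(r));
      if (ws < 0 || wp < 0) continue;
      bump_t(a_sem.data(), S, ncs, ws, act_sigma, semAlive);
      transfer_t(a_un.data(), Lt_sun, a_sem.data(), S, P);
      peak_normalize(a_un.data(), P);
      bump_t(a_tr.data(), P, ncp, wp, act_sigma, trAlive);
      hebb_t(Lt_trun, a_tr.data(), a_un.data(), r3b, P, P);
      hebb_t(Lt_untr, a_un.data(), a_tr.data(), r3b, P, P);
    }
  }

  // probe naming of the treatment set in both languages
  double s1 = 0.0, s2 = 0.0;
  for (int i = 0; i < n; ++i) {
    const int r = treat_rows[i];
    const int ws = winner_t(semWt, semAlive, semVt.colptr(r));
    if (ws < 0) continue;
    bump_t(a_sem.data(), S, ncs, ws, act_sigma, semAlive);
    transfer_t(ap.data(), Lt_s1, a_sem.data(), S, P);
    const int u1 = argmax_alive(ap.data(), p1Alive, P);
    if (u1 >= 0 && p1Labels[u1] != NA_INTEGER && p1Labels[u1] == word_ids[r])
      s1 += 1.0;
    transfer_t(ap.data(), Lt_s2, a_sem.data(), S, P);
    const int u2 = argmax_alive(ap.data(), p2Alive, P);
    if (u2 >= 0 && p2Labels[u2] != NA_INTEGER && p2Labels[u2] == word_ids[r])
      s2 += 1.0;
  }
  return List::create(
    _["semW"] = semWt.t(), _["p1W"] = p1Wt.t(), _["p2W"] = p2Wt.t(),
    _["L_s1"] = Lt_s1.t(), _["L_1s"] = Lt_1s.t(), _["L_s2"] = Lt_s2.t(),
    _["L_2s"] = Lt_2s.t(), _["L_12"] = Lt_12.t(), _["L_21"] = Lt_21.t(),
    _["score_L1"] = s1 / n, _["score_L2"] = s2 / n,
    _["named"] = named, _["translatable"] = transl);
}
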