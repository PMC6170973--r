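// Collapsed Bernoulli-mixture allocation sampler.
//
// Items (allergen components) are rows of a binary matrix X (n x J); each
// cluster k has, per subject j, a Bernoulli success probability integrated
// out under a Beta(a, b) prior; mixture weights are integrated out under a
// symmetric Dirichlet(g) prior; K carries its own prior (uniform or
// truncated Poisson). The state is (K, z) with z the allocation vector;
// empty labels are permitted. All randomness comes from R's RNG so runs are
// reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Params {
  int n, J, Kmax;
  double a, b, g;
  std::vector<double> logpk;            // log prior on K, index K-1
  // lookup tables over integer counts 0..n
  std::vector<double> la, lb, lab;      // log(a+c), log(b+c), log(a+b+c)
  std::vector<double> ga, gb, gab;      // lgamma(a+c), lgamma(b+c), lgamma(a+b+c)
  double lbeta_ab;
  const int* X;                         // column-major n x J

  int x(int i, int j) const { return X[i + (size_t)n * j]; }
};

Params make_params(const IntegerMatrix& X, int Kmax, double a, double b,
                   double g, const NumericVector& logpk) {
  Params P;
  P.n = X.nrow(); P.J = X.ncol(); P.Kmax = Kmax;
  P.a = a; P.b = b; P.g = g;
  P.logpk.assign(logpk.begin(), logpk.end());
  P.la.resize(P.n + 2); P.lb.resize(P.n + 2); P.lab.resize(P.n + 2);
  P.ga.resize(P.n + 2); P.gb.resize(P.n + 2); P.gab.resize(P.n + 2);
  for (int c = 0; c <= P.n + 1; ++c) {
    P.la[c] = std::log(a + c);
    P.lb[c] = std::log(b + c);
    P.lab[c] = std::log(a + b + c);
    P.ga[c] = R::lgammafn(a + c);
    P.gb[c] = R::lgammafn(b + c);
    P.gab[c] = R::lgammafn(a + b + c);
  }
  P.lbeta_ab = R::lbeta(a, b);
  P.X = X.begin();
  return P;
}

struct Chain {
  int K;
  std::vector<int> z;      // 0-based labels
  std::vector<int> m;      // cluster sizes, length Kmax
  std::vector<int> S;      // per-cluster per-subject positive counts, Kmax x J
  std::vector<double> L;   // per-cluster collapsed log marginal likelihood
  double lp;               // untempered log posterior (cached)
};

// collapsed log marginal likelihood of one cluster from its counts
double row_L(const Params& P, const int* s, int m) {
  if (m == 0) return 0.0;
  double tot = 0.0;
  for (int j = 0; j < P.J; ++j)
    tot += P.ga[s[j]] + P.gb[m - s[j]];
  tot -= P.J * (P.gab[m] + P.lbeta_ab);
  return tot;
}

double alloc_term(const Params& P, const Chain& ch) {
  double t = R::lgammafn(ch.K * P.g) - R::lgammafn(P.n + ch.K * P.g);
  for (int k = 0; k < ch.K; ++k)
    t += R::lgammafn(ch.m[k] + P.g) - R::lgammafn(P.g);
  return t;
}

double full_lp(const Params& P, const Chain& ch) {
  double t = P.logpk[ch.K - 1] + alloc_term(P, ch);
  for (int k = 0; k < ch.K; ++k) t += ch.L[k];
  return t;
}

Chain init_chain(const Params& P, const std::vector<int>& z, int K) {
  Chain ch;
  ch.K = K;
  ch.z = z;
  ch.m.assign(P.Kmax, 0);
  ch.S.assign((size_t)P.Kmax * P.J, 0);
  ch.L.assign(P.Kmax, 0.0);
  for (int i = 0; i < P.n; ++i) {
    int k = z[i];
    ch.m[k]++;
    int* s = &ch.S[(size_t)k * P.J];
    for (int j = 0; j < P.J; ++j) s[j] += P.x(i, j);
  }
  for (int k = 0; k < K; ++k)
    ch.L[k] = row_L(P, &ch.S[(size_t)k * P.J], ch.m[k]);
  ch.lp = full_lp(P, ch);
  return ch;
}

void refresh_cache(const Params& P, Chain& ch) {
  for (int k = 0; k < ch.K; ++k)
    ch.L[k] = row_L(P, &ch.S[(size_t)k * P.J], ch.m[k]);
  ch.lp = full_lp(P, ch);
}

// log predictive of adding item i to cluster k (item currently not in k)
double pred_add(const Params& P, const Chain& ch, int k, int i) {
  const int* s = &ch.S[(size_t)k * P.J];
  int mk = ch.m[k];
  double tot = -(double)P.J * P.lab[mk];
  for (int j = 0; j < P.J; ++j)
    tot += P.x(i, j) ? P.la[s[j]] : P.lb[mk - s[j]];
  return tot;
}

void add_item(const Params& P, Chain& ch, int k, int i) {
  int* s = &ch.S[(size_t)k * P.J];
  for (int j = 0; j < P.J; ++j) s[j] += P.x(i, j);
  ch.m[k]++;
  ch.z[i] = k;
}

void remove_item(const Params& P, Chain& ch, int i) {
  int k = ch.z[i];
  int* s = &ch.S[(size_t)k * P.J];
  for (int j = 0; j < P.J; ++j) s[j] -= P.x(i, j);
  ch.m[k]--;
}

struct MoveStats {
  long att_gibbs = 0, att_m1 = 0, att_m2 = 0, att_m3 = 0, att_ej = 0, att_ab = 0;
  long acc_m1 = 0, acc_m2 = 0, acc_m3 = 0, acc_ej = 0, acc_ab = 0;
};

// one full-conditional Gibbs sweep over all items
void gibbs_sweep_chain(const Params& P, Chain& ch, double beta) {
  std::vector<double> pred(ch.K), w(ch.K);
  for (int i = 0; i < P.n; ++i) {
    remove_item(P, ch, i);
    int k0 = ch.z[i];
    double p0 = pred_add(P, ch, k0, i);
    ch.L[k0] -= p0;
    ch.lp -= p0 + std::log(ch.m[k0] + P.g);
    double wmax = R_NegInf;
    for (int k = 0; k < ch.K; ++k) {
      pred[k] = pred_add(P, ch, k, i);
      w[k] = beta * (pred[k] + std::log(ch.m[k] + P.g));
      if (w[k] > wmax) wmax = w[k];
    }
    double tot = 0.0;
    for (int k = 0; k < ch.K; ++k) { w[k] = std::exp(w[k] - wmax); tot += w[k]; }
    double u = unif_rand() * tot, cum = 0.0;
    int ks = ch.K - 1;
    for (int k = 0; k < ch.K; ++k) { cum += w[k]; if (u <= cum) { ks = k; break; } }
    double lpre = std::log(ch.m[ks] + P.g);
    add_item(P, ch, ks, i);
    ch.L[ks] += pred[ks];
    ch.lp += pred[ks] + lpre;
  }
}

// pick an ordered pair of distinct labels
void pick_pair(int K, int& k1, int& k2) {
  k1 = (int)(unif_rand() * K); if (k1 >= K) k1 = K - 1;
  k2 = (int)(unif_rand() * (K - 1)); if (k2 >= K - 1) k2 = K - 2;
  if (k2 >= k1) k2++;
}

// M1: each member of two clusters switches sides with probability 1/2
void move_m1(const Params& P, Chain& ch, double beta, MoveStats& st) {
  if (ch.K < 2) return;
  st.att_m1++;
  int k1, k2; pick_pair(ch.K, k1, k2);
  std::vector<int> un;
  for (int i = 0; i < P.n; ++i)
    if (ch.z[i] == k1 || ch.z[i] == k2) un.push_back(i);
  if (un.empty()) { st.acc_m1++; return; }
  std::vector<int> tmp1(&ch.S[(size_t)k1 * P.J], &ch.S[(size_t)k1 * P.J] + P.J);
  std::vector<int> tmp2(&ch.S[(size_t)k2 * P.J], &ch.S[(size_t)k2 * P.J] + P.J);
  int m1 = ch.m[k1], m2 = ch.m[k2];
  std::vector<int> flip;
  for (int i : un) {
    if (unif_rand() < 0.5) {
      flip.push_back(i);
      int sgn1 = (ch.z[i] == k1) ? -1 : 1;
      for (int j = 0; j < P.J; ++j) {
        int xv = P.x(i, j);
        tmp1[j] += sgn1 * xv;
        tmp2[j] -= sgn1 * xv;
      }
      m1 += sgn1; m2 -= sgn1;
    }
  }
  double nL1 = row_L(P, tmp1.data(), m1);
  double nL2 = row_L(P, tmp2.data(), m2);
  double dlp = nL1 + nL2 - ch.L[k1] - ch.L[k2]
    + R::lgammafn(m1 + P.g) + R::lgammafn(m2 + P.g)
    - R::lgammafn(ch.m[k1] + P.g) - R::lgammafn(ch.m[k2] + P.g);
  if (std::log(unif_rand()) < beta * dlp) {
    std::copy(tmp1.begin(), tmp1.end(), &ch.S[(size_t)k1 * P.J]);
    std::copy(tmp2.begin(), tmp2.end(), &ch.S[(size_t)k2 * P.J]);
    ch.m[k1] = m1; ch.m[k2] = m2;
    for (int i : flip) ch.z[i] = (ch.z[i] == k1) ? k2 : k1;
    ch.L[k1] = nL1; ch.L[k2] = nL2;
    ch.lp += dlp;
    st.acc_m1++;
  }
}

// M2: move a Binomial(p) subset of one cluster into another; with p ~ U(0,1)
// the marginal proposal probability of a d-subset is 1/((m1+1)*choose(m1,d))
void move_m2(const Params& P, Chain& ch, double beta, MoveStats& st) {
  if (ch.K < 2) return;
  st.att_m2++;
  int k1, k2; pick_pair(ch.K, k1, k2);
  int m1 = ch.m[k1], m2 = ch.m[k2];
  double p = unif_rand();
  std::vector<int> moved;
  for (int i = 0; i < P.n; ++i)
    if (ch.z[i] == k1 && unif_rand() < p) moved.push_back(i);
  int d = (int)moved.size();
  if (d == 0) { st.acc_m2++; return; }
  std::vector<int> tmp1(&ch.S[(size_t)k1 * P.J], &ch.S[(size_t)k1 * P.J] + P.J);
  std::vector<int> tmp2(&ch.S[(size_t)k2 * P.J], &ch.S[(size_t)k2 * P.J] + P.J);
  for (int i : moved)
    for (int j = 0; j < P.J; ++j) {
      int xv = P.x(i, j);
      tmp1[j] -= xv; tmp2[j] += xv;
    }
  double nL1 = row_L(P, tmp1.data(), m1 - d);
  double nL2 = row_L(P, tmp2.data(), m2 + d);
  double dlp = nL1 + nL2 - ch.L[k1] - ch.L[k2]
    + R::lgammafn(m1 - d + P.g) + R::lgammafn(m2 + d + P.g)
    - R::lgammafn(m1 + P.g) - R::lgammafn(m2 + P.g);
  double lqf = -std::log(m1 + 1.0) - R::lchoose(m1, d);
  double lqr = -std::log(m2 + d + 1.0) - R::lchoose(m2 + d, d);
  if (std::log(unif_rand()) < beta * dlp + lqr - lqf) {
    std::copy(tmp1.begin(), tmp1.end(), &ch.S[(size_t)k1 * P.J]);
    std::copy(tmp2.begin(), tmp2.end(), &ch.S[(size_t)k2 * P.J]);
    ch.m[k1] = m1 - d; ch.m[k2] = m2 + d;
    for (int i : moved) ch.z[i] = k2;
    ch.L[k1] = nL1; ch.L[k2] = nL2;
    ch.lp += dlp;
    st.acc_m2++;
  }
}

// restricted two-cluster full-conditional log-probability of choosing k1
double restricted_lp1(const Params& P, const Chain& ch, int k1, int k2,
                      int i, double beta, double& pred1, double& pred2) {
  pred1 = pred_add(P, ch, k1, i);
  pred2 = pred_add(P, ch, k2, i);
  double w1 = beta * (pred1 + std::log(ch.m[k1] + P.g));
  double w2 = beta * (pred2 + std::log(ch.m[k2] + P.g));
  double mx = std::max(w1, w2);
  double lse = mx + std::log(std::exp(w1 - mx) + std::exp(w2 - mx));
  return w1 - lse;
}

// M3: sequentially reallocate the union of two clusters from their
// restricted full conditionals; Metropolis-Hastings corrected
void move_m3(const Params& P, Chain& ch, double beta, MoveStats& st) {
  if (ch.K < 2) return;
  st.att_m3++;
  int k1, k2; pick_pair(ch.K, k1, k2);
  std::vector<int> un;
  for (int i = 0; i < P.n; ++i)
    if (ch.z[i] == k1 || ch.z[i] == k2) un.push_back(i);
  if (un.empty()) { st.acc_m3++; return; }
  std::vector<int> oldz(un.size());
  for (size_t t = 0; t < un.size(); ++t) oldz[t] = ch.z[un[t]];
  int om1 = ch.m[k1], om2 = ch.m[k2];
  double oL1 = ch.L[k1], oL2 = ch.L[k2];

  // reverse-proposal probability: replay the current allocation
  for (int i : un) remove_item(P, ch, i);
  double lqr = 0.0, pred1, pred2;
  for (size_t t = 0; t < un.size(); ++t) {
    int i = un[t];
    double lp1 = restricted_lp1(P, ch, k1, k2, i, beta, pred1, pred2);
    double lp2 = std::log1p(-std::min(1.0 - 1e-300, std::exp(lp1)));
    lqr += (oldz[t] == k1) ? lp1 : lp2;
    add_item(P, ch, oldz[t], i);
  }

  // forward: sample a fresh allocation of the union
  for (int i : un) remove_item(P, ch, i);
  double lqf = 0.0, aL1 = 0.0, aL2 = 0.0;
  for (size_t t = 0; t < un.size(); ++t) {
    int i = un[t];
    double lp1 = restricted_lp1(P, ch, k1, k2, i, beta, pred1, pred2);
    double p1 = std::exp(lp1);
    int kc;
    if (unif_rand() < p1) { kc = k1; lqf += lp1; aL1 += pred1; }
    else { kc = k2; lqf += std::log1p(-std::min(1.0 - 1e-300, p1)); aL2 += pred2; }
    add_item(P, ch, kc, i);
  }
  double dlp = aL1 + aL2 - oL1 - oL2
    + R::lgammafn(ch.m[k1] + P.g) + R::lgammafn(ch.m[k2] + P.g)
    - R::lgammafn(om1 + P.g) - R::lgammafn(om2 + P.g);
  if (std::log(unif_rand()) < beta * dlp + lqr - lqf) {
    ch.L[k1] = aL1; ch.L[k2] = aL2;
    ch.lp += dlp;
    st.acc_m3++;
  } else {
    for (int i : un) remove_item(P, ch, i);
    for (size_t t = 0; t < un.size(); ++t) add_item(P, ch, oldz[t], un[t]);
  }
}

// Eject: split a Binomial subset of one cluster into new top label K;
// Absorb: merge top label K-1 into a chosen lower label. The two moves are
// exact reverses of one another, giving a simple detailed-balance pair.
void move_eject_absorb(const Params& P, Chain& ch, double beta, MoveStats& st) {
  if (unif_rand() < 0.5) {               // eject
    if (ch.K >= P.Kmax) return;
    st.att_ej++;
    int k1 = (int)(unif_rand() * ch.K); if (k1 >= ch.K) k1 = ch.K - 1;
    int m1 = ch.m[k1];
    double p = unif_rand();
    std::vector<int> moved;
    for (int i = 0; i < P.n; ++i)
      if (ch.z[i] == k1 && unif_rand() < p) moved.push_back(i);
    int d = (int)moved.size();
    int knew = ch.K;
    std::vector<int> tmp1(&ch.S[(size_t)k1 * P.J], &ch.S[(size_t)k1 * P.J] + P.J);
    std::vector<int> tmpn(P.J, 0);
    for (int i : moved)
      for (int j = 0; j < P.J; ++j) {
        int xv = P.x(i, j);
        tmp1[j] -= xv; tmpn[j] += xv;
      }
    double nL1 = row_L(P, tmp1.data(), m1 - d);
    double nLn = row_L(P, tmpn.data(), d);
    int K = ch.K;
    double dlp = P.logpk[K] - P.logpk[K - 1]
      + R::lgammafn((K + 1) * P.g) - R::lgammafn(P.n + (K + 1) * P.g)
      - R::lgammafn(K * P.g) + R::lgammafn(P.n + K * P.g)
      + R::lgammafn(m1 - d + P.g) + R::lgammafn(d + P.g)
      - R::lgammafn(m1 + P.g) - R::lgammafn(P.g)
      + nL1 + nLn - ch.L[k1];
    double lrat = std::log(m1 + 1.0) + R::lchoose(m1, d);
    if (std::log(unif_rand()) < beta * dlp + lrat) {
      std::copy(tmp1.begin(), tmp1.end(), &ch.S[(size_t)k1 * P.J]);
      std::copy(tmpn.begin(), tmpn.end(), &ch.S[(size_t)knew * P.J]);
      ch.m[k1] = m1 - d; ch.m[knew] = d;
      for (int i : moved) ch.z[i] = knew;
      ch.L[k1] = nL1; ch.L[knew] = nLn;
      ch.K = K + 1;
      ch.lp += dlp;
      st.acc_ej++;
    }
  } else {                               // absorb
    if (ch.K <= 1) return;
    st.att_ab++;
    int K = ch.K, t = K - 1;
    int k2 = (int)(unif_rand() * (K - 1)); if (k2 >= K - 1) k2 = K - 2;
    int d = ch.m[t], m2 = ch.m[k2];
    std::vector<int> tmp(&ch.S[(size_t)k2 * P.J], &ch.S[(size_t)k2 * P.J] + P.J);
    const int* st_ = &ch.S[(size_t)t * P.J];
    for (int j = 0; j < P.J; ++j) tmp[j] += st_[j];
    double nL2 = row_L(P, tmp.data(), m2 + d);
    double dlp = P.logpk[K - 2] - P.logpk[K - 1]
      + R::lgammafn((K - 1) * P.g) - R::lgammafn(P.n + (K - 1) * P.g)
      - R::lgammafn(K * P.g) + R::lgammafn(P.n + K * P.g)
      + R::lgammafn(m2 + d + P.g) - R::lgammafn(m2 + P.g)
      - R::lgammafn(d + P.g) + R::lgammafn(P.g)
      + nL2 - ch.L[k2] - ch.L[t];
    double lrat = -std::log(m2 + d + 1.0) - R::lchoose(m2 + d, d);
    if (std::log(unif_rand()) < beta * dlp + lrat) {
      std::copy(tmp.begin(), tmp.end(), &ch.S[(size_t)k2 * P.J]);
      std::fill(&ch.S[(size_t)t * P.J], &ch.S[(size_t)t * P.J] + P.J, 0);
      for (int i = 0; i < P.n; ++i) if (ch.z[i] == t) ch.z[i] = k2;
      ch.m[k2] = m2 + d; ch.m[t] = 0;
      ch.L[k2] = nL2; ch.L[t] = 0.0;
      ch.K = K - 1;
      ch.lp += dlp;
      st.acc_ab++;
    }
  }
}

void sweep_chain(const Params& P, Chain& ch, double beta, MoveStats& st,
                 const bool* mv) {
  if (mv[0]) { st.att_gibbs++; gibbs_sweep_chain(P, ch, beta); }
  if (mv[1]) move_m1(P, ch, beta, st);
  if (mv[2]) move_m2(P, ch, beta, st);
  if (mv[3]) move_m3(P, ch, beta, st);
  if (mv[4]) move_eject_absorb(P, ch, beta, st);
}

std::vector<int> to_z0(const IntegerVector& z) {
  std::vector<int> out(z.size());
  for (int i = 0; i < z.size(); ++i) out[i] = z[i] - 1;
  return out;
}

} // namespace

// [[Rcpp::export(name = ".mc3_run_cpp")]]
List mc3_run_cpp(IntegerMatrix X, int Kmax, double a, double b, double g,
                 NumericVector log_k_prior, NumericVector betas,
                 int n_sweeps, int n_burn, int thin, LogicalVector do_moves) {
  Params P = make_params(X, Kmax, a, b, g, log_k_prior);
  int C = betas.size();
  bool mv[5];
  for (int t = 0; t < 5; ++t) mv[t] = do_moves[t];

  std::vector<Chain> chains;
  std::vector<int> z0(P.n, 0);
  for (int c = 0; c < C; ++c) chains.push_back(init_chain(P, z0, 1));

  int n_keep = 0;
  for (int s = 1; s <= n_sweeps; ++s)
    if (s > n_burn && (s - n_burn) % thin == 0) n_keep++;

  IntegerVector Kout(n_keep), sweep_out(n_keep);
  NumericVector lpout(n_keep);
  IntegerMatrix zout(n_keep, P.n);
  MoveStats cold;
  std::vector<MoveStats> hot(C);
  std::vector<long> swap_att(std::max(C - 1, 0), 0), swap_acc(std::max(C - 1, 0), 0);

  int idx = 0;
  for (int s = 1; s <= n_sweeps; ++s) {
    for (int c = 0; c < C; ++c)
      sweep_chain(P, chains[c], betas[c], c == 0 ? cold : hot[c], mv);
    if (C > 1) {
      int c = (int)(unif_rand() * (C - 1)); if (c >= C - 1) c = C - 2;
      swap_att[c]++;
      double la_ = (betas[c] - betas[c + 1]) * (chains[c + 1].lp - chains[c].lp);
      if (std::log(unif_rand()) < la_) {
        std::swap(chains[c], chains[c + 1]);
        swap_acc[c]++;
      }
    }
    if ((s & 511) == 0)
      for (int c = 0; c < C; ++c) refresh_cache(P, chains[c]);
    if (s > n_burn && (s - n_burn) % thin == 0) {
      const Chain& ch = chains[0];
      Kout[idx] = ch.K;
      lpout[idx] = ch.lp;
      sweep_out[idx] = s;
      for (int i = 0; i < P.n; ++i) zout(idx, i) = ch.z[i] + 1;
      idx++;
    }
    if ((s & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  if (idx > 0 && !R_finite(lpout[idx - 1]))
    stop("non-finite log posterior encountered; aborting");

  NumericVector sw_att(swap_att.begin(), swap_att.end());
  NumericVector sw_acc(swap_acc.begin(), swap_acc.end());
  return List::create(
    _["sweep"] = sweep_out,
    _["K"] = Kout,
    _["z"] = zout,
    _["log_post"] = lpout,
    _["accept"] = List::create(
      _["gibbs_sweeps"] = (double)cold.att_gibbs,
      _["m1"] = NumericVector::create(cold.att_m1, cold.acc_m1),
      _["m2"] = NumericVector::create(cold.att_m2, cold.acc_m2),
      _["m3"] = NumericVector::create(cold.att_m3, cold.acc_m3),
      _["eject"] = NumericVector::create(cold.att_ej, cold.acc_ej),
      _["absorb"] = NumericVector::create(cold.att_ab, cold.acc_ab)),
    _["swap_attempts"] = sw_att,
    _["swap_accepts"] = sw_acc);
}

// [[Rcpp::export(name = ".bmm_step_cpp")]]
List bmm_step_cpp(IntegerMatrix X, IntegerVector z, int K, int Kmax,
                  double a, double b, double g, NumericVector log_k_prior,
                  double beta, LogicalVector do_moves) {
  Params P = make_params(X, Kmax, a, b, g, log_k_prior);
  Chain ch = init_chain(P, to_z0(z), K);
  bool mv[5];
  for (int t = 0; t < 5; ++t) mv[t] = do_moves[t];
  MoveStats st;
  sweep_chain(P, ch, beta, st, mv);
  IntegerVector zo(P.n);
  for (int i = 0; i < P.n; ++i) zo[i] = ch.z[i] + 1;
  return List::create(_["z"] = zo, _["K"] = ch.K, _["log_post"] = ch.lp);
}

// [[Rcpp::export(name = ".full_conditional_cpp")]]
NumericVector full_conditional_cpp(IntegerMatrix X, IntegerVector z, int K,
                                   int i, double a, double b, double g,
                                   double beta) {
  NumericVector dummy(K);
  for (int k = 0; k < K; ++k) dummy[k] = 0.0;   // flat K prior: cancels
  Params P = make_params(X, K, a, b, g, dummy);
  Chain ch = init_chain(P, to_z0(z), K);
  int ii = i - 1;
  remove_item(P, ch, ii);
  NumericVector w(K);
  double wmax = R_NegInf;
  for (int k = 0; k < K; ++k) {
    w[k] = beta * (pred_add(P, ch, k, ii) + std::log(ch.m[k] + P.g));
    if (w[k] > wmax) wmax = w[k];
  }
  double tot = 0.0;
  for (int k = 0; k < K; ++k) { w[k] = std::exp(w[k] - wmax); tot += w[k]; }
  for (int k = 0; k < K; ++k) w[k] /= tot;
  return w;
}

// [[Rcpp::export(name = ".chain_log_post_cpp")]]
double chain_log_post_cpp(IntegerMatrix X, IntegerVector z, int K, int Kmax,
                          double a, double b, double g,
                          NumericVector log_k_prior) {
  Params P = make_params(X, Kmax, a, b, g, log_k_prior);
  Chain ch = init_chain(P, to_z0(z), K);
  return ch.lp;
}
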