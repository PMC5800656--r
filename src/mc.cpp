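#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Periodic 4-neighborhood on a column-major nr x nc lattice.
static inline void neighbors4(int idx, int nr, int nc, int out[4]) {
  int r = idx % nr, c = idx / nr;
  out[0] = (r == 0 ? nr - 1 : r - 1) + c * nr;
  out[1] = (r == nr - 1 ? 0 : r + 1) + c * nr;
  out[2] = r + (c == 0 ? nc - 1 : c - 1) * nr;
  out[3] = r + (c == nc - 1 ? 0 : c + 1) * nr;
}

static inline bool adjacent4(int a, int b, int nr, int nc) {
  int nb[4];
  neighbors4(a, nr, nc, nb);
  for (int i = 0; i < 4; ++i) if (nb[i] == b) return true;
  return false;
}

// Unordered target-target edges incident to sites a or b (shared edge a-b
// counted once), under the current mask.
static inline int cc_edges_local(const std::vector<char>& mask, int a, int b,
                                 int nr, int nc) {
  int nb[4], e = 0;
  if (mask[a]) {
    neighbors4(a, nr, nc, nb);
    for (int i = 0; i < 4; ++i) if (mask[nb[i]]) ++e;
  }
  if (mask[b]) {
    neighbors4(b, nr, nc, nb);
    for (int i = 0; i < 4; ++i) if (mask[nb[i]]) ++e;
  }
  if (mask[a] && mask[b] && adjacent4(a, b, nr, nc)) --e;
  return e;
}

// Greedy Metropolis refinement: swap a random target site with a random
// non-target site whenever the swap strictly reduces |p_CC - goal|.
// Conserves the target count exactly.
// [[Rcpp::export]]
List mh_refine_cpp(LogicalMatrix mask_in, double p_cc_target, double tol,
                   double max_iter) {
  int nr = mask_in.nrow(), nc = mask_in.ncol(), n = nr * nc;
  std::vector<char> mask(n);
  std::vector<int> targets, others;
  for (int i = 0; i < n; ++i) {
    mask[i] = mask_in[i] ? 1 : 0;
    if (mask[i]) targets.push_back(i); else others.push_back(i);
  }
  if (targets.empty() || others.empty())
    stop("saturated lattice: nothing to swap");
  long long cc2 = 0;  // ordered target-target adjacency count
  int nb[4];
  for (int i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    neighbors4(i, nr, nc, nb);
    for (int k = 0; k < 4; ++k) if (mask[nb[k]]) ++cc2;
  }
  const double denom = 4.0 * n;
  const double goal = p_cc_target * denom;
  const double tolcnt = tol * denom;
  double iter = 0;
  while (std::fabs((double)cc2 - goal) >= tolcnt && iter < max_iter) {
    ++iter;
    int ia = (int)(unif_rand() * targets.size());
    int ib = (int)(unif_rand() * others.size());
    int a = targets[ia], b = others[ib];
    int before = cc_edges_local(mask, a, b, nr, nc);
    mask[a] = 0; mask[b] = 1;
    int after = cc_edges_local(mask, a, b, nr, nc);
    long long cand = cc2 + 2LL * (after - before);
    if (std::fabs((double)cand - goal) < std::fabs((double)cc2 - goal)) {
      cc2 = cand;
      targets[ia] = b;
      others[ib] = a;
    } else {
      mask[a] = 1; mask[b] = 0;  // reject (ties included)
    }
  }
  LogicalMatrix out(nr, nc);
  for (int i = 0; i < n; ++i) out[i] = mask[i] != 0;
  return List::create(_["mask"] = out, _["iterations"] = iter,
                      _["p_CC"] = (double)cc2 / denom);
}

// Synchronous stochastic SIS updates on the lattice. Site codes: -1
// non-target, 0 susceptible target, k in 1..K infected by strain k.
// Per step, a susceptible target is infected with probability
// 1 - exp(-h dt), h = sum_k beta_G G_k x_{I_k} + beta_L L_k n_k / 4
// (x_{I_k} the whole-lattice density of strain k, n_k its count among the 4
// neighbors); the infecting strain is drawn proportionally to its hazard
// contribution and mutates to an adjacent grid strain with probability mu
// (half each side, bouncing off the grid ends). Infected sites recover with
// probability 1 - exp(-alpha dt). All events in one step use the state at
// the start of the step.
// [[Rcpp::export]]
List mc_simulate_cpp(IntegerMatrix state0, NumericVector G, double tradeoff_s,
                     double betaG, double betaL, double alpha, double dt,
                     int nsteps, double mu, int record_every,
                     bool record_strains) {
  int nr = state0.nrow(), nc = state0.ncol(), n = nr * nc;
  int K = G.size();
  std::vector<double> lw(K), gcoef(K);
  for (int k = 0; k < K; ++k) {
    double L = 1.0 - std::pow(G[k], tradeoff_s);
    lw[k] = betaL * L * 0.25;
    gcoef[k] = betaG * G[k];
  }
  std::vector<int> cur(state0.begin(), state0.end()), nxt(n);
  const double p_rec = 1.0 - std::exp(-alpha * dt);
  if (p_rec > 0.1 + 1e-12)
    stop("per-site recovery probability exceeds 0.1 per step; reduce dt");
  int nrec = nsteps / record_every + 1;
  NumericVector rec_t(nrec), rec_ninf(nrec), rec_meanG(nrec);
  NumericMatrix rec_counts = record_strains ? NumericMatrix(nrec, K)
                                            : NumericMatrix(0, 0);
  std::vector<double> cnt(K), glob(K);
  bool extinct = false;
  double t_extinct = NA_REAL;
  int nb[4], irec = 0;

  auto record = [&](int step) {
    double ninf = 0, sumG = 0;
    for (int k = 0; k < K; ++k) { ninf += cnt[k]; sumG += cnt[k] * G[k]; }
    rec_t[irec] = step * dt;
    rec_ninf[irec] = ninf;
    rec_meanG[irec] = ninf > 0 ? sumG / ninf : NA_REAL;
    if (record_strains)
      for (int k = 0; k < K; ++k) rec_counts(irec, k) = cnt[k];
    ++irec;
  };

  auto tally = [&]() {
    std::fill(cnt.begin(), cnt.end(), 0.0);
    for (int i = 0; i < n; ++i) if (cur[i] > 0) cnt[cur[i] - 1] += 1.0;
  };

  tally();
  record(0);
  for (int step = 1; step <= nsteps; ++step) {
    if (step % 4096 == 0) Rcpp::checkUserInterrupt();
    double sumGlob = 0;
    for (int k = 0; k < K; ++k) {
      glob[k] = gcoef[k] * cnt[k] / n;
      sumGlob += glob[k];
    }
    for (int i = 0; i < n; ++i) {
      int st = cur[i];
      if (st < 0) { nxt[i] = -1; continue; }
      if (st > 0) { nxt[i] = (unif_rand() < p_rec) ? 0 : st; continue; }
      // susceptible target cell
      double lh = 0;
      neighbors4(i, nr, nc, nb);
      for (int j = 0; j < 4; ++j) {
        int ns = cur[nb[j]];
        if (ns > 0) lh += lw[ns - 1];
      }
      double h = sumGlob + lh;
      if (h <= 0) { nxt[i] = 0; continue; }
      double p = 1.0 - std::exp(-h * dt);
      if (p > 0.1 + 1e-12)
        stop("per-site infection probability exceeds 0.1 per step; reduce dt");
      if (unif_rand() >= p) { nxt[i] = 0; continue; }
      // pick the infecting strain proportional to hazard contributions
      double u = unif_rand() * h;
      int chosen = -1;
      for (int j = 0; j < 4 && chosen < 0; ++j) {
        int ns = cur[nb[j]];
        if (ns > 0) { u -= lw[ns - 1]; if (u < 0) chosen = ns; }
      }
      if (chosen < 0) {
        for (int k = 0; k < K && chosen < 0; ++k) {
          u -= glob[k];
          if (u < 0) chosen = k + 1;
        }
      }
      if (chosen < 0) {  // numerical spill: last contributing strain
        for (int k = K - 1; k >= 0; --k) if (cnt[k] > 0) { chosen = k + 1; break; }
        if (chosen < 0) { nxt[i] = 0; continue; }
      }
      if (mu > 0 && K > 1 && unif_rand() < mu) {
        chosen += (unif_rand() < 0.5) ? -1 : 1;
        if (chosen < 1) chosen = 2;
        if (chosen > K) chosen = K - 1;
      }
      nxt[i] = chosen;
    }
    std::swap(cur, nxt);
    tally();
    double tot = 0;
    for (int k = 0; k < K; ++k) tot += cnt[k];
    if (step % record_every == 0 && irec < nrec) record(step);
    if (tot == 0) {
      extinct = true;
      t_extinct = step * dt;
      break;
    }
  }
  // the disease-free state is absorbing: pad any remaining records
  while (irec < nrec) {
    rec_t[irec] = (double)irec * record_every * dt;
    rec_ninf[irec] = 0;
    rec_meanG[irec] = NA_REAL;
    ++irec;
  }
  IntegerMatrix final_state(nr, nc);
  for (int i = 0; i < n; ++i) final_state[i] = cur[i];
  return List::create(_["time"] = rec_t, _["n_infected"] = rec_ninf,
                      _["mean_G"] = rec_meanG, _["strain_counts"] = rec_counts,
                      _["state"] = final_state, _["extinct"] = extinct,
                      _["t_extinct"] = t_extinct);
}
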