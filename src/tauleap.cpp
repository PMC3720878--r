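#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step binomial tau-leap engine for the reduced compartmental synapse
// model: receptors in the cleft, transporter pools in the perisynaptic and
// outer extracellular compartments, and free glutamate moving cleft -> peri
// -> outer -> sink by first-order escape. All molecule bookkeeping is
// integer, so conservation of receptors, transporters and glutamate
// (free + bound + absorbed) is exact by construction.
//
// molecules per nm^3 per molar (Avogadro * 1e-24 L/nm^3)
static const double MOL_PER_NM3_PER_M = 0.6022140857;

// Draw transitions for one molecular pool for one time step.
// counts: per-state molecule counts (updated in place).
// p[j] = per-molecule probability of transition j this step (before capping).
// Returns glutamate released back to the compartment; updates free_glu
// (consumption by ligand-binding transitions, clamped to availability) and
// absorbed (consuming transitions, e.g. transporter translocation).
static void step_pool(std::vector<int> &counts,
                      const IntegerVector &from, const IntegerVector &to,
                      const std::vector<double> &p,
                      const IntegerVector &dglu, const LogicalVector &consumes,
                      long long &free_glu, long long &absorbed,
                      long long &cap_events, long long &total_events) {
  const int ntr = from.size();
  std::vector<int> moves(ntr, 0);
  const int nstates = counts.size();
  for (int s = 0; s < nstates; ++s) {
    if (counts[s] <= 0) continue;
    double ptot = 0.0;
    for (int j = 0; j < ntr; ++j) if (from[j] == s) ptot += p[j];
    if (ptot <= 0.0) continue;
    double scale = 1.0;
    bool capped = false;
    if (ptot > 1.0) { scale = 1.0 / ptot; capped = true; }
    // sequential conditional binomials: multinomial over channels + stay
    double rem_p = 1.0;
    int avail = counts[s];
    for (int j = 0; j < ntr && avail > 0; ++j) {
      if (from[j] != s) continue;
      double pj = p[j] * scale;
      double pc = (rem_p > 0.0) ? pj / rem_p : 1.0;
      if (pc > 1.0) pc = 1.0;
      int x = (int) R::rbinom((double) avail, pc);
      moves[j] += x;
      avail -= x;
      rem_p -= pj;
      total_events += x;
      if (capped) cap_events += x;
    }
  }
  // clamp glutamate consumption to the free pool
  long long need = 0;
  for (int j = 0; j < ntr; ++j) if (dglu[j] > 0) need += (long long) moves[j] * dglu[j];
  if (need > free_glu) {
    long long avail_glu = free_glu;
    for (int j = 0; j < ntr; ++j) {
      if (dglu[j] <= 0) continue;
      long long take = std::min((long long) moves[j], avail_glu / dglu[j]);
      avail_glu -= take * dglu[j];
      moves[j] = (int) take;
    }
  }
  // apply
  for (int j = 0; j < ntr; ++j) {
    int x = moves[j];
    if (x == 0) continue;
    counts[from[j]] -= x;
    counts[to[j]] += x;
    if (dglu[j] > 0) {
      free_glu -= (long long) x * dglu[j];
    } else if (dglu[j] < 0) {
      if (consumes[j]) absorbed += (long long) x * (-dglu[j]);
      else free_glu += (long long) x * (-dglu[j]);
    }
  }
}

// [[Rcpp::export]]
List sim_tauleap_cpp(int steps, double dt,
                     IntegerVector r_init,
                     IntegerVector r_from, IntegerVector r_to,
                     NumericVector r_rate, IntegerVector r_order,
                     IntegerVector r_dglu, LogicalVector r_consumes,
                     int open_state,
                     IntegerVector tp_init, IntegerVector to_init,
                     IntegerVector t_from, IntegerVector t_to,
                     NumericVector t_rate, IntegerVector t_order,
                     IntegerVector t_dglu, LogicalVector t_consumes,
                     int glu0,
                     NumericVector volumes, NumericVector escape,
                     bool cleft_to_outer, bool keep_full) {
  const int nR = r_init.size(), nT = tp_init.size();
  const int nrt = r_from.size(), ntt = t_from.size();
  std::vector<int> rc(r_init.begin(), r_init.end());
  std::vector<int> tp(tp_init.begin(), tp_init.end());
  std::vector<int> tu(to_init.begin(), to_init.end());
  long long g_cleft = glu0, g_peri = 0, g_outer = 0, g_sink = 0, r_absorbed = 0;
  long long cap_events = 0, total_events = 0;
  const double v_cleft = volumes[0], v_peri = volumes[1], v_outer = volumes[2];
  const double p_cp = std::min(1.0, escape[0] * dt);
  const double p_po = std::min(1.0, escape[1] * dt);
  const double p_os = std::min(1.0, escape[2] * dt);
  long long n_receptors = 0;
  for (int s = 0; s < nR; ++s) n_receptors += rc[s];

  NumericVector open(steps + 1);
  IntegerMatrix full_r, full_tp, full_to;
  NumericMatrix full_glu;
  if (keep_full) {
    full_r = IntegerMatrix(steps + 1, nR);
    full_tp = IntegerMatrix(steps + 1, nT);
    full_to = IntegerMatrix(steps + 1, nT);
    full_glu = NumericMatrix(steps + 1, 4);
  }
  std::vector<double> pr(nrt), pt(ntt);

  for (int it = 0; it <= steps; ++it) {
    open[it] = rc[open_state];
    if (keep_full) {
      for (int s = 0; s < nR; ++s) full_r(it, s) = rc[s];
      for (int s = 0; s < nT; ++s) { full_tp(it, s) = tp[s]; full_to(it, s) = tu[s]; }
      full_glu(it, 0) = (double) g_cleft; full_glu(it, 1) = (double) g_peri;
      full_glu(it, 2) = (double) g_outer; full_glu(it, 3) = (double) g_sink;
    }
    if (it == steps) break;

    const double c_cleft = (v_cleft > 0) ? g_cleft / (MOL_PER_NM3_PER_M * v_cleft) : 0.0;
    const double c_peri  = (v_peri > 0) ? g_peri / (MOL_PER_NM3_PER_M * v_peri) : 0.0;
    const double c_outer = (v_outer > 0) ? g_outer / (MOL_PER_NM3_PER_M * v_outer) : 0.0;

    // receptors see the cleft concentration
    for (int j = 0; j < nrt; ++j)
      pr[j] = (r_order[j] == 1 ? r_rate[j] * c_cleft : r_rate[j]) * dt;
    step_pool(rc, r_from, r_to, pr, r_dglu, r_consumes,
              g_cleft, r_absorbed, cap_events, total_events);

    // transporter pools in the perisynaptic and outer compartments
    if (nT > 0 && ntt > 0) {
      long long tp_total = 0; for (int s = 0; s < nT; ++s) tp_total += tp[s];
      if (tp_total > 0) {
        for (int j = 0; j < ntt; ++j)
          pt[j] = (t_order[j] == 1 ? t_rate[j] * c_peri : t_rate[j]) * dt;
        step_pool(tp, t_from, t_to, pt, t_dglu, t_consumes,
                  g_peri, g_sink, cap_events, total_events);
      }
      long long tu_total = 0; for (int s = 0; s < nT; ++s) tu_total += tu[s];
      if (tu_total > 0) {
        for (int j = 0; j < ntt; ++j)
          pt[j] = (t_order[j] == 1 ? t_rate[j] * c_outer : t_rate[j]) * dt;
        step_pool(tu, t_from, t_to, pt, t_dglu, t_consumes,
                  g_outer, g_sink, cap_events, total_events);
      }
    }

    // glutamate escape, drawn in parallel from post-reaction pools
    int e_cp = (g_cleft > 0) ? (int) R::rbinom((double) g_cleft, p_cp) : 0;
    int e_po = (g_peri > 0) ? (int) R::rbinom((double) g_peri, p_po) : 0;
    int e_os = (g_outer > 0) ? (int) R::rbinom((double) g_outer, p_os) : 0;
    g_cleft -= e_cp;
    if (cleft_to_outer) g_outer += e_cp; else g_peri += e_cp;
    g_peri -= e_po; g_outer += e_po;
    g_outer -= e_os; g_sink += e_os;
  }

  List out = List::create(
    _["open_counts"] = open,
    _["n_receptors"] = (double) n_receptors,
    _["cap_events"] = (double) cap_events,
    _["total_events"] = (double) total_events);
  if (keep_full) {
    out["receptor_counts"] = full_r;
    out["transporter_peri"] = full_tp;
    out["transporter_outer"] = full_to;
    out["glutamate"] = full_glu;
  }
  return out;
}
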