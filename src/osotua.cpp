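#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Correlated disaster fields: M Gaussian clusters on the (location x year)
// lattice, sampled without replacement (distinct cells across the field).
// Space wraps on the ring; out-of-range temporal draws are redrawn.
// occ is column-major: cell (location x, year t) at index x + X*(t-1).
// ---------------------------------------------------------------------------
static void gen_field_core(int X, int T, double n_total, int m,
                           double sx, double st, std::vector<int> &occ) {
  std::fill(occ.begin(), occ.end(), 0);
  const int cap = 10000;
  for (int c = 0; c < m; ++c) {
    int cy = 1 + (int)(unif_rand() * T); if (cy > T) cy = T;
    int cx = (int)(unif_rand() * X);     if (cx >= X) cx = X - 1;
    long cnt = std::lround(R::rnorm(n_total / (double)m, 1.0));
    if (cnt < 0) cnt = 0;
    if (cnt == 0) continue;
    if (sx == 0.0 && st == 0.0) {
      // delta-distribution limit: the cluster collapses onto its mode
      occ[cx + X * (cy - 1)] = 1;
      continue;
    }
    long got = 0;
    int iter = 0;
    while (got < cnt && iter < cap) {
      ++iter;
      long yr = std::lround(R::rnorm((double)cy, st));
      if (yr < 1 || yr > T) continue;
      long lc = std::lround(R::rnorm((double)cx, sx)) % X;
      if (lc < 0) lc += X;
      int idx = (int)lc + X * ((int)yr - 1);
      if (!occ[idx]) { occ[idx] = 1; ++got; }
    }
    if (got < cnt) {
      // deterministic spill-out: nearest unoccupied cells, scaled distance
      double sxe = std::max(sx, 1e-9), ste = std::max(st, 1e-9);
      std::vector<std::pair<double, int> > cand;
      for (int t = 0; t < T; ++t) {
        for (int x = 0; x < X; ++x) {
          int idx = x + X * t;
          if (occ[idx]) continue;
          int dx = std::abs(x - cx); dx = std::min(dx, X - dx);
          int dt = std::abs(t + 1 - cy);
          cand.push_back(std::make_pair((dx / sxe) * (dx / sxe) +
                                        (dt / ste) * (dt / ste), idx));
        }
      }
      std::sort(cand.begin(), cand.end());
      long need = std::min(cnt - got, (long)cand.size());
      for (long j = 0; j < need; ++j) occ[cand[j].second] = 1;
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_generate_field(int x_extent, int t_extent, double n_total,
                                 int m_clusters, double sigma_x,
                                 double sigma_t) {
  std::vector<int> occ(x_extent * t_extent);
  gen_field_core(x_extent, t_extent, n_total, m_clusters, sigma_x, sigma_t,
                 occ);
  IntegerMatrix out(x_extent, t_extent);
  std::copy(occ.begin(), occ.end(), out.begin());
  return out;
}

// ---------------------------------------------------------------------------
// One 50-year run of the gift-giving survival dynamics. Year order:
// growth -> disaster loss -> need-based requests/gifts -> survival check.
// ---------------------------------------------------------------------------
struct SimOut {
  double survival_rate;
  int survivors;
  double surv_herd_sum;
  int eff_disasters;
};

static SimOut sim_core(int n, const std::vector<int> &adj_flat,
                       const std::vector<int> &adj_ptr,
                       const std::vector<int> &spatial, const int *occ, int X,
                       int t_years, double initial_herd, double thr,
                       double gm, double gs, double lm, double ls,
                       int death_lag, bool check_pre_gift, int retries,
                       bool ask_need, bool networked,
                       std::vector<double> &herd,
                       std::vector<char> &alive, int *gifts_per_year,
                       bool collect, std::vector<int> *g_year,
                       std::vector<int> *g_giver, std::vector<int> *g_recv,
                       std::vector<double> *g_amt) {
  herd.assign(n, initial_herd);
  alive.assign(n, 1);
  std::vector<int> below(n, 0);
  std::vector<double> check(n);
  std::vector<int> needy, nb;
  std::vector<char> hit(n, 0);
  needy.reserve(n);
  int eff = 0;
  for (int yr = 1; yr <= t_years; ++yr) {
    for (int i = 0; i < n; ++i) {
      if (!alive[i]) continue;
      double g = R::rnorm(gm, gs);
      if (g < -1.0) g = -1.0;
      herd[i] *= 1.0 + g;
    }
    std::fill(hit.begin(), hit.end(), 0);
    for (int i = 0; i < n; ++i) {
      if (!alive[i]) continue;
      if (occ[spatial[i] + X * (yr - 1)]) {
        ++eff;
        hit[i] = 1;
        double l = R::rnorm(lm, ls);
        if (l < 0.0) l = 0.0;
        if (l > 1.0) l = 1.0;
        herd[i] *= 1.0 - l;
      }
    }
    if (check_pre_gift) check = herd;
    if (networked) {
      needy.clear();
      for (int i = 0; i < n; ++i)
        if (alive[i] && herd[i] < thr && (ask_need || hit[i]))
          needy.push_back(i);
      // uniformly random processing order (Fisher-Yates)
      for (int i = (int)needy.size() - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(needy[i], needy[j]);
      }
      for (size_t q = 0; q < needy.size(); ++q) {
        int i = needy[q];
        nb.clear();
        for (int e = adj_ptr[i]; e < adj_ptr[i + 1]; ++e) {
          int v = adj_flat[e] - 1;  // 1-based ids in the flat adjacency
          if (alive[v]) nb.push_back(v);
        }
        if (nb.empty()) continue;
        double req = thr - herd[i];
        int ntry = std::min((int)nb.size(), 1 + retries);
        for (int t = 0; t < ntry; ++t) {
          int j = t + (int)(unif_rand() * (nb.size() - t));
          if (j >= (int)nb.size()) j = (int)nb.size() - 1;
          std::swap(nb[t], nb[j]);
          int p = nb[t];
          if (herd[p] - req >= thr) {  // all-or-nothing giving rule
            herd[p] -= req;
            herd[i] = thr;
            ++gifts_per_year[yr - 1];
            if (collect) {
              g_year->push_back(yr);
              g_giver->push_back(p + 1);
              g_recv->push_back(i + 1);
              g_amt->push_back(req);
            }
            break;
          }
        }
      }
    }
    const std::vector<double> &ch = check_pre_gift ? check : herd;
    for (int i = 0; i < n; ++i) {
      if (!alive[i]) continue;
      if (ch[i] < thr) {
        if (++below[i] >= death_lag) alive[i] = 0;
      } else {
        below[i] = 0;
      }
    }
  }
  SimOut out;
  out.survivors = 0;
  out.surv_herd_sum = 0.0;
  for (int i = 0; i < n; ++i) {
    if (alive[i]) {
      ++out.survivors;
      out.surv_herd_sum += herd[i];
    }
  }
  out.survival_rate = (double)out.survivors / n;
  out.eff_disasters = eff;
  return out;
}

// [[Rcpp::export]]
List cpp_run_sim(int n, IntegerVector adj_flat, IntegerVector adj_ptr,
                 IntegerVector spatial_index, IntegerMatrix occupancy,
                 int t_years, double initial_herd, double threshold,
                 double growth_mean, double growth_sd, double loss_mean,
                 double loss_sd, int death_lag, bool check_pre_gift,
                 int retries, bool ask_need, bool networked,
                 bool collect_gifts) {
  std::vector<int> af(adj_flat.begin(), adj_flat.end());
  std::vector<int> ap(adj_ptr.begin(), adj_ptr.end());
  if (!networked) ap.assign(n + 1, 0);
  std::vector<int> sp(spatial_index.begin(), spatial_index.end());
  std::vector<double> herd;
  std::vector<char> alive;
  IntegerVector gifts_per_year(t_years);
  std::vector<int> gy, gg, gr;
  std::vector<double> ga;
  SimOut out = sim_core(n, af, ap, sp, occupancy.begin(), occupancy.nrow(),
                        t_years, initial_herd, threshold, growth_mean,
                        growth_sd, loss_mean, loss_sd, death_lag,
                        check_pre_gift, retries, ask_need, networked,
                        herd, alive, gifts_per_year.begin(), collect_gifts,
                        &gy, &gg, &gr, &ga);
  LogicalVector alive_out(n);
  NumericVector herd_out(n);
  for (int i = 0; i < n; ++i) {
    alive_out[i] = (bool)alive[i];
    herd_out[i] = herd[i];
  }
  return List::create(
      _["herd"] = herd_out, _["alive"] = alive_out,
      _["effective_disasters"] = out.eff_disasters,
      _["gifts_per_year"] = gifts_per_year, _["gift_year"] = wrap(gy),
      _["gift_giver"] = wrap(gg), _["gift_receiver"] = wrap(gr),
      _["gift_amount"] = wrap(ga));
}

// Replicate driver: regenerates the disaster field per repetition (or keeps
// one field) and accumulates per-rep summaries; used by the sweep module.
// [[Rcpp::export]]
List cpp_run_reps(int n, IntegerVector adj_flat, IntegerVector adj_ptr,
                  IntegerVector spatial_index, int x_extent, int t_extent,
                  double n_total, int m_clusters, double sigma_x,
                  double sigma_t, int n_reps, int t_years,
                  double initial_herd, double threshold, double growth_mean,
                  double growth_sd, double loss_mean, double loss_sd,
                  int death_lag, bool check_pre_gift, int retries,
                  bool ask_need, bool networked, bool regenerate_field) {
  std::vector<int> af(adj_flat.begin(), adj_flat.end());
  std::vector<int> ap(adj_ptr.begin(), adj_ptr.end());
  if (!networked) ap.assign(n + 1, 0);
  std::vector<int> sp(spatial_index.begin(), spatial_index.end());
  std::vector<int> occ(x_extent * t_extent);
  NumericVector survival(n_reps), herd_sum(n_reps);
  IntegerVector survivors(n_reps), eff(n_reps), realized(n_reps);
  IntegerVector gifts_per_year(t_years);  // summed across reps
  std::vector<double> herd;
  std::vector<char> alive;
  bool have_field = false;
  for (int r = 0; r < n_reps; ++r) {
    if (regenerate_field || !have_field) {
      gen_field_core(x_extent, t_extent, n_total, m_clusters, sigma_x,
                     sigma_t, occ);
      have_field = true;
    }
    int nev = 0;
    for (size_t j = 0; j < occ.size(); ++j) nev += occ[j];
    realized[r] = nev;
    SimOut out = sim_core(n, af, ap, sp, occ.data(), x_extent, t_years,
                          initial_herd, threshold, growth_mean, growth_sd,
                          loss_mean, loss_sd, death_lag, check_pre_gift,
                          retries, ask_need, networked, herd, alive,
                          gifts_per_year.begin(), false, 0, 0, 0, 0);
    survival[r] = out.survival_rate;
    survivors[r] = out.survivors;
    herd_sum[r] = out.surv_herd_sum;
    eff[r] = out.eff_disasters;
  }
  return List::create(
      _["survival"] = survival, _["survivors"] = survivors,
      _["herd_sum"] = herd_sum, _["effective_disasters"] = eff,
      _["realized_events"] = realized,
      _["gifts_per_year_sum"] = gifts_per_year);
}
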