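#include <Rcpp.h>
using namespace Rcpp;

// Exact-time Gillespie simulation of the homogeneous birth-death process.
// Waiting times are exponential with total rate n*(lambda+mu); the event
// type is chosen lambda:mu and the affected lineage uniformly. Uses R's
// RNG so that set.seed() in R makes whole batches reproducible.
//
// conditioning: 0 = none, 1 = survival (>= 1 tip at T),
//               2 = size window (tip count in [nT_lo, nT_hi]).
//
// Each accepted tree is returned as a list with an event matrix
// (time, kind 1=speciation/0=extinction, lineage, child) and the vector
// of lineage ids alive at T.
// [[Rcpp::export]]
List bd_sim_batch_cpp(double lambda, double mu, double T, int n_trees,
                      int conditioning, int nT_lo, int nT_hi,
                      double max_events, double max_attempts) {
  List trees(n_trees);
  double attempts = 0;

  std::vector<double> ev_time;
  std::vector<int> ev_kind, ev_lin, ev_child, alive;

  for (int k = 0; k < n_trees; ++k) {
    bool accepted = false;
    while (!accepted) {
      if (attempts >= max_attempts) {
        double acc = attempts > 0 ? (double)k / attempts : 0.0;
        stop("max_attempts (%g) exceeded with %d accepted trees; "
             "estimated acceptance probability %g",
             max_attempts, k, acc);
      }
      attempts += 1;

      ev_time.clear(); ev_kind.clear(); ev_lin.clear(); ev_child.clear();
      alive.clear(); alive.push_back(1);
      int next_id = 2;
      double t = 0.0;
      bool ok = true;

      while (!alive.empty()) {
        int n_alive = (int)alive.size();
        double total_rate = n_alive * (lambda + mu);
        t += R::exp_rand() / total_rate;
        if (t >= T) break;
        if ((double)ev_time.size() >= max_events) { ok = false; break; }
        int idx = (int)(unif_rand() * n_alive);
        if (idx >= n_alive) idx = n_alive - 1;
        int lin = alive[idx];
        if (unif_rand() * (lambda + mu) < lambda) {
          ev_time.push_back(t); ev_kind.push_back(1);
          ev_lin.push_back(lin); ev_child.push_back(next_id);
          alive.push_back(next_id);
          ++next_id;
        } else {
          ev_time.push_back(t); ev_kind.push_back(0);
          ev_lin.push_back(lin); ev_child.push_back(NA_INTEGER);
          alive[idx] = alive.back();
          alive.pop_back();
        }
      }
      if (!ok) continue; // event cap hit: treat as a rejected attempt

      int ntips = (int)alive.size();
      if (conditioning == 1 && ntips < 1) continue;
      if (conditioning == 2 && (ntips < nT_lo || ntips > nT_hi)) continue;

      int ne = (int)ev_time.size();
      NumericVector tm(ne);
      IntegerVector kd(ne), ln(ne), ch(ne);
      for (int i = 0; i < ne; ++i) {
        tm[i] = ev_time[i]; kd[i] = ev_kind[i];
        ln[i] = ev_lin[i]; ch[i] = ev_child[i];
      }
      IntegerVector tips(alive.begin(), alive.end());
      std::sort(tips.begin(), tips.end());
      trees[k] = List::create(_["time"] = tm, _["kind"] = kd,
                              _["lineage"] = ln, _["child"] = ch,
                              _["tips"] = tips,
                              _["n_lineages"] = next_id - 1);
      accepted = true;
    }
  }
  return List::create(_["trees"] = trees, _["attempts"] = attempts);
}

// Lineage counts for a batch of trees at one time point, without
// materializing per-tree R structures: returns the number of lineages
// alive at t (n_t) or the number alive at t with >= 1 descendant tip at
// T (m_t) for each tree.
// [[Rcpp::export]]
IntegerVector bd_count_at_cpp(List trees, double t, double T, bool surviving) {
  int B = trees.size();
  IntegerVector out(B);
  for (int b = 0; b < B; ++b) {
    List tr = trees[b];
    NumericVector tm = tr["time"];
    IntegerVector kd = tr["kind"], ln = tr["lineage"], ch = tr["child"];
    IntegerVector tips = tr["tips"];
    int n_lin = as<int>(tr["n_lineages"]);
    int ne = tm.size();

    std::vector<double> birth(n_lin + 1, -1.0), death(n_lin + 1, T + 1.0);
    birth[1] = 0.0;
    for (int i = 0; i < ne; ++i) {
      if (kd[i] == 1) birth[ch[i]] = tm[i];
      else death[ln[i]] = tm[i];
    }
    if (!surviving) {
      int cnt = 0;
      for (int l = 1; l <= n_lin; ++l)
        if (birth[l] >= 0 && birth[l] <= t && death[l] > t) ++cnt;
      out[b] = cnt;
      continue;
    }
    // surv_until[l]: latest time at which lineage l, if alive, still has
    // descendants reaching T (beyond T for tips, which are themselves the
    // descendants; else the birth time of its latest surviving child).
    // Events scanned in reverse time order so children are finalized
    // before their parents.
    std::vector<double> surv_until(n_lin + 1, -1.0);
    for (int i = 0; i < tips.size(); ++i) surv_until[tips[i]] = T + 1.0;
    for (int i = ne - 1; i >= 0; --i) {
      if (kd[i] == 1 && surv_until[ch[i]] >= 0.0 && tm[i] > surv_until[ln[i]])
        surv_until[ln[i]] = tm[i];
    }
    int cnt = 0;
    for (int l = 1; l <= n_lin; ++l)
      if (birth[l] >= 0 && birth[l] <= t && death[l] > t && surv_until[l] > t)
        ++cnt;
    out[b] = cnt;
  }
  return out;
}
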