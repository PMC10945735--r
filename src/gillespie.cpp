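#include <Rcpp.h>
using namespace Rcpp;

// Exact Gillespie simulation of the three-phase stem cell model at
// single-cell resolution.  The genealogy is stored on branches: each node
// records its parent and the number of new mutations assigned to the branch
// leading to it (infinite sites: mutation identities are the cumulative
// ranges of `nmut`).  Living cells are pointers into the node table, so
// memory scales with the number of divisions, not cells x mutations.
//
// Growth divisions run at per-cell rate gamma while N < NM, so every
// realization matures at exactly NM cells (the mean hitting time is tM when
// gamma = log(NM)/tM).  Homeostatic events (Moran at rho, asymmetric at phi)
// run once N > NH.  A Moran event picks the divider and the removed cell
// independently and uniformly; when the same cell is picked for both, the
// division leaves a single surviving daughter.

// [[Rcpp::export(name = ".sim_genealogy_cpp")]]
List sim_genealogy_cpp(int NM, double NH, double gamma, double rho,
                       double phi, double mu, double t_end,
                       double max_events) {
  std::vector<int> parent;  parent.reserve(4 * NM);
  std::vector<int> nmut;    nmut.reserve(4 * NM);
  parent.push_back(0);      // founder, 1-based parent id 0 = none
  nmut.push_back(0);

  std::vector<int> alive;   alive.reserve(NM + 1);
  alive.push_back(1);       // 1-based node ids

  double t = 0.0, n_events = 0.0;
  bool capped = false;

  auto new_node = [&](int par) -> int {
    parent.push_back(par);
    nmut.push_back((int) R::rpois(mu));
    return (int) parent.size();
  };

  while (t < t_end) {
    int N = (int) alive.size();
    double ge = (N < NM) ? gamma : 0.0;
    bool homeo = N > NH;
    double re = homeo ? rho : 0.0;
    double pe = homeo ? phi : 0.0;
    double rate1 = ge + re + pe;
    if (rate1 <= 0.0) break;            // nothing can happen any more
    double dt = R::exp_rand() / (N * rate1);
    if (t + dt >= t_end) { t = t_end; break; }
    t += dt;

    double u = unif_rand() * rate1;
    int cell = (int) (unif_rand() * N);
    if (cell >= N) cell = N - 1;
    int v = alive[cell];

    if (u < ge) {                        // growth division
      alive[cell] = new_node(v);
      alive.push_back(new_node(v));
    } else if (u < ge + re) {            // Moran event
      int rem = (int) (unif_rand() * N);
      if (rem >= N) rem = N - 1;
      if (rem == cell) {                 // self-replacement: one daughter
        alive[cell] = new_node(v);
      } else {
        alive[cell] = new_node(v);
        alive[rem] = new_node(v);
      }
    } else {                             // asymmetric division
      alive[cell] = new_node(v);
    }
    if (++n_events >= max_events) { capped = true; break; }
  }

  return List::create(
    _["parent"] = IntegerVector(parent.begin(), parent.end()),
    _["nmut"] = IntegerVector(nmut.begin(), nmut.end()),
    _["alive"] = IntegerVector(alive.begin(), alive.end()),
    _["t"] = t, _["n_events"] = n_events, _["capped"] = capped);
}

// Per-node mutational burden: branch mutation counts summed along the root
// path.  Parents always precede children in the node table.
// [[Rcpp::export(name = ".node_burdens_cpp")]]
IntegerVector node_burdens_cpp(IntegerVector parent, IntegerVector nmut) {
  int n = parent.size();
  IntegerVector b(n);
  for (int i = 0; i < n; ++i)
    b[i] = nmut[i] + (parent[i] > 0 ? b[parent[i] - 1] : 0);
  return b;
}

// Number of cells from `cells` (node ids) whose root path passes each node.
// [[Rcpp::export(name = ".descendant_counts_cpp")]]
IntegerVector descendant_counts_cpp(IntegerVector parent, IntegerVector cells) {
  int n = parent.size();
  IntegerVector cnt(n);
  for (int i = 0; i < cells.size(); ++i) cnt[cells[i] - 1]++;
  for (int i = n - 1; i > 0; --i)
    if (parent[i] > 0) cnt[parent[i] - 1] += cnt[i];
  return cnt;
}

// Burden-only simulation of mutation acquisition in a constant population:
// N cells start with zero mutations; division events occur at total rate
// N * lam, a fraction p of them asymmetric.  An asymmetric division adds
// Poisson(mu) mutations to the dividing cell.  A symmetric (Moran) event
// picks a divider and a replaced slot independently and uniformly: the
// replaced slot receives the divider's burden plus Poisson(mu) new
// mutations and the divider also gains Poisson(mu).
// [[Rcpp::export(name = ".sim_burden_only_cpp")]]
IntegerMatrix sim_burden_only_cpp(int N, double p, double mu, double lam,
                                  double t_end, int reps,
                                  double max_events) {
  IntegerMatrix out(N, reps);
  for (int r = 0; r < reps; ++r) {
    std::vector<int> m(N, 0);
    double t = 0.0, n_events = 0.0;
    double total = N * lam;
    if (total > 0) {
      while (true) {
        t += R::exp_rand() / total;
        if (t >= t_end || ++n_events > max_events) break;
        int i = (int) (unif_rand() * N); if (i >= N) i = N - 1;
        if (unif_rand() < p) {           // asymmetric
          m[i] += (int) R::rpois(mu);
        } else {                          // symmetric replacement
          int j = (int) (unif_rand() * N); if (j >= N) j = N - 1;
          if (j == i) {
            m[i] += (int) R::rpois(mu);  // self-replacement: one daughter
          } else {
            m[j] = m[i] + (int) R::rpois(mu);
            m[i] += (int) R::rpois(mu);
          }
        }
      }
    }
    for (int i = 0; i < N; ++i) out(i, r) = m[i];
  }
  return out;
}
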