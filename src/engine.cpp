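#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Growth-rate lookup for a recruit establishing on a given soil.
// `look` has one row per species (residents 1..n, invader last) and
// n_species + 1 columns: column 0 is unconditioned soil, column j is soil
// conditioned by species j. Values are per-step multiplicative rates.
static inline double est_rate(const NumericMatrix& look, int sp, int soil) {
  return look(sp - 1, soil);
}

// Immigration: each empty cell is independently colonised with probability
// p by a uniformly drawn *resident* species (the invader never immigrates).
static void do_immigration(IntegerVector& occ, NumericVector& bio,
                           NumericVector& rate, IntegerVector& soil,
                           const NumericMatrix& look, double p, int n_res,
                           double init_b) {
  if (p <= 0.0) return;
  const int n = occ.size();
  for (int i = 0; i < n; ++i) {
    if (occ[i] == 0 && unif_rand() < p) {
      int sp = static_cast<int>(unif_rand() * n_res) + 1;
      if (sp > n_res) sp = n_res;
      occ[i] = sp;
      bio[i] = init_b;
      rate[i] = est_rate(look, sp, soil[i]);
      soil[i] = sp;
    }
  }
}

// Recruitment under global dispersal: every still-empty cell receives one
// recruit whose species is drawn with probability proportional to that
// species' total biomass at the start of the phase (invader included once
// present). No recruitment when the community holds no biomass.
static void do_recruitment(IntegerVector& occ, NumericVector& bio,
                           NumericVector& rate, IntegerVector& soil,
                           const NumericMatrix& look, double init_b) {
  const int n = occ.size();
  const int S = look.nrow();
  std::vector<double> cum(S, 0.0);
  double tot = 0.0;
  for (int i = 0; i < n; ++i)
    if (occ[i] > 0) cum[occ[i] - 1] += bio[i];
  for (int s = 0; s < S; ++s) {
    tot += cum[s];
    cum[s] = tot;
  }
  if (tot <= 0.0) return;
  for (int i = 0; i < n; ++i) {
    if (occ[i] == 0) {
      double u = unif_rand() * tot;
      int sp = static_cast<int>(
                   std::upper_bound(cum.begin(), cum.end(), u) - cum.begin()) +
               1;
      if (sp > S) sp = S;
      occ[i] = sp;
      bio[i] = init_b;
      rate[i] = est_rate(look, sp, soil[i]);
      soil[i] = sp;
    }
  }
}

// Synchronous growth: every plant's biomass is multiplied by its fixed
// establishment rate, then clipped so that the plant plus its von Neumann
// neighbours (pre-step biomasses) do not exceed the neighbourhood cap.
// Clipping never pushes biomass below its pre-growth value.
static void do_growth(const IntegerVector& occ, NumericVector& bio,
                      const NumericVector& rate, int side, double cap,
                      bool torus) {
  const int n = occ.size();
  std::vector<double> pre(bio.begin(), bio.end());
  for (int r = 0; r < side; ++r) {
    for (int c = 0; c < side; ++c) {
      const int i = r * side + c;
      if (occ[i] == 0) continue;
      double nb = 0.0;
      if (torus) {
        nb += pre[((r + side - 1) % side) * side + c];
        nb += pre[((r + 1) % side) * side + c];
        nb += pre[r * side + (c + side - 1) % side];
        nb += pre[r * side + (c + 1) % side];
      } else {
        if (r > 0) nb += pre[i - side];
        if (r < side - 1) nb += pre[i + side];
        if (c > 0) nb += pre[i - 1];
        if (c < side - 1) nb += pre[i + 1];
      }
      double nv = std::min(pre[i] * rate[i], cap - nb);
      bio[i] = (nv < pre[i]) ? pre[i] : nv;
    }
  }
}

// Mortality: each individual independently dies with probability p; its cell
// becomes empty but keeps the dead plant's species as soil conditioning.
static void do_mortality(IntegerVector& occ, NumericVector& bio,
                         NumericVector& rate, double p) {
  if (p <= 0.0) return;
  const int n = occ.size();
  for (int i = 0; i < n; ++i) {
    if (occ[i] > 0 && unif_rand() < p) {
      occ[i] = 0;
      bio[i] = 0.0;
      rate[i] = 0.0;
    }
  }
}

// Invasion: place min(n_inv, #empty) invader individuals into distinct
// uniformly sampled empty cells (partial Fisher-Yates over empty indices).
static int do_invasion(IntegerVector& occ, NumericVector& bio,
                       NumericVector& rate, IntegerVector& soil,
                       const NumericMatrix& look, int n_inv, double init_b,
                       int inv_sp) {
  std::vector<int> empties;
  const int n = occ.size();
  for (int i = 0; i < n; ++i)
    if (occ[i] == 0) empties.push_back(i);
  int m = static_cast<int>(empties.size());
  int k = std::min(m, n_inv);
  for (int j = 0; j < k; ++j) {
    int pick = j + static_cast<int>(unif_rand() * (m - j));
    if (pick >= m) pick = m - 1;
    std::swap(empties[j], empties[pick]);
    int i = empties[j];
    occ[i] = inv_sp;
    bio[i] = init_b;
    rate[i] = est_rate(look, inv_sp, soil[i]);
    soil[i] = inv_sp;
  }
  return k;
}

// ---- single-step wrappers (used by the R-level step functions) -----------

static List pack_state(const IntegerVector& occ, const NumericVector& bio,
                       const NumericVector& rate, const IntegerVector& soil) {
  return List::create(_["occupant"] = occ, _["biomass"] = bio,
                      _["growth_rate"] = rate, _["soil"] = soil);
}

// [[Rcpp::export]]
List cpp_step_immigration(IntegerVector occupant, NumericVector biomass,
                          NumericVector growth_rate, IntegerVector soil,
                          NumericMatrix lookup, double p_immigration,
                          int n_resident, double initial_biomass) {
  IntegerVector occ = clone(occupant), so = clone(soil);
  NumericVector bio = clone(biomass), rate = clone(growth_rate);
  do_immigration(occ, bio, rate, so, lookup, p_immigration, n_resident,
                 initial_biomass);
  return pack_state(occ, bio, rate, so);
}

// [[Rcpp::export]]
List cpp_step_recruitment(IntegerVector occupant, NumericVector biomass,
                          NumericVector growth_rate, IntegerVector soil,
                          NumericMatrix lookup, double initial_biomass) {
  IntegerVector occ = clone(occupant), so = clone(soil);
  NumericVector bio = clone(biomass), rate = clone(growth_rate);
  do_recruitment(occ, bio, rate, so, lookup, initial_biomass);
  return pack_state(occ, bio, rate, so);
}

// [[Rcpp::export]]
List cpp_step_growth(IntegerVector occupant, NumericVector biomass,
                     NumericVector growth_rate, IntegerVector soil, int side,
                     double cap, bool toroidal) {
  NumericVector bio = clone(biomass);
  do_growth(occupant, bio, growth_rate, side, cap, toroidal);
  return pack_state(occupant, bio, growth_rate, soil);
}

// [[Rcpp::export]]
List cpp_step_mortality(IntegerVector occupant, NumericVector biomass,
                        NumericVector growth_rate, IntegerVector soil,
                        double p_mortality) {
  IntegerVector occ = clone(occupant);
  NumericVector bio = clone(biomass), rate = clone(growth_rate);
  do_mortality(occ, bio, rate, p_mortality);
  return pack_state(occ, bio, rate, soil);
}

// [[Rcpp::export]]
List cpp_introduce_invader(IntegerVector occupant, NumericVector biomass,
                           NumericVector growth_rate, IntegerVector soil,
                           NumericMatrix lookup, int n_invaders,
                           double initial_biomass) {
  IntegerVector occ = clone(occupant), so = clone(soil);
  NumericVector bio = clone(biomass), rate = clone(growth_rate);
  int placed = do_invasion(occ, bio, rate, so, lookup, n_invaders,
                           initial_biomass, lookup.nrow());
  List out = pack_state(occ, bio, rate, so);
  out["n_placed"] = placed;
  return out;
}

// ---- full simulation loop -------------------------------------------------

// Per-step order: (invasion, once, at invasion_step) -> immigration ->
// recruitment (from step 2 onward) -> growth -> mortality -> recording.
// invasion_step == 0 disables invasion. record_steps must be sorted,
// within 1..n_steps.
// [[Rcpp::export]]
List cpp_run_simulation(int side, int n_resident, NumericMatrix lookup,
                        double p_immigration, double p_mortality, int n_steps,
                        int invasion_step, int n_invaders,
                        double initial_biomass, double cap, bool toroidal,
                        IntegerVector record_steps) {
  const int ncell = side * side;
  const int S = lookup.nrow();
  const int inv_sp = S;
  IntegerVector occ(ncell, 0), soil(ncell, 0);
  NumericVector bio(ncell, 0.0), rate(ncell, 0.0);

  const int n_rec = record_steps.size();
  NumericMatrix rec_bio(n_rec, S);
  IntegerMatrix rec_abund(n_rec, S);
  std::vector<int> row_of(n_steps + 1, -1);
  for (int k = 0; k < n_rec; ++k) row_of[record_steps[k]] = k;

  int invaders_placed = NA_INTEGER;
  for (int t = 1; t <= n_steps; ++t) {
    if (invasion_step > 0 && t == invasion_step)
      invaders_placed =
          do_invasion(occ, bio, rate, soil, lookup, n_invaders,
                      initial_biomass, inv_sp);
    do_immigration(occ, bio, rate, soil, lookup, p_immigration, n_resident,
                   initial_biomass);
    if (t >= 2) do_recruitment(occ, bio, rate, soil, lookup, initial_biomass);
    do_growth(occ, bio, rate, side, cap, toroidal);
    do_mortality(occ, bio, rate, p_mortality);
    const int row = row_of[t];
    if (row >= 0) {
      for (int i = 0; i < ncell; ++i) {
        if (occ[i] > 0) {
          rec_bio(row, occ[i] - 1) += bio[i];
          rec_abund(row, occ[i] - 1) += 1;
        }
      }
    }
  }
  return List::create(
      _["steps"] = record_steps, _["biomass"] = rec_bio,
      _["abundance"] = rec_abund,
      _["final"] = pack_state(occ, bio, rate, soil),
      _["invaders_placed"] = invaders_placed);
}
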