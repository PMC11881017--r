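// Individual-based simulation core.
//
// Diploid hermaphroditic individuals on the unit torus, with a polygenic
// trait (sparse QTL haplotypes), Gaussian local competition, nearest-
// neighbour mating, Poisson fecundity, single-step habitat choice, and
// Bernoulli viability from the product fitness expression. All randomness
// flows through R's RNG so set.seed() on the R side fixes entire runs.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline double wrap01(double v) {
  double w = v - std::floor(v);
  return w >= 1.0 ? 0.0 : w;   // guard against rounding at the seam
}

static inline double torus_dist2(double x1, double y1, double x2, double y2) {
  double dx = std::fabs(x1 - x2); dx = std::min(dx, 1.0 - dx);
  double dy = std::fabs(y1 - y2); dy = std::min(dy, 1.0 - dy);
  return dx * dx + dy * dy;
}

// --- cell list spatial index -------------------------------------------------
// Bin width >= interaction radius, so the 3x3 bin neighbourhood covers every
// possible interaction partner. For very large radii (few bins) we fall back
// to scanning everyone.
struct CellList {
  int nbin;
  std::vector<std::vector<int>> bins;
  const std::vector<double> *px, *py;

  void build(const std::vector<double> &x, const std::vector<double> &y,
             double radius) {
    px = &x; py = &y;
    nbin = std::max(1, (int)std::floor(1.0 / radius));
    bins.assign((size_t)nbin * nbin, {});
    for (int i = 0; i < (int)x.size(); ++i) bins[bin_of(x[i], y[i])].push_back(i);
  }
  inline int bin_of(double x, double y) const {
    int bx = std::min(nbin - 1, (int)std::floor(wrap01(x) * nbin));
    int by = std::min(nbin - 1, (int)std::floor(wrap01(y) * nbin));
    return bx * nbin + by;
  }
  // visit indices possibly within the radius of (x, y)
  template <typename F>
  void visit(double x, double y, F f) const {
    if (nbin < 3) {
      for (const auto &b : bins) for (int i : b) f(i);
      return;
    }
    int bx = std::min(nbin - 1, (int)std::floor(wrap01(x) * nbin));
    int by = std::min(nbin - 1, (int)std::floor(wrap01(y) * nbin));
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        int cx = (bx + dx + nbin) % nbin, cy = (by + dy + nbin) % nbin;
        for (int i : bins[(size_t)cx * nbin + cy]) f(i);
      }
  }
};

// total competition felt at (x, y), excluding individual `self` (-1 = none)
static double competition_at(const CellList &cl, const std::vector<double> &x,
                             const std::vector<double> &y, double qx, double qy,
                             int self, double sigma_p) {
  double cut2 = 9.0 * sigma_p * sigma_p, inv2s2 = 1.0 / (2.0 * sigma_p * sigma_p);
  double C = 0.0;
  cl.visit(qx, qy, [&](int j) {
    if (j == self) return;
    double d2 = torus_dist2(qx, qy, x[j], y[j]);
    if (d2 < cut2) C += std::exp(-d2 * inv2s2);
  });
  return C;
}

// nearest other individual within 3*sigma_p; ties by lowest id; -1 if none
static int nearest_within(const CellList &cl, const std::vector<double> &x,
                          const std::vector<double> &y,
                          const std::vector<int> &id, int i, double sigma_p,
                          int limit /* only indices < limit are candidates */) {
  double cut2 = 9.0 * sigma_p * sigma_p;
  double best = cut2; int bi = -1;
  cl.visit(x[i], y[i], [&](int j) {
    if (j == i || j >= limit) return;
    double d2 = torus_dist2(x[i], y[i], x[j], y[j]);
    if (d2 < best || (d2 == best && bi >= 0 && id[j] < id[bi])) {
      best = d2; bi = j;
    }
  });
  return bi;
}

// [[Rcpp::export]]
NumericVector total_competition_cpp(NumericVector x, NumericVector y,
                                    double sigma_p) {
  std::vector<double> vx(x.begin(), x.end()), vy(y.begin(), y.end());
  CellList cl; cl.build(vx, vy, 3.0 * sigma_p);
  NumericVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = competition_at(cl, vx, vy, vx[i], vy[i], i, sigma_p);
  return out;
}

// [[Rcpp::export]]
IntegerVector nearest_neighbor_cpp(NumericVector x, NumericVector y,
                                   IntegerVector id, double sigma_p) {
  std::vector<double> vx(x.begin(), x.end()), vy(y.begin(), y.end());
  std::vector<int> vid(id.begin(), id.end());
  CellList cl; cl.build(vx, vy, 3.0 * sigma_p);
  IntegerVector out(x.size());
  for (int i = 0; i < x.size(); ++i) {
    int j = nearest_within(cl, vx, vy, vid, i, sigma_p, (int)vx.size());
    out[i] = j < 0 ? NA_INTEGER : j + 1;  // 1-based
  }
  return out;
}

// --- fitness -----------------------------------------------------------------
static inline double fitness_w(double Ci, double P, double e, bool destroyed,
                               double sigma_b, double sigma_p, double sigma_f,
                               double K) {
  if (destroyed) return 0.0;
  double comp = (Ci > 0.0) ? (2.0 * M_PI * sigma_p * sigma_p * K / Ci) : 1.0;
  double dev = (P - e) * sigma_b;
  double w = comp * std::exp(-dev * dev / (2.0 * sigma_f * sigma_f));
  return std::min(1.0, w);
}

// --- population state --------------------------------------------------------
struct Pop {
  std::vector<double> x, y, phen;
  std::vector<int> age, id;
  std::vector<std::vector<int>> hapA, hapB;  // allele ids, sorted by site key
  // allele registry
  std::vector<double> eff;
  std::vector<int> agrp, asite;
  int next_id;

  int size() const { return (int)x.size(); }
  void erase_dead(const std::vector<char> &dead) {
    int k = 0;
    for (int i = 0; i < size(); ++i) {
      if (!dead[i]) {
        if (k != i) {
          x[k] = x[i]; y[k] = y[i]; phen[k] = phen[i];
          age[k] = age[i]; id[k] = id[i];
          hapA[k] = std::move(hapA[i]); hapB[k] = std::move(hapB[i]);
        }
        ++k;
      }
    }
    x.resize(k); y.resize(k); phen.resize(k); age.resize(k); id.resize(k);
    hapA.resize(k); hapB.resize(k);
  }
};

struct Cfg {
  double sigma_p, sigma_f, sigma_qtl, mu_qtl, lambda0, sigma_b0, recomb_rate;
  double K;
  int max_age, burn_in, n_qtl_groups, sites_per_group;
  bool choice_full;
};

// gamete from one parent: free recombination between linkage groups,
// per-site crossover rate within a group; new QTL mutations only while
// enabled (the burn-in)
static std::vector<int> make_gamete(Pop &p, int parent, const Cfg &cfg,
                                    bool mutations_enabled) {
  std::vector<int> gam;
  const std::vector<int> &A = p.hapA[parent], &B = p.hapB[parent];
  const long sites = cfg.sites_per_group;
  for (int g = 0; g < cfg.n_qtl_groups; ++g) {
    int h = (unif_rand() < 0.5) ? 0 : 1;  // starting parental haplotype
    int ncross = (int)R::rpois(cfg.recomb_rate * (sites - 1));
    std::vector<long> br(ncross);
    for (int k = 0; k < ncross; ++k)
      br[k] = (long)std::floor(unif_rand() * (sites - 1));  // cross after site br[k]
    std::sort(br.begin(), br.end());
    // an allele at site s comes from haplotype (h + #breakpoints before s) % 2
    auto take = [&](const std::vector<int> &hap, int which) {
      for (int a : hap) {
        if (p.agrp[a] != g) continue;
        int seg = (int)(std::upper_bound(br.begin(), br.end(),
                                         (long)p.asite[a] - 1) - br.begin());
        if ((h + seg) % 2 == which) gam.push_back(a);
      }
    };
    take(A, 0); take(B, 1);
  }
  if (mutations_enabled) {
    double rate = cfg.mu_qtl * (double)cfg.sites_per_group * cfg.n_qtl_groups;
    int nm = (int)R::rpois(rate);
    for (int k = 0; k < nm; ++k) {
      int g = std::min(cfg.n_qtl_groups - 1,
                       (int)std::floor(unif_rand() * cfg.n_qtl_groups));
      int s = std::min(cfg.sites_per_group - 1,
                       (int)std::floor(unif_rand() * cfg.sites_per_group));
      p.eff.push_back(norm_rand() * cfg.sigma_qtl);
      p.agrp.push_back(g); p.asite.push_back(s);
      gam.push_back((int)p.eff.size() - 1);
    }
  }
  std::sort(gam.begin(), gam.end(), [&](int a, int b) {
    long ka = (long)p.agrp[a] * cfg.sites_per_group + p.asite[a];
    long kb = (long)p.agrp[b] * cfg.sites_per_group + p.asite[b];
    return ka < kb;
  });
  return gam;
}

static double hap_sum(const Pop &p, const std::vector<int> &hap) {
  double s = 0; for (int a : hap) s += p.eff[a]; return s;
}

// random permutation 0..n-1 via R's RNG (Fisher-Yates)
static std::vector<int> rand_perm(int n) {
  std::vector<int> o(n);
  for (int i = 0; i < n; ++i) o[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(o[i], o[j]);
  }
  return o;
}

static int count_segregating(const Pop &p) {
  if (p.eff.empty()) return 0;
  std::vector<char> seen(p.eff.size(), 0);
  for (const auto &h : p.hapA) for (int a : h) seen[a] = 1;
  for (const auto &h : p.hapB) for (int a : h) seen[a] = 1;
  int n = 0; for (char c : seen) n += c;
  return n;
}

// --- list <-> struct ---------------------------------------------------------
static Pop pop_from_state(List st) {
  Pop p;
  NumericVector x = st["x"], y = st["y"], phen = st["phen"], eff = st["allele_effect"];
  IntegerVector age = st["age"], id = st["id"], grp = st["allele_group"],
                site = st["allele_site"];
  p.x.assign(x.begin(), x.end()); p.y.assign(y.begin(), y.end());
  p.phen.assign(phen.begin(), phen.end());
  p.age.assign(age.begin(), age.end()); p.id.assign(id.begin(), id.end());
  p.eff.assign(eff.begin(), eff.end());
  p.agrp.assign(grp.begin(), grp.end()); p.asite.assign(site.begin(), site.end());
  List hA = st["hapA"], hB = st["hapB"];
  p.hapA.resize(hA.size()); p.hapB.resize(hB.size());
  for (int i = 0; i < hA.size(); ++i) {
    IntegerVector v = hA[i]; p.hapA[i].assign(v.begin(), v.end());
    IntegerVector w = hB[i]; p.hapB[i].assign(w.begin(), w.end());
  }
  p.next_id = as<int>(st["next_id"]);
  return p;
}

static List state_from_pop(const Pop &p, int generation) {
  int n = p.size();
  List hA(n), hB(n);
  for (int i = 0; i < n; ++i) {
    hA[i] = IntegerVector(p.hapA[i].begin(), p.hapA[i].end());
    hB[i] = IntegerVector(p.hapB[i].begin(), p.hapB[i].end());
  }
  List st = List::create(
    _["x"] = NumericVector(p.x.begin(), p.x.end()),
    _["y"] = NumericVector(p.y.begin(), p.y.end()),
    _["age"] = IntegerVector(p.age.begin(), p.age.end()),
    _["id"] = IntegerVector(p.id.begin(), p.id.end()),
    _["phen"] = NumericVector(p.phen.begin(), p.phen.end()),
    _["hapA"] = hA, _["hapB"] = hB,
    _["allele_effect"] = NumericVector(p.eff.begin(), p.eff.end()),
    _["allele_group"] = IntegerVector(p.agrp.begin(), p.agrp.end()),
    _["allele_site"] = IntegerVector(p.asite.begin(), p.asite.end()),
    _["next_id"] = p.next_id,
    _["generation"] = generation);
  st.attr("class") = "sim_state";
  return st;
}

// --- main driver -------------------------------------------------------------
// Runs `n_gen` generations from `state`. Event order per generation:
// (1) reproduction, (2) habitat choice (all, incl. newborns),
// (3) viability, (4) ageing + max-age removal, (5) counter/schedule updates.
// [[Rcpp::export]]
List ibm_run_cpp(NumericMatrix env, IntegerMatrix loss, List cfg_list,
                 List state, int n_gen, double warm_delta_e, int warm_duration,
                 int warm_start) {
  Cfg cfg;
  cfg.sigma_p = as<double>(cfg_list["sigma_p"]);
  cfg.sigma_f = as<double>(cfg_list["sigma_f"]);
  cfg.sigma_qtl = as<double>(cfg_list["sigma_qtl"]);
  cfg.mu_qtl = as<double>(cfg_list["mu_rate"]) * as<double>(cfg_list["p_qtl"]);
  cfg.lambda0 = as<double>(cfg_list["lambda_0"]);
  cfg.sigma_b0 = as<double>(cfg_list["sigma_b0"]);
  cfg.recomb_rate = as<double>(cfg_list["recomb_rate"]);
  cfg.K = as<double>(cfg_list["K"]);
  cfg.max_age = as<int>(cfg_list["max_age"]);
  cfg.burn_in = as<int>(cfg_list["burn_in"]);
  cfg.n_qtl_groups = as<int>(cfg_list["n_qtl_groups"]);
  cfg.sites_per_group = as<int>(cfg_list["sites_per_group"]);
  cfg.choice_full = as<bool>(cfg_list["habitat_choice_full"]);

  const int R_ = env.nrow();
  const bool has_loss = loss.nrow() == R_;
  auto destroyed_at = [&](double qx, double qy) -> bool {
    if (!has_loss) return false;
    int ix = std::min(R_ - 1, (int)std::floor(wrap01(qx) * R_));
    int iy = std::min(R_ - 1, (int)std::floor(wrap01(qy) * R_));
    return loss(ix, iy) == 1;
  };
  auto env_of = [&](double qx, double qy, double offset) -> double {
    int ix = std::min(R_ - 1, (int)std::floor(wrap01(qx) * R_));
    int iy = std::min(R_ - 1, (int)std::floor(wrap01(qy) * R_));
    return env(ix, iy) + offset;
  };

  RNGScope scope;
  Pop p = pop_from_state(state);
  int gen = as<int>(state["generation"]);
  double radius = 3.0 * cfg.sigma_p;

  NumericMatrix census(n_gen, 8);
  colnames(census) = CharacterVector::create(
    "generation", "n_alive", "n_alleles", "mean_phenotype", "var_phenotype",
    "mean_displacement", "max_age", "n_moving");

  for (int t = 0; t < n_gen; ++t) {
    double sigma_b = (gen >= cfg.burn_in)
      ? 1.0
      : cfg.sigma_b0 + (1.0 - cfg.sigma_b0) * ((double)gen / cfg.burn_in);
    double offset = 0.0;
    if (warm_duration > 0) {
      long el = gen - warm_start;
      if (el < 0) el = 0;
      if (el > warm_duration) el = warm_duration;
      offset = warm_delta_e / warm_duration * (double)el;
    }
    bool mutations_enabled = gen < cfg.burn_in;
    int n0 = p.size();
    double disp_sum = 0.0; int disp_n = 0;

    if (n0 > 0) {
      // (1) reproduction: nearest-neighbour mate among the generation's
      // adults (snapshot); Poisson(lambda0) offspring at parent-1's position
      {
        CellList cl; cl.build(p.x, p.y, radius);
        std::vector<int> order = rand_perm(n0);
        for (int oi = 0; oi < n0; ++oi) {
          int i = order[oi];
          int j = nearest_within(cl, p.x, p.y, p.id, i, cfg.sigma_p, n0);
          if (j < 0) continue;
          int noff = (int)R::rpois(cfg.lambda0);
          for (int k = 0; k < noff; ++k) {
            std::vector<int> g1 = make_gamete(p, i, cfg, mutations_enabled);
            std::vector<int> g2 = make_gamete(p, j, cfg, mutations_enabled);
            p.x.push_back(p.x[i]); p.y.push_back(p.y[i]);
            p.age.push_back(0); p.id.push_back(p.next_id++);
            p.phen.push_back(hap_sum(p, g1) + hap_sum(p, g2));
            p.hapA.push_back(std::move(g1)); p.hapB.push_back(std::move(g2));
          }
        }
      }

      // (2) habitat choice for everyone, newborns included; fitness at the
      // candidate is evaluated against the neighbour positions held at the
      // start of the movement phase
      {
        int n = p.size();
        std::vector<double> sx = p.x, sy = p.y;  // snapshot
        CellList cl; cl.build(sx, sy, radius);
        std::vector<int> order = rand_perm(n);
        disp_n = n;
        for (int oi = 0; oi < n; ++oi) {
          int i = order[oi];
          double cx = wrap01(p.x[i] + (unif_rand() * 2.0 - 1.0) * cfg.sigma_p);
          double cy = wrap01(p.y[i] + (unif_rand() * 2.0 - 1.0) * cfg.sigma_p);
          if (destroyed_at(cx, cy)) continue;   // unsuitable, never accepted
          double w_cur, w_cand;
          if (cfg.choice_full) {
            double Ccur = competition_at(cl, sx, sy, p.x[i], p.y[i], i, cfg.sigma_p);
            double Ccand = competition_at(cl, sx, sy, cx, cy, i, cfg.sigma_p);
            w_cur = fitness_w(Ccur, p.phen[i], env_of(p.x[i], p.y[i], offset),
                              destroyed_at(p.x[i], p.y[i]), sigma_b,
                              cfg.sigma_p, cfg.sigma_f, cfg.K);
            w_cand = fitness_w(Ccand, p.phen[i], env_of(cx, cy, offset), false,
                               sigma_b, cfg.sigma_p, cfg.sigma_f, cfg.K);
          } else {  // phenotype-matching component only
            double dc = (p.phen[i] - env_of(p.x[i], p.y[i], offset)) * sigma_b;
            double dn = (p.phen[i] - env_of(cx, cy, offset)) * sigma_b;
            w_cur = destroyed_at(p.x[i], p.y[i]) ? 0.0 :
              std::exp(-dc * dc / (2 * cfg.sigma_f * cfg.sigma_f));
            w_cand = std::exp(-dn * dn / (2 * cfg.sigma_f * cfg.sigma_f));
          }
          if (w_cand > w_cur) {
            disp_sum += std::sqrt(torus_dist2(p.x[i], p.y[i], cx, cy));
            p.x[i] = cx; p.y[i] = cy;
          }
        }
      }

      // (3) viability selection: Bernoulli(w_i) with competition from the
      // post-movement configuration
      {
        int n = p.size();
        CellList cl; cl.build(p.x, p.y, radius);
        std::vector<char> dead(n, 0);
        for (int i = 0; i < n; ++i) {
          double Ci = competition_at(cl, p.x, p.y, p.x[i], p.y[i], i, cfg.sigma_p);
          double w = fitness_w(Ci, p.phen[i], env_of(p.x[i], p.y[i], offset),
                               destroyed_at(p.x[i], p.y[i]), sigma_b,
                               cfg.sigma_p, cfg.sigma_f, cfg.K);
          if (unif_rand() >= w) dead[i] = 1;
        }
        p.erase_dead(dead);
      }

      // (4) ageing and hard age cap
      {
        int n = p.size();
        std::vector<char> dead(n, 0);
        for (int i = 0; i < n; ++i) {
          p.age[i] += 1;
          if (p.age[i] > cfg.max_age) dead[i] = 1;
        }
        p.erase_dead(dead);
      }
    }

    // (5) schedule update + census
    gen += 1;
    int n = p.size();
    double mp = 0, vp = 0;
    if (n > 0) {
      for (double v : p.phen) mp += v;
      mp /= n;
      for (double v : p.phen) vp += (v - mp) * (v - mp);
      vp = n > 1 ? vp / (n - 1) : 0.0;
    }
    int amax = 0; for (int a : p.age) amax = std::max(amax, a);
    census(t, 0) = gen;
    census(t, 1) = n;
    census(t, 2) = count_segregating(p);
    census(t, 3) = n > 0 ? mp : NA_REAL;
    census(t, 4) = n > 0 ? vp : NA_REAL;
    census(t, 5) = disp_n > 0 ? disp_sum / disp_n : 0.0;
    census(t, 6) = amax;
    census(t, 7) = disp_n;
  }

  return List::create(_["state"] = state_from_pop(p, gen),
                      _["census"] = census);
}
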