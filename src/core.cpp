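// Compiled core: internal-coordinate chain rebuild (NeRF), staged
// coarse-grained scoring, and the Monte Carlo inner loops (MMC stages and
// greedy improvement). All randomness is drawn from R's RNG so that
// set.seed() at the R level makes every run reproducible.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

struct Vec3 {
  double x, y, z;
};

static inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  return Vec3{a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return Vec3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x};
}
static inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }
static inline Vec3 unit(const Vec3 &a) {
  double n = norm(a);
  return Vec3{a.x / n, a.y / n, a.z / n};
}

// Place atom D given A-B-C, bond length |C-D|, bond angle B-C-D (deg) and
// torsion A-B-C-D (deg); standard three-atom (NeRF) frame construction.
static Vec3 place(const Vec3 &A, const Vec3 &B, const Vec3 &C, double bond,
                  double theta_deg, double chi_deg) {
  double theta = theta_deg * DEG, chi = chi_deg * DEG;
  Vec3 bc = unit(sub(C, B));
  Vec3 n = unit(cross(sub(B, A), bc));
  Vec3 m = cross(n, bc);
  double ct = std::cos(theta), st = std::sin(theta);
  double cx = std::cos(chi), sx = std::sin(chi);
  return Vec3{C.x + bond * (-ct * bc.x + st * (cx * m.x + sx * n.x)),
              C.y + bond * (-ct * bc.y + st * (cx * m.y + sx * n.y)),
              C.z + bond * (-ct * bc.z + st * (cx * m.z + sx * n.z))};
}

// IUPAC torsion angle p1-p2-p3-p4 in degrees, range (-180, 180].
static double torsion(const Vec3 &p1, const Vec3 &p2, const Vec3 &p3,
                      const Vec3 &p4) {
  Vec3 b1 = sub(p2, p1), b2 = sub(p3, p2), b3 = sub(p4, p3);
  Vec3 n1 = cross(b1, b2), n2 = cross(b2, b3);
  Vec3 m1 = cross(unit(b2), n1);
  double ang = std::atan2(dot(m1, n2), dot(n1, n2)) / DEG;
  if (ang <= -180.0) ang += 360.0;
  return ang;
}

// [[Rcpp::export(name = ".cpp_torsion")]]
double cpp_torsion(NumericVector p1, NumericVector p2, NumericVector p3,
                   NumericVector p4) {
  Vec3 a{p1[0], p1[1], p1[2]}, b{p2[0], p2[1], p2[2]};
  Vec3 c{p3[0], p3[1], p3[2]}, d{p4[0], p4[1], p4[2]};
  return torsion(a, b, c, d);
}

struct Geometry {
  double b_nca, b_cac, b_cn, b_co, b_cacen;
  double a_ncac, a_cacn, a_cnca, a_caco, a_ncacen;
  double t_cen;
};

static Geometry as_geometry(NumericVector g) {
  Geometry geo;
  geo.b_nca = g["b_nca"];
  geo.b_cac = g["b_cac"];
  geo.b_cn = g["b_cn"];
  geo.b_co = g["b_co"];
  geo.b_cacen = g["b_cacen"];
  geo.a_ncac = g["a_ncac"];
  geo.a_cacn = g["a_cacn"];
  geo.a_cnca = g["a_cnca"];
  geo.a_caco = g["a_caco"];
  geo.a_ncacen = g["a_ncacen"];
  geo.t_cen = g["t_cen"];
  return geo;
}

// Rebuild Cartesian coordinates for a chain of l residues from an l x 3
// matrix of (phi, psi, omega) in degrees. Output: 5l x 3 matrix with rows
// ordered N, CA, C, O, CEN per residue. omega[i] is the peptide torsion
// between residues i and i+1 (CA_i-C_i-N_{i+1}-CA_{i+1}); phi of residue 1
// and psi/omega of the last residue are geometrically inert.
static void rebuild(const NumericMatrix &dih, const Geometry &geo,
                    std::vector<Vec3> &N, std::vector<Vec3> &CA,
                    std::vector<Vec3> &C, std::vector<Vec3> &O,
                    std::vector<Vec3> &CEN) {
  int l = dih.nrow();
  N.resize(l);
  CA.resize(l);
  C.resize(l);
  O.resize(l);
  CEN.resize(l);
  // canonical origin frame for residue 1
  N[0] = Vec3{0.0, 0.0, 0.0};
  CA[0] = Vec3{geo.b_nca, 0.0, 0.0};
  double a = geo.a_ncac * DEG;
  C[0] = Vec3{geo.b_nca - geo.b_cac * std::cos(a), geo.b_cac * std::sin(a),
              0.0};
  for (int i = 0; i < l; ++i) {
    if (i + 1 < l) {
      N[i + 1] = place(N[i], CA[i], C[i], geo.b_cn, geo.a_cacn, dih(i, 1));
      CA[i + 1] =
          place(CA[i], C[i], N[i + 1], geo.b_nca, geo.a_cnca, dih(i, 2));
      C[i + 1] = place(C[i], N[i + 1], CA[i + 1], geo.b_cac, geo.a_ncac,
                       dih(i + 1, 0));
    }
    // carbonyl O anti to the following N (planar trans carbonyl)
    O[i] = place(N[i], CA[i], C[i], geo.b_co, geo.a_caco, dih(i, 1) + 180.0);
    // side-chain centroid pseudo-atom off CA
    CEN[i] = place(C[i], N[i], CA[i], geo.b_cacen, geo.a_ncacen, geo.t_cen);
  }
}

// [[Rcpp::export(name = ".cpp_rebuild")]]
NumericMatrix cpp_rebuild(NumericMatrix dih, NumericVector geom) {
  Geometry geo = as_geometry(geom);
  std::vector<Vec3> N, CA, C, O, CEN;
  rebuild(dih, geo, N, CA, C, O, CEN);
  int l = dih.nrow();
  NumericMatrix out(5 * l, 3);
  for (int i = 0; i < l; ++i) {
    const Vec3 *atoms[5] = {&N[i], &CA[i], &C[i], &O[i], &CEN[i]};
    for (int k = 0; k < 5; ++k) {
      out(5 * i + k, 0) = atoms[k]->x;
      out(5 * i + k, 1) = atoms[k]->y;
      out(5 * i + k, 2) = atoms[k]->z;
    }
  }
  return out;
}

struct EnergyParams {
  double w_steric, w_hb, w_rg, w_tor;
  double r_clash, hb_lo, hb_hi, hb_depth;
  int s_cut;
  double basin_radius, rg_a, rg_b;
};

static EnergyParams as_params(List p) {
  EnergyParams ep;
  ep.w_steric = as<double>(p["w_steric"]);
  ep.w_hb = as<double>(p["w_hb"]);
  ep.w_rg = as<double>(p["w_rg"]);
  ep.w_tor = as<double>(p["w_tor"]);
  ep.r_clash = as<double>(p["r_clash"]);
  ep.hb_lo = as<double>(p["hb_lo"]);
  ep.hb_hi = as<double>(p["hb_hi"]);
  ep.hb_depth = as<double>(p["hb_depth"]);
  ep.s_cut = as<int>(p["s_cut"]);
  ep.basin_radius = as<double>(p["basin_radius"]);
  ep.rg_a = as<double>(p["rg_a"]);
  ep.rg_b = as<double>(p["rg_b"]);
  return ep;
}

static inline double wrap180(double x) {
  double y = x - 360.0 * std::floor(x / 360.0);  // [0, 360)
  if (y > 180.0) y -= 360.0;
  return y;
}

struct EnergyTerms {
  double steric, hb_sr, hb_lr, rg_pen, tor;
};

static EnergyTerms energy_terms(const NumericMatrix &dih,
                                const EnergyParams &ep, const Geometry &geo) {
  std::vector<Vec3> N, CA, C, O, CEN;
  rebuild(dih, geo, N, CA, C, O, CEN);
  int l = dih.nrow();
  EnergyTerms t{0.0, 0.0, 0.0, 0.0, 0.0};
  // soft steric repulsion on CA-CA and CEN-CEN pairs, separation >= 2
  for (int i = 0; i < l; ++i) {
    for (int j = i + 2; j < l; ++j) {
      double d = norm(sub(CA[i], CA[j]));
      if (d < ep.r_clash) {
        double u = (ep.r_clash - d) / ep.r_clash;
        t.steric += u * u;
      }
      d = norm(sub(CEN[i], CEN[j]));
      if (d < ep.r_clash) {
        double u = (ep.r_clash - d) / ep.r_clash;
        t.steric += u * u;
      }
    }
  }
  // backbone hydrogen-bond well on O(i)...N(j), |i-j| >= 3
  for (int i = 0; i < l; ++i) {
    for (int j = 0; j < l; ++j) {
      int sep = i > j ? i - j : j - i;
      if (sep < 3) continue;
      double d = norm(sub(O[i], N[j]));
      if (d >= ep.hb_lo && d <= ep.hb_hi) {
        if (sep <= ep.s_cut)
          t.hb_sr -= ep.hb_depth;
        else
          t.hb_lr -= ep.hb_depth;
      }
    }
  }
  // compactness: quadratic penalty above the target radius of gyration
  Vec3 cm{0, 0, 0};
  for (int i = 0; i < l; ++i) {
    cm.x += CA[i].x;
    cm.y += CA[i].y;
    cm.z += CA[i].z;
  }
  cm.x /= l;
  cm.y /= l;
  cm.z /= l;
  double s2 = 0.0;
  for (int i = 0; i < l; ++i) s2 += dot(sub(CA[i], cm), sub(CA[i], cm));
  double rg = std::sqrt(s2 / l);
  double rg0 = ep.rg_a * std::pow((double)l, ep.rg_b);
  double ex = rg > rg0 ? rg - rg0 : 0.0;
  t.rg_pen = ex * ex;
  // torsion preference: count residues with (phi, psi) outside the three
  // canonical Ramachandran basins
  const double basins[3][2] = {{-57.0, -47.0}, {-120.0, 120.0}, {60.0, 45.0}};
  for (int i = 0; i < l; ++i) {
    double best = R_PosInf;
    for (int b = 0; b < 3; ++b) {
      double dphi = wrap180(dih(i, 0) - basins[b][0]);
      double dpsi = wrap180(dih(i, 1) - basins[b][1]);
      double d = std::sqrt(dphi * dphi + dpsi * dpsi);
      if (d < best) best = d;
    }
    if (best > ep.basin_radius) t.tor += 1.0;
  }
  return t;
}

// stage: 0 = steric only, 1 = + hydrogen bonds, 3 = + compactness
static double stage_score(const NumericMatrix &dih, int stage,
                          const EnergyParams &ep, const Geometry &geo) {
  EnergyTerms t = energy_terms(dih, ep, geo);
  double s = ep.w_steric * t.steric;
  if (stage >= 1) s += ep.w_hb * (t.hb_sr + t.hb_lr);
  if (stage >= 3) s += ep.w_rg * t.rg_pen;
  return s;
}

// [[Rcpp::export(name = ".cpp_stage_score")]]
double cpp_stage_score(NumericMatrix dih, int stage, List params,
                       NumericVector geom) {
  return stage_score(dih, stage, as_params(params), as_geometry(geom));
}

// [[Rcpp::export(name = ".cpp_objectives")]]
NumericVector cpp_objectives(NumericMatrix dih, List params,
                             NumericVector geom) {
  EnergyParams ep = as_params(params);
  EnergyTerms t = energy_terms(dih, ep, as_geometry(geom));
  NumericVector out =
      NumericVector::create(_["E_sr_hb"] = ep.w_hb * t.hb_sr,
                            _["E_lr_hb"] = ep.w_hb * t.hb_lr,
                            _["E_other"] = ep.w_steric * t.steric +
                                           ep.w_rg * t.rg_pen +
                                           ep.w_tor * t.tor);
  return out;
}

// [[Rcpp::export(name = ".cpp_energy_terms")]]
NumericVector cpp_energy_terms(NumericMatrix dih, List params,
                               NumericVector geom) {
  EnergyTerms t = energy_terms(dih, as_params(params), as_geometry(geom));
  return NumericVector::create(_["steric"] = t.steric, _["hb_sr"] = t.hb_sr,
                               _["hb_lr"] = t.hb_lr, _["rg_pen"] = t.rg_pen,
                               _["tor"] = t.tor);
}

static inline int rand_index(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Replace the f-residue window starting at pos (0-based) with the config
// stored as a row (phi1, psi1, omega1, phi2, ...) of the library matrix.
static void apply_config(NumericMatrix &dih, int pos,
                         const NumericMatrix &configs, int row, int f) {
  for (int r = 0; r < f; ++r)
    for (int c = 0; c < 3; ++c) dih(pos + r, c) = configs(row, 3 * r + c);
}

// Metropolis criterion: downhill and flat moves always accepted; uphill
// moves with probability exp(-dE / alpha), never when alpha = 0.
static bool metropolis(double de, double alpha) {
  if (de <= 0.0) return true;
  if (alpha <= 0.0) return false;
  return unif_rand() < std::exp(-de / alpha);
}

// One MMC local-search stage. lib is a list over start positions of config
// matrices (n_config x 3f). Terminates on max_attempts proposals (if >= 0),
// on fail_limit consecutive rejections (if >= 0), or when the evaluation
// budget max_evals is exhausted. Every proposal scores once; the initial
// score also counts one evaluation.
// [[Rcpp::export(name = ".cpp_mmc_stage")]]
List cpp_mmc_stage(NumericMatrix dih0, List lib, int f, int stage,
                   double alpha, int max_attempts, int fail_limit, List params,
                   NumericVector geom, double max_evals) {
  EnergyParams ep = as_params(params);
  Geometry geo = as_geometry(geom);
  NumericMatrix dih = clone(dih0);
  int npos = lib.size();
  double evals = 0.0;
  int attempts = 0, accepts = 0, fails = 0;
  if (max_evals < 1.0)
    return List::create(_["dihedrals"] = dih, _["evals"] = evals,
                        _["attempts"] = attempts, _["accepts"] = accepts);
  double cur = stage_score(dih, stage, ep, geo);
  evals += 1.0;
  while ((max_attempts < 0 || attempts < max_attempts) &&
         (fail_limit < 0 || fails < fail_limit) && evals < max_evals) {
    int pos = rand_index(npos);
    NumericMatrix configs = lib[pos];
    int row = rand_index(configs.nrow());
    NumericMatrix cand = clone(dih);
    apply_config(cand, pos, configs, row, f);
    double s = stage_score(cand, stage, ep, geo);
    evals += 1.0;
    ++attempts;
    if (metropolis(s - cur, alpha)) {
      dih = cand;
      cur = s;
      ++accepts;
      fails = 0;
    } else {
      ++fails;
    }
  }
  return List::create(_["dihedrals"] = dih, _["evals"] = evals,
                      _["attempts"] = attempts, _["accepts"] = accepts,
                      _["score"] = cur);
}

// Greedy improvement: f = 3 fragment moves accepted only on a strict
// decrease of the stage-3 score; stops after k consecutive failures or when
// the evaluation budget runs out. Returns the accepted-score trace.
// [[Rcpp::export(name = ".cpp_improve")]]
List cpp_improve(NumericMatrix dih0, List lib, int k, List params,
                 NumericVector geom, double max_evals) {
  EnergyParams ep = as_params(params);
  Geometry geo = as_geometry(geom);
  NumericMatrix dih = clone(dih0);
  int npos = lib.size();
  double evals = 0.0;
  int proposals = 0, accepts = 0, fails = 0;
  std::vector<double> trace;
  if (max_evals < 1.0)
    return List::create(_["dihedrals"] = dih, _["evals"] = evals,
                        _["proposals"] = proposals, _["accepts"] = accepts,
                        _["trace"] = NumericVector(trace.begin(), trace.end()));
  double cur = stage_score(dih, 3, ep, geo);
  evals += 1.0;
  trace.push_back(cur);
  while (fails < k && evals < max_evals) {
    int pos = rand_index(npos);
    NumericMatrix configs = lib[pos];
    int row = rand_index(configs.nrow());
    NumericMatrix cand = clone(dih);
    apply_config(cand, pos, configs, row, 3);
    double s = stage_score(cand, 3, ep, geo);
    evals += 1.0;
    ++proposals;
    if (s < cur) {
      dih = cand;
      cur = s;
      ++accepts;
      fails = 0;
      trace.push_back(cur);
    } else {
      ++fails;
    }
  }
  return List::create(_["dihedrals"] = dih, _["evals"] = evals,
                      _["proposals"] = proposals, _["accepts"] = accepts,
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}
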