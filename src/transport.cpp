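// Woodcock delta-tracking photon transport through a voxel phantom under the
// kerma approximation: photoelectric absorption deposits locally, Compton
// scattering follows the free-electron Klein-Nishina distribution with the
// recoil energy deposited at the interaction site, Rayleigh scattering uses
// the Thomson angular shape with no deposit. Track-length energy-fluence and
// energy-deposition tallies are scored in axis-aligned cylinders or voxel
// masks. All randomness comes from R's RNG so runs are reproducible from
// set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double EPS = 1e-9;

struct Cyl {
  int kind;        // 0 = edep, 1 = efluence
  double c[3];
  int axis;        // 0,1,2
  double radius, half_len;
  int nbins;       // efluence only
  double emin, emax;
  double edep;             // keV (kind 0)
  std::vector<double> flu; // mm track length per energy bin (kind 1)
};

static inline double interp_row(const NumericMatrix& m, int row, int i0,
                                double w) {
  return m(row, i0) * (1.0 - w) + m(row, i0 + 1) * w;
}

// overlap length of segment p + t*d, t in [0, seg], with axis-aligned cylinder
static double cyl_overlap(const Cyl& cy, const double* p, const double* d,
                          double seg) {
  int a = cy.axis, r1 = (a + 1) % 3, r2 = (a + 2) % 3;
  double pa = p[a] - cy.c[a], da = d[a];
  double px = p[r1] - cy.c[r1], py = p[r2] - cy.c[r2];
  double dx = d[r1], dy = d[r2];
  double lo = 0.0, hi = seg;
  // radial constraint
  double A = dx * dx + dy * dy;
  double C = px * px + py * py - cy.radius * cy.radius;
  if (A < EPS) {
    if (C > 0) return 0.0;
  } else {
    double B = 2.0 * (px * dx + py * dy);
    double disc = B * B - 4.0 * A * C;
    if (disc <= 0) return 0.0;
    double sq = std::sqrt(disc);
    double t1 = (-B - sq) / (2.0 * A), t2 = (-B + sq) / (2.0 * A);
    if (t1 > lo) lo = t1;
    if (t2 < hi) hi = t2;
  }
  // axial constraint
  if (std::fabs(da) < EPS) {
    if (std::fabs(pa) > cy.half_len) return 0.0;
  } else {
    double t1 = (-cy.half_len - pa) / da, t2 = (cy.half_len - pa) / da;
    if (t1 > t2) std::swap(t1, t2);
    if (t1 > lo) lo = t1;
    if (t2 < hi) hi = t2;
  }
  return (hi > lo) ? (hi - lo) : 0.0;
}

static inline bool point_in_cyl(const Cyl& cy, const double* p) {
  int a = cy.axis, r1 = (a + 1) % 3, r2 = (a + 2) % 3;
  double px = p[r1] - cy.c[r1], py = p[r2] - cy.c[r2];
  if (px * px + py * py > cy.radius * cy.radius) return false;
  return std::fabs(p[a] - cy.c[a]) <= cy.half_len;
}

// Klein-Nishina scattering: sample cos(theta) by rejection (envelope f(1)=2),
// return scattered energy via the Compton relation.
static void kn_scatter(double E, double& Eout, double& mu) {
  double alpha = E / 510.999;
  for (;;) {
    double m = -1.0 + 2.0 * unif_rand();
    double r = 1.0 / (1.0 + alpha * (1.0 - m));
    double f = r * r * (r + 1.0 / r - 1.0 + m * m);
    if (2.0 * unif_rand() <= f) { mu = m; Eout = E * r; return; }
  }
}

static double thomson_mu() {
  for (;;) {
    double m = -1.0 + 2.0 * unif_rand();
    if (unif_rand() <= 0.5 * (1.0 + m * m)) return m;
  }
}

// rotate unit vector d by polar angle (cos = mu) about itself, uniform azimuth
static void rotate_direction(double* d, double mu) {
  double phi = 2.0 * M_PI * unif_rand();
  double sint = std::sqrt(std::max(0.0, 1.0 - mu * mu));
  double u[3], v[3];
  // orthonormal basis perpendicular to d
  if (std::fabs(d[2]) < 0.99) {
    double n = std::sqrt(d[0] * d[0] + d[1] * d[1]);
    u[0] = -d[1] / n; u[1] = d[0] / n; u[2] = 0.0;
  } else {
    double n = std::sqrt(d[1] * d[1] + d[2] * d[2]);
    u[0] = 0.0; u[1] = -d[2] / n; u[2] = d[1] / n;
  }
  v[0] = d[1] * u[2] - d[2] * u[1];
  v[1] = d[2] * u[0] - d[0] * u[2];
  v[2] = d[0] * u[1] - d[1] * u[0];
  double ca = std::cos(phi) * sint, sa = std::sin(phi) * sint;
  for (int k = 0; k < 3; ++k) d[k] = mu * d[k] + ca * u[k] + sa * v[k];
  double n = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  for (int k = 0; k < 3; ++k) d[k] /= n;
}

// [[Rcpp::export]]
List transport_kernel(NumericMatrix pos, NumericMatrix dir,
                      NumericVector energy, NumericVector weight,
                      IntegerVector dims, NumericVector spacing,
                      NumericVector origin, IntegerVector mat_index,
                      NumericVector density, double egrid_min,
                      double egrid_step, NumericMatrix mr_tot,
                      NumericMatrix mr_pe, NumericMatrix mr_inc,
                      NumericVector mu_majorant, double cutoff_keV,
                      List tallies, bool record_first_collision = false) {
  const int n = pos.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ne = mu_majorant.size();
  double box_lo[3], box_hi[3];
  for (int k = 0; k < 3; ++k) {
    box_lo[k] = origin[k] - 0.5 * spacing[k];
    box_hi[k] = origin[k] + (dims[k] - 0.5) * spacing[k];
  }
  std::vector<Cyl> cyls;
  std::vector<int> mask;          // voxel-mask edep tally (at most one)
  double mask_edep = 0.0;
  bool has_mask = false;
  for (int i = 0; i < tallies.size(); ++i) {
    List tl = tallies[i];
    std::string kind = as<std::string>(tl["kind"]);
    if (kind == "mask") {
      mask = as<std::vector<int> >(tl["mask"]);   // 0/1 per voxel
      has_mask = true;
      Cyl cy; cy.kind = 2; cyls.push_back(cy);    // placeholder slot
      continue;
    }
    Cyl cy;
    cy.kind = (kind == "efluence") ? 1 : 0;
    NumericVector c = tl["center"];
    cy.c[0] = c[0]; cy.c[1] = c[1]; cy.c[2] = c[2];
    cy.axis = as<int>(tl["axis"]);
    cy.radius = as<double>(tl["radius"]);
    cy.half_len = as<double>(tl["half_length"]);
    cy.edep = 0.0;
    if (cy.kind == 1) {
      cy.nbins = as<int>(tl["nbins"]);
      cy.emin = as<double>(tl["emin"]);
      cy.emax = as<double>(tl["emax"]);
      cy.flu.assign(cy.nbins, 0.0);
    }
    cyls.push_back(cy);
  }
  double total_edep = 0.0, escape_E = 0.0;
  int n_escaped = 0;
  NumericVector first_dist;
  if (record_first_collision) {
    first_dist = NumericVector(n, NA_REAL);
  }

  for (int ip = 0; ip < n; ++ip) {
    double p[3] = { pos(ip, 0), pos(ip, 1), pos(ip, 2) };
    double d[3] = { dir(ip, 0), dir(ip, 1), dir(ip, 2) };
    double E = energy[ip], w = weight[ip];
    double travelled = 0.0;
    bool had_real = false;

    // advance to the grid box if starting outside
    bool inside = true;
    for (int k = 0; k < 3; ++k)
      if (p[k] < box_lo[k] || p[k] > box_hi[k]) inside = false;
    if (!inside) {
      double tmin = 0.0, tmax = 1e300;
      bool hit = true;
      for (int k = 0; k < 3; ++k) {
        if (std::fabs(d[k]) < EPS) {
          if (p[k] < box_lo[k] || p[k] > box_hi[k]) { hit = false; break; }
        } else {
          double t1 = (box_lo[k] - p[k]) / d[k];
          double t2 = (box_hi[k] - p[k]) / d[k];
          if (t1 > t2) std::swap(t1, t2);
          if (t1 > tmin) tmin = t1;
          if (t2 < tmax) tmax = t2;
        }
      }
      if (!hit || tmax <= tmin || tmax < 0) {
        escape_E += E * w; ++n_escaped; continue;
      }
      double t0 = tmin + 1e-7;
      for (int k = 0; k < 3; ++k) p[k] += t0 * d[k];
    }

    bool alive = true;
    while (alive) {
      // energy grid lookup
      double fi = (E - egrid_min) / egrid_step;
      int i0 = (int)std::floor(fi);
      if (i0 < 0) i0 = 0;
      if (i0 > ne - 2) i0 = ne - 2;
      double fw = fi - i0;
      if (fw < 0) fw = 0; if (fw > 1) fw = 1;
      double mu_maj = std::max(mu_majorant[i0], mu_majorant[i0 + 1]);
      // distance to box exit
      double t_exit = 1e300;
      for (int k = 0; k < 3; ++k) {
        if (std::fabs(d[k]) < EPS) continue;
        double tb = (d[k] > 0 ? box_hi[k] - p[k] : box_lo[k] - p[k]) / d[k];
        if (tb < t_exit) t_exit = tb;
      }
      if (t_exit < 0) t_exit = 0;
      double s = (mu_maj > 0) ? -std::log(unif_rand()) / mu_maj : 1e300;
      double seg = std::min(s, t_exit);
      for (size_t ic = 0; ic < cyls.size(); ++ic) {
        Cyl& cy = cyls[ic];
        if (cy.kind != 1) continue;
        double L = cyl_overlap(cy, p, d, seg);
        if (L > 0 && E > cy.emin && E <= cy.emax) {
          int b = (int)((E - cy.emin) / (cy.emax - cy.emin) * cy.nbins);
          if (b >= cy.nbins) b = cy.nbins - 1;
          cy.flu[b] += L * w;
        }
      }
      if (s >= t_exit) {                 // leaves the grid
        escape_E += E * w; ++n_escaped;
        break;
      }
      for (int k = 0; k < 3; ++k) p[k] += s * d[k];
      travelled += s;
      int ix = (int)std::floor((p[0] - box_lo[0]) / spacing[0]);
      int iy = (int)std::floor((p[1] - box_lo[1]) / spacing[1]);
      int iz = (int)std::floor((p[2] - box_lo[2]) / spacing[2]);
      if (ix < 0) ix = 0; if (ix >= nx) ix = nx - 1;
      if (iy < 0) iy = 0; if (iy >= ny) iy = ny - 1;
      if (iz < 0) iz = 0; if (iz >= nz) iz = nz - 1;
      int v = ix + nx * (iy + ny * iz);
      int m = mat_index[v];
      double rho = density[v];
      double mu_tot = interp_row(mr_tot, m, i0, fw) * rho;
      if (unif_rand() * mu_maj > mu_tot) continue;     // virtual collision
      if (record_first_collision && !had_real) {
        first_dist[ip] = travelled;
        had_real = true;
      }
      double xi = unif_rand() * mu_tot;
      double mu_pe = interp_row(mr_pe, m, i0, fw) * rho;
      double mu_inc = interp_row(mr_inc, m, i0, fw) * rho;
      double dep = 0.0;
      if (xi < mu_pe) {                  // photoelectric: local absorption
        dep = E; alive = false;
      } else if (xi < mu_pe + mu_inc) {  // Compton
        double Eout, mu_cos;
        kn_scatter(E, Eout, mu_cos);
        dep = E - Eout;
        if (Eout <= cutoff_keV) { dep = E; alive = false; }
        else { E = Eout; rotate_direction(d, mu_cos); }
      } else {                           // Rayleigh: elastic
        rotate_direction(d, thomson_mu());
      }
      if (dep > 0) {
        total_edep += dep * w;
        for (size_t ic = 0; ic < cyls.size(); ++ic) {
          Cyl& cy = cyls[ic];
          if (cy.kind == 0 && point_in_cyl(cy, p)) cy.edep += dep * w;
        }
        if (has_mask && mask[v]) mask_edep += dep * w;
      }
    }
  }

  List scores(cyls.size());
  for (size_t ic = 0; ic < cyls.size(); ++ic) {
    if (cyls[ic].kind == 1) scores[ic] = NumericVector(cyls[ic].flu.begin(),
                                                       cyls[ic].flu.end());
    else if (cyls[ic].kind == 2) scores[ic] = mask_edep;
    else scores[ic] = cyls[ic].edep;
  }
  List out = List::create(_["scores"] = scores,
                          _["total_edep"] = total_edep,
                          _["escape_energy"] = escape_E,
                          _["n_escaped"] = n_escaped);
  if (record_first_collision) out["first_collision_mm"] = first_dist;
  return out;
}

// [[Rcpp::export]]
NumericMatrix kn_sample_cpp(int n, double energy) {
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double E, mu;
    kn_scatter(energy, E, mu);
    out(i, 0) = E;
    out(i, 1) = mu;
  }
  colnames(out) = CharacterVector::create("energy_keV", "cos_theta");
  return out;
}

// [[Rcpp::export]]
NumericVector thomson_sample_cpp(int n) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = thomson_mu();
  return out;
}
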