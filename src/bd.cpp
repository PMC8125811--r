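// Overdamped Brownian-dynamics core: rigid-body translation/rotation for
// domains and ligand, bead-level propagation for flexible linker beads,
// Debye-Hueckel screened electrostatics + WCA excluded volume between
// molecules, harmonic bonds/angles along the linker, and an optional
// Gaussian attraction well anchored at the native ligand site.
//
// Units: Angstrom, ns, kcal/mol, elementary charge. Uses R's RNG so that
// set.seed() in R makes every trajectory bit-reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double min_image(double d, double box) {
  if (box > 0.0) d -= box * std::round(d / box);
  return d;
}

struct Vec3 { double x, y, z; };

// Rodrigues rotation of v about unit axis u by angle a
static inline Vec3 rotate(const Vec3& v, const Vec3& u, double a) {
  double c = std::cos(a), s = std::sin(a);
  double dot = u.x * v.x + u.y * v.y + u.z * v.z;
  Vec3 cr = {u.y * v.z - u.z * v.y, u.z * v.x - u.x * v.z,
             u.x * v.y - u.y * v.x};
  Vec3 out;
  out.x = v.x * c + cr.x * s + u.x * dot * (1.0 - c);
  out.y = v.y * c + cr.y * s + u.y * dot * (1.0 - c);
  out.z = v.z * c + cr.z * s + u.z * dot * (1.0 - c);
  return out;
}

// [[Rcpp::export]]
List bd_run_cpp(NumericMatrix coords0, NumericVector charge,
                NumericVector radius, NumericVector mass,
                IntegerVector body, IntegerVector molecule,
                NumericVector body_dt, NumericVector body_dr,
                IntegerMatrix bond_ij, NumericVector bond_r0,
                NumericVector bond_k, IntegerMatrix angle_ijk,
                NumericVector ang_t0, NumericVector ang_k,
                IntegerVector site_beads, double box, double kBT,
                double lB, double kappa, double ev_eps, double well_depth,
                double well_width, double cutoff, double dt, double t0,
                int n_steps, int stride, int bind_mode,
                double bind_threshold, double contact_cutoff,
                int check_every, double noise_scale, bool stop_on_bind,
                bool record_frames) {
  const int n = coords0.nrow();
  const int nb = body_dt.size();
  const int n_bonds = bond_ij.nrow();
  const int n_angles = angle_ijk.nrow();
  const double cutoff2 = cutoff * cutoff;
  const double ccut2 = contact_cutoff * contact_cutoff;

  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords0(i, 0); y[i] = coords0(i, 1); z[i] = coords0(i, 2);
  }
  std::vector<int> lig, rec;
  for (int i = 0; i < n; ++i) (molecule[i] == 1 ? lig : rec).push_back(i);
  const int n_lig = (int)lig.size(), n_rec = (int)rec.size();

  // per-body bead lists and mass
  std::vector<std::vector<int> > members(nb);
  std::vector<double> body_mass(nb, 0.0);
  for (int i = 0; i < n; ++i) {
    members[body[i]].push_back(i);
    body_mass[body[i]] += mass[i];
  }
  double min_radius = radius[0];
  for (int i = 1; i < n; ++i) min_radius = std::min(min_radius, radius[i]);

  std::vector<double> fx(n), fy(n), fz(n);

  const int n_frames_max = n_steps / stride + 2;
  NumericMatrix frames(record_frames ? n_frames_max : 1, 3 * n);
  NumericVector times(n_frames_max), energies(n_frames_max),
      contacts_out(n_frames_max), com_out(n_frames_max);
  int n_frames = 0;
  double fpt = NA_REAL;
  bool bound = false;

  RNGScope rng;

  // --- helpers as lambdas ---
  auto compute_forces = [&](double* energy) -> void {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    double U = 0.0;
    // inter-molecular nonbonded: DH electrostatics + WCA
    for (int a = 0; a < n_rec; ++a) {
      const int i = rec[a];
      for (int b = 0; b < n_lig; ++b) {
        const int j = lig[b];
        double dxx = min_image(x[i] - x[j], box);
        double dyy = min_image(y[i] - y[j], box);
        double dzz = min_image(z[i] - z[j], box);
        double r2 = dxx * dxx + dyy * dyy + dzz * dzz;
        if (r2 > cutoff2 || r2 <= 0.0) continue;
        double r = std::sqrt(r2);
        double fmag = 0.0; // dU/dr (negative of radial force)
        if (lB > 0.0 && charge[i] != 0.0 && charge[j] != 0.0) {
          double pref = kBT * lB * charge[i] * charge[j];
          double screen = (kappa > 0.0) ? std::exp(-kappa * r) : 1.0;
          double u_el = pref * screen / r;
          U += u_el;
          fmag += -u_el * (1.0 / r + kappa);
        }
        // soft-core overlap repulsion: bounded force, BD-step safe
        double sigma = radius[i] + radius[j];
        if (ev_eps > 0.0 && r < sigma) {
          double ov = 1.0 - r / sigma;
          U += ev_eps * ov * ov;
          fmag += -2.0 * ev_eps * ov / sigma;
        }
        if (fmag != 0.0) {
          double s = -fmag / r; // radial force / r
          fx[i] += s * dxx; fy[i] += s * dyy; fz[i] += s * dzz;
          fx[j] -= s * dxx; fy[j] -= s * dyy; fz[j] -= s * dzz;
        }
      }
    }
    // bonds (no imaging: molecules kept whole/unwrapped)
    for (int bnd = 0; bnd < n_bonds; ++bnd) {
      int i = bond_ij(bnd, 0), j = bond_ij(bnd, 1);
      double dxx = x[i] - x[j], dyy = y[i] - y[j], dzz = z[i] - z[j];
      double r = std::sqrt(dxx * dxx + dyy * dyy + dzz * dzz);
      if (r <= 1e-12) continue;
      double dr = r - bond_r0[bnd];
      U += bond_k[bnd] * dr * dr;
      double s = -2.0 * bond_k[bnd] * dr / r;
      fx[i] += s * dxx; fy[i] += s * dyy; fz[i] += s * dzz;
      fx[j] -= s * dxx; fy[j] -= s * dyy; fz[j] -= s * dzz;
    }
    // angles
    for (int an = 0; an < n_angles; ++an) {
      int i = angle_ijk(an, 0), j = angle_ijk(an, 1), k = angle_ijk(an, 2);
      double ax = x[i] - x[j], ay = y[i] - y[j], az = z[i] - z[j];
      double bx = x[k] - x[j], by = y[k] - y[j], bz = z[k] - z[j];
      double la = std::sqrt(ax * ax + ay * ay + az * az);
      double lb2 = std::sqrt(bx * bx + by * by + bz * bz);
      if (la <= 1e-12 || lb2 <= 1e-12) continue;
      double c = (ax * bx + ay * by + az * bz) / (la * lb2);
      c = std::max(-1.0, std::min(1.0, c));
      double s = std::sqrt(std::max(1e-12, 1.0 - c * c));
      double th = std::acos(c);
      double dth = th - ang_t0[an];
      U += 0.5 * ang_k[an] * dth * dth;
      double coef = ang_k[an] * dth / s;
      double fix = coef * (bx / (la * lb2) - c * ax / (la * la));
      double fiy = coef * (by / (la * lb2) - c * ay / (la * la));
      double fiz = coef * (bz / (la * lb2) - c * az / (la * la));
      double fkx = coef * (ax / (la * lb2) - c * bx / (lb2 * lb2));
      double fky = coef * (ay / (la * lb2) - c * by / (lb2 * lb2));
      double fkz = coef * (az / (la * lb2) - c * bz / (lb2 * lb2));
      fx[i] += fix; fy[i] += fiy; fz[i] += fiz;
      fx[k] += fkx; fy[k] += fky; fz[k] += fkz;
      fx[j] -= fix + fkx; fy[j] -= fiy + fky; fz[j] -= fiz + fkz;
    }
    // native-site Gaussian well on the ligand centre of mass
    if (well_depth > 0.0 && site_beads.size() > 0 && n_lig > 0) {
      double sx = 0, sy = 0, sz = 0;
      for (int m = 0; m < site_beads.size(); ++m) {
        int i = site_beads[m];
        sx += x[i]; sy += y[i]; sz += z[i];
      }
      sx /= site_beads.size(); sy /= site_beads.size();
      sz /= site_beads.size();
      double cxl = 0, cyl = 0, czl = 0, ml = 0;
      for (int b = 0; b < n_lig; ++b) {
        int j = lig[b];
        cxl += mass[j] * x[j]; cyl += mass[j] * y[j]; czl += mass[j] * z[j];
        ml += mass[j];
      }
      cxl /= ml; cyl /= ml; czl /= ml;
      double dxx = min_image(cxl - sx, box);
      double dyy = min_image(cyl - sy, box);
      double dzz = min_image(czl - sz, box);
      double d2 = dxx * dxx + dyy * dyy + dzz * dzz;
      double w2 = well_width * well_width;
      double u = -well_depth * std::exp(-0.5 * d2 / w2);
      U += u;
      // radial force on ligand COM toward the site: F = -dU/dd * dhat
      double fcoef = u / w2; // (-dU/dd)/d = -(depth*exp()*d/w2)/d
      double gx = fcoef * dxx, gy = fcoef * dyy, gz = fcoef * dzz;
      for (int b = 0; b < n_lig; ++b) {
        int j = lig[b];
        double wgt = mass[j] / ml; // mass-weighted COM force share
        fx[j] += gx * wgt;
        fy[j] += gy * wgt;
        fz[j] += gz * wgt;
      }
      // reaction on the site beads
      for (int m = 0; m < site_beads.size(); ++m) {
        int i = site_beads[m];
        fx[i] -= gx / site_beads.size();
        fy[i] -= gy / site_beads.size();
        fz[i] -= gz / site_beads.size();
      }
    }
    if (energy) *energy = U;
  };

  auto count_contacts_now = [&]() -> int {
    int cnt = 0;
    for (int a = 0; a < n_rec; ++a) {
      const int i = rec[a];
      for (int b = 0; b < n_lig; ++b) {
        const int j = lig[b];
        double dxx = min_image(x[i] - x[j], box);
        double dyy = min_image(y[i] - y[j], box);
        double dzz = min_image(z[i] - z[j], box);
        if (dxx * dxx + dyy * dyy + dzz * dzz <= ccut2) ++cnt;
      }
    }
    return cnt;
  };

  auto com_distance_now = [&]() -> double {
    double cr[3] = {0, 0, 0}, cl[3] = {0, 0, 0}, mr = 0, ml = 0;
    for (int a = 0; a < n_rec; ++a) {
      int i = rec[a];
      cr[0] += mass[i] * x[i]; cr[1] += mass[i] * y[i];
      cr[2] += mass[i] * z[i]; mr += mass[i];
    }
    for (int b = 0; b < n_lig; ++b) {
      int j = lig[b];
      cl[0] += mass[j] * x[j]; cl[1] += mass[j] * y[j];
      cl[2] += mass[j] * z[j]; ml += mass[j];
    }
    double dxx = min_image(cr[0] / mr - cl[0] / ml, box);
    double dyy = min_image(cr[1] / mr - cl[1] / ml, box);
    double dzz = min_image(cr[2] / mr - cl[2] / ml, box);
    return std::sqrt(dxx * dxx + dyy * dyy + dzz * dzz);
  };

  auto emit_frame = [&](double t) {
    if (n_frames >= n_frames_max) return;
    if (record_frames) {
      for (int i = 0; i < n; ++i) {
        frames(n_frames, 3 * i) = x[i];
        frames(n_frames, 3 * i + 1) = y[i];
        frames(n_frames, 3 * i + 2) = z[i];
      }
    }
    double U;
    compute_forces(&U);
    times[n_frames] = t;
    energies[n_frames] = U;
    contacts_out[n_frames] = count_contacts_now();
    com_out[n_frames] = com_distance_now();
    ++n_frames;
  };

  emit_frame(t0);
  if (bind_mode == 1 && contacts_out[0] >= bind_threshold) {
    bound = true; fpt = t0;
  } else if (bind_mode == 2 && com_out[0] <= bind_threshold) {
    bound = true; fpt = t0;
  }

  const double sqrt2dt = std::sqrt(2.0 * dt);
  int step = 0;
  while (step < n_steps && !(bound && stop_on_bind)) {
    compute_forces(nullptr);
    // propagate each body
    for (int bidx = 0; bidx < nb; ++bidx) {
      const std::vector<int>& mem = members[bidx];
      if (mem.empty()) continue;
      double Dt = body_dt[bidx], Dr = body_dr[bidx];
      if (Dt <= 0.0 && Dr <= 0.0) continue;
      double Fx = 0, Fy = 0, Fz = 0;
      for (size_t m = 0; m < mem.size(); ++m) {
        Fx += fx[mem[m]]; Fy += fy[mem[m]]; Fz += fz[mem[m]];
      }
      double drift = Dt * dt / kBT;
      double ddx = drift * Fx, ddy = drift * Fy, ddz = drift * Fz;
      // displacement limiter: cap the deterministic step at half the
      // smallest bead radius so transient force spikes (overlaps kicked in
      // by the noise) cannot destabilise the Euler step
      double dmag = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
      double cap = 0.5 * min_radius;
      if (dmag > cap) {
        double sc = cap / dmag;
        ddx *= sc; ddy *= sc; ddz *= sc;
      }
      if (Dt > 0.0) {
        double ns_ = noise_scale * sqrt2dt * std::sqrt(Dt);
        ddx += ns_ * norm_rand();
        ddy += ns_ * norm_rand();
        ddz += ns_ * norm_rand();
        for (size_t m = 0; m < mem.size(); ++m) {
          x[mem[m]] += ddx; y[mem[m]] += ddy; z[mem[m]] += ddz;
        }
      }
      if (Dr > 0.0 && mem.size() > 1) {
        // COM and torque
        double cx = 0, cy = 0, cz = 0, mm = 0;
        for (size_t m = 0; m < mem.size(); ++m) {
          int i = mem[m];
          cx += mass[i] * x[i]; cy += mass[i] * y[i]; cz += mass[i] * z[i];
          mm += mass[i];
        }
        cx /= mm; cy /= mm; cz /= mm;
        double Tx = 0, Ty = 0, Tz = 0;
        for (size_t m = 0; m < mem.size(); ++m) {
          int i = mem[m];
          double rx_ = x[i] - cx, ry_ = y[i] - cy, rz_ = z[i] - cz;
          Tx += ry_ * fz[i] - rz_ * fy[i];
          Ty += rz_ * fx[i] - rx_ * fz[i];
          Tz += rx_ * fy[i] - ry_ * fx[i];
        }
        double rdrift = Dr * dt / kBT;
        double wx = rdrift * Tx, wy = rdrift * Ty, wz = rdrift * Tz;
        double nr = noise_scale * sqrt2dt * std::sqrt(Dr);
        wx += nr * norm_rand(); wy += nr * norm_rand();
        wz += nr * norm_rand();
        double ang = std::sqrt(wx * wx + wy * wy + wz * wz);
        if (ang > 1e-14) {
          Vec3 u = {wx / ang, wy / ang, wz / ang};
          for (size_t m = 0; m < mem.size(); ++m) {
            int i = mem[m];
            Vec3 v = {x[i] - cx, y[i] - cy, z[i] - cz};
            Vec3 w = rotate(v, u, ang);
            x[i] = cx + w.x; y[i] = cy + w.y; z[i] = cz + w.z;
          }
        }
      }
    }
    ++step;
    double t = t0 + step * dt;
    bool do_check = (bind_mode != 0) && !bound && (step % check_every == 0);
    if (do_check) {
      if (bind_mode == 1) {
        if (count_contacts_now() >= bind_threshold) { bound = true; fpt = t; }
      } else if (bind_mode == 2) {
        if (com_distance_now() <= bind_threshold) { bound = true; fpt = t; }
      }
    }
    if (step % stride == 0 || (bound && stop_on_bind)) emit_frame(t);
  }

  List out = List::create(
      Named("frames") = frames, Named("times") = times,
      Named("energies") = energies, Named("contacts") = contacts_out,
      Named("com_distance") = com_out, Named("n_frames") = n_frames,
      Named("fpt") = fpt, Named("bound") = bound);
  return out;
}
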