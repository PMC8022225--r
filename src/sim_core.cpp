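#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Confined Brownian motion simulator for rod-shaped bacterial cells.
//
// The cell volume is a stack of contiguous coaxial cylindrical segments
// along x; a molecule at (x, y, z) is inside iff x lies within the axial
// extent and y^2 + z^2 < r(x)^2.  Each camera frame is split into n_sub
// sub-frames; per sub-frame the molecule takes an isotropic Gaussian step
// with per-axis variance 2 * D * dt_sub, where D is the diffusion
// coefficient of the state occupied at the sub-frame start (bound dwell
// times ~ Exp(mean_t_bound), free dwells ~ Exp(mean_t_free)).  Confinement
// is specular: steps crossing the axial ends or the cylindrical wall are
// reflected; in the rare case the reflected point is still outside (a step
// across a sharp radius change), the move is rejected and the molecule
// stays put.  The observed frame position is the mean of the sub-frame
// (x, y) positions plus Gaussian localization noise.  All randomness comes
// from R's RNG so set.seed() in the caller fixes the output.

struct Geom {
  std::vector<double> start, end, radius, cumvol;
  double x0, x1, total_vol;
};

static inline int seg_index(const Geom &g, double x) {
  // binary search: first segment with end > x
  int lo = 0, hi = (int)g.end.size() - 1;
  if (x <= g.start[0]) return 0;
  if (x >= g.end[hi]) return hi;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (g.end[mid] > x) hi = mid; else lo = mid + 1;
  }
  return lo;
}

static Geom make_geom(NumericVector s, NumericVector e, NumericVector r) {
  Geom g;
  int n = s.size();
  g.start.assign(s.begin(), s.end());
  g.end.assign(e.begin(), e.end());
  g.radius.assign(r.begin(), r.end());
  g.cumvol.resize(n);
  double acc = 0.0;
  for (int i = 0; i < n; i++) {
    acc += M_PI * r[i] * r[i] * (e[i] - s[i]);
    g.cumvol[i] = acc;
  }
  g.total_vol = acc;
  g.x0 = g.start[0];
  g.x1 = g.end[n - 1];
  return g;
}

static void uniform_point(const Geom &g, double &x, double &y, double &z) {
  // segment chosen with probability proportional to its volume
  double u = unif_rand() * g.total_vol;
  int i = 0, n = (int)g.cumvol.size();
  while (i < n - 1 && g.cumvol[i] < u) i++;
  x = g.start[i] + unif_rand() * (g.end[i] - g.start[i]);
  double r = g.radius[i], rho, yy, zz;
  do {  // rejection sampling in the disc
    yy = (2.0 * unif_rand() - 1.0) * r;
    zz = (2.0 * unif_rand() - 1.0) * r;
    rho = yy * yy + zz * zz;
  } while (rho >= r * r);
  y = yy; z = zz;
}

// Reflect a proposed position into the geometry (specular). Three walls
// exist in a stepped-cylinder cell: the axial end planes, the radius-step
// faces between segments of different radii, and the curved cylindrical
// wall of the local segment. A step that lands in a narrower segment while
// its radial distance fits the segment it came from has crossed a
// radius-step face and is reflected axially; a step whose radial distance
// exceeds the local radius has crossed the curved wall and is folded
// radially. Returns false if the point cannot be brought inside (caller
// rejects the move and the molecule stays put).
static inline bool confine(const Geom &g, double x_old,
                           double &x, double &y, double &z) {
  for (int it = 0; it < 4; it++) {
    if (x < g.x0) { x = 2.0 * g.x0 - x; continue; }
    if (x > g.x1) { x = 2.0 * g.x1 - x; continue; }
    int si = seg_index(g, x);
    double r = g.radius[si];
    double rho2 = y * y + z * z;
    if (rho2 < r * r) return true;
    double rho = std::sqrt(rho2);
    int so = seg_index(g, x_old);
    if (so != si && g.radius[so] >= rho) {
      // crossed a radius-step face: reflect off the last interface whose
      // far side still admits this radial distance
      if (x > x_old) {
        int k = so;
        while (k + 1 <= si && g.radius[k + 1] >= rho) k++;
        double wall = g.end[k];
        if (x > wall) { x = 2.0 * wall - x; continue; }
      } else {
        int k = so;
        while (k - 1 >= si && g.radius[k - 1] >= rho) k--;
        double wall = g.start[k];
        if (x < wall) { x = 2.0 * wall - x; continue; }
      }
    }
    // curved wall of the local segment: fold radially
    double rr = 2.0 * r - rho;
    if (rr <= 0.0 || rr >= r) return false;
    double f = rr / rho;
    y *= f; z *= f;
    return true;
  }
  return false;
}

// [[Rcpp::export(name = ".sim_tracks_cpp")]]
List sim_tracks_cpp(NumericVector seg_start, NumericVector seg_end,
                    NumericVector seg_radius, int n_molecules,
                    double D_free, double D_bound, bool switching,
                    double phi, double mean_t_bound,
                    double frame_dt, int n_sub, double sigma_loc,
                    double bleach_mean, int movie_frames, int max_frames,
                    bool keep_truth, bool dstar_only, int n_dstar_steps) {
  Geom g = make_geom(seg_start, seg_end, seg_radius);
  double dt_sub = frame_dt / n_sub;
  double mean_t_free = (switching && phi < 1.0)
    ? mean_t_bound * (1.0 - phi) / phi : 0.0;  // unused when phi==1
  double sd_free = std::sqrt(2.0 * D_free * dt_sub);
  double sd_bound = std::sqrt(2.0 * D_bound * dt_sub);

  std::vector<int> loc_mol, loc_frame;
  std::vector<double> loc_x, loc_y;
  std::vector<int> tr_mol, tr_frame, tr_sub, tr_state;
  std::vector<double> tr_x, tr_y, tr_z;
  std::vector<int> meta_act(n_molecules), meta_nfr(n_molecules);
  std::vector<double> meta_dur(n_molecules), meta_fbound(n_molecules);
  NumericVector dstar(dstar_only ? n_molecules : 0);

  for (int m = 0; m < n_molecules; m++) {
    double x, y, z;
    uniform_point(g, x, y, z);
    int act = (int)std::floor(unif_rand() * movie_frames);
    if (act >= movie_frames) act = movie_frames - 1;
    double dur = exp_rand() * bleach_mean;
    int nfr = (int)std::floor(dur / frame_dt);  // completed frames only
    if (nfr > movie_frames - act) nfr = movie_frames - act;
    if (nfr > max_frames) nfr = max_frames;
    meta_act[m] = act; meta_dur[m] = dur; meta_nfr[m] = nfr;

    bool bound = switching ? (phi >= 1.0 || unif_rand() < phi) : false;
    double rem = 0.0;  // time left in current dwell
    if (switching && phi < 1.0)
      rem = exp_rand() * (bound ? mean_t_bound : mean_t_free);

    int nbound = 0, nsubtot = 0;
    double px = 0.0, py = 0.0;  // previous observed position (for dstar)
    double acc_d2 = 0.0;
    int nsteps_used = 0;

    for (int f = 0; f < nfr; f++) {
      double sx = 0.0, sy = 0.0;
      for (int s = 0; s < n_sub; s++) {
        if (switching && phi < 1.0) {
          while (rem <= 0.0) {
            bound = !bound;
            rem += exp_rand() * (bound ? mean_t_bound : mean_t_free);
          }
        }
        double sd = bound ? sd_bound : sd_free;
        double nx = x + norm_rand() * sd;
        double ny = y + norm_rand() * sd;
        double nz = z + norm_rand() * sd;
        if (confine(g, x, nx, ny, nz)) { x = nx; y = ny; z = nz; }
        sx += x; sy += y;
        if (switching) { rem -= dt_sub; if (bound) nbound++; nsubtot++; }
        if (keep_truth) {
          tr_mol.push_back(m + 1); tr_frame.push_back(act + f);
          tr_sub.push_back(s); tr_state.push_back(bound ? 1 : 0);
          tr_x.push_back(x); tr_y.push_back(y); tr_z.push_back(z);
        }
      }
      double ox = sx / n_sub + (sigma_loc > 0 ? norm_rand() * sigma_loc : 0.0);
      double oy = sy / n_sub + (sigma_loc > 0 ? norm_rand() * sigma_loc : 0.0);
      if (dstar_only) {
        if (f > 0 && nsteps_used < n_dstar_steps) {
          double dx = ox - px, dy = oy - py;
          acc_d2 += dx * dx + dy * dy;
          nsteps_used++;
        }
        px = ox; py = oy;
      } else {
        loc_mol.push_back(m + 1);
        loc_frame.push_back(act + f);
        loc_x.push_back(ox); loc_y.push_back(oy);
      }
    }
    meta_fbound[m] = nsubtot > 0 ? (double)nbound / nsubtot : NA_REAL;
    if (dstar_only)
      dstar[m] = (nsteps_used == n_dstar_steps)
        ? acc_d2 / (4.0 * n_dstar_steps * frame_dt) : NA_REAL;
  }

  List out;
  out["meta"] = DataFrame::create(
    _["molecule"] = seq_len(n_molecules),
    _["activation_frame"] = wrap(meta_act),
    _["n_frames"] = wrap(meta_nfr),
    _["duration_s"] = wrap(meta_dur),
    _["frac_bound"] = wrap(meta_fbound));
  if (dstar_only) {
    out["dstar"] = dstar;
  } else {
    out["localizations"] = DataFrame::create(
      _["molecule"] = wrap(loc_mol), _["frame"] = wrap(loc_frame),
      _["x_um"] = wrap(loc_x), _["y_um"] = wrap(loc_y));
  }
  if (keep_truth) {
    out["subframe"] = DataFrame::create(
      _["molecule"] = wrap(tr_mol), _["frame"] = wrap(tr_frame),
      _["subframe"] = wrap(tr_sub), _["bound"] = wrap(tr_state),
      _["x_um"] = wrap(tr_x), _["y_um"] = wrap(tr_y),
      _["z_um"] = wrap(tr_z));
  }
  return out;
}
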