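#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Pairwise terms of the network potential.
//
// Harmonic links: (kappa/2) (r - r0)^2 per unordered pair.
// Breakable links: shifted-force truncated Lennard-Jones built on
// A ((r0/r)^12 - 2 (r0/r)^6); energy and radial force are continuous and
// exactly zero at the truncation length dt and identically zero beyond it.

static inline double lj_u(double r, double A, double r0) {
  double s6 = std::pow(r0 / r, 6);
  return A * (s6 * s6 - 2.0 * s6);
}
static inline double lj_du(double r, double A, double r0) {
  double s6 = std::pow(r0 / r, 6);
  return (12.0 * A / r) * (s6 - s6 * s6);
}

struct Network {
  arma::uvec li, lj;   // 0-based harmonic link ends
  arma::vec lr0;
  double kappa;
  arma::uvec bi, bj;   // 0-based breakable pair ends
  double bA, br0, bdt;
  double shift_u, shift_f; // lj_u(dt), lj_du(dt)
};

static Network make_net(const IntegerVector& li, const IntegerVector& lj,
                        const NumericVector& lr0, double kappa,
                        const IntegerVector& bi, const IntegerVector& bj,
                        double bA, double br0, double bdt) {
  Network n;
  n.li = arma::conv_to<arma::uvec>::from(as<arma::ivec>(li)) - 1;
  n.lj = arma::conv_to<arma::uvec>::from(as<arma::ivec>(lj)) - 1;
  n.lr0 = as<arma::vec>(lr0);
  n.kappa = kappa;
  n.bi = arma::conv_to<arma::uvec>::from(as<arma::ivec>(bi));
  n.bj = arma::conv_to<arma::uvec>::from(as<arma::ivec>(bj));
  if (n.bi.n_elem > 0) { n.bi -= 1; n.bj -= 1; }
  n.bA = bA; n.br0 = br0; n.bdt = bdt;
  n.shift_u = lj_u(bdt, bA, br0);
  n.shift_f = lj_du(bdt, bA, br0);
  return n;
}

// X and F are m x 3, column-major (Armadillo layout), accessed raw for speed.
static double net_energy(const arma::mat& X, const Network& n) {
  const double* x = X.memptr();
  const arma::uword m = X.n_rows;
  double e = 0.0;
  for (arma::uword k = 0; k < n.li.n_elem; ++k) {
    arma::uword a = n.li[k], b = n.lj[k];
    double dx = x[b] - x[a], dy = x[b + m] - x[a + m],
           dz = x[b + 2 * m] - x[a + 2 * m];
    double dr = std::sqrt(dx * dx + dy * dy + dz * dz) - n.lr0[k];
    e += 0.5 * n.kappa * dr * dr;
  }
  for (arma::uword k = 0; k < n.bi.n_elem; ++k) {
    arma::uword a = n.bi[k], b = n.bj[k];
    double dx = x[b] - x[a], dy = x[b + m] - x[a + m],
           dz = x[b + 2 * m] - x[a + 2 * m];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < n.bdt)
      e += lj_u(r, n.bA, n.br0) - n.shift_u - (r - n.bdt) * n.shift_f;
  }
  return e;
}

static void net_forces(const arma::mat& X, const Network& n, arma::mat& F) {
  F.zeros();
  const double* x = X.memptr();
  double* f = F.memptr();
  const arma::uword m = X.n_rows;
  for (arma::uword k = 0; k < n.li.n_elem; ++k) {
    arma::uword a = n.li[k], b = n.lj[k];
    double dx = x[b] - x[a], dy = x[b + m] - x[a + m],
           dz = x[b + 2 * m] - x[a + 2 * m];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-9)
      stop("linked beads %d and %d coincide; force direction undefined",
           (int)a + 1, (int)b + 1);
    // force on b along -dU/dr * unit(d); dU/dr = kappa (r - r0)
    double c = -n.kappa * (r - n.lr0[k]) / r;
    double fx = c * dx, fy = c * dy, fz = c * dz;
    f[b] += fx; f[b + m] += fy; f[b + 2 * m] += fz;
    f[a] -= fx; f[a + m] -= fy; f[a + 2 * m] -= fz;
  }
  for (arma::uword k = 0; k < n.bi.n_elem; ++k) {
    arma::uword a = n.bi[k], b = n.bj[k];
    double dx = x[b] - x[a], dy = x[b + m] - x[a + m],
           dz = x[b + 2 * m] - x[a + 2 * m];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r >= n.bdt) continue;
    if (r < 1e-9)
      stop("breakable pair %d-%d coincide", (int)a + 1, (int)b + 1);
    double c = -(lj_du(r, n.bA, n.br0) - n.shift_f) / r;
    double fx = c * dx, fy = c * dy, fz = c * dz;
    f[b] += fx; f[b + m] += fy; f[b + 2 * m] += fz;
    f[a] -= fx; f[a + m] -= fy; f[a + 2 * m] -= fz;
  }
}

// Rigid-body balancing field for an external force field: a uniform
// translation plus a linear rotation field about the center of mass, chosen
// so that total force and total torque of (ext + balancing) vanish.
static void add_balancing(const arma::mat& X, const arma::mat& ext,
                          arma::mat& F) {
  arma::uword m = X.n_rows;
  arma::rowvec com = arma::mean(X, 0);
  arma::rowvec ftot = arma::sum(ext, 0);
  arma::rowvec a = -ftot / (double)m;
  arma::vec tau(3, arma::fill::zeros);
  arma::mat S(3, 3, arma::fill::zeros);
  double tr = 0.0;
  for (arma::uword i = 0; i < m; ++i) {
    arma::rowvec d = X.row(i) - com;
    tau += arma::cross(d.t(), ext.row(i).t());
    S += d.t() * d;
    tr += arma::dot(d, d);
  }
  arma::mat M = tr * arma::eye(3, 3) - S;
  arma::vec b;
  if (!arma::solve(b, M, -tau))
    stop("degenerate (collinear) geometry: cannot balance torque");
  for (arma::uword i = 0; i < m; ++i) {
    arma::rowvec d = X.row(i) - com;
    F.row(i) += a + arma::cross(b, d.t()).t();
  }
}

struct OrderPars {
  double d13, d24, phi, comdist_sum;
  bool have;
};

static OrderPars order_pars(const arma::mat& X, const std::vector<arma::uvec>& sub) {
  OrderPars op; op.have = false;
  op.d13 = op.d24 = op.phi = op.comdist_sum = NA_REAL;
  if (sub.size() != 4) return op;
  const double* x = X.memptr();
  const arma::uword m = X.n_rows;
  double C[4][3];
  for (int k = 0; k < 4; ++k) {
    if (sub[k].n_elem == 0) return op;
    double sx = 0, sy = 0, sz = 0;
    for (arma::uword t = 0; t < sub[k].n_elem; ++t) {
      arma::uword i = sub[k][t];
      sx += x[i]; sy += x[i + m]; sz += x[i + 2 * m];
    }
    C[k][0] = sx / sub[k].n_elem;
    C[k][1] = sy / sub[k].n_elem;
    C[k][2] = sz / sub[k].n_elem;
  }
  auto distc = [&](int a, int b) {
    double dx = C[a][0] - C[b][0], dy = C[a][1] - C[b][1],
           dz = C[a][2] - C[b][2];
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  };
  op.comdist_sum = 0.0;
  for (int a = 0; a < 4; ++a)
    for (int b = a + 1; b < 4; ++b)
      op.comdist_sum += distc(a, b);
  op.d13 = distc(0, 2);
  op.d24 = distc(1, 3);
  // dihedral of sequence C2-C1-C3-C4, right-handed about C1->C3
  arma::vec b1 = {C[0][0] - C[1][0], C[0][1] - C[1][1], C[0][2] - C[1][2]};
  arma::vec b2 = {C[2][0] - C[0][0], C[2][1] - C[0][1], C[2][2] - C[0][2]};
  arma::vec b3 = {C[3][0] - C[2][0], C[3][1] - C[2][1], C[3][2] - C[2][2]};
  arma::vec n1 = arma::cross(b1, b2);
  arma::vec n2 = arma::cross(b2, b3);
  double xx = arma::dot(n1, n2);
  double yy = arma::dot(arma::cross(n1, n2), b2) / arma::norm(b2);
  double phi = std::atan2(yy, xx) * 180.0 / M_PI;
  if (phi <= -180.0) phi += 360.0;
  op.phi = phi;
  op.have = true;
  return op;
}

static std::vector<arma::uvec> make_sub(const List& subdomains) {
  std::vector<arma::uvec> sub;
  if (subdomains.size() != 4) return sub;
  for (int k = 0; k < 4; ++k) {
    IntegerVector v = subdomains[k];
    arma::uvec u(v.size());
    for (int i = 0; i < v.size(); ++i) u[i] = v[i] - 1;
    sub.push_back(u);
  }
  return sub;
}

// [[Rcpp::export]]
double cpp_en_energy(const arma::mat& X, IntegerVector li, IntegerVector lj,
                     NumericVector lr0, double kappa, IntegerVector bi,
                     IntegerVector bj, double bA, double br0, double bdt) {
  Network n = make_net(li, lj, lr0, kappa, bi, bj, bA, br0, bdt);
  return net_energy(X, n);
}

// [[Rcpp::export]]
arma::mat cpp_en_forces(const arma::mat& X, IntegerVector li, IntegerVector lj,
                        NumericVector lr0, double kappa, IntegerVector bi,
                        IntegerVector bj, double bA, double br0, double bdt) {
  Network n = make_net(li, lj, lr0, kappa, bi, bj, bA, br0, bdt);
  arma::mat F(X.n_rows, 3);
  net_forces(X, n, F);
  return F;
}

// Explicit Euler / Euler-Maruyama integration of the overdamped equations
// of motion dR_i/dt = F_i + xi_i, with optional static external forces,
// rigid-body immobilization, and Gaussian noise of variance 2 D dt per
// coordinate per step. Stationarity (checked only for D = 0) follows the
// order-parameter criterion: the sum of the six pairwise subdomain-COM
// distances and the dihedral angle must each change by less than eps per
// step. Networks without subdomain labels fall back to a maximum per-bead
// displacement criterion. To keep the per-step cost down the criterion is
// evaluated over single steps spaced check_every steps apart.
// [[Rcpp::export]]
List cpp_integrate(const arma::mat& X0, IntegerVector li, IntegerVector lj,
                   NumericVector lr0, double kappa, IntegerVector bi,
                   IntegerVector bj, double bA, double br0, double bdt,
                   const arma::mat& ext, List subdomains, double dt,
                   int max_steps, double eps_dist, double eps_angle,
                   double noise_D, bool immobilize, bool check_stationarity,
                   int record_stride, bool record_frames, int frame_stride) {
  Network n = make_net(li, lj, lr0, kappa, bi, bj, bA, br0, bdt);
  arma::mat X = X0;
  const arma::uword m = X.n_rows;
  arma::mat F(m, 3);
  bool has_ext = arma::any(arma::vectorise(ext) != 0.0);
  std::vector<arma::uvec> sub = make_sub(subdomains);
  double sigma = std::sqrt(2.0 * noise_D * dt);
  bool stochastic = noise_D > 0.0;
  bool use_op = order_pars(X, sub).have;
  const int check_every = 10;

  std::vector<double> rec_step, rec_d13, rec_d24, rec_phi, rec_energy;
  std::vector<arma::mat> frames;
  auto record = [&](int step) {
    OrderPars op = order_pars(X, sub);
    rec_step.push_back(step);
    rec_d13.push_back(op.d13);
    rec_d24.push_back(op.d24);
    rec_phi.push_back(op.phi);
    rec_energy.push_back(net_energy(X, n));
  };
  record(0);
  if (record_frames) frames.push_back(X);

  bool converged = false;
  int step = 0;
  OrderPars pre_op; pre_op.have = false;
  arma::mat Xpre(m, 3);
  bool have_pre = false;
  for (step = 1; step <= max_steps; ++step) {
    // snapshot just before the step that will be tested for stationarity
    bool test_step = check_stationarity && !stochastic &&
      (step % check_every == 0 || step == max_steps);
    if (test_step) {
      if (use_op) pre_op = order_pars(X, sub); else Xpre = X;
      have_pre = true;
    }
    net_forces(X, n, F);
    if (has_ext) {
      F += ext;
      if (immobilize) add_balancing(X, ext, F);
    }
    double* xp = X.memptr();
    const double* fp = F.memptr();
    if (stochastic) {
      for (arma::uword i = 0; i < 3 * m; ++i)
        xp[i] += dt * fp[i] + sigma * norm_rand();
    } else {
      for (arma::uword i = 0; i < 3 * m; ++i)
        xp[i] += dt * fp[i];
    }
    if (!X.is_finite())
      stop("non-finite coordinates at step %d: the time step dt = %g is "
           "too large for this network (reduce dt)", step, dt);
    if (record_stride > 0 && step % record_stride == 0) record(step);
    if (record_frames && step % frame_stride == 0) frames.push_back(X);
    if (test_step && have_pre) {
      if (use_op) {
        OrderPars op = order_pars(X, sub);
        double dphi = std::fabs(op.phi - pre_op.phi);
        if (dphi > 180.0) dphi = 360.0 - dphi;
        if (std::fabs(op.comdist_sum - pre_op.comdist_sum) < eps_dist &&
            dphi < eps_angle)
          converged = true;
      } else {
        double maxd2 = 0.0;
        const double* xq = Xpre.memptr();
        for (arma::uword i = 0; i < m; ++i) {
          double dx = xp[i] - xq[i], dy = xp[i + m] - xq[i + m],
                 dz = xp[i + 2 * m] - xq[i + 2 * m];
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 > maxd2) maxd2 = d2;
        }
        if (std::sqrt(maxd2) < eps_dist) converged = true;
      }
      if (converged) break;
    }
    if (step % 10000 == 0) checkUserInterrupt();
  }
  if (step > max_steps) step = max_steps;
  if (rec_step.back() != step) record(step);
  if (record_frames && !arma::approx_equal(frames.back(), X, "absdiff", 0.0))
    frames.push_back(X);

  List out = List::create(
    _["coords"] = X, _["converged"] = converged, _["steps"] = step,
    _["traj"] = DataFrame::create(
      _["step"] = rec_step, _["d13"] = rec_d13, _["d24"] = rec_d24,
      _["phi"] = rec_phi, _["energy"] = rec_energy));
  if (record_frames) {
    List fl(frames.size());
    for (size_t k = 0; k < frames.size(); ++k) fl[k] = frames[k];
    out["frames"] = fl;
  }
  return out;
}
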