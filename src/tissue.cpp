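#include <Rcpp.h>
#include "crn_core.h"
using namespace Rcpp;

crn::Params params_from_r(const NumericVector &pv);  // cell.cpp

// 2D monodomain reaction-diffusion solver, Godunov operator splitting:
// reaction (CRN cell step per node, Rush-Larsen + forward Euler) followed by
// an explicit finite-difference diffusion substep with zero-flux boundaries.
// Node (i, j) lives at (i*dx, j*dx, 0) mm, column-major index id = i + nx*j.
//
// stims: list of lists with elements nodes (0-based int), amp (pA/pF),
//        dur (ms), onsets (ms, sorted).
// electrodes: k x 3 matrix (mm); pseudo-unipolar EGMs are accumulated every
//        egm_every steps via the large-volume-conductor kernel with constant
//        Kegm and slab thickness `thick` (mm).
// Activation bookkeeping: upward crossing of -40 mV with -60 mV reset.
// [[Rcpp::export]]
List tissue_run_cpp(NumericMatrix states, NumericVector params, int nx, int ny,
                    double dx, double Deff, double dt, double duration,
                    double t0, List stims, int record_every,
                    NumericMatrix electrodes, int egm_every, double thick,
                    double Kegm, bool early_exit, double quiesce_vm,
                    double quiesce_ms, double t_stim_end) {
  const int N = nx * ny;
  if (states.nrow() != crn::NSTATE || states.ncol() != N)
    stop("states must be a 21 x (nx*ny) matrix");
  if (dt <= 0) stop("dt must be positive");
  const double coef = Deff * dt / (dx * dx);
  if (coef > 0.25)
    stop("explicit diffusion step unstable (D*dt/dx^2 = %.3f > 0.25): reduce dt",
         coef);

  crn::Params p = params_from_r(params);
  crn::RateTable tab;
  tab.build(dt);
  double r[crn::NR];
  crn::StepConsts sc;
  sc.set(dt);

  // working copy of all states
  std::vector<double> S((size_t)N * crn::NSTATE);
  for (int id = 0; id < N; ++id)
    for (int k = 0; k < crn::NSTATE; ++k)
      S[(size_t)id * crn::NSTATE + k] = states(k, id);

  std::vector<double> vbuf(N);
  std::vector<double> istim(N, 0.0);
  std::vector<double> nst((size_t)N * 3);
  for (int id = 0; id < N; ++id)
    crn::nernst(&S[(size_t)id * crn::NSTATE], p, &nst[(size_t)id * 3]);

  // stimuli
  int nstim = stims.size();
  std::vector<IntegerVector> stim_nodes;
  std::vector<double> stim_amp(nstim), stim_dur(nstim);
  std::vector<NumericVector> stim_on;
  std::vector<int> stim_ptr(nstim, 0);
  for (int q = 0; q < nstim; ++q) {
    List st = stims[q];
    stim_nodes.push_back(st["nodes"]);
    stim_amp[q] = as<double>(st["amp"]);
    stim_dur[q] = as<double>(st["dur"]);
    stim_on.push_back(st["onsets"]);
  }

  // activation maps
  std::vector<int> act_count(N, 0), act_count_post(N, 0);
  std::vector<double> act_first(N, NA_REAL), act_last(N, NA_REAL);
  std::vector<char> above(N, 0);
  for (int id = 0; id < N; ++id) above[id] = S[(size_t)id * crn::NSTATE] >= -40.0;
  double last_act_global = -1e30;

  long nsteps = (long)std::ceil(duration / dt - 1e-9);

  // snapshots
  long nframes = record_every > 0 ? nsteps / record_every + 1 : 0;
  NumericMatrix snaps(record_every > 0 ? N : 0, nframes);
  NumericVector snap_t(nframes);
  long iframe = 0;

  // EGM kernel weights
  int nel = electrodes.nrow();
  std::vector<double> Wx((size_t)nel * N), Wy((size_t)nel * N);
  const double dv = dx * dx * thick;
  for (int e = 0; e < nel; ++e) {
    double ex = electrodes(e, 0), ey = electrodes(e, 1), ez = electrodes(e, 2);
    if (std::fabs(ez) < 1e-9) stop("electrode lies in the tissue plane");
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double rx = i * dx - ex, ry = j * dx - ey, rz = -ez;
        double d = std::sqrt(rx * rx + ry * ry + rz * rz);
        double d3 = d * d * d;
        // grad' [1/|r'-r|] = -(r'-r)/|r'-r|^3 ; phi_e = -K * sum grad'Vm . grad'[] dv
        Wx[(size_t)e * N + i + (size_t)nx * j] = -Kegm * (-rx / d3) * dv;
        Wy[(size_t)e * N + i + (size_t)nx * j] = -Kegm * (-ry / d3) * dv;
      }
  }
  long negm = (nel > 0 && egm_every > 0) ? nsteps / egm_every + 1 : 0;
  NumericMatrix egm(negm, nel);
  NumericVector egm_t(negm);
  long iegm = 0;

  bool stopped_early = false;
  long k = 0;
  for (; k < nsteps; ++k) {
    double t = t0 + k * dt;

    if (record_every > 0 && k % record_every == 0) {
      for (int id = 0; id < N; ++id) snaps(id, iframe) = S[(size_t)id * crn::NSTATE];
      snap_t[iframe] = t;
      ++iframe;
    }
    if (negm > 0 && k % egm_every == 0) {
      for (int e = 0; e < nel; ++e) {
        double acc = 0.0;
        const double *wx = &Wx[(size_t)e * N], *wy = &Wy[(size_t)e * N];
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            int id = i + nx * j;
            double vl = S[(size_t)(i > 0 ? id - 1 : id) * crn::NSTATE];
            double vr = S[(size_t)(i < nx - 1 ? id + 1 : id) * crn::NSTATE];
            double vd = S[(size_t)(j > 0 ? id - nx : id) * crn::NSTATE];
            double vu = S[(size_t)(j < ny - 1 ? id + nx : id) * crn::NSTATE];
            double gx = (vr - vl) / (2.0 * dx), gy = (vu - vd) / (2.0 * dx);
            acc += wx[id] * gx + wy[id] * gy;
          }
        egm(iegm, e) = acc;
      }
      egm_t[iegm] = t;
      ++iegm;
    }

    // stimulus currents for this step
    std::fill(istim.begin(), istim.end(), 0.0);
    for (int q = 0; q < nstim; ++q) {
      const NumericVector &on = stim_on[q];
      while (stim_ptr[q] < on.size() && t >= on[stim_ptr[q]] + stim_dur[q] - 1e-9)
        ++stim_ptr[q];
      if (stim_ptr[q] < on.size() && t >= on[stim_ptr[q]] - 1e-9 &&
          t < on[stim_ptr[q]] + stim_dur[q] - 1e-9) {
        const IntegerVector &nd = stim_nodes[q];
        for (int m = 0; m < nd.size(); ++m) istim[nd[m]] += stim_amp[q];
      }
    }

    // reaction substep
    double vmax = -1e30;
    bool refresh_nernst = (k % crn::NERNST_EVERY == 0);
    for (int id = 0; id < N; ++id) {
      double *s = &S[(size_t)id * crn::NSTATE];
      double *e = &nst[(size_t)id * 3];
      if (refresh_nernst) crn::nernst(s, p, e);
      tab.lookup(s[0], r);
      crn::step(s, p, sc, istim[id], r, true, e);
      if (s[0] > vmax) vmax = s[0];
    }

    // diffusion substep (explicit, zero-flux; pairwise-grouped stencil so a
    // grid reflection reflects the solution bit-for-bit)
    if (Deff > 0.0) {
      for (int id = 0; id < N; ++id) vbuf[id] = S[(size_t)id * crn::NSTATE];
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int id = i + nx * j;
          double vc = vbuf[id];
          double vl = (i > 0) ? vbuf[id - 1] : vc;
          double vr = (i < nx - 1) ? vbuf[id + 1] : vc;
          double vd = (j > 0) ? vbuf[id - nx] : vc;
          double vu = (j < ny - 1) ? vbuf[id + nx] : vc;
          double dvm = coef * (((vl + vr) + (vd + vu)) - 4.0 * vc);
          if (std::fabs(dvm) > 5.0)
            stop("diffusion substep moved Vm by %.1f mV at t = %.2f ms: reduce dt",
                 dvm, t);
          S[(size_t)id * crn::NSTATE] += dvm;
        }
    }

    // activation bookkeeping
    double tnew = t + dt;
    for (int id = 0; id < N; ++id) {
      double v = S[(size_t)id * crn::NSTATE];
      if (!above[id] && v >= -40.0) {
        above[id] = 1;
        ++act_count[id];
        if (tnew > t_stim_end) ++act_count_post[id];
        if (!R_finite(act_first[id])) act_first[id] = tnew;
        act_last[id] = tnew;
        last_act_global = tnew;
      } else if (above[id] && v < -60.0) {
        above[id] = 0;
      }
    }

    if ((k & 255) == 0 && !std::isfinite(vmax))
      stop("non-finite membrane potential at t = %.2f ms", t);

    if (early_exit && tnew > t_stim_end && vmax < quiesce_vm &&
        tnew - std::max(last_act_global, t_stim_end) > quiesce_ms) {
      stopped_early = true;
      ++k;
      break;
    }
  }
  double t_end = t0 + k * dt;

  NumericMatrix out_states(crn::NSTATE, N);
  for (int id = 0; id < N; ++id)
    for (int kk = 0; kk < crn::NSTATE; ++kk)
      out_states(kk, id) = S[(size_t)id * crn::NSTATE + kk];

  List res = List::create(
      _["states"] = out_states, _["t_end"] = t_end,
      _["stopped_early"] = stopped_early,
      _["act_count"] = IntegerVector(act_count.begin(), act_count.end()),
      _["act_count_post"] = IntegerVector(act_count_post.begin(), act_count_post.end()),
      _["act_first"] = NumericVector(act_first.begin(), act_first.end()),
      _["act_last"] = NumericVector(act_last.begin(), act_last.end()),
      _["last_activation"] =
          (last_act_global > -1e29) ? wrap(last_act_global) : wrap(NA_REAL));
  if (record_every > 0) {
    res["snapshots"] = snaps(_, Range(0, std::max((long)0, iframe - 1)));
    res["snap_times"] = snap_t[Range(0, std::max((long)0, iframe - 1))];
  }
  if (negm > 0) {
    res["egm"] = egm(Range(0, std::max((long)0, iegm - 1)), _);
    res["egm_times"] = egm_t[Range(0, std::max((long)0, iegm - 1))];
  }
  return res;
}
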