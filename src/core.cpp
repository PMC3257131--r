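// Explicit-Euler integrator for the compartmentalized energy-transfer model.
//
// State layout: 5 species (ATP, ADP, PCr, Cr, Pi) on n_units grid cells
// (myofibril + cytosol + IMS) plus a well-mixed matrix pool (ATP, ADP, Pi).
// Fickian diffusion runs over the first n_units-1 cells with no-flux ends;
// the last cell (IMS) exchanges with the chain through the outer-membrane
// permeability law, and with the matrix through ANT / PiC / synthase.
// All whole-tissue fluxes are in mmol/s/kg wm; concentrations in mM;
// internal time in seconds.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pars {
  int n_units, n_myo, n_diff, ims;
  std::vector<double> v;       // unit volumes, L/kg wm
  double v_matrix;
  double v_myo_tot, v_mmck_tot, v_ims;
  double kdiff[5];             // D/dx^2, 1/s
  double mom_coeff[5];         // restriction multiplier per species
  double mom_ps;               // 1/s (relative to IMS volume)
  double dt;                   // s
  int steps_per_cycle;
  double cycle_s, t_peak, t_end;
  // CK
  bool ck_present;
  double mm_vf, mm_ka, mm_kb, mm_kic, mm_kd;
  double mt_vf, mt_ka, mt_kb, mt_kic, mt_kd;
  double keq;
  bool coupled;
  double gain, jhalf, capture;
  // mitochondrial carriers
  double ant_vmax, ant_km_adp, ant_km_atp, ant_hill, ant_ratio_q;
  double syn_vmax, syn_km_adp, syn_km_pi;
  double pic_vmax, pic_km;
};

inline double ck_net(double atp, double adp, double pcr, double cr,
                     double vf, double ka, double kb, double kic, double kd,
                     double keq) {
  double num = atp * cr - keq * adp * pcr;
  double den = (1.0 + atp / ka + adp / kic) * (1.0 + cr / kb + pcr / kd);
  return vf * num / (ka * kb * den);
}

Pars build_pars(const List& pars) {
  Pars p;
  p.n_units = as<int>(pars["n_units"]);
  p.n_myo = as<int>(pars["n_myo"]);
  p.n_diff = p.n_units - 1;
  p.ims = p.n_units - 1;
  p.v = as<std::vector<double> >(pars["v"]);
  p.v_matrix = as<double>(pars["v_matrix"]);
  p.v_ims = p.v[p.ims];
  p.v_myo_tot = 0.0;
  for (int i = 0; i < p.n_myo; ++i) p.v_myo_tot += p.v[i];
  p.v_mmck_tot = 0.0;
  for (int i = 0; i < p.n_diff; ++i) p.v_mmck_tot += p.v[i];
  NumericVector kd = pars["kdiff"], mc = pars["mom_coeff"];
  for (int s = 0; s < 5; ++s) { p.kdiff[s] = kd[s]; p.mom_coeff[s] = mc[s]; }
  p.mom_ps = as<double>(pars["mom_ps"]);
  p.dt = as<double>(pars["dt_s"]);
  p.steps_per_cycle = as<int>(pars["steps_per_cycle"]);
  p.cycle_s = as<double>(pars["cycle_s"]);
  p.t_peak = as<double>(pars["t_peak_s"]);
  p.t_end = as<double>(pars["t_end_s"]);
  p.ck_present = as<bool>(pars["ck_present"]);
  p.mm_vf = as<double>(pars["mm_vf"]);
  p.mm_ka = as<double>(pars["mm_ka"]);
  p.mm_kb = as<double>(pars["mm_kb"]);
  p.mm_kic = as<double>(pars["mm_kic"]);
  p.mm_kd = as<double>(pars["mm_kd"]);
  p.mt_vf = as<double>(pars["mt_vf"]);
  p.mt_ka = as<double>(pars["mt_ka"]);
  p.mt_kb = as<double>(pars["mt_kb"]);
  p.mt_kic = as<double>(pars["mt_kic"]);
  p.mt_kd = as<double>(pars["mt_kd"]);
  p.keq = as<double>(pars["keq"]);
  p.coupled = as<bool>(pars["coupled"]);
  p.gain = as<double>(pars["gain"]);
  p.jhalf = as<double>(pars["jhalf"]);
  p.capture = as<double>(pars["capture"]);
  p.ant_vmax = as<double>(pars["ant_vmax"]);
  p.ant_km_adp = as<double>(pars["ant_km_adp"]);
  p.ant_km_atp = as<double>(pars["ant_km_atp"]);
  p.ant_hill = as<double>(pars["ant_hill"]);
  p.ant_ratio_q = as<double>(pars["ant_ratio_q"]);
  p.syn_vmax = as<double>(pars["syn_vmax"]);
  p.syn_km_adp = as<double>(pars["syn_km_adp"]);
  p.syn_km_pi = as<double>(pars["syn_km_pi"]);
  p.pic_vmax = as<double>(pars["pic_vmax"]);
  p.pic_km = as<double>(pars["pic_km"]);
  return p;
}

const char* SP_NAMES[5] = {"ATP", "ADP", "PCr", "Cr", "Pi"};

}  // namespace

// [[Rcpp::export]]
List ck_core_run(NumericMatrix conc0, NumericVector matrix0, List pars_list,
                 double mean_rate, int max_cycles, double steady_tol,
                 bool until_steady, int record_stride, int min_cycles) {
  Pars p = build_pars(pars_list);
  const int N = p.n_units, ND = p.n_diff, IMS = p.ims;
  if (conc0.nrow() != 5 || conc0.ncol() != N)
    stop("conc0 must be 5 x n_units");

  std::vector<double> c(5 * N);
  for (int s = 0; s < 5; ++s)
    for (int i = 0; i < N; ++i) c[s * N + i] = conc0(s, i);
  double atp_m = matrix0[0], adp_m = matrix0[1], pi_m = matrix0[2];

  const double dt = p.dt;
  const double peak = mean_rate * 2.0 * p.cycle_s / p.t_end;
  const double mm_dens = (p.ck_present && p.v_mmck_tot > 0)
                             ? p.mm_vf / p.v_mmck_tot : 0.0;  // mM/s scale
  const int spc = p.steps_per_cycle;

  // per-cycle summaries (at most max_cycles + 1 recording cycle)
  const int SUMCOL = 14;
  std::vector<double> cyc;
  cyc.reserve((max_cycles + 1) * SUMCOL);

  std::vector<double> prev(5 * N + 3, NA_REAL);
  bool converged = false;
  double residual = NA_REAL;
  int cycles_run = 0;

  // trace of the final (recording) cycle
  const int NTR = 1 + 5 * N + 3 + 11;
  int nrec = (spc + record_stride - 1) / record_stride;
  NumericMatrix trace(nrec, NTR);
  bool recording = false;
  int rec_row = 0;

  std::vector<double> lap(ND);

  for (int cycle = 0; cycle < max_cycles + 1; ++cycle) {
    bool last = recording;
    double I_atpase = 0, I_syn = 0, I_ant = 0, I_pic = 0, I_mtck = 0,
           I_mmck = 0, I_mom[5] = {0, 0, 0, 0, 0};

    for (int s_in = 0; s_in < spc; ++s_in) {
      double tc = s_in * dt;
      // --- rates from current state ---
      double A = 0.0;
      if (mean_rate > 0) {
        if (tc < p.t_peak) A = peak * tc / p.t_peak;
        else if (tc < p.t_end) A = peak * (p.t_end - tc) / (p.t_end - p.t_peak);
      }
      double* atp = &c[0 * N];
      double* adp = &c[1 * N];
      double* pcr = &c[2 * N];
      double* cre = &c[3 * N];
      double* pin = &c[4 * N];

      double xa = (p.ant_hill == 1.0) ? adp[IMS] / p.ant_km_adp
                    : std::pow(adp[IMS] / p.ant_km_adp, p.ant_hill);
      double bden = adp[IMS] + p.ant_ratio_q * atp[IMS];
      double back = (bden > 0) ? adp[IMS] / bden : 0.0;
      double Jant = p.ant_vmax * (atp_m / (atp_m + p.ant_km_atp)) *
                    (xa / (1.0 + xa)) * back;
      double Jpic = p.pic_vmax * (pin[IMS] - pi_m) /
                    (p.pic_km + pin[IMS] + pi_m);
      double Jsyn = p.syn_vmax * (adp_m / (adp_m + p.syn_km_adp)) *
                    (pi_m / (pi_m + p.syn_km_pi));

      double Jmt = 0.0;  // net MtCK flux, mmol/s/kg, PCr-producing
      if (p.ck_present && p.mt_vf > 0) {
        double atp_eff = atp[IMS];
        if (p.coupled && Jant > 0)
          atp_eff += p.gain * Jant * Jant / (Jant + p.jhalf);
        Jmt = ck_net(atp_eff, adp[IMS], pcr[IMS], cre[IMS],
                     p.mt_vf, p.mt_ka, p.mt_kb, p.mt_kic, p.mt_kd, p.keq);
        // channeled MtCK intercepts at most a fixed fraction of the
        // translocase output; it cannot outrun its local ATP supply
        if (p.coupled && Jmt > p.capture * Jant) Jmt = p.capture * Jant;
        double cap = atp[IMS] * p.v_ims / dt + Jant;
        if (Jmt > cap) Jmt = cap;
      }

      double Jmm = 0.0;  // summed MM-CK flux, PCr-producing
      double vmm[ /* ND<=32 */ 32];
      if (p.ck_present && mm_dens > 0) {
        for (int i = 0; i < ND; ++i) {
          double v = ck_net(atp[i], adp[i], pcr[i], cre[i],
                            mm_dens, p.mm_ka, p.mm_kb, p.mm_kic, p.mm_kd,
                            p.keq);  // mM/s
          vmm[i] = v;
          Jmm += v * p.v[i];
        }
      } else {
        for (int i = 0; i < ND; ++i) vmm[i] = 0.0;
      }

      double Jmom[5];
      for (int s = 0; s < 5; ++s) {
        double* cs = &c[s * N];
        Jmom[s] = p.mom_coeff[s] * p.mom_ps * p.v_ims * (cs[IMS] - cs[ND - 1]);
      }

      if (last && (s_in % record_stride == 0) && rec_row < nrec) {
        int col = 0;
        trace(rec_row, col++) = tc * 1000.0;
        for (int s = 0; s < 5; ++s)
          for (int i = 0; i < N; ++i) trace(rec_row, col++) = c[s * N + i];
        trace(rec_row, col++) = atp_m;
        trace(rec_row, col++) = adp_m;
        trace(rec_row, col++) = pi_m;
        trace(rec_row, col++) = A;
        trace(rec_row, col++) = Jsyn;
        trace(rec_row, col++) = Jant;
        trace(rec_row, col++) = Jpic;
        trace(rec_row, col++) = Jmt;
        trace(rec_row, col++) = Jmm;
        for (int s = 0; s < 5; ++s) trace(rec_row, col++) = Jmom[s];
        ++rec_row;
      }

      // --- diffusion on the chain ---
      for (int s = 0; s < 5; ++s) {
        double* cs = &c[s * N];
        double k = p.kdiff[s];
        lap[0] = cs[1] - cs[0];
        for (int i = 1; i < ND - 1; ++i)
          lap[i] = cs[i - 1] - 2.0 * cs[i] + cs[i + 1];
        lap[ND - 1] = cs[ND - 2] - cs[ND - 1];
        for (int i = 0; i < ND; ++i) cs[i] += dt * k * lap[i];
        // MOM exchange chain <-> IMS
        cs[ND - 1] += dt * Jmom[s] / p.v[ND - 1];
        cs[IMS] -= dt * Jmom[s] / p.v_ims;
      }

      // --- reactions ---
      if (A > 0) {
        double d = A / p.v_myo_tot;  // mM/s in each myofibrillar unit
        for (int i = 0; i < p.n_myo; ++i) {
          atp[i] -= dt * d;
          adp[i] += dt * d;
          pin[i] += dt * d;
        }
      }
      if (p.ck_present && mm_dens > 0) {
        for (int i = 0; i < ND; ++i) {
          double dv = dt * vmm[i];
          atp[i] -= dv; cre[i] -= dv; adp[i] += dv; pcr[i] += dv;
        }
      }
      if (Jmt != 0.0) {
        double dv = dt * Jmt / p.v_ims;
        atp[IMS] -= dv; cre[IMS] -= dv; adp[IMS] += dv; pcr[IMS] += dv;
      }
      // carriers
      atp[IMS] += dt * Jant / p.v_ims;
      adp[IMS] -= dt * Jant / p.v_ims;
      pin[IMS] -= dt * Jpic / p.v_ims;
      atp_m += dt * (Jsyn - Jant) / p.v_matrix;
      adp_m += dt * (Jant - Jsyn) / p.v_matrix;
      pi_m += dt * (Jpic - Jsyn) / p.v_matrix;

      // --- accumulate, guard negativity ---
      I_atpase += A * dt; I_syn += Jsyn * dt; I_ant += Jant * dt;
      I_pic += Jpic * dt; I_mtck += Jmt * dt; I_mmck += Jmm * dt;
      for (int s = 0; s < 5; ++s) I_mom[s] += Jmom[s] * dt;

      for (int s = 0; s < 5; ++s) {
        double* cs = &c[s * N];
        for (int i = 0; i < N; ++i) {
          if (cs[i] < 0) {
            if (cs[i] > -1e-9) cs[i] = 0.0;
            else stop("negative concentration: %s at unit %d, cycle %d, step %d (%g mM)",
                      SP_NAMES[s], i + 1, cycle + 1, s_in + 1, cs[i]);
          }
        }
      }
      if (atp_m < 0 || adp_m < 0 || pi_m < 0) {
        if (atp_m > -1e-9) atp_m = std::max(atp_m, 0.0);
        if (adp_m > -1e-9) adp_m = std::max(adp_m, 0.0);
        if (pi_m > -1e-9) pi_m = std::max(pi_m, 0.0);
        if (atp_m < 0 || adp_m < 0 || pi_m < 0)
          stop("negative matrix concentration at cycle %d, step %d", cycle + 1,
               s_in + 1);
      }
    }
    ++cycles_run;

    // end-of-cycle diastolic myoplasmic PCr/Cr (volume-weighted, chain units)
    double pcr_w = 0, cr_w = 0, vtot = 0;
    for (int i = 0; i < ND; ++i) {
      pcr_w += c[2 * N + i] * p.v[i];
      cr_w += c[3 * N + i] * p.v[i];
      vtot += p.v[i];
    }
    double pcr_cr = (cr_w > 0) ? pcr_w / cr_w : NA_REAL;

    // convergence residual vs previous end-diastolic state
    double res = NA_REAL;
    if (!ISNA(prev[0])) {
      res = 0.0;
      for (int j = 0; j < 5 * N; ++j) {
        double d = std::fabs(c[j] - prev[j]) / (1e-6 + std::fabs(prev[j]));
        if (d > res) res = d;
      }
      double mx[3] = {atp_m, adp_m, pi_m};
      for (int j = 0; j < 3; ++j) {
        double d = std::fabs(mx[j] - prev[5 * N + j]) /
                   (1e-6 + std::fabs(prev[5 * N + j]));
        if (d > res) res = d;
      }
    }
    for (int j = 0; j < 5 * N; ++j) prev[j] = c[j];
    prev[5 * N] = atp_m; prev[5 * N + 1] = adp_m; prev[5 * N + 2] = pi_m;
    residual = res;

    double inv = 1.0 / p.cycle_s;
    double row[SUMCOL] = {
      (double)(cycle + 1), I_atpase * inv, I_syn * inv, I_ant * inv,
      I_pic * inv, I_mtck * inv, I_mmck * inv, I_mom[0] * inv, I_mom[1] * inv,
      I_mom[2] * inv, I_mom[3] * inv, I_mom[4] * inv, pcr_cr, res};
    for (int j = 0; j < SUMCOL; ++j) cyc.push_back(row[j]);

    if (last) break;  // recording cycle done
    bool done_steady = until_steady && cycle + 1 >= min_cycles &&
                       !ISNA(res) && res < steady_tol;
    bool done_count = !until_steady && cycle + 1 >= max_cycles;
    bool exhausted = until_steady && cycle + 1 >= max_cycles;
    if (done_steady || done_count || exhausted) {
      converged = done_steady || done_count;
      if (until_steady && exhausted && !done_steady) converged = false;
      recording = true;  // one extra cycle with trace capture
    }
  }

  int ncyc = (int)(cyc.size() / SUMCOL);
  NumericMatrix cycmat(ncyc, SUMCOL);
  for (int r = 0; r < ncyc; ++r)
    for (int j = 0; j < SUMCOL; ++j) cycmat(r, j) = cyc[r * SUMCOL + j];

  NumericMatrix concout(5, N);
  for (int s = 0; s < 5; ++s)
    for (int i = 0; i < N; ++i) concout(s, i) = c[s * N + i];
  NumericVector matout = NumericVector::create(atp_m, adp_m, pi_m);

  return List::create(
      _["conc"] = concout, _["matrix"] = matout, _["cycles"] = cycmat,
      _["trace"] = trace(Range(0, std::max(rec_row - 1, 0)), _),
      _["converged"] = converged, _["residual"] = residual,
      _["cycles_run"] = cycles_run);
}
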