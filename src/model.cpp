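// Guinea pig ventricular myocyte model: compiled right-hand side and module
// primitives. Layout and conventions:
//   * units: ms, mV, mM, uA/uF; volumes in uL; outward currents positive.
//   * CaRU joint state index: z[l*4 + r], l = 0..9 LCC state, r = 0..3 RyR
//     state (row-major "LCC times RyR" as in the 40-state diagram).
//     LCC 0..4  = C0,C1,C2,C3,O   (available, normal mode)
//     LCC 5..9  = I0,I1,I2,I3,IO  (inactivated mode, non-conducting)
//     RyR 0..3  = R1 (rested), R2 (primed), R3 (open), R4 (inactivated)
//   * dV/dt = -(sum of ionic currents + Istim); concentrations follow with
//     CF1 = Acap*Cm/(Vmyo*F).
#include <Rcpp.h>
#include <R_ext/Rdynload.h>
#include <cmath>
#include <cstring>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Parameter table (single source of truth for name <-> index)
// ---------------------------------------------------------------------------
#define GP_PARAMS(X)                                                        \
  /* physical constants & geometry */                                       \
  X(faraday)  X(temp)     X(acap)     X(cmem)     X(vmyo)     X(vnsr)      \
  X(vmito)    X(vss_dyad) X(n_caru)                                         \
  /* extracellular ions */                                                  \
  X(ko)       X(nao)      X(cao)                                            \
  /* LCC Markov */                                                          \
  X(lcc_a0)   X(lcc_av)   X(lcc_as)   X(lcc_b0)   X(lcc_bv)   X(lcc_bs)    \
  X(lcc_f)    X(lcc_g)                                                      \
  X(lcc_gamma) X(lcc_vdi0) X(lcc_vdi_vh) X(lcc_vdi_k)                       \
  X(lcc_rec0) X(lcc_rec_vh) X(lcc_rec_k) X(lcc_rec_ped)                     \
  X(lcc_perm) X(lcc_gamma_cao) X(lcc_cdi_on)                                \
  /* RyR Markov (single-channel values; open flux uses 5x cluster) */       \
  X(ryr_kap)  X(ryr_hill) X(ryr_kam)  X(ryr_kbp)  X(ryr_kbm)               \
  X(ryr_kcp)  X(ryr_krec) X(ryr_v1)   X(ryr_nclust)                        \
  /* subspace */                                                            \
  X(xfer_rate)                                                              \
  /* INa */                                                                 \
  X(gna)                                                                    \
  /* IKr, IKs */                                                            \
  X(gkr)      X(gks)      X(iks_variant) X(prnak)                           \
  X(iks_tau_scale) X(iks_tau2_mult)                                         \
  /* IK1, IKp, IKATP */                                                     \
  X(gk1)      X(gkp)      X(gkatp)    X(katp_km)  X(katp_h)                 \
  /* Ito (optional) */                                                      \
  X(gto)                                                                    \
  /* INaK */                                                                \
  X(inak_max) X(km_nai)   X(km_ko)                                          \
  /* NCX (Weber) */                                                         \
  X(ncx_vmax) X(ncx_kmcaact) X(ncx_eta) X(ncx_ksat)                         \
  X(ncx_kmcai) X(ncx_kmcao) X(ncx_kmnai) X(ncx_kmnao)                      \
  /* sarcolemmal Ca pump, backgrounds */                                    \
  X(ipca_max) X(ipca_km)  X(gcab)     X(gnab)                               \
  /* SERCA */                                                               \
  X(up_vmaxf) X(up_vmaxr) X(up_kfb)   X(up_nfb)   X(up_krb)   X(up_nrb)    \
  X(up_katp)                                                                \
  /* cytosolic buffers */                                                   \
  X(ltrpn_tot) X(kltrpn_p) X(kltrpn_m) X(htrpn_tot) X(khtrpn_p) X(khtrpn_m)\
  X(cmdn_tot) X(kcmdn_p)  X(kcmdn_m)                                        \
  /* NSR buffer */                                                          \
  X(csqn_tot) X(kcsqn_p)  X(kcsqn_m)                                        \
  /* crossbridge / force */                                                 \
  X(xb_f01)   X(xb_f12)   X(xb_f23)   X(xb_g01)   X(xb_g12)   X(xb_g23)    \
  X(xb_kpn)   X(xb_perm50) X(xb_nperm) X(force_norm) X(fmax_mn) X(xs_area) \
  X(vam_scale)                                                              \
  /* cytosolic energetics */                                                \
  X(adn_tot_c) X(cr_tot)  X(kck)      X(keq_ck)                             \
  /* mitochondria: pools and membrane */                                    \
  X(cmito)    X(fm_ca)    X(nad_tot)  X(adn_tot_m) X(gh_leak)              \
  X(vuni_max) X(vuni_scale) X(uni_ktrans) X(uni_kact) X(uni_L) X(uni_na)   \
  X(uni_psi0)                                                               \
  X(vmnc_max) X(mnc_b)    X(mnc_psi0) X(mnc_kna)  X(mnc_kca)               \
  X(vnhe_max) X(nhe_k)    X(nhe_rh)                                         \
  X(vresp_max) X(resp_km_nadh) X(resp_psi_th) X(resp_k)                     \
  X(vf1_max)  X(f1_km_adp) X(f1_psi_th) X(f1_k)                             \
  X(vant_max) X(ant_h)                                                      \
  /* TCA cycle */                                                           \
  X(accoa)    X(vcs_max)  X(cs_km_accoa) X(cs_km_oaa)                       \
  X(kaco_f)   X(keq_aco)                                                    \
  X(vidh_max) X(idh_km_isoc) X(idh_ni) X(idh_km_nad) X(idh_kca) X(idh_amp) \
  X(vkgdh_max) X(kgdh_km_akg) X(kgdh_km_nad) X(kgdh_kca) X(kgdh_amp)       \
  X(ksl_f)    X(keq_sl)                                                     \
  X(vsdh_max) X(sdh_km_suc)                                                 \
  X(kfh_f)    X(keq_fh)                                                     \
  X(vmdh_max) X(mdh_km_mal) X(mdh_km_nad)                                   \
  X(kaat)

enum ParamIndex {
#define X(name) P_##name,
  GP_PARAMS(X)
#undef X
  N_PARAM
};

static const char* PARAM_NAMES[] = {
#define X(name) #name,
  GP_PARAMS(X)
#undef X
};

// ---------------------------------------------------------------------------
// State vector layout
// ---------------------------------------------------------------------------
enum StateIndex {
  S_V = 0,
  S_m, S_h, S_j,
  S_xr,
  S_xs1, S_xs2,
  S_xto, S_yto,
  S_Z0,                 // 40 CaRU occupancies: S_Z0 .. S_Z0+39
  S_cai = S_Z0 + 40,
  S_cansr,
  S_nai,
  S_ki,
  S_ltr, S_htr, S_cmdn, S_csqn,
  S_N0, S_N1, S_P0, S_P1, S_P2, S_P3,
  S_atpi, S_crp,
  S_cam, S_nam, S_nadh, S_adpm, S_dpsi,
  S_cit, S_isoc, S_akg, S_scoa, S_suc, S_fum, S_mal, S_oaa,
  N_STATE
};

static const char* STATE_NAMES[N_STATE] = {
  "V", "m", "h", "j", "xr", "xs1", "xs2", "xto", "yto",
  "z01","z02","z03","z04","z05","z06","z07","z08","z09","z10",
  "z11","z12","z13","z14","z15","z16","z17","z18","z19","z20",
  "z21","z22","z23","z24","z25","z26","z27","z28","z29","z30",
  "z31","z32","z33","z34","z35","z36","z37","z38","z39","z40",
  "cai", "cansr", "nai", "ki",
  "ltrpn_ca", "htrpn_ca", "cmdn_ca", "csqn_ca",
  "xb_n0", "xb_n1", "xb_p0", "xb_p1", "xb_p2", "xb_p3",
  "atpi", "crp",
  "cam", "nam", "nadh", "adpm", "dpsi",
  "cit", "isoc", "akg", "scoa", "suc", "fum", "mal", "oaa"
};

// Derived output layout (currents/fluxes reported per sample)
static const char* DERIVED_NAMES[] = {
  "i_na", "i_cal", "i_kr", "i_ks", "i_k1", "i_kp", "i_katp", "i_to",
  "i_nak", "i_ncx", "i_pca", "i_cab", "i_nab",
  "j_lcc", "j_ryr", "j_xfer", "j_up", "j_ncx_ca", "j_pca_ca", "j_cab_ca",
  "j_uni", "j_mncx", "j_nhe",
  "ca_ss_avg", "ca_ss_cc", "ca_ss_oc", "ca_ss_co", "ca_ss_oo",
  "p_ryr_open", "p_lcc_open", "p_oo", "lcc_avail", "force_norm", "stress",
  "v_resp", "v_f1f0", "v_ant", "v_am", "caru_sum", "ca_sr_total"
};
static const int N_DERIVED = sizeof(DERIVED_NAMES) / sizeof(char*);

// ---------------------------------------------------------------------------
// Small helpers
// ---------------------------------------------------------------------------
static inline double sq(double x) { return x * x; }

// safe x/(exp(x)-1)
static inline double xoem1(double x) {
  if (std::fabs(x) < 1e-6) return 1.0 - 0.5 * x;
  return x / std::expm1(x);
}

struct CaRUrates {
  double alpha, beta, f, g;     // LCC activation chain
  double vdi;                   // voltage-dependent entry to inactivated mode
  double rec;                   // recovery from inactivated mode
  double k12[2], k21, k23, k32, k34, k41; // RyR rates; k12 per LCC config
  double cass[4];               // subspace Ca for cc, oc(LCC open), co(RyR), oo
  double AL, BL;                // GHK split: J_L = AL - BL*cass
};

// GHK split of the unitary LCC flux (subspace-referenced, mM/ms):
//   J_L(V, ca) = AL(V) - BL(V) * ca,  influx positive.
static inline void ghk_split(double V, const double* p, double* AL, double* BL) {
  double rtf = 8.314 * p[P_temp] / p[P_faraday];   // ~26.71 mV
  double u = 2.0 * V / rtf;
  double q = xoem1(u);                             // u/(e^u - 1)
  *AL = p[P_lcc_perm] * q * p[P_lcc_gamma_cao] * p[P_cao];
  // u e^u/(e^u-1) = u + u/(e^u-1)
  *BL = p[P_lcc_perm] * (u + q);
}

// subspace Ca for a dyad configuration (rapid equilibrium, closed form)
static inline double subspace_ca_cfg(int lcc_open, int ryr_open, double V,
                                     double cai, double cansr, const double* p,
                                     double AL, double BL) {
  double vr = p[P_ryr_nclust] * p[P_ryr_v1];
  double num = p[P_xfer_rate] * cai;
  double den = p[P_xfer_rate];
  if (ryr_open) { num += vr * cansr; den += vr; }
  if (lcc_open) { num += AL;         den += BL; }
  return num / den;
}

static void caru_rates(double V, double cai, double cansr, const double* p,
                       CaRUrates* r) {
  r->alpha = p[P_lcc_a0] * std::exp((V + p[P_lcc_av]) / p[P_lcc_as]);
  r->beta  = p[P_lcc_b0] * std::exp(-(V + p[P_lcc_bv]) / p[P_lcc_bs]);
  r->f     = p[P_lcc_f];
  r->g     = p[P_lcc_g];
  r->vdi   = p[P_lcc_vdi0] / (1.0 + std::exp(-(V - p[P_lcc_vdi_vh]) / p[P_lcc_vdi_k]));
  r->rec   = p[P_lcc_rec0] / (1.0 + std::exp((V - p[P_lcc_rec_vh]) / p[P_lcc_rec_k]))
           + p[P_lcc_rec_ped];
  ghk_split(V, p, &r->AL, &r->BL);
  // subspace Ca for the four macro configurations
  r->cass[0] = subspace_ca_cfg(0, 0, V, cai, cansr, p, r->AL, r->BL); // cc
  r->cass[1] = subspace_ca_cfg(1, 0, V, cai, cansr, p, r->AL, r->BL); // oc
  r->cass[2] = subspace_ca_cfg(0, 1, V, cai, cansr, p, r->AL, r->BL); // co
  r->cass[3] = subspace_ca_cfg(1, 1, V, cai, cansr, p, r->AL, r->BL); // oo
  // RyR activation rate depends on the LCC configuration via subspace Ca
  for (int lo = 0; lo < 2; ++lo) {
    double ca = r->cass[lo];              // RyR closed when deciding to open
    r->k12[lo] = p[P_ryr_kap] * std::pow(ca, p[P_ryr_hill]);
  }
  r->k21 = p[P_ryr_kam];
  r->k23 = p[P_ryr_kbp];
  r->k32 = p[P_ryr_kbm];
  r->k34 = p[P_ryr_kcp];
  r->k41 = p[P_ryr_krec];
}

// CDI rate for joint state (l, r): driven by the subspace Ca the LCC sees.
static inline double cdi_rate(const CaRUrates* rt, const double* p,
                              int lcc_open, int ryr_open) {
  if (p[P_lcc_cdi_on] < 0.5) return 0.0;
  double ca = rt->cass[(lcc_open ? 1 : 0) + (ryr_open ? 2 : 0)];
  return p[P_lcc_gamma] * ca;
}

// Fill dz (length 40) given occupancy z. Pure generator action; also usable
// to build the explicit 40x40 matrix.
static void caru_derivs(const double* z, const CaRUrates* rt, const double* p,
                        double* dz) {
  for (int i = 0; i < 40; ++i) dz[i] = 0.0;
  // chain multiplicities for C0->C1->C2->C3 then C3<->O via f/g
  const double fw[3] = {3.0, 2.0, 1.0};
  const double bw[3] = {1.0, 2.0, 3.0};
  for (int l = 0; l < 10; ++l) {
    int mode = l / 5;          // 0 normal, 1 inactivated
    int pos = l % 5;           // 0..3 closed chain, 4 open position
    for (int r = 0; r < 4; ++r) {
      int idx = l * 4 + r;
      double occ = z[idx];
      int lcc_open = (l == 4);                // only normal-mode O conducts
      int ryr_open = (r == 2);
      // --- LCC activation chain (same rates both modes; no opening when
      //     inactivated) ---
      if (pos < 3) { // forward within closed chain
        double k = fw[pos] * rt->alpha;
        dz[idx] -= k * occ; dz[idx + 4] += k * occ;
      }
      if (pos > 0 && pos < 4) { // backward within closed chain
        double k = bw[pos - 1] * rt->beta;
        dz[idx] -= k * occ; dz[idx - 4] += k * occ;
      }
      if (pos == 3 && mode == 0) { // C3 -> O
        dz[idx] -= rt->f * occ; dz[idx + 4] += rt->f * occ;
      }
      if (pos == 4) {              // O -> C3 (or IO -> I3)
        dz[idx] -= rt->g * occ; dz[idx - 4] += rt->g * occ;
      }
      // --- LCC inactivation / recovery (mode switch, position preserved) ---
      if (mode == 0) {
        double k = rt->vdi + cdi_rate(rt, p, lcc_open, ryr_open);
        dz[idx] -= k * occ; dz[idx + 20] += k * occ;
      } else {
        dz[idx] -= rt->rec * occ; dz[idx - 20] += rt->rec * occ;
      }
      // --- RyR transitions (rates use subspace Ca of current LCC config) ---
      double k12 = rt->k12[lcc_open];
      switch (r) {
        case 0: dz[idx] -= k12 * occ;      dz[idx + 1] += k12 * occ; break;
        case 1: dz[idx] -= (rt->k21 + rt->k23) * occ;
                dz[idx - 1] += rt->k21 * occ; dz[idx + 1] += rt->k23 * occ;
                break;
        case 2: dz[idx] -= (rt->k32 + rt->k34) * occ;
                dz[idx - 1] += rt->k32 * occ; dz[idx + 1] += rt->k34 * occ;
                break;
        case 3: dz[idx] -= rt->k41 * occ;  dz[idx - 3] += rt->k41 * occ; break;
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Hodgkin-Huxley gates (Luo-Rudy lineage)
// ---------------------------------------------------------------------------
static inline void ina_gates(double V, double* am, double* bm, double* ah,
                             double* bh, double* aj, double* bj) {
  double vm = V + 47.13;
  *am = (std::fabs(vm) < 1e-6) ? 3.2 : 0.32 * vm / (1.0 - std::exp(-0.1 * vm));
  *bm = 0.08 * std::exp(-V / 11.0);
  if (V < -40.0) {
    *ah = 0.135 * std::exp((80.0 + V) / -6.8);
    *bh = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    *aj = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V)) *
          (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    *bj = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
  } else {
    *ah = 0.0;
    *bh = 1.0 / (0.13 * (1.0 + std::exp((V + 10.66) / -11.1)));
    *aj = 0.0;
    *bj = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  }
}

static inline void ikr_gate(double V, double* xinf, double* tau) {
  *xinf = 1.0 / (1.0 + std::exp(-(V + 21.5) / 7.5));
  double a = 0.00138 * (V + 14.2) / (1.0 - std::exp(-0.123 * (V + 14.2)));
  double b = 0.00061 * (V + 38.9) / (std::exp(0.145 * (V + 38.9)) - 1.0);
  if (std::fabs(V + 14.2) < 1e-6) a = 0.00138 / 0.123;
  if (std::fabs(V + 38.9) < 1e-6) b = 0.00061 / 0.145;
  *tau = 1.0 / (a + b);
}

static inline void iks_gate(double V, double* xinf, double* tau1) {
  *xinf = 1.0 / (1.0 + std::exp(-(V - 1.5) / 16.7));
  double a = 7.19e-5 * (V + 30.0) / (1.0 - std::exp(-0.148 * (V + 30.0)));
  double b = 1.31e-4 * (V + 30.0) / (std::exp(0.0687 * (V + 30.0)) - 1.0);
  if (std::fabs(V + 30.0) < 1e-6) { a = 7.19e-5 / 0.148; b = 1.31e-4 / 0.0687; }
  *tau1 = 1.0 / (a + b);
}

static inline void ito_gates(double V, double* xinf, double* taux,
                             double* yinf, double* tauy) {
  *xinf = 1.0 / (1.0 + std::exp(-(V - 19.0) / 13.0));
  *taux = 9.0 / (1.0 + std::exp((V + 3.0) / 15.0)) + 0.5;
  *yinf = 1.0 / (1.0 + std::exp((V + 19.5) / 5.0));
  *tauy = 3000.0 / (1.0 + std::exp((V + 60.0) / 10.0)) + 30.0;
}

// ---------------------------------------------------------------------------
// Full right-hand side.  mode: 0 current clamp, 1 voltage clamp (V held),
// 2 AP clamp (V follows table; table slope supplied by caller via vslope).
// ---------------------------------------------------------------------------
struct Derived {
  double out[64];
};

static void model_rhs(double t, const double* y, const double* p, int mode,
                      double istim, double vslope, double* dy, Derived* der) {
  const double F = p[P_faraday];
  const double rtf = 8.314 * p[P_temp] / F;
  const double cf1 = 1e-3 * p[P_acap] * p[P_cmem] / (p[P_vmyo] * F);
  // cf1: (mM/ms) per (uA/uF); 1e-3 converts uC/s to uC/ms
  const double vss_tot = p[P_vss_dyad] * p[P_n_caru];

  double V = y[S_V];
  double cai = y[S_cai], cansr = y[S_cansr], nai = y[S_nai], ki = y[S_ki];
  if (cai < 1e-12) cai = 1e-12;
  if (cansr < 1e-12) cansr = 1e-12;

  // ---- reversal potentials -------------------------------------------------
  double ena = rtf * std::log(p[P_nao] / nai);
  double ek  = rtf * std::log(p[P_ko] / ki);
  double eks = rtf * std::log((p[P_ko] + p[P_prnak] * p[P_nao]) /
                              (ki + p[P_prnak] * nai));
  double eca = 0.5 * rtf * std::log(p[P_cao] / cai);

  // ---- CaRU ----------------------------------------------------------------
  CaRUrates rt;
  caru_rates(V, cai, cansr, p, &rt);
  const double* z = y + S_Z0;
  double dz[40];
  caru_derivs(z, &rt, p, dz);

  double p_lcc_open = 0.0, p_ryr_open = 0.0, lcc_avail = 0.0, zsum = 0.0;
  double j_lcc = 0.0, j_ryr = 0.0;     // subspace-referenced mM/ms (ensemble)
  double cass_avg = 0.0;
  double vr = p[P_ryr_nclust] * p[P_ryr_v1];
  for (int l = 0; l < 10; ++l) {
    for (int r = 0; r < 4; ++r) {
      double occ = z[l * 4 + r];
      zsum += occ;
      int lcc_open = (l == 4), ryr_open = (r == 2);
      int cfg = (lcc_open ? 1 : 0) + (ryr_open ? 2 : 0);
      double cass = rt.cass[cfg];
      cass_avg += occ * cass;
      if (l < 5) lcc_avail += occ;
      if (lcc_open) {
        p_lcc_open += occ;
        j_lcc += occ * (rt.AL - rt.BL * cass);
      }
      if (ryr_open) {
        p_ryr_open += occ;
        j_ryr += occ * vr * (cansr - cass);
      }
    }
  }
  // transfer flux subspace -> cytosol: at rapid equilibrium it equals the
  // sum of source fluxes, which keeps the subspace balance exact.
  double j_xfer_ss = j_lcc + j_ryr;
  double j_xfer_cyto = j_xfer_ss * vss_tot / p[P_vmyo];       // mM/ms cytosol
  double j_ryr_nsr   = j_ryr * vss_tot / p[P_vnsr];           // mM/ms NSR

  double i_cal = -2.0 * (j_lcc * vss_tot / p[P_vmyo]) / cf1;  // uA/uF

  // ---- sarcolemmal currents ------------------------------------------------
  double m = y[S_m], h = y[S_h], jg = y[S_j];
  double i_na = p[P_gna] * m * m * m * h * jg * (V - ena);

  double rkr = 1.0 / (1.0 + std::exp((V + 9.0) / 22.4));
  double i_kr = p[P_gkr] * std::sqrt(p[P_ko] / 5.4) * y[S_xr] * rkr * (V - ek);

  double gks_ca = p[P_gks] * (1.0 + 0.6 / (1.0 + std::pow(3.8e-5 / cai, 1.4)));
  double i_ks;
  if (p[P_iks_variant] < 0.5) {         // viswanathan99: two gates
    i_ks = gks_ca * y[S_xs1] * y[S_xs2] * (V - eks);
  } else {                               // zeng95: single (fast) gate squared
    i_ks = gks_ca * y[S_xs1] * y[S_xs1] * (V - eks);
  }

  double vk = V - ek;
  double ak1 = 1.02 / (1.0 + std::exp(0.2385 * (vk - 59.215)));
  double bk1 = (0.49124 * std::exp(0.08032 * (vk + 5.476)) +
                std::exp(0.06175 * (vk - 594.31))) /
               (1.0 + std::exp(-0.5143 * (vk + 4.753)));
  double i_k1 = p[P_gk1] * std::sqrt(p[P_ko] / 5.4) * (ak1 / (ak1 + bk1)) * vk;

  double i_kp = p[P_gkp] * vk / (1.0 + std::exp((7.488 - V) / 5.98));

  double atpi = y[S_atpi];
  double fatp = 1.0 / (1.0 + std::pow(atpi / p[P_katp_km], p[P_katp_h]));
  double i_katp = p[P_gkatp] * std::pow(p[P_ko] / 5.4, 0.24) * fatp * vk;

  double i_to = p[P_gto] * y[S_xto] * y[S_yto] * vk;

  double sigma = (std::exp(p[P_nao] / 67.3) - 1.0) / 7.0;
  double fnak = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / rtf) +
                       0.0365 * sigma * std::exp(-V / rtf));
  double i_nak = p[P_inak_max] * fnak /
                 (1.0 + std::pow(p[P_km_nai] / nai, 1.5)) *
                 p[P_ko] / (p[P_ko] + p[P_km_ko]);

  // Weber NCX with allosteric cytosolic Ca activation; positive = outward
  // current = reverse mode (Ca entry).
  double allo = 1.0 / (1.0 + sq(p[P_ncx_kmcaact] / cai));
  double e1 = std::exp(p[P_ncx_eta] * V / rtf);
  double e2 = std::exp((p[P_ncx_eta] - 1.0) * V / rtf);
  double nai3 = nai * nai * nai, nao3 = p[P_nao] * p[P_nao] * p[P_nao];
  double kmnai3 = std::pow(p[P_ncx_kmnai], 3.0), kmnao3 = std::pow(p[P_ncx_kmnao], 3.0);
  double num_ncx = e1 * nai3 * p[P_cao] - e2 * nao3 * cai;
  double den_ncx = (p[P_ncx_kmcao] * nai3 + kmnao3 * cai +
                    kmnai3 * p[P_cao] * (1.0 + cai / p[P_ncx_kmcai]) +
                    p[P_ncx_kmcai] * nao3 * (1.0 + nai3 / kmnai3) +
                    nai3 * p[P_cao] + nao3 * cai) *
                   (1.0 + p[P_ncx_ksat] * e2);
  double i_ncx = p[P_ncx_vmax] * allo * num_ncx / den_ncx;

  double i_pca = p[P_ipca_max] * cai / (p[P_ipca_km] + cai);
  double i_cab = p[P_gcab] * (V - eca);
  double i_nab = p[P_gnab] * (V - ena);

  // ---- SERCA and buffers ---------------------------------------------------
  double fb = std::pow(cai / p[P_up_kfb], p[P_up_nfb]);
  double rb = std::pow(cansr / p[P_up_krb], p[P_up_nrb]);
  double fatp_up = 1.0 / (1.0 + p[P_up_katp] / atpi);
  double j_up = fatp_up * (p[P_up_vmaxf] * fb - p[P_up_vmaxr] * rb) /
                (1.0 + fb + rb);

  double force_norm_raw = y[S_P1] + y[S_N1] + 2.0 * y[S_P2] + 3.0 * y[S_P3];
  double force_norm = force_norm_raw / p[P_force_norm];
  double kltr_m = p[P_kltrpn_m] * (1.0 - 0.5 * std::min(1.0, force_norm));
  double j_ltr = p[P_kltrpn_p] * cai * (p[P_ltrpn_tot] - y[S_ltr]) -
                 kltr_m * y[S_ltr];
  double j_htr = p[P_khtrpn_p] * cai * (p[P_htrpn_tot] - y[S_htr]) -
                 p[P_khtrpn_m] * y[S_htr];
  double j_cmdn = p[P_kcmdn_p] * cai * (p[P_cmdn_tot] - y[S_cmdn]) -
                  p[P_kcmdn_m] * y[S_cmdn];
  double j_csqn = p[P_kcsqn_p] * cansr * (p[P_csqn_tot] - y[S_csqn]) -
                  p[P_kcsqn_m] * y[S_csqn];

  // ---- mitochondria --------------------------------------------------------
  double cam = y[S_cam], nam = y[S_nam], nadh = y[S_nadh];
  double adpm = y[S_adpm], dpsi = y[S_dpsi];
  if (cam < 1e-12) cam = 1e-12;
  double nadm = p[P_nad_tot] - nadh;
  double atpm = p[P_adn_tot_m] - adpm;
  if (nadm < 1e-9) nadm = 1e-9;
  if (atpm < 1e-9) atpm = 1e-9;

  // uniporter (Magnus-Keizer form), matrix-referenced mM/ms
  double ctr = cai / p[P_uni_ktrans];
  double mwc = ctr * std::pow(1.0 + ctr, 3.0) /
               (std::pow(1.0 + ctr, 4.0) +
                p[P_uni_L] / std::pow(1.0 + cai / p[P_uni_kact], p[P_uni_na]));
  double dpsi_drive = 2.0 * (dpsi - p[P_uni_psi0]) / rtf;
  double psi_fac = (std::fabs(dpsi_drive) < 1e-6)
                       ? 1.0
                       : dpsi_drive / (1.0 - std::exp(-dpsi_drive));
  double j_uni = p[P_vuni_max] * p[P_vuni_scale] * mwc * psi_fac;

  // mitochondrial NCX (3 Na in / 1 Ca out per cycle), matrix-referenced
  double j_mncx = p[P_vmnc_max] *
                  std::exp(p[P_mnc_b] * (dpsi - p[P_mnc_psi0]) / rtf) *
                  (cam / (cam + p[P_mnc_kca])) /
                  (1.0 + std::pow(p[P_mnc_kna] / nai, 3.0));

  // mitochondrial NHE: Na efflux from matrix, zero when nam*rh == nai
  double j_nhe = p[P_vnhe_max] * (nam * p[P_nhe_rh] - nai) /
                 (p[P_nhe_k] + nam * p[P_nhe_rh] + nai);

  // respiration (NADH oxidation) and FADH2 branch via SDH
  double v_resp = p[P_vresp_max] * (nadh / (nadh + p[P_resp_km_nadh])) /
                  (1.0 + std::exp((dpsi - p[P_resp_psi_th]) / p[P_resp_k]));
  double v_sdh = p[P_vsdh_max] * y[S_suc] / (y[S_suc] + p[P_sdh_km_suc]) /
                 (1.0 + std::exp((dpsi - p[P_resp_psi_th]) / p[P_resp_k]));

  // F1F0 ATP synthase
  double v_f1 = p[P_vf1_max] * (adpm / (adpm + p[P_f1_km_adp])) /
                (1.0 + std::exp((p[P_f1_psi_th] - dpsi) / p[P_f1_k]));

  // adenine nucleotide translocator (exports ATPm, imports cytosolic ADP)
  double adpi = p[P_adn_tot_c] - atpi;
  if (adpi < 1e-9) adpi = 1e-9;
  double rat_c = atpi / adpi, rat_m = adpm / atpm;
  double v_ant = p[P_vant_max] *
                 (1.0 - rat_c * rat_m * std::exp(-dpsi / rtf)) /
                 ((1.0 + rat_c * std::exp(-p[P_ant_h] * dpsi / rtf)) *
                  (1.0 + rat_m));

  double v_hleak = p[P_gh_leak] * dpsi;

  // TCA cycle
  double fca_idh = 1.0 + p[P_idh_amp] * cam / (cam + p[P_idh_kca]);
  double fca_kgdh = 1.0 + p[P_kgdh_amp] * cam / (cam + p[P_kgdh_kca]);
  double isoc_n = std::pow(y[S_isoc], p[P_idh_ni]);
  double v_cs = p[P_vcs_max] * (p[P_accoa] / (p[P_accoa] + p[P_cs_km_accoa])) *
                (y[S_oaa] / (y[S_oaa] + p[P_cs_km_oaa]));
  double v_aco = p[P_kaco_f] * (y[S_cit] - y[S_isoc] * p[P_keq_aco]);
  double v_idh = p[P_vidh_max] * fca_idh *
                 (isoc_n / (isoc_n + std::pow(p[P_idh_km_isoc], p[P_idh_ni]))) *
                 (nadm / (nadm + p[P_idh_km_nad]));
  double v_kgdh = p[P_vkgdh_max] * fca_kgdh *
                  (y[S_akg] / (y[S_akg] + p[P_kgdh_km_akg])) *
                  (nadm / (nadm + p[P_kgdh_km_nad]));
  double v_sl = p[P_ksl_f] * (y[S_scoa] * adpm - y[S_suc] * atpm / p[P_keq_sl]);
  double v_fh = p[P_kfh_f] * (y[S_fum] - y[S_mal] / p[P_keq_fh]);
  double v_mdh = p[P_vmdh_max] * (y[S_mal] / (y[S_mal] + p[P_mdh_km_mal])) *
                 (nadm / (nadm + p[P_mdh_km_nad]));
  double v_aat = p[P_kaat] * y[S_oaa];

  // ---- crossbridge / force -------------------------------------------------
  double ltr_frac = y[S_ltr] / p[P_ltrpn_tot];
  double perm = ltr_frac / p[P_xb_perm50];
  double knp = p[P_xb_kpn] * std::min(100.0, std::pow(perm, p[P_xb_nperm]));
  double kpn = p[P_xb_kpn];
  double N0 = y[S_N0], N1 = y[S_N1], P0 = y[S_P0], P1 = y[S_P1],
         P2 = y[S_P2], P3 = y[S_P3];
  double f01 = p[P_xb_f01], f12 = p[P_xb_f12], f23 = p[P_xb_f23];
  double g01 = p[P_xb_g01], g12 = p[P_xb_g12], g23 = p[P_xb_g23];
  dy[S_N0] = kpn * P0 + g01 * N1 - knp * N0;
  dy[S_N1] = kpn * P1 - (g01 + knp) * N1;
  dy[S_P0] = knp * N0 + g01 * P1 - (kpn + f01) * P0;
  dy[S_P1] = knp * N1 + f01 * P0 + g12 * P2 - (kpn + g01 + f12) * P1;
  dy[S_P2] = f12 * P1 + g23 * P3 - (g12 + f23) * P2;
  dy[S_P3] = f23 * P2 - g23 * P3;
  double v_am = p[P_vam_scale] * (g01 * P1 + g12 * P2 + g23 * P3 + g01 * N1);

  // ---- cytosolic energetics ------------------------------------------------
  double cr = p[P_cr_tot] - y[S_crp];
  double v_ck = p[P_kck] * (y[S_crp] * adpi - atpi * cr / p[P_keq_ck]);
  double j_nak_atp = i_nak * cf1;            // 1 ATP per cycle (per +1 charge)
  double j_pca_atp = 0.5 * i_pca * cf1;      // 1 ATP per Ca
  double v_atpase = v_am + 0.5 * std::max(0.0, j_up) + j_nak_atp + j_pca_atp;
  dy[S_atpi] = v_ant * p[P_vmito] / p[P_vmyo] + v_ck - v_atpase;
  dy[S_crp] = -v_ck;

  // ---- membrane potential --------------------------------------------------
  double i_ion = i_na + i_cal + i_kr + i_ks + i_k1 + i_kp + i_katp + i_to +
                 i_nak + i_ncx + i_pca + i_cab + i_nab;
  if (mode == 0) {
    dy[S_V] = -(i_ion + istim);
  } else if (mode == 1) {
    dy[S_V] = 0.0;
  } else {
    dy[S_V] = vslope;
  }

  // ---- gates ---------------------------------------------------------------
  double am, bm, ah, bh, aj, bj;
  ina_gates(V, &am, &bm, &ah, &bh, &aj, &bj);
  dy[S_m] = am * (1.0 - m) - bm * m;
  dy[S_h] = ah * (1.0 - h) - bh * h;
  dy[S_j] = aj * (1.0 - jg) - bj * jg;
  double xinf, tau;
  ikr_gate(V, &xinf, &tau);
  dy[S_xr] = (xinf - y[S_xr]) / tau;
  iks_gate(V, &xinf, &tau);
  tau *= p[P_iks_tau_scale];
  dy[S_xs1] = (xinf - y[S_xs1]) / tau;
  dy[S_xs2] = (xinf - y[S_xs2]) / (p[P_iks_tau2_mult] * tau);
  double xti, txt, yti, tyt;
  ito_gates(V, &xti, &txt, &yti, &tyt);
  dy[S_xto] = (xti - y[S_xto]) / txt;
  dy[S_yto] = (yti - y[S_yto]) / tyt;

  // ---- CaRU occupancies ----------------------------------------------------
  for (int i = 0; i < 40; ++i) dy[S_Z0 + i] = dz[i];

  // ---- ionic concentration balances ---------------------------------------
  double vmr = p[P_vmito] / p[P_vmyo];
  dy[S_cai] = j_xfer_cyto - j_up - j_ltr - j_htr - j_cmdn +
              cf1 * (i_ncx - 0.5 * (i_cab + i_pca)) -
              (j_uni - j_mncx) * vmr;
  dy[S_cansr] = j_up * p[P_vmyo] / p[P_vnsr] - j_ryr_nsr - j_csqn;
  dy[S_nai] = -cf1 * (i_na + i_nab + 3.0 * i_ncx + 3.0 * i_nak) -
              (3.0 * j_mncx - j_nhe) * vmr;
  double i_k_tot = i_kr + i_ks + i_k1 + i_kp + i_katp + i_to - 2.0 * i_nak;
  dy[S_ki] = -cf1 * (i_k_tot + ((mode == 0) ? istim : 0.0));
  dy[S_ltr] = j_ltr;
  dy[S_htr] = j_htr;
  dy[S_cmdn] = j_cmdn;
  dy[S_csqn] = j_csqn;

  // ---- mitochondrial states ------------------------------------------------
  dy[S_cam] = p[P_fm_ca] * (j_uni - j_mncx);
  dy[S_nam] = 3.0 * j_mncx - j_nhe;
  dy[S_nadh] = v_idh + v_kgdh + v_mdh - v_resp;
  dy[S_adpm] = v_ant - v_f1 - v_sl;
  dy[S_dpsi] = (10.0 * v_resp + 6.0 * v_sdh - 3.0 * v_f1 - v_ant - v_hleak -
                2.0 * j_uni - j_mncx) / p[P_cmito];
  dy[S_cit] = v_cs - v_aco;
  dy[S_isoc] = v_aco - v_idh;
  dy[S_akg] = v_idh + v_aat - v_kgdh;
  dy[S_scoa] = v_kgdh - v_sl;
  dy[S_suc] = v_sl - v_sdh;
  dy[S_fum] = v_sdh - v_fh;
  dy[S_mal] = v_fh - v_mdh;
  dy[S_oaa] = v_mdh - v_cs - v_aat;

  // ---- derived outputs -----------------------------------------------------
  if (der) {
    double* o = der->out;
    int k = 0;
    o[k++] = i_na; o[k++] = i_cal; o[k++] = i_kr; o[k++] = i_ks; o[k++] = i_k1;
    o[k++] = i_kp; o[k++] = i_katp; o[k++] = i_to; o[k++] = i_nak;
    o[k++] = i_ncx; o[k++] = i_pca; o[k++] = i_cab; o[k++] = i_nab;
    o[k++] = j_lcc; o[k++] = j_ryr; o[k++] = j_xfer_cyto; o[k++] = j_up;
    o[k++] = cf1 * i_ncx;                  // Ca entry via NCX, mM/ms cytosol
    o[k++] = -0.5 * cf1 * i_pca;           // Ca flux via SL pump (negative=out)
    o[k++] = -0.5 * cf1 * i_cab;           // Ca entry via background
    o[k++] = j_uni * vmr; o[k++] = j_mncx * vmr; o[k++] = j_nhe * vmr;
    o[k++] = cass_avg; o[k++] = rt.cass[0]; o[k++] = rt.cass[1];
    o[k++] = rt.cass[2]; o[k++] = rt.cass[3];
    o[k++] = p_ryr_open; o[k++] = p_lcc_open;
    o[k++] = z[4 * 4 + 2];                 // open-LCC/open-RyR occupancy
    o[k++] = lcc_avail;
    o[k++] = force_norm;
    o[k++] = force_norm * p[P_fmax_mn] / p[P_xs_area];
    o[k++] = v_resp; o[k++] = v_f1; o[k++] = v_ant; o[k++] = v_am;
    o[k++] = zsum;
    o[k++] = cansr + y[S_csqn];            // total SR Ca (free + buffered)
  }
}

// ---------------------------------------------------------------------------
// deSolve compiled interface.  The parms vector passed from R is:
//   [ model params (N_PARAM) | mode | istim_amp | stim_t0 | stim_dur |
//     stim_period | stim_n | ntab | tab_t[ntab] | tab_v[ntab] ]
// In mode 1 the clamp table is piecewise-constant (steps); in mode 2 it is
// piecewise-linear (AP clamp waveform).
// ---------------------------------------------------------------------------
#define MAXTAB 4096
static double g_parms[N_PARAM + 7 + 2 * MAXTAB];

extern "C" {

void gp_initmod(void (*odeparms)(int*, double*)) {
  int n = N_PARAM + 7 + 2 * MAXTAB;  // fixed layout; R pads the table region
  odeparms(&n, g_parms);
}

void gp_derivs(int* neq, double* t, double* y, double* ydot, double* yout,
               int* ip) {
  const double* p = g_parms;
  int mode = (int)(p[N_PARAM] + 0.5);
  double istim = 0.0, vslope = 0.0;
  double ybuf[N_STATE];
  std::memcpy(ybuf, y, sizeof(double) * N_STATE);
  if (mode == 0) {
    double amp = p[N_PARAM + 1], t0 = p[N_PARAM + 2], dur = p[N_PARAM + 3];
    double period = p[N_PARAM + 4];
    int nstim = (int)(p[N_PARAM + 5] + 0.5);
    if (nstim > 0 && period > 0.0) {
      double tt = *t - t0;
      if (tt >= 0.0) {
        int beat = (int)(tt / period);
        if (beat < nstim && (tt - beat * period) < dur) istim = amp;
      }
    } else if (nstim > 0) {
      if (*t >= t0 && *t < t0 + dur) istim = amp;
    }
  } else {
    int ntab = (int)(p[N_PARAM + 6] + 0.5);
    const double* tt = p + N_PARAM + 7;
    const double* vv = tt + MAXTAB;   // fixed-size table slots
    double tq = *t;
    if (ntab == 1 || tq <= tt[0]) {
      ybuf[S_V] = vv[0];
    } else if (tq >= tt[ntab - 1]) {
      ybuf[S_V] = vv[ntab - 1];
    } else {
      int lo = 0, hi = ntab - 1;
      while (hi - lo > 1) {
        int mid = (lo + hi) / 2;
        if (tt[mid] <= tq) lo = mid; else hi = mid;
      }
      if (mode == 1) {
        ybuf[S_V] = vv[lo];
      } else {
        double w = (tq - tt[lo]) / (tt[hi] - tt[lo]);
        ybuf[S_V] = vv[lo] * (1.0 - w) + vv[hi] * w;
        vslope = (vv[hi] - vv[lo]) / (tt[hi] - tt[lo]);
      }
    }
  }
  model_rhs(*t, ybuf, p, mode, istim, vslope, ydot, nullptr);
}

} // extern "C"

// ---------------------------------------------------------------------------
// Rcpp-exported module primitives
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_param_names")]]
CharacterVector cpp_param_names() {
  CharacterVector out(N_PARAM);
  for (int i = 0; i < N_PARAM; ++i) out[i] = PARAM_NAMES[i];
  return out;
}

// [[Rcpp::export(name = ".cpp_state_names")]]
CharacterVector cpp_state_names() {
  CharacterVector out(N_STATE);
  for (int i = 0; i < N_STATE; ++i) out[i] = STATE_NAMES[i];
  return out;
}

// [[Rcpp::export(name = ".cpp_derived_names")]]
CharacterVector cpp_derived_names() {
  CharacterVector out(N_DERIVED);
  for (int i = 0; i < N_DERIVED; ++i) out[i] = DERIVED_NAMES[i];
  return out;
}

static void check_params(const NumericVector& p) {
  if (p.size() < N_PARAM) stop("parameter vector has wrong length");
}

// [[Rcpp::export(name = ".cpp_subspace_ca")]]
double cpp_subspace_ca(bool lcc_open, bool ryr_open, double V, double cai,
                       double cansr, NumericVector params) {
  check_params(params);
  if (cai <= 0.0 || cansr <= 0.0)
    stop("concentrations must be positive");
  if (!std::isfinite(V)) stop("V must be finite");
  double AL, BL;
  ghk_split(V, REAL(params), &AL, &BL);
  return subspace_ca_cfg(lcc_open ? 1 : 0, ryr_open ? 1 : 0, V, cai, cansr,
                         REAL(params), AL, BL);
}

// [[Rcpp::export(name = ".cpp_lcc_unitary_flux")]]
double cpp_lcc_unitary_flux(double V, double cass, NumericVector params) {
  check_params(params);
  double AL, BL;
  ghk_split(V, REAL(params), &AL, &BL);
  return AL - BL * cass;
}

// [[Rcpp::export(name = ".cpp_generator")]]
NumericMatrix cpp_generator(double V, double cai, double cansr,
                            NumericVector params) {
  check_params(params);
  if (cai <= 0.0 || cansr <= 0.0) stop("concentrations must be positive");
  const double* p = REAL(params);
  CaRUrates rt;
  caru_rates(V, cai, cansr, p, &rt);
  NumericMatrix Q(40, 40);
  double z[40], dz[40];
  for (int i = 0; i < 40; ++i) {
    std::memset(z, 0, sizeof(z));
    z[i] = 1.0;
    caru_derivs(z, &rt, p, dz);
    for (int jcol = 0; jcol < 40; ++jcol) Q(i, jcol) = dz[jcol];
  }
  for (int i = 0; i < 40; ++i)
    for (int jcol = 0; jcol < 40; ++jcol)
      if (!std::isfinite(Q(i, jcol)))
        stop("non-finite rate between states %d and %d", i + 1, jcol + 1);
  return Q; // Q[i, j] = rate i -> j (j != i); rows sum to zero
}

// [[Rcpp::export(name = ".cpp_caru_fluxes")]]
List cpp_caru_fluxes(NumericVector z, double V, double cai, double cansr,
                     NumericVector params) {
  check_params(params);
  if (z.size() != 40) stop("occupancy vector must have length 40");
  double s = 0.0;
  for (int i = 0; i < 40; ++i) s += z[i];
  if (std::fabs(s - 1.0) > 1e-6) stop("occupancy vector is not normalized");
  const double* p = REAL(params);
  CaRUrates rt;
  caru_rates(V, cai, cansr, p, &rt);
  double vr = p[P_ryr_nclust] * p[P_ryr_v1];
  double j_lcc = 0.0, j_ryr = 0.0, cass_avg = 0.0;
  for (int l = 0; l < 10; ++l) {
    for (int r = 0; r < 4; ++r) {
      double occ = z[l * 4 + r];
      int lcc_open = (l == 4), ryr_open = (r == 2);
      double cass = rt.cass[(lcc_open ? 1 : 0) + (ryr_open ? 2 : 0)];
      cass_avg += occ * cass;
      if (lcc_open) j_lcc += occ * (rt.AL - rt.BL * cass);
      if (ryr_open) j_ryr += occ * vr * (cansr - cass);
    }
  }
  double vss_tot = p[P_vss_dyad] * p[P_n_caru];
  double cf1 = 1e-3 * p[P_acap] * p[P_cmem] / (p[P_vmyo] * p[P_faraday]);
  double i_cal = -2.0 * (j_lcc * vss_tot / p[P_vmyo]) / cf1;
  return List::create(_["j_lcc"] = j_lcc, _["j_ryr"] = j_ryr,
                      _["i_cal"] = i_cal, _["ca_ss_avg"] = cass_avg);
}

// [[Rcpp::export(name = ".cpp_rhs")]]
NumericVector cpp_rhs(double t, NumericVector y, NumericVector params,
                      int mode, double istim, double vslope) {
  check_params(params);
  if (y.size() != N_STATE) stop("state vector must have length %d", N_STATE);
  NumericVector dy(N_STATE);
  model_rhs(t, REAL(y), REAL(params), mode, istim, vslope, REAL(dy), nullptr);
  for (int i = 0; i < N_STATE; ++i)
    if (!std::isfinite(dy[i]))
      stop("non-finite derivative for state %s", STATE_NAMES[i]);
  return dy;
}

// [[Rcpp::export(name = ".cpp_derived")]]
NumericMatrix cpp_derived(NumericMatrix y, NumericVector params) {
  check_params(params);
  if (y.ncol() != N_STATE) stop("state matrix must have %d columns", N_STATE);
  int n = y.nrow();
  NumericMatrix out(n, N_DERIVED);
  std::vector<double> row(N_STATE), dy(N_STATE);
  Derived der;
  for (int i = 0; i < n; ++i) {
    for (int jcol = 0; jcol < N_STATE; ++jcol) row[jcol] = y(i, jcol);
    model_rhs(0.0, row.data(), REAL(params), 1, 0.0, 0.0, dy.data(), &der);
    for (int jcol = 0; jcol < N_DERIVED; ++jcol) out(i, jcol) = der.out[jcol];
  }
  colnames(out) = cpp_derived_names();
  return out;
}

// Gillespie simulation of n independent LCC-RyR pairs under clamped
// (piecewise-constant between samples) V / Ca inputs.  Returns empirical
// occupancy (40 columns) at the supplied sample times.
// [[Rcpp::export(name = ".cpp_gillespie")]]
NumericMatrix cpp_gillespie(NumericVector times, NumericVector vtrace,
                            NumericVector cai_trace, NumericVector cansr_trace,
                            NumericVector params, int n_pairs, int init_state) {
  check_params(params);
  int nt = times.size();
  if (vtrace.size() != nt || cai_trace.size() != nt || cansr_trace.size() != nt)
    stop("input traces must share the time grid");
  if (n_pairs < 1) stop("n_pairs must be >= 1");
  const double* p = REAL(params);
  NumericMatrix occ(nt, 40);
  std::vector<int> state(n_pairs, init_state);

  // count initial occupancy
  for (int k = 0; k < n_pairs; ++k) occ(0, state[k]) += 1.0;

  double rates[64];
  int targets[64];

  for (int it = 1; it < nt; ++it) {
    double t0 = times[it - 1], t1 = times[it];
    CaRUrates rt;
    caru_rates(vtrace[it - 1], cai_trace[it - 1], cansr_trace[it - 1], p, &rt);
    for (int k = 0; k < n_pairs; ++k) {
      double t = t0;
      int s = state[k];
      while (true) {
        // enumerate outgoing transitions of joint state s
        int l = s / 4, r = s % 4, mode = l / 5, pos = l % 5, nr = 0;
        int lcc_open = (l == 4), ryr_open = (r == 2);
        const double fw[3] = {3.0, 2.0, 1.0};
        const double bw[3] = {1.0, 2.0, 3.0};
        if (pos < 3) { rates[nr] = fw[pos] * rt.alpha; targets[nr++] = s + 4; }
        if (pos > 0 && pos < 4) { rates[nr] = bw[pos - 1] * rt.beta; targets[nr++] = s - 4; }
        if (pos == 3 && mode == 0) { rates[nr] = rt.f; targets[nr++] = s + 4; }
        if (pos == 4) { rates[nr] = rt.g; targets[nr++] = s - 4; }
        if (mode == 0) {
          rates[nr] = rt.vdi + cdi_rate(&rt, p, lcc_open, ryr_open);
          targets[nr++] = s + 20;
        } else {
          rates[nr] = rt.rec; targets[nr++] = s - 20;
        }
        double k12 = rt.k12[lcc_open];
        switch (r) {
          case 0: rates[nr] = k12; targets[nr++] = s + 1; break;
          case 1: rates[nr] = rt.k21; targets[nr++] = s - 1;
                  rates[nr] = rt.k23; targets[nr++] = s + 1; break;
          case 2: rates[nr] = rt.k32; targets[nr++] = s - 1;
                  rates[nr] = rt.k34; targets[nr++] = s + 1; break;
          case 3: rates[nr] = rt.k41; targets[nr++] = s - 3; break;
        }
        double rtot = 0.0;
        for (int q = 0; q < nr; ++q) rtot += rates[q];
        if (rtot <= 0.0) break;
        double dt = -std::log(R::runif(0.0, 1.0)) / rtot;
        if (t + dt > t1) break;
        t += dt;
        double u = R::runif(0.0, 1.0) * rtot, acc = 0.0;
        for (int q = 0; q < nr; ++q) {
          acc += rates[q];
          if (u <= acc) { s = targets[q]; break; }
        }
      }
      state[k] = s;
    }
    for (int k = 0; k < n_pairs; ++k) occ(it, state[k]) += 1.0;
  }
  for (int it = 0; it < nt; ++it)
    for (int s = 0; s < 40; ++s) occ(it, s) /= n_pairs;
  return occ;
}

// ---------------------------------------------------------------------------
// Registration: expose the deSolve entry points as registered C routines and
// keep dynamic symbol lookup for the Rcpp attribute wrappers.
// ---------------------------------------------------------------------------
extern "C" {
static const R_CMethodDef CEntries[] = {
  {"gp_derivs", (DL_FUNC) &gp_derivs, 6},
  {"gp_initmod", (DL_FUNC) &gp_initmod, 1},
  {NULL, NULL, 0}
};

void R_init_gpmyocyte(DllInfo* dll) {
  R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
  R_useDynamicSymbols(dll, TRUE);
}
}
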