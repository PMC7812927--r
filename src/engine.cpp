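// Compiled daily simulation loop. Mirrors the R reference path
// (daily_step and the module operations it composes) operation for
// operation; the R/C++ equivalence is asserted by the test suite.
#include <Rcpp.h>
using namespace Rcpp;

static const int N_POOLS = 12;
static const int N_GUILDS = 9;
static const int N_TRACE = 42;

// smallest accessible pore class (0-based: 0 inac, 1 bact, 2 micro,
// 3 meso, 4 macro) by body-size code 1..4; engineers override to 1
static inline int min_class_for_size(int size_code) {
  switch (size_code) {
    case 1: return 1;  // bacteria enter bacterial pores and larger
    case 2: return 2;
    case 3: return 3;
    default: return 4;
  }
}

static inline double temp_modifier(double T, double Tmin, double Topt,
                                   double Tmax, double Q) {
  if (T < Tmin || T >= Tmax) return 0.0;
  if (T < Topt) return std::pow(Q, (T - Topt) / 10.0);
  return 1.0;
}

static inline double resp_temp_factor(double T, double Topt, double Q) {
  return std::pow(Q, (T - Topt) / 10.0);
}

static inline double ph_mod_bacteria(double pH) {
  if (pH <= 2.9) return std::min(1.0, 1.0 / ((3.0 - pH) * 10.0));
  return 1.0;
}

static inline double ph_mod_fungi(double pH) {
  if (pH >= 8.1) return std::min(1.0, 1.0 / ((pH - 8.0) * 10.0));
  return 1.0;
}

static inline double ph_gmax_eng(double g_max, double pH) {
  if (pH < 3.0) return 0.0;
  if (pH < 5.0) return (g_max / 2.0) * (pH - 3.0);
  return g_max;
}

// [[Rcpp::export]]
List engine_run(NumericVector st0, NumericMatrix clim, NumericMatrix gm,
                NumericMatrix dm, NumericVector pars) {
  const int n_days = clim.nrow();
  const int n_links = dm.nrow();

  // unpack parameters (see engine_run_from in R/engine.R for the layout)
  double pv_text[5];
  for (int i = 0; i < 5; ++i) pv_text[i] = pars[i];
  const double f_PV = pars[5], PV_Bmax = pars[6], VE_ratio = pars[7],
    tPV_B = pars[8], k_agg = pars[9], c_agg = pars[10], PV_Ag_cap = pars[11];
  const bool meso_drains = pars[12] != 0;
  const double I_maxMat = pars[13], subsoil_imax = pars[14], th = pars[15],
    pH = pars[16], fClay = pars[17], D_b = pars[18], f_DOM = pars[19],
    aKD = pars[20], bKD = pars[21], cKD = pars[22], litterfall = pars[23],
    rootlitter = pars[24], myc_alloc = pars[25], exudation = pars[26],
    root_pool = pars[27], root_growth = pars[28], CN_lf = pars[29],
    Rec_lf = pars[30], CN_rl = pars[31], Rec_rl = pars[32],
    biot_lit = pars[33], biot_som = pars[34];
  const bool myc_ph_fungal = pars[35] != 0, eq16_alt = pars[36] != 0,
    use_T = pars[37] != 0, use_pH = pars[38] != 0, use_CN = pars[39] != 0,
    use_rec = pars[40] != 0, use_H2O = pars[41] != 0,
    most_limiting = pars[42] != 0;

  // state
  double p[N_POOLS];
  for (int i = 0; i < N_POOLS; ++i) p[i] = st0[i];
  double CN_lit = st0[12], Rec_lit = st0[13], CN_SOM = st0[14],
    Rec_SOM = st0[15], PV_B = st0[16], SW = st0[17], R_tot_prev = st0[18],
    CO2_cum = st0[19], leach_cum = st0[20], biot_cum = st0[21],
    inputs_cum = st0[22];
  int day = (int) st0[23];

  const double K_D = aKD - bKD * pH + cKD * fClay;
  const double dis_frac = 1.0 / (1.0 + K_D * 1000.0 * D_b);

  std::vector<double> li_G(n_links), li_cons(n_links), li_faec(n_links),
    li_fN(n_links), li_fRec(n_links);

  NumericMatrix trace(n_days, N_TRACE);

  for (int t = 0; t < n_days; ++t) {
    const double P_mm = clim(t, 0), E_mm = clim(t, 1), T_C = clim(t, 2);

    // (a) pore structure
    double Ag = 0.0;
    if (p[10] > 0)
      Ag = std::min(1.0, c_agg * (p[1] + p[2]) / p[10]);
    const double PV_Ag = std::min(PV_Ag_cap, k_agg * Ag * p[10]);
    const double agg_half = PV_Ag / 2.0;
    const double meso_shift = (Ag / 4.0) * pv_text[3];
    double pv[5];
    pv[0] = pv_text[0];
    pv[1] = std::max(0.0, pv_text[1] + agg_half + meso_shift);
    pv[2] = std::max(0.0, pv_text[2] + agg_half + meso_shift);
    pv[3] = std::max(0.0, pv_text[3] - (1.0 - f_PV) * PV_B -
                           (Ag / 2.0) * pv_text[3]);
    pv[4] = std::max(0.0, pv_text[4] + PV_B);
    double PV_tot = pv[0] + pv[1] + pv[2] + pv[3] + pv[4];

    // (b) water balance
    const double P_net = P_mm - E_mm;
    const double SA = std::min(1.0, std::max(0.0, pv[4] / 1000.0));
    double runoff = 0, fill = 0, bypass = 0, spill = 0, et = 0;
    if (P_net >= 0) {
      const double I_maxPor = pv[4] * th + subsoil_imax;
      runoff = std::max(0.0, P_net - (I_maxPor + I_maxMat));
      const double Pn = P_net - runoff;
      const double free_mm = std::max(0.0, PV_tot - SW) * th;
      fill = std::min(free_mm, std::min(I_maxMat * (1.0 - SA),
                                        Pn * (1.0 - SA)));
      if (fill < 0) fill = 0;
      bypass = Pn - fill;
      SW += fill / th;
      double fc = pv[0] + pv[1] + pv[2];
      if (!meso_drains) fc += pv[3];
      spill = std::max(0.0, SW - fc);
      SW -= spill;
    } else {
      const double demand = -P_net / th;
      et = std::min(demand, std::max(0.0, SW - pv[0]));
      SW -= et;
    }
    if (SW > PV_tot) { spill += SW - PV_tot; SW = PV_tot; }
    const double drainage = bypass / th + spill;

    // water allocation, smallest pores first
    double volW[5], volA[5];
    int partial = -1;
    {
      double rest = std::min(std::max(SW, 0.0), PV_tot);
      for (int c = 0; c < 5; ++c) {
        volW[c] = std::min(rest, pv[c]);
        rest -= volW[c];
        volA[c] = pv[c] - volW[c];
        if (partial < 0 && volW[c] < pv[c]) partial = c;
      }
    }

    // (c) DOM production (from yesterday's respiration) and leaching
    const double sol = std::min(f_DOM * R_tot_prev, p[10]);
    p[10] -= sol;
    p[11] += sol + exudation;
    inputs_cum += exudation;
    double leach = 0.0;
    if (p[11] > 0 && SW > 0 && drainage > 0) {
      leach = std::min(p[11], p[11] * dis_frac / SW * drainage);
    }
    p[11] -= leach;
    leach_cum += leach;

    // (d, e) moisture modifiers
    double m_class[5] = {1, 1, 1, 1, 1};
    double m_lit = 1.0;
    if (use_H2O) {
      double m_tot_H2O = 0.0;
      if (PV_tot > 0) {
        const double x = SW / PV_tot;
        m_tot_H2O = (x < 0.5) ? 4.0 * x * (1.0 - x) : 1.0;
      }
      for (int c = 0; c < 5; ++c) m_class[c] = 0.0;
      if (partial >= 0) {
        const double tot = volW[partial] + volA[partial];
        if (tot > 0) {
          m_class[partial] = volA[partial] / tot * m_tot_H2O;
          if (partial < 4)
            m_class[partial + 1] = (eq16_alt ? volA[partial] : volW[partial])
              / tot * m_tot_H2O;
        }
      }
      double denom = pv[1] + pv[2] + pv[3] + pv[4];
      m_lit = 0.0;
      if (denom > 0) {
        for (int c = 1; c < 5; ++c) m_lit += pv[c] * m_class[c];
        m_lit /= denom;
      }
    }

    // (f) fluxes: per-guild modifiers, then the diet links
    double m_T[N_GUILDS], fR[N_GUILDS], m_pH[N_GUILDS], g_base[N_GUILDS];
    for (int i = 0; i < N_GUILDS; ++i) {
      if (use_T) {
        m_T[i] = temp_modifier(T_C, gm(i, 8), gm(i, 9), gm(i, 10), gm(i, 11));
        fR[i] = resp_temp_factor(T_C, gm(i, 9), gm(i, 11));
      } else { m_T[i] = 1.0; fR[i] = 1.0; }
      m_pH[i] = 1.0;
      g_base[i] = gm(i, 0);
      if (use_pH) {
        if (i == 0) m_pH[i] = ph_mod_bacteria(pH);
        if (i == 1) m_pH[i] = ph_mod_fungi(pH);
        if (i == 2 && myc_ph_fungal) m_pH[i] = ph_mod_fungi(pH);
        if (i == 6) g_base[i] = ph_gmax_eng(gm(i, 0), pH);
      }
    }

    for (int l = 0; l < n_links; ++l) {
      li_G[l] = li_cons[l] = li_faec[l] = li_fN[l] = li_fRec[l] = 0.0;
      const int i = (int) dm(l, 0) - 1;      // consumer guild, 0-based
      const int sub = (int) dm(l, 1);        // 1..12 pool, 13 roots
      const double B = p[i];
      if (B <= 0) continue;
      const double S = (sub == 13) ? root_pool : p[sub - 1];
      if (S <= 0) continue;
      const bool dead = (sub == 10 || sub == 11);
      double m_CN = 1.0, m_rec = 1.0, CN_sub = 0.0, Rec_sub = 0.0;
      if (dead) {
        CN_sub = (sub == 10) ? CN_lit : CN_SOM;
        Rec_sub = (sub == 10) ? Rec_lit : Rec_SOM;
        if (use_CN && gm(i, 6) > 0)
          m_CN = std::min(1.0, std::pow(gm(i, 5) / CN_sub, gm(i, 6)));
        if (use_rec && gm(i, 7) > 0)
          m_rec = std::min(1.0, 1.0 - gm(i, 7) * Rec_sub);
      }
      // accessibility
      double f_a;
      if (sub == 10) {
        f_a = 1.0;
      } else {
        int sub_min;
        if (sub == 11) sub_min = 0;
        else if (sub == 13) sub_min = 3;
        else sub_min = (sub - 1 == 6) ? 1
               : min_class_for_size((int) gm(sub - 1, 12));
        int lo = (i == 6) ? 1 : min_class_for_size((int) gm(i, 12));
        if (lo < sub_min) lo = sub_min;
        double denom = 0.0, num = 0.0;
        for (int c = sub_min; c < 5; ++c) denom += pv[c];
        for (int c = lo; c < 5; ++c) num += pv[c] * m_class[c];
        f_a = (denom > 0) ? num / denom : 0.0;
      }
      const double m_H2O_comp = (sub == 10) ? m_lit : 1.0;
      double m_tot;
      if (most_limiting) {
        m_tot = std::min(std::min(std::min(m_T[i], m_pH[i]),
                                  std::min(m_CN, m_rec)), m_H2O_comp);
      } else {
        m_tot = m_T[i] * m_pH[i] * m_CN * m_rec * m_H2O_comp;
      }
      const double G = g_base[i] * m_tot * (S * f_a / (dm(l, 2) + S)) * B;
      li_G[l] = G;
      if (dead) {
        double ff = gm(i, 3);
        if (i == 5 || i == 6) {  // detritivores, engineers
          ff = gm(i, 3) + gm(i, 4) * (CN_sub - gm(i, 5)) / CN_sub * gm(i, 3);
          ff = std::min(std::max(ff, 0.0), 0.999);
        }
        li_cons[l] = G / (1.0 - ff);
        li_faec[l] = li_cons[l] - G;
        li_fN[l] = li_faec[l] / CN_sub;
        li_fRec[l] = li_faec[l] * Rec_sub;
      } else {
        const double ff = gm(i, 3);
        li_cons[l] = G * (1.0 + ff);
        li_faec[l] = G * ff;
        const double CN_f = (sub == 13) ? CN_rl : gm(sub - 1, 5);
        li_fN[l] = li_faec[l] / CN_f;
        li_fRec[l] = 0.0;
      }
    }

    double R[N_GUILDS], Dt[N_GUILDS], prey_loss[N_GUILDS];
    for (int i = 0; i < N_GUILDS; ++i) {
      R[i] = gm(i, 1) * fR[i] * p[i];
      Dt[i] = gm(i, 2) * p[i];
      prey_loss[i] = 0.0;
    }
    for (int l = 0; l < n_links; ++l) {
      const int src = (int) dm(l, 1);
      if (src >= 1 && src <= 9) prey_loss[src - 1] += li_cons[l];
    }

    // (g) conserving Euler update with per-pool flux limiting
    double out[N_POOLS] = {0};
    for (int i = 0; i < N_GUILDS; ++i)
      out[i] = R[i] + Dt[i] + prey_loss[i];
    for (int l = 0; l < n_links; ++l) {
      const int src = (int) dm(l, 1);
      if (src == 10 || src == 11) out[src - 1] += li_cons[l];
    }
    double lambda[N_POOLS];
    for (int i = 0; i < N_POOLS; ++i)
      lambda[i] = (out[i] > p[i] && out[i] > 0) ? p[i] / out[i] : 1.0;
    // root boundary pool: replenished daily, so at most root_pool per day
    double root_out = 0.0;
    for (int l = 0; l < n_links; ++l)
      if ((int) dm(l, 1) == 13) root_out += li_cons[l];
    const double lam_root =
      (root_out > root_growth && root_out > 0) ? root_growth / root_out
                                               : 1.0;

    double G_in[N_GUILDS] = {0};
    double cons_lit = 0, cons_som = 0, root_cons = 0, faec_sum = 0,
      fN_sum = 0, fRec_sum = 0;
    double resp_b = 0, resp_f = 0, resp_m = 0, cons_lit_b = 0,
      cons_som_b = 0, cons_lit_e = 0;
    for (int l = 0; l < n_links; ++l) {
      const int src = (int) dm(l, 1);
      const int i = (int) dm(l, 0) - 1;
      const double s = (src == 13) ? lam_root : lambda[src - 1];
      G_in[i] += s * li_G[l];
      const double cs = s * li_cons[l];
      faec_sum += s * li_faec[l];
      fN_sum += s * li_fN[l];
      fRec_sum += s * li_fRec[l];
      if (src == 10) {
        cons_lit += cs;
        if (i == 0) cons_lit_b += cs;
        if (i == 6) cons_lit_e += cs;
      } else if (src == 11) {
        cons_som += cs;
        if (i == 0) cons_som_b += cs;
      } else if (src == 13) {
        root_cons += cs;
      }
    }
    G_in[2] += myc_alloc;

    double R_tot = 0, Dt_sum = 0, DtN_sum = 0;
    for (int i = 0; i < N_GUILDS; ++i) {
      const double Rs = lambda[i] * R[i];
      const double Ds = lambda[i] * Dt[i];
      R_tot += Rs;
      Dt_sum += Ds;
      DtN_sum += Ds / gm(i, 5);
      p[i] = std::max(0.0, p[i] + G_in[i] -
                      lambda[i] * (R[i] + Dt[i] + prey_loss[i]));
      if (i == 0) resp_b = Rs;
      if (i == 1) resp_f = Rs;
      if (i == 2) resp_m = Rs;
    }
    const double som_in = rootlitter + faec_sum + Dt_sum;
    p[9] = std::max(0.0, p[9] + litterfall - cons_lit);
    p[10] = std::max(0.0, p[10] + som_in - cons_som);
    CO2_cum += R_tot;
    inputs_cum += litterfall + rootlitter + myc_alloc + root_cons;

    // (h) quality update: harmonic C:N (conserves N), mass-weighted Rec
    {
      const double retained = std::max(p[9] - litterfall, 0.0);
      const double total = retained + litterfall;
      if (total > 0 && litterfall > 0) {
        const double N = retained / CN_lit + litterfall / CN_lf;
        if (N > 0) CN_lit = total / N;
        Rec_lit = (retained * Rec_lit + litterfall * Rec_lf) / total;
      }
    }
    {
      const double in_N = rootlitter / CN_rl + fN_sum + DtN_sum;
      const double in_rec = rootlitter * Rec_rl + fRec_sum;
      const double retained = std::max(p[10] - som_in, 0.0);
      const double total = retained + som_in;
      if (total > 0 && som_in > 0) {
        const double N = retained / CN_SOM + in_N;
        if (N > 0) CN_SOM = total / N;
        Rec_SOM = (retained * Rec_SOM + in_rec) / total;
      }
    }

    // (i) engineering: burrow volume and bioturbation export
    PV_B = std::max(std::min(PV_Bmax, VE_ratio * p[6]),
                    PV_B * (1.0 - tPV_B));
    const double exp_lit = std::min(p[9], biot_lit * p[6]);
    const double exp_som = std::min(p[10], biot_som * p[6]);
    p[9] -= exp_lit;
    p[10] -= exp_som;
    biot_cum += exp_lit + exp_som;

    ++day;
    int k = 0;
    trace(t, k++) = day;
    for (int i = 0; i < N_POOLS; ++i) trace(t, k++) = p[i];
    trace(t, k++) = CO2_cum;
    trace(t, k++) = leach_cum;
    trace(t, k++) = biot_cum;
    trace(t, k++) = inputs_cum;
    trace(t, k++) = SW;
    trace(t, k++) = runoff;
    trace(t, k++) = fill;
    trace(t, k++) = bypass;
    trace(t, k++) = et;
    trace(t, k++) = drainage;
    trace(t, k++) = leach;
    trace(t, k++) = R_tot;
    for (int c = 0; c < 5; ++c) trace(t, k++) = pv[c];
    trace(t, k++) = PV_B;
    trace(t, k++) = Ag;
    trace(t, k++) = CN_lit;
    trace(t, k++) = Rec_lit;
    trace(t, k++) = CN_SOM;
    trace(t, k++) = Rec_SOM;
    trace(t, k++) = resp_b;
    trace(t, k++) = resp_f;
    trace(t, k++) = resp_m;
    trace(t, k++) = cons_lit_b;
    trace(t, k++) = cons_som_b;
    trace(t, k++) = cons_lit_e;

    R_tot_prev = R_tot;
  }

  NumericVector fs(24);
  for (int i = 0; i < N_POOLS; ++i) fs[i] = p[i];
  fs[12] = CN_lit; fs[13] = Rec_lit; fs[14] = CN_SOM; fs[15] = Rec_SOM;
  fs[16] = PV_B; fs[17] = SW; fs[18] = R_tot_prev; fs[19] = CO2_cum;
  fs[20] = leach_cum; fs[21] = biot_cum; fs[22] = inputs_cum; fs[23] = day;
  return List::create(_["trace"] = trace, _["state"] = fs);
}
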